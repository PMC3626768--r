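test_that("tumor kind follows the 3.5 mean-seed-index rule, boundary to HCC", {
  lab <- array(0L, c(3, 10, 10))
  lab[2, , ] <- 3L
  lab[2, 5, 5] <- 1L
  lab[2, 5, 6] <- 6L
  cl <- fake_clusters(lab)
  s_dark <- seed_set(c(2, 5, 5), "tumor")
  expect_equal(classify_tumor_kind(cl, s_dark)$kind, "metastasis")
  s_mixed <- seed_set(rbind(c(2, 5, 5), c(2, 5, 6)), "tumor") # mean 3.5 exactly
  k <- classify_tumor_kind(cl, s_mixed)
  expect_equal(k$mean_seed_index, 3.5)
  expect_equal(k$kind, "HCC")
  expect_error(classify_tumor_kind(cl, seed_set(c(1, 1, 1), "tumor")),
               "outside the liver")
  expect_error(classify_tumor_kind(cl, seed_set(c(2, 5, 5), "necrosis")),
               "target")
})

test_that("monotone growth climbs concentric rings but cannot descend or escape the band", {
  # rings 1|2|3 with parenchyma 5 outside; lone dark voxel in the parenchyma
  lab <- matrix(5L, 30, 30)
  mk_disc <- function(r) outer(1:30, 1:30, function(i, j) (i - 15)^2 + (j - 15)^2 <= r^2)
  lab[mk_disc(9)] <- 3L
  lab[mk_disc(6)] <- 2L
  lab[mk_disc(3)] <- 1L
  lab[2, 2] <- 1L # disjoint dark voxel
  g <- cpp_grow_monotone(lab, matrix(c(15, 15), 1), 1L, 1L, 4L)
  expect_true(all(g[mk_disc(9)]))
  expect_false(g[2, 2])
  expect_false(any(g & lab == 5L))
  # seed inside a cluster-2 pocket walled by >= 3: growth ascends into the
  # wall ring but cannot cross below its own level on the far side
  lab2 <- matrix(1L, 20, 20)
  lab2[8:12, 8:12] <- 2L
  lab2[7, 7:13] <- 3L; lab2[13, 7:13] <- 3L
  lab2[7:13, 7] <- 3L; lab2[7:13, 13] <- 3L
  g2 <- cpp_grow_monotone(lab2, matrix(c(10, 10), 1), 1L, 1L, 4L)
  expect_true(all(g2[8:12, 8:12]))
  expect_false(any(g2[lab2 == 1L])) # the outer 1s are a descent: blocked
})

test_that("growth on a slice without in-band voxels stays empty without error", {
  lab <- array(5L, c(2, 10, 10))
  lab[1, 4:6, 4:6] <- 1L
  cl <- fake_clusters(lab)
  s <- seed_set(rbind(c(1, 5, 5), c(2, 5, 5)), "tumor")
  m <- suppressWarnings(extract_tumor(cl, s, structure(list(kind = "metastasis"),
                                                       class = "tumor_kind")))
  expect_equal(sum(m$voxels[2, , ]), 0)
  expect_equal(sum(m$voxels[1, , ]), 9)
})

test_that("only the seeded lesion of two disjoint ones is extracted", {
  lab <- array(6L, c(1, 40, 40))
  lab[1, 5:10, 5:10] <- 1L
  lab[1, 25:30, 25:30] <- 1L
  cl <- fake_clusters(lab)
  m <- extract_tumor(cl, seed_set(c(1, 7, 7), "tumor"),
                     structure(list(kind = "metastasis"), class = "tumor_kind"))
  expect_true(all(m$voxels[1, 5:10, 5:10]))
  expect_false(any(m$voxels[1, 25:30, 25:30]))
})

test_that("a larger band never shrinks the extracted tumor", {
  p <- small_phantom()
  pp <- preprocess_volume(p$pre, p$liver_mask_pre)
  cl <- fcm_cluster(pp$enhanced, p$liver_mask_pre)
  seeds <- phantom_seeds(p, "tumor")
  kind <- classify_tumor_kind(cl, seeds)
  m2 <- suppressWarnings(extract_tumor(cl, seeds, kind, delta = 2))
  m3 <- suppressWarnings(extract_tumor(cl, seeds, kind, delta = 3))
  expect_true(all(m3$voxels[m2$voxels]))
})

test_that("grossly inconsistent tumor seeds are rejected", {
  lab <- array(7L, c(1, 10, 10))
  cl <- fake_clusters(lab)
  expect_error(extract_tumor(cl, seed_set(c(1, 5, 5), "tumor"),
                             structure(list(kind = "metastasis"), class = "tumor_kind")),
               "inconsistent with a \\(hypodense\\) metastasis")
  lab2 <- array(1L, c(1, 10, 10))
  expect_error(extract_tumor(fake_clusters(lab2), seed_set(c(1, 5, 5), "tumor"),
                             structure(list(kind = "HCC"), class = "tumor_kind")),
               "inconsistent with a \\(hyperdense\\) HCC")
})

test_that("uniform necrosis is the seeded component of the two darkest clusters", {
  lab <- array(5L, c(1, 30, 30))
  lab[1, 10:20, 10:20] <- 2L
  lab[1, 12:18, 12:18] <- 1L
  lab[1, 2:4, 2:4] <- 1L # unseeded dark blob elsewhere
  cl <- fake_clusters(lab)
  m <- extract_necrosis(cl, seed_set(c(1, 15, 15), "necrosis"))
  expect_true(all(m$voxels[1, 10:20, 10:20]))
  expect_false(any(m$voxels[1, 2:4, 2:4]))
})

test_that("a seeded hyperdense patch is relabelled and absorbed into the necrosis", {
  lab <- array(5L, c(1, 40, 40))
  lab[1, 10:30, 10:30] <- 1L     # hypodense necrosis
  lab[1, 18:24, 18:24] <- 7L     # hyperdense coagulation inside it
  cl <- fake_clusters(lab)
  seeds <- seed_set(rbind(c(1, 12, 12), c(1, 20, 20)), "necrosis")
  m <- extract_necrosis(cl, seeds)
  expect_true(all(m$voxels[1, 10:30, 10:30]))
  # without the patch seed the hyperdense area stays out
  m0 <- extract_necrosis(cl, seed_set(c(1, 12, 12), "necrosis"))
  expect_false(any(m0$voxels[1, 19:23, 19:23]))
})

test_that("growth cannot cross a bright ring around a dark seed pocket", {
  lab <- array(1L, c(1, 30, 30))
  lab[1, 10:20, 10:20] <- 2L
  lab[1, 9, 9:21] <- 5L; lab[1, 21, 9:21] <- 5L
  lab[1, 9:21, 9] <- 5L; lab[1, 9:21, 21] <- 5L
  cl <- fake_clusters(lab)
  m <- extract_necrosis(cl, seed_set(c(1, 15, 15), "necrosis"))
  expect_true(all(m$voxels[1, 10:20, 10:20]))
  expect_false(any(m$voxels[1, 1:8, ]))
})

test_that("cleanup removes thin tails, fills holes and clips to the eroded liver", {
  liver <- roi_mask(array(TRUE, c(1, 40, 40)), "liver", c(5, 1, 1))
  vox <- array(FALSE, c(1, 40, 40))
  vox[1, 10:25, 10:25] <- TRUE
  vox[1, 17, 26:38] <- TRUE       # 1-voxel vessel-like tail
  vox[1, 15, 15] <- FALSE         # interior pinhole
  m <- roi_mask(vox, "tumor", c(5, 1, 1))
  cleaned <- morphological_cleanup(m, liver, seeds = seed_set(c(1, 12, 12), "tumor"))
  expect_false(any(cleaned$voxels[1, 17, 30:38]))
  expect_true(cleaned$voxels[1, 15, 15])
  # leaking outside the liver gets clipped
  small_liver <- roi_mask(array(FALSE, c(1, 40, 40)), "liver", c(5, 1, 1))
  small_liver$voxels[1, 5:30, 5:30] <- TRUE
  vox2 <- array(FALSE, c(1, 40, 40)); vox2[1, 20:35, 20:35] <- TRUE
  c2 <- morphological_cleanup(roi_mask(vox2, "tumor", c(5, 1, 1)), small_liver,
                              seeds = seed_set(c(1, 22, 22), "tumor"))
  expect_true(all(which(c2$voxels, arr.ind = TRUE)[, 2:3] <= 29))
})

test_that("a compact convex mask survives cleanup almost unchanged", {
  liver <- roi_mask(array(TRUE, c(1, 40, 40)), "liver", c(5, 1, 1))
  vox <- array(FALSE, c(1, 40, 40))
  vox[1, , ] <- raster_ellipse(40, 12, 8, 20)
  m <- roi_mask(vox, "tumor", c(5, 1, 1))
  cleaned <- morphological_cleanup(m, liver, seeds = seed_set(c(1, 20, 20), "tumor"))
  expect_gte(dice(m, cleaned), 0.97)
})

test_that("cleanup that would empty the mask returns the input with a warning", {
  liver <- roi_mask(array(TRUE, c(1, 20, 20)), "liver", c(5, 1, 1))
  vox <- array(FALSE, c(1, 20, 20))
  vox[1, 5, 5] <- TRUE # a single voxel: opening erases it
  m <- roi_mask(vox, "tumor", c(5, 1, 1))
  expect_warning(out <- morphological_cleanup(m, liver,
                                              seeds = seed_set(c(1, 5, 5), "tumor")),
                 "emptied")
  expect_identical(out$voxels, vox)
})

test_that("phantom tumor and necrosis segmentations beat the PM/P+ bounds", {
  p <- small_phantom()
  pp <- preprocess_volume(p$pre, p$liver_mask_pre)
  cl <- fcm_cluster(pp$enhanced, p$liver_mask_pre)
  seeds <- phantom_seeds(p, "tumor")
  tm <- morphological_cleanup(
    suppressWarnings(extract_tumor(cl, seeds, classify_tumor_kind(cl, seeds))),
    p$liver_mask_pre, seeds = seeds)
  v <- validate_segmentation(p$gt_tumor, tm, p$liver_mask_pre)
  expect_gte(v$pm, 90)
  expect_gte(v$pplus, 94)

  ppn <- preprocess_volume(p$post, p$liver_mask_post)
  cln <- fcm_cluster(ppn$enhanced, p$liver_mask_post)
  sn <- phantom_seeds(p, "necrosis")
  nm <- morphological_cleanup(extract_necrosis(cln, sn), p$liver_mask_post,
                              seeds = sn)
  vn <- validate_segmentation(p$gt_necrosis, nm, p$liver_mask_post)
  expect_gte(vn$pm, 90)
  expect_gte(vn$pplus, 94)
})
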