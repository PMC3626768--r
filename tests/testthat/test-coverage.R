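mask3d <- function(arr, role = "tumor", sp = c(5, 1, 1)) roi_mask(arr, role, sp)

block_mask <- function(dim3, slices, rows, cols) {
  a <- array(FALSE, dim3)
  a[slices, rows, cols] <- TRUE
  a
}

# Chebyshev distance from every tumor voxel to the nearest non-necrosis voxel,
# by brute force: the independent margin oracle (a 3x3 dilation per iteration
# grows the mask by one Chebyshev unit)
cheb_margin_oracle <- function(tum2, nec2) {
  if (any(tum2 & !nec2)) return(0L)
  tu <- which(tum2, arr.ind = TRUE)
  comp <- which(!nec2, arr.ind = TRUE)
  if (nrow(comp) == 0) return(Inf)
  d <- min(vapply(seq_len(nrow(tu)), function(i) {
    min(pmax(abs(comp[, 1] - tu[i, 1]), abs(comp[, 2] - tu[i, 2])))
  }, numeric(1)))
  as.integer(d - 1)
}

test_that("residual tumor volume and percentage follow the voxel arithmetic", {
  dims <- c(2, 50, 50)
  tum <- mask3d(block_mask(dims, 1, 1:20, 1:50))   # 1000 voxels
  nec <- mask3d(block_mask(dims, 1, 1:18, 1:50), "necrosis") # covers 900
  r <- residual_tumor(tum, nec, c(5, 1, 1))
  expect_equal(r$percent, 10)
  expect_equal(r$volume_cm3, 100 * 5 / 1000)
  # containment and disjointness
  expect_equal(residual_tumor(tum, tum, c(5, 1, 1))$percent, 0)
  far <- mask3d(block_mask(dims, 2, 30:40, 30:40), "necrosis")
  expect_equal(residual_tumor(tum, far, c(5, 1, 1))$percent, 100)
  expect_error(residual_tumor(mask3d(array(FALSE, dims)), nec), "empty")
})

test_that("margin by dilation matches the concentric-square arithmetic", {
  dims <- c(1, 41, 41)
  tum <- mask3d(block_mask(dims, 1, 16:26, 16:26))        # half-width 5
  nec <- mask3d(block_mask(dims, 1, 12:30, 12:30), "necrosis") # half-width 9
  tfm <- tumor_free_margin(tum, nec, c(5, 1, 1))
  expect_equal(unname(tfm$per_slice), 4)
  # equal masks: the first dilation already escapes
  expect_equal(unname(tumor_free_margin(tum, tum, c(5, 1, 1))$per_slice), 0)
  # any residual voxel forces margin 0 on that slice
  nec2 <- nec; nec2$voxels[1, 20, 20] <- FALSE
  expect_equal(unname(tumor_free_margin(tum, nec2, c(5, 1, 1))$per_slice), 0)
})

test_that("iterative-dilation margin equals the Chebyshev distance-transform oracle", {
  set.seed(31)
  p <- 1
  for (i in 1:20) {
    n <- 36
    tum2 <- raster_ellipse(n, runif(1, 3, 7), runif(1, 2, 6), runif(1, 0, 180))
    grow <- sample(0:4, 1)
    nec2 <- tum2
    if (grow > 0) for (k in seq_len(grow)) nec2 <- EBImage::dilate(nec2, EBImage::makeBrush(3, "box")) > 0
    if (runif(1) < 0.3) nec2[sample(which(tum2), 1)] <- FALSE # residual case
    tum <- mask3d(array(tum2, c(1, n, n)))
    nec <- mask3d(array(nec2, c(1, n, n)), "necrosis")
    got <- unname(tumor_free_margin(tum, nec, c(5, p, p))$per_slice)
    expect_equal(got, max(cheb_margin_oracle(tum2, nec2), 0) * p)
  }
})

test_that("barycentric distance is exact for known translations", {
  dims <- c(1, 60, 60)
  tum <- mask3d(block_mask(dims, 1, 20:30, 20:30))
  same <- mask3d(block_mask(dims, 1, 20:30, 20:30), "necrosis")
  expect_equal(unname(barycenter_distance(tum, same)$per_slice), 0)
  shifted <- mask3d(block_mask(dims, 1, 23:33, 24:34), "necrosis")
  bd <- barycenter_distance(tum, shifted, c(5, 0.74, 0.74))
  expect_equal(unname(bd$per_slice), 5 * 0.74, tolerance = 1e-9)
})

test_that("barycentric distance is translation-equivariant slice-wise", {
  p <- small_phantom_clean()
  tum <- p$gt_tumor
  for (v in list(c(2, 0), c(0, 3), c(4, 5))) {
    shifted <- tum$voxels
    shifted[] <- FALSE
    idx <- which(tum$voxels, arr.ind = TRUE)
    idx[, 2] <- idx[, 2] + v[1]
    idx[, 3] <- idx[, 3] + v[2]
    shifted[idx] <- TRUE
    bd <- barycenter_distance(tum, mask3d(shifted, "necrosis", tum$spacing_mm),
                              tum$spacing_mm)
    expect_equal(unname(bd$per_slice),
                 rep(sqrt(sum(v^2)), length(bd$per_slice)), tolerance = 1e-9)
  }
})

test_that("moment-fitted orientations reproduce analytic rotations within 2 degrees", {
  for (th in c(0, 17, 30, 75, 120, 160)) {
    m <- raster_ellipse(64, 20, 9, th)
    got <- rfacover:::slice_orientation(m)
    d <- abs(got - th) %% 180
    expect_lt(min(d, 180 - d), 2)
  }
})

test_that("the orientation index folds into [0, 180) and handles the critical band", {
  n <- 64
  t30 <- mask3d(array(raster_ellipse(n, 18, 8, 30), c(1, n, n)))
  t75 <- mask3d(array(raster_ellipse(n, 18, 8, 75), c(1, n, n)), "necrosis")
  oi <- orientation_index(t30, t75)
  expect_equal(unname(oi$per_slice), 45, tolerance = 2)
  t0 <- mask3d(array(raster_ellipse(n, 18, 8, 0), c(1, n, n)))
  t90 <- mask3d(array(raster_ellipse(n, 18, 8, 90), c(1, n, n)), "necrosis")
  expect_equal(unname(orientation_index(t0, t90)$per_slice), 90, tolerance = 2)
  same <- mask3d(array(raster_ellipse(n, 18, 8, 40), c(1, n, n)), "necrosis")
  both40 <- mask3d(array(raster_ellipse(n, 20, 9, 40), c(1, n, n)))
  expect_equal(unname(orientation_index(both40, same)$per_slice), 0, tolerance = 2)
})

test_that("the orientation index is invariant under joint rotation", {
  n <- 80
  base_t <- 25; base_n <- 70
  for (rot in c(0, 15, 40)) {
    tt <- mask3d(array(raster_ellipse(n, 22, 10, base_t + rot), c(1, n, n)))
    nn <- mask3d(array(raster_ellipse(n, 24, 12, base_n + rot), c(1, n, n)), "necrosis")
    oi <- orientation_index(tt, nn)
    expect_equal(unname(oi$per_slice), 45, tolerance = 2)
  }
})

test_that("near-circular sections are flagged and excluded from the mean", {
  n <- 50
  circ <- mask3d(array(raster_ellipse(n, 12, 12, 0), c(1, n, n)))
  ell <- mask3d(array(raster_ellipse(n, 18, 8, 30), c(1, n, n)), "necrosis")
  oi <- orientation_index(circ, ell)
  expect_true(is.na(oi$per_slice[1]))
  expect_equal(oi$excluded_slices, 1L)
})

test_that("residual percentage is antitone in necrosis dilation", {
  p <- small_phantom()
  tum <- p$gt_tumor
  nec <- p$gt_necrosis
  nec$voxels <- tum$voxels # start from the tumor itself shifted a bit
  idx <- which(tum$voxels, arr.ind = TRUE)
  idx[, 3] <- pmin(idx[, 3] + 6, dim(tum$voxels)[3])
  nec$voxels[] <- FALSE
  nec$voxels[idx] <- TRUE
  prev <- Inf
  cur <- nec
  for (i in 1:4) {
    r <- residual_tumor(tum, cur)$percent
    expect_lte(r, prev)
    prev <- r
    cur <- dilate_roi(cur, 1)
  }
})

test_that("the full report assembles the indexes and round-trips through JSON", {
  p <- small_phantom()
  rep1 <- p$gt_coverage
  expect_s3_class(rep1, "coverage_report")
  expect_true(rep1$tfm_min_mm <= rep1$tfm_max_mm)
  expect_equal(rep1$tumor_slices, nrow(rep1$per_slice))
  f <- tempfile(fileext = ".json")
  write_coverage_report(rep1, f)
  rep2 <- read_coverage_report(f)
  for (field in c("residual_volume_cm3", "residual_percent", "tfm_min_mm",
                  "tfm_max_mm", "barycentric_mean_mm", "oi_mean_deg",
                  "tumor_volume_cm3"))
    expect_equal(rep2[[field]], rep1[[field]], tolerance = 1e-12)
  expect_equal(rep2$totally_treated, rep1$totally_treated)
  expect_equal(as.data.frame(rep2$per_slice), rep1$per_slice, tolerance = 1e-12)
})

test_that("the ideal margin contour is the tumor dilated to the safety margin", {
  dims <- c(1, 40, 40)
  tum <- mask3d(block_mask(dims, 1, 18:22, 18:22))
  ideal <- ideal_margin_mask(tum, c(5, 1, 1), margin_mm = 10)
  expect_true(all(ideal$voxels[1, 8:32, 8:32]))
  expect_equal(sum(ideal$voxels), 25 * 25) # square grown by 10 unit dilations
})
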