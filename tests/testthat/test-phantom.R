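test_that("phantom generation is deterministic for a fixed seed", {
  sp <- small_phantom_spec(seed = 7)
  a <- make_phantom_pair(sp)
  b <- make_phantom_pair(sp)
  expect_identical(a$pre$data, b$pre$data)
  expect_identical(a$post$data, b$post$data)
  expect_identical(a$gt_necrosis$voxels, b$gt_necrosis$voxels)
})

test_that("zero deformation and zero noise give voxel-identical liver masks", {
  sp <- small_phantom_spec(
    noise = list(sigma = 0, impulse_fraction = 0),
    deformation = list(rotation_deg = 0, scale = c(1, 1, 1),
                       translation_voxels = c(0, 0, 0),
                       amplitude = c(0, 0, 0),
                       wavelength = c(20, 70, 80), phase = c(0.15, 0.55)))
  p <- make_phantom_pair(sp)
  expect_identical(p$liver_mask_pre$voxels, p$liver_mask_post$voxels)
  # the two volumes differ only where tumor was replaced by necrosis
  diff_zone <- p$pre$data != p$post$data
  lesion_zone <- dilate_roi(p$gt_tumor, 3)$voxels | dilate_roi(p$gt_necrosis, 3)$voxels
  expect_true(all(lesion_zone[diff_zone]))
})

test_that("invalid specifications are rejected", {
  expect_error(small_phantom_spec(necrosis_margin = -20), "radii")
  sp <- small_phantom_spec()
  sp$tumor$center <- c(3.5, 5, 5) # pokes out of the liver
  expect_error(validate_phantom_spec(sp), "exits the liver")
  sp2 <- small_phantom_spec()
  sp2$tumor$intensities <- c(2000, 1500, 1000) # decreasing: wrong for metastasis
  expect_error(validate_phantom_spec(sp2), "increase")
  sp3 <- small_phantom_spec()
  sp3$spacing_mm <- c(5, 0, 1)
  expect_error(validate_phantom_spec(sp3), "spacing")
})

test_that("rendered ground-truth masks match analytic ellipsoid volumes within 5%", {
  p <- small_phantom_clean()
  sp <- p$spec
  v_tumor <- sum(p$gt_tumor$voxels)
  expect_lt(abs(v_tumor - 4 / 3 * pi * prod(sp$tumor$radii)) /
              (4 / 3 * pi * prod(sp$tumor$radii)), 0.05)
  # necrosis is rendered on the deformed grid; the smooth deformation is
  # near volume-preserving (|scale| within 1%)
  v_necr <- sum(p$gt_necrosis$voxels)
  expect_lt(abs(v_necr - 4 / 3 * pi * prod(sp$necrosis$radii)) /
              (4 / 3 * pi * prod(sp$necrosis$radii)), 0.05)
})

test_that("warping the post volume by the ground-truth transform recovers the pre anatomy", {
  p <- small_phantom_clean()
  lw <- warp(p$liver_mask_post, p$gt_transform, fixed_dim = dim(p$pre$data))
  expect_gte(dice(p$liver_mask_pre, lw), 0.99)
  # warp followed by inverse warp reconstructs a smooth volume (the sharp
  # organ boundary itself is sub-slice at 5 mm spacing, so invertibility is
  # checked on smooth content)
  d <- dim(p$pre$data)
  co <- expand.grid(z = 0:(d[1] - 1), y = 0:(d[2] - 1), x = 0:(d[3] - 1))
  smooth <- array(2000 + 800 * sin(2 * pi * co$y / 40) * cos(2 * pi * co$x / 45) +
                    300 * sin(2 * pi * co$z / 10), d)
  sv <- ct_volume(smooth, spacing_mm = p$pre$spacing_mm)
  tfm <- p$gt_transform
  inv_ffd <- rfacover:::ffd_from_field(d, c(1, 4, 4), function(z, y, x) {
    pts <- cbind(z, y, x)
    inv <- invert_transform_points(tfm, pts)
    list(inv[, 1] - z, inv[, 2] - y, inv[, 3] - x)
  })
  tfm_inv <- rfa_transform(affine = diag(4), ffd = inv_ffd)
  round_trip <- warp(warp(sv, tfm), tfm_inv)
  inner <- array(FALSE, d)
  inner[2:(d[1] - 1), 8:(d[2] - 8), 8:(d[3] - 8)] <- TRUE
  expect_gt(stats::cor(round_trip$data[inner], sv$data[inner]), 0.99)
})

test_that("noise-free phantom histograms contain the configured intensity plateaus", {
  p <- small_phantom_clean()
  sp <- p$spec
  vals <- round(p$pre_clean$data)
  for (plateau in c(sp$background, sp$tumor$intensities[1:2]))
    expect_gt(sum(abs(vals - plateau) < 2), 50)
  # liver plateau is spread by the texture field around its base value
  expect_gt(sum(abs(vals - sp$liver$intensity) < sp$liver$texture$amplitude + 2),
            10000)
})

test_that("necrosis covering the dilated tumor yields zero residual, totally treated", {
  sp <- small_phantom_spec(necrosis_offset = c(0, 0, 0), necrosis_margin = 2)
  sp$necrosis$radii <- sp$tumor$radii + 2
  p <- make_phantom_pair(sp)
  expect_equal(p$gt_coverage$residual_percent, 0)
  expect_true(p$gt_coverage$totally_treated)
})

test_that("a necrosis disjoint from the tumor leaves 100% residual", {
  sp <- small_phantom_spec()
  sp$necrosis <- list(center = c(3.5, 60, 60), radii = c(2, 8, 8),
                      intensity = 900, patch = NULL)
  p <- make_phantom_pair(sp)
  expect_equal(p$gt_coverage$residual_percent, 100)
  expect_false(p$gt_coverage$totally_treated)
})

test_that("phantom seeds lie inside the lesions and respect the 3-per-slice cap", {
  p <- small_phantom()
  for (target in c("tumor", "necrosis")) {
    s <- phantom_seeds(p, target)
    mask <- if (target == "tumor") p$gt_tumor else p$gt_necrosis
    expect_true(all(mask$voxels[s$points]))
    expect_true(all(table(s$points[, 1]) <= 3))
  }
})

test_that("the study schedule spans residual 0-40% with both tumor kinds", {
  specs <- phantom_study_specs(base_seed = 1)
  expect_length(specs, 10)
  kinds <- vapply(specs, function(s) s$tumor$kind, character(1))
  expect_setequal(unique(kinds), c("metastasis", "HCC"))
  # geometric residual proxy from the analytic ellipsoids of first/last cases
  expect_equal(specs[[1]]$necrosis$radii - specs[[1]]$tumor$radii, c(0.8, 4, 4))
  expect_equal(specs[[9]]$necrosis$radii - specs[[9]]$tumor$radii, c(0.8, 0, 0))
})
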