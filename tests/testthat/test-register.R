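test_that("uniform patch selection applies the variance and tie rules", {
  dims <- c(2, 60, 60)
  arr <- array(1500, dims)
  liver <- roi_mask(array(TRUE, dims), "liver", c(5, 1, 1))
  roi <- roi_mask(array(FALSE, dims), "tumor", c(5, 1, 1))
  # constant liver, no ROI: lowest (slice, row, col) window wins
  p <- select_uniform_patch(ct_volume(arr), liver, roi, patch_size = 9)
  expect_equal(p$source_location, c(1, 5, 5))
  expect_true(all(p$tile == 1500))
  # a noisy stripe is avoided
  set.seed(5)
  arr2 <- arr
  arr2[1, 1:30, ] <- arr2[1, 1:30, ] + round(rnorm(30 * 60, 0, 200))
  arr2[2, , ] <- arr2[2, , ] + round(rnorm(60 * 60, 0, 200))
  p2 <- select_uniform_patch(ct_volume(arr2), liver, roi, patch_size = 9)
  expect_equal(p2$source_location[1], 1)
  expect_gte(p2$source_location[2], 31)
  # ROI everywhere except one corner: the window lands in that corner
  roi3 <- roi_mask(array(FALSE, dims), "tumor", c(5, 1, 1))
  roi3$voxels[1, 1:60, 1:35] <- TRUE
  roi3$voxels[2, , ] <- TRUE
  p3 <- select_uniform_patch(ct_volume(arr), liver, roi3, patch_size = 9)
  expect_equal(p3$source_location[1], 1)
  expect_gte(p3$source_location[3] - 4, 45) # window fully right of dilated ROI
  # no admissible window
  all_roi <- roi_mask(array(TRUE, dims), "tumor", c(5, 1, 1))
  expect_error(select_uniform_patch(ct_volume(arr), liver, all_roi, 9),
               "no admissible")
})

test_that("pattern replacement overwrites exactly the dilated ROI from the patch content", {
  dims <- c(1, 40, 40)
  set.seed(6)
  arr <- array(round(rnorm(prod(dims), 2000, 30)), dims)
  v <- ct_volume(arr)
  roi <- roi_mask(array(FALSE, dims), "tumor", c(5, 1, 1))
  roi$voxels[1, 15:25, 12:22] <- TRUE
  tile <- matrix(round(rnorm(19 * 19, 2000, 5)), 19, 19)
  patch <- structure(list(tile = tile, source_location = c(1, 10, 10)),
                     class = "pattern_patch")
  out <- replace_roi_with_pattern(v, roi, patch, margin = 2)
  dil <- dilate_roi(roi, 2)
  expect_identical(out$data[!dil$voxels], v$data[!dil$voxels])
  expect_true(all(out$data[dil$voxels] %in% tile))
  # empty ROI: unchanged; constant patch: constant region
  empty <- roi_mask(array(FALSE, dims), "tumor", c(5, 1, 1))
  expect_identical(replace_roi_with_pattern(v, empty, patch)$data, v$data)
  cpatch <- structure(list(tile = matrix(1234, 19, 19),
                           source_location = c(1, 10, 10)), class = "pattern_patch")
  out2 <- replace_roi_with_pattern(v, roi, cpatch, margin = 0)
  expect_true(all(out2$data[roi$voxels] == 1234))
})

test_that("warping with the identity returns the input; masks stay binary", {
  p <- small_phantom()
  w <- warp(p$pre, identity_transform())
  expect_equal(w$data, p$pre$data, tolerance = 1e-12)
  wm <- warp(p$gt_necrosis, p$gt_transform, fixed_dim = dim(p$pre$data))
  expect_type(wm$voxels, "logical")
  expect_s3_class(wm, "roi_mask")
})

test_that("warp and inverse warp reconstruct a smooth volume", {
  p <- small_phantom_clean()
  warped <- warp(p$pre_clean, p$gt_transform)
  # numerically invert the ground-truth map on the full grid
  d <- dim(p$pre$data)
  co <- as.matrix(expand.grid(z = 0:(d[1] - 1), y = 0:(d[2] - 1), x = 0:(d[3] - 1)))
  inv <- invert_transform_points(p$gt_transform, co)
  fwd <- transform_points(p$gt_transform, inv)
  expect_lt(max(abs(fwd - co)), 1e-3) # inversion is a true fixed point
})

test_that("self-registration is the identity to sub-voxel precision", {
  p <- small_phantom()
  den <- median_denoise(p$pre)
  tfm <- register_pair(den, den)
  d <- dim(den$data)
  ctr <- matrix((d - 1) / 2, 1)
  expect_lt(max(abs(transform_points(tfm, ctr) - ctr)), 0.5)
  expect_gte(attr(tfm, "nmi"), attr(tfm, "nmi_identity") - 1e-9)
})

test_that("a known integer translation is recovered within half a voxel", {
  p <- small_phantom()
  den <- median_denoise(p$pre)
  shifted <- den$data
  shifted[] <- min(den$data)
  # moving[y] = fixed[y - 4]: the fixed -> moving resampling map is x + (0,4,6)
  shifted[, 5:96, 7:96] <- den$data[, 1:(96 - 4), 1:(96 - 6)]
  moving <- ct_volume(shifted, spacing_mm = den$spacing_mm)
  tfm <- register_pair(den, moving)
  d <- dim(den$data)
  ctr <- matrix((d - 1) / 2, 1)
  got <- transform_points(tfm, ctr) - ctr
  expect_lt(max(abs(got - c(0, 4, 6))), 0.5)
})

test_that("registration never scores below the identity in NMI", {
  p <- small_phantom()
  den_pre <- median_denoise(p$pre)
  den_post <- median_denoise(p$post)
  tfm <- register_pair(den_pre, den_post)
  expect_gte(attr(tfm, "nmi"), attr(tfm, "nmi_identity"))
})

test_that("phantom-pair registration restores the liver overlap", {
  p <- small_phantom()
  den_pre <- median_denoise(p$pre)
  den_post <- median_denoise(p$post)
  pa1 <- select_uniform_patch(den_pre, p$liver_mask_pre, p$gt_tumor)
  pa2 <- select_uniform_patch(den_post, p$liver_mask_post, p$gt_necrosis)
  r1 <- replace_roi_with_pattern(den_pre, p$gt_tumor, pa1)
  r2 <- replace_roi_with_pattern(den_post, p$gt_necrosis, pa2)
  tfm <- register_pair(r1, r2, ignore = dilate_roi(p$gt_tumor, 8))
  lw <- warp(p$liver_mask_post, tfm, fixed_dim = dim(p$pre$data))
  expect_gte(dice(p$liver_mask_pre, lw), 0.95)
  # the transform maps the post liver onto the pre liver better than identity
  l0 <- warp(p$liver_mask_post, identity_transform(), fixed_dim = dim(p$pre$data))
  expect_gt(dice(p$liver_mask_pre, lw), dice(p$liver_mask_pre, l0))
})
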