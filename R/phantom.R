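# Synthetic CT phantom pairs with known geometry, noise and deformation.
#
# The phantom emulates the image content the pipeline was designed for: a
# smooth high-intensity liver on a darker background; a tumor built from
# concentric ellipsoidal rings whose intensities rise outward for a (hypodense)
# metastasis and fall outward for a (hyperdense) HCC; a post-ablation necrosis
# that replaces the tumor, hypodense with an optional hyperdense coagulation
# patch; Gaussian plus impulse intensity noise; and a smooth invertible
# deformation (small affine + low-frequency sinusoidal field) between the two
# visits. All geometry is analytic, so every downstream stage can be scored
# against exact ground truth.

#' Specification of a synthetic pre/post-ablation CT pair
#'
#' Defaults define the package's reference study conditions: a 160 x 160 x 12
#' grid at 1 x 1 x 5 mm, a ~2.8 cm three-ring metastasis, a necrosis covering
#' the tumor with a ~4 mm margin, moderate Gaussian noise (sigma 60 on the
#' 12-bit scale), 0.5% impulse noise, and a deformation whose total
#' displacement stays within about 6 voxels over the liver.
#'
#' All centers/radii are in voxels, `(z, y, x)` order, 0-based coordinates.
#'
#' @param grid_shape Voxel counts `(slices, rows, cols)`.
#' @param spacing_mm Voxel spacing `(z, y, x)` in mm.
#' @param liver List: `center`, `radii`, `intensity`.
#' @param background Background intensity.
#' @param tumor List: `kind` (`"metastasis"` or `"HCC"`), `center`, `radii`
#'   (outermost ring), `ring_fractions` (ascending, last = 1), `intensities`
#'   (inner to outer; must rise outward for metastasis, fall for HCC).
#' @param necrosis List: `center`, `radii`, `intensity`, optional `patch`
#'   (list `center`, `radii`, `intensity`) for a hyperdense coagulation area.
#' @param deformation List: `rotation_deg`, `scale`, `translation_voxels`,
#'   `amplitude` (sinusoid, voxels, `(z, y, x)`), `wavelength` (voxels),
#'   `phase`.
#' @param noise List: `sigma` (Gaussian, intensity units), `impulse_fraction`.
#' @param seed Integer RNG seed.
#' @return A validated `phantom_spec` object.
#' @export
phantom_spec <- function(
    grid_shape = c(12, 160, 160),
    spacing_mm = c(5, 1, 1),
    liver = list(center = c(5.5, 79.5, 79.5), radii = c(9, 64, 72),
                 intensity = 2200,
                 texture = list(amplitude = 50, wavelength = c(6.3, 17.3, 21.6),
                                phase = c(0.3, 0.8))),
    background = 1000,
    tumor = list(kind = "metastasis", center = c(5.5, 60, 62),
                 radii = c(2.6, 13, 17), ring_fractions = c(0.35, 0.78, 1),
                 intensities = NULL, edge_voxels = 1.5),
    necrosis = list(center = NULL, radii = NULL, intensity = 900,
                    patch = NULL),
    deformation = list(rotation_deg = 1.2, scale = c(1, 1.004, 1.004),
                       translation_voxels = c(0, 2, 2.5),
                       amplitude = c(0.2, 1.8, 1.8),
                       wavelength = c(30, 110, 130),
                       phase = c(0.15, 0.55)),
    noise = list(sigma = 12, impulse_fraction = 0.005),
    seed = 1L) {
  tumor$kind <- match.arg(tumor$kind, c("metastasis", "HCC"))
  if (is.null(tumor$intensities)) {
    tumor$intensities <- if (tumor$kind == "metastasis")
      c(1000, 1450, 1850) else c(3400, 2950, 2550)
  }
  if (is.null(tumor$ring_fractions)) tumor$ring_fractions <- c(0.45, 0.75, 1)
  if (is.null(necrosis$center)) necrosis$center <- tumor$center + c(0, 2, 2)
  if (is.null(necrosis$radii)) necrosis$radii <- tumor$radii + c(0.8, 4, 4)
  if (is.null(necrosis$intensity)) necrosis$intensity <- 900

  spec <- structure(list(
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    liver = liver, background = background, tumor = tumor,
    necrosis = necrosis, deformation = deformation, noise = noise,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' Checks radii positivity, ring monotonicity (rising outward for metastasis,
#' falling for HCC), the representable intensity range, and containment of
#' tumor and necrosis inside the liver ellipsoid.
#'
#' @param spec A [phantom_spec].
#' @return The spec, invisibly; errors describe the first violated invariant.
#' @export
validate_phantom_spec <- function(spec) {
  if (any(spec$spacing_mm <= 0)) stop("spacing must be positive")
  if (any(spec$liver$radii <= 0) || any(spec$tumor$radii <= 0) ||
      any(spec$necrosis$radii <= 0))
    stop("all radii must be positive")
  rf <- spec$tumor$ring_fractions
  if (length(rf) < 1 || any(diff(c(0, rf)) <= 0) || abs(rf[length(rf)] - 1) > 1e-9)
    stop("ring fractions must be strictly increasing and end at 1")
  if (length(spec$tumor$intensities) != length(rf))
    stop("one intensity per ring required")
  di <- diff(spec$tumor$intensities)
  if (length(di)) {
    if (spec$tumor$kind == "metastasis" && any(di <= 0))
      stop("metastasis ring intensities must increase from center outward")
    if (spec$tumor$kind == "HCC" && any(di >= 0))
      stop("HCC ring intensities must decrease from center outward")
  }
  ints <- c(spec$liver$intensity, spec$background, spec$tumor$intensities,
            spec$necrosis$intensity,
            if (!is.null(spec$necrosis$patch)) spec$necrosis$patch$intensity)
  if (any(ints < DYNAMIC_RANGE[1]) || any(ints > DYNAMIC_RANGE[2]))
    stop("intensities must lie in [0, 4095]")
  check_inside <- function(inner, what) {
    if (!ellipsoid_inside(inner$center, inner$radii,
                          spec$liver$center, spec$liver$radii))
      stop(what, " ellipsoid exits the liver ellipsoid")
  }
  check_inside(spec$tumor, "tumor")
  check_inside(spec$necrosis, "necrosis")
  invisible(spec)
}

# is ellipsoid (c1, r1) contained in ellipsoid (c2, r2)? checked on a dense
# deterministic (Fibonacci lattice) sample of the inner boundary
ellipsoid_inside <- function(c1, r1, c2, r2, n = 400) {
  i <- seq_len(n) - 0.5
  theta <- acos(1 - 2 * i / n)
  phi <- pi * (1 + sqrt(5)) * i
  u <- cbind(cos(theta), sin(theta) * sin(phi), sin(theta) * cos(phi))
  pts <- sweep(sweep(u, 2, r1, "*"), 2, c1, "+")
  d <- sweep(sweep(pts, 2, c2), 2, r2, "/")
  all(rowSums(d^2) <= 1)
}

# soft ellipsoid membership with an `edge`-voxel in-plane transition (linear
# intensity mixing at boundaries); z, y, x are equal-length coordinate vectors
ellipsoid_alpha <- function(z, y, x, center, radii, edge = 1) {
  r <- sqrt(((z - center[1]) / radii[1])^2 +
            ((y - center[2]) / radii[2])^2 +
            ((x - center[3]) / radii[3])^2)
  k <- mean(radii[2:3]) / edge
  pmin(pmax((1 - r) * k + 0.5, 0), 1)
}

ellipsoid_inside_pts <- function(z, y, x, center, radii) {
  ((z - center[1]) / radii[1])^2 + ((y - center[2]) / radii[2])^2 +
    ((x - center[3]) / radii[3])^2 <= 1
}

# analytic noise-free anatomy at continuous voxel coordinates (pre space);
# phase = "pre" includes the tumor, "post" the necrosis
render_anatomy <- function(z, y, x, spec, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  img <- rep(spec$background, length(z))
  blend <- function(img, alpha, value) img * (1 - alpha) + value * alpha
  liver_alpha <- ellipsoid_alpha(z, y, x, spec$liver$center, spec$liver$radii)
  liver_val <- spec$liver$intensity
  tx <- spec$liver$texture
  if (!is.null(tx) && tx$amplitude > 0) {
    # vessel-scale intra-organ heterogeneity, tied to the anatomy so it
    # deforms with the liver between the two visits; triangle waves give a
    # broad flat intensity distribution (as in a perfused organ) instead of
    # piling mass onto a razor-thin histogram peak, and the minor cross
    # component breaks the texture into patches rather than long strips
    tri <- function(t) 2 * abs(2 * (t - floor(t + 0.5))) - 1
    # the through-plane phase drift is kept slow (a fraction of a period per
    # slice) so the anatomy stays resolvable at the 5 mm slice spacing
    liver_val <- liver_val + tx$amplitude *
      (0.75 * tri(y / tx$wavelength[2] + tx$phase[1] +
                    0.06 * sin(2 * pi * z / tx$wavelength[1])) +
       0.25 * tri(x / tx$wavelength[3] + tx$phase[2] +
                    0.06 * cos(2 * pi * z / tx$wavelength[1])))
  }
  img <- blend(img, liver_alpha, liver_val)
  if (phase == "pre") {
    tu <- spec$tumor
    nr <- length(tu$ring_fractions)
    edge_out <- if (is.null(tu$edge_voxels)) 1.5 else tu$edge_voxels
    for (i in rev(seq_len(nr))) { # outermost first, inner rings painted over
      radii <- tu$radii * tu$ring_fractions[i]
      # the outermost ring vanishes gradually into the parenchyma, as lesions
      # of this kind do at their periphery; inner ring boundaries are sharper
      img <- blend(img, ellipsoid_alpha(z, y, x, tu$center, radii,
                                        edge = if (i == nr) edge_out else 1),
                   tu$intensities[i])
    }
  } else {
    ne <- spec$necrosis
    img <- blend(img, ellipsoid_alpha(z, y, x, ne$center, ne$radii), ne$intensity)
    if (!is.null(ne$patch))
      img <- blend(img, ellipsoid_alpha(z, y, x, ne$patch$center, ne$patch$radii),
                   ne$patch$intensity)
  }
  img
}

# analytic ground-truth deformation, fixed (pre) coords -> displacement
phantom_displacement_field <- function(spec) {
  de <- spec$deformation
  a <- de$amplitude
  w <- de$wavelength
  ph <- de$phase
  function(z, y, x) {
    s1 <- sin(2 * pi * (y / w[2] + ph[1])) * sin(2 * pi * (x / w[3] + ph[2]))
    s2 <- cos(2 * pi * (x / w[3] + ph[1])) * sin(2 * pi * (z / w[1] + ph[2]))
    s3 <- sin(2 * pi * (y / w[2] + ph[2])) * cos(2 * pi * (z / w[1] + ph[1]))
    list(a[1] * s1, a[2] * s2, a[3] * s3)
  }
}

phantom_affine <- function(spec) {
  de <- spec$deformation
  center <- (spec$grid_shape - 1) / 2
  make_affine(rotation_deg = de$rotation_deg, scale = de$scale,
              translation_voxels = de$translation_voxels, center = center)
}

#' Ground-truth transform of a phantom spec
#'
#' The fixed(pre) -> moving(post) resampling map: the spec's affine plus its
#' sinusoidal displacement field fitted on a fine (4-voxel in-plane, 1-slice)
#' B-spline control grid.
#'
#' @param spec A [phantom_spec].
#' @return An [rfa_transform].
#' @export
phantom_transform <- function(spec) {
  field <- phantom_displacement_field(spec)
  zero_def <- all(spec$deformation$amplitude == 0)
  ffd <- if (zero_def) NULL else
    ffd_from_field(spec$grid_shape, spacing = c(1, 4, 4), field)
  rfa_transform(affine = phantom_affine(spec), ffd = ffd)
}

#' Generate a synthetic pre/post-ablation CT pair
#'
#' Renders the pre-treatment volume (liver + tumor) on its grid and the
#' post-treatment volume (deformed liver + necrosis) by numerically inverting
#' the ground-truth deformation at every post voxel, so that warping the post
#' volume through [phantom_transform()] reproduces the pre anatomy to
#' sub-voxel accuracy by construction. Gaussian and impulse noise are then
#' added independently to each volume.
#'
#' @param spec A [phantom_spec].
#' @return A `phantom_pair` list: `pre`, `post` ([ct_volume]), `liver_mask_pre`,
#'   `liver_mask_post`, `gt_tumor` (pre grid), `gt_necrosis`, `gt_patch`
#'   (post grid; patch `NULL` when absent), `gt_transform`, `gt_coverage`,
#'   and the `spec`.
#' @export
make_phantom_pair <- function(spec) {
  validate_phantom_spec(spec)
  gs <- spec$grid_shape
  co <- expand.grid(z = seq_len(gs[1]) - 1, y = seq_len(gs[2]) - 1,
                    x = seq_len(gs[3]) - 1)

  pre_clean <- array(render_anatomy(co$z, co$y, co$x, spec, "pre"), dim = gs)
  liver_pre <- array(ellipsoid_inside_pts(co$z, co$y, co$x,
                                          spec$liver$center, spec$liver$radii),
                     dim = gs)
  tu <- spec$tumor
  gt_tumor <- array(ellipsoid_inside_pts(co$z, co$y, co$x, tu$center, tu$radii),
                    dim = gs)

  # post grid: invert T(x) = A x + d(x) at every post voxel (fixed point)
  field <- phantom_displacement_field(spec)
  A <- phantom_affine(spec)
  Ainv <- solve(A)
  tgt <- cbind(co$z, co$y, co$x)
  apply_ainv <- function(m) cbind(m, 1) %*% t(Ainv[1:3, , drop = FALSE])
  xx <- apply_ainv(tgt)
  if (any(spec$deformation$amplitude != 0)) {
    for (i in 1:12) {
      d <- field(xx[, 1], xx[, 2], xx[, 3])
      xx <- apply_ainv(tgt - cbind(d[[1]], d[[2]], d[[3]]))
    }
  }
  post_clean <- array(render_anatomy(xx[, 1], xx[, 2], xx[, 3], spec, "post"),
                      dim = gs)
  liver_post <- array(ellipsoid_inside_pts(xx[, 1], xx[, 2], xx[, 3],
                                           spec$liver$center, spec$liver$radii),
                      dim = gs)
  ne <- spec$necrosis
  gt_necrosis <- array(ellipsoid_inside_pts(xx[, 1], xx[, 2], xx[, 3],
                                            ne$center, ne$radii), dim = gs)
  gt_patch <- NULL
  if (!is.null(ne$patch))
    gt_patch <- array(ellipsoid_inside_pts(xx[, 1], xx[, 2], xx[, 3],
                                           ne$patch$center, ne$patch$radii),
                      dim = gs)

  set.seed(spec$seed)
  pre_noisy <- add_phantom_noise(pre_clean, spec$noise)
  post_noisy <- add_phantom_noise(post_clean, spec$noise)

  sp <- spec$spacing_mm
  pair <- list(
    pre = ct_volume(pre_noisy, spacing_mm = sp),
    post = ct_volume(post_noisy, spacing_mm = sp),
    pre_clean = ct_volume(pre_clean, spacing_mm = sp),
    post_clean = ct_volume(post_clean, spacing_mm = sp),
    liver_mask_pre = roi_mask(liver_pre, "liver", sp),
    liver_mask_post = roi_mask(liver_post, "liver", sp),
    gt_tumor = roi_mask(gt_tumor, "tumor", sp),
    gt_necrosis = roi_mask(gt_necrosis, "necrosis", sp),
    gt_patch = if (is.null(gt_patch)) NULL else roi_mask(gt_patch, "necrosis", sp),
    gt_transform = phantom_transform(spec),
    spec = spec
  )
  class(pair) <- "phantom_pair"
  pair$gt_coverage <- ground_truth_coverage(pair)
  pair
}

add_phantom_noise <- function(arr, noise) {
  n <- length(arr)
  out <- arr
  if (noise$sigma > 0) out <- out + rnorm(n, sd = noise$sigma)
  if (noise$impulse_fraction > 0) {
    k <- round(noise$impulse_fraction * n)
    if (k > 0) {
      idx <- sample.int(n, k)
      out[idx] <- ifelse(runif(k) < 0.5, DYNAMIC_RANGE[1], DYNAMIC_RANGE[2])
    }
  }
  array(round(pmin(pmax(out, DYNAMIC_RANGE[1]), DYNAMIC_RANGE[2])), dim = dim(arr))
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("<phantom_pair> grid %s, tumor kind %s, gt residual %.1f%%\n",
              paste(x$spec$grid_shape, collapse = "x"), x$spec$tumor$kind,
              x$gt_coverage$residual_percent))
  invisible(x)
}

#' Coverage indexes computed from phantom ground truth
#'
#' Maps the ground-truth necrosis mask into pre-treatment space through the
#' known transform and evaluates the four coverage indexes on the ground-truth
#' masks; the recovery target for the full pipeline.
#'
#' @param pair A `phantom_pair`.
#' @return A `coverage_report` (see [coverage_report()]).
#' @export
ground_truth_coverage <- function(pair) {
  necr_pre <- warp(pair$gt_necrosis, pair$gt_transform,
                   fixed_dim = dim(pair$gt_tumor$voxels))
  coverage_report(pair$gt_tumor, necr_pre, spacing_mm = pair$gt_tumor$spacing_mm)
}

#' Emulated operator seed pixels for a phantom lesion
#'
#' Picks one interior point per lesion-bearing slice (the deepest point of the
#' slice mask, i.e. the distance-transform maximum), which for the phantom's
#' concentric-ring lesions is the darkest part of a metastasis / brightest of
#' an HCC — the pixel an operator is instructed to pick. For a necrosis with a
#' hyperdense patch, a second seed is placed inside the patch on each slice
#' where it appears.
#'
#' @param pair A `phantom_pair`.
#' @param target `"tumor"` (seeds on the pre image) or `"necrosis"` (post).
#' @return A [seed_set].
#' @export
phantom_seeds <- function(pair, target = c("tumor", "necrosis")) {
  target <- match.arg(target)
  mask <- if (target == "tumor") pair$gt_tumor else pair$gt_necrosis
  patch <- if (target == "necrosis") pair$gt_patch else NULL
  pts <- NULL
  deepest <- function(m2) {
    dm <- EBImage::distmap(m2)
    which(dm == max(dm), arr.ind = TRUE)[1, , drop = FALSE]
  }
  for (s in seq_len(dim(mask$voxels)[1])) {
    m2 <- mask$voxels[s, , ]
    if (!is.null(patch)) {
      rim <- m2 & !EBImage::dilate(patch$voxels[s, , ],
                                   EBImage::makeBrush(5, "box"))
      if (sum(rim) >= 5) m2 <- rim
    }
    if (sum(m2) < 5) next
    p <- deepest(m2)
    pts <- rbind(pts, c(s, p[1], p[2]))
    if (!is.null(patch) && sum(patch$voxels[s, , ]) >= 5) {
      p2 <- deepest(patch$voxels[s, , ])
      pts <- rbind(pts, c(s, p2[1], p2[2]))
    }
  }
  if (is.null(pts)) stop("phantom lesion too small to seed")
  seed_set(pts, target = target)
}

#' Reference study conditions: ten phantoms spanning residual 0-40%
#'
#' A fixed schedule of ten phantom specifications — alternating hypodense
#' metastases and hyperdense HCCs, with necrosis offsets and margins chosen so
#' the ground-truth residual tumor spans 0% (totally treated, with and without
#' centring error) up to about 40% — used for end-to-end recovery evaluation.
#'
#' @param base_seed Integer; each phantom's RNG seed is derived from it.
#' @return List of 10 [phantom_spec] objects.
#' @export
phantom_study_specs <- function(base_seed = 1) {
  tc <- c(5.5, 60, 62)
  sched <- list(
    list(kind = "metastasis", off = c(0, 2), m = 4),
    list(kind = "HCC",        off = c(0, 0), m = 3),
    list(kind = "metastasis", off = c(3, 3), m = 2.5),
    list(kind = "HCC",        off = c(5, 4), m = 2),
    list(kind = "metastasis", off = c(6, 5), m = 2),
    list(kind = "HCC",        off = c(6, 6), m = 1),
    list(kind = "metastasis", off = c(7, 6), m = 0.5),
    list(kind = "HCC",        off = c(7, 6), m = 0.5),
    list(kind = "metastasis", off = c(7, 6), m = 0),
    list(kind = "HCC",        off = c(4, 4), m = 1.5)
  )
  lapply(seq_along(sched), function(i) {
    s <- sched[[i]]
    phantom_spec(
      seed = as.integer(base_seed %% 1000L) * 1000L + i,
      tumor = list(kind = s$kind, center = tc, radii = c(2.6, 13, 17),
                   ring_fractions = c(0.35, 0.78, 1), intensities = NULL,
                   edge_voxels = 1.5),
      necrosis = list(center = tc + c(0, s$off[1], s$off[2]),
                      radii = c(2.6, 13, 17) + c(0.8, s$m, s$m),
                      intensity = 900, patch = NULL)
    )
  })
}

#' Write a phantom pair to disk (NIfTI volumes + JSON sidecar)
#'
#' @param pair A `phantom_pair`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(pair$pre, file.path(dir, "pre.nii.gz"))
  write_volume(pair$post, file.path(dir, "post.nii.gz"))
  write_mask(pair$liver_mask_pre, file.path(dir, "liver_pre.nii.gz"))
  write_mask(pair$liver_mask_post, file.path(dir, "liver_post.nii.gz"))
  write_mask(pair$gt_tumor, file.path(dir, "gt_tumor.nii.gz"))
  write_mask(pair$gt_necrosis, file.path(dir, "gt_necrosis.nii.gz"))
  write_transform(pair$gt_transform, file.path(dir, "gt_transform.json"),
                  spacing_mm = pair$pre$spacing_mm)
  side <- list(spec = unclass(pair$spec), seed = pair$spec$seed,
               gt_coverage = unclass_report(pair$gt_coverage))
  jsonlite::write_json(side, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  tum_seeds <- phantom_seeds(pair, "tumor")
  nec_seeds <- phantom_seeds(pair, "necrosis")
  df <- rbind(as.data.frame(tum_seeds), as.data.frame(nec_seeds))
  jsonlite::write_json(df, file.path(dir, "seeds.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
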