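# Spatial transforms: a global affine composed (additively, in the usual
# free-form-deformation formulation) with a cubic B-spline displacement field,
# T(x) = A x + D(x), mapping fixed-image voxel coordinates onto moving-image
# voxel coordinates. Coordinates are 0-based (slice, row, col) voxel units.

#' Construct a spatial transform (affine + free-form deformation)
#'
#' @param affine 4x4 matrix acting on homogeneous `(z, y, x, 1)` fixed-image
#'   voxel coordinates.
#' @param ffd Optional list with `spacing` (control-point spacing in voxels,
#'   `(z, y, x)`), `origin` (voxel coordinate of control point `[1,1,1]`),
#'   `dim` (control grid size) and `disp` (array `dim x 3` of displacements in
#'   voxels). `NULL` for a purely affine transform.
#' @return An object of class `rfa_transform`.
#' @export
rfa_transform <- function(affine = diag(4), ffd = NULL) {
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4x4")
  if (!is.null(ffd)) {
    stopifnot(
      length(ffd$spacing) == 3, all(ffd$spacing > 0),
      length(ffd$origin) == 3, length(ffd$dim) == 3,
      identical(dim(ffd$disp), c(as.integer(ffd$dim), 3L))
    )
  }
  structure(list(affine = affine, ffd = ffd), class = "rfa_transform")
}

#' @export
print.rfa_transform <- function(x, ...) {
  cat("<rfa_transform>\n  affine:\n")
  print(round(x$affine, 4))
  if (!is.null(x$ffd)) {
    mx <- max(abs(x$ffd$disp))
    cat(sprintf("  ffd: %s control points, spacing %s voxels, max |disp| %.2f voxels\n",
                paste(x$ffd$dim, collapse = "x"),
                paste(x$ffd$spacing, collapse = "x"), mx))
  } else cat("  ffd: none\n")
  invisible(x)
}

#' Identity transform
#' @return An [rfa_transform] with identity affine and no deformation.
#' @export
identity_transform <- function() rfa_transform(diag(4))

#' Build an affine matrix from in-plane rotation, scale and translation
#'
#' The rotation (degrees, anticlockwise in the row/col plane) and scaling are
#' applied about `center` (voxel coordinates, `(z, y, x)`, 0-based), then the
#' translation (voxels) is added. This parameterisation matches the global
#' motion expected between two abdominal CT visits: small in-plane rotation,
#' near-unit scale, a few voxels of shift.
#'
#' @param rotation_deg In-plane rotation in degrees.
#' @param scale Length-3 scale factors `(z, y, x)` (scalars recycled).
#' @param translation_voxels Length-3 translation `(z, y, x)` in voxels.
#' @param center Length-3 center of rotation/scaling in voxel coordinates.
#' @return A 4x4 affine matrix.
#' @export
make_affine <- function(rotation_deg = 0, scale = 1,
                        translation_voxels = c(0, 0, 0),
                        center = c(0, 0, 0)) {
  scale <- rep_len(scale, 3)
  th <- rotation_deg * pi / 180
  # rotation in the (row, col) plane; slice axis untouched
  R <- diag(3)
  R[2, 2] <- cos(th); R[2, 3] <- -sin(th)
  R[3, 2] <- sin(th); R[3, 3] <- cos(th)
  M <- R %*% diag(scale)
  t <- as.numeric(center) - M %*% as.numeric(center) + as.numeric(translation_voxels)
  A <- diag(4)
  A[1:3, 1:3] <- M
  A[1:3, 4] <- t
  A
}

#' Lay out an FFD control grid covering a volume
#'
#' Control points are spaced `spacing` voxels apart with a one-point margin on
#' every side, so the cubic B-spline support covers the whole grid.
#'
#' @param vol_dim Volume dimensions `(nz, ny, nx)`.
#' @param spacing Control-point spacing in voxels, `(z, y, x)`.
#' @return An `ffd` list with zero displacements.
#' @export
ffd_grid <- function(vol_dim, spacing) {
  spacing <- rep_len(as.numeric(spacing), 3)
  gdim <- as.integer(floor((vol_dim - 1) / spacing) + 4)
  list(spacing = spacing, origin = -spacing, dim = gdim,
       disp = array(0, dim = c(gdim, 3L)))
}

#' Fit an FFD to a displacement-field function
#'
#' Samples an analytic displacement field at the control points of a (usually
#' fine) grid; for fields varying slowly relative to the control spacing the
#' resulting B-spline reproduces the field to well under a tenth of a voxel.
#'
#' @param vol_dim Volume dimensions.
#' @param spacing Control spacing in voxels.
#' @param field Function taking matrices `z, y, x` of voxel coordinates and
#'   returning a list of three displacement components (voxels).
#' @return An `ffd` list.
#' @keywords internal
ffd_from_field <- function(vol_dim, spacing, field) {
  g <- ffd_grid(vol_dim, spacing)
  pz <- g$origin[1] + (seq_len(g$dim[1]) - 1) * g$spacing[1]
  py <- g$origin[2] + (seq_len(g$dim[2]) - 1) * g$spacing[2]
  px <- g$origin[3] + (seq_len(g$dim[3]) - 1) * g$spacing[3]
  co <- expand.grid(z = pz, y = py, x = px)
  d <- field(co$z, co$y, co$x)
  # a cubic B-spline with coefficients equal to field samples smooths the
  # field slightly; a one-step Jacobi correction on the interpolation residual
  # restores near-interpolation for low-frequency fields
  for (a in 1:3) g$disp[, , , a] <- array(d[[a]], dim = g$dim)
  approx1 <- function(gd) {
    # value of the spline at the control points (separable 1-4-1/6 smoothing)
    smooth_axis <- function(arr, axis) {
      n <- dim(arr)[axis]
      idx <- function(i) pmin(pmax(i, 1), n)
      slice_at <- function(i) {
        switch(axis,
               arr[idx(i), , , drop = FALSE],
               arr[, idx(i), , drop = FALSE],
               arr[, , idx(i), drop = FALSE])
      }
      out <- arr
      for (i in seq_len(n)) {
        v <- (slice_at(i - 1) + 4 * slice_at(i) + slice_at(i + 1)) / 6
        switch(axis,
               out[i, , ] <- v,
               out[, i, ] <- v,
               out[, , i] <- v)
      }
      out
    }
    smooth_axis(smooth_axis(smooth_axis(gd, 1), 2), 3)
  }
  for (a in 1:3) {
    target <- g$disp[, , , a]
    coef <- target
    for (it in 1:8) coef <- coef + (target - approx1(coef))
    g$disp[, , , a] <- coef
  }
  g
}

#' Evaluate a transform at voxel coordinates
#'
#' @param transform An [rfa_transform].
#' @param coords Matrix with columns `(z, y, x)` of 0-based fixed-image voxel
#'   coordinates, or a volume dimension vector to map every voxel.
#' @return Matrix of mapped `(z, y, x)` moving-image voxel coordinates.
#' @export
transform_points <- function(transform, coords) {
  coords <- as.matrix(coords)
  h <- cbind(coords, 1)
  out <- h %*% t(transform$affine[1:3, , drop = FALSE])
  if (!is.null(transform$ffd)) {
    f <- transform$ffd
    d <- bspline_displacement(f, coords)
    out <- out + d
  }
  out
}

# evaluate the FFD displacement at arbitrary coordinates (vectorised R mirror
# of the C++ kernel; used for point mapping and tests)
bspline_displacement <- function(ffd, coords) {
  n <- nrow(coords)
  out <- matrix(0, n, 3)
  wts <- function(f) {
    cbind((1 - f)^3 / 6,
          (3 * f^3 - 6 * f^2 + 4) / 6,
          (-3 * f^3 + 3 * f^2 + 3 * f + 1) / 6,
          f^3 / 6)
  }
  u <- sweep(sweep(coords, 2, ffd$origin), 2, ffd$spacing, "/")
  b <- floor(u)
  f <- u - b
  W <- list(wts(f[, 1]), wts(f[, 2]), wts(f[, 3]))
  B <- b - 1 # 0-based first control index per axis
  gd <- ffd$dim
  clampi <- function(i, n) pmin(pmax(i, 0), n - 1)
  for (kz in 0:3) for (ky in 0:3) for (kx in 0:3) {
    w <- W[[1]][, kz + 1] * W[[2]][, ky + 1] * W[[3]][, kx + 1]
    iz <- clampi(B[, 1] + kz, gd[1])
    iy <- clampi(B[, 2] + ky, gd[2])
    ix <- clampi(B[, 3] + kx, gd[3])
    lin <- 1 + iz + gd[1] * (iy + gd[2] * ix)
    npts <- prod(gd)
    for (a in 1:3) out[, a] <- out[, a] + w * ffd$disp[lin + (a - 1) * npts]
  }
  out
}

#' Resample an image or mask through a transform
#'
#' Maps every fixed-grid voxel through the transform and samples the moving
#' image there: linear interpolation for intensity volumes, nearest-neighbour
#' for masks (so masks stay binary). Voxels mapping outside the moving volume
#' get the background value (0 / outside-mask).
#'
#' @param x A [ct_volume] or [roi_mask] in moving-image space.
#' @param transform An [rfa_transform] mapping fixed coordinates to moving
#'   coordinates.
#' @param fixed_dim Dimensions of the output (fixed) grid; defaults to the
#'   input's own grid.
#' @param interpolation `"linear"` or `"nearest"`; defaults to linear for
#'   volumes and nearest for masks.
#' @param background Value for out-of-domain voxels (volumes only).
#' @return An object of the same class as `x`, on the fixed grid.
#' @export
warp <- function(x, transform, fixed_dim = NULL, interpolation = NULL,
                 background = 0) {
  is_mask <- inherits(x, "roi_mask")
  if (!is_mask && !inherits(x, "ct_volume"))
    stop("`x` must be a ct_volume or roi_mask")
  if (is.null(interpolation)) interpolation <- if (is_mask) "nearest" else "linear"
  interp <- match.arg(interpolation, c("nearest", "linear"))
  arr <- if (is_mask) x$voxels * 1.0 else x$data
  mdim <- dim(arr)
  if (is.null(fixed_dim)) fixed_dim <- mdim
  f <- transform$ffd
  out <- cpp_warp(
    as.numeric(arr), as.integer(mdim), as.integer(fixed_dim),
    transform$affine,
    !is.null(f),
    if (is.null(f)) numeric(3) else f$spacing,
    if (is.null(f)) numeric(3) else f$origin,
    if (is.null(f)) integer(3) else as.integer(f$dim),
    if (is.null(f)) numeric(0) else as.numeric(f$disp),
    if (interp == "nearest") 0L else 1L,
    if (is_mask) 0 else background
  )
  out <- array(out, dim = fixed_dim)
  if (is_mask) {
    roi_mask(out > 0.5, role = x$role, spacing_mm = x$spacing_mm)
  } else {
    ct_volume(out, spacing_mm = x$spacing_mm, origin_mm = x$origin_mm)
  }
}

#' Numerically invert a transform at given fixed-space target points
#'
#' Solves `T(x) = y` for `x` by fixed-point iteration, valid for the small
#' smooth deformations this package models.
#'
#' @param transform An [rfa_transform].
#' @param targets Matrix of `(z, y, x)` coordinates in moving space.
#' @param iters Number of fixed-point iterations.
#' @return Matrix of `(z, y, x)` coordinates in fixed space.
#' @export
invert_transform_points <- function(transform, targets, iters = 20) {
  targets <- as.matrix(targets)
  Ainv <- solve(transform$affine)
  apply_ainv <- function(y) cbind(y, 1) %*% t(Ainv[1:3, , drop = FALSE])
  x <- apply_ainv(targets)
  if (is.null(transform$ffd)) return(x)
  for (i in seq_len(iters)) {
    d <- bspline_displacement(transform$ffd, x)
    x <- apply_ainv(targets - d)
  }
  x
}
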