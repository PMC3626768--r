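# Core containers shared by every stage: a CT volume and a binary ROI mask.
# Axis order is fixed throughout the package as (slice, row, col); spacing and
# origin follow the same (z, y, x) order, in millimetres.

#' Intensity range representable by the pipeline (12-bit CT-like units)
#'
#' Volumes are held in abstract 12-bit units in `[0, 4095]`; the pipeline never
#' assumes Hounsfield calibration. Voxels excluded from processing (outside the
#' liver) carry the reserved sentinel value `-1`.
#' @keywords internal
#' @name intensity-scale
NULL

DYNAMIC_RANGE <- c(0, 4095)
SENTINEL <- -1

#' Construct a CT volume
#'
#' @param data Numeric 3D array indexed `[slice, row, col]`.
#' @param spacing_mm Positive voxel spacing `(z, y, x)` in mm.
#' @param origin_mm World coordinate of voxel `[1, 1, 1]`, `(z, y, x)` in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing_mm = c(5, 0.74, 0.74), origin_mm = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array (slice, row, col)")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive finite numbers (z, y, x)")
  if (any(!is.finite(data)))
    stop("volume intensities must be finite")
  structure(
    list(data = data, spacing_mm = spacing_mm, origin_mm = as.numeric(origin_mm)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ct_volume> %d x %d x %d (slice x row x col), spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]
  ))
  v <- x$data[x$data != SENTINEL]
  if (length(v))
    cat(sprintf("  intensities: [%.1f, %.1f]%s\n", min(v), max(v),
                if (any(x$data == SENTINEL)) " (+ sentinel voxels)" else ""))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Construct a binary ROI mask on a CT grid
#'
#' @param voxels Logical (or 0/1) 3D array, same shape as the volume it
#'   annotates.
#' @param role One of `"tumor"`, `"necrosis"`, `"liver"`.
#' @param spacing_mm Voxel spacing `(z, y, x)` in mm, inherited from the volume.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(voxels, role = c("tumor", "necrosis", "liver"),
                     spacing_mm = c(5, 0.74, 0.74)) {
  role <- match.arg(role)
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask may not contain NA")
  structure(
    list(voxels = voxels, role = role, spacing_mm = as.numeric(spacing_mm)),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<roi_mask:%s> %d x %d x %d, %d voxels (%.2f cm3)\n",
              x$role, d[1], d[2], d[3], sum(x$voxels),
              mask_volume_cm3(x)))
  invisible(x)
}

#' @export
dim.roi_mask <- function(x) dim(x$voxels)

#' Physical volume of a mask in cm^3
#' @param mask A [roi_mask].
#' @return Volume in cm^3 (voxel count times voxel volume).
#' @export
mask_volume_cm3 <- function(mask) {
  sum(mask$voxels) * prod(mask$spacing_mm) / 1000
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b [roi_mask] objects (or logical arrays) on the same grid.
#' @return Dice coefficient in `[0, 1]`; 1 for two empty masks.
#' @export
dice <- function(a, b) {
  av <- if (inherits(a, "roi_mask")) a$voxels else a
  bv <- if (inherits(b, "roi_mask")) b$voxels else b
  if (!identical(dim(av), dim(bv))) stop("masks are on different grids")
  s <- sum(av) + sum(bv)
  if (s == 0) return(1)
  2 * sum(av & bv) / s
}

#' Dilate a mask in-plane
#' @param mask A [roi_mask].
#' @param r Dilation radius in voxels (square structuring element), per slice.
#' @return The dilated [roi_mask].
#' @export
dilate_roi <- function(mask, r) {
  if (r < 1) return(mask)
  brush <- EBImage::makeBrush(2 * round(r) + 1, "box")
  arr <- aperm(mask$voxels, c(2, 3, 1)) * 1
  out <- EBImage::dilate(arr, brush) > 0
  roi_mask(aperm(out, c(3, 1, 2)), role = mask$role, spacing_mm = mask$spacing_mm)
}

check_same_grid <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$voxels)))
    stop("volume and mask shapes differ: ",
         paste(dim(volume$data), collapse = "x"), " vs ",
         paste(dim(mask$voxels), collapse = "x"))
  invisible(TRUE)
}
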