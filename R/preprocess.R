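# Pre-processing: slice-wise median denoising, restriction to the liver, and
# remapping of the characteristic liver intensity range onto the full dynamic
# range. All later statistics and clustering see liver voxels only.

#' Slice-wise median denoising
#'
#' Filters each axial slice independently with a `window x window` 2D median
#' (default 5 x 5), suppressing impulse noise and CT quantum-noise granularity.
#' Filtering is 2D because the 5 mm slice thickness makes a through-plane
#' median anatomically unsound.
#'
#' @param volume A [ct_volume].
#' @param window Odd window size >= 3.
#' @return The filtered [ct_volume] (same grid).
#' @export
median_denoise <- function(volume, window = 5) {
  if (length(window) != 1 || window < 3 || window %% 2 != 1)
    stop("`window` must be an odd integer >= 3")
  lo <- DYNAMIC_RANGE[1]
  hi <- DYNAMIC_RANGE[2]
  # EBImage filters frames of an (row, col, frame) array on a [0,1] scale;
  # 16-bit internal precision is exact after rounding back to integer units
  arr <- aperm(volume$data, c(2, 3, 1))
  arr <- (pmin(pmax(arr, lo), hi) - lo) / (hi - lo)
  out <- EBImage::medianFilter(arr, size = (window - 1) / 2)
  out <- round(as.array(out) * (hi - lo) + lo)
  ct_volume(aperm(out, c(3, 1, 2)), spacing_mm = volume$spacing_mm,
            origin_mm = volume$origin_mm)
}

#' Restrict a volume to the liver
#'
#' Voxels outside the liver mask are set to the reserved sentinel value, which
#' every later statistic and the clustering exclude.
#'
#' @param volume A [ct_volume].
#' @param liver A liver [roi_mask] on the same grid.
#' @return The masked [ct_volume].
#' @export
apply_liver_mask <- function(volume, liver) {
  check_same_grid(volume, liver)
  if (!any(liver$voxels)) stop("liver mask is empty")
  out <- volume$data
  out[!liver$voxels] <- SENTINEL
  ct_volume(out, spacing_mm = volume$spacing_mm, origin_mm = volume$origin_mm)
}

#' Characteristic liver intensity range from the liver histogram
#'
#' Builds the histogram of liver voxels (unit-width bins on the 12-bit scale),
#' locates its modal height `H`, and returns the lowest and highest intensities
#' whose bin count reaches `peak_fraction * H`. With liver intensities close to
#' Gaussian this brackets the distribution where its density falls to the given
#' fraction of the peak; lesion plateaus large enough to register on the
#' histogram extend the range so they survive the subsequent remapping.
#'
#' @param volume A [ct_volume] (masked or not).
#' @param liver Liver [roi_mask]; only voxels inside it are used.
#' @param peak_fraction Fraction of the modal bin height defining the cut
#'   (default 0.025, the midpoint of the 2-3% convention).
#' @return An `intensity_range` list with `lo` and `hi`.
#' @export
liver_intensity_range <- function(volume, liver, peak_fraction = 0.025) {
  if (peak_fraction <= 0 || peak_fraction >= 1)
    stop("peak_fraction must be in (0, 1)")
  check_same_grid(volume, liver)
  v <- volume$data[liver$voxels]
  v <- v[v != SENTINEL]
  v <- round(v)
  if (length(unique(v)) < 2) stop("degenerate liver histogram (single value)")
  counts <- tabulate(v - min(v) + 1L)
  vals <- seq(min(v), max(v))
  thr <- peak_fraction * max(counts)
  ok <- which(counts >= thr)
  lo <- vals[ok[1]]
  hi <- vals[ok[length(ok)]]
  if (lo >= hi) stop("degenerate liver histogram: lo >= hi")
  structure(list(lo = lo, hi = hi), class = "intensity_range")
}

#' Spread the liver range onto the full dynamic range
#'
#' Linearly remaps `[lo, hi]` onto `[0, 4095]`, clipping values outside the
#' range; sentinel (non-liver) voxels are left untouched. The map is monotone,
#' so intensity ordering is preserved on unclipped voxels.
#'
#' @param volume A [ct_volume].
#' @param range An `intensity_range` from [liver_intensity_range()].
#' @param round_output Round to integer units (default `TRUE`; the histogram
#'   convention downstream assumes integer data).
#' @return The contrast-enhanced [ct_volume].
#' @export
enhance_contrast <- function(volume, range, round_output = TRUE) {
  if (!is.list(range) || is.null(range$lo) || is.null(range$hi))
    stop("`range` must come from liver_intensity_range()")
  if (range$lo >= range$hi) stop("invalid range: lo >= hi")
  sent <- volume$data == SENTINEL
  out <- (volume$data - range$lo) / (range$hi - range$lo)
  out <- pmin(pmax(out, 0), 1) * (DYNAMIC_RANGE[2] - DYNAMIC_RANGE[1]) +
    DYNAMIC_RANGE[1]
  if (round_output) out <- round(out)
  out[sent] <- SENTINEL
  ct_volume(out, spacing_mm = volume$spacing_mm, origin_mm = volume$origin_mm)
}

#' Run the full pre-processing chain on one volume
#'
#' Median denoising, liver restriction, liver-range estimation and contrast
#' enhancement, in that order.
#'
#' @param volume A [ct_volume].
#' @param liver Liver [roi_mask].
#' @param window Median window (see [median_denoise()]).
#' @param peak_fraction See [liver_intensity_range()].
#' @return List with `enhanced` and `denoised` [ct_volume]s and the `range`.
#' @export
preprocess_volume <- function(volume, liver, window = 5, peak_fraction = 0.025) {
  den <- median_denoise(volume, window = window)
  masked <- apply_liver_mask(den, liver)
  rng <- liver_intensity_range(masked, liver, peak_fraction = peak_fraction)
  list(enhanced = enhance_contrast(masked, rng), denoised = den, range = rng)
}
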