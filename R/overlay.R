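# Static overlay export: treated / not-treated tumor areas and the ideal
# safety-margin contour on a CT slice, written as PNG.

#' Write a coverage overlay for one slice
#'
#' Renders the CT slice in grayscale with the treated tumor area tinted
#' green, residual (untreated) tumor tinted red, the necrosis outline in
#' blue, and the ideal safety-margin contour (tumor dilated by `margin_mm`)
#' in yellow.
#'
#' @param volume A [ct_volume] (pre-treatment space).
#' @param tumor Tumor [roi_mask].
#' @param necrosis Necrosis [roi_mask] in the same (pre-treatment) space.
#' @param slice Slice index (1-based).
#' @param path Output PNG path.
#' @param margin_mm Ideal margin in mm (default 10).
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(volume, tumor, necrosis, slice, path,
                              margin_mm = 10) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for overlay export")
  check_same_grid(volume, tumor)
  check_same_grid(volume, necrosis)
  img <- volume$data[slice, , ]
  img[img == SENTINEL] <- DYNAMIC_RANGE[1]
  g <- (img - min(img)) / max(max(img) - min(img), 1)
  r <- g; b <- g; gr <- g

  outline <- function(m2) m2 & !(EBImage::erode(m2, EBImage::makeBrush(3, "box")) > 0)
  tum <- tumor$voxels[slice, , ]
  nec <- necrosis$voxels[slice, , ]
  treated <- tum & nec
  residual <- tum & !nec
  ideal <- outline(ideal_margin_mask(tumor, volume$spacing_mm,
                                     margin_mm)$voxels[slice, , ])
  gr[treated] <- pmin(gr[treated] + 0.35, 1)
  r[residual] <- pmin(r[residual] + 0.45, 1)
  gr[residual] <- gr[residual] * 0.6
  b[outline(nec)] <- 1
  r[ideal] <- 1; gr[ideal] <- 1; b[ideal] <- 0.2
  arr <- array(c(r, gr, b), dim = c(dim(g), 3))
  png::writePNG(arr, path)
  invisible(path)
}
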