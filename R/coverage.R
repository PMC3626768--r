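# The four RFA-coverage indexes, computed slice-wise on the co-registered
# tumor (pre-treatment space) and necrosis masks:
#   (i)   residual tumor: volume and percentage of tumor outside the necrosis;
#   (ii)  tumor-free margin (T.F.M.): necrosis thickness beyond the tumor
#         edge, by isotropic in-plane dilation;
#   (iii) inter-barycentric distance |B_T - B_N|: in-plane centroid distance;
#   (iv)  orientation index (O.I.): angle between the major axes of the
#         moment-fitted ellipses of the two masks.
# Indexes (ii)-(iv) are 2D per slice with in-plane mm scaling (the 5 mm slice
# thickness makes through-plane geometry too coarse); volumes use the full
# voxel volume.

slice_indices <- function(mask) which(apply(mask$voxels, 1, any))

#' Residual (untreated) tumor
#'
#' Voxels of the pre-treatment tumor not included in the necrosis are labelled
#' untreated; reported as absolute volume and as a percentage of the tumor.
#'
#' @param tumor,necrosis [roi_mask]s on the same grid (necrosis already warped
#'   into pre-treatment space).
#' @param spacing_mm Voxel spacing `(z, y, x)` in mm.
#' @return List: `volume_cm3`, `percent`, `per_slice` (residual voxel counts).
#' @export
residual_tumor <- function(tumor, necrosis, spacing_mm = tumor$spacing_mm) {
  if (!identical(dim(tumor$voxels), dim(necrosis$voxels)))
    stop("masks are on different grids")
  nt <- sum(tumor$voxels)
  if (nt == 0) stop("empty tumor mask")
  resid <- tumor$voxels & !necrosis$voxels
  per_slice <- apply(resid, 1, sum)
  list(volume_cm3 = sum(resid) * prod(spacing_mm) / 1000,
       percent = 100 * sum(resid) / nt,
       per_slice = per_slice)
}

#' Tumor-free margin by isotropic in-plane dilation
#'
#' Per slice: if the tumor cross-section is not fully inside the necrosis the
#' margin is 0; otherwise the tumor is dilated one voxel at a time (square
#' 8-connected unit element) until it escapes the necrosis, and the margin is
#' the number of complete dilations times the in-plane pixel size. Slices
#' without tumor are skipped.
#'
#' @inheritParams residual_tumor
#' @return List: `per_slice` (named mm values), `min_mm`, `max_mm`.
#' @export
tumor_free_margin <- function(tumor, necrosis, spacing_mm = tumor$spacing_mm) {
  if (!identical(dim(tumor$voxels), dim(necrosis$voxels)))
    stop("masks are on different grids")
  p <- mean(spacing_mm[2:3])
  brush <- EBImage::makeBrush(3, "box")
  sl <- slice_indices(tumor)
  if (!length(sl)) stop("empty tumor mask")
  tfm <- vapply(sl, function(s) {
    tm <- tumor$voxels[s, , ]
    nm <- necrosis$voxels[s, , ]
    if (any(tm & !nm)) return(0)
    n <- 0L
    cur <- tm
    repeat {
      nxt <- EBImage::dilate(cur, brush) > 0
      if (any(nxt & !nm)) break
      cur <- nxt
      n <- n + 1L
      if (n > max(dim(tm))) break # necrosis fills the slice
    }
    n * p
  }, numeric(1))
  names(tfm) <- sl
  list(per_slice = tfm, min_mm = min(tfm), max_mm = max(tfm))
}

slice_centroid <- function(m2) {
  w <- which(m2, arr.ind = TRUE)
  colMeans(w)
}

#' Inter-barycentric distance per slice
#'
#' Euclidean in-plane distance (mm) between the centroids of the tumor and
#' necrosis cross-sections, over slices where both are present.
#'
#' @inheritParams residual_tumor
#' @return List: `per_slice` (named mm values), `mean_mm`, `sd_mm`.
#' @export
barycenter_distance <- function(tumor, necrosis, spacing_mm = tumor$spacing_mm) {
  if (!identical(dim(tumor$voxels), dim(necrosis$voxels)))
    stop("masks are on different grids")
  sl <- intersect(slice_indices(tumor), slice_indices(necrosis))
  if (!length(sl)) stop("no slice carries both tumor and necrosis")
  d <- vapply(sl, function(s) {
    bt <- slice_centroid(tumor$voxels[s, , ])
    bn <- slice_centroid(necrosis$voxels[s, , ])
    sqrt(((bt[1] - bn[1]) * spacing_mm[2])^2 +
         ((bt[2] - bn[2]) * spacing_mm[3])^2)
  }, numeric(1))
  names(d) <- sl
  list(per_slice = d, mean_mm = mean(d), sd_mm = if (length(d) > 1) stats::sd(d) else 0)
}

# major-axis orientation (degrees in [0, 180)) of a slice mask from its
# second-order central moments; NA when the shape is (near-)circular so the
# axis is undefined
slice_orientation <- function(m2, eccentricity_tol = 0.02) {
  w <- which(m2, arr.ind = TRUE)
  if (nrow(w) < 3) return(NA_real_)
  r <- w[, 1] - mean(w[, 1])
  c <- w[, 2] - mean(w[, 2])
  mu20 <- mean(r^2)
  mu02 <- mean(c^2)
  mu11 <- mean(r * c)
  ecc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2) / (mu20 + mu02)
  if (!is.finite(ecc) || ecc < eccentricity_tol) return(NA_real_)
  th <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  th %% 180
}

#' Orientation index per slice
#'
#' Fits an ellipse to each cross-section by matching second-order central
#' moments and measures the angle between the two major axes, folded into
#' `[0, 180)` so that the clinically critical 60-120 degree band is
#' expressible. Slices where either shape is too circular for a defined axis
#' are flagged and excluded from the summary.
#'
#' @inheritParams residual_tumor
#' @param eccentricity_tol Normalised second-moment anisotropy below which the
#'   orientation is treated as undefined.
#' @return List: `per_slice` (named degrees, NA where undefined), `mean_deg`,
#'   `sd_deg`, `excluded_slices`.
#' @export
orientation_index <- function(tumor, necrosis, eccentricity_tol = 0.02) {
  if (!identical(dim(tumor$voxels), dim(necrosis$voxels)))
    stop("masks are on different grids")
  sl <- intersect(slice_indices(tumor), slice_indices(necrosis))
  if (!length(sl)) stop("no slice carries both tumor and necrosis")
  oi <- vapply(sl, function(s) {
    tt <- slice_orientation(tumor$voxels[s, , ], eccentricity_tol)
    tn <- slice_orientation(necrosis$voxels[s, , ], eccentricity_tol)
    if (is.na(tt) || is.na(tn)) return(NA_real_)
    d <- abs(tt - tn) %% 360
    d <- min(d, 360 - d)
    d %% 180
  }, numeric(1))
  names(oi) <- sl
  ok <- !is.na(oi)
  list(per_slice = oi,
       mean_deg = if (any(ok)) mean(oi[ok]) else NA_real_,
       sd_deg = if (sum(ok) > 1) stats::sd(oi[ok]) else 0,
       excluded_slices = as.integer(sl[!ok]))
}

#' Ideal necrosis edge at a safety margin
#'
#' The contour a guideline-conform ablation should reach: the tumor dilated
#' in-plane by `margin_mm` (default the recommended 1 cm), for overlay
#' visualisation.
#'
#' @param tumor Tumor [roi_mask].
#' @param spacing_mm Voxel spacing.
#' @param margin_mm Safety margin in mm.
#' @return A [roi_mask] of the ideally treated region.
#' @export
ideal_margin_mask <- function(tumor, spacing_mm = tumor$spacing_mm,
                              margin_mm = 10) {
  p <- mean(spacing_mm[2:3])
  n <- max(0L, round(margin_mm / p))
  if (n == 0) return(tumor)
  brush <- EBImage::makeBrush(3, "box")
  out <- tumor$voxels
  for (s in slice_indices(tumor)) {
    cur <- out[s, , ]
    for (i in seq_len(n)) cur <- EBImage::dilate(cur, brush) > 0
    out[s, , ] <- cur
  }
  roi_mask(out, role = "necrosis", spacing_mm = spacing_mm)
}

#' Assemble the full coverage report
#'
#' Computes all four indexes plus summary statistics and the
#' totally/not-totally-treated classification (totally treated iff no slice
#' carries residual tumor voxels).
#'
#' @inheritParams residual_tumor
#' @return A `coverage_report` with fields `residual_volume_cm3`,
#'   `residual_percent`, `totally_treated`, `tfm_min_mm`, `tfm_max_mm`,
#'   `barycentric_mean_mm`, `barycentric_std_mm`, `oi_mean_deg`, `oi_std_deg`,
#'   `tumor_volume_cm3`, `tumor_slices` and a `per_slice` data frame.
#' @export
coverage_report <- function(tumor, necrosis, spacing_mm = tumor$spacing_mm) {
  res <- residual_tumor(tumor, necrosis, spacing_mm)
  tfm <- tumor_free_margin(tumor, necrosis, spacing_mm)
  bd <- barycenter_distance(tumor, necrosis, spacing_mm)
  oi <- orientation_index(tumor, necrosis)
  sl <- slice_indices(tumor)
  per_slice <- data.frame(
    slice = sl,
    residual_voxels = res$per_slice[sl],
    tfm_mm = unname(tfm$per_slice[as.character(sl)]),
    barycentric_distance_mm = unname(bd$per_slice[as.character(sl)]),
    orientation_index_deg = unname(oi$per_slice[as.character(sl)])
  )
  structure(list(
    residual_volume_cm3 = res$volume_cm3,
    residual_percent = res$percent,
    totally_treated = all(res$per_slice == 0),
    tfm_min_mm = tfm$min_mm,
    tfm_max_mm = tfm$max_mm,
    barycentric_mean_mm = bd$mean_mm,
    barycentric_std_mm = bd$sd_mm,
    oi_mean_deg = oi$mean_deg,
    oi_std_deg = oi$sd_deg,
    tumor_volume_cm3 = mask_volume_cm3(tumor),
    tumor_slices = length(sl),
    per_slice = per_slice
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report>\n")
  cat(sprintf("  tumor: %.2f cm3 over %d slices\n", x$tumor_volume_cm3, x$tumor_slices))
  cat(sprintf("  residual tumor: %.2f cm3 [%.2f%%] -> %s\n",
              x$residual_volume_cm3, x$residual_percent,
              if (x$totally_treated) "totally treated" else "NOT totally treated"))
  cat(sprintf("  T.F.M.: %.2f - %.2f mm\n", x$tfm_min_mm, x$tfm_max_mm))
  cat(sprintf("  |B_T-B_N|: %.2f +/- %.2f mm\n",
              x$barycentric_mean_mm, x$barycentric_std_mm))
  if (is.na(x$oi_mean_deg)) cat("  O.I.: undefined (near-circular sections)\n")
  else cat(sprintf("  O.I.: %.2f +/- %.2f deg\n", x$oi_mean_deg, x$oi_std_deg))
  invisible(x)
}

unclass_report <- function(report) {
  r <- unclass(report)
  r$per_slice <- as.list(r$per_slice)
  r
}

#' Write a coverage report to JSON
#' @param report A `coverage_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_report <- function(report, path) {
  jsonlite::write_json(unclass_report(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a coverage report written by [write_coverage_report()]
#' @param path Path to the JSON report.
#' @return A `coverage_report`.
#' @export
read_coverage_report <- function(path) {
  r <- jsonlite::fromJSON(path)
  r$per_slice <- as.data.frame(r$per_slice)
  structure(r, class = "coverage_report")
}
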