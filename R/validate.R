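# Segmentation validation: confusion counts against a ground-truth mask
# within the liver domain, and the four percentage indexes — Percentage Match
# (sensitivity), Positive Predictivity (precision), Specificity, Negative
# Predictivity.

#' Confusion counts of an algorithm mask against ground truth
#'
#' Counts are restricted to the evaluation domain (normally the liver mask),
#' so the image background does not inflate the negative classes.
#'
#' @param gt Ground-truth [roi_mask].
#' @param algo Algorithm [roi_mask].
#' @param domain Domain [roi_mask] (e.g. the liver); `gt` and `algo` must lie
#'   inside it.
#' @return A `confusion_counts` list: `tp`, `fp`, `tn`, `fn`, `domain_size`.
#' @export
confusion_counts <- function(gt, algo, domain) {
  if (!identical(dim(gt$voxels), dim(algo$voxels)) ||
      !identical(dim(gt$voxels), dim(domain$voxels)))
    stop("masks are on different grids")
  if (any(gt$voxels & !domain$voxels) || any(algo$voxels & !domain$voxels))
    stop("masks escape the evaluation domain")
  d <- domain$voxels
  g <- gt$voxels[d]
  a <- algo$voxels[d]
  out <- list(tp = sum(g & a), fp = sum(!g & a),
              tn = sum(!g & !a), fn = sum(g & !a),
              domain_size = sum(d))
  stopifnot(out$tp + out$fp + out$tn + out$fn == out$domain_size)
  structure(out, class = "confusion_counts")
}

#' The four segmentation-validation indexes
#'
#' \itemize{
#'   \item PM (Percentage Match, sensitivity) = 100 TP / (TP + FN)
#'   \item P+ (Positive Predictivity) = 100 TP / (TP + FP)
#'   \item SPEC (Specificity) = 100 TN / (TN + FP)
#'   \item P- (Negative Predictivity) = 100 TN / (TN + FN)
#' }
#' An index whose denominator is zero is reported as `NA` (undefined), never
#' as 0. `printed_variant = TRUE` switches the specificity denominator to
#' `TP + FP`, reproducing a formula variant that circulates in print; the
#' default is the standard definition.
#'
#' @param counts A `confusion_counts`.
#' @param printed_variant Use the non-standard specificity denominator.
#' @return A `validation_report`: `pm`, `pplus`, `spec`, `pminus` (percent).
#' @export
validation_indexes <- function(counts, printed_variant = FALSE) {
  sdiv <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  spec_den <- if (printed_variant) counts$tp + counts$fp else counts$tn + counts$fp
  structure(list(
    pm = sdiv(counts$tp, counts$tp + counts$fn),
    pplus = sdiv(counts$tp, counts$tp + counts$fp),
    spec = sdiv(counts$tn, spec_den),
    pminus = sdiv(counts$tn, counts$tn + counts$fn)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("<validation_report> PM %s | P+ %s | SPEC %s | P- %s\n",
              fmt(x$pm), fmt(x$pplus), fmt(x$spec), fmt(x$pminus)))
  invisible(x)
}

#' Score an algorithm mask against ground truth in one call
#'
#' @inheritParams confusion_counts
#' @param printed_variant See [validation_indexes()].
#' @return A `validation_report`.
#' @export
validate_segmentation <- function(gt, algo, domain, printed_variant = FALSE) {
  validation_indexes(confusion_counts(gt, algo, domain), printed_variant)
}
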