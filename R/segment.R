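# Semi-automatic segmentation: fuzzy c-means clustering of liver voxels and
# seed-driven extraction of tumor / necrosis ROIs from the cluster-label map.
#
# Clusters are labelled 1..c by ascending centroid intensity (1 darkest).
# Tumors have a concentric ring structure in the label map: indexes ascend
# from center to periphery for a metastasis and descend for an HCC, which the
# region-growing rules exploit.

#' Operator seed pixels
#'
#' @param points Matrix (or vector of length 3) of 1-based `(slice, row, col)`
#'   voxel indices. At most 3 seeds per slice.
#' @param target `"tumor"` or `"necrosis"`.
#' @return A `seed_set`.
#' @export
seed_set <- function(points, target = c("tumor", "necrosis")) {
  target <- match.arg(target)
  points <- matrix(as.integer(points), ncol = 3,
                   dimnames = list(NULL, c("slice", "row", "col")))
  if (nrow(points) == 0) stop("seed set may not be empty")
  if (any(table(points[, 1]) > 3))
    stop("at most 3 seeds per slice per region")
  structure(list(points = points, target = target), class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set:%s> %d seeds on %d slice(s)\n", x$target,
              nrow(x$points), length(unique(x$points[, 1]))))
  invisible(x)
}

#' @export
#' @method as.data.frame seed_set
as.data.frame.seed_set <- function(x, ...) {
  # 0-based indices: the on-disk seeds-file convention
  data.frame(slice = x$points[, 1] - 1L, row = x$points[, 2] - 1L,
             col = x$points[, 3] - 1L, target = x$target)
}

#' Fuzzy c-means clustering of liver voxels
#'
#' Minimises the standard FCM objective
#' \deqn{J = \sum_i \sum_k u_{ik}^m (x_i - v_k)^2}
#' by alternating membership and centroid updates until the relative objective
#' change falls below `tol`. Because intensities are integers on a 12-bit
#' scale, the computation runs on the value histogram (every voxel with the
#' same intensity has the same membership vector), which is exactly equivalent
#' to the voxel-wise iteration. Centroids are initialised at `c` evenly spaced
#' quantiles of the liver intensities, making the fit deterministic; the RNG
#' seed is used only to re-seed a centroid in the degenerate empty-cluster
#' case. Clusters are relabelled 1..c by ascending centroid.
#'
#' @param volume A (pre-processed) [ct_volume].
#' @param liver Liver [roi_mask]; clustering sees liver voxels only.
#' @param c Number of clusters (default 7).
#' @param m Fuzziness exponent (> 1, default 2).
#' @param tol Relative objective-change convergence threshold.
#' @param max_iter Iteration cap (warns if reached).
#' @param seed RNG seed for empty-cluster re-seeding.
#' @return A `cluster_result`: `labels` (integer array, 0 outside liver),
#'   `centroids` (ascending), `c`, `m`, `iterations`, `objective`,
#'   `objective_trace`, plus the value-level membership table (`values`,
#'   `memberships`).
#' @export
fcm_cluster <- function(volume, liver, c = 7, m = 2, tol = 1e-5,
                        max_iter = 300, seed = 1L) {
  check_same_grid(volume, liver)
  if (c < 1) stop("c must be >= 1")
  if (m <= 1) stop("m must be > 1")
  x <- round(volume$data[liver$voxels])
  x <- x[x != SENTINEL]
  vals <- sort(unique(x))
  if (length(vals) < c)
    stop("need at least c distinct intensities in the liver")
  cnt <- as.numeric(tabulate(match(x, vals), nbins = length(vals)))
  v <- as.numeric(vals)

  set.seed(seed)
  # deterministic init: centroids evenly spaced over the observed intensity
  # range, so minority plateaus (lesions) anchor their own clusters instead of
  # every centroid starting inside the dominant parenchyma mode
  rng <- range(v)
  centroids <- rng[1] + (2 * seq_len(c) - 1) / (2 * c) * diff(rng)
  expo <- -1 / (m - 1)
  trace <- numeric(0)
  obj <- Inf
  iter <- 0
  u <- NULL
  repeat {
    iter <- iter + 1
    d2 <- outer(v, centroids, function(a, b) (a - b)^2)
    zero <- d2 < 1e-12
    u <- d2^expo
    if (any(zero)) {
      u[rowSums(zero) > 0, ] <- 0
      u[zero] <- 1
    }
    u <- u / rowSums(u)
    um <- u^m
    w <- cnt * um
    denom <- colSums(w)
    if (any(denom < 1e-12)) {
      # empty cluster: re-seed its centroid at a random observed value
      for (k in which(denom < 1e-12)) centroids[k] <- v[sample.int(length(v), 1)]
      message("fcm_cluster: re-seeded empty cluster")
      next
    }
    centroids <- colSums(w * v) / denom
    new_obj <- sum(cnt * um * outer(v, centroids, function(a, b) (a - b)^2))
    trace <- c(trace, new_obj)
    if (is.finite(obj) && abs(obj - new_obj) <= tol * max(obj, 1e-12)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
    if (iter >= max_iter) {
      warning("fcm_cluster: no convergence after ", max_iter, " iterations")
      break
    }
  }

  ord <- order(centroids)
  centroids <- centroids[ord]
  u <- u[, ord, drop = FALSE]
  if (any(diff(centroids) <= 0))
    centroids <- centroids + seq_len(c) * 1e-9
  value_label <- max.col(u, ties.method = "last")

  labels <- array(0L, dim = dim(volume$data))
  xv <- round(volume$data[liver$voxels])
  keep <- xv != SENTINEL
  lab_vec <- integer(length(xv))
  lab_vec[keep] <- value_label[match(xv[keep], vals)]
  labels[liver$voxels] <- lab_vec

  structure(list(
    labels = labels, centroids = centroids, c = as.integer(c), m = m,
    iterations = iter, objective = obj, objective_trace = trace,
    values = vals, memberships = u, spacing_mm = volume$spacing_mm
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> c = %d, m = %g, %d iterations, objective %.4g\n",
              x$c, x$m, x$iterations, x$objective))
  cat("  centroids:", paste(sprintf("%.1f", x$centroids), collapse = ", "), "\n")
  invisible(x)
}

#' Membership vector(s) of given intensities
#' @param clusters A `cluster_result`.
#' @param intensities Intensity values (rounded to the histogram grid).
#' @return Matrix of memberships (rows sum to 1).
#' @export
memberships_at <- function(clusters, intensities) {
  idx <- match(round(intensities), clusters$values)
  if (anyNA(idx)) stop("intensity not present in the clustered data")
  clusters$memberships[idx, , drop = FALSE]
}

seed_labels <- function(clusters, seeds) {
  l <- clusters$labels[seeds$points]
  if (any(l == 0))
    stop("seed outside the liver mask at row ",
         paste(which(l == 0), collapse = ", "))
  l
}

#' Classify the tumor kind from seed cluster indexes
#'
#' The mean cluster index of the reference pixels over all slices decides the
#' kind: below 3.5 a (hypodense) metastasis, otherwise a (hyperdense) HCC.
#' Seeds are pooled across slices; a mean of exactly 3.5 goes to the HCC
#' branch.
#'
#' @param clusters A `cluster_result`.
#' @param seeds A [seed_set] with target `"tumor"`.
#' @return A `tumor_kind` list: `kind`, `mean_seed_index`.
#' @export
classify_tumor_kind <- function(clusters, seeds) {
  if (seeds$target != "tumor") stop("seeds must target the tumor")
  mean_idx <- mean(seed_labels(clusters, seeds))
  structure(list(kind = if (mean_idx < 3.5) "metastasis" else "HCC",
                 mean_seed_index = mean_idx), class = "tumor_kind")
}

# per-slice seeded growth linked across slices by component overlap: after
# growing on seeded slices, adjacent slices are grown from the projection of
# the neighbouring slice's mask, until stable
link_slices <- function(labels, seeds, grow_slice) {
  nz <- dim(labels)[1]
  out <- array(FALSE, dim = dim(labels))
  seeded <- sort(unique(seeds$points[, 1]))
  for (s in seeded) {
    pts <- seeds$points[seeds$points[, 1] == s, , drop = FALSE][, 2:3, drop = FALSE]
    out[s, , ] <- grow_slice(s, pts)
  }
  repeat {
    changed <- FALSE
    for (s in seq_len(nz)) {
      proj <- NULL
      if (s > 1 && any(out[s - 1, , ])) proj <- rbind(proj, which(out[s - 1, , ], arr.ind = TRUE))
      if (s < nz && any(out[s + 1, , ])) proj <- rbind(proj, which(out[s + 1, , ], arr.ind = TRUE))
      if (is.null(proj)) next
      grown <- grow_slice(s, proj)
      new_mask <- out[s, , ] | grown
      if (any(new_mask != out[s, , ])) {
        out[s, , ] <- new_mask
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out
}

#' Extract the tumor ROI by monotone seeded region growing
#'
#' Grows per-slice regions from the seeds over the cluster-label map. A
#' neighbouring pixel (8-connectivity) is accepted when its cluster index does
#' not break the concentric-ring monotonicity — non-decreasing away from the
#' seeds for a metastasis, non-increasing for an HCC — and stays within the
#' admissible band of `delta` clusters anchored at the seeds' extreme index.
#' Slices without seeds are grown from the projection of the adjacent slice's
#' component, so the ROI stays connected through the stack.
#'
#' @param clusters A `cluster_result`.
#' @param seeds A [seed_set] with target `"tumor"`.
#' @param kind A `tumor_kind` from [classify_tumor_kind()].
#' @param delta Band width in clusters (default 3: e.g. a metastasis seeded in
#'   cluster 1 may span clusters 1-4).
#' @return A tumor [roi_mask].
#' @export
extract_tumor <- function(clusters, seeds, kind, delta = 3) {
  if (seeds$target != "tumor") stop("seeds must target the tumor")
  sl <- seed_labels(clusters, seeds)
  metastasis <- kind$kind == "metastasis"
  if (metastasis) {
    if (min(sl) >= clusters$c - 1)
      stop("all tumor seeds lie in the brightest clusters; ",
           "inconsistent with a (hypodense) metastasis")
    anchor <- min(sl)
    band <- c(anchor, min(anchor + delta, clusters$c))
    if (any(sl > band[2]))
      warning(sum(sl > band[2]), " seed(s) above the admissible cluster band ",
              "ignored as growth points")
  } else {
    if (max(sl) <= 2)
      stop("all tumor seeds lie in the darkest clusters; ",
           "inconsistent with a (hyperdense) HCC")
    anchor <- max(sl)
    band <- c(max(anchor - delta, 1L), anchor)
    if (any(sl < band[1]))
      warning(sum(sl < band[1]), " seed(s) below the admissible cluster band ",
              "ignored as growth points")
  }
  direction <- if (metastasis) 1L else -1L
  grow_slice <- function(s, pts) {
    cpp_grow_monotone(clusters$labels[s, , ], as.matrix(pts), direction,
                      band[1], band[2])
  }
  vox <- link_slices(clusters$labels, seeds, grow_slice)
  roi_mask(vox, role = "tumor", spacing_mm = clusters$spacing_mm)
}

#' Extract the necrosis ROI
#'
#' A uniformly hypodense necrosis consists of pixels in the two darkest
#' clusters: the mask is the connected component of cluster-{1,2} pixels
#' around the seeds. When a seed has a cluster index above 2 (a hyperdense
#' coagulation area inside the necrosis), the connected hyperdense component
#' containing it is first relabelled to cluster 1; the uniform procedure then
#' treats the irregular necrosis exactly like a uniform one.
#'
#' @param clusters A `cluster_result`.
#' @param seeds A [seed_set] with target `"necrosis"`.
#' @return A necrosis [roi_mask].
#' @export
extract_necrosis <- function(clusters, seeds) {
  if (seeds$target != "necrosis") stop("seeds must target the necrosis")
  sl <- seed_labels(clusters, seeds)
  labels <- clusters$labels
  hyper <- which(sl > 2)
  for (i in hyper) {
    p <- seeds$points[i, ]
    s <- p[1]
    comp <- cpp_grow_monotone(labels[s, , ],
                              matrix(p[2:3], ncol = 2), 0L, 3L, clusters$c)
    sl2 <- labels[s, , ]
    sl2[comp] <- 1L
    labels[s, , ] <- sl2
  }
  grow_slice <- function(s, pts) {
    cpp_grow_monotone(labels[s, , ], as.matrix(pts), 0L, 1L, 2L)
  }
  vox <- link_slices(labels, seeds, grow_slice)
  if (!any(vox)) {
    bad <- paste(apply(seeds$points, 1, paste, collapse = ","), collapse = "; ")
    stop("necrosis growth produced an empty mask; seeds isolated at (", bad, ")")
  }
  roi_mask(vox, role = "necrosis", spacing_mm = clusters$spacing_mm)
}

#' Morphological cleanup of a segmented ROI
#'
#' Per slice: binary opening (square structuring element of radius `r_open`)
#' removes thin artificial extensions (vessel-like tails, partial-volume
#' bridges); interior holes are filled; then only the component containing a
#' seed — or overlapping the retained component of an adjacent slice — is
#' kept. Finally the mask is clipped to the liver eroded by one voxel. If
#' cleanup empties the mask the input is returned with a warning.
#'
#' @param mask A [roi_mask] from [extract_tumor()] / [extract_necrosis()].
#' @param liver Liver [roi_mask].
#' @param seeds Optional [seed_set]; without it the largest per-slice
#'   component is retained.
#' @param r_open Opening radius in voxels (default 1).
#' @return The cleaned [roi_mask].
#' @export
morphological_cleanup <- function(mask, liver, seeds = NULL, r_open = 1) {
  if (!any(mask$voxels)) stop("mask is empty")
  check_same_grid(list(data = mask$voxels), liver)
  brush <- EBImage::makeBrush(2 * r_open + 1, "box")
  arr <- aperm(mask$voxels, c(2, 3, 1)) * 1 # (row, col, slice) frames
  opened <- EBImage::opening(arr, brush)
  filled <- EBImage::fillHull(EBImage::bwlabel(opened)) > 0
  lab <- EBImage::bwlabel(filled)
  nz <- dim(mask$voxels)[1]
  keep <- array(FALSE, dim = dim(filled))

  comp_ids_at <- function(s, pts) {
    ids <- lab[, , s][pts]
    unique(ids[ids > 0])
  }
  # retain seeded components
  if (!is.null(seeds)) {
    for (s in unique(seeds$points[, 1])) {
      pts <- seeds$points[seeds$points[, 1] == s, 2:3, drop = FALSE]
      ids <- comp_ids_at(s, pts)
      if (length(ids)) keep[, , s] <- lab[, , s] %in% ids
    }
  }
  if (!any(keep)) {
    # fall back to the largest component on the best slice
    areas <- apply(lab, 3, function(m) if (max(m) > 0) max(tabulate(m[m > 0])) else 0)
    s <- which.max(areas)
    if (areas[s] > 0) {
      tb <- tabulate(lab[, , s][lab[, , s] > 0])
      keep[, , s] <- lab[, , s] == which.max(tb)
    }
  }
  # propagate through the stack by overlap with adjacent retained components
  repeat {
    changed <- FALSE
    for (s in seq_len(nz)) {
      adj <- NULL
      if (s > 1) adj <- keep[, , s - 1]
      if (s < nz) adj <- if (is.null(adj)) keep[, , s + 1] else adj | keep[, , s + 1]
      if (is.null(adj) || !any(adj)) next
      ids <- unique(lab[, , s][adj & lab[, , s] > 0])
      if (length(ids)) {
        new <- keep[, , s] | matrix(lab[, , s] %in% ids, dim(lab)[1], dim(lab)[2])
        if (any(new != keep[, , s])) {
          keep[, , s] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  liver_arr <- aperm(liver$voxels, c(2, 3, 1)) * 1
  liver_eroded <- EBImage::erode(liver_arr, EBImage::makeBrush(3, "box")) > 0
  keep <- keep & liver_eroded
  out <- aperm(keep, c(3, 1, 2))
  if (!any(out)) {
    warning("morphological cleanup emptied the mask; returning the input")
    return(mask)
  }
  roi_mask(out, role = mask$role, spacing_mm = mask$spacing_mm)
}
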