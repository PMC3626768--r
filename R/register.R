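# Non-rigid realignment of the post-ablation volume onto the pre-treatment
# volume: a global affine followed by a cubic B-spline free-form deformation,
# both driven by normalised mutual information (NMI). Before registration both
# lesions are replaced by a synthetic parenchyma pattern so that the
# tumor/necrosis intensity difference cannot pull the deformation (the
# "fictitious deformation" artefact); the estimated transform is then applied
# to the original images, so pre-treatment voxels are never resampled.

#' Registration parameters
#'
#' @param ffd_spacing Control-point spacing `(slices, rows, cols)` in voxels
#'   of the full-resolution grid (default one slice through-plane, 16 voxels
#'   in-plane).
#' @param nmi_bins Histogram bins for NMI (default 128: 32-unit bins on the
#'   12-bit scale, fine enough to resolve parenchymal texture).
#' @param downsample In-plane downsampling factor of the coarse level
#'   (default 2; 1 disables the coarse level).
#' @param affine_maxit Nelder-Mead iteration budget per affine phase.
#' @param ffd_steps_coarse Pattern-search step sizes (coarse-level voxels).
#' @param ffd_steps_fine Step sizes for the full-resolution refinement sweep.
#' @param sweeps Sweeps per step size.
#' @param optimize_z Also optimise through-plane control displacements.
#' @return A `registration_params` list.
#' @export
registration_params <- function(ffd_spacing = c(1, 16, 16), nmi_bins = 128,
                                downsample = 2, affine_maxit = 200,
                                ffd_steps_coarse = c(2, 1, 0.5),
                                ffd_steps_fine = 0.5, sweeps = 2,
                                optimize_z = TRUE, min_gain = 2e-6,
                                ffd_penalty = 5e-4, relax_mu = 1,
                                relax_iters = 40) {
  structure(list(ffd_spacing = ffd_spacing, nmi_bins = nmi_bins,
                 downsample = downsample, affine_maxit = affine_maxit,
                 ffd_steps_coarse = ffd_steps_coarse,
                 ffd_steps_fine = ffd_steps_fine, sweeps = sweeps,
                 optimize_z = optimize_z, min_gain = min_gain,
                 ffd_penalty = ffd_penalty, relax_mu = relax_mu,
                 relax_iters = relax_iters),
            class = "registration_params")
}

#' Normalised mutual information between two volumes on one grid
#'
#' Studholme's overlap-invariant form `(H(A) + H(B)) / H(A, B)` from a joint
#' histogram over all voxels.
#'
#' @param a,b [ct_volume]s (or arrays) of identical shape.
#' @param bins Number of histogram bins per image.
#' @return NMI (>= 1; 2 for identical discrete images).
#' @export
nmi <- function(a, b, bins = 32) {
  av <- if (inherits(a, "ct_volume")) a$data else a
  bv <- if (inherits(b, "ct_volume")) b$data else b
  if (!identical(dim(av), dim(bv))) stop("volumes are on different grids")
  cpp_nmi(as.numeric(av), as.numeric(bv), as.integer(bins),
          range(av), range(bv))
}

# 2x2 in-plane block averaging, slices untouched
downsample_inplane <- function(arr, f) {
  if (f == 1) return(arr)
  d <- dim(arr)
  ny <- floor(d[2] / f) * f
  nx <- floor(d[3] / f) * f
  a <- arr[, seq_len(ny), seq_len(nx), drop = FALSE]
  dim(a) <- c(d[1], f, ny / f, f, nx / f)
  apply(a, c(1, 3, 5), mean)
}

# coordinate map from level-f voxel coords to full-resolution coords:
# y_full = f * y_coarse + (f - 1) / 2 (block centers), slices unchanged
level_matrix <- function(f) {
  M <- diag(4)
  M[2, 2] <- f; M[3, 3] <- f
  M[2, 4] <- (f - 1) / 2
  M[3, 4] <- (f - 1) / 2
  M
}

affine_to_level <- function(affine_full, f) {
  M <- level_matrix(f)
  solve(M) %*% affine_full %*% M
}

affine_from_level <- function(affine_coarse, f) {
  M <- level_matrix(f)
  M %*% affine_coarse %*% solve(M)
}

# affine stage: Nelder-Mead over (tz, ty, tx[, rot, sy, sx]) maximising NMI
optimize_affine <- function(fv, mv, bins, center, maxit, init = NULL) {
  fdim <- dim(fv)
  frange <- range(fv)
  mrange <- range(mv)
  fvec <- as.numeric(fv)
  mvec <- as.numeric(mv)
  obj <- function(p) {
    A <- make_affine(rotation_deg = if (length(p) > 3) p[4] else 0,
                     scale = if (length(p) > 3) c(1, p[5], p[6]) else 1,
                     translation_voxels = p[1:3], center = center)
    w <- cpp_warp(mvec, dim(mv), fdim, A, FALSE, numeric(3), numeric(3),
                  integer(3), numeric(0), 1L, mrange[1])
    -cpp_nmi(fvec, w, bins, frange, mrange)
  }
  p0 <- if (is.null(init)) c(0, 0, 0) else init[1:3]
  fit1 <- stats::optim(p0, obj, method = "Nelder-Mead",
                       control = list(maxit = maxit,
                                      parscale = c(0.5, 2, 2), reltol = 1e-7))
  p <- c(fit1$par, if (is.null(init) || length(init) < 6) c(0, 1, 1) else init[4:6])
  fit2 <- stats::optim(p, obj, method = "Nelder-Mead",
                       control = list(maxit = maxit,
                                      parscale = c(0.5, 2, 2, 1, 0.02, 0.02),
                                      reltol = 1e-8))
  p <- fit2$par
  list(affine = make_affine(rotation_deg = p[4], scale = c(1, p[5], p[6]),
                            translation_voxels = p[1:3], center = center),
       params = p, nmi = -fit2$value)
}

# 6-neighbour mean over a (gz, gy, gx) control grid, edge-aware
ffd_neighbor_mean <- function(d) {
  gd <- dim(d)
  s <- array(0, gd)
  n <- array(0, gd)
  add <- function(idx_to, idx_from) {
    s[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <<-
      s[idx_to[[1]], idx_to[[2]], idx_to[[3]]] +
      d[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
    n[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <<-
      n[idx_to[[1]], idx_to[[2]], idx_to[[3]]] + 1
  }
  for (ax in 1:3) {
    g <- gd[ax]
    if (g < 2) next
    lo <- lapply(gd, seq_len); hi <- lo
    lo[[ax]] <- 1:(g - 1); hi[[ax]] <- 2:g
    add(lo, hi)
    add(hi, lo)
  }
  s / pmax(n, 1)
}

# information-weighted relaxation of an optimised FFD: control points whose
# support carries little image gradient (uniform parenchyma, pattern-replaced
# lesions, background) are pulled towards the mean of their neighbours, so the
# deformation there interpolates the surrounding, well-determined field
# instead of keeping whatever histogram noise the search left behind.
relax_ffd <- function(ffd, fixed_arr, ignore = NULL, mu = 1, iters = 40) {
  d <- dim(fixed_arr)
  gx <- fixed_arr
  grad <- array(0, d)
  grad[, -1, ] <- abs(gx[, -1, ] - gx[, -d[2], ])
  grad[, , -1] <- grad[, , -1] + abs(gx[, , -1] - gx[, , -d[3]])
  if (!is.null(ignore)) grad[ignore] <- 0
  # integral volume for O(1) box sums
  iv <- array(0, d + 1)
  iv[-1, -1, -1] <- grad
  for (ax in 1:3) iv <- apply(iv, setdiff(1:3, ax), cumsum) |>
    (\(a) if (ax == 1) a else if (ax == 2) aperm(a, c(2, 1, 3)) else aperm(a, c(2, 3, 1)))()
  boxsum <- function(lo, hi) { # 0-based voxel bounds, inclusive
    f <- function(z, y, x) iv[z + 1, y + 1, x + 1]
    f(hi[1] + 1, hi[2] + 1, hi[3] + 1) - f(lo[1], hi[2] + 1, hi[3] + 1) -
      f(hi[1] + 1, lo[2], hi[3] + 1) - f(hi[1] + 1, hi[2] + 1, lo[3]) +
      f(lo[1], lo[2], hi[3] + 1) + f(lo[1], hi[2] + 1, lo[3]) +
      f(hi[1] + 1, lo[2], lo[3]) - f(lo[1], lo[2], lo[3])
  }
  gd <- ffd$dim
  w <- array(0, gd)
  for (iz in seq_len(gd[1])) for (iy in seq_len(gd[2])) for (ix in seq_len(gd[3])) {
    p <- c(iz, iy, ix) - 1
    lo <- pmax(ceiling(ffd$origin + (p - 2) * ffd$spacing), 0)
    hi <- pmin(floor(ffd$origin + (p + 2) * ffd$spacing), d - 1)
    if (any(lo > hi)) next
    w[iz, iy, ix] <- boxsum(lo, hi) / prod(hi - lo + 1)
  }
  ref <- stats::quantile(w[w > 0], 0.7)
  if (!is.finite(ref) || ref <= 0) return(ffd)
  w <- (w / ref)^2
  w <- w / (w + 1) # in [0, 1): 0 = uninformative, ~1 = strong gradient
  raw <- ffd$disp
  cur <- raw
  for (a in 1:3) {
    da <- raw[, , , a]
    x <- da
    for (i in seq_len(iters)) {
      m <- ffd_neighbor_mean(x)
      x <- (w * da + mu * m) / (w + mu)
    }
    cur[, , , a] <- x
  }
  ffd$disp <- cur
  ffd
}

#' Register the post-ablation volume onto the pre-treatment volume
#'
#' Two-stage, two-resolution optimisation: a global affine (translation, then
#' translation + in-plane rotation and scale, Nelder-Mead on NMI), followed by
#' a free-form deformation refined by a coordinate pattern search over the
#' B-spline control-point displacements with incremental NMI updates — first
#' on an in-plane downsampled level, then a half-voxel sweep at full
#' resolution. Inputs should be the pattern-replaced volumes (see
#' [replace_roi_with_pattern()]); the result maps fixed (pre) voxel
#' coordinates onto moving (post) coordinates, and is guaranteed not to score
#' below the identity transform in NMI (otherwise the identity is returned
#' with a warning).
#'
#' @param fixed The pre-treatment [ct_volume] (pattern-replaced).
#' @param moving The post-treatment [ct_volume] (pattern-replaced).
#' @param params A [registration_params] list.
#' @param ignore Optional [roi_mask] (fixed space) of regions whose image
#'   content must not inform the deformation — typically the pattern-replaced
#'   lesion neighbourhood; the final field is interpolated there from its
#'   surroundings.
#' @return An [rfa_transform] with attributes `nmi` (achieved),
#'   `nmi_identity`, and `affine_params`.
#' @export
register_pair <- function(fixed, moving, params = registration_params(),
                          ignore = NULL) {
  fd <- fixed$data
  md <- moving$data
  bins <- params$nmi_bins
  f <- params$downsample
  sp <- params$ffd_spacing

  nmi_id <- nmi(fd, md, bins)

  # ---- coarse level ----
  fc <- downsample_inplane(fd, f)
  mc <- downsample_inplane(md, f)
  center_c <- (dim(fc) - 1) / 2
  aff_c <- optimize_affine(fc, mc, bins, center_c, params$affine_maxit)
  affine <- affine_from_level(aff_c$affine, f)

  # ---- affine polish at full resolution ----
  center_f <- (dim(fd) - 1) / 2
  aff_f <- optimize_affine(fd, md, bins, center_f,
                           maxit = ceiling(params$affine_maxit / 2),
                           init = aff_c$params * c(1, f, f, 1, 1, 1))
  affine <- aff_f$affine

  # ---- FFD, coarse level ----
  sp_c <- c(sp[1], sp[2] / f, sp[3] / f)
  grid_c <- ffd_grid(dim(fc), sp_c)
  axes <- if (params$optimize_z) c(0L, 1L, 2L) else c(1L, 2L)
  res_c <- cpp_ffd_optimize(
    as.numeric(fc), dim(fc), as.numeric(mc), dim(mc),
    affine_to_level(affine, f),
    grid_c$spacing, grid_c$origin, as.integer(grid_c$dim),
    as.numeric(grid_c$disp), bins, range(fc), range(mc),
    params$ffd_steps_coarse, params$sweeps, axes, min(mc), params$min_gain,
    params$ffd_penalty
  )

  # ---- FFD, full resolution ----
  grid_f <- ffd_grid(dim(fd), sp)
  disp_c <- array(res_c$disp, dim = c(grid_c$dim, 3L))
  disp_f <- array(0, dim = c(grid_f$dim, 3L))
  nz <- pmin(grid_f$dim, grid_c$dim)
  disp_f[seq_len(nz[1]), seq_len(nz[2]), seq_len(nz[3]), 1] <-
    disp_c[seq_len(nz[1]), seq_len(nz[2]), seq_len(nz[3]), 1]
  for (a in 2:3)
    disp_f[seq_len(nz[1]), seq_len(nz[2]), seq_len(nz[3]), a] <-
      f * disp_c[seq_len(nz[1]), seq_len(nz[2]), seq_len(nz[3]), a]
  res_f <- cpp_ffd_optimize(
    as.numeric(fd), dim(fd), as.numeric(md), dim(md), affine,
    grid_f$spacing, grid_f$origin, as.integer(grid_f$dim),
    as.numeric(disp_f), bins, range(fd), range(md),
    params$ffd_steps_fine, params$sweeps, axes, min(md), params$min_gain / 2,
    params$ffd_penalty
  )

  ffd <- grid_f
  ffd$disp <- array(res_f$disp, dim = c(grid_f$dim, 3L))
  if (params$relax_mu > 0)
    ffd <- relax_ffd(ffd, fd,
                     ignore = if (is.null(ignore)) NULL else ignore$voxels,
                     mu = params$relax_mu, iters = params$relax_iters)
  tfm <- rfa_transform(affine = affine, ffd = ffd)

  nmi_final <- nmi(fd, warp(moving, tfm, fixed_dim = dim(fd),
                            background = min(md))$data, bins)
  if (nmi_final < nmi_id) {
    warning("registration did not improve NMI over the identity; ",
            "returning the identity transform")
    tfm <- identity_transform()
    nmi_final <- nmi_id
  }
  attr(tfm, "nmi") <- nmi_final
  attr(tfm, "nmi_identity") <- nmi_id
  attr(tfm, "affine_params") <- aff_f$params
  tfm
}

#' Select a uniform liver-parenchyma patch
#'
#' Scans every in-plane `patch_size` x `patch_size` window lying fully inside
#' the liver and outside the ROI dilated by `patch_size` voxels, and returns
#' the one with minimal intensity variance (ties broken towards the lowest
#' `(slice, row, col)`): the most uniform piece of parenchyma available.
#'
#' @param volume A [ct_volume] (denoised).
#' @param liver Liver [roi_mask].
#' @param roi The lesion [roi_mask] to stay clear of.
#' @param patch_size Patch side in voxels (default 19).
#' @return A `pattern_patch`: `tile` (`patch_size` square matrix) and
#'   `source_location` (1-based `(slice, row, col)` of the window center).
#' @export
select_uniform_patch <- function(volume, liver, roi, patch_size = 19) {
  check_same_grid(volume, liver)
  check_same_grid(volume, roi)
  d <- dim(volume$data)
  ps <- patch_size
  brush <- EBImage::makeBrush(2 * ps + 1, "box")
  best <- NULL
  for (s in seq_len(d[1])) {
    allowed <- liver$voxels[s, , ]
    if (!any(allowed)) next
    if (any(roi$voxels[s, , ]))
      allowed <- allowed & !(EBImage::dilate(roi$voxels[s, , ], brush) > 0)
    if (!any(allowed)) next
    img <- volume$data[s, , ]
    # integral images for window sums
    ii <- function(m) {
      p <- matrix(0, nrow(m) + 1, ncol(m) + 1)
      p[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
      p
    }
    wsum <- function(p) {
      nr <- nrow(p) - 1; nc <- ncol(p) - 1
      r1 <- seq_len(nr - ps + 1); c1 <- seq_len(nc - ps + 1)
      p[r1 + ps, c1 + ps, drop = FALSE] - p[r1 + ps, c1, drop = FALSE] -
        p[r1, c1 + ps, drop = FALSE] + p[r1, c1, drop = FALSE]
    }
    if (nrow(img) < ps || ncol(img) < ps) next
    cnt <- wsum(ii(allowed * 1))
    ok <- cnt == ps * ps
    if (!any(ok)) next
    s1 <- wsum(ii(img))
    s2 <- wsum(ii(img^2))
    v <- s2 / ps^2 - (s1 / ps^2)^2
    v[!ok] <- Inf
    i <- which(v == min(v), arr.ind = TRUE)
    i <- i[order(i[, 1], i[, 2]), , drop = FALSE][1, ]
    cand <- list(var = min(v), slice = s, row = i[1], col = i[2])
    if (is.null(best) || cand$var < best$var) best <- cand
  }
  if (is.null(best) || !is.finite(best$var))
    stop("no admissible uniform window inside the liver and clear of the ROI; ",
         "supply a patch manually")
  r <- unname(best$row); c0 <- unname(best$col)
  tile <- volume$data[best$slice, r:(r + ps - 1), c0:(c0 + ps - 1)]
  structure(list(tile = tile,
                 source_location = c(best$slice, r + (ps - 1) / 2,
                                     c0 + (ps - 1) / 2),
                 variance = unname(best$var)),
            class = "pattern_patch")
}

#' Replace a lesion ROI with a synthetic parenchyma pattern
#'
#' Overwrites every voxel of the ROI (dilated in-plane by `margin` voxels so
#' edge gradients cannot leak into the similarity measure) with the patch
#' content, replicated across the region: by periodic tiling anchored at the
#' ROI bounding-box corner (default), or by reflected replication about the
#' ROI center (`style = "radial"`). All other voxels are untouched.
#'
#' @param volume A [ct_volume].
#' @param roi The [roi_mask] to replace.
#' @param patch A `pattern_patch` from [select_uniform_patch()].
#' @param margin In-plane dilation of the ROI before replacement (voxels).
#' @param style `"tiled"` or `"radial"`.
#' @return The [ct_volume] with the ROI region replaced.
#' @export
replace_roi_with_pattern <- function(volume, roi, patch, margin = 2,
                                     style = c("tiled", "radial")) {
  style <- match.arg(style)
  check_same_grid(volume, roi)
  if (!any(roi$voxels)) return(volume)
  ps <- nrow(patch$tile)
  d <- dim(volume$data)
  out <- volume$data
  brush <- EBImage::makeBrush(2 * margin + 1, "box")
  idx <- which(apply(roi$voxels, 1, any))
  bb <- which(roi$voxels, arr.ind = TRUE)
  r0 <- min(bb[, 2]) - margin
  c0 <- min(bb[, 3]) - margin
  for (s in idx) {
    m2 <- if (margin > 0) EBImage::dilate(roi$voxels[s, , ], brush) > 0
          else roi$voxels[s, , ]
    w <- which(m2, arr.ind = TRUE)
    if (style == "tiled") {
      pr <- ((w[, 1] - r0) %% ps) + 1
      pc <- ((w[, 2] - c0) %% ps) + 1
    } else {
      cen <- colMeans(which(roi$voxels[s, , ], arr.ind = TRUE))
      reflect <- function(dv) {
        half <- (ps - 1) / 2
        per <- 2 * ps
        dd <- (dv + half) %% per
        dd <- ifelse(dd >= ps, per - 1 - dd, dd)
        round(dd) + 1
      }
      pr <- reflect(w[, 1] - round(cen[1]))
      pc <- reflect(w[, 2] - round(cen[2]))
    }
    sl <- out[s, , ]
    sl[cbind(w[, 1], w[, 2])] <- patch$tile[cbind(pr, pc)]
    out[s, , ] <- sl
  }
  ct_volume(out, spacing_mm = volume$spacing_mm, origin_mm = volume$origin_mm)
}
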