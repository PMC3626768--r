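# NIfTI I/O and small JSON sidecars (seeds, transforms, reports).
#
# On disk, NIfTI stores axes in (x, y, z) order; in memory the package uses
# (slice, row, col) = (z, y, x). read_volume()/write_volume() permute between
# the two so that a round trip is lossless.

#' Read a CT volume from a NIfTI file
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A [ct_volume] with axis order `(slice, row, col)` and spacing
#'   `(z, y, x)` in mm.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  sp <- RNifti::pixdim(img)
  ct_volume(aperm(arr, c(3, 2, 1)), spacing_mm = rev(sp))
}

#' Write a CT volume to a NIfTI file
#'
#' Intensities are stored as 16-bit signed integers (the pipeline's 12-bit
#' range plus the non-liver sentinel fit losslessly).
#'
#' @param volume A [ct_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- round(aperm(volume$data, c(3, 2, 1)))
  storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(volume$spacing_mm)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a binary ROI mask from a NIfTI file
#' @param path Path to a uint8 NIfTI mask (non-zero = inside).
#' @param role Mask role: `"tumor"`, `"necrosis"` or `"liver"`.
#' @return A [roi_mask].
#' @export
read_mask <- function(path, role) {
  v <- read_volume(path)
  roi_mask(v$data != 0, role = role, spacing_mm = v$spacing_mm)
}

#' Write a binary ROI mask as uint8 NIfTI
#' @param mask A [roi_mask].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  arr <- aperm(mask$voxels, c(3, 2, 1))
  storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(mask$spacing_mm)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read operator seed pixels from a JSON file
#'
#' The file holds a list of objects `{"slice": i, "row": j, "col": k,
#' "target": "tumor"|"necrosis"}` with 0-based voxel indices (the convention
#' documented in the README). Indices are converted to the package's 1-based
#' convention on read.
#'
#' @param path Path to the JSON seeds file.
#' @param target Keep only seeds for this target (`"tumor"` or `"necrosis"`).
#' @return A [seed_set].
#' @export
read_seeds <- function(path, target) {
  if (!file.exists(path)) stop("no such seeds file: ", path)
  df <- jsonlite::fromJSON(path)
  if (!all(c("slice", "row", "col", "target") %in% names(df)))
    stop("seeds file must provide slice, row, col, target")
  df <- df[df$target == target, , drop = FALSE]
  if (nrow(df) == 0) stop("no seeds with target '", target, "' in ", path)
  seed_set(cbind(df$slice, df$row, df$col) + 1L, target = target)
}

#' Write seed pixels to JSON (0-based indices)
#' @param seeds A [seed_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seeds <- function(seeds, path) {
  df <- data.frame(
    slice = seeds$points[, 1] - 1L,
    row = seeds$points[, 2] - 1L,
    col = seeds$points[, 3] - 1L,
    target = seeds$target
  )
  jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a spatial transform to JSON
#'
#' Stores the global affine and the free-form-deformation control grid in
#' millimetres of fixed-image space, plus the voxel-level representation used
#' internally, so the file is self-describing.
#'
#' @param transform An [rfa_transform].
#' @param path Output path.
#' @param spacing_mm Fixed-image voxel spacing used to express the grid in mm.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path, spacing_mm) {
  ffd <- transform$ffd
  obj <- list(
    units = "voxel (fixed-image grid); *_mm fields in mm",
    affine_voxel = transform$affine,
    ffd = if (is.null(ffd)) NULL else list(
      spacing_voxel = ffd$spacing,
      spacing_mm = ffd$spacing * spacing_mm,
      origin_voxel = ffd$origin,
      dim = ffd$dim,
      disp_voxel = as.vector(ffd$disp),
      disp_dim = dim(ffd$disp)
    ),
    fixed_spacing_mm = spacing_mm
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a spatial transform written by [write_transform()]
#' @param path Path to the transform JSON.
#' @return An [rfa_transform].
#' @export
read_transform <- function(path) {
  obj <- jsonlite::fromJSON(path)
  ffd <- NULL
  if (!is.null(obj$ffd) && length(obj$ffd)) {
    ffd <- list(
      spacing = as.numeric(obj$ffd$spacing_voxel),
      origin = as.numeric(obj$ffd$origin_voxel),
      dim = as.integer(obj$ffd$dim),
      disp = array(as.numeric(obj$ffd$disp_voxel), dim = as.integer(obj$ffd$disp_dim))
    )
  }
  aff <- as.matrix(obj$affine_voxel)
  dimnames(aff) <- NULL
  rfa_transform(affine = aff, ffd = ffd)
}
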