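#' 3D image volume with voxel spacing
#'
#' Lightweight container for a 3D scalar grid plus the per-axis voxel
#' spacing in millimetres and a modality tag. CT values are interpreted as
#' Hounsfield units; MR and synthetic volumes carry arbitrary units.
#'
#' @param data Numeric 3D array of voxel values; all values must be finite.
#' @param spacing Numeric length-3 vector `(dx, dy, dz)` of voxel edge
#'   lengths in mm; strictly positive.
#' @param modality One of `"CT"`, `"MR"`, `"SYNTH"`.
#' @return An object of class `rad_volume`.
#' @export
rad_volume <- function(data, spacing = c(1, 1, 1), modality = "SYNTH") {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array (non-3D)")
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive values (mm)")
  }
  modality <- match.arg(modality, c("CT", "MR", "SYNTH"))
  structure(list(data = data, spacing = spacing, modality = modality),
            class = "rad_volume")
}

#' Binary region-of-interest mask
#'
#' @param data Logical or 0/1 numeric 3D array; any nonzero voxel is
#'   foreground.
#' @return An object of class `rad_mask` holding a logical array.
#' @export
rad_mask <- function(data) {
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array (non-3D)")
  m <- array(as.logical(data != 0), dim(data))
  if (!sum(m)) warning("mask is empty (no foreground voxels)")
  structure(list(data = m), class = "rad_mask")
}

#' @export
print.rad_volume <- function(x, ...) {
  cat(sprintf("<rad_volume> %s, dim %s, spacing (%.3g, %.3g, %.3g) mm\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
print.rad_mask <- function(x, ...) {
  cat(sprintf("<rad_mask> dim %s, %d foreground voxels\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

check_pair <- function(img, mask) {
  stopifnot(inherits(img, "rad_volume"), inherits(mask, "rad_mask"))
  if (!identical(dim(img$data), dim(mask$data))) {
    stop("mask shape does not match volume shape")
  }
  if (!any(mask$data)) stop("mask is empty; cannot extract features")
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' @param path Path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param modality Modality tag to attach (`"CT"`, `"MR"`, `"SYNTH"`).
#' @return A [rad_volume].
#' @export
read_volume <- function(path, modality = "SYNTH") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(img, d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) stop("non-3D image: ", path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  rad_volume(array(as.numeric(img), d), spacing = sp, modality = modality)
}

#' Write a volume to NIfTI
#'
#' @param vol A [rad_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "rad_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary ROI mask aligned to a reference volume
#'
#' Any nonzero voxel is treated as foreground.
#'
#' @param path Path to a NIfTI mask file.
#' @param ref Reference [rad_volume] whose shape the mask must match.
#' @return A [rad_mask].
#' @export
read_mask <- function(path, ref) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(img, d[1:3]); d <- d[1:3]
  }
  if (length(d) != 3L) stop("non-3D mask: ", path)
  if (!identical(d, dim(ref$data))) stop("mask shape does not match volume shape")
  rad_mask(array(as.numeric(img), d))
}

#' Write a mask to NIfTI
#'
#' @param mask A [rad_mask].
#' @param path Output path.
#' @param spacing Voxel spacing to record in the header.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1)) {
  stopifnot(inherits(mask, "rad_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
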