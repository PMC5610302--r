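#' 3D image volume with physical geometry
#'
#' A minimal container for a 3D scalar MRI-like volume: the voxel data, the
#' per-axis physical voxel size (in-plane pixel spacing and slice thickness,
#' in mm), a physical origin, and a modality tag. The physical coordinate of
#' voxel `(i, j, k)` (0-based) is `origin_mm + c(i, j, k) * spacing_mm`, i.e.
#' voxel centres carry the coordinates.
#'
#' @param data Numeric 3D array of intensities; all values must be finite.
#' @param spacing_mm Numeric length-3 vector `(pixel_x, pixel_y,
#'   slice_thickness)` in mm; all components must be positive.
#' @param origin_mm Physical coordinate (mm) of the centre of voxel
#'   `(0, 0, 0)`.
#' @param modality Either `"dwi"` (diffusion-weighted, pre-treatment) or
#'   `"flair"` (T2 FLAIR, post-treatment).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing_mm, origin_mm = c(0, 0, 0),
                         modality = c("dwi", "flair")) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!all(is.finite(data)))
    stop("image intensities must be finite", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers", call. = FALSE)
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite numbers", call. = FALSE)
  structure(list(data = data, spacing_mm = spacing_mm,
                 origin_mm = origin_mm, modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume [%s]> %d x %d x %d voxels, spacing %s mm\n",
              x$modality, d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 4), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Binary lesion mask sharing an image volume's geometry
#'
#' @param data Logical (or 0/1) 3D array.
#' @param spacing_mm,origin_mm Geometry, as in [image_volume()]. May be
#'   supplied via `geometry_from` instead.
#' @param geometry_from Optional `image_volume` or `lesion_mask` whose
#'   geometry (shape, spacing, origin) the mask inherits; `data` must match
#'   its shape.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(data, spacing_mm = NULL, origin_mm = NULL,
                        geometry_from = NULL) {
  if (!is.null(geometry_from)) {
    if (!is.null(spacing_mm) || !is.null(origin_mm))
      stop("give either explicit geometry or `geometry_from`, not both",
           call. = FALSE)
    spacing_mm <- geometry_from$spacing_mm
    origin_mm <- geometry_from$origin_mm
    ref_dim <- dim(if (inherits(geometry_from, "image_volume"))
      geometry_from$data else geometry_from$data)
    if (!identical(dim(data), ref_dim))
      stop("mask shape does not match the reference geometry", call. = FALSE)
  }
  if (is.null(origin_mm)) origin_mm <- c(0, 0, 0)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  mode(data) <- "logical"
  if (anyNA(data)) stop("mask must not contain NA", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers", call. = FALSE)
  structure(list(data = data, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lesion_mask> %d x %d x %d voxels, %d in mask (%.3g cm^3)\n",
              d[1], d[2], d[3], sum(x$data),
              sum(x$data) * prod(x$spacing_mm) / 1000))
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing_mm, b$spacing_mm)) &&
    isTRUE(all.equal(a$origin_mm, b$origin_mm))
}

#' Physical voxel-centre coordinates of a grid
#'
#' @param dim Integer length-3 grid shape.
#' @param spacing_mm,origin_mm Grid geometry in mm.
#' @param subset Optional logical array (same shape) or integer vector of
#'   linear voxel indices; only those voxel centres are returned.
#' @return An n x 3 matrix of coordinates in mm, rows in R's column-major
#'   voxel order.
#' @export
voxel_centers_mm <- function(dim, spacing_mm, origin_mm = c(0, 0, 0),
                             subset = NULL) {
  dim <- as.integer(dim)
  if (is.null(subset)) {
    idx <- arrayInd(seq_len(prod(dim)), dim)
  } else {
    if (is.array(subset)) subset <- which(subset)
    idx <- arrayInd(as.integer(subset), dim)
  }
  # arrayInd is 1-based; voxel (0,0,0) sits at the origin
  sweep(sweep(idx - 1L, 2L, spacing_mm, `*`), 2L, origin_mm, `+`)
}

#' Read a NIfTI-1 volume as an image_volume
#'
#' Voxel spacing is taken from the NIfTI `pixdim` field.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param modality Modality tag to attach (`"dwi"` or `"flair"`).
#' @return An [image_volume()].
#' @export
read_volume_nifti <- function(path, modality = c("dwi", "flair")) {
  modality <- match.arg(modality)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
  image_volume(arr, spacing_mm = RNifti::pixdim(img)[1:3],
               modality = modality)
}

#' Write an image volume or mask to NIfTI-1
#'
#' Masks are written as uint8 (0/1); images keep floating point. The voxel
#' spacing is stored in the NIfTI `pixdim` header field.
#'
#' @param x An `image_volume` or `lesion_mask`.
#' @param path Output path (`.nii` for an uncompressed, byte-stable file).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "lesion_mask")) {
    arr <- array(as.integer(x$data), dim = dim(x$data))
    dt <- "uint8"
  } else if (inherits(x, "image_volume")) {
    arr <- x$data
    dt <- "double"
  } else stop("`x` must be an image_volume or lesion_mask", call. = FALSE)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read a uint8 NIfTI mask as a lesion_mask
#'
#' @param path Path to the mask file.
#' @return A [lesion_mask()].
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  lesion_mask(as.array(img) != 0, spacing_mm = RNifti::pixdim(img)[1:3])
}
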