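#' Specification of a synthetic lesion phantom
#'
#' Describes one 3D phantom volume: an axis-aligned ellipsoidal hyperintense
#' lesion of known true geometry embedded in uniform background tissue with
#' additive Gaussian noise. An ellipsoid is used because its volume has a
#' closed form, which gives every downstream stage an analytic ground truth.
#'
#' The default grid is 164 x 238 x 36 voxels at (1, 1, 5) mm — a
#' 164 x 238 x 180 mm^3 extent comparable to a head-sized dosimetry
#' subdomain, with the anisotropic slice thickness typical of clinical
#' axial acquisitions.
#'
#' @param grid_shape Integer length-3 voxel counts per axis.
#' @param spacing_mm Voxel size per axis in mm: in-plane pixel spacing (x, y)
#'   and slice thickness (z). All positive.
#' @param lesion_center_mm Ellipsoid centre in the volume's physical frame
#'   (mm); defaults to the grid centre.
#' @param lesion_semiaxes_mm Ellipsoid semi-axes (mm), one per axis.
#' @param lesion_intensity,background_intensity Scalar intensities; the
#'   lesion must be hyperintense (`lesion_intensity > background_intensity`).
#' @param noise_sd Standard deviation of additive Gaussian noise (0 for a
#'   noiseless phantom).
#' @param rng_seed Integer seed controlling the noise field; identical seeds
#'   give bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(164L, 238L, 36L),
                         spacing_mm = c(1, 1, 5),
                         lesion_center_mm = NULL,
                         lesion_semiaxes_mm = c(18, 14, 10),
                         lesion_intensity = 200,
                         background_intensity = 100,
                         noise_sd = 5,
                         rng_seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(spacing_mm) == 3L)
  if (any(spacing_mm <= 0)) stop("spacings must be > 0", call. = FALSE)
  if (is.null(lesion_center_mm))
    lesion_center_mm <- (grid_shape - 1) * spacing_mm / 2
  lesion_center_mm <- as.numeric(lesion_center_mm)
  lesion_semiaxes_mm <- as.numeric(lesion_semiaxes_mm)
  stopifnot(length(lesion_center_mm) == 3L, length(lesion_semiaxes_mm) == 3L)
  if (any(lesion_semiaxes_mm <= 0))
    stop("lesion semi-axes must be > 0", call. = FALSE)
  if (lesion_intensity <= background_intensity)
    stop("lesion must be hyperintense: lesion_intensity > background_intensity",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  # the ellipsoid bounding box must lie within the physical grid extent
  lo <- lesion_center_mm - lesion_semiaxes_mm
  hi <- lesion_center_mm + lesion_semiaxes_mm
  if (any(lo < 0) || any(hi > (grid_shape - 1) * spacing_mm))
    stop("lesion ellipsoid does not fit inside the grid", call. = FALSE)
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 lesion_center_mm = lesion_center_mm,
                 lesion_semiaxes_mm = lesion_semiaxes_mm,
                 lesion_intensity = lesion_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> grid %s @ %s mm; lesion semi-axes %s mm\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$spacing_mm, collapse = "x"),
              paste(x$lesion_semiaxes_mm, collapse = ", ")))
  cat(sprintf("  intensities %g (lesion) / %g (background), noise sd %g, seed %d\n",
              x$lesion_intensity, x$background_intensity, x$noise_sd,
              x$rng_seed))
  invisible(x)
}

# Exact voxel-centre-in-ellipsoid membership; vectorized via outer sums of
# the per-axis squared normalized offsets.
ellipsoid_truth_mask <- function(spec) {
  d <- spec$grid_shape
  ax <- lapply(1:3, function(k) {
    x <- (seq_len(d[k]) - 1) * spec$spacing_mm[k]
    ((x - spec$lesion_center_mm[k]) / spec$lesion_semiaxes_mm[k])^2
  })
  q <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  lesion_mask(q <= 1, spacing_mm = spec$spacing_mm)
}

phantom_volume <- function(spec, modality) {
  truth <- ellipsoid_truth_mask(spec)
  arr <- array(spec$background_intensity, dim = spec$grid_shape)
  arr[truth$data] <- spec$lesion_intensity
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(spec$rng_seed)
    arr <- arr + array(stats::rnorm(prod(spec$grid_shape), 0, spec$noise_sd),
                       dim = spec$grid_shape)
  }
  list(volume = image_volume(arr, spec$spacing_mm, modality = modality),
       truth = truth)
}

#' Generate a paired DWI-like / FLAIR-like phantom with ground truth
#'
#' Emulates the pre-treatment DWI and 1-month post-treatment FLAIR
#' acquisitions of one subject: two volumes on the identical grid, each with
#' an ellipsoidal hyperintense lesion whose size may differ between the two
#' (lesion growth or shrinkage), plus the exact truth masks. A voxel belongs
#' to a truth mask iff its centre lies inside the ellipsoid.
#'
#' @param spec_pre Phantom specification for the DWI-like (pre) volume.
#' @param spec_post Phantom specification for the FLAIR-like (post) volume;
#'   must share `grid_shape` and `spacing_mm` with `spec_pre`.
#' @return A list of class `phantom_pair` with elements `dwi`, `flair`
#'   ([image_volume()]s) and `truth_pre`, `truth_post` ([lesion_mask()]s).
#' @examples
#' p <- make_phantom_pair(phantom_spec(grid_shape = c(48, 48, 12)),
#'                        phantom_spec(grid_shape = c(48, 48, 12),
#'                                     lesion_semiaxes_mm = c(14, 11, 8)))
#' sum(p$truth_pre$data) > sum(p$truth_post$data)
#' @export
make_phantom_pair <- function(spec_pre, spec_post = spec_pre) {
  stopifnot(inherits(spec_pre, "phantom_spec"),
            inherits(spec_post, "phantom_spec"))
  if (!identical(spec_pre$grid_shape, spec_post$grid_shape) ||
      !isTRUE(all.equal(spec_pre$spacing_mm, spec_post$spacing_mm)))
    stop("pre and post phantoms must share grid shape and spacing",
         call. = FALSE)
  pre <- phantom_volume(spec_pre, "dwi")
  post <- phantom_volume(spec_post, "flair")
  structure(list(dwi = pre$volume, flair = post$volume,
                 truth_pre = pre$truth, truth_post = post$truth),
            class = "phantom_pair")
}

#' Head model for coil warping
#'
#' The head is approximated, for the purpose of bending the stimulation coil
#' onto the scalp, by a cylinder whose radius is the mean head curvature in
#' the coronal plane.
#'
#' @param curvature_radius_mm Cylinder radius in mm (default 90, a typical
#'   adult half-breadth).
#' @param surface_offset_mm Coil-to-scalp standoff in mm (default 0: coil
#'   flush with the scalp).
#' @return An object of class `head_model`.
#' @export
head_model <- function(curvature_radius_mm = 90, surface_offset_mm = 0) {
  if (curvature_radius_mm <= 0)
    stop("curvature radius must be > 0", call. = FALSE)
  if (surface_offset_mm < 0)
    stop("surface offset must be >= 0", call. = FALSE)
  structure(list(curvature_radius_mm = curvature_radius_mm,
                 surface_offset_mm = surface_offset_mm),
            class = "head_model")
}

#' Serialize a phantom specification to a YAML-ready list
#'
#' @param spec A [phantom_spec()].
#' @return A plain named list mirroring the constructor arguments, suitable
#'   for `yaml::write_yaml()` and for the pipeline config `phantom:` block.
#' @export
phantom_spec_to_list <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  unclass(spec)
}
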