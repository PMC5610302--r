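#' Per-lesion magnetic dose summary
#'
#' Distance and flux-density extrema of a lesion under the stimulation
#' coil, plus the fraction of lesion voxels at or above the biological
#' threshold (default 1 mT, the minimum flux density reported to upregulate
#' A2A adenosine receptors in vitro).
#'
#' @param d_min_cm,d_max_cm Min/max Euclidean distance from the coil centre
#'   to lesion voxel centres, cm (may be `NA` when distances were not
#'   computed).
#' @param b_min_mT,b_max_mT Min/max |B| over lesion voxels, mT.
#' @param frac_above_threshold Fraction of lesion voxels with |B| >=
#'   `threshold_mT`.
#' @param threshold_mT Biological threshold, mT (default 1).
#' @return An object of class `dose_summary`.
#' @export
dose_summary <- function(d_min_cm, d_max_cm, b_min_mT, b_max_mT,
                         frac_above_threshold, threshold_mT = 1) {
  if (!is.na(d_min_cm) && !is.na(d_max_cm) && d_min_cm > d_max_cm)
    stop("d_min must be <= d_max", call. = FALSE)
  if (b_min_mT > b_max_mT) stop("b_min must be <= b_max", call. = FALSE)
  if (frac_above_threshold < 0 || frac_above_threshold > 1)
    stop("frac_above_threshold must lie in [0, 1]", call. = FALSE)
  structure(list(d_min_cm = d_min_cm, d_max_cm = d_max_cm,
                 b_min_mT = b_min_mT, b_max_mT = b_max_mT,
                 frac_above_threshold = frac_above_threshold,
                 threshold_mT = threshold_mT),
            class = "dose_summary")
}

#' @export
print.dose_summary <- function(x, ...) {
  cat(sprintf("<dose_summary> D %.1f-%.1f cm, B %.1f-%.1f mT; %.0f%% of voxels >= %g mT (%s)\n",
              x$d_min_cm, x$d_max_cm, x$b_min_mT, x$b_max_mT,
              100 * x$frac_above_threshold, x$threshold_mT,
              if (check_biological_threshold(x)) "pass" else "fail"))
  invisible(x)
}

#' Distance extrema of a lesion from the stimulation coil
#'
#' Euclidean distances from the coil reference to every lesion voxel
#' centre, reported in cm. The default reference is the coil centre point
#' (a single point, matching how lesion-to-coil distance is reported);
#' `mode = "surface"` instead measures to the nearest point of the coil
#' conductor, for sensitivity analysis.
#'
#' @param mask A nonempty [lesion_mask()].
#' @param coil_center_mm Coil centre in the mask's physical frame (mm).
#' @param mode `"center"` (default) or `"surface"`.
#' @param coil A [coil_geometry()], required for `mode = "surface"`; its
#'   vertices (meters) are interpreted in the frame centred at
#'   `coil_center_mm`.
#' @return Named numeric `c(d_min_cm, d_max_cm)`.
#' @export
lesion_distance_stats <- function(mask, coil_center_mm = c(0, 0, 0),
                                  mode = c("center", "surface"),
                                  coil = NULL) {
  stopifnot(inherits(mask, "lesion_mask"))
  mode <- match.arg(mode)
  if (!any(mask$data)) stop("lesion mask is empty", call. = FALSE)
  pts <- voxel_centers_mm(dim(mask$data), mask$spacing_mm, mask$origin_mm,
                          subset = mask$data)
  rel <- sweep(pts, 2, as.numeric(coil_center_mm), `-`)
  if (mode == "center") {
    d_mm <- sqrt(rowSums(rel^2))
  } else {
    stopifnot(inherits(coil, "coil_geometry"))
    s <- coil_segments(coil)
    a_mm <- s$a * 1000; b_mm <- s$b * 1000
    d_mm <- apply(rel, 1, function(p)
      min(dist_point_segments(a_mm, b_mm, p)))
  }
  c(d_min_cm = min(d_mm) / 10, d_max_cm = max(d_mm) / 10)
}

resolve_bmag <- function(field, mask) {
  dm <- dim(mask$data)
  if (inherits(field, "field_grid")) {
    if (nrow(field$points) != prod(dm))
      stop("field grid does not cover the mask's voxel grid", call. = FALSE)
    array(field_magnitude_mT(field), dim = dm)
  } else if (is.array(field)) {
    if (!identical(dim(field), dm))
      stop("field array shape does not match the mask", call. = FALSE)
    field
  } else stop("`field` must be a field_grid or a |B| array in mT",
              call. = FALSE)
}

#' Field-intensity dose summary over a lesion
#'
#' Extrema of |B| over the lesion voxels and the fraction of lesion voxels
#' at or above the biological threshold.
#'
#' @param field Either a `field_grid` from [coil_field()] evaluated at every
#'   voxel centre of the mask's grid (in R's column-major voxel order, as
#'   produced by [field_on_grid()]), or a numeric 3D array of |B| in mT with
#'   the mask's shape.
#' @param mask A nonempty [lesion_mask()].
#' @param threshold_mT Biological threshold in mT (default 1).
#' @param coil_center_mm Optional coil centre (mm, mask frame); when given,
#'   distance extrema are filled in via [lesion_distance_stats()].
#' @return A [dose_summary()].
#' @export
lesion_field_stats <- function(field, mask, threshold_mT = 1,
                               coil_center_mm = NULL) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (!any(mask$data)) stop("lesion mask is empty", call. = FALSE)
  bmag <- resolve_bmag(field, mask)
  vals <- bmag[mask$data]
  d <- c(NA_real_, NA_real_)
  if (!is.null(coil_center_mm))
    d <- lesion_distance_stats(mask, coil_center_mm)
  dose_summary(d_min_cm = d[[1]], d_max_cm = d[[2]],
               b_min_mT = min(vals), b_max_mT = max(vals),
               frac_above_threshold = mean(vals >= threshold_mT),
               threshold_mT = threshold_mT)
}

#' Does the lesion's peak field reach the biological threshold?
#'
#' Peak-based check: true iff the maximum |B| in the lesion is at or above
#' the threshold (inclusive).
#'
#' @param summary A [dose_summary()].
#' @return Logical.
#' @export
check_biological_threshold <- function(summary) {
  stopifnot(inherits(summary, "dose_summary"))
  summary$b_max_mT >= summary$threshold_mT
}

#' Evaluate the coil field at every voxel centre of a grid
#'
#' Maps the image grid into the coil frame (coil centre at
#' `coil_center_mm`, axis along the grid's +z) and evaluates the
#' Biot-Savart sum at each voxel centre.
#'
#' @param coil A [coil_geometry()].
#' @param geometry An [image_volume()] or [lesion_mask()] supplying shape,
#'   spacing and origin.
#' @param coil_center_mm Coil centre in the grid's physical frame (mm).
#' @param guard_m Singularity guard (meters).
#' @return A `field_grid` whose rows follow R's column-major voxel order.
#' @export
field_on_grid <- function(coil, geometry, coil_center_mm = c(0, 0, 0),
                          guard_m = 1e-3) {
  pts_mm <- voxel_centers_mm(dim(geometry$data), geometry$spacing_mm,
                             geometry$origin_mm)
  pts_m <- sweep(pts_mm, 2, as.numeric(coil_center_mm), `-`) / 1000
  coil_field(coil, pts_m, guard_m = guard_m)
}

#' Per-patient dose report table
#'
#' @param summaries Named list of [dose_summary()]s (names are patient ids).
#' @return Data frame with one row per patient: distance and field extrema,
#'   fraction of voxels at or above threshold, and the pass/fail of the
#'   peak-based threshold check.
#' @export
dose_report <- function(summaries) {
  stopifnot(length(summaries) >= 1L,
            all(vapply(summaries, inherits, TRUE, "dose_summary")))
  ids <- names(summaries)
  if (is.null(ids)) ids <- as.character(seq_along(summaries))
  df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(d_min_cm = s$d_min_cm, d_max_cm = s$d_max_cm,
               b_min_mT = s$b_min_mT, b_max_mT = s$b_max_mT,
               frac_above_threshold = s$frac_above_threshold,
               threshold_mT = s$threshold_mT,
               threshold_pass = check_biological_threshold(s))))
  cbind(patient = ids, df, row.names = NULL)
}
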