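# Binary dilation by grid shifts; zero-filled borders. conn: 4/8 in 2D,
# 6/26 in 3D.
shift2d <- function(M, di, dj) {
  n <- nrow(M); m <- ncol(M)
  out <- matrix(FALSE, n, m)
  si <- seq_len(n) - di; sj <- seq_len(m) - dj
  ok_i <- si >= 1 & si <= n; ok_j <- sj >= 1 & sj <= m
  out[ok_i, ok_j] <- M[si[ok_i], sj[ok_j]]
  out
}

dilate2d <- function(M, connectivity) {
  offs <- if (connectivity == 4L)
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  else
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  out <- M
  for (o in offs) out <- out | shift2d(M, o[1], o[2])
  out
}

shift3d <- function(A, d) {
  dm <- dim(A)
  out <- array(FALSE, dm)
  src <- lapply(1:3, function(k) seq_len(dm[k]) - d[k])
  ok <- lapply(1:3, function(k) src[[k]] >= 1 & src[[k]] <= dm[k])
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    A[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

dilate3d <- function(A, connectivity) {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  out <- A
  for (r in seq_len(nrow(offs))) out <- out | shift3d(A, offs[r, ])
  out
}

# Connected component containing `start` (logical array of the same shape)
# within predicate `P`, grown to the fixed point of masked dilation. The
# result depends only on the set {P} and the start voxel, so it is invariant
# to any traversal order by construction.
grow_component <- function(P, start, dilate) {
  R <- start & P
  repeat {
    R2 <- dilate(R) & P
    if (!any(R2 & !R)) return(R)
    R <- R2
  }
}

normalize_seeds <- function(seeds) {
  if (is.list(seeds) && !is.data.frame(seeds))
    seeds <- do.call(rbind, lapply(seeds, as.numeric))
  seeds <- matrix(as.numeric(seeds), ncol = 3)
  if (nrow(seeds) < 1L) stop("at least one seed is required", call. = FALSE)
  if (anyNA(seeds) || any(seeds != round(seeds)))
    stop("seeds must be integer voxel indices (i, j, k), 0-based",
         call. = FALSE)
  storage.mode(seeds) <- "integer"
  seeds
}

#' Convert seed coordinates from mm to 0-based voxel indices
#'
#' Maps physical coordinates to the nearest voxel centre of a volume's grid.
#'
#' @param seeds_mm n x 3 matrix (or list of length-3 vectors) of physical
#'   coordinates in mm.
#' @param volume An [image_volume()] (or any object with `spacing_mm` and
#'   `origin_mm`).
#' @return An n x 3 integer matrix of 0-based voxel indices.
#' @export
seeds_from_mm <- function(seeds_mm, volume) {
  if (is.list(seeds_mm) && !is.data.frame(seeds_mm))
    seeds_mm <- do.call(rbind, lapply(seeds_mm, as.numeric))
  seeds_mm <- matrix(as.numeric(seeds_mm), ncol = 3)
  idx <- round(sweep(sweep(seeds_mm, 2, volume$origin_mm, `-`),
                     2, volume$spacing_mm, `/`))
  storage.mode(idx) <- "integer"
  idx
}

#' Seeded region-growing lesion segmentation
#'
#' Grows, from each seed voxel, the connected region of voxels whose
#' intensity lies within a band defined relative to that seed's own
#' intensity, and returns the union over seeds. With the default
#' `rel_threshold = 0.20` a voxel of intensity I joins seed intensity
#' I_seed's region when `|I - I_seed| <= 0.20 * I_seed` (symmetric band);
#' `band = "lower"` keeps only the lower bound (`I >= 0.80 * I_seed`), for
#' sensitivity analysis. Growth is section-by-section by default: each seed's
#' region is confined to the seed's own axial slice (`mode = "slice"`,
#' 8-connectivity in-plane), matching how hyperintense lesions are outlined
#' slice by slice; `mode = "3d"` grows through the volume (26-connectivity
#' default).
#'
#' The output is a deterministic function of the volume, the seeds and the
#' parameters — independent of seed order and of any traversal strategy.
#'
#' @param volume An [image_volume()].
#' @param seeds n x 3 matrix (or list of length-3 vectors) of 0-based voxel
#'   indices `(i, j, k)`; every seed must lie in bounds and have positive
#'   intensity.
#' @param rel_threshold Relative inclusion band half-width (fraction of the
#'   seed intensity); default 0.20.
#' @param connectivity In-plane neighbourhood for `mode = "slice"` (4 or 8,
#'   default 8); volumetric neighbourhood for `mode = "3d"` (6 or 26,
#'   default 26).
#' @param mode `"slice"` (per-section growth, default) or `"3d"`.
#' @param band `"symmetric"` (default) or `"lower"` (one-sided).
#' @return A [lesion_mask()] on the volume's grid.
#' @examples
#' sl <- rbind(c(100, 85, 79), c(120, 121, 60), c(50, 40, 30))
#' vol <- image_volume(array(sl, dim = c(3, 3, 1)), c(1, 1, 1))
#' m <- region_grow(vol, rbind(c(0, 0, 0)))
#' which(m$data) # voxels within 20% of 100 reachable from the corner
#' @export
region_grow <- function(volume, seeds, rel_threshold = 0.20,
                        connectivity = NULL,
                        mode = c("slice", "3d"),
                        band = c("symmetric", "lower")) {
  stopifnot(inherits(volume, "image_volume"))
  mode <- match.arg(mode)
  band <- match.arg(band)
  if (rel_threshold <= 0) stop("rel_threshold must be > 0", call. = FALSE)
  if (is.null(connectivity))
    connectivity <- if (mode == "slice") 8L else 26L
  connectivity <- as.integer(connectivity)
  if (mode == "slice" && !connectivity %in% c(4L, 8L))
    stop("in-plane connectivity must be 4 or 8", call. = FALSE)
  if (mode == "3d" && !connectivity %in% c(6L, 26L))
    stop("3D connectivity must be 6 or 26", call. = FALSE)

  seeds <- normalize_seeds(seeds)
  dm <- dim(volume$data)
  if (any(seeds < 0L) || any(sweep(seeds, 2, dm, `>=`)))
    stop("seed out of grid bounds", call. = FALSE)

  out <- array(FALSE, dm)
  for (r in seq_len(nrow(seeds))) {
    s <- seeds[r, ] + 1L
    I_seed <- volume$data[s[1], s[2], s[3]]
    if (I_seed <= 0)
      stop("seed intensity must be > 0 (relative band is degenerate)",
           call. = FALSE)
    lo <- (1 - rel_threshold) * I_seed
    hi <- if (band == "symmetric") (1 + rel_threshold) * I_seed else Inf
    if (mode == "slice") {
      sl <- volume$data[, , s[3]]
      P <- sl >= lo & sl <= hi
      start <- matrix(FALSE, dm[1], dm[2]); start[s[1], s[2]] <- TRUE
      comp <- grow_component(P, start,
                             function(M) dilate2d(M, connectivity))
      out[, , s[3]] <- out[, , s[3]] | comp
    } else {
      P <- volume$data >= lo & volume$data <= hi
      start <- array(FALSE, dm); start[s[1], s[2], s[3]] <- TRUE
      comp <- grow_component(P, start,
                             function(A) dilate3d(A, connectivity))
      out <- out | comp
    }
  }
  lesion_mask(out, geometry_from = volume)
}

#' Apply manual-style corrections to a segmentation mask
#'
#' Stands in for the expert's manual-editing pass over the automatically
#' grown borders: voxels in `add` are included, voxels in `remove` are
#' excluded, and removal wins where the two overlap —
#' `(mask | add) & !remove`.
#'
#' @param mask,add,remove [lesion_mask()]s sharing shape, spacing and origin.
#' @return The corrected [lesion_mask()].
#' @export
edit_mask <- function(mask, add, remove) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(add, "lesion_mask"),
            inherits(remove, "lesion_mask"))
  if (!same_geometry(mask, add) || !same_geometry(mask, remove))
    stop("mask, add and remove must share grid geometry", call. = FALSE)
  lesion_mask((mask$data | add$data) & !remove$data,
              spacing_mm = mask$spacing_mm, origin_mm = mask$origin_mm)
}

#' Lesion volume from a binary mask
#'
#' Sums the mask voxels and multiplies by the voxel volume — in-plane pixel
#' spacing times slice thickness — then converts mm^3 to cm^3.
#'
#' @param mask A [lesion_mask()].
#' @param spacing_mm Optional override of the mask's own spacing (mm).
#' @return Volume in cm^3 (0 with a warning for an empty mask).
#' @export
lesion_volume <- function(mask, spacing_mm = NULL) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (is.null(spacing_mm)) spacing_mm <- mask$spacing_mm
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing must be 3 positive numbers", call. = FALSE)
  n <- sum(mask$data)
  if (n == 0L) {
    warning("empty mask: volume is 0", call. = FALSE)
    return(0)
  }
  n * prod(spacing_mm) / 1000
}

#' Per-slice area table of a mask
#'
#' @param mask A [lesion_mask()].
#' @return A data frame with 0-based `slice`, `voxels`, and `area_mm2`
#'   (voxel count times in-plane pixel area), one row per axial slice.
#' @export
slice_area_table <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  counts <- apply(mask$data, 3, sum)
  data.frame(slice = seq_along(counts) - 1L,
             voxels = as.integer(counts),
             area_mm2 = counts * mask$spacing_mm[1] * mask$spacing_mm[2])
}

#' Per-slice seed points from a reference mask
#'
#' For each axial slice intersecting the mask, returns one seed. By default
#' it is the mask voxel nearest the slice's in-plane centroid. When the
#' underlying `volume` is supplied, the seed is instead the mask voxel whose
#' intensity is closest to the median intensity of the slice's mask voxels
#' (nearest the centroid on ties) — emulating an expert picking a
#' representative, rather than arbitrary, lesion voxel, which keeps the
#' seed-relative inclusion band centred on the lesion's typical intensity
#' under noise. Used to seed section-by-section growth on phantoms, where
#' the truth mask is known.
#'
#' @param mask A [lesion_mask()].
#' @param volume Optional [image_volume()] on the same grid.
#' @return An n x 3 integer matrix of 0-based seed indices.
#' @export
seeds_from_mask <- function(mask, volume = NULL) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (!is.null(volume)) {
    stopifnot(inherits(volume, "image_volume"))
    if (!identical(dim(volume$data), dim(mask$data)))
      stop("volume and mask shapes differ", call. = FALSE)
  }
  dm <- dim(mask$data)
  seeds <- list()
  for (k in seq_len(dm[3])) {
    w <- which(mask$data[, , k], arr.ind = TRUE)
    if (nrow(w) == 0L) next
    ctr <- colMeans(w)
    d2 <- (w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2
    if (is.null(volume)) {
      best <- w[which.min(d2), ]
    } else {
      sl <- volume$data[, , k]
      iv <- sl[w]
      dev <- abs(iv - stats::median(iv))
      cand <- which(dev == min(dev))
      best <- w[cand[which.min(d2[cand])], ]
    }
    seeds[[length(seeds) + 1L]] <- c(best[1] - 1L, best[2] - 1L, k - 1L)
  }
  if (length(seeds) == 0L) stop("mask is empty", call. = FALSE)
  do.call(rbind, seeds)
}
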