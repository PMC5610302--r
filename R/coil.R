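MU0 <- 4e-7 * pi  # vacuum permeability, T m / A

#' Single-turn stimulation coil geometry
#'
#' An ordered closed polyline of 3D vertices (meters) carrying a drive
#' current. The constructor closes the loop implicitly: `vertices[n]`
#' connects back to `vertices[1]`.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates in meters;
#'   consecutive vertices (including last-to-first) must be distinct.
#' @param current_A Drive current in amperes; sign sets the orientation.
#' @return An object of class `coil_geometry`.
#' @export
coil_geometry <- function(vertices, current_A) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L || nrow(vertices) < 3L)
    stop("`vertices` must be an n x 3 matrix with n >= 3", call. = FALSE)
  if (!all(is.finite(vertices)) || !is.finite(current_A))
    stop("coil geometry must be finite", call. = FALSE)
  # drop an explicit duplicate closing vertex
  n <- nrow(vertices)
  if (sqrt(sum((vertices[n, ] - vertices[1, ])^2)) < 1e-12)
    vertices <- vertices[-n, , drop = FALSE]
  nxt <- rbind(vertices[-1, , drop = FALSE], vertices[1, , drop = FALSE])
  if (any(sqrt(rowSums((nxt - vertices)^2)) < 1e-12))
    stop("consecutive coil vertices must be distinct", call. = FALSE)
  structure(list(vertices = unname(vertices),
                 current_A = as.numeric(current_A)),
            class = "coil_geometry")
}

#' @export
print.coil_geometry <- function(x, ...) {
  cat(sprintf("<coil_geometry> %d segments, current %g A, perimeter %.4g m\n",
              nrow(x$vertices), x$current_A, coil_perimeter(x)))
  invisible(x)
}

coil_segments <- function(coil) {
  v <- coil$vertices
  list(a = v, b = rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]))
}

#' Total polyline length of a coil
#' @param coil A [coil_geometry()].
#' @return Perimeter in meters.
#' @export
coil_perimeter <- function(coil) {
  s <- coil_segments(coil)
  sum(sqrt(rowSums((s$b - s$a)^2)))
}

#' Construct the flat rectangular stimulation coil
#'
#' Builds a single-turn rectangular loop centred at the origin in the x-y
#' plane, axis along +z (pointing into the head). The defaults are the
#' 14 x 10.6 cm loop driven at 240 A, which produces about 2 mT at the coil
#' centre. The perimeter is discretized into `n_segments` straight segments
#' with the four corners always preserved as vertices; 4 segments (one per
#' side) already evaluate the field of the flat loop exactly, finer
#' discretization matters only as a warping substrate.
#'
#' @param width_m Side along x in meters (default 0.14; the dimension that
#'   gets warped onto the head).
#' @param height_m Side along y in meters (default 0.106).
#' @param current_A Drive current in amperes (default 240).
#' @param n_segments Number of straight segments (>= 4).
#' @return A [coil_geometry()] traversed counter-clockwise seen from +z, so
#'   positive current gives B along +z at the centre.
#' @export
make_rect_coil <- function(width_m = 0.14, height_m = 0.106,
                           current_A = 240, n_segments = 4L) {
  if (width_m <= 0 || height_m <= 0)
    stop("coil dimensions must be > 0", call. = FALSE)
  if (current_A <= 0)
    stop("drive current must be > 0 (reverse orientation via vertices)",
         call. = FALSE)
  n_segments <- as.integer(n_segments)
  if (n_segments < 4L) stop("n_segments must be >= 4", call. = FALSE)
  a <- width_m / 2; b <- height_m / 2
  corners <- rbind(c(a, -b), c(a, b), c(-a, b), c(-a, -b))
  sides <- c(height_m, width_m, height_m, width_m)
  # largest-remainder allocation of segments to sides, at least 1 each
  quota <- n_segments * sides / sum(sides)
  n_side <- pmax(1L, floor(quota))
  rem <- n_segments - sum(n_side)
  if (rem > 0) {
    ord <- order(quota - floor(quota), decreasing = TRUE)
    for (i in seq_len(rem)) n_side[ord[(i - 1) %% 4 + 1]] <-
        n_side[ord[(i - 1) %% 4 + 1]] + 1L
  } else if (rem < 0) {
    ord <- order(n_side, decreasing = TRUE)
    for (i in seq_len(-rem)) n_side[ord[(i - 1) %% 4 + 1]] <-
        n_side[ord[(i - 1) %% 4 + 1]] - 1L
  }
  verts <- NULL
  for (s in 1:4) {
    p0 <- corners[s, ]; p1 <- corners[s %% 4 + 1, ]
    t <- seq(0, 1, length.out = n_side[s] + 1L)[-(n_side[s] + 1L)]
    verts <- rbind(verts, cbind(p0[1] + t * (p1[1] - p0[1]),
                                p0[2] + t * (p1[2] - p0[2])))
  }
  coil_geometry(cbind(verts, 0), current_A)
}

#' Warp a flat coil onto a cylindrical head surface
#'
#' Bends the coil's width dimension (x) onto a cylinder of the head model's
#' curvature radius, emulating the flexible coil conforming to the scalp.
#' The wrap is arc-length preserving along x: a vertex at `(x, y, 0)` maps to
#' `(R sin(x/R), y, R (cos(x/R) - 1))`, so the cylinder axis runs along the
#' coil's height direction (y) and is tangent to the original coil plane at
#' x = 0. As the radius grows the flat coil is recovered. Any scalp standoff
#' in the head model shifts the warped coil along -z (away from the head,
#' which lies toward +z).
#'
#' Warping bends straight segments into chords of arcs, so use a fine
#' discretization (several hundred segments) to keep segment lengths close
#' to the arc lengths.
#'
#' @param coil A [coil_geometry()], normally from [make_rect_coil()].
#' @param head A [head_model()]; its `curvature_radius_mm` must exceed half
#'   the coil's x-extent.
#' @return The warped [coil_geometry()].
#' @export
warp_coil <- function(coil, head) {
  stopifnot(inherits(coil, "coil_geometry"), inherits(head, "head_model"))
  R <- head$curvature_radius_mm / 1000
  half_width <- max(abs(coil$vertices[, 1]))
  if (R <= half_width)
    stop(sprintf(
      "curvature radius (%.3g m) must exceed half the coil width (%.3g m)",
      R, half_width), call. = FALSE)
  v <- coil$vertices
  th <- v[, 1] / R
  w <- cbind(R * sin(th), v[, 2], R * (cos(th) - 1) + v[, 3])
  w[, 3] <- w[, 3] - head$surface_offset_mm / 1000
  coil_geometry(w, coil$current_A)
}

dist_point_segments <- function(a, b, p) {
  # distance from point p to each closed segment [a_i, b_i]
  ap <- sweep(a, 2, p, `-`) * -1
  ab <- b - a
  t <- rowSums(ap * ab) / rowSums(ab * ab)
  t <- pmin(pmax(t, 0), 1)
  q <- a + ab * t
  sqrt(rowSums(sweep(q, 2, p, `-`)^2))
}

#' Magnetic field of one straight current segment
#'
#' Exact closed-form Biot-Savart contribution of a finite straight filament
#' carrying current I from `p_start` to `p_end`, evaluated at one or more
#' field points, in the singularity-robust two-ray form
#' \deqn{B = \frac{\mu_0 I}{4\pi}\,
#'   \frac{(r_1 + r_2)\; (\mathbf{r}_1 \times \mathbf{r}_2)}
#'        {r_1 r_2 (r_1 r_2 + \mathbf{r}_1\cdot\mathbf{r}_2)},}
#' with \eqn{\mathbf{r}_1, \mathbf{r}_2} the vectors from the segment ends to
#' the field point. This equals the classic \eqn{\mu_0 I (\cos\theta_1 -
#' \cos\theta_2)/(4\pi\rho)} form and tends to the infinite-wire field
#' \eqn{\mu_0 I / 2\pi\rho} as the ends recede.
#'
#' @param p_start,p_end Segment endpoints, meters.
#' @param current_A Current in amperes (flowing start to end).
#' @param points Field point (length-3) or n x 3 matrix, meters.
#' @param guard_m Minimum allowed distance from the segment (default 1 mm);
#'   closer points raise an error rather than being regularized.
#' @return n x 3 matrix of B vectors in tesla.
#' @export
biot_savart_segment <- function(p_start, p_end, current_A, points,
                                guard_m = 1e-3) {
  p_start <- as.numeric(p_start); p_end <- as.numeric(p_end)
  points <- matrix(as.numeric(points), ncol = 3)
  # distances point-to-segment, vectorized over points
  ab <- p_end - p_start
  ap <- sweep(points, 2, p_start, `-`)
  t <- pmin(pmax(as.vector(ap %*% ab) / sum(ab * ab), 0), 1)
  q <- sweep(outer(t, ab), 2, p_start, `+`)
  dmin <- sqrt(rowSums((points - q)^2))
  if (any(dmin < guard_m))
    stop(sprintf(
      "field point within the %g m singularity guard of the conductor (closest: %.3g m)",
      guard_m, min(dmin)), call. = FALSE)
  r1 <- ap                                  # from start to point
  r2 <- sweep(points, 2, p_end, `-`)        # from end to point
  n1 <- sqrt(rowSums(r1^2)); n2 <- sqrt(rowSums(r2^2))
  cr <- cbind(r1[, 2] * r2[, 3] - r1[, 3] * r2[, 2],
              r1[, 3] * r2[, 1] - r1[, 1] * r2[, 3],
              r1[, 1] * r2[, 2] - r1[, 2] * r2[, 1])
  denom <- n1 * n2 * (n1 * n2 + rowSums(r1 * r2))
  cr * (MU0 * current_A / (4 * pi)) * ((n1 + n2) / denom)
}

#' Magnetic field of a coil over a set of points
#'
#' Sums the exact finite-segment Biot-Savart contributions of every coil
#' segment at each field point. The result is linear in the drive current
#' and reverses with loop orientation.
#'
#' @param coil A [coil_geometry()].
#' @param points n x 3 matrix of field points in meters (or a length-3
#'   vector for a single point).
#' @param guard_m Singularity guard distance passed to
#'   [biot_savart_segment()]; if any point lies within it, the error names
#'   the offending point index.
#' @return An object of class `field_grid`: list with `points` (n x 3, m)
#'   and `B` (n x 3, tesla).
#' @export
coil_field <- function(coil, points, guard_m = 1e-3) {
  stopifnot(inherits(coil, "coil_geometry"))
  points <- matrix(as.numeric(points), ncol = 3)
  s <- coil_segments(coil)
  B <- matrix(0, nrow(points), 3)
  for (i in seq_len(nrow(s$a))) {
    contrib <- tryCatch(
      biot_savart_segment(s$a[i, ], s$b[i, ], coil$current_A, points,
                          guard_m = guard_m),
      error = function(e) {
        ab <- s$b[i, ] - s$a[i, ]
        ap <- sweep(points, 2, s$a[i, ], `-`)
        t <- pmin(pmax(as.vector(ap %*% ab) / sum(ab * ab), 0), 1)
        q <- sweep(outer(t, ab), 2, s$a[i, ], `+`)
        bad <- which.min(sqrt(rowSums((points - q)^2)))
        stop(sprintf("point %d lies on or too near the conductor: %s",
                     bad, conditionMessage(e)), call. = FALSE)
      })
    B <- B + contrib
  }
  structure(list(points = points, B = B), class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  m <- field_magnitude_mT(x)
  cat(sprintf("<field_grid> %d points, |B| in [%.3g, %.3g] mT\n",
              nrow(x$points), min(m), max(m)))
  invisible(x)
}

#' Flux-density magnitude of a field grid in mT
#' @param field A `field_grid` from [coil_field()].
#' @return Numeric vector of |B| in millitesla.
#' @export
field_magnitude_mT <- function(field) {
  stopifnot(inherits(field, "field_grid"))
  sqrt(rowSums(field$B^2)) * 1000
}

#' Closed-form centre field of a flat rectangular loop
#'
#' Analytic magnitude of B at the geometric centre of a flat rectangular
#' loop with half-sides a, b:
#' \deqn{B = \frac{\mu_0 I \sqrt{a^2 + b^2}}{\pi a b}.}
#' Serves as an independent oracle for the segment-summation path.
#'
#' @param half_width_a,half_height_b Half-side lengths in meters.
#' @param current_A Current in amperes.
#' @return |B| in tesla.
#' @export
rect_center_field <- function(half_width_a, half_height_b, current_A) {
  if (half_width_a <= 0 || half_height_b <= 0)
    stop("half-sides must be > 0", call. = FALSE)
  MU0 * current_A * sqrt(half_width_a^2 + half_height_b^2) /
    (pi * half_width_a * half_height_b)
}

#' Closed-form on-axis field of a flat rectangular loop
#'
#' Analytic |B| on the symmetry axis at height z above the loop plane:
#' \deqn{B(z) = \frac{\mu_0 I\, a b}{\pi}
#'   \left[\frac{1}{a^2+z^2} + \frac{1}{b^2+z^2}\right]
#'   \frac{1}{\sqrt{a^2+b^2+z^2}}.}
#' Reduces to [rect_center_field()] at z = 0 and decays as \eqn{1/z^3}
#' (magnetic dipole) far from the loop.
#'
#' @param half_width_a,half_height_b Half-side lengths in meters.
#' @param current_A Current in amperes.
#' @param z Axial distance(s) in meters.
#' @return |B| in tesla (vectorized over `z`).
#' @export
rect_axis_field <- function(half_width_a, half_height_b, current_A, z) {
  if (half_width_a <= 0 || half_height_b <= 0)
    stop("half-sides must be > 0", call. = FALSE)
  a <- half_width_a; b <- half_height_b
  MU0 * current_A * a * b / pi *
    (1 / (a^2 + z^2) + 1 / (b^2 + z^2)) / sqrt(a^2 + b^2 + z^2)
}

#' Pulsed stimulation waveform
#'
#' The stimulation device delivers a single-pulsed signal: a rectangular
#' envelope of the given peak flux density, repeated at the pulse frequency.
#' Defaults are the device's nominal 75 Hz repetition rate, 1.3 ms pulse
#' width and 1.8 mT peak (with stated device tolerances of +/- 2 Hz and
#' +/- 0.2 mT, carried as metadata).
#'
#' @param frequency_Hz Pulse repetition frequency (default 75).
#' @param pulse_width_s Pulse duration in seconds (default 1.3e-3); must be
#'   shorter than the period.
#' @param peak_mT Peak flux density in mT (default 1.8).
#' @param frequency_tol_Hz,peak_tol_mT Stated device tolerances (metadata).
#' @return An object of class `pulse_waveform`.
#' @export
pulse_waveform <- function(frequency_Hz = 75, pulse_width_s = 1.3e-3,
                           peak_mT = 1.8, frequency_tol_Hz = 2,
                           peak_tol_mT = 0.2) {
  if (frequency_Hz <= 0 || pulse_width_s <= 0 || peak_mT <= 0)
    stop("frequency, pulse width and peak must be > 0", call. = FALSE)
  if (pulse_width_s >= 1 / frequency_Hz)
    stop("pulse width must be shorter than the period", call. = FALSE)
  structure(list(frequency_Hz = frequency_Hz, pulse_width_s = pulse_width_s,
                 peak_mT = peak_mT, frequency_tol_Hz = frequency_tol_Hz,
                 peak_tol_mT = peak_tol_mT),
            class = "pulse_waveform")
}

#' @export
print.pulse_waveform <- function(x, ...) {
  cat(sprintf(
    "<pulse_waveform> %g +/- %g Hz, %.3g ms pulses, peak %g +/- %g mT (duty %.4g)\n",
    x$frequency_Hz, x$frequency_tol_Hz, x$pulse_width_s * 1000,
    x$peak_mT, x$peak_tol_mT, duty_fraction(x)))
  invisible(x)
}

#' Instantaneous waveform amplitude
#'
#' @param wave A [pulse_waveform()].
#' @param t Time(s) in seconds, t >= 0.
#' @return Amplitude in mT: the peak while `t mod period < pulse_width`,
#'   otherwise 0.
#' @export
pulse_amplitude <- function(wave, t) {
  stopifnot(inherits(wave, "pulse_waveform"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  ifelse(t %% (1 / wave$frequency_Hz) < wave$pulse_width_s, wave$peak_mT, 0)
}

#' Duty fraction of the pulsed waveform
#' @param wave A [pulse_waveform()].
#' @return Fraction of each period spent at peak (width x frequency).
#' @export
duty_fraction <- function(wave) {
  stopifnot(inherits(wave, "pulse_waveform"))
  wave$pulse_width_s * wave$frequency_Hz
}

#' Write coil vertices to a plain-text file
#'
#' One `x y z` triple per line, meters; the loop closure is implicit.
#' @param coil A [coil_geometry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coil_vertices <- function(coil, path) {
  stopifnot(inherits(coil, "coil_geometry"))
  utils::write.table(format(coil$vertices, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
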