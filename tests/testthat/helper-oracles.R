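# Independent oracles, deliberately written along different code paths than
# the package implementation.

# Brute-force count of voxel centres inside an axis-aligned ellipsoid,
# looping over an explicit coordinate table.
count_centers_in_ellipsoid <- function(grid_shape, spacing_mm, center_mm,
                                       semiaxes_mm) {
  g <- expand.grid(i = 0:(grid_shape[1] - 1), j = 0:(grid_shape[2] - 1),
                   k = 0:(grid_shape[3] - 1))
  x <- g$i * spacing_mm[1]
  y <- g$j * spacing_mm[2]
  z <- g$k * spacing_mm[3]
  sum(((x - center_mm[1]) / semiaxes_mm[1])^2 +
        ((y - center_mm[2]) / semiaxes_mm[2])^2 +
        ((z - center_mm[3]) / semiaxes_mm[3])^2 <= 1)
}

# Explicit stack/queue flood fill over one 2D slice with a fixed intensity
# band: a traversal-order-dependent algorithm whose *result* must equal the
# package's fixed-point growth. `order = "lifo"` is depth-first,
# `order = "fifo"` breadth-first.
flood_fill_slice <- function(slice, seed_rc, lo, hi, connectivity = 8L,
                             order = c("lifo", "fifo")) {
  order <- match.arg(order)
  offs <- if (connectivity == 4L)
    rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  else as.matrix(expand.grid(-1:1, -1:1))[-5, ]
  n <- nrow(slice); m <- ncol(slice)
  inband <- function(r, c) slice[r, c] >= lo & slice[r, c] <= hi
  visited <- matrix(FALSE, n, m)
  if (!inband(seed_rc[1], seed_rc[2])) return(visited)
  frontier <- list(seed_rc)
  visited[seed_rc[1], seed_rc[2]] <- TRUE
  while (length(frontier) > 0) {
    idx <- if (order == "lifo") length(frontier) else 1L
    cur <- frontier[[idx]]
    frontier[[idx]] <- NULL
    for (r in seq_len(nrow(offs))) {
      p <- cur + offs[r, ]
      if (p[1] >= 1 && p[1] <= n && p[2] >= 1 && p[2] <= m &&
          !visited[p[1], p[2]] && inband(p[1], p[2])) {
        visited[p[1], p[2]] <- TRUE
        frontier[[length(frontier) + 1L]] <- p
      }
    }
  }
  visited
}

# Adaptive-quadrature evaluation of the Biot-Savart integral for one finite
# straight segment: B = mu0 I / 4pi * int_0^1 L x (p - X(s)) / |p - X(s)|^3 ds.
bs_quadrature <- function(p_start, p_end, current_A, point,
                          rel.tol = 1e-10) {
  mu0 <- 4e-7 * pi
  L <- p_end - p_start
  comp <- function(j) {
    f <- function(s) {
      sapply(s, function(si) {
        r <- point - (p_start + si * L)
        cr <- c(L[2] * r[3] - L[3] * r[2],
                L[3] * r[1] - L[1] * r[3],
                L[1] * r[2] - L[2] * r[1])
        cr[j] / sum(r^2)^1.5
      })
    }
    stats::integrate(f, 0, 1, rel.tol = rel.tol, abs.tol = 0)$value
  }
  mu0 * current_A / (4 * pi) * c(comp(1), comp(2), comp(3))
}

# Quick small phantom specification used across tests.
quick_spec <- function(seed = 1L, noise_sd = 0, semiaxes = c(10, 10, 5),
                       spacing = c(1, 1, 1), shape = c(40L, 40L, 20L),
                       center = NULL, lesion = 200, background = 100) {
  phantom_spec(grid_shape = shape, spacing_mm = spacing,
               lesion_center_mm = center,
               lesion_semiaxes_mm = semiaxes,
               lesion_intensity = lesion,
               background_intensity = background,
               noise_sd = noise_sd, rng_seed = seed)
}
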