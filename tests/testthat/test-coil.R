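test_that("rectangular coil construction preserves corners, perimeter and centre", {
  co <- make_rect_coil()
  expect_equal(coil_perimeter(co), 2 * (0.14 + 0.106))
  co4 <- make_rect_coil(n_segments = 4)
  expect_equal(nrow(co4$vertices), 4L)
  expect_setequal(apply(sign(co4$vertices[, 1:2]), 1, paste, collapse = ""),
                  c("11", "1-1", "-11", "-1-1"))
  expect_equal(colMeans(co4$vertices), c(0, 0, 0))
  # corners survive finer discretization
  co720 <- make_rect_coil(n_segments = 720)
  expect_equal(nrow(co720$vertices), 720L)
  expect_equal(coil_perimeter(co720), 0.492)
  corners <- co4$vertices
  d <- apply(corners, 1, function(p)
    min(sqrt(rowSums(sweep(co720$vertices, 2, p)^2))))
  expect_true(all(d < 1e-12))
  expect_error(make_rect_coil(width_m = -0.1), "> 0")
  expect_error(make_rect_coil(n_segments = 3), ">= 4")
})

test_that("finite-segment kernel matches the infinite-wire limit and vanishes on the axis line", {
  # near-infinite wire along y, field point 1 cm off: mu0 I / 2 pi rho
  B <- biot_savart_segment(c(0, -100, 0), c(0, 100, 0), 1, c(0.01, 0, 0))
  expect_equal(sqrt(sum(B^2)), 2e-5, tolerance = 1e-4)
  expect_equal(B[1, c(1, 2)], c(0, 0), tolerance = 1e-20)
  # collinear field point outside the segment: zero cross product
  B0 <- biot_savart_segment(c(0, 0, 0), c(0, 0, 0.1), 5, c(0, 0, 0.2))
  expect_equal(as.vector(B0), c(0, 0, 0))
  # points on or within 1 mm of the conductor are refused
  expect_error(biot_savart_segment(c(0, 0, 0), c(0, 0, 0.1), 5,
                                   c(5e-4, 0, 0.05)),
               "singularity guard")
})

test_that("segment kernel equals adaptive quadrature of the Biot-Savart integrand", {
  set.seed(7)
  for (i in 1:8) {
    a <- runif(3, -0.1, 0.1)
    b <- runif(3, -0.1, 0.1)
    p <- runif(3, 0.12, 0.3) * sample(c(-1, 1), 3, TRUE)
    I <- runif(1, 1, 300)
    got <- as.vector(biot_savart_segment(a, b, I, p))
    want <- bs_quadrature(a, b, I, p)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("segment sum reproduces the closed-form centre and on-axis fields", {
  co <- make_rect_coil(n_segments = 4)
  b_centre <- field_magnitude_mT(coil_field(co, c(0, 0, 0)))
  expect_equal(b_centre, 1000 * rect_center_field(0.07, 0.053, 240),
               tolerance = 0.005)
  expect_equal(b_centre, 2.272, tolerance = 0.005)
  b_33 <- field_magnitude_mT(coil_field(co, c(0, 0, 0.033)))
  expect_equal(b_33, 1000 * rect_axis_field(0.07, 0.053, 240, 0.033),
               tolerance = 0.005)
  expect_equal(b_33, 1.61, tolerance = 0.005)
  # z = 0 consistency and the square-loop specialization
  expect_equal(rect_axis_field(0.07, 0.053, 240, 0),
               rect_center_field(0.07, 0.053, 240))
  # square loop of side L = 2a: B = 2 sqrt(2) mu0 I / (pi L)
  expect_equal(rect_center_field(0.05, 0.05, 10),
               2 * sqrt(2) * (4e-7 * pi) * 10 / (pi * 0.1))
  expect_equal(rect_center_field(0.07, 0.053, 0), 0)
})

test_that("field is linear in current and reverses with loop orientation", {
  pts <- rbind(c(0.02, 0.01, 0.05), c(0, 0, 0.1), c(-0.03, 0.02, 0.02))
  f1 <- coil_field(make_rect_coil(current_A = 240), pts)
  f2 <- coil_field(make_rect_coil(current_A = 480), pts)
  expect_equal(f2$B, 2 * f1$B, tolerance = 1e-12)
  rev_coil <- coil_geometry(make_rect_coil()$vertices[4:1, ], 240)
  f3 <- coil_field(rev_coil, pts)
  expect_equal(f3$B, -f1$B, tolerance = 1e-12)
})

test_that("on-axis magnitude decays monotonically and reaches the dipole regime", {
  z <- seq(0.01, 0.2, by = 0.005)
  co <- make_rect_coil()
  bz <- field_magnitude_mT(coil_field(co, cbind(0, 0, z)))
  expect_true(all(diff(bz) < 0))
  # 1/z^3 far-field: B(z)/B(2z) -> 8
  bfar <- rect_axis_field(0.07, 0.053, 240, c(5, 10, 20))
  expect_equal(bfar[1] / bfar[2], 8, tolerance = 0.01)
  expect_equal(bfar[2] / bfar[3], 8, tolerance = 0.005)
})

test_that("numerical divergence of B vanishes away from the conductor", {
  co <- make_rect_coil()
  h <- 0.002
  set.seed(3)
  for (i in 1:5) {
    p <- c(runif(1, -0.04, 0.04), runif(1, -0.03, 0.03), runif(1, 0.03, 0.08))
    pts <- rbind(p + c(h, 0, 0), p - c(h, 0, 0),
                 p + c(0, h, 0), p - c(0, h, 0),
                 p + c(0, 0, h), p - c(0, 0, h), p)
    f <- coil_field(co, pts)
    div <- (f$B[1, 1] - f$B[2, 1] + f$B[3, 2] - f$B[4, 2] +
              f$B[5, 3] - f$B[6, 3]) / (2 * h)
    bmag <- sqrt(sum(f$B[7, ]^2))
    expect_lt(abs(div), 1e-3 * bmag / h)
  }
})

test_that("cylindrical warp preserves arc length and recovers the flat coil", {
  co <- make_rect_coil(n_segments = 720)
  # enormous radius: essentially flat
  w_flat <- warp_coil(co, head_model(1e12))
  expect_lt(max(abs(w_flat$vertices - co$vertices)), 1e-6)
  # realistic radius: polyline length within 0.1% of the flat perimeter
  w <- warp_coil(co, head_model(90))
  expect_lt(abs(coil_perimeter(w) - 0.492) / 0.492, 0.001)
  # sup-norm field convergence to the flat coil as the radius grows
  pts <- rbind(c(0, 0, 0.03), c(0.02, -0.01, 0.05), c(-0.03, 0.02, 0.04))
  b_flat <- coil_field(co, pts)$B
  err <- vapply(c(0.2, 0.8, 3.2), function(R)
    max(abs(coil_field(warp_coil(co, head_model(R * 1000)), pts)$B -
              b_flat)), numeric(1))
  expect_true(all(diff(err) < 0))
  # at R = 3.2 m the vertices move by at most ~0.8 mm, so the field at
  # 3-5 cm standoff should agree to a couple of percent
  expect_lt(err[3] / max(abs(b_flat)), 0.02)
  # radius smaller than the half-width is rejected
  expect_error(warp_coil(co, head_model(60)), "must exceed")
  # standoff shifts the coil away from the head
  w_off <- warp_coil(co, head_model(90, surface_offset_mm = 10))
  expect_equal(w_off$vertices[, 3], w$vertices[, 3] - 0.01)
})

test_that("pulse waveform has the stated duty cycle, peak and period", {
  w <- pulse_waveform()
  expect_equal(duty_fraction(w), 0.0975)
  expect_equal(pulse_amplitude(w, 0), 1.8)
  expect_equal(pulse_amplitude(w, 1.29e-3), 1.8)
  expect_equal(pulse_amplitude(w, 1.31e-3), 0)
  # periodicity at 75 Hz (sample away from the pulse edges, where the
  # floating-point modulo is allowed to tip either way)
  t <- seq(1e-6, 1 / 75 - 1e-6, length.out = 500)
  expect_equal(pulse_amplitude(w, t), pulse_amplitude(w, t + 1 / 75))
  expect_equal(pulse_amplitude(w, t), pulse_amplitude(w, t + 4 / 75))
  # mean over one period is peak x duty
  tt <- seq(0, 1 / 75, length.out = 200001)[-200001]
  expect_equal(mean(pulse_amplitude(w, tt)), 1.8 * 0.0975,
               tolerance = 1e-3)
  expect_error(pulse_waveform(pulse_width_s = 0.02), "shorter than")
})

test_that("coil vertices serialize to a plain-text list and re-read exactly", {
  co <- make_rect_coil(n_segments = 12)
  f <- tempfile(fileext = ".txt")
  write_coil_vertices(co, f)
  back <- as.matrix(utils::read.table(f))
  expect_equal(unname(back), co$vertices, tolerance = 1e-15)
})
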