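test_that("noise-free wall detection lands on the physical wall within one pixel", {
  f <- straight_field()
  vm <- field_as_map(f)
  edges <- detect_wall(vm, zero_threshold = 1e-9)
  expect_true(all(abs(edges$upper$x - 1.6) <= 0.05))
  expect_true(all(abs(edges$lower$x + 1.6) <= 0.05))
})

test_that("an all-zero velocity map is rejected as an empty lumen", {
  vm <- velocity_map(matrix(0, 10, 10), matrix(0, 10, 10),
                     z = 1:10, x = 1:10)
  expect_error(detect_wall(vm, zero_threshold = 1e-9), "empty lumen")
})

test_that("contour fitting recovers a jittered straight wall to sub-pixel accuracy", {
  set.seed(21)
  z <- seq(0, 8, by = 0.05)
  edges <- data.frame(wall_id = "upper", z = z,
                      x = 1.6 + stats::runif(length(z), -0.05, 0.05))
  ct <- fit_wall_contour(edges)
  expect_lt(sqrt(mean((ct$x - 1.6)^2)), 0.025)       # < 0.5 pixel
  # normals straight-up: median within 2 degrees, no gross outliers
  ang <- abs(atan2(ct$nz, ct$nx)) * 180 / pi
  expect_lt(stats::median(ang), 2)
  expect_true(all(ang < 5))
  expect_true(all(abs(ct$nz^2 + ct$nx^2 - 1) < 1e-9))
  expect_true(all(abs(ct$nz * ct$tz + ct$nx * ct$tx) < 1e-9))
})

test_that("contour fitting reproduces an exact parabolic wall", {
  z <- seq(0, 8, by = 0.05)
  xw <- 1.6 + 0.01 * (z - 4)^2
  ct <- fit_wall_contour(data.frame(wall_id = "upper", z = z, x = xw))
  expect_equal(ct$x, xw, tolerance = 1e-8)
})

test_that("a pure sine profile yields the exact wall derivative for any K", {
  L <- 3.2
  y <- seq(0, L, by = 0.01)
  A <- 0.05
  for (K in c(1, 5, 20)) {
    fit <- fit_sine_series(y, A * sin(pi * y / L), L, K = K)
    expect_equal(sine_series_deriv(fit, 0), A * pi / L, tolerance = 1e-9)
    expect_equal(sine_series_deriv(fit, L), -A * pi / L, tolerance = 1e-9)
  }
  z <- fit_sine_series(y, numeric(length(y)), L, K = 10)
  expect_true(all(z$coefficients == 0))
})

test_that("sine reconstructions satisfy no-slip at the walls exactly", {
  L <- 3.2
  y <- seq(0, L, by = 0.02)
  fit <- fit_sine_series(y, 0.08 * 4 * y * (L - y) / L^2, L, K = 20)
  expect_equal(sine_series_eval(fit, 0), 0, tolerance = 1e-14)
  expect_equal(sine_series_eval(fit, L), 0, tolerance = 1e-14)
})

test_that("underdetermined sine fits are rejected", {
  expect_error(fit_sine_series(seq(0, 1, length.out = 10), rnorm(10), 1, K = 10),
               "underdetermined")
})

test_that("a 100/s wall shear rate maps to 0.1 Pa with mu = 1e-3", {
  # profile A sin(pi y / L) with A chosen so the wall derivative is 100 1/s;
  # hand evaluation of sigma = -mu (grad u + grad u^T) projected tangentially
  L <- 3.2e-3                                   # m
  gam <- 100
  A <- gam * L / pi
  x <- seq(-2.2, 2.2, by = 0.05)
  z <- seq(0, 8, by = 0.05)
  yy <- (x + 1.6) * 1e-3
  prof <- ifelse(yy >= 0 & yy <= L, A * sin(pi * pmax(pmin(yy, L), 0) / L), 0)
  vm <- velocity_map(outer(rep(1, length(z)), prof),
                     matrix(0, length(z), length(x)), z, x,
                     low_power = outer(rep(TRUE, length(z)), !(yy > 0 & yy < L)))
  ct <- contour_from_geometry(straight_geom(), seq(0.5, 7.5, by = 0.1))
  w <- compute_wss_map(vm, ct, fluid_properties(mu = 1e-3), K = 20)
  expect_true(all(abs(w$wss_pa - 0.1) < 1e-3))
  expect_true(all(abs(w$shear_rate) > 99 & abs(w$shear_rate) < 101))
  # vector tangency: wss is axial, the lateral component vanishes
  expect_true(all(abs(w$wssx_pa) < 1e-6))
})

test_that("zero flow produces zero wall shear stress", {
  x <- seq(-2.2, 2.2, by = 0.05)
  z <- seq(0, 8, by = 0.05)
  vm <- velocity_map(matrix(0, length(z), length(x)),
                     matrix(0, length(z), length(x)), z, x)
  ct <- contour_from_geometry(straight_geom(), seq(0.5, 7.5, by = 0.1))
  w <- compute_wss_map(vm, ct, fluid_properties())
  expect_true(all(w$wss_pa == 0))
})

test_that("pseudo-spectral and finite-difference oracles agree on Poiseuille", {
  g <- straight_geom()
  f <- straight_field()                          # 64 samples per diameter
  zs <- seq(1, 7, by = 0.1)
  ct <- contour_from_geometry(g, zs)
  ps <- compute_wss_map(field_as_map(f), ct, fluid_properties(0.9e-3), K = 20)
  fd <- fd_wss_oracle(f, ct, fluid_properties(0.9e-3))
  key <- paste(fd$wall_id, round(fd$z_mm, 6))
  m <- match(paste(ps$wall_id, round(ps$z_mm, 6)), key)
  expect_true(all(abs(ps$wss_pa / fd$wss_pa[m] - 1) < 0.03))
})

test_that("near-wall margin exclusion leaves noise-free profiles unbiased", {
  g <- straight_geom()
  f <- straight_field()
  ct <- contour_from_geometry(g, seq(1, 7, by = 0.2))
  w0 <- compute_wss_map(field_as_map(f), ct, fluid_properties(0.9e-3),
                        wall_margin = 0)
  w1 <- compute_wss_map(field_as_map(f), ct, fluid_properties(0.9e-3),
                        wall_margin = 0.1)
  expect_equal(mean(w1$wss_pa), mean(w0$wss_pa), tolerance = 0.01)
})
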