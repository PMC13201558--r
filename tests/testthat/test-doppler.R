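test_that("SVD of the Casorati matrix is orthonormal with descending singular values", {
  iq <- small_ensemble()
  dec <- svd_casorati(iq, nu = 8)
  expect_true(all(diff(dec$d) <= 1e-9))
  expect_true(all(dec$d >= 0))
  V <- dec$v[, 1:8]
  G <- Conj(t(V)) %*% V
  expect_lt(max(Mod(G - diag(8))), 1e-8)
})

test_that("clutter filtering never increases ensemble energy and n_discard = 0 is identity", {
  iq <- add_clutter_and_noise(small_ensemble(), 40, 20, seed = 3)
  f1 <- svd_clutter_filter(iq, 1)
  expect_lte(sum(Mod(f1$data)^2), sum(Mod(iq$data)^2))
  f0 <- svd_clutter_filter(iq, 0)
  expect_equal(f0$data, iq$data, tolerance = 1e-10)
})

test_that("a purely static ensemble is annihilated as an exact rank-1 component", {
  g <- straight_geom()
  cl <- seed_scatterers(g, 2e5, 0.3, seed = 3)
  iq <- simulate_iq_ensemble(cl, uniform_field(0, 0), acq_params(n_frames = 32),
                             to_enabled = FALSE)
  iqf <- svd_clutter_filter(iq, 1)
  expect_lt(sum(Mod(iqf$data)^2) / sum(Mod(iq$data)^2), 1e-10)
})

test_that("axial estimates are zero on static data and invariant to global phase", {
  g <- straight_geom()
  cl <- seed_scatterers(g, 2e5, 0.3, seed = 3)
  iq <- simulate_iq_ensemble(cl, uniform_field(0, 0), acq_params(n_frames = 16),
                             to_enabled = FALSE)
  vm <- estimate_axial_velocity(iq)
  expect_true(all(vm$v_axial == 0))
  iqm <- small_ensemble()
  iqr <- iq_ensemble(iqm$data * exp(1i * 0.7), iqm$params, iqm$z, iqm$x)
  expect_equal(estimate_axial_velocity(iqr)$v_axial,
               estimate_axial_velocity(iqm)$v_axial, tolerance = 1e-10)
})

test_that("TO quadrature of a lateral cosine splits into conjugate complex tones", {
  p <- acq_params(n_frames = 2)
  x <- seq(-2.2, 2.2, by = 0.05)
  z <- seq(0, 4, by = 0.05)
  tone <- outer(rep(1, length(z)), cos(2 * pi * x / 0.25))
  cube <- array(complex(real = tone), dim = c(length(z), length(x), 2))
  iq <- iq_ensemble(cube, p, z, x)
  q <- make_to_quadrature(iq)
  interior <- 20:70
  # each branch carries half-amplitude with lateral phase +/- 2 pi x / lambda
  for (br in c("pos", "neg")) {
    b <- q[[br]][which.min(abs(z - 2)), interior, 1]
    expect_equal(mean(Mod(b)), 0.5, tolerance = 0.05)
    dph <- Arg(Conj(b[-length(b)]) * b[-1])
    expect_equal(abs(mean(dph)), 2 * pi * 0.05 / 0.25, tolerance = 0.02)
  }
  ph1 <- Arg(q$pos[which.min(abs(z - 2)), interior, 1])
  ph2 <- Arg(q$neg[which.min(abs(z - 2)), interior, 1])
  expect_equal(ph1, -ph2, tolerance = 0.05)
})

test_that("estimator variance decreases with ensemble length", {
  g <- straight_geom()
  cl <- seed_scatterers(g, 2.5e6, 0.3, seed = 12)
  f <- uniform_field(0.04, 0)
  iq <- add_clutter_and_noise(
    simulate_iq_ensemble(cl, f, acq_params(n_frames = 1100), to_enabled = FALSE),
    40, 20, seed = 13)
  inl <- interior_mask()
  vars <- vapply(c(64L, 256L, 1100L), function(nf) {
    sub <- iq_ensemble(iq$data[, , seq_len(nf), drop = FALSE],
                       acq_params(n_frames = nf), iq$z, iq$x)
    vm <- estimate_axial_velocity(svd_clutter_filter(sub, 1))
    stats::var(vm$v_axial[inl])
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})

test_that("loess smoothing reproduces quadratic and constant profiles exactly", {
  x <- seq(-2, 2, by = 0.05)
  z <- seq(0, 1, by = 0.05)
  quad <- outer(rep(1, length(z)), 0.08 * (1 - (x / 2)^2))
  vm <- velocity_map(quad, quad * 0, z, x)
  sm <- loess_smooth(vm, span = 0.10)
  expect_equal(sm$v_axial, quad, tolerance = 1e-8)
  expect_true(sm$smoothing_applied)
  const <- matrix(0.05, length(z), length(x))
  smc <- loess_smooth(velocity_map(const, const * 0, z, x), span = 0.10)
  expect_equal(smc$v_axial, const, tolerance = 1e-8)
})

test_that("loess smoothing reduces noise on parabolic profiles in every seeded trial", {
  x <- seq(-2, 2, by = 0.05)
  clean <- 0.08 * (1 - (x / 2)^2)
  z <- 0:1
  for (s in 1:50) {
    set.seed(s)
    noisy <- clean + stats::rnorm(length(x), sd = 0.1 * max(clean))
    vm <- velocity_map(rbind(noisy, noisy), rbind(noisy, noisy) * 0, z, x)
    sm <- loess_smooth(vm, span = 0.10)
    rmse_in <- sqrt(mean((noisy - clean)^2))
    rmse_out <- sqrt(mean((sm$v_axial[1, ] - clean)^2))
    expect_lt(rmse_out, rmse_in)
  }
})

test_that("profiles shorter than five samples pass through with a warning", {
  x <- seq(0, 0.15, by = 0.05)
  v <- matrix(c(0.01, 0.02, 0.02, 0.01), 1, 4)
  vm <- velocity_map(v, v * 0, z = 1, x = x)
  expect_warning(sm <- loess_smooth(vm, span = 0.10), "fewer than 5")
  expect_equal(sm$v_axial, v)
})
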