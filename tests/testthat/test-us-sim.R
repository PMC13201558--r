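test_that("acquisition defaults derive the axial wavelength and Nyquist velocity", {
  p <- acq_params()
  expect_equal(p$lambda_z, 1480 / 23.44e6 * 1e3, tolerance = 1e-12)
  expect_equal(p$v_nyquist, 1480 * 1e4 / (4 * 23.44e6), tolerance = 1e-12)
  expect_equal(p$v_nyquist, 0.15785, tolerance = 1e-4)
  expect_error(acq_params(fc = 0), "fc")
  expect_error(acq_params(n_frames = 0), "n_frames")
})

test_that("a static scene renders identical frames", {
  g <- straight_geom()
  cl <- seed_scatterers(g, 2e5, 0.3, seed = 3)
  f <- uniform_field(0, 0)
  iq <- simulate_iq_ensemble(cl, f, acq_params(n_frames = 5), to_enabled = FALSE)
  for (k in 2:5)
    expect_equal(iq$data[, , k], iq$data[, , 1], tolerance = 1e-12)
})

test_that("a scatterer at constant axial speed produces the pulse-echo phase shift", {
  # 4 cm/s at 23.44 MHz / 10 kHz: phase per frame = 4 pi fc v / (c PRF)
  g <- straight_geom()
  cl <- structure(list(z = 4, x = 0, amp = complex(real = 1), n = 1L, seed = 1L),
                  class = "scatterer_cloud")
  f <- uniform_field(0.04, 0)
  iq <- simulate_iq_ensemble(cl, f, acq_params(n_frames = 2), to_enabled = FALSE)
  pk <- which(Mod(iq$data[, , 1]) == max(Mod(iq$data[, , 1])), arr.ind = TRUE)[1, ]
  ph <- Arg(Conj(iq$data[pk[1], pk[2], 1]) * iq$data[pk[1], pk[2], 2])
  expected <- 4 * pi * 23.44e6 * 0.04 / (1480 * 1e4)
  expect_equal(expected, 0.796, tolerance = 1e-3)
  expect_equal(abs(ph), expected, tolerance = 0.05 * expected)
})

test_that("transverse oscillation puts symmetric lateral spectral peaks at 1/lambda", {
  g <- straight_geom()
  cl <- seed_scatterers(g, 2.5e6, 0.3, seed = 5)
  iq <- simulate_iq_ensemble(cl, straight_field(), acq_params(n_frames = 1),
                             to_enabled = TRUE)
  row <- iq$data[which.min(abs(iq$z - 4)), , 1]
  nx <- length(row)
  spec <- Mod(stats::fft(row))
  freq <- (seq_len(nx) - 1) / (nx * iq$dx)          # cycles per mm
  half <- freq <= 1 / (2 * iq$dx)
  pk <- freq[half][which.max(spec[half])]
  expect_equal(pk, 1 / 0.25, tolerance = 1 / (nx * iq$dx) / (1 / 0.25))
})

test_that("advection conserves the scatterer count via wrap-around re-entry", {
  g <- straight_geom()
  cl <- seed_scatterers(g, 2e5, 0.3, seed = 6)
  f <- uniform_field(0.08, 0)
  iq <- simulate_iq_ensemble(cl, f, acq_params(n_frames = 50), to_enabled = FALSE)
  # energy per frame stays of the same order: scatterers leaving re-enter
  e <- apply(iq$data, 3, function(m) sum(Mod(m)^2))
  expect_gt(min(e), 0.5 * max(e))
})

test_that("clutter energy matches the stated clutter-to-signal ratio", {
  iq <- small_ensemble()
  iqc <- add_clutter_and_noise(iq, clutter_db = 40, snr_db = Inf, seed = 2)
  e_sig <- sum(Mod(iq$data)^2)
  e_cl <- sum(Mod(iqc$data - iq$data)^2)
  expect_rel_equal(e_cl / e_sig, 1e4, 0.01)
})

test_that("disabled clutter and noise return the input unchanged", {
  iq <- small_ensemble()
  out <- add_clutter_and_noise(iq, clutter_db = -Inf, snr_db = Inf, seed = 2)
  expect_equal(out$data, iq$data, tolerance = 1e-12)
})

test_that("clutter and noise are reproducible for a fixed seed", {
  iq <- small_ensemble()
  a <- add_clutter_and_noise(iq, 40, 20, seed = 9)
  b <- add_clutter_and_noise(iq, 40, 20, seed = 9)
  d <- add_clutter_and_noise(iq, 40, 20, seed = 10)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, d$data))
})

test_that("super-Nyquist velocities raise an aliasing warning recorded in metadata", {
  g <- straight_geom()
  cl <- seed_scatterers(g, 1e5, 0.3, seed = 4)
  f <- uniform_field(0.2, 0)              # > 0.158 m/s Nyquist
  expect_warning(
    iq <- simulate_iq_ensemble(cl, f, acq_params(n_frames = 2), to_enabled = FALSE),
    "Nyquist")
  expect_true(iq$meta$aliasing)
})
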