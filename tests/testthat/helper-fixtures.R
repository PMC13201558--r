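# Shared fixtures, generated in code. Heavy simulations are cached per test
# session so several test files can reuse the same rendered ensemble.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

straight_geom <- function() make_geometry("straight", diameter = 3.2, length = 8)

straight_field <- function() fixture("straight_field",
  analytic_flow_field(straight_geom(), 20, fluid_properties(0.9e-3),
                      dz = 0.05, dx = 0.05))

# noise-free gridded field packaged as a velocity map
field_as_map <- function(field) {
  velocity_map(field$v_axial, field$v_lateral, field$z, field$x,
               low_power = !field$lumen_mask)
}

# uniform-velocity field over the straight lumen, for estimator bias tests
uniform_field <- function(vz, vx) {
  f0 <- straight_field()
  g <- straight_geom()
  flow_field(z = f0$z, x = f0$x,
             v_axial = matrix(vz, length(f0$z), length(f0$x)) * f0$lumen_mask,
             v_lateral = matrix(vx, length(f0$z), length(f0$x)) * f0$lumen_mask,
             lumen_mask = f0$lumen_mask, flow_rate = 0, geom = g)
}

# interior evaluation mask away from walls and ends, matching uniform_field
interior_mask <- function() {
  f0 <- straight_field()
  f0$lumen_mask &
    outer(rep(TRUE, length(f0$z)), abs(f0$x) < 1.1) &
    outer(f0$z > 1 & f0$z < 7, rep(TRUE, length(f0$x)))
}

# a small simulated straight-vessel ensemble shared by doppler tests
small_ensemble <- function() fixture("small_ensemble", {
  g <- straight_geom()
  cl <- seed_scatterers(g, 2.5e6, 0.3, seed = 11)
  iq <- simulate_iq_ensemble(cl, straight_field(), acq_params(n_frames = 128),
                             to_enabled = FALSE)
  iq
})

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
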