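test_that("straight geometry has parallel walls at half the diameter", {
  g <- straight_geom()
  z <- seq(0, 8, by = 0.5)
  w <- geometry_walls(g, z)
  expect_equal(w$upper, rep(1.6, length(z)))
  expect_equal(w$lower, rep(-1.6, length(z)))
  expect_equal(geometry_radius(g, z), rep(1.6, length(z)))
})

test_that("eccentric stenosis narrows only one wall to the stated severity", {
  g <- make_geometry("stenotic", diameter = 3.2, length = 8,
                     stenosis_severity = 0.55, stenosis_length = 4,
                     stenosis_center = 4, eccentric = TRUE)
  w <- geometry_walls(g, c(0, 4, 8))
  # lower wall untouched; upper wall dips by severity * diameter at the throat
  expect_equal(w$lower, rep(-1.6, 3))
  expect_equal(w$upper[c(1, 3)], c(1.6, 1.6))
  expect_equal(w$upper[2], 1.6 - 0.55 * 3.2)
  expect_equal(geometry_radius(g, 4), 1.6 * (1 - 0.55))
})

test_that("geometry constructor rejects invalid severity and malapposition", {
  expect_error(make_geometry("stenotic", stenosis_severity = 1.0), "severity")
  expect_error(make_geometry("stenotic", stenosis_severity = -0.1), "severity")
  expect_error(make_geometry("straight", diameter = 3.2,
                             malapposition_offset = 1.7), "malapposition")
  expect_error(make_geometry("straight", diameter = 0), "diameter")
})

test_that("Poiseuille field peaks at 2Q/(pi R^2) and vanishes at the walls", {
  f <- straight_field()
  q_si <- 20 * 1e-6 / 60
  vmax <- 2 * q_si / (pi * (1.6e-3)^2)
  expect_rel_equal(max(f$v_axial), vmax, 1e-3)
  # no-slip: zero at and outside the walls
  outside <- abs(outer(rep(1, length(f$z)), f$x)) >= 1.6
  expect_true(all(f$v_axial[outside] == 0))
  expect_true(all(f$v_lateral == 0))
})

test_that("axial flux of the analytic field recovers the volumetric rate", {
  # planar sampling of the axisymmetric profile integrates to Q within the
  # discretization error of the 0.05 mm grid
  f <- straight_field()
  expect_rel_equal(axial_flux(f), 20, 0.01)
})

test_that("analytic wall shear equals 4 mu Q / (pi R^3) on the straight tube", {
  g <- straight_geom()
  ref <- analytic_wall_shear(g, 20, fluid_properties(0.9e-3))
  q_si <- 20 * 1e-6 / 60
  tau <- 4 * 0.9e-3 * q_si / (pi * (1.6e-3)^3)
  expect_true(all(abs(ref$wss_pa / tau - 1) < 1e-6))
  expect_equal(tau, 0.0933, tolerance = 1e-3)
})

test_that("stenotic throat wall shear scales as 1/r^3 in the quasi-1D model", {
  g <- make_geometry("stenotic", diameter = 3.2, length = 8,
                     stenosis_severity = 0.55, stenosis_length = 4,
                     stenosis_center = 4, eccentric = FALSE)
  ref <- analytic_wall_shear(g, 6, fluid_properties(0.9e-3))
  q_si <- 6 * 1e-6 / 60
  r_throat <- 1.6e-3 * (1 - 0.55)
  tau <- 4 * 0.9e-3 * q_si / (pi * r_throat^3)
  at_throat <- ref$wss_pa[which.min(abs(ref$z_mm - 4))]
  expect_rel_equal(at_throat, tau, 0.02)
})

test_that("scatterer seeding converts concentration to a planar count", {
  g <- straight_geom()
  cl <- seed_scatterers(g, 2.5e6, 0.3, seed = 1)
  # count = concentration * lumen area * slice thickness (per-mL -> per mm^3)
  expect_equal(cl$n, round(2.5e6 * (3.2 * 8) * 0.3 / 1000))
  w <- geometry_walls(g, cl$z)
  expect_true(all(cl$x > w$lower & cl$x < w$upper))
})

test_that("scatterer seeding is reproducible and degenerates gracefully", {
  g <- straight_geom()
  a <- seed_scatterers(g, 1e5, 0.3, seed = 7)
  b <- seed_scatterers(g, 1e5, 0.3, seed = 7)
  expect_identical(a$z, b$z)
  expect_identical(a$amp, b$amp)
  expect_false(identical(a$z, seed_scatterers(g, 1e5, 0.3, seed = 8)$z))
  expect_equal(seed_scatterers(g, 0, 0.3, seed = 1)$n, 0L)
})

test_that("finite-difference oracle agrees with the closed form on Poiseuille", {
  g <- straight_geom()
  f <- straight_field()
  ct <- contour_from_geometry(g, seq(1, 7, by = 0.1))
  fd <- fd_wss_oracle(f, ct, fluid_properties(0.9e-3))
  expect_true(all(abs(fd$wss_pa / 0.093255 - 1) < 0.01))
})

test_that("wake shielding reduces analytic upper-wall shear at the strut pitch", {
  g <- make_geometry("straight", diameter = 3.2, length = 8,
                     malapposition_offset = 0.8)
  ref <- analytic_wall_shear(g, 20, fluid_properties(0.9e-3))
  up <- ref[ref$wall_id == "upper", ]
  lo <- ref[ref$wall_id == "lower", ]
  mid <- up$z_mm > 2.5 & up$z_mm < 5.5
  tau <- 4 * 0.9e-3 * (20 * 1e-6 / 60) / (pi * (1.6e-3)^3)
  # shielded upper wall drops below the unshielded value; lower wall untouched
  expect_lt(mean(up$wss_pa[mid]), 0.8 * tau)
  expect_true(all(abs(lo$wss_pa / tau - 1) < 1e-9))
  # oscillation at the strut pitch: minima well below maxima inside the extent
  expect_lt(min(up$wss_pa[mid]), 0.35 * max(up$wss_pa[mid]))
})
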