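#' Construct a gridded 2D flow field
#'
#' Container for a steady velocity field sampled on the imaging plane through
#' the vessel axis. Rows of the velocity matrices index the axial coordinate
#' `z`, columns the lateral coordinate `x` (both in mm); velocities are in m/s
#' and are zero outside the lumen mask.
#'
#' @param z,x Axial and lateral sample positions, mm (equally spaced).
#' @param v_axial,v_lateral Velocity component matrices, m/s,
#'   `length(z)` x `length(x)`.
#' @param lumen_mask Logical matrix of the same shape.
#' @param flow_rate Volumetric rate, mL/min.
#' @param geom Optional `vessel_geometry` the field was built from.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(z, x, v_axial, v_lateral, lumen_mask, flow_rate,
                       geom = NULL) {
  stopifnot(is.matrix(v_axial), is.matrix(v_lateral), is.matrix(lumen_mask),
            nrow(v_axial) == length(z), ncol(v_axial) == length(x),
            all(dim(v_lateral) == dim(v_axial)),
            all(dim(lumen_mask) == dim(v_axial)))
  v_axial[!lumen_mask] <- 0
  v_lateral[!lumen_mask] <- 0
  structure(list(z = z, x = x,
                 dz = if (length(z) > 1) z[2] - z[1] else NA_real_,
                 dx = if (length(x) > 1) x[2] - x[1] else NA_real_,
                 v_axial = v_axial, v_lateral = v_lateral,
                 lumen_mask = lumen_mask, flow_rate = flow_rate,
                 geom = geom),
            class = "flow_field")
}

#' Analytic steady flow field for a vessel geometry
#'
#' Builds the ground-truth velocity field on the diametral imaging plane.
#' For a straight tube this is the plane sampling of axisymmetric
#' Hagen--Poiseuille flow: a parabolic axial profile with peak
#' `v_max = 2 Q / (pi R^2)`. For a stenotic tube a quasi-1D mass-conserving
#' model is used: at each axial station the local radius `r(z)` defines a
#' locally parabolic profile with `v_max(z) = 2 Q / (pi r(z)^2)` about the
#' local centerline, and the lateral component follows from 2D continuity on
#' the plane (with a linear correction enforcing no-slip at both walls). The
#' quasi-1D field is an approximation, not an exact Navier--Stokes solution.
#'
#' Malapposed struts (when `geom$malapposition_offset > 0`) damp the velocity
#' in the strut-to-wall gap band by a smooth periodic wake-shielding factor
#' `1 - A(z) h(d/g)` (d = distance from the upper wall, g = gap width),
#' emulating the flow shadowing behind free-standing struts; the wall shear on
#' the malapposed wall is thereby reduced by the factor `1 - A(z)`.
#'
#' @param geom A `vessel_geometry`.
#' @param flow_rate Volumetric flow rate, mL/min.
#' @param fluid A `fluid_properties` (carried along for downstream stress use).
#' @param dz,dx Grid spacings, mm.
#' @param lateral_margin Extra lateral extent beyond the widest lumen on each
#'   side, mm.
#' @return A `flow_field`.
#' @examples
#' g <- make_geometry("straight", diameter = 3.2, length = 8)
#' f <- analytic_flow_field(g, flow_rate = 20, dz = 0.1, dx = 0.05)
#' max(f$v_axial)  # ~0.0829 m/s
#' @export
analytic_flow_field <- function(geom, flow_rate = 20, fluid = fluid_properties(),
                                dz = 0.05, dx = 0.05, lateral_margin = 0.6) {
  stopifnot(inherits(geom, "vessel_geometry"))
  if (flow_rate < 0) stop("`flow_rate` must be nonnegative (mL/min)")
  if (geom$diameter / dx < 8)
    stop("grid too coarse: fewer than 8 lateral samples across the diameter")
  z <- seq(0, geom$length, by = dz)
  half_span <- geom$diameter / 2 + lateral_margin
  x <- seq(-half_span, half_span, by = dx)
  nz <- length(z); nx <- length(x)

  walls <- geometry_walls(geom, z)
  xu <- walls$upper; xl <- walls$lower
  r_mm <- (xu - xl) / 2
  xc <- (xu + xl) / 2
  q_si <- flow_rate * 1e-6 / 60                  # mL/min -> m^3/s
  vmax <- 2 * q_si / (pi * (r_mm * 1e-3)^2)      # m/s, per axial station

  xm <- matrix(x, nz, nx, byrow = TRUE)
  xu_m <- matrix(xu, nz, nx); xl_m <- matrix(xl, nz, nx)
  xc_m <- matrix(xc, nz, nx); r_m <- matrix(r_mm, nz, nx)
  lumen <- xm > xl_m & xm < xu_m

  eta <- (xm - xc_m) / r_m
  vz <- matrix(vmax, nz, nx) * (1 - eta^2)
  vz[!lumen] <- 0
  vz[vz < 0] <- 0

  # wake shielding behind malapposed struts (upper side)
  if (geom$malapposition_offset > 0 && flow_rate > 0) {
    amp <- .strut_shielding_amplitude(geom, z)
    g_mm <- geom$malapposition_offset
    d <- xu_m - xm                                # distance from upper wall, mm
    h <- matrix(0, nz, nx)
    in_gap <- lumen & d >= 0 & d <= g_mm
    h[in_gap] <- 0.5 * (1 + cos(pi * d[in_gap] / g_mm))
    vz <- vz * (1 - matrix(amp, nz, nx) * h)
  }

  # lateral component from 2D continuity dvx/dx = -dvz/dz, integrated from the
  # lower wall, then linearly corrected so vx vanishes at both walls
  vx <- matrix(0, nz, nx)
  if (geom$kind == "stenotic" && flow_rate > 0) {
    dvzdz <- matrix(0, nz, nx)
    dvzdz[2:(nz - 1), ] <- (vz[3:nz, ] - vz[1:(nz - 2), ]) / (2 * dz * 1e-3)
    dvzdz[!lumen] <- 0
    cum <- t(apply(dvzdz, 1, cumsum)) * (dx * 1e-3)   # running integral in x
    vx <- -cum
    vx[!lumen] <- 0
    # value accumulated at the upper wall, per row
    top <- vapply(seq_len(nz), function(i) {
      idx <- which(lumen[i, ])
      if (length(idx)) vx[i, idx[length(idx)]] else 0
    }, numeric(1))
    frac <- (xm - xl_m) / (xu_m - xl_m)
    vx <- vx - matrix(top, nz, nx) * frac
    vx[!lumen] <- 0
  }

  out <- flow_field(z, x, vz, vx, lumen, flow_rate, geom)
  out$fluid <- fluid
  out
}

#' Axial volumetric flux implied by the axisymmetric profile
#'
#' Integrates the diametral axial-velocity profile at one axial station over
#' the circular cross-section implied by the axisymmetric model,
#' `Q = int v(r) 2 pi r dr`, averaging the two half-profiles. Useful to check
#' mass conservation of generated fields.
#'
#' @param field A `flow_field`.
#' @param z_mm Axial station, mm (nearest grid row is used).
#' @return Flux in mL/min.
#' @export
axial_flux <- function(field, z_mm = stats::median(field$z)) {
  stopifnot(inherits(field, "flow_field"))
  i <- which.min(abs(field$z - z_mm))
  v <- field$v_axial[i, ]
  inside <- field$lumen_mask[i, ]
  if (!any(inside)) return(0)
  idx <- which(inside)
  xc <- mean(range(field$x[idx]))
  r <- abs(field$x - xc) * 1e-3                 # m
  dr <- field$dx * 1e-3
  q_si <- sum(v * 2 * pi * r * dr * inside) / 2 # both halves counted once
  q_si * 6e7                                    # m^3/s -> mL/min
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d x %d grid (dz %.3g, dx %.3g mm), Q = %g mL/min, peak |v| = %.3g m/s\n",
              length(x$z), length(x$x), x$dz, x$dx, x$flow_rate,
              max(abs(x$v_axial))))
  invisible(x)
}
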