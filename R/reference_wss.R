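#' Reference wall shear stress container
#'
#' @param df Data frame with columns `wall_id`, `s_mm`, `z_mm`, `x_mm`,
#'   `wss_pa` (magnitude), `wssz_pa`, `wssx_pa` (vector components).
#' @param provenance "analytic" or "finite-difference".
#' @return An object of class `reference_wss`.
#' @export
reference_wss <- function(df, provenance = c("analytic", "finite-difference")) {
  provenance <- match.arg(provenance)
  stopifnot(is.data.frame(df),
            all(c("wall_id", "s_mm", "z_mm", "x_mm", "wss_pa",
                  "wssz_pa", "wssx_pa") %in% names(df)))
  if (any(df$wss_pa < 0)) stop("WSS magnitudes must be nonnegative")
  attr(df, "provenance") <- provenance
  class(df) <- c("reference_wss", "data.frame")
  df
}

#' Closed-form wall shear stress of the analytic flow model
#'
#' For a straight tube, the Hagen--Poiseuille wall shear
#' `tau = 4 mu Q / (pi R^3)`, uniform along both walls. For the quasi-1D
#' stenotic model, `tau(z) = 4 mu Q / (pi r(z)^3)` follows the local radius
#' (a model approximation, not an exact Navier--Stokes solution). Behind
#' malapposed struts the upper-wall shear is additionally reduced by the
#' wake-shielding factor `1 - A(z)` of the flow model. The stress vector is
#' tangential, pointing along the flow direction.
#'
#' @param geom A `vessel_geometry`.
#' @param flow_rate Volumetric rate, mL/min.
#' @param fluid A `fluid_properties`.
#' @param z Axial sample positions, mm (default: 0.1 mm sampling).
#' @param walls Which walls to report.
#' @return A `reference_wss` with provenance "analytic".
#' @examples
#' g <- make_geometry("straight", diameter = 3.2)
#' w <- analytic_wall_shear(g, 20, fluid_properties(mu = 0.9e-3))
#' unique(round(w$wss_pa, 4))  # 0.0933 Pa
#' @export
analytic_wall_shear <- function(geom, flow_rate = 20, fluid = fluid_properties(),
                                z = seq(0, geom$length, by = 0.1),
                                walls = c("both", "upper", "lower")) {
  stopifnot(inherits(geom, "vessel_geometry"), inherits(fluid, "fluid_properties"))
  walls <- match.arg(walls)
  q_si <- flow_rate * 1e-6 / 60
  r_si <- geometry_radius(geom, z) * 1e-3
  tau <- 4 * fluid$mu * q_si / (pi * r_si^3)
  ctr <- contour_from_geometry(geom, z, walls)
  mag <- numeric(nrow(ctr))
  for (i in seq_len(nrow(ctr))) {
    j <- which.min(abs(z - ctr$z[i]))
    m <- tau[j]
    if (ctr$wall_id[i] == "upper" && geom$malapposition_offset > 0)
      m <- m * (1 - .strut_shielding_amplitude(geom, ctr$z[i]))
    mag[i] <- m
  }
  df <- data.frame(wall_id = ctr$wall_id, s_mm = ctr$s, z_mm = ctr$z,
                   x_mm = ctr$x,
                   wss_pa = mag,
                   wssz_pa = mag * ctr$tz,
                   wssx_pa = mag * ctr$tx)
  reference_wss(df, "analytic")
}

#' Finite-difference wall shear stress oracle
#'
#' Independent brute-force evaluation of the wall stress from a gridded
#' velocity field: the full velocity-gradient tensor is computed on the grid
#' by centered finite differences, sampled (bilinearly) at two and three grid
#' steps inside the wall along the inward normal, linearly extrapolated to the
#' wall (exact for quadratic velocity profiles). Sampling starts two steps
#' inside so that no node feeding the interpolation sits within one cell of
#' the wall, where centered stencils straddle the zero-filled exterior and
#' understate the gradient. The tensor is assembled into the deviatoric
#' stress `sigma = -mu (grad u + grad u^T)` and projected tangentially,
#' `WSS = sigma n - (n . sigma n) n`. Intended as a check of the
#' pseudo-spectral estimator on noise-free fields.
#'
#' @param field A `flow_field` (noise-free).
#' @param contour A `wall_contour` consistent with the field's lumen.
#' @param fluid A `fluid_properties`.
#' @param step Inward sampling distance, mm (default: one grid step).
#' @return A `reference_wss` with provenance "finite-difference".
#' @export
fd_wss_oracle <- function(field, contour, fluid = field$fluid, step = NULL) {
  stopifnot(inherits(field, "flow_field"), inherits(contour, "wall_contour"))
  if (is.null(fluid)) fluid <- fluid_properties()
  h <- if (is.null(step)) max(field$dz, field$dx) else step
  dz_m <- field$dz * 1e-3; dx_m <- field$dx * 1e-3
  Gzz <- .grad_z(field$v_axial, dz_m)
  Gzx <- .grad_x(field$v_axial, dx_m)
  Gxz <- .grad_z(field$v_lateral, dz_m)
  Gxx <- .grad_x(field$v_lateral, dx_m)

  inside <- function(zq, xq) {
    zq >= min(field$z) & zq <= max(field$z) & xq >= min(field$x) & xq <= max(field$x)
  }
  n <- nrow(contour)
  out <- data.frame(wall_id = contour$wall_id, s_mm = contour$s,
                    z_mm = contour$z, x_mm = contour$x,
                    wss_pa = NA_real_, wssz_pa = NA_real_, wssx_pa = NA_real_)
  for (i in seq_len(n)) {
    p <- c(contour$z[i], contour$x[i])
    if (!inside(p[1], p[2])) stop("wall point outside the field grid")
    m <- -c(contour$nz[i], contour$nx[i])          # inward unit vector
    p1 <- p + 2 * h * m; p2 <- p + 3 * h * m
    if (!inside(p1[1], p1[2]) || !inside(p2[1], p2[2]))
      stop("wall point too close to the grid border for the oracle stencil")
    g <- function(G) {
      g1 <- .bilinear(G, field$z, field$x, p1[1], p1[2])
      g2 <- .bilinear(G, field$z, field$x, p2[1], p2[2])
      3 * g1 - 2 * g2                               # linear extrapolation to wall
    }
    G <- matrix(c(g(Gzz), g(Gzx), g(Gxz), g(Gxx)), 2, 2, byrow = TRUE)
    sig <- -fluid$mu * (G + t(G))
    nv <- c(contour$nz[i], contour$nx[i])
    tr <- sig %*% nv
    wss <- tr - sum(nv * tr) * nv
    out$wssz_pa[i] <- wss[1]; out$wssx_pa[i] <- wss[2]
    out$wss_pa[i] <- sqrt(sum(wss^2))
  }
  reference_wss(out, "finite-difference")
}

#' Export a reference or estimated WSS table to CSV
#'
#' @param wss A `reference_wss` or `wss_map`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_wss_csv <- function(wss, path) {
  stopifnot(is.data.frame(wss))
  df <- as.data.frame(wss)
  names(df)[names(df) == "shear_rate"] <- "shear_rate_s-1"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
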