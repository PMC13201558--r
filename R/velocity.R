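#' Velocity map container
#'
#' Estimated axial/lateral velocity images. Pixels flagged low-power carry
#' zero velocity; `smoothing_applied` records whether [loess_smooth()] was
#' run.
#'
#' @param v_axial,v_lateral Velocity matrices, m/s (rows = depth, cols =
#'   lateral).
#' @param z,x Pixel positions, mm.
#' @param power Mean signal power per pixel (linear units).
#' @param low_power Logical matrix flagging pixels below the power mask.
#' @param params The `acq_params` used for estimation.
#' @param smoothing_applied Logical.
#' @param span Loess span actually applied (NA when unsmoothed).
#' @return An object of class `velocity_map`.
#' @export
velocity_map <- function(v_axial, v_lateral, z, x, power = NULL,
                         low_power = NULL, params = NULL,
                         smoothing_applied = FALSE, span = NA_real_) {
  stopifnot(is.matrix(v_axial), all(dim(v_lateral) == dim(v_axial)))
  if (is.null(low_power)) low_power <- matrix(FALSE, nrow(v_axial), ncol(v_axial))
  structure(list(v_axial = v_axial, v_lateral = v_lateral, z = z, x = x,
                 dz = if (length(z) > 1) z[2] - z[1] else NA_real_,
                 dx = if (length(x) > 1) x[2] - x[1] else NA_real_,
                 power = power, low_power = low_power, params = params,
                 smoothing_applied = isTRUE(smoothing_applied), span = span),
            class = "velocity_map")
}

# lag-one temporal autocorrelation and mean power of a complex cube,
# accumulated in frame blocks to bound memory
.lag_one_stats <- function(cube, block = 256L) {
  d <- dim(cube)
  n_pix <- d[1] * d[2]; nt <- d[3]
  M <- matrix(cube, n_pix, nt)
  r1 <- complex(n_pix)
  pw <- numeric(n_pix)
  t0 <- 1L
  while (t0 < nt) {
    t1 <- min(t0 + block, nt)
    a <- M[, t0:(t1 - 1L), drop = FALSE]
    b <- M[, (t0 + 1L):t1, drop = FALSE]
    r1 <- r1 + rowSums(Conj(a) * b)
    t0 <- t1
  }
  for (t0 in seq(1L, nt, by = block)) {
    t1 <- min(t0 + block - 1L, nt)
    pw <- pw + rowSums(Mod(M[, t0:t1, drop = FALSE])^2)
  }
  list(r1 = r1 / (nt - 1L), power = pw / nt,
       dims = d[1:2])
}

# power-mask threshold: `mask_db` decibels below the median pixel power
.power_threshold <- function(power, mask_db) {
  stats::median(power[power > 0]) * 10^(-mask_db / 10)
}

#' Axial velocity by first-order (lag-one) autocorrelation
#'
#' Per pixel, the lag-one temporal autocorrelation `R(1)` over the full
#' ensemble gives the axial velocity
#' `v = -c * frame_rate * arg(R(1)) / (4 pi fc)`, positive along increasing
#' depth (the +z axis of the simulated flow field); magnitudes are bounded by
#' the Nyquist velocity `c * frame_rate / (4 fc)`. Pixels whose mean power
#' falls `power_mask_db` below the median pixel power are flagged low-power
#' and set to zero velocity.
#'
#' @param iq An `iq_ensemble` with at least 2 frames.
#' @param power_mask_db Low-power mask depth, dB.
#' @return A `velocity_map` with the axial component filled (lateral zero).
#' @export
estimate_axial_velocity <- function(iq, power_mask_db = 20) {
  stopifnot(inherits(iq, "iq_ensemble"))
  if (dim(iq$data)[3] < 2) stop("need at least 2 frames")
  p <- iq$params
  st <- .lag_one_stats(iq$data)
  v <- -p$c * p$frame_rate * Arg(st$r1) / (4 * pi * p$fc)
  v <- matrix(v, st$dims[1], st$dims[2])
  pw <- matrix(st$power, st$dims[1], st$dims[2])
  low <- pw < .power_threshold(pw, power_mask_db)
  v[low] <- 0
  velocity_map(v, matrix(0, nrow(v), ncol(v)), iq$z, iq$x,
               power = pw, low_power = low, params = p)
}

#' Lateral velocity by the transverse-oscillation branch-phase estimator
#'
#' Implements the TO phase-based vector estimator: the lag-one
#' autocorrelations `r+` and `r-` of the two lateral-quadrature branches are
#' combined so that the branch-phase difference isolates the lateral
#' oscillation (the shared axial carrier cancels):
#' `phi_lat = arg(r+ conj(r-))` and
#' `v_lat = -lambda_lat * frame_rate * phi_lat / (4 pi)`. The estimate is
#' unbiased for pure lateral motion and insensitive to simultaneous axial
#' motion up to the Nyquist limit.
#'
#' @param quad A `to_quadrature` pair from [make_to_quadrature()].
#' @param power_mask_db Low-power mask depth, dB (applied on the summed
#'   branch power).
#' @return A `velocity_map` with the lateral component filled (axial zero).
#' @export
estimate_lateral_velocity <- function(quad, power_mask_db = 20) {
  stopifnot(inherits(quad, "to_quadrature"))
  p <- quad$params
  sp <- .lag_one_stats(quad$pos)
  sn <- .lag_one_stats(quad$neg)
  phi <- Arg(sp$r1 * Conj(sn$r1))
  v <- -(p$lambda_lat * 1e-3) * p$frame_rate * phi / (4 * pi)
  v <- matrix(v, sp$dims[1], sp$dims[2])
  pw <- matrix(sp$power + sn$power, sp$dims[1], sp$dims[2])
  low <- pw < .power_threshold(pw, power_mask_db)
  v[low] <- 0
  velocity_map(matrix(0, nrow(v), ncol(v)), v, quad$z, quad$x,
               power = pw, low_power = low, params = p)
}

#' Full vector velocity estimation
#'
#' Convenience chain: axial component from the first-order autocorrelation of
#' the ordinary (fine lateral resolution) ensemble, lateral component from
#' the transverse-oscillation quadrature pair of the TO ensemble, merged into
#' one map with a common low-power mask. When only one ensemble is given it
#' serves both roles (it must then be TO-modulated).
#'
#' @param iq A (clutter-filtered) `iq_ensemble` for axial estimation.
#' @param iq_to A (clutter-filtered) TO-modulated `iq_ensemble` of the same
#'   acquisition for lateral estimation; defaults to `iq`.
#' @param power_mask_db Low-power mask depth, dB.
#' @return A `velocity_map` with both components.
#' @export
estimate_velocity <- function(iq, iq_to = iq, power_mask_db = 20) {
  ax <- estimate_axial_velocity(iq, power_mask_db)
  quad <- make_to_quadrature(iq_to)
  lat <- estimate_lateral_velocity(quad, power_mask_db)
  if (!all(dim(lat$v_lateral) == dim(ax$v_axial)))
    stop("`iq` and `iq_to` must share the same pixel grid")
  low <- ax$low_power | lat$low_power
  va <- ax$v_axial; vl <- lat$v_lateral
  va[low] <- 0; vl[low] <- 0
  velocity_map(va, vl, iq$z, iq$x, power = ax$power, low_power = low,
               params = iq$params)
}

#' @export
print.velocity_map <- function(x, ...) {
  cat(sprintf("<velocity_map> %d x %d (dz %.3g, dx %.3g mm), peak |v| = %.3g m/s%s\n",
              nrow(x$v_axial), ncol(x$v_axial), x$dz, x$dx,
              max(abs(x$v_axial), abs(x$v_lateral)),
              if (x$smoothing_applied) ", smoothed" else ""))
  invisible(x)
}

#' Export a velocity map to long-format CSV
#'
#' Columns `z_mm, x_mm, vz_mps, vx_mps`.
#' @param map A `velocity_map`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_velocity_csv <- function(map, path) {
  stopifnot(inherits(map, "velocity_map"))
  df <- data.frame(z_mm = rep(map$z, times = length(map$x)),
                   x_mm = rep(map$x, each = length(map$z)),
                   vz_mps = as.vector(map$v_axial),
                   vx_mps = as.vector(map$v_lateral))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
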