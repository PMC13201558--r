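#' Detect lumen wall positions from a velocity map
#'
#' For each depth row, scanning laterally outward from the in-lumen peak of
#' the axial speed, the wall is located where the speed falls to the
#' threshold (the "first zero-velocity value outside of the velocity data"),
#' with the crossing interpolated linearly between the bracketing pixels for
#' sub-pixel localization. Pixel-quantized walls would carry a systematic
#' half-pixel outward bias, which the boundary-derivative stage amplifies
#' strongly. Scanning uses the axial component only: it is the low-noise
#' channel, while transverse-oscillation lateral estimates carry a noise
#' floor that can exceed a near-zero threshold and mask the crossing.
#'
#' The threshold matters because a finite lateral point spread function blurs
#' the no-slip edge: the apparent axial speed directly at the wall is the
#' one-sided Gaussian average of the near-wall profile,
#' `sqrt(2/pi) * sigma * |dv/dn|`, which for a parabolic profile of radius R
#' equals `2 sqrt(2/pi) * sigma / R` of the peak speed. When `blur_sigma` is
#' supplied, that fraction is computed in two passes: a near-zero scan (2% of
#' the robust peak) measures the apparent radius, the radius is corrected for
#' the blur toe (2 sigma), and the final scan uses the resulting fraction, so
#' detection lands at the physical wall rather than at either edge of the
#' blur. Pass an explicit near-zero `zero_threshold` for noise-free gridded
#' fields, which have exact zeros at the wall, or `threshold_frac` to force a
#' fixed fraction of the robust peak speed.
#'
#' @param map A `velocity_map`.
#' @param zero_threshold Absolute speed threshold, m/s.
#' @param threshold_frac Threshold as a fixed fraction of the robust peak
#'   speed (98th percentile of nonzero axial speeds).
#' @param blur_sigma Lateral PSF standard deviation of the map, mm, enabling
#'   the blur-derived threshold. When all three arguments are `NULL`, a
#'   fraction of 0.1 is used.
#' @return A list of class `wall_edges` with data frames `upper` and `lower`
#'   (columns `z`, `x` in mm, sub-pixel) and the threshold used (m/s).
#' @export
detect_wall <- function(map, zero_threshold = NULL, threshold_frac = NULL,
                        blur_sigma = NULL) {
  stopifnot(inherits(map, "velocity_map"))
  speed <- abs(map$v_axial)
  if (all(speed == 0)) stop("empty lumen: velocity map is zero everywhere")
  vref <- stats::quantile(speed[speed > 0], 0.98, names = FALSE)
  thr <- if (!is.null(zero_threshold)) {
    zero_threshold
  } else if (!is.null(threshold_frac)) {
    threshold_frac * vref
  } else if (!is.null(blur_sigma)) {
    e1 <- .scan_edges(speed, map$z, map$x, 0.02 * vref)
    if (is.null(e1$upper) || is.null(e1$lower))
      stop("empty lumen: no rows cross the near-zero threshold")
    zc <- intersect(e1$upper$z, e1$lower$z)
    half <- (e1$upper$x[match(zc, e1$upper$z)] -
               e1$lower$x[match(zc, e1$lower$z)]) / 2
    r_hat <- stats::median(half) - 2 * blur_sigma
    if (r_hat <= 0) stop("lumen narrower than the blur toe: cannot derive a wall threshold")
    min(0.3, max(0.02, 2 * sqrt(2 / pi) * blur_sigma / r_hat)) * vref
  } else {
    0.1 * vref
  }
  out <- .scan_edges(speed, map$z, map$x, thr)
  if (out$skipped > 0)
    warning(sprintf("%d row/wall combinations had no sub-threshold sample and were skipped",
                    out$skipped))
  if (!is.null(blur_sigma) && is.null(zero_threshold) && is.null(threshold_frac)) {
    out$upper <- .refine_edges(out$upper, speed, map$z, map$x, blur_sigma, "upper")
    out$lower <- .refine_edges(out$lower, speed, map$z, map$x, blur_sigma, "lower")
  }
  structure(list(upper = out$upper, lower = out$lower, threshold = thr),
            class = "wall_edges")
}

# refine each detected edge to the zero crossing of the interior profile:
# the samples 2-8 blur sigma inside the wall are uncontaminated by
# partial-volume blur and by the slow-flow suppression of clutter filtering
# (both of which distort the toe amplitude that any threshold rule relies
# on), and a quadratic fit over that band extrapolates exactly to the no-slip
# point for locally parabolic profiles. The extrapolation is iterated as a
# fixed-point update, re-centering the band on the corrected edge each pass:
# where near-wall flow is locally slowed (e.g. in a strut wake) the initial
# threshold crossing can sit well inside the wall, and a single capped
# correction leaves a residual inward bias that the boundary-derivative stage
# amplifies.
.refine_edges <- function(edges, speed, z, x, sigma, wall) {
  if (is.null(edges)) return(edges)
  sgn <- if (wall == "upper") 1 else -1
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$z[k], z)
    for (pass in 1:4) {
      # distance inward from the current edge estimate
      d <- (edges$x[k] - x) * sgn
      band <- d >= 2 * sigma & d <= 8 * sigma
      if (sum(band) < 4) break
      dd <- d[band]; uu <- speed[i, band]
      cf <- tryCatch(stats::lm.fit(cbind(1, dd, dd^2), uu)$coefficients,
                     error = function(e) NULL)
      if (is.null(cf) || any(is.na(cf))) break
      disc <- cf[2]^2 - 4 * cf[3] * cf[1]
      d0 <- if (abs(cf[3]) < 1e-12 || disc < 0) {
        if (abs(cf[2]) > 1e-12) -cf[1] / cf[2] else NA_real_
      } else {
        r <- (-cf[2] + c(1, -1) * sqrt(disc)) / (2 * cf[3])
        r[which.min(abs(r))]
      }
      # accept only small per-pass corrections; larger ones mean the local
      # profile is not parabolic and the crossing estimate is kept
      if (!is.finite(d0) || abs(d0) > 3 * sigma) break
      edges$x[k] <- edges$x[k] - d0 * sgn
      # a sub-sigma correction means the edge already sits at the wall;
      # further passes would only chase the residual near-wall sag left by
      # clutter-filter slow-flow suppression, walking the edge inward
      if (abs(d0) <= sigma) break
    }
  }
  edges
}

# outward scan of each depth row for the first sub-threshold sample, with
# linear sub-pixel interpolation of the crossing
.scan_edges <- function(speed, z, x, thr) {
  nz <- nrow(speed); nx <- ncol(speed)
  up <- lo <- vector("list", nz)
  skipped <- 0L
  for (i in seq_len(nz)) {
    row <- speed[i, ]
    # anchor at the peak of a 3-sample running median, so a single spurious
    # high pixel (e.g. smoothing overshoot at the edge of the valid run)
    # cannot pull the anchor out of the lumen
    jmax <- which.max(stats::runmed(row, 3))
    if (row[jmax] <= max(thr, 0) * 2) { skipped <- skipped + 1L; next }
    cross <- function(j_in, j_out) {
      if (row[j_in] <= thr) return(x[j_in])
      x[j_in] + (row[j_in] - thr) / (row[j_in] - row[j_out]) * (x[j_out] - x[j_in])
    }
    ju <- if (jmax < nx) jmax + match(TRUE, row[(jmax + 1):nx] <= thr) else NA
    jl <- if (jmax > 1) jmax - match(TRUE, rev(row[1:(jmax - 1)]) <= thr) else NA
    if (is.na(ju)) { skipped <- skipped + 1L } else
      up[[i]] <- data.frame(z = z[i], x = cross(ju - 1L, ju))
    if (is.na(jl)) { skipped <- skipped + 1L } else
      lo[[i]] <- data.frame(z = z[i], x = cross(jl + 1L, jl))
  }
  list(upper = do.call(rbind, up[!vapply(up, is.null, TRUE)]),
       lower = do.call(rbind, lo[!vapply(lo, is.null, TRUE)]),
       skipped = skipped)
}

#' Fit smooth wall contours to raw edge pixels
#'
#' Sliding locally weighted quadratic least-squares fit of the wall curve
#' `x(z)`: at each edge point, the `window` nearest edge pixels (by axial
#' distance) are fit with a 2nd-degree polynomial under tri-cube weights, a
#' robust way to suppress the effect of clutter and noise at the wall. Wall
#' tangents come from the fitted derivative; normals are oriented out of the
#' lumen. Degenerate windows (collinear in `z`) fall back to a linear fit and
#' are flagged.
#'
#' @param edges A `wall_edges` list from [detect_wall()], or a data frame
#'   with columns `wall_id`, `z`, `x`.
#' @param window_frac Window size as a fraction of the edge-pixel count.
#' @param min_window Minimum window size, points.
#' @return A `wall_contour` with local quadratic coefficients (`quad_a`,
#'   `quad_b`, `quad_c` for the centered fit `a + b dz + c dz^2`) and a
#'   `flag` column marking linear fallbacks.
#' @export
fit_wall_contour <- function(edges, window_frac = 0.15, min_window = 5) {
  df <- if (inherits(edges, "wall_edges")) {
    rbind(if (!is.null(edges$upper)) cbind(wall_id = "upper", edges$upper),
          if (!is.null(edges$lower)) cbind(wall_id = "lower", edges$lower))
  } else edges
  stopifnot(is.data.frame(df), all(c("wall_id", "z", "x") %in% names(df)))
  out <- list()
  for (w in unique(df$wall_id)) {
    pts <- df[df$wall_id == w, , drop = FALSE]
    pts <- pts[order(pts$z), , drop = FALSE]
    n <- nrow(pts)
    if (n < 5) stop(sprintf("need at least 5 edge pixels on the %s wall", w))
    win <- max(min_window, ceiling(window_frac * n))
    fit <- .local_quad_fit(pts$z, pts$x, win)
    tn <- sqrt(1 + fit$slope^2)
    tz <- 1 / tn; tx <- fit$slope / tn
    if (w == "upper") { nzv <- -tx; nxv <- tz } else { nzv <- tx; nxv <- -tz }
    out[[w]] <- data.frame(wall_id = w, z = pts$z, x = fit$value,
                           tz = tz, tx = tx, nz = nzv, nx = nxv,
                           quad_a = fit$a, quad_b = fit$b, quad_c = fit$c,
                           flag = fit$flag)
  }
  wall_contour(do.call(rbind, out))
}

# locally weighted quadratic fit of y(z) at each sample; tri-cube weights on
# axial distance within the window of the `win` nearest points
.local_quad_fit <- function(z, y, win) {
  n <- length(z)
  value <- slope <- a <- b <- cc <- numeric(n)
  flag <- logical(n)
  for (i in seq_len(n)) {
    d <- abs(z - z[i])
    idx <- order(d)[seq_len(min(win, n))]
    dz <- z[idx] - z[i]
    h <- max(abs(dz))
    wgt <- if (h > 0) (1 - pmin(abs(dz) / h, 1)^3)^3 else rep(1, length(dz))
    wgt[wgt <= 0] <- 1e-6
    X <- cbind(1, dz, dz^2)
    ok_quad <- length(unique(dz)) >= 3
    cf <- NULL
    if (ok_quad) {
      cf <- tryCatch(stats::lm.wfit(X, y[idx], wgt)$coefficients,
                     error = function(e) NULL)
      if (!is.null(cf) && any(is.na(cf))) cf <- NULL
    }
    if (is.null(cf)) {
      lf <- stats::lm.wfit(cbind(1, dz), y[idx], wgt)$coefficients
      cf <- c(lf[1], lf[2], 0)
      flag[i] <- TRUE
    }
    a[i] <- cf[1]; b[i] <- cf[2]; cc[i] <- cf[3]
    value[i] <- cf[1]
    slope[i] <- cf[2]
  }
  list(value = value, slope = slope, a = a, b = b, c = cc, flag = flag)
}
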