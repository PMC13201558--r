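#' Loess smoothing of velocity profiles
#'
#' Applies local quadratic regression with tri-cubic weights (loess) along
#' each lateral velocity profile, using the given data span. Smoothing acts
#' on the contiguous run of above-power-mask pixels in each depth row (the
#' lumen and its immediate blur margin); masked pixels stay zero. Profiles
#' with fewer than 5 usable samples are passed through unchanged (with a
#' single warning summarizing the skipped rows).
#'
#' A degree-2 local fit reproduces quadratic profiles exactly, so parabolic
#' (Poiseuille-like) profiles are not biased by the smoother.
#'
#' @param map A `velocity_map`.
#' @param span Fraction of profile samples in each local fit, in (0, 1].
#' @return A smoothed `velocity_map` with `smoothing_applied = TRUE`.
#' @export
loess_smooth <- function(map, span = 0.10) {
  stopifnot(inherits(map, "velocity_map"))
  if (span <= 0 || span > 1) stop("`span` must lie in (0, 1]")
  va <- map$v_axial; vl <- map$v_lateral
  nz <- nrow(va)
  skipped <- 0L
  for (i in seq_len(nz)) {
    usable <- if (is.null(map$low_power)) rep(TRUE, ncol(va)) else !map$low_power[i, ]
    idx <- .main_run(usable)
    if (length(idx) == 0) next
    if (length(idx) < 5) { skipped <- skipped + 1L; next }
    xx <- map$x[idx]
    eff_span <- max(span, min(1, 5 / length(idx)))
    va[i, idx] <- .loess_profile(xx, va[i, idx], eff_span)
    vl[i, idx] <- .loess_profile(xx, vl[i, idx], eff_span)
  }
  if (skipped > 0)
    warning(sprintf("%d profiles had fewer than 5 samples and were passed through", skipped))
  velocity_map(va, vl, map$z, map$x, power = map$power,
               low_power = map$low_power, params = map$params,
               smoothing_applied = TRUE, span = span)
}

.loess_profile <- function(x, y, span) {
  # loess emits "NaNs produced" from its approximate standard-error
  # bookkeeping on short profiles; the predictions are unaffected and the
  # standard errors are never used, so that specific warning is muffled
  out <- withCallingHandlers(
    {
      fit <- stats::loess(y ~ x, span = span, degree = 2, family = "gaussian",
                          surface = "direct",
                          control = stats::loess.control(iterations = 1))
      as.numeric(stats::predict(fit, newdata = data.frame(x = x)))
    },
    warning = function(w) {
      if (grepl("NaNs produced", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  bad <- !is.finite(out)
  out[bad] <- y[bad]
  out
}
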