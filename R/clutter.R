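#' Add static tissue clutter and white noise to an IQ ensemble
#'
#' The clutter model is a frame-constant, spatially smooth complex image
#' (white complex Gaussian field low-pass filtered with a Gaussian kernel)
#' added identically to every frame, hence exactly rank one in time; its total
#' ensemble energy is scaled to `clutter_db` decibels above the blood-signal
#' energy of the input. White circular complex Gaussian noise is then added at
#' `snr_db` decibels below the blood-signal energy.
#'
#' @param iq An `iq_ensemble`.
#' @param clutter_db Clutter-to-signal energy ratio, dB (`-Inf` disables).
#' @param snr_db Signal-to-noise energy ratio, dB (`Inf` disables).
#' @param seed RNG seed.
#' @param smooth_sigma Clutter correlation length, pixels.
#' @return An `iq_ensemble` with `meta$clutter_db` and `meta$snr_db` recorded.
#' @export
add_clutter_and_noise <- function(iq, clutter_db = 40, snr_db = 20, seed = 1L,
                                  smooth_sigma = 8) {
  stopifnot(inherits(iq, "iq_ensemble"))
  d <- dim(iq$data)
  nz <- d[1]; nx <- d[2]; nt <- d[3]
  e_sig <- .iq_energy(iq)
  if (e_sig == 0 && (is.finite(clutter_db) || is.finite(snr_db)))
    stop("cannot scale clutter or noise relative to an all-zero blood signal")
  out <- iq$data
  rng <- .seeded_rng(seed)
  on.exit(rng$restore())
  if (is.finite(clutter_db)) {
    base <- matrix(complex(real = stats::rnorm(nz * nx),
                           imaginary = stats::rnorm(nz * nx)), nz, nx)
    cl <- .gauss_smooth2d(base, smooth_sigma)
    target <- e_sig * 10^(clutter_db / 10)          # total over all frames
    cl <- cl * sqrt(target / (nt * sum(Mod(cl)^2)))
    out <- out + array(rep(cl, nt), dim = d)
  }
  if (is.finite(snr_db)) {
    e_noise <- e_sig * 10^(-snr_db / 10)
    sd <- sqrt(e_noise / (2 * prod(d)))
    out <- out + array(complex(real = stats::rnorm(prod(d), sd = sd),
                               imaginary = stats::rnorm(prod(d), sd = sd)),
                       dim = d)
  }
  meta <- iq$meta
  meta$clutter_db <- clutter_db
  meta$snr_db <- snr_db
  meta$noise_seed <- seed
  iq_ensemble(out, iq$params, iq$z, iq$x, meta)
}

# separable Gaussian smoothing of a complex matrix (reflective edges)
.gauss_smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    padded <- c(rev(v[seq_len(min(r, n))]), v, rev(v[seq.int(max(1, n - r + 1), n)]))
    stats::filter(padded, k, sides = 2)[(r + 1):(r + n)]
  }
  re <- apply(Re(m), 2, smooth1); re <- t(apply(re, 1, smooth1))
  im <- apply(Im(m), 2, smooth1); im <- t(apply(im, 1, smooth1))
  matrix(complex(real = re, imaginary = im), nrow(m), ncol(m))
}
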