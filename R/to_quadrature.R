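#' Lateral spatial-quadrature pair for transverse-oscillation velocimetry
#'
#' Splits the lateral spatial spectrum of each depth/frame line at zero
#' frequency (lateral analytic-signal construction): the positive-frequency
#' branch and the negative-frequency branch, with the DC (and Nyquist) bin
#' shared equally. For a TO-modulated field with lateral wavelength
#' `lambda_lat` the two branch phases advance as `-/+ 2 pi x_s / lambda_lat`
#' with scatterer position, so their lag-one autocorrelation phases carry the
#' lateral motion with opposite signs while sharing the axial carrier phase.
#'
#' @param iq An `iq_ensemble` whose acquisition parameters define
#'   `lambda_lat`.
#' @return A list of class `to_quadrature` with complex cubes `pos` and
#'   `neg` (same dimensions as the input) and the acquisition parameters.
#' @export
make_to_quadrature <- function(iq) {
  stopifnot(inherits(iq, "iq_ensemble"))
  if (is.na(iq$params$lambda_lat))
    stop("acquisition metadata lacks `lambda_lat`; transverse oscillation undefined")
  d <- dim(iq$data)
  nz <- d[1]; nx <- d[2]; nt <- d[3]
  if ((nx - 1) * iq$dx < 4 * iq$params$lambda_lat)
    stop("lateral extent must be at least 4 lateral wavelengths")
  # lateral dimension first, all (depth, frame) lines as columns
  m <- matrix(aperm(iq$data, c(2, 1, 3)), nx, nz * nt)
  F <- stats::mvfft(m)
  wpos <- numeric(nx)
  if (nx %% 2 == 0) {
    wpos[1] <- 0.5
    wpos[2:(nx / 2)] <- 1
    wpos[nx / 2 + 1] <- 0.5
  } else {
    wpos[1] <- 0.5
    wpos[2:((nx + 1) / 2)] <- 1
  }
  wneg <- 1 - wpos
  pos <- stats::mvfft(F * wpos, inverse = TRUE) / nx
  neg <- stats::mvfft(F * wneg, inverse = TRUE) / nx
  reshape <- function(m) aperm(array(m, dim = c(nx, nz, nt)), c(2, 1, 3))
  structure(list(pos = reshape(pos), neg = reshape(neg),
                 params = iq$params, z = iq$z, x = iq$x,
                 dz = iq$dz, dx = iq$dx),
            class = "to_quadrature")
}
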