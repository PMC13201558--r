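#' Ultrafast acquisition parameters
#'
#' Parameters of the compounded plane-wave acquisition the simulator emulates.
#' Defaults reproduce a high-frequency coronary-scale protocol: 23.44 MHz
#' center frequency, 2-cycle pulses, 10,000 compounded frames per second and
#' 1100-frame ensembles. The simulator emits already-compounded baseband IQ,
#' so the per-angle transmit sequence is not represented.
#'
#' Two receive beamformations of the same acquisition are modeled, as in
#' practice: an ordinary one with the diffraction-limited lateral resolution
#' (`sigma_lat`, default 0.05 mm, i.e. a lateral FWHM of about two
#' wavelengths at 23.44 MHz) used for axial velocity estimation and wall
#' work, and a transverse-oscillation (TO) one whose two-lobed apodization
#' yields a wider oscillating lateral point spread function (`sigma_to`,
#' default 0.1 mm, envelope of the `lambda_lat` = 0.25 mm oscillation) used
#' for lateral velocity estimation. The TO envelope must span the lateral
#' oscillation for the two spectral lobes at +/- 1/lambda_lat to separate;
#' the fine beamformation must not, or the blur it adds would corrupt the
#' near-wall velocity gradients.
#'
#' @param fc Center frequency, Hz.
#' @param n_cycles Pulse length in cycles.
#' @param c Speed of sound, m/s.
#' @param frame_rate Compounded frame rate, frames/s.
#' @param n_frames Ensemble length.
#' @param lambda_lat TO lateral wavelength, mm (`NA` disables TO).
#' @param sigma_lat Lateral Gaussian PSF standard deviation of the ordinary
#'   beamformation, mm.
#' @param sigma_to Lateral Gaussian envelope standard deviation of the TO
#'   beamformation, mm.
#' @return An object of class `acq_params`, with derived fields `lambda_z`
#'   (axial wavelength, mm) and `v_nyquist` (axial Nyquist velocity
#'   `c * frame_rate / (4 fc)`, m/s).
#' @examples
#' p <- acq_params()
#' p$v_nyquist  # ~0.158 m/s
#' @export
acq_params <- function(fc = 23.44e6, n_cycles = 2, c = 1480,
                       frame_rate = 1e4, n_frames = 1100,
                       lambda_lat = 0.25, sigma_lat = 0.05, sigma_to = 0.1) {
  stopifnot(fc > 0, n_cycles > 0, c > 0, frame_rate > 0, n_frames >= 1,
            sigma_lat > 0, sigma_to > 0)
  if (!is.na(lambda_lat) && lambda_lat <= 0) stop("`lambda_lat` must be positive or NA")
  lambda_z <- c / fc * 1e3                   # mm
  structure(list(fc = fc, n_cycles = n_cycles, c = c,
                 frame_rate = frame_rate, n_frames = as.integer(n_frames),
                 lambda_lat = lambda_lat, sigma_lat = sigma_lat,
                 sigma_to = sigma_to,
                 lambda_z = lambda_z,
                 sigma_z = n_cycles * lambda_z / (2 * sqrt(2 * log(2))),
                 v_nyquist = c * frame_rate / (4 * fc)),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("<acq_params> fc %.4g MHz, %g cycles, %g fps x %d frames, Nyquist %.3g m/s\n",
              x$fc / 1e6, x$n_cycles, x$frame_rate, x$n_frames, x$v_nyquist))
  invisible(x)
}
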