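#' Default pipeline configuration
#'
#' The shipped defaults reproduce the straight-phantom scenario: 3.2 mm lumen
#' with 20 mL/min steady flow, 23.44 MHz 2-cycle pulses at 10,000 compounded
#' fps, 1100-frame ensembles, 40 dB static clutter, 20 dB SNR, SVD filtering
#' discarding the largest singular value, 10% loess span, K = 20 sine
#' harmonics and a 3% moving average on the wall-normal component. The imaged
#' axial extent is 8 mm (a typical high-frequency field of view) with 50 um
#' pixels, giving 64 lateral samples across the 3.2 mm diameter. The
#' near-wall exclusion margin for the profile fits
#' (`estimation$wall_margin_mm`) defaults to `NA`, meaning two lateral PSF
#' sigma (`2 * acquisition$sigma_lat_mm`), the support over which
#' partial-volume blur biases near-wall velocities.
#'
#' @return A nested configuration list (class `pipeline_config`).
#' @export
default_config <- function() {
  structure(list(
    geometry = list(kind = "straight", diameter_mm = 3.2, length_mm = 8,
                    stenosis_severity = 0, stenosis_length_mm = 4,
                    stenosis_center_mm = NA, eccentric = TRUE,
                    malapposition_offset_mm = 0, strut_pitch_mm = 1.0,
                    strut_extent_mm = 4),
    fluid = list(mu_pa_s = 0.9e-3, rho_kg_m3 = 998),
    flow = list(flow_rate_ml_min = 20),
    acquisition = list(fc_hz = 23.44e6, n_cycles = 2, c_mps = 1480,
                       frame_rate_hz = 1e4, n_frames = 1100,
                       lambda_lat_mm = 0.25, sigma_lat_mm = 0.05,
                       sigma_to_mm = 0.1,
                       dz_mm = 0.05, dx_mm = 0.05, lateral_margin_mm = 0.6,
                       concentration_per_ml = 2.5e6, slice_thickness_mm = 0.3,
                       clutter_db = 40, snr_db = 20, to_enabled = TRUE),
    estimation = list(n_discard = 1, loess_span = 0.10, K = 20,
                      ma_span = 0.03, zero_threshold_mps = NA,
                      power_mask_db = 20, wall_margin_mm = NA),
    metrics = list(trim_mm = 0.5),
    seed = 1L,
    out_dir = "echowss-out"
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys at both levels, fills missing keys with defaults, and
#' checks ranges by constructing the corresponding domain objects.
#'
#' @param config A (possibly partial) nested list.
#' @return A complete validated `pipeline_config`.
#' @export
validate_config <- function(config) {
  def <- default_config()
  if (!is.list(config)) stop("config must be a list")
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  for (blk in names(config)) {
    if (is.list(def[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(def[[blk]]))
      if (length(bad))
        stop(sprintf("unknown key(s) in `%s`: %s", blk, paste(bad, collapse = ", ")))
      def[[blk]][names(config[[blk]])] <- config[[blk]]
    } else {
      def[[blk]] <- config[[blk]]
    }
  }
  # range checks via the domain constructors
  .config_geometry(def)
  .config_fluid(def)
  .config_acq(def)
  if (def$estimation$loess_span <= 0 || def$estimation$loess_span > 1)
    stop("`estimation$loess_span` must lie in (0, 1]")
  if (def$estimation$K < 1) stop("`estimation$K` must be at least 1")
  if (def$estimation$n_discard < 0) stop("`estimation$n_discard` must be nonnegative")
  class(def) <- "pipeline_config"
  def
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file; keys mirror [default_config()].
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

.config_geometry <- function(cfg) {
  g <- cfg$geometry
  make_geometry(kind = g$kind, diameter = g$diameter_mm, length = g$length_mm,
                stenosis_severity = g$stenosis_severity,
                stenosis_length = g$stenosis_length_mm,
                stenosis_center = if (is.na(g$stenosis_center_mm))
                  g$length_mm / 2 else g$stenosis_center_mm,
                eccentric = g$eccentric,
                malapposition_offset = g$malapposition_offset_mm,
                strut_pitch = g$strut_pitch_mm,
                strut_extent = g$strut_extent_mm)
}

.config_fluid <- function(cfg) {
  fluid_properties(mu = cfg$fluid$mu_pa_s, rho = cfg$fluid$rho_kg_m3)
}

.config_acq <- function(cfg) {
  a <- cfg$acquisition
  acq_params(fc = a$fc_hz, n_cycles = a$n_cycles, c = a$c_mps,
             frame_rate = a$frame_rate_hz, n_frames = a$n_frames,
             lambda_lat = a$lambda_lat_mm, sigma_lat = a$sigma_lat_mm,
             sigma_to = a$sigma_to_mm)
}
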