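#' Run the full simulation-to-WSS pipeline
#'
#' Executes the post-processing chain end to end: phantom geometry and
#' analytic flow field, scatterer seeding, IQ ensemble simulation, clutter
#' and noise injection, SVD clutter filtering, transverse-oscillation vector
#' velocity estimation, loess smoothing, wall detection and contour fitting,
#' pseudo-spectral WSS mapping, and comparison against the analytic wall
#' shear reference. All artifacts (containers, CSV/JSON maps, report and a
#' manifest with content hashes) are written under `out_dir`; identical
#' config and seed produce identical outputs.
#'
#' @param config A `pipeline_config` (see [default_config()]); partial lists
#'   are completed and validated.
#' @param seed Overrides `config$seed` when given.
#' @param out_dir Overrides `config$out_dir` when given.
#' @param keep_iq Keep the (large) IQ ensembles in the returned list.
#' @return Invisibly, a list with the flow field, velocity map, WSS map,
#'   analytic reference, comparison report, manifest and file paths.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         out_dir = NULL, keep_iq = FALSE) {
  cfg <- validate_config(unclass(config))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  geom <- stage("geometry", .config_geometry(cfg))
  fluid <- stage("geometry", .config_fluid(cfg))
  acq <- stage("acquisition", .config_acq(cfg))
  a <- cfg$acquisition

  field <- stage("flow", analytic_flow_field(
    geom, cfg$flow$flow_rate_ml_min, fluid,
    dz = a$dz_mm, dx = a$dx_mm, lateral_margin = a$lateral_margin_mm))

  cloud <- stage("scatterers", seed_scatterers(
    geom, a$concentration_per_ml, a$slice_thickness_mm, seed = cfg$seed))

  # two receive beamformations of the same acquisition: ordinary (fine
  # lateral PSF, axial estimation) and transverse-oscillation (lateral
  # estimation), sharing the scatterer trajectories
  iq <- stage("simulate", simulate_iq_ensemble(
    cloud, field, acq, to_enabled = FALSE))
  iq <- stage("clutter", add_clutter_and_noise(
    iq, a$clutter_db, a$snr_db, seed = cfg$seed + 1L))
  paths$iq <- file.path(cfg$out_dir, "iq.rds")
  stage("io", write_dataset(iq, paths$iq))
  iq_to <- NULL
  if (isTRUE(a$to_enabled)) {
    iq_to <- stage("simulate", simulate_iq_ensemble(
      cloud, field, acq, to_enabled = TRUE))
    iq_to <- stage("clutter", add_clutter_and_noise(
      iq_to, a$clutter_db, a$snr_db, seed = cfg$seed + 2L))
    paths$iq_to <- file.path(cfg$out_dir, "iq_to.rds")
    stage("io", write_dataset(iq_to, paths$iq_to))
  }

  est <- cfg$estimation
  iqf <- stage("svd_filter", svd_clutter_filter(iq, est$n_discard))
  vm <- stage("velocity", if (is.null(iq_to)) {
    ax <- estimate_axial_velocity(iqf, est$power_mask_db)
    ax
  } else {
    iqtf <- svd_clutter_filter(iq_to, est$n_discard)
    estimate_velocity(iqf, iqtf, est$power_mask_db)
  })
  vm <- stage("smooth", loess_smooth(vm, est$loess_span))
  paths$velocity <- file.path(cfg$out_dir, "velocity.rds")
  paths$velocity_csv <- file.path(cfg$out_dir, "velocity.csv")
  stage("io", write_dataset(vm, paths$velocity))
  stage("io", write_velocity_csv(vm, paths$velocity_csv))

  thr <- est$zero_threshold_mps
  edges <- stage("wall", suppressWarnings(detect_wall(
    vm, zero_threshold = if (is.na(thr)) NULL else thr,
    blur_sigma = if (is.na(thr)) a$sigma_lat_mm else NULL)))
  contour <- stage("wall", fit_wall_contour(edges))
  trim <- cfg$metrics$trim_mm
  contour <- stage("wall", contour[contour$z >= trim &
                                     contour$z <= geom$length - trim, ])
  class(contour) <- c("wall_contour", "data.frame")

  # exclude profile samples within the blur toe (2 lateral PSF sigma) of the
  # walls; closer samples are partial-volume biased
  margin <- if (is.na(est$wall_margin_mm)) 2 * a$sigma_lat_mm else est$wall_margin_mm
  wss <- stage("wss", compute_wss_map(vm, contour, fluid,
                                      K = est$K, ma_span = est$ma_span,
                                      wall_margin = margin))
  paths$wss_csv <- file.path(cfg$out_dir, "wss.csv")
  stage("io", write_wss_csv(wss, paths$wss_csv))

  ref <- stage("reference", analytic_wall_shear(
    geom, cfg$flow$flow_rate_ml_min, fluid))
  paths$reference_csv <- file.path(cfg$out_dir, "reference_wss.csv")
  stage("io", write_wss_csv(ref, paths$reference_csv))

  matched <- stage("compare", .match_reference(wss, ref))
  report <- stage("compare", compare_maps(wss$z_mm, wss$wss_pa,
                                          wss$z_mm, matched,
                                          extent = geom$length))
  paths$report <- file.path(cfg$out_dir, "report.json")
  stage("io", write_report(report, paths$report))

  manifest <- list(package = "echowss",
                   version = as.character(utils::packageVersion("echowss")),
                   seed = cfg$seed,
                   config_hash = .stable_hash(cfg),
                   files = lapply(paths, function(p)
                     list(path = p, md5 = unname(tools::md5sum(p)))))
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(config = cfg, field = field,
                 iq = if (keep_iq) iq else NULL,
                 velocity = vm, contour = contour, wss = wss,
                 reference = ref, report = report, manifest = manifest,
                 paths = paths))
}

# per-wall nearest-neighbor lookup of the analytic reference at the
# estimated wall points
.match_reference <- function(wss, ref) {
  out <- numeric(nrow(wss))
  for (w in unique(wss$wall_id)) {
    sel <- wss$wall_id == w
    rsel <- ref$wall_id == w
    out[sel] <- .nearest_neighbor(ref$z_mm[rsel], ref$wss_pa[rsel],
                                  wss$z_mm[sel])
  }
  out
}

.stable_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(x, digits.d = 15)), tmp)
  unname(tools::md5sum(tmp))
}

#' Mean estimated WSS over the middle axial third
#'
#' Convenience accessor for the headline quantity of the straight-phantom
#' experiment: the mean WSS magnitude over wall points whose axial position
#' falls in the middle third of the analyzed extent (both walls).
#'
#' @param wss A `wss_map` or `reference_wss`.
#' @param extent Axial extent, mm.
#' @return Mean WSS, Pa.
#' @export
middle_segment_mean <- function(wss, extent) {
  st <- segment_stats(wss$wss_pa, wss$z_mm, extent)
  st$mean[st$segment == "middle"]
}
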