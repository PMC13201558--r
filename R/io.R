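#' Dataset round-tripping
#'
#' Writes and reads the package's containers (`iq_ensemble`,
#' `velocity_map`, `wss_map`, `flow_field`, `reference_wss`) losslessly with
#' schema-versioned metadata, so pipeline artifacts can be re-loaded and
#' validated later. Containers are stored as serialized R objects wrapped in
#' a schema envelope; map and report exchange with other tools goes through
#' the CSV/JSON writers ([write_velocity_csv()], [write_wss_csv()],
#' [write_report()]).
#'
#' @param object A supported container.
#' @param path Output path (conventionally `.rds`).
#' @return `write_dataset` returns the path invisibly; `read_dataset`
#'   returns the restored object after schema validation.
#' @export
write_dataset <- function(object, path) {
  kind <- .dataset_kind(object)
  env <- list(schema = paste0("echowss/", kind), version = 1L,
              object = object)
  saveRDS(env, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such dataset: ", path)
  env <- readRDS(path)
  if (!is.list(env) || is.null(env$schema) || !startsWith(env$schema, "echowss/"))
    stop("not an echowss dataset (missing schema attribute): ", path)
  if (!identical(env$version, 1L))
    stop(sprintf("unsupported schema version %s for %s", format(env$version), env$schema))
  obj <- env$object
  .validate_dataset(obj, sub("^echowss/", "", env$schema))
  obj
}

.dataset_kind <- function(object) {
  for (k in c("iq_ensemble", "velocity_map", "wss_map", "flow_field",
              "reference_wss", "wall_contour"))
    if (inherits(object, k)) return(k)
  stop("unsupported dataset type: ", paste(class(object), collapse = "/"))
}

.validate_dataset <- function(obj, kind) {
  need <- switch(kind,
    iq_ensemble = c("data", "params", "z", "x"),
    velocity_map = c("v_axial", "v_lateral", "z", "x"),
    flow_field = c("v_axial", "v_lateral", "lumen_mask", "z", "x"),
    wss_map = , reference_wss = c("wall_id", "s_mm", "z_mm", "x_mm", "wss_pa"),
    wall_contour = c("wall_id", "z", "x", "nz", "nx"),
    stop("unknown dataset kind: ", kind))
  have <- if (is.data.frame(obj)) names(obj) else names(obj)
  missing <- setdiff(need, have)
  if (length(missing))
    stop(sprintf("schema error in %s dataset: missing field(s) %s",
                 kind, paste(missing, collapse = ", ")))
  if (kind == "iq_ensemble" && !inherits(obj$params, "acq_params"))
    stop("schema error in iq_ensemble dataset: missing field(s) fc (acq_params)")
  invisible(obj)
}
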