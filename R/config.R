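## Configuration files: a single YAML document with one block per parameter
## group, validated against a fixed schema with location-aware messages.

config_schema <- function() {
  list(
    schema_version = "scalar",
    seed = "scalar",
    output_dir = "scalar",
    log_level = "scalar",
    params = names(kinetic_params()),
    temperature_rules = c("theta_mu_AOO", "theta_mu_NOO", "theta_b",
                          "henry_ref", "henry_vant_hoff_K", "D_ref",
                          "biofilm_diffusivity_ratio", "perm_ref",
                          "perm_activation_energy", "T_ref"),
    geometry = c("mode", "Lf", "L_LBL", "membrane_outer_radius",
                 "membrane_wall"),
    matrix = c("temperatures", "Lf", "L_LBL", "bulk_NH4", "mode"),
    batch = c("windows", "T0", "volume_m3", "area_m2"),
    synthetic = c("temperatures", "R_T0", "theta", "T0", "C0",
                  "interval_min", "volume", "area", "noise_sd", "K_app",
                  "C_stop", "seed")
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with blocks `params`, `temperature_rules`,
#' `geometry`, `matrix`, `batch` and `synthetic` plus top-level `seed`,
#' `output_dir`, `log_level` and `schema_version`.  Unknown keys are rejected
#' with their full key path; block values are filled with package defaults
#' and validated by the corresponding constructors.
#'
#' @param path Path to the YAML file.
#' @return Object of class `"run_config"`: list with validated `params`
#'   ([kinetic_params()]), `rules` ([temperature_rules()]), optional
#'   `geometry`, the raw blocks and the top-level settings.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("load_config: file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  schema <- config_schema()
  for (key in names(raw)) {
    if (!key %in% names(schema))
      stop("load_config: unknown key `", key, "`", call. = FALSE)
    block <- schema[[key]]
    if (!identical(block, "scalar")) {
      bad <- setdiff(names(raw[[key]]), block)
      if (length(bad))
        stop("load_config: unknown key `", key, ".", bad[1], "`",
             call. = FALSE)
    }
  }
  check_pos <- function(block, field, label) {
    v <- raw[[block]][[field]]
    if (!is.null(v) && (!is.numeric(v) || any(v <= 0)))
      stop("load_config: `", label, "` must be positive", call. = FALSE)
  }
  for (f in c("Lf", "L_LBL", "membrane_outer_radius"))
    check_pos("geometry", f, paste0("geometry.", f))
  params <- do.call(kinetic_params, raw$params %||% list())
  rules_args <- raw$temperature_rules %||% list()
  if (!is.null(rules_args$D_ref)) rules_args$D_ref <- unlist(rules_args$D_ref)
  rules <- do.call(temperature_rules, rules_args)
  geometry <- if (!is.null(raw$geometry))
    do.call(biofilm_geometry, raw$geometry)
  structure(list(params = params, rules = rules, geometry = geometry,
                 matrix = raw$matrix, batch = raw$batch,
                 synthetic = raw$synthetic,
                 seed = raw$seed %||% 1L,
                 output_dir = raw$output_dir %||% ".",
                 log_level = raw$log_level %||% "info",
                 schema_version = raw$schema_version %||% 1),
            class = "run_config")
}

#' Write result tables as delimited text with a manifest
#'
#' Writes each table as a tab-separated file named after its list element,
#' with numeric columns at full precision plus display-rounded twin columns
#' (suffix `_display`, 2 decimals), and a `manifest.tsv` listing every file
#' written.  Output is deterministic: same tables, same bytes.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("write_results: cannot create `", out_dir, "`", call. = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    tb <- as.data.frame(tables[[nm]])
    for (col in names(tb)) {
      if (is.numeric(tb[[col]]) && !all(tb[[col]] == round(tb[[col]])))
        tb[[paste0(col, "_display")]] <- round(tb[[col]], 2)
    }
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(format(tb, digits = 15, trim = TRUE, scientific = NA),
                       path, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, path)
  }
  manifest <- data.frame(file = basename(files),
                         rows = vapply(tables, function(t)
                           nrow(as.data.frame(t)), integer(1)))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Write a run configuration back to YAML
#'
#' Inverse of [load_config()] for the blocks it validated; load-write-load is
#' an identity on the validated content.
#'
#' @param config A `"run_config"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- list(schema_version = config$schema_version,
              seed = config$seed,
              output_dir = config$output_dir,
              log_level = config$log_level,
              params = unclass(config$params),
              temperature_rules = {
                r <- unclass(config$rules)
                r$D_ref <- as.list(r$D_ref)
                r
              })
  if (!is.null(config$geometry)) out$geometry <- unclass(config$geometry)
  for (b in c("matrix", "batch", "synthetic"))
    if (!is.null(config[[b]])) out[[b]] <- config[[b]]
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}
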