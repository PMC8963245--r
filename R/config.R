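# YAML run configuration with a strict schema: unknown keys are rejected
# with their full key path, defaults are filled explicitly, and a fully
# specified config round-trips losslessly through save/load.

config_schema <- function() {
  list(
    seed = 1L,
    output_prefix = "pepgamd_run",
    system = list(
      kind = "double_well",          # double_well | three_state |
                                     # harmonic | toy_peptide
      barrier_height = 5,
      well_separation = 2,
      kappa = 1,
      minima = list(c(8.6, 8), c(11.1, 4), c(15.3, 5)),
      depths = c(6, 5, 5.5),
      widths = c(0.8, 0.8, 0.8),
      n_peptide_beads = 3L,
      n_env_beads = 4L,
      binding_depth = 6,
      temperature = 1),
    protocol = list(
      n_cmd_steps = 5000L,
      n_equil_steps = 20000L,
      n_prod_steps = 50000L,
      n_replicas = 3L,               # three independent production runs
      dt = 0.01,
      friction = 1,
      temperature = 1,
      update_interval = 50L,
      record_stride = 1L,
      include_cmd_in_stats = TRUE),
    boost = list(
      sigma_0 = 10,                  # kT units; also the per-term default
      sigma_0_L = 10,
      sigma_0_D = 10,
      bound_mode = "lower"),
    reweight = list(
      bin_width = 1.0,               # 1 coordinate unit per bin
      cutoff_frames = 500L,          # occupancy cutoff per bin or cluster
      beta = 1.0),
    analysis = list(
      n_clusters = 10L,              # top 10 representative conformations
      stride = 1L,
      depth_threshold = 3,
      state_names = c("Inactive", "Intermediate", "Active"),
      state_breaks = c(0, 10, 13, Inf)))
}

#' Default run configuration
#'
#' All analysis defaults in one place: bin width 1 coordinate unit,
#' occupancy cutoff 500 frames per bin or cluster, 10 structural
#' clusters, 3 production replicas, statistics refresh every 50 steps.
#'
#' @return A `run_config` list.
#' @export
default_config <- function() {
  structure(config_schema(), class = "run_config")
}

merge_config <- function(schema, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(schema))
      stop("unknown key: ", full)
    if (is.list(schema[[key]]) && !is.null(names(schema[[key]]))) {
      if (!is.list(user[[key]]))
        stop("schema violation at ", full, ": expected a mapping")
      schema[[key]] <- merge_config(schema[[key]], user[[key]],
                                    c(path, key))
    } else {
      schema[[key]] <- user[[key]]
    }
  }
  schema
}

#' Load and validate a YAML run configuration
#'
#' Missing keys take their defaults; unknown keys raise an error naming
#' the offending key path. The effective (default-filled) configuration
#' is echoed to the log when `verbose`.
#'
#' @param path YAML file.
#' @param verbose Echo the effective configuration to stderr.
#' @return A validated `run_config`.
#' @export
load_config <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(config_schema(), user)
  cfg <- normalize_config(cfg)
  if (verbose) {
    message("effective configuration:")
    message(paste(" ", yaml::as.yaml(unclass(cfg)), collapse = ""))
  }
  structure(cfg, class = "run_config")
}

normalize_config <- function(cfg) {
  for (nm in c("n_cmd_steps", "n_equil_steps", "n_prod_steps", "n_replicas",
               "update_interval", "record_stride"))
    cfg$protocol[[nm]] <- as.integer(cfg$protocol[[nm]])
  cfg$reweight$cutoff_frames <- as.integer(cfg$reweight$cutoff_frames)
  cfg$analysis$n_clusters <- as.integer(cfg$analysis$n_clusters)
  cfg$seed <- as.integer(cfg$seed)
  kinds <- c("double_well", "three_state", "harmonic", "toy_peptide")
  if (!cfg$system$kind %in% kinds)
    stop("schema violation at system.kind: must be one of ",
         paste(kinds, collapse = ", "))
  st <- cfg$analysis$state_breaks
  st <- vapply(st, function(v)
    if (identical(v, "Inf") || identical(v, ".inf")) Inf else as.numeric(v),
    0.0)
  cfg$analysis$state_breaks <- st
  cfg
}

#' Save a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path Output file.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  cat(paste0("  ", strsplit(yaml::as.yaml(unclass(x)), "\n")[[1]],
             collapse = "\n"), "\n")
  invisible(x)
}

#' Build the simulation system a configuration describes
#'
#' @param config A `run_config`.
#' @return A `potential_surface` or `toy_peptide_system`.
#' @export
config_system <- function(config) {
  s <- config$system
  switch(s$kind,
    double_well = make_double_well(s$barrier_height, s$well_separation),
    harmonic = make_harmonic_well(s$kappa),
    three_state = make_three_state_landscape(s$minima, s$depths, s$widths),
    toy_peptide = make_toy_peptide_system(
      s$n_peptide_beads, seed = config$seed, n_env_beads = s$n_env_beads,
      temperature = s$temperature, binding_depth = s$binding_depth))
}

#' Build the protocol a configuration describes
#'
#' @param config A `run_config`.
#' @return A `protocol_spec`.
#' @export
config_protocol <- function(config) {
  p <- config$protocol
  protocol_spec(p$n_cmd_steps, p$n_equil_steps, p$n_prod_steps,
                n_replicas = p$n_replicas, dt = p$dt,
                friction = p$friction, temperature = p$temperature,
                seed = config$seed, update_interval = p$update_interval,
                record_stride = p$record_stride,
                include_cmd_in_stats = p$include_cmd_in_stats)
}
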