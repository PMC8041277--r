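# Flat run configuration shared by the command-line pipeline and scripts.
# A run config is a plain named list, serialisable to/from a single YAML
# file, holding every density/score/swarm parameter plus selection size and
# seed; it is written verbatim into every run's output directory for
# provenance.

#' Default run configuration
#'
#' @param ... named overrides of any default (unknown names are an error).
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    grid_spacing = 1.0, kernel_sigma = 1.8, atom_weighting = "uniform",
    padding = 8.0, isovalue = 0.5,
    contact_distance = 1.4, clash_depth = 0.0, clash_penalty = 2.0,
    n_particles = 80L, n_iterations = 300L, n_repetitions = 3L,
    kick_fraction = 0.04, inertia = 0.72, cognitive = 1.49, social = 1.49,
    repulsion_sigma = 0.05,
    k = 300L, seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown run_config field(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "memdock_config_error")
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file of key: value pairs (any subset of the defaults).
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path),
                 class = "memdock_io_error")
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

#' Save a run configuration as YAML
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
config_density_params <- function(cfg) {
  density_params(grid_spacing = cfg$grid_spacing, kernel_sigma = cfg$kernel_sigma,
                 atom_weighting = cfg$atom_weighting, padding = cfg$padding,
                 isovalue = cfg$isovalue)
}

#' @rdname run_config
#' @export
config_score_params <- function(cfg) {
  score_params(contact_distance = cfg$contact_distance,
               clash_depth = cfg$clash_depth, clash_penalty = cfg$clash_penalty)
}

#' @rdname run_config
#' @export
config_swarm <- function(cfg) {
  swarm_config(n_particles = cfg$n_particles, n_iterations = cfg$n_iterations,
               n_repetitions = cfg$n_repetitions,
               kick_fraction = cfg$kick_fraction, inertia = cfg$inertia,
               cognitive = cfg$cognitive, social = cfg$social,
               repulsion_sigma = cfg$repulsion_sigma, rng_seed = cfg$seed)
}
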