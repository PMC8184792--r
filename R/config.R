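#' Default run configuration
#'
#' The benchmark parameter set used throughout the illustrative analyses:
#' `D = 0.1` um^2/s, `dx = dy = 0.1` um, `dt = 0.01` s, with a 20 um ring
#' (`N = 200`) and a 200 x 200 torus, FRAP ROI radius 0.55 um, and the
#' reaction-diffusion splitting `dt_R = 1e-5` s, `dt_D = 0.002` s, mass
#' `m = 3`.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    solver = "ufdm", scheme = "explicit", ic = "gaussian",
    D = 0.1, dx = 0.1, dy = 0.1, dt = 0.01,
    N = 200L, M = 200L, t_end = 10, alpha = 1,
    m = 3, dtR = 1e-5, dtD = 0.002, roi = 0.55,
    method = "cubic", snapshot_every = 0.1,
    out = NA_character_, seed = 1L),
    class = "run_config")
}

config_numeric_keys <- c("D", "dx", "dy", "dt", "N", "M", "t_end", "alpha",
                         "m", "dtR", "dtD", "roi", "snapshot_every", "seed")
config_string_keys <- c("solver", "scheme", "ic", "method", "out")

#' Load a run configuration from a flat key-value file
#'
#' The file is YAML restricted to flat `key: value` pairs mirroring the CLI
#' flags. Missing keys take their defaults from [default_config()]; unknown
#' keys and non-numeric values for numeric keys are rejected with an error
#' naming the offending key. An empty file yields all defaults.
#'
#' @param path path to the configuration file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop_invalid("config file must contain key: value pairs")
  cfg <- default_config()
  for (key in names(raw)) {
    if (!key %in% c(config_numeric_keys, config_string_keys))
      stop_invalid(sprintf("unknown configuration key: %s", key))
    val <- raw[[key]]
    if (key %in% config_numeric_keys) {
      val <- suppressWarnings(as.numeric(val))
      if (length(val) != 1L || is.na(val))
        stop_invalid(sprintf("configuration key '%s' must be a single number", key))
      if (key %in% c("N", "M", "seed")) val <- as.integer(val)
    } else {
      if (!is.character(val) || length(val) != 1L)
        stop_invalid(sprintf("configuration key '%s' must be a single string", key))
    }
    cfg[[key]] <- val
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!cfg$solver %in% c("ufdm", "fdm1d", "fdm2d"))
    stop_invalid("configuration key 'solver' must be one of ufdm, fdm1d, fdm2d")
  if (!cfg$scheme %in% c("explicit", "semi-implicit"))
    stop_invalid("configuration key 'scheme' must be explicit or semi-implicit")
  if (!cfg$ic %in% c("gaussian", "bleach"))
    stop_invalid("configuration key 'ic' must be gaussian or bleach")
  if (!cfg$method %in% c("cubic", "linear"))
    stop_invalid("configuration key 'method' must be linear or cubic")
  cfg
}

#' Write a run configuration to a file
#'
#' Round-trips losslessly through [load_config()].
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$out <- if (is.na(out$out)) NULL else out$out
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Stability of a configuration's solver/scheme pair
#'
#' @param cfg a `run_config`.
#' @return A [stability_report()] for the configured solver and scheme.
#' @export
config_stability <- function(cfg) {
  params <- diffusion_params(cfg$D, cfg$dt, cfg$dx, cfg$dy)
  scheme_id <- switch(cfg$solver,
    fdm1d = "explicit_1d",
    fdm2d = if (cfg$scheme == "explicit") "explicit_2d" else "semi_implicit_2d",
    ufdm  = if (cfg$scheme == "explicit") "explicit_ufdm" else "semi_implicit_ufdm")
  stability_report(scheme_id, params)
}
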