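#' Full run configuration
#'
#' Bundles and validates everything a simulation needs before any compute:
#' the connectome source (files or a synthetic specification), the node
#' parameters, engine, plasticity and recorder settings. Every component
#' invariant is checked here, so an invalid configuration fails before the
#' first solver step.
#'
#' @param connectome Either a [connectome()] object, a list
#'   `list(n =, p =, seed =)` describing a synthetic connectome, or a list
#'   `list(streamlines =, lengths =)` of file paths.
#' @param params A [population_params()].
#' @param engine An [engine_config()].
#' @param plasticity A [plasticity_config()] or NULL (off).
#' @param recorder A [recorder_config()].
#' @param seed Integer seed covering every source of randomness in the run.
#' @param out_dir Optional output directory for streamed snapshots (overrides
#'   the recorder's `out_dir`).
#' @param verbose Progress logging during [run_simulation()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(connectome = list(n = 82, p = 0.2),
                              params = population_params(),
                              engine = engine_config(t_end = 1000),
                              plasticity = NULL,
                              recorder = recorder_config(),
                              seed = 1, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(params, "population_params"),
            inherits(engine, "engine_config"),
            inherits(recorder, "recorder_config"))
  if (!is.null(plasticity)) stopifnot(inherits(plasticity, "plasticity_config"))
  if (!inherits(connectome, "connectome")) {
    if (!is.list(connectome)) {
      abort("simulation_config: connectome must be a connectome object or a list.")
    }
    known <- c("n", "p", "seed", "streamlines", "lengths", "v", "length_range")
    extra <- setdiff(names(connectome), known)
    if (length(extra)) {
      abort(sprintf("simulation_config: unknown connectome key(s): %s.",
                    paste(extra, collapse = ", ")))
    }
    synth <- all(c("n", "p") %in% names(connectome))
    files <- all(c("streamlines", "lengths") %in% names(connectome))
    if (!synth && !files) {
      abort("simulation_config: connectome needs either {n, p} or {streamlines, lengths}.")
    }
  }
  if (!is.null(out_dir)) recorder$out_dir <- out_dir
  structure(list(connectome = connectome, params = params, engine = engine,
                 plasticity = plasticity, recorder = recorder,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "simulation_config")
}

# stable fingerprint of a configuration (used in run metadata)
config_hash <- function(config) {
  ser <- list(
    connectome = if (inherits(config$connectome, "connectome")) {
      list(n = config$connectome$n, sumW = sum(config$connectome$W),
           sumD = sum(config$connectome$D))
    } else config$connectome,
    params = unclass(config$params),
    engine = unclass(config$engine),
    plasticity = if (!is.null(config$plasticity)) unclass(config$plasticity),
    recorder = list(interval = config$recorder$interval),
    seed = config$seed)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(md5sum(tmp))
}

resolve_connectome <- function(spec, seed) {
  if (inherits(spec, "connectome")) return(spec)
  if (all(c("streamlines", "lengths") %in% names(spec))) {
    return(read_connectome(spec$streamlines, spec$lengths,
                           v = spec$v %||% 7))
  }
  synthetic_connectome(n = spec$n, p = spec$p,
                       seed = spec$seed %||% seed,
                       length_range = spec$length_range %||% c(20, 150),
                       v = spec$v %||% 7)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured simulation
#'
#' Orchestrates connectome resolution, integration, plasticity and recording,
#' with progress logging of biological time, wall time and the running
#' maximum of the embedded error estimate. The run is fully determined by the
#' configuration and its seed: repeating it reproduces the snapshot series
#' byte for byte.
#'
#' @param config A [simulation_config()].
#' @return A `brainmass_sim` (see [run_chunked()]).
#' @examples
#' cfg <- simulation_config(connectome = list(n = 3, p = 0.5),
#'                          engine = engine_config(t_end = 100), seed = 7)
#' sim <- run_simulation(cfg)
#' sim$counters$snapshots
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  con <- resolve_connectome(config$connectome, config$seed)
  engine <- config$engine
  if (is.null(engine$rng_seed)) engine$rng_seed <- config$seed
  meta <- list(config_hash = config_hash(config), seed = config$seed,
               package_version = as.character(utils::packageVersion("brainmass")))
  if (config$verbose) {
    message(sprintf("run_simulation: %d regions, %g ms biological time, step %g ms",
                    con$n, engine$t_end, engine$step))
  }
  sim <- run_chunked(con, config$params, engine,
                     plasticity = config$plasticity,
                     recorder = config$recorder,
                     metadata = meta, verbose = config$verbose)
  if (config$verbose) {
    message(sprintf("run_simulation: done in %.2f s wall (max err est %.3g).",
                    sim$wall_time, sim$counters$max_err_est))
  }
  sim
}

#' Read / write a run configuration as JSON
#'
#' A flat JSON encoding of a [simulation_config()]: sections `connectome`,
#' `params`, `engine`, `plasticity`, `recorder`, plus `seed` and `verbose`.
#' Unknown keys anywhere are rejected. Every model constant (step = 1 ms,
#' chunk = 10, update_every = 10, snapshot interval = 50 s, v = 7 m/s,
#' p = 0.2, weight scale 0.1) is present and overridable through this file.
#'
#' @param path JSON file path.
#' @return `read_config`: a [simulation_config()]. `write_config`: `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("connectome", "params", "engine", "plasticity", "recorder",
             "seed", "out_dir", "verbose")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(sprintf("read_config: unknown key(s): %s.", paste(extra, collapse = ", ")))
  }
  take <- function(section, builder, allowed) {
    sec <- raw[[section]]
    if (is.null(sec)) return(NULL)
    sec <- as.list(sec)
    extra <- setdiff(names(sec), allowed)
    if (length(extra)) {
      abort(sprintf("read_config: unknown %s key(s): %s.", section,
                    paste(extra, collapse = ", ")))
    }
    do.call(builder, sec)
  }
  params <- take("params", population_params,
                 c("tau_e", "tau_i", "a_e", "a_i", "theta_e", "theta_i", "w",
                   "P_e", "P_s", "P_d", "dynamic_k")) %||% population_params()
  engine <- take("engine", engine_config,
                 c("t_end", "step", "chunk_steps", "initial_state", "init_noise",
                   "rng_seed", "divergence_limit", "err_warn")) %||%
    engine_config(t_end = 1000)
  plasticity <- take("plasticity", plasticity_config,
                     c("c", "update_every", "external_on", "internal_on",
                       "plastic_internal_set", "rule"))
  recorder <- take("recorder", recorder_config, c("interval", "out_dir")) %||%
    recorder_config()
  simulation_config(connectome = as.list(raw$connectome) %||% list(n = 82, p = 0.2),
                    params = params, engine = engine, plasticity = plasticity,
                    recorder = recorder, seed = raw$seed %||% 1,
                    out_dir = raw$out_dir, verbose = isTRUE(raw$verbose))
}

#' @rdname read_config
#' @param config A [simulation_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  ser <- list(
    connectome = if (inherits(config$connectome, "connectome")) {
      abort("write_config: in-memory connectome objects cannot be serialized; use write_connectome() and file paths.")
    } else config$connectome,
    params = unclass(config$params)[c("tau_e", "tau_i", "a_e", "a_i", "theta_e",
                                      "theta_i", "w", "P_e", "P_s", "P_d",
                                      "dynamic_k")],
    engine = unclass(config$engine),
    plasticity = if (!is.null(config$plasticity)) unclass(config$plasticity),
    recorder = list(interval = config$recorder$interval,
                    out_dir = config$recorder$out_dir),
    seed = config$seed, verbose = config$verbose)
  ser <- ser[!vapply(ser, is.null, logical(1))]
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
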