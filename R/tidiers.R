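#' Tidy a snapshot series
#'
#' @param x A [snapshot_series()].
#' @param what `"activity"` (default): one row per snapshot, region and
#'   population with columns `time, region, variable, value`;
#'   `"weights"`: long inter-region weights `time, from, to, weight`
#'   (existing connections only); `"internal"`: long internal weights
#'   `time, region, weight, value`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy snapshot_series
#' @export
tidy.snapshot_series <- function(x, what = c("activity", "weights", "internal"),
                                 ...) {
  what <- match.arg(what)
  ns <- length(x$times)
  n <- x$n
  if (what == "activity") {
    if (ns == 0) {
      return(tibble(time = numeric(0), region = integer(0),
                    variable = character(0), value = numeric(0)))
    }
    out <- lapply(seq_len(ns), function(k) {
      tibble(time = x$times[k], region = rep(seq_len(n), 3L),
             variable = rep(c("E", "Is", "Id"), each = n),
             value = c(x$E[[k]], x$Is[[k]], x$Id[[k]]))
    })
    return(dplyr::bind_rows(out))
  }
  if (what == "weights") {
    out <- lapply(seq_len(ns), function(k) {
      W <- x$W[[k]]
      idx <- which(W != 0, arr.ind = TRUE)
      tibble(time = x$times[k], to = as.integer(idx[, 1]),
             from = as.integer(idx[, 2]), weight = W[idx])
    })
    return(dplyr::bind_rows(out))
  }
  out <- lapply(seq_len(ns), function(k) {
    iw <- x$internal_w[[k]]
    tibble(time = x$times[k], region = rep(seq_len(n), 7L),
           weight = rep(paste0("w", 1:7), each = n),
           value = as.vector(iw))
  })
  dplyr::bind_rows(out)
}

#' Tidy a simulation result
#'
#' Forwards to [tidy.snapshot_series()] on the in-memory series, or reads the
#' streamed series back from disk first.
#'
#' @param x A `brainmass_sim` from [run_chunked()] / [run_simulation()].
#' @inheritParams tidy.snapshot_series
#' @return A tibble.
#' @method tidy brainmass_sim
#' @export
tidy.brainmass_sim <- function(x, what = c("activity", "weights", "internal"),
                               ...) {
  series <- x$series %||% read_series(x$out_dir)
  tidy(series, what = match.arg(what))
}

#' One-row summary of a simulation
#'
#' @param x A `brainmass_sim`.
#' @param ... Unused.
#' @return A one-row tibble: problem size, horizon, counters, the maximum
#'   embedded error estimate, buffer capacity and wall time.
#' @method glance brainmass_sim
#' @export
glance.brainmass_sim <- function(x, ...) {
  tibble(n = x$n, t_end_ms = x$t_end, steps = x$steps, step_ms = x$step,
         snapshots = x$counters$snapshots,
         rhs_evals = x$counters$rhs_evals,
         coupling_madds = x$counters$coupling_madds,
         plasticity_cycles = x$counters$plasticity_cycles,
         max_err_est = x$counters$max_err_est,
         buffer_capacity = x$capacity,
         wall_time_s = x$wall_time)
}
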