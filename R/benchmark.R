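#' Scaling benchmark over a family of synthetic networks
#'
#' Rebuilds the published scaling experiment in hardware-independent terms:
#' for each network size `n`, a synthetic connectome is generated and a fixed
#' biological duration is simulated, and deterministic instrumentation
#' counters are reported alongside the (informational-only) wall time. The
#' coupling multiply-add counter grows with the number of external
#' connections per right-hand-side evaluation, which is what makes the
#' overall complexity O(n^2) in the region count.
#'
#' The default biological duration mirrors the published table (50 s); tests
#' and quick looks should pass something much smaller — the counters scale
#' exactly linearly with duration.
#'
#' @param sizes Integer vector of region counts.
#' @param p Connection probability (default 0.2; use 1 for full connectivity).
#' @param plasticity Logical (default TRUE) or a [plasticity_config()].
#' @param bio_time Biological duration per run in ms (default 50,000 = 50 s).
#' @param step Solver step (ms).
#' @param seed Base seed; run for size `n` uses `seed + n`.
#' @param params A [population_params()].
#' @return A tibble of class `brainmass_bench` with columns `n`, `p`,
#'   `edges_expected` (closed form [count_edges()]), `edges_realized`,
#'   `rhs_evals`, `coupling_madds`, `plasticity_cycles`, `bio_time_ms` and
#'   `wall_time_s`.
#' @examples
#' benchmark_scaling(c(2, 10), p = 0.2, plasticity = FALSE, bio_time = 50)
#' @export
benchmark_scaling <- function(sizes, p = 0.2, plasticity = TRUE,
                              bio_time = 50000, step = 1, seed = 1,
                              params = population_params()) {
  if (any(sizes < 1)) abort("benchmark_scaling: sizes must be >= 1.")
  pl <- if (isTRUE(plasticity)) plasticity_config() else
    if (inherits(plasticity, "plasticity_config")) plasticity else NULL
  rows <- lapply(sizes, function(n) {
    con <- synthetic_connectome(n = n, p = p, seed = seed + n)
    sim <- run_chunked(con, params,
                       engine_config(t_end = bio_time, step = step),
                       plasticity = pl,
                       recorder = recorder_config(interval = max(bio_time, step)))
    tibble(
      n = as.integer(n), p = p,
      edges_expected = count_edges(n, p),
      edges_realized = sum(con$W != 0) + 7L * as.integer(n),
      rhs_evals = sim$counters$rhs_evals,
      coupling_madds = sim$counters$coupling_madds,
      plasticity_cycles = sim$counters$plasticity_cycles,
      bio_time_ms = bio_time,
      wall_time_s = sim$wall_time)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("brainmass_bench", class(out))
  out
}

#' Log-log scaling slope of the coupling work
#'
#' Fits `log(coupling_madds) ~ log(n)` over a benchmark table; a slope near 2
#' is the O(n^2) coupling cost made literal.
#'
#' @param bench A `brainmass_bench` tibble from [benchmark_scaling()].
#' @return The fitted slope (numeric scalar).
#' @export
scaling_slope <- function(bench) {
  stopifnot(nrow(bench) >= 2)
  unname(coef(lm(log(coupling_madds) ~ log(n), data = bench))[2])
}
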