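#' Circular history buffer for delayed-state lookup
#'
#' A fixed-capacity ring holding the most recent `(time, state, derivative)`
#' triples of the integration. Once full, the oldest entry is overwritten, so
#' retained memory is bounded by the capacity regardless of how long the
#' simulation runs. The capacity must cover the longest delay:
#' `ceiling(max_delay / step) + 4` entries suffice to interpolate any delayed
#' lookup the solver can issue.
#'
#' @param capacity Number of stored steps (>= 2).
#' @param n_vars State dimension.
#' @return An object of class `history_buffer` (an environment).
#' @seealso [hb_push()], [interpolate_history()]
#' @export
history_buffer <- function(capacity, n_vars) {
  capacity <- as.integer(capacity)
  if (capacity < 2) abort("history_buffer: capacity must be >= 2.")
  buf <- new.env(parent = emptyenv())
  buf$capacity <- capacity
  buf$n_vars <- as.integer(n_vars)
  buf$t <- numeric(capacity)
  buf$y <- matrix(0, capacity, n_vars)
  buf$f <- matrix(0, capacity, n_vars)
  buf$count <- 0L     # filled entries
  buf$total <- 0L     # total pushes (ring position = total %% capacity)
  class(buf) <- "history_buffer"
  buf
}

#' Append one step to a history buffer
#'
#' Times must be strictly increasing; when the buffer is full the oldest
#' entry is overwritten.
#'
#' @param buf A [history_buffer()].
#' @param t Node time.
#' @param y State vector at `t`.
#' @param f Derivative vector at `t`.
#' @return The buffer, invisibly.
#' @export
hb_push <- function(buf, t, y, f) {
  if (buf$count > 0L && t <= hb_newest_time(buf)) {
    abort(sprintf("hb_push: times must be strictly increasing (got %g after %g).",
                  t, hb_newest_time(buf)))
  }
  slot <- (buf$total %% buf$capacity) + 1L
  buf$t[slot] <- t
  buf$y[slot, ] <- y
  buf$f[slot, ] <- f
  buf$total <- buf$total + 1L
  buf$count <- min(buf$count + 1L, buf$capacity)
  invisible(buf)
}

# chronological slot order (oldest first)
hb_slots <- function(buf) {
  if (buf$count < buf$capacity) return(seq_len(buf$count))
  newest <- ((buf$total - 1L) %% buf$capacity) + 1L
  c(if (newest < buf$capacity) (newest + 1L):buf$capacity, seq_len(newest))
}

hb_times <- function(buf) buf$t[hb_slots(buf)]

hb_newest_time <- function(buf) buf$t[((buf$total - 1L) %% buf$capacity) + 1L]

#' @export
print.history_buffer <- function(x, ...) {
  cat(sprintf("<history_buffer> %d/%d entries, %d state variables\n",
              x$count, x$capacity, x$n_vars))
  if (x$count > 0) {
    tt <- hb_times(x)
    cat(sprintf("  covering t in [%g, %g]\n", tt[1], tt[x$count]))
  }
  invisible(x)
}

# cubic Hermite basis at parameter th in [0,1] over an interval of width h
hermite_weights <- function(th, h) {
  th2 <- th * th
  th3 <- th2 * th
  list(h00 = 2 * th3 - 3 * th2 + 1,
       h01 = -2 * th3 + 3 * th2,
       h10 = (th3 - 2 * th2 + th) * h,
       h11 = (th3 - th2) * h)
}

#' Interpolate the buffered solution at an earlier time
#'
#' Piecewise cubic Hermite interpolation through the stored
#' `(state, derivative)` pairs — the dense output matching the RK(2,3) pair's
#' third order. At a stored node time the stored state is returned exactly.
#' Queries older than the retained window raise a "history underrun" error
#' that reports the capacity that would have been required.
#'
#' @param buf A [history_buffer()].
#' @param t_query Query time; must lie within the buffered time span.
#' @return State vector at `t_query`.
#' @export
interpolate_history <- function(buf, t_query) {
  if (buf$count == 0L) abort("interpolate_history: buffer is empty.")
  slots <- hb_slots(buf)
  tt <- buf$t[slots]
  k <- buf$count
  if (t_query > tt[k] + 1e-9) {
    abort(sprintf("interpolate_history: t_query = %g is ahead of newest buffered time %g.",
                  t_query, tt[k]))
  }
  if (t_query < tt[1]) {
    h <- if (k > 1) tt[2] - tt[1] else 1
    need <- ceiling((tt[k] - t_query) / h) + 4
    abort(sprintf(paste0("history underrun: t_query = %g precedes oldest buffered ",
                         "time %g; a capacity of at least %d would be required."),
                  t_query, tt[1], need))
  }
  idx <- findInterval(t_query, tt)
  if (t_query == tt[idx]) return(buf$y[slots[idx], ])
  if (idx == k) idx <- k - 1L  # t_query within 1e-9 above the newest node
  s0 <- slots[idx]; s1 <- slots[idx + 1L]
  h <- tt[idx + 1L] - tt[idx]
  th <- (t_query - tt[idx]) / h
  w <- hermite_weights(th, h)
  w$h00 * buf$y[s0, ] + w$h01 * buf$y[s1, ] +
    w$h10 * buf$f[s0, ] + w$h11 * buf$f[s1, ]
}

#' One Bogacki-Shampine RK(2,3) step
#'
#' Advances `y` by one step of the explicit Bogacki-Shampine pair: four stage
#' evaluations, a third-order solution and an embedded second-order estimate
#' whose difference is the local error estimate. The fourth stage equals the
#' first stage of the next step (FSAL), so passing it back as `k1` saves one
#' evaluation per step.
#'
#' @param f Right-hand side `f(t, y)` returning `dy/dt`.
#' @param t Current time.
#' @param y Current state vector.
#' @param h Step size (> 0).
#' @param k1 Optional derivative at `(t, y)` (the previous step's `k4`).
#' @return List with `y` (third-order solution at `t + h`), `k4` (derivative
#'   at the new point, reusable as the next `k1`), `err` (componentwise
#'   embedded error estimate) and `err_norm` (its max-abs).
#' @examples
#' s <- step_rk23(function(t, y) -y, 0, 1, 0.1)
#' abs(s$y - exp(-0.1))  # ~ 1e-6
#' @export
step_rk23 <- function(f, t, y, h, k1 = NULL) {
  if (h <= 0) abort("step_rk23: step size must be > 0.")
  if (is.null(k1)) k1 <- f(t, y)
  k2 <- f(t + h / 2, y + (h / 2) * k1)
  k3 <- f(t + 3 * h / 4, y + (3 * h / 4) * k2)
  ynew <- y + h * (2 * k1 + 3 * k2 + 4 * k3) / 9
  k4 <- f(t + h, ynew)
  if (any(!is.finite(ynew)) || any(!is.finite(k4))) {
    abort(sprintf("step_rk23: non-finite stage value at t = %g.", t + h))
  }
  err <- h * (-5 / 72 * k1 + 1 / 12 * k2 + 1 / 9 * k3 - 1 / 8 * k4)
  list(y = ynew, k4 = k4, err = err, err_norm = max(abs(err)))
}

#' Fixed-step DDE integration with full dense output
#'
#' A straightforward (monolithic) fixed-step integrator for delay systems:
#' every accepted step is retained, so delayed lookups via
#' [interpolate_history()] can reach arbitrarily far back. This is the
#' reference path that the memory-bounded chunked engine ([run_chunked()]) is
#' validated against; it is intended for small problems and tests, not for
#' day-long horizons.
#'
#' @param f Right-hand side `f(t, y, ylag)`; `ylag(tq)` returns the state at
#'   an earlier time `tq` (pre-history for `tq <= t0`, interpolated otherwise).
#' @param y0 Initial state vector at `t0`.
#' @param t0,t_end Integration span; `t_end - t0` must be a whole number of
#'   steps.
#' @param h Step size (> 0).
#' @param history Function of time giving the state for `t <= t0`; defaults
#'   to the constant initial state.
#' @param capacity Buffer capacity; defaults to the whole run (monolithic).
#' @return List with `times`, `y` (matrix, one row per node), `final`,
#'   `buffer`.
#' @examples
#' # y'(t) = -y(t - 1), constant history 1: solution 1 - t on [0, 1]
#' sol <- dde_integrate(function(t, y, ylag) -ylag(t - 1), 1, 0, 1, 0.1)
#' max(abs(sol$y[, 1] - (1 - sol$times)))
#' @export
dde_integrate <- function(f, y0, t0 = 0, t_end, h,
                          history = function(t) y0, capacity = NULL) {
  if (h <= 0) abort("dde_integrate: step size must be > 0.")
  nsteps <- round((t_end - t0) / h)
  if (nsteps < 0 || abs(t0 + nsteps * h - t_end) > 1e-8 * max(1, abs(t_end))) {
    abort("dde_integrate: (t_end - t0) must be a non-negative multiple of h.")
  }
  y0 <- as.numeric(y0)
  nv <- length(y0)
  if (is.null(capacity)) capacity <- nsteps + 1L
  buf <- history_buffer(max(2L, capacity), nv)
  ylag <- function(tq) {
    if (tq <= t0) history(tq) else interpolate_history(buf, tq)
  }
  fwrap <- function(t, y) as.numeric(f(t, y, ylag))
  traj <- matrix(0, nsteps + 1L, nv)
  times <- t0 + h * (0:nsteps)
  y <- y0
  k1 <- fwrap(t0, y)
  hb_push(buf, t0, y, k1)
  traj[1L, ] <- y
  if (nsteps > 0) {
    for (k in seq_len(nsteps)) {
      t <- times[k]
      st <- step_rk23(fwrap, t, y, h, k1 = k1)
      y <- st$y
      k1 <- st$k4
      hb_push(buf, times[k + 1L], y, k1)
      traj[k + 1L, ] <- y
    }
  }
  list(times = times, y = traj, final = y, buffer = buf)
}

#' Right-hand side closure for a delayed network
#'
#' Builds the `f(t, y, ylag)` function that [dde_integrate()] needs to run
#' the full coupled system: it unpacks the flat state, gathers every delayed
#' source activity `E_j(t - D_ij)` through `ylag`, and evaluates
#' [network_rhs()]. Used as the monolithic reference for the chunked engine.
#'
#' @param con A [connectome()].
#' @param params A [population_params()].
#' @param internal_w Optional n x 7 per-region internal weight matrix.
#' @return Function `f(t, y, ylag)` returning the flat derivative vector.
#' @export
network_rhs_fun <- function(con, params, internal_w = NULL) {
  n <- con$n
  idx <- which(con$W != 0, arr.ind = TRUE)
  force(params); force(internal_w)
  function(t, y, ylag) {
    st <- vec_to_state(y, t = t)
    delayed <- matrix(0, n, n)
    if (nrow(idx) > 0) {
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        lag_state <- ylag(t - con$D[i, j])
        delayed[i, j] <- lag_state[j]
      }
    }
    d <- network_rhs(st, delayed, con$W, params, internal_w = internal_w)
    c(d$dE, d$dIs, d$dId)
  }
}
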