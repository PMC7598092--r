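# Shared fixtures and independent reference implementations.

# a tiny deterministic connectome with delays safely above one 1-ms step
tiny_connectome <- function(n = 3, seed = 11, p = 0.8) {
  synthetic_connectome(n = n, p = p, seed = seed,
                       length_range = c(20, 150))
}

# default parameters shortened for tests
test_params <- function(...) population_params(...)

# scalar (loop-everything) reference of one external Hebbian update with
# normalization -- independent of the vectorized implementation
ref_external_update <- function(W, delayed_E, E_now, E_prev, c) {
  n <- nrow(W)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (W[i, j] != 0) {
        dW <- c * delayed_E[i, j] * (E_now[i] - E_prev[i])
        W[i, j] <- max(0, W[i, j] + dW)
      }
    }
  }
  for (i in seq_len(n)) {
    s <- sum(W[i, ])
    if (s > 0) W[i, ] <- W[i, ] / s
  }
  W
}

# scalar reference of one internal update cycle with per-node conservation
ref_internal_update <- function(internal_w, now, prev, c,
                                plastic = paste0("w", 1:7)) {
  pre_of  <- c(w1 = "E", w2 = "Is", w3 = "Id", w4 = "E",
               w5 = "E", w6 = "Is", w7 = "Id")
  post_of <- c(w1 = "E", w2 = "E", w3 = "E", w4 = "Is",
               w5 = "Id", w6 = "Id", w7 = "Id")
  cols <- match(plastic, paste0("w", 1:7))
  n <- nrow(internal_w)
  out <- internal_w
  for (i in seq_len(n)) {
    before <- 0; after <- 0
    upd <- numeric(length(cols))
    for (s in seq_along(cols)) {
      k <- cols[s]
      pre <- now[[pre_of[k]]][i]
      dpost <- now[[post_of[k]]][i] - prev[[post_of[k]]][i]
      upd[s] <- max(0, internal_w[i, k] + c * pre * dpost)
      before <- before + internal_w[i, k]
      after <- after + upd[s]
    }
    if (after > 0) upd <- upd * (before / after)
    out[i, cols] <- upd
  }
  out
}

# independent full reference simulation of the coupled system WITH plasticity:
# generic buffer + interpolate_history + step_rk23 + scalar plasticity rules
ref_plastic_run <- function(con, params, nsteps, h = 1, plast = NULL,
                            fill = 0.1) {
  n <- con$n
  W <- con$W
  D <- con$D
  D[W != 0 & D < h] <- h
  internal_w <- matrix(rep(params$w, each = n), n, 7)
  y0 <- rep(fill, 3 * n)
  buf <- history_buffer(nsteps + 1, 3 * n)
  ylag <- function(tq) if (tq <= 0) y0 else interpolate_history(buf, tq)
  rhs <- function(t, y) {
    E <- y[1:n]; Is <- y[n + 1:n]; Id <- y[2 * n + 1:n]
    delayed <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (W[i, j] != 0) delayed[i, j] <- ylag(t - D[i, j])[j]
    }
    d <- network_rhs(network_state(E, Is, Id, t = t), delayed, W, params,
                     internal_w = internal_w)
    c(d$dE, d$dIs, d$dId)
  }
  y <- y0
  prev <- y0
  k1 <- rhs(0, y)
  hb_push(buf, 0, y, k1)
  for (k in seq_len(nsteps)) {
    st <- step_rk23(rhs, (k - 1) * h, y, h, k1 = k1)
    prev <- y
    y <- st$y
    k1 <- st$k4
    hb_push(buf, k * h, y, k1)
    if (!is.null(plast) && plast$c > 0 && k %% plast$update_every == 0) {
      E <- y[1:n]; Is <- y[n + 1:n]; Id <- y[2 * n + 1:n]
      Ep <- prev[1:n]; Isp <- prev[n + 1:n]; Idp <- prev[2 * n + 1:n]
      delayed <- matrix(0, n, n)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (W[i, j] != 0) delayed[i, j] <- ylag(k * h - D[i, j])[j]
      }
      if (plast$external_on) {
        W <- ref_external_update(W, delayed, E, Ep, plast$c)
      }
      if (plast$internal_on) {
        internal_w <- ref_internal_update(
          internal_w,
          now = list(E = E, Is = Is, Id = Id),
          prev = list(E = Ep, Is = Isp, Id = Idp),
          c = plast$c, plastic = plast$plastic_internal_set)
      }
      # refresh the boundary-node derivative under the new weights
      k1 <- rhs(k * h, y)
      slot <- ((buf$total - 1L) %% buf$capacity) + 1L
      buf$f[slot, ] <- k1
    }
  }
  list(final = y, W = W, internal_w = internal_w)
}
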