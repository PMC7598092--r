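#' Net excitatory drive to every region
#'
#' The driver input of each region's excitatory population: local recurrent
#' excitation `w1 * E_i(t)`, plus delayed input from every other region
#' `sum_j W_ij * E_j(t - del_ij)`, plus the external drive `P_e`. Row `i` of
#' `W` holds the incoming weights of region `i` (row = target, column =
#' source).
#'
#' The `"vectorized"` method accumulates column by column in exactly the same
#' order as the naive per-element double loop, so the two methods agree
#' bit-for-bit.
#'
#' @param E Current excitatory activities (length n).
#' @param delayed_E n x n matrix with `delayed_E[i, j] = E_j(t - del_ij)`.
#' @param W n x n inter-region weight matrix, zero diagonal.
#' @param params A [population_params()] object (supplies `w1` and `P_e`);
#'   `w1` may also be a per-region vector via `w1` override.
#' @param method `"vectorized"` (default) or `"loop"` (reference double loop).
#' @param w1 Optional per-region override of the recurrent weight (vector of
#'   length n), used when internal weights are plastic.
#'
#' @return Numeric vector of length n of driver inputs.
#' @examples
#' W <- matrix(c(0, 0.5, 0.3, 0), 2, 2, byrow = TRUE)
#' dE <- matrix(1, 2, 2)
#' coupling_drive(c(0.2, 0.1), dE, W, population_params())
#' @export
coupling_drive <- function(E, delayed_E, W, params,
                           method = c("vectorized", "loop"), w1 = NULL) {
  method <- match.arg(method)
  n <- length(E)
  if (!is.matrix(W) || nrow(W) != n || ncol(W) != n) {
    abort("coupling_drive: W must be an n x n matrix matching length(E).")
  }
  if (!is.matrix(delayed_E) || nrow(delayed_E) != n || ncol(delayed_E) != n) {
    abort("coupling_drive: delayed_E must be an n x n matrix matching length(E).")
  }
  if (any(diag(W) != 0)) abort("coupling_drive: W must have a zero diagonal.")
  if (is.null(w1)) w1 <- params$w[["w1"]]
  if (method == "loop") {
    drive <- numeric(n)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(n)) {
        if (j != i) s <- s + W[i, j] * delayed_E[i, j]
      }
      drive[i] <- (w1 * E)[i] + s + params$P_e
    }
    return(drive)
  }
  # column sweep: same accumulation order per element as the double loop
  s <- numeric(n)
  for (j in seq_len(n)) {
    contrib <- W[, j] * delayed_E[, j]
    contrib[j] <- 0
    s <- s + contrib
  }
  w1 * E + s + params$P_e
}

#' Time derivatives of the coupled three-population system
#'
#' The right-hand side of the delayed differential system. Per region `i`:
#' \deqn{\tau_e \dot E_i = -E_i + (k_e - E_i)\,F_e(\mathrm{drive}_i,\; w_2 Is_i,\; w_3 Id_i)}
#' \deqn{\tau_i \dot{Is}_i = -Is_i + (k_i - Is_i)\,F_i(w_4 E_i + P_s,\; 0,\; 0)}
#' \deqn{\tau_i \dot{Id}_i = -Id_i + (k_i - Id_i)\,F_i(w_5 E_i + P_d,\; w_6 Is_i + w_7 Id_i,\; 0)}
#' where `drive` is [coupling_drive()] and `F` is [sigmoid_F()]. The
#' subtractive population inhibits by raising the excitatory threshold, the
#' divisive population by dividing the excitatory gain.
#'
#' @param state A [network_state()].
#' @param delayed_E n x n matrix of delayed source activities (see
#'   [coupling_drive()]).
#' @param W Inter-region weight matrix.
#' @param params A [population_params()].
#' @param internal_w Optional n x 7 matrix of per-region internal weights
#'   (columns w1..w7); defaults to the constant weights in `params`.
#'
#' @return List with numeric vectors `dE`, `dIs`, `dId` (units 1/ms).
#' @examples
#' st <- network_state(0, 0, 0)
#' network_rhs(st, matrix(0, 1, 1), matrix(0, 1, 1),
#'             population_params(w = rep(0, 7), P_e = 0, P_s = 0, P_d = 0))
#' @export
network_rhs <- function(state, delayed_E, W, params, internal_w = NULL) {
  E <- state$E; Is <- state$Is; Id <- state$Id
  n <- length(E)
  bad <- !is.finite(E) | !is.finite(Is) | !is.finite(Id)
  if (any(bad)) {
    i <- which(bad)[1]
    pop <- c("E", "Is", "Id")[which(!is.finite(c(E[i], Is[i], Id[i])))[1]]
    abort(sprintf("network_rhs: non-finite state at region %d, population %s.",
                  i, pop))
  }
  if (is.null(internal_w)) {
    wv <- params$w
    w1 <- wv[[1]]; w2 <- wv[[2]]; w3 <- wv[[3]]; w4 <- wv[[4]]
    w5 <- wv[[5]]; w6 <- wv[[6]]; w7 <- wv[[7]]
  } else {
    w1 <- internal_w[, 1]; w2 <- internal_w[, 2]; w3 <- internal_w[, 3]
    w4 <- internal_w[, 4]; w5 <- internal_w[, 5]; w6 <- internal_w[, 6]
    w7 <- internal_w[, 7]
  }
  drive <- coupling_drive(E, delayed_E, W, params, w1 = rep(w1, length.out = n))
  rhs_from_drive(E, Is, Id, drive, params, w2, w3, w4, w5, w6, w7)
}

# population dynamics given the already-computed excitatory drive; shared by
# network_rhs (full-matrix path) and the sparse chunked engine
rhs_from_drive <- function(E, Is, Id, drive, params, w2, w3, w4, w5, w6, w7) {
  a_div <- w3 * Id
  k_e <- if (params$dynamic_k) refractory_k(params$a_e, params$theta_e, a_div) else params$k_e
  Fe <- sigmoid_F(drive, theta = w2 * Is, a = a_div,
                  a_j = params$a_e, theta_j = params$theta_e)
  Fs <- sigmoid_F(w4 * E + params$P_s, 0, 0,
                  a_j = params$a_i, theta_j = params$theta_i)
  Fd <- sigmoid_F(w5 * E + params$P_d, theta = w6 * Is + w7 * Id, a = 0,
                  a_j = params$a_i, theta_j = params$theta_i)
  list(
    dE  = (-E + (k_e - E) * Fe) / params$tau_e,
    dIs = (-Is + (params$k_i - Is) * Fs) / params$tau_i,
    dId = (-Id + (params$k_i - Id) * Fd) / params$tau_i
  )
}
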