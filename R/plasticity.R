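#' Plasticity configuration
#'
#' Controls the Hebbian updates of inter-region ("external") and intra-region
#' ("internal") weights. Updates run every `update_every` solver steps (10 by
#' default, matching the biological timescale argument for not updating at
#' every millisecond step). A learning rate of 0 — or both toggles off —
#' makes every cycle a strict no-op, so such runs are bitwise identical to
#' plasticity-off runs.
#'
#' The default rule is the simplified Hebbian rule with synaptic
#' normalization. `rule = "oja"` swaps in an Oja-style alternative
#' `dW = c * post * (pre - post * W)` through the same plugin seam; it is
#' provided as a non-validated extra.
#'
#' @param c Learning rate, >= 0. The paper behind the model does not print
#'   its value; 0.01 is the package default.
#' @param update_every Solver steps between updates (>= 1), default 10.
#' @param external_on,internal_on Toggles for the two weight classes.
#' @param plastic_internal_set Which of `w1..w7` are subject to updating.
#' @param rule `"hebbian"` (default) or `"oja"`.
#' @return An object of class `plasticity_config`.
#' @export
plasticity_config <- function(c = 0.01, update_every = 10,
                              external_on = TRUE, internal_on = TRUE,
                              plastic_internal_set = paste0("w", 1:7),
                              rule = c("hebbian", "oja")) {
  rule <- match.arg(rule)
  if (!is.numeric(c) || length(c) != 1 || !is.finite(c) || c < 0) {
    abort("plasticity_config: learning rate c must be a single number >= 0.")
  }
  update_every <- as.integer(update_every)
  if (update_every < 1) abort("plasticity_config: update_every must be >= 1.")
  if (!all(plastic_internal_set %in% paste0("w", 1:7))) {
    abort("plasticity_config: plastic_internal_set must be a subset of w1..w7.")
  }
  structure(list(c = c, update_every = update_every,
                 external_on = isTRUE(external_on),
                 internal_on = isTRUE(internal_on),
                 plastic_internal_set = plastic_internal_set,
                 rule = rule),
            class = "plasticity_config")
}

#' Normalize incoming weights to unit sum
#'
#' Synaptic scaling: each region's incoming external weight vector (a row of
#' `W` under the row-equals-target convention) is divided by its sum, so
#' every region with at least one nonzero afferent ends up with incoming
#' weights summing to exactly 1. All-zero rows are left untouched (no
#' division by zero). The operation is idempotent.
#'
#' @param W Non-negative weight matrix (rows = targets), or a single
#'   non-negative vector of incoming weights.
#' @return Normalized matrix or vector of the same shape.
#' @examples
#' normalize_weights(c(0.2, 0.6, 0, 1.2))  # 0.1 0.3 0 0.6
#' @export
normalize_weights <- function(W) {
  if (any(W < 0)) abort("normalize_weights: weights must be non-negative.")
  if (is.matrix(W)) {
    s <- rowSums(W)
    keep <- s > 0
    W[keep, ] <- W[keep, , drop = FALSE] / s[keep]
    return(W)
  }
  s <- sum(W)
  if (s > 0) W / s else W
}

#' Hebbian update of the inter-region weights
#'
#' The simplified Hebbian rule, applied to every existing connection (target
#' `i`, source `j`):
#' \deqn{\Delta W_{ij} = c \; E_j(t - del_{ij}) \; (E_i(t) - E_i(t - 1))}
#' i.e. learning is driven by the delayed presynaptic (source) activity times
#' the change of the postsynaptic (target) activity over the last solver
#' step. Updated weights are clipped at zero, absent connections
#' (`W_ij == 0`) are never touched, and each target's incoming weights are
#' then renormalized to unit sum (see [normalize_weights()]).
#'
#' @param W Weight matrix (rows = targets); zeros mark absent connections.
#' @param delayed_E n x n matrix with `delayed_E[i, j] = E_j(t - D_ij)`.
#' @param E_now,E_prev Excitatory activities at `t` and one solver step
#'   earlier.
#' @param c Learning rate.
#' @param normalize Apply the row normalization afterwards (default TRUE).
#' @return Updated weight matrix.
#' @export
hebbian_update_external <- function(W, delayed_E, E_now, E_prev, c,
                                    normalize = TRUE) {
  n <- nrow(W)
  if (!all(dim(delayed_E) == dim(W))) {
    abort("hebbian_update_external: delayed_E must match W in shape.")
  }
  dpost <- E_now - E_prev
  dW <- c * delayed_E * matrix(dpost, n, ncol(W))  # row i scales with target i
  active <- W != 0
  W[active] <- pmax(0, W[active] + dW[active])
  if (normalize) W <- normalize_weights(W)
  W
}

#' Hebbian update of internal weights
#'
#' The intra-region analogue `dw = c * Pre(t) * (Post(t) - Post(t - 1))`,
#' applied elementwise and clipped at zero. Renormalization across the
#' plastic set of a node is handled by [apply_plasticity_cycle()] (the
#' node's total plastic internal weight is conserved).
#'
#' @param w_k Internal weight value(s).
#' @param pre_now Presynaptic population activity at `t`.
#' @param post_now,post_prev Postsynaptic activity at `t` and `t - step`.
#' @param c Learning rate.
#' @return Updated weight value(s), clipped at 0.
#' @examples
#' hebbian_update_internal(0.5, pre_now = 1, post_now = 0.5,
#'                         post_prev = 0.6, c = 0.01)  # 0.499
#' @export
hebbian_update_internal <- function(w_k, pre_now, post_now, post_prev, c) {
  if (!all(is.finite(pre_now), is.finite(post_now), is.finite(post_prev))) {
    abort("hebbian_update_internal: activities must be finite.")
  }
  pmax(0, w_k + c * pre_now * (post_now - post_prev))
}

# population feeding each internal weight and the population it targets
INTERNAL_PRE  <- c(w1 = "E", w2 = "Is", w3 = "Id", w4 = "E",
                   w5 = "E", w6 = "Is", w7 = "Id")
INTERNAL_POST <- c(w1 = "E", w2 = "E", w3 = "E", w4 = "Is",
                   w5 = "Id", w6 = "Id", w7 = "Id")

#' One full plasticity cycle
#'
#' Performs, in order: the external Hebbian update with row normalization
#' (when enabled), then the internal updates with per-node renormalization
#' that conserves each node's total plastic internal weight. With `c = 0` or
#' both toggles off the cycle is a strict no-op. Weights seen by the
#' integrator change only at these cycle boundaries (they are
#' piecewise-constant in between).
#'
#' @param W External weight matrix (rows = targets).
#' @param internal_w n x 7 matrix of per-region internal weights (columns
#'   `w1..w7`).
#' @param state_now A [network_state()] at the update time `t`.
#' @param state_prev The state one solver step earlier.
#' @param delayed_E n x n matrix of `E_j(t - D_ij)` for existing connections.
#' @param config A [plasticity_config()].
#' @return List with updated `W` and `internal_w`.
#' @export
apply_plasticity_cycle <- function(W, internal_w, state_now, state_prev,
                                   delayed_E, config) {
  if (config$c == 0 || (!config$external_on && !config$internal_on)) {
    return(list(W = W, internal_w = internal_w))
  }
  if (config$external_on) {
    W <- if (config$rule == "oja") {
      oja_update_external(W, delayed_E, state_now$E, config$c)
    } else {
      hebbian_update_external(W, delayed_E, state_now$E, state_prev$E, config$c)
    }
  }
  if (config$internal_on && length(config$plastic_internal_set) > 0) {
    cols <- match(config$plastic_internal_set, paste0("w", 1:7))
    pops_now <- list(E = state_now$E, Is = state_now$Is, Id = state_now$Id)
    pops_prev <- list(E = state_prev$E, Is = state_prev$Is, Id = state_prev$Id)
    new_sub <- internal_w[, cols, drop = FALSE]
    for (s in seq_along(cols)) {
      k <- cols[s]
      pre <- pops_now[[INTERNAL_PRE[k]]]
      post_now <- pops_now[[INTERNAL_POST[k]]]
      post_prev <- pops_prev[[INTERNAL_POST[k]]]
      new_sub[, s] <- hebbian_update_internal(internal_w[, k], pre,
                                              post_now, post_prev, config$c)
    }
    # conserve each node's total plastic internal weight
    before <- rowSums(internal_w[, cols, drop = FALSE])
    after <- rowSums(new_sub)
    keep <- after > 0
    new_sub[keep, ] <- new_sub[keep, , drop = FALSE] * (before[keep] / after[keep])
    internal_w[, cols] <- new_sub
  }
  list(W = W, internal_w = internal_w)
}

# Oja-style alternative rule (plugin seam; non-validated extra)
oja_update_external <- function(W, delayed_E, E_now, c) {
  n <- nrow(W)
  post <- matrix(E_now, n, ncol(W))
  dW <- c * post * (delayed_E - post * W)
  active <- W != 0
  W[active] <- pmax(0, W[active] + dW[active])
  normalize_weights(W)
}
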