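#' Node-level model parameters
#'
#' Collects every constant describing the three populations of one region:
#' time constants, sigmoid gains and thresholds, the seven internal connection
#' weights and the external drives. The paper behind this model does not print
#' its parameter values; the defaults below are package choices tuned to give
#' bounded, well-behaved activity in a single node, and every one of them can be
#' overridden.
#'
#' The seven internal weights, in order, couple: `w1` E->E, `w2` Is->E
#' (subtractive), `w3` Id->E (divisive), `w4` E->Is, `w5` E->Id, `w6` Is->Id
#' (subtractive), `w7` Id->Id (subtractive).
#'
#' The refractory ceilings `k_e`, `k_i` are computed once here with zero
#' divisive input (the static reading of "constant"); setting
#' `dynamic_k = TRUE` makes the integrator recompute `k_e` at every evaluation
#' from the current divisive input `w3 * Id`.
#'
#' @param tau_e,tau_i Time constants (ms) of the excitatory and the two
#'   inhibitory responses; both > 0.
#' @param a_e,a_i Sigmoid gain constants, > 0.
#' @param theta_e,theta_i Sigmoid threshold constants.
#' @param w Numeric vector of the seven internal weights `w1..w7`, all >= 0.
#' @param P_e,P_s,P_d External drive to the E, Is and Id populations.
#' @param dynamic_k Recompute the excitatory refractory ceiling from the
#'   instantaneous divisive input instead of freezing it at configuration time.
#'
#' @return An object of class `population_params`.
#' @examples
#' p <- population_params()
#' p$k_e  # static refractory ceiling of the E population
#' @export
population_params <- function(tau_e = 5, tau_i = 10,
                              a_e = 1, a_i = 1,
                              theta_e = 4, theta_i = 4,
                              w = c(2.4, 1, 1, 2, 2, 0.5, 0.5),
                              P_e = 0.5, P_s = 0.5, P_d = 0.5,
                              dynamic_k = FALSE) {
  stopifnot(length(w) == 7)
  if (!all(vapply(list(tau_e, tau_i, a_e, a_i, theta_e, theta_i,
                       P_e, P_s, P_d), function(v) is.numeric(v) &&
                    length(v) == 1 && is.finite(v), logical(1)))) {
    abort("population_params: all scalar parameters must be finite numbers.")
  }
  if (tau_e <= 0 || tau_i <= 0) abort("population_params: time constants must be > 0.")
  if (a_e <= 0 || a_i <= 0) abort("population_params: sigmoid gains must be > 0.")
  if (any(!is.finite(w)) || any(w < 0)) {
    abort("population_params: internal weights w1..w7 must be finite and >= 0.")
  }
  w <- setNames(as.numeric(w), paste0("w", 1:7))
  out <- list(
    tau_e = tau_e, tau_i = tau_i,
    a_e = a_e, a_i = a_i,
    theta_e = theta_e, theta_i = theta_i,
    w = w,
    P_e = P_e, P_s = P_s, P_d = P_d,
    dynamic_k = isTRUE(dynamic_k),
    # refractory ceilings, frozen at zero divisive input
    k_e = refractory_k(a_e, theta_e, 0),
    k_i = refractory_k(a_i, theta_i, 0)
  )
  structure(out, class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("<population_params>\n")
  cat(sprintf("  tau_e = %g ms, tau_i = %g ms\n", x$tau_e, x$tau_i))
  cat(sprintf("  a_e = %g, theta_e = %g, a_i = %g, theta_i = %g\n",
              x$a_e, x$theta_e, x$a_i, x$theta_i))
  cat("  internal weights:", paste(names(x$w), signif(x$w, 4),
                                   sep = "=", collapse = ", "), "\n")
  cat(sprintf("  drives: P_e = %g, P_s = %g, P_d = %g\n", x$P_e, x$P_s, x$P_d))
  cat(sprintf("  k_e = %.7f, k_i = %.7f (%s)\n", x$k_e, x$k_i,
              if (x$dynamic_k) "recomputed per evaluation" else "static"))
  invisible(x)
}

#' Network state at one instant
#'
#' The activities of all three populations over every region at a single
#' simulation time: firing-rate proxies `E` (excitatory), `Is` (subtractive
#' inhibitory) and `Id` (divisive inhibitory).
#'
#' @param E,Is,Id Numeric vectors of equal length (one entry per region).
#' @param t Simulation time in ms.
#' @return An object of class `network_state`.
#' @examples
#' network_state(E = c(0.1, 0.1), Is = c(0.1, 0.1), Id = c(0.1, 0.1))
#' @export
network_state <- function(E, Is, Id, t = 0) {
  n <- length(E)
  if (length(Is) != n || length(Id) != n) {
    abort("network_state: E, Is, Id must have equal length.")
  }
  if (!all(is.finite(E), is.finite(Is), is.finite(Id))) {
    bad <- which(!is.finite(E) | !is.finite(Is) | !is.finite(Id))[1]
    abort(sprintf("network_state: non-finite activity at region %d.", bad))
  }
  structure(list(t = t, E = as.numeric(E), Is = as.numeric(Is),
                 Id = as.numeric(Id)),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state> t = %g ms, %d regions\n", x$t, length(x$E)))
  cat("  E  :", paste(signif(head(x$E, 6), 4), collapse = " "),
      if (length(x$E) > 6) "..." else "", "\n")
  cat("  Is :", paste(signif(head(x$Is, 6), 4), collapse = " "),
      if (length(x$E) > 6) "..." else "", "\n")
  cat("  Id :", paste(signif(head(x$Id, 6), 4), collapse = " "),
      if (length(x$E) > 6) "..." else "", "\n")
  invisible(x)
}

# pack/unpack between a network_state and the flat vector the integrator uses
state_to_vec <- function(state) c(state$E, state$Is, state$Id)

vec_to_state <- function(y, t = 0) {
  n <- length(y) / 3L
  network_state(E = y[seq_len(n)], Is = y[n + seq_len(n)],
                Id = y[2L * n + seq_len(n)], t = t)
}
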