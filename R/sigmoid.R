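#' Three-argument population input-output function
#'
#' A modified logistic function in which the second argument shifts the curve
#' to higher inputs (subtractive inhibition) and the third divides its gain
#' (divisive inhibition), lowering both the slope at the midpoint and the
#' maximum output. The curve is shifted so that `sigmoid_F(0, 0, 0)` is zero:
#'
#' \deqn{F_j(x,\theta,a) = \frac{1}{1+\exp[-\frac{a_j}{1+a}(x-(\theta_j+\theta))]}
#'   - \frac{1}{1+\exp[\frac{a_j\theta_j}{1+a}]}}
#'
#' All arguments are recycled to a common length.
#'
#' @param x Driver input (dimensionless net excitation).
#' @param theta Subtractive modulator (raises the effective threshold); default 0.
#' @param a Divisive modulator (gain control), must be non-negative; default 0.
#' @param a_j Gain constant of the population, strictly positive.
#' @param theta_j Threshold constant of the population.
#'
#' @return Numeric vector of activation values, strictly increasing in `x`,
#'   bounded above by [refractory_k()].
#' @seealso [refractory_k()] for the saturation value.
#' @examples
#' sigmoid_F(4, 0, 0, a_j = 1, theta_j = 4)  # 0.5 - 1/(1 + e^4)
#' sigmoid_F(4, 0, 1, a_j = 1, theta_j = 4)  # divisive input halves the gain
#' @export
sigmoid_F <- function(x, theta = 0, a = 0, a_j, theta_j) {
  if (!all(is.finite(x), is.finite(theta), is.finite(a))) {
    abort("sigmoid_F: inputs must be finite.")
  }
  if (any(a < 0)) abort("sigmoid_F: divisive modulator `a` must be >= 0.")
  if (any(a_j <= 0)) abort("sigmoid_F: gain constant `a_j` must be > 0.")
  g <- a_j / (1 + a)
  z <- g * (x - (theta_j + theta))
  z <- pmin(pmax(z, -500), 500)
  plogis(z) - plogis(pmin(pmax(-g * theta_j, -500), 500))
}

#' Refractory saturation constant of a population
#'
#' The limit of [sigmoid_F()] as the driver grows without bound,
#' \eqn{k_j = e^{a_j\theta_j/(1+a)} / (1 + e^{a_j\theta_j/(1+a)})},
#' capturing the refractory ceiling of the population's firing rate.
#' By default the model evaluates it once at configuration time with `a = 0`
#' (see `dynamic_k` in [population_params()]).
#'
#' @inheritParams sigmoid_F
#' @return Saturation value in (0, 1).
#' @examples
#' refractory_k(1, 4)      # e^4 / (1 + e^4)
#' refractory_k(1, 4, 1)   # divisive input lowers the ceiling
#' @export
refractory_k <- function(a_j, theta_j, a = 0) {
  if (any(!is.finite(a)) || any(a < 0)) {
    abort("refractory_k: divisive modulator `a` must be finite and >= 0.")
  }
  if (any(a_j <= 0)) abort("refractory_k: gain constant `a_j` must be > 0.")
  plogis(a_j * theta_j / (1 + a))
}
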