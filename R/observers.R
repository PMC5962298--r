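# Simulated observers for the 2AFC illumination discrimination task: a
# parametric observer whose probability correct follows a cumulative Weibull
# with the task's 0.5 guess rate, and a uniformly random responder.

#' Cumulative-Weibull probability correct
#'
#' `p(x) = guess + (1 - guess - lapse) * (1 - exp(-(x/alpha)^beta))` with the
#' task-determined guess rate 0.5.
#'
#' @param x Stimulus magnitude (actual Delta E), `x >= 0`; vectorized.
#' @param alpha Weibull scale (Delta E), > 0.
#' @param beta Weibull slope, > 0.
#' @param lapse Lapse rate in `[0, 0.05]`.
#' @param guess Guess rate (fixed at 0.5 for the 2AFC task).
#' @return Probability correct in `[guess, 1 - lapse]`.
#' @export
weibull_p <- function(x, alpha, beta, lapse = 0, guess = 0.5) {
  guess + (1 - guess - lapse) * (1 - exp(-(x / alpha)^beta))
}

#' Parametric psychometric observer
#'
#' @param alpha,beta,lapse Weibull parameters (possibly per condition and
#'   direction: pass named vectors keyed `"condition.direction"` or scalars
#'   applied everywhere).
#' @return Object of class `psychometric_observer`.
#' @export
psychometric_observer <- function(alpha, beta = 3, lapse = 0.01) {
  stopifnot(all(alpha > 0), all(beta > 0), all(lapse >= 0), all(lapse <= 0.05))
  structure(list(alpha = alpha, beta = beta, lapse = lapse),
            class = c("psychometric_observer", "sim_observer"))
}

#' Uniformly random responder
#'
#' Responds correctly with probability 0.5 on every trial regardless of
#' stimulus.
#'
#' @return Object of class `random_responder`.
#' @export
random_responder <- function() {
  structure(list(), class = c("random_responder", "sim_observer"))
}

# resolve a possibly condition/direction-keyed parameter
.param_for <- function(p, condition, direction) {
  if (length(p) == 1 && is.null(names(p))) return(p)
  key <- paste(condition, direction, sep = ".")
  if (!is.null(names(p)) && key %in% names(p)) return(p[[key]])
  if (!is.null(names(p)) && direction %in% names(p)) return(p[[direction]])
  p[[1]]
}

#' Probability correct of an observer at a stimulus level
#'
#' @param observer A `sim_observer`.
#' @param delta_e Actual Delta E of the trial (>= 0).
#' @param condition,direction Context used to resolve per-condition
#'   parameters.
#' @return Scalar probability.
#' @export
p_correct <- function(observer, delta_e, condition = NULL, direction = NULL) {
  UseMethod("p_correct")
}

#' @export
p_correct.psychometric_observer <- function(observer, delta_e,
                                            condition = NULL, direction = NULL) {
  weibull_p(delta_e,
            .param_for(observer$alpha, condition, direction),
            .param_for(observer$beta, condition, direction),
            .param_for(observer$lapse, condition, direction))
}

#' @export
p_correct.random_responder <- function(observer, delta_e,
                                       condition = NULL, direction = NULL) {
  0.5
}

#' Draw a 2AFC response
#'
#' Bernoulli draw from the observer's probability correct at the trial's
#' stimulus level (uses the current RNG stream).
#'
#' @inheritParams p_correct
#' @return Logical: response correct?
#' @export
respond <- function(observer, delta_e, condition = NULL, direction = NULL) {
  stopifnot(delta_e >= 0)
  stats::runif(1) < p_correct(observer, delta_e, condition, direction)
}

#' Invert the Weibull observer: alpha giving a threshold
#'
#' Convenience for simulation studies: the scale `alpha` for which the
#' psychometric function crosses `criterion` at stimulus level `threshold`.
#'
#' @param threshold Target threshold (Delta E).
#' @param beta,lapse,guess Remaining Weibull parameters.
#' @param criterion Performance criterion (default the 1-up-2-down
#'   equilibrium 0.7071).
#' @return Scalar alpha.
#' @export
alpha_for_threshold <- function(threshold, beta = 3, lapse = 0.01,
                                guess = 0.5, criterion = 0.7071) {
  q <- (criterion - guess) / (1 - guess - lapse)
  stopifnot(q > 0, q < 1)
  threshold / (-log(1 - q))^(1 / beta)
}
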