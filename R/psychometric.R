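#' Psychometric observer model
#'
#' Defines the probability of a correct response as a function of stimulus
#' intensity on a log10 scale. The function is a logistic sigmoid squeezed
#' between the guess rate \eqn{\gamma} (chance performance, 0.5 for 2AFC and
#' 0.25 for 4AFC tasks) and \eqn{1 - \delta} where \eqn{\delta} is the lapse
#' (motor-error) rate:
#' \deqn{P(correct \mid x) = \gamma + (1 - \gamma - \delta)\,F(x;\alpha,\beta)}
#' The threshold \eqn{\alpha} is parameterised so that
#' \eqn{P(correct \mid \alpha) = } \code{target_p} exactly (75\% for 2AFC,
#' 62.5\% for 4AFC), i.e. the threshold *is* the intensity at the task's
#' target-performance level. Intensity is oriented so that larger values are
#' easier.
#'
#' @param threshold Location parameter \eqn{\alpha}, log10 intensity at which
#'   performance equals `target_p`.
#' @param slope Positive logistic slope \eqn{\beta} per log10 unit.
#' @param guess Guess rate \eqn{\gamma} (0.5 for 2AFC, 0.25 for 4AFC).
#' @param lapse Lapse / motor-error rate \eqn{\delta}.
#' @param target_p Performance level defining the threshold; defaults to the
#'   midpoint-like convention 0.75 for 2AFC and 0.625 for 4AFC when `NULL`.
#'
#' @return An object of class `psychometric_model`.
#' @examples
#' m <- psychometric_model(threshold = -1.5, guess = 0.5)
#' prob_correct(-1.5, m)  # 0.75 by construction
#' @export
psychometric_model <- function(threshold = 0, slope = 3.5, guess = 0.5,
                               lapse = 0.03, target_p = NULL) {
  if (is.null(target_p)) {
    target_p <- if (isTRUE(all.equal(guess, 0.25))) 0.625 else 0.75
  }
  stopifnot(
    is.numeric(threshold), length(threshold) == 1L, is.finite(threshold),
    is.finite(slope), slope > 0,
    guess >= 0, guess < 1, lapse >= 0, lapse < 1,
    guess < target_p, target_p < 1 - lapse
  )
  structure(
    list(threshold = threshold, slope = slope, guess = guess,
         lapse = lapse, target_p = target_p),
    class = "psychometric_model"
  )
}

#' @export
print.psychometric_model <- function(x, ...) {
  cat(sprintf(
    "<psychometric_model> alpha = %.4g, beta = %.3g, guess = %.3g, lapse = %.3g, target P = %.4g\n",
    x$threshold, x$slope, x$guess, x$lapse, x$target_p))
  invisible(x)
}

# Inner-sigmoid value at threshold implied by the target-performance convention.
target_f <- function(model) {
  (model$target_p - model$guess) / (1 - model$guess - model$lapse)
}

#' Probability of a correct response
#'
#' Evaluates the psychometric function at one or more log10 intensity levels,
#' optionally overriding the threshold (vectorised over `threshold`, used by
#' the QUEST grid update).
#'
#' @param level Log10 stimulus intensity (numeric vector).
#' @param model A [psychometric_model()].
#' @param threshold Optional vector of candidate thresholds replacing the
#'   model's; `level` must then be scalar or of equal length.
#' @return Probabilities in `[guess, 1 - lapse]`.
#' @export
prob_correct <- function(level, model, threshold = NULL) {
  stopifnot(inherits(model, "psychometric_model"))
  if (!is.numeric(level) || any(!is.finite(level))) {
    stop("`level` must be finite numeric", call. = FALSE)
  }
  alpha <- if (is.null(threshold)) model$threshold else threshold
  # centre so F(alpha) hits the target convention exactly
  x0 <- alpha - stats::qlogis(target_f(model)) / model$slope
  model$guess + (1 - model$guess - model$lapse) *
    stats::plogis(model$slope * (level - x0))
}

#' Simulate Bernoulli responses from an observer
#'
#' @param level Log10 intensity per trial (vector recycled against `n`).
#' @param model A [psychometric_model()].
#' @param n Number of trials when `level` is scalar.
#' @return Logical vector of correct/incorrect responses.
#' @export
simulate_responses <- function(level, model, n = length(level)) {
  p <- prob_correct(rep_len(level, n), model)
  stats::runif(n) < p
}
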