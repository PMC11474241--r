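#' Initialise a QUEST adaptive staircase
#'
#' QUEST maintains a posterior over candidate log10 thresholds on a fixed grid
#' spanning the search space, starting from a Gaussian prior. Each trial is
#' placed at the current posterior mode; responses update the posterior through
#' the psychometric likelihood. The template model supplies the (fixed) slope,
#' guess and lapse rates; only the threshold is treated as unknown.
#'
#' @param search_space Length-2 numeric, lower/upper bound of candidate
#'   log10 thresholds.
#' @param template A [psychometric_model()] whose slope/guess/lapse define the
#'   likelihood (its threshold field is ignored).
#' @param prior_mean Prior mean; defaults to the centre of the search space.
#' @param prior_sd Prior SD; defaults to a quarter of the search-space width.
#' @param grid_n Number of grid points (default 201).
#' @return A `quest_state` object.
#' @export
quest_new <- function(search_space, template, prior_mean = NULL,
                      prior_sd = NULL, grid_n = 201L) {
  stopifnot(length(search_space) == 2L, all(is.finite(search_space)),
            search_space[1] < search_space[2],
            inherits(template, "psychometric_model"))
  if (is.null(prior_mean)) prior_mean <- mean(search_space)
  if (is.null(prior_sd)) prior_sd <- diff(search_space) / 4
  grid <- seq(search_space[1], search_space[2], length.out = grid_n)
  structure(
    list(
      grid = grid,
      log_posterior = stats::dnorm(grid, prior_mean, prior_sd, log = TRUE),
      prior_mean = prior_mean,
      prior_sd = prior_sd,
      template = template,
      history = list(level = numeric(0), correct = logical(0))
    ),
    class = "quest_state"
  )
}

#' Next test level proposed by QUEST
#'
#' Returns the posterior mode over the threshold grid (QUEST's classic
#' placement statistic), which is clipped to the search space by construction.
#'
#' @param state A `quest_state`.
#' @return Log10 intensity for the next trial.
#' @export
quest_next_level <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  lp <- state$log_posterior
  if (all(!is.finite(lp))) stop("degenerate posterior: all mass lost", call. = FALSE)
  # ties broken towards the grid centre so a flat stretch does not drift
  idx <- which(lp == max(lp))
  state$grid[idx[which.min(abs(idx - (length(lp) + 1) / 2))]]
}

#' Bayesian update of a QUEST state after one trial
#'
#' Multiplies the posterior at each candidate threshold by the likelihood of
#' the observed response under the template psychometric function with that
#' candidate threshold, and appends the trial to the history.
#'
#' @param state A `quest_state`.
#' @param level Log10 intensity that was tested.
#' @param correct Logical, whether the response was correct.
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, level, correct) {
  stopifnot(inherits(state, "quest_state"),
            is.numeric(level), length(level) == 1L, is.finite(level),
            is.logical(correct), length(correct) == 1L, !is.na(correct))
  p <- prob_correct(level, state$template, threshold = state$grid)
  state$log_posterior <- state$log_posterior + log(if (correct) p else 1 - p)
  # keep exponentiation well-scaled
  state$log_posterior <- state$log_posterior - max(state$log_posterior)
  state$history$level <- c(state$history$level, level)
  state$history$correct <- c(state$history$correct, correct)
  state
}

#' Normalised posterior over the threshold grid
#'
#' @param state A `quest_state`.
#' @return Numeric vector summing to one, aligned with `state$grid`.
#' @export
quest_posterior <- function(state) {
  w <- exp(state$log_posterior - max(state$log_posterior))
  w / sum(w)
}

#' Run a complete QUEST staircase against a simulated observer
#'
#' Drives `n_trials` of adaptive placement and Bernoulli responding from the
#' observer's true psychometric function, then returns the trial list. This is
#' the generative engine behind the battery simulator.
#'
#' @param observer True [psychometric_model()] generating responses.
#' @param template Template model for the staircase likelihood (defaults to the
#'   observer's shape with unknown threshold).
#' @param search_space Length-2 search-space bounds.
#' @param n_trials Number of adaptive trials.
#' @return A tibble with columns `trial`, `level`, `correct`.
#' @export
run_staircase <- function(observer, search_space, n_trials = 60L,
                          template = observer) {
  state <- quest_new(search_space, template)
  levels <- numeric(n_trials)
  corrects <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    lev <- quest_next_level(state)
    corr <- stats::runif(1) < prob_correct(lev, observer)
    state <- quest_update(state, lev, corr)
    levels[i] <- lev
    corrects[i] <- corr
  }
  tibble::tibble(trial = seq_len(n_trials), level = levels, correct = corrects)
}

#' Maximum-likelihood threshold estimate from all trials of a block
#'
#' Maximises the Bernoulli log-likelihood over a dense grid of candidate
#' thresholds, holding slope, guess and lapse fixed at the template's values.
#' A block is invalid when the estimated point of subjective equality lies on a
#' search-space boundary (`pse_out_of_range`) or when the likelihood carries no
#' usable information (flat over the grid, `no_convergence`); invalid blocks
#' are discarded downstream.
#'
#' @param trials Data frame with numeric `level` and logical `correct` columns,
#'   all trials of one staircase block.
#' @param template A [psychometric_model()] fixing slope/guess/lapse.
#' @param search_space Length-2 bounds of the threshold search.
#' @param grid_n Grid resolution (default 1001).
#' @return A `quest_fit` object with fields `threshold_estimate`, `valid`,
#'   `invalid_reason` (`"none"`, `"pse_out_of_range"` or `"no_convergence"`),
#'   `n_trials` and `logLik`.
#' @export
ml_threshold <- function(trials, template, search_space, grid_n = 1001L) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0L) stop("no trials: cannot estimate a threshold", call. = FALSE)
  stopifnot(all(c("level", "correct") %in% names(trials)),
            all(is.finite(trials$level)), !anyNA(trials$correct))
  grid <- seq(search_space[1], search_space[2], length.out = grid_n)
  ll <- staircase_loglik(trials$level, trials$correct, template, grid)
  best <- which.max(ll)
  flat <- (max(ll) - min(ll)) < 1e-9
  on_boundary <- best == 1L || best == length(grid)
  reason <- if (on_boundary) "pse_out_of_range" else if (flat) "no_convergence" else "none"
  structure(
    list(
      threshold_estimate = grid[best],
      valid = reason == "none",
      invalid_reason = reason,
      n_trials = nrow(trials),
      logLik = ll[best],
      search_space = search_space
    ),
    class = "quest_fit"
  )
}

# Bernoulli log-likelihood of a trial set over a vector of candidate thresholds.
staircase_loglik <- function(level, correct, template, alpha_grid) {
  ll <- numeric(length(alpha_grid))
  for (j in seq_along(alpha_grid)) {
    p <- prob_correct(level, template, threshold = alpha_grid[j])
    ll[j] <- sum(log(ifelse(correct, p, 1 - p)))
  }
  ll
}

#' @export
print.quest_fit <- function(x, ...) {
  cat(sprintf("<quest_fit> alpha-hat = %.4g (%s, %d trials)\n",
              x$threshold_estimate,
              if (x$valid) "valid" else x$invalid_reason, x$n_trials))
  invisible(x)
}

#' Tidy a maximum-likelihood threshold fit
#'
#' @param x A `quest_fit` returned by [ml_threshold()].
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `valid`, `invalid_reason`,
#'   `n_trials`.
#' @export
tidy.quest_fit <- function(x, ...) {
  tibble::tibble(
    estimate = x$threshold_estimate,
    valid = x$valid,
    invalid_reason = x$invalid_reason,
    n_trials = x$n_trials
  )
}

#' Glance at a maximum-likelihood threshold fit
#'
#' @param x A `quest_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `logLik`, `n_trials`, `valid`.
#' @export
glance.quest_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, n_trials = x$n_trials, valid = x$valid)
}
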