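# Shared fixtures and independent oracles used across the suite.

model_2afc <- function(threshold = -1.9, slope = 3.5) {
  psychometric_model(threshold = threshold, slope = slope, guess = 0.5,
                     lapse = 0.03, target_p = 0.75)
}

model_4afc <- function(threshold = -0.1, slope = 3.5) {
  psychometric_model(threshold = threshold, slope = slope, guess = 0.25,
                     lapse = 0.03, target_p = 0.625)
}

con_space <- c(-3, -0.5)

# Independent Bayes-rule posterior over a threshold grid: explicit products of
# per-trial Bernoulli likelihoods with a Gaussian prior, no reuse of the
# package's QUEST update path.
oracle_posterior <- function(grid, prior_mean, prior_sd, levels, corrects,
                             model) {
  post <- dnorm(grid, prior_mean, prior_sd)
  for (i in seq_along(levels)) {
    p <- vapply(grid, function(a) prob_correct(levels[i], model, threshold = a),
                numeric(1))
    post <- post * (if (corrects[i]) p else 1 - p)
  }
  post / sum(post)
}

# Exhaustive fine-grid likelihood search, written independently of
# ml_threshold's internals.
oracle_ml <- function(levels, corrects, model, space, n_grid = 4001) {
  grid <- seq(space[1], space[2], length.out = n_grid)
  ll <- vapply(grid, function(a) {
    p <- prob_correct(levels, model, threshold = a)
    sum(dbinom(as.integer(corrects), 1, p, log = TRUE))
  }, numeric(1))
  grid[which.max(ll)]
}

# Two-sided permutation p-value for a difference-of-means style statistic.
perm_pvalue <- function(a, b, stat, n_perm = 20000) {
  obs <- stat(a, b)
  pooled <- c(a, b)
  n1 <- length(a)
  exceed <- replicate(n_perm, {
    idx <- sample(length(pooled), n1)
    abs(stat(pooled[idx], pooled[-idx])) >= abs(obs) - 1e-12
  })
  mean(exceed)
}

# Small score-level two-repetition study: cohort + observed scores,
# retest-filtered and averaged, for tests that do not need trial-level detail.
quick_scored_study <- function(design, seed, reps = 2) {
  coh <- make_cohort(design, seed = seed)
  sc <- observe_scores(coh$observers, reps = reps, seed = seed + 1)
  list(cohort = coh, scores = sc,
       averaged = average_repetitions(retest_filter(sc)))
}
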