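test_that("student t reproduces the hand-computed example", {
  res <- student_t(c(0, 1, 2), c(1, 2, 3))
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$d, -1.0)
  same <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  expect_equal(same$p, 1)
  expect_error(student_t(rep(1, 5), rep(1, 5)))
})

test_that("welch t reduces to student t under equal variances and equal n", {
  set.seed(41)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(welch_t(a, b)$t, student_t(a, b)$t)
  expect_equal(welch_t(a, a)$t, 0)
  # Satterthwaite limit: df -> n_a - 1 when one group dominates the variance
  big <- rnorm(10, sd = 100); tiny <- rnorm(50, sd = 1e-4)
  expect_equal(welch_t(big, tiny)$df, 9, tolerance = 0.01)
})

test_that("welch anova matches its algebraic identities", {
  set.seed(42)
  a <- rnorm(10); b <- rnorm(12); c <- rnorm(9)
  same <- welch_anova(list(a, a + 0, a))
  expect_equal(same$F, 0, tolerance = 1e-12)
  # two groups: F = t^2 (exact algebraic identity)
  expect_equal(welch_anova(list(a, b))$F, welch_t(a, b)$t^2)
  # balanced homoscedastic case: Welch's F approaches the classical F
  # (for k > 2 the Welch denominator correction keeps them close, not equal)
  x <- rnorm(15); y <- x[sample(15)] + 1; z <- x[sample(15)] - 0.5
  F_classic <- unname(summary(aov(v ~ g, data.frame(
    v = c(x, y, z), g = factor(rep(1:3, each = 15)))))[[1]]$`F value`[1])
  expect_equal(welch_anova(list(x, y, z))$F, F_classic, tolerance = 0.05)
  expect_error(welch_anova(list(a, rep(2, 5))))
  # eta2 within [0, 1]
  expect_true(welch_anova(list(a, b, c))$eta2 >= 0)
  expect_true(welch_anova(list(a, b, c))$eta2 <= 1)
})

test_that("parametric p-values agree with permutation references", {
  set.seed(43)
  meandiff <- function(a, b) mean(a) - mean(b)
  for (k in 1:3) {
    a <- rnorm(15); b <- rnorm(15, mean = 0.4)
    p_perm <- perm_pvalue(a, b, meandiff, n_perm = 20000)
    expect_equal(student_t(a, b)$p, p_perm, tolerance = 0.05)
    expect_equal(welch_t(a, b)$p, p_perm, tolerance = 0.05)
  }
})

test_that("holm adjustment matches the hand step-down and its properties", {
  expect_equal(holm(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm(0.2), 0.2)
  set.seed(44)
  p <- runif(10)
  expect_true(all(holm(p) >= p))
  expect_true(all(holm(p) <= 1))
  expect_error(holm(c(0.5, 1.2)))
})

test_that("spearman correlation honours monotone invariance and the null", {
  x <- seq(-2, 2, length.out = 20)
  expect_equal(spearman(x, x^3)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  set.seed(45)
  res <- spearman(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(res$rho), 0.03)
  expect_equal(res$n_used, 1e4)
  # pairwise deletion
  xm <- c(x, NA); ym <- c(x^3, 5)
  expect_equal(spearman(xm, ym)$n_used, 20L)
  expect_true(is.na(spearman(c(1, 2), c(1, 2))$rho))
})

test_that("partial spearman removes a confound and reduces to plain when irrelevant", {
  set.seed(46)
  n <- 300
  z <- rnorm(n)
  # x and y related only through the covariate
  x <- z + rnorm(n, 0, 0.3)
  y <- z + rnorm(n, 0, 0.3)
  expect_gt(spearman(x, y)$rho, 0.6)
  expect_lt(abs(partial_spearman(x, y, z)$rho), 0.12)

  # covariate independent of both: partial ~ plain
  w <- rnorm(n)
  x2 <- rnorm(n); y2 <- x2 + rnorm(n)
  expect_equal(partial_spearman(x2, y2, w)$rho, spearman(x2, y2)$rho,
               tolerance = 0.05)

  # degenerate covariate falls back to the plain correlation
  fb <- partial_spearman(x2, y2, rep(1, n))
  expect_equal(fb$rho, spearman(x2, y2)$rho)
  expect_true(fb$partial)
})

test_that("effect-size labels follow the conventional bands", {
  expect_equal(effect_label(c(0.1, 0.3, 0.6, 1.2), "d"),
               c("negligible", "small", "medium", "large"))
  expect_equal(effect_label(c(-0.05, -0.2, 0.4, -0.9), "rho"),
               c("negligible", "small", "medium", "large"))
})

test_that("the full analysis produces every table with the right dimensions", {
  des <- cohort_design()
  st <- quick_scored_study(des, seed = 47)
  prep <- preprocess_scores(st$averaged)
  an <- run_full_analysis(prep$scores, st$cohort$symptoms, st$cohort$observers)
  expect_s3_class(an, "vss_analysis")
  expect_equal(nrow(an$group_tests), 7L)
  expect_equal(nrow(an$correlations), 147L)
  expect_equal(nrow(an$colour_anova), 7L)
  expect_equal(nrow(an$colour_posthoc), 21L)
  expect_equal(nrow(an$comorbidity_tests), 14L)
  expect_true(all(an$group_tests$p_holm >= an$group_tests$p))
  # the duration row is age-partialled, everything else is plain
  dur <- an$correlations[an$correlations$symptom == "vss_duration", ]
  expect_true(all(dur$partial))
  expect_true(all(!an$correlations$partial[
    an$correlations$symptom != "vss_duration"]))
  expect_named(glance(an),
               c("n_tests", "n_correlations", "n_group_sig_holm", "n_anova_sig"))
  expect_equal(tidy(an), an$group_tests)
  expect_error(run_full_analysis(dplyr::select(prep$scores, -score),
                                 st$cohort$symptoms),
               "score")
})

test_that("analysis plots build without error", {
  des <- cohort_design()
  st <- quick_scored_study(des, seed = 48)
  prep <- preprocess_scores(st$averaged)
  an <- run_full_analysis(prep$scores, st$cohort$symptoms)
  expect_s3_class(plot_scores(prep$scores), "ggplot")
  expect_s3_class(plot_correlations(an), "ggplot")
  expect_s3_class(autoplot(an), "ggplot")
  expect_s3_class(plot_reliability(reliability_table(st$scores)), "ggplot")
})
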