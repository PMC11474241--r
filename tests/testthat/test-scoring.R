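test_that("the RT effect formula reproduces direct arithmetic", {
  tr <- tibble::tibble(
    rt_ms = c(rep(500, 5), rep(600, 5)),
    correct = TRUE,
    congruent = rep(c(TRUE, FALSE), each = 5)
  )
  # medians 600 vs 500 over a retained mean of 550
  expect_equal(rt_effect(tr)$value, 100 / 550)

  same <- tibble::tibble(rt_ms = rep(550, 10), correct = TRUE,
                         congruent = rep(c(TRUE, FALSE), 5))
  expect_equal(rt_effect(same)$value, 0)
})

test_that("incorrect trials and modified-z outliers are removed before the effect", {
  set.seed(13)
  clean <- tibble::tibble(
    rt_ms = exp(rnorm(60, log(550), 0.1)),
    correct = TRUE,
    congruent = rep(c(TRUE, FALSE), 30)
  )
  res_clean <- rt_effect(clean)

  spiked <- dplyr::bind_rows(
    clean, tibble::tibble(rt_ms = 10000, correct = TRUE, congruent = TRUE))
  res_spiked <- rt_effect(spiked)
  expect_equal(res_spiked$n_outliers_removed, 1L)
  expect_equal(res_spiked$value, res_clean$value)

  # an incorrect trial with an extreme RT never enters the score
  wrong <- dplyr::bind_rows(
    clean, tibble::tibble(rt_ms = 10000, correct = FALSE, congruent = TRUE))
  expect_equal(rt_effect(wrong)$value, res_clean$value)

  # a condition with zero retained trials yields a flagged missing score
  onecond <- tibble::tibble(rt_ms = rep(500, 10), correct = TRUE,
                            congruent = TRUE)
  res <- rt_effect(onecond)
  expect_false(res$valid)
  expect_true(is.na(res$value))
})

test_that("the RT effect is invariant to a common rescaling of all RTs", {
  set.seed(14)
  tr <- tibble::tibble(rt_ms = exp(rnorm(80, log(450), 0.2)),
                       correct = runif(80) > 0.05,
                       congruent = rep(c(TRUE, FALSE), c(56, 24)))
  expect_equal(rt_effect(tr)$value,
               rt_effect(dplyr::mutate(tr, rt_ms = rt_ms * 3.7))$value)
})

test_that("threshold scores convert to reported units and flag invalid blocks", {
  cfg <- battery_config()
  m <- model_2afc(threshold = -1.9)
  set.seed(15)
  st <- run_staircase(m, con_space, 60, template = model_2afc())
  sc <- threshold_score(st, "Con", cfg)
  expect_true(sc$valid)
  # one 60-trial staircase estimates the log threshold to ~0.1 log units
  expect_lt(abs(log10(sc$value) - (-1.9)), 0.3)

  allcorrect <- tibble::tibble(level = rep(-1, 40), correct = TRUE)
  bad <- threshold_score(allcorrect, "Con", cfg)
  expect_false(bad$valid)
  expect_identical(bad$reason, "pse_out_of_range")
  expect_true(is.na(bad$value))
})

test_that("retest filtering excludes both repetitions of an unstable test result", {
  set.seed(16)
  n <- 37
  base <- rnorm(n)
  diffs <- seq(0.04, 0.06, length.out = n)  # ordinary, tightly spread retest gaps
  sc <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:n), each = 2),
    group = "patient",
    test = "Con",
    repetition = rep(1:2, n),
    score = as.vector(rbind(base, base + diffs)),
    valid = TRUE
  )
  # plant a gross instability for one participant
  sc$score[sc$participant_id == "P05" & sc$repetition == 2] <- base[5] + 20
  filt <- retest_filter(sc)
  excl <- filt[filt$excluded, ]
  expect_setequal(unique(excl$participant_id), "P05")
  expect_equal(nrow(excl), 2L)  # both repetitions go
  expect_equal(attr(filt, "n_slots"), 37L)

  # identical differences: nothing excluded
  stable <- dplyr::mutate(sc, score = rep(base, each = 2))
  expect_equal(sum(retest_filter(stable)$excluded), 0L)
})

test_that("averaging keeps the surviving repetition when the other is missing", {
  sc <- tibble::tibble(
    participant_id = c("A", "A", "B"),
    group = "patient", test = "VA",
    repetition = c(1L, 2L, 1L),
    score = c(1.0, 2.0, 5.0), valid = TRUE
  )
  avg <- average_repetitions(sc)
  expect_equal(avg$score[avg$participant_id == "A"], 1.5)
  expect_equal(avg$score[avg$participant_id == "B"], 5.0)
  expect_equal(avg$n_reps_used, c(2L, 1L))
})

test_that("ICC(3,1) matches its defining two-way ANOVA identities", {
  set.seed(17)
  x <- rnorm(20)
  expect_equal(icc31(x, x)$icc, 1.0)
  # consistency ICC ignores a constant session shift
  expect_equal(icc31(x, x + 5)$icc, 1.0)
  # independent pairs: near zero
  expect_lt(abs(icc31(rnorm(1000), rnorm(1000))$icc), 0.1)
  expect_error(icc31(c(1, 2), c(1, 2)))

  # against an explicit aov decomposition
  r1 <- rnorm(15); r2 <- r1 + rnorm(15, 0, 0.7)
  d <- data.frame(y = c(r1, r2),
                  subj = factor(rep(1:15, 2)), sess = factor(rep(1:2, each = 15)))
  ms <- summary(aov(y ~ subj + sess, data = d))[[1]]$`Mean Sq`
  oracle <- (ms[1] - ms[3]) / (ms[1] + ms[3])
  expect_equal(icc31(r1, r2)$icc, oracle, tolerance = 1e-10)
})

test_that("reliability falls monotonically with session noise", {
  mean_icc <- vapply(c(0.02, 0.15, 0.5), function(s) {
    des <- cohort_design(n_patients = 80, n_controls = 2,
                         session_sd_threshold = s, session_sd_rt = s / 2,
                         session_sd_area = s)
    sc <- observe_scores(make_cohort(des, seed = 21)$observers, seed = 22)
    mean(reliability_table(sc)$icc)
  }, numeric(1))
  expect_true(all(diff(mean_icc) < 0))
})

test_that("score_battery scores every block type of a small study", {
  des <- cohort_design(n_patients = 2, n_controls = 2)
  study <- run_study(des, battery_config(), seed = 23)
  sc <- score_battery(study$trials)
  expect_equal(nrow(sc), 4 * 7 * 2)
  expect_true(all(c("score", "valid", "reason") %in% names(sc)))
  hw <- sc$score[sc$test == "HoneyW"]
  expect_true(all(hw > 0))
  va <- sc$score[sc$test == "VA" & sc$valid]
  expect_true(all(va > 0.3 & va < 4))  # decimal acuity range
})
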