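test_that("cohort sizes, groups and demographics follow the design", {
  coh <- make_cohort(cohort_design(), seed = 1)
  expect_equal(nrow(coh$observers), 37L)
  expect_equal(sum(coh$observers$group == "patient"), 20L)
  expect_equal(sum(coh$observers$group == "control"), 17L)
  expect_equal(nrow(coh$symptoms), 20L)
  expect_true(all(coh$observers$age >= 18))
  expect_true(all(!coh$observers$migraine[coh$observers$group == "control"]))
  expect_identical(make_cohort(cohort_design(), seed = 5),
                   make_cohort(cohort_design(), seed = 5))
})

test_that("symptom profiles respect their scale bounds for every seed", {
  d <- cohort_design(n_patients = 30, n_controls = 2)
  for (s in 1:25) {
    sym <- make_cohort(d, seed = s)$symptoms
    for (v in c("vs", "palinopsia", "blue_field", "photopsia", "floaters",
                "flashes_darkness", "photophobia", "nyctalopia")) {
      expect_true(all(sym[[v]] >= 0 & sym[[v]] <= 10))
      expect_true(all(sym[[v]] == round(sym[[v]])))
    }
    expect_true(all(sym$density >= 0 & sym$density <= 6))
    expect_true(all(sym$speed >= 0 & sym$speed <= 4))
    expect_true(all(sym$size >= 0 & sym$size <= 5))
    for (v in grep("^light_", names(sym), value = TRUE)) {
      expect_true(all(sym[[v]] >= 1 & sym[[v]] <= 7))
    }
    expect_true(all(sym$vs_colour %in% 1:5))
    expect_true(all(sym$vss_duration > 0))
  }
  expect_length(symptom_variables(), 21L)
})

test_that("a null severity correlation stays null and a planted one is recovered", {
  null_d <- cohort_design(
    n_patients = 500, n_controls = 2,
    severity_rho = c(VA = 0, Con = 0, CMot = 0, VBM = 0, HoneyW = 0,
                     Stroop = 0, Posner = 0))
  coh <- make_cohort(null_d, seed = 2)
  pat <- coh$observers[coh$observers$group == "patient", ]
  for (col in c("alpha_con", "alpha_cmot", "log_area_honeyw")) {
    expect_lt(abs(cor(pat$latent_severity, pat[[col]], method = "spearman")),
              0.15)
  }

  # planted rho = -0.7 between severity and contrast performance, n = 200
  # (lower contrast threshold = better, so the performance score is -10^alpha)
  d07 <- cohort_design(n_patients = 200, n_controls = 2)
  rec <- vapply(1:100, function(s) {
    p <- make_cohort(d07, seed = 100 + s)$observers
    p <- p[p$group == "patient", ]
    cor(p$latent_severity, -10^p$alpha_con, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rec) - (-0.7)), 0.1)
})

test_that("planted group effects shift the right parameters in the right direction", {
  base <- cohort_design(n_patients = 4000, n_controls = 4000)
  coh <- make_cohort(base, seed = 3)
  obs <- coh$observers
  d_hat <- function(col, orient) {
    a <- obs[[col]][obs$group == "patient"]
    b <- obs[[col]][obs$group == "control"]
    orient * (mean(a) - mean(b)) /
      sqrt((var(a) + var(b)) / 2)
  }
  # defaults plant d = 0.52 (VA), -0.64 (HoneyW) on the performance scale
  expect_lt(abs(d_hat("alpha_va", -1) - 0.52), 0.08)
  expect_lt(abs(d_hat("log_area_honeyw", +1) - (-0.64)), 0.08)
  expect_lt(abs(d_hat("alpha_con", -1) - 0.03), 0.08)
})

test_that("increasing the planted effect increases the recovered effect monotonically", {
  rec <- vapply(c(0, 0.5, 1.0), function(dd) {
    des <- cohort_design(n_patients = 400, n_controls = 400,
                         effect_d = c(VA = 0, Con = dd, CMot = 0, VBM = 0,
                                      HoneyW = 0, Stroop = 0, Posner = 0))
    obs <- make_cohort(des, seed = 9)$observers
    a <- obs$alpha_con[obs$group == "patient"]
    b <- obs$alpha_con[obs$group == "control"]
    -(mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("run_study produces two repetitions per test and honours missingness", {
  des <- cohort_design(n_patients = 3, n_controls = 2)
  study <- run_study(des, battery_config(tests = c("VA", "Stroop", "HoneyW")),
                     seed = 6)
  blocks <- dplyr::count(study$trials, participant_id, test, repetition)
  expect_equal(nrow(blocks), 5 * 3 * 2)
  expect_identical(
    study$trials,
    run_study(des, battery_config(tests = c("VA", "Stroop", "HoneyW")),
              seed = 6)$trials)

  des$missingness <- 0.5
  lossy <- run_study(des, battery_config(tests = c("VA", "Stroop")), seed = 6)
  kept <- dplyr::distinct(lossy$trials, participant_id, test)
  expect_lt(nrow(kept), 10)
  # missingness removes whole participant-test blocks, both repetitions
  reps <- dplyr::count(dplyr::distinct(lossy$trials, participant_id, test,
                                       repetition),
                       participant_id, test)
  expect_true(all(reps$n == 2))
})

test_that("zero session noise makes repeated scores agree up to sampling error", {
  des <- cohort_design(n_patients = 60, n_controls = 2,
                       session_sd_threshold = 0, session_sd_rt = 0,
                       session_sd_area = 0)
  coh <- make_cohort(des, seed = 4)
  sc0 <- observe_scores(coh$observers, seed = 11)
  icc0 <- reliability_table(sc0)
  des2 <- cohort_design(n_patients = 60, n_controls = 2)
  sc1 <- observe_scores(make_cohort(des2, seed = 4)$observers, seed = 11)
  icc1 <- reliability_table(sc1)
  # removing session noise can only improve average reliability
  expect_gt(mean(icc0$icc), mean(icc1$icc) - 0.02)
})
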