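#' Synthetic cohort design
#'
#' Parameterises the generative model for a study-shaped cohort: group sizes,
#' the group effect planted on each test, and the correlation planted between a
#' patient's latent symptom severity and each test's true performance. The
#' defaults emulate the study conditions: 20 patients and 17 controls, patient
#' ages Normal(31.6, 6.55) and control ages Normal(26.0, 5.34) truncated at 18,
#' a 8/20 probability of black-and-white visual snow, 45\% migraine and 80\%
#' tinnitus comorbidity among patients, and per-test effect sizes / severity
#' correlations matching the magnitudes the study reports on its own cohort.
#'
#' `effect_d` is Cohen's d on the performance scale (positive = patients
#' better); `severity_rho` is the Spearman correlation between latent severity
#' (standard normal in patients, fixed at 0 in controls) and performance
#' (negative = more severe, worse). Internally Spearman targets are converted
#' to Pearson loadings via \eqn{r = 2 \sin(\pi \rho / 6)} under the Gaussian
#' copula of the generator.
#'
#' @param n_patients,n_controls Group sizes.
#' @param effect_d Named length-7 vector of planted group effects.
#' @param severity_rho Named length-7 vector of planted severity-performance
#'   Spearman correlations (applies to patients).
#' @param missingness Probability a (participant, test) block is lost (both
#'   repetitions).
#' @param session_sd_threshold,session_sd_rt,session_sd_area Session-to-session
#'   SD of the governing parameter per test family (log10 units for thresholds,
#'   log-RT units for the congruency effect, log10 deg^2 for HoneyW).
#' @param p_bw Probability a patient reports black-and-white snow.
#' @return A `cohort_design` list; also carries the per-test population table
#'   (`population`): control mean and between-subject SD of the governing
#'   parameter and its orientation (+1 when a larger parameter means better
#'   performance, -1 otherwise).
#' @export
cohort_design <- function(n_patients = 20L, n_controls = 17L,
                          effect_d = c(VA = 0.52, Con = 0.03, CMot = 0.32,
                                       VBM = 0.57, HoneyW = -0.64,
                                       Stroop = -0.35, Posner = 0.17),
                          severity_rho = c(VA = -0.18, Con = -0.70,
                                           CMot = -0.55, VBM = -0.19,
                                           HoneyW = -0.36, Stroop = 0.03,
                                           Posner = -0.09),
                          missingness = 0,
                          session_sd_threshold = 0.05,
                          session_sd_rt = 0.02,
                          session_sd_area = 0.08,
                          p_bw = 8 / 20) {
  stopifnot(n_patients >= 1, n_controls >= 1,
            missingness >= 0, missingness < 1,
            all(abs(severity_rho) < 1), p_bw > 0, p_bw < 1)
  population <- tibble::tibble(
    test   = c("VA", "Con", "CMot", "VBM", "HoneyW", "Stroop", "Posner"),
    # governing parameter: log10 threshold intensity, log10 area, or log-RT delta
    mean   = c(-0.10, -1.90, -0.90, 1.50, 1.90, 0.10, 0.03),
    sd     = c(0.10, 0.20, 0.20, 0.25, 0.25, 0.08, 0.04),
    orient = c(-1, -1, -1, -1, +1, -1, -1)
  )
  effect_d <- effect_d[population$test]
  severity_rho <- severity_rho[population$test]
  if (anyNA(effect_d) || anyNA(severity_rho)) {
    stop("`effect_d` and `severity_rho` must name all seven tests", call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
      effect_d = effect_d, severity_rho = severity_rho,
      missingness = missingness,
      session_sd_threshold = session_sd_threshold,
      session_sd_rt = session_sd_rt, session_sd_area = session_sd_area,
      p_bw = p_bw,
      age_patients = c(mean = 31.6, sd = 6.55),
      age_controls = c(mean = 26.0, sd = 5.34),
      p_migraine = 0.45, p_tinnitus = 0.80,
      sigma_rt = 0.15, error_rate = 0.03, adjust_sd = 0.06,
      population = population
    ),
    class = "cohort_design"
  )
}

spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

#' Generate a synthetic cohort of observers and symptom profiles
#'
#' Draws one observer per participant: group, age, comorbidity flags, a latent
#' severity factor (standard normal, patients only), and true parameters for
#' every test. A test's governing parameter is
#' \deqn{\theta_i = \mu_g + b\,s_i + e_i,\qquad e_i \sim N(0,(1-c^2)\sigma^2),}
#' where the group shift \eqn{\mu_{pat} - \mu_{ctl} = d\,\sigma\cdot orient}
#' plants the requested Cohen's d and the loading \eqn{b = c\,\sigma} (with
#' \eqn{c} the Pearson equivalent of the requested Spearman rho, signed by the
#' test's orientation) plants the severity-performance correlation while
#' keeping the patient between-subject SD equal to \eqn{\sigma}.
#'
#' Each patient also receives a 21-variable symptom profile: eight clinical
#' 0--10 ratings, syndrome duration in years, five 30-day-diary characteristic
#' means plus size (on their stated 0--6 / 0--4 / 0--5 ranges), a visual-snow
#' colour category (1 = black and white, ..., 5 = other) and six light-condition
#' severities on the 1--7 scale where 7 is best. Every symptom is a range-mapped
#' monotone (Gaussian-copula) function of loading x severity + noise, so higher
#' severity patients report denser, larger, more distracting snow and worse
#' light-condition scores.
#'
#' @param design A [cohort_design()].
#' @param seed Optional integer seed.
#' @return A list with tibbles `observers` (one row per participant, true
#'   parameters and metadata) and `symptoms` (one row per patient).
#' @examples
#' coh <- make_cohort(cohort_design(), seed = 1)
#' nrow(coh$observers)  # 37
#' @export
make_cohort <- function(design = cohort_design(), seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(seed, {
    n <- design$n_patients + design$n_controls
    group <- rep(c("patient", "control"),
                 c(design$n_patients, design$n_controls))
    id <- sprintf("P%03d", seq_len(n))
    age <- ifelse(
      group == "patient",
      stats::rnorm(n, design$age_patients["mean"], design$age_patients["sd"]),
      stats::rnorm(n, design$age_controls["mean"], design$age_controls["sd"])
    )
    age <- pmax(age, 18)
    severity <- ifelse(group == "patient", stats::rnorm(n), 0)

    obs <- tibble::tibble(
      participant_id = id, group = group, age = age,
      latent_severity = severity,
      migraine = group == "patient" & stats::runif(n) < design$p_migraine,
      tinnitus = group == "patient" & stats::runif(n) < design$p_tinnitus,
      sigma_rt = design$sigma_rt, error_rate = design$error_rate,
      adjust_sd = design$adjust_sd,
      session_sd_threshold = design$session_sd_threshold,
      session_sd_rt = design$session_sd_rt,
      session_sd_area = design$session_sd_area
    )
    pop <- design$population
    for (k in seq_len(nrow(pop))) {
      tname <- pop$test[k]
      c_load <- spearman_to_pearson(design$severity_rho[[tname]]) * pop$orient[k]
      if (abs(c_load) >= 1) stop("infeasible severity correlation for ", tname,
                                 call. = FALSE)
      mu <- pop$mean[k] +
        (group == "patient") * design$effect_d[[tname]] * pop$sd[k] * pop$orient[k]
      b <- c_load * pop$sd[k]
      e_sd <- ifelse(group == "patient", sqrt(1 - c_load^2) * pop$sd[k], pop$sd[k])
      theta <- mu + b * severity + stats::rnorm(n, 0, e_sd)
      col <- switch(tname,
                    VA = "alpha_va", Con = "alpha_con", CMot = "alpha_cmot",
                    VBM = "alpha_vbm", HoneyW = "log_area_honeyw",
                    Stroop = "delta_stroop", Posner = "delta_posner")
      obs[[col]] <- theta
    }
    # baseline log-RT level (ms scale), mild individual differences
    obs$mu_stroop <- stats::rnorm(n, log(650), 0.10)
    obs$mu_posner <- stats::rnorm(n, log(400), 0.10)

    pat <- obs[obs$group == "patient", ]
    symptoms <- make_symptoms(pat, design)
    list(observers = obs, symptoms = symptoms)
  })
}

# Range-mapped monotone symptom from the latent factor: Gaussian copula with
# the given loading, then the scale's quantile map.
symptom_from_latent <- function(severity, loading, lo, hi, integer = FALSE) {
  u <- loading * severity + sqrt(1 - loading^2) * stats::rnorm(length(severity))
  val <- lo + (hi - lo) * stats::pnorm(u)
  if (integer) val <- round(val)
  clamp(val, lo, hi)
}

make_symptoms <- function(patients, design) {
  s <- patients$latent_severity
  n <- nrow(patients)
  # clinical visit ratings, 0-10 integer scales
  clin <- list(vs = 0.80, palinopsia = 0.50, blue_field = 0.45,
               photopsia = 0.50, floaters = 0.40, flashes_darkness = 0.45,
               photophobia = 0.50, nyctalopia = 0.45)
  out <- tibble::tibble(participant_id = patients$participant_id,
                        age = patients$age)
  for (nm in names(clin)) {
    out[[nm]] <- symptom_from_latent(s, clin[[nm]], 0, 10, integer = TRUE)
  }
  # duration in years, weakly severity-linked, right-skewed like real cohorts
  u_dur <- 0.20 * s + sqrt(1 - 0.20^2) * stats::rnorm(n)
  out$vss_duration <- round(exp(log(4) + 1.0 * u_dur), 1)
  # 30-day diary characteristic means (continuous on their stated ranges)
  out$density <- symptom_from_latent(s, 0.70, 0, 6)
  out$speed <- symptom_from_latent(s, 0.20, 0, 4)
  out$surface_dependence <- symptom_from_latent(s, 0.50, 0, 4)
  out$distraction <- symptom_from_latent(s, 0.60, 0, 4)
  out$time_course <- symptom_from_latent(s, 0.40, 0, 4)
  out$size <- symptom_from_latent(s, 0.50, 0, 5)
  out$vs_colour <- sample(1:5, n, replace = TRUE,
                          prob = c(design$p_bw, rep((1 - design$p_bw) / 4, 4)))
  # light-condition severities, 1-7 with 7 = best, hence negative loadings
  for (nm in c("light_sunny", "light_cloudy", "light_rainy", "light_indoor",
               "light_fluorescent", "light_night")) {
    out[[nm]] <- symptom_from_latent(s, -0.50, 1, 7)
  }
  out
}

#' Names of the 21 symptom variables entering the correlation analysis
#'
#' Duration, the eight clinical ratings, the six diary characteristic means
#' (colour excluded: categorical) and the six light-condition severities.
#'
#' @return Character vector of length 21.
#' @export
symptom_variables <- function() {
  c("vss_duration", "vs", "density", "speed", "surface_dependence",
    "distraction", "time_course", "size",
    "light_sunny", "light_cloudy", "light_rainy", "light_indoor",
    "light_fluorescent", "light_night",
    "palinopsia", "blue_field", "photopsia", "floaters", "flashes_darkness",
    "photophobia", "nyctalopia")
}

#' Simulate a full two-repetition study at the trial level
#'
#' Generates a cohort, runs every observer through the full battery twice with
#' independent session noise, and applies block-level missingness. Seeds for
#' every (participant, repetition) session are derived deterministically from
#' the master seed, so a fixed seed reproduces the study bit for bit.
#'
#' @param design A [cohort_design()].
#' @param battery A [battery_config()].
#' @param seed Master seed.
#' @return A list with `trials` (long trial table), `observers`, `symptoms`.
#' @export
run_study <- function(design = cohort_design(), battery = battery_config(),
                      seed = 1L) {
  coh <- make_cohort(design, seed = derive_seed(seed, "cohort"))
  obs <- coh$observers
  sessions <- tidyr::expand_grid(i = seq_len(nrow(obs)), repetition = 1:2)
  trials <- purrr::pmap(sessions, function(i, repetition) {
    simulate_session(
      obs[i, ], battery, repetition,
      seed = derive_seed(seed, paste0(obs$participant_id[i], "_", repetition))
    )
  })
  trials <- dplyr::bind_rows(trials)
  if (design$missingness > 0) {
    blocks <- dplyr::distinct(trials, .data$participant_id, .data$test)
    drop <- with_seed(derive_seed(seed, "missingness"),
                      stats::runif(nrow(blocks)) < design$missingness)
    blocks <- blocks[drop, , drop = FALSE]
    trials <- dplyr::anti_join(trials, blocks, by = c("participant_id", "test"))
  }
  list(trials = trials, observers = obs, symptoms = coh$symptoms)
}

#' Score-level cohort observation (fast path)
#'
#' Skips the trial-level simulation and draws measured scores directly on each
#' test's governing-parameter scale: true parameter + session noise +
#' measurement noise, converted to reported units. The measurement-noise SDs
#' approximate the sampling error of the corresponding trial-level estimators
#' (a 40--60 trial staircase, 15--56 trial RT medians, 2 adjustments) and are
#' used for calibration studies (reliability curves, error-rate simulations)
#' where thousands of cohorts are needed.
#'
#' @param observers Observers tibble from [make_cohort()].
#' @param reps Number of repetitions.
#' @param measurement_sd Named per-test SDs on the parameter scale.
#' @param seed Optional seed.
#' @return Long score tibble: `participant_id`, `group`, `age`, `test`,
#'   `repetition`, `score`, `valid`.
#' @export
observe_scores <- function(observers, reps = 2L,
                           measurement_sd = c(VA = 0.10, Con = 0.08,
                                              CMot = 0.08, VBM = 0.08,
                                              HoneyW = 0.10, Stroop = 0.05,
                                              Posner = 0.035),
                           seed = NULL) {
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      i = seq_len(nrow(observers)),
      test = names(measurement_sd),
      repetition = seq_len(reps)
    )
    param_col <- c(VA = "alpha_va", Con = "alpha_con", CMot = "alpha_cmot",
                   VBM = "alpha_vbm", HoneyW = "log_area_honeyw",
                   Stroop = "delta_stroop", Posner = "delta_posner")
    session_col <- c(VA = "session_sd_threshold", Con = "session_sd_threshold",
                     CMot = "session_sd_threshold", VBM = "session_sd_threshold",
                     HoneyW = "session_sd_area", Stroop = "session_sd_rt",
                     Posner = "session_sd_rt")
    true_p <- mapply(function(i, t) observers[[param_col[[t]]]][i],
                     grid$i, grid$test)
    sess_sd <- mapply(function(i, t) observers[[session_col[[t]]]][i],
                      grid$i, grid$test)
    # one session draw per (participant, test, repetition)
    measured <- true_p + stats::rnorm(nrow(grid), 0, sess_sd) +
      stats::rnorm(nrow(grid), 0, measurement_sd[grid$test])
    tibble::tibble(
      participant_id = observers$participant_id[grid$i],
      group = observers$group[grid$i],
      age = observers$age[grid$i],
      test = grid$test,
      repetition = as.integer(grid$repetition),
      score = param_to_score(measured, grid$test),
      valid = TRUE
    )
  })
}

# Convert a governing parameter to the test's reported unit.
param_to_score <- function(param, test) {
  dplyr::case_when(
    test == "VA" ~ 10^(-param),           # decimal acuity
    test == "Con" ~ 10^param,             # contrast threshold
    test == "CMot" ~ 10^param,            # coherence ratio
    test == "VBM" ~ 10^param,             # ISI in ms
    test == "HoneyW" ~ 10^param,          # ellipse area deg^2
    test %in% c("Stroop", "Posner") ~ expm1(param),  # RT effect ratio
    TRUE ~ NA_real_
  )
}
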