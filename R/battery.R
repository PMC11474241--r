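#' Battery configuration
#'
#' Describes the seven-test battery: four adaptive threshold tasks (Freiburg
#' visual acuity `VA`, contrast sensitivity `Con`, coherent motion `CMot`,
#' visual backward masking `VBM`), one adjustment task (Honeycomb white
#' illusion `HoneyW`) and two reaction-time tasks (`Stroop`, `Posner`).
#' Threshold staircases run on a log10 intensity scale oriented so that larger
#' values are easier; scores are converted back to each test's reported unit
#' (decimal acuity, contrast, coherence ratio, ISI in ms) by [threshold_score()].
#'
#' Defaults follow the study design: 40 adaptive trials for VA (4AFC), 60 for
#' the 2AFC threshold tasks, 2 Honeycomb adjustments, 15 Stroop trials per
#' word-by-colour condition with at most 4 consecutive repeats of a condition,
#' and 80 Posner trials with 70\% cue validity, a 500 ms cue, ISI uniform in
#' 100--600 ms and ITI uniform in 500--1000 ms.
#'
#' @param tests Character vector of test ids to include (default all seven).
#' @param slope Logistic slope per log10 unit shared by the threshold tasks.
#' @param lapse Motor-error (lapse) rate of the observer model.
#' @param stroop_per_condition,stroop_max_run Stroop design constants.
#' @param posner_n,posner_validity,posner_isi,posner_iti,posner_cue_ms Posner
#'   design constants.
#' @return A `battery_config` list with a `tests` tibble (id, type, n_trials,
#'   guess, target_p, search-space bounds, unit) plus RT design parameters.
#' @examples
#' cfg <- battery_config()
#' cfg$tests
#' @export
battery_config <- function(tests = c("VA", "Con", "CMot", "VBM", "HoneyW",
                                     "Stroop", "Posner"),
                           slope = 3.5, lapse = 0.03,
                           stroop_per_condition = 15L, stroop_max_run = 4L,
                           posner_n = 80L, posner_validity = 0.70,
                           posner_isi = c(100, 600), posner_iti = c(500, 1000),
                           posner_cue_ms = 500) {
  stopifnot(posner_validity > 0, posner_validity < 1,
            posner_isi[1] < posner_isi[2], posner_iti[1] < posner_iti[2],
            stroop_per_condition > 0, stroop_max_run >= 1, posner_n > 0)
  all_tests <- tibble::tibble(
    test = c("VA", "Con", "CMot", "VBM", "HoneyW", "Stroop", "Posner"),
    type = c("threshold", "threshold", "threshold", "threshold",
             "adjustment", "rt", "rt"),
    n_trials = c(40L, 60L, 60L, 60L, 2L,
                 4L * stroop_per_condition, posner_n),
    guess = c(0.25, 0.5, 0.5, 0.5, NA, NA, NA),
    target_p = c(0.625, 0.75, 0.75, 0.75, NA, NA, NA),
    space_lo = c(-0.5, -3.0, -2.0, 0.5, NA, NA, NA),
    space_hi = c(1.0, -0.5, 0.0, 2.5, NA, NA, NA),
    unit = c("decimal acuity", "contrast", "coherence ratio", "ISI ms",
             "deg^2", "RT ratio", "RT ratio")
  )
  unknown <- setdiff(tests, all_tests$test)
  if (length(unknown)) stop("unknown test id(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  structure(
    list(
      tests = all_tests[all_tests$test %in% tests, , drop = FALSE],
      slope = slope, lapse = lapse,
      stroop_per_condition = as.integer(stroop_per_condition),
      stroop_max_run = as.integer(stroop_max_run),
      posner_n = as.integer(posner_n), posner_validity = posner_validity,
      posner_isi = posner_isi, posner_iti = posner_iti,
      posner_cue_ms = posner_cue_ms,
      vbm_familiarization = 20L
    ),
    class = "battery_config"
  )
}

# Template psychometric model for one threshold test of a config.
test_template <- function(config, test, threshold = 0) {
  row <- config$tests[config$tests$test == test, ]
  stopifnot(nrow(row) == 1L, row$type == "threshold")
  psychometric_model(threshold = threshold, slope = config$slope,
                     guess = row$guess, lapse = config$lapse,
                     target_p = row$target_p)
}

test_search_space <- function(config, test) {
  row <- config$tests[config$tests$test == test, ]
  c(row$space_lo, row$space_hi)
}

#' Generate a Posner cueing trial sequence
#'
#' Exactly `round(validity * n)` trials are congruent (cue points at the
#' target location); order is a uniform shuffle. Each trial carries an ISI and
#' ITI drawn uniformly from the configured windows.
#'
#' @param n Number of trials.
#' @param validity Cue validity in (0, 1).
#' @param isi_window,iti_window Length-2 ms windows.
#' @param seed Optional integer seed for a reproducible sequence.
#' @return A tibble with `trial_index`, `condition`, `congruent`, `isi_ms`,
#'   `iti_ms`.
#' @export
posner_sequence <- function(n = 80L, validity = 0.70,
                            isi_window = c(100, 600),
                            iti_window = c(500, 1000), seed = NULL) {
  if (!is.numeric(n) || n <= 0) stop("`n` must be positive", call. = FALSE)
  stopifnot(validity > 0, validity < 1)
  n <- as.integer(n)
  with_seed(seed, {
    n_con <- as.integer(round(validity * n))
    congruent <- sample(rep(c(TRUE, FALSE), c(n_con, n - n_con)))
    tibble::tibble(
      trial_index = seq_len(n),
      condition = ifelse(congruent, "congruent", "incongruent"),
      congruent = congruent,
      isi_ms = stats::runif(n, isi_window[1], isi_window[2]),
      iti_ms = stats::runif(n, iti_window[1], iti_window[2])
    )
  })
}

#' Generate a Stroop trial sequence
#'
#' The four conditions are the word-by-ink cells (word red/green written in red
#' or green ink). Each cell appears exactly `per_condition` times in random
#' order, with no cell occurring more than `max_run` times consecutively
#' (constrained shuffle with bounded rejection retries). Congruent trials are
#' those where the word matches the ink.
#'
#' @param per_condition Trials per word-by-ink cell.
#' @param max_run Longest allowed same-cell run.
#' @param seed Optional seed.
#' @param max_tries Rejection-sampling cap.
#' @return A tibble with `trial_index`, `condition`, `congruent`.
#' @export
stroop_sequence <- function(per_condition = 15L, max_run = 4L, seed = NULL,
                            max_tries = 10000L) {
  stopifnot(per_condition >= 1, max_run >= 1)
  cells <- c("red_red", "red_green", "green_red", "green_green")
  pool <- rep(cells, each = per_condition)
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      seq_i <- sample(pool)
      runs <- rle(seq_i)$lengths
      if (max(runs) <= max_run) {
        word <- sub("_.*", "", seq_i)
        ink <- sub(".*_", "", seq_i)
        return(tibble::tibble(
          trial_index = seq_along(seq_i),
          condition = seq_i,
          congruent = word == ink
        ))
      }
    }
    stop("could not satisfy the max-run constraint in ", max_tries, " tries",
         call. = FALSE)
  })
}

#' Simulate one full battery session for one observer
#'
#' Threshold tasks run a complete QUEST staircase against the observer's
#' session-perturbed psychometric function; reaction-time tasks draw lognormal
#' RTs with a congruency effect (log-RT mean shifted by \eqn{\Delta} on
#' incongruent trials) and independent response errors; the Honeycomb task
#' returns the adjusted ellipse area under multiplicative lognormal noise.
#' Session noise perturbs each test's governing parameter once per repetition,
#' which is what limits test--retest reliability downstream.
#'
#' @param observer One row of the observers tibble from [make_cohort()].
#' @param config A [battery_config()].
#' @param repetition Session index (1 or 2).
#' @param seed Optional integer seed; a fixed seed gives a bit-identical
#'   trial list.
#' @return A long tibble of trial records: `participant_id`, `group`, `test`,
#'   `repetition`, `trial_index`, `condition`, `congruent`, `level`, `correct`,
#'   `rt_ms`, `isi_ms`, `iti_ms`. For HoneyW the adjusted area (deg^2) is
#'   recorded in `level`.
#' @export
simulate_session <- function(observer, config = battery_config(),
                             repetition = 1L, seed = NULL) {
  stopifnot(is.data.frame(observer), nrow(observer) == 1L,
            inherits(config, "battery_config"))
  with_seed(seed, {
    out <- purrr::map(config$tests$test, function(tname) {
      row <- config$tests[config$tests$test == tname, ]
      rec <- switch(
        row$type,
        threshold = sim_threshold_block(observer, config, tname, row$n_trials),
        rt = sim_rt_block(observer, config, tname),
        adjustment = sim_adjustment_block(observer, row$n_trials),
        stop("unknown test type for ", tname, call. = FALSE)
      )
      rec$test <- tname
      rec
    })
    trials <- dplyr::bind_rows(out)
    trials$participant_id <- observer$participant_id
    trials$group <- observer$group
    trials$repetition <- as.integer(repetition)
    dplyr::select(
      trials, "participant_id", "group", "test", "repetition", "trial_index",
      "condition", "congruent", "level", "correct", "rt_ms", "isi_ms", "iti_ms"
    )
  })
}

sim_threshold_block <- function(observer, config, tname, n_trials) {
  alpha_true <- observer[[paste0("alpha_", tolower(tname))]] +
    stats::rnorm(1, 0, observer$session_sd_threshold)
  true_model <- test_template(config, tname, threshold = alpha_true)
  space <- test_search_space(config, tname)
  st <- run_staircase(true_model, space, n_trials = n_trials,
                      template = test_template(config, tname))
  tibble::tibble(
    trial_index = st$trial, condition = "staircase", congruent = NA,
    level = st$level, correct = st$correct,
    rt_ms = NA_real_, isi_ms = NA_real_, iti_ms = NA_real_
  )
}

sim_rt_block <- function(observer, config, tname) {
  if (tname == "Stroop") {
    des <- stroop_sequence(config$stroop_per_condition, config$stroop_max_run)
    des$isi_ms <- NA_real_
    des$iti_ms <- NA_real_
  } else {
    des <- posner_sequence(config$posner_n, config$posner_validity,
                           config$posner_isi, config$posner_iti)
  }
  mu <- observer[[paste0("mu_", tolower(tname))]]
  delta <- observer[[paste0("delta_", tolower(tname))]] +
    stats::rnorm(1, 0, observer$session_sd_rt)
  n <- nrow(des)
  log_rt <- stats::rnorm(n, mu + delta * (!des$congruent), observer$sigma_rt)
  tibble::tibble(
    trial_index = des$trial_index, condition = des$condition,
    congruent = des$congruent, level = NA_real_,
    correct = stats::runif(n) > observer$error_rate,
    rt_ms = exp(log_rt), isi_ms = des$isi_ms, iti_ms = des$iti_ms
  )
}

sim_adjustment_block <- function(observer, n_trials) {
  log_area <- observer$log_area_honeyw +
    stats::rnorm(1, 0, observer$session_sd_area)
  area <- 10^(log_area + stats::rnorm(n_trials, 0, observer$adjust_sd))
  tibble::tibble(
    trial_index = seq_len(n_trials), condition = "adjusted_area",
    congruent = NA, level = area, correct = NA,
    rt_ms = NA_real_, isi_ms = NA_real_, iti_ms = NA_real_
  )
}
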