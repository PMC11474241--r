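#' Reaction-time congruency effect for one block
#'
#' Implements the Stroop/Posner effect score: incorrect trials are removed,
#' outlier trials are removed by a modified z-score on log RTs (|z| > 3.5,
#' pooled across conditions by default), and the effect is
#' \deqn{\frac{median(RT_{incongruent}) - median(RT_{congruent})}
#'            {mean(RT_{all\ retained})}}
#' on the raw millisecond scale, giving a dimensionless ratio.
#'
#' @param trials Trial tibble for one participant, one RT test, one repetition;
#'   needs `rt_ms`, `correct`, `congruent`.
#' @param z_cut Modified z cutoff (default 3.5).
#' @param pool_conditions Compute the outlier z pooled across conditions
#'   (default) or within each condition.
#' @return A one-row tibble: `value`, `n_congruent_used`, `n_incongruent_used`,
#'   `n_outliers_removed`, `valid`, `reason`. The value is `NA` (invalid) when
#'   either condition retains no correct trial.
#' @examples
#' tr <- tibble::tibble(rt_ms = c(500, 520, 480, 610, 590, 600),
#'                      correct = TRUE,
#'                      congruent = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' rt_effect(tr)
#' @export
rt_effect <- function(trials, z_cut = 3.5, pool_conditions = TRUE) {
  stopifnot(is.data.frame(trials),
            all(c("rt_ms", "correct", "congruent") %in% names(trials)))
  keep <- trials[!is.na(trials$correct) & trials$correct &
                   is.finite(trials$rt_ms), , drop = FALSE]
  n_out <- 0L
  if (nrow(keep) >= 3L) {
    logs <- log(keep$rt_ms)
    z <- if (pool_conditions) {
      modified_z_safe(logs)
    } else {
      stats::ave(logs, keep$congruent, FUN = modified_z_safe)
    }
    out <- abs(z) > z_cut
    n_out <- sum(out)
    keep <- keep[!out, , drop = FALSE]
  }
  con <- keep$rt_ms[keep$congruent]
  inc <- keep$rt_ms[!keep$congruent]
  if (length(con) < 1L || length(inc) < 1L) {
    return(tibble::tibble(value = NA_real_, n_congruent_used = length(con),
                          n_incongruent_used = length(inc),
                          n_outliers_removed = n_out,
                          valid = FALSE, reason = "empty_condition"))
  }
  tibble::tibble(
    value = (stats::median(inc) - stats::median(con)) / mean(keep$rt_ms),
    n_congruent_used = length(con),
    n_incongruent_used = length(inc),
    n_outliers_removed = n_out,
    valid = TRUE, reason = "none"
  )
}

# modified z that degrades gracefully on zero spread (no trial flagged)
modified_z_safe <- function(x) {
  m <- stats::median(x)
  mad0 <- stats::median(abs(x - m))
  if (mad0 == 0) return(rep(0, length(x)))
  0.6745 * (x - m) / mad0
}

#' Threshold score for one staircase block, in reported units
#'
#' Delegates to [ml_threshold()] and converts the log10 threshold to the test's
#' reported unit: decimal acuity (VA, = 10^-alpha), contrast threshold (Con),
#' coherence ratio (CMot) or ISI in ms (VBM). Blocks with an invalid fit (PSE
#' on the search-space boundary or a non-informative likelihood) yield a
#' missing score with the reason recorded.
#'
#' @param trials Trial tibble of one block (`level`, `correct`).
#' @param test Test id, one of `"VA", "Con", "CMot", "VBM"`.
#' @param config A [battery_config()].
#' @return One-row tibble: `value`, `valid`, `reason`, `n_trials`.
#' @export
threshold_score <- function(trials, test, config = battery_config()) {
  fit <- ml_threshold(trials, test_template(config, test),
                      test_search_space(config, test))
  tibble::tibble(
    value = if (fit$valid) param_to_score(fit$threshold_estimate, test) else NA_real_,
    valid = fit$valid,
    reason = fit$invalid_reason,
    n_trials = fit$n_trials
  )
}

#' Score a full trial table
#'
#' Computes one score per (participant, test, repetition): maximum-likelihood
#' thresholds for the adaptive tasks, the RT congruency effect for Stroop and
#' Posner, and the mean adjusted ellipse area (deg^2) for HoneyW.
#'
#' @param trials Long trial tibble from [run_study()] / [simulate_session()].
#' @param config A [battery_config()].
#' @return Long score tibble: `participant_id`, `group`, `test`, `repetition`,
#'   `score`, `valid`, `reason`.
#' @export
score_battery <- function(trials, config = battery_config()) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  type_of <- stats::setNames(config$tests$type, config$tests$test)
  trials |>
    dplyr::group_by(.data$participant_id, .data$group, .data$test,
                    .data$repetition) |>
    dplyr::group_modify(function(d, key) {
      switch(
        type_of[[key$test]],
        threshold = threshold_score(d, key$test, config)[, c("value", "valid", "reason")],
        rt = rt_effect(d)[, c("value", "valid", "reason")],
        adjustment = tibble::tibble(
          value = mean(d$level, na.rm = TRUE), valid = TRUE, reason = "none")
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(score = "value")
}

#' Test-retest outlier filter
#'
#' For each test, the absolute difference between the repetition-1 and
#' repetition-2 scores is computed across all participants (groups merged) and
#' participants whose difference is an outlier by the modified z-score
#' criterion (|z| > 3.5) have that test excluded entirely -- both repetitions --
#' flagging exceptional performance instability or stability.
#'
#' @param scores Long score tibble from [score_battery()] (needs `score`,
#'   `repetition` in 1:2).
#' @param z_cut Modified z cutoff.
#' @return The score tibble with logical `excluded` and `exclusion_reason`
#'   columns added, plus attributes `n_slots` (participant-by-test results
#'   scanned) and `n_excluded`.
#' @export
retest_filter <- function(scores, z_cut = 3.5) {
  stopifnot(all(c("participant_id", "test", "repetition", "score")
                %in% names(scores)))
  wide <- scores |>
    dplyr::filter(!is.na(.data$score)) |>
    tidyr::pivot_wider(id_cols = c("participant_id", "test"),
                       names_from = "repetition", values_from = "score",
                       names_prefix = "rep")
  n_slots <- dplyr::n_distinct(scores$participant_id) *
    dplyr::n_distinct(scores$test)
  excl <- wide |>
    dplyr::filter(!is.na(.data$rep1), !is.na(.data$rep2)) |>
    dplyr::group_by(.data$test) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3L) {
        warning("fewer than 3 complete pairs for ", key$test,
                "; retest filter skipped", call. = FALSE)
        return(d[0, "participant_id"])
      }
      z <- modified_z_safe(abs(d$rep1 - d$rep2))
      d[abs(z) > z_cut, "participant_id"]
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(excluded = TRUE)
  out <- scores |>
    dplyr::left_join(excl, by = c("participant_id", "test")) |>
    dplyr::mutate(
      excluded = !is.na(.data$excluded),
      exclusion_reason = ifelse(.data$excluded, "retest_outlier", "none")
    )
  attr(out, "n_slots") <- n_slots
  attr(out, "n_excluded") <- nrow(excl)
  out
}

#' Average the valid repetitions into one score per participant per test
#'
#' Cells excluded by the retest filter (or invalid blocks) do not contribute;
#' a participant keeps a score whenever at least one valid repetition remains.
#'
#' @param scores Output of [retest_filter()] (or [score_battery()]; then
#'   nothing is excluded).
#' @return Tibble `participant_id`, `group`, `test`, `score`, `n_reps_used`.
#' @export
average_repetitions <- function(scores) {
  if (!"excluded" %in% names(scores)) scores$excluded <- FALSE
  scores |>
    dplyr::filter(!.data$excluded, !is.na(.data$score)) |>
    dplyr::group_by(.data$participant_id, .data$group, .data$test) |>
    dplyr::summarise(n_reps_used = dplyr::n(),
                     score = mean(.data$score), .groups = "drop")
}

#' Intraclass correlation ICC(3,1) for test-retest reliability
#'
#' Two-way mixed-effects, single-rater, consistency ICC: from the two-way
#' ANOVA decomposition with subjects as rows and the k sessions as columns,
#' \deqn{ICC(3,1) = \frac{MS_{rows} - MS_{error}}
#'                       {MS_{rows} + (k-1)\,MS_{error}}.}
#' Session (column) main effects are removed, so a constant shift between
#' repetitions does not lower the coefficient. Incomplete pairs are dropped.
#'
#' @param rep1,rep2 Score vectors for the two repetitions.
#' @return An `icc_fit` object (fields `icc`, `ms_rows`, `ms_error`, `n`, `k`,
#'   `defined`); `tidy()` and `glance()` methods available.
#' @examples
#' x <- rnorm(20); icc31(x, x + rnorm(20, sd = 0.2))
#' @export
icc31 <- function(rep1, rep2) {
  ok <- is.finite(rep1) & is.finite(rep2)
  x <- cbind(rep1[ok], rep2[ok])
  n <- nrow(x); k <- 2L
  if (n < 3L) stop("need at least 3 complete pairs for ICC(3,1)", call. = FALSE)
  grand <- mean(x)
  ss_rows <- k * sum((rowMeans(x) - grand)^2)
  ss_cols <- n * sum((colMeans(x) - grand)^2)
  ss_err <- sum((x - grand)^2) - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_rows + (k - 1) * ms_err
  defined <- denom > 0 && ms_rows > 0
  structure(
    list(icc = if (defined) (ms_rows - ms_err) / denom else NA_real_,
         ms_rows = ms_rows, ms_error = ms_err, n = n, k = k,
         defined = defined),
    class = "icc_fit"
  )
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("<icc_fit> ICC(3,1) = %.3f (n = %d pairs)\n", x$icc, x$n))
  invisible(x)
}

#' @rdname icc31
#' @param x An `icc_fit`.
#' @param ... Unused.
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(icc = x$icc, ms_rows = x$ms_rows, ms_error = x$ms_error,
                 n = x$n, defined = x$defined)
}

#' @rdname icc31
#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(icc = x$icc, n = x$n, k = x$k, defined = x$defined)
}

#' Per-test reliability table for a two-repetition score table
#'
#' @param scores Long score tibble with both repetitions.
#' @return Tibble with one ICC(3,1) row per test.
#' @export
reliability_table <- function(scores) {
  scores |>
    tidyr::pivot_wider(id_cols = c("participant_id", "test"),
                       names_from = "repetition", values_from = "score",
                       names_prefix = "rep") |>
    dplyr::group_by(.data$test) |>
    dplyr::group_modify(~ tidy(icc31(.x$rep1, .x$rep2))) |>
    dplyr::ungroup()
}
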