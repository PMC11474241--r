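#' Full group and symptom analysis of a preprocessed score table
#'
#' Runs the study's statistical layer on a preprocessed (higher-is-better,
#' z-scored) score table:
#' \enumerate{
#'   \item patient-versus-control two-tailed Student t-tests per test, with
#'     Bonferroni-Holm correction and Cohen's d;
#'   \item comorbidity splits within patients (tinnitus and migraine yes/no)
#'     compared by Welch t-tests;
#'   \item visual-snow-colour analysis: one-way Welch ANOVA over three groups
#'     (controls, black-and-white snow, other colours) per test with classical
#'     eta-squared, followed by post-hoc pairwise Welch t-tests Holm-corrected
#'     over the three comparisons;
#'   \item the tests-by-symptoms Spearman correlation matrix within patients
#'     (7 x 21 = 147 cells, pairwise deletion, uncorrected by design -- an
#'     exploratory analysis read through effect sizes), with the duration row
#'     partialled for age.
#' }
#'
#' @param preprocessed Long tibble `participant_id`, `group`, `test`, `score`
#'   from [preprocess_scores()].
#' @param symptoms Patient symptom tibble from [make_cohort()] (needs the 21
#'   symptom columns, `vs_colour` and `age`).
#' @param observers Observers tibble (for the comorbidity flags); optional --
#'   when absent the comorbidity block is skipped.
#' @return A `vss_analysis` object: list of tibbles `group_tests`,
#'   `comorbidity_tests`, `colour_anova`, `colour_posthoc`, `correlations`.
#' @export
run_full_analysis <- function(preprocessed, symptoms, observers = NULL) {
  need <- c("participant_id", "group", "test", "score")
  missing_cols <- setdiff(need, names(preprocessed))
  if (length(missing_cols)) {
    stop("preprocessed scores lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tests <- unique(preprocessed$test)
  wide <- tidyr::pivot_wider(preprocessed, id_cols = c("participant_id", "group"),
                             names_from = "test", values_from = "score")

  # (1) patients vs controls, Student t + Holm + d
  group_tests <- purrr::map_dfr(tests, function(tn) {
    a <- wide[[tn]][wide$group == "patient"]
    b <- wide[[tn]][wide$group == "control"]
    dplyr::bind_cols(tibble::tibble(test = tn), student_t(a, b))
  })
  group_tests$p_holm <- holm(group_tests$p)
  group_tests$magnitude <- effect_label(group_tests$d, "d")

  # (2) comorbidity splits within patients, Welch t
  comorbidity_tests <- NULL
  if (!is.null(observers) &&
      all(c("migraine", "tinnitus") %in% names(observers))) {
    pat <- dplyr::inner_join(
      wide[wide$group == "patient", ],
      observers[, c("participant_id", "migraine", "tinnitus")],
      by = "participant_id")
    comorbidity_tests <- purrr::map_dfr(c("tinnitus", "migraine"), function(cm) {
      purrr::map_dfr(tests, function(tn) {
        a <- pat[[tn]][!pat[[cm]]]   # symptom-free
        b <- pat[[tn]][pat[[cm]]]
        res <- tryCatch(welch_t(a, b), error = function(e) {
          tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                         d = NA_real_, n1 = sum(is.finite(a)),
                         n2 = sum(is.finite(b)), method = "welch")
        })
        dplyr::bind_cols(tibble::tibble(comorbidity = cm, test = tn), res)
      })
    })
  }

  # (3) colour subgroups: controls / black-and-white / other
  colour <- symptoms[, c("participant_id", "vs_colour")]
  wide3 <- dplyr::left_join(wide, colour, by = "participant_id") |>
    dplyr::mutate(colour_group = dplyr::case_when(
      group == "control" ~ "control",
      vs_colour == 1 ~ "bw",
      TRUE ~ "other"
    ))
  colour_anova <- purrr::map_dfr(tests, function(tn) {
    gs <- split(wide3[[tn]], wide3$colour_group)
    res <- tryCatch(welch_anova(gs), error = function(e) {
      tibble::tibble(F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                     p = NA_real_, eta2 = NA_real_, n = NA_integer_)
    })
    dplyr::bind_cols(tibble::tibble(test = tn), res)
  })
  pairs <- list(c("bw", "other"), c("control", "bw"), c("control", "other"))
  colour_posthoc <- purrr::map_dfr(tests, function(tn) {
    ph <- purrr::map_dfr(pairs, function(pr) {
      a <- wide3[[tn]][wide3$colour_group == pr[1]]
      b <- wide3[[tn]][wide3$colour_group == pr[2]]
      res <- tryCatch(welch_t(a, b), error = function(e) {
        tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_, d = NA_real_,
                       n1 = NA_integer_, n2 = NA_integer_, method = "welch")
      })
      dplyr::bind_cols(tibble::tibble(test = tn, group1 = pr[1],
                                      group2 = pr[2]), res)
    })
    ph$p_holm <- holm(ph$p)
    ph
  })

  # (4) 7 x 21 Spearman matrix within patients; duration age-partialled
  pat_scores <- wide[wide$group == "patient", ]
  joined <- dplyr::inner_join(pat_scores, symptoms, by = "participant_id")
  correlations <- purrr::map_dfr(tests, function(tn) {
    purrr::map_dfr(symptom_variables(), function(sv) {
      res <- if (sv == "vss_duration") {
        partial_spearman(joined[[tn]], joined[[sv]], joined$age)
      } else {
        spearman(joined[[tn]], joined[[sv]])
      }
      dplyr::bind_cols(tibble::tibble(test = tn, symptom = sv), res)
    })
  })
  correlations$magnitude <- effect_label(correlations$rho, "rho")

  structure(
    list(group_tests = group_tests, comorbidity_tests = comorbidity_tests,
         colour_anova = colour_anova, colour_posthoc = colour_posthoc,
         correlations = correlations, tests = tests),
    class = "vss_analysis"
  )
}

#' @export
print.vss_analysis <- function(x, ...) {
  cat("<vss_analysis>\n")
  cat(sprintf("  %d group comparisons, %d correlation cells\n",
              nrow(x$group_tests), nrow(x$correlations)))
  sig <- x$group_tests$test[x$group_tests$p_holm < 0.05]
  cat("  Holm-significant group differences: ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}

#' Tidy the group-comparison table of a full analysis
#'
#' @param x A `vss_analysis`.
#' @param ... Unused.
#' @return Tibble: one Student t-test row per test (`t`, `df`, `p`, `p_holm`,
#'   `d`, `magnitude`).
#' @export
tidy.vss_analysis <- function(x, ...) x$group_tests

#' One-row summary counts of a full analysis
#'
#' @param x A `vss_analysis`.
#' @param ... Unused.
#' @return One-row tibble: numbers of tests, correlation cells, and
#'   Holm-significant group differences.
#' @export
glance.vss_analysis <- function(x, ...) {
  tibble::tibble(
    n_tests = length(x$tests),
    n_correlations = nrow(x$correlations),
    n_group_sig_holm = sum(x$group_tests$p_holm < 0.05, na.rm = TRUE),
    n_anova_sig = sum(x$colour_anova$p < 0.05, na.rm = TRUE)
  )
}
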