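#' Pipeline run configuration
#'
#' Bundles the master seed, cohort design, battery configuration and
#' preprocessing switches into one serialisable object. Every stochastic stage
#' derives its own seed deterministically from the master seed, so a
#' configuration fully determines the output bundle.
#'
#' @param seed Master integer seed.
#' @param design A [cohort_design()].
#' @param battery A [battery_config()].
#' @param z_cut Modified z cutoff used throughout.
#' @param pool_conditions RT outlier z pooled across conditions (see
#'   [rt_effect()]).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, design = cohort_design(),
                       battery = battery_config(), z_cut = 3.5,
                       pool_conditions = TRUE) {
  structure(
    list(seed = as.integer(seed), design = design, battery = battery,
         z_cut = z_cut, pool_conditions = pool_conditions),
    class = "run_config"
  )
}

#' Write / read a run configuration as YAML
#'
#' Round-trips the scalar fields of a [run_config()] (seed, design parameters,
#' battery constants, preprocessing switches).
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  d <- config$design
  b <- config$battery
  yaml::write_yaml(list(
    seed = config$seed, z_cut = config$z_cut,
    pool_conditions = config$pool_conditions,
    design = list(
      n_patients = d$n_patients, n_controls = d$n_controls,
      effect_d = as.list(d$effect_d), severity_rho = as.list(d$severity_rho),
      missingness = d$missingness,
      session_sd_threshold = d$session_sd_threshold,
      session_sd_rt = d$session_sd_rt, session_sd_area = d$session_sd_area,
      p_bw = d$p_bw
    ),
    battery = list(
      tests = b$tests$test, slope = b$slope, lapse = b$lapse,
      stroop_per_condition = b$stroop_per_condition,
      stroop_max_run = b$stroop_max_run,
      posner_n = b$posner_n, posner_validity = b$posner_validity,
      posner_isi = b$posner_isi, posner_iti = b$posner_iti,
      posner_cue_ms = b$posner_cue_ms
    )
  ), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- do.call(cohort_design, c(
    y$design[c("n_patients", "n_controls", "missingness",
               "session_sd_threshold", "session_sd_rt", "session_sd_area",
               "p_bw")],
    list(effect_d = unlist(y$design$effect_d),
         severity_rho = unlist(y$design$severity_rho))
  ))
  battery <- do.call(battery_config, c(
    list(tests = y$battery$tests),
    y$battery[c("slope", "lapse", "stroop_per_condition", "stroop_max_run",
                "posner_n", "posner_validity", "posner_cue_ms")],
    list(posner_isi = unlist(y$battery$posner_isi),
         posner_iti = unlist(y$battery$posner_iti))
  ))
  run_config(seed = y$seed, design = design, battery = battery,
             z_cut = y$z_cut, pool_conditions = y$pool_conditions)
}

#' Run the complete pipeline
#'
#' Simulate a cohort, run the battery twice per participant, score every
#' block, apply the test-retest filter, average repetitions, preprocess, and
#' run the full statistical analysis. When `out_dir` is given, writes
#' `trials.csv`, `scores.csv`, `symptoms.csv`, `preprocessed_scores.csv`,
#' `transform_log.json`, `group_tests.tsv`, `correlations.tsv` and
#' `reliability.tsv` (UTF-8, comma/tab separated, empty string for missing).
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return Invisibly, a list with every intermediate: `trials`, `observers`,
#'   `symptoms`, `scores`, `filtered`, `averaged`, `reliability`,
#'   `preprocessed`, `transforms`, `analysis`, `log`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  study <- run_study(config$design, config$battery, seed = config$seed)
  scores <- score_battery(study$trials, config$battery)
  filtered <- retest_filter(scores, z_cut = config$z_cut)
  reliability <- reliability_table(
    dplyr::filter(filtered, !.data$excluded))
  averaged <- average_repetitions(filtered)
  prep <- preprocess_scores(averaged, z_cut = config$z_cut)
  analysis <- run_full_analysis(prep$scores, study$symptoms, study$observers)
  log <- tibble::tibble(
    stage = c("trials", "scores", "retest_excluded", "averaged",
              "preprocess_outliers", "missing_final"),
    n = c(nrow(study$trials), nrow(scores), attr(filtered, "n_excluded"),
          nrow(averaged),
          sum(prep$transforms$n_outliers_pass2, na.rm = TRUE),
          sum(is.na(prep$scores$score)))
  )
  out <- list(trials = study$trials, observers = study$observers,
              symptoms = study$symptoms, scores = scores, filtered = filtered,
              averaged = averaged, reliability = reliability,
              preprocessed = prep$scores, transforms = prep$transforms,
              analysis = analysis, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) readr::write_csv(x, file.path(out_dir, f), na = "")
    wr(study$trials, "trials.csv")
    wr(filtered, "scores.csv")
    wr(study$symptoms, "symptoms.csv")
    wr(prep$scores, "preprocessed_scores.csv")
    readr::write_tsv(analysis$group_tests, file.path(out_dir, "group_tests.tsv"),
                     na = "")
    readr::write_tsv(analysis$correlations, file.path(out_dir, "correlations.tsv"),
                     na = "")
    readr::write_tsv(reliability, file.path(out_dir, "reliability.tsv"), na = "")
    jsonlite::write_json(
      list(transforms = prep$transforms, log = log,
           seed = config$seed),
      file.path(out_dir, "transform_log.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  invisible(out)
}
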