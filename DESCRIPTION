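Package: vssbattery
Title: Simulation and Analysis of a Visual Snow Syndrome Psychophysical Test Battery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse a seven-test psychophysical battery
    for visual snow syndrome studies. Implements a QUEST adaptive staircase with
    maximum-likelihood threshold estimation under a logistic psychometric model,
    reaction-time congruency scoring for Stroop and Posner tasks, test-retest
    filtering and ICC(3,1) reliability, a robust modified z-score / Yeo-Johnson
    preprocessing chain, and the group-comparison and symptom-correlation
    statistical layer (Student and Welch t-tests, Welch one-way ANOVA,
    Bonferroni-Holm correction, Spearman and age-partialled partial
    correlations). A synthetic-cohort generator with a latent severity factor
    provides fully reproducible study-shaped data for power, calibration and
    parameter-recovery work.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
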