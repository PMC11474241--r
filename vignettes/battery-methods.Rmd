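---
title: "Methods: simulating and analysing a visual snow psychophysical battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a visual snow psychophysical battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vssbattery)
```

## Overview

Visual snow syndrome (VSS) studies compare patients and controls on batteries
of psychophysical tests — adaptive threshold tasks (visual acuity, contrast
sensitivity, coherent motion, visual backward masking), an illusion adjustment
task (the Honeycomb white illusion) and speeded attention tasks (Stroop,
Posner) — and relate test performance to clinical symptom profiles. Because
individual-level clinical data are rarely public, method development needs a
generative stand-in with the same statistical structure. This package provides
both halves: the full computational chain that turns trial-level responses into
group- and symptom-level statistics, and a synthetic-cohort simulator whose
outputs exercise every stage of that chain.

This vignette documents the models, the tunable parameters and their defaults,
the numerical choices, and what the simulator does and does not emulate.

## The psychometric observer model

Threshold tasks assume a logistic psychometric function on a log10 intensity
scale, bounded by the guess rate $\gamma$ and the lapse (motor-error) rate
$\delta$:

$$P(\text{correct} \mid x) = \gamma + (1 - \gamma - \delta)\,
  \frac{1}{1 + e^{-\beta (x - x_0)}}.$$

Conventions:

* $\gamma = 0.5$ for the 2AFC tasks and $0.25$ for the 4AFC acuity task;
  $\delta = 0.03$ throughout.
* The threshold $\alpha$ is *defined* as the intensity at the task's target
  performance level — 75% correct for 2AFC, 62.5% for 4AFC — so the adaptive
  placement target and the reported score are the same quantity. The logistic
  midpoint $x_0$ is derived from $\alpha$, $\beta$, $\gamma$, $\delta$ and the
  target; `prob_correct(alpha, model)` returns the target level exactly.
* Intensity is oriented so larger = easier. Scores are converted to each
  test's reported unit afterwards (decimal acuity $= 10^{-\alpha}$; contrast,
  coherence and ISI thresholds $= 10^{\alpha}$).
* The slope $\beta$ is fixed at 3.5 per log10 unit for every test. Only the
  threshold is estimated; slope, guess and lapse are treated as known. This
  choice keeps the estimation problem one-dimensional and is the conventional
  simplification when slopes are not themselves of interest.

The logistic family was chosen over cumulative-Gaussian or Weibull
alternatives for its closed forms and numerical robustness; at matched slope
the three families are nearly indistinguishable over the performance range an
adaptive procedure visits.

## QUEST placement and maximum-likelihood scoring

`quest_new()` holds a posterior over 201 candidate thresholds spanning the
test's search space. The prior is Gaussian with mean at the centre of the
search space and SD equal to one quarter of its width — wide enough to be
weakly informative, narrow enough to anchor the first trials. Each trial is
placed at the posterior mode (QUEST's classic placement statistic; a posterior
mean or quantile variant would behave nearly identically here) and the
response multiplies the posterior by the Bernoulli likelihood.

The *score* of a block is not the final posterior but a maximum-likelihood
estimate over all trials of the block (`ml_threshold()`), maximised on a dense
grid of 1001 candidates. A block is discarded as invalid when

* the estimate lands on a search-space boundary (`pse_out_of_range`), as
  happens when a participant is at ceiling or floor everywhere tested, or
* the likelihood is flat over the grid (`no_convergence`), i.e. the trials
  carry no information about the threshold.

No numeric convergence criterion beyond these two conditions is imposed; a
boundary or non-informative likelihood is exactly what "the fit did not
converge" means for a one-parameter grid search.

Calibration (recomputed by the test suite and the acceptance script): over 500
simulated 60-trial 2AFC staircases, the observer's true probability correct at
the estimated threshold averages within a few tenths of a percentage point of
the 75% target, and the threshold RMSE of a 60-trial block is roughly 0.1
log10 units, shrinking with trial count.

## Reaction-time tasks

Stroop trials are the four word-by-ink cells, 15 each, shuffled under the
constraint that no cell repeats more than four times in a row (rejection
sampling with a 10,000-try cap — at these sizes a valid shuffle is found in a
handful of tries). Posner sequences contain exactly
$\mathrm{round}(0.7 \times 80) = 56$ congruent trials — fixed design
proportions, not Bernoulli draws — with per-trial ISI uniform in 100–600 ms
and ITI uniform in 500–1000 ms.

Simulated RTs are lognormal: $\log RT \sim N(\mu + \Delta\,[\text{incongruent}],
\sigma^2)$ with independent response errors at rate 3%. Scoring
(`rt_effect()`) removes incorrect trials, removes outliers by a modified
z-score on log RTs with the 3.5 criterion (pooled across conditions by
default; per-condition pooling is a switch), and reports

$$\text{effect} = \frac{\mathrm{median}(RT_{inc}) - \mathrm{median}(RT_{con})}
 {\mathrm{mean}(RT_{\text{all retained}})},$$

a dimensionless ratio invariant to a common rescaling of all RTs. The
denominator is the mean of all retained correct trials across both conditions
on the raw millisecond scale; whether the original convention included
incorrect trials in the denominator is ambiguous, so the retained-correct
reading is used and kept behind one function so it can be changed in one
place.

## Test–retest filtering, reliability, averaging

Every test is administered twice. Per test, with groups merged, the absolute
difference between the two repetition scores is formed across participants and
participants whose difference is a modified-z outlier (|z| > 3.5) lose that
test entirely — both repetitions — on the grounds that exceptional instability
(or suspicious stability) makes the average meaningless. When the differences
are all identical the MAD is zero and the filter degrades to excluding nobody.

Reliability is summarised by ICC(3,1), the two-way mixed-effects single-rater
consistency coefficient,
$$ICC(3,1) = \frac{MS_{rows} - MS_{err}}{MS_{rows} + (k-1) MS_{err}}, \quad k = 2,$$
which ignores a constant session shift (learning between repetitions does not
depress it). Valid repetitions are then averaged into one score per
participant per test.

## Score preprocessing

Per test, groups merged, three steps (`preprocess_scores()`):

1. modified-z outlier removal (median/MAD, 0.6745 scaling, |z| > 3.5);
2. Yeo–Johnson transformation with the exponent $\lambda \in [-5, 5]$ chosen
   to maximise the Shapiro–Wilk W of the inlier sample;
3. reinsertion of the removed values, transformation of everything with the
   chosen $\lambda$, and a second modified-z removal pass on the transformed
   data.

Survivors are standardised to mean 0 / SD 1 and the sign of every test except
VA and HoneyW is reversed so higher always means better. W is maximised rather
than the Shapiro–Wilk p-value (monotonically equivalent at fixed n, numerically
stabler). $\lambda$ is optimised on the inliers only and then applied to all
values, following the step ordering above; standardisation happens after the
second removal pass. The optimiser evaluates W on a coarse grid (step 0.1) and
refines with golden-section search inside the bracketing interval, resolving
$\lambda$ to ~1e-4 — finer than a fixed fine grid at a tenth of the cost, and
safe because W($\lambda$) is smooth and single-basined on these samples. A
degenerate column (zero MAD, too few values) passes through centred but
untransformed, with a warning, without aborting the other tests.

## The statistical layer

* Patients vs controls: two-tailed pooled-variance Student t-tests per test,
  Bonferroni–Holm corrected, with Cohen's d on the pooled SD (labels at
  0.2/0.5/0.8).
* Comorbidity splits within patients (tinnitus, migraine): Welch t-tests,
  uncorrected — descriptive secondary contrasts.
* Visual-snow colour: a one-way Welch (heteroscedastic) ANOVA over three
  groups — controls, black-and-white snow, other colours — per test. The
  classical between/total sum-of-squares $\eta^2$ is reported alongside
  Welch's F, and post-hoc pairwise Welch t-tests are Holm-corrected over the
  three comparisons. (A genuinely three-*way* ANOVA is not meaningful here;
  the three-group one-way reading is the one consistent with F(2, ·) degrees
  of freedom.)
* Symptom correlations, within patients: Spearman rho for each of the 7 tests
  × 21 symptom variables (pairwise deletion; p from the t approximation), the
  duration row partialled for age by rank-transforming all three variables and
  taking the first-order partial Pearson correlation on ranks. These 147
  cells are deliberately uncorrected: the analysis is exploratory and read
  through effect-size magnitudes (0.1/0.3/0.5).

Standard machinery (t-tests, the Welch ANOVA F, Holm, Shapiro–Wilk) delegates
to base R; the tests validate them against permutation references and hand
examples rather than re-deriving them.

## The synthetic cohort

`cohort_design()` fixes the study conditions; `make_cohort()` draws observers.
Defaults: 20 patients, 17 controls; ages Normal(31.6, 6.55) / Normal(26.0,
5.34) truncated at 18; black-and-white snow with probability 8/20 and the
other four colour categories equiprobable; migraine 45% and tinnitus 80%
among patients, absent in controls.

A single latent severity factor $s \sim N(0,1)$ (patients; controls at the
reference 0) drives both symptoms and performance. Each test's governing
parameter (log10 threshold, log10 Honeycomb area, or the log-RT congruency
shift $\Delta$) is

$$\theta_i = \mu_g + b\,s_i + e_i,$$

where the group shift plants a chosen Cohen's d on the performance scale and
the loading $b$ plants a chosen Spearman correlation between severity and
performance (converted to a Pearson loading by $r = 2\sin(\pi\rho/6)$ under
the generator's Gaussian copula), while keeping the patient between-subject SD
equal to the control SD. Planted values default to the magnitudes reported for
the real cohort (e.g. d = 0.52 for acuity, −0.64 for the Honeycomb; severity
correlations of −0.70 for contrast and −0.55 for coherent motion). Note the
planted $\rho$ refers to the *latent* severity; correlations with observed
symptom variables are attenuated by those variables' own loadings, exactly as
noisy ratings attenuate latent relationships in real data.

Symptom variables (21 of them: duration, eight clinical 0–10 ratings, six
30-day-diary characteristic means on their stated ranges, six 1–7
light-condition scores where 7 is best) are range-mapped monotone
Gaussian-copula functions of $loading \times s + noise$; clinical ratings are
rounded to integers, diary means stay continuous, light-condition loadings are
negative. Population means/SDs of the governing parameters (e.g. contrast
threshold centred at $10^{-1.9} \approx 1.3\%$ contrast with 0.2 log10-unit
between-subject SD; Stroop $\Delta$ = 0.10 ± 0.08) were chosen once as
plausible for healthy-adult psychophysics, with measurement noise small
enough relative to between-subject spread that planted effects survive the
pipeline attenuated by no more than ~15–20%.

Session-to-session noise (defaults 0.05 log10 units for thresholds, 0.02 for
RT effects, 0.08 log10 for the adjustment area) is what limits test–retest
reliability; ICCs fall monotonically as it grows, and the defaults put most
simulated tests in the 0.6–0.9 range with the difference-score tasks lower —
the familiar reliability ordering for difference scores.

What the generator does **not** emulate: perceptual learning or fatigue
within/between sessions, day-to-day colour-category changes, comorbidity as a
causal factor (flags are independent of severity), diary time series (only
30-day means), and any multi-factor symptom structure. Passing recovery tests
therefore shows the chain is consistent and calibrated under a single-factor
world, not that real VSS data satisfy that structure.

## Problem sizes and determinism

Simulation-based checks use sizes chosen to keep Monte-Carlo error well below
the tolerances they assert: 500 staircases for the 75%-convergence check,
10,000 trials for asymptote rates, 50 cohorts of 200 + 200 participants for
pipeline-level d recovery, 100 cohorts of 200 patients for severity-correlation
recovery, and 1,000 null cohorts at the study's 20/17 size for the familywise
error check (run through a score-level fast path, `observe_scores()`, whose
measurement-noise SDs approximate the trial-level estimators). Every
stochastic stage takes a seed derived deterministically from one master seed,
so a `run_config()` reproduces an entire study bit for bit.

## Known limitations

* Slopes, lapses and guesses are fixed, not estimated; misspecifying the
  slope biases threshold estimates mildly (the target-performance convention
  absorbs most of it).
* The Welch-ANOVA $\eta^2$ uses classical sums of squares, which is standard
  reporting practice but inherits the classical statistic's sensitivity to
  variance heterogeneity.
* The Stroop/Posner effect denominator convention changes scores by a few
  percent between readings; it is isolated in `rt_effect()`.
* At the study's real size (20/17) the symptom-correlation matrix is
  exploratory by construction; the package reports it uncorrected and labels
  magnitudes, mirroring how such matrices should be read.
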