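---
title: "moodwatch: models, calibration and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{moodwatch: models, calibration and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`moodwatch` turns continuous 1 Hz neurophysiologic ("immersion") recordings
and daily self-reports into models of daily mood and energy. This vignette
explains the statistical machinery, the synthetic cohort generator that makes
the pipeline testable end to end, the numerical choices, and the design
decisions taken where more than one reasonable convention exists.

## 1. The event statistic

Physiological indices are strongly mean-reverting, so daily averages are
nearly uninformative; the signal lives in sustained excursions. For person
$i$ with record median $m_i$ and standard deviation $SD_i$ (both pooled over
the person's entire retained record), a **trough** is a maximal run of
consecutive observed samples with

$$x_{it} < m_i - k \cdot SD_i$$

lasting at least $T$ seconds, and a **peak** is the symmetric run above
$m_i + k \cdot SD_i$. Defaults are $k = 1.5$ and $T = 180$ s; the duration
boundary is inclusive ("at least 3 minutes" admits exactly 3 minutes) and
the threshold is strict (a sample exactly at the threshold is not beyond
it). We note that the symmetric peak rule (a *plus* sign in the threshold)
is the only definition under which peaks are rare events complementary to
troughs; a minus sign would label essentially every sample a peak.

Three conventions were open and are now fixed (all configurable):

* **Depth/height** is the mean deviation from the person median over the
  run's samples (not the deviation from the threshold, and not the
  extremum); the extremum is reported separately.
* **Runs break at unobserved samples.** Sub-minute gaps have already been
  repaired by interpolation, so any remaining gap is a genuine
  discontinuity and must not be bridged.
* **Inter-event time** is the mean start-to-start interval; events belong
  to the time-of-day bin of their start (bins are half-open:
  morning [07:00, 11:00), afternoon [11:00, 15:00), evening [15:00, 19:00)).

Counts are *not* monotone in $k$: raising the threshold can split one long
run into two shorter ones that both clear the duration rule. The property
that does hold, and that the tests assert, is nesting — every event at a
stricter threshold lies inside an event interval at a looser one — together
with monotonicity in $T$.

### Data-quality rules

Unobserved runs strictly shorter than 60 s are linearly interpolated between
their flanking samples (leading/trailing gaps have no flank and stay
missing). After repair, a day is retained iff it has at least 4 observed
hours, boundary inclusive. All exclusions are logged.

### Grid-search calibration

`grid_search_params()` evaluates a grid of $(k, T)$ candidates (default
$k \in \{0.5, 1, 1.5, 2, 2.5\} \times T \in \{60, 120, 180, 240, 300, 600\}$ s)
by the Pearson correlation between daily trough counts and the binary
low-mood indicator, selecting the largest $|r|$; ties break toward the more
conservative candidate (larger $T$, then larger $k$). The objective uses
troughs only and the selected parameters are reused for peaks, keeping the
two definitions symmetric. Candidates that detect nothing score zero.

## 2. Self-reports and the analysis table

Mood is the mean of four 1–5 Likert items — cheerful, stressed, lonely,
energy — with stressed and lonely reverse-coded ($6 - x$); energy is its own
single item. A day is "low" when the score is below 3. Any missing item
makes the composite missing and drops the row from the analysis table (the
attrition is logged). The table has one row per retained participant-day;
aggregates of an empty event set are explicitly missing, never zero — a
regression of mood on mean trough depth must not conflate "no troughs" with
"zero depth". Rows with missing predictors are dropped listwise per model,
so each model reports its own n.

## 3. Association models

Each of the six neurophysiologic variables (trough/peak counts, mean
durations, mean depth/height) is evaluated in its own OLS model to avoid
multicollinearity, always controlling for sickness and sex:

$$y_{id} = \beta_1 x_{id} + \beta_2 \text{sick}_{id} + \beta_3 \text{male}_i
  + \gamma_d + \varepsilon_{id}$$

with day fixed effects $\gamma_d$ (the event statistic is built from
within-person deviations, so day-level shocks are the confounder to absorb)
and standard errors clustered by day using the CR1 sandwich

$$\widehat V = \frac{G}{G-1}\,\frac{N-1}{N-K}\,
  (X'X)^{-1} \Big(\sum_g X_g' \hat u_g \hat u_g' X_g\Big) (X'X)^{-1}.$$

The small-sample factor is the conventional CR1 correction from the
cluster-robust literature; the estimator reduces exactly to HC1 when every
cluster is a singleton (asserted in the tests).
Confidence intervals are the normal approximation
$\hat\beta \pm 1.96\,\widehat{SE}$ and p-values are two-sided normal; no
multiple-testing correction is applied. Group contrasts use Welch's t with
Cohen's d (pooled SD), the variance-ratio F, and one-way ANOVA with
$\eta^2 = SS_B / SS_T$.

## 4. Classification protocol

For a binary outcome (low mood / low energy) on the analysis table:

1. stratified 75/25 train/test split;
2. z-score scaler fit **on the training rows only** and applied to both
   partitions — the protocol's own "avoid data leakage" intent wins over
   any reading in which standardization precedes the split (a
   `scale_before_split` toggle exposes the alternative);
3. SMOTE on the scaled training set: synthetic minority rows are uniform
   interpolations toward one of the $k = 5$ nearest minority neighbours
   until classes balance exactly (if the minority has fewer than $k+1$
   rows, $k$ shrinks with a warning);
4. exhaustive hyperparameter search by stratified 5-fold CV mean AUC, for
   four families: ridge-penalized logit (`glmnet`), RBF SVM (`e1071`),
   random forest (`ranger`), gradient boosted trees (`xgboost`);
5. metrics on both the pre-SMOTE training data and the untouched test set:
   AUC (rank-sum identity, tie-safe), accuracy, precision and recall at a
   0.5 threshold with the *low* class as positive. We use the standard
   definitions of precision (positive predictive value) and recall
   (sensitivity); descriptions of precision as "the true positive rate"
   and recall as "the true negative rate" are nonstandard and not followed;
6. permutation feature importance: the mean decrement in accuracy when one
   feature's column is shuffled, over `n_importance_iters` iterations.
   "Randomly removing" a feature is implemented as value permutation
   because literal deletion changes dimensionality, which most fitted
   models cannot accept;
7. the chance test: 100 resamples draw 70% of rows without replacement,
   refit the family with the already-tuned hyperparameters (retraining the
   tuning per resample is configurable but off — cheaper and conservative),
   record the held-out AUC, and compare the distribution to 0.5 with a
   two-sided one-sample t-test. Resamples missing a class are re-drawn and
   counted.

A caution on the chance test: the 100 AUCs share one finite dataset, so they
carry a common dataset-level offset while the t-test treats them as
independent. On truly null data the test therefore rejects far more often
than its nominal level — the known anti-conservatism of resampling-based
t-tests. The package implements the protocol as specified and the test
suite documents this behaviour rather than hiding it: the null-calibration
check of rejection rates is expected to fail for this reason, while the
mean of the AUC distribution stays near 0.5.

## 5. The synthetic cohort generator

`generate_cohort()` emulates the data regime the pipeline targets: 24
participants, 20 days, 8–10 h/day at 1 Hz, 72% female, daily 1–5 self-reports
with ~5% low-mood and ~21% low-energy days.

* **Baseline.** Per participant, a discretized Ornstein–Uhlenbeck process
  with mean in [40, 60] immersion units, stationary SD in [6, 10], and
  reversion rate 1/300 s⁻¹. The five-minute correlation time makes the
  signal smooth at the within-event scale, which a strict every-sample run
  rule requires of any realistic physiological index.
* **Events.** Per-day Poisson counts (defaults 2.25 troughs, 3.28 peaks),
  additive excursions with a raised-cosine onset/offset (30 s ramps, so
  threshold crossings are smooth rather than square-pulse artifacts),
  uniform durations 240–480 s, amplitude 4.5× the person's baseline SD,
  placed uniformly without overlap. Injected events inflate the empirical
  person SD, which is precisely why false-positive baseline excursions stay
  rare at the default threshold.
* **Mood model.** Latent mood = intercept + β_trough·n_troughs +
  β_peak·n_peaks + β_sick·sick + β_male·male + day shock (SD 0.1, shared
  across participants — the motivation for day fixed effects) + noise
  (SD 0.5), clipped to [1, 5]. Energy is analogous with its own
  coefficients and *no* sex effect, mirroring the asymmetry the association
  stage is meant to detect. The four Likert items are rounded noisy
  realizations (item noise SD 0.25): cheerful tracks latent mood, stressed
  and lonely track its reverse, the energy item tracks latent energy. The
  stored continuous mood is the expected composite (3·mood + energy)/4, so
  the reverse-coded item composite reproduces it up to item noise.
* **Attrition and gaps.** Self-reports go missing with probability 0.15
  (≈480 → ≈408 rows); missing runs start with per-sample probability 10⁻⁴
  and last 15–90 s, so most are repaired by interpolation and a few are
  genuine discontinuities.

**Calibration.** The defaults were calibrated once, before the tests were
frozen: mood intercept 4.1 and energy intercept 3.1 put low-mood prevalence
near 5% and low-energy near 21%; reversion 1/300 with amplitude 4.5 SD puts
detector sensitivity for injected events above 0.9 and the *detected* daily
means near 2.25 troughs / 3.28 peaks. Three presets package the scenarios
used in testing: `"study"` (the calibrated defaults), `"strong"` (larger
planted effects at the same prevalence, for the classification check), and
`"null"` (all coefficients zero — self-reports carry no signal). The null
scenario lowers the mood intercept to keep low-mood days common enough
(~13%) for resampled AUCs to be defined at all; with the study intercept a
null cohort has so few low days that train/test resamples cannot contain
both classes. The parameter-recovery scenario plants equal coefficients in
the mood and energy latents (so the composite's loading equals the planted
value) and mid-scale intercepts (3.7/3.5) so the 1–5 clipping does not
censor the effect.

**What the generator does not emulate:** circadian rate modulation beyond
the clock-anchored recording window, autocorrelated mood across days,
participant-level heterogeneity in event rates, overdispersed counts (the
study's observed count SD exceeds Poisson), or any structure of the raw PPG
signal. Passing tests demonstrate that the pipeline recovers what this
generator plants under realistic noise, sampling and attrition — not that
the commercial index itself predicts mood.

## 6. Problem sizes and determinism

Every stochastic function takes or derives an explicit seed;
`run_pipeline()` fans a single seed into per-stage substreams, and a fixed
seed reproduces cohorts, splits, SMOTE points, tuned parameters and metrics
bit-identically (asserted by manifest-hash comparison). The test suite runs
detector-oracle equivalence on 1,000 random series (length ≤ 2,000),
parameter recovery over 100 study-scale cohorts, null calibration over 50,
and the effectful classification check over 20 — sizes chosen to put
Monte-Carlo error well below the asserted margins. The acceptance script
reruns the full pipeline on one study-scale cohort.

## 7. Known limitations

* The strict every-sample run rule makes detection sensitive to
  high-frequency noise; indices with substantial 1 Hz jitter would need a
  smoothing front-end the package deliberately does not apply.
* The chance test's t-statistic overstates evidence (Section 4); treat its
  p-value as descriptive, or replace it with a label-permutation null if a
  calibrated test is needed.
* SMOTE interpolates binary features (sick, male) like any other
  coordinate, producing fractional synthetic values in scaled space; this
  matches the standard algorithm but means synthetic rows are not valid
  "days".
* Precision is undefined (NA) when a model predicts no positives at the 0.5
  threshold.
* Day-of-week effects are only as real as the `day_index mod 7` convention;
  the generator plants none.
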