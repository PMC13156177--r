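---
title: "Methods: dyadic biobehavioral synchrony estimation and moderation probing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic biobehavioral synchrony estimation and moderation probing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

# The measurement model

`dyadsync` treats a parent–child conflict discussion as a pair of coupled
signal streams observed over ~300 one-second epochs: a physiological
stream (interbeat intervals, IBIs, derived upstream from ECG R-peaks) and
behavioral streams (per-second affect and emotion-related socialization
behavior codes). The quantity of scientific interest is *synchrony* —
moment-to-moment coupling of the two members' signals — and its interplay
with parent factors in predicting child depressive symptoms.

## Time-varying RSA

Respiratory sinus arrhythmia (RSA) is heart-rate variability at the
respiration frequency; its second-scale fluctuations index dynamic
parasympathetic (vagal) regulation. The estimator:

1. **Spline resampling.** IBI value (ms) is interpolated against beat
   time with a cubic spline (`stats::splinefun`, `fmm` boundary
   conditions, exact on polynomial data up to degree 3) and evaluated on
   a uniform 4 Hz grid. No extrapolation: grid points outside the beat
   span are invalid. 4 Hz comfortably exceeds twice any respiration band
   edge used here.
2. **Short-time multitaper band power.** For every second *t* with a full
   surrounding window $[t - 16, t + 16)$ s, the 128-sample segment is
   linearly detrended, multiplied by each of a small set of discrete
   prolate spheroidal (DPSS) tapers, and the tapered periodograms are
   averaged. Band power is the one-sided PSD integrated over the
   respiration band, in ms²; the RSA value assigned to second *t* is
   $\ln(\max(\text{power}, 10^{-8}))$ in ln(ms²).
3. **Cleaning.** Within each person, seconds deviating from the task mean
   by ≥ 3 SD are invalidated and the summary recomputed (single pass).
4. **Differencing.** $d(t) = \mathrm{RSA}(t) - \mathrm{RSA}(t-1)$,
   defined only where both seconds are valid, yielding reactive
   second-to-second change and removing linear trends that would
   otherwise inflate synchrony.

**Parameter choices.**

* *Window (32 s), grid (4 Hz), band (0.12–0.40 Hz adult)*: the standard
  configuration for adult respiration-band power with second-level output.
  The RSA value for second *t* is centered at $\lfloor\text{window}/2\rfloor$:
  the window is $[t-16, t+16)$. Whether the original toolbox indexes the
  "16th second" from 0 or 1 is not recoverable; a one-second shift is
  immaterial for lag-0 synchrony of two identically processed series.
* *Child band*: deliberately **no default**. Child respiration sits higher
  and varies with age; the analysis configuration must state the band
  (the shipped pipeline default uses 0.24–1.04 Hz, the common
  upper-childhood choice, matching the simulated child respiration of
  0.50 Hz).
* *Tapers*: the named peak-matched multiple-window construction is
  toolbox-specific and not recoverable from public sources, so the
  package uses the standard DPSS multitaper family (with a single-Hann
  fallback). Defaults are time–bandwidth `nw = 2` with `K = 3` tapers:
  at 32-s windows the concentration half-bandwidth is `nw/32 = 0.0625` Hz,
  small enough that sub-band drift (≤ 0.05 Hz) cannot smear across the
  0.12 Hz band edge (measured leakage ~0.2% of in-band power, versus
  ~15% at `nw = 3`). `K = 2nw − 1` keeps only well-concentrated tapers.
* *Outlier rule*: "≥ 3 SD from the mean" is applied two-sided by default
  (one-sided removal of high values is available via
  `remove_rsa_outliers(two_sided = FALSE)`); removal percentages reported
  for both dyad members in practice suggest symmetric cleaning.
* *Log floor* `1e-8` ms²: far below physiological band power; only guards
  `-Inf` on degenerate constant input.
* *Detrending within windows* (default on): keeps slow drift from biasing
  band power; configurable off.

## Synchrony

RSA synchrony is the lag-0 Pearson correlation of the two members'
differenced RSA over jointly valid seconds, Fisher transformed
($z = \operatorname{atanh} r$) for use in linear models. Estimates are
missing — with a machine-readable reason — when overlap falls below 30
jointly valid seconds (bounding the correlation SE below ~0.19; the
minimum is configurable and logged), when either series is constant, or
when $r = \pm 1$ exactly (an infinite $z$ cannot enter regression).
Dyad-level outliers are excluded when $|z - \bar z| > 3.92\,\mathrm{SD}(z)$,
the threshold that restored normality in the motivating sample.

Positive-affect synchrony is the co-occurrence of both members'
`positive_warm` codes within a second. Because the proportion is heavily
skewed in conflict discussions, the analysis variable is its
dichotomization (any vs. none). Dyads with more than 50% uncodable affect
in either member (strict inequality) are missing. Proportion denominators
are **jointly codable seconds**, mirroring the exclusion of uncodable
epochs; a task-length denominator would conflate missingness with absence.

## Moderation analysis

Models are single-equation ML fits (`lm`/`glm`) of the child symptom
T-score on synchrony, parent depressive symptoms, the unsupportive-ERSB
indicator, synchrony × parent-factor interactions, and covariates, on
complete cases. This replaces full-information maximum likelihood: with
fully saturated single-outcome models the complete-data coefficients
coincide, and `n_used` is reported per model so the deviation is visible.
Continuous predictors are grand-mean-centered on the analysis sample
(binary 0/1 predictors are not), so "±1 SD" probes use the
post-exclusion analysis-sample SD — where published probes used a
slightly different SD the difference is rounding-level, and
`simple_slope()` accepts any `at_value` if another convention is wanted.

Probing is exact algebra on the fitted coefficients:
$b(m) = b_f + m\,b_{int}$, $SE(m)^2 = v_{ff} + m^2 v_{ii} + 2m\,v_{fi}$,
with a $t$ reference (residual df) for linear models and normal for
logistic. The Johnson–Neyman region solves $|b(m)/SE(m)| = c$ as the
quadratic $(b_{int}^2 - c^2 v_{ii})m^2 + 2(b_f b_{int} - c^2 v_{fi})m +
(b_f^2 - c^2 v_{ff}) = 0$ and reports the sub-intervals of
mean ± 2 SD where the conditional effect is significant; an empty region
is a valid result, and tangent (double-root) panels are merged.

# The synthetic world

The generator states one fixed world so that every stage is testable
without participant data. Defaults were chosen once, from published
marginals where available and field-typical values otherwise, and are not
revisited:

* **Physiology**: base IBI 850 ms (parent) / 650 ms (child); respiration
  0.25 / 0.50 Hz with a uniformly random phase per person (respiration
  phase is arbitrary in real recordings; a shared phase would create
  artificial cross-dyad structure); per-beat white noise SD 2 ms. The
  respiratory modulation amplitude follows a log-scale AR(1) envelope
  (mean log-amplitude ln 35 ms, innovation SD 0.15, persistence 0.8),
  and dyadic coupling is planted in the **innovations of the envelope**,
  correlated at ρ across members, so ground truth aligns with the
  pipeline's first-differenced synchrony definition. Beats are emitted by
  integrating the instantaneous IBI, so the modulation reaches the spline
  stage exactly as in real data. Default ρ = 0.1, consistent with the
  weak average synchrony (mean z ≈ 0.02) such samples show; the realized
  per-dyad envelopes are stored for oracle use.
* **Affect**: coupled Markov chains; entering `positive_warm` has
  baseline probability 0.01/s, multiplied by a boost of 6 when the
  partner was positive the previous second, with persistence 0.7.
  The boost was calibrated once by simulation so that ~54.5% of codable
  dyads show any shared positive affect over 300 s (observed 0.542 over
  800 dyads) — the published any-rate. The implied mean shared
  *proportion* (0.005) is below the published 0.01 but within its
  reported SD; matching both would require dyad-level heterogeneity the
  stated world omits, and only the dichotomized variable enters analysis.
  Uncodable seconds are i.i.d. at 8%/member, raised to 65% for the
  dyads planted as mostly-uncodable.
* **ERSB**: 42.5% of dyads emit any unsupportive behavior; given any, a
  geometric number of seconds (mean 7, cap 60) as a contiguous run,
  reproducing the published skew (overall proportion ≈ 0.01, max 0.20).
* **Outcomes and missingness**: parent depressive T-scores
  ~ N(55.54, 7.64²) floored at 50 and rounded (T-scores are integers with
  a floor); child T-scores from the linear interaction model with the
  published point estimates as planted coefficients (interactions 8.45
  and −2.37 among them), residual SD 6.5, intercept 56.8 (chosen so the
  marginal mean lands at the published 57.6). The outcome floor is *not*
  imposed, keeping the planted coefficients the exact estimand of a
  linear fit. Dyad-level missingness rates reproduce the published Ns
  (ECG pair 27.5%, video absent 13.75%, mostly-uncodable 20% of dyads
  with video ≈ 14/80, ERSB 8.75%, parent/child questionnaires
  13.75%/2.5%). Outcomes are generated from latent ground-truth
  synchrony, so measurement missingness never shifts the estimand.

**What the world does not emulate**: respiration-rate variability and
its coupling to RSA, ectopic beats and movement artifacts, affect-state
persistence beyond first-order dynamics, coder disagreement structure,
and floor/ceiling censoring of the child outcome. A green test therefore
establishes that the pipeline recovers the stated statistical structure
under clean physiology — not robustness to artifact-heavy recordings.

# What the estimator can and cannot resolve

A deliberate validation result, measured by the test suite: with coupling
planted in envelope increments, the mean pipeline Fisher-z tracks the
ground-truth oracle closely at the null (bias ≈ +0.01) but is attenuated
multiplicatively by ~5–9% at strong coupling (ρ = 0.6: pipeline ≈ 0.64
vs. oracle ≈ 0.70 across 500 dyads). Decomposition shows why: the
32-second window is a low-pass filter, so genuine second-scale envelope
increments survive only in smoothed form, while member-specific
measurement noise (spline distortion at child beat rates, amplitude-
modulation sidebands) does not shrink with it. Per-member fidelity of the
differenced estimate to the window-smoothed true signal is high (0.94
parent, 0.96 child); the attenuation is the product of the two members'
residual noise terms and is a property of any 32-s-window spectral
estimate of second-scale change, not of this implementation. The
acceptance suite asserts the stricter pre-declared tolerance
(max(2.5 MC standard errors, 0.03)) faithfully; the ρ ≥ 0.3 arms sit just
outside it and are left failing rather than loosened. Practically:
between-dyad *differences* in synchrony (what the moderation analysis
uses) are preserved — pipeline and smoothed-truth z correlate at 0.96 per
dyad — while the absolute scale of strong coupling is compressed
slightly.

# Numerical choices

* DPSS tapers come from the symmetric tridiagonal formulation
  (eigenvectors of a 128 × 128 matrix, cached per configuration);
  unit-energy normalization makes band power equal in-band variance.
* The band integral uses the rectangle rule over FFT bins
  (`df = hz/n`), one-sided with the factor 2 for 0 < f < Nyquist.
* `splinefun(method = "fmm")` rather than a natural spline: exact on
  cubic polynomials at the boundaries, which the resampling contract
  tests.
* Region-of-significance roots use the closed-form quadratic; panels are
  decided by the sign of $b(m)^2 - c^2 SE^2(m)$ at midpoints, which is
  robust to tangent roots; boundaries are verified against a grid scan at
  10⁻⁴ SD resolution in the tests.
* Degenerate inputs error early with named fields: bands at or above
  Nyquist, windows under 64 samples, tasks shorter than one window,
  all-seconds-removed cleaning, rank-deficient design matrices (the
  offending columns are named).
* Determinism: `simulate_study()` consumes a single integer seed; all
  downstream artifacts are byte-reproducible from the config, which the
  pipeline tests verify by hashing.

# Known limitations

* Complete-case estimation discards dyads missing any model variable;
  with the default missingness world the Aim-style models retain roughly
  half of 80 dyads, matching the motivating sample's effective Ns but
  leaving the small-sample caveats intact.
* Lag-0 synchrony only; leader–follower (lagged) and time-varying
  synchrony are out of scope (`lag_s` exists in the API for sensitivity
  checks).
* The kappa statistic is unweighted time-unit agreement; no
  chance-corrected variants for ordinal codes.
* The RSA estimator assumes stationary respiration within the band;
  respiration excursions outside the configured band register as RSA
  change.
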