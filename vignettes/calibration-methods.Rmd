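---
title: "Calibration methods and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration methods and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actimet)
```

This vignette documents the statistical model, the two simulation
fidelities, and the parameter and design choices behind `actimet`, with
the rationale for each. The README shows the workflow; this is the
"why".

## The calibration model

The unit of analysis is one steady-state observation per participant,
treadmill condition and device-placement stratum: the mean counts/min
and mean MET over the central four minutes of a 10-minute stage. The
model is ordinary least squares on the square-root scale,

$$\sqrt{\mathrm{MET}} = \beta_0 + \beta_1\sqrt{A}
  + \sum_{s} \left(\gamma_s + \delta_s \sqrt{A}\right)\,[\text{stratum}=s]
  + \varepsilon,$$

where $A$ is counts/min and the sum runs over the non-reference strata
(ActTrust hip, ActTrust wrist, GT3X+ wrist; hip-worn GT3X+ is the
reference). The square-root transform serves two purposes: it
linearises the concave counts–MET relationship over the rest-to-run
range, and it stabilises the residual variance, which grows with
intensity on the raw scale. Because the model is saturated in the
stratum factor, the joint fit is algebraically identical to four
separate per-stratum regressions (a property the test suite checks);
fitting jointly simply yields one coefficient covariance matrix for all
strata, which the cut-point CIs need.

Each stratum collapses to $\sqrt{\mathrm{MET}} = b_0 + b_1\sqrt{A}$
with, e.g., $b_0 = \beta_0 + \gamma_s$. `stratum_equation()` extracts
$(b_0, b_1)$ with the $2\times 2$ covariance
$A\,\Sigma\,A^\top$ of the corresponding contrast rows.

### Cut-points and their uncertainty

The counts/min threshold for a MET boundary $M \in \{3, 6, 9\}$ is the
inverse of the calibration line,

$$c(M) = \left(\frac{\sqrt{M} - b_0}{b_1}\right)^2,$$

defined whenever $\sqrt{M} > b_0$ and $b_1 > 0$ (`invert_cutpoint()`
rejects thresholds at or below the model's resting intercept).
Uncertainty is propagated by the delta method with gradient

$$\nabla c = \left(-\frac{2(\sqrt{M}-b_0)}{b_1^2},\;
  -\frac{2(\sqrt{M}-b_0)^2}{b_1^3}\right),$$

so $\mathrm{se}(c) = \sqrt{\nabla c^\top\, \Sigma_2\, \nabla c}$. The
first-order approximation is accurate when the slope is well estimated;
`cutpoint_ci_boot()` provides a $10^5$-draw parametric bootstrap
(multivariate-normal coefficient draws) as a cross-check, and the test
suite requires the two standard errors to agree within 5% whenever the
coefficient of variation of $b_1$ is below 10%. Confidence intervals
are truncated at zero, since a negative count threshold is meaningless.

CIs use normal (z) quantiles by default, matching the large residual
degrees of freedom of the intended designs (a 56-participant, 5-stage,
4-stratum study gives > 1000 observations); `fit_calibration(...,
ci_multiplier = "t")` switches to Student t for small fits.

## Ground truth and the reference coefficients

`inst/extdata/reference_calibration.csv` stores one published
calibration per stratum — $(b_0, b_1)$ with their CIs and the three
cut-points. These serve two roles:

1. **Internal consistency check** (`validate_reference()`): inverting
   the stored coefficients must reproduce the stored cut-points within
   2% relative; the slack exists only because the stored coefficients
   are rounded to 3–4 significant figures. `scripts/acceptance.R` is
   the script form of this check.
2. **Simulator ground truth**: `truth_parameters()` uses these
   coefficients as the generating model, so parameter recovery has a
   known target.

## Two simulation fidelities

A central design decision is that the package offers two generators
with different purposes, selected by `pipeline_config(fidelity = ...)`.

### Observation level (`simulate_observations()`)

Draws the analysis table directly from the calibration model:
each participant gets a lognormal activity factor
(`between_subject_sdlog = 0.15`) shared across strata; the counts/min
for a condition is the truth-implied value at the condition's MET
target times that factor; the MET is then
$(b_0 + b_1\sqrt{A} + \epsilon)^2$ with
$\epsilon \sim N(0, \texttt{residual\_sd\_sqrt\_met})$.

Because the generative model *is* the fitted model, this path supports
exact statistical claims: with zero noise the fit interpolates the
truth; with noise, 95% CIs for every coefficient and every cut-point
must cover the truth at nominal rate. The acceptance-level coverage
study (200 replicates of a 34-male/22-female cohort at
`residual_sd_sqrt_met = 0.15`, a value chosen to reproduce the
published model's $R^2 \approx 0.96$ at this design) runs on this path.

### Signal level (`write_cohort_dataset()` and friends)

Synthesises what the devices would record and what the metabolic cart
would measure, then lets the preprocessing pipeline reduce it:

- **Gait acceleration**: per axis, a fundamental at the step frequency
  $f = 1.1 + 0.13\,\mathrm{speed}$ plus two overtones (relative
  amplitudes 0.35 and 0.15), axis weights (1, 0.6, 0.45), gravity on
  the vertical axis, Gaussian sensor noise, clipped to the device's
  dynamic range. The ActTrust range (0.03–4 g) is implemented as a
  per-axis magnitude clamp whose floor zeroes sub-threshold samples.
- **Count emulation** (`emulate_counts()`): 4th-order zero-phase
  Butterworth band-pass (implemented as an order-2 `signal::butter`
  design applied forward–backward with `filtfilt`, which squares the
  magnitude response), then per 1-s epoch either the norm of the
  per-axis rectified integrals (VM, GT3X+) or the integral of the
  rectified acceleration norm (PIM, ActTrust), scaled by a fixed
  `count_scale` (320 for GT3X+, 1500 for ActTrust). Column means are
  subtracted before filtering so the gravity DC offset cannot leak
  edge transients into the counts; without this the counts are not
  homogeneous in amplitude.
- **Amplitude calibration**: vendors do not publish the scaling between
  g-seconds and counts, so `count_scale` is an explicit constant, not
  an estimate; the two values were chosen once so that plausible gait
  amplitudes (a fraction of 1 g) land in each device's published
  counts/min range, and were not revisited. The waveform amplitude for
  a (device, speed) pair is then solved by `uniroot` on a noiseless
  30-s probe so that the emulated counts/min hits the truth-implied
  target; results are cached per session.
- **Breaths** (`simulate_breaths()`): breath rate $12 +
  2.8\,\mathrm{MET}$ breaths/min with lognormal gap jitter; VO2 follows
  first-order on-kinetics with $\tau = 30$ s, with the ramp capped at
  $5\tau = 150$ s so the central window ($[t_0+180, t_0+420)$) is
  exactly at steady state; multiplicative noise
  (`breath_noise_cv = 0.08`, typical of breath-by-breath systems) and
  errant breaths (rate 0.01, spikes 2.5–4x) that the 3-SD cleaning rule
  is meant to remove.

This path exercises device emulation and every preprocessing step, but
it **cannot** support exact parameter recovery: the counts carry
measurement error (errors-in-predictors attenuate the slope) and the
squared-noise MET has a small positive bias. Tests on this path
therefore assert qualitative properties (monotonicity in speed,
linearity in amplitude, determinism, successful end-to-end fits close
to truth) rather than coverage. Keeping both fidelities — rather than
forcing one generator to do both jobs — is what lets the statistical
machinery be tested sharply while the signal chain is still exercised
realistically.

### MET targets by speed

`met_by_speed` defaults to 0 → 1, 3 → 2.5, 5 → 4, 7 → 7, 9 → 10 MET:
rest at 1 MET by definition; walking values consistent with standard
metabolic-cost equations for level walking at 3 and 5 km/h; running
values consistent with ~1 MET per km/h at running speeds. They place
the five conditions on both sides of every cut-point threshold, which
the classification evaluation needs. They are configuration, not
estimates.

One known model inconsistency is accepted deliberately: the calibration
line predicts $b_0^2 \approx 1.13$ MET at zero counts, while the
simulated resting MET is 1.0. This mirrors the real phenomenon that a
straight line fitted through exercise data does not pass exactly
through rest, and it is below the noise floor of every test that uses
the default settings.

## Preprocessing rules

- **Breath cleaning** (`clean_breaths()`): a breath is errant when it
  deviates by more than 3 local SDs from the mean of its four
  neighbours (two before, two after). The rule is applied in a single
  pass over the original series — removed breaths still act as
  references for their neighbours — and the first/last two breaths are
  always kept. Limiting behaviours are pinned by tests: a constant
  series is untouched; when the four references are identical (local SD
  zero) *any* deviation is errant; series under 5 breaths are returned
  unchanged with a warning. A brute-force oracle re-implementation is
  compared record-for-record on 1,000 random series.
- **Steady-state MET** (`steady_state_met()`): time-weighted mean of
  per-breath VO2/kg over the window (breath sampling is irregular, so a
  simple mean would over-weight fast-breathing segments), divided
  by 3.5.
- **Steady-state counts** (`steady_state_counts()`): mean of the four
  per-minute sums of 1-s epochs; a minute missing at most 5% of its
  epochs is rescaled, more missingness marks the observation missing.
- **Accounting**: `build_observation_table()` completes against the
  full participant × condition × stratum design, so every absent or
  unusable series appears in the `exclusions` attribute — rows in
  equal rows out plus exclusions, never silent loss. Duplicated epoch
  series are a hard error.

## Evaluation choices

- **Intensity bands** are left-closed: light $[0,3)$, moderate
  $[3,6)$, vigorous $[6,9)$, very vigorous $[9,\infty)$, applied
  identically on the MET side (`met_to_class()`) and the counts side
  (`counts_to_class()`), so a value exactly at a boundary belongs to
  the upper class on both sides.
- **AUC orientation**: one-vs-rest AUC uses the rank (Mann–Whitney)
  formulation with mid-ranks. For the light class the raw score
  (predicted MET) is *negated*, because lower predicted intensity is
  evidence *for* the light class; without the flip the light-class AUC
  would be near 0 by construction. Interior classes keep the raw score
  and therefore have structurally weak AUCs — membership in a middle
  band is not monotone in predicted MET — which is exactly the pattern
  such studies report and the test suite asserts qualitatively. `pROC`
  is used as an independent oracle in tests only, never in package
  code.
- **ANOVA** (`anova_counts()`): one-way `aov` of $\sqrt{A}$ over the 20
  condition × stratum cells (hence between-groups df 19), with
  $\eta^2 = SS_b/SS_{tot}$ and Tukey HSD for pairwise contrasts. The
  response is the square-root-transformed activity — the scale on which
  the model is linear and variance is stable — not raw counts.
- **Bland–Altman** (`bland_altman()`): bias and 1.96-SD limits of
  agreement between measured MET and the stratum equation's prediction,
  plus a regression slope of difference on mean to flag proportional
  bias.

## Problem sizes and runtime

The defaults mirror the intended study: 34 male + 22 female
participants, 5 conditions, 4 strata (1,120 observations). A full
observation-level pipeline runs in seconds; the signal-level path
simulates ~1 hour of multi-device raw acceleration per participant and
is the runtime-dominant choice (minutes for a small cohort), so tests
use short stages and small cohorts on that path. The 200-replicate
coverage study and $10^5$-draw bootstraps run in a few minutes on one
CPU.

## Limitations

- The signal simulator aims for *statistical* plausibility of the
  counts, not waveform realism; `count_scale` and the gait-harmonic
  shape are explicit conventions.
- The ActTrust detection floor makes its emulated counts only
  approximately homogeneous in amplitude (≈1% deviation at gait
  amplitudes).
- Delta-method CIs are first-order; for very noisy slopes
  (CV($b_1$) ≳ 10%) use the bootstrap.
- The published coefficients in the reference table are rounded, so
  checks against them carry a 2% tolerance by construction.
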