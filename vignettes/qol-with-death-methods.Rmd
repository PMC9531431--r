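---
title: "Methods: QOL with survival outcomes, from simulation to display"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QOL with survival outcomes, from simulation to display}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qolsurv)
```

`qolsurv` exists to make one methodological point inspectable: when death
truncates a quality-of-life (QOL) endpoint, every analysis method embeds a
different answer to "what does QOL mean for a patient who died?", and those
answers produce visibly different graphs from the same trial. This vignette
documents the data-generating model, the estimators, and the numerical and
design choices, in enough detail that a reader can judge what a passing
test suite does and does not establish.

## The data-generating model

Each simulated trial randomizes `n_patients` (default 20,000) patients 1:1
to a standard (arm 0) or new (arm 1) treatment.

**Overall survival.** A single uniform draw per patient is inverted through
the exponential law twice, once per arm: `T*(a) = -log(u) / (r0 * HR^a)`
with `r0 = log(2)/12` per month, so the standard-arm median is 12 months.
Any draw exceeding 12 months is shifted by +6 months, creating a no-death
plateau on (12, 18] while leaving S(12) = 0.5 and a constant hazard ratio
wherever the hazard is nonzero. Death at exactly month 12 counts as
pre-plateau. Using a common `u` for both arms (common random numbers) makes
the potential death times rank-preserving: `T(1) >= T(0)` exactly when
`HR <= 1`, which is what lets the always-survivor stratum be read off the
simulated data.

**Censoring.** Independent and exponential. The rate is not a free
parameter: `calibrate_censor_rate()` solves `P(C < T) = 0.5` analytically
(the Laplace transform of the plateau-shifted exponential has a closed
form, mixed half-and-half over the two arms at the scenario-1 hazard
ratio 0.74) with `uniroot` at tolerance 1e-12. The calibration is therefore
deterministic and identical across machines; no Monte-Carlo tuning is
involved.

**QOL.** Each patient's stable level is
`stable_mean + sex_effect * sex + N(0, stable_sd)` with defaults 80, +2 and
8 points. The latent trajectory is flat at that level until `delta = 6`
months before death and then declines linearly so that the value at death
is `D` points lower: `D = 20` in the standard arm, `D = 10` in the new arm
when the treatment affects QOL (scenarios 1–3) and `D = 20` in scenario 4.
Observed measurements are taken every 3 months from 0 to 18, only while the
patient is alive and uncensored, with `N(0, 5)` measurement noise, clipped
to the 0–100 instrument range. The stable level, its spread, the noise and
the sex effect are declared defaults of this package — the values a
maintainer would call realistic for a 0–100 instrument in advanced cancer —
and all of them are exposed in `trial_config()`.

**Scenarios.** 1: OS better (HR 0.74) and QOL better; 2: QOL better but OS
worse (HR 1.35); 3: QOL better, OS equal; 4: OS better, QOL equal. A
"QOL worse but OS better" case is scenario 2 with the arm labels flipped,
and is therefore not simulated separately.

### Potential outcomes and the scenario-4 design choice

`simulate_trial()` records, per patient and scheduled visit, the noise-free
latent QOL under both arms. When the QOL effect is on, the trajectory under
arm `a` is anchored to that arm's potential death time with that arm's
decline depth. Scenario 4 required a genuine design decision. "No treatment
effect on QOL" could mean (i) the same decline *law* applied to each arm's
own death time, or (ii) literally identical potential QOL trajectories.
Under (i) the SACE would not be null: among always-survivors whose standard
death falls inside the decline window but whose new-arm death does not, the
trajectories differ even though the decline law is shared — an effect of
treatment on QOL transmitted entirely through survival. This package takes
(ii): when `qol_effect_on = FALSE`, both potential trajectories follow the
control-arm death process, so the true SACE contrast is exactly zero at
every visit by construction. Observed QOL, in contrast, always declines
before the patient's *actual* death under the assigned arm. The two choices
deliberately coexist: the observed data reproduce the survivor-analysis
artefact (a treatment that only prolongs survival appears to improve QOL at
every visit), while the potential outcomes encode the causal null that the
SACE is meant to recover.

What the generator does **not** emulate: informative censoring, QOL-
dependent mortality (survival is independent of the QOL level and of sex),
missed visits among the living, floor/ceiling measurement artefacts beyond
simple clipping, and recurrent intercurrent events other than death. Tests
that pass against this generator therefore say nothing about, for example,
MMRM bias under outcome-dependent dropout among survivors, and the
weighted SACE estimator is exercised under conditions where its
explainable-non-random-survival assumption holds by construction (survival
independent of everything, or hazard ratio 1); under the scenarios where
treatment shifts survival *and* QOL tracks death, that assumption fails and
the estimator inherits the survivor-analysis selection, which is visible in
the scenario-wise contrast tables produced by `analysis/05_qol_methods.R`.

## Estimators and numerical choices

**Composite score and curve.** `score_u()` puts death at exactly the cutoff
`t` in the death branch (`U = t`). Patients censored before `t` without a
death have an undefined score; they enter the combined curve only through
the product-limit weighting of the death segment and are excluded from the
survivor ECDF (a complete-case right segment — the censoring ambiguity is
flagged rather than resolved). The curve's left segment is `1 − KM` of
death on `[0, t]`; the right segment is `F(t) + (1 − F(t)) · G(q)` with `G`
the ECDF of QOL at `t` among patients under follow-up. Quantiles use the
left-continuous inverse (the smallest domain point whose cumulative
probability reaches `p`), so `percentile_u()` is nondecreasing in `p` along
the concatenated time-then-QOL domain. The display maps time to
`[0, split_fraction]` and QOL (over the fixed 0–100 range) to the
remainder; the default split is one half, and it is configurable precisely
because the impression a reader takes from the graph depends on it.

**Pairwise comparisons.** A pair is decided on death ordering whenever
censoring leaves that ordering observable — both deaths observed, or one
patient's follow-up extending to at least the other's death time (a patient
censored at exactly the other's death time counts as having outlived them).
Otherwise the pair falls through to QOL at `t` when both patients are alive
at `t` with observed values; exact equality (or equality within an optional
clinically-relevant margin, default 0) is a tie, and anything else is
uninformative. `win_statistics()` counts all `n1 × n0` pairs by order
statistics (`findInterval` on sorted vectors) rather than enumeration, so
the 10^8 pairs of a full scenario are counted in milliseconds; the test
suite checks the counts against exhaustive enumeration with
`pairwise_compare()` on small arms. Zero losses yield an explicitly flagged
infinite win ratio. Bootstrap CIs resample patients within arm.

**TTD and semi-competing risks.** Deterioration is a decline of at least
`threshold` (default 10) points below the month-0 value, dated at the visit
where first observed (interval censoring is ignored; no confirmation visit
is required; the best-previous-value reference used by some trials is not).
The Cox fit uses Efron ties by default, Breslow optionally. The CIF is the
Aalen–Johansen estimator; its additivity
(`CIF_det + CIF_death + S = 1`) holds to machine precision and is asserted
at 1e-12. Gray's test is the rho = 0 sub-distribution score test, validated
against a 1,000-permutation reference of the same statistic on a small
fixture. The Fine–Gray fit uses the censoring-weighted partial likelihood
with pooled product-limit censoring weights (the `finegray` expansion plus
a weighted Cox fit with robust SE); the quadratic-time `cmprsk::crr`
routine serves as an independent cross-check in the tests, not as the
implementation, because it is impractical at n = 20,000. Deaths after an
observed deterioration are irrelevant to the CIF of first deterioration.

**Terminal decline.** Backward times `death − visit` are binned on the
3-month measurement grid with no interpolation; each bin also records its
mean backward time, and the changepoint fit uses that mean (not the bin
midpoint) as the abscissa, which makes the fit exact on noise-free data.
The flat-then-linear model is fitted by weighted least squares profiled
over a 0.75-month grid of candidate knots from 1.5 to 12 months; ties in
the residual sum of squares resolve to the smallest knot. The reported
depth is `slope × knot`: the gap between the stable level and the value
extrapolated to the moment of death.

**MMRM.** `nlme::gls` by REML with categorical visit, visit-by-arm
interaction, baseline QOL and sex; unstructured within-patient correlation
with per-visit variances, falling back to compound symmetry when the
unstructured fit fails to converge (the fallback is recorded in the result).
The covariance structure and the categorical-visit coding are this
package's choices; nothing in the method fixes them. Every fit carries the
caveat that death-truncated values are not implicitly imputed and the
implied estimand is ill-defined under death.

**Weighted SACE.** Per arm and visit, a logistic regression of
survival-to-visit on baseline QOL and sex (the functional form is a package
choice; `~ 1` is allowed and reduces the estimator exactly to the
survivor-analysis contrast). Observed survivors are weighted by the
predicted survival probability under the *opposite* arm, reweighting both
arms toward the always-survivor stratum. Patients censored before the visit
contribute to neither the survival model nor the contrast; visits where a
survival model is degenerate fall back to the arm's empirical survival
fraction, and weight ranges are reported so non-overlap is visible.

**Graphics.** Panels are built as coordinates first (`build_panel()`) and
rendered second (`plot_panel()`); tests assert coordinates, never pixels.
Step curves are right-continuous from (0, 1); CIF panels refuse to build
without the OS Kaplan–Meier series of the same arms; the terminal-decline
panel runs its x-axis backward; the composite panel marks the time/QOL
split. The ggplot object's data slot is exactly the panel's series tibble,
so rendering round-trips.

## Problem sizes and reproducibility

The full study (the `analysis/` drivers and `scripts/acceptance.R`) runs
each scenario at n = 20,000 — the size at which one simulated trial makes
the graphical features essentially noise-free. The test suite works at
smaller sizes chosen for the property being tested: exact oracles on 3–50
record fixtures, structural properties at a few hundred patients, and
Monte-Carlo calibration checks at n = 5,000 with tolerances widened to
match (4 binomial standard errors for the censoring fraction, 3 Wald
standard errors for hazard-ratio recovery, ±2 points and ±1.5 months for
the terminal-decline fit). The MMRM driver subsamples to 5,000 patients
because the unstructured REML fit scales poorly in n while its standard
errors are already ~0.3 points there. All randomness flows from the seed
in `trial_config()`; a fixed seed gives bit-identical datasets, and the
same seed couples scenarios through common random numbers, so
between-scenario comparisons are not confounded by simulation noise.

## Known limitations

- The scenario-2 TTD display shows *attenuated* rather than eliminated
  separation under these generator defaults: the standard arm's
  deterioration is observed at the last visit before death while the new
  arm's events are mostly deaths, so the TTD curves nearly coincide over
  the first half year and separate modestly later, always less than the OS
  curves do. The qualitative reading — the TTD graph mixes OS and QOL
  effects and cannot be read as either — is unchanged.
- The pattern-mixture model, restricted-mean summaries, hierarchical
  composites with more than two priority levels, stratified win ratios,
  SACE testing within covariate strata, and joint longitudinal–survival
  models are out of scope.
- `percentile_u()` signals non-estimable quantiles under heavy censoring
  rather than extrapolating; `gray_test()` and `fine_gray_hr()` refuse
  datasets with no event of interest; `backward_trajectory()` warns and
  returns an empty summary when no deaths are observed.
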