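# qolsurv

Analysis and graphical display of quality-of-life (QOL) endpoints that are
**truncated by death** in two-arm oncology trials.

In trials with substantial mortality — palliative care, immunotherapy — QOL
after death is not missing, it is *undefined*, and any analysis of QOL must
say what it does about patients who die. The estimand framework (ICH E9 R1)
offers several strategies for this intercurrent event; each leads to a
different statistical method, a different graph, and a different impression
of the same trial. `qolsurv` implements a simulation study that puts seven
of these methods side by side on the same four hypothetical trials, so the
information each graph does and does not carry can be examined directly.

## Methods implemented

**Composite-variable strategies**

- *Prioritized composite outcome.* Each patient is scored by

  ```
  U = survival time           if death occurs by the cutoff t
  U = QOL(t) + t              if alive at t
  ```

  so death outranks any QOL value and higher `U` is better. The package
  builds the two-part distribution curve (cumulative incidence of death on
  `[0, t]`, continued by the scaled cumulative distribution of QOL among
  survivors), its quantiles, and generalized pairwise comparisons with the
  win ratio `W/L` and net benefit `(W − L) / (n1 · n0)`.
- *Time-to-deterioration (TTD).* First of death or a ≥ 10-point decline
  from baseline; Kaplan–Meier curves, Cox hazard ratio, median times.
- *Semi-competing risks.* QOL deterioration as the event of interest with
  death as a competing event: Aalen–Johansen cumulative incidence, Gray's
  test, Fine–Gray sub-distribution hazard ratio — always displayed together
  with the OS Kaplan–Meier curve.

**Strategies for QOL itself**

- *Survivor analysis* (means among patients under follow-up) and
  *terminal-decline summarization* on the time scale counting backward from
  death, with a flat-then-linear changepoint fit of the decline.
- *MMRM*: REML fit with categorical visit × arm, baseline QOL and sex,
  unstructured within-patient covariance (compound-symmetry fallback).
- *Survivor average causal effect (SACE)*: the treatment contrast among
  "always survivors" — patients who would live to the visit under either
  arm. The true SACE is computed from the simulator's potential outcomes;
  a survival-probability-weighted estimator is provided for observed data.

## The simulated trials

Each scenario randomizes 20,000 patients 1:1. Overall survival is
exponential with a standard-arm median of 12 months, no deaths in the
(12, 18] month window, and new-arm hazard ratios 0.74 / 1.35 / 1 / 0.74 in
scenarios 1–4; about 50% of patients are independently censored. QOL
(0–100, measured every 3 months) is stable until 6 months before death and
then declines linearly by 20 points (standard arm) or 10 points (new arm,
when the treatment affects QOL). Scenario 4 turns the QOL effect off: both
potential QOL trajectories are identical, so the true SACE is exactly zero
while survivor-type analyses still show a difference caused purely by the
survival benefit.

## Worked example

```r
library(qolsurv)

trial <- simulate_trial(trial_config(scenario = 2, n_patients = 20000,
                                     seed = 2026))
scored <- patient_scores(trial, t = 12)
for (a in 0:1) {
  cc <- combined_curve(scored[scored$arm == a, ], t = 12, arm_label = a)
  print(percentile_u(cc, c(0.5, 0.7)))
}
win_statistics(scored, t = 12)
```

In scenario 2 (new arm: better QOL, worse survival) this prints a composite
median of **11.9 months** for the standard arm against **8.8 months** for
the new arm — the standard arm is better at the median, driven by survival —
while the 70th percentiles fall in the QOL part of the curve and are
similar (**78.6** vs **74.2** points). The pairwise comparisons give a win
ratio of **0.75** and a net benefit of **−0.09** (new vs standard): a
trial where the treatment "wins" on the QOL component but loses overall
once death is given priority.

The numbered drivers under `analysis/` run the full study (simulation,
all seven methods, and the six panel types for every scenario) and write
their summary tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_composite.R   # ... through 06_figures.R
```

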