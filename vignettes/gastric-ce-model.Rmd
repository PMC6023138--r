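---
title: "A three-state cost-effectiveness model for first-line chemotherapy in elderly advanced gastric cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state cost-effectiveness model for first-line chemotherapy in elderly advanced gastric cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceagc)
```

## The decision problem

Elderly patients (70+) with advanced gastric cancer have no single standard
first-line chemotherapy. A two-arm phase III trial compared capecitabine
monotherapy (the X arm, n = 26) against capecitabine plus oxaliplatin
(XELOX, n = 24); XELOX prolongs progression-free and overall survival but
adds an expensive intravenous drug. `ceagc` implements the full
cost-effectiveness pipeline that turns that trial's survival curves and a
Chinese-healthcare cost table (2016 US$) into discounted lifetime costs,
quality-adjusted life years (QALYs) and an incremental cost-effectiveness
ratio (ICER), with one-way and probabilistic sensitivity analyses.

## Survival model

Both endpoints in both arms are modelled with log-logistic survival curves

$$S(t) = \frac{1}{1 + e^{\theta}\, t^{\kappa}}, \qquad
  \text{median} = e^{-\theta/\kappa},$$

with $t$ counted in **21-day cycles** -- one chemotherapy cycle. The time
unit matters: with the fitted overall-survival parameters, a 260-cycle
horizon (just under 15 years) puts 99.26% of the X cohort and 97.70% of the
XELOX cohort in the death state, which is the published 15-year mortality to
the printed precision and pins functional form, unit and horizon
simultaneously:

```{r}
x_os <- llogis_params(-3.2726, 1.4703)
xelox_os <- llogis_params(-4.5714, 1.4960)
round(100 * (1 - llogis_survival(x_os, 260)), 2)
round(100 * (1 - llogis_survival(xelox_os, 260)), 2)
```

`fit_parametric()` estimates these parameters from (pseudo-)individual
patient data by maximum likelihood via `flexsurv`, with right-censored
records contributing $S(t)$ and events the density. Four candidate families
(log-logistic, Weibull, exponential, log-normal) are compared by AIC/BIC, and
`adjusted_r2_vs_km()` scores a fit against a Kaplan-Meier curve on the
survival-probability scale. The probability scale was chosen over a
transformed (e.g. log-odds) scale because digitized KM ordinates are read off
on that scale; the alternative is a one-line change in the residual
computation.

## Synthetic data

The original trial's patient-level data are unpublished; the published
analysis worked from graph-digitized KM curves. The generator module
reproduces that situation rather than the raw trial:

* `simulate_ipd()` draws event times by inversion,
  $t = (u/(1-u))^{1/\kappa} e^{-\theta/\kappa}$, with optional
  administrative censoring -- the simplest censoring mechanism, sufficient
  for testing because the trial's follow-up scheme is unpublished.
* `digitized_km_fixture()` samples the resulting KM step function on a
  regular grid, with optional bounded jitter (off by default) mimicking
  digitizer read-off error.
* `make_trial_fixture()` bundles the trial-scale defaults (n = 26/24 and the
  four fitted parameter pairs above).

What these fixtures emulate is sampling noise and digitization granularity at
trial scale. What they do **not** emulate: informative censoring, the
original randomization, or any within-patient correlation between PFS and OS
times -- so passing tests demonstrate correctness of the pipeline on data of
the right shape and scale, not clinical validity of the trial itself.

## Cohort model

Three mutually exclusive states: progression-free (PFS), progressed disease
(PD), death. Two trace constructions are implemented:

* **Partitioned survival** (`build_partitioned_trace()`): occupancy read
  directly off the curves, `pfs = min(S_PFS, S_OS)`, `dead = 1 - S_OS`, `pd`
  the remainder. The `min` cap keeps PD non-negative if fitted curves cross.
* **KM-hazard Markov chain** (`build_markov_trace()`): per-cycle transition
  probabilities derived from the same curves, with the OS death probability
  applied to *both* alive states and the PFS-exit probability additionally to
  PFS. In closed form `pfs = S_PFS * S_OS`; total survival is exactly
  `S_OS`, so the death fractions above are identical under both methods.

The published methods say only that transition probabilities were obtained
from the KM curves; how PFS exits split between progression and death is not
stated. The chain variant deliberately treats progression and death as
independent per-cycle hazards -- the construction a cohort-simulation tool
produces when each curve is converted to a transition probability
separately. Because the trial's PFS endpoint already counts death as an
event, this double-counts a small amount of mortality inside the PFS state
and shifts person-time from PFS to PD relative to partitioned survival. That
shift is exactly what the published per-state QALY split exhibits (most
visibly the XELOX PFS QALYs, far below utility times mean fitted PFS time),
which is why calibration selects the chain (see below). Both constructions
are exported, property-tested against an explicit transition-matrix loop,
and selectable via `conventions$trace_method`.

## Cost and QALY accrual

Per cycle, each state's occupancy accrues a state cost and
`utility * 21/365` QALYs, discounted by `(1+r)^(-t * 21/365)` at `r = 3%`
per year. State costs:

* **PFS**: first-line drug acquisition (capecitabine tablets rounded up to
  whole 500 mg units; oxaliplatin rounded up to whole 50 mg vials, XELOX
  only; body surface area 1.72 m2, a typical elderly Chinese adult,
  configurable), administration, laboratory evaluation.
* **PD**: a follow-up package (abdominal CT, abdominal MRI, chest
  radiograph, laboratory) on a configurable schedule, plus second-line
  treatment: the fraction `p_second_line` of occupants accrues second-line
  chemotherapy, the remainder supportive care.
* **Death**: nothing.

Grade 3/4 adverse-event costs (risk times cost per episode, summed over the
five main events) are charged once at model start, undiscounted -- the
published risks are per-patient trial incidences, not per-cycle rates.

### Calibration of under-determined conventions

Several accrual conventions are not derivable from the published methods:
the trace construction, whether occupancy is taken at cycle start, end or
midpoint, tablet-rounding granularity, whether the oral-only X arm pays the
administration fee, the capecitabine dose reading, the follow-up frequency,
and how the second-line cost enters (per PD cycle replacing supportive care;
per PD cycle on top of it; or once on PD entry). The package therefore ships
a calibration harness, `calibrate_conventions()`, which grid-searches the
discrete convention space (648 combinations) and scores each against the
eight published per-state base-case cells (costs and QALYs in PFS and PD,
both arms) by summed relative absolute deviation -- relative, because the
cells mix dollars and QALYs. The winner is frozen into `default_config()`:

```{r}
unlist(default_config()$conventions)
```

The residual of the winning configuration is real and reported (worst cell
about 3.4%, XELOX PFS cost; run `calibrate_conventions()` to print the full
per-cell table). It is a fit, not a derivation: the published model's exact
accrual rules remain unknown, and all downstream results inherit this
residual.

## Sensitivity analyses

**One-way / tornado.** `one_way()` pins one parameter at each end of its
published range and recomputes the ICER; `tornado()` does this for all 29
parameters (the 28 cost/risk/utility rows of the parameter table plus the
discount rate, varied 0-5% -- the published count is 29 without an explicit
list, and the discount rate is the conventional extra variable) and sorts by
bar width. Survival parameters are *not* varied -- the published
distribution table contains only cost, risk and utility rows -- which is a
known limitation.

**Probabilistic.** `run_psa()` redraws all 28 uncertain parameters jointly
and independently each iteration (no correlation structure is published).
The point value/range pairs map to distributions via `build_sampler()`:
ranges are read as 95% intervals; lognormal uses `meanlog = log(median)`
(preserving the median exactly), gamma and beta are moment-matched with the
point value as mean. Infeasible beta moments raise an error naming the
parameter. Cost-effectiveness is decided by net monetary benefit
`NMB = WTP * QALY - cost`, which handles dominance correctly;
`ceac()` traces the acceptability curves over a WTP grid, complementary by
construction in the two-strategy case.

## Numerical choices and degenerate inputs

* Evaluation at integer cycle indices; the half-cycle correction is an
  accrual-timing option (`"half"`), not baked into the trace.
* Degenerate parameter ranges (`low == high`) yield constant samplers, so a
  fully degenerate config turns the PSA into 1000 copies of the base case --
  used as a test oracle.
* Fitting refuses all-censored data (unidentifiable) and single-point event
  data (degenerate); zero event times are nudged by half the smallest
  positive time so the likelihood exists.
* Ties in the KM estimator follow the standard event-before-censor rule.
* All randomness is seeded: `simulate_ipd(seed=)`, `run_psa(seed=)`,
  fixture seeds. Identical seeds give bit-identical output files.

Problem sizes used in the test suite: parameter-recovery fits at
n = 5000, sampler and law-of-large-number checks at 1e5 draws, PSA checks at
30-1000 iterations, trace properties over randomized parameter sets at a
60-80 cycle horizon -- sizes at which every stochastic assertion has
comfortable margin while the whole suite stays quick.

## Known limitations

* The calibrated conventions reproduce the published base case to within a
  few percent but are inferred, not documented; the published one-way ICER
  bracket for the XELOX second-line risk is about 4-5% narrower than this
  model's, and the published $100k acceptability (0.48) is below what any
  model with the published base-case ICER ($102,113/QALY, i.e. above
  $100,000) and a roughly symmetric draw distribution can produce -- this
  package reports its own computed values.
* No treatment-duration caps, dose modifications, tunnel states or
  patient-level microsimulation; second-line therapy enters as a single
  pooled cost.
* Utilities come from a different trial population and enter as two scalars.
* The irinotecan-only second-line scenario can be explored via config
  overrides (`set_param(cfg, "cost_second_line", ...)`), but no published
  unit cost exists for it, so it is not part of the defaults.
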