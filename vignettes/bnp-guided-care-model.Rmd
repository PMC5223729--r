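---
title: "A Markov cohort model of BNP-guided care in heart failure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of BNP-guided care in heart failure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnpcea)
```

## The decision problem

Serial monitoring of B-type natriuretic peptide (BNP) can guide the
uptitration of heart-failure pharmacotherapy. The randomised evidence,
pooled at the individual-patient level, points to a survival benefit that
is strongest in patients under 75 with reduced ejection fraction (mortality
HR 0.68), weaker and more uncertain in younger patients with preserved
ejection fraction (0.76) and in older patients with reduced ejection
fraction (0.87), with a modest effect on all-cause hospitalisation (0.94).
BNP-guided care also costs more: the tests themselves, extra medication,
and more unscheduled outpatient visits. `bnpcea` weighs these against each
other over the patient lifetime from a health-service perspective.

The model is deliberately simple: a two-state (*Alive*/*Dead*) Markov
cohort process with a 3-month cycle, in which hospitalisation is not a
state but a probability-weighted experience of each cycle spent alive.
This mirrors the structure used in national clinical-guideline modelling
for heart failure and reflects what the trial evidence can support — the
trials report mortality and admission rates, not transitions between
functional-status states. The price of that simplicity is discussed under
*Limitations*.

## Transition probabilities

**First 8 years.** Mortality uses a constant monthly hazard of 0.009
(under-75 baseline, estimated from linked primary-care/mortality registry
data), converted to a cycle probability as $p = 1 - e^{-3h}$. A sensitivity
scenario (SA1) replaces the exponential with a Weibull in the
proportional-hazards metric, $S(t) = \exp(-0.017\,t^{0.842})$: the shape
below 1 encodes a hazard that falls with time since the index admission,
so the conditional cycle probabilities decrease over the 8-year window.

**Beyond 8 years.** The cohort's attained age (start age + 8, advancing
one year every four cycles) indexes an age/sex life table; annual
probabilities are sex-weighted (two-thirds male), converted to 3-month
probabilities via $1-(1-q)^{1/4}$, and inflated by the heart-failure
relative risk. That RR is not stored as a number but derived the way it
was published: 7-year mortality of heart-failure cases (199/293) versus
matched controls (176/586), each converted to a per-cycle probability over
28 cycles, giving RR ≈ 3.14. In the probabilistic analysis the two
proportions are sampled from β(199, 94) and β(176, 410), so the RR's
uncertainty propagates without assuming a distribution for the ratio
itself. The HFpEF mortality adjustment (≈0.78) is derived identically from
1-year mortality proportions (766/3631 vs 584/2205) and multiplies every
cycle, including the life-table phase, since the evidence adjusts overall
survival rather than a time window.

**Hospitalisation.** A constant monthly hazard of 0.066 applies for the
model lifetime, identical for HFrEF and HFpEF (cohort data show a
negligible difference in all-cause admission risk at one year).

**Two hazard-ratio conventions.** The age ratios (mortality 2.801,
hospitalisation 1.248) come from the same proportional-hazards fits as the
baseline rates, so they multiply the monthly *hazard* before conversion.
The treatment-effect ratios, by contrast, multiply the cycle
*probability* during the effect window. At these magnitudes the two
conventions differ by well under 1% (e.g. 0.018114 vs 0.018192 for the
treated under-75 cycle probability); the probability-scale choice for
treatment effects matches how the relative risks are used elsewhere in
the model and keeps the HFpEF, life-table-RR and treatment multipliers
composable. All products are capped at probability 1.

**Effect window.** The primary analysis lets the treatment effect run for
4 years (16 cycles) — trial follow-up extends to 18 months with long-term
extensions suggesting persistence — and scenarios SA2/SA3 shrink it to 2
years or extend it for life. The hospitalisation effect shares the
mortality window: the evidence does not address its duration separately,
and a shared window is the conservative coherent choice.

## Accrual, costing and discounting

Transitions occur halfway through each cycle: a member dying in cycle *t*
contributes half a cycle of the not-hospitalised utility and state cost;
survivors contribute a full cycle split by $h_t$ between the hospitalised
and not-hospitalised experience. Discounting uses the matching mid-cycle
exponent, $(1+0.035)^{-(t+0.5)/4}$.

A hospitalised cycle mixes utilities by the 13.21-day mean stay within the
91.31-day cycle; a cycle is 91.31/365.25 years. The BNP-specific cost
streams are spread uniformly over their stated durations — £25 per test
for six cycles (18 months), £58.32/6 of medication per cycle for six
cycles, and (1.40 − 1.10)/8 incremental visits at £123 per cycle for eight
cycles (24 months) — and are scaled by the surviving fraction, so the dead
accrue nothing. Six tests over 18 months is the default reading of
"3-monthly testing for 18 months"; a seventh (baseline) test is available
via `strategy_costing(n_tests = 7)`. In the probabilistic analysis the
visit increment is the difference of two independently sampled γ variates,
floored at zero.

## Parameter registry and distributions

`inst/extdata/parameters.yaml` mirrors the published parameter tables row
for row: point estimate, units, distribution and source note. β
distributions represent probabilities and utilities, γ distributions
costs and resource use, log-normals hazard rates and ratios; fixed rows
(unit costs) never vary. Fitting is by the method of moments
(`beta_from_mean_se()`, `gamma_from_mean_se()`) or 95%-CI inversion
(`lognormal_from_ratio_ci()`, using the exact quantile 1.959964 — the
difference from 1.96 is below printed rounding).

Two registry conventions deserve a note:

- The utility rows keep their published β parameters (7321, 3772 and
  7978, 2383) as authoritative for sampling. The "SD" printed beside those
  means (0.26, 0.23) describes patient-level score spread, not the
  uncertainty of the mean — the β parameters imply standard errors around
  0.004, consistent with several-thousand-patient trial arms.
- γ rows are refit at load time from the published (mean, SE), which
  guarantees the sampling mean equals the point estimate. For all but one
  row this reproduces the published (shape, scale) to within printed
  rounding; the BNP visits row prints shape 94.52 where the method of
  moments on the printed (1.40, 0.14) gives exactly 100 — evidently
  computed from unrounded inputs. The refit is used and the discrepancy
  recorded in the row's source note.

## Probabilistic sensitivity analysis

Each PSA iteration draws every non-fixed parameter independently (no
correlation structure is imposed — there is no published information to
estimate one), rebuilds both arms' schedules, costings and traces, and
records costs, QALYs and the iNMB at λ = £20,000. Each iteration's RNG
stream is derived deterministically from `(seed, iteration)`, so results
are reproducible and independent of execution order. Summaries use
percentile intervals (2.5th/97.5th); a normal-approximation interval would
be a one-line change in `summarise_psa()` but percentiles make no
symmetry assumption. The acceptability curve uses a λ grid of £0–£50,000
in £500 steps (always containing £20,000) and counts draws with strictly
positive net benefit. The reference run uses 10,000 iterations, which
takes a few seconds per subgroup.

## Synthetic data

Two external-shaped inputs are generated rather than shipped:

- **Life table.** `generate_life_table()` builds Gompertz–Makeham
  mortality, $q(a) = 1-\exp(-(A + B e^{ca}))$, with defaults (slope 0.117,
  male level 5.5×10⁻⁶, female 4×10⁻⁶, Makeham term 5×10⁻⁴) chosen once to
  give plausible UK-scale magnitudes: male $q(65) ≈ 0.01$, $q(85) ≈ 0.1$,
  women somewhat lower. It is tagged `synthetic` and is **not** a national
  life table: headline lifetime totals computed from it differ from
  totals built on the genuine table by up to a few percent (the published
  £58,139 / 5.02 QALYs for the clinically guided under-75 HFrEF arm comes
  out at £57,302 / 5.06 here). Quantities resolved within the first 8
  model years — both arms' median survival among them — do not touch the
  life table at all. Users reproducing life-table-dependent results must
  supply the real table via `read_life_table()`.
- **Survival records.** `simulate_ipd_survival()` draws right-censored
  event times by inverse transform from exponential or Weibull
  proportional-hazards models with a binary age covariate, with optional
  administrative censoring and 7-day left truncation mirroring the
  exclusion of in-hospital and early deaths. What it does *not* emulate:
  real coding noise, competing risks, covariate measurement error, or
  calendar-time effects — parameter-recovery tests on these records
  validate the fitting machinery, not the epidemiology.

Survival fitting itself uses the closed-form stratified MLE for the
exponential (events over person-time; SE of the log rate $1/\sqrt{d}$) and
delegates the Weibull proportional-hazards MLE to
`flexsurv::flexsurvreg(dist = "weibullPH")`, started from the exponential
fit; `ph_to_aft()`/`aft_to_ph()` convert to the accelerated-failure-time
metric that `survival::survreg()` reports, and the test suite cross-checks
the two routes against each other.

## Numerical choices and degenerate inputs

- Median survival interpolates the alive curve linearly across the
  crossing cycle. On the cycle grid this yields 6.419 years for the
  clinically guided under-75 HFrEF cohort (continuous-time closed form:
  $\ln 2/0.009 = 77.0$ months = 6.418 years) and 7.710 years for the
  BNP-guided arm (closed form 7.70); the corresponding published figures
  (6.43, 7.75) carry roughly ±0.05 years of extraction/discretisation
  ambiguity, since the exact crossing rule used there is unstated. A
  cohort that never crosses 0.5 within its horizon returns `NA` flagged
  `censored`.
- Cycle-probability caps at 1 apply after all multiplications; no floor
  at the general-population rate is imposed.
- Fixed-seed determinism contracts: identical `(seed, iteration)` gives
  bit-identical parameter draws; simulators restore the caller's RNG
  state.
- Degenerate distribution inputs (zero-width CIs, SEs at the β
  feasibility bound) are rejected with errors naming the bound, except
  the exactly-degenerate ratio CI (lo = hi = ratio), which returns σ = 0
  flagged `degenerate`.

## Problem sizes used by the test suite

The suite runs the deterministic model at its full horizons (120/60
cycles), the reference PSA at 10,000 iterations, and parameter recovery on
50,000 simulated records — the same sizes as the reference analysis, since
all complete in seconds. Monte-Carlo properties (1/√n error shrinkage,
CEAC monotonicity) are checked on the 10,000-draw run; distribution
round-trips are exact-arithmetic checks.

## Limitations

- Two states only: no functional-status (NYHA) progression, no dependence
  of death risk on accumulated admissions, no readmission clustering.
  If BNP-guided care mainly changed morbidity among survivors, this
  structure would miss it.
- Utilities come from a hospitalised acute-decompensation population and
  are assumed age- and EF-invariant.
- The default life table is synthetic (see above); life-table-dependent
  totals are only comparable against analyses using the same table.
- No parameter correlations in the PSA; uncertainty intervals are
  conditional on independence.
- Costs are health-service only — social care, informal care and
  productivity are out of scope.
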