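---
title: "Methods: a Markov cost-effectiveness model of telehealth primary care for ADRD"
author: "teleCEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cost-effectiveness model of telehealth primary care for ADRD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teleCEA)
```

## The decision problem

Community-dwelling people living with Alzheimer's Disease-Related Disorders
(ADRD; ICD-10-CM F01 vascular dementia, F02 dementia in other diseases, F03
unspecified dementia) receive primary care either in person or by
telehealth. In provider-shortage regions the choice of delivery mode has
both cost consequences — caregiver travel and lost work time for in-person
care, training effort for telehealth — and consequences for the informal
caregiver's burden, which drives much of the downstream utilization (it is
usually the caregiver who decides to call 911 or attend the ED). Because
direct quality-of-life measurement is unreliable in moderate-to-severe
dementia, the analysis uses the caregiver's burden as the effectiveness
measure: the 12-item short-form Zarit Burden Interview (ZBI-12, raw range
0 = minimum burden to 48 = maximum burden), linearly rescaled to a
modified 0–100 scale where **higher is better**:

$$E = 100\left(1 - \frac{\mathrm{ZBI}_{\mathrm{raw}}}{48}\right).$$

`rescale_zbi()` implements this map; it is a bijection and its inverse is
`zbi_raw_from_modified()`. Whether the original instrument's "modified
scoring matrix" was linear is not documented anywhere we know of; linearity
is the simplest map consistent with both printed endpoints, and we flag it
as an assumption rather than a fact.

## The Markov cohort model

`run_cohort()` advances a closed cohort through three states — *in-person*,
*telehealth*, *dead* — in yearly cycles over a 10-year horizon (dementia
life expectancy makes longer horizons uninformative). The per-cycle inputs
for each live state are

| symbol | meaning | units |
|---|---|---|
| $s_{I\to T}, s_{T\to I}$ | annual switch probability, given survival | probability |
| $m_I, m_T$ | annual mortality | probability |
| $c_I, c_T$ | annual delivery-mode cost | USD/cycle |
| $e_I, e_T$ | mean modified ZBI-12 | points |
| $r$ | discount rate | 0.03/cycle |

**Competing risks within a cycle.** The inputs are marginal annual
percentages; an ordering must be chosen to compose them. We apply death
first and switching among survivors, which treats the printed mortality as
the actual annual death probability:

$$P(i \to \text{dead}) = m_i,\quad
  P(i \to j) = s_i\,(1 - m_i),\quad
  P(i \to i) = (1 - s_i)(1 - m_i).$$

`build_transition_matrix()` constructs this row-stochastic matrix; the
alternative (switch first) differs only at second order in $s\,m$. The same
ordering is used by the synthetic generator and by the estimators, so the
three stages are mutually consistent: in particular
`estimate_annual_probability(..., event = "switch")` divides switch events
by *surviving* at-risk person-years, which is the quantity the matrix uses.

**Rewards.** Rewards accrue at cycle start (cycle 0 undiscounted), with no
half-cycle correction by default; a `half_cycle_correction` flag exists for
comparison. The dead state carries zero cost and zero effectiveness —
assigning the burden scale's maximum (100) to death would reward mortality.
By default, per-cycle cost is the delivery-mode cost alone;
`include_utilization_costs = TRUE` additionally charges the expected
ED/hospitalization spending ($\lambda_{ED} c_{ED} + \lambda_H c_H$) per
live state-cycle, which is reported as a secondary analysis because the
scenario comparisons are defined on delivery-mode costs.

**Oracle.** The cohort trace is validated against an individual-level
microsimulation (100,000 walkers simulating the yearly events directly) to
3 binomial standard errors per trace cell; since a full trace has dozens of
cells, the test allows the single ~3-SE exceedance expected from sampling
noise while capping every cell at 4.5 SE.

## ICER conventions

For strategies defined by the starting state, `compute_icer()` reports
$\Delta C$ and $\Delta E$ (telehealth minus in-person) and two ratios:
`icer_standard` $= \Delta C / \Delta E$, and `icer_reported`
$= -\Delta C / \Delta E$, the sign convention of the scenario table this
package reproduces (negative = cost saving with telehealth; positive =
cost saving with in-person care).

Two bases for $\Delta$ are supported:

* **Totals** (`per_life_year = FALSE`): discounted 10-year sums. Because
  the two strategies differ in mortality, survival differences dominate
  the effectiveness totals: longer-lived cohorts accumulate more burden
  point-years *and* more cost-years, and the ratio mostly measures the
  value of added survival time.
* **Per person-year alive** (`per_life_year = TRUE`, the reported
  convention): each strategy's discounted totals are first divided by its
  discounted person-years alive. Writing the per-life-year cost as a
  survival-weighted average $w\,c_I + (1-w)\,c_T$ (with $w$ the share of
  discounted live time spent in-person) and likewise for effectiveness,
  the weights cancel in the ratio:

  $$\mathrm{ICER} =
    \frac{(w_T - w_I)(c_I - c_T)}{(w_T - w_I)(e_I - e_T)} =
    \frac{c_T - c_I}{e_T - e_I}.$$

  The per-person-year ICER therefore equals the incremental annual reward
  ratio exactly, for any transition structure. This identity is what makes
  the three scenario ICERs reproducible from the printed inputs (see
  below), and it is tested as a property of the implementation.

When $|\Delta E| < 10^{-9}$ point-years the ratio is declared undefined
(`NA`) to avoid meaningless huge ratios from floating-point noise, and the
comparison is decided on cost alone. Dominance is classified from the signs
of $\Delta C$ and $\Delta E$ (telehealth dominates iff it is no dearer and
no less effective, and not identical; NE/SW trade-offs otherwise).

```{r icers}
rep_ <- reproduce_paper_models()
rep_$deviation
```

The computed ICERs differ from the published ones by 0.6–4.8%. Two sources
fully account for this: the scenario inputs are printed rounded to two
decimals, and the accrual conventions of the original modelling software
are not documented. Under the totals convention the ratios are an order of
magnitude smaller (−1.03, −2.14, −0.34 for the three scenarios), which is
not compatible with the published values; the per-person-year convention
is, and is therefore the default for scenario reproduction. Both are
always available.

## The synthetic generator

`generate_cohort()` and `generate_discharges()` emulate the person-level
data the estimators need, since the underlying EHR/claims records are not
publicly available.

* **Demographics** come from packaged profiles of the urban (n = 58) and
  rural (n = 33) source cohorts. Gender and race probabilities are the
  published cohort *counts* as exact fractions (the printed percentages
  are rounded and do not sum to 100). Ages are truncated normal.
* **Moment calibration.** A truncated normal naively parameterised by the
  printed mean and SD realises a different mean (the truncation shift is
  ~0.5–3 points here), which would bias every downstream recovery check.
  `fit_truncnorm()` therefore solves for latent parameters such that the
  *realised* truncated mean equals the target exactly (root finding) and
  the realised SD is as close as the truncation allows (bounded 1-D
  optimisation). The same machinery calibrates the raw ZBI-12 score
  distribution on [0, 48].
* **Urban age range.** The source prints two ranges for the urban cohort
  (61–89 in the table, 61–98 in the text). No distribution on [61, 89] can
  have mean 81.3 *and* SD 9.7 under interior unimodality, while on
  [61, 98] the moments fit exactly, so the profile uses 98 ("89" is
  plausibly a digit transposition). The rural range (63–89) is kept as
  printed; its printed SD 6.5 is unattainable under that truncation (the
  fitter reaches 5.66 with the mean matched exactly).
* **Events.** Death then switching are drawn as annual Bernoulli events
  (death first, switching among survivors); ED/hospitalization counts are
  modality-specific Poisson draws that accrue regardless of same-year
  death; a dead person contributes no later person-years.
* **Discharges.** One record per counted event. ED stays are 1 day (ED
  visits have no overnight stay and are priced per event); inpatient
  length of stay is $1 + \mathrm{Poisson}(\mu_{LOS} - 1)$; daily charges
  are positive-truncated normal. Because the analysis prices an event as
  LOS times the mean daily charge of its diagnosis/age/gender group, the
  generator is calibrated with daily-charge mean equal to the scenario's
  ED cost per event and $\mu_{LOS}$ equal to the hospitalization/ED cost
  ratio (5.7–6.3 days, a realistic dementia inpatient stay), so estimated
  per-event costs reproduce the scenario unit costs. The raw ZBI-12 SD
  (9 points) is typical of dementia-caregiver samples; neither it nor the
  LOS/charge spread is printed anywhere, and none of the recovery targets
  depend on them beyond sampling error.
* **Contamination.** A configurable fraction of discharge records carries
  non-ADRD principal diagnoses (hypertension, stroke, Alzheimer's disease
  proper G30, etc.) to exercise the F01/F02/F03 cohort filter
  (`select_adrd_records()`).

What the generator does **not** emulate: real claims layouts and
adjudication, within-person correlation of utilization across years,
correlation between caregiver burden and utilization, age- or
severity-dependent event rates, or the matching step that produced the
source cohorts. Passing recovery tests therefore shows the estimators are
consistent for data with this independence structure, not that they would
be unbiased on real claims.

## Cost construction

`delivery_costs()` builds the two annual delivery-mode costs:
telehealth = trainer wage × training hours per conversion × annual
conversion probability; in-person = visits/year × (roundtrip miles ×
mileage rate + caregiver time valued at the wage rate over
`time_savings()` = roundtrip drive + in-person visit − telehealth visit
time). The construction inputs behind the published totals (USD 202–503)
are not printed; the packaged scenarios carry the totals directly and the
analysis scripts demonstrate the construction with plausible Nevada
magnitudes. `adjust_inflation()` compounds yearly healthcare inflation to
a 2022 baseline. `estimate_event_cost()` prices each discharge as LOS ×
mean daily charge of its (age band, gender, principal diagnosis) group and
directly standardizes the cell means by `{≤79, 80+} × {male, female}`
weights (the only age split the source prints; the small "other" gender
category is pooled with the majority gender for weighting). The
`sample_size()` helper implements the standard worst-case-proportion
formula with finite-population correction; with the stated confidence and
margin it yields 47 urban participants, not the 58 of the source cohort,
whose sample-size procedure is not documented — the function makes no
claim to reproduce it.

## Numerical and testing choices

All arithmetic is double precision with no rounding before presentation.
Truncated-normal draws use the inverse-CDF method (exact, vectorised,
deterministic under seed); the normalizing mass is computed in the upper
tail when both standardized bounds are positive to avoid cancellation.
Every pipeline output embeds a provenance header (package version, seed,
config hash) and no timestamps, so fixed-seed reruns are byte-identical.
Test problem sizes were chosen once as the smallest with comfortable
statistical resolution: 5,000–6,000 person-years for 3-SE recovery checks
(binomial SE ≈ 0.4–0.5 pp), 100,000 walkers for the microsimulation
oracle, 20–50 random parameter draws for property loops; the whole suite
runs in seconds.

## Known limitations

The model has no age-dependent transitions, no tunnel states and no
individual heterogeneity (the microsimulation exists only as a test
oracle). The per-person-year ICER convention makes the headline ratio
insensitive to mortality and discounting by construction — a property
inherited from the comparison it reproduces, visible in the sensitivity
stage where only the reward inputs move the ICER. The effectiveness scale
is a caregiver-burden substitute for utility, so the ICER is not
comparable to cost-per-QALY thresholds, and no willingness-to-pay or
probabilistic sensitivity analysis is defined for it.
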