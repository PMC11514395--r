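---
title: "Model structure, assumptions and uncertainty analysis in pgxcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and uncertainty analysis in pgxcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxcea)
```

## The decision problem

`pgxcea` evaluates, from a public-hospital payer perspective, whether
prescribing antidepressants for moderate-to-severe major depressive disorder
(MDD) guided by a CYP2D6/CYP2C19 multi-gene panel (PGx) is cost-effective
against standard dosing without testing (SoC). Poor (PM) and intermediate
(IM) metabolizers in the guided arm start at half the standard dose; rapid
(RM), ultra-rapid (URM) and normal metabolizers receive standard dosing in
both arms. The evaluation has two stages:

1. a **6-week decision tree** over the acute titration episode, producing
   per-patient success probabilities and expected cost, and
2. a **lifetime Markov cohort model** (ages 48 to 81, 3-month cycles) over
   five states — response, relapse, no response, suicide death, non-suicide
   death — producing discounted life-years (LY), quality-adjusted life-years
   (QALYs) and costs by category.

Costs are 2024 Qatari Riyal (QAR, 3.64 QAR = 1 USD); the willingness-to-pay
(WTP) threshold defaults to QAR 546,000 (USD 150,000) per QALY or life-year.
All outcomes are discounted at 3%/year, continuously in cycle time.

## The 6-week decision tree

Each patient belongs to one gene sub-model (CYP2D6 or CYP2C19, default
prescription share 0.5/0.5 — the weighting across the two gene panels is not
identified by the inputs, so it is an explicit setting) and one metabolizer
class with the Qatari phenotype prevalences; the non-NORMAL classes are
modelled as allele carriers and the NORMAL remainder as non-carriers. Within
each gene x class cell the tree is: response (yes/no), side effects among
responders, relapse among responders, and a management disposition after
relapse or non-response — switch to an alternative, titrate the dose
(non-response only), observe, discontinue, or attempt suicide, the attempt
splitting into death or survival. That grammar yields exactly 18 leaves per
cell, and leaf probabilities include the prevalence and gene weights, so the
full pathway table sums to one (enforced to 1e-12).

Two numerical conventions matter:

* **Disposition renormalization.** The published management shares
  (switch 0.68, titrate 0.20, observe 0.25, discontinue 0.26, attempt 0.06
  in the guided arm) do not form a simplex. They are renormalized within
  each decision context — relapse offers four options, non-response five —
  which preserves the printed relative weights. The printed suicide-death
  value 0.006 is interpreted as conditional on an attempt.
* **NORMAL-class probabilities.** No clinical rows are printed for normal
  metabolizers. The package assigns them the trial-baseline response (0.37),
  the strategy-specific relapse probabilities used by every other class, and
  the wild-type-like (URM/non-carrier) side-effect probabilities. These rows
  live in the clinical CSV and can be replaced wholesale.

Pathway costs sum lab/screening, one consultation, the genotyping panel
(guided arm only), acquisition (reduced-dose entries for PM/IM under
guidance), side-effect management, the relapse event, and
disposition-specific components. Discontinuation charges half the first-line
course plus a full alternative course; the alternative is priced like the
first line. The printed per-class "discontinuation" acquisition entries are
shipped too and can replace the half-course rule
(`settings$discontinuation_half_rule = FALSE`); the two disagree for one
cell, which is why the rule, not the entries, is the default. Switch,
post-discontinuation and post-attempt alternative courses are assumed
successful but, by default, do not count toward the success endpoints (they
are successes of the *replacement* regimen);
`settings$count_alternative_success = TRUE` counts them, which raises both
success probabilities by the same rescue mass and leaves costs unchanged.

## The lifetime Markov model

Everyone enters the response state. Per cycle, responders can relapse, stop
responding, or die; relapse and no-response states can return to response;
death states are absorbing. The published long-term transition block is
internally inconsistent (it contains two distinct "relapse" rows, a
"response" row, and a per-cycle suicide-death probability of 0.1175 — about
a 39% annual suicide rate — alongside a non-suicide-death row duplicating
the response row). The package therefore ships two parameterizations,
selectable with `load_parameters(variant = )`:

* **`reconciled` (default).** The block is read as a transition list:
  response→relapse onset (0.0949 / 0.2062 for PGx / SoC), relapse→response
  remission (0.0229 / 0.0572), response→no-response onset (0.0965), and
  no-response→response return (0.1180 / 0.1170). The per-cycle suicide
  hazard is *derived* from the short-term machinery — the context
  attempt shares times P(death | attempt) = 0.006 — applied to failure-state
  occupants and to incident failures, since the printed 0.1175 cannot be a
  per-cycle rate.
* **`as_printed`.** Identical structure, but the printed suicide-death
  entries (0.1175/0.1176) are kept as per-cycle hazards from the response
  state.

In both variants the non-suicide-death column comes from an age-specific
mortality schedule: age-group rates are fitted with a least-squares
polynomial (degree 2 by default) against band midpoints and converted to
3-month probabilities by `1 - (1 - p)^0.25`. Each living row is closed by
self-transition; rows that would exceed one are renormalized with a warning.
No local life table ships with the package, so the packaged schedule is a
**synthetic Gompertz-like stand-in** (0.002/year at age 48, doubling every
8 years — ordinary adult mortality reaching ~3%/year at 80). Every run
manifest flags this; users with real data point `mortality$table` at a CSV
of band midpoints and rates.

Rewards accrue on start-of-cycle occupancy: 0.25 LY per living cycle;
QALYs weight response time by age-banded utilities (0.871 at 40–49 falling
to 0.736 at 80+, half-open bands on the integer age), relapse by 0.55 and
no response by 0.48. Medication acquisition (648/595 QAR per cycle),
lab/screening (560) and follow-up (500) are charged per cycle alive. Event
costs (relapse 1,908; suicide death 29; attempt 779; non-suicide death
2,040) are charged on incident transitions by default; the cadence is
configurable (`event_cost_cadence = "per_cycle"` charges relapse per
occupied cycle, the only reading that approaches the published event-cost
scale). The survival event (2,600) is charged once to the mass alive at the
horizon. An optional trapezoidal half-cycle correction halves the first and
last cycle rewards.

## What reproduces and what does not

The packaged base case reproduces the *structure* and inputs of the
published analysis, but three published defects block exact reproduction of
its headline numbers, and the package reports its own computed values rather
than tuning toward printed ones:

* The short-term strategy totals imply a per-patient scale about seven times
  larger than any combination of the printed unit costs, and the genotyping
  panel (QAR 540) exceeds the recoverable per-patient differences (relapse
  events ≈ 47, side-effect management ≈ 20–50, acquisition ≈ 12), so the
  printed positive 6-week saving cannot follow from the printed unit costs;
  the package computes a small negative saving.
* The published per-arm lifetime cost rows imply roughly 39 discounted
  alive cycle-units per person — heavy excess mortality consistent only
  with the implausible printed suicide row — while any realistic schedule
  gives about twice that; lifetime cost levels therefore differ.
* The published cohort-scaled outcome rows are mutually inconsistent (more
  non-suicide deaths than cohort members), so the package reports
  per-person values and exposes `markov$cohort_size` as a multiplier only.

The per-person incremental results under the reconciled variant — about
0.12 discounted life-years saved — do land close to the published
per-person figures, and the probabilistic analysis reproduces the published
long-term dominance fraction (~40%).

## Uncertainty analysis

* **Distribution fitting.** Probabilities and utilities get beta
  distributions, costs gamma distributions, fitted by method of moments
  from a mean and 95% CI with SD = (upper − lower)/3.92. Fits preserve the
  mean exactly, which is what makes the PSA-centring property testable.
  Beta fits additionally require both shape parameters above one (a
  unimodal density); wider intervals are rejected as overdispersed.
  Most published inputs come without printed intervals, so defaults are
  ±20% of the mean for probabilities/utilities (upper bounds capped below
  one) and ±50% for costs, declared in `default_distribution_specs()` and
  overridable per parameter. Phenotype prevalences are fixed. The discount
  rate uses a symmetric triangular distribution (±25%).
* **PSA.** `run_psa()` jointly samples all non-fixed parameters and
  re-evaluates both stages per draw through a compiled evaluator that the
  test suite pins, to machine precision, against the reference
  implementations. The master seed spawns one substream per parameter, so
  increasing the draw count never reshuffles earlier draws. Sampled sets
  that break simplex constraints are renormalized in the same contexts as
  the base case.
* **CEAC and tornado.** The acceptability curve is the fraction of draws
  with positive net monetary benefit per WTP grid point. The tornado is an
  ordinary least-squares regression of the standardized output on the
  standardized sampled inputs, ranked by absolute coefficient; constant
  columns are dropped with a warning. (Mapped-value and stepwise variants
  exist in commercial tools; plain standardized OLS is committed here
  because it is reproducible and directly interpretable.)
* **Univariate sweeps and scenarios.** `univariate_sweep()` re-evaluates
  one parameter at ±25% of its mean. `apply_scenario()` provides the six
  standard scenarios (base, undiscounted, frozen age trends, 5-year
  horizon, duloxetine as the alternative course, half-cycle correction) as
  pure config transformations; the runner asserts that Markov-only
  scenarios leave the 6-week results bit-identical. The duloxetine course
  cost is not among the printed inputs, so the config ships an assumption
  (QAR 90 per 6-week course) that users should replace.

## The synthetic-data generator

`random_parameter_set()` draws complete parameterizations with the
structural constraints the analysis assumes — per-gene prevalence
simplexes, probabilities in (0.05, 0.95), positive disposition weights,
exponential costs, monotone-decreasing response utilities, feasible
transition rows — and every generated set passes the same validator as
hand-written configs. It emulates structure, not clinical realism: values
are not correlated the way real evidence synthesis would make them
(response and relapse are drawn independently, for instance), so passing
property tests on synthetic sets demonstrates correctness of the
probability algebra, conservation and accounting, not external validity on
real populations. `synthetic_mortality_table()` produces the Gompertz-like
age-band schedules; `perturbed_set()` applies bounded multiplicative noise
for robustness sweeps.

## Numerical choices and limitations

* Occupancy is propagated in exact arithmetic; conservation is enforced at
  1e-10 per cycle in tests over a thousand random parameterizations.
* Discounting is continuous, `(1.03)^(-t)`, with rewards booked at cycle
  start; there is no annual stepping.
* Test problem sizes: 1,000 synthetic parameter sets for the simplex and
  conservation properties, 200,000 simulated patients for the tree oracle,
  100,000 for the Markov oracle (3 Monte-Carlo SE agreement), and 50,000
  PSA draws for the centring check — sizes at which Monte-Carlo error is
  far below every tolerance asserted.
* Post-relapse refractory depression, recurrence dynamics beyond the five
  states, adherence, polypharmacy and indirect costs are out of scope, as
  is any claim of clinical utility on real patients.
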