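# pgxcea

Health-economic evaluation of pharmacogenetic (CYP2D6/CYP2C19 panel) guided
antidepressant prescribing versus standard of care in moderate-to-severe
major depressive disorder, for health-economics and pharmacogenomics
researchers who want the full model as tested, scriptable code rather than a
spreadsheet.

The model has two stages. A **6-week decision tree** stratifies a cohort by
gene (CYP2D6 or CYP2C19) and metabolizer phenotype (PM/IM/URM/RM/normal,
Qatari prevalences), with poor and intermediate metabolizers dose-reduced
under guidance, and expands response, side effects, relapse and the failure
dispositions (switch / titrate / observe / discontinue / suicide attempt)
into 18 pathways per cell; it yields success probabilities

P(success) = Σ_g w_g Σ_c π_gc · p_resp (1 − p_SE)(1 − p_relapse)

and expected per-patient cost Σ p_i c_i over all pathways. A **lifetime
Markov cohort model** (ages 48–81, 3-month cycles, states response /
relapse / no response / suicide death / non-suicide death, age-trended
mortality from a fitted polynomial schedule) accumulates discounted
(3%/year) life-years, age-band-utility-weighted QALYs and costs by
category. On top sit the standard decision-analytic quantities — ICER with
dominance classification, net monetary benefit at a QAR 546,000 WTP — and
the uncertainty apparatus: ±25% univariate sweeps, a seeded
beta/gamma/triangular Monte Carlo PSA, cost-effectiveness acceptability
curves, standardized-regression tornado rankings, six scenario analyses,
and cross-country cost adaptation. A synthetic-data module generates valid
random parameter sets and Gompertz-like mortality schedules so every
invariant is testable offline; the packaged mortality schedule itself is a
clearly flagged synthetic stand-in.

The published inputs this parameterization encodes contain three internal
inconsistencies (management shares that do not sum to one, a garbled
long-term transition block, an ambiguous cohort reporting scale). The
package resolves the first by context renormalization and ships two
long-term variants — `reconciled` (default) and `as_printed` — rather than
silently picking one; see `vignette("pgxcea-model")` for exactly what was
assumed and what does not reproduce.

## Worked example

```r
library(pgxcea)

params <- load_parameters()          # packaged base case, "reconciled" variant

compare_short_term(params)
#> <pgx_short_comparison> 6-week decision tree, PGx-guided vs standard of care
#>   P(response, no SE, no relapse): 0.1991 vs 0.1389  (diff +0.06019)
#>   P(response, +/- SE, no relapse): 0.3442 vs 0.2845  (diff +0.05970)
#>   expected cost/patient: 2387.9 vs 1953.6 QAR (saving -434.3)
#>   ICER (no-SE endpoint): COST_EFFECTIVE

compare_long_term(params)
#> <pgx_long_comparison> lifetime Markov cohort, PGx-guided vs standard of care
#>   LY/person: 19.4415 vs 19.3183 (diff +0.1232)
#>   QALY/person: 11.7495 vs 11.5864 (diff +0.1631)
#>   cost/person: 139343 vs 138856 QAR (saving -487)
#>   ICER per QALY: COST_EFFECTIVE
```

Guided prescribing buys a 6-point higher probability of side-effect-free,
relapse-free response, 0.12 discounted life-years and 0.16 discounted QALYs
per person; it costs slightly more than standard care (the QAR 540 panel is
not fully recouped at these unit costs), at an ICER of a few thousand QAR
per QALY — deeply cost-effective against the QAR 546,000 threshold.

```r
psa <- run_psa(params, n = 50000, seed = 1)   # ~2 min, bit-reproducible
psa$summary$fraction_dominant_long
#> [1] 0.42132                       # cost-saving in ~40% of draws
ceac(psa, seq(0, 1e6, by = 5e4))              # acceptability curve data
tornado_regression(psa, "delta_cost_short")   # ranked cost-saving drivers

run_report(params, which = c("base", "scenarios"), out_dir = "out")
```

`run_report()` writes the base-case and six-scenario tables, pathway and
trace audit CSVs, CEAC/tornado data and a `manifest.json` (seed, version,
config hash, synthetic-mortality warning). The same runs are available from
a shell via `inst/cli/pgxcea` (`validate`, `run-base`, `run-scenarios`,
`run-univariate`, `run-psa`, `adapt-cost`).

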