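# tilcea

Cost-utility modelling of adoptive cell therapy with tumor-infiltrating
lymphocytes (TIL) versus ipilimumab for unresectable stage IIIC–IV melanoma
after failure of first- or second-line treatment.

TIL therapy trades a large up-front cost (tumor harvest, GMP cell
production, admission for lymphodepleting chemotherapy, infusion, high-dose
IL-2) for substantially longer progression-free survival than ipilimumab.
`tilcea` implements the economic comparison as a tested R pipeline for
health-economics practitioners: a three-state (progression-free /
progressive disease / death) cohort model on a 3-month cycle, with

* **partitioned survival occupancy** read off two parametric curves:
  PFS(t) = S<sub>PFS</sub>(t), dead(t) = 1 − S<sub>OS</sub>(t),
  PD(t) = max(0, S<sub>OS</sub>(t) − S<sub>PFS</sub>(t));
* **parametric survival fitting and extrapolation** from summary points
  (closed-form linearisations, e.g. logit S on log t for the log-logistic
  S(t) = 1/(1 + (t/α)<sup>β</sup>)) or from right-censored individual
  patient data (maximum likelihood via `flexsurv`), with AIC/BIC ranking;
* **discounted accumulation** of life years, QALYs (progression-free
  utility series, next-line mixture utility in PD, pre-death utility 0.665
  in the cycle of death) and itemised costs with an exact per-cycle ledger;
* **incremental reporting**: ICER = ΔCost/ΔQALY, dominance classification
  on the cost-effectiveness plane, net monetary benefit
  NMB = λ·ΔQALY − ΔCost;
* **sensitivity analyses**: one-way tornado (±20% or 95% CI bounds, ranked
  by NMB span), 10,000-draw probabilistic analysis
  (beta/gamma/Dirichlet/lognormal sampling) and cost-effectiveness
  acceptability curves;
* a **seeded synthetic-data module** (PFS/OS event times with OS ≥ PFS per
  patient, EQ-5D-like visit utilities) so every stage is testable without
  access to trial data.

Scenario inputs (discount rates, willingness-to-pay, cost bundles, utility
series, next-line treatment mixtures, survival curves or points) live in
YAML configuration files; Dutch base-case and Danish scenario files with
the published 2021-€ inputs ship under `inst/extdata/`.

## Worked example

```r
library(tilcea)

model <- load_scenario(cua_example("nl_base_case.yaml"))
summary_table(model, horizons = Inf)
```

```
Cost-utility summary — Netherlands
 horizon_years discounted        arm life_years qalys total_cost
           Inf      FALSE        TIL       5.28  4.34     156096
           Inf      FALSE Ipilimumab       3.85  3.00     117733
           Inf       TRUE        TIL       4.68  3.86     153142
           Inf       TRUE Ipilimumab       3.50  2.73     116038

Incremental (TIL vs Ipilimumab):
 horizon_years discounted delta_ly delta_qaly delta_cost   classification icer_value nmb_at_wtp
           Inf      FALSE     1.43       1.35      38363 icer_ne_quadrant      28478      69404
           Inf       TRUE     1.18       1.13      37104 icer_ne_quadrant      32873      53193
```

Read: over a lifetime horizon the TIL arm gains 1.13 discounted QALYs at an
extra €37,104 — an ICER of €32,873 per QALY, cost-effective at the Dutch
€80,000 threshold (positive net monetary benefit of €53,193) though not
cost-saving. Lifetime *absolute* totals depend on inputs that are only
published in supplementary material (notably how long next-line regimens
run in progressive disease; this configuration charges each regimen's
per-course cost once at progression), so they are lower than the published
totals — see the methods vignette (`vignettes/cost-utility-model.Rmd`) for
the full discussion.

Uncertainty:

```r
psa <- run_psa(model, n = 10000, seed = 1)
prob_cost_effective(psa, 80000)   # fraction of draws with positive NMB
#> [1] 0.8739
head(run_dsa(model)[, c("parameter", "span")], 3)
#>                       parameter      span
#>          arms/TIL/os_curve/beta 105586.02
#>   arms/Ipilimumab/os_curve/beta  87695.77
#>         arms/TIL/os_curve/alpha  81901.72
```

The tornado is headed by the survival parameters and (further down) the
progressive-disease utilities and next-line costs, matching the published
qualitative finding.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/cua.R run --scenario inst/extdata/nl_base_case.yaml --out out/
Rscript inst/cli/cua.R fit-survival inst/extdata/table1_survival_points.csv --arm TIL --endpoint PFS
Rscript inst/cli/cua.R psa --scenario inst/extdata/dk_scenario.yaml --n 10000 --seed 1 --out psa/
Rscript inst/cli/cua.R simulate --scenario inst/extdata/nl_base_case.yaml --n-per-arm 500 --seed 1 --out sim/
```

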