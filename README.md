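# quitcea

Cost-effectiveness analysis of high- versus low-intensity smoking-cessation
treatment, built around a lifetime Markov cohort model of
smoking-attributable disease.

## The problem

Intensive cessation support (HIT: eight behavioural-therapy sessions,
€801 per participant) produces more quitters than minimal support (LIT: one
counselling session, €189 per participant), but its value depends on health
events decades later: a quitter's excess risk of lung cancer, COPD, CHD and
stroke decays gradually towards the never-smoker baseline, avoiding future
societal costs and quality-of-life losses. `quitcea` is for health
economists and trialists who need that whole chain in one tested place:

* a **Markov cohort engine** — annual cycles over states {well, lung
  cancer, COPD, CHD, stroke, dead} to age 95; quitter incidence
  `i_never + f(t)·(i_smoker − i_never)` with time-since-quit decay `f`,
  no relapse; discounted (3%/year) societal costs and QALYs;
* an **incremental CEA layer** — ICER = (ΔC_intervention − ΔC_societal) /
  ΔQALY with explicit dominance handling (`"<0"`, never a negative ratio);
* a **logistic abstinence model** —
  `logit P = −3.124 + 1.001·programme − 0.077·gender + 0.005·age`,
  with fitting, odds ratios, CIs and a synthetic-trial generator;
* a **PSA** — the HIT quit rate drawn 10 000 times from a truncated normal
  matched to its 95% CI (9%–22%), LIT fixed at 7%, summarised as a
  cost-effectiveness acceptability curve (CEAC);
* transcriptions of the trial's published summary tables as plain-CSV
  fixtures, and a synthetic parameter generator standing in for the
  unpublished national incidence/cost/utility tables.

## Worked example

Reproduce the published short-term incremental analysis from the packaged
fixtures:

```r
library(quitcea)

counts <- load_fixture_table("table3_counts")
pp     <- load_fixture_table("table3_per_person", refined = TRUE)
agg <- aggregate_benefits(
  data.frame(sex = counts$sex, age_group = counts$age_group,
             n_hit = counts$n_hit_short, n_lit = counts$n_lit_short), pp)
incremental_analysis(117011, 27927, agg$costs_avoided, agg$qalys_gained,
                     delta_intervention_cost = 89085)
#> <incremental_result> HIT vs LIT
#>   intervention cost difference: 89085 EUR
#>   societal costs avoided:       82253 EUR
#>   incremental net cost:         6832 EUR
#>   incremental QALYs:            7.44
#>   ICER:                         918 EUR/QALY
```

The 13 extra six-month abstainers in HIT avoid €82 253 of future societal
costs and gain 7.44 QALYs; the remaining net cost of €6 832 buys those
QALYs at €918 each — far below any conventional willingness-to-pay
threshold. (`refined = TRUE` de-rounds the printed per-person values using
the table's own group cells; see the methods vignette.)

Engine and PSA on synthetic parameters:

```r
p <- generate_synthetic_parameters(seed = 1)
quit_benefit("female", 42, p)
#> <quit_benefit> female, quit at 42: 12931 EUR avoided, 1.596 QALYs gained

curve <- ceac(run_psa(psa_config(n_runs = 10000, seed = 1)))
curve[curve$wtp %in% c(0, 2000, 5000, 10000), ]
#>      wtp probability_cost_effective
#> 1      0                     0.6541
#> 5   2000                     0.7637
#> 11  5000                     0.8481
#> 21 10000                     0.9132
```

At a willingness-to-pay of €5 000/QALY, HIT has an 85% probability of
positive net monetary benefit over LIT under the quit-rate uncertainty.

Command line (after install):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","quitcea.R",package="quitcea"))')" \
  report --horizon short --out out/
```

## Layout

| path | contents |
|---|---|
| `R/parameters.R` | parameter container, validator, synthetic generator, scenarios, CSV I/O |
| `R/fixtures.R` | registry of transcribed published tables |
| `R/markov.R` | cohort engine, quit benefits, discounting |
| `R/effectiveness.R` | logistic abstinence model, fitting, trial simulator |
| `R/cea.R` | incremental analysis, aggregation, per-person CEA, cost adjustment |
| `R/psa.R` | quit-rate sampling, PSA draws, CEAC |
| `R/pipeline.R` | run configs, provenance-stamped report writers |
| `vignettes/cessation-cea-methods.Rmd` | model, conventions, design choices, limitations |
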