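---
title: "Methods: modelling the cost-effectiveness of smoking-cessation intensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the cost-effectiveness of smoking-cessation intensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quitcea)
```

## The question the package answers

A high-intensity smoking-cessation programme (HIT: eight behavioural-therapy
sessions over four months) costs far more to deliver than a low-intensity one
(LIT: a single counselling session with a self-help programme). Whether the
extra cost is worth paying depends on events decades after the intervention:
a quitter's excess risk of lung cancer, COPD, CHD and stroke declines slowly
towards the never-smoker baseline, and with it the societal costs and
quality-of-life losses those diseases cause. `quitcea` implements the full
evaluation chain — lifetime Markov cohort model, incremental
cost-effectiveness analysis, logistic abstinence model, probabilistic
sensitivity analysis — for the trial comparing these two programmes in a
Swedish dental setting (294 smokers aged 19–71, ~78% women; 27 vs 14
six-month continuous abstainers at one year, 17 vs 7 sustained abstainers at
5–8 years).

## The Markov cohort model

States are `well`, one state per disease (lung cancer, COPD, CHD, stroke —
kept as four separate states; CHD and stroke are *not* merged into one
cardiovascular state, so cause-specific fatality and costs can differ), and
`dead`. Cycles are annual, from the quit age to age 95. For a cohort of
status $s$ at age $a$, the per-cycle incidence of disease $d$ is

$$
i_d(a, t) =
\begin{cases}
i_d^{\text{smoker}}(a) & s = \text{smoker}\\[2pt]
i_d^{\text{never}}(a) + f_d(t)\,\bigl(i_d^{\text{smoker}}(a) - i_d^{\text{never}}(a)\bigr) & s = \text{quitter},
\end{cases}
$$

where $f_d(t)$ is the remaining excess-risk fraction $t$ years after
quitting, with $f_d(0) = 1$ and $f_d$ non-increasing. There is no relapse to
smoking. Disease states are absorbing except for death (cause-specific case
fatality plus background mortality); competing outflows that would exceed
probability 1 are rescaled proportionally. Costs (`disease_cost` per year in
state) and QALYs (`utility` per year in state) accrue at cycle start — no
half-cycle correction, the simplest convention in the absence of a stated
one — discounted at 3% per year with year 0 undiscounted and the discount
clock starting at the intervention year (not at birth). Death is split into
disease-attributable and other-cause columns in the occupancy trace only;
outcome totals never need the split.

Per-person quit benefits are differences taken *outside* the model:
`costs_avoided` = smoker cost − quitter cost, `qalys_gained` = quitter QALYs
− smoker QALYs, per sex and quit age. Banded sweeps key each 5-year band by
its midpoint (42 for "40–44").

## What is fixture and what is synthetic

The national parameter tables behind the original analysis (incidence,
decay, costs, utilities for Sweden) are unpublished. The package therefore
separates two concerns:

* **Engine correctness** is established on *synthetic* parameters
  ([generate_synthetic_parameters()]) plus an independent brute-force
  path-enumeration oracle on small chains (tolerance 1e-10), conservation
  and limit checks (no excess risk ⇒ zero benefit; decay ≡ 1 ⇒ zero
  benefit).
* **Arithmetic reproduction** of the published incremental analyses uses the
  published per-person benefit table itself, shipped as a fixture
  (`load_fixture_table("table3_per_person")`).

The synthetic generator's anchors are calibrated to epidemiological orders
of magnitude only: never-smoker incidence rising log-linearly with age
(e.g. CHD $5\times10^{-4}$ at 19 growing at ~4.5%/year), smoker relative
risks of 15 (lung cancer), 10 (COPD) and 2 (CHD, stroke), exponential
post-quit decay with e-folding times of 2 years (cardiovascular) to 4 years
(lung cancer, COPD; 10% residual excess never resolves), Gompertz background
mortality, disease costs of €12 000–45 000/year and utilities of 0.55–0.72
against 0.88 when well. Seeded ~10% lognormal jitter turns property tests
into sweeps over a family of plausible models. What a green engine test
establishes is that the machinery is right; it deliberately does *not*
establish that any national parameter value is reproduced — those numbers
enter only through fixtures. The generator's defaults do reproduce the
qualitative published pattern (benefits decline with quit age; the
conservative scenario shrinks them), which real data also show.

## De-rounding the published per-person table

The published totals (82 253 € / 7.44 QALYs short-term) are *not* the sum of
the printed per-person values times count differences (that gives 82 256 /
7.43): the totals were computed from unrounded per-person values. The
printed group-difference cells recover the lost precision wherever the count
difference exceeds 1 — e.g. 42 658/5 = 8 531.6 € and 3.55/5 = 0.710 for
women 40–44, 13 342/4 = 3 335.5 € and 1.29/4 = 0.3225 for women 60–64.
`load_fixture_table("table3_per_person", refined = TRUE)` applies exactly
this de-rounding (preferring the short-term cell, then the long-term one,
then the printed value). With it the short-term aggregation is exact, and
the long-term one lands at 67 464.9 € / 5.705 QALYs against printed totals
of 67 466 / 5.71 — inside the ±5 € / ±0.01 QALY band that rounding of the
unprinted intermediates implies.

A related one-euro wrinkle: the published intervention-cost difference is
89 085 although the printed totals differ by 89 084; the published net costs
follow from 89 085. `incremental_analysis()` therefore accepts an optional
`delta_intervention_cost` so the published cells can be reproduced exactly;
ICERs (918, 3 786, 11 746 €/QALY) are identical either way after rounding.

## The logistic abstinence layer

Sustained abstinence is modelled as
$\operatorname{logit} P = -3.124 + 1.001\,\text{programme} - 0.077\,\text{gender} + 0.005\,\text{age}$
(programme 1 = HIT; gender documented as 1 = male; age in years, 19–71). The
published constant appears once without its decimal point ("−3124"); the
equation form is authoritative. `fit_abstinence_model()` delegates the MLE
to `stats::glm` and refuses fits with separation (including the silent kind
where `glm` "converges" to |coefficients| in the tens); parameter-recovery
tests regenerate records from the published coefficients and check CI
coverage across seeds.

Two printed statements could not be taken at face value and are handled
explicitly rather than silently corrected:

* The published LIT probabilities "0.4–0.5 (men) / 0.5–0.6 (women)" are an
  order of magnitude above what the equation yields (≈0.04–0.06) — almost
  certainly a decimal-point slip. The package reports what the equation
  gives.
* The population-level per-person analysis (779 € / 0.0664 QALYs for men,
  502 € / 0.0462 for women, incremental costs −167 and 110, women's ICER
  2 391) is reproduced *exactly* by evaluating the model at the sample mean
  age 48.6 with probabilities rounded to two decimals **and the gender
  indicator set to 1 for women** — the opposite of the documented coding.
  No single age reproduces all four cells under the documented coding,
  so the original computation evidently attached the (tiny, non-significant)
  gender term to women. `per_person_cea()` defaults to this reconstructed
  convention (`gender_indicator = "reported"`); the documented coding is a
  switch away (`"as_coded"`). The reconstruction also resolves the apparent
  ICER puzzle 110/0.0462 ≈ 2 381 ≠ 2 391: the unrounded incremental cost is
  110.45, and 110.45/0.0462 = 2 390.7.

## Sensitivity analyses

The deterministic conservative scenario (costs −25%, disease risks −50%,
death risks −10%, post-quit risk fractions −0.1, floored at 0) is a pure
parameter transformation ([apply_scenario()]). The decay delta is applied
for $t \ge 1$ only: $f_d(0) = 1$ is a structural identity (no time has
elapsed), and perturbing it would break the container's invariant without
affecting any benefit, which accrues only through $1 - f_d(t)$.

The PSA varies only what the trial left uncertain at population scale: the
HIT quit rate, drawn from a distribution matched to its 95% CI (9%–22%),
with LIT fixed at 7%. The distribution is unstated in the source; the
package uses a normal with mean at the CI midpoint (15.5%) and SD
$(0.22-0.09)/(2\times1.96) \approx 0.0332$, truncated to $[0,1]$ (a
moment-matched beta is available via `distribution = "beta"`). Each of the
10 000 draws $q$ maps linearly to per-participant incrementals using the
reference group with most quitters (women 40–44: 8 532 € / 0.71 QALYs per
quitter) and the per-participant cost difference 612 €:
$\Delta E = (q-0.07)\times 0.71$, $\Delta C = 612 - (q-0.07)\times 8532$.
The CEAC reports, per willingness-to-pay $\lambda$, the fraction of draws
with strictly positive net monetary benefit $\lambda\Delta E - \Delta C$
(ties count against, a convention fixed for determinism). Because the
framing is monotone in $q$, the curve has a closed form — the
truncated-normal survival function at
$q^\*(\lambda) = 0.07 + 612/(0.71\lambda + 8532)$ — which the test suite
uses as an independent oracle at every grid point.

One published sentence is deliberately *not* asserted: that HIT was more
cost-effective "at all values of willingness-to-pay, including zero". Under
any symmetric distribution matched to (9%, 22%), the probability at
$\lambda = 0$ is ≈0.65 (the threshold $q^\* \approx 0.142$ sits below the
mean but well within the distribution), not ~1. The package reports the
curve as computed.

## Numerical conventions and limitations

* Currency rounds half-away-from-zero to whole euros, QALYs to 2 decimals,
  at reporting time only; all internal arithmetic is unrounded.
* Dominance (net cost ≤ 0 with QALYs gained) is reported as `"<0"`, never a
  negative ratio; zero QALYs with non-zero net cost is "undefined".
* CSV outputs carry `#` provenance headers (package version, command, seed,
  config hash) and no timestamps, so identical configs give byte-identical
  files.
* The model inherits the source's structural simplifications: only three
  disease groups (effects of quitting are therefore conservative), no
  relapse among quitters (anti-conservative for short-term quitters), no
  comorbidity (first incident disease wins), no passive-smoking effects.
  Currency conversion (`adjust_costs()`) implements the CPI-then-PPP
  mechanism but ships no index values.
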