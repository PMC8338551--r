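---
title: "Cost-effectiveness of chemotherapy-free versus chemotherapy-based stem-cell mobilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-effectiveness of chemotherapy-free versus chemotherapy-based stem-cell mobilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobcea)
```

## The decision problem

Patients with multiple myeloma who are eligible for an autologous stem-cell
transplant first need their CD34+ progenitor cells mobilized into peripheral
blood and collected by apheresis. Two strategies are compared here from the
Italian societal perspective, in euro at 2019 prices:

* **Chemotherapy-based mobilization** (the comparator): cyclophosphamide
  4 g/m² plus G-CSF, with plerixafor added on demand for predicted poor
  mobilizers (probability 0.09).
* **Chemotherapy-free mobilization** (the treatment): G-CSF alone, with
  on-demand plerixafor (probability 0.47).

The effectiveness outcome is the probability of a *successful apheresis*,
defined as collecting at least 4×10⁶ CD34+ cells/kg. The model horizon runs
from mobilization to apheresis; the subsequent transplant, and the (remote)
risk of death in that window, are outside the model. Costs and effects are
undiscounted because the horizon is under a year.

## The decision tree and its flattening

Each arm's tree branches on on-demand plerixafor use, and (in the
chemotherapy arm) on febrile neutropenia and red-cell/platelet transfusions,
before reaching apheresis. Because every downstream cost is linear in the
event quantities, the chance nodes can be collapsed into expected quantities
without approximation: the model carries, per arm, the expected vials of
plerixafor, inpatient days, transfusions, performed and missed apheresis
sessions, and hours of lost work and informal care. Arm effectiveness is the
plerixafor-weighted mixture

$$E = p_\text{plx}\, e_\text{with} + (1 - p_\text{plx})\, e_\text{without},$$

with $e_\text{with} = 0.838$ and $e_\text{without} = 0.702$ shared between
the arms, giving $E = 0.766$ (chemotherapy-free) and $E = 0.714$
(chemotherapy-based) and an incremental effectiveness
$\Delta E = (p_1 - p_2)(e_\text{with} - e_\text{without}) = 0.38 \times 0.136
= 0.05168$.

```{r base-case}
cfg <- base_case_fixture()
compare_strategies(cfg)
```

## Costing rules

Costs are partitioned by payer: the Italian National Health Service (INHS,
whose tariffs proxy facility costs), out-of-pocket expenses (transportation,
parking), and patient/caregiver time. The societal total is the sum of the
three. The valuation rules implemented in `daily_hospital_cost()`,
`hotel_cost()`, `time_cost()` and `blended_time_rate()` are:

* inpatient per-diem = admission tariff / mean length of stay;
* when a procedure inside a tariff is costed separately, the tariff is halved
  to its hotel component (no double counting);
* lost working time is valued at the gross wage, blended over the employed
  fraction (0.5); informal-care and leisure time (the latter substituting
  work from age 70) at the net wage;
* missed apheresis sessions due to poor mobilization enter as an INHS
  opportunity cost at the session tariff.

Every cost item is `quantity × unit cost`, with the quantity a product of
parameter means (e.g. plerixafor drug cost = P(plerixafor) × vials per
treated patient × price per vial). Unit values not printed in the published
cost table were reconstructed by arithmetic on it, reconciled so that every
printed item, category subtotal, arm total and the incremental cost are
reproduced within €0.02 — the published table's own pennies are not
internally consistent (its chemo-free items sum to €7494.28 against a
printed €7494.27 subtotal), so exact per-item back-division alone cannot
match every figure. Items whose decomposition is genuinely unrecoverable
(G-CSF and cyclophosphamide acquisition, catheter, neutropenia episode cost,
handling, transport) are carried at their printed amounts with quantity one.
Two minor incoherences in the source are carried as-is rather than resolved:
the implied hourly informal-care rates differ slightly between arms
(€15.36 vs €16.17), and the chemotherapy arm's apheresis session rate
(€479.95) exceeds the chemotherapy-free one (€438.99), presumably an
inpatient/outpatient mix.

## Parameter uncertainty

Resource quantities are gamma distributed. A single coefficient of variation
of 0.4 (shape 6.25, scale mean/6.25) reproduces every reported 95% CI with a
strictly positive lower bound among the quantity rows — e.g. mean 2.00 →
(0.75, 3.85), mean 70.00 → (26.34, 134.61), mean 1.60 → (0.60, 3.08) — so
`gamma_from_mean_cv(mean, 0.4)` is the default when no interval is declared.
Where an interval is declared, `fit_shape_to_quantiles()` holds the mean
fixed and finds the shape minimizing the summed squared relative quantile
errors; on CV-0.4 intervals it recovers shape 6.25, and on the zero-lower-
bound rows (plerixafor vials, neutropenia days, transfusions, hours) — which
are composites of an event indicator and an amount — it yields shapes below
one, reproducing the reported spike near zero. The anthropometric height row
is the one reported interval inconsistent with CV 0.4 (it implies CV ≈ 0.1);
the fitter simply recovers its own shape.

Probabilities are beta distributed. Only their means are reported, so the
package adopts a dispersion convention: `sd = 0.4 · min(mean, 1 − mean)`,
capped at 95% of the feasibility bound. The choice mirrors the CV-0.4
convention, keeps the beta unimodal near either boundary (a naive
`0.4 · mean` at mean 0.838 would give a U-shaped density piling mass at 0
and 1), and implies P(e_with > e_without) ≈ 0.84, consistent with the
published share of Monte Carlo iterations with positive incremental
effectiveness (23.14% + 59.92% = 83.06%). It is a convention, clearly
flagged: the per-parameter distributions actually used for the published
probabilistic analysis are not recoverable, so printed quadrant shares and
acceptability values are qualitative references, not exact targets.

Drug acquisition costs and wage rates are held fixed (family `fixed`), so
they do not enter the sensitivity analyses.

## Sensitivity analyses

**One-way / tornado.** Each parameter with a declared CI or range is set to
its bounds, one at a time (`one_way()`, `tornado()`); parameters shared
between arms move both arms together. Bars are the percent deviation of the
raw ICER ratio from its base-case value, sorted widest-first. Because the
base case sits near $\Delta E$'s sign boundary for the effectiveness
parameters, their bars are strongly asymmetric — the ratio explodes as
$\Delta E \to 0$.

**Scenarios.** `run_scenario()` ships the published presets:
equal effectiveness (weak dominance of the cheaper arm), reversed
effectiveness, cyclophosphamide given in day-hospital, reversed
inpatient/outpatient neutropenia management, a catheter for all
chemotherapy-free patients, and outpatient apheresis in the chemotherapy
arm. Presets whose tariff recompositions are not recoverable carry the
published arm totals directly as cost overrides. The reversed-effectiveness
preset defaults to the `"printed"` rounding mode — increments rounded to
report precision (cost to cents, effectiveness to three decimals) before
division, which is how its published value 23,049.81 = 1198.59/0.052 arises
— while the day-hospital preset divides by the unrounded increment, again
following the published arithmetic; both behaviours are selectable for every
scenario via the `rounding` argument.

**Probabilistic.** `run_psa()` runs a 10,000-iteration Monte Carlo
simulation. Every uncertain parameter is drawn from its assigned
distribution using a deterministic substream derived from the master seed
and the parameter's name, so adding a parameter never perturbs another's
draws, and the effectiveness pair is drawn once per iteration and shared by
both arms. Each iteration yields $(\Delta C, \Delta E)$, a
cost-effectiveness-plane quadrant, and — across thresholds $\lambda$ — the
acceptability curve (share of iterations with positive incremental net
monetary benefit $\lambda \Delta E - \Delta C$) and frontier (the strategy
with the higher *expected* net benefit). Structural identities hold by
construction: quadrant shares sum to one, CEAC(0) equals the cost-saving
share SE + SW, and CEAC(λ) tends to the more-effective share NE + SE as
λ grows.

```{r psa}
psa <- run_psa(cfg, n = 10000, seed = 1)
psa
curve <- ceac(psa, c(0, 25000, 40000))
curve[, c("lambda", "p_treatment")]
ceaf(curve, psa)
```

## Numerical conventions

* Zero increments are detected with tolerance 1e-12; exact zeros arise only
  from structural scenarios (equal effectiveness), not from sampling.
* On the quadrant boundary $\Delta E = 0$, a draw is assigned to SE if
  cost-saving and NW otherwise, preserving "cost-effective at λ = 0 iff
  cost-saving"; ties in net benefit are credited to the comparator
  (conservative for the treatment).
* The ICER is reported as a dominance label *and* as the raw ratio — the
  published base case does both (−€23,192 yet "strongly dominant").
* Currency is kept at full floating precision internally and rounded
  half-even to cents only in reports; checks against printed aggregates use
  a €0.02 band for the pennies lost in the source's own rounding.
* The gamma shape fit searches log-shape in [−9.2, 13.8] with `optimize()`
  (tolerance 1e-12); the relative quantile error uses the bound as
  denominator, or the mean where the bound is zero.

## The synthetic generator

`random_model_config()` emulates the structure the analysis assumes — two
arms sharing an effectiveness pair, payer-partitioned items, gamma
quantities whose CIs are computed from their own generating distribution (so
the fitter inverts them exactly, unlike the published composite rows), beta
probabilities, optional Bernoulli-gated items — with every magnitude only
order-of-magnitude plausible. Two deliberate design points: with small
probability it emits an exactly zero effectiveness gap, or two mirrored
arms, because the weak-dominance and indeterminate labels otherwise occur
with probability zero; across many seeds all five dominance labels are
exercised. `perturb()` provides the metamorphic oracles (cost-scaling
homogeneity, common-item invariance of $\Delta C$, CI widening) used in the
test suite.

What passing tests on synthetic data do *not* show: the generator draws
parameters independently, uses round tariffs, and makes CIs exactly
invertible — real elicited data (like the published table) carry rounding
noise, composite rows and between-arm incoherences that the fixture
preserves but the generator does not emulate.

## Problem sizes and limitations

The shipped analyses use the published problem sizes: 10,000 Monte Carlo
iterations, a λ grid from 0 to 100,000 in steps of 1,000, and 1,000 seeded
synthetic configurations in the property suite; all run in seconds to a
couple of minutes on a single core.

Known limitations: only two strategies (no extended dominance), no
QALY/utility analysis, no correlation between parameters beyond the shared
effectiveness pair, no tariff database (supplementary tariff tables of the
source are not public), and the probabilistic results depend on the
dispersion conventions described above.
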