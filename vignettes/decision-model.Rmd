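---
title: "A three-state decision model for first-line immunochemotherapy in ES-SCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state decision model for first-line immunochemotherapy in ES-SCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclccea)
```

## The decision problem

Extensive-stage small-cell lung cancer (ES-SCLC) is treated first line with
platinum–etoposide chemotherapy, to which several immune checkpoint
inhibitors (ICIs) — atezolizumab, durvalumab (with or without tremelimumab),
serplulimab and adebrelimab — can be added. The combinations improve median
overall survival by a few months at a large acquisition cost. `sclccea`
implements the full decision-analytic pipeline used to weigh those
trade-offs from a Chinese healthcare-system perspective: reconstruction of
patient-level data from published survival curves, parametric extrapolation,
a three-state cohort model, cost and QALY accounting, an incremental
cost-effectiveness frontier, and deterministic and probabilistic
sensitivity analysis.

## Model structure and assumptions

Patients occupy one of three mutually exclusive states: progression-free
disease (PFD), progressed disease (PD) and death. Everyone starts in PFD.
The cycle length is 21 days (the treatment administration interval) and the
horizon 20 years — long enough that essentially the whole cohort reaches
the absorbing state. Costs and QALYs are discounted at 5% per year at cycle
resolution, `(1 + r)^(-k * 21 / 365.25)`.

State occupancy is driven by the progression-free survival (PFS) and
overall survival (OS) curves rather than by explicit transition matrices
(`state_occupancy()`): at each cycle start,

* Dead = 1 − S_OS(t),
* PFD = min(S_PFS(t), S_OS(t)),
* PD = S_OS(t) − PFD.

This partitioned-survival assignment reproduces both marginal curves
exactly and avoids committing to a PD→death rate that the published model
description leaves unspecified. The equivalent per-cycle conditional
probabilities `1 − S(t_{k+1})/S(t_k)` are exposed by `transition_prob()`
and the two formulations agree to numerical precision for non-crossing
curves (this equivalence is property-tested). Because the two endpoints
receive *independent* hazard-ratio adjustments, an adjusted PFS curve can
rise above the adjusted OS curve; occupancy is then clamped (PFD = S_OS,
PD = 0) and the number of clamped cycles is recorded on the trace.

## Survival inputs

The reference chemotherapy arm's curves are fitted to pseudo individual
patient data reconstructed from digitized Kaplan–Meier coordinates and
numbers-at-risk tables (`reconstruct_ipd()`). Within each risk-table
interval the number of censorings is solved iteratively so the
reconstructed number at risk matches the published value exactly, events
are allocated at the digitized drop times, and censor times are placed at
evenly spaced — deterministic, hence reproducible — positions inside the
interval. When no risk table is available, a stated effective sample size
is used and censoring is assumed administrative only; this degraded mode is
flagged with a message.

A digitized curve is a step function sampled at grid times: between grid
points the true event times are information that digitization has
discarded, so round-trip fidelity is assessed *at the digitized
coordinates*. There the reconstruction agrees with the source cohort's
Kaplan–Meier estimate to well under 0.02 across seeds (tested at n = 300
with a 1-month grid); pointwise deviations between grid points can exceed
that bound for any reconstruction algorithm and do not indicate an error.

Six candidate distributions (exponential, Weibull, log-normal,
log-logistic, Gompertz, gamma) are fitted by maximum likelihood under right
censoring (`fit_parametric()`) and compared by AIC/BIC (`select_best()`,
ties broken by fewer parameters then family name). The log-logistic family
is parameterised as

S(t) = 1 / (1 + exp(θ) t^κ),   κ > 0,

with t in months (30.4375 days/month, so cycle k sits at k·21/30.4375
months). Fitting is done by direct optimisation of the censored
log-likelihood on a transformed (unconstrained) scale with
moment-style starting values read off the Kaplan–Meier curve and up to two
perturbed restarts; `survival::survreg` is used in the test suite as an
independent cross-check for the families it supports.

ICI arms are obtained by raising the reference survival to the hazard
ratio, S(t)^HR (`apply_hr()`). For a log-logistic curve this exponent
adjustment is *not* the proportional-hazards transform; it is implemented
deliberately in this form because it is the adjustment the modelled
comparison specifies. A consequence worth knowing: HR < 1 lifts the whole
curve, and independent PFS/OS HRs can cross (see clamping above).

## Costs, utilities and adverse events

Drug acquisition costs accrue per cycle while in PFD (`drug_cost_schedule()`),
with doses computed from population anthropometrics: per-kg doses use the
sex-weighted mean weight (0.5·69.6 + 0.5·59.0 kg by default), per-BSA doses
use 1.72 m², and carboplatin uses the Calvert formula AUC·(CrCl + 25) at
70 ml/min. The chemotherapy backbone is capped at 4 induction cycles; ICIs
continue until progression. Vial sharing is assumed (exact milligrams
billed). The PD state carries a per-cycle subsequent-therapy cost, both
alive states carry follow-up and best-supportive-care costs, and a one-off
palliative cost is paid on each death (new deaths per cycle are the
increments of the Dead column, so the total equals final mortality).

Grade 3/4 adverse events enter as a one-off burden at model entry
(`ae_burden()`): each AE's chemotherapy frequency is scaled by the
strategy's AE hazard ratio (capped at 1), then cost is the
frequency-weighted sum of unit costs and the QALY loss the
frequency-weighted sum of disutility × duration. A one-off is used rather
than a per-cycle hazard because the AE inputs are cumulative incidence
proportions, not rates.

Health-state utilities default to 0.856 (PFD) and 0.768 (PD). QALYs
accumulate as occupancy × utility × cycle length, discounted; life-years
are reported undiscounted.

## The frontier

`icer()` is the plain incremental ratio; equal-QALY pairs are treated as
dominance cases, never as infinite ratios. `frontier()` sorts strategies by
ascending cost, removes strictly dominated strategies (weakly worse on
both axes against any single alternative, strictly on one), then removes
extended-dominated strategies one at a time — recomputing after each
removal — until the sequential ICERs along the chain strictly increase.
This is exactly the upper-left convex hull, and equivalence with an
exhaustive hull oracle is tested on 200 random instances. Negative ICERs
are reported verbatim in stepwise tables but never interpreted as
cost-effective. A paper-style stepwise presentation (per-pass D/ED flags
against the neighbouring alternative) is kept in `$rounds` for reporting;
on well-behaved tables it reaches the same frontier, and the authoritative
classification is always the hull-equivalent one.

## Sensitivity analysis

One-way DSA (`dsa_oneway()`) perturbs each parameter to its bounds —
hazard-ratio 95% CIs, 0–8% for the discount rate, ±25% for other inputs —
and ranks by ICER spread. `threshold_search()` bisects a monotone ICER to
a relative tolerance of 1e-6 (monotonicity is probed at the endpoints and
midpoint; non-monotone inputs are refused with advice to grid-search).

PSA (`psa()`) draws parameters independently: gamma for costs and prices,
beta for utilities, lognormal for hazard ratios matched to their 95% CI on
the log scale; ranges are converted to a standard deviation as
(high − low)/(2·1.96) and moment-matched so the mean equals the base value.
No correlation structure is imposed because none is specified for the
inputs. Draws are seed-deterministic; the seed is recorded in the result.
`ceac()` converts draws to acceptability curves — the probability of
maximal net monetary benefit per WTP, ties split equally — over a default
grid of 0–60,000 USD/QALY in 500-unit steps, spanning the 15,217–38,042.49
USD/QALY decision range (1.2–3.0 × per-capita GDP).

Subgroup analyses (`subgroup_run()`) swap in subgroup-specific hazard
ratios, with gender subgroups additionally using the sex-specific weight
for per-kg dosing.

## The synthetic world

The original model's input workbook (supplementary tables) is not publicly
available, so the package ships a generator, `demo_workbook()`, that
emulates it. Published constants — utilities, anthropometrics, exchange
rate 7.0467 CNY/USD, discount rate, WTP range, cycle and horizon, and the
six strategy-level (cost, QALY) pairs — are carried verbatim and isolated
in `paper_constants()` so provenance is machine-checkable. Everything else
is a labelled synthetic stand-in chosen once for realism:

* chemotherapy OS log-logistic (θ = −3.70, κ = 1.6), median ≈ 10.1 months,
  matching the commonly reported ~10-month median under chemotherapy;
  PFS (θ = −3.07, κ = 1.8), median ≈ 5.5 months;
* NMA-style hazard ratios in the 0.63–0.84 (OS) and 0.47–0.84 (PFS) range
  with serplulimab most effective, mirroring the qualitative ordering of
  the published comparison;
* label-schedule dosing rules with price-per-mg values of a realistic
  order of magnitude for 2023 Chinese bid-winning prices;
* a six-item grade 3/4 AE table typical of platinum–etoposide.

A green test on this world establishes that the *machinery* is correct
(accounting identities, oracle equivalences, recovery of known generating
parameters), not that the original cost and QALY totals are reproduced —
those depend on the unavailable inputs and are deliberately out of reach.
Where the printed results themselves suffice as inputs (the strategy-level
table), the published pairwise and stepwise ICERs and the dominance
classification are reproduced to within rounding of the printed figures.

## Numerical choices and limitations

* Cycle-start state evaluation, no half-cycle correction; the horizon is
  348 cycles (⌈20·365.25/21⌉).
* Trace rows sum to 1 within 1e-9; the accumulation step was verified
  against an independent scalar cycle-by-cycle oracle to 1e-6 relative.
* Bisection caps at 200 iterations; optimiser restarts cap at 3.
* Calendar conversions use 365.25 days/year and 30.4375 days/month
  throughout.
* Not modelled: background all-cause mortality floor, treatment-duration
  caps for ICIs, vial wastage (available as exact-mg billing only),
  correlated PSA parameters, EVPI.

## A worked example

```{r, eval = FALSE}
wb <- demo_workbook()
results <- run_base_case(wb)
ce_table(results)
fr <- frontier(results)
fr$table

# published strategy table: pairwise ICERs and the dominance frontier
frontier(published_strategies())$table

# one-way DSA and a 10,000-draw PSA
runner <- make_icer_runner(wb, "serplulimab+chemo")
tor <- dsa_oneway(default_dsa_specs(wb, "serplulimab+chemo"), runner)
run_pipeline(wb, "out", analyses = c("basecase", "frontier", "dsa", "psa"),
             seed = 1, psa_draws = 10000)
```
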