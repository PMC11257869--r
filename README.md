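# sclccea

Cost-effectiveness modelling of first-line immunochemotherapy for
extensive-stage small-cell lung cancer (ES-SCLC) from a Chinese
healthcare-system perspective.

Adding an immune checkpoint inhibitor (atezolizumab, durvalumab ±
tremelimumab, serplulimab or adebrelimab) to platinum–etoposide
chemotherapy buys a few months of survival at a large acquisition cost.
`sclccea` is a reusable, tested implementation of the decision-analytic
pipeline used to weigh that trade-off, for health-economics analysts who
want every stage scriptable and verifiable:

* **Pseudo-IPD reconstruction** — individual patient data rebuilt from
  digitized Kaplan–Meier coordinates plus numbers-at-risk tables
  (`reconstruct_ipd()`), with per-interval event/censor allocation solved
  to match the published counts exactly.
* **Parametric survival** — censored maximum-likelihood fits of six
  candidate families with AIC/BIC selection; the log-logistic family is
  parameterised S(t) = 1 / (1 + e^θ t^κ), and treatment arms are derived
  by exponent adjustment S(t)^HR.
* **Cohort model** — three states (progression-free, progressed, dead) on
  21-day cycles over 20 years, occupancy partitioned from the PFS and OS
  curves; discounted costs (anthropometric drug dosing incl. Calvert
  carboplatin dosing, adverse-event burden, supportive and palliative
  care) and QALYs (utilities 0.856 / 0.768).
* **Frontier analysis** — pairwise ICERs, net monetary benefit, and the
  stepwise dominance comparison: strict dominance, then iterative
  extended-dominance removal until sequential ICERs strictly increase
  (the ICER = ΔC/ΔE convex-hull frontier).
* **Sensitivity analysis** — one-way tornado DSA, bisection threshold
  search, 10,000-draw probabilistic sensitivity analysis with
  cost-effectiveness acceptability curves, and subgroup runs.
* **Synthetic data** — a generator (`demo_workbook()`, `gen_ipd()`,
  `digitize_km()`) producing every input the pipeline needs, with
  published constants isolated in `paper_constants()` and all stand-in
  values labelled synthetic.

## Worked example

The published strategy-level (cost, QALY) table ships as a fixture; the
frontier routine reproduces its dominance structure directly:

```r
library(sclccea)
fr <- frontier(published_strategies())
fr$table[, c("strategy", "cost", "qalys", "status", "seq_icer")]
#>                        strategy      cost   qalys             status seq_icer
#> 1                  chemotherapy  21409.67 1.02657           frontier       NA
#> 2             adebrelimab+chemo  60235.07 1.33257 extended_dominated       NA
#> 3             serplulimab+chemo  60519.52 1.51286           frontier 80424.95
#> 4            atezolizumab+chemo  73236.05 1.26971          dominated       NA
#> 5              durvalumab+chemo  90534.88 1.28249          dominated       NA
#> 6 durvalumab+tremelimumab+chemo 155946.55 1.19217          dominated       NA
```

Only serplulimab plus chemotherapy survives on the frontier, at a
sequential ICER of $80,424.95/QALY versus chemotherapy (the printed value,
$80,425.31, differs only by rounding of the printed inputs) — far above
the $15,217–$38,042.49/QALY willingness-to-pay range, so none of the
combinations is cost-effective against chemotherapy alone, but serplulimab
is the efficient choice among them.

The full synthetic pipeline runs end to end from the generated workbook:

```r
wb <- demo_workbook()
ce_table(run_base_case(wb))
#>                        strategy      cost    qalys      lys
#> 1                  chemotherapy  13460.72 1.163178 1.608080
#> 2             serplulimab+chemo 103591.71 2.120708 3.122083
#> 3             adebrelimab+chemo  61058.75 1.759268 2.583358
#> 4            atezolizumab+chemo 105496.05 1.633273 2.389360
#> 5              durvalumab+chemo 130889.94 1.653730 2.435608
#> 6 durvalumab+tremelimumab+chemo 127329.93 1.483567 2.139825

run_pipeline(wb, "out", analyses = c("basecase", "frontier", "dsa", "psa"),
             seed = 1, psa_draws = 10000)
```

`run_pipeline()` writes `basecase.csv`, `frontier.csv`, `stepwise.csv`,
`tornado.csv`, `psa_samples.csv`, `ceac.csv`, a JSON summary, a log and an
MD5 manifest (hash-identical across reruns with the same seed). These
synthetic totals exercise the machinery; they are not the published totals,
whose underlying input workbook is not publicly available (see the
vignette in `vignettes/decision-model.Rmd`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the installed package, the sequential ICER of the single
strategy remaining on the efficiency frontier versus chemotherapy after
strict- and extended-dominance removal on the six published (cost, QALY)
pairs, and writes it as JSON.
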