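# psmcea

Cost-effectiveness of adding the PD-L1 inhibitor **sugemalimab** to
first-line **CAPOX** chemotherapy (capecitabine + oxaliplatin) for advanced
or metastatic gastric / gastroesophageal-junction adenocarcinoma with PD-L1
combined positive score (CPS) ≥ 5, from the perspective of Taiwan's
single-payer National Health Insurance. Written for health-economics
analysts who want the full analysis — base case, sensitivity analyses,
scenario grid, price thresholds — as reproducible, tested R functions
driven by a single configuration object.

## The model

A three-state **partitioned survival model** (progression-free PF,
progressed disease PD, dead) on a 21-day cycle over a 40-year horizon.
State occupancy comes directly from the two parametric survival curves:

    PF(t)   = min{ S_PFS(t), S_OS(t) }
    PD(t)   = S_OS(t) − PF(t)
    dead(t) = 1 − S_OS(t)

OS and PFS are log-logistic fits per arm (log-normal in the CPS ≥ 10
subgroup), selected by AIC/BIC among seven parametric families fitted to
pseudo individual patient data reconstructed from published Kaplan–Meier
curves (Guyot-type algorithm, implemented in `reconstruct_ipd()`).

Discounted costs (2024 USD) and QALYs accrue per cycle; the headline
metrics are the incremental cost-effectiveness ratio and the incremental
net monetary benefit at willingness-to-pay λ = USD 101,949/QALY
(3× 2024 GDP per capita):

    ICER = ΔC / ΔE        INMB = ΔE·λ − ΔC

Uncertainty is handled by a one-way tornado analysis (`one_way_dsa()`), a
5000-iteration probabilistic sensitivity analysis with acceptability curve
and per-person expected value of perfect information (`run_psa()`,
`ceac()`, `evpi()`), a declarative scenario grid (`scenario_grid()`), and
bisection on the sugemalimab price for the value-based price
(`price_threshold()`). See the methods vignette
(`vignettes/psmcea-methods.Rmd`) for the accrual rules, counting
conventions and their rationale.

## Worked example

```r
library(psmcea)

cfg <- cea_config()        # bundled inputs, CPS >= 5 population
res <- cea(cfg)
res
#> sugemalimab + CAPOX vs CAPOX
#>   Incremental cost      46748 USD
#>   Incremental QALY      0.387   Incremental LY   0.458
#>   ICER     120641 USD/QALY   (   102059 USD/LY)
#>   INMB      -7243 USD at WTP 101,949 USD/QALY
```

Adding sugemalimab buys 0.39 QALYs for an extra USD 46,748 — an ICER of
about USD 120,600 per QALY, above the threshold, so the INMB is negative:
at the hypothesized price (USD 1,720 per 600 mg) the combination is **not
cost-effective**. `summary(res)` prints the full cost/LY/QALY breakdown by
state. The price that would flip the decision if reimbursement continued
until progression:

```r
price_threshold(cfg, duration_rule = "until_progression")
#> Threshold price: 561 USD per 600 mg (multiplier 0.326, a 67% reduction)
```

Other entry points: `run_psa(cfg, n = 5000, seed = 1)` for the
probabilistic analysis, `one_way_dsa(cfg)` for the tornado table,
`scenario_grid(cfg)` for the scenario rows, `cea(cea_config("cps10"))` for
the CPS ≥ 10 subgroup, and `simulate_ipd()` / `make_km_fixture()` /
`reconstruct_ipd()` / `fit_parsurv()` for the survival-curve pipeline.
Configurations round-trip through JSON with `write_config()` /
`load_config()`; `inst/extdata/config_base.json` is the bundled base case.

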