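---
title: "Model structure, conventions and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, conventions and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem

`psmcea` evaluates whether adding the PD-L1 inhibitor sugemalimab (1200 mg
IV every 3 weeks) to first-line CAPOX chemotherapy (capecitabine +
oxaliplatin, 21-day cycles, up to 6 cycles) is cost-effective for
unresectable advanced or metastatic gastric / gastroesophageal-junction
adenocarcinoma with PD-L1 combined positive score (CPS) ≥ 5, from the
perspective of Taiwan's single-payer National Health Insurance. Outcomes
are quality-adjusted life-years (QALYs); costs are direct medical costs in
2024 USD (TWD 32.11 per USD, applied when the configuration was authored);
the willingness-to-pay threshold is three times 2024 GDP per capita,
USD 101,949 per QALY. Both costs and effects are discounted at 3% per year
over a 40-year horizon.

## The partitioned survival model

The cohort occupies three states — progression-free (PF), progressed
disease (PD), dead — whose occupancy is read directly off the two survival
curves rather than from transition probabilities:

$$\mathrm{PF}(t) = \min\{S_{\mathrm{PFS}}(t),\, S_{\mathrm{OS}}(t)\},\qquad
  \mathrm{PD}(t) = S_{\mathrm{OS}}(t) - \mathrm{PF}(t),\qquad
  \mathrm{dead}(t) = 1 - S_{\mathrm{OS}}(t).$$

Because the two curves are extrapolated independently, the fitted PFS curve
can cross above OS in the far tail; the `min` cap resolves this and the
engine counts capped time points in its diagnostics. Health states are
independent in the usual partitioned-survival sense: nothing conditions PD
costs on the path into the state.

### Survival inputs

Trial patient-level data are not public, so the survival models are
parametric fits to pseudo individual patient data (IPD) reconstructed from
published Kaplan–Meier curves with `reconstruct_ipd()` (the standard
Guyot-type inversion). Seven families are supported (exponential, Weibull,
gamma, log-normal, log-logistic, Gompertz, generalized gamma), ranked by
AIC/BIC with `information_criteria()`. The bundled configuration carries
the fitted parameters: log-logistic for both endpoints and arms in the
CPS ≥ 5 population (e.g. OS shape 1.904, scale 16.860 months for the
combination; the log-logistic scale is the median, so these values imply
plausible median survivals in months), log-normal in the CPS ≥ 10
subgroup, plus an alternative "scenario" block per population. Parameter
standard errors feed the probabilistic analysis; 95% confidence bounds
feed the one-way analysis.

## Cycle grid and counting conventions

The cycle is 21 days — the dosing interval of both regimens — and the
horizon is covered by `ceiling(40 × 12 / 0.69)` = 696 cycles (months are
365.25/12 days). Two counting rules coexist, chosen once and validated by
a grid-convergence test (halving the cycle length moves total cost and
QALYs by well under 0.5%):

* **State occupancy** (life-years, QALYs, service costs on PF/PD
  occupancy) is evaluated at cycle *midpoints*. The midpoint rule is
  second-order accurate, serving the same purpose as a half-cycle
  correction.
* **On-treatment exposure** (drug acquisition and chemotherapy
  administration) is evaluated at cycle *ends*, over whole treatment
  cycles up to each drug's stopping time. Treatment is delivered in
  complete 21-day cycles, so a stopping time of 6.3 months buys
  `floor(6.3/0.69)` = 9 cycles; counting the progression-free fraction at
  the end of each cycle is the conservative claims-style accrual for a
  cycle of therapy. Exact per-component reproduction is not possible
  without the original implementation, and this pairing reproduced the
  reference cost breakdown markedly better than midpoint or
  beginning-of-cycle exposure during design.

Each cycle's flows are discounted at the cycle midpoint,
$(1+r)^{-t_{\mathrm{mid}}/12}$ with $r = 0.03$ per year.

## Treatment duration

Chemotherapy is a fixed 6-cycle protocol (about 4.14 months) in both arms
under every reimbursement rule: the comparator arm is therefore identical
across duration scenarios, and its drug spend reflects 6 cycles, not the
5.2-month arm-level median (which mixes in post-chemotherapy time). The
`duration_rule` governs only sugemalimab:

| rule | sugemalimab stops at | default |
|---|---|---|
| `median_duration` | 6.3 months (trial median treatment duration) | yes |
| `median_pfs` | 7.72 months (trial median PFS, used as printed) | |
| `protocol_max` | 24 months | |
| `until_progression` | never (follows PF occupancy to the horizon) | |

Stopping times interact with cost only; effectiveness is unchanged across
rules because treatment effect is already embedded in the fitted curves.

## Costs and utilities

Annual rates (2024 USD) accrue as occupancy × rate × cycle-years:

* PF: sugemalimab 59,814/yr and CAPOX 8,959/yr on on-treatment occupancy;
  chemotherapy administration 1,226/yr on chemotherapy exposure;
  non-medication services 25,925/yr on PF occupancy.
* PD: supportive care 63,077/yr, PD medication 4,682/yr and PD
  administration 2,018/yr on PD occupancy; terminal care as one month of
  54,893/yr per incident death (deaths counted from the OS decrement per
  cycle).
* Adverse events (grade ≥ 3, incidence > 5%: neutropenia and anemia,
  grouped by management) are one-off first-cycle quantities:
  cost `Σ prob × episode cost` and a QALY decrement
  `Σ prob × disutility`. The decrement is applied unscaled — an episode
  costs its full disutility once, not prorated to the 21-day cycle — which
  is what the reference state-level QALY breakdown implies.

Taiwan's fee schedule is point-based: medications are valued at TWD 1 per
point, while non-medication services (PF services, supportive care,
terminal care) are point counts cashed out at the conversion factor
(0.9198 TWD/point at base). The configuration stores those three rates as
point counts expressed in USD, and the engine multiplies them by the
conversion factor, so setting the factor to 1 (scenario 5) scales them by
exactly 1/0.9198.

Utilities are 0.812/0.746 (PF/PD, combination) and 0.798/0.721
(chemotherapy alone), beta-distributed in the probabilistic analysis.

The sugemalimab annual rate corresponds to a hypothesized price of
USD 1,720 per 600 mg vial (2 vials per administration, 365.25/21
administrations per year); `price_threshold()` exploits this
proportionality to solve, by bisection on the price multiplier, for the
price at which the incremental net monetary benefit (INMB) crosses zero
(tolerance 0.5 USD; INMB is linear in the multiplier, so the solution is
initialization-independent, which the tests assert).

## Sensitivity and scenario analysis

**One-way (tornado).** Every parameter moves to its 95% CI bound or ±25%
where no CI exists, others held at base; shared cost parameters move in
both arms together, arm-specific parameters in their arm. Rows are ranked
by INMB range. Degenerate bounds (low = high = base) produce exactly zero
range.

**Probabilistic.** 5000 Monte Carlo iterations by default: normal draws
for survival parameters (redrawn if non-positive, which is negligible at
the stated SEs), gamma for cost rates (mean/SD parameterization), beta for
utilities and disutilities, uniform for the conversion factor. The
sugemalimab price, adverse-event probabilities, treatment durations and
the discount rate are fixed. Draws are independent across parameters
(no published covariance; a simplification) **and across strategies**:
each arm receives its own draw of the shared cost, disutility and
conversion-factor parameters. Fully shared draws would make those
parameters cancel in the incremental comparison and compress the INMB
distribution (spread roughly 20k rather than 24k USD), understating the
decision uncertainty and the value of information implied by the reference
acceptability results; per-strategy draws are this package's convention.
The acceptability curve is evaluated on a 0–150,000 USD grid in 1,000-USD
steps, and `evpi()` returns
`mean(max per-draw NMB) − max(mean NMB)` per person.

**Scenarios.** `scenario_grid()` reproduces the standard grid: the
equal-value-of-life-years measure (effectiveness in unweighted life-years
— survival valued at weight 1, quality-of-life differences excluded),
the three alternative duration rules, 5/10/20/30-year horizons, price
multipliers 0.9–0.5, conversion factor 1, and the alternative survival
block. Declarative `scenario_spec()` overrides reject unknown keys.

## Synthetic data

`simulate_ipd()` draws event times by inverse-CDF sampling and censors by
the earlier of an administrative cutoff and (for a random fraction) a
uniform dropout time; `make_km_fixture()` turns a sample into a
digitized-curve fixture (exact KM step values plus exact at-risk counts,
optionally noise-perturbed). Default test fixtures use 250–300 subjects
per arm, the scale of a phase-3 arm. The generator emulates the
*statistical shape* of trial data — right-censored parametric event times —
but not real digitization artifacts (pixel quantization, clustered reading
errors), informative censoring, or covariate structure; round-trip
reconstruction accuracy on these fixtures (≤ 0.02 absolute survival)
therefore bounds algorithmic error, not end-to-end digitization error.

## Numerical choices and degenerate inputs

* Whole-cycle caps use `floor(cap/cycle + 1e-9)` to keep caps that are
  exact multiples of the cycle stable against floating-point noise.
* Reconstruction absorbs small digitization inconsistencies by padding
  censorings (or trimming events) at interval boundaries, but raises an
  error naming the interval when the risk table cannot be reconciled
  within 0.05 absolute survival.
* All-censored samples yield the constant-1 KM function; fits require at
  least 2 events and strictly positive times; non-convergent fits are
  returned flagged with diagnostics rather than silently.
* A horizon shorter than one cycle is a configuration error; residual
  survival above 1% at the horizon sets a diagnostic flag on the run.

## Known limitations

Survival parameters are sampled without covariance; time on treatment is a
fixed stopping time rather than a fitted time-to-discontinuation curve;
the model is cohort-level (no patient heterogeneity) and two-strategy (no
efficiency frontier); published parameters are used at their printed
precision, which — together with the unpublished cycle and counting
conventions of the reference implementation — bounds reproduction accuracy
at roughly the 1–3% level, far smaller than the parameter uncertainty the
probabilistic analysis propagates but visible in quantities that are small
differences of large numbers (e.g. net benefit near zero).
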