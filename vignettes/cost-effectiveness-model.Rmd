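---
title: "A partitioned-survival cost-effectiveness model for maintenance olaparib plus bevacizumab in advanced ovarian cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A partitioned-survival cost-effectiveness model for maintenance olaparib plus bevacizumab in advanced ovarian cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncocea)
```

## The decision problem

First-line maintenance therapy with the PARP inhibitor olaparib added to
bevacizumab improves progression-free survival (PFS) in advanced ovarian
cancer, with the largest gains in patients whose tumors carry a BRCA
mutation or are homologous-recombination deficient (HRD). The drug is
expensive, so the clinical question — *who should receive the
combination?* — has an economic counterpart: in which molecular subgroup
does the added benefit justify the added cost from a US payer's
perspective?

`oncocea` answers this with a three-state cohort model (progression
free, progressed disease, dead) evaluated separately for four
populations of the PAOLA-1 trial: all comers, BRCA-mutated, HRD-positive,
and HRD-positive without a BRCA mutation. For each subgroup it compares
olaparib plus bevacizumab (intervention) against bevacizumab alone
(comparator) on discounted lifetime cost, life-years (LYs) and
quality-adjusted life-years (QALYs), and summarizes the trade-off as an
incremental cost-effectiveness ratio (ICER) judged against a
willingness-to-pay (WTP) threshold of \$150,000/QALY.

## State occupancy: partitioned survival

Each arm of each subgroup is characterized by two parametric survival
curves, one for PFS and one for overall survival (OS). All bundled
curves are Weibull laws in the "proportional-hazards" parameterization

$$S(t) = \exp(-\lambda\, t^{\gamma}),$$

with $t$ in months, $\lambda$ the `scale` and $\gamma$ the `shape`
(see `?surv_spec` for the other four supported families). State
occupancy at time $t$ is read directly off the two curves:

$$\Pr(\text{PFS}) = \min\{S_\text{PFS}(t), S_\text{OS}(t)\}, \qquad
  \Pr(\text{dead}) = 1 - S_\text{OS}(t), \qquad
  \Pr(\text{PD}) = S_\text{OS}(t) - \Pr(\text{PFS}).$$

This *partitioned-survival* formulation was chosen over a
transition-probability Markov chain because the model's inputs **are**
fitted PFS and OS curves: partitioning reproduces those curves exactly,
by construction, whereas per-cycle transition probabilities derived from
them require additional assumptions about where post-progression
mortality risk resides (and, with a progression-reset death clock, can
imply overall survival the fitted OS curve never exhibited). The cost of
this choice is that the PD sojourn is only identified as the difference
of the two marginal curves — individual-level pathways through PD are
not modelled.

Where the extrapolated PFS curve crosses above the OS curve, PD
occupancy is clamped at zero; a crossing deeper than 0.02 attaches a
warning finding to the trace (attribute `findings`) rather than failing,
since modest tail crossings are an expected artifact of independently
fitted curves.

The trace is evaluated on a 3-week (21-day) cycle over a 15-year
horizon — 261 cycles — by which point more than 98% of every bundled
cohort is deceased, so the horizon effectively captures lifetime
outcomes. Months are converted at 30.4375 days/month.

```{r trace}
inp <- builtin_inputs("overall")
tr <- partitioned_trace(inp$arms$comparator$pfs, inp$arms$comparator$os,
                        inp$settings)
tail(tr[, c("cycle", "time_months", "pfs", "pd", "dead")], 3)
```

## Accrual, discounting and half-cycle correction

Costs and health effects accrue per cycle in proportion to state
occupancy, discounted at 3%/year with the continuous-time convention
$(1+r)^{-t/12}$. With half-cycle correction (the default) every
occupancy-proportional accrual uses the trapezoid of the
discounted occupancy at the two cycle boundaries; one-off costs
(molecular testing, AE management at entry, terminal care at death) are
not half-cycle corrected. Doubling the cycle length changes discounted
life-years by well under 1% with the correction on, so discretization
error is negligible at the 21-day default.

QALYs weight PFS time by utility 0.840 and PD time by 0.790. Grade ≥ 3
adverse events (AEs) enter twice, both applied once at model entry
because maintenance-therapy toxicity is front-loaded: a one-off QALY
decrement $\sum_{AE} \text{risk} \times \text{disutility}$ lasting one
cycle, and a one-off management cost. The published disutility set
assigns 0.17 to fatigue and 0.09 to the leukopenia-class event
(keyed here to lymphopenia, the grade ≥ 3 cytopenia observed in the
combination arm); the remaining AEs carry zero disutility.

Cost components per arm (all 2022 USD):

* **Maintenance drugs** — olaparib \$3,657/cycle for at most 35 cycles
  (2 years) and bevacizumab \$7,326/cycle for at most 22 cycles
  (15 months), both while progression free. Bevacizumab is dosed by
  weight (15 mg/kg), so its cost scales by `body_weight / 70`.
* **Administration** (\$124), **laboratory** (\$4) and **imaging**
  (\$105) per cycle while progression free; administration only on
  bevacizumab cycles (olaparib is oral). The laboratory row of the
  source cost table prints its three numbers ambiguously; it is read
  as mean \$4, range \$3–5, an interpretation that is immaterial at
  these magnitudes.
* **Molecular testing** — germline BRCA (\$2,901) plus HRD (\$4,682)
  once per patient in both arms, since the trial genotyped everyone;
  zero the costs to disable.
* **Second line** — a fraction (48.4% intervention / 61.0% comparator)
  of each cycle's incident progressions receives carboplatin +
  paclitaxel plus administration for 6 cycles (a standard course; the
  duration is an explicit, variable parameter). Paclitaxel is dosed by
  body surface area and scales by `body_surface_area / 1.84`.
* **Best supportive care** — \$4,143/cycle for PD occupancy not on
  second-line chemotherapy; BSC is taken to subsume routine monitoring
  after progression, so laboratory/imaging stop at progression to avoid
  double counting.
* **Terminal care** — \$85,904 applied to each cycle's incident deaths.

```{r base}
res <- run_base_case(inp)
res$comparison
```

## Survival fitting and synthetic IPD

The bundled curves were estimated upstream from trial Kaplan-Meier
data; the package also ships the estimation stage itself so it can be
audited and reused. `fit_parametric()` maximizes the right-censored
log-likelihood for any of the five families (via `flexsurvreg`,
re-expressed in the scale/shape forms above) and `select_best_model()`
picks the minimum-AIC fit, breaking ties by BIC and then parsimony —
with clean, well-identified data the two criteria rarely disagree, and
when they do AIC is given precedence as the less conservative choice
for a two-parameter family set.

Because the underlying patient-level data are not redistributable, the
`simulate_ipd()` generator provides statistically faithful stand-ins:
event times drawn by inverse-transform sampling from any `surv_spec`,
censored by an administrative cutoff and/or exponential dropout. It
emulates the right-censoring structure of trial follow-up, but not
digitization artifacts (pixel noise, risk-table rounding) of curves
reconstructed from published figures — parameter-recovery results on
synthetic IPD are therefore a best case with respect to those extra
error sources, while correctly exercising the likelihood, the
censoring handling and the selection rule.

```{r fit}
truth <- inp$arms$comparator$os
ipd <- simulate_ipd(truth, 5000, censoring_spec(surv_quantile(truth, 0.8)),
                    seed = 1)
fit_parametric(ipd, "weibull")
```

## Sensitivity analyses

* `one_way()` moves every distribution-bearing parameter ±20% around its
  baseline (utilities capped at 1) and ranks ICER spans — the tornado
  diagram. PFS utility dominates, followed by the olaparib price.
* `two_way()` evaluates a grid over two parameters, classifying each
  cell by the sign of the net monetary benefit
  $\text{NMB} = \text{WTP}\cdot\Delta\text{QALY} - \Delta\text{cost}$.
  The headline use varies the two arms' PFS utilities independently,
  which is why `arm_params` carries an optional per-arm
  `utility_pfs` override on top of the shared base-case utility.
* `run_psa()` performs Monte Carlo simulation: each iteration redraws
  all 28 distribution-bearing parameters and re-evaluates the full
  model. Beta (probabilities, utilities) and gamma (costs) distributions
  are moment-matched to the published mean and range, reading the range
  as a 95% interval, SE = (high − low)/3.92 — the published tables name
  families and ranges but no variance rule, so this interval reading is
  the package's own convention. Body measurements are truncated normals,
  the discount rate uniform on [0, 0.05]. Survival-curve parameters are
  held fixed: no sampling distribution (e.g. a covariance matrix on the
  log scale) is published for them, and inventing one would misstate
  decision uncertainty. The single bevacizumab price parameter moves
  both arms together. `ceac()` then gives the probability of positive
  NMB on a WTP grid (default \$0–300,000 in \$2,000 steps) and
  `wtp_at_probability()` interpolates threshold WTPs.

```{r psa, eval = FALSE}
draws <- run_psa(inp, n = 10000, seed = 1)
curve <- ceac(draws)
curve[curve$wtp == 150000, ]
```

All stochastic entry points take a seed and are reproducible
byte-for-byte. The test suite exercises the PSA at n = 2,000 iterations
and fitting at n = 5,000 patients, sizes at which Monte Carlo error is
comfortably below the assertion tolerances while the whole suite stays
fast; reported analyses use n = 10,000.

## Data quality: the HRD progression-free survival parameters

The bundled HRD-positive and HRD-positive/BRCA-wild-type parameter sets
carry PFS shapes numerically equal to their scales (0.014599 and
0.021614) exactly as printed in the source table. Shapes this far below
1 are not credible for maintenance-therapy PFS (they imply an extreme
early-failure law with essentially flat long-term survival) and the
shape = scale coincidence across four rows indicates a transcription
defect whose true values cannot be recovered from the printed table.
`validate_inputs()` therefore flags these inputs with warnings, every
report logs them, and quantitative conclusions for the two HRD
subgroups should not be drawn from the bundled curves; the subgroups
remain available so the machinery (validation, trace conservation,
sensitivity structure) can be exercised on them.

```{r hrd}
f <- validate_inputs(builtin_inputs("hrd_pos"))
f$message[f$severity == "warning"][1]
```

## Numerical choices and edge cases

* Optimization inside `fit_parametric()` inherits `flexsurvreg`'s
  behaviour (BFGS on log-transformed positive parameters); fits
  reaching non-positive shape or scale — possible for Gompertz on
  decelerating-hazard data — are rejected with a numerical error rather
  than silently returned outside the supported parameter space.
* Fewer than 10 records or all-censored data are refused as degenerate.
* A zero QALY delta with non-zero cost delta yields a signed infinite
  ICER (status `tradeoff`); identical outcomes yield `NaN`. Dominance
  is classified before any ratio is formed.
* Kaplan-Meier ties are processed events-before-censorings (the
  product-limit convention of `survival::survfit`).
* Occupancy conservation (`pfs + pd + dead = 1`) holds to 1e-12 at
  every cycle by construction and is asserted in tests.

## Limitations

Beyond the HRD input defect above: the model has no tunnel states or
time-in-state utilities; second-line therapy is a fixed 6-cycle course
followed by BSC; AE burden is front-loaded at entry rather than spread
over the treatment period; costs are US 2022 payer-perspective with no
inflation or currency adjustment; and extrapolation beyond trial
follow-up rests entirely on the Weibull tails — alternative families
fit nearly as well inside the observed window can imply materially
different lifetime estimates, which is precisely why the fitting and
selection stage is shipped rather than hidden.
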