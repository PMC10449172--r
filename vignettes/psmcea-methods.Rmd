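---
title: "Methods: a partitioned survival cost-effectiveness model for T-DXd in HER2-low advanced breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

This vignette documents the model implemented by `psmcea`, the assumptions
behind each accrual rule, the numerical choices, and the limits of what the
package's validation can show. It is written for an analyst who wants to
audit or extend the model, not only run it.

## The decision problem

Trastuzumab deruxtecan (T-DXd, 5.4 mg/kg IV every three weeks) is compared
with a physician's-choice single-agent chemotherapy basket (eribulin 51.1%,
capecitabine 20.1%, nab-paclitaxel 10.3%, gemcitabine 10.3%, paclitaxel
8.2% — the treatment distribution of the DESTINY-Breast04 trial) in
previously treated HER2-low advanced breast cancer, from a U.S. third-party
payer perspective, in 2021 USD. Three cohorts are analysed: the full
HER2-low population and the hormone-receptor-positive and -negative
subpopulations (`scenario_config("all" | "hr_positive" | "hr_negative")`).

## Model structure

A three-state partitioned survival model (progression-free, progressed,
dead) with weekly cycles over a 10-year horizon. State occupancy is read
directly off the marginal OS and PFS curves at each cycle boundary:
`pf = min(S_PFS, S_OS)`, `dead = 1 − S_OS`, `pd = S_OS − pf`. This makes
conservation (`pf + pd + dead = 1`) an identity, which the tests assert at
`1e-12`. Three deliberate choices:

* **Curve-crossing clamp.** Independently fitted PFS and OS curves can cross
  in the far tail; `pf` is clamped to `S_OS`. This is the standard PSM
  repair.
* **Trapezoid areas.** State-time is the trapezoidal area of occupancy
  across cycle boundaries. On a 1-week grid this is numerically equivalent
  to a half-cycle-corrected Markov sum, and it converges to the continuous
  area: the suite checks that `state_years()` matches adaptive-quadrature
  `rmst()` of the same curve to better than 0.2%.
* **Discounting.** 3%/year applied as `v(t) = 1.03^(−t/52)` at each weekly
  boundary. Annual-compounding-on-a-weekly-grid versus continuous
  compounding differs by under 0.05% over ten years; the former is used.
  Costs and QALYs are discounted; reported life-years are undiscounted
  (that convention is what reproduces the published life-expectancy cells).

## Survival inputs

Seven parametric families are supported, all on the **weekly** time scale:
exponential, Weibull, gamma, lognormal, Gompertz (hazard `a·e^{bt}`),
log-logistic, and generalized gamma in the Prentice `(μ, σ, Q)` form with
its Weibull (`Q = 1`) and lognormal (`Q = 0`) reductions verified
numerically in the tests. The log-logistic uses `S(t) = 1/(1+(λt)^γ)`: with
the published full-cohort parameters this puts the T-DXd OS median at
`1/λ ≈ 105.3` weeks ≈ 24.2 months and the chemotherapy OS median at ≈ 16.9
months, matching the trial medians — which is how the parameterization (and
the weekly scale) was pinned down, since the source does not state its
software's conventions. The lognormal uses `S(t) = 1 − Φ((ln t − μ)/σ)`,
whose median `e^μ` reproduces the trial PFS medians.

Distribution functions for Gompertz, log-logistic and generalized gamma
come from `flexsurv`; the rest from `stats`. These are standard numerics
and are deliberately not re-implemented.

### Censored maximum likelihood

`fit_censored_mle()` maximizes
`Σ_events ln f(t_i) + Σ_censored ln S(t_i)` with BFGS on log-transformed
positive parameters (identity for real-valued ones: lognormal `μ`, Gompertz
`b`, generalized-gamma `μ` and `Q`), from a moment-based start plus five
jittered restarts drawn under an internal fixed seed, so fits are
deterministic for fixed data. The covariance is the observed-information
inverse mapped to the natural scale by the delta method. Non-convergence is
flagged on the result, never silently absorbed. `rank_fits()` sorts by AIC
with deterministic tie-breaks: lower BIC, then fewer parameters, then a
fixed family order. The fit is cross-checked in the suite against
`flexsurv::flexsurvreg()` (matching log-likelihood and estimates on the
same data) and against closed forms (the exponential MLE
`#events / Σ time`).

### Kaplan–Meier reconstruction

`reconstruct_ipd()` implements the Guyot numbers-at-risk algorithm:
digitized survival probabilities are first re-monotonized by cumulative
minimum (digitizer jitter), then, interval by interval, integer event and
censoring counts are solved so that the product-limit curve of the output
tracks the digitized drops and the published at-risk count at the next
boundary, with censoring spread uniformly within the interval. Rounding
discrepancies of a subject or two (unavoidable with jittered input) are
absorbed at the interval end — surpluses as end-of-interval censorings,
deficits by retracting the latest events — while truly unsolvable
combinations raise an error naming the interval. When the total event count
is known it calibrates the final interval. The algorithm is deterministic,
and the output size equals the initial at-risk count by construction.
Because the source deposits no digitized coordinates or at-risk tables, the
built-in scenario configurations bypass this stage and carry the published
fitted parameters directly; reconstruction is validated entirely on
synthetic trials (round-trip agreement ≤ 0.02 in survival probability, and
parameter/RMST recovery — see below).

## Economic inputs and accrual rules

Unit costs (2021 USD), utilities and their 95% CIs are the published model
inputs; they ship in `econ_inputs()`, `default_tdxd_regimen()`,
`default_chemo_regimen()` and `default_param_specs()`. Accrual rules, per
cycle and discounted:

* **Drug + administration while progression-free.** Treat-to-progression
  with no maximum-cycles cap (the source states no duration rule; this is
  the standard assumption for this trial design). Per-administration drug
  cost is dose × (kg | m² | flat) × price/mg with no vial rounding;
  per-week cost prorates the dosing cycle. Administration is a first-hour
  fee plus additional-hour fees (default one extra hour for IV drugs, none
  for oral capecitabine).
* **Chemotherapy basket dosing** is share-weighted across the five agents.
  The shares are published; the schedules are **not**, so the package
  defaults to standard single-agent regimens (eribulin 1.4 mg/m² d1+d8
  q21d; capecitabine 1250 mg/m² bid d1–14 q21d; nab-paclitaxel 100 mg/m²
  d1,8,15 q28d; gemcitabine 1000 mg/m² d1,8 q21d; paclitaxel 80 mg/m²
  weekly), all config-overridable.
* **Monitoring.** One CT scan plus one follow-up fee per event while alive,
  every 6 weeks by default — the source prices the scan but not its
  frequency, so the frequency is a package default (`scan_interval_weeks`).
* **Best supportive care** per cycle while progressed.
* **Adverse events.** The aggregate per-arm grade ≥ 3 cost and disutility
  are applied once at model entry, reflecting how the published aggregates
  are defined; `aggregate_ae_burden()` is the frequency-weighting helper
  for itemized inputs.
* **Terminal care** accrues at death: the one-time cost times the per-cycle
  increment of the dead state, discounted at that cycle. At zero discount
  this conserves exactly `cost × dead(horizon)`, which the tests assert.

QALYs integrate `u_pf·pf + u_pd·pd` with discounting, minus the one-time AE
disutility. The type contract allows `u_pf = u_pd` so that the suite can
verify the degenerate identity QALY = LY at unit utilities.

`INHB(λ) = ΔE − ΔC/λ`. The source renders this formula inconsistently (its
inline text drops the division); the division form is used because it is
dimensionally correct and reproduces the printed net-benefit cells of the
hormone-receptor-positive and -negative cohorts exactly. The identity
`INHB·λ = INMB` is property-tested.

## Sensitivity machinery

* **One-way sweeps** re-run the whole pipeline at each parameter's bounds
  (95% CI where published, else ±20%), sorted by ICER spread; values that
  violate a type invariant flag the row rather than dropping it. A
  hazard-ratio multiplier on the T-DXd PFS curve is included as a driver
  and swept ±20% — its trial CI is not printed in the source, so the
  generic default is used rather than an invented interval.
* **PSA** draws gamma (costs), beta (utilities/disutilities) and normal
  (body measures) distributions, moment-matched from mean and CI with
  `SE = (hi − lo)/3.92`; survival parameters are point values in the source
  ("ND") and stay fixed, so the state traces are computed once and only the
  accrual re-runs per iteration. Out-of-support normal draws are redrawn
  and counted. All randomness flows from the seed argument; identical seeds
  give identical output.
* **CEAC** is the fraction of iterations with `ΔE·λ − ΔC > 0` on a
  $0–200,000 grid ($2,000 steps by default).
* **Threshold price** brackets the per-mg price with `uniroot` and verifies
  the returned price reproduces the target ICER within $1/QALY; the
  absence of a crossing is an explicit no-solution result.
* **Subgroups** replace the T-DXd PFS curve with `S_chemo(t)^HR` at the
  published subgroup hazard ratio, leaving OS unchanged. The source does
  not state which arm's curve was transformed; the comparator baseline is
  used because the printed ratios are T-DXd-vs-chemotherapy effects, and
  the choice is confined to `subgroup_analysis()`.

## Synthetic-data generator

`trial_truth()` fixes known parametric truth emulating the source trial's
conditions: 373 vs 184 patients, uniform accrual over 104 weeks inside a
160-week study window (administrative censoring = window − entry), weekly
digitization grid, at-risk tables every 13 weeks, digitizer jitter ±0.002
survival. PFS is coupled to OS per subject as
`min(progression, death)` so orderings are logically consistent; the
marginal curves the pipeline consumes are unaffected by the coupling.

What the generator does *not* emulate: informative censoring, delayed
treatment effects or non-proportional hazards, reading errors concentrated
at plateaus, and the discreteness of published at-risk grids coarser than
13 weeks. Passing the round-trip and recovery tests therefore shows the
algorithmic chain is faithful under clean trial-like conditions, not that
any specific published figure was digitized accurately.

## Validation scope and problem sizes

The suite checks closed forms (family medians and means, exponential MLE,
proportional-hazards identities), conservation at machine precision,
oracle-equivalence of the PSM area against quadrature RMST, Guyot
round-trips, parameter/RMST recovery on simulated trials, PSA degeneracy
and seed-reproducibility, CEAC limits and monotonicity, and threshold-price
inverse consistency. Simulation sizes are chosen to make the checks sharp
but quick: recovery at n = 1000–2000 subjects, model selection across all
seven families at n = 600 with 12 replicates (requiring the generating
family to rank first by AIC in ≥ 90%), PSA at a few hundred iterations for
distributional properties (the production default remains 10,000), and the
full synthetic pipeline at n = 500 per arm.

The headline *survival* quantities are exactly desk-checkable and are
recomputed by `scripts/acceptance.R`: the chemotherapy 10-year restricted
mean OS per cohort. Two published result groups are deliberately **not**
reproduction targets: (i) the analogous T-DXd life-year cells cannot be
obtained from the published T-DXd parameters under any standard
parameterization (the discrepancy is on the order of 10%, far beyond
integration error), and (ii) absolute cost totals, the base-case ICERs, the
threshold prices and CEAC probabilities depend on dosing schedules,
monitoring frequency and treatment-duration rules that are not published —
with the package's documented defaults the implied per-arm drug totals
differ several-fold from the printed ones, and no printed rule reconciles
them. For those, the package asserts internal properties (linearity,
conservation, inverse consistency, monotonicity) rather than numeric
agreement. The published full-cohort net-benefit cells also fail the
source's own INHB/INMB formulas as printed and are excluded from checks;
the other two cohorts' cells verify exactly.

## Known limitations

Marginal (not joint) survival modelling; no interval censoring, covariate
adjustment, spline or cure-fraction extrapolation; no per-event AE
itemization beyond the aggregation helper; no inflation machinery (inputs
are taken as 2021 USD); proportional hazards is assumed exact in subgroup
transforms; and the chemotherapy basket is costed as a share-weighted
average rather than as separate strategies.
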