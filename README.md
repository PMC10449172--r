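# psmcea

Partitioned survival cost-effectiveness modelling of trastuzumab deruxtecan
(T-DXd) versus physician's-choice chemotherapy for previously treated
HER2-low advanced breast cancer, from a United States third-party-payer
perspective.

`psmcea` is aimed at health-economics analysts who want a fully programmable,
testable version of the standard three-state partitioned survival model (PSM)
used in oncology health technology assessment, together with the machinery
around it: parametric survival extrapolation, pseudo individual-patient-data
(IPD) reconstruction from published Kaplan–Meier figures, deterministic and
probabilistic sensitivity analysis, threshold pricing, and hazard-ratio
subgroup analysis.

## The model

Patients occupy one of three mutually exclusive states — progression-free
(PF), progressed disease (PD), dead — with occupancy read directly off the
overall-survival (OS) and progression-free-survival (PFS) curves at weekly
cycles over a 10-year horizon:

```
pf(t)   = min(S_PFS(t), S_OS(t))
dead(t) = 1 − S_OS(t)
pd(t)   = S_OS(t) − pf(t)
```

Curves are parametric fits (exponential, Weibull, gamma, lognormal,
Gompertz, log-logistic, generalized gamma) on the weekly time scale; the
log-logistic survival function is `S(t) = 1/(1 + (λt)^γ)` and the lognormal
is `S(t) = 1 − Φ((ln t − μ)/σ)`. Curves can be supplied directly, or fitted
by censored maximum likelihood to pseudo-IPD reconstructed from digitized
Kaplan–Meier coordinates and numbers-at-risk tables (the Guyot algorithm),
with AIC/BIC ranking across families.

Costs (drug acquisition, administration, CT monitoring and follow-up, best
supportive care, adverse-event management, terminal care; 2021 USD) and
utilities (PF 0.830, PD 0.443 per year) accrue over the trace with 3%/year
discounting. Incremental results are reported as

```
ICER = ΔC/ΔE,   INHB(λ) = ΔE − ΔC/λ,   INMB(λ) = ΔE·λ − ΔC
```

at willingness-to-pay thresholds λ of $50,000 and $100,000 per QALY.

## Worked example

```r
library(psmcea)

cfg <- scenario_config("all")        # full HER2-low cohort, published inputs
res <- run_base_case(cfg)

res$result$strategies$tdxd
#> <strategy_result> trastuzumab_deruxtecan
#>   LY (PF / total): 1.458 / 2.980   QALY: 1.729
#>   cost total: $353,768 (drug 284,027, admin 4,622, monitor 9,026, BSC 33,746, AE 4,586, terminal 17,761)

res$result$strategies$chemo
#> <strategy_result> chemotherapy
#>   LY (PF / total): 0.697 / 2.151   QALY: 1.135
#>   cost total: $115,207 (drug 47,191, admin 3,870, monitor 6,566, BSC 32,952, AE 5,896, terminal 18,734)

res$result$comparisons[[2]]          # at the $100,000/QALY threshold
#> <ce_comparison> dC = $238,561, dE = 0.594 QALY, dLY = 0.829
#>   ICER: $401,454/QALY ($287,862/LY)
#>   at lambda $1e+05/QALY: INHB -1.791 QALY, INMB $-179,137
```

T-DXd gains 0.83 life-years and 0.59 QALYs over the chemotherapy basket at
an incremental cost of ~$239k under this package's treat-to-progression
drug-cost rule, giving an ICER of ~$401k/QALY — cost-ineffective at the
$100,000/QALY threshold under these assumptions (see the methods vignette
for why absolute cost totals are assumption-heavy, and which quantities are
instead exactly desk-checkable). The price at which T-DXd becomes
cost-effective is a bisection away:

```r
threshold_price(cfg, wtp = 1e5)
#> <threshold_result> price $10.9607/mg gives ICER $100000.00/QALY (target $1e+05)
```

Survival-side quantities reproduce the published life expectancies: the
chemotherapy OS model of the full cohort integrates to 2.151 undiscounted
life-years over 10 years (`rmst(model_from_spec(cfg$survival$chemo$os), 520, 0)`),
against 2.142 printed.

Probabilistic sensitivity analysis and acceptability curves:

```r
psa <- sample_psa(cfg, n_iter = 10000, seed = 1)
head(ceac(psa))                      # P(cost-effective) vs willingness-to-pay
tornado <- one_way_sweep(cfg)        # one-way sweeps, sorted by ICER spread
subgroups <- subgroup_table(scenario_config("hr_positive"))
```

Everything the pipeline consumes can also be generated synthetically from
known parametric truth — `trial_truth()`, `simulate_trial()`,
`digitize_km()`, `reconstruct_ipd()` — which is how the reconstruction and
fitting stages are validated end-to-end without any external data.

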