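# mltcburden

Illness-death Markov models for quantifying the burden of multiple
long-term conditions (MLTCs) — how many years people live with a
condition combination such as diabetes plus hypertension, and how many
years of life it costs them — estimated from person-month panel data of
the kind disease registries hold (monthly condition flags and vital
status per person).

The package is aimed at epidemiologists and health-service analysts. It
provides, as testable R functions plus a scripted analysis workflow:

* **Transition estimation** — tally monthly moves over the state space
  {healthy, ill, dead} by single year of age, estimate monthly transition
  matrices `P(i,j,a) = n(i,j,a) / Σ_k n(i,k,a)`, annualize by matrix
  power `T_y = T_m^12`, with an identity fallback at data-free ages and a
  ≥1,000-observations-per-transition-type eligibility filter.
* **Burden metrics** — propagate a birth cohort through the yearly
  matrices and compute lifetime risk
  `L_r = Σ_a P_healthy(a)·P(healthy→ill, a)`, median onset age, years
  lived with the combination `Y_LW`, years of life lost `Y_LL` against a
  two-state alive–dead comparator pooled from the same data, age at
  death, and community totals `C = 1000 · metric · L_r` per 1,000
  population.
* **Prevalence analytics** — point prevalence, observed-minus-expected
  joint prevalence of condition pairs (expected = product of marginals),
  and condition-count distributions by age band, sex and diabetes status.
* **A synthetic cohort generator** with analytic ground truth
  (Gompertz-type age-dependent hazards, excess mortality in illness,
  absorbing death, no remission), so the whole pipeline is validated by
  parameter recovery.

## Worked example

Simulate a 100,000-person panel under the default study hazards (a
common, high-incidence pair in an adult register), estimate, and compare
with the analytic ground truth:

```r
library(mltcburden)

hz <- default_study_hazards()
truth <- analytic_metrics(hz)

cc <- cohort_config(100000, uniform_ages(0, 99), observation_months = 12,
                    random_seed = 42,
                    initial_illness_prob = model_illness_prevalence(hz))
panel <- generate_panel(cc, hz)          # 1.3 million person-month rows
counts <- tally_transitions(panel)
check_eligibility(counts)
#>     transition count pass
#>   healthy->ill  1074 TRUE
#>  healthy->dead  1558 TRUE
#>      ill->dead  2126 TRUE
#> => eligible

matrices <- annualize(estimate_monthly_matrices(counts))
compute_burden(matrices, counts)
#> Illness-death burden metrics
#>   lifetime risk          0.5106
#>   median onset age       66
#>   years lived with       19.29
#>   years of life lost     3.76
#>   age at death           85.29
#>   per 1,000: lived 9851, lost 1921
truth
#> Illness-death burden metrics
#>   lifetime risk          0.5221
#>   median onset age       67
#>   years lived with       18.53
#>   years of life lost     3.75
#>   age at death           85.53
#>   per 1,000: lived 9675, lost 1958
```

Reading the output: about half the cohort eventually develops the
condition pair, typically in their late 60s; those who do live with it
close to 19 years and die roughly 3.8 years earlier than the general
population of the same age; per 1,000 residents that amounts to ~9,700
years lived with the pair and ~1,900 years of life lost. The estimates
track the ground truth; at the validation scale of 500,000 persons they
recover it within 2% relative on lifetime risk, 0.5 years on the year
metrics and one year on median onset.

The same steps, from simulation through prevalence tables, are scripted
as numbered drivers in `analysis/` (`01_simulate.R` … `04_prevalence.R`),
each writing its outputs under `results/`. Configuration-file driven
orchestration is available through `run_simulate()`, `run_burden()` and
`run_prevalence()`.

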