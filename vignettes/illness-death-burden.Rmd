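---
title: "Quantifying the burden of multiple long-term conditions with a discrete-time illness-death model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the burden of multiple long-term conditions with a discrete-time illness-death model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mltcburden)
```

## The problem

People living with diabetes frequently accumulate further long-term
conditions — hypertension, depression, coronary heart disease, and many
others. Two questions matter for planning care: if someone develops a given
condition pair (say, diabetes together with hypertension), **how many years
will they live with it**, and **how many years of life does it cost them**
relative to the general population? And at the population level, **how much
of this burden exists per 1,000 residents**, once the chance of ever
developing the pair is taken into account?

`mltcburden` answers these questions with a three-state illness-death
Markov model estimated from person-month panel data: monthly snapshots of
each person's condition flags and vital status. Because registry panels of
this kind are not publicly accessible, the package ships a synthetic cohort
generator with analytic ground truth, so every step of the pipeline can be
validated by parameter recovery.

## The model

The state space is $S = \{\text{healthy}, \text{ill}, \text{dead}\}$. "Ill"
means the condition combination of interest is present — for a pair, both
conditions at once, irrespective of any other conditions. Three transitions
are allowed: healthy $\to$ ill, healthy $\to$ dead, ill $\to$ dead. Death is
absorbing, and remission (ill $\to$ healthy) is not permitted; panels that
contain remission are reported and the combination is excluded by default,
since such data are incompatible with the model's structure.

### Estimation

Transition probabilities are age-dependent. For every pair of consecutive
months, one move from state $i$ to state $j$ is tallied at the person's age
$a$ in completed years at the *first* month of the pair (the data give no
finer resolution; first-month attribution is the package's deterministic
choice). The monthly transition probability is the observed proportion

$$P_{i,j,a} = \frac{n_{i,j,a}}{\sum_{k \in S} n_{i,k,a}},$$

which makes each estimated row sum to one exactly. Where a state has no
observed moves out of it at some age, the row falls back to the identity —
individuals are assumed to remain in their state — and the gap is recorded
per age and origin state. The fallback is applied per row, not per whole
age, which is the minimal reading of "no data for a state at an age".

Because the model advances in years, the monthly matrices $T_m(a)$ are
converted to yearly matrices by matrix power,

$$T_y(a) = T_m(a)^{12},$$

computed by 12 successive multiplications (exact and cheap at $3 \times 3$;
eigendecomposition would add nothing but rounding). Row sums are preserved
to $10^{-10}$ and the dead row is pinned at $(0, 0, 1)$ exactly.

### Eligibility

Rare combinations leave too few observed transitions to estimate
age-specific rates. A combination enters the model only when **at least
1,000 observations of each transition type** (healthy→ill, healthy→dead,
ill→dead) were recorded across all ages; the threshold is configurable and
the report lists which types failed. `compute_burden()` refuses ineligible
input unless explicitly overridden.

## The five metrics

A birth cohort starts healthy at age 0 and is propagated one age at a time
through $T_y(a)$, ages capped at 100 (beyond which survivors are too few to
matter for the outputs). Before each advance the **inflow** into illness is
recorded:

$$P_{h \to i}(a) = P_{\text{healthy}}(a) \cdot P_{\text{healthy},\,\text{ill},\,a}.$$

* **Lifetime risk** $L_r = \sum_{a=0}^{100} P_{h \to i}(a)$: the
  probability of ever entering the illness state.
* **Years lived with** the combination after entry at age $a$,
  $Y_{LW}(a)$: the sum of ill-state survival probabilities over ages
  $a..100$, with survival 1 at the entry age itself. There is no
  half-cycle correction: the entry year counts as lived, so certain death
  within the first year still yields exactly 1.0 years. The same
  convention is used for the comparator below, so the *difference* of the
  two curves is insensitive to it to first order.
* **Years of life lost** $Y_{LL}(a)$: the comparator's expected remaining
  years at $a$ minus $Y_{LW}(a)$. The comparator is a two-state
  alive–dead model *of the same form, from the same data*: its monthly
  death probability at each age pools deaths out of both alive states
  over all moves out of them, and is annualized the same way. When ill
  and comparator mortality coincide, $Y_{LL}(a) = 0$ exactly at every
  age.
* **Median onset age** $a_{\mathrm{median}}$: the integer $\alpha$
  minimizing $\left| \sum_{a=\alpha}^{100} P_{h \to i}(a) / L_r - 0.5
  \right|$. Ties are resolved to the lowest age at or after the
  half-crossing — the smallest tied $\alpha$ whose successor tail share
  is at most one half. This makes a point mass of inflow at age
  $a^\*$ return $a^\*$ itself, and a run of ages with tail share exactly
  one half return its lowest age.
* **Age at death**: reported as $a_{\mathrm{median}} + Y_{LW}$, the median
  onset plus the years lived with the combination.

The per-age quantities are averaged over entry ages with weights
$P_{h \to i}(a) / L_r$ — the share of lifetime entries occurring at each
age — giving $Y_{LW}$ and $Y_{LL}$. Community burden rescales them by how
common the combination is:

$$C_{YLW} = 1000 \cdot Y_{LW} \cdot L_r, \qquad
  C_{YLL} = 1000 \cdot Y_{LL} \cdot L_r,$$

total years lived with / lost to the combination per 1,000 population.
These identities hold to machine precision by construction.

If $L_r = 0$ the weighted averages and the median are undefined; the
package returns `NA` with a warning rather than 0, since "no one ever
becomes ill" is not the same as "zero years burden per affected person".

## Prevalence analytics

Cross-sectional snapshots (one row per person, one 0/1 flag per condition)
support three computations:

* **Point prevalence** of a condition within an age/sex stratum; empty
  strata are flagged not-computable rather than reported as zero.
* **Observed-minus-expected** joint prevalence of a pair, the expected
  value being the product of the two marginals. The published national
  worked example anchors this arithmetic: 3,663,429 of 46,748,714
  registered adults is 7.8% diabetes prevalence, and a 14% joint
  diabetes–hypertension prevalence against a 9.5% independence
  expectation leaves a 4.5-point excess. The default computation is
  crude (whole-population); a stratum filter is available because
  age-confounded excess can differ substantially from within-stratum
  excess.
* **Condition-count distributions**: per age band × sex × diabetes
  status, the proportion of persons with at least $k$ conditions. Persons
  with diabetes count diabetes among their conditions; the comparator
  group (no diabetes) counts the remaining conditions only. Reported
  percentages are rounded to one decimal, half away from zero.

## The synthetic study

`generate_panel()` simulates the discrete-time process the estimator
assumes: per month, death is sampled first with the state-appropriate
mortality hazard, then illness onset among surviving healthy persons — so
nobody becomes ill and dies in the same month, matching what monthly
snapshots can actually record. All randomness derives from one root seed,
with each person owning a fixed row of pre-drawn uniforms, so panels are
byte-identical across runs and independent of iteration order.

The default study conditions emulate a common, high-incidence condition
pair in an adult register:

| parameter | default | meaning |
|---|---|---|
| illness onset | Gompertz $\min(1, 5\times 10^{-5} e^{0.05 a})$ / month | ≈1.2%/year at age 60, rising with age |
| healthy mortality | Gompertz $\min(1, 2.5\times 10^{-6} e^{0.09 a})$ / month | ≈0.7%/year at 60, a life-table-like slope |
| ill mortality | 2.5 × healthy | proportional excess mortality, capped at 1 |
| cohort | 500,000 persons, start ages uniform 0–99 | one year of monthly follow-up (13 snapshots) |

Two features matter for validity of the validation itself. First, a
one-year window only recovers the pooled alive–dead comparator if the
healthy/ill mix among the alive at each age matches the model's own
conditional occupancy; the generator therefore seeds prevalent cases at
entry with `model_illness_prevalence()`, the prevalence implied by
propagating the hazards from birth. Second, the analytic ground truth
(`analytic_metrics()`) pushes the *generating* hazards through the *same*
metric definitions — true monthly matrices, annualization, yearly cohort
propagation — so recovery tests compare estimator noise, not definition
mismatch.

What the generator does **not** emulate: mid-window entry and exit
(censoring) — every person has complete follow-up, unlike GP registration
data; realistic national demography or calibrated life tables; more than
one illness process at a time in the panel (multi-condition flag panels
are supported as input via `apply_illness_definition()`, but the generator
produces the three-state panel directly). Passing recovery tests therefore
demonstrates correctness of the estimation machinery under the model's own
assumptions, not robustness to the messiness of real registry data.

## Validation strategy

The test suite validates the pipeline along independent routes:

* **Closed forms**: annualization against the scalar identity
  $1-(1-p)^{12}$ on two-state collapses (tolerance $10^{-12}$); geometric
  survival sums; hand-computed weighted means.
* **Brute force**: yearly propagation against 1,200-step monthly
  propagation collapsed to years ($10^{-8}$); lifetime risk against a
  plain scalar loop.
* **Microsimulation**: 200,000 walkers traverse the same yearly matrices;
  lifetime risk and years-lived-with must agree within 3 Monte-Carlo
  standard errors, median onset within one year (it is integer-valued).
  A walker drawing the ill destination from the age-$a$ row is treated
  as entering *at* $a$ — entry year lived, same-year ill mortality
  applied — the exact estimand of the deterministic curves.
* **Parameter recovery**: panels of 500,000 persons under the default
  hazards, end to end through tally, estimation and metrics, recover the
  analytic ground truth within 2% relative on $L_r$, 0.5 years on
  $Y_{LW}$ and $Y_{LL}$, one year on $a_{\mathrm{median}}$. Per-age
  estimated probabilities are checked cell by cell against the generating
  hazards with exact binomial intervals, multiplicity-controlled across
  the ~300 simultaneous checks (at young ages expected death counts are
  far below 1, where normal-approximation z-scores are meaningless).
* **Structural properties**: row-stochasticity and occupancy conservation
  at $10^{-10}$; exact zero years lost under equal mortality; and across
  randomized matrix families, uniformly increased ill mortality never
  decreases $Y_{LL}$ nor increases $Y_{LW}$.

A worked end-to-end run, with the numbers it prints, is in the README; the
numbered scripts under `analysis/` reproduce the whole study and write
their tables under `results/`.

## Numerical and design choices

* Ages are integers 0–100 inclusive (101 bins); all sums truncate at 100.
* Matrix powers use repeated multiplication, never eigendecomposition.
* The identity fallback at data-free ages implies immortality in the ill
  state wherever ill-state data run out at high ages; the age cap bounds
  the resulting bias, and `data_present` exposes exactly where the
  fallback acted. The bias is documented rather than corrected, because
  inventing mortality where none was observed would be a stronger
  assumption than staying put.
* The comparator pools *all* alive person-months, including those with
  the condition pair — "the general population" rather than "the healthy
  population". This makes the null case ($Y_{LL} = 0$ under equal
  mortality) exact and avoids an external life-table dependency.
* Per-age $Y_{LW}(a)$/$Y_{LL}(a)$ are expectations of the survival
  distribution, not medians; a median-based variant would be a natural
  extension but is not implemented.
* The observed-minus-expected excess is computed crudely by default; the
  stratified option exists because the crude figure mixes age effects
  into the association.

## Limitations

Beyond the generator's idealizations listed above: the model has no
covariates (no smoothing or borrowing strength across ages), no
interval-censoring correction for events between monthly snapshots, no
confidence intervals (no bootstrap), and no adjustment for third
conditions co-occurring with a pair — years lost are associational, not
causal. The age-at-death composition $a_{\mathrm{median}} + Y_{LW}$
combines a median with an expectation and should be read as a summary
construction, not a distributional statement.
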