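# ticsim

Dynamic microsimulation of cognitive trajectories in older adults, built
around the 27-point Telephone Interview for Cognitive Status score
(TICS27, 0–27). The package is aimed at health-policy and epidemiology
modellers who need to project cognitive decline, dementia incidence and
mortality jointly over multi-year horizons, and to validate such
simulators against longitudinal survey data.

## The model

Two first-order Markov transition models drive biennial steps:

* **Score transition** — an ordered probit. The next score S arises from a
  latent index y\* = x'β + ε, ε ~ N(0, 1), observed as level j when
  κ\_{j−1} < y\* ≤ κ\_j with strictly increasing cutpoints κ. Covariates:
  the scores two and four years prior, demographics (piecewise-linear age
  spline with knots at 65/75, sex, race/ethnicity, education),
  chronic-condition indicators, recent heart attack, employment,
  widowhood, smoking, the absorbing verified MCI/dementia indicator,
  interview-gap deviation, and a lagged log-BMI spline split at BMI 30.
* **Mortality** — a probit for two-year death with an age spline adding a
  knot at 85, ADL/IADL difficulty categories, current smoking, by-age-50
  disease history and congestive heart failure.

Scores 0–6 classify as dementia, 7–11 as MCI, 12–27 as normal; a
category is **verified** when confirmed by the adjacent wave (or death)
and is then absorbing. Monte Carlo projection over many replicates turns
the models into per-person risk scores — the fraction of replicates in
which an outcome occurs — which are validated by k-fold cross-validated
AUROC, weighted score-distribution comparison and cognitive/mortality
transition matrices. A synthetic survey-like cohort generator (with
missing-not-at-random proxy masking of scores) makes the whole pipeline
testable without any data download, and a sequential-regression multiple
imputation module (predictive mean matching) completes masked scores.

## Worked example

```r
library(ticsim)

cfg   <- cohort_config(n_individuals = 2000, seed = 42)
panel <- generate_panel(cfg)            # 6 biennial waves + pre-baseline
fits  <- fit_transition_models(panel)   # ordered probit + probit MLE
summary(fits$tics)$coefficients[c("lag2_tics", "lag4_tics", "verified_ever"), ]
#>                  Estimate    Std. Err   z value      Pr(>|z|)
#> lag2_tics      0.09383438 0.003042134  30.84492 6.553135e-209
#> lag4_tics      0.09168706 0.003317205  27.63986 3.695319e-168
#> verified_ever -0.72608409 0.044272042 -16.40051  1.896377e-60

out <- simulate_cohort(panel[panel$wave %in% c(-1, 0), ], fits,
                       sim_config(horizon_waves = 5, replicates = 50,
                                  base_seed = 1))
report <- evaluate_simulation(panel, out, horizons = c(1, 5))
report
#> Transition matrix (observed, % of total):
#>          normal mci dementia dead_without_dementia dead_with_dementia
#> normal     49.9 7.1      3.6                  27.6                1.1
#> mci         0.0 3.0      2.8                   2.4                1.1
#> dementia    0.0 0.0      0.8                   0.0                0.6
#>
#> Transition matrix (simulated, % of total):
#>          normal mci dementia dead_without_dementia dead_with_dementia
#> normal       50 6.8      3.2                  28.2                1.0
#> mci           0 3.1      3.1                   2.0                1.2
#> dementia      0 0.0      1.0                   0.0                0.5
#>
#> AUROC (full sample):
#>     subgroup horizon                      predicate     auroc    n n_cases
#>  full_sample       1 dementia_or_dead_with_dementia 0.9439166 2000      69
#>  full_sample       5 dementia_or_dead_with_dementia 0.9043169 2000     209
#>  ...
```

Reading the output: the fitted lag coefficients recover the generating
values (here ~0.094 and ~0.092 latent-index units per score point, with a
strong negative verified-status effect), the simulated ten-year
cognitive/mortality mix tracks the observed panel cell by cell (weighted
percent of the full-follow-up population; cells like MCI→normal are
structurally zero because verified status absorbs), and the
replicate-fraction risks rank individuals well — AUROC ≈ 0.94 for
dementia-or-death-with-dementia at two years, declining to ≈ 0.90 at ten
years as the horizon grows.

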