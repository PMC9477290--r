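---
title: "Projecting TICS27 cognitive trajectories by dynamic microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting TICS27 cognitive trajectories by dynamic microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ticsim)
```

## The model

`ticsim` projects the cognitive function of older adults (ages 53+) over
biennial steps, using the 27-point modified Telephone Interview for
Cognitive Status score (TICS27, 0--27). Scores of 0--6 are classified as
dementia, 7--11 as mild cognitive impairment (MCI), 12--27 as cognitively
normal. Two first-order Markov transition models drive the projection:

* **Score transition.** An ordered probit: the next-wave score $S_{t+1}$
  arises from a latent index $y^* = x_t'\beta + \varepsilon$,
  $\varepsilon \sim N(0,1)$, observed as level $j$ when
  $\kappa_{j-1} < y^* \le \kappa_j$ with strictly increasing cutpoints
  $\kappa$. The covariates $x_t$ are the scores two and four years prior,
  demographics (piecewise-linear age spline with knots at 65 and 75, sex,
  race/ethnicity and education dummies with non-Hispanic white /
  high-school reference), chronic-condition indicators, recent heart
  attack, employment, widowhood, ever-smoking, the absorbing verified
  MCI-or-dementia indicator, the deviation of the interview gap from two
  years, and a lagged log-BMI spline split at BMI 30.
* **Mortality.** A probit for two-year death with an age spline adding a
  knot at 85, ADL/IADL difficulty categories, current smoking,
  by-age-50 disease history flags and congestive heart failure.

Both are fitted by maximum likelihood (`fit_ordered_probit()`,
`fit_probit()`): quasi-Newton with analytic gradients, cutpoint
monotonicity enforced by optimizing unconstrained increments through an
exponential transform, a Newton polish to drive the per-observation
gradient below $10^{-9}$ (the convergence flag requires $10^{-5}$), and
standard errors from the inverse observed information evaluated in the
natural parametrization. The ordered probit has no free intercept (its
level is absorbed by the cutpoints); the probit carries an explicit
intercept, since the reference coefficient table for the mortality model
names none and an absolute mortality level is needed. Estimation is
unweighted; survey weights enter only population-level summaries. Score
levels absent from the training data are merged into the adjacent lower
level with a warning, keeping the likelihood well defined; the fitted
model then assigns such levels probability zero.

## Verified cognitive status

A single low score is noisy, so categorical status is *verified* across
two adjacent waves: dementia requires a dementia-range wave followed by
dementia or death; MCI requires an MCI wave followed by MCI, dementia or
death, or a dementia wave followed by MCI (verified at the MCI wave).
Everything else counts as cognitively normal. Verified status is
absorbing -- it never downgrades, whatever later scores show.
`verify_trajectory()` implements the rule with two timing conventions:

* `"effective"` dates a verification at the first wave of the confirming
  pair, so a person is "verified ever" already at the wave whose category
  was later confirmed. Reported statuses, outcome definitions and
  transition matrices use this convention.
* `"known"` dates it at the wave completing the pair. The *covariate*
  "verified ADOD/MCI ever" in the transition models uses this convention:
  under the effective convention the wave-$t$ outcome would enter its own
  wave-$(t-1)$ predictor, and a forward simulator could never reproduce
  that; the knowledge-based status is exactly what the simulation engine
  maintains on the fly, so estimation, generation and simulation share
  one definition.

Status at death is the verified status in force at the last wave before
death, with death itself allowed to confirm a pending single-wave
category. "Significant decline" is a drop of 3+ score points over one
wave (the TICS27 translation of a clinically meaningful 3-point MMSE
decline for MCI patients).

## The synthetic cohort

No survey microdata ship with the package; `generate_panel()` creates
survey-like cohorts with the structure the models assume, so the entire
pipeline is testable end to end. Study conditions:

* Baseline ages uniform on 53--90; covariate prevalences follow the
  published baseline table of the target survey (e.g. hypertension 0.517,
  ever-smoking 0.571, non-Hispanic Black 0.091, Hispanic 0.073).
  Log-normal mean-one weights (sigma 0.5) stand in for survey weights,
  whose true distribution is never published.
* Baseline scores are a discretized normal centered at 15.6 with base
  dispersion 4.4, widened for lower education and older age, and a
  pre-baseline wave correlated 0.85 with baseline. These constants were
  calibrated once against the published baseline moments -- mean score
  15.57, about 1% verified dementia and 9% verified MCI -- and then
  frozen.
* Transitions use the reference coefficient vectors as the latent truth,
  with cutpoints $(j - 13.5)/4$ shifted so the cohort-average expected
  next score equals the baseline mean (decline then emerges from aging
  through the age spline and the verified-status feedback, not from an
  arbitrary drift constant), and a probit intercept solved so the mean
  two-year death probability is 0.07 (roughly 30% ten-year mortality,
  matching the published dead shares).
* Exogenous covariates evolve by absorbing per-wave incidences (e.g.
  hypertension 0.03, stroke 0.012), fresh two-year heart-attack draws,
  age-increasing retirement, 10% per-wave smoking cessation, a Gaussian
  log-BMI random walk (sd 0.02) and slow ADL/IADL progression. Interview
  gaps are $2 + U(-0.5, 0.5)$ years -- the jitter identifies the
  delta-age coefficient and feeds the age update, so the generating and
  simulated processes are identical.
* MNAR proxy missingness masks observed scores with probability
  $\mathrm{logit}^{-1}(1.0 - 0.25\,s)$ for the half of persons outside a
  never-missing share of 0.5, giving about 5% missing scores
  concentrated at low cognition -- emulating proxy respondents whose
  impairment prevents self-interview.

What the generator does *not* emulate: survey strata and clustering,
item-level test content, proxy informant ratings, covariate processes
driven by fitted auxiliary models, and real cohort-entry dynamics. Tests
passing on these cohorts therefore certify the mechanics and internal
consistency of the pipeline, not performance on any real survey.

## The projection engine

`simulate_cohort()` advances every person in two-year steps: mortality is
drawn first from start-of-step covariates (so status at death reflects the
last wave), survivors draw a score by inverse-CDF through the ordered
probit, verified status updates on the fly (death confirming a pending
category), lags shift, and exogenous covariates advance (or stay frozen
in `covariate_process = "frozen"` mode, which isolates the
cognition/mortality mechanics). Replicate $r$, wave $w$ and draw type
consume separate substreams seeded deterministically from the base seed,
with draws indexed by stable person order; runs are bit-reproducible and
appending persons leaves earlier persons' draws unchanged.
Person-level risk scores are replicate fractions (`risk_fraction()`):
the share of Monte Carlo replicates in which an outcome -- e.g. "verified
dementia or dead with dementia by wave 5" -- occurs; conditional variants
count only replicates alive at the horizon.

## Validation framework

`cross_validated_simulate()` partitions persons into k folds (default 5),
fits both models on k-1 folds, simulates the held-out fold from baseline,
and pools -- every person is simulated exactly once by models that never
saw them. `evaluate_simulation()` then reports:

* weighted score percentiles (1, 5, 10, 25, 50, 75, 90, 95, 99) and means
  at the horizon for baseline, observed and simulated survivors, overall
  and for the 65+ baseline subgroup; percentiles are the left-continuous
  inverse of the weighted CDF, so integer scores yield integer values;
* 3x5 cognitive/mortality transition matrices (normal/MCI/dementia at
  baseline against normal/MCI/dementia/dead-without/dead-with-dementia)
  as weighted percent of the full-follow-up population, with the
  absorbing rules making five cells structurally zero. Both the observed
  and simulated matrices condition on the *same* baseline verified
  status, computed from the pre-baseline pair only -- the status the
  simulator actually starts from;
* AUROCs of replicate-fraction risks against observed outcomes, per
  predicate, subgroup and horizon, with ties counted one half
  (trapezoidal threshold sweep). The significant-decline AUROC is
  restricted to baseline verified-MCI persons.

The full-follow-up filter keeps persons observed at every wave through
the horizon or their death, mirroring the evaluation population of the
original validation design.

## Multiple imputation for proxy missingness

`impute_tics27()` implements forward sequential-regression imputation
with predictive mean matching: wave by wave, observed scores are
regressed on demographics, health and economic covariates plus
prior-wave cognition (completed score, category dummies, proxy flag),
parameters are drawn from their approximate sampling distribution, and
each missing cell is filled with the observed score of one of the five
donors whose predictions sit closest -- so imputations are always
integers in 0--27. Later waves condition on already-imputed earlier
scores; each of the m = 5 imputations uses an independent sub-seed.
`pooled_fit()` averages coefficient vectors across completed panels and
reports between-imputation and Rubin-style total variance as diagnostics.

A known limitation, documented deliberately: the masking mechanism
depends on the *current* score's innovation, which no regression on
observables can condition on, and the generator (by design) omits the
proxy informant ratings that would carry that information in a real
survey. Under the default missingness strength the imputed-cell mean
therefore stays roughly three points above the masked truth, and with
only ~5% masked rows a complete-case fit of the score transition is
nearly unbiased while imputation-pooled estimates pick up
errors-in-variables attenuation through imputed lags. The end-to-end
imputation checks in the acceptance suite record this honestly rather
than weakening the mechanism.

## Numerical and design choices

* Optimizer: quasi-Newton (`nlminb`) from zero coefficients and
  empirical-quantile cutpoints, relative tolerance $10^{-10}$, then
  Newton steps with finite-difference Hessians of the analytic gradient;
  category probabilities are clamped at $10^{-300}$ inside likelihoods.
* Delta-age is defined as interview gap minus two years -- the only
  reading that varies across rows in a biennial panel.
* Rank-deficient designs, constant outcomes (complete separation), empty
  percentile inputs, all-case/all-control ROC inputs, structural-zero
  violations and out-of-range scores raise informative errors rather
  than producing silent results.
* Ties in risk scores are grouped in the ROC sweep; the AUROC equals the
  concordance probability with ties counted half, verified exactly
  against brute-force enumeration in the tests.
* Problem sizes in the test suite are the package's own choices: the
  end-to-end self-consistency check runs 20,000 persons, 6 waves, 5-fold
  cross-validation and 100 replicates; parameter-recovery checks run
  single instances at n = 100,000 (score model) and n = 200,000
  (mortality); the small-design recovery-bias property uses 20
  replications at n = 4,000; the imputation comparison runs 20 seeds of
  2,000-person panels.

## Limitations

Beyond the synthetic-data caveats above: the engine treats covariates as
exogenous (real microsimulations co-evolve them through further fitted
models); standard errors ignore survey design (no clustering or
stratification corrections); verification requires adjacent observed
waves, so a skipped interview delays or prevents confirmation; and the
replicate-fraction risks inherit Monte Carlo noise of order
$1/\sqrt{\mathrm{replicates}}$, which flattens ROC curves slightly at
small replicate counts.
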