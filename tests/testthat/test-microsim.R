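# helper: a degenerate baseline of identical persons with fixed scores
flat_baseline <- function(n, score0 = 15L, score_pre = 15L) {
  raw <- reference_raw(n)
  mk <- function(wave, score) {
    out <- raw[, setdiff(names(raw), c("verified_ever", "delta_age",
                                       "lag2_tics", "lag4_tics"))]
    out$wave <- wave
    out$calendar_year <- 2006 + 2 * wave
    out$tics27 <- score
    out$proxy <- 0L
    out$alive <- 1L
    out$interview_gap_years <- 2
    out
  }
  rbind(mk(-1L, score_pre), mk(0L, score0))
}

no_death_model <- function() {
  gamma <- fem_mortality_coefs()$coef
  gamma[] <- 0
  make_probit_params(gamma, -10)
}

test_that("simulation is bit-reproducible and truncates at death", {
  p <- small_panel(150L, seed = 3L)
  tm <- attr(p, "true_models")
  base <- p[p$wave %in% c(-1L, 0L), ]
  cfg <- sim_config(horizon_waves = 5L, replicates = 3L, base_seed = 11L)
  o1 <- simulate_cohort(base, tm, cfg)
  o2 <- simulate_cohort(base, tm, cfg)
  expect_identical(o1, o2)
  # death is terminal: no scores at or after the death wave
  for (r in 1:3) {
    dw <- o1$death_wave[, r]
    for (i in which(!is.na(dw))) {
      expect_true(all(is.na(o1$tics[i, dw[i]:o1$horizon, r])))
      if (dw[i] > 1) expect_true(all(!is.na(o1$tics[i, 1:(dw[i] - 1), r])))
    }
  }
})

test_that("an already dead person is unchanged by a step", {
  p <- small_panel(50L, seed = 6L)
  tm <- attr(p, "true_models")
  pop <- population_state(p[p$wave %in% c(-1L, 0L), ])
  pop$alive[1:10] <- FALSE
  snapshot <- pop$st[1:10, ]
  set.seed(1)
  pop2 <- step_population(pop, tm)
  expect_identical(pop2$st[1:10, ], snapshot)
  expect_false(any(pop2$alive[1:10]))
})

test_that("forced indexes give a deterministic trajectory", {
  # cutpoints all far above the zero index: every draw lands on level 0
  tm <- list(tics = make_oprobit_params(
    stats::setNames(rep(0, 24), names(fem_tics27_coefs()$coef)),
    20 + 0:26),
    mortality = no_death_model())
  base <- flat_baseline(20L)
  out <- simulate_cohort(base, tm, sim_config(horizon_waves = 3L,
                                              replicates = 2L,
                                              base_seed = 5L))
  expect_true(all(out$tics == 0L))
  expect_true(all(is.na(out$death_wave)))
})

test_that("one-step score frequencies match the category probabilities", {
  n <- 200000L
  base <- flat_baseline(n)
  tics <- make_oprobit_params(fem_tics27_coefs()$coef,
                              default_cutpoints() + 2.5)
  tm <- list(tics = tics, mortality = no_death_model())
  out <- simulate_cohort(base, tm,
                         sim_config(horizon_waves = 1L, replicates = 1L,
                                    base_seed = 7L,
                                    covariate_process = "frozen"))
  pop <- population_state(base)
  X <- build_design(pop$st[1, , drop = FALSE], "tics")
  P <- drop(category_probabilities(tics, X))
  emp <- tabulate(out$tics[, 1L, 1L] + 1L, 28L) / n
  band <- 4 * sqrt(P * (1 - P) / n)
  expect_true(all(abs(emp - P) <= band + 1e-12))
})

test_that("statuses are monotone and lags shift consistently across steps", {
  p <- small_panel(120L, seed = 13L)
  tm <- attr(p, "true_models")
  pop <- population_state(p[p$wave %in% c(-1L, 0L), ])
  set.seed(4)
  for (s in 1:4) {
    prev_ver <- pop$verified
    prev_lag2 <- pop$st$lag2_tics
    pop2 <- step_population(pop, tm)
    alive_both <- pop2$alive
    # verified severity never decreases
    expect_true(all(pop2$verified >= prev_ver))
    # tics_lag4yr after the step equals tics_lag2yr before it (survivors)
    expect_identical(pop2$st$lag4_tics[alive_both], prev_lag2[alive_both])
    # dead persons frozen
    expect_identical(pop2$st$lag2_tics[!pop2$alive & pop$alive],
                     prev_lag2[!pop2$alive & pop$alive])
    pop <- pop2
  }
})

test_that("risk fractions count hand-built replicate outcomes correctly", {
  # one person, four replicates: dementia-alive, dead-with-dementia,
  # dead-without-dementia, alive-normal
  out <- structure(list(
    tics = array(10L, c(1, 5, 4)),
    death_wave = matrix(c(NA, 3L, 2L, NA), 1),
    status_at_death = matrix(c(NA, 2L, 0L, NA), 1),
    dem_attain = matrix(c(2L, 1L, NA, NA), 1),
    mci_attain = matrix(c(1L, 1L, NA, NA), 1),
    person_id = 1L, weight = 1, baseline_score = 15L,
    baseline_verified = 0L, horizon = 5L, replicates = 4L, base_seed = 1L
  ), class = "replicate_outcomes")
  expect_equal(risk_fraction(out, "dementia_or_dead_with_dementia", 5L), 0.5)
  expect_equal(risk_fraction(out, "dementia_given_alive", 5L), 0.5)
  expect_equal(risk_fraction(out, "mci_or_worse_or_dead_with_mci_or_worse",
                             5L), 0.5)
  expect_error(risk_fraction(out, "nonsense", 5L), "predicate")
  expect_error(risk_fraction(out, "dementia_given_alive", 9L), "horizon")
  # all replicates dead with dementia / all alive-normal extremes
  out$death_wave[] <- 2L
  out$status_at_death[] <- 2L
  expect_equal(risk_fraction(out, "dementia_or_dead_with_dementia", 5L), 1)
  out$death_wave[] <- NA_integer_
  out$dem_attain[] <- NA_integer_
  out$mci_attain[] <- NA_integer_
  expect_equal(risk_fraction(out, "dementia_or_dead_with_dementia", 5L), 0)
})

test_that("mean scores track the analytic expectation iteration", {
  # mortality off, covariates frozen: the (lag2, lag4, verified) chain is
  # finite and its expectation can be iterated exactly
  cfg <- cohort_config(n_individuals = 50L, seed = 21L)
  base <- generate_baseline(cfg)
  tics <- calibrate_true_models(cfg, base)$tics
  tm <- list(tics = tics, mortality = no_death_model())
  H <- 5L
  R <- 400L
  out <- simulate_cohort(base, tm,
                         sim_config(horizon_waves = H, replicates = R,
                                    base_seed = 3L,
                                    covariate_process = "frozen"))
  # analytic iteration
  pop <- population_state(base)
  st <- pop$st
  st$delta_age <- 0
  X <- build_design(st, "tics")
  beta <- tics$coefficients
  b2 <- beta[["lag2_tics"]]
  b4 <- beta[["lag4_tics"]]
  bv <- beta[["verified_ever"]]
  eta_base <- drop(X %*% beta) - b2 * st$lag2_tics - b4 * st$lag4_tics -
    bv * st$verified_ever
  grid <- expand.grid(l2 = 0:27, l4 = 0:27, v = 0:1)
  sev <- function(s) (s <= 11) + (s <= 6)
  prev_rep <- matrix(sev(grid$l2), nrow(grid), 28)
  new_rep <- matrix(sev(0:27), nrow(grid), 28, byrow = TRUE)
  conf <- matrix(ticsim:::.pair_confirm(as.vector(prev_rep),
                                        as.vector(new_rep)),
                 nrow(grid), 28)
  vnew <- matrix(pmax(grid$v, (conf > 0) * 1), nrow(grid), 28)
  state_of <- function(l2, l4, v) 1L + l2 + 28L * l4 + 784L * v
  # new state after drawing snew: (snew, old l2, updated verified flag)
  nxt_idx <- outer(seq_len(nrow(grid)), 0:27, function(s, snew) {
    state_of(snew, grid$l2[s], vnew[cbind(s, snew + 1L)])
  })
  kappa <- tics$kappa
  analytic <- matrix(0, length(out$person_id), H)
  for (i in seq_along(eta_base)) {
    eta <- eta_base[i] + b2 * grid$l2 + b4 * grid$l4 + bv * grid$v
    Z <- outer(eta, kappa, function(e, k) k - e)
    Pm <- cbind(pnorm(Z), 1) - cbind(0, pnorm(Z))
    d <- numeric(nrow(grid))
    d[state_of(st$lag2_tics[i], st$lag4_tics[i], st$verified_ever[i])] <- 1
    for (w in seq_len(H)) {
      wts <- as.vector(d * Pm)
      keep <- wts > 0
      dn <- rowsum(wts[keep], as.vector(nxt_idx)[keep])
      d <- numeric(nrow(grid))
      d[as.integer(rownames(dn))] <- dn[, 1L]
      analytic[i, w] <- sum(d * grid$l2)
    }
  }
  mc_mean <- apply(out$tics, 2L, mean)              # cohort mean per wave
  an_mean <- colMeans(analytic)
  rep_means <- apply(out$tics, c(2L, 3L), mean)     # wave x replicate
  se <- apply(rep_means, 1L, sd) / sqrt(R)
  expect_true(all(abs(mc_mean - an_mean) <= 3 * se + 1e-9))
})

test_that("true-model simulation reproduces the cohort's final score distribution", {
  cfg <- cohort_config(n_individuals = 20000L, seed = 314L)
  p <- generate_panel(cfg)
  tm <- attr(p, "true_models")
  out <- simulate_cohort(p[p$wave %in% c(-1L, 0L), ], tm,
                         sim_config(horizon_waves = 5L, replicates = 30L,
                                    base_seed = 8L))
  obs <- p[p$wave == 5L & p$alive == 1L, ]
  od <- weighted_percentiles(obs$tics27, obs$weight)
  sv <- matrix(out$tics[, 5L, ], nrow = length(out$person_id))
  sw <- matrix(out$weight, nrow(sv), ncol(sv))
  ok <- !is.na(sv)
  sd_ <- weighted_percentiles(sv[ok], sw[ok])
  expect_true(all(abs(sd_$percentiles - od$percentiles) <= 0.3))
  expect_lt(abs(sd_$mean - od$mean), 0.2)
})
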