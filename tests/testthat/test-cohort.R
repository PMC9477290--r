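test_that("generation is deterministic under a fixed config", {
  cfg <- cohort_config(n_individuals = 100L, seed = 7L)
  expect_identical(generate_baseline(cfg), generate_baseline(cfg))
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  attr(p1, "true_models") <- attr(p2, "true_models") <- NULL
  expect_identical(p1, p2)
})

test_that("zero prevalences give all-zero binary covariates", {
  pv <- ticsim:::.default_prevalences
  pv[] <- 0
  cfg <- cohort_config(n_individuals = 200L, seed = 2L,
                       covariate_prevalences = pv)
  b <- generate_baseline(cfg)
  bin_cols <- c("male", "heart_ever", "stroke_ever", "cancer_ever",
                "hypertension_ever", "diabetes_ever", "lung_ever",
                "chf_ever", "heart_attack_2yr", "working", "widowed",
                "smoke_ever", "smoke_current", "heart50", "smoke_ever50")
  for (cl in bin_cols) expect_true(all(b[[cl]] == 0), label = cl)
  expect_true(all(b$race_ethnicity == "nh_white"))
  expect_true(all(b$adl_count == 0) && all(b$iadl_count == 0))
})

test_that("configuration errors name the offending field", {
  expect_error(cohort_config(covariate_prevalences = c(male = 1.2)),
               "male")
  expect_error(cohort_config(incidence_rates = c(stroke_ever = -0.1)),
               "stroke_ever")
  expect_error(cohort_config(n_waves = 1), "n_waves")
  expect_error(cohort_config(age_range = c(45, 90)), "age_range")
  expect_error(generate_panel(structure(list(true_models = NULL),
                                        class = "cohort_config")),
               "true_models")
})

test_that("baseline mean TICS27 is near the survey calibration target", {
  cfg <- cohort_config(n_individuals = 20000L, seed = 1L)
  b <- generate_baseline(cfg)
  expect_lt(abs(mean(b$tics27[b$wave == 0L]) - 15.57), 1.0)
  expect_equal(mean(b$weight[b$wave == 0L]), 1, tolerance = 1e-9)
})

test_that("zero incidence keeps condition columns constant over waves", {
  inc <- ticsim:::.default_incidence
  inc[] <- 0
  cfg <- cohort_config(n_individuals = 150L, seed = 5L,
                       incidence_rates = inc)
  p <- generate_panel(cfg)
  for (cl in names(inc)) {
    rng <- tapply(p[[cl]], p$person_id, function(v) max(v) - min(v))
    expect_true(all(rng == 0), label = cl)
  }
})

test_that("a mortality index forced to -10 makes death impossible", {
  tm <- default_true_models()
  tm$mortality$gamma[] <- 0
  tm$mortality$target_rate <- pnorm(-10)
  cfg <- cohort_config(n_individuals = 300L, seed = 4L, true_models = tm)
  p <- generate_panel(cfg)
  expect_true(all(p$alive == 1L))
  expect_equal(sum(p$wave == cfg$n_waves - 1L), 300L)
})

test_that("generated panels satisfy the schema invariants", {
  set.seed(77)
  for (rep in 1:4) {
    cfg <- cohort_config(n_individuals = sample(80:250, 1),
                         n_waves = sample(3:6, 1),
                         seed = sample.int(10000, 1))
    p <- generate_panel(cfg)
    p <- p[order(p$person_id, p$wave), ]
    expect_true(all(p$tics27[p$alive == 1L] %in% 0:27))
    expect_true(all(is.na(p$tics27[p$alive == 0L])))
    expect_true(all(p$weight > 0))
    sp <- split(p, p$person_id)
    absorbing <- c("heart_ever", "stroke_ever", "cancer_ever",
                   "hypertension_ever", "diabetes_ever", "lung_ever",
                   "chf_ever", "widowed", "smoke_ever", "heart50",
                   "stroke50", "cancer50", "hypertension50", "diabetes50",
                   "lung50", "smoke_ever50", "smoke_current50")
    for (d in sp) {
      expect_true(all(diff(d$wave) == 1))          # no rows after death
      expect_true(all(diff(d$alive) <= 0))         # alive non-increasing
      expect_lte(sum(d$alive == 0L), 1L)
      for (cl in absorbing) expect_true(all(diff(d[[cl]]) >= 0))
    }
  }
})

test_that("one-step score distribution matches the analytic category mix", {
  cfg <- cohort_config(n_individuals = 50000L, n_waves = 2L, seed = 1L)
  p <- generate_panel(cfg)
  tm <- attr(p, "true_models")
  # oracle: average the analytic category probabilities over the realized
  # wave-0 design rows of wave-1 survivors (delta-age at its realized value)
  p <- p[order(p$person_id, p$wave), ]
  surv <- p$person_id[p$wave == 1L & p$alive == 1L]
  base <- p[p$wave %in% c(-1L, 0L) & p$person_id %in% surv, ]
  st <- ticsim:::.state_from_baseline(base)
  w1 <- p[p$wave == 1L & p$alive == 1L, ]
  st$delta_age <- w1$interview_gap_years[match(st$person_id,
                                               w1$person_id)] - 2
  X <- build_design(st, "tics")
  P <- category_probabilities(tm$tics, X)
  expected <- colMeans(P)
  emp <- tabulate(w1$tics27 + 1L, 28L) / nrow(w1)
  expect_lt(max(abs(emp - expected)), 0.005)
})

test_that("proxy masking is MNAR in the constructed direction", {
  cfg <- cohort_config(n_individuals = 20000L, n_waves = 3L, seed = 9L)
  p <- generate_panel(cfg)
  masked <- apply_proxy_missingness(p, cfg$proxy_missingness, seed = 3L)
  # original untouched
  expect_false(anyNA(p$tics27[p$alive == 1L]))
  mis <- is.na(masked$tics27) & masked$alive == 1L
  expect_gt(sum(mis), 100)
  expect_lt(mean(p$tics27[mis]), mean(p$tics27[!mis & p$alive == 1L]))
  expect_true(all(masked$proxy[mis] == 1L))
  # monotone missingness on the analytic logistic form
  pm <- cfg$proxy_missingness
  pr <- plogis(pm$intercept + pm$slope_per_score_point * (0:27))
  expect_true(all(diff(pr) <= 0))
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("masking probability zero or one are exact edge cases", {
  cfg <- cohort_config(n_individuals = 150L, n_waves = 3L, seed = 12L)
  p <- generate_panel(cfg)
  none <- apply_proxy_missingness(
    p, list(intercept = -1e6, slope_per_score_point = 0,
            share_never_missing = 0), seed = 1L)
  expect_identical(none$tics27, p$tics27)
  all_m <- apply_proxy_missingness(
    p, list(intercept = 1e6, slope_per_score_point = 0,
            share_never_missing = 0), seed = 1L)
  expect_true(all(is.na(all_m$tics27)))
})
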