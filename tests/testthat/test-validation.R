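test_that("k-fold split partitions evenly and reproducibly", {
  f <- kfold_split(1:10, k = 5, seed = 3)
  expect_equal(unname(table(f)), rep(2L, 5), ignore_attr = TRUE)
  expect_identical(f, kfold_split(1:10, k = 5, seed = 3))
  f2 <- kfold_split(seq_len(13106), k = 5, seed = 1)
  expect_true(all(table(f2) %in% c(2621L, 2622L)))
  expect_equal(sum(table(f2)), 13106L)
  expect_error(kfold_split(1:10, k = 1), "k must")
  expect_error(kfold_split(1:3, k = 5), "k must")
  expect_error(kfold_split(c(1, 1, 2), k = 2), "unique")
})

test_that("weighted percentiles invert the weighted CDF left-continuously", {
  d <- weighted_percentiles(c(10, 20, 30), c(1, 1, 2), probs = 0.5)
  expect_equal(unname(d$percentiles), 20)
  # uniform weights reduce to type-1 quantiles
  set.seed(4)
  v <- sample(0:27, 200, replace = TRUE)
  d2 <- weighted_percentiles(v, rep(1, 200))
  q1 <- quantile(v, c(.01, .05, .1, .25, .5, .75, .9, .95, .99), type = 1)
  expect_equal(unname(d2$percentiles), unname(q1))
  expect_true(all(diff(d2$percentiles) >= 0))
  # all weight on one observation
  d3 <- weighted_percentiles(c(5, 17, 9), c(1e-12, 1, 1e-12))
  expect_true(all(d3$percentiles == 17))
  expect_error(weighted_percentiles(numeric(0)), "empty")
  expect_error(weighted_percentiles(1:3, c(1, -1, 1)), "positive")
})

test_that("transition matrix tabulates weighted percents with forced zeros", {
  M <- status_transition_matrix(
    c("normal", "normal", "mci", "dementia"),
    c("mci", "dead_without_dementia", "dead_with_dementia", "dementia"),
    rep(1, 4))
  expect_equal(sum(M), 100, tolerance = 1e-9)
  expect_equal(unname(M["normal", "mci"]), 25)
  expect_equal(unname(M["mci", "dead_with_dementia"]), 25)
  expect_equal(unname(M["dementia", "dementia"]), 25)
  expect_equal(unname(M["normal", "dead_without_dementia"]), 25)
  # all-normal cohort with no events
  M2 <- status_transition_matrix(rep(0L, 5), rep("normal", 5))
  expect_equal(unname(M2["normal", "normal"]), 100)
  # structurally zero cells reject mass
  expect_error(status_transition_matrix("mci", "normal"), "structurally")
  expect_error(status_transition_matrix("dementia", "dead_without_dementia"),
               "structurally")
})

test_that("AUROC equals the O(n^2) concordance count, ties counted half", {
  r <- roc_auc(c(0.9, 0.1), c(1, 0))
  expect_equal(r$auroc, 1)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0))$auroc, 0.5)
  expect_equal(roc_auc(c(0.8, 0.6, 0.4, 0.2), c(1, 0, 1, 0))$auroc, 0.75)
  set.seed(9)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    risks <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    outcomes <- rbinom(n, 1, 0.4)
    if (length(unique(outcomes)) < 2) next
    rc <- roc_auc(risks, outcomes)
    expect_equal(rc$auroc, brute_auroc(risks, outcomes), tolerance = 1e-12)
    # curve runs (0,0) -> (1,1) monotonically; trapezoid equals auroc
    expect_equal(rc$points$fpr[1], 0)
    expect_equal(rc$points$tpr[nrow(rc$points)], 1)
    expect_true(all(diff(rc$points$fpr) >= 0))
    expect_true(all(diff(rc$points$tpr) >= 0))
    area <- sum(diff(rc$points$fpr) *
                  (head(rc$points$tpr, -1) + tail(rc$points$tpr, -1)) / 2)
    expect_equal(rc$auroc, area, tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(qlogis(pmin(pmax(risks, .01), .99)),
                         outcomes)$auroc, rc$auroc, tolerance = 1e-12)
  }
  expect_error(roc_auc(c(.1, .2), c(1, 1)), "case and one control")
})

test_that("AUROC agrees with pROC on a nondegenerate instance", {
  skip_if_not_installed("pROC")
  set.seed(11)
  risks <- runif(300)
  outcomes <- rbinom(300, 1, plogis(3 * risks - 1.5))
  rc <- roc_auc(risks, outcomes)
  ref <- pROC::auc(pROC::roc(outcomes, risks, quiet = TRUE))
  expect_equal(rc$auroc, as.numeric(ref), tolerance = 1e-12)
})

test_that("cross-validated simulation holds every person out exactly once", {
  p <- small_panel(400L, seed = 19L, n_waves = 5L)
  cv <- suppressWarnings(
    cross_validated_simulate(p, k = 2L,
                             config = sim_config(horizon_waves = 3L,
                                                 replicates = 4L,
                                                 base_seed = 2L),
                             fold_seed = 5L))
  expect_length(cv$fits, 2L)
  expect_s3_class(cv$fits[[1]]$tics, "oprobit")
  ids <- sort(unique(p$person_id[p$wave == 0L]))
  expect_setequal(cv$outcomes$person_id, ids)
  expect_equal(length(cv$outcomes$person_id), length(ids))
})

test_that("fold exclusion changes at least one risk score", {
  p <- small_panel(1000L, seed = 23L, n_waves = 5L)
  cfg <- sim_config(horizon_waves = 3L, replicates = 8L, base_seed = 4L)
  cv <- suppressWarnings(cross_validated_simulate(p, k = 5L, config = cfg,
                                                  fold_seed = 1L))
  fit_all <- suppressWarnings(fit_transition_models(p))
  base <- p[p$wave %in% c(-1L, 0L), ]
  full <- simulate_cohort(base, fit_all, cfg)
  m <- match(full$person_id, cv$outcomes$person_id)
  r_cv <- risk_fraction(cv$outcomes, "dementia_or_dead_with_dementia", 3L)[m]
  r_full <- risk_fraction(full, "dementia_or_dead_with_dementia", 3L)
  expect_true(any(r_cv != r_full))
})

test_that("full-follow-up filter drops mid-panel nonrespondents", {
  p <- small_panel(60L, seed = 29L)
  # delete one alive mid-panel wave for one person (nonresponse)
  pid <- p$person_id[p$wave == 3L & p$alive == 1L][1L]
  p2 <- p[!(p$person_id == pid & p$wave == 3L), ]
  tr <- observed_outcomes(p2, horizon = 5L)
  expect_false(tr$full_followup[tr$person_id == pid])
  # everyone else with rows through death or horizon is retained
  expect_gt(mean(tr$full_followup), 0.9)
})

test_that("the everyone-subgroup duplicates the full-sample AUROC row", {
  p <- small_panel(400L, seed = 17L)
  tm <- attr(p, "true_models")
  out <- simulate_cohort(p[p$wave %in% c(-1L, 0L), ], tm,
                         sim_config(horizon_waves = 5L, replicates = 10L,
                                    base_seed = 6L))
  ids <- out$person_id
  rep1 <- evaluate_simulation(p, out, horizons = 5L,
                              subgroups = list(full_sample = ids,
                                               everyone = ids))
  a <- rep1$auroc
  for (pr in unique(a$predicate)) {
    expect_equal(a$auroc[a$subgroup == "everyone" & a$predicate == pr],
                 a$auroc[a$subgroup == "full_sample" & a$predicate == pr])
  }
  expect_error(evaluate_simulation(p, out, horizons = 9L), "horizon")
})
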