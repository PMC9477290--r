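test_that("category probabilities match direct normal-CDF evaluation", {
  # 3-category model, index 1, cutpoints (-1, 1)
  pp <- list(beta = c(x = 1), kappa = c(-1, 1), levels = 0:2)
  P <- category_probabilities(pp, matrix(1, 1, 1,
                                         dimnames = list(NULL, "x")))
  expect_equal(drop(P), c(pnorm(-2), pnorm(0) - pnorm(-2), 1 - pnorm(0)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(P), 1, tolerance = 1e-10)
})

test_that("probabilities are normalized and shifted indexes dominate", {
  set.seed(2)
  kappa <- sort(rnorm(27))
  pp <- list(beta = c(x = 1), kappa = kappa, levels = 0:27)
  for (delta in c(0.1, 0.5, 1, 2)) {
    P0 <- drop(category_probabilities(pp, matrix(0, 1, 1)))
    P1 <- drop(category_probabilities(pp, matrix(delta, 1, 1)))
    expect_equal(sum(P0), 1, tolerance = 1e-10)
    # larger index -> higher scores: cdf of shifted lies below
    expect_true(all(cumsum(P1) <= cumsum(P0) + 1e-12))
  }
  expect_error(category_probabilities(list(beta = c(x = 1),
                                           kappa = c(1, 0), levels = 0:2),
                                      matrix(0, 1, 1)), "increasing")
})

test_that("log-likelihood handles single rows and empty data", {
  pp <- list(beta = c(x = 1), kappa = c(-1, 1), levels = 0:2)
  # observed category probability 0.5 at index 1 for level 2
  expect_equal(op_loglik(pp, 2, matrix(1, 1, 1)), log(0.5))
  expect_equal(op_loglik(pp, integer(0), matrix(0, 0, 1)), 0)
})

test_that("true parameters beat perturbed parameters in likelihood", {
  set.seed(7)
  n <- 30000
  X <- cbind(x = rnorm(n))
  kappa <- c(-1, 0, 1)
  y <- findInterval(0.7 * X[, 1] + rnorm(n), kappa)
  truth <- list(beta = c(x = 0.7), kappa = kappa, levels = 0:3)
  ll_true <- op_loglik(truth, y, X)
  for (eps in c(0.05, 0.2)) {
    pert <- truth
    pert$beta <- truth$beta + eps
    expect_gt(ll_true, op_loglik(pert, y, X))
  }
})

test_that("ordered probit recovers known parameters and matches MASS::polr", {
  skip_if_not_installed("MASS")
  set.seed(12)
  n <- 4000
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  kappa <- c(-0.8, 0.2, 1.1)
  y <- findInterval(0.6 * X[, "a"] - 0.4 * X[, "b"] + rnorm(n), kappa)
  fit <- fit_ordered_probit(y, X)
  expect_true(fit$converged)
  ref <- MASS::polr(factor(y) ~ a + b,
                    data = data.frame(y = y, a = X[, "a"], b = X[, "b"]),
                    method = "probit", Hess = TRUE)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$kappa), unname(ref$zeta), tolerance = 1e-4)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(ref)))[1:2]), tolerance = 1e-3)
  expect_equal(as.numeric(logLik(fit)), as.numeric(logLik(ref)),
               tolerance = 1e-8)
})

test_that("two-category ordered probit reproduces the probit fit", {
  set.seed(3)
  n <- 5000
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.3))
  y <- as.integer(runif(n) < pnorm(-0.5 + 0.8 * X[, "a"] - 0.3 * X[, "b"]))
  op <- fit_ordered_probit(y, X)
  bp <- fit_probit(y, X)
  expect_equal(unname(coef(op)),
               unname(coef(bp)[c("a", "b")]), tolerance = 1e-6)
  expect_equal(op$kappa[1], -unname(coef(bp)[["(Intercept)"]]),
               tolerance = 1e-6)
})

test_that("estimates are invariant to row order; duplication halves variance", {
  set.seed(21)
  n <- 2000
  X <- cbind(a = rnorm(n))
  y <- findInterval(0.5 * X[, 1] + rnorm(n), c(-1, 0.5))
  f1 <- fit_ordered_probit(y, X)
  perm <- sample(n)
  f2 <- fit_ordered_probit(y[perm], X[perm, , drop = FALSE])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-7)
  dup <- fit_ordered_probit(c(y, y), rbind(X, X))
  expect_equal(coef(dup), coef(f1), tolerance = 1e-7)
  expect_equal(unname(dup$se / f1$se), rep(1 / sqrt(2), 1),
               tolerance = 0.01)
})

test_that("recovery is unbiased over seeded replications", {
  # 20 seeded replications on a reduced design; bias within 2 MC SEs of 0
  truth_beta <- 0.6
  ests <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 4000
    X <- cbind(a = rnorm(n))
    y <- findInterval(truth_beta * X[, 1] + rnorm(n),
                      seq(-1.5, 1.5, length.out = 7))
    coef(fit_ordered_probit(y, X))[["a"]]
  }, numeric(1))
  bias <- mean(ests) - truth_beta
  mcse <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(bias), 2 * mcse + 1e-9)
})

test_that("degenerate and deficient inputs raise informative errors", {
  X <- cbind(a = rnorm(100))
  expect_error(fit_ordered_probit(rep(1L, 100), X), "constant")
  X2 <- cbind(a = rnorm(100), b = 1:100, c = 2 * (1:100))
  y <- findInterval(rnorm(100), 0)
  expect_error(fit_ordered_probit(y, X2), "collinear")
  expect_warning(
    fit_ordered_probit(c(rep(0L, 50), rep(2L, 50)), X),
    "absent")
})

test_that("sampler and inverse-CDF draws follow the category probabilities", {
  pp <- make_oprobit_params(c(x = 1), c(-1, -0.2, 0.6, 1.4),
                            levels = 0:4)
  set.seed(99)
  n <- 100000
  draws <- ticsim:::.op_draw(pp, rep(0.3, n), runif(n))
  P <- drop(category_probabilities(pp, matrix(0.3, 1, 1)))[1:5]
  emp <- tabulate(draws + 1L, 5L) / n
  expect_true(all(abs(emp - P) < 4 * sqrt(P * (1 - P) / n)))
})

test_that("marginal effects match finite differences and closed forms", {
  set.seed(5)
  n <- 3000
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  y <- findInterval(0.5 * X[, "a"] + 0.3 * X[, "b"] + rnorm(n),
                    c(-1, 0, 1))
  fit <- fit_ordered_probit(y, X)
  ame <- average_marginal_effects(fit, X)
  # continuous effect vs central difference of the mean expected score
  h <- 1e-5
  Xp <- X; Xp[, "a"] <- X[, "a"] + h
  Xm <- X; Xm[, "a"] <- X[, "a"] - h
  fd <- (mean(predict(fit, Xp, type = "expected")) -
           mean(predict(fit, Xm, type = "expected"))) / (2 * h)
  expect_equal(ame[["a"]], fd, tolerance = 1e-6)
  # binary effect equals the mean discrete difference
  X1 <- X; X1[, "b"] <- 1
  X0 <- X; X0[, "b"] <- 0
  dd <- mean(predict(fit, X1, type = "expected") -
               predict(fit, X0, type = "expected"))
  expect_equal(ame[["b"]], dd, tolerance = 1e-10)
  # zero coefficient -> zero AME
  fit0 <- fit
  fit0$coefficients[["a"]] <- 0
  expect_equal(average_marginal_effects(fit0, X)[["a"]], 0)
})

test_that("probit marginal effect at zero index is dnorm(0) times gamma", {
  fit <- structure(list(coefficients = c(`(Intercept)` = 0, a = 0.7),
                        converged = TRUE, intercept = TRUE),
                   class = "bprobit")
  # continuous covariate with a negligible index contribution
  X <- cbind(a = rnorm(500) * 1e-12)
  ame <- average_marginal_effects(fit, X)
  expect_equal(ame[["a"]], dnorm(0) * 0.7, tolerance = 1e-9)
})
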