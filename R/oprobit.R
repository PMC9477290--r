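# Ordered probit by maximum likelihood.
#
# Latent model: y* = x'beta + e, e ~ N(0,1); observed level j when
# kappa_{j-1} < y* <= kappa_j (kappa_{-1} = -Inf, kappa_J = +Inf). There is
# no free intercept: the level is absorbed by the cutpoints. Cutpoint
# monotonicity is enforced by optimizing unconstrained increments
# (kappa_1 = theta_1, kappa_j = kappa_{j-1} + exp(theta_j)); standard errors
# come from the inverse observed information evaluated in the natural
# (beta, kappa) parametrization at the optimum.

.theta_to_kappa <- function(theta) {
  if (length(theta) == 1L) return(theta)
  cumsum(c(theta[1L], exp(theta[-1L])))
}

.kappa_to_theta <- function(kappa) {
  if (length(kappa) == 1L) return(kappa)
  c(kappa[1L], log(diff(kappa)))
}

# category probabilities for linear index eta: n x J matrix
.op_probs <- function(eta, kappa) {
  J <- length(kappa) + 1L
  Z <- outer(eta, kappa, function(e, k) k - e)
  P1 <- cbind(stats::pnorm(Z), 1)
  P0 <- cbind(0, stats::pnorm(Z))
  P1 - P0
}

# negative log-likelihood and gradient wrt (beta, kappa); yi is the
# 1-based category index. Returns list(nll, gbeta, gkappa).
.op_nll_core <- function(beta, kappa, yi, X, w) {
  eta <- if (length(beta)) drop(X %*% beta) else numeric(nrow(X))
  J <- length(kappa) + 1L
  kup <- c(kappa, Inf)[yi]
  klo <- c(-Inf, kappa)[yi]
  z1 <- kup - eta
  z0 <- klo - eta
  p <- pmax(stats::pnorm(z1) - stats::pnorm(z0), 1e-300)
  nll <- -sum(w * log(p))
  d1 <- stats::dnorm(z1)   # 0 at +-Inf
  d0 <- stats::dnorm(z0)
  wp <- w / p
  geta <- wp * (d1 - d0)   # gradient of +loglik wrt eta is -(d1-d0)/p
  gbeta <- if (length(beta)) drop(crossprod(X, geta)) else numeric(0)
  # +loglik wrt kappa_j: +d1/p on rows with yi == j, -d0/p on rows with
  # yi == j + 1; negate for nll
  gk_up <- rowsum(wp * d1, factor(yi, levels = seq_len(J)))[, 1L]
  gk_lo <- rowsum(wp * d0, factor(yi, levels = seq_len(J)))[, 1L]
  gkappa <- -(gk_up[seq_len(J - 1L)] - gk_lo[2:J])
  list(nll = nll, gbeta = gbeta, gkappa = gkappa)
}

#' Fit an ordered probit model
#'
#' Maximum-likelihood ordered probit for an integer-valued ordinal outcome
#' (such as the TICS27 score, 0-27) on a fixed design matrix. Outcome levels
#' absent from the data are merged into the adjacent less-severe level with a
#' warning; the fitted model then assigns them probability zero.
#'
#' @param y integer outcome vector.
#' @param X numeric design matrix with column names (no intercept column; the
#'   level is absorbed by the cutpoints).
#' @param weights optional non-negative case weights.
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @param maxit maximum number of optimizer iterations.
#' @return an object of class `"oprobit"`: coefficients, strictly increasing
#'   cutpoints `kappa`, observed outcome `levels`, standard errors (inverse
#'   observed information), `vcov`, `logLik`, `converged` (mean-gradient
#'   max-norm below 1e-5), and `n`.
#' @examples
#' set.seed(1)
#' x <- cbind(z = rnorm(500))
#' y <- findInterval(0.8 * x[, 1] + rnorm(500), c(-1, 0, 1))
#' fit <- fit_ordered_probit(y, x)
#' coef(fit)
#' @export
fit_ordered_probit <- function(y, X, weights = NULL, reltol = 1e-10,
                               maxit = 500L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  levels <- sort(unique(y))
  J <- length(levels)
  if (J < 2L) {
    stop("outcome is constant: ordered probit is not identified",
         call. = FALSE)
  }
  if (is.numeric(y) && all(y == round(y))) {
    full <- seq(min(levels), max(levels))
    absent <- setdiff(full, levels)
    if (length(absent)) {
      warning("outcome level(s) absent from data and merged with the ",
              "adjacent lower level: ", paste(absent, collapse = ", "),
              call. = FALSE)
    }
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  yi <- match(y, levels)
  p <- ncol(X)

  # start: beta = 0, cutpoints at normal quantiles of the empirical cdf
  cw <- cumsum(rowsum(w, factor(yi, levels = seq_len(J)))[, 1L]) / sum(w)
  kappa0 <- unname(stats::qnorm(pmin(pmax(cw[-J], 1e-6), 1 - 1e-6)))
  kappa0 <- cummax(kappa0 + seq_len(J - 1L) * 1e-8)  # guard exact ties
  start <- c(rep(0, p), .kappa_to_theta(kappa0))

  nobs <- sum(w)
  # fn and gr share one cached evaluation per parameter value
  cache <- new.env(parent = emptyenv())
  core_at <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$core)
    kappa <- .theta_to_kappa(par[p + seq_len(J - 1L)])
    cache$par <- par
    cache$core <- .op_nll_core(par[seq_len(p)], kappa, yi, X, w)
    cache$core
  }
  fn <- function(par) core_at(par)$nll
  gr <- function(par) {
    theta <- par[p + seq_len(J - 1L)]
    core <- core_at(par)
    gk <- core$gkappa
    # chain rule through the increment transform
    gtheta <- rev(cumsum(rev(gk)))
    if (J > 2L) gtheta[-1L] <- gtheta[-1L] * exp(theta[-1L])
    c(core$gbeta, gtheta)
  }
  opt <- stats::nlminb(start, fn, gr,
                       control = list(rel.tol = reltol, iter.max = maxit,
                                      eval.max = 4L * maxit))
  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(X)
  kappa <- .theta_to_kappa(opt$par[p + seq_len(J - 1L)])

  grad_bk <- function(b, k) {
    core <- .op_nll_core(b, k, yi, X, w)
    c(core$gbeta, core$gkappa)
  }
  hess_bk <- function(par) .fd_hessian(function(q) {
    grad_bk(q[seq_len(p)], q[p + seq_len(J - 1L)])
  }, par)
  # Newton polish in the natural parametrization: quasi-Newton stops on
  # relative likelihood change; a couple of Newton steps drive the gradient
  # to machine level so the convergence check is meaningful
  par_bk <- c(beta, kappa)
  nll_at <- function(q) {
    k <- q[p + seq_len(J - 1L)]
    if (any(diff(k) <= 0)) return(Inf)
    .op_nll_core(q[seq_len(p)], k, yi, X, w)$nll
  }
  cur_nll <- nll_at(par_bk)
  H <- hess_bk(par_bk)
  for (it in 1:4) {
    g <- grad_bk(par_bk[seq_len(p)], par_bk[p + seq_len(J - 1L)])
    if (max(abs(g)) / nobs < 1e-9) break
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    sc <- 1
    repeat {
      cand <- par_bk - sc * step
      cand_nll <- nll_at(cand)
      if (cand_nll <= cur_nll || sc < 1e-4) break
      sc <- sc / 2
    }
    if (cand_nll > cur_nll) break
    par_bk <- cand
    cur_nll <- cand_nll
    H <- hess_bk(par_bk)
  }
  beta <- par_bk[seq_len(p)]
  names(beta) <- colnames(X)
  kappa <- unname(par_bk[p + seq_len(J - 1L)])
  opt$objective <- cur_nll
  g <- grad_bk(beta, kappa)
  converged <- max(abs(g)) / nobs < 1e-5
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p + J - 1L,
                                                     p + J - 1L))
  nm <- c(colnames(X), paste0("kappa_", seq_len(J - 1L) - 1L))
  dimnames(V) <- list(nm, nm)
  se <- sqrt(pmax(diag(V), 0))
  structure(list(
    coefficients = beta, kappa = kappa, levels = levels,
    se = se[seq_len(p)], se_kappa = se[p + seq_len(J - 1L)], vcov = V,
    logLik = -opt$objective, converged = converged,
    grad_norm = max(abs(g)) / nobs, n = length(y), nobs_weight = nobs
  ), class = "oprobit")
}

# central finite differences of an analytic gradient -> symmetrized Hessian
.fd_hessian <- function(grad, par, eps = 1e-5) {
  k <- length(par)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    h <- eps * max(1, abs(par[i]))
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    H[i, ] <- (grad(up) - grad(dn)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Ordered-probit category probabilities
#'
#' Probability of each outcome level given design rows, from a fitted
#' [fit_ordered_probit()] object or a bare parameter list with elements
#' `beta`, `kappa` and optionally `levels`. For score-scale models (levels
#' within 0..27) the result has 28 columns `"0"`..`"27"` with zeros at
#' levels the model cannot emit; otherwise one column per model level.
#' Rows are non-negative and sum to one.
#'
#' @param object an `"oprobit"` fit or `list(beta =, kappa =, levels =)`.
#' @param X design matrix (or single row) matching the coefficients.
#' @return matrix of probabilities, one row per row of `X`.
#' @export
category_probabilities <- function(object, X) {
  pp <- .op_params(object)
  if (any(diff(pp$kappa) <= 0)) {
    stop("cutpoints must be strictly increasing", call. = FALSE)
  }
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  eta <- if (length(pp$beta)) drop(X %*% pp$beta) else numeric(nrow(X))
  P <- .op_probs(eta, pp$kappa)
  lv <- pp$levels
  # score-scale models (top of the 0..27 range observed) report the full
  # 28-column scale, with zeros at levels merged away during estimation
  if (all(lv %in% 0:27) && max(lv) == 27 && length(lv) < 28L) {
    out <- matrix(0, nrow(P), 28L, dimnames = list(NULL, as.character(0:27)))
    out[, as.character(lv)] <- P
    out
  } else {
    colnames(P) <- as.character(lv)
    P
  }
}

.op_params <- function(object) {
  if (inherits(object, "oprobit")) {
    list(beta = object$coefficients, kappa = object$kappa,
         levels = object$levels)
  } else {
    lv <- object$levels
    if (is.null(lv)) lv <- seq_len(length(object$kappa) + 1L) - 1L
    list(beta = object$beta, kappa = object$kappa, levels = lv)
  }
}

#' Ordered-probit log-likelihood of a data set
#'
#' @param object fit or parameter list as in [category_probabilities()].
#' @param y outcome vector (values must be among the model levels).
#' @param X design matrix.
#' @param weights optional case weights.
#' @return the summed log-likelihood (0 for empty data); category
#'   probabilities are clamped at 1e-300 so the result is finite.
#' @export
op_loglik <- function(object, y, X, weights = NULL) {
  if (length(y) == 0L) return(0)
  pp <- .op_params(object)
  yi <- match(y, pp$levels)
  if (anyNA(yi)) stop("outcome value outside model levels", call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  X <- if (is.null(dim(X))) matrix(X, nrow = length(y)) else as.matrix(X)
  .op_nll_core(pp$beta, pp$kappa, yi, X, w)$nll * -1
}

# inverse-cdf draw of outcome levels: u uniform(0,1) per row
.op_draw <- function(object, eta, u) {
  pp <- .op_params(object)
  z <- eta + stats::qnorm(u)
  pp$levels[findInterval(z, pp$kappa) + 1L]
}

#' @export
print.oprobit <- function(x, ...) {
  cat("Ordered probit fit:", length(x$coefficients), "coefficients,",
      length(x$kappa) + 1L, "outcome levels, n =", x$n, "\n")
  cat("logLik:", format(x$logLik), " converged:", x$converged, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.oprobit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Err` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, kappa = object$kappa,
                 se_kappa = object$se_kappa, logLik = object$logLik,
                 converged = object$converged, n = object$n),
            class = "summary.oprobit")
}

#' @export
print.summary.oprobit <- function(x, ...) {
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nCutpoints:", paste(round(x$kappa, 3), collapse = " "), "\n")
  cat("logLik:", format(x$logLik), " n:", x$n,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
coef.oprobit <- function(object, ...) object$coefficients

#' @export
vcov.oprobit <- function(object, ...) object$vcov

#' @export
logLik.oprobit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) +
              length(object$kappa), nobs = object$n, class = "logLik")
}

#' Predict from an ordered probit fit
#'
#' @param object an `"oprobit"` fit.
#' @param newdata design matrix matching the fitted coefficients.
#' @param type `"prob"` (category probabilities), `"expected"` (expected
#'   outcome level), or `"class"` (most probable level).
#' @param ... unused.
#' @export
predict.oprobit <- function(object, newdata,
                            type = c("prob", "expected", "class"), ...) {
  type <- match.arg(type)
  P <- category_probabilities(object, newdata)
  lv <- as.numeric(colnames(P))
  switch(type,
         prob = P,
         expected = drop(P %*% lv),
         class = lv[max.col(P, ties.method = "first")])
}

#' Simulate outcomes from an ordered probit fit
#'
#' @param object an `"oprobit"` fit.
#' @param nsim number of replicate outcome vectors.
#' @param seed optional seed.
#' @param newdata design matrix.
#' @param ... unused.
#' @return matrix `nrow(newdata) x nsim` of drawn levels.
#' @export
simulate.oprobit <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(newdata)
  eta <- drop(X %*% object$coefficients)
  out <- matrix(0L, nrow(X), nsim)
  for (s in seq_len(nsim)) {
    out[, s] <- .op_draw(object, eta, stats::runif(nrow(X)))
  }
  out
}
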