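# Binary probit by maximum likelihood: P(y = 1 | x) = Phi(x'gamma + c).
# Written against the same optimizer/SE conventions as the ordered probit
# (quasi-Newton with analytic gradient, observed-information standard
# errors); glm(family = binomial("probit")) is used only as an independent
# cross-check in the test suite.

.bp_nll_grad <- function(par, y, X, w, has_int) {
  eta <- drop(X %*% par)
  # stable log Phi via log.p
  lp1 <- stats::pnorm(eta, log.p = TRUE)
  lp0 <- stats::pnorm(-eta, log.p = TRUE)
  nll <- -sum(w * ifelse(y == 1L, lp1, lp0))
  d <- stats::dnorm(eta)
  p1 <- stats::pnorm(eta)
  r <- ifelse(y == 1L, -d / pmax(p1, 1e-300), d / pmax(1 - p1, 1e-300))
  list(nll = nll, grad = drop(crossprod(X, w * r)))
}

#' Fit a binary probit model
#'
#' Maximum-likelihood probit for a 0/1 outcome (such as two-year mortality).
#' An explicit intercept is added by default; the published mortality
#' coefficient table omits one, but a calibrated level is required for any
#' absolute mortality probability.
#'
#' @param y 0/1 outcome vector.
#' @param X numeric design matrix with column names.
#' @param intercept add an intercept column (default TRUE).
#' @param weights optional case weights.
#' @param reltol,maxit optimizer controls.
#' @return an object of class `"bprobit"` with coefficients (intercept first
#'   when present), `se`, `vcov`, `logLik`, `converged`, `n`.
#' @export
fit_probit <- function(y, X, intercept = TRUE, weights = NULL,
                       reltol = 1e-10, maxit = 300L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  if (all(y == 0) || all(y == 1)) {
    stop("outcome is constant (complete separation): probit not identified",
         call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(X)[qx$pivot[-seq_len(qx$rank)]], collapse = ", "),
         call. = FALSE)
  }
  start <- rep(0, ncol(X))
  if (intercept) start[1L] <- stats::qnorm(sum(w * y) / sum(w))
  cache <- new.env(parent = emptyenv())
  core_at <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$core)
    cache$par <- par
    cache$core <- .bp_nll_grad(par, y, X, w, intercept)
    cache$core
  }
  fn <- function(par) core_at(par)$nll
  gr <- function(par) core_at(par)$grad
  opt <- stats::nlminb(start, fn, gr,
                       control = list(rel.tol = reltol, iter.max = maxit,
                                      eval.max = 4L * maxit))
  par <- opt$par
  nobs <- sum(w)
  # Newton polish with observed-information steps: the quasi-Newton stop
  # rule is a likelihood change, not a gradient norm
  gr1 <- function(q) .bp_nll_grad(q, y, X, w, intercept)$grad
  cur_nll <- .bp_nll_grad(par, y, X, w, intercept)$nll
  H <- .fd_hessian(gr1, par)
  for (it in 1:4) {
    g <- gr1(par)
    if (max(abs(g)) / nobs < 1e-9) break
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    sc <- 1
    repeat {
      cand <- par - sc * step
      cand_nll <- .bp_nll_grad(cand, y, X, w, intercept)$nll
      if (cand_nll <= cur_nll || sc < 1e-4) break
      sc <- sc / 2
    }
    if (cand_nll > cur_nll) break
    par <- cand
    cur_nll <- cand_nll
    H <- .fd_hessian(gr1, par)
  }
  opt$objective <- cur_nll
  names(par) <- colnames(X)
  g <- gr1(par)
  converged <- max(abs(g)) / nobs < 1e-5
  V <- tryCatch(solve(H),
                error = function(e) matrix(NA_real_, length(par),
                                           length(par)))
  dimnames(V) <- list(names(par), names(par))
  structure(list(
    coefficients = par, se = sqrt(pmax(diag(V), 0)), vcov = V,
    logLik = -opt$objective, converged = converged,
    grad_norm = max(abs(g)) / nobs, n = length(y), intercept = intercept
  ), class = "bprobit")
}

#' Probit log-likelihood of a data set
#'
#' @param object a `"bprobit"` fit or a named coefficient vector (including
#'   `(Intercept)` if the design carries one).
#' @param y 0/1 outcome vector.
#' @param X design matrix; an intercept column is added automatically when
#'   the coefficients contain `(Intercept)` and `X` does not.
#' @param weights optional case weights.
#' @return summed log-likelihood (0 for empty data).
#' @export
probit_loglik <- function(object, y, X, weights = NULL) {
  if (length(y) == 0L) return(0)
  cf <- if (inherits(object, "bprobit")) object$coefficients else object
  X <- if (is.null(dim(X))) matrix(X, nrow = length(y)) else as.matrix(X)
  if ("(Intercept)" %in% names(cf) &&
      !"(Intercept)" %in% colnames(X)) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  X <- X[, names(cf), drop = FALSE]
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  -.bp_nll_grad(cf, y, X, w, FALSE)$nll
}

#' @export
print.bprobit <- function(x, ...) {
  cat("Probit fit:", length(x$coefficients), "coefficients, n =", x$n, "\n")
  cat("logLik:", format(x$logLik), " converged:", x$converged, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.bprobit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Err` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, logLik = object$logLik,
                 converged = object$converged, n = object$n),
            class = "summary.bprobit")
}

#' @export
print.summary.bprobit <- function(x, ...) {
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("logLik:", format(x$logLik), " n:", x$n,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
coef.bprobit <- function(object, ...) object$coefficients

#' @export
vcov.bprobit <- function(object, ...) object$vcov

#' @export
logLik.bprobit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' Predict event probabilities from a probit fit
#'
#' @param object a `"bprobit"` fit.
#' @param newdata design matrix (without intercept column; added when the
#'   fit has one).
#' @param type `"prob"` for Phi(index) or `"link"` for the linear index.
#' @param ... unused.
#' @export
predict.bprobit <- function(object, newdata, type = c("prob", "link"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (object$intercept) X <- cbind(`(Intercept)` = 1, X)
  eta <- drop(X %*% object$coefficients[colnames(X)])
  if (type == "link") eta else stats::pnorm(eta)
}
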