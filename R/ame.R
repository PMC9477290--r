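#' Average marginal effects
#'
#' Sample-average marginal effects of each covariate. For the probit the
#' effect is on the event probability: the mean of `dnorm(index) * gamma_k`
#' for continuous covariates and the mean discrete difference
#' `Phi(index | x_k = 1) - Phi(index | x_k = 0)` for binary ones. For the
#' ordered probit the effect is on the expected outcome level
#' `E[S | x] = sum_j j P(j | x)`, with the same continuous/binary treatment.
#' A column is treated as binary when all its observed values are 0 or 1.
#'
#' @param fit a converged `"oprobit"` or `"bprobit"` fit.
#' @param X design matrix of evaluation rows (without intercept column).
#' @return named numeric vector of average marginal effects (the intercept,
#'   when present, is omitted).
#' @export
average_marginal_effects <- function(fit, X) {
  if (!isTRUE(fit$converged)) {
    stop("average marginal effects require a converged fit", call. = FALSE)
  }
  X <- as.matrix(X)
  is_bin <- apply(X, 2L, function(v) all(v %in% c(0, 1)))
  if (inherits(fit, "bprobit")) {
    cf <- fit$coefficients
    nm <- setdiff(names(cf), "(Intercept)")
    Xi <- if (fit$intercept) cbind(`(Intercept)` = 1, X) else X
    eta <- drop(Xi %*% cf[colnames(Xi)])
    out <- numeric(length(nm))
    names(out) <- nm
    mphi <- mean(stats::dnorm(eta))
    for (k in nm) {
      if (is_bin[[k]]) {
        d <- eta + (1 - X[, k]) * cf[[k]]   # index with x_k = 1
        d0 <- eta - X[, k] * cf[[k]]        # index with x_k = 0
        out[[k]] <- mean(stats::pnorm(d) - stats::pnorm(d0))
      } else {
        out[[k]] <- mphi * cf[[k]]
      }
    }
    return(out)
  }
  if (!inherits(fit, "oprobit")) stop("unsupported fit class", call. = FALSE)
  cf <- fit$coefficients
  lv <- fit$levels
  eta <- drop(X[, names(cf), drop = FALSE] %*% cf)
  expected <- function(e) drop(.op_probs(e, fit$kappa) %*% lv)
  # dE/deta = sum_j lv_j * (phi(kappa_{j-1} - eta) - phi(kappa_j - eta))
  D <- stats::dnorm(outer(eta, fit$kappa, function(e, k) k - e))
  dEdeta <- drop(cbind(D, 0) %*% lv - cbind(0, D) %*% lv) * -1
  out <- numeric(length(cf))
  names(out) <- names(cf)
  for (k in names(cf)) {
    if (is_bin[[k]]) {
      e1 <- eta + (1 - X[, k]) * cf[[k]]
      e0 <- eta - X[, k] * cf[[k]]
      out[[k]] <- mean(expected(e1) - expected(e0))
    } else {
      out[[k]] <- mean(dEdeta) * cf[[k]]
    }
  }
  out
}
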