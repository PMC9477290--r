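# Sequential-regression multiple imputation of MNAR-flagged missing TICS27
# for proxy respondents. Wave by wave from earliest to latest, the observed
# scores are regressed on demographics, health and economic covariates plus
# prior-wave cognition (score, category, proxy flag); parameters are drawn
# from their approximate sampling distribution and missing cells filled by
# predictive mean matching, so imputed values are always observed donor
# scores (integers in 0..27). Nonrespondent waves are absent rows and are
# never imputed.

.imp_predictors <- function(rows, prior = NULL) {
  X <- cbind(
    intercept = 1,
    age = rows$age, male = rows$male,
    nh_black = as.numeric(rows$race_ethnicity == "nh_black"),
    hispanic = as.numeric(rows$race_ethnicity == "hispanic"),
    lt_hs = as.numeric(rows$education == "lt_hs"),
    some_college = as.numeric(rows$education == "some_college"),
    heart = rows$heart_ever, stroke = rows$stroke_ever,
    cancer = rows$cancer_ever, hypertension = rows$hypertension_ever,
    diabetes = rows$diabetes_ever, lung = rows$lung_ever,
    chf = rows$chf_ever, adl = rows$adl_count, iadl = rows$iadl_count,
    log_bmi = rows$log_bmi, working = rows$working,
    widowed = rows$widowed, smoke_ever = rows$smoke_ever
  )
  if (!is.null(prior)) {
    X <- cbind(X,
               prior_score = prior$score,
               prior_mci = as.numeric(prior$score <= 11 & prior$score >= 7),
               prior_dem = as.numeric(prior$score <= 6),
               prior_proxy = prior$proxy)
  }
  for (cl in colnames(X)) {
    if (anyNA(X[, cl])) {
      stop("imputation predictor '", cl, "' has missing values",
           call. = FALSE)
    }
  }
  X
}

#' Multiple imputation of missing TICS27 scores
#'
#' @param panel long panel whose only missingness is in `tics27` on alive
#'   (proxy) rows.
#' @param m number of completed panels (>= 2, default 5).
#' @param seed integer seed; imputations use sub-seeds derived from it.
#' @param donor_count predictive-mean-matching donor pool size (default 5).
#' @return object of class `"completed_panels"`: a list `panels` of m
#'   completed copies (observed cells identical across copies, imputed cells
#'   integer scores in 0..27), plus `m` and `seed`.
#' @export
impute_tics27 <- function(panel, m = 5L, seed = 1L, donor_count = 5L) {
  if (m < 2L) stop("m must be >= 2", call. = FALSE)
  if (donor_count < 1L) stop("donor_count must be >= 1", call. = FALSE)
  panel <- panel[order(panel$person_id, panel$wave), , drop = FALSE]
  waves <- sort(unique(panel$wave[panel$alive == 1L]))
  for (w in waves) {
    sc <- panel$tics27[panel$alive == 1L & panel$wave == w]
    if (length(sc) && all(is.na(sc))) {
      stop("all tics27 missing at wave ", w, ": cannot impute",
           call. = FALSE)
    }
  }
  panels <- vector("list", m)
  for (imp in seq_len(m)) {
    set.seed((seed * 131L + imp * 7919L) %% 2147483629L)
    panels[[imp]] <- .impute_once(panel, waves, donor_count)
  }
  structure(list(panels = panels, m = m, seed = seed,
                 donor_count = donor_count), class = "completed_panels")
}

.impute_once <- function(panel, waves, donor_count) {
  out <- panel
  key <- paste(out$person_id, out$wave)
  for (w in waves) {
    rows_idx <- which(out$alive == 1L & out$wave == w)
    rows <- out[rows_idx, , drop = FALSE]
    mis <- is.na(rows$tics27)
    if (!any(mis)) next
    prior_idx <- match(paste(rows$person_id, w - 1L), key)
    prior <- NULL
    if (!all(is.na(prior_idx))) {
      has_prior <- !is.na(prior_idx)
      # prior-wave scores already completed by earlier-wave imputation
      prior <- list(score = ifelse(has_prior, out$tics27[prior_idx], 0),
                    proxy = ifelse(has_prior, out$proxy[prior_idx], 0))
      prior$score[is.na(prior$score)] <- 0
      # flag rows lacking a prior wave so the level is absorbed
      prior$no_prior <- as.numeric(!has_prior)
    }
    X <- .imp_predictors(rows, prior)
    if (!is.null(prior)) X <- cbind(X, no_prior = prior$no_prior)
    yobs <- rows$tics27[!mis]
    Xo <- X[!mis, , drop = FALSE]
    Xm <- X[mis, , drop = FALSE]
    qx <- qr(Xo)
    use <- qx$pivot[seq_len(qx$rank)]
    Xo <- Xo[, use, drop = FALSE]
    Xm <- Xm[, use, drop = FALSE]
    fit <- stats::lm.fit(Xo, yobs)
    df <- length(yobs) - ncol(Xo)
    sigma2 <- sum(fit$residuals^2) / max(df, 1L)
    sigma2_draw <- sigma2 * max(df, 1L) / stats::rchisq(1L, max(df, 1L))
    XtXinv <- chol2inv(chol(crossprod(Xo)))
    beta_draw <- drop(fit$coefficients +
                        crossprod(chol(XtXinv * sigma2_draw),
                                  stats::rnorm(ncol(Xo))))
    pred_obs <- drop(Xo %*% fit$coefficients)
    pred_mis <- drop(Xm %*% beta_draw)
    ord <- order(pred_obs)
    po <- pred_obs[ord]
    yo <- yobs[ord]
    k <- min(donor_count, length(yo))
    pos <- findInterval(pred_mis, po)
    fill <- vapply(seq_along(pred_mis), function(i) {
      lo <- max(1L, pos[i] - k)
      hi <- min(length(po), pos[i] + k)
      cand <- lo:hi
      cand <- cand[order(abs(po[cand] - pred_mis[i]))][seq_len(
        min(k, length(cand)))]
      yo[cand[sample.int(length(cand), 1L)]]
    }, numeric(1))
    out$tics27[rows_idx[mis]] <- as.integer(fill)
  }
  out
}

#' @export
print.completed_panels <- function(x, ...) {
  cat("Completed panels: m =", x$m, "imputations of",
      nrow(x$panels[[1L]]), "rows\n")
  invisible(x)
}

#' Pooled transition-model fit over completed panels
#'
#' Fits the requested transition model on each completed panel and returns
#' the equal-weight average of the coefficient vectors (and, for the ordered
#' probit, cutpoints). Between-imputation variance and the Rubin-style total
#' variance (within + (1 + 1/m) between) are attached as diagnostics.
#'
#' @param completed a [impute_tics27()] result.
#' @param model `"tics"` or `"mortality"`.
#' @param spec a [design_spec()].
#' @return the first imputation's fit object with averaged parameters;
#'   fields `pooled_m`, `coef_by_imputation`, `between_var`, `total_var`
#'   added.
#' @export
pooled_fit <- function(completed, model = c("tics", "mortality"),
                       spec = design_spec()) {
  model <- match.arg(model)
  fits <- vector("list", completed$m)
  for (i in seq_len(completed$m)) {
    fits[[i]] <- tryCatch({
      rt <- transition_rows(completed$panels[[i]], model)
      X <- build_design(rt, model, spec)
      if (model == "tics") fit_ordered_probit(rt$outcome, X)
      else fit_probit(rt$outcome, X)
    }, error = function(e) stop("fit failed for imputation ", i, ": ",
                                conditionMessage(e), call. = FALSE))
  }
  B <- do.call(rbind, lapply(fits, coef))
  out <- fits[[1L]]
  out$coefficients <- colMeans(B)
  if (model == "tics") {
    out$kappa <- colMeans(do.call(rbind, lapply(fits, `[[`, "kappa")))
  }
  within <- colMeans(do.call(rbind, lapply(fits, function(f) {
    f$se[seq_len(ncol(B))]^2
  })))
  between <- apply(B, 2L, stats::var)
  out$pooled_m <- completed$m
  out$coef_by_imputation <- B
  out$between_var <- between
  out$total_var <- within + (1 + 1 / completed$m) * between
  out$converged <- all(vapply(fits, `[[`, logical(1), "converged"))
  out
}
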