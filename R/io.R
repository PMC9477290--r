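# Plain-text interchange: panels as CSV (missing scores as empty fields),
# model parameters as CSV or JSON, cohort configurations as JSON or YAML.

#' Write / read a panel as CSV
#'
#' @param panel panel data frame.
#' @param file path; missing `tics27` is encoded as an empty field.
#' @export
write_panel <- function(panel, file) {
  utils::write.csv(panel, file, row.names = FALSE, na = "")
}

#' @rdname write_panel
#' @export
read_panel <- function(file) {
  panel <- utils::read.csv(file, stringsAsFactors = FALSE)
  panel$tics27 <- suppressWarnings(as.integer(panel$tics27))
  panel
}

#' Write / read transition-model parameters
#'
#' CSV carries rows `(name, estimate, std_err)` with cutpoints as
#' `kappa_0..`; JSON carries `model`, `beta`, `se`, and for the ordered
#' probit `kappa` and `levels`.
#'
#' @param fit an `"oprobit"` or `"bprobit"` fit (or parameter object).
#' @param file output path ending in `.csv` or `.json`.
#' @export
write_model_params <- function(fit, file) {
  type <- if (inherits(fit, "oprobit")) "oprobit" else "bprobit"
  se <- fit$se
  if (is.null(se)) se <- rep(NA_real_, length(fit$coefficients))
  if (grepl("\\.json$", file)) {
    obj <- list(model = type,
                beta = as.list(fit$coefficients),
                se = as.list(stats::setNames(se,
                                             names(fit$coefficients))))
    if (type == "oprobit") {
      obj$kappa <- fit$kappa
      obj$levels <- fit$levels
    }
    jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  } else {
    nm <- names(fit$coefficients)
    est <- unname(fit$coefficients)
    sev <- unname(se)
    if (type == "oprobit") {
      nm <- c(nm, paste0("kappa_", seq_along(fit$kappa) - 1L))
      est <- c(est, fit$kappa)
      ks <- fit$se_kappa
      if (is.null(ks)) ks <- rep(NA_real_, length(fit$kappa))
      sev <- c(sev, unname(ks))
    }
    utils::write.csv(data.frame(name = nm, estimate = est, std_err = sev),
                     file, row.names = FALSE)
  }
}

#' @rdname write_model_params
#' @export
read_model_params <- function(file) {
  if (grepl("\\.json$", file)) {
    obj <- jsonlite::read_json(file, simplifyVector = TRUE)
    if (identical(obj$model, "oprobit")) {
      return(make_oprobit_params(unlist(obj$beta), as.numeric(obj$kappa),
                                 as.numeric(obj$levels)))
    }
    beta <- unlist(obj$beta)
    int <- beta[["(Intercept)"]]
    return(make_probit_params(beta[names(beta) != "(Intercept)"], int))
  }
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  is_k <- grepl("^kappa_", tab$name)
  if (any(is_k)) {
    beta <- stats::setNames(tab$estimate[!is_k], tab$name[!is_k])
    return(make_oprobit_params(beta, tab$estimate[is_k]))
  }
  beta <- stats::setNames(tab$estimate, tab$name)
  int <- if ("(Intercept)" %in% names(beta)) beta[["(Intercept)"]] else 0
  make_probit_params(beta[names(beta) != "(Intercept)"], int)
}

#' Read a cohort configuration from JSON or YAML
#'
#' Recognized fields mirror the [cohort_config()] arguments; absent fields
#' keep their defaults. True models always default to
#' [default_true_models()].
#'
#' @param file path ending in `.json`, `.yml` or `.yaml`.
#' @return a validated `"cohort_config"`.
#' @export
read_cohort_config <- function(file) {
  obj <- if (grepl("\\.ya?ml$", file)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(file)
  } else {
    jsonlite::read_json(file, simplifyVector = TRUE)
  }
  args <- list()
  for (nm in c("n_individuals", "n_waves", "seed", "age_range",
               "weight_dispersion")) {
    if (!is.null(obj[[nm]])) args[[nm]] <- obj[[nm]]
  }
  if (!is.null(obj$covariate_prevalences)) {
    args$covariate_prevalences <- unlist(obj$covariate_prevalences)
  }
  if (!is.null(obj$incidence_rates)) {
    args$incidence_rates <- unlist(obj$incidence_rates)
  }
  if (!is.null(obj$proxy_missingness)) {
    args$proxy_missingness <- as.list(obj$proxy_missingness)
  }
  do.call(cohort_config, args)
}
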