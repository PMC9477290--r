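#' Parameter-recovery experiment seeded by the reference coefficients
#'
#' Generates single-transition synthetic data whose latent-index truth is
#' the reference coefficient vector of the chosen transition model, then
#' refits that model by maximum likelihood. For the TICS27 model: lag scores
#' uniform integers 0..27, binary covariates Bernoulli at the default
#' prevalences, race multinomial (0.81 white / 0.09 Black / 0.07 Hispanic),
#' verified-ever Bernoulli(0.1), age uniform 53..95 through the (65, 75)
#' spline, delta-age uniform on (-0.5, 0.5); the latent index is centered at
#' its sample mean, cutpoints are the default grid, and standard-normal
#' noise is added before thresholding. For the mortality model the same raw
#' covariates feed the (65, 75, 85) spline design, the intercept is solved
#' so the average death probability equals `target_rate`, and deaths are
#' Bernoulli draws from the probit probabilities.
#'
#' @param model `"tics"` or `"mortality"`.
#' @param n number of rows (default 100,000 for TICS, 200,000 for
#'   mortality).
#' @param seed integer seed.
#' @param target_rate mean event probability for the mortality experiment.
#' @return list with `fit` (the recovered model), `truth` (the generating
#'   coefficients), and for mortality `intercept_truth`.
#' @export
recovery_experiment <- function(model = c("tics", "mortality"), n = NULL,
                                seed = 1L, target_rate = 0.1) {
  model <- match.arg(model)
  if (is.null(n)) n <- if (model == "tics") 100000L else 200000L
  set.seed(seed)
  pv <- .default_prevalences
  bern <- function(p) as.integer(stats::runif(n) < p)
  u_race <- stats::runif(n)
  u_ed <- stats::runif(n)
  u_adl <- stats::runif(n)
  u_iadl <- stats::runif(n)
  raw <- data.frame(
    person_id = seq_len(n), wave = 1L,
    age = stats::runif(n, 53, 95),
    male = bern(pv[["male"]]),
    race_ethnicity = ifelse(u_race < 0.09, "nh_black",
                            ifelse(u_race < 0.16, "hispanic", "nh_white")),
    education = ifelse(u_ed < pv[["lt_hs"]], "lt_hs",
                       ifelse(u_ed < pv[["lt_hs"]] + pv[["some_college"]],
                              "some_college", "hs")),
    heart_ever = bern(pv[["heart_ever"]]),
    stroke_ever = bern(pv[["stroke_ever"]]),
    cancer_ever = bern(pv[["cancer_ever"]]),
    hypertension_ever = bern(pv[["hypertension_ever"]]),
    diabetes_ever = bern(pv[["diabetes_ever"]]),
    lung_ever = bern(pv[["lung_ever"]]),
    chf_ever = bern(0.1),
    heart_attack_2yr = bern(pv[["heart_attack_2yr"]]),
    working = bern(pv[["working"]]),
    widowed = bern(pv[["widowed"]]),
    smoke_ever = bern(pv[["smoke_ever"]]),
    smoke_current = bern(pv[["smoke_current"]]),
    log_bmi = stats::rnorm(n, log(27.5), 0.17),
    adl_count = (u_adl < pv[["adl_1"]] + pv[["adl_2"]] + pv[["adl_3p"]]) +
      (u_adl < pv[["adl_2"]] + pv[["adl_3p"]]) + (u_adl < pv[["adl_3p"]]),
    iadl_count = (u_iadl < pv[["iadl_1"]] + pv[["iadl_2p"]]) +
      (u_iadl < pv[["iadl_2p"]]),
    verified_ever = bern(0.1),
    delta_age = stats::runif(n, -0.5, 0.5),
    lag2_tics = sample(0:27, n, replace = TRUE),
    lag4_tics = sample(0:27, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  raw$heart50 <- raw$heart_ever * bern(0.25)
  raw$stroke50 <- raw$stroke_ever * bern(0.25)
  raw$cancer50 <- raw$cancer_ever * bern(0.25)
  raw$hypertension50 <- raw$hypertension_ever * bern(0.3)
  raw$diabetes50 <- raw$diabetes_ever * bern(0.3)
  raw$lung50 <- raw$lung_ever * bern(0.25)
  raw$smoke_ever50 <- raw$smoke_ever * bern(0.85)
  raw$smoke_current50 <- raw$smoke_ever50 * bern(0.5)
  X <- build_design(raw, model)
  if (model == "tics") {
    truth <- fem_tics27_coefs()$coef[colnames(X)]
    eta <- drop(X %*% truth)
    eta <- eta - mean(eta)
    y <- findInterval(eta + stats::rnorm(n), default_cutpoints())
    fit <- fit_ordered_probit(y, X)
    return(list(fit = fit, truth = truth))
  }
  truth <- fem_mortality_coefs()$coef[colnames(X)]
  eta <- drop(X %*% truth)
  c0 <- stats::uniroot(function(c0) mean(stats::pnorm(eta + c0)) -
                         target_rate, c(-20, 20))$root
  y <- as.integer(stats::runif(n) < stats::pnorm(eta + c0))
  fit <- fit_probit(y, X)
  list(fit = fit, truth = truth, intercept_truth = c0)
}
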