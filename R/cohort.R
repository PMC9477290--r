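# Synthetic survey-like cohorts with the statistical structure the
# transition models assume: ages 53+, biennial waves, lagged scores (a
# pre-baseline wave so the four-year lag exists at the first transition),
# absorbing condition indicators, sample weights, and MNAR proxy
# missingness of the cognitive score.

.default_prevalences <- c(
  male = 0.45, nh_black = 0.091, hispanic = 0.073,
  lt_hs = 0.181, some_college = 0.472,
  heart_ever = 0.215, stroke_ever = 0.075, cancer_ever = 0.131,
  hypertension_ever = 0.517, diabetes_ever = 0.179, lung_ever = 0.083,
  chf_ever = 0.05, heart_attack_2yr = 0.017, working = 0.429,
  widowed = 0.177, smoke_ever = 0.571, smoke_current = 0.15,
  adl_1 = 0.06, adl_2 = 0.03, adl_3p = 0.04, iadl_1 = 0.06, iadl_2p = 0.05
)

.default_incidence <- c(
  heart_ever = 0.020, stroke_ever = 0.012, cancer_ever = 0.015,
  hypertension_ever = 0.030, diabetes_ever = 0.015, lung_ever = 0.008,
  chf_ever = 0.012, widowed = 0.015
)

#' Default data-generating transition models
#'
#' The reference TICS27 and mortality coefficient vectors combined with the
#' default cutpoint grid, used as the latent-index truth of the synthetic
#' cohort process. Level calibrations (the cutpoint shift that makes the
#' baseline score distribution approximately stationary, and the mortality
#' intercept hitting a target two-year death rate) are performed against a
#' concrete baseline cohort by [calibrate_true_models()].
#'
#' @return list with elements `tics` (list `beta`, `kappa`) and `mortality`
#'   (list `gamma`, `target_rate`).
#' @export
default_true_models <- function() {
  list(
    tics = list(beta = fem_tics27_coefs()$coef, kappa = default_cutpoints()),
    mortality = list(gamma = fem_mortality_coefs()$coef, target_rate = 0.07)
  )
}

#' Configuration for synthetic cohort generation
#'
#' @param n_individuals number of persons.
#' @param n_waves number of on-study waves (baseline plus `n_waves - 1`
#'   transitions; default 6, i.e. a 2006-2016 style ten-year panel). A
#'   pre-baseline wave (index -1) is always generated so the four-year lag
#'   score exists at the first transition.
#' @param seed non-negative integer seed.
#' @param age_range baseline age bounds in years (minimum must be >= 51).
#' @param covariate_prevalences named vector of baseline probabilities; see
#'   `ticsim:::.default_prevalences` for the recognized names and defaults.
#' @param incidence_rates named per-wave incidence probabilities for the
#'   absorbing conditions.
#' @param weight_dispersion log-normal sigma of the sample weights
#'   (normalized to mean one).
#' @param proxy_missingness list with `intercept`, `slope_per_score_point`
#'   (logit scale, applied to the true score) and `share_never_missing`.
#' @param true_models data-generating models, see [default_true_models()].
#' @return a validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_individuals = 1000L, n_waves = 6L, seed = 1L,
                          age_range = c(53, 90),
                          covariate_prevalences = .default_prevalences,
                          incidence_rates = .default_incidence,
                          weight_dispersion = 0.5,
                          proxy_missingness = list(
                            intercept = 1.0,
                            slope_per_score_point = -0.25,
                            share_never_missing = 0.5),
                          true_models = default_true_models()) {
  prev <- .default_prevalences
  prev[names(covariate_prevalences)] <- covariate_prevalences
  inc <- .default_incidence
  inc[names(incidence_rates)] <- incidence_rates
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_waves = as.integer(n_waves), seed = as.integer(seed),
              age_range = age_range, covariate_prevalences = prev,
              incidence_rates = inc, weight_dispersion = weight_dispersion,
              proxy_missingness = proxy_missingness,
              true_models = true_models)
  for (nm in names(prev)) {
    if (is.na(prev[[nm]]) || prev[[nm]] < 0 || prev[[nm]] > 1) {
      stop("covariate_prevalences['", nm, "'] must be a probability",
           call. = FALSE)
    }
  }
  for (nm in names(inc)) {
    if (is.na(inc[[nm]]) || inc[[nm]] < 0 || inc[[nm]] > 1) {
      stop("incidence_rates['", nm, "'] must be a probability", call. = FALSE)
    }
  }
  pm <- proxy_missingness
  if (!is.null(pm)) {
    if (is.na(pm$share_never_missing) || pm$share_never_missing < 0 ||
        pm$share_never_missing > 1) {
      stop("proxy_missingness$share_never_missing must be a probability",
           call. = FALSE)
    }
    if (!is.finite(pm$intercept) || !is.finite(pm$slope_per_score_point)) {
      stop("proxy_missingness intercept/slope must be finite", call. = FALSE)
    }
  }
  if (cfg$n_individuals < 1L) stop("n_individuals must be positive",
                                   call. = FALSE)
  if (cfg$n_waves < 2L) stop("n_waves must be >= 2", call. = FALSE)
  if (cfg$seed < 0L) stop("seed must be non-negative", call. = FALSE)
  if (age_range[1L] < 51) stop("age_range minimum must be >= 51",
                               call. = FALSE)
  if (weight_dispersion <= 0) stop("weight_dispersion must be positive",
                                   call. = FALSE)
  class(cfg) <- "cohort_config"
  cfg
}

# latent score draw: discretized normal, center 15.6, dispersion declining
# in education and increasing in age
.baseline_score_sd <- function(age, education) {
  fac <- c(lt_hs = 1.15, hs = 1.0, some_college = 0.9)[education]
  4.4 * fac * (1 + 0.008 * (age - 70))
}

.clamp_score <- function(z) pmin(pmax(round(z), 0), 27)

#' Generate a baseline cohort (waves -1 and 0)
#'
#' Draws demographics, chronic-condition and behavioral covariates at the
#' configured prevalences, mean-one log-normal sample weights, and baseline
#' TICS27 scores from a discretized normal centered at 15.6 whose dispersion
#' declines with education and grows with age; the pre-baseline wave shares
#' the person's covariates (two years younger) and a latent score correlated
#' 0.85 with baseline, so the four-year lag and a baseline verified status
#' exist at the first transition.
#'
#' @param config a [cohort_config()].
#' @return a panel data frame with waves -1 and 0 for every person.
#' @export
generate_baseline <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  .draw_baseline(config)
}

.draw_baseline <- function(config) {
  n <- config$n_individuals
  pv <- config$covariate_prevalences
  age <- stats::runif(n, config$age_range[1L], config$age_range[2L])
  u_race <- stats::runif(n)
  race <- ifelse(u_race < pv[["nh_black"]], "nh_black",
                 ifelse(u_race < pv[["nh_black"]] + pv[["hispanic"]],
                        "hispanic", "nh_white"))
  u_ed <- stats::runif(n)
  education <- ifelse(u_ed < pv[["lt_hs"]], "lt_hs",
                      ifelse(u_ed < pv[["lt_hs"]] + pv[["some_college"]],
                             "some_college", "hs"))
  bern <- function(p) as.integer(stats::runif(n) < p)
  st <- data.frame(
    person_id = seq_len(n), age = age, male = bern(pv[["male"]]),
    race_ethnicity = race, education = education,
    heart_ever = bern(pv[["heart_ever"]]),
    stroke_ever = bern(pv[["stroke_ever"]]),
    cancer_ever = bern(pv[["cancer_ever"]]),
    hypertension_ever = bern(pv[["hypertension_ever"]]),
    diabetes_ever = bern(pv[["diabetes_ever"]]),
    lung_ever = bern(pv[["lung_ever"]]),
    chf_ever = bern(pv[["chf_ever"]]),
    heart_attack_2yr = bern(pv[["heart_attack_2yr"]]),
    working = bern(pv[["working"]]), widowed = bern(pv[["widowed"]]),
    smoke_ever = bern(pv[["smoke_ever"]]),
    log_bmi = stats::rnorm(n, log(27.5), 0.17),
    stringsAsFactors = FALSE
  )
  st$smoke_current <- st$smoke_ever * bern(pv[["smoke_current"]] /
                                             max(pv[["smoke_ever"]], 1e-12))
  u_adl <- stats::runif(n)
  st$adl_count <- (u_adl < pv[["adl_1"]] + pv[["adl_2"]] + pv[["adl_3p"]]) +
    (u_adl < pv[["adl_2"]] + pv[["adl_3p"]]) + (u_adl < pv[["adl_3p"]])
  u_iadl <- stats::runif(n)
  st$iadl_count <- (u_iadl < pv[["iadl_1"]] + pv[["iadl_2p"]]) +
    (u_iadl < pv[["iadl_2p"]])
  # by-age-50 history: a fixed share of the ever flags
  st$heart50 <- st$heart_ever * bern(0.25)
  st$stroke50 <- st$stroke_ever * bern(0.25)
  st$cancer50 <- st$cancer_ever * bern(0.25)
  st$hypertension50 <- st$hypertension_ever * bern(0.3)
  st$diabetes50 <- st$diabetes_ever * bern(0.3)
  st$lung50 <- st$lung_ever * bern(0.25)
  st$smoke_ever50 <- st$smoke_ever * bern(0.85)
  st$smoke_current50 <- st$smoke_ever50 * bern(0.5)
  w <- stats::rlnorm(n, 0, config$weight_dispersion)
  st$weight <- w / mean(w)

  sd0 <- .baseline_score_sd(st$age, st$education)
  rho <- 0.85
  z_pre <- stats::rnorm(n)
  z_base <- rho * z_pre + sqrt(1 - rho^2) * stats::rnorm(n)
  score_pre <- .clamp_score(15.6 + sd0 * z_pre)
  score_base <- .clamp_score(15.6 + sd0 * z_base)
  gap0 <- 2 + stats::runif(n, -0.5, 0.5)

  mk_wave <- function(wave, age, score, gap) {
    out <- st
    out$wave <- wave
    out$calendar_year <- 2006 + 2 * wave
    out$age <- age
    out$tics27 <- score
    out$proxy <- 0L
    out$alive <- 1L
    out$interview_gap_years <- gap
    out
  }
  panel <- rbind(mk_wave(-1L, st$age - gap0, score_pre, 2),
                 mk_wave(0L, st$age, score_base, gap0))
  panel <- panel[order(panel$person_id, panel$wave), , drop = FALSE]
  rownames(panel) <- NULL
  panel
}

#' Calibrate the level of the data-generating models to a baseline cohort
#'
#' Shifts the latent-score cutpoints so the expected next-wave score of the
#' baseline cohort equals the baseline mean for the cohort-average design
#' row (cognitive decline then emerges from aging through the age spline and
#' verified-status feedback rather than from an arbitrary level offset), and
#' solves for the probit intercept giving the target mean two-year death
#' probability.
#'
#' @param config a [cohort_config()].
#' @param baseline panel from [generate_baseline()] (waves -1 and 0).
#' @return list with `tics` (class `"oprobit"` parameter object) and
#'   `mortality` (class `"bprobit"` parameter object), usable directly by
#'   the simulation engine.
#' @export
calibrate_true_models <- function(config, baseline) {
  tm <- config$true_models
  if (is.null(tm)) stop("config$true_models is missing", call. = FALSE)
  raw <- .state_from_baseline(baseline)
  Xt <- build_design(raw, "tics")
  eta <- drop(Xt %*% tm$tics$beta[colnames(Xt)])
  target <- (mean(raw$lag2_tics) - 13.5) / 4
  shift <- mean(eta) - target
  tics <- make_oprobit_params(tm$tics$beta[colnames(Xt)],
                              tm$tics$kappa + shift)
  Xm <- build_design(raw, "mortality")
  etam <- drop(Xm %*% tm$mortality$gamma[colnames(Xm)])
  rate <- tm$mortality$target_rate
  if (is.null(rate)) rate <- 0.07
  f <- function(c0) mean(stats::pnorm(etam + c0)) - rate
  c0 <- stats::uniroot(f, c(-20, 20))$root
  mortality <- make_probit_params(tm$mortality$gamma[colnames(Xm)], c0)
  list(tics = tics, mortality = mortality)
}

# raw covariate frame describing the baseline state (predictors of the
# first transition): wave-0 covariates, lag2 = wave-0 score, lag4 = wave -1
# score, verified status knowable at wave 0
.state_from_baseline <- function(baseline) {
  baseline <- add_cognition_columns(baseline, timing = "known")
  b0 <- baseline[baseline$wave == 0L, , drop = FALSE]
  bpre <- baseline[baseline$wave == -1L, , drop = FALSE]
  stopifnot(nrow(b0) == nrow(bpre),
            all(b0$person_id == bpre$person_id))
  raw <- b0[, c("person_id", .setdiff_raw()[.setdiff_raw() != "verified_ever"],
                "weight")]
  raw$verified_ever <- as.integer(b0$verified_status != "normal")
  raw$lag2_tics <- b0$tics27
  raw$lag4_tics <- bpre$tics27
  raw$delta_age <- 0
  raw$wave <- 0L
  raw
}

#' Minimal ordered-probit parameter object
#'
#' Wraps a coefficient vector and cutpoints in the `"oprobit"` container so
#' externally supplied or data-generating parameters can be used wherever a
#' fitted model is (prediction, simulation).
#'
#' @param beta named coefficient vector.
#' @param kappa strictly increasing cutpoints.
#' @param levels outcome levels (default 0..27).
#' @export
make_oprobit_params <- function(beta, kappa, levels = 0:27) {
  if (any(diff(kappa) <= 0)) stop("kappa must be strictly increasing",
                                  call. = FALSE)
  if (length(levels) != length(kappa) + 1L) {
    stop("need length(levels) == length(kappa) + 1", call. = FALSE)
  }
  structure(list(coefficients = beta, kappa = kappa, levels = levels,
                 converged = TRUE, n = NA_integer_),
            class = "oprobit")
}

#' Minimal probit parameter object
#'
#' @param gamma named coefficient vector (without intercept).
#' @param intercept intercept value.
#' @export
make_probit_params <- function(gamma, intercept) {
  structure(list(coefficients = c(`(Intercept)` = intercept, gamma),
                 converged = TRUE, n = NA_integer_, intercept = TRUE),
            class = "bprobit")
}

#' Generate a multi-wave synthetic panel
#'
#' Starts from [generate_baseline()] and evolves waves 1..`n_waves - 1` with
#' the configured true models: a probit mortality draw, an ordered-probit
#' score draw for survivors (latent index plus standard-normal noise,
#' thresholded at the calibrated cutpoints), on-the-fly verified-status
#' updates, and an exogenous covariate process (absorbing condition
#' incidences; fresh two-year heart-attack draws; retirement with an
#' age-increasing stopping probability; smoking cessation; a Gaussian
#' log-BMI random walk, sd 0.02; ADL/IADL progression; interview gaps
#' 2 + U(-0.5, 0.5) years feeding the delta-age covariate). Scores are fully
#' observed; apply [apply_proxy_missingness()] for the MNAR mechanism.
#'
#' @param config a [cohort_config()] with `true_models` present.
#' @return long panel data frame (waves -1..n_waves-1; a death wave carries
#'   `alive = 0` and no later rows exist for that person). The calibrated
#'   true models are attached as attribute `"true_models"`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(config$true_models)) {
    stop("config$true_models must be present to evolve a panel",
         call. = FALSE)
  }
  set.seed(config$seed)
  baseline <- .draw_baseline(config)
  models <- calibrate_true_models(config, baseline)
  st <- .state_from_baseline(baseline)
  # verified severity 0/1/2 tracked on the fly (knowledge-based)
  b0 <- add_cognition_columns(baseline, timing = "known")
  b0 <- b0[b0$wave == 0L, ]
  st$verified <- match(b0$verified_status, .status_labels) - 1L
  rows <- list(baseline)
  inc <- config$incidence_rates
  n <- nrow(st)
  alive <- rep(TRUE, n)
  for (w in seq_len(config$n_waves - 1L)) {
    ia <- which(alive)
    if (!length(ia)) break
    gap <- 2 + stats::runif(length(ia), -0.5, 0.5)
    st$delta_age[ia] <- gap - 2
    # (1) mortality, using start-of-step covariates
    Xm <- build_design(st[ia, , drop = FALSE], "mortality")
    p_die <- predict(models$mortality, Xm)
    died <- stats::runif(length(ia)) < p_die
    # (2) survivors draw the next score
    is <- ia[!died]
    new_score <- integer(0)
    if (length(is)) {
      Xt <- build_design(st[is, , drop = FALSE], "tics")
      eta <- drop(Xt %*% models$tics$coefficients)
      new_score <- .op_draw(models$tics, eta,
                            stats::runif(length(is)))
    }
    # (3) verified-status update (knowledge-based, death confirms)
    prev_sev <- .score_severity(st$lag2_tics)
    if (any(died)) {
      id <- ia[died]
      st$verified[id] <- pmax(st$verified[id], prev_sev[id])
    }
    if (length(is)) {
      new_sev <- .score_severity(new_score)
      st$verified[is] <- pmax(st$verified[is],
                              .pair_confirm(prev_sev[is], new_sev))
    }
    st$verified_ever <- as.integer(st$verified > 0L)
    # death rows (state frozen at death values, score unobserved)
    if (any(died)) {
      id <- ia[died]
      dr <- .wave_rows(st[id, , drop = FALSE], w, NA_integer_, 0L,
                       gap[died])
      rows[[length(rows) + 1L]] <- dr
      alive[id] <- FALSE
    }
    if (length(is)) {
      # (4) lags shift, age and exogenous covariates advance
      st$lag4_tics[is] <- st$lag2_tics[is]
      st$lag2_tics[is] <- new_score
      st$age[is] <- st$age[is] + gap[!died]
      st <- .advance_covariates(st, is, inc)
      rows[[length(rows) + 1L]] <- .wave_rows(st[is, , drop = FALSE], w,
                                              new_score, 1L, gap[!died])
    }
  }
  panel <- do.call(rbind, rows)
  panel <- panel[order(panel$person_id, panel$wave), , drop = FALSE]
  rownames(panel) <- NULL
  attr(panel, "true_models") <- models
  panel
}

.score_severity <- function(score) (score <= 11L) + (score <= 6L)

# severity confirmed by a (previous, new) category pair
.pair_confirm <- function(prev_sev, new_sev) {
  out <- integer(length(prev_sev))
  out[prev_sev == 2L & new_sev == 2L] <- 2L
  out[prev_sev == 1L & new_sev >= 1L] <- 1L
  out[prev_sev == 2L & new_sev == 1L] <- pmax(
    out[prev_sev == 2L & new_sev == 1L], 1L)
  out
}

.advance_covariates <- function(st, is, inc) {
  n <- length(is)
  bern <- function(p) stats::runif(n) < p
  for (nm in setdiff(names(inc), "widowed")) {
    hit <- bern(inc[[nm]])
    st[[nm]][is] <- pmax(st[[nm]][is], as.integer(hit))
  }
  st$widowed[is] <- pmax(st$widowed[is], as.integer(bern(inc[["widowed"]])))
  st$heart_attack_2yr[is] <- as.integer(bern(0.015))
  stop_p <- stats::plogis(-3 + 0.07 * (st$age[is] - 50))
  st$working[is] <- st$working[is] * as.integer(!bern(stop_p))
  st$smoke_current[is] <- st$smoke_current[is] * as.integer(!bern(0.1))
  st$log_bmi[is] <- st$log_bmi[is] + stats::rnorm(n, 0, 0.02)
  up_adl <- bern(0.05)
  st$adl_count[is] <- pmin(st$adl_count[is] + as.integer(up_adl), 3L)
  up_iadl <- bern(0.05)
  st$iadl_count[is] <- pmin(st$iadl_count[is] + as.integer(up_iadl), 2L)
  st
}

.wave_rows <- function(st, wave, score, alive, gap) {
  data.frame(
    person_id = st$person_id, age = st$age, male = st$male,
    race_ethnicity = st$race_ethnicity, education = st$education,
    heart_ever = st$heart_ever, stroke_ever = st$stroke_ever,
    cancer_ever = st$cancer_ever, hypertension_ever = st$hypertension_ever,
    diabetes_ever = st$diabetes_ever, lung_ever = st$lung_ever,
    chf_ever = st$chf_ever, heart_attack_2yr = st$heart_attack_2yr,
    working = st$working, widowed = st$widowed, smoke_ever = st$smoke_ever,
    log_bmi = st$log_bmi, smoke_current = st$smoke_current,
    adl_count = st$adl_count, iadl_count = st$iadl_count,
    heart50 = st$heart50, stroke50 = st$stroke50, cancer50 = st$cancer50,
    hypertension50 = st$hypertension50, diabetes50 = st$diabetes50,
    lung50 = st$lung50, smoke_ever50 = st$smoke_ever50,
    smoke_current50 = st$smoke_current50, weight = st$weight,
    wave = wave, calendar_year = 2006 + 2 * wave,
    tics27 = score, proxy = 0L, alive = alive,
    interview_gap_years = gap, stringsAsFactors = FALSE
  )
}

#' Apply MNAR proxy missingness to a panel
#'
#' Masks observed TICS27 scores with probability
#' `plogis(intercept + slope * true_score)` (lower scores more likely
#' missing under a negative slope, emulating proxy respondents whose
#' cognitive limitation prevents self-interview). A configurable share of
#' persons is never masked. The input is untouched; a modified copy is
#' returned with `proxy = 1` and `tics27 = NA` on masked rows.
#'
#' @param panel panel with fully observed `tics27` on alive rows.
#' @param params list with `intercept`, `slope_per_score_point`,
#'   `share_never_missing`.
#' @param seed integer seed for the masking draws.
#' @return the masked panel copy.
#' @export
apply_proxy_missingness <- function(panel, params, seed = 1L) {
  if (anyNA(panel$tics27[panel$alive == 1L])) {
    stop("tics27 must be fully observed before masking", call. = FALSE)
  }
  set.seed(seed)
  ids <- sort(unique(panel$person_id))
  never <- ids[stats::runif(length(ids)) < params$share_never_missing]
  eligible <- panel$alive == 1L & !(panel$person_id %in% never)
  p_miss <- stats::plogis(params$intercept +
                            params$slope_per_score_point * panel$tics27)
  mask <- eligible & !is.na(panel$tics27) &
    stats::runif(nrow(panel)) < p_miss
  out <- panel
  out$proxy[mask] <- 1L
  out$tics27[mask] <- NA_integer_
  out
}
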