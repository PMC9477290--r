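#' Design specification for the transition models
#'
#' Names the covariate rows of the two transition models and the spline
#' knots: the TICS27 ordered probit uses an age spline with knots at 65 and
#' 75; the mortality probit adds a knot at 85; both BMI terms split at
#' BMI 30 on the log scale.
#'
#' @return a list with elements `tics` and `mortality` (each with
#'   `covariates` and `age_knots`) and `bmi_knot`.
#' @export
design_spec <- function() {
  spec <- list(
    tics = list(covariates = names(fem_tics27_coefs()$coef),
                age_knots = c(65, 75)),
    mortality = list(covariates = names(fem_mortality_coefs()$coef),
                     age_knots = c(65, 75, 85)),
    bmi_knot = log(30)
  )
  for (m in c("tics", "mortality")) {
    if (anyDuplicated(spec[[m]]$covariates)) {
      stop("duplicate covariate names in ", m, " design", call. = FALSE)
    }
    if (any(diff(spec[[m]]$age_knots) <= 0)) {
      stop("age knots must be strictly increasing", call. = FALSE)
    }
  }
  spec
}

# raw per-transition columns expected by build_design (values at the lag
# wave, except delta_age and the outcome)
.raw_cols <- c(
  "age", "male", "race_ethnicity", "education", "heart_ever", "stroke_ever",
  "cancer_ever", "hypertension_ever", "diabetes_ever", "lung_ever",
  "chf_ever", "heart_attack_2yr", "working", "widowed", "smoke_ever",
  "smoke_current", "log_bmi", "adl_count", "iadl_count", "heart50",
  "stroke50", "cancer50", "hypertension50", "diabetes50", "lung50",
  "smoke_ever50", "smoke_current50", "delta_age", "verified_ever",
  "lag2_tics", "lag4_tics"
)

#' Build a transition-model design matrix
#'
#' Assembles the covariate matrix for one of the two transition models from
#' a raw per-transition data frame (one row per person-wave, covariates
#' measured at the wave preceding the transition). Spline expansions and
#' race/education dummies (reference: non-Hispanic white, high school) are
#' constructed here so estimation, simulation and the synthetic truth all
#' share one definition.
#'
#' @param raw data frame of raw covariates; see Details for required columns.
#' @param model `"tics"` or `"mortality"`.
#' @param spec a [design_spec()].
#' @return numeric matrix whose columns match `spec[[model]]$covariates`.
#' @details Required columns: `age`, `male`, `race_ethnicity`
#'   (`nh_white`/`nh_black`/`hispanic`), `education`
#'   (`lt_hs`/`hs`/`some_college`), the chronic-condition `_ever` flags,
#'   `heart_attack_2yr`, `working`, `widowed`, `smoke_ever`, `smoke_current`,
#'   `log_bmi`, `adl_count` (0/1/2/3 = 3+), `iadl_count` (0/1/2 = 2+), the
#'   by-age-50 history flags, `delta_age`, `verified_ever`, and for the TICS
#'   model `lag2_tics`, `lag4_tics`.
#' @export
build_design <- function(raw, model = c("tics", "mortality"),
                         spec = design_spec()) {
  model <- match.arg(model)
  need <- if (model == "tics") .raw_cols else
    setdiff(.raw_cols, c("lag2_tics", "lag4_tics"))
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("missing covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (cl in need) {
    if (anyNA(raw[[cl]])) {
      i <- which(is.na(raw[[cl]]))[1L]
      stop("missing value in '", cl, "'",
           if (!is.null(raw$person_id)) paste0(" for person ",
                                               raw$person_id[i]),
           if (!is.null(raw$wave)) paste0(" at wave ", raw$wave[i]),
           call. = FALSE)
    }
  }
  ag <- age_spline_basis(raw$age, spec[[model]]$age_knots)
  bm <- bmi_spline_basis(raw$log_bmi)
  n <- nrow(raw)
  X <- cbind(
    lag2_tics = if (model == "tics") raw$lag2_tics,
    lag4_tics = if (model == "tics") raw$lag4_tics,
    nh_black = as.numeric(raw$race_ethnicity == "nh_black"),
    hispanic = as.numeric(raw$race_ethnicity == "hispanic"),
    lt_hs = as.numeric(raw$education == "lt_hs"),
    some_college = as.numeric(raw$education == "some_college"),
    male = as.numeric(raw$male),
    age_to_65 = ag[, 1L],
    age_65_75 = ag[, 2L],
    age_75_85 = if (model == "mortality") ag[, 3L],
    age_over_75 = if (model == "tics") ag[, 3L],
    age_over_85 = if (model == "mortality") ag[, 4L],
    heart_ever = as.numeric(raw$heart_ever),
    stroke_ever = as.numeric(raw$stroke_ever),
    cancer_ever = as.numeric(raw$cancer_ever),
    hypertension_ever = as.numeric(raw$hypertension_ever),
    diabetes_ever = as.numeric(raw$diabetes_ever),
    lung_ever = as.numeric(raw$lung_ever),
    heart_attack_2yr = as.numeric(raw$heart_attack_2yr),
    working = if (model == "tics") as.numeric(raw$working),
    widowed = as.numeric(raw$widowed),
    smoke_ever = if (model == "tics") as.numeric(raw$smoke_ever),
    verified_ever = if (model == "tics") as.numeric(raw$verified_ever),
    delta_age = if (model == "tics") raw$delta_age,
    lbmi_below30 = if (model == "tics") bm[, 1L],
    lbmi_above30 = if (model == "tics") bm[, 2L],
    iadl_1 = if (model == "mortality") as.numeric(raw$iadl_count == 1),
    iadl_2p = if (model == "mortality") as.numeric(raw$iadl_count >= 2),
    adl_1 = if (model == "mortality") as.numeric(raw$adl_count == 1),
    adl_2 = if (model == "mortality") as.numeric(raw$adl_count == 2),
    adl_3p = if (model == "mortality") as.numeric(raw$adl_count >= 3),
    smoke_current = if (model == "mortality") as.numeric(raw$smoke_current),
    heart50 = if (model == "mortality") as.numeric(raw$heart50),
    stroke50 = if (model == "mortality") as.numeric(raw$stroke50),
    cancer50 = if (model == "mortality") as.numeric(raw$cancer50),
    hypertension50 = if (model == "mortality")
      as.numeric(raw$hypertension50),
    diabetes50 = if (model == "mortality") as.numeric(raw$diabetes50),
    lung50 = if (model == "mortality") as.numeric(raw$lung50),
    smoke_ever50 = if (model == "mortality") as.numeric(raw$smoke_ever50),
    smoke_current50 = if (model == "mortality")
      as.numeric(raw$smoke_current50),
    chf_ever = if (model == "mortality") as.numeric(raw$chf_ever)
  )
  X[, spec[[model]]$covariates, drop = FALSE]
}

#' Extract transition rows from a long panel
#'
#' Turns a long person-by-wave panel into the per-transition estimation
#' frames for the two models. TICS27 transitions require three consecutive
#' observed waves (outcome wave plus the two lag waves, all scores observed,
#' person alive at the outcome wave); mortality transitions require the lag
#' wave plus either a survival row or a death row at the next wave. The
#' verified-ever covariate is the status knowable at the lag wave.
#'
#' @param panel a panel data frame.
#' @param model `"tics"` or `"mortality"`.
#' @return raw data frame suitable for [build_design()], with columns
#'   `person_id`, `wave` (outcome wave), `outcome` (score, or 1 = died) and
#'   `weight` added.
#' @export
transition_rows <- function(panel, model = c("tics", "mortality")) {
  model <- match.arg(model)
  panel <- add_cognition_columns(panel, timing = "known")
  panel <- panel[order(panel$person_id, panel$wave), , drop = FALSE]
  panel$verified_ever <- as.integer(!is.na(panel$verified_status) &
                                      panel$verified_status != "normal")
  n <- nrow(panel)
  prev <- function(i, k) {  # TRUE when row i - k is the same person, k waves back
    j <- i - k
    ok <- j >= 1L
    ok[ok] <- panel$person_id[j[ok]] == panel$person_id[i[ok]] &
      panel$wave[j[ok]] == panel$wave[i[ok]] - k
    ok
  }
  i <- seq_len(n)
  if (model == "mortality") {
    # outcome waves start at 1: the baseline wave is conditioned alive and
    # the pre-baseline wave exists only to supply lag scores
    keep <- i[prev(i, 1L) & panel$alive[pmax(i - 1L, 1L)] == 1L &
                panel$wave >= 1L]
  } else {
    keep <- i[prev(i, 1L) & prev(i, 2L) & panel$alive == 1L &
                !is.na(panel$tics27)]
    keep <- keep[panel$alive[keep - 1L] == 1L &
                   !is.na(panel$tics27[keep - 1L]) &
                   !is.na(panel$tics27[keep - 2L])]
  }
  out <- panel[keep - 1L, c("person_id", .setdiff_raw(), "weight")]
  out$delta_age <- panel$interview_gap_years[keep] - 2
  out$wave <- panel$wave[keep]
  if (model == "mortality") {
    out$outcome <- 1L - panel$alive[keep]
  } else {
    out$lag2_tics <- panel$tics27[keep - 1L]
    out$lag4_tics <- panel$tics27[keep - 2L]
    out$outcome <- panel$tics27[keep]
  }
  rownames(out) <- NULL
  out
}

# panel columns copied from the lag wave into the raw transition frame
.setdiff_raw <- function() {
  c("age", "male", "race_ethnicity", "education", "heart_ever",
    "stroke_ever", "cancer_ever", "hypertension_ever", "diabetes_ever",
    "lung_ever", "chf_ever", "heart_attack_2yr", "working", "widowed",
    "smoke_ever", "smoke_current", "log_bmi", "adl_count", "iadl_count",
    "heart50", "stroke50", "cancer50", "hypertension50", "diabetes50",
    "lung50", "smoke_ever50", "smoke_current50", "verified_ever")
}
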