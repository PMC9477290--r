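#' Reference coefficients of the FEM TICS27 transition model
#'
#' Coefficient estimates (with standard errors) reported for the Future
#' Elderly Model's biennial TICS27 transition model, an ordered probit fitted
#' to Health and Retirement Study data. These serve two purposes: as a
#' realistic latent-index truth for the synthetic cohort generator, and as
#' the seed values for the parameter-recovery experiments.
#'
#' Covariate naming: `lag2_tics`/`lag4_tics` are the scores two and four
#' years prior; `age_to_65`, `age_65_75`, `age_over_75` the piecewise-linear
#' age spline slopes; `lbmi_below30`/`lbmi_above30` the lagged log-BMI spline;
#' `verified_ever` the absorbing verified-MCI-or-dementia indicator;
#' `delta_age` the deviation of the interview gap from the nominal two years.
#' Reference categories are non-Hispanic white and high-school education.
#'
#' @return named list with `coef` (named numeric vector) and `se`.
#' @seealso [fem_mortality_coefs()], [default_true_models()]
#' @export
fem_tics27_coefs <- function() {
  coef <- c(
    lag2_tics         =  0.0915,
    lag4_tics         =  0.0955,
    nh_black          = -0.2343,
    hispanic          = -0.1502,
    lt_hs             = -0.1361,
    some_college      =  0.1967,
    male              = -0.0884,
    age_to_65         = -0.0009,
    age_65_75         = -0.0173,
    age_over_75       = -0.0353,
    heart_ever        = -0.0126,
    stroke_ever       = -0.1288,
    cancer_ever       =  0.0008,
    hypertension_ever = -0.0355,
    diabetes_ever     = -0.0693,
    lung_ever         = -0.0430,
    heart_attack_2yr  = -0.0750,
    working           =  0.0943,
    widowed           = -0.0298,
    smoke_ever        = -0.0426,
    verified_ever     = -0.7105,
    delta_age         = -0.1374,
    lbmi_below30      =  0.1314,
    lbmi_above30      = -0.0090
  )
  se <- c(0.0015, 0.0017, 0.0116, 0.0144, 0.0131, 0.0092, 0.0086, 0.0013,
          0.0015, 0.0013, 0.0108, 0.0165, 0.0117, 0.0088, 0.0105, 0.0147,
          0.0334, 0.0100, 0.0121, 0.0083, 0.0155, 0.0208, 0.0350, 0.0441)
  names(se) <- names(coef)
  list(coef = coef, se = se)
}

#' Reference coefficients of the FEM two-year mortality transition model
#'
#' Probit coefficients reported for the Future Elderly Model's biennial
#' mortality model (age spline knots at 65, 75 and 85; ADL/IADL difficulty
#' categories; chronic-condition and by-age-50 history indicators). The
#' published table carries no intercept; mortality level is set by a
#' calibrated intercept wherever these coefficients are used as a
#' data-generating truth (see [default_true_models()]).
#'
#' @return named list with `coef` (named numeric vector) and `se`.
#' @export
fem_mortality_coefs <- function() {
  coef <- c(
    nh_black          =  0.0028,
    hispanic          = -0.0094,
    lt_hs             = -0.0002,
    some_college      = -0.0072,
    male              =  0.0177,
    age_to_65         =  0.0025,
    age_65_75         =  0.0029,
    age_75_85         =  0.0040,
    age_over_85       =  0.0067,
    heart_ever        =  0.0131,
    stroke_ever       =  0.0110,
    cancer_ever       =  0.0334,
    hypertension_ever =  0.0097,
    diabetes_ever     =  0.0155,
    lung_ever         =  0.0294,
    heart_attack_2yr  =  0.0049,
    widowed           =  0.0055,
    iadl_1            =  0.0162,
    iadl_2p           =  0.0483,
    adl_1             =  0.0222,
    adl_2             =  0.0342,
    adl_3p            =  0.0603,
    smoke_current     =  0.0187,
    heart50           =  0.0051,
    stroke50          = -0.0107,
    cancer50          = -0.0083,
    hypertension50    =  0.0027,
    diabetes50        =  0.0142,
    lung50            = -0.0278,
    smoke_ever50      =  0.0061,
    smoke_current50   =  0.0174,
    chf_ever          =  0.0259
  )
  se <- c(0.0023, 0.0031, 0.0022, 0.0019, 0.0019, 0.0004, 0.0003, 0.0003,
          0.0004, 0.0020, 0.0023, 0.0020, 0.0019, 0.0020, 0.0023, 0.0047,
          0.0022, 0.0028, 0.0031, 0.0025, 0.0033, 0.0028, 0.0027, 0.0067,
          0.0167, 0.0057, 0.0042, 0.0034, 0.1480, 0.0022, 0.0024, 0.0028)
  names(se) <- names(coef)
  list(coef = coef, se = se)
}

#' Default cutpoints for the synthetic latent TICS27 process
#'
#' Evenly spaced cutpoints `(j - 13.5) / 4` for `j = 0..26`, i.e. one latent
#' standard deviation spans four score points and the grid is centered on the
#' middle of the 0-27 scale. Used as the data-generating truth; fitted models
#' estimate their own free cutpoints.
#'
#' @return numeric vector of 27 strictly increasing cutpoints.
#' @export
default_cutpoints <- function() (0:26 - 13.5) / 4
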