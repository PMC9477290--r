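#' Piecewise-linear age spline basis
#'
#' Expands age into the piecewise-linear ("hockey-stick") basis used by the
#' biennial transition models: the first element is age capped at the first
#' knot, interior elements are the years accumulated between consecutive
#' knots, and the last element is the years beyond the final knot. The TICS27
#' model uses knots at ages 65 and 75; the mortality model adds a knot at 85.
#'
#' @param age numeric vector of ages in years (> 0).
#' @param knots strictly increasing numeric vector of knot ages.
#' @return a numeric matrix with `length(knots) + 1` columns, one row per age.
#' @examples
#' age_spline_basis(70, c(65, 75))        # 65, 5, 0
#' age_spline_basis(90, c(65, 75, 85))    # 65, 10, 10, 5
#' @export
age_spline_basis <- function(age, knots) {
  if (any(!is.finite(age)) || any(age <= 0)) {
    stop("age must be positive and finite", call. = FALSE)
  }
  if (length(knots) < 1L || any(diff(knots) <= 0)) {
    stop("knots must be strictly increasing", call. = FALSE)
  }
  k <- length(knots)
  out <- matrix(0, length(age), k + 1L)
  out[, 1L] <- pmin(age, knots[1L])
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      out[, i + 1L] <- pmin(pmax(age - knots[i], 0), knots[i + 1L] - knots[i])
    }
  }
  out[, k + 1L] <- pmax(age - knots[k], 0)
  colnames(out) <- c(
    paste0("age_to_", knots[1L]),
    if (k > 1L) paste0("age_", knots[-k], "_", knots[-1L]),
    paste0("age_over_", knots[k])
  )
  out
}

#' Log body-mass-index spline basis with a knot at BMI 30
#'
#' Splits log BMI at log(30) (the obesity threshold): the first column is
#' log BMI capped at log(30), the second the excess above it. Matches the
#' "lag log BMI below/above 30" terms of the TICS27 transition model.
#'
#' @param log_bmi numeric vector of log body-mass-index values.
#' @return numeric matrix with columns `lbmi_below30`, `lbmi_above30`.
#' @export
bmi_spline_basis <- function(log_bmi) {
  if (any(!is.finite(log_bmi))) stop("log_bmi must be finite", call. = FALSE)
  k <- log(30)
  cbind(lbmi_below30 = pmin(log_bmi, k), lbmi_above30 = pmax(log_bmi - k, 0))
}
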