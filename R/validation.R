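# Validation framework: k-fold cross-validated estimation + simulation,
# weighted score-distribution comparison, 10-year cognitive/mortality
# transition matrices, and AUROC on replicate-fraction risk scores.

#' Fit both transition models on a panel
#'
#' Extracts the per-transition estimation rows (see [transition_rows()]) and
#' fits the TICS27 ordered probit and the mortality probit by unweighted
#' maximum likelihood (survey weights enter only population-level
#' summaries).
#'
#' @param panel a long panel data frame.
#' @param spec a [design_spec()].
#' @return list of class `"transition_fits"` with elements `tics` and
#'   `mortality`.
#' @export
fit_transition_models <- function(panel, spec = design_spec()) {
  rt <- transition_rows(panel, "tics")
  rm_ <- transition_rows(panel, "mortality")
  tics <- fit_ordered_probit(rt$outcome, build_design(rt, "tics", spec))
  mortality <- fit_probit(rm_$outcome, build_design(rm_, "mortality", spec))
  structure(list(tics = tics, mortality = mortality),
            class = "transition_fits")
}

#' @export
print.transition_fits <- function(x, ...) {
  cat("TICS27 transition model:\n")
  print(x$tics)
  cat("\nMortality transition model:\n")
  print(x$mortality)
  invisible(x)
}

#' Random k-fold partition of person ids
#'
#' @param person_ids vector of unique ids.
#' @param k number of folds (>= 2, <= number of ids).
#' @param seed integer seed.
#' @return named integer vector mapping each id to a fold in `0..k-1`; fold
#'   sizes differ by at most one.
#' @export
kfold_split <- function(person_ids, k = 5L, seed = 1L) {
  n <- length(person_ids)
  if (anyDuplicated(person_ids)) stop("person_ids must be unique",
                                      call. = FALSE)
  if (k < 2L || k > n) stop("k must be in [2, #ids]", call. = FALSE)
  set.seed(seed)
  fold <- sample(rep(seq_len(k) - 1L, length.out = n))
  names(fold) <- as.character(person_ids)
  fold
}

#' Cross-validated estimation and simulation
#'
#' For each fold, fits both transition models on the other k-1 folds and
#' simulates the held-out persons from their baseline, so every person is
#' simulated exactly once by models that never saw them; held-out outcomes
#' are pooled.
#'
#' @param panel long panel (waves -1..horizon) providing both estimation
#'   transitions and the baseline.
#' @param k number of folds (default 5).
#' @param config a [sim_config()].
#' @param fold_seed seed for the random partition.
#' @param spec a [design_spec()].
#' @return list with pooled `outcomes` (`"replicate_outcomes"`), per-fold
#'   `fits`, and the `folds` assignment.
#' @export
cross_validated_simulate <- function(panel, k = 5L, config = sim_config(),
                                     fold_seed = 1L, spec = design_spec()) {
  ids <- sort(unique(panel$person_id[panel$wave == 0L]))
  folds <- kfold_split(ids, k, fold_seed)
  fits <- vector("list", k)
  outs <- vector("list", k)
  for (f in seq_len(k) - 1L) {
    test_ids <- ids[folds[as.character(ids)] == f]
    train <- panel[!(panel$person_id %in% test_ids), , drop = FALSE]
    fits[[f + 1L]] <- tryCatch(
      fit_transition_models(train, spec),
      error = function(e) stop("estimation failed in fold ", f, ": ",
                               conditionMessage(e), call. = FALSE))
    base <- panel[panel$person_id %in% test_ids & panel$wave %in%
                    c(-1L, 0L), , drop = FALSE]
    cfg_f <- config
    cfg_f$base_seed <- config$base_seed + f
    outs[[f + 1L]] <- simulate_cohort(base, fits[[f + 1L]], cfg_f)
  }
  list(outcomes = .concat_outcomes(outs), fits = fits, folds = folds)
}

.concat_outcomes <- function(lst) {
  H <- lst[[1L]]$horizon
  R <- lst[[1L]]$replicates
  n <- sum(vapply(lst, function(o) length(o$person_id), 1L))
  bindm <- function(f) do.call(rbind, lapply(lst, `[[`, f))
  tics <- array(NA_integer_, c(n, H, R))
  at <- 0L
  for (o in lst) {
    ni <- length(o$person_id)
    tics[at + seq_len(ni), , ] <- o$tics
    at <- at + ni
  }
  structure(list(
    tics = tics, death_wave = bindm("death_wave"),
    status_at_death = bindm("status_at_death"),
    dem_attain = bindm("dem_attain"), mci_attain = bindm("mci_attain"),
    person_id = unlist(lapply(lst, `[[`, "person_id")),
    weight = unlist(lapply(lst, `[[`, "weight")),
    baseline_score = unlist(lapply(lst, `[[`, "baseline_score")),
    baseline_verified = unlist(lapply(lst, `[[`, "baseline_verified")),
    horizon = H, replicates = R, base_seed = lst[[1L]]$base_seed
  ), class = "replicate_outcomes")
}

#' Weighted percentiles of a score distribution
#'
#' Left-continuous inverse of the weighted empirical CDF (the type-1
#' quantile generalized to weights): the reported value is the smallest
#' observation at which the normalized cumulative weight reaches the target
#' probability. Integer inputs therefore yield integer outputs.
#'
#' @param values numeric vector.
#' @param weights positive weights.
#' @param probs probabilities (default the nine standard report percentiles
#'   1, 5, 10, 25, 50, 75, 90, 95, 99 plus the weighted mean as `mean`).
#' @return list of class `"distribution_summary"`: `percentiles` (named
#'   vector) and `mean`.
#' @export
weighted_percentiles <- function(values, weights = rep(1, length(values)),
                                 probs = c(0.01, 0.05, 0.10, 0.25, 0.50,
                                           0.75, 0.90, 0.95, 0.99)) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (length(weights) != length(values) || any(weights <= 0) ||
      anyNA(weights)) {
    stop("weights must be positive and match values", call. = FALSE)
  }
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o]) / sum(weights)
  idx <- vapply(probs, function(p) which(cw >= p - 1e-9)[1L], integer(1))
  pct <- v[idx]
  names(pct) <- paste0("p", probs * 100)
  q <- sum(values * weights) / sum(weights)
  structure(list(percentiles = pct, mean = q), class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  print(c(x$percentiles, mean = round(x$mean, 2)))
  invisible(x)
}

.tm_cols <- c("normal", "mci", "dementia", "dead_without_dementia",
              "dead_with_dementia")

#' Cognitive/mortality status transition matrix
#'
#' Weighted percent of the total population in each (baseline status, final
#' outcome) cell, the composite cognition-plus-mortality summary of a
#' ten-year projection. Rows: baseline normal/MCI/dementia. Columns: final
#' normal/MCI/dementia/dead without dementia/dead with dementia. The
#' absorbing verification rules make some cells structurally zero (MCI
#' cannot revert to normal; baseline dementia can only stay dementia or die
#' with dementia); mass in such a cell signals inconsistent inputs and is an
#' error.
#'
#' @param baseline_status severity codes 0/1/2 (or `"normal"`/`"mci"`/
#'   `"dementia"`) at baseline.
#' @param final_outcome final codes among `"normal"`, `"mci"`, `"dementia"`,
#'   `"dead_without_dementia"`, `"dead_with_dementia"`.
#' @param weights positive person weights (each person's weight may be
#'   split over replicates by the caller).
#' @return 3 x 5 matrix of percentages summing to 100.
#' @export
status_transition_matrix <- function(baseline_status, final_outcome,
                                     weights = rep(1,
                                                   length(baseline_status))) {
  bl <- if (is.numeric(baseline_status)) {
    c("normal", "mci", "dementia")[baseline_status + 1L]
  } else as.character(baseline_status)
  fo <- as.character(final_outcome)
  if (!all(bl %in% .tm_cols[1:3]) || !all(fo %in% .tm_cols)) {
    stop("invalid status codes", call. = FALSE)
  }
  M <- matrix(0, 3L, 5L, dimnames = list(.tm_cols[1:3], .tm_cols))
  agg <- tapply(weights, list(factor(bl, .tm_cols[1:3]),
                              factor(fo, .tm_cols)), sum)
  agg[is.na(agg)] <- 0
  M[] <- agg
  M <- 100 * M / sum(M)
  bad <- M["mci", "normal"] > 0 ||
    any(M["dementia", c("normal", "mci", "dead_without_dementia")] > 0)
  if (bad) {
    stop("inconsistent status sequences: mass in a structurally zero cell",
         call. = FALSE)
  }
  M
}

#' ROC curve and AUROC for a risk score
#'
#' Threshold sweep over the distinct risk values, with the area computed by
#' the trapezoidal rule (equivalently, the probability that a random case
#' outranks a random control, ties counted one half).
#'
#' @param risks numeric risk scores.
#' @param outcomes 0/1 observed outcomes.
#' @return list of class `"roc_result"`: `points` (data frame `fpr`, `tpr`
#'   from (0,0) to (1,1)), `auroc`, `n_cases`, `n_controls`.
#' @export
roc_auc <- function(risks, outcomes) {
  keep <- !is.na(risks) & !is.na(outcomes)
  risks <- risks[keep]
  outcomes <- outcomes[keep]
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be 0/1",
                                        call. = FALSE)
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("AUROC undefined: need at least one case and one control",
         call. = FALSE)
  }
  o <- order(risks, decreasing = TRUE)
  r <- risks[o]
  y <- outcomes[o]
  last <- !duplicated(r, fromLast = TRUE)   # end of each tie group
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  tpr <- c(0, tp / n1, 1)
  fpr <- c(0, fp / n0, 1)
  keep_pt <- !duplicated(cbind(fpr, tpr))
  pts <- data.frame(fpr = fpr[keep_pt], tpr = tpr[keep_pt])
  auroc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                  utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auroc = auroc, n_cases = n1,
                 n_controls = n0), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("AUROC:", format(x$auroc, digits = 4), "(", x$n_cases, "cases /",
      x$n_controls, "controls )\n")
  invisible(x)
}

#' Observed person-level outcomes from a panel
#'
#' Collapses an observed panel to one row per baseline person: death wave
#' and severity at death, first waves at which verified MCI/dementia are in
#' force (two-wave rules, death-confirmed, dated at the first wave of the
#' confirming pair), baseline score and verified severity (from the
#' pre-baseline pair), first projected-wave score, and a full-follow-up flag
#' (a row at every wave through the horizon or death).
#'
#' @param panel observed long panel including waves -1 and 0.
#' @param horizon last wave of interest (default the panel maximum).
#' @return data frame keyed by `person_id`.
#' @export
observed_outcomes <- function(panel, horizon = max(panel$wave)) {
  eff <- add_cognition_columns(panel, timing = "effective")
  # baseline status uses only the information available at baseline
  # (pre-baseline pair), matching the state the simulator starts from
  known <- add_cognition_columns(panel[panel$wave <= 0L, , drop = FALSE],
                                 timing = "known")
  sp_e <- split(eff, eff$person_id)
  ids <- as.numeric(names(sp_e))
  k0 <- known[known$wave == 0L, ]
  base_ver <- (match(k0$verified_status, .status_labels) - 1L)[
    match(ids, k0$person_id)]
  out <- data.frame(person_id = ids)
  g <- function(f) vapply(sp_e, f, numeric(1))
  out$weight <- g(function(d) d$weight[1L])
  out$baseline_score <- g(function(d) {
    s <- d$tics27[d$wave == 0L]
    if (length(s)) as.numeric(s) else NA_real_
  })
  out$baseline_verified <- base_ver
  out$death_wave <- g(function(d) {
    w <- d$wave[d$alive == 0L]
    if (length(w)) as.numeric(w[1L]) else NA_real_
  })
  out$status_at_death <- g(function(d) {
    if (!any(d$alive == 0L)) return(NA_real_)
    al <- d[d$alive == 1L, ]
    if (!nrow(al)) return(0)
    traj <- c(al$category, "death")
    as.numeric(match(status_at_death(traj), .status_labels) - 1L)
  })
  attain <- function(d, lvl) {
    sev <- match(d$verified_status, .status_labels) - 1L
    w <- d$wave[!is.na(sev) & sev >= lvl]
    if (length(w)) as.numeric(min(w)) else NA_real_
  }
  out$mci_attain <- g(function(d) attain(d, 1L))
  out$dem_attain <- g(function(d) attain(d, 2L))
  # death can confirm severity never reflected in a wave status
  sad <- out$status_at_death
  dw <- out$death_wave
  upd <- !is.na(sad) & sad >= 1 & (is.na(out$mci_attain) |
                                     out$mci_attain > dw - 1)
  out$mci_attain[upd] <- pmin(out$mci_attain[upd], dw[upd] - 1, na.rm = TRUE)
  upd <- !is.na(sad) & sad >= 2 & (is.na(out$dem_attain) |
                                     out$dem_attain > dw - 1)
  out$dem_attain[upd] <- pmin(out$dem_attain[upd], dw[upd] - 1, na.rm = TRUE)
  out$score_w1 <- g(function(d) {
    s <- d$tics27[d$wave == 1L & d$alive == 1L]
    if (length(s) && !is.na(s[1L])) as.numeric(s[1L]) else NA_real_
  })
  out$full_followup <- vapply(sp_e, function(d) {
    w <- d$wave[d$wave >= 0L]
    last <- if (any(d$alive == 0L)) d$wave[d$alive == 0L][1L] else horizon
    all(seq(0L, min(last, horizon)) %in% w)
  }, logical(1))
  rownames(out) <- NULL
  out
}

# final-outcome code (among .tm_cols) at a horizon wave, observed side
.observed_final <- function(truth, horizon) {
  dead <- !is.na(truth$death_wave) & truth$death_wave <= horizon
  sev <- ifelse(!is.na(truth$dem_attain) & truth$dem_attain <= horizon, 2L,
                ifelse(!is.na(truth$mci_attain) &
                         truth$mci_attain <= horizon, 1L, 0L))
  ifelse(dead,
         ifelse(!is.na(truth$status_at_death) & truth$status_at_death >= 2,
                "dead_with_dementia", "dead_without_dementia"),
         .tm_cols[sev + 1L])
}

#' Evaluate simulated outcomes against an observed panel
#'
#' Produces the three population- and individual-level validation summaries:
#' weighted TICS27 distribution comparison at the horizon (baseline,
#' observed, simulated; overall and for the 65+-at-baseline subgroup),
#' cognitive/mortality transition matrices on the full-follow-up sample
#' (observed and simulated, conditioned on the same baseline verified
#' status), and AUROCs of the replicate-fraction risks against observed
#' outcomes for each predicate, subgroup and horizon.
#'
#' @param panel observed panel (the truth).
#' @param outcomes `"replicate_outcomes"` for the same persons (e.g. pooled
#'   cross-validated simulations).
#' @param horizons waves at which dementia-prediction AUROCs are computed
#'   (default the simulated horizon; the Table-6-style sweep passes
#'   `1:horizon`).
#' @param subgroups named list of person-id vectors; defaults to the full
#'   sample plus baseline verified-MCI, age-65+, race/ethnicity, education
#'   and disease-history groups.
#' @return list of class `"validation_report"` with `distribution`,
#'   `transition` and `auroc` entries.
#' @export
evaluate_simulation <- function(panel, outcomes,
                                horizons = outcomes$horizon,
                                subgroups = NULL) {
  H <- outcomes$horizon
  if (any(horizons < 1L | horizons > H)) {
    stop("horizon beyond the simulated waves", call. = FALSE)
  }
  truth <- observed_outcomes(panel, horizon = H)
  m <- match(outcomes$person_id, truth$person_id)
  if (anyNA(m)) stop("simulated persons missing from the panel",
                     call. = FALSE)
  truth <- truth[m, , drop = FALSE]
  b0 <- panel[panel$wave == 0L, ]
  b0 <- b0[match(outcomes$person_id, b0$person_id), ]
  if (is.null(subgroups)) {
    id <- outcomes$person_id
    subgroups <- list(
      full_sample = id,
      verified_mci_baseline = id[truth$baseline_verified == 1L],
      age_65_plus = id[b0$age >= 65],
      nh_white = id[b0$race_ethnicity == "nh_white"],
      nh_black = id[b0$race_ethnicity == "nh_black"],
      hispanic = id[b0$race_ethnicity == "hispanic"],
      lt_hs = id[b0$education == "lt_hs"],
      hs = id[b0$education == "hs"],
      some_college = id[b0$education == "some_college"],
      diabetes_baseline = id[b0$diabetes_ever == 1L],
      stroke_baseline = id[b0$stroke_ever == 1L],
      hypertension_baseline = id[b0$hypertension_ever == 1L],
      heart_baseline = id[b0$heart_ever == 1L]
    )
  }
  ff <- truth$full_followup

  # --- distribution comparison at the final horizon ---------------------
  sim_final <- matrix(outcomes$tics[, H, ], nrow = length(outcomes$person_id))
  dist_row <- function(keep) {
    pan_keep <- panel$person_id %in% outcomes$person_id[keep]
    base <- panel[pan_keep & panel$wave == 0L & !is.na(panel$tics27), ]
    obs <- panel[pan_keep & panel$wave == H & panel$alive == 1L &
                   !is.na(panel$tics27), ]
    sv <- sim_final[keep, , drop = FALSE]
    sw <- matrix(outcomes$weight[keep], nrow(sv), ncol(sv))
    ok <- !is.na(sv)
    list(baseline = weighted_percentiles(base$tics27, base$weight),
         observed = weighted_percentiles(obs$tics27, obs$weight),
         simulated = weighted_percentiles(sv[ok], sw[ok]))
  }
  all_keep <- rep(TRUE, length(outcomes$person_id))
  distribution <- list(all = dist_row(all_keep),
                       age_65_plus = dist_row(b0$age >= 65))

  # --- transition matrices (full-follow-up persons) ---------------------
  base_sev <- truth$baseline_verified
  obs_final <- .observed_final(truth, H)
  observed_tm <- status_transition_matrix(base_sev[ff], obs_final[ff],
                                          truth$weight[ff])
  R <- outcomes$replicates
  sim_dead <- !is.na(outcomes$death_wave) & outcomes$death_wave <= H
  sim_sev <- ifelse(!is.na(outcomes$dem_attain) & outcomes$dem_attain <= H,
                    2L,
                    ifelse(!is.na(outcomes$mci_attain) &
                             outcomes$mci_attain <= H, 1L, 0L))
  sim_final_code <- ifelse(
    sim_dead,
    ifelse(outcomes$status_at_death >= 2L, "dead_with_dementia",
           "dead_without_dementia"),
    .tm_cols[sim_sev + 1L])
  bl_rep <- matrix(base_sev, length(base_sev), R)
  w_rep <- matrix(truth$weight / R, length(base_sev), R)
  simulated_tm <- status_transition_matrix(bl_rep[ff, ],
                                           sim_final_code[ff, ],
                                           w_rep[ff, ])
  transition <- list(observed = observed_tm, simulated = simulated_tm)

  # --- AUROC tables -----------------------------------------------------
  rows <- list()
  for (sg in names(subgroups)) {
    in_sg <- outcomes$person_id %in% subgroups[[sg]] & ff
    for (h in horizons) {
      alive_h <- is.na(truth$death_wave) | truth$death_wave > h
      specs <- list(
        dementia_or_dead_with_dementia = list(
          risk = risk_fraction(outcomes, "dementia_or_dead_with_dementia",
                               h),
          y = as.integer((!is.na(truth$dem_attain) &
                            truth$dem_attain <= h) |
                           (!alive_h & !is.na(truth$status_at_death) &
                              truth$status_at_death >= 2)),
          keep = in_sg),
        dementia_given_alive = list(
          risk = risk_fraction(outcomes, "dementia_given_alive", h),
          y = as.integer(!is.na(truth$dem_attain) & truth$dem_attain <= h),
          keep = in_sg & alive_h),
        mci_or_worse_or_dead_with_mci_or_worse = list(
          risk = risk_fraction(outcomes,
                               "mci_or_worse_or_dead_with_mci_or_worse", h),
          y = as.integer((!is.na(truth$mci_attain) &
                            truth$mci_attain <= h) |
                           (!is.na(truth$dem_attain) &
                              truth$dem_attain <= h) |
                           (!alive_h & !is.na(truth$status_at_death) &
                              truth$status_at_death >= 1)),
          keep = in_sg),
        mci_or_worse_given_alive = list(
          risk = risk_fraction(outcomes, "mci_or_worse_given_alive", h),
          y = as.integer((!is.na(truth$mci_attain) &
                            truth$mci_attain <= h) |
                           (!is.na(truth$dem_attain) &
                              truth$dem_attain <= h)),
          keep = in_sg & alive_h)
      )
      if (h == 1L) {
        specs$significant_decline_2yr <- list(
          risk = risk_fraction(outcomes, "significant_decline_2yr", 1L),
          y = as.integer(!is.na(truth$score_w1) &
                           truth$score_w1 <= truth$baseline_score - 3),
          keep = in_sg & truth$baseline_verified == 1L &
            !is.na(truth$score_w1))
      }
      for (pr in names(specs)) {
        sp <- specs[[pr]]
        keep <- sp$keep & !is.na(sp$risk)
        if (sum(sp$y[keep] == 1) == 0 || sum(sp$y[keep] == 0) == 0) next
        rc <- roc_auc(sp$risk[keep], sp$y[keep])
        rows[[length(rows) + 1L]] <- data.frame(
          subgroup = sg, horizon = h, predicate = pr, auroc = rc$auroc,
          n = sum(keep), n_cases = rc$n_cases, stringsAsFactors = FALSE)
      }
    }
  }
  auroc <- do.call(rbind, rows)
  structure(list(distribution = distribution, transition = transition,
                 auroc = auroc, horizons = horizons),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report\n\nTransition matrix (observed, % of total):\n")
  print(round(x$transition$observed, 1))
  cat("\nTransition matrix (simulated, % of total):\n")
  print(round(x$transition$simulated, 1))
  cat("\nAUROC (full sample):\n")
  print(x$auroc[x$auroc$subgroup == "full_sample", ], row.names = FALSE)
  invisible(x)
}
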