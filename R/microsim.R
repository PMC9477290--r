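# Monte Carlo projection engine: two-year steps from a baseline cohort,
# drawing mortality first (so status at death uses the last wave's status),
# then next-wave scores for survivors, updating verified status on the fly
# and shifting lags. One random substream per (replicate, wave, draw type),
# with draws indexed by stable person order.

#' Simulation configuration
#'
#' @param horizon_waves number of projected two-year waves (default 5, a
#'   ten-year horizon).
#' @param replicates number of Monte Carlo replicates (default 500).
#' @param base_seed non-negative integer; replicate r and wave w consume
#'   substreams derived deterministically from `(base_seed, r, w)`.
#' @param covariate_process `"synthetic"` evolves exogenous covariates with
#'   the same process the synthetic cohort generator uses; `"frozen"` keeps
#'   them (and age) fixed to isolate the cognition/mortality mechanics.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(horizon_waves = 5L, replicates = 500L, base_seed = 1L,
                       covariate_process = c("synthetic", "frozen")) {
  covariate_process <- match.arg(covariate_process)
  if (horizon_waves < 1L) stop("horizon_waves must be >= 1", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (base_seed < 0L) stop("base_seed must be non-negative", call. = FALSE)
  structure(list(horizon_waves = as.integer(horizon_waves),
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 covariate_process = covariate_process),
            class = "sim_config")
}

.substream_seed <- function(base_seed, r, w, type) {
  (7919 * (base_seed %% 100000) + 1000003 * r + 9973 * w + type) %% 2147483629
}

#' Initial population state from a baseline panel
#'
#' @param baseline panel containing waves -1 and 0 for every person.
#' @return list of class `"population_state"` with the raw covariate frame,
#'   current/lagged scores, verified severity (0 normal, 1 MCI, 2 dementia,
#'   knowledge-based at baseline) and alive flags.
#' @export
population_state <- function(baseline) {
  st <- .state_from_baseline(baseline)
  b0 <- add_cognition_columns(baseline, timing = "known")
  b0 <- b0[b0$wave == 0L, ]
  structure(list(
    st = st,
    alive = rep(TRUE, nrow(st)),
    verified = match(b0$verified_status, .status_labels) - 1L,
    wave = 0L
  ), class = "population_state")
}

# one transition; u = list(gap, die, tics) of uniforms over all n persons
# (dead entries ignored). Covariate advancement consumes the current RNG
# stream when covariate_process == "synthetic".
.sim_step <- function(pop, models, u, covariate_process = "synthetic",
                      inc = .default_incidence) {
  st <- pop$st
  ia <- which(pop$alive)
  n <- nrow(st)
  attain_sev <- integer(n)
  attain_wave <- rep(NA_integer_, n)
  died_ids <- integer(0)
  new_score <- rep(NA_integer_, n)
  if (length(ia)) {
    if (covariate_process == "synthetic") {
      gap <- 2 + (u$gap[ia] - 0.5)
    } else {
      gap <- rep(2, length(ia))
    }
    st$delta_age[ia] <- gap - 2
    Xm <- tryCatch(build_design(st[ia, , drop = FALSE], "mortality"),
                   error = function(e) stop("simulation step failed: ",
                                            conditionMessage(e),
                                            call. = FALSE))
    p_die <- predict(models$mortality, Xm)
    died <- u$die[ia] < p_die
    prev_sev <- .score_severity(st$lag2_tics)
    if (any(died)) {
      id <- ia[died]
      conf <- pmax(pop$verified[id], prev_sev[id])
      newly <- conf > pop$verified[id]
      pop$verified[id] <- conf
      attain_sev[id[newly]] <- conf[newly]
      attain_wave[id[newly]] <- pop$wave        # death confirms last wave
      died_ids <- id
      pop$alive[id] <- FALSE
    }
    is <- ia[!died]
    if (length(is)) {
      Xt <- tryCatch(build_design(st[is, , drop = FALSE], "tics"),
                     error = function(e) stop("simulation step failed: ",
                                              conditionMessage(e),
                                              call. = FALSE))
      eta <- drop(Xt %*% models$tics$coefficients[colnames(Xt)])
      sc <- .op_draw(models$tics, eta, u$tics[is])
      new_score[is] <- sc
      new_sev <- .score_severity(sc)
      conf <- .pair_confirm(prev_sev[is], new_sev)
      upgraded <- conf > pop$verified[is]
      # dementia->MCI confirms at the MCI wave (the new wave); other pairs
      # confirm at the first wave of the pair
      eff <- ifelse(prev_sev[is] == 2L & new_sev == 1L,
                    pop$wave + 1L, pop$wave)
      pop$verified[is] <- pmax(pop$verified[is], conf)
      attain_sev[is[upgraded]] <- conf[upgraded]
      attain_wave[is[upgraded]] <- eff[upgraded]
      st$verified_ever[is] <- as.integer(pop$verified[is] > 0L)
      st$lag4_tics[is] <- st$lag2_tics[is]
      st$lag2_tics[is] <- sc
      if (covariate_process == "synthetic") {
        st$age[is] <- st$age[is] + gap[!died]
        st <- .advance_covariates(st, is, inc)
      }
    }
  }
  pop$st <- st
  pop$wave <- pop$wave + 1L
  list(pop = pop, died = died_ids, new_score = new_score,
       attain_sev = attain_sev, attain_wave = attain_wave)
}

#' Advance a population state by one two-year step
#'
#' Draws uniforms from the current RNG stream in fixed person order and
#' applies one mortality/cognition transition. Mainly a building block and
#' testing surface; [simulate_cohort()] runs full replicate sets with
#' controlled substreams.
#'
#' @param pop a [population_state()].
#' @param models list with `tics` (`"oprobit"`) and `mortality`
#'   (`"bprobit"`) models.
#' @param covariate_process `"synthetic"` or `"frozen"`.
#' @return the updated `population_state`; the step's events are attached as
#'   attribute `"events"` (died ids, new scores, attained statuses).
#' @export
step_population <- function(pop, models,
                            covariate_process = c("synthetic", "frozen")) {
  covariate_process <- match.arg(covariate_process)
  n <- nrow(pop$st)
  u <- list(gap = stats::runif(n), die = stats::runif(n),
            tics = stats::runif(n))
  res <- .sim_step(pop, models, u, covariate_process)
  out <- res$pop
  attr(out, "events") <- res[c("died", "new_score", "attain_sev",
                               "attain_wave")]
  out
}

#' Monte Carlo projection of a baseline cohort
#'
#' Projects every person forward `horizon_waves` two-year steps,
#' `replicates` times. Each replicate re-initializes the population and
#' consumes independent substreams seeded by `(base_seed, replicate, wave,
#' draw type)`; results are bit-reproducible for a fixed configuration.
#'
#' @param baseline panel with waves -1 and 0 (e.g. from
#'   [generate_baseline()] or the baseline waves of an observed panel).
#' @param models list with `tics` and `mortality` fitted (or parameter)
#'   models.
#' @param config a [sim_config()].
#' @return object of class `"replicate_outcomes"`: integer score array
#'   `tics[n, horizon, replicates]` (NA once dead), matrices `death_wave`,
#'   `status_at_death` (severity 0/1/2), `dem_attain` / `mci_attain`
#'   (first wave at which the verified status is in force; 0 when already
#'   verified at baseline; NA if never), plus person ids, weights, baseline
#'   scores and verified severities.
#' @export
simulate_cohort <- function(baseline, models, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  pop0 <- population_state(baseline)
  n <- nrow(pop0$st)
  H <- config$horizon_waves
  R <- config$replicates
  tics <- array(NA_integer_, c(n, H, R))
  death_wave <- matrix(NA_integer_, n, R)
  status_at_death <- matrix(NA_integer_, n, R)
  dem_attain <- matrix(NA_integer_, n, R)
  mci_attain <- matrix(NA_integer_, n, R)
  base_ver <- pop0$verified
  dem0 <- ifelse(base_ver >= 2L, 0L, NA_integer_)
  mci0 <- ifelse(base_ver >= 1L, 0L, NA_integer_)
  for (r in seq_len(R)) {
    pop <- pop0
    dem_attain[, r] <- dem0
    mci_attain[, r] <- mci0
    for (w in seq_len(H)) {
      u <- list()
      for (ti in 1:3) {
        set.seed(.substream_seed(config$base_seed, r, w, ti))
        u[[c("gap", "die", "tics")[ti]]] <- stats::runif(n)
      }
      set.seed(.substream_seed(config$base_seed, r, w, 4L))
      res <- .sim_step(pop, models, u, config$covariate_process)
      pop <- res$pop
      if (length(res$died)) {
        death_wave[res$died, r] <- w
        status_at_death[res$died, r] <- pop$verified[res$died]
      }
      tics[, w, r] <- res$new_score
      att <- which(res$attain_sev > 0L)
      if (length(att)) {
        d_new <- att[res$attain_sev[att] >= 2L & is.na(dem_attain[att, r])]
        dem_attain[d_new, r] <- res$attain_wave[d_new]
        m_new <- att[is.na(mci_attain[att, r])]
        mci_attain[m_new, r] <- res$attain_wave[m_new]
      }
    }
  }
  structure(list(
    tics = tics, death_wave = death_wave, status_at_death = status_at_death,
    dem_attain = dem_attain, mci_attain = mci_attain,
    person_id = pop0$st$person_id, weight = pop0$st$weight,
    baseline_score = pop0$st$lag2_tics, baseline_verified = base_ver,
    horizon = H, replicates = R, base_seed = config$base_seed
  ), class = "replicate_outcomes")
}

#' @export
print.replicate_outcomes <- function(x, ...) {
  cat("Replicate outcomes:", length(x$person_id), "persons x", x$horizon,
      "waves x", x$replicates, "replicates (base seed", x$base_seed, ")\n")
  invisible(x)
}

.predicates <- c("dementia_or_dead_with_dementia", "dementia_given_alive",
                 "mci_or_worse_or_dead_with_mci_or_worse",
                 "mci_or_worse_given_alive", "significant_decline_2yr")

#' Per-person replicate-fraction risk scores
#'
#' The share of Monte Carlo replicates in which a person experiences an
#' outcome by a given wave: the microsimulation's individual risk score.
#' Conditional predicates are computed among the replicates in which the
#' person is alive at that wave (NA when alive in none).
#'
#' @param outcomes a `"replicate_outcomes"` object.
#' @param predicate one of `"dementia_or_dead_with_dementia"`,
#'   `"dementia_given_alive"`, `"mci_or_worse_or_dead_with_mci_or_worse"`,
#'   `"mci_or_worse_given_alive"`, `"significant_decline_2yr"` (score drop
#'   of 3+ points at the first projected wave; a replicate in which the
#'   person dies first counts as no decline).
#' @param wave horizon wave (1..`outcomes$horizon`); ignored for the
#'   two-year decline predicate.
#' @return numeric vector of per-person risks in `[0, 1]`.
#' @export
risk_fraction <- function(outcomes, predicate, wave = outcomes$horizon) {
  if (!predicate %in% .predicates) {
    stop("unknown predicate: ", predicate, call. = FALSE)
  }
  if (wave < 1L || wave > outcomes$horizon) {
    stop("wave outside the simulated horizon", call. = FALSE)
  }
  dw <- outcomes$death_wave
  alive_w <- is.na(dw) | dw > wave
  dead_w <- !alive_w
  if (predicate == "significant_decline_2yr") {
    w1 <- matrix(outcomes$tics[, 1L, ], nrow = length(outcomes$person_id))
    dec <- w1 <= outcomes$baseline_score - 3L
    dec[is.na(dec)] <- FALSE             # died before the first wave
    return(rowMeans(dec))
  }
  dem_by <- !is.na(outcomes$dem_attain) & outcomes$dem_attain <= wave
  if (predicate == "dementia_or_dead_with_dementia") {
    ev <- dem_by | (dead_w & outcomes$status_at_death >= 2L &
                      !is.na(outcomes$status_at_death))
    ev[is.na(ev)] <- FALSE
    return(rowMeans(ev))
  }
  if (predicate == "dementia_given_alive") {
    num <- rowSums(dem_by & alive_w)
    den <- rowSums(alive_w)
    return(ifelse(den > 0, num / den, NA_real_))
  }
  worse_by <- (!is.na(outcomes$mci_attain) & outcomes$mci_attain <= wave) |
    dem_by
  if (predicate == "mci_or_worse_or_dead_with_mci_or_worse") {
    ev <- worse_by | (dead_w & !is.na(outcomes$status_at_death) &
                        outcomes$status_at_death >= 1L)
    ev[is.na(ev)] <- FALSE
    return(rowMeans(ev))
  }
  num <- rowSums(worse_by & alive_w)
  den <- rowSums(alive_w)
  ifelse(den > 0, num / den, NA_real_)
}
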