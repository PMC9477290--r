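# shared fixtures built in code

# small panel with known true models attached
small_panel <- local({
  memo <- new.env(parent = emptyenv())
  function(n = 600L, seed = 42L, n_waves = 6L) {
    key <- paste(n, seed, n_waves)
    if (is.null(memo[[key]])) {
      cfg <- cohort_config(n_individuals = n, seed = seed,
                           n_waves = n_waves)
      memo[[key]] <- generate_panel(cfg)
    }
    memo[[key]]
  }
})

# a raw single-row covariate frame (reference-category person)
reference_raw <- function(n = 1L) {
  data.frame(
    person_id = seq_len(n), wave = 1L, age = rep(70, n), male = 0L,
    race_ethnicity = "nh_white", education = "hs", heart_ever = 0L,
    stroke_ever = 0L, cancer_ever = 0L, hypertension_ever = 0L,
    diabetes_ever = 0L, lung_ever = 0L, chf_ever = 0L,
    heart_attack_2yr = 0L, working = 0L, widowed = 0L, smoke_ever = 0L,
    smoke_current = 0L, log_bmi = log(27), adl_count = 0L, iadl_count = 0L,
    heart50 = 0L, stroke50 = 0L, cancer50 = 0L, hypertension50 = 0L,
    diabetes50 = 0L, lung50 = 0L, smoke_ever50 = 0L, smoke_current50 = 0L,
    verified_ever = 0L, delta_age = 0, lag2_tics = 15L, lag4_tics = 15L,
    weight = 1, stringsAsFactors = FALSE
  )
}

# literal transcription of the verification sentence, used as oracle:
# dementia requires one wave with dementia followed by dementia or death;
# MCI requires one wave with MCI followed by MCI, dementia or death, or one
# wave with dementia followed by MCI; everything else is normal; statuses
# absorb at the first wave of the confirming pair (the dementia->MCI pair
# confirms at the MCI wave)
brute_verify <- function(traj) {
  died <- length(traj) > 0 && traj[length(traj)] == "death"
  waves <- if (died) traj[-length(traj)] else traj
  n <- length(waves)
  if (n == 0L) return(character(0))
  events <- list()
  for (t in seq_len(n)) {
    nxt <- if (t < n) waves[t + 1L] else if (died) "death" else NA
    if (is.na(waves[t]) || is.na(nxt)) next
    if (waves[t] == "dementia" && nxt %in% c("dementia", "death")) {
      events[[length(events) + 1L]] <- c(t, 2)
    }
    if (waves[t] == "mci" && nxt %in% c("mci", "dementia", "death")) {
      events[[length(events) + 1L]] <- c(t, 1)
    }
    if (waves[t] == "dementia" && identical(nxt, "mci")) {
      events[[length(events) + 1L]] <- c(t + 1, 1)
    }
  }
  sev <- integer(n)
  for (e in events) sev[seq(e[1], n)] <- pmax(sev[seq(e[1], n)], e[2])
  c("normal", "verified_mci", "verified_dementia")[sev + 1L]
}

# O(n^2) concordance-count AUROC oracle
brute_auroc <- function(risks, outcomes) {
  cases <- risks[outcomes == 1]
  controls <- risks[outcomes == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}
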