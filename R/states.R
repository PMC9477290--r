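#' Classify a TICS27 score into a cognitive category
#'
#' Scores 0-6 are classified as dementia, 7-11 as mild cognitive impairment
#' (MCI), and 12-27 as cognitively normal (the Langa-Weir cutoffs on the
#' 27-point TICS scale).
#'
#' @param score integer vector of TICS27 scores in 0..27 (NA allowed, passed
#'   through).
#' @return character vector with values `"normal"`, `"mci"`, `"dementia"`.
#' @examples
#' classify_score(c(6, 7, 11, 12, 27))
#' @export
classify_score <- function(score) {
  ok <- is.na(score) | (is.numeric(score) & score == round(score) &
                          score >= 0 & score <= 27)
  if (!all(ok)) {
    stop("score must be an integer in [0, 27], got: ",
         paste(utils::head(score[!ok], 3L), collapse = ", "), call. = FALSE)
  }
  out <- rep(NA_character_, length(score))
  out[!is.na(score) & score <= 6] <- "dementia"
  out[!is.na(score) & score >= 7 & score <= 11] <- "mci"
  out[!is.na(score) & score >= 12] <- "normal"
  out
}

# severity coding used throughout: normal 0 < mci 1 < dementia 2
.severity <- c(normal = 0L, mci = 1L, dementia = 2L)
.status_labels <- c("normal", "verified_mci", "verified_dementia")

#' Verified cognitive status along a category trajectory
#'
#' Applies the two-wave verification rules to a per-wave sequence of
#' cognitive categories: dementia is verified by one wave with dementia
#' followed by dementia or death; MCI is verified by one wave with MCI
#' followed by MCI, dementia or death, or by one wave with dementia followed
#' by MCI (verified at the MCI wave). All other patterns are cognitively
#' normal. Verified status is absorbing: once attained it is carried forward
#' and never downgraded, even if later scores return to the normal range.
#'
#' @param traj character vector of per-wave categories (`"normal"`, `"mci"`,
#'   `"dementia"`; NA for an unobserved score), optionally ending in
#'   `"death"` (at most once, terminal). Pairs only confirm across adjacent
#'   observed waves.
#' @param timing `"effective"` (default) dates each verification at the first
#'   wave of the confirming pair, so the status is already in force at the
#'   wave whose category was later confirmed; `"known"` dates it at the wave
#'   that completes the pair, i.e. the status actually knowable at each wave
#'   (this is what the simulation engine maintains, and what enters the
#'   verified-ever model covariate).
#' @return character vector of statuses (`"normal"`, `"verified_mci"`,
#'   `"verified_dementia"`), one per non-death wave of `traj`.
#' @examples
#' verify_trajectory(c("dementia", "dementia", "normal"))
#' verify_trajectory(c("mci", "normal", "normal"))
#' verify_trajectory(c("dementia", "mci", "death"))
#' @export
verify_trajectory <- function(traj, timing = c("effective", "known")) {
  timing <- match.arg(timing)
  traj <- as.character(traj)
  died <- length(traj) > 0L && !is.na(traj[length(traj)]) &&
    traj[length(traj)] == "death"
  waves <- if (died) traj[-length(traj)] else traj
  if (any(waves %in% "death")) {
    stop("death must be terminal and occur at most once", call. = FALSE)
  }
  bad <- !is.na(waves) & !(waves %in% names(.severity))
  if (any(bad)) stop("invalid category: ", waves[which(bad)[1L]], call. = FALSE)
  n <- length(waves)
  if (n == 0L) return(character(0))

  # attained[w] = severity first attained with (effective or known) wave w
  attained <- integer(n)
  nxt <- c(waves[-1L], if (died) "death" else NA_character_)
  for (t in seq_len(n)) {
    ct <- waves[t]
    et <- nxt[t]
    if (is.na(ct) || is.na(et)) next
    w_eff <- t                       # first wave of the pair
    w_known <- min(t + 1L, n)        # wave completing the pair (death -> last)
    if (ct == "dementia" && et %in% c("dementia", "death")) {
      w <- if (timing == "effective") w_eff else w_known
      attained[w] <- max(attained[w], 2L)
    }
    if (ct == "mci" && et %in% c("mci", "dementia", "death")) {
      w <- if (timing == "effective") w_eff else w_known
      attained[w] <- max(attained[w], 1L)
    }
    if (ct == "dementia" && et == "mci" && t < n) {
      # confirmed as MCI at the MCI wave itself under either convention
      attained[t + 1L] <- max(attained[t + 1L], 1L)
    }
  }
  .status_labels[cummax(attained) + 1L]
}

#' Cognitive status at death
#'
#' The verified status in force at the last observed wave before death, with
#' death itself allowed to confirm a pending single-wave dementia or MCI.
#'
#' @param traj category trajectory ending in `"death"` (see
#'   [verify_trajectory()]).
#' @return one of `"normal"`, `"verified_mci"`, `"verified_dementia"`.
#' @examples
#' status_at_death(c("dementia", "death"))   # death confirms dementia
#' status_at_death(c("normal", "mci", "death"))
#' @export
status_at_death <- function(traj) {
  traj <- as.character(traj)
  if (length(traj) < 2L || is.na(traj[length(traj)]) ||
      traj[length(traj)] != "death") {
    stop("trajectory must end in death", call. = FALSE)
  }
  st <- verify_trajectory(traj)
  st[length(st)]
}

#' Significant two-year cognitive decline
#'
#' TRUE when the score drops by 3 or more points between consecutive waves
#' (the TICS27 translation of a clinically significant 3-point MMSE decline
#' for people with MCI).
#'
#' @param score_t,score_next integer scores in 0..27 at a wave and the next.
#' @return logical vector.
#' @export
significant_decline <- function(score_t, score_next) {
  for (s in list(score_t, score_next)) {
    bad <- !is.na(s) & (s != round(s) | s < 0 | s > 27)
    if (any(bad)) stop("scores must be integers in [0, 27]", call. = FALSE)
  }
  (score_t - score_next) >= 3
}

#' Add per-wave category and verified-status columns to a panel
#'
#' Classifies each observed TICS27 score and runs the verification state
#' machine along every person's observed trajectory (death, marked by an
#' `alive == 0` row, may confirm a pending category). Two extra columns are
#' returned: `category` and `verified_status`.
#'
#' @param panel a panel data frame (see [generate_panel()] for the schema).
#' @param timing passed to [verify_trajectory()].
#' @return the panel with `category` and `verified_status` columns added;
#'   rows with `alive == 0` keep NA in both.
#' @export
add_cognition_columns <- function(panel, timing = "effective") {
  timing <- match.arg(timing, c("effective", "known"))
  panel <- panel[order(panel$person_id, panel$wave), , drop = FALSE]
  n <- nrow(panel)
  cat <- classify_score(panel$tics27)
  cat[panel$alive == 0L] <- NA_character_
  panel$category <- cat
  if (n == 0L) {
    panel$verified_status <- character(0)
    return(panel)
  }
  # vectorized pair scan: the event following row i is the category at the
  # adjacent next wave, or death when that row is a death record
  adj <- c(panel$person_id[-1L] == panel$person_id[-n] &
             panel$wave[-1L] == panel$wave[-n] + 1L, FALSE)
  nxt <- c(cat[-1L], NA_character_)
  nxt[!adj] <- NA_character_
  nxt[adj & c(panel$alive[-1L] == 0L, FALSE)] <- "death"
  alive <- panel$alive == 1L
  here <- alive & !is.na(cat) & !is.na(nxt)
  dem_pair <- here & cat == "dementia" & nxt %in% c("dementia", "death")
  mci_pair <- here & cat == "mci" & nxt %in% c("mci", "dementia", "death")
  dem_mci <- here & cat == "dementia" & nxt == "mci"
  attain <- integer(n)
  place <- function(idx, sev) {
    attain[idx] <<- pmax(attain[idx], sev)
  }
  shift1 <- function(idx) pmin(idx + 1L, n)   # pair-completing row
  if (timing == "effective") {
    place(which(mci_pair), 1L)
    place(which(dem_pair), 2L)
  } else {
    # category pairs become known at the completing wave; a terminal death
    # confirms at the last observed wave itself
    mp <- which(mci_pair)
    dp <- which(dem_pair)
    place(ifelse(nxt[mp] == "death", mp, shift1(mp)), 1L)
    place(ifelse(nxt[dp] == "death", dp, shift1(dp)), 2L)
  }
  place(shift1(which(dem_mci)), 1L)           # confirmed at the MCI wave
  cm <- stats::ave(attain, panel$person_id, FUN = cummax)
  panel$verified_status <- .status_labels[cm + 1L]
  panel$verified_status[!alive] <- NA_character_
  panel
}
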