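#' Classify per-person treatment trajectories over a fixed horizon
#'
#' Builds, for every cohort member with complete potential follow-up, the
#' time-ordered sequence of treatment events during `horizon_days` after
#' initiation: first within-class switch, discontinuation(s),
#' reinitiation(s), death or emigration, and continued treatment at the
#' horizon. Paths are truncated to `max_events` entries; only the first
#' switch appears as a path event (all switches are still counted in the
#' switch matrix by [summarize_trajectories()]). Persons are eligible when
#' `index_day + horizon_days <= study_end_day`, guaranteeing full potential
#' follow-up.
#'
#' The terminal state at the horizon is `"died_or_emigrated"`,
#' `"continued"` (grace-extended coverage spans the horizon day) or
#' `"discontinued"`. `reinitiated_later` flags, among persons ever
#' discontinuing, a reinitiation at any time after the first
#' discontinuation during the full follow-up (it may fall beyond the
#' horizon).
#'
#' @param episodes episodes from [derive_episodes()] (full follow-up).
#' @param switches switch events from [detect_switches()].
#' @param cohort cohort entries from [assemble_new_users()].
#' @param study_end_day administrative end of the study period.
#' @param horizon_days trajectory horizon, default 1095 days (3 years).
#' @param max_events maximum path length, default 5.
#' @return data.frame: `person_id`, `path` (events joined by `" > "`),
#'   `n_events`, `terminal`, `ever_switched` (within horizon),
#'   `reinitiated_later`, `first_switch_from`, `first_switch_to`.
#' @export
classify_trajectory <- function(episodes, switches, cohort, study_end_day,
                                horizon_days = 1095, max_events = 5) {
  grace <- attr(episodes, "grace_days") %||% unique(episodes$grace_days)[1]
  eligible <- cohort[cohort$index_day + horizon_days <= study_end_day, , drop = FALSE]
  if (nrow(eligible) == 0L) {
    return(data.frame(person_id = character(0), path = character(0),
                      n_events = integer(0), terminal = character(0),
                      ever_switched = logical(0), reinitiated_later = logical(0),
                      first_switch_from = character(0), first_switch_to = character(0),
                      stringsAsFactors = FALSE))
  }
  ep_split <- split(episodes, episodes$person_id)
  sw_split <- split(switches, switches$person_id)
  res <- lapply(seq_len(nrow(eligible)), function(i) {
    pid <- eligible$person_id[i]
    index <- eligible$index_day[i]
    h <- index + horizon_days
    ep <- ep_split[[as.character(pid)]]
    sw <- sw_split[[as.character(pid)]]
    days <- numeric(0); types <- character(0)
    fsw_from <- NA_character_; fsw_to <- NA_character_
    ever_sw <- FALSE
    if (!is.null(sw) && nrow(sw) > 0L) {
      sw_h <- sw[sw$day < h, , drop = FALSE]
      if (nrow(sw_h) > 0L) {
        ever_sw <- TRUE
        days <- c(days, sw_h$day[1L]); types <- c(types, "switch")
        fsw_from <- sw_h$from_category[1L]; fsw_to <- sw_h$to_category[1L]
      }
    }
    reinit_later <- FALSE
    covered_at_h <- FALSE
    if (!is.null(ep) && nrow(ep) > 0L) {
      disc <- ep$status == "discontinued" & !is.na(ep$discontinuation_day) &
        ep$discontinuation_day < h
      days <- c(days, ep$discontinuation_day[disc])
      types <- c(types, rep("discontinuation", sum(disc)))
      rein <- ep$episode_index > 1L & ep$start_day < h
      days <- c(days, ep$start_day[rein])
      types <- c(types, rep("reinitiation", sum(rein)))
      first_disc <- ep$discontinuation_day[ep$status == "discontinued"]
      if (length(first_disc) > 0L) {
        reinit_later <- any(ep$start_day > min(first_disc))
      }
      covered_at_h <- any(ep$start_day <= h & h < ep$supply_end_day + grace)
    }
    died <- eligible$end_reason[i] %in% c("death", "emigration") &&
      eligible$follow_up_end_day[i] < h
    if (died) {
      days <- c(days, eligible$follow_up_end_day[i])
      types <- c(types, "died_or_emigrated")
      # events after death/emigration cannot occur; keep only earlier ones
      keep <- days <= eligible$follow_up_end_day[i]
      days <- days[keep]; types <- types[keep]
      terminal <- "died_or_emigrated"
    } else if (covered_at_h) {
      terminal <- "continued"
    } else {
      terminal <- "discontinued"
    }
    o <- order(days, match(types, c("switch", "discontinuation", "reinitiation",
                                    "died_or_emigrated")))
    path <- types[o]
    if (terminal == "continued") path <- c(path, "continued")
    path <- head(path, max_events)
    data.frame(person_id = pid, path = paste(path, collapse = " > "),
               n_events = length(path), terminal = terminal,
               ever_switched = ever_sw, reinitiated_later = reinit_later,
               first_switch_from = fsw_from, first_switch_to = fsw_to,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Percentage arithmetic for trajectory summaries
#'
#' Pure arithmetic used by [summarize_trajectories()]: percentages (to one
#' decimal) of the three terminal states, of ever-switching, and of later
#' reinitiation among those discontinued. Supplied as a standalone function
#' so published trajectory counts can be turned into the exact reported
#' shares.
#'
#' @param counts named list/vector with `n_total`, `n_discontinued`,
#'   `n_continued`, `n_died_or_emigrated`, and optionally `n_switched`,
#'   `n_reinitiated_among_discontinued`.
#' @return named numeric vector of percentages rounded to one decimal:
#'   `pct_discontinued`, `pct_continued`, `pct_died_or_emigrated`, and when
#'   the optional counts are present `pct_switched`,
#'   `pct_reinitiated_among_discontinued`.
#' @examples
#' trajectory_shares(list(n_total = 4, n_discontinued = 2, n_continued = 1,
#'                        n_died_or_emigrated = 1,
#'                        n_reinitiated_among_discontinued = 1))
#' @export
trajectory_shares <- function(counts) {
  counts <- as.list(counts)
  n <- counts$n_total
  pct <- function(num, den) if (is.null(num) || den == 0) NA_real_ else round(100 * num / den, 1)
  out <- c(pct_discontinued = pct(counts$n_discontinued, n),
           pct_continued = pct(counts$n_continued, n),
           pct_died_or_emigrated = pct(counts$n_died_or_emigrated, n))
  if (!is.null(counts$n_switched)) {
    out <- c(out, pct_switched = pct(counts$n_switched, n))
  }
  if (!is.null(counts$n_reinitiated_among_discontinued)) {
    out <- c(out, pct_reinitiated_among_discontinued =
               pct(counts$n_reinitiated_among_discontinued, counts$n_discontinued))
  }
  out[!is.na(out)]
}

#' Summarize treatment trajectories for one cohort
#'
#' Aggregates classified trajectories into the headline counts and
#' percentages: terminal states at the horizon, share ever switching, share
#' of the discontinued who later reinitiated, the distribution of paths, and
#' a first-switch matrix between within-class drug categories (with
#' percentages relative to the number of initiators of the origin category
#' when `initiators` is supplied).
#'
#' @param traj classified trajectories from [classify_trajectory()].
#' @param initiators optional: named integer vector of initiator counts per
#'   drug category, or a data.frame `person_id`, `category` covering the
#'   trajectory cohort.
#' @return list with `counts` (named integers), `shares` (percentages, one
#'   decimal, from [trajectory_shares()]), `paths` (data.frame of path,
#'   count, pct), `switch_matrix` (counts), and `switch_pct` (percent of
#'   origin-category initiators; only when `initiators` given). Empty input
#'   gives zero counts.
#' @export
summarize_trajectories <- function(traj, initiators = NULL) {
  n <- nrow(traj)
  counts <- list(
    n_total = n,
    n_discontinued = sum(traj$terminal == "discontinued"),
    n_continued = sum(traj$terminal == "continued"),
    n_died_or_emigrated = sum(traj$terminal == "died_or_emigrated"),
    n_switched = sum(traj$ever_switched),
    n_reinitiated_among_discontinued =
      sum(traj$terminal == "discontinued" & traj$reinitiated_later)
  )
  if (n == 0L) {
    return(list(counts = counts, shares = numeric(0),
                paths = data.frame(path = character(0), count = integer(0),
                                   pct = numeric(0)),
                switch_matrix = table(character(0), character(0))))
  }
  shares <- trajectory_shares(counts)
  ptab <- sort(table(traj$path), decreasing = TRUE)
  paths <- data.frame(path = names(ptab), count = as.integer(ptab),
                      pct = round(100 * as.integer(ptab) / n, 1),
                      stringsAsFactors = FALSE)
  sw <- traj[traj$ever_switched, , drop = FALSE]
  switch_matrix <- table(from = sw$first_switch_from, to = sw$first_switch_to)
  out <- list(counts = counts, shares = shares, paths = paths,
              switch_matrix = switch_matrix)
  if (!is.null(initiators)) {
    if (is.data.frame(initiators)) {
      ini <- table(initiators$category[match(traj$person_id, initiators$person_id)])
    } else {
      ini <- initiators
    }
    pctm <- switch_matrix
    for (fr in rownames(switch_matrix)) {
      den <- if (fr %in% names(ini)) as.numeric(ini[[fr]]) else NA_real_
      pctm[fr, ] <- round(100 * switch_matrix[fr, ] / den, 1)
    }
    out$initiators <- ini
    out$switch_pct <- pctm
  }
  out
}
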