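#' Resolve days of supply from dispensed package counts
#'
#' Register extracts often carry the number of dispensed package units rather
#' than days of supply. This maps `drug_code` to days per package through a
#' configured lookup table and multiplies by the dispensed amount. Records
#' whose code is missing from the table use `default` days per package when
#' given, and are otherwise rejected (never silently zeroed).
#'
#' @param records data.frame with columns `drug_code` and `n_packages`
#'   (positive dispensed package units).
#' @param supply_table named numeric vector: days of supply per package unit,
#'   names are drug codes.
#' @param default fallback days per package for unknown codes, or `NULL` to
#'   reject such records.
#' @return `records` with an integer `days_supply` column; rejected rows are
#'   dropped, their count reported in a message and in attribute
#'   `"n_rejected"`.
#' @export
resolve_days_supply <- function(records, supply_table, default = NULL) {
  if (any(is.na(records$n_packages) | records$n_packages <= 0)) {
    stop("n_packages must be positive for all records")
  }
  per_pkg <- unname(supply_table[as.character(records$drug_code)])
  if (!is.null(default)) per_pkg[is.na(per_pkg)] <- default
  bad <- is.na(per_pkg)
  if (any(bad)) {
    message(sum(bad), " record(s) with unknown drug_code rejected by supply lookup")
  }
  out <- records[!bad, , drop = FALSE]
  out$days_supply <- as.integer(round(out$n_packages * per_pkg[!bad]))
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Build drug-coverage segments from a fill stream
#'
#' Converts fills into disjoint, sorted coverage segments per person, at the
#' drug-class level. With `stockpiling = TRUE` (the default), a refill made
#' before the pooled supply of earlier fills is exhausted is assumed to be
#' used only after that supply runs out, so overlapping supplies are carried
#' forward and the total covered time equals the total dispensed days of
#' supply. Without stockpiling each fill covers
#' `[fill_day, fill_day + days_supply)` and overlaps are unioned (overlapping
#' days counted once). Same-day fills pool their supply under stockpiling.
#'
#' @param fills data.frame with columns `person_id`, `fill_day`,
#'   `days_supply`; may contain several persons.
#' @param stockpiling logical, carry unused supply forward.
#' @return data.frame of segments: `person_id`, `start_day`, `end_day`
#'   (half-open), `n_fills` (contributing fill count), sorted by person and
#'   start day.
#' @export
build_coverage <- function(fills, stockpiling = TRUE) {
  empty <- data.frame(person_id = character(0), start_day = integer(0),
                      end_day = integer(0), n_fills = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(fills) || nrow(fills) == 0L) return(empty)
  stopifnot(all(fills$days_supply >= 1))
  dt <- as.data.table(fills)[, list(person_id, fill_day, days_supply)]
  setorder(dt, person_id, fill_day)
  if (stockpiling) {
    # pool same-day fills, then: end_k = cumsum(s)_k + cummax(fill_k - cumsum(s)_{k-1});
    # a new segment starts where fill_k > end_{k-1}
    dt <- dt[, list(days_supply = sum(days_supply), n_fills = .N),
             by = list(person_id, fill_day)]
    seg <- dt[, {
      cs <- cumsum(as.numeric(days_supply))
      prev <- c(0, cs[-length(cs)])
      ends <- cs + cummax(fill_day - prev)
      newseg <- c(TRUE, fill_day[-1] > ends[-length(ends)])
      gid <- cumsum(newseg)
      list(start_day = fill_day[match(unique(gid), gid)],
           end_day = as.integer(tapply(ends, gid, max)),
           n_fills = as.integer(tapply(n_fills, gid, sum)))
    }, by = "person_id"]
  } else {
    seg <- dt[, {
      s <- fill_day
      e <- fill_day + days_supply
      newseg <- c(TRUE, s[-1] > cummax(e)[-length(e)])
      gid <- cumsum(newseg)
      list(start_day = s[match(unique(gid), gid)],
           end_day = as.integer(tapply(e, gid, max)),
           n_fills = as.integer(tabulate(gid)))
    }, by = "person_id"]
  }
  out <- as.data.frame(seg)
  out$start_day <- as.integer(out$start_day)
  out
}

#' Derive grace-extended treatment episodes from coverage segments
#'
#' Consecutive coverage segments separated by a gap of at most `grace_days`
#' belong to one treatment episode. A gap exceeding the grace period closes
#' the episode: the discontinuation day is the estimated end of supply plus
#' the grace period, and the start of the next segment is the reinitiation
#' day. An episode whose supply end plus grace extends beyond the end of
#' follow-up is `ongoing_at_censor` (its discontinuation cannot be observed).
#'
#' @param segments coverage segments from [build_coverage()].
#' @param grace_days non-negative grace period in days.
#' @param follow_up_end scalar day index, or a data.frame with columns
#'   `person_id`, `follow_up_end_day` (e.g. cohort entries from
#'   [assemble_new_users()]).
#' @return data.frame: `person_id`, `episode_index` (1-based), `start_day`,
#'   `supply_end_day`, `grace_days`, `discontinuation_day` (NA unless
#'   discontinued), `status` (`"discontinued"` / `"ongoing_at_censor"`),
#'   `reinitiation_day` (start of the next episode, NA for the last).
#'   Segments starting after the person's end of follow-up are dropped with
#'   a message. Attribute `"grace_days"` records the grace used.
#' @export
derive_episodes <- function(segments, grace_days, follow_up_end) {
  stopifnot(grace_days >= 0)
  empty <- data.frame(person_id = character(0), episode_index = integer(0),
                      start_day = integer(0), supply_end_day = integer(0),
                      grace_days = integer(0), discontinuation_day = integer(0),
                      status = character(0), reinitiation_day = integer(0),
                      stringsAsFactors = FALSE)
  attr(empty, "grace_days") <- as.integer(grace_days)
  if (is.null(segments) || nrow(segments) == 0L) return(empty)
  dt <- as.data.table(segments)
  if (is.data.frame(follow_up_end)) {
    fu <- follow_up_end$follow_up_end_day[match(dt$person_id, follow_up_end$person_id)]
  } else {
    fu <- rep_len(as.numeric(follow_up_end), nrow(dt))
  }
  dt[, follow_up_end_day := fu]
  late <- dt$start_day > dt$follow_up_end_day
  if (any(late)) {
    message(sum(late), " coverage segment(s) starting after end of follow-up dropped")
    dt <- dt[!late]
    if (nrow(dt) == 0L) return(empty)
  }
  setorder(dt, person_id, start_day)
  ep <- dt[, {
    g <- c(Inf, start_day[-1] - end_day[-.N])  # gap to previous segment
    eid <- cumsum(g > grace_days)
    list(episode_index = unique(eid),
         start_day = start_day[match(unique(eid), eid)],
         supply_end_day = as.integer(tapply(end_day, eid, max)),
         follow_up_end_day = follow_up_end_day[1L])
  }, by = "person_id"]
  ep[, grace_days := as.integer(grace_days)]
  disc_day <- ep$supply_end_day + grace_days
  ep[, status := ifelse(disc_day <= follow_up_end_day, "discontinued", "ongoing_at_censor")]
  ep[, discontinuation_day := ifelse(status == "discontinued", as.integer(disc_day), NA_integer_)]
  ep[, reinitiation_day := shift(start_day, type = "lead"), by = "person_id"]
  out <- as.data.frame(ep[, list(person_id, episode_index, start_day, supply_end_day,
                                 grace_days, discontinuation_day, status,
                                 reinitiation_day)])
  attr(out, "grace_days") <- as.integer(grace_days)
  out
}

#' Competing-risk records for time to first treatment discontinuation
#'
#' Follows each cohort member from the index day until the first of
#' treatment discontinuation (event 1), death (competing event 2), or
#' censoring by emigration or the administrative study end (0). The event
#' time for discontinuation is by default the grace-inclusive discontinuation
#' day (supply end + grace); `event_time = "supply_end"` records the end of
#' supply instead (the discontinuation *definition* is unchanged). A
#' discontinuation coinciding with death on the same day counts as
#' discontinuation. Same-day events at the index get time 0.5 (end-of-day
#' convention).
#'
#' @param episodes episodes from [derive_episodes()].
#' @param cohort cohort entries from [assemble_new_users()] (supplies
#'   `index_day`, `follow_up_end_day`, `end_reason`).
#' @param event_time `"discontinuation_day"` or `"supply_end"`.
#' @return data.frame `person_id`, `time` (> 0, days since index), `event`
#'   (0 censored, 1 discontinuation, 2 death).
#' @export
discontinuation_records <- function(episodes, cohort,
                                    event_time = c("discontinuation_day", "supply_end")) {
  event_time <- match.arg(event_time)
  ep1 <- episodes[!duplicated(episodes$person_id), , drop = FALSE]  # first episode
  idx <- match(cohort$person_id, ep1$person_id)
  disc <- !is.na(idx) & ep1$status[idx] == "discontinued"
  tday <- ifelse(disc,
                 if (event_time == "discontinuation_day") ep1$discontinuation_day[idx]
                 else ep1$supply_end_day[idx],
                 cohort$follow_up_end_day)
  event <- ifelse(disc, 1L, ifelse(cohort$end_reason == "death", 2L, 0L))
  time <- tday - cohort$index_day
  time[time <= 0] <- 0.5
  data.frame(person_id = cohort$person_id, time = as.numeric(time),
             event = event, stringsAsFactors = FALSE)
}

#' Follow-up records for treatment reinitiation after discontinuation
#'
#' For each observed discontinuation, follow-up starts on the
#' discontinuation day and ends at the first of reinitiation (start of the
#' next episode, event 1), death (competing event 2), or censoring by
#' emigration or the administrative study end (0). By default only the
#' first discontinuation per person contributes (headline analysis); set
#' `first_only = FALSE` to keep all discontinuation cycles.
#'
#' @inheritParams discontinuation_records
#' @param first_only keep only each person's first discontinuation.
#' @return data.frame `person_id`, `discontinuation_day`, `time` (> 0, days
#'   since discontinuation), `event` (0/1/2).
#' @export
reinitiation_followup <- function(episodes, cohort, first_only = TRUE) {
  ep <- episodes[episodes$status == "discontinued", , drop = FALSE]
  if (first_only) ep <- ep[!duplicated(ep$person_id), , drop = FALSE]
  if (nrow(ep) == 0L) {
    return(data.frame(person_id = character(0), discontinuation_day = integer(0),
                      time = numeric(0), event = integer(0), stringsAsFactors = FALSE))
  }
  ci <- match(ep$person_id, cohort$person_id)
  fu_end <- cohort$follow_up_end_day[ci]
  reason <- cohort$end_reason[ci]
  has_reinit <- !is.na(ep$reinitiation_day)
  tday <- ifelse(has_reinit, ep$reinitiation_day, fu_end)
  event <- ifelse(has_reinit, 1L, ifelse(reason == "death", 2L, 0L))
  time <- tday - ep$discontinuation_day
  time[time <= 0] <- 0.5
  data.frame(person_id = ep$person_id,
             discontinuation_day = ep$discontinuation_day,
             time = as.numeric(time), event = event, stringsAsFactors = FALSE)
}

#' Detect within-class drug switches in a fill stream
#'
#' A switch is emitted at every fill whose drug code differs from the code of
#' the person's previous fill within the class. Code changes inside an
#' aggregate `"other"` category still count as switches (recorded with
#' `from_category == to_category`).
#'
#' @param fills data.frame with `person_id`, `fill_day`, `drug_code`,
#'   `drug_category`; may contain several persons.
#' @return data.frame of switch events: `person_id`, `day`, `from_code`,
#'   `to_code`, `from_category`, `to_category`, time-ordered within person.
#' @export
detect_switches <- function(fills) {
  empty <- data.frame(person_id = character(0), day = integer(0),
                      from_code = character(0), to_code = character(0),
                      from_category = character(0), to_category = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(fills) || nrow(fills) == 0L) return(empty)
  dt <- as.data.table(fills)
  setorder(dt, person_id, fill_day, drug_code)
  sw <- dt[, {
    prev_code <- shift(drug_code)
    prev_cat <- shift(drug_category)
    i <- which(!is.na(prev_code) & drug_code != prev_code)
    list(day = fill_day[i], from_code = prev_code[i], to_code = drug_code[i],
         from_category = prev_cat[i], to_category = drug_category[i])
  }, by = "person_id"]
  if (nrow(sw) == 0L) return(empty)
  as.data.frame(sw)
}
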