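#' Proportion of days covered (PDC) over the first year of treatment
#'
#' Adherence as the number of days covered by raw drug supply (no grace
#' extension) during `[index, index + window_days)`, divided by
#' `window_days`. Only persons alive at `index + window_days` are included;
#' emigration does not exclude, since dispensed supply remains observable
#' up to emigration.
#'
#' @param segments raw coverage segments from [build_coverage()] (supply
#'   only, stockpiling as configured -- PDC is unaffected by stockpiling when
#'   fills never overlap).
#' @param cohort cohort entries (supplies `index_day`).
#' @param persons person table with `death_day` (NA = alive).
#' @param window_days adherence window, default 365.
#' @return data.frame: `person_id`, `days_covered`, `window_days`, `pdc`
#'   (fraction in `[0, 1]`).
#' @export
proportion_days_covered <- function(segments, cohort, persons, window_days = 365) {
  death <- persons$death_day[match(cohort$person_id, persons$person_id)]
  alive <- is.na(death) | death >= cohort$index_day + window_days
  coh <- cohort[alive, , drop = FALSE]
  seg <- as.data.table(segments)
  seg[, index_day := coh$index_day[match(person_id, coh$person_id)]]
  seg <- seg[!is.na(index_day)]
  seg[, covered := pmax(0, pmin(end_day, index_day + window_days) - pmax(start_day, index_day))]
  cov <- seg[, list(days_covered = sum(covered)), by = "person_id"]
  days <- cov$days_covered[match(coh$person_id, cov$person_id)]
  days[is.na(days)] <- 0
  days <- pmin(days, window_days)
  data.frame(person_id = coh$person_id,
             days_covered = as.integer(days),
             window_days = as.integer(window_days),
             pdc = days / window_days,
             stringsAsFactors = FALSE)
}

#' Summary of PDC adherence over a cohort
#'
#' Shares of patients reaching the conventional adherence thresholds (at
#' least 80%, at least 90%, exactly 100% of days covered) plus mean, SD,
#' median and IQR of PDC, all on the percent scale.
#'
#' @param results PDC results from [proportion_days_covered()].
#' @return named list: `n`, `pct_ge80`, `pct_ge90`, `pct_100`, `mean`, `sd`,
#'   `median`, `iqr` (length-2, 25th/75th percentile); percentages of
#'   included persons.
#' @export
pdc_summary <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("pdc_summary: no PDC results to summarise")
  }
  p <- results$pdc
  q <- unname(quantile(p * 100, c(0.25, 0.75)))
  list(n = nrow(results),
       pct_ge80 = 100 * mean(p >= 0.80),
       pct_ge90 = 100 * mean(p >= 0.90),
       pct_100 = 100 * mean(results$days_covered >= results$window_days),
       mean = mean(p * 100),
       sd = sd(p * 100),
       median = median(p * 100),
       iqr = q)
}

#' Proportion of patients covered (PPC) over time since initiation
#'
#' At each evaluation time `t` (days since index), the share of patients
#' with ongoing grace-extended treatment among those alive, not emigrated
#' and -- by default -- enrolled early enough that `index + t` does not
#' exceed the administrative study end (late initiators otherwise deflate
#' late-time PPC). Patients may discontinue and reinitiate any number of
#' times; every episode counts.
#'
#' @param episodes episodes from [derive_episodes()] built with the *same*
#'   grace period (checked; mismatch is an error).
#' @param cohort cohort entries.
#' @param grace_days grace period the episodes were built with.
#' @param eval_days evaluation grid in days since index (default: every 30
#'   days to 5 years).
#' @param study_end_day administrative end of the study period (required
#'   when `admin_exclude = TRUE`).
#' @param admin_exclude drop person-time beyond the study end from the
#'   denominator.
#' @return data.frame: `grace_days`, `eval_day`, `covered`, `at_risk`,
#'   `ppc`.
#' @export
proportion_patients_covered <- function(episodes, cohort, grace_days,
                                        eval_days = seq(0, 1825, by = 30),
                                        study_end_day = NULL,
                                        admin_exclude = TRUE) {
  g <- attr(episodes, "grace_days") %||% unique(episodes$grace_days)[1]
  if (!isTRUE(all.equal(as.numeric(g), as.numeric(grace_days)))) {
    stop("episodes were built with grace ", g, " days, but grace ", grace_days,
         " was requested")
  }
  if (admin_exclude && is.null(study_end_day)) {
    stop("study_end_day is required when admin_exclude = TRUE")
  }
  idx <- cohort$index_day
  fu <- cohort$follow_up_end_day
  reason <- cohort$end_reason
  ep <- as.data.table(episodes)
  ep[, index_day := idx[match(person_id, cohort$person_id)]]
  ep[, cov_start := start_day - index_day]
  ep[, cov_end := supply_end_day + grace_days - index_day]  # half-open
  out <- lapply(eval_days, function(t) {
    in_denom <- (!(reason %in% c("death", "emigration")) | fu - idx >= t)
    if (admin_exclude) in_denom <- in_denom & (idx + t <= study_end_day)
    at_risk <- cohort$person_id[in_denom]
    cov_ids <- unique(ep$person_id[ep$cov_start <= t & t < ep$cov_end])
    covered <- sum(cov_ids %in% at_risk)
    data.frame(grace_days = as.integer(grace_days), eval_day = t,
               covered = covered, at_risk = length(at_risk),
               ppc = if (length(at_risk) > 0) covered / length(at_risk) else NA_real_)
  })
  do.call(rbind, out)
}
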