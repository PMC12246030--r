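#' Read and validate a prescription-fill table
#'
#' Delimited file with header columns `person_id`, `drug_class`,
#' `drug_code`, `drug_category`, `fill_day`, `days_supply`. Dates are
#' accepted as ISO-8601 or integer day indices (single conversion point,
#' see [as_day()]). Rows with a non-positive or missing `days_supply` are
#' rejected and counted; duplicate `(person, class, code, day)` rows are
#' merged with summed supply. Both counts are reported in messages and as
#' attributes `"n_rejected"` / `"n_deduped"`.
#'
#' @param path CSV/TSV file path.
#' @param epoch epoch date for ISO-date conversion.
#' @return validated data.frame of fill records.
#' @export
read_fills <- function(path, epoch = "2017-01-01") {
  req <- c("person_id", "drug_class", "drug_code", "drug_category",
           "fill_day", "days_supply")
  dt <- fread(path, colClasses = list(character = "person_id"))
  miss <- setdiff(req, names(dt))
  if (length(miss) > 0) {
    stage_stop("read_fills", "missing required column(s): ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(dt)
  df$fill_day <- as_day(df$fill_day, epoch)
  bad <- is.na(df$days_supply) | df$days_supply < 1 | is.na(df$fill_day)
  if (any(bad)) {
    message("read_fills: ", sum(bad), " malformed row(s) rejected")
    df <- df[!bad, , drop = FALSE]
  }
  key <- paste(df$person_id, df$drug_class, df$drug_code, df$fill_day, sep = "\r")
  if (anyDuplicated(key)) {
    n0 <- nrow(df)
    dd <- as.data.table(df)[, list(
      drug_category = drug_category[1L],
      days_supply = sum(days_supply)),
      by = list(person_id, drug_class, drug_code, fill_day)]
    df <- as.data.frame(dd[, list(person_id, drug_class, drug_code,
                                  drug_category, fill_day, days_supply)])
    message("read_fills: ", n0 - nrow(df),
            " duplicate (person, class, code, day) row(s) merged with summed supply")
    attr(df, "n_deduped") <- n0 - nrow(df)
  } else {
    attr(df, "n_deduped") <- 0L
  }
  attr(df, "n_rejected") <- sum(bad)
  df
}

#' Read and validate a person table
#'
#' Header must contain `person_id`, `sex`, `birth_day`, `death_day`,
#' `emigration_day`; any further columns are carried along as baseline
#' covariates. Empty cells in the day columns mean "absent" (NA).
#'
#' @inheritParams read_fills
#' @return validated data.frame, one row per person (duplicate ids are an
#'   error).
#' @export
read_persons <- function(path, epoch = "2017-01-01") {
  req <- c("person_id", "sex", "birth_day", "death_day", "emigration_day")
  dt <- fread(path, colClasses = list(character = "person_id"))
  miss <- setdiff(req, names(dt))
  if (length(miss) > 0) {
    stage_stop("read_persons", "missing required column(s): ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(dt)
  if (anyDuplicated(df$person_id)) {
    stage_stop("read_persons", "person_id values are not unique")
  }
  for (col in c("birth_day", "death_day", "emigration_day")) {
    df[[col]] <- as_day(df[[col]], epoch)
  }
  df
}

#' Run the full drug-utilization study on one cohort
#'
#' Orchestrates the pipeline end to end: new-user cohort assembly,
#' stockpiled coverage, grace-period episodes, time-to-discontinuation and
#' time-to-reinitiation competing-risk records with Aalen-Johansen
#' cumulative incidences (one per grace period), proportion of patients
#' covered, one-year adherence (PDC), 3-year treatment trajectories with
#' switch summary, and Fine-Gray regressions of discontinuation adjusted
#' for sex and age. Deterministic given its inputs; when `out_dir` is set,
#' all results are written as CSV/JSON together with a manifest of the
#' configuration and record counts.
#'
#' @param config list (or [run_config()]) with entries: `fills` and
#'   `persons` (data.frames or file paths), `drug_class`,
#'   `inclusion_window`, `study_end_day`; optional `grace_main` (90),
#'   `grace_list` (60/90/180/365), `ppc_grace_list` (30/60/90/180/365),
#'   `horizon_days` (1095), `max_events` (5), `eval_days` (every 30 days to
#'   5 years), `event_time` (`"discontinuation_day"`), `pdc_window` (365),
#'   `fg_covariates` (`c("sex", "age_band")`), `fg_extra` (further
#'   covariates, each fitted separately adjusted for the base covariates),
#'   `stockpiling` (TRUE), `epoch`, `out_dir`.
#' @return invisible list bundle: `cohort`, `coverage`, `episodes` (main
#'   grace), `cif_discontinuation` / `cif_reinitiation` (per grace),
#'   `cif_table` (evaluations at 1 and 3 years), `ppc`, `pdc`,
#'   `pdc_summary`, `trajectories`, `trajectory_summary`, `fg_fits`,
#'   `manifest`.
#' @export
run_study <- function(config) {
  cfg <- config
  defaults <- list(grace_main = 90L, grace_list = c(60L, 90L, 180L, 365L),
                   ppc_grace_list = c(30L, 60L, 90L, 180L, 365L),
                   horizon_days = 1095L, max_events = 5L,
                   eval_days = seq(0L, 1825L, by = 30L),
                   event_time = "discontinuation_day", pdc_window = 365L,
                   fg_covariates = c("sex", "age_band"),
                   fg_extra = character(0),
                   stockpiling = TRUE, epoch = "2017-01-01", out_dir = NULL)
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  for (nm in c("fills", "persons", "drug_class", "inclusion_window", "study_end_day")) {
    if (is.null(cfg[[nm]])) stage_stop("run_study", "config entry '", nm, "' is required")
  }
  fills <- if (is.character(cfg$fills)) read_fills(cfg$fills, cfg$epoch) else cfg$fills
  persons <- if (is.character(cfg$persons)) read_persons(cfg$persons, cfg$epoch) else cfg$persons

  cohort <- tryCatch(
    assemble_new_users(fills, persons, cfg$drug_class, cfg$inclusion_window,
                       cfg$study_end_day),
    error = function(e) stage_stop("cohort", conditionMessage(e)))
  if (nrow(cohort) == 0L) stage_stop("cohort", "no eligible new users")

  f <- fills[fills$drug_class == cfg$drug_class &
               fills$person_id %in% cohort$person_id, , drop = FALSE]
  fu <- cohort$follow_up_end_day[match(f$person_id, cohort$person_id)]
  late <- f$fill_day > fu
  if (any(late)) {
    message("run_study: ", sum(late), " fill(s) after end of follow-up dropped")
    f <- f[!late, , drop = FALSE]
  }
  coverage <- tryCatch(build_coverage(f, stockpiling = cfg$stockpiling),
                       error = function(e) stage_stop("coverage", conditionMessage(e)))

  graces <- sort(unique(c(cfg$grace_main, cfg$grace_list)))
  episodes_by_grace <- lapply(graces, function(g)
    derive_episodes(coverage, g, cohort))
  names(episodes_by_grace) <- as.character(graces)

  cif_disc <- list(); cif_rein <- list(); cif_rows <- list()
  for (g in graces) {
    ep <- episodes_by_grace[[as.character(g)]]
    rec_d <- discontinuation_records(ep, cohort, event_time = cfg$event_time)
    cif_d <- tryCatch(aalen_johansen(rec_d, cause = 1),
                      error = function(e) stage_stop("survstats", conditionMessage(e)))
    rec_r <- reinitiation_followup(ep, cohort)
    cif_r <- if (nrow(rec_r) > 0 && any(rec_r$event != 0))
      aalen_johansen(rec_r, cause = 1) else NULL
    cif_disc[[as.character(g)]] <- cif_d
    cif_rein[[as.character(g)]] <- cif_r
    at <- cif_at(cif_d, c(365, 1095))
    cif_rows[[as.character(g)]] <- data.frame(
      grace_days = g, outcome = "discontinuation", time = at$time,
      cif = at$cif, lower = at$lower, upper = at$upper)
    if (!is.null(cif_r)) {
      atr <- cif_at(cif_r, c(365, 1095))
      cif_rows[[paste0(g, "r")]] <- data.frame(
        grace_days = g, outcome = "reinitiation", time = atr$time,
        cif = atr$cif, lower = atr$lower, upper = atr$upper)
    }
  }
  cif_table <- do.call(rbind, cif_rows)
  rownames(cif_table) <- NULL

  ppc <- do.call(rbind, lapply(cfg$ppc_grace_list, function(g) {
    ep <- if (as.character(g) %in% names(episodes_by_grace))
      episodes_by_grace[[as.character(g)]] else derive_episodes(coverage, g, cohort)
    proportion_patients_covered(ep, cohort, g, eval_days = cfg$eval_days,
                                study_end_day = cfg$study_end_day)
  }))

  pdc <- proportion_days_covered(coverage, cohort, persons,
                                 window_days = cfg$pdc_window)
  pdc_sum <- pdc_summary(pdc)

  switches <- detect_switches(f)
  ep_main <- episodes_by_grace[[as.character(cfg$grace_main)]]
  traj <- classify_trajectory(ep_main, switches, cohort, cfg$study_end_day,
                              horizon_days = cfg$horizon_days,
                              max_events = cfg$max_events)
  first_fill <- f[order(f$person_id, f$fill_day), , drop = FALSE]
  first_fill <- first_fill[!duplicated(first_fill$person_id), , drop = FALSE]
  initiators <- data.frame(person_id = first_fill$person_id,
                           category = first_fill$drug_category,
                           stringsAsFactors = FALSE)
  traj_sum <- summarize_trajectories(traj, initiators = initiators)

  rec_main <- discontinuation_records(ep_main, cohort, event_time = cfg$event_time)
  pcov <- persons[match(rec_main$person_id, persons$person_id), , drop = FALSE]
  fg_fits <- list()
  base <- cfg$fg_covariates[cfg$fg_covariates %in% names(pcov)]
  if (length(base) > 0) {
    dat <- cbind(rec_main, pcov[, base, drop = FALSE])
    fg_fits[["base"]] <- tryCatch(fine_gray_fit(dat, base),
                                  error = function(e) stage_stop("finegray", conditionMessage(e)))
    for (v in cfg$fg_extra) {
      if (!v %in% names(pcov)) next
      dat_v <- cbind(rec_main, pcov[, unique(c(base, v)), drop = FALSE])
      fg_fits[[v]] <- tryCatch(fine_gray_fit(dat_v, unique(c(base, v))),
                               error = function(e) stage_stop("finegray", conditionMessage(e)))
    }
  }

  manifest <- list(package = "rxpersist",
                   version = as.character(utils::packageVersion("rxpersist")),
                   r_version = R.version.string,
                   drug_class = cfg$drug_class,
                   inclusion_window = cfg$inclusion_window,
                   study_end_day = cfg$study_end_day,
                   grace_main = cfg$grace_main, grace_list = cfg$grace_list,
                   ppc_grace_list = cfg$ppc_grace_list,
                   horizon_days = cfg$horizon_days,
                   event_time = cfg$event_time,
                   n_fills_in = nrow(fills), n_fills_used = nrow(f),
                   n_fills_dropped_after_followup = sum(late),
                   n_cohort = nrow(cohort), n_trajectory = nrow(traj))

  bundle <- list(cohort = cohort, coverage = coverage, episodes = ep_main,
                 episodes_by_grace = episodes_by_grace,
                 cif_discontinuation = cif_disc, cif_reinitiation = cif_rein,
                 cif_table = cif_table, ppc = ppc, pdc = pdc,
                 pdc_summary = pdc_sum, switches = switches,
                 trajectories = traj, trajectory_summary = traj_sum,
                 fg_fits = fg_fits, manifest = manifest)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    wout <- function(x, name) fwrite(x, file.path(cfg$out_dir, name))
    wout(cohort, "cohort.csv")
    wout(ep_main, "episodes.csv")
    wout(cif_table, "cif_table.csv")
    wout(ppc, "ppc.csv")
    wout(pdc, "pdc.csv")
    if (nrow(switches) > 0) wout(switches, "switches.csv")
    if (nrow(traj) > 0) wout(traj, "trajectories.csv")
    jout <- function(x, name) jsonlite::write_json(
      x, file.path(cfg$out_dir, name), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jout(pdc_sum, "pdc_summary.json")
    jout(list(counts = traj_sum$counts, shares = as.list(traj_sum$shares)),
         "trajectory_summary.json")
    jout(lapply(fg_fits, function(ft) list(
      coef = as.list(ft$coef), se = as.list(ft$se), sdHR = as.list(ft$sdHR),
      ci_lower = as.list(ft$ci_lower), ci_upper = as.list(ft$ci_upper),
      n = ft$n, events = ft$n_events, iterations = ft$iterations,
      converged = ft$converged)), "finegray.json")
    jout(manifest, "manifest.json")
  }
  invisible(bundle)
}
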