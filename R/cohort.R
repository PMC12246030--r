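#' Assemble a new-user cohort for one drug class
#'
#' Identifies, per person, the first-ever fill of `drug_class` over the entire
#' available fill history (full-history washout) and includes the person when
#' that first fill lies inside the inclusion window. The first-fill day is the
#' index day. Persons whose first fill of the class precedes the window are
#' prevalent users and are excluded; persons dead or emigrated strictly before
#' the index day are excluded (a same-day death keeps the patient, who is then
#' censored at the end of the index day).
#'
#' @param fills data.frame of fill records with columns `person_id`,
#'   `drug_class`, `fill_day` (integer day index).
#' @param persons data.frame with columns `person_id`, `death_day`,
#'   `emigration_day` (NA = absent) and any baseline covariates.
#' @param drug_class class label to select.
#' @param inclusion_window length-2 integer vector `[first, last]` admissible
#'   index day (closed interval).
#' @param study_end_day administrative end of follow-up (day index).
#' @param tie_order precedence when death/emigration/study end coincide.
#' @return data.frame (one row per included person): `person_id`,
#'   `drug_class`, `index_day`, `follow_up_end_day`, `end_reason`.
#'   Fills referencing unknown persons are dropped with a warning.
#' @export
assemble_new_users <- function(fills, persons, drug_class,
                               inclusion_window, study_end_day,
                               tie_order = c("death", "emigration", "admin_censor")) {
  f <- as.data.frame(fills)
  f <- f[f$drug_class == drug_class, , drop = FALSE]
  f <- as.data.table(f)
  unknown <- !(f$person_id %in% persons$person_id)
  if (any(unknown)) {
    warning(sum(unknown), " fill record(s) reference unknown person_id; dropped")
    f <- f[!unknown]
  }
  if (nrow(f) == 0L) {
    return(data.frame(person_id = character(0), drug_class = character(0),
                      index_day = integer(0), follow_up_end_day = integer(0),
                      end_reason = character(0), stringsAsFactors = FALSE))
  }
  first <- f[, list(index_day = min(fill_day)), by = "person_id"]
  keep <- first$index_day >= inclusion_window[1] & first$index_day <= inclusion_window[2]
  first <- first[keep]
  p <- as.data.table(persons)
  idx <- match(first$person_id, p$person_id)
  death <- p$death_day[idx]
  emig <- p$emigration_day[idx]
  alive <- (is.na(death) | death >= first$index_day) &
           (is.na(emig) | emig >= first$index_day)
  first <- first[alive]
  death <- death[alive]; emig <- emig[alive]
  cens <- censor_day(death, emig, study_end_day, tie_order)
  out <- data.frame(person_id = first$person_id,
                    drug_class = drug_class,
                    index_day = as.integer(first$index_day),
                    follow_up_end_day = as.integer(cens$day),
                    end_reason = cens$reason,
                    stringsAsFactors = FALSE)
  out[order(out$person_id), , drop = FALSE]
}

#' End of follow-up and its reason
#'
#' Follow-up ends at the earliest of death, emigration and the administrative
#' study end. Ties are broken by `tie_order` (default: death beats emigration
#' beats administrative censoring). Vectorized over persons.
#'
#' @param death_day,emigration_day integer day index or NA when absent.
#' @param study_end_day administrative end of the study period.
#' @param tie_order character vector giving precedence among
#'   `"death"`, `"emigration"`, `"admin_censor"`.
#' @return list with integer vector `day` and character vector `reason`.
#' @export
censor_day <- function(death_day, emigration_day, study_end_day,
                       tie_order = c("death", "emigration", "admin_censor")) {
  n <- max(length(death_day), length(emigration_day), 1L)
  death_day <- rep_len(as.numeric(death_day %||% NA_real_), n)
  emigration_day <- rep_len(as.numeric(emigration_day %||% NA_real_), n)
  cand <- cbind(death = death_day,
                emigration = emigration_day,
                admin_censor = rep_len(as.numeric(study_end_day), n))
  cand[is.na(cand)] <- Inf
  # order columns by tie precedence, take first minimiser
  ord <- match(tie_order, colnames(cand))
  cand <- cand[, ord, drop = FALSE]
  j <- max.col(-cand, ties.method = "first")
  list(day = as.integer(cand[cbind(seq_len(n), j)]),
       reason = colnames(cand)[j])
}

#' BMI category labels used for subgroup analyses
#'
#' Cut-offs: normal < 25, overweight 25 to <30, obese class I 30 to <35,
#' obese class II/III >= 35 kg/m^2. Missing values label `"missing"`.
#'
#' @param bmi numeric BMI (kg/m^2).
#' @return character vector of labels.
#' @export
bmi_category <- function(bmi) {
  out <- rep("missing", length(bmi))
  ok <- !is.na(bmi)
  out[ok] <- c("normal", "overweight", "obese1", "obese23")[
    findInterval(bmi[ok], c(-Inf, 25, 30, 35))]
  out
}

#' Assign deterministic subgroup labels to cohort entries
#'
#' Produces the subgroup labels used in stratified analyses: comorbidity
#' flags (ASCVD, chronic kidney disease, heart failure), BMI category and
#' calendar year of treatment initiation. Missing covariates label
#' `"missing"`; no imputation is performed.
#'
#' @param entries cohort entries from [assemble_new_users()].
#' @param persons person table; recognised covariate columns: `ascvd`,
#'   `ckd`, `hf` (logical), and `bmi` (numeric) or `bmi_category`.
#' @param epoch epoch date for calendar-year labels.
#' @return data.frame of `person_id` plus one label column per subgroup
#'   variable present.
#' @export
assign_subgroups <- function(entries, persons, epoch = "2017-01-01") {
  idx <- match(entries$person_id, persons$person_id)
  out <- data.frame(person_id = entries$person_id, stringsAsFactors = FALSE)
  flag_label <- function(x, tag) {
    ifelse(is.na(x), "missing", ifelse(as.logical(x), paste0(tag, "+"), paste0(tag, "-")))
  }
  if ("ascvd" %in% names(persons)) out$ascvd <- flag_label(persons$ascvd[idx], "ASCVD")
  if ("ckd" %in% names(persons)) out$ckd <- flag_label(persons$ckd[idx], "CKD")
  if ("hf" %in% names(persons)) out$hf <- flag_label(persons$hf[idx], "HF")
  if ("bmi" %in% names(persons)) {
    out$bmi_category <- bmi_category(persons$bmi[idx])
  } else if ("bmi_category" %in% names(persons)) {
    bc <- as.character(persons$bmi_category[idx])
    out$bmi_category <- ifelse(is.na(bc), "missing", bc)
  }
  out$calendar_year <- day_to_year(entries$index_day, epoch)
  out
}
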