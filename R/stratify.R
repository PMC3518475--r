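#' Rate of metastatic progression
#'
#' New recurrent metastases per year of follow-up: the total count of
#' recurrent metastases divided by the years elapsed between lung surgery and
#' last follow-up (or death, whichever comes first). Patients without
#' recurrence have rate 0.
#'
#' @param nRecurrentMets count of recurrent metastases over follow-up.
#' @param followupMonths months from surgery to last follow-up or death.
#' @return Rate in new metastases per year.
#' @examples
#' computeRate(8, 24)   # 4 per year
#' computeRate(0, 60)   # 0
#' @export
computeRate <- function(nRecurrentMets, followupMonths) {
  if (any(followupMonths <= 0))
    stop("follow-up must be positive (months)")
  if (any(nRecurrentMets < 0)) stop("metastasis counts must be >= 0")
  nRecurrentMets / (followupMonths / 12)
}

#' Classify the rate of progression into LRP / IRP / HRP
#'
#' Low rate of progression (LRP): fewer than 0.6 new metastases per year,
#' including patients with no recurrence. High rate (HRP): more than 3.6 per
#' year. Intermediate (IRP): 0.6 to 3.6 inclusive -- the band boundaries
#' belong to IRP since the outer classes are defined by strict inequalities.
#'
#' @param ratePerYear non-negative rate(s) in new metastases per year.
#' @param lrpBelow,hrpAbove band thresholds (per year).
#' @return Character vector of `"LRP"`, `"IRP"`, `"HRP"`.
#' @export
classifyRate <- function(ratePerYear, lrpBelow = 0.6, hrpAbove = 3.6) {
  if (any(is.na(ratePerYear)) || any(ratePerYear < 0))
    stop("rates must be non-negative and non-missing")
  ifelse(ratePerYear < lrpBelow, "LRP",
         ifelse(ratePerYear > hrpAbove, "HRP", "IRP"))
}

# largest number of events inside any `window`-month span starting at an
# event, restricted to events within `horizon` months after the first one
slidingWindowMax <- function(eventMonths, window = 4, horizon = 18) {
  ev <- sort(eventMonths)
  if (!length(ev)) return(0L)
  ev <- ev[ev <= ev[1L] + horizon]
  max(vapply(ev, function(t0) sum(ev >= t0 & ev <= t0 + window), 0L))
}

#' Oligo- vs polymetastatic progression (OM / PM)
#'
#' Polymetastatic progression (PM) is declared when, within 18 months after
#' the first metastatic recurrence, either (i) more than 5 new metastases
#' develop within any 4-month span, or (ii) progression occurs within a body
#' cavity. Everything else, including no recurrence at all, is oligometastatic
#' (OM). The >5-in-4-months test scans a sliding window over recurrence event
#' dates when an event list is given; otherwise a precomputed
#' `maxNewMetsIn4Months` is used; otherwise only the cavity criterion applies.
#'
#' @param cavityProgression logical; body-cavity progression within 18 months
#'   of first recurrence.
#' @param maxNewMetsIn4Months precomputed maximum new metastases within any
#'   4-month span of the 18-month window (optional).
#' @param eventMonths vector of recurrence event times (months after surgery);
#'   optional, takes precedence over `maxNewMetsIn4Months`.
#' @param burstCount,burstWindowMonths,horizonMonths rule parameters: PM
#'   requires more than `burstCount` metastases within `burstWindowMonths`,
#'   inside `horizonMonths` of first recurrence.
#' @return `"PM"` or `"OM"`.
#' @export
classifyPattern <- function(cavityProgression = FALSE,
                            maxNewMetsIn4Months = NA_integer_,
                            eventMonths = NULL,
                            burstCount = 5, burstWindowMonths = 4,
                            horizonMonths = 18) {
  burst <- if (!is.null(eventMonths) && length(eventMonths)) {
    slidingWindowMax(eventMonths, burstWindowMonths, horizonMonths) > burstCount
  } else if (!is.na(maxNewMetsIn4Months)) {
    maxNewMetsIn4Months > burstCount
  } else FALSE
  if (isTRUE(as.logical(cavityProgression)) || burst) "PM" else "OM"
}

#' Stratify a clinical cohort into progression phenotypes
#'
#' Computes each patient's rate of metastatic progression, the HRP/LRP/IRP
#' rate class, and the OM/PM progression pattern, from a clinical table in
#' the package's CSV dialect (see [readClinical()]).
#'
#' @param clinical data.frame with columns `patient_id`, `n_recurrent_mets`,
#'   `followup_months`, `cavity_progression` and optionally
#'   `max_new_mets_in_4_months`.
#' @param lrpBelow,hrpAbove rate-band thresholds per year.
#' @return A data.frame (one row per patient) with `patient_id`,
#'   `rate_per_year`, `rate_class`, `pattern`; group sizes in
#'   `attr(, "summary")`.
#' @examples
#' cl <- data.frame(patient_id = c("a", "b"), n_recurrent_mets = c(0, 8),
#'                  followup_months = c(60, 24), cavity_progression = c(0, 1))
#' stratifyCohort(cl)
#' @export
stratifyCohort <- function(clinical, lrpBelow = 0.6, hrpAbove = 3.6) {
  if (!nrow(clinical)) stop("empty clinical table")
  if (anyDuplicated(clinical$patient_id))
    stop("duplicate patient_id(s): ",
         paste(unique(clinical$patient_id[duplicated(clinical$patient_id)]),
               collapse = ", "))
  rate <- computeRate(clinical$n_recurrent_mets, clinical$followup_months)
  cls <- classifyRate(rate, lrpBelow, hrpAbove)
  maxBurst <- if ("max_new_mets_in_4_months" %in% names(clinical))
    clinical$max_new_mets_in_4_months else rep(NA_integer_, nrow(clinical))
  pat <- vapply(seq_len(nrow(clinical)), function(i)
    classifyPattern(clinical$cavity_progression[i], maxBurst[i]), "")
  out <- data.frame(patient_id = clinical$patient_id,
                    rate_per_year = rate, rate_class = cls, pattern = pat,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- table(factor(cls, levels = c("LRP", "HRP", "IRP")))
  out
}

#' Read / write clinical tables
#'
#' CSV dialect: `patient_id`, `n_mets_at_surgery`, `surgery_date_or_t0`,
#' `time_to_first_recurrence_months` (empty when no recurrence),
#' `n_recurrent_mets`, `max_new_mets_in_4_months`, `cavity_progression`
#' (0/1), `followup_months`, `alive` (0/1), `survival_months`.
#'
#' @param path CSV path.
#' @return `readClinical()` returns a validated data.frame; `writeClinical()`
#'   its path, invisibly.
#' @export
readClinical <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  req <- c("patient_id", "n_recurrent_mets", "cavity_progression",
           "followup_months", "alive", "survival_months")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("clinical CSV lacks column(s): ", paste(missing, collapse = ", "))
  if (any(df$followup_months <= 0, na.rm = TRUE))
    stop("non-positive follow-up in clinical CSV")
  bad <- !is.na(df$time_to_first_recurrence_months) &
    df$time_to_first_recurrence_months > df$followup_months
  if (!is.null(df$time_to_first_recurrence_months) && any(bad))
    stop("time to first recurrence exceeds follow-up for: ",
         paste(df$patient_id[bad], collapse = ", "))
  inconsistent <- (df$n_recurrent_mets == 0) !=
    is.na(df$time_to_first_recurrence_months)
  if (!is.null(df$time_to_first_recurrence_months) && any(inconsistent))
    stop("recurrence count and first-recurrence time disagree for: ",
         paste(df$patient_id[inconsistent], collapse = ", "))
  df
}

#' @rdname readClinical
#' @param clinical data.frame to serialize.
#' @export
writeClinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, na = "")
  invisible(path)
}
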