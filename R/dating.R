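# Onset and last-activity dating from first/last recorded codes.
#
# Age at disease onset is approximated by the age at the first core
# diagnosis code (or first eczema-related prescription); age at last
# disease activity by the age at the last such code. Any conditioning of
# the cohort (e.g. keeping only patients with no symptoms in the year
# before their last visit) is a selection applied by the caller, not here.

#' Date one patient's first/last diagnosis and treatment codes
#'
#' First/last diagnosis ages use `CORE_DX` events only; first/last
#' prescription ages use any treatment-category event. A missing event
#' class yields `NA` ages (absence is a value, not an error).
#'
#' @param patient One-row data frame with `birth_date` (and `patient_id`).
#' @param events That patient's events (`date`, `code`).
#' @param lists A `codelist` collection.
#' @return A one-row data frame: `patient_id`, `first_dx_age`,
#'   `first_rx_age`, `last_dx_age`, `last_rx_age` (years).
#' @export
estimate_dates <- function(patient, events, lists) {
  birth <- as.Date(patient$birth_date[1])
  date <- as.Date(events$date)
  cat <- classify_code(events$code, lists)
  dx <- date[!is.na(cat) & cat == "CORE_DX"]
  rx <- date[!is.na(cat) & cat %in% treatment_categories()]
  age_or_na <- function(d, pick) {
    if (length(d) == 0L) NA_real_ else age_at(birth, pick(d))
  }
  data.frame(
    patient_id = as.character(patient$patient_id[1]),
    first_dx_age = age_or_na(dx, min),
    first_rx_age = age_or_na(rx, min),
    last_dx_age = age_or_na(dx, max),
    last_rx_age = age_or_na(rx, max),
    stringsAsFactors = FALSE
  )
}

#' Date first/last codes for every patient in a cohort
#'
#' Vectorised equivalent of [estimate_dates()] over all patients.
#'
#' @param x An `ehr_cohort`.
#' @param lists A `codelist` collection.
#' @return Data frame with one row per patient: `patient_id`,
#'   `first_dx_age`, `first_rx_age`, `last_dx_age`, `last_rx_age`.
#' @export
date_cohort <- function(x, lists) {
  stopifnot(inherits(x, "ehr_cohort"))
  ev <- as.data.table(x$events)
  out <- data.frame(patient_id = x$patients$patient_id,
                    first_dx_age = NA_real_, first_rx_age = NA_real_,
                    last_dx_age = NA_real_, last_rx_age = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(ev) == 0L) return(out)
  cat <- classify_code(ev$code, lists)
  ev[, category := cat]
  ev[, is_core := !is.na(category) & category == "CORE_DX"]
  ev[, is_treat := !is.na(category) & category %in% treatment_categories()]
  rng <- ev[is_core | is_treat, .(
    first_dx = if (any(is_core)) min(date[is_core]) else as.Date(NA),
    last_dx = if (any(is_core)) max(date[is_core]) else as.Date(NA),
    first_rx = if (any(is_treat)) min(date[is_treat]) else as.Date(NA),
    last_rx = if (any(is_treat)) max(date[is_treat]) else as.Date(NA)
  ), by = patient_id]
  idx <- match(out$patient_id, rng$patient_id)
  birth <- as.Date(x$patients$birth_date)
  to_age <- function(col) {
    d <- rng[[col]][idx]
    ifelse(is.na(d), NA_real_, as.numeric(as.Date(d, origin = "1970-01-01") - birth) / 365.25)
  }
  out$first_dx_age <- to_age("first_dx")
  out$first_rx_age <- to_age("first_rx")
  out$last_dx_age <- to_age("last_dx")
  out$last_rx_age <- to_age("last_rx")
  out
}
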