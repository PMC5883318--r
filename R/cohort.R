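# Longitudinal cohort model: patients with demographics and observation
# windows, plus date-stamped coded events. Dates are ISO 8601 only.

.parse_iso_date <- function(x, what, file = NULL) {
  x <- as.character(x)
  ok_format <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- as.Date(rep(NA_character_, length(x)))
  d[ok_format] <- as.Date(x[ok_format], format = "%Y-%m-%d", optional = TRUE)
  bad <- which(is.na(d) & !is.na(x) & nzchar(x))
  if (length(bad) > 0L) {
    where <- if (is.null(file)) "" else paste0(" in ", file)
    stop("unparseable ", what, " date '", x[bad[1]], "'", where,
         " at data line ", bad[1], call. = FALSE)
  }
  d
}

#' Construct a cohort
#'
#' Bundles a patient table and a longitudinal event table into an
#' `ehr_cohort`. Events with unknown `patient_id` are dropped with a counted
#' warning; patients whose registration starts before their recorded birth
#' date are rejected as data errors (also with a counted warning); events
#' are sorted ascending by date within patient with a stable sort, so
#' same-day events keep their input order.
#'
#' @param patients Data frame with columns `patient_id`, `birth_date`,
#'   `sex` (`male`/`female`/`unknown`), `reg_start`, `reg_end` (Date or
#'   ISO 8601 strings).
#' @param events Data frame with columns `patient_id`, `date`, `code`,
#'   `event_class` (`diagnosis`/`prescription`/`referral`/`other`).
#' @param reference_date Date used for age stratification (default
#'   2013-01-01).
#' @return An `ehr_cohort`: list with `patients`, `events`,
#'   `reference_date`.
#' @export
cohort <- function(patients, events, reference_date = as.Date("2013-01-01")) {
  req_p <- c("patient_id", "birth_date", "sex", "reg_start", "reg_end")
  req_e <- c("patient_id", "date", "code", "event_class")
  miss_p <- setdiff(req_p, names(patients))
  miss_e <- setdiff(req_e, names(events))
  if (length(miss_p) > 0L) {
    stop("patients table missing column(s): ", paste(miss_p, collapse = ", "),
         call. = FALSE)
  }
  if (length(miss_e) > 0L) {
    stop("events table missing column(s): ", paste(miss_e, collapse = ", "),
         call. = FALSE)
  }
  patients <- as.data.frame(patients)[, req_p]
  events <- as.data.frame(events)[, req_e]
  for (col in c("birth_date", "reg_start", "reg_end")) {
    if (!inherits(patients[[col]], "Date")) {
      patients[[col]] <- .parse_iso_date(patients[[col]], col, "patients")
    }
  }
  if (!inherits(events$date, "Date")) {
    events$date <- .parse_iso_date(events$date, "event", "events")
  }
  patients$patient_id <- as.character(patients$patient_id)
  events$patient_id <- as.character(events$patient_id)
  events$code <- canonicalise_code(as.character(events$code))
  if (any(!nzchar(events$code))) {
    stop("empty event code at data line ", which(!nzchar(events$code))[1],
         call. = FALSE)
  }
  if (anyDuplicated(patients$patient_id) > 0L) {
    stop("duplicate patient_id in patients table", call. = FALSE)
  }
  if (any(patients$reg_start > patients$reg_end)) {
    stop("reg_start after reg_end for patient ",
         patients$patient_id[which(patients$reg_start > patients$reg_end)[1]],
         call. = FALSE)
  }
  bad_birth <- patients$reg_start < patients$birth_date
  if (any(bad_birth)) {
    warning(sum(bad_birth),
            " patient(s) rejected: registration starts before birth date",
            call. = FALSE)
    patients <- patients[!bad_birth, , drop = FALSE]
  }
  orphan <- !(events$patient_id %in% patients$patient_id)
  if (any(orphan)) {
    warning(sum(orphan), " orphan event(s) dropped (unknown patient_id)",
            call. = FALSE)
    events <- events[!orphan, , drop = FALSE]
  }
  # stable sort: ties on (patient, date) keep input order
  ord <- order(events$patient_id, events$date, method = "radix")
  events <- events[ord, , drop = FALSE]
  rownames(patients) <- rownames(events) <- NULL
  structure(
    list(patients = patients, events = events,
         reference_date = as.Date(reference_date)),
    class = "ehr_cohort"
  )
}

#' Read a cohort from CSV files
#'
#' Reads `patients.csv` (`patient_id,birth_date,sex,reg_start,reg_end`) and
#' `events.csv` (`patient_id,date,code,event_class`), both with a header
#' row, dates ISO 8601. See [cohort()] for the validation applied.
#'
#' @param patients_path,events_path Paths to the two CSV files.
#' @param reference_date Stratification reference date.
#' @return An `ehr_cohort`.
#' @export
read_cohort <- function(patients_path, events_path,
                        reference_date = as.Date("2013-01-01")) {
  for (p in c(patients_path, events_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  patients <- read.csv(patients_path, colClasses = "character",
                       fileEncoding = "UTF-8")
  events <- read.csv(events_path, colClasses = "character",
                     fileEncoding = "UTF-8")
  cohort(patients, events, reference_date = reference_date)
}

#' Write a cohort to CSV files
#'
#' @param x An `ehr_cohort`.
#' @param dir Output directory (created if needed); writes `patients.csv`
#'   and `events.csv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "ehr_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- x$patients
  e <- x$events
  for (col in c("birth_date", "reg_start", "reg_end")) p[[col]] <- format(p[[col]])
  e$date <- format(e$date)
  write.csv(p, file.path(dir, "patients.csv"), row.names = FALSE, quote = FALSE)
  write.csv(e, file.path(dir, "events.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Age in years at a date
#'
#' Day-count convention: `(date - birth_date) / 365.25`.
#'
#' @param birth_date,date Date vectors (recycled).
#' @return Non-negative numeric years.
#' @export
#' @examples
#' age_at(as.Date("2000-01-01"), as.Date("2010-01-01"))
age_at <- function(birth_date, date) {
  birth_date <- as.Date(birth_date)
  date <- as.Date(date)
  if (any(date < birth_date)) {
    stop("date precedes birth_date", call. = FALSE)
  }
  as.numeric(date - birth_date) / 365.25
}

#' Child/adult stratum at a reference date
#'
#' Children are the half-open age interval \[0, 18) years at
#' `reference_date`; exactly 18.0 years is an adult.
#'
#' @param birth_date Date vector.
#' @param reference_date Date (default 2013-01-01).
#' @return Character vector, `"child"` or `"adult"`.
#' @export
stratum <- function(birth_date, reference_date = as.Date("2013-01-01")) {
  ifelse(age_at(birth_date, reference_date) < 18, "child", "adult")
}

#' Restrict events to each patient's registration window
#'
#' By default a cohort retains events dated outside
#' \[`reg_start`, `reg_end`\]; this filter drops them for analyses that
#' should only see in-registration records.
#'
#' @param x An `ehr_cohort`.
#' @return An `ehr_cohort` with filtered events.
#' @export
within_registration <- function(x) {
  stopifnot(inherits(x, "ehr_cohort"))
  idx <- match(x$events$patient_id, x$patients$patient_id)
  keep <- x$events$date >= x$patients$reg_start[idx] &
    x$events$date <= x$patients$reg_end[idx]
  x$events <- x$events[keep, , drop = FALSE]
  rownames(x$events) <- NULL
  x
}

#' @export
print.ehr_cohort <- function(x, ...) {
  st <- stratum(x$patients$birth_date, x$reference_date)
  cat("<ehr_cohort> ", nrow(x$patients), " patients (",
      sum(st == "child"), " children, ", sum(st == "adult"), " adults at ",
      format(x$reference_date), "), ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}
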