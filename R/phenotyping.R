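# Declarative case definitions and their evaluation against event streams.
#
# A case definition combines a minimum number of distinct dates carrying a
# core diagnosis code with a minimum number of distinct treatment dates,
# optionally tightened by drug-class specificity, a diagnosis-treatment
# temporal window, exclusion-free records, atopy codes or dermatology
# consults. Treatment events may precede the diagnosis: chronic disease is
# often treated before (or without) a fresh diagnostic code.

#' Construct a case-definition rule set
#'
#' @param name Label for the rule set.
#' @param min_core_dx Minimum distinct calendar dates carrying a `CORE_DX`
#'   code (>= 1). Two core codes on one day count once: the requirement is
#'   a second coded *occasion*, evidence of chronicity.
#' @param min_treatment_dates Minimum distinct dates carrying any
#'   eczema-related treatment code (>= 0); different drugs on one date
#'   count once.
#' @param min_specific_treatments Of the treatment dates, how many must
#'   carry a topical steroid or topical calcineurin inhibitor code.
#' @param temporal_window `NULL`, or `c(days_before, days_after)`: require
#'   at least one steroid/TCI event within `days_before` days before or
#'   `days_after` days after some core diagnosis event (endpoints
#'   inclusive).
#' @param require_no_exclusion Require zero `EXCLUSION` events anywhere in
#'   the record.
#' @param require_atopy Require at least one `ATOPY` event (asthma or
#'   rhinitis code).
#' @param require_derm_consult Require at least one `DERM_CONSULT` event.
#' @return An `algorithm_spec`.
#' @export
algorithm_spec <- function(name = "custom",
                           min_core_dx = 1L,
                           min_treatment_dates = 2L,
                           min_specific_treatments = 0L,
                           temporal_window = NULL,
                           require_no_exclusion = FALSE,
                           require_atopy = FALSE,
                           require_derm_consult = FALSE) {
  min_core_dx <- as.integer(min_core_dx)
  min_treatment_dates <- as.integer(min_treatment_dates)
  min_specific_treatments <- as.integer(min_specific_treatments)
  stopifnot(min_core_dx >= 1L, min_treatment_dates >= 0L,
            min_specific_treatments >= 0L)
  if (min_specific_treatments > min_treatment_dates) {
    stop("min_specific_treatments cannot exceed min_treatment_dates",
         call. = FALSE)
  }
  if (!is.null(temporal_window)) {
    temporal_window <- as.integer(temporal_window)
    if (length(temporal_window) != 2L || any(temporal_window < 0L)) {
      stop("temporal_window must be c(days_before, days_after), both >= 0",
           call. = FALSE)
    }
    names(temporal_window) <- c("days_before", "days_after")
  }
  structure(
    list(name = name,
         min_core_dx = min_core_dx,
         min_treatment_dates = min_treatment_dates,
         min_specific_treatments = min_specific_treatments,
         temporal_window = temporal_window,
         require_no_exclusion = isTRUE(require_no_exclusion),
         require_atopy = isTRUE(require_atopy),
         require_derm_consult = isTRUE(require_derm_consult)),
    class = "algorithm_spec"
  )
}

#' Preset case definitions
#'
#' The baseline definition (one of five core eczema codes plus at least two
#' treatment codes on separate dates) and the nine published variants of
#' increasing stringency:
#'
#' * `baseline` — 1 core dx date + 2 treatment dates.
#' * `steroid1` — baseline; >= 1 treatment date carries a steroid/TCI code.
#' * `steroid2` — baseline; >= 2 treatment dates carry steroid/TCI codes.
#' * `window` — baseline; a steroid/TCI event within 3 months (91 days)
#'   before to 1 year (365 days) after a core diagnosis code.
#' * `twocodes` — baseline with a second core diagnosis date.
#' * `twocodes_steroid1`, `twocodes_steroid2` — `twocodes` plus the
#'   steroid/TCI counts above.
#' * `no_exclusion` — baseline + no exclusionary condition code, ever.
#' * `atopy` — baseline + an asthma or rhinitis code.
#' * `derm_consult` — baseline + a dermatology consult code.
#'
#' @param name One of the preset names above.
#' @return An `algorithm_spec`.
#' @export
#' @examples
#' preset("baseline")$min_treatment_dates
preset <- function(name) {
  specs <- list(
    baseline          = algorithm_spec("baseline"),
    steroid1          = algorithm_spec("steroid1", min_specific_treatments = 1L),
    steroid2          = algorithm_spec("steroid2", min_specific_treatments = 2L),
    window            = algorithm_spec("window", temporal_window = c(91L, 365L)),
    twocodes          = algorithm_spec("twocodes", min_core_dx = 2L),
    twocodes_steroid1 = algorithm_spec("twocodes_steroid1", min_core_dx = 2L,
                                       min_specific_treatments = 1L),
    twocodes_steroid2 = algorithm_spec("twocodes_steroid2", min_core_dx = 2L,
                                       min_specific_treatments = 2L),
    no_exclusion      = algorithm_spec("no_exclusion", require_no_exclusion = TRUE),
    atopy             = algorithm_spec("atopy", require_atopy = TRUE),
    derm_consult      = algorithm_spec("derm_consult", require_derm_consult = TRUE)
  )
  if (!name %in% names(specs)) {
    stop("unknown preset '", name, "'; valid names: ",
         paste(names(specs), collapse = ", "), call. = FALSE)
  }
  specs[[name]]
}

#' Names of all preset case definitions
#' @return Character vector, baseline first.
#' @export
preset_names <- function() {
  c("baseline", "steroid1", "steroid2", "window", "twocodes",
    "twocodes_steroid1", "twocodes_steroid2", "no_exclusion", "atopy",
    "derm_consult")
}

#' Serialise / deserialise a rule set
#'
#' @param spec An `algorithm_spec`.
#' @param path YAML file path.
#' @return `write_algorithm_spec` returns `path` invisibly;
#'   `read_algorithm_spec` returns an `algorithm_spec`.
#' @export
write_algorithm_spec <- function(spec, path) {
  stopifnot(inherits(spec, "algorithm_spec"))
  x <- unclass(spec)
  if (!is.null(x$temporal_window)) x$temporal_window <- as.list(x$temporal_window)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_algorithm_spec
#' @export
read_algorithm_spec <- function(path) {
  x <- yaml::read_yaml(path)
  tw <- if (!is.null(x$temporal_window)) {
    c(x$temporal_window$days_before, x$temporal_window$days_after)
  }
  algorithm_spec(
    name = x$name %||% "custom",
    min_core_dx = x$min_core_dx %||% 1L,
    min_treatment_dates = x$min_treatment_dates %||% 2L,
    min_specific_treatments = x$min_specific_treatments %||% 0L,
    temporal_window = tw,
    require_no_exclusion = x$require_no_exclusion %||% FALSE,
    require_atopy = x$require_atopy %||% FALSE,
    require_derm_consult = x$require_derm_consult %||% FALSE
  )
}

#' @export
print.algorithm_spec <- function(x, ...) {
  cat("<algorithm_spec> ", x$name, "\n",
      "  core dx dates >= ", x$min_core_dx,
      "; treatment dates >= ", x$min_treatment_dates,
      "; steroid/TCI dates >= ", x$min_specific_treatments, "\n", sep = "")
  if (!is.null(x$temporal_window)) {
    cat("  steroid/TCI within [dx - ", x$temporal_window[["days_before"]],
        "d, dx + ", x$temporal_window[["days_after"]], "d]\n", sep = "")
  }
  flags <- c("no exclusion code" = x$require_no_exclusion,
             "atopy code" = x$require_atopy,
             "dermatology consult" = x$require_derm_consult)
  if (any(flags)) cat("  requires:", paste(names(flags)[flags], collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a case definition on one patient's events
#'
#' Applies each criterion of `spec` to the patient's coded events and
#' returns the decision with the evidence events satisfying each criterion.
#' Criteria (all must hold): (1) >= `min_core_dx` distinct dates with a
#' `CORE_DX` code; (2) >= `min_treatment_dates` distinct dates with any
#' treatment-category code; (3) >= `min_specific_treatments` of those dates
#' with a steroid/TCI code; (4) if a temporal window is set, some
#' steroid/TCI event within it of some core diagnosis event; (5)–(7) the
#' exclusion/atopy/consult flags. An empty event sequence is a negative
#' result, not an error. Decisions are invariant to the input order of
#' events.
#'
#' @param events Data frame of one patient's events (`date`, `code`; extra
#'   columns ignored).
#' @param spec An `algorithm_spec`.
#' @param lists A `codelist` collection covering every category the spec
#'   references.
#' @return A `phenotype_result`: list with `patient_id`, `positive`,
#'   `evidence` (per-criterion data frames), `counts`, `spec_name`.
#' @export
evaluate_patient <- function(events, spec, lists) {
  stopifnot(inherits(spec, "algorithm_spec"))
  pid <- if (nrow(events) > 0 && "patient_id" %in% names(events)) {
    events$patient_id[1]
  } else {
    NA_character_
  }
  date <- as.Date(events$date)
  cat <- classify_code(events$code, lists)
  is_core <- !is.na(cat) & cat == "CORE_DX"
  is_treat <- !is.na(cat) & cat %in% treatment_categories()
  is_spec <- !is.na(cat) & cat %in% specific_treatment_categories()

  evidence <- list()
  ok <- logical(0)

  core_dates <- unique(date[is_core])
  ok["core_dx"] <- length(core_dates) >= spec$min_core_dx
  evidence$core_dx <- events[is_core, , drop = FALSE]

  treat_dates <- unique(date[is_treat])
  ok["treatment_dates"] <- length(treat_dates) >= spec$min_treatment_dates
  evidence$treatment_dates <- events[is_treat, , drop = FALSE]

  spec_dates <- unique(date[is_spec])
  if (spec$min_specific_treatments > 0L) {
    ok["specific_treatments"] <- length(spec_dates) >= spec$min_specific_treatments
    evidence$specific_treatments <- events[is_spec, , drop = FALSE]
  }

  if (!is.null(spec$temporal_window)) {
    before <- spec$temporal_window[["days_before"]]
    after <- spec$temporal_window[["days_after"]]
    hit <- FALSE
    if (length(core_dates) > 0L && length(spec_dates) > 0L) {
      diffs <- outer(as.numeric(spec_dates), as.numeric(core_dates), "-")
      hit <- any(diffs >= -before & diffs <= after)
    }
    ok["temporal_window"] <- hit
    evidence$temporal_window <- events[is_spec, , drop = FALSE]
  }

  if (spec$require_no_exclusion) {
    is_excl <- !is.na(cat) & cat == "EXCLUSION"
    ok["no_exclusion"] <- !any(is_excl)
    # evidence for an absence criterion: the offending events, if any
    evidence$no_exclusion <- events[is_excl, , drop = FALSE]
  }
  if (spec$require_atopy) {
    is_atopy <- !is.na(cat) & cat == "ATOPY"
    ok["atopy"] <- any(is_atopy)
    evidence$atopy <- events[is_atopy, , drop = FALSE]
  }
  if (spec$require_derm_consult) {
    is_derm <- !is.na(cat) & cat == "DERM_CONSULT"
    ok["derm_consult"] <- any(is_derm)
    evidence$derm_consult <- events[is_derm, , drop = FALSE]
  }

  structure(
    list(patient_id = pid,
         positive = all(ok),
         criteria = ok,
         evidence = evidence,
         counts = c(n_core_dx_dates = length(core_dates),
                    n_treatment_dates = length(treat_dates),
                    n_specific_dates = length(spec_dates)),
         spec_name = spec$name),
    class = "phenotype_result"
  )
}

#' @export
print.phenotype_result <- function(x, ...) {
  cat("<phenotype_result> patient ", x$patient_id, " [", x$spec_name, "]: ",
      if (x$positive) "POSITIVE" else "negative", "\n", sep = "")
  print(x$criteria)
  invisible(x)
}

#' Apply a case definition to a whole cohort
#'
#' Vectorised evaluation of `spec` over every patient, equivalent to
#' [evaluate_patient()] patient by patient. Returns one row per patient
#' with the decision and the per-criterion date counts, plus a summary of
#' positives overall and by child/adult stratum as an attribute.
#'
#' @param x An `ehr_cohort`.
#' @param spec An `algorithm_spec` (or preset name).
#' @param lists A `codelist` collection.
#' @return Data frame (`patient_id`, `positive`, `n_core_dx_dates`,
#'   `n_treatment_dates`, `n_specific_dates`, `stratum`, `spec_name`) with
#'   attribute `summary`.
#' @export
phenotype_cohort <- function(x, spec, lists) {
  stopifnot(inherits(x, "ehr_cohort"))
  if (is.character(spec)) spec <- preset(spec)
  ev <- as.data.table(x$events)
  if (nrow(ev) == 0L) {
    ev <- data.table(patient_id = character(), date = as.Date(character()),
                     code = character())
  }
  cat <- classify_code(ev$code, lists)
  ev[, category := cat]
  ev[, is_core := !is.na(category) & category == "CORE_DX"]
  ev[, is_treat := !is.na(category) & category %in% treatment_categories()]
  ev[, is_specific := !is.na(category) & category %in% specific_treatment_categories()]

  per <- ev[, .(
    n_core_dx_dates = length(unique(date[is_core])),
    n_treatment_dates = length(unique(date[is_treat])),
    n_specific_dates = length(unique(date[is_specific])),
    n_exclusion = sum(!is.na(category) & category == "EXCLUSION"),
    n_atopy = sum(!is.na(category) & category == "ATOPY"),
    n_derm = sum(!is.na(category) & category == "DERM_CONSULT")
  ), by = patient_id]

  out <- data.frame(patient_id = x$patients$patient_id,
                    stringsAsFactors = FALSE)
  idx <- match(out$patient_id, per$patient_id)
  take <- function(col) ifelse(is.na(idx), 0L, per[[col]][idx])
  out$n_core_dx_dates <- take("n_core_dx_dates")
  out$n_treatment_dates <- take("n_treatment_dates")
  out$n_specific_dates <- take("n_specific_dates")

  positive <- out$n_core_dx_dates >= spec$min_core_dx &
    out$n_treatment_dates >= spec$min_treatment_dates &
    out$n_specific_dates >= spec$min_specific_treatments
  if (spec$require_no_exclusion) positive <- positive & take("n_exclusion") == 0L
  if (spec$require_atopy) positive <- positive & take("n_atopy") > 0L
  if (spec$require_derm_consult) positive <- positive & take("n_derm") > 0L

  if (!is.null(spec$temporal_window)) {
    before <- spec$temporal_window[["days_before"]]
    after <- spec$temporal_window[["days_after"]]
    cand <- out$patient_id[positive]
    sub <- ev[patient_id %in% cand & (is_core | is_specific)]
    win_ok <- sub[, {
      dx <- unique(as.numeric(date[is_core]))
      tx <- unique(as.numeric(date[is_specific]))
      hit <- length(dx) > 0L && length(tx) > 0L &&
        any(outer(tx, dx, "-") >= -before & outer(tx, dx, "-") <= after)
      .(ok = hit)
    }, by = patient_id]
    ok_ids <- win_ok$patient_id[win_ok$ok]
    positive <- positive & out$patient_id %in% ok_ids
  }

  out$positive <- positive
  out$stratum <- as.character(stratum(x$patients$birth_date, x$reference_date))
  out$spec_name <- rep(spec$name, nrow(out))
  out <- out[, c("patient_id", "positive", "n_core_dx_dates",
                 "n_treatment_dates", "n_specific_dates", "stratum",
                 "spec_name")]
  attr(out, "summary") <- c(
    n = nrow(out),
    positives = sum(out$positive),
    positives_child = sum(out$positive & out$stratum == "child"),
    positives_adult = sum(out$positive & out$stratum == "adult")
  )
  out
}
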