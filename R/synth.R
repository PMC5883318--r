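# Seeded generator of synthetic coded cohorts with planted ground truth.
#
# The generator emulates the coded-record structure the phenotyping rules
# operate on: rarely repeated core diagnosis codes (low mean count with
# small spread), heavily overdispersed prescription counts, a configurable
# probability that an algorithm-positive patient is physician-confirmed,
# and noisy offsets between the physician's recalled onset/last-activity
# ages and the first/last recorded codes. It is a test harness, not an
# epidemiological model: calendar structure, consultation patterns and
# code-vocabulary breadth are deliberately minimal.

#' Synthetic code vocabulary
#'
#' A code-list collection pairing the built-in core diagnosis codes with
#' small synthetic lists for every other category the case definitions
#' reference (treatment classes, exclusions, atopy, dermatology consults).
#' All non-core codes are invented tokens, present only so generated
#' cohorts exercise every rule; they correspond to no real clinical
#' terminology.
#'
#' @return A `codelist` collection.
#' @export
synth_codelists <- function() {
  syn <- function(codes, what, category) {
    new_codelist(codes, paste("synthetic", what, seq_along(codes)), category,
                 provenance = "synthetic")
  }
  codelist_collection(
    builtin_core_codes(),
    syn(paste0("EMOL00", 1:4), "emollient", "EMOLLIENT"),
    syn(paste0("TSTER0", 1:4), "topical steroid", "TOPICAL_STEROID"),
    syn(paste0("TCI00", 1:2), "topical calcineurin inhibitor", "TCI"),
    syn(paste0("TABX0", 1:2), "topical anti-infective", "TOPICAL_ANTIINFECTIVE"),
    syn(paste0("SYST0", 1:2), "systemic immunomodulator", "SYSTEMIC"),
    syn("PHOT01", "phototherapy", "PHOTOTHERAPY"),
    syn(paste0("EXCL0", 1:3), "exclusionary condition", "EXCLUSION"),
    syn(paste0("ATOP0", 1:2), "asthma/rhinitis", "ATOPY"),
    syn("DERM01", "dermatology consult", "DERM_CONSULT")
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the coded-record structure the generator emulates: 13%
#' of patients are true cases (the share of the source population with at
#' least one core eczema code), cases carry a mean of 1.2 (SD 0.5) core
#' diagnosis codes and a mean of 16.3 (SD 24.5) eczema-related
#' prescriptions, 86% of algorithm-positive patients are
#' physician-confirmed, and the physician's recalled onset age differs
#' from the first recorded diagnosis age by N(0.8, 5) years (last activity
#' by N(-1.3, 4.5) years relative to the last recorded code).
#'
#' @param n_patients Number of patients.
#' @param child_fraction Proportion aged under 18 at the reference date.
#' @param seed Integer seed; the whole generation is deterministic given it.
#' @param case_prevalence Proportion of patients who are true cases.
#' @param confirm_prob_given_positive Probability an algorithm-positive
#'   patient is physician-confirmed (the planted PPV).
#' @param dx_count_mean,dx_count_sd Moments of the per-case core-code
#'   count (integer support >= 1; see Details).
#' @param rx_count_mean,rx_count_sd Moments of the per-case prescription
#'   count; requires `rx_count_sd^2 > rx_count_mean` for the
#'   negative-binomial match unless `rx_dist = "poisson"`.
#' @param rx_dist `"nbinom"` (moment-matched, default) or `"poisson"`
#'   (ignores `rx_count_sd`).
#' @param treat_noncase_rate Expected emollient scripts per non-case
#'   (Poisson).
#' @param stray_dx_prob Probability a non-case carries one stray core
#'   diagnosis code.
#' @param onset_lag_mean,onset_lag_sd Years between first recorded
#'   diagnosis age and physician-recalled onset age (survey minus
#'   database).
#' @param last_activity_lead_mean,last_activity_lead_sd Years between last
#'   recorded code age and physician-recalled last-activity age (survey
#'   minus database).
#' @param nonresponse_prob Probability a surveyed label is missing
#'   (unreturned or incomplete survey).
#' @param exclusion_rate_case,exclusion_rate_noncase,atopy_rate_case,
#'   atopy_rate_noncase,derm_rate_case,derm_rate_noncase Per-patient
#'   probabilities of carrying at least one code of the flag categories.
#' @param rx_mix Named probabilities over treatment categories for each
#'   prescription event.
#' @param reference_date Stratification reference date.
#' @return A validated `synth_config` list.
#' @details Core-code counts use a 1-shifted negative binomial matched to
#'   the configured mean/SD (shifted Poisson when `sd^2 <= mean - 1`),
#'   giving integer support >= 1 with both moments reproduced exactly.
#' @export
synth_config <- function(n_patients = 1000L,
                         child_fraction = 0.5,
                         seed = 1L,
                         case_prevalence = 0.13,
                         confirm_prob_given_positive = 0.86,
                         dx_count_mean = 1.2, dx_count_sd = 0.5,
                         rx_count_mean = 16.3, rx_count_sd = 24.5,
                         rx_dist = c("nbinom", "poisson"),
                         treat_noncase_rate = 0.5,
                         stray_dx_prob = 0.005,
                         onset_lag_mean = 0.8, onset_lag_sd = 5,
                         last_activity_lead_mean = -1.3,
                         last_activity_lead_sd = 4.5,
                         nonresponse_prob = 0.055,
                         exclusion_rate_case = 0.15,
                         exclusion_rate_noncase = 0.115,
                         atopy_rate_case = 0.41,
                         atopy_rate_noncase = 0.24,
                         derm_rate_case = 0.11,
                         derm_rate_noncase = 0.04,
                         rx_mix = c(EMOLLIENT = 0.40, TOPICAL_STEROID = 0.48,
                                    TCI = 0.05, TOPICAL_ANTIINFECTIVE = 0.04,
                                    SYSTEMIC = 0.02, PHOTOTHERAPY = 0.01),
                         reference_date = as.Date("2013-01-01")) {
  rx_dist <- match.arg(rx_dist)
  props <- c(child_fraction, case_prevalence, confirm_prob_given_positive,
             stray_dx_prob, nonresponse_prob, exclusion_rate_case,
             exclusion_rate_noncase, atopy_rate_case, atopy_rate_noncase,
             derm_rate_case, derm_rate_noncase)
  if (any(props < 0 | props > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_patients < 0 || dx_count_sd < 0 || rx_count_sd < 0 ||
      treat_noncase_rate < 0 || onset_lag_sd < 0 || last_activity_lead_sd < 0) {
    stop("counts, rates and SDs must be non-negative", call. = FALSE)
  }
  if (dx_count_mean < 1) stop("dx_count_mean must be >= 1", call. = FALSE)
  if (rx_dist == "nbinom" && rx_count_sd^2 <= rx_count_mean) {
    stop("rx_count_sd^2 must exceed rx_count_mean for the negative-",
         "binomial moment match; set rx_dist = \"poisson\" for ",
         "equidispersed counts", call. = FALSE)
  }
  if (abs(sum(rx_mix) - 1) > 1e-8 || any(rx_mix < 0) ||
      !all(names(rx_mix) %in% treatment_categories())) {
    stop("rx_mix must be non-negative probabilities over treatment ",
         "categories summing to 1", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         child_fraction = child_fraction, seed = as.integer(seed),
         case_prevalence = case_prevalence,
         confirm_prob_given_positive = confirm_prob_given_positive,
         dx_count_mean = dx_count_mean, dx_count_sd = dx_count_sd,
         rx_count_mean = rx_count_mean, rx_count_sd = rx_count_sd,
         rx_dist = rx_dist,
         treat_noncase_rate = treat_noncase_rate,
         stray_dx_prob = stray_dx_prob,
         onset_lag_mean = onset_lag_mean, onset_lag_sd = onset_lag_sd,
         last_activity_lead_mean = last_activity_lead_mean,
         last_activity_lead_sd = last_activity_lead_sd,
         nonresponse_prob = nonresponse_prob,
         exclusion_rate_case = exclusion_rate_case,
         exclusion_rate_noncase = exclusion_rate_noncase,
         atopy_rate_case = atopy_rate_case,
         atopy_rate_noncase = atopy_rate_noncase,
         derm_rate_case = derm_rate_case,
         derm_rate_noncase = derm_rate_noncase,
         rx_mix = rx_mix,
         reference_date = as.Date(reference_date)),
    class = "synth_config"
  )
}

# integer counts >= `shift`, matching (mean, sd) exactly via a shifted
# negative binomial; shifted Poisson when the residual variance allows no
# overdispersion
.r_shifted_count <- function(n, mean, sd, shift = 1) {
  mu <- mean - shift
  v <- sd^2
  if (n == 0L) return(integer(0))
  if (mu <= 0) return(rep(shift, n))
  if (v > mu) {
    size <- mu^2 / (v - mu)
    shift + rnbinom(n, size = size, mu = mu)
  } else {
    shift + rpois(n, mu)
  }
}

.r_count <- function(n, mean, sd, dist) {
  if (n == 0L) return(integer(0))
  if (dist == "poisson" || sd^2 <= mean) return(rpois(n, mean))
  size <- mean^2 / (sd^2 - mean)
  rnbinom(n, size = size, mu = mean)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Deterministic given `config$seed`. True cases receive core diagnosis
#' codes and eczema-related prescriptions placed uniformly over their
#' registration window from a random onset date onward; non-cases receive
#' sporadic emollient scripts and, rarely, a stray diagnosis code. Flag
#' codes (exclusionary conditions, asthma/rhinitis, dermatology consults)
#' are sprinkled at the configured per-patient rates. After event
#' generation the baseline case definition is evaluated and each
#' algorithm-positive patient is labelled physician-confirmed with
#' probability `confirm_prob_given_positive` (algorithm-negative patients
#' carry their true-case status); a configurable fraction of labels is
#' then set to missing to mimic survey non-response. Physician-recalled
#' onset and last-activity ages are the first/last recorded-code ages plus
#' normal recall noise.
#'
#' @param config A [synth_config()].
#' @return List with `cohort` (an `ehr_cohort`) and `truth` (data frame:
#'   `patient_id`, `true_case`, `algorithm_positive`,
#'   `physician_confirmed` = yes/no/missing, `stratum`, `true_onset_age`,
#'   `true_last_activity_age`; onset/last ages are `NA` for non-cases).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ref <- config$reference_date
  lists <- synth_codelists()

  if (n == 0L) {
    empty_p <- data.frame(patient_id = character(), birth_date = as.Date(character()),
                          sex = character(), reg_start = as.Date(character()),
                          reg_end = as.Date(character()), stringsAsFactors = FALSE)
    empty_e <- data.frame(patient_id = character(), date = as.Date(character()),
                          code = character(), event_class = character(),
                          stringsAsFactors = FALSE)
    truth <- data.frame(patient_id = character(), true_case = logical(),
                        algorithm_positive = logical(),
                        physician_confirmed = character(), stratum = character(),
                        true_onset_age = numeric(), true_last_activity_age = numeric(),
                        stringsAsFactors = FALSE)
    return(list(cohort = cohort(empty_p, empty_e, reference_date = ref),
                truth = truth))
  }

  pid <- sprintf("P%06d", seq_len(n))
  is_child <- runif(n) < config$child_fraction
  age_ref <- ifelse(is_child, runif(n, 0.5, 17.99), runif(n, 18, 85))
  birth <- ref - round(age_ref * 365.25)
  reg_start <- birth
  reg_end <- ref + round(runif(n, 0, 730))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  patients <- data.frame(patient_id = pid, birth_date = birth, sex = sex,
                         reg_start = reg_start, reg_end = reg_end,
                         stringsAsFactors = FALSE)

  true_case <- runif(n) < config$case_prevalence

  core <- builtin_core_codes()
  dx_codes <- core$code
  dx_weights <- c(116, 30, 16, 3, 86) / 251  # relative use of the five codes
  rx_codes_by_cat <- list(
    EMOLLIENT = paste0("EMOL00", 1:4),
    TOPICAL_STEROID = paste0("TSTER0", 1:4),
    TCI = paste0("TCI00", 1:2),
    TOPICAL_ANTIINFECTIVE = paste0("TABX0", 1:2),
    SYSTEMIC = paste0("SYST0", 1:2),
    PHOTOTHERAPY = "PHOT01"
  )

  ev_pid <- character(0); ev_date <- numeric(0)
  ev_code <- character(0); ev_class <- character(0)
  add_events <- function(idx, dates, codes, class) {
    ev_pid <<- c(ev_pid, pid[idx])
    ev_date <<- c(ev_date, as.numeric(dates))
    ev_code <<- c(ev_code, codes)
    ev_class <<- c(ev_class, rep(class, length(idx)))
  }

  ci <- which(true_case)
  window_start <- rep(as.numeric(reg_start), 1)
  window_end <- as.numeric(reg_end)
  onset_num <- rep(NA_real_, n)
  if (length(ci) > 0L) {
    span_years <- (window_end[ci] - window_start[ci]) / 365.25
    onset_age <- runif(length(ci), 0.25, pmax(0.30, span_years - 0.1))
    onset_num[ci] <- window_start[ci] + onset_age * 365.25

    n_dx <- .r_shifted_count(length(ci), config$dx_count_mean,
                             config$dx_count_sd, shift = 1)
    rep_i <- rep(ci, n_dx)
    u <- runif(length(rep_i))
    dx_dates <- round(onset_num[rep_i] + u * (window_end[rep_i] - onset_num[rep_i]))
    add_events(rep_i, dx_dates,
               sample(dx_codes, length(rep_i), replace = TRUE, prob = dx_weights),
               "diagnosis")

    n_rx <- .r_count(length(ci), config$rx_count_mean, config$rx_count_sd,
                     config$rx_dist)
    rep_i <- rep(ci, n_rx)
    if (length(rep_i) > 0L) {
      u <- runif(length(rep_i))
      rx_dates <- round(onset_num[rep_i] + u * (window_end[rep_i] - onset_num[rep_i]))
      cats <- sample(names(config$rx_mix), length(rep_i), replace = TRUE,
                     prob = config$rx_mix)
      codes <- vapply(cats, function(cc) sample(rx_codes_by_cat[[cc]], 1L),
                      character(1), USE.NAMES = FALSE)
      add_events(rep_i, rx_dates, codes, "prescription")
    }
  }

  nci <- which(!true_case)
  if (length(nci) > 0L) {
    n_rx0 <- rpois(length(nci), config$treat_noncase_rate)
    rep_i <- rep(nci, n_rx0)
    if (length(rep_i) > 0L) {
      u <- runif(length(rep_i))
      dates <- round(window_start[rep_i] + u * (window_end[rep_i] - window_start[rep_i]))
      add_events(rep_i, dates,
                 sample(rx_codes_by_cat$EMOLLIENT, length(rep_i), replace = TRUE),
                 "prescription")
    }
    stray <- nci[runif(length(nci)) < config$stray_dx_prob]
    if (length(stray) > 0L) {
      u <- runif(length(stray))
      dates <- round(window_start[stray] + u * (window_end[stray] - window_start[stray]))
      add_events(stray, dates,
                 sample(dx_codes, length(stray), replace = TRUE, prob = dx_weights),
                 "diagnosis")
    }
  }

  flag_events <- function(rate_case, rate_noncase, codes, class) {
    rate <- ifelse(true_case, rate_case, rate_noncase)
    has <- which(runif(n) < rate)
    if (length(has) == 0L) return(invisible(NULL))
    u <- runif(length(has))
    dates <- round(window_start[has] + u * (window_end[has] - window_start[has]))
    add_events(has, dates, sample(codes, length(has), replace = TRUE), class)
  }
  flag_events(config$exclusion_rate_case, config$exclusion_rate_noncase,
              paste0("EXCL0", 1:3), "diagnosis")
  flag_events(config$atopy_rate_case, config$atopy_rate_noncase,
              paste0("ATOP0", 1:2), "diagnosis")
  flag_events(config$derm_rate_case, config$derm_rate_noncase,
              "DERM01", "referral")

  events <- data.frame(patient_id = ev_pid,
                       date = as.Date(ev_date, origin = "1970-01-01"),
                       code = ev_code, event_class = ev_class,
                       stringsAsFactors = FALSE)
  coh <- cohort(patients, events, reference_date = ref)

  base <- phenotype_cohort(coh, preset("baseline"), lists)
  alg_pos <- base$positive[match(pid, base$patient_id)]

  confirmed <- ifelse(alg_pos,
                      runif(n) < config$confirm_prob_given_positive,
                      true_case)
  label <- ifelse(confirmed, "yes", "no")
  label[runif(n) < config$nonresponse_prob] <- "missing"

  dates_tbl <- date_cohort(coh, lists)
  first_dx_age <- dates_tbl$first_dx_age[match(pid, dates_tbl$patient_id)]
  last_code_age <- pmax(dates_tbl$last_dx_age[match(pid, dates_tbl$patient_id)],
                        dates_tbl$last_rx_age[match(pid, dates_tbl$patient_id)],
                        na.rm = TRUE)
  # Recalled ages are planted labels: the noise is left unbounded so the
  # configured mean offset is exactly recoverable by the agreement analysis
  # (bounding at zero would bias the planted mean for young patients).
  onset_noise <- rnorm(n, config$onset_lag_mean, config$onset_lag_sd)
  last_noise <- rnorm(n, config$last_activity_lead_mean,
                      config$last_activity_lead_sd)
  true_onset <- ifelse(true_case, first_dx_age + onset_noise, NA_real_)
  true_last <- ifelse(true_case, last_code_age + last_noise, NA_real_)

  truth <- data.frame(
    patient_id = pid,
    true_case = true_case,
    algorithm_positive = alg_pos,
    physician_confirmed = label,
    stratum = stratum(birth, ref),
    true_onset_age = true_onset,
    true_last_activity_age = true_last,
    stringsAsFactors = FALSE
  )
  list(cohort = coh, truth = truth)
}

#' Realised prevalences and moments of a generated cohort
#'
#' Tabulates, overall and by child/adult stratum, the percentage of
#' patients with at least one / at least two core diagnosis codes, with at
#' least one eczema-related prescription, one steroid/TCI prescription,
#' one exclusionary condition and one dermatology consult, plus the
#' mean/SD core-code and prescription counts among carriers — the same
#' shape as a code-distribution table, for eyeball calibration.
#'
#' @param x An `ehr_cohort` (the `cohort` element of [generate_cohort()]).
#' @param lists Code-list collection (default [synth_codelists()]).
#' @return Data frame with columns `statistic`, `total`, `child`, `adult`.
#' @export
summary_statistics <- function(x, lists = synth_codelists()) {
  stopifnot(inherits(x, "ehr_cohort"))
  ev <- as.data.table(x$events)
  cat <- classify_code(ev$code, lists)
  ev[, category := cat]
  per <- ev[, .(
    n_core = sum(!is.na(category) & category == "CORE_DX"),
    n_rx = sum(!is.na(category) & category %in% treatment_categories()),
    n_spec = sum(!is.na(category) & category %in% specific_treatment_categories()),
    n_excl = sum(!is.na(category) & category == "EXCLUSION"),
    n_derm = sum(!is.na(category) & category == "DERM_CONSULT")
  ), by = patient_id]
  idx <- match(x$patients$patient_id, per$patient_id)
  g <- function(col) ifelse(is.na(idx), 0L, per[[col]][idx])
  n_core <- g("n_core"); n_rx <- g("n_rx"); n_spec <- g("n_spec")
  n_excl <- g("n_excl"); n_derm <- g("n_derm")
  st <- stratum(x$patients$birth_date, x$reference_date)

  one <- function(mask) {
    if (sum(mask) == 0L) return(rep(NA_real_, 8))
    c(100 * mean(n_core[mask] >= 1), 100 * mean(n_core[mask] >= 2),
      100 * mean(n_rx[mask] >= 1), 100 * mean(n_spec[mask] >= 1),
      100 * mean(n_excl[mask] >= 1), 100 * mean(n_derm[mask] >= 1),
      mean(n_core[mask][n_core[mask] >= 1]),
      sd(n_core[mask][n_core[mask] >= 1]))
  }
  stat_names <- c("pct_core_ge1", "pct_core_ge2", "pct_any_treatment_ge1",
                  "pct_steroid_tci_ge1", "pct_exclusion_ge1",
                  "pct_derm_consult_ge1", "mean_core_count_carriers",
                  "sd_core_count_carriers")
  data.frame(statistic = stat_names,
             total = one(rep(TRUE, length(st))),
             child = one(st == "child"),
             adult = one(st == "adult"),
             stringsAsFactors = FALSE)
}

#' Write a generated cohort and its truth table to CSV
#'
#' @param x Result of [generate_cohort()].
#' @param dir Output directory; writes `patients.csv`, `events.csv`,
#'   `truth.csv`.
#' @return `dir`, invisibly.
#' @export
write_synth <- function(x, dir) {
  write_cohort(x$cohort, dir)
  write.csv(x$truth, file.path(dir, "truth.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}
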