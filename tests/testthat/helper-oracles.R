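# Independent oracles used by the property and acceptance tests. These are
# deliberately naive (enumeration / numeric inversion), kept separate from
# the implementation paths they check.

# Brute-force case-definition oracle: enumerates event subsets rather than
# counting distinct dates. Feasible for patients with few events.
oracle_evaluate <- function(events, spec, lists) {
  date <- as.Date(events$date)
  cat <- classify_code(events$code, lists)
  core_idx <- which(!is.na(cat) & cat == "CORE_DX")
  treat_idx <- which(!is.na(cat) & cat %in% treatment_categories())
  spec_idx <- which(!is.na(cat) & cat %in% specific_treatment_categories())

  distinct_subset_exists <- function(idx, k) {
    if (k == 0L) return(TRUE)
    if (length(idx) < k) return(FALSE)
    combs <- utils::combn(idx, k, simplify = FALSE)
    any(vapply(combs, function(s) !anyDuplicated(date[s]), logical(1)))
  }

  ok <- distinct_subset_exists(core_idx, spec$min_core_dx) &&
    distinct_subset_exists(treat_idx, spec$min_treatment_dates) &&
    distinct_subset_exists(spec_idx, spec$min_specific_treatments)

  if (!is.null(spec$temporal_window)) {
    before <- spec$temporal_window[["days_before"]]
    after <- spec$temporal_window[["days_after"]]
    win <- FALSE
    for (d in core_idx) {
      for (t in spec_idx) {
        delta <- as.numeric(date[t] - date[d])
        if (delta >= -before && delta <= after) win <- TRUE
      }
    }
    ok <- ok && win
  }
  if (spec$require_no_exclusion) ok <- ok && !any(cat %in% "EXCLUSION", na.rm = TRUE)
  if (spec$require_atopy) ok <- ok && any(cat %in% "ATOPY", na.rm = TRUE)
  if (spec$require_derm_consult) ok <- ok && any(cat %in% "DERM_CONSULT", na.rm = TRUE)
  ok
}

# Clopper-Pearson endpoints by direct numeric inversion of the binomial
# tails (no beta quantiles).
oracle_clopper_pearson <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lo <- if (x == 0) 0 else {
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  hi <- if (x == n) 1 else {
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lo, hi)
}

# Fisher's exact two-sided p by exhaustive hypergeometric enumeration of
# tables with the observed margins.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b     # row 1 total
  n2 <- c + d    # row 2 total
  k <- a + c     # column 1 total
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random small patients for property tests: a handful of events drawn from
# the synthetic vocabulary plus junk codes, on a small date pool so date
# collisions are common.
random_patient_events <- function(n_events, vocab = NULL) {
  if (is.null(vocab)) {
    cl <- synth_codelists()
    vocab <- c(cl$code, "JUNK01", "JUNK02")
  }
  pool <- as.Date("2010-01-01") + sample(0:600, 6)
  data.frame(
    patient_id = rep("PX", n_events),
    date = sample(pool, n_events, replace = TRUE),
    code = sample(vocab, n_events, replace = TRUE),
    event_class = rep("other", n_events),
    stringsAsFactors = FALSE
  )
}
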