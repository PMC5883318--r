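# Validation statistics for a labelled cohort: PPV with binomial CIs,
# detection fractions, stratified 2x2 tests, Bland-Altman agreement and
# rank-sum comparisons.

#' Round a proportion to an integer percent (half up)
#'
#' Matches the rendering convention of published validation tables:
#' 0.865 -> 87, 0.8624 -> 86.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return Integer percent(s).
#' @export
percent_round <- function(p) as.integer(floor(p * 100 + 0.5))

#' Positive predictive value with a binomial confidence interval
#'
#' Point estimate `true_positives / positives` with a two-sided 95%
#' interval. The default is the Clopper-Pearson exact interval (beta
#' quantile form of the inverted binomial tails); Wilson score and Wald
#' intervals are available as alternatives.
#'
#' @param true_positives,positives Counts, `0 <= tp <= positives`,
#'   `positives > 0`.
#' @param ci_method `"clopper_pearson"` (default), `"wilson"` or `"wald"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A `ppv_estimate`: list with `true_positives`, `positives`,
#'   `ppv`, `ci_low`, `ci_high`, `ci_method`, `percent`.
#' @export
#' @examples
#' ppv(163, 189)
ppv <- function(true_positives, positives,
                ci_method = c("clopper_pearson", "wilson", "wald"),
                conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (positives <= 0) stop("positives must be > 0", call. = FALSE)
  if (true_positives < 0 || true_positives > positives) {
    stop("need 0 <= true_positives <= positives", call. = FALSE)
  }
  x <- true_positives
  n <- positives
  p <- x / n
  alpha <- 1 - conf_level
  ci <- switch(ci_method,
    clopper_pearson = c(
      if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1),
      if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
    ),
    wilson = {
      z <- qnorm(1 - alpha / 2)
      centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      c(max(0, centre - half), min(1, centre + half))
    },
    wald = {
      z <- qnorm(1 - alpha / 2)
      half <- z * sqrt(p * (1 - p) / n)
      c(max(0, p - half), min(1, p + half))
    }
  )
  structure(
    list(true_positives = x, positives = n, ppv = p,
         ci_low = ci[1], ci_high = ci[2], ci_method = ci_method,
         percent = percent_round(p)),
    class = "ppv_estimate"
  )
}

#' @export
print.ppv_estimate <- function(x, ...) {
  cat(sprintf("PPV %d/%d = %d%% (%s 95%% CI %d-%d%%)\n",
              x$true_positives, x$positives, x$percent, x$ci_method,
              percent_round(x$ci_low), percent_round(x$ci_high)))
  invisible(x)
}

#' Fraction of reference-confirmed cases a variant still detects
#'
#' Stricter case-definition variants trade detection for predictive value:
#' this is the share of the reference-standard-confirmed cases (those
#' confirmed among the baseline positives) that the variant still flags.
#'
#' @param variant_tp Confirmed cases flagged by the variant.
#' @param reference_confirmed Confirmed cases in the reference
#'   (baseline-positive) set; must be > 0.
#' @return Proportion in \[0, 1\]; render with [percent_round()].
#' @export
#' @examples
#' percent_round(detection_fraction(83, 163))
detection_fraction <- function(variant_tp, reference_confirmed) {
  if (reference_confirmed <= 0) {
    stop("reference_confirmed must be > 0", call. = FALSE)
  }
  if (variant_tp < 0 || variant_tp > reference_confirmed) {
    stop("need 0 <= variant_tp <= reference_confirmed", call. = FALSE)
  }
  variant_tp / reference_confirmed
}

#' Compare two proportions (2x2 test)
#'
#' Pearson chi-square without continuity correction by default; Fisher's
#' exact test when any expected cell count is 5 or less (the conservative
#' variant of the usual small-expected-count rule). Reports which test was
#' used.
#'
#' @param a_success,a_total,b_success,b_total Counts of the two groups.
#' @return List with `statistic` (chi-square; `NA` for Fisher), `p_value`,
#'   `test_used`.
#' @export
compare_proportions <- function(a_success, a_total, b_success, b_total) {
  tab <- matrix(c(a_success, a_total - a_success,
                  b_success, b_total - b_success),
                nrow = 2, byrow = TRUE)
  if (any(tab < 0)) stop("negative cell count", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table (zero margin)", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 5)) {
    ft <- fisher.test(tab)
    list(statistic = NA_real_, p_value = unname(ft$p.value),
         test_used = "fisher")
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
         test_used = "pearson_chisq")
  }
}

#' Bland-Altman agreement between two measurement methods
#'
#' Differences are `survey - database`. Reports the mean difference, its
#' 95% confidence interval (normal approximation, mean +/- 1.96 SD/sqrt(n))
#' and the limits of agreement (mean +/- 1.96 SD).
#'
#' @param survey,database Paired numeric vectors (n >= 2 complete pairs).
#' @return A `bland_altman` object: `n`, `mean_diff`, `ci_low`, `ci_high`,
#'   `loa_low`, `loa_high`, `sd_diff`, plus the pair means/differences for
#'   plotting.
#' @export
bland_altman <- function(survey, database) {
  ok <- !is.na(survey) & !is.na(database)
  survey <- survey[ok]
  database <- database[ok]
  n <- length(survey)
  if (length(database) != n) stop("unequal pair lengths", call. = FALSE)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- survey - database
  m <- mean(d)
  s <- sd(d)
  structure(
    list(n = n, mean_diff = m, sd_diff = s,
         ci_low = m - 1.96 * s / sqrt(n), ci_high = m + 1.96 * s / sqrt(n),
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         means = (survey + database) / 2, diffs = d),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean difference %.2f (95%% CI %.2f to %.2f), limits of agreement %.2f to %.2f\n",
    x$n, x$mean_diff, x$ci_low, x$ci_high, x$loa_low, x$loa_high))
  invisible(x)
}

#' @param x A `bland_altman` object.
#' @param ... Passed to [graphics::plot()].
#' @rdname bland_altman
#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$means, x$diffs,
       xlab = "Mean of survey and database estimates (years)",
       ylab = "Survey - database (years)", ...)
  abline(h = x$mean_diff, lty = 1)
  abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Two-sample Wilcoxon rank-sum comparison
#'
#' Two-sided test with midrank handling of ties; exact when both groups
#' have at most 20 observations and there are no ties, otherwise the
#' normal approximation (without continuity correction). Medians of both
#' groups are reported alongside.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `statistic` (rank-sum W of `group_a`), `p_value`,
#'   `median_a`, `median_b`, `method`.
#' @export
rank_sum <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- any(duplicated(c(group_a, group_b)))
  use_exact <- !ties && length(group_a) <= 20L && length(group_b) <= 20L
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = use_exact, correct = FALSE)
  )
  p <- unname(wt$p.value)
  # zero rank variance (all observations tied): no evidence either way
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = p,
       median_a = median(group_a), median_b = median(group_b),
       method = if (use_exact) "exact" else "normal_approximation")
}

#' Validate case-definition variants against physician labels
#'
#' Computes, for each variant's phenotyping result, the PPV (overall and by
#' child/adult stratum), the detection fraction against the confirmed
#' baseline-positive set, and a child-vs-adult comparison of the confirmed
#' proportion. Patients whose physician label is missing (unreturned or
#' incomplete surveys) are excluded from both numerator and denominator.
#'
#' @param outcomes Data frame: `patient_id`, `physician_confirmed`
#'   (`"yes"`/`"no"`/`"missing"` or NA), `stratum` (`"child"`/`"adult"`).
#' @param results Named list of phenotyping results (data frames with
#'   `patient_id`, `positive`), one per variant; must include
#'   `reference` (default `"baseline"`).
#' @param reference Name of the reference variant for detection fractions.
#' @param ci_method Passed to [ppv()].
#' @return A `validation_report`: list with `table` (one row per variant)
#'   and `reference_confirmed`.
#' @export
validate_cohort <- function(outcomes, results, reference = "baseline",
                            ci_method = "clopper_pearson") {
  stopifnot(is.list(results), reference %in% names(results))
  outcomes <- as.data.frame(outcomes)
  lab <- as.character(outcomes$physician_confirmed)
  lab[is.na(lab)] <- "missing"
  stopifnot(all(lab %in% c("yes", "no", "missing")))
  usable <- lab != "missing"

  pos_ids <- function(res) as.character(res$patient_id[res$positive])
  confirmed_ids <- outcomes$patient_id[usable & lab == "yes"]
  ref_confirmed <- intersect(pos_ids(results[[reference]]), confirmed_ids)
  n_ref_confirmed <- length(ref_confirmed)

  rows <- lapply(names(results), function(nm) {
    ids <- pos_ids(results[[nm]])
    keep <- outcomes$patient_id %in% ids & usable
    n_pos <- sum(keep)
    if (n_pos == 0L) {
      return(data.frame(
        variant = nm, n_tp = 0L, n_pos = 0L, ppv_pct = NA_integer_,
        ci_low_pct = NA_integer_, ci_high_pct = NA_integer_,
        ppv_child_pct = NA_integer_, ppv_adult_pct = NA_integer_,
        detection_pct = NA_integer_, strata_p_value = NA_real_,
        notice = "no positives", stringsAsFactors = FALSE))
    }
    tp <- sum(keep & lab == "yes")
    est <- ppv(tp, n_pos, ci_method = ci_method)
    by_stratum <- function(s) {
      k <- keep & outcomes$stratum == s
      if (sum(k) == 0L) NA_integer_ else percent_round(sum(k & lab == "yes") / sum(k))
    }
    cp <- tryCatch({
      kc <- keep & outcomes$stratum == "child"
      ka <- keep & outcomes$stratum == "adult"
      compare_proportions(sum(kc & lab == "yes"), sum(kc),
                          sum(ka & lab == "yes"), sum(ka))$p_value
    }, error = function(e) NA_real_)
    det <- if (n_ref_confirmed > 0) {
      percent_round(detection_fraction(
        length(intersect(ids, ref_confirmed)), n_ref_confirmed))
    } else {
      NA_integer_
    }
    data.frame(
      variant = nm, n_tp = tp, n_pos = n_pos,
      ppv_pct = est$percent,
      ci_low_pct = percent_round(est$ci_low),
      ci_high_pct = percent_round(est$ci_high),
      ppv_child_pct = by_stratum("child"),
      ppv_adult_pct = by_stratum("adult"),
      detection_pct = det, strata_p_value = cp, notice = "",
      stringsAsFactors = FALSE)
  })
  structure(
    list(table = do.call(rbind, rows),
         reference = reference,
         reference_confirmed = n_ref_confirmed,
         ci_method = ci_method),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> reference '", x$reference, "' with ",
      x$reference_confirmed, " confirmed cases; CI method ", x$ci_method,
      "\n\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
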