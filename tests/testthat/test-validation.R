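test_that("PPV point estimates render to the expected integer percents", {
  est <- ppv(163, 189)
  expect_equal(est$percent, 86L)
  expect_equal(est$ppv, 163 / 189)
  expect_equal(ppv(0, 10)$percent, 0L)
  expect_equal(ppv(0, 10)$ci_low, 0)
  expect_equal(ppv(10, 10)$ci_high, 1)
  expect_error(ppv(1, 0), "positives")
  expect_error(ppv(5, 4), "true_positives")
  # half-up rounding convention
  expect_equal(percent_round(0.865), 87L)
  expect_equal(percent_round(0.005), 1L)
})

test_that("Clopper-Pearson endpoints match numeric tail inversion", {
  cases <- list(c(9, 10), c(163, 189), c(1, 19), c(52, 56), c(100, 200))
  for (cs in cases) {
    est <- ppv(cs[1], cs[2])
    orc <- oracle_clopper_pearson(cs[1], cs[2])
    expect_equal(est$ci_low, orc[1], tolerance = 1e-9)
    expect_equal(est$ci_high, orc[2], tolerance = 1e-9)
  }
})

test_that("exact interval keeps at least nominal coverage; Wilson is narrower", {
  set.seed(31)
  n <- 189
  for (p in c(0.5, 0.86, 0.95)) {
    x <- rbinom(1e4, n, p)
    lo <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
    hi <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
    expect_gte(mean(lo <= p & p <= hi), 0.95)
  }
  cp <- ppv(163, 189)
  wi <- ppv(163, 189, ci_method = "wilson")
  expect_lt(wi$ci_high - wi$ci_low, cp$ci_high - cp$ci_low)
})

test_that("detection fractions reproduce the published percents", {
  expect_equal(percent_round(detection_fraction(83, 163)), 51L)
  expect_equal(percent_round(detection_fraction(18, 163)), 11L)
  expect_equal(detection_fraction(163, 163), 1)
  expect_error(detection_fraction(1, 0), "reference_confirmed")
  expect_error(detection_fraction(164, 163), "variant_tp")
})

test_that("2x2 comparison picks the documented test and matches hand formulas", {
  bal <- compare_proportions(10, 20, 10, 20)
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)
  expect_equal(bal$test_used, "pearson_chisq")

  big <- compare_proportions(50, 100, 90, 100)
  tab <- matrix(c(50, 50, 90, 10), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(big$statistic, sum((tab - expected)^2 / expected))

  small <- compare_proportions(8, 10, 2, 10)
  expect_equal(small$test_used, "fisher")
  expect_equal(small$p_value, oracle_fisher_p(8, 2, 2, 8))

  expect_error(compare_proportions(0, 10, 0, 10), "degenerate")
})

test_that("Fisher p-values equal hypergeometric enumeration on all small tables", {
  for (n1 in 1:9) for (n2 in 1:9) for (a in 0:n1) for (c_ in 0:n2) {
    if (a + c_ == 0 || (n1 - a) + (n2 - c_) == 0) next  # zero column margin
    got <- fisher.test(matrix(c(a, n1 - a, c_, n2 - c_), 2, byrow = TRUE))$p.value
    expect_equal(got, oracle_fisher_p(a, n1 - a, c_, n2 - c_),
                 tolerance = 1e-10,
                 info = paste(a, n1 - a, c_, n2 - c_))
  }
})

test_that("Bland-Altman closed forms", {
  id <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$mean_diff, 0)
  expect_equal(c(id$loa_low, id$loa_high), c(0, 0))
  ba <- bland_altman(c(1, 0), c(0, 1))  # differences {1, -1}
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  expect_equal(ba$ci_high, 1.96 * sqrt(2) / sqrt(2))
  expect_error(bland_altman(1, 1), "at least 2")
  # CI nested inside limits of agreement for n > 4
  set.seed(41)
  x <- rnorm(50, 10, 3); y <- rnorm(50, 9, 3)
  b <- bland_altman(x, y)
  expect_true(b$ci_low >= b$loa_low && b$ci_high <= b$loa_high)
  expect_true(b$ci_low <= b$mean_diff && b$mean_diff <= b$ci_high)
})

test_that("rank-sum comparison: exact small-sample p and midrank ties", {
  rs <- rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(rs$method, "exact")
  expect_equal(rs$p_value, 0.1)  # 2/20 labellings as extreme
  ties <- rank_sum(c(5, 5, 5, 5), c(5, 5, 5, 5))
  expect_equal(ties$method, "normal_approximation")
  expect_equal(ties$p_value, 1)
  med <- rank_sum(c(5, 5, 5), c(2, 2, 2))
  expect_equal(c(med$median_a, med$median_b), c(5, 2))
  expect_error(rank_sum(numeric(0), 1), "non-empty")
})

test_that("cohort validation excludes missing labels from both PPV terms", {
  outcomes <- data.frame(
    patient_id = sprintf("P%02d", 1:10),
    physician_confirmed = c(rep("yes", 8), "no", "missing"),
    stratum = rep(c("child", "adult"), 5),
    stringsAsFactors = FALSE
  )
  res <- list(baseline = data.frame(patient_id = outcomes$patient_id,
                                    positive = TRUE))
  report <- validate_cohort(outcomes, res)
  row <- report$table[report$table$variant == "baseline", ]
  expect_equal(row$n_pos, 9L)   # 10 positives, 1 missing label excluded
  expect_equal(row$n_tp, 8L)
  expect_equal(row$ppv_pct, percent_round(8 / 9))
})

test_that("a variant with no positives is reported with a notice", {
  outcomes <- data.frame(patient_id = c("A", "B"),
                         physician_confirmed = c("yes", "no"),
                         stratum = c("child", "adult"))
  res <- list(baseline = data.frame(patient_id = c("A", "B"),
                                    positive = c(TRUE, TRUE)),
              strict = data.frame(patient_id = c("A", "B"),
                                  positive = c(FALSE, FALSE)))
  report <- validate_cohort(outcomes, res)
  expect_equal(report$table$notice[report$table$variant == "strict"], "no positives")
  expect_true(is.na(report$table$ppv_pct[report$table$variant == "strict"]))
})

test_that("an engineered cohort reproduces the published validation table", {
  # Printed numerator/denominator pairs define the cohort: 189 analysable
  # baseline positives, 163 physician-confirmed, plus 11 missing labels.
  printed <- list(
    baseline          = c(163, 189),
    steroid1          = c(157, 183),
    steroid2          = c(133, 153),
    window            = c(81, 92),
    twocodes          = c(83, 91),
    twocodes_steroid1 = c(82, 90),
    twocodes_steroid2 = c(133, 153),
    no_exclusion      = c(138, 161),
    atopy             = c(52, 56),
    derm_consult      = c(18, 19)
  )
  expected_ppv <- c(86, 86, 87, 88, 91, 91, 87, 86, 93, 95)
  expected_det <- c(NA, 96, 82, 50, 51, 50, 82, 85, 32, 11)

  confirmed_ids <- sprintf("C%03d", 1:163)
  unconfirmed_ids <- sprintf("U%03d", 1:26)
  missing_ids <- sprintf("M%03d", 1:11)
  outcomes <- data.frame(
    patient_id = c(confirmed_ids, unconfirmed_ids, missing_ids),
    physician_confirmed = c(rep("yes", 163), rep("no", 26), rep("missing", 11)),
    stratum = "adult", stringsAsFactors = FALSE
  )
  all_ids <- outcomes$patient_id
  res <- lapply(printed, function(cnt) {
    ids <- c(confirmed_ids[seq_len(cnt[1])],
             unconfirmed_ids[seq_len(cnt[2] - cnt[1])])
    data.frame(patient_id = all_ids, positive = all_ids %in% ids)
  })
  report <- validate_cohort(outcomes, res)
  expect_equal(report$reference_confirmed, 163)
  expect_equal(report$table$ppv_pct, expected_ppv)
  expect_equal(report$table$detection_pct[-1], expected_det[-1])
  expect_equal(report$table$detection_pct[1], 100L)
})
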