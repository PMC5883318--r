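lists <- synth_codelists()

ev <- function(dates, codes) {
  data.frame(patient_id = rep("P1", length(dates)), date = as.Date(dates),
             code = codes, event_class = rep("other", length(dates)),
             stringsAsFactors = FALSE)
}

test_that("presets encode the published rule-set family", {
  expect_equal(preset("baseline")$min_treatment_dates, 2L)
  expect_equal(preset("baseline")$min_core_dx, 1L)
  expect_equal(preset("twocodes")$min_core_dx, 2L)
  expect_equal(unname(preset("window")$temporal_window), c(91L, 365L))
  expect_equal(preset("steroid2")$min_specific_treatments, 2L)
  expect_true(preset("no_exclusion")$require_no_exclusion)
  expect_true(preset("atopy")$require_atopy)
  expect_true(preset("derm_consult")$require_derm_consult)
  expect_error(preset("nope"), "baseline.*derm_consult")
  expect_length(preset_names(), 10)
})

test_that("rule sets serialise to YAML and back unchanged", {
  f <- withr::local_tempfile(fileext = ".yaml")
  for (nm in c("baseline", "window", "atopy")) {
    write_algorithm_spec(preset(nm), f)
    expect_equal(read_algorithm_spec(f), preset(nm))
  }
})

test_that("invalid rule sets are rejected", {
  expect_error(algorithm_spec(min_core_dx = 0), "min_core_dx")
  expect_error(algorithm_spec(min_treatment_dates = 1,
                              min_specific_treatments = 2), "exceed")
  expect_error(algorithm_spec(temporal_window = c(-1, 10)), "temporal_window")
})

test_that("baseline decision: separate treatment dates required, same-day dx+rx fine", {
  base <- preset("baseline")
  pos <- evaluate_patient(
    ev(c("2010-05-01", "2010-05-01", "2010-06-01"),
       c("M111.00", "EMOL001", "EMOL002")), base, lists)
  expect_true(pos$positive)
  neg <- evaluate_patient(
    ev(c("2010-05-01", "2010-06-01", "2010-06-01"),
       c("M111.00", "EMOL001", "EMOL002")), base, lists)
  expect_false(neg$positive)
  expect_false(evaluate_patient(ev(character(0), character(0)), base, lists)$positive)
})

test_that("temporal window is inclusive at 91 days before and 365 after", {
  win <- preset("window")
  in_win <- evaluate_patient(
    ev(c("2010-01-01", "2009-11-01", "2010-02-01"),
       c("M111.00", "TSTER01", "EMOL001")), win, lists)
  expect_true(in_win$positive)   # steroid 61 days before dx
  out_win <- evaluate_patient(
    ev(c("2010-01-01", "2009-09-01", "2010-02-01"),
       c("M111.00", "TSTER01", "EMOL001")), win, lists)
  expect_false(out_win$positive) # 122 days before dx
  # exact boundaries
  expect_true(evaluate_patient(
    ev(c("2010-01-01", "2009-10-02", "2010-02-01"),
       c("M111.00", "TSTER01", "EMOL001")), win, lists)$positive)  # 91 before
  expect_false(evaluate_patient(
    ev(c("2010-01-01", "2009-10-01", "2010-02-01"),
       c("M111.00", "TSTER01", "EMOL001")), win, lists)$positive)  # 92 before
  expect_true(evaluate_patient(
    ev(c("2010-01-01", "2011-01-01", "2010-02-01"),
       c("M111.00", "TSTER01", "EMOL001")), win, lists)$positive)  # 365 after
})

test_that("two-codes variants count distinct diagnosis dates, not codes", {
  two <- preset("twocodes")
  same_day <- evaluate_patient(
    ev(c("2010-05-01", "2010-05-01", "2010-06-01", "2010-07-01"),
       c("M111.00", "M113.00", "EMOL001", "EMOL002")), two, lists)
  expect_false(same_day$positive)
  two_days <- evaluate_patient(
    ev(c("2010-05-01", "2011-05-01", "2010-06-01", "2010-07-01"),
       c("M111.00", "M111.00", "EMOL001", "EMOL002")), two, lists)
  expect_true(two_days$positive)
})

test_that("a positive decision implies every criterion has evidence", {
  spec <- preset("atopy")
  res <- evaluate_patient(
    ev(c("2010-05-01", "2010-06-01", "2010-07-01", "2010-08-01"),
       c("M111.00", "EMOL001", "EMOL002", "ATOP01")), spec, lists)
  expect_true(res$positive)
  expect_true(all(res$criteria))
  expect_true(all(vapply(res$evidence[c("core_dx", "treatment_dates", "atopy")],
                         nrow, integer(1)) > 0))
})

test_that("decisions are invariant to event input order", {
  set.seed(11)
  specs <- lapply(preset_names(), preset)
  for (i in 1:40) {
    events <- random_patient_events(sample(3:10, 1))
    perm <- events[sample(nrow(events)), ]
    for (spec in specs) {
      expect_equal(evaluate_patient(perm, spec, lists)$positive,
                   evaluate_patient(events, spec, lists)$positive)
    }
  }
})

test_that("evaluate_patient agrees with the brute-force subset oracle", {
  set.seed(21)
  specs <- lapply(preset_names(), preset)
  for (i in 1:150) {
    events <- random_patient_events(sample(0:10, 1))
    for (spec in specs) {
      expect_equal(
        evaluate_patient(events, spec, lists)$positive,
        oracle_evaluate(events, spec, lists),
        info = paste("case", i, spec$name)
      )
    }
  }
})

test_that("cohort-level evaluation matches per-patient evaluation", {
  g <- generate_cohort(synth_config(n_patients = 300, seed = 5))
  for (nm in c("baseline", "window", "twocodes_steroid2", "no_exclusion")) {
    spec <- preset(nm)
    res <- phenotype_cohort(g$cohort, spec, lists)
    per <- vapply(res$patient_id, function(id) {
      evaluate_patient(g$cohort$events[g$cohort$events$patient_id == id, ],
                       spec, lists)$positive
    }, logical(1))
    expect_equal(unname(per), res$positive)
  }
})

test_that("every stricter variant selects a subset of baseline positives", {
  g <- generate_cohort(synth_config(n_patients = 1000, seed = 9))
  base <- phenotype_cohort(g$cohort, preset("baseline"), lists)
  for (nm in setdiff(preset_names(), "baseline")) {
    res <- phenotype_cohort(g$cohort, preset(nm), lists)
    expect_true(all(base$positive[res$positive]), info = nm)
  }
  # summary accounting
  s <- attr(base, "summary")
  expect_equal(unname(s["positives"]),
               unname(s["positives_child"] + s["positives_adult"]))
})

test_that("empty cohorts yield empty results", {
  g <- generate_cohort(synth_config(n_patients = 0, seed = 1))
  res <- phenotype_cohort(g$cohort, preset("baseline"), lists)
  expect_equal(nrow(res), 0)
})
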