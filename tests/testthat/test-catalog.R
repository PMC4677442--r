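test_that("the default catalog has 26 items of which 17 (65%) are extractable", {
  cat26 <- default_catalog()
  s <- catalog_stats(cat26)
  expect_equal(s$n_items, 26)
  expect_equal(s$n_extractable, 17)
  expect_equal(s$pct_extractable, 65)
  td <- tidy(cat26)
  expect_equal(nrow(td), 26)
  expect_equal(sum(!td$extractable), 9)
  # non-extractable items all carry an on-site note
  expect_true(all(!is.na(td$on_site_note[!td$extractable])))
  # advisory history items flagged for attention, not exclusion
  expect_setequal(vapply(cat26$advisories, `[[`, character(1), "label"),
                  c("atrial fibrillation", "dementia", "heart failure"))
})

test_that("catalog_stats rounds the extractable percentage to the nearest integer", {
  one <- lysisgate:::new_catalog(
    list(lysisgate:::ci_rule(1, "x", predicate = exists_clause("diagnosis", "gout"))),
    list(), complete = FALSE)
  expect_equal(catalog_stats(one)$pct_extractable, 100)

  four <- lysisgate:::new_catalog(
    c(list(lysisgate:::ci_rule(1, "x",
                               predicate = exists_clause("diagnosis", "gout"))),
      lapply(2:4, function(i) {
        lysisgate:::ci_rule(i, paste0("y", i), extractable = FALSE,
                            on_site_note = "bedside")
      })),
    list(), complete = FALSE)
  expect_equal(catalog_stats(four)$pct_extractable, 25)
})

test_that("anticoagulant-use and stroke-plus-diabetes rules behave as specified", {
  cat26 <- default_catalog()
  items <- setNames(cat26$items,
                    vapply(cat26$items, `[[`, integer(1), "item_id"))
  riva <- ehr_cohort(
    patients = tibble::tibble(patient_id = "p"),
    medications = tibble::tibble(patient_id = "p", hospital_id = "CCH",
                                 drug_concept = "rivaroxaban",
                                 start_date = "2014-06-01",
                                 stop_date = NA_character_))
  f16 <- evaluate_rule(items[["16"]], riva, "2014-09-01")
  expect_equal(f16$status, "TRIGGERED")
  expect_equal(f16$evidence$concept, "rivaroxaban")

  # the class tag alone is enough, drug name unknown to the concept set
  tagged <- ehr_cohort(
    patients = tibble::tibble(patient_id = "p"),
    medications = tibble::tibble(patient_id = "p", hospital_id = "CCH",
                                 drug_concept = "edoxaban",
                                 start_date = "2014-08-01",
                                 stop_date = NA_character_,
                                 tags = list("anticoagulant")))
  expect_equal(evaluate_rule(items[["16"]], tagged, "2014-09-01")$status,
               "TRIGGERED")

  # conjunction: diabetes without stroke leaves item 17 unsatisfied
  dm_only <- ehr_cohort(
    patients = tibble::tibble(patient_id = "p"),
    diagnoses = tibble::tibble(patient_id = "p", hospital_id = "CCH",
                               concept = "Diabetes", date = "2010-01-01"))
  expect_equal(evaluate_rule(items[["17"]], dm_only, "2014-09-01")$status,
               "CLEAR")
})

test_that("catalogs round-trip through YAML and JSON configs", {
  cat26 <- default_catalog()
  fy <- withr::local_tempfile(fileext = ".yaml")
  fj <- withr::local_tempfile(fileext = ".json")
  write_catalog(cat26, fy)
  write_catalog(cat26, fj)
  expect_identical(load_catalog(fy), cat26)
  expect_identical(load_catalog(fj), cat26)
})

test_that("the shipped example config loads to the default catalog", {
  shipped <- system.file("extdata", "default-catalog.yaml",
                         package = "lysisgate")
  expect_identical(load_catalog(shipped), default_catalog())
})

test_that("config validation rejects wrong counts, duplicates, and negation", {
  cat26 <- default_catalog()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_catalog(cat26, f)
  doc <- yaml::read_yaml(f)

  short <- doc; short$items <- short$items[1:25]
  yaml::write_yaml(short, f)
  expect_error(load_catalog(f), "25")

  dup <- doc; dup$items[[2]]$id <- 1
  yaml::write_yaml(dup, f)
  expect_error(load_catalog(f), "Duplicate item_id")

  nopred <- doc; nopred$items[[1]]$predicate <- NULL
  yaml::write_yaml(nopred, f)
  expect_error(load_catalog(f), "extractable but has no predicate")

  neg <- doc
  neg$items[[1]]$predicate <- list(not = neg$items[[1]]$predicate)
  yaml::write_yaml(neg, f)
  expect_error(load_catalog(f), "negation")
})

test_that("a site-configured stroke window is honored end-to-end", {
  cat26 <- default_catalog()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_catalog(cat26, f)
  doc <- yaml::read_yaml(f)
  id3 <- which(vapply(doc$items, `[[`, integer(1), "id") == 3)
  expect_equal(doc$items[[id3]]$predicate$exists$lookback_days, 90)
  # shrink the window to 30 days: the 60-days-ago stroke no longer triggers
  doc$items[[id3]]$predicate$exists$lookback_days <- 30
  yaml::write_yaml(doc, f)
  narrow <- load_catalog(f)
  cases <- make_mock_cases()
  rep1 <- screen_patient(cohort_patient(cases, "case-1"), narrow,
                         attr(cases, "index"))
  expect_equal(triggered_items(rep1), 17L)
  # while the shipped 90-day window does trigger item 3
  rep1w <- screen_patient(cohort_patient(cases, "case-1"), cat26,
                          attr(cases, "index"))
  expect_equal(triggered_items(rep1w), c(3L, 17L))
})

test_that("predicate evaluation is monotone under event-superset growth", {
  set.seed(99)
  index <- "2014-09-01"
  for (i in 1:40) {
    pred <- random_predicate()
    small <- random_record(n_diag = sample(0:4, 1), n_med = sample(0:2, 1))
    extra <- random_record(n_diag = 3, n_med = 1)
    grown <- ehr_cohort(
      patients = small$patients,
      diagnoses = dplyr::bind_rows(
        small$diagnoses,
        dplyr::mutate(extra$diagnoses, patient_id = small$patients$patient_id)),
      medications = dplyr::bind_rows(
        small$medications,
        dplyr::mutate(extra$medications,
                      patient_id = small$patients$patient_id)))
    if (predicate_satisfied(pred, small, index)) {
      expect_true(predicate_satisfied(pred, grown, index),
                  label = sprintf("monotonicity case %d", i))
    }
  }
})
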