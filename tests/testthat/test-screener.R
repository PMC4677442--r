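idx_ts <- function() as.POSIXct("2014-09-01", tz = "UTC")

test_that("single-rule evaluation reports evidence with provenance", {
  cases <- make_mock_cases()
  cat26 <- default_catalog()
  items <- setNames(cat26$items,
                    vapply(cat26$items, `[[`, integer(1), "item_id"))

  f1 <- evaluate_rule(items[["1"]], cohort_patient(cases, "case-3"), idx_ts())
  expect_equal(f1$status, "TRIGGERED")
  expect_equal(f1$evidence$hospital_id, "CCH")
  expect_equal(format(f1$evidence$date, "%Y"), "2010")
  expect_equal(f1$evidence$concept, "Intracranial hemorrhage")

  # a five-year-old stroke is outside the 90-day window
  f3 <- evaluate_rule(items[["3"]], cohort_patient(cases, "case-2"), idx_ts())
  expect_equal(f3$status, "CLEAR")

  empty <- ehr_cohort(patients = tibble::tibble(patient_id = "e"))
  for (it in items[c("1", "3", "16", "17")]) {
    expect_equal(evaluate_rule(it, empty, idx_ts())$status, "CLEAR")
  }
})

test_that("the four mock cases reproduce their known contraindication sets", {
  cases <- make_mock_cases()
  cat26 <- default_catalog()
  want <- mock_case_truth()
  total <- 0L
  all_items <- integer()
  for (pid in names(want)) {
    rep <- screen_patient(cohort_patient(cases, pid), cat26, attr(cases, "index"))
    expect_equal(triggered_items(rep), sort(want[[pid]]), info = pid)
    expect_true("dementia" %in% rep$advisories$label, info = pid)
    total <- total + length(want[[pid]])
    all_items <- c(all_items, want[[pid]])
  }
  expect_equal(total, 9L)
  expect_equal(length(unique(all_items)), 6L)

  # item 16 evidence covers both anticoagulants
  rep4 <- screen_patient(cohort_patient(cases, "case-4"), cat26,
                         attr(cases, "index"))
  ev16 <- rep4$evidence[rep4$evidence$item_id == 16, ]
  expect_setequal(tolower(ev16$concept), c("warfarin", "rivaroxaban"))
})

test_that("lookback windows are closed intervals and future events are ignored", {
  cat26 <- default_catalog()
  items <- setNames(cat26$items,
                    vapply(cat26$items, `[[`, integer(1), "item_id"))
  mk <- function(date) {
    ehr_cohort(patients = tibble::tibble(patient_id = "p"),
               diagnoses = tibble::tibble(patient_id = "p",
                                          hospital_id = "CCH",
                                          concept = "Ischemic stroke",
                                          date = date))
  }
  expect_equal(evaluate_rule(items[["3"]], mk("2014-06-03"), idx_ts())$status,
               "TRIGGERED")  # exactly 90 days before
  expect_equal(evaluate_rule(items[["3"]], mk("2014-06-02"), idx_ts())$status,
               "CLEAR")      # 91 days before
  expect_equal(evaluate_rule(items[["3"]], mk("2014-09-01"), idx_ts())$status,
               "TRIGGERED")  # on the index day
  expect_equal(evaluate_rule(items[["3"]], mk("2014-09-02"), idx_ts())$status,
               "CLEAR")      # the future cannot inform a code-stroke screen
})

test_that("the 24-hour lab/imaging window is closed at both ends", {
  idx <- idx_ts()
  rec <- ehr_cohort(
    patients = tibble::tibble(patient_id = "p"),
    labs = tibble::tibble(patient_id = "p", hospital_id = "CCH",
                          analyte = c("glucose", "glucose", "inr"),
                          value = c(100, 110, 1.1), units = "u",
                          collected_at = c(idx - 25 * 3600, idx - 23 * 3600,
                                           idx - 24 * 3600)),
    imaging = tibble::tibble(patient_id = "p", hospital_id = "CCH",
                             modality = "CT brain",
                             finding_summary = "no hemorrhage",
                             acquired_at = idx - 3600))
  rep <- screen_patient(rec, default_catalog(), idx)
  expect_equal(sort(rep$recent_labs$analyte), c("glucose", "inr"))
  expect_equal(nrow(rep$recent_imaging), 1)
})

test_that("the snapshot database precomputes exactly the triggered findings of consented patients", {
  cases <- make_mock_cases()
  cat26 <- default_catalog()
  snap <- build_snapshot(cases, cat26, attr(cases, "index"))
  got <- split(snap$triggered$item_id, snap$triggered$patient_id)
  want <- lapply(mock_case_truth(), sort)
  expect_equal(lapply(got, sort), want)

  # unconsented patients are omitted at build time
  cases$patients$sharing_consent[cases$patients$patient_id == "case-3"] <- FALSE
  snap2 <- build_snapshot(cases, cat26, attr(cases, "index"))
  expect_false("case-3" %in% snap2$triggered$patient_id)

  empty <- build_snapshot(ehr_cohort(), cat26, idx_ts())
  expect_equal(nrow(empty$triggered), 0)
})

test_that("snapshot query plus live refresh equals a fresh full screen (random cohort)", {
  co <- generate_cohort(cohort_spec(50, seed = 7))
  cat26 <- default_catalog()
  idx <- idx_ts()
  snap <- build_snapshot(co, cat26, "2014-08-15")
  for (pid in co$patients$patient_id) {
    rec <- cohort_patient(co, pid)
    merged <- screen_with_snapshot(snap, rec, cat26, idx)
    fresh <- screen_patient(rec, cat26, idx)
    expect_equal(merged$findings, fresh$findings, info = pid)
    expect_equal(merged$evidence, fresh$evidence, info = pid)
  }
})

test_that("a snapshot-era finding persists even when its evidence predates the build", {
  cases <- make_mock_cases()
  cat26 <- default_catalog()
  snap <- build_snapshot(cases, cat26, "2014-08-31")
  rep4 <- screen_with_snapshot(snap, cohort_patient(cases, "case-4"), cat26,
                               idx_ts())
  expect_equal(triggered_items(rep4), c(3L, 16L, 17L))
  expect_equal(rep4$snapshot_time, as.POSIXct("2014-08-31", tz = "UTC"))

  expect_error(screen_with_snapshot(build_snapshot(cases, cat26, "2014-09-05"),
                                    cohort_patient(cases, "case-4"), cat26,
                                    idx_ts()),
               "built after")
})

test_that("a patient absent from the snapshot still gets a full live screen", {
  cases <- make_mock_cases()
  cases$patients$sharing_consent[cases$patients$patient_id == "case-2"] <- FALSE
  cat26 <- default_catalog()
  snap <- build_snapshot(cases, cat26, "2014-08-31")
  expect_false("case-2" %in% snap$triggered$patient_id)
  # consent granted since the nightly build
  rec <- cohort_patient(cases, "case-2")
  rec$patients$sharing_consent <- TRUE
  rep <- screen_with_snapshot(snap, rec, cat26, idx_ts())
  expect_equal(triggered_items(rep), c(13L, 15L, 17L))
})

test_that("consent gating can only shrink the triggered set", {
  set.seed(123)
  for (i in 1:15) {
    rec <- random_record(pid = sprintf("p%d", i), n_diag = sample(2:8, 1),
                         n_med = sample(0:3, 1))
    rec_no <- rec
    rec_no$patients$sharing_consent <- FALSE
    cat26 <- default_catalog()
    with_consent <- triggered_items(screen_patient(rec, cat26, idx_ts(), "CCH"))
    without <- triggered_items(screen_patient(rec_no, cat26, idx_ts(), "CCH"))
    expect_true(all(without %in% with_consent),
                label = sprintf("consent subset case %d", i))
  }
})

test_that("rendered reports are stable, complete, and mirror the evidence notation", {
  cases <- make_mock_cases()
  cat26 <- default_catalog()
  rep3 <- screen_patient(cohort_patient(cases, "case-3"), cat26,
                         attr(cases, "index"))
  txt <- render_report(rep3, cat26)
  expect_true(grepl("Intracranial hemorrhage (CCH, 2010)", txt, fixed = TRUE))
  # determinism: byte-identical re-render
  expect_identical(render_report(rep3, cat26), txt)

  clear <- screen_patient(ehr_cohort(patients = tibble::tibble(patient_id = "e")),
                          cat26, idx_ts())
  lines <- strsplit(render_report(clear, cat26), "\n")[[1]]
  item_lines <- grep("^ ?[0-9]+ \\[", lines, value = TRUE)
  expect_length(item_lines, 26)
  expect_length(grep("\\[on-site\\]", item_lines), 9)
  expect_length(grep("\\[TRIGGERED\\]", item_lines), 0)

  doc <- jsonlite::fromJSON(render_report(rep3, cat26, "json"),
                            simplifyVector = FALSE)
  expect_named(doc, c("patient_id", "index", "snapshot_time", "findings",
                      "advisories", "recent_labs", "recent_imaging"))
  expect_length(doc$findings, 26)
  ev1 <- doc$findings[[1]]$evidence[[1]]
  expect_equal(ev1$hospital_id, "CCH")
  expect_equal(ev1$date, "2010-07-01")
})

test_that("snapshots persist to JSON and back", {
  cases <- make_mock_cases()
  cat26 <- default_catalog()
  snap <- build_snapshot(cases, cat26, "2014-08-31")
  f <- withr::local_tempfile(fileext = ".json")
  write_snapshot(snap, f)
  back <- read_snapshot(f)
  expect_equal(back$build_time, snap$build_time)
  expect_equal(back$triggered, snap$triggered)
  expect_equal(back$evidence, snap$evidence)
})
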