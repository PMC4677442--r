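test_that("the reference assignment is the fixed counterbalanced design", {
  a <- counterbalanced_assignment(12, paste0("case-", 1:4), seed = NULL)
  ph1 <- a$cells[a$cells$physician_id == 1, ]
  expect_equal(ph1$case_id[ph1$arm == "control"], c("case-1", "case-2"))
  expect_equal(ph1$case_id[ph1$arm == "intervention"], c("case-3", "case-4"))
  ph6 <- a$cells[a$cells$physician_id == 6, ]
  expect_equal(ph6$case_id[ph6$arm == "control"], c("case-3", "case-4"))
  # physicians 7-12 repeat the six patterns
  ph7 <- a$cells[a$cells$physician_id == 7, ]
  expect_equal(ph7$case_id, ph1$case_id)

  v <- validate_assignment(a, mock_case_truth())
  expect_true(v$valid)
  expect_true(all(v$appearances$n == 6))
  expect_equal(unname(v$opportunities), c(54, 54))
})

test_that("seeded assignments stay balanced and infeasible sizes are refused", {
  for (s in c(5, 23, 101)) {
    a <- counterbalanced_assignment(12, paste0("case-", 1:4), seed = s)
    v <- validate_assignment(a, mock_case_truth())
    expect_true(all(v$appearances$n == 6))
  }
  a18 <- counterbalanced_assignment(18, paste0("case-", 1:4), seed = 2)
  expect_true(all(validate_assignment(a18)$appearances$n == 9))

  expect_error(counterbalanced_assignment(10), "multiple of 6")
  expect_error(counterbalanced_assignment(12, paste0("c", 1:3)), "four")
})

test_that("arm summaries reproduce the expected totals, percentages, and moments", {
  ctrl <- summarize_arm(c(2, 6, 5, 2, 1, 7), opportunities = 54,
                        n_physicians = 12)
  expect_equal(ctrl$total_missed, 23)
  expect_equal(ctrl$pct_missed, 100 * 23 / 54)
  d <- arm_summary_display(ctrl)
  expect_equal(d$pct_missed, 42.6)
  expect_equal(d$item_mean, 3.8)
  expect_equal(d$item_sd, 2.5)
  expect_equal(d$item_median, 3.5)
  expect_equal(d$phys_mean, 1.9)

  intv <- arm_summary_display(summarize_arm(c(0, 1, 1, 1, 0, 4), 54, 12))
  expect_equal(intv$total_missed, 7)
  expect_equal(intv$pct_missed, 13.0)
  expect_equal(intv$item_mean, 1.2)
  expect_equal(intv$item_sd, 1.5)
  expect_equal(intv$item_median, 1.0)
  expect_equal(intv$phys_mean, 0.6)

  zeros <- summarize_arm(rep(0, 6), 54, 12)
  expect_equal(zeros$total_missed, 0)
  expect_equal(zeros$pct_missed, 0)
  expect_equal(zeros$item_sd, 0)

  expect_error(summarize_arm(c(1, 2), opportunities = 0, n_physicians = 2),
               "positive")
  expect_error(summarize_arm(c(1, 2), 54, 12, per_physician_counts = c(9, 9)),
               "disagree")
})

test_that("the pooled t test matches its closed form to 1e-10", {
  x <- c(2, 6, 5, 2, 1, 7); y <- c(0, 1, 1, 1, 0, 4)
  got <- two_sample_t(x, y, "pooled")
  oracle <- t_pooled_oracle(x, y)
  expect_equal(got$statistic, oracle$t, tolerance = 1e-10)
  expect_equal(got$df, 10)
  expect_equal(got$p_value, oracle$p, tolerance = 1e-10)

  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), mean = 0.5)
    got <- two_sample_t(x, y, "pooled")
    oracle <- t_pooled_oracle(x, y)
    expect_equal(got$statistic, oracle$t, tolerance = 1e-10)
    expect_equal(got$p_value, oracle$p, tolerance = 1e-10)
  }

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3), "pooled")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "Zero combined variance")
  expect_error(two_sample_t(1, c(1, 2)), ">= 2")

  w <- two_sample_t(c(2, 6, 5, 2, 1, 7), c(0, 1, 1, 1, 0, 4), "welch")
  expect_lt(w$df, 10)  # Welch df shrinks under unequal variances
})

test_that("exact Mann-Whitney agrees with exhaustive enumeration, including ties", {
  samples <- list(
    list(x = c(2, 6, 5, 2, 1, 7), y = c(0, 1, 1, 1, 0, 4)),
    list(x = c(1, 2, 3), y = c(4, 5, 6)),
    list(x = c(1, 1, 2, 2), y = c(1, 2, 3)),
    list(x = c(0.3, 1.7, 2.2, 0.9), y = c(1.1, 0.4, 2.9, 3.3))
  )
  for (s in samples) {
    got <- mann_whitney(s$x, s$y, "exact")
    oracle <- mw_enumeration_oracle(s$x, s$y)
    expect_equal(got$statistic, oracle$u)
    expect_equal(got$p_value, oracle$p)
  }

  expect_equal(mann_whitney(3, 3, "exact")$p_value, 1)
  expect_error(mann_whitney(rnorm(12), rnorm(12), "exact"), "normal_approx")
})

test_that("exact and normal-approximation Mann-Whitney agree on untied size-8 samples", {
  set.seed(17)
  x <- rnorm(8); y <- rnorm(8, mean = 0.8)
  pe <- mann_whitney(x, y, "exact")$p_value
  pa <- mann_whitney(x, y, "normal_approx")$p_value
  expect_lt(abs(pe - pa), 0.02)
})

test_that("the 2x2 chi-square matches its closed form, and Yates shrinks it", {
  tab <- matrix(c(23, 31, 7, 47), nrow = 2, byrow = TRUE)
  raw <- chi_square_2x2(tab, correction = FALSE)
  expect_equal(raw$statistic, chisq_2x2_oracle(tab), tolerance = 1e-10)
  expect_equal(raw$df, 1)
  expect_lt(raw$p_value, 0.001)

  yates <- chi_square_2x2(tab, correction = TRUE)
  expect_equal(yates$statistic, chisq_2x2_oracle(tab, correct = TRUE),
               tolerance = 1e-10)
  expect_lt(yates$statistic, raw$statistic)

  flat <- chi_square_2x2(matrix(c(5, 10, 5, 10), 2, byrow = TRUE),
                         correction = FALSE)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
  expect_error(chi_square_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("analyze_study conserves totals across per-item and per-physician views", {
  a <- counterbalanced_assignment(12)
  res <- simulate_responses(a, mock_case_truth(), miss_model(0.4, 0.15),
                            seed = 21)
  an <- analyze_study(a, res)
  for (arm in c("control", "intervention")) {
    total <- an$summary$total_missed[an$summary$arm == arm]
    expect_equal(sum(an$per_item$missed[an$per_item$arm == arm]), total)
    expect_equal(sum(an$per_physician$missed[an$per_physician$arm == arm]),
                 total)
    expect_equal(sum(res$missed[res$arm == arm]), total)
  }
  expect_equal(sum(an$table_2x2), 108)
  expect_equal(unname(rowSums(an$table_2x2)), c(54, 54))

  # review-time summary present and t test battery complete
  expect_false(is.null(an$times))
  expect_setequal(unique(tidy(an)$unit),
                  c("per_item", "per_physician", "opportunities_2x2",
                    "review_time"))

  # missing cells are named
  expect_error(analyze_study(a, res[res$physician_id != 4, ]),
               "missing assignment cells")
})

test_that("a zero-miss study is summarized with degenerate test flags, not errors", {
  a <- counterbalanced_assignment(12)
  res <- simulate_responses(a, mock_case_truth(), miss_model(0, 0), seed = 2)
  an <- analyze_study(a, res)
  expect_equal(an$summary$total_missed, c(0, 0))
  flags <- tidy(an)
  degen <- flags[flags$test %in% c("two_sample_t", "chi_square") &
                   flags$unit != "review_time", ]
  expect_true(all(grepl("degenerate", degen$note)))
})

test_that("study analyses export to CSV and JSON", {
  a <- counterbalanced_assignment(12)
  res <- simulate_responses(a, mock_case_truth(), miss_model(0.4, 0.1),
                            seed = 9)
  an <- analyze_study(a, res)
  fc <- withr::local_tempfile(fileext = ".csv")
  fj <- withr::local_tempfile(fileext = ".json")
  write_study_analysis(an, csv_path = fc, json_path = fj)
  expect_equal(nrow(read.csv(fc)), 12)  # 6 items x 2 arms
  doc <- jsonlite::fromJSON(fj)
  expect_equal(doc$summary$total_missed,
               an$summary$total_missed)
})
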