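# Crossover-study machinery: counterbalanced case assignment, per-arm
# summaries of missed contraindication counts, and the univariate test
# battery (pooled/Welch two-sample t, exact and normal-approximation
# Mann-Whitney, 2x2 chi-square with and without Yates correction).

#' Counterbalanced crossover assignment of test cases
#'
#' Each physician screens two cases without the decision-support tool
#' (control arm) and the other two with it (intervention arm). With four
#' cases there are six (pair | complementary pair) patterns; balance
#' requires the physician count be a multiple of six so that every case
#' appears `n_physicians / 2` times in each arm. With `seed = NULL` the
#' fixed reference assignment is returned (patterns in canonical order,
#' repeating); with a seed the pattern multiset is shuffled across
#' physicians, preserving balance.
#'
#' @param n_physicians Number of physicians; must be a positive multiple
#'   of 6 (12 in the reference design).
#' @param cases Character vector of exactly four case ids.
#' @param seed `NULL` for the reference assignment, or an integer seed.
#' @return A `study_assignment`: `$cells` tibble
#'   (`physician_id`, `arm`, `case_id`), `$n_physicians`, `$cases`.
#' @export
#' @examples
#' a <- counterbalanced_assignment(12, paste0("case-", 1:4))
#' validate_assignment(a)
counterbalanced_assignment <- function(n_physicians = 12,
                                       cases = paste0("case-", 1:4),
                                       seed = NULL) {
  if (length(cases) != 4 || anyDuplicated(cases)) {
    abort("Exactly four distinct cases are required")
  }
  if (n_physicians < 1 || n_physicians %% 6 != 0) {
    abort(paste("n_physicians must be a positive multiple of 6 so each case",
                "appears n/2 times per arm; got", n_physicians))
  }
  splits <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  patterns <- lapply(splits, function(ctrl) {
    list(control = cases[ctrl], intervention = cases[setdiff(1:4, ctrl)])
  })
  idx <- rep(seq_along(patterns), length.out = n_physicians)
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    idx <- sample(idx)
  }
  cells <- bind_rows(lapply(seq_len(n_physicians), function(p) {
    pat <- patterns[[idx[p]]]
    tibble(physician_id = p,
           arm = rep(c("control", "intervention"), each = 2),
           case_id = c(pat$control, pat$intervention))
  }))
  structure(list(cells = cells, n_physicians = n_physicians, cases = cases),
            class = "study_assignment")
}

#' @export
print.study_assignment <- function(x, ...) {
  cat(sprintf("<study_assignment> %d physicians x 4 cases (2 control / 2 intervention each)\n",
              x$n_physicians))
  invisible(x)
}

#' Validate the counterbalance of an assignment
#'
#' Checks that every physician's control and intervention pairs are disjoint
#' and cover four distinct cases, and that every case appears exactly
#' `n_physicians / 2` times per arm. When `case_truth` is supplied the
#' per-arm number of contraindication-item opportunities is also computed
#' (appearances per case times items per case).
#'
#' @param assignment A `study_assignment`.
#' @param case_truth Optional named list: case id -> item-id vector (see
#'   [mock_case_truth()]).
#' @return A list: `valid` (TRUE or an error is raised),
#'   `appearances` tibble (`case_id`, `arm`, `n`), and `opportunities`
#'   per arm (named numeric, present when `case_truth` given).
#' @export
validate_assignment <- function(assignment, case_truth = NULL) {
  stopifnot(inherits(assignment, "study_assignment"))
  cells <- assignment$cells
  per_phys <- split(cells, cells$physician_id)
  for (ph in per_phys) {
    if (nrow(ph) != 4 || anyDuplicated(ph$case_id) ||
        !setequal(ph$case_id, assignment$cases) ||
        sum(ph$arm == "control") != 2) {
      abort(sprintf("Physician %s: pairs must be disjoint and cover all 4 cases",
                    ph$physician_id[1]))
    }
  }
  appearances <- count(cells, .data$case_id, .data$arm)
  want <- assignment$n_physicians / 2
  if (any(appearances$n != want)) {
    abort(sprintf("Unbalanced assignment: each case must appear %d times per arm",
                  want))
  }
  out <- list(valid = TRUE, appearances = appearances)
  if (!is.null(case_truth)) {
    items_per_case <- vapply(case_truth, length, integer(1))
    opp <- vapply(c("control", "intervention"), function(a) {
      sub <- cells[cells$arm == a, ]
      sum(items_per_case[sub$case_id])
    }, numeric(1))
    out$opportunities <- opp
  }
  out
}

#' Summarize one study arm's missed contraindications
#'
#' @param per_item_counts Numeric vector: missed count per contraindication
#'   item (one entry per distinct item in the design).
#' @param opportunities Total contraindication-item opportunities in the arm
#'   (54 in the reference design: 9 items per full case set, 6 appearances).
#' @param n_physicians Number of physicians contributing to the arm.
#' @param per_physician_counts Optional numeric vector of per-physician
#'   missed totals; enables the per-physician SD and median.
#' @return A one-row tibble at full precision: `total_missed`, `pct_missed`,
#'   `item_mean`, `item_sd`, `item_median`, `phys_mean`, `phys_sd`,
#'   `phys_median` (the latter two `NA` without per-physician counts).
#'   Use [arm_summary_display()] for the 1-decimal display view.
#' @export
#' @examples
#' summarize_arm(c(2, 6, 5, 2, 1, 7), opportunities = 54, n_physicians = 12)
summarize_arm <- function(per_item_counts, opportunities, n_physicians,
                          per_physician_counts = NULL) {
  if (opportunities <= 0) abort("opportunities must be positive")
  if (any(per_item_counts < 0)) abort("Counts must be non-negative")
  total <- sum(per_item_counts)
  if (!is.null(per_physician_counts) &&
      !isTRUE(all.equal(sum(per_physician_counts), total))) {
    abort("Per-item and per-physician totals disagree")
  }
  tibble(
    total_missed = total,
    pct_missed = 100 * total / opportunities,
    item_mean = mean(per_item_counts),
    item_sd = if (length(per_item_counts) > 1) sd(per_item_counts) else 0,
    item_median = median(per_item_counts),
    phys_mean = total / n_physicians,
    phys_sd = if (!is.null(per_physician_counts))
      sd(per_physician_counts) else NA_real_,
    phys_median = if (!is.null(per_physician_counts))
      median(per_physician_counts) else NA_real_
  )
}

#' Display view of an arm summary (1 decimal, half-up)
#'
#' @param summary A one- or two-row tibble from [summarize_arm()].
#' @return The same tibble with all non-count columns rounded to one
#'   decimal using half-up rounding.
#' @export
arm_summary_display <- function(summary) {
  num <- setdiff(names(summary)[vapply(summary, is.numeric, logical(1))],
                 "total_missed")
  for (col in num) summary[[col]] <- round_half_up(summary[[col]], 1)
  summary
}

#' Two-sample (unpaired) t test
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param variant `"pooled"` (classic equal-variance, df `n1 + n2 - 2`) or
#'   `"welch"`.
#' @return One-row tibble: `test`, `variant`, `statistic`, `df`, `p_value`.
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) abort("Each sample needs >= 2 values")
  if (sd(x) == 0 && sd(y) == 0) {
    abort("Zero combined variance: t statistic undefined")
  }
  fit <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  tibble(test = "two_sample_t", variant = variant,
         statistic = unname(fit$statistic), df = unname(fit$parameter),
         p_value = fit$p.value)
}

rank_midties <- function(v) rank(v, ties.method = "average")

u_statistic <- function(x, y) {
  r <- rank_midties(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' `mode = "exact"` enumerates all `choose(n1 + n2, n1)` assignments of the
#' pooled mid-rank vector to the first sample (valid under ties) and reports
#' the two-sided probability of a U at least as far from its null mean
#' `n1 n2 / 2` as observed. `mode = "normal_approx"` uses the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param x,y Non-empty numeric samples; exact mode requires
#'   `n1 + n2 <= 20`.
#' @param mode `"exact"` or `"normal_approx"`.
#' @return One-row tibble: `test`, `mode`, `statistic` (U for the first
#'   sample), `df` (NA), `p_value`.
#' @export
mann_whitney <- function(x, y, mode = c("exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) abort("Samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  u_obs <- u_statistic(x, y)
  if (mode == "exact") {
    if (n1 + n2 > 20) {
      abort("Exact enumeration limited to n1 + n2 <= 20; use mode = \"normal_approx\"")
    }
    r <- rank_midties(c(x, y))
    mu <- n1 * n2 / 2
    dev_obs <- abs(u_obs - mu)
    sets <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= dev_obs - 1e-9)
    return(tibble(test = "mann_whitney", mode = mode, statistic = u_obs,
                  df = NA_real_, p_value = p))
  }
  fit <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  tibble(test = "mann_whitney", mode = mode, statistic = u_obs,
         df = NA_real_, p_value = fit$p.value)
}

#' Chi-square test on a 2x2 table
#'
#' @param table 2x2 matrix of non-negative integer counts (e.g. missed vs
#'   not-missed opportunities by study arm); no marginal may be zero.
#' @param correction Apply the Yates continuity correction (default TRUE).
#' @return One-row tibble: `test`, `corrected`, `statistic`, `df`,
#'   `p_value`.
#' @export
chi_square_2x2 <- function(table, correction = TRUE) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) abort("A 2x2 table is required")
  if (any(m < 0) || any(m != round(m))) {
    abort("Counts must be non-negative integers")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Zero marginal: chi-square undefined")
  }
  fit <- suppressWarnings(stats::chisq.test(m, correct = correction))
  tibble(test = "chi_square", corrected = correction,
         statistic = unname(fit$statistic), df = unname(fit$parameter),
         p_value = fit$p.value)
}

#' Analyze a crossover screening study
#'
#' Aggregates per-opportunity results into per-arm summaries and runs the
#' univariate battery: pooled t and Mann-Whitney on the per-item and
#' per-physician missed-count vectors, and chi-square (with and without
#' Yates correction) on the 2x2 of missed vs caught opportunities by arm.
#' When `time_min` is present, per-arm review-time summaries and a t test
#' on the per-set times are added. Degenerate comparisons (zero variance,
#' all-zero counts) are flagged rather than run.
#'
#' @param assignment A `study_assignment`.
#' @param results Tibble with columns `physician_id`, `arm`, `case_id`,
#'   `item_id`, `missed` (0/1), optionally `time_min` — one row per
#'   contraindication-item opportunity, covering every assignment cell
#'   (as produced by [simulate_responses()]).
#' @return A `study_analysis`: `$summary` (two rows, control then
#'   intervention), `$tests`, `$per_item` counts, `$per_physician` counts,
#'   `$times` (or NULL), `$opportunities`.
#' @export
analyze_study <- function(assignment, results) {
  stopifnot(inherits(assignment, "study_assignment"))
  need <- c("physician_id", "arm", "case_id", "item_id", "missed")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols)) {
    abort(paste("results lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  cells <- distinct(results[, c("physician_id", "arm", "case_id")])
  missing_cells <- dplyr::anti_join(assignment$cells, cells,
                                    by = c("physician_id", "arm", "case_id"))
  if (nrow(missing_cells)) {
    abort(paste("results missing assignment cells:",
                paste(sprintf("(%s,%s,%s)", missing_cells$physician_id,
                              missing_cells$arm, missing_cells$case_id),
                      collapse = " ")))
  }
  arms <- c("control", "intervention")
  items <- sort(unique(results$item_id))
  per_item <- results %>%
    group_by(.data$arm, .data$item_id) %>%
    summarise(missed = sum(.data$missed), .groups = "drop") %>%
    tidyr::complete(arm = arms, item_id = items, fill = list(missed = 0L))
  per_phys <- results %>%
    group_by(.data$arm, .data$physician_id) %>%
    summarise(missed = sum(.data$missed), .groups = "drop") %>%
    tidyr::complete(arm = arms,
                    physician_id = unique(assignment$cells$physician_id),
                    fill = list(missed = 0L))
  opportunities <- vapply(arms, function(a) sum(results$arm == a), numeric(1))
  vec <- function(df, a) df$missed[df$arm == a]
  summary <- bind_rows(lapply(arms, function(a) {
    mutate(summarize_arm(vec(per_item, a), opportunities[[a]],
                         assignment$n_physicians, vec(per_phys, a)),
           arm = a, .before = 1)
  }))
  safe <- function(expr, test, unit, extra = list()) {
    row <- tryCatch(expr, error = function(e) {
      tibble(test = test, statistic = NA_real_, df = NA_real_,
             p_value = NA_real_, note = paste("degenerate:",
                                              conditionMessage(e)))
    })
    if (!"note" %in% names(row)) row$note <- NA_character_
    row$unit <- unit
    for (nm in names(extra)) row[[nm]] <- extra[[nm]]
    row
  }
  xs_item <- vec(per_item, "control"); ys_item <- vec(per_item, "intervention")
  xs_ph <- vec(per_phys, "control"); ys_ph <- vec(per_phys, "intervention")
  tot <- c(sum(xs_item), sum(ys_item))
  tab <- matrix(c(tot[1], opportunities[["control"]] - tot[1],
                  tot[2], opportunities[["intervention"]] - tot[2]),
                nrow = 2, byrow = TRUE,
                dimnames = list(arms, c("missed", "caught")))
  tests <- bind_rows(
    safe(two_sample_t(xs_item, ys_item, "pooled"), "two_sample_t", "per_item"),
    safe(mann_whitney(xs_item, ys_item,
                      if (length(c(xs_item, ys_item)) <= 20) "exact"
                      else "normal_approx"),
         "mann_whitney", "per_item"),
    safe(two_sample_t(xs_ph, ys_ph, "pooled"), "two_sample_t",
         "per_physician"),
    safe(mann_whitney(xs_ph, ys_ph, "normal_approx"), "mann_whitney",
         "per_physician"),
    safe(chi_square_2x2(tab, correction = TRUE), "chi_square",
         "opportunities_2x2"),
    safe(chi_square_2x2(tab, correction = FALSE), "chi_square",
         "opportunities_2x2")
  )
  times <- NULL
  if ("time_min" %in% names(results)) {
    sets <- distinct(results[, c("physician_id", "arm", "time_min")])
    times <- sets %>%
      group_by(.data$arm) %>%
      summarise(mean_min = mean(.data$time_min), sd_min = sd(.data$time_min),
                median_min = median(.data$time_min), .groups = "drop")
    tests <- bind_rows(tests,
                       safe(two_sample_t(sets$time_min[sets$arm == "control"],
                                         sets$time_min[sets$arm == "intervention"],
                                         "pooled"),
                            "two_sample_t", "review_time"))
  }
  structure(list(summary = summary, tests = tests, per_item = per_item,
                 per_physician = per_phys, times = times,
                 opportunities = opportunities,
                 table_2x2 = tab),
            class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  disp <- arm_summary_display(x$summary)
  cat("<study_analysis>\n")
  for (i in seq_len(nrow(disp))) {
    cat(sprintf("  %-12s missed %d/%d (%.1f%%), per-item %.1f +/- %.1f (median %.1f)\n",
                disp$arm[i], disp$total_missed[i],
                x$opportunities[[disp$arm[i]]], disp$pct_missed[i],
                disp$item_mean[i], disp$item_sd[i], disp$item_median[i]))
  }
  invisible(x)
}

#' @method tidy study_analysis
#' @export
tidy.study_analysis <- function(x, ...) {
  select(x$tests, "test", "unit", dplyr::any_of(c("variant", "mode",
                                                  "corrected")),
         "statistic", "df", "p_value", "note")
}

#' @method glance study_analysis
#' @export
glance.study_analysis <- function(x, ...) {
  s <- x$summary
  chi <- x$tests[x$tests$test == "chi_square" &
                   vapply(x$tests$corrected %||% NA, isTRUE, logical(1)), ]
  tibble(control_missed = s$total_missed[s$arm == "control"],
         control_pct = s$pct_missed[s$arm == "control"],
         intervention_missed = s$total_missed[s$arm == "intervention"],
         intervention_pct = s$pct_missed[s$arm == "intervention"],
         opportunities = unname(x$opportunities[["control"]]),
         chi_sq_p = if (nrow(chi)) chi$p_value[1] else NA_real_)
}

#' Plot per-item missed counts by arm
#'
#' @param object A `study_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot study_analysis
#' @export
autoplot.study_analysis <- function(object, ...) {
  ggplot2::ggplot(object$per_item,
                  ggplot2::aes(x = factor(.data$item_id), y = .data$missed,
                               fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "contraindication item", y = "missed count",
                  fill = NULL,
                  title = "Missed contraindications per item by study arm") +
    ggplot2::theme_minimal()
}

#' Export a study analysis
#'
#' @param analysis A `study_analysis`.
#' @param csv_path Optional path: writes the per-item counts as CSV.
#' @param json_path Optional path: writes summaries and tests as JSON.
#' @return `analysis`, invisibly.
#' @export
write_study_analysis <- function(analysis, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(analysis, "study_analysis"))
  if (!is.null(csv_path)) {
    write.csv(analysis$per_item, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    doc <- list(summary = analysis$summary,
                summary_display = arm_summary_display(analysis$summary),
                tests = analysis$tests,
                opportunities = as.list(analysis$opportunities),
                times = analysis$times)
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", na = "null", digits = NA)
  }
  invisible(analysis)
}
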