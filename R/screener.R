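# Screening engine: evaluates the contraindication catalog against one
# patient's consent-visible events at a code-stroke index time, supports a
# daily precomputed snapshot database merged with a live refresh, and
# renders evidence-backed checklist reports.
#
# Window semantics: a clause with lookback W matches events with
# index_day - W <= date <= index_day (closed interval, calendar days).
# Events dated after the index are ignored entirely. Medication orders
# match when their active interval [start, stop] (stop open = ongoing)
# overlaps the clause window and started on or before the index.

empty_evidence <- function() {
  tibble(source = character(), hospital_id = character(), concept = character(),
         date = as.Date(character()), end_date = as.Date(character()),
         code = character())
}

sort_evidence <- function(ev) {
  distinct(arrange(ev, .data$date, .data$hospital_id, .data$concept))
}

clause_evidence <- function(clause, record, index_day) {
  labels <- clause$concepts$labels
  codes <- clause$concepts$codes
  lb <- clause$lookback_days
  window_lo <- if (identical(lb, "unlimited")) as.Date("0001-01-01") else
    index_day - lb
  if (clause$source == "diagnosis") {
    df <- record$diagnoses
    hit <- tolower(df$concept) %in% labels
    if (length(codes)) {
      coded <- toupper(paste0(df$code_system, ":", df$code))
      hit <- hit | (!is.na(df$code) & coded %in% codes)
    }
    df <- df[hit & df$date >= window_lo & df$date <= index_day, ]
    return(tibble(source = rep("diagnosis", nrow(df)),
                  hospital_id = df$hospital_id, concept = df$concept,
                  date = df$date, end_date = as.Date(NA)[rep(1, nrow(df))],
                  code = ifelse(is.na(df$code), NA_character_,
                                paste0(df$code_system, ":", df$code))))
  }
  if (clause$source == "adr") {
    df <- record$adverse_reactions
    hit <- tolower(df$drug_concept) %in% labels |
      tolower(df$reaction) %in% labels
    df <- df[hit & df$date >= window_lo & df$date <= index_day, ]
    return(tibble(source = rep("adr", nrow(df)),
                  hospital_id = df$hospital_id, concept = df$drug_concept,
                  date = df$date, end_date = as.Date(NA)[rep(1, nrow(df))],
                  code = NA_character_[rep(1, nrow(df))]))
  }
  # medication: concept or class-tag match, interval overlap with the window
  df <- record$medications
  tag_hit <- vapply(df$tags, function(t) any(tolower(t %||% character()) %in% labels),
                    logical(1))
  hit <- tolower(df$drug_concept) %in% labels | tag_hit
  started <- !is.na(df$start_date) & df$start_date <= index_day
  active_end <- ifelse(is.na(df$stop_date), as.numeric(index_day),
                       as.numeric(df$stop_date))
  overlaps <- active_end >= as.numeric(window_lo)
  df <- df[hit & started & overlaps, ]
  tibble(source = rep("medication", nrow(df)),
         hospital_id = df$hospital_id, concept = df$drug_concept,
         date = df$start_date, end_date = df$stop_date,
         code = NA_character_[rep(1, nrow(df))])
}

eval_predicate <- function(node, record, index_day) {
  key <- names(node)
  if (identical(key, "exists")) {
    ev <- clause_evidence(node$exists, record, index_day)
    return(list(satisfied = nrow(ev) > 0, evidence = ev))
  }
  child <- lapply(node[[1]], eval_predicate, record = record,
                  index_day = index_day)
  sat <- vapply(child, `[[`, logical(1), "satisfied")
  ok <- if (identical(key, "all")) all(sat) else any(sat)
  ev <- if (ok) bind_rows(lapply(child[sat], `[[`, "evidence")) else
    empty_evidence()
  list(satisfied = ok, evidence = ev)
}

#' Evaluate a single contraindication rule against a patient record
#'
#' @param rule One element of a `ci_catalog`'s `$items`.
#' @param record Single-patient [ehr_cohort()] (already consent-filtered if
#'   that is wanted; [screen_patient()] handles it for you).
#' @param index Index (stroke-onset/code-stroke) timestamp; events dated
#'   after it are ignored.
#' @return A list: `item_id`, `status` (`"TRIGGERED"`, `"CLEAR"`, or
#'   `"NOT_EXTRACTABLE"`), and an `evidence` tibble listing every matching
#'   event (all hospitals), sorted by date, hospital, concept.
#' @export
evaluate_rule <- function(rule, record, index) {
  index_day <- as_day(as_clock(index))
  if (!rule$extractable) {
    return(list(item_id = rule$item_id, status = "NOT_EXTRACTABLE",
                evidence = empty_evidence()))
  }
  res <- eval_predicate(rule$predicate, record, index_day)
  list(item_id = rule$item_id,
       status = if (res$satisfied) "TRIGGERED" else "CLEAR",
       evidence = sort_evidence(res$evidence))
}

finding_tibbles <- function(catalog, record, index_day) {
  findings <- lapply(catalog$items, function(rule) {
    if (!rule$extractable) {
      return(list(item_id = rule$item_id, status = "NOT_EXTRACTABLE",
                  evidence = empty_evidence()))
    }
    res <- eval_predicate(rule$predicate, record, index_day)
    list(item_id = rule$item_id,
         status = if (res$satisfied) "TRIGGERED" else "CLEAR",
         evidence = sort_evidence(res$evidence))
  })
  ftab <- bind_rows(lapply(findings, function(f) {
    tibble(item_id = f$item_id, status = f$status)
  }))
  ev <- bind_rows(lapply(findings, function(f) {
    if (!nrow(f$evidence)) return(NULL)
    mutate(f$evidence, item_id = f$item_id, .before = 1)
  }))
  if (is.null(ev) || !nrow(ev)) {
    ev <- mutate(empty_evidence(), item_id = integer(), .before = 1)
  }
  list(findings = ftab, evidence = ev)
}

advisory_tibble <- function(catalog, record, index_day) {
  out <- bind_rows(lapply(catalog$advisories, function(a) {
    res <- eval_predicate(a$predicate, record, index_day)
    if (!res$satisfied) return(NULL)
    mutate(sort_evidence(res$evidence), label = a$label, .before = 1)
  }))
  if (is.null(out) || !nrow(out)) {
    out <- mutate(empty_evidence(), label = character(), .before = 1)
  }
  out
}

new_screen_report <- function(patient_id, index, findings, evidence,
                              advisories, recent_labs, recent_imaging,
                              snapshot_time = NULL) {
  structure(list(patient_id = patient_id, index = index,
                 snapshot_time = snapshot_time, findings = findings,
                 evidence = evidence, advisories = advisories,
                 recent_labs = recent_labs, recent_imaging = recent_imaging),
            class = "screen_report")
}

#' Screen a patient for thrombolysis contraindications
#'
#' Runs every catalog item against the patient's consent-visible events at
#' the index time and collects the last-24-hour laboratory and imaging
#' results. The result is deterministic given its inputs.
#'
#' @param record Single-patient [ehr_cohort()].
#' @param catalog A `ci_catalog`, e.g. [default_catalog()].
#' @param index Index (code-stroke) timestamp, `POSIXct`/`Date`/ISO string.
#' @param home_hospital Treating hospital code; consent gating is applied
#'   relative to this site via [restrict_to_consented()].
#' @return A `screen_report`: per-item `findings` (one row per catalog item),
#'   `evidence` with provenance (hospital, date, concept, code), triggered
#'   `advisories`, and `recent_labs` / `recent_imaging` within
#'   `index - 24 h <= t <= index`.
#' @export
#' @examples
#' cases <- make_mock_cases()
#' rep1 <- screen_patient(cohort_patient(cases, "case-1"), default_catalog(),
#'                        attr(cases, "index"))
#' dplyr::filter(tidy(rep1), status == "TRIGGERED")
screen_patient <- function(record, catalog, index, home_hospital = "CCH") {
  stopifnot(inherits(catalog, "ci_catalog"))
  validate_cohort(record)
  if (nrow(record$patients) != 1) {
    abort("screen_patient expects a single-patient record; see cohort_patient()")
  }
  index <- as_clock(index)
  index_day <- as_day(index)
  record <- restrict_to_consented(record, home_hospital)
  ft <- finding_tibbles(catalog, record, index_day)
  adv <- advisory_tibble(catalog, record, index_day)
  lab_ok <- record$labs$collected_at >= index - 86400 &
    record$labs$collected_at <= index
  img_ok <- record$imaging$acquired_at >= index - 86400 &
    record$imaging$acquired_at <= index
  new_screen_report(record$patients$patient_id, index, ft$findings,
                    ft$evidence, adv,
                    select(record$labs[lab_ok, ], -"extras"),
                    select(record$imaging[img_ok, ], -"extras"))
}

#' @export
print.screen_report <- function(x, ...) {
  trig <- x$findings$item_id[x$findings$status == "TRIGGERED"]
  cat(sprintf("<screen_report> patient %s @ %s\n", x$patient_id,
              iso_clock(x$index)))
  cat(sprintf("  triggered items: %s\n",
              if (length(trig)) paste(trig, collapse = ", ") else "none"))
  cat(sprintf("  advisories: %s\n",
              if (nrow(x$advisories)) paste(unique(x$advisories$label),
                                            collapse = ", ") else "none"))
  invisible(x)
}

#' Build the daily snapshot database
#'
#' Precomputes, for every consented patient, the catalog items that are
#' TRIGGERED using only events dated on or before `as_of`, together with
#' their evidence. Patients without sharing consent are omitted; CLEAR
#' findings are not stored (they are recomputed at query time).
#'
#' @param cohort An [ehr_cohort()] of the whole population.
#' @param catalog A `ci_catalog`.
#' @param as_of Build timestamp.
#' @return An `ehr_snapshot`: `build_time`, `triggered`
#'   (patient_id, item_id), and `evidence` tibbles.
#' @export
build_snapshot <- function(cohort, catalog, as_of) {
  stopifnot(inherits(catalog, "ci_catalog"))
  validate_cohort(cohort)
  as_of <- as_clock(as_of)
  as_of_day <- as_day(as_of)
  consented <- cohort$patients$patient_id[cohort$patients$sharing_consent]
  trig <- list(); evid <- list()
  for (pid in consented) {
    rec <- cohort_patient(cohort, pid)
    ft <- finding_tibbles(catalog, rec, as_of_day)
    t <- filter(ft$findings, .data$status == "TRIGGERED")
    if (nrow(t)) {
      trig[[pid]] <- mutate(t, patient_id = pid, .before = 1)
      evid[[pid]] <- mutate(filter(ft$evidence, .data$item_id %in% t$item_id),
                            patient_id = pid, .before = 1)
    }
  }
  triggered <- if (length(trig)) select(bind_rows(trig), -"status") else
    tibble(patient_id = character(), item_id = integer())
  evidence <- if (length(evid)) bind_rows(evid) else
    mutate(mutate(empty_evidence(), item_id = integer(), .before = 1),
           patient_id = character(), .before = 1)
  structure(list(build_time = as_of, triggered = triggered,
                 evidence = evidence),
            class = "ehr_snapshot")
}

#' @export
print.ehr_snapshot <- function(x, ...) {
  cat(sprintf("<ehr_snapshot> built %s: %d triggered findings across %d patients\n",
              iso_clock(x$build_time), nrow(x$triggered),
              length(unique(x$triggered$patient_id))))
  invisible(x)
}

#' Screen at code-stroke time using the snapshot plus a live refresh
#'
#' Queries the precomputed snapshot for the patient and merges it with a
#' live evaluation over the consent-visible record up to the index time,
#' so that findings whose evidence straddles the snapshot build time are
#' still complete. The merged report is identical to running
#' [screen_patient()] directly on the full record.
#'
#' @param snapshot An `ehr_snapshot` with `build_time <= index`.
#' @inheritParams screen_patient
#' @return A `screen_report` with `snapshot_time` set.
#' @export
screen_with_snapshot <- function(snapshot, record, catalog, index,
                                 home_hospital = "CCH") {
  stopifnot(inherits(snapshot, "ehr_snapshot"))
  index <- as_clock(index)
  if (snapshot$build_time > index) {
    abort("Snapshot was built after the index time")
  }
  live <- screen_patient(record, catalog, index, home_hospital)
  pid <- live$patient_id
  snap_t <- filter(snapshot$triggered, .data$patient_id == pid)
  snap_e <- select(filter(snapshot$evidence, .data$patient_id == pid),
                   -"patient_id")
  findings <- mutate(live$findings,
                     status = ifelse(.data$item_id %in% snap_t$item_id,
                                     "TRIGGERED", .data$status))
  evidence <- sort_evidence_by_item(bind_rows(live$evidence, snap_e))
  new_screen_report(pid, index, findings, evidence, live$advisories,
                    live$recent_labs, live$recent_imaging,
                    snapshot_time = snapshot$build_time)
}

sort_evidence_by_item <- function(ev) {
  distinct(arrange(ev, .data$item_id, .data$date, .data$hospital_id,
                   .data$concept))
}

#' Tidy a screen report
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return A tibble with one row per catalog item: `item_id`, `status`, and
#'   `n_evidence`.
#' @method tidy screen_report
#' @export
tidy.screen_report <- function(x, ...) {
  evn <- count(x$evidence, .data$item_id, name = "n_evidence")
  out <- left_join(x$findings, evn, by = "item_id")
  out$n_evidence[is.na(out$n_evidence)] <- 0L
  out
}

#' @method glance screen_report
#' @export
glance.screen_report <- function(x, ...) {
  tibble(patient_id = x$patient_id,
         n_triggered = sum(x$findings$status == "TRIGGERED"),
         n_clear = sum(x$findings$status == "CLEAR"),
         n_on_site = sum(x$findings$status == "NOT_EXTRACTABLE"),
         n_advisories = length(unique(x$advisories$label)),
         n_recent_labs = nrow(x$recent_labs),
         n_recent_imaging = nrow(x$recent_imaging))
}

format_evidence <- function(ev) {
  cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  paste0(cap(ev$concept), " (", ev$hospital_id, ", ", format(ev$date, "%Y"), ")")
}

#' Render a screen report as text or JSON
#'
#' The text view is a checklist ordered by item id; TRIGGERED items list
#' their evidence in `Concept (HOSPITAL, year)` notation. Output is stable
#' for diffing: identical inputs render byte-identically.
#'
#' @param report A `screen_report`.
#' @param catalog The `ci_catalog` the report was produced with.
#' @param format `"text"` (default) or `"json"`.
#' @return A single string.
#' @export
render_report <- function(report, catalog, format = c("text", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "screen_report"), inherits(catalog, "ci_catalog"))
  labels <- setNames(vapply(catalog$items, `[[`, character(1), "label"),
                     vapply(catalog$items, `[[`, integer(1), "item_id"))
  if (format == "json") {
    ev_by_item <- split(report$evidence, report$evidence$item_id)
    doc <- list(
      patient_id = report$patient_id,
      index = iso_clock(report$index),
      snapshot_time = if (is.null(report$snapshot_time)) NULL else
        iso_clock(report$snapshot_time),
      findings = lapply(seq_len(nrow(report$findings)), function(i) {
        id <- report$findings$item_id[i]
        ev <- ev_by_item[[as.character(id)]]
        list(item_id = id, label = unname(labels[as.character(id)]),
             status = report$findings$status[i],
             evidence = if (is.null(ev)) list() else
               lapply(seq_len(nrow(ev)), function(j) {
                 list(source = ev$source[j], hospital_id = ev$hospital_id[j],
                      concept = ev$concept[j], date = iso_day(ev$date[j]),
                      end_date = iso_day(ev$end_date[j]), code = ev$code[j])
               }))
      }),
      advisories = lapply(unique(report$advisories$label), function(l) {
        ev <- filter(report$advisories, .data$label == l)
        list(label = l, evidence = format_evidence(ev))
      }),
      recent_labs = nrow(report$recent_labs),
      recent_imaging = nrow(report$recent_imaging)
    )
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                                         na = "null", pretty = TRUE,
                                         digits = NA)))
  }
  lines <- c(sprintf("Contraindication screen for %s at %s",
                     report$patient_id, iso_clock(report$index)))
  if (!is.null(report$snapshot_time)) {
    lines <- c(lines, sprintf("Snapshot database built %s",
                              iso_clock(report$snapshot_time)))
  }
  for (i in seq_len(nrow(report$findings))) {
    id <- report$findings$item_id[i]
    status <- report$findings$status[i]
    tag <- switch(status, TRIGGERED = "[TRIGGERED]", CLEAR = "[clear]    ",
                  NOT_EXTRACTABLE = "[on-site]  ")
    line <- sprintf("%2d %s %s", id, tag, labels[as.character(id)])
    if (status == "TRIGGERED") {
      ev <- filter(report$evidence, .data$item_id == id)
      line <- paste0(line, ": ", paste(format_evidence(ev), collapse = "; "))
    }
    lines <- c(lines, line)
  }
  if (nrow(report$advisories)) {
    lines <- c(lines, "Advisories (attention, not exclusion):")
    for (l in unique(report$advisories$label)) {
      ev <- filter(report$advisories, .data$label == l)
      lines <- c(lines, sprintf("  - %s: %s", l,
                                paste(format_evidence(ev), collapse = "; ")))
    }
  }
  lines <- c(lines,
             sprintf("Recent labs (24 h): %d; recent imaging (24 h): %d",
                     nrow(report$recent_labs), nrow(report$recent_imaging)))
  paste(lines, collapse = "\n")
}

#' Plot a screen report as a checklist tile strip
#'
#' @param object A `screen_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_report
#' @export
autoplot.screen_report <- function(object, ...) {
  df <- tidy(object)
  df$status <- factor(df$status,
                      levels = c("TRIGGERED", "CLEAR", "NOT_EXTRACTABLE"))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$item_id), y = 1,
                                   fill = .data$status)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(TRIGGERED = "#c0392b",
                                          CLEAR = "#7fbf7f",
                                          NOT_EXTRACTABLE = "#95a5a6"),
                               drop = FALSE) +
    ggplot2::labs(x = "contraindication item", y = NULL,
                  title = paste("Screen:", object$patient_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Persist / load a snapshot database as JSON
#'
#' @param snapshot An `ehr_snapshot`.
#' @param path JSON file path.
#' @return `path` (write) or an `ehr_snapshot` (read).
#' @export
write_snapshot <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "ehr_snapshot"))
  ev <- snapshot$evidence
  doc <- list(build_time = iso_clock(snapshot$build_time),
              triggered = snapshot$triggered,
              evidence = mutate(ev, date = iso_day(.data$date),
                                end_date = iso_day(.data$end_date)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", na = "null", digits = NA)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  trig <- as_tibble(doc$triggered)
  if (!nrow(trig)) trig <- tibble(patient_id = character(), item_id = integer())
  trig$item_id <- as.integer(trig$item_id)
  ev <- as_tibble(doc$evidence)
  if (!nrow(ev)) {
    ev <- mutate(mutate(empty_evidence(), item_id = integer(), .before = 1),
                 patient_id = character(), .before = 1)
  } else {
    ev$item_id <- as.integer(ev$item_id)
    ev$date <- as_day(ev$date)
    ev$end_date <- as_day(ev$end_date)
    ev$code <- as.character(ev$code)
  }
  structure(list(build_time = as_clock(doc$build_time), triggered = trig,
                 evidence = ev),
            class = "ehr_snapshot")
}
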