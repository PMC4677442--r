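# JSON Lines serialization of EHR cohorts.
#
# One JSON object per line. A patient header line
#   {"record_type":"patient","patient_id":...,"sharing_consent":...}
# precedes that patient's events ("diagnosis", "medication", "adr", "lab",
# "imaging"). Dates are ISO-8601 days, timestamps ISO-8601 seconds. Unknown
# fields on any line are preserved in an `extras` map and round-trip.

record_type_of <- c(diagnoses = "diagnosis", medications = "medication",
                    adverse_reactions = "adr", labs = "lab", imaging = "imaging")

known_fields <- list(
  patient = c("patient_id", "birth_year", "sex", "weight_kg", "sharing_consent"),
  diagnosis = c("patient_id", "hospital_id", "concept", "code", "code_system",
                "date", "encounter_kind"),
  medication = c("patient_id", "hospital_id", "drug_concept", "start_date",
                 "stop_date", "tags"),
  adr = c("patient_id", "hospital_id", "drug_concept", "reaction", "date"),
  lab = c("patient_id", "hospital_id", "analyte", "value", "units",
          "collected_at"),
  imaging = c("patient_id", "hospital_id", "modality", "finding_summary",
              "acquired_at")
)

json_line <- function(obj) {
  obj <- obj[order(names(obj))]
  jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", na = "null",
                   digits = NA)
}

row_to_obj <- function(row, type) {
  obj <- list(record_type = type)
  for (f in known_fields[[type]]) {
    v <- row[[f]]
    if (is.list(v)) v <- v[[1]]
    if (inherits(v, "Date")) v <- iso_day(v)
    if (inherits(v, "POSIXct")) v <- iso_clock(v)
    if (identical(f, "tags")) {
      obj[[f]] <- as.list(v %||% character())
    } else {
      obj[[f]] <- if (length(v) == 1 && is.na(v)) NULL else v
    }
  }
  # medication stop_date: open-ended serializes explicitly as null
  if (type == "medication" && is.null(obj$stop_date)) obj["stop_date"] <- list(NULL)
  extras <- row$extras[[1]]
  if (!is.null(extras) && length(extras)) obj[names(extras)] <- extras
  obj
}

#' Write an EHR cohort to a JSON Lines file
#'
#' Serialization is deterministic: patients in `patient_id` order, events in
#' canonical (date, hospital, concept) order, JSON keys sorted, dates as
#' ISO-8601. A file written here re-reads to an equal cohort via
#' [read_records()].
#'
#' @param cohort An [ehr_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(cohort, path) {
  cohort <- sort_cohort(validate_cohort(cohort))
  lines <- character(0)
  for (i in seq_len(nrow(cohort$patients))) {
    prow <- cohort$patients[i, ]
    lines <- c(lines, json_line(row_to_obj(prow, "patient")))
    for (kind in event_kinds) {
      ev <- cohort[[kind]]
      ev <- ev[ev$patient_id == prow$patient_id, ]
      for (j in seq_len(nrow(ev))) {
        lines <- c(lines, json_line(row_to_obj(ev[j, ], record_type_of[[kind]])))
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

parse_obj <- function(obj, lineno) {
  type <- obj$record_type
  if (is.null(type) || !type %in% c("patient", names(known_fields))) {
    abort(sprintf("Line %d: missing or unknown record_type", lineno))
  }
  known <- known_fields[[type]]
  extras <- obj[setdiff(names(obj), c("record_type", known))]
  row <- obj[intersect(names(obj), known)]
  row$extras <- if (length(extras)) list(extras) else list(NULL)
  if (type == "medication") {
    row$tags <- list(as.character(unlist(obj$tags)))
    if (!"stop_date" %in% names(obj) || is.null(obj$stop_date)) {
      row$stop_date <- NA_character_
    }
  }
  row[vapply(row, is.null, logical(1))] <- NULL
  list(type = type, row = row)
}

#' Read an EHR cohort from a JSON Lines file
#'
#' @param path Path to a JSONL event file as produced by [write_records()].
#' @return An [ehr_cohort()]. Reading is order-independent: shuffling event
#'   lines yields an equal cohort.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) abort(paste("No such file:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) {
                      abort(sprintf("Line %d: malformed JSON (%s)",
                                    i, conditionMessage(e)))
                    })
    rows[[i]] <- parse_obj(obj, i)
  }
  types <- vapply(rows, `[[`, character(1), "type")
  bind_typed <- function(keep) {
    sel <- rows[types == keep]
    if (!length(sel)) return(NULL)
    bind_rows(lapply(sel, function(r) {
      r <- r$row
      scalar <- r[!names(r) %in% c("tags", "extras")]
      scalar <- lapply(scalar, function(v) if (is.null(v)) NA else v)
      out <- as_tibble(scalar)
      if ("tags" %in% names(r)) out$tags <- r["tags"]$tags
      out$extras <- r$extras
      out
    }))
  }
  pats <- bind_typed("patient")
  if (!is.null(pats) && anyDuplicated(pats$patient_id)) {
    abort(paste("Duplicate patient header for:",
                paste(unique(pats$patient_id[duplicated(pats$patient_id)]),
                      collapse = ", ")))
  }
  sort_cohort(ehr_cohort(
    patients = pats,
    diagnoses = bind_typed("diagnosis"),
    medications = bind_typed("medication"),
    adverse_reactions = bind_typed("adr"),
    labs = bind_typed("lab"),
    imaging = bind_typed("imaging")
  ))
}

#' Export diagnosis events as CSV
#'
#' One row per diagnosis event, for spreadsheet inspection.
#'
#' @param cohort An [ehr_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_diagnoses_csv <- function(cohort, path) {
  cohort <- sort_cohort(validate_cohort(cohort))
  df <- select(cohort$diagnoses, -"extras")
  df$date <- iso_day(df$date)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
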