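#' The seven-hospital registry of the modelled healthcare system
#'
#' A small registry of hospital short codes and display names: a synthetic
#' regional network of one medical center and six affiliated community
#' hospitals sharing an electronic medical record. Short codes are what
#' event records and rendered evidence carry; the display names are
#' placeholders a deployment would replace.
#'
#' @return A tibble with columns `hospital_id` and `name`.
#' @export
#' @examples
#' hospital_registry()
hospital_registry <- function() {
  tibble(
    hospital_id = c("CCH", "ECH", "LCH", "NCH", "YCH", "YMH", "YSH"),
    name = c("Central Medical Center", "East District Hospital",
             "Lakeside Community Hospital", "North County Hospital",
             "West Community Hospital", "Midtown Hospital",
             "South District Hospital")
  )
}

event_kinds <- c("diagnoses", "medications", "adverse_reactions", "labs", "imaging")

empty_patients <- function() {
  tibble(patient_id = character(), birth_year = integer(), sex = character(),
         weight_kg = double(), sharing_consent = logical(), extras = list())
}

empty_events <- function(kind) {
  switch(kind,
    diagnoses = tibble(patient_id = character(), hospital_id = character(),
                       concept = character(), code = character(),
                       code_system = character(), date = as.Date(character()),
                       encounter_kind = character(), extras = list()),
    medications = tibble(patient_id = character(), hospital_id = character(),
                         drug_concept = character(),
                         start_date = as.Date(character()),
                         stop_date = as.Date(character()),
                         tags = list(), extras = list()),
    adverse_reactions = tibble(patient_id = character(), hospital_id = character(),
                               drug_concept = character(), reaction = character(),
                               date = as.Date(character()), extras = list()),
    labs = tibble(patient_id = character(), hospital_id = character(),
                  analyte = character(), value = double(), units = character(),
                  collected_at = as.POSIXct(character(), tz = "UTC"),
                  extras = list()),
    imaging = tibble(patient_id = character(), hospital_id = character(),
                     modality = character(), finding_summary = character(),
                     acquired_at = as.POSIXct(character(), tz = "UTC"),
                     extras = list()),
    abort(paste("Unknown event kind:", kind))
  )
}

fill_events <- function(df, kind) {
  template <- empty_events(kind)
  if (is.null(df)) return(template)
  df <- as_tibble(df)
  for (col in setdiff(names(template), names(df))) {
    df[[col]] <- template[[col]][rep(NA_integer_, nrow(df))]
    if (col %in% c("tags", "extras")) df[[col]] <- rep(list(NULL), nrow(df))
  }
  if ("date" %in% names(df)) df$date <- as_day(df$date)
  if ("start_date" %in% names(df)) df$start_date <- as_day(df$start_date)
  if ("stop_date" %in% names(df)) df$stop_date <- as_day(df$stop_date)
  if ("collected_at" %in% names(df)) df$collected_at <- as_clock(df$collected_at)
  if ("acquired_at" %in% names(df)) df$acquired_at <- as_clock(df$acquired_at)
  df[, names(template)]
}

#' Assemble a multi-hospital EHR cohort
#'
#' Bundles per-patient demographics and five kinds of time-stamped clinical
#' events (diagnoses, medication orders, adverse drug reactions, laboratory
#' results, imaging results) into a single validated container. Every event
#' table is keyed by `patient_id`; each patient carries a `sharing_consent`
#' flag that gates cross-hospital visibility of their events (see
#' [restrict_to_consented()]).
#'
#' @param patients Tibble with columns `patient_id`, and optionally
#'   `birth_year`, `sex`, `weight_kg`, `sharing_consent` (default `TRUE`).
#' @param diagnoses,medications,adverse_reactions,labs,imaging Event tibbles;
#'   any may be omitted. Dates are coerced from ISO-8601 strings.
#' @param hospitals Hospital registry tibble; defaults to [hospital_registry()].
#'
#' @return An object of class `ehr_cohort`: a named list of the six tibbles
#'   plus the hospital registry.
#' @export
ehr_cohort <- function(patients = NULL, diagnoses = NULL, medications = NULL,
                       adverse_reactions = NULL, labs = NULL, imaging = NULL,
                       hospitals = hospital_registry()) {
  if (is.null(patients)) {
    patients <- empty_patients()
  } else {
    patients <- as_tibble(patients)
    tmpl <- empty_patients()
    for (col in setdiff(names(tmpl), names(patients))) {
      patients[[col]] <- tmpl[[col]][rep(NA_integer_, nrow(patients))]
      if (col == "extras") patients[[col]] <- rep(list(NULL), nrow(patients))
    }
    patients$sharing_consent[is.na(patients$sharing_consent)] <- TRUE
    patients <- patients[, names(tmpl)]
  }
  events <- list(diagnoses = diagnoses, medications = medications,
                 adverse_reactions = adverse_reactions, labs = labs,
                 imaging = imaging)
  events <- purrr::imap(events, fill_events)
  out <- structure(c(list(patients = patients), events,
                     list(hospitals = as_tibble(hospitals))),
                   class = "ehr_cohort")
  validate_cohort(out)
}

validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  pats <- cohort$patients
  if (anyDuplicated(pats$patient_id)) {
    abort(paste("Duplicate patient ids:",
                paste(unique(pats$patient_id[duplicated(pats$patient_id)]),
                      collapse = ", ")))
  }
  if (anyDuplicated(cohort$hospitals$hospital_id)) {
    abort("Duplicate hospital_id in registry")
  }
  for (kind in event_kinds) {
    ev <- cohort[[kind]]
    orphan <- setdiff(ev$patient_id, pats$patient_id)
    if (length(orphan)) {
      abort(sprintf("%s events reference unknown patients: %s", kind,
                    paste(orphan, collapse = ", ")))
    }
    if (any(!nzchar(ev$patient_id))) abort(sprintf("%s: empty patient_id", kind))
  }
  if (any(!nzchar(compact_chr(cohort$diagnoses$concept)) |
          is.na(cohort$diagnoses$concept))) {
    abort("Diagnosis events require a non-empty concept")
  }
  bad <- with(cohort$medications,
              !is.na(stop_date) & !is.na(start_date) & stop_date < start_date)
  if (any(bad)) abort("Medication stop_date precedes start_date")
  if (any(!is.finite(cohort$labs$value))) abort("Lab values must be finite")
  if (any(is.na(cohort$labs$collected_at))) abort("Lab collected_at must be valid")
  if (any(is.na(cohort$imaging$acquired_at))) abort("Imaging acquired_at must be valid")
  if (any(is.na(cohort$adverse_reactions$date))) abort("ADR date must be valid")
  if (any(is.na(cohort$diagnoses$date))) abort("Diagnosis date must be valid")
  invisible(cohort)
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf("<ehr_cohort> %d patients (%d consented)\n",
              nrow(x$patients), sum(x$patients$sharing_consent)))
  for (kind in event_kinds) {
    cat(sprintf("  %-18s %d events\n", kind, nrow(x[[kind]])))
  }
  invisible(x)
}

#' Extract one patient's record from a cohort
#'
#' @param cohort An [ehr_cohort()].
#' @param patient_id Patient identifier present in the cohort.
#' @return An `ehr_cohort` containing that single patient.
#' @export
cohort_patient <- function(cohort, patient_id) {
  validate_cohort(cohort)
  if (!patient_id %in% cohort$patients$patient_id) {
    abort(paste("Unknown patient:", patient_id))
  }
  pid <- patient_id
  out <- cohort
  out$patients <- filter(cohort$patients, .data$patient_id == pid)
  for (kind in event_kinds) {
    out$kind <- NULL
    out[[kind]] <- filter(cohort[[kind]], .data$patient_id == pid)
  }
  out
}

#' Apply consent gating to a record
#'
#' In the modelled shared-EMR system a treating physician may only see a
#' patient's records from other hospitals when the patient has signed a
#' health-information sharing consent. This operation enforces that rule:
#' for patients with `sharing_consent = TRUE` the record passes through
#' unchanged; otherwise only events recorded at the treating (home) hospital
#' are retained. It is idempotent and never adds events.
#'
#' @param cohort An [ehr_cohort()] (one patient or many).
#' @param home_hospital_id Hospital code of the treating site; must be in the
#'   cohort's hospital registry.
#' @return The consent-filtered `ehr_cohort`.
#' @export
restrict_to_consented <- function(cohort, home_hospital_id) {
  validate_cohort(cohort)
  if (!home_hospital_id %in% cohort$hospitals$hospital_id) {
    abort(paste("Unknown hospital:", home_hospital_id))
  }
  gated <- cohort$patients$patient_id[!cohort$patients$sharing_consent]
  if (!length(gated)) return(cohort)
  out <- cohort
  for (kind in event_kinds) {
    ev <- cohort[[kind]]
    keep <- !(ev$patient_id %in% gated) | ev$hospital_id == home_hospital_id
    out[[kind]] <- ev[keep, ]
  }
  out
}

# Canonical ordering so that parse order never matters for equality.
sort_cohort <- function(cohort) {
  out <- cohort
  out$patients <- arrange(cohort$patients, .data$patient_id)
  key <- list(diagnoses = c("patient_id", "date", "hospital_id", "concept"),
              medications = c("patient_id", "start_date", "hospital_id", "drug_concept"),
              adverse_reactions = c("patient_id", "date", "hospital_id", "drug_concept"),
              labs = c("patient_id", "collected_at", "hospital_id", "analyte"),
              imaging = c("patient_id", "acquired_at", "hospital_id", "modality"))
  for (kind in event_kinds) {
    out[[kind]] <- arrange(cohort[[kind]],
                           !!!rlang::syms(key[[kind]]))
  }
  out
}
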