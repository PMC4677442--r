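# Synthetic EHR generation: the four mock test cases with multi-hospital
# histories, randomized cohorts with configurable prevalences and consent
# rates, and simulated physician screening responses for crossover-study
# replay. Everything is reproducible under a fixed seed and needs no
# external data.

mock_case_events <- function(index_day) {
  mid_year <- function(y) as.Date(sprintf("%d-07-01", y))
  recent <- index_day - 60  # recent-stroke events: 60 days before index
  diag <- function(pid, concept, hosp, year, date = mid_year(year)) {
    tibble(patient_id = pid, hospital_id = hosp, concept = concept,
           code = NA_character_, code_system = "LOCAL", date = date,
           encounter_kind = "OUTPATIENT")
  }
  diagnoses <- bind_rows(
    # case 1: dementia, diabetes, remote stroke, and a stroke 60 days back
    diag("case-1", "Dementia", "YCH", 2007),
    diag("case-1", "Diabetes", "YCH", 2009),
    diag("case-1", "Ischemic stroke", "CCH", 2012),
    diag("case-1", "Ischemic stroke", "YCH", 2014, recent),
    # case 2: broad comorbidity at NCH plus remote hemodialysis at CCH
    diag("case-2", "Atrial fibrillation", "NCH", 2010),
    diag("case-2", "Dementia", "NCH", 2010),
    diag("case-2", "Diabetes", "NCH", 2010),
    diag("case-2", "Heart failure", "NCH", 2008),
    diag("case-2", "Hemodialysis", "CCH", 2000),
    diag("case-2", "Ischemic stroke", "NCH", 2009),
    diag("case-2", "Liver cirrhosis", "NCH", 2009),
    # case 3: prior intracranial hemorrhage, no diabetes
    diag("case-3", "Atrial fibrillation", "CCH", 2012),
    diag("case-3", "Dementia", "ECH", 2012),
    diag("case-3", "Heart failure", "ECH", 2011),
    diag("case-3", "Intracranial hemorrhage", "CCH", 2010),
    diag("case-3", "Ischemic stroke", "CCH", 2012),
    # case 4: anticoagulated, diabetic, stroke 60 days back
    diag("case-4", "Atrial fibrillation", "YSH", 2005),
    diag("case-4", "Dementia", "CCH", 2014),
    diag("case-4", "Diabetes", "CCH", 2011),
    diag("case-4", "Ischemic stroke", "CCH", 2011),
    diag("case-4", "Ischemic stroke", "CCH", 2014, recent)
  )
  medications <- tibble(
    patient_id = c("case-4", "case-4"),
    hospital_id = c("CCH", "CCH"),
    drug_concept = c("Rivaroxaban", "Warfarin"),
    start_date = as.Date(c("2014-02-01", "2014-05-01")),
    stop_date = as.Date(c(NA, NA)),
    tags = list("anticoagulant", "anticoagulant")
  )
  list(diagnoses = diagnoses, medications = medications)
}

#' Generate the four mock test cases
#'
#' Builds four consented patient records whose multi-hospital medical
#' histories reproduce, event for event, the mock cases used to exercise
#' the screening engine: each case carries dementia; cases 1 and 4 carry a
#' stroke 60 days before the index (inside the 90-day item-3 window) on top
#' of a remote stroke; case 2 carries liver cirrhosis, hemodialysis, and
#' stroke-plus-diabetes; case 3 a prior intracranial hemorrhage; case 4
#' open-ended warfarin and rivaroxaban orders. Screened with
#' [default_catalog()] these yield triggered sets \{3, 17\}, \{13, 15, 17\},
#' \{1\}, and \{3, 16, 17\} — nine findings over six distinct items.
#'
#' Histories are dated July 1 of their recorded year (source records carry
#' years only); recent strokes at index − 60 days; anticoagulant orders
#' start in 2014 and remain open.
#'
#' @param index Reference index (code-stroke) timestamp;
#'   default `"2014-09-01"`.
#' @return An [ehr_cohort()] of the four cases, with the index timestamp
#'   attached as attribute `"index"`.
#' @export
make_mock_cases <- function(index = "2014-09-01") {
  index <- as_clock(index)
  ev <- mock_case_events(as_day(index))
  patients <- tibble(
    patient_id = paste0("case-", 1:4),
    birth_year = c(1941L, 1936L, 1944L, 1939L),
    sex = c("F", "M", "F", "M"),
    weight_kg = c(58, 70, 62, 75),
    sharing_consent = TRUE
  )
  out <- ehr_cohort(patients = patients, diagnoses = ev$diagnoses,
                    medications = ev$medications)
  attr(out, "index") <- index
  out
}

#' Specify a randomized multi-hospital cohort
#'
#' @param n_patients Number of patients (>= 0).
#' @param prevalence Named numeric vector in `[0, 1]`: probability that a
#'   patient carries each concept. Names matching known anticoagulant drugs
#'   (`warfarin`, `dabigatran`, `rivaroxaban`, `apixaban`) become medication
#'   orders tagged `"anticoagulant"`; all others become diagnoses.
#' @param hospitals Character vector of hospital codes events are drawn from.
#' @param consent_rate Probability a patient has signed sharing consent.
#' @param date_range Length-2 Date (or ISO string) vector events are drawn
#'   uniformly from.
#' @param lab_rate Expected number of lab results per patient (Poisson).
#' @param seed Integer seed; same seed, same cohort.
#' @return A `cohort_spec` list, for [generate_cohort()].
#' @export
cohort_spec <- function(n_patients,
                        prevalence = c("ischemic stroke" = 0.15,
                                       "diabetes" = 0.25,
                                       "atrial fibrillation" = 0.12,
                                       "dementia" = 0.10,
                                       "heart failure" = 0.10,
                                       "hemodialysis" = 0.03,
                                       "liver cirrhosis" = 0.04,
                                       "intracranial hemorrhage" = 0.03,
                                       "warfarin" = 0.06,
                                       "rivaroxaban" = 0.04),
                        hospitals = hospital_registry()$hospital_id,
                        consent_rate = 0.9,
                        date_range = as.Date(c("2000-01-01", "2014-08-31")),
                        lab_rate = 1,
                        seed = 1L) {
  if (n_patients < 0) abort("n_patients must be >= 0")
  if (any(prevalence < 0 | prevalence > 1)) {
    abort("prevalence values must be in [0, 1]")
  }
  if (consent_rate < 0 || consent_rate > 1) {
    abort("consent_rate must be in [0, 1]")
  }
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 hospitals = hospitals, consent_rate = consent_rate,
                 date_range = as_day(date_range), lab_rate = lab_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

anticoagulant_drugs <- c("warfarin", "dabigatran", "rivaroxaban", "apixaban")

#' Generate a randomized multi-hospital cohort
#'
#' Patients independently carry each concept with its prevalence; each
#' carried concept becomes one event at a hospital drawn from the spec's
#' hospital list, dated uniformly in the date range. Anticoagulant concepts
#' become medication orders (30% open-ended). Reproducible under the spec's
#' seed.
#'
#' @param spec A [cohort_spec()].
#' @return An [ehr_cohort()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  if (n == 0) return(ehr_cohort())
  set.seed(spec$seed)
  pid <- sprintf("pt-%05d", seq_len(n))
  patients <- tibble(
    patient_id = pid,
    birth_year = as.integer(sample(1925:1975, n, replace = TRUE)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    weight_kg = round(rnorm(n, 68, 12), 1),
    sharing_consent = runif(n) < spec$consent_rate
  )
  days <- as.numeric(spec$date_range[2] - spec$date_range[1])
  rand_date <- function(k) spec$date_range[1] + floor(runif(k, 0, days + 1))
  rand_hosp <- function(k) sample(spec$hospitals, k, replace = TRUE)
  diag_rows <- list(); med_rows <- list()
  for (concept in names(spec$prevalence)) {
    carriers <- pid[runif(n) < spec$prevalence[[concept]]]
    k <- length(carriers)
    if (!k) next
    if (tolower(concept) %in% anticoagulant_drugs) {
      start <- rand_date(k)
      open <- runif(k) < 0.3
      med_rows[[concept]] <- tibble(
        patient_id = carriers, hospital_id = rand_hosp(k),
        drug_concept = concept, start_date = start,
        stop_date = as.Date(ifelse(open, NA, start + floor(runif(k, 30, 365))),
                            origin = "1970-01-01"),
        tags = rep(list("anticoagulant"), k))
    } else {
      diag_rows[[concept]] <- tibble(
        patient_id = carriers, hospital_id = rand_hosp(k), concept = concept,
        code = NA_character_, code_system = "LOCAL", date = rand_date(k),
        encounter_kind = sample(c("ADMISSION", "OUTPATIENT"), k, replace = TRUE))
    }
  }
  n_labs <- stats::rpois(n, spec$lab_rate)
  labs <- if (sum(n_labs)) {
    owner <- rep(pid, n_labs)
    k <- length(owner)
    tibble(patient_id = owner, hospital_id = rand_hosp(k),
           analyte = sample(c("glucose", "creatinine", "platelets", "inr"),
                            k, replace = TRUE),
           value = round(runif(k, 0.8, 300), 2), units = "lab-units",
           collected_at = as_clock(rand_date(k)) + floor(runif(k, 0, 86400)))
  }
  ehr_cohort(patients = patients, diagnoses = bind_rows(diag_rows),
             medications = bind_rows(med_rows), labs = labs)
}

#' Miss-probability model for simulated physician screening
#'
#' Each contraindication-item opportunity is missed independently with the
#' arm's probability; per-set review times are log-normal with the given
#' mean and SD (minutes) on the natural scale.
#'
#' @param p_control,p_intervention Per-opportunity miss probabilities.
#' @param time_mean,time_sd Length-2 numeric vectors `(control,
#'   intervention)`: review-time mean and SD in minutes. Defaults emulate
#'   unassisted review taking roughly twice as long as assisted review.
#' @return A `miss_model` list.
#' @export
miss_model <- function(p_control, p_intervention,
                       time_mean = c(14.6, 7.3), time_sd = c(7.4, 5.2)) {
  for (p in c(p_control, p_intervention)) {
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) {
      abort("Miss probabilities must be in [0, 1]")
    }
  }
  structure(list(p = c(control = p_control, intervention = p_intervention),
                 time_mean = setNames(time_mean, c("control", "intervention")),
                 time_sd = setNames(time_sd, c("control", "intervention"))),
            class = "miss_model")
}

rlnorm_moments <- function(k, m, s) {
  sigma2 <- log(1 + (s / m)^2)
  rlnorm(k, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Simulate physician screening responses under a crossover assignment
#'
#' For every (physician, arm, case) cell of the assignment, each of the
#' case's true contraindication items is independently missed with the
#' arm's probability, and one review time per (physician, arm) set is drawn
#' from the arm's log-normal distribution.
#'
#' @param assignment A [counterbalanced_assignment()].
#' @param case_truth Named list mapping case id to the integer vector of
#'   item ids truly present; defaults to the mock cases' triggered sets via
#'   [mock_case_truth()].
#' @param model A [miss_model()].
#' @param seed Integer seed.
#' @return A tibble with columns `physician_id`, `arm`, `case_id`,
#'   `item_id`, `missed` (0/1), `time_min` (the set-level time, repeated
#'   across the set's rows).
#' @export
simulate_responses <- function(assignment, case_truth = mock_case_truth(),
                               model, seed = 1L) {
  stopifnot(inherits(assignment, "study_assignment"),
            inherits(model, "miss_model"))
  set.seed(as.integer(seed))
  grid <- assignment$cells
  missing_truth <- setdiff(unique(grid$case_id), names(case_truth))
  if (length(missing_truth)) {
    abort(paste("case_truth missing cases:",
                paste(missing_truth, collapse = ", ")))
  }
  sets <- distinct(grid[, c("physician_id", "arm")])
  times <- mutate(sets,
                  time_min = round(rlnorm_moments(nrow(sets),
                                                  model$time_mean[.data$arm],
                                                  model$time_sd[.data$arm]), 2))
  truth <- case_truth[grid$case_id]
  k <- lengths(truth)
  out <- tibble(physician_id = rep(grid$physician_id, k),
                arm = rep(grid$arm, k),
                case_id = rep(grid$case_id, k),
                item_id = as.integer(unlist(truth, use.names = FALSE)))
  out$missed <- as.integer(runif(nrow(out)) < model$p[out$arm])
  left_join(out, times, by = c("physician_id", "arm"))
}

#' True contraindication items per mock case
#'
#' @return Named list: case id -> integer vector of catalog item ids truly
#'   present (the sets the screening engine reproduces from the records).
#' @export
mock_case_truth <- function() {
  list("case-1" = c(3L, 17L), "case-2" = c(13L, 15L, 17L),
       "case-3" = 1L, "case-4" = c(3L, 16L, 17L))
}
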