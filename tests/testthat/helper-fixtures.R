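# Shared generators and independent oracles for the test suite.

# Vocabulary a random record can draw events from (superset of what the
# default catalog can match, plus noise concepts it cannot).
random_concepts <- c(
  "ischemic stroke", "diabetes", "intracranial hemorrhage", "liver cirrhosis",
  "hemodialysis", "atrial fibrillation", "dementia", "heart failure",
  "myocardial infarction", "appendicitis", "migraine", "gout"
)
random_drugs <- c("warfarin", "rivaroxaban", "metformin", "aspirin")

# Random single-patient record with diagnoses and medications scattered over
# hospitals and the decade before the index.
random_record <- function(pid = "rnd-1", n_diag = 6, n_med = 2,
                          index_day = as.Date("2014-09-01"),
                          consent = TRUE) {
  diag <- if (n_diag > 0) {
    tibble::tibble(
      patient_id = pid,
      hospital_id = sample(hospital_registry()$hospital_id, n_diag,
                           replace = TRUE),
      concept = sample(random_concepts, n_diag, replace = TRUE),
      code = NA_character_, code_system = "LOCAL",
      date = index_day - sample(0:3650, n_diag, replace = TRUE),
      encounter_kind = "OUTPATIENT"
    )
  }
  med <- if (n_med > 0) {
    start <- index_day - sample(0:720, n_med, replace = TRUE)
    tibble::tibble(
      patient_id = pid,
      hospital_id = sample(hospital_registry()$hospital_id, n_med,
                           replace = TRUE),
      drug_concept = sample(random_drugs, n_med, replace = TRUE),
      start_date = start,
      stop_date = dplyr::if_else(stats::runif(n_med) < 0.5,
                                 as.Date(NA), start + 60),
      tags = rep(list(character()), n_med)
    )
  }
  ehr_cohort(patients = tibble::tibble(patient_id = pid,
                                       sharing_consent = consent),
             diagnoses = diag, medications = med)
}

# Random negation-free predicate of depth <= 2 over the test vocabulary.
random_predicate <- function() {
  leaf <- function() {
    if (stats::runif(1) < 0.7) {
      exists_clause("diagnosis", sample(random_concepts, sample(1:3, 1)),
                    lookback_days = sample(list("unlimited", 90, 365, 1800), 1)[[1]])
    } else {
      exists_clause("medication", sample(random_drugs, sample(1:2, 1)),
                    lookback_days = sample(list("unlimited", 30, 180), 1)[[1]])
    }
  }
  n <- sample(1:3, 1)
  if (n == 1) return(leaf())
  comb <- if (stats::runif(1) < 0.5) pred_all else pred_any
  do.call(comb, replicate(n, leaf(), simplify = FALSE))
}

predicate_satisfied <- function(pred, record, index) {
  rule <- lysisgate:::ci_rule(1, "test", predicate = pred)
  evaluate_rule(rule, record, index)$status == "TRIGGERED"
}

triggered_items <- function(report) {
  sort(report$findings$item_id[report$findings$status == "TRIGGERED"])
}

# Independent Mann-Whitney oracle: for every C(n1+n2, n1) split of the pooled
# values, compute U by direct pair counting (wins + half-ties), then the
# two-sided tail probability of deviations from the null mean n1*n2/2.
mw_enumeration_oracle <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(x, y)
  mu <- n1 * n2 / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2, function(ix) u_of(pool[ix], pool[-ix]))
  list(u = u_obs,
       p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# Closed-form pooled two-sample t.
t_pooled_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Closed-form 2x2 chi-square, optional Yates correction.
chisq_2x2_oracle <- function(m, correct = FALSE) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c + d
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(0, dev - n / 2)
  n * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
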