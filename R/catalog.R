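# The contraindication catalog: 26 items for intravenous stroke
# thrombolysis, of which 17 are decidable from pre-stroke health records
# ("extractable") and 9 require on-site measurement. Extractable items carry
# a monotone (negation-free) predicate over event-existence clauses with
# optional lookback windows; advisory items (atrial fibrillation, dementia,
# heart failure) flag history that warrants attention without excluding
# treatment on its own.

rule_sources <- c("diagnosis", "medication", "adr")

#' Build an event-existence clause
#'
#' The leaf of the rule language: "an event of this kind, matching this
#' concept set, exists within the lookback window ending at the index time".
#'
#' @param source One of `"diagnosis"`, `"medication"`, `"adr"`.
#' @param labels Character vector of canonical concept labels (matched
#'   case-insensitively against diagnosis concepts, drug names, or — for
#'   medications — route/class tags such as `"anticoagulant"`).
#' @param codes Character vector of `"SYSTEM:CODE"` pairs (e.g.
#'   `"ICD9:430"`); matched against coded diagnoses. Optional.
#' @param lookback_days Positive number of days, or `"unlimited"` for
#'   any-time history. For medication clauses the window is matched against
#'   the order's active interval (see Details in [evaluate_rule()]).
#' @return A predicate node (named list) usable in [pred_all()]/[pred_any()].
#' @export
exists_clause <- function(source, labels, codes = character(),
                          lookback_days = "unlimited") {
  if (!source %in% rule_sources) {
    abort(paste("Clause source must be one of:",
                paste(rule_sources, collapse = ", ")))
  }
  if (!length(labels) && !length(codes)) {
    abort("Clause needs a non-empty concept set (labels and/or codes)")
  }
  if (!identical(lookback_days, "unlimited")) {
    if (!is.numeric(lookback_days) || length(lookback_days) != 1 ||
        is.na(lookback_days) || lookback_days < 1) {
      abort("lookback_days must be >= 1 or \"unlimited\"")
    }
    lookback_days <- as.numeric(lookback_days)
  }
  list(exists = list(source = source,
                     concepts = list(labels = tolower(as.character(labels)),
                                     codes = toupper(as.character(codes))),
                     lookback_days = lookback_days))
}

#' Conjunction / disjunction of predicate nodes
#'
#' The rule language permits only AND/OR over existence clauses — no
#' negation — which makes every rule monotone: adding events to a record can
#' only switch a rule from unsatisfied to satisfied, never back.
#'
#' @param ... Predicate nodes ([exists_clause()], [pred_all()], [pred_any()]).
#' @return A predicate node.
#' @export
pred_all <- function(...) {
  nodes <- list(...)
  if (!length(nodes)) abort("pred_all needs at least one child")
  list(all = nodes)
}

#' @rdname pred_all
#' @export
pred_any <- function(...) {
  nodes <- list(...)
  if (!length(nodes)) abort("pred_any needs at least one child")
  list(any = nodes)
}

validate_predicate <- function(node, where = "predicate") {
  if (!is.list(node) || length(node) != 1) {
    abort(paste(where, "must be a single {all|any|exists} node"))
  }
  key <- names(node)
  if (identical(key, "not")) {
    abort(paste(where, "contains a negation node; the rule language is negation-free"))
  }
  if (key %in% c("all", "any")) {
    if (!length(node[[1]])) abort(paste(where, "has an empty", key, "node"))
    for (i in seq_along(node[[1]])) {
      validate_predicate(node[[1]][[i]], paste0(where, "/", key, "[", i, "]"))
    }
  } else if (identical(key, "exists")) {
    cl <- node$exists
    if (!cl$source %in% rule_sources) abort(paste(where, ": bad clause source"))
    if (!length(cl$concepts$labels) && !length(cl$concepts$codes)) {
      abort(paste(where, ": empty concept set"))
    }
    ok <- identical(cl$lookback_days, "unlimited") ||
      (is.numeric(cl$lookback_days) && cl$lookback_days >= 1)
    if (!ok) abort(paste(where, ": bad lookback_days"))
  } else {
    abort(paste(where, "has unknown node type:", key))
  }
  invisible(node)
}

ci_rule <- function(item_id, label, severity = "exclusion", extractable = TRUE,
                    predicate = NULL, on_site_note = NULL, provisional = FALSE) {
  if (extractable) {
    if (is.null(predicate)) {
      abort(sprintf("Item %s is extractable but has no predicate", item_id))
    }
    validate_predicate(predicate, paste0("item ", item_id))
  } else if (!is.null(predicate)) {
    abort(sprintf("Item %s is not extractable yet carries a predicate", item_id))
  }
  list(item_id = as.integer(item_id), label = label, severity = severity,
       extractable = isTRUE(extractable), predicate = predicate,
       on_site_note = on_site_note, provisional = isTRUE(provisional))
}

advisory_rule <- function(label, predicate) {
  validate_predicate(predicate, paste0("advisory '", label, "'"))
  list(label = label, severity = "advisory", predicate = predicate)
}

new_catalog <- function(items, advisories, complete = TRUE) {
  ids <- vapply(items, `[[`, integer(1), "item_id")
  if (anyDuplicated(ids)) {
    abort(paste("Duplicate item_id:", paste(ids[duplicated(ids)], collapse = ", ")))
  }
  if (complete && length(items) != 26L) {
    abort(sprintf("Catalog must contain exactly 26 items, got %d", length(items)))
  }
  adv_labels <- vapply(advisories, `[[`, character(1), "label")
  if (anyDuplicated(adv_labels)) abort("Duplicate advisory labels")
  structure(list(items = items[order(ids)], advisories = advisories),
            class = "ci_catalog")
}

#' @export
print.ci_catalog <- function(x, ...) {
  s <- catalog_stats(x)
  cat(sprintf("<ci_catalog> %d contraindication items (%d extractable, %d%%); %d advisories\n",
              s$n_items, s$n_extractable, s$pct_extractable,
              length(x$advisories)))
  invisible(x)
}

stroke_labels <- c("ischemic stroke", "stroke", "cerebral infarction")

#' The default contraindication catalog
#'
#' Returns the shipped catalog of 26 thrombolysis contraindication items,
#' 17 of them extractable from pre-stroke records, plus three advisory
#' history items. The clinically anchored extractable items are:
#'
#' * item 1 — prior intracranial hemorrhage, any time;
#' * item 3 — ischemic stroke within the last 90 days;
#' * item 13 — significant liver disease (matches liver cirrhosis);
#' * item 15 — severe renal disease (matches hemodialysis);
#' * item 16 — current oral anticoagulant use (warfarin, dabigatran,
#'   rivaroxaban, apixaban, or any order tagged `"anticoagulant"`; an order
#'   counts when its active interval overlaps the 30 days before index);
#' * item 17 — known history of both stroke and diabetes (conjunction,
#'   unlimited lookback on both legs).
#'
#' The remaining items are populated from standard tPA exclusion criteria
#' and flagged `provisional = TRUE`: their numbering is a configuration
#' convention, not an authoritative mapping, and sites are expected to
#' override them via [load_catalog()]. Nine items (NIHSS > 25, platelet
#' count, glucose, blood pressure, onset time, and similar) require on-site
#' measurement and are marked not extractable with an `on_site_note`.
#'
#' @return A `ci_catalog` object: `$items` (26 rules) and `$advisories`
#'   (atrial fibrillation, dementia, heart failure).
#' @export
#' @examples
#' cat26 <- default_catalog()
#' catalog_stats(cat26)
default_catalog <- function() {
  diag_any <- function(labels, lookback = "unlimited", codes = character()) {
    exists_clause("diagnosis", labels, codes, lookback)
  }
  items <- list(
    ci_rule(1, "Prior intracranial hemorrhage (any time)",
            predicate = diag_any(c("intracranial hemorrhage",
                                   "intracerebral hemorrhage",
                                   "subarachnoid hemorrhage"))),
    ci_rule(2, "Serious head trauma within 3 months",
            predicate = diag_any(c("head trauma", "traumatic brain injury",
                                   "skull fracture"), 90),
            provisional = TRUE),
    ci_rule(3, "Ischemic stroke within 3 months",
            predicate = diag_any(stroke_labels, 90)),
    ci_rule(4, "Major surgery within 14 days",
            predicate = diag_any(c("major surgery", "surgical procedure"), 14),
            provisional = TRUE),
    ci_rule(5, "Gastrointestinal or urinary tract hemorrhage within 21 days",
            predicate = diag_any(c("gastrointestinal hemorrhage", "gi bleeding",
                                   "urinary tract hemorrhage"), 21),
            provisional = TRUE),
    ci_rule(6, "Arterial puncture at a noncompressible site within 7 days",
            predicate = diag_any(c("arterial puncture"), 7), provisional = TRUE),
    ci_rule(7, "Lumbar puncture within 7 days",
            predicate = diag_any(c("lumbar puncture"), 7), provisional = TRUE),
    ci_rule(8, "Acute myocardial infarction within 3 months",
            predicate = diag_any(c("myocardial infarction"), 90),
            provisional = TRUE),
    ci_rule(9, "Acute pericarditis",
            predicate = diag_any(c("pericarditis"), 90), provisional = TRUE),
    ci_rule(10, "Known intracranial neoplasm",
            predicate = diag_any(c("intracranial neoplasm", "brain tumor")),
            provisional = TRUE),
    ci_rule(11, "Known cerebral arteriovenous malformation",
            predicate = diag_any(c("arteriovenous malformation")),
            provisional = TRUE),
    ci_rule(12, "Known intracranial aneurysm",
            predicate = diag_any(c("intracranial aneurysm")), provisional = TRUE),
    ci_rule(13, "Significant liver disease",
            predicate = diag_any(c("liver cirrhosis", "cirrhosis",
                                   "hepatic failure", "severe liver disease"))),
    ci_rule(14, "Known bleeding diathesis or hemorrhagic disorder",
            predicate = diag_any(c("bleeding diathesis", "hemophilia",
                                   "hemorrhagic disorder")),
            provisional = TRUE),
    ci_rule(15, "Severe renal disease (hemodialysis)",
            predicate = diag_any(c("hemodialysis", "end-stage renal disease"))),
    ci_rule(16, "Current oral anticoagulant use",
            predicate = exists_clause("medication",
                                      c("warfarin", "dabigatran", "rivaroxaban",
                                        "apixaban", "anticoagulant"),
                                      lookback_days = 30)),
    ci_rule(17, "Known history of both stroke and diabetes",
            predicate = pred_all(
              diag_any(stroke_labels),
              diag_any(c("diabetes", "diabetes mellitus", "type 2 diabetes")))),
    ci_rule(18, "Severe stroke (NIHSS > 25)", extractable = FALSE,
            on_site_note = "NIHSS > 25 measured at presentation",
            provisional = TRUE),
    ci_rule(19, "Platelet count <= 100,000/mm3", extractable = FALSE,
            on_site_note = "platelet count from current labs", provisional = TRUE),
    ci_rule(20, "Blood glucose < 50 or > 400 mg/dL", extractable = FALSE,
            on_site_note = "point-of-care glucose", provisional = TRUE),
    ci_rule(21, "Blood pressure > 185/110 mmHg refractory to treatment",
            extractable = FALSE, on_site_note = "blood pressure at presentation",
            provisional = TRUE),
    ci_rule(22, "Onset beyond the treatment time window", extractable = FALSE,
            on_site_note = "onset-to-needle time", provisional = TRUE),
    ci_rule(23, "Rapidly improving or minor symptoms", extractable = FALSE,
            on_site_note = "serial neurological examination", provisional = TRUE),
    ci_rule(24, "CT evidence of hemorrhage or extensive infarction",
            extractable = FALSE, on_site_note = "current brain CT read",
            provisional = TRUE),
    ci_rule(25, "Seizure at stroke onset with postictal impairment",
            extractable = FALSE, on_site_note = "witnessed onset account",
            provisional = TRUE),
    ci_rule(26, "Pregnancy", extractable = FALSE,
            on_site_note = "pregnancy test / history at presentation",
            provisional = TRUE)
  )
  advisories <- list(
    advisory_rule("atrial fibrillation",
                  exists_clause("diagnosis", "atrial fibrillation")),
    advisory_rule("dementia", exists_clause("diagnosis", "dementia")),
    advisory_rule("heart failure",
                  exists_clause("diagnosis",
                                c("heart failure", "congestive heart failure")))
  )
  new_catalog(items, advisories)
}

#' Summary counts for a catalog
#'
#' @param catalog A `ci_catalog`.
#' @return A one-row tibble: `n_items`, `n_extractable`, `pct_extractable`
#'   (percentage rounded to the nearest integer).
#' @export
catalog_stats <- function(catalog) {
  stopifnot(inherits(catalog, "ci_catalog"))
  n <- length(catalog$items)
  ne <- sum(vapply(catalog$items, `[[`, logical(1), "extractable"))
  tibble(n_items = n, n_extractable = ne,
         pct_extractable = as.integer(round(100 * ne / n)))
}

#' Tidy view of a catalog
#'
#' @param x A `ci_catalog`.
#' @param ... Unused.
#' @return A tibble with one row per item: `item_id`, `label`, `severity`,
#'   `extractable`, `provisional`, `on_site_note`.
#' @method tidy ci_catalog
#' @export
tidy.ci_catalog <- function(x, ...) {
  bind_rows(lapply(x$items, function(r) {
    tibble(item_id = r$item_id, label = r$label, severity = r$severity,
           extractable = r$extractable, provisional = r$provisional,
           on_site_note = r$on_site_note %||% NA_character_)
  }))
}

predicate_to_config <- function(node) {
  key <- names(node)
  if (key %in% c("all", "any")) {
    setNames(list(lapply(node[[1]], predicate_to_config)), key)
  } else {
    cl <- node$exists
    list(exists = list(source = cl$source,
                       concepts = list(labels = as.list(cl$concepts$labels),
                                       codes = as.list(cl$concepts$codes)),
                       lookback_days = cl$lookback_days))
  }
}

predicate_from_config <- function(node, where) {
  if (!is.list(node) || length(node) != 1) {
    abort(paste(where, ": predicate node must have exactly one key"))
  }
  key <- names(node)
  if (identical(key, "not")) {
    abort(paste(where, ": negation nodes are not allowed"))
  }
  if (key %in% c("all", "any")) {
    children <- lapply(node[[1]], predicate_from_config, where = where)
    if (key == "all") do.call(pred_all, children) else do.call(pred_any, children)
  } else if (identical(key, "exists")) {
    cl <- node$exists
    exists_clause(cl$source,
                  labels = unlist(cl$concepts$labels) %||% character(),
                  codes = unlist(cl$concepts$codes) %||% character(),
                  lookback_days = if (identical(cl$lookback_days, "unlimited"))
                    "unlimited" else as.numeric(cl$lookback_days))
  } else {
    abort(paste(where, ": unknown predicate node", key))
  }
}

#' Serialize a catalog to YAML or JSON
#'
#' @param catalog A `ci_catalog`.
#' @param path Output path; `.json` writes JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "ci_catalog"))
  doc <- list(
    items = lapply(catalog$items, function(r) {
      out <- list(id = r$item_id, label = r$label, severity = r$severity,
                  extractable = r$extractable, provisional = r$provisional)
      if (!is.null(r$on_site_note)) out$on_site_note <- r$on_site_note
      if (!is.null(r$predicate)) out$predicate <- predicate_to_config(r$predicate)
      out
    }),
    advisories = lapply(catalog$advisories, function(a) {
      list(label = a$label, predicate = predicate_to_config(a$predicate))
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' Load a catalog from a YAML or JSON config
#'
#' Validates the config against the catalog contract (26 unique items,
#' extractable items carry a negation-free predicate, non-extractable items
#' an on-site note) and rejects violations with item-level messages.
#'
#' @param path Path to a catalog config file.
#' @return A `ci_catalog` equal (round-trip) to what [write_catalog()] wrote.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) abort(paste("No such file:", path))
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$items)) abort("Catalog config lacks a top-level 'items' key")
  items <- lapply(doc$items, function(it) {
    where <- paste0("item ", it$id %||% "<missing id>")
    if (is.null(it$id)) abort("Catalog item without an id")
    pred <- if (!is.null(it$predicate)) {
      predicate_from_config(it$predicate, where)
    }
    ci_rule(it$id, it$label %||% abort(paste(where, ": missing label")),
            severity = it$severity %||% "exclusion",
            extractable = isTRUE(it$extractable),
            predicate = pred, on_site_note = it$on_site_note,
            provisional = isTRUE(it$provisional))
  })
  advisories <- lapply(doc$advisories %||% list(), function(a) {
    advisory_rule(a$label, predicate_from_config(
      a$predicate, paste0("advisory '", a$label, "'")))
  })
  new_catalog(items, advisories)
}
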