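---
title: "Screening shared health records for thrombolysis contraindications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening shared health records for thrombolysis contraindications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysisgate)
library(dplyr)
```

## The clinical problem

Intravenous thrombolysis with tissue-type plasminogen activator (tPA) is the
standard medical treatment for acute ischemic stroke, but it is both
time-critical and restricted by a long checklist of contraindications —
mostly items of prior medical history (old intracranial bleeding, recent
stroke or surgery, anticoagulant use, organ failure) that raise the risk of
hemorrhage. When the patient is aphasic or confused and no family member is
available, that history can only come from records. In a regional healthcare
system where patients move freely between hospitals, the relevant events may
be scattered across several sites' electronic medical records (EMRs), shared
only for patients who have signed a cross-hospital consent.

`lysisgate` models this setting as a testable rule engine: multi-hospital
event records in, an evidence-backed contraindication screen out. It also
ships the machinery to evaluate such a tool the way a counterbalanced
two-period crossover study would — physicians screening mock cases with and
without assistance, compared on missed contraindications.

## The data model

A cohort is six tibbles: patients (with a `sharing_consent` flag) plus
diagnoses, medication orders, adverse drug reactions, labs, and imaging,
each keyed by `patient_id` and `hospital_id`. Records serialize to JSON
Lines with ISO-8601 dates; serialization is deterministic (sorted patients,
canonical event order, sorted JSON keys) so reports and files diff cleanly,
and reading is order-independent.

Consent gating is the one access-control rule of the modelled system: a
treating physician at hospital H sees a non-consented patient's events only
if they were recorded at H. `restrict_to_consented()` implements exactly
that filter; it is idempotent and can only remove events, which gives the
screening engine its consent-monotonicity property (gating can only shrink
the set of triggered findings).

All timestamps are naive local clock times: the modelled system is a
single-region hospital network, so time-zone arithmetic would add failure
modes without adding correctness.

## The rule language and the default catalog

A contraindication item is either *extractable* — decidable from pre-stroke
records — or requires on-site measurement (NIHSS, platelets, glucose, blood
pressure, onset time...). Extractable items carry a predicate in a
deliberately small language:

* a leaf `exists(source, concept_set, lookback_days)` is true when at least
  one matching event lies in the closed window
  `[index − lookback, index]` (calendar days; `unlimited` for any-time
  history);
* internal nodes are `all(...)` / `any(...)`;
* there is **no negation**.

Negation-freeness makes every rule monotone: adding events to a record can
flip a rule from CLEAR to TRIGGERED but never back. That is the property a
safety screen wants — more data can only surface more warnings — and it is
what makes the daily snapshot design (below) sound. It is enforced at
catalog load time and property-tested against random predicates and records.

Concept sets match on canonical labels (case-insensitive) and optionally on
`SYSTEM:CODE` pairs. Label matching is primary because authoritative
ICD code lists per condition are site-specific configuration, not portable
package content; codes are fully supported for sites that configure them.

The default catalog has 26 items, 17 of them extractable (65%). Six
extractable items are clinically anchored and exercised by the mock cases:

| item | rule |
|---|---|
| 1 | prior intracranial hemorrhage, unlimited lookback |
| 3 | ischemic stroke within 90 days |
| 13 | significant liver disease (matches liver cirrhosis) |
| 15 | severe renal disease (matches hemodialysis) |
| 16 | current oral anticoagulant use |
| 17 | `all(stroke any time, diabetes any time)` |

Item 3's "three months" is fixed at 90 days: deterministic and
conventional. Item 16 counts a medication order when its active interval
`[start, stop]` (open stop = ongoing) overlaps the 30 days before the
index; 30 days absorbs dispensing gaps while still meaning "current" use,
and is configurable like every window. Item 17 keeps unlimited lookback on
both legs: a "known history of diabetes and stroke" states no window, and
the mock cases (stroke 2009, diabetes 2010, index 2014) require it.

The remaining items are populated from standard tPA exclusion criteria so
the catalog is complete and realistic, but they are flagged
`provisional: true` in the shipped config: their numbering is a local
convention. Nine items are non-extractable and carry an `on_site_note`; the
engine reports them as `NOT_EXTRACTABLE` rather than guessing. Three
history items — atrial fibrillation, dementia, heart failure — are
*advisories*: they demand attention (e.g. anticoagulation for atrial
fibrillation) without excluding treatment by themselves; only advanced
dementia would exclude, and that judgment is not record-decidable, so
dementia stays advisory.

Catalogs round-trip through YAML/JSON configs validated against the schema
in `inst/extdata/catalog-schema.json` (26 unique items, predicates
negation-free, extractable iff predicate present).

## Screening, the snapshot database, and the live refresh

`screen_patient(record, catalog, index, home_hospital)` evaluates every
item against the consent-visible record, ignoring events dated after the
index (future data cannot inform a code-stroke screen), and returns one
finding per item with full evidence provenance — source, hospital, date,
concept, code — sorted by date, hospital, concept for stable output. It
also collects labs and imaging in the closed 24-hour window before the
index, the "fresh data" a treating physician needs alongside the history
screen.

The modelled production system cannot afford to scan years of records from
seven hospitals at code-stroke time, so it precomputes: a nightly
`build_snapshot()` stores, for every consented patient, the items TRIGGERED
as of the build time with their evidence. CLEAR is never stored — by
monotonicity it is the default that new data can only overturn, and
recomputing it keeps the store small and never stale-negative.
`screen_with_snapshot()` merges the snapshot's findings with a live
evaluation of the record up to the index. The live pass re-evaluates rules
over the full visible record rather than only post-build events: a
conjunction like item 17 can have one leg before the build and one after,
and only a full re-evaluation guarantees the merged report is *identical*
to a fresh `screen_patient()` — an invariant tested over random cohorts.
The snapshot in this design functions as a precomputed index (and keeps a
patient's findings available even when a later record extract is
incomplete); correctness never depends on it.

A worked screen of the mock cases:

```{r screen}
cases <- make_mock_cases()
cat26 <- default_catalog()
report <- screen_patient(cohort_patient(cases, "case-4"), cat26,
                         attr(cases, "index"))
filter(tidy(report), status == "TRIGGERED")
glance(report)
```

## The synthetic data

`make_mock_cases()` builds the four test patients the engine is validated
against: elderly stroke-registry-style histories spread over four of the
seven hospitals, every case carrying dementia, and between them exactly
nine contraindications over six distinct items — sets {3, 17},
{13, 15, 17}, {1}, {3, 16, 17}. Source histories carry years only, so the
generator dates ordinary events July 1 of their year; the two "recent
stroke" events are dated index − 60 days, the minimal dating that puts
them inside item 3's 90-day window while the cases' 2011/2012 strokes stay
safely outside; anticoagulant orders start in 2014 and remain open. The
index defaults to 2014-09-01.

`generate_cohort()` draws randomized cohorts for property testing:
independent per-concept prevalences, events scattered uniformly over
hospitals and a date range, a configurable consent rate, Poisson lab
counts, all seed-reproducible. It deliberately does *not* model comorbidity
correlations, realistic code distributions, or free-text records — so
passing tests show the engine's logic is correct on clean structured
events, not that real-world extraction (coding variation, typos,
unstructured notes) is solved. That extraction layer is exactly what a
deploying site configures through the catalog's concept sets.

`simulate_responses()` is the stand-in for human screening behavior: each
contraindication opportunity is missed independently with a per-arm
probability, and per-set review times are log-normal (defaults: mean 14.6,
SD 7.4 minutes unassisted; 7.3 and 5.2 assisted — about a halving, used
only for simulation realism since human outcomes are not computable). The
independence assumption is a simplification — real misses cluster within
physicians — and is the reason the simulated per-physician SDs need not
match any observed study.

## The crossover evaluation machinery

`counterbalanced_assignment(12, cases)` yields the fixed-sequence
two-period design: each physician screens two cases unassisted (control)
and two assisted, the six (pair | complement) patterns each used twice, so
every case appears exactly six times per arm and each arm holds
6 × 9 = 54 contraindication opportunities. `validate_assignment()` checks
exactly that arithmetic, for the reference design or any seeded shuffle.

`summarize_arm()` computes totals, percentages of opportunities, and
per-item / per-physician means, SDs (sample, n − 1), and medians at full
precision; `arm_summary_display()` applies the conventional half-up
rounding to one decimal for presentation. Replaying the observed per-item
miss counts `[2, 6, 5, 2, 1, 7]` vs `[0, 1, 1, 1, 0, 4]`:

```{r replay}
arm_summary_display(summarize_arm(c(2, 6, 5, 2, 1, 7), 54, 12))
arm_summary_display(summarize_arm(c(0, 1, 1, 1, 0, 4), 54, 12))
```

The test battery follows the univariate conventions of such pilot studies:

* **Unpaired t** — pooled (equal-variance) by default, since with n = 6
  per-item counts per arm the pooled variant is the textbook choice; Welch
  is a flag. On the counts above: t = 2.26, df 10, p ≈ 0.047.
* **Mann–Whitney** — `exact` enumerates all `choose(n1+n2, n1)` rank
  assignments with mid-ranks for ties (924 arrangements for 6 vs 6) and
  reports the two-sided tail of |U − n₁n₂/2|; this keeps exactness under
  ties, which the usual algorithms abandon. The tie-corrected,
  continuity-corrected normal approximation is available and required past
  n₁ + n₂ = 20.
* **Chi-square** — on the 2×2 of missed vs caught opportunities per arm
  (23/31 vs 7/47), the only construction that matches totals expressed as
  percentages of 54. Yates correction defaults on for these cell sizes;
  both variants are reported (11.8 uncorrected, 10.4 corrected — both
  p ≈ 0.001). The 108 opportunities are treated as independent although
  they cluster within physicians; a cluster-robust analysis is out of
  scope and the caveat stands.

`analyze_study()` wires these together over per-opportunity results,
enforces the conservation identity (per-item totals = per-physician totals
= arm total), flags degenerate comparisons (all-zero arms) instead of
erroring, and exports CSV/JSON. Carryover and period effects of the
crossover are deliberately not modelled — with a fixed sequence and
preset cases there is no washout structure to estimate — and that is a
stated limitation, not an omission.

## Bedside calculators

`nihss_total()` validates and sums the standard 15-item NIHSS (range
0–42), with the item set and maxima encoded as data. `tpa_dose()` applies
the licensed regimen — 0.9 mg/kg to a 90 mg ceiling, 10% bolus, remainder
infused — rounding to 0.1 mg (vial-practical increments vary by site; 0.1
mg is the neutral choice). The `capped` flag marks when the ceiling truly
binds (weight > 100 kg). Both formulas are parameters, not constants, so
protocol variants are configuration.

## Numerical and design choices, in one place

* Lookback windows and the 24-hour lab/imaging window are **closed**
  intervals; boundary behavior is tested at exactly 90 days and exactly
  24 hours.
* Events dated after the index are ignored everywhere.
* Evidence ordering (date, then hospital, then concept) and sorted-key
  JSON make every rendered report byte-stable.
* Duplicate diagnoses across hospitals are all kept; rules aggregate over
  them, so duplicates are harmless and provenance stays complete.
* Display rounding is half-up to 1 decimal; all stored values keep full
  precision.
* Exact Mann–Whitney defines the two-sided p as the null probability of a
  U at least as far from n₁n₂/2 as observed; with heavy ties this
  deviation definition is the defensible one (doubling the smaller tail
  can exceed 1).
* Test problem sizes — 50-patient equivalence cohorts, 2000-replicate
  parameter recovery, 40-case property loops — were chosen as the smallest
  sizes at which the properties are sharp (3-SE Monte-Carlo bands,
  enumerable rank spaces), and they run in seconds.

## Known limitations

* The engine decides from structured events only; it does not parse notes,
  reconcile conflicting records, or link mismatched patient identities.
* The catalog's provisional items (2, 4–12, 14, 18–26) are defensible
  defaults, not an authoritative numbering; deploying sites must review
  them.
* Advisory vs exclusion severity for borderline items (advanced dementia,
  renal disease short of dialysis) encodes clinical judgment that belongs
  to the treating physician, not the tool.
* The simulation model treats misses as independent Bernoulli draws;
  clustered behavior within physicians is not modelled.
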