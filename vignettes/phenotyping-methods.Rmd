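---
title: "Methods: rule-based phenotyping of degenerative rotator cuff tear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based phenotyping of degenerative rotator cuff tear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocuff)
```

## The phenotype and its assumptions

`phenocuff` classifies patients for degenerative (atraumatic) rotator
cuff tear from billed CPT and ICD-9-CM/ICD-10-CM codes alone. The
underlying assumptions are those of any code-based phenotype:

- **Billing codes track clinical events.** A cuff-repair CPT code means
  a repair happened; an imaging CPT code followed within a year by an
  RCT diagnosis code means imaging established the tear.
- **Day granularity suffices.** Billing extracts carry calendar dates,
  not times, so all temporal logic works on whole days and same-day
  events cannot be ordered relative to each other.
- **Traumatic codes separate the competing aetiology.** Acute
  sprain/strain/laceration and traumatic-arthropathy codes *after* an
  inclusion anchor indicate a traumatic tear, which the phenotype must
  exclude; the same codes before the anchor carry no veto.

Each patient is evaluated against five case definitions (specific
surgery; non-specific surgery + diagnosis within a year; imaging +
diagnosis within a year, no later exclusion; ≥ 3 diagnosis visit dates;
≥ 4 diagnosis mentions in one vocabulary) and two control definitions
(any non-case; imaging-confirmed non-case with no surgical or diagnosis
codes). Cases take precedence over controls unconditionally: a patient
meeting any case definition is never a control.

## Tunable parameters

All knobs live in `rule_config()`:

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window_days` | 365 | days | "within 1 year after" on day-level data |
| `window_includes_anchor_day` | `TRUE` | — | same-day imaging + coded diagnosis is common, and day-level data cannot order them; excluding day 0 would drop genuine same-day confirmations |
| `exclusion_after_is_strict` | `TRUE` | — | a same-day exclusion code is ambiguous at day granularity; only a strictly later one vetoes |
| `min_unique_visits_4a` | 3 | visits | repeated-ascertainment threshold of the visit-count definition |
| `min_mentions_4b` | 4 | mentions | threshold of the mention-count definition |
| `dot_insensitive` | `FALSE` | — | dictionaries print dotted ICD codes; some EHR extracts strip dots. Off by default because exact matching is safer (dot-stripping can merge distinct codes) |
| `control_mode` | `"strict"` | — | the study population was MRI-ascertained, so the imaging-confirmed control definition is the operative one; `"broad"` labels any non-case a control |
| `case3_icd10_imaging` | `FALSE` | — | the published case table lists only CPT and ICD-9 imaging anchors; ICD-10 imaging codes appear only in the control table. The default follows the tables literally; the switch adds them to definition 3 |

## Decisions where the published tables are ambiguous

Several points are under-specified by the published rule tables; the
package fixes them as follows, each exposed in configuration or
documented here so a user can disagree:

- **Visit vs mention counting.** The visit-count definition pools both
  ICD vocabularies when counting distinct visit dates (its logic joins
  the two groups with OR inside one count), while the mention-count
  definition counts mentions *within* a single vocabulary (its logic
  reads "≥ 4 mentions of [ICD-9] OR ≥ 4 mentions of [ICD-10]"). Same-day
  repeats are distinct mentions but one visit.
- **Dx-date tie-break.** When several case definitions fire, the final
  diagnosis date is the minimum over their dx dates; all hits are kept
  in the output. No precedence between definitions is stated anywhere,
  and the earliest onset is the epidemiologically conservative index
  date.
- **"Third unique ICD code".** Read as the third *unique visit date*
  bearing a qualifying code: on day-level data a "unique code
  occurrence" and a "visit" are indistinguishable, and the definition's
  own description is phrased in visits.
- **The general repetition requirement.** The narrative statement that
  codes must recur at separate time points is implemented only where
  the rule tables impose it (the visit- and mention-count definitions);
  definitions 1–3 fire on single qualifying events, exactly as their
  Boolean logic is written.
- **Dictionary quirks are preserved, not repaired.** The packaged
  dictionary keeps the published typing of 80.21 as CPT, the dual group
  membership of ICD-9 83.63, and the duplicated rows (which the loader
  collapses with a warning); `inst/extdata/rct_dictionary_errata.md`
  documents each. The published aggregate counts of codes per
  vocabulary, and the published shared/unique percentages, follow
  counting conventions that are not stated; the package reports the
  tallies of the file it actually ships (8 / 10 / 59 entries = 10.4 /
  13.0 / 76.6 %) rather than guessing a convention that reproduces the
  published rounding.
- **Orphan groups.** `rct_icd9_nontraum` and `rct_cpt_surg_exclude`
  are loaded and queryable but drive no default rule, since no rule
  table references them.

## Numerical and degenerate-input choices

- **Rounding.** Metrics are computed as exact rationals and rendered as
  percentages with half-away-from-zero rounding at the printed
  precision (`round_half_up()`), the convention of clinical reporting.
  Base R's banker's rounding would turn 80.85 into 80.8.
- **Zero denominators.** Sensitivity/specificity/accuracy with an empty
  denominator are `NA` ("not applicable"), never 0 or 100.
- **Empty records.** A patient with no (valid) events is INDETERMINATE
  under strict control mode and CONTROL under broad mode — the "any
  non-case" reading.
- **Ties.** Events are ordered by date, then by source row; this makes
  classification invariant to input row order (evidence row *numbers*
  follow the input file, but labels and dates never change under
  permutation).
- **Malformed input.** Unparseable rows are rejected individually and
  reported, never silently dropped; contradictory dictionary provenance
  is a hard load error.

## The synthetic cohort generator

`generate_cohort()` builds each patient to satisfy **exactly one**
archetype: one of the five case definitions, the imaging-confirmed
control, an indeterminate pattern (a lone diagnosis mention), or a
near-miss that violates exactly one clause (diagnosis one day past the
window; one qualifying visit short; exclusion code after the imaging
anchor). Dates are drawn uniformly with the archetype's ordering
constraints imposed by construction — not by rejection sampling — so
generation is fast and validity is guaranteed. Background noise events
(codes outside every dictionary group) are added at a configurable
Poisson rate, and a dialect map can rewrite codes the way a second
institution would bill them. Gold labels can be corrupted at
per-category rates, with the injected errors recorded in a truth
ledger.

The defaults mirror the validation study's conditions: 492 patients at
the study's 405:87 case:control ratio (cases spread evenly across the
five definitions, since the study does not report which definitions
fired), and gold-error rates of 44/492 conflicting-diagnosis, 12/492
data-entry and 1/492 dual-diagnosis mislabels. A single seed drives
everything; label-error injection derives its stream as `seed + 1`.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: realistic visit-frequency and disease
progression patterns, code co-occurrence structure, patients whose
streams satisfy several definitions at once (real cases often do),
laterality, demographics, and miscoded events. The generator's purpose
is to exercise every rule path with known truth, not to imitate a real
EHR's marginal distributions.

## Verification strategy and problem sizes

The test suite checks the engine two independent ways: frozen
small-record examples per definition, and a brute-force evaluator
(plain loops over events with hand-listed group membership, sharing no
code with the engine) compared against the engine on exhaustive ≤
2-event records and 800 randomized ≤ 8-event records over an
11-code alphabet under five configuration variants. End-to-end
properties use synthetic cohorts of 1,000 (clean recovery), 400
(truth-ledger restoration), 100 (dialect recall collapse) and 50
(permutation/date-shift invariance) patients — sizes chosen to exercise
every archetype many times over while keeping the whole suite quick to
run routinely.

## Known limitations

- The phenotype is only as portable as its dictionary: the packaged
  code list reflects two institutions, and a third site would likely
  need further local codes (the dialect machinery exists precisely to
  study this failure mode).
- No NLP: radiology impressions, operative notes and laterality are out
  of scope; a tear documented only in free text is invisible.
- No eligibility screening: age and MRI-enrollment criteria are
  upstream recruitment, not part of the classification.
- Day-granularity semantics (anchor-day-inclusive windows, strict
  "after") are conventions, not ground truth; both are configurable and
  their effect is testable per cohort.
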