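# phenocuff

Rule-based EHR phenotyping of degenerative rotator cuff tear (RCT).

Large observational studies — genome-wide association studies in
particular — need case/control status for thousands of patients, and
manual chart review does not scale. A computable phenotype classifies
patients from the structured codes already in the electronic health
record: CPT procedure codes and ICD-9-CM / ICD-10-CM diagnosis codes,
combined with temporal and frequency logic. `phenocuff` implements such
a phenotype for atraumatic (degenerative) rotator cuff tear, together
with the machinery needed to validate it against a manually curated
gold standard and to study how it degrades when moved between
institutions with different coding dialects.

## The algorithm

Each patient's coded events are evaluated against five case definitions
and two control definitions over named code groups (the packaged data
dictionary maps each (vocabulary, code) pair into groups such as
`rct_cpt_surg_spec_include` or `rct_icd10_exclusions`):

| Definition | Logic | Dx date |
|---|---|---|
| Case 1 | any specific surgical cuff-repair code | earliest such event |
| Case 2 | non-specific shoulder surgery **and** an RCT diagnosis code within 1 year after | earliest qualifying surgery |
| Case 3 | imaging code (CPT/ICD-9) **and** a diagnosis code within 1 year after, **not** followed by an exclusion code | earliest qualifying imaging |
| Case 4a | diagnosis codes on ≥ 3 unique visit dates (ICD-9 and ICD-10 pooled), no exclusion after the first | 3rd unique visit |
| Case 4b | ≥ 4 diagnosis mentions within one ICD vocabulary, no exclusion after the first | 4th mention |
| Control 1 | any non-case | — |
| Control 2 | imaging code present, no surgical or diagnosis code at all, and not a case | — |

A patient meeting any case definition is a CASE (diagnosis date = the
earliest over the definitions met); a non-case is a CONTROL under the
imaging-confirmed definition (Control 2, the default) or any non-case
in broad mode; everything else is INDETERMINATE. Exclusion codes are
the traumatic sprain/strain/laceration and traumatic-arthropathy codes;
"within 1 year" is an anchor-day-inclusive 365-day window. All of these
choices are explicit knobs of `rule_config()`.

Validation against a gold standard uses the standard confusion-matrix
metrics (CASE as the positive class),

    sensitivity = TP/(TP+FN),  specificity = TN/(TN+FP),
    accuracy = (TP+TN)/N,

plus an adjudication workflow: chart review assigns each false positive
and false negative a cause (true algorithm error, or a gold-standard
mislabel — conflicting diagnosis, data-entry error, dual diagnosis),
and gold-mislabel records are reclassified (FP→TP, FN→TN).

## Worked example

```r
library(phenocuff)
dict <- load_dictionary()         # packaged RCT data dictionary

ev <- data.frame(
  patient_id = c("P001","P001","P002","P003","P003","P003","P004"),
  date       = c("2020-02-01","2020-03-15","2019-03-04","2021-01-05",
                 "2021-02-10","2021-03-02","2022-06-01"),
  vocabulary = c("CPT","ICD10CM","CPT","ICD10CM","ICD10CM","ICD10CM","CPT"),
  code       = c("73221","M75.111","29827","M75.101","M75.101","M75.101","73221"))

classify_cohort(as_coded_events(ev), dict)
#>   patient_id   label final_dx_date     definitions_met evidence_rows
#> 1       P001    CASE    2020-02-01              CASE_3           1;2
#> 2       P002    CASE    2019-03-04              CASE_1             1
#> 3       P003    CASE    2021-03-02             CASE_4A         1;2;3
#> 4       P004 CONTROL          <NA> CONTROL_1;CONTROL_2           1
```

P001 is a case via imaging + diagnosis within a year (dx = the imaging
date); P002 via a specific surgical repair; P003 via three unique visit
dates with a diagnosis mention (dx = the third visit); P004 has imaging
only and is an imaging-confirmed control.

Scoring a corrected validation matrix:

```r
compute_metrics(confusion_matrix(tp = 420, fp = 11, fn = 26, tn = 35))
#> <metrics_report>
#>   sensitivity: 94%
#>   specificity: 76%
#>   accuracy:    92%
```

Dictionary portability at a glance — how many codes are shared between
the originating and implementing sites versus unique to one of them:

```r
site_overlap_summary(dict)
#>   site_flags  n percent
#> 1  UTSW_ONLY  8    10.4
#> 2  VUMC_ONLY 10    13.0
#> 3     SHARED 59    76.6
```

A synthetic cohort with known truth (every archetype constructed to
satisfy exactly one definition, plus optional gold-label corruption and
cross-site code substitutions) is one call away:

```r
cohort <- generate_cohort(simulation_config(n_patients = 500, seed = 1), dict)
res <- classify_cohort(cohort$events, dict)
```

## Command line

A thin wrapper over the same functions ships at
`inst/cli/phenocuff.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","phenocuff.R",package="phenocuff"))')" \
  classify --events events.csv --out labels.csv
```

Subcommands: `classify`, `validate` (optionally with an adjudication
ledger), `simulate`, `dict-summary`. Every run writes a JSON manifest
(inputs, md5 digests, config echo, summary counts). Exit codes: 0
success, 2 usage/config error, 3 data error.

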