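# Errata for the packaged rotator cuff tear code dictionary

The packaged file `rct_dictionary.csv` reproduces the source data
dictionary verbatim, internal inconsistencies included. The loader does
not silently repair them; this note documents what a careful user should
know.

1. **Code 80.21 is typed CPT.** 80.21 ("Arthroscopy, shoulder") is an
   ICD-9 procedure code, not a CPT code. The dictionary keeps the CPT
   typing it was published with; events coded (CPT, 80.21) will match it,
   events coded (ICD9CM, 80.21) will not.
2. **ICD-9 83.63 appears under two groups.** "Rotator cuff repair" is
   listed both under `rct_cpt_surg_spec_include` (despite the group's CPT
   prefix) and under `rct_icd9_diag_include`. Both memberships are kept;
   an (ICD9CM, 83.63) event therefore counts for case definition 1 and as
   a diagnosis mention.
3. **Duplicate rows.** ICD-9 727.6 is listed twice under
   `rct_icd9_nontraum` with two descriptions, and the three
   "unspecified shoulder" strain rows repeat the right-shoulder codes
   S46.011A/D/S. The loader collapses duplicate
   (variable_name, vocabulary, code) triples with a warning; the first
   description wins.
4. **Group-label spelling.** `rct_icd10_exclude` (dictionary) and
   `rct_icd10_exclusions` (rule definitions) name the same group; the
   loader canonicalizes both, and mixed upper/lower-case variable names
   (e.g. `RCT_icd9_diag_include`), to one lower-case label.
5. **Orphan groups.** `rct_icd9_nontraum` (727.6) and
   `rct_cpt_surg_exclude` (24341) belong to no default rule; they are
   loaded and queryable but do not affect classification.
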