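# Independent brute-force evaluator of the phenotype rules, used to
# cross-check the engine. Written as plain loops over events with its own
# hand-listed group membership for a small code alphabet; it shares no
# code path with the package's rule engine.

ORACLE_ALPHABET <- data.frame(
  vocabulary = c("CPT", "CPT", "CPT", "ICD9CM", "ICD10CM", "ICD9CM",
                 "ICD10CM", "ICD9CM", "ICD9CM", "ICD10CM", "CPT"),
  code = c("29827", "29823", "73221", "88.94", "M75.101", "726.13",
           "S43.421A", "840.4", "83.63", "BP3FYZZ", "99213"),
  stringsAsFactors = FALSE
)

# membership transcribed by hand from the published dictionary
ORACLE_GROUPS <- list(
  "CPT|29827"        = "surg_spec",
  "CPT|29823"        = "surg_nonspec",
  "CPT|73221"        = "cpt_image",
  "ICD9CM|88.94"     = "icd9_image",
  "ICD10CM|M75.101"  = "diag10",
  "ICD9CM|726.13"    = "diag9",
  "ICD10CM|S43.421A" = "excl10",
  "ICD9CM|840.4"     = "excl9",
  "ICD9CM|83.63"     = c("surg_spec", "diag9"),
  "ICD10CM|BP3FYZZ"  = "icd10_image",
  "CPT|99213"        = character()
)

oracle_has <- function(groups_i, g) vapply(groups_i, function(x) g %in% x, logical(1))

# dates: Date vector; keys: "VOC|CODE" strings; cfg: a rule_config list.
# Returns list(label, final_dx (Date or NA), defs (sorted character)).
oracle_classify <- function(dates, keys, cfg) {
  n <- length(dates)
  groups_i <- ORACLE_GROUPS[keys]
  inw <- function(anchor, target) {
    d <- as.integer(target - anchor)
    lo <- if (cfg$window_includes_anchor_day) 0L else 1L
    d >= lo & d <= cfg$window_days
  }
  excl <- dates[oracle_has(groups_i, "excl9") | oracle_has(groups_i, "excl10")]
  after <- function(anchor) {
    if (cfg$exclusion_after_is_strict) any(excl > anchor) else any(excl >= anchor)
  }
  diag_dates <- dates[oracle_has(groups_i, "diag9") | oracle_has(groups_i, "diag10")]

  hits <- list()
  # definition 1
  d1 <- dates[oracle_has(groups_i, "surg_spec")]
  if (length(d1)) hits$CASE_1 <- min(d1)
  # definition 2
  anchors <- dates[oracle_has(groups_i, "surg_nonspec")]
  qual <- anchors[vapply(anchors, function(a) any(inw(a, diag_dates)), logical(1))]
  if (length(qual)) hits$CASE_2 <- min(qual)
  # definition 3
  img <- oracle_has(groups_i, "cpt_image") | oracle_has(groups_i, "icd9_image")
  if (isTRUE(cfg$case3_icd10_imaging)) img <- img | oracle_has(groups_i, "icd10_image")
  anchors <- dates[img]
  qual <- anchors[vapply(anchors, function(a) any(inw(a, diag_dates)), logical(1))]
  if (length(qual) && !after(min(qual))) hits$CASE_3 <- min(qual)
  # definition 4a
  visits <- sort(unique(diag_dates))
  k <- cfg$min_unique_visits_4a
  if (length(visits) >= k && !after(visits[1])) hits$CASE_4A <- visits[k]
  # definition 4b
  m <- cfg$min_mentions_4b
  for (g in c("diag9", "diag10")) {
    dg <- sort(dates[oracle_has(groups_i, g)])
    if (length(dg) >= m && !after(dg[1])) {
      cand <- dg[m]
      if (is.null(hits$CASE_4B) || cand < hits$CASE_4B) hits$CASE_4B <- cand
    }
  }

  if (length(hits)) {
    dxs <- as.Date(vapply(hits, format, character(1), format = "%Y-%m-%d"))
    return(list(label = "CASE", final_dx = min(dxs),
                defs = sort(names(hits)), hits = hits))
  }
  # controls (case precedence already handled)
  defs <- "CONTROL_1"
  imaging <- oracle_has(groups_i, "cpt_image") | oracle_has(groups_i, "icd9_image") |
    oracle_has(groups_i, "icd10_image")
  blocking <- oracle_has(groups_i, "surg_spec") | oracle_has(groups_i, "surg_nonspec") |
    oracle_has(groups_i, "diag9") | oracle_has(groups_i, "diag10")
  if (any(imaging) && !any(blocking)) defs <- c(defs, "CONTROL_2")
  wanted <- if (cfg$control_mode == "strict") "CONTROL_2" else "CONTROL_1"
  list(label = if (wanted %in% defs) "CONTROL" else "INDETERMINATE",
       final_dx = as.Date(NA), defs = defs, hits = list())
}

# build the engine-side record for the same (dates, keys)
oracle_record <- function(dates, keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  make_record(codes = vapply(parts, `[`, character(1), 2),
              dates = format(dates, "%Y-%m-%d"),
              vocabularies = vapply(parts, `[`, character(1), 1))
}

# compare engine and oracle on one record; returns NULL if they agree,
# else a description of the mismatch
oracle_mismatch <- function(dates, keys, cfg, dict) {
  rec <- oracle_record(dates, keys)
  eng <- classify(rec, dict, cfg)
  ora <- oracle_classify(dates, keys, cfg)
  eng_defs <- sort(vapply(eng$hits, `[[`, character(1), "definition_id"))
  eng_dx <- if (is.null(eng$final_dx_date)) as.Date(NA) else eng$final_dx_date
  eng_def_dx <- lapply(eng$hits, `[[`, "dx_date")
  names(eng_def_dx) <- vapply(eng$hits, `[[`, character(1), "definition_id")
  per_def_ok <- all(vapply(names(ora$hits), function(d) {
    identical(format(eng_def_dx[[d]]), format(ora$hits[[d]]))
  }, logical(1)))
  ok <- identical(eng$label, ora$label) &&
    identical(eng_defs, ora$defs) &&
    identical(format(eng_dx), format(ora$final_dx)) &&
    per_def_ok
  if (ok) return(NULL)
  sprintf("keys=[%s] dates=[%s]: engine %s/%s/%s vs oracle %s/%s/%s",
          paste(keys, collapse = ","), paste(format(dates), collapse = ","),
          eng$label, paste(eng_defs, collapse = "+"), format(eng_dx),
          ora$label, paste(ora$defs, collapse = "+"), format(ora$final_dx))
}
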