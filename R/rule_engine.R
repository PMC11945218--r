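# Temporal Boolean rule engine: five case definitions and two control
# definitions over dictionary code groups, with window, frequency and
# post-anchor exclusion logic.

CASE_DEFINITIONS    <- c("CASE_1", "CASE_2", "CASE_3", "CASE_4A", "CASE_4B")
CONTROL_DEFINITIONS <- c("CONTROL_1", "CONTROL_2")

#' Rule engine configuration
#'
#' Bundles the tunable parameters of the phenotype rules. Defaults encode
#' the published algorithm: a 365-day "within 1 year" window that
#' includes the anchor day (day-granularity data cannot order same-day
#' events, and same-day imaging plus coded diagnosis is common), an
#' exclusion clause that requires the exclusion code to fall strictly
#' after the anchor date, three unique visits for the visit-count case
#' definition, four mentions for the mention-count case definition, and
#' the imaging-confirmed control definition as the operative one.
#'
#' @param window_days length of the "within 1 year after" window, days.
#' @param window_includes_anchor_day logical; is a same-day diagnosis
#'   inside the window?
#' @param exclusion_after_is_strict logical; must an exclusion code be
#'   dated strictly after the anchor (`TRUE`) or does the anchor day
#'   itself count (`FALSE`)?
#' @param min_unique_visits_4a unique visit dates required by case
#'   definition 4a.
#' @param min_mentions_4b single-vocabulary diagnosis mentions required
#'   by case definition 4b.
#' @param dot_insensitive logical; match codes ignoring internal dots
#'   (for EHR extracts that strip them).
#' @param control_mode `"strict"` labels CONTROL only on the
#'   imaging-confirmed definition (CONTROL_2); `"broad"` labels any
#'   non-case CONTROL (CONTROL_1).
#' @param case3_icd10_imaging logical; also accept ICD-10 imaging codes
#'   as anchors for case definition 3. The published case table omits
#'   them (only the control table lists ICD-10 imaging), so the default
#'   follows it literally.
#' @return a `rule_config` list.
#' @export
rule_config <- function(window_days = 365L,
                        window_includes_anchor_day = TRUE,
                        exclusion_after_is_strict = TRUE,
                        min_unique_visits_4a = 3L,
                        min_mentions_4b = 4L,
                        dot_insensitive = FALSE,
                        control_mode = c("strict", "broad"),
                        case3_icd10_imaging = FALSE) {
  control_mode <- match.arg(control_mode)
  window_days <- as.integer(window_days)
  min_unique_visits_4a <- as.integer(min_unique_visits_4a)
  min_mentions_4b <- as.integer(min_mentions_4b)
  if (is.na(window_days) || window_days < 1L) {
    abort_config("window_days must be a positive integer")
  }
  if (is.na(min_unique_visits_4a) || min_unique_visits_4a < 1L ||
      is.na(min_mentions_4b) || min_mentions_4b < 1L) {
    abort_config("visit/mention thresholds must be positive integers")
  }
  structure(list(
    window_days = window_days,
    window_includes_anchor_day = isTRUE(window_includes_anchor_day),
    exclusion_after_is_strict = isTRUE(exclusion_after_is_strict),
    min_unique_visits_4a = min_unique_visits_4a,
    min_mentions_4b = min_mentions_4b,
    dot_insensitive = isTRUE(dot_insensitive),
    control_mode = control_mode,
    case3_icd10_imaging = isTRUE(case3_icd10_imaging)
  ), class = "rule_config")
}

#' Read a rule configuration from a JSON file
#'
#' Unknown fields are rejected; omitted fields keep their defaults.
#'
#' @param path JSON file whose top-level fields are [rule_config()]
#'   arguments.
#' @return a `rule_config`.
#' @export
read_rule_config <- function(path) {
  if (!file.exists(path)) abort_config("config file not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(vals), names(formals(rule_config)))
  if (length(unknown)) {
    abort_config("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(rule_config, vals)
}

#' Is a target date within the follow-up window after an anchor?
#'
#' The window is `[0, window_days]` days after the anchor when the anchor
#' day is included (default), `[1, window_days]` otherwise. Events
#' preceding the anchor are never in the window.
#'
#' @param anchor,target `Date` vectors (recycled).
#' @param cfg a [rule_config()].
#' @return logical vector.
#' @examples
#' within_window(as.Date("2020-01-01"), as.Date("2020-12-31"), rule_config())
#' @export
within_window <- function(anchor, target, cfg = rule_config()) {
  d <- as.integer(as.Date(target) - as.Date(anchor))
  lo <- if (cfg$window_includes_anchor_day) 0L else 1L
  !is.na(d) & d >= lo & d <= cfg$window_days
}

# ---- group membership -------------------------------------------------

# Logical matrix (events x rule-relevant groups). Computed once per
# record and shared by all definition workers.
event_group_matrix <- function(record, dict, cfg) {
  groups <- list(
    surg_spec    = "rct_cpt_surg_spec_include",
    surg_nonspec = "rct_cpt_surg_nonspec_include",
    cpt_image    = "rct_cpt_image_include",
    icd9_image   = "rct_icd9_image_include",
    icd10_image  = "rct_icd10_image_include",
    diag9        = "rct_icd9_diag_include",
    diag10       = "rct_icd10_diag_include",
    excl9        = "rct_icd9_exclusions",
    excl10       = "rct_icd10_exclusions"
  )
  code <- if (cfg$dot_insensitive) strip_dots(record$code) else record$code
  key <- paste(record$vocabulary, code, sep = "|")
  m <- vapply(groups, function(g) {
    key %in% group_keys(dict, g, dot_insensitive = cfg$dot_insensitive)
  }, logical(nrow(record)))
  # vapply drops to a bare vector for single-row records
  if (nrow(record) == 1L) m <- matrix(m, nrow = 1L,
                                      dimnames = list(NULL, names(groups)))
  m
}

# exclusion = ICD-9 or ICD-10 exclusion group
exclusion_dates <- function(record, gm) {
  record$event_date[gm[, "excl9"] | gm[, "excl10"]]
}

#' Does any exclusion-group event follow the anchor date?
#'
#' Exclusion codes (traumatic sprain/strain/laceration, traumatic
#' arthropathy) dated after the inclusion anchor veto the definitions
#' that carry an exclusion clause. "After" is strictly later than the
#' anchor date by default; with `exclusion_after_is_strict = FALSE` the
#' anchor day itself also vetoes.
#'
#' @param record single-patient `coded_events` data.frame.
#' @param dict a `code_dictionary`.
#' @param anchor `Date`, the definition's inclusion anchor.
#' @param cfg a [rule_config()].
#' @return logical scalar.
#' @export
has_exclusion_after <- function(record, dict, anchor, cfg = rule_config()) {
  gm <- event_group_matrix(record, dict, cfg)
  ex <- exclusion_dates(record, gm)
  if (!length(ex)) return(FALSE)
  if (cfg$exclusion_after_is_strict) any(ex > anchor) else any(ex >= anchor)
}

# ---- definition workers (share a precomputed group matrix) ------------

def_hit <- function(id, dx_date, evidence) {
  list(definition_id = id,
       dx_date = dx_date,
       evidence = sort(unique(as.integer(evidence))))
}

# definition 1: any specific surgical repair code; dx = earliest
.case_1 <- function(record, gm, cfg) {
  idx <- which(gm[, "surg_spec"])
  if (!length(idx)) return(NULL)
  dx <- min(record$event_date[idx])
  def_hit("CASE_1", dx, record$source_row[idx])
}

# anchor events qualified by a diagnosis mention inside the window
.anchored_by_diag <- function(record, gm, anchor_idx, cfg) {
  diag_idx <- which(gm[, "diag9"] | gm[, "diag10"])
  if (!length(anchor_idx) || !length(diag_idx)) return(NULL)
  diag_dates <- record$event_date[diag_idx]
  ok <- vapply(anchor_idx, function(i) {
    any(within_window(record$event_date[i], diag_dates, cfg))
  }, logical(1))
  if (!any(ok)) return(NULL)
  qual <- anchor_idx[ok]
  anchor_date <- min(record$event_date[qual])
  supporting <- diag_idx[within_window(anchor_date, diag_dates, cfg)]
  list(anchor_date = anchor_date,
       evidence = c(record$source_row[qual], record$source_row[supporting]))
}

# definition 2: non-specific surgery anchored by a diagnosis within the window
.case_2 <- function(record, gm, cfg) {
  a <- .anchored_by_diag(record, gm, which(gm[, "surg_nonspec"]), cfg)
  if (is.null(a)) return(NULL)
  def_hit("CASE_2", a$anchor_date, a$evidence)
}

# definition 3: imaging anchored by a diagnosis within the window, vetoed
# by exclusions after the anchor
.case_3 <- function(record, gm, cfg) {
  img <- gm[, "cpt_image"] | gm[, "icd9_image"]
  if (cfg$case3_icd10_imaging) img <- img | gm[, "icd10_image"]
  a <- .anchored_by_diag(record, gm, which(img), cfg)
  if (is.null(a)) return(NULL)
  ex <- exclusion_dates(record, gm)
  veto <- if (cfg$exclusion_after_is_strict) any(ex > a$anchor_date)
          else any(ex >= a$anchor_date)
  if (veto) return(NULL)
  def_hit("CASE_3", a$anchor_date, a$evidence)
}

# definition 4a: >= 3 unique visit dates carrying a diagnosis mention
# (vocabularies pooled), no exclusion after the first visit; dx = the
# threshold-th distinct visit date
.case_4a <- function(record, gm, cfg) {
  diag_idx <- which(gm[, "diag9"] | gm[, "diag10"])
  visit_dates <- sort(unique(record$event_date[diag_idx]))
  k <- cfg$min_unique_visits_4a
  if (length(visit_dates) < k) return(NULL)
  ex <- exclusion_dates(record, gm)
  veto <- if (cfg$exclusion_after_is_strict) any(ex > visit_dates[1])
          else any(ex >= visit_dates[1])
  if (veto) return(NULL)
  def_hit("CASE_4A", visit_dates[k], record$source_row[diag_idx])
}

# definition 4b: >= 4 diagnosis mentions within one vocabulary (same-day
# repeats count), no exclusion after the first counted mention; dx = the
# threshold-th mention's date in that vocabulary
.case_4b <- function(record, gm, cfg) {
  k <- cfg$min_mentions_4b
  ex <- exclusion_dates(record, gm)
  best <- NULL
  for (col in c("diag9", "diag10")) {
    idx <- which(gm[, col])
    if (length(idx) < k) next
    dates <- record$event_date[idx]  # record is chronologically sorted
    veto <- if (cfg$exclusion_after_is_strict) any(ex > dates[1])
            else any(ex >= dates[1])
    if (veto) next
    dx <- dates[k]
    if (is.null(best) || dx < best$dx_date) {
      best <- def_hit("CASE_4B", dx, record$source_row[idx])
    }
  }
  best
}

.control_defs <- function(record, gm, cfg, any_case) {
  hits <- list()
  if (any_case) return(hits)
  hits <- c(hits, list(list(definition_id = "CONTROL_1", dx_date = NULL,
                            evidence = integer())))
  imaging <- gm[, "cpt_image"] | gm[, "icd9_image"] | gm[, "icd10_image"]
  blocking <- gm[, "surg_spec"] | gm[, "surg_nonspec"] |
    gm[, "diag9"] | gm[, "diag10"]
  if (any(imaging) && !any(blocking)) {
    hits <- c(hits, list(list(definition_id = "CONTROL_2", dx_date = NULL,
                              evidence = sort(record$source_row[imaging]))))
  }
  hits
}

# normalize/validate a single-patient record before evaluation
as_patient_record <- function(record) {
  if (!inherits(record, "coded_events")) {
    record <- as_coded_events(as.data.frame(record))
  }
  if (length(unique(record$patient_id)) > 1L) {
    abort_data("record contains multiple patient ids")
  }
  ord <- order(record$event_date, record$source_row)
  as.data.frame(record)[ord, , drop = FALSE]
}

.def_wrapper <- function(worker) {
  function(record, dict, cfg = rule_config()) {
    record <- as_patient_record(record)
    gm <- event_group_matrix(record, dict, cfg)
    worker(record, gm, cfg)
  }
}

#' Case definitions
#'
#' Evaluate one case definition against a single patient's chronology.
#' Each returns `NULL` when the definition is not met, otherwise a hit:
#' a list with `definition_id`, `dx_date` (the assigned diagnosis index
#' date) and `evidence` (source rows of the qualifying events).
#'
#' \describe{
#'   \item{`case_def_1`}{A specific surgical rotator cuff repair code;
#'     dx = earliest such event.}
#'   \item{`case_def_2`}{A non-specific shoulder surgery code with a
#'     rotator cuff tear diagnosis code within the window after it;
#'     dx = earliest qualifying surgical event.}
#'   \item{`case_def_3`}{An imaging code (CPT or ICD-9; optionally
#'     ICD-10, see [rule_config()]) with a diagnosis code within the
#'     window after it and no exclusion code after the anchor;
#'     dx = earliest qualifying imaging event.}
#'   \item{`case_def_4a`}{Diagnosis mentions on at least 3 distinct
#'     visit dates (vocabularies pooled), no exclusion after the first
#'     visit; dx = 3rd distinct visit date.}
#'   \item{`case_def_4b`}{At least 4 diagnosis mentions within a single
#'     vocabulary (same-day repeats count), no exclusion after the first
#'     mention; dx = the 4th mention's date.}
#' }
#'
#' @param record single-patient event table (a `coded_events` subset or
#'   any data.frame with the event columns).
#' @param dict a `code_dictionary`.
#' @param cfg a [rule_config()].
#' @return a hit list or `NULL`.
#' @name case_definitions
NULL

#' @rdname case_definitions
#' @export
case_def_1 <- .def_wrapper(.case_1)

#' @rdname case_definitions
#' @export
case_def_2 <- .def_wrapper(.case_2)

#' @rdname case_definitions
#' @export
case_def_3 <- .def_wrapper(.case_3)

#' @rdname case_definitions
#' @export
case_def_4a <- .def_wrapper(.case_4a)

#' @rdname case_definitions
#' @export
case_def_4b <- .def_wrapper(.case_4b)

#' Control definitions
#'
#' Evaluates the two control definitions for a patient, honouring case
#' precedence: a patient meeting any case definition receives no control
#' hit. CONTROL_1 is "any non-case"; CONTROL_2 additionally requires at
#' least one imaging event (CPT, ICD-9 or ICD-10 imaging groups) and no
#' surgical or diagnosis group event at all.
#'
#' @inheritParams case_definitions
#' @param case_hits optional precomputed list of case hits for the
#'   record; computed internally when `NULL`.
#' @return list of control hits (possibly empty).
#' @export
control_defs <- function(record, dict, cfg = rule_config(), case_hits = NULL) {
  record <- as_patient_record(record)
  gm <- event_group_matrix(record, dict, cfg)
  if (is.null(case_hits)) case_hits <- .all_case_hits(record, gm, cfg)
  .control_defs(record, gm, cfg, any_case = length(case_hits) > 0L)
}

.all_case_hits <- function(record, gm, cfg) {
  hits <- list(.case_1(record, gm, cfg), .case_2(record, gm, cfg),
               .case_3(record, gm, cfg), .case_4a(record, gm, cfg),
               .case_4b(record, gm, cfg))
  hits[!vapply(hits, is.null, logical(1))]
}

#' Classify a single patient
#'
#' Evaluates all case and control definitions and assigns the three-way
#' label. A patient meeting any case definition is a CASE with
#' `final_dx_date` the earliest diagnosis date over the definitions met.
#' A non-case is a CONTROL under the configured control mode
#' (imaging-confirmed CONTROL_2 by default, any non-case in `"broad"`
#' mode), otherwise INDETERMINATE.
#'
#' @inheritParams case_definitions
#' @return a `classification`: list with `patient_id`, `label`, `hits`
#'   (all definition hits) and `final_dx_date` (`NULL` for non-cases).
#' @examples
#' dict <- load_dictionary()
#' rec <- data.frame(patient_id = "P1", date = "2019-03-04",
#'                   vocabulary = "CPT", code = "29827")
#' classify(rec, dict)$label
#' @export
classify <- function(record, dict, cfg = rule_config()) {
  record <- as_patient_record(record)
  gm <- event_group_matrix(record, dict, cfg)
  case_hits <- .all_case_hits(record, gm, cfg)
  control_hits <- .control_defs(record, gm, cfg, any_case = length(case_hits) > 0L)
  hits <- c(case_hits, control_hits)
  control_ids <- vapply(control_hits, `[[`, character(1), "definition_id")

  if (length(case_hits)) {
    label <- "CASE"
    final_dx <- min(as.Date(vapply(case_hits, function(h)
      format(h$dx_date, "%Y-%m-%d"), character(1))))
  } else {
    final_dx <- NULL
    wanted <- if (cfg$control_mode == "strict") "CONTROL_2" else "CONTROL_1"
    label <- if (wanted %in% control_ids) "CONTROL" else "INDETERMINATE"
  }
  pid <- unique(record$patient_id)
  if (length(pid) != 1L) pid <- NA_character_
  structure(list(patient_id = pid,
                 label = label, hits = hits, final_dx_date = final_dx),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  ids <- vapply(x$hits, `[[`, character(1), "definition_id")
  cat(sprintf("<classification> %s: %s", x$patient_id, x$label))
  if (!is.null(x$final_dx_date)) cat(", dx", format(x$final_dx_date))
  cat("\n  definitions met:",
      if (length(ids)) paste(ids, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Classify a cohort of patients
#'
#' Applies [classify()] to every patient in an event table and returns
#' one row per patient. Patients are identified by `patient_id`; output
#' order is the sorted patient id. Deterministic: the same inputs always
#' produce the same table, and row order of the input file is irrelevant.
#'
#' @param events a `coded_events` table (several patients), or a list of
#'   single-patient records (duplicate patient ids across list elements
#'   are an error).
#' @param dict a `code_dictionary`.
#' @param cfg a [rule_config()].
#' @return data.frame with columns `patient_id`, `label`,
#'   `final_dx_date` (`NA` for non-cases), `definitions_met`
#'   (`;`-separated) and `evidence_rows` (`;`-separated source rows);
#'   the full hit lists are attached as attribute `"hits"`.
#' @export
classify_cohort <- function(events, dict, cfg = rule_config()) {
  if (is.list(events) && !is.data.frame(events)) {
    ids <- vapply(events, function(r) unique(r$patient_id)[1], character(1))
    if (anyDuplicated(ids)) {
      abort_data("duplicate patient id(s) across records: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    records <- events[order(ids)]
  } else {
    records <- patient_records(events)
  }
  res <- lapply(records, classify, dict = dict, cfg = cfg)
  out <- data.frame(
    patient_id = vapply(res, `[[`, character(1), "patient_id"),
    label = vapply(res, `[[`, character(1), "label"),
    final_dx_date = as.Date(vapply(res, function(r) {
      if (is.null(r$final_dx_date)) NA_character_
      else format(r$final_dx_date, "%Y-%m-%d")
    }, character(1))),
    definitions_met = vapply(res, function(r) {
      paste(vapply(r$hits, `[[`, character(1), "definition_id"),
            collapse = ";")
    }, character(1)),
    evidence_rows = vapply(res, function(r) {
      paste(sort(unique(unlist(lapply(r$hits, `[[`, "evidence")))),
            collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "hits") <- lapply(res, `[[`, "hits")
  out
}

#' Write a cohort classification table
#'
#' @param x output of [classify_cohort()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_classification <- function(x, path, sep = ",") {
  out <- x
  out$final_dx_date <- ifelse(is.na(out$final_dx_date), "",
                              format(out$final_dx_date, "%Y-%m-%d"))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a classification (prediction) table
#'
#' Reads a delimited table with at least `patient_id` and `label`
#' columns, as written by [write_classification()] or produced by any
#' other classifier.
#'
#' @param path file path.
#' @param sep field separator.
#' @return data.frame with `patient_id` and `label`.
#' @export
read_predictions <- function(path, sep = ",") {
  if (!file.exists(path)) abort_data("prediction file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("patient_id", "label")
  if (!all(need %in% names(df))) {
    abort_data("prediction file lacks column(s): ",
               paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$label <- toupper(trimws(df$label))
  df
}
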