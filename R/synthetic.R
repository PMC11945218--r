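# Seedable synthetic coded-event cohorts. Each patient is built to
# satisfy exactly one archetype (a case definition, the imaging-confirmed
# control, an indeterminate pattern, or a near-miss that violates exactly
# one clause), so the rule engine's behaviour on the cohort is known by
# construction.

ARCHETYPES <- c("CASE_1", "CASE_2", "CASE_3", "CASE_4A", "CASE_4B",
                "CONTROL_IMAGING", "INDETERMINATE",
                "NEAR_MISS_WINDOW", "NEAR_MISS_VISIT", "NEAR_MISS_EXCLUSION")

# Codes outside every dictionary group: routine office visits,
# venipuncture, hypertension/diabetes and similar background codes.
NOISE_CODES <- data.frame(
  vocabulary = c("CPT", "CPT", "CPT", "ICD10CM", "ICD10CM", "ICD10CM",
                 "ICD9CM", "ICD9CM"),
  code = c("99213", "99214", "36415", "E11.9", "I10", "Z00.00",
           "401.9", "250.00"),
  stringsAsFactors = FALSE
)

#' Simulation configuration for synthetic cohorts
#'
#' Defaults emulate the validation study's cohort: 492 patients with the
#' study's 405:87 case:control ratio (cases spread evenly over the five
#' case definitions), and gold-label error rates matching the review's
#' findings — 44 conflicting-diagnosis mislabels, 12 data-entry errors
#' and 1 dual diagnosis among 492 patients. Near-miss and indeterminate
#' archetypes default to zero and are switched on for targeted tests.
#'
#' @param n_patients number of patients to simulate.
#' @param archetype_mix named proportions over the archetypes (must sum
#'   to 1): `CASE_1`, `CASE_2`, `CASE_3`, `CASE_4A`, `CASE_4B`,
#'   `CONTROL_IMAGING`, `INDETERMINATE`, `NEAR_MISS_WINDOW` (diagnosis
#'   one day past the window), `NEAR_MISS_VISIT` (one qualifying visit
#'   short), `NEAR_MISS_EXCLUSION` (exclusion code after the imaging
#'   anchor).
#' @param date_range length-2 `Date` (or ISO string) vector; event dates
#'   fall inside it. Must span at least 800 days so every archetype's
#'   ordering constraints fit.
#' @param dialect_map optional cross-site code substitution map (see
#'   [apply_site_dialect()]) applied to the emitted events.
#' @param gold_error named per-category gold-label corruption rates
#'   (`conflicting_dx`, `data_entry`, `dual_dx`), each the probability
#'   that a patient's gold label is flipped for that reason.
#' @param noise_rate mean number of irrelevant background-code events
#'   added per patient (Poisson).
#' @param seed integer; all randomness derives from it (label-error
#'   injection uses `seed + 1`).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 492L,
                              archetype_mix = c(
                                CASE_1 = 405 / (5 * 492),
                                CASE_2 = 405 / (5 * 492),
                                CASE_3 = 405 / (5 * 492),
                                CASE_4A = 405 / (5 * 492),
                                CASE_4B = 405 / (5 * 492),
                                CONTROL_IMAGING = 87 / 492),
                              date_range = as.Date(c("2015-01-01", "2023-12-31")),
                              dialect_map = NULL,
                              gold_error = c(conflicting_dx = 44 / 492,
                                             data_entry = 12 / 492,
                                             dual_dx = 1 / 492),
                              noise_rate = 1,
                              seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 0L) {
    abort_config("n_patients must be a non-negative integer")
  }
  if (is.null(names(archetype_mix)) ||
      !all(names(archetype_mix) %in% ARCHETYPES)) {
    abort_config("archetype_mix must be named with archetypes from: ",
                 paste(ARCHETYPES, collapse = ", "))
  }
  if (any(archetype_mix < 0) || abs(sum(archetype_mix) - 1) > 1e-8) {
    abort_config("archetype_mix proportions must be non-negative and sum to 1")
  }
  date_range <- as.Date(date_range)
  if (length(date_range) != 2L || anyNA(date_range) ||
      diff(as.integer(date_range)) < 800) {
    abort_config("date_range must be two dates spanning at least 800 days")
  }
  if (any(gold_error < 0) || sum(gold_error) > 1) {
    abort_config("gold_error rates must be in [0,1] and sum to at most 1")
  }
  structure(list(n_patients = n_patients,
                 archetype_mix = archetype_mix,
                 date_range = date_range,
                 dialect_map = dialect_map,
                 gold_error = gold_error,
                 noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# deterministic largest-remainder apportionment of n over proportions
apportion <- function(n, p) {
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

# code pools for archetype construction, drawn from the dictionary
archetype_pools <- function(dict) {
  e <- dict$entries
  pick <- function(group, vocab = NULL, drop_codes = character()) {
    sel <- e$variable_name %in% group
    if (!is.null(vocab)) sel <- sel & e$vocabulary %in% vocab
    out <- unique(e[sel & !(e$code %in% drop_codes), c("vocabulary", "code")])
    rownames(out) <- NULL
    out
  }
  surg_multi <- unique(e$code[e$variable_name %in%
    c("rct_cpt_surg_spec_include", "rct_cpt_surg_nonspec_include",
      "rct_cpt_image_include", "rct_icd9_image_include",
      "rct_icd10_image_include")])
  pools <- list(
    # restrict to CPT so the surgery event carries no diagnosis meaning
    surg_spec = pick("rct_cpt_surg_spec_include", vocab = "CPT"),
    surg_nonspec = pick("rct_cpt_surg_nonspec_include"),
    imaging_case3 = pick(c("rct_cpt_image_include", "rct_icd9_image_include")),
    imaging_any = pick(c("rct_cpt_image_include", "rct_icd9_image_include",
                         "rct_icd10_image_include")),
    # diagnosis mentions must not double as surgical/imaging codes
    diag = pick(c("rct_icd9_diag_include", "rct_icd10_diag_include"),
                drop_codes = surg_multi),
    diag10 = pick("rct_icd10_diag_include", drop_codes = surg_multi),
    exclusion = pick(c("rct_icd9_exclusions", "rct_icd10_exclusions"))
  )
  empty <- names(pools)[vapply(pools, nrow, integer(1)) == 0L]
  if (length(empty)) {
    abort_data("dictionary provides no usable codes for pool(s): ",
               paste(empty, collapse = ", "))
  }
  pools
}

sample_row <- function(pool, n = 1L) pool[sample.int(nrow(pool), n, replace = TRUE), , drop = FALSE]

# one patient's rows (patient_id, date, vocabulary, code)
build_archetype <- function(archetype, pid, pools, cfg, rc) {
  start <- cfg$date_range[1]
  latest_anchor <- cfg$date_range[2] - (rc$window_days + 2L)
  anchor <- start + sample.int(as.integer(latest_anchor - start), 1L)
  ev <- function(dates, pool_rows) {
    data.frame(patient_id = pid, date = format(dates, "%Y-%m-%d"),
               vocabulary = pool_rows$vocabulary, code = pool_rows$code,
               stringsAsFactors = FALSE)
  }
  switch(archetype,
    CASE_1 = ev(anchor, sample_row(pools$surg_spec)),
    CASE_2 = rbind(
      ev(anchor, sample_row(pools$surg_nonspec)),
      ev(anchor + sample.int(rc$window_days + 1L, 1L) - 1L,
         sample_row(pools$diag))),
    CASE_3 = rbind(
      ev(anchor, sample_row(pools$imaging_case3)),
      ev(anchor + sample.int(rc$window_days + 1L, 1L) - 1L,
         sample_row(pools$diag))),
    CASE_4A = {
      gaps <- cumsum(c(0L, sample.int(120L, rc$min_unique_visits_4a - 1L,
                                      replace = TRUE)))
      ev(anchor + gaps, sample_row(pools$diag, rc$min_unique_visits_4a))
    },
    CASE_4B = {
      # one vocabulary, fewer distinct dates than the visit threshold
      n_dates <- min(rc$min_unique_visits_4a - 1L, rc$min_mentions_4b)
      dates <- anchor + cumsum(c(0L, sample.int(120L, n_dates - 1L,
                                                replace = TRUE)))
      ev(rep(dates, length.out = rc$min_mentions_4b),
         sample_row(pools$diag10, rc$min_mentions_4b))
    },
    CONTROL_IMAGING = ev(anchor, sample_row(pools$imaging_any)),
    INDETERMINATE = ev(anchor, sample_row(pools$diag)),
    NEAR_MISS_WINDOW = rbind(
      ev(anchor, sample_row(pools$imaging_case3)),
      ev(anchor + rc$window_days + 1L, sample_row(pools$diag))),
    NEAR_MISS_VISIT = {
      n <- rc$min_unique_visits_4a - 1L
      gaps <- cumsum(c(0L, sample.int(120L, n - 1L, replace = TRUE)))
      ev(anchor + gaps, sample_row(pools$diag, n))
    },
    NEAR_MISS_EXCLUSION = rbind(
      ev(anchor, sample_row(pools$imaging_case3)),
      ev(anchor + sample.int(rc$window_days + 1L, 1L) - 1L,
         sample_row(pools$diag)),
      ev(anchor + sample.int(rc$window_days, 1L), sample_row(pools$exclusion))),
    abort_config("unknown archetype: ", archetype)
  )
}

#' Generate a synthetic coded-event cohort with known truth
#'
#' Builds per-patient event streams archetype by archetype (dates drawn
#' uniformly, ordering constraints imposed by construction), adds
#' background noise events, optionally applies a cross-site dialect map,
#' and emits a gold-label table corrupted at the configured error rates
#' together with a truth ledger recording each patient's archetype, true
#' label and injected gold error.
#'
#' @param cfg a [simulation_config()].
#' @param dict a `code_dictionary` supplying codes for each archetype.
#' @param rule_cfg the [rule_config()] whose thresholds the archetypes
#'   must satisfy (or just miss).
#' @return list with `events` (a `coded_events` table), `gold`
#'   (data.frame `patient_id`, `label` — after error injection) and
#'   `truth` (data.frame `patient_id`, `archetype`, `true_label`,
#'   `gold_error` category or `NA`).
#' @examples
#' dict <- load_dictionary()
#' cohort <- generate_cohort(simulation_config(n_patients = 20, seed = 7), dict)
#' table(classify_cohort(cohort$events, dict)$label)
#' @export
generate_cohort <- function(cfg, dict, rule_cfg = rule_config()) {
  stopifnot(inherits(cfg, "simulation_config"),
            inherits(dict, "code_dictionary"))
  pools <- archetype_pools(dict)
  counts <- apportion(cfg$n_patients, cfg$archetype_mix)
  archetype <- rep(names(cfg$archetype_mix), counts)
  n <- length(archetype)
  if (n == 0L) {
    empty_events <- as_coded_events(data.frame(
      patient_id = character(), date = character(),
      vocabulary = character(), code = character()))
    return(list(events = empty_events,
                gold = data.frame(patient_id = character(),
                                  label = character()),
                truth = data.frame(patient_id = character(),
                                   archetype = character(),
                                   true_label = character(),
                                   gold_error = character())))
  }
  pid <- sprintf("SIM%05d", seq_len(n))
  rows <- with_seed(cfg$seed, {
    per_patient <- lapply(seq_len(n), function(i) {
      r <- build_archetype(archetype[i], pid[i], pools, cfg, rule_cfg)
      n_noise <- stats::rpois(1L, cfg$noise_rate)
      if (n_noise > 0L) {
        span <- as.integer(cfg$date_range[2] - cfg$date_range[1])
        nd <- cfg$date_range[1] + sample.int(span + 1L, n_noise,
                                             replace = TRUE) - 1L
        nr <- sample_row(NOISE_CODES, n_noise)
        r <- rbind(r, data.frame(patient_id = pid[i],
                                 date = format(nd, "%Y-%m-%d"),
                                 vocabulary = nr$vocabulary, code = nr$code,
                                 stringsAsFactors = FALSE))
      }
      r
    })
    do.call(rbind, per_patient)
  })
  events <- as_coded_events(rows)
  if (!is.null(cfg$dialect_map)) {
    events <- apply_site_dialect(events, cfg$dialect_map)
  }
  true_label <- ifelse(startsWith(archetype, "CASE"), "CASE", "CONTROL")
  gold <- data.frame(patient_id = pid, label = true_label,
                     stringsAsFactors = FALSE)
  inj <- inject_label_errors(gold, cfg$gold_error, seed = cfg$seed + 1L)
  truth <- data.frame(patient_id = pid, archetype = archetype,
                      true_label = true_label,
                      gold_error = NA_character_, stringsAsFactors = FALSE)
  truth$gold_error <- inj$errors$category[match(pid, inj$errors$patient_id)]
  list(events = events, gold = inj$gold, truth = truth)
}

#' Apply a cross-site code-dialect substitution map to events
#'
#' Different institutions can bill the same clinical act under different
#' codes (for instance open chronic rotator cuff repair as CPT 23412 at
#' one site and 23410 at another). This rewrites every event matching a
#' map entry to its substituted (vocabulary, code); non-matching events
#' are untouched. The number of substitutions is attached as attribute
#' `"n_substituted"`.
#'
#' @param events a `coded_events` table.
#' @param dialect_map data.frame with columns `vocabulary`, `code` and
#'   `to_code` (optionally `to_vocabulary`; defaults to the same
#'   vocabulary).
#' @return the rewritten `coded_events` table.
#' @examples
#' \dontrun{
#' remap <- data.frame(vocabulary = "CPT", code = "23412", to_code = "23410")
#' apply_site_dialect(events, remap)
#' }
#' @export
apply_site_dialect <- function(events, dialect_map) {
  dialect_map <- as.data.frame(dialect_map)
  need <- c("vocabulary", "code", "to_code")
  if (!all(need %in% names(dialect_map))) {
    abort_data("dialect_map lacks column(s): ",
               paste(setdiff(need, names(dialect_map)), collapse = ", "))
  }
  if (!"to_vocabulary" %in% names(dialect_map)) {
    dialect_map$to_vocabulary <- dialect_map$vocabulary
  }
  from_voc <- normalize_vocabulary(dialect_map$vocabulary)
  to_voc <- normalize_vocabulary(dialect_map$to_vocabulary)
  if (anyNA(from_voc) || anyNA(to_voc)) {
    abort_data("dialect_map contains unknown vocabularies")
  }
  key <- paste(events$vocabulary, events$code, sep = "|")
  map_key <- paste(from_voc, canonical_code(dialect_map$code), sep = "|")
  if (anyDuplicated(map_key)) abort_data("duplicate dialect_map keys")
  hit <- match(key, map_key)
  sel <- !is.na(hit)
  events$vocabulary[sel] <- to_voc[hit[sel]]
  events$code[sel] <- canonical_code(dialect_map$to_code)[hit[sel]]
  attr(events, "n_substituted") <- sum(sel)
  events
}

#' Corrupt gold-standard labels at configured error rates
#'
#' Emulates gold-standard bookkeeping errors: each patient's label is
#' flipped with per-category probability (conflicting diagnosis,
#' data-entry error, dual diagnosis; mutually exclusive draws).
#' Deterministic for a given seed.
#'
#' @param gold data.frame with `patient_id`, `label`.
#' @param rates named rates over `conflicting_dx`, `data_entry`,
#'   `dual_dx` (a single unnamed rate is split evenly), summing to at
#'   most 1.
#' @param seed integer seed.
#' @return list with `gold` (corrupted copy) and `errors` (data.frame
#'   `patient_id`, `category` — as adjudication-ledger categories —
#'   `original_label`, `corrupted_label`).
#' @export
inject_label_errors <- function(gold, rates, seed = 1L) {
  gold <- as.data.frame(gold)
  if (length(rates) == 1L && is.null(names(rates))) {
    rates <- c(conflicting_dx = rates / 3, data_entry = rates / 3,
               dual_dx = rates / 3)
  }
  known <- c("conflicting_dx", "data_entry", "dual_dx")
  if (!all(names(rates) %in% known)) {
    abort_config("gold error rates must be named among: ",
                 paste(known, collapse = ", "))
  }
  full <- stats::setNames(numeric(length(known)), known)
  full[names(rates)] <- rates
  if (any(full < 0) || sum(full) > 1 + 1e-12) {
    abort_config("gold error rates must be non-negative and sum to at most 1")
  }
  category_map <- c(conflicting_dx = "GOLD_MISLABEL_CONFLICTING_DX",
                    data_entry = "GOLD_MISLABEL_DATA_ENTRY",
                    dual_dx = "DUAL_DIAGNOSIS")
  n <- nrow(gold)
  draw <- with_seed(seed, stats::runif(n))
  cuts <- cumsum(full)
  category <- rep(NA_character_, n)
  category[draw < cuts[1]] <- category_map[["conflicting_dx"]]
  category[draw >= cuts[1] & draw < cuts[2]] <- category_map[["data_entry"]]
  category[draw >= cuts[2] & draw < cuts[3]] <- category_map[["dual_dx"]]
  sel <- !is.na(category)
  corrupted <- gold
  corrupted$label[sel] <- ifelse(gold$label[sel] == "CASE", "CONTROL", "CASE")
  errors <- data.frame(patient_id = gold$patient_id[sel],
                       category = category[sel],
                       original_label = gold$label[sel],
                       corrupted_label = corrupted$label[sel],
                       stringsAsFactors = FALSE)
  list(gold = corrupted, errors = errors)
}

#' Build an adjudication ledger from simulation truth
#'
#' Translates the injected gold-label errors of a synthetic cohort into
#' the adjudication records a chart review would produce: each corrupted
#' patient whose algorithm label disagrees with the corrupted gold
#' becomes an FP or FN ledger row carrying its injected error category.
#' Patients where the algorithm happens to agree with the corrupted gold
#' are not discrepancies and yield no record.
#'
#' @param errors the `errors` table from [inject_label_errors()] (or the
#'   corrupted rows of a [generate_cohort()] truth ledger).
#' @param predictions classification table (`patient_id`, `label`);
#'   INDETERMINATE counts as non-case.
#' @return ledger data.frame (`patient_id`, `initial_cell`, `category`)
#'   suitable for [apply_adjudication()].
#' @export
adjudication_from_truth <- function(errors, predictions) {
  errors <- as.data.frame(errors)
  pred <- predictions$label[match(errors$patient_id, predictions$patient_id)]
  if (anyNA(pred)) {
    abort_data("prediction missing for corrupted patient(s): ",
               paste(errors$patient_id[is.na(pred)], collapse = ", "))
  }
  is_case_pred <- pred == "CASE"
  cell <- ifelse(is_case_pred & errors$corrupted_label == "CONTROL", "FP",
                 ifelse(!is_case_pred & errors$corrupted_label == "CASE",
                        "FN", NA_character_))
  keep <- !is.na(cell)
  data.frame(patient_id = errors$patient_id[keep],
             initial_cell = cell[keep],
             category = errors$category[keep],
             stringsAsFactors = FALSE)
}

#' Write the truth ledger of a synthetic cohort
#'
#' @param truth truth table from [generate_cohort()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, sep = ",") {
  utils::write.table(truth, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
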