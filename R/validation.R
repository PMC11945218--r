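# Validation against a gold standard: confusion matrix, diagnostic
# accuracy metrics, and the adjudication/reclassification workflow for
# gold-label errors found by chart review.

ADJUDICATION_CATEGORIES <- c(
  "TRUE_ALGORITHM_ERROR",          # the algorithm was genuinely wrong
  "GOLD_MISLABEL_CONFLICTING_DX",  # gold label contradicted by imaging
  "GOLD_MISLABEL_DATA_ENTRY",      # research-staff data entry error
  "DUAL_DIAGNOSIS"                 # both target and competing diagnosis
)

# categories that flip the gold label (i.e. the algorithm was right)
GOLD_FLIP_CATEGORIES <- setdiff(ADJUDICATION_CATEGORIES, "TRUE_ALGORITHM_ERROR")

#' Construct a confusion matrix from counts
#'
#' CASE is the positive class throughout: `tp` = algorithm CASE and gold
#' CASE, `fp` = algorithm CASE and gold CONTROL, `fn` = algorithm
#' non-case and gold CASE, `tn` = algorithm non-case and gold CONTROL.
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return a `confusion_matrix` list with the four cells and `total`.
#' @examples
#' confusion_matrix(tp = 420, fp = 11, fn = 26, tn = 35)
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  cells <- vapply(cells, as.integer, integer(1))
  if (anyNA(cells) || any(cells < 0L)) {
    abort_data("confusion matrix cells must be non-negative integers")
  }
  structure(as.list(cells) |> c(list(total = sum(cells))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(c("labeled case", "labeled control"),
                              c("gold case", "gold control")))
  cat(sprintf("<confusion_matrix> n = %d\n", x$total))
  print(m)
  invisible(x)
}

#' Cross-tabulate algorithm labels against a gold standard
#'
#' @param predictions data.frame with `patient_id` and `label`
#'   (CASE / CONTROL / INDETERMINATE), e.g. from [classify_cohort()].
#' @param gold data.frame with `patient_id` and `label` (CASE /
#'   CONTROL); every gold patient must appear in `predictions`.
#' @param indeterminate_policy how to score INDETERMINATE predictions
#'   against the two-class gold: `"as_control"` (default; mirrors the
#'   "any non-case" control notion), `"drop"` (omit those patients), or
#'   `"error"`.
#' @return a `confusion_matrix` with attribute `"n_dropped"`.
#' @export
build_confusion <- function(predictions, gold,
                            indeterminate_policy = c("as_control", "drop", "error")) {
  indeterminate_policy <- match.arg(indeterminate_policy)
  if (anyDuplicated(gold$patient_id)) {
    abort_data("duplicate patient id(s) in gold standard")
  }
  missing_ids <- setdiff(gold$patient_id, predictions$patient_id)
  if (length(missing_ids)) {
    abort_data("gold patient(s) missing from predictions: ",
               paste(missing_ids, collapse = ", "))
  }
  pred <- predictions$label[match(gold$patient_id, predictions$patient_id)]
  gl <- toupper(trimws(gold$label))
  if (!all(gl %in% c("CASE", "CONTROL"))) {
    abort_data("gold labels must be CASE or CONTROL")
  }
  ind <- pred == "INDETERMINATE"
  n_dropped <- 0L
  if (any(ind)) {
    if (indeterminate_policy == "error") {
      abort_data(sum(ind), " INDETERMINATE prediction(s) with policy 'error'")
    }
    if (indeterminate_policy == "drop") {
      n_dropped <- sum(ind)
      pred <- pred[!ind]; gl <- gl[!ind]
    } else {
      pred[ind] <- "CONTROL"
    }
  }
  cm <- confusion_matrix(
    tp = sum(pred == "CASE" & gl == "CASE"),
    fp = sum(pred == "CASE" & gl == "CONTROL"),
    fn = sum(pred != "CASE" & gl == "CASE"),
    tn = sum(pred != "CASE" & gl == "CONTROL")
  )
  attr(cm, "n_dropped") <- n_dropped
  cm
}

#' Diagnostic accuracy metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` and accuracy
#' `(tp+tn)/total` as exact proportions, each also rendered as a
#' half-up-rounded percentage at the requested precision. A zero
#' denominator yields `NA` for that metric.
#'
#' @param cm a `confusion_matrix`.
#' @param percent_digits decimal places for the percentage rendering.
#' @return a `metrics_report`: list with `sensitivity`, `specificity`,
#'   `accuracy` (proportions) and `sensitivity_pct` etc. (percentages).
#' @examples
#' compute_metrics(confusion_matrix(420, 11, 26, 35))
#' @export
compute_metrics <- function(cm, percent_digits = 0) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$total == 0L) abort_data("empty confusion matrix")
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  sens <- ratio(cm$tp, cm$tp + cm$fn)
  spec <- ratio(cm$tn, cm$tn + cm$fp)
  acc  <- ratio(cm$tp + cm$tn, cm$total)
  structure(list(
    sensitivity = sens, specificity = spec, accuracy = acc,
    sensitivity_pct = as_pct(sens, percent_digits),
    specificity_pct = as_pct(spec, percent_digits),
    accuracy_pct    = as_pct(acc, percent_digits),
    percent_digits  = percent_digits
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(p) if (is.na(p)) "n/a" else
    sprintf(paste0("%.", x$percent_digits, "f%%"), p)
  cat("<metrics_report>\n",
      "  sensitivity: ", fmt(x$sensitivity_pct), "\n",
      "  specificity: ", fmt(x$specificity_pct), "\n",
      "  accuracy:    ", fmt(x$accuracy_pct), "\n", sep = "")
  invisible(x)
}

# validate a ledger data.frame
check_ledger <- function(ledger) {
  need <- c("patient_id", "initial_cell", "category")
  if (!all(need %in% names(ledger))) {
    abort_data("adjudication ledger lacks column(s): ",
               paste(setdiff(need, names(ledger)), collapse = ", "))
  }
  ledger$initial_cell <- toupper(trimws(ledger$initial_cell))
  ledger$category <- toupper(trimws(ledger$category))
  if (!all(ledger$initial_cell %in% c("FP", "FN"))) {
    abort_data("ledger initial_cell must be FP or FN")
  }
  if (!all(ledger$category %in% ADJUDICATION_CATEGORIES)) {
    abort_data("unknown ledger category: ",
               paste(setdiff(unique(ledger$category), ADJUDICATION_CATEGORIES),
                     collapse = ", "))
  }
  if (anyDuplicated(ledger$patient_id)) {
    abort_data("duplicate patient id(s) in adjudication ledger")
  }
  ledger
}

#' Apply an adjudication ledger to a confusion matrix
#'
#' Chart review of prediction–gold discrepancies assigns each reviewed
#' FP or FN patient a category. Gold-mislabel categories (conflicting
#' diagnosis, data-entry error, dual diagnosis) mean the algorithm was
#' right and the gold label flips: such FP records move to TP and FN
#' records to TN. `TRUE_ALGORITHM_ERROR` records stay where they are.
#' The total is preserved. A ledger citing more records in a cell than
#' the matrix holds is rejected, which also makes re-applying a consumed
#' ledger an error rather than a silent double count.
#'
#' @param cm a `confusion_matrix` (pre-adjudication).
#' @param ledger data.frame with columns `patient_id`, `initial_cell`
#'   (`FP`/`FN`) and `category` (see `ADJUDICATION_CATEGORIES`).
#' @param gold optional gold-label data.frame (`patient_id`, `label`);
#'   when given, flipped patients' labels are corrected in the returned
#'   copy.
#' @return list with `cm` (corrected `confusion_matrix`), `gold`
#'   (corrected gold or `NULL`) and `n_flipped` per cell.
#' @examples
#' cm <- confusion_matrix(371, 60, 34, 27)
#' led <- data.frame(
#'   patient_id = paste0("D", 1:57),
#'   initial_cell = rep(c("FP", "FN"), c(49, 8)),
#'   category = "GOLD_MISLABEL_CONFLICTING_DX")
#' apply_adjudication(cm, led)$cm
#' @export
apply_adjudication <- function(cm, ledger, gold = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ledger <- check_ledger(as.data.frame(ledger))
  n_cell <- c(FP = sum(ledger$initial_cell == "FP"),
              FN = sum(ledger$initial_cell == "FN"))
  if (n_cell[["FP"]] > cm$fp || n_cell[["FN"]] > cm$fn) {
    abort_data("ledger cites more FP/FN records (", n_cell[["FP"]], "/",
               n_cell[["FN"]], ") than the matrix holds (", cm$fp, "/",
               cm$fn, "); has it already been applied?")
  }
  flip <- ledger$category %in% GOLD_FLIP_CATEGORIES
  fp_flips <- sum(flip & ledger$initial_cell == "FP")
  fn_flips <- sum(flip & ledger$initial_cell == "FN")
  corrected <- confusion_matrix(tp = cm$tp + fp_flips,
                                fp = cm$fp - fp_flips,
                                fn = cm$fn - fn_flips,
                                tn = cm$tn + fn_flips)
  corrected_gold <- NULL
  if (!is.null(gold)) {
    corrected_gold <- as.data.frame(gold)
    flipped_ids <- ledger$patient_id[flip]
    sel <- corrected_gold$patient_id %in% flipped_ids
    corrected_gold$label[sel] <-
      ifelse(toupper(corrected_gold$label[sel]) == "CASE", "CONTROL", "CASE")
  }
  list(cm = corrected, gold = corrected_gold,
       n_flipped = c(FP = fp_flips, FN = fn_flips))
}

#' Summarize prediction–gold discrepancies and their adjudicated causes
#'
#' @param cm the pre-adjudication `confusion_matrix`.
#' @param ledger adjudication ledger (see [apply_adjudication()]); may
#'   cover only part of the discrepancies.
#' @return a `discrepancy_report`: list with `n_discrepancies`
#'   (`fp + fn`), per-cell counts, a cell-by-category table, pooled
#'   per-category totals, and the review shares
#'   `fp_true_error_pct` (truly-false share of FPs),
#'   `fn_true_error_pct` (truly-missed share of FNs) and
#'   `fp_mislabel_conflicting_pct` (conflicting-diagnosis share among
#'   FP gold mislabels), each `NA` when its denominator is zero.
#' @export
discrepancy_report <- function(cm, ledger) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ledger <- check_ledger(as.data.frame(ledger))
  n_cell <- c(FP = sum(ledger$initial_cell == "FP"),
              FN = sum(ledger$initial_cell == "FN"))
  if (n_cell[["FP"]] > cm$fp || n_cell[["FN"]] > cm$fn) {
    abort_data("ledger inconsistent with matrix: cites more FP/FN records ",
               "than the matrix holds")
  }
  tab <- table(factor(ledger$initial_cell, levels = c("FP", "FN")),
               factor(ledger$category, levels = ADJUDICATION_CATEGORIES))
  by_category <- colSums(tab)
  fp_mislabels <- sum(tab["FP", GOLD_FLIP_CATEGORIES])
  share <- function(num, den) if (den == 0) NA_real_ else as_pct(num / den, 1)
  structure(list(
    n_discrepancies = cm$fp + cm$fn,
    n_fp = cm$fp, n_fn = cm$fn,
    by_cell_category = tab,
    by_category = by_category,
    fp_true_error_pct = share(tab["FP", "TRUE_ALGORITHM_ERROR"], cm$fp),
    fn_true_error_pct = share(tab["FN", "TRUE_ALGORITHM_ERROR"], cm$fn),
    fp_mislabel_conflicting_pct =
      share(tab["FP", "GOLD_MISLABEL_CONFLICTING_DX"], fp_mislabels)
  ), class = "discrepancy_report")
}

#' @export
print.discrepancy_report <- function(x, ...) {
  cat(sprintf("<discrepancy_report> %d discrepancies (%d FP, %d FN)\n",
              x$n_discrepancies, x$n_fp, x$n_fn))
  print(x$by_cell_category)
  invisible(x)
}

#' Read / write gold-standard label tables
#'
#' Delimited text with columns `patient_id,label` (CASE / CONTROL).
#'
#' @param path file path.
#' @param sep field separator.
#' @return `read_gold()`: data.frame with `patient_id`, `label`.
#' @export
read_gold <- function(path, sep = ",") {
  if (!file.exists(path)) abort_data("gold file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("patient_id", "label")
  if (!all(need %in% names(df))) {
    abort_data("gold file lacks column(s): ",
               paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$label <- toupper(trimws(df$label))
  if (!all(df$label %in% c("CASE", "CONTROL"))) {
    abort_data("gold labels must be CASE or CONTROL")
  }
  df
}

#' @rdname read_gold
#' @param gold data.frame with `patient_id`, `label`.
#' @export
write_gold <- function(gold, path, sep = ",") {
  utils::write.table(gold[, c("patient_id", "label")], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an adjudication ledger file
#'
#' Delimited text with columns `patient_id,initial_cell,category`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return validated ledger data.frame.
#' @export
read_ledger <- function(path, sep = ",") {
  if (!file.exists(path)) abort_data("ledger file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", stringsAsFactors = FALSE)
  check_ledger(df)
}
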