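# Coded-event ingestion: normalization, reading, writing, per-patient
# chronologies. An event table is a plain data.frame with columns
# patient_id, event_date (Date), vocabulary, code, source_row, carrying
# class "coded_events".

VOCABULARIES <- c("CPT", "ICD9CM", "ICD10CM")

# case-insensitive aliases accepted on input
.vocab_aliases <- c(
  "CPT"      = "CPT",   "HCPCS-CPT" = "CPT",
  "ICD9CM"   = "ICD9CM",  "ICD9"   = "ICD9CM",  "ICD-9"     = "ICD9CM",
  "ICD-9-CM" = "ICD9CM",  "ICD_9"  = "ICD9CM",  "ICD9-CM"   = "ICD9CM",
  "ICD10CM"  = "ICD10CM", "ICD10"  = "ICD10CM", "ICD-10"    = "ICD10CM",
  "ICD-10-CM" = "ICD10CM", "ICD_10" = "ICD10CM", "ICD10-CM" = "ICD10CM"
)

# vectorized; NA for unknown vocabularies
normalize_vocabulary <- function(x) {
  unname(.vocab_aliases[toupper(trimws(as.character(x)))])
}

canonical_code <- function(x) toupper(trimws(as.character(x)))

strip_dots <- function(x) gsub(".", "", x, fixed = TRUE)

#' Normalize a vocabulary name and raw code
#'
#' Canonicalizes a coded-event pair: the vocabulary is resolved against
#' case-insensitive aliases of CPT / ICD9CM / ICD10CM, the code is trimmed
#' and upper-cased. Internal dots are preserved; dot-insensitive matching
#' is a choice made at lookup time (see [rule_config()]), not at
#' normalization time.
#'
#' @param vocabulary character scalar naming the coding system
#'   (e.g. `"cpt"`, `"ICD-10-CM"`).
#' @param raw_code character scalar, the code as extracted.
#' @return list with elements `vocabulary` (one of `"CPT"`, `"ICD9CM"`,
#'   `"ICD10CM"`) and `code` (canonical form).
#' @examples
#' normalize_code("icd10cm", " m75.101 ")
#' @export
normalize_code <- function(vocabulary, raw_code) {
  voc <- normalize_vocabulary(vocabulary)
  if (length(voc) != 1L || is.na(voc)) {
    abort_data("unknown vocabulary: '", as.character(vocabulary)[1], "'")
  }
  code <- canonical_code(raw_code)
  if (!nzchar(code)) abort_data("empty code for vocabulary ", voc)
  list(vocabulary = voc, code = code)
}

# strict ISO date parsing: NA unless YYYY-MM-DD and a real calendar day
parse_iso_date <- function(x) {
  x <- trimws(as.character(x))
  d <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  # as.Date() rolls over some impossible dates on certain platforms;
  # round-trip to be sure
  bad <- ok & (is.na(d) | format(d, "%Y-%m-%d") != x)
  d[bad] <- NA
  d
}

new_coded_events <- function(df, report = NULL) {
  rownames(df) <- NULL
  structure(df, class = c("coded_events", "data.frame"), report = report)
}

#' Build a normalized coded-event table from an in-memory data frame
#'
#' Applies the same normalization and sorting as [read_events()] but to a
#' data frame already in memory (as produced, e.g., by
#' [generate_cohort()]). Rows with an unknown vocabulary, an invalid
#' date, an empty code or an empty patient id are dropped and recorded in
#' the attached read report.
#'
#' @param df data.frame with columns `patient_id`, `date` (or
#'   `event_date`), `vocabulary`, `code`.
#' @return a `coded_events` data.frame sorted by patient, date and source
#'   row, with a `report` attribute (`rows_read`, `rows_rejected`,
#'   `rejects`).
#' @export
as_coded_events <- function(df) {
  df <- as.data.frame(df)
  if (!"date" %in% names(df) && "event_date" %in% names(df)) {
    names(df)[names(df) == "event_date"] <- "date"
  }
  need <- c("patient_id", "date", "vocabulary", "code")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_data("event table lacks column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  n <- nrow(df)
  pid  <- trimws(as.character(df$patient_id))
  voc  <- normalize_vocabulary(df$vocabulary)
  code <- canonical_code(df$code)
  date <- if (inherits(df$date, "Date")) df$date else parse_iso_date(df$date)

  reason <- rep(NA_character_, n)
  reason[is.na(voc)]                      <- "unknown vocabulary"
  reason[is.na(date)]                     <- "invalid date"
  reason[!nzchar(code) | is.na(df$code)]  <- "empty code"
  reason[!nzchar(pid)]                    <- "empty patient id"
  keep <- is.na(reason)

  out <- data.frame(
    patient_id = pid[keep],
    event_date = date[keep],
    vocabulary = voc[keep],
    code       = code[keep],
    source_row = seq_len(n)[keep],
    stringsAsFactors = FALSE
  )
  ord <- order(out$patient_id, out$event_date, out$source_row)
  out <- out[ord, , drop = FALSE]
  rejects <- data.frame(
    source_row = seq_len(n)[!keep],
    reason     = reason[!keep],
    stringsAsFactors = FALSE
  )
  report <- list(rows_read = n, rows_kept = nrow(out),
                 rows_rejected = nrow(rejects), rejects = rejects)
  new_coded_events(out, report)
}

#' Read a delimited coded-event file
#'
#' Reads longitudinal coded-event data (one row per billed or recorded
#' code) and returns a normalized, per-patient-sorted event table.
#' Malformed rows are rejected individually and listed in the read
#' report; a missing file is a fatal error.
#'
#' @param path path to a delimited text file with header columns
#'   `patient_id,date,vocabulary,code` (extra columns are ignored).
#'   Dates must be ISO-8601 `YYYY-MM-DD`.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @param col_map named character vector remapping the expected column
#'   names onto the file's headers, e.g.
#'   `c(patient_id = "mrn", date = "svc_date")`.
#' @return a `coded_events` data.frame (columns `patient_id`,
#'   `event_date`, `vocabulary`, `code`, `source_row`) sorted by patient
#'   id, date and source row. The read report is attached as attribute
#'   `report` and retrievable with [read_report()].
#' @seealso [write_events()], [as_coded_events()]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("patient_id,date,vocabulary,code",
#'              "P1,2020-06-01,CPT,29827",
#'              "P1,2020-01-01,ICD10CM,M75.101"), f)
#' ev <- read_events(f)
#' ev$event_date  # sorted ascending
#' @export
read_events <- function(path, sep = ",", col_map = NULL) {
  if (!file.exists(path)) abort_data("event file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", comment.char = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(raw)) {
        abort_data("mapped column '", col_map[[std]], "' absent from ", path)
      }
      names(raw)[names(raw) == col_map[[std]]] <- std
    }
  }
  need <- c("patient_id", "date", "vocabulary", "code")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort_data("event file ", path, " lacks column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  as_coded_events(raw[, need, drop = FALSE])
}

#' Retrieve the read report attached to an event table
#'
#' @param events a `coded_events` object.
#' @return list with `rows_read`, `rows_kept`, `rows_rejected` and a
#'   `rejects` data.frame (source row and reason), or `NULL`.
#' @export
read_report <- function(events) attr(events, "report", exact = TRUE)

#' Write a coded-event table back to delimited text
#'
#' Writes the four canonical columns (`patient_id,date,vocabulary,code`)
#' so that [read_events()] round-trips the normalized content.
#'
#' @param events a `coded_events` data.frame.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, sep = ",") {
  out <- data.frame(
    patient_id = events$patient_id,
    date       = format(events$event_date, "%Y-%m-%d"),
    vocabulary = events$vocabulary,
    code       = events$code,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split an event table into per-patient records
#'
#' @param events a `coded_events` data.frame.
#' @return named list of `coded_events`, one per patient id, each sorted
#'   chronologically.
#' @export
patient_records <- function(events) {
  if (nrow(events) == 0L) return(structure(list(), names = character()))
  split(as.data.frame(events), events$patient_id, drop = TRUE)
}

#' @export
print.coded_events <- function(x, ...) {
  rep <- read_report(x)
  cat(sprintf("<coded_events> %d events, %d patients\n",
              nrow(x), length(unique(x$patient_id))))
  if (!is.null(rep)) {
    cat(sprintf("  read report: %d rows read, %d rejected\n",
                rep$rows_read, rep$rows_rejected))
  }
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}
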