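# Code dictionary: (vocabulary, code) -> variable groups, with per-site
# provenance. The packaged default reproduces the phenotype's published
# data dictionary verbatim (see inst/extdata/rct_dictionary_errata.md for
# its documented quirks).

SITE_FLAGS <- c("UTSW_ONLY", "VUMC_ONLY", "SHARED")

# closed set of group labels used by the rule definitions / dictionary
KNOWN_GROUPS <- c(
  "rct_cpt_surg_spec_include",
  "rct_cpt_surg_nonspec_include",
  "rct_cpt_surg_exclude",
  "rct_cpt_image_include",
  "rct_icd9_diag_include",
  "rct_icd9_nontraum",
  "rct_icd9_exclusions",
  "rct_icd9_image_include",
  "rct_icd10_diag_include",
  "rct_icd10_exclusions",
  "rct_icd10_image_include"
)

# Lower-cases and resolves the exclude/exclusions spelling split: the
# dictionary spells the ICD-10 exclusion group "rct_icd10_exclude" while
# the rule definitions spell it "rct_icd10_exclusions".
canonical_group <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x == "rct_icd10_exclude"] <- "rct_icd10_exclusions"
  x
}

#' Path to the packaged rotator cuff tear code dictionary
#'
#' @return file path of the CSV shipped with the package.
#' @export
phenocuff_dictionary_file <- function() {
  system.file("extdata", "rct_dictionary.csv", package = "phenocuff",
              mustWork = TRUE)
}

.yesno <- function(x) tolower(trimws(as.character(x))) %in% c("yes", "y", "true", "1")

#' Load a code dictionary
#'
#' Reads a delimited dictionary file (columns
#' `variable_name,vocabulary,code,description,utsw_only,vumc_only,shared`,
#' provenance columns yes/no) into an indexed `code_dictionary`. Group
#' labels are canonicalized to lower case (and the `rct_icd10_exclude` /
#' `rct_icd10_exclusions` spelling split resolved); duplicate
#' (variable, vocabulary, code) rows are collapsed with a warning; labels
#' outside the known set raise a warning but load. A row flagged for more
#' than one provenance column, or none, is a load error.
#'
#' @param path dictionary file path; defaults to the packaged dictionary.
#' @param sep field separator.
#' @return a `code_dictionary`: list with `entries` (data.frame of
#'   `variable_name`, `vocabulary`, `code`, `description`, `site_flags`)
#'   and internal lookup indexes (exact and dot-stripped).
#' @examples
#' dict <- load_dictionary()
#' groups_for(dict, "CPT", "29827")
#' @export
load_dictionary <- function(path = phenocuff_dictionary_file(), sep = ",") {
  if (!file.exists(path)) abort_data("dictionary file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", comment.char = "",
                           stringsAsFactors = FALSE)
  need <- c("variable_name", "vocabulary", "code", "description",
            "utsw_only", "vumc_only", "shared")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort_data("dictionary lacks column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warning("dictionary file has a header but no rows; empty dictionary")
    entries <- data.frame(variable_name = character(), vocabulary = character(),
                          code = character(), description = character(),
                          site_flags = character(), stringsAsFactors = FALSE)
    return(new_code_dictionary(entries))
  }

  voc <- normalize_vocabulary(raw$vocabulary)
  if (anyNA(voc)) {
    abort_data("dictionary row(s) with unknown vocabulary: ",
               paste(which(is.na(voc)), collapse = ", "))
  }
  flags <- cbind(.yesno(raw$utsw_only), .yesno(raw$vumc_only), .yesno(raw$shared))
  nyes <- rowSums(flags)
  if (any(nyes != 1L)) {
    bad <- which(nyes != 1L)
    abort_data("dictionary row(s) with contradictory or absent provenance ",
               "flags (exactly one of utsw_only/vumc_only/shared must be ",
               "yes): row ", paste(bad, collapse = ", "))
  }
  site_flags <- SITE_FLAGS[max.col(flags)]

  entries <- data.frame(
    variable_name = canonical_group(raw$variable_name),
    vocabulary    = voc,
    code          = canonical_code(raw$code),
    description   = raw$description,
    site_flags    = site_flags,
    stringsAsFactors = FALSE
  )

  unknown <- setdiff(unique(entries$variable_name), KNOWN_GROUPS)
  if (length(unknown)) {
    warning("dictionary contains group label(s) outside the known set: ",
            paste(unknown, collapse = ", "))
  }

  key <- paste(entries$variable_name, entries$vocabulary, entries$code)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    warning("collapsing ", sum(duplicated(key)),
            " duplicate dictionary row(s): ", paste(dup, collapse = "; "))
    entries <- entries[!duplicated(key), , drop = FALSE]
  }
  rownames(entries) <- NULL
  new_code_dictionary(entries)
}

new_code_dictionary <- function(entries) {
  index       <- split(entries$variable_name,
                       paste(entries$vocabulary, entries$code, sep = "|"))
  index_nodot <- split(entries$variable_name,
                       paste(entries$vocabulary, strip_dots(entries$code), sep = "|"))
  structure(
    list(entries = entries,
         index = lapply(index, unique),
         index_nodot = lapply(index_nodot, unique)),
    class = "code_dictionary"
  )
}

#' Variable groups a code belongs to
#'
#' Pure lookup: returns the (possibly empty) set of group labels the
#' dictionary assigns to a (vocabulary, code) pair. With
#' `dot_insensitive = TRUE` the comparison ignores internal dots on both
#' sides, accommodating EHR extracts that strip them from ICD codes.
#'
#' @param dict a `code_dictionary`.
#' @param vocabulary vocabulary name (aliases accepted).
#' @param code code string (canonicalized internally).
#' @param dot_insensitive logical; match after stripping dots.
#' @return character vector of group labels (empty if unknown code).
#' @export
groups_for <- function(dict, vocabulary, code, dot_insensitive = FALSE) {
  stopifnot(inherits(dict, "code_dictionary"))
  voc <- normalize_vocabulary(vocabulary)
  if (is.na(voc)) abort_data("unknown vocabulary: '", vocabulary, "'")
  code <- canonical_code(code)
  if (dot_insensitive) {
    dict$index_nodot[[paste(voc, strip_dots(code), sep = "|")]] %||% character()
  } else {
    dict$index[[paste(voc, code, sep = "|")]] %||% character()
  }
}

# all canonical "VOC|CODE" keys belonging to a set of groups
group_keys <- function(dict, groups, dot_insensitive = FALSE) {
  e <- dict$entries[dict$entries$variable_name %in% groups, , drop = FALSE]
  code <- if (dot_insensitive) strip_dots(e$code) else e$code
  unique(paste(e$vocabulary, code, sep = "|"))
}

#' Per-site provenance summary of a dictionary
#'
#' Tallies dictionary entries by provenance flag — codes used only at the
#' implementing site (UTSW), only at the originating site (VUMC), or
#' shared — and expresses each as a percentage of all entries (one
#' decimal). With an empty dictionary the counts are zero and the
#' percentages `NA`.
#'
#' @param dict a `code_dictionary`.
#' @return data.frame with columns `site_flags`, `n`, `percent`.
#' @examples
#' site_overlap_summary(load_dictionary())
#' @export
site_overlap_summary <- function(dict) {
  stopifnot(inherits(dict, "code_dictionary"))
  n <- vapply(SITE_FLAGS, function(f) sum(dict$entries$site_flags == f),
              integer(1))
  total <- sum(n)
  percent <- if (total == 0L) rep(NA_real_, length(n)) else as_pct(n / total, 1)
  data.frame(site_flags = SITE_FLAGS, n = unname(n), percent = unname(percent),
             stringsAsFactors = FALSE)
}

#' @export
print.code_dictionary <- function(x, ...) {
  cat(sprintf("<code_dictionary> %d entries, %d groups, %d distinct codes\n",
              nrow(x$entries), length(unique(x$entries$variable_name)),
              length(x$index)))
  s <- site_overlap_summary(x)
  cat(sprintf("  %s: %d (%.1f%%)\n", s$site_flags, s$n, s$percent), sep = "")
  invisible(x)
}
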