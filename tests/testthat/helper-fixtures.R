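# Shared fixtures: the packaged dictionary (loaded once; its duplicate
# rows warn by contract) and small file-writing helpers.

test_dict <- suppressWarnings(load_dictionary())

# single-patient record from parallel vectors
make_record <- function(codes, dates, vocabularies, patient_id = "P1") {
  n <- max(length(codes), length(dates), length(vocabularies))
  as_coded_events(data.frame(
    patient_id = rep_len(patient_id, n),
    date = rep_len(dates, n),
    vocabulary = rep_len(vocabularies, n),
    code = rep_len(codes, n),
    stringsAsFactors = FALSE
  ))
}

write_event_file <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("patient_id,date,vocabulary,code", lines), path)
  path
}

# minimal dictionary file with controllable provenance flags
write_toy_dictionary <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("variable_name,vocabulary,code,description,utsw_only,vumc_only,shared",
               rows), path)
  path
}

paper_initial_cm <- function() confusion_matrix(tp = 371, fp = 60, fn = 34, tn = 27)

# the chart review's adjudication ledger, one row per reviewed record
paper_ledger <- function() {
  data.frame(
    patient_id = sprintf("D%03d", seq_len(94)),
    initial_cell = rep(c("FP", "FN"), c(60, 34)),
    category = c(rep("GOLD_MISLABEL_CONFLICTING_DX", 42),
                 rep("GOLD_MISLABEL_DATA_ENTRY", 6),
                 rep("DUAL_DIAGNOSIS", 1),
                 rep("TRUE_ALGORITHM_ERROR", 11),
                 rep("GOLD_MISLABEL_CONFLICTING_DX", 2),
                 rep("GOLD_MISLABEL_DATA_ENTRY", 6),
                 rep("TRUE_ALGORITHM_ERROR", 26)),
    stringsAsFactors = FALSE
  )
}
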