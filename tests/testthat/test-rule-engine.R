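cfg <- rule_config()

test_that("within_window implements the inclusive 365-day follow-up", {
  a <- as.Date("2020-01-01")
  expect_true(within_window(a, as.Date("2020-12-31"), cfg))   # 365 days
  expect_false(within_window(a, as.Date("2021-01-02"), cfg))  # 367 days
  expect_false(within_window(a, a - 1, cfg))                  # before anchor
  expect_true(within_window(a, a, cfg))                       # same day
  expect_false(within_window(a, a,
                             rule_config(window_includes_anchor_day = FALSE)))
})

test_that("exclusion-after predicate honours strictness and direction", {
  anchor <- as.Date("2020-05-01")
  rec_after <- make_record(c("73221", "S43.421A"),
                           c("2020-05-01", "2020-05-11"), c("CPT", "ICD10CM"))
  rec_before <- make_record(c("73221", "S43.421A"),
                            c("2020-05-01", "2020-04-21"), c("CPT", "ICD10CM"))
  rec_none <- make_record("73221", "2020-05-01", "CPT")
  expect_true(has_exclusion_after(rec_after, test_dict, anchor, cfg))
  expect_false(has_exclusion_after(rec_before, test_dict, anchor, cfg))
  expect_false(has_exclusion_after(rec_none, test_dict, anchor, cfg))
  # same-day exclusion only vetoes under non-strict "after"
  same_day <- make_record(c("73221", "840.4"),
                          c("2020-05-01", "2020-05-01"), c("CPT", "ICD9CM"))
  expect_false(has_exclusion_after(same_day, test_dict, anchor, cfg))
  expect_true(has_exclusion_after(same_day, test_dict, anchor,
                                  rule_config(exclusion_after_is_strict = FALSE)))
})

test_that("definition 1 fires on specific surgery with earliest-date dx", {
  one <- make_record("29827", "2019-03-04", "CPT")
  expect_equal(case_def_1(one, test_dict)$dx_date, as.Date("2019-03-04"))
  two <- make_record(c("23412", "23420"), c("2020-05-05", "2018-02-02"), "CPT")
  expect_equal(case_def_1(two, test_dict)$dx_date, as.Date("2018-02-02"))
  diag_only <- make_record("M75.101", "2020-01-01", "ICD10CM")
  expect_null(case_def_1(diag_only, test_dict))
})

test_that("definition 2 needs a diagnosis within the window after surgery", {
  hit <- make_record(c("29823", "M75.102"), c("2020-01-10", "2020-04-01"),
                     c("CPT", "ICD10CM"))
  h <- case_def_2(hit, test_dict)
  expect_equal(h$dx_date, as.Date("2020-01-10"))
  late <- make_record(c("29823", "M75.102"), c("2020-01-10", "2021-06-01"),
                      c("CPT", "ICD10CM"))
  expect_null(case_def_2(late, test_dict))
  expect_null(case_def_2(make_record("M75.102", "2020-01-10", "ICD10CM"),
                         test_dict))
})

test_that("definition 3 anchors on imaging and is vetoed by later exclusions", {
  base <- make_record(c("73221", "M75.111"), c("2020-02-01", "2020-03-15"),
                      c("CPT", "ICD10CM"))
  expect_equal(case_def_3(base, test_dict)$dx_date, as.Date("2020-02-01"))
  vetoed <- make_record(c("73221", "M75.111", "S46.021A"),
                        c("2020-02-01", "2020-03-15", "2020-06-01"),
                        c("CPT", "ICD10CM", "ICD10CM"))
  expect_null(case_def_3(vetoed, test_dict))
  no_diag <- make_record("73221", "2020-02-01", "CPT")
  expect_null(case_def_3(no_diag, test_dict))
  # ICD-10 imaging anchors only under the configured extension
  icd10_img <- make_record(c("BP3FYZZ", "M75.111"),
                           c("2020-02-01", "2020-03-15"), "ICD10CM")
  expect_null(case_def_3(icd10_img, test_dict))
  expect_equal(case_def_3(icd10_img, test_dict,
                          rule_config(case3_icd10_imaging = TRUE))$dx_date,
               as.Date("2020-02-01"))
})

test_that("definition 4a counts unique visit dates pooled across vocabularies", {
  three <- make_record("M75.101", c("2020-01-01", "2020-02-01", "2020-03-01"),
                       "ICD10CM")
  expect_equal(case_def_4a(three, test_dict)$dx_date, as.Date("2020-03-01"))
  same_day <- make_record("M75.101", rep("2020-01-01", 3), "ICD10CM")
  expect_null(case_def_4a(same_day, test_dict))
  pooled <- make_record(c("M75.101", "M75.101", "726.13"),
                        c("2020-01-01", "2020-02-01", "2020-03-01"),
                        c("ICD10CM", "ICD10CM", "ICD9CM"))
  h <- case_def_4a(pooled, test_dict)
  expect_equal(h$dx_date, as.Date("2020-03-01"))
  # exclusion after the first qualifying visit vetoes
  excl <- make_record(c("M75.101", "M75.101", "M75.101", "M12.511"),
                      c("2020-01-01", "2020-02-01", "2020-03-01", "2020-01-15"),
                      c(rep("ICD10CM", 4)))
  expect_null(case_def_4a(excl, test_dict))
})

test_that("definition 4b counts mentions within one vocabulary only", {
  four <- make_record("M75.100", c("2020-01-01", "2020-01-01",
                                   "2020-02-01", "2020-02-01"), "ICD10CM")
  h <- case_def_4b(four, test_dict)
  expect_equal(h$dx_date, as.Date("2020-02-01"))
  split_vocab <- make_record(c("726.13", "727.61", "M75.100", "M75.101"),
                             c("2020-01-01", "2020-02-01", "2020-03-01",
                               "2020-04-01"),
                             c("ICD9CM", "ICD9CM", "ICD10CM", "ICD10CM"))
  expect_null(case_def_4b(split_vocab, test_dict))
  after_excl <- make_record(c(rep("M75.100", 4), "M12.511"),
                            c("2020-01-01", "2020-01-02", "2020-01-03",
                              "2020-01-04", "2020-06-01"), "ICD10CM")
  expect_null(case_def_4b(after_excl, test_dict))
})

test_that("control definitions honour case precedence and imaging confirmation", {
  imaging_only <- make_record("73221", "2020-01-01", "CPT")
  ids <- vapply(control_defs(imaging_only, test_dict), `[[`, character(1),
                "definition_id")
  expect_setequal(ids, c("CONTROL_1", "CONTROL_2"))
  # diagnosis mention present but no case met: broad control only
  img_diag <- make_record(c("73221", "M75.101"), c("2020-06-01", "2020-01-01"),
                          c("CPT", "ICD10CM"))
  expect_equal(classify(img_diag, test_dict)$label, "INDETERMINATE")
  ids <- vapply(control_defs(img_diag, test_dict), `[[`, character(1),
                "definition_id")
  expect_equal(ids, "CONTROL_1")
  case_rec <- make_record("29827", "2020-01-01", "CPT")
  expect_length(control_defs(case_rec, test_dict), 0L)
})

test_that("classify assigns three-way labels and earliest dx date", {
  empty <- make_record(character(), character(), character())
  expect_equal(classify(empty, test_dict)$label, "INDETERMINATE")
  expect_equal(classify(empty, test_dict,
                        rule_config(control_mode = "broad"))$label, "CONTROL")
  # two definitions met: final dx is the earliest over them
  multi <- make_record(c("29823", "M75.102", "M75.102", "M75.102"),
                       c("2020-01-10", "2020-02-01", "2020-03-01", "2020-04-01"),
                       c("CPT", rep("ICD10CM", 3)))
  res <- classify(multi, test_dict)
  expect_equal(res$label, "CASE")
  defs <- vapply(res$hits, `[[`, character(1), "definition_id")
  expect_true(all(c("CASE_2", "CASE_4A") %in% defs))
  expect_equal(res$final_dx_date, as.Date("2020-01-10"))
  imaging_only <- make_record("73221", "2020-01-01", "CPT")
  expect_equal(classify(imaging_only, test_dict)$label, "CONTROL")
  expect_equal(classify(imaging_only, test_dict,
                        rule_config(control_mode = "broad"))$label, "CONTROL")
})

test_that("classify_cohort is deterministic, one row per patient", {
  f <- write_event_file(c("A,2019-03-04,CPT,29827",
                          "B,2020-01-01,CPT,73221",
                          "C,2020-01-01,ICD10CM,M75.101"))
  ev <- read_events(f)
  r1 <- classify_cohort(ev, test_dict)
  r2 <- classify_cohort(ev, test_dict)
  expect_identical(r1, r2)
  expect_equal(sort(r1$label), c("CASE", "CONTROL", "INDETERMINATE"))
  expect_equal(nrow(classify_cohort(ev[0, ], test_dict)), 0L)
  recs <- patient_records(ev)
  expect_error(classify_cohort(c(recs, recs["A"]), test_dict), "duplicate")
})

test_that("irrelevant codes never alter labels (noise invariance)", {
  base <- make_record(c("73221", "M75.111"), c("2020-02-01", "2020-03-15"),
                      c("CPT", "ICD10CM"))
  noisy <- make_record(c("73221", "M75.111", "99213", "E11.9"),
                       c("2020-02-01", "2020-03-15", "2020-02-10", "2021-05-01"),
                       c("CPT", "ICD10CM", "CPT", "ICD10CM"))
  b <- classify(base, test_dict); nz <- classify(noisy, test_dict)
  expect_equal(nz$label, b$label)
  expect_equal(nz$final_dx_date, b$final_dx_date)
})

test_that("adding case-qualifying evidence never demotes a CASE", {
  set.seed(42)
  add_pool <- data.frame(
    vocabulary = c("CPT", "CPT", "ICD10CM", "ICD9CM"),
    code = c("29827", "29823", "M75.101", "726.13"),
    stringsAsFactors = FALSE)
  base <- make_record(c("29823", "M75.102"), c("2020-01-10", "2020-04-01"),
                      c("CPT", "ICD10CM"))
  for (i in 1:25) {
    extra <- add_pool[sample.int(nrow(add_pool), 1), ]
    d <- as.Date("2019-06-01") + sample.int(700, 1)
    aug <- make_record(c(base$code, extra$code),
                       c(format(base$event_date), format(d)),
                       c(base$vocabulary, extra$vocabulary))
    expect_equal(classify(aug, test_dict)$label, "CASE")
  }
})

test_that("translating all dates shifts dx dates and preserves labels", {
  recs <- list(
    make_record(c("29823", "M75.102"), c("2020-01-10", "2020-04-01"),
                c("CPT", "ICD10CM")),
    make_record("M75.101", c("2020-01-01", "2020-02-01", "2020-03-01"),
                "ICD10CM"),
    make_record("73221", "2020-01-01", "CPT"),
    make_record(c("73221", "M75.111", "S46.021A"),
                c("2020-02-01", "2020-03-15", "2020-06-01"),
                c("CPT", "ICD10CM", "ICD10CM")))
  for (shift in c(-400L, 37L, 1000L)) {
    for (rec in recs) {
      shifted <- rec
      shifted$event_date <- shifted$event_date + shift
      a <- classify(rec, test_dict); b <- classify(shifted, test_dict)
      expect_equal(b$label, a$label)
      if (!is.null(a$final_dx_date)) {
        expect_equal(b$final_dx_date, a$final_dx_date + shift)
      }
    }
  }
})

test_that("configuration is validated and readable from JSON", {
  expect_error(rule_config(window_days = 0), "positive")
  expect_error(rule_config(min_mentions_4b = 0), "positive")
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(window_days = 180, control_mode = "broad"), f,
                       auto_unbox = TRUE)
  rc <- read_rule_config(f)
  expect_equal(rc$window_days, 180L)
  expect_equal(rc$control_mode, "broad")
  jsonlite::write_json(list(window = 1), f, auto_unbox = TRUE)
  expect_error(read_rule_config(f), "unknown config field")
})
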