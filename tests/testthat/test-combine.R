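test_that("length partitions are total with the documented boundaries", {
  opts <- combine_opts()
  lens <- c(99, 100, 350, 351, 600, 601, 2000, 2001)
  expect_equal(partition_by_length(lens, opts),
               c("too_short", "P1", "P1", "P2", "P2", "P3", "P3", "too_long"))
  # per-partition blast thresholds
  p <- opts$partitions
  expect_equal(p$min_id, c(75, 80, 86))
  expect_equal(p$min_coverage, c(0.80, 0.86, 0.86))
})

test_that("outcome classes are the four combinations of the two pass bits", {
  expect_equal(outcome_class(TRUE, TRUE), "RPSP")
  expect_equal(outcome_class(TRUE, FALSE), "RPSF")
  expect_equal(outcome_class(FALSE, TRUE), "RFSP")
  expect_equal(outcome_class(FALSE, FALSE), "RFSF")
  grid <- expand.grid(rt = c(TRUE, FALSE), s = c(TRUE, FALSE))
  expect_setequal(outcome_class(grid$rt, grid$s), OUTCOME_CLASSES)
})

test_that("every engine error name maps to exactly one GenBank-style error", {
  all_errors <- c(SENSOR_ERRORS,
                  paste0("R_", c("NoHits", "MultipleFamilies", "LowScore",
                                 "BothStrands", "InconsistentHits",
                                 "DuplicateRegion", "UnacceptableModel",
                                 "LowCoverage", "QuestionableModel",
                                 "MultipleHits")))
  for (err in all_errors) {
    rt <- grepl("^R_", err)
    # RFSF with no acceptability errors: no suppression applies to this set
    m <- map_to_genbank_errors("RFSF",
                               rt_errors = if (rt) err else character(0),
                               sensor_errors = if (rt) character(0) else err,
                               combine_opts(strict_c = TRUE))
    expect_equal(nrow(m), 1L, info = err)
    expect_true(m$fails_to %in% c("submitter", "indexer"))
  }
  expect_error(map_to_genbank_errors("RFSF", "R_Bogus", character(0)),
               "unknown source error")
})

test_that("footnote suppressions apply exactly in their stated outcome classes", {
  opts <- combine_opts()
  # RPSF without strict combining: the four similarity errors are forgiven
  m <- map_to_genbank_errors("RPSF", character(0), "S_LowScore", opts)
  expect_equal(nrow(m), 0L)
  m <- map_to_genbank_errors("RPSF", character(0),
                             c("S_NoHits", "S_NoSimilarity", "S_LowSimilarity",
                               "S_LowScore"), opts)
  expect_equal(nrow(m), 0L)
  # ...but not non-similarity blast errors
  m <- map_to_genbank_errors("RPSF", character(0), "S_MultipleHits", opts)
  expect_equal(m$genbank_error, "SEQ_HOM_MultipleHits")
  # strict combining restores them
  m <- map_to_genbank_errors("RPSF", character(0), "S_LowScore",
                             combine_opts(strict_c = TRUE))
  expect_equal(m$genbank_error, "SEQ_HOM_LowSimilarity")
  # RFSF with an acceptability error also forgives them
  m <- map_to_genbank_errors("RFSF", "R_UnacceptableModel", "S_LowScore", opts)
  expect_equal(m$genbank_error, "SEQ_HOM_TaxNotExpectedSSUrRNA")
  m <- map_to_genbank_errors("RFSF", "R_QuestionableModel", "S_NoHits", opts)
  expect_equal(m$genbank_error, "SEQ_HOM_TaxQuestionableSSUrRNA")
  # RFSF without one does not
  m <- map_to_genbank_errors("RFSF", "R_LowScore", "S_LowScore", opts)
  expect_equal(m$genbank_error, "SEQ_HOM_LowSimilarity")  # deduplicated
  # RFSP forgives the two indexer-side profile errors
  expect_equal(nrow(map_to_genbank_errors("RFSP", "R_QuestionableModel",
                                          character(0), opts)), 0L)
  expect_equal(nrow(map_to_genbank_errors("RFSP", "R_MultipleHits",
                                          character(0), opts)), 0L)
  # ...but only in RFSP
  expect_equal(nrow(map_to_genbank_errors("RFSF", "R_QuestionableModel",
                                          character(0), opts)), 1L)
  # RFSF joint failure maps once, to the submitter
  m <- map_to_genbank_errors("RFSF", "R_NoHits", "S_NoHits", opts)
  expect_equal(m$genbank_error, "SEQ_HOM_NotSSUOrLSUrRNA")
  expect_equal(m$fails_to, "submitter")
})

test_that("mapping is deterministic and order-independent", {
  opts <- combine_opts()
  errs_r <- c("R_LowCoverage", "R_MultipleFamilies")
  errs_s <- c("S_MultipleHits", "S_BothStrands")
  a <- map_to_genbank_errors("RFSF", errs_r, errs_s, opts)
  b <- map_to_genbank_errors("RFSF", rev(errs_r), rev(errs_s), opts)
  expect_identical(a, b)
})

combine_inputs <- function() {
  models <- fixture_models()
  mk <- function(id, score, len = 1000) {
    data.frame(seq_id = id, model_name = "SSU_bac", model_start = 1,
               model_stop = min(len, 1533), seq_start = 1, seq_stop = len,
               strand = "plus", bit_score = score, e_value = 1e-90,
               stage = 1L, stringsAsFactors = FALSE)
  }
  blast <- function(id, pident, evalue, len = 990) {
    data.frame(query_id = id, subject_id = "db", pct_identity = pident,
               aln_length = len, mismatches = 0, gap_opens = 0, q_start = 1,
               q_stop = len, s_start = 1, s_stop = len, e_value = evalue,
               bit_score = 900, strand = "plus", stringsAsFactors = FALSE)
  }
  seqs <- as_seq_records(
    c("rpsp", "rpsf", "rfsp", "rfsf", "tiny", "huge"),
    vapply(c(1000, 1000, 1000, 1000, 50, 2500), function(n) strrep("A", n), "")
  )
  s1 <- rbind(mk("rpsp", 900), mk("rpsf", 900), mk("rfsp", 400),
              mk("rfsf", 400))
  s2 <- s1
  s2$stage <- 2L
  bl <- rbind(blast("rpsp", 95, 1e-80), blast("rpsf", 70, 1e-80),
              blast("rfsp", 95, 1e-80))
  list(seqs = seqs, s1 = s1, s2 = s2, models = models, blast = bl)
}

test_that("combined validation assigns outcomes, maps errors and routes failures", {
  ci <- combine_inputs()
  res <- combined_validate(ci$seqs, ci$s1, ci$s2, ci$models, ci$blast,
                           combine_opts())
  by_id <- function(id) res[res$seq_id == id, ]
  expect_equal(by_id("rpsp")$outcome, "RPSP")
  expect_true(by_id("rpsp")$pass)
  # profile pass + blast imperfect: similarity errors forgiven without -c
  expect_equal(by_id("rpsf")$outcome, "RPSF")
  expect_true(by_id("rpsf")$pass)
  # profile LowScore is fatal in combined mode; R_LowScore maps for RFSP
  expect_equal(by_id("rfsp")$outcome, "RFSP")
  expect_false(by_id("rfsp")$pass)
  expect_equal(by_id("rfsp")$genbank_errors, "SEQ_HOM_LowSimilarity")
  expect_equal(by_id("rfsp")$fails_to, "submitter")
  expect_equal(by_id("rfsf")$outcome, "RFSF")
  expect_false(by_id("rfsf")$pass)
  # out-of-range sequences are not analyzed and cannot pass
  expect_equal(by_id("tiny")$outcome, "too_short")
  expect_equal(by_id("huge")$outcome, "too_long")
  expect_false(by_id("tiny")$pass)
  expect_false(attr(res, "submission_pass"))
  # analyzed sequences all land in exactly one outcome class
  analyzed <- res[!res$outcome %in% c("too_short", "too_long"), ]
  expect_true(all(analyzed$outcome %in% OUTCOME_CLASSES))
  expect_setequal(analyzed$outcome, OUTCOME_CLASSES)

  # strict combining turns the forgiven RPSF sequence into a failure
  strict <- combined_validate(ci$seqs, ci$s1, ci$s2, ci$models, ci$blast,
                              combine_opts(strict_c = TRUE))
  expect_false(strict[strict$seq_id == "rpsf", "pass"])
})

test_that("an all-pass submission passes as a whole", {
  ci <- combine_inputs()
  keep <- ci$seqs$seq_id %in% c("rpsp", "rpsf")
  res <- combined_validate(ci$seqs[keep, ], ci$s1, ci$s2, ci$models, ci$blast,
                           combine_opts())
  expect_true(attr(res, "submission_pass"))
})

test_that("mode fixes the expected model set", {
  models <- fixture_models()
  m16 <- riboscreen:::mode_acceptability(models, "16S")
  expect_equal(m16$acceptability[m16$model_name == "SSU_bac"], "acceptable")
  expect_equal(m16$acceptability[m16$model_name == "SSU_arc"], "acceptable")
  expect_equal(m16$acceptability[m16$model_name == "SSU_chl"], "questionable")
  expect_equal(m16$acceptability[m16$model_name == "SSU_euk"], "unacceptable")
  m18 <- riboscreen:::mode_acceptability(models, "18S")
  expect_equal(m18$acceptability[m18$model_name == "SSU_euk"], "acceptable")
  expect_equal(m18$acceptability[m18$model_name == "SSU_bac"], "unacceptable")
  expect_false(any(m18$acceptability == "questionable"))
})
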