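mkhit <- function(seq_id, model, score, evalue = 1e-50, strand = "plus",
                  mstart = 1, mstop = 1000, sstart = 1, sstop = 1000,
                  stage = 1L) {
  data.frame(seq_id = seq_id, model_name = model, model_start = mstart,
             model_stop = mstop,
             seq_start = if (strand == "plus") sstart else sstop,
             seq_stop = if (strand == "plus") sstop else sstart,
             strand = strand, bit_score = score, e_value = evalue,
             stage = as.integer(stage), stringsAsFactors = FALSE)
}

test_that("stage-1 classification picks the best model and other-domain runner-up", {
  models <- fixture_models()
  s1 <- rbind(mkhit("a", "SSU_bac", 1500), mkhit("a", "SSU_arc", 1400))
  asg <- classify_stage1(s1, models)[["a"]]
  expect_equal(asg$best_model$model_name, "SSU_bac")
  expect_equal(asg$second_model_other_domain$model_name, "SSU_arc")
  expect_equal(asg$second_score_other_domain, 1400)

  # zero hits -> empty assignment
  empty <- classify_stage1(s1, models, seq_ids = "zzz")[["zzz"]]
  expect_null(empty$best_model)
  expect_length(empty$families_hit, 0)

  # exact score tie: lexicographically smaller model name wins
  tie <- rbind(mkhit("t", "SSU_bac", 1000), mkhit("t", "SSU_arc", 1000))
  expect_equal(classify_stage1(tie, models)[["t"]]$best_model$model_name,
               "SSU_arc")

  # same-domain runner-up is not a score-difference basis
  same <- rbind(mkhit("d", "SSU_bac", 1000), mkhit("d", "LSU_bac", 950))
  expect_null(classify_stage1(same, models)[["d"]]$second_model_other_domain)
})

test_that("score and coverage detectors sit exactly at their printed thresholds", {
  base <- good_seq_inputs()

  # bits/nt: 0.50 exactly is not below threshold; just under is
  at <- good_seq_inputs(score = 500)
  under <- good_seq_inputs(score = 499.9)
  expect_false("LowScore" %in% run_features(at))
  expect_true("LowScore" %in% run_features(under))
  expect_true("LowScore" %in% run_features(good_seq_inputs(score = 400)))

  # coverage: 860/1000 = 0.86 exactly passes, 859/1000 does not
  cov86 <- good_seq_inputs(seq_stop = 860)
  cov86$stage1$model_stop <- cov86$stage2$model_stop <- 860
  cov85 <- good_seq_inputs(seq_stop = 859)
  cov85$stage1$model_stop <- cov85$stage2$model_stop <- 859
  expect_false("LowCoverage" %in% run_features(cov86))
  expect_true("LowCoverage" %in% run_features(cov85))
})

test_that("short-sequence coverage regime switches at the configured length", {
  opts <- typer_opts(tshort_coverage = 0.80, tshort_len = 350)
  short <- good_seq_inputs(len = 350, score = 350, seq_stop = 285)
  short$stage1$model_stop <- short$stage2$model_stop <- 285
  expect_false("LowCoverage" %in% run_features(short, opts))  # 0.814 >= 0.80
  expect_true("LowCoverage" %in% run_features(short))         # default floor 0.86
  long <- good_seq_inputs(len = 351, score = 351, seq_stop = 286)
  long$stage1$model_stop <- long$stage2$model_stop <- 286
  expect_true("LowCoverage" %in% run_features(long, opts))    # 0.815 < 0.86
})

test_that("score-difference features compare against the other-domain runner-up", {
  inp <- good_seq_inputs(score = 1000)
  with_second <- function(second_score) {
    x <- inp
    x$stage1 <- rbind(x$stage1,
                      mkhit("s1", "SSU_arc", second_score, evalue = 1e-40))
    run_features(x)
  }
  f <- with_second(950)  # diff 0.05 bits/nt
  expect_true("LowScoreDifference" %in% f)
  expect_false("VeryLowScoreDifference" %in% f)
  f <- with_second(980)  # diff 0.02: both fire
  expect_true(all(c("LowScoreDifference", "VeryLowScoreDifference") %in% f))
  f <- with_second(900)  # diff 0.10 exactly: not below threshold
  expect_false("LowScoreDifference" %in% f)
  f <- with_second(960)  # diff 0.04 exactly: low yes, very-low no
  expect_true("LowScoreDifference" %in% f)
  expect_false("VeryLowScoreDifference" %in% f)
})

test_that("duplicate-region overlap threshold is 10 model positions inclusive", {
  two <- function(m2start) {
    x <- good_seq_inputs(len = 1500, score = 1200, seq_stop = 760)
    x$stage1$model_stop <- 760
    x$stage2 <- rbind(
      mkhit("s1", "SSU_bac", 600, mstart = 1, mstop = 100,
            sstart = 1, sstop = 760, stage = 2L),
      mkhit("s1", "SSU_bac", 600, mstart = m2start, mstop = 200,
            sstart = 761, sstop = 1500, stage = 2L)
    )
    run_features(x)
  }
  expect_true("DuplicateRegion" %in% two(91))   # overlap 10
  expect_false("DuplicateRegion" %in% two(92))  # overlap 9
  expect_true("MultipleHits" %in% two(92))      # two same-strand hits regardless
})

test_that("hit-order inconsistency fires only on genuine direction violations", {
  geom <- function(m1, m2, strand = "plus") {
    x <- good_seq_inputs(score = 1000)
    s <- if (strand == "plus") list(c(1, 500), c(501, 1000)) else
      list(c(500, 1), c(1000, 501))
    x$stage2 <- rbind(
      mkhit("s1", "SSU_bac", 500, mstart = m1[1], mstop = m1[2],
            sstart = min(s[[1]]), sstop = max(s[[1]]), strand = strand, stage = 2L),
      mkhit("s1", "SSU_bac", 500, mstart = m2[1], mstop = m2[2],
            sstart = min(s[[2]]), sstop = max(s[[2]]), strand = strand, stage = 2L)
    )
    run_features(x)
  }
  expect_false("InconsistentHits" %in% geom(c(1, 500), c(700, 1199)))
  expect_true("InconsistentHits" %in% geom(c(700, 1199), c(1, 500)))
  # minus strand: model positions must decrease along the sequence
  expect_false("InconsistentHits" %in% geom(c(700, 1199), c(1, 500), "minus"))
  expect_true("InconsistentHits" %in% geom(c(1, 500), c(700, 1199), "minus"))
})

test_that("verdicts honour the default and option-extended fatal sets", {
  expect_true(typer_verdict(character(0))$pass)
  expect_true(typer_verdict("MinusStrand")$pass)
  expect_false(typer_verdict("MinusStrand", typer_opts(minusfail = TRUE))$pass)
  expect_false(typer_verdict("NoHits")$pass)
  expect_true(typer_verdict("LowScore")$pass)
  expect_false(typer_verdict("LowScore", typer_opts(scfail = TRUE))$pass)
  v <- typer_verdict(c("MultipleFamilies", "LowCoverage"),
                     typer_opts(covfail = TRUE))
  expect_false(v$pass)
  expect_equal(v$reasons, c("MultipleFamilies", "LowCoverage"))
})

test_that("decisions are invariant to hit row order", {
  fc <- feature_catalogue(5L)
  set.seed(42)
  baseline <- profile_validate(fc$seqs, fc$stage1, fc$stage2, fc$models, fc$opts)
  for (rep in 1:3) {
    s1 <- fc$stage1[sample(nrow(fc$stage1)), ]
    s2 <- fc$stage2[sample(nrow(fc$stage2)), ]
    shuffled <- profile_validate(fc$seqs, s1, s2, fc$models, fc$opts)
    expect_equal(shuffled$features, baseline$features)
    expect_equal(shuffled$best_model, baseline$best_model)
  }
})

test_that("raising a threshold never unflags a sequence (monotonicity)", {
  inp <- good_seq_inputs(score = 450)  # 0.45 bits/nt
  flagged_at <- function(thr) {
    "LowScore" %in% run_features(inp, typer_opts(low_score_bpnt = thr))
  }
  flags <- vapply(c(0.2, 0.4, 0.45, 0.5, 0.7, 1.0), flagged_at, logical(1))
  expect_false(is.unsorted(flags))  # FALSE..FALSE TRUE..TRUE
})
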