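self_hit <- function(id, qstart, qstop, sstart, sstop, len, evalue) {
  data.frame(query_id = id, subject_id = id, pct_identity = 98,
             aln_length = len, mismatches = 0, gap_opens = 0,
             q_start = qstart, q_stop = qstop, s_start = sstart,
             s_stop = sstop, e_value = evalue, bit_score = 100,
             strand = ifelse(sstart > sstop, "minus", "plus"),
             stringsAsFactors = FALSE)
}

test_that("self-repeat test ignores the trivial diagonal and keys on strand-specific lengths", {
  opts <- curation_opts(model = "m")
  trivial <- self_hit("s", 1, 1000, 1, 1000, 1000, 0)
  expect_false(self_repeat_fail("s", trivial, opts))
  # plus-strand off-diagonal: length 20 fails, 19 does not
  expect_true(self_repeat_fail("s", rbind(trivial,
    self_hit("s", 1, 20, 200, 219, 20, 0.5)), opts))
  expect_false(self_repeat_fail("s", rbind(trivial,
    self_hit("s", 1, 19, 200, 218, 19, 0.5)), opts))
  # minus strand: length 50 fails, 49 does not
  expect_true(self_repeat_fail("s", rbind(trivial,
    self_hit("s", 1, 50, 500, 451, 50, 0.5)), opts))
  expect_false(self_repeat_fail("s", rbind(trivial,
    self_hit("s", 1, 49, 500, 452, 49, 0.5)), opts))
  # E-value gate: just above 1 is forgiven
  expect_false(self_repeat_fail("s", rbind(trivial,
    self_hit("s", 1, 30, 200, 229, 30, 1.5)), opts))
  expect_true(self_repeat_fail("s", rbind(trivial,
    self_hit("s", 1, 30, 200, 229, 30, 1)), opts))
})

test_that("vector contamination fails on any non-weak match", {
  m <- function(strength) data.frame(seq_id = "s", start = 1, stop = 30,
                                     strength = strength)
  expect_false(vecscreen_fail(m("Weak")[0, ]))
  expect_false(vecscreen_fail(m("Weak")))
  expect_true(vecscreen_fail(m("Moderate")))
  expect_true(vecscreen_fail(m("Strong")))
  expect_true(vecscreen_fail(rbind(m("Weak"), m("Strong"))))
})

test_that("model-span test enforces the required positions, optionally without gaps", {
  expect_true(span_pass(600, 1100, 604, 1070))
  expect_true(span_pass(604, 1070, 604, 1070))
  expect_false(span_pass(610, 1100, 604, 1070))
  expect_false(span_pass(600, 1060, 604, 1070))
  occ <- rep(TRUE, 1200)
  expect_true(span_pass(600, 1100, 604, 1070, nogap = TRUE, occupancy = occ))
  occ[604] <- FALSE  # deletion exactly at the left boundary
  expect_false(span_pass(600, 1100, 604, 1070, nogap = TRUE, occupancy = occ))
})

test_that("ingroup analysis fails taxonomic outliers and spares singletons", {
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3")
  groups <- stats::setNames(c("A", "A", "A", "B", "B", "B"), ids)
  m <- matrix(0.80, 6, 6, dimnames = list(ids, ids))
  m[1:3, 1:3] <- 0.99
  m[4:6, 4:6] <- 0.99
  diag(m) <- 1
  expect_length(ingroup_fail(m, groups), 0)
  # a1 closer to the other group than to its own
  m2 <- m
  m2["a1", c("b1", "b2", "b3")] <- m2[c("b1", "b2", "b3"), "a1"] <- 0.95
  m2["a1", c("a2", "a3")] <- m2[c("a2", "a3"), "a1"] <- 0.85
  expect_equal(ingroup_fail(m2, groups), "a1")
  # singleton group never fails, however distant
  groups3 <- stats::setNames(c("A", "A", "A", "B", "B", "C"), ids)
  m3 <- m
  m3["b3", ] <- m3[, "b3"] <- 0.5
  diag(m3) <- 1
  expect_false("b3" %in% ingroup_fail(m3, groups3))
  # invariant to sequence order
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_setequal(ingroup_fail(m2[perm, perm], groups), ingroup_fail(m2, groups))
})

test_that("single-linkage clustering matches its definition and picks centroids", {
  ids <- c("a", "b", "c")
  m <- matrix(1, 3, 3, dimnames = list(ids, ids))
  cl <- cluster_and_centroids(m, threshold = 0.97)
  expect_equal(length(unique(cl$clusters$cluster)), 1L)
  expect_equal(cl$centroids, "a")  # all tied: lexicographic
  m0 <- diag(3)
  dimnames(m0) <- list(ids, ids)
  cl <- cluster_and_centroids(m0, threshold = 0.97)
  expect_equal(length(unique(cl$clusters$cluster)), 3L)
  expect_setequal(cl$centroids, ids)
  # chain: a-b and b-c linked, a-c not; single linkage joins all three
  m1 <- m0
  m1["a", "b"] <- m1["b", "a"] <- 0.99
  m1["b", "c"] <- m1["c", "b"] <- 0.99
  m1["a", "c"] <- m1["c", "a"] <- 0.90
  cl <- cluster_and_centroids(m1, threshold = 0.95)
  expect_equal(length(unique(cl$clusters$cluster)), 1L)
  expect_equal(cl$centroids, "b")  # highest mean identity to the others
})

test_that("single-linkage clustering agrees with brute-force transitive closure", {
  set.seed(23)
  for (rep in 1:12) {
    n <- sample(5:50, 1)
    m <- random_identity_matrix(n)
    thr <- stats::runif(1, 0.3, 0.9)
    cl <- cluster_and_centroids(m, threshold = thr)
    oracle <- brute_force_single_linkage(m, thr)
    got <- cl$clusters$cluster[match(rownames(m), cl$clusters$seq_id)]
    # same partition: co-membership matrices agree
    expect_equal(outer(got, got, "=="), outer(oracle, oracle, "=="),
                 ignore_attr = TRUE)
  }
})

test_that("one-per-taxid selection breaks ties by span, ambiguity, then id", {
  tab <- data.frame(
    seq_id = c("s1", "s2", "s3", "s4", "s5"),
    species_taxid = c(100, 100, 100, 200, 300),
    span = c(900, 950, 950, 800, 700),
    n_ambiguous = c(0, 2, 1, 5, 0)
  )
  kept <- select_one_per_taxid(tab)$seq_id
  expect_setequal(kept, c("s3", "s4", "s5"))  # s3: span tie, fewer Ns
  tab$n_ambiguous[2:3] <- 1  # full tie: lexicographic id
  expect_true("s2" %in% select_one_per_taxid(tab)$seq_id)
})

test_that("the pipeline records every fate, gates correctly and clusters survivors", {
  cf <- curation_fixture(9L)
  rep <- curate_rrna_db(cf$seqs, cf$stage1, cf$stage2, cf$models, cf$aln,
                        cf$opts, taxonomy = cf$taxonomy,
                        seq_taxids = cf$seq_taxids, vecscreen = cf$vecscreen,
                        self_hits = cf$self_hits)
  # complete report: every sequence has a fate for every enabled step
  expect_equal(sort(rownames(rep$steps)), sort(cf$seqs$seq_id))
  expect_true(all(rep$steps %in% c("pass", "fail", "skipped")))
  # the ambiguity+vector sequence fails both independent filters
  expect_equal(unname(rep$steps["amb1", "ambiguity"]), "fail")
  expect_equal(unname(rep$steps["amb1", "vecscreen"]), "fail")
  # profile failure gates the alignment step
  expect_equal(unname(rep$steps["low1", "profile_validation"]), "fail")
  expect_equal(unname(rep$steps["low1", "alignment_validation"]), "skipped")
  expect_equal(unname(rep$steps["low1", "model_span"]), "skipped")
  # ingroup runs only on sequences passing all single-sequence tests
  expect_equal(unname(rep$steps["tax1", "ingroup"]), "skipped")
  expect_equal(rep$survivors, cf$survivors)
  expect_setequal(rep$final_ids, cf$final_ids)
})

test_that("one-per-taxid selection and skip flags thread through the pipeline", {
  cf <- curation_fixture(9L)
  run <- function(opts) {
    curate_rrna_db(cf$seqs, cf$stage1, cf$stage2, cf$models, cf$aln, opts,
                   taxonomy = cf$taxonomy, seq_taxids = cf$seq_taxids,
                   vecscreen = cf$vecscreen, self_hits = cf$self_hits)
  }
  fione <- run(curation_opts(model = "SSU_toy", fmlpos = 3, fmrpos = 18,
                             fione = TRUE, skip_cluster = TRUE))
  # g1 and g2 are distinct species: both kept; g3 too
  expect_setequal(fione$final_ids, c("g1", "g2", "g3"))
  noclust <- run(curation_opts(model = "SSU_toy", skip_cluster = TRUE))
  expect_setequal(noclust$final_ids, noclust$survivors)
  # a missing required input names the flag that would disable the step
  expect_error(
    curate_rrna_db(cf$seqs, cf$stage1, cf$stage2, cf$models, cf$aln,
                   curation_opts(model = "SSU_toy"),
                   self_hits = cf$self_hits),
    "skip_taxid")
  expect_error(
    curate_rrna_db(cf$seqs, cf$stage1, cf$stage2, cf$models, cf$aln,
                   curation_opts(model = "SSU_toy", skip_taxid = TRUE,
                                 skip_ingroup = TRUE),
                   self_hits = cf$self_hits),
    "skip_vecscreen")
})

test_that("survivor sets shrink monotonically as tests are enabled", {
  cf <- curation_fixture(9L)
  variants <- list(
    curation_opts(model = "SSU_toy", skip_taxid = TRUE, skip_vecscreen = TRUE,
                  skip_ingroup = TRUE, skip_cluster = TRUE),
    curation_opts(model = "SSU_toy", skip_vecscreen = TRUE,
                  skip_ingroup = TRUE, skip_cluster = TRUE),
    curation_opts(model = "SSU_toy", skip_ingroup = TRUE, skip_cluster = TRUE),
    curation_opts(model = "SSU_toy", skip_cluster = TRUE),
    curation_opts(model = "SSU_toy", fmlpos = 3, fmrpos = 18,
                  skip_cluster = TRUE)
  )
  survivors <- lapply(variants, function(o) {
    curate_rrna_db(cf$seqs, cf$stage1, cf$stage2, cf$models, cf$aln, o,
                   taxonomy = cf$taxonomy, seq_taxids = cf$seq_taxids,
                   vecscreen = cf$vecscreen, self_hits = cf$self_hits)$survivors
  })
  for (i in seq_along(survivors)[-1]) {
    expect_true(all(survivors[[i]] %in% survivors[[i - 1]]))
  }
})
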