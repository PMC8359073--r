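# Deterministic synthetic fixtures. Every input format the engines consume
# can be generated with controllable properties, so each rule and boundary is
# independently triggerable without external data. Sequences are random with
# fixed nucleotide composition; biological realism is a non-goal — fixtures
# target rule boundaries, and the generator asserts (via the engines' own
# detectors) that each directive triggers exactly the intended outcome.

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", genv, inherits = FALSE)) {
    get(".Random.seed", genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, genv)
    }
  })
  set.seed(seed)
  force(code)
}

random_residues <- function(n, n_ambiguous = 0L) {
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (n_ambiguous > 0L) x[sample.int(n, n_ambiguous)] <- "N"
  paste(x, collapse = "")
}

phit <- function(seq_id, model, mstart, mstop, sstart, sstop,
                 strand = "plus", score, evalue, stage) {
  data.frame(seq_id = seq_id, model_name = model,
             model_start = mstart, model_stop = mstop,
             seq_start = sstart, seq_stop = sstop, strand = strand,
             bit_score = score, e_value = evalue, stage = as.integer(stage),
             stringsAsFactors = FALSE)
}

bhit <- function(query, subject, pident, len, qstart, qstop, sstart, sstop,
                 evalue, score) {
  data.frame(query_id = query, subject_id = subject, pct_identity = pident,
             aln_length = len, mismatches = 0, gap_opens = 0,
             q_start = qstart, q_stop = qstop, s_start = sstart,
             s_stop = sstop, e_value = evalue, bit_score = score,
             strand = ifelse(sstart > sstop, "minus", "plus"),
             stringsAsFactors = FALSE)
}

#' Toy model registry used by the fixture suites
#'
#' Five models patterned on the real per-domain SSU/LSU profile set, with
#' one model marked unacceptable and one questionable (mirroring an
#' `--inaccept` input list) so the acceptability diagnostics are reachable.
#' @return A model registry `data.frame`.
#' @export
fixture_models <- function() {
  model_registry(
    model_name = c("SSU_arc", "SSU_bac", "SSU_euk", "SSU_chl", "LSU_bac"),
    family = c("SSU", "SSU", "SSU", "SSU", "LSU"),
    domain = c("archaea", "bacteria", "eukarya", "chloroplast", "bacteria"),
    model_length = c(1477, 1533, 1851, 1488, 2925),
    acceptability = c("acceptable", "acceptable", "unacceptable",
                      "questionable", "acceptable")
  )
}

#' Feature catalogue: one sequence per unexpected feature
#'
#' Builds sequences and stage-1/stage-2 hit tables engineered so each of the
#' sixteen unexpected features is triggered in isolation (plus logically
#' entailed ones: a duplicated or inconsistently ordered region implies
#' multiple hits; a very low score difference implies a low one). The
#' catalogue option set enables all optional flags so option-gated features
#' are reportable. Before returning, the generator re-runs the validation
#' engine and stops if any sequence reports a feature set other than the
#' intended one.
#'
#' @param seed Integer seed; the same seed yields identical output.
#' @return List with `seqs`, `stage1`, `stage2`, `models`, `opts` and
#'   `certificate` (a `data.frame` mapping each sequence to its expected
#'   semicolon-joined feature set).
#' @export
feature_catalogue <- function(seed = 42L) {
  models <- fixture_models()
  opts <- typer_opts(evalues = TRUE, shortfail = 300, longfail = 2400)

  spec <- list(
    list(id = "noh", len = 500, exp = "NoHits", s1 = NULL, s2 = NULL),
    list(id = "unacc", len = 1000, exp = "UnacceptableModel",
         s1 = phit("unacc", "SSU_euk", 1, 1000, 1, 1000, "plus", 900, 1e-90, 1),
         s2 = phit("unacc", "SSU_euk", 1, 1000, 1, 1000, "plus", 900, 1e-90, 2)),
    list(id = "multfam", len = 1000, exp = "MultipleFamilies",
         s1 = rbind(phit("multfam", "SSU_bac", 1, 1000, 1, 1000, "plus", 1000, 1e-100, 1),
                    phit("multfam", "LSU_bac", 1, 400, 1, 400, "plus", 400, 1e-30, 1)),
         s2 = phit("multfam", "SSU_bac", 1, 1000, 1, 1000, "plus", 1000, 1e-100, 2)),
    list(id = "bstr", len = 1000, exp = "BothStrands",
         s1 = rbind(phit("bstr", "SSU_bac", 1, 1000, 1, 1000, "plus", 1000, 1e-100, 1),
                    phit("bstr", "SSU_bac", 1, 150, 950, 800, "minus", 100, 1e-5, 1)),
         s2 = phit("bstr", "SSU_bac", 1, 1000, 1, 1000, "plus", 1000, 1e-100, 2)),
    list(id = "dup", len = 1500, exp = "DuplicateRegion;MultipleHits",
         s1 = phit("dup", "SSU_bac", 1, 760, 1, 760, "plus", 600, 1e-60, 1),
         s2 = rbind(phit("dup", "SSU_bac", 1, 760, 1, 760, "plus", 600, 1e-60, 2),
                    phit("dup", "SSU_bac", 751, 1490, 761, 1500, "plus", 600, 1e-58, 2))),
    list(id = "incons", len = 1000, exp = "InconsistentHits;MultipleHits",
         s1 = phit("incons", "SSU_bac", 700, 1199, 1, 500, "plus", 500, 1e-50, 1),
         s2 = rbind(phit("incons", "SSU_bac", 700, 1199, 1, 500, "plus", 500, 1e-50, 2),
                    phit("incons", "SSU_bac", 1, 500, 501, 1000, "plus", 500, 1e-49, 2))),
    list(id = "ques", len = 1000, exp = "QuestionableModel",
         s1 = phit("ques", "SSU_chl", 1, 1000, 1, 1000, "plus", 900, 1e-90, 1),
         s2 = phit("ques", "SSU_chl", 1, 1000, 1, 1000, "plus", 900, 1e-90, 2)),
    list(id = "minus", len = 1000, exp = "MinusStrand",
         s1 = phit("minus", "SSU_bac", 1, 1000, 1000, 1, "minus", 900, 1e-90, 1),
         s2 = phit("minus", "SSU_bac", 1, 1000, 1000, 1, "minus", 900, 1e-90, 2)),
    list(id = "lowsc", len = 1000, exp = "LowScore",
         s1 = phit("lowsc", "SSU_bac", 1, 1000, 1, 1000, "plus", 400, 1e-40, 1),
         s2 = phit("lowsc", "SSU_bac", 1, 1000, 1, 1000, "plus", 400, 1e-40, 2)),
    list(id = "lowcov", len = 1000, exp = "LowCoverage",
         s1 = phit("lowcov", "SSU_bac", 1, 850, 1, 850, "plus", 800, 1e-80, 1),
         s2 = phit("lowcov", "SSU_bac", 1, 850, 1, 850, "plus", 800, 1e-80, 2)),
    list(id = "lowdiff", len = 1000, exp = "LowScoreDifference",
         s1 = rbind(phit("lowdiff", "SSU_bac", 1, 1000, 1, 1000, "plus", 1000, 1e-100, 1),
                    phit("lowdiff", "SSU_arc", 1, 1000, 1, 1000, "plus", 950, 1e-95, 1)),
         s2 = phit("lowdiff", "SSU_bac", 1, 1000, 1, 1000, "plus", 1000, 1e-100, 2)),
    list(id = "verylow", len = 1000,
         exp = "LowScoreDifference;VeryLowScoreDifference",
         s1 = rbind(phit("verylow", "SSU_bac", 1, 1000, 1, 1000, "plus", 1000, 1e-100, 1),
                    phit("verylow", "SSU_arc", 1, 1000, 1, 1000, "plus", 980, 1e-98, 1)),
         s2 = phit("verylow", "SSU_bac", 1, 1000, 1, 1000, "plus", 1000, 1e-100, 2)),
    list(id = "multhit", len = 1000, exp = "MultipleHits",
         s1 = phit("multhit", "SSU_bac", 1, 500, 1, 500, "plus", 300, 1e-30, 1),
         s2 = rbind(phit("multhit", "SSU_bac", 1, 500, 1, 500, "plus", 300, 1e-30, 2),
                    phit("multhit", "SSU_bac", 521, 1000, 521, 1000, "plus", 300, 1e-29, 2))),
    list(id = "evd", len = 1000, exp = "EvalueScoreDiscrepancy",
         s1 = rbind(phit("evd", "SSU_bac", 1, 600, 1, 600, "plus", 500, 1e-50, 1),
                    phit("evd", "SSU_bac", 1, 1000, 1, 1000, "plus", 800, 1e-40, 1)),
         s2 = phit("evd", "SSU_bac", 1, 1000, 1, 1000, "plus", 800, 1e-40, 2)),
    list(id = "short", len = 250, exp = "TooShort",
         s1 = phit("short", "SSU_bac", 1, 250, 1, 250, "plus", 250, 1e-25, 1),
         s2 = phit("short", "SSU_bac", 1, 250, 1, 250, "plus", 250, 1e-25, 2)),
    list(id = "long", len = 2500, exp = "TooLong",
         s1 = phit("long", "SSU_bac", 1, 1533, 1, 2500, "plus", 1500, 1e-150, 1),
         s2 = phit("long", "SSU_bac", 1, 1533, 1, 2500, "plus", 1500, 1e-150, 2))
  )

  seqs <- with_seed(seed, {
    as_seq_records(
      vapply(spec, `[[`, "", "id"),
      vapply(spec, function(s) random_residues(s$len), "")
    )
  })
  stage1 <- do.call(rbind, c(lapply(spec, `[[`, "s1"),
                             list(empty_profile_hits())))
  stage2 <- do.call(rbind, c(lapply(spec, `[[`, "s2"),
                             list(empty_profile_hits())))
  certificate <- data.frame(seq_id = vapply(spec, `[[`, "", "id"),
                            features = vapply(spec, `[[`, "", "exp"),
                            stringsAsFactors = FALSE)

  # the generator proves its own directives by running the engine
  got <- profile_validate(seqs, stage1, stage2, models, opts)
  mism <- which(got$features != certificate$features)
  if (length(mism) > 0L) {
    stop("fixture generation error: sequence ", got$seq_id[mism[[1L]]],
         " reports {", got$features[mism[[1L]]], "} instead of {",
         certificate$features[mism[[1L]]], "}")
  }
  list(seqs = seqs, stage1 = stage1, stage2 = stage2, models = models,
       opts = opts, certificate = certificate)
}

# one aligned row over 2 insert cols + 20 consensus cols + 2 insert cols
catalogue_row <- function(cons_present, ins5 = 0L, ins3 = 0L) {
  a <- c(rep("a", ins5), rep(".", 2L - ins5))
  b <- c(rep("a", ins3), rep(".", 2L - ins3))
  cons <- ifelse(seq_len(20L) %in% cons_present, "A", "-")
  paste(c(a, cons, b), collapse = "")
}

#' Length-class catalogue: one aligned row per class
#'
#' A 24-column toy reference alignment (20 consensus positions flanked by
#' two insert columns at each end) whose thirteen rows realize every length
#' class. The generator asserts the classifier's output before returning.
#'
#' @return List with `alignment` (a `ref_alignment`) and `certificate`
#'   (`data.frame` of `seq_id`, `length_class`).
#' @export
length_class_catalogue <- function() {
  rows <- c(
    "full-exact" = catalogue_row(1:20),
    "full-extra" = catalogue_row(1:20, ins5 = 2L),
    "full-ambig-more" = catalogue_row(setdiff(1:20, 2L), ins5 = 2L),
    "full-ambig-less" = catalogue_row(setdiff(1:20, 2L)),
    "5flush-exact" = catalogue_row(1:15),
    "5flush-extra" = catalogue_row(1:15, ins5 = 2L),
    "5flush-ambig-more" = catalogue_row(setdiff(1:15, 3L), ins5 = 2L),
    "5flush-ambig-less" = catalogue_row(setdiff(1:15, 3L)),
    "3flush-exact" = catalogue_row(6:20),
    "3flush-extra" = catalogue_row(6:20, ins3 = 2L),
    "3flush-ambig-more" = catalogue_row(setdiff(6:20, 18L), ins3 = 2L),
    "3flush-ambig-less" = catalogue_row(setdiff(6:20, 18L)),
    "partial" = catalogue_row(5:15)
  )
  rf <- paste(c("..", rep("x", 20L), ".."), collapse = "")
  aln <- as_ref_alignment(rows, rf)
  got <- length_classify(aln)
  mism <- which(got$length_class != got$seq_id)
  if (length(mism) > 0L) {
    stop("fixture generation error: row ", got$seq_id[mism[[1L]]],
         " classified as ", got$length_class[mism[[1L]]])
  }
  list(alignment = aln,
       certificate = data.frame(seq_id = got$seq_id,
                                length_class = got$length_class,
                                stringsAsFactors = FALSE))
}

#' Sensor catalogue: one sequence per sensor class
#'
#' @param seed Integer seed.
#' @return List with `seqs`, `blast`, `opts` and `certificate`.
#' @export
sensor_catalogue <- function(seed = 42L) {
  seqs <- with_seed(seed + 1L, as_seq_records(
    c("sl", "ss", "sy", "si", "sn"),
    vapply(c(3000, 300, 1200, 1200, 1200), random_residues, "")
  ))
  blast <- rbind(
    bhit("sy", "db1", 95, 1150, 1, 1150, 10, 1159, 1e-60, 1500),
    bhit("si", "db1", 70, 1150, 1, 1150, 10, 1159, 1e-60, 600)
  )
  opts <- sensor_opts(min_length = 400, max_length = 2500)
  certificate <- data.frame(
    seq_id = c("sl", "ss", "sy", "si", "sn"),
    klass = c("too_long", "too_short", "yes", "imperfect_match", "no"),
    stringsAsFactors = FALSE
  )
  got <- blast_validate(seqs, blast, opts)
  if (!identical(got$klass, certificate$klass)) {
    stop("fixture generation error: sensor classes ",
         paste(got$klass, collapse = ","))
  }
  list(seqs = seqs, blast = blast, opts = opts, certificate = certificate)
}

#' Curation fixture: a small coherent dataset for the full pipeline
#'
#' Seven sequences against a 20-position toy model: three clean survivors
#' in two taxonomic orders, one sequence with both excess ambiguity and a
#' Strong vector match (failing two independent filters), one without a
#' specified species, one with an internal repeat, and one failing profile
#' validation on score density (whose alignment step is therefore skipped).
#'
#' @param seed Integer seed.
#' @return List with every pipeline input plus `opts` and the expected
#'   `survivors` and `final_ids`.
#' @export
curation_fixture <- function(seed = 42L) {
  models <- model_registry("SSU_toy", "SSU", "bacteria", 20)
  ids <- c("g1", "g2", "g3", "amb1", "tax1", "rep1", "low1")
  lens <- c(1000, 1000, 1000, 2000, 1000, 1000, 1000)
  seqs <- with_seed(seed + 2L, as_seq_records(
    ids, mapply(function(n, k) random_residues(n, k), lens,
                c(0L, 0L, 0L, 6L, 0L, 0L, 0L))
  ))
  score <- c(900, 900, 900, 1800, 900, 900, 400)  # low1: 0.4 bits/nt
  stage1 <- do.call(rbind, lapply(seq_along(ids), function(i) {
    phit(ids[[i]], "SSU_toy", 1, 20, 1, lens[[i]], "plus",
         score[[i]], 1e-90, 1)
  }))
  stage2 <- stage1
  stage2$stage <- 2L

  taxonomy <- data.frame(
    taxid = c(1, 10, 11, 100, 101, 102, 103, 104, 105, 106),
    parent_taxid = c(1, 1, 1, 10, 10, 11, 10, 10, 11, 11),
    rank = c("no rank", "order", "order", rep("species", 7)),
    specified = c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  seq_taxids <- stats::setNames(c(100, 101, 102, 104, 103, 105, 106), ids)

  base <- "ACGTACGTACGTACGTACGT"
  g3row <- "TGCAACGTACGTACGTTTGC"  # 6 mismatches vs base
  aln <- as_ref_alignment(
    stats::setNames(c(base, base, g3row, base, base, base, base), ids),
    paste(rep("x", 20), collapse = "")
  )

  vecscreen <- data.frame(seq_id = c("amb1", "g1"), start = c(1, 5),
                          stop = c(30, 20),
                          strength = c("Strong", "Weak"),
                          stringsAsFactors = FALSE)
  self_hits <- rbind(
    do.call(rbind, lapply(seq_along(ids), function(i) {
      bhit(ids[[i]], ids[[i]], 100, lens[[i]], 1, lens[[i]], 1, lens[[i]],
           0, 2 * lens[[i]])
    })),
    bhit("rep1", "rep1", 98, 30, 1, 30, 200, 229, 0.1, 55)
  )
  opts <- curation_opts(model = "SSU_toy", fmlpos = 3, fmrpos = 18)
  list(seqs = seqs, stage1 = stage1, stage2 = stage2, models = models,
       aln = aln, taxonomy = taxonomy, seq_taxids = seq_taxids,
       vecscreen = vecscreen, self_hits = self_hits, opts = opts,
       survivors = c("g1", "g2", "g3"), final_ids = c("g1", "g3"))
}

write_tsv_plain <- function(df, path, comment = NULL) {
  lines <- character(0)
  if (!is.null(comment)) lines <- paste0("# ", comment)
  lines <- c(lines, paste(names(df), collapse = "\t"))
  if (nrow(df) > 0L) {
    lines <- c(lines, do.call(paste, c(lapply(df, function(v) {
      if (is.numeric(v)) format_num(v) else as.character(v)
    }), sep = "\t")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the full fixture bundle to a directory
#'
#' Emits every input format the package consumes: FASTA, normalized profile
#' hit tables, a model registry, blastn tabular files, a taxonomy table,
#' vecscreen matches, Stockholm alignments, and the coverage certificates.
#' Output is byte-identical for the same seed.
#'
#' @param dir Output directory (created; must not exist unless `force`).
#' @param seed Integer seed.
#' @param force Overwrite an existing directory.
#' @return Invisibly, the named vector of written paths.
#' @export
generate_bundle <- function(dir, seed = 42L, force = FALSE) {
  if (dir.exists(dir)) {
    if (!force) stop("output directory exists (use force = TRUE): ", dir)
  } else {
    dir.create(dir, recursive = TRUE)
  }
  fc <- feature_catalogue(seed)
  lc <- length_class_catalogue()
  sc <- sensor_catalogue(seed)
  cf <- curation_fixture(seed)
  p <- function(f) file.path(dir, f)

  write_fasta(fc$seqs, p("catalogue.fa"))
  write_profile_hits(fc$stage1, p("catalogue.stage1.tblout"))
  write_profile_hits(fc$stage2, p("catalogue.stage2.tblout"))
  write_tsv_plain(fc$models, p("models.tsv"))
  write_tsv_plain(fc$certificate, p("catalogue_certificate.tsv"))

  write_stockholm(lc$alignment, p("length_classes.sto"))
  write_tsv_plain(lc$certificate, p("length_certificate.tsv"))

  write_fasta(sc$seqs, p("sensor.fa"))
  write_blast_hits(sc$blast, p("sensor_blast.tsv"))
  write_tsv_plain(sc$certificate, p("sensor_certificate.tsv"))

  write_fasta(cf$seqs, p("curation.fa"))
  write_profile_hits(cf$stage1, p("curation.stage1.tblout"))
  write_profile_hits(cf$stage2, p("curation.stage2.tblout"))
  write_tsv_plain(cf$models, p("curation_models.tsv"))
  write_tsv_plain(cf$taxonomy, p("taxonomy.tsv"))
  write_tsv_plain(cf$vecscreen, p("vecscreen.tsv"))
  write_blast_hits(cf$self_hits, p("selfhits.tsv"))
  write_stockholm(cf$aln, p("curation.sto"))
  write_tsv_plain(data.frame(seq_id = names(cf$seq_taxids),
                             taxid = unname(cf$seq_taxids)),
                  p("seq_taxids.tsv"))

  files <- list.files(dir, full.names = TRUE)
  invisible(stats::setNames(files, basename(files)))
}
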