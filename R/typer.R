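# Two-stage profile-based classification with the sixteen unexpected-feature
# detectors. Stage 1 ranks models by their best single-hit bit score; stage 2
# supplies hit endpoints for the best model, from which score density,
# coverage and the hit-geometry diagnostics are computed.

#' Canonical unexpected-feature labels
#'
#' The sixteen per-sequence diagnostics, in canonical report order. The first
#' seven plus `TooShort`/`TooLong` are fatal by default.
#' @export
UNEXPECTED_FEATURES <- c(
  "NoHits", "UnacceptableModel", "MultipleFamilies", "BothStrands",
  "DuplicateRegion", "InconsistentHits", "QuestionableModel",
  "MinusStrand", "LowScore", "LowCoverage", "LowScoreDifference",
  "VeryLowScoreDifference", "MultipleHits", "EvalueScoreDiscrepancy",
  "TooShort", "TooLong"
)

DEFAULT_FATAL <- c("NoHits", "UnacceptableModel", "MultipleFamilies",
                   "BothStrands", "DuplicateRegion", "InconsistentHits",
                   "QuestionableModel", "TooShort", "TooLong")

#' Options for profile-based validation
#'
#' Thresholds and pass/fail semantics for the two-stage classifier.
#'
#' @param low_score_bpnt Bits-per-nucleotide floor below which `LowScore` is
#'   reported (total best-model bit score divided by sequence length).
#' @param low_coverage Coverage floor below which `LowCoverage` is reported.
#' @param low_diff_bpp,very_low_diff_bpp Bits-per-position floors on the
#'   score difference between the best model and the best model from another
#'   taxonomic domain.
#' @param duplicate_overlap_min Minimum model-coordinate overlap (inclusive
#'   positions) between two same-strand hits for `DuplicateRegion`.
#' @param minusfail,scfail,covfail,difffail,multfail Make `MinusStrand`,
#'   `LowScore`, `LowCoverage`, the score-difference pair, and `MultipleHits`
#'   fatal, respectively.
#' @param evalues Enable E-value-sorted reporting, which makes
#'   `EvalueScoreDiscrepancy` detectable.
#' @param shortfail,longfail Optional length bounds; when set, sequences
#'   shorter/longer than the bound get the fatal `TooShort`/`TooLong` feature.
#' @param tshort_coverage,tshort_len Optional short-sequence coverage regime:
#'   sequences of length `<= tshort_len` use `tshort_coverage` as the
#'   `LowCoverage` floor instead of `low_coverage`.
#' @return An object of class `typer_opts`.
#' @export
typer_opts <- function(low_score_bpnt = 0.50, low_coverage = 0.86,
                       low_diff_bpp = 0.10, very_low_diff_bpp = 0.04,
                       duplicate_overlap_min = 10,
                       minusfail = FALSE, scfail = FALSE, covfail = FALSE,
                       difffail = FALSE, multfail = FALSE, evalues = FALSE,
                       shortfail = NULL, longfail = NULL,
                       tshort_coverage = NULL, tshort_len = NULL) {
  stopifnot(low_score_bpnt >= 0, low_coverage >= 0, low_diff_bpp >= 0,
            very_low_diff_bpp >= 0, very_low_diff_bpp <= low_diff_bpp,
            duplicate_overlap_min >= 0)
  if (is.null(tshort_coverage) != is.null(tshort_len)) {
    stop("tshort_coverage and tshort_len must be set together")
  }
  structure(list(
    low_score_bpnt = low_score_bpnt, low_coverage = low_coverage,
    low_diff_bpp = low_diff_bpp, very_low_diff_bpp = very_low_diff_bpp,
    duplicate_overlap_min = duplicate_overlap_min,
    minusfail = minusfail, scfail = scfail, covfail = covfail,
    difffail = difffail, multfail = multfail, evalues = evalues,
    shortfail = shortfail, longfail = longfail,
    tshort_coverage = tshort_coverage, tshort_len = tshort_len
  ), class = "typer_opts")
}

#' Fatal feature set implied by an option object
#' @param opts A [typer_opts()] object.
#' @return Character vector of fatal feature labels.
#' @export
fatal_features <- function(opts) {
  fatal <- DEFAULT_FATAL
  if (opts$minusfail) fatal <- c(fatal, "MinusStrand")
  if (opts$scfail) fatal <- c(fatal, "LowScore")
  if (opts$covfail) fatal <- c(fatal, "LowCoverage")
  if (opts$difffail) fatal <- c(fatal, "LowScoreDifference", "VeryLowScoreDifference")
  if (opts$multfail) fatal <- c(fatal, "MultipleHits")
  intersect(UNEXPECTED_FEATURES, fatal)
}

# Best single hit of a model within one sequence's stage-1 hits.
best_hit_per_model <- function(hits) {
  split_idx <- split(seq_len(nrow(hits)), hits$model_name)
  rows <- vapply(split_idx, function(idx) {
    h <- hits[idx, , drop = FALSE]
    idx[order(-h$bit_score, h$e_value)[1L]]
  }, integer(1))
  hits[rows, , drop = FALSE]
}

#' Stage-1 classification: pick the best model per sequence
#'
#' Ranks models by their best single-hit bit score (ties broken by lower
#' E-value, then lexicographic model name) and records the best-scoring
#' model from a different taxonomic domain, which is the basis of the
#' score-difference diagnostics. Sequences with zero stage-1 hits get an
#' empty assignment.
#'
#' @param stage1 Stage-1 profile hits (all sequences).
#' @param models Model registry.
#' @param seq_ids Sequence ids to assign (defaults to those present in
#'   `stage1`).
#' @return Named list of assignments; each has `best_model` (registry row),
#'   `best_score`, `best_evalue`, `best_strand`, `second_model_other_domain`,
#'   `second_score_other_domain`, `families_hit`, `strands_hit` and the
#'   sequence's stage-1 `hits`.
#' @export
classify_stage1 <- function(stage1, models, seq_ids = unique(stage1$seq_id)) {
  validate_profile_hits(stage1, models)
  out <- lapply(seq_ids, function(sid) {
    h <- stage1[stage1$seq_id == sid & stage1$stage == 1L, , drop = FALSE]
    if (nrow(h) == 0L) {
      return(list(seq_id = sid, best_model = NULL, best_score = NA_real_,
                  best_evalue = NA_real_, best_strand = NA_character_,
                  second_model_other_domain = NULL,
                  second_score_other_domain = NA_real_,
                  families_hit = character(0), strands_hit = character(0),
                  hits = h))
    }
    per_model <- best_hit_per_model(h)
    ord <- order(-per_model$bit_score, per_model$e_value, per_model$model_name)
    per_model <- per_model[ord, , drop = FALSE]
    best <- per_model[1L, ]
    best_row <- models[match(best$model_name, models$model_name), ]
    fam <- models$family[match(h$model_name, models$model_name)]
    dom <- models$domain[match(per_model$model_name, models$model_name)]
    other <- which(dom != dom[[1L]])
    second_row <- NULL
    second_score <- NA_real_
    if (length(other) > 0L) {
      second <- per_model[other[[1L]], ]
      second_row <- models[match(second$model_name, models$model_name), ]
      second_score <- second$bit_score
    }
    list(seq_id = sid, best_model = best_row, best_score = best$bit_score,
         best_evalue = best$e_value, best_strand = best$strand,
         second_model_other_domain = second_row,
         second_score_other_domain = second_score,
         families_hit = sort(unique(fam)),
         strands_hit = sort(unique(h$strand)),
         hits = h)
  })
  names(out) <- seq_ids
  out
}

# model-coordinate overlap (inclusive positions) of two hits; <=0 means none
model_overlap <- function(a_start, a_stop, b_start, b_stop) {
  min(a_stop, b_stop) - max(a_start, b_start) + 1
}

#' Detect unexpected features for one sequence
#'
#' Evaluates all sixteen detectors. Option-gated features
#' (`EvalueScoreDiscrepancy`, `TooShort`, `TooLong`) are only reportable when
#' the corresponding option is active; `UnacceptableModel` and
#' `QuestionableModel` derive from the registry's acceptability column.
#'
#' @param seq_length Sequence length in nt.
#' @param assignment One element of [classify_stage1()]'s result.
#' @param stage2 Stage-2 hits restricted to this sequence and its best model
#'   (falls back to the best model's stage-1 hits when empty).
#' @param opts A [typer_opts()] object.
#' @return Character vector of detected features in canonical order.
#' @export
detect_features <- function(seq_length, assignment, stage2, opts = typer_opts()) {
  feats <- character(0)
  if (!is.null(opts$shortfail) && seq_length < opts$shortfail) feats <- c(feats, "TooShort")
  if (!is.null(opts$longfail) && seq_length > opts$longfail) feats <- c(feats, "TooLong")

  if (is.null(assignment$best_model)) {
    return(intersect(UNEXPECTED_FEATURES, c(feats, "NoHits")))
  }
  acc <- assignment$best_model$acceptability
  if (acc == "unacceptable") feats <- c(feats, "UnacceptableModel")
  if (acc == "questionable") feats <- c(feats, "QuestionableModel")
  if (length(assignment$families_hit) >= 2L) feats <- c(feats, "MultipleFamilies")
  if (all(c("plus", "minus") %in% assignment$strands_hit)) feats <- c(feats, "BothStrands")
  if (identical(assignment$best_strand, "minus")) feats <- c(feats, "MinusStrand")

  bm <- stage2
  if (nrow(bm) == 0L) {
    bm <- assignment$hits[assignment$hits$model_name ==
                            assignment$best_model$model_name, , drop = FALSE]
  }
  for (str in unique(bm$strand)) {
    g <- bm[bm$strand == str, , drop = FALSE]
    if (nrow(g) < 2L) next
    feats <- c(feats, "MultipleHits")
    # pairwise model-span overlap
    for (i in seq_len(nrow(g) - 1L)) {
      for (j in seq(i + 1L, nrow(g))) {
        if (model_overlap(g$model_start[[i]], g$model_stop[[i]],
                          g$model_start[[j]], g$model_stop[[j]]) >=
            opts$duplicate_overlap_min) {
          feats <- c(feats, "DuplicateRegion")
        }
      }
    }
    # order consistency between sequence and model coordinates
    s_lo <- pmin(g$seq_start, g$seq_stop)
    ord <- order(s_lo, g$model_start)
    ms <- g$model_start[ord]
    s_sorted <- s_lo[ord]
    strict <- s_sorted[-1L] > s_sorted[-length(s_sorted)]
    dm <- ms[-1L] - ms[-length(ms)]
    violated <- if (str == "plus") any(strict & dm < 0) else any(strict & dm > 0)
    if (violated) feats <- c(feats, "InconsistentHits")
  }

  total_score <- sum(bm$bit_score)
  if (total_score / seq_length < opts$low_score_bpnt) feats <- c(feats, "LowScore")
  cov <- hit_coverage(bm, seq_length)
  cov_floor <- if (!is.null(opts$tshort_len) && seq_length <= opts$tshort_len) {
    opts$tshort_coverage
  } else {
    opts$low_coverage
  }
  if (cov < cov_floor) feats <- c(feats, "LowCoverage")

  if (!is.na(assignment$second_score_other_domain)) {
    diff_bpp <- (assignment$best_score - assignment$second_score_other_domain) / seq_length
    if (diff_bpp < opts$low_diff_bpp) feats <- c(feats, "LowScoreDifference")
    if (diff_bpp < opts$very_low_diff_bpp) feats <- c(feats, "VeryLowScoreDifference")
  }

  if (opts$evalues && nrow(assignment$hits) >= 2L) {
    h <- assignment$hits
    ord <- order(h$e_value, -h$bit_score)
    if (h$bit_score[ord[1L]] < h$bit_score[ord[2L]]) {
      feats <- c(feats, "EvalueScoreDiscrepancy")
    }
  }
  intersect(UNEXPECTED_FEATURES, unique(feats))
}

#' Pass/fail verdict from a feature set
#'
#' A sequence fails iff any detected feature is in the fatal set implied by
#' the options; the failure reasons are the fatal detected features in
#' canonical order.
#'
#' @param features Character vector from [detect_features()].
#' @param opts A [typer_opts()] object.
#' @return List with `pass` (logical) and `reasons` (character).
#' @export
typer_verdict <- function(features, opts = typer_opts()) {
  reasons <- intersect(features, fatal_features(opts))
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Two-stage profile validation of a sequence set
#'
#' Runs stage-1 classification, the sixteen feature detectors against the
#' stage-2 hits of each sequence's best model, and the pass/fail verdict.
#'
#' @param seqs Sequence table from [read_fasta()].
#' @param stage1 Stage-1 profile hits (`stage == 1`).
#' @param stage2 Stage-2 profile hits (`stage == 2`); may be empty, in which
#'   case stage-1 hits to the best model stand in.
#' @param models Model registry.
#' @param opts A [typer_opts()] object.
#' @return A `data.frame` (class `typer_result`) with one row per sequence:
#'   pass/fail, best model and score, bits per nt, coverage, and
#'   semicolon-joined feature and reason lists.
#' @export
profile_validate <- function(seqs, stage1, stage2 = empty_profile_hits(),
                             models, opts = typer_opts()) {
  validate_profile_hits(stage2, models)
  assignments <- classify_stage1(stage1, models, seq_ids = seqs$seq_id)
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    sid <- seqs$seq_id[[i]]
    len <- seqs$length[[i]]
    asg <- assignments[[sid]]
    bm_name <- if (is.null(asg$best_model)) NA_character_ else asg$best_model$model_name
    s2 <- stage2[stage2$seq_id == sid & stage2$stage == 2L &
                   !is.na(bm_name) & stage2$model_name %in% bm_name, , drop = FALSE]
    feats <- detect_features(len, asg, s2, opts)
    verdict <- typer_verdict(feats, opts)
    bm <- if (nrow(s2) > 0L) s2 else if (!is.null(asg$best_model)) {
      asg$hits[asg$hits$model_name == bm_name, , drop = FALSE]
    } else {
      empty_profile_hits()
    }
    data.frame(
      seq_id = sid, length = len,
      pass = verdict$pass,
      best_model = bm_name,
      family = if (is.null(asg$best_model)) NA_character_ else asg$best_model$family,
      domain = if (is.null(asg$best_model)) NA_character_ else asg$best_model$domain,
      best_score = asg$best_score,
      bits_per_nt = if (nrow(bm) > 0L) sum(bm$bit_score) / len else NA_real_,
      coverage = if (nrow(bm) > 0L) hit_coverage(bm, len) else NA_real_,
      features = paste(feats, collapse = ";"),
      reasons = paste(verdict$reasons, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("typer_result", "data.frame")
  attr(res, "opts") <- opts
  res
}

#' @export
print.typer_result <- function(x, ...) {
  cat("Profile validation of", nrow(x), "sequence(s):",
      sum(x$pass), "pass,", sum(!x$pass), "fail\n")
  print.data.frame(x[, c("seq_id", "pass", "best_model", "bits_per_nt",
                         "coverage", "features")], ...)
  invisible(x)
}
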