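# Run-both-and-combine logic: length partitions, four outcome classes, the
# static mapping from engine errors to GenBank-style errors with the two
# footnote suppression rules, and submitter/indexer routing.

#' Outcome class labels
#' @export
OUTCOME_CLASSES <- c("RPSP", "RPSF", "RFSP", "RFSF")

# profile-side features that have a combined-mode error name (R_ prefix)
TYPER_ERROR_FEATURES <- c("NoHits", "MultipleFamilies", "LowScore",
                          "BothStrands", "InconsistentHits", "DuplicateRegion",
                          "UnacceptableModel", "LowCoverage",
                          "QuestionableModel", "MultipleHits")

# source error -> GenBank-style error (total over both engines' error names)
GENBANK_ERROR_MAP <- c(
  S_NoHits = "SEQ_HOM_NotSSUOrLSUrRNA",
  S_NoSimilarity = "SEQ_HOM_LowSimilarity",
  S_LowSimilarity = "SEQ_HOM_LowSimilarity",
  S_LowScore = "SEQ_HOM_LowSimilarity",
  S_BothStrands = "SEQ_HOM_MisAsBothStrands",
  S_MultipleHits = "SEQ_HOM_MultipleHits",
  R_NoHits = "SEQ_HOM_NotSSUOrLSUrRNA",
  R_MultipleFamilies = "SEQ_HOM_SSUAndLSUrRNA",
  R_LowScore = "SEQ_HOM_LowSimilarity",
  R_BothStrands = "SEQ_HOM_MisAsBothStrands",
  R_InconsistentHits = "SEQ_HOM_MisAsHitOrder",
  R_DuplicateRegion = "SEQ_HOM_MisAsDupRegion",
  R_UnacceptableModel = "SEQ_HOM_TaxNotExpectedSSUrRNA",
  R_LowCoverage = "SEQ_HOM_LowCoverage",
  R_QuestionableModel = "SEQ_HOM_TaxQuestionableSSUrRNA",
  R_MultipleHits = "SEQ_HOM_MultipleHits"
)

# GenBank-style error -> recipient of the failure
GENBANK_FAILS_TO <- c(
  SEQ_HOM_NotSSUOrLSUrRNA = "submitter",
  SEQ_HOM_LowSimilarity = "submitter",
  SEQ_HOM_SSUAndLSUrRNA = "submitter",
  SEQ_HOM_MisAsBothStrands = "submitter",
  SEQ_HOM_MisAsHitOrder = "submitter",
  SEQ_HOM_MisAsDupRegion = "submitter",
  SEQ_HOM_TaxNotExpectedSSUrRNA = "submitter",
  SEQ_HOM_TaxQuestionableSSUrRNA = "indexer",
  SEQ_HOM_LowCoverage = "indexer",
  SEQ_HOM_MultipleHits = "indexer"
)

# blast-side errors suppressed under the first footnote rule
SUPPRESSIBLE_SENSOR_ERRORS <- c("S_NoHits", "S_NoSimilarity",
                                "S_LowSimilarity", "S_LowScore")
# profile-side errors suppressed when the sequence passes the blast engine
SUPPRESSIBLE_TYPER_ERRORS <- c("R_QuestionableModel", "R_MultipleHits")

#' Options for the combined validator
#'
#' @param mode `"16S"` (bacterial/archaeal SSU) or `"18S"` (eukaryotic SSU).
#'   The mode fixes the expected model set: in 16S mode, SSU models for
#'   bacteria, archaea and cyanobacteria are acceptable and the chloroplast
#'   SSU model is questionable; in 18S mode only the eukaryotic SSU model is
#'   acceptable. All other models are unacceptable.
#' @param strict_c Strict combining (`-c` semantics): blast-side similarity
#'   errors are no longer forgiven for sequences that pass the profile
#'   engine.
#' @param partitions Length partitions with per-partition blast thresholds:
#'   columns `lo`, `hi` (nt, inclusive), `min_id` (percent identity floor)
#'   and `min_coverage` (best-hit coverage floor). Defaults:
#'   100-350 nt at 75\%/0.80, 351-600 nt at 80\%/0.86, 601-2000 nt at
#'   86\%/0.86; sequences outside 100-2000 nt are not analyzed.
#' @param max_evalue Blast E-value ceiling for a `yes` verdict.
#' @return An object of class `combine_opts`.
#' @export
combine_opts <- function(mode = c("16S", "18S"), strict_c = FALSE,
                         partitions = NULL, max_evalue = 1e-40) {
  mode <- match.arg(mode)
  if (is.null(partitions)) {
    partitions <- data.frame(
      name = c("P1", "P2", "P3"),
      lo = c(100, 351, 601), hi = c(350, 600, 2000),
      min_id = c(75, 80, 86), min_coverage = c(0.80, 0.86, 0.86),
      stringsAsFactors = FALSE
    )
  }
  if (any(partitions$lo[-1L] != partitions$hi[-nrow(partitions)] + 1)) {
    stop("length partitions must be contiguous and non-overlapping")
  }
  structure(list(mode = mode, strict_c = strict_c, partitions = partitions,
                 max_evalue = max_evalue), class = "combine_opts")
}

#' Assign sequences to length partitions
#'
#' @param lengths Sequence lengths in nt.
#' @param opts A [combine_opts()] object.
#' @return Character vector over `{too_short, P1, P2, P3, too_long}` (total:
#'   every sequence is assigned).
#' @export
partition_by_length <- function(lengths, opts = combine_opts()) {
  p <- opts$partitions
  vapply(lengths, function(len) {
    if (len < min(p$lo)) return("too_short")
    if (len > max(p$hi)) return("too_long")
    p$name[[which(len >= p$lo & len <= p$hi)]]
  }, "")
}

#' Outcome class from the two pass/fail bits
#'
#' @param rt_pass Profile-engine pass bit.
#' @param sensor_pass Blast-engine pass bit.
#' @return `"RPSP"`, `"RPSF"`, `"RFSP"` or `"RFSF"` (vectorized).
#' @export
outcome_class <- function(rt_pass, sensor_pass) {
  paste0(ifelse(rt_pass, "RP", "RF"), ifelse(sensor_pass, "SP", "SF"))
}

#' Map engine errors to GenBank-style errors
#'
#' Applies the static mapping plus the two exception rules: the four
#' blast-side similarity errors are dropped when the sequence is `RPSF` and
#' strict combining is off, or when it is `RFSF` with `R_UnacceptableModel`
#' or `R_QuestionableModel` also reported; `R_QuestionableModel` and
#' `R_MultipleHits` are dropped when the sequence is `RFSP`. Results are
#' deduplicated and carry their submitter/indexer routing.
#'
#' @param outcome One of [OUTCOME_CLASSES].
#' @param rt_errors Profile-side error names (`R_` prefix).
#' @param sensor_errors Blast-side error names (`S_` prefix).
#' @param opts A [combine_opts()] object (for `strict_c`).
#' @return A `data.frame` with columns `genbank_error`, `fails_to` (possibly
#'   zero rows). Unknown source error names are a hard error.
#' @export
map_to_genbank_errors <- function(outcome, rt_errors, sensor_errors,
                                  opts = combine_opts()) {
  stopifnot(outcome %in% OUTCOME_CLASSES)
  errs <- c(sensor_errors, rt_errors)
  unknown <- setdiff(errs, names(GENBANK_ERROR_MAP))
  if (length(unknown) > 0L) {
    stop("unknown source error name(s): ", paste(unknown, collapse = ", "))
  }
  drop_sensor <- (outcome == "RPSF" && !opts$strict_c) ||
    (outcome == "RFSF" &&
       any(rt_errors %in% c("R_UnacceptableModel", "R_QuestionableModel")))
  if (drop_sensor) errs <- setdiff(errs, SUPPRESSIBLE_SENSOR_ERRORS)
  if (outcome == "RFSP") errs <- setdiff(errs, SUPPRESSIBLE_TYPER_ERRORS)
  gb <- unique(unname(GENBANK_ERROR_MAP[errs]))
  gb <- intersect(names(GENBANK_FAILS_TO), gb)  # canonical order
  data.frame(genbank_error = gb, fails_to = unname(GENBANK_FAILS_TO[gb]),
             stringsAsFactors = FALSE)
}

# registry acceptability implied by the combined-validator mode
mode_acceptability <- function(models, mode) {
  acc <- rep("unacceptable", nrow(models))
  if (mode == "16S") {
    acc[models$family == "SSU" &
          models$domain %in% c("bacteria", "archaea", "cyanobacteria")] <- "acceptable"
    acc[models$family == "SSU" & models$domain == "chloroplast"] <- "questionable"
  } else {
    acc[models$family == "SSU" & models$domain == "eukarya"] <- "acceptable"
  }
  models$acceptability <- acc
  models
}

#' Combined profile + blast validation
#'
#' Runs the profile engine (with the combined-mode option set: `LowScore`
#' and `LowCoverage` fatal, short-sequence coverage floor 0.80 at or below
#' 350 nt) and the blast engine with per-partition thresholds, assigns each
#' analyzed sequence an outcome class, maps the engine errors to
#' GenBank-style errors and routes failures. Sequences outside the hard
#' length bounds are not analyzed and cannot pass.
#'
#' @param seqs Sequence table.
#' @param stage1,stage2 Profile hit tables.
#' @param models Model registry (acceptability is overridden by the mode).
#' @param blast Blast hit table.
#' @param opts A [combine_opts()] object.
#' @return A `data.frame` (class `combine_result`) with per-sequence
#'   partition, both engines' verdicts and errors, outcome class, mapped
#'   GenBank errors, routing and final pass bit; attribute
#'   `submission_pass` is `TRUE` iff every sequence passes.
#' @export
combined_validate <- function(seqs, stage1, stage2, models, blast,
                              opts = combine_opts()) {
  models <- mode_acceptability(models, opts$mode)
  part <- partition_by_length(seqs$length, opts)
  t_opts <- typer_opts(scfail = TRUE, covfail = TRUE,
                       tshort_coverage = 0.80, tshort_len = 350)
  rt <- profile_validate(seqs, stage1, stage2, models, t_opts)

  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    sid <- seqs$seq_id[[i]]
    len <- seqs$length[[i]]
    base <- data.frame(seq_id = sid, length = len, partition = part[[i]],
                       stringsAsFactors = FALSE)
    if (part[[i]] %in% c("too_short", "too_long")) {
      base$rt_pass <- NA
      base$sensor_pass <- NA
      base$outcome <- part[[i]]
      base$rt_errors <- ""
      base$sensor_errors <- ""
      base$genbank_errors <- ""
      base$fails_to <- ""
      base$pass <- FALSE
      return(base)
    }
    p <- opts$partitions[opts$partitions$name == part[[i]], ]
    s_opts <- sensor_opts(min_length = min(opts$partitions$lo),
                          max_length = max(opts$partitions$hi),
                          min_id = p$min_id, max_evalue = opts$max_evalue,
                          min_coverage = p$min_coverage)
    h <- blast[blast$query_id == sid, , drop = FALSE]
    s_errs <- sensor_errors(len, h, s_opts)
    rt_row <- rt[rt$seq_id == sid, ]
    feats <- strsplit(rt_row$features, ";", fixed = TRUE)[[1L]]
    mappable <- intersect(feats, TYPER_ERROR_FEATURES)
    r_errs <- if (length(mappable) > 0L) paste0("R_", mappable) else character(0)
    out <- outcome_class(rt_row$pass, length(s_errs) == 0L)
    gb <- map_to_genbank_errors(out, r_errs, s_errs, opts)
    routing <- if (nrow(gb) == 0L) "" else {
      if (any(gb$fails_to == "submitter")) "submitter" else "indexer"
    }
    base$rt_pass <- rt_row$pass
    base$sensor_pass <- length(s_errs) == 0L
    base$outcome <- out
    base$rt_errors <- paste(r_errs, collapse = ";")
    base$sensor_errors <- paste(s_errs, collapse = ";")
    base$genbank_errors <- paste(gb$genbank_error, collapse = ";")
    base$fails_to <- routing
    base$pass <- nrow(gb) == 0L
    base
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("combine_result", "data.frame")
  attr(res, "submission_pass") <- all(res$pass)
  res
}

#' @export
print.combine_result <- function(x, ...) {
  cat("Combined validation of", nrow(x), "sequence(s):",
      sum(x$pass), "pass,", sum(!x$pass), "fail;",
      "submission", if (attr(x, "submission_pass")) "PASSES" else "FAILS", "\n")
  print(table(x$outcome))
  invisible(x)
}
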