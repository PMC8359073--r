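# Single-sequence blastn-based screening: the five-class verdict and, in
# combined mode, the six blast-side error diagnostics.

#' Sensor error labels
#' @export
SENSOR_ERRORS <- c("S_NoHits", "S_NoSimilarity", "S_LowSimilarity",
                   "S_LowScore", "S_BothStrands", "S_MultipleHits")

#' Five sensor class labels
#' @export
SENSOR_CLASSES <- c("too_long", "too_short", "no", "yes", "imperfect_match")

#' Options for blastn-based screening
#'
#' Defaults mirror the permissive screening regime for prokaryotic SSU rRNA:
#' length window \[400, 2500\] nt, minimum identity 80\%, maximum E-value
#' 1e-40.
#'
#' @param min_length,max_length Allowed sequence length window in nt.
#' @param min_id Minimum percent identity for a `yes` verdict.
#' @param max_evalue Maximum E-value for a `yes` verdict.
#' @param min_coverage Best-hit coverage floor used by the error diagnostics
#'   in combined mode (proportion of the query covered by the best hit).
#' @param nosimilarity_floor Best-hit coverage below which the stronger
#'   `S_NoSimilarity` diagnostic is reported instead of `S_LowSimilarity`.
#' @return An object of class `sensor_opts`.
#' @export
sensor_opts <- function(min_length = 400, max_length = 2500, min_id = 80,
                        max_evalue = 1e-40, min_coverage = 0.86,
                        nosimilarity_floor = 0.10) {
  stopifnot(min_length <= max_length, min_id >= 0, min_id <= 100,
            max_evalue >= 0, min_coverage >= 0, min_coverage <= 1)
  structure(list(min_length = min_length, max_length = max_length,
                 min_id = min_id, max_evalue = max_evalue,
                 min_coverage = min_coverage,
                 nosimilarity_floor = nosimilarity_floor),
            class = "sensor_opts")
}

# best hit: lowest E-value, ties by higher bit score
best_blast_hit <- function(hits) {
  hits[order(hits$e_value, -hits$bit_score)[1L], , drop = FALSE]
}

#' Classify one sequence into the five sensor classes
#'
#' Length gates apply first and are total: a sequence outside
#' `[min_length, max_length]` is `too_short`/`too_long` and its blast hits
#' are not evaluated. In-range sequences are `no` (zero hits), `yes` (at
#' least one hit meeting both the E-value and identity thresholds) or
#' `imperfect_match` (hits exist but none meets both).
#'
#' @param seq_length Query sequence length in nt.
#' @param hits Blast hits of this sequence against the verified database.
#' @param opts A [sensor_opts()] object.
#' @return List with `klass`, `n_hits`, and best-hit summaries
#'   (`best_coverage`, `best_identity`, `best_evalue`; `NA` when not
#'   evaluated).
#' @export
sensor_classify <- function(seq_length, hits, opts = sensor_opts()) {
  if (seq_length > opts$max_length) {
    return(list(klass = "too_long", n_hits = NA_integer_,
                best_coverage = NA_real_, best_identity = NA_real_,
                best_evalue = NA_real_))
  }
  if (seq_length < opts$min_length) {
    return(list(klass = "too_short", n_hits = NA_integer_,
                best_coverage = NA_real_, best_identity = NA_real_,
                best_evalue = NA_real_))
  }
  if (nrow(hits) == 0L) {
    return(list(klass = "no", n_hits = 0L, best_coverage = 0,
                best_identity = NA_real_, best_evalue = NA_real_))
  }
  best <- best_blast_hit(hits)
  ok <- hits$e_value <= opts$max_evalue & hits$pct_identity >= opts$min_id
  list(klass = if (any(ok)) "yes" else "imperfect_match",
       n_hits = nrow(hits),
       best_coverage = best$aln_length / seq_length,
       best_identity = best$pct_identity,
       best_evalue = best$e_value)
}

#' Blast-side error diagnostics (combined mode)
#'
#' Evaluated with the per-length-partition identity and coverage thresholds
#' supplied in `opts`. Coverage is the best hit's alignment length divided by
#' the query length; `S_NoSimilarity` (coverage below 10\%) pre-empts
#' `S_LowSimilarity` (coverage below the partition floor).
#'
#' @inheritParams sensor_classify
#' @return Character vector, a subset of [SENSOR_ERRORS].
#' @export
sensor_errors <- function(seq_length, hits, opts = sensor_opts()) {
  if (nrow(hits) == 0L) return("S_NoHits")
  errs <- character(0)
  best <- best_blast_hit(hits)
  cov <- best$aln_length / seq_length
  if (cov < opts$nosimilarity_floor) {
    errs <- c(errs, "S_NoSimilarity")
  } else if (cov < opts$min_coverage) {
    errs <- c(errs, "S_LowSimilarity")
  }
  ok <- hits$e_value <= opts$max_evalue & hits$pct_identity >= opts$min_id
  if (!any(ok)) errs <- c(errs, "S_LowScore")
  if (all(c("plus", "minus") %in% hits$strand)) errs <- c(errs, "S_BothStrands")
  if (nrow(hits) > 1L) errs <- c(errs, "S_MultipleHits")
  intersect(SENSOR_ERRORS, errs)
}

#' Blastn-based screening of a sequence set
#'
#' @param seqs Sequence table.
#' @param blast Blast hit table (`query_id` keyed).
#' @param opts A [sensor_opts()] object.
#' @param errors Also evaluate the combined-mode error diagnostics.
#' @return A `data.frame` (class `sensor_result`): per sequence, length, the
#'   five-class verdict, hit count and best-hit summary (and `errors` when
#'   requested).
#' @export
blast_validate <- function(seqs, blast, opts = sensor_opts(), errors = FALSE) {
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    sid <- seqs$seq_id[[i]]
    len <- seqs$length[[i]]
    h <- blast[blast$query_id == sid, , drop = FALSE]
    cls <- sensor_classify(len, h, opts)
    out <- data.frame(seq_id = sid, length = len, klass = cls$klass,
                      n_hits = cls$n_hits, best_coverage = cls$best_coverage,
                      best_identity = cls$best_identity,
                      best_evalue = cls$best_evalue, stringsAsFactors = FALSE)
    if (errors) {
      errs <- if (cls$klass %in% c("too_short", "too_long")) character(0) else {
        sensor_errors(len, h, opts)
      }
      out$errors <- paste(errs, collapse = ";")
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("sensor_result", "data.frame")
  res
}

#' @export
print.sensor_result <- function(x, ...) {
  cat("Blast screening of", nrow(x), "sequence(s)\n")
  print(table(x$klass))
  invisible(x)
}
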