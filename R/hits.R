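# Parsing of tabular homology-search output and interval arithmetic shared by
# every engine. Two dialects are supported: a normalized 10-column profile hit
# table (a fixed simplification of Infernal/HMMER tblout) and 12-column
# blastn tabular output (outfmt 6).

#' Read a model registry
#'
#' TSV with columns `model_name`, `family` (SSU/LSU), `domain` (taxonomic
#' group label such as bacteria, archaea, eukarya, cyanobacteria,
#' chloroplast), `model_length` (number of reference model positions) and
#' `acceptability` (one of acceptable/unacceptable/questionable, mirroring an
#' `--inaccept`-style input list). Header optional, `#` comments skipped.
#'
#' @param path Path to the registry TSV.
#' @return A validated `data.frame`.
#' @export
read_model_registry <- function(path) {
  if (!file.exists(path)) stop("model registry not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) > 0L &&
      is.na(suppressWarnings(as.numeric(parts[[1L]][[4L]])))) {
    parts <- parts[-1L]
  }
  bad <- which(lengths(parts) != 5L)
  if (length(bad) > 0L) stop("model registry line ", bad[[1L]], ": expected 5 fields")
  reg <- data.frame(
    model_name = vapply(parts, `[[`, "", 1L),
    family = vapply(parts, `[[`, "", 2L),
    domain = vapply(parts, `[[`, "", 3L),
    model_length = as.numeric(vapply(parts, `[[`, "", 4L)),
    acceptability = vapply(parts, `[[`, "", 5L),
    stringsAsFactors = FALSE
  )
  validate_model_registry(reg)
}

validate_model_registry <- function(reg) {
  if (anyDuplicated(reg$model_name)) stop("duplicate model names in registry")
  if (any(is.na(reg$model_length)) || any(reg$model_length < 1)) {
    stop("model_length must be >= 1 for all models")
  }
  ok <- reg$acceptability %in% c("acceptable", "unacceptable", "questionable")
  if (!all(ok)) {
    stop("invalid acceptability value(s): ",
         paste(unique(reg$acceptability[!ok]), collapse = ", "))
  }
  reg
}

#' Construct a model registry in code
#'
#' @param model_name,family,domain,model_length,acceptability Column vectors;
#'   see [read_model_registry()].
#' @return A validated registry `data.frame`.
#' @export
model_registry <- function(model_name, family, domain, model_length,
                           acceptability = "acceptable") {
  validate_model_registry(data.frame(
    model_name = model_name, family = family, domain = domain,
    model_length = model_length,
    acceptability = rep_len(acceptability, length(model_name)),
    stringsAsFactors = FALSE
  ))
}

#' Read normalized profile hits
#'
#' Whitespace-delimited rows with 10 columns: `seq_id`, `model_name`,
#' `model_start`, `model_stop`, `seq_start`, `seq_stop`, `strand` (`+`/`-`),
#' `bit_score`, `e_value`, `stage` (1 or 2). `#` comment lines are ignored.
#' Sequence coordinates are 1-based inclusive and run backwards on the minus
#' strand; model coordinates always run forwards.
#'
#' @param path Path to the hit table.
#' @param models Optional model registry; hits to unregistered models are an
#'   error listing the registered model names.
#' @return A `data.frame` of hits with `strand` as `"plus"`/`"minus"`.
#' @export
read_profile_hits <- function(path, models = NULL) {
  if (!file.exists(path)) stop("profile hit file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  if (length(parts) == 0L) return(empty_profile_hits())
  bad <- which(lengths(parts) != 10L)
  if (length(bad) > 0L) {
    stop(path, " line ", lineno[bad[[1L]]], ": expected 10 fields, found ",
         lengths(parts)[bad[[1L]]])
  }
  num <- function(k) as.numeric(vapply(parts, `[[`, "", k))
  strand_sym <- vapply(parts, `[[`, "", 7L)
  if (!all(strand_sym %in% c("+", "-"))) {
    stop(path, " line ", lineno[which(!strand_sym %in% c("+", "-"))[1L]],
         ": strand must be '+' or '-'")
  }
  hits <- data.frame(
    seq_id = vapply(parts, `[[`, "", 1L),
    model_name = vapply(parts, `[[`, "", 2L),
    model_start = num(3L), model_stop = num(4L),
    seq_start = num(5L), seq_stop = num(6L),
    strand = ifelse(strand_sym == "+", "plus", "minus"),
    bit_score = num(8L), e_value = num(9L),
    stage = as.integer(num(10L)),
    stringsAsFactors = FALSE
  )
  coords <- c("model_start", "model_stop", "seq_start", "seq_stop",
              "bit_score", "e_value")
  for (col in coords) {
    if (anyNA(hits[[col]])) {
      stop(path, " line ", lineno[which(is.na(hits[[col]]))[1L]],
           ": malformed numeric field '", col, "'")
    }
  }
  validate_profile_hits(hits, models, path = path, lineno = lineno)
}

empty_profile_hits <- function() {
  data.frame(seq_id = character(0), model_name = character(0),
             model_start = numeric(0), model_stop = numeric(0),
             seq_start = numeric(0), seq_stop = numeric(0),
             strand = character(0), bit_score = numeric(0),
             e_value = numeric(0), stage = integer(0),
             stringsAsFactors = FALSE)
}

validate_profile_hits <- function(hits, models = NULL, path = "profile hits",
                                  lineno = seq_len(nrow(hits))) {
  if (nrow(hits) == 0L) return(hits)
  bad <- hits$model_start > hits$model_stop
  if (any(bad)) {
    stop(path, " line ", lineno[which(bad)[1L]], ": model_start > model_stop")
  }
  bad <- ifelse(hits$strand == "plus",
                hits$seq_start > hits$seq_stop,
                hits$seq_start < hits$seq_stop)
  if (any(bad)) {
    stop(path, " line ", lineno[which(bad)[1L]],
         ": sequence coordinates inconsistent with strand")
  }
  if (any(!is.finite(hits$bit_score))) stop(path, ": non-finite bit score")
  if (any(hits$e_value < 0)) stop(path, ": negative E-value")
  if (!all(hits$stage %in% c(1L, 2L))) stop(path, ": stage must be 1 or 2")
  if (!is.null(models)) {
    unknown <- setdiff(hits$model_name, models$model_name)
    if (length(unknown) > 0L) {
      stop(path, ": unknown model(s) ", paste(unknown, collapse = ", "),
           "; registered models: ", paste(models$model_name, collapse = ", "))
    }
  }
  hits
}

#' Write normalized profile hits
#'
#' Inverse of [read_profile_hits()]; used by the fixture generator.
#'
#' @param hits Profile hit table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_hits <- function(hits, path) {
  lines <- c("# seq_id model model_start model_stop seq_start seq_stop strand bit_score e_value stage")
  if (nrow(hits) > 0L) {
    lines <- c(lines, paste(
      hits$seq_id, hits$model_name,
      format_num(hits$model_start), format_num(hits$model_stop),
      format_num(hits$seq_start), format_num(hits$seq_stop),
      ifelse(hits$strand == "plus", "+", "-"),
      format_num(hits$bit_score), format_num(hits$e_value), hits$stage
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

format_num <- function(x) {
  vapply(x, function(v) format(v, scientific = v != 0 && abs(v) < 1e-4,
                               trim = TRUE, digits = 12),
         "")
}

#' Convert genuine Infernal tblout to the normalized dialect
#'
#' Convenience plumbing for users with real `cmsearch --tblout` output
#' (18+ whitespace-delimited columns). Only the coordinate, strand, score and
#' E-value columns are retained.
#'
#' @param path Path to a cmsearch/cmscan tblout file.
#' @param stage Stage number to assign to the converted hits (1 or 2).
#' @return A normalized profile hit `data.frame`.
#' @export
convert_infernal_tblout <- function(path, stage = 1L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_profile_hits())
  parts <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(parts) < 17L)) stop("not a cmsearch tblout file: ", path)
  num <- function(k) as.numeric(vapply(parts, `[[`, "", k))
  hits <- data.frame(
    seq_id = vapply(parts, `[[`, "", 1L),
    model_name = vapply(parts, `[[`, "", 3L),
    model_start = num(6L), model_stop = num(7L),
    seq_start = num(8L), seq_stop = num(9L),
    strand = ifelse(vapply(parts, `[[`, "", 10L) == "+", "plus", "minus"),
    bit_score = num(15L), e_value = num(16L),
    stage = as.integer(stage),
    stringsAsFactors = FALSE
  )
  validate_profile_hits(hits, path = path)
}

#' Read blastn tabular hits (outfmt 6)
#'
#' Standard 12 columns: qid, sid, pident, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, bitscore. Strand is derived: minus iff
#' `sstart > send`.
#'
#' @param path Path to the tabular file.
#' @return A `data.frame` of hits with a derived `strand` column.
#' @export
read_blast_hits <- function(path) {
  if (!file.exists(path)) stop("blast tabular file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(parts) == 0L) return(empty_blast_hits())
  bad <- which(lengths(parts) != 12L)
  if (length(bad) > 0L) {
    stop(path, " line ", lineno[bad[[1L]]], ": expected 12 tab-separated fields")
  }
  num <- function(k) as.numeric(vapply(parts, `[[`, "", k))
  hits <- data.frame(
    query_id = vapply(parts, `[[`, "", 1L),
    subject_id = vapply(parts, `[[`, "", 2L),
    pct_identity = num(3L), aln_length = num(4L),
    mismatches = num(5L), gap_opens = num(6L),
    q_start = num(7L), q_stop = num(8L),
    s_start = num(9L), s_stop = num(10L),
    e_value = num(11L), bit_score = num(12L),
    stringsAsFactors = FALSE
  )
  hits$strand <- ifelse(hits$s_start > hits$s_stop, "minus", "plus")
  validate_blast_hits(hits)
}

empty_blast_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), aln_length = numeric(0),
             mismatches = numeric(0), gap_opens = numeric(0),
             q_start = numeric(0), q_stop = numeric(0),
             s_start = numeric(0), s_stop = numeric(0),
             e_value = numeric(0), bit_score = numeric(0),
             strand = character(0), stringsAsFactors = FALSE)
}

validate_blast_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
    stop("percent identity outside [0,100]")
  }
  if (any(hits$aln_length < 1)) stop("alignment length must be >= 1")
  hits
}

#' Write blastn tabular hits
#' @param hits Blast hit table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_hits <- function(hits, path) {
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "mismatches", "gap_opens", "q_start", "q_stop", "s_start",
            "s_stop", "e_value", "bit_score")
  lines <- if (nrow(hits) == 0L) character(0) else {
    do.call(paste, c(lapply(cols, function(cn) {
      v <- hits[[cn]]
      if (is.numeric(v)) format_num(v) else v
    }), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Merge 1-based inclusive intervals
#'
#' Returns the disjoint sorted union; adjacent intervals (gap 0) are merged,
#' intervals separated by at least one position are not.
#'
#' @param intervals Two-column matrix or data.frame of `start`, `stop` pairs
#'   with `start <= stop`.
#' @return A `data.frame` with columns `start`, `stop`.
#' @export
merge_intervals <- function(intervals) {
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) == 0L) {
    return(data.frame(start = numeric(0), stop = numeric(0)))
  }
  start <- intervals[[1L]]
  stop_ <- intervals[[2L]]
  if (any(start > stop_)) stop("interval with start > stop")
  r <- IRanges::reduce(IRanges::IRanges(start = start, end = stop_))
  data.frame(start = as.numeric(IRanges::start(r)),
             stop = as.numeric(IRanges::end(r)))
}

#' Fraction of a sequence covered by profile hits
#'
#' Sequence spans of all hits are normalized to `(min, max)` regardless of
#' strand, merged, and the covered length is divided by the sequence length,
#' so duplicated or overlapping hits never push coverage above 1.
#'
#' @param hits Profile hits, all for one sequence.
#' @param seq_length Sequence length in nt (`>= 1`).
#' @return Coverage proportion in `[0, 1]`.
#' @export
hit_coverage <- function(hits, seq_length) {
  stopifnot(seq_length >= 1)
  if (nrow(hits) == 0L) return(0)
  spans <- data.frame(start = pmin(hits$seq_start, hits$seq_stop),
                      stop = pmax(hits$seq_start, hits$seq_stop))
  merged <- merge_intervals(spans)
  sum(merged$stop - merged$start + 1) / seq_length
}
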