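# Alignment post-processing: Stockholm parsing with the per-column reference
# (#=GC RF) annotation, model spans, terminal indel counts and the thirteen
# length classes.

#' The thirteen length-class labels
#'
#' A sequence's aligned span either reaches neither model terminus
#' (`partial`), both (`full-*`), only the first (`5flush-*`) or only the
#' final one (`3flush-*`); the sub-label summarizes insertions and deletions
#' within the terminal window at the flush end(s): `exact` (none), `extra`
#' (insertions only), `ambig-more`/`ambig-less` (deletions present, with
#' insertions exceeding them or not).
#' @export
LENGTH_CLASSES <- c(
  "partial",
  "full-exact", "full-extra", "full-ambig-more", "full-ambig-less",
  "5flush-exact", "5flush-extra", "5flush-ambig-more", "5flush-ambig-less",
  "3flush-exact", "3flush-extra", "3flush-ambig-more", "3flush-ambig-less"
)

#' Read a reference-annotated Stockholm alignment
#'
#' Single-alignment Stockholm with a `#=GC RF` line; columns whose RF
#' character is alphanumeric are consensus (reference model) positions, gap
#' characters mark insert columns. Interleaved (multi-block) files are
#' supported. A missing RF line or ragged rows are hard errors.
#'
#' @param path Path to the Stockholm file.
#' @return An object of class `ref_alignment`: list with `rows` (named
#'   character vector of aligned sequences), `rf` (the RF string), `rf_mask`
#'   (logical per column), `columns` and `model_length`.
#' @export
read_stockholm <- function(path) {
  if (!file.exists(path)) stop("Stockholm file not found: ", path)
  lines <- readLines(path)
  rows <- list()
  rf <- character(0)
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || ln == "//" || grepl("^# STOCKHOLM", ln)) next
    if (startsWith(ln, "#=GC RF")) {
      rf <- c(rf, sub("^#=GC RF\\s+", "", ln))
      next
    }
    if (startsWith(ln, "#")) next  # other annotation lines ignored
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) != 2L) stop("malformed Stockholm row: ", ln)
    nm <- parts[[1L]]
    rows[[nm]] <- paste0(if (is.null(rows[[nm]])) "" else rows[[nm]], parts[[2L]])
  }
  if (length(rf) == 0L) stop("Stockholm alignment lacks a #=GC RF reference line")
  rf <- paste(rf, collapse = "")
  widths <- nchar(unlist(rows))
  if (length(rows) == 0L) stop("Stockholm alignment has no sequence rows")
  if (any(widths != nchar(rf))) {
    stop("ragged Stockholm alignment: rows and RF line differ in length")
  }
  as_ref_alignment(unlist(rows), rf)
}

#' Build a reference alignment in code
#'
#' @param rows Named character vector of aligned rows (equal widths).
#' @param rf Reference annotation string of the same width; alphanumeric
#'   characters mark consensus columns.
#' @return A `ref_alignment` object.
#' @export
as_ref_alignment <- function(rows, rf) {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("alignment rows must be named")
  }
  if (any(nchar(rows) != nchar(rf))) stop("alignment rows must match RF width")
  rf_mask <- grepl("[A-Za-z0-9]", strsplit(rf, "")[[1L]])
  structure(list(rows = rows, rf = rf, rf_mask = rf_mask,
                 columns = nchar(rf), model_length = sum(rf_mask)),
            class = "ref_alignment")
}

#' @export
print.ref_alignment <- function(x, ...) {
  cat("Reference alignment:", length(x$rows), "row(s),", x$columns,
      "column(s),", x$model_length, "consensus position(s)\n")
  invisible(x)
}

#' Write a reference alignment to Stockholm
#' @param aln A `ref_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(aln, path) {
  nm <- c(names(aln$rows), "#=GC RF")
  pad <- formatC(nm, width = max(nchar(nm)) + 2L, flag = "-")
  writeLines(c("# STOCKHOLM 1.0", "",
               paste0(pad, c(unname(aln$rows), aln$rf)), "//"), path)
  invisible(path)
}

# per-row logicals: residue present at each alignment column
row_residue_mask <- function(aln, seq_id) {
  if (!seq_id %in% names(aln$rows)) {
    stop("sequence ", seq_id, " not in alignment")
  }
  row <- aln$rows[[seq_id]]
  !(strsplit(row, "")[[1L]] %in% GAP_CHARS)
}

#' First and last consensus position covered by a row
#'
#' Model coordinates are 1-based indices into the consensus (RF) columns.
#' Residues confined to insert columns do not extend the span: it starts at
#' the first occupied consensus column.
#'
#' @param aln A `ref_alignment`.
#' @param seq_id Row name.
#' @return Numeric `c(model_start, model_stop)`.
#' @export
model_span <- function(aln, seq_id) {
  res <- row_residue_mask(aln, seq_id)
  if (!any(res)) stop("sequence ", seq_id, " is all-gap in the alignment")
  occupied <- which(res[aln$rf_mask])
  if (length(occupied) == 0L) {
    stop("sequence ", seq_id, " has residues only in insert columns")
  }
  c(model_start = min(occupied), model_stop = max(occupied))
}

#' Insertion and deletion counts in the terminal model windows
#'
#' Deletions are gap characters at consensus columns whose model position
#' falls in the first (`del5`) or final (`del3`) `window` positions.
#' Insertions are residues in insert columns, each attributed to the number
#' of consensus columns preceding it: attributions `0..window-1` count
#' toward `ins5`, attributions `model_length-window+1..model_length` toward
#' `ins3`. Windows are truncated when the model is shorter than `2*window`.
#'
#' @param aln A `ref_alignment`.
#' @param seq_id Row name.
#' @param window Window size in model positions (default 10).
#' @return Numeric vector `c(ins5, del5, ins3, del3)`.
#' @export
terminal_indels <- function(aln, seq_id, window = 10L) {
  res <- row_residue_mask(aln, seq_id)
  L <- aln$model_length
  w <- min(window, L)
  att <- cumsum(aln$rf_mask)  # consensus col: its model position; insert col: preceding one
  cons <- aln$rf_mask
  del5 <- sum(cons & att >= 1 & att <= w & !res)
  del3 <- sum(cons & att >= L - w + 1 & !res)
  ins5 <- sum(!cons & att <= w - 1 & res)
  ins3 <- sum(!cons & att >= L - w + 1 & res)
  c(ins5 = ins5, del5 = del5, ins3 = ins3, del3 = del3)
}

#' Assign one of the thirteen length classes
#'
#' @param span Numeric `c(model_start, model_stop)` from [model_span()].
#' @param indels Numeric `c(ins5, del5, ins3, del3)` from
#'   [terminal_indels()].
#' @param model_length Number of consensus positions in the model.
#' @return One of [LENGTH_CLASSES]. The classification is total and
#'   exclusive.
#' @export
length_class <- function(span, indels, model_length) {
  stopifnot(span[[1L]] >= 1, span[[1L]] <= span[[2L]],
            span[[2L]] <= model_length, all(indels >= 0))
  reaches5 <- span[[1L]] == 1
  reaches3 <- span[[2L]] == model_length
  if (!reaches5 && !reaches3) return("partial")
  prefix <- if (reaches5 && reaches3) "full" else if (reaches5) "5flush" else "3flush"
  ins <- (if (reaches5) indels[["ins5"]] else 0) + (if (reaches3) indels[["ins3"]] else 0)
  del <- (if (reaches5) indels[["del5"]] else 0) + (if (reaches3) indels[["del3"]] else 0)
  sub <- if (del == 0 && ins == 0) "exact"
    else if (del == 0) "extra"
    else if (ins > del) "ambig-more"
    else "ambig-less"
  paste0(prefix, "-", sub)
}

#' Length-classify aligned sequences
#'
#' @param aln A `ref_alignment`.
#' @param seq_ids Rows to classify (default: all).
#' @param window Terminal window size in model positions.
#' @return A `data.frame` with `seq_id`, `model_start`, `model_stop`,
#'   `ins5`, `del5`, `ins3`, `del3` and `length_class`.
#' @export
length_classify <- function(aln, seq_ids = names(aln$rows), window = 10L) {
  rows <- lapply(seq_ids, function(sid) {
    span <- model_span(aln, sid)
    ind <- terminal_indels(aln, sid, window)
    data.frame(seq_id = sid,
               model_start = span[["model_start"]],
               model_stop = span[["model_stop"]],
               ins5 = ind[["ins5"]], del5 = ind[["del5"]],
               ins3 = ind[["ins3"]], del3 = ind[["del3"]],
               length_class = length_class(span, ind, aln$model_length),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Profile validation plus alignment-based length classification
#'
#' Runs the profile validator with the aligner's stricter defaults
#' (minus-strand, low-score and low-coverage features fatal), then appends
#' the length classification for passing sequences whose best model is
#' acceptable. Pass/fail designations are never altered by the length step;
#' failing sequences carry `NA` length columns.
#'
#' @param seqs Sequence table.
#' @param stage1,stage2 Profile hit tables.
#' @param models Model registry; the acceptable set plays the role of the
#'   desired-model list.
#' @param aln A `ref_alignment` holding rows for the passing sequences.
#' @param opts A [typer_opts()] object (default: `minusfail`, `scfail`,
#'   `covfail` active).
#' @param window Terminal window size in model positions.
#' @return The [profile_validate()] result with added length columns
#'   (class `aligner_result`).
#' @export
aligned_validate <- function(seqs, stage1, stage2, models, aln,
                             opts = typer_opts(minusfail = TRUE, scfail = TRUE,
                                               covfail = TRUE),
                             window = 10L) {
  rt <- profile_validate(seqs, stage1, stage2, models, opts)
  len_cols <- data.frame(model_start = NA_real_, model_stop = NA_real_,
                         ins5 = NA_real_, del5 = NA_real_, ins3 = NA_real_,
                         del3 = NA_real_, length_class = NA_character_,
                         stringsAsFactors = FALSE)
  res <- cbind(as.data.frame(rt), len_cols[rep(1L, nrow(rt)), , drop = FALSE])
  rownames(res) <- NULL
  eligible <- which(rt$pass & rt$seq_id %in% names(aln$rows))
  if (length(eligible) > 0L) {
    lc <- length_classify(aln, rt$seq_id[eligible], window)
    for (col in names(len_cols)) res[eligible, col] <- lc[[col]]
  }
  class(res) <- c("aligner_result", "data.frame")
  res
}

#' Pairwise alignment identity matrix
#'
#' Identity of two rows is the fraction of alignment columns where both have
#' residues and the residues match (`U` and `T` equated, case-insensitive);
#' rows sharing no columns get identity 0.
#'
#' @param aln A `ref_alignment`.
#' @return Symmetric numeric matrix with unit diagonal, dimnames = row
#'   names.
#' @export
alignment_identity <- function(aln) {
  n <- length(aln$rows)
  ids <- names(aln$rows)
  chars <- lapply(aln$rows, function(r) {
    v <- strsplit(chartr("uU", "tT", r), "")[[1L]]
    toupper(v)
  })
  res_mask <- lapply(chars, function(v) !(v %in% GAP_CHARS))
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      both <- res_mask[[i]] & res_mask[[j]]
      m[i, j] <- m[j, i] <- if (!any(both)) 0 else {
        sum(chars[[i]][both] == chars[[j]][both]) / sum(both)
      }
    }
  }
  m
}
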