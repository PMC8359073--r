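# FASTA and taxonomy input, per-sequence statistics used by the filters.

GAP_CHARS <- c("-", ".", "_", "~")

#' Read a FASTA file into a sequence table
#'
#' Reads nucleotide sequences (DNA or RNA alphabet) and computes the
#' per-sequence statistics used by the screening rules: length and the number
#' of ambiguous residues, i.e. residues outside `{A,C,G,T,U}` after
#' uppercasing. `U` is preserved, not converted to `T`.
#'
#' @param path Path to a FASTA file. Multi-line records are allowed.
#' @return A `data.frame` with columns `seq_id`, `description`, `residues`,
#'   `length` and `n_ambiguous`, in file order.
#' @details Duplicate sequence identifiers and empty sequences are hard
#'   errors: both indicate a malformed submission file.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 a test", "ACGTN"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seq_id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(seq_id))) stop("FASTA record with empty identifier in ", path)
  dup <- unique(seq_id[duplicated(seq_id)])
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  residues <- toupper(as.character(set))
  empty <- seq_id[nchar(residues) == 0L]
  if (length(empty) > 0L) {
    stop("empty sequence(s) in ", path, ": ", paste(empty, collapse = ", "))
  }
  as_seq_records(seq_id, residues, description)
}

#' Build a sequence table from character vectors
#'
#' @param seq_id Unique sequence identifiers.
#' @param residues Residue strings (uppercased on entry; `U` preserved).
#' @param description Optional free-text descriptions.
#' @return A sequence `data.frame` as returned by [read_fasta()].
#' @export
as_seq_records <- function(seq_id, residues, description = "") {
  stopifnot(length(seq_id) == length(residues))
  if (anyDuplicated(seq_id)) stop("duplicate sequence ids")
  residues <- toupper(residues)
  data.frame(
    seq_id = as.character(seq_id),
    description = rep_len(as.character(description), length(seq_id)),
    residues = residues,
    length = nchar(residues),
    n_ambiguous = nchar(gsub("[ACGTU]", "", residues, perl = TRUE)),
    stringsAsFactors = FALSE
  )
}

#' Write a sequence table to FASTA
#'
#' @param seqs Sequence table from [read_fasta()] or [as_seq_records()].
#' @param path Output path.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  headers <- ifelse(nzchar(seqs$description),
                    paste(seqs$seq_id, seqs$description),
                    seqs$seq_id)
  set <- Biostrings::BStringSet(seqs$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Ambiguous-nucleotide filter policy
#'
#' A sequence fails the ambiguity filter when its ambiguous-residue count
#' exceeds the smaller of an absolute cap and a fraction of its length.
#' Defaults: 5 residues and 0.5\% of the length.
#'
#' @param max_count Absolute cap on ambiguous residues (nonnegative integer).
#' @param max_fraction Fractional cap as a proportion of sequence length.
#' @return An object of class `ambiguity_policy`.
#' @export
ambiguity_policy <- function(max_count = 5, max_fraction = 0.005) {
  stopifnot(length(max_count) == 1L, max_count >= 0,
            length(max_fraction) == 1L, max_fraction >= 0, max_fraction <= 1)
  structure(list(max_count = max_count, max_fraction = max_fraction),
            class = "ambiguity_policy")
}

#' Apply the ambiguity filter
#'
#' The effective threshold is `min(max_count, max_fraction * length)`,
#' compared as a real number without rounding: a 600 nt sequence with
#' defaults has threshold exactly 3.
#'
#' @param seqs Sequence table (rows are tested independently).
#' @param policy An [ambiguity_policy()].
#' @return Logical vector: `TRUE` where the sequence passes.
#' @export
ambiguity_pass <- function(seqs, policy = ambiguity_policy()) {
  stopifnot(inherits(policy, "ambiguity_policy"))
  seqs$n_ambiguous <= pmin(policy$max_count, policy$max_fraction * seqs$length)
}

#' Read a taxonomy table
#'
#' Four-column TSV: `taxid`, `parent_taxid`, `rank`, `specified` (0/1 flag
#' marking a valid, currently preferred species-level name). A header line is
#' optional and `#` comment lines are skipped. The table must contain exactly
#' one root (a row whose parent is itself or 0) and every parent must be
#' present.
#'
#' @param path Path to the TSV file.
#' @return A validated `data.frame` with the four columns above.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("taxonomy file is empty: ", path)
  first <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (is.na(suppressWarnings(as.numeric(first[[1L]])))) lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad) > 0L) {
    stop("taxonomy line ", bad[[1L]], " does not have 4 tab-separated fields")
  }
  tab <- data.frame(
    taxid = as.numeric(vapply(parts, `[[`, "", 1L)),
    parent_taxid = as.numeric(vapply(parts, `[[`, "", 2L)),
    rank = vapply(parts, `[[`, "", 3L),
    specified = as.integer(vapply(parts, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  validate_taxonomy(tab)
}

validate_taxonomy <- function(tab) {
  if (anyNA(tab$taxid) || anyNA(tab$parent_taxid)) stop("non-numeric taxid in taxonomy table")
  if (anyDuplicated(tab$taxid)) stop("duplicate taxid in taxonomy table")
  if (!all(tab$specified %in% c(0L, 1L))) stop("specified flag must be 0 or 1")
  root <- tab$parent_taxid == tab$taxid | tab$parent_taxid == 0
  if (sum(root) != 1L) stop("taxonomy table must have exactly one root, found ", sum(root))
  missing_parent <- setdiff(tab$parent_taxid[!root], tab$taxid)
  if (length(missing_parent) > 0L) {
    stop("parent taxid(s) absent from taxonomy table: ",
         paste(missing_parent, collapse = ", "))
  }
  tab
}

# Walk ancestors of `taxid` (inclusive) until the root; returns the taxid at
# `rank`, or NA if no self-or-ancestor has that rank.
ancestor_at_rank <- function(taxid, taxonomy, rank = "species") {
  i <- match(taxid, taxonomy$taxid)
  if (is.na(i)) stop("taxid ", taxid, " not present in taxonomy table")
  for (step in seq_len(nrow(taxonomy) + 1L)) {
    if (taxonomy$rank[[i]] == rank) return(taxonomy$taxid[[i]])
    parent <- taxonomy$parent_taxid[[i]]
    if (parent == taxonomy$taxid[[i]] || parent == 0) return(NA_real_)
    i <- match(parent, taxonomy$taxid)
  }
  stop("cycle detected in taxonomy table at taxid ", taxid)
}

#' Species-rank taxid for a taxon
#'
#' @param taxid Taxid present in the taxonomy table.
#' @param taxonomy Table from [read_taxonomy()].
#' @return The species-rank self-or-ancestor taxid, or `NA` if the taxon has
#'   no species-rank ancestor.
#' @export
species_taxid <- function(taxid, taxonomy) {
  ancestor_at_rank(taxid, taxonomy, "species")
}

#' Specified-species test
#'
#' A taxon passes when its species-rank self-or-ancestor carries the
#' specified-species flag (a necessary condition for inclusion in curated
#' reference sets). Taxa with no species-rank ancestor fail.
#'
#' @inheritParams species_taxid
#' @return `TRUE` or `FALSE`. An absent taxid is an error.
#' @export
specified_species_pass <- function(taxid, taxonomy) {
  sp <- species_taxid(taxid, taxonomy)
  if (is.na(sp)) return(FALSE)
  taxonomy$specified[[match(sp, taxonomy$taxid)]] == 1L
}
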