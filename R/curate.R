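# Ordered eight-step curation pipeline for building high-quality rRNA
# reference sets: per-sequence filters, profile and alignment validation,
# model-span enforcement, ingroup analysis, optional one-per-taxid
# selection, and single-linkage clustering with centroid selection.

CURATION_STEPS <- c("ambiguity", "specified_species", "vecscreen",
                    "self_repeat", "profile_validation",
                    "alignment_validation", "model_span", "ingroup")

#' Options for the curation pipeline
#'
#' Defaults mirror the curation regime: ambiguity cap = smaller of 5 and
#' 0.5\% of length; profile validation with minus-strand and low-score
#' (0.5 bits/nt) failures fatal; alignment validation additionally requiring
#' 99\% coverage and failing on the score-difference and multiple-hit
#' features; single-linkage clustering at 97\% identity.
#'
#' @param model Name of the target model; sequences whose best model differs
#'   fail profile validation.
#' @param ambiguity An [ambiguity_policy()].
#' @param repeat_max_evalue,repeat_min_len_plus,repeat_min_len_minus
#'   Self-repeat thresholds: an off-diagonal self-alignment with E-value at
#'   most `repeat_max_evalue` and length at least 20 (plus strand) or 50
#'   (minus strand) fails the sequence.
#' @param low_score_bpnt Bits/nt floor used by both validation steps.
#' @param aligner_coverage Coverage floor for the alignment-validation step.
#' @param fmlpos,fmrpos Optional model span bounds: survivors must start at
#'   or before `fmlpos` and end at or after `fmrpos`.
#' @param fmnogap Additionally require a residue (not a deletion) at model
#'   positions `fmlpos` and `fmrpos`.
#' @param fione Keep only one survivor per species taxid (greatest model
#'   span, ties by fewer ambiguous residues, then lexicographic id).
#' @param ingroup_rank Taxonomic rank defining the groups for ingroup
#'   analysis.
#' @param cluster_threshold Single-linkage identity threshold for the final
#'   clustering.
#' @param skip_taxid,skip_vecscreen,skip_ingroup,skip_cluster Disable the
#'   corresponding steps.
#' @return An object of class `curation_opts`.
#' @export
curation_opts <- function(model, ambiguity = ambiguity_policy(),
                          repeat_max_evalue = 1, repeat_min_len_plus = 20,
                          repeat_min_len_minus = 50, low_score_bpnt = 0.5,
                          aligner_coverage = 0.99,
                          fmlpos = NULL, fmrpos = NULL, fmnogap = FALSE,
                          fione = FALSE, ingroup_rank = "order",
                          cluster_threshold = 0.97,
                          skip_taxid = FALSE, skip_vecscreen = FALSE,
                          skip_ingroup = FALSE, skip_cluster = FALSE) {
  if (!is.null(fmlpos) != !is.null(fmrpos)) {
    stop("fmlpos and fmrpos must be set together")
  }
  if (!is.null(fmlpos) && fmlpos > fmrpos) stop("fmlpos must be <= fmrpos")
  stopifnot(cluster_threshold > 0, cluster_threshold <= 1)
  structure(list(
    model = model, ambiguity = ambiguity,
    repeat_max_evalue = repeat_max_evalue,
    repeat_min_len_plus = repeat_min_len_plus,
    repeat_min_len_minus = repeat_min_len_minus,
    low_score_bpnt = low_score_bpnt, aligner_coverage = aligner_coverage,
    fmlpos = fmlpos, fmrpos = fmrpos, fmnogap = fmnogap, fione = fione,
    ingroup_rank = ingroup_rank, cluster_threshold = cluster_threshold,
    skip_taxid = skip_taxid, skip_vecscreen = skip_vecscreen,
    skip_ingroup = skip_ingroup, skip_cluster = skip_cluster
  ), class = "curation_opts")
}

#' Read vector-contamination matches
#'
#' Four-column TSV: `seq_id`, `start`, `stop` (1-based inclusive),
#' `strength` (Strong/Moderate/Weak). `#` comments and an optional header
#' are skipped.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of matches.
#' @export
read_vecscreen <- function(path) {
  if (!file.exists(path)) stop("vecscreen file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) > 0L &&
      is.na(suppressWarnings(as.numeric(parts[[1L]][[2L]])))) {
    parts <- parts[-1L]
  }
  if (any(lengths(parts) != 4L)) stop("vecscreen rows must have 4 fields")
  m <- data.frame(
    seq_id = vapply(parts, `[[`, "", 1L),
    start = as.numeric(vapply(parts, `[[`, "", 2L)),
    stop = as.numeric(vapply(parts, `[[`, "", 3L)),
    strength = vapply(parts, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
  if (any(m$start > m$stop)) stop("vecscreen match with start > stop")
  if (!all(m$strength %in% c("Strong", "Moderate", "Weak"))) {
    stop("vecscreen strength must be Strong, Moderate or Weak")
  }
  m
}

#' Vector-contamination test
#'
#' @param matches Vecscreen matches for one sequence.
#' @return `TRUE` (fail) iff any match has non-Weak strength.
#' @export
vecscreen_fail <- function(matches) {
  nrow(matches) > 0L && any(matches$strength != "Weak")
}

#' Internal-repeat test from self-alignment hits
#'
#' A sequence fails when blastn against itself reports an off-diagonal local
#' alignment with E-value at most `repeat_max_evalue` and length at least
#' `repeat_min_len_plus` (plus strand) or `repeat_min_len_minus` (minus
#' strand). The trivial full-length plus-strand identity hit (query span
#' equal to subject span) never counts; minus-strand self-hits are
#' off-diagonal by construction.
#'
#' @param seq_id Sequence id.
#' @param self_hits Blast hit table of self-alignments.
#' @param opts A [curation_opts()] object.
#' @return `TRUE` iff the sequence fails.
#' @export
self_repeat_fail <- function(seq_id, self_hits, opts) {
  h <- self_hits[self_hits$query_id == seq_id &
                   self_hits$subject_id == seq_id, , drop = FALSE]
  if (nrow(h) == 0L) return(FALSE)
  plus <- h$strand == "plus"
  diagonal <- plus & h$q_start == h$s_start & h$q_stop == h$s_stop
  bad_plus <- plus & !diagonal & h$e_value <= opts$repeat_max_evalue &
    h$aln_length >= opts$repeat_min_len_plus
  bad_minus <- !plus & h$e_value <= opts$repeat_max_evalue &
    h$aln_length >= opts$repeat_min_len_minus
  any(bad_plus | bad_minus)
}

#' Model-span test
#'
#' @param model_start,model_stop Span from [model_span()].
#' @param fmlpos,fmrpos Required left/right model positions.
#' @param nogap Require residues (not deletions) at exactly `fmlpos` and
#'   `fmrpos`.
#' @param occupancy Logical vector over model positions (residue present);
#'   required when `nogap` is `TRUE`.
#' @return `TRUE` iff the sequence covers the span.
#' @export
span_pass <- function(model_start, model_stop, fmlpos, fmrpos,
                      nogap = FALSE, occupancy = NULL) {
  ok <- model_start <= fmlpos && model_stop >= fmrpos
  if (ok && nogap) {
    if (is.null(occupancy)) stop("occupancy required for the no-gap span test")
    ok <- isTRUE(occupancy[[fmlpos]]) && isTRUE(occupancy[[fmrpos]])
  }
  ok
}

# residue occupancy per model position for one aligned row
model_position_occupancy <- function(aln, seq_id) {
  row_residue_mask(aln, seq_id)[aln$rf_mask]
}

#' Ingroup analysis
#'
#' A sequence fails when its nearest neighbor by alignment identity belongs
#' to a different taxonomic group and its identity to its nearest same-group
#' neighbor is lower. Sequences that are the only member of their group
#' (including those with no group assignment) never fail. Decisions are
#' deterministic and invariant to input order.
#'
#' @param identity Symmetric identity matrix with sequence ids as dimnames.
#' @param groups Named vector of group labels (`NA` = unassigned).
#' @return Character vector of failing sequence ids.
#' @export
ingroup_fail <- function(identity, groups) {
  ids <- rownames(identity)
  groups <- groups[ids]
  failing <- vapply(seq_along(ids), function(i) {
    if (is.na(groups[[i]])) return(FALSE)
    same <- which(groups == groups[[i]] & seq_along(ids) != i & !is.na(groups))
    if (length(same) == 0L) return(FALSE)  # singleton group: never fails
    other <- setdiff(seq_along(ids), c(i, same))
    if (length(other) == 0L) return(FALSE)
    max(identity[i, other]) > max(identity[i, same])
  }, logical(1))
  ids[failing]
}

#' Single-linkage clustering and centroid selection
#'
#' Clusters sequences by single linkage at `identity >= threshold`
#' (equivalently distance `1 - identity <= 1 - threshold`), then selects as
#' centroid the member with the greatest mean identity to its other cluster
#' members (ties by lexicographic id).
#'
#' @param identity Symmetric identity matrix with ids as dimnames.
#' @param ids Sequence ids to cluster (default: all rows).
#' @param threshold Identity threshold in `(0, 1]`.
#' @return List with `clusters` (data.frame `seq_id`, `cluster`) and
#'   `centroids` (character vector, one per cluster).
#' @export
cluster_and_centroids <- function(identity, ids = rownames(identity),
                                  threshold = 0.97) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(ids) == 0L) {
    return(list(clusters = data.frame(seq_id = character(0),
                                      cluster = integer(0)),
                centroids = character(0)))
  }
  m <- identity[ids, ids, drop = FALSE]
  membership <- if (length(ids) == 1L) stats::setNames(1L, ids) else {
    hc <- stats::hclust(stats::as.dist(1 - m), method = "single")
    stats::cutree(hc, h = 1 - threshold + 1e-12)
  }
  centroids <- vapply(sort(unique(membership)), function(k) {
    members <- names(membership)[membership == k]
    if (length(members) == 1L) return(members)
    mean_id <- vapply(members, function(a) {
      mean(m[a, setdiff(members, a)])
    }, numeric(1))
    members[order(-mean_id, members)][1L]
  }, "")
  list(clusters = data.frame(seq_id = names(membership),
                             cluster = unname(membership),
                             stringsAsFactors = FALSE),
       centroids = unname(centroids))
}

#' One survivor per species taxid
#'
#' @param survivors `data.frame` with `seq_id`, `species_taxid`, `span`
#'   (covered model positions) and `n_ambiguous`.
#' @return Subset of `survivors`: per species taxid, the sequence with the
#'   greatest span, ties broken by fewer ambiguous residues, then
#'   lexicographic id.
#' @export
select_one_per_taxid <- function(survivors) {
  keep <- unlist(lapply(split(seq_len(nrow(survivors)),
                              survivors$species_taxid), function(idx) {
    s <- survivors[idx, , drop = FALSE]
    idx[order(-s$span, s$n_ambiguous, s$seq_id)[1L]]
  }))
  out <- survivors[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the curation pipeline
#'
#' Executes the enabled steps in order: (1) ambiguity filter, (2) specified
#' species, (3) vector contamination, (4) self-repeats — all evaluated for
#' every sequence, so a sequence may fail several of them — then (5) profile
#' validation for every sequence, (6) alignment validation gated on 5,
#' (7) model span gated on 6, and (8) ingroup analysis gated on all previous
#' steps. Survivors pass every enabled step; optional one-per-taxid
#' selection and single-linkage clustering with centroid selection follow.
#'
#' @param seqs Sequence table.
#' @param stage1,stage2 Profile hit tables.
#' @param models Model registry containing `opts$model`.
#' @param aln A `ref_alignment` with rows for sequences reaching step 6.
#' @param opts A [curation_opts()] object.
#' @param taxonomy Taxonomy table (required unless taxonomy-dependent steps
#'   are skipped).
#' @param seq_taxids Named vector mapping `seq_id` to taxid.
#' @param vecscreen Vecscreen match table (required unless skipped).
#' @param self_hits Self-alignment blast hit table.
#' @return An object of class `curation_report`: `steps` (per-sequence
#'   status matrix over the enabled steps, values pass/fail/skipped),
#'   `survivors`, `selected` (post one-per-taxid), `clusters`, `centroids`
#'   and `final_ids`.
#' @export
curate_rrna_db <- function(seqs, stage1, stage2, models, aln, opts,
                           taxonomy = NULL, seq_taxids = NULL,
                           vecscreen = NULL, self_hits = empty_blast_hits()) {
  stopifnot(inherits(opts, "curation_opts"))
  if (!opts$model %in% models$model_name) {
    stop("target model ", opts$model, " not in registry")
  }
  need_tax <- !opts$skip_taxid || opts$fione ||
    (!opts$skip_ingroup)
  if (need_tax && (is.null(taxonomy) || is.null(seq_taxids))) {
    stop("taxonomy and seq_taxids are required for the specified-species, ",
         "ingroup and one-per-taxid steps (disable with skip_taxid/",
         "skip_ingroup and fione = FALSE)")
  }
  if (!opts$skip_vecscreen && is.null(vecscreen)) {
    stop("vecscreen matches are required (disable with skip_vecscreen)")
  }

  enabled <- c("ambiguity",
               if (!opts$skip_taxid) "specified_species",
               if (!opts$skip_vecscreen) "vecscreen",
               "self_repeat", "profile_validation", "alignment_validation",
               if (!is.null(opts$fmlpos)) "model_span",
               if (!opts$skip_ingroup) "ingroup")
  ids <- seqs$seq_id
  steps <- matrix("pass", nrow = length(ids), ncol = length(enabled),
                  dimnames = list(ids, enabled))
  reasons <- stats::setNames(vector("list", length(ids)), ids)
  note <- function(sid, step, status, why = NULL) {
    steps[sid, step] <<- status
    if (!is.null(why)) reasons[[sid]] <<- c(reasons[[sid]], paste0(step, ":", why))
  }

  # steps 1-4: evaluated for all sequences
  amb_ok <- ambiguity_pass(seqs, opts$ambiguity)
  for (i in which(!amb_ok)) note(ids[[i]], "ambiguity", "fail", "too-many-ambiguous")
  if (!opts$skip_taxid) {
    for (i in seq_along(ids)) {
      tid <- seq_taxids[[ids[[i]]]]
      if (is.null(tid) || is.na(tid) || !(tid %in% taxonomy$taxid)) {
        note(ids[[i]], "specified_species", "fail", "taxonomy-missing")
      } else if (!specified_species_pass(tid, taxonomy)) {
        note(ids[[i]], "specified_species", "fail", "not-specified-species")
      }
    }
  }
  if (!opts$skip_vecscreen) {
    for (i in seq_along(ids)) {
      m <- vecscreen[vecscreen$seq_id == ids[[i]], , drop = FALSE]
      if (vecscreen_fail(m)) note(ids[[i]], "vecscreen", "fail", "non-weak-match")
    }
  }
  for (i in seq_along(ids)) {
    if (self_repeat_fail(ids[[i]], self_hits, opts)) {
      note(ids[[i]], "self_repeat", "fail", "internal-repeat")
    }
  }

  # step 5: profile validation against the target model
  m5 <- models
  m5$acceptability <- ifelse(m5$model_name == opts$model,
                             "acceptable", "unacceptable")
  rt <- profile_validate(seqs, stage1, stage2, m5,
                         typer_opts(low_score_bpnt = opts$low_score_bpnt,
                                    minusfail = TRUE, scfail = TRUE))
  for (i in which(!rt$pass)) {
    note(ids[[i]], "profile_validation", "fail", rt$reasons[[i]])
  }

  # step 6: alignment validation, gated on step 5
  ra_opts <- typer_opts(low_score_bpnt = opts$low_score_bpnt,
                        low_coverage = opts$aligner_coverage,
                        minusfail = TRUE, covfail = TRUE,
                        difffail = TRUE, multfail = TRUE)
  ra <- aligned_validate(seqs, stage1, stage2, m5, aln, ra_opts)
  spans <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    sid <- ids[[i]]
    if (!rt$pass[[i]]) {
      note(sid, "alignment_validation", "skipped")
      next
    }
    if (!ra$pass[[i]]) {
      note(sid, "alignment_validation", "fail", ra$reasons[[i]])
    } else if (!sid %in% names(aln$rows)) {
      note(sid, "alignment_validation", "fail", "not-aligned")
    } else {
      spans[[sid]] <- c(ra$model_start[[i]], ra$model_stop[[i]])
    }
  }

  # step 7: model span, gated on step 6
  if ("model_span" %in% enabled) {
    for (sid in ids) {
      if (steps[sid, "alignment_validation"] != "pass") {
        note(sid, "model_span", "skipped")
        next
      }
      occ <- if (opts$fmnogap) model_position_occupancy(aln, sid) else NULL
      if (!span_pass(spans[[sid]][[1L]], spans[[sid]][[2L]], opts$fmlpos,
                     opts$fmrpos, opts$fmnogap, occ)) {
        note(sid, "model_span", "fail", "span-not-covered")
      }
    }
  }

  # step 8: ingroup analysis among sequences passing all single-sequence tests
  single <- setdiff(enabled, "ingroup")
  single_pass <- ids[apply(steps[, single, drop = FALSE] == "pass", 1L, all)]
  if ("ingroup" %in% enabled) {
    for (sid in setdiff(ids, single_pass)) note(sid, "ingroup", "skipped")
    eligible <- intersect(single_pass, names(aln$rows))
    if (length(eligible) >= 2L) {
      sub <- aln
      sub$rows <- aln$rows[eligible]
      ident <- alignment_identity(sub)
      groups <- vapply(eligible, function(sid) {
        g <- ancestor_at_rank(seq_taxids[[sid]], taxonomy, opts$ingroup_rank)
        if (is.na(g)) NA_character_ else as.character(g)
      }, "")
      for (sid in ingroup_fail(ident, groups)) {
        note(sid, "ingroup", "fail", "outlier-in-taxon")
      }
    }
  }

  survivors <- ids[apply(steps == "pass", 1L, all)]

  # optional one-per-taxid selection
  selected <- survivors
  if (opts$fione && length(survivors) > 0L) {
    tab <- data.frame(
      seq_id = survivors,
      species_taxid = vapply(survivors, function(sid) {
        species_taxid(seq_taxids[[sid]], taxonomy)
      }, numeric(1)),
      span = vapply(survivors, function(sid) {
        spans[[sid]][[2L]] - spans[[sid]][[1L]] + 1
      }, numeric(1)),
      n_ambiguous = seqs$n_ambiguous[match(survivors, seqs$seq_id)],
      stringsAsFactors = FALSE
    )
    selected <- select_one_per_taxid(tab)$seq_id
  }

  # final clustering and centroid selection
  clusters <- data.frame(seq_id = selected,
                         cluster = seq_along(selected),
                         stringsAsFactors = FALSE)
  centroids <- selected
  if (!opts$skip_cluster && length(selected) > 0L) {
    avail <- intersect(selected, names(aln$rows))
    sub <- aln
    sub$rows <- aln$rows[avail]
    cl <- cluster_and_centroids(alignment_identity(sub), avail,
                                opts$cluster_threshold)
    clusters <- cl$clusters
    centroids <- cl$centroids
  }

  structure(list(steps = steps, reasons = reasons, survivors = survivors,
                 selected = selected, clusters = clusters,
                 centroids = centroids,
                 final_ids = if (opts$skip_cluster) selected else centroids,
                 opts = opts),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation pipeline:", nrow(x$steps), "input sequence(s),",
      length(x$survivors), "survivor(s),", length(x$final_ids),
      "in the final set\n")
  for (step in colnames(x$steps)) {
    st <- x$steps[, step]
    cat(sprintf("  %-21s pass %d / fail %d / skipped %d\n", step,
                sum(st == "pass"), sum(st == "fail"), sum(st == "skipped")))
  }
  invisible(x)
}

#' @export
summary.curation_report <- function(object, ...) {
  data.frame(step = colnames(object$steps),
             pass = colSums(object$steps == "pass"),
             fail = colSums(object$steps == "fail"),
             skipped = colSums(object$steps == "skipped"),
             row.names = NULL)
}
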