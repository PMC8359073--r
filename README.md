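# riboscreen

Rule-based validation, classification and curation of ribosomal RNA (rRNA)
sequences.

## The problem

SSU and LSU rRNA genes (16S/18S and 23S/25S/26S/28S) are the most heavily
submitted marker genes in public sequence databases, and they arrive in
wildly varying quality: partial amplicons, reverse-complemented reads,
misassembled contigs containing duplicated or reordered gene regions,
vector-contaminated clones, and sequences assigned to the wrong taxonomic
domain. Archives and curators need *deterministic*, auditable pass/fail
decisions — a submission whose sequences all pass can be accepted
automatically, and a curated reference set should contain only full-length,
non-redundant, taxonomically consistent sequences.

`riboscreen` implements that decision layer. It does not run homology
searches itself: it consumes the standard tabular outputs of profile
(HMM/CM) search tools and of `blastn`, plus reference-annotated Stockholm
alignments, and renders verdicts with machine-readable reasons. Who it is
for: submitters who want to pre-screen rRNA sequences before submission,
and database curators building trusted reference sets.

## What it computes

**Profile validation** (`profile_validate`) — a two-stage classifier. Stage
1 ranks a model library by best single-hit bit score per model and assigns
each sequence its best model; stage 2 hit endpoints for that model feed 16
named *unexpected feature* detectors, among them:

* `LowScore` — score density `B/L < 0.50` bits/nt, where `B` is the summed
  best-model bit score and `L` the sequence length;
* `LowCoverage` — fraction of the sequence covered by merged hit spans
  `< 0.86` (or `< 0.80` for sequences ≤ 350 nt in combined mode);
* `LowScoreDifference` / `VeryLowScoreDifference` — score gap to the best
  model of another taxonomic domain `< 0.10` / `< 0.04` bits/position;
* `DuplicateRegion` — two same-strand hits overlapping ≥ 10 model
  positions; `InconsistentHits` — hits ordered differently in sequence and
  model coordinates; `BothStrands`, `MultipleFamilies` (SSU and LSU hits),
  `MinusStrand`, `MultipleHits`, and acceptability/length gates.

A configurable subset of features is fatal; a sequence fails iff a fatal
feature is detected.

**Blast screening** (`blast_validate`) — each sequence gets one of five
classes: `too_short` / `too_long` (outside a length window, e.g.
[400, 2500] nt for prokaryotic SSU), `no` (zero hits), `yes` (some hit with
E ≤ 1e−40 and identity ≥ 80%), or `imperfect_match`.

**Combined validation** (`combined_validate`) — runs both engines, assigns
each sequence an outcome class `RPSP`/`RPSF`/`RFSP`/`RFSF` (profile
pass/fail × blast pass/fail), maps engine errors to GenBank-style
`SEQ_HOM_*` errors with two documented forgiveness rules, and routes each
failure to *submitter* or *indexer*. Blast thresholds are
length-partitioned: 100–350 nt (id 75%, cov 0.80), 351–600 nt (80%, 0.86),
601–2000 nt (86%, 0.86).

**Length classification** (`length_classify`) — from a Stockholm alignment
with a `#=GC RF` consensus annotation, each sequence's model span and
terminal indel counts place it in exactly one of 13 length classes
(`partial`, and `full`/`5flush`/`3flush` × `exact`/`extra`/`ambig-more`/
`ambig-less`).

**Database curation** (`curate_rrna_db`) — an ordered eight-step filter
battery: ambiguous residues (more than min(5, 0.5% of length) fails),
specified-species taxonomy flag, vector contamination, internal repeats
(off-diagonal self-alignments, ≥ 20 nt plus / ≥ 50 nt minus strand at
E ≤ 1), profile validation, alignment validation (99% coverage), model-span
enforcement (e.g. positions 604–1070 of the eukaryotic SSU model, the
V4–V5 window), and ingroup analysis; survivors are single-linkage clustered
at 97% identity and represented by centroids.

All inputs can also be produced synthetically: `generate_bundle()` writes a
deterministic fixture bundle in every supported format, engineered (and
self-verified) to trigger each rule boundary.

## Worked example

```r
library(riboscreen)

fc <- feature_catalogue(seed = 42)   # synthetic sequences + hit tables
res <- profile_validate(fc$seqs, fc$stage1, fc$stage2, fc$models, fc$opts)
res[c(1, 9, 10, 13), ]
#>     seq_id  pass best_model bits_per_nt coverage     features
#> 1      noh FALSE       <NA>          NA       NA       NoHits
#> 9    lowsc  TRUE    SSU_bac         0.4     1.00     LowScore
#> 10  lowcov  TRUE    SSU_bac         0.8     0.85  LowCoverage
#> 13 multhit  TRUE    SSU_bac         0.6     0.98 MultipleHits
```

`noh` has no stage-1 hits, a fatal feature, so it fails. `lowsc` scores
0.4 bits/nt — below the 0.50 floor — and `lowcov`'s hits cover only 85% of
the sequence; both features are reported but non-fatal by default (they
become fatal under `scfail`/`covfail`, as in combined mode).

```r
cf <- curation_fixture(seed = 42)
rep <- curate_rrna_db(cf$seqs, cf$stage1, cf$stage2, cf$models, cf$aln, cf$opts,
                      taxonomy = cf$taxonomy, seq_taxids = cf$seq_taxids,
                      vecscreen = cf$vecscreen, self_hits = cf$self_hits)
rep
#> Curation pipeline: 7 input sequence(s), 3 survivor(s), 2 in the final set
#>   ambiguity             pass 6 / fail 1 / skipped 0
#>   specified_species     pass 6 / fail 1 / skipped 0
#>   vecscreen             pass 6 / fail 1 / skipped 0
#>   self_repeat           pass 6 / fail 1 / skipped 0
#>   profile_validation    pass 6 / fail 1 / skipped 0
#>   alignment_validation  pass 6 / fail 0 / skipped 1
#>   model_span            pass 6 / fail 0 / skipped 1
#>   ingroup               pass 3 / fail 0 / skipped 4
```

Three sequences survive all filters; two identical survivors collapse into
one cluster, leaving two centroids in the final set. The sequence failing
profile validation is *skipped*, not failed, at the alignment step — gated
steps are only evaluated for eligible sequences.

A command-line front end mirrors the library
(`riboscreen_main()` / `inst/scripts/riboscreen`) with subcommands `typer`,
`sensor`, `combine`, `aligner`, `dbmaker` and `fixtures`; exit status 0
means every sequence passed, 1 means validation failures, 2 a usage error.

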