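---
title: "Screening rRNA sequences: rules, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening rRNA sequences: rules, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboscreen)
```

`riboscreen` is a decision layer, not a search tool. Homology evidence —
profile (HMM/CM) hits and blastn hits — arrives as tabular files; the
package's job is to turn that evidence into deterministic, auditable
pass/fail verdicts for individual rRNA sequences and into curated,
non-redundant reference sets. This vignette documents the rules, the
parameters that matter, the places where the procedure was genuinely open
and a concrete choice had to be made, and what the synthetic test data do
and do not demonstrate.

## The validation model

### Two-stage profile classification

Every sequence is compared against a small library of per-gene, per-domain
profile models (SSU/LSU × archaea/bacteria/eukarya/organelles). Stage 1 is
a ranking pass: for each model, the best single-hit bit score; the
best-scoring model wins and is carried into stage 2, which supplies hit
endpoints for that model only. This mirrors the common
classification-then-coverage architecture of profile-based annotators,
where a cheap scoring pass selects a model and a full pass determines
coordinates.

Ties in stage 1 are broken by higher score, then lower E-value, then
lexicographically smaller model name — an arbitrary but fixed rule, so runs
are reproducible and permutation-invariant in the input hit order (a tested
invariant).

Sixteen *unexpected features* are then evaluated per sequence. The
thresholds, with units and defaults:

| parameter | default | units | role |
|---|---|---|---|
| `low_score_bpnt` | 0.50 | bits/nt | `LowScore`: summed best-model bit score ÷ sequence length |
| `low_coverage` | 0.86 | proportion | `LowCoverage`: merged hit spans ÷ sequence length |
| `tshort_coverage`/`tshort_len` | 0.80 / 350 | proportion / nt | short-sequence coverage regime (combined mode) |
| `low_diff_bpp` | 0.10 | bits/position | `LowScoreDifference` vs best other-domain model |
| `very_low_diff_bpp` | 0.04 | bits/position | `VeryLowScoreDifference` |
| `duplicate_overlap_min` | 10 | model positions | `DuplicateRegion` overlap floor (inclusive) |

All comparisons are strict (`< threshold` flags): a sequence at exactly
0.50 bits/nt or exactly 0.86 coverage is *not* flagged. The boundary sweeps
in the test suite pin these semantics.

Seven structural features (`NoHits`, `UnacceptableModel`,
`MultipleFamilies`, `BothStrands`, `DuplicateRegion`, `InconsistentHits`,
`QuestionableModel`) are fatal by default, as are the option-gated length
gates `TooShort`/`TooLong` (which are only reportable when a bound is
supplied, so their fatality is inert unless requested). The score- and
coverage-based features are advisory by default and become fatal through
`scfail`, `covfail`, `minusfail`, `difffail`, `multfail` — different
front ends enable different subsets (combined mode: `scfail covfail`;
aligner mode: `minusfail scfail covfail`; curation: stricter still).

Three detectors required concretization beyond their one-line definitions:

* **`LowScore` numerator.** Stage-1 ranking uses the best single hit per
  model, but the bits-per-nucleotide statistic sums all best-model hit
  scores ("total bit score divided by total length"). A fragmented
  alignment therefore still accumulates its full score mass.
* **`InconsistentHits`.** Same-strand best-model hits are sorted by
  sequence start; the feature fires iff model starts are not monotone in
  the strand's expected direction (non-decreasing on plus, non-increasing
  on minus). Ties — equal sequence or model starts — never violate.
* **`EvalueScoreDiscrepancy`.** Only evaluated under E-value sorting: the
  sequence's stage-1 hits are ordered by (E-value ascending, score
  descending) and the feature fires iff the top hit's bit score is strictly
  below the second's.

Coverage merges overlapping and adjacent hit spans (strand-agnostic, spans
normalized to `(min, max)`) before summing, so duplicated or overlapping
hits can never push coverage above 1 and coverage is a true proportion.
Whether overlaps should be merged was not externally fixed; merging is the
only choice that keeps the statistic interpretable, and it is declared
rather than inferred.

### Blast screening and the combined engine

The blast engine is intentionally simple: length gates first (every
sequence is classified, including out-of-range ones), then `no` /
`yes` / `imperfect_match` from the hit list, with `yes` requiring a single
hit meeting both E ≤ 1e−40 and identity ≥ 80% (inclusive). In combined
mode, six error diagnostics are evaluated with length-partitioned
thresholds (100–350 / 351–600 / 601–2000 nt at identity 75/80/86% and
coverage 0.80/0.86/0.86); the best hit is the lowest-E-value one (ties by
higher bit score) and its coverage is `aln_length / query_length`.
`S_NoSimilarity` (best-hit coverage < 10%) pre-empts `S_LowSimilarity`;
both map to the same downstream error, so the distinction is diagnostic
only. Hit multiplicity counts reported rows — no merging — because the
diagnostic mirrors a column count in the original report format.

The combined engine classifies each analyzed sequence into
`RPSP`/`RPSF`/`RFSP`/`RFSF` and maps engine errors to GenBank-style
`SEQ_HOM_*` errors with two forgiveness rules: the four blast similarity
errors are dropped for `RPSF` sequences (unless strict combining `-c` is
requested) or for `RFSF` sequences that also carry a model-acceptability
error; and the two indexer-side profile errors (`R_QuestionableModel`,
`R_MultipleHits`) are dropped for `RFSP` sequences. The mapping is total
over both engines' error vocabularies — a property the acceptance suite
checks exhaustively.

Two points were open and are declared here:

* **Routing precedence.** When mapped errors route to both submitter and
  indexer, the whole sequence routes to the submitter — the stricter
  recipient, since submitter-side errors require submitter action anyway.
* **Out-of-range sequences.** Sequences shorter than 100 nt or longer than
  2000 nt are not analyzed; they are reported with outcome
  `too_short`/`too_long` and cannot pass, so their presence fails a
  submission. No GenBank-style error exists for them, and none is invented.

### Length classes

Sequences passing the aligner-mode profile validation are placed in one of
13 length classes from their alignment to the model. The span is the
first/last *consensus* (reference-annotated) column carrying a residue;
residues confined to insert columns never extend it. The class prefix comes
from which model termini the span reaches (`partial`, `full`, `5flush`,
`3flush`); the suffix from insertions and deletions within the terminal
ten model positions *at the flush end(s) only*: `exact` (none), `extra`
(insertions, no deletions), `ambig-more`/`ambig-less` (deletions present;
insertions exceed them or not).

The class names and the exact sub-label rules are this package's
enumeration: the upstream definition fixes only the count (13) and the
ingredients (terminus attainment, terminal-window indel counts). Insert
columns are attributed to the preceding consensus position; the 5' window
covers attributions 0–9 and the 3' window attributions L−9 to L for a
model of length L and the default window of 10 — a symmetric concretization
(each window spans ten attribution slots) of "the first and final ten model
positions". Windows truncate when L < 2·window. The classification is total
and exclusive by construction, which the tests verify over randomized
span/indel combinations.

### The curation pipeline

Eight steps run in a fixed order with explicit gating:

1–4 (ambiguity, specified species, vector contamination, self-repeats) are
evaluated for *every* sequence, so one sequence can fail several filters —
the audit report records each fate separately. Step 5 (profile validation,
with `minusfail` and a 0.5 bits/nt floor fatal, best model forced to the
target model) also runs for all sequences. Step 6 (alignment validation)
runs only for step-5 passers; step 7 (model span) only for step-6 passers;
step 8 (ingroup) only for sequences passing everything else. Gated steps
record `skipped`, never `fail`, preserving the monotone-filtering property:
enabling an additional test can only shrink the survivor set (tested).

The step-6 option set differs deliberately from standalone aligner mode:
coverage tightens to 0.99, the score-difference and multiple-hit features
become fatal, but the plain low-score failure is not re-applied (it already
acted in step 5).

Parameter notes:

* **Ambiguity**: a sequence fails with more than min(5, 0.5% × length)
  ambiguous residues; the fractional bound is compared as a real number
  (no rounding), so a 600 nt sequence's threshold is exactly 3.
* **Self-repeats**: an off-diagonal self-alignment with E ≤ 1 and length
  ≥ 20 (plus strand) or ≥ 50 (minus strand) fails the sequence.
  "Off-diagonal" is defined as query span ≠ subject span for plus-strand
  hits; every minus-strand self-hit is off-diagonal by construction.
* **Ingroup rule** (a declared concretization; only the option surface of
  the original is documented): compute pairwise alignment identities among
  all eligible sequences; a sequence fails iff its nearest neighbor belongs
  to a different taxonomic group (default rank: order) *and* it is strictly
  closer to that group than to its nearest same-group neighbor. Sequences
  alone in their group never fail — there is no evidence against them.
  The decision is order-invariant and matches a brute-force
  nearest-neighbor oracle in the tests.
* **Clustering**: survivors are single-linkage clustered at identity
  ≥ 0.97 — the same 97% used when clustering curated sets into blast
  databases, adopted here as the default for the in-pipeline step, whose
  own threshold is not externally documented. The centroid is the member
  with the greatest mean identity to its cluster mates, ties broken
  lexicographically. Implementation is `hclust(..., "single")` +
  `cutree` at height 1 − threshold (with a 1e−12 slack so exact-boundary
  identities merge); tests compare against an independent
  transitive-closure oracle.
* **One-per-taxid selection** keeps, per species taxid, the survivor with
  the widest model span, ties broken by fewer ambiguous residues, then
  lexicographic id.
* **Pairwise identity** is matches ÷ columns where both rows have
  residues, with U and T equated; rows sharing no columns get 0. The
  original's identity definition is not documented; this one is symmetric,
  in [0, 1], and insensitive to flanking gaps.

## What the synthetic data show — and what they do not

All tests run on fixtures built in code (`feature_catalogue()`,
`length_class_catalogue()`, `sensor_catalogue()`, `curation_fixture()`,
bundled by `generate_bundle()`). Residues are i.i.d. uniform A/C/G/T;
hit tables and alignments are constructed directly to sit on rule
boundaries, and each generator re-runs the relevant engine and aborts if
any directive does not produce exactly the intended feature set or class —
the suites are self-certifying.

This design is deliberate: the package's contract is the decision layer,
and the fixtures exercise every branch and threshold of it exactly. What
passing tests do *not* show is anything about search sensitivity or
alignment quality on real rRNA — there is no secondary structure, no
realistic score distribution, no intron, no chimera in the fixtures. A
correct decision layer fed by a poorly chosen model library or misconfigured
search will still faithfully reproduce the searches' mistakes. Problem
sizes are kept small (tens of sequences, toy 20-position models, identity
matrices up to n = 50 for oracle comparisons) — chosen as the smallest
sizes that exercise every rule, since the rules themselves are
per-sequence and size-independent.

## Degenerate inputs and numerical choices

* Duplicate FASTA ids, empty sequences, ragged alignments, a missing
  `#=GC RF` line, unknown model names, and malformed table rows are hard
  errors with the offending id or line number — silent repair would
  undermine auditability.
* All-gap alignment rows, and rows with residues only in insert columns,
  are errors in `model_span` (there is no defensible span).
* A sequence absent from the alignment but reaching the alignment
  validation step fails with reason `not-aligned` rather than erroring:
  at pipeline scale a missing row is a data defect of one sequence, not of
  the run.
* Zero-hit sequences short-circuit to `NoHits`; the length gates
  `TooShort`/`TooLong` are still evaluated for them.
* Score/coverage comparisons are plain floating-point `<`; thresholds are
  representable (0.50, 0.86, 0.10, 0.04) and inputs are bit scores with
  one decimal, so no tolerance machinery is needed. The single deliberate
  epsilon is the 1e−12 slack in the clustering cut height.

## Limitations

* Introns and other unaligned insertions are treated uniformly as insert
  columns; long introns will inflate `ins` counts and can demote a
  sequence from `full-extra` to `full-ambig-*` only via genuine deletions,
  but they are not modelled.
* The default thresholds are tuned for prokaryotic SSU rRNA; other genes
  and domains need their own calibration, which is why every threshold is
  a visible, documented option.
* The ingroup rule and the 13-class sub-label boundaries are this
  package's concretizations of procedures whose originals are documented
  only at the option level; results at exactly those boundaries may differ
  from other implementations.
* The CLI's `-p` option chunks in-process for interface compatibility;
  chunked and unchunked runs are byte-identical (tested), but there is no
  actual parallel speedup.
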