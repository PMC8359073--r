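Package: riboscreen
Title: Rule-Based Validation, Classification and Curation of Ribosomal RNA Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic pass/fail screening of small and large subunit ribosomal RNA
    (SSU/LSU rRNA) sequences from tabular homology-search evidence. Post-processes
    profile (HMM/CM) hit tables through a two-stage classifier with sixteen named
    unexpected-feature detectors, classifies blastn results into five classes, combines
    both engines into four outcome classes with a GenBank-style error mapping and
    submitter/indexer routing, assigns one of thirteen alignment-based length classes
    from reference-annotated Stockholm alignments, and runs an eight-step database
    curation pipeline (ambiguity, taxonomy, vector contamination, self-repeats, profile
    validation, alignment validation, model span, ingroup analysis) with single-linkage
    clustering and centroid selection. Includes a deterministic synthetic fixture
    generator that can trigger every rule boundary, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
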