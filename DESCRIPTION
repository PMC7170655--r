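Package: tadakit
Title: Targeted DamID Occupancy Tracks, Shuffle-Null Peak Calling and
    CATaDa Accessibility Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for Targeted DamID (TaDa) protein-DNA
    binding profiles at native GATC-fragment resolution. Builds GATC
    fragment maps from genome sequence, computes RPM and log2
    Dam-fusion/Dam-only occupancy-ratio tracks, calls broadly bound
    regions as runs of consecutive enriched fragments with a
    permutation-null false discovery rate, intersects replicates into
    final peaks, maps peaks to putatively regulated genes under a 5 kb
    no-intervening-gene rule, classifies peaks by genomic feature, and
    analyses CATaDa chromatin accessibility (accessible-region calling,
    metaprofiles around region centres, chromatin-state enrichment).
    Includes differential-expression and tissue-of-origin integration
    and a fully deterministic synthetic-data generator with planted
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
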