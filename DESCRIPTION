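Package: multiway3c
Title: Multi-Way Chromatin Contact Detection and 3D Genome Inference
    from Proximity-Ligation Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for chromosome-conformation-capture libraries digested
    with frequently cutting (4-base) restriction enzymes, in which single
    100 bp read ends frequently span ligation junctions.  Implements a
    two-phase mapping strategy that splits chimeric read ends at restriction
    cleavage sites to recover pairwise, three-way and four-way chromatin
    contacts; builds binned contact maps; performs copy-number-aware
    iterative correction (ICE) for near-haploid genomes with partially
    diploid segments; calls A/B compartments by eigendecomposition of
    intrachromosomal correlation matrices oriented by GC content; computes
    observed/expected enrichment of contacts over compartment labels, DNase
    hypersensitivity classes and topological domains with a shuffled-domain
    null; and infers consensus 3D genome structures under a Poisson
    likelihood with power-law distance decay, apportioning contact counts
    among homologous copies by constrained grid search.  A seed-reproducible
    simulator generates genomes, proximity-ligation libraries with planted
    multi-way contacts, and structure-driven contact matrices so that every
    stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Matrix,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
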