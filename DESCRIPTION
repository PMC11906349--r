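Package: rarecis
Title: Rare-Variant cis Association Discovery for Circulating Protein Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end discovery of rare coding and noncoding cis associations
    with quantitative molecular traits (circulating protein levels) from
    whole-genome sequencing genotypes. Implements per-genotype depth/quality
    filtering, cis-window definition and variant classification, annotation-based
    mask construction (conservation, constraint, deleteriousness and splice
    scores), sliding-window and regulatory-region aggregate units, single-variant
    association with rank-inverse normalization, conditional-joint (forward plus
    backward) lead-variant selection, rare-variant aggregate tests (burden, SKAT,
    ACAT-V, ACAT-O, singleton, all-mask) under layered conditioning with a
    stepwise aggregate-independence procedure, per-base coverage QC with
    beta-discrepancy and problematic-region checks, Fisher and bootstrap
    regulatory-region enrichment, and empirical significance thresholds from
    null-trait scans. A synthetic-locus simulator generates fully specified
    fixtures (genotypes, annotations, gene models, depth profiles, phenotypes
    with known truth) so that every stage is testable without controlled-access
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    vcfR,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
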