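Package: echinoname
Title: Orthology-Informed Gene Nomenclature for Echinoderm Genomes
Version: 0.1.0
Authors@R:
    person("Echinoname", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Assigns standardized, machine-readable gene symbols and full
    names to echinoderm genes from multi-tool ortholog predictions against
    a human reference gene set. Implements consensus orthology voting
    (a relationship counts when three or more independent tools support
    it), bipartite orthology-group topology classification (one:one,
    one:many, many:one, many:many), detection of pseudoduplicate gene
    models arising from under-collapsed heterozygosity via a 90/90
    identity-and-coverage rule over gene models with 1 kb flanks,
    a deterministic naming cascade with family-stem and alphanumeric
    tie-breaking, paralog and pseudoduplicate suffixing, LOC fallback
    identifiers, symbol normalization (Greek letters and Roman numerals
    to Latin and Arabic equivalents), synonym bookkeeping, cohort-level
    category reporting, and a deterministic synthetic-cohort generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    igraph,
    jsonlite,
    utils,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
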