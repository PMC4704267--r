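Package: mapforge
Title: High-Density RIL Linkage Maps for Genome Assembly Curation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds high-density genetic linkage maps from recombinant inbred
    line (RIL) genotype matrices and uses them to curate a draft genome
    assembly: segregation-distortion and missingness filters, binning of
    markers with identical segregation patterns, LOD-threshold linkage
    grouping, marker ordering with Kosambi map distances, detection of
    assembly regions needing re-orientation or re-positioning from
    genetic-vs-physical order concordance, anchoring of unplaced scaffolds,
    delimitation of heterochromatic regions from Marey maps, and in-silico
    placement of SSR and SNP markers on an assembly sequence. Includes a
    seeded simulator of F5-derived RIL populations over a model genome with
    planted assembly errors, so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
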