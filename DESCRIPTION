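Package: miptkit
Title: Organelle Genome Degradation and Plastid-to-Mitochondrion Transfer
    Analysis in Parasitic Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of plastid and mitochondrial genomes of
    holoparasitic plants: classification of plastome genes as intact,
    pseudogenized or lost against a reference catalog and assignment of the
    five-stage plastome degradation model; detection of the quadripartite
    plastome architecture (LSC/SSC/inverted repeats) and region-size
    comparisons across species; discovery of plastid-derived fragments in
    mitochondrial chromosomes with ORF-completeness assessment; phylogenetic
    classification of such fragments as intracellular or horizontal transfers
    from bootstrap-annotated trees, including an audit of single-site
    fragility of donor assignments; and mapping of transcriptome expression
    evidence onto photosynthesis and chlorophyll-biosynthesis pathway
    definitions. A seeded synthetic-data generator builds complete organelle
    genome fixtures so every stage runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
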