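Package: mitonom
Title: Reference-Based Nomenclature for Introns in Fungal Mitochondrial
    Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates intron insertion points in fungal mitochondrial
    protein-coding genes on the coordinate system of the intron-free
    Tolypocladium inflatum ortholog set and constructs, parses and compares
    standard intron names of the form Sce.cox1S169 (species abbreviation,
    host gene, group I/II/unknown letter P/S/U, reference insertion site,
    optional twintron letter and strain-variant number). Reads exon/intron
    structure from GenBank flat files, maps insertion points through global
    pairwise alignment, infers introns de novo from unannotated gene
    regions, builds cross-species intron-site matrices with per-gene
    summaries, and generates synthetic mitogenome fixtures with planted
    introns for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
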