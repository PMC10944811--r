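Package: hlafull
Title: Characterization of Full-Length HLA Allele Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing newly resolved full-length HLA class I
    and class II allele sequences: HLA allele nomenclature parsing and
    ordering, reference allele selection within an allele group, feature-aware
    cataloguing of substitutions, insertions and deletions in IMGT-style
    genomic coordinates, accounting of newly resolved coding and non-coding
    nucleotides, inference of intragenic gene-conversion breakpoints from
    informative sites, lineage phylogenetics with square-root
    percentage-difference distances and neighbor-joining trees, serotype motif
    classification from exon-2 residues, homopolymer tract analysis, and a
    synthetic allele-family generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
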