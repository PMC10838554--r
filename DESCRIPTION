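Package: mitocharacter
Title: Characterization of Annotated Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytics for annotated circular mitochondrial genomes, built
    around the standard descriptive toolkit of avian mitogenome studies:
    per-region nucleotide composition with AT/GC skew, codon usage and
    relative synonymous codon usage (RSCU), start/stop-codon classification
    including incomplete (T--/TA-) stops, circular junction arithmetic for
    gene overlaps and intergenic spacers, control-region duplication
    gene-order classification, and 13-gene protein-coding supermatrix
    preparation with a neighbor-joining preview tree. A seeded synthetic
    mitogenome generator with recorded ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
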