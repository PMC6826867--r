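Package: csindel
Title: Discovery and Validation of Conserved Signature Indels in Protein
    Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects conserved signature indels (CSIs) in protein multiple
    sequence alignments: clade-specific insertions or deletions of fixed
    length embedded in conserved flanking sequence.  Provides alignment
    input/output with gapped/ungapped coordinate maps, candidate indel
    scanning with a configurable flank-conservation rule, taxonomic
    specificity calls against a named-clade taxonomy with outgroup-based
    insertion/deletion polarization, a semi-global affine-gap screen of
    BLAST homolog hit sets, signature report and table emitters, a
    single-copy-family supermatrix utility, and a clade-structured sequence
    simulator with planted indels for closed-loop benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
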