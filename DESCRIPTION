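Package: annocurate
Title: Curation-Oriented Functional Annotation of Phage and Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A headless toolkit for manual functional annotation of phage and
    bacterial genomes. Genomes are ingested from single-record FASTA files,
    genes are called with a built-in ORF finder or external caller adapters,
    phage genomes can be re-oriented to start at the terminase gene, and every
    feature is linked to a sequence-deduplicated annotation record with an
    automatic accession, a triage flag, notes, a user assignment, and a full
    edit history. Homology evidence from BLAST tabular and HH-suite reports
    (or a built-in Smith-Waterman search) is summarised into the predicates a
    rule-based decision guide uses to suggest product labels, and annotated
    genomes are exported as GenBank, GFF3, FASTA, and tabular files. A
    synthetic-genome fixture generator with known ground truth makes the whole
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
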