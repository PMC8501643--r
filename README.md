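# annocurate

Manual functional annotation of phage and bacterial genomes — the labelling
of predicted genes with product names, notes, and triage flags — is usually
done by juggling half a dozen homology web servers and a spreadsheet.
`annocurate` is a headless R toolkit that gives that workflow structure: a
persistent annotation store with sequence-deduplicated records and full edit
history, genome ingest with terminase-based re-orientation for phage
genomes, homology-evidence collection from the standard search tools, a
rule-based decision guide that turns the evidence into suggested labels, and
exporters for the formats downstream tools expect (GenBank, GFF3, FASTA,
tabular). It is aimed at annotation teams — phage-therapy safety screens,
novel-isolate characterisation, teaching labs — who want scriptable,
reproducible curation rather than a GUI.

## The data model

Three entities carry everything:

* a **genome** is one uploaded nucleotide sequence;
* a **feature** is a located CDS, tRNA, or repeat region on one genome;
* an **annotation** holds the accession, label, flag, notes, assignment, and
  history — and is unique per distinct sequence. Two features anywhere in
  the store with an identical protein share one annotation, so a label
  assigned once propagates to every genome that encodes that protein, and
  `n` genomes of a related phage cluster cost roughly one genome's worth of
  curation.

Accessions (`MAS_0000001`, …) are assigned automatically and never reused.
Every edit appends an event to an append-only history; replaying the history
reconstructs the current record exactly.

## Evidence and the decision guide

For each protein, stored homology results (BLAST tabular `-outfmt "6 std
slen stitle"`, HH-suite `.hhr`, or the built-in Smith–Waterman search used
for the internal and terminase databases) are summarised into the predicates
an annotator actually weighs: which databases answered, significance
(e ≤ 1e−5 significant, ≤ 1e−2 moderate; HHsearch probability ≥ 80 / ≥ 50),
within- and across-database label consistency (token-set Jaccard ≥ 0.5),
query/subject length similarity (min/max ≥ 0.8), and alignment coverage
classes (≥ 0.8 all/most, ≥ 0.35 some). An ordered rule table — from "no
results anywhere → hypothetical protein" through domain-containing naming,
curated-database trust, partial-coverage review, "putative" hedging,
internal-database naming consistency, remote-homology generalisation, and
cross-database conflict review — maps each evidence situation to a procedure
(P1–P12), a suggested label and flag, and a rationale listing every
predicate and threshold used. Suggestions are never auto-committed; a human
applies them with `apply_recommendation()`.

## Worked example

```r
library(annocurate)

# a synthetic circularly permuted, reverse-complemented phage genome with a
# known terminase operon
fx <- make_synthetic_phage(seed = 7, n_genes = 8, with_terminase = "both",
                           permute = TRUE, rc = TRUE)
fa <- tempfile(fileext = ".fasta"); cat(fx$fasta, file = fa)

store <- open_store("demo.store")
g <- upload_genome(store, fa, "Synthetic phage demo7",
                   upload_options(mode = "phage", reorient_terminase = TRUE))
identical(g$sequence, fx$truth$canonical_sequence)
#> [1] TRUE
list_genomes(store)[, c("name", "length", "n_features", "UNANNOTATED")]
#>                    name length n_features UNANNOTATED
#> 1 Synthetic phage demo7   3408          8           8

ft <- feature_table(store, g$name)
acc <- ft$accession[ft$start == 0]  # the re-oriented genome starts at the terminase
ann <- update_annotation(store, acc, list(label = "terminase small subunit",
                                          flag = "GREEN"), user = "alice")
get_history(store, acc)[, c("user", "field_changed", "old_value", "new_value")]
#>    user field_changed old_value               new_value
#> 1 alice         label           terminase small subunit
#> 2 alice          flag UNANNOTATED                 GREEN

rec <- recommend_annotation(summarize_evidence(store, acc))
rec$procedure; rec$suggested_label
#> [1] "P1"
#> [1] "hypothetical protein"   # no homology results stored yet

export_bundle(store, g$name, "demo7.tar.gz")
close_store(store)
```

The upload above called genes, searched the CDSs against the packaged
synthetic terminase database, found the small subunit upstream of the large
one, and rotated (here also reverse-complemented) the genome so annotation
starts at the terminase — the conventional canonical start for circularly
permuted phage genomes, which makes related genomes directly comparable.
The exported bundle contains `<genome>.fasta`, `<genome>_proteins.faa`,
`<genome>.gff3`, `<genome>_annotations.tsv`, and `<genome>.gbk`; public
notes appear in the GenBank file, private notes only in the annotation
table.

A thin command-line wrapper over the same functions ships at
`inst/cli/annocurate.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","annocurate.R",package="annocurate"))')" \
    upload-phage --store demo.store --fasta genome.fasta \
    --name "Escherichia phage Demo" --reorient-terminase
```

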