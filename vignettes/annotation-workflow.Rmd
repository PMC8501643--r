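---
title: "Models and methods behind annocurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind annocurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annocurate)
```

This vignette explains the models, conventions, and numerical choices the
package is built on: what the store guarantees, how ingest and terminase
re-orientation work, how homology evidence becomes a recommendation, what
the synthetic-data generator does and does not emulate, and the known
limitations.

## The store and its guarantees

The store is a single-file embedded database holding the genome, feature,
annotation, annotation-event, and search-result tables, with an exclusive
writer lock alongside the file. All access goes through the exported
operations; the file format is an implementation detail.

Three invariants do the real work:

* **Deduplication.** Exactly one annotation exists per distinct
  `(sequence, molecule kind)`. `get_or_create_annotation()` is the only
  path that creates annotations, so the invariant holds by construction:
  the count of protein annotations always equals the count of distinct CDS
  translations in the store.
* **Append-only history.** Edits that change nothing append nothing; every
  real change appends one event per field with the old and new values.
  Replaying the event log over the creation state reconstructs the current
  record — the property the test suite checks with an independent fold over
  the log.
* **Monotone accessions.** `MAS_%07d` with a strictly increasing counter
  that survives deletions; the zero-padded fixed width makes lexicographic
  and numeric order agree, which keeps "sorted by accession" navigation
  stable.

Coordinates are 0-based half-open internally and converted to 1-based
inclusive only at the format boundary (GenBank, GFF3, tabular exports).
Half-open arithmetic makes rotation and reverse-complement transforms
single-expression operations with no ±1 cases; a feature spanning the
origin is stored with `start > stop` plus a `wraps_origin` flag and covers
`[start, N) ∪ [0, stop)`.

Uploads are transactional: the store state is snapshotted first and
restored on any failure, so a half-ingested genome can never persist. Bulk
operations batch their on-disk writes; single edits write through
immediately.

## Ingest and terminase re-orientation

The built-in gene caller enumerates maximal ORFs on both strands (start
codon `ATG`/`GTG`/`TTG`, stops per the genetic code, default table 11,
minimum protein length 30 residues). Within one reading frame, nested ORFs
resolve to the longest (first qualifying start after the previous stop);
ORFs overlapping across frames are all kept, since over-calling is cheaper
to curate than silent under-calling. This caller is deliberately simple —
it has no coding-potential model — and exists so the whole pipeline runs
offline; production gene calling should go through the external-caller
adapters, which wrap a real CDS caller and a tRNA caller as pure functions
of the sequence and parse their native output formats.

Phage chromosomes assembled from circularly permuted packaging open at an
arbitrary position and orientation. Re-orientation standardises both: every
CDS translation is searched against a terminase protein database, and a CDS
counts as terminase evidence when its best hit has e-value ≤ 1e−10 with
query coverage ≥ 0.5 (both configurable; "enough evidence" is not defined
more precisely anywhere authoritative, so the package treats these as
explicit, auditable defaults). If both subunits are detected on one strand
the upstream one — 5′-most in the transcription direction — wins, because
the small subunit conventionally precedes the large one in the packaging
operon; otherwise the lowest e-value candidate wins. The transform then (1)
reverse-complements the genome when the chosen terminase lies on the minus
strand, so annotation reads forward, and (2) rotates the sequence so the
terminase starts at coordinate 0. Whether re-orientation should
reverse-complement at all is an interpretation (the convention is stated
only in terms of the start position); the package chooses yes, because a
canonical orientation as well as a canonical start is what makes related
genomes comparable, and the choice is visible and reversible. When both
subunits are detected but on opposite strands, no convention exists; the
package falls back to the lowest e-value candidate and warns. Genome
length, feature count, per-feature lengths, and the multiset of CDS
translations are invariant under the transform, and re-running it is the
identity — both properties are tested.

Direct terminal repeats are taken as user input (their length), not
detected: repeat detection on a single assembly is unreliable, and the
value is usually known from termini analysis upstream.

## The built-in protein search

The internal annotation database and the packaged terminase database are
searched with a built-in Smith–Waterman local aligner (BLOSUM62, affine
gaps: a gap of length L costs 11 + L), with bit scores from the published
gapped Karlin–Altschul parameters (λ = 0.267, K = 0.041) and e-values
`E = m·n·2^(−S′)` over the query length m and total database residues n.
These statistics are approximate — fixed constants, no edge or length
corrections — which is adequate for the databases it serves (small, and
queried for near-identity matches) and clearly inadequate as a general
BLAST substitute, which it is not meant to be. The aligner itself is exact:
the test suite checks its raw scores against an independently written
brute-force dynamic-programming oracle on hundreds of random pairs.
Profile and HMM–HMM searches are never emulated; those tools are reached
only through result-file parsers (`-outfmt "6 std slen stitle"` tabular,
HH-suite `.hhr`).

Internal-database searches exclude the query's own annotation entry:
deduplication means the query's sequence is always present as itself, and a
guaranteed self-hit with a possibly empty label would only pollute the
evidence.

## From evidence to a recommendation

`summarize_evidence()` reduces each stored result set to the predicates an
annotator weighs, all thresholds explicit and configurable
(`default_thresholds()`):

| predicate | default |
|---|---|
| significant / moderate (BLAST-style e-value) | ≤ 1e−5 / ≤ 1e−2 |
| significant / moderate (HHsearch probability) | ≥ 80 / ≥ 50 |
| coverage class all/most / some | ≥ 0.8 / ≥ 0.35 |
| length similarity (min/max of query and subject length) | ≥ 0.8 |
| label consistency (pairwise token-set Jaccard, majority) | ≥ 0.5, top 5 |

None of these numbers has an authoritative value; they are design choices,
and every recommendation records the values it used in its rationale so a
reviewer can audit exactly why a rule fired.

The decision guide itself is a set of situations, not an algorithm — in its
source form several rows can apply at once and many cells are left blank.
Making it executable required imposing a total order. The package evaluates
the rules specificity-first (single-database situations before multi-
database ones, internal-database preference before generic conflict
handling) and reports, in the rationale, every other rule that would also
have applied. Two deliberate interpretation points:

* **P1 as fallback.** "No results in any database" suggests *hypothetical
  protein*. A summary whose results exist but are all non-significant, or
  moderate yet mutually inconsistent, matches no other row; the engine
  routes these to P1 too, because the evidence supports nothing stronger.
  This makes the engine total: every well-formed summary fires exactly one
  procedure, which a fuzz test over randomized summaries enforces.
* **Curated-trust generalisation (P7).** The "trust the curated database's
  label directly" rule is keyed to the most curated significant database
  (curation order: internal > curated protein db > domain db > structure
  db > nr) rather than hard-coded to one database, so consistent
  full-coverage evidence from, say, domain + structure searches does not
  fall through to the fallback. With the curated protein database present
  the behaviour is exactly the original rule. Remote-homology-only evidence
  is explicitly excluded (that is P11's case, which generalises the label
  to its head noun to avoid over-annotation, prefixing "putative" when the
  generalisation loses information).

The engine only ever *suggests*. `apply_recommendation()` writes the label
and flag through the normal edit path (history recorded, internal database
marked stale) and refuses stale recommendations — if the annotation was
edited after the evidence was summarised, the caller must re-summarise.

## Exports

GenBank, GFF3, FASTA, and tabular writers convert coordinates at the
boundary; origin-wrapping features become `join()` locations in GenBank and
two `ID`-sharing lines in GFF3. Private notes appear in exactly one output
(the annotation table, which exists to round-trip curation data); the
GenBank `/note` carries public notes only — a privacy property the tests
check against every writer. "Spreadsheet" import/export is TSV: the column
set is fixed, import matches rows to annotations by exact case-insensitive
protein sequence, and re-importing an unmodified export is a no-op. The
per-genome bundle (FASTA, protein multi-FASTA, GFF3, annotation table,
GenBank) is a gzip tarball with deterministic member order; in test mode
member timestamps are pinned, making the archive byte-reproducible.

## The synthetic-data generator

`make_synthetic_phage()` is first-class, tested code, not a convenience: it
is the ground truth the whole suite measures against. It plants genes with
valid structure in random intergenic background, optionally including fixed
synthetic terminase marker proteins (small subunit immediately upstream of
the large, operon-like), optional direct terminal repeats, and optional
circular permutation / reverse complement of the emitted sequence. Truth
records gene coordinates (in emitted-sequence space), proteins, coding
sequences, roles, and the canonical (terminase-first, forward-strand)
sequence that re-orientation should recover.

The generator guarantees the built-in caller recovers *exactly* the planted
genes. Three mechanisms combine: every gene is flanked by in-frame stop
guards so no upstream start can extend it; genes are built nucleotide-first
with a short "stop cassette" (four sense codons whose junction windows read
as a stop codon in all five off-frames) interleaved every ~18 codons, so no
reportable ORF fits inside a gene in another frame; and a post-assembly
scrub breaks any remaining incidental ORF by sowing stop codons in
intergenic sequence or, where an ORF lies within a gene, recoding gene
codons synonymously — repairs are position-locked so later repairs cannot
undo earlier ones. Permutation offsets are drawn from intergenic positions
only, mirroring the biology (packaging cuts do not bisect the genes a
re-orientation test needs) and keeping the planted truth exact.

What the generator does *not* emulate, and what passing tests therefore do
not show: real codon usage and GC content (codons are uniform over
synonyms, plus the cassette motif), overlapping genes, programmed
frameshifts, sequencing error, IUPAC ambiguity, tRNA genes (the built-in
caller has no tRNA model), or realistic homology structure (the terminase
database contains synthetic markers mutated at ≤ 10% of positions plus
random decoys, not real terminase diversity). Results on real genomes
depend on the external callers and search tools plugged into the adapters;
the synthetic suite validates the plumbing, bookkeeping, transforms, and
decision logic around them.

Mock homology-result files (`make_mock_results()`) encode one evidence
pattern per decision-guide procedure — fourteen patterns including the
domain-of-unknown-function and disjoint-multi-domain variants — as
syntactically valid BLAST tabular and `.hhr` files, so the parser → summary
→ recommendation path is exercised end to end without any search backend.

## Numerical and convention choices

* E-value colour scale: linear interpolation in log10 space from black
  (`#000000`) at e = 10 to light yellow (`#FFFFE0`) at e = 0, with the
  floor pinned at 1e−180 to keep `log10` finite in double precision; hex
  values for the two named colours are design choices.
* Genome-map data products are emitted only for genomes with fewer than
  1000 features (a drawability threshold); the map is a JSON block list,
  not an interactive view.
* Strict nucleotide alphabet `{A,C,G,T,N}`: IUPAC ambiguity codes are
  rejected at upload. This keeps translation deterministic and is a
  documented limitation — degenerate bases must be resolved upstream.
* Accession format, the 5-column custom gene-call table (`seqid`, `kind`,
  `start`, `stop`, `strand`; 1-based inclusive), and the
  `accession|flag|label` internal-database header encoding are fixed
  conventions chosen for round-trip safety.
* Problem sizes in the shipped tests and the acceptance script — genomes of
  5–10 genes around 120 codons, 20 re-orientation fixtures, 200
  aligner-oracle pairs, map-threshold genomes of 998–1001 single-annotation
  features — were chosen as the smallest sizes at which each property is
  non-trivially exercised.

## Known limitations

The store is single-writer (the lock refuses concurrent writers rather
than serialising them); user identity is a free-text name with no
authentication; tRNA and repeat annotations are not searchable (only
CDS/protein searches are implemented); polyprotein splitting and
feature-coordinate editing are out of scope (coordinates come from callers
or the user); and the built-in caller and search statistics are, as noted,
offline stand-ins with documented simplifications rather than replacements
for the real tools.
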