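# A small fully-annotated store shared by the export tests.
export_fixture <- function() {
  store <- new_test_store()
  fx <- make_synthetic_phage(seed = 91, n_genes = 5)
  res <- upload_fixture(fx, name = "Escherichia phage Exporter", store = store)
  ft <- feature_table(store, res$genome$name)
  update_annotation(store, ft$accession[1],
                    list(label = "portal protein", public_notes = "seen in many phages",
                         private_notes = "PRIV-abc123", assigned_to = "alice"),
                    "alice")
  update_annotation(store, ft$accession[2], list(label = "holin", flag = "GREEN"),
                    "alice")
  list(store = store, genome = res$genome$name, ft = ft, fx = fx)
}

test_that("genome FASTA wraps at 70 columns and round-trips", {
  ex <- export_fixture()
  on.exit(close_store(ex$store))
  txt <- write_genome_fasta(ex$store, ex$genome)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(lines[1], paste0(">", ex$genome))       # spaces preserved
  body <- lines[-1]
  expect_true(all(nchar(body[-length(body)]) == 70L))

  fa <- tempfile(fileext = ".fa")
  write_genome_fasta(ex$store, ex$genome, fa)
  back <- read_single_fasta(fa)
  expect_equal(back$sequence, get_genome(ex$store, ex$genome)$sequence)
})

test_that("CDS translation export lists proteins in genomic order with accessions", {
  ex <- export_fixture()
  on.exit(close_store(ex$store))
  txt <- write_cds_translations(ex$store, ex$genome)
  hdr <- grep("^>", strsplit(txt, "\n")[[1]], value = TRUE)
  expect_equal(length(hdr), 5L)
  expect_match(hdr[1], "^>MAS_[0-9]{7} portal protein$")

  # two features sharing one annotation -> two records, same accession header
  store <- new_test_store()
  on.exit(close_store(store), add = TRUE)
  upload_repeat_cds_genome(store, "dup", 2L)
  txt2 <- write_cds_translations(store, "dup")
  hdr2 <- grep("^>", strsplit(txt2, "\n")[[1]], value = TRUE)
  expect_equal(length(hdr2), 2L)
  expect_equal(hdr2[1], hdr2[2])
})

test_that("GFF3 export converts coordinates and round-trips through the loader", {
  ex <- export_fixture()
  on.exit(close_store(ex$store))
  txt <- write_gff3(ex$store, ex$genome)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(lines[1], "##gff-version 3")
  first <- strsplit(grep("\tCDS\t", lines, value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(first[4]), ex$ft$start[1] + 1L)
  expect_equal(as.integer(first[5]), ex$ft$stop[1])
  expect_match(first[9], "ID=MAS_[0-9]{7};product=")

  gff <- tempfile(fileext = ".gff3")
  write_gff3(ex$store, ex$genome, gff)
  back <- load_user_features(gff, nchar(get_genome(ex$store, ex$genome)$sequence))
  expect_equal(back[, c("kind", "start", "stop", "strand")],
               ex$ft[order(ex$ft$start), c("kind", "start", "stop", "strand")],
               ignore_attr = TRUE)
})

test_that("GenBank export parses with an independent reader to the same features", {
  ex <- export_fixture()
  on.exit(close_store(ex$store))
  gbk <- tempfile(fileext = ".gbk")
  write_genbank(ex$store, ex$genome, gbk)
  txt <- paste(readLines(gbk), collapse = "\n")
  expect_match(txt, "PHG")                       # phage division
  expect_match(txt, "/product=\"portal protein\"")
  expect_match(txt, "/note=\"seen in many phages\"")

  py <- sprintf(paste0(
    "from Bio import SeqIO\n",
    "rec = list(SeqIO.parse('%s', 'genbank'))[0]\n",
    "cds = [f for f in rec.features if f.type == 'CDS']\n",
    "print(len(rec.seq))\n",
    "for f in cds:\n",
    "    pid = f.qualifiers['protein_id'][0]\n",
    "    print(int(f.location.start), int(f.location.end), f.location.strand, pid)\n"),
    gbk)
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  expect_equal(as.integer(out[1]),
               nchar(get_genome(ex$store, ex$genome)$sequence))
  parsed <- read.table(text = out[-1],
                       col.names = c("start", "end", "strand", "protein_id"))
  internal <- ex$ft[ex$ft$kind == "CDS", ]
  internal <- internal[order(internal$start), ]
  expect_equal(parsed$start, internal$start)     # biopython is 0-based too
  expect_equal(parsed$end, internal$stop)
  expect_equal(ifelse(parsed$strand > 0, "+", "-"), internal$strand)
  expect_equal(parsed$protein_id, internal$accession)
})

test_that("private notes never leak into GenBank, GFF3, or FASTA outputs", {
  ex <- export_fixture()
  on.exit(close_store(ex$store))
  secret <- "PRIV-abc123"
  expect_false(grepl(secret, write_genbank(ex$store, ex$genome), fixed = TRUE))
  expect_false(grepl(secret, write_gff3(ex$store, ex$genome), fixed = TRUE))
  expect_false(grepl(secret, write_genome_fasta(ex$store, ex$genome), fixed = TRUE))
  expect_false(grepl(secret, write_cds_translations(ex$store, ex$genome), fixed = TRUE))
  # the annotation table is the one place that carries them
  tab <- write_annotation_table(ex$store, "genome", ex$genome)
  expect_true(secret %in% tab$private_notes)
})

test_that("wrapping features export as two GFF3 lines and a GenBank join()", {
  store <- new_test_store()
  on.exit(close_store(store))
  n <- 120L
  seqn <- strrep("ACGT", n / 4)
  # a CDS crossing the origin: [90, 120) + [0, 30), length 60
  prot <- translate_cds(seqn, 90L, 30L, "+", wraps_origin = TRUE)
  acc <- get_or_create_annotation(store, prot, "protein")$annotation$accession
  annocurate:::add_genome_record(
    store, "wrapped", seqn, "linear", "phage",
    data.frame(kind = "CDS", start = 90L, stop = 30L, strand = "+",
               wraps_origin = TRUE, accession = acc, stringsAsFactors = FALSE))

  gff <- strsplit(write_gff3(store, "wrapped"), "\n")[[1]]
  segs <- grep("\tCDS\t", gff, value = TRUE)
  expect_equal(length(segs), 2L)                      # two lines, same ID
  cols <- do.call(rbind, strsplit(segs, "\t"))
  expect_equal(as.integer(cols[, 4]), c(91L, 1L))
  expect_equal(as.integer(cols[, 5]), c(120L, 30L))
  expect_equal(length(unique(cols[, 9])), 1L)

  gbk <- write_genbank(store, "wrapped")
  expect_match(gbk, "join\\(91\\.\\.120,1\\.\\.30\\)")
})

test_that("annotation table import matches by sequence and suppresses no-ops", {
  ex <- export_fixture()
  on.exit(close_store(ex$store))
  tab <- write_annotation_table(ex$store, "genome", ex$genome)
  expect_equal(names(tab),
               c("accession", "label", "flag", "public_notes", "private_notes",
                 "assigned_to", "sequence", "genome", "start", "stop", "strand"))
  expect_equal(nrow(tab), 5L)

  # re-import of an unchanged export is a no-op
  rep0 <- import_annotation_table(ex$store, tab, "carol")
  expect_equal(rep0$matched, 5L)
  expect_equal(rep0$updated, 0L)

  # lowercase sequence still matches; unknown sequence is reported verbatim
  tab2 <- data.frame(sequence = c(tolower(tab$sequence[1]), "MNOTINSTORE"),
                     label = c("renamed protein", "whatever"),
                     stringsAsFactors = FALSE)
  rep1 <- import_annotation_table(ex$store, tab2, "carol")
  expect_equal(rep1$matched, 1L)
  expect_equal(rep1$updated, 1L)
  expect_equal(rep1$unmatched$sequence, "MNOTINSTORE")
  expect_equal(get_annotation(ex$store, tab$accession[1])$label, "renamed protein")
  h <- get_history(ex$store, tab$accession[1])
  expect_equal(h$user[nrow(h)], "carol")

  expect_error(import_annotation_table(ex$store, data.frame(label = "x"), "u"),
               class = "anno_format_error")
  rep2 <- import_annotation_table(ex$store,
                                  data.frame(sequence = character(),
                                             label = character()), "u")
  expect_equal(unlist(rep2[c("matched", "updated")]), c(matched = 0L, updated = 0L))
})

test_that("store-wide annotation table has one row per annotation, blank genome columns", {
  ex <- export_fixture()
  on.exit(close_store(ex$store))
  tab <- write_annotation_table(ex$store, "store")
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab$genome == ""))
})

test_that("export bundle is complete, valid, and byte-reproducible in test mode", {
  ex <- export_fixture()
  on.exit(close_store(ex$store))
  b1 <- tempfile(fileext = ".tar.gz")
  b2 <- tempfile(fileext = ".tar.gz")
  export_bundle(ex$store, ex$genome, b1)
  export_bundle(ex$store, ex$genome, b2)
  expect_identical(readBin(b1, "raw", file.info(b1)$size),
                   readBin(b2, "raw", file.info(b2)$size))

  ed <- tempfile()
  untar(b1, exdir = ed)
  files <- list.files(ed)
  base <- "Escherichia_phage_Exporter"
  expect_setequal(files, paste0(base, c(".fasta", "_proteins.faa", ".gff3",
                                        "_annotations.tsv", ".gbk")))
  # each member passes its own reader
  expect_silent(read_single_fasta(file.path(ed, paste0(base, ".fasta"))))
  expect_gt(nrow(load_user_features(file.path(ed, paste0(base, ".gff3")), 1e7)), 0)
  expect_gt(nrow(read.delim(file.path(ed, paste0(base, "_annotations.tsv")))), 0)
  expect_error(export_bundle(ex$store, "absent", tempfile()),
               class = "anno_not_found_error")
})
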