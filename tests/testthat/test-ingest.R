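test_that("single-record FASTA reading normalizes case and rejects bad input", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">p", "acgt"), fa)
  expect_equal(read_single_fasta(fa), list(header = "p", sequence = "ACGT"))

  writeLines(c(">a", "ACGT", ">b", "ACGT"), fa)
  expect_error(read_single_fasta(fa), class = "anno_format_error")

  writeLines(c(">a", "ACGX"), fa)
  expect_error(read_single_fasta(fa), class = "anno_format_error")

  writeLines(c(">a", "ACGW"), fa)  # IUPAC ambiguity is rejected by design
  expect_error(read_single_fasta(fa), class = "anno_format_error")
})

test_that("builtin caller recovers planted ORFs exactly, on both strands", {
  fx <- make_synthetic_phage(seed = 5, n_genes = 6)
  called <- call_genes_builtin(fx$sequence)
  expect_equal(called[, c("start", "stop", "strand")],
               fx$truth$genes[, c("start", "stop", "strand")],
               ignore_attr = TRUE)
  expect_setequal(called$strand, c("+", "-"))
  # recovered minus-strand translations equal the planted proteins
  for (i in seq_len(nrow(called))) {
    expect_equal(
      translate_cds(fx$sequence, called$start[i], called$stop[i], called$strand[i]),
      fx$truth$genes$protein[i])
  }
  # all-N sequence has no ORFs
  expect_equal(nrow(call_genes_builtin(strrep("N", 2000))), 0L)
})

test_that("user feature files load from GFF3 and 5-column TSV with validation", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "g\t.\tCDS\t1\t99\t.\t+\t.\tID=x",
               "g\t.\tgene\t10\t20\t.\t+\t.\tID=y"), f)
  expect_warning(d <- load_user_features(f, 200L), "not modeled")
  expect_equal(nrow(d), 1L)
  expect_equal(d$start, 0L)   # 1-based inclusive -> 0-based half-open
  expect_equal(d$stop, 99L)

  t5 <- tempfile(fileext = ".tsv")
  writeLines("g\ttRNA\t5\t80\t-", t5)
  d <- load_user_features(t5, 100L)
  expect_equal(d[, c("kind", "start", "stop", "strand")],
               data.frame(kind = "tRNA", start = 4L, stop = 80L, strand = "-"),
               ignore_attr = TRUE)

  writeLines("g\tCDS\t1\t500\t+", t5)
  expect_error(load_user_features(t5, 100L), class = "anno_validation_error")
  writeLines("g\tCDS\t1\t100\t+", t5)   # length 100, not divisible by 3
  expect_error(load_user_features(t5, 200L), class = "anno_validation_error")
})

test_that("CDS translation follows table 11, strips stop, flags internal stops", {
  expect_equal(translate_cds("ATGAAATAA", 0, 9, "+"), "MK")
  expect_equal(translate_cds("TTACATCAT", 0, 9, "-"), "MM")
  expect_error(translate_cds("ATGTAAAAATAA", 0, 12, "+"),
               class = "anno_validation_error")
  # wrap-aware extraction: gene crossing the origin reads tail then head
  expect_equal(translate_cds("AAATAAATG", 6, 6, "+", wraps_origin = TRUE), "MK")
})

test_that("terminal repeat features sit at both genome ends", {
  d <- add_terminal_repeats(1000L, 50L)
  expect_equal(d$start, c(0L, 950L))
  expect_equal(d$stop, c(50L, 1000L))
  expect_equal(unique(d$kind), "repeat_region")
  expect_error(add_terminal_repeats(100L, 50L), class = "anno_validation_error")
  d <- add_terminal_repeats(1000L, 1L)
  expect_equal(d$start, c(0L, 999L))
})

test_that("terminase detection finds the planted subunit and prefers the upstream one", {
  tdb <- tempfile(fileext = ".faa")
  make_terminase_db(seed = 2, path = tdb)

  fx <- make_synthetic_phage(seed = 21, n_genes = 6, with_terminase = "large")
  cds <- fx$truth$genes
  call <- detect_terminase(cds, cds$protein, tdb)
  expect_false(is.null(call))
  expect_equal(call$subunit, "large")
  expect_equal(cds$role[call$feature_index], "terminase_large")
  expect_lte(call$best_evalue, 1e-10)
  expect_gte(call$query_coverage, 0.5)

  # both subunits on one strand: the upstream (5'-most transcribed) wins
  fx2 <- make_synthetic_phage(seed = 22, n_genes = 6, with_terminase = "both")
  cds2 <- fx2$truth$genes
  call2 <- detect_terminase(cds2, cds2$protein, tdb)
  tg <- cds2[cds2$role != "generic", ]
  upstream <- if (tg$strand[1] == "+") tg[which.min(tg$start), ] else tg[which.max(tg$start), ]
  expect_equal(call2$start, upstream$start)
  expect_equal(call2$subunit,
               sub("terminase_", "", upstream$role))

  # no candidate below threshold -> NULL
  fx3 <- make_synthetic_phage(seed = 23, n_genes = 4, with_terminase = "none")
  expect_null(detect_terminase(fx3$truth$genes, fx3$truth$genes$protein, tdb))
  expect_error(detect_terminase(cds, cds$protein,
                                data.frame(id = character(), description = character(),
                                           sequence = character())),
               class = "anno_config_error")
})

test_that("re-orientation rotates, reverse-complements, and is idempotent", {
  # plain rotation arithmetic
  feats <- data.frame(kind = "CDS", start = c(300L, 500L), stop = c(360L, 800L),
                      strand = "+", wraps_origin = FALSE, source = "x")
  s <- strrep("ACGT", 250)  # 1000 nt
  ro <- reorient_genome(s, feats, list(start = 300L, stop = 360L, strand = "+"))
  expect_equal(ro$features$start, c(0L, 200L))
  expect_equal(ro$features$stop, c(60L, 500L))
  expect_equal(nchar(ro$sequence), 1000L)

  # a feature crossing the new origin is marked wrapping, length preserved
  feats2 <- data.frame(kind = "CDS", start = c(300L, 250L), stop = c(360L, 350L),
                       strand = "+", wraps_origin = FALSE, source = "x")
  ro2 <- reorient_genome(s, feats2, list(start = 300L, stop = 360L, strand = "+"))
  w <- ro2$features[2, ]
  expect_true(w$wraps_origin)
  expect_equal((w$stop - w$start) %% 1000L, 100L)

  # minus-strand terminase: genome reverse-complemented, terminase ends at 0/+
  fx <- make_synthetic_phage(seed = 31, n_genes = 5, with_terminase = "large")
  tg <- fx$truth$genes[fx$truth$genes$role == "terminase_large", ]
  ro3 <- reorient_genome(fx$sequence, fx$truth$genes[, c("start", "stop", "strand")],
                         list(start = tg$start, stop = tg$stop, strand = tg$strand))
  ti <- which(fx$truth$genes$role == "terminase_large")
  expect_equal(ro3$features$start[ti], 0L)
  expect_equal(ro3$features$strand[ti], "+")
  # idempotence: re-running with the terminase already at 0/+ changes nothing
  ro4 <- reorient_genome(ro3$sequence, ro3$features,
                         list(start = 0L, stop = ro3$features$stop[ti], strand = "+"))
  expect_identical(ro4$sequence, ro3$sequence)
  expect_equal(ro4$features$start, ro3$features$start)

  expect_error(reorient_genome(s, feats, list(start = 1L, stop = 2L, strand = "+")),
               class = "anno_validation_error")
})

test_that("re-orientation conserves length, feature count, and CDS translations", {
  for (seed in c(41, 42)) {
    fx <- make_synthetic_phage(seed = seed, n_genes = 6, with_terminase = "large",
                               permute = TRUE, rc = (seed %% 2 == 0))
    tg <- fx$truth$genes[fx$truth$genes$role == "terminase_large", ]
    ro <- reorient_genome(fx$sequence, fx$truth$genes[, c("start", "stop", "strand")],
                          list(start = tg$start, stop = tg$stop, strand = tg$strand))
    expect_equal(nchar(ro$sequence), nchar(fx$sequence))
    expect_equal(nrow(ro$features), nrow(fx$truth$genes))
    before <- sort(fx$truth$genes$protein)
    after <- sort(vapply(seq_len(nrow(ro$features)), function(i)
      translate_cds(ro$sequence, ro$features$start[i], ro$features$stop[i],
                    ro$features$strand[i], wraps_origin = ro$features$wraps_origin[i]),
      character(1)))
    expect_equal(after, before)
  }
})

test_that("upload orchestrates calling, dedup, assignment, and atomicity", {
  store <- new_test_store()
  on.exit(close_store(store))
  fx <- make_synthetic_phage(seed = 51, n_genes = 10)
  fa <- tempfile(fileext = ".fa"); cat(fx$fasta, file = fa)

  g <- upload_genome(store, fa, "Pseudomonas phage T1",
                     upload_options(mode = "phage", assign_to = "bob"))
  ft <- feature_table(store, g$name)
  expect_equal(sum(ft$kind == "CDS"), 10L)
  anns <- list_annotations(store, flag = "UNANNOTATED")
  expect_equal(nrow(anns), 10L)
  expect_true(all(anns$assigned_to == "bob"))

  # same fixture under a different name: zero new annotations (all dedup)
  n_before <- nrow(list_annotations(store))
  upload_genome(store, fa, "Pseudomonas phage T2", upload_options(mode = "phage"))
  expect_equal(nrow(list_annotations(store)), n_before)

  # duplicate name refused
  expect_error(upload_genome(store, fa, "Pseudomonas phage T1",
                             upload_options(mode = "phage")),
               class = "anno_validation_error")

  # atomicity: a failing upload leaves counts unchanged
  bad <- tempfile(fileext = ".fa"); writeLines(c(">x", "ACGTX"), bad)
  genomes_before <- nrow(list_genomes(store))
  expect_error(upload_genome(store, bad, "broken", upload_options(mode = "phage")))
  expect_equal(nrow(list_genomes(store)), genomes_before)
  expect_equal(nrow(list_annotations(store)), n_before)
})

test_that("circular-permutation recovery: upload restores the canonical start", {
  store <- new_test_store()
  on.exit(close_store(store))
  fx <- make_synthetic_phage(seed = 61, n_genes = 8, with_terminase = "both",
                             permute = TRUE, rc = TRUE)
  fa <- tempfile(fileext = ".fa"); cat(fx$fasta, file = fa)
  g <- upload_genome(store, fa, fx$name,
                     upload_options(mode = "phage", reorient_terminase = TRUE))
  expect_identical(g$sequence, fx$truth$canonical_sequence)
})

test_that("DTR upload creates repeat features with TRNA/NONE flag conventions", {
  store <- new_test_store()
  on.exit(close_store(store))
  fx <- make_synthetic_phage(seed = 71, n_genes = 4, dtr_length = 60L)
  fa <- tempfile(fileext = ".fa"); cat(fx$fasta, file = fa)
  g <- upload_genome(store, fa, "dtr phage",
                     upload_options(mode = "phage", dtr_length = 60L))
  ft <- feature_table(store, g$name)
  reps <- ft[ft$kind == "repeat_region", ]
  expect_equal(nrow(reps), 2L)
  expect_equal(reps$start, c(0L, nchar(g$sequence) - 60L))
  # repeat annotations are nucleotide records, one shared annotation (identical repeats)
  expect_equal(length(unique(reps$accession)), 1L)
  expect_equal(get_annotation(store, reps$accession[1])$molecule_kind, "dna")
})

test_that("external caller adapters parse recorded outputs and fail loudly", {
  glimmer_out <- system.file("extdata", "glimmer_example.predict",
                             package = "annocurate")
  cfg <- list(adapters = list(
    glimmer = list(command = "cp", args = paste(glimmer_out, "{out}"),
                   parser = "glimmer_predict")))
  d <- run_external_caller(strrep("ACGT", 500), "glimmer", cfg)
  expect_equal(nrow(d), 3L)
  expect_equal(d$start, c(100L, 499L, 949L))
  expect_equal(d$stop, c(403L, 712L, 1276L))
  expect_equal(d$strand, c("+", "-", "+"))

  trna_out <- system.file("extdata", "trnascan_example.tsv", package = "annocurate")
  cfg2 <- list(adapters = list(
    trnascan = list(command = "cp", args = paste(trna_out, "{out}"),
                    parser = "trnascan_tabular")))
  d2 <- run_external_caller(strrep("ACGT", 500), "trnascan", cfg2)
  expect_equal(d2$kind, c("tRNA", "tRNA"))
  expect_equal(d2$start, c(119L, 379L))
  expect_equal(d2$strand, c("+", "-"))

  expect_error(run_external_caller("ACGT", "missing", list(adapters = list())),
               class = "anno_adapter_error")
  cfg3 <- list(adapters = list(x = list(command = "no-such-binary-xyz",
                                        args = "{fasta}", parser = "glimmer_predict")))
  expect_error(run_external_caller("ACGT", "x", cfg3), class = "anno_adapter_error")
})
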