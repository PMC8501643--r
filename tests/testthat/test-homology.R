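blast_row <- function(q = "q", s = "sp|P1|X", pid = 55.2, len = 100, mm = 40,
                      go = 2, qs = 1, qe = 100, ss = 1, se = 100, ev = "3e-42",
                      bs = 150.3, slen = 100, title = "terminase large subunit") {
  paste(q, s, pid, len, mm, go, qs, qe, ss, se, ev, bs, slen, title, sep = "\t")
}

test_that("BLAST tabular parsing handles the fixed dialect, comments, and errors", {
  h <- parse_blast_tabular(blast_row())
  expect_equal(nrow(h), 1L)
  expect_equal(h$evalue, 3e-42)
  expect_equal(h$subject_description, "terminase large subunit")
  expect_equal(h$subject_length, 100L)

  txt <- paste("# BLASTP 2.12.0", "# Fields: qseqid, ...", blast_row(), sep = "\n")
  expect_equal(nrow(parse_blast_tabular(txt, has_comments = TRUE)), 1L)
  expect_error(parse_blast_tabular(txt, has_comments = FALSE),
               class = "anno_format_error")

  expect_error(parse_blast_tabular("a\tb\tc"), class = "anno_format_error")
  expect_error(parse_blast_tabular(blast_row(qs = 50, qe = 10)),
               class = "anno_format_error")
  expect_error(parse_blast_tabular(blast_row(ev = "banana")),
               class = "anno_format_error")

  # rows re-sorted by ascending e-value
  two <- paste(blast_row(ev = "1e-3"), blast_row(ev = "1e-30"), sep = "\n")
  expect_equal(parse_blast_tabular(two)$evalue, c(1e-30, 1e-3))
})

test_that("tabular serialization round-trips through the parser", {
  hits <- parse_blast_tabular(paste(blast_row(ev = "1e-30"),
                                    blast_row(s = "Y", ev = "2e-10", title = "holin"),
                                    sep = "\n"))
  back <- parse_blast_tabular(write_blast_tabular(hits))
  expect_equal(back[, c("subject_id", "evalue", "q_start", "q_end", "s_start",
                        "s_end", "subject_length", "subject_description")],
               hits[, c("subject_id", "evalue", "q_start", "q_end", "s_start",
                        "s_end", "subject_length", "subject_description")])
})

test_that(".hhr reports parse to probability-ordered hits", {
  hits_in <- data.frame(
    subject_id = c("2ABC_A", "3XYZ_B"),
    subject_description = c("cell death-related nuclease", "putative helicase"),
    subject_length = c(120L, 310L), evalue = c(1.2e-30, 0.5),
    score = c(99.1, 45.0), q_start = c(5L, 10L), q_end = c(99L, 180L),
    s_start = c(10L, 12L), s_end = c(110L, 190L),
    aligned_query = NA_character_, aligned_subject = NA_character_,
    stringsAsFactors = FALSE)
  txt <- annocurate:::write_hhr(hits_in, query = "q1", match_columns = 200L)
  h <- parse_hhr(txt)
  expect_equal(nrow(h), 2L)
  expect_equal(h$score, c(99.1, 45.0))       # Prob first
  expect_equal(h$subject_id, c("2ABC_A", "3XYZ_B"))
  expect_equal(h$subject_description[1], "cell death-related nuclease")
  expect_equal(h$q_start, c(5L, 10L))
  expect_equal(h$subject_length, c(120L, 310L))

  # empty hit list
  empty <- sub("(?s)(No Hit[^\n]*\n).*", "\\1\n", txt, perl = TRUE)
  expect_equal(nrow(parse_hhr(empty)), 0L)

  # truncated summary row
  lines <- strsplit(txt, "\n")[[1]]
  row_i <- grep("^  1 ", lines)[1]
  lines[row_i] <- substr(lines[row_i], 1, 45)
  expect_error(parse_hhr(paste(lines, collapse = "\n")), class = "anno_format_error")

  expect_error(parse_hhr("not a report"), class = "anno_format_error")
})

test_that("builtin search ranks a self-hit first with full coordinates", {
  set.seed(7)
  db <- data.frame(id = sprintf("P%02d", 1:5),
                   description = paste("decoy", 1:5),
                   sequence = replicate(5, random_aa_string(80)),
                   stringsAsFactors = FALSE)
  db$sequence[3] <- random_aa_string(60)
  hits <- builtin_protein_search(db$sequence[3], db)
  expect_equal(hits$subject_id[1], "P03")
  expect_equal(c(hits$q_start[1], hits$q_end[1]), c(1L, 60L))
  expect_equal(c(hits$s_start[1], hits$s_end[1]), c(1L, 60L))
  expect_error(builtin_protein_search("", db), class = "anno_validation_error")

  # unrelated random proteins under a strict cutoff: nothing reported
  strict <- builtin_protein_search(random_aa_string(60), db,
                                   params = list(max_evalue = 1e-10))
  expect_equal(nrow(strict), 0L)
})

test_that("builtin aligner raw scores equal the brute-force DP oracle", {
  set.seed(11)
  for (k in 1:25) {
    a <- random_aa_string(sample(8:40, 1))
    b <- random_aa_string(sample(8:40, 1))
    impl <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(impl, sw_oracle(a, b))
  }
})

test_that("e-value decreases monotonically in bit score", {
  bits <- annocurate:::raw_to_bit(seq(20, 400, by = 20))
  ev <- 200 * 10000 * 2^(-bits)
  expect_true(all(diff(bits) > 0))
  expect_true(all(diff(ev) < 0))
})

test_that("search results supersede per (annotation, tool, database)", {
  store <- new_test_store()
  on.exit(close_store(store))
  acc <- get_or_create_annotation(store, random_aa_string(50),
                                  "protein")$annotation$accession
  h1 <- parse_blast_tabular(blast_row(title = "first run"))
  h2 <- parse_blast_tabular(blast_row(title = "second run"))
  store_search_result(store, acc, "blastp", "swissprot", h1)
  store_search_result(store, acc, "blastp", "swissprot", h2)
  res <- get_search_results(store, acc)
  expect_equal(length(res), 1L)
  expect_equal(res[[1]]$hits$subject_description, "second run")

  expect_error(store_search_result(store, acc, "blastp", "cdd", h1),
               class = "anno_validation_error")  # unsupported pairing
  expect_error(store_search_result(store, acc, "rpsblast", "pdb", h1),
               class = "anno_validation_error")
  expect_error(run_search(store, acc, "hhsearch", "pdb", backend = "builtin"),
               class = "anno_adapter_error")     # no builtin HMM search
})

test_that("internal database rebuild reflects store edits and dedup", {
  store <- new_test_store()
  on.exit(close_store(store))
  res <- upload_fixture(make_synthetic_phage(seed = 81, n_genes = 4), store = store)
  upload_fixture(make_synthetic_phage(seed = 82, n_genes = 3), store = store,
                 name = "second")

  idb <- rebuild_internal_db(store)
  expect_equal(nrow(idb$entries), 7L)   # distinct proteins across both genomes
  expect_false(internal_db_stale(store))

  acc <- idb$entries$accession[1]
  update_annotation(store, acc, list(label = "portal protein", flag = "GREEN"),
                    "alice")
  expect_true(internal_db_stale(store))
  idb2 <- rebuild_internal_db(store)
  e <- idb2$entries[idb2$entries$accession == acc, ]
  expect_equal(e$label, "portal protein")
  expect_equal(e$flag, "GREEN")

  # FASTA materialization carries accession|flag|label headers
  f <- tempfile(fileext = ".faa")
  write_internal_db_fasta(store, f)
  hdr <- grep("^>", readLines(f), value = TRUE)
  expect_true(sprintf(">%s|GREEN|portal protein", acc) %in% hdr)
})

test_that("searching the internal database rebuilds it first when stale", {
  store <- new_test_store()
  on.exit(close_store(store))
  upload_fixture(make_synthetic_phage(seed = 83, n_genes = 3), store = store)
  ft <- feature_table(store, list_genomes(store)$name[1])
  acc <- ft$accession[1]
  update_annotation(store, acc, list(label = "endolysin"), "alice")
  expect_true(internal_db_stale(store))
  run_search(store, acc, "blastp", "internal")
  expect_false(internal_db_stale(store))
  # the query's own entry is excluded: identical sequence never self-reported
  res <- get_search_results(store, acc)[["blastp|internal"]]
  expect_false(acc %in% res$hits$subject_id)
})

test_that("genome-wide searches collect per-search failures without aborting", {
  store <- new_test_store()
  on.exit(close_store(store))
  res <- upload_fixture(make_synthetic_phage(seed = 84, n_genes = 5), store = store)
  g <- res$genome$name
  out <- run_genome_searches(store, g,
                             combos = list(c("blastp", "internal"),
                                           c("hhsearch", "pdb")))
  expect_equal(length(out$results), 5L)      # internal works
  expect_equal(nrow(out$failures), 5L)       # no hhsearch backend available
  expect_true(all(out$failures$tool == "hhsearch"))

  # genome with 0 CDS
  fa <- tempfile(fileext = ".fa"); writeLines(c(">e", strrep("TTAA", 300)), fa)
  ft <- tempfile(fileext = ".tsv"); writeLines(character(0), ft)
  upload_genome(store, fa, "no-genes",
                upload_options(mode = "custom", features_path = ft))
  out2 <- run_genome_searches(store, "no-genes", combos = list(c("blastp", "internal")))
  expect_equal(length(out2$results), 0L)
})
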