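# Shared test helpers: a brute-force affine-gap Smith-Waterman oracle
# (independent of the package's aligner), store constructors, and an
# evidence-summary builder for engine tests.

new_test_store <- function(test_mode = TRUE) {
  open_store(tempfile(fileext = ".store"), test_mode = test_mode)
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Exhaustive dynamic-programming Smith-Waterman with affine gaps: a gap of
# length L costs open + ext * L. Written independently of the package's
# search path; used as the scoring oracle.
sw_oracle <- function(a, b, open = 11, ext = 1) {
  m <- blosum62()
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n1 <- length(A); n2 <- length(B)
  NEG <- -1e9
  M <- matrix(0, n1 + 1L, n2 + 1L)
  X <- matrix(NEG, n1 + 1L, n2 + 1L)
  Y <- matrix(NEG, n1 + 1L, n2 + 1L)
  best <- 0
  for (i in 2:(n1 + 1L)) {
    for (j in 2:(n2 + 1L)) {
      X[i, j] <- max(M[i - 1L, j] - open - ext, X[i - 1L, j] - ext)
      Y[i, j] <- max(M[i, j - 1L] - open - ext, Y[i, j - 1L] - ext)
      s <- m[A[i - 1L], B[j - 1L]]
      M[i, j] <- max(0, M[i - 1L, j - 1L] + s, X[i - 1L, j - 1L] + s,
                     Y[i - 1L, j - 1L] + s)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

random_aa_string <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), len, replace = TRUE),
        collapse = "")
}

# Distinct 200-residue proteins for mock-pattern annotations.
pattern_protein <- function(i) {
  paste0("M", strrep(c("A","C","D","E","F","G","H","I","K","L","N","P","Q","R")[i], 9),
         strrep("GAVLIPFMW", 21), strrep("S", 1))
}

# A store holding one annotation per decision-guide pattern, with the mock
# result files parsed and attached. Returns list(store, accessions).
make_pattern_store <- function(patterns) {
  store <- new_test_store()
  accs <- character(length(patterns))
  for (i in seq_along(patterns)) {
    accs[i] <- get_or_create_annotation(store, pattern_protein(i),
                                        "protein")$annotation$accession
  }
  manifest <- make_mock_results(tempfile("mockres"), setNames(patterns, accs),
                                query_length = 200L)
  for (j in seq_len(nrow(manifest))) {
    txt <- paste(readLines(manifest$path[j]), collapse = "\n")
    hits <- if (manifest$format[j] == "hhr") parse_hhr(txt)
            else parse_blast_tabular(txt)
    store_search_result(store, manifest$accession[j], manifest$tool[j],
                        manifest$database[j], hits, raw_path = manifest$path[j])
  }
  list(store = store, accessions = setNames(accs, patterns))
}

# Upload a synthetic fixture into a store; returns list(store, genome, fixture).
upload_fixture <- function(fx, name = fx$name, store = new_test_store(),
                           options = upload_options(mode = "phage")) {
  fa <- tempfile(fileext = ".fasta")
  cat(fx$fasta, file = fa)
  g <- upload_genome(store, fa, name, options)
  list(store = store, genome = g, fixture = fx)
}

# A genome with exactly n features: one 30-nt CDS repeated back to back
# (all features share one deduplicated annotation), uploaded in custom mode.
upload_repeat_cds_genome <- function(store, name, n_features) {
  unit <- "ATGGCTGCAGCCGCGGCTGCAGCCGCGTAA"
  seqn <- strrep(unit, n_features)
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">g", seqn), fa)
  feats <- tempfile(fileext = ".tsv")
  starts <- (seq_len(n_features) - 1L) * nchar(unit) + 1L
  writeLines(sprintf("g\tCDS\t%d\t%d\t+", starts, starts + nchar(unit) - 1L), feats)
  upload_genome(store, fa, name,
                upload_options(mode = "custom", features_path = feats))
}

# Build an evidence_summary object directly (for engine fuzz tests that do
# not need a store).
synthetic_summary <- function(per_db, query_length = 200L,
                              thresholds = default_thresholds()) {
  structure(list(accession = "MAS_0000001", query_length = query_length,
                 per_db = per_db, version = 0L, thresholds = thresholds),
            class = "evidence_summary")
}

synthetic_db_evidence <- function(present = TRUE,
                                  significance = "significant",
                                  consistent_within = TRUE,
                                  top_label = "terminase large subunit",
                                  top_flag = NA_character_,
                                  length_similar = TRUE,
                                  q_coverage_class = "all_most",
                                  s_coverage_class = "all_most",
                                  qlen = 200L) {
  hit <- data.frame(subject_id = gsub("\\s+", "_", top_label),
                    subject_description = top_label, subject_length = qlen,
                    evalue = 1e-30, score = 120, q_start = 1L, q_end = qlen,
                    s_start = 1L, s_end = qlen,
                    aligned_query = NA_character_,
                    aligned_subject = NA_character_, stringsAsFactors = FALSE)
  list(present = present, significance = significance,
       consistent_within = consistent_within, top_hit = hit,
       top_label = top_label, top_flag = top_flag,
       length_similar = length_similar,
       q_coverage_class = q_coverage_class,
       s_coverage_class = s_coverage_class,
       n_hits = 1L, hits = hit)
}
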