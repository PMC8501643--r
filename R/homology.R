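# Homology evidence: parsers for NCBI BLAST tabular and HH-suite .hhr
# reports, a dependency-free Smith-Waterman protein search for offline use
# (internal/terminase databases), result persistence with supersede
# semantics, and the auto-updating internal annotation database.

.blast_columns <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                    "qstart", "qend", "sstart", "send", "evalue", "bitscore",
                    "slen", "stitle")

empty_hits <- function() {
  data.frame(subject_id = character(), subject_description = character(),
             subject_length = integer(), evalue = numeric(), score = numeric(),
             q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), aligned_query = character(),
             aligned_subject = character(), stringsAsFactors = FALSE)
}

#' Parse NCBI BLAST tabular output
#'
#' Reads the fixed dialect `-outfmt "6 std slen stitle"` (the two extra
#' columns guarantee subject length and description are available to the
#' evidence predicates). With `has_comments = TRUE`, `#` comment lines
#' (outfmt 7) are skipped. Rows are validated (numeric fields, `qstart <=
#' qend`) and the result is sorted by ascending e-value.
#'
#' @param text The file content as a single string or character vector of lines.
#' @param has_comments Skip `#` comment lines (outfmt 7)?
#' @return Hit data frame with columns `subject_id`, `subject_description`,
#'   `subject_length`, `evalue`, `score` (bit score), `q_start`, `q_end`,
#'   `s_start`, `s_end`, `aligned_query`, `aligned_subject`, `pident`.
#' @export
parse_blast_tabular <- function(text, has_comments = FALSE) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  rows <- list()
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (!nzchar(trimws(l))) next
    if (grepl("^#", l)) {
      if (has_comments) next
      anno_format_error("line %d: unexpected comment line (set has_comments = TRUE for outfmt 7)", i)
    }
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) != length(.blast_columns))
      anno_format_error("line %d: expected %d tab-separated columns (outfmt '6 std slen stitle'), got %d",
                        i, length(.blast_columns), length(f))
    num <- suppressWarnings(as.numeric(f[c(3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13)]))
    if (anyNA(num))
      anno_format_error("line %d: unparsable numeric field", i)
    qs <- as.integer(num[5]); qe <- as.integer(num[6])
    ss <- as.integer(num[7]); se <- as.integer(num[8])
    if (qe < qs) anno_format_error("line %d: qend < qstart", i)
    if (se < ss) anno_format_error("line %d: send < sstart", i)
    if (num[9] < 0) anno_format_error("line %d: negative e-value", i)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = f[2], subject_description = f[14],
      subject_length = as.integer(num[11]), evalue = num[9], score = num[10],
      q_start = qs, q_end = qe, s_start = ss, s_end = se,
      aligned_query = NA_character_, aligned_subject = NA_character_,
      pident = num[1], stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    out <- empty_hits(); out$pident <- numeric(0); return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$evalue, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize hits as BLAST tabular text
#'
#' Inverse of [parse_blast_tabular()] for the same `6 std slen stitle`
#' dialect. Fields the hit table does not carry (mismatch, gapopen) are
#' written as 0.
#'
#' @param hits Hit data frame.
#' @param query_id Query identifier for column 1.
#' @return Character scalar of tab-separated lines (empty string for no hits).
#' @export
write_blast_tabular <- function(hits, query_id = "query") {
  if (!nrow(hits)) return("")
  pid <- if ("pident" %in% names(hits)) hits$pident else rep(100, nrow(hits))
  lines <- vapply(seq_len(nrow(hits)), function(i) paste(
    query_id, hits$subject_id[i], format(pid[i]),
    hits$q_end[i] - hits$q_start[i] + 1L, 0L, 0L,
    hits$q_start[i], hits$q_end[i], hits$s_start[i], hits$s_end[i],
    format(hits$evalue[i]), format(hits$score[i]), hits$subject_length[i],
    hits$subject_description[i], sep = "\t"), character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse an HH-suite .hhr report
#'
#' Reads the summary table (header ` No Hit ... Prob E-value ...`) and the
#' per-hit blocks of an HH-suite report. Each summary row becomes one hit:
#' `score` is the Prob column (0-100), `evalue` the E-value column,
#' coordinates come from the Query/Template HMM columns, the subject length
#' from the trailing `(len)`, and descriptions from the `>` header line of
#' the matching hit block when present. Hits are ordered by descending
#' probability.
#'
#' @param text File content as a single string or character vector of lines.
#' @return Hit data frame (see [parse_blast_tabular()] for columns; `score`
#'   here is the HHsearch probability).
#' @export
parse_hhr <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  hdr <- grep("^\\s*No\\s+Hit\\s+Prob", lines)
  if (!length(hdr))
    anno_format_error("not an .hhr report: summary header (' No Hit ... Prob ...') not found")
  i <- hdr[1] + 1L
  rows <- list()
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    l <- lines[i]
    no <- suppressWarnings(as.integer(substr(l, 1L, 3L)))
    if (is.na(no)) anno_format_error("line %d: unparsable summary row", i)
    hit_field <- trimws(substr(l, 5L, 34L))
    rest <- strsplit(trimws(substr(l, 35L, nchar(l))), "\\s+")[[1]]
    # Prob E-value P-value Score SS Cols Query Template (Len)
    if (length(rest) < 9L)
      anno_format_error("line %d: truncated summary row (%d fields)", i, length(rest))
    prob <- suppressWarnings(as.numeric(rest[1]))
    ev <- suppressWarnings(as.numeric(rest[2]))
    qr <- strsplit(rest[7], "-", fixed = TRUE)[[1]]
    tr <- strsplit(rest[8], "-", fixed = TRUE)[[1]]
    slen <- suppressWarnings(as.integer(gsub("[()]", "", rest[9])))
    if (is.na(prob) || is.na(ev) || length(qr) != 2L || length(tr) != 2L)
      anno_format_error("line %d: unparsable summary row", i)
    rows[[length(rows) + 1L]] <- list(
      no = no, id = strsplit(hit_field, "\\s+")[[1]][1], desc = hit_field,
      prob = prob, evalue = ev,
      q_start = as.integer(qr[1]), q_end = as.integer(qr[2]),
      s_start = as.integer(tr[1]), s_end = as.integer(tr[2]),
      slen = slen
    )
    i <- i + 1L
  }
  if (!length(rows)) return(empty_hits())
  # richer descriptions from the per-hit blocks: "No <n>" then ">id desc"
  descs <- list()
  blk <- grep("^No [0-9]+", lines)
  for (b in blk) {
    no <- as.integer(sub("^No ", "", lines[b]))
    if (b + 1L <= length(lines) && startsWith(lines[b + 1L], ">")) {
      hd <- sub("^>", "", lines[b + 1L])
      parts <- strsplit(hd, "\\s+")[[1]]
      descs[[as.character(no)]] <- list(id = parts[1],
                                        desc = trimws(sub("^\\S+\\s*", "", hd)))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    d <- descs[[as.character(r$no)]]
    data.frame(subject_id = if (!is.null(d)) d$id else r$id,
               subject_description = if (!is.null(d) && nzchar(d$desc)) d$desc else r$desc,
               subject_length = r$slen, evalue = r$evalue, score = r$prob,
               q_start = r$q_start, q_end = r$q_end,
               s_start = r$s_start, s_end = r$s_end,
               aligned_query = NA_character_, aligned_subject = NA_character_,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$score, out$evalue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# -- built-in protein search ---------------------------------------------------

# Normalize a protein database: FASTA path, named character vector,
# AAStringSet, or data.frame(id, description, sequence).
as_protein_db <- function(db) {
  if (is.data.frame(db)) {
    stopifnot(all(c("id", "description", "sequence") %in% names(db)))
    return(db)
  }
  if (is.character(db) && length(db) == 1L && file.exists(db)) {
    set <- readAAStringSet(db)
    hdr <- names(set)
    ids <- vapply(strsplit(hdr, "\\s+"), `[[`, character(1), 1L)
    desc <- trimws(sub("^\\S+\\s*", "", hdr))
    return(data.frame(id = ids, description = desc,
                      sequence = as.character(set), stringsAsFactors = FALSE))
  }
  if (is.character(db) && !is.null(names(db))) {
    ids <- vapply(strsplit(names(db), "\\s+"), `[[`, character(1), 1L)
    desc <- trimws(sub("^\\S+\\s*", "", names(db)))
    return(data.frame(id = ids, description = desc, sequence = unname(db),
                      stringsAsFactors = FALSE))
  }
  anno_validation_error("cannot interpret protein database (need FASTA path, named vector, or data frame)")
}

blosum62_matrix <- local({
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

# Karlin-Altschul parameters for gapped BLOSUM62 (open 11 / extend 1).
.ka_lambda <- 0.267
.ka_K <- 0.041

raw_to_bit <- function(raw_score) (.ka_lambda * raw_score - log(.ka_K)) / log(2)

#' Built-in Smith-Waterman protein search
#'
#' A dependency-free local-alignment search used for the packaged terminase
#' database and the internal annotation database: Smith-Waterman with
#' BLOSUM62 and affine gaps (open 11, extend 1), bit scores via the gapped
#' Karlin-Altschul parameters (lambda = 0.267, K = 0.041), and e-values
#' `E = m * n * 2^(-S')` with `m` the query length and `n` the total database
#' residue count. The statistics are approximate (fixed published constants,
#' no length corrections) and intended for offline use, not as a BLAST
#' replacement.
#'
#' @param query Protein string.
#' @param database Protein database (FASTA path, named character vector, or
#'   data frame with `id`, `description`, `sequence`).
#' @param params List; `max_evalue` (default 10) filters reported hits.
#' @return Hit data frame sorted by ascending e-value; `score` is the bit
#'   score.
#' @export
builtin_protein_search <- function(query, database, params = list()) {
  if (!is.character(query) || length(query) != 1L || !nzchar(query))
    anno_validation_error("query must be a non-empty protein string")
  db <- as_protein_db(database)
  if (!nrow(db)) anno_validation_error("protein database is empty")
  max_evalue <- params$max_evalue %||% 10
  m <- nchar(query)
  n_total <- sum(nchar(db$sequence))
  mat <- blosum62_matrix()
  q <- AAString(query)
  raw <- vapply(db$sequence, function(s)
    pairwiseAlignment(q, AAString(s), type = "local", substitutionMatrix = mat,
                      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE),
    numeric(1), USE.NAMES = FALSE)
  bits <- raw_to_bit(raw)
  ev <- m * n_total * 2^(-bits)
  keep <- which(ev <= max_evalue)
  if (!length(keep)) return(empty_hits())
  rows <- lapply(keep, function(i) {
    aln <- pairwiseAlignment(q, AAString(db$sequence[i]), type = "local",
                             substitutionMatrix = mat, gapOpening = 11,
                             gapExtension = 1)
    p <- pattern(aln); s <- subject(aln)
    data.frame(subject_id = db$id[i], subject_description = db$description[i],
               subject_length = nchar(db$sequence[i]), evalue = ev[i],
               score = bits[i],
               q_start = BiocGenerics::start(p), q_end = BiocGenerics::end(p),
               s_start = BiocGenerics::start(s), s_end = BiocGenerics::end(s),
               aligned_query = as.character(p), aligned_subject = as.character(s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$evalue, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# -- result persistence --------------------------------------------------------

.tool_databases <- list(
  blastp = c("swissprot", "nr", "internal", "terminase"),
  rpsblast = "cdd",
  hhsearch = "pdb"
)

check_combo <- function(tool, database) {
  dbs <- .tool_databases[[tool]]
  if (is.null(dbs))
    anno_validation_error("unknown tool '%s'", tool)
  if (!(database %in% dbs || startsWith(database, "custom:")) ||
      (tool != "blastp" && startsWith(database, "custom:")))
    anno_validation_error("unsupported (tool, database) combination: (%s, %s)",
                          tool, database)
  invisible(TRUE)
}

result_key <- function(accession, tool, database) paste(accession, tool, database, sep = "|")

#' Attach a parsed search result to an annotation
#'
#' Persists a hit table as the current result of `(accession, tool,
#' database)`, superseding any previous result for the same triple (re-runs
#' replace; raw files can be retained via `raw_path` for audit).
#'
#' @param store An open store.
#' @param accession Annotation accession.
#' @param tool `"blastp"`, `"rpsblast"`, or `"hhsearch"`.
#' @param database Database name (`swissprot`, `nr`, `internal`, `cdd`,
#'   `pdb`, `terminase`, or `custom:<name>`).
#' @param hits Hit data frame ([parse_blast_tabular()] / [parse_hhr()] /
#'   [builtin_protein_search()]).
#' @param raw_path Optional path of the raw result file.
#' @return The stored search-result record, invisibly.
#' @export
store_search_result <- function(store, accession, tool, database, hits,
                                raw_path = NULL) {
  check_store(store)
  get_annotation(store, accession)
  check_combo(tool, database)
  rec <- list(accession = accession, tool = tool, database = database,
              run_time = store_now(store), hits = hits, raw_path = raw_path)
  store$results[[result_key(accession, tool, database)]] <- rec
  store_save(store)
  invisible(rec)
}

#' Stored search results for an annotation
#'
#' @param store An open store.
#' @param accession Annotation accession.
#' @return Named list of search-result records, keyed `tool|database`.
#' @export
get_search_results <- function(store, accession) {
  check_store(store)
  get_annotation(store, accession)
  res <- as.list(store$results)
  res <- Filter(function(r) r$accession == accession, res)
  setNames(res, vapply(res, function(r) paste(r$tool, r$database, sep = "|"),
                       character(1)))
}

#' Run one homology search
#'
#' Executes a single `(tool, database)` search for one annotation and stores
#' the result (superseding any previous result for the triple). Supported
#' combinations: `blastp` against `swissprot`/`nr`/`internal`/`terminase`/
#' `custom:<name>`; `rpsblast` against `cdd`; `hhsearch` against `pdb`. The
#' backend is either a function `(query, tool, database) -> hits` (an external
#' adapter or a mock), or `"builtin"` for blastp-style searches against the
#' internal database (rebuilt first when stale; the query's own annotation
#' entry is excluded), the packaged terminase database, or a custom database
#' supplied via `db`.
#'
#' @param store An open store.
#' @param accession Annotation accession (must be a protein annotation).
#' @param tool,database Search combination.
#' @param backend `"builtin"` or a function.
#' @param db Database for `backend = "builtin"` with a custom database.
#' @param params Parameters for [builtin_protein_search()].
#' @return The stored search-result record.
#' @export
run_search <- function(store, accession, tool, database, backend = "builtin",
                       db = NULL, params = list()) {
  check_store(store)
  ann <- get_annotation(store, accession)
  check_combo(tool, database)
  query <- ann$sequence
  hits <- if (is.function(backend)) {
    backend(query, tool, database)
  } else if (identical(backend, "builtin")) {
    if (tool != "blastp")
      anno_adapter_error("the builtin backend only supports blastp-style searches (%s requested)", tool)
    dbase <- if (database == "internal") {
      internal_db_as_protein_db(store, exclude = accession)
    } else if (database == "terminase") {
      db %||% system.file("extdata", "terminase_db_synthetic.faa", package = "annocurate")
    } else if (!is.null(db)) {
      db
    } else {
      anno_adapter_error("no builtin database available for '%s'; supply db= or an adapter backend", database)
    }
    if (is.data.frame(dbase) && !nrow(dbase)) empty_hits()
    else builtin_protein_search(query, dbase, params)
  } else {
    anno_adapter_error("backend must be 'builtin' or a function")
  }
  store_search_result(store, accession, tool, database, hits)
}

#' Run searches for every CDS annotation of a genome
#'
#' Searches every protein annotation of the genome for every `(tool,
#' database)` combination. Per-search failures are collected, not fatal, so
#' results are usable as they complete.
#'
#' @param store An open store.
#' @param genome Genome name.
#' @param combos List of `c(tool, database)` pairs.
#' @param backend,db,params As in [run_search()].
#' @return List with `results` (stored records) and `failures` (data frame of
#'   accession/tool/database/message).
#' @export
run_genome_searches <- function(store, genome, combos, backend = "builtin",
                                db = NULL, params = list()) {
  check_store(store)
  get_genome(store, genome)
  ft <- feature_table(store, genome)
  accs <- unique(ft$accession[ft$kind == "CDS"])
  results <- list()
  failures <- data.frame(accession = character(), tool = character(),
                         database = character(), message = character(),
                         stringsAsFactors = FALSE)
  with_deferred_save(store, {
    for (acc in accs) {
      for (cb in combos) {
        r <- tryCatch(run_search(store, acc, cb[[1]], cb[[2]], backend = backend,
                                 db = db, params = params),
                      error = function(e) e)
        if (inherits(r, "error")) {
          failures <- rbind(failures, data.frame(
            accession = acc, tool = cb[[1]], database = cb[[2]],
            message = conditionMessage(r), stringsAsFactors = FALSE))
        } else {
          results[[length(results) + 1L]] <- r
        }
      }
    }
  })
  list(results = results, failures = failures)
}

# -- internal database ---------------------------------------------------------

#' Rebuild the internal annotation database
#'
#' The internal database holds one entry per distinct CDS protein in the
#' store, with the annotation's accession, current label, and current flag as
#' metadata. It is marked stale whenever an annotation is edited or a genome
#' is uploaded, and rebuilding brings it back in sync (`stale = FALSE`).
#'
#' @param store An open store.
#' @return The internal database record: list with `entries` (data frame
#'   `sequence`, `accession`, `label`, `flag`), `built_at`, `stale`.
#' @export
rebuild_internal_db <- function(store) {
  check_store(store)
  anns <- Filter(function(a) a$molecule_kind == "protein", as.list(store$annotations))
  entries <- if (length(anns)) {
    data.frame(
      sequence = vapply(anns, `[[`, character(1), "sequence"),
      accession = vapply(anns, `[[`, character(1), "accession"),
      label = vapply(anns, `[[`, character(1), "label"),
      flag = vapply(anns, `[[`, character(1), "flag"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(sequence = character(), accession = character(),
               label = character(), flag = character(), stringsAsFactors = FALSE)
  }
  entries <- entries[order(entries$accession), , drop = FALSE]
  rownames(entries) <- NULL
  idb <- list(entries = entries, built_at = store_now(store), stale = FALSE)
  store$internal_db <- idb
  store$internal_stale <- FALSE
  store_save(store)
  idb
}

#' Is the internal database stale?
#'
#' @param store An open store.
#' @return Logical.
#' @export
internal_db_stale <- function(store) {
  check_store(store)
  isTRUE(store$internal_stale) || is.null(store$internal_db)
}

internal_db_as_protein_db <- function(store, exclude = NULL) {
  if (internal_db_stale(store)) rebuild_internal_db(store)
  e <- store$internal_db$entries
  if (!is.null(exclude)) e <- e[e$accession != exclude, , drop = FALSE]
  data.frame(id = e$accession,
             description = paste(e$accession, e$flag, e$label, sep = "|"),
             sequence = e$sequence, stringsAsFactors = FALSE)
}

#' Materialize the internal database as a protein FASTA
#'
#' Headers encode `accession|flag|label`, so the flag and current label of
#' every previously annotated protein travel with the database (consumable by
#' an external `makeblastdb`).
#'
#' @param store An open store.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_internal_db_fasta <- function(store, path) {
  if (internal_db_stale(store)) rebuild_internal_db(store)
  e <- store$internal_db$entries
  lines <- character(0)
  for (i in seq_len(nrow(e))) {
    lines <- c(lines, paste0(">", e$accession[i], "|", e$flag[i], "|", e$label[i]),
               e$sequence[i])
  }
  writeLines(lines, path)
  invisible(path)
}
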