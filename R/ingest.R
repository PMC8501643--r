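# Genome ingest: FASTA reading, gene calling (built-in ORF finder + external
# caller adapters), user-supplied coordinates, CDS translation, direct
# terminal repeats, terminase detection, and genome re-orientation.
#
# Coordinates are 0-based half-open internally. A feature that spans the
# origin of a (conceptually circular) genome is stored with start > stop and
# wraps_origin = TRUE: it covers [start, N) followed by [0, stop).

.start_codons <- c("ATG", "GTG", "TTG")

#' Read a single-record nucleotide FASTA file
#'
#' Genomes are provided as single-sequence FASTA. The sequence is uppercased
#' and restricted to the strict alphabet `{A, C, G, T, N}` (IUPAC ambiguity
#' codes are rejected; this keeps translation unambiguous and is a documented
#' limitation).
#'
#' @param path Path to the FASTA file.
#' @return List with `header` (text after `>`) and `sequence`.
#' @export
read_single_fasta <- function(path) {
  if (!file.exists(path)) anno_validation_error("no such file: %s", path)
  set <- tryCatch(readBStringSet(path),
                  error = function(e) anno_format_error("cannot parse FASTA '%s': %s",
                                                        path, conditionMessage(e)))
  if (length(set) == 0L)
    anno_format_error("'%s' contains no FASTA records; exactly one is required", path)
  if (length(set) > 1L)
    anno_format_error("'%s' contains %d records; a single-sequence FASTA is required",
                      path, length(set))
  seq <- toupper(as.character(set[[1]]))
  if (!nzchar(seq)) anno_validation_error("'%s' has an empty sequence", path)
  bad <- unique(strsplit(gsub("[ACGTN]", "", seq), "")[[1]])
  if (length(bad))
    anno_format_error("sequence contains characters outside {A,C,G,T,N}: %s",
                      paste(bad, collapse = ", "))
  list(header = names(set)[1], sequence = seq)
}

feature_draft <- function(kind, start, stop, strand, wraps_origin = FALSE,
                          source = "builtin_orf") {
  data.frame(kind = kind, start = as.integer(start), stop = as.integer(stop),
             strand = strand, wraps_origin = wraps_origin, source = source,
             stringsAsFactors = FALSE)
}

empty_drafts <- function() feature_draft(character(), integer(), integer(),
                                         character(), logical(), character())

# ORFs on the forward strand of `sequence` in one frame. Returns 0-based
# half-open [start, stop) including the stop codon.
orfs_one_frame <- function(sequence, frame, min_aa_len, code) {
  n <- nchar(sequence)
  starts_at <- seq.int(frame + 1L, n - 2L, by = 3L)
  if (!length(starts_at)) return(NULL)
  codons <- substring(sequence, starts_at, starts_at + 2L)
  stop_codons <- names(code)[code == "*"]
  is_stop <- codons %in% stop_codons
  is_start <- codons %in% .start_codons
  res <- list()
  seg_begin <- 1L  # first codon index of the current stop-free segment
  for (i in seq_along(codons)) {
    if (!is_stop[i]) next
    # Longest ORF ending at this stop: the first start codon in the segment.
    j <- seg_begin
    while (j < i && !is_start[j]) j <- j + 1L
    if (j < i && (i - j) >= min_aa_len) {
      res[[length(res) + 1L]] <- c(starts_at[j] - 1L, starts_at[i] + 2L)
    }
    seg_begin <- i + 1L
  }
  res
}

#' Built-in ORF-based gene caller
#'
#' Finds all maximal open reading frames on both strands: start codon in
#' `ATG/GTG/TTG`, stop codon per the genetic code, encoded protein at least
#' `min_aa_len` residues. Overlapping ORFs in the same frame are resolved to
#' the longest (the first qualifying start codon after the previous stop);
#' overlapping ORFs in different frames are all kept -- curation happens
#' downstream. This is the offline stand-in behind the same interface the
#' external caller adapters use.
#'
#' @param sequence Nucleotide string (A/C/G/T/N).
#' @param min_aa_len Minimum protein length in residues (default 30).
#' @param genetic_code NCBI translation table id (default `"11"`).
#' @return Feature-draft data frame (`kind`, `start`, `stop`, `strand`,
#'   `wraps_origin`, `source`), sorted by start; possibly empty.
#' @export
call_genes_builtin <- function(sequence, min_aa_len = 30L, genetic_code = "11") {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 3L * (min_aa_len + 2L)) return(empty_drafts())
  code <- getGeneticCode(genetic_code)
  out <- list()
  for (f in 0:2) {
    for (orf in orfs_one_frame(sequence, f, min_aa_len, code)) {
      out[[length(out) + 1L]] <- c(orf[1], orf[2], 1L)
    }
  }
  rc <- as.character(reverseComplement(DNAString(sequence)))
  for (f in 0:2) {
    for (orf in orfs_one_frame(rc, f, min_aa_len, code)) {
      # [a, b) on the reverse complement maps to [n - b, n - a) on the genome.
      out[[length(out) + 1L]] <- c(n - orf[2], n - orf[1], -1L)
    }
  }
  if (!length(out)) return(empty_drafts())
  m <- do.call(rbind, out)
  d <- feature_draft("CDS", m[, 1], m[, 2], ifelse(m[, 3] > 0, "+", "-"))
  d <- d[order(d$start, d$stop, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# -- external caller adapters --------------------------------------------------

# Parse Glimmer's .predict output: header line ">name" then rows
# "orf00001  <start> <end> <frame> <score>", 1-based inclusive, start/end in
# coding orientation (start > end on the minus strand).
parse_glimmer_predict <- function(text, genome_length) {
  lines <- grep("^(>|\\s*$)", strsplit(text, "\n", fixed = TRUE)[[1]],
                value = TRUE, invert = TRUE)
  rows <- lapply(lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 4L) anno_format_error("unparsable glimmer line: '%s'", l)
    a <- suppressWarnings(as.integer(f[2])); b <- suppressWarnings(as.integer(f[3]))
    if (is.na(a) || is.na(b)) anno_format_error("non-numeric glimmer coordinates: '%s'", l)
    strand <- if (grepl("^-", f[4])) "-" else "+"
    left <- min(a, b); right <- max(a, b)
    if (left < 1L || right > genome_length) return(NULL)  # wrapped circular call
    feature_draft("CDS", left - 1L, right, strand, source = "external_caller")
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty_drafts())
  d <- do.call(rbind, rows)
  d[order(d$start), , drop = FALSE]
}

# Parse tRNAscan-SE tabular output (-o): three header lines then rows with
# sequence name, tRNA number, begin, end (1-based inclusive; begin > end on
# the minus strand), isotype, anticodon, intron bounds, score.
parse_trnascan_tabular <- function(text, genome_length) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  body <- grep("^(Sequence|Name|--------|\\s*$)", lines, value = TRUE, invert = TRUE)
  rows <- lapply(body, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 4L) anno_format_error("unparsable tRNAscan line: '%s'", l)
    a <- suppressWarnings(as.integer(f[3])); b <- suppressWarnings(as.integer(f[4]))
    if (is.na(a) || is.na(b)) anno_format_error("non-numeric tRNAscan coordinates: '%s'", l)
    strand <- if (a <= b) "+" else "-"
    left <- min(a, b); right <- max(a, b)
    if (left < 1L || right > genome_length)
      anno_format_error("tRNAscan coordinates out of range: '%s'", l)
    feature_draft("tRNA", left - 1L, right, strand, source = "external_caller")
  })
  if (!length(rows)) return(empty_drafts())
  d <- do.call(rbind, rows)
  d[order(d$start), , drop = FALSE]
}

.adapter_parsers <- list(glimmer_predict = parse_glimmer_predict,
                         trnascan_tabular = parse_trnascan_tabular)

#' Run an external gene-caller adapter
#'
#' Adapters wrap external callers (e.g. a Glimmer-style CDS caller or a
#' tRNAscan-style tRNA caller) as pure functions of `(sequence, config)`: the
#' sequence is written to a temporary FASTA, the configured command is run,
#' and its native output is parsed into feature drafts. A missing or
#' unconfigured executable raises an adapter-unavailable error
#' (`anno_adapter_error`).
#'
#' @param sequence Nucleotide string.
#' @param adapter_name Name of the adapter in `config$adapters`.
#' @param config Configuration list (see [read_config()]); each adapter entry
#'   needs `command`, `args` (template; `{fasta}` and `{out}` are
#'   substituted), and `parser` (`"glimmer_predict"` or `"trnascan_tabular"`).
#' @return Feature-draft data frame.
#' @export
run_external_caller <- function(sequence, adapter_name, config) {
  ad <- config$adapters[[adapter_name]]
  if (is.null(ad) || is.null(ad$command) || !nzchar(ad$command %||% ""))
    anno_adapter_error("adapter '%s' is not configured", adapter_name)
  if (!nzchar(Sys.which(ad$command)))
    anno_adapter_error("adapter '%s': executable '%s' not found on PATH",
                       adapter_name, ad$command)
  parser <- .adapter_parsers[[ad$parser %||% ""]]
  if (is.null(parser))
    anno_config_error("adapter '%s': unknown parser '%s'", adapter_name, ad$parser %||% "")
  fasta <- tempfile(fileext = ".fasta")
  out <- tempfile(fileext = ".out")
  on.exit(unlink(c(fasta, out)), add = TRUE)
  writeLines(c(">query", sequence), fasta)
  args <- gsub("{out}", out, gsub("{fasta}", fasta, ad$args %||% "{fasta}",
                                  fixed = TRUE), fixed = TRUE)
  status <- system2(ad$command, strsplit(args, "\\s+")[[1]],
                    stdout = if (grepl("\\{out\\}", ad$args %||% "")) "" else out,
                    stderr = FALSE)
  if (!identical(status, 0L))
    anno_adapter_error("adapter '%s' exited with status %s", adapter_name, status)
  parser(paste(readLines(out, warn = FALSE), collapse = "\n"), nchar(sequence))
}

#' Load user-supplied gene calls
#'
#' Accepts GFF3 (9 tab-separated columns, `##` pragmas skipped) or a
#' 5-column TSV (`seqid`, `kind`, `start`, `stop`, `strand`), both with
#' 1-based inclusive coordinates, and converts to internal 0-based half-open.
#' Only `CDS`, `tRNA`, and `repeat_region` kinds are modeled; other types are
#' skipped with a warning. CDS lengths must be divisible by 3.
#'
#' @param path Path to the feature file.
#' @param genome_length Length of the target genome, for range validation.
#' @return Feature-draft data frame with `source = "user_supplied"`.
#' @export
load_user_features <- function(path, genome_length) {
  if (!file.exists(path)) anno_validation_error("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 9L) {            # GFF3
      kind <- f[3]; start1 <- f[4]; stop1 <- f[5]; strand <- f[7]
    } else if (length(f) == 5L) {     # seqid, kind, start, stop, strand
      kind <- f[2]; start1 <- f[3]; stop1 <- f[4]; strand <- f[5]
    } else {
      anno_format_error("line %d: expected GFF3 (9 columns) or 5-column TSV, got %d fields",
                        i, length(f))
    }
    if (!kind %in% c("CDS", "tRNA", "repeat_region")) {
      warning(sprintf("line %d: feature type '%s' is not modeled; skipped", i, kind),
              call. = FALSE)
      next
    }
    a <- suppressWarnings(as.integer(start1)); b <- suppressWarnings(as.integer(stop1))
    if (is.na(a) || is.na(b) || a < 1L || b < a)
      anno_validation_error("line %d: bad coordinates '%s'..'%s'", i, start1, stop1)
    if (b > genome_length)
      anno_validation_error("line %d: stop %d beyond genome length %d", i, b, genome_length)
    if (!strand %in% c("+", "-")) strand <- "+"
    if (kind == "CDS" && (b - a + 1L) %% 3L != 0L)
      anno_validation_error("line %d: CDS length %d is not a multiple of 3", i, b - a + 1L)
    rows[[length(rows) + 1L]] <- feature_draft(kind, a - 1L, b, strand,
                                               source = "user_supplied")
  }
  if (!length(rows)) return(empty_drafts())
  d <- do.call(rbind, rows)
  d[order(d$start), , drop = FALSE]
}

# Extract the nucleotide sequence of a (possibly origin-wrapping) feature.
feature_nt <- function(sequence, start, stop, strand, wraps_origin = FALSE) {
  n <- nchar(sequence)
  nt <- if (wraps_origin) {
    paste0(substr(sequence, start + 1L, n), substr(sequence, 1L, stop))
  } else {
    substr(sequence, start + 1L, stop)
  }
  if (strand == "-") nt <- as.character(reverseComplement(DNAString(nt)))
  nt
}

#' Translate a CDS
#'
#' Extracts the coding nucleotides (wrap-aware, reverse-complementing minus
#' strand features), translates with the requested NCBI genetic code (table 11
#' by default), and strips the trailing stop. An internal stop codon raises a
#' translation error.
#'
#' @param sequence Genome nucleotide string.
#' @param start,stop 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @param genetic_code NCBI translation table id.
#' @param wraps_origin Does the feature span the origin?
#' @return Protein string.
#' @export
translate_cds <- function(sequence, start, stop, strand, genetic_code = "11",
                          wraps_origin = FALSE) {
  nt <- feature_nt(sequence, start, stop, strand, wraps_origin)
  if (nchar(nt) %% 3L != 0L)
    anno_validation_error("CDS length %d is not a multiple of 3", nchar(nt))
  aa <- as.character(translate(DNAString(nt), genetic.code = getGeneticCode(genetic_code),
                               if.fuzzy.codon = "solve"))
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", aa, fixed = TRUE))
    anno_validation_error("internal stop codon in CDS %d..%d (%s)", start, stop, strand)
  aa
}

#' Direct terminal repeat features
#'
#' Linear phage genomes flanked by direct terminal repeats get one
#' `repeat_region` feature at each end: `[0, dtr_length)` and
#' `[genome_length - dtr_length, genome_length)`.
#'
#' @param genome_length Genome length in nt.
#' @param dtr_length Repeat length; must satisfy `0 < dtr_length < genome_length / 2`.
#' @return Feature-draft data frame with two rows.
#' @export
add_terminal_repeats <- function(genome_length, dtr_length) {
  if (!is.numeric(dtr_length) || length(dtr_length) != 1L || dtr_length < 1L ||
      dtr_length >= genome_length / 2)
    anno_validation_error("dtr_length must satisfy 0 < dtr_length < genome_length/2 (got %s for length %d)",
                          toString(dtr_length), genome_length)
  rbind(
    feature_draft("repeat_region", 0L, dtr_length, "+", source = "dtr"),
    feature_draft("repeat_region", genome_length - dtr_length, genome_length, "+",
                  source = "dtr")
  )
}

#' Detect a terminase gene among called CDSs
#'
#' Searches every CDS protein against a terminase protein database with the
#' built-in Smith-Waterman search. A CDS is a candidate when its best hit has
#' e-value at most `thresholds$terminase_evalue` (default 1e-10) and query
#' coverage at least `thresholds$terminase_qcov` (default 0.5). Subunit
#' identity is read from the subject header ("terminase large subunit" /
#' "terminase small subunit", case-insensitive). When both a large- and a
#' small-subunit candidate lie on the same strand, the upstream one (5'-most
#' in the transcription direction) is returned; otherwise the candidate with
#' the lowest e-value wins. Returns `NULL` when there is no candidate.
#'
#' @param cds_drafts Feature-draft data frame of CDSs.
#' @param proteins Character vector, one protein per CDS draft.
#' @param terminase_db Path to a protein FASTA, or a protein database as
#'   accepted by [builtin_protein_search()].
#' @param thresholds Threshold list (see [default_thresholds()]).
#' @return `NULL`, or a list with `feature_index`, `start`, `stop`, `strand`,
#'   `subunit`, `best_evalue`, `query_coverage`.
#' @export
detect_terminase <- function(cds_drafts, proteins, terminase_db,
                             thresholds = default_thresholds()) {
  db <- as_protein_db(terminase_db)
  if (!nrow(db)) anno_config_error("terminase database is empty")
  if (nrow(cds_drafts) != length(proteins))
    anno_validation_error("need exactly one protein per CDS draft")
  cands <- list()
  for (i in seq_along(proteins)) {
    hits <- builtin_protein_search(proteins[i], db,
                                   params = list(max_evalue = thresholds$terminase_evalue))
    if (!nrow(hits)) next
    top <- hits[1, ]
    qcov <- (top$q_end - top$q_start + 1) / nchar(proteins[i])
    if (qcov < thresholds$terminase_qcov) next
    desc <- paste(top$subject_id, top$subject_description)
    subunit <- if (grepl("large subunit", desc, ignore.case = TRUE)) "large"
               else if (grepl("small subunit", desc, ignore.case = TRUE)) "small"
               else "unspecified"
    cands[[length(cands) + 1L]] <- list(
      feature_index = i, start = cds_drafts$start[i], stop = cds_drafts$stop[i],
      strand = cds_drafts$strand[i], subunit = subunit,
      best_evalue = top$evalue, query_coverage = qcov
    )
  }
  if (!length(cands)) return(NULL)
  sub <- vapply(cands, `[[`, character(1), "subunit")
  str <- vapply(cands, `[[`, character(1), "strand")
  ev  <- vapply(cands, `[[`, numeric(1), "best_evalue")
  for (sg in c("+", "-")) {
    if (any(sub == "large" & str == sg) && any(sub == "small" & str == sg)) {
      idx <- which(str == sg & sub %in% c("large", "small"))
      starts <- vapply(cands[idx], `[[`, integer(1), "start")
      pick <- if (sg == "+") idx[which.min(starts)] else idx[which.max(starts)]
      return(cands[[pick]])
    }
  }
  if (any(sub == "large") && any(sub == "small")) {
    # both subunits seen, but never on one strand (handled above)
    warning("terminase subunits found on opposite strands; falling back to lowest e-value",
            call. = FALSE)
  }
  cands[[which.min(ev)]]
}

#' Re-orient a genome to start at the terminase gene
#'
#' If the terminase lies on the minus strand the whole genome is first
#' reverse-complemented (a feature `[s, e)` on strand `sigma` becomes
#' `[N - e, N - s)` on the opposite strand); the sequence is then rotated so
#' the terminase start becomes coordinate 0. Features that end up spanning the
#' new origin get `wraps_origin = TRUE`. Genome length, feature count,
#' per-feature lengths, and the multiset of CDS translations are invariant;
#' afterwards the terminase feature starts at 0 on the plus strand, so
#' re-running the transform is the identity.
#'
#' @param sequence Genome nucleotide string.
#' @param features Feature-draft data frame.
#' @param call Terminase call as returned by [detect_terminase()], or any list
#'   with `start`, `stop`, `strand` naming a feature present in `features`.
#' @return List with `sequence` and remapped `features`.
#' @export
reorient_genome <- function(sequence, features, call) {
  n <- nchar(sequence)
  on_genome <- any(features$start == call$start & features$stop == call$stop &
                     features$strand == call$strand)
  if (!on_genome)
    anno_validation_error("terminase call (%d..%d %s) does not match any feature",
                          call$start, call$stop, call$strand)
  f <- features
  if (call$strand == "-") {
    sequence <- as.character(reverseComplement(DNAString(sequence)))
    new_start <- (n - f$stop) %% n
    new_stop_incl <- (n - 1L - f$start) %% n
    f$start <- as.integer(new_start)
    f$stop <- as.integer(new_stop_incl + 1L)
    # a wrapping feature stays wrapping; recompute the flag from coordinates
    f$wraps_origin <- f$start >= f$stop
    f$strand <- ifelse(f$strand == "+", "-", "+")
    call <- list(start = (n - call$stop) %% n, stop = n - call$start, strand = "+")
  }
  s <- call$start %% n
  if (s != 0L) {
    sequence <- paste0(substr(sequence, s + 1L, n), substr(sequence, 1L, s))
    a <- (f$start - s) %% n
    e_incl <- (f$stop - 1L - s) %% n
    f$start <- as.integer(a)
    f$stop <- as.integer(e_incl + 1L)
    f$wraps_origin <- f$start >= f$stop
  }
  rownames(f) <- NULL
  list(sequence = sequence, features = f)
}

#' Upload options
#'
#' Bundles the options of [upload_genome()]. `reorient_terminase` and
#' `dtr_length` are only valid in phage mode; `dtr_length` must be smaller
#' than half the genome.
#'
#' @param mode `"phage"`, `"bacterial"`, or `"custom"`.
#' @param reorient_terminase Re-orient the genome to start at the terminase?
#' @param dtr_length Optional direct terminal repeat length.
#' @param assign_to Optional user every newly created annotation is assigned to.
#' @param gene_caller `"builtin"` or `"external:<adapter>"`.
#' @param genetic_code NCBI translation table id (default `"11"`).
#' @param min_aa_len Minimum protein length for the built-in caller.
#' @param features_path Path to user gene calls (custom mode).
#' @param terminase_db Terminase protein FASTA; defaults to the packaged
#'   synthetic database.
#' @param thresholds Threshold list (see [default_thresholds()]).
#' @param config Adapter configuration (external callers).
#' @return List of class `upload_options`.
#' @export
upload_options <- function(mode = c("phage", "bacterial", "custom"),
                           reorient_terminase = FALSE, dtr_length = NULL,
                           assign_to = NULL, gene_caller = "builtin",
                           genetic_code = "11", min_aa_len = 30L,
                           features_path = NULL, terminase_db = NULL,
                           thresholds = default_thresholds(), config = list()) {
  mode <- match.arg(mode)
  if (mode != "phage" && (isTRUE(reorient_terminase) || !is.null(dtr_length)))
    anno_validation_error("reorient_terminase and dtr_length are only valid in phage mode")
  if (mode == "custom" && is.null(features_path))
    anno_validation_error("custom mode requires features_path")
  structure(list(mode = mode, reorient_terminase = isTRUE(reorient_terminase),
                 dtr_length = dtr_length, assign_to = assign_to,
                 gene_caller = gene_caller, genetic_code = genetic_code,
                 min_aa_len = as.integer(min_aa_len), features_path = features_path,
                 terminase_db = terminase_db, thresholds = thresholds,
                 config = config),
            class = "upload_options")
}

#' Upload a genome
#'
#' The full ingest pipeline: read the FASTA, call genes (built-in caller,
#' external adapter, or user-supplied coordinates in custom mode), optionally
#' re-orient a phage genome to start at the terminase, optionally add direct
#' terminal repeat features, translate every CDS, and create or reuse one
#' annotation per feature sequence ([get_or_create_annotation()]). tRNA
#' annotations are flagged `TRNA` automatically; when `assign_to` is set,
#' all newly created annotations are assigned to that user. The upload is
#' transactional: any failure leaves the store unchanged. The internal
#' database is marked stale.
#'
#' @param store An open store.
#' @param fasta_path Path to a single-record nucleotide FASTA.
#' @param name Unique genome name. Phage naming best practice is to include
#'   the host bacterium in the name; a name without a recognisable host part
#'   is accepted as-is.
#' @param options An [upload_options()] list.
#' @return The created genome record.
#' @export
upload_genome <- function(store, fasta_path, name, options = upload_options()) {
  check_store(store)
  if (!inherits(options, "upload_options"))
    anno_validation_error("options must come from upload_options()")
  if (name %in% names(store$genomes))
    anno_validation_error("genome name '%s' already exists; the selected name must be unique", name)
  snap <- store_snapshot(store)
  result <- tryCatch(with_deferred_save(store, {
    fa <- read_single_fasta(fasta_path)
    seqn <- fa$sequence
    n <- nchar(seqn)
    drafts <- if (options$mode == "custom") {
      load_user_features(options$features_path, n)
    } else if (identical(options$gene_caller, "builtin")) {
      call_genes_builtin(seqn, min_aa_len = options$min_aa_len,
                         genetic_code = options$genetic_code)
    } else if (startsWith(options$gene_caller, "external:")) {
      run_external_caller(seqn, sub("^external:", "", options$gene_caller),
                          options$config)
    } else {
      anno_validation_error("unknown gene_caller '%s'", options$gene_caller)
    }
    if (options$mode == "phage" && options$reorient_terminase) {
      cds <- drafts[drafts$kind == "CDS", , drop = FALSE]
      prots <- vapply(seq_len(nrow(cds)), function(i)
        translate_cds(seqn, cds$start[i], cds$stop[i], cds$strand[i],
                      options$genetic_code, cds$wraps_origin[i]), character(1))
      db <- options$terminase_db %||%
        system.file("extdata", "terminase_db_synthetic.faa", package = "annocurate")
      tc <- detect_terminase(cds, prots, db, options$thresholds)
      if (!is.null(tc)) {
        ro <- reorient_genome(seqn, drafts, tc)
        seqn <- ro$sequence
        drafts <- ro$features
      }
    }
    if (!is.null(options$dtr_length)) {
      drafts <- rbind(drafts, add_terminal_repeats(n, options$dtr_length))
      drafts <- drafts[order(drafts$start), , drop = FALSE]
    }
    accs <- character(nrow(drafts))
    for (i in seq_len(nrow(drafts))) {
      if (drafts$kind[i] == "CDS") {
        prot <- translate_cds(seqn, drafts$start[i], drafts$stop[i], drafts$strand[i],
                              options$genetic_code, drafts$wraps_origin[i])
        res <- get_or_create_annotation(store, prot, "protein",
                                        assigned_to = options$assign_to)
      } else {
        nt <- feature_nt(seqn, drafts$start[i], drafts$stop[i], drafts$strand[i],
                         drafts$wraps_origin[i])
        kind <- if (drafts$kind[i] == "tRNA") "rna" else "dna"
        res <- get_or_create_annotation(store, nt, kind,
                                        assigned_to = options$assign_to)
        if (res$created && drafts$kind[i] == "tRNA") {
          ann <- res$annotation
          ann$flag <- "TRNA"
          store$annotations[[ann$accession]] <- ann
          res$annotation <- ann
        }
      }
      accs[i] <- res$annotation$accession
    }
    drafts$accession <- accs
    g <- add_genome_record(store, name, seqn,
                           topology = "linear",
                           organism_kind = if (options$mode == "custom") "custom" else options$mode,
                           feature_rows = drafts)
    store$internal_stale <- TRUE
    g
  }), error = function(e) {
    store_restore(store, snap)
    store_save(store)
    stop(e)
  })
  result
}
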