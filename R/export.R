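# Standard-format writers (FASTA, GFF3, GenBank, tabular), spreadsheet-style
# annotation import, and the per-genome export bundle. Internal coordinates
# are 0-based half-open; every export converts to the 1-based inclusive
# convention of GenBank/GFF3. Private notes never leave the store except in
# the annotation table, which exists precisely to carry them.

to_one_based <- function(start, stop) c(start + 1L, stop)

wrap_seq <- function(s, width = 70L) {
  if (!nzchar(s)) return(character(0))
  starts <- seq.int(1L, nchar(s), by = width)
  substring(s, starts, pmin(starts + width - 1L, nchar(s)))
}

#' Write a genome as FASTA
#'
#' Single record, header = genome name (spaces preserved), sequence wrapped
#' at 70 columns.
#'
#' @param store An open store.
#' @param genome Genome name.
#' @param path Optional output path; when `NULL` the text is returned.
#' @return FASTA text (invisibly when written to `path`).
#' @export
write_genome_fasta <- function(store, genome, path = NULL) {
  g <- get_genome(store, genome)
  txt <- paste0(paste(c(paste0(">", g$name), wrap_seq(g$sequence)), collapse = "\n"), "\n")
  if (!is.null(path)) { cat(txt, file = path); return(invisible(txt)) }
  txt
}

#' Write CDS translations as multi-FASTA
#'
#' One record per CDS feature in genomic order; tRNA and repeat features are
#' excluded. Headers are `accession label`; a protein shared by two features
#' of the genome appears twice under the same accession.
#'
#' @inheritParams write_genome_fasta
#' @return Multi-FASTA text.
#' @export
write_cds_translations <- function(store, genome, path = NULL) {
  get_genome(store, genome)
  ft <- feature_table(store, genome)
  ft <- ft[ft$kind == "CDS", , drop = FALSE]
  ft <- ft[order(ft$start), , drop = FALSE]
  lines <- character(0)
  for (i in seq_len(nrow(ft))) {
    ann <- store$annotations[[ft$accession[i]]]
    hdr <- trimws(paste(ann$accession, ann$label))
    lines <- c(lines, paste0(">", hdr), wrap_seq(ann$sequence))
  }
  txt <- if (length(lines)) paste0(paste(lines, collapse = "\n"), "\n") else ""
  if (!is.null(path)) { cat(txt, file = path); return(invisible(txt)) }
  txt
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x
}

#' Write a genome's features as GFF3
#'
#' Emits a `##gff-version 3` file with 1-based inclusive coordinates,
#' `seqid` = genome name, feature types CDS/tRNA/repeat_region, and
#' attributes `ID=<accession>;product=<label>;mas_flag=<flag>`. A feature
#' that wraps the origin is written as two lines sharing the same `ID`.
#'
#' @inheritParams write_genome_fasta
#' @return GFF3 text.
#' @export
write_gff3 <- function(store, genome, path = NULL) {
  g <- get_genome(store, genome)
  n <- nchar(g$sequence)
  ft <- feature_table(store, genome)
  ft <- ft[order(ft$start), , drop = FALSE]
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", gff3_escape(g$name), n))
  for (i in seq_len(nrow(ft))) {
    ann <- store$annotations[[ft$accession[i]]]
    attrs <- sprintf("ID=%s;product=%s;mas_flag=%s",
                     gff3_escape(ft$accession[i]), gff3_escape(ann$label),
                     gff3_escape(ann$flag))
    segs <- if (ft$wraps_origin[i]) {
      list(c(ft$start[i] + 1L, n), c(1L, ft$stop[i]))
    } else {
      list(c(ft$start[i] + 1L, ft$stop[i]))
    }
    for (sg in segs) {
      lines <- c(lines, paste(gff3_escape(g$name), "annocurate", ft$kind[i],
                              sg[1], sg[2], ".", ft$strand[i],
                              if (ft$kind[i] == "CDS") "0" else ".",
                              attrs, sep = "\t"))
    }
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) { cat(txt, file = path); return(invisible(txt)) }
  txt
}

genbank_location <- function(start, stop, strand, wraps_origin, n) {
  loc <- if (wraps_origin) {
    sprintf("join(%d..%d,%d..%d)", start + 1L, n, 1L, stop)
  } else {
    sprintf("%d..%d", start + 1L, stop)
  }
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

gb_qualifier <- function(name, value, quote = TRUE) {
  text <- if (quote) sprintf("/%s=\"%s\"", name, value) else sprintf("/%s=%s", name, value)
  # wrap at 79 columns with the 21-column feature-qualifier indent
  width <- 79L - 21L
  out <- character(0)
  while (nchar(text) > width) {
    cut <- width
    sp <- gregexpr(" ", substr(text, 1L, width))[[1]]
    if (length(sp) && sp[1] > 0 && max(sp) > 21L) cut <- max(sp) - 1L
    out <- c(out, substr(text, 1L, cut))
    text <- substr(text, cut + 1L, nchar(text))
    text <- sub("^ ", "", text)
  }
  paste0(strrep(" ", 21L), c(out, text))
}

gb_feature <- function(key, location) {
  loc_lines <- character(0)
  text <- location
  width <- 79L - 21L
  while (nchar(text) > width) {
    commas <- gregexpr(",", substr(text, 1L, width))[[1]]
    cut <- if (length(commas) && commas[1] > 0) max(commas) else width
    loc_lines <- c(loc_lines, substr(text, 1L, cut))
    text <- substr(text, cut + 1L, nchar(text))
  }
  loc_lines <- c(loc_lines, text)
  c(paste0("     ", formatC(key, width = -16), loc_lines[1]),
    if (length(loc_lines) > 1L) paste0(strrep(" ", 21L), loc_lines[-1]))
}

#' Write a genome as a GenBank flat file
#'
#' Emits LOCUS/DEFINITION/ACCESSION/FEATURES/ORIGIN sections with a `source`
#' feature spanning the genome. CDS features carry `/product` (the label),
#' `/protein_id` (the accession), `/translation`, and `/note` with the
#' public notes when non-empty; tRNA features carry `/product`;
#' `repeat_region` features carry `/rpt_type=direct`. Private notes never
#' appear anywhere in the output. Minus-strand locations use
#' `complement()`; origin-wrapping features use `join()` of two intervals.
#' The LOCUS division is PHG for phage genomes, BCT for bacterial, UNA
#' otherwise; in test mode the LOCUS date is fixed for reproducibility.
#'
#' @inheritParams write_genome_fasta
#' @return GenBank text.
#' @export
write_genbank <- function(store, genome, path = NULL) {
  g <- get_genome(store, genome)
  n <- nchar(g$sequence)
  division <- switch(g$organism_kind, phage = "PHG", bacterial = "BCT", "UNA")
  date <- if (isTRUE(store$test_mode)) "01-JAN-2000"
          else toupper(format(Sys.Date(), "%d-%b-%Y"))
  locus_name <- gsub("\\s+", "_", g$name)
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     linear   %s %s",
            formatC(locus_name, width = -16), n, division, date),
    sprintf("DEFINITION  %s.", g$name),
    sprintf("ACCESSION   %s", locus_name),
    "FEATURES             Location/Qualifiers",
    gb_feature("source", sprintf("1..%d", n)),
    gb_qualifier("organism", g$name),
    gb_qualifier("mol_type", "genomic DNA")
  )
  ft <- feature_table(store, genome)
  ft <- ft[order(ft$start), , drop = FALSE]
  for (i in seq_len(nrow(ft))) {
    ann <- store$annotations[[ft$accession[i]]]
    loc <- genbank_location(ft$start[i], ft$stop[i], ft$strand[i],
                            ft$wraps_origin[i], n)
    if (ft$kind[i] == "CDS") {
      lines <- c(lines, gb_feature("CDS", loc))
      if (nzchar(ann$label)) lines <- c(lines, gb_qualifier("product", ann$label))
      lines <- c(lines, gb_qualifier("protein_id", ann$accession))
      if (nzchar(ann$public_notes)) lines <- c(lines, gb_qualifier("note", ann$public_notes))
      lines <- c(lines, gb_qualifier("transl_table", "11", quote = FALSE),
                 gb_qualifier("translation", ann$sequence))
    } else if (ft$kind[i] == "tRNA") {
      lines <- c(lines, gb_feature("tRNA", loc))
      if (nzchar(ann$label)) lines <- c(lines, gb_qualifier("product", ann$label))
      if (nzchar(ann$public_notes)) lines <- c(lines, gb_qualifier("note", ann$public_notes))
    } else {
      lines <- c(lines, gb_feature("repeat_region", loc),
                 gb_qualifier("rpt_type", "direct", quote = FALSE))
      if (nzchar(ann$public_notes)) lines <- c(lines, gb_qualifier("note", ann$public_notes))
    }
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(g$sequence)
  pos <- seq.int(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, n))
    tens <- substring(chunk, seq.int(1L, nchar(chunk), 10L),
                      pmin(seq.int(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  lines <- c(lines, "//")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) { cat(txt, file = path); return(invisible(txt)) }
  txt
}

.table_columns <- c("accession", "label", "flag", "public_notes", "private_notes",
                    "assigned_to", "sequence", "genome", "start", "stop", "strand")

#' Annotation table (spreadsheet-style export)
#'
#' Tabular listing of features and annotations with the fixed column set
#' `accession, label, flag, public_notes, private_notes, assigned_to,
#' sequence, genome, start, stop, strand`. With `scope = "genome"` there is
#' one row per feature (coordinates 1-based inclusive); with `scope =
#' "store"` one row per annotation, genome columns blank. This is the one
#' export that carries private notes.
#'
#' @param store An open store.
#' @param scope `"genome"` or `"store"`.
#' @param genome Genome name (required for genome scope).
#' @param path Optional output path (TSV).
#' @return Data frame (written as TSV when `path` is given).
#' @export
write_annotation_table <- function(store, scope = c("genome", "store"),
                                   genome = NULL, path = NULL) {
  check_store(store)
  scope <- match.arg(scope)
  if (scope == "genome") {
    if (is.null(genome)) anno_validation_error("genome scope requires a genome name")
    get_genome(store, genome)
    ft <- feature_table(store, genome)
    ft <- ft[order(ft$start), , drop = FALSE]
    rows <- lapply(seq_len(nrow(ft)), function(i) {
      a <- store$annotations[[ft$accession[i]]]
      data.frame(accession = a$accession, label = a$label, flag = a$flag,
                 public_notes = a$public_notes, private_notes = a$private_notes,
                 assigned_to = a$assigned_to, sequence = a$sequence,
                 genome = genome, start = ft$start[i] + 1L, stop = ft$stop[i],
                 strand = ft$strand[i], stringsAsFactors = FALSE)
    })
  } else {
    anns <- as.list(store$annotations)
    anns <- anns[order(vapply(anns, `[[`, character(1), "accession"))]
    rows <- lapply(anns, function(a) data.frame(
      accession = a$accession, label = a$label, flag = a$flag,
      public_notes = a$public_notes, private_notes = a$private_notes,
      assigned_to = a$assigned_to, sequence = a$sequence,
      genome = "", start = NA_integer_, stop = NA_integer_, strand = "",
      stringsAsFactors = FALSE))
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character()), length(.table_columns)),
                           .table_columns), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    return(invisible(tab))
  }
  tab
}

#' Import annotations from a table
#'
#' Each row is matched to an existing protein annotation by exact,
#' case-insensitive sequence comparison; on a match, `label` and any of
#' `flag`, `public_notes`, `private_notes` present in the table are written
#' through [update_annotation()] (history recorded; no-op rows count as
#' matched but not updated). Unmatched rows are returned verbatim.
#'
#' @param store An open store.
#' @param table Data frame or path to a TSV with at least `sequence` and
#'   `label` columns.
#' @param user Editing user recorded in the history.
#' @return List with `matched`, `updated`, and `unmatched` (data frame).
#' @export
import_annotation_table <- function(store, table, user) {
  check_store(store)
  if (is.character(table)) {
    table <- utils::read.delim(table, sep = "\t", stringsAsFactors = FALSE,
                               colClasses = "character", na.strings = NULL)
  }
  if (!all(c("sequence", "label") %in% names(table)))
    anno_format_error("annotation table needs 'sequence' and 'label' columns")
  prot <- Filter(function(a) a$molecule_kind == "protein", as.list(store$annotations))
  by_seq <- setNames(vapply(prot, `[[`, character(1), "accession"),
                     toupper(vapply(prot, `[[`, character(1), "sequence")))
  matched <- 0L; updated <- 0L
  unmatched <- table[0, , drop = FALSE]
  opt_cols <- intersect(c("flag", "public_notes", "private_notes"), names(table))
  with_deferred_save(store, {
    for (i in seq_len(nrow(table))) {
      acc <- by_seq[toupper(table$sequence[i])]
      if (is.na(acc)) {
        unmatched <- rbind(unmatched, table[i, , drop = FALSE])
        next
      }
      matched <- matched + 1L
      changes <- list(label = table$label[i])
      for (cc in opt_cols) changes[[cc]] <- table[[cc]][i]
      before <- annotation_version(store, acc)
      update_annotation(store, acc, changes, user)
      if (annotation_version(store, acc) > before) updated <- updated + 1L
    }
  })
  rownames(unmatched) <- NULL
  list(matched = matched, updated = updated, unmatched = unmatched)
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Export a genome's deliverables as a tarball
#'
#' Writes the five members `<genome>.fasta` (genome sequence),
#' `<genome>_proteins.faa` (CDS translations), `<genome>.gff3`,
#' `<genome>_annotations.tsv`, and `<genome>.gbk` into a gzip tarball with
#' deterministic member order. In test mode member timestamps are fixed, so
#' exporting the same store state twice yields byte-identical archives. On
#' failure no partial file is left behind.
#'
#' @param store An open store.
#' @param genome Genome name.
#' @param out_path Output tarball path.
#' @return Character vector of member names, invisibly.
#' @export
export_bundle <- function(store, genome, out_path) {
  get_genome(store, genome)
  base <- sanitize_filename(genome)
  stage <- tempfile("bundle")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  members <- c(paste0(base, ".fasta"), paste0(base, "_proteins.faa"),
               paste0(base, ".gff3"), paste0(base, "_annotations.tsv"),
               paste0(base, ".gbk"))
  write_genome_fasta(store, genome, file.path(stage, members[1]))
  write_cds_translations(store, genome, file.path(stage, members[2]))
  write_gff3(store, genome, file.path(stage, members[3]))
  write_annotation_table(store, "genome", genome, file.path(stage, members[4]))
  write_genbank(store, genome, file.path(stage, members[5]))
  if (isTRUE(store$test_mode)) {
    epoch <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
    for (m in members) Sys.setFileTime(file.path(stage, m), epoch)
  }
  tmp_tar <- tempfile(fileext = ".tar")
  old <- setwd(stage)
  status <- tryCatch(utils::tar(tmp_tar, files = members, compression = "none",
                                tar = "internal"),
                     finally = setwd(old))
  raw_tar <- readBin(tmp_tar, "raw", file.info(tmp_tar)$size)
  unlink(tmp_tar)
  ok <- tryCatch({
    con <- gzfile(out_path, "wb")
    writeBin(raw_tar, con)
    close(con)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    unlink(out_path)
    anno_store_error("failed to write bundle to %s", out_path)
  }
  invisible(members)
}
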