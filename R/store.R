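# The embedded annotation store: a single-file persistent database holding the
# genome / feature / annotation / annotation_event / search_result tables, with
# an exclusive-writer lock file alongside. All access goes through the exported
# operations; the on-disk format is an implementation detail.

#' Annotation flag values
#'
#' The closed set of triage flags an annotation can carry. `UNANNOTATED` is the
#' default for newly created CDS (protein) annotations; `TRNA` is set
#' automatically for tRNA features; `REVIEW_NAME` marks annotations that need
#' revisiting; the colour flags have no predefined meaning and are free for
#' lab-specific conventions (e.g. green = safe, red = problematic).
#'
#' @return Character vector of valid flag values.
#' @export
annotation_flags <- function() {
  c("UNANNOTATED", "REVIEW_NAME", "TRNA", "GREEN", "RED", "BLUE",
    "PURPLE", "YELLOW", "ORANGE", "NONE")
}

.editable_fields <- c("label", "flag", "public_notes", "private_notes", "assigned_to")

.store_fields <- c("genomes", "features", "feature_counter", "annotations",
                   "seq_index", "events", "event_counter", "acc_counter",
                   "results", "internal_db", "internal_stale", "clock_counter")

#' Open (or create) an annotation store
#'
#' Opens the single-file store at `path`, creating an empty one if the file
#' does not exist. While open for writing the store holds an exclusive lock
#' (`<path>.lock`); a second writer opening the same path receives a lock
#' error rather than risking silent corruption. Call [close_store()] to
#' release the lock.
#'
#' @param path File path of the store. The parent directory must exist.
#' @param test_mode Logical; when `TRUE` all timestamps drawn by the store are
#'   deterministic (a fixed epoch plus an event counter), which makes exports
#'   byte-reproducible.
#' @return A store handle (environment of class `anno_store`).
#' @export
open_store <- function(path, test_mode = FALSE) {
  if (!dir.exists(dirname(path)))
    anno_store_error("parent directory of store path does not exist: %s", dirname(path))
  lock <- paste0(path, ".lock")
  if (file.exists(lock))
    anno_store_error("store '%s' is locked by another writer (lock file %s)", path, lock)
  ok <- file.create(lock)
  if (!ok) anno_store_error("cannot create lock file %s", lock)

  store <- new.env(parent = emptyenv())
  class(store) <- "anno_store"
  store$path <- path
  store$lock <- lock
  store$test_mode <- isTRUE(test_mode)

  if (file.exists(path)) {
    state <- tryCatch(readRDS(path), error = function(e) {
      unlink(lock)
      anno_store_error("store file '%s' is corrupt or unreadable: %s", path, conditionMessage(e))
    })
    if (!is.list(state) || !all(.store_fields %in% names(state))) {
      unlink(lock)
      anno_store_error("store file '%s' is corrupt: missing tables", path)
    }
    for (f in .store_fields) assign(f, state[[f]], envir = store)
    store$annotations <- list2env(state$annotations, parent = emptyenv())
    store$seq_index   <- list2env(state$seq_index, parent = emptyenv())
    store$results     <- list2env(state$results, parent = emptyenv())
  } else {
    store$genomes <- list()
    store$features <- list()
    store$feature_counter <- 0L
    store$annotations <- new.env(parent = emptyenv())
    store$seq_index <- new.env(parent = emptyenv())
    store$events <- list()
    store$event_counter <- 0L
    store$acc_counter <- 0L
    store$results <- new.env(parent = emptyenv())
    store$internal_db <- NULL
    store$internal_stale <- TRUE
    store$clock_counter <- 0L
    store_save(store)
  }
  store
}

#' Close an annotation store
#'
#' Persists the current state and releases the writer lock.
#'
#' @param store An open store.
#' @return Invisibly, `TRUE`.
#' @export
close_store <- function(store) {
  check_store(store)
  store_save(store)
  unlink(store$lock)
  store$closed <- TRUE
  invisible(TRUE)
}

check_store <- function(store) {
  if (!inherits(store, "anno_store"))
    anno_validation_error("not an anno_store handle")
  if (isTRUE(store$closed))
    anno_store_error("store has been closed")
  invisible(store)
}

store_save <- function(store) {
  if (isTRUE(store$defer_save)) return(invisible(store))
  state <- mget(.store_fields, envir = store)
  state$annotations <- as.list(store$annotations)
  state$seq_index <- as.list(store$seq_index)
  state$results <- as.list(store$results)
  saveRDS(state, store$path)
  invisible(store)
}

# Batch many mutations into one on-disk write (used by the bulk operations;
# a failure inside `expr` still leaves the store consistent because the
# caller snapshots/restores around it).
with_deferred_save <- function(store, expr) {
  old <- isTRUE(store$defer_save)
  store$defer_save <- TRUE
  on.exit({
    store$defer_save <- old
    store_save(store)
  }, add = TRUE)
  force(expr)
}

# Deterministic clock in test mode; wall clock otherwise.
store_now <- function(store) {
  store$clock_counter <- store$clock_counter + 1L
  if (store$test_mode) {
    as.POSIXct("2000-01-01 00:00:00", tz = "UTC") + store$clock_counter
  } else {
    Sys.time()
  }
}

# Snapshot/restore give transactional semantics to multi-step operations
# (upload_genome): any failure rolls the store back to the snapshot.
store_snapshot <- function(store) {
  state <- mget(.store_fields, envir = store)
  state$annotations <- as.list(store$annotations)
  state$seq_index <- as.list(store$seq_index)
  state$results <- as.list(store$results)
  state
}

store_restore <- function(store, state) {
  for (f in .store_fields) assign(f, state[[f]], envir = store)
  store$annotations <- list2env(state$annotations, parent = emptyenv())
  store$seq_index <- list2env(state$seq_index, parent = emptyenv())
  store$results <- list2env(state$results, parent = emptyenv())
  invisible(store)
}

seq_key <- function(sequence, molecule_kind) paste0(molecule_kind, "\r", sequence)

#' Draw the next automatic accession
#'
#' Accessions follow the format `MAS_%07d`: a zero-padded strictly increasing
#' counter. Values are never reused, even after deletions.
#'
#' @param store An open store.
#' @return A single accession string.
#' @export
assign_accession <- function(store) {
  check_store(store)
  store$acc_counter <- store$acc_counter + 1L
  acc <- sprintf("MAS_%07d", store$acc_counter)
  store_save(store)
  acc
}

#' Fetch or create the annotation for a sequence
#'
#' Annotations are deduplicated by `(sequence, molecule_kind)`: if a matching
#' annotation already exists anywhere in the store it is returned unchanged
#' (`created = FALSE`); otherwise a new one is created with a fresh accession,
#' an empty label, and the default flag (`UNANNOTATED` for proteins, `NONE`
#' otherwise).
#'
#' @param store An open store.
#' @param sequence Non-empty sequence string (one-letter amino acids for
#'   proteins, nucleotides for RNA/DNA annotations).
#' @param molecule_kind One of `"protein"`, `"rna"`, `"dna"`.
#' @param assigned_to Optional user name assigned at creation (no history
#'   event; this is part of the creation state).
#' @return List with elements `annotation` and `created`.
#' @export
get_or_create_annotation <- function(store, sequence, molecule_kind = "protein",
                                     assigned_to = NULL) {
  check_store(store)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    anno_validation_error("annotation sequence must be a non-empty string")
  if (!molecule_kind %in% c("protein", "rna", "dna"))
    anno_validation_error("molecule_kind must be protein, rna or dna, got '%s'", molecule_kind)
  key <- seq_key(sequence, molecule_kind)
  acc <- store$seq_index[[key]]
  if (!is.null(acc)) {
    return(list(annotation = store$annotations[[acc]], created = FALSE))
  }
  acc <- assign_accession(store)
  ann <- list(
    accession = acc,
    sequence = sequence,
    molecule_kind = molecule_kind,
    label = "",
    flag = if (molecule_kind == "protein") "UNANNOTATED" else "NONE",
    public_notes = "",
    private_notes = "",
    assigned_to = assigned_to %||% "",
    created_at = store_now(store)
  )
  store$annotations[[acc]] <- ann
  store$seq_index[[key]] <- acc
  store$internal_stale <- TRUE
  store_save(store)
  list(annotation = ann, created = TRUE)
}

#' Fetch one annotation by accession
#'
#' @param store An open store.
#' @param accession Annotation accession.
#' @return The annotation record (a named list).
#' @export
get_annotation <- function(store, accession) {
  check_store(store)
  ann <- store$annotations[[accession]]
  if (is.null(ann)) anno_not_found_error("no annotation with accession '%s'", accession)
  ann
}

#' Edit an annotation's attributes
#'
#' Updates any of `label`, `flag`, `public_notes`, `private_notes`,
#' `assigned_to`, appending one history event per field that actually changes
#' (edits that change nothing append no event). Any change marks the internal
#' database stale.
#'
#' @param store An open store.
#' @param accession Annotation accession.
#' @param changes Named list of field -> new value.
#' @param user Free-text name of the editing user, recorded in the history.
#' @return The updated annotation record.
#' @export
update_annotation <- function(store, accession, changes, user) {
  check_store(store)
  ann <- get_annotation(store, accession)
  if (length(changes) == 0L) return(ann)
  if (is.null(names(changes)) || any(!nzchar(names(changes))))
    anno_validation_error("changes must be a named list")
  bad <- setdiff(names(changes), .editable_fields)
  if (length(bad))
    anno_validation_error("field(s) not editable: %s", paste(bad, collapse = ", "))
  if ("flag" %in% names(changes) && !changes$flag %in% annotation_flags())
    anno_validation_error("unknown flag value '%s'", changes$flag)
  touched <- FALSE
  for (field in names(changes)) {
    new <- as.character(changes[[field]])
    old <- as.character(ann[[field]])
    if (identical(new, old)) next
    store$event_counter <- store$event_counter + 1L
    store$events[[length(store$events) + 1L]] <- list(
      seq = store$event_counter,
      accession = accession,
      timestamp = store_now(store),
      user = user,
      field_changed = field,
      old_value = old,
      new_value = new
    )
    ann[[field]] <- new
    touched <- TRUE
  }
  if (touched) {
    store$annotations[[accession]] <- ann
    store$internal_stale <- TRUE
    store_save(store)
  }
  invisible(ann)
}

#' Edit history of an annotation
#'
#' Events are append-only and returned in chronological order; replaying them
#' over the annotation's creation state reconstructs its current field values.
#'
#' @param store An open store.
#' @param accession Annotation accession.
#' @return Data frame with columns `seq`, `accession`, `timestamp`, `user`,
#'   `field_changed`, `old_value`, `new_value` (zero rows for a fresh
#'   annotation).
#' @export
get_history <- function(store, accession) {
  check_store(store)
  get_annotation(store, accession)
  ev <- Filter(function(e) e$accession == accession, store$events)
  if (!length(ev)) {
    return(data.frame(seq = integer(), accession = character(),
                      timestamp = as.POSIXct(character()), user = character(),
                      field_changed = character(), old_value = character(),
                      new_value = character(), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    seq = vapply(ev, `[[`, integer(1), "seq"),
    accession = accession,
    timestamp = as.POSIXct(vapply(ev, function(e) as.numeric(e$timestamp), numeric(1)),
                           origin = "1970-01-01", tz = "UTC"),
    user = vapply(ev, `[[`, character(1), "user"),
    field_changed = vapply(ev, `[[`, character(1), "field_changed"),
    old_value = vapply(ev, `[[`, character(1), "old_value"),
    new_value = vapply(ev, `[[`, character(1), "new_value"),
    stringsAsFactors = FALSE
  )
  out[order(out$seq), , drop = FALSE]
}

# Number of history events recorded so far for an accession (staleness token
# for recommendations).
annotation_version <- function(store, accession) {
  sum(vapply(store$events, function(e) e$accession == accession, logical(1)))
}

#' Feature table of a genome (or the whole store)
#'
#' One row per feature with its genome, kind, 0-based half-open coordinates,
#' strand, origin-wrap flag, and the accession of its annotation.
#'
#' @param store An open store.
#' @param genome Optional genome name to restrict to.
#' @return Data frame of features.
#' @export
feature_table <- function(store, genome = NULL) {
  feats <- store$features
  if (!is.null(genome)) feats <- Filter(function(f) f$genome == genome, feats)
  if (!length(feats)) {
    return(data.frame(id = integer(), genome = character(), kind = character(),
                      start = integer(), stop = integer(), strand = character(),
                      wraps_origin = logical(), accession = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    id = vapply(feats, `[[`, integer(1), "id"),
    genome = vapply(feats, `[[`, character(1), "genome"),
    kind = vapply(feats, `[[`, character(1), "kind"),
    start = vapply(feats, `[[`, integer(1), "start"),
    stop = vapply(feats, `[[`, integer(1), "stop"),
    strand = vapply(feats, `[[`, character(1), "strand"),
    wraps_origin = vapply(feats, `[[`, logical(1), "wraps_origin"),
    accession = vapply(feats, `[[`, character(1), "accession"),
    stringsAsFactors = FALSE
  )
}

#' Fetch one genome record
#'
#' @param store An open store.
#' @param name Genome name.
#' @return The genome record (named list with `name`, `sequence`, `topology`,
#'   `organism_kind`, `upload_time`, `features`).
#' @export
get_genome <- function(store, name) {
  check_store(store)
  g <- store$genomes[[name]]
  if (is.null(g)) anno_not_found_error("no genome named '%s'", name)
  g
}

#' Summary table of genomes
#'
#' One row per genome: name, sequence length, feature count, and the number of
#' features carrying each flag (via their annotations). The filter is a
#' case-insensitive substring match on the genome name; the table is sortable
#' by any column, including per-flag counts.
#'
#' @param store An open store.
#' @param filter Optional substring to match against genome names.
#' @param sort_key Column to sort by (default `"name"`).
#' @param decreasing Sort direction.
#' @return Data frame of genome summaries.
#' @export
list_genomes <- function(store, filter = NULL, sort_key = "name", decreasing = FALSE) {
  check_store(store)
  flags <- annotation_flags()
  names_ <- names(store$genomes)
  if (!is.null(filter) && nzchar(filter))
    names_ <- names_[grepl(filter, names_, ignore.case = TRUE, fixed = FALSE)]
  rows <- lapply(names_, function(nm) {
    g <- store$genomes[[nm]]
    ft <- feature_table(store, nm)
    fl <- vapply(ft$accession, function(a) store$annotations[[a]]$flag, character(1))
    counts <- vapply(flags, function(f) sum(fl == f), integer(1))
    c(list(name = nm, length = nchar(g$sequence), n_features = nrow(ft)),
      as.list(counts))
  })
  out <- if (length(rows)) {
    do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  } else {
    empty <- c(list(name = character(), length = integer(), n_features = integer()),
               setNames(rep(list(integer()), length(flags)), flags))
    as.data.frame(empty, stringsAsFactors = FALSE)
  }
  if (!sort_key %in% names(out))
    anno_validation_error("unknown sort key '%s'", sort_key)
  out[order(out[[sort_key]], decreasing = decreasing), , drop = FALSE]
}

#' Filterable table of annotations
#'
#' Supports the three navigation modes: by flag and by assignment (sorted by
#' accession) and by genome (sorted by genomic start coordinate; one row per
#' feature). The text filter is a case-insensitive substring match on the
#' label or accession.
#'
#' @param store An open store.
#' @param flag Optional flag value to filter on.
#' @param assigned_to Optional assignee to filter on.
#' @param text Optional substring filter on label/accession.
#' @param order `"accession"` (default) or `"genomic"`.
#' @param genome Genome name; required when `order = "genomic"`.
#' @return Data frame of annotations (plus feature coordinates for genomic
#'   order).
#' @export
list_annotations <- function(store, flag = NULL, assigned_to = NULL, text = NULL,
                             order = c("accession", "genomic"), genome = NULL) {
  check_store(store)
  order <- match.arg(order)
  anns <- as.list(store$annotations)
  keep <- function(a) {
    (is.null(flag) || a$flag == flag) &&
      (is.null(assigned_to) || a$assigned_to == assigned_to) &&
      (is.null(text) || grepl(text, a$label, ignore.case = TRUE) ||
         grepl(text, a$accession, ignore.case = TRUE))
  }
  anns <- Filter(keep, anns)
  ann_row <- function(a) data.frame(
    accession = a$accession, label = a$label, flag = a$flag,
    assigned_to = a$assigned_to, molecule_kind = a$molecule_kind,
    stringsAsFactors = FALSE
  )
  if (order == "accession") {
    out <- if (length(anns)) {
      do.call(rbind, lapply(anns, ann_row))
    } else {
      data.frame(accession = character(), label = character(),
                 flag = character(), assigned_to = character(),
                 molecule_kind = character(), stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    return(out[order(out$accession), , drop = FALSE])
  }
  if (is.null(genome))
    anno_validation_error("order = 'genomic' requires a genome name")
  get_genome(store, genome)
  ft <- feature_table(store, genome)
  accs <- vapply(anns, `[[`, character(1), "accession")
  ft <- ft[ft$accession %in% accs, , drop = FALSE]
  ft <- ft[order(ft$start), , drop = FALSE]
  if (!nrow(ft)) {
    return(data.frame(accession = character(), label = character(),
                      flag = character(), assigned_to = character(),
                      molecule_kind = character(), genome = character(),
                      start = integer(), stop = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(ft)), function(i) {
    a <- store$annotations[[ft$accession[i]]]
    cbind(ann_row(a),
          data.frame(genome = genome, start = ft$start[i], stop = ft$stop[i],
                     strand = ft$strand[i], stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Internal: register a genome + its features/annotations. Used by
# upload_genome; drafts carry 0-based half-open coordinates.
add_genome_record <- function(store, name, sequence, topology, organism_kind,
                              feature_rows) {
  g <- list(name = name, sequence = sequence, topology = topology,
            organism_kind = organism_kind, upload_time = store_now(store),
            features = integer(0))
  ids <- integer(0)
  for (i in seq_len(nrow(feature_rows))) {
    store$feature_counter <- store$feature_counter + 1L
    id <- store$feature_counter
    store$features[[as.character(id)]] <- list(
      id = id, genome = name, kind = feature_rows$kind[i],
      start = as.integer(feature_rows$start[i]),
      stop = as.integer(feature_rows$stop[i]),
      strand = feature_rows$strand[i],
      wraps_origin = isTRUE(feature_rows$wraps_origin[i]),
      accession = feature_rows$accession[i]
    )
    ids <- c(ids, id)
  }
  g$features <- ids
  store$genomes[[name]] <- g
  g
}
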