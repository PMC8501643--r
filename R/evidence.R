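# Evidence summarisation: turn stored per-database hits into the predicates
# the decision guide consumes (significance, within/across-database
# consistency, length similarity, alignment coverage), the e-value colour
# scale, and the genome-map data product.

#' Default thresholds
#'
#' All numeric cutoffs used by the evidence predicates, the decision engine,
#' and terminase detection. None of these is prescribed by the annotation
#' guide itself, so every one is explicit and configurable, and each fired
#' recommendation records the values it used in its rationale.
#'
#' \describe{
#'   \item{evalue_significant / evalue_moderate}{BLAST-style hits: significant
#'     when `e <= 1e-5`; moderate when `1e-5 < e <= 1e-2`.}
#'   \item{prob_significant / prob_moderate}{HHsearch probability (0-100):
#'     significant at `>= 80`, moderate at `>= 50`.}
#'   \item{coverage_high / coverage_some}{Alignment coverage classes:
#'     `all_most` at `>= 0.8`, `some` in `[0.35, 0.8)`, else `negligible`.}
#'   \item{length_similar}{Query/subject lengths are "similar" when
#'     `min/max >= 0.8`.}
#'   \item{jaccard / consistency_k}{Label-consistency: majority of pairwise
#'     Jaccard similarities `>= 0.5` among the top `k = 5` hits.}
#'   \item{terminase_evalue / terminase_qcov}{"Enough evidence" of a
#'     terminase: best hit `e <= 1e-10` with query coverage `>= 0.5`.}
#' }
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(evalue_significant = 1e-5, evalue_moderate = 1e-2,
       prob_significant = 80, prob_moderate = 50,
       coverage_high = 0.8, coverage_some = 0.35,
       length_similar = 0.8, jaccard = 0.5, consistency_k = 5L,
       terminase_evalue = 1e-10, terminase_qcov = 0.5)
}

#' Alignment coverage fractions
#'
#' Fraction of the query and of the subject covered by the aligned interval:
#' `q_cov = (q_end - q_start + 1) / query_length` and
#' `s_cov = (s_end - s_start + 1) / subject_length`.
#'
#' @param hit One-row hit data frame (or list with the coordinate fields).
#' @param query_length Query length in residues.
#' @return Named numeric vector `c(q_cov, s_cov)`, each in `(0, 1]`.
#' @export
coverage_fractions <- function(hit, query_length) {
  c(q_cov = (hit$q_end - hit$q_start + 1) / query_length,
    s_cov = (hit$s_end - hit$s_start + 1) / hit$subject_length)
}

coverage_class <- function(frac, thresholds = default_thresholds()) {
  ifelse(frac >= thresholds$coverage_high, "all_most",
         ifelse(frac >= thresholds$coverage_some, "some", "negligible"))
}

#' Classify hit significance
#'
#' BLAST-style tools (`blastp`, `rpsblast`) classify on the e-value;
#' `hhsearch` on the probability column. Cutoffs come from the threshold
#' list.
#'
#' @param hit One-row hit data frame.
#' @param tool Tool that produced the hit.
#' @param thresholds Threshold list.
#' @return `"significant"`, `"moderate"`, or `"none"`.
#' @export
classify_significance <- function(hit, tool, thresholds = default_thresholds()) {
  if (tool == "hhsearch") {
    p <- hit$score
    if (p >= thresholds$prob_significant) "significant"
    else if (p >= thresholds$prob_moderate) "moderate"
    else "none"
  } else {
    e <- hit$evalue
    if (e <= thresholds$evalue_significant) "significant"
    else if (e <= thresholds$evalue_moderate) "moderate"
    else "none"
  }
}

.label_stopwords <- c("protein", "putative", "probable", "predicted",
                      "hypothetical", "family", "domain", "phage",
                      "uncharacterized", "conserved")

# Ordered token sequence after normalization (used by generalize_label).
normalize_tokens <- function(text) {
  x <- tolower(text %||% "")
  x <- gsub("[][(){}<>,;:/\\\\'\"!?.*+=|_-]", " ", x)
  toks <- strsplit(trimws(gsub("\\s+", " ", x)), " ")[[1]]
  toks <- toks[nzchar(toks)]
  toks[!toks %in% .label_stopwords]
}

#' Normalize a product label to a token set
#'
#' Lowercases, strips punctuation and brackets, drops uninformative stopwords
#' (protein, putative, probable, predicted, hypothetical, family, domain,
#' phage, uncharacterized, conserved), and collapses whitespace. The token
#' set is what the consistency predicates compare.
#'
#' @param text Label text.
#' @return Character vector of unique tokens (possibly empty).
#' @export
normalize_label <- function(text) unique(normalize_tokens(text))

jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Are a set of hit labels consistent?
#'
#' Normalizes the first `k` labels to token sets and requires a majority of
#' pairwise Jaccard similarities to reach `min_jaccard`. One label is
#' trivially consistent. Used both within one database (top-k hits) and
#' across databases (top hit of each).
#'
#' @param labels Character vector of labels.
#' @param k Number of labels considered (default 5).
#' @param min_jaccard Pairwise similarity cutoff (default 0.5).
#' @return Logical.
#' @export
labels_consistent <- function(labels, k = 5L, min_jaccard = 0.5) {
  labels <- head(labels, k)
  if (length(labels) < 1L)
    anno_validation_error("labels_consistent needs at least one label")
  if (length(labels) == 1L) return(TRUE)
  sets <- lapply(labels, normalize_label)
  pairs <- utils::combn(length(sets), 2L)
  sims <- apply(pairs, 2L, function(p) jaccard(sets[[p[1]]], sets[[p[2]]]))
  mean(sims >= min_jaccard) > 0.5
}

# The label a hit contributes: internal-database hits carry
# "accession|flag|label" descriptions; everything else uses the subject
# description (falling back to the subject id).
hit_label <- function(hit, database) {
  if (database == "internal") {
    parts <- strsplit(hit$subject_description, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 3L) return(paste(parts[3:length(parts)], collapse = "|"))
  }
  if (!is.na(hit$subject_description) && nzchar(hit$subject_description))
    hit$subject_description
  else hit$subject_id
}

hit_flag <- function(hit, database) {
  if (database == "internal") {
    parts <- strsplit(hit$subject_description, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2L && parts[2] %in% annotation_flags()) return(parts[2])
  }
  NA_character_
}

neutral_db_evidence <- function() {
  list(present = FALSE, significance = "none", consistent_within = TRUE,
       top_hit = NULL, top_label = "", length_similar = FALSE,
       q_coverage_class = "negligible", s_coverage_class = "negligible",
       n_hits = 0L)
}

#' Summarize stored evidence for an annotation
#'
#' Builds the per-database predicate block the decision engine consumes: for
#' every stored search result of the annotation, the top hit's significance
#' class, within-database label consistency (top-k), query/subject length
#' similarity, and coverage classes. Databases without stored results are
#' `present = FALSE` with neutral defaults. The summary is a pure function of
#' the stored hits.
#'
#' @param store An open store.
#' @param accession Annotation accession.
#' @param thresholds Threshold list.
#' @return List of class `evidence_summary`: `accession`, `query_length`,
#'   `per_db` (map `"tool:database"` -> evidence), `version` (history length
#'   at summary time, used for staleness detection), `thresholds`.
#' @export
summarize_evidence <- function(store, accession, thresholds = default_thresholds()) {
  check_store(store)
  ann <- get_annotation(store, accession)
  qlen <- nchar(ann$sequence)
  results <- get_search_results(store, accession)
  per_db <- list()
  for (r in results) {
    key <- paste(r$tool, r$database, sep = ":")
    hits <- r$hits
    if (is.null(hits) || !nrow(hits)) {
      ev <- neutral_db_evidence()
      per_db[[key]] <- ev
      next
    }
    top <- hits[1, ]
    covs <- coverage_fractions(top, qlen)
    labels <- vapply(seq_len(min(nrow(hits), thresholds$consistency_k)),
                     function(i) hit_label(hits[i, ], r$database), character(1))
    per_db[[key]] <- list(
      present = TRUE,
      significance = classify_significance(top, r$tool, thresholds),
      consistent_within = labels_consistent(labels, k = thresholds$consistency_k,
                                            min_jaccard = thresholds$jaccard),
      top_hit = top,
      top_label = hit_label(top, r$database),
      top_flag = hit_flag(top, r$database),
      length_similar = min(qlen, top$subject_length) / max(qlen, top$subject_length) >=
        thresholds$length_similar,
      q_coverage_class = coverage_class(covs[["q_cov"]], thresholds),
      s_coverage_class = coverage_class(covs[["s_cov"]], thresholds),
      n_hits = nrow(hits),
      database = r$database,
      tool = r$tool,
      hits = hits
    )
  }
  structure(list(accession = accession, query_length = qlen, per_db = per_db,
                 version = annotation_version(store, accession),
                 thresholds = thresholds),
            class = "evidence_summary")
}

#' E-value colour scale
#'
#' Maps an e-value to the hex colour used when drawing hit blocks: black
#' (`#000000`) at e-value 10 (or worse), light yellow (`#FFFFE0`) at e-value
#' 0, interpolating linearly in log10 space between a floor of 1e-180 and 10.
#' Smaller e-values are strictly lighter in every channel.
#'
#' @param evalue Numeric vector of e-values (`>= 0`).
#' @return Character vector of `#RRGGBB` colours.
#' @export
evalue_color <- function(evalue) {
  if (any(evalue < 0)) anno_validation_error("e-values must be non-negative")
  lo <- -180; hi <- 1  # log10 bounds
  l <- ifelse(evalue <= 0, lo, pmin(pmax(log10(evalue), lo), hi))
  t <- (l - lo) / (hi - lo)              # 0 at light-yellow end, 1 at black
  light <- c(255L, 255L, 224L)           # #FFFFE0
  chan <- function(c0) as.integer(round((1 - t) * c0))
  sprintf("#%02X%02X%02X", chan(light[1]), chan(light[2]), chan(light[3]))
}

#' Genome map data product
#'
#' A drawable summary of a genome: one block per feature with its
#' coordinates, strand, kind, flag (which determines the rendered colour),
#' label, and accession. Emitted only for genomes with fewer than 1000
#' features; returns `NULL` at or above that threshold.
#'
#' @param store An open store.
#' @param genome Genome name.
#' @return `NULL`, or a list of class `genome_map` with `genome`, `length`,
#'   `blocks` (data frame).
#' @export
genome_map <- function(store, genome) {
  check_store(store)
  g <- get_genome(store, genome)
  ft <- feature_table(store, genome)
  if (nrow(ft) >= 1000L) return(NULL)
  blocks <- ft[order(ft$start), c("start", "stop", "strand", "kind", "accession"),
               drop = FALSE]
  blocks$flag <- vapply(blocks$accession, function(a) store$annotations[[a]]$flag,
                        character(1))
  blocks$label <- vapply(blocks$accession, function(a) store$annotations[[a]]$label,
                         character(1))
  rownames(blocks) <- NULL
  structure(list(genome = genome, length = nchar(g$sequence),
                 blocks = blocks[, c("start", "stop", "strand", "kind", "flag",
                                     "label", "accession")]),
            class = "genome_map")
}

#' Serialize a genome map as JSON
#'
#' @param map A [genome_map()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_map <- function(map, path) {
  if (is.null(map)) anno_validation_error("no map to write (>= 1000 features?)")
  jsonlite::write_json(list(genome = map$genome, length = map$length,
                            blocks = map$blocks),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
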