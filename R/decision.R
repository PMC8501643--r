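# The annotation decision guide as a rule engine: an ordered encoding of the
# situations an annotator meets when weighing homology evidence (which
# databases answered, how significant, how consistent, how well the
# alignments cover query and subject) and the procedure each situation leads
# to. The engine only suggests; a human applies the suggestion via
# apply_recommendation().

.curation_order <- c("internal", "swissprot", "cdd", "pdb", "nr")
.decision_dbs <- c(swissprot = "blastp:swissprot", nr = "blastp:nr",
                   internal = "blastp:internal", cdd = "rpsblast:cdd",
                   pdb = "hhsearch:pdb")

.protected_heads <- list(c("large", "subunit"), c("small", "subunit"),
                         c("tail", "fiber"), c("major", "capsid"),
                         c("binding", "site"))

#' Generalize a product label to its head functional noun
#'
#' When only remote-homology evidence supports a label, a highly specific
#' subject name risks over-annotation; the safer label is the head functional
#' noun (e.g. "cell death-related nuclease" generalizes to "nuclease").
#' Multiword heads from a small protected list ("large subunit", "tail
#' fiber", ...) are restored together with the noun before them, so
#' "terminase large subunit" is its own generalization.
#'
#' @param label Label text.
#' @return Generalized label; `"hypothetical protein"` when the label
#'   normalizes to nothing.
#' @export
generalize_label <- function(label) {
  toks <- normalize_tokens(label)
  if (!length(toks)) return("hypothetical protein")
  for (ph in .protected_heads) {
    np <- length(ph)
    if (length(toks) >= np && identical(tail(toks, np), ph)) {
      keep <- min(length(toks), np + 1L)
      return(paste(tail(toks, keep), collapse = " "))
    }
  }
  tail(toks, 1L)
}

# DUF (domain of unknown function) token in a hit's id/description, or NA.
duf_token <- function(hit) {
  m <- regmatches(paste(hit$subject_id, hit$subject_description),
                  regexpr("DUF[0-9]+", paste(hit$subject_id, hit$subject_description),
                          ignore.case = TRUE))
  if (length(m)) toupper(m[1]) else NA_character_
}

# The "name of the domain" for domain-containing labels: the DUF token when
# the model is a DUF, otherwise the domain model's id.
domain_name <- function(hit) {
  duf <- duf_token(hit)
  if (!is.na(duf)) duf else hit$subject_id
}

# Decision context: evidence per short database name plus the significant /
# moderate / present sets.
decision_context <- function(summary) {
  ev <- lapply(.decision_dbs, function(key) summary$per_db[[key]] %||% neutral_db_evidence())
  names(ev) <- names(.decision_dbs)
  present <- names(ev)[vapply(ev, `[[`, logical(1), "present")]
  sig <- present[vapply(ev[present], function(e) e$significance == "significant", logical(1))]
  mod <- present[vapply(ev[present], function(e) e$significance == "moderate", logical(1))]
  list(summary = summary, ev = ev, present = present, sig = sig, mod = mod,
       th = summary$thresholds)
}

best_curated <- function(dbs) .curation_order[.curation_order %in% dbs][1]

consistent_across <- function(ctx, dbs) {
  labels <- vapply(dbs, function(d) ctx$ev[[d]]$top_label, character(1))
  labels_consistent(labels, k = length(labels), min_jaccard = ctx$th$jaccard)
}

full_coverage <- function(e) e$q_coverage_class == "all_most" && e$s_coverage_class == "all_most"

# Ordered rule table. Each rule: id, match(ctx) -> logical, fire(ctx) ->
# list(label, flag, putative, notes). The first matching rule decides; P1
# doubles as the total-function fallback (see the methods vignette).
.rules <- list(
  list(id = "P2",
       match = function(ctx) identical(ctx$present, "nr") &&
         "nr" %in% ctx$sig && !ctx$ev$nr$consistent_within,
       fire = function(ctx) list(
         label = "hypothetical protein", flag = "REVIEW_NAME", putative = FALSE,
         notes = "only nr answered and its hits disagree; such results can typically be disregarded")),
  list(id = "P3",
       match = function(ctx) identical(ctx$present, "nr") &&
         "nr" %in% ctx$sig && ctx$ev$nr$consistent_within,
       fire = function(ctx) list(
         label = ctx$ev$nr$top_label, flag = "REVIEW_NAME", putative = FALSE,
         notes = "only nr answered; hits agree but nr curation varies -- verify before trusting")),
  list(id = "P4",
       match = function(ctx) "cdd" %in% ctx$sig && all(ctx$sig %in% c("cdd", "nr")) &&
         ctx$ev$cdd$consistent_within && full_coverage(ctx$ev$cdd),
       fire = function(ctx) {
         hit <- ctx$ev$cdd$top_hit
         duf <- duf_token(hit)
         if (!is.na(duf)) {
           list(label = paste(duf, "domain-containing protein"), flag = NA_character_,
                putative = FALSE,
                notes = sprintf("domain model %s is a domain of unknown function", duf))
         } else {
           list(label = ctx$ev$cdd$top_label, flag = NA_character_, putative = FALSE,
                notes = "consistent full-coverage domain hit describing a singular function")
         }
       }),
  list(id = "P5",
       match = function(ctx) "cdd" %in% ctx$sig && all(ctx$sig %in% c("cdd", "nr")) &&
         ctx$ev$cdd$consistent_within &&
         ctx$ev$cdd$s_coverage_class == "all_most" &&
         ctx$ev$cdd$q_coverage_class == "some",
       fire = function(ctx) list(
         label = paste(domain_name(ctx$ev$cdd$top_hit), "domain-containing protein"),
         flag = NA_character_, putative = FALSE,
         notes = "domain covers only part of the query; name by the contained domain")),
  list(id = "P6",
       match = function(ctx) "cdd" %in% ctx$sig && all(ctx$sig %in% c("cdd", "nr")) &&
         !ctx$ev$cdd$consistent_within,
       fire = function(ctx) {
         hits <- ctx$ev$cdd$hits
         k <- min(nrow(hits), ctx$th$consistency_k)
         qint <- hits[seq_len(k), c("q_start", "q_end")]
         overlap <- all(max(qint$q_start) <= min(qint$q_end))
         nm <- domain_name(hits[1, ])  # most significant domain
         note <- if (overlap)
           "inconsistent domains align to the same query interval; named by the most significant"
         else
           "inconsistent domains occupy disjoint query intervals (likely multi-domain); named by the most significant"
         list(label = paste(nm, "domain-containing protein"), flag = NA_character_,
              putative = FALSE, notes = note)
       }),
  list(id = "P7",
       match = function(ctx) length(ctx$sig) >= 1L && !"internal" %in% ctx$sig &&
         !identical(ctx$sig, "pdb") &&   # remote-homology-only evidence is P11's case
         consistent_across(ctx, ctx$sig) && {
           e <- ctx$ev[[best_curated(ctx$sig)]]
           full_coverage(e) && e$length_similar
         },
       fire = function(ctx) {
         d <- best_curated(ctx$sig)
         note <- if (d == "swissprot")
           "curated (Swiss-Prot-style) hit with full coverage; label used directly"
         else
           sprintf("consistent full-coverage evidence; label from the most curated database (%s)", d)
         list(label = ctx$ev[[d]]$top_label, flag = NA_character_, putative = FALSE,
              notes = note)
       }),
  list(id = "P8",
       match = function(ctx) length(ctx$sig) >= 1L && {
         e <- ctx$ev[[best_curated(ctx$sig)]]
         !e$length_similar || !full_coverage(e)
       },
       fire = function(ctx) {
         d <- best_curated(ctx$sig)
         e <- ctx$ev[[d]]
         hit <- e$top_hit
         pattern <- if (!is.null(hit) && hit$s_end >= 0.9 * hit$subject_length &&
                        hit$s_start > 0.1 * hit$subject_length)
           "query aligns to the subject C-terminus: the start codon may be incorrect"
         else if (!is.null(hit) && hit$s_start <= 0.1 * hit$subject_length &&
                  hit$s_end < 0.9 * hit$subject_length)
           "query aligns to the subject N-terminus: the query may be truncated"
         else
           "partial alignment: query and subject may only share a domain"
         list(label = e$top_label, flag = "REVIEW_NAME", putative = FALSE,
              notes = paste("length/coverage mismatch --", pattern))
       }),
  list(id = "P9",
       match = function(ctx) length(ctx$sig) == 0L && length(ctx$mod) >= 1L &&
         consistent_across(ctx, ctx$mod),
       fire = function(ctx) {
         d <- best_curated(ctx$mod)
         list(label = ctx$ev[[d]]$top_label, flag = NA_character_, putative = TRUE,
              notes = "only moderate significance without multi-database confirmation; label prefixed with 'putative'")
       }),
  list(id = "P10",
       match = function(ctx) "internal" %in% ctx$sig &&
         (length(ctx$sig) == 1L || consistent_across(ctx, ctx$sig)),
       fire = function(ctx) {
         e <- ctx$ev$internal
         list(label = e$top_label, flag = e$top_flag %||% NA_character_,
              putative = FALSE,
              notes = "previously annotated identical/similar protein in the internal database; reusing its label keeps naming consistent")
       }),
  list(id = "P11",
       match = function(ctx) identical(ctx$sig, "pdb"),
       fire = function(ctx) {
         full <- ctx$ev$pdb$top_label
         gen <- generalize_label(full)
         lossy <- !identical(normalize_tokens(gen), normalize_tokens(full))
         list(label = gen, flag = NA_character_, putative = lossy,
              notes = "remote-homology evidence only; label generalized to avoid over-annotation")
       }),
  list(id = "P12",
       match = function(ctx) length(ctx$sig) >= 2L && !consistent_across(ctx, ctx$sig),
       fire = function(ctx) {
         d <- best_curated(ctx$sig)
         list(label = ctx$ev[[d]]$top_label, flag = "REVIEW_NAME", putative = FALSE,
              notes = sprintf("significant databases disagree; label from the most curated (%s); investigate the inconsistency", d))
       })
)

#' Recommend a label for an annotation
#'
#' Runs the evidence summary through the ordered decision guide and returns
#' the first procedure whose situation matches, with a suggested label, a
#' suggested flag (`NA` = keep the current flag), whether "putative" was
#' prepended, and a rationale listing the predicates evaluated, the
#' thresholds used, and any other procedures that would also have applied.
#' P1 -- no usable results in any database -- suggests "hypothetical
#' protein" and is also the fallback when evidence matches no other row, so
#' every well-formed summary yields exactly one procedure.
#'
#' @param summary An [summarize_evidence()] result.
#' @return List of class `annotation_recommendation`.
#' @export
recommend_annotation <- function(summary) {
  if (!inherits(summary, "evidence_summary"))
    anno_validation_error("summary must come from summarize_evidence()")
  ctx <- decision_context(summary)
  matched <- vapply(.rules, function(r) isTRUE(r$match(ctx)), logical(1))
  rationale <- c(
    sprintf("databases with results: %s",
            if (length(ctx$present)) paste(ctx$present, collapse = ", ") else "none"),
    sprintf("significant: %s; moderate: %s",
            if (length(ctx$sig)) paste(ctx$sig, collapse = ", ") else "none",
            if (length(ctx$mod)) paste(ctx$mod, collapse = ", ") else "none"),
    sprintf("thresholds: significant e<=%g (hh prob>=%g), moderate e<=%g (hh prob>=%g), coverage all_most>=%g some>=%g, length similarity>=%g, jaccard>=%g",
            ctx$th$evalue_significant, ctx$th$prob_significant,
            ctx$th$evalue_moderate, ctx$th$prob_moderate,
            ctx$th$coverage_high, ctx$th$coverage_some,
            ctx$th$length_similar, ctx$th$jaccard)
  )
  if (any(matched)) {
    first <- which(matched)[1]
    rule <- .rules[[first]]
    out <- rule$fire(ctx)
    proc <- rule$id
    rationale <- c(rationale, paste0(proc, ": ", out$notes))
    others <- vapply(.rules[matched], `[[`, character(1), "id")
    others <- setdiff(others, proc)
    if (length(others))
      rationale <- c(rationale,
                     sprintf("also applicable: %s", paste(others, collapse = ", ")))
  } else {
    proc <- "P1"
    out <- list(label = "hypothetical protein", flag = NA_character_, putative = FALSE)
    rationale <- c(rationale,
                   if (length(ctx$present) == 0L)
                     "P1: no results in any database; label as 'hypothetical protein'"
                   else
                     "P1 (fallback): results present but none usable under the thresholds; label as 'hypothetical protein'")
  }
  label <- out$label
  if (!nzchar(label %||% "")) label <- "hypothetical protein"
  if (isTRUE(out$putative) && !grepl("^putative\\b", label, ignore.case = TRUE))
    label <- paste("putative", label)
  structure(list(accession = summary$accession, procedure = proc,
                 suggested_label = label,
                 suggested_flag = out$flag,
                 prepend_putative = isTRUE(out$putative),
                 rationale = rationale,
                 version = summary$version),
            class = "annotation_recommendation")
}

#' Apply (or reject) a recommendation
#'
#' When accepted, writes the suggested label -- and flag, when the procedure
#' suggested one -- through [update_annotation()], so the change is recorded
#' in the history and the internal database is marked stale. The engine never
#' auto-commits: this call is the explicit human decision. If the annotation
#' was edited after the evidence was summarized, a conflict error is raised.
#'
#' @param store An open store.
#' @param recommendation An [recommend_annotation()] result.
#' @param user Editing user recorded in the history.
#' @param accept Apply (`TRUE`) or record nothing (`FALSE`).
#' @return The updated annotation, or `NULL` when rejected.
#' @export
apply_recommendation <- function(store, recommendation, user, accept = TRUE) {
  check_store(store)
  if (!inherits(recommendation, "annotation_recommendation"))
    anno_validation_error("recommendation must come from recommend_annotation()")
  if (!accept) return(invisible(NULL))
  acc <- recommendation$accession
  if (annotation_version(store, acc) != recommendation$version)
    anno_conflict_error("annotation %s was edited after this recommendation was computed; re-summarize", acc)
  changes <- list(label = recommendation$suggested_label)
  if (!is.na(recommendation$suggested_flag %||% NA_character_))
    changes$flag <- recommendation$suggested_flag
  update_annotation(store, acc, changes, user)
}

#' Export recommendations as a review sheet
#'
#' One TSV row per recommendation: accession, current label, suggested
#' label, procedure, rationale.
#'
#' @param store An open store.
#' @param recommendations List of recommendations.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_review_sheet <- function(store, recommendations, path) {
  check_store(store)
  rows <- lapply(recommendations, function(r) data.frame(
    accession = r$accession,
    current_label = get_annotation(store, r$accession)$label,
    suggested_label = r$suggested_label,
    procedure = r$procedure,
    rationale = paste(r$rationale, collapse = "; "),
    stringsAsFactors = FALSE))
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(), current_label = character(),
               suggested_label = character(), procedure = character(),
               rationale = character(), stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
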