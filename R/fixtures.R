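# Synthetic-data generators: seeded phage genomes with exactly known gene
# content, a synthetic terminase protein database, and mock homology-result
# files covering every row of the decision guide. Everything regenerates
# byte-identically from (seed, params), so the whole pipeline is testable
# offline with no external binaries or reference databases.

# Fixed synthetic marker genes standing in for the terminase large/small
# subunits. These are synthetic sequences, not real terminase entries: the
# fixtures only need a recognisable pair of proteins whose database headers
# carry the subunit keywords. The nucleotide encodings were built with the
# same stop-cassette construction as the generic fixture genes (stop-rich
# off-frames), so they are safe to plant verbatim.
.TERMINASE_LARGE_NT <- paste0(
  "ATGTCACTGGCACACCTTGGCTATCAAAATAATAGGTGCCCGTTCCTCGAGGATCTGCTAATTAATTACGGCTGCC",
  "GGTGCCTGGGCAGATTGACTAGGCAAGTTTGTCCGCGCAAGTATGTTCTAATTAACTACTGGGTTCGGGGGCGGGT",
  "CATTCTTCGCGATGTCTATTTAACTACTGGGTCATTGTTAACTAACTACGTTCATGTTGAGGTACGCGTTCGAGGA",
  "GCGGTGACAGGACGCTACAGAGGAGTGCTAACTAACTACACTAAATTATATTCGGATGGATGGACAGCGACTAATG",
  "AGTGTAGACTACCTGTCTTAATTAATTATACGGTCAATGGGGCCGAACTGATTAGCCATTTGTGCTTTCTTGTGTT",
  "CGGAGTCCTAACTAACTACGATAGTTATCGTACTACTATACAAAGATGTGGGCGACGAATAGTGACGAAGAGGCTA",
  "ATTAATTATGCAATTTGGGATGCGCCTAACGCAGTTATTATCGCACCCGGGCCAAGGGGGCGTTTAACTAATTATG",
  "GTTTCAGCTGA")
.TERMINASE_SMALL_NT <- paste0(
  "ATGTATCGACTGACCTCCCCTGCAAGTGCTGCTGGAGAACGATACTATGAGTGGACGTTAACTAACTATAACGAAA",
  "CCACGGTTTCCATTAGCGTTATGGACCTTTTGATTCCATTCGCTGCACTAACTAATTATGATTGTATGAACATATG",
  "CTTTCGATGTTCAGCTTGTCTACACTCGTTGGGGCTTCTAATTAATTACAGCAGCGGATCCTGCGCCTCCCGGCCC",
  "CGACCCTGCACCGGTTCGCTTCAGTTACTAACTAATTATCGGTGA")
.TERMINASE_LARGE_AA <- paste0(
  "MSLAHLGYQNNRCPFLEDLLINYGCRCLGRLTRQVCPRKYVLINYWVRGRVILRDVYLTTGSLLTNYVHVEVRVRG",
  "AVTGRYRGVLTNYTKLYSDGWTATNECRLPVLINYTVNGAELISHLCFLVFGVLTNYDSYRTTIQRCGRRIVTKRL",
  "INYAIWDAPNAVIIAPGPRGRLTNYGFS")
.TERMINASE_SMALL_AA <- paste0(
  "MYRLTSPASAAGERYYEWTLTNYNETTVSISVMDLLIPFAALTNYDCMNICFRCSACLHSLGLLINYSSGSCASRP",
  "RPCTGSLQLLTNYR")

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  force(code)
}

.FWD_STOPS <- c("TAA", "TAG", "TGA")
.REV_STOPS <- c("TTA", "CTA", "TCA")   # minus-strand stops read on the plus strand

# Which of the five off-frames (fwd+1, fwd+2, rev aligned 0/1/2) gain a stop
# when codon `cand` follows codon `prev` in the gene's own frame.
off_frame_stops <- function(prev, cand) {
  w1 <- paste0(substr(prev, 2L, 3L), substr(cand, 1L, 1L))
  w2 <- paste0(substr(prev, 3L, 3L), substr(cand, 1L, 2L))
  c(f1 = w1 %in% .FWD_STOPS, f2 = w2 %in% .FWD_STOPS,
    r0 = cand %in% .REV_STOPS, r1 = w1 %in% .REV_STOPS, r2 = w2 %in% .REV_STOPS)
}

# Longest stop-free run (in codons) over the five off-frames of a gene's
# coding-strand nucleotide sequence.
max_offframe_run <- function(nt) {
  codons <- substring(nt, seq.int(1L, nchar(nt) - 2L, 3L),
                      seq.int(3L, nchar(nt), 3L))
  runs <- rep(0L, 5L); worst <- 0L
  for (i in 2:length(codons)) {
    st <- off_frame_stops(codons[i - 1L], codons[i])
    runs <- ifelse(st, 0L, runs + 1L)
    worst <- max(worst, runs)
  }
  worst
}

# Four-sense-codon "stop cassettes" whose junction windows read as a stop in
# every one of the five off-frames: codon 1 (CTA/TTA) is itself a
# minus-strand stop; TA|A gives the +1 frame stop; TT|A / CT|A the
# minus-strand +1 alignment; T|AA the +2 frame stop; T|TA / C|TA the
# minus-strand +2 alignment. All 2x2x2x2 variants (Leu, Ile/Thr, Asn, Tyr)
# are equivalent; sampling among them keeps the planted proteins from
# sharing one long exact motif.
.CASSETTE_OPTIONS <- list(c("CTA", "TTA"), c("ATT", "ACT"),
                          c("AAT", "AAC"), c("TAT", "TAC"))

stop_cassette <- function() vapply(.CASSETTE_OPTIONS, function(o)
  o[sample.int(length(o), 1L)], character(1))

# Build a gene as nucleotides first: ATG, then random sense codons with a
# stop cassette interleaved every ~18 codons, then a stop. The planted
# protein is simply what the gene encodes. The cassettes guarantee that
# every off-frame sees a stop at least every ~22 codons, so no incidental
# ORF of caller-reportable length (>= 30 codons by default) fits inside a
# planted gene.
constrained_gene_nt <- function(n_codons, code, max_run = 26L) {
  sense <- names(code)[code != "*"]
  codons <- "ATG"
  while (length(codons) < n_codons) {
    gap <- min(18L, n_codons - length(codons))
    codons <- c(codons, sample(sense, gap, replace = TRUE))
    if (n_codons - length(codons) >= 4L) codons <- c(codons, stop_cassette())
  }
  nt <- paste0(paste(codons, collapse = ""), sample(.FWD_STOPS, 1L))
  if (max_offframe_run(nt) > max_run)
    anno_validation_error("could not build a stop-rich gene encoding (internal)")
  nt
}

random_protein <- function(len) {
  paste0("M", paste(sample(.AA20, len - 1L, replace = TRUE), collapse = ""))
}

# Spacer with in-frame stop guards at both ends: starts with TTA (a stop for
# an abutting minus-strand gene) and ends with TAA (a stop in the frame of
# an abutting plus-strand gene), random in between.
random_spacer <- function(len) {
  stopifnot(len >= 12L)
  paste0("TTA", paste(sample(c("A", "C", "G", "T"), len - 6L, replace = TRUE),
                      collapse = ""), "TAA")
}

rotate_seq <- function(s, offset) {
  n <- nchar(s)
  offset <- offset %% n
  if (offset == 0L) return(s)
  paste0(substr(s, offset + 1L, n), substr(s, 1L, offset))
}

# Remove every ORF the built-in caller would report beyond the planted genes:
# insert a stop codon in intergenic sequence when possible, otherwise recode
# a planted-gene codon synonymously so the offending frame gains a stop.
# Returns the repaired sequence or NULL when some ORF cannot be broken.
scrub_incidental_orfs <- function(sequence, genes, min_aa_len, code,
                                  frozen = NULL, max_iter = 60L) {
  planted_key <- paste(genes$start, genes$stop, genes$strand)
  n <- nchar(sequence)
  in_gene <- rep(FALSE, n)
  for (i in seq_len(nrow(genes))) {
    # protect the gene body plus the in-frame stop guards flanking it
    lo <- max(1L, genes$start[i] - 2L)
    hi <- min(n, genes$stop[i] + 3L)
    in_gene[lo:hi] <- TRUE
  }
  if (!is.null(frozen)) for (fr in frozen) in_gene[(fr[1] + 1L):fr[2]] <- TRUE
  stop_for <- c("+" = "TAA", "-" = "TTA")
  syn <- split(names(code), unname(code))
  # positions already rewritten by a repair; later repairs must not undo them
  locked <- rep(FALSE, n)

  for (iter in seq_len(max_iter)) {
    found <- call_genes_builtin(sequence, min_aa_len = min_aa_len)
    extra <- found[!(paste(found$start, found$stop, found$strand) %in% planted_key), ,
                   drop = FALSE]
    missing <- setdiff(planted_key, paste(found$start, found$stop, found$strand))
    if (length(missing))
      anno_validation_error("fixture generator broke a planted gene (internal error)")
    if (!nrow(extra)) return(sequence)
    progressed <- FALSE
    # sow stops densely enough along each offending frame that no sub-ORF of
    # min_aa_len codons survives (a single mid-ORF stop would just split the
    # ORF into two smaller ones)
    gap_max <- max(5L, min_aa_len - 5L)
    for (r in seq_len(nrow(extra))) {
      orf <- extra[r, ]
      tri <- seq.int(orf$start + 3L, orf$stop - 6L, by = 3L)  # interior triples
      fixed <- FALSE
      since_stop <- 0L
      for (p in tri) {           # p is 0-based triple start
        since_stop <- since_stop + 1L
        if (since_stop < gap_max) next
        idx <- (p + 1L):(p + 3L)
        if (!any(in_gene[idx]) && !any(locked[idx])) {
          substr(sequence, p + 1L, p + 3L) <- stop_for[[orf$strand]]
          locked[idx] <- TRUE
          fixed <- TRUE
          since_stop <- 0L
        }
      }
      if (!fixed) {
        targets <- if (orf$strand == "+") c("TAA", "TAG", "TGA") else c("TTA", "CTA", "TCA")
        tri_mid <- tri[order(abs(tri - (orf$start + orf$stop) / 2))]
        for (p in tri_mid) {
          cand <- try_recode_triple(sequence, p, genes, in_gene, syn, targets, locked)
          if (!is.null(cand)) {
            sequence <- cand$sequence
            locked[cand$touched] <- TRUE
            fixed <- TRUE
            break
          }
        }
      }
      progressed <- progressed || fixed
    }
    if (!progressed) return(NULL)
  }
  NULL
}

# Try to rewrite the 0-based triple [p, p+3) so it reads one of `targets`,
# changing planted-gene codons only synonymously and protected positions
# (guards, frozen regions, already-repaired positions) not at all. Returns
# list(sequence, touched) or NULL.
try_recode_triple <- function(sequence, p, genes, in_gene, syn, targets, locked) {
  idx <- (p + 1L):(p + 3L)
  if (any(locked[idx])) return(NULL)
  # per-position choice sets, driven by the overlapping gene codons; a
  # protected position outside a gene body (stop guard / frozen region)
  # makes the triple untouchable
  pos_info <- lapply(idx, function(i) {
    gi <- which(genes$start < i & i <= genes$stop)
    if (!length(gi)) {
      if (in_gene[i]) return(NULL)
      return(list(free = TRUE))
    }
    g <- genes[gi[1], ]
    off0 <- (i - 1L) - g$start                 # 0-based offset into the gene
    list(free = FALSE, gene = gi[1], codon_i = off0 %/% 3L, codon_off = off0 %% 3L)
  })
  if (any(vapply(pos_info, is.null, logical(1)))) return(NULL)
  gene_codons <- unique(do.call(rbind, lapply(pos_info, function(pi)
    if (pi$free) NULL else c(pi$gene, pi$codon_i))))
  # enumerate synonymous choices for each touched gene codon
  codon_opts <- list()
  if (!is.null(gene_codons)) {
    for (r in seq_len(nrow(gene_codons))) {
      g <- genes[gene_codons[r, 1], ]
      cp <- g$start + 3L * gene_codons[r, 2]    # 0-based genomic codon start
      if (any(locked[(cp + 1L):(cp + 3L)])) return(NULL)
      cur <- substr(sequence, cp + 1L, cp + 3L)
      cur_read <- if (g$strand == "-")
        as.character(reverseComplement(DNAString(cur))) else cur
      aa <- GENETIC_CODE_11()[[cur_read]]
      opts <- syn[[aa]] %||% cur_read
      genomic <- vapply(opts, function(cd)
        if (g$strand == "-") as.character(reverseComplement(DNAString(cd))) else cd,
        character(1), USE.NAMES = FALSE)
      codon_opts[[r]] <- list(pos = cp, options = genomic)
    }
  }
  free_idx <- idx[vapply(pos_info, `[[`, logical(1), "free")]
  free_sets <- rep(list(c("A", "C", "G", "T")), length(free_idx))
  n_codon <- length(codon_opts)
  grids <- c(lapply(codon_opts, function(co) seq_along(co$options)),
             free_sets)
  if (!length(grids)) return(NULL)
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  for (ci in seq_len(nrow(combos))) {
    s2 <- sequence
    if (n_codon) for (r in seq_len(n_codon)) {
      co <- codon_opts[[r]]
      substr(s2, co$pos + 1L, co$pos + 3L) <- co$options[[combos[ci, r]]]
    }
    if (length(free_idx)) for (k in seq_along(free_idx)) {
      substr(s2, free_idx[k], free_idx[k]) <- combos[ci, n_codon + k]
    }
    if (substr(s2, p + 1L, p + 3L) %in% targets) {
      touched <- idx
      if (n_codon) for (r in seq_len(n_codon))
        touched <- c(touched, (codon_opts[[r]]$pos + 1L):(codon_opts[[r]]$pos + 3L))
      return(list(sequence = s2, touched = unique(touched)))
    }
  }
  NULL
}

GENETIC_CODE_11 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- getGeneticCode("11")
    cache
  }
})

#' Generate a synthetic phage genome with known ground truth
#'
#' Plants `n_genes` protein-coding genes (uniform synonymous-codon model,
#' valid start/stop codons, no internal stops) in random intergenic
#' background, optionally including the synthetic terminase marker proteins
#' (`with_terminase = "large"` plants the large subunit; `"both"` plants the
#' small subunit immediately upstream of the large one, operon-like, on a
#' shared strand). The assembled genome is post-processed so the built-in
#' caller recovers exactly the planted genes: incidental ORFs are broken by
#' stop-codon insertion in intergenic sequence or synonymous recoding inside
#' genes. Optionally the sequence is circularly permuted by a random
#' intergenic offset and/or reverse-complemented (emulating the arbitrary
#' opening and orientation of an assembled, circularly permuted phage
#' chromosome), and/or flanked by direct terminal repeats (mutually exclusive
#' with permutation). All coordinates in the returned truth refer to the
#' emitted sequence; `canonical_sequence` is the re-orientation target
#' (terminase-first, forward strand).
#'
#' @param seed Integer seed; regeneration from `(seed, params)` is
#'   byte-identical.
#' @param n_genes Number of planted genes (>= 1; includes terminase genes).
#' @param mean_gene_len Mean protein length of generic genes, residues.
#' @param with_terminase `"none"`, `"large"`, or `"both"`.
#' @param dtr_length Optional direct terminal repeat length.
#' @param permute Circularly permute by a random intergenic offset?
#' @param rc Reverse-complement the emitted sequence?
#' @param min_aa_len Caller threshold the scrubbing guarantees against.
#' @param include_genes_nt Optional character vector of coding sequences
#'   (in-frame, from a previous fixture's `truth$genes$coding`) planted as
#'   additional genes -- the way to make two fixture genomes share identical
#'   proteins.
#' @return List with `fasta` (text), `sequence`, `name`, and `truth` (list:
#'   `genes` data frame with `start`, `stop`, `strand`, `protein`, `coding`,
#'   `role`; `canonical_sequence`; `dtr_length`; `permutation_offset`;
#'   `reverse_complemented`; `seed`).
#' @export
make_synthetic_phage <- function(seed, n_genes = 10L, mean_gene_len = 120L,
                                 with_terminase = c("none", "large", "both"),
                                 dtr_length = NULL, permute = FALSE, rc = FALSE,
                                 min_aa_len = 30L, include_genes_nt = NULL) {
  with_terminase <- match.arg(with_terminase)
  if (n_genes < 1L) anno_validation_error("n_genes must be >= 1")
  n_term <- switch(with_terminase, none = 0L, large = 1L, both = 2L)
  if (n_genes < n_term)
    anno_validation_error("n_genes too small to fit the terminase genes")
  if (!is.null(dtr_length) && permute)
    anno_validation_error("dtr_length and permute are mutually exclusive (genomes with terminal repeats are not circularly permuted)")

  for (attempt in 0:4) {
    out <- tryCatch(
      with_seed(seed + attempt * 100003L,
                build_synthetic_phage(seed, n_genes, mean_gene_len,
                                      with_terminase, dtr_length, permute,
                                      rc, min_aa_len, include_genes_nt)),
      anno_error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  anno_validation_error("could not assemble a clean synthetic genome for these parameters")
}

build_synthetic_phage <- function(seed, n_genes, mean_gene_len, with_terminase,
                                  dtr_length, permute, rc, min_aa_len,
                                  include_genes_nt = NULL) {
  code <- GENETIC_CODE_11()
  n_term <- switch(with_terminase, none = 0L, large = 1L, both = 2L)
  n_generic <- n_genes - n_term

  lens <- pmax(40L, round(rnorm(n_generic, mean_gene_len, mean_gene_len / 5)))
  coding <- vapply(lens, constrained_gene_nt, character(1), code = code)
  coding <- c(coding, include_genes_nt)
  n_generic <- length(coding)
  strands <- sample(c("+", "-"), n_generic, replace = TRUE)
  roles <- rep("generic", n_generic)

  if (n_term > 0L) {
    tstrand <- sample(c("+", "-"), 1L)
    slot <- sample.int(n_generic + 1L, 1L) - 1L   # genes before the terminase block
    if (with_terminase == "large") {
      block_nt <- .TERMINASE_LARGE_NT
      block_r <- "terminase_large"
      block_s <- tstrand
    } else {
      # small subunit immediately upstream (5'-most in transcription
      # direction): genomically first on "+", last on "-"
      if (tstrand == "+") {
        block_nt <- c(.TERMINASE_SMALL_NT, .TERMINASE_LARGE_NT)
        block_r <- c("terminase_small", "terminase_large")
      } else {
        block_nt <- c(.TERMINASE_LARGE_NT, .TERMINASE_SMALL_NT)
        block_r <- c("terminase_large", "terminase_small")
      }
      block_s <- rep(tstrand, 2L)
    }
    coding <- append(coding, block_nt, after = slot)
    strands <- append(strands, block_s, after = slot)
    roles <- append(roles, block_r, after = slot)
  }

  proteins <- vapply(coding, function(x) {
    aa <- as.character(translate(DNAString(x), genetic.code = code))
    substr(aa, 1L, nchar(aa) - 1L)     # trailing stop
  }, character(1), USE.NAMES = FALSE)
  nt <- vapply(seq_along(coding), function(i) {
    if (strands[i] == "-") as.character(reverseComplement(DNAString(coding[i])))
    else coding[i]
  }, character(1))

  spacer_lens <- sample(40:80, length(nt) + 1L, replace = TRUE)
  pieces <- character(0)
  starts <- integer(length(nt)); stops <- integer(length(nt))
  pos <- 0L
  for (i in seq_along(nt)) {
    sp <- random_spacer(spacer_lens[i])
    pieces <- c(pieces, sp); pos <- pos + nchar(sp)
    starts[i] <- pos
    pieces <- c(pieces, nt[i]); pos <- pos + nchar(nt[i])
    stops[i] <- pos
  }
  pieces <- c(pieces, random_spacer(spacer_lens[length(spacer_lens)]))
  core <- paste(pieces, collapse = "")
  genes <- data.frame(start = starts, stop = stops, strand = strands,
                      protein = proteins, coding = coding, role = roles,
                      stringsAsFactors = FALSE)

  frozen <- NULL
  if (!is.null(dtr_length)) {
    if (dtr_length < 1L) anno_validation_error("dtr_length must be positive")
    dtr <- paste(rep("TAAA", ceiling(dtr_length / 4)), collapse = "")
    dtr <- substr(dtr, 1L, dtr_length)
    sequence <- paste0(dtr, core, dtr)
    if (dtr_length >= nchar(sequence) / 2)
      anno_validation_error("dtr_length too large for the assembled genome")
    genes$start <- genes$start + dtr_length
    genes$stop <- genes$stop + dtr_length
    n <- nchar(sequence)
    frozen <- list(c(0L, dtr_length), c(n - dtr_length, n))
  } else {
    sequence <- core
  }
  n <- nchar(sequence)

  offset <- 0L
  if (permute) {
    # rotate at an intergenic point well clear of gene boundaries (keeps the
    # stop guards attached to their genes)
    in_gene <- rep(FALSE, n)
    for (i in seq_len(nrow(genes)))
      in_gene[pmax(1L, genes$start[i] - 5L):pmin(n, genes$stop[i] + 6L)] <- TRUE
    free <- which(!in_gene)
    offset <- free[sample.int(length(free), 1L)] - 1L
    sequence <- rotate_seq(sequence, offset)
    e_incl <- (genes$stop - 1L - offset) %% n
    genes$start <- (genes$start - offset) %% n
    genes$stop <- e_incl + 1L
  }
  if (rc) {
    sequence <- as.character(reverseComplement(DNAString(sequence)))
    new_start <- n - genes$stop
    genes$stop <- n - genes$start
    genes$start <- new_start
    genes$strand <- ifelse(genes$strand == "+", "-", "+")
    if (!is.null(frozen)) frozen <- lapply(frozen, function(fr) c(n - fr[2], n - fr[1]))
  }
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  sequence <- scrub_incidental_orfs(sequence, genes, min_aa_len,
                                    GENETIC_CODE_11(), frozen = frozen)
  if (is.null(sequence)) return(NULL)   # caller retries with a derived seed
  # refresh coding sequences: the scrub may have recoded codons synonymously
  genes$coding <- vapply(seq_len(nrow(genes)), function(i)
    feature_nt(sequence, genes$start[i], genes$stop[i], genes$strand[i]),
    character(1))

  canonical <- sequence
  if (n_term > 0L) {
    tg <- genes[genes$role %in% c("terminase_large", "terminase_small"), ,
                drop = FALSE]
    upstream <- if (tg$strand[1] == "+") tg[which.min(tg$start), ]
                else tg[which.max(tg$start), ]
    ro <- reorient_genome(sequence, genes[, c("start", "stop", "strand")],
                          list(start = upstream$start, stop = upstream$stop,
                               strand = upstream$strand))
    canonical <- ro$sequence
  }

  name <- sprintf("synthetic phage seed%d", seed)
  list(
    fasta = paste0(paste(c(paste0(">", name), wrap_seq(sequence)), collapse = "\n"), "\n"),
    sequence = sequence,
    name = name,
    truth = list(genes = genes, canonical_sequence = canonical,
                 dtr_length = dtr_length, permutation_offset = offset,
                 reverse_complemented = rc, seed = seed)
  )
}

#' Generate the synthetic terminase protein database
#'
#' A FASTA of the two synthetic terminase marker proteins, each mutated at up
#' to 10% of positions (so detection exercises non-identical matching), with
#' headers carrying the "terminase large subunit" / "terminase small
#' subunit" keywords, plus `n_decoys` unrelated random proteins. All content
#' is synthetic -- no real database entries are included.
#'
#' @param seed Integer seed.
#' @param n_decoys Number of decoy proteins (default 8).
#' @param mutation_rate Fraction of positions substituted (default 0.05,
#'   capped at 0.10).
#' @param path Optional output path; when `NULL` the FASTA text is returned.
#' @return FASTA text (invisibly when written).
#' @export
make_terminase_db <- function(seed, n_decoys = 8L, mutation_rate = 0.05,
                              path = NULL) {
  mutation_rate <- min(mutation_rate, 0.10)
  with_seed(seed, {
    mutate <- function(p) {
      x <- strsplit(p, "")[[1]]
      k <- floor(mutation_rate * length(x))
      if (k > 0L) {
        at <- sample(2:length(x), k)
        x[at] <- vapply(x[at], function(a) sample(setdiff(.AA20, a), 1L), character(1))
      }
      paste(x, collapse = "")
    }
    lines <- c(
      ">TERL_SYN01 synthetic marker terminase large subunit",
      wrap_seq(mutate(.TERMINASE_LARGE_AA)),
      ">TERS_SYN01 synthetic marker terminase small subunit",
      wrap_seq(mutate(.TERMINASE_SMALL_AA))
    )
    for (i in seq_len(n_decoys)) {
      lines <- c(lines, sprintf(">DECOY_%02d synthetic decoy protein %d", i, i),
                 wrap_seq(random_protein(sample(100:250, 1L))))
    }
    txt <- paste0(paste(lines, collapse = "\n"), "\n")
    if (!is.null(path)) { cat(txt, file = path); return(invisible(txt)) }
    txt
  })
}

# -- mock homology results -----------------------------------------------------

mock_hit <- function(label, id = NULL, evalue = 1e-30, qlen = 200L, slen = qlen,
                     q_start = 1L, q_end = qlen, s_start = 1L, s_end = slen,
                     prob = NULL) {
  data.frame(subject_id = id %||% gsub("\\s+", "_", label),
             subject_description = label, subject_length = slen,
             evalue = evalue,
             score = prob %||% max(30, round(-log10(max(evalue, 1e-300)) * 2.2, 1)),
             q_start = q_start, q_end = q_end, s_start = s_start, s_end = s_end,
             aligned_query = NA_character_, aligned_subject = NA_character_,
             stringsAsFactors = FALSE)
}

# Evidence patterns keyed by decision-guide procedure. Each returns a named
# list (tool:database -> hit df) for a query of length `L`.
mock_pattern <- function(pattern, L = 200L) {
  many <- function(labels, evalue = 1e-30, ...)
    do.call(rbind, lapply(seq_along(labels), function(i)
      mock_hit(labels[i], evalue = evalue * 10^(i - 1), qlen = L, ...)))
  switch(pattern,
    "P1" = list(),
    "P2" = list("blastp:nr" = many(c("integrase", "tail fiber protein",
                                     "DNA polymerase", "holin"), 1e-20)),
    "P3" = list("blastp:nr" = many(rep("terminase large subunit", 4), 1e-20)),
    "P4" = list(
      "rpsblast:cdd" = many(rep("terminase large subunit (GpA)", 3), 1e-25,
                            id = "TerL_GpA"),
      "blastp:nr" = many(rep("terminase large subunit", 2), 1e-18)),
    "P4-DUF" = list(
      "rpsblast:cdd" = many(rep("Domain of unknown function (DUF9999)", 3),
                            1e-25, id = "DUF9999")),
    "P5" = list(
      "rpsblast:cdd" = {
        h <- many(rep("helix-turn-helix domain", 2), 1e-12, id = "HTH_XRE",
                  slen = 80L, s_start = 1L, s_end = 80L,
                  q_start = 41L, q_end = 120L)
        h
      }),
    "P6" = list(
      "rpsblast:cdd" = rbind(
        mock_hit("nuclease domain", id = "Nuc_dom", evalue = 1e-20, qlen = L,
                 slen = 95L, q_start = 10L, q_end = 100L, s_start = 1L, s_end = 91L),
        mock_hit("helix-turn-helix domain", id = "HTH_dom", evalue = 1e-15,
                 qlen = L, slen = 85L, q_start = 15L, q_end = 95L,
                 s_start = 1L, s_end = 81L))),
    "P6-disjoint" = list(
      "rpsblast:cdd" = rbind(
        mock_hit("nuclease domain", id = "Nuc_dom", evalue = 1e-20, qlen = L,
                 slen = 95L, q_start = 10L, q_end = 100L, s_start = 1L, s_end = 91L),
        mock_hit("helix-turn-helix domain", id = "HTH_dom", evalue = 1e-15,
                 qlen = L, slen = 85L, q_start = 110L, q_end = 190L,
                 s_start = 1L, s_end = 81L))),
    "P7" = list(
      "blastp:swissprot" = many(rep("major capsid protein", 3), 1e-40),
      "blastp:nr" = many(rep("major capsid protein", 3), 1e-35)),
    "P8" = list(
      "blastp:swissprot" = mock_hit("tape measure protein", evalue = 1e-20,
                                    qlen = L, slen = 400L, q_start = 1L,
                                    q_end = 96L, s_start = 300L, s_end = 395L)),
    "P9" = list(
      "blastp:swissprot" = many(rep("endolysin", 2), 5e-4)),
    "P10" = list(
      "blastp:internal" = mock_hit("MAS_0000001|GREEN|portal protein",
                                   id = "MAS_0000001", evalue = 1e-60, qlen = L),
      "blastp:swissprot" = many(rep("portal protein", 2), 1e-45)),
    "P11" = list(
      "hhsearch:pdb" = rbind(
        mock_hit("cell death-related nuclease", id = "2ABC_A", evalue = 1e-20,
                 qlen = L, prob = 97.5),
        mock_hit("cell death-related nuclease", id = "3XYZ_B", evalue = 1e-12,
                 qlen = L, prob = 85.0))),
    "P12" = list(
      "blastp:swissprot" = mock_hit("integrase", evalue = 1e-30, qlen = L),
      "rpsblast:cdd" = mock_hit("terminase large subunit", id = "TerL",
                                evalue = 1e-25, qlen = L)),
    anno_validation_error("unknown mock pattern '%s'", pattern)
  )
}

# Serialize hits as a minimal valid HH-suite .hhr report.
write_hhr <- function(hits, query = "query", match_columns = 200L) {
  head_block <- c(
    sprintf("Query         %s", query),
    sprintf("Match_columns %d", match_columns),
    "No_of_seqs    1 out of 1",
    "Neff          1.0",
    "Searched_HMMs 100",
    "Date          Sat Jan  1 00:00:00 2000",
    "Command       hhsearch synthetic",
    ""
  )
  hdr <- " No Hit                             Prob E-value P-value  Score    SS Cols Query HMM  Template HMM"
  rows <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    hitfield <- substr(paste(h$subject_id, h$subject_description), 1L, 30L)
    sprintf("%3d %-30s %5.1f %7.2g %7.2g %6.1f %5.1f %4d %4d-%-4d %4d-%-4d (%d)",
            i, hitfield, h$score, h$evalue, h$evalue / 10, h$score * 1.5, 0,
            h$q_end - h$q_start + 1L, h$q_start, h$q_end, h$s_start, h$s_end,
            h$subject_length)
  }, character(1))
  blocks <- unlist(lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    c(sprintf("No %d", i),
      sprintf(">%s %s", h$subject_id, h$subject_description),
      sprintf("Probab=%.2f  E-value=%.2g  Score=%.2f  Aligned_cols=%d",
              h$score, h$evalue, h$score * 1.5, h$q_end - h$q_start + 1L),
      "")
  }))
  paste0(paste(c(head_block, hdr, rows, "", blocks), collapse = "\n"), "\n")
}

#' Write mock homology-result files for decision-guide patterns
#'
#' For each `accession -> pattern` pair, writes syntactically valid result
#' files (BLAST tabular for blastp/rpsblast, `.hhr` for hhsearch) whose hits
#' realise that evidence pattern: one pattern exists for every procedure of
#' the decision guide (`"P1"` .. `"P12"`, plus variants `"P4-DUF"` and
#' `"P6-disjoint"`), so parsing the files and summarising the evidence fires
#' the intended procedure.
#'
#' @param dir Output directory (created if needed).
#' @param patterns Named character vector: `accession -> pattern id`.
#' @param query_length Query length the coordinates are scaled to.
#' @return Manifest data frame: `accession`, `tool`, `database`, `format`,
#'   `path` (zero rows for hit-less patterns).
#' @export
make_mock_results <- function(dir, patterns, query_length = 200L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (acc in names(patterns)) {
    pats <- mock_pattern(patterns[[acc]], L = query_length)
    for (key in names(pats)) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      tool <- parts[1]; database <- parts[2]
      hits <- pats[[key]]
      if (tool == "hhsearch") {
        path <- file.path(dir, sprintf("%s_%s_%s.hhr", sanitize_filename(acc),
                                       tool, database))
        cat(write_hhr(hits, query = acc, match_columns = query_length), file = path)
        fmt <- "hhr"
      } else {
        path <- file.path(dir, sprintf("%s_%s_%s.tsv", sanitize_filename(acc),
                                       tool, database))
        cat(write_blast_tabular(hits, query_id = acc), file = path)
        fmt <- "blast_tabular"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, tool = tool, database = database, format = fmt,
        path = path, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(accession = character(), tool = character(),
                      database = character(), format = character(),
                      path = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
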