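#' Ungapped Karlin-Altschul lambda for a match/mismatch scheme
#'
#' Solves sum_ij p_i p_j exp(lambda * s_ij) = 1 under uniform base
#' composition for a two-value nucleotide scoring scheme.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @return lambda (nats per score unit).
#' @export
karlin_lambda <- function(match = 1, mismatch = -2) {
  stopifnot(match > 0, mismatch < 0)
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

#' Default local-alignment scoring configuration
#'
#' Match +1 / mismatch -2 with the corresponding published ungapped
#' Karlin-Altschul K (0.621); lambda is solved from the scheme at run time.
#' Gap penalties apply to the Smith-Waterman search itself.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_ext gap penalties (positive).
#' @param K Karlin-Altschul K.
#' @return list of scoring parameters with `lambda` attached.
#' @export
alignment_scoring <- function(match = 1, mismatch = -2, gap_open = 5,
                              gap_ext = 2, K = 0.621) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext, K = K, lambda = karlin_lambda(match, mismatch))
}

#' Raw local-alignment score to bit score
#' @param raw raw Smith-Waterman score(s).
#' @param scoring an [alignment_scoring()] list.
#' @return bit score(s).
#' @export
bit_score <- function(raw, scoring = alignment_scoring()) {
  (scoring$lambda * raw - log(scoring$K)) / log(2)
}

.local_scores <- function(patterns, subject, scoring) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                                mismatch = scoring$mismatch)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = m,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext,
    scoreOnly = TRUE)
}

#' Align miRNA hairpins against repeat consensus sequences
#'
#' Local (Smith-Waterman) alignment of every miRNA against every repeat,
#' reporting alignment length and bit score; the desk-scale stand-in for a
#' precomputed homology hit table.
#'
#' @param mirna_seqs named character vector of hairpin sequences.
#' @param repeat_seqs named character vector of repeat consensi.
#' @param scoring an [alignment_scoring()] list.
#' @return data.frame `query_id`, `subject_id`, `align_len`, `raw_score`,
#'   `bit_score`.
#' @export
align_to_repeats <- function(mirna_seqs, repeat_seqs,
                             scoring = alignment_scoring()) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                                mismatch = scoring$mismatch)
  rows <- list()
  for (rn in names(repeat_seqs)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(mirna_seqs),
      Biostrings::DNAString(repeat_seqs[[rn]]),
      type = "local", substitutionMatrix = m,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
    raw <- Biostrings::score(aln)
    alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
    rows[[rn]] <- data.frame(query_id = names(mirna_seqs), subject_id = rn,
                             align_len = alen, raw_score = raw,
                             bit_score = bit_score(raw, scoring),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shuffle-null bit-score threshold for repeat-derived miRNA calling
#'
#' Each repeat sequence (only those with an original hit belong here) is
#' shuffled `n_shuffles` times by seeded mononucleotide permutation; all
#' miRNA sequences are locally aligned against every shuffle and the
#' maximum bit score observed is the threshold: a genuine repeat match
#' must beat everything composition alone can produce. Per-repeat seeds
#' are derived from `rng_seed`, so enlarging `n_shuffles` extends (never
#' replaces) the shuffle set and the threshold is non-decreasing in it.
#'
#' @param mirna_seqs named character vector of hairpin sequences.
#' @param repeat_seqs named character vector of repeat consensi.
#' @param n_shuffles shuffles per repeat (default 1000).
#' @param rng_seed integer seed.
#' @param scoring an [alignment_scoring()] list.
#' @param dinucleotide logical; preserve dinucleotide composition by a
#'   seeded Eulerian-style swap shuffle instead of plain permutation.
#' @return the threshold bit score, with attributes `max_raw` and `scoring`.
#' @export
shuffle_null_threshold <- function(mirna_seqs, repeat_seqs,
                                   n_shuffles = 1000L, rng_seed = 1L,
                                   scoring = alignment_scoring(),
                                   dinucleotide = FALSE) {
  if (!length(mirna_seqs) || !length(repeat_seqs))
    stop("empty miRNA or repeat set")
  max_raw <- -Inf
  for (ri in seq_along(repeat_seqs)) {
    set.seed(rng_seed + ri)
    for (s in seq_len(n_shuffles)) {
      shuf <- shuffle_sequence(repeat_seqs[[ri]], dinucleotide = dinucleotide)
      max_raw <- max(max_raw, .local_scores(mirna_seqs, shuf, scoring))
    }
  }
  structure(bit_score(max_raw, scoring), max_raw = max_raw,
            scoring = scoring)
}

#' Shuffle a sequence preserving mono- or dinucleotide composition
#'
#' Mononucleotide mode is a plain permutation. Dinucleotide mode performs
#' repeated swaps of two internal segments whose first and last letters
#' match, which leaves the dinucleotide multiset unchanged. Uses the
#' caller's RNG state (seed outside for reproducibility).
#'
#' @param seq sequence string.
#' @param dinucleotide preserve dinucleotide composition (default FALSE).
#' @return shuffled sequence string.
#' @export
shuffle_sequence <- function(seq, dinucleotide = FALSE) {
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  if (!dinucleotide) return(paste(sample(chars), collapse = ""))
  if (n < 6L) return(seq)
  for (it in seq_len(8L * n)) {
    cuts <- sort(sample(2:(n - 1L), 4L))
    i <- cuts[1L]; j <- cuts[2L]; k <- cuts[3L]; l <- cuts[4L]
    if (j >= k) next
    # swapping [i..j] and [k..l] preserves all junction dinucleotides when
    # the segments share first and last letters
    if (chars[i] != chars[k] || chars[j] != chars[l]) next
    chars <- c(chars[seq_len(i - 1L)], chars[k:l],
               if (j + 1L <= k - 1L) chars[(j + 1L):(k - 1L)],
               chars[i:j],
               if (l < n) chars[(l + 1L):n])
  }
  paste(chars, collapse = "")
}

#' Flag repeat-derived miRNA loci
#'
#' A locus is repeat-derived iff some hit against a repeat has alignment
#' length >= `min_len` and bit score strictly greater than the shuffle-null
#' threshold.
#'
#' @param hits data.frame from [align_to_repeats()] (or a read hit table
#'   with `query_id`, `align_len`, `bit_score`).
#' @param threshold shuffle-null bit-score threshold.
#' @param min_len minimum alignment length (default 30 nt).
#' @return character vector of flagged locus IDs.
#' @export
classify_repeat_derived <- function(hits, threshold, min_len = 30L) {
  sel <- hits$align_len >= min_len & hits$bit_score > threshold
  sort(unique(hits$query_id[sel]))
}

#' Find antisense miRNA couples
#'
#' Pairs of loci on the same contig and opposite strands where the overlap
#' covers at least `min_frac` of at least one of the two loci.
#'
#' @param loci data.frame `locus_id`, `seq_id`, `start`, `end`, `strand`.
#' @param min_frac minimum overlap fraction (default 0.95).
#' @return data.frame `locus_a`, `locus_b`, `overlap_fraction` (the larger
#'   of the two fractions), each unordered pair once.
#' @export
find_antisense_pairs <- function(loci, min_frac = 0.95) {
  loci <- loci[order(loci$locus_id), , drop = FALSE]
  out <- list()
  n <- nrow(loci)
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    a <- loci[i, ]; b <- loci[j, ]
    if (a$seq_id != b$seq_id || a$strand == b$strand) next
    ov <- interval_overlap(a$start, a$end, b$start, b$end)
    fa <- ov / (a$end - a$start); fb <- ov / (b$end - b$start)
    if (max(fa, fb) >= min_frac)
      out[[length(out) + 1L]] <- data.frame(
        locus_a = a$locus_id, locus_b = b$locus_id,
        overlap_fraction = max(fa, fb), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(locus_a = character(), locus_b = character(),
                      overlap_fraction = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Cross-mapping check for an antisense couple
#'
#' Sequencing errors in reads of a highly expressed miRNA can map to the
#' opposite strand and fabricate an antisense partner. For every pair of
#' equal-length reads from the two loci the positionwise mismatch count is
#' reported; pairs within `max_mismatch` are flagged as potential
#' cross-mapping artifacts together with both abundances.
#'
#' @param reads_a,reads_b read-stack data.frames (`seq`, `count`).
#' @param max_mismatch flag threshold (default 1).
#' @return data.frame `read_a`, `read_b`, `mismatches`, `count_a`,
#'   `count_b`, `flagged`, `abundance_ratio`; unequal-length pairs are
#'   skipped (their count is in attribute `skipped`).
#' @export
cross_mapping_check <- function(reads_a, reads_b, max_mismatch = 1L) {
  out <- list(); skipped <- 0L
  for (i in seq_len(nrow(reads_a))) for (j in seq_len(nrow(reads_b))) {
    sa <- reads_a$seq[i]; sb <- reads_b$seq[j]
    if (nchar(sa) != nchar(sb)) { skipped <- skipped + 1L; next }
    mm <- sum(strsplit(sa, "")[[1L]] != strsplit(sb, "")[[1L]])
    out[[length(out) + 1L]] <- data.frame(
      read_a = sa, read_b = sb, mismatches = mm,
      count_a = reads_a$count[i], count_b = reads_b$count[j],
      flagged = mm <= max_mismatch,
      abundance_ratio = reads_a$count[i] / reads_b$count[j],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read_a = character(), read_b = character(),
               mismatches = integer(), count_a = integer(),
               count_b = integer(), flagged = logical(),
               abundance_ratio = numeric(), stringsAsFactors = FALSE)
  attr(res, "skipped") <- skipped
  res
}

#' All introns of a gene-model set
#' @param gene_models named list of `gene_model`.
#' @return interval data.frame of introns.
#' @export
all_introns <- function(gene_models) {
  out <- lapply(gene_models, gene_introns)
  out <- out[vapply(out, nrow, 0L) > 0L]
  if (!length(out))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Detect miRtron candidates
#'
#' A locus is a miRtron candidate iff some intron overlaps it reciprocally
#' at >= `min_frac` of both lengths, on the same strand, and the locus
#' itself passed the duplex-evidence and hairpin-structure checks (the
#' splicing-derived hairpin still needs Dicer processing evidence).
#'
#' @param loci data.frame `locus_id`, `seq_id`, `start`, `end`, `strand`.
#' @param gene_models named list of `gene_model`.
#' @param passed named logical per locus: passed duplex + structure checks.
#' @param min_frac reciprocal overlap fraction (default 0.9).
#' @return character vector of flagged locus IDs.
#' @export
detect_mirtrons <- function(loci, gene_models, passed, min_frac = 0.9) {
  introns <- all_introns(gene_models)
  flagged <- character()
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    if (!isTRUE(passed[[lc$locus_id]])) next
    sel <- introns$seq_id == lc$seq_id & introns$strand == lc$strand
    if (!any(sel)) next
    itr <- introns[sel, , drop = FALSE]
    ov <- interval_overlap(itr$start, itr$end, lc$start, lc$end)
    ok <- ov / (lc$end - lc$start) >= min_frac &
      ov / (itr$end - itr$start) >= min_frac
    if (any(ok)) flagged <- c(flagged, lc$locus_id)
  }
  sort(unique(flagged))
}

#' Flag duplicated orthogroups and tandem arrangements
#'
#' An orthogroup is duplicated iff some species contributes two or more
#' member loci at distinct (non-overlapping) genomic positions -- two
#' strands of one interval, as in an antisense couple, are one locus
#' region, not paralogous copies. It is tandem iff such a pair lies on the
#' same contig within `tandem_window` (start-to-start, strand-agnostic).
#'
#' @param clusters output of [greedy_cluster()].
#' @param loci data.frame `locus_id`, `seq_id`, `start`, `end`, `species`.
#' @param tandem_window distance in bp (default 100 kb).
#' @return data.frame `og_id`, `duplicated`, `tandem`,
#'   `duplicated_species` (comma-joined).
#' @export
find_duplications <- function(clusters, loci, tandem_window = 1e5) {
  rownames(loci) <- loci$locus_id
  do.call(rbind, lapply(clusters, function(cl) {
    mem <- loci[cl$members, , drop = FALSE]
    dup_sp <- character(); tandem <- FALSE
    for (sp in unique(mem$species)) {
      d <- mem[mem$species == sp, , drop = FALSE]
      if (nrow(d) < 2L) next
      for (i in seq_len(nrow(d) - 1L)) for (j in (i + 1L):nrow(d)) {
        distinct <- d$seq_id[i] != d$seq_id[j] ||
          interval_overlap(d$start[i], d$end[i], d$start[j], d$end[j]) == 0L
        if (!distinct) next
        dup_sp <- union(dup_sp, sp)
        if (d$seq_id[i] == d$seq_id[j] &&
            abs(d$start[i] - d$start[j]) <= tandem_window)
          tandem <- TRUE
      }
    }
    data.frame(og_id = cl$og_id, duplicated = length(dup_sp) > 0L,
               tandem = tandem,
               duplicated_species = paste(sort(dup_sp), collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

.gene_feature_intervals <- function(gene) {
  ex <- gene$exons; cds <- gene$cds
  strand <- gene$interval$strand
  clip <- function(iv, lo, hi) {
    s <- pmax(iv$start, lo); e <- pmin(iv$end, hi)
    keep <- s < e
    if (!any(keep)) return(NULL)
    gintervals(iv$seq_id[keep], s[keep], e[keep], iv$strand[keep])
  }
  if (!nrow(cds)) {
    return(list(utr5 = NULL, utr3 = NULL, introns = gene_introns(gene)))
  }
  cs <- min(cds$start); ce <- max(cds$end)
  left <- clip(ex, gene$interval$start, cs)
  right <- clip(ex, ce, gene$interval$end)
  if (strand == "+") list(utr5 = left, utr3 = right, introns = gene_introns(gene))
  else list(utr5 = right, utr3 = left, introns = gene_introns(gene))
}

#' Genomic context of a locus
#'
#' Majority-overlap classification against gene annotation, strand-agnostic
#' (antisense relationships are a separate flag): `utr3`, `utr5`, `intron`
#' or `intergenic`, with ties broken by the precedence utr3 > utr5 > intron
#' (the rarer annotation wins). A locus overlapping a gene only in coding
#' exons is binned as genic/intronic.
#'
#' @param locus single-row interval data.frame.
#' @param gene_models named list of `gene_model`.
#' @return one of "utr3", "utr5", "intron", "intergenic".
#' @export
genomic_context <- function(locus, gene_models) {
  ov_sum <- function(iv) {
    if (is.null(iv) || !nrow(iv)) return(0L)
    sel <- iv$seq_id == locus$seq_id
    sum(interval_overlap(iv$start[sel], iv$end[sel], locus$start, locus$end))
  }
  tot <- c(utr3 = 0L, utr5 = 0L, intron = 0L)
  gene_ov <- 0L
  for (g in gene_models) {
    if (g$interval$seq_id != locus$seq_id) next
    gene_ov <- gene_ov + interval_overlap(g$interval$start, g$interval$end,
                                          locus$start, locus$end)
    f <- .gene_feature_intervals(g)
    tot["utr3"] <- tot["utr3"] + ov_sum(f$utr3)
    tot["utr5"] <- tot["utr5"] + ov_sum(f$utr5)
    tot["intron"] <- tot["intron"] + ov_sum(f$introns)
  }
  if (gene_ov == 0L) return("intergenic")
  if (all(tot == 0L)) return("intron")
  names(tot)[which.max(tot)]   # order utr3, utr5, intron encodes precedence
}
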