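#' Merge candidate locus intervals from two prediction tools
#'
#' Overlapping or book-ended intervals on the same contig and strand are
#' merged into maximal intervals (bedtools-merge semantics), the usual first
#' step when combining miRCat-style and miRDeep2-style predictions.
#'
#' @param set_a,set_b interval data.frames ([gintervals()]); `set_b` may be
#'   omitted to merge a single set.
#' @return merged interval data.frame sorted by (contig, start).
#' @export
merge_candidates <- function(set_a, set_b = NULL) {
  df <- if (is.null(set_b)) set_a else
    rbind(set_a[c("seq_id", "start", "end", "strand")],
          set_b[c("seq_id", "start", "end", "strand")])
  key <- paste(df$seq_id, df$strand, sep = "\r")
  out <- lapply(split(df, key), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    gintervals(d$seq_id[1L], IRanges::start(ir) - 1L, IRanges::end(ir),
               d$strand[1L])
  })
  out <- do.call(rbind, out)
  out <- out[order(out$seq_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.PAIRABLE <- c(AT = TRUE, TA = TRUE, GC = TRUE, CG = TRUE, GT = TRUE, TG = TRUE)

.can_pair <- function(a, b) isTRUE(.PAIRABLE[paste0(a, b)])

#' Fold a hairpin candidate into a secondary structure
#'
#' Returns a deterministic fold as balanced dot-bracket plus a score.
#' Engines: "rnafold" calls the ViennaRNA `RNAfold` binary (minimum free
#' energy, score in kcal/mol); "nussinov" is a built-in maximum
#' base-pairing dynamic programme (Watson-Crick + GU wobble pairs, minimum
#' loop 3 nt, score = minus the pair count). The default "auto" uses the
#' thermodynamic engine when the binary is on PATH and the built-in
#' fallback otherwise; the contract is only that the structure is a valid,
#' deterministic fold of the sequence.
#'
#' @param sequence nucleotide string (>= 40 nt for hairpin candidates;
#'   shorter sequences fold fine, the length gate belongs to curation).
#' @param engine "auto" (default), "nussinov" or "rnafold".
#' @param min_loop minimum hairpin loop size (unpaired nt), default 3.
#' @param no_lonely_pairs drop isolated base pairs (helices of length 1)
#'   from the returned structure, as thermodynamic folders do by default;
#'   isolated pairs are essentially unstable and inflate spurious pairing
#'   in random sequences.
#' @return list with `structure` (dot-bracket) and `energy`.
#' @export
fold_hairpin <- function(sequence, engine = c("auto", "nussinov", "rnafold"),
                         min_loop = 3L, no_lonely_pairs = TRUE) {
  engine <- match.arg(engine)
  sequence <- chartr("U", "T", toupper(sequence))
  if (grepl("[^ACGTN]", sequence)) stop("invalid characters in sequence")
  if (engine == "auto")
    engine <- if (Sys.which("RNAfold") != "") "rnafold" else "nussinov"
  if (engine == "rnafold") return(.fold_rnafold(sequence))
  s <- strsplit(sequence, "")[[1L]]
  n <- length(s)
  if (n < 2L) return(list(structure = strrep(".", n), energy = 0))
  # M[i,j] = max pairs in s[i..j]; banded recursion over subsequence length
  M <- matrix(0L, n, n)
  for (len in (min_loop + 2L):n) {
    if (len > n) break
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      best <- M[i, j - 1L]                      # j unpaired
      for (k in i:(j - min_loop - 1L)) {        # j paired with k
        if (.can_pair(s[k], s[j])) {
          v <- 1L + (if (k > i) M[i, k - 1L] else 0L) +
            (if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L)
          if (v > best) best <- v
        }
      }
      M[i, j] <- best
    }
  }
  db <- rep(".", n)
  # deterministic traceback: prefer j unpaired, else smallest pairing k
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (i >= j || j - i < min_loop + 1L || M[i, j] == 0L) next
    if (M[i, j] == M[i, j - 1L]) { stack[[length(stack) + 1L]] <- c(i, j - 1L); next }
    for (k in i:(j - min_loop - 1L)) {
      if (!.can_pair(s[k], s[j])) next
      v <- 1L + (if (k > i) M[i, k - 1L] else 0L) +
        (if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L)
      if (v == M[i, j]) {
        db[k] <- "("; db[j] <- ")"
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        break
      }
    }
  }
  if (no_lonely_pairs) db <- .drop_lonely_pairs(db)
  list(structure = paste(db, collapse = ""),
       energy = -sum(db == "("))
}

# iteratively remove base pairs with no stacked neighbour on either side
.drop_lonely_pairs <- function(db) {
  repeat {
    pt <- pair_table(paste(db, collapse = ""))
    n <- length(db)
    lonely <- integer()
    for (i in which(!is.na(pt))) {
      j <- pt[i]
      if (i > j) next
      inner <- i + 1L <= n && !is.na(pt[i + 1L]) && pt[i + 1L] == j - 1L
      outer <- i - 1L >= 1L && !is.na(pt[i - 1L]) && pt[i - 1L] == j + 1L
      if (!inner && !outer) lonely <- c(lonely, i, j)
    }
    if (!length(lonely)) return(db)
    db[lonely] <- "."
  }
}

.fold_rnafold <- function(sequence) {
  if (Sys.which("RNAfold") == "") stop("RNAfold binary not found on PATH")
  out <- system2("RNAfold", "--noPS", input = sequence, stdout = TRUE)
  m <- regmatches(out[2L], regexec("^([.()]+) \\(\\s*(-?[0-9.]+)\\)", out[2L]))[[1L]]
  list(structure = m[2L], energy = as.numeric(m[3L]))
}

#' Pairing partner table of a dot-bracket structure
#' @param structure dot-bracket string.
#' @return integer vector, 1-based partner index per position (NA unpaired).
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1L]]
  pt <- rep(NA_integer_, length(ch))
  stack <- integer()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket")
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket")
  pt
}

#' Does a fold look like a canonical miRNA hairpin?
#'
#' Criteria (each threshold configurable): (a) exactly one terminal loop
#' (no multiloop), (b) at least `min_arm_pairing` of annotated arm bases
#' paired with the opposite arm -- the miRNA/miRNA* duplex the arms are
#' annotated for, (c) the two arms lie on opposite sides of the terminal
#' loop, (d) no arm base pairs within its own arm. These operationalise
#' the qualitative "miRNA-like hairpin" requirement used in small-RNA
#' locus curation.
#'
#' @param fold list from [fold_hairpin()].
#' @param arm_5p,arm_3p integer pairs `c(start, end)`, 0-based half-open
#'   offsets of the arms on the hairpin.
#' @param min_arm_pairing minimum fraction of arm bases paired (default 0.6).
#' @return list `ok` (logical) and `reason` (first failed criterion, or "ok").
#' @export
is_mirna_like <- function(fold, arm_5p, arm_3p, min_arm_pairing = 0.6) {
  db <- fold$structure
  n <- nchar(db)
  if (arm_5p[2L] > n || arm_3p[2L] > n || arm_5p[1L] < 0L || arm_3p[1L] < 0L)
    stop("arm coordinates outside hairpin")
  n_loops <- length(gregexpr("\\(\\.*\\)", db)[[1L]])
  if (attr(gregexpr("\\(\\.*\\)", db)[[1L]], "match.length")[1L] == -1L)
    n_loops <- 0L
  if (n_loops != 1L)
    return(list(ok = FALSE, reason = if (n_loops > 1L) "multiloop" else "no stem"))
  pt <- pair_table(db)
  i5 <- (arm_5p[1L] + 1L):arm_5p[2L]
  i3 <- (arm_3p[1L] + 1L):arm_3p[2L]
  frac <- (sum(pt[i5] %in% i3, na.rm = TRUE) +
             sum(pt[i3] %in% i5, na.rm = TRUE)) / (length(i5) + length(i3))
  if (frac < min_arm_pairing)
    return(list(ok = FALSE, reason = "pairing fraction"))
  # terminal loop position = span between the innermost pair
  loop <- regexpr("\\(\\.*\\)", db)
  loop_mid <- loop + attr(loop, "match.length") / 2
  if (!(max(i5) < loop_mid && min(i3) > loop_mid))
    return(list(ok = FALSE, reason = "arms not flanking loop"))
  self5 <- any(pt[i5] %in% i5, na.rm = TRUE)
  self3 <- any(pt[i3] %in% i3, na.rm = TRUE)
  if (self5 || self3)
    return(list(ok = FALSE, reason = "intra-arm pairing"))
  list(ok = TRUE, reason = "ok", arm_pairing = frac)
}

#' Arm-duplex read-coverage evidence (Drosha/Dicer processing filter)
#'
#' A read is assigned to an arm when at least `min_span_frac` of its span
#' lies within the arm extended by `slack` nt on each side. The locus passes
#' when both arms carry at least one read and total coverage is at least
#' `min_total` reads.
#'
#' @param reads data.frame with columns `seq`, `count`, `offset` (0-based
#'   offset of the read on the hairpin).
#' @param arm_5p,arm_3p arm offsets `c(start, end)`, 0-based half-open.
#' @param min_total minimum total read count (default 10).
#' @param min_span_frac fraction of the read span required inside the
#'   (slack-extended) arm (default 0.8).
#' @param slack arm extension in nt (default 3).
#' @return list `reads_5p`, `reads_3p`, `total_reads`, `pass`.
#' @export
duplex_evidence <- function(reads, arm_5p, arm_3p, min_total = 10L,
                            min_span_frac = 0.8, slack = 3L) {
  if (!nrow(reads))
    return(list(reads_5p = 0L, reads_3p = 0L, total_reads = 0L, pass = FALSE))
  rs <- reads$offset
  re <- reads$offset + nchar(reads$seq)
  assign_to <- function(arm) {
    ov <- interval_overlap(rs, re, arm[1L] - slack, arm[2L] + slack)
    ov / (re - rs) >= min_span_frac
  }
  in5 <- assign_to(arm_5p); in3 <- assign_to(arm_3p)
  # a read engulfing both arms is ambiguous; keep it only in the arm holding
  # the larger share of its span
  both <- in5 & in3
  if (any(both)) {
    o5 <- interval_overlap(rs[both], re[both], arm_5p[1L], arm_5p[2L])
    o3 <- interval_overlap(rs[both], re[both], arm_3p[1L], arm_3p[2L])
    in5[both] <- o5 >= o3
    in3[both] <- o3 > o5
  }
  r5 <- sum(reads$count[in5]); r3 <- sum(reads$count[in3])
  tot <- sum(reads$count)
  list(reads_5p = as.integer(r5), reads_3p = as.integer(r3),
       total_reads = as.integer(tot),
       pass = r5 >= 1L && r3 >= 1L && tot >= min_total)
}

#' Count mismatches of every ungapped placement of a probe on a sequence
#' @keywords internal
.best_ungapped_mismatch <- function(hairpin, probe) {
  n <- nchar(hairpin); m <- nchar(probe)
  if (m > n) return(Inf)
  h <- strsplit(hairpin, "")[[1L]]
  p <- strsplit(probe, "")[[1L]]
  best <- Inf
  for (i in 0:(n - m)) {
    mm <- sum(h[(i + 1L):(i + m)] != p)
    if (mm < best) best <- mm
    if (best == 0L) break
  }
  best
}

#' Classify a curated locus as known or novel
#'
#' Known iff some database mature sequence aligns ungapped within the
#' hairpin (sense strand) with at most one mismatch; otherwise novel.
#'
#' @param hairpin_seq hairpin sequence.
#' @param mature_db named character vector of mature sequences (18-26 nt).
#' @param max_mismatch maximum mismatches (default 1).
#' @return "known" or "novel".
#' @export
classify_known <- function(hairpin_seq, mature_db, max_mismatch = 1L) {
  hairpin_seq <- chartr("U", "T", toupper(hairpin_seq))
  for (m in mature_db) {
    m <- chartr("U", "T", toupper(m))
    if (.best_ungapped_mismatch(hairpin_seq, m) <= max_mismatch)
      return("known")
  }
  "novel"
}

#' Rescue low-coverage loci with processing evidence and homology
#'
#' A locus rejected only for total coverage can be rescued when it still
#' shows Drosha/Dicer processing (>= 1 read on each arm) and is homologous
#' to an accepted locus elsewhere (orthogroup membership).
#'
#' @param rejected data.frame with columns `locus_id`, `reads_5p`, `reads_3p`.
#' @param homolog_accepted named logical: does each rejected locus share an
#'   orthogroup with an accepted locus?
#' @return character vector of rescued locus IDs.
#' @export
rescue_low_coverage <- function(rejected, homolog_accepted) {
  if (!nrow(rejected)) return(character())
  ok <- rejected$reads_5p >= 1L & rejected$reads_3p >= 1L &
    as.logical(homolog_accepted[rejected$locus_id])
  ok[is.na(ok)] <- FALSE
  rejected$locus_id[ok]
}

#' Run the full curation filter stack on one candidate locus
#'
#' Order-independent combination of the structure and duplex filters plus
#' known/novel classification; returns the locus status and per-filter
#' diagnostics so a rejection can be replayed.
#'
#' @param hairpin_seq hairpin sequence.
#' @param arm_5p,arm_3p arm offsets (0-based half-open) on the hairpin.
#' @param reads read-stack data.frame (`seq`, `count`, `offset`).
#' @param mature_db optional mature database for known/novel classification.
#' @param engine folding engine, passed to [fold_hairpin()].
#' @inheritParams duplex_evidence
#' @inheritParams is_mirna_like
#' @return list with `status` ("known"/"novel"/"rejected"), `structure_ok`,
#'   `duplex`, `fold`, `reason`.
#' @export
curate_locus <- function(hairpin_seq, arm_5p, arm_3p, reads,
                         mature_db = NULL, min_total = 10L,
                         min_arm_pairing = 0.6,
                         engine = c("auto", "nussinov", "rnafold")) {
  fold <- fold_hairpin(hairpin_seq, engine = engine)
  st <- is_mirna_like(fold, arm_5p, arm_3p, min_arm_pairing = min_arm_pairing)
  dx <- duplex_evidence(reads, arm_5p, arm_3p, min_total = min_total)
  if (!st$ok || !dx$pass) {
    return(list(status = "rejected", structure_ok = st$ok, duplex = dx,
                fold = fold,
                reason = if (!st$ok) st$reason else "duplex evidence"))
  }
  status <- if (is.null(mature_db)) "novel"
  else classify_known(hairpin_seq, mature_db)
  list(status = status, structure_ok = TRUE, duplex = dx, fold = fold,
       reason = "ok")
}
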