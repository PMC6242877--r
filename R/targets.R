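#' Extract the seed of a mature miRNA
#'
#' The 7-nt seed is mature positions 2-8 (1-based); the 6-nt seed is
#' positions 2-7.
#'
#' @param mature_sequence mature miRNA sequence (>= 8 nt).
#' @return list `seed7`, `seed6`.
#' @export
extract_seed <- function(mature_sequence) {
  mature_sequence <- chartr("U", "T", toupper(mature_sequence))
  if (nchar(mature_sequence) < 8L)
    stop("mature sequence shorter than 8 nt")
  list(seed7 = substr(mature_sequence, 2L, 8L),
       seed6 = substr(mature_sequence, 2L, 7L))
}

#' Group matures into seed families
#'
#' Two matures belong to one family iff they share the 7-nt seed exactly.
#'
#' @param matures named character vector of mature sequences.
#' @param species_of optional named character: mature ID -> species.
#' @return list per family: `seed7`, `members`, `species_span`.
#' @export
seed_families <- function(matures, species_of = NULL) {
  seeds <- vapply(matures, function(m) extract_seed(m)$seed7, "")
  fams <- split(names(matures), seeds)
  lapply(names(fams), function(s) {
    mem <- fams[[s]]
    list(seed7 = s, members = mem,
         species_span = if (is.null(species_of)) character()
         else sort(unique(stats::na.omit(species_of[mem]))))
  })
}

#' Seed x species presence matrix for turnover analysis
#' @param families list from [seed_families()].
#' @param species ordered species vector.
#' @return 0/1 integer matrix, rows = seeds.
#' @export
seed_presence_matrix <- function(families, species) {
  m <- matrix(0L, length(families), length(species),
              dimnames = list(vapply(families, `[[`, "", "seed7"), species))
  for (i in seq_along(families))
    m[i, intersect(families[[i]]$species_span, species)] <- 1L
  m
}

#' Build 3'UTR windows downstream of gene models
#'
#' Strand-aware 5-kb window starting immediately after the 3'-most
#' annotated exon, trimmed back to the start of the first overlapping
#' coding sequence of any other gene, clipped at the contig end; genes
#' whose final window is shorter than `min_len` are dropped.
#'
#' @param gene_models named list of `gene_model`.
#' @param contig_lengths named integer vector of contig lengths.
#' @param window window size in nt (default 5000).
#' @param min_len minimum retained window length (default 500).
#' @return named list of single-row interval data.frames (one per kept gene).
#' @export
build_utr_windows <- function(gene_models, contig_lengths, window = 5000L,
                              min_len = 500L) {
  cds_parts <- Filter(Negate(is.null), lapply(gene_models, function(g) {
    if (!nrow(g$cds)) return(NULL)
    cbind(g$cds, gene_id = g$gene_id)
  }))
  cds_all <- if (length(cds_parts)) do.call(rbind, cds_parts) else NULL
  out <- list()
  for (g in gene_models) {
    iv <- g$interval
    clen <- contig_lengths[[iv$seq_id]]
    if (is.null(clen)) stop("no contig length for ", iv$seq_id)
    other <- !is.null(cds_all) && nrow(cds_all) > 0
    oc <- if (other) cds_all[cds_all$gene_id != g$gene_id &
                               cds_all$seq_id == iv$seq_id, , drop = FALSE]
    else NULL
    if (iv$strand == "+") {
      ws <- max(g$exons$end)
      we <- min(ws + window, clen)
      if (!is.null(oc) && nrow(oc)) {
        hit <- oc$start < we & oc$end > ws
        if (any(hit)) we <- max(ws, min(pmax(oc$start[hit], ws)))
      }
    } else {
      we <- min(g$exons$start)
      ws <- max(we - window, 0L)
      if (!is.null(oc) && nrow(oc)) {
        hit <- oc$start < we & oc$end > ws
        if (any(hit)) ws <- min(we, max(pmin(oc$end[hit], we)))
      }
    }
    if (we - ws >= min_len)
      out[[g$gene_id]] <- gintervals(iv$seq_id, ws, we, iv$strand)
  }
  out
}

#' Find canonical seed-match target sites in a 3'UTR
#'
#' Scans for the reverse complement of the seed. Site taxonomy follows the
#' canonical definitions: 8mer = full 7-nt match followed by A (8 nt);
#' 7mer-m8 = full 7-nt match not followed by A; 7mer-A1 = 6-nt match to
#' seed positions 2-7 followed by A, excluding positions already reported
#' as 8mers. Overlapping occurrences are all reported; offsets are 0-based.
#'
#' @param utr_sequence UTR sequence over ACGT.
#' @param seed7 7-nt seed (mature positions 2-8).
#' @return data.frame `utr_offset`, `site_type`, `site_len`, `seed7`.
#' @export
find_sites <- function(utr_sequence, seed7) {
  stopifnot(nchar(seed7) == 7L)
  utr_sequence <- chartr("U", "T", toupper(utr_sequence))
  seed7 <- chartr("U", "T", toupper(seed7))
  m7 <- revcomp(seed7)              # m8..m2 match
  m6 <- substr(m7, 2L, 7L)          # m7..m2 match (seed 2-7)
  n <- nchar(utr_sequence)
  rows <- list()
  add <- function(off, type, len)
    rows[[length(rows) + 1L]] <<- data.frame(
      utr_offset = off, site_type = type, site_len = len, seed7 = seed7,
      stringsAsFactors = FALSE)
  if (n >= 7L) for (i in 0:(n - 7L)) {
    if (substr(utr_sequence, i + 1L, i + 7L) == m7) {
      if (i + 8L <= n && substr(utr_sequence, i + 8L, i + 8L) == "A")
        add(i, "8mer", 8L)
      else add(i, "7mer-m8", 7L)
    }
  }
  if (n >= 7L) for (i in 0:(n - 7L)) {
    if (substr(utr_sequence, i + 1L, i + 6L) == m6 &&
        substr(utr_sequence, i + 7L, i + 7L) == "A" &&
        (i == 0L || substr(utr_sequence, i, i) != substr(m7, 1L, 1L)))
      add(i, "7mer-A1", 7L)
  }
  if (!length(rows))
    return(data.frame(utr_offset = integer(), site_type = character(),
                      site_len = integer(), seed7 = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$utr_offset, out$site_type), , drop = FALSE]
}

#' Filter sites on outgroup support and context score
#'
#' Sites are grouped by (gene, homologous alignment position, seed); a
#' group is kept iff the outgroup species carries it and at least
#' `min_supporting_species` others do too. When context scores are present
#' each retained occurrence must score at or below `min_context`; without
#' scores the context filter is skipped with a notice.
#'
#' @param sites data.frame `gene_id`, `species`, `msa_start`, `seed7`
#'   (+ optional `context_score`).
#' @param min_context context score ceiling (default -0.1).
#' @param outgroup outgroup species (default "rabbit").
#' @param min_supporting_species minimum non-outgroup species (default 1).
#' @return filtered data.frame.
#' @export
filter_sites <- function(sites, min_context = -0.1, outgroup = "rabbit",
                         min_supporting_species = 1L) {
  if (!nrow(sites)) return(sites)
  has_scores <- "context_score" %in% names(sites) &&
    any(!is.na(sites$context_score))
  if (has_scores) {
    keep <- is.na(sites$context_score) | sites$context_score <= min_context
    sites <- sites[keep, , drop = FALSE]
  } else {
    message("no context scores provided; context filter skipped")
  }
  key <- paste(sites$gene_id, sites$msa_start, sites$seed7, sep = "\r")
  ok <- vapply(split(seq_len(nrow(sites)), key), function(idx) {
    sp <- unique(sites$species[idx])
    outgroup %in% sp && length(setdiff(sp, outgroup)) >= min_supporting_species
  }, TRUE)
  sites[ok[key], , drop = FALSE]
}

.gap_maps <- function(aln_row) {
  ch <- strsplit(aln_row, "")[[1L]]
  nongap <- which(ch != "-")
  list(cols_of = nongap,                       # ungapped index -> column
       n_ungapped = length(nongap))
}

#' Lift an ungapped interval through a multiple alignment
#'
#' Maps a 0-based half-open interval on one species' ungapped sequence to
#' alignment columns, and projects those columns back onto every other
#' species' ungapped coordinates; projections that cross gaps are flagged.
#'
#' @param msa named character vector of equal-length aligned sequences.
#' @param species species (row) carrying the interval.
#' @param ungapped_interval integer `c(start, end)`, 0-based half-open.
#' @return list `msa_columns` (0-based half-open column span) and
#'   `projections` (data.frame `species`, `start`, `end`, `has_gaps`).
#' @export
lift_through_msa <- function(msa, species, ungapped_interval) {
  if (!species %in% names(msa)) stop("species not in alignment: ", species)
  gm <- .gap_maps(msa[[species]])
  s <- ungapped_interval[1L]; e <- ungapped_interval[2L]
  if (s < 0L || e > gm$n_ungapped || s >= e)
    stop("interval out of range for ", species)
  cols <- c(gm$cols_of[s + 1L] - 1L, gm$cols_of[e])   # 0-based half-open
  proj <- do.call(rbind, lapply(names(msa), function(sp) {
    ch <- strsplit(msa[[sp]], "")[[1L]]
    win <- ch[(cols[1L] + 1L):cols[2L]]
    before <- sum(ch[seq_len(cols[1L])] != "-")
    n_nongap <- sum(win != "-")
    data.frame(species = sp, start = before, end = before + n_nongap,
               has_gaps = any(win == "-"), stringsAsFactors = FALSE)
  }))
  list(msa_columns = cols, projections = proj)
}

#' Pairwise similarity of a target site across two species
#'
#' Computed over the six alignment columns of the seed 2-7 match:
#' similarity = identical non-gap column pairs / 6 (a gap counts as
#' non-identical).
#'
#' @param msa_site_block named character vector of aligned site blocks
#'   (site +/- 2 nt columns).
#' @param species_a,species_b species to compare.
#' @param seed_cols 1-based indices of the six seed-match columns within
#'   the block.
#' @return similarity fraction in [0, 1].
#' @export
pairwise_site_similarity <- function(msa_site_block, species_a, species_b,
                                     seed_cols) {
  stopifnot(length(seed_cols) == 6L)
  for (sp in c(species_a, species_b))
    if (!sp %in% names(msa_site_block)) stop("species absent from block: ", sp)
  a <- strsplit(msa_site_block[[species_a]], "")[[1L]][seed_cols]
  b <- strsplit(msa_site_block[[species_b]], "")[[1L]][seed_cols]
  sum(a == b & a != "-" & b != "-") / 6
}

#' Binned conservation profile around target sites
#'
#' Each site window (the 7-nt site plus `flank` nt on both sides) is tiled
#' into consecutive `bin`-nt bins with the site occupying the central bin.
#' Per bin the statistic is the median across sites of per-site mean scores
#' (positions without track data are dropped from the mean; a site whose
#' bin is entirely missing is dropped from that bin's median), with a
#' seeded bootstrap percentile 95% CI of the median. `stat = "pooled"`
#' instead pools per-position scores per bin and takes their median.
#'
#' @param sites data.frame `seq_id`, `pos` (0-based site start on the
#'   score-track coordinate system).
#' @param track a `score_track`.
#' @param flank flank length in nt (default 49).
#' @param bin bin width in nt (default 7).
#' @param bootstrap_B bootstrap replicates (default 1000).
#' @param rng_seed seed for the bootstrap.
#' @param stat "site_mean" (default) or "pooled".
#' @return data.frame `bin_offset` (bin start relative to site start),
#'   `median`, `ci_low`, `ci_high`, `n_sites`.
#' @export
conservation_profile <- function(sites, track, flank = 49L, bin = 7L,
                                 bootstrap_B = 1000L, rng_seed = 1L,
                                 stat = c("site_mean", "pooled")) {
  stat <- match.arg(stat)
  if (!nrow(sites)) stop("no sites supplied")
  if ((2L * flank + bin) %% bin != 0L)
    stop("window (2*flank + bin) must be a multiple of the bin width")
  n_bins <- (2L * flank + bin) %/% bin
  offs <- seq(-flank, by = bin, length.out = n_bins)
  # per-site per-bin means
  bm <- matrix(NA_real_, nrow(sites), n_bins)
  for (i in seq_len(nrow(sites))) {
    w0 <- sites$pos[i] - flank
    sc <- score_at(track, sites$seq_id[i], w0:(w0 + n_bins * bin - 1L))
    for (b in seq_len(n_bins)) {
      v <- sc[((b - 1L) * bin + 1L):(b * bin)]
      if (any(!is.na(v))) bm[i, b] <- mean(v, na.rm = TRUE)
    }
  }
  set.seed(rng_seed)
  med <- lo <- hi <- ns <- numeric(n_bins)
  if (stat == "site_mean") {
    boot_idx <- matrix(sample.int(nrow(sites), nrow(sites) * bootstrap_B,
                                  replace = TRUE), nrow(sites))
    for (b in seq_len(n_bins)) {
      v <- bm[, b]
      ns[b] <- sum(!is.na(v))
      med[b] <- stats::median(v, na.rm = TRUE)
      reps <- apply(boot_idx, 2L, function(ix)
        stats::median(v[ix], na.rm = TRUE))
      ci <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      lo[b] <- ci[1L]; hi[b] <- ci[2L]
    }
  } else {
    for (b in seq_len(n_bins)) {
      pool <- unlist(lapply(seq_len(nrow(sites)), function(i) {
        w0 <- sites$pos[i] - flank + (b - 1L) * bin
        score_at(track, sites$seq_id[i], w0:(w0 + bin - 1L))
      }))
      pool <- pool[!is.na(pool)]
      ns[b] <- length(pool)
      med[b] <- stats::median(pool)
      reps <- vapply(seq_len(bootstrap_B), function(r)
        stats::median(sample(pool, replace = TRUE)), 0)
      ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
      lo[b] <- ci[1L]; hi[b] <- ci[2L]
    }
  }
  data.frame(bin_offset = offs, median = med, ci_low = lo, ci_high = hi,
             n_sites = ns)
}
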