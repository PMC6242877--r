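#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. Defaults describe
#' the study conditions the generators emulate: a handful of mammalian
#' species profiled at moderate small-RNA depth, Dollo-consistent orthogroup
#' histories, and conservation tracks with elevated scores at target sites.
#'
#' @param rng_seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_orthogroups number of orthogroup histories to simulate.
#' @param gain_rate gain events per Myr (gains are placed proportionally to
#'   branch length; the rate sets the units, not the count, since each
#'   orthogroup carries exactly one gain under Dollo).
#' @param loss_rate loss events per Myr on branches below the gain.
#' @param read_depth_per_arm expected read count per hairpin arm.
#' @param read_error_rate per-base sequencing error probability.
#' @param n_repeat_families number of repeat consensus families.
#' @param site_conservation_mean mean per-base conservation inside planted
#'   target sites (Beta-distributed, bounded in [0,1] like phastCons).
#' @param background_conservation_mean mean conservation elsewhere.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L, n_orthogroups = 200L, gain_rate = 0.02,
                       loss_rate = 0.005, read_depth_per_arm = 30L,
                       read_error_rate = 0.01, n_repeat_families = 2L,
                       site_conservation_mean = 0.8,
                       background_conservation_mean = 0.3) {
  stopifnot(gain_rate >= 0, loss_rate >= 0,
            read_error_rate >= 0, read_error_rate < 0.5,
            site_conservation_mean >= 0, site_conservation_mean <= 1,
            background_conservation_mean >= 0,
            background_conservation_mean <= 1,
            n_repeat_families >= 1)
  structure(list(rng_seed = as.integer(rng_seed),
                 n_orthogroups = as.integer(n_orthogroups),
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 read_depth_per_arm = as.integer(read_depth_per_arm),
                 read_error_rate = read_error_rate,
                 n_repeat_families = as.integer(n_repeat_families),
                 site_conservation_mean = site_conservation_mean,
                 background_conservation_mean = background_conservation_mean),
            class = "sim_config")
}

#' Default dated 5-species tree
#'
#' A rooted binary tree over cow, pig, horse, dog and rabbit with branch
#' lengths in Myr following round-number mammalian divergence times
#' (cow-pig 62, +horse 78, +dog 80, +rabbit 90 Myr).
#'
#' @return an `ape::phylo` tree.
#' @export
default_tree <- function() {
  ape::read.tree(text =
    "((((cow:62,pig:62):16,horse:78):2,dog:80):10,rabbit:90);")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate Dollo-consistent gain/loss histories
#'
#' Each orthogroup receives exactly one gain on a branch chosen with
#' probability proportional to branch length (the root stem included), and
#' losses placed by a Poisson process at `loss_rate` events/Myr on branches
#' strictly below the gain; a lineage, once lost, stays lost. Histories
#' whose leaves end up all-absent are discarded and regenerated, mirroring
#' the ascertainment of observable orthogroups.
#'
#' @param tree dated `phylo` tree.
#' @param config a [sim_config()].
#' @param root_stem_length length (Myr) of the synthetic branch above the
#'   root, on which root-level gains sit.
#' @return list with `histories` (one record per orthogroup: `orthogroup_id`,
#'   `gain_branch`, `loss_branches`, `leaf_presence`) and `matrix`
#'   (orthogroup x species presence matrix).
#' @export
simulate_dollo_histories <- function(tree, config, root_stem_length = 10) {
  validate_dated_tree(tree)
  if (ape::Ntip(tree) < 2L) stop("tree must have >= 2 leaves")
  set.seed(config$rng_seed)
  br <- branch_table(tree, root_stem_length = root_stem_length)
  kids <- tree_children(tree)
  root <- ape::Ntip(tree) + 1L
  tips <- tree$tip.label
  p_loss <- 1 - exp(-config$loss_rate * br$length_myr)
  names(p_loss) <- br$branch_id
  histories <- vector("list", config$n_orthogroups)
  mat <- matrix(0L, config$n_orthogroups, length(tips),
                dimnames = list(NULL, tips))
  for (i in seq_len(config$n_orthogroups)) {
    repeat {
      gi <- sample.int(nrow(br), 1L, prob = br$length_myr)
      gain_node <- br$node[gi]
      if (is.na(gain_node)) gain_node <- root       # root-stem gain
      presence <- stats::setNames(rep(0L, length(tips)), tips)
      presence[clade_tips(tree, gain_node)] <- 1L
      losses <- character()
      walk <- function(node) {
        bid <- branch_id(tree, node)
        if (stats::runif(1) < p_loss[[bid]]) {
          losses <<- c(losses, bid)
          presence[clade_tips(tree, node)] <<- 0L
          return(invisible())
        }
        for (ch in kids[[node]]) walk(ch)
      }
      if (gain_node > ape::Ntip(tree))
        for (ch in kids[[gain_node]]) walk(ch)
      if (any(presence == 1L)) break
    }
    og <- sprintf("og%04d", i)
    histories[[i]] <- list(orthogroup_id = og, gain_branch = br$branch_id[gi],
                           loss_branches = losses, leaf_presence = presence)
    mat[i, ] <- presence
  }
  rownames(mat) <- vapply(histories, `[[`, "", "orthogroup_id")
  list(histories = histories, matrix = mat)
}

#' Simulate a stem-loop hairpin with annotated arms
#'
#' Builds 5p arm + loop + reverse complement of the 5p arm, with a chosen
#' number of mismatches injected into the 3p arm, so the stem pairs in a
#' fold by construction.
#'
#' @param arm_len arm length in nt (18-25).
#' @param loop_len loop length in nt (>= 3).
#' @param n_mismatches substitutions placed in the 3p arm.
#' @param config optional [sim_config()]; when given its seed is applied.
#' @return list `seq`, `arm_5p`, `arm_3p` (0-based half-open offsets).
#' @export
simulate_hairpin_locus <- function(arm_len = 22L, loop_len = 8L,
                                   n_mismatches = 0L, config = NULL) {
  stopifnot(arm_len >= 18L, arm_len <= 25L, loop_len >= 3L,
            n_mismatches <= arm_len)
  if (!is.null(config)) set.seed(config$rng_seed)
  arm5 <- .rand_dna(arm_len)
  loop <- .rand_dna(loop_len)
  arm3 <- strsplit(revcomp(arm5), "")[[1L]]
  if (n_mismatches > 0L) {
    pos <- sample.int(arm_len, n_mismatches)
    for (p in pos) arm3[p] <- sample(setdiff(c("A", "C", "G", "T"), arm3[p]), 1L)
  }
  seq <- paste0(arm5, loop, paste(arm3, collapse = ""))
  list(seq = seq,
       arm_5p = c(0L, arm_len),
       arm_3p = c(arm_len + loop_len, arm_len + loop_len + arm_len))
}

#' Simulate small-RNA read stacks over a hairpin
#'
#' Read counts per arm are Poisson with mean `depth` per arm; read ends
#' wobble by up to 1 nt (imprecise Drosha/Dicer cuts) and bases flip at the
#' configured error rate.
#'
#' @param locus list from [simulate_hairpin_locus()].
#' @param config a [sim_config()] (depth, error rate, seed).
#' @param wobble logical; apply the +/-1 nt end wobble.
#' @param depth_5p,depth_3p override the per-arm expected depth.
#' @return data.frame `seq`, `count`, `offset` aggregated over identical
#'   (sequence, offset) pairs.
#' @export
simulate_read_stacks <- function(locus, config, wobble = TRUE,
                                 depth_5p = config$read_depth_per_arm,
                                 depth_3p = config$read_depth_per_arm) {
  set.seed(config$rng_seed)
  n <- nchar(locus$seq)
  draw_arm <- function(arm, depth) {
    k <- stats::rpois(1L, depth)
    if (k == 0L) return(NULL)
    s <- arm[1L] + if (wobble) sample(-1:1, k, replace = TRUE) else integer(k)
    e <- arm[2L] + if (wobble) sample(-1:1, k, replace = TRUE) else integer(k)
    s <- pmax(0L, s); e <- pmin(n, pmax(s + 15L, e))
    seqs <- substring(locus$seq, s + 1L, e)
    if (config$read_error_rate > 0) {
      seqs <- vapply(seqs, function(x) {
        ch <- strsplit(x, "")[[1L]]
        err <- stats::runif(length(ch)) < config$read_error_rate
        if (any(err))
          ch[err] <- vapply(ch[err], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        paste(ch, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    data.frame(seq = seqs, offset = s, stringsAsFactors = FALSE)
  }
  reads <- rbind(draw_arm(locus$arm_5p, depth_5p),
                 draw_arm(locus$arm_3p, depth_3p))
  if (is.null(reads) || !nrow(reads))
    return(data.frame(seq = character(), count = integer(),
                      offset = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(count = rep(1L, nrow(reads))),
                          by = list(seq = reads$seq, offset = reads$offset),
                          FUN = sum)
  agg <- agg[order(agg$offset, agg$seq), c("seq", "count", "offset")]
  rownames(agg) <- NULL
  agg
}

.plant <- function(genome_chars, pos, seq) {
  ch <- strsplit(seq, "")[[1L]]
  genome_chars[(pos + 1L):(pos + length(ch))] <- ch
  genome_chars
}

.template_gene <- function(gid, seq_id, at, strand, short_intron = FALSE) {
  if (!short_intron) {
    ex <- gintervals(seq_id, at + c(0L, 1800L, 3400L), at + c(600L, 2400L, 4000L), strand)
    cds <- gintervals(seq_id, at + c(200L, 1800L, 3400L), at + c(600L, 2400L, 3600L), strand)
    gene_model(gid, gintervals(seq_id, at, at + 4000L, strand), ex, cds)
  } else {
    # two exons split by a hairpin-sized (60 nt) intron: miRtron host
    ex <- gintervals(seq_id, at + c(0L, 1060L), at + c(1000L, 2000L), strand)
    cds <- gintervals(seq_id, at + c(100L, 1060L), at + c(1000L, 1900L), strand)
    gene_model(gid, gintervals(seq_id, at, at + 2000L, strand), ex, cds)
  }
}

#' Simulate a genome with annotation, repeats and planted miRNA loci
#'
#' Builds one synthetic contig carrying protein-coding gene models, repeat
#' consensus families (with genomic copies), and miRNA hairpin loci whose
#' genomic origins are known by construction: intronic, intergenic,
#' miRtron (>= 90% reciprocal intron overlap), antisense pair (identical
#' span, opposite strands), tandem duplicates (10 kb apart), and a
#' repeat-derived locus sharing a >= 30 nt contiguous block with a repeat
#' consensus. Every planted locus carries its ground-truth labels.
#'
#' @param config a [sim_config()].
#' @return list: `genome` (named character), `genes` (named list of
#'   `gene_model`), `repeats` (named character), `loci` (data.frame of
#'   planted loci with coordinates, hairpin/arm info and truth columns
#'   `context`, `repeat_derived`, `antisense_partner`, `mirtron`, `tandem`),
#'   and `hairpins` (named character of hairpin sequences).
#' @export
simulate_annotation_and_repeats <- function(config) {
  set.seed(config$rng_seed)
  L <- 60000L
  g <- strsplit(.rand_dna(L), "")[[1L]]
  seq_id <- "chr1"
  genes <- list(
    geneA = .template_gene("geneA", seq_id, 2000L, "+"),
    geneB = .template_gene("geneB", seq_id, 10000L, "+", short_intron = TRUE),
    geneC = .template_gene("geneC", seq_id, 20000L, "-")
  )
  repeats <- stats::setNames(
    vapply(seq_len(config$n_repeat_families), function(i) .rand_dna(300L), ""),
    paste0("repfam", seq_len(config$n_repeat_families)))
  # genomic copies of repeat family 1 in intergenic space
  g <- .plant(g, 52000L, repeats[[1L]])
  g <- .plant(g, 54000L, repeats[[1L]])

  mk <- function(id, pos, strand, context, hp = NULL,
                 repeat_derived = FALSE, antisense_partner = NA_character_,
                 mirtron = FALSE, tandem = FALSE) {
    if (is.null(hp)) hp <- simulate_hairpin_locus(22L, 8L, 1L)
    list(id = id, pos = pos, strand = strand, hp = hp, context = context,
         repeat_derived = repeat_derived, antisense_partner = antisense_partner,
         mirtron = mirtron, tandem = tandem)
  }
  # miRtron hairpin sized exactly to geneB's 60-nt intron [11000, 11060)
  hp_mirtron <- simulate_hairpin_locus(25L, 10L, 1L)   # 60 nt
  # repeat-derived hairpin: 5p arm + loop copied from repfam1 (30 nt block)
  rep1 <- repeats[[1L]]
  arm5 <- substr(rep1, 1L, 22L)
  hp_rep <- list(seq = paste0(substr(rep1, 1L, 30L), revcomp(arm5)),
                 arm_5p = c(0L, 22L), arm_3p = c(30L, 52L))
  hp_tandem <- simulate_hairpin_locus(22L, 8L, 1L)
  hp_anti <- simulate_hairpin_locus(22L, 8L, 1L)
  plan <- list(
    mk("mir_intronic", 3000L, "+", "intron"),
    mk("mir_mirtron", 11000L, "+", "intron", hp = hp_mirtron, mirtron = TRUE),
    mk("mir_utr3", 5650L, "+", "utr3"),   # inside geneA 3'UTR [5600, 6000)
    mk("mir_intergenic", 30000L, "+", "intergenic"),
    mk("mir_anti_a", 32000L, "+", "intergenic", hp = hp_anti,
       antisense_partner = "mir_anti_b"),
    mk("mir_anti_b", 32000L, "-", "intergenic",
       hp = list(seq = revcomp(hp_anti$seq), arm_5p = hp_anti$arm_5p,
                 arm_3p = hp_anti$arm_3p),
       antisense_partner = "mir_anti_a"),
    mk("mir_tandem_a", 35000L, "+", "intergenic", hp = hp_tandem, tandem = TRUE),
    mk("mir_tandem_b", 45000L, "+", "intergenic",
       hp = list(seq = .mutate_seq(hp_tandem$seq, 3L),
                 arm_5p = hp_tandem$arm_5p, arm_3p = hp_tandem$arm_3p),
       tandem = TRUE),
    mk("mir_repeat", 50000L, "+", "intergenic", hp = hp_rep,
       repeat_derived = TRUE)
  )
  rows <- lapply(plan, function(p) {
    len <- nchar(p$hp$seq)
    genomic <- if (p$strand == "+") p$hp$seq else revcomp(p$hp$seq)
    g <<- .plant(g, p$pos, genomic)
    data.frame(locus_id = p$id, seq_id = seq_id, start = p$pos,
               end = p$pos + len, strand = p$strand,
               arm5_start = p$hp$arm_5p[1L], arm5_end = p$hp$arm_5p[2L],
               arm3_start = p$hp$arm_3p[1L], arm3_end = p$hp$arm_3p[2L],
               context = p$context, repeat_derived = p$repeat_derived,
               antisense_partner = p$antisense_partner, mirtron = p$mirtron,
               tandem = p$tandem, stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, rows)
  hairpins <- stats::setNames(vapply(plan, function(p) p$hp$seq, ""),
                              loci$locus_id)
  list(genome = stats::setNames(paste(g, collapse = ""), seq_id),
       genes = genes, repeats = repeats, loci = loci, hairpins = hairpins)
}

.mutate_seq <- function(seq, n_sub) {
  ch <- strsplit(seq, "")[[1L]]
  pos <- sample.int(length(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

.rbeta_mean <- function(n, mean, concentration = 20) {
  mean <- pmin(0.99, pmax(0.01, mean))
  stats::rbeta(n, mean * concentration, (1 - mean) * concentration)
}

#' Simulate 3'UTR multiple alignments with planted target sites
#'
#' Per gene: a reference UTR, per-species copies diverged by substitutions
#' and deletions (gaps never fall inside planted sites of carrier species),
#' 8mer seed-match sites planted at fixed offsets in all species, and a
#' per-base conservation track on the reference species' coordinates whose
#' mean is elevated inside sites (with a 10-nt linear decay flank) over the
#' background. Scores are Beta-distributed so they stay in [0,1].
#'
#' @param config a [sim_config()].
#' @param n_genes number of UTR alignments.
#' @param species_list species names; the first is the score-track
#'   reference and never carries gaps.
#' @param utr_len alignment length (>= 500 per the UTR length filter).
#' @param seeds character vector of 7-nt seeds to plant (recycled over
#'   genes); default two random seeds.
#' @param divergence per-base substitution probability in non-reference
#'   species.
#' @return list: `msa` (per-gene named character alignments), `track`
#'   (`score_track` keyed by gene ID over reference coordinates), `sites`
#'   (data.frame of planted sites: gene_id, species, utr_offset, msa_start,
#'   site_type, seed7).
#' @export
simulate_utr_alignments <- function(config, n_genes = 5L,
                                    species_list = c("human", "cow", "dog",
                                                     "horse", "pig", "rabbit",
                                                     "mouse"),
                                    utr_len = 600L, seeds = NULL,
                                    divergence = 0.08) {
  stopifnot(length(species_list) >= 2L, utr_len >= 500L)
  set.seed(config$rng_seed)
  if (is.null(seeds)) seeds <- c(.rand_dna(7L), .rand_dna(7L))
  site_offsets <- c(120L, 420L)         # clear of the 49-nt profile flanks
  msa <- list(); site_rows <- list()
  tr_seq <- character(); tr_start <- integer(); tr_end <- integer()
  tr_score <- numeric()
  for (gi in seq_len(n_genes)) {
    gene <- sprintf("gene%03d", gi)
    ref <- strsplit(.rand_dna(utr_len), "")[[1L]]
    seed7 <- seeds[((gi - 1L) %% length(seeds)) + 1L]
    site8 <- paste0(revcomp(seed7), "A")
    site_cols <- unlist(lapply(site_offsets, function(o) (o + 1L):(o + 8L)))
    for (o in site_offsets) ref <- .plant(ref, o, site8)
    aln <- matrix("", length(species_list), utr_len,
                  dimnames = list(species_list, NULL))
    aln[1L, ] <- ref
    for (si in seq_along(species_list)[-1L]) {
      sp <- ref
      sub <- which(stats::runif(utr_len) < divergence)
      sub <- setdiff(sub, site_cols)
      for (p in sub) sp[p] <- sample(setdiff(c("A", "C", "G", "T"), sp[p]), 1L)
      del <- which(stats::runif(utr_len) < 0.02)
      del <- setdiff(del, site_cols)
      sp[del] <- "-"
      aln[si, ] <- sp
    }
    msa[[gene]] <- apply(aln, 1L, paste, collapse = "")
    for (o in site_offsets) {
      for (si in seq_along(species_list)) {
        row <- aln[si, ]
        ungapped_off <- sum(row[seq_len(o)] != "-")   # gaps before the site
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          gene_id = gene, species = species_list[si],
          utr_offset = ungapped_off, msa_start = o, site_type = "8mer",
          seed7 = seed7, stringsAsFactors = FALSE)
      }
    }
    # per-base scores over reference coordinates
    mu <- rep(config$background_conservation_mean, utr_len)
    for (o in site_offsets) {
      mu[(o + 1L):(o + 8L)] <- config$site_conservation_mean
      for (d in 1:10) {
        w <- (10 - d) / 10
        lev <- config$background_conservation_mean +
          w * (config$site_conservation_mean - config$background_conservation_mean)
        if (o + 8L + d <= utr_len) mu[o + 8L + d] <- lev
        if (o - d >= 0L) mu[o - d + 1L] <- lev
      }
    }
    sc <- .rbeta_mean(utr_len, mu)
    tr_seq <- c(tr_seq, rep(gene, utr_len))
    tr_start <- c(tr_start, 0:(utr_len - 1L))
    tr_end <- c(tr_end, 1:utr_len)
    tr_score <- c(tr_score, sc)
  }
  list(msa = msa,
       track = score_track(tr_seq, tr_start, tr_end, tr_score),
       sites = do.call(rbind, site_rows))
}
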