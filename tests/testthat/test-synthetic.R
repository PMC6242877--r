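test_that("Dollo histories respect the single-gain constraint and the matrix", {
  tree <- default_tree()
  sim <- simulate_dollo_histories(tree, sim_config(rng_seed = 11,
                                                   n_orthogroups = 80,
                                                   loss_rate = 0.01))
  expect_equal(nrow(sim$matrix), 80L)
  expect_true(all(rowSums(sim$matrix) >= 1L))
  for (h in sim$histories) {
    expect_identical(sim$matrix[h$orthogroup_id, ],
                     h$leaf_presence[colnames(sim$matrix)])
    # losses never sit on or above the gain branch
    expect_false(h$gain_branch %in% h$loss_branches)
  }
})

test_that("loss_rate zero yields presence equal to the gain clade", {
  tree <- default_tree()
  sim <- simulate_dollo_histories(tree, sim_config(rng_seed = 5,
                                                   n_orthogroups = 60,
                                                   loss_rate = 0))
  for (h in sim$histories) {
    expect_length(h$loss_branches, 0L)
    clade <- if (h$gain_branch == "root") tree$tip.label
    else strsplit(h$gain_branch, "+", fixed = TRUE)[[1L]]
    expect_setequal(names(which(h$leaf_presence == 1L)), clade)
  }
  # a gain on a terminal branch is a single-species orthogroup
  term <- Filter(function(h) !grepl("+", h$gain_branch, fixed = TRUE) &&
                   h$gain_branch != "root", sim$histories)
  expect_gt(length(term), 0L)
  for (h in term) expect_equal(sum(h$leaf_presence), 1L)
})

test_that("generators are deterministic under a fixed seed", {
  tree <- default_tree()
  cfg <- sim_config(rng_seed = 42, n_orthogroups = 30)
  expect_identical(simulate_dollo_histories(tree, cfg),
                   simulate_dollo_histories(tree, cfg))
  hp1 <- simulate_hairpin_locus(22, 8, 2, config = cfg)
  hp2 <- simulate_hairpin_locus(22, 8, 2, config = cfg)
  expect_identical(hp1, hp2)
  expect_identical(simulate_read_stacks(hp1, cfg),
                   simulate_read_stacks(hp2, cfg))
  expect_identical(simulate_utr_alignments(cfg, n_genes = 2),
                   simulate_utr_alignments(cfg, n_genes = 2))
})

test_that("simulated hairpins have the designed arm geometry", {
  cfg <- sim_config(rng_seed = 3)
  hp <- simulate_hairpin_locus(22, 8, 0, config = cfg)
  expect_equal(nchar(hp$seq), 52L)
  arm5 <- substr(hp$seq, 1, 22)
  arm3 <- substr(hp$seq, 31, 52)
  expect_identical(arm3, revcomp(arm5))

  hp3 <- simulate_hairpin_locus(22, 8, 3, config = cfg)
  a5 <- strsplit(revcomp(substr(hp3$seq, 1, 22)), "")[[1]]
  a3 <- strsplit(substr(hp3$seq, 31, 52), "")[[1]]
  expect_equal(sum(a5 != a3), 3L)
})

test_that("read stacks without wobble or errors reproduce the arms", {
  cfg <- sim_config(rng_seed = 9, read_error_rate = 0)
  hp <- simulate_hairpin_locus(22, 8, 0, config = cfg)
  rd <- simulate_read_stacks(hp, cfg, wobble = FALSE)
  r5 <- rd[rd$offset == hp$arm_5p[1], ]
  expect_equal(unique(r5$seq), substr(hp$seq, hp$arm_5p[1] + 1, hp$arm_5p[2]))
  # zero depth on one arm drives a duplex-evidence failure downstream
  rd0 <- simulate_read_stacks(hp, cfg, depth_3p = 0)
  dx <- duplex_evidence(rd0, hp$arm_5p, hp$arm_3p)
  expect_false(dx$pass)
  expect_equal(dx$reads_3p, 0L)
})

test_that("planted genome satisfies the documented origin geometries", {
  ann <- simulate_annotation_and_repeats(sim_config(rng_seed = 7))
  loci <- ann$loci
  # miRtron: reciprocal overlap >= 0.9 with an intron by construction
  mt <- loci[loci$mirtron, ]
  introns <- all_introns(ann$genes)
  ov <- interval_overlap(introns$start, introns$end, mt$start, mt$end)
  sel <- introns$strand == mt$strand
  expect_true(any(ov[sel] / (mt$end - mt$start) >= 0.9 &
                    ov[sel] / (introns$end[sel] - introns$start[sel]) >= 0.9))
  # antisense pair at identical coordinates, opposite strands
  ap <- loci[!is.na(loci$antisense_partner), ]
  expect_equal(nrow(ap), 2L)
  expect_equal(ap$start[1], ap$start[2])
  expect_setequal(ap$strand, c("+", "-"))
  # repeat-derived locus shares >= 30 contiguous nt with its source repeat
  rp <- loci[loci$repeat_derived, ]
  hp <- ann$hairpins[[rp$locus_id]]
  expect_true(grepl(substr(hp, 1, 30), ann$repeats[[1]], fixed = TRUE))
  # planted loci are embedded in the genome at their coordinates
  for (i in seq_len(nrow(loci))) {
    g <- substr(ann$genome[[loci$seq_id[i]]], loci$start[i] + 1, loci$end[i])
    want <- if (loci$strand[i] == "+") ann$hairpins[[loci$locus_id[i]]]
    else revcomp(ann$hairpins[[loci$locus_id[i]]])
    expect_identical(g, want)
  }
})

test_that("UTR alignments plant discoverable sites and honest truth tables", {
  cfg <- sim_config(rng_seed = 13)
  u <- simulate_utr_alignments(cfg, n_genes = 3)
  for (i in seq_len(nrow(u$sites))) {
    s <- u$sites[i, ]
    aln <- u$msa[[s$gene_id]][[s$species]]
    ungapped <- gsub("-", "", aln)
    found <- find_sites(ungapped, s$seed7)
    expect_true(s$utr_offset %in%
                  found$utr_offset[found$site_type == "8mer"])
  }
})

test_that("null conservation config shows no center elevation", {
  cfg <- sim_config(rng_seed = 21, site_conservation_mean = 0.3,
                    background_conservation_mean = 0.3)
  u <- simulate_utr_alignments(cfg, n_genes = 4)
  ref <- u$sites[u$sites$species == "human", ]
  pr <- conservation_profile(
    data.frame(seq_id = ref$gene_id, pos = ref$utr_offset),
    u$track, bootstrap_B = 200, rng_seed = 1)
  center <- pr[pr$bin_offset == 0, ]
  flanks <- pr[abs(pr$bin_offset) >= 21, ]
  expect_true(center$ci_low <= max(flanks$ci_high))
})
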