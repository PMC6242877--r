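test_that("candidate merging follows bedtools semantics", {
  a <- gintervals("chr1", 10, 50, "+")
  b <- gintervals("chr1", 40, 80, "+")
  expect_equal(merge_candidates(a, b),
               gintervals("chr1", 10, 80, "+"))
  # book-ended intervals merge
  b2 <- gintervals("chr1", 50, 80, "+")
  expect_equal(merge_candidates(a, b2),
               gintervals("chr1", 10, 80, "+"))
  # opposite strands stay separate
  b3 <- gintervals("chr1", 40, 80, "-")
  m <- merge_candidates(a, b3)
  expect_equal(nrow(m), 2L)
  # merging is idempotent
  expect_equal(merge_candidates(m), m)
})

test_that("built-in fold matches brute-force maximum pairing on small RNAs", {
  f <- fold_hairpin("GGGGAAAACCCC", engine = "nussinov")
  expect_identical(f$structure, "((((....))))")
  expect_equal(f$energy, -4)
  expect_identical(fold_hairpin("AAAAAAAAAA", engine = "nussinov")$structure,
                   "..........")
  # determinism
  s <- "GCGCGAAACGCGCAAAGC"
  expect_identical(fold_hairpin(s, engine = "nussinov"),
                   fold_hairpin(s, engine = "nussinov"))
  # pair counts equal the independent enumeration (lonely pairs allowed so
  # the objective is comparable)
  set.seed(101)
  for (i in 1:15) {
    seq <- rand_dna(sample(10:14, 1))
    f <- fold_hairpin(seq, engine = "nussinov", no_lonely_pairs = FALSE)
    expect_equal(-f$energy, oracle_max_pairs(seq),
                 info = paste("sequence", seq))
    # structure is balanced and respects the minimum loop
    pt <- pair_table(f$structure)
    paired <- which(!is.na(pt))
    if (length(paired)) expect_true(all(abs(pt[paired] - paired) >= 4))
  }
})

test_that("fold rejects invalid characters", {
  expect_error(fold_hairpin("ACGTX"), "invalid characters")
})

test_that("hairpin structure criteria accept the designed positive", {
  hp <- simulate_hairpin_locus(22, 8, 0, config = sim_config(rng_seed = 2))
  f <- fold_hairpin(hp$seq, engine = "nussinov")
  r <- is_mirna_like(f, hp$arm_5p, hp$arm_3p)
  expect_true(r$ok)
  expect_identical(r$reason, "ok")
})

test_that("structure criteria name the first failed criterion", {
  # two terminal loops -> multiloop
  fold2 <- list(structure = "((((....))))....((((....))))", energy = -8)
  r <- is_mirna_like(fold2, c(0L, 12L), c(16L, 28L))
  expect_false(r$ok)
  expect_identical(r$reason, "multiloop")
  # single loop but arms mostly unpaired -> pairing fraction
  fold3 <- list(structure = paste0("(((", strrep(".", 20), ")))",
                                   strrep(".", 14)), energy = -3)
  r3 <- is_mirna_like(fold3, c(0L, 10L), c(30L, 40L))
  expect_false(r3$ok)
  expect_identical(r3$reason, "pairing fraction")
  # arms out of range error
  expect_error(is_mirna_like(fold2, c(0L, 50L), c(0L, 10L)), "outside")
})

test_that("duplex evidence applies the coverage thresholds", {
  hp <- simulate_hairpin_locus(22, 8, 0, config = sim_config(rng_seed = 4))
  arm_read <- function(arm, count)
    data.frame(seq = substr(hp$seq, arm[1] + 1, arm[2]), count = count,
               offset = arm[1])
  # 6 + 6 reads: both ends covered, total 12 >= 10 -> pass
  dx <- duplex_evidence(rbind(arm_read(hp$arm_5p, 6), arm_read(hp$arm_3p, 6)),
                        hp$arm_5p, hp$arm_3p)
  expect_true(dx$pass)
  expect_equal(dx$total_reads, 12L)
  # 9 + 0: one end uncovered -> fail regardless of total
  expect_false(duplex_evidence(arm_read(hp$arm_5p, 9),
                               hp$arm_5p, hp$arm_3p)$pass)
  # 5 + 4 = 9 < 10 -> fail
  expect_false(duplex_evidence(rbind(arm_read(hp$arm_5p, 5),
                                     arm_read(hp$arm_3p, 4)),
                               hp$arm_5p, hp$arm_3p)$pass)
})

test_that("known/novel classification tolerates exactly one mismatch", {
  hp <- "ACGTACGTACGTTTTACGCAGTCAGTCAGTCAGGCATGCATCGATT"
  mature <- substr(hp, 5, 26)
  sliding_best <- function(probe) {
    min(vapply(1:(nchar(hp) - nchar(probe) + 1), function(i)
      sum(strsplit(substr(hp, i, i + nchar(probe) - 1), "")[[1]] !=
            strsplit(probe, "")[[1]]), 0L))
  }
  mutate_at <- function(s, pos) {
    for (p in pos)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(s, p, p))[1]
    s
  }
  expect_identical(classify_known(hp, c(m1 = mature)), "known")
  one_mm <- mutate_at(mature, 3)
  expect_equal(sliding_best(one_mm), 1L)
  expect_identical(classify_known(hp, c(m1 = one_mm)), "known")
  # best ungapped placement has two mismatches, verified by exhaustive
  # sliding-window count
  two_mm <- mutate_at(mature, c(3, 11))
  expect_equal(sliding_best(two_mm), 2L)
  expect_identical(classify_known(hp, c(m1 = two_mm)), "novel")
})

test_that("low-coverage rescue needs both processing evidence and homology", {
  rej <- data.frame(locus_id = c("l1", "l2", "l3"),
                    reads_5p = c(3L, 3L, 0L), reads_3p = c(3L, 3L, 6L))
  hom <- c(l1 = TRUE, l2 = FALSE, l3 = TRUE)
  expect_identical(rescue_low_coverage(rej, hom), "l1")
  expect_identical(rescue_low_coverage(rej[0, ], hom), character())
})

test_that("structure and duplex filters commute and statuses partition", {
  cfg <- sim_config(rng_seed = 17)
  for (i in 1:5) {
    cfg_i <- sim_config(rng_seed = 100 + i)
    hp <- simulate_hairpin_locus(22, 8, sample(0:3, 1), config = cfg_i)
    rd <- simulate_read_stacks(hp, cfg_i)
    f <- fold_hairpin(hp$seq)
    s_then_d <- is_mirna_like(f, hp$arm_5p, hp$arm_3p)$ok &&
      duplex_evidence(rd, hp$arm_5p, hp$arm_3p)$pass
    d_then_s <- duplex_evidence(rd, hp$arm_5p, hp$arm_3p)$pass &&
      is_mirna_like(f, hp$arm_5p, hp$arm_3p)$ok
    expect_identical(s_then_d, d_then_s)
    st <- curate_locus(hp$seq, hp$arm_5p, hp$arm_3p, rd)
    expect_true(st$status %in% c("known", "novel", "rejected"))
  }
})
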