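test_that("seed extraction takes mature positions 2-8 and 2-7", {
  s <- extract_seed("TTACAATACAACCTGATAAGT")
  expect_identical(s$seed7, "TACAATA")
  expect_identical(s$seed6, "TACAAT")
  expect_identical(extract_seed("ACGTACGT")$seed7, "CGTACGT")
  expect_error(extract_seed("ACGTACG"), "shorter than 8")
})

test_that("seed families partition matures by exact seed identity", {
  mat <- c(a = "TTACAATACAACCTGATAAGT", b = "GTACAATAGGGGGGGGGG",
           c = "TTTTTTTTTTTTTTTTTT")
  fams <- seed_families(mat, species_of = c(a = "cow", b = "dog", c = "cow"))
  seeds <- vapply(fams, `[[`, "", "seed7")
  expect_setequal(seeds, c("TACAATA", "TTTTTTT"))
  fam1 <- fams[[which(seeds == "TACAATA")]]
  expect_setequal(fam1$members, c("a", "b"))
  expect_setequal(fam1$species_span, c("cow", "dog"))
  m <- seed_presence_matrix(fams, c("cow", "dog", "pig"))
  expect_equal(unname(m["TACAATA", ]), c(1L, 1L, 0L))
})

test_that("UTR windows extend, trim and filter as specified", {
  mk <- function(id, exon_end, strand = "+", cds = NULL) {
    ex <- gintervals("c1", exon_end - 200L, exon_end, strand)
    gene_model(id, ex, ex, cds)
  }
  clen <- c(c1 = 20000L)
  # no downstream CDS: full 5-kb window after the last exon
  g1 <- mk("g1", 1000L)
  w <- build_utr_windows(list(g1 = g1), clen)
  expect_equal(c(w$g1$start, w$g1$end), c(1000L, 6000L))
  # a downstream CDS at 3000 trims the window
  blocker <- gene_model("g2", gintervals("c1", 3000L, 3400L, "+"),
                        gintervals("c1", 3000L, 3400L, "+"),
                        gintervals("c1", 3000L, 3400L, "+"))
  w2 <- build_utr_windows(list(g1 = g1, g2 = blocker), clen)
  expect_equal(c(w2$g1$start, w2$g1$end), c(1000L, 3000L))
  # a window trimmed below 500 nt drops the gene
  near <- gene_model("g3", gintervals("c1", 1100L, 1500L, "+"),
                     gintervals("c1", 1100L, 1500L, "+"),
                     gintervals("c1", 1100L, 1500L, "+"))
  w3 <- build_utr_windows(list(g1 = g1, g3 = near), clen)
  expect_false("g1" %in% names(w3))
  # minus strand extends upstream of the first exon
  gm <- mk("gm", 10000L, strand = "-")
  wm <- build_utr_windows(list(gm = gm), clen)
  expect_equal(c(wm$gm$start, wm$gm$end), c(4800L, 9800L))
})

test_that("site discovery equals the brute-force regex oracle", {
  # worked cases first
  hit8 <- find_sites("GGTATTGTAAGG", "TACAATA")
  expect_identical(hit8$site_type, "8mer")
  expect_equal(hit8$utr_offset, 2L)
  hit7 <- find_sites("GGTATTGTACGG", "TACAATA")
  expect_identical(hit7$site_type, "7mer-m8")
  # poly-A contains no match for a mixed-composition seed
  expect_equal(nrow(find_sites("AAAAAAAAAAAA", "TACAATA")), 0L)
  set.seed(11)
  for (i in 1:40) {
    utr <- rand_dna(300)
    seed <- rand_dna(7)
    got <- find_sites(utr, seed)
    want <- oracle_sites(utr, seed)
    key <- function(d) if (is.null(d) || !nrow(d)) character() else
      sort(paste(d$utr_offset, d$site_type))
    expect_identical(key(got), key(want), info = paste("case", i))
  }
})

test_that("site filtering demands outgroup plus supporting species", {
  sites <- data.frame(
    gene_id = "g1", msa_start = 100L, seed7 = "TACAATA",
    species = c("rabbit", "cow", "dog"),
    context_score = c(-0.2, -0.15, -0.05),
    stringsAsFactors = FALSE)
  kept <- filter_sites(sites)
  # dog occurrence fails the context ceiling; rabbit + cow remain
  expect_setequal(kept$species, c("rabbit", "cow"))
  # outgroup-only groups are dropped
  only_rabbit <- sites[1, ]
  expect_equal(nrow(filter_sites(only_rabbit)), 0L)
  # without scores the context filter is skipped with a notice
  noscore <- sites[, setdiff(names(sites), "context_score")]
  expect_message(kept2 <- filter_sites(noscore), "skipped")
  expect_equal(nrow(kept2), 3L)
})

test_that("MSA lifting maps coordinates both ways", {
  msa <- c(sp1 = "AC-GT", sp2 = "ACAGT")
  lift <- lift_through_msa(msa, "sp2", c(2L, 4L))
  expect_equal(lift$msa_columns, c(2L, 4L))
  p1 <- lift$projections[lift$projections$species == "sp1", ]
  expect_equal(c(p1$start, p1$end), c(2L, 3L))
  expect_true(p1$has_gaps)
  # identity on gap-free alignments, and a clean round trip
  msa2 <- c(a = "ACGTACGT", b = "TTGTACCA")
  l2 <- lift_through_msa(msa2, "a", c(3L, 6L))
  expect_equal(l2$msa_columns, c(3L, 6L))
  pb <- l2$projections[l2$projections$species == "b", ]
  expect_equal(c(pb$start, pb$end), c(3L, 6L))
  expect_false(pb$has_gaps)
  # round trip: lift the projection back
  l3 <- lift_through_msa(msa, "sp1", c(p1$start, p1$end))
  ps2 <- l3$projections[l3$projections$species == "sp2", ]
  expect_true(ps2$start >= 2L && ps2$end <= 4L)
  expect_error(lift_through_msa(msa, "sp2", c(3L, 9L)), "out of range")
})

test_that("pairwise site similarity counts identical non-gap seed columns", {
  block <- c(cow = "GGTATTGTAAGG", dog = "GGTATTGTAAGG",
             pig = "GGTACTGTAAGG", gap = "GGTA-TGTAAGG")
  seed_cols <- 4:9
  expect_equal(pairwise_site_similarity(block, "cow", "dog", seed_cols), 1)
  expect_equal(pairwise_site_similarity(block, "cow", "pig", seed_cols), 5 / 6)
  expect_lte(pairwise_site_similarity(block, "cow", "gap", seed_cols), 5 / 6)
  expect_error(pairwise_site_similarity(block, "cow", "horse", seed_cols),
               "absent")
})

test_that("conservation profile tiles 15 bins and handles constant tracks", {
  tr <- score_track("g1", 0L, 1000L, 0.5)
  sites <- data.frame(seq_id = "g1", pos = c(200L, 400L, 600L))
  pr <- conservation_profile(sites, tr, bootstrap_B = 50, rng_seed = 1)
  expect_equal(nrow(pr), 15L)
  expect_true(all(pr$median == 0.5))
  expect_true(all(pr$ci_low == 0.5 & pr$ci_high == 0.5))
  expect_true(all(pr$ci_low <= pr$median & pr$median <= pr$ci_high))
  expect_equal(pr$bin_offset, seq(-49L, 49L, by = 7L))
  # positions without scores are excluded, not zero-filled
  tr2 <- score_track("g1", 150L, 152L, 0.9)
  pr2 <- conservation_profile(data.frame(seq_id = "g1", pos = 200L), tr2,
                              bootstrap_B = 10, rng_seed = 1)
  expect_equal(pr2$n_sites[pr2$bin_offset == -49], 1)
  expect_true(all(is.na(pr2$median[pr2$bin_offset > -42])))
  expect_error(conservation_profile(data.frame(seq_id = character(),
                                               pos = integer())[0, ], tr),
               "no sites")
})
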