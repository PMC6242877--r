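test_that("alignment identity agrees with the hand-rolled NW oracle", {
  set.seed(7)
  for (i in 1:12) {
    a <- rand_dna(sample(40:90, 1))
    b <- rand_dna(sample(40:90, 1))
    expect_equal(seq_identity(a, b), oracle_identity(a, b),
                 info = paste("pair", i))
  }
})

test_that("greedy clustering follows CD-HIT semantics", {
  s <- c(x = "ACGTACGTAC", y = "ACGTACGTAC", z = "TTTTTCTTTT")
  cl <- greedy_cluster(s, 0.8)
  expect_length(cl, 2L)
  expect_setequal(cl[[1]]$members, c("x", "y"))
  expect_identical(cl[[1]]$representative, "x")   # lexicographic tie-break

  # threshold 1.0 splits sequences differing by one substitution
  s2 <- c(a = "ACGTACGTACGTACGTACGT", b = "ACGTACGTACCTACGTACGT")
  expect_length(greedy_cluster(s2, 1.0), 2L)
  expect_length(greedy_cluster(s2, 0.9), 1L)
  expect_error(greedy_cluster(character()), "empty")
})

test_that("clustering splits or joins exactly at the oracle identity", {
  set.seed(19)
  base <- rand_dna(100)
  mut <- strsplit(base, "")[[1]]
  pos <- sample(100, 21)
  for (p in pos) mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
  pair <- c(s1 = base, s2 = paste(mut, collapse = ""))
  o <- oracle_identity(pair[[1]], pair[[2]])
  expect_length(greedy_cluster(pair, o + 0.005), 2L)
  expect_length(greedy_cluster(pair, max(0.5, o - 0.005)), 1L)
})

test_that("clustering is invariant to input order and recovers families", {
  set.seed(23)
  fams <- lapply(1:5, function(i) rand_dna(82))
  seqs <- character(); truth <- character()
  for (i in seq_along(fams)) {
    seed <- fams[[i]]
    seqs[sprintf("f%d_rep", i)] <- seed
    truth[sprintf("f%d_rep", i)] <- i
    for (j in 1:3) {
      copy <- strsplit(substr(seed, 1, 80), "")[[1]]
      pos <- sample(80, sample(6:12, 1))       # <= 15% divergence
      for (p in pos) copy[p] <- setdiff(c("A", "C", "G", "T"), copy[p])[1]
      id <- sprintf("f%d_c%d", i, j)
      seqs[id] <- paste(copy, collapse = "")
      truth[id] <- i
    }
  }
  cl <- greedy_cluster(seqs, 0.8)
  expect_length(cl, 5L)
  for (c in cl) expect_length(unique(truth[c$members]), 1L)
  # member-to-representative identity >= threshold, by the oracle
  for (c in cl) for (m in c$members)
    expect_gte(oracle_identity(seqs[[m]], seqs[[c$representative]]), 0.8)
  # shuffled insertion order yields identical clusters
  perm <- sample(seq_along(seqs))
  cl2 <- greedy_cluster(seqs[perm], 0.8)
  key <- function(cl) lapply(cl, function(c) sort(c$members))
  expect_identical(key(cl), key(cl2))
})

test_that("orthogroup composition reflects member statuses", {
  cl <- list(list(og_id = "og1", representative = "a", members = c("a", "b")),
             list(og_id = "og2", representative = "c", members = "c"))
  st <- c(a = "known", b = "novel", c = "known")
  comp <- orthogroup_composition(cl, st)
  expect_identical(comp$composition, c("mixed", "mirbase_only"))
})

test_that("hit filtering keeps exactly the quoted thresholds", {
  hits <- data.frame(query_id = c("a", "b", "c"),
                     evalue = c(1e-7, 1e-5, 1e-7),
                     align_len = c(45L, 45L, 39L))
  kept <- filter_hits(hits)
  expect_identical(kept$query_id, "a")
  # boundary values are inclusive
  edge <- data.frame(query_id = "d", evalue = 1e-6, align_len = 40L)
  expect_equal(nrow(filter_hits(edge)), 1L)
})

test_that("synteny support enumerates flank pairs on a toy annotation", {
  mkgene <- function(id, start, end, strand = "+", seq_id = "q1")
    gene_model(id, gintervals(seq_id, start, end, strand),
               gintervals(seq_id, start, end, strand))
  qg <- list(mkgene("g1", 0, 100), mkgene("g2", 500, 600),
             mkgene("g3", 1000, 1100))
  sg <- list(mkgene("h1", 0, 100, seq_id = "s1"),
             mkgene("h2", 500, 600, seq_id = "s1"),
             mkgene("hx", 1000, 1100, seq_id = "s1"))
  qi <- gintervals("q1", 200, 300, "+")
  si <- gintervals("s1", 200, 300, "+")
  hom <- c(g1 = "h1", g3 = "h9")
  # upstream pair (g1, h1) are homologs -> supported
  expect_true(synteny_support(qi, si, qg, sg, hom))
  # no flanking homolog pair -> unsupported
  expect_false(synteny_support(qi, si, qg, sg, c(g1 = "hz")))
  # reverse orientation swaps the subject flanks
  hom_down <- c(g2 = "h1")
  expect_false(synteny_support(qi, si, qg, sg, hom_down))
  expect_true(synteny_support(qi, si, qg, sg, hom_down,
                              subject_orientation = "reverse"))
  # intragenic: the containing gene counts as both flanks
  qi2 <- gintervals("q1", 520, 560, "+")
  si2 <- gintervals("s1", 520, 560, "+")
  expect_true(synteny_support(qi2, si2, qg, sg, c(g2 = "h2")))
})

test_that("presence matrix combines evidence sources by priority", {
  cl <- list(list(og_id = "og1", representative = "a",
                  members = c("a", "b")),
             list(og_id = "og2", representative = "c", members = "c"))
  sp_of <- c(a = "cow", b = "dog", c = "pig")
  species <- c("cow", "dog", "pig", "horse", "rabbit")
  m <- build_matrix(cl, sp_of, species,
                    syntenic_hits = data.frame(og_id = "og1", species = "pig"),
                    unaligned_read_matches = data.frame(og_id = "og1",
                                                        species = c("pig", "horse")))
  expect_equal(unname(m$presence["og1", ]), c(1L, 1L, 1L, 1L, 0L))
  expect_identical(unname(m$evidence["og1", c("cow", "pig", "horse", "rabbit")]),
                   c("annotated", "synteny_homolog", "unaligned_read", "absent"))
  expect_true(all(rowSums(m$presence) >= 1L))
  expect_identical((m$evidence != "absent"), (m$presence == 1L))
})
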