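# Independent oracles used to cross-check the package implementations.
# Each is written from first principles (brute force / enumeration / closed
# form) and must never call the code path it checks.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Needleman-Wunsch with match 1 / mismatch 0 / indel 0: the maximum number
# of identical aligned positions (classic DP, row by row).
oracle_nw_matches <- function(a, b) {
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(b, "")[[1L]]
  prev <- rep(0L, length(y) + 1L)
  for (i in seq_along(x)) {
    cur <- rep(0L, length(y) + 1L)
    for (j in seq_along(y)) {
      cur[j + 1L] <- max(prev[j] + (x[i] == y[j]), prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[length(y) + 1L]
}

oracle_identity <- function(a, b) {
  oracle_nw_matches(a, b) / min(nchar(a), nchar(b))
}

# Brute-force maximum nested base pairing (min loop 3, WC + GU), by
# recursion on the leftmost position -- a different decomposition from the
# implementation's rightmost-position DP. Exponential; tiny inputs only.
oracle_max_pairs <- function(seq, min_loop = 3L) {
  pairs_ok <- c("AT", "TA", "GC", "CG", "GT", "TG")
  s <- strsplit(toupper(seq), "")[[1L]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)                       # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (paste0(s[i], s[k]) %in% pairs_ok) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  rec(1L, length(s))
}

# Exhaustive Dollo oracle: enumerate every 0/1 assignment to internal nodes
# with exactly one gain (a 0->1 edge, or a present root = gain on the root
# stem), minimising 1->0 edges. Returns the minimal loss count and every
# optimal (gain, loss-set) reconstruction, using the package's branch IDs.
oracle_dollo <- function(tree, presence) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- ntip + 1L
  tips <- tree$tip.label
  edge <- tree$edge
  best <- Inf
  opts <- list()
  for (mask in 0:(2^nnode - 1L)) {
    state <- integer(ntip + nnode)
    state[seq_len(ntip)] <- presence[tips]
    state[(ntip + 1L):(ntip + nnode)] <- bitwAnd(bitwShiftR(mask, 0:(nnode - 1L)), 1L)
    gains <- character(); losses <- character()
    if (state[root] == 1L) gains <- "root"
    for (e in seq_len(nrow(edge))) {
      p <- state[edge[e, 1L]]; c <- state[edge[e, 2L]]
      bid <- mirevol::branch_id(tree, edge[e, 2L])
      if (p == 0L && c == 1L) gains <- c(gains, bid)
      if (p == 1L && c == 0L) losses <- c(losses, bid)
    }
    if (length(gains) != 1L) next
    if (length(losses) < best) { best <- length(losses); opts <- list() }
    if (length(losses) == best)
      opts[[length(opts) + 1L]] <- list(gain_branch = gains,
                                        loss_branches = sort(losses))
  }
  # deduplicate co-optimal reconstructions that differ only in unreachable
  # internal states
  keys <- vapply(opts, function(o)
    paste(o$gain_branch, paste(o$loss_branches, collapse = ","), sep = "|"), "")
  list(min_losses = best, optima = opts[!duplicated(keys)])
}

# Regex-based overlapping scan for the three canonical site types.
oracle_sites <- function(utr, seed7) {
  m7 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seed7)))
  m6 <- substr(m7, 2L, 7L)
  m1 <- substr(m7, 1L, 1L)
  hits <- function(pattern) {
    g <- gregexpr(pattern, utr, perl = TRUE)[[1L]]
    if (g[1L] == -1L) integer() else as.integer(g) - 1L
  }
  e8 <- hits(paste0("(?=", m7, "A)"))
  e7m8 <- setdiff(hits(paste0("(?=", m7, ")")), e8)
  a1 <- hits(paste0("(?=", m6, "A)"))
  if (length(a1)) {
    prev_is_m8 <- a1 >= 1L & substring(utr, a1, a1) == m1
    a1 <- a1[!prev_is_m8]
  }
  rbind(
    if (length(e8)) data.frame(utr_offset = e8, site_type = "8mer"),
    if (length(e7m8)) data.frame(utr_offset = e7m8, site_type = "7mer-m8"),
    if (length(a1)) data.frame(utr_offset = a1, site_type = "7mer-A1"))
}

# Exact hypergeometric upper tail by combinatorial enumeration.
oracle_hyper_upper <- function(N, K, n, k) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Fixed 5-leaf test tree used across Dollo tests.
dollo_test_tree <- function() {
  ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,E:2);")
}
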