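#' Children of every node in a tree
#' @param tree `phylo` tree.
#' @return list indexed by node number; empty integer for tips.
#' @export
tree_children <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n)
  for (i in seq_len(n)) kids[[i]] <- integer()
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  kids
}

#' Tip labels below a node
#' @param tree `phylo` tree.
#' @param node node number (a tip number returns its own label).
#' @return character vector of tip labels.
#' @export
clade_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  # iterative descent
  stack <- node; tips <- integer()
  kids <- tree_children(tree)
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (nd <= ntip) tips <- c(tips, nd)
    else stack <- c(stack, kids[[nd]])
  }
  tree$tip.label[sort(tips)]
}

#' Stable branch identifier
#'
#' The stem branch above a node is named by the sorted "+"-joined tip labels
#' of its clade; the synthetic branch above the root is named "root".
#'
#' @param tree `phylo` tree.
#' @param node node number, or NA for the root stem.
#' @return character branch ID.
#' @export
branch_id <- function(tree, node) {
  if (is.na(node) || node == ape::Ntip(tree) + 1L) return("root")
  paste(sort(clade_tips(tree, node)), collapse = "+")
}

#' Branch table of a dated tree
#'
#' One row per branch (stem of each non-root node) plus the synthetic root
#' stem, with lengths in Myr.
#'
#' @param tree `phylo` tree.
#' @param root_stem_length length of the root stem (NA when root-level
#'   gains should carry no rate).
#' @return data.frame `branch_id`, `node`, `length_myr`.
#' @export
branch_table <- function(tree, root_stem_length = NA_real_) {
  ids <- vapply(tree$edge[, 2L], function(nd) branch_id(tree, nd), "")
  df <- data.frame(branch_id = c(ids, "root"),
                   node = c(tree$edge[, 2L], NA_integer_),
                   length_myr = c(tree$edge.length, root_stem_length),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Dollo-parsimony reconstruction for one presence/absence character
#'
#' Under the Dollo constraint (exactly one gain, any number of subsequent
#' losses) the loss-minimising reconstruction places the gain on the branch
#' above the MRCA of all present leaves (the root stem when that MRCA is
#' the root) and one loss on the stem of each maximal all-absent subtree
#' below the gain node.
#'
#' @param tree rooted dated `phylo` tree.
#' @param presence named 0/1 vector over the tree's leaves.
#' @return list `gain_branch` (branch ID) and `loss_branches` (character).
#' @export
dollo_reconstruct <- function(tree, presence) {
  tips <- tree$tip.label
  missing <- setdiff(tips, names(presence))
  if (length(missing))
    stop("presence vector missing leaves: ", paste(missing, collapse = ", "))
  present <- names(presence)[presence[tips] == 1L & !is.na(presence[tips])]
  if (!length(present)) stop("all-absent presence vector")
  ntip <- ape::Ntip(tree)
  gain_node <- if (length(present) == 1L) match(present, tips)
  else ape::getMRCA(tree, present)
  gain <- branch_id(tree, if (gain_node == ntip + 1L) NA_integer_ else gain_node)
  losses <- character()
  if (gain_node > ntip) {
    kids <- tree_children(tree)
    walk <- function(node) {
      below <- clade_tips(tree, node)
      if (!any(presence[below] == 1L)) {
        losses <<- c(losses, branch_id(tree, node))
        return(invisible())
      }
      if (node > ntip) for (ch in kids[[node]]) walk(ch)
    }
    for (ch in kids[[gain_node]]) walk(ch)
  }
  list(gain_branch = gain, loss_branches = sort(losses))
}

#' Gain/loss counts and net rates over an orthogroup matrix
#'
#' Applies [dollo_reconstruct()] to every matrix row and aggregates gains
#' and losses per branch; net rate = (gains - losses) / branch length
#' (Myr). Root-stem gains are reported on the "root" branch, whose length
#' (and hence rate) is user-supplied since trees rarely date their stem.
#'
#' @param tree rooted dated `phylo` tree.
#' @param matrix orthogroup x species 0/1 matrix (colnames must be a subset
#'   of the tree's leaves).
#' @param root_stem_length optional root stem length in Myr.
#' @return list: `per_og` (og_id, gain_branch, n_losses, loss_branches) and
#'   `per_branch` (branch_id, length_myr, gains, losses, net_rate).
#' @export
count_gain_loss <- function(tree, matrix, root_stem_length = NA_real_) {
  unmatched <- setdiff(colnames(matrix), tree$tip.label)
  if (length(unmatched))
    stop("matrix species not in tree: ", paste(unmatched, collapse = ", "))
  br <- branch_table(tree, root_stem_length)
  gains <- stats::setNames(rep(0L, nrow(br)), br$branch_id)
  losses <- gains
  full <- stats::setNames(rep(0L, ape::Ntip(tree)), tree$tip.label)
  per_og <- vector("list", nrow(matrix))
  keep <- rep(TRUE, nrow(matrix))
  for (i in seq_len(nrow(matrix))) {
    pres <- full
    pres[colnames(matrix)] <- matrix[i, ]
    if (!any(pres == 1L)) {
      warning("row ", rownames(matrix)[i], " has no presence in the tree's ",
              "leaf set; skipped")
      keep[i] <- FALSE
      next
    }
    rec <- dollo_reconstruct(tree, pres)
    gains[rec$gain_branch] <- gains[rec$gain_branch] + 1L
    for (lb in rec$loss_branches) losses[lb] <- losses[lb] + 1L
    per_og[[i]] <- data.frame(
      og_id = if (is.null(rownames(matrix))) as.character(i) else rownames(matrix)[i],
      gain_branch = rec$gain_branch, n_losses = length(rec$loss_branches),
      loss_branches = paste(rec$loss_branches, collapse = ","),
      stringsAsFactors = FALSE)
  }
  per_branch <- data.frame(branch_id = br$branch_id,
                           length_myr = br$length_myr,
                           gains = as.integer(gains),
                           losses = as.integer(losses),
                           stringsAsFactors = FALSE)
  per_branch$net_rate <- ifelse(
    is.na(per_branch$length_myr), NA_real_,
    (per_branch$gains - per_branch$losses) / per_branch$length_myr)
  per_og <- do.call(rbind, per_og[keep])
  if (is.null(per_og))
    per_og <- data.frame(og_id = character(), gain_branch = character(),
                         n_losses = integer(), loss_branches = character(),
                         stringsAsFactors = FALSE)
  list(per_og = per_og, per_branch = per_branch)
}

#' Net gain rate on a branch
#' @param gains,losses integer counts.
#' @param branch_length_myr branch length in Myr (> 0).
#' @return (gains - losses) / branch_length_myr.
#' @export
net_rate <- function(gains, losses, branch_length_myr) {
  if (any(is.na(branch_length_myr)) || any(branch_length_myr <= 0))
    stop("branch length must be positive")
  (gains - losses) / branch_length_myr
}

#' Gain/loss turnover of seed families
#'
#' Identical contract to [count_gain_loss()] with rows keyed by 7-nt seed
#' sequence rather than orthogroup: a species keeps a seed as long as any
#' of its loci carries it, so the loss of one orthogroup can be compensated
#' by another sharing the seed.
#'
#' @inheritParams count_gain_loss
#' @param seed_presence seed x species 0/1 matrix (rownames = 7-mers).
#' @return as [count_gain_loss()].
#' @export
seed_family_turnover <- function(tree, seed_presence,
                                 root_stem_length = NA_real_) {
  count_gain_loss(tree, seed_presence, root_stem_length)
}
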