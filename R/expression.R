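#' Expression table for orthogroups across species and tissues
#'
#' @param counts data.frame `og_id`, `species`, `tissue`, `count`.
#' @param tissues ordered tissue panel (default the four profiled tissues).
#' @param presence_threshold minimum summed read count (over species) for a
#'   tissue to count as expressed (default 1).
#' @return list of class `expression_table`.
#' @export
expression_table <- function(counts,
                             tissues = c("brain", "heart", "kidney", "testis"),
                             presence_threshold = 1L) {
  stopifnot(all(c("og_id", "species", "tissue", "count") %in% names(counts)),
            all(counts$count >= 0))
  bad <- setdiff(unique(counts$tissue), tissues)
  if (length(bad)) stop("unknown tissue name(s): ", paste(bad, collapse = ", "))
  structure(list(counts = counts, tissues = tissues,
                 presence_threshold = as.integer(presence_threshold)),
            class = "expression_table")
}

.expressed_tissues <- function(table, og_id) {
  d <- table$counts[table$counts$og_id == og_id, , drop = FALSE]
  sums <- vapply(table$tissues, function(tt)
    sum(d$count[d$tissue == tt]), 0)
  table$tissues[sums >= table$presence_threshold]
}

#' Tissue-specificity category of an orthogroup in a focal tissue
#'
#' An orthogroup is expressed in a tissue iff its read count summed over
#' species reaches the presence threshold. For an expressed focal tissue
#' the category counts the additional expressed tissues: 0 ->
#' tissue_specific, 1 -> plus1, 2 -> plus2, 3 -> all_tissues; a silent
#' focal tissue is not_expressed.
#'
#' @param table an [expression_table()].
#' @param og_id orthogroup ID.
#' @param tissue focal tissue.
#' @return one of "not_expressed", "tissue_specific", "plus1", "plus2",
#'   "all_tissues".
#' @export
classify_specificity <- function(table, og_id, tissue) {
  if (!tissue %in% table$tissues)
    stop("unknown tissue name: ", tissue)
  expr <- .expressed_tissues(table, og_id)
  if (!tissue %in% expr) return("not_expressed")
  extra <- length(setdiff(expr, tissue))
  c("tissue_specific", "plus1", "plus2", "all_tissues")[extra + 1L]
}

#' Specificity categories for every (orthogroup, tissue) pair
#' @param table an [expression_table()].
#' @return data.frame `og_id`, `tissue`, `category`.
#' @export
specificity_table <- function(table) {
  ogs <- unique(table$counts$og_id)
  grid <- expand.grid(og_id = ogs, tissue = table$tissues,
                      stringsAsFactors = FALSE)
  grid$category <- mapply(function(og, tt)
    classify_specificity(table, og, tt), grid$og_id, grid$tissue)
  grid
}

#' Two-proportion z-test (pooled, two-sided)
#'
#' The standard pooled two-proportion z statistic with p-value from the
#' normal distribution, used to compare tissue-specific fractions between
#' novel and database-annotated orthogroup sets.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list `z`, `p` (two-sided).
#' @export
proportion_ztest <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  if (se == 0) return(list(z = 0, p = 1))
  z <- (p1 - p2) / se
  list(z = z, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Fraction of tissue-specific orthogroups among gains per branch
#'
#' For each branch, among the orthogroups whose Dollo gain lies on it and
#' that are expressed in the focal tissue, the fraction categorised
#' tissue_specific; branches with no qualifying gains report NA.
#'
#' @param gain_assignments data.frame `og_id`, `gain_branch`
#'   (from [count_gain_loss()]`$per_og`).
#' @param spec_df data.frame `og_id`, `tissue`, `category`
#'   (from [specificity_table()]).
#' @param tissue focal tissue.
#' @return named numeric vector, one fraction per branch with gains.
#' @export
branch_restriction <- function(gain_assignments, spec_df, tissue) {
  sd <- spec_df[spec_df$tissue == tissue, , drop = FALSE]
  cat_of <- stats::setNames(sd$category, sd$og_id)
  branches <- unique(gain_assignments$gain_branch)
  out <- stats::setNames(rep(NA_real_, length(branches)), branches)
  for (b in branches) {
    ogs <- gain_assignments$og_id[gain_assignments$gain_branch == b]
    cats <- cat_of[ogs]
    cats <- cats[!is.na(cats) & cats != "not_expressed"]
    if (length(cats)) out[b] <- mean(cats == "tissue_specific")
  }
  out
}

#' Hypergeometric overlap test between two gene sets
#'
#' Reports the overlap size, its expectation under random draws from the
#' background, the fold enrichment, and the upper-tail hypergeometric
#' p-value P(X >= k).
#'
#' @param set_a,set_b character vectors (subsets of `background`).
#' @param background character vector (the gene universe).
#' @return list `k`, `expected`, `fold`, `p_upper`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, background) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  background <- unique(background)
  bad <- c(setdiff(set_a, background), setdiff(set_b, background))
  if (length(bad))
    stop("set members outside background: ", paste(unique(bad), collapse = ", "))
  N <- length(background); K <- length(set_a); n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  expected <- K * n / N
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, expected = expected,
       fold = if (expected > 0) k / expected else NA_real_,
       p_upper = min(1, p))
}
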