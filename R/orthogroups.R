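.identity_matrix_cache <- new.env(parent = emptyenv())

.match_matrix <- function() {
  if (is.null(.identity_matrix_cache$m)) {
    .identity_matrix_cache$m <-
      Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0)
  }
  .identity_matrix_cache$m
}

#' Global-alignment identity of sequences against a reference
#'
#' Identity = identical aligned positions / length of the shorter sequence
#' (CD-HIT's global-identity convention). The maximum number of identical
#' positions is obtained from a Needleman-Wunsch alignment with match 1,
#' mismatch 0 and free gaps.
#'
#' @param seqs character vector of sequences.
#' @param ref single reference sequence.
#' @return numeric identities in [0, 1].
#' @export
seq_identity <- function(seqs, ref) {
  scores <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = .match_matrix(),
    gapOpening = 0, gapExtension = 0, scoreOnly = TRUE)
  scores / pmin(nchar(seqs), nchar(ref))
}

#' Greedy incremental identity clustering of loci into orthogroups
#'
#' CD-HIT semantics: sequences are sorted by length (descending, ties
#' broken lexicographically by ID), the first unassigned sequence seeds a
#' new cluster as its representative, and each subsequent sequence joins
#' the first existing cluster (in creation order) whose representative it
#' matches at or above the identity threshold. Deterministic for fixed
#' input, independent of input order.
#'
#' @param sequences named character vector of locus sequences.
#' @param identity_threshold minimum identity to the representative
#'   (default 0.8).
#' @return list of clusters, each `og_id`, `representative`, `members`.
#' @export
greedy_cluster <- function(sequences, identity_threshold = 0.8) {
  if (!length(sequences)) stop("empty sequence set")
  stopifnot(identity_threshold >= 0.5, identity_threshold <= 1.0,
            !is.null(names(sequences)))
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  reps <- character(); members <- list()
  for (i in seq_along(sequences)) {
    id <- names(sequences)[i]
    joined <- FALSE
    if (length(reps)) {
      # one vectorised alignment call: all representatives vs this sequence
      ident <- seq_identity(unname(sequences[reps]), sequences[[i]])
      hit <- which(ident >= identity_threshold)
      if (length(hit)) {
        k <- hit[1L]
        members[[k]] <- c(members[[k]], id)
        joined <- TRUE
      }
    }
    if (!joined) {
      reps <- c(reps, id)
      members[[length(reps)]] <- id
    }
  }
  lapply(seq_along(reps), function(k)
    list(og_id = sprintf("og%04d", k), representative = reps[k],
         members = members[[k]]))
}

#' Annotate cluster composition from locus statuses
#' @param clusters output of [greedy_cluster()].
#' @param status_of named character ("known"/"novel") per locus ID.
#' @return data.frame og_id, representative, n_members, composition
#'   (mirbase_only / novel_only / mixed).
#' @export
orthogroup_composition <- function(clusters, status_of) {
  do.call(rbind, lapply(clusters, function(cl) {
    st <- unique(status_of[cl$members])
    comp <- if (all(st == "known")) "mirbase_only"
    else if (all(st == "novel")) "novel_only" else "mixed"
    data.frame(og_id = cl$og_id, representative = cl$representative,
               n_members = length(cl$members), composition = comp,
               stringsAsFactors = FALSE)
  }))
}

#' Filter homology hits on e-value and alignment length
#'
#' Keeps exactly the hits with e-value at most `max_evalue` and alignment
#' length at least `min_len` nucleotides, the gate applied before any
#' synteny assessment.
#'
#' @param hits hit-record data.frame ([read_hit_table()]).
#' @param max_evalue e-value ceiling (default 1e-6).
#' @param min_len minimum alignment length in nt (default 40).
#' @return filtered data.frame.
#' @export
filter_hits <- function(hits, max_evalue = 1e-6, min_len = 40L) {
  hits[hits$evalue <= max_evalue & hits$align_len >= min_len, , drop = FALSE]
}

.flank_genes <- function(interval, genes) {
  same <- Filter(function(g) g$interval$seq_id == interval$seq_id &&
                   g$biotype == "protein_coding", genes)
  if (!length(same)) return(list(up = character(), down = character()))
  ids <- vapply(same, `[[`, "", "gene_id")
  starts <- vapply(same, function(g) g$interval$start, 0L)
  ends <- vapply(same, function(g) g$interval$end, 0L)
  containing <- ids[starts < interval$end & ends > interval$start]
  up <- ids[ends <= interval$start]
  up <- if (length(up)) up[which.max(ends[match(up, ids)])] else character()
  down <- ids[starts >= interval$end]
  down <- if (length(down)) down[which.min(starts[match(down, ids)])] else character()
  list(up = unique(c(containing, up)), down = unique(c(containing, down)))
}

#' Synteny support for a homology hit
#'
#' Finds the nearest protein-coding gene upstream and downstream of the
#' query locus and of the subject hit (a containing gene counts as both
#' flanks when the locus is intragenic) and returns TRUE iff at least one
#' flank pair (query gene, subject gene) are homologs per `homolog_map`,
#' after normalising flank orientation for reverse-orientation hits.
#'
#' @param query_interval,subject_interval single-row interval data.frames.
#' @param query_genes,subject_genes lists of `gene_model` on the respective
#'   assemblies.
#' @param homolog_map named character: query gene ID -> subject gene ID.
#' @param subject_orientation "forward" or "reverse" (from the hit record).
#' @return logical.
#' @export
synteny_support <- function(query_interval, subject_interval, query_genes,
                            subject_genes, homolog_map,
                            subject_orientation = "forward") {
  qf <- .flank_genes(query_interval, query_genes)
  sf <- .flank_genes(subject_interval, subject_genes)
  if (identical(subject_orientation, "reverse"))
    sf <- list(up = sf$down, down = sf$up)
  pair_ok <- function(qs, ss) {
    if (!length(qs) || !length(ss)) return(FALSE)
    any(stats::na.omit(homolog_map[qs]) %in% ss)
  }
  pair_ok(qf$up, sf$up) || pair_ok(qf$down, sf$down)
}

#' Build the orthogroup presence-absence matrix with evidence codes
#'
#' Presence of an orthogroup in a species is called when the species has an
#' annotated member locus, a synteny-supported homology hit, or an
#' annotated miRNA recovered among its unaligned reads; the evidence code
#' records the highest-priority source in that order.
#'
#' @param clusters output of [greedy_cluster()].
#' @param species_of named character: locus ID -> species.
#' @param species ordered character vector of species (matrix columns).
#' @param syntenic_hits data.frame `og_id`, `species` of synteny-supported
#'   hits (may be NULL).
#' @param unaligned_read_matches data.frame `og_id`, `species` (may be NULL).
#' @return list `presence` (integer matrix) and `evidence` (character
#'   matrix over \{annotated, synteny_homolog, unaligned_read, absent\}).
#' @export
build_matrix <- function(clusters, species_of, species,
                         syntenic_hits = NULL,
                         unaligned_read_matches = NULL) {
  ogs <- vapply(clusters, `[[`, "", "og_id")
  pres <- matrix(0L, length(ogs), length(species),
                 dimnames = list(ogs, species))
  evid <- matrix("absent", length(ogs), length(species),
                 dimnames = list(ogs, species))
  set_cell <- function(og, sp, code) {
    if (!og %in% ogs || !sp %in% species)
      stop("unknown orthogroup/species: ", og, "/", sp)
    pri <- c(annotated = 3L, synteny_homolog = 2L, unaligned_read = 1L,
             absent = 0L)
    if (pri[[code]] > pri[[evid[og, sp]]]) evid[og, sp] <<- code
    pres[og, sp] <<- 1L
  }
  for (cl in clusters) {
    for (sp in unique(stats::na.omit(species_of[cl$members])))
      set_cell(cl$og_id, sp, "annotated")
  }
  if (!is.null(syntenic_hits) && nrow(syntenic_hits))
    for (i in seq_len(nrow(syntenic_hits)))
      set_cell(syntenic_hits$og_id[i], syntenic_hits$species[i],
               "synteny_homolog")
  if (!is.null(unaligned_read_matches) && nrow(unaligned_read_matches))
    for (i in seq_len(nrow(unaligned_read_matches)))
      set_cell(unaligned_read_matches$og_id[i],
               unaligned_read_matches$species[i], "unaligned_read")
  keep <- rowSums(pres) > 0L
  list(presence = pres[keep, , drop = FALSE],
       evidence = evid[keep, , drop = FALSE])
}
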