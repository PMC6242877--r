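#' Construct a table of genomic intervals
#'
#' All coordinates inside the package are 0-based half-open (`start`
#' inclusive, `end` exclusive); conversions from 1-based formats (GFF3,
#' outfmt6) happen only at the I/O boundary.
#'
#' @param seq_id character vector of contig names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand character vector of "+"/"-".
#' @param name optional record names.
#' @return A data.frame with columns `seq_id`, `start`, `end`, `strand`
#'   (and `name` when given).
#' @export
gintervals <- function(seq_id, start, end, strand, name = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-integer interval coordinates")
  if (any(start < 0L)) stop("negative start coordinate")
  if (any(start >= end)) stop("interval with start >= end")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df <- data.frame(seq_id = as.character(seq_id), start = start, end = end,
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  df
}

#' Overlap length of two half-open intervals on a shared axis
#' @param s1,e1,s2,e2 interval bounds (vectors recycle).
#' @return integer overlap lengths (0 when disjoint).
#' @export
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and U is normalised to T, so genomic and
#' small-RNA inputs share one DNA alphabet. IDs are the first
#' whitespace-delimited header token.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences over \{A,C,G,T,N\}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ID: ", ids[duplicated(ids)][1L], " in ", path)
  if (any(!nzchar(seqs)))
    stop("empty sequence for ID: ", ids[!nzchar(seqs)][1L], " in ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTUN characters in sequence: ", ids[bad][1L], " in ", path)
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(chartr("U", "T", toupper(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a BED6 file
#'
#' BED is interpreted 0-based half-open. Records are kept in file order and
#' malformed lines are rejected with their line number; strand is required
#' ("." is an error because all downstream overlap logic is stranded).
#'
#' @param path BED file with >= 6 tab-separated columns.
#' @return data.frame `seq_id,start,end,strand,name,score`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) stop("empty BED file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 6L)
      stop(path, " line ", i, ": need >= 6 BED columns, got ", length(p))
    s <- suppressWarnings(as.integer(p[2L])); e <- suppressWarnings(as.integer(p[3L]))
    if (is.na(s) || is.na(e))
      stop(path, " line ", i, ": non-numeric coordinates")
    if (s >= e)
      stop(path, " line ", i, ": start >= end (", s, " >= ", e, ")")
    if (!(p[6L] %in% c("+", "-")))
      stop(path, " line ", i, ": strand must be '+' or '-', got '", p[6L], "'")
    out[[i]] <- data.frame(seq_id = p[1L], start = s, end = e, strand = p[6L],
                           name = p[4L],
                           score = suppressWarnings(as.numeric(p[5L])),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write intervals as BED6
#' @param intervals data.frame from [gintervals()] (a `name` column is used
#'   when present, else row index).
#' @param path output file.
#' @param score score column value (default 0).
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, score = 0) {
  nm <- if (!is.null(intervals$name)) intervals$name else seq_len(nrow(intervals))
  writeLines(paste(intervals$seq_id, intervals$start, intervals$end,
                   nm, score, intervals$strand, sep = "\t"), path)
  invisible(path)
}

#' A gene model with exon/CDS structure
#'
#' @param gene_id gene identifier.
#' @param interval single-row interval data.frame (gene span).
#' @param exons interval data.frame of exons (same contig/strand).
#' @param cds interval data.frame of coding segments (may be empty).
#' @param biotype biotype string.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, interval, exons, cds = NULL, biotype = "protein_coding") {
  stopifnot(nrow(interval) == 1L, nrow(exons) >= 1L)
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$start < interval$start) || any(exons$end > interval$end))
    stop("gene ", gene_id, ": exon outside gene span")
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("gene ", gene_id, ": overlapping exons")
  if (is.null(cds)) cds <- exons[0, , drop = FALSE]
  if (nrow(cds)) cds <- cds[order(cds$start), , drop = FALSE]
  structure(list(gene_id = gene_id, interval = interval, exons = exons,
                 cds = cds, biotype = biotype),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, sprintf("%s:%d-%d(%s)", x$interval$seq_id,
      x$interval$start, x$interval$end, x$interval$strand),
      nrow(x$exons), "exons,", nrow(x$cds), "CDS segments\n")
  invisible(x)
}

#' Introns of a gene model
#' @param gene a `gene_model`.
#' @return interval data.frame of the gaps between sorted exons (0 rows for
#'   single-exon genes).
#' @export
gene_introns <- function(gene) {
  ex <- gene$exons
  if (nrow(ex) < 2L) return(ex[0, c("seq_id", "start", "end", "strand")])
  gintervals(ex$seq_id[1L], ex$end[-nrow(ex)], ex$start[-1L], ex$strand[1L])
}

#' Read gene models from GFF3
#'
#' Parses gene/exon/CDS features (1-based inclusive) and converts to the
#' internal 0-based half-open convention. Exons are attached to genes via
#' Parent chains (transcript level is collapsed).
#'
#' @param path GFF3 file.
#' @return named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  type <- tolower(as.character(df$type))
  genes <- df[type == "gene", , drop = FALSE]
  if (!nrow(genes)) stop("no gene features in ", path)
  if (any(is.na(genes$ID)) || any(!nzchar(genes$ID)))
    stop("gene feature without ID/gene_id in ", path)
  # map transcript ID -> gene ID so exon Parents resolve either way
  tx <- df[type %in% c("mrna", "transcript"), , drop = FALSE]
  parent_of <- function(x) vapply(x, function(p) if (length(p)) p[[1L]] else NA_character_, "")
  tx2gene <- if (nrow(tx)) stats::setNames(parent_of(tx$Parent), tx$ID) else character()
  resolve <- function(p) {
    if (is.na(p)) return(NA_character_)
    if (p %in% names(tx2gene)) tx2gene[[p]] else p
  }
  models <- vector("list", nrow(genes))
  names(models) <- genes$ID
  feat_gene <- vapply(parent_of(df$Parent), resolve, "")
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    gi <- gintervals(genes$seqnames[i], genes$start[i] - 1L, genes$end[i],
                     genes$strand[i])
    sel_e <- type == "exon" & feat_gene == gid
    sel_c <- type == "cds" & feat_gene == gid
    if (!any(sel_e)) sel_e <- sel_c  # CDS-only annotations
    if (!any(sel_e)) {
      models[[i]] <- gene_model(gid, gi, gi, biotype = genes$source[i])
      next
    }
    ex <- gintervals(df$seqnames[sel_e], df$start[sel_e] - 1L, df$end[sel_e],
                     df$strand[sel_e])
    # merge duplicate exons contributed by multiple transcripts
    ex <- merge_candidates(ex)
    cds <- if (any(sel_c))
      merge_candidates(gintervals(df$seqnames[sel_c], df$start[sel_c] - 1L,
                                  df$end[sel_c], df$strand[sel_c]))
    else NULL
    bt <- if (!is.null(genes$biotype)) genes$biotype[i] else "protein_coding"
    models[[i]] <- gene_model(gid, gi, ex, cds, biotype = bt)
  }
  models
}

#' Read a 12-column tabular alignment table (outfmt6 layout)
#'
#' Columns: query, subject, percent identity, alignment length, mismatches,
#' gap opens, qstart, qend, sstart, send, evalue, bit score; spans are
#' 1-based inclusive. Subject orientation is inferred from sstart/send order
#' and subject coordinates are normalised to the forward strand.
#'
#' @param path tab-separated file.
#' @return data.frame of hit records with an `orientation` column.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 12L)
      stop(path, " line ", i, ": expected 12 columns, got ", length(p))
    num <- suppressWarnings(as.numeric(p[3:12]))
    if (anyNA(num))
      stop(path, " line ", i, ": non-numeric field")
    sstart <- num[7L]; send <- num[8L]
    rev <- sstart > send
    out[[i]] <- data.frame(
      query_id = p[1L], subject_id = p[2L], identity_pct = num[1L],
      align_len = as.integer(num[2L]), mismatches = as.integer(num[3L]),
      gap_opens = as.integer(num[4L]),
      qstart = as.integer(num[5L]), qend = as.integer(num[6L]),
      sstart = as.integer(min(sstart, send)), send = as.integer(max(sstart, send)),
      evalue = num[9L], bit_score = num[10L],
      orientation = if (rev) "reverse" else "forward",
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(query_id = character(), subject_id = character(),
                      identity_pct = numeric(), align_len = integer(),
                      mismatches = integer(), gap_opens = integer(),
                      qstart = integer(), qend = integer(), sstart = integer(),
                      send = integer(), evalue = numeric(),
                      bit_score = numeric(), orientation = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Read a rooted dated tree from Newick
#'
#' @param path Newick file; branch lengths in Myr required.
#' @return an [ape::phylo] tree, validated rooted with a binary root,
#'   positive branch lengths and unique leaf names.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  validate_dated_tree(tree)
  tree
}

#' Validate a dated species tree
#' @param tree an `ape::phylo`.
#' @return the tree, invisibly; errors on violation.
#' @export
validate_dated_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length <= 0)) stop("tree has non-positive branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names in tree")
  root <- ape::Ntip(tree) + 1L
  if (sum(tree$edge[, 1L] == root) != 2L)
    stop("tree root must be bifurcating (rooted binary root)")
  invisible(tree)
}

#' Read a per-base conservation score track
#'
#' Accepts bedGraph or fixed-step wiggle; positions are held sparsely per
#' contig and positions without data are missing (NA), never 0 -- real
#' conservation tracks have gaps.
#'
#' @param path bedGraph or fixedStep wig file.
#' @return a `score_track` object queryable with [score_at()].
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- if (any(startsWith(readLines(path, n = 5L), "fixedStep"))) "wig" else "bedGraph"
  df <- as.data.frame(rtracklayer::import(path, format = fmt))
  score_track(as.character(df$seqnames), df$start - 1L, df$end, df$score)
}

#' Build a score track from run-length intervals
#' @param seq_id,start,end half-open runs (0-based).
#' @param score per-run score.
#' @return `score_track` object.
#' @export
score_track <- function(seq_id, start, end, score) {
  df <- data.frame(seq_id = as.character(seq_id), start = as.integer(start),
                   end = as.integer(end), score = as.numeric(score),
                   stringsAsFactors = FALSE)
  runs <- split(df[c("start", "end", "score")], df$seq_id)
  runs <- lapply(runs, function(d) d[order(d$start), , drop = FALSE])
  structure(list(runs = runs), class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat("score_track over", length(x$runs), "contigs,",
      sum(vapply(x$runs, nrow, 0L)), "runs\n")
  invisible(x)
}

#' Query per-base scores
#' @param track a `score_track`.
#' @param seq_id single contig name.
#' @param positions integer vector of 0-based positions.
#' @return numeric vector of scores; NA where the track has no data.
#' @export
score_at <- function(track, seq_id, positions) {
  d <- track$runs[[seq_id]]
  if (is.null(d)) return(rep(NA_real_, length(positions)))
  idx <- findInterval(positions, d$start)
  out <- rep(NA_real_, length(positions))
  hit <- idx >= 1L
  hit[hit] <- positions[hit] < d$end[idx[hit]]
  out[hit] <- d$score[idx[hit]]
  out
}

#' Read / write an orthogroup presence-absence matrix
#'
#' TSV layout: header row of species names, first column orthogroup IDs,
#' cells in \{0,1\}.
#'
#' @param path TSV file.
#' @return integer matrix, rows = orthogroups, columns = species.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix needs an ID column plus species columns")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  if (anyNA(m) || any(!m %in% c(0L, 1L)))
    stop("matrix cells must all be 0 or 1 in ", path)
  m
}

#' @rdname read_matrix
#' @param mat integer 0/1 matrix with dimnames.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(orthogroup = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse complement (DNA, U-free)
#' @param x character vector of sequences.
#' @return reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
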