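#' Alignment utilities and summary statistics
#'
#' Alignments are character matrices over `{A,C,G,T,-,N}` with unique row
#' names; `-` and (by default) `N` count as missing for both column
#' occupancy and parsimony informativeness.
#'
#' @name alnstats
NULL

#' Build an alignment matrix from sequence strings
#'
#' @param seqs named character vector of equal-length sequences.
#' @return character matrix with one row per sequence.
#' @export
as_alignment <- function(seqs) {
  if (is.matrix(seqs)) return(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) stop("sequences differ in length", call. = FALSE)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("alignment rows need unique names", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Collapse an alignment matrix back to strings
#'
#' @param a alignment matrix.
#' @return named character vector.
#' @export
alignment_strings <- function(a) {
  out <- apply(a, 1, paste, collapse = "")
  names(out) <- rownames(a)
  out
}

#' Read / write a FASTA alignment
#'
#' @param path file path.
#' @return `read_fasta_alignment()` returns an alignment matrix.
#' @export
read_fasta_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(x) paste(toupper(x), collapse = ""),
                 character(1))
  as_alignment(seqs)
}

#' @param a alignment matrix.
#' @rdname read_fasta_alignment
#' @export
write_fasta_alignment <- function(a, path) {
  seqs <- alignment_strings(a)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  invisible(path)
}

#' Remove low-occupancy alignment columns
#'
#' Keeps a column iff the fraction of rows carrying a non-missing character
#' is at least `min_occupancy` (boundary inclusive). By default both `-` and
#' `N` count as missing.
#'
#' @param a alignment matrix.
#' @param min_occupancy minimum occupied fraction, in (0, 1] (default 0.10).
#' @param missing_chars characters treated as missing.
#' @return alignment with the same rows and a subset of columns.
#' @export
clean_columns <- function(a, min_occupancy = 0.10,
                          missing_chars = c("-", "N")) {
  stopifnot(min_occupancy > 0, min_occupancy <= 1)
  if (ncol(a) == 0L) return(a)
  occ <- colMeans(!matrix(a %in% missing_chars, nrow(a), ncol(a)))
  a[, occ >= min_occupancy, drop = FALSE]
}

#' Concatenate gene alignments into a supermatrix
#'
#' Rows are the union of all row names; a row absent from a gene is filled
#' with `-` across that gene's span. Partition records give each gene's
#' 1-based inclusive column range.
#'
#' @param alns named list of alignment matrices (names are gene ids).
#' @return list with `alignment` and `partitions` (data frame `gene_id`,
#'   `start`, `end`).
#' @export
concatenate_alignments <- function(alns) {
  stopifnot(length(alns) >= 1L)
  if (is.null(names(alns)) || anyDuplicated(names(alns))) {
    stop("gene ids must be unique and named", call. = FALSE)
  }
  all_rows <- unique(unlist(lapply(alns, rownames)))
  lens <- vapply(alns, ncol, integer(1))
  total <- sum(lens)
  out <- matrix("-", length(all_rows), total,
                dimnames = list(all_rows, NULL))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  for (i in seq_along(alns)) {
    a <- alns[[i]]
    out[rownames(a), starts[i]:ends[i]] <- a
  }
  list(alignment = out,
       partitions = data.frame(gene_id = names(alns),
                               start = as.integer(starts),
                               end = as.integer(ends)))
}

#' Split a supermatrix back into gene blocks
#'
#' @param a concatenated alignment.
#' @param partitions partition data frame from [concatenate_alignments()].
#' @return named list of alignment matrices.
#' @export
split_by_partitions <- function(a, partitions) {
  out <- lapply(seq_len(nrow(partitions)), function(i) {
    a[, partitions$start[i]:partitions$end[i], drop = FALSE]
  })
  names(out) <- partitions$gene_id
  out
}

#' Count parsimony-informative sites
#'
#' A column is informative when at least two distinct non-missing states
#' each occur in at least two rows.
#'
#' @param a alignment matrix.
#' @param missing_chars characters ignored when tallying states.
#' @return integer count.
#' @export
parsimony_informative_sites <- function(a, missing_chars = c("-", "N")) {
  if (ncol(a) == 0L) return(0L)
  sum(apply(a, 2, function(col) {
    tab <- table(col[!(col %in% missing_chars)])
    sum(tab >= 2L) >= 2L
  }))
}

#' Total tree length
#'
#' Sum of all branch lengths (invariant under re-rooting).
#'
#' @param tree a `phylo`.
#' @return numeric total, in subs/site.
#' @export
tree_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) return(0)
  sum(tree$edge.length)
}

#' Write RAxML-style partition text
#'
#' One line per gene: `DNA, gene1 = 1-100`.
#'
#' @param partitions partition data frame.
#' @param path output file.
#' @export
write_partitions_raxml <- function(partitions, path) {
  writeLines(sprintf("DNA, %s = %d-%d", partitions$gene_id,
                     partitions$start, partitions$end), path)
}

#' Summary statistics for an alignment
#'
#' @param a alignment matrix.
#' @return one-row data frame: rows, columns, occupancy (mean non-missing
#'   fraction) and parsimony-informative site count.
#' @export
alignment_stats <- function(a) {
  miss <- matrix(a %in% c("-", "N"), nrow(a), ncol(a))
  data.frame(n_rows = nrow(a), n_cols = ncol(a),
             occupancy = if (length(a)) mean(!miss) else NA_real_,
             informative_sites = parsimony_informative_sites(a))
}
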