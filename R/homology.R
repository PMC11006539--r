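#' Homolog clustering
#'
#' Builds homolog clusters from per-sample coding sequences: greedy
#' redundancy reduction within each sample (cd-hit-style, default identity
#' 0.99), an all-by-all k-mer-seeded similarity graph across samples, Markov
#' clustering (default inflation 1.4) and retention of clusters spanning at
#' least four taxa.
#'
#' Sequence records are data frames with columns `id` (`"<sample>@<copy>"`),
#' `sample_id`, `copy_index` and `seq` (alphabet A, C, G, T, N; `-` is
#' tolerated as alignment padding and ignored by the k-mer seeding).
#'
#' @name homology
NULL

#' Construct sequence records for one sample
#'
#' @param sample_id sample identifier.
#' @param seqs character vector of nucleotide sequences.
#' @param copy_index optional copy indices (default `seq_along(seqs)`).
#' @return data frame with columns `id`, `sample_id`, `copy_index`, `seq`.
#' @export
sequence_records <- function(sample_id, seqs, copy_index = seq_along(seqs)) {
  stopifnot(length(sample_id) == 1L, length(seqs) == length(copy_index))
  if (length(seqs) == 0L) {
    return(data.frame(id = character(), sample_id = character(),
                      copy_index = integer(), seq = character()))
  }
  data.frame(id = paste0(sample_id, "@", copy_index),
             sample_id = sample_id,
             copy_index = as.integer(copy_index),
             seq = toupper(seqs))
}

# identity of record a against a representative at least as long:
# matches divided by the length of the shorter sequence; exact containment
# counts as identity 1, otherwise the comparison is ungapped at offset 0
pair_identity_short <- function(short, long) {
  ns <- nchar(short)
  nl <- nchar(long)
  if (ns == 0L) return(0)
  if (ns < nl && grepl(short, long, fixed = TRUE)) return(1)
  a <- strsplit(short, "")[[1]]
  b <- strsplit(substr(long, 1L, ns), "")[[1]]
  sum(a == b) / ns
}

#' Greedy redundancy reduction within one sample
#'
#' Longest-first greedy clustering: records are visited by decreasing length
#' (ties broken lexicographically by `id`); a record joins the first existing
#' representative with identity at or above the threshold, otherwise it
#' founds a new representative. Identity is matches divided by the shorter
#' length, with exact containment counting as 1. Only representatives are
#' returned, so the longest member of every cluster survives.
#'
#' @param records sequence records from a single sample.
#' @param identity_threshold identity needed to absorb a record (default
#'   0.99).
#' @return the representative subset of `records`, in visiting order.
#' @export
reduce_redundancy <- function(records, identity_threshold = 0.99) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (nrow(records) == 0L) return(records)
  if (length(unique(records$sample_id)) > 1L) {
    stop("reduce_redundancy() operates on one sample at a time", call. = FALSE)
  }
  ord <- order(-nchar(records$seq), records$id)
  records <- records[ord, , drop = FALSE]
  reps <- integer(0)
  for (i in seq_len(nrow(records))) {
    absorbed <- FALSE
    for (r in reps) {
      if (pair_identity_short(records$seq[i], records$seq[r]) >= identity_threshold) {
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) reps <- c(reps, i)
  }
  out <- records[reps, , drop = FALSE]
  rownames(out) <- NULL
  out
}

kmer_positions <- function(seq, k, stride) {
  n <- nchar(seq)
  if (n < k) return(data.frame(kmer = character(), pos = integer()))
  pos <- seq.int(1L, n - k + 1L, by = stride)
  km <- substring(seq, pos, pos + k - 1L)
  keep <- !grepl("[^ACGT]", km)
  data.frame(kmer = km[keep], pos = pos[keep])
}

#' Build an all-by-all similarity graph
#'
#' Pairs of records sharing at least one exact k-mer (seeds sampled every
#' `stride` positions) are compared by an ungapped alignment at the offset
#' implied by their first shared seed; an edge is stored when identity over
#' the non-gap overlap reaches `min_identity`. This is the in-package
#' stand-in for an all-by-all blastn search; it assumes homologous records
#' share exact seeds at a common offset, which holds for high-identity
#' coding sequences without indels.
#'
#' @param records combined representative records from all samples.
#' @param min_identity minimum identity for an edge (default 0.7).
#' @param k seed k-mer length (default 12).
#' @param stride sampling step between seed start positions (default 5).
#' @return a `similarity_graph`: list with `vertices` (record ids) and
#'   `edges` (data frame `u`, `v`, `weight`).
#' @export
build_similarity_graph <- function(records, min_identity = 0.7, k = 12L,
                                   stride = 5L) {
  stopifnot(nrow(records) >= 2L)
  n <- nrow(records)
  tabs <- lapply(records$seq, kmer_positions, k = k, stride = stride)
  km_all <- data.frame(
    kmer = unlist(lapply(tabs, `[[`, "kmer")),
    pos = unlist(lapply(tabs, `[[`, "pos")),
    rec = rep.int(seq_len(n), vapply(tabs, nrow, integer(1))))
  # one entry per (k-mer, record): the record's first occurrence
  km_all <- km_all[!duplicated(km_all[c("kmer", "rec")]), , drop = FALSE]
  edges <- data.frame(u = character(), v = character(), weight = numeric())
  if (nrow(km_all) > 0L) {
    buckets <- split(seq_len(nrow(km_all)), km_all$kmer)
    buckets <- buckets[lengths(buckets) > 1L]
    # first-shared-seed offset per candidate pair
    seen <- new.env(hash = TRUE, parent = emptyenv())
    pair_i <- integer(0); pair_j <- integer(0); pair_off <- integer(0)
    for (ix in buckets) {
      recs <- km_all$rec[ix]
      pos <- km_all$pos[ix]
      ord <- order(recs)
      recs <- recs[ord]; pos <- pos[ord]
      for (a in seq_len(length(recs) - 1L)) {
        for (b in (a + 1L):length(recs)) {
          key <- paste0(recs[a], "_", recs[b])
          if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            pair_i <- c(pair_i, recs[a])
            pair_j <- c(pair_j, recs[b])
            pair_off <- c(pair_off, pos[a] - pos[b])
          }
        }
      }
    }
    if (length(pair_i) > 0L) {
      chars <- lapply(records$seq, function(s) strsplit(s, "")[[1]])
      w <- vapply(seq_along(pair_i), function(p) {
        idy <- offset_identity_chars(chars[[pair_i[p]]], chars[[pair_j[p]]],
                                     pair_off[p])
        if (is.na(idy)) -1 else idy
      }, numeric(1))
      keep <- w >= min_identity
      if (any(keep)) {
        edges <- data.frame(u = records$id[pair_i[keep]],
                            v = records$id[pair_j[keep]],
                            weight = w[keep])
      }
    }
  }
  rownames(edges) <- NULL
  structure(list(vertices = records$id, edges = edges),
            class = "similarity_graph")
}

# identity of a vs b when a[off + i] aligns with b[i]; gaps/N excluded
offset_identity <- function(a, b, off) {
  offset_identity_chars(strsplit(a, "")[[1]], strsplit(b, "")[[1]], off)
}

offset_identity_chars <- function(av, bv, off) {
  ia <- max(1L, 1L + off); ib <- max(1L, 1L - off)
  len <- min(length(av) - ia, length(bv) - ib) + 1L
  if (len < 1L) return(NA_real_)
  sa <- av[ia:(ia + len - 1L)]
  sb <- bv[ib:(ib + len - 1L)]
  ok <- !(sa %in% c("-", "N")) & !(sb %in% c("-", "N"))
  if (!any(ok)) return(NA_real_)
  sum(sa[ok] == sb[ok]) / sum(ok)
}

#' Markov clustering of a similarity graph
#'
#' Runs MCL on the weighted adjacency matrix with self-loops (weight equal to
#' the vertex's maximum incident weight, 1 for isolated vertices): columns
#' are normalized to stochastic form, then expansion (matrix square) and
#' inflation (elementwise power, renormalize, prune entries below `prune`)
#' alternate until the matrix changes by less than `tol` or `max_iter`
#' rounds. Clusters are the connected components of the limit matrix, so
#' every vertex lands in exactly one cluster.
#'
#' @param g a `similarity_graph`.
#' @param inflation inflation exponent, > 1 (default 1.4).
#' @param prune entries below this are zeroed each round (default 1e-8).
#' @param tol convergence tolerance on the max absolute change (default 1e-6).
#' @param max_iter iteration cap (default 100); if reached, the current
#'   partition is returned with attribute `converged = FALSE` and a warning.
#' @return list of character vectors of vertex ids (a partition of
#'   `g$vertices`), with logical attribute `converged`.
#' @export
markov_cluster <- function(g, inflation = 1.4, prune = 1e-8, tol = 1e-6,
                           max_iter = 100L) {
  stopifnot(inflation > 1)
  verts <- g$vertices
  n <- length(verts)
  if (n == 0L) return(structure(list(), converged = TRUE))
  M <- matrix(0, n, n, dimnames = list(verts, verts))
  if (nrow(g$edges) > 0L) {
    iu <- match(g$edges$u, verts)
    iv <- match(g$edges$v, verts)
    M[cbind(iu, iv)] <- g$edges$weight
    M[cbind(iv, iu)] <- g$edges$weight
  }
  loop <- apply(M, 2, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  M <- sweep(M, 2, colSums(M), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    prev <- M
    M <- M %*% M                      # expansion
    M <- M^inflation                  # inflation
    M[M < prune] <- 0
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2, cs, "/")
    if (max(abs(M - prev)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("markov_cluster: no convergence after ", max_iter,
                          " iterations; returning current partition")
  # components of the symmetrized nonzero pattern
  adj <- (M > 0) | (t(M) > 0)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  out <- unname(split(verts, comp))
  structure(out, converged = converged)
}

#' Retain clusters spanning enough taxa
#'
#' A cluster's taxa are the distinct sample ids of its members (the part of
#' each record id before `@`). Clusters with fewer than `min_taxa` taxa are
#' dropped.
#'
#' @param clusters list of character vectors of record ids.
#' @param min_taxa minimum distinct-taxon count (default 4).
#' @return list with `clusters` (kept, each with a `taxa` attribute), and
#'   counts `n_kept` / `n_dropped`.
#' @export
filter_clusters <- function(clusters, min_taxa = 4L) {
  kept <- list()
  for (cl in clusters) {
    taxa <- unique(tip_taxon(cl))
    if (length(taxa) >= min_taxa) {
      kept[[length(kept) + 1L]] <- structure(cl, taxa = taxa)
    }
  }
  list(clusters = kept, n_kept = length(kept),
       n_dropped = length(clusters) - length(kept))
}

#' Write cluster membership as TSV
#'
#' Columns: `cluster_id`, `sample_id`, `copy_index`.
#'
#' @param clusters list of character vectors of record ids.
#' @param path output file.
#' @export
write_cluster_tsv <- function(clusters, path) {
  rows <- lapply(seq_along(clusters), function(i) {
    ids <- clusters[[i]]
    data.frame(cluster_id = sprintf("cluster_%04d", i),
               sample_id = tip_taxon(ids),
               copy_index = sub("^.*@", "", ids))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(), sample_id = character(),
               copy_index = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
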