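#' Genotype PCA and Hardy-Weinberg diagnostics
#'
#' Builds a samples x sites alt-allele-count matrix from filtered variants,
#' standardizes it EIGENSTRAT-style, performs PCA via eigendecomposition of
#' the sample covariance, reports per-site heterozygosity against the
#' Hardy-Weinberg expectation, and scores recovery of known layer structure
#' with a best-permutation k-means agreement.
#'
#' @name popstruct
NULL

#' Alt-allele-count genotype matrix from a variant set
#'
#' Counts copies of allele 1 in each genotype (0, 1 or 2; `NA` when
#' missing). Rows are samples, columns sites (`locus:pos`).
#'
#' @param vs a `variant_set`.
#' @return integer matrix (samples x sites).
#' @export
genotype_matrix <- function(vs) {
  alt_count <- function(g) {
    if (is.na(g)) return(NA_integer_)
    sum(as.integer(strsplit(g, "/", fixed = TRUE)[[1]]) == 1L)
  }
  G <- t(apply(vs$gt, 1, function(row) vapply(row, alt_count, integer(1))))
  if (n_sites(vs) == 1L) G <- matrix(G, nrow = 1L)
  G <- t(G)  # samples x sites
  rownames(G) <- vs$samples
  colnames(G) <- paste0(vs$meta$locus_id, ":", vs$meta$pos)
  G
}

#' EIGENSTRAT-style genotype standardization
#'
#' Per column, with allele frequency p = mean(g)/2 over non-missing entries,
#' each entry becomes (g - 2p) / sqrt(2p(1-p)); missing entries contribute 0
#' after centring (mean imputation). Columns with zero variance (monomorphic
#' or constant) are dropped with a warning.
#'
#' @param G genotype matrix from [genotype_matrix()].
#' @return numeric matrix (samples x retained sites).
#' @export
standardize_genotypes <- function(G) {
  p <- colMeans(G, na.rm = TRUE) / 2
  varies <- apply(G, 2, function(g) {
    g <- g[!is.na(g)]
    length(unique(g)) > 1L
  })
  keep <- varies & p > 0 & p < 1
  if (!any(keep)) stop("all genotype columns have zero variance", call. = FALSE)
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance column(s) dropped before PCA")
  }
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  S <- sweep(G, 2, 2 * p, "-")
  S <- sweep(S, 2, sqrt(2 * p * (1 - p)), "/")
  S[is.na(S)] <- 0
  S
}

#' Principal component analysis of standardized genotypes
#'
#' Eigendecomposition of the n x n sample covariance S S^T / m. Coordinates
#' are the top-k eigenvectors scaled by sqrt(eigenvalue); explained
#' fractions are eigenvalues over the trace. Each component is oriented so
#' its largest-magnitude coordinate is positive.
#'
#' @param S standardized matrix from [standardize_genotypes()].
#' @param k number of components (default `min(n - 1, m, 10)`).
#' @return list with `coordinates` (n x k, rownames = samples) and
#'   `explained_fraction` (length k, non-increasing).
#' @export
genotype_pca <- function(S, k = NULL) {
  n <- nrow(S)
  m <- ncol(S)
  if (is.null(k)) k <- min(n - 1L, m, 10L)
  stopifnot(k >= 1L, k <= min(n - 1L, m))
  C <- S %*% t(S) / m
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  tot <- sum(vals)
  coords <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
    coords[, j] <- coords[, j] * sqrt(vals[j])
  }
  rownames(coords) <- rownames(S)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coordinates = coords,
       explained_fraction = vals[seq_len(k)] / tot)
}

#' Observed vs Hardy-Weinberg expected heterozygosity
#'
#' Per site: allele frequency from non-missing genotypes, the observed
#' heterozygote fraction, and the expected 2p(1-p).
#'
#' @param G genotype matrix (samples x sites).
#' @return data frame `site`, `p_hat`, `observed_het`, `expected_het`,
#'   `n_called`.
#' @export
het_vs_hwe <- function(G) {
  res <- lapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    g <- g[!is.na(g)]
    n <- length(g)
    p <- if (n > 0) mean(g) / 2 else NA_real_
    data.frame(site = colnames(G)[j],
               p_hat = p,
               observed_het = if (n > 0) mean(g == 1L) else NA_real_,
               expected_het = 2 * p * (1 - p),
               n_called = n)
  })
  do.call(rbind, res)
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

#' Best-permutation agreement of k-means clusters with known labels
#'
#' Runs k-means on the first two PCA axes (k = number of distinct truth
#' labels unless given) and returns the best agreement over all label
#' permutations, in [0, 1].
#'
#' @param pca result of [genotype_pca()] (or any matrix whose first two
#'   columns are coordinates).
#' @param truth vector of true layer labels, one per sample.
#' @param k number of clusters (default: distinct truth labels).
#' @param nstart k-means restarts (default 25).
#' @return agreement fraction in [0, 1].
#' @export
cluster_recovery <- function(pca, truth, k = NULL, nstart = 25L) {
  coords <- if (is.list(pca)) pca$coordinates else pca
  stopifnot(nrow(coords) == length(truth))
  truth <- as.integer(factor(truth))
  if (is.null(k)) k <- length(unique(truth))
  xy <- coords[, seq_len(min(2L, ncol(coords))), drop = FALSE]
  cl <- if (k == 1L) rep(1L, nrow(xy)) else
    stats::kmeans(xy, centers = k, nstart = nstart)$cluster
  n_lab <- length(unique(truth))
  if (k == n_lab) {
    best <- 0
    for (perm in all_permutations(seq_len(k))) {
      best <- max(best, mean(perm[cl] == truth))
    }
    best
  } else {
    # unequal cardinality: map each cluster to its modal truth label
    sum(vapply(split(truth, cl), function(tr) max(table(tr)), numeric(1))) /
      length(truth)
  }
}

#' Write PCA coordinates and explained fractions as TSV
#'
#' @param pca result of [genotype_pca()].
#' @param path output file.
#' @export
write_pca_tsv <- function(pca, path) {
  df <- data.frame(sample = rownames(pca$coordinates), pca$coordinates)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# explained_fraction\t",
                    paste(sprintf("%.6g", pca$explained_fraction),
                          collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
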