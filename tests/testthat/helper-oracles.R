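# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately re-derive results by a different route
# than the package implementation.

# -- alignment oracles ------------------------------------------------------

# informative-site count by direct per-column tabulation
oracle_informative <- function(a, missing_chars = c("-", "N")) {
  count <- 0L
  for (j in seq_len(ncol(a))) {
    states <- c()
    for (i in seq_len(nrow(a))) {
      ch <- a[i, j]
      if (!(ch %in% missing_chars)) states <- c(states, ch)
    }
    if (length(states) > 0L) {
      tab <- table(states)
      if (sum(tab >= 2L) >= 2L) count <- count + 1L
    }
  }
  count
}

# indices of columns an occupancy filter should keep
oracle_kept_columns <- function(a, min_occ, missing_chars = c("-", "N")) {
  keep <- integer()
  for (j in seq_len(ncol(a))) {
    occupied <- 0L
    for (i in seq_len(nrow(a))) {
      if (!(a[i, j] %in% missing_chars)) occupied <- occupied + 1L
    }
    if (occupied / nrow(a) >= min_occ) keep <- c(keep, j)
  }
  keep
}

random_alignment <- function(nrow_ = sample(5:20, 1), ncol_ = sample(20:60, 1),
                             gap_prob = 0.25) {
  chars <- sample(c("A", "C", "G", "T", "-", "N"), nrow_ * ncol_,
                  replace = TRUE,
                  prob = c(rep((1 - gap_prob) / 4, 4), gap_prob * 0.7,
                           gap_prob * 0.3))
  m <- matrix(chars, nrow_, ncol_)
  rownames(m) <- paste0("row", seq_len(nrow_))
  m
}

# -- maximum-inclusion oracle ----------------------------------------------

# tip sets induced by cutting each edge in each direction, via node-based
# descendant queries (phangorn) rather than the package's edge walk
oracle_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- list(sort(tree$tip.label))
  for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
    below <- tree$tip.label[phangorn::Descendants(tree, nd, "tips")[[1]]]
    for (side in list(below, setdiff(tree$tip.label, below))) {
      if (length(side) >= 2L && length(side) < ntip) {
        sets[[length(sets) + 1L]] <- sort(side)
      }
    }
  }
  for (i in seq_len(ntip)) {
    side <- sort(tree$tip.label[-i])
    if (length(side) >= 2L) sets[[length(sets) + 1L]] <- side
  }
  unique(sets)
}

# Steiner-subtree total length of a tip set: sum of edges with members of
# the set on both sides (closed-form alternative to pruning)
oracle_subtree_length <- function(tree, tip_set) {
  ntip <- length(tree$tip.label)
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    below <- if (ch <= ntip) tree$tip.label[ch] else
      tree$tip.label[phangorn::Descendants(tree, ch, "tips")[[1]]]
    k <- length(intersect(below, tip_set))
    if (k >= 1L && k <= length(tip_set) - 1L) total <- total + tree$edge.length[e]
  }
  total
}

# the documented greedy loop, driven entirely by the oracle pieces
oracle_max_inclusion <- function(tree, min_taxa) {
  out <- list()
  working <- tree
  repeat {
    if (is.null(working) || length(working$tip.label) < 2L) break
    if (length(unique(tip_taxon(working$tip.label))) < min_taxa) break
    sets <- oracle_tip_sets(working)
    sets <- Filter(function(s) !anyDuplicated(tip_taxon(s)), sets)
    if (length(sets) == 0L) break
    ntaxa <- vapply(sets, length, integer(1))
    best <- which(ntaxa == max(ntaxa))
    if (length(best) > 1L) {
      tl <- vapply(sets[best], oracle_subtree_length, numeric(1), tree = working)
      best <- best[tl == min(tl)]
      if (length(best) > 1L) {
        keys <- vapply(sets[best], paste, character(1), collapse = "\r")
        best <- best[order(keys)][1]
      }
    }
    pick <- sets[[best[1]]]
    if (length(pick) < min_taxa) break
    out[[length(out) + 1L]] <- pick
    rest <- setdiff(working$tip.label, pick)
    if (length(rest) < 2L) break
    working <- ape::keep.tip(working, rest)
  }
  out
}

# random gene tree with short branches (below every trim cutoff) and
# n_dup tips relabelled as extra copies of existing taxa
random_dup_tree <- function(ntip, n_dup = 0L) {
  tr <- ape::rtree(ntip, tip.label = paste0("tax", seq_len(ntip)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.001, 0.01)
  if (n_dup > 0L) {
    dup_tips <- sample(ntip, n_dup)
    hosts <- sample(setdiff(seq_len(ntip), dup_tips), n_dup, replace = TRUE)
    for (k in seq_len(n_dup)) {
      tr$tip.label[dup_tips[k]] <- paste0("tax", hosts[k], "@", k + 1L)
    }
  }
  tr
}

# -- graph fixtures ---------------------------------------------------------

sim_graph <- function(vertices, edges) {
  structure(list(vertices = vertices, edges = edges),
            class = "similarity_graph")
}

planted_partition_graph <- function(blocks = 3L, size = 10L, p_in = 0.9,
                                    p_out = 0.02) {
  n <- blocks * size
  lab <- paste0("v", seq_len(n))
  blk <- rep(seq_len(blocks), each = size)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      prob <- if (blk[i] == blk[j]) p_in else p_out
      if (stats::runif(1) < prob) {
        rows[[length(rows) + 1L]] <- data.frame(u = lab[i], v = lab[j],
                                                weight = stats::runif(1, 0.8, 1))
      }
    }
  }
  list(graph = sim_graph(lab, do.call(rbind, rows)),
       truth = split(lab, blk))
}

same_partition <- function(clusters, truth) {
  setequal(lapply(clusters, sort), lapply(truth, sort))
}

# -- variant-set fixture ----------------------------------------------------

# build a variant_set from a genotype matrix, with clean read/qual defaults
# that pass every criterion unless overridden
make_vs <- function(gt, qual = NULL, dp = NULL, ad_alt = NULL, ad_ref = NULL,
                    locus = NULL, pos = NULL) {
  n_site <- nrow(gt)
  n_samp <- ncol(gt)
  if (is.null(qual)) qual <- rep(500, n_site)
  if (is.null(dp)) dp <- matrix(20L, n_site, n_samp)
  if (is.null(ad_alt)) {
    ad_alt <- matrix(0L, n_site, n_samp)
    for (i in seq_len(n_site)) {
      for (j in seq_len(n_samp)) {
        g <- gt[i, j]
        ad_alt[i, j] <- if (is.na(g)) 0L else
          switch(g, "0/0" = 0L, "0/1" = as.integer(dp[i, j] %/% 2L),
                 "1/1" = dp[i, j], "1/2" = as.integer(dp[i, j] %/% 2L), 0L)
      }
    }
  }
  if (is.null(ad_ref)) ad_ref <- dp - ad_alt
  if (is.null(locus)) locus <- sprintf("loc%03d", seq_len(n_site))
  if (is.null(pos)) pos <- rep(100L, n_site)
  n_alt <- vapply(seq_len(n_site), function(i) {
    max(site_allele_counts_helper(gt[i, ]), 1L)
  }, integer(1))
  alt <- ifelse(n_alt >= 2L, "C,G", "C")
  variant_set(data.frame(locus_id = locus, pos = pos, ref = "A", alt = alt,
                         qual = qual),
              gt, dp, ad_ref, ad_alt,
              samples = sprintf("Sample_%02d", seq_len(n_samp)))
}

site_allele_counts_helper <- function(gt_row) {
  called <- gt_row[!is.na(gt_row)]
  if (length(called) == 0L) return(0L)
  max(as.integer(unlist(strsplit(called, "[/|]"))))
}

# 19-sample genotype row helper: all hom-ref except the named entries
gt_row19 <- function(...) {
  row <- rep("0/0", 19)
  over <- list(...)
  for (nm in names(over)) row[as.integer(nm)] <- over[[nm]]
  row
}
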