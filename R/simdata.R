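#' Synthetic-data generator
#'
#' Generates every input the pipeline consumes, with ground-truth labels: a
#' 19-ingroup + 2-outgroup species tree, homolog families with planted
#' paralog clades, contaminant long-branch tips and deep splits, aligned
#' Jukes-Cantor-evolved sequences, and diploid genotypes under a k = 3
#' layered-admixture (Balding-Nichols) model with planted violations of
#' each genotype-filter criterion.
#'
#' @name simdata
NULL

#' Family simulation settings
#'
#' Threshold-separating defaults make truth unambiguous: contaminant tips
#' are at least 0.05 subs/site long while legitimate terminal branches stay
#' at or below 0.01, and planted deep splits are 0.25 subs/site against the
#' 0.2 splitting cutoff.
#'
#' @param n_ingroup,n_outgroup sample counts (defaults 19 and 2).
#' @param n_families number of homolog families.
#' @param dup_prob probability a family carries a duplicated (paralog)
#'   clade.
#' @param contaminant_prob probability a family carries a contaminant tip.
#' @param contaminant_length_min minimum contaminant terminal length.
#' @param legit_tip_max maximum legitimate branch length.
#' @param deep_split_prob probability a planted paralog stem is deep.
#' @param deep_length stem length of a planted deep split.
#' @param seq_length simulated sequence length (sites).
#' @param mask_prob per-sequence probability of terminal gap masking.
#' @param seed RNG seed.
#' @return a `family_sim_config` list.
#' @export
family_sim_config <- function(n_ingroup = 19L, n_outgroup = 2L,
                              n_families = 40L, dup_prob = 0.3,
                              contaminant_prob = 0.2,
                              contaminant_length_min = 0.05,
                              legit_tip_max = 0.01,
                              deep_split_prob = 0.15, deep_length = 0.25,
                              seq_length = 1000L, mask_prob = 0.1,
                              seed = 1L) {
  stopifnot(dup_prob >= 0, dup_prob <= 1, contaminant_prob >= 0,
            contaminant_prob <= 1, deep_split_prob >= 0, deep_split_prob <= 1,
            mask_prob >= 0, mask_prob <= 1,
            contaminant_length_min > 0.03, legit_tip_max < 0.02)
  structure(as.list(environment()), class = "family_sim_config")
}

ingroup_names <- function(n) sprintf("Sample_%02d", seq_len(n))
outgroup_names <- function(n) sprintf("Outgroup_%02d", seq_len(n))

#' Simulate the species tree
#'
#' Coalescent-shaped ingroup topology with every ingroup branch drawn from
#' U(0.001, 0.01) (minimal molecular divergence among individuals); the
#' outgroup pair attaches on a 0.05 subs/site stem.
#'
#' @param cfg a [family_sim_config()].
#' @param seed RNG seed (default `cfg$seed`).
#' @return a rooted `phylo` with `n_ingroup + n_outgroup` tips.
#' @export
simulate_species_tree <- function(cfg = family_sim_config(), seed = cfg$seed) {
  set.seed(seed)
  simulate_species_tree_impl(cfg)
}

# unseeded worker so batch generators can draw a whole stream from one seed
simulate_species_tree_impl <- function(cfg) {
  ing <- ape::rcoal(cfg$n_ingroup, tip.label = ingroup_names(cfg$n_ingroup))
  ing$edge.length <- stats::runif(nrow(ing$edge), 0.001, 0.01)
  out_tips <- outgroup_names(cfg$n_outgroup)
  ing_nwk <- sub(";$", "", write_newick(ing))
  out_nwk <- paste0("(", paste0(out_tips, ":",
                                sprintf("%.6f", stats::runif(cfg$n_outgroup,
                                                             0.001, 0.01)),
                                collapse = ","), "):0.05")
  parse_newick(paste0("(", ing_nwk, ":0.05,", out_nwk, ");"))
}

# JC sequence evolution along a tree; returns named character vector of
# equal-length strings (no indels, so rows are aligned by construction)
evolve_jc_sequences <- function(tree, seq_length) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  seqs <- vector("list", nnode)
  seqs[[root]] <- sample.int(4L, seq_length, replace = TRUE)
  edges <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(edges$edge))) {
    p <- edges$edge[e, 1]
    ch <- edges$edge[e, 2]
    d <- edges$edge.length[e]
    s <- seqs[[p]]
    p_change <- 0.75 * (1 - exp(-4 * d / 3))
    hit <- which(stats::runif(seq_length) < p_change)
    if (length(hit) > 0L) {
      # mutate to one of the three other bases, uniformly
      s[hit] <- 1L + (s[hit] - 1L + sample.int(3L, length(hit),
                                               replace = TRUE)) %% 4L
    }
    seqs[[ch]] <- s
  }
  bases <- c("A", "C", "G", "T")
  out <- vapply(seq_len(ntip), function(i) {
    paste(bases[seqs[[i]]], collapse = "")
  }, character(1))
  names(out) <- tree$tip.label
  out
}

mask_terminal <- function(seq, frac) {
  n <- nchar(seq)
  k <- max(1L, round(frac * n))
  if (stats::runif(1) < 0.5) {
    paste0(strrep("-", k), substr(seq, k + 1L, n))
  } else {
    paste0(substr(seq, 1L, n - k), strrep("-", k))
  }
}

# nodes whose clade has a tip count within [lo, hi] (root excluded)
candidate_clade_nodes <- function(tree, lo, hi) {
  ntip <- length(tree$tip.label)
  desc <- descendant_tips_by_node(tree)
  nodes <- (ntip + 2L):(ntip + tree$Nnode)
  nodes[vapply(nodes, function(nd) {
    k <- length(desc[[nd]])
    k >= lo && k <= hi
  }, logical(1))]
}

#' Simulate one homolog family
#'
#' Copies the species tree; with probability `dup_prob` duplicates a random
#' clade (copy tips get an `@2` suffix) whose stem is set to `deep_length`
#' with probability `deep_split_prob` (a planted deep split, with at least
#' four taxa in the clade) or to 0.05 otherwise; with probability
#' `contaminant_prob` attaches a contaminant tip with terminal length in
#' [`contaminant_length_min`, `contaminant_length_min` + 0.05). Sequences
#' evolve under Jukes-Cantor along the family tree (no indels, so rows are
#' aligned); terminal masking with probability `mask_prob` per sequence
#' creates occupancy variation. All plants are recorded in the truth
#' labels. The caller controls the RNG state.
#'
#' @param species_tree a `phylo` from [simulate_species_tree()].
#' @param cfg a [family_sim_config()].
#' @return list with `tree` (`phylo`), `alignment` (character matrix, rows
#'   = tip labels) and `truth` (list: `contaminant_tips`, `paralog_tips`,
#'   `deep_split`, `dup_clade_taxa`).
#' @export
simulate_family <- function(species_tree, cfg = family_sim_config()) {
  tree <- species_tree
  truth <- list(contaminant_tips = character(), paralog_tips = character(),
                deep_split = FALSE, dup_clade_taxa = character())
  if (stats::runif(1) < cfg$dup_prob) {
    deep <- stats::runif(1) < cfg$deep_split_prob
    lo <- if (deep) 4L else 2L
    nodes <- candidate_clade_nodes(tree, lo, length(tree$tip.label) - 2L)
    if (length(nodes) > 0L) {
      nd <- if (length(nodes) == 1L) nodes else sample(nodes, 1L)
      clade <- ape::extract.clade(tree, nd)
      clade$tip.label <- paste0(clade$tip.label, "@2")
      clade$root.edge <- if (deep) cfg$deep_length else 0.005
      # attach the copy as sister to the original clade, splitting its stem
      stem_edge <- which(tree$edge[, 2] == nd)
      pos <- tree$edge.length[stem_edge] / 2
      tree <- ape::bind.tree(tree, clade, where = nd, position = pos)
      truth$paralog_tips <- clade$tip.label
      truth$dup_clade_taxa <- tip_taxon(clade$tip.label)
      truth$deep_split <- deep
    }
  }
  if (stats::runif(1) < cfg$contaminant_prob) {
    host <- sample(ingroup_names(cfg$n_ingroup), 1L)
    lab <- paste0(host, "@9")
    len <- cfg$contaminant_length_min + stats::runif(1) * 0.05
    edge <- sample(nrow(tree$edge), 1L)
    tree <- bind_tip_at_edge(tree, lab, len, edge)
    truth$contaminant_tips <- lab
  }
  aln_seqs <- evolve_jc_sequences(tree, cfg$seq_length)
  for (i in seq_along(aln_seqs)) {
    if (stats::runif(1) < cfg$mask_prob) {
      aln_seqs[i] <- mask_terminal(aln_seqs[i], stats::runif(1, 0.05, 0.3))
    }
  }
  list(tree = tree, alignment = as_alignment(aln_seqs), truth = truth)
}

# attach a new tip of given terminal length at the midpoint of an edge
bind_tip_at_edge <- function(tree, label, length, edge) {
  tip <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                        tip.label = label,
                        edge.length = length,
                        Nnode = 1L),
                   class = "phylo")
  where <- tree$edge[edge, 2]
  pos <- tree$edge.length[edge] / 2
  ape::bind.tree(tree, tip, where = where, position = pos)
}

#' Simulate a batch of homolog families
#'
#' Seeds the generator once from `cfg$seed`, simulates the species tree and
#' `cfg$n_families` families from it.
#'
#' @param cfg a [family_sim_config()].
#' @return list with `species_tree` and `families` (list from
#'   [simulate_family()]).
#' @export
simulate_family_set <- function(cfg = family_sim_config()) {
  set.seed(cfg$seed)
  sp <- simulate_species_tree_impl(cfg)
  fams <- lapply(seq_len(cfg$n_families), function(i) {
    simulate_family(sp, cfg)
  })
  names(fams) <- sprintf("fam_%04d", seq_len(cfg$n_families))
  list(species_tree = sp, families = fams)
}

#' Genotype simulation settings
#'
#' The default layout mirrors the study design qualitatively: 19 samples in
#' a k = 3 spatial-layer admixture model, with 8 samples of pure
#' north-east ancestry, 9 of pure south-west ancestry and 2 admixed 60/40
#' between the two; layer divergence Fst = 0.1 (Balding-Nichols); 2000
#' loci with one SNP each at mean read depth 30. Artifact rates plant
#' violations of each filter criterion, recorded in the truth labels.
#'
#' @param n_samples number of diploid samples.
#' @param n_layers number of ancestry layers (k).
#' @param layer_assignment samples x layers admixture matrix, rows summing
#'   to 1; default as above.
#' @param fst layer divergence (0 collapses all layers to the ancestral
#'   frequency).
#' @param n_loci,snps_per_locus locus layout.
#' @param mean_depth Poisson mean read depth.
#' @param depth_floor minimum depth at clean sites (so they genuinely pass
#'   the depth criterion).
#' @param p_multiallelic,p_lowqual,p_lowdepth,p_het_ab_skew,p_hom_ab_noise,p_low_maf,p_missing
#'   per-site artifact rates (each plants a violation of one criterion).
#' @param seed RNG seed.
#' @return a `geno_sim_config` list.
#' @export
geno_sim_config <- function(n_samples = 19L, n_layers = 3L,
                            layer_assignment = NULL, fst = 0.1,
                            n_loci = 2000L, snps_per_locus = 1L,
                            mean_depth = 30, depth_floor = 10L,
                            p_multiallelic = 0.02, p_lowqual = 0.02,
                            p_lowdepth = 0.02, p_het_ab_skew = 0.02,
                            p_hom_ab_noise = 0.02, p_low_maf = 0.02,
                            p_missing = 0.02, seed = 1L) {
  if (is.null(layer_assignment)) {
    layer_assignment <- default_layer_assignment(n_samples, n_layers)
  }
  layer_assignment <- as.matrix(layer_assignment)
  if (nrow(layer_assignment) != n_samples ||
      ncol(layer_assignment) != n_layers) {
    stop("layer_assignment must be n_samples x n_layers", call. = FALSE)
  }
  if (any(abs(rowSums(layer_assignment) - 1) > 1e-9)) {
    stop("admixture rows must sum to 1", call. = FALSE)
  }
  stopifnot(fst >= 0, fst < 1)
  structure(as.list(environment()), class = "geno_sim_config")
}

# 8 pure layer-1 (NE), 9 pure layer-2 (SW), 2 admixed 60/40
default_layer_assignment <- function(n_samples = 19L, n_layers = 3L) {
  if (n_samples == 19L && n_layers == 3L) {
    A <- rbind(matrix(rep(c(1, 0, 0), each = 8), 8, 3),
               matrix(rep(c(0, 1, 0), each = 9), 9, 3),
               matrix(rep(c(0.6, 0.4, 0), each = 2), 2, 3))
  } else {
    A <- matrix(0, n_samples, n_layers)
    A[cbind(seq_len(n_samples),
            rep_len(seq_len(n_layers), n_samples))] <- 1
  }
  rownames(A) <- ingroup_names(n_samples)
  A
}

#' Ancestry-profile labels for a genotype simulation
#'
#' Samples sharing an admixture row form one class; used as the truth for
#' [cluster_recovery()]. Under the default layout this yields three
#' classes: pure NE, pure SW and the admixed pair.
#'
#' @param cfg a [geno_sim_config()].
#' @return integer vector of class labels, one per sample.
#' @export
ancestry_profiles <- function(cfg) {
  keys <- apply(round(cfg$layer_assignment, 9), 1, paste, collapse = ",")
  as.integer(factor(keys, levels = unique(keys)))
}

draw_reads_for_genotype <- function(g, dp, clean, th_lo = 0.25, th_hi = 0.75,
                                    hom_max = 0.05) {
  if (dp <= 0L) return(c(ref = 0L, alt = 0L))
  if (g == 1L) {
    alt <- stats::rbinom(1L, dp, 0.5)
    if (clean) {
      alt <- min(max(alt, ceiling(th_lo * dp)), floor(th_hi * dp))
    }
  } else {
    minor <- stats::rbinom(1L, dp, 0.01)
    if (clean) minor <- min(minor, floor(hom_max * dp))
    alt <- if (g == 0L) minor else dp - minor
  }
  c(ref = as.integer(dp - alt), alt = as.integer(alt))
}

#' Simulate layered-admixture genotypes with planted filter violations
#'
#' Per SNP: ancestral frequency p ~ U(0.1, 0.9); layer frequencies follow
#' the Balding-Nichols model Beta(p(1-F)/F, (1-p)(1-F)/F); each sample's
#' frequency is its admixture-weighted mix of layer frequencies and its
#' genotype is Binomial(2, .). Read depths are Poisson(`mean_depth`)
#' floored at `depth_floor`; allele depths follow the genotype with 1%
#' error. Clean sites are constructed to genuinely pass all six criteria
#' (minor allele count is rejection-resampled above the MAF cutoff and
#' allele balances are clamped inside the allowed ranges). Each planted
#' artifact corrupts one site to violate exactly one criterion, recorded in
#' the truth labels (`violated_criterion`: 0 = clean, 1-6 = the cascade
#' criterion the plant triggers; planted missing genotypes count against
#' criterion 3).
#'
#' @param cfg a [geno_sim_config()].
#' @return list with `variants` (a `variant_set`), and `truth` (list:
#'   `sites` data frame with `locus_id`, `pos`, `artifact`,
#'   `violated_criterion`; `layer_freq` sites x layers matrix;
#'   `admixture` the assignment matrix; `profiles` class labels).
#' @export
simulate_genotypes <- function(cfg = geno_sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_samples
  A <- cfg$layer_assignment
  n_sites <- cfg$n_loci * cfg$snps_per_locus
  locus <- rep(sprintf("locus_%05d", seq_len(cfg$n_loci)),
               each = cfg$snps_per_locus)
  pos <- rep(seq_len(cfg$snps_per_locus) * 100L, times = cfg$n_loci)
  bases <- c("A", "C", "G", "T")
  types <- c("multiallelic", "lowqual", "lowdepth", "het_ab_skew",
             "hom_ab_noise", "low_maf", "missing")
  rates <- c(cfg$p_multiallelic, cfg$p_lowqual, cfg$p_lowdepth,
             cfg$p_het_ab_skew, cfg$p_hom_ab_noise, cfg$p_low_maf,
             cfg$p_missing)
  stopifnot(sum(rates) <= 1)
  criterion_of <- c(multiallelic = 1L, lowqual = 2L, lowdepth = 3L,
                    het_ab_skew = 4L, hom_ab_noise = 5L, low_maf = 6L,
                    missing = 3L)

  gt <- matrix(NA_character_, n_sites, n)
  dp <- ad_ref <- ad_alt <- matrix(0L, n_sites, n)
  qual <- numeric(n_sites)
  ref <- alt <- character(n_sites)
  artifact <- character(n_sites)
  layer_freq <- matrix(NA_real_, n_sites, cfg$n_layers)

  for (i in seq_len(n_sites)) {
    u <- stats::runif(1)
    type <- "clean"
    acc <- 0
    for (k in seq_along(types)) {
      acc <- acc + rates[k]
      if (u < acc) { type <- types[k]; break }
    }
    artifact[i] <- type

    p <- stats::runif(1, 0.1, 0.9)
    pl <- if (cfg$fst == 0) rep(p, cfg$n_layers) else
      stats::rbeta(cfg$n_layers, p * (1 - cfg$fst) / cfg$fst,
                   (1 - p) * (1 - cfg$fst) / cfg$fst)
    pl <- pmin(pmax(pl, 1e-6), 1 - 1e-6)
    layer_freq[i, ] <- pl
    q <- as.numeric(A %*% pl)
    g <- stats::rbinom(n, 2L, q)
    if (type == "low_maf") {
      # exactly one heterozygote: MAF 1/(2n) <= 0.05, still informative
      g <- rep(0L, n)
      g[sample.int(n, 1L)] <- 1L
    } else {
      # resample so the clean base passes the MAF criterion (alt count in
      # [2, 2n - 2]: 2/38 = 0.0526 > 0.05 for 19 diploids)
      for (try in 1:100) {
        ac <- sum(g)
        if (ac >= 2L && ac <= 2L * n - 2L) break
        g <- stats::rbinom(n, 2L, q)
      }
      if (sum(g) < 2L || sum(g) > 2L * n - 2L) {
        flip <- sample.int(n, 2L)
        g[flip] <- if (sum(g) < 2L) 1L else 1L
      }
    }
    two <- sample(bases, 2L)
    ref[i] <- two[1]
    alt[i] <- two[2]

    d <- pmax(cfg$depth_floor, stats::rpois(n, cfg$mean_depth))
    reads <- vapply(seq_len(n), function(j) {
      draw_reads_for_genotype(g[j], d[j], clean = TRUE)
    }, integer(2))
    gt[i, ] <- c("0/0", "0/1", "1/1")[g + 1L]
    dp[i, ] <- d
    ad_ref[i, ] <- reads[1, ]
    ad_alt[i, ] <- reads[2, ]
    qual[i] <- stats::runif(1, 60, 2000)

    # corrupt per plant, leaving all other criteria passing
    if (type == "multiallelic") {
      j <- sample.int(n, 1L)
      third <- sample(setdiff(bases, two), 1L)
      alt[i] <- paste0(alt[i], ",", third)
      gt[i, j] <- "1/2"
      half <- floor(dp[i, j] / 2)
      ad_ref[i, j] <- 0L
      ad_alt[i, j] <- half  # AB ~ 0.5 so the balance checks stay quiet
    } else if (type == "lowqual") {
      qual[i] <- stats::runif(1, 2, 19.5)
    } else if (type == "lowdepth") {
      j <- sample.int(n, 1L)
      d_low <- sample(0:(cfg$depth_floor - 1L), 1L)
      dp[i, j] <- d_low
      reads_j <- draw_reads_for_genotype(g[j], d_low, clean = TRUE)
      ad_ref[i, j] <- reads_j[1]
      ad_alt[i, j] <- reads_j[2]
    } else if (type == "het_ab_skew") {
      j <- which(g == 1L)
      j <- if (length(j) == 0L) sample.int(n, 1L) else
        if (length(j) == 1L) j else sample(j, 1L)
      if (g[j] != 1L) { g[j] <- 1L; gt[i, j] <- "0/1" }
      skew_hi <- stats::runif(1) < 0.5
      a <- if (skew_hi) ceiling(0.8 * dp[i, j]) else floor(0.2 * dp[i, j])
      ad_alt[i, j] <- a
      ad_ref[i, j] <- dp[i, j] - a
    } else if (type == "hom_ab_noise") {
      j <- which(g != 1L)
      j <- if (length(j) == 0L) sample.int(n, 1L) else
        if (length(j) == 1L) j else sample(j, 1L)
      if (g[j] == 1L) { g[j] <- 0L; gt[i, j] <- "0/0" }
      minor <- max(ceiling(0.1 * dp[i, j]), floor(0.05 * dp[i, j]) + 1L)
      if (g[j] == 0L) {
        ad_alt[i, j] <- minor; ad_ref[i, j] <- dp[i, j] - minor
      } else {
        ad_ref[i, j] <- minor; ad_alt[i, j] <- dp[i, j] - minor
      }
    } else if (type == "missing") {
      j <- sample.int(n, 1L)
      gt[i, j] <- NA_character_
      dp[i, j] <- 0L
      ad_ref[i, j] <- 0L
      ad_alt[i, j] <- 0L
    }
  }

  meta <- data.frame(locus_id = locus, pos = pos, ref = ref, alt = alt,
                     qual = qual)
  vs <- variant_set(meta, gt, dp, ad_ref, ad_alt,
                    samples = rownames(A))
  truth_sites <- data.frame(locus_id = locus, pos = pos, artifact = artifact,
                            violated_criterion = ifelse(
                              artifact == "clean", 0L,
                              criterion_of[artifact]))
  list(variants = vs,
       truth = list(sites = truth_sites, layer_freq = layer_freq,
                    admixture = A, profiles = ancestry_profiles(cfg)))
}
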