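test_that("species trees have 21 tips, short ingroup branches and a deep stem", {
  cfg <- family_sim_config(seed = 121)
  sp <- simulate_species_tree(cfg)
  expect_equal(length(sp$tip.label), 21L)
  expect_setequal(sp$tip.label, c(ingroup_names(19), outgroup_names(2)))
  ing <- ape::keep.tip(sp, ingroup_names(19))
  expect_true(all(ing$edge.length <= 0.05))
  expect_identical(write_newick(simulate_species_tree(cfg)),
                   write_newick(sp))
  expect_false(identical(write_newick(simulate_species_tree(cfg, seed = 2)),
                         write_newick(sp)))
})

test_that("families without artifacts equal the species tree with empty truth", {
  cfg <- family_sim_config(dup_prob = 0, contaminant_prob = 0, mask_prob = 0,
                           seed = 122)
  set.seed(cfg$seed)
  sp <- simulate_species_tree_impl(cfg)
  fam <- simulate_family(sp, cfg)
  expect_identical(write_newick(fam$tree), write_newick(sp))
  expect_equal(fam$truth$contaminant_tips, character())
  expect_equal(fam$truth$paralog_tips, character())
  expect_false(fam$truth$deep_split)
  expect_equal(dim(fam$alignment), c(21L, cfg$seq_length))
  expect_false(any(fam$alignment == "-"))
})

test_that("planted contaminants exceed the removal cutoff and are trimmable", {
  cfg <- family_sim_config(contaminant_prob = 1, dup_prob = 0, seed = 123)
  set.seed(cfg$seed)
  sp <- simulate_species_tree_impl(cfg)
  for (rep in 1:10) {
    fam <- simulate_family(sp, cfg)
    expect_length(fam$truth$contaminant_tips, 1L)
    term <- terminal_edge_lengths(fam$tree)
    expect_gte(unname(term[fam$truth$contaminant_tips]), 0.05)
    res <- trim_long_tips(fam$tree)
    expect_equal(res$removed, fam$truth$contaminant_tips)
  }
})

test_that("jc evolution matches the expected mismatch fraction", {
  set.seed(124)
  d <- 0.08
  tr <- parse_newick(sprintf("(X:%g,Y:%g);", d / 2, d / 2))
  seqs <- evolve_jc_sequences(tr, 10000L)
  p_obs <- mean(strsplit(seqs[["X"]], "")[[1]] != strsplit(seqs[["Y"]], "")[[1]])
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("terminal masking creates sub-threshold occupancy columns only at ends", {
  set.seed(125)
  cfg <- family_sim_config(mask_prob = 1, dup_prob = 0, contaminant_prob = 0,
                           seq_length = 200L, seed = 125)
  sp <- simulate_species_tree_impl(cfg)
  fam <- simulate_family(sp, cfg)
  gaps <- fam$alignment == "-"
  expect_true(any(gaps))
  # every gap run touches a sequence end
  for (i in seq_len(nrow(gaps))) {
    r <- rle(gaps[i, ])
    gap_runs <- which(r$values)
    expect_true(all(gap_runs %in% c(1L, length(r$values))))
  }
})

test_that("genotype simulation is deterministic given the seed", {
  cfg <- geno_sim_config(n_loci = 40, seed = 126)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  on.exit(unlink(c(f1, f2)))
  write_vcf(a$variants, f1)
  write_vcf(b$variants, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(a$truth$sites, b$truth$sites)
})

test_that("layer frequencies collapse to the ancestral value as fst vanishes", {
  sim0 <- simulate_genotypes(geno_sim_config(n_loci = 100, fst = 0,
                                             seed = 127))
  spread0 <- apply(sim0$truth$layer_freq, 1, function(x) diff(range(x)))
  expect_true(all(spread0 == 0))
  sim1 <- simulate_genotypes(geno_sim_config(n_loci = 100, fst = 0.2,
                                             seed = 127))
  spread1 <- apply(sim1$truth$layer_freq, 1, function(x) diff(range(x)))
  expect_gt(mean(spread1), 0.05)
})

test_that("admixture rows must sum to one", {
  A <- default_layer_assignment()
  A[1, ] <- c(0.5, 0.4, 0)
  expect_error(geno_sim_config(layer_assignment = A), "sum to 1")
})

test_that("ancestry profiles identify the three default classes", {
  cfg <- geno_sim_config()
  prof <- ancestry_profiles(cfg)
  expect_equal(prof, c(rep(1L, 8), rep(2L, 9), rep(3L, 2)))
})

test_that("artifact-free simulations pass the filter cascade entirely", {
  cfg <- geno_sim_config(n_loci = 80, p_multiallelic = 0, p_lowqual = 0,
                         p_lowdepth = 0, p_het_ab_skew = 0,
                         p_hom_ab_noise = 0, p_low_maf = 0, p_missing = 0,
                         seed = 128)
  sim <- simulate_genotypes(cfg)
  res <- apply_site_filters(sim$variants)
  expect_equal(res$report$sites_out, 80L)
  expect_equal(unname(res$report$first_failure), rep(0L, 6))
})

test_that("planted artifacts land within binomial error of their rates", {
  cfg <- geno_sim_config(n_loci = 1500, seed = 129)
  sim <- simulate_genotypes(cfg)
  counts <- table(factor(sim$truth$sites$artifact,
                         levels = c("multiallelic", "lowqual", "lowdepth",
                                    "het_ab_skew", "hom_ab_noise", "low_maf",
                                    "missing")))
  for (nm in names(counts)) {
    rate <- 0.02
    se <- sqrt(1500 * rate * (1 - rate))
    expect_lt(abs(counts[[nm]] - 1500 * rate), 3 * se)
  }
})
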