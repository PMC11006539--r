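test_that("long-tip removal applies the absolute and relative-sister rules", {
  # A at 0.035 exceeds the absolute cutoff regardless of its sister
  tr <- parse_newick("((A:0.035,B:0.02):0.01,(C:0.001,D:0.001):0.01,E:0.005);")
  res <- trim_long_tips(tr)
  expect_equal(res$removed, "A")
  # 0.025 with a 0.001 sister: relative rule fires (>= 0.02 and 25x sister)
  tr2 <- parse_newick("((A:0.025,B:0.001):0.01,(C:0.001,D:0.001):0.01);")
  expect_equal(trim_long_tips(tr2)$removed, "A")
  # 0.025 with a 0.02 sister: fails both clauses
  tr3 <- parse_newick("((A:0.025,B:0.02):0.01,(C:0.001,D:0.001):0.01);")
  expect_equal(trim_long_tips(tr3)$removed, character())
})

test_that("an internal sibling contributes its own edge length as sister", {
  # A's sibling is the internal clade (C,D) with stem 0.002: 0.025 >= 10x
  tr <- parse_newick("((A:0.025,(C:0.001,D:0.001):0.002):0.01,(E:0.001,F:0.001):0.01);")
  expect_equal(trim_long_tips(tr)$removed, "A")
  # same topology, sibling stem 0.02: relative clause fails
  tr2 <- parse_newick("((A:0.025,(C:0.001,D:0.001):0.02):0.01,(E:0.001,F:0.001):0.01);")
  expect_equal(trim_long_tips(tr2)$removed, character())
})

test_that("removals are decided on the input tree in a single sweep", {
  # B (0.004) is A's sister; removing A must not re-evaluate B against C/D
  tr <- parse_newick("((A:0.04,B:0.004):0.01,(C:0.0001,D:0.0001):0.01);")
  res <- trim_long_tips(tr)
  expect_equal(res$removed, "A")
  expect_true("B" %in% res$tree$tip.label)
})

test_that("degree-2 suppression merges edge lengths by summation", {
  tr <- parse_newick("((A:0.05,B:0.001):0.01,(C:0.001,D:0.001):0.02,E:0.001);")
  res <- trim_long_tips(tr)
  expect_equal(res$removed, "A")
  term <- terminal_edge_lengths(res$tree)
  # B's terminal edge absorbs the suppressed parent edge: 0.001 + 0.01
  expect_equal(unname(term["B"]), 0.011)
})

test_that("a tree left with fewer than two tips is discarded and flagged", {
  tr <- parse_newick("(A:0.05,B:0.06,C:0.07);")
  res <- trim_long_tips(tr)
  expect_null(res$tree)
  expect_true(res$discarded)
  expect_setequal(res$removed, c("A", "B", "C"))
})

test_that("deep-branch splitting honours length and side-taxon conditions", {
  lhs <- "(A:0.01,B:0.01,(C:0.01,D:0.01):0.01)"
  rhs <- "(E:0.01,F:0.01,(G:0.01,H:0.01):0.01)"
  tr <- parse_newick(paste0("(", lhs, ":0.25,", rhs, ":0.01);"))
  parts <- split_deep_branches(tr)
  expect_length(parts, 2L)
  sets <- lapply(parts, function(p) sort(p$tip.label))
  expect_true(same_partition(sets, list(c("A", "B", "C", "D"),
                                        c("E", "F", "G", "H"))))
  # 3 vs 5 taxa: min_side_taxa violated, no split
  tr2 <- parse_newick(
    "((A:0.01,B:0.01,C:0.01):0.25,(E:0.01,F:0.01,G:0.01,H:0.01,I:0.01):0.01);")
  expect_length(split_deep_branches(tr2), 1L)
  # below the 0.2 cutoff, no split
  tr3 <- parse_newick(paste0("(", lhs, ":0.15,", rhs, ":0.01);"))
  expect_length(split_deep_branches(tr3), 1L)
})

test_that("paralog copies on one side count once per taxon", {
  # left side has 4 tips but only 3 distinct taxa: no split
  lhs <- "(A@1:0.01,A@2:0.01,(B:0.01,C:0.01):0.01)"
  rhs <- "(E:0.01,F:0.01,(G:0.01,H:0.01):0.01)"
  tr <- parse_newick(paste0("(", lhs, ":0.25,", rhs, ":0.01);"))
  expect_length(split_deep_branches(tr), 1L)
})

test_that("cleaning preserves surviving branch lengths and tip subsets", {
  set.seed(61)
  for (rep in 1:10) {
    fam <- simulate_family(simulate_species_tree_impl(family_sim_config()),
                           family_sim_config(contaminant_prob = 1))
    res <- trim_long_tips(fam$tree)
    expect_true(all(res$tree$tip.label %in% fam$tree$tip.label))
    d_in <- ape::cophenetic.phylo(fam$tree)
    d_out <- ape::cophenetic.phylo(res$tree)
    keep <- rownames(d_out)
    expect_equal(d_out, d_in[keep, keep], tolerance = 1e-9)
  }
})

test_that("removal rates equal removed over before, per sample", {
  trees <- list(
    parse_newick("((A:0.05,B:0.001):0.01,(C:0.001,A@2:0.001):0.01);"),
    parse_newick("((A:0.001,B:0.001):0.01,(C:0.001,D:0.001):0.01);"))
  res <- clean_round(trees)
  rep_a <- res$report[res$report$sample_id == "A", ]
  expect_equal(rep_a$tips_before, 3L)
  expect_equal(rep_a$tips_removed, 1L)
  expect_equal(rep_a$removal_rate, 1 / 3)
  expect_true(all(res$report$removal_rate >= 0 & res$report$removal_rate <= 1))
})

test_that("clean trees below every cutoff pass through unchanged", {
  trees <- list(parse_newick("((A:0.005,B:0.004):0.01,(C:0.003,D:0.002):0.01);"))
  out <- clean_trees(trees, clean_params())
  expect_length(out$trees, 1L)
  expect_equal(write_newick(out$trees[[1]]), write_newick(trees[[1]]))
  expect_true(all(out$reports$removal_rate == 0))
})

test_that("second-round removals do not exceed first-round removals", {
  set.seed(71)
  cfg <- family_sim_config(n_families = 60, contaminant_prob = 0.4, seed = 71)
  fams <- simulate_family_set(cfg)
  res <- clean_trees(lapply(fams$families, `[[`, "tree"), clean_params())
  by_round <- tapply(res$reports$tips_removed, res$reports$round, sum)
  expect_lte(by_round["2"], by_round["1"])
})
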