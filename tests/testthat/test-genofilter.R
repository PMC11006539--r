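test_that("each criterion fires at its boundary and not inside it", {
  th <- filter_thresholds()
  # (1) three alleles segregating
  gt1 <- rbind(gt_row19("1" = "1/2", "2" = "0/1", "3" = "0/1"),
               gt_row19("1" = "0/1", "2" = "0/1", "3" = "0/1"))
  V <- site_violations(make_vs(gt1), th)
  expect_equal(unname(V[, "multiallelic"]), c(TRUE, FALSE))
  # (2) polymorphic with QUAL below 20; 20.0 exactly passes
  gt2 <- rbind(gt_row19("1" = "0/1", "2" = "0/1"),
               gt_row19("1" = "0/1", "2" = "0/1"))
  V <- site_violations(make_vs(gt2, qual = c(19.9, 20.0)), th)
  expect_equal(unname(V[, "low_qual"]), c(TRUE, FALSE))
  # (3) depth below ten in any sample; 10 exactly passes
  gt3 <- rbind(gt_row19("1" = "0/1", "2" = "0/1"),
               gt_row19("1" = "0/1", "2" = "0/1"))
  dp <- matrix(20L, 2, 19)
  dp[1, 7] <- 9L
  dp[2, 7] <- 10L
  vs3 <- make_vs(gt3, dp = dp)
  V <- site_violations(vs3, th)
  expect_equal(unname(V[, "low_depth"]), c(TRUE, FALSE))
  # (4) heterozygote AD (2,8) at DP 10: AB 0.8 > 0.75 fails; 0.75 passes
  gt4 <- rbind(gt_row19("1" = "0/1", "2" = "0/1"),
               gt_row19("1" = "0/1", "2" = "0/1"))
  dp4 <- matrix(20L, 2, 19)
  dp4[, 1] <- c(10L, 20L)
  ad_alt <- matrix(0L, 2, 19)
  ad_alt[, 1] <- c(8L, 15L)   # 0.8 and 0.75
  ad_alt[, 2] <- 10L
  vs4 <- make_vs(gt4, dp = dp4, ad_alt = ad_alt, ad_ref = dp4 - ad_alt)
  V <- site_violations(vs4, th)
  expect_equal(unname(V[, "het_ab"]), c(TRUE, FALSE))
  # (5) homozygote minor-read fraction above 0.05; exactly 0.05 passes
  gt5 <- rbind(gt_row19("1" = "0/1", "2" = "0/1"),
               gt_row19("1" = "0/1", "2" = "0/1"))
  dp5 <- matrix(20L, 2, 19)
  ad_alt5 <- matrix(0L, 2, 19)
  ad_alt5[, 1:2] <- 10L
  ad_alt5[1, 5] <- 2L  # hom-ref with 2/20 = 0.10 minor reads
  ad_alt5[2, 5] <- 1L  # 1/20 = 0.05 exactly: passes
  vs5 <- make_vs(gt5, dp = dp5, ad_alt = ad_alt5, ad_ref = dp5 - ad_alt5)
  V <- site_violations(vs5, th)
  expect_equal(unname(V[, "hom_ab"]), c(TRUE, FALSE))
})

test_that("minor allele frequency boundary follows the <= rule", {
  # 19 diploids: alt count 2/38 = 0.0526 passes; 1/38 = 0.0263 removed
  gt <- rbind(gt_row19("1" = "0/1", "2" = "0/1"),
              gt_row19("1" = "0/1"))
  V <- site_violations(make_vs(gt), filter_thresholds())
  expect_equal(unname(V[, "low_maf"]), c(FALSE, TRUE))
  # a site at exactly MAF = 0.05 is removed under <=, kept under strict <
  gt20 <- matrix("0/0", 2, 20)
  gt20[, 1] <- "1/1"  # 2/40 = 0.05
  vs20 <- make_vs(gt20)
  th20 <- filter_thresholds(n_samples = 20)
  expect_true(site_violations(vs20, th20)[1, "low_maf"])
  th20s <- filter_thresholds(n_samples = 20, maf_strict = TRUE)
  expect_false(site_violations(vs20, th20s)[1, "low_maf"])
  # monomorphic sites fall to the MAF criterion
  mono <- make_vs(rbind(gt_row19()))
  expect_true(site_violations(mono, filter_thresholds())[1, "low_maf"])
})

test_that("missing genotypes count as depth failures only when configured", {
  gt <- rbind(gt_row19("1" = "0/1", "2" = "0/1", "3" = NA))
  dp <- matrix(20L, 1, 19)
  vs <- make_vs(gt, dp = dp)
  expect_true(site_violations(vs, filter_thresholds())[1, "low_depth"])
  th_off <- filter_thresholds(missing_fails_depth = FALSE)
  expect_false(site_violations(vs, th_off)[1, "low_depth"])
})

test_that("the kept set is an OR over criteria, independent of order", {
  set.seed(101)
  sim <- simulate_genotypes(geno_sim_config(n_loci = 300, seed = 101))
  res <- apply_site_filters(sim$variants)
  V <- res$violations
  kept_fwd <- which(!Reduce(`|`, lapply(1:6, function(k) V[, k])))
  kept_rev <- which(!Reduce(`|`, lapply(6:1, function(k) V[, k])))
  expect_identical(kept_fwd, kept_rev)
  expect_identical(sort(res$kept$meta$locus_id),
                   sort(sim$variants$meta$locus_id[kept_fwd]))
  expect_equal(res$report$sites_out,
               res$report$sites_in - sum(res$report$first_failure))
})

test_that("missing AD where a balance check needs it names the site", {
  gt <- rbind(gt_row19("1" = "0/1", "2" = "0/1"))
  vs <- make_vs(gt, locus = "locus_X", pos = 42L)
  vs$ad_alt[1, 1] <- NA_integer_
  expect_error(site_violations(vs, filter_thresholds()), "locus_X:42")
})

test_that("locus presence requires genotypes in at least 15 of 19 samples", {
  gt <- rbind(gt_row19("1" = "0/1", "2" = "0/1"),
              gt_row19("1" = "0/1", "2" = "0/1"))
  gt[1, 15:19] <- NA  # locus A: 14 samples genotyped
  gt[2, 16:19] <- NA  # locus B: 15 samples genotyped
  vs <- make_vs(gt, locus = c("locA", "locB"))
  out <- locus_presence_filter(vs, filter_thresholds())
  expect_equal(out$meta$locus_id, "locB")
  empty <- subset_sites(vs, integer(0))
  expect_equal(n_sites(locus_presence_filter(empty, filter_thresholds())), 0L)
})

test_that("one SNP per locus is seeded, informative and exhaustive", {
  gt <- rbind(gt_row19("1" = "0/1", "2" = "0/1"),
              gt_row19("3" = "0/1", "4" = "0/1"),
              gt_row19("5" = "0/1", "6" = "0/1"),
              matrix("0/0", 1, 19))  # monomorphic: not informative
  vs <- make_vs(gt, locus = c("locA", "locA", "locA", "locB"),
                pos = c(10L, 20L, 30L, 40L))
  pick1 <- one_snp_per_locus(vs, seed = 5)
  expect_equal(n_sites(pick1), 1L)
  expect_equal(pick1$meta$locus_id, "locA")
  expect_identical(one_snp_per_locus(vs, seed = 5)$meta$pos, pick1$meta$pos)
  # without the informativeness requirement the monomorphic locus contributes
  pick2 <- one_snp_per_locus(vs, seed = 5, require_informative = FALSE)
  expect_equal(n_sites(pick2), 2L)
})

test_that("VCF output re-parses to the in-memory variant set", {
  set.seed(102)
  sim <- simulate_genotypes(geno_sim_config(n_loci = 60, seed = 102))
  f <- tempfile(fileext = ".vcf")
  on.exit(unlink(f))
  write_vcf(sim$variants, f)
  back <- read_vcf(f)
  expect_identical(back$gt, sim$variants$gt)
  expect_identical(back$dp, sim$variants$dp)
  expect_identical(back$ad_ref, sim$variants$ad_ref)
  expect_identical(back$ad_alt, sim$variants$ad_alt)
  expect_equal(back$meta$qual, sim$variants$meta$qual, tolerance = 1e-5)
  expect_identical(back$meta$locus_id, sim$variants$meta$locus_id)
  expect_identical(back$samples, sim$variants$samples)
  # filtering the re-parsed set gives the same kept sites
  expect_identical(apply_site_filters(back)$report$sites_out,
                   apply_site_filters(sim$variants)$report$sites_out)
})
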