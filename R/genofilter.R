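#' Six-criterion genotype filter cascade
#'
#' Hard filtering of multi-sample genotype calls, removing any site that (1)
#' has more than two alleles segregating, (2) is polymorphic with
#' Phred-scaled site quality below 20, (3) has read depth below ten in any
#' sample, (4) has a heterozygous sample with allele balance outside
#' [0.25, 0.75], (5) has a homozygous sample with minor-read fraction above
#' 0.05, or (6) has minor allele frequency at or below 0.05 across called
#' genotypes; plus locus-presence (>= 15 of 19 samples) and random
#' one-SNP-per-locus selection.
#'
#' @name genofilter
NULL

#' Filter thresholds
#'
#' Defaults are the standard cascade: biallelic only, QUAL >= 20 for
#' polymorphic sites, per-sample depth >= 10, heterozygote allele balance in
#' [0.25, 0.75], homozygote minor-read fraction <= 0.05, minor allele
#' frequency > 0.05, loci present in >= 15 of 19 samples.
#'
#' @param max_alleles maximum alleles segregating (criterion 1).
#' @param min_qual minimum site QUAL for polymorphic sites (criterion 2).
#' @param min_depth minimum per-sample read depth (criterion 3).
#' @param het_ab_low,het_ab_high allowed heterozygote allele-balance range
#'   (criterion 4, exclusive bounds on failure: fails when AB < low or
#'   AB > high).
#' @param hom_ab_max maximum homozygote minor-read fraction (criterion 5).
#' @param min_maf minor-allele-frequency cutoff (criterion 6); sites with
#'   MAF <= `min_maf` are removed, or MAF < `min_maf` when
#'   `maf_strict = TRUE`.
#' @param maf_strict use strict `<` for criterion 6.
#' @param min_samples_present locus-presence cutoff.
#' @param n_samples expected number of samples.
#' @param missing_fails_depth treat a missing genotype as a depth failure
#'   for criterion 3 (default TRUE).
#' @return a `filter_thresholds` list.
#' @export
filter_thresholds <- function(max_alleles = 2L, min_qual = 20,
                              min_depth = 10L, het_ab_low = 0.25,
                              het_ab_high = 0.75, hom_ab_max = 0.05,
                              min_maf = 0.05, maf_strict = FALSE,
                              min_samples_present = 15L, n_samples = 19L,
                              missing_fails_depth = TRUE) {
  stopifnot(het_ab_low > 0, het_ab_low < het_ab_high, het_ab_high < 1,
            hom_ab_max < het_ab_low)
  structure(list(max_alleles = as.integer(max_alleles), min_qual = min_qual,
                 min_depth = as.integer(min_depth), het_ab_low = het_ab_low,
                 het_ab_high = het_ab_high, hom_ab_max = hom_ab_max,
                 min_maf = min_maf, maf_strict = maf_strict,
                 min_samples_present = as.integer(min_samples_present),
                 n_samples = as.integer(n_samples),
                 missing_fails_depth = missing_fails_depth),
            class = "filter_thresholds")
}

#' Multi-sample variant container
#'
#' @param meta data frame with columns `locus_id`, `pos`, `ref`, `alt`
#'   (comma-separated when multiallelic) and `qual`.
#' @param gt character genotype matrix (sites x samples), `"0/0"`, `"0/1"`,
#'   `"1/1"`, `"1/2"`, ... ; `NA` or `"./."` for missing.
#' @param dp,ad_ref,ad_alt integer matrices of read depth and ref/alt read
#'   counts, same shape as `gt`.
#' @param samples sample ids (column names).
#' @return a `variant_set` object.
#' @export
variant_set <- function(meta, gt, dp, ad_ref, ad_alt, samples = colnames(gt)) {
  stopifnot(is.data.frame(meta),
            all(c("locus_id", "pos", "ref", "alt", "qual") %in% names(meta)),
            nrow(gt) == nrow(meta),
            all(dim(gt) == dim(dp)), all(dim(gt) == dim(ad_ref)),
            all(dim(gt) == dim(ad_alt)))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
  gt <- normalize_gt(gt)
  storage.mode(dp) <- "integer"
  storage.mode(ad_ref) <- "integer"
  storage.mode(ad_alt) <- "integer"
  colnames(gt) <- colnames(dp) <- colnames(ad_ref) <- colnames(ad_alt) <- samples
  if (any(meta$qual < 0, na.rm = TRUE)) stop("negative QUAL", call. = FALSE)
  structure(list(meta = meta, gt = gt, dp = dp, ad_ref = ad_ref,
                 ad_alt = ad_alt, samples = samples),
            class = "variant_set")
}

normalize_gt <- function(gt) {
  d <- dim(gt)
  v <- gsub("|", "/", as.character(gt), fixed = TRUE)
  v[grepl("\\.", v)] <- NA_character_
  parts <- strsplit(v, "/", fixed = TRUE)
  v <- vapply(parts, function(p) {
    if (anyNA(p) || length(p) == 0L) return(NA_character_)
    paste(sort(as.integer(p)), collapse = "/")
  }, character(1))
  v[is.na(gt)] <- NA_character_
  matrix(v, d[1], d[2])
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites x %d samples, %d loci\n",
              nrow(x$meta), length(x$samples),
              length(unique(x$meta$locus_id))))
  invisible(x)
}

#' Number of sites in a variant set
#' @param vs a `variant_set`.
#' @return integer.
#' @export
n_sites <- function(vs) nrow(vs$meta)

#' Subset a variant set by site index
#' @param vs a `variant_set`.
#' @param idx integer or logical site index.
#' @return a `variant_set`.
#' @export
subset_sites <- function(vs, idx) {
  variant_set(vs$meta[idx, , drop = FALSE],
              vs$gt[idx, , drop = FALSE],
              vs$dp[idx, , drop = FALSE],
              vs$ad_ref[idx, , drop = FALSE],
              vs$ad_alt[idx, , drop = FALSE],
              samples = vs$samples)
}

site_allele_list <- function(gt_row) {
  called <- gt_row[!is.na(gt_row)]
  if (length(called) == 0L) return(integer())
  as.integer(unlist(strsplit(called, "/", fixed = TRUE)))
}

is_het <- function(gt_row) {
  !is.na(gt_row) & vapply(strsplit(ifelse(is.na(gt_row), "0/0", gt_row), "/"),
                          function(p) p[1] != p[2], logical(1))
}

#' Evaluate the six criteria independently for every site
#'
#' Returns a sites x 6 logical matrix: `TRUE` means the site violates that
#' criterion. Because removal is an OR over criteria, the kept set does not
#' depend on evaluation order; the matrix supports both first-failure
#' attribution and independent violation counts.
#'
#' @param vs a `variant_set`.
#' @param th a [filter_thresholds()] list.
#' @return logical matrix with columns `multiallelic`, `low_qual`,
#'   `low_depth`, `het_ab`, `hom_ab`, `low_maf`.
#' @export
site_violations <- function(vs, th = filter_thresholds()) {
  if (length(vs$samples) != th$n_samples) {
    stop(sprintf("variant set has %d samples; thresholds expect %d",
                 length(vs$samples), th$n_samples), call. = FALSE)
  }
  n <- n_sites(vs)
  V <- matrix(FALSE, n, 6,
              dimnames = list(NULL, c("multiallelic", "low_qual", "low_depth",
                                      "het_ab", "hom_ab", "low_maf")))
  for (i in seq_len(n)) {
    gt <- vs$gt[i, ]
    alleles <- site_allele_list(gt)
    n_distinct <- length(unique(alleles))
    polymorphic <- n_distinct >= 2L
    # (1) more than two alleles segregating across all samples
    V[i, 1] <- n_distinct > th$max_alleles
    # (2) polymorphic but QUAL below cutoff
    V[i, 2] <- polymorphic && vs$meta$qual[i] < th$min_qual
    # (3) read depth below cutoff in any sample
    dp <- vs$dp[i, ]
    low_dp <- !is.na(dp) & dp < th$min_depth
    if (th$missing_fails_depth) low_dp <- low_dp | is.na(gt)
    V[i, 3] <- any(low_dp)
    # (4) heterozygote allele balance outside the allowed range
    het <- is_het(gt)
    if (any(het)) {
      need <- het & dp > 0
      if (any(need & (is.na(vs$ad_alt[i, ]) | is.na(vs$ad_ref[i, ])))) {
        stop(sprintf("missing AD at %s:%d for a heterozygous sample",
                     vs$meta$locus_id[i], vs$meta$pos[i]), call. = FALSE)
      }
      ab <- vs$ad_alt[i, need] / dp[need]
      V[i, 4] <- any(ab < th$het_ab_low | ab > th$het_ab_high)
    }
    # (5) homozygote minor-read fraction above cutoff
    hom <- !is.na(gt) & !het
    need <- hom & dp > 0
    if (any(need)) {
      if (any(need & (is.na(vs$ad_alt[i, ]) | is.na(vs$ad_ref[i, ])))) {
        stop(sprintf("missing AD at %s:%d for a homozygous sample",
                     vs$meta$locus_id[i], vs$meta$pos[i]), call. = FALSE)
      }
      first_allele <- as.integer(sub("/.*$", "", gt[need]))
      minor <- ifelse(first_allele == 0L, vs$ad_alt[i, need], vs$ad_ref[i, need])
      V[i, 5] <- any(minor / dp[need] > th$hom_ab_max)
    }
    # (6) minor allele frequency at / below cutoff over called genotypes
    maf <- if (n_distinct >= 2L) {
      tab <- table(alleles)
      min(tab) / sum(tab)
    } else 0
    V[i, 6] <- if (th$maf_strict) maf < th$min_maf else maf <= th$min_maf
  }
  V
}

#' Apply the six-criterion site filter cascade
#'
#' A site is removed when ANY criterion fires; criteria are attributed in
#' order 1 to 6 for first-failure counts, and independent violation counts
#' are reported alongside.
#'
#' @param vs a `variant_set`.
#' @param th a [filter_thresholds()] list.
#' @return list with `kept` (a `variant_set`), `report` (a `filter_report`:
#'   `first_failure` and `independent` named counts, `sites_in`,
#'   `sites_out`, `loci_out`) and `violations` (the full logical matrix).
#' @export
apply_site_filters <- function(vs, th = filter_thresholds()) {
  V <- site_violations(vs, th)
  any_fail <- rowSums(V) > 0
  first <- apply(V, 1, function(r) if (any(r)) which(r)[1] else 0L)
  ff <- vapply(seq_len(6), function(k) sum(first == k), integer(1))
  names(ff) <- colnames(V)
  kept <- subset_sites(vs, !any_fail)
  report <- structure(list(first_failure = ff,
                           independent = colSums(V),
                           sites_in = n_sites(vs),
                           sites_out = n_sites(kept),
                           loci_out = length(unique(kept$meta$locus_id))),
                      class = "filter_report")
  list(kept = kept, report = report, violations = V)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d sites in -> %d kept (%d loci)\n",
              x$sites_in, x$sites_out, x$loci_out))
  cat("first-failure removals:\n")
  print(x$first_failure)
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a `filter_report`.
#' @param path output file.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(criterion = names(report$first_failure),
                   first_failure = as.integer(report$first_failure),
                   independent = as.integer(report$independent))
  df <- rbind(df, data.frame(criterion = c("sites_in", "sites_out", "loci_out"),
                             first_failure = c(report$sites_in,
                                               report$sites_out,
                                               report$loci_out),
                             independent = NA_integer_))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Drop loci genotyped in too few samples
#'
#' A sample counts as having a locus when it carries at least one
#' non-missing genotype at that locus; loci present in fewer than
#' `min_samples_present` samples lose all their sites.
#'
#' @param vs a `variant_set`.
#' @param th a [filter_thresholds()] list.
#' @return a `variant_set`.
#' @export
locus_presence_filter <- function(vs, th = filter_thresholds()) {
  if (n_sites(vs) == 0L) return(vs)
  called <- !is.na(vs$gt)
  loci <- vs$meta$locus_id
  presence <- vapply(split(seq_len(n_sites(vs)), loci), function(ix) {
    sum(colSums(called[ix, , drop = FALSE]) > 0)
  }, numeric(1))
  keep_loci <- names(presence)[presence >= th$min_samples_present]
  subset_sites(vs, loci %in% keep_loci)
}

site_is_informative <- function(gt_row) {
  g <- unique(gt_row[!is.na(gt_row)])
  length(g) >= 2L
}

#' Keep one random informative SNP per locus
#'
#' For each locus, one site is chosen uniformly among its informative sites
#' (those variable across called genotypes) using the seeded generator; loci
#' without an informative site contribute nothing. Deterministic given the
#' seed.
#'
#' @param vs a `variant_set`.
#' @param seed integer RNG seed.
#' @param require_informative restrict choice to informative sites
#'   (default TRUE).
#' @return a `variant_set` with at most one site per locus.
#' @export
one_snp_per_locus <- function(vs, seed, require_informative = TRUE) {
  if (n_sites(vs) == 0L) return(vs)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  loci <- vs$meta$locus_id
  pick <- integer(0)
  for (loc in unique(loci)) {
    ix <- which(loci == loc)
    if (require_informative) {
      ok <- vapply(ix, function(i) site_is_informative(vs$gt[i, ]), logical(1))
      ix <- ix[ok]
    }
    if (length(ix) == 0L) next
    pick <- c(pick, if (length(ix) == 1L) ix else sample(ix, 1L))
  }
  subset_sites(vs, sort(pick))
}
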