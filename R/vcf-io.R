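#' VCF input and output
#'
#' A `variant_set` round-trips through VCF 4.2 with per-sample `GT:DP:AD`
#' fields and the site QUAL column. Reading uses vcfR; writing emits plain
#' uncompressed text.
#'
#' @name vcf-io
NULL

#' Write a variant set as VCF 4.2
#'
#' @param vs a `variant_set`.
#' @param path output file (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=phylopop",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele read depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs$samples), collapse = "\t"))
  n <- n_sites(vs)
  body <- character(n)
  for (i in seq_len(n)) {
    n_alt <- length(strsplit(vs$meta$alt[i], ",", fixed = TRUE)[[1]])
    cells <- vapply(seq_along(vs$samples), function(j) {
      gt <- vs$gt[i, j]
      dp <- vs$dp[i, j]
      ad <- c(vs$ad_ref[i, j], vs$ad_alt[i, j], rep(0L, max(0L, n_alt - 1L)))
      sprintf("%s:%s:%s",
              if (is.na(gt)) "./." else gt,
              if (is.na(dp)) "." else as.character(dp),
              if (anyNA(ad)) "." else paste(ad, collapse = ","))
    }, character(1))
    body[i] <- paste(c(vs$meta$locus_id[i], vs$meta$pos[i], ".",
                       vs$meta$ref[i], vs$meta$alt[i],
                       sprintf("%.6g", vs$meta$qual[i]), "PASS", ".",
                       "GT:DP:AD", cells), collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a variant set
#'
#' Requires per-sample GT, DP and AD FORMAT fields; the first two AD values
#' are taken as reference and alternate read counts.
#'
#' @param path a VCF file (plain or gzipped).
#' @return a `variant_set`.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  meta <- data.frame(locus_id = fix$CHROM,
                     pos = as.integer(fix$POS),
                     ref = fix$REF,
                     alt = fix$ALT,
                     qual = as.numeric(fix$QUAL))
  gt <- vcfR::extract.gt(vcf, "GT")
  dp <- vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, "AD")
  split_ad <- function(k) {
    v <- vapply(strsplit(as.character(ad), ",", fixed = TRUE), function(p) {
      if (length(p) < k || anyNA(p) || p[k] == ".") NA_integer_
      else as.integer(p[k])
    }, integer(1))
    matrix(v, nrow(gt), ncol(gt))
  }
  rownames(gt) <- NULL
  variant_set(meta,
              gt = gt,
              dp = matrix(as.integer(dp), nrow(gt), ncol(gt)),
              ad_ref = split_ad(1L),
              ad_alt = split_ad(2L),
              samples = colnames(vcf@gt)[-1])
}
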