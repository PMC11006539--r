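#' End-to-end pipeline driver
#'
#' Wires the stages together over a file-based workspace: `simulate` writes
#' synthetic inputs (family FASTA/newick plus a genotype VCF, each with
#' truth labels), `cluster` builds homolog clusters from the pooled
#' sequences, `clean-trees` infers neighbor-joining trees per cluster and
#' runs the two-round long-branch cleaning, `orthologs` extracts
#' maximum-inclusion orthologs with their alignments, `alnstats`
#' concatenates them and reports summary statistics, `filter-vcf` runs the
#' six-criterion cascade plus locus-presence and one-SNP-per-locus
#' selection, and `pca` computes the genotype PCA with Hardy-Weinberg
#' diagnostics. `all` runs the whole chain. Every run writes a
#' machine-readable JSON manifest (parameters, seed, md5 of each artifact).
#'
#' @name pipeline
NULL

PIPELINE_STAGES <- c("simulate", "cluster", "clean-trees", "orthologs",
                     "alnstats", "filter-vcf", "pca", "all")

#' Assemble a pipeline configuration
#'
#' Defaults are the pipeline's standard settings: cd-hit-style redundancy
#' threshold 0.99, similarity-graph minimum identity 0.7, MCL inflation
#' 1.4, clusters kept at >= 4 taxa, two cleaning rounds at
#' relative 0.02 / sister factor 10 / absolute 0.03 / deep split 0.2,
#' orthologs at >= 10 taxa, 10% column occupancy, and the six-criterion
#' genotype filter.
#'
#' @param seed global seed; per-stage seeds are derived deterministically
#'   from it and the stage name.
#' @param family a [family_sim_config()].
#' @param geno a [geno_sim_config()].
#' @param clean a [clean_params()].
#' @param mi an [mi_params()].
#' @param thresholds a [filter_thresholds()].
#' @param identity_threshold redundancy-reduction identity.
#' @param min_identity similarity-graph edge cutoff.
#' @param inflation MCL inflation.
#' @param min_cluster_taxa minimum taxa per homolog cluster.
#' @param occupancy minimum column occupancy for alignment cleaning.
#' @param pca_k number of principal components to report.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            family = family_sim_config(seed = seed),
                            geno = geno_sim_config(seed = seed),
                            clean = clean_params(),
                            mi = mi_params(),
                            thresholds = filter_thresholds(),
                            identity_threshold = 0.99,
                            min_identity = 0.7,
                            inflation = 1.4,
                            min_cluster_taxa = 4L,
                            occupancy = 0.10,
                            pca_k = 5L) {
  structure(list(seed = as.integer(seed), family = family, geno = geno,
                 clean = clean, mi = mi, thresholds = thresholds,
                 identity_threshold = identity_threshold,
                 min_identity = min_identity, inflation = inflation,
                 min_cluster_taxa = as.integer(min_cluster_taxa),
                 occupancy = occupancy, pca_k = as.integer(pca_k)),
            class = "pipeline_config")
}

#' Derive a deterministic per-stage seed from the global seed
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return an integer below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) %% 1e6 * 9973 + h * 131) %% 2147483647)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; nested blocks
#' (`family`, `geno`, `clean`, `mi`, `thresholds`) mirror the matching
#' constructor arguments. Unknown keys at any level are rejected.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  builders <- list(family = family_sim_config, geno = geno_sim_config,
                   clean = clean_params, mi = mi_params,
                   thresholds = filter_thresholds)
  top_ok <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), top_ok)
  if (length(bad) > 0L) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  args <- list()
  for (key in names(raw)) {
    if (key %in% names(builders)) {
      sub <- raw[[key]]
      ok <- names(formals(builders[[key]]))
      bad <- setdiff(names(sub), ok)
      if (length(bad) > 0L) {
        stop("unknown config key(s) under '", key, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      args[[key]] <- do.call(builders[[key]], sub)
    } else {
      args[[key]] <- raw[[key]]
    }
  }
  if (!is.null(args$seed)) {
    if (is.null(raw$family)) args$family <- family_sim_config(seed = args$seed)
    if (is.null(raw$geno)) args$geno <- geno_sim_config(seed = args$seed)
  }
  do.call(pipeline_config, args)
}

pp_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

require_input <- function(path) {
  if (!all(file.exists(path))) {
    stop("missing input file: ", paste(path[!file.exists(path)],
                                       collapse = ", "), call. = FALSE)
  }
  invisible(path)
}

## ---- stages --------------------------------------------------------------

stage_simulate <- function(config, out_dir) {
  fam_dir <- file.path(out_dir, "families")
  dir.create(fam_dir, recursive = TRUE, showWarnings = FALSE)
  fam_cfg <- config$family
  fam_cfg$seed <- derive_seed(config$seed, "simulate-families")
  fams <- simulate_family_set(fam_cfg)
  write_newick_file(fams$species_tree, file.path(out_dir, "species_tree.nwk"))
  truth_rows <- list()
  for (nm in names(fams$families)) {
    f <- fams$families[[nm]]
    write_fasta_alignment(f$alignment, file.path(fam_dir, paste0(nm, ".fasta")))
    write_newick_file(f$tree, file.path(fam_dir, paste0(nm, ".nwk")))
    truth_rows[[nm]] <- data.frame(
      family = nm,
      contaminant_tips = paste(f$truth$contaminant_tips, collapse = ","),
      paralog_tips = paste(f$truth$paralog_tips, collapse = ","),
      deep_split = f$truth$deep_split)
  }
  utils::write.table(do.call(rbind, truth_rows),
                     file.path(out_dir, "family_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  geno_cfg <- config$geno
  geno_cfg$seed <- derive_seed(config$seed, "simulate-genotypes")
  geno <- simulate_genotypes(geno_cfg)
  write_vcf(geno$variants, file.path(out_dir, "genotypes.vcf"))
  utils::write.table(geno$truth$sites, file.path(out_dir, "geno_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = rownames(geno$truth$admixture),
               geno$truth$admixture, profile = geno$truth$profiles),
    file.path(out_dir, "admixture_truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  pp_log("simulate", length(fams$families), " families, ",
         n_sites(geno$variants), " genotype sites out")
  c("species_tree.nwk", "family_truth.tsv", "genotypes.vcf",
    "geno_truth.tsv", "admixture_truth.tsv",
    file.path("families", paste0(names(fams$families),
                                 rep(c(".fasta", ".nwk"),
                                     each = length(fams$families)))))
}

# pool per-sample records across family alignments; record ids get a
# running copy index per sample, with provenance kept for later stages
pool_family_records <- function(out_dir) {
  fam_files <- sort(list.files(file.path(out_dir, "families"),
                               pattern = "\\.fasta$", full.names = TRUE))
  require_input(fam_files)
  counter <- new.env()
  rows <- list()
  for (fp in fam_files) {
    fam <- sub("\\.fasta$", "", basename(fp))
    a <- read_fasta_alignment(fp)
    seqs <- alignment_strings(a)
    for (tip in names(seqs)) {
      sample <- tip_taxon(tip)
      k <- (get0(sample, envir = counter, ifnotfound = 0L)) + 1L
      assign(sample, k, envir = counter)
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0(sample, "@", k), sample_id = sample, copy_index = k,
        family = fam, tip_label = tip, seq = unname(seqs[[tip]]))
    }
  }
  do.call(rbind, rows)
}

stage_cluster <- function(config, out_dir) {
  records <- pool_family_records(out_dir)
  reps <- do.call(rbind, lapply(split(records, records$sample_id), function(r) {
    reduce_redundancy(r, config$identity_threshold)
  }))
  pp_log("cluster", nrow(records), " records in, ", nrow(reps),
         " after redundancy reduction")
  g <- build_similarity_graph(reps, min_identity = config$min_identity)
  clusters <- markov_cluster(g, inflation = config$inflation)
  kept <- filter_clusters(clusters, min_taxa = config$min_cluster_taxa)
  pp_log("cluster", length(clusters), " raw clusters, ", kept$n_kept,
         " kept (>= ", config$min_cluster_taxa, " taxa)")
  write_cluster_tsv(kept$clusters, file.path(out_dir, "clusters.tsv"))
  utils::write.table(records[, c("id", "sample_id", "copy_index", "family",
                                 "tip_label")],
                     file.path(out_dir, "records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hom_dir <- file.path(out_dir, "homologs")
  dir.create(hom_dir, showWarnings = FALSE)
  seq_of <- stats::setNames(records$seq, records$id)
  for (i in seq_along(kept$clusters)) {
    ids <- kept$clusters[[i]]
    aln <- as_alignment(seq_of[ids])
    write_fasta_alignment(aln, file.path(hom_dir,
                                         sprintf("hom_%04d.fasta", i)))
  }
  c("clusters.tsv", "records.tsv",
    file.path("homologs", sprintf("hom_%04d.fasta",
                                  seq_along(kept$clusters))))
}

stage_clean_trees <- function(config, out_dir) {
  hom_files <- sort(list.files(file.path(out_dir, "homologs"),
                               pattern = "\\.fasta$", full.names = TRUE))
  require_input(hom_files)
  trees <- list()
  alns <- list()
  for (fp in hom_files) {
    a <- read_fasta_alignment(fp)
    nm <- sub("\\.fasta$", "", basename(fp))
    alns[[nm]] <- a
    if (nrow(a) < 3L) next
    d <- tryCatch(jc_distance_matrix(alignment_strings(a)),
                  error = function(e) NULL)
    if (is.null(d)) {
      pp_log("clean-trees", "skipping ", nm, ": saturated distances")
      next
    }
    trees[[nm]] <- neighbor_joining(d)
  }
  pp_log("clean-trees", length(trees), " homolog trees in")
  res <- clean_trees(trees, config$clean)
  write_clean_report(res$reports, file.path(out_dir, "clean_report.tsv"))
  clean_dir <- file.path(out_dir, "cleaned_trees")
  dir.create(clean_dir, showWarnings = FALSE)
  out <- character()
  for (i in seq_along(res$trees)) {
    fn <- sprintf("clean_%04d.nwk", i)
    write_newick_file(res$trees[[i]], file.path(clean_dir, fn))
    out <- c(out, file.path("cleaned_trees", fn))
  }
  pp_log("clean-trees", length(res$trees), " trees out after ",
         config$clean$rounds, " rounds")
  c("clean_report.tsv", out)
}

stage_orthologs <- function(config, out_dir) {
  tree_files <- sort(list.files(file.path(out_dir, "cleaned_trees"),
                                pattern = "\\.nwk$", full.names = TRUE))
  require_input(tree_files)
  require_input(file.path(out_dir, "records.tsv"))
  records <- utils::read.delim(file.path(out_dir, "records.tsv"))
  fam_of <- stats::setNames(records$family, records$id)
  orth_dir <- file.path(out_dir, "orthologs")
  dir.create(orth_dir, showWarnings = FALSE)
  manifest <- list()
  k <- 0L
  n_trees <- 0L
  for (fp in tree_files) {
    tr <- read_newick_file(fp)[[1]]
    n_trees <- n_trees + 1L
    orths <- max_inclusion(tr, config$mi)
    for (o in orths) {
      k <- k + 1L
      oid <- sprintf("orth_%04d", k)
      fams <- unique(fam_of[o$tip.label])
      fam_fa <- file.path(out_dir, "families",
                          paste0(fams[1], ".fasta"))
      require_input(fam_fa)
      fam_aln <- read_fasta_alignment(fam_fa)
      tip_of <- stats::setNames(records$tip_label, records$id)
      rows <- fam_aln[tip_of[o$tip.label], , drop = FALSE]
      rownames(rows) <- o$tip.label
      aln <- extract_ortholog_alignment(rows, o, occupancy = config$occupancy)
      write_fasta_alignment(aln, file.path(orth_dir, paste0(oid, ".fasta")))
      write_newick_file(o, file.path(orth_dir, paste0(oid, ".nwk")))
      manifest[[oid]] <- data.frame(ortholog_id = oid,
                                    source_tree = basename(fp),
                                    n_taxa = length(o$tip.label))
    }
  }
  df <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(ortholog_id = character(), source_tree = character(),
               n_taxa = integer())
  utils::write.table(df, file.path(out_dir, "ortholog_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pp_log("orthologs", n_trees, " trees in, ", k, " orthologs out")
  c("ortholog_manifest.tsv",
    file.path("orthologs", paste0(df$ortholog_id,
                                  rep(c(".fasta", ".nwk"), each = nrow(df)))))
}

stage_alnstats <- function(config, out_dir) {
  orth_files <- sort(list.files(file.path(out_dir, "orthologs"),
                                pattern = "\\.fasta$", full.names = TRUE))
  require_input(orth_files)
  alns <- lapply(orth_files, read_fasta_alignment)
  names(alns) <- sub("\\.fasta$", "", basename(orth_files))
  conc <- concatenate_alignments(alns)
  write_fasta_alignment(conc$alignment, file.path(out_dir, "supermatrix.fasta"))
  write_partitions_raxml(conc$partitions, file.path(out_dir, "partitions.txt"))
  stats_df <- do.call(rbind, lapply(names(alns), function(nm) {
    cbind(gene_id = nm, alignment_stats(alns[[nm]]))
  }))
  total <- cbind(gene_id = "concatenated", alignment_stats(conc$alignment))
  # tree length of an NJ tree on the supermatrix, organelle-style
  tl <- tryCatch({
    d <- jc_distance_matrix(alignment_strings(conc$alignment))
    tree_length(neighbor_joining(d))
  }, error = function(e) NA_real_)
  stats_df <- rbind(stats_df, total)
  stats_df$tree_length <- c(rep(NA_real_, nrow(stats_df) - 1L), tl)
  utils::write.table(stats_df, file.path(out_dir, "alignment_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pp_log("alnstats", length(alns), " ortholog alignments, ",
         ncol(conc$alignment), " concatenated columns, ",
         total$informative_sites, " informative sites")
  c("supermatrix.fasta", "partitions.txt", "alignment_stats.tsv")
}

stage_filter_vcf <- function(config, out_dir, vcf = NULL) {
  vcf <- if (is.null(vcf)) file.path(out_dir, "genotypes.vcf") else vcf
  require_input(vcf)
  th <- config$thresholds
  pp_log("filter-vcf", sprintf(
    "criteria: max_alleles=%d min_qual=%g min_depth=%d het_ab=%g-%g hom_ab=%g min_maf=%g",
    th$max_alleles, th$min_qual, th$min_depth, th$het_ab_low, th$het_ab_high,
    th$hom_ab_max, th$min_maf))
  vs <- read_vcf(vcf)
  res <- apply_site_filters(vs, th)
  pp_log("filter-vcf", res$report$sites_in, " sites in, ",
         res$report$sites_out, " after the six-criterion cascade")
  present <- locus_presence_filter(res$kept, th)
  snps <- one_snp_per_locus(present, seed = derive_seed(config$seed,
                                                        "one-snp-per-locus"))
  pp_log("filter-vcf", n_sites(present), " after locus presence, ",
         n_sites(snps), " informative SNPs (one per locus)")
  write_filter_report(res$report, file.path(out_dir, "filter_report.tsv"))
  write_vcf(snps, file.path(out_dir, "filtered.vcf"))
  c("filter_report.tsv", "filtered.vcf")
}

stage_pca <- function(config, out_dir) {
  require_input(file.path(out_dir, "filtered.vcf"))
  vs <- read_vcf(file.path(out_dir, "filtered.vcf"))
  G <- genotype_matrix(vs)
  S <- suppressWarnings(standardize_genotypes(G))
  k <- min(config$pca_k, nrow(S) - 1L, ncol(S))
  pca <- genotype_pca(S, k)
  write_pca_tsv(pca, file.path(out_dir, "pca.tsv"))
  hwe <- het_vs_hwe(G)
  utils::write.table(hwe, file.path(out_dir, "hwe.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pp_log("pca", ncol(S), " SNPs, PC1/PC2 explain ",
         sprintf("%.2f%%/%.2f%%", 100 * pca$explained_fraction[1],
                 100 * pca$explained_fraction[2]))
  c("pca.tsv", "hwe.tsv")
}

## ---- driver --------------------------------------------------------------

#' Run pipeline stages
#'
#' @param subcommand one of `"simulate"`, `"cluster"`, `"clean-trees"`,
#'   `"orthologs"`, `"alnstats"`, `"filter-vcf"`, `"pca"` or `"all"`.
#' @param config a [pipeline_config()].
#' @param out_dir workspace directory (created if needed); stages read
#'   their inputs from it and write their artifacts into it.
#' @param vcf optional external VCF path for `filter-vcf`.
#' @return invisibly, the manifest list (also written to
#'   `manifest.json` in `out_dir`).
#' @export
run_pipeline <- function(subcommand = "all", config = pipeline_config(),
                         out_dir, vcf = NULL) {
  if (!subcommand %in% PIPELINE_STAGES) {
    stop("unknown subcommand '", subcommand, "'; expected one of: ",
         paste(PIPELINE_STAGES, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (subcommand == "all") {
    c("simulate", "cluster", "clean-trees", "orthologs", "alnstats",
      "filter-vcf", "pca")
  } else subcommand
  artifacts <- character()
  for (st in stages) {
    out <- switch(st,
      "simulate" = stage_simulate(config, out_dir),
      "cluster" = stage_cluster(config, out_dir),
      "clean-trees" = stage_clean_trees(config, out_dir),
      "orthologs" = stage_orthologs(config, out_dir),
      "alnstats" = stage_alnstats(config, out_dir),
      "filter-vcf" = stage_filter_vcf(config, out_dir, vcf = vcf),
      "pca" = stage_pca(config, out_dir))
    artifacts <- c(artifacts, out)
  }
  paths <- file.path(out_dir, artifacts)
  manifest <- list(
    package = "phylopop",
    version = as.character(utils::packageVersion("phylopop")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    subcommand = subcommand,
    seed = config$seed,
    parameters = strip_classes(config),
    artifacts = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                        artifacts)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

strip_classes <- function(x) {
  if (is.matrix(x)) return(apply(x, 1, as.numeric, simplify = FALSE))
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}
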