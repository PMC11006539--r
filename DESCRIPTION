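Package: phylopop
Title: Phylotranscriptomic Orthology and Population-Structure Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for phylotranscriptomic and population-genetic
    analysis of multi-sample transcriptome data: greedy redundancy reduction,
    k-mer-seeded similarity graphs refined by Markov clustering into homolog
    clusters, two-round long-branch trimming and deep-branch splitting of
    homolog gene trees, maximum-inclusion orthology extraction, alignment
    occupancy cleaning and summary statistics, a six-criterion genotype
    hard-filter cascade over VCF calls (allele count, site quality, depth,
    allele balance, minor allele frequency), locus-presence and
    one-SNP-per-locus selection, and genotype PCA with Hardy-Weinberg
    diagnostics. A layered-admixture synthetic-data generator produces every
    input the pipeline consumes, with ground-truth labels, so the whole chain
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
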