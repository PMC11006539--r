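---
title: "Methods: from transcriptomes to orthologs and population structure"
author: "phylopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from transcriptomes to orthologs and population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phylopop` chains two analyses that usually live in separate toolboxes: a
phylotranscriptomic ortholog-extraction pipeline (clustering, gene-tree
cleaning, maximum-inclusion orthology, alignment statistics) and a
population-genetic one (genotype hard filtering, LD thinning, PCA,
Hardy–Weinberg diagnostics). This vignette describes the models and
procedures, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic-data generator does
and does not emulate.

## Homolog clustering

Per-sample transcript sets are first reduced for redundancy with a greedy
longest-first pass (`reduce_redundancy()`): records are visited by
decreasing length, ties broken lexicographically by record id for
determinism, and a record is absorbed by the first representative whose
identity — matches divided by the length of the shorter sequence, with
exact containment scoring 1 — reaches the threshold (default **0.99**).
This is the cd-hit convention for full-length/containment clustering; the
longest member of every cluster always survives.

The all-by-all similarity search is an in-package k-mer comparison
(`build_similarity_graph()`): two records become a candidate pair when they
share an exact 12-mer (seeds sampled every 5 positions), and are then
compared ungapped at the offset implied by their first shared seed;
identity over the non-gap overlap must reach `min_identity` (default
**0.7**) to store an edge. A sequence-similarity cutoff converting search
hits into clustering input is not something the upstream literature fixes
precisely (e-value-based searches admit arbitrarily weak hits); 0.7 is far
above the ~0.25 identity of unrelated DNA and far below the within-family
identities the simulator produces, and it is exposed in the configuration.
The seeding assumes homologous sequences align without indels at a common
offset — true for the generator's data and for high-identity coding
sequences; diverged sequences with indels would need a real local aligner,
which is exactly the component this one stands in for.

Markov clustering (`markov_cluster()`) runs on the weighted adjacency with
self-loops set to each vertex's maximum incident weight: columns are
normalized to stochastic form, then expansion (matrix square) alternates
with inflation (elementwise power **1.4**, renormalize, prune entries
below 1e-8) until the matrix moves by less than 1e-6 or 100 iterations.
Clusters are connected components of the limit matrix, so the result is
always a partition. The numeric details (self-loop weight, pruning,
tolerance) follow common MCL practice; inflation 1.4 deliberately produces
coarse clusters, which is the behaviour wanted for homolog families.
Clusters spanning fewer than **4** distinct taxa are dropped.

## Gene-tree cleaning

Homolog trees carry branch lengths in substitutions per site; tip labels
are `sample[@copy]`, and the taxon of a tip is the label before `@`.
`trim_long_tips()` removes a tip iff

* its terminal branch is ≥ `relative_cutoff` (**0.02** subs/site) AND
  ≥ `sister_factor` (**10**) times its sister branch, **or**
* its terminal branch is ≥ `absolute_cutoff` (**0.03** subs/site).

Two points are interpretations and are flagged as such. First, the
"and/or" in the rule is read as (relative AND sister-factor) OR absolute,
matching the two-cutoff (relative, absolute) parameterization that the
orthology stage reuses. Second, the sister branch of a tip whose sibling
subtree is internal is taken to be the sibling edge length itself (when
tip siblings exist, the minimum of their terminal lengths is used); this
gives a concrete, testable rule. All removals in a sweep are decided on
the pre-sweep tree — no cascading within a round — so the result is
order-independent; cascading happens only across rounds. After pruning,
degree-2 nodes are suppressed with their two edge lengths summed. A tree
that would drop below two tips is discarded and flagged.

`split_deep_branches()` cuts internal edges longer than `deep_cutoff`
(**0.2** subs/site) when both sides retain at least `min_side_taxa`
(**4**) distinct taxa, longest edge first, re-examining the resulting
components. The whole trim+split procedure runs for **2** rounds with the
same settings, and each round reports per-sample removal rates
(tips removed / tips before).

## Maximum-inclusion orthology

`max_inclusion()` iterates three steps on each cleaned homolog tree:
(1) trim long tips with the same relative/absolute cutoffs; (2) enumerate
every subtree induced by cutting each edge in each direction (plus the
full tree) and, among those containing no repeated taxon, select the one
with the most distinct taxa — ties broken by smaller total branch length,
then by the lexicographically smallest sorted tip-label list; (3) if the
winner has at least `min_taxa` (**10**) taxa, emit it as an ortholog and
delete its tips from the working tree. The greedy loop, the tie rules and
the per-iteration re-trim are not fully pinned down by the method's
literature; the deterministic rules above make the output reproducible and
testable against a brute-force enumeration oracle. Whether trimming
recurs at every iteration or only once is configurable
(`retrim = "each_iteration"` / `"once"`); re-trimming every iteration is
the default since deleting subtrees can expose new long terminal branches.
Note a consequence of enumerating both directions of every edge: removing
a single duplicated tip (the complement side of its terminal edge) can
legitimately beat any clade-side subtree, because the complement keeps all
other taxa.

Ortholog alignments are extracted from the homolog alignment rows
(`extract_ortholog_alignment()`), re-cleaned for column occupancy and
renamed to bare taxa.

## Alignment statistics

`clean_columns()` keeps a column iff the fraction of rows with a
non-missing character is **≥ 0.10** (boundary inclusive — "minimum
occupancy" is read as attainment). `N` counts as missing alongside `-` by
default; the choice is exposed (`missing_chars`) since conventions differ.
`concatenate_alignments()` pads absent taxa with gaps and emits 1-based
inclusive partitions that tile the supermatrix; a column is
parsimony-informative when ≥ 2 non-missing states each occur in ≥ 2 rows;
`tree_length()` is the plain branch-length sum and is invariant to
rooting.

## The genotype filter cascade

A site is removed when **any** of the six criteria fires; because removal
is an OR, the kept set does not depend on evaluation order, and the report
gives both first-failure attribution (order 1→6) and independent counts.

1. more than `max_alleles` (**2**) alleles segregating across samples;
2. polymorphic but site QUAL < `min_qual` (**20**) — invariant sites are
   exempt, having no variant to score;
3. read depth < `min_depth` (**10**) in any of the 19 samples — a missing
   genotype counts as a depth failure by default
   (`missing_fails_depth = TRUE`, configurable, since callers differ on
   whether an uncalled sample implies insufficient depth);
4. any heterozygote with allele balance (alt reads / depth) < **0.25** or
   > **0.75**;
5. any homozygote with minor-read fraction > **0.05** — "minor" is the
   non-called allele, so reference reads for 1/1 calls and alternate reads
   for 0/0 calls, a symmetric reading that matches caller usage;
6. minor allele frequency ≤ `min_maf` (**0.05**) over called genotypes
   (missing genotypes excluded from the denominator). The boundary is
   implemented as ≤ with a strict-`<` variant available
   (`maf_strict = TRUE`), since both conventions appear in practice.

After the cascade, loci genotyped in fewer than **15 of 19** samples are
dropped — a sample counts as having a locus when it has at least one
called genotype there (the per-locus aggregation is otherwise unspecified;
this is the permissive reading and is documented here) — and one SNP per
locus is drawn uniformly among the locus's *informative* sites (≥ 2
distinct called genotype values across samples), under a caller-supplied
seed.

## PCA and Hardy–Weinberg diagnostics

Genotypes are standardized per site as (g − 2p)/√(2p(1−p)) with p the alt
allele frequency over non-missing calls; missing entries are
mean-imputed (0 after centring) and monomorphic or constant columns are
dropped with a warning. This is the EIGENSTRAT convention the standard
SNP-PCA tools default to. PCA is the eigendecomposition of the n × n
sample covariance S·Sᵀ/m; coordinates are eigenvectors scaled by
√eigenvalue, explained fractions are eigenvalues over the trace, and each
component is oriented so its largest-magnitude coordinate is positive — a
pure output convention that makes runs reproducible. `het_vs_hwe()`
tabulates the observed heterozygote fraction against 2p̂(1−p̂) per site.
`cluster_recovery()` scores k-means on PC1–2 against known labels by the
best label permutation (or, when the cluster count differs from the label
count, by modal-label mapping — for k = 1 this reduces to the modal label
frequency).

## What the simulator emulates — and what it does not

`simulate_species_tree()` draws a coalescent-shaped 19-sample ingroup with
every branch from U(0.001, 0.01) substitutions per site — the "minimal
divergence among individuals" regime where gene trees are shallow — and
attaches a 2-sample outgroup on a 0.05 stem. `simulate_family()` plants,
per family: a duplicated clade (probability 0.3) whose stem is a deep
0.25-subs/site split with probability 0.15 (the clade is then required to
hold ≥ 4 taxa so the split is detectable) or a short 0.005 stem otherwise;
and a contaminant tip (probability 0.2) with terminal length in
[0.05, 0.10). The threshold separation — contaminants ≥ 0.05 against
legitimate branches ≤ 0.01, deep splits at 0.25 against the 0.2 cutoff —
makes the truth labels unambiguous, which is what lets the cleaning tests
demand sensitivity and specificity of exactly 1. Sequences evolve under
Jukes–Cantor with no indels, so family rows are aligned by construction;
occupancy variation comes from terminal masking (probability 0.1 per
sequence, masking 5–30% of one end) rather than from indels — simpler,
and sufficient to exercise the occupancy cleaner. Defaults of 40 families
at 1000 sites keep a full run around half a minute on one core while
leaving every per-sample count in the hundreds.

`simulate_genotypes()` draws, per SNP, an ancestral frequency
p ~ U(0.1, 0.9) and layer frequencies from the Balding–Nichols model
Beta(p(1−F)/F, (1−p)(1−F)/F) with **F = 0.1** (F = 0 collapses all layers
to p); each of 19 samples mixes layer frequencies by its admixture row and
draws a Binomial(2, ·) genotype. The default layout is 8 samples of pure
layer-1 (north-east) ancestry, 9 of pure layer-2 (south-west) and 2
admixed 60/40 — the third layer of the k = 3 model carries no weight under
this default, and the "truth classes" for recovery scoring are the
distinct ancestry profiles (NE, SW, admixed). Depth is
Poisson(30) floored at 10; allele depths follow the genotype with 1%
error. Non-corrupted sites are constructed to genuinely pass the cascade:
the minor allele count is rejection-resampled above the MAF cutoff,
heterozygote allele balances are clamped into [0.25, 0.75] and homozygote
minor reads to ≤ 5% of depth. Each corrupted site (rate 0.02 per artifact
type) violates exactly the criterion recorded in its truth label: an extra
third allele; QUAL drawn below 20; one sample's depth below 10; a
heterozygote pushed to AB ≈ 0.2 or 0.8; a homozygote given > 5% minor
reads; a single-heterozygote site (MAF 1/38); or a missing genotype
(scored against the depth criterion, matching the default
`missing_fails_depth`).

Features of real data the generator does **not** emulate: indels and
alignment error, recombination and within-locus linkage beyond a shared
locus id, selection, spatially continuous gene flow, reference bias in
read mapping, and base-calling error structure beyond the symmetric 1%.
Passing tests therefore demonstrate the correctness of the implemented
rules and the recoverability of planted signal under those rules — not
robustness to the full messiness of empirical transcriptome data.

## Test and verification sizes

The suite checks each operation against independent oracles (brute-force
column scans, a maximum-inclusion enumeration oracle built on different
tree machinery, closed-form distances, an external JC69 implementation)
and validates the planted-truth recoveries at these sizes, chosen to give
tight binomial bounds while keeping the default run near a minute:
200 random trees (≤ 12 tips, 0–4 duplicate taxa) for orthology oracle
equivalence; 500 simulated families for contaminant-trim recovery;
100 families for deep-split recovery; 2000 sites for filter-cascade
exactness; 100 replicates each for neighbor-joining topology recovery and
for MCL planted partitions (3 blocks × 10 vertices — block size at the
scale of a homolog family; within-block edge probability 0.9 with weights
U(0.8, 1), between-block 0.02); 2000 loci for three-layer PCA recovery
(three pure layers of 7/6/6 — k-means recovery needs every sample to have
a true layer, so the admixed default layout instead backs the PC1
intermediacy check); 50 replicates × 500 loci for the panmictic (F = 0)
no-structure control; 1000 sites for the Hardy–Weinberg diagnostic.

## Known limitations

The k-mer seeding assumes a shared exact seed at a common offset, so
highly diverged or indel-rich homologs would be missed; MCL runs on a
dense matrix, fine for thousands of vertices but not hundreds of
thousands; neighbor-joining trees from JC distances stand in for
likelihood-based gene-tree inference, so terminal-branch estimates on real
data would be noisier than the simulator's planted lengths; and the
admixture model treats loci as exchangeable and unlinked. The deliberately
coarse inflation of 1.4 means MCL can merge two families bridged by
several spurious high-weight edges; at realistic cross-family identities
such edges fall below the 0.7 cutoff and never form.
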