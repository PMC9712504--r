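---
title: "Methods behind cephatlas: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind cephatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephatlas)
```

cephatlas packages the statistical stages used to build a droplet
single-cell atlas of the octopus paralarval brain, together with a
synthetic-data generator that plants known ground truth so every stage can
be validated without access to sequencing data. This vignette explains each
stage's model, its tunable parameters, and the design decisions taken where
the procedure left genuine freedom.

## Evidence-guided 3' extension of gene models

Droplet protocols sequence the 3' ends of transcripts, so genes with
truncated 3' UTR annotations lose reads to "intergenic" space. The
extension stage grows each gene's 3' extent from three evidence tiers,
applied in order:

1. **Long-read isoforms** (`extend_by_isoforms()`): each isoform interval
   is assigned to the same-strand gene it overlaps (an explicit gene hint
   wins; overlap ties go to the largest overlap), and the gene's 3' end
   becomes the end of the longest assigned isoform.
2. **Cleavage sites** (`assign_cleavage_sites()`, `extend_by_cleavage()`):
   each site is assigned to the closest upstream same-strand gene if the
   distance from the gene's current 3' end is at most 60,000 bp
   (inclusive), and a gene extends to its most distal assigned site.
3. **Short-read coverage** (`extend_by_coverage()`): genes *without*
   cleavage support advance base by base downstream while read depth stays
   at or above 5, stopping at the first base below threshold. Contiguity is
   evaluated at base resolution: a single sub-threshold base ends the walk.

Design choices where the procedure is underdetermined:

* **Tier combination.** The tiers have a stated order but no stated
  conflict rule; we take the extension-only maximum across tiers (a gene's
  3' extent never shrinks), and restrict the coverage tier to genes lacking
  cleavage evidence, since that tier exists to cover genes the cleavage
  data misses.
* **Downstream collisions.** An extension that would cross the next
  same-strand gene's start is clamped to 1 bp before it and reported with
  tier `clamped`, keeping the annotation usable for read counting.
* **Assignment geometry.** "Closest upstream" is measured from the gene's
  current 3' end. A site falling inside a gene body is assigned to that
  gene (and, being upstream of the 3' end, changes nothing).
* **Coordinates.** Gene models are 1-based closed (GFF3); BED and bedGraph
  input is converted on import by the rtracklayer-based readers. An
  optional `max_walk` caps the coverage walk; the default is unlimited
  because the 60 kb cap is stated only for cleavage sites.

`intergenic_read_fraction()` reports the share of reads overlapping no gene
body (strand-agnostic, any overlap counts as genic); comparing it before
and after extension quantifies the annotation improvement.

## Droplet and gene QC

`filter_cells()` implements the printed exclusion rules as strict
inequalities: droplets are removed iff detected genes are **> 4000**, or
**< 400** (nuclei) / **< 800** (cells), or the mitochondrial fraction is
**> 5%**. Equality keeps the droplet — a nucleus with exactly 400 detected
genes, or a cell at exactly 5.0% mitochondrial reads, passes.
`filter_genes()` removes genes detected in fewer than 10 cells. The
pipeline order is cells first, then genes, matching the narrative order of
the original preprocessing; the gene filter is therefore computed on the
QC-passing cells. Mitochondrial gene identity is an input (a gene list),
because octopus mitochondrial genes do not follow the vertebrate `MT-`
naming convention. Whether "gene counts" means detected genes or total UMIs
is ambiguous in the printed rules; we use detected genes, consistent with
the median-detected-genes framing of the original QC summary.

## Cluster stability

`assess_stability()` quantifies how reproducible each cluster is under
perturbation: per iteration it draws a fraction of cells without
replacement (default 0.8), reclusters the subsample, and records for each
original cluster the maximum Jaccard index against any recluster. The
per-cluster mean across iterations (20 by default) is the stability score;
clusters at or above 0.6 are called stable. Matching is one-sided
max-Jaccard per original cluster rather than an optimal bipartite
assignment — the convention of the subsampling-stability approach this
reproduces. A cluster absent from a subsample contributes 0 for that
iteration rather than an error, so rare clusters are penalized, not
skipped.

The clusterer is pluggable (`function(counts, seed)`), because the original
SNN-graph community-detection stack is out of scope here:
`pca_kmeans_clusterer()` provides a deterministic, dependency-free
reference (k-means on top principal components of log-normalized
expression), and `fixed_label_clusterer()` wraps labels precomputed by any
external pipeline. `grid_search_stability()` scans a parameter grid and
returns the point maximizing the number of stable clusters, with ties
broken by more clusters total, then grid order. Cluster merging (manual
curation of batch-split clusters) is supported only as an explicit
relabeling utility, `merge_clusters()`.

## Tau specificity and rank-based family enrichment

For a nonnegative cluster-averaged profile $x$ over $N$ clusters,

$$\tau = \frac{\sum_{i=1}^{N} (1 - x_i / \max x)}{N - 1},$$

the canonical specificity index: 0 for uniform expression, 1 for expression
confined to one cluster, undefined (flagged `NA`) for all-zero profiles.
Tau is scale-invariant and monotone under concentration of mass into the
maximal cluster; the test suite checks both properties on random profiles.

`tf_specificity_pipeline()` applies the published analysis recipe:
genes expressed in fewer than 20 cells are excluded, expression is averaged
per cluster on the normalized assay, tau is computed per gene, and genes
with tau **strictly above 0.85** are labeled "specific" (tau exactly 0.85
is "broad"). Families are then tested for enrichment within the descending
tau ranking by `rank_family_enrichment()`: a weighted Kolmogorov–Smirnov
running sum (hits step up by $|\tau|^w$ normalized, misses step down by
$1/(N - N_h)$), with the enrichment score being the extreme signed
deviation; ties between equal positive and negative extremes resolve to the
positive side so the score does not depend on accumulation order.
P-values come from permuting the family's positions in the ranking
(`n_perm` draws at a fixed seed, with the add-one convention
$p = (1 + \#\{|ES_b| \ge |ES|\})/(B+1)$, which is uniform under the null).
The default weight is 1 (the classic weighted form); weight 0 gives the
unweighted statistic used by the exhaustive-enumeration oracle in the
tests. Ranking ties are broken by gene identifier for determinism. Families
with fewer than two genes in the ranking are flagged untestable.

## Cell-type taxonomy

`expression_distance()` computes pairwise distances between
cluster-averaged profiles, by default $1 - r$ (Pearson), which is
scale-invariant per cluster; Euclidean distance is selectable. The distance
metric is a genuine free choice — prior cell-type taxonomies used
correlation distance on averaged profiles, so that is the default.

`nj_tree()` is a from-scratch Saitou–Nei neighbor joining with fully
deterministic behavior: Q-criterion ties are broken by lexicographic order
of the taxon-pair labels (an internal node carries the alphabetically
smallest tip label of its cluster), and negative branch lengths are clamped
to zero with the deficit moved to the sibling branch, preserving the
joined pair's path length. On an exactly additive matrix the additive
topology and branch lengths are recovered to machine precision; the test
suite also cross-checks topologies against the reference NJ implementation
in ape.

`bootstrap_support()` resamples genes (columns of the averaged-expression
matrix) with replacement — the expression analog of the phylogenetic
bootstrap over characters — rebuilding the tree per replicate and scoring
each internal bipartition of the full-data tree by the fraction of
replicates containing it. Replicates that produce a zero-variance profile
under the correlation metric are skipped and counted. The desk-scale
default is B = 1000; B = 10,000 matches the published setting and is a
single argument away.

## Marker tables and Fisher family enrichment

`marker_genes()` compares each cluster against all other cells:
`avg_logFC = ln(mean_in + 1) − ln(mean_out + 1)` (natural log, pseudocount
1 — the convention the original marker tables inherit from their toolkit
era; the pseudocount is exposed), percent-expressing from raw positivity,
Wilcoxon rank-sum p-values, and retention at `pct_in ≥ 0.25` and
`|avg_logFC| ≥ 0.25`.

`family_fisher()` tests each (cluster, family) pair on a 2×2 table whose
universe is the union of all clusters' retained markers: rows split the
universe into family/non-family, columns into this cluster's marker set
versus the other clusters' deduplicated markers. The two-sided p-value is
computed by hypergeometric enumeration — summing the probabilities of all
tables with the observed margins that are no more probable than the
observed one (relative tolerance 1e-7, matching `fisher.test`, which
serves as an independent oracle in the tests together with a brute-force
factorial enumeration). Bonferroni correction multiplies by the number of
tests actually performed, capped at 1; significance is `p_adj < 0.05`. An
alternative universe (all tested genes) can be emulated by passing a
marker table built with relaxed thresholds.

`per_cell_family_diversity()` counts, per cell, the distinct family genes
with raw count > 0 and reports per-class means — the statistic behind the
observation that individual cells express many distinct protocadherins.

## Composition statistics

Positivity is raw count > 0 everywhere (`phenotype_fractions()`,
`coexpression_fraction()`), with no expression threshold knob — the
percent-expressing convention. `signature_score()` implements module
scoring: the per-cell mean normalized expression of a gene set minus that
of a control set matched on average expression (genes binned into 25
expression bins; 100 controls sampled per set gene from its bin at a fixed
seed).

## The synthetic-data generator

`simulate_counts()` draws raw counts from a gamma-Poisson (negative
binomial) law with shared dispersion $\phi$ (variance $\mu + \phi\mu^2$,
default $\phi = 0.5$), the standard model for UMI counts. Its default
configuration *is* the planted study condition used throughout the tests
and the acceptance script:

* **Six cell types** — four neuronal (GLUT 38%, ACH 24%, DOP 22%, and a 5%
  dual-transmitter DUAL type) and two non-neuronal (GLIA 10%, PREC 1%) —
  related by a fixed topology `(((GLUT,ACH),(DOP,DUAL)),(GLIA,PREC))`.
  Background cell-type mean profiles follow a log-normal Brownian walk
  along that tree (per-gene increments of sd 0.35 per unit branch length),
  so profile distances reflect the planted topology and the taxonomy stage
  has a recoverable signal.
* **Phenotype markers** realize exact per-type Bernoulli positivity:
  positive cells draw a zero-truncated negative binomial count, negative
  cells are 0. The default per-type probabilities mix to the planted
  composition — 64% vglut+, 29% vacht+, 27% th+, 10% gs2+ (glia), 1%
  ascl1+ (precursors), 89% elav+, 83% onecut+ — and the joint th+/vglut+
  fraction of 5% is carried entirely by the DUAL type (markers are
  independent within a type, so `planted_joint_fraction()` gives the
  planted co-expression truth).
* **A 60-gene protocadherin-like family** with planted per-class mean
  diversity: each family gene is positive with probability 19/60 in
  neuronal and 13/60 in non-neuronal cells, so the per-cell count of
  distinct positive family genes is binomial with means 19 and 13.
* **Mitochondrial content**: each droplet's target fraction is drawn from
  its batch's Beta law (defaults: mean 3% for cells, 2% for nuclei), and
  mitochondrial counts are added on top of the nuclear transcriptome so
  the realized fraction matches the draw up to rounding. We deliberately
  add rather than reallocate counts: thinning the non-mitochondrial counts
  would systematically depress the planted marker positivity fractions the
  recovery tests check, whereas the modest (< 10%) increase in per-droplet
  totals is immaterial to every downstream statistic, all of which
  normalize per cell or use positivity.
* **Batch structure**: droplets are labeled cell/nucleus (50/50 by
  default). The magnitude of the cell-versus-nucleus composition shift is
  not quantified in the source analyses, so it is exposed as a free
  parameter (`batch_lfc`, a log-fold shift on a configurable gene subset)
  and defaults to 0 for clean tests.

`simulate_genome_fixture()` builds a toy genome whose genes sit in
equal-width slots with alternating strand, so same-strand genes never
overlap and planted extensions cannot collide. Each gene's tier emits
exactly the evidence the corresponding extension rule needs (an isoform
ending at the true end; a cleavage site at the true end within 60 kb; a
depth-5 coverage run of exactly the true extension followed by a depth-2
block), so the pipeline provably recovers every evidence-supported true
end; a configurable fraction of simulated reads is planted inside the
extension zones, intergenic under the input annotation and annexed by the
extension.

What the generator does *not* emulate: ambient RNA, doublets, realistic
sequence content, gene-length effects, or correlated marker noise. Passing
tests therefore demonstrate that the statistics are implemented correctly
and recover planted truth under their own model assumptions — not that the
original dataset's headline numbers (17,081 cells, 87/42 clusters, the
mapping-rate gains) are reproducible, which requires the deposited raw
data and the full original toolchain.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at deliberately modest sizes
chosen to make binomial recovery bands tight while keeping runs fast:
10,000 cells and ~900 genes for parameter-recovery checks (3 binomial
standard errors at n = 10,000 is about ±1.4 percentage points for a 64%
fraction), 200 genes across 4 chromosomes for the extension genome,
B = 1000 for bootstrap supports, 50 iterations for the half-split
stability oracle. Seeds are explicit everywhere; identical configs and
seeds give bitwise-identical output. Degenerate inputs fail loudly:
all-zero tau profiles are flagged rather than scored, empty cell subsets
and empty Jaccard universes are errors, and zero-variance profiles under
the correlation metric name the offending cluster.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_counts(sim_config(n_cells = 10000, seed = 1))
phenotype_fractions(sim$counts, c(vglut = "vglut", th = "th"))
coexpression_fraction(sim$counts, "th", "vglut")

avg <- average_expression_by_cluster(normalize_counts(sim$counts),
                                     sim$truth$cell_type_of_cell)
bs <- bootstrap_support(avg, B = 1000, seed = 17)
bs$splits
```
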