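# cephatlas

Statistical building blocks for a droplet single-cell atlas of the octopus
paralarval brain — for computational biologists who need the bespoke stages
of such an atlas as tested, reusable R functions rather than one-off
analysis scripts.

The octopus brain poses two problems that standard toolchains do not solve
out of the box. First, its genome annotation has truncated 3' UTRs, so the
3'-biased reads of droplet protocols fall into "intergenic" space and are
lost; cephatlas implements the evidence-guided fix — extending each gene's
3' end from long-read isoform ends, mRNA cleavage sites (assigned to the
closest upstream gene within 60 kb), and continuous short-read coverage
(depth ≥ 5), in that order, extension-only, clamped at the next same-strand
gene. Second, with no prior atlas of expected cell types, cluster quality,
cell-type relationships, and gene-family novelty must be established
statistically. cephatlas provides:

* **QC** — the batch-aware droplet filter (exclude > 4000 detected genes,
  < 400 for nuclei / < 800 for cells, > 5% mitochondrial reads; strict
  inequalities) and the detected-in-≥ 10-cells gene filter;
* **cluster stability** — subsample 80% of cells, recluster, score each
  cluster by its best-match Jaccard index, average over 20 iterations, and
  call clusters below 0.6 unstable;
* **tau specificity** — for a cluster-averaged profile *x* over *N*
  clusters, τ = Σᵢ(1 − xᵢ/max x)/(N − 1), with genes in fewer than 20
  cells excluded and τ > 0.85 labeled "specific", plus gene-family
  enrichment within the τ ranking (weighted Kolmogorov–Smirnov running sum
  with permutation p-values);
* **a cell-type taxonomy** — Saitou–Nei neighbor joining on correlation
  distances between cluster-averaged profiles, with gene-resampling
  bootstrap support per bipartition;
* **gene-family enrichment** — one-vs-rest marker tables
  (ln(mean+1) fold changes, min.pct 0.25, |logFC| ≥ 0.25), two-sided
  Fisher's exact tests by hypergeometric enumeration with Bonferroni
  correction, and per-cell family-diversity counts;
* **composition statistics** — percent-positive and co-expression
  fractions (raw count > 0) and expression-bin-matched module scores;
* **synthetic data with planted truth** — a negative-binomial droplet
  simulator (planted cell types on a known tree, exact marker-positivity
  fractions, Beta-distributed mitochondrial content, planted family
  diversity) and a toy genome fixture whose true 3' ends are recoverable
  by construction.

## Worked example

Simulate 10,000 droplets under the default planted composition, then
recover it:

```r
library(cephatlas)
sim <- simulate_counts(sim_config(n_cells = 10000, seed = 1))

phenotype_fractions(sim$counts, c(vglut = "vglut", vacht = "vacht",
                                  th = "th", gs2 = "gs2"))
#> vglut vacht    th   gs2
#> 63.92 28.77 26.70 10.35
coexpression_fraction(sim$counts, "th", "vglut")
#> [1] 5.37
```

The planted mixture is 64% glutamatergic, 29% cholinergic, 27%
dopaminergic and 10% glial, with a 5% dual th+/vglut+ population — the
recovered fractions sit within binomial sampling error of those targets.
Per-cell protocadherin diversity and the cell-type tree:

```r
cls <- unname(sim$config$cell_type_class[sim$truth$cell_type_of_cell])
per_cell_family_diversity(sim$counts, sim$truth$gene_roles$family$PCDH,
                          class_labels = cls)
#> Family diversity over 60 genes: mean 18.33 distinct genes per cell
#>   neuronal: 19.03
#>   non-neuronal: 12.83

avg <- average_expression_by_cluster(normalize_counts(sim$counts),
                                     sim$truth$cell_type_of_cell)
bootstrap_support(avg, B = 1000, seed = 17)
#> NJ cell-type tree ( 6 types ), 1000 bootstrap replicates ( 0 skipped )
#>               split support
#>           GLIA|PREC   1.000
#>            DOP|DUAL   0.899
#>  DOP|DUAL|GLIA|PREC   0.996
```

All three recovered bipartitions are exactly the planted hierarchy
(((GLUT,ACH),(DOP,DUAL)),(GLIA,PREC)): neuronal types separate from
glia/precursors with full support. And the annotation-extension stage on a
200-gene toy genome:

```r
fx <- simulate_genome_fixture(genome_fixture_config(n_chroms = 4,
                                                    n_genes = 200, seed = 2))
run_extension_pipeline(fx$genes, fx$isoforms, fx$sites, fx$coverage,
                       reads = fx$reads)
#> 3' extension of 200 genes
#>
#> coverage  flamseq   isoseq     none
#>       50       50       50       50
#> Intergenic read fraction: 0.2000 -> 0.0505
```

Every evidence-supported gene recovers its true 3' end exactly, no
unevidenced gene moves, and the planted intergenic reads are annexed — a
fourfold drop in the intergenic read fraction.

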