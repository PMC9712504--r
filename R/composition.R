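# Marker positivity, co-expression fractions and gene-set signature scoring.
# Positivity is raw count > 0 throughout (the percent-expressing convention).

#' Marker-positivity fractions
#'
#' Percentage of (subset) cells with raw count > 0 for each panel gene.
#'
#' @param counts genes x cells matrix of raw counts
#' @param panel named character vector, phenotype label -> gene id
#' @param subset optional logical or integer cell subset (must be nonempty)
#' @return named numeric vector of percentages
#' @export
phenotype_fractions <- function(counts, panel, subset = NULL) {
  missing <- setdiff(panel, rownames(counts))
  if (length(missing)) {
    stop("panel genes absent from the matrix: ",
         paste(missing, collapse = ", "))
  }
  cols <- seq_len(ncol(counts))
  if (!is.null(subset)) cols <- cols[subset]
  if (!length(cols)) stop("empty cell subset")
  out <- vapply(panel, function(g) {
    100 * mean(counts[g, cols] > 0)
  }, numeric(1))
  names(out) <- names(panel) %||% panel
  out
}

#' Co-expression (dual-positivity) fraction
#'
#' Percentage of (subset) cells with raw count > 0 for both genes.
#'
#' @param counts genes x cells matrix of raw counts
#' @param gene_a,gene_b gene ids
#' @param subset optional cell subset
#' @return percentage in \[0, 100\]
#' @export
coexpression_fraction <- function(counts, gene_a, gene_b, subset = NULL) {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(counts)) stop("gene not found: ", g)
  }
  cols <- seq_len(ncol(counts))
  if (!is.null(subset)) cols <- cols[subset]
  if (!length(cols)) stop("empty cell subset")
  100 * mean(counts[gene_a, cols] > 0 & counts[gene_b, cols] > 0)
}

#' Gene-set signature (module) score
#'
#' Per-cell mean normalized expression of the gene set minus the mean of an
#' expression-matched control set: all genes are binned into `n_bins` by
#' average expression, and `n_ctrl_per_gene` control genes are sampled (with
#' replacement) from each set gene's bin at a fixed seed. Identical seeds
#' give identical scores.
#'
#' @param x genes x cells matrix of normalized expression
#' @param gene_set character vector of gene ids (intersected with the matrix;
#'   must be nonempty after intersection)
#' @param n_bins number of average-expression bins (default 25)
#' @param n_ctrl_per_gene control genes sampled per set gene (default 100)
#' @param seed integer seed
#' @return named numeric vector: one score per cell
#' @export
signature_score <- function(x, gene_set, n_bins = 25, n_ctrl_per_gene = 100,
                            seed = 1) {
  set <- intersect(gene_set, rownames(x))
  if (!length(set)) stop("gene_set shares no gene with the matrix")
  xm <- as(x, "CsparseMatrix")
  avg <- Matrix::rowMeans(xm)
  nb <- min(n_bins, length(unique(avg)))
  breaks <- unique(quantile(avg, probs = seq(0, 1, length.out = nb + 1)))
  bin <- cut(avg, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  names(bin) <- rownames(xm)

  set.seed(seed)
  ctrl <- unlist(lapply(set, function(g) {
    pool <- names(bin)[bin == bin[[g]]]
    sample(pool, n_ctrl_per_gene, replace = TRUE)
  }), use.names = FALSE)

  set_mean <- Matrix::colMeans(xm[set, , drop = FALSE])
  ## control mean with multiplicity: average over all sampled control genes
  ctrl_tab <- table(ctrl)
  ctrl_genes <- names(ctrl_tab)
  wts <- as.numeric(ctrl_tab) / length(ctrl)
  ctrl_mean <- as.numeric(wts %*% xm[ctrl_genes, , drop = FALSE])
  score <- set_mean - ctrl_mean
  names(score) <- colnames(xm)
  score
}
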