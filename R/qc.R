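# Droplet and gene quality-control filters.
#
# The printed filtering rules are strict-inequality exclusions: droplets are
# removed iff detected genes > 4000, or < 400 (nuclei) / < 800 (cells), or
# mitochondrial fraction > 5%. Equality keeps the droplet. The pipeline order
# is cells first, then genes.

#' QC thresholds
#'
#' @param min_genes_nucleus lower detected-gene bound for nuclei (exclusive:
#'   droplets strictly below are removed)
#' @param min_genes_cell lower detected-gene bound for cells (exclusive)
#' @param max_genes upper detected-gene bound (exclusive: strictly above is
#'   removed)
#' @param max_mito_fraction mitochondrial-fraction bound (exclusive: strictly
#'   above is removed)
#' @param min_cells_per_gene genes detected in fewer cells are removed
#' @return a list of class `qc_thresholds`
#' @export
qc_thresholds <- function(min_genes_nucleus = 400, min_genes_cell = 800,
                          max_genes = 4000, max_mito_fraction = 0.05,
                          min_cells_per_gene = 10) {
  if (min_genes_nucleus >= max_genes || min_genes_cell >= max_genes) {
    stop("lower gene-count thresholds must be below max_genes")
  }
  structure(list(min_genes_nucleus = min_genes_nucleus,
                 min_genes_cell = min_genes_cell,
                 max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = min_cells_per_gene),
            class = "qc_thresholds")
}

#' Batch-aware droplet filter
#'
#' Keeps a droplet iff its detected-gene count is not strictly below the
#' batch's lower bound (400 nuclei / 800 cells), not strictly above
#' `max_genes` (4000), and its mitochondrial fraction is not strictly above
#' `max_mito_fraction` (5%).
#'
#' @param counts genes x cells matrix of raw counts (used when `meta` lacks
#'   `n_genes_detected`)
#' @param meta data.frame with columns `batch` (`cell`/`nucleus`),
#'   `mito_fraction` and optionally `n_genes_detected`; rows align with the
#'   matrix columns
#' @param thr a [qc_thresholds()]
#' @return logical keep-mask over cells
#' @export
filter_cells <- function(counts, meta, thr = qc_thresholds()) {
  if (nrow(meta) != ncol(counts)) {
    stop("meta rows must align with matrix columns")
  }
  bad <- setdiff(unique(meta$batch), c("cell", "nucleus"))
  if (length(bad)) stop("unknown batch label: ", paste(bad, collapse = ", "))
  ngene <- meta$n_genes_detected %||% col_totals(counts > 0)
  lower <- ifelse(meta$batch == "nucleus",
                  thr$min_genes_nucleus, thr$min_genes_cell)
  keep <- !(ngene < lower) & !(ngene > thr$max_genes) &
    !(meta$mito_fraction > thr$max_mito_fraction)
  unname(keep)
}

#' Gene detection filter
#'
#' Keeps a gene iff it is detected (raw count > 0) in at least `min_cells`
#' cells; genes expressed in fewer cells are excluded.
#'
#' @param counts genes x cells matrix of raw counts
#' @param min_cells minimum number of expressing cells (default 10)
#' @return logical keep-mask over genes
#' @export
filter_genes <- function(counts, min_cells = 10) {
  n_expr <- if (inherits(counts, "Matrix")) {
    Matrix::rowSums(counts > 0)
  } else {
    rowSums(counts > 0)
  }
  unname(n_expr >= min_cells)
}

#' Percentage of cells expressing a gene
#'
#' The percent-expressing statistic: 100 x (number of cells in the subset
#' with raw count > 0) / (subset size).
#'
#' @param counts genes x cells matrix of raw counts
#' @param gene gene id (rowname)
#' @param subset optional logical or integer cell subset; default all cells
#' @return percentage in \[0, 100\]
#' @export
pct_cells_expressing <- function(counts, gene, subset = NULL) {
  if (!gene %in% rownames(counts)) stop("gene not found: ", gene)
  x <- counts[gene, ]
  if (!is.null(subset)) x <- x[subset]
  if (!length(x)) stop("empty cell subset")
  100 * mean(x > 0)
}

#' Normalize raw counts (library-size scaling + log1p)
#'
#' Standard droplet normalization: counts are scaled so every cell sums to
#' `scale_factor`, then log(1 + x) transformed. Zeros stay zero, so
#' positivity (count > 0) is preserved.
#'
#' @param counts genes x cells matrix of raw counts
#' @param scale_factor per-cell total after scaling (default 1e4)
#' @return a `dgCMatrix` of normalized expression
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  x <- as(counts, "CsparseMatrix")
  tot <- Matrix::colSums(x)
  if (any(tot == 0)) stop("cells with zero total counts cannot be normalized")
  x <- x %*% Matrix::Diagonal(x = scale_factor / tot)
  x@x <- log1p(x@x)
  dimnames(x) <- dimnames(counts)
  as(x, "CsparseMatrix")
}
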