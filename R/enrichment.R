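# Marker tables, Fisher's exact gene-family enrichment, per-cell family
# diversity.

#' Marker genes per cluster (one-vs-rest)
#'
#' For each cluster versus all other cells:
#' `avg_logFC = ln(mean_in + eps) - ln(mean_out + eps)` with pseudocount
#' `eps = 1` (natural log), percent-expressing fractions from counts > 0, and
#' a Wilcoxon rank-sum p-value per retained gene. Genes are retained when
#' `pct_in >= min_pct` and `|avg_logFC| >= logfc_threshold`.
#'
#' @param x genes x cells matrix of normalized expression
#' @param labels cluster labels covering all cells (>= 2 clusters)
#' @param min_pct minimum in-cluster expressing fraction (default 0.25)
#' @param logfc_threshold minimum |avg_logFC| (default 0.25)
#' @param pseudocount eps in the log fold change (default 1)
#' @return data.frame of class `marker_table`: `cluster`, `gene`,
#'   `avg_logFC`, `pct_in`, `pct_out`, `p_value`, `p_unreliable` (TRUE for
#'   clusters of fewer than 3 cells, which trigger a warning)
#' @export
marker_genes <- function(x, labels, min_pct = 0.25, logfc_threshold = 0.25,
                         pseudocount = 1) {
  if (length(labels) != ncol(x)) stop("labels must cover all cells")
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  xm <- as(x, "CsparseMatrix")

  rows <- list()
  for (cl in clusters) {
    inside <- labels == cl
    small <- sum(inside) < 3
    if (small) {
      warning("cluster ", cl, " has fewer than 3 cells; ",
              "rank-sum p-values are unreliable")
    }
    mean_in <- Matrix::rowMeans(xm[, inside, drop = FALSE])
    mean_out <- Matrix::rowMeans(xm[, !inside, drop = FALSE])
    lfc <- log(mean_in + pseudocount) - log(mean_out + pseudocount)
    pct_in <- Matrix::rowMeans(xm[, inside, drop = FALSE] > 0)
    pct_out <- Matrix::rowMeans(xm[, !inside, drop = FALSE] > 0)
    keep <- which(pct_in >= min_pct & abs(lfc) >= logfc_threshold)
    if (!length(keep)) next
    pv <- vapply(keep, function(g) {
      wilcox.test(xm[g, inside], xm[g, !inside], exact = FALSE)$p.value
    }, numeric(1))
    rows[[cl]] <- data.frame(
      cluster = cl, gene = rownames(xm)[keep],
      avg_logFC = lfc[keep], pct_in = pct_in[keep], pct_out = pct_out[keep],
      p_value = pv, p_unreliable = small,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(cluster = character(0), gene = character(0),
                  avg_logFC = numeric(0), pct_in = numeric(0),
                  pct_out = numeric(0), p_value = numeric(0),
                  p_unreliable = logical(0))
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Two-sided Fisher's exact p-value for a 2x2 table
#'
#' Conventional two-sided definition by hypergeometric enumeration: with
#' margins fixed, the p-value is the sum of the probabilities of all tables
#' whose probability does not exceed that of the observed table (up to a
#' relative tolerance of 1e-7, matching the reference implementation).
#'
#' @param a,b,c_,d table cells: `a` family-and-in-cluster, `b`
#'   family-and-elsewhere, `c_` non-family-in-cluster, `d`
#'   non-family-elsewhere
#' @return list: `p_value`, `odds_ratio` (sample odds ratio ad/bc)
#' @export
fisher_exact_2x2 <- function(a, b, c_, d) {
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  m <- a + b          # family genes
  n2 <- c_ + d        # non-family genes
  k <- a + c_         # in-cluster genes
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(1, p),
       odds_ratio = (a * d) / (b * c_))
}

#' Fisher's exact gene-family enrichment per cluster
#'
#' The gene universe is the union of all clusters' retained marker genes.
#' For each (cluster, family) pair a 2x2 table is built: rows split the
#' universe into family / non-family, columns into this cluster's marker set
#' versus the deduplicated union of the other clusters' marker sets
#' (excluding this cluster's). Two-sided Fisher p-values are Bonferroni
#' corrected over all tests performed; a pair is significant iff
#' `p_adjusted < alpha`. Families absent from the universe, and clusters with
#' empty marker sets, are flagged untestable.
#'
#' @param markers a [marker_genes()] table (or any data.frame with `cluster`
#'   and `gene` columns)
#' @param family_map data.frame with columns `gene_id`, `family`
#' @param alpha significance level on the adjusted p (default 0.05)
#' @return data.frame of class `family_enrichment`: `cluster`, `family`,
#'   `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`, `p_adjusted`,
#'   `significant`, `testable`
#' @export
family_fisher <- function(markers, family_map, alpha = 0.05) {
  if (!all(c("cluster", "gene") %in% names(markers))) {
    stop("markers needs cluster and gene columns")
  }
  clusters <- sort(unique(markers$cluster))
  sets <- lapply(clusters, function(cl) unique(markers$gene[markers$cluster == cl]))
  names(sets) <- clusters
  universe <- unique(markers$gene)
  families <- sort(unique(family_map$family))
  fam_genes <- split(family_map$gene_id, family_map$family)

  grid <- expand.grid(cluster = clusters, family = families,
                      stringsAsFactors = FALSE)
  res <- data.frame(grid, a = NA_integer_, b = NA_integer_,
                    c = NA_integer_, d = NA_integer_,
                    odds_ratio = NA_real_, p_value = NA_real_,
                    p_adjusted = NA_real_, significant = NA,
                    testable = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    cl <- res$cluster[i]; fam <- res$family[i]
    inset <- sets[[cl]]
    outset <- setdiff(universe, inset)
    fam_u <- intersect(fam_genes[[fam]], universe)
    if (!length(inset) || !length(fam_u)) next
    a <- length(intersect(fam_u, inset))
    b <- length(intersect(fam_u, outset))
    c_ <- length(inset) - a
    d <- length(outset) - b
    ft <- fisher_exact_2x2(a, b, c_, d)
    res[i, c("a", "b", "c", "d")] <- c(a, b, c_, d)
    res$odds_ratio[i] <- ft$odds_ratio
    res$p_value[i] <- ft$p_value
    res$testable[i] <- TRUE
  }
  m_tests <- sum(res$testable)
  res$p_adjusted[res$testable] <- pmin(1, res$p_value[res$testable] * m_tests)
  res$significant[res$testable] <- res$p_adjusted[res$testable] < alpha
  class(res) <- c("family_enrichment", "data.frame")
  attr(res, "n_tests") <- m_tests
  res
}

#' Per-cell gene-family diversity
#'
#' Number of distinct family genes with raw count > 0 in each cell, with
#' per-class arithmetic means.
#'
#' @param counts genes x cells matrix of raw counts
#' @param family_genes character vector of family gene ids (intersected with
#'   the matrix rows; must be nonempty after intersection)
#' @param class_labels optional per-cell class labels (e.g.
#'   neuronal / non-neuronal)
#' @return a list of class `family_diversity`: `per_cell` (named integer
#'   vector), `class_means` (named numeric, NULL without class labels),
#'   `family_size`
#' @export
per_cell_family_diversity <- function(counts, family_genes,
                                      class_labels = NULL) {
  genes <- intersect(family_genes, rownames(counts))
  if (!length(genes)) stop("no family gene is present in the matrix")
  sub <- counts[genes, , drop = FALSE]
  per_cell <- if (inherits(sub, "Matrix")) {
    Matrix::colSums(sub > 0)
  } else {
    colSums(sub > 0)
  }
  class_means <- NULL
  if (!is.null(class_labels)) {
    if (length(class_labels) != ncol(counts)) {
      stop("class_labels must cover all cells")
    }
    class_means <- tapply(per_cell, class_labels, mean)
  }
  structure(list(per_cell = per_cell, class_means = class_means,
                 family_size = length(genes)),
            class = "family_diversity")
}

#' @method print family_diversity
#' @export
print.family_diversity <- function(x, ...) {
  cat("Family diversity over", x$family_size, "genes: mean",
      round(mean(x$per_cell), 2), "distinct genes per cell\n")
  if (!is.null(x$class_means)) {
    for (cl in names(x$class_means)) {
      cat(sprintf("  %s: %.2f\n", cl, x$class_means[[cl]]))
    }
  }
  invisible(x)
}
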