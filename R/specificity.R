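# Tau cell-type specificity and rank-based gene-family enrichment.

#' Average expression per cluster
#'
#' Arithmetic mean of (normalized) expression per cluster per gene.
#'
#' @param x genes x cells matrix of normalized expression
#' @param labels cluster labels covering all cells
#' @return clusters x genes matrix
#' @export
average_expression_by_cluster <- function(x, labels) {
  if (length(labels) != ncol(x)) stop("labels must cover all cells")
  labels <- as.factor(labels)
  if (any(table(labels) == 0)) {
    stop("empty cluster: ", paste(levels(labels)[table(labels) == 0],
                                  collapse = ", "))
  }
  ind <- Matrix::fac2sparse(labels)            # clusters x cells
  sums <- ind %*% Matrix::t(as(x, "CsparseMatrix"))
  avg <- as.matrix(sums / as.vector(table(labels)))
  dimnames(avg) <- list(levels(labels), rownames(x))
  avg
}

#' Tau specificity index
#'
#' For a nonnegative expression profile x over N >= 2 clusters, with
#' normalized values x_i / max(x), tau is the mean shortfall from the
#' maximum: sum(1 - x_i/max(x)) / (N - 1). 0 means uniform expression, 1
#' means expression confined to a single cluster. Undefined (NA) when the
#' profile is all zero.
#'
#' @param profile nonnegative numeric vector over clusters (length >= 2)
#' @return tau in \[0, 1\], or NA for an all-zero profile
#' @examples
#' tau(c(1, 1, 1, 1))  # 0
#' tau(c(0, 0, 5, 0))  # 1
#' tau(c(2, 4, 8))     # 0.625
#' @export
tau <- function(profile) {
  if (any(is.na(profile))) stop("profile contains NA")
  if (any(profile < 0)) stop("tau requires nonnegative expression values")
  n <- length(profile)
  if (n < 2) stop("tau requires at least 2 clusters")
  m <- max(profile)
  if (m == 0) return(NA_real_)
  sum(1 - profile / m) / (n - 1)
}

#' Tau for every gene of a cluster-averaged matrix
#'
#' @param avg clusters x genes matrix (e.g. from
#'   [average_expression_by_cluster()])
#' @return named numeric vector of tau scores (NA for all-zero genes)
#' @export
tau_per_gene <- function(avg) {
  if (nrow(avg) < 2) stop("tau requires at least 2 clusters")
  if (any(avg < 0)) stop("tau requires nonnegative expression values")
  m <- apply(avg, 2, max)
  out <- rep(NA_real_, ncol(avg))
  ok <- m > 0
  out[ok] <- colSums(1 - sweep(avg[, ok, drop = FALSE], 2, m[ok], "/")) /
    (nrow(avg) - 1)
  names(out) <- colnames(avg)
  out
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score for the genes of
# one family within a ranked list. Hits step up by |stat|^weight (normalized),
# misses step down by 1/(N - Nh); the score is the extreme signed deviation,
# with ties between equal positive and negative extremes resolved to the
# positive side (tolerance 1e-12, so floating-point noise cannot flip it).
running_sum_es <- function(hit, stats_abs, weight) {
  n <- length(hit)
  nh <- sum(hit)
  if (nh == 0) return(NA_real_)
  if (nh == n) return(0)
  w <- stats_abs^weight
  w[!hit] <- 0
  denom <- sum(w)
  step <- numeric(n)
  if (denom > 0) {
    step[hit] <- w[hit] / denom
  } else {
    step[hit] <- 1 / nh   # all-zero weights: fall back to unweighted hits
  }
  step[!hit] <- -1 / (n - nh)
  rs <- cumsum(step)
  mx <- max(rs); mn <- min(rs)
  if (mx >= -mn - 1e-12) mx else mn
}

#' Rank-based gene-family enrichment within a tau ranking
#'
#' For each family, computes a weighted Kolmogorov-Smirnov running-sum
#' enrichment score over the ranked gene list (hits weighted by
#' `|stat|^weight`, misses by the usual decrement) and a permutation p-value
#' from random reassignments of the family's positions in the ranking.
#' Families with fewer than 2 genes in the ranked list are flagged
#' untestable.
#'
#' @param ranked_genes gene ids in ranking order (descending statistic)
#' @param ranked_stats the ranking statistic (e.g. tau) aligned with
#'   `ranked_genes`; required when `weight > 0`
#' @param family_sets named list of gene-id vectors
#' @param n_perm number of permutations
#' @param weight hit-weight exponent; 0 gives the classic unweighted KS form
#' @param seed integer seed for the permutations
#' @return data.frame: `family`, `es`, `p_value`, `n_genes`, `direction`
#'   (`top`/`bottom`), `testable`
#' @export
rank_family_enrichment <- function(ranked_genes, ranked_stats = NULL,
                                   family_sets, n_perm = 1000, weight = 1,
                                   seed = 1) {
  n <- length(ranked_genes)
  if (anyDuplicated(ranked_genes)) stop("ranked gene list has duplicates")
  if (weight > 0 && is.null(ranked_stats)) {
    stop("ranked_stats are required when weight > 0")
  }
  stats_abs <- if (is.null(ranked_stats)) rep(1, n) else abs(ranked_stats)
  if (length(stats_abs) != n) stop("ranked_stats must align with ranked_genes")

  out <- data.frame(family = names(family_sets), es = NA_real_,
                    p_value = NA_real_, n_genes = 0L,
                    direction = NA_character_, testable = FALSE,
                    stringsAsFactors = FALSE)
  set.seed(seed)
  for (i in seq_along(family_sets)) {
    hit <- ranked_genes %in% family_sets[[i]]
    nh <- sum(hit)
    out$n_genes[i] <- nh
    if (nh < 2 || nh == n) next
    es <- running_sum_es(hit, stats_abs, weight)
    perm <- vapply(seq_len(n_perm), function(b) {
      h <- logical(n)
      h[sample.int(n, nh)] <- TRUE
      running_sum_es(h, stats_abs, weight)
    }, numeric(1))
    out$es[i] <- es
    out$p_value[i] <- (1 + sum(abs(perm) >= abs(es))) / (n_perm + 1)
    out$direction[i] <- if (es >= 0) "top" else "bottom"
    out$testable[i] <- TRUE
  }
  out
}

#' Transcription-factor specificity pipeline
#'
#' Restricts the matrix to the genes of the family map, excludes genes
#' expressed (raw count > 0) in fewer than `min_cells` cells, averages
#' normalized expression per cluster, computes tau per gene, ranks genes by
#' descending tau (ties broken by gene id), runs the rank-based family
#' enrichment, and labels genes with tau strictly above `tau_specific_cutoff`
#' as "specific" and the rest as "broad".
#'
#' @param counts genes x cells raw counts
#' @param labels cluster labels covering all cells
#' @param family_map data.frame with columns `gene_id`, `family`
#' @param min_cells minimum expressing cells for inclusion (default 20)
#' @param tau_specific_cutoff specificity cutoff (default 0.85, strict)
#' @param n_perm,weight,seed passed to [rank_family_enrichment()]
#' @param normalized optional precomputed normalized matrix; default
#'   [normalize_counts()] of `counts`
#' @return a list of class `tau_result`: `tau_table` (gene_id, family,
#'   n_cells_expressing, included, tau, class), `enrichment`
#'   (from [rank_family_enrichment()]), `specific_genes`
#' @export
tf_specificity_pipeline <- function(counts, labels, family_map,
                                    min_cells = 20,
                                    tau_specific_cutoff = 0.85,
                                    n_perm = 1000, weight = 1, seed = 1,
                                    normalized = NULL) {
  if (!all(c("gene_id", "family") %in% names(family_map))) {
    stop("family_map needs gene_id and family columns")
  }
  if (!nrow(family_map)) stop("family map is empty")
  genes <- intersect(family_map$gene_id, rownames(counts))
  if (!length(genes)) stop("no family_map gene is present in the matrix")

  n_expr <- Matrix::rowSums(counts[genes, , drop = FALSE] > 0)
  included <- n_expr >= min_cells
  normalized <- normalized %||% normalize_counts(counts)

  tau_table <- data.frame(
    gene_id = genes,
    family = family_map$family[match(genes, family_map$gene_id)],
    n_cells_expressing = as.integer(n_expr),
    included = included, tau = NA_real_, class = NA_character_,
    stringsAsFactors = FALSE
  )
  inc <- genes[included]
  if (length(inc)) {
    avg <- average_expression_by_cluster(normalized[inc, , drop = FALSE],
                                         labels)
    tv <- tau_per_gene(avg)
    tau_table$tau[match(inc, tau_table$gene_id)] <- tv
    tau_table$class[match(inc, tau_table$gene_id)] <-
      ifelse(is.na(tv), NA_character_,
             ifelse(tv > tau_specific_cutoff, "specific", "broad"))
  }

  ranked <- tau_table[tau_table$included & !is.na(tau_table$tau), ]
  ranked <- ranked[order(-ranked$tau, ranked$gene_id), ]
  fam_sets <- split(tau_table$gene_id, tau_table$family)
  enrichment <- rank_family_enrichment(ranked$gene_id, ranked$tau,
                                       fam_sets, n_perm = n_perm,
                                       weight = weight, seed = seed)
  structure(
    list(tau_table = tau_table, enrichment = enrichment,
         specific_genes = tau_table$gene_id[!is.na(tau_table$class) &
                                              tau_table$class == "specific"],
         cutoff = tau_specific_cutoff),
    class = "tau_result"
  )
}

#' @method print tau_result
#' @export
print.tau_result <- function(x, ...) {
  inc <- sum(x$tau_table$included)
  cat("Tau specificity over", nrow(x$tau_table), "genes (",
      inc, "included );", length(x$specific_genes),
      "specific at tau >", x$cutoff, "\n")
  print(x$enrichment, row.names = FALSE)
  invisible(x)
}
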