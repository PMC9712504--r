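# Cluster-stability assessment by subsampling and Jaccard matching.
#
# Semantics follow the one-sided max-Jaccard convention: per iteration, each
# original cluster (restricted to the subsample) is matched to the recluster
# maximizing the Jaccard index; the per-cluster aggregate across iterations
# is the stability score, and clusters below the threshold are unstable.

#' Jaccard index of two cell-id sets
#'
#' @param a,b vectors of cell identifiers over a common universe
#' @return |a intersect b| / |a union b|
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) stop("Jaccard undefined: both sets empty")
  length(intersect(a, b)) / u
}

#' Stability-assessment parameters
#'
#' Subsample fraction and iteration count follow the defaults of the
#' subsampling-stability approach (0.8 of cells, 20 iterations); the 0.6
#' mean-Jaccard threshold is the published stable-cluster cutoff.
#'
#' @param subsample_fraction fraction of cells drawn without replacement per
#'   iteration (0 < f < 1)
#' @param n_iterations number of subsample/recluster iterations
#' @param jaccard_threshold aggregate score at or above which a cluster is
#'   called stable
#' @param aggregation `"mean"` or `"median"`
#' @param seed integer seed driving subsampling and the clusterer
#' @return a list of class `stability_params`
#' @export
stability_params <- function(subsample_fraction = 0.8, n_iterations = 20,
                             jaccard_threshold = 0.6,
                             aggregation = c("mean", "median"), seed = 1) {
  if (subsample_fraction <= 0 || subsample_fraction >= 1) {
    stop("subsample_fraction must lie strictly between 0 and 1")
  }
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  structure(list(subsample_fraction = subsample_fraction,
                 n_iterations = as.integer(n_iterations),
                 jaccard_threshold = jaccard_threshold,
                 aggregation = match.arg(aggregation),
                 seed = as.integer(seed)),
            class = "stability_params")
}

#' Assess cluster stability by subsampling and reclustering
#'
#' Per iteration: draw `subsample_fraction` of the cells without replacement,
#' recluster the subsample with `clusterer`, and record, for every original
#' cluster restricted to the subsample, the maximum Jaccard index against any
#' recluster. A cluster entirely absent from a subsample contributes 0 for
#' that iteration. Scores are aggregated per cluster and compared to the
#' threshold. Deterministic given `params$seed` and a seed-respecting
#' clusterer.
#'
#' @param counts genes x cells matrix (passed to the clusterer)
#' @param labels cluster labels covering all cells (named by cell or in
#'   column order)
#' @param clusterer `function(counts_subset, seed)` returning labels for the
#'   subset's cells (in column order or named); e.g.
#'   [pca_kmeans_clusterer()], or a wrapper around labels precomputed
#'   elsewhere
#' @param params a [stability_params()]
#' @return a list of class `stability_table`: `scores` (clusters x iterations
#'   matrix of max-Jaccard values), `aggregate`, `stable` (aggregate >=
#'   threshold), `params`
#' @export
assess_stability <- function(counts, labels, clusterer,
                             params = stability_params()) {
  if (length(labels) != ncol(counts)) stop("labels must cover all cells")
  cells <- colnames(counts) %||% as.character(seq_len(ncol(counts)))
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  members <- split(cells, labels)

  set.seed(params$seed)
  iter_seeds <- sample.int(2^31 - 1, params$n_iterations)
  n_sub <- max(1L, round(params$subsample_fraction * ncol(counts)))

  scores <- matrix(0, nrow = length(clusters), ncol = params$n_iterations,
                   dimnames = list(clusters, NULL))
  for (it in seq_len(params$n_iterations)) {
    set.seed(iter_seeds[it])
    idx <- sample(ncol(counts), n_sub)
    sub_cells <- cells[idx]
    relab <- clusterer(counts[, idx, drop = FALSE], iter_seeds[it])
    relab <- as.character(relab)
    if (length(relab) != length(idx)) {
      stop("clusterer must label every cell of the subsample")
    }
    re_members <- split(sub_cells, relab)
    for (ci in seq_along(clusters)) {
      orig <- intersect(members[[clusters[ci]]], sub_cells)
      if (!length(orig)) next  # absent from subsample: contributes 0
      scores[ci, it] <- max(vapply(re_members, function(m) jaccard(orig, m),
                                   numeric(1)))
    }
  }
  aggregate <- apply(scores, 1,
                     if (params$aggregation == "mean") mean else stats::median)
  structure(list(scores = scores, aggregate = aggregate,
                 stable = aggregate >= params$jaccard_threshold,
                 params = params),
            class = "stability_table")
}

#' @method print stability_table
#' @export
print.stability_table <- function(x, ...) {
  df <- data.frame(cluster = names(x$aggregate),
                   score = round(x$aggregate, 3), stable = x$stable)
  print(df, row.names = FALSE)
  cat(sum(x$stable), "of", length(x$stable), "clusters stable at threshold",
      x$params$jaccard_threshold, "\n")
  invisible(x)
}

#' Reference clusterer: k-means on top principal components
#'
#' A deterministic, dependency-free stand-in clusterer for stability
#' assessment: log-normalized expression is reduced to its top principal
#' components and partitioned by k-means with a fixed seed. The SNN-graph
#' community-detection pipeline used on the real atlas is deliberately not
#' reimplemented; [assess_stability()] accepts any label-producing procedure.
#'
#' @param k number of clusters
#' @param n_pcs number of principal components (capped at the data rank)
#' @param normalize log-normalize the matrix first (default TRUE)
#' @return a `function(counts, seed)` usable as the `clusterer` argument
#' @export
pca_kmeans_clusterer <- function(k, n_pcs = 10, normalize = TRUE) {
  force(k); force(n_pcs); force(normalize)
  function(counts, seed) {
    x <- if (normalize) normalize_counts(counts) else counts
    x <- t(as.matrix(x))
    keep <- apply(x, 2, sd) > 0
    pc <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
    d <- min(n_pcs, ncol(pc$x))
    set.seed(seed)
    kmeans(pc$x[, seq_len(d), drop = FALSE], centers = k, nstart = 5,
           iter.max = 50)$cluster
  }
}

#' Identity reclusterer built from fixed labels
#'
#' Returns the provided labels restricted to whatever subsample it is given;
#' useful as the perfect-stability control and for plugging in labels
#' precomputed by an external clustering stack.
#'
#' @param labels full-data labels named by cell id (or in column order of the
#'   full matrix whose colnames are cell ids)
#' @return a `function(counts, seed)` usable as the `clusterer` argument
#' @export
fixed_label_clusterer <- function(labels) {
  force(labels)
  function(counts, seed) {
    if (is.null(names(labels))) stop("labels must be named by cell id")
    labels[colnames(counts)]
  }
}

#' Grid search for the clustering parameters maximizing stable clusters
#'
#' Runs a full-data clustering and a stability assessment per grid point and
#' reports the point with the highest number of stable clusters. Ties are
#' broken by more clusters total, then by grid order.
#'
#' @param counts genes x cells matrix
#' @param grid data.frame of parameter combinations, one row per grid point
#' @param clusterer_factory `function(grid_row)` returning a
#'   `function(counts, seed)` clusterer
#' @param params a [stability_params()]
#' @return a list of class `stability_grid`: `table` (grid + `n_stable` +
#'   `n_clusters`), `best` (row index of the argmax)
#' @export
grid_search_stability <- function(counts, grid, clusterer_factory,
                                  params = stability_params()) {
  if (!nrow(grid)) stop("empty parameter grid")
  n_stable <- integer(nrow(grid))
  n_clusters <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cl <- clusterer_factory(grid[i, , drop = FALSE])
    labels <- cl(counts, params$seed)
    st <- assess_stability(counts, labels, cl, params)
    n_stable[i] <- sum(st$stable)
    n_clusters[i] <- length(st$stable)
  }
  tab <- cbind(grid, n_stable = n_stable, n_clusters = n_clusters)
  best <- order(-n_stable, -n_clusters, seq_len(nrow(grid)))[1]
  structure(list(table = tab, best = best), class = "stability_grid")
}

#' Merge or relabel clusters by an explicit mapping
#'
#' Manual curation utility (e.g. merging two batch-split clusters into one
#' annotated cell type): labels found in `mapping` are replaced by their
#' mapped value; all others pass through.
#'
#' @param labels cluster label vector
#' @param mapping named character vector, `old label -> new label`
#' @return relabeled vector
#' @export
merge_clusters <- function(labels, mapping) {
  labels <- as.character(labels)
  hit <- labels %in% names(mapping)
  labels[hit] <- unname(mapping[labels[hit]])
  labels
}
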