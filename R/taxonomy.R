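# Neighbor-joining cell-type taxonomy with gene-resampling bootstrap.

#' Pairwise distance between cluster expression profiles
#'
#' Default is correlation distance (1 - Pearson correlation of cluster
#' profiles), which is scale-invariant per cluster; Euclidean distance is
#' available.
#'
#' @param avg_expr clusters x genes matrix of averaged expression (>= 3
#'   clusters, >= 2 genes)
#' @param metric `"correlation"` or `"euclidean"`
#' @return symmetric distance matrix with a `metric` attribute
#' @export
expression_distance <- function(avg_expr,
                                metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  if (nrow(avg_expr) < 3) stop("need at least 3 clusters")
  if (ncol(avg_expr) < 2) stop("need at least 2 genes")
  if (metric == "correlation") {
    v <- apply(avg_expr, 1, var)
    if (any(v == 0)) {
      stop("zero-variance profile under correlation metric: ",
           paste(rownames(avg_expr)[v == 0], collapse = ", "))
    }
    d <- 1 - cor(t(avg_expr))
  } else {
    d <- as.matrix(stats::dist(avg_expr))
  }
  diag(d) <- 0
  d[abs(d) < 1e-15] <- 0
  attr(d, "metric") <- metric
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration: repeatedly join the taxon pair minimizing
#' the Q-criterion, compute the two branch lengths from the two-point
#' formulas, and reduce the matrix, until three taxa remain. Q-ties are
#' broken by lexicographic order of the taxon-pair labels (internal nodes
#' carry the alphabetically smallest tip label of their cluster), making the
#' topology deterministic. Negative branch lengths are clamped to 0 with the
#' deficit transferred to the sibling branch of the join, preserving the
#' pair's path length.
#'
#' On an exactly additive distance matrix the unique additive topology and
#' branch lengths are recovered to machine precision.
#'
#' @param D symmetric nonnegative distance matrix with dimnames (>= 3 taxa)
#' @return an unrooted `ape::phylo` tree
#' @examples
#' D <- matrix(c(0, 2, 4, 4, 2, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' nj_tree(D)
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  taxa <- rownames(D)
  if (is.null(taxa)) stop("distance matrix must carry taxon dimnames")
  n0 <- nrow(D)
  if (n0 < 3) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distance matrix must be nonnegative")

  frag <- taxa               # newick fragment per active node
  key <- taxa                # tie-break label (smallest tip in the cluster)
  d <- D
  while (nrow(d) > 3) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    ties <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    ties <- ties[ties[, 1] < ties[, 2], , drop = FALSE]
    pair_key <- paste(pmin(key[ties[, 1]], key[ties[, 2]]),
                      pmax(key[ties[, 1]], key[ties[, 2]]))
    pick <- ties[order(pair_key)[1], ]
    i <- pick[1]; j <- pick[2]

    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }

    new_frag <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], li, frag[j], lj)
    new_key <- min(key[i], key[j])
    dk <- (d[i, -c(i, j)] + d[j, -c(i, j)] - d[i, j]) / 2

    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk),
               c(dk, 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
  }
  ## final three nodes: closed-form two-point solution
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  l <- pmax(c(la, lb, lc), 0)
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[1], l[1], frag[2], l[2], frag[3], l[3])
  ape::read.tree(text = nwk)
}

#' Nontrivial bipartitions of a tree
#'
#' One split per internal edge, keyed by the sorted tip set on the side not
#' containing the alphabetically first tip; the same keying used by
#' [bootstrap_support()] and [all_bipartitions()], so planted and inferred
#' topologies can be compared split by split.
#'
#' @param tree an `ape::phylo` tree (rooted trees are treated as unrooted)
#' @return character vector of split keys
#' @export
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  n_tip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    labs <- tree$tip.label[p]
    if (length(labs) <= 1 || length(labs) >= n_tip - 1) next
    side <- if (ref %in% labs) setdiff(tips, labs) else labs
    if (length(side) <= 1) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' All possible nontrivial bipartitions of a taxon set
#'
#' Enumerates every split of the taxa into two sides of size >= 2, keyed like
#' [bootstrap_support()]'s split table; useful for comparing planted versus
#' spurious splits.
#'
#' @param taxa character vector of taxon names
#' @return character vector of split keys
#' @export
all_bipartitions <- function(taxa) {
  taxa <- sort(taxa)
  n <- length(taxa)
  ref <- taxa[1]
  keys <- character(0)
  for (k in 2:(n - 2)) {
    cmb <- utils::combn(taxa, k)
    for (c_i in seq_len(ncol(cmb))) {
      labs <- cmb[, c_i]
      side <- if (ref %in% labs) setdiff(taxa, labs) else labs
      if (length(side) < 2 || length(side) > n - 2) next
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

#' Neighbor-joining tree with gene-resampling bootstrap support
#'
#' Builds the full-data NJ tree, then resamples genes (matrix columns) with
#' replacement `B` times, recomputing the distance matrix and NJ tree per
#' replicate. The support of each internal branch of the full-data tree is
#' the fraction of (successful) replicates containing the same bipartition.
#' Replicates whose resampled matrix has a zero-variance profile under the
#' correlation metric are skipped and counted. Deterministic under `seed`.
#'
#' @param avg_expr clusters x genes matrix of averaged expression
#' @param B number of bootstrap replicates (>= 1)
#' @param metric passed to [expression_distance()]
#' @param seed integer seed
#' @return a list of class `support_tree`: `tree` (`phylo`, with node labels
#'   carrying support on internal branches), `splits` (data.frame `split`,
#'   `support`), `split_freq` (frequency of every split seen in replicates),
#'   `B`, `n_skipped`
#' @export
bootstrap_support <- function(avg_expr, B = 1000,
                              metric = c("correlation", "euclidean"),
                              seed = 1) {
  metric <- match.arg(metric)
  if (B < 1) stop("B must be >= 1")
  full <- nj_tree(expression_distance(avg_expr, metric))
  full_splits <- tree_bipartitions(full)

  set.seed(seed)
  counts <- structure(numeric(length(full_splits)), names = full_splits)
  seen <- new.env(parent = emptyenv())
  n_used <- 0L; n_skipped <- 0L
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(avg_expr), replace = TRUE)
    rep_tree <- tryCatch(
      nj_tree(expression_distance(avg_expr[, cols, drop = FALSE], metric)),
      error = function(e) NULL
    )
    if (is.null(rep_tree)) { n_skipped <- n_skipped + 1L; next }
    n_used <- n_used + 1L
    sp <- tree_bipartitions(rep_tree)
    hit <- full_splits %in% sp
    counts[hit] <- counts[hit] + 1
    for (s in sp) assign(s, (get0(s, envir = seen) %||% 0) + 1, envir = seen)
  }
  if (n_used == 0L) stop("all bootstrap replicates failed")
  support <- counts / n_used
  freq_names <- ls(seen)
  split_freq <- vapply(freq_names, get, numeric(1), envir = seen) / n_used

  ## attach support to internal nodes for Newick export
  tree <- full
  tree$node.label <- rep("", tree$Nnode)
  parts <- ape::prop.part(tree)
  tips <- sort(tree$tip.label); ref <- tips[1]
  for (k in seq_along(parts)) {
    labs <- tree$tip.label[parts[[k]]]
    side <- if (ref %in% labs) setdiff(tips, labs) else labs
    keyk <- paste(sort(side), collapse = "|")
    if (keyk %in% names(support)) {
      tree$node.label[k] <- format(round(support[[keyk]], 4))
    }
  }
  structure(
    list(tree = tree,
         splits = data.frame(split = names(support),
                             support = unname(support),
                             stringsAsFactors = FALSE),
         split_freq = split_freq, B = B, n_skipped = n_skipped,
         metric = metric),
    class = "support_tree"
  )
}

#' @method print support_tree
#' @export
print.support_tree <- function(x, ...) {
  cat("NJ cell-type tree (", length(x$tree$tip.label), "types ),",
      x$B, "bootstrap replicates (", x$n_skipped, "skipped )\n")
  print(x$splits, row.names = FALSE)
  invisible(x)
}

#' Write a support tree as Newick
#'
#' Internal-node labels carry the bootstrap support fractions.
#'
#' @param x a `support_tree` (or plain `phylo`)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_newick <- function(x, path) {
  tree <- if (inherits(x, "support_tree")) x$tree else x
  ape::write.tree(tree, file = path)
  invisible(path)
}
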