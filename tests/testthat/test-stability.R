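# Cluster-stability assessment: Jaccard matching, identity and half-split
# oracles, threshold behavior, grid search.

test_that("jaccard follows set arithmetic", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_error(jaccard(character(0), character(0)), "empty")
})

make_labeled_sim <- function(n_cells = 300, seed = 1) {
  sim <- simulate_counts(sim_config(
    n_cells = n_cells, n_genes = 150,
    cell_type_props = c(A = 0.4, B = 0.35, C = 0.25),
    cell_type_class = c(A = "neuronal", B = "neuronal", C = "non-neuronal"),
    marker_spec = list(A = list(genes = paste0("A.m", 1:5), fold_change = 8),
                       B = list(genes = paste0("B.m", 1:5), fold_change = 8),
                       C = list(genes = paste0("C.m", 1:5), fold_change = 8)),
    phenotype_spec = list(), family_spec = list(), n_mito_genes = 0,
    tree = "((A:1,B:1):1,C:2);", seed = seed
  ))
  list(counts = sim$counts, labels = sim$truth$cell_type_of_cell)
}

test_that("the identity reclusterer scores 1.0 for every cluster", {
  d <- make_labeled_sim()
  st <- assess_stability(d$counts, d$labels, fixed_label_clusterer(d$labels),
                         stability_params(n_iterations = 5, seed = 7))
  expect_true(all(st$scores == 1))
  expect_true(all(st$aggregate == 1))
  expect_true(all(st$stable))
})

# A clusterer that reproduces the original labels but deterministically
# splits one target cluster in half each iteration.
half_split_clusterer <- function(labels, target) {
  force(labels); force(target)
  function(counts, seed) {
    out <- labels[colnames(counts)]
    hit <- which(out == target)
    out[hit[seq_along(hit) %% 2 == 0]] <- paste0(target, ".half")
    out
  }
}

test_that("a half-splitting clusterer drives the split cluster to ~0.5 and unstable", {
  d <- make_labeled_sim(n_cells = 400, seed = 3)
  st <- assess_stability(
    d$counts, d$labels, half_split_clusterer(d$labels, "A"),
    stability_params(n_iterations = 50, seed = 11)
  )
  expect_lt(abs(st$aggregate[["A"]] - 0.5), 0.02)
  expect_false(st$stable[["A"]])
  expect_true(st$stable[["B"]])
  expect_true(st$stable[["C"]])
})

test_that("the stable call is aggregate >= threshold, exactly at the boundary", {
  # 100 cells in one cluster A plus a fixed cluster B; the clusterer keeps a
  # controlled fraction of A's subsampled members, giving an exact Jaccard
  labels <- c(rep("A", 100), rep("B", 100))
  names(labels) <- sprintf("c%d", 1:200)
  counts <- tiny_counts(matrix(1, 2, 200), cells = names(labels))
  keep_frac_clusterer <- function(n_keep_of) {
    function(cnts, seed) {
      out <- labels[colnames(cnts)]
      ia <- which(out == "A")
      out[ia[-seq_len(n_keep_of(length(ia)))]] <- "A.rest"
      out
    }
  }
  p <- stability_params(subsample_fraction = 0.5, n_iterations = 4, seed = 5)
  # keep just under / at least 60% of A's subsampled members
  st59 <- assess_stability(counts, labels,
                           keep_frac_clusterer(function(m) floor(0.59 * m)), p)
  st60 <- assess_stability(counts, labels,
                           keep_frac_clusterer(function(m) ceiling(0.60 * m)), p)
  expect_lt(st59$aggregate[["A"]], 0.6)
  expect_false(st59$stable[["A"]])
  expect_gte(st60$aggregate[["A"]], 0.6)
  expect_true(st60$stable[["A"]])
  # raising the threshold never grows the stable set
  thresholds <- c(0.2, 0.5, 0.8, 1)
  stable_sets <- lapply(thresholds, function(thr) {
    st <- assess_stability(counts, labels,
                           keep_frac_clusterer(function(m) ceiling(0.60 * m)),
                           stability_params(subsample_fraction = 0.5,
                                            n_iterations = 4,
                                            jaccard_threshold = thr, seed = 5))
    names(st$stable)[st$stable]
  })
  for (i in seq_len(length(stable_sets) - 1)) {
    expect_true(all(stable_sets[[i + 1]] %in% stable_sets[[i]]))
  }
})

test_that("assessment is deterministic under a fixed seed", {
  d <- make_labeled_sim(n_cells = 200, seed = 9)
  cl <- pca_kmeans_clusterer(k = 3, n_pcs = 5)
  p <- stability_params(n_iterations = 5, seed = 13)
  s1 <- assess_stability(d$counts, d$labels, cl, p)
  s2 <- assess_stability(d$counts, d$labels, cl, p)
  expect_identical(s1$scores, s2$scores)
})

test_that("grid search returns the argmax with documented tie-breaks", {
  d <- make_labeled_sim(n_cells = 300, seed = 15)
  # single point
  g1 <- grid_search_stability(
    d$counts, data.frame(k = 3),
    function(row) pca_kmeans_clusterer(k = row$k, n_pcs = 5),
    stability_params(n_iterations = 3, seed = 17)
  )
  expect_equal(g1$best, 1)
  # planted 3 types: some grid point reaches >= 3 stable clusters
  g2 <- grid_search_stability(
    d$counts, data.frame(k = 2:4),
    function(row) pca_kmeans_clusterer(k = row$k, n_pcs = 5),
    stability_params(n_iterations = 5, seed = 19)
  )
  expect_gte(max(g2$table$n_stable), 3)
  # exact ties resolve to the earlier grid row
  same <- grid_search_stability(
    d$counts, data.frame(k = c(3, 3)),
    function(row) pca_kmeans_clusterer(k = row$k, n_pcs = 5),
    stability_params(n_iterations = 3, seed = 21)
  )
  expect_equal(same$best, 1)
  expect_error(
    grid_search_stability(d$counts, data.frame(),
                          function(row) fixed_label_clusterer(d$labels)),
    "empty"
  )
})

test_that("merge_clusters relabels only mapped clusters", {
  labs <- c("3", "15", "7", "3")
  out <- merge_clusters(labs, c(`3` = "IGL2-GLUT/DOP", `15` = "IGL2-GLUT/DOP"))
  expect_equal(out, c("IGL2-GLUT/DOP", "IGL2-GLUT/DOP", "7", "IGL2-GLUT/DOP"))
})
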