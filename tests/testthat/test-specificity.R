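# Tau specificity: formula oracle, invariance properties, rank enrichment
# against brute-force enumeration, pipeline exclusion rules.

test_that("cluster averages are arithmetic means per cluster", {
  counts <- tiny_counts(matrix(c(1, 3, 5,
                                 2, 2, 2), nrow = 2, byrow = TRUE),
                        genes = c("gA", "gB"))
  avg <- average_expression_by_cluster(counts, c("x", "x", "y"))
  expect_equal(avg["x", "gA"], 2)
  expect_equal(avg["y", "gA"], 5)
  expect_equal(unname(avg[, "gB"]), c(2, 2))
  one <- average_expression_by_cluster(counts, c("z", "z", "z"))
  expect_equal(unname(one[1, ]), unname(Matrix::rowMeans(counts)))
  expect_error(
    average_expression_by_cluster(counts, factor(c("x", "x", "x"),
                                                 levels = c("x", "y"))),
    "empty cluster"
  )
})

test_that("tau matches the direct formula", {
  expect_equal(tau(c(1, 1, 1, 1)), 0)
  expect_equal(tau(c(0, 0, 5, 0)), 1)
  expect_equal(tau(c(2, 4, 8)), 0.625)
  expect_true(is.na(tau(c(0, 0, 0))))
  expect_error(tau(c(-1, 2)), "nonnegative")
  expect_error(tau(5), "at least 2")
  # matrix version agrees with the scalar version
  m <- matrix(c(2, 4, 8, 1, 1, 1), nrow = 3,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(tau_per_gene(m)), c(0.625, 0))
})

test_that("tau is scale-invariant and monotone under concentration", {
  set.seed(101)
  for (rep in 1:1000) {
    n <- sample(3:12, 1)
    x <- runif(n, 0, 10)
    t0 <- tau(x)
    expect_true(t0 >= 0 && t0 <= 1)
    expect_equal(tau(x * runif(1, 0.1, 100)), t0, tolerance = 1e-12)
    # move mass from a non-max cluster to the max cluster
    i_max <- which.max(x)
    i_from <- sample(setdiff(seq_len(n), i_max), 1)
    delta <- x[i_from] * runif(1)
    y <- x
    y[i_from] <- y[i_from] - delta
    y[i_max] <- y[i_max] + delta
    expect_gte(tau(y), t0 - 1e-12)
  }
})

test_that("rank enrichment hits its closed-form extremes", {
  genes <- sprintf("g%02d", 1:20)
  # family = exactly the top 5 ranks, weight 0: ES = 1
  res <- rank_family_enrichment(genes, family_sets = list(top = genes[1:5]),
                                n_perm = 50, weight = 0, seed = 1)
  expect_equal(res$es, 1)
  expect_equal(res$direction, "top")
  # family = whole list: ES = 0 by normalization, untestable flag unset
  res2 <- rank_family_enrichment(genes, family_sets = list(all = genes),
                                 n_perm = 10, weight = 0, seed = 1)
  expect_false(res2$testable)
  # family with < 2 genes in the list: untestable
  res3 <- rank_family_enrichment(genes, family_sets = list(one = genes[3]),
                                 n_perm = 10, weight = 0, seed = 1)
  expect_false(res3$testable)
  # family disjoint from the list: untestable
  res4 <- rank_family_enrichment(genes, family_sets = list(no = c("zz", "yy")),
                                 n_perm = 10, weight = 0, seed = 1)
  expect_false(res4$testable)
})

test_that("unweighted ES equals brute-force running-sum enumeration", {
  genes <- sprintf("g%02d", 1:20)
  set.seed(7)
  for (rep in 1:200) {
    fam_pos <- sort(sample(20, 5))
    res <- rank_family_enrichment(genes,
                                  family_sets = list(f = genes[fam_pos]),
                                  n_perm = 2, weight = 0, seed = rep)
    expect_equal(res$es, brute_force_es(20, fam_pos), tolerance = 1e-12)
  }
})

test_that("permutation p-values are uniform under an exchangeable null", {
  genes <- sprintf("g%03d", 1:60)
  set.seed(33)
  pvals <- vapply(1:200, function(r) {
    fam <- sample(genes, 8)  # random placement: the null holds
    rank_family_enrichment(genes, family_sets = list(f = fam),
                           n_perm = 99, weight = 0, seed = 1000 + r)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the TF pipeline applies the 20-cell and tau > 0.85 rules", {
  # 75 cells, 3 clusters of 25; hand-built counts
  n <- 75
  labels <- rep(c("c1", "c2", "c3"), each = 25)
  m <- matrix(0, nrow = 5, ncol = n,
              dimnames = list(c("tf.onehot", "tf.broad", "tf.rare",
                                "tf.edge", "bg"),
                              sprintf("cell%02d", 1:n)))
  m["tf.onehot", labels == "c1"] <- 5          # one-hot: tau 1
  m["tf.broad", ] <- 3                         # uniform: tau 0
  m["tf.rare", 1:19] <- 1                      # 19 cells: excluded
  m["tf.edge", ] <- 1
  m["bg", ] <- 1
  counts <- tiny_counts(m, genes = rownames(m), cells = colnames(m))
  fam <- data.frame(gene_id = c("tf.onehot", "tf.broad", "tf.rare", "tf.edge"),
                    family = c("HOX", "HOX", "ZnF", "ZnF"))
  res <- tf_specificity_pipeline(counts, labels, fam, min_cells = 20,
                                 n_perm = 20, seed = 2, normalized = counts)
  tt <- res$tau_table
  expect_false(tt$included[tt$gene_id == "tf.rare"])
  expect_true(is.na(tt$tau[tt$gene_id == "tf.rare"]))
  expect_equal(tt$tau[tt$gene_id == "tf.onehot"], 1)
  expect_equal(tt$class[tt$gene_id == "tf.onehot"], "specific")
  expect_equal(tt$tau[tt$gene_id == "tf.broad"], 0)
  expect_equal(tt$class[tt$gene_id == "tf.broad"], "broad")
  expect_true("tf.onehot" %in% res$specific_genes)
})

test_that("tau exactly at the cutoff is classified broad (strict >)", {
  # profile (2, 4, 8) over unequal clusters would not give 0.85; build a
  # profile with tau exactly 0.85 over 3 clusters: solve sum(1 - x/max)/2 = .85
  # with x = (a, b, 1): (1-a) + (1-b) = 1.7, take a = 0.3, b = 0 -> tau = 0.85
  labels <- c("k1", "k2", "k3")
  m <- matrix(c(0.3, 0, 1), nrow = 1,
              dimnames = list("tf.x", c("u", "v", "w")))
  # counts that normalize to those cluster means: single cell per cluster,
  # bypass normalization by passing the matrix as `normalized`
  counts <- tiny_counts(rbind(m, bg = c(1, 1, 1)),
                        genes = c("tf.x", "bg"), cells = colnames(m))
  cutoff <- tau(c(0.3, 0, 1))  # exactly the profile's tau
  res <- tf_specificity_pipeline(
    counts, labels, data.frame(gene_id = "tf.x", family = "F"),
    min_cells = 1, normalized = counts, n_perm = 5, seed = 3,
    tau_specific_cutoff = cutoff
  )
  expect_equal(res$tau_table$tau[1], 0.85, tolerance = 1e-12)
  expect_identical(res$tau_table$tau[1] > cutoff, FALSE)
  expect_equal(res$tau_table$class[1], "broad")
})

test_that("a planted one-hot family is enriched at the top of the tau ranking", {
  # 4 clusters x 8 cells; family genes one-hot in distinct clusters,
  # background genes uniform
  labels <- rep(paste0("c", 1:4), each = 8)
  genes <- c(paste0("fam", 1:4), paste0("bg", 1:12))
  m <- matrix(0, nrow = length(genes), ncol = 32,
              dimnames = list(genes, sprintf("cell%02d", 1:32)))
  for (i in 1:4) m[paste0("fam", i), labels == paste0("c", i)] <- 4
  m[paste0("bg", 1:12), ] <- 2
  counts <- tiny_counts(m, genes = genes, cells = colnames(m))
  fam_map <- data.frame(gene_id = genes,
                        family = c(rep("PCDH", 4), rep("none", 12)))
  res <- tf_specificity_pipeline(counts, labels, fam_map, min_cells = 1,
                                 n_perm = 500, weight = 0, seed = 4,
                                 normalized = counts)
  tt <- res$tau_table
  expect_true(all(tt$tau[grepl("^fam", tt$gene_id)] == 1))
  enr <- res$enrichment[res$enrichment$family == "PCDH", ]
  expect_equal(enr$es, 1)
  expect_lt(enr$p_value, 0.05)
})
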