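#' Configuration for the droplet count simulator
#'
#' Builds the full parameter set for [simulate_counts()]. The defaults define
#' a six-type paralarval-brain-like mixture whose planted marker-positivity
#' fractions reproduce the composition reported for the real atlas: 64%
#' vglut+, 29% vacht+, 27% th+, a 5% dual th+/vglut+ population, 10% glia
#' (gs2+), 1% precursors, 89% elav+ and 83% onecut+ cells, plus a
#' protocadherin-like gene family expressed at a planted mean diversity of
#' 19 distinct genes per neuronal cell and 13 per non-neuronal cell.
#'
#' @param n_cells number of droplets.
#' @param n_genes total number of genes (background + markers + family +
#'   mitochondrial). Must exceed the number of special genes implied by the
#'   other arguments.
#' @param cell_type_props named vector of cell-type proportions summing to 1.
#' @param cell_type_class named character vector mapping each cell type to a
#'   class label (e.g. `"neuronal"` / `"non-neuronal"`), used for planted
#'   family diversity.
#' @param marker_spec named list, one element per cell type: a list with
#'   `genes` (character ids) and `fold_change` (>= 1). These genes have their
#'   negative-binomial mean multiplied by `fold_change` in that type,
#'   providing cluster structure and marker-gene signal.
#' @param phenotype_spec named list, one element per phenotype marker gene.
#'   Each element is either a single fraction in \[0,1\] (cells positive
#'   independently at that rate) or a named vector of per-cell-type
#'   positivity probabilities (missing types default to 0). Positive cells
#'   receive a zero-truncated negative-binomial count (mean `marker_mu`);
#'   negative cells receive 0, so planted positive fractions are exact
#'   Bernoulli rates.
#' @param batch_props named fractions for the `cell` / `nucleus` batches.
#' @param n_mito_genes number of mitochondrial genes (ids `mt-1`, ...).
#' @param mito_beta_params named list of `c(shape1, shape2)` per batch; each
#'   droplet's mitochondrial fraction is drawn from its batch's Beta law.
#' @param family_spec named list, one element per gene family: a list with
#'   `n_genes` and `diversity` (named vector: target mean number of distinct
#'   positive family genes per cell, by class).
#' @param tree rooted topology with branch lengths over the cell types
#'   (newick string or `ape::phylo`). Background cell-type mean profiles
#'   follow a log-normal Brownian walk along its branches so profile
#'   distances reflect the planted topology.
#' @param walk_sd standard deviation of the per-gene log-mean increment per
#'   unit branch length of `tree`.
#' @param nb_dispersion gamma-Poisson dispersion phi (variance
#'   `mu + phi * mu^2`).
#' @param base_mean median baseline negative-binomial mean per gene.
#' @param base_sdlog log-sd of the baseline gene means.
#' @param marker_mu mean of the zero-truncated count given positivity for
#'   phenotype genes.
#' @param family_mu mean of the zero-truncated count given positivity for
#'   family genes.
#' @param batch_lfc natural-log fold shift applied to `batch_genes` in the
#'   nucleus batch (emulating lncRNA/heat-shock composition biases); 0
#'   disables it.
#' @param batch_genes gene ids affected by `batch_lfc`; default the first 50
#'   background genes when `batch_lfc != 0`.
#' @param seed integer seed; identical configs and seeds give identical
#'   output.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 10000,
                       n_genes = 900,
                       cell_type_props = c(
                         GLUT = 0.38, ACH = 0.24, DOP = 0.22,
                         DUAL = 0.05, GLIA = 0.10, PREC = 0.01
                       ),
                       cell_type_class = c(
                         GLUT = "neuronal", ACH = "neuronal",
                         DOP = "neuronal", DUAL = "neuronal",
                         GLIA = "non-neuronal", PREC = "non-neuronal"
                       ),
                       marker_spec = default_marker_spec(names(cell_type_props)),
                       phenotype_spec = default_phenotype_spec(),
                       batch_props = c(cell = 0.5, nucleus = 0.5),
                       n_mito_genes = 10,
                       mito_beta_params = list(
                         cell = c(2, 64), nucleus = c(1.5, 73.5)
                       ),
                       family_spec = list(
                         PCDH = list(
                           n_genes = 60,
                           diversity = c(neuronal = 19, `non-neuronal` = 13)
                         )
                       ),
                       tree = paste0(
                         "(((GLUT:0.6,ACH:0.6):0.4,(DOP:0.6,DUAL:0.6):0.4)",
                         ":0.8,(GLIA:1,PREC:1):0.8);"
                       ),
                       walk_sd = 0.35,
                       nb_dispersion = 0.5,
                       base_mean = 0.3,
                       base_sdlog = 1,
                       marker_mu = 3,
                       family_mu = 2,
                       batch_lfc = 0,
                       batch_genes = NULL,
                       seed = 1) {
  types <- names(cell_type_props)
  if (is.null(types) || any(!nzchar(types))) {
    stop("cell_type_props must be a named vector")
  }
  if (abs(sum(cell_type_props) - 1) > 1e-9) {
    stop("cell_type_props must sum to 1 (within 1e-9)")
  }
  if (any(cell_type_props < 0)) stop("cell_type_props must be nonnegative")
  if (!all(types %in% names(cell_type_class))) {
    stop("cell_type_class must cover every cell type")
  }
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!is.null(tree)) {
    if (!inherits(tree, "phylo")) stop("tree must be a newick string or phylo")
    if (!setequal(tree$tip.label, types)) {
      stop("tree tip labels must equal the cell-type names")
    }
  }
  for (ct in names(marker_spec)) {
    if (!ct %in% types) stop("marker_spec names a type absent from cell_type_props: ", ct)
    fc <- marker_spec[[ct]]$fold_change
    if (any(fc < 1)) stop("marker fold changes must be >= 1")
  }
  for (ph in names(phenotype_spec)) {
    p <- phenotype_spec[[ph]]
    if (!is.numeric(p) || any(p < 0 | p > 1)) {
      stop("phenotype_spec probabilities must lie in [0, 1]")
    }
    if (length(p) > 1 && !all(names(p) %in% types)) {
      stop("phenotype_spec for ", ph, " names an unknown cell type")
    }
  }
  if (abs(sum(batch_props) - 1) > 1e-9) stop("batch_props must sum to 1")
  if (!all(names(batch_props) %in% names(mito_beta_params)) && n_mito_genes > 0) {
    stop("mito_beta_params must cover every batch")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (base_mean <= 0) stop("base_mean must be positive")

  marker_gene_ids <- unique(c(
    names(phenotype_spec),
    unlist(lapply(marker_spec, `[[`, "genes"), use.names = FALSE)
  ))
  n_family <- sum(vapply(family_spec, `[[`, numeric(1), "n_genes"))
  n_special <- length(marker_gene_ids) + n_family + n_mito_genes
  if (n_genes <= n_special) {
    stop("n_genes (", n_genes, ") must exceed the ", n_special,
         " marker/family/mito genes implied by the config")
  }

  structure(
    list(
      n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
      cell_type_props = cell_type_props, cell_type_class = cell_type_class,
      marker_spec = marker_spec, phenotype_spec = phenotype_spec,
      batch_props = batch_props, n_mito_genes = as.integer(n_mito_genes),
      mito_beta_params = mito_beta_params, family_spec = family_spec,
      tree = tree, walk_sd = walk_sd, nb_dispersion = nb_dispersion,
      base_mean = base_mean, base_sdlog = base_sdlog,
      marker_mu = marker_mu, family_mu = family_mu,
      batch_lfc = batch_lfc, batch_genes = batch_genes,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default per-type differential markers (4 genes per type, fold change 6)
#' @param types cell-type names
#' @return named list usable as `marker_spec`
#' @export
default_marker_spec <- function(types) {
  out <- lapply(types, function(ct) {
    list(genes = paste0(ct, ".m", 1:4), fold_change = 6)
  })
  names(out) <- types
  out
}

#' Default phenotype positivity probabilities
#'
#' Per-cell-type positivity probabilities whose mixture over the default
#' cell-type proportions equals the planted composition: vglut 0.64,
#' vacht 0.29, th 0.27, gs2 0.10, ascl1 0.01, elav 0.89, onecut 0.83, and a
#' joint th & vglut fraction of 0.05 carried entirely by the DUAL type.
#'
#' @return named list usable as `phenotype_spec`
#' @export
default_phenotype_spec <- function() {
  list(
    vglut  = c(GLUT = 1, DUAL = 1, ACH = 0.875),
    vacht  = c(ACH = 1, GLUT = 0.05 / 0.38),
    th     = c(DOP = 1, DUAL = 1),
    gs2    = c(GLIA = 1),
    ascl1  = c(PREC = 1),
    elav   = c(GLUT = 1, ACH = 1, DOP = 1, DUAL = 1),
    onecut = c(GLUT = 0.83 / 0.89, ACH = 0.83 / 0.89,
               DOP = 0.83 / 0.89, DUAL = 0.83 / 0.89)
  )
}

# Expand a phenotype entry (scalar or partial per-type vector) to a full
# per-type probability vector.
phenotype_probs <- function(p, types) {
  if (length(p) == 1L && is.null(names(p))) {
    return(structure(rep(as.numeric(p), length(types)), names = types))
  }
  full <- structure(rep(0, length(types)), names = types)
  full[names(p)] <- p
  full
}

# Planted overall positive fraction of a phenotype marker.
planted_fraction <- function(config, marker) {
  pr <- phenotype_probs(config$phenotype_spec[[marker]],
                        names(config$cell_type_props))
  sum(config$cell_type_props * pr)
}

#' Planted joint positive fraction of two phenotype markers
#'
#' Marker positivity is independent between markers given the cell type, so
#' the planted joint fraction is the mixture of per-type products.
#'
#' @param config a [sim_config()]
#' @param marker_a,marker_b phenotype gene ids named in `phenotype_spec`
#' @return planted fraction of cells positive for both markers
#' @export
planted_joint_fraction <- function(config, marker_a, marker_b) {
  types <- names(config$cell_type_props)
  pa <- phenotype_probs(config$phenotype_spec[[marker_a]], types)
  pb <- phenotype_probs(config$phenotype_spec[[marker_b]], types)
  sum(config$cell_type_props * pa * pb)
}

#' Simulate a droplet count matrix with planted ground truth
#'
#' Draws a genes x cells raw count matrix under a gamma-Poisson (negative
#' binomial) law with shared dispersion. Background cell-type mean profiles
#' follow a multiplicative log-normal random walk along the configured tree;
#' phenotype markers realize exact Bernoulli positivity per cell type;
#' family genes realize a planted per-class mean diversity; mitochondrial
#' counts realize a Beta-distributed per-droplet fraction, added on top of
#' the nuclear transcriptome so the planted marker fractions stay unbiased.
#'
#' @param config a [sim_config()]
#' @return a list of class `ceph_sim` with elements
#'   \describe{
#'     \item{counts}{`dgCMatrix`, genes x cells, raw integer counts}
#'     \item{meta}{data.frame: `barcode`, `batch`, `mito_fraction`,
#'       `n_genes_detected`}
#'     \item{truth}{list: `cell_type_of_cell`, `planted_fractions`,
#'       `planted_diversity`, `tree_used`, `gene_roles`}
#'   }
#' @examples
#' sim <- simulate_counts(sim_config(n_cells = 200, n_genes = 250, seed = 7))
#' dim(sim$counts)
#' mean(sim$counts["vglut", ] > 0) # near the planted 0.64
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be built with sim_config()")
  }
  set.seed(config$seed)
  n <- config$n_cells
  types <- names(config$cell_type_props)

  phen_genes <- names(config$phenotype_spec)
  de_genes <- setdiff(
    unique(unlist(lapply(config$marker_spec, `[[`, "genes"), use.names = FALSE)),
    phen_genes
  )
  fam_genes <- unlist(lapply(names(config$family_spec), function(f) {
    paste0(tolower(f), sprintf("%02d", seq_len(config$family_spec[[f]]$n_genes)))
  }), use.names = FALSE) %||% character(0)
  fam_of <- rep(names(config$family_spec),
                vapply(config$family_spec, `[[`, numeric(1), "n_genes")) %||%
    character(0)
  mito_genes <- if (config$n_mito_genes > 0) paste0("mt-", seq_len(config$n_mito_genes)) else character(0)
  n_bg <- config$n_genes - length(phen_genes) - length(de_genes) -
    length(fam_genes) - length(mito_genes)
  bg_genes <- sprintf("g%04d", seq_len(n_bg))
  gene_ids <- c(bg_genes, de_genes, phen_genes, fam_genes, mito_genes)
  stopifnot(!anyDuplicated(gene_ids))

  ## cell assignments
  cell_type <- sample(types, n, replace = TRUE, prob = config$cell_type_props)
  batch <- sample(names(config$batch_props), n, replace = TRUE,
                  prob = config$batch_props)
  barcodes <- sprintf("cell%05d", seq_len(n))

  ## baseline means for NB-drawn genes (background + DE markers)
  nb_ids <- c(bg_genes, de_genes)
  base_mu <- exp(rnorm(length(nb_ids), log(config$base_mean), config$base_sdlog))
  names(base_mu) <- nb_ids

  ## tree-structured per-type log offsets on the NB-drawn genes
  type_lfc <- matrix(0, nrow = length(nb_ids), ncol = length(types),
                     dimnames = list(nb_ids, types))
  if (!is.null(config$tree) && config$walk_sd > 0) {
    tr <- config$tree
    n_tip <- length(tr$tip.label)
    node_val <- vector("list", n_tip + tr$Nnode)
    root <- n_tip + 1L
    node_val[[root]] <- numeric(length(nb_ids))
    ord <- reorder(tr, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; chd <- ord$edge[e, 2]
      bl <- ord$edge.length[e]
      node_val[[chd]] <- node_val[[par]] +
        rnorm(length(nb_ids), 0, config$walk_sd * sqrt(bl))
    }
    for (i in seq_len(n_tip)) type_lfc[, tr$tip.label[i]] <- node_val[[i]]
  }

  ## per-type fold changes from marker_spec
  fc <- matrix(1, nrow = length(nb_ids), ncol = length(types),
               dimnames = list(nb_ids, types))
  for (ct in names(config$marker_spec)) {
    ms <- config$marker_spec[[ct]]
    g <- intersect(ms$genes, nb_ids)
    fc[g, ct] <- ms$fold_change
  }

  size <- 1 / config$nb_dispersion
  counts <- matrix(0L, nrow = length(gene_ids), ncol = n,
                   dimnames = list(gene_ids, barcodes))

  ## NB-drawn genes, blocked by cell type (fixed type order for determinism)
  for (ct in types) {
    idx <- which(cell_type == ct)
    if (!length(idx)) next
    mu_ct <- base_mu * exp(type_lfc[, ct]) * fc[, ct]
    counts[nb_ids, idx] <- matrix(
      rnbinom(length(nb_ids) * length(idx), mu = mu_ct, size = size),
      nrow = length(nb_ids)
    )
  }

  ## nucleus-batch composition shift on a gene subset
  if (config$batch_lfc != 0) {
    bg_shift <- config$batch_genes %||% utils::head(bg_genes, 50)
    bg_shift <- intersect(bg_shift, nb_ids)
    nuc <- which(batch == "nucleus")
    for (ct in types) {
      idx <- intersect(which(cell_type == ct), nuc)
      if (!length(idx)) next
      mu_ct <- base_mu[bg_shift] * exp(type_lfc[bg_shift, ct]) *
        fc[bg_shift, ct] * exp(config$batch_lfc)
      counts[bg_shift, idx] <- matrix(
        rnbinom(length(bg_shift) * length(idx), mu = mu_ct, size = size),
        nrow = length(bg_shift)
      )
    }
  }

  ## phenotype markers: exact Bernoulli positivity, zero-truncated NB counts
  for (ph in phen_genes) {
    pr <- phenotype_probs(config$phenotype_spec[[ph]], types)
    pos <- runif(n) < pr[cell_type]
    cnt <- integer(n)
    cnt[pos] <- rztnbinom(sum(pos), mu = config$marker_mu, size = size)
    counts[ph, ] <- cnt
  }

  ## family genes: per-class Bernoulli positivity with planted mean diversity
  cls <- config$cell_type_class[cell_type]
  for (f in names(config$family_spec)) {
    fs <- config$family_spec[[f]]
    gidx <- fam_genes[fam_of == f]
    q <- fs$diversity / fs$n_genes
    if (any(q > 1)) stop("planted diversity exceeds family size for ", f)
    qcell <- ifelse(cls %in% names(q), q[cls], 0)
    for (g in gidx) {
      pos <- runif(n) < qcell
      cnt <- integer(n)
      cnt[pos] <- rztnbinom(sum(pos), mu = config$family_mu, size = size)
      counts[g, ] <- cnt
    }
  }

  ## mitochondrial counts: Beta-drawn target fraction per droplet, realized
  ## by adding mito counts on top of the nuclear total
  mito_fraction <- numeric(n)
  if (length(mito_genes)) {
    fdraw <- numeric(n)
    for (b in names(config$batch_props)) {
      bi <- which(batch == b)
      sh <- config$mito_beta_params[[b]]
      fdraw[bi] <- rbeta(length(bi), sh[1], sh[2])
    }
    tot <- colSums(counts)
    m_tot <- round(fdraw / (1 - fdraw) * tot)
    mito_counts <- vapply(m_tot, function(m) {
      if (m == 0) integer(length(mito_genes))
      else as.integer(rmultinom(1, m, rep(1, length(mito_genes))))
    }, integer(length(mito_genes)))
    counts[mito_genes, ] <- mito_counts
    mito_fraction <- m_tot / pmax(tot + m_tot, 1)
  }

  counts <- as(counts, "CsparseMatrix")
  meta <- data.frame(
    barcode = barcodes, batch = batch,
    mito_fraction = mito_fraction,
    n_genes_detected = Matrix::colSums(counts > 0),
    row.names = barcodes, stringsAsFactors = FALSE
  )

  planted <- vapply(phen_genes, function(ph) planted_fraction(config, ph),
                    numeric(1))
  truth <- list(
    cell_type_of_cell = structure(cell_type, names = barcodes),
    planted_fractions = planted,
    planted_diversity = lapply(config$family_spec, `[[`, "diversity"),
    tree_used = config$tree,
    gene_roles = list(background = bg_genes, de_markers = de_genes,
                      phenotype = phen_genes, family = split(fam_genes, fam_of),
                      mito = mito_genes)
  )
  structure(list(counts = counts, meta = meta, truth = truth, config = config),
            class = "ceph_sim")
}

#' @method print ceph_sim
#' @export
print.ceph_sim <- function(x, ...) {
  cat("Simulated droplet dataset:", nrow(x$counts), "genes x",
      ncol(x$counts), "cells\n")
  cat("Cell types:",
      paste(names(x$config$cell_type_props), collapse = ", "), "\n")
  cat("Planted fractions:",
      paste(sprintf("%s=%.2f", names(x$truth$planted_fractions),
                    x$truth$planted_fractions), collapse = ", "), "\n")
  invisible(x)
}
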