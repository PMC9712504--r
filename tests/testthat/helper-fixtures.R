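# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# Small labeled count matrix with hand-set values.
tiny_counts <- function(values, genes = NULL, cells = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- cells %||% sprintf("c%d", seq_len(ncol(m)))
  Matrix::Matrix(m, sparse = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gene set builder for extension tests: 1-based closed coordinates.
make_genes <- function(chrom, start, end, strand, gene_id = NULL) {
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, end), strand = strand,
    gene_id = gene_id %||% sprintf("g%02d", seq_along(start))
  )
}

make_sites <- function(chrom, pos, strand) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos), strand = strand)
}

make_isoforms <- function(chrom, start, end, strand, hint = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  if (!is.null(hint)) S4Vectors::mcols(gr)$gene_hint <- hint
  gr
}

make_coverage <- function(chrom, start, end, score) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), score = score)
}

empty_gr <- function() GenomicRanges::GRanges()

# Mirror a coordinate system around `axis` for strand-duality tests.
mirror_granges <- function(gr, axis) {
  s <- axis - GenomicRanges::end(gr)
  e <- axis - GenomicRanges::start(gr)
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr), IRanges::IRanges(s, e),
    strand = chartr("+-", "-+", as.character(GenomicRanges::strand(gr)))
  )
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  out
}

# Independent brute-force running-sum enrichment score (unweighted), used as
# the oracle for rank_family_enrichment at weight 0.
brute_force_es <- function(n, hit_positions) {
  hit <- seq_len(n) %in% hit_positions
  nh <- length(hit_positions)
  rs <- 0; mx <- -Inf; mn <- Inf
  for (i in seq_len(n)) {
    rs <- rs + if (hit[i]) 1 / nh else -1 / (n - nh)
    if (rs > mx) mx <- rs
    if (rs < mn) mn <- rs
  }
  if (mx >= -mn - 1e-12) mx else mn  # ties go to the positive extreme
}

# Independent brute-force two-sided Fisher p: enumerate all tables with the
# observed margins via factorial probabilities.
brute_force_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; k <- a + c_; n <- r1 + r2
  xs <- max(0, k - r2):min(k, r1)
  logp <- lfactorial(r1) + lfactorial(r2) + lfactorial(k) +
    lfactorial(n - k) - lfactorial(n) -
    (lfactorial(xs) + lfactorial(r1 - xs) + lfactorial(k - xs) +
       lfactorial(r2 - k + xs))
  p <- exp(logp)
  p_obs <- p[xs == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}
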