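#' Configuration for the toy genome fixture
#'
#' Parameters for [simulate_genome_fixture()], which builds a small genome
#' with known true 3' ends and the three evidence tiers consumed by the
#' extension pipeline. Genes are laid out in equal-width slots along each
#' chromosome, alternating strand, so that same-strand genes never overlap
#' and true extensions never cross the next same-strand gene start.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes total number of genes, split evenly across chromosomes.
#' @param gene_length annotated gene-body length in bp.
#' @param true_extension_lengths per-gene true 3' extension in bp (>= 0);
#'   recycled to `n_genes`.
#' @param evidence_assignment per-gene tier in `isoseq`, `flamseq`,
#'   `coverage`, `none`; recycled to `n_genes`.
#' @param intergenic_read_frac_before fraction of simulated reads planted in
#'   the to-be-annexed extension zones (fully intergenic under the input
#'   annotation).
#' @param n_reads number of simulated reads.
#' @param read_length read length in bp.
#' @param seed integer seed.
#' @return an object of class `genome_fixture_config`.
#' @export
genome_fixture_config <- function(n_chroms = 2,
                                  chrom_length = 1e6,
                                  n_genes = 40,
                                  gene_length = 2000,
                                  true_extension_lengths = c(150, 400, 1200, 5000),
                                  evidence_assignment = c("isoseq", "flamseq",
                                                          "coverage", "none"),
                                  intergenic_read_frac_before = 0.2,
                                  n_reads = 10000,
                                  read_length = 100,
                                  seed = 1) {
  tiers <- c("isoseq", "flamseq", "coverage", "none")
  evidence_assignment <- rep_len(evidence_assignment, n_genes)
  true_extension_lengths <- rep_len(as.integer(true_extension_lengths), n_genes)
  if (!all(evidence_assignment %in% tiers)) {
    stop("evidence_assignment entries must be one of: ",
         paste(tiers, collapse = ", "))
  }
  if (any(true_extension_lengths < 0)) stop("true extensions must be >= 0")
  genes_per_chrom <- ceiling(n_genes / n_chroms)
  slot <- floor(chrom_length / genes_per_chrom)
  max_ext <- slot - gene_length - 2 * 1000 - 10
  if (any(true_extension_lengths > max_ext)) {
    stop("a true extension (max ", max(true_extension_lengths),
         " bp) would cross the next same-strand gene start; ",
         "slot layout allows at most ", max_ext, " bp")
  }
  fl <- evidence_assignment == "flamseq"
  if (any(true_extension_lengths[fl] > 60000)) {
    stop("flamseq-tier extensions must stay within 60,000 bp")
  }
  structure(
    list(n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
         n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
         true_extension_lengths = true_extension_lengths,
         evidence_assignment = evidence_assignment,
         intergenic_read_frac_before = intergenic_read_frac_before,
         n_reads = as.integer(n_reads), read_length = as.integer(read_length),
         genes_per_chrom = genes_per_chrom, slot = slot,
         seed = as.integer(seed)),
    class = "genome_fixture_config"
  )
}

#' Simulate a genome fixture with planted true 3' ends
#'
#' Emits, per gene and by its assigned evidence tier:
#' * `isoseq` -- a full isoform interval from the gene 5' start to the true
#'   3' end (half carry an explicit gene hint, half are assigned by overlap);
#' * `flamseq` -- a 1-bp cleavage site at the true 3' end;
#' * `coverage` -- a depth-5 coverage block from the annotated 3' end to the
#'   true end, followed by a depth-2 block (below the >= 5 threshold);
#' * `none` -- no supporting evidence.
#'
#' A controlled fraction of simulated reads is placed fully inside the
#' extension zones (intergenic under the input annotation; annexed by the
#' pipeline when the zone's gene has evidence), the rest inside gene bodies.
#' By construction the extension pipeline recovers every evidence-supported
#' true end exactly.
#'
#' @param config a [genome_fixture_config()]
#' @return a list of class `ceph_genome_fixture` with `GRanges` elements
#'   `genes` (with `gene_id`), `isoforms` (with `gene_hint`), `sites`,
#'   `coverage` (with `score`), `reads`, plus a `truth` data.frame
#'   (`gene_id`, `chrom`, `strand`, `annotated_end3`, `true_end3`, `tier`)
#'   and the `config`.
#' @examples
#' fx <- simulate_genome_fixture(genome_fixture_config(n_genes = 8, seed = 3))
#' fx$truth[, c("gene_id", "tier", "annotated_end3", "true_end3")]
#' @export
simulate_genome_fixture <- function(config) {
  if (!inherits(config, "genome_fixture_config")) {
    stop("config must be built with genome_fixture_config()")
  }
  set.seed(config$seed)
  L <- config$gene_length
  slot <- config$slot
  margin <- 1000L

  gene_id <- sprintf("gene%03d", seq_len(config$n_genes))
  chrom <- paste0("chr", rep(seq_len(config$n_chroms),
                             each = config$genes_per_chrom))[seq_len(config$n_genes)]
  within_idx <- stats::ave(seq_len(config$n_genes), chrom, FUN = seq_along)
  strand <- ifelse(within_idx %% 2 == 1, "+", "-")
  slot_start <- (within_idx - 1L) * slot + 1L
  ext <- config$true_extension_lengths
  tier <- config$evidence_assignment

  start <- integer(config$n_genes); end <- integer(config$n_genes)
  plus <- strand == "+"
  start[plus] <- slot_start[plus] + margin
  end[plus] <- start[plus] + L - 1L
  end[!plus] <- slot_start[!plus] + slot - margin
  start[!plus] <- end[!plus] - L + 1L

  end3 <- ifelse(plus, end, start)
  true_end3 <- ifelse(plus, end3 + ext, end3 - ext)

  genes <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, end), strand = strand, gene_id = gene_id
  )

  ## isoseq tier: full isoform intervals ending at the true end
  iso_i <- which(tier == "isoseq")
  isoforms <- GenomicRanges::GRanges(
    chrom[iso_i],
    IRanges::IRanges(
      start = ifelse(plus[iso_i], start[iso_i], true_end3[iso_i]),
      end = ifelse(plus[iso_i], true_end3[iso_i], end[iso_i])
    ),
    strand = strand[iso_i],
    gene_hint = ifelse(seq_along(iso_i) %% 2 == 0, gene_id[iso_i], NA_character_)
  )

  ## flamseq tier: cleavage sites at the true end
  fl_i <- which(tier == "flamseq")
  sites <- GenomicRanges::GRanges(
    chrom[fl_i], IRanges::IRanges(true_end3[fl_i], true_end3[fl_i]),
    strand = strand[fl_i]
  )

  ## coverage tier: depth-5 run over the zone, then a depth-2 block
  cov_i <- which(tier == "coverage")
  cov_list <- lapply(cov_i, function(i) {
    if (ext[i] == 0) {
      lo <- if (plus[i]) end3[i] + 1L else end3[i] - 200L
      hi <- if (plus[i]) end3[i] + 200L else end3[i] - 1L
      return(data.frame(chrom = chrom[i], start = lo, end = hi, score = 2))
    }
    if (plus[i]) {
      data.frame(chrom = chrom[i],
                 start = c(end3[i] + 1L, true_end3[i] + 1L),
                 end = c(true_end3[i], true_end3[i] + 200L),
                 score = c(5, 2))
    } else {
      data.frame(chrom = chrom[i],
                 start = c(true_end3[i], true_end3[i] - 200L),
                 end = c(end3[i] - 1L, true_end3[i] - 1L),
                 score = c(5, 2))
    }
  })
  cov_df <- do.call(rbind, cov_list)
  coverage <- if (is.null(cov_df)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$score <- numeric(0)
    gr
  } else {
    GenomicRanges::GRanges(cov_df$chrom,
                           IRanges::IRanges(cov_df$start, cov_df$end),
                           score = cov_df$score)
  }
  coverage <- GenomicRanges::sort(coverage, ignore.strand = TRUE)

  ## reads: planted fraction in extension zones, rest in gene bodies
  rl <- config$read_length
  n_int <- round(config$intergenic_read_frac_before * config$n_reads)
  zone_ok <- which(ext >= rl)
  if (n_int > 0 && !length(zone_ok)) {
    stop("no extension zone is long enough to hold an intergenic read")
  }
  zpick <- if (n_int > 0) sample(zone_ok, n_int, replace = TRUE) else integer(0)
  zstart <- vapply(zpick, function(i) {
    lo <- if (plus[i]) end3[i] + 1L else true_end3[i]
    hi <- (if (plus[i]) true_end3[i] else end3[i] - 1L) - rl + 1L
    as.integer(sample(seq(lo, hi), 1))
  }, integer(1))
  gpick <- sample(config$n_genes, config$n_reads - n_int, replace = TRUE)
  gstart <- start[gpick] + vapply(gpick, function(i) {
    as.integer(sample.int(L - rl + 1L, 1)) - 1L
  }, integer(1))
  reads <- GenomicRanges::GRanges(
    c(chrom[zpick], chrom[gpick]),
    IRanges::IRanges(c(zstart, gstart), width = rl),
    strand = "*"
  )

  truth <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = start, end = end,
    annotated_end3 = end3, true_end3 = true_end3,
    extension = ext, tier = tier, stringsAsFactors = FALSE
  )
  structure(
    list(genes = genes, isoforms = isoforms, sites = sites,
         coverage = coverage, reads = reads, truth = truth, config = config),
    class = "ceph_genome_fixture"
  )
}

#' @method print ceph_genome_fixture
#' @export
print.ceph_genome_fixture <- function(x, ...) {
  cat("Genome fixture:", length(x$genes), "genes on",
      x$config$n_chroms, "chromosomes;",
      length(x$reads), "reads\n")
  print(table(x$truth$tier))
  invisible(x)
}
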