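# Evidence-guided extension of gene 3' ends.
#
# All coordinates are 1-based closed (GFF3 convention); readers convert
# BED/bedGraph half-open input on import. Genes are GRanges with a gene_id
# metadata column. Every operation is extension-only: a gene's 3' extent can
# only grow.

# 3'-most coordinate of each range, by strand.
three_prime_end <- function(gr) {
  ifelse(as.character(GenomicRanges::strand(gr)) == "+",
         GenomicRanges::end(gr), GenomicRanges::start(gr))
}

# Set the 3' extent, but only outward (extension-only contract).
extend_to <- function(gr, new_end3) {
  plus <- as.character(GenomicRanges::strand(gr)) == "+"
  GenomicRanges::end(gr)[plus] <-
    pmax(GenomicRanges::end(gr)[plus], new_end3[plus])
  GenomicRanges::start(gr)[!plus] <-
    pmin(GenomicRanges::start(gr)[!plus], new_end3[!plus])
  gr
}

check_gene_set <- function(genes, overlap = TRUE) {
  if (!is(genes, "GRanges")) stop("genes must be a GRanges")
  if (is.null(genes$gene_id)) stop("genes must carry a gene_id column")
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  if (overlap) {
    hits <- GenomicRanges::findOverlaps(genes, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits)) {
      stop("input genes overlap on the same strand: ",
           genes$gene_id[S4Vectors::queryHits(hits)[1]], " / ",
           genes$gene_id[S4Vectors::subjectHits(hits)[1]])
    }
  }
  invisible(genes)
}

#' Extend gene 3' ends from long-read isoform intervals
#'
#' Each isoform is assigned to a gene: an explicit `gene_hint` metadata value
#' is honored first; otherwise the isoform goes to the same-strand gene it
#' overlaps, ties broken by largest overlap. A gene's 3' extent becomes the
#' maximum (in transcriptional orientation) of its current extent and the
#' 3'-most assigned isoform end -- the end of the longest assigned isoform.
#' Isoforms overlapping no gene and lacking a hint are skipped and counted in
#' the `n_skipped` attribute.
#'
#' @param genes `GRanges` with `gene_id`
#' @param isoforms `GRanges` of full isoform intervals, optional `gene_hint`
#' @return the extended `GRanges` (attribute `n_skipped`)
#' @export
extend_by_isoforms <- function(genes, isoforms) {
  check_gene_set(genes, overlap = FALSE)
  n_skipped <- 0L
  if (!length(isoforms)) {
    attr(genes, "n_skipped") <- 0L
    return(genes)
  }
  hint <- isoforms$gene_hint %||% rep(NA_character_, length(isoforms))
  assigned <- match(hint, genes$gene_id)

  need <- which(is.na(assigned))
  if (length(need)) {
    # disjoint seqlevels between evidence and genes are a plain "no overlap"
    ov <- suppressWarnings(GenomicRanges::findOverlaps(isoforms[need], genes))
    if (length(ov)) {
      w <- GenomicRanges::width(IRanges::pintersect(
        isoforms[need][S4Vectors::queryHits(ov)],
        genes[S4Vectors::subjectHits(ov)]
      ))
      ord <- order(S4Vectors::queryHits(ov), -w,
                   genes$gene_id[S4Vectors::subjectHits(ov)])
      best <- !duplicated(S4Vectors::queryHits(ov)[ord])
      assigned[need[S4Vectors::queryHits(ov)[ord][best]]] <-
        S4Vectors::subjectHits(ov)[ord][best]
    }
    n_skipped <- sum(is.na(assigned[need]))
  }

  keep <- !is.na(assigned)
  if (any(keep)) {
    iso_end3 <- three_prime_end(isoforms)[keep]
    gi <- assigned[keep]
    plus <- as.character(GenomicRanges::strand(genes)) == "+"
    agg_max <- tapply(iso_end3, gi, max)
    agg_min <- tapply(iso_end3, gi, min)
    target <- three_prime_end(genes)
    idx <- as.integer(names(agg_max))
    target[idx] <- ifelse(plus[idx], pmax(target[idx], agg_max),
                          pmin(target[idx], agg_min))
    genes <- extend_to(genes, target)
  }
  attr(genes, "n_skipped") <- n_skipped
  genes
}

#' Assign cleavage sites to their closest upstream gene
#'
#' Each site is assigned to the nearest same-strand gene lying upstream of it
#' in transcriptional orientation, provided the distance from that gene's
#' current 3' end to the site is at most `max_dist` (inclusive). A site
#' falling inside a gene body is assigned to that gene (negative distance;
#' extension-only semantics leave such genes unchanged). Unassignable sites
#' get `NA`.
#'
#' @param genes `GRanges` with `gene_id`
#' @param sites `GRanges` of 1-bp cleavage sites
#' @param max_dist maximum assignment distance in bp (default 60000)
#' @return data.frame: `chrom`, `pos`, `strand`, `gene_id`, `distance`
#' @export
assign_cleavage_sites <- function(genes, sites, max_dist = 60000) {
  check_gene_set(genes, overlap = FALSE)
  gchr <- as.character(GenomicRanges::seqnames(genes))
  gstr <- as.character(GenomicRanges::strand(genes))
  gend3 <- three_prime_end(genes)
  g5 <- ifelse(gstr == "+", GenomicRanges::start(genes),
               GenomicRanges::end(genes))
  schr <- as.character(GenomicRanges::seqnames(sites))
  sstr <- as.character(GenomicRanges::strand(sites))
  spos <- GenomicRanges::start(sites)

  gene_id <- rep(NA_character_, length(sites))
  distance <- rep(NA_real_, length(sites))
  for (i in seq_along(sites)) {
    cand <- which(gchr == schr[i] & gstr == sstr[i] &
                    (if (sstr[i] == "+") g5 <= spos[i] else g5 >= spos[i]))
    if (!length(cand)) next
    d <- if (sstr[i] == "+") spos[i] - gend3[cand] else gend3[cand] - spos[i]
    down <- cand[d >= 0 & d <= max_dist]
    if (length(down)) {
      dd <- d[d >= 0 & d <= max_dist]
      pick <- down[order(dd, genes$gene_id[down])[1]]
      gene_id[i] <- genes$gene_id[pick]
      distance[i] <- min(dd)
    } else if (any(d < 0)) {
      inside <- cand[d < 0]
      di <- d[d < 0]
      pick <- inside[order(-di, genes$gene_id[inside])[1]]
      gene_id[i] <- genes$gene_id[pick]
      distance[i] <- max(di)
    }
  }
  data.frame(chrom = schr, pos = spos, strand = sstr,
             gene_id = gene_id, distance = distance,
             stringsAsFactors = FALSE)
}

#' Extend gene 3' ends to their most distal assigned cleavage site
#'
#' @param genes `GRanges` with `gene_id`
#' @param assignment data.frame from [assign_cleavage_sites()]
#' @return the extended `GRanges` (extension-only: genes are never shortened)
#' @export
extend_by_cleavage <- function(genes, assignment) {
  check_gene_set(genes, overlap = FALSE)
  asn <- assignment[!is.na(assignment$gene_id), , drop = FALSE]
  if (!nrow(asn)) return(genes)
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  target <- three_prime_end(genes)
  for (g in unique(asn$gene_id)) {
    i <- match(g, genes$gene_id)
    pos <- asn$pos[asn$gene_id == g]
    target[i] <- if (plus[i]) max(target[i], pos) else min(target[i], pos)
  }
  extend_to(genes, target)
}

#' Extend gene 3' ends by continuous downstream short-read coverage
#'
#' For genes lacking cleavage-site support, the 3' extent advances base by
#' base downstream while read depth stays at or above `min_cov`, stopping at
#' the first base below the threshold. Positions absent from the coverage
#' track have depth 0. Contiguity is evaluated at base resolution: a single
#' sub-threshold base terminates the walk.
#'
#' @param genes `GRanges` with `gene_id`
#' @param cov `GRanges` coverage track with a `score` column (1-based closed;
#'   use [read_bedgraph()] for bedGraph input)
#' @param min_cov minimum depth (default 5)
#' @param flamseq_supported gene ids with cleavage evidence; these are not
#'   extended by coverage
#' @param max_walk optional cap on walk length in bp (default unlimited)
#' @return the extended `GRanges`
#' @export
extend_by_coverage <- function(genes, cov, min_cov = 5,
                               flamseq_supported = character(0),
                               max_walk = Inf) {
  check_gene_set(genes, overlap = FALSE)
  ok <- cov[S4Vectors::mcols(cov)$score >= min_cov]
  runs <- GenomicRanges::reduce(ok, min.gapwidth = 1L, ignore.strand = TRUE)
  rchr <- as.character(GenomicRanges::seqnames(runs))

  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  gchr <- as.character(GenomicRanges::seqnames(genes))
  target <- three_prime_end(genes)
  for (i in seq_along(genes)) {
    if (genes$gene_id[i] %in% flamseq_supported) next
    pos0 <- if (plus[i]) target[i] + 1L else target[i] - 1L
    j <- which(rchr == gchr[i] &
                 GenomicRanges::start(runs) <= pos0 &
                 GenomicRanges::end(runs) >= pos0)
    if (!length(j)) next
    walk_end <- if (plus[i]) {
      min(GenomicRanges::end(runs)[j[1]], target[i] + max_walk)
    } else {
      max(GenomicRanges::start(runs)[j[1]], target[i] - max_walk)
    }
    target[i] <- walk_end
  }
  extend_to(genes, target)
}

#' Run the full three-tier 3'-extension pipeline
#'
#' Applies the evidence tiers in order -- long-read isoform ends, then
#' cleavage sites, then short-read coverage (the last restricted to genes
#' without cleavage support) -- each extension-only, then clamps any
#' extension that would cross the start of the next same-strand gene to 1 bp
#' before it. The per-gene report records which tier set the final end
#' (`isoseq`, `flamseq`, `coverage`, `clamped`, or `none` for unchanged
#' genes). If `reads` are supplied, the intergenic read fraction is computed
#' against the input and the extended annotation.
#'
#' @param genes `GRanges` with `gene_id`; same-strand genes must not overlap
#' @param isoforms `GRanges` of isoform intervals (may be empty)
#' @param sites `GRanges` of cleavage sites (may be empty)
#' @param cov `GRanges` coverage track with `score` (may be empty)
#' @param reads optional `GRanges` of read intervals
#' @param max_dist cleavage-site assignment cap in bp (default 60000)
#' @param min_cov coverage threshold (default 5)
#' @param max_walk optional coverage-walk cap in bp
#' @return a list of class `extension_result`: `extended_genes`, `report`
#'   (gene_id, old_end3, new_end3, tier), `intergenic_fraction_before`,
#'   `intergenic_fraction_after`
#' @examples
#' fx <- simulate_genome_fixture(genome_fixture_config(n_genes = 8, seed = 2))
#' res <- run_extension_pipeline(fx$genes, fx$isoforms, fx$sites,
#'                               fx$coverage, reads = fx$reads)
#' res$report
#' @export
run_extension_pipeline <- function(genes, isoforms, sites, cov,
                                   reads = NULL, max_dist = 60000,
                                   min_cov = 5, max_walk = Inf) {
  check_gene_set(genes)
  old_end3 <- three_prime_end(genes)

  g1 <- extend_by_isoforms(genes, isoforms)
  e1 <- three_prime_end(g1)

  asn <- assign_cleavage_sites(g1, sites, max_dist = max_dist)
  g2 <- extend_by_cleavage(g1, asn)
  e2 <- three_prime_end(g2)
  flamseq_supported <- unique(asn$gene_id[!is.na(asn$gene_id)])

  g3 <- extend_by_coverage(g2, cov, min_cov = min_cov,
                           flamseq_supported = flamseq_supported,
                           max_walk = max_walk)
  e3 <- three_prime_end(g3)

  ## clamp at the next same-strand gene start
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  gchr <- as.character(GenomicRanges::seqnames(genes))
  gstr <- as.character(GenomicRanges::strand(genes))
  g5 <- ifelse(plus, GenomicRanges::start(genes), GenomicRanges::end(genes))
  clamped <- logical(length(genes))
  final <- e3
  for (i in seq_along(genes)) {
    same <- which(gchr == gchr[i] & gstr == gstr[i])
    same <- setdiff(same, i)
    if (!length(same)) next
    if (plus[i]) {
      nxt <- same[g5[same] > old_end3[i]]
      if (!length(nxt)) next
      lim <- min(g5[nxt]) - 1L
      if (final[i] > lim) { final[i] <- lim; clamped[i] <- TRUE }
    } else {
      nxt <- same[g5[same] < old_end3[i]]
      if (!length(nxt)) next
      lim <- max(g5[nxt]) + 1L
      if (final[i] < lim) { final[i] <- lim; clamped[i] <- TRUE }
    }
  }
  extended <- genes
  GenomicRanges::end(extended)[plus] <- final[plus]
  GenomicRanges::start(extended)[!plus] <- final[!plus]

  tier <- rep("none", length(genes))
  tier[final != old_end3 & final == e1] <- "isoseq"
  tier[final != old_end3 & e2 != e1 & final == e2] <- "flamseq"
  tier[final != old_end3 & e3 != e2 & final == e3] <- "coverage"
  tier[clamped] <- "clamped"

  frac_before <- frac_after <- NA_real_
  if (!is.null(reads)) {
    frac_before <- intergenic_read_fraction(reads, genes)
    frac_after <- intergenic_read_fraction(reads, extended)
  }
  structure(
    list(extended_genes = extended,
         report = data.frame(gene_id = genes$gene_id,
                             old_end3 = old_end3, new_end3 = final,
                             tier = tier, stringsAsFactors = FALSE),
         intergenic_fraction_before = frac_before,
         intergenic_fraction_after = frac_after),
    class = "extension_result"
  )
}

#' @method print extension_result
#' @export
print.extension_result <- function(x, ...) {
  cat("3' extension of", nrow(x$report), "genes\n")
  print(table(x$report$tier))
  if (!is.na(x$intergenic_fraction_before)) {
    cat(sprintf("Intergenic read fraction: %.4f -> %.4f\n",
                x$intergenic_fraction_before, x$intergenic_fraction_after))
  }
  invisible(x)
}

#' Fraction of reads overlapping no gene body
#'
#' Strand-agnostic: a read counts as intergenic only if it overlaps no gene
#' by any amount.
#'
#' @param reads `GRanges` of read intervals (must be nonempty)
#' @param genes `GRanges` of gene bodies
#' @return fraction in \[0, 1\]
#' @export
intergenic_read_fraction <- function(reads, genes) {
  if (!length(reads)) stop("reads must be nonempty")
  hits <- GenomicRanges::countOverlaps(reads, genes, ignore.strand = TRUE)
  mean(hits == 0)
}
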