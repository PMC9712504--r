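# 3'-extension operations: per-tier rules, tier combination, clamping,
# strand duality, truth recovery.

test_that("isoform extension takes the 3'-most assigned end, extension-only", {
  genes <- make_genes("chr1", c(500, 6000), c(1000, 9000), c("+", "-"))
  # + strand gene end=1000, isoform to 1500 -> new end 1500
  iso <- make_isoforms("chr1", 600, 1500, "+")
  out <- extend_by_isoforms(genes, iso)
  expect_equal(GenomicRanges::end(out)[1], 1500)
  # - strand gene start=6000 (3' end), isoform 3' end at 4200 -> new start 4200
  iso2 <- make_isoforms("chr1", 4200, 8000, "-")
  out2 <- extend_by_isoforms(genes, iso2)
  expect_equal(GenomicRanges::start(out2)[2], 4200)
  # isoform ending inside the gene leaves it unchanged
  iso3 <- make_isoforms("chr1", 600, 900, "+")
  out3 <- extend_by_isoforms(genes, iso3)
  expect_equal(GenomicRanges::end(out3)[1], 1000)
})

test_that("isoform assignment honors hints, overlap, and skips orphans", {
  genes <- make_genes("chr1", c(100, 3000), c(1000, 4000), c("+", "+"),
                      gene_id = c("gA", "gB"))
  # hint wins even without overlap
  iso <- make_isoforms("chr1", 5000, 6000, "+", hint = "gB")
  out <- extend_by_isoforms(genes, iso)
  expect_equal(GenomicRanges::end(out)[2], 6000)
  # overlap tie broken by largest overlap
  genes2 <- make_genes("chr1", c(100, 900), c(1000, 2000), c("+", "-"),
                      gene_id = c("gA", "gB"))
  iso2 <- make_isoforms("chr1", 800, 1200, "+")  # same strand as gA only
  out2 <- extend_by_isoforms(genes2, iso2)
  expect_equal(GenomicRanges::end(out2)[1], 1200)
  # no overlap, no hint -> skipped
  iso3 <- make_isoforms("chr2", 10, 20, "+")
  out3 <- extend_by_isoforms(genes, iso3)
  expect_equal(attr(out3, "n_skipped"), 1L)
  expect_equal(GenomicRanges::end(out3), GenomicRanges::end(genes))
})

test_that("cleavage sites go to the closest upstream gene within 60 kb", {
  g <- make_genes("chr1", 9000, 10000, "+", gene_id = "gA")
  asn <- assign_cleavage_sites(g, make_sites("chr1", 15000, "+"))
  expect_equal(asn$gene_id, "gA")
  expect_equal(asn$distance, 5000)
  # boundary: 60,000 accepted, 60,001 rejected
  expect_equal(assign_cleavage_sites(g, make_sites("chr1", 70000, "+"))$gene_id, "gA")
  expect_true(is.na(
    assign_cleavage_sites(g, make_sites("chr1", 70001, "+"))$gene_id
  ))
  expect_true(is.na(
    assign_cleavage_sites(g, make_sites("chr1", 70500, "+"))$gene_id
  ))
  # two candidates: nearest upstream wins (brute-force scan agrees)
  g2 <- make_genes("chr1", c(9000, 13000), c(10000, 14000), c("+", "+"),
                   gene_id = c("gA", "gB"))
  asn2 <- assign_cleavage_sites(g2, make_sites("chr1", 15000, "+"))
  expect_equal(asn2$gene_id, "gB")
  # minus strand mirror: gene 3' end = start
  g3 <- make_genes("chr1", 50000, 51000, "-", gene_id = "gC")
  asn3 <- assign_cleavage_sites(g3, make_sites("chr1", 45000, "-"))
  expect_equal(asn3$gene_id, "gC")
  expect_equal(asn3$distance, 5000)
})

test_that("cleavage extension takes the most distal site and never shortens", {
  g <- make_genes("chr1", 9000, 10000, "+", gene_id = "gA")
  sites <- make_sites("chr1", c(12000, 13500), c("+", "+"))
  out <- extend_by_cleavage(g, assign_cleavage_sites(g, sites))
  expect_equal(GenomicRanges::end(out), 13500)
  # a site upstream of the current end (inside the body) changes nothing
  out2 <- extend_by_cleavage(g, assign_cleavage_sites(g, make_sites("chr1", 9500, "+")))
  expect_equal(GenomicRanges::end(out2), 10000)
  # no assigned site: identity
  out3 <- extend_by_cleavage(g, assign_cleavage_sites(g, empty_gr()))
  expect_equal(GenomicRanges::end(out3), 10000)
})

test_that("coverage walk stops at the first sub-threshold base", {
  g <- make_genes("chr1", 50, 100, "+", gene_id = "gA")
  # depth 5 on (100, 220], depth 4 after -> new end 220
  cov <- make_coverage("chr1", c(101, 221), c(220, 400), c(5, 4))
  out <- extend_by_coverage(g, cov)
  expect_equal(GenomicRanges::end(out), 220)
  # depth 4 at the first downstream base: unchanged
  cov2 <- make_coverage("chr1", 101, 400, 4)
  expect_equal(GenomicRanges::end(extend_by_coverage(g, cov2)), 100)
  # flamseq-supported genes are not touched
  out3 <- extend_by_coverage(g, cov, flamseq_supported = "gA")
  expect_equal(GenomicRanges::end(out3), 100)
  # minus strand: walk decreases coordinates
  gm <- make_genes("chr1", 1000, 1500, "-", gene_id = "gM")
  covm <- make_coverage("chr1", c(700, 880), c(879, 999), c(4, 5))
  expect_equal(GenomicRanges::start(extend_by_coverage(gm, covm)), 880)
  # max_walk caps the advance
  out4 <- extend_by_coverage(g, cov, max_walk = 50)
  expect_equal(GenomicRanges::end(out4), 150)
})

test_that("the pipeline combines tiers extension-only and clamps collisions", {
  # isoseq end 1500 beats an assigned cleavage site at 1400
  g <- make_genes("chr1", c(100, 30000), c(1000, 31000), c("+", "+"),
                  gene_id = c("gA", "gB"))
  iso <- make_isoforms("chr1", 200, 1500, "+")
  sites <- make_sites("chr1", 1400, "+")
  res <- run_extension_pipeline(g, iso, sites, empty_gr())
  expect_equal(res$report$new_end3[1], 1500)
  expect_equal(res$report$tier[1], "isoseq")

  # cleavage extension overrunning the next same-strand gene start at 2000
  g2 <- make_genes("chr1", c(100, 2000), c(1000, 3000), c("+", "+"),
                   gene_id = c("gA", "gB"))
  res2 <- run_extension_pipeline(g2, empty_gr(), make_sites("chr1", 2500, "+"),
                                 empty_gr())
  expect_equal(res2$report$new_end3[1], 1999)
  expect_equal(res2$report$tier[1], "clamped")
  # clamp safety: no same-strand overlap afterwards
  expect_length(GenomicRanges::findOverlaps(res2$extended_genes,
                                            drop.self = TRUE), 0)

  # overlapping input genes are rejected
  gbad <- make_genes("chr1", c(100, 500), c(1000, 1500), c("+", "+"))
  expect_error(run_extension_pipeline(gbad, empty_gr(), empty_gr(), empty_gr()),
               "overlap")
})

test_that("the pipeline recovers every planted evidence-supported true end", {
  fx <- simulate_genome_fixture(genome_fixture_config(n_genes = 40, seed = 17))
  res <- run_extension_pipeline(fx$genes, fx$isoforms, fx$sites, fx$coverage,
                                reads = fx$reads)
  rep <- res$report[match(fx$truth$gene_id, res$report$gene_id), ]
  ev <- fx$truth$tier != "none"
  expect_equal(rep$new_end3[ev], fx$truth$true_end3[ev])
  expect_equal(rep$new_end3[!ev], fx$truth$annotated_end3[!ev])
  expect_equal(rep$tier[ev], fx$truth$tier[ev])
  expect_true(all(rep$tier[!ev] == "none"))
  # monotonicity: every gene's 3' extent grew or stayed
  plus <- fx$truth$strand == "+"
  expect_true(all((rep$new_end3 - rep$old_end3)[plus] >= 0))
  expect_true(all((rep$new_end3 - rep$old_end3)[!plus] <= 0))
  # intergenic fraction decreases when planted reads are annexed
  expect_lt(res$intergenic_fraction_after, res$intergenic_fraction_before)
})

test_that("strand duality: mirrored input gives mirrored output", {
  fx <- simulate_genome_fixture(genome_fixture_config(n_genes = 12, seed = 30))
  res <- run_extension_pipeline(fx$genes, fx$isoforms, fx$sites, fx$coverage)
  axis <- 2e6
  mg <- mirror_granges(fx$genes, axis)
  mi <- mirror_granges(fx$isoforms, axis)
  ms <- mirror_granges(fx$sites, axis)
  mc <- mirror_granges(fx$coverage, axis)
  mres <- run_extension_pipeline(mg, mi, ms, mc)
  # mirrored new 3' ends must be the mirror of the original new 3' ends
  expect_equal(mres$report$new_end3[match(res$report$gene_id,
                                          mres$report$gene_id)],
               axis - res$report$new_end3)
  expect_equal(mres$report$tier, res$report$tier)
})

test_that("intergenic_read_fraction counts zero-overlap reads, strand-agnostic", {
  genes <- make_genes("chr1", c(100, 500), c(200, 600), c("+", "-"))
  inside <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(c(150, 550, 190), width = 10))
  expect_equal(intergenic_read_fraction(inside, genes), 0)
  mixed <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(150, 550, 300, 900, 120, 130, 140, 160, 170, 180),
                             width = 10))
  expect_equal(intergenic_read_fraction(mixed, genes), 0.2)
  expect_error(intergenic_read_fraction(empty_gr(), genes), "nonempty")
})

test_that("round trip through GFF3/BED/bedGraph files preserves the pipeline result", {
  skip_if_not_installed("rtracklayer")
  fx <- simulate_genome_fixture(genome_fixture_config(n_genes = 8, seed = 12))
  dir <- withr::local_tempdir()
  write_genome_fixture(fx, dir)
  genes <- read_genes_gff3(file.path(dir, "genes.gff3"))
  isoforms <- read_bed(file.path(dir, "isoforms.bed"))
  sites <- read_bed(file.path(dir, "sites.bed"))
  cov <- read_bedgraph(file.path(dir, "coverage.bedGraph"))
  expect_equal(GenomicRanges::start(genes), GenomicRanges::start(fx$genes))
  expect_equal(GenomicRanges::end(genes), GenomicRanges::end(fx$genes))
  res_mem <- run_extension_pipeline(fx$genes, fx$isoforms, fx$sites, fx$coverage)
  res_file <- run_extension_pipeline(genes, isoforms, sites, cov)
  expect_equal(res_file$report$new_end3, res_mem$report$new_end3)
})
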