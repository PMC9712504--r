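# Readers and writers for the standard exchange formats. Genomic files go
# through rtracklayer, which converts BED/bedGraph half-open coordinates to
# the 1-based closed GRanges used everywhere inside the package.

#' Write a count matrix as MatrixMarket + gene/barcode TSVs
#'
#' @param counts genes x cells sparse matrix with dimnames
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`
#' @return `dir`, invisibly
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#' @return a `dgCMatrix`, genes x cells
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- as(m, "CsparseMatrix")
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  m
}

#' Write cell metadata as TSV
#' @param meta data.frame with barcode, batch, mito_fraction, ...
#' @param path output file
#' @return `path`, invisibly
#' @export
write_cell_meta <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cell metadata TSV
#' @param path file written by [write_cell_meta()]
#' @return data.frame
#' @export
read_cell_meta <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read gene models from GFF3
#'
#' Keeps `gene`-type records (or all records if none are typed `gene`) and
#' carries their `ID` as `gene_id`.
#'
#' @param path GFF3 file
#' @return `GRanges` with `gene_id`
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene")) {
    gr <- gr[gr$type == "gene"]
  }
  id <- S4Vectors::mcols(gr)$ID %||% S4Vectors::mcols(gr)$gene_id
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$gene_id <- as.character(id)
  out
}

#' Write gene models as GFF3
#' @param genes `GRanges` with `gene_id`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genes_gff3 <- function(genes, path) {
  out <- genes
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    source = "cephatlas", type = "gene", ID = genes$gene_id
  )
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read a BED6 file as stranded intervals
#'
#' The BED name field, when present and not ".", is kept as `gene_hint`
#' (used for isoform records).
#'
#' @param path BED file
#' @return `GRanges`
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)$name
  out <- GenomicRanges::granges(gr)
  if (!is.null(nm)) {
    hint <- as.character(nm)
    hint[hint == "." | hint == ""] <- NA_character_
    S4Vectors::mcols(out)$gene_hint <- hint
  }
  out
}

#' Write intervals as BED6
#' @param gr `GRanges`; an optional `gene_hint` column becomes the BED name
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bed <- function(gr, path) {
  out <- GenomicRanges::granges(gr)
  nm <- S4Vectors::mcols(gr)$gene_hint
  if (!is.null(nm)) {
    names(out) <- ifelse(is.na(nm), ".", nm)
  }
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' Read a bedGraph coverage track
#' @param path bedGraph file
#' @return `GRanges` with `score` (1-based closed coordinates)
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Write a coverage track as bedGraph
#' @param cov `GRanges` with `score`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(cov, path) {
  rtracklayer::export(cov, path, format = "bedGraph")
  invisible(path)
}

#' Write a full genome fixture to disk
#'
#' Writes `genes.gff3`, `isoforms.bed`, `sites.bed`, `coverage.bedGraph`,
#' `reads.bed` and `truth.tsv` into `dir`.
#'
#' @param fixture a [simulate_genome_fixture()] result
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_genome_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genes_gff3(fixture$genes, file.path(dir, "genes.gff3"))
  write_bed(fixture$isoforms, file.path(dir, "isoforms.bed"))
  write_bed(fixture$sites, file.path(dir, "sites.bed"))
  write_bedgraph(fixture$coverage, file.path(dir, "coverage.bedGraph"))
  write_bed(fixture$reads, file.path(dir, "reads.bed"))
  write.table(fixture$truth, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write an extension report and JSON summary
#'
#' @param result an `extension_result` from [run_extension_pipeline()]
#' @param dir output directory; writes `extended.gff3`, `report.tsv`,
#'   `summary.json`
#' @return `dir`, invisibly
#' @export
write_extension_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genes_gff3(result$extended_genes, file.path(dir, "extended.gff3"))
  write.table(result$report, file.path(dir, "report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_genes = nrow(result$report),
         tiers = as.list(table(result$report$tier)),
         intergenic_fraction_before = result$intergenic_fraction_before,
         intergenic_fraction_after = result$intergenic_fraction_after),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
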