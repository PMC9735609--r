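#' Deterministic TSV writer
#'
#' No quoting, no row names, fixed line endings, so identical inputs always
#' give byte-identical files.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a TSV written by [write_tsv_plain()]
#'
#' @param path File path.
#' @param ... Passed to [utils::read.delim()].
#' @return A data.frame.
#' @export
read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read a founder genotype table
#'
#' Expects a TSV with columns `snp_id`, `chrom`, `pos`, optionally `gene_id`,
#' and one single-nucleotide allele column per founder line. If `gene_id` is
#' absent, supply `genes` (a GRanges of gene models) so SNPs can be assigned
#' by position; a SNP overlapping more than one gene is an error.
#'
#' @param path TSV path.
#' @param genes Optional `GRanges` of gene models (from [read_gene_gff3()]).
#' @return A data.frame of SNP records.
#' @export
read_genotypes <- function(path, genes = NULL) {
  g <- read_tsv_plain(path)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(g)))
    stop("genotype table must have columns: ", paste(need, collapse = ", "))
  if (!"gene_id" %in% names(g)) {
    if (is.null(genes)) stop("genotype table lacks gene_id; supply gene models")
    g <- assign_snps_to_genes(g, genes)
  }
  g
}

#' Assign SNPs to genes by genomic position
#'
#' A SNP within the annotated span of exactly one gene is assigned to it;
#' SNPs overlapping more than one gene are rejected (counts would be
#' ambiguous), and SNPs in no gene are dropped.
#'
#' @param snps Data.frame with `chrom` and `pos` (1-based).
#' @param genes A `GRanges` with a `gene_id` metadata column.
#' @return `snps` with a `gene_id` column, intergenic SNPs removed.
#' @export
assign_snps_to_genes <- function(snps, genes) {
  gr <- GenomicRanges::GRanges(snps$chrom,
                               IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(gr, genes)
  qh <- S4Vectors::queryHits(hits)
  dup <- unique(qh[duplicated(qh)])
  if (length(dup) > 0L)
    stop("SNP(s) overlapping more than one gene: ",
         paste(utils::head(snps$snp_id[dup], 5), collapse = ", "))
  snps$gene_id <- NA_character_
  snps$gene_id[qh] <- genes$gene_id[S4Vectors::subjectHits(hits)]
  snps[!is.na(snps$gene_id), , drop = FALSE]
}

#' Read a per-sample SNP allele count table
#'
#' @param path TSV with columns `snp_id`, `allele`, `count`.
#' @return A data.frame.
#' @export
read_snp_counts <- function(path) {
  x <- read_tsv_plain(path)
  need <- c("snp_id", "allele", "count")
  if (!all(need %in% names(x)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  x
}

#' Write gene models from a truth table as GFF3
#'
#' @param truth A `truth_table` (or any data.frame with `gene_id`, `chrom`,
#'   `start`, `end`).
#' @param path Output path; coordinates are 1-based inclusive.
#' @return Invisibly, the path.
#' @export
write_gene_gff3 <- function(truth, path) {
  gr <- GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(truth$start, truth$end), strand = "+",
    type = "gene", ID = truth$gene_id, gene_id = truth$gene_id
  )
  names(gr) <- truth$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  # drop the run-date header so identical inputs give byte-identical files
  lines <- readLines(path)
  writeLines(lines[!startsWith(lines, "##date")], path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 path.
#' @return A `GRanges` of `type == "gene"` features with a `gene_id` column.
#' @export
read_gene_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (is.null(gr$gene_id)) gr$gene_id <- gr$ID
  gr
}

#' Write promoter sequences to FASTA
#'
#' @param sequences Named character vector, one promoter per gene.
#' @param path Output FASTA path.
#' @return Invisibly, the path.
#' @export
write_promoter_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_promoter_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- names(ss)
  out
}

#' Read an FPKM matrix
#'
#' @param path TSV with a `gene_id` column followed by one column per sample.
#' @return A numeric matrix, genes in rows.
#' @export
read_fpkm <- function(path) {
  x <- read_tsv_plain(path)
  m <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  rownames(m) <- x$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write imprinted-gene clusters as BED
#'
#' Converts 1-based inclusive cluster spans to BED's 0-based half-open
#' convention; the name field carries the member gene ids.
#'
#' @param clusters Output of [find_clusters()].
#' @param path Output BED path.
#' @return Invisibly, the path.
#' @export
write_clusters_bed <- function(clusters, path) {
  if (nrow(clusters) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = clusters$chrom,
    start = clusters$start - 1L,
    end = clusters$end,
    name = vapply(clusters$member_gene_ids, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
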