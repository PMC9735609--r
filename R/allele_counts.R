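#' Select SNPs informative for one cross
#'
#' In a triparental design, a SNP assigns a read unambiguously to a parental
#' genome only when every maternal founder carries one allele, every paternal
#' founder carries one allele, and the two differ — e.g. a site identical in
#' B73 and Mo17 but different in CAU5 is informative for the (B73 x Mo17) x
#' CAU5 cross. Informativeness is symmetric under reversing the cross
#' direction.
#'
#' @param snps Data.frame of SNP records with `snp_id`, `gene_id`, and one
#'   allele column per founder.
#' @param cross A `cross_spec`.
#' @return The informative subset of `snps`, input order preserved, with
#'   `maternal_allele` and `paternal_allele` columns appended.
#' @export
informative_snps <- function(snps, cross) {
  stopifnot(inherits(cross, "cross_spec"))
  founders <- c(cross$maternal, cross$paternal)
  missing <- setdiff(founders, names(snps))
  if (length(missing) > 0L)
    stop("founder column(s) absent from SNP table: ",
         paste(missing, collapse = ", "))
  for (f in founders) {
    bad <- !(snps[[f]] %in% c("A", "C", "G", "T"))
    if (any(bad))
      stop("non-nucleotide allele for founder ", f, " at SNP ",
           snps$snp_id[which(bad)[1]])
  }
  mat <- as.matrix(snps[, cross$maternal, drop = FALSE])
  pat <- as.matrix(snps[, cross$paternal, drop = FALSE])
  m_allele <- mat[, 1]
  p_allele <- pat[, 1]
  keep <- rowSums(mat != m_allele) == 0L &
          rowSums(pat != p_allele) == 0L &
          m_allele != p_allele
  out <- snps[keep, , drop = FALSE]
  out$maternal_allele <- m_allele[keep]
  out$paternal_allele <- p_allele[keep]
  out
}

#' Partition per-SNP allele counts into maternal and paternal reads
#'
#' Reads carrying the maternal-side allele of an informative SNP are booked
#' maternal, reads carrying the paternal-side allele paternal; reads carrying
#' any third allele (sequencing error or residual heterozygosity) are dropped
#' and tallied. Counts at SNPs not in the informative set are skipped and
#' tallied separately.
#'
#' @param snp_counts Data.frame with `snp_id`, `allele`, `count`.
#' @param info Informative SNP table from [informative_snps()].
#' @return A list: `counts` (data.frame `snp_id`, `gene_id`,
#'   `maternal`, `paternal`), `discarded_reads` (third-allele reads),
#'   `skipped_snps` (count rows at non-informative SNPs).
#' @export
assign_reads <- function(snp_counts, info) {
  stopifnot(all(c("snp_id", "allele", "count") %in% names(snp_counts)))
  known <- snp_counts$snp_id %in% info$snp_id
  skipped <- sum(!known)
  if (skipped > 0L)
    warning(skipped, " count row(s) at SNPs outside the informative set were skipped")
  sc <- snp_counts[known, , drop = FALSE]
  idx <- match(sc$snp_id, info$snp_id)
  is_m <- sc$allele == info$maternal_allele[idx]
  is_p <- sc$allele == info$paternal_allele[idx]
  discarded <- sum(sc$count[!is_m & !is_p])
  m <- tapply(sc$count * is_m, sc$snp_id, sum)
  p <- tapply(sc$count * is_p, sc$snp_id, sum)
  # every informative SNP is reported, including those with zero coverage
  counts <- data.frame(
    snp_id = info$snp_id,
    gene_id = info$gene_id,
    maternal = as.integer(ifelse(is.na(m[info$snp_id]), 0L, m[info$snp_id])),
    paternal = as.integer(ifelse(is.na(p[info$snp_id]), 0L, p[info$snp_id])),
    stringsAsFactors = FALSE
  )
  list(counts = counts, discarded_reads = discarded, skipped_snps = skipped)
}

#' Sum SNP-level parental counts to per-gene totals
#'
#' One row per gene with the number of informative SNPs recorded; genes with
#' zero informative SNPs do not appear (their parental origin cannot be read).
#'
#' @param assigned `counts` element of [assign_reads()] output.
#' @param sample_id Sample label attached to every row.
#' @return A data.frame of per-gene allele counts: `gene_id`, `sample_id`,
#'   `maternal_reads`, `paternal_reads`, `n_informative_snps`.
#' @export
aggregate_gene <- function(assigned, sample_id) {
  if (nrow(assigned) == 0L)
    return(data.frame(gene_id = character(0), sample_id = character(0),
                      maternal_reads = integer(0), paternal_reads = integer(0),
                      n_informative_snps = integer(0)))
  sp <- split(assigned, assigned$gene_id)
  out <- data.frame(
    gene_id = names(sp),
    sample_id = sample_id,
    maternal_reads = vapply(sp, function(d) sum(d$maternal), 0L),
    paternal_reads = vapply(sp, function(d) sum(d$paternal), 0L),
    n_informative_snps = vapply(sp, nrow, 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$gene_id), , drop = FALSE]
}

#' SNP counts to per-gene allele counts, one sample
#'
#' Convenience wrapper chaining [informative_snps()], [assign_reads()] and
#' [aggregate_gene()].
#'
#' @param snp_counts Per-SNP allele counts (`snp_id`, `allele`, `count`).
#' @param snps Founder genotype table.
#' @param cross The `cross_spec` the sample was drawn from.
#' @return Per-gene count data.frame (see [aggregate_gene()]), with the
#'   discard/skip tallies attached as attributes `discarded_reads` and
#'   `skipped_snps`.
#' @export
count_gene_alleles <- function(snp_counts, snps, cross) {
  info <- informative_snps(snps, cross)
  a <- assign_reads(snp_counts, info)
  out <- aggregate_gene(a$counts, cross$sample_id)
  attr(out, "discarded_reads") <- a$discarded_reads
  attr(out, "skipped_snps") <- a$skipped_snps
  out
}
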