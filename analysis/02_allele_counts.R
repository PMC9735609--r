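#!/usr/bin/env Rscript
# From founder genotypes and per-SNP allele counts to per-gene maternal and
# paternal read totals: select the SNPs informative for each cross (one
# allele per parental side, differing), split the reads by allele, and sum
# over each gene's informative SNPs.

suppressMessages(library(imprintr))

fixdir <- "results/fixture"
samples <- read_tsv_plain(file.path(fixdir, "samples.tsv"))
geno <- read_genotypes(file.path(fixdir, "genotypes.tsv"))

design <- default_cross_design()
counts <- list()
for (cs in design) {
  sc <- read_snp_counts(file.path(fixdir, "counts", paste0(cs$sample_id, ".tsv")))
  gc <- count_gene_alleles(sc, geno, cs)
  cat(sprintf("%-18s %5d genes, %8d reads assigned, %d discarded\n",
              cs$sample_id, nrow(gc),
              sum(gc$maternal_reads + gc$paternal_reads),
              attr(gc, "discarded_reads")))
  counts[[cs$sample_id]] <- gc
}
counts <- do.call(rbind, counts)
write_tsv_plain(counts, "results/gene_allele_counts.tsv")
cat("per-gene allele counts written to results/gene_allele_counts.tsv\n")
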