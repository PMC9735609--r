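#!/usr/bin/env Rscript
# Conservation of imprinting across cross pairs: assign the set memberships
# comparing each F1-hybrid pair against the biparental reference (sets I-VI
# for the Mo17-added group, VII-XII for B73-added), derive conserved /
# non-conserved gene lists, intersect the two groups, detect 1-Mb
# imprinted-gene clusters, and summarise chromosomes. The simulator imprints
# genes in every cross, so genuine truth-imprinted genes land in the
# conserved sets; non-conserved genes here arise only from sampling noise.

suppressMessages(library(imprintr))

calls <- read_tsv_plain("results/imprint_calls.tsv")
mo17 <- assign_sets(calls, "Mo17-added")
b73 <- assign_sets(calls, "B73-added")
write_tsv_plain(rbind(mo17, b73), "results/conservation_sets.tsv")

for (a in list(mo17, b73))
  cat(sprintf("%s group: %d conserved, %d non-conserved, %d unclassified\n",
              a$group[1], sum(a$label == "conserved"),
              sum(a$label == "non_conserved"),
              sum(a$label == "unclassified")))
ov <- overlap_groups(mo17, b73)
cat(sprintf("conserved overlap between groups: %d genes (%.0f%% of Mo17-added)\n",
            ov$conserved$n_overlap, 100 * ov$conserved$fraction_of_mo17))

# clusters of imprinted genes within 1 Mb, per tissue
genes <- read_gene_gff3("results/fixture/genes.gff3")
coords <- data.frame(gene_id = genes$gene_id,
                     chrom = as.character(GenomicRanges::seqnames(genes)),
                     start = GenomicRanges::start(genes),
                     end = GenomicRanges::end(genes))
for (ti in c("embryo", "endosperm")) {
  ids <- unique(calls$gene_id[calls$status %in% c("MEG", "PEG") &
                                calls$tissue == ti])
  cl <- find_clusters(coords[coords$gene_id %in% ids, ])
  write_clusters_bed(cl, sprintf("results/clusters_%s.bed", ti))
  cat(sprintf("%s: %d imprinted genes, %d cluster(s) of >= 2 within 1 Mb\n",
              ti, length(ids), nrow(cl)))
}

s <- summarize_chromosomes(calls, coords)
top <- stats::aggregate(n_genes ~ chrom, data = s$by_chromosome, FUN = sum)
top <- top[order(-top$n_genes), ]
cat("chromosome with most imprinted genes:", top$chrom[1],
    "(", top$n_genes[1], ")\n")
write_tsv_plain(s$by_chromosome, "results/imprinted_by_chromosome.tsv")
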