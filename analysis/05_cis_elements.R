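#!/usr/bin/env Rscript
# Scan the 1.5-kb promoters for the 13 cis-regulatory element classes
# (hormone / light / stress responsive) and compare element presence ratios
# between the conserved and non-conserved gene groups.

suppressMessages(library(imprintr))

promoters <- read_promoter_fasta("results/fixture/promoters.fa")
hits <- scan_promoters(promoters)
write_tsv_plain(hits, "results/motif_hits.tsv")
cat(nrow(hits), "motif hits across", length(promoters), "promoters\n")

sets <- read_tsv_plain("results/conservation_sets.tsv")
mo17 <- sets[sets$group == "Mo17-added", ]
groups <- list(conserved = mo17$gene_id[mo17$label == "conserved"],
               non_conserved = mo17$gene_id[mo17$label == "non_conserved"])
prof <- group_profile(hits, groups, scanned_genes = names(promoters))
write_tsv_plain(prof$ratios, "results/motif_group_ratios.tsv")
write_tsv_plain(prof$classes_per_gene, "results/motif_classes_per_gene.tsv")

r <- prof$ratios[prof$ratios$group == "conserved", ]
cat("element presence in the conserved group (fraction of genes):\n")
print(r[order(-r$ratio), c("motif_name", "ratio")], row.names = FALSE)
cat(sprintf("distinct element classes per gene: median %d (range %d-%d)\n",
            stats::median(prof$classes_per_gene$n_element_classes),
            min(prof$classes_per_gene$n_element_classes),
            max(prof$classes_per_gene$n_element_classes)))
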