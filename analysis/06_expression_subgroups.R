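#!/usr/bin/env Rscript
# Partition the imprinted genes into endosperm-primary and constitutive
# expression subgroups: FPKM is normalised to each gene's maximum over all
# samples, rows are clustered by average-linkage / Euclidean hierarchical
# clustering, and the cluster with the largest endosperm-vs-rest margin of
# mean relative expression is the endosperm-primary subgroup. Accuracy is
# checked against the generator's planted profiles.

suppressMessages(library(imprintr))

fpkm <- read_fpkm("results/fixture/fpkm.tsv")
samples <- read_tsv_plain("results/fixture/samples.tsv")
calls <- read_tsv_plain("results/imprint_calls.tsv")

imp <- sort(unique(calls$gene_id[calls$status %in% c("MEG", "PEG")]))
rel <- relative_expression(fpkm[imp, , drop = FALSE])
sg <- cluster_subgroups(rel, samples$tissue[match(colnames(rel),
                                                  samples$sample_id)])
write_tsv_plain(sg, "results/expression_subgroups.tsv")
print(table(sg$subgroup))

manifest <- jsonlite::read_json("results/fixture/truth.json",
                                simplifyVector = TRUE)
planted <- manifest$subgroup_truth
acc <- mean(sg$subgroup ==
              planted$subgroup[match(sg$gene_id, planted$gene_id)])
cat(sprintf("agreement with planted subgroups: %.1f%% of %d imprinted genes\n",
            100 * acc, nrow(sg)))
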