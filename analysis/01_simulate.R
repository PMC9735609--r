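#!/usr/bin/env Rscript
# Simulate the study design: four reciprocal cross pairs (BC/CB, MC/CM,
# BM-C/C-BM, MB-C/C-MB) sampled in embryo and endosperm, 1,000 genes with
# 5% MEGs, 5% PEGs, 5% low-coverage (untestable) genes, merged-replicate
# depth ~100 reads per gene, and writes the fixture files every later step
# consumes. Rerunning with the same seed reproduces every file byte for byte.

suppressMessages(library(imprintr))

outdir <- "results/fixture"
cfg <- sim_config(n_genes = 1000, depth_mean = 100, seed = 20220915L)
fixture <- simulate_fixture(cfg, default_cross_design())
paths <- emit_fixture_files(fixture, outdir)

truth_tab <- table(fixture$truth$true_status)
cat("simulated", cfg$n_genes, "genes on", cfg$n_chromosomes, "chromosomes:\n")
print(truth_tab)
cat("samples:", length(paths$counts), "count tables under",
    file.path(outdir, "counts"), "\n")
cat("fixture written to", outdir, "(truth manifest: truth.json)\n")
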