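# Small shared builders for tests.

# one reciprocal pair (B73 x CAU5) in both tissues
bc_pair_design <- function(tissues = c("embryo", "endosperm")) {
  design <- list()
  for (ti in tissues) {
    design[[length(design) + 1]] <- cross_spec("BC", "B73", "CAU5", ti, "BC/CB")
    design[[length(design) + 1]] <- cross_spec("CB", "CAU5", "B73", ti, "BC/CB")
  }
  design
}

# hand-built SNP table covering the informativeness patterns
example_snps <- function() {
  data.frame(
    snp_id = paste0("s", 1:4),
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    gene_id = c("g1", "g1", "g2", "g2"),
    B73  = c("A", "A", "A", "A"),
    Mo17 = c("A", "G", "A", "C"),
    CAU5 = c("G", "G", "A", "C"),
    stringsAsFactors = FALSE
  )
}

# build a calls table row-by-row for the conservation set algebra
make_calls <- function(gene_id, cross_pair, status, tissue = "endosperm") {
  data.frame(gene_id = gene_id, cross_pair = cross_pair, tissue = tissue,
             status = status, stringsAsFactors = FALSE)
}

triparental_pairs <- c("BM-C/C-BM", "MB-C/C-MB")
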