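#' Run the full imprinting analysis end to end
#'
#' Generates (or reuses) a seeded fixture on disk, then runs the whole
#' analysis from the emitted files exactly as a user would: reads founder
#' genotypes, per-sample SNP counts, gene models, promoters and FPKM; builds
#' per-gene allele counts; calls MEGs/PEGs per reciprocal pair; assigns
#' conservation sets for both comparison groups; detects 1-Mb imprinted-gene
#' clusters per tissue; scans promoters for cis elements; and partitions
#' imprinted genes into expression subgroups. All result tables are written
#' as TSV/BED/JSON under `file.path(outdir, "results")`.
#'
#' Given the same `config` (including seed) two runs produce byte-identical
#' fixture and result files.
#'
#' @param outdir Working directory for fixture and results.
#' @param config A `sim_config`.
#' @param design A list of `cross_spec`.
#' @param cfg A `caller_config`.
#' @param swap_roles Passed to the simulator (see [simulate_counts()]).
#' @return Invisibly, a list with the in-memory results and the paths of all
#'   written files.
#' @export
run_imprinting_pipeline <- function(outdir,
                                    config = sim_config(),
                                    design = default_cross_design(),
                                    cfg = caller_config(),
                                    swap_roles = FALSE) {
  fixture <- simulate_fixture(config, design, swap_roles = swap_roles)
  paths <- emit_fixture_files(fixture, outdir)

  # --- read everything back from disk: the files are the interface
  genes_gr <- read_gene_gff3(paths$gff)
  geno <- read_genotypes(paths$genotypes)
  counts <- do.call(rbind, lapply(design, function(cs) {
    sc <- read_snp_counts(paths$counts[[cs$sample_id]])
    count_gene_alleles(sc, geno, cs)
  }))

  calls <- call_all(counts, design, cfg)

  mo17 <- assign_sets(calls$calls, "Mo17-added")
  b73 <- assign_sets(calls$calls, "B73-added")
  overlap <- overlap_groups(mo17, b73)

  gene_coords <- data.frame(gene_id = genes_gr$gene_id,
                            chrom = as.character(GenomicRanges::seqnames(genes_gr)),
                            start = GenomicRanges::start(genes_gr),
                            end = GenomicRanges::end(genes_gr),
                            stringsAsFactors = FALSE)
  imprinted <- unique(calls$calls[calls$calls$status %in% c("MEG", "PEG"),
                                  c("gene_id", "tissue")])
  clusters <- list()
  for (ti in unique(imprinted$tissue)) {
    g <- gene_coords[gene_coords$gene_id %in%
                       imprinted$gene_id[imprinted$tissue == ti], , drop = FALSE]
    clusters[[ti]] <- find_clusters(g)
  }
  chrom_summary <- summarize_chromosomes(calls$calls, gene_coords)

  promoters <- read_promoter_fasta(paths$promoters)
  hits <- scan_promoters(promoters)
  profile <- group_profile(
    hits,
    groups = list(conserved = mo17$gene_id[mo17$label == "conserved"],
                  non_conserved = mo17$gene_id[mo17$label == "non_conserved"]),
    scanned_genes = names(promoters)
  )

  fpkm <- read_fpkm(paths$fpkm)
  samples <- read_tsv_plain(paths$samples)
  imp_genes <- sort(unique(imprinted$gene_id))
  subgroups <- if (length(imp_genes) >= 2L) {
    rel <- relative_expression(fpkm[imp_genes, , drop = FALSE])
    cluster_subgroups(rel, samples$tissue[match(colnames(rel),
                                                samples$sample_id)])
  } else {
    data.frame(gene_id = character(0), cluster = integer(0),
               subgroup = character(0))
  }

  # --- write result tables
  rdir <- file.path(outdir, "results")
  dir.create(rdir, showWarnings = FALSE)
  out_paths <- list(
    counts = file.path(rdir, "gene_allele_counts.tsv"),
    calls = file.path(rdir, "imprint_calls.tsv"),
    sets = file.path(rdir, "conservation_sets.tsv"),
    hits = file.path(rdir, "motif_hits.tsv"),
    profile = file.path(rdir, "motif_group_ratios.tsv"),
    subgroups = file.path(rdir, "expression_subgroups.tsv"),
    summary = file.path(rdir, "summary.json")
  )
  write_tsv_plain(counts, out_paths$counts)
  write_tsv_plain(calls$calls, out_paths$calls)
  write_tsv_plain(rbind(mo17, b73), out_paths$sets)
  write_tsv_plain(hits, out_paths$hits)
  write_tsv_plain(profile$ratios, out_paths$profile)
  write_tsv_plain(subgroups, out_paths$subgroups)
  for (ti in names(clusters)) {
    out_paths[[paste0("clusters_", ti)]] <-
      file.path(rdir, paste0("clusters_", ti, ".bed"))
    write_clusters_bed(clusters[[ti]], out_paths[[paste0("clusters_", ti)]])
  }
  jsonlite::write_json(
    list(call_summary = calls$summary,
         by_chromosome = chrom_summary$by_chromosome,
         overlap = list(
           conserved_n = overlap$conserved$n_overlap,
           non_conserved_n = overlap$non_conserved$n_overlap)),
    out_paths$summary, dataframe = "columns", auto_unbox = TRUE, digits = NA)

  invisible(list(
    fixture = fixture, counts = counts, calls = calls,
    conservation = list(mo17 = mo17, b73 = b73, overlap = overlap),
    clusters = clusters, chrom_summary = chrom_summary,
    motif_hits = hits, motif_profile = profile, subgroups = subgroups,
    fixture_paths = paths, result_paths = out_paths
  ))
}
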