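#' Simulation configuration
#'
#' Parameters for the synthetic-data generator. Imprinted genes are simulated
#' with a true maternal transcript fraction `theta` per tissue; biallelic genes
#' are pinned to the dosage null (1/2 in embryo, 2/3 in triploid endosperm).
#' Untestable genes receive total allelic depth below the minimum-read rule so
#' that the caller's >=20-read filter is exercised.
#'
#' @param n_genes Number of genes.
#' @param n_chromosomes Number of chromosomes genes are placed on.
#' @param snps_per_gene Poisson mean of the per-gene SNP count.
#' @param frac_meg,frac_peg,frac_untestable Proportions of genes that are
#'   truly MEG, PEG, and untestable (low coverage); must sum to <= 1, the
#'   remainder is biallelic.
#' @param theta_meg_embryo,theta_peg_embryo True maternal fraction of MEGs and
#'   PEGs in embryo.
#' @param theta_meg_endo,theta_peg_endo True maternal fraction of MEGs and
#'   PEGs in endosperm.
#' @param depth_mean Mean total allelic read depth per gene per sample
#'   (after merging replicates).
#' @param overdispersion Beta-binomial intraclass correlation rho in [0, 1);
#'   0 gives plain binomial counts.
#' @param replicates Biological replicates simulated i.i.d. per sample and
#'   summed before calling, mirroring the merge-then-test convention.
#' @param untestable_depth_mean Mean depth of untestable genes (draws are
#'   truncated below `min_reads`).
#' @param min_reads Read threshold the untestable genes must stay under.
#' @param founders Founder line names; the first two form the F1 hybrid
#'   group, the third is the added tester line.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       n_chromosomes = 10L,
                       snps_per_gene = 3,
                       frac_meg = 0.05,
                       frac_peg = 0.05,
                       frac_untestable = 0.05,
                       theta_meg_embryo = 0.95,
                       theta_peg_embryo = 0.05,
                       theta_meg_endo = 0.95,
                       theta_peg_endo = 0.20,
                       depth_mean = 100,
                       overdispersion = 0,
                       replicates = 3L,
                       untestable_depth_mean = 8,
                       min_reads = 20L,
                       founders = c("B73", "Mo17", "CAU5"),
                       seed = 1L) {
  fr <- c(frac_meg, frac_peg, frac_untestable)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("frac_meg, frac_peg, frac_untestable must lie in [0,1] and sum to <= 1")
  th <- c(theta_meg_embryo, theta_peg_embryo, theta_meg_endo, theta_peg_endo)
  if (any(th <= 0) || any(th >= 1)) stop("all theta values must lie in (0,1)")
  if (overdispersion < 0 || overdispersion >= 1) stop("overdispersion must lie in [0,1)")
  if (n_genes < 1 || n_chromosomes < 1) stop("n_genes and n_chromosomes must be positive")
  if (snps_per_gene < 0) stop("snps_per_gene must be >= 0")
  if (length(founders) != 3L) stop("exactly three founder names are required")
  structure(list(
    n_genes = as.integer(n_genes), n_chromosomes = as.integer(n_chromosomes),
    snps_per_gene = snps_per_gene,
    frac_meg = frac_meg, frac_peg = frac_peg, frac_untestable = frac_untestable,
    theta_meg_embryo = theta_meg_embryo, theta_peg_embryo = theta_peg_embryo,
    theta_meg_endo = theta_meg_endo, theta_peg_endo = theta_peg_endo,
    depth_mean = depth_mean, overdispersion = overdispersion,
    replicates = as.integer(replicates),
    untestable_depth_mean = untestable_depth_mean,
    min_reads = as.integer(min_reads),
    founders = as.character(founders),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate the ground-truth gene table
#'
#' Assigns each gene an imprinting status (MEG, PEG, biallelic, untestable),
#' non-overlapping 1-based coordinates on `n_chromosomes` chromosomes, and
#' true maternal fractions per tissue. Biallelic and untestable genes carry
#' the dosage-null fractions exactly (1/2 embryo, 2/3 endosperm).
#'
#' @param config A `sim_config`.
#' @return A data.frame (class `truth_table`) with columns `gene_id`,
#'   `true_status`, `chrom`, `start`, `end`, `theta_embryo`,
#'   `theta_endosperm`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  status <- sample(
    c("MEG", "PEG", "untestable", "biallelic"), n, replace = TRUE,
    prob = c(config$frac_meg, config$frac_peg, config$frac_untestable,
             1 - config$frac_meg - config$frac_peg - config$frac_untestable)
  )
  gene_id <- sprintf("gene%04d", seq_len(n))
  chrom <- paste0("chr", 1L + (seq_len(n) - 1L) %% config$n_chromosomes)
  # lay genes out left to right per chromosome with random intergenic gaps,
  # so spans never overlap
  width <- sample(2000:5000, n, replace = TRUE)
  gap <- sample(20000:120000, n, replace = TRUE)
  start <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- cumsum(gap[i]) + c(0L, cumsum(width[i])[-length(i)])
  }
  theta_e <- ifelse(status == "MEG", config$theta_meg_embryo,
             ifelse(status == "PEG", config$theta_peg_embryo, 1 / 2))
  theta_n <- ifelse(status == "MEG", config$theta_meg_endo,
             ifelse(status == "PEG", config$theta_peg_endo, 2 / 3))
  out <- data.frame(
    gene_id = gene_id, true_status = status, chrom = chrom,
    start = start, end = start + width - 1L,
    theta_embryo = theta_e, theta_endosperm = theta_n,
    stringsAsFactors = FALSE
  )
  class(out) <- c("truth_table", "data.frame")
  out
}

# beta-binomial draws with intraclass correlation rho; rho = 0 is binomial
rbetabinom <- function(n, size, prob, rho) {
  if (rho == 0) return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, a, b))
}

# maternal fraction after exchanging parental roles: embryo is a plain
# complement; in endosperm the 2:1 genome dosage re-applies to the swapped
# per-copy rates, giving 4(1-theta)/(4-3theta) (fixed point at 2/3)
swap_theta <- function(theta, tissue) {
  if (tissue == "embryo") 1 - theta else 4 * (1 - theta) / (4 - 3 * theta)
}

#' Simulate per-gene allele counts for a cross design
#'
#' For every gene and every cross direction/tissue in `design`, draws a total
#' allelic depth (sum of `replicates` i.i.d. Poisson replicate depths, merged)
#' and splits it into maternal and paternal reads with a beta-binomial around
#' the gene's true maternal fraction for that tissue. Untestable genes get
#' depth truncated below `min_reads`. Within a reciprocal pair the maternal
#' fraction is parent-of-origin anchored, so the same founder's allele is
#' counted maternal in one direction and paternal in the other.
#'
#' @param truth A `truth_table` from [generate_truth()].
#' @param design A list of `cross_spec` objects.
#' @param config The `sim_config` used for `truth`.
#' @param swap_roles If `TRUE`, maternal and paternal roles are exchanged in
#'   every direction (a labelling swap): simulated maternal fractions become
#'   `1 - theta` in embryo and the dosage-adjusted complement in endosperm, so
#'   true MEGs present as PEGs.
#' @return A data.frame with columns `gene_id`, `sample_id`,
#'   `maternal_reads`, `paternal_reads`, `n_informative_snps` (NA here; filled
#'   by the SNP-level fixture path).
#' @export
simulate_counts <- function(truth, design, config, swap_roles = FALSE) {
  stopifnot(inherits(truth, "truth_table"))
  for (cs in design) {
    if (!inherits(cs, "cross_spec")) stop("design must be a list of cross_spec objects")
    if (!cs$tissue %in% c("embryo", "endosperm"))
      stop("unknown tissue: ", cs$tissue)
  }
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  res <- vector("list", length(design))
  for (k in seq_along(design)) {
    cs <- design[[k]]
    theta <- if (cs$tissue == "embryo") truth$theta_embryo else truth$theta_endosperm
    if (swap_roles) theta <- swap_theta(theta, cs$tissue)
    # replicate depths are drawn i.i.d. and merged before testing
    depth <- rowSums(matrix(
      rpois(n * config$replicates, config$depth_mean / config$replicates),
      nrow = n))
    low <- truth$true_status == "untestable"
    if (any(low)) {
      d <- rpois(sum(low), config$untestable_depth_mean)
      depth[low] <- pmin(d, config$min_reads - 1L)
    }
    m <- rbetabinom(n, depth, theta, config$overdispersion)
    res[[k]] <- data.frame(
      gene_id = truth$gene_id, sample_id = cs$sample_id,
      maternal_reads = m, paternal_reads = depth - m,
      n_informative_snps = NA_integer_, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, res)
}

#' Simulate founder genotypes at SNPs within genes
#'
#' Draws per-gene SNP counts from a Poisson with mean `snps_per_gene` and
#' assigns founder alleles by pattern: most SNPs share one allele in the two
#' hybrid founders and differ in the tester line (informative for every cross
#' here), with a minority of monomorphic or partially informative patterns.
#' Every gene is guaranteed at least one universally informative SNP so that
#' SNP-level fixtures cover all genes.
#'
#' @param truth A `truth_table`.
#' @param config The matching `sim_config`.
#' @return A data.frame with columns `snp_id`, `chrom`, `pos`, `gene_id`, and
#'   one allele column per founder.
#' @export
simulate_snps <- function(truth, config) {
  stopifnot(inherits(truth, "truth_table"))
  set.seed(config$seed + 2L)
  f <- config$founders
  nt <- c("A", "C", "G", "T")
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    n_snp <- max(1L, rpois(1, config$snps_per_gene))
    pat <- sample(c("universal", "monomorphic", "hyb_split1", "hyb_split2"),
                  n_snp, replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1))
    pat[1L] <- "universal"  # guarantee coverage of the gene
    pos <- sort(sample(truth$start[i]:truth$end[i], n_snp))
    al <- matrix("", n_snp, 3L, dimnames = list(NULL, f))
    for (j in seq_len(n_snp)) {
      ab <- sample(nt, 2L)
      al[j, ] <- switch(pat[j],
        universal   = c(ab[1], ab[1], ab[2]),  # hybrid founders same, tester differs
        monomorphic = rep(ab[1], 3L),
        hyb_split1  = c(ab[1], ab[2], ab[2]),  # first hybrid founder differs
        hyb_split2  = c(ab[2], ab[1], ab[2]))  # second hybrid founder differs
    }
    rows[[i]] <- data.frame(
      snp_id = sprintf("%s_snp%02d", truth$gene_id[i], seq_len(n_snp)),
      chrom = truth$chrom[i], pos = pos, gene_id = truth$gene_id[i],
      al, stringsAsFactors = FALSE, check.names = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Distribute per-gene allele totals over informative SNP sites
#'
#' Converts gene-level maternal/paternal totals for one sample into per-SNP
#' allele counts: each gene's maternal reads are split multinomially across
#' its informative SNPs and booked under each SNP's maternal-side allele
#' (likewise paternal). Aggregating the result recovers the gene totals
#' exactly for genes with at least one informative SNP.
#'
#' @param gene_counts Rows of the [simulate_counts()] output for one sample.
#' @param snps Founder genotype table from [simulate_snps()].
#' @param cross The `cross_spec` the sample belongs to.
#' @return A data.frame with columns `snp_id`, `allele`, `count`.
#' @export
snp_level_counts <- function(gene_counts, snps, cross) {
  info <- informative_snps(snps, cross)
  out <- vector("list", nrow(gene_counts))
  for (i in seq_len(nrow(gene_counts))) {
    s <- info[info$gene_id == gene_counts$gene_id[i], , drop = FALSE]
    if (nrow(s) == 0L) next
    msplit <- as.vector(rmultinom(1, gene_counts$maternal_reads[i],
                                  rep(1, nrow(s))))
    psplit <- as.vector(rmultinom(1, gene_counts$paternal_reads[i],
                                  rep(1, nrow(s))))
    out[[i]] <- data.frame(
      snp_id = rep(s$snp_id, 2L),
      allele = c(s$maternal_allele, s$paternal_allele),
      count = c(msplit, psplit), stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- stats::aggregate(count ~ snp_id + allele, data = res, FUN = sum)
  res[order(res$snp_id, res$allele), , drop = FALSE]
}

#' Simulate promoter sequences with planted motif instances
#'
#' Promoters are i.i.d. uniform A/C/G/T of length `promoter_length`; for each
#' gene 1-3 motifs from `motifs` are overwritten at random offsets on the
#' forward strand and recorded. Background (chance) motif occurrences are
#' possible and allowed; tests assert only that planted instances are found.
#'
#' @param truth A `truth_table`.
#' @param config The matching `sim_config`.
#' @param motifs A motif definition table, see [default_motifs()].
#' @param promoter_length Promoter length in bp (1.5 kb upstream of ATG).
#' @return A list with `sequences` (named character vector per gene) and
#'   `planted` (data.frame `gene_id`, `motif_name`, `offset` 0-based,
#'   `strand`).
#' @export
simulate_promoters <- function(truth, config, motifs = default_motifs(),
                               promoter_length = 1500L) {
  set.seed(config$seed + 3L)
  nt <- c("A", "C", "G", "T")
  seqs <- character(nrow(truth))
  planted <- list()
  for (i in seq_len(nrow(truth))) {
    s <- sample(nt, promoter_length, replace = TRUE)
    k <- sample(1:3, 1)
    picks <- sample(nrow(motifs), k)
    used <- logical(promoter_length)  # planted windows must not overwrite
    for (j in picks) {
      cons <- strsplit(motifs$consensus[j], "")[[1]]
      # resolve IUPAC ambiguity codes to a concrete planted instance
      inst <- vapply(cons, function(code) sample(iupac_bases(code), 1), "")
      repeat {
        off <- sample.int(promoter_length - length(inst) + 1L, 1) - 1L  # 0-based
        if (!any(used[(off + 1):(off + length(inst))])) break
      }
      used[(off + 1):(off + length(inst))] <- TRUE
      s[(off + 1):(off + length(inst))] <- inst
      planted[[length(planted) + 1L]] <- data.frame(
        gene_id = truth$gene_id[i], motif_name = motifs$name[j],
        offset = off, strand = "+", stringsAsFactors = FALSE
      )
    }
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- truth$gene_id
  list(sequences = seqs, planted = do.call(rbind, planted))
}

#' Simulate an FPKM matrix with planted expression subgroups
#'
#' Imprinted genes are split between an endosperm-primary profile (high FPKM
#' in endosperm samples, near-zero elsewhere) and a constitutive profile
#' (comparable FPKM everywhere); all other genes get constitutive profiles.
#' Log-normal noise is applied throughout.
#'
#' @param truth A `truth_table`.
#' @param design A list of `cross_spec` (defines sample ids and tissues).
#' @param config The matching `sim_config`.
#' @param frac_endosperm_primary Fraction of imprinted genes planted as
#'   endosperm-primary.
#' @return A list with `fpkm` (genes x samples matrix), `tissues` (per-sample
#'   tissue labels), and `subgroup_truth` (per-gene planted subgroup).
#' @export
simulate_fpkm <- function(truth, design, config, frac_endosperm_primary = 0.5) {
  set.seed(config$seed + 4L)
  samples <- vapply(design, function(cs) cs$sample_id, "")
  tissues <- vapply(design, function(cs) cs$tissue, "")
  n <- nrow(truth)
  imprinted <- truth$true_status %in% c("MEG", "PEG")
  subgroup <- rep("constitutive", n)
  subgroup[imprinted] <- ifelse(
    runif(sum(imprinted)) < frac_endosperm_primary,
    "endosperm_primary", "constitutive")
  base <- matrix(0, n, length(samples), dimnames = list(truth$gene_id, samples))
  for (j in seq_along(samples)) {
    mu <- ifelse(subgroup == "endosperm_primary",
                 ifelse(tissues[j] == "endosperm", 60, 1), 30)
    base[, j] <- mu * exp(rnorm(n, 0, 0.2))
  }
  list(fpkm = base, tissues = tissues,
       subgroup_truth = data.frame(gene_id = truth$gene_id,
                                   subgroup = subgroup,
                                   stringsAsFactors = FALSE))
}

#' Simulate a complete fixture
#'
#' Orchestrates truth generation, founder SNPs, per-gene and per-SNP counts
#' for every direction in the design, promoters with planted motifs, and an
#' FPKM matrix. Fully deterministic given `config$seed`.
#'
#' @param config A `sim_config`.
#' @param design A list of `cross_spec`; defaults to the study's four
#'   reciprocal pairs in both tissues.
#' @param swap_roles Passed to [simulate_counts()].
#' @return A list with elements `config`, `design`, `truth`, `snps`,
#'   `gene_counts`, `snp_counts` (per sample), `promoters`, `expression`.
#' @export
simulate_fixture <- function(config, design = default_cross_design(),
                             swap_roles = FALSE) {
  truth <- generate_truth(config)
  snps <- simulate_snps(truth, config)
  gene_counts <- simulate_counts(truth, design, config, swap_roles = swap_roles)
  set.seed(config$seed + 5L)
  snp_counts <- list()
  for (cs in design) {
    gc <- gene_counts[gene_counts$sample_id == cs$sample_id, , drop = FALSE]
    snp_counts[[cs$sample_id]] <- snp_level_counts(gc, snps, cs)
  }
  promoters <- simulate_promoters(truth, config)
  expression <- simulate_fpkm(truth, design, config)
  list(config = config, design = design, truth = truth, snps = snps,
       gene_counts = gene_counts, snp_counts = snp_counts,
       promoters = promoters, expression = expression)
}

#' Write a simulated fixture to disk
#'
#' Emits the plain-text files a real analysis would start from: a founder
#' genotype TSV, one per-SNP allele count TSV per sample, gene models as
#' GFF3 (1-based inclusive), promoter FASTA, FPKM TSV, sample metadata TSV,
#' and a JSON manifest recording the ground truth (gene status, planted
#' motifs, planted expression subgroups) for test assertions.
#'
#' @param fixture Output of [simulate_fixture()].
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a named list of written paths.
#' @export
emit_fixture_files <- function(fixture, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  p <- list()
  p$genotypes <- file.path(outdir, "genotypes.tsv")
  write_tsv_plain(fixture$snps, p$genotypes)

  cdir <- file.path(outdir, "counts")
  dir.create(cdir, showWarnings = FALSE)
  p$counts <- character(0)
  for (sid in names(fixture$snp_counts)) {
    path <- file.path(cdir, paste0(sid, ".tsv"))
    write_tsv_plain(fixture$snp_counts[[sid]], path)
    p$counts[sid] <- path
  }

  p$gff <- file.path(outdir, "genes.gff3")
  write_gene_gff3(fixture$truth, p$gff)

  p$promoters <- file.path(outdir, "promoters.fa")
  write_promoter_fasta(fixture$promoters$sequences, p$promoters)

  p$fpkm <- file.path(outdir, "fpkm.tsv")
  fp <- data.frame(gene_id = rownames(fixture$expression$fpkm),
                   fixture$expression$fpkm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_plain(fp, p$fpkm)

  p$samples <- file.path(outdir, "samples.tsv")
  write_tsv_plain(design_table(fixture$design), p$samples)

  p$manifest <- file.path(outdir, "truth.json")
  manifest <- list(
    seed = fixture$config$seed,
    truth = fixture$truth,
    planted_motifs = fixture$promoters$planted,
    subgroup_truth = fixture$expression$subgroup_truth
  )
  jsonlite::write_json(manifest, p$manifest, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(p)
}
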