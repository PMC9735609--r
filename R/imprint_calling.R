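#' Caller configuration
#'
#' Thresholds of the imprinting caller. A gene is testable in a direction
#' when its summed allelic reads reach `min_reads`. In the embryo a gene is
#' called MEG (PEG) when the chi-square test against the 1:1 null is
#' significant and more than `embryo_fraction` of reads are maternal
#' (paternal) — the 2:1 threshold, i.e. >66% read as the rational 2/3. In the
#' triploid endosperm the null is 2:1 maternal:paternal, MEGs need a maternal
#' fraction above `endo_meg_fraction` and PEGs a paternal fraction above
#' `endo_peg_paternal_fraction`. Inequalities at the thresholds are strict.
#'
#' @param min_reads Minimum summed allelic reads per direction (default 20).
#' @param alpha Chi-square significance level (default 0.05, uncorrected).
#' @param embryo_fraction Embryo allelic-fraction threshold (default 2/3).
#' @param endo_meg_fraction Endosperm maternal-fraction threshold for MEGs
#'   (default 0.80).
#' @param endo_peg_paternal_fraction Endosperm paternal-fraction threshold
#'   for PEGs (default 0.50).
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(min_reads = 20L, alpha = 0.05,
                          embryo_fraction = 2 / 3,
                          endo_meg_fraction = 0.80,
                          endo_peg_paternal_fraction = 0.50) {
  fr <- c(embryo_fraction, endo_meg_fraction, endo_peg_paternal_fraction)
  if (any(fr <= 0) || any(fr >= 1)) stop("fraction thresholds must lie in (0,1)")
  if (min_reads < 1) stop("min_reads must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  structure(list(min_reads = as.integer(min_reads), alpha = alpha,
                 embryo_fraction = embryo_fraction,
                 endo_meg_fraction = endo_meg_fraction,
                 endo_peg_paternal_fraction = endo_peg_paternal_fraction),
            class = "caller_config")
}

#' Chi-square dosage test for allelic bias
#'
#' Pearson chi-square (1 df, no continuity correction) of observed maternal
#' and paternal read counts against the tissue's expected dosage: 1:1 in the
#' diploid embryo, 2:1 maternal:paternal in the triploid endosperm. With
#' total n and null maternal fraction f, the statistic is
#' (m - nf)^2 / (nf) + (p - n(1-f))^2 / (n(1-f)) and the p-value is the upper
#' tail of the chi-square distribution with one degree of freedom.
#'
#' Vectorised over `maternal` and `paternal`.
#'
#' @param maternal,paternal Non-negative integer read counts; each pair must
#'   have a positive total.
#' @param tissue `"embryo"` or `"endosperm"`.
#' @return A list with numeric vectors `chi2` and `p_value`.
#' @examples
#' chi2_dosage_test(18, 2, "embryo")   # chi2 = 12.8
#' chi2_dosage_test(20, 10, "endosperm")  # exact 2:1 null, chi2 = 0, p = 1
#' @export
chi2_dosage_test <- function(maternal, paternal, tissue) {
  f <- tissue_null_fraction(tissue)
  if (any(maternal < 0) || any(paternal < 0)) stop("counts must be non-negative")
  n <- maternal + paternal
  if (any(n == 0)) stop("zero total reads: filter untestable genes before testing")
  em <- n * f
  ep <- n * (1 - f)
  chi2 <- (maternal - em)^2 / em + (paternal - ep)^2 / ep
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Classify one cross direction
#'
#' Applies the read filter, the chi-square dosage test, and the tissue's
#' allelic-fraction thresholds to per-gene counts from a single cross
#' direction, yielding a provisional per-direction status.
#'
#' @param counts Per-gene allele counts (`gene_id`, `maternal_reads`,
#'   `paternal_reads`).
#' @param tissue `"embryo"` or `"endosperm"`.
#' @param cfg A `caller_config`.
#' @return A data.frame with `gene_id`, `maternal_fraction`, `chi2`,
#'   `p_value`, `testable`, and `status` in
#'   MEG/PEG/biallelic/untestable.
#' @export
classify_direction <- function(counts, tissue, cfg = caller_config()) {
  tissue <- match.arg(tissue, c("embryo", "endosperm"))
  m <- counts$maternal_reads
  p <- counts$paternal_reads
  tot <- m + p
  testable <- tot >= cfg$min_reads
  frac <- ifelse(tot > 0, m / tot, NA_real_)
  chi2 <- rep(NA_real_, length(m))
  pv <- rep(NA_real_, length(m))
  if (any(testable)) {
    t1 <- chi2_dosage_test(m[testable], p[testable], tissue)
    chi2[testable] <- t1$chi2
    pv[testable] <- t1$p_value
  }
  sig <- !is.na(pv) & pv < cfg$alpha
  status <- rep("biallelic", length(m))
  if (tissue == "embryo") {
    status[sig & frac > cfg$embryo_fraction] <- "MEG"
    status[sig & (1 - frac) > cfg$embryo_fraction] <- "PEG"
  } else {
    status[sig & frac > cfg$endo_meg_fraction] <- "MEG"
    status[sig & (1 - frac) > cfg$endo_peg_paternal_fraction] <- "PEG"
  }
  status[!testable] <- "untestable"
  data.frame(gene_id = counts$gene_id, maternal_fraction = frac,
             chi2 = chi2, p_value = pv, testable = testable, status = status,
             stringsAsFactors = FALSE)
}

#' Combine the two directions of a reciprocal pair
#'
#' Imprinting is a parent-of-origin effect, so a gene is called MEG (PEG)
#' only when both directions of the reciprocal cross independently classify
#' it MEG (PEG). A gene favouring the same founder allele in both directions
#' shows opposite maternal fractions across directions and is called
#' biallelic (allele-specific, not imprinted). A gene untestable in either
#' direction is untestable for the pair. A pooled-count mode sums reads
#' across directions before testing instead; the read filter is still applied
#' per direction.
#'
#' @param dir1,dir2 Per-direction classifications of the same genes and
#'   tissue ([classify_direction()] output); gene sets must match.
#' @param tissue Tissue of both directions.
#' @param cfg A `caller_config`.
#' @param mode `"strict"` (both directions must pass independently, default)
#'   or `"pooled"` (test on summed counts).
#' @param counts1,counts2 Original per-direction counts, required for
#'   `mode = "pooled"`.
#' @return A data.frame with `gene_id`, `status`, and per-direction
#'   fractions/statistics.
#' @export
combine_reciprocal <- function(dir1, dir2, tissue, cfg = caller_config(),
                               mode = c("strict", "pooled"),
                               counts1 = NULL, counts2 = NULL) {
  mode <- match.arg(mode)
  if (!setequal(dir1$gene_id, dir2$gene_id))
    stop("the two directions cover different gene sets")
  dir2 <- dir2[match(dir1$gene_id, dir2$gene_id), , drop = FALSE]
  untest <- !dir1$testable | !dir2$testable
  if (mode == "strict") {
    status <- ifelse(dir1$status == "MEG" & dir2$status == "MEG", "MEG",
              ifelse(dir1$status == "PEG" & dir2$status == "PEG", "PEG",
                     "biallelic"))
  } else {
    if (is.null(counts1) || is.null(counts2))
      stop("pooled mode needs the per-direction counts")
    counts2 <- counts2[match(dir1$gene_id, counts2$gene_id), , drop = FALSE]
    counts1 <- counts1[match(dir1$gene_id, counts1$gene_id), , drop = FALSE]
    pooled <- data.frame(
      gene_id = dir1$gene_id,
      maternal_reads = counts1$maternal_reads + counts2$maternal_reads,
      paternal_reads = counts1$paternal_reads + counts2$paternal_reads
    )
    status <- classify_direction(pooled, tissue, cfg)$status
  }
  status[untest] <- "untestable"
  data.frame(
    gene_id = dir1$gene_id, tissue = tissue, status = status,
    maternal_fraction_1 = dir1$maternal_fraction,
    maternal_fraction_2 = dir2$maternal_fraction,
    chi2_1 = dir1$chi2, chi2_2 = dir2$chi2,
    p_value_1 = dir1$p_value, p_value_2 = dir2$p_value,
    stringsAsFactors = FALSE
  )
}

#' Call imprinting across all reciprocal pairs
#'
#' Runs the per-direction classifier and the reciprocal combination for every
#' (cross pair, tissue) in the design, and tallies MEG/PEG counts.
#'
#' @param counts Per-gene allele counts for all samples (`gene_id`,
#'   `sample_id`, `maternal_reads`, `paternal_reads`); duplicated
#'   (gene, sample) rows are an error.
#' @param design A list of `cross_spec`; each (pair, tissue) must have
#'   exactly two directions.
#' @param cfg A `caller_config`.
#' @param mode Reciprocal combination mode, see [combine_reciprocal()].
#' @return A list: `calls` (data.frame with `gene_id`, `cross_pair`,
#'   `tissue`, `status` and per-direction statistics) and `summary`
#'   (MEG/PEG/biallelic/untestable counts per pair and tissue).
#' @export
call_all <- function(counts, design, cfg = caller_config(),
                     mode = c("strict", "pooled")) {
  mode <- match.arg(mode)
  if (anyDuplicated(counts[, c("gene_id", "sample_id")]) > 0L)
    stop("duplicate (gene_id, sample_id) rows in counts")
  dt <- design_table(design)
  keys <- unique(dt[, c("pair", "tissue")])
  calls <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- dt$pair == keys$pair[i] & dt$tissue == keys$tissue[i]
    if (sum(sel) != 2L)
      stop("cross pair ", keys$pair[i], " (", keys$tissue[i],
           ") needs exactly two directions, found ", sum(sel))
    sids <- dt$sample_id[sel]
    c1 <- counts[counts$sample_id == sids[1], , drop = FALSE]
    c2 <- counts[counts$sample_id == sids[2], , drop = FALSE]
    if (nrow(c1) == 0L || nrow(c2) == 0L)
      stop("missing counts for direction(s) of pair ", keys$pair[i],
           " (", keys$tissue[i], ")")
    shared <- intersect(c1$gene_id, c2$gene_id)
    c1 <- c1[match(shared, c1$gene_id), , drop = FALSE]
    c2 <- c2[match(shared, c2$gene_id), , drop = FALSE]
    d1 <- classify_direction(c1, keys$tissue[i], cfg)
    d2 <- classify_direction(c2, keys$tissue[i], cfg)
    cc <- combine_reciprocal(d1, d2, keys$tissue[i], cfg, mode = mode,
                             counts1 = c1, counts2 = c2)
    cc$cross_pair <- keys$pair[i]
    calls[[i]] <- cc
  }
  calls <- do.call(rbind, calls)
  calls <- calls[order(calls$cross_pair, calls$tissue, calls$gene_id), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  tab <- as.data.frame(table(pair = calls$cross_pair, tissue = calls$tissue,
                             status = calls$status),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n_genes"
  list(calls = calls, summary = tab[tab$n_genes > 0 | tab$status %in%
                                      c("MEG", "PEG"), , drop = FALSE])
}

#' Tissue overlap of imprinted genes
#'
#' For each cross pair, the imprinted (MEG or PEG) gene sets per tissue and
#' their intersection — the genes imprinted in both embryo and endosperm.
#'
#' @param calls `calls` element of [call_all()] output.
#' @return A list per cross pair with `embryo`, `endosperm`, and `both` gene
#'   id vectors.
#' @export
tissue_overlap <- function(calls) {
  imp <- calls[calls$status %in% c("MEG", "PEG"), , drop = FALSE]
  out <- list()
  for (pr in unique(calls$cross_pair)) {
    e <- sort(imp$gene_id[imp$cross_pair == pr & imp$tissue == "embryo"])
    n <- sort(imp$gene_id[imp$cross_pair == pr & imp$tissue == "endosperm"])
    out[[pr]] <- list(embryo = e, endosperm = n, both = intersect(e, n))
  }
  out
}
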