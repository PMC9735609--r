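#' Per-pair imprinting summary used by the set algebra
#'
#' Reduces a calls table to one row per (gene, cross pair): whether the gene
#' was testable and whether it was imprinted (MEG or PEG) in any of the
#' selected tissues of that pair.
#'
#' @param calls `calls` element of [call_all()] output.
#' @param tissue Optional tissue filter; default uses all tissues present.
#' @return A data.frame with `gene_id`, `cross_pair`, `testable`,
#'   `imprinted`, `direction` (MEG/PEG/none; "mixed" if both occur across
#'   tissues).
#' @export
pair_imprinting_status <- function(calls, tissue = NULL) {
  if (!is.null(tissue)) calls <- calls[calls$tissue %in% tissue, , drop = FALSE]
  sp <- split(calls, list(calls$gene_id, calls$cross_pair), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    imp <- d$status %in% c("MEG", "PEG")
    dirs <- unique(d$status[imp])
    data.frame(
      gene_id = d$gene_id[1], cross_pair = d$cross_pair[1],
      testable = any(d$status != "untestable"),
      imprinted = any(imp),
      direction = if (length(dirs) == 0) "none"
                  else if (length(dirs) == 1) dirs else "mixed",
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

# set labels for the two comparison groups: each group compares the two
# F1-hybrid pairs against one biparental reference pair
conservation_set_labels <- list(
  `Mo17-added` = list(ref = "BC/CB",
                      sets = list(c("I", "II", "III"), c("IV", "V", "VI"))),
  `B73-added` = list(ref = "MC/CM",
                     sets = list(c("VII", "VIII", "IX"), c("X", "XI", "XII")))
)

#' Assign conservation sets for one comparison group
#'
#' Compares imprinting status between each triparental pair (BM-C/C-BM and
#' MB-C/C-MB) and the group's biparental reference pair (BC/CB for the
#' Mo17-added group, MC/CM for the B73-added group). Per comparison a gene
#' falls in one of three sets: imprinted only in the triparental pair,
#' imprinted only in the reference pair, or imprinted in both. Genes are
#' labelled `non_conserved` when their status differs from the reference in
#' both comparisons (membership in the union of the two "differs" sets of
#' each comparison), `conserved` when imprinted in both pairs of both
#' comparisons, and `unclassified` otherwise. Genes untestable in any
#' compared pair are excluded from set logic entirely.
#'
#' @param calls `calls` element of [call_all()] output covering the three
#'   pairs the group needs.
#' @param group `"Mo17-added"` or `"B73-added"`.
#' @param tissue Optional tissue filter passed to
#'   [pair_imprinting_status()].
#' @param same_direction If `TRUE`, "imprinted in both" sets additionally
#'   require the same direction (MEG in both or PEG in both).
#' @return A data.frame with `gene_id`, `group`, `sets` (comma-joined
#'   labels), `label` in conserved/non_conserved/unclassified.
#' @export
assign_sets <- function(calls, group = c("Mo17-added", "B73-added"),
                        tissue = NULL, same_direction = FALSE) {
  group <- match.arg(group)
  spec <- conservation_set_labels[[group]]
  pairs_f1 <- c("BM-C/C-BM", "MB-C/C-MB")
  needed <- c(pairs_f1, spec$ref)
  st <- pair_imprinting_status(calls, tissue = tissue)
  missing <- setdiff(needed, unique(st$cross_pair))
  if (length(missing) > 0L)
    stop("calls are missing cross pair(s): ", paste(missing, collapse = ", "))
  st <- st[st$cross_pair %in% needed, , drop = FALSE]
  wide <- lapply(needed, function(pr) st[st$cross_pair == pr, , drop = FALSE])
  names(wide) <- needed
  genes <- Reduce(intersect, lapply(wide, function(d)
    d$gene_id[d$testable]))
  genes <- sort(genes)
  get <- function(pr, col) {
    d <- wide[[pr]]
    d[[col]][match(genes, d$gene_id)]
  }
  out <- data.frame(gene_id = genes, group = group, sets = "",
                    label = "unclassified", stringsAsFactors = FALSE)
  ref_imp <- get(spec$ref, "imprinted")
  ref_dir <- get(spec$ref, "direction")
  differs <- matrix(FALSE, length(genes), 2L)
  both <- matrix(FALSE, length(genes), 2L)
  sets <- rep("", length(genes))
  for (k in 1:2) {
    f1_imp <- get(pairs_f1[k], "imprinted")
    f1_dir <- get(pairs_f1[k], "direction")
    lab <- spec$sets[[k]]  # c(only-F1, only-ref, both)
    in_both <- f1_imp & ref_imp
    if (same_direction)
      in_both <- in_both & f1_dir == ref_dir & f1_dir %in% c("MEG", "PEG")
    only_f1 <- f1_imp & !ref_imp
    only_ref <- ref_imp & !f1_imp
    differs[, k] <- only_f1 | only_ref
    both[, k] <- in_both
    add <- ifelse(only_f1, lab[1], ifelse(only_ref, lab[2],
                  ifelse(in_both, lab[3], "")))
    sets <- ifelse(add == "", sets,
                   ifelse(sets == "", add, paste(sets, add, sep = ",")))
  }
  out$sets <- sets
  out$label[differs[, 1] & differs[, 2]] <- "non_conserved"
  out$label[both[, 1] & both[, 2]] <- "conserved"
  out
}

#' Overlap of conservation labels between the two comparison groups
#'
#' @param mo17,b73 [assign_sets()] outputs for the Mo17-added and B73-added
#'   groups.
#' @return A list with conserved/non-conserved overlap gene vectors, counts,
#'   and overlap fractions (denominator: the first group's list).
#' @export
overlap_groups <- function(mo17, b73) {
  pick <- function(a, lab) sort(a$gene_id[a$label == lab])
  res <- list()
  for (lab in c("conserved", "non_conserved")) {
    g1 <- pick(mo17, lab)
    g2 <- pick(b73, lab)
    ov <- intersect(g1, g2)
    res[[lab]] <- list(
      mo17_added = g1, b73_added = g2, overlap = ov,
      n_overlap = length(ov),
      fraction_of_mo17 = if (length(g1) > 0) length(ov) / length(g1) else NA_real_,
      fraction_of_b73 = if (length(g2) > 0) length(ov) / length(g2) else NA_real_
    )
  }
  res
}

#' Join conservation assignments to cross-species imprinting tables
#'
#' @param assignments [assign_sets()] output (any label subset).
#' @param orthologs Data.frame with `gene_id`, `species`, `ortholog_id`,
#'   `imprinted` (logical); gene ids absent from `assignments` are logged and
#'   excluded from denominators.
#' @return A list: `flags` (per gene x species imprinted-ortholog flag) and
#'   `rates` (per species, fraction of joined genes with an imprinted
#'   ortholog; NA when no genes join).
#' @export
interspecies_join <- function(assignments, orthologs) {
  species <- unique(orthologs$species)
  if (nrow(orthologs) == 0L || length(species) == 0L)
    return(list(flags = data.frame(), rates = data.frame(
      species = character(0), n = integer(0), rate = numeric(0))))
  unknown <- setdiff(orthologs$gene_id, assignments$gene_id)
  if (length(unknown) > 0L)
    message(length(unknown), " ortholog row(s) reference genes outside the ",
            "assignment table and were excluded")
  ort <- orthologs[orthologs$gene_id %in% assignments$gene_id, , drop = FALSE]
  flags <- stats::aggregate(imprinted ~ gene_id + species, data = ort, FUN = any)
  rates <- do.call(rbind, lapply(sort(species), function(sp) {
    d <- flags[flags$species == sp, , drop = FALSE]
    data.frame(species = sp, n = nrow(d),
               rate = if (nrow(d) > 0) mean(d$imprinted) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(flags = flags, rates = rates)
}

#' Detect imprinted-gene clusters
#'
#' Sorts imprinted genes per chromosome by anchor position and chains
#' consecutive genes whose anchor distance is at most `window` (single
#' linkage, so a chained cluster may span more than one window overall).
#' Clusters of at least two members are reported.
#'
#' @param genes Data.frame of imprinted genes with `gene_id`, `chrom`,
#'   `start`, `end`.
#' @param window Maximum gap between consecutive anchors in bp (default 1 Mb).
#' @param anchor `"start"` (default) or `"midpoint"`.
#' @return A data.frame with `chrom`, `start`, `end`, `n_members`, and a
#'   list-column `member_gene_ids` (members sorted by position).
#' @export
find_clusters <- function(genes, window = 1e6, anchor = c("start", "midpoint")) {
  anchor <- match.arg(anchor)
  if (nrow(genes) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_members = integer(0)))
  if (any(is.na(genes$chrom)) || any(is.na(genes$start)))
    stop("genes must carry chrom and start coordinates")
  pos <- if (anchor == "start") genes$start else (genes$start + genes$end) / 2
  genes$.anchor <- pos
  out <- list()
  for (ch in sort(unique(genes$chrom))) {
    d <- genes[genes$chrom == ch, , drop = FALSE]
    d <- d[order(d$.anchor, d$gene_id), , drop = FALSE]
    grp <- cumsum(c(1, diff(d$.anchor) > window))
    for (g in unique(grp)) {
      memb <- d[grp == g, , drop = FALSE]
      if (nrow(memb) < 2L) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = min(memb$start),
        end = max(memb$end),
        n_members = nrow(memb),
        member_gene_ids = I(list(memb$gene_id)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_members = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-chromosome imprinted-gene counts and tissue overlap
#'
#' @param calls `calls` element of [call_all()] output.
#' @param genes Data.frame of gene coordinates (`gene_id`, `chrom`).
#' @return A list: `by_chromosome` (counts of distinct imprinted genes per
#'   chromosome and tissue) and `tissue_overlap` (see [tissue_overlap()]).
#' @export
summarize_chromosomes <- function(calls, genes) {
  imp <- calls[calls$status %in% c("MEG", "PEG"), , drop = FALSE]
  imp$chrom <- genes$chrom[match(imp$gene_id, genes$gene_id)]
  by_chr <- if (nrow(imp) == 0L) {
    data.frame(chrom = character(0), tissue = character(0), n_genes = integer(0))
  } else {
    u <- unique(imp[, c("gene_id", "chrom", "tissue")])
    tab <- as.data.frame(table(chrom = u$chrom, tissue = u$tissue),
                         stringsAsFactors = FALSE)
    names(tab)[names(tab) == "Freq"] <- "n_genes"
    tab
  }
  list(by_chromosome = by_chr, tissue_overlap = tissue_overlap(calls))
}
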