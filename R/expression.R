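#' Relative expression: row-normalise FPKM by each gene's maximum
#'
#' Each gene's FPKM values are divided by the gene's maximum over all
#' samples, so every row peaks at 1; all-zero genes map to all-zero rows
#' (rather than NaN) so downstream clustering never sees undefined values.
#' The transform is idempotent.
#'
#' @param m Numeric matrix of FPKM values, genes in rows; must be
#'   non-negative.
#' @return A matrix of the same shape with values in [0, 1].
#' @examples
#' relative_expression(rbind(g1 = c(10, 5, 0)))  # 1.0 0.5 0.0
#' @export
relative_expression <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0L) stop("empty expression matrix")
  if (any(m < 0)) stop("FPKM values must be non-negative")
  mx <- apply(m, 1, max)
  mx[mx == 0] <- 1  # all-zero rows stay all-zero
  sweep(m, 1, mx, "/")
}

#' Partition genes into endosperm-primary and constitutive subgroups
#'
#' Agglomerative hierarchical clustering (average linkage, Euclidean
#' distance) of relative-expression rows, cut into `k` groups. The cluster
#' whose mean relative expression in endosperm samples exceeds its mean in
#' the remaining samples by the largest margin is labelled
#' `endosperm_primary`; all other clusters are `constitutive`. With fewer
#' than two genes (or a degenerate all-identical input collapsing to one
#' cluster) the margin rule is applied to whatever clusters exist.
#'
#' @param rel Relative-expression matrix (genes x samples), e.g. from
#'   [relative_expression()].
#' @param tissues Character vector of tissue labels per sample (column).
#' @param k Number of clusters to cut the tree into (default 2).
#' @return A data.frame with `gene_id`, `cluster`, `subgroup`.
#' @export
cluster_subgroups <- function(rel, tissues, k = 2L) {
  rel <- as.matrix(rel)
  if (length(tissues) != ncol(rel))
    stop("tissues must label every sample column")
  if (!any(tissues == "endosperm"))
    stop("no endosperm samples: the subgroup rule needs at least one")
  if (is.null(rownames(rel))) rownames(rel) <- paste0("g", seq_len(nrow(rel)))
  if (nrow(rel) < 2L) {
    warning("fewer than two genes: all assigned constitutive")
    return(data.frame(gene_id = rownames(rel), cluster = 1L,
                      subgroup = rep("constitutive", nrow(rel)),
                      stringsAsFactors = FALSE))
  }
  # deterministic agglomeration: order rows lexicographically before
  # clustering so tie-breaks do not depend on input order
  ord <- order(rownames(rel))
  rel <- rel[ord, , drop = FALSE]
  hc <- stats::hclust(stats::dist(rel, method = "euclidean"),
                      method = "average")
  # never cut deeper than the number of distinct profiles (all-identical
  # input collapses to a single cluster rather than an arbitrary split)
  k_eff <- min(k, nrow(rel), nrow(unique(rel)))
  cl <- stats::cutree(hc, k = k_eff)
  endo <- tissues == "endosperm"
  margin <- vapply(sort(unique(cl)), function(g) {
    rows <- rel[cl == g, , drop = FALSE]
    mean(rows[, endo, drop = FALSE]) -
      if (all(endo)) 0 else mean(rows[, !endo, drop = FALSE])
  }, 0)
  primary <- sort(unique(cl))[which.max(margin)]
  data.frame(
    gene_id = rownames(rel),
    cluster = unname(cl),
    subgroup = ifelse(cl == primary, "endosperm_primary", "constitutive"),
    stringsAsFactors = FALSE
  )
}
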