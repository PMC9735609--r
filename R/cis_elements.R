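IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

iupac_bases <- function(code) {
  b <- IUPAC_MAP[[toupper(code)]]
  if (is.null(b)) stop("not an IUPAC nucleotide code: ", code)
  b
}

#' Default promoter cis-regulatory element table
#'
#' The thirteen element classes profiled in maize imprinting promoters,
#' grouped as hormone-responsive (ABRE, CGTCA-motif, TGACG-motif, ERE,
#' TGA-element, TCA-element), light-responsive (G-box, GT1-motif, TCT-motif,
#' Box-4) and stress-responsive (ARE, W-box, LTR). Consensus strings follow
#' common PlantCARE-style definitions and are implementation defaults, meant
#' to be overridden with a user motif table when exact site definitions
#' matter.
#'
#' @return A data.frame with `name`, `consensus` (IUPAC), `category`.
#' @export
default_motifs <- function() {
  data.frame(
    name = c("ABRE", "CGTCA-motif", "TGACG-motif", "ERE", "TGA-element",
             "TCA-element", "G-box", "GT1-motif", "TCT-motif", "Box-4",
             "ARE", "W-box", "LTR"),
    consensus = c("ACGTG", "CGTCA", "TGACG", "ATTTTAAA", "AACGAC",
                  "CCATCTTTTT", "CACGTG", "GGTTAA", "TCTTAC", "ATTAAT",
                  "AAACCA", "TTGACC", "CCGAAA"),
    category = c(rep("hormone", 6), rep("light", 4), rep("stress", 3)),
    stringsAsFactors = FALSE
  )
}

validate_motifs <- function(motifs) {
  stopifnot(all(c("name", "consensus") %in% names(motifs)))
  if (any(nchar(motifs$consensus) == 0)) stop("empty motif consensus")
  ok <- grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]+$", motifs$consensus)
  if (any(!ok))
    stop("non-IUPAC characters in consensus for: ",
         paste(motifs$name[!ok], collapse = ", "))
  invisible(motifs)
}

iupac_to_regex <- function(consensus) {
  paste(vapply(strsplit(toupper(consensus), "")[[1]], function(code) {
    b <- iupac_bases(code)
    if (length(b) == 1) b else paste0("[", paste(b, collapse = ""), "]")
  }, ""), collapse = "")
}

revcomp <- function(seq) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(strsplit(toupper(seq), ""), function(x)
           paste(rev(x), collapse = ""), ""))
}

# all 0-based offsets where the IUPAC consensus matches, overlaps included;
# N in the sequence matches nothing
match_offsets <- function(seq, consensus) {
  rx <- paste0("(?=", iupac_to_regex(consensus), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Scan one promoter for cis-element motifs
#'
#' Reports every position (overlaps included) where each motif's IUPAC
#' consensus matches the sequence, and optionally the reverse strand:
#' reverse-strand hits are found on the reverse complement and reported as
#' the 0-based forward-strand offset of the matched window. `N` in the
#' sequence never matches.
#'
#' @param seq Promoter sequence over A/C/G/T/N (5' to 3', upstream of ATG).
#' @param motifs Motif table (`name`, `consensus`); see [default_motifs()].
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @param dedup Collapse +/- hits of a palindromic consensus at the same
#'   offset into one record (default `FALSE`).
#' @return A data.frame of hits: `motif_name`, `offset` (0-based from the
#'   promoter 5' end), `strand`, in ascending offset.
#' @export
scan_promoter <- function(seq, motifs = default_motifs(),
                          both_strands = TRUE, dedup = FALSE) {
  stopifnot(length(seq) == 1L)
  seq <- toupper(seq)
  if (!grepl("^[ACGTN]*$", seq))
    stop("sequence contains non-nucleotide characters")
  validate_motifs(motifs)
  L <- nchar(seq)
  hits <- list()
  for (i in seq_len(nrow(motifs))) {
    cons <- motifs$consensus[i]
    k <- nchar(cons)
    if (k > L) next
    fwd <- match_offsets(seq, cons)
    if (length(fwd) > 0)
      hits[[length(hits) + 1L]] <- data.frame(
        motif_name = motifs$name[i], offset = fwd, strand = "+",
        stringsAsFactors = FALSE)
    if (both_strands) {
      rev_hits <- match_offsets(revcomp(seq), cons)
      if (length(rev_hits) > 0)
        hits[[length(hits) + 1L]] <- data.frame(
          motif_name = motifs$name[i],
          offset = L - rev_hits - k,  # forward-strand coordinates
          strand = "-", stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(motif_name = character(0), offset = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  if (dedup)
    out <- out[!duplicated(out[, c("motif_name", "offset")]), , drop = FALSE]
  out <- out[order(out$offset, out$motif_name, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of promoters
#'
#' @param sequences Named character vector of promoter sequences.
#' @param motifs,both_strands,dedup Passed to [scan_promoter()].
#' @return A data.frame of hits with a leading `gene_id` column.
#' @export
scan_promoters <- function(sequences, motifs = default_motifs(),
                           both_strands = TRUE, dedup = FALSE) {
  stopifnot(!is.null(names(sequences)))
  out <- lapply(names(sequences), function(g) {
    h <- scan_promoter(sequences[[g]], motifs, both_strands, dedup)
    if (nrow(h) > 0) cbind(gene_id = g, h, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), motif_name = character(0),
                      offset = integer(0), strand = character(0))
  rownames(out) <- NULL
  out
}

#' Convert promoter offsets to distance upstream of the ATG
#'
#' A hit at 0-based `offset` in a promoter of `promoter_length` bp ends
#' `promoter_length - offset - motif_length + 1` bp upstream of the start
#' codon's A (position 1 = the base immediately before the ATG).
#'
#' @param offset 0-based offsets from the promoter 5' end.
#' @param motif_length Motif length(s) in bp.
#' @param promoter_length Promoter length in bp (default 1500).
#' @return Distance (bp) from the motif's 3'-most base to the ATG.
#' @export
offset_to_atg_distance <- function(offset, motif_length, promoter_length = 1500L) {
  promoter_length - offset - motif_length + 1L
}

#' Per-group cis-element presence profile
#'
#' For each gene group, the fraction of genes whose promoter carries at least
#' one hit of each motif class, plus the per-gene count of distinct classes.
#' Genes in a group without a scanned promoter are excluded and logged.
#'
#' @param hits [scan_promoters()] output.
#' @param groups Named list of gene-id vectors.
#' @param scanned_genes Gene ids whose promoters were scanned (defines which
#'   group members count toward denominators); defaults to the genes present
#'   in `hits`, which undercounts hit-free promoters — pass the full scanned
#'   set when available.
#' @param motifs Motif table (defines the rows of the ratio output).
#' @return A list: `ratios` (data.frame group x motif presence fraction; NA
#'   for empty groups) and `classes_per_gene` (distinct motif classes per
#'   scanned gene).
#' @export
group_profile <- function(hits, groups, scanned_genes = unique(hits$gene_id),
                          motifs = default_motifs()) {
  ratios <- list()
  for (grp in names(groups)) {
    members <- groups[[grp]]
    absent <- setdiff(members, scanned_genes)
    if (length(absent) > 0L)
      message(length(absent), " gene(s) in group ", grp,
              " lack a scanned promoter and were excluded")
    members <- intersect(members, scanned_genes)
    for (mo in motifs$name) {
      with_hit <- unique(hits$gene_id[hits$motif_name == mo])
      ratios[[length(ratios) + 1L]] <- data.frame(
        group = grp, motif_name = mo,
        n_genes = length(members),
        ratio = if (length(members) == 0L) NA_real_
                else mean(members %in% with_hit),
        stringsAsFactors = FALSE
      )
    }
  }
  cls <- stats::aggregate(motif_name ~ gene_id, data = hits,
                          FUN = function(x) length(unique(x)))
  names(cls)[2] <- "n_element_classes"
  zero <- setdiff(scanned_genes, cls$gene_id)
  if (length(zero) > 0L)
    cls <- rbind(cls, data.frame(gene_id = zero, n_element_classes = 0L))
  list(ratios = do.call(rbind, ratios),
       classes_per_gene = cls[order(cls$gene_id), , drop = FALSE])
}
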