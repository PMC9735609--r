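#' Define one cross direction
#'
#' A cross specification names the maternal and paternal founder sets for one
#' direction of a reciprocal cross, the tissue sampled, and (derived from the
#' tissue) the expected maternal transcript fraction under biallelic
#' expression: 1/2 in the diploid embryo, 2/3 in the triploid endosperm
#' (two maternal genome copies to one paternal).
#'
#' @param name Cross direction label, e.g. `"BM-C"` for (B73 x Mo17) x CAU5.
#' @param maternal Character vector of maternal founder line names (non-empty).
#' @param paternal Character vector of paternal founder line names (non-empty,
#'   disjoint from `maternal`).
#' @param tissue `"embryo"` or `"endosperm"`.
#' @param pair Label shared by the two directions of one reciprocal pair,
#'   e.g. `"BM-C/C-BM"`.
#' @return An object of class `cross_spec`.
#' @examples
#' cross_spec("BM-C", c("B73", "Mo17"), "CAU5", "endosperm", "BM-C/C-BM")
#' @export
cross_spec <- function(name, maternal, paternal, tissue, pair) {
  stopifnot(is.character(name), length(name) == 1L)
  maternal <- unique(as.character(maternal))
  paternal <- unique(as.character(paternal))
  if (length(maternal) == 0L || length(paternal) == 0L)
    stop("maternal and paternal founder sets must be non-empty")
  if (length(intersect(maternal, paternal)) > 0L)
    stop("maternal and paternal founder sets must be disjoint: ",
         paste(intersect(maternal, paternal), collapse = ", "))
  tissue <- match.arg(tissue, c("embryo", "endosperm"))
  structure(
    list(
      name = name,
      maternal = maternal,
      paternal = paternal,
      tissue = tissue,
      pair = pair,
      expected_maternal_fraction = tissue_null_fraction(tissue),
      sample_id = paste(name, tissue, sep = ".")
    ),
    class = "cross_spec"
  )
}

#' @export
print.cross_spec <- function(x, ...) {
  cat(sprintf("<cross_spec> %s  [%s]  %s x %s  (%s, null maternal fraction %s)\n",
              x$name, x$pair,
              paste(x$maternal, collapse = "+"),
              paste(x$paternal, collapse = "+"),
              x$tissue, format(x$expected_maternal_fraction, digits = 4)))
  invisible(x)
}

#' Expected maternal transcript fraction under biallelic expression
#'
#' @param tissue `"embryo"` (returns 1/2) or `"endosperm"` (returns 2/3).
#' @return A single numeric.
#' @export
tissue_null_fraction <- function(tissue) {
  tissue <- match.arg(tissue, c("embryo", "endosperm"))
  if (tissue == "embryo") 1 / 2 else 2 / 3
}

#' Swap maternal and paternal roles of a cross direction
#'
#' Used to probe label anti-symmetry: relabelling which side counts as
#' maternal must convert MEG calls to PEG calls and vice versa.
#'
#' @param cross A `cross_spec`.
#' @return A `cross_spec` with the founder sets exchanged.
#' @export
swap_cross <- function(cross) {
  stopifnot(inherits(cross, "cross_spec"))
  cross_spec(cross$name, cross$paternal, cross$maternal, cross$tissue, cross$pair)
}

#' The study's four reciprocal cross pairs
#'
#' Builds the full design used throughout: two biparental pairs (BC/CB between
#' B73 and CAU5, MC/CM between Mo17 and CAU5) and two triparental pairs in
#' which an F1 hybrid of B73 and Mo17 is crossed reciprocally with CAU5
#' (BM-C/C-BM and MB-C/C-MB), each sampled in embryo and endosperm.
#'
#' @param tissues Tissues to include for every direction.
#' @return A list of `cross_spec` objects (class `cross_design`).
#' @examples
#' length(default_cross_design())  # 8 directions x 2 tissues = 16
#' @export
default_cross_design <- function(tissues = c("embryo", "endosperm")) {
  hyb <- c("B73", "Mo17")
  dirs <- list(
    list("BC",   "B73",  "CAU5", "BC/CB"),
    list("CB",   "CAU5", "B73",  "BC/CB"),
    list("MC",   "Mo17", "CAU5", "MC/CM"),
    list("CM",   "CAU5", "Mo17", "MC/CM"),
    list("BM-C", hyb,    "CAU5", "BM-C/C-BM"),
    list("C-BM", "CAU5", hyb,    "BM-C/C-BM"),
    list("MB-C", hyb,    "CAU5", "MB-C/C-MB"),
    list("C-MB", "CAU5", hyb,    "MB-C/C-MB")
  )
  design <- list()
  for (d in dirs) for (ti in tissues)
    design[[length(design) + 1L]] <- cross_spec(d[[1]], d[[2]], d[[3]], ti, d[[4]])
  structure(design, class = c("cross_design", "list"))
}

#' Tabulate a cross design
#'
#' @param design A list of `cross_spec` objects.
#' @return A data.frame with one row per cross direction/tissue.
#' @export
design_table <- function(design) {
  stopifnot(length(design) > 0L)
  do.call(rbind, lapply(design, function(cs) {
    data.frame(
      sample_id = cs$sample_id, name = cs$name, pair = cs$pair,
      tissue = cs$tissue,
      maternal = paste(cs$maternal, collapse = ","),
      paternal = paste(cs$paternal, collapse = ","),
      expected_maternal_fraction = cs$expected_maternal_fraction,
      stringsAsFactors = FALSE
    )
  }))
}
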