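# Independent oracles, coded separately from the package implementations.

# Pearson chi-square for a 1-df dosage test, via the one-cell closed form
# (m - n f)^2 / (n f (1 - f)) and a normal-tail p-value -- a different
# algebraic route than the package's per-cell sum + pchisq.
oracle_chi2 <- function(m, p, f) {
  n <- m + p
  chi2 <- (m - n * f)^2 / (n * f * (1 - f))
  list(chi2 = chi2, p_value = 2 * pnorm(sqrt(chi2), lower.tail = FALSE))
}

# brute-force cluster chaining: connected components of the "anchor distance
# <= window on the same chromosome" graph, grown by repeated merging
oracle_clusters <- function(genes, window = 1e6, anchor = "start") {
  pos <- if (anchor == "start") genes$start else (genes$start + genes$end) / 2
  n <- nrow(genes)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (genes$chrom[i] == genes$chrom[j] &&
          abs(pos[i] - pos[j]) <= window && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep <- as.integer(names(which(table(comp) >= 2)))
  lapply(keep, function(k) sort(genes$gene_id[comp == k]))
}

# naive position-by-position IUPAC matcher (forward strand, 0-based offsets)
oracle_match <- function(seq, consensus) {
  map <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  s <- strsplit(toupper(seq), "")[[1]]
  cons <- strsplit(toupper(consensus), "")[[1]]
  k <- length(cons)
  hits <- integer(0)
  if (length(s) < k) return(hits)
  for (i in 1:(length(s) - k + 1)) {
    ok <- TRUE
    for (j in 1:k) {
      if (!(s[i + j - 1] %in% map[[cons[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

oracle_revcomp <- function(seq) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(toupper(seq), "")[[1]])),
        collapse = "")
}

# explicit UPGMA: returns sorted merge heights for <= 10 rows
oracle_upgma_heights <- function(m) {
  d <- as.matrix(dist(m))
  active <- lapply(seq_len(nrow(m)), identity)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i >= j) next
      h <- mean(d[active[[i]], active[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(active[[best[2]]], active[[best[3]]])
    active <- active[-c(best[2], best[3])]
    active[[length(active) + 1]] <- merged
  }
  sort(heights)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
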