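# build calls for one gene across the three pairs a group compares
group_calls <- function(gene, imp_bmc, imp_mbc, imp_ref, ref = "BC/CB",
                        testable = c(TRUE, TRUE, TRUE)) {
  st <- function(imp, ok) if (!ok) "untestable" else if (imp) "MEG" else "biallelic"
  make_calls(rep(gene, 3), c("BM-C/C-BM", "MB-C/C-MB", ref),
             c(st(imp_bmc, testable[1]), st(imp_mbc, testable[2]),
               st(imp_ref, testable[3])))
}

test_that("set assignment matches the worked definitions", {
  calls <- rbind(
    group_calls("g1", TRUE, TRUE, FALSE),   # sets I, IV -> non-conserved
    group_calls("g2", TRUE, TRUE, TRUE),    # sets III, VI -> conserved
    group_calls("g3", FALSE, FALSE, FALSE), # no sets -> unclassified
    group_calls("g4", FALSE, FALSE, TRUE),  # sets II, V -> non-conserved
    group_calls("g5", TRUE, FALSE, TRUE),   # sets III, V -> unclassified
    group_calls("g6", TRUE, TRUE, TRUE, testable = c(TRUE, FALSE, TRUE))
  )
  a <- assign_sets(calls, "Mo17-added")
  expect_false("g6" %in% a$gene_id)  # untestable in a compared pair: excluded
  row <- function(g) a[a$gene_id == g, ]
  expect_equal(row("g1")$sets, "I,IV")
  expect_equal(row("g1")$label, "non_conserved")
  expect_equal(row("g2")$sets, "III,VI")
  expect_equal(row("g2")$label, "conserved")
  expect_equal(row("g3")$sets, "")
  expect_equal(row("g3")$label, "unclassified")
  expect_equal(row("g4")$sets, "II,V")
  expect_equal(row("g4")$label, "non_conserved")
  expect_equal(row("g5")$sets, "III,V")
  expect_equal(row("g5")$label, "unclassified")

  expect_error(assign_sets(calls[calls$cross_pair != "BC/CB", ], "Mo17-added"),
               "BC/CB")
})

test_that("exhaustive status combinations reproduce hand-enumerated sets", {
  # oracle: for imprinted flags (a = BM-C/C-BM, b = MB-C/C-MB, r = reference),
  # spell the six set definitions out directly
  oracle <- function(a, b, r) {
    sets <- c("I"[a && !r], "II"[r && !a], "III"[a && r],
              "IV"[b && !r], "V"[r && !b], "VI"[b && r])
    sets <- sets[!is.na(sets)]
    label <- if (("I" %in% sets || "II" %in% sets) &&
                 ("IV" %in% sets || "V" %in% sets)) "non_conserved"
             else if ("III" %in% sets && "VI" %in% sets) "conserved"
             else "unclassified"
    list(sets = paste(sets, collapse = ","), label = label)
  }
  grid <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                      r = c(TRUE, FALSE))
  calls <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    group_calls(sprintf("g%02d", i), grid$a[i], grid$b[i], grid$r[i])))
  got <- assign_sets(calls, "Mo17-added")
  for (i in seq_len(nrow(grid))) {
    exp <- oracle(grid$a[i], grid$b[i], grid$r[i])
    g <- got[got$gene_id == sprintf("g%02d", i), ]
    expect_equal(g$sets, exp$sets, label = paste("sets, combination", i))
    expect_equal(g$label, exp$label, label = paste("label, combination", i))
    # exclusivity: a gene is never in both sets of one comparison
    s <- strsplit(g$sets, ",")[[1]]
    expect_false(all(c("I", "II") %in% s))
    expect_false(all(c("IV", "V") %in% s))
  }
  # the mirrored B73-added sets behave identically against MC/CM
  calls_b <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    group_calls(sprintf("g%02d", i), grid$a[i], grid$b[i], grid$r[i],
                ref = "MC/CM")))
  got_b <- assign_sets(calls_b, "B73-added")
  roman_map <- c(I = "VII", II = "VIII", III = "IX",
                 IV = "X", V = "XI", VI = "XII")
  for (i in seq_len(nrow(grid))) {
    exp <- oracle(grid$a[i], grid$b[i], grid$r[i])
    mapped <- paste(roman_map[strsplit(exp$sets, ",")[[1]]], collapse = ",")
    g <- got_b[got_b$gene_id == sprintf("g%02d", i), ]
    expect_equal(g$sets, mapped)
    expect_equal(g$label, exp$label)
  }
})

test_that("same-direction mode tightens the 'imprinted in both' sets", {
  calls <- rbind(
    make_calls("g1", "BM-C/C-BM", "MEG"),
    make_calls("g1", "MB-C/C-MB", "MEG"),
    make_calls("g1", "BC/CB", "PEG"))  # imprinted everywhere, direction flips
  expect_equal(assign_sets(calls, "Mo17-added")$label, "conserved")
  strict <- assign_sets(calls, "Mo17-added", same_direction = TRUE)
  expect_equal(strict$label, "unclassified")
  expect_equal(strict$sets, "")
})

test_that("group overlaps are plain set intersections", {
  mk <- function(genes, label) data.frame(gene_id = genes, group = "x",
                                          sets = "", label = label)
  mo <- rbind(mk(c("a", "b", "c"), "non_conserved"), mk("z", "conserved"))
  b7 <- rbind(mk(c("b", "c", "d"), "non_conserved"), mk("z", "conserved"))
  ov <- overlap_groups(mo, b7)
  expect_setequal(ov$non_conserved$overlap, c("b", "c"))
  expect_equal(ov$non_conserved$n_overlap, 2)
  expect_equal(ov$conserved$overlap, "z")
  expect_equal(ov$conserved$fraction_of_mo17, 1)
  # disjoint lists overlap in nothing
  ov0 <- overlap_groups(mk("a", "conserved"), mk("b", "conserved"))
  expect_equal(ov0$conserved$n_overlap, 0)
  # identical lists overlap completely
  ov1 <- overlap_groups(mk(letters[1:5], "conserved"),
                        mk(letters[1:5], "conserved"))
  expect_equal(ov1$conserved$n_overlap, 5)
  expect_equal(ov1$conserved$fraction_of_b73, 1)
})

test_that("interspecies joins report per-species conservation rates", {
  assignments <- data.frame(gene_id = paste0("g", 1:10), group = "x",
                            sets = "", label = "conserved")
  empty <- interspecies_join(assignments,
                             data.frame(gene_id = character(0),
                                        species = character(0),
                                        ortholog_id = character(0),
                                        imprinted = logical(0)))
  expect_equal(nrow(empty$rates), 0)

  ort <- data.frame(gene_id = paste0("g", 1:10), species = "rice",
                    ortholog_id = paste0("Os", 1:10),
                    imprinted = rep(c(TRUE, FALSE), 5))
  j <- interspecies_join(assignments, ort)
  expect_equal(j$rates$rate[j$rates$species == "rice"], 0.5)

  # a gene imprinted in two species counts once per species; unknown gene
  # ids are excluded from denominators
  ort2 <- rbind(ort,
                data.frame(gene_id = "g1", species = "sorghum",
                           ortholog_id = "Sb1", imprinted = TRUE),
                data.frame(gene_id = "gX", species = "sorghum",
                           ortholog_id = "Sb2", imprinted = TRUE))
  expect_message(j2 <- interspecies_join(assignments, ort2), "excluded")
  expect_equal(j2$rates$n[j2$rates$species == "sorghum"], 1)
  expect_equal(j2$rates$rate[j2$rates$species == "sorghum"], 1)
})

test_that("cluster detection matches the worked 1-Mb examples", {
  g <- function(id, chrom, start) data.frame(gene_id = id, chrom = chrom,
                                             start = start, end = start + 999L)
  # 800 kb apart: one cluster of two
  cl <- find_clusters(rbind(g("a", "chr1", 1e5), g("b", "chr1", 9e5)))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 2)
  expect_equal(cl$member_gene_ids[[1]], c("a", "b"))
  # 1.2 Mb apart: none
  expect_equal(nrow(find_clusters(rbind(g("a", "chr1", 1e5),
                                        g("b", "chr1", 13e5)))), 0)
  # 0.1 / 0.9 / 1.7 Mb: consecutive gaps of 0.8 Mb chain all three
  cl3 <- find_clusters(rbind(g("a", "chr1", 1e5), g("b", "chr1", 9e5),
                             g("c", "chr1", 17e5)))
  expect_equal(cl3$n_members, 3)
  # chromosomes never chain together
  expect_equal(nrow(find_clusters(rbind(g("a", "chr1", 1e5),
                                        g("b", "chr2", 1e5)))), 0)
  expect_error(find_clusters(g("a", NA, 1e5)), "coordinates")
})

test_that("cluster chaining equals the brute-force oracle on random instances", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(2:50, 1)
    genes <- data.frame(
      gene_id = sprintf("g%02d", 1:n),
      chrom = sample(paste0("chr", 1:3), n, TRUE),
      start = sample.int(8e6, n))
    genes$end <- genes$start + 2000L
    as_keys <- function(sets) sort(vapply(sets, function(s)
      paste(sort(s), collapse = ","), ""))
    got <- find_clusters(genes)
    exp_keys <- as_keys(oracle_clusters(genes))
    expect_equal(as_keys(got$member_gene_ids), exp_keys)
    # membership is invariant under input shuffling
    shuf <- find_clusters(genes[sample(n), ])
    expect_equal(as_keys(shuf$member_gene_ids), exp_keys)
  }
})

test_that("chromosome summaries count distinct imprinted genes per tissue", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      chrom = c("chr1", "chr1", "chr2"))
  calls <- rbind(
    make_calls(c("g1", "g2", "g3"), "BC/CB", c("MEG", "PEG", "biallelic"),
               tissue = "embryo"),
    make_calls(c("g1", "g2", "g3"), "MC/CM", c("MEG", "biallelic", "PEG"),
               tissue = "embryo"))
  s <- summarize_chromosomes(calls, genes)
  bc <- s$by_chromosome
  # g1 imprinted in two pairs still counts once on chr1
  expect_equal(bc$n_genes[bc$chrom == "chr1" & bc$tissue == "embryo"], 2)
  expect_equal(bc$n_genes[bc$chrom == "chr2" & bc$tissue == "embryo"], 1)
  # empty calls give an empty summary, not an error
  empty <- summarize_chromosomes(calls[0, ], genes)
  expect_equal(nrow(empty$by_chromosome), 0)
})
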