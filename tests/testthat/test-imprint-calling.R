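test_that("chi-square dosage test matches the worked closed forms", {
  # exact nulls give chi2 = 0, p = 1
  t0 <- chi2_dosage_test(10, 10, "embryo")
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p_value, 1)
  t1 <- chi2_dosage_test(20, 10, "endosperm")
  expect_equal(t1$chi2, 0)
  expect_equal(t1$p_value, 1)

  # (18, 2) embryo: (18-10)^2/10 + (2-10)^2/10 = 12.8
  t2 <- chi2_dosage_test(18, 2, "embryo")
  expect_equal(t2$chi2, 12.8)
  expect_equal(t2$p_value, pchisq(12.8, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(t2$p_value, 3.47e-4, tolerance = 1e-2)

  # (10, 20) endosperm: (10-20)^2/20 + (20-10)^2/10 = 15
  expect_equal(chi2_dosage_test(10, 20, "endosperm")$chi2, 15)

  expect_error(chi2_dosage_test(0, 0, "embryo"), "zero total")
  expect_error(chi2_dosage_test(-1, 5, "embryo"), "non-negative")
})

test_that("chi-square test agrees with stats::chisq.test on random counts", {
  set.seed(42)
  for (tissue in c("embryo", "endosperm")) {
    f <- if (tissue == "embryo") 1 / 2 else 2 / 3
    m <- sample(0:300, 300, TRUE)
    p <- sample(0:300, 300, TRUE)
    keep <- m + p > 0
    m <- m[keep]; p <- p[keep]
    got <- chi2_dosage_test(m, p, tissue)
    for (i in seq_along(m)) {
      ref <- suppressWarnings(chisq.test(c(m[i], p[i]), p = c(f, 1 - f),
                                         correct = FALSE))
      expect_equal(got$chi2[i], unname(ref$statistic), tolerance = 1e-12)
      expect_equal(got$p_value[i], ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("per-direction classification applies the threshold rules", {
  cfg <- caller_config()
  cls <- function(m, p, tissue)
    classify_direction(data.frame(gene_id = "g", maternal_reads = m,
                                  paternal_reads = p), tissue, cfg)$status
  expect_equal(cls(18, 2, "embryo"), "MEG")     # frac 0.90 > 2/3, p < 0.05
  expect_equal(cls(2, 18, "embryo"), "PEG")
  expect_equal(cls(13, 7, "embryo"), "biallelic")  # frac 0.65 <= 2/3
  expect_equal(cls(40, 60, "endosperm"), "PEG")    # paternal 0.60 > 0.50
  expect_equal(cls(66, 34, "endosperm"), "biallelic")  # chi2 ~ 0.02
  expect_equal(cls(9, 10, "embryo"), "untestable")     # total 19 < 20
  expect_equal(cls(9, 10, "endosperm"), "untestable")

  # endosperm MEG needs > 80% maternal, not just significance:
  # 78/22 deviates from 2:1 (p < .05) but stays below the MEG bar
  expect_equal(cls(78, 22, "endosperm"), "biallelic")
  expect_equal(cls(85, 15, "endosperm"), "MEG")
})

test_that("thresholds are strict inequalities at the boundary", {
  cfg <- caller_config()
  # embryo: exactly 2/3 maternal must NOT pass the fraction bar even when
  # the chi-square is significant at this depth
  r <- classify_direction(data.frame(gene_id = "g", maternal_reads = 400,
                                     paternal_reads = 200), "embryo", cfg)
  expect_lt(r$p_value, 0.05)
  expect_equal(r$status, "biallelic")
  # one extra maternal read tips it over
  expect_equal(classify_direction(
    data.frame(gene_id = "g", maternal_reads = 401, paternal_reads = 200),
    "embryo", cfg)$status, "MEG")
  # endosperm PEG: exactly 50% paternal is not enough
  r2 <- classify_direction(data.frame(gene_id = "g", maternal_reads = 300,
                                      paternal_reads = 300), "endosperm", cfg)
  expect_equal(r2$status, "biallelic")
})

test_that("reciprocal combination is strict AND with untestable dominant", {
  cfg <- caller_config()
  mk <- function(m, p, tissue = "embryo")
    classify_direction(data.frame(gene_id = "g", maternal_reads = m,
                                  paternal_reads = p), tissue, cfg)
  comb <- function(d1, d2, ...) combine_reciprocal(d1, d2, "embryo", cfg, ...)$status

  expect_equal(comb(mk(18, 2), mk(45, 5)), "MEG")          # MEG + MEG
  expect_equal(comb(mk(2, 18), mk(5, 45)), "PEG")
  expect_equal(comb(mk(18, 2), mk(9, 10)), "untestable")   # MEG + untestable
  expect_equal(comb(mk(18, 2), mk(10, 10)), "biallelic")   # MEG + biallelic

  # founder-allele effect: the same founder is favored in both directions,
  # so maternal fractions are opposite -> allele-specific, not imprinted
  expect_equal(comb(mk(18, 2), mk(2, 18)), "biallelic")

  # pooled mode tests the summed counts instead
  expect_equal(comb(mk(18, 2), mk(14, 7), mode = "pooled",
                    counts1 = data.frame(gene_id = "g", maternal_reads = 18,
                                         paternal_reads = 2),
                    counts2 = data.frame(gene_id = "g", maternal_reads = 14,
                                         paternal_reads = 7)), "MEG")
  expect_error(combine_reciprocal(mk(18, 2), mk(5, 45)[0, ], "embryo", cfg),
               "different gene sets")
})

test_that("embryo labels are anti-symmetric under maternal/paternal swap", {
  cfg <- caller_config()
  set.seed(7)
  m1 <- sample(0:200, 100, TRUE); p1 <- sample(0:200, 100, TRUE)
  m2 <- sample(0:200, 100, TRUE); p2 <- sample(0:200, 100, TRUE)
  ids <- paste0("g", 1:100)
  call_pair <- function(a1, b1, a2, b2) {
    d1 <- classify_direction(data.frame(gene_id = ids, maternal_reads = a1,
                                        paternal_reads = b1), "embryo", cfg)
    d2 <- classify_direction(data.frame(gene_id = ids, maternal_reads = a2,
                                        paternal_reads = b2), "embryo", cfg)
    combine_reciprocal(d1, d2, "embryo", cfg)$status
  }
  orig <- call_pair(m1, p1, m2, p2)
  swapped <- call_pair(p1, m1, p2, m2)
  expect_equal(swapped[orig == "MEG"], rep("PEG", sum(orig == "MEG")))
  expect_equal(swapped[orig == "PEG"], rep("MEG", sum(orig == "PEG")))
  expect_equal(swapped[orig == "biallelic"],
               rep("biallelic", sum(orig == "biallelic")))
})

test_that("adding maternal reads at fixed total never demotes a MEG call", {
  cfg <- caller_config()
  for (tissue in c("embryo", "endosperm")) {
    for (tot in c(20, 47, 100)) {
      st <- classify_direction(
        data.frame(gene_id = paste0("g", 0:tot),
                   maternal_reads = 0:tot, paternal_reads = tot:0),
        tissue, cfg)$status
      meg <- st == "MEG"
      # MEG region is an upper tail in maternal reads: once reached, it stays
      if (any(meg)) expect_true(all(meg[min(which(meg)):length(meg)]))
    }
  }
})

test_that("call_all validates input and is invariant to gene order", {
  cfg <- sim_config(n_genes = 50, depth_mean = 100, seed = 30)
  truth <- generate_truth(cfg)
  design <- bc_pair_design()
  counts <- simulate_counts(truth, design, cfg)
  res <- call_all(counts, design)

  shuffled <- counts[sample(nrow(counts)), ]
  res2 <- call_all(shuffled, design)
  expect_equal(res$calls, res2$calls)

  expect_error(call_all(rbind(counts, counts[1, ]), design), "duplicate")
  expect_error(call_all(counts, design[1:3]), "exactly two directions")
  expect_error(call_all(counts[counts$sample_id != "BC.embryo", ], design),
               "missing counts")
})

test_that("all-untestable input yields no imprinted calls and no error", {
  cfg <- sim_config(n_genes = 20, frac_meg = 0, frac_peg = 0,
                    frac_untestable = 1, seed = 31)
  truth <- generate_truth(cfg)
  design <- bc_pair_design()
  res <- call_all(simulate_counts(truth, design, cfg), design)
  expect_true(all(res$calls$status == "untestable"))
})

test_that("tissue overlap reports genes imprinted in both tissues", {
  calls <- rbind(
    make_calls(c("g1", "g2", "g3"), "BC/CB", c("MEG", "PEG", "biallelic"),
               tissue = "embryo"),
    make_calls(c("g1", "g2", "g3"), "BC/CB", c("MEG", "biallelic", "PEG"),
               tissue = "endosperm"))
  ov <- tissue_overlap(calls)[["BC/CB"]]
  expect_setequal(ov$embryo, c("g1", "g2"))
  expect_setequal(ov$endosperm, c("g1", "g3"))
  expect_equal(ov$both, "g1")
})
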