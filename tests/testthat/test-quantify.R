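test_that("peptide filtering applies the strict majority rule per fraction", {
  n <- 26
  qGood <- rep(0.005, n)
  q14 <- c(rep(0.02, 14), rep(0.005, n - 14))   # bad in 14 of 26
  q13 <- c(rep(0.02, 13), rep(0.005, n - 13))   # bad in exactly half
  rep <- tinyReport(n, list(
    list(id = "pepA", protein = "P1", abundance = rep(10, n), qvalue = qGood),
    list(id = "pepB", protein = "P1", abundance = rep(10, n), qvalue = q14),
    list(id = "pepC", protein = "P1", abundance = rep(10, n), qvalue = q13)))
  out <- filterPeptides(rep)
  expect_setequal(unique(out$peptide), c("pepA", "pepC"))
  # idempotence
  expect_identical(filterPeptides(out), out)
})

test_that("filtering is scoped to the fraction", {
  n <- 4
  rep <- tinyReport(n, list(
    list(id = "pep", protein = "P1", fraction = "F1",
         abundance = rep(1, n), qvalue = rep(0.5, n)),
    list(id = "pep", protein = "P1", fraction = "F2",
         abundance = rep(2, n), qvalue = rep(0.001, n))))
  out <- filterPeptides(rep)
  expect_setequal(unique(out$fraction), "F2")
})

test_that("fractions combine by per-sample summation", {
  n <- 2
  rep <- tinyReport(n, list(
    list(id = "pep1", protein = "P1", fraction = "F1",
         abundance = c(3, 30), qvalue = rep(0, n)),
    list(id = "pep1", protein = "P1", fraction = "F2",
         abundance = c(5, 50), qvalue = rep(0, n)),
    list(id = "pep2", protein = "P2", fraction = "F1",
         abundance = c(7, 70), qvalue = rep(0, n))))
  out <- combineFractions(rep)
  expect_equal(out$abundance[out$peptide == "pep1" & out$sample == "S01"], 8)
  expect_equal(out$abundance[out$peptide == "pep1" & out$sample == "S02"], 80)
  expect_equal(out$abundance[out$peptide == "pep2" & out$sample == "S01"], 7)
})

test_that("a peptide mapped to two proteins is an error", {
  n <- 2
  rep <- tinyReport(n, list(
    list(id = "pep1", protein = "P1", fraction = "F1",
         abundance = c(1, 1), qvalue = rep(0, n)),
    list(id = "pep1", protein = "P2", fraction = "F2",
         abundance = c(1, 1), qvalue = rep(0, n))))
  expect_error(combineFractions(rep), "ambiguous")
})

test_that("rollup selects the overall top-k peptides for every sample", {
  # 7 peptides with overall totals 10, 8, 6, 4, 2, 1, 1
  totals <- c(10, 8, 6, 4, 2, 1, 1)
  n <- 2
  split <- rbind(totals * 0.25, totals * 0.75)
  peps <- lapply(seq_along(totals), function(i)
    list(id = sprintf("pep%02d", i), protein = "P1",
         abundance = split[, i], qvalue = rep(0, n)))
  comb <- combineFractions(tinyReport(n, peps))
  se <- rollupProteins(comb, top_k = 5)
  # brute-force oracle: rank by totals, sum top 5 per sample
  ord <- order(-totals)
  expected <- colSums(t(split)[ord[1:5], ])
  got <- SummarizedExperiment::assay(se, "abundance")["P1", ]
  expect_equal(unname(got), unname(expected))
})

test_that("rollup ties break lexicographically and small proteins use all", {
  n <- 2
  peps <- list(
    list(id = "pepB", protein = "P1", abundance = c(5, 5), qvalue = rep(0, n)),
    list(id = "pepA", protein = "P1", abundance = c(5, 5), qvalue = rep(0, n)),
    list(id = "pepC", protein = "P2", abundance = c(1, 2), qvalue = rep(0, n)),
    list(id = "pepD", protein = "P2", abundance = c(3, 4), qvalue = rep(0, n)),
    list(id = "pepE", protein = "P2", abundance = c(5, 6), qvalue = rep(0, n)))
  comb <- combineFractions(tinyReport(n, peps))
  se1 <- rollupProteins(comb, top_k = 1)
  m1 <- SummarizedExperiment::assay(se1, "abundance")
  expect_equal(unname(m1["P1", ]), c(5, 5))      # pepA wins the tie
  se <- rollupProteins(comb, top_k = 5)
  m <- SummarizedExperiment::assay(se, "abundance")
  expect_equal(unname(m["P2", ]), c(1 + 3 + 5, 2 + 4 + 6))
})

test_that("rollup is monotone in a selected peptide's abundance", {
  n <- 3
  base <- list(
    list(id = "pep1", protein = "P1", abundance = c(10, 10, 10),
         qvalue = rep(0, n)),
    list(id = "pep2", protein = "P1", abundance = c(5, 5, 5),
         qvalue = rep(0, n)))
  up <- base
  up[[1]]$abundance <- c(12, 10, 10)
  m0 <- SummarizedExperiment::assay(
    rollupProteins(combineFractions(tinyReport(n, base))), "abundance")
  m1 <- SummarizedExperiment::assay(
    rollupProteins(combineFractions(tinyReport(n, up))), "abundance")
  expect_true(all(m1["P1", ] >= m0["P1", ]))
})

test_that("total normalization equalizes column totals and is idempotent", {
  m <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 3,
              dimnames = list(paste0("P", 1:3), c("S1", "S2")))
  se <- asProteinSE(m)
  norm <- normalizeTotal(se, target = 6)
  mn <- SummarizedExperiment::assay(norm, "abundance")
  expect_equal(unname(colSums(mn)), c(6, 6))
  expect_equal(unname(mn[, "S2"]), c(1, 2, 3))   # sample at 2x target halved
  again <- SummarizedExperiment::assay(normalizeTotal(norm, 6), "abundance")
  expect_equal(again, mn)
  expect_lt(max(abs(colSums(mn) / 6 - 1)), 1e-9)
})

test_that("normalization errors on a zero-total sample, naming it", {
  m <- matrix(c(1, 2, 0, 0), nrow = 2,
              dimnames = list(paste0("P", 1:2), c("S1", "Sbad")))
  expect_error(normalizeTotal(asProteinSE(m)), "Sbad")
})

test_that("rescaling the normalization target leaves correlations unchanged", {
  sim <- latentBlockMatrix(c(10, 10), 5, nSamples = 12, seed = 4)
  se <- asProteinSE(2^sim$matrix)
  c1 <- cor(t(SummarizedExperiment::assay(
    normalizeTotal(se, 100), "abundance")))
  c2 <- cor(t(SummarizedExperiment::assay(
    normalizeTotal(se, 1e6), "abundance")))
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("the end-to-end quantification chain yields a complete matrix", {
  cfg <- simConfig(n_proteins = 120, module_sizes = c(30L, 20L),
                   module_effects = matrix(0, 2, 2),
                   hot_modules = character(0))
  sim <- simulatePeptideReport(cfg, seed = 5)
  se <- quantifyProteins(sim$report)
  m <- SummarizedExperiment::assay(se, "abundance")
  expect_false(anyNA(m))
  expect_true(all(m >= 0))
  tot <- colSums(m)
  expect_lt(max(abs(tot / mean(tot) - 1)), 1e-9)
})
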