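smallCfg <- function(...) {
  simConfig(n_proteins = 150, module_sizes = c(40L, 30L),
            module_effects = matrix(c(-0.6, 0.5, -0.3, 0.3), 2, 2,
              dimnames = list(c("M01", "M02"), c("tau", "tdp"))),
            hot_modules = character(0), ...)
}

test_that("the generator is byte-deterministic given a seed", {
  cfg <- smallCfg()
  s1 <- simulatePeptideReport(cfg, seed = 9)
  s2 <- simulatePeptideReport(cfg, seed = 9)
  expect_identical(s1$report, s2$report)
  expect_identical(s1$truth$module_of, s2$truth$module_of)
  s3 <- simulatePeptideReport(cfg, seed = 10)
  expect_false(identical(s1$report, s3$report))
})

test_that("config invariants are enforced", {
  expect_error(simConfig(n_proteins = 100, module_sizes = c(80L, 30L)),
               "exceeds")
  expect_error(simConfig(module_sizes = c(10L, 0L)), "positive")
  expect_error(simConfig(loading = 1.2), "loading")
  expect_error(simConfig(noise_sd = 0), "noise_sd")
  expect_error(simConfig(concordant_modules = "M99"), "unknown")
})

test_that("factor loading controls within- versus between-module correlation", {
  cfgNone <- simConfig(n_proteins = 120, module_sizes = c(30L, 30L),
                       module_effects = matrix(0, 2, 2),
                       hot_modules = character(0), loading = 0)
  simN <- simulatePeptideReport(cfgNone, seed = 11)
  xN <- simN$truth$protein_log2
  w <- which(simN$truth$module_of == "M01")
  rw <- cor(t(xN[w, ]))
  expect_lt(mean(abs(rw[upper.tri(rw)])), 0.25)   # noise bound at n=26

  cfgHi <- simConfig(n_proteins = 120, module_sizes = c(30L, 30L),
                     module_effects = matrix(0, 2, 2),
                     hot_modules = character(0),
                     loading = 0.9, noise_sd = 0.05)
  simH <- simulatePeptideReport(cfgHi, seed = 11)
  xH <- simH$truth$protein_log2
  w1 <- which(simH$truth$module_of == "M01")
  w2 <- which(simH$truth$module_of == "M02")
  rww <- cor(t(xH[w1, ]))
  rbb <- cor(t(xH[w1, ]), t(xH[w2, ]))
  expect_gt(mean(abs(rww[upper.tri(rww)])), mean(abs(rbb)))
})

test_that("bad peptides carry Q-values above 0.01 in a sample majority", {
  cfg <- smallCfg(bad_peptide_rate = 0.2)
  sim <- simulatePeptideReport(cfg, seed = 12)
  rep <- sim$report
  ns <- length(unique(rep$sample))
  perPep <- rep[, list(nbad = length(unique(sample[qvalue > 0.01]))),
                by = peptide]
  fracBad <- mean(perPep$nbad > ns / 2)
  expect_gt(fracBad, 0.1)
  expect_lt(fracBad, 0.3)
  # and the filter removes exactly those
  kept <- filterPeptides(rep)
  keptBad <- kept[, list(nbad = length(unique(sample[qvalue > 0.01]))),
                  by = peptide]
  expect_true(all(keptBad$nbad <= ns / 2))
})

test_that("abundances are strictly positive and keys unique", {
  sim <- simulatePeptideReport(smallCfg(), seed = 13)
  expect_true(all(sim$report$abundance > 0))
  expect_equal(anyDuplicated(sim$report,
                             by = c("sample", "fraction", "peptide")), 0)
  expect_true(all(sim$report$qvalue >= 0 & sim$report$qvalue <= 1))
})

test_that("validation statistics reproduce only concordant modules", {
  cfg <- smallCfg()
  sim <- simulatePeptideReport(cfg, seed = 14)
  # no concordant modules: signs agree about half the time for planted
  cfg0 <- smallCfg(concordant_modules = character(0))
  val0 <- simulateValidationStats(sim$truth, cfg0, seed = 15)
  planted <- names(sim$truth$module_of)[!is.na(sim$truth$module_of)]
  planted <- intersect(planted, val0$protein)
  trueSign <- sign(sim$truth$effects[sim$truth$module_of[planted], "tau"])
  agree <- mean(sign(val0$log2fc[match(planted, val0$protein)]) == trueSign)
  expect_gt(agree, 0.35); expect_lt(agree, 0.65)

  # all modules concordant with strong effects: >= 90% sign-concordant
  cfgS <- simConfig(n_proteins = 150, module_sizes = c(40L, 30L),
                    module_effects = matrix(c(-1, 1, -0.6, 0.6), 2, 2,
                      dimnames = list(c("M01", "M02"), c("tau", "tdp"))),
                    hot_modules = character(0),
                    concordant_modules = c("M01", "M02"))
  simS <- simulatePeptideReport(cfgS, seed = 16)
  valS <- simulateValidationStats(simS$truth, cfgS, seed = 17)
  plantedS <- intersect(names(simS$truth$module_of)[
    !is.na(simS$truth$module_of)], valS$protein)
  tS <- sign(simS$truth$effects[simS$truth$module_of[plantedS], "tau"])
  vs <- valS[match(plantedS, valS$protein), ]
  expect_gte(mean(sign(vs$log2fc) == tS & vs$pvalue < 0.1), 0.9)

  # zero dropout keeps the protein universe identical
  cfgD <- smallCfg(dropout = 0)
  valD <- simulateValidationStats(sim$truth, cfgD, seed = 18)
  expect_setequal(valD$protein, names(sim$truth$module_of))
  expect_error(simulateValidationStats(sim$truth, cfg, case_group = "zz"),
               "unknown case group")
})

test_that("annotation sets align with modules as requested", {
  sim <- simulatePeptideReport(smallCfg(), seed = 19)
  aligned <- simulateAnnotationSets(sim$truth, n_terms = 10, alignment = 1,
                                    jitter = 0, seed = 20)
  mem1 <- names(sim$truth$module_of)[which(sim$truth$module_of == "M01")]
  expect_setequal(as.character(aligned[[1]]), mem1)
  expect_error(simulateAnnotationSets(sim$truth, n_terms = 0), "n_terms")

  # alignment 0: overlaps follow the hypergeometric expectation
  rand <- simulateAnnotationSets(sim$truth, n_terms = 200, alignment = 0,
                                 size_range = c(20L, 20L), seed = 21)
  ov <- vapply(rand, function(s) length(intersect(s, mem1)), numeric(1))
  expected <- 20 * length(mem1) / 150
  expect_lt(abs(mean(ov) - expected), 0.5)
})

test_that("cell-type inputs give markers dominant specificity", {
  cfg <- simConfig(n_proteins = 150, module_sizes = c(40L, 30L),
                   module_effects = matrix(0, 2, 2),
                   hot_modules = character(0),
                   celltype_modules = c(M01 = "astrocytes", M02 = NA))
  sim <- simulatePeptideReport(cfg, seed = 22)
  ctin <- simulateCelltypeInputs(sim$truth, cfg, seed = 23)
  spec <- computeSpecificity(ctin$expression)
  # canonical markers dominate their own class
  for (ctype in names(cnsMarkerSet())) {
    own <- spec[cnsMarkerSet()[[ctype]], ctype, drop = FALSE]
    expect_true(all(own > 0.5))
  }
  expect_true("SLC17A7" %in% ctin$markers$excitatory_neurons)
  # non-marker, non-module genes are near-uniform
  bgGene <- setdiff(names(sim$truth$module_of),
                    c(unlist(ctin$markers),
                      names(sim$truth$module_of)[
                        !is.na(sim$truth$module_of)]))[1]
  expect_lt(max(spec[bgGene, ]), 0.35)
  # module-driven markers come from the mapped module and are disjoint
  expect_equal(anyDuplicated(unlist(ctin$markers)), 0)
  extra <- setdiff(ctin$markers$astrocytes, cnsMarkerSet()$astrocytes)
  expect_true(all(sim$truth$module_of[extra] == "M01"))
})
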