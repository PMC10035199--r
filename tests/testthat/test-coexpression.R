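test_that("similarity entries are |r|^power with exact arithmetic", {
  # orthogonal design gives cor(x, y) = 0.8 exactly
  x <- c(1, -1, 1, -1)
  z <- c(1, 1, -1, -1)
  y <- 0.8 * x + 0.6 * z
  m <- rbind(P1 = x, P2 = y, P3 = -y) + 10
  colnames(m) <- paste0("S", 1:4)
  se <- asProteinSE(m)
  s7 <- buildSimilarity(se, 7)
  expect_equal(unname(s7["P1", "P2"]), 0.8^7, tolerance = 1e-12)
  expect_equal(unname(s7["P1", "P3"]), 0.2097152, tolerance = 1e-12)
  expect_equal(unname(s7["P2", "P3"]), 1)        # r = -1
  expect_equal(unname(diag(s7)), rep(1, 3))
  s1 <- buildSimilarity(se, 1)
  expect_equal(unname(s1["P1", "P2"]), 0.8, tolerance = 1e-12)
})

test_that("zero-variance proteins get similarity 0 and are flagged", {
  m <- rbind(P1 = c(1, 2, 3, 4), P2 = rep(5, 4)) + 0
  colnames(m) <- paste0("S", 1:4)
  s <- buildSimilarity(asProteinSE(m), 7)
  expect_equal(unname(s["P1", "P2"]), 0)
  expect_identical(attr(s, "flagged"), "P2")
})

test_that("similarity is invariant to per-protein affine transforms", {
  sim <- latentBlockMatrix(c(10, 10), 4, nSamples = 10, seed = 2)
  se1 <- asProteinSE(sim$matrix)
  scaled <- sim$matrix * runif(nrow(sim$matrix), 0.5, 2) +
    rnorm(nrow(sim$matrix))
  se2 <- asProteinSE(scaled)
  expect_equal(buildSimilarity(se1, 7), buildSimilarity(se2, 7),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("scale-free fit index matches a direct regression", {
  set.seed(8)
  k <- rlnorm(200, 2, 0.8)
  idx <- scaleFreeFitIndex(k, n_bins = 10)
  bins <- cut(k, breaks = 10)
  freq <- tapply(k, bins, length)
  meank <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0
  fit <- lm(log10(freq[keep]) ~ log10(meank[keep]))
  expect_equal(unname(idx),
               unname(-sign(coef(fit)[2]) * summary(fit)$r.squared),
               tolerance = 1e-12)
})

test_that("pickSoftThreshold returns a power and honors fit_min", {
  sim <- latentBlockMatrix(c(40, 30, 20), 60, nSamples = 20, seed = 3)
  se <- asProteinSE(2^sim$matrix)
  pw <- suppressWarnings(pickSoftThreshold(se, powers = 1:10))
  expect_true(pw %in% 1:10)
  tab <- attr(pw, "fitTable")
  expect_equal(nrow(tab), 10)
  # pure-noise matrix: warning and argmax fallback
  noise <- latentBlockMatrix(integer(0), 80, nSamples = 12, seed = 4)
  expect_warning(pn <- pickSoftThreshold(asProteinSE(2^noise$matrix),
                                         powers = 1:6, fit_min = 0.99),
                 "best fit")
  tabN <- attr(pn, "fitTable")
  expect_equal(as.integer(pn), tabN$power[which.max(tabN$fit)])
})

test_that("module detection recovers planted blocks and orders labels", {
  sim <- latentBlockMatrix(c(60, 40, 30), 40, nSamples = 26, seed = 5)
  se <- asProteinSE(2^sim$matrix)
  asg <- detectModules(buildSimilarity(se, 7), min_size = 15)
  truth <- ifelse(is.na(sim$labels), "none", paste0("B", sim$labels))
  ari <- mclust::adjustedRandIndex(truth, moduleLabels(asg))
  expect_gte(ari, 0.9)
  sz <- moduleSizes(asg)
  real <- setdiff(names(sz), "M00")
  expect_true(all(diff(sz[real]) <= 0))
  # largest planted block is M01
  m01 <- moduleMembers(asg, "M01")
  expect_gt(mean(sim$labels[m01] == 1, na.rm = TRUE), 0.9)
})

test_that("independent proteins end up unassigned", {
  noise <- latentBlockMatrix(integer(0), 300, nSamples = 26, seed = 6)
  asg <- detectModules(buildSimilarity(asProteinSE(2^noise$matrix), 7),
                       min_size = 15)
  expect_gte(mean(moduleLabels(asg) == "M00"), 0.8)
})

test_that("module detection is permutation-equivariant", {
  sim <- latentBlockMatrix(c(30, 20), 15, nSamples = 20, seed = 7)
  s <- buildSimilarity(asProteinSE(2^sim$matrix), 7)
  asg1 <- detectModules(s, min_size = 10)
  set.seed(1)
  perm <- sample(nrow(s))
  asg2 <- detectModules(s[perm, perm], min_size = 10)
  lab1 <- moduleLabels(asg1)
  lab2 <- moduleLabels(asg2)[names(lab1)]
  # same partition: every module maps to exactly one module
  expect_equal(mclust::adjustedRandIndex(lab1, lab2), 1)
})

test_that("min_size larger than the matrix sends everything to M00", {
  sim <- latentBlockMatrix(c(10), 0, nSamples = 8, seed = 8)
  s <- buildSimilarity(asProteinSE(2^sim$matrix), 7)
  expect_warning(asg <- detectModules(s, min_size = 50), "M00")
  expect_true(all(moduleLabels(asg) == "M00"))
})

test_that("module dysregulation testing follows the one-sample t contract", {
  labels <- setNames(c(rep("M01", 100), rep("M02", 50), rep("M03", 10)),
                     sprintf("P%03d", 1:160))
  asg <- protmod:::newModuleAssignment(labels)
  set.seed(9)
  ct <- data.frame(protein = names(labels),
                   log2fc = c(rnorm(100, 0.5, 0.1),   # shifted module
                              rep(0, 50),             # degenerate module
                              rnorm(10, 0, 0.1)))     # null module
  ct$pvalue <- 0.5
  st <- testModuleDysregulation(asg, ct)
  m1 <- st[st$module == "M01", ]
  expect_true(m1$dysregulated)
  expect_lt(abs(m1$mean_log2fc - 0.5), 0.05)
  m2 <- st[st$module == "M02", ]
  expect_equal(m2$p_raw, 1)
  expect_true(m2$flagged)
  expect_false(m2$dysregulated)
  # BH never lowers below raw
  expect_true(all(st$p_bh >= st$p_raw - 1e-12))
  expect_identical(st$dysregulated, st$p_bh < 0.05)
})

test_that("a single tested module has p_bh equal to p_raw", {
  labels <- setNames(rep("M01", 20), sprintf("P%03d", 1:20))
  asg <- protmod:::newModuleAssignment(labels)
  set.seed(10)
  ct <- data.frame(protein = names(labels), log2fc = rnorm(20),
                   pvalue = 0.5)
  st <- testModuleDysregulation(asg, ct)
  expect_equal(st$p_bh, st$p_raw)
})
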