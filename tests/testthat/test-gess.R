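fourProteinTables <- function() {
  # (p_d, p_v, sign_d, sign_v) per protein:
  # (0.05, 0.08, +, +), (0.05, 0.2, +, +), (0.01, 0.01, +, -), (0.9, 0.9, +, +)
  disc <- data.frame(protein = c("P1", "P2", "P3", "P4"),
                     log2fc = c(1, 1, 1, 1),
                     pvalue = c(0.05, 0.05, 0.01, 0.9))
  val <- data.frame(protein = c("P1", "P2", "P3", "P4"),
                    log2fc = c(1, 1, -1, 1),
                    pvalue = c(0.08, 0.2, 0.01, 0.9))
  list(disc = disc, val = val)
}

test_that("the concordance fraction matches the hand-computed example", {
  tb <- fourProteinTables()
  mem <- tb$disc$protein
  expect_equal(concordanceFraction(mem, tb$disc, tb$val, 0.1), 0.25)
  expect_equal(concordanceFraction(mem, tb$disc, tb$val, 0.5), 0.5)
  # all tiny p and concordant: F = 1 at every threshold
  d2 <- data.frame(protein = mem, log2fc = -1, pvalue = 1e-6)
  v2 <- data.frame(protein = mem, log2fc = -2, pvalue = 1e-6)
  for (t in c(0.1, 0.2, 0.5, 0.8))
    expect_equal(concordanceFraction(mem, d2, v2, t), 1)
})

test_that("strict inequalities: zero log2FC counts as non-concordant", {
  d <- data.frame(protein = "P1", log2fc = 0, pvalue = 0.001)
  v <- data.frame(protein = "P1", log2fc = 2, pvalue = 0.001)
  expect_equal(concordanceFraction("P1", d, v, 0.5), 0)
  # p exactly at the threshold fails the strict comparison
  d2 <- data.frame(protein = "P1", log2fc = 1, pvalue = 0.1)
  v2 <- data.frame(protein = "P1", log2fc = 1, pvalue = 0.01)
  expect_equal(concordanceFraction("P1", d2, v2, 0.1), 0)
})

test_that("missing proteins are dropped from the denominator by default", {
  d <- data.frame(protein = c("P1", "P2"), log2fc = 1, pvalue = 0.01)
  v <- data.frame(protein = "P1", log2fc = 1, pvalue = 0.01)
  expect_equal(concordanceFraction(c("P1", "P2"), d, v, 0.5), 1)
  expect_equal(concordanceFraction(c("P1", "P2"), d, v, 0.5,
                                   missing = "fail"), 0.5)
  expect_error(concordanceFraction("P9", d, v, 0.5), "no module member")
})

test_that("F is monotone non-decreasing in t on random tables", {
  set.seed(14)
  for (rep_ in 1:1000) {
    n <- sample(4:30, 1)
    ids <- sprintf("P%03d", seq_len(n))
    d <- data.frame(protein = ids, log2fc = rnorm(n), pvalue = runif(n))
    v <- data.frame(protein = ids, log2fc = rnorm(n), pvalue = runif(n))
    f <- vapply(c(0.1, 0.2, 0.5, 0.8), function(t)
      concordanceFraction(ids, d, v, t), numeric(1))
    expect_true(all(diff(f) >= 0))
  }
})

test_that("gessScore is deterministic and its fractions sit in the result", {
  set.seed(20)
  n <- 300
  ids <- sprintf("P%03d", seq_len(n))
  d <- data.frame(protein = ids, log2fc = rnorm(n), pvalue = runif(n))
  v <- data.frame(protein = ids, log2fc = rnorm(n), pvalue = runif(n))
  mem <- ids[1:40]
  g1 <- gessScore(mem, d, v, n_perm = 200, seed = 3)
  g2 <- gessScore(mem, d, v, n_perm = 200, seed = 3)
  expect_identical(g1@fractions, g2@fractions)
  expect_identical(g1@pvalues, g2@pvalues)
  expect_identical(g1@score, g2@score)
  expect_equal(unname(g1@fractions),
               vapply(c(0.1, 0.2, 0.5, 0.8), function(t)
                 concordanceFraction(mem, d, v, t), numeric(1)))
  expect_equal(g1@moduleSize, 40L)
})

test_that("a module with no discovery signal is never validated", {
  n <- 200
  ids <- sprintf("P%03d", seq_len(n))
  set.seed(21)
  d <- data.frame(protein = ids, log2fc = rnorm(n),
                  pvalue = runif(n, 0.9, 1))
  v <- data.frame(protein = ids, log2fc = rnorm(n), pvalue = runif(n))
  g <- gessScore(ids[1:50], d, v, n_perm = 200, seed = 1)
  expect_equal(unname(g@fractions), rep(0, 4))
  expect_equal(g@score, 1)
  expect_false(isValidated(g))
})

test_that("a perfectly replicated dysregulated module validates", {
  set.seed(22)
  n <- 500
  ids <- sprintf("P%03d", seq_len(n))
  fc <- rnorm(n)
  p <- runif(n)
  mem <- ids[1:100]
  fc[1:100] <- rnorm(100, 2, 0.3)
  p[1:100] <- runif(100, 0, 0.01)
  d <- data.frame(protein = ids, log2fc = fc, pvalue = p)
  g <- gessScore(mem, d, d, n_perm = 500, seed = 2)   # validation = discovery
  expect_true(isValidated(g))
  expect_equal(g@fractionSameDirection, 1)
})

test_that("permutation modes are exposed and the t-test mode is literal", {
  set.seed(23)
  n <- 400
  ids <- sprintf("P%03d", seq_len(n))
  d <- data.frame(protein = ids, log2fc = rnorm(n), pvalue = runif(n))
  v <- data.frame(protein = ids, log2fc = rnorm(n), pvalue = runif(n))
  mem <- ids[1:30]
  for (mode in c("empirical", "zscore", "ttest")) {
    g <- gessScore(mem, d, v, n_perm = 200, seed = 4, mode = mode)
    expect_true(all(g@pvalues > 0 & g@pvalues <= 1))
  }
})

test_that("validateAllModules composes gessScore and summarizes cohorts", {
  set.seed(24)
  n <- 300
  ids <- sprintf("P%03d", seq_len(n))
  fc <- rnorm(n); p <- runif(n)
  fc[1:60] <- rnorm(60, 1.5, 0.2); p[1:60] <- runif(60, 0, 0.005)
  d <- data.frame(protein = ids, log2fc = fc, pvalue = p)
  vNull <- data.frame(protein = ids, log2fc = rnorm(n), pvalue = runif(n))
  labels <- setNames(c(rep("M01", 60), rep("M02", 40), rep("M00", 200)), ids)
  asg <- protmod:::newModuleAssignment(labels)
  tab <- validateAllModules(asg, d, list(good = d, null = vNull),
                            n_perm = 300)
  expect_equal(nrow(tab), 4)          # 2 modules x 2 cohorts
  m1good <- tab[tab$module == "M01" & tab$cohort == "good", ]
  expect_true(m1good$validated)
  expect_equal(tab$validated_in[tab$module == "M01"][1],
               sum(tab$validated[tab$module == "M01"]))
  # empty overlap: cohort missing all members is skipped with a warning
  vMiss <- data.frame(protein = paste0("X", 1:10), log2fc = 1,
                      pvalue = 0.5)
  w <- capture_warnings(
    tab2 <- validateAllModules(asg, d, list(m = vMiss), n_perm = 300))
  expect_length(w, 2)            # one per skipped module
  expect_true(all(grepl("skipped", w)))
  expect_equal(nrow(tab2), 0)
})
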