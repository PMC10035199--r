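#' Scale-free fit of candidate soft-thresholding powers
#'
#' For each candidate power, builds the soft similarity
#' \eqn{s_{ij} = |r_{ij}|^\beta}, computes node connectivities
#' \eqn{k_i = \sum_{j \ne i} s_{ij}}, bins \eqn{\log_{10} k} and regresses
#' log-frequency on log-connectivity. The scale-free fit index is
#' \eqn{-\mathrm{sign}(slope)\, R^2}, so a decaying degree distribution
#' scores positively. Returns the smallest power whose fit reaches
#' `fit_min`, or the power maximizing the fit (with a warning) when none
#' does.
#'
#' @param se protein matrix (`SummarizedExperiment`).
#' @param powers candidate integer powers (default 1:12).
#' @param fit_min required fit index (default 0.8).
#' @param n_bins connectivity histogram bins (default 10).
#' @return chosen power, with the per-power fit table in
#'   `attr(, "fitTable")`.
#' @export
pickSoftThreshold <- function(se, powers = 1:12, fit_min = 0.8,
                              n_bins = 10L) {
  m <- SummarizedExperiment::assay(se, "abundance")
  if (nrow(m) < 30L) stop("need at least 30 proteins")
  absr <- abs(cor(t(m)))
  diag(absr) <- 0
  fits <- vapply(powers, function(b)
    scaleFreeFitIndex(rowSums(absr^b), n_bins), numeric(1))
  tab <- data.frame(power = powers, fit = fits)
  ok <- which(fits >= fit_min)
  chosen <- if (length(ok)) {
    powers[ok[1L]]
  } else {
    warning("no candidate power reaches fit_min; returning the best fit")
    powers[which.max(fits)]
  }
  attr(chosen, "fitTable") <- tab
  chosen
}

#' @describeIn pickSoftThreshold Scale-free topology fit index of a
#'   connectivity vector: signed \eqn{R^2} of the log-log regression of
#'   binned frequency on mean connectivity.
#' @param k vector of node connectivities.
#' @export
scaleFreeFitIndex <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) {
    warning("degenerate connectivity; fit index 0")
    return(0)
  }
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  meank <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3L) return(0)
  fit <- lm(log10(freq[keep]) ~ log10(meank[keep]))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2]) * r2
}

#' Soft-powered correlation similarity matrix
#'
#' \eqn{s_{ij} = |\mathrm{cor}(x_i, x_j)|^{\beta}} with unit diagonal.
#' Zero-variance proteins have undefined correlations; these are set to 0
#' and reported in `attr(, "flagged")`.
#'
#' @param se protein matrix with at least 3 samples.
#' @param soft_power positive integer exponent (default 7).
#' @return symmetric numeric matrix with entries in \[0, 1\], carrying
#'   `soft_power` as an attribute.
#' @export
buildSimilarity <- function(se, soft_power = 7L) {
  m <- SummarizedExperiment::assay(se, "abundance")
  if (ncol(m) < 3L) stop("need at least 3 samples")
  sds <- apply(m, 1, sd)
  flagged <- rownames(m)[sds == 0]
  suppressWarnings(r <- cor(t(m)))
  r[!is.finite(r)] <- 0
  s <- abs(r)^soft_power
  diag(s) <- 1
  attr(s, "soft_power") <- soft_power
  attr(s, "flagged") <- flagged
  s
}

#' Detect co-expression modules by adaptive tree cut
#'
#' Builds the dissimilarity \eqn{1 - s}, grows an average-linkage tree
#' over proteins and prunes its branches adaptively: the cut height is a
#' `deep_split`-dependent fraction of the maximum merge height, so the
#' separation between branches is judged relative to the tree's own
#' scale rather than at a fixed dissimilarity. Maximal branches joining
#' the tree above the cut that hold at least `min_size` proteins become
#' modules, labelled `"M01"`, `"M02"`, ... by decreasing size (ties by
#' first protein id); everything else -- undersized branches and leaves
#' only attaching near the top of the tree -- is collected in `"M00"`.
#'
#' @param similarity matrix from [buildSimilarity()].
#' @param min_size minimum module size (default 15).
#' @param deep_split split sensitivity 0-3 (default 2); larger values cut
#'   closer to the top of the tree and so separate more, finer branches.
#' @return a [ModuleAssignment-class].
#' @export
detectModules <- function(similarity, min_size = 15L, deep_split = 2L) {
  stopifnot(nrow(similarity) == ncol(similarity))
  proteins <- rownames(similarity)
  n <- length(proteins)
  if (min_size > n) {
    warning("min_size exceeds the number of proteins; everything is M00")
    return(newModuleAssignment(setNames(rep("M00", n), proteins)))
  }
  deep_split <- max(0L, min(3L, as.integer(deep_split)))
  tree <- hclust(as.dist(1 - similarity), method = "average")
  maxH <- max(tree$height)
  cutFrac <- c(0.90, 0.93, 0.95, 0.97)[deep_split + 1L]
  cutHeight <- cutFrac * maxH

  # maximal branches joining the tree above the cut height are the module
  # candidates; those below min_size (and singleton leaves cut off near
  # the top) fall into M00
  cl <- cutree(tree, h = cutHeight)
  labels <- setNames(rep("M00", n), proteins)
  tab <- table(cl)
  keep <- names(tab)[tab >= min_size]
  if (length(keep)) {
    firstId <- vapply(keep, function(k) min(proteins[cl == k]),
                      character(1))
    ord <- keep[order(-tab[keep], firstId)]
    for (i in seq_along(ord))
      labels[cl == as.integer(ord[i])] <- sprintf("M%02d", i)
  }
  newModuleAssignment(labels)
}

newModuleAssignment <- function(labels) {
  tab <- table(labels)
  real <- setdiff(names(tab), "M00")
  sizes <- as.integer(tab[real])
  names(sizes) <- real
  sizes <- sizes[order(names(sizes))]
  if ("M00" %in% names(tab))
    sizes <- c(sizes, M00 = as.integer(tab[["M00"]]))
  new("ModuleAssignment", labels = labels, sizes = sizes)
}

#' Per-module dysregulation test
#'
#' For each module (M00 excluded), performs a two-sided one-sample
#' Student t-test of the member proteins' log2 fold changes against zero
#' and applies Benjamini-Hochberg correction across the modules of the
#' contrast. A module whose members' log2FC values are constant (t
#' undefined) or that has fewer than 3 members is flagged and given p = 1.
#'
#' @param assignment a [ModuleAssignment-class].
#' @param contrast a contrast result (`data.frame` with `protein, log2fc,
#'   pvalue`).
#' @return `data.frame` with columns `module, n, mean_log2fc,
#'   t_statistic, p_raw, p_bh, dysregulated, flagged`.
#' @export
testModuleDysregulation <- function(assignment, contrast) {
  labels <- moduleLabels(assignment)
  modules <- setdiff(names(moduleSizes(assignment)), "M00")
  rows <- lapply(modules, function(m) {
    members <- names(labels)[labels == m]
    fc <- contrast$log2fc[match(members, contrast$protein)]
    fc <- fc[is.finite(fc)]
    if (length(fc) < 3L || sd(fc) == 0) {
      return(data.frame(module = m, n = length(fc),
                        mean_log2fc = if (length(fc)) mean(fc) else NA_real_,
                        t_statistic = NA_real_, p_raw = 1,
                        flagged = TRUE))
    }
    tt <- t.test(fc, mu = 0)
    data.frame(module = m, n = length(fc), mean_log2fc = mean(fc),
               t_statistic = unname(tt$statistic), p_raw = tt$p.value,
               flagged = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bh <- p.adjust(res$p_raw, method = "BH")
  res$dysregulated <- res$p_bh < 0.05
  res[, c("module", "n", "mean_log2fc", "t_statistic",
          "p_raw", "p_bh", "dysregulated", "flagged")]
}
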