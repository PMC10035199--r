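#' Cell-type specificity matrix
#'
#' Row-normalizes a gene-by-cell-type mean-expression table: the
#' specificity of gene g in cell type c is g's mean expression in c
#' divided by the sum of g's mean expression over all cell types, so
#' rows sum to one. Genes with all-zero expression are dropped with a
#' warning; negative entries are an error.
#'
#' @param expression numeric matrix, genes x cell types (>= 2 columns).
#' @return specificity matrix with rows summing to 1.
#' @export
computeSpecificity <- function(expression) {
  expression <- as.matrix(expression)
  if (ncol(expression) < 2L) stop("need at least 2 cell types")
  if (any(expression < 0)) stop("expression must be non-negative")
  totals <- rowSums(expression)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " gene(s) with all-zero expression dropped")
    expression <- expression[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  expression / totals
}

#' Bootstrap expression-weighted cell-type enrichment
#'
#' For each cell type, compares the mean specificity of a target gene
#' list against `n_boot` random lists of the same size drawn uniformly
#' without replacement from the background. Reports the observed mean,
#' the bootstrap mean and standard deviation, the standardized score
#' \eqn{z = (obs - mean) / sd} and the empirical p-value
#' \eqn{(1 + \#\{boot \ge obs\}) / (1 + n_{boot})}.
#'
#' @param target character vector of target genes (non-empty, contained
#'   in `background`; duplicates are removed).
#' @param specificity matrix from [computeSpecificity()].
#' @param background character vector of background genes (contained in
#'   the specificity rows).
#' @param n_boot number of bootstrap lists (default 20000).
#' @param seed integer seed.
#' @return `data.frame` with one row per cell type: `cell_type,
#'   observed, boot_mean, boot_sd, z, p`.
#' @export
ewceBootstrap <- function(target, specificity, background,
                          n_boot = 20000L, seed = 1L) {
  target <- unique(target)
  background <- unique(background)
  if (!length(target)) stop("empty target list")
  if (!all(background %in% rownames(specificity)))
    stop("background gene(s) missing from the specificity matrix")
  if (!all(target %in% background))
    stop("target must be contained in the background")
  m <- length(target)
  spec <- specificity[background, , drop = FALSE]
  obs <- colMeans(spec[target, , drop = FALSE])

  set.seed(seed)
  # flat index draws averaged by list via rowsum, chunked to bound memory
  chunk <- max(1L, min(n_boot, ceiling(2e6 / m)))
  bootMeans <- do.call(rbind, lapply(
    split(seq_len(n_boot), ceiling(seq_len(n_boot) / chunk)),
    function(bs) {
      idx <- unlist(lapply(bs, function(b)
        sample.int(length(background), m)), use.names = FALSE)
      rowsum(spec[idx, , drop = FALSE],
             rep(seq_along(bs), each = m)) / m
    }))

  bootMean <- colMeans(bootMeans)
  bootSd <- apply(bootMeans, 2, sd)
  z <- ifelse(bootSd > 0, (obs - bootMean) / bootSd, NA_real_)
  p <- vapply(seq_along(obs), function(j)
    (1 + sum(bootMeans[, j] >= obs[j])) / (1 + n_boot), numeric(1))
  data.frame(cell_type = colnames(spec), observed = unname(obs),
             boot_mean = unname(bootMean), boot_sd = unname(bootSd),
             z = unname(z), p = unname(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Directional marker enrichment within a module
#'
#' For each cell type with at least one marker among the module members,
#' compares the log2 fold changes of the in-module markers against all
#' other module members with a two-sided Wilcoxon rank-sum test.
#' Direction is `"up"` when the marker median log2FC exceeds the
#' non-marker median (the cell type's proteins are relatively more
#' abundant in the case group), `"down"` otherwise; p-values are
#' BH-corrected across the cell types tested. Cell types represented by
#' a single in-module marker are flagged low-power.
#'
#' @param module_members character vector of module protein ids.
#' @param contrast contrast result (`protein, log2fc, pvalue`).
#' @param markers named list cell type -> marker tokens.
#' @return `data.frame` with columns `cell_type, n_markers, direction,
#'   median_marker, median_other, p_raw, p_bh, low_power`; zero rows
#'   (with a warning) when no marker of any cell type is in the module.
#' @export
markerDirectionEnrichment <- function(module_members, contrast, markers) {
  fc <- setNames(contrast$log2fc, contrast$protein)
  members <- intersect(module_members, names(fc))
  rows <- list()
  for (ct in names(markers)) {
    inMod <- intersect(markers[[ct]], members)
    if (!length(inMod)) next
    others <- setdiff(members, inMod)
    if (!length(others)) next
    mfc <- fc[inMod]
    ofc <- fc[others]
    wt <- suppressWarnings(wilcox.test(mfc, ofc))
    rows[[ct]] <- data.frame(
      cell_type = ct, n_markers = length(inMod),
      direction = if (median(mfc) > median(ofc)) "up" else "down",
      median_marker = median(mfc), median_other = median(ofc),
      p_raw = wt$p.value, low_power = length(inMod) < 2L)
  }
  if (!length(rows)) {
    warning("no cell-type marker found among the module members")
    return(data.frame(cell_type = character(), n_markers = integer(),
                      direction = character(), median_marker = numeric(),
                      median_other = numeric(), p_raw = numeric(),
                      p_bh = numeric(), low_power = logical()))
  }
  res <- do.call(rbind, rows)
  res$p_bh <- p.adjust(res$p_raw, method = "BH")
  rownames(res) <- NULL
  res[, c("cell_type", "n_markers", "direction", "median_marker",
          "median_other", "p_raw", "p_bh", "low_power")]
}
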