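#' Filter peptides on identification quality
#'
#' Within each chromatographic fraction, a peptide is discarded when its
#' Q-value exceeds `q_max` in strictly more than `sample_fraction` of the
#' samples; all other records pass through unchanged. The sample count is
#' the number of distinct samples in the report, so a peptide observed in
#' only a few samples is judged against the full cohort.
#'
#' @param report peptide report (`data.frame`/`data.table` with columns
#'   `sample, group, fraction, peptide, protein, abundance, qvalue`).
#' @param q_max Q-value cutoff (default 0.01).
#' @param sample_fraction fraction of samples allowed to fail (default
#'   0.5; a peptide failing in exactly half of the samples is retained).
#' @return filtered peptide report (`data.table`).
#' @export
filterPeptides <- function(report, q_max = 0.01, sample_fraction = 0.5) {
  if (q_max <= 0 || q_max >= 1 || sample_fraction <= 0 ||
      sample_fraction >= 1)
    stop("thresholds must lie in (0, 1)")
  dt <- validatePeptideReport(report)
  if (nrow(dt) == 0L) {
    warning("empty peptide report")
    return(dt)
  }
  nSamples <- length(unique(dt$sample))
  limit <- sample_fraction * nSamples
  nbad <- qvalue <- fraction <- peptide <- NULL  # R CMD check
  bad <- dt[, list(nbad = sum(qvalue > q_max)), by = list(fraction, peptide)]
  bad <- bad[nbad > limit]
  if (nrow(bad) == 0L) return(dt)
  dt[!bad, on = c("fraction", "peptide")]
}

#' Combine fractions by summation
#'
#' Sums same-peptide abundances over fractions within each sample,
#' yielding one record per (sample, peptide). The peptide-to-protein map
#' must be unambiguous; a peptide mapped to two proteins is an error.
#'
#' @param report a (typically filtered) peptide report.
#' @return `data.table` with columns `sample, group, peptide, protein,
#'   abundance`.
#' @export
combineFractions <- function(report) {
  dt <- data.table::as.data.table(report)
  peptide <- protein <- abundance <- NULL
  nprot <- dt[, list(n = length(unique(protein))), by = peptide]
  if (any(nprot$n > 1L))
    stop("ambiguous rollup: peptide(s) mapped to multiple proteins: ",
         paste(head(nprot$peptide[nprot$n > 1L], 3L), collapse = ", "))
  dt[, list(abundance = sum(abundance)),
     by = list(sample, group, peptide, protein)]
}

#' Roll peptides up to protein abundances (top-k summation)
#'
#' For each protein, its peptides are ranked once by total abundance
#' summed over all samples (ties broken by peptide id) and the same top-k
#' set is summed in every sample. Proteins with at most `top_k` peptides
#' use all of them; a peptide missing from a sample contributes zero.
#'
#' @param peptideTable fraction-combined table from [combineFractions()].
#' @param top_k number of peptides summed per protein (default 5).
#' @return a `SummarizedExperiment` with assay `"abundance"` (protein x
#'   sample) and colData column `group`.
#' @export
rollupProteins <- function(peptideTable, top_k = 5L) {
  dt <- data.table::as.data.table(peptideTable)
  peptide <- protein <- abundance <- total <- NULL
  totals <- dt[, list(total = sum(abundance)), by = list(protein, peptide)]
  data.table::setorder(totals, protein, -total, peptide)
  totals[, rank := seq_len(.N), by = protein]
  selected <- totals[rank <= top_k, list(protein, peptide)]
  sel <- dt[selected, on = c("protein", "peptide")]
  samples <- sort(unique(dt$sample))
  groupOf <- setNames(dt$group[match(samples, dt$sample)], samples)
  agg <- sel[, list(abundance = sum(abundance)),
             by = list(protein, sample)]
  wide <- data.table::dcast(agg, protein ~ sample,
                            value.var = "abundance", fill = 0)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$protein
  m <- m[, samples, drop = FALSE]
  makeProteinMatrix(m, groupOf)
}

#' Normalize samples to a common total protein abundance
#'
#' Scales each sample (column) so that all column totals are equal,
#' leaving relative abundances within a sample unchanged. LC-MS/MS
#' measures relative rather than absolute abundance, so downstream
#' statistics are invariant to the choice of target.
#'
#' @param se protein matrix (`SummarizedExperiment`).
#' @param target common column total, or `"mean"` (default) for the mean
#'   of the input totals.
#' @return the rescaled `SummarizedExperiment`.
#' @export
normalizeTotal <- function(se, target = "mean") {
  m <- SummarizedExperiment::assay(se, "abundance")
  totals <- colSums(m)
  if (any(totals <= 0))
    stop("zero-total sample(s): ",
         paste(colnames(m)[totals <= 0], collapse = ", "))
  tval <- if (identical(target, "mean")) mean(totals) else as.numeric(target)
  m <- sweep(m, 2, tval / totals, `*`)
  SummarizedExperiment::assay(se, "abundance") <- m
  se
}

#' Peptide report to normalized protein matrix
#'
#' Convenience chain: [filterPeptides()] -> [combineFractions()] ->
#' [rollupProteins()] -> [normalizeTotal()].
#'
#' @inheritParams filterPeptides
#' @inheritParams rollupProteins
#' @inheritParams normalizeTotal
#' @return normalized protein matrix (`SummarizedExperiment`).
#' @export
quantifyProteins <- function(report, q_max = 0.01, sample_fraction = 0.5,
                             top_k = 5L, target = "mean") {
  filtered <- filterPeptides(report, q_max, sample_fraction)
  combined <- combineFractions(filtered)
  normalizeTotal(rollupProteins(combined, top_k), target)
}
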