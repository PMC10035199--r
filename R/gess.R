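## Align discovery/validation statistics over a module's members.
## Members missing from either cohort are dropped (default policy) or
## retained as guaranteed failures.
.alignModuleStats <- function(module_members, discovery, validation,
                              missing = c("drop", "fail")) {
  missing <- match.arg(missing)
  di <- match(module_members, discovery$protein)
  vi <- match(module_members, validation$protein)
  present <- !is.na(di) & !is.na(vi)
  if (missing == "drop") {
    list(pd = discovery$pvalue[di[present]],
         pv = validation$pvalue[vi[present]],
         fcd = discovery$log2fc[di[present]],
         fcv = validation$log2fc[vi[present]],
         n = sum(present))
  } else {
    pd <- ifelse(present, discovery$pvalue[di], 1)
    pv <- ifelse(present, validation$pvalue[vi], 1)
    list(pd = pd, pv = pv,
         fcd = ifelse(present, discovery$log2fc[di], 0),
         fcv = ifelse(present, validation$log2fc[vi], 0),
         n = length(module_members))
  }
}

#' Cross-cohort concordance fraction of a module
#'
#' Evaluates
#' \deqn{F_{m,t} = \frac{\sum_{P \in m} 1\,[\,p_{P,d} < t \wedge
#'   p_{P,v} < t \wedge FC_{P,d}\cdot FC_{P,v} > 0\,]}{N_m},}
#' the fraction of module proteins significant below `t` in both the
#' discovery and validation cohort with same-direction log2 fold change.
#' Inequalities are strict; a log2FC of exactly zero therefore counts as
#' non-concordant. Module members missing from either cohort are, by
#' default, excluded from both the numerator and \eqn{N_m}.
#'
#' @param module_members character vector of the module's protein ids.
#' @param discovery,validation contrast results (`data.frame` with
#'   columns `protein, log2fc, pvalue`).
#' @param t p-value threshold.
#' @param missing `"drop"` (default) or `"fail"` (count missing proteins
#'   as non-concordant).
#' @return the fraction in \[0, 1\].
#' @export
concordanceFraction <- function(module_members, discovery, validation, t,
                                missing = c("drop", "fail")) {
  st <- .alignModuleStats(module_members, discovery, validation, missing)
  if (st$n == 0L) stop("no module member is scored in both cohorts")
  sum(st$pd < t & st$pv < t & st$fcd * st$fcv > 0) / st$n
}

#' GESS score of one module against one validation cohort
#'
#' Computes the observed concordance fraction \eqn{F_{m,t}} at each
#' threshold, then permutes the validation cohort's protein labels over
#' the shared protein universe `n_perm` times, recomputing \eqn{F_{m,t}}
#' each time. Each threshold receives a one-sided p-value for the
#' observed fraction exceeding the permutation null; the GESS score is
#' the mean of the per-threshold p-values and the module is validated
#' when it falls below 0.05.
#'
#' Three p-value modes are provided. `"empirical"` (default) uses the
#' standard permutation estimate \eqn{(1 + \#\{F^{perm} \ge F^{obs}\}) /
#' (1 + n_{perm})}, which is calibrated under the null. `"zscore"`
#' standardizes the observed fraction by the permutation mean and
#' standard deviation and takes the upper normal tail. `"ttest"` is the
#' literal one-sample t-test of the permuted fractions against the
#' observed value (alternative: permuted mean smaller); because its
#' standard error shrinks with \eqn{n_{perm}} it degenerates towards a
#' 0/1 indicator and is not calibrated -- it is kept as a documented
#' alternative, not the default.
#'
#' @inheritParams concordanceFraction
#' @param thresholds p-value thresholds (default `c(0.1, 0.2, 0.5, 0.8)`).
#' @param n_perm number of label permutations (default 1000, minimum 100).
#' @param seed integer seed.
#' @param mode p-value mode, see Details.
#' @param module module label used for reporting.
#' @return a [GessResult-class].
#' @export
gessScore <- function(module_members, discovery, validation,
                      thresholds = c(0.1, 0.2, 0.5, 0.8),
                      n_perm = 1000L, seed = 1L,
                      mode = c("empirical", "zscore", "ttest"),
                      missing = c("drop", "fail"),
                      module = "module") {
  mode <- match.arg(mode)
  missing <- match.arg(missing)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  if (n_perm < 100L) stop("need at least 100 permutations")
  thresholds <- sort(thresholds)

  st <- .alignModuleStats(module_members, discovery, validation, missing)
  if (st$n == 0L) stop("no module member is scored in both cohorts")
  Fobs <- vapply(thresholds, function(t)
    sum(st$pd < t & st$pv < t & st$fcd * st$fcv > 0) / st$n, numeric(1))
  names(Fobs) <- paste0("t", thresholds)

  # permutation: validation (p, log2FC) pairs reassigned to labels by a
  # uniform permutation of the shared universe; restricted to the module
  # this is a uniform draw of n_m pairs without replacement
  shared <- intersect(discovery$protein, validation$protein)
  vp <- validation$pvalue[match(shared, validation$protein)]
  vfc <- validation$log2fc[match(shared, validation$protein)]
  nU <- length(shared)

  set.seed(seed)
  nt <- length(thresholds)
  Fperm <- matrix(0, n_perm, nt)
  pdLt <- outer(st$pd, thresholds, `<`)        # n_m x nt, fixed
  for (b in seq_len(n_perm)) {
    ix <- sample.int(nU, st$n)
    okSign <- st$fcd * vfc[ix] > 0
    pvB <- vp[ix]
    for (j in seq_len(nt))
      Fperm[b, j] <- sum(pdLt[, j] & pvB < thresholds[j] & okSign)
  }
  Fperm <- Fperm / st$n

  pvals <- vapply(seq_len(nt), function(j) {
    fp <- Fperm[, j]
    switch(mode,
      empirical = (1 + sum(fp >= Fobs[j])) / (1 + n_perm),
      zscore = {
        sdv <- sd(fp)
        if (sdv == 0) (1 + sum(fp >= Fobs[j])) / (1 + n_perm)
        else pnorm((Fobs[j] - mean(fp)) / sdv, lower.tail = FALSE)
      },
      ttest = {
        if (sd(fp) == 0) (1 + sum(fp >= Fobs[j])) / (1 + n_perm)
        else t.test(fp, mu = Fobs[j], alternative = "less")$p.value
      })
  }, numeric(1))
  names(pvals) <- names(Fobs)
  pvals <- pmin(pmax(pvals, .Machine$double.xmin), 1)

  if (all(Fobs == 0)) {
    score <- 1
    pvals[] <- 1
  } else {
    score <- mean(pvals)
  }
  new("GessResult", module = module, thresholds = thresholds,
      fractions = Fobs, pvalues = pvals, score = score,
      validated = score < 0.05, moduleSize = as.integer(st$n),
      nPerm = as.integer(n_perm),
      fractionSameDirection = sum(st$fcd * st$fcv > 0) / st$n)
}

#' Validate every module against one or more cohorts
#'
#' Runs [gessScore()] for each module (M00 excluded) against each named
#' validation cohort and summarizes, per module, in how many cohorts it
#' validated (mirroring the one-asterisk / two-asterisk convention for
#' "validated in one" / "validated in both").
#'
#' @param assignment a [ModuleAssignment-class].
#' @param discovery discovery contrast result.
#' @param validation_list named list of validation contrast results.
#' @param ... passed to [gessScore()] (`thresholds`, `n_perm`, `mode`,
#'   `missing`).
#' @param seed integer seed; each (module, cohort) pair gets a distinct
#'   sub-seed derived from it.
#' @return `data.frame` with one row per module x cohort: `module,
#'   cohort, n, F` at each threshold, `p` at each threshold,
#'   `gess, validated`, plus the per-module summary `validated_in`
#'   (number of cohorts) replicated across rows. Modules with no overlap
#'   with a cohort's universe are skipped with a warning.
#' @export
validateAllModules <- function(assignment, discovery, validation_list,
                               seed = 1L, ...) {
  if (!length(validation_list)) stop("need at least one validation cohort")
  if (is.null(names(validation_list)))
    names(validation_list) <- paste0("cohort", seq_along(validation_list))
  labels <- moduleLabels(assignment)
  modules <- setdiff(names(moduleSizes(assignment)), "M00")
  rows <- list()
  k <- 0L
  for (m in modules) {
    members <- names(labels)[labels == m]
    for (ci in seq_along(validation_list)) {
      cohort <- names(validation_list)[ci]
      val <- validation_list[[ci]]
      k <- k + 1L
      if (!any(members %in% val$protein)) {
        warning("module ", m, " absent from cohort ", cohort, "; skipped")
        next
      }
      res <- gessScore(members, discovery, val,
                       seed = seed + 1000L * k, module = m, ...)
      row <- data.frame(module = m, cohort = cohort, n = res@moduleSize,
                        gess = res@score, validated = res@validated,
                        fraction_same_direction =
                          res@fractionSameDirection)
      for (j in seq_along(res@thresholds)) {
        row[[paste0("F_t", res@thresholds[j])]] <- res@fractions[j]
        row[[paste0("p_t", res@thresholds[j])]] <- res@pvalues[j]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows))
    return(data.frame(module = character(), cohort = character()))
  out <- do.call(rbind, rows)
  nval <- tapply(out$validated, out$module, sum)
  out$validated_in <- as.integer(nval[out$module])
  rownames(out) <- NULL
  out
}
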