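## Beta-binomial log-likelihood of counts y out of totals n with mean
## proportion pi and precision theta (alpha = pi*theta, beta = (1-pi)*theta).
.bbLoglik <- function(y, n, pi, theta) {
  a <- pi * theta
  b <- (1 - pi) * theta
  sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
}

.logistic <- function(x) 1 / (1 + exp(-x))

## ML fit under H0 (one proportion) for one protein.
.bbFitNull <- function(y, n) {
  piHat <- max(min(sum(y) / sum(n), 1 - 1e-12), 1e-12)
  nll <- function(par)
    -.bbLoglik(y, n, .logistic(par[1]), exp(par[2]))
  start <- c(log(piHat / (1 - piHat)), log(1e3))
  fit <- try(optim(start, nll, method = "L-BFGS-B",
                   lower = c(-40, -2), upper = c(40, 30)), silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value)) return(NULL)
  list(loglik = -fit$value, par = fit$par)
}

## ML fit under H1 (group-specific proportions, common dispersion).
.bbFitAlt <- function(y, n, grp, startTheta) {
  p1 <- max(min(sum(y[grp]) / sum(n[grp]), 1 - 1e-12), 1e-12)
  p2 <- max(min(sum(y[!grp]) / sum(n[!grp]), 1 - 1e-12), 1e-12)
  nll <- function(par) {
    pis <- ifelse(grp, .logistic(par[1]), .logistic(par[2]))
    theta <- exp(par[3])
    a <- pis * theta
    b <- (1 - pis) * theta
    -sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
  }
  start <- c(log(p1 / (1 - p1)), log(p2 / (1 - p2)), startTheta)
  fit <- try(optim(start, nll, method = "L-BFGS-B",
                   lower = c(-40, -40, -2), upper = c(40, 40, 30)),
             silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value)) return(NULL)
  list(loglik = -fit$value)
}

#' Beta-binomial differential abundance test
#'
#' Tests each protein for a difference in relative abundance between two
#' groups. Normalized abundances are converted to integer pseudo-counts
#' (rounded after global rescaling so the median sample total is about
#' `1e6 * scale`), with per-sample totals as trial counts. For each
#' protein a beta-binomial model with common dispersion is fitted by
#' maximum likelihood under the null (one proportion) and the alternative
#' (group-specific proportions) and the likelihood-ratio statistic is
#' referred to its small-sample F approximation
#' \eqn{F = (N-2)(e^{\Lambda/N} - 1) \sim F_{1,N-2}} (the exact
#' transformation for Gaussian likelihoods, which calibrates the test at
#' the cohort sizes used here), or to the asymptotic \eqn{\chi^2_1} tail
#' when `tail = "chisq"`. The log2 fold change is computed from group
#' means of the normalized abundance with a pseudocount.
#'
#' @param se normalized protein matrix (`SummarizedExperiment` with
#'   colData column `group`).
#' @param contrast character vector `c(case, reference)` of group tokens.
#' @param pseudocount added to group means before the log-ratio.
#' @param scale multiplier of the count-conversion target (default 1
#'   gives a median sample total of about 1e6 counts).
#' @param tail `"f"` (default, small-sample calibrated) or `"chisq"`.
#' @return `data.frame` with columns `protein, log2fc, pvalue` and a
#'   logical `flagged` column marking proteins whose likelihood could not
#'   be maximized (these get p = 1). The contrast is stored in
#'   `attr(, "contrast")`.
#' @export
betaBinomialTest <- function(se, contrast, pseudocount = 0.5, scale = 1,
                             tail = c("f", "chisq")) {
  tail <- match.arg(tail)
  m <- SummarizedExperiment::assay(se, "abundance")
  groups <- as.character(se$group)
  if (!all(contrast %in% groups))
    stop("group(s) absent from matrix: ",
         paste(setdiff(contrast, groups), collapse = ", "))
  keep <- groups %in% contrast
  m <- m[, keep, drop = FALSE]
  groups <- groups[keep]
  if (min(table(groups)) < 2L) stop("both groups need at least 2 samples")
  isCase <- groups == contrast[1]

  sf <- scale * 1e6 / median(colSums(m))
  counts <- round(m * sf)
  totals <- colSums(counts)
  N <- ncol(counts)

  # fold change on the (unrounded) count scale so the pseudocount has
  # fixed units and the result is invariant to global rescaling
  caseMean <- rowMeans(m[, isCase, drop = FALSE]) * sf
  refMean <- rowMeans(m[, !isCase, drop = FALSE]) * sf
  log2fc <- log2((caseMean + pseudocount) / (refMean + pseudocount))

  pvalue <- rep(1, nrow(counts))
  flagged <- logical(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    y <- counts[i, ]
    h0 <- .bbFitNull(y, totals)
    h1 <- if (is.null(h0)) NULL else
      .bbFitAlt(y, totals, isCase, h0$par[2])
    if (is.null(h0) || is.null(h1)) {
      flagged[i] <- TRUE
      next
    }
    lrt <- max(0, 2 * (h1$loglik - h0$loglik))
    pvalue[i] <- if (tail == "chisq") {
      pchisq(lrt, df = 1, lower.tail = FALSE)
    } else {
      fstat <- (N - 2) * (exp(lrt / N) - 1)
      pf(fstat, 1, N - 2, lower.tail = FALSE)
    }
  }
  pvalue <- pmin(pmax(pvalue, .Machine$double.xmin), 1)
  res <- data.frame(protein = rownames(m), log2fc = log2fc,
                    pvalue = pvalue, flagged = flagged,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "contrast") <- contrast
  res
}

#' Fit a beta-uniform mixture to a p-value distribution
#'
#' Maximizes the likelihood of the mixture density
#' \eqn{f(p) = \lambda + (1-\lambda) a p^{a-1}} over \eqn{\lambda \in
#' [0,1]}, \eqn{a \in (0,1]} by bounded quasi-Newton optimization on
#' \eqn{(\mathrm{logit}\,\lambda, \log a)} from five fixed starting
#' points (a multi-modality guard); the best likelihood wins, so the fit
#' is deterministic given the input.
#'
#' @param p_values numeric vector of p-values in (0, 1], length >= 50.
#' @return a [BumFit-class] object.
#' @export
fitBum <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  if (length(p) < 50L) stop("need at least 50 p-values")
  logp <- log(p)
  nll <- function(par) {
    lambda <- .logistic(par[1])
    a <- exp(par[2])
    -sum(log(lambda + (1 - lambda) * a * exp((a - 1) * logp)))
  }
  starts <- rbind(c(0.2, 0.1), c(0.5, 0.3), c(0.8, 0.5),
                  c(0.95, 0.8), c(0.6, 0.95))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    par0 <- c(log(starts[s, 1] / (1 - starts[s, 1])), log(starts[s, 2]))
    fit <- try(optim(par0, nll, method = "L-BFGS-B",
                     lower = c(-15, -15), upper = c(15, 0)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("beta-uniform mixture fit failed")
  new("BumFit", lambda = .logistic(best$par[1]),
      a = min(exp(best$par[2]), 1), loglik = -best$value,
      n = length(p))
}

#' BUM density (exported for checks and plotting)
#'
#' @param p numeric vector in (0, 1].
#' @param lambda,a mixture parameters.
#' @return density values.
#' @export
bumDensity <- function(p, lambda, a) {
  lambda + (1 - lambda) * a * p^(a - 1)
}

#' Map an FDR level to a p-value threshold under a BUM fit
#'
#' Under the fitted mixture, the estimated false-discovery proportion
#' among discoveries \eqn{\{p \le \tau\}} is \eqn{\pi_{ub}\tau / F(\tau)}
#' with \eqn{F(\tau) = \lambda\tau + (1-\lambda)\tau^a} and
#' \eqn{\pi_{ub} = \lambda + (1-\lambda)a}. The returned \eqn{\tau} is
#' the largest cutoff at which this proportion does not exceed `fdr`,
#' available in closed form:
#' \deqn{\tau = \left(\frac{fdr\,(1-\lambda)}{\pi_{ub} - fdr\,\lambda}
#'   \right)^{1/(1-a)}.}
#'
#' @param fit a [BumFit-class].
#' @param fdr target false discovery rate in (0, 1).
#' @return p-value threshold in \[0, 1\].
#' @export
fdrThreshold <- function(fit, fdr) {
  stopifnot(is(fit, "BumFit"))
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)")
  lambda <- fit@lambda
  a <- fit@a
  piUb <- piUpperBound(fit)
  if (piUb >= 1 - 1e-9) {
    warning("signal-free fit (pi_ub ~ 1): threshold is 0")
    return(0)
  }
  if (a >= 1 - 1e-12) return(0)
  denom <- piUb - fdr * lambda
  if (denom <= 0) return(1)
  tau <- (fdr * (1 - lambda) / denom)^(1 / (1 - a))
  min(max(tau, 0), 1)
}

## Brute-force average linkage used nowhere in production, kept internal
## for the clusterSamples contract; see tests for the independent oracle.

#' Hierarchical clustering of samples on top differential proteins
#'
#' Ranks proteins by their minimum p-value across the supplied contrasts,
#' selects the `top_n` most significant, centers and scales each protein,
#' and clusters both samples and proteins with average linkage on the
#' correlation distance \eqn{1 - r}.
#'
#' @param se normalized protein matrix.
#' @param contrasts list of contrast results (from [betaBinomialTest()]).
#' @param top_n number of proteins to keep (default 50).
#' @return list with `sampleTree`, `proteinTree` (both `hclust`),
#'   `proteins` (selected ids) and `values` (the scaled submatrix).
#' @export
clusterSamples <- function(se, contrasts, top_n = 50L) {
  m <- SummarizedExperiment::assay(se, "abundance")
  pmat <- sapply(contrasts, function(ct)
    ct$pvalue[match(rownames(m), ct$protein)])
  minp <- apply(as.matrix(pmat), 1, min, na.rm = TRUE)
  if (top_n > nrow(m)) {
    warning("fewer proteins than top_n; using all")
    top_n <- nrow(m)
  }
  ord <- order(minp, rownames(m))
  sel <- rownames(m)[ord[seq_len(top_n)]]
  vals <- t(scale(t(m[sel, , drop = FALSE])))
  sampleTree <- hclust(as.dist(1 - cor(vals)), method = "average")
  proteinTree <- hclust(as.dist(1 - cor(t(vals))), method = "average")
  list(sampleTree = sampleTree, proteinTree = proteinTree,
       proteins = sel, values = vals)
}
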