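#' @import methods
#' @importFrom stats approx cor cutree dist hclust lm median optim p.adjust
#'   pchisq pf phyper pnorm pt qnorm quantile rbeta rlnorm rnorm rpois runif
#'   sd setNames t.test uniroot wilcox.test complete.cases coef rbinom
#'   as.dist
#' @importFrom utils head tail
#' @importFrom data.table := .N data.table as.data.table fread fwrite
#'   setorder dcast rbindlist
NULL

#' Beta-uniform mixture fit of a p-value distribution
#'
#' Container for a maximum-likelihood fit of the two-component
#' beta-uniform mixture density
#' \deqn{f(p \mid \lambda, a) = \lambda + (1-\lambda)\, a\, p^{a-1},}
#' \eqn{\lambda \in [0,1]}, \eqn{a \in (0,1]}, to a vector of p-values.
#' The quantity \eqn{\pi_{ub} = \lambda + (1-\lambda) a} is an upper bound
#' on the proportion of true null hypotheses and drives the FDR-to-p-value
#' threshold mapping in [fdrThreshold()].
#'
#' @slot lambda numeric(1), mixing weight of the uniform component.
#' @slot a numeric(1), beta shape parameter in (0, 1].
#' @slot loglik numeric(1), maximized log-likelihood.
#' @slot n integer(1), number of p-values fitted.
#'
#' @seealso [fitBum()], [fdrThreshold()]
#' @export
setClass("BumFit",
  representation(lambda = "numeric", a = "numeric",
                 loglik = "numeric", n = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@lambda) != 1L || object@lambda < 0 || object@lambda > 1)
      msg <- c(msg, "'lambda' must be a single value in [0, 1]")
    if (length(object@a) != 1L || object@a <= 0 || object@a > 1)
      msg <- c(msg, "'a' must be a single value in (0, 1]")
    if (!is.finite(object@loglik))
      msg <- c(msg, "'loglik' must be finite")
    if (length(msg)) msg else TRUE
  })

#' @describeIn BumFit Upper bound \eqn{\lambda + (1-\lambda)a} on the null
#'   proportion.
#' @param fit A [BumFit-class] object.
#' @export
piUpperBound <- function(fit) {
  stopifnot(is(fit, "BumFit"))
  fit@lambda + (1 - fit@lambda) * fit@a
}

#' @describeIn BumFit Accessor for the fitted parameters, returned as a
#'   named numeric vector `c(lambda, a, pi_ub, loglik)`.
#' @export
bumParameters <- function(fit) {
  stopifnot(is(fit, "BumFit"))
  c(lambda = fit@lambda, a = fit@a,
    pi_ub = piUpperBound(fit), loglik = fit@loglik)
}

setMethod("show", "BumFit", function(object) {
  cat("BumFit (beta-uniform mixture, n =", object@n, "p-values)\n")
  cat(sprintf("  lambda = %.4f  a = %.4f  pi_ub = %.4f  logLik = %.2f\n",
              object@lambda, object@a, piUpperBound(object), object@loglik))
  cat(sprintf("  estimated signal proportion <= %.4f\n",
              1 - piUpperBound(object)))
})

#' Protein-to-module assignment
#'
#' Result of [detectModules()]: every protein carries exactly one module
#' label. Labels are `"M01"`, `"M02"`, ... in order of strictly
#' non-increasing module size; `"M00"` collects the leftover proteins that
#' did not fall into any module and is not itself a module.
#'
#' @slot labels named character vector, protein id -> module label.
#' @slot sizes named integer vector of module sizes, names are module
#'   labels sorted `"M01"`, `"M02"`, ... (`"M00"` listed last when present).
#'
#' @seealso [detectModules()], [moduleMembers()]
#' @export
setClass("ModuleAssignment",
  representation(labels = "character", sizes = "integer"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@labels)))
      msg <- c(msg, "'labels' must be named by protein id")
    tab <- table(object@labels)
    if (!all(object@sizes[names(tab)] == as.integer(tab)))
      msg <- c(msg, "'sizes' inconsistent with 'labels'")
    real <- setdiff(names(object@sizes), "M00")
    if (length(real) > 1L && is.unsorted(rev(object@sizes[real])))
      msg <- c(msg, "module sizes must be non-increasing in label order")
    if (length(msg)) msg else TRUE
  })

#' @describeIn ModuleAssignment Named character vector protein -> label.
#' @param x A [ModuleAssignment-class] object.
#' @export
moduleLabels <- function(x) { stopifnot(is(x, "ModuleAssignment")); x@labels }

#' @describeIn ModuleAssignment Named integer vector of module sizes.
#' @export
moduleSizes <- function(x) { stopifnot(is(x, "ModuleAssignment")); x@sizes }

#' @describeIn ModuleAssignment Protein ids belonging to module `label`.
#' @param label module label, e.g. `"M01"`.
#' @export
moduleMembers <- function(x, label) {
  stopifnot(is(x, "ModuleAssignment"))
  names(x@labels)[x@labels == label]
}

setMethod("show", "ModuleAssignment", function(object) {
  real <- setdiff(names(object@sizes), "M00")
  cat("ModuleAssignment:", length(object@labels), "proteins,",
      length(real), "modules\n")
  if (length(real)) {
    rng <- range(object@sizes[real])
    cat("  sizes", rng[2], "(", real[1], ") down to", rng[1], "\n")
  }
  if ("M00" %in% names(object@sizes))
    cat("  unassigned (M00):", object@sizes[["M00"]], "proteins\n")
})

#' Hot-subnetwork extraction result
#'
#' Result of [findHotSubnetworks()]: the hierarchy of connected components
#' obtained by thresholding the exchanged diffusion-score similarity at
#' decreasing cutoffs \eqn{\delta}, the selected \eqn{\delta}, the reported
#' subnetworks (components with at least two nodes at the selected
#' threshold, largest first) and a permutation p-value for the
#' largest-component statistic.
#'
#' @slot beta numeric(1), restart probability of the random walk.
#' @slot hierarchy data.frame with columns `delta` and `largest_component`
#'   (observed largest component size at each candidate threshold) and
#'   `perm_mean` (its mean under score permutation).
#' @slot chosenDelta numeric(1), selected threshold.
#' @slot subnetworks list of character vectors (node sets), largest first.
#' @slot permutationP numeric(1), permutation p-value.
#' @slot nPerm integer(1), number of score permutations.
#' @slot scores named numeric vector of the vertex scores used.
#'
#' @seealso [findHotSubnetworks()], [diffusionMatrix()]
#' @export
setClass("HotnetResult",
  representation(beta = "numeric", hierarchy = "data.frame",
                 chosenDelta = "numeric", subnetworks = "list",
                 permutationP = "numeric", nPerm = "integer",
                 scores = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@beta <= 0 || object@beta > 1)
      msg <- c(msg, "'beta' must lie in (0, 1]")
    if (object@permutationP <= 0 || object@permutationP > 1)
      msg <- c(msg, "'permutationP' must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' @describeIn HotnetResult List of reported subnetworks (node id vectors).
#' @param x A [HotnetResult-class] object.
#' @export
hotSubnetworks <- function(x) { stopifnot(is(x, "HotnetResult")); x@subnetworks }

setMethod("show", "HotnetResult", function(object) {
  cat("HotnetResult: beta =", object@beta,
      " permutations =", object@nPerm, "\n")
  if (length(object@subnetworks)) {
    cat(sprintf("  %d subnetwork(s) at delta = %.4g, largest = %d nodes, p = %.4g\n",
                length(object@subnetworks), object@chosenDelta,
                length(object@subnetworks[[1]]), object@permutationP))
  } else {
    cat("  no subnetwork reported (p =", object@permutationP, ")\n")
  }
})

#' Cross-cohort module validation (GESS) result
#'
#' Result of [gessScore()] for one module and one validation cohort. For
#' each p-value threshold `t` the concordance fraction \eqn{F_{m,t}} is the
#' fraction of module proteins significant below `t` in both cohorts with
#' same-direction log2 fold change; each threshold receives a one-sided
#' p-value against a protein-label permutation null and the GESS score is
#' the mean of these p-values. A module is validated when GESS < 0.05.
#'
#' @slot module character(1), module label.
#' @slot thresholds numeric vector of p-value thresholds.
#' @slot fractions named numeric, observed \eqn{F_{m,t}} per threshold.
#' @slot pvalues named numeric, per-threshold one-sided p-values.
#' @slot score numeric(1), mean of the per-threshold p-values.
#' @slot validated logical(1), `score < 0.05`.
#' @slot moduleSize integer(1), number of member proteins scored.
#' @slot nPerm integer(1), number of label permutations.
#' @slot fractionSameDirection numeric(1), fraction of members whose log2FC
#'   sign agrees between cohorts.
#'
#' @seealso [gessScore()], [concordanceFraction()], [validateAllModules()]
#' @export
setClass("GessResult",
  representation(module = "character", thresholds = "numeric",
                 fractions = "numeric", pvalues = "numeric",
                 score = "numeric", validated = "logical",
                 moduleSize = "integer", nPerm = "integer",
                 fractionSameDirection = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@fractions < 0 | object@fractions > 1))
      msg <- c(msg, "'fractions' must lie in [0, 1]")
    if (is.unsorted(object@fractions[order(object@thresholds)]))
      msg <- c(msg, "F_{m,t} must be non-decreasing in t")
    if (object@score < 0 || object@score > 1)
      msg <- c(msg, "'score' must lie in [0, 1]")
    if (!identical(object@validated, unname(object@score < 0.05)))
      msg <- c(msg, "'validated' must equal score < 0.05")
    if (length(msg)) msg else TRUE
  })

#' @describeIn GessResult The GESS score (mean per-threshold p-value).
#' @param x A [GessResult-class] object.
#' @export
gessValue <- function(x) { stopifnot(is(x, "GessResult")); x@score }

#' @describeIn GessResult Logical, validated at GESS < 0.05.
#' @export
isValidated <- function(x) { stopifnot(is(x, "GessResult")); x@validated }

setMethod("show", "GessResult", function(object) {
  cat("GessResult for", object@module,
      sprintf("(%d proteins, %d permutations)\n",
              object@moduleSize, object@nPerm))
  tab <- rbind(F = object@fractions, p = object@pvalues)
  colnames(tab) <- paste0("t=", object@thresholds)
  print(round(tab, 4))
  cat(sprintf("  GESS = %.4f -> %s; same-direction fraction = %.3f\n",
              object@score,
              if (object@validated) "validated" else "not validated",
              object@fractionSameDirection))
})
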