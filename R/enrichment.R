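#' Gene-set over-representation test for a module
#'
#' One-sided hypergeometric upper-tail test of the overlap between a
#' module's member set and each gene set, computed on the annotated
#' background only (sets and the module are intersected with
#' `background` first), with Benjamini-Hochberg correction across the
#' terms tested for the module.
#'
#' @param module_members character vector of member tokens (must be a
#'   subset of `background`).
#' @param collection named list of gene sets (see [readGmt()]).
#' @param background character vector of annotated background tokens.
#' @return `data.frame` with columns `term, overlap, set_size,
#'   module_size, background_size, p_raw, p_bh`, sorted by `p_raw`.
#' @export
goOverrepresentation <- function(module_members, collection, background) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  if (!all(module_members %in% background))
    stop("module members must be contained in the background")
  module_members <- unique(module_members)
  q <- length(module_members)
  N <- length(background)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], background)
    k <- length(intersect(set, module_members))
    p <- phyper(k - 1, length(set), N - length(set), q,
                lower.tail = FALSE)
    data.frame(term = nm, overlap = k, set_size = length(set),
               module_size = q, background_size = N, p_raw = p)
  })
  res <- do.call(rbind, rows)
  res$p_bh <- p.adjust(res$p_raw, method = "BH")
  res[order(res$p_raw, res$term), ]
}

## Weighted Kolmogorov-Smirnov enrichment score of a hit set given the
## descending-sorted score vector. hits: logical over positions.
.gseaES <- function(scores, hits, weight = 1) {
  N <- length(scores)
  nh <- sum(hits)
  if (nh == 0L || nh == N) return(NA_real_)
  w <- abs(scores)^weight
  inc <- numeric(N)
  inc[hits] <- w[hits] / sum(w[hits])
  inc[!hits] <- -1 / (N - nh)
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the weighted Kolmogorov-Smirnov enrichment score (ES) of each
#' gene set against a ranked list: walking down the ranking, hits
#' increment the running sum proportionally to \eqn{|score|^{weight}}
#' (normalized over the set) and misses decrement it by \eqn{1/(N-k)};
#' the ES is the maximum deviation from zero. The null is random gene-set
#' resampling of matched size (the standard preranked convention):
#' `n_perm` same-size sets drawn uniformly from the ranking universe.
#' NES divides the ES by the mean absolute permuted ES of the same sign;
#' the nominal p-value uses the same-sign permutation pool, and FDR q
#' compares each NES to the pooled permuted NES distribution.
#'
#' @param ranking named numeric vector of scores (ties are broken by
#'   token order; tokens must be unique).
#' @param collection named list of gene sets.
#' @param n_perm number of random-set permutations (default 1000).
#' @param weight hit-weighting exponent (default 1, the GSEA default).
#' @param min_set minimum post-filter set size (default 5).
#' @param seed integer seed.
#' @return `data.frame` with columns `term, size, es, nes, p_nominal,
#'   fdr_q`; sets larger than the universe, smaller than `min_set` after
#'   filtering or covering the whole universe are skipped with a warning.
#' @export
gseaPreranked <- function(ranking, collection, n_perm = 1000L, weight = 1,
                          min_set = 5L, seed = 1L) {
  if (anyDuplicated(names(ranking))) stop("duplicate tokens in ranking")
  ord <- order(-ranking, names(ranking))
  scores <- as.numeric(ranking[ord])
  tokens <- names(ranking)[ord]
  N <- length(scores)

  sizes <- integer(0)
  obs <- list()
  for (nm in names(collection)) {
    set <- intersect(collection[[nm]], tokens)
    if (length(set) < min_set || length(set) >= N) {
      warning("skipping set '", nm, "' (size out of range after filtering)")
      next
    }
    hits <- tokens %in% set
    obs[[nm]] <- c(size = length(set), es = .gseaES(scores, hits, weight))
    sizes <- c(sizes, length(set))
  }
  if (!length(obs))
    return(data.frame(term = character(), size = integer(),
                      es = numeric(), nes = numeric(),
                      p_nominal = numeric(), fdr_q = numeric()))

  set.seed(seed)
  uSizes <- sort(unique(sizes))
  permES <- lapply(setNames(uSizes, uSizes), function(sz) {
    vapply(seq_len(n_perm), function(b) {
      hits <- logical(N)
      hits[sample.int(N, sz)] <- TRUE
      .gseaES(scores, hits, weight)
    }, numeric(1))
  })

  rows <- lapply(names(obs), function(nm) {
    sz <- obs[[nm]]["size"]
    es <- obs[[nm]]["es"]
    perm <- permES[[as.character(sz)]]
    pos <- perm[perm >= 0]
    neg <- perm[perm < 0]
    if (es >= 0) {
      denom <- if (length(pos)) mean(pos) else NA_real_
      pnom <- (1 + sum(pos >= es)) / (1 + length(pos))
    } else {
      denom <- if (length(neg)) mean(abs(neg)) else NA_real_
      pnom <- (1 + sum(neg <= es)) / (1 + length(neg))
    }
    nes <- if (is.na(denom) || denom == 0) NA_real_ else es / denom
    data.frame(term = nm, size = as.integer(sz), es = unname(es),
               nes = unname(nes), p_nominal = unname(pnom))
  })
  res <- do.call(rbind, rows)

  # FDR q: pooled permuted NES (each permuted ES normalized by the
  # same-sign mean of its size class), standard positive/negative pools
  permNES <- unlist(lapply(permES, function(perm) {
    pos <- perm[perm >= 0]; neg <- perm[perm < 0]
    mpos <- if (length(pos)) mean(pos) else NA_real_
    mneg <- if (length(neg)) mean(abs(neg)) else NA_real_
    ifelse(perm >= 0, perm / mpos, perm / mneg)
  }), use.names = FALSE)
  permNES <- permNES[is.finite(permNES)]
  res$fdr_q <- vapply(res$nes, function(nes) {
    if (!is.finite(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- sum(permNES >= nes) / max(1, sum(permNES >= 0))
      den <- sum(res$nes >= nes, na.rm = TRUE) /
        max(1, sum(res$nes >= 0, na.rm = TRUE))
    } else {
      num <- sum(permNES <= nes) / max(1, sum(permNES < 0))
      den <- sum(res$nes <= nes, na.rm = TRUE) /
        max(1, sum(res$nes < 0, na.rm = TRUE))
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  res[order(res$p_nominal, res$term), ]
}
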