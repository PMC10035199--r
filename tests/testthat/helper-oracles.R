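# Independent brute-force oracles used to check the package's
# implementations on small instances.

# UPGMA (average linkage) by direct pairwise-mean agglomeration; returns
# the cophenetic distance matrix.
naiveAverageLinkageCophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  active <- seq_len(n)
  dd <- d
  while (length(active) > 1L) {
    best <- c(NA, NA); bestVal <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1L)) {
      a <- active[i]; b <- active[j]
      val <- mean(d[clusters[[a]], clusters[[b]]])
      if (val < bestVal) { bestVal <- val; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    for (x in clusters[[a]]) for (y in clusters[[b]]) {
      coph[x, y] <- bestVal; coph[y, x] <- bestVal
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    active <- setdiff(active, b)
  }
  coph
}

# Weighted Kolmogorov-Smirnov enrichment score by an explicit walk.
bruteForceES <- function(scores, hitPositions, weight = 1) {
  N <- length(scores)
  w <- abs(scores[hitPositions])^weight
  running <- 0
  best <- 0
  for (pos in seq_len(N)) {
    if (pos %in% hitPositions) {
      running <- running + abs(scores[pos])^weight / sum(w)
    } else {
      running <- running - 1 / (N - length(hitPositions))
    }
    if (abs(running) > abs(best)) best <- unname(running)
  }
  best
}

# Best connected subgraph of exactly size k by exhaustive enumeration.
bestConnectedScore <- function(graph, scores, k) {
  nodes <- igraph::V(graph)$name
  best <- -Inf
  for (ix in utils::combn(length(nodes), k, simplify = FALSE)) {
    sub <- igraph::induced_subgraph(graph, nodes[ix])
    if (igraph::is_connected(sub))
      best <- max(best, sum(scores[nodes[ix]]))
  }
  best
}

# Tiny peptide report builder: one fraction, n samples, explicit rows.
tinyReport <- function(nSamples, peptides) {
  rows <- list()
  for (p in peptides) {
    for (s in seq_len(nSamples)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("S%02d", s),
        group = if (s <= nSamples / 2) "case" else "control",
        fraction = p$fraction %||% "F1",
        peptide = p$id, protein = p$protein,
        abundance = p$abundance[s],
        qvalue = p$qvalue[s])
    }
  }
  data.table::rbindlist(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Latent protein matrix with planted block structure (no peptide layer);
# fast fixture for network-level tests.
latentBlockMatrix <- function(blockSizes, nNoise, nSamples = 26,
                              loading = 0.9, factorSd = 0.45,
                              noiseSd = 0.15, seed = 1) {
  set.seed(seed)
  n <- sum(blockSizes) + nNoise
  lab <- c(rep(seq_along(blockSizes), blockSizes), rep(NA, nNoise))
  f <- matrix(rnorm(length(blockSizes) * nSamples), ncol = nSamples)
  x <- matrix(rnorm(n * nSamples, sd = noiseSd), n, nSamples) + 10
  inB <- !is.na(lab)
  x[inB, ] <- x[inB, ] + loading * factorSd * f[lab[inB], ]
  rownames(x) <- sprintf("P%04d", seq_len(n))
  colnames(x) <- sprintf("S%02d", seq_len(nSamples))
  list(matrix = x, labels = setNames(lab, rownames(x)))
}

# Wrap a plain matrix as the package's protein-matrix container.
asProteinSE <- function(m, groups = NULL) {
  if (is.null(groups))
    groups <- rep(c("case", "control"), length.out = ncol(m))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = m),
    colData = S4Vectors::DataFrame(group = groups,
                                   row.names = colnames(m)))
}
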