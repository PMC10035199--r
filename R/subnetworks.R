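#' Correlation graph of one module
#'
#' Builds the undirected graph over a module's member proteins with an
#' edge wherever the absolute Pearson correlation of abundance reaches
#' `edge_threshold`; edge weights are \eqn{|r|}.
#'
#' @param se protein matrix (`SummarizedExperiment`).
#' @param members module member protein ids (>= 2, all present in `se`).
#' @param edge_threshold minimum \eqn{|r|} for an edge (default 0.5);
#'   0 gives the complete weighted graph.
#' @return an `igraph` graph with vertex attribute `name` and edge
#'   attribute `weight`; `edge_threshold` is stored as a graph attribute.
#' @export
buildModuleGraph <- function(se, members, edge_threshold = 0.5) {
  m <- SummarizedExperiment::assay(se, "abundance")
  if (!all(members %in% rownames(m)))
    stop("members absent from the matrix: ",
         paste(head(setdiff(members, rownames(m)), 3L), collapse = ", "))
  if (length(members) < 2L) stop("need at least 2 members")
  r <- abs(cor(t(m[members, , drop = FALSE])))
  diag(r) <- 0
  adj <- r * (r >= edge_threshold)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::ecount(g) == 0L)
    warning("no edge passes the threshold; graph of isolated nodes")
  g <- igraph::set_graph_attr(g, "edge_threshold", edge_threshold)
  g
}

#' Random-walk-with-restart diffusion matrix
#'
#' \eqn{F = \beta (I - (1-\beta) W)^{-1}} where `W` is the
#' column-normalized (weighted) adjacency of the graph. Columns of `F`
#' sum to one; an isolated node's column is its own indicator, so
#' diffusion is confined to connected components.
#'
#' @param graph an `igraph` graph (from [buildModuleGraph()]).
#' @param beta restart probability in (0, 1\]; `beta = 1` gives the
#'   identity (no diffusion).
#' @return node-by-node matrix with dimnames from the vertex names.
#' @export
diffusionMatrix <- function(graph, beta = 0.5) {
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]")
  A <- as.matrix(igraph::as_adjacency_matrix(graph, attr =
    if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL,
    sparse = FALSE))
  n <- nrow(A)
  csums <- colSums(A)
  W <- matrix(0, n, n, dimnames = dimnames(A))
  nz <- csums > 0
  W[, nz] <- sweep(A[, nz, drop = FALSE], 2, csums[nz], `/`)
  # a walker on an isolated node stays put, keeping F column-stochastic
  diag(W)[!nz] <- 1
  FF <- beta * solve(diag(n) - (1 - beta) * W)
  # isolated nodes: the walk never leaves, F column = indicator
  dimnames(FF) <- dimnames(A)
  FF
}

## Largest-component trajectory of the thresholded min-symmetrized
## similarity, via single-linkage: connectivity at similarity >= delta
## equals the single-linkage clustering cut at that level.
.componentTrajectory <- function(A) {
  n <- nrow(A)
  maxA <- max(A)
  if (maxA <= 0)
    return(list(delta = numeric(0), largest = integer(0)))
  hc <- hclust(as.dist(maxA - A), method = "single")
  sizes <- integer(2 * n)            # leaf sizes then internal node sizes
  sizes[seq_len(n)] <- 1L
  largest <- integer(n - 1L)
  cur <- 1L
  for (k in seq_len(n - 1L)) {
    kids <- hc$merge[k, ]
    sz <- sum(ifelse(kids < 0, 1L, sizes[n + pmax(kids, 0)]))
    sizes[n + k] <- sz
    cur <- max(cur, sz)
    largest[k] <- cur
  }
  delta <- maxA - hc$height          # similarity level of each merge
  keep <- delta > 1e-12              # merges through zero similarity are
  list(delta = delta[keep], largest = largest[keep])   # not real edges
}

## Evaluate the (non-increasing in delta) trajectory at query thresholds.
.largestAt <- function(traj, deltas) {
  if (!length(traj$delta)) return(rep(1L, length(deltas)))
  vapply(deltas, function(d) {
    ix <- traj$delta >= d - 1e-12
    if (!any(ix)) 1L else max(traj$largest[ix])
  }, integer(1))
}

.exchangedSimilarity <- function(FF, scores) {
  S <- FF * rep(scores, each = nrow(FF))   # S_ij = F_ij * score_j
  A <- pmin(S, t(S))
  diag(A) <- 0
  A
}

#' Hot-subnetwork discovery by diffusion and thresholding
#'
#' Propagates per-protein significance scores over the module graph
#' (random walk with restart, see [diffusionMatrix()]), forms the
#' exchanged similarity \eqn{S_{ij} = F_{ij}\,score_j}, symmetrizes it as
#' \eqn{\min(S_{ij}, S_{ji})} and sweeps a threshold \eqn{\delta} over
#' the observed entries: at each \eqn{\delta} the graph keeps entries
#' \eqn{\ge \delta} and the connected components form the hierarchy.
#' \eqn{\delta} is chosen to maximize the observed largest-component
#' size relative to its mean under uniform permutation of the scores
#' across the module's nodes; components with at least two nodes
#' at the chosen \eqn{\delta} are reported, largest first, together with
#' a permutation p-value for the largest-component size. When the scores
#' carry no structure (all equal, or never exceeding the permuted
#' landscape) no subnetwork is reported and p = 1.
#'
#' @param graph module graph from [buildModuleGraph()].
#' @param scores named non-negative vertex scores covering all nodes
#'   (conventionally \eqn{-\log_{10} p} capped at 16, see
#'   [vertexScores()]).
#' @param beta restart probability (default 0.5).
#' @param n_perm number of score permutations (default 100).
#' @param seed integer seed.
#' @return a [HotnetResult-class].
#' @export
findHotSubnetworks <- function(graph, scores, beta = 0.5, n_perm = 100L,
                               seed = 1L) {
  nodes <- igraph::V(graph)$name
  if (!all(nodes %in% names(scores)))
    stop("scores must cover all nodes")
  s <- as.numeric(scores[nodes])
  if (any(!is.finite(s) | s < 0)) stop("scores must be finite and >= 0")
  names(s) <- nodes
  FF <- diffusionMatrix(graph, beta)

  empty <- function(p) new("HotnetResult", beta = beta,
    hierarchy = data.frame(delta = numeric(0),
                           largest_component = integer(0),
                           perm_mean = numeric(0)),
    chosenDelta = NA_real_, subnetworks = list(),
    permutationP = p, nPerm = as.integer(n_perm), scores = s)

  A <- .exchangedSimilarity(FF, s)
  traj <- .componentTrajectory(A)
  if (!length(traj$delta)) return(empty(1))
  deltas <- sort(unique(traj$delta), decreasing = TRUE)
  Lobs <- .largestAt(traj, deltas)

  set.seed(seed)
  permL <- matrix(0L, n_perm, length(deltas))
  for (b in seq_len(n_perm)) {
    sp <- s[sample.int(length(s))]
    names(sp) <- nodes
    permL[b, ] <- .largestAt(.componentTrajectory(
      .exchangedSimilarity(FF, sp)), deltas)
  }
  permMean <- colMeans(permL)
  # relative excess of the observed largest component over the permuted
  # landscape; the absolute difference would always favour the near-full
  # components at small delta
  gap <- Lobs / pmax(permMean, 1)
  hier <- data.frame(delta = deltas, largest_component = Lobs,
                     perm_mean = permMean)
  if (max(gap) <= 1) return(`slot<-`(empty(1), "hierarchy", value = hier))

  # among thresholds whose anomaly is within 15% of the maximum, prefer
  # the smallest delta (the most complete subnetwork at near-maximal
  # excess), so the reported component is not clipped by a marginally
  # sharper but smaller peak
  nearMax <- which(gap >= 0.85 * max(gap))
  pick <- max(nearMax)               # deltas are sorted decreasing
  chosen <- deltas[pick]
  pval <- (1 + sum(permL[, pick] >= Lobs[pick])) / (1 + n_perm)

  keepEdges <- which(A >= chosen - 1e-12 & upper.tri(A), arr.ind = TRUE)
  gSub <- igraph::graph_from_data_frame(
    data.frame(from = nodes[keepEdges[, 1]], to = nodes[keepEdges[, 2]]),
    directed = FALSE, vertices = nodes)
  comp <- igraph::components(gSub)
  subnets <- split(nodes, comp$membership)
  subnets <- subnets[lengths(subnets) >= 2L]
  subnets <- subnets[order(-lengths(subnets),
                           vapply(subnets, min, character(1)))]
  names(subnets) <- NULL
  subnets <- lapply(subnets, function(v) sort(v))

  new("HotnetResult", beta = beta, hierarchy = hier,
      chosenDelta = chosen, subnetworks = subnets,
      permutationP = pval, nPerm = as.integer(n_perm), scores = s)
}

#' Vertex scores from per-protein p-values
#'
#' The conventional transform \eqn{-\log_{10} p}, capped at `cap` so a
#' vanishing p-value cannot dominate the diffusion.
#'
#' @param contrast contrast result with columns `protein, pvalue`.
#' @param cap upper cap (default 16).
#' @return named numeric vector of scores.
#' @export
vertexScores <- function(contrast, cap = 16) {
  setNames(pmin(-log10(contrast$pvalue), cap), contrast$protein)
}

#' Write a hot-subnetwork result for graph tools
#'
#' Writes an edge list (`source, target, weight`) of the module graph
#' restricted to reported subnetworks and a node table
#' (`protein, score, subnetwork_id`), a layout suitable for Cytoscape
#' import.
#'
#' @param result a [HotnetResult-class].
#' @param graph the module graph the result was computed on.
#' @param prefix output prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>_nodes.tsv`.
#' @export
writeSubnetworks <- function(result, graph, prefix) {
  subnets <- hotSubnetworks(result)
  nodeTab <- data.table::data.table(
    protein = names(result@scores), score = unname(result@scores),
    subnetwork_id = NA_integer_)
  for (i in seq_along(subnets))
    nodeTab[nodeTab$protein %in% subnets[[i]], "subnetwork_id"] <- i
  keep <- nodeTab$protein[!is.na(nodeTab$subnetwork_id)]
  sub <- igraph::induced_subgraph(graph, keep)
  el <- igraph::as_data_frame(sub, what = "edges")
  data.table::fwrite(data.table::data.table(
    source = el$from, target = el$to, weight = el$weight),
    paste0(prefix, "_edges.tsv"), sep = "\t")
  data.table::fwrite(nodeTab, paste0(prefix, "_nodes.tsv"), sep = "\t")
  invisible(prefix)
}
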