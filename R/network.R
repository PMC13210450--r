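# Weighted-graph summaries of an ROI connectivity matrix. Convention
# throughout: W is symmetric, non-negative, zero diagonal; the length of an
# edge is the reciprocal of its weight (strong connections are short), the
# Brain-Connectivity-Toolbox convention for efficiency measures.

as_weight_matrix <- function(M) {
  W <- unclass(as.matrix(M))
  if (nrow(W) != ncol(W)) stopf("weight matrix must be square")
  if (max(abs(W - t(W))) > 1e-9) stopf("weight matrix must be symmetric")
  if (min(W) < 0) stopf("weights must be non-negative")
  diag(W) <- 0
  W
}

shortest_path_lengths <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, 0) # 0 = no edge for igraph
  g <- igraph::graph_from_adjacency_matrix(L, mode = "undirected", weighted = TRUE)
  igraph::distances(g, algorithm = "dijkstra")
}

#' Nodal strength
#'
#' Sum of each node's edge weights: the total connectivity of an ROI.
#'
#' @param M Symmetric non-negative weight matrix (diagonal ignored), e.g. an
#'   ROI `conn_matrix`.
#' @return Named numeric vector of strengths.
#' @export
nodal_strength <- function(M) {
  W <- as_weight_matrix(M)
  rowSums(W)
}

#' Weighted global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs,
#' E = 1/(n(n-1)) sum_{i != j} 1/d_ij, with path lengths computed by
#' Dijkstra's algorithm on the reciprocal-weight length matrix; disconnected
#' pairs contribute 0. Summarizes network integration; equals 1 for a
#' complete unit-weight graph and lies in `[0, 1]` whenever weights do.
#'
#' @inheritParams nodal_strength
#' @return A scalar.
#' @export
global_efficiency <- function(M) {
  W <- as_weight_matrix(M)
  n <- nrow(W)
  if (n < 2) stopf("global efficiency needs at least 2 nodes")
  D <- shortest_path_lengths(W)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Onnela weighted clustering coefficient
#'
#' C_i = sum_{j,k} (w'_ij w'_jk w'_ik)^(1/3) / (k_i (k_i - 1)) with weights
#' normalized by the network maximum (w' = W / max(W)) and k_i the number of
#' nonzero-weight neighbors; 0 where k_i < 2. Invariant to a global
#' rescaling of the weights.
#'
#' @inheritParams nodal_strength
#' @return Named numeric vector of per-node clustering coefficients.
#' @export
clustering_coefficient <- function(M) {
  W <- as_weight_matrix(M)
  k <- rowSums(W > 0)
  mx <- max(W)
  if (mx == 0) return(stats::setNames(numeric(nrow(W)), rownames(W)))
  Wh <- (W / mx)^(1 / 3)
  num <- diag(Wh %*% Wh %*% Wh)
  C <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  stats::setNames(C, rownames(W))
}

#' Weighted local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbors (weights restricted to that subgraph); 0 for nodes with fewer
#' than 2 neighbors. A measure of fault tolerance / local integration.
#'
#' @inheritParams nodal_strength
#' @return Named numeric vector of per-node local efficiencies.
#' @export
local_efficiency <- function(M) {
  W <- as_weight_matrix(M)
  out <- vapply(seq_len(nrow(W)), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(W[nb, nb, drop = FALSE])
  }, numeric(1))
  stats::setNames(out, rownames(W))
}

#' All network metrics of one connectivity matrix
#'
#' @inheritParams nodal_strength
#' @return List with `global_efficiency` (scalar) and per-node `strength`,
#'   `clustering`, `local_efficiency`.
#' @export
network_summary <- function(M) {
  list(global_efficiency = global_efficiency(M),
       strength = nodal_strength(M),
       clustering = clustering_coefficient(M),
       local_efficiency = local_efficiency(M))
}
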