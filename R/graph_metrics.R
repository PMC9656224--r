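#' @name graph-metrics
#' @title Weighted graph measures of a connectivity network
#' @description
#' Nine network measures are extracted from each window's
#' mutual-information adjacency matrix: five global (characteristic path
#' length, global efficiency, transitivity, modularity, density) and four
#' node-level (clustering coefficient, local efficiency, betweenness
#' centrality, degree centrality/strength). All formulas are weighted: the
#' MI graph is complete, so binary variants would be constant. For
#' path-based measures an edge of weight w is traversed at length 1/w, the
#' standard brain-connectivity convention (stronger coupling = shorter
#' path); a zero weight means no edge.
NULL

# Dijkstra distances from one source on lengths 1/w (O(n^2), n <= 32).
dijkstra <- function(len, src) {
  n <- nrow(len)
  dist <- rep(Inf, n)
  dist[src] <- 0
  done <- rep(FALSE, n)
  for (k in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    nd <- dist[u] + len[u, ]
    upd <- !done & nd < dist
    dist[upd] <- nd[upd]
  }
  dist
}

length_matrix <- function(W) {
  len <- 1 / W
  len[W == 0] <- Inf
  diag(len) <- Inf  # no self-loops
  len
}

#' All-pairs shortest-path distance matrix
#'
#' Edge traversal length is the inverse weight (weight 0 = no edge);
#' distances are exact single-source shortest paths from every node.
#' Disconnected pairs have distance `Inf`; the diagonal is 0.
#'
#' @param W Symmetric nonnegative adjacency matrix.
#' @return n x n distance matrix.
#' @export
shortest_path_matrix <- function(W) {
  check_adjacency(W)
  len <- length_matrix(W)
  D <- t(vapply(seq_len(nrow(W)), function(s) dijkstra(len, s),
                numeric(nrow(W))))
  dimnames(D) <- dimnames(W)
  D
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all ordered node pairs i != j.
#' Requires a connected graph (always true for complete positive-weight
#' MI graphs).
#'
#' @param W Adjacency matrix.
#' @return Scalar; errors if any pair is disconnected.
#' @export
characteristic_path_length <- function(W) {
  D <- shortest_path_matrix(W)
  off <- D[row(D) != col(D)]
  if (any(!is.finite(off)))
    stop("graph is disconnected: characteristic path length undefined")
  mean(off)
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over ordered pairs; 1/Inf = 0, so
#' the measure is defined for disconnected graphs.
#'
#' @param W Adjacency matrix.
#' @return Scalar in `[0, Inf)`.
#' @export
global_efficiency <- function(W) {
  D <- shortest_path_matrix(W)
  off <- D[row(D) != col(D)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

#' Local efficiency per node
#'
#' For each node, the [global_efficiency()] of the subgraph induced by its
#' neighbours (nodes with a positive edge to it), keeping original weights.
#' Nodes with fewer than 2 neighbours score 0.
#'
#' @param W Adjacency matrix.
#' @return Named numeric vector, one value per node.
#' @export
local_efficiency <- function(W) {
  check_adjacency(W)
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    out[i] <- if (length(nb) < 2L) 0 else
      global_efficiency(W[nb, nb, drop = FALSE])
  }
  names(out) <- rownames(W)
  out
}

# Onnela triangle intensity t_i and binary degree k_i on max-normalized
# weights; shared by clustering and transitivity.
triangle_intensity <- function(W) {
  mx <- max(W)
  k <- rowSums(W > 0)
  if (mx == 0) return(list(t = numeric(nrow(W)), k = k))
  A <- (W / mx)^(1 / 3)
  list(t = diag(A %*% A %*% A) / 2, k = k)
}

#' Weighted clustering coefficient per node
#'
#' Onnela's geometric-mean form on max-normalized weights:
#' C_i = 2 t_i / (k_i (k_i - 1)), with t_i the summed cube-root triangle
#' intensity around node i and k_i the binary degree. Reduces to the
#' classic unweighted coefficient on 0/1 graphs; nodes with k_i < 2
#' score 0.
#'
#' @param W Adjacency matrix.
#' @return Named numeric vector per node, values in \[0, 1\].
#' @export
clustering_coefficients <- function(W) {
  check_adjacency(W)
  ti <- triangle_intensity(W)
  denom <- ti$k * (ti$k - 1)
  out <- ifelse(denom > 0, 2 * ti$t / denom, 0)
  names(out) <- rownames(W)
  out
}

#' Weighted transitivity
#'
#' Graph-level ratio of (weighted) closed triplets to all triplets:
#' `sum_i 2 t_i / sum_i k_i (k_i - 1)`; 0 when no node has two
#' neighbours. Equals the classical transitivity on 0/1 graphs.
#'
#' @param W Adjacency matrix.
#' @return Scalar in \[0, 1\].
#' @export
transitivity <- function(W) {
  check_adjacency(W)
  ti <- triangle_intensity(W)
  denom <- sum(ti$k * (ti$k - 1))
  if (denom == 0) return(0)
  sum(2 * ti$t) / denom
}

#' Betweenness centrality per node
#'
#' Fraction of all-pairs shortest paths passing through each node, on
#' inverse-weight edge lengths, with shortest-path multiplicities
#' (Brandes-style dependency accumulation). Normalized by
#' (n-1)(n-2) — the number of ordered pairs excluding the node — so values
#' lie in \[0, 1\] regardless of the channel-set size.
#'
#' @param W Adjacency matrix.
#' @return Named numeric vector per node.
#' @export
betweenness_centrality <- function(W) {
  check_adjacency(W)
  n <- nrow(W)
  len <- length_matrix(W)
  bc <- numeric(n)
  eps <- 1e-10
  for (s in seq_len(n)) {
    d <- dijkstra(len, s)
    ord <- order(d)  # increasing distance from s
    sigma <- numeric(n); sigma[s] <- 1
    # path counts in increasing-distance order; edge (u,v) lies on a
    # shortest path iff d[u] + len(u,v) == d[v] (tolerance for fp sums)
    for (v in ord) {
      if (v == s || !is.finite(d[v])) next
      pred <- which(is.finite(len[, v]) &
                    abs(d + len[, v] - d[v]) <= eps * max(1, d[v]))
      sigma[v] <- sum(sigma[pred])
    }
    delta <- numeric(n)
    for (v in rev(ord)) {
      if (v == s || !is.finite(d[v]) || sigma[v] == 0) next
      pred <- which(is.finite(len[, v]) &
                    abs(d + len[, v] - d[v]) <= eps * max(1, d[v]))
      delta[pred] <- delta[pred] +
        sigma[pred] / sigma[v] * (1 + delta[v])
    }
    delta[s] <- 0
    bc <- bc + delta
  }
  out <- if (n > 2) bc / ((n - 1) * (n - 2)) else numeric(n)
  names(out) <- rownames(W)
  out
}

#' Degree centrality (node strength)
#'
#' Sum of a node's edge weights. On a complete weighted graph the literal
#' edge count is the constant n - 1, so the weighted degree (strength) is
#' used throughout.
#'
#' @param W Adjacency matrix.
#' @return Named numeric vector per node.
#' @export
degree_centrality <- function(W) {
  check_adjacency(W)
  out <- rowSums(W)
  names(out) <- rownames(W)
  out
}

#' Graph density (total weight)
#'
#' Sum of edge weights over unordered pairs (each undirected edge counted
#' once). This is the literal "sum of all the weights" definition, not the
#' edge-fraction density of binary graph theory.
#'
#' @param W Adjacency matrix.
#' @return Nonnegative scalar.
#' @export
graph_density <- function(W) {
  check_adjacency(W)
  sum(W) / 2
}

modularity_of <- function(W, comm) {
  m2 <- sum(W)
  if (m2 == 0) return(0)
  s <- rowSums(W)
  same <- outer(comm, comm, "==")
  sum((W - outer(s, s) / m2)[same]) / m2
}

#' Newman modularity via greedy community detection
#'
#' Maximizes Q(partition) = (1/2m) sum_ij \[w_ij - s_i s_j / 2m\]
#' delta(c_i, c_j) by deterministic greedy agglomeration (merge the
#' community pair with the largest positive gain until none remains)
#' followed by local node-moving refinement passes. The detector is fully
#' deterministic; `seed` is accepted for interface stability and ignored.
#' The single-community partition (Q = 0) is always a candidate, so the
#' result is nonnegative.
#'
#' @param W Adjacency matrix.
#' @param seed Unused; the detector is deterministic.
#' @param details If `TRUE`, return a list with the partition as well.
#' @return Best modularity Q found (scalar), or a list `(Q, membership)`.
#' @export
modularity <- function(W, seed = 0L, details = FALSE) {
  check_adjacency(W)
  n <- nrow(W)
  m2 <- sum(W)
  if (m2 == 0) {
    return(if (details) list(Q = 0, membership = rep(1L, n)) else 0)
  }
  comm <- seq_len(n)
  Q <- modularity_of(W, comm)
  # greedy agglomeration
  repeat {
    labs <- unique(comm)
    if (length(labs) < 2L) break
    best <- 0; bi <- 0L; bj <- 0L
    for (a in seq_along(labs)[-length(labs)]) {
      for (b in (a + 1L):length(labs)) {
        trial <- comm
        trial[trial == labs[b]] <- labs[a]
        dq <- modularity_of(W, trial) - Q
        if (dq > best + 1e-12) { best <- dq; bi <- labs[a]; bj <- labs[b] }
      }
    }
    if (bi == 0L) break
    comm[comm == bj] <- bi
    Q <- Q + best
  }
  # local refinement: move single nodes while any move improves Q
  repeat {
    improved <- FALSE
    for (v in seq_len(n)) {
      cands <- unique(comm[-v])
      for (cc in setdiff(cands, comm[v])) {
        trial <- comm
        trial[v] <- cc
        dq <- modularity_of(W, trial) - Q
        if (dq > 1e-12) { comm <- trial; Q <- Q + dq; improved <- TRUE }
      }
    }
    if (!improved) break
  }
  if (Q < 0) { Q <- 0; comm <- rep(1L, n) }  # one community always scores 0
  if (details) list(Q = Q, membership = match(comm, unique(comm))) else Q
}

GLOBAL_MEASURES <- c("characteristic_path_length", "global_efficiency",
                     "transitivity", "modularity", "density")
LOCAL_MEASURES <- c("clustering_coefficient", "local_efficiency",
                    "betweenness_centrality", "degree_centrality")

#' Full graph feature block of an adjacency matrix
#'
#' Five global measures followed by the four per-node measures, each local
#' vector grouped by measure with names `<measure>__<channel>`. Length is
#' `5 + 4 n` (61 features for the 14-channel montage, 133 for 32 channels).
#'
#' @param W Adjacency matrix with channel dimnames.
#' @return Named numeric vector of length `5 + 4 * nrow(W)`.
#' @export
graph_feature_block <- function(W) {
  check_adjacency(W)
  glob <- c(characteristic_path_length = characteristic_path_length(W),
            global_efficiency = global_efficiency(W),
            transitivity = transitivity(W),
            modularity = modularity(W),
            density = graph_density(W))
  locs <- list(clustering_coefficient = clustering_coefficients(W),
               local_efficiency = local_efficiency(W),
               betweenness_centrality = betweenness_centrality(W),
               degree_centrality = degree_centrality(W))
  loc <- unlist(lapply(names(locs), function(m) {
    v <- locs[[m]]
    names(v) <- paste0(m, "__", names(v))
    v
  }))
  c(glob, loc)
}
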