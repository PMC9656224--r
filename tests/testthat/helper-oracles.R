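# Definition-level brute-force oracles, independent of the package's
# implementations: Floyd-Warshall distances, exhaustive simple-path
# enumeration for betweenness, exhaustive set-partition search for
# modularity, triangle counting for clustering/transitivity, an O(N^2)
# approximate-entropy implementation and an entropy-decomposition MI
# estimate.

oracle_lengths <- function(W) {
  L <- 1 / W
  L[W == 0] <- Inf
  diag(L) <- Inf
  L
}

# Floyd-Warshall all-pairs shortest paths on 1/w lengths
fw_distances <- function(W) {
  n <- nrow(W)
  D <- oracle_lengths(W)
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_global_efficiency <- function(W) {
  D <- fw_distances(W)
  off <- D[row(D) != col(D)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

oracle_local_efficiency <- function(W) {
  vapply(seq_len(nrow(W)), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2L) return(0)
    oracle_global_efficiency(W[nb, nb, drop = FALSE])
  }, numeric(1))
}

# all simple paths s -> t by depth-first enumeration; returns a list of
# (length, interior nodes) entries
enum_paths <- function(L, s, t) {
  n <- nrow(L)
  out <- list()
  walk <- function(v, visited, len, interior) {
    for (u in seq_len(n)) {
      if (visited[u] || !is.finite(L[v, u])) next
      if (u == t) {
        out[[length(out) + 1L]] <<- list(len = len + L[v, u],
                                         interior = interior)
      } else {
        visited[u] <- TRUE
        walk(u, visited, len + L[v, u], c(interior, u))
        visited[u] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  walk(s, visited, 0, integer(0))
  out
}

oracle_betweenness <- function(W) {
  n <- nrow(W)
  L <- oracle_lengths(W)
  delta <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- enum_paths(L, s, t)
      if (!length(paths)) next
      lens <- vapply(paths, `[[`, numeric(1), "len")
      dmin <- min(lens)
      short <- which(lens <= dmin * (1 + 1e-9))
      sigma <- length(short)
      for (k in short)
        delta[paths[[k]]$interior] <- delta[paths[[k]]$interior] + 1 / sigma
    }
  }
  if (n > 2) 2 * delta / ((n - 1) * (n - 2)) else delta * 0
}

# enumerate all set partitions via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in seq_len(mx + 1L)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

oracle_q <- function(W, comm) {
  m2 <- sum(W)
  if (m2 == 0) return(0)
  s <- rowSums(W)
  q <- 0
  for (i in seq_len(nrow(W)))
    for (j in seq_len(nrow(W)))
      if (comm[i] == comm[j]) q <- q + W[i, j] - s[i] * s[j] / m2
  unname(q / m2)
}

oracle_max_modularity <- function(W) {
  best <- -Inf
  for (comm in all_partitions(nrow(W))) {
    q <- oracle_q(W, comm)
    if (q > best) best <- q
  }
  best
}

oracle_binary_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2L) return(0)
    tri <- 0
    for (a in seq_len(k - 1L))
      for (b in (a + 1L):k)
        if (A[nb[a], nb[b]] > 0) tri <- tri + 1
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

oracle_binary_transitivity <- function(A) {
  n <- nrow(A)
  closed <- 0; triplets <- 0
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2L) next
    triplets <- triplets + k * (k - 1) / 2
    for (a in seq_len(k - 1L))
      for (b in (a + 1L):k)
        if (A[nb[a], nb[b]] > 0) closed <- closed + 1
  }
  if (triplets == 0) 0 else closed / triplets
}

# O(N^2) approximate entropy, vectorized differently from the compiled
# implementation (Chebyshev distances via outer/pmax)
oracle_apen <- function(x, m, r) {
  phi <- function(mm) {
    nt <- length(x) - mm + 1L
    D <- matrix(0, nt, nt)
    for (k in seq_len(mm) - 1L) {
      seg <- x[(1L:nt) + k]
      D <- pmax(D, abs(outer(seg, seg, "-")))
    }
    C <- rowSums(D <= r) / nt
    mean(log(C))
  }
  phi(m) - phi(m + 1L)
}

# MI via the entropy decomposition H(X) + H(Y) - H(X, Y) on cut()-based
# equal-width binning
oracle_mi <- function(x, y, bins) {
  edges <- function(v) seq(min(v), max(v), length.out = bins + 1L)
  bx <- cut(x, edges(x), include.lowest = TRUE, right = FALSE)
  by <- cut(y, edges(y), include.lowest = TRUE, right = FALSE)
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  n <- length(x)
  H(table(bx) / n) + H(table(by) / n) - H(table(bx, by) / n)
}

# random symmetric weighted graph on n nodes; edge probability p
rand_graph <- function(n, p = 0.5, wmin = 0.2, wmax = 1) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      if (runif(1) < p) W[i, j] <- W[j, i] <- runif(1, wmin, wmax)
  dimnames(W) <- list(paste0("n", 1:n), paste0("n", 1:n))
  W
}

adjacency_from <- function(M, labels = paste0("n", seq_len(nrow(M)))) {
  dimnames(M) <- list(labels, labels)
  M
}
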