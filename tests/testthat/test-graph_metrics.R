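triangle_W <- function(ab = 1, bc = 1, ac = 1) {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- ab
  W[2, 3] <- W[3, 2] <- bc
  W[1, 3] <- W[3, 1] <- ac
  adjacency_from(W, c("A", "B", "C"))
}

star_W <- function(n) {
  W <- matrix(0, n, n)
  W[1, 2:n] <- W[2:n, 1] <- 1
  adjacency_from(W)
}

complete_W <- function(n, w = 1) {
  W <- matrix(w, n, n); diag(W) <- 0
  adjacency_from(W)
}

test_that("shortest paths use inverse-weight lengths", {
  # path A-B-C with unit weights
  P <- triangle_W(1, 1, 0)
  D <- shortest_path_matrix(P)
  expect_equal(D["A", "C"], 2)
  # weak direct edge (length 4) loses to the 2-hop route
  T2 <- triangle_W(1, 1, 0.25)
  expect_equal(shortest_path_matrix(T2)["A", "C"], 2)
  # Floyd-Warshall oracle on random graphs
  set.seed(41)
  for (i in 1:25) {
    W <- rand_graph(sample(4:8, 1))
    expect_equal(shortest_path_matrix(W), fw_distances(W),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("characteristic path length and global efficiency", {
  expect_equal(characteristic_path_length(complete_W(6)), 1.0)
  P <- triangle_W(1, 1, 0)
  expect_equal(characteristic_path_length(P), 4 / 3)
  expect_equal(global_efficiency(P), 5 / 6)
  expect_equal(global_efficiency(complete_W(5)), 1.0)
  expect_equal(global_efficiency(adjacency_from(matrix(0, 3, 3))), 0)
  # scaling all weights by c divides L by c
  set.seed(42)
  W <- rand_graph(6, p = 0.9)
  expect_equal(characteristic_path_length(3 * W),
               characteristic_path_length(W) / 3)
  # disconnection errors for L, not for efficiency
  disc <- adjacency_from(matrix(0, 3, 3))
  disc[1, 2] <- disc[2, 1] <- 1
  expect_error(characteristic_path_length(disc), "disconnected")
  expect_silent(global_efficiency(disc))
})

test_that("local efficiency: unit triangle, star leaves, oracle", {
  expect_equal(unname(local_efficiency(triangle_W())), rep(1, 3))
  le <- local_efficiency(star_W(5))
  expect_equal(unname(le[2:5]), rep(0, 4))  # single-neighbour rule
  set.seed(43)
  for (i in 1:15) {
    W <- rand_graph(7)
    expect_equal(unname(local_efficiency(W)), oracle_local_efficiency(W),
                 tolerance = 1e-12)
  }
})

test_that("clustering and transitivity: exact cases and binary reduction", {
  expect_equal(unname(clustering_coefficients(triangle_W())), rep(1, 3))
  expect_equal(unname(clustering_coefficients(star_W(5))), rep(0, 5))
  expect_equal(transitivity(triangle_W()), 1)
  expect_equal(transitivity(star_W(5)), 0)
  set.seed(44)
  for (i in 1:25) {
    A <- rand_graph(8, p = 0.5, wmin = 1, wmax = 1)  # binary graph
    expect_equal(unname(clustering_coefficients(A)),
                 oracle_binary_clustering(A), tolerance = 1e-12)
    expect_equal(transitivity(A), oracle_binary_transitivity(A),
                 tolerance = 1e-12)
  }
})

test_that("betweenness: stars, complete graphs, enumeration oracle", {
  bc <- betweenness_centrality(star_W(4))
  expect_equal(unname(bc), c(1, 0, 0, 0))
  expect_equal(unname(betweenness_centrality(complete_W(6))), rep(0, 6))
  set.seed(45)
  for (i in 1:20) {
    W <- rand_graph(sample(5:7, 1))
    expect_equal(unname(betweenness_centrality(W)), oracle_betweenness(W),
                 tolerance = 1e-12)
  }
})

test_that("degree centrality is node strength; handshake identity", {
  expect_equal(unname(degree_centrality(triangle_W())), rep(2, 3))
  s <- degree_centrality(star_W(5))
  expect_equal(unname(s), c(4, 1, 1, 1, 1))
  set.seed(46)
  W <- rand_graph(8)
  expect_equal(sum(degree_centrality(W)), 2 * graph_density(W))
})

test_that("density is the total edge weight", {
  expect_equal(graph_density(triangle_W()), 3)
  expect_equal(graph_density(adjacency_from(matrix(0, 4, 4))), 0)
  set.seed(47)
  W <- rand_graph(6)
  expect_equal(graph_density(2 * W), 2 * graph_density(W))
})

test_that("modularity: single community zero, two triangles = 0.5, detector", {
  W <- triangle_W()
  expect_equal(emograph:::modularity_of(W, rep(1, 3)), 0)
  # two disjoint unit triangles
  W6 <- matrix(0, 6, 6)
  W6[1:3, 1:3] <- triangle_W()
  W6[4:6, 4:6] <- triangle_W()
  W6 <- adjacency_from(W6)
  expect_equal(modularity(W6), 0.5)
  expect_equal(oracle_max_modularity(W6), 0.5)
  det <- modularity(W6, details = TRUE)
  expect_equal(length(unique(det$membership)), 2L)
  expect_equal(modularity(adjacency_from(matrix(0, 4, 4))), 0)
})

test_that("metrics agree with igraph on random weighted graphs", {
  skip_if_not_installed("igraph")
  set.seed(48)
  for (i in 1:10) {
    W <- rand_graph(8, p = 0.7)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    len <- 1 / igraph::E(g)$weight
    expect_equal(unname(shortest_path_matrix(W)),
                 unname(igraph::distances(g, weights = len)),
                 tolerance = 1e-12)
    expect_equal(unname(betweenness_centrality(W)),
                 unname(igraph::betweenness(g, weights = len)) * 2 / (7 * 6),
                 tolerance = 1e-10)
    expect_equal(unname(degree_centrality(W)),
                 unname(igraph::strength(g)), tolerance = 1e-12)
  }
})

test_that("node permutation permutes locals and fixes globals", {
  set.seed(49)
  W <- rand_graph(7, p = 0.8)
  perm <- sample(7)
  Wp <- W[perm, perm]
  expect_equal(characteristic_path_length(Wp), characteristic_path_length(W))
  expect_equal(global_efficiency(Wp), global_efficiency(W))
  expect_equal(transitivity(Wp), transitivity(W))
  expect_equal(graph_density(Wp), graph_density(W))
  expect_equal(modularity(Wp), modularity(W), tolerance = 1e-10)
  expect_equal(unname(clustering_coefficients(Wp)),
               unname(clustering_coefficients(W))[perm])
  expect_equal(unname(betweenness_centrality(Wp)),
               unname(betweenness_centrality(W))[perm], tolerance = 1e-12)
  expect_equal(unname(local_efficiency(Wp)),
               unname(local_efficiency(W))[perm])
})

test_that("harmonic-arithmetic inequality on complete positive graphs", {
  set.seed(50)
  for (i in 1:10) {
    W <- rand_graph(6, p = 1)
    expect_lte(1 / characteristic_path_length(W),
               global_efficiency(W) + 1e-12)
  }
})

test_that("graph feature block: size, names, determinism", {
  recs <- tiny_recordings()
  win <- slide_windows(recs[[1]]$trials[[1]], recs[[1]]$rate_hz)[[1]]
  W <- connectivity_matrix(win)
  blk <- graph_feature_block(W)
  expect_length(blk, 5 + 4 * 14)  # 61 for the Emotiv montage
  expect_false(anyDuplicated(names(blk)) > 0)
  expect_identical(names(blk)[1:5],
                   c("characteristic_path_length", "global_efficiency",
                     "transitivity", "modularity", "density"))
  expect_identical(names(blk)[6], "clustering_coefficient__AF3")
  expect_identical(blk, graph_feature_block(W))  # deterministic

  W32 <- complete_W(32, 0.5)
  expect_length(graph_feature_block(W32), 133L)  # 5 + 4*32
})
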