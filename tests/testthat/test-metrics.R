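test_that("clustering, path length and betweenness match textbook cases", {
  k3 <- complete_graph(3)
  expect_equal(nodal_clustering(k3)$Ci, c(1, 1, 1))
  expect_equal(nodal_clustering(k3)$C, 1)
  expect_equal(characteristic_path_length(k3), 1)
  p3 <- path_graph(3)
  expect_equal(nodal_clustering(p3)$Ci[2], 0)  # k = 2, no neighbour edge
  p4 <- path_graph(4)
  expect_equal(characteristic_path_length(p4), 10 / 6)
  # star: all leaf pairs route through the centre
  s4 <- star_graph(4)
  expect_equal(betweenness_centrality(s4), c(3, 0, 0, 0))
  expect_equal(as.numeric(normalized_betweenness(betweenness_centrality(s4))),
               c(4, 0, 0, 0))
  # 4-cycle: each opposite pair splits its two geodesics over two routes
  expect_equal(betweenness_centrality(cycle_graph(4)), rep(0.5, 4))
})

test_that("graph metrics equal brute-force oracles on every small connected graph", {
  # exhaustive over all connected labelled graphs with <= 5 nodes
  for (n in 3:5) {
    for (adj in enumerate_connected_graphs(n)) {
      expect_equal(nodal_clustering(adj)$Ci, oracle_clustering(adj)$Ci)
      expect_equal(characteristic_path_length(adj), oracle_path_length(adj))
      expect_equal(betweenness_centrality(adj), oracle_betweenness(adj),
                   tolerance = 1e-9)
    }
  }
  # sampled connected graphs with 6-8 nodes
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(6:8, 1)
    adj <- random_connected_graph(n, runif(1, 0.3, 0.7))
    expect_equal(nodal_clustering(adj)$Ci, oracle_clustering(adj)$Ci)
    expect_equal(characteristic_path_length(adj), oracle_path_length(adj))
    expect_equal(betweenness_centrality(adj), oracle_betweenness(adj),
                 tolerance = 1e-9)
  }
})

test_that("graph metrics equal oracles and igraph on seeded 10-12 node graphs", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(10:12, 1)
    adj <- random_connected_graph(n, runif(1, 0.25, 0.6))
    expect_equal(betweenness_centrality(adj), oracle_betweenness(adj),
                 tolerance = 1e-9)
    expect_equal(nodal_clustering(adj)$Ci, oracle_clustering(adj)$Ci)
    expect_equal(characteristic_path_length(adj), oracle_path_length(adj))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(betweenness_centrality(adj),
                 unname(igraph::betweenness(g)), tolerance = 1e-9)
    ci_ig <- igraph::transitivity(g, type = "local", isolates = "zero")
    ki <- rowSums(adj)
    ci_ig[ki < 2] <- 0
    expect_equal(nodal_clustering(adj)$Ci, ci_ig)
    expect_equal(characteristic_path_length(adj),
                 igraph::mean_distance(g, directed = FALSE))
  }
})

test_that("disconnected networks error by default, with a connected-pairs mode", {
  two_tri <- adjacency_from_edges(6, rbind(c(1, 2), c(2, 3), c(1, 3),
                                           c(4, 5), c(5, 6), c(4, 6)))
  expect_error(characteristic_path_length(two_tri), "3, 3")
  L <- characteristic_path_length(two_tri, disconnected = "connected_pairs")
  expect_equal(as.numeric(L), 1)
  expect_true(attr(L, "connected_pairs_only"))
  # betweenness: disconnected pairs contribute nothing
  expect_equal(betweenness_centrality(two_tri), rep(0, 6))
})

test_that("normalized betweenness has mean 1 and flags the degenerate case", {
  set.seed(8)
  adj <- random_connected_graph(10, 0.3)
  b <- normalized_betweenness(betweenness_centrality(adj))
  expect_equal(mean(b), 1)
  expect_equal(as.numeric(normalized_betweenness(c(2, 2, 2))), c(1, 1, 1))
  # complete graph: all betweenness zero -> undefined flag
  bk <- normalized_betweenness(betweenness_centrality(complete_graph(5)))
  expect_true(all(is.na(bk)))
  expect_true(attr(bk, "undefined"))
  expect_error(normalized_betweenness(c(-1, 2)), "non-negative")
})

test_that("random references preserve the degree sequence exactly", {
  net <- generate_latent_network(90, 8, 0.05, seed = 1)
  adj <- as_adjacency(net)
  set.seed(2)
  ref <- random_reference(adj)
  expect_identical(rowSums(ref), rowSums(adj))      # per node, not just sorted
  expect_true(all(diag(ref) == 0))
  expect_true(all(ref %in% c(0, 1)))
  expect_true(isSymmetric(ref))
  expect_false(identical(ref, adj))
  # seeded determinism
  set.seed(2)
  expect_identical(random_reference(adj), ref)
  # randomization destroys lattice clustering
  expect_lt(nodal_clustering(ref)$C, nodal_clustering(adj)$C)
})

test_that("small-world indices are internally consistent and directionally right", {
  net <- generate_latent_network(90, 8, 0, seed = 1)  # pure ring lattice
  set.seed(3)
  sw <- small_world(net, n_random = 20)
  expect_equal(sw$sigma, sw$gamma / sw$lambda)
  expect_gt(sw$gamma, 2)                     # regular lattice: strong clustering
  expect_equal(sw$density, 8 / 89)
  expect_length(sw$C_refs, 20)
  # a randomized graph is its own reference: gamma, lambda, sigma near 1
  set.seed(4)
  rnd <- random_reference(as_adjacency(net))
  set.seed(5)
  sw0 <- small_world(rnd, n_random = 30)
  expect_lt(abs(sw0$gamma - 1), 0.3)
  expect_lt(abs(sw0$lambda - 1), 0.1)
  expect_error(small_world(adjacency_from_edges(4, rbind(c(1, 2), c(3, 4)))),
               "connected")
})

test_that("clustering and path length fall along the rewiring trajectory", {
  set.seed(9)
  mean_CL <- function(p) {
    C <- L <- numeric(5)
    for (i in 1:5) {
      adj <- as_adjacency(generate_latent_network(60, 6, p))
      C[i] <- nodal_clustering(adj)$C
      L[i] <- characteristic_path_length(adj, disconnected = "connected_pairs")
    }
    c(C = mean(C), L = mean(L))
  }
  traj <- vapply(c(0, 0.2, 1), mean_CL, numeric(2))
  expect_true(all(diff(traj["C", ]) < 0))
  expect_true(all(diff(traj["L", ]) < 0))
})

test_that("hub identification applies the strict threshold with stable ordering", {
  rt <- load_region_table()
  b <- rep(1, 90)
  expect_equal(nrow(identify_hubs(b, rt)), 0)   # all b = 1: no hubs
  b[c(5, 12, 40)] <- c(2.5, 1.6, 2.5)
  hubs <- identify_hubs(b, rt)
  expect_equal(hubs$index, c(5, 40, 12))        # ties broken by region index
  expect_equal(nrow(identify_hubs(b, rt, threshold = 2.5)), 0)  # strict >
  # membership invariant under positive rescaling of B
  B <- runif(90) + 0.1
  h1 <- identify_hubs(normalized_betweenness(B), rt)
  h2 <- identify_hubs(normalized_betweenness(17.3 * B), rt)
  expect_equal(h1$index, h2$index)
})

test_that("shared hubs intersect by region identity", {
  rt <- load_region_table()
  b1 <- rep(0, 90); b1[c(3, 7, 20)] <- 2
  b2 <- rep(0, 90); b2[c(7, 20, 55)] <- 3
  h1 <- identify_hubs(b1, rt); h2 <- identify_hubs(b2, rt)
  sh <- shared_hubs(h1, h2)
  expect_equal(sh$index, c(7, 20))
  expect_equal(nrow(shared_hubs(h1, identify_hubs(rep(0, 90), rt))), 0)
  self <- shared_hubs(h1, h1)
  expect_equal(self$index, sort(h1$index))
})
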