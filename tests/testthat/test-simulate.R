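test_that("latent ring lattice is deterministic with the stated degree", {
  net <- generate_latent_network(12, 4, 0)
  adj <- as_adjacency(net)
  expect_true(all(rowSums(adj) == 4))
  expect_equal(net$density, 4 / 11)
  # no rewiring: same graph every time regardless of RNG state
  expect_identical(adj, as_adjacency(generate_latent_network(12, 4, 0)))
  # k = 4 ring lattice clustering, frozen from neighbour-pair enumeration
  expect_equal(nodal_clustering(adj)$C, 0.5)
  expect_equal(oracle_clustering(adj)$C, 0.5)
})

test_that("rewired latent networks preserve density, stay connected, reproduce", {
  net1 <- generate_latent_network(90, 8, 0.1, seed = 11)
  net2 <- generate_latent_network(90, 8, 0.1, seed = 11)
  expect_identical(as_adjacency(net1), as_adjacency(net2))
  adj <- as_adjacency(net1)
  expect_equal(sum(adj) / 2, 90 * 8 / 2)          # exact edge count
  expect_equal(net1$density, 8 / 89)
  expect_equal(largest_component_size(net1), 90)
  # a different seed gives a different graph
  expect_false(identical(adj, as_adjacency(generate_latent_network(90, 8, 0.1,
                                                                   seed = 12))))
  expect_error(generate_latent_network(12, 3, 0), "even")
  expect_error(generate_latent_network(12, 14, 0), "below")
})

test_that("distance-decay correlation matches its formula and is repaired PD", {
  net <- generate_latent_network(20, 4, 0.2, seed = 3)
  adj <- as_adjacency(net)
  R <- correlation_from_network(net, edge_corr = 0.6, corr_decay = 0.5)
  expect_equal(diag(R), rep(1, 20))
  expect_true(isSymmetric(R))
  expect_gt(attr(R, "min_eigenvalue"), 0)
  dev <- attr(R, "repair_max_dev")
  D <- oracle_distances(adj)
  # adjacent pair: target 0.6; distance 3: target 0.6 * 0.5^2 = 0.15,
  # both up to the reported repair deviation
  ij1 <- which(D == 1, arr.ind = TRUE)[1, ]
  expect_lte(abs(R[ij1[1], ij1[2]] - 0.6), dev + 1e-12)
  ij3 <- which(D == 3, arr.ind = TRUE)
  if (nrow(ij3)) {
    expect_lte(abs(R[ij3[1, 1], ij3[1, 2]] - 0.15), dev + 1e-12)
  }
})

test_that("generate_cohort honours sizes, seed determinism and null sharing", {
  spec <- cohort_spec(seed = 7)
  coh <- generate_cohort(spec)
  expect_equal(nrow(coh$panel_a$values), 73)
  expect_equal(nrow(coh$panel_b$values), 91)
  expect_equal(ncol(coh$panel_a$values), 90)
  expect_true(all(coh$panel_a$values > 0))
  # bit-reproducible
  coh2 <- generate_cohort(spec)
  expect_identical(coh$panel_a$values, coh2$panel_a$values)
  expect_identical(coh$panel_b$covariates, coh2$panel_b$covariates)
  # no perturbation: one shared latent topology and correlation
  coh0 <- generate_cohort(cohort_spec(n_group_a = 10, n_group_b = 12,
                                      n_regions = 20, latent_degree = 4,
                                      group_b_perturbation = 0, seed = 5))
  expect_identical(coh0$truth$adjacency_a, coh0$truth$adjacency_b)
  expect_identical(coh0$truth$correlation_a, coh0$truth$correlation_b)
  # perturbation at matched density keeps the edge count
  cohp <- generate_cohort(cohort_spec(n_group_a = 10, n_group_b = 12,
                                      n_regions = 30, latent_degree = 6,
                                      group_b_perturbation = 0.3, seed = 5))
  expect_equal(sum(cohp$truth$adjacency_b), sum(cohp$truth$adjacency_a))
  expect_false(identical(cohp$truth$adjacency_a, cohp$truth$adjacency_b))
  # degree-preserving mode keeps every node's degree
  expect_equal(rowSums(cohp$truth$adjacency_b), rowSums(cohp$truth$adjacency_a))
})

test_that("cohort_spec validates its parameters", {
  expect_error(cohort_spec(n_group_a = 2), "n_group_a")
  expect_error(cohort_spec(latent_degree = 5))
  expect_error(cohort_spec(rewire_prob = 1.5))
  expect_error(cohort_spec(edge_corr = 0))
  expect_error(cohort_spec(covariate_effects = list(age = 0)), "glucose")
  expect_error(cohort_spec(perturb_target = 200))
})

test_that("null pairs are exchangeable by construction and consistent at large n", {
  spec <- cohort_spec(n_group_a = 10, n_group_b = 12, n_regions = 20,
                      latent_degree = 4, seed = 9)
  np <- generate_null_pair(spec)
  expect_identical(np$truth$correlation_a, np$truth$correlation_b)
  expect_identical(np$truth$adjacency_a, np$truth$adjacency_b)
  # Monte-Carlo consistency on the latent (log) scale: with no noise, no
  # covariate effects and no global factor, log-values are exactly the
  # planted Gaussian, so the sample correlation converges to the planted
  # matrix; at n = 1500 the max deviation over 780 pairs is bounded by
  # ~sqrt(2 log 780) standard errors (~0.10), tested at 0.15
  specL <- cohort_spec(n_group_a = 1500, n_group_b = 3, n_regions = 40,
                       latent_degree = 6, noise_sd = 0, signal_sd = 0.05,
                       global_sd = 0,
                       covariate_effects = list(age = 0, sex = 0, glucose = 0),
                       group_b_perturbation = 0, seed = 5)
  npL <- generate_null_pair(specL)
  rhat <- cor(log(npL$panel_a$values))
  expect_lt(max(abs(rhat - npL$truth$correlation_a)), 0.15)
})

test_that("thresholding residualized data recovers the planted edge set", {
  # covariate effects off, small noise, n = 500: edges recovered at the
  # latent density with Jaccard >= 0.9 (fixed seed)
  spec <- cohort_spec(n_group_a = 500, n_group_b = 3, n_regions = 90,
                      latent_degree = 8, rewire_prob = 0.1, noise_sd = 0.05,
                      covariate_effects = list(age = 0, sex = 0, glucose = 0),
                      group_b_perturbation = 0, seed = 99)
  coh <- generate_cohort(spec)
  truth <- coh$truth$adjacency_a
  corr <- pearson_matrix(preprocess_panel(coh$panel_a))
  dens <- sum(truth) / 2 / (90 * 89 / 2)
  est <- as_adjacency(density_threshold(corr, dens))
  jaccard <- (sum(est * truth) / 2) / (sum((est + truth) > 0) / 2)
  expect_gte(jaccard, 0.9)
})

test_that("residualization removes the injected covariate structure", {
  spec <- cohort_spec(n_group_a = 500, n_group_b = 3, seed = 17)
  coh <- generate_cohort(spec)
  res <- preprocess_panel(coh$panel_a)
  for (v in c("age", "sex", "glucose")) {
    expect_lt(max(abs(cor(res$residuals, coh$panel_a$covariates[[v]]))), 0.05)
  }
})

test_that("targeted perturbation degrades the planted node's centrality", {
  net <- generate_latent_network(90, 8, 0.1, seed = 21)
  target <- which.max(betweenness_centrality(net))
  coh <- generate_cohort(cohort_spec(group_b_perturbation = 0.75,
                                     perturb_target = target, seed = 21))
  b_a <- normalized_betweenness(betweenness_centrality(coh$truth$adjacency_a))
  b_b <- normalized_betweenness(betweenness_centrality(coh$truth$adjacency_b))
  expect_gt(b_a[target], 1.5)        # it is a latent hub in group A
  expect_lt(b_b[target], b_a[target] / 2)
  expect_equal(largest_component_size(coh$truth$adjacency_b), 90)
})
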