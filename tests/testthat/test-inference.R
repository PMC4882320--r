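tiny_null_pair <- function(seed, n = 15, regions = 20) {
  generate_null_pair(cohort_spec(n_group_a = n, n_group_b = n,
                                 n_regions = regions, latent_degree = 4,
                                 group_b_perturbation = 0, seed = seed))
}

test_that("identical groups give a zero observed difference, never significant", {
  np <- tiny_null_pair(1)
  g <- global_permutation_test(np$panel_a, np$panel_a, densities = 0.25,
                               metrics = "C", n_perm = 30, seed = 2)
  expect_equal(g$table$observed, 0)
  expect_false(g$table$significant)
  nt <- nodal_permutation_test(np$panel_a, np$panel_a, density = 0.25,
                               n_perm = 30, seed = 2)
  expect_equal(nt$table$observed, rep(0, 20))
  expect_false(any(nt$table$significant_decrease))
  expect_false(any(nt$table$significant_increase))
})

test_that("permutation results are bit-reproducible for a fixed seed", {
  np <- tiny_null_pair(3)
  g1 <- global_permutation_test(np$panel_a, np$panel_b,
                                densities = c(0.2, 0.25),
                                metrics = c("C", "L"), n_perm = 50, seed = 9)
  g2 <- global_permutation_test(np$panel_a, np$panel_b,
                                densities = c(0.2, 0.25),
                                metrics = c("C", "L"), n_perm = 50, seed = 9)
  expect_identical(g1$null, g2$null)
  expect_identical(g1$table, g2$table)
  # and depend on the seed
  g3 <- global_permutation_test(np$panel_a, np$panel_b,
                                densities = c(0.2, 0.25),
                                metrics = c("C", "L"), n_perm = 50, seed = 10)
  expect_false(identical(g1$null, g3$null))
  # null dimensions: metrics x densities x permutations
  expect_equal(dim(g1$null), c(2, 2, 50))
  expect_error(global_permutation_test(np$panel_a, np$panel_b, n_perm = 10),
               "at least 20")
})

test_that("p-values follow the add-one convention and flags match them", {
  np <- tiny_null_pair(4)
  g <- global_permutation_test(np$panel_a, np$panel_b, densities = 0.25,
                               metrics = "C", n_perm = 40, seed = 5)
  tab <- g$table
  expect_gte(tab$p_value, 1 / 41)
  expect_lte(tab$p_value, 1)
  nv <- g$null[1, 1, ]
  expect_equal(tab$p_upper, (1 + sum(nv >= tab$observed)) / 41)
  expect_equal(tab$p_lower, (1 + sum(nv <= tab$observed)) / 41)
  expect_equal(tab$p_abs, (1 + sum(abs(nv) >= abs(tab$observed))) / 41)
  expect_equal(tab$significant, tab$p_value <= g$alpha)
})

test_that("observed rank within the null is uniform for exchangeable cohorts", {
  # reduced-scale exchangeability check: one-sided permutation p-values over
  # independent null replicates should be close to uniform
  pv <- numeric(40)
  for (i in seq_len(40)) {
    np <- tiny_null_pair(300 + i)
    g <- global_permutation_test(np$panel_a, np$panel_b, densities = 0.25,
                                 metrics = "C", n_perm = 60, seed = 500 + i)
    pv[i] <- g$table$p_upper
  }
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.005)
})

test_that("nodal test reports directional decisions per region", {
  np <- tiny_null_pair(6)
  nt <- nodal_permutation_test(np$panel_a, np$panel_b, density = 0.25,
                               n_perm = 60, seed = 7,
                               region_table = NULL)
  expect_equal(nrow(nt$table), 20)
  expect_true(all(nt$table$p_lower >= 1 / 61 & nt$table$p_lower <= 1))
  expect_equal(nt$table$significant_decrease, nt$table$p_lower <= 0.05)
  expect_equal(nt$table$significant_increase, nt$table$p_upper <= 0.05)
  expect_equal(dim(nt$null), c(60, 20))
})

test_that("betweenness distribution correlation behaves like Pearson", {
  set.seed(10)
  b <- runif(90, 0, 3)
  expect_equal(centrality_distribution_correlation(b, b)$r, 1)
  centred <- b - mean(b)
  expect_equal(centrality_distribution_correlation(centred, -centred)$r, -1)
  # independent vectors: near-zero correlation
  for (i in 1:5) {
    r <- centrality_distribution_correlation(runif(90), runif(90))$r
    expect_lt(abs(r), 0.3)
  }
  out <- centrality_distribution_correlation(rnorm(90), rnorm(90))
  expect_true(out$p >= 0 && out$p <= 1)
  expect_error(centrality_distribution_correlation(rep(1, 5), rnorm(5)),
               "zero-variance")
  expect_error(centrality_distribution_correlation(rnorm(4), rnorm(5)),
               "equal length")
})

test_that("density runs are formatted in percentage notation", {
  expect_equal(format_density_runs(c(0.10, 0.11, 0.12, 0.34)), "10-12, 34")
  expect_equal(format_density_runs(c(0.36, 0.37, 0.38, 0.39, 0.40)), "36-40")
  expect_equal(format_density_runs(0.1), "10")
  expect_equal(format_density_runs(numeric(0)), "none")
})
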