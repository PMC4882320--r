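# Synthetic two-group cohorts with a known ground-truth covariance topology.
# The generator emulates the statistical structure the pipeline assumes:
# positive, globally-scaled regional uptake values whose cross-subject
# correlations are induced by a latent small-world graph, contaminated by
# linear age/sex/glucose effects.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Specify a synthetic cohort
#'
#' Bundles and validates all generator parameters. Defaults emulate the
#' design of the motivating FDG-PET study: two groups of 73 and 91 subjects
#' over 90 regions, with Table-style covariate distributions (age about
#' 57 +/- 10 vs 56 +/- 8 years, fasting glucose about 8.4 +/- 0.9 vs
#' 5.1 +/- 0.4 mmol/L, mostly male) and a ring-rewired latent graph of mean
#' degree 8.
#'
#' @param n_group_a,n_group_b Subject counts (>= 3).
#' @param n_regions Number of regions (default 90).
#' @param latent_degree Even mean degree of the latent ground-truth graph.
#' @param rewire_prob Ring-rewiring probability in \[0, 1\].
#' @param edge_corr Target correlation of adjacent regions, in (0, 1).
#' @param corr_decay Per-hop multiplicative correlation decay, in (0, 1).
#' @param signal_sd Log-scale standard deviation of the correlated regional
#'   signal (dimensionless; default 0.15, a mild lognormal).
#' @param noise_sd Independent noise scale relative to the signal
#'   (default 0.3; sample correlations are attenuated by
#'   `1 / (1 + noise_sd^2)`).
#' @param covariate_effects Named list of per-unit log-scale coefficients
#'   (`age` per year, `sex` for male vs female, `glucose` per mmol/L); each
#'   a scalar or an `n_regions` vector.
#' @param group_b_perturbation Fraction of latent edges rewired only in
#'   group B, in \[0, 1\] (0 = both groups share one topology).
#' @param perturb_target Optional node index: instead of degree-preserving
#'   rewiring across the whole graph, move that fraction of the target
#'   node's edges elsewhere (a planted focal hub degradation).
#' @param global_sd Log-scale SD of the per-subject global scaling factor.
#' @param seed Integer seed; all generation is reproducible given the spec.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 73, n_group_b = 91, n_regions = 90,
                        latent_degree = 8, rewire_prob = 0.1,
                        edge_corr = 0.6, corr_decay = 0.5,
                        signal_sd = 0.15, noise_sd = 0.3,
                        covariate_effects = list(age = -0.002, sex = 0.02,
                                                 glucose = -0.01),
                        group_b_perturbation = 0.1, perturb_target = NULL,
                        global_sd = 0.2, seed = 1L) {
  spec <- list(n_group_a = n_group_a, n_group_b = n_group_b,
               n_regions = n_regions, latent_degree = latent_degree,
               rewire_prob = rewire_prob, edge_corr = edge_corr,
               corr_decay = corr_decay, signal_sd = signal_sd,
               noise_sd = noise_sd, covariate_effects = covariate_effects,
               group_b_perturbation = group_b_perturbation,
               perturb_target = perturb_target, global_sd = global_sd,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_group_a >= 3, n_group_b >= 3, n_regions >= 4,
              latent_degree %% 2 == 0, latent_degree >= 2,
              latent_degree < n_regions,
              rewire_prob >= 0, rewire_prob <= 1,
              edge_corr > 0, edge_corr < 1,
              corr_decay > 0, corr_decay < 1,
              signal_sd > 0, noise_sd >= 0, global_sd >= 0,
              group_b_perturbation >= 0, group_b_perturbation <= 1)
  })
  if (!all(c("age", "sex", "glucose") %in% names(spec$covariate_effects))) {
    stop("covariate_effects must name age, sex and glucose")
  }
  if (!is.null(spec$perturb_target)) {
    stopifnot(spec$perturb_target >= 1, spec$perturb_target <= n_regions)
  }
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a latent small-world ground-truth network
#'
#' Starts from the deterministic ring lattice in which every node is linked
#' to its `latent_degree / 2` nearest neighbours on each side, then rewires
#' each lattice edge with probability `rewire_prob` to a uniformly chosen
#' new endpoint (no self-loops or duplicate edges), Watts-Strogatz style.
#' The edge count — hence the density `latent_degree / (n_regions - 1)` —
#' is preserved exactly. Regeneration is attempted until the graph is
#' connected.
#'
#' @param n_regions Number of nodes.
#' @param latent_degree Even lattice degree (>= 2, < `n_regions`).
#' @param rewire_prob Per-edge rewiring probability in \[0, 1\].
#' @param seed Optional seed (restores the caller's RNG state afterwards).
#' @return A `binary_network`.
#' @export
generate_latent_network <- function(n_regions, latent_degree, rewire_prob,
                                    seed = NULL) {
  if (latent_degree %% 2 != 0 || latent_degree < 2 ||
      latent_degree >= n_regions) {
    stop("latent_degree must be even, >= 2 and below n_regions")
  }
  .with_seed(seed, {
    for (attempt in seq_len(100)) {
      adj <- .ring_lattice(n_regions, latent_degree)
      if (rewire_prob > 0) {
        for (step in seq_len(latent_degree / 2)) {
          for (i in seq_len(n_regions)) {
            j <- ((i - 1 + step) %% n_regions) + 1
            if (adj[i, j] == 0) next  # already rewired away
            if (stats::runif(1) >= rewire_prob) next
            candidates <- which(adj[i, ] == 0 & seq_len(n_regions) != i)
            if (!length(candidates)) next
            newj <- candidates[sample.int(length(candidates), 1)]
            adj[i, j] <- adj[j, i] <- 0
            adj[i, newj] <- adj[newj, i] <- 1
          }
        }
      }
      if (.is_connected(adj)) return(.new_binary_network(adj))
    }
    stop("could not generate a connected latent network in 100 attempts")
  })
}

#' Distance-decay correlation matrix implied by a latent network
#'
#' Builds the target correlation `r_ij = edge_corr * corr_decay^(d_ij - 1)`
#' from the shortest-path distances `d_ij` of a connected latent graph
#' (adjacent regions correlate at `edge_corr`, correlation decaying
#' geometrically with each extra hop), then repairs the result to the
#' nearest symmetric positive-definite correlation matrix by eigenvalue
#' clipping (floor 1e-6) and renormalization to unit diagonal.
#'
#' @param net A connected `binary_network` or adjacency matrix.
#' @param edge_corr,corr_decay As in [cohort_spec()].
#' @return A correlation matrix with attributes `repair_max_dev` (largest
#'   absolute entry change introduced by the repair) and `min_eigenvalue`.
#' @export
correlation_from_network <- function(net, edge_corr = 0.6, corr_decay = 0.5) {
  adj <- as_adjacency(net)
  if (!.is_connected(adj)) stop("latent network must be connected")
  D <- .bfs_distances(adj)
  R <- edge_corr * corr_decay^(D - 1)
  diag(R) <- 1
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 1e-6)
  R2 <- e$vectors %*% (vals * t(e$vectors))
  R2 <- stats::cov2cor(R2)
  R2 <- (R2 + t(R2)) / 2
  min_eig <- min(eigen(R2, symmetric = TRUE, only.values = TRUE)$values)
  if (min_eig <= 0) stop("correlation matrix not positive definite after repair")
  attr(R2, "repair_max_dev") <- max(abs(R2 - R))
  attr(R2, "min_eigenvalue") <- min_eig
  R2
}

# Degree-preserving rewiring of ~fraction*m edges (double-edge swaps), or a
# targeted detachment of the planted node's edges; retried for connectivity.
.perturb_network <- function(adj, fraction, target = NULL) {
  if (fraction <= 0) return(adj)
  n <- nrow(adj)
  for (attempt in seq_len(100)) {
    a <- adj
    if (is.null(target)) {
      m <- sum(a) / 2
      goal <- ceiling(fraction * m / 2)  # each swap rewires two edges
      done <- 0L
      tries <- 0L
      while (done < goal && tries < 200 * goal) {
        tries <- tries + 1L
        edges <- .edge_list(a)
        pick <- sample.int(nrow(edges), 2L)
        e1 <- edges[pick[1L], ]; e2 <- edges[pick[2L], ]
        if (stats::runif(1) < 0.5) e2 <- rev(e2)
        if (length(unique(c(e1, e2))) < 4L) next
        if (a[e1[1], e2[2]] != 0 || a[e2[1], e1[2]] != 0) next
        a[e1[1], e1[2]] <- a[e1[2], e1[1]] <- 0
        a[e2[1], e2[2]] <- a[e2[2], e2[1]] <- 0
        a[e1[1], e2[2]] <- a[e2[2], e1[1]] <- 1
        a[e2[1], e1[2]] <- a[e1[2], e2[1]] <- 1
        done <- done + 1L
      }
    } else {
      nbrs <- which(a[target, ] != 0)
      k_move <- min(length(nbrs) - 1L, max(1L, round(fraction * length(nbrs))))
      if (k_move < 1) return(a)
      move <- sample(nbrs, k_move)
      for (v in move) {
        a[target, v] <- a[v, target] <- 0
        # re-attach the freed edge between two random non-adjacent others
        for (tr in seq_len(500)) {
          pq <- sample(setdiff(seq_len(n), target), 2L)
          if (a[pq[1], pq[2]] == 0) {
            a[pq[1], pq[2]] <- a[pq[2], pq[1]] <- 1
            break
          }
        }
      }
    }
    if (.is_connected(a)) return(a)
  }
  stop("could not perturb the network while keeping it connected")
}

.draw_covariates <- function(n, profile) {
  data.frame(
    age = stats::rnorm(n, profile$age_mean, profile$age_sd),
    sex = stats::rbinom(n, 1, profile$p_male),
    glucose = stats::rnorm(n, profile$glucose_mean, profile$glucose_sd)
  )
}

# Covariate profiles for the two emulated groups (patients / controls).
.group_profiles <- function() {
  list(A = list(age_mean = 57, age_sd = 10, p_male = 54 / 73,
                glucose_mean = 8.4, glucose_sd = 0.9),
       B = list(age_mean = 56, age_sd = 8, p_male = 66 / 91,
                glucose_mean = 5.1, glucose_sd = 0.4))
}

.expand_effect <- function(x, n_regions) {
  x <- as.numeric(x)
  if (length(x) == 1) rep(x, n_regions)
  else if (length(x) == n_regions) x
  else stop("covariate effect must be scalar or length n_regions")
}

.simulate_panel <- function(n, R, mu_log, betas, spec, profile, group) {
  n_regions <- spec$n_regions
  cov <- .draw_covariates(n, profile)
  Z <- MASS::mvrnorm(n, mu = rep(0, n_regions), Sigma = R)
  if (n == 1) Z <- matrix(Z, nrow = 1)
  eps <- matrix(stats::rnorm(n * n_regions), n, n_regions)
  x <- matrix(mu_log, n, n_regions, byrow = TRUE) +
    spec$signal_sd * (Z + spec$noise_sd * eps) +
    outer(cov$age, betas$age) + outer(cov$sex, betas$sex) +
    outer(cov$glucose, betas$glucose)
  g <- exp(stats::rnorm(n, 0, spec$global_sd))
  values <- g * exp(x)
  colnames(values) <- sprintf("R%03d", seq_len(n_regions))
  subject_panel(values, cov, group = group,
                subject_ids = sprintf("%s%03d", group, seq_len(n)))
}

#' Generate a synthetic two-group cohort with known ground truth
#'
#' Draws two subject panels whose cross-subject regional correlation
#' structure is induced by a latent small-world graph
#' ([generate_latent_network()] + [correlation_from_network()]): regional
#' log-signals are multivariate normal with the implied correlation, linear
#' age/sex/glucose effects and independent noise are added, and values are
#' exponentiated and multiplied by a lognormal per-subject global factor —
#' positive, globally scaled "metabolism-like" data whose confounds are
#' exactly what [global_normalize()] and [residualize()] remove.
#'
#' Group B either shares group A's latent topology
#' (`group_b_perturbation = 0`) or receives a topological perturbation at
#' matched density (see [cohort_spec()]).
#'
#' @param spec A [cohort_spec()].
#' @return A list with `panel_a`, `panel_b` (subject panels) and `truth`
#'   (latent adjacencies, implied correlation matrices, covariate
#'   coefficients, regional log-means, perturbation target).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(spec$seed, {
    net_a <- generate_latent_network(spec$n_regions, spec$latent_degree,
                                     spec$rewire_prob)
    adj_a <- as_adjacency(net_a)
    adj_b <- .perturb_network(adj_a, spec$group_b_perturbation,
                              spec$perturb_target)
    R_a <- correlation_from_network(adj_a, spec$edge_corr, spec$corr_decay)
    R_b <- if (identical(adj_a, adj_b)) R_a else {
      correlation_from_network(adj_b, spec$edge_corr, spec$corr_decay)
    }
    mu_log <- stats::runif(spec$n_regions, log(4), log(8))
    betas <- lapply(spec$covariate_effects[c("age", "sex", "glucose")],
                    .expand_effect, n_regions = spec$n_regions)
    profiles <- .group_profiles()
    panel_a <- .simulate_panel(spec$n_group_a, R_a, mu_log, betas, spec,
                               profiles$A, "A")
    panel_b <- .simulate_panel(spec$n_group_b, R_b, mu_log, betas, spec,
                               profiles$B, "B")
    list(panel_a = panel_a, panel_b = panel_b,
         truth = list(adjacency_a = adj_a, adjacency_b = adj_b,
                      correlation_a = R_a, correlation_b = R_b,
                      coefficients = betas, mu_log = mu_log,
                      perturb_target = spec$perturb_target,
                      spec = spec))
  })
}

#' Generate an exchangeable null cohort pair
#'
#' Both panels are drawn i.i.d. from the identical generative model (group
#' A's latent topology and covariate distributions), so the two groups are
#' exchangeable under relabeling — the configuration used to check the
#' type-I error of the permutation tests.
#'
#' @param spec A [cohort_spec()]; `group_b_perturbation` and group-specific
#'   covariate profiles are ignored.
#' @return A list with `panel_a`, `panel_b` and `truth`.
#' @export
generate_null_pair <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(spec$seed, {
    net_a <- generate_latent_network(spec$n_regions, spec$latent_degree,
                                     spec$rewire_prob)
    adj_a <- as_adjacency(net_a)
    R_a <- correlation_from_network(adj_a, spec$edge_corr, spec$corr_decay)
    mu_log <- stats::runif(spec$n_regions, log(4), log(8))
    betas <- lapply(spec$covariate_effects[c("age", "sex", "glucose")],
                    .expand_effect, n_regions = spec$n_regions)
    profile <- .group_profiles()$A
    panel_a <- .simulate_panel(spec$n_group_a, R_a, mu_log, betas, spec,
                               profile, "A")
    panel_b <- .simulate_panel(spec$n_group_b, R_a, mu_log, betas, spec,
                               profile, "B")
    list(panel_a = panel_a, panel_b = panel_b,
         truth = list(adjacency_a = adj_a, adjacency_b = adj_a,
                      correlation_a = R_a, correlation_b = R_a,
                      coefficients = betas, mu_log = mu_log,
                      perturb_target = NULL, spec = spec))
  })
}
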