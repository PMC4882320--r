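# Group-relabeling permutation tests. For every permutation the subjects are
# reassigned (without replacement, preserving the original group sizes) and
# the full network-construction pipeline — per-pseudo-group covariate
# residualization, Pearson correlation, density thresholding, metric — is
# recomputed, so the null distribution reflects the entire procedure.

# residuals of `values` on intercept + covariate columns
.fit_residuals <- function(values, covmat) {
  qr.resid(qr(cbind(1, covmat)), values)
}

# correlation -> thresholded adjacency, lean path for permutation loops
.corr_to_adjacency <- function(res, density) {
  r <- suppressWarnings(stats::cor(res))
  r[!is.finite(r)] <- 0
  as_adjacency(density_threshold(r, density))
}

# global metrics for one pseudo-group at one density
.global_metrics_once <- function(adj, metrics, n_random_refs, n_swaps) {
  out <- numeric(length(metrics))
  names(out) <- metrics
  need_sw <- any(metrics %in% c("gamma", "lambda", "sigma"))
  if (need_sw) {
    # inline small-world computation tolerating disconnected graphs
    C <- nodal_clustering(adj)$C
    L <- as.numeric(characteristic_path_length(adj,
                                               disconnected = "connected_pairs"))
    C_refs <- numeric(n_random_refs)
    L_refs <- numeric(n_random_refs)
    for (i in seq_len(n_random_refs)) {
      ref <- random_reference(adj, n_swaps_per_edge = n_swaps)
      C_refs[i] <- nodal_clustering(ref)$C
      L_refs[i] <- as.numeric(
        characteristic_path_length(ref, disconnected = "connected_pairs"))
    }
    gamma <- C / mean(C_refs)
    lambda <- L / mean(L_refs)
    vals <- c(C = C, L = L, gamma = gamma, lambda = lambda,
              sigma = gamma / lambda)
    out[] <- vals[metrics]
  } else {
    if ("C" %in% metrics) out["C"] <- nodal_clustering(adj)$C
    if ("L" %in% metrics) {
      out["L"] <- as.numeric(
        characteristic_path_length(adj, disconnected = "connected_pairs"))
    }
  }
  out
}

.perm_pvalues <- function(observed, null_values, n_perm) {
  p_upper <- (1 + sum(null_values >= observed)) / (n_perm + 1)
  p_lower <- (1 + sum(null_values <= observed)) / (n_perm + 1)
  p_abs <- (1 + sum(abs(null_values) >= abs(observed))) / (n_perm + 1)
  c(p_lower = p_lower, p_upper = p_upper, p_abs = p_abs)
}

.pool_panels <- function(panel_a, panel_b, covariates, normalize) {
  if (normalize) {
    panel_a <- global_normalize(panel_a)
    panel_b <- global_normalize(panel_b)
  }
  list(values = rbind(panel_a$values, panel_b$values),
       covmat = as.matrix(rbind(panel_a$covariates,
                                panel_b$covariates)[, covariates,
                                                    drop = FALSE]),
       n_a = nrow(panel_a$values),
       n_b = nrow(panel_b$values))
}

#' Permutation test for global network metrics across a density sweep
#'
#' Compares two groups' global network metrics (clustering `C`, path length
#' `L`, and/or the normalized indices `gamma`, `lambda`, `sigma`) at each
#' connection density by a group-relabeling permutation test: subjects are
#' repeatedly reassigned to two pseudo-groups of the original sizes, the two
#' networks are rebuilt from scratch (residualization, correlation,
#' thresholding) and the between-group metric difference is recomputed,
#' giving the null distribution of the difference. One relabeling sequence
#' is reused across all densities and metrics.
#'
#' The per-direction 95th-percentile critical values and one-tailed
#' empirical p-values (`p_lower`, `p_upper`, with the `(b + 1)/(n_perm + 1)`
#' convention) are always reported. The primary significance flag is
#' controlled by `tail`: `"auto"` (default) compares `|observed|` to the
#' null of absolute differences — a direction-agnostic test whose size is
#' the nominal `alpha` — while `"greater"`/`"less"` apply the one-tailed
#' rule in a fixed direction (difference taken as group A minus group B).
#' Benjamini-Hochberg adjusted p-values across densities are reported
#' alongside the uncorrected flags.
#'
#' @param panel_a,panel_b Subject panels for the two groups.
#' @param densities Connection densities to test (default the 10-40% sweep).
#' @param metrics Metrics to test, subset of
#'   `c("C", "L", "gamma", "lambda", "sigma")`.
#' @param n_perm Number of relabelings (>= 20; 1000 for reported analyses).
#' @param alpha Significance level (default 0.05).
#' @param n_random_refs Random references per network for the normalized
#'   metrics inside the permutation loop (default 10; the observed networks
#'   can be characterized separately with more references).
#' @param covariates Covariates residualized inside every permutation.
#' @param normalize Apply [global_normalize()] first (default `TRUE`).
#' @param tail `"auto"`, `"greater"` or `"less"` (see Details).
#' @param n_swaps_per_edge Swap attempts per edge in random references.
#' @param seed Integer seed; results are bit-reproducible given it.
#' @return An object of class `permutation_result`: `table` (one row per
#'   metric x density with observed difference, critical values, p-values,
#'   flags), `null` (metrics x densities x n_perm array), plus the call
#'   parameters.
#' @export
global_permutation_test <- function(panel_a, panel_b,
                                    densities = seq(0.10, 0.40, 0.01),
                                    metrics = c("gamma", "lambda", "sigma"),
                                    n_perm = 1000, alpha = 0.05,
                                    n_random_refs = 10,
                                    covariates = c("age", "sex", "glucose"),
                                    normalize = TRUE,
                                    tail = c("auto", "greater", "less"),
                                    n_swaps_per_edge = 10,
                                    seed = 1L) {
  tail <- match.arg(tail)
  metrics <- match.arg(metrics, c("C", "L", "gamma", "lambda", "sigma"),
                       several.ok = TRUE)
  if (n_perm < 20) stop("n_perm must be at least 20 for meaningful percentiles")
  pool <- .pool_panels(panel_a, panel_b, covariates, normalize)
  n_tot <- pool$n_a + pool$n_b
  group_stat <- function(idx_a) {
    idx_b <- setdiff(seq_len(n_tot), idx_a)
    vapply(densities, function(d) {
      adj_a <- .corr_to_adjacency(
        .fit_residuals(pool$values[idx_a, , drop = FALSE],
                       pool$covmat[idx_a, , drop = FALSE]), d)
      adj_b <- .corr_to_adjacency(
        .fit_residuals(pool$values[idx_b, , drop = FALSE],
                       pool$covmat[idx_b, , drop = FALSE]), d)
      .global_metrics_once(adj_a, metrics, n_random_refs, n_swaps_per_edge) -
        .global_metrics_once(adj_b, metrics, n_random_refs, n_swaps_per_edge)
    }, numeric(length(metrics)))
  }
  .with_seed(seed, {
    observed <- matrix(group_stat(seq_len(pool$n_a)),
                       nrow = length(metrics),
                       dimnames = list(metrics, sprintf("%.2f", densities)))
    null <- array(NA_real_,
                  dim = c(length(metrics), length(densities), n_perm),
                  dimnames = list(metrics, sprintf("%.2f", densities), NULL))
    for (p in seq_len(n_perm)) {
      idx_a <- sample.int(n_tot, pool$n_a)
      null[, , p] <- group_stat(idx_a)
    }
    rows <- list()
    for (mi in seq_along(metrics)) {
      for (di in seq_along(densities)) {
        nv <- null[mi, di, ]
        obs <- observed[mi, di]
        pv <- .perm_pvalues(obs, nv, n_perm)
        p_primary <- switch(tail, auto = pv["p_abs"],
                            greater = pv["p_upper"], less = pv["p_lower"])
        rows[[length(rows) + 1L]] <- data.frame(
          metric = metrics[mi], density = densities[di], observed = obs,
          crit_lower = unname(stats::quantile(nv, alpha)),
          crit_upper = unname(stats::quantile(nv, 1 - alpha)),
          crit_abs = unname(stats::quantile(abs(nv), 1 - alpha)),
          p_lower = unname(pv["p_lower"]), p_upper = unname(pv["p_upper"]),
          p_abs = unname(pv["p_abs"]), p_value = unname(p_primary),
          significant = unname(p_primary) <= alpha,
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    tab$p_fdr <- stats::ave(tab$p_value, tab$metric,
                            FUN = function(p) stats::p.adjust(p, "BH"))
    tab$significant_fdr <- tab$p_fdr <= alpha
    rownames(tab) <- NULL
    structure(list(table = tab, null = null, observed = observed,
                   metrics = metrics, densities = densities,
                   n_perm = n_perm, alpha = alpha, tail = tail,
                   n_random_refs = n_random_refs, seed = seed,
                   type = "global"),
              class = "permutation_result")
  })
}

#' Permutation test for nodal normalized betweenness at a fixed density
#'
#' Tests, region by region, the between-group difference in normalized
#' betweenness `b_i` of networks built at one fixed connection density
#' (10% by default: the lowest density at which every region is included
#' while false-positive paths are fewest). The permutation machinery is as
#' in [global_permutation_test()]; the two one-sided decisions at the
#' `1 - alpha` percentile are reported separately as `significant_decrease`
#' (group A below group B) and `significant_increase`.
#'
#' @inheritParams global_permutation_test
#' @param density Single connection density (default 0.10).
#' @param region_table Optional region table for labeling (used when its
#'   row count matches the panel's region count).
#' @return A `permutation_result` whose `table` has one row per region.
#' @export
nodal_permutation_test <- function(panel_a, panel_b, density = 0.10,
                                   n_perm = 1000, alpha = 0.05,
                                   covariates = c("age", "sex", "glucose"),
                                   normalize = TRUE,
                                   region_table = NULL,
                                   seed = 1L) {
  if (n_perm < 20) stop("n_perm must be at least 20 for meaningful percentiles")
  pool <- .pool_panels(panel_a, panel_b, covariates, normalize)
  n_tot <- pool$n_a + pool$n_b
  n_regions <- ncol(pool$values)
  group_stat <- function(idx_a) {
    idx_b <- setdiff(seq_len(n_tot), idx_a)
    b_of <- function(idx) {
      adj <- .corr_to_adjacency(
        .fit_residuals(pool$values[idx, , drop = FALSE],
                       pool$covmat[idx, , drop = FALSE]), density)
      b <- normalized_betweenness(betweenness_centrality(adj))
      as.numeric(b)
    }
    b_of(idx_a) - b_of(idx_b)
  }
  .with_seed(seed, {
    observed <- group_stat(seq_len(pool$n_a))
    null <- matrix(NA_real_, nrow = n_perm, ncol = n_regions)
    for (p in seq_len(n_perm)) {
      null[p, ] <- group_stat(sample.int(n_tot, pool$n_a))
    }
    tab <- data.frame(index = seq_len(n_regions), observed = observed)
    if (!is.null(region_table) && nrow(region_table) == n_regions) {
      tab$abbreviation <- region_table$abbreviation
      tab$hemisphere <- region_table$hemisphere
      tab$func_class <- region_table$func_class
    } else if (!is.null(colnames(pool$values))) {
      tab$abbreviation <- colnames(pool$values)
    }
    pvs <- t(vapply(seq_len(n_regions), function(i) {
      .perm_pvalues(observed[i], null[, i], n_perm)
    }, numeric(3)))
    tab$crit_lower <- apply(null, 2, stats::quantile, probs = alpha)
    tab$crit_upper <- apply(null, 2, stats::quantile, probs = 1 - alpha)
    tab$p_lower <- pvs[, "p_lower"]
    tab$p_upper <- pvs[, "p_upper"]
    tab$significant_decrease <- tab$p_lower <= alpha
    tab$significant_increase <- tab$p_upper <= alpha
    tab$p_two_sided <- pvs[, "p_abs"]
    tab$p_fdr <- stats::p.adjust(tab$p_two_sided, "BH")
    rownames(tab) <- NULL
    structure(list(table = tab, null = null, observed = observed,
                   density = density, n_perm = n_perm, alpha = alpha,
                   seed = seed, type = "nodal"),
              class = "permutation_result")
  })
}

#' @export
print.permutation_result <- function(x, ...) {
  if (x$type == "global") {
    cat(sprintf("Global permutation test (%d relabelings, alpha %.2f, tail '%s')\n",
                x$n_perm, x$alpha, x$tail))
    for (m in x$metrics) {
      sub <- x$table[x$table$metric == m & x$table$significant, ]
      cat(sprintf("  %-6s significant at: %s\n", m,
                  if (nrow(sub)) paste0(format_density_runs(sub$density), "%")
                  else "none"))
    }
  } else {
    cat(sprintf("Nodal permutation test at density %.2f (%d relabelings, alpha %.2f)\n",
                x$density, x$n_perm, x$alpha))
    dec <- sum(x$table$significant_decrease)
    inc <- sum(x$table$significant_increase)
    cat(sprintf("  %d region(s) significantly decreased, %d increased (A vs B)\n",
                dec, inc))
  }
  invisible(x)
}

#' Compress a set of densities into percentage run notation
#'
#' Formats e.g. `c(0.10, 0.11, 0.12, 0.34)` as `"10-12, 34"`, the notation
#' used for per-density significance summaries.
#'
#' @param densities Numeric densities (fractions).
#' @return A single string.
#' @export
format_density_runs <- function(densities) {
  if (!length(densities)) return("none")
  pct <- sort(unique(as.integer(round(100 * densities))))
  breaks <- c(0, which(diff(pct) > 1), length(pct))
  runs <- vapply(seq_len(length(breaks) - 1), function(i) {
    seg <- pct[(breaks[i] + 1):breaks[i + 1]]
    if (length(seg) == 1) as.character(seg)
    else paste0(seg[1], "-", seg[length(seg)])
  }, character(1))
  paste(runs, collapse = ", ")
}

#' Correlation between two groups' normalized betweenness distributions
#'
#' A high correlation between the per-region normalized betweenness profiles
#' of two group networks argues against genuine hub reorganization; a
#' near-zero correlation is consistent with it.
#'
#' @param b_a,b_b Equal-length per-region normalized betweenness vectors
#'   over the same region set.
#' @return A list with `r` (Pearson correlation) and `p` (two-sided
#'   p-value).
#' @export
centrality_distribution_correlation <- function(b_a, b_b) {
  b_a <- as.numeric(b_a); b_b <- as.numeric(b_b)
  if (length(b_a) != length(b_b)) stop("vectors must have equal length")
  if (anyNA(b_a) || anyNA(b_b)) stop("betweenness vectors contain NA")
  if (stats::sd(b_a) == 0 || stats::sd(b_b) == 0) {
    stop("zero-variance betweenness vector")
  }
  ct <- stats::cor.test(b_a, b_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
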