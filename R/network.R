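#' Extract the adjacency matrix of a network object
#'
#' @param net A `binary_network` (from [density_threshold()] or
#'   [generate_latent_network()]) or a plain 0/1 adjacency matrix.
#' @return The validated adjacency matrix.
#' @export
as_adjacency <- function(net) {
  adj <- if (inherits(net, "binary_network")) net$adjacency else net
  .check_adjacency(adj)
  adj
}

.new_binary_network <- function(adjacency, source_threshold = NA_real_) {
  .check_adjacency(adjacency)
  n <- nrow(adjacency)
  structure(list(
    adjacency = adjacency,
    density = sum(adjacency[upper.tri(adjacency)]) / (n * (n - 1) / 2),
    source_threshold = source_threshold
  ), class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat(sprintf("Binary network: %d nodes, %d edges (density %.4f)",
              n, sum(x$adjacency) / 2, x$density))
  if (!is.na(x$source_threshold)) {
    cat(sprintf(", |r| cutoff %.4f", x$source_threshold))
  }
  cat("\n")
  invisible(x)
}

#' Inter-regional Pearson correlation matrix
#'
#' Correlates every pair of regions across the subjects of one group,
#' yielding the group's metabolic covariance matrix. Input should normally
#' be a residual panel ([residualize()]) so that age, sex and blood-glucose
#' effects do not masquerade as inter-regional coupling.
#'
#' @param panel A `residual_panel`, a `subject_panel`, or a plain
#'   subjects-by-regions matrix.
#' @return A list of class `correlation_matrix` with elements `r` (symmetric
#'   matrix, unit diagonal) and `n_subjects`.
#' @export
pearson_matrix <- function(panel) {
  values <- panel_values(panel)
  if (nrow(values) < 3) stop("need at least 3 subjects for a correlation")
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(values)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(values)
  diag(r) <- 1
  structure(list(r = r, n_subjects = nrow(values)),
            class = "correlation_matrix")
}

.corr_r <- function(corr) {
  r <- if (inherits(corr, "correlation_matrix")) corr$r else corr
  if (!is.matrix(r) || nrow(r) != ncol(r)) stop("correlation must be square")
  r
}

#' Binarize a correlation matrix at a fixed connection density
#'
#' Keeps exactly `round(density * N(N-1)/2)` undirected edges: the region
#' pairs with the largest absolute correlation. Anticorrelations count via
#' `|r|` by default (`positive_only = TRUE` restricts to positive
#' correlations as a sensitivity mode). Ties at the cutoff are broken
#' deterministically by larger `|r|`, then smaller row index, then smaller
#' column index, so results are bit-reproducible.
#'
#' @param corr A `correlation_matrix` or square symmetric matrix.
#' @param density Target fraction of the `N(N-1)/2` possible edges, in (0,1).
#' @param positive_only If `TRUE`, rank only positive correlations.
#' @return A `binary_network`; `source_threshold` records the smallest
#'   `|r|` among kept edges and `density` the realized edge fraction.
#' @export
density_threshold <- function(corr, density, positive_only = FALSE) {
  r <- .corr_r(corr)
  n <- nrow(r)
  n_pairs <- n * (n - 1) / 2
  if (!is.numeric(density) || length(density) != 1 || density <= 0 ||
      density >= 1) {
    stop("`density` must be a single value in (0, 1)")
  }
  m <- round(density * n_pairs)
  if (m < 1) stop("requested density keeps no edges")
  if (m >= n_pairs) stop("requested density keeps all possible edges")
  ut <- which(upper.tri(r))
  score <- if (positive_only) r[ut] else abs(r[ut])
  idx <- arrayInd(ut, dim(r))
  ord <- order(-score, idx[, 1], idx[, 2])
  keep <- ut[ord[seq_len(m)]]
  adj <- matrix(0, n, n)
  adj[keep] <- 1
  adj <- adj + t(adj)
  dimnames(adj) <- dimnames(r)
  .new_binary_network(adj, source_threshold = min(score[ord[seq_len(m)]]))
}

#' Threshold a correlation matrix over a density sweep
#'
#' Because there is no consensus fixed correlation threshold, networks are
#' characterized over a range of connection densities, by default 10% to 40%
#' in 1% increments (31 networks), both endpoints included.
#'
#' @inheritParams density_threshold
#' @param d_min,d_max,step Density range and increment.
#' @return A named list of `binary_network` objects, names like `"0.10"`.
#' @export
density_sweep <- function(corr, d_min = 0.10, d_max = 0.40, step = 0.01,
                          positive_only = FALSE) {
  if (d_max < d_min || step <= 0) stop("invalid density range")
  densities <- seq(d_min, d_max, by = step)
  if (length(densities) == 0) stop("empty density range")
  nets <- lapply(densities, function(d) {
    density_threshold(corr, d, positive_only = positive_only)
  })
  names(nets) <- sprintf("%.2f", densities)
  attr(nets, "densities") <- densities
  nets
}

#' Size of the largest connected component
#'
#' @param net A binary network or 0/1 adjacency matrix.
#' @return Integer: number of nodes in the largest component.
#' @export
largest_component_size <- function(net) {
  adj <- as_adjacency(net)
  max(tabulate(.component_labels(adj)))
}

#' Lowest sweep density at which the network is fully connected
#'
#' Scans a density sweep for the smallest density whose network's largest
#' component spans all nodes — the usual lower anchor of the analysis range
#' (all regions included, fewest false-positive paths).
#'
#' @param corr A `correlation_matrix` or square symmetric matrix.
#' @param densities Densities to scan (default the standard sweep).
#' @return The smallest fully-connecting density, or `NA_real_` when no
#'   scanned density connects all nodes.
#' @export
min_full_connection_density <- function(corr,
                                        densities = seq(0.10, 0.40, 0.01)) {
  r <- .corr_r(corr)
  n <- nrow(r)
  for (d in densities) {
    net <- density_threshold(corr, d)
    if (largest_component_size(net) == n) return(d)
  }
  NA_real_
}
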