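#' Per-node and mean clustering coefficient
#'
#' The clustering coefficient of node i is `C_i = 2 e_i / (k_i (k_i - 1))`,
#' where `k_i` is the degree of i and `e_i` the number of edges among its
#' neighbours. Nodes with degree below 2 have `C_i = 0` by convention (they
#' still enter the network mean), which keeps the network clustering
#' coefficient `C = mean(C_i)` defined at sparse connection densities.
#'
#' @param net A binary network from [density_threshold()], or a plain 0/1
#'   adjacency matrix.
#' @return A list with `Ci` (per-node vector) and `C` (unweighted mean over
#'   all nodes).
#' @examples
#' nodal_clustering(generate_latent_network(12, 4, 0))$C  # ring lattice: 0.5
#' @export
nodal_clustering <- function(net) {
  adj <- as_adjacency(net)
  k <- rowSums(adj)
  # diag(A^3) counts closed 2-paths; each neighbour edge twice
  ei <- rowSums((adj %*% adj) * adj) / 2
  Ci <- ifelse(k >= 2, 2 * ei / (k * (k - 1)), 0)
  list(Ci = as.numeric(Ci), C = mean(Ci))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered pairs of distinct nodes,
#' shortest paths taken by unweighted breadth-first search.
#'
#' @param net A binary network or 0/1 adjacency matrix.
#' @param disconnected How to treat disconnected networks: `"error"`
#'   (default) fails naming the component sizes; `"connected_pairs"` averages
#'   over reachable pairs only and marks the result with attribute
#'   `connected_pairs_only = TRUE`.
#' @return The characteristic path length (numeric scalar).
#' @export
characteristic_path_length <- function(net,
                                       disconnected = c("error",
                                                        "connected_pairs")) {
  disconnected <- match.arg(disconnected)
  adj <- as_adjacency(net)
  n <- nrow(adj)
  if (n < 2) stop("need at least two nodes")
  D <- .bfs_distances(adj)
  off <- D[upper.tri(D)]
  if (any(!is.finite(off))) {
    if (disconnected == "error") {
      sizes <- sort(tabulate(.component_labels(adj)), decreasing = TRUE)
      stop("network is disconnected (component sizes: ",
           paste(sizes, collapse = ", "), ")")
    }
    L <- mean(off[is.finite(off)])
    attr(L, "connected_pairs_only") <- TRUE
    return(L)
  }
  mean(off)
}

#' Betweenness centrality
#'
#' For each node i, sums over all unordered pairs \{j, k\} (j, k distinct
#' from i) the fraction of shortest j-k paths that pass through i (endpoints
#' excluded). Computed by Brandes' accumulation; pairs in different
#' components contribute nothing.
#'
#' @param net A binary network or 0/1 adjacency matrix.
#' @return Numeric vector of per-node betweenness values.
#' @examples
#' betweenness_centrality(.adjacency_from_edges(4,
#'   cbind(c(1, 1, 1), c(2, 3, 4))))  # star: centre 3, leaves 0
#' @export
betweenness_centrality <- function(net) {
  adj <- as_adjacency(net)
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] != 0))
  B <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep.int(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    visited <- integer(0)
    frontier <- s
    while (length(frontier)) {
      visited <- c(visited, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in nbrs[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    delta <- numeric(n)
    for (w in rev(visited)) {
      coef <- (1 + delta[w]) / sigma[w]
      for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coef
    }
    delta[s] <- 0
    B <- B + delta
  }
  B / 2  # each unordered pair counted from both endpoints
}

#' Normalized betweenness
#'
#' `b_i = B(i) / mean(B)`, so the mean of `b` over nodes is 1. Hubs are
#' defined as nodes with `b_i` above a threshold (1.5 in the hub rule).
#'
#' @param B Per-node betweenness values.
#' @return Per-node normalized betweenness. If all betweenness values are
#'   zero (e.g. a complete graph), returns an all-`NA` vector with attribute
#'   `undefined = TRUE` rather than dividing by zero.
#' @export
normalized_betweenness <- function(B) {
  if (any(B < 0) || anyNA(B)) stop("betweenness values must be non-negative")
  m <- mean(B)
  if (m == 0) {
    out <- rep(NA_real_, length(B))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  B / m
}

#' Nodal centrality profile of a network
#'
#' Convenience wrapper returning per-node degree, clustering, betweenness
#' and normalized betweenness in one table.
#'
#' @param net A binary network or 0/1 adjacency matrix.
#' @param region_table Optional region table; when given (and matching the
#'   node count) abbreviations and hemispheres are attached.
#' @return A data frame with columns `index`, `degree`, `Ci`, `B`, `b` (and
#'   region labels when available).
#' @export
nodal_centrality <- function(net, region_table = NULL) {
  adj <- as_adjacency(net)
  n <- nrow(adj)
  cl <- nodal_clustering(adj)
  B <- betweenness_centrality(adj)
  b <- normalized_betweenness(B)
  out <- data.frame(index = seq_len(n), degree = rowSums(adj),
                    Ci = cl$Ci, B = B, b = as.numeric(b))
  if (!is.null(region_table) && nrow(region_table) == n) {
    out$abbreviation <- region_table$abbreviation
    out$hemisphere <- region_table$hemisphere
    out$func_class <- region_table$func_class
  }
  out
}

#' Degree-preserving random reference network
#'
#' Randomizes a network by repeated double-edge swaps: two edges (a, b) and
#' (c, d) are replaced by (a, d) and (c, b) whenever this creates neither
#' self-loops nor multi-edges. The degree of every node is preserved exactly,
#' so the reference shares the node count, mean degree and degree
#' distribution of the input while topology (clustering, path structure) is
#' randomized.
#'
#' @param net A binary network or 0/1 adjacency matrix with at least 2 edges.
#' @param n_swaps_per_edge Attempted swaps per edge (default 10).
#' @return The randomized adjacency matrix. If no swap could be performed the
#'   input is returned with attribute `no_swap = TRUE` and a warning.
#' @export
random_reference <- function(net, n_swaps_per_edge = 10) {
  adj <- as_adjacency(net)
  edges <- .edge_list(adj)
  m <- nrow(edges)
  if (m < 2) stop("need at least 2 edges to randomize")
  attempts <- ceiling(n_swaps_per_edge * m)
  swapped <- 0L
  for (t in seq_len(attempts)) {
    pick <- sample.int(m, 2L)
    e1 <- edges[pick[1L], ]; e2 <- edges[pick[2L], ]
    a <- e1[1L]; b <- e1[2L]
    # random orientation of the second edge
    if (stats::runif(1) < 0.5) { c_ <- e2[1L]; d <- e2[2L] } else { c_ <- e2[2L]; d <- e2[1L] }
    if (length(unique(c(a, b, c_, d))) < 4L) next
    if (adj[a, d] != 0 || adj[c_, b] != 0) next
    adj[a, b] <- adj[b, a] <- 0
    adj[c_, d] <- adj[d, c_] <- 0
    adj[a, d] <- adj[d, a] <- 1
    adj[c_, b] <- adj[b, c_] <- 1
    e1n <- sort(c(a, d)); e2n <- sort(c(c_, b))
    edges[pick[1L], ] <- e1n
    edges[pick[2L], ] <- e2n
    swapped <- swapped + 1L
  }
  if (swapped == 0L) {
    warning("no valid double-edge swap found; returning the input network")
    attr(adj, "no_swap") <- TRUE
  }
  adj
}

#' Small-world indices against degree-matched random references
#'
#' Computes the clustering coefficient `C` and characteristic path length
#' `L` of a network, the means `C_random` and `L_random` over `n_random`
#' degree-preserving random references ([random_reference()]), and the
#' normalized quantities `gamma = C / C_random`, `lambda = L / L_random` and
#' the small-world index `sigma = gamma / lambda`. A network is called
#' small-world when `gamma >> 1`, `lambda ~ 1`, i.e. `sigma > 1`.
#'
#' Random references can come out disconnected at sparse densities; their
#' path length is then computed over connected pairs only (rather than
#' discarding the reference, which would bias the null towards connected,
#' shorter-path graphs). The number of such references is reported.
#'
#' @param net A connected binary network or 0/1 adjacency matrix.
#' @param n_random Number of random references (default 100).
#' @param n_swaps_per_edge Swap attempts per edge in each reference.
#' @param disconnected_reference `"connected_pairs"` (default) or `"error"`.
#' @return A list of class `small_world` with elements `C`, `L`, `C_random`,
#'   `L_random`, `gamma`, `lambda`, `sigma`, `density`, `n_random`,
#'   `n_disconnected_refs`, and per-reference vectors `C_refs`, `L_refs`.
#' @export
small_world <- function(net, n_random = 100, n_swaps_per_edge = 10,
                        disconnected_reference = c("connected_pairs",
                                                   "error")) {
  disconnected_reference <- match.arg(disconnected_reference)
  adj <- as_adjacency(net)
  if (!.is_connected(adj)) {
    stop("small_world requires a connected network; see ",
         "characteristic_path_length for component diagnostics")
  }
  n <- nrow(adj)
  C <- nodal_clustering(adj)$C
  L <- characteristic_path_length(adj)
  C_refs <- numeric(n_random)
  L_refs <- numeric(n_random)
  n_disc <- 0L
  for (r in seq_len(n_random)) {
    ref <- random_reference(adj, n_swaps_per_edge = n_swaps_per_edge)
    C_refs[r] <- nodal_clustering(ref)$C
    Lr <- characteristic_path_length(ref, disconnected = "connected_pairs")
    if (isTRUE(attr(Lr, "connected_pairs_only"))) {
      if (disconnected_reference == "error") stop("disconnected random reference")
      n_disc <- n_disc + 1L
    }
    L_refs[r] <- as.numeric(Lr)
  }
  gamma <- C / mean(C_refs)
  lambda <- L / mean(L_refs)
  out <- list(C = C, L = L, C_random = mean(C_refs), L_random = mean(L_refs),
              gamma = gamma, lambda = lambda, sigma = gamma / lambda,
              density = mean(adj[upper.tri(adj)]), n_random = n_random,
              n_disconnected_refs = n_disc, C_refs = C_refs, L_refs = L_refs)
  class(out) <- "small_world"
  out
}

#' @export
print.small_world <- function(x, ...) {
  cat(sprintf("Small-world indices (density %.3f, %d random references)\n",
              x$density, x$n_random))
  cat(sprintf("  C = %.4f  (random %.4f)  gamma  = %.3f\n",
              x$C, x$C_random, x$gamma))
  cat(sprintf("  L = %.4f  (random %.4f)  lambda = %.3f\n",
              x$L, x$L_random, x$lambda))
  cat(sprintf("  sigma = gamma/lambda = %.3f\n", x$sigma))
  if (x$n_disconnected_refs > 0) {
    cat(sprintf("  (%d references disconnected; L over connected pairs)\n",
                x$n_disconnected_refs))
  }
  invisible(x)
}

#' Identify hub regions by normalized betweenness
#'
#' A node is a hub when its normalized betweenness `b_i` exceeds the
#' threshold (1.5 by the standard rule).
#'
#' @param centrality Either a data frame from [nodal_centrality()] (with a
#'   `b` column) or a numeric vector of normalized betweenness values.
#' @param region_table Region table supplying labels; must match the node
#'   count.
#' @param threshold Hub threshold on `b_i` (strictly greater than).
#' @return A data frame of hubs sorted by descending `b` (ties broken by
#'   region index): columns `index`, `abbreviation`, `hemisphere`,
#'   `func_class`, `b`. Zero rows when there is no hub.
#' @export
identify_hubs <- function(centrality, region_table = load_region_table(),
                          threshold = 1.5) {
  b <- if (is.data.frame(centrality)) centrality$b else as.numeric(centrality)
  if (is.null(b)) stop("`centrality` must supply normalized betweenness `b`")
  if (length(b) != nrow(region_table)) {
    stop("centrality length does not match the region table")
  }
  sel <- which(!is.na(b) & b > threshold)
  out <- data.frame(index = region_table$index[sel],
                    abbreviation = region_table$abbreviation[sel],
                    hemisphere = region_table$hemisphere[sel],
                    func_class = region_table$func_class[sel],
                    b = b[sel], stringsAsFactors = FALSE)
  out <- out[order(-out$b, out$index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Hub regions shared between two networks
#'
#' @param hubs_a,hubs_b Hub tables from [identify_hubs()] (or any data frame
#'   with an `index` column over the same region table).
#' @return The rows of `hubs_a` whose region also appears in `hubs_b`, in
#'   canonical region order, with `b` columns from both networks.
#' @export
shared_hubs <- function(hubs_a, hubs_b) {
  common <- sort(intersect(hubs_a$index, hubs_b$index))
  out <- hubs_a[match(common, hubs_a$index),
                setdiff(names(hubs_a), "b"), drop = FALSE]
  out$b_a <- hubs_a$b[match(common, hubs_a$index)]
  out$b_b <- hubs_b$b[match(common, hubs_b$index)]
  rownames(out) <- NULL
  out
}
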