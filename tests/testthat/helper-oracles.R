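# Independent brute-force oracles for the graph metrics. These deliberately
# use different algorithms from the package (direct neighbour-pair counting,
# Floyd-Warshall, exhaustive shortest-path enumeration) so agreement is a
# genuine cross-check.

adjacency_from_edges <- function(n, edges) {
  adj <- matrix(0, n, n)
  if (length(edges)) {
    edges <- matrix(edges, ncol = 2)
    adj[edges] <- 1
    adj[edges[, c(2, 1), drop = FALSE]] <- 1
  }
  adj
}

path_graph <- function(n) adjacency_from_edges(n, cbind(1:(n - 1), 2:n))
cycle_graph <- function(n) adjacency_from_edges(n, cbind(1:n, c(2:n, 1)))
star_graph <- function(n) adjacency_from_edges(n, cbind(1, 2:n))
complete_graph <- function(n) {
  adj <- matrix(1, n, n); diag(adj) <- 0; adj
}

# clustering by explicit neighbour-pair counting
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  Ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] != 0) links <- links + 1
      }
    }
    Ci[i] <- 2 * links / (k * (k - 1))
  }
  list(Ci = Ci, C = mean(Ci))
}

# all-pairs shortest paths by Floyd-Warshall dynamic programming
oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj != 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- D[i, k] + D[k, ]
      upd <- nd < D[i, ]
      D[i, upd] <- nd[upd]
    }
  }
  D
}

oracle_path_length <- function(adj) {
  D <- oracle_distances(adj)
  mean(D[upper.tri(D)])
}

# betweenness by exhaustive enumeration of shortest paths: walk every
# geodesic j -> k (following only distance-decreasing steps) and tally the
# interior nodes of each
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  B <- numeric(n)
  enum_paths <- function(v, k) {
    if (v == k) return(list(integer(0)))
    nxt <- which(adj[v, ] != 0 & D[, k] == D[v, k] - 1)
    out <- list()
    for (w in nxt) {
      for (tail in enum_paths(w, k)) {
        out[[length(out) + 1]] <- c(w, tail)
      }
    }
    out
  }
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      if (!is.finite(D[j, k])) next
      paths <- enum_paths(j, k)
      njk <- length(paths)
      for (p in paths) {
        interior <- setdiff(p, k)
        B[interior] <- B[interior] + 1 / njk
      }
    }
  }
  B
}

oracle_largest_component <- function(adj) {
  D <- oracle_distances(adj)
  max(rowSums(is.finite(D)))
}

# seeded Erdos-Renyi graph, resampled until connected
random_connected_graph <- function(n, p) {
  repeat {
    adj <- matrix(0, n, n)
    ut <- which(upper.tri(adj))
    on <- ut[runif(length(ut)) < p]
    adj[on] <- 1
    adj <- adj + t(adj)
    if (oracle_largest_component(adj) == n) return(adj)
  }
}

# all connected labelled graphs on n nodes (edge-subset enumeration);
# feasible for n <= 5
enumerate_connected_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- list()
  for (code in seq_len(2^m - 1)) {
    sel <- which(bitwAnd(code, 2^(seq_len(m) - 1)) != 0)
    adj <- adjacency_from_edges(n, pairs[sel, , drop = FALSE])
    if (oracle_largest_component(adj) == n) out[[length(out) + 1]] <- adj
  }
  out
}

# brute-force density thresholding: sort all |r| pairs and keep the top m
oracle_density_threshold <- function(r, density) {
  n <- nrow(r)
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  score <- abs(r[pairs])
  ord <- order(-score, pairs[, 1], pairs[, 2])
  m <- round(density * nrow(pairs))
  adjacency_from_edges(n, pairs[ord[seq_len(m)], , drop = FALSE])
}

# direct textbook Pearson formula
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
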