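# Internal graph primitives on dense 0/1 adjacency matrices.
# All networks in the pipeline are small (~90 nodes), undirected and
# unweighted, so dense logical/numeric matrices plus level-synchronous BFS
# are fast enough everywhere, including inside permutation loops.

.check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    stop("adjacency must be a square matrix")
  }
  if (any(adj != 0 & adj != 1)) stop("adjacency must be binary (0/1)")
  if (any(diag(adj) != 0)) stop("adjacency must have a zero diagonal")
  if (!isTRUE(all.equal(adj, t(adj)))) stop("adjacency must be symmetric")
  invisible(adj)
}

# All-pairs shortest-path lengths by level-synchronous breadth-first search
# expressed as boolean matrix products; Inf marks unreachable pairs.
.bfs_distances <- function(adj) {
  n <- nrow(adj)
  a <- adj != 0
  storage.mode(adj) <- "double"
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reached <- diag(n) > 0
  frontier <- reached
  d <- 0L
  while (any(frontier)) {
    d <- d + 1L
    nxt <- ((frontier %*% adj) > 0) & !reached
    if (!any(nxt)) break
    D[nxt] <- d
    reached <- reached | nxt
    frontier <- nxt
  }
  D
}

# Connected-component labels (integer vector) via BFS reachability.
.component_labels <- function(adj) {
  n <- nrow(adj)
  labels <- integer(n)
  cur <- 0L
  nbrs <- adj != 0
  for (s in seq_len(n)) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    labels[s] <- cur
    while (length(frontier)) {
      nxt <- which(colSums(nbrs[frontier, , drop = FALSE]) > 0 & labels == 0L)
      labels[nxt] <- cur
      frontier <- nxt
    }
  }
  labels
}

.is_connected <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(TRUE)
  reached <- logical(n)
  reached[1L] <- TRUE
  frontier <- 1L
  nbrs <- adj != 0
  while (length(frontier)) {
    nxt <- which(colSums(nbrs[frontier, , drop = FALSE]) > 0 & !reached)
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  all(reached)
}

# Edge list (i < j) of an adjacency matrix, ordered by (i, j).
.edge_list <- function(adj) {
  which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
}

.adjacency_from_edges <- function(n, edges) {
  adj <- matrix(0, n, n)
  if (nrow(edges)) {
    adj[edges] <- 1
    adj[edges[, c(2, 1), drop = FALSE]] <- 1
  }
  adj
}

# Deterministic ring lattice: each node linked to its k/2 nearest neighbours
# on each side of a ring.
.ring_lattice <- function(n, k) {
  if (k %% 2 != 0 || k < 2) stop("ring lattice degree must be even and >= 2")
  if (k >= n) stop("ring lattice degree must be below the node count")
  adj <- matrix(0, n, n)
  for (step in seq_len(k / 2)) {
    i <- seq_len(n)
    j <- ((i - 1 + step) %% n) + 1
    adj[cbind(i, j)] <- 1
    adj[cbind(j, i)] <- 1
  }
  adj
}
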