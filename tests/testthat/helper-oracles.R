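# Independent brute-force oracles and small fixtures used across tests.
# Everything here is deliberately naive: the point is independence from the
# implementation paths being checked.

## adjacency matrix of an Erdos-Renyi draw (upper-triangle Bernoulli)
random_adjacency <- function(n, p, seed) {
  withr::with_seed(seed, {
    A <- matrix(FALSE, n, n)
    A[upper.tri(A)] <- stats::runif(n * (n - 1) / 2) < p
    A | t(A)
  })
}

## all-pairs shortest-path distances by Floyd-Warshall (no igraph)
fw_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A != 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

## enumerate every shortest path between s and t by backtracking through the
## distance matrix; returns a list of vertex sequences
enumerate_shortest_paths <- function(A, D, s, t) {
  if (!is.finite(D[s, t])) return(list())
  if (s == t) return(list(s))
  paths <- list()
  for (u in which(A[, t] != 0)) {
    if (D[s, u] == D[s, t] - 1) {
      for (p in enumerate_shortest_paths(A, D, s, u))
        paths[[length(paths) + 1L]] <- c(p, t)
    }
  }
  paths
}

## betweenness by exhaustive path enumeration with fractional counting,
## normalized to [0, 1]
brute_betweenness <- function(A) {
  n <- nrow(A)
  D <- fw_distances(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      paths <- enumerate_shortest_paths(A, D, s, t)
      if (!length(paths)) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        b[interior] <- b[interior] + 1 / length(paths)
      }
    }
  }
  b * 2 / ((n - 1) * (n - 2))
}

## per-node clustering coefficient by looping over all vertex triples
brute_clustering <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] != 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0L
    for (a in seq_len(k - 1))
      for (b in seq.int(a + 1, k))
        if (A[nb[a], nb[b]] != 0) tri <- tri + 1L
    cc[v] <- 2 * tri / (k * (k - 1))
  }
  cc
}

## ring lattice where each node connects to k/2 neighbours on each side
ring_lattice <- function(n, k) {
  A <- matrix(FALSE, n, n)
  for (v in seq_len(n))
    for (s in seq_len(k / 2)) {
      u <- ((v - 1 + s) %% n) + 1
      A[v, u] <- A[u, v] <- TRUE
    }
  A
}

## Watts-Strogatz graph: ring lattice with probabilistic rewiring
ws_graph <- function(n, k, p, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_smallworld(1, n, k / 2, p)
    as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) != 0
  })
}

## a grid whose mask is the full box (single "hemisphere" split at midline)
full_box_grid <- function(shape, voxel_size_mm = 2) {
  shape <- as.integer(shape)
  hemi <- array(0L, dim = shape)
  xs <- array(rep(0:(shape[1] - 1), times = prod(shape[2:3])), dim = shape)
  cx <- (shape[1] - 1) / 2
  hemi[xs < cx] <- 1L
  hemi[xs > cx] <- 2L
  mask <- hemi > 0L
  gm_idx <- which(mask)
  structure(
    list(shape = shape, voxel_size_mm = voxel_size_mm, mask = mask,
         hemisphere = hemi, gm_idx = gm_idx,
         coords = hubtopo:::index_vox(gm_idx, shape), seed = 0L),
    class = "brain_grid"
  )
}

## wrap an endpoint matrix as a streamline set
as_streamlines <- function(ep, subject_id = "test") {
  colnames(ep) <- c("xa", "ya", "za", "xb", "yb", "zb")
  structure(list(endpoints = ep, subject_id = subject_id),
            class = "streamline_set")
}

## tiny shared fixtures
small_grid <- function() make_brain_grid(c(12, 14, 12), voxel_size_mm = 2)
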