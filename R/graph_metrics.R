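## Graph-theoretic node metrics, null models and small-world indices.
## All graphs are binary and undirected (the pipeline binarizes before any
## metric is computed). igraph supplies the graph algorithms; this file fixes
## the conventions (normalization, largest-component handling, null-model
## construction) used throughout the analysis.

as_graph <- function(adjacency) {
  igraph::graph_from_adjacency_matrix(adjacency * 1, mode = "undirected",
                                      diag = FALSE)
}

check_adjacency <- function(adjacency) {
  stopifnot(is.matrix(adjacency))
  assert_that(isTRUE(all(adjacency == t(adjacency))),
              "adjacency must be symmetric")
  assert_that(all(diag(adjacency) == 0), "adjacency must have a zero diagonal")
  invisible(adjacency)
}

#' Node degree
#'
#' Number of connections of each node: the row sums of the binary adjacency
#' matrix.
#'
#' @param adjacency symmetric logical/0-1 matrix, zero diagonal.
#' @return integer vector of degrees.
#' @export
node_degree <- function(adjacency) {
  check_adjacency(adjacency)
  as.integer(rowSums(adjacency != 0))
}

#' Normalized betweenness centrality
#'
#' Fraction of all-pairs shortest paths that pass through each node as an
#' interior vertex (endpoints excluded), with equal-length shortest paths
#' contributing fractionally. Computed with Brandes' algorithm and normalized
#' by `2 / ((N - 1)(N - 2))` so values lie in `[0, 1]`; isolated nodes score
#' 0. For `N < 3` the normalization is undefined and a zero vector is
#' returned with a warning.
#'
#' @param adjacency symmetric logical/0-1 matrix, zero diagonal.
#' @return numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(adjacency) {
  check_adjacency(adjacency)
  N <- nrow(adjacency)
  if (N < 3L) {
    warning("betweenness normalization undefined for N < 3; returning zeros")
    return(numeric(N))
  }
  b <- igraph::betweenness(as_graph(adjacency), directed = FALSE)
  as.numeric(b) * 2 / ((N - 1) * (N - 2))
}

#' Watts-Strogatz clustering coefficient
#'
#' Per-node fraction of neighbour pairs that are themselves connected
#' (`2 T_i / (k_i (k_i - 1))`); nodes with degree below 2 contribute 0.
#'
#' @param adjacency symmetric logical/0-1 matrix, zero diagonal.
#' @return list with `per_node` and the `mean` over all nodes.
#' @export
clustering_mean <- function(adjacency) {
  check_adjacency(adjacency)
  cc <- igraph::transitivity(as_graph(adjacency), type = "local",
                             isolates = "zero")
  cc[is.nan(cc)] <- 0
  list(per_node = as.numeric(cc), mean = mean(cc))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all reachable node pairs within the largest
#' connected component, together with the fraction of nodes that component
#' contains. Path metrics are restricted to the largest component so that
#' disconnected fragments never contribute infinite distances silently.
#'
#' @param adjacency symmetric logical/0-1 matrix.
#' @return list with `gamma_path` and `component_fraction`.
#' @export
char_path_length <- function(adjacency) {
  check_adjacency(adjacency)
  N <- nrow(adjacency)
  if (N < 2L || sum(adjacency) == 0) stop("no paths: graph has no edges")
  g <- as_graph(adjacency)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  list(gamma_path = igraph::mean_distance(sub, directed = FALSE),
       component_fraction = max(comp$csize) / N)
}

#' Degree-preserving random reference network
#'
#' Maslov-Sneppen double-edge swaps: repeatedly pick two edges and exchange
#' their endpoints, rejecting swaps that would create a self-loop or a
#' multi-edge. Every node's degree is preserved exactly. `swaps_per_edge *
#' n_edges` swap attempts are made (default 10 per edge). Graphs admitting no
#' valid swap (e.g. a star or a triangle) come back unchanged, with a
#' warning.
#'
#' @param adjacency symmetric logical/0-1 matrix, zero diagonal.
#' @param seed integer seed; deterministic given the seed.
#' @param swaps_per_edge attempted swaps per edge.
#' @return logical adjacency matrix with the same degree sequence.
#' @export
random_reference <- function(adjacency, seed = 1L, swaps_per_edge = 10L) {
  check_adjacency(adjacency)
  m <- sum(adjacency != 0) / 2
  if (m < 2) stop("random reference requires at least 2 edges")
  g <- as_graph(adjacency)
  g2 <- with_seed(seed, igraph::rewire(
    g, igraph::keeping_degseq(loops = FALSE, niter = ceiling(swaps_per_edge * m))
  ))
  A2 <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE)) != 0
  dimnames(A2) <- dimnames(adjacency)
  if (identical(A2, adjacency != 0))
    warning("rewiring returned the graph unchanged (no valid swap found)")
  A2
}

#' Small-world index
#'
#' `sigma = (C / C_rand) / (gamma / gamma_rand)`: the clustering coefficient
#' and characteristic path length of the observed graph relative to an
#' equivalent random network. Observed values are computed on the largest
#' connected component; the null terms are averaged over `n_null` random
#' references (each itself restricted to its largest component).
#' `sigma > 1` indicates small-world topology.
#'
#' @param adjacency symmetric logical/0-1 matrix, zero diagonal; at least 3
#'   nodes and 2 edges.
#' @param n_null number of null networks.
#' @param seed integer seed for the null ensemble.
#' @param swaps_per_edge passed to [random_reference()].
#' @param null_model `"rewire"` (degree-preserving, default),
#'   `"erdos_renyi"` (same node and edge count) or `"identity"` (the graph
#'   itself; yields sigma = 1 exactly, used for self-consistency checks).
#' @return object of class `small_world_result` with fields `C`, `C_rand`,
#'   `gamma_path`, `gamma_rand`, `sigma`, `n_null`, `component_fraction`.
#' @export
small_world_sigma <- function(adjacency, n_null = 10L, seed = 1L,
                              swaps_per_edge = 10L,
                              null_model = c("rewire", "erdos_renyi",
                                             "identity")) {
  check_adjacency(adjacency)
  null_model <- match.arg(null_model)
  N <- nrow(adjacency)
  if (N < 3L || sum(adjacency) / 2 < 2) stop("graph too small for sigma")
  assert_that(n_null >= 1L, "n_null must be at least 1")

  g <- as_graph(adjacency)
  comp <- igraph::components(g)
  big_nodes <- which(comp$membership == which.max(comp$csize))
  A0 <- adjacency[big_nodes, big_nodes, drop = FALSE] != 0
  comp_frac <- length(big_nodes) / N

  C <- clustering_mean(A0)$mean
  gamma <- char_path_length(A0)$gamma_path

  n0 <- nrow(A0)
  m0 <- sum(A0) / 2
  null_terms <- vapply(seq_len(n_null), function(i) {
    Ai <- switch(null_model,
      rewire = suppressWarnings(random_reference(A0, seed = seed + i,
                                                 swaps_per_edge = swaps_per_edge)),
      erdos_renyi = with_seed(seed + i, {
        gi <- igraph::sample_gnm(n0, m0)
        as.matrix(igraph::as_adjacency_matrix(gi, sparse = FALSE)) != 0
      }),
      identity = A0
    )
    gi <- as_graph(Ai)
    compi <- igraph::components(gi)
    bigi <- which(compi$membership == which.max(compi$csize))
    Ab <- Ai[bigi, bigi, drop = FALSE]
    c(clustering_mean(Ab)$mean, char_path_length(Ab)$gamma_path)
  }, numeric(2))

  C_rand <- mean(null_terms[1, ])
  gamma_rand <- mean(null_terms[2, ])
  if (!is.finite(C_rand) || C_rand <= 0 || !is.finite(gamma_rand) ||
      gamma_rand <= 0)
    stop("degenerate null: zero clustering or path length in the reference ensemble")

  structure(
    list(C = C, C_rand = C_rand, gamma_path = gamma, gamma_rand = gamma_rand,
         sigma = (C / C_rand) / (gamma / gamma_rand),
         n_null = as.integer(n_null), component_fraction = comp_frac,
         null_model = null_model),
    class = "small_world_result"
  )
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf(
    "<small_world_result> sigma = %.3f (C %.3f / C_rand %.3f; gamma %.3f / gamma_rand %.3f; %d nulls, %s)\n",
    x$sigma, x$C, x$C_rand, x$gamma_path, x$gamma_rand, x$n_null,
    x$null_model))
  invisible(x)
}

#' Induced hemispheric subgraph
#'
#' Adjacency restricted to the nodes of one hemisphere; inter-hemispheric
#' edges are dropped (induced-subgraph convention).
#'
#' @param connectome a [make_connectome()] object (or a list with
#'   `adjacency` and `node_hemisphere`).
#' @param hemisphere `"left"` or `"right"`.
#' @return logical adjacency matrix over that hemisphere's nodes.
#' @export
hemisphere_subgraph <- function(connectome, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  assert_that(!is.null(connectome$node_hemisphere),
              "connectome lacks node_hemisphere labels")
  idx <- which(connectome$node_hemisphere == hemisphere)
  if (length(idx) < 3L)
    stop(sprintf("%s hemisphere has fewer than 3 nodes", hemisphere))
  connectome$adjacency[idx, idx, drop = FALSE] != 0
}

#' Per-subject small-world profile across a parcellation ensemble
#'
#' Computes whole-brain, left- and right-hemisphere sigma for each of a
#' subject's parcellation-level connectomes and averages each index across
#' the members; the small-world asymmetry index is `delta = sigma_lh -
#' sigma_rh` of the averages.
#'
#' @param connectomes list of [make_connectome()] objects (one per
#'   parcellation member).
#' @param n_null,swaps_per_edge,null_model passed to [small_world_sigma()].
#' @param seed integer; member `p` uses seeds derived from `seed + 1000 p`.
#' @return object of class `hemisphere_sigma` with `sigma_whole`, `sigma_lh`,
#'   `sigma_rh`, `delta` and the per-member values.
#' @export
subject_sigma_profile <- function(connectomes, n_null = 10L, seed = 1L,
                                  swaps_per_edge = 10L,
                                  null_model = "rewire") {
  assert_that(length(connectomes) >= 1L, "need at least one connectome")
  per <- matrix(NA_real_, length(connectomes), 3,
                dimnames = list(NULL, c("whole", "lh", "rh")))
  for (p in seq_along(connectomes)) {
    cn <- connectomes[[p]]
    sp <- as.integer(seed) + 1000L * p
    res <- tryCatch({
      c(
        small_world_sigma(cn$adjacency != 0, n_null, seed = sp,
                          swaps_per_edge = swaps_per_edge,
                          null_model = null_model)$sigma,
        small_world_sigma(hemisphere_subgraph(cn, "left"), n_null,
                          seed = sp + 1L, swaps_per_edge = swaps_per_edge,
                          null_model = null_model)$sigma,
        small_world_sigma(hemisphere_subgraph(cn, "right"), n_null,
                          seed = sp + 2L, swaps_per_edge = swaps_per_edge,
                          null_model = null_model)$sigma
      )
    }, error = function(e) stop(sprintf("ensemble member %d: %s", p,
                                        conditionMessage(e)), call. = FALSE))
    per[p, ] <- res
  }
  means <- colMeans(per)
  structure(
    list(sigma_whole = means[["whole"]], sigma_lh = means[["lh"]],
         sigma_rh = means[["rh"]], delta = means[["lh"]] - means[["rh"]],
         per_member = per),
    class = "hemisphere_sigma"
  )
}

#' Node metrics table for one connectome
#'
#' @param connectome a [make_connectome()] object.
#' @return data frame with `node`, `hemisphere`, `degree`, `betweenness`.
#' @export
compute_node_metrics <- function(connectome) {
  A <- connectome$adjacency != 0
  data.frame(
    node = seq_len(nrow(A)),
    hemisphere = connectome$node_hemisphere,
    degree = node_degree(A),
    betweenness = betweenness_centrality(A),
    stringsAsFactors = FALSE
  )
}
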