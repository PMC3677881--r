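#' Count streamlines between ROIs
#'
#' Maps both endpoints of every streamline to ROI ids via exact voxel lookup
#' and accumulates a symmetric fibre-count matrix. Pairs with both endpoints
#' in the same ROI (self-loops) and pairs with an endpoint outside the
#' grey-matter mask are discarded and tallied in the drop log; endpoints
#' outside the grid bounds are an error (reported with the first offending
#' row).
#'
#' @param streamlines a [simulate_streamlines()] object (or anything with an
#'   `endpoints` matrix `xa,ya,za,xb,yb,zb`, 0-based voxel indices).
#' @param parcellation a [parcellate_grid()] object.
#' @param grid the shared [make_brain_grid()].
#' @return integer ROI x ROI weight matrix with zero diagonal and a
#'   `drop_log` attribute (`n_input`, `n_outside_mask`, `n_self`, `n_kept`).
#' @export
count_fibres <- function(streamlines, parcellation, grid) {
  stopifnot(inherits(parcellation, "parcellation"),
            inherits(grid, "brain_grid"))
  ep <- streamlines$endpoints
  stopifnot(is.matrix(ep), ncol(ep) == 6L)
  N <- 2L * parcellation$K_per_hemisphere

  a <- ep[, 1:3, drop = FALSE]
  b <- ep[, 4:6, drop = FALSE]
  bad <- which(!(in_bounds(a, grid$shape) & in_bounds(b, grid$shape)))
  if (length(bad))
    stop(sprintf("streamline endpoint outside grid bounds at row %d", bad[1]))

  lab_of <- integer(prod(grid$shape))
  lab_of[grid$gm_idx] <- parcellation$labels
  la <- lab_of[vox_index(a, grid$shape)]
  lb <- lab_of[vox_index(b, grid$shape)]

  outside <- la == 0L | lb == 0L
  self <- !outside & la == lb
  keep <- !outside & !self

  W <- matrix(0L, N, N)
  if (any(keep)) {
    lo <- pmin(la[keep], lb[keep])
    hi <- pmax(la[keep], lb[keep])
    key <- (lo - 1L) * N + hi
    counts <- tabulate(key, nbins = N * N)
    nz <- which(counts > 0L)
    lo_nz <- (nz - 1L) %/% N + 1L
    hi_nz <- (nz - 1L) %% N + 1L
    W[cbind(lo_nz, hi_nz)] <- counts[nz]
    W[cbind(hi_nz, lo_nz)] <- counts[nz]
  }

  attr(W, "drop_log") <- list(n_input = nrow(ep),
                              n_outside_mask = sum(outside),
                              n_self = sum(self),
                              n_kept = sum(keep))
  W
}

#' Binarize a fibre-count matrix
#'
#' An edge exists wherever at least `threshold` streamlines connect two ROIs
#' (default 1: no strength thresholding). The diagonal is forced off.
#' Idempotent: binarizing an adjacency matrix returns it unchanged.
#'
#' @param weights non-negative symmetric count matrix.
#' @param threshold minimum count for an edge.
#' @return logical adjacency matrix.
#' @export
binarize <- function(weights, threshold = 1L) {
  stopifnot(is.matrix(weights))
  assert_that(all(weights >= 0), "weights must be non-negative")
  A <- weights >= threshold
  diag(A) <- FALSE
  A | t(A)
}

#' Connection density of a binary network
#'
#' Fraction of realized connections: edge count over `N (N - 1) / 2`.
#'
#' @param adjacency symmetric logical matrix with zero diagonal.
#' @return density in `[0, 1]`.
#' @export
connectome_density <- function(adjacency) {
  stopifnot(is.matrix(adjacency))
  N <- nrow(adjacency)
  if (N < 2L) stop("density undefined for fewer than 2 nodes")
  assert_that(all(diag(adjacency) == 0), "adjacency must have a zero diagonal")
  assert_that(isTRUE(all(adjacency == t(adjacency))),
              "adjacency must be symmetric")
  sum(adjacency) / (N * (N - 1))
}

#' Build a subject x parcellation connectome
#'
#' Convenience constructor tying together [count_fibres()] and [binarize()]
#' with the node-to-hemisphere map of the parcellation.
#'
#' @inheritParams count_fibres
#' @param subject_id identifier stored with the connectome.
#' @param threshold binarization threshold (default 1, i.e. untresholded).
#' @return object of class `connectome`: `weights`, `adjacency`,
#'   `node_hemisphere`, `parcellation_seed`, `subject_id`, `drop_log`.
#' @export
make_connectome <- function(streamlines, parcellation, grid,
                            subject_id = NULL, threshold = 1L) {
  W <- count_fibres(streamlines, parcellation, grid)
  drop_log <- attr(W, "drop_log")
  attr(W, "drop_log") <- NULL
  structure(
    list(
      weights = W,
      adjacency = binarize(W, threshold = threshold),
      node_hemisphere = parcellation$roi_hemisphere,
      parcellation_seed = parcellation$seed,
      subject_id = subject_id %||% streamlines$subject_id,
      threshold = as.integer(threshold),
      drop_log = drop_log
    ),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %s: %d nodes, %d edges (density %.3f)\n",
              x$subject_id %||% "?", nrow(x$adjacency),
              sum(x$adjacency) / 2L, connectome_density(x$adjacency)))
  invisible(x)
}
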