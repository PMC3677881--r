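#' Lloyd's k-means on a coordinate matrix
#'
#' Low-level clustering engine used for random parcellation: k-means++-style
#' seeding from the point set, Lloyd iterations until assignments stop
#' changing (or `max_iter`), and empty-cluster repair by re-seeding an empty
#' cluster at the point farthest from its current centroid. The repair
#' guarantees exactly `K` non-empty clusters, which the parcellation
#' partition invariant requires.
#'
#' @param X numeric matrix of points (rows) to cluster.
#' @param K number of clusters (`K <= nrow(X)`).
#' @param seed integer seed; the result is deterministic given `(X, K, seed)`.
#' @param init optional `K x ncol(X)` matrix of initial centres (overrides the
#'   seeded initialization; used by tests that step Lloyd by hand).
#' @param max_iter iteration cap.
#' @return list with integer `labels` (length `nrow(X)`, values `1..K`),
#'   `centers`, `iterations` and `converged`.
#' @export
lloyd_kmeans <- function(X, K, seed = 1L, init = NULL, max_iter = 300L) {
  X <- as.matrix(X)
  n <- nrow(X)
  K <- as.integer(K)
  if (K > n) stop(sprintf("K = %d exceeds the number of points (%d)", K, n))
  assert_that(K >= 1L, "K must be at least 1")

  run <- function() {
    centers <- if (is.null(init)) kmeanspp_init(X, K) else {
      stopifnot(nrow(init) == K)
      as.matrix(init)
    }
    labels_prev <- integer(n)
    labels <- integer(n)
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      D <- dist2_to_centers(X, centers)
      labels <- max.col(-D, ties.method = "first")
      ## empty-cluster repair: re-seed at the point farthest from its centroid
      guard <- 0L
      repeat {
        empty <- which(tabulate(labels, nbins = K) == 0L)
        if (!length(empty)) break
        guard <- guard + 1L
        if (guard > 10L * K)
          stop("failed to resolve empty clusters after repeated re-seeding")
        for (k in empty) {
          d_own <- D[cbind(seq_len(n), labels)]
          far <- which.max(d_own)
          labels[far] <- k
          centers[k, ] <- X[far, ]
          D[, k] <- rowSums(sweep(X, 2L, centers[k, ], "-")^2)
        }
      }
      if (identical(labels, labels_prev)) {
        converged <- TRUE
        break
      }
      labels_prev <- labels
      centers <- centroids_of(X, labels, K)
    }
    list(labels = labels, centers = centers, iterations = it,
         converged = converged)
  }
  with_seed(seed, run())
}

kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  first <- sample.int(n, 1L)
  centers[1L, ] <- X[first, ]
  if (K == 1L) return(centers)
  d2 <- rowSums(sweep(X, 2L, centers[1L, ], "-")^2)
  for (k in 2:K) {
    pick <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else sample.int(n, 1L)
    centers[k, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[k, ], "-")^2))
  }
  centers
}

centroids_of <- function(X, labels, K) {
  counts <- tabulate(labels, nbins = K)
  S <- rowsum(X, group = factor(labels, levels = seq_len(K)))
  sweep(S, 1L, pmax(counts, 1L), "/")
}

#' Random k-means parcellation of one hemisphere
#'
#' Clusters the grey-matter voxel centres (mm coordinates) of one hemisphere
#' into `K` regions of interest with [lloyd_kmeans()]. Randomly initialized,
#' so different seeds give different parcellation schemes over the same mask.
#'
#' @param grid a [make_brain_grid()] object.
#' @param hemisphere `"left"` or `"right"`.
#' @param K number of ROIs for this hemisphere.
#' @param seed integer seed.
#' @return integer vector of ROI labels `1..K`, one per grey-matter voxel of
#'   the requested hemisphere (in grid row order), with the fitted centres as
#'   an attribute.
#' @export
kmeans_parcellate <- function(grid, hemisphere = c("left", "right"), K,
                              seed = 1L) {
  stopifnot(inherits(grid, "brain_grid"))
  hemisphere <- match.arg(hemisphere)
  code <- if (hemisphere == "left") 1L else 2L
  rows <- which(grid_hemi_vec(grid) == code)
  if (K > length(rows))
    stop(sprintf("K = %d exceeds the %s-hemisphere voxel count (%d)",
                 K, hemisphere, length(rows)))
  X <- grid_coords_mm(grid)[rows, , drop = FALSE]
  fit <- lloyd_kmeans(X, K, seed = seed)
  structure(fit$labels, centers = fit$centers, rows = rows,
            iterations = fit$iterations)
}

#' Parcellate both hemispheres into a full parcellation
#'
#' Runs [kmeans_parcellate()] on each hemisphere and combines the results
#' with globally unique ROI ids: left ROIs are `1..K`, right ROIs are
#' `K+1..2K`. No ROI ever spans hemispheres, by construction.
#'
#' @param grid a [make_brain_grid()] object.
#' @param K ROIs per hemisphere.
#' @param seed member seed (the right hemisphere uses a fixed offset of this
#'   seed so the two runs are independent).
#' @return object of class `parcellation`: `labels` (per grey-matter voxel,
#'   grid row order), `K_per_hemisphere`, `seed`, `roi_hemisphere`,
#'   `roi_centroid` (mm), `roi_volume_voxels`.
#' @export
parcellate_grid <- function(grid, K, seed = 1L) {
  K <- as.integer(K)
  hemi <- grid_hemi_vec(grid)
  labels <- integer(length(hemi))

  left <- kmeans_parcellate(grid, "left", K, seed = seed)
  labels[attr(left, "rows")] <- as.integer(left)
  right <- kmeans_parcellate(grid, "right", K, seed = seed + 500000L)
  labels[attr(right, "rows")] <- as.integer(right) + K

  vol <- tabulate(labels, nbins = 2L * K)
  cents <- centroids_of(grid_coords_mm(grid), labels, 2L * K)

  structure(
    list(
      labels = labels,
      K_per_hemisphere = K,
      seed = as.integer(seed),
      roi_hemisphere = rep(c("left", "right"), each = K),
      roi_centroid = cents,
      roi_volume_voxels = vol,
      settings = list(algorithm = "lloyd", init = "kmeans++",
                      max_iter = 300L,
                      empty_cluster = "reseed-at-farthest-point")
    ),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d ROIs (%d per hemisphere), seed %d\n",
              2L * x$K_per_hemisphere, x$K_per_hemisphere, x$seed))
  invisible(x)
}

#' Ensemble of random parcellations
#'
#' Produces `P` independent parcellations of the same grid with member seeds
#' `master_seed + 1 .. master_seed + P`. The ensemble defines the network
#' nodes for the template-free analysis: averaging node metrics across the
#' members removes the dependence on any single node placement.
#'
#' @param grid a [make_brain_grid()] object.
#' @param K ROIs per hemisphere per member.
#' @param P number of ensemble members.
#' @param master_seed integer.
#' @return object of class `parcellation_ensemble` (list of members plus
#'   `K`, `P`, `seeds`).
#' @export
ensemble_parcellate <- function(grid, K, P, master_seed = 1L) {
  assert_that(P >= 1L, "P must be at least 1")
  seeds <- as.integer(master_seed) + seq_len(P)
  members <- vector("list", P)
  for (p in seq_len(P)) {
    members[[p]] <- tryCatch(
      parcellate_grid(grid, K, seed = seeds[p]),
      error = function(e) stop(sprintf("ensemble member %d: %s", p,
                                       conditionMessage(e)), call. = FALSE)
    )
  }
  structure(list(parcellations = members, K = as.integer(K), P = as.integer(P),
                 seeds = seeds),
            class = "parcellation_ensemble")
}

#' @export
print.parcellation_ensemble <- function(x, ...) {
  cat(sprintf("<parcellation_ensemble> P = %d members, K = %d per hemisphere\n",
              x$P, x$K))
  invisible(x)
}

#' ROI size statistics
#'
#' Per-ROI volume as a fraction of the total grey-matter volume. The mean
#' fraction is `1 / (number of ROIs)` exactly, for any grid and seed; the
#' standard deviation measures how uneven the random parcellation is.
#'
#' @param parcellation a [parcellate_grid()] object.
#' @return list with `mean_fraction`, `sd_fraction` and the per-ROI
#'   `fractions`.
#' @export
roi_size_stats <- function(parcellation) {
  stopifnot(inherits(parcellation, "parcellation"))
  fr <- parcellation$roi_volume_voxels / sum(parcellation$roi_volume_voxels)
  list(mean_fraction = mean(fr), sd_fraction = stats::sd(fr), fractions = fr)
}

#' Contiguity report for a parcellation
#'
#' k-means on voxel coordinates does not guarantee spatially contiguous ROIs;
#' this reports, per ROI, whether its voxels form a single 26-connected
#' component, rather than silently relabelling.
#'
#' @param parcellation a [parcellate_grid()] object.
#' @param grid the grid it was computed on.
#' @return list with a per-ROI data frame (`roi`, `hemisphere`, `n_voxels`,
#'   `contiguous`) and the overall `fraction_contiguous`.
#' @export
contiguity_report <- function(parcellation, grid) {
  stopifnot(inherits(parcellation, "parcellation"),
            inherits(grid, "brain_grid"))
  n_roi <- 2L * parcellation$K_per_hemisphere
  contig <- logical(n_roi)
  nvox <- integer(n_roi)
  for (r in seq_len(n_roi)) {
    rows <- which(parcellation$labels == r)
    nvox[r] <- length(rows)
    cc <- components26(grid$coords[rows, , drop = FALSE], grid$shape)
    contig[r] <- length(rows) > 0L && max(cc) == 1L
  }
  per_roi <- data.frame(roi = seq_len(n_roi),
                        hemisphere = parcellation$roi_hemisphere,
                        n_voxels = nvox, contiguous = contig,
                        stringsAsFactors = FALSE)
  list(per_roi = per_roi, fraction_contiguous = mean(contig))
}
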