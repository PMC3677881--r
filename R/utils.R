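# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# All stochastic operations funnel through here so the caller's RNG state is
# never disturbed and identical seeds give identical results.
with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

#' @noRd
assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

## 1-based linear index of 0-based voxel coordinates (n x 3 matrix).
vox_index <- function(coords, shape) {
  coords <- matrix(as.integer(coords), ncol = 3)
  1L + coords[, 1] + shape[1] * (coords[, 2] + shape[2] * coords[, 3])
}

## inverse of vox_index
index_vox <- function(idx, shape) {
  idx0 <- as.integer(idx) - 1L
  cbind(
    x = idx0 %% shape[1],
    y = (idx0 %/% shape[1]) %% shape[2],
    z = idx0 %/% (shape[1] * shape[2])
  )
}

in_bounds <- function(coords, shape) {
  coords[, 1] >= 0L & coords[, 1] < shape[1] &
    coords[, 2] >= 0L & coords[, 2] < shape[2] &
    coords[, 3] >= 0L & coords[, 3] < shape[3]
}

## Weighted sampling with replacement over a (possibly huge) support.
## R's sample(prob=) walks the weight vector per draw; cumulative-sum +
## findInterval is O(support + draws * log(support)).
sample_weighted <- function(n, w) {
  sample_from_cw(n, cumsum(as.numeric(w)))
}

## same, but from a precomputed cumulative weight vector
sample_from_cw <- function(n, cw) {
  tot <- cw[length(cw)]
  assert_that(is.finite(tot) && tot > 0, "weights must have a positive finite sum")
  findInterval(stats::runif(n) * tot, cw) + 1L
}

## 26-neighbourhood offsets (3^3 - 1 rows).
offsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0L, , drop = FALSE]
}

## Connected-component labels (26-connectivity) for a set of voxels given as
## 0-based coordinates. Returns an integer label per row.
components26 <- function(coords, shape) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  row_of <- integer(prod(shape))
  idx <- vox_index(coords, shape)
  row_of[idx] <- seq_len(n)
  offs <- offsets26()
  labels <- integer(n)
  queue <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (labels[s] > 0L) next
    cur <- cur + 1L
    labels[s] <- cur
    queue[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      nb <- sweep(offs, 2L, coords[v, ], "+")
      nb <- nb[in_bounds(nb, shape), , drop = FALSE]
      if (nrow(nb) == 0L) next
      r <- row_of[vox_index(nb, shape)]
      r <- r[r > 0L]
      r <- r[labels[r] == 0L]
      if (length(r)) {
        labels[r] <- cur
        queue[(tail + 1L):(tail + length(r))] <- r
        tail <- tail + length(r)
      }
    }
  }
  labels
}

## Squared Euclidean distances between rows of X (n x d) and C (k x d).
dist2_to_centers <- function(X, C) {
  D <- -2 * (X %*% t(C))
  D <- sweep(D, 1L, rowSums(X^2), "+")
  D <- sweep(D, 2L, rowSums(C^2), "+")
  D[D < 0] <- 0
  D
}

## Dice overlap between two voxel index sets.
dice_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}
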