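#' Construct a two-lobed synthetic grey-matter grid
#'
#' Builds the common voxel space shared by all subjects of a synthetic cohort:
#' two mirrored ellipsoidal grey-matter lobes inside a rectangular voxel grid,
#' split into left and right hemispheres at the sagittal midline. The mask is
#' mirror symmetric by construction, so left and right voxel counts are equal.
#'
#' @param shape integer triple, grid dimensions in voxels (each at least 8).
#' @param voxel_size_mm isotropic voxel edge length in millimetres.
#' @param seed integer; stored with the grid. The mask itself is deterministic.
#'
#' @return An object of class `brain_grid` with fields `shape`,
#'   `voxel_size_mm`, `mask` (logical array), `hemisphere` (integer array,
#'   0 = background, 1 = left, 2 = right), `gm_idx` (linear indices of
#'   grey-matter voxels) and `coords` (0-based voxel coordinates, one row per
#'   grey-matter voxel, in `gm_idx` order).
#' @export
make_brain_grid <- function(shape, voxel_size_mm = 2, seed = 1L) {
  shape <- as.integer(shape)
  assert_that(length(shape) == 3L && all(is.finite(shape)),
              "shape must be an integer triple")
  if (any(shape < 8L))
    stop("degenerate shape: every grid dimension must be at least 8 voxels")
  assert_that(is.numeric(voxel_size_mm) && voxel_size_mm > 0,
              "voxel_size_mm must be positive")

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2; cz <- (nz - 1) / 2
  # lobe centres sit at cx +/- dxc; semi-axes scale with the grid
  dxc <- 0.24 * nx
  ax <- 0.26 * nx; ay <- 0.42 * ny; az <- 0.42 * nz

  X <- array(rep(0:(nx - 1), times = ny * nz), dim = shape)
  Y <- array(rep(rep(0:(ny - 1), each = nx), times = nz), dim = shape)
  Z <- array(rep(0:(nz - 1), each = nx * ny), dim = shape)

  left_lobe  <- ((X - (cx - dxc)) / ax)^2 + ((Y - cy) / ay)^2 + ((Z - cz) / az)^2 <= 1
  right_lobe <- ((X - (cx + dxc)) / ax)^2 + ((Y - cy) / ay)^2 + ((Z - cz) / az)^2 <= 1
  # midline plane voxels (odd nx) are their own mirror image; exclude them so
  # the hemispheres stay disjoint and equal-sized
  mask <- (left_lobe | right_lobe) & (X != cx)

  hemisphere <- array(0L, dim = shape)
  hemisphere[mask & X < cx] <- 1L
  hemisphere[mask & X > cx] <- 2L

  gm_idx <- which(mask)
  assert_that(sum(hemisphere == 1L) > 0L && sum(hemisphere == 2L) > 0L,
              "mask construction produced an empty hemisphere")

  structure(
    list(
      shape = shape,
      voxel_size_mm = voxel_size_mm,
      mask = mask,
      hemisphere = hemisphere,
      gm_idx = gm_idx,
      coords = index_vox(gm_idx, shape),
      seed = as.integer(seed)
    ),
    class = "brain_grid"
  )
}

#' @export
print.brain_grid <- function(x, ...) {
  cat(sprintf(
    "<brain_grid> %dx%dx%d voxels (%.3g mm), %d grey-matter voxels (L %d / R %d)\n",
    x$shape[1], x$shape[2], x$shape[3], x$voxel_size_mm,
    length(x$gm_idx), sum(x$hemisphere == 1L), sum(x$hemisphere == 2L)
  ))
  invisible(x)
}

## hemisphere label (1/2) per grey-matter voxel, in gm_idx order
grid_hemi_vec <- function(grid) grid$hemisphere[grid$gm_idx]

## grey-matter voxel centre coordinates in mm
grid_coords_mm <- function(grid) grid$coords * grid$voxel_size_mm

## mirror 0-based voxel coordinates across the sagittal midline
mirror_coords <- function(coords, shape) {
  coords <- matrix(as.integer(coords), ncol = 3)
  cbind(shape[1] - 1L - coords[, 1], coords[, 2], coords[, 3])
}

## place per-grey-matter-voxel values into a full array (0 elsewhere)
gm_to_array <- function(grid, values, fill = 0) {
  a <- array(fill, dim = grid$shape)
  a[grid$gm_idx] <- values
  a
}
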