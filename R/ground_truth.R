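#' Plant hub zones and group effects on a brain grid
#'
#' Defines the ground truth of a synthetic cohort: bilateral pairs of hub
#' zones (connector or provincial), an optional lateralization effect on a
#' subset of connector pairs, the sex effects applied during streamline
#' simulation, and the calibration target for binarized connectome density.
#'
#' Zone centres are drawn in the left hemisphere (greedy placement with a
#' minimum separation), mirrored across the midline, then jittered by up to
#' `jitter_vox` voxels per axis. With `jitter_vox = 0` the two centres of a
#' pair are exact mirror images.
#'
#' @param grid a [make_brain_grid()] object.
#' @param n_zone_pairs number of bilateral zone pairs (default 18, the number
#'   of hub regions the topographic analysis is designed to recover).
#' @param sex_effects named numeric vector with `female_bc_multiplier`
#'   (scales the bridge-streamline rate for female subjects) and
#'   `male_degree_multiplier` (scales the total streamline count for males).
#' @param density_target target fraction of realized connections for the
#'   binarized connectome; stored verbatim and used only for calibration
#'   checks.
#' @param zone_radius_mm radius of a hub zone's spherical footprint.
#' @param prop_provincial fraction of zone pairs planted as provincial
#'   (dense within-zone wiring) rather than connector (inter-zone bridges).
#' @param n_lateralized number of connector pairs given a lateralized rate.
#' @param lateralization_strength signed multiplier offset: the right zone of
#'   a lateralized pair has its rate scaled by `1 + lateralization_strength`.
#' @param jitter_vox maximum per-axis jitter (voxels) applied to each centre.
#' @param min_separation_mm minimum distance between zone centres within a
#'   hemisphere; defaults to `2.2 * zone_radius_mm`. Should exceed the
#'   smoothing kernel width when downstream peak separation matters.
#' @param seed integer seed for placement and jitter.
#'
#' @return An object of class `ground_truth` with a `zones` data frame
#'   (zone_id, pair_id, hemisphere, kind, rate multiplier, centre coordinates)
#'   plus the effect and calibration parameters.
#' @export
make_ground_truth <- function(grid,
                              n_zone_pairs = 18L,
                              sex_effects = c(female_bc_multiplier = 1.5,
                                              male_degree_multiplier = 1.2),
                              density_target = 0.0977,
                              zone_radius_mm = 5,
                              prop_provincial = 1 / 3,
                              n_lateralized = 1L,
                              lateralization_strength = 0.3,
                              jitter_vox = 1L,
                              min_separation_mm = NULL,
                              seed = 1L) {
  stopifnot(inherits(grid, "brain_grid"))
  assert_that(n_zone_pairs >= 1L, "n_zone_pairs must be at least 1")
  assert_that(density_target > 0 && density_target < 0.5,
              "density_target must lie in (0, 0.5)")
  assert_that(all(c("female_bc_multiplier", "male_degree_multiplier") %in%
                    names(sex_effects)),
              "sex_effects must name female_bc_multiplier and male_degree_multiplier")

  r_vox <- zone_radius_mm / grid$voxel_size_mm
  hemi <- grid_hemi_vec(grid)
  left_rows <- which(hemi == 1L)
  coords_l <- grid$coords[left_rows, , drop = FALSE]

  # candidate centres: left voxels whose zone ball is mostly inside the mask
  cover <- ball_coverage(grid, r_vox)[left_rows]
  cand <- left_rows[cover >= 0.6]
  # keep pairs disjoint across the midline: centre must sit at least a ball
  # radius away from the midline plane
  cx <- (grid$shape[1] - 1) / 2
  cand <- cand[abs(grid$coords[cand, 1] - cx) > r_vox]
  assert_that(length(cand) > 0, "no feasible zone centres for this grid/radius")

  ## placement separation includes an allowance for the jitter applied below,
  ## so jittered centres still respect the requested minimum separation
  min_sep <- (min_separation_mm %||% (2.2 * zone_radius_mm)) +
    2 * jitter_vox * grid$voxel_size_mm
  ## farthest-point placement: random first centre, then repeatedly take the
  ## candidate farthest from all chosen centres (maximin); gives a well-spread
  ## arrangement whenever one exists
  centers_left <- with_seed(seed, {
    cc <- grid$coords[cand, , drop = FALSE] * grid$voxel_size_mm
    best <- NULL
    best_sep <- -Inf
    for (restart in 1:8) {  # several random starts; keep the best spread
      chosen <- sample.int(length(cand), 1L)
      dmin <- sqrt(rowSums(sweep(cc, 2L, cc[chosen, ], "-")^2))
      while (length(chosen) < n_zone_pairs) {
        nxt <- which.max(dmin)
        chosen <- c(chosen, nxt)
        dmin <- pmin(dmin, sqrt(rowSums(sweep(cc, 2L, cc[nxt, ], "-")^2)))
      }
      sep <- if (n_zone_pairs > 1L) min(stats::dist(cc[chosen, , drop = FALSE]))
             else Inf
      if (sep > best_sep) {
        best_sep <- sep
        best <- chosen
      }
    }
    cand[best]
  })
  sep <- stats::dist(grid$coords[centers_left, , drop = FALSE] *
                       grid$voxel_size_mm)
  if (n_zone_pairs > 1L && min(sep) < min_sep - 1e-9)
    stop(sprintf(
      "could not place %d zone pairs at %.1f mm separation (achieved %.1f mm)",
      n_zone_pairs, min_sep, min(sep)))

  cl <- grid$coords[centers_left, , drop = FALSE]
  cr <- mirror_coords(cl, grid$shape)

  if (jitter_vox > 0) {
    jit <- function(cc, s) with_seed(s, {
      cc + matrix(sample(seq(-jitter_vox, jitter_vox), 3L * nrow(cc),
                         replace = TRUE), ncol = 3)
    })
    cl <- snap_to_hemisphere(jit(cl, seed + 101L), grid, 1L)
    cr <- snap_to_hemisphere(jit(cr, seed + 202L), grid, 2L)
  }

  n_prov <- round(prop_provincial * n_zone_pairs)
  n_conn <- n_zone_pairs - n_prov
  assert_that(n_conn >= 1L || n_prov >= 1L, "no zones requested")
  kind_pair <- c(rep("connector_hub", n_conn), rep("provincial_hub", n_prov))

  lat_pair <- numeric(n_zone_pairs)
  if (n_lateralized > 0 && n_conn > 0) {
    k <- min(n_lateralized, n_conn)
    lat_pair[seq_len(k)] <- lateralization_strength
  }

  zones <- data.frame(
    zone_id = seq_len(2L * n_zone_pairs),
    pair_id = rep(seq_len(n_zone_pairs), 2L),
    hemisphere = rep(c("left", "right"), each = n_zone_pairs),
    kind = rep(kind_pair, 2L),
    # lateralization boosts the right member of a flagged pair
    rate_multiplier = c(rep(1, n_zone_pairs), 1 + lat_pair),
    cx = c(cl[, 1], cr[, 1]),
    cy = c(cl[, 2], cr[, 2]),
    cz = c(cl[, 3], cr[, 3]),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      zones = zones,
      n_zone_pairs = as.integer(n_zone_pairs),
      zone_radius_mm = zone_radius_mm,
      sex_effects = sex_effects,
      density_target = density_target,
      lateralized_pairs = which(lat_pair != 0),
      lateralization_strength = lateralization_strength,
      jitter_vox = as.integer(jitter_vox),
      seed = as.integer(seed)
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d zone pairs (%d connector / %d provincial), %d lateralized; density target %.4f\n",
    x$n_zone_pairs,
    sum(x$zones$kind == "connector_hub") / 2L,
    sum(x$zones$kind == "provincial_hub") / 2L,
    length(x$lateralized_pairs), x$density_target
  ))
  invisible(x)
}

## fraction of each grey-matter voxel's r-ball that lies inside the mask
ball_coverage <- function(grid, r_vox) {
  r <- ceiling(r_vox)
  offs <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  offs <- offs[rowSums(offs^2) <= r_vox^2, , drop = FALSE]
  cnt <- numeric(length(grid$gm_idx))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(grid$coords, 2L, offs[k, ], "+")
    ok <- in_bounds(nb, grid$shape)
    inside <- logical(length(cnt))
    inside[ok] <- grid$mask[vox_index(nb[ok, , drop = FALSE], grid$shape)]
    cnt <- cnt + inside
  }
  cnt / nrow(offs)
}

## rows (into grid$coords) of grey-matter voxels within radius of a centre,
## optionally restricted to one hemisphere
zone_ball_rows <- function(grid, center, radius_mm) {
  d <- sqrt(rowSums((grid$coords - matrix(center, nrow(grid$coords), 3,
                                          byrow = TRUE))^2)) * grid$voxel_size_mm
  which(d <= radius_mm)
}

## move each coordinate to the nearest grey-matter voxel of the requested
## hemisphere (jitter can push a centre off the mask)
snap_to_hemisphere <- function(coords, grid, hemi_code) {
  hemi <- grid_hemi_vec(grid)
  rows <- which(hemi == hemi_code)
  cc <- grid$coords[rows, , drop = FALSE]
  out <- coords
  for (i in seq_len(nrow(coords))) {
    d2 <- rowSums(sweep(cc, 2L, coords[i, ], "-")^2)
    out[i, ] <- cc[which.min(d2), ]
  }
  out
}
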