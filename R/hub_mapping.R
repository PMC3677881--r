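## Voxelwise topographic hub maps, hub-region extraction and hub scores.

new_hub_map <- function(values, metric, level, fwhm, grid) {
  structure(list(values = as.numeric(values), metric = metric, level = level,
                 smoothing_fwhm_mm = fwhm, grid = grid),
            class = "hub_map")
}

#' @export
print.hub_map <- function(x, ...) {
  cat(sprintf("<hub_map> %s (%s), fwhm %.1f mm, range [%.4g, %.4g]\n",
              x$metric, x$level, x$smoothing_fwhm_mm,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Subject hub map by ensemble voxel averaging
#'
#' Each grey-matter voxel's value is the mean, across the parcellation
#' ensemble members, of the chosen node metric of the ROI the voxel falls
#' within. This turns per-parcellation node metrics into a topographic map
#' that no longer depends on any single node placement.
#'
#' @param ensemble a [ensemble_parcellate()] object.
#' @param node_metrics list (one per member) of [compute_node_metrics()]
#'   tables, in ensemble order.
#' @param metric `"degree"` or `"betweenness"`.
#' @param grid the shared grid.
#' @return a `hub_map` (level `"subject"`, unsmoothed).
#' @export
voxel_average_map <- function(ensemble, node_metrics,
                              metric = c("degree", "betweenness"), grid) {
  stopifnot(inherits(ensemble, "parcellation_ensemble"))
  metric <- match.arg(metric)
  assert_that(length(node_metrics) == ensemble$P,
              "need one node-metrics table per ensemble member")
  acc <- numeric(length(grid$gm_idx))
  for (p in seq_len(ensemble$P)) {
    labels <- ensemble$parcellations[[p]]$labels
    if (any(labels == 0L))
      stop(sprintf("member %d: unlabeled grey-matter voxel (partition violated)", p))
    vals <- node_metrics[[p]][[metric]]
    acc <- acc + vals[labels]
  }
  new_hub_map(acc / ensemble$P, metric, "subject", 0, grid)
}

#' Mask-renormalized Gaussian smoothing of a hub map
#'
#' Separable Gaussian kernel with `sigma = fwhm / (2 sqrt(2 ln 2))` (in
#' voxels after dividing by the voxel size), restricted to the grey-matter
#' mask: both `values * mask` and `mask` are convolved and the ratio is
#' taken, so values outside the mask never leak in and a constant map is
#' preserved exactly. `fwhm_mm = 0` is the identity.
#'
#' @param map a `hub_map`.
#' @param fwhm_mm kernel full width at half maximum, millimetres.
#' @param grid the grid (defaults to the map's own).
#' @return a smoothed `hub_map`.
#' @export
smooth_map <- function(map, fwhm_mm, grid = map$grid) {
  stopifnot(inherits(map, "hub_map"))
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) {
    map$smoothing_fwhm_mm <- 0
    return(map)
  }
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_size_mm
  r <- max(1L, ceiling(3 * sigma_vox))
  kern <- stats::dnorm(-r:r, sd = sigma_vox)
  kern <- kern / sum(kern)

  V <- gm_to_array(grid, map$values)
  M <- array(0, dim = grid$shape)
  M[grid$gm_idx] <- 1
  for (axis in 1:3) {
    V <- convolve_axis(V, kern, axis)
    M <- convolve_axis(M, kern, axis)
  }
  out <- V[grid$gm_idx] / M[grid$gm_idx]
  new_hub_map(out, map$metric, map$level, fwhm_mm, grid)
}

## zero-padded 1-D convolution of a 3-D array along one axis
convolve_axis <- function(A, kern, axis) {
  d <- dim(A)
  r <- (length(kern) - 1L) / 2L
  out <- array(0, dim = d)
  for (t in seq_along(kern)) {
    s <- t - r - 1L  # shift
    w <- kern[t]
    if (w == 0) next
    n <- d[axis]
    lo_dst <- max(1L, 1L + s); hi_dst <- min(n, n + s)
    if (lo_dst > hi_dst) next
    lo_src <- lo_dst - s; hi_src <- hi_dst - s
    if (axis == 1L) {
      out[lo_dst:hi_dst, , ] <- out[lo_dst:hi_dst, , ] +
        w * A[lo_src:hi_src, , ]
    } else if (axis == 2L) {
      out[, lo_dst:hi_dst, ] <- out[, lo_dst:hi_dst, ] +
        w * A[, lo_src:hi_src, ]
    } else {
      out[, , lo_dst:hi_dst] <- out[, , lo_dst:hi_dst] +
        w * A[, , lo_src:hi_src]
    }
  }
  out
}

#' Group-average hub map
#'
#' Voxelwise mean of subject hub maps sharing one grid and metric (identity
#' registration: all subjects of a synthetic cohort live in the same space).
#'
#' @param maps list of subject `hub_map`s.
#' @return a `hub_map` with level `"group"`.
#' @export
group_average <- function(maps) {
  assert_that(length(maps) >= 1L, "need at least one map")
  m1 <- maps[[1]]
  for (m in maps) {
    stopifnot(inherits(m, "hub_map"))
    if (!identical(m$metric, m1$metric)) stop("mixed metrics in group average")
    if (!identical(m$grid$shape, m1$grid$shape) ||
        length(m$values) != length(m1$values))
      stop("maps are not on the same grid")
  }
  vals <- rowMeans(vapply(maps, `[[`, numeric(length(m1$values)), "values"))
  new_hub_map(vals, m1$metric, "group", m1$smoothing_fwhm_mm, m1$grid)
}

#' Extract hub regions from a group map
#'
#' Thresholds the map at the given percentile of in-mask values (strictly
#' above, i.e. the top `100 - percentile` percent), splits the
#' supra-threshold mask into regions by watershed flooding seeded at local
#' maxima (26-connectivity, descending-value flooding; this automates the
#' manual separation of neighbouring peaks along their inflection lines),
#' and merges regions smaller than `min_voxels` into the adjacent region
#' with the highest peak. Region ids are ordered by decreasing peak value.
#'
#' @param group_map a group-level `hub_map`.
#' @param percentile threshold percentile in (0, 100); default 80. The
#'   percentile estimator interpolates linearly between order statistics.
#' @param min_voxels minimum region size before merging (default 5).
#' @param grid the grid (defaults to the map's own).
#' @return list of `hub_region` objects (region_id, voxel rows into the
#'   grey-matter set, 0-based peak coordinates, peak value, hemisphere by
#'   majority vote), with the threshold as an attribute.
#' @export
define_hub_regions <- function(group_map, percentile = 80, min_voxels = 5L,
                               grid = group_map$grid) {
  stopifnot(inherits(group_map, "hub_map"))
  assert_that(percentile > 0 && percentile < 100,
              "percentile must lie in (0, 100)")
  v <- group_map$values
  thr <- stats::quantile(v, percentile / 100, type = 7, names = FALSE)
  sel <- which(v > thr)
  if (!length(sel))
    stop("threshold too high: empty hub mask (is the map constant?)")

  coords <- grid$coords[sel, , drop = FALSE]
  lab <- watershed_flood(coords, v[sel], grid$shape)

  ## merge undersized regions into their strongest neighbour
  lab <- merge_small_regions(lab, coords, v[sel], grid$shape, min_voxels)

  hemi <- grid_hemi_vec(grid)[sel]
  ids <- sort(unique(lab))
  regions <- lapply(ids, function(k) {
    rows <- which(lab == k)
    pk <- rows[which.max(v[sel][rows])]
    list(voxel_rows = sel[rows],
         coords = coords[rows, , drop = FALSE],
         hemisphere = if (mean(hemi[rows] == 1L) >= 0.5) "left" else "right",
         peak_voxel = coords[pk, ],
         peak_value = v[sel][pk],
         n_voxels = length(rows))
  })
  ord <- order(vapply(regions, `[[`, 0, "peak_value"), decreasing = TRUE)
  regions <- regions[ord]
  for (k in seq_along(regions)) {
    regions[[k]]$region_id <- k
    class(regions[[k]]) <- "hub_region"
  }
  attr(regions, "threshold") <- thr
  attr(regions, "percentile") <- percentile
  regions
}

## descending-value flooding: each voxel joins the region of its
## highest-valued already-labelled 26-neighbour, or starts a new region
## (a local maximum within the mask)
watershed_flood <- function(coords, values, shape) {
  n <- nrow(coords)
  ord <- order(values, decreasing = TRUE)
  lab_of <- integer(prod(shape))
  val_of <- numeric(prod(shape))
  idx <- vox_index(coords, shape)
  val_of[idx] <- values
  offs <- offsets26()
  lab <- integer(n)
  next_lab <- 0L
  for (v in ord) {
    nb <- sweep(offs, 2L, coords[v, ], "+")
    nb <- nb[in_bounds(nb, shape), , drop = FALSE]
    nl <- if (nrow(nb)) lab_of[vox_index(nb, shape)] else integer(0)
    assigned <- which(nl > 0L)
    if (!length(assigned)) {
      next_lab <- next_lab + 1L
      lab[v] <- next_lab
    } else {
      nbi <- vox_index(nb[assigned, , drop = FALSE], shape)
      lab[v] <- nl[assigned][which.max(val_of[nbi])]
    }
    lab_of[idx[v]] <- lab[v]
  }
  lab
}

merge_small_regions <- function(lab, coords, values, shape, min_voxels) {
  if (min_voxels <= 1L) return(lab)
  offs <- offsets26()
  idx <- vox_index(coords, shape)
  repeat {
    sizes <- table(lab)
    small <- as.integer(names(sizes)[sizes < min_voxels])
    if (!length(small)) break
    lab_of <- integer(prod(shape))
    lab_of[idx] <- lab
    peaks <- tapply(values, lab, max)
    ## merge the smallest region first
    small <- small[order(sizes[as.character(small)])]
    merged_any <- FALSE
    for (k in small) {
      rows <- which(lab == k)
      nb_lab <- integer(0)
      for (v in rows) {
        nb <- sweep(offs, 2L, coords[v, ], "+")
        nb <- nb[in_bounds(nb, shape), , drop = FALSE]
        if (nrow(nb)) nb_lab <- c(nb_lab, lab_of[vox_index(nb, shape)])
      }
      nb_lab <- setdiff(unique(nb_lab[nb_lab > 0L]), k)
      if (!length(nb_lab)) next  # isolated small component: keep it
      target <- nb_lab[which.max(peaks[as.character(nb_lab)])]
      lab[rows] <- target
      merged_any <- TRUE
      break  # region table changed; recompute
    }
    if (!merged_any) break
  }
  lab
}

#' @export
print.hub_region <- function(x, ...) {
  cat(sprintf("<hub_region> id %d (%s): %d voxels, peak %.4g at (%d,%d,%d)\n",
              x$region_id, x$hemisphere, x$n_voxels, x$peak_value,
              x$peak_voxel[1], x$peak_voxel[2], x$peak_voxel[3]))
  invisible(x)
}

#' Pair left and right hub regions bilaterally
#'
#' Mirrors each left-hemisphere region's peak across the midline and matches
#' it to the closest right-hemisphere peak (greedy, one-to-one, within
#' `max_peak_dist_mm`). Unmatched regions are reported as unilateral.
#'
#' @param regions output of [define_hub_regions()].
#' @param grid the grid.
#' @param max_peak_dist_mm maximum mirrored peak distance for a pair.
#' @return data frame with `pair_id`, `left_id`, `right_id`,
#'   `peak_dist_mm`; attribute `unpaired` lists unilateral region ids.
#' @export
pair_regions <- function(regions, grid, max_peak_dist_mm = 12) {
  left <- Filter(function(r) r$hemisphere == "left", regions)
  right <- Filter(function(r) r$hemisphere == "right", regions)
  if (!length(left) || !length(right)) {
    out <- data.frame(pair_id = integer(0), left_id = integer(0),
                      right_id = integer(0), peak_dist_mm = numeric(0))
    attr(out, "unpaired") <- vapply(regions, `[[`, 0L, "region_id")
    return(out)
  }
  lp <- t(vapply(left, `[[`, numeric(3), "peak_voxel"))
  rp <- t(vapply(right, `[[`, numeric(3), "peak_voxel"))
  lpm <- mirror_coords(lp, grid$shape)
  D <- outer(rowSums(lpm^2), rowSums(rp^2), "+") - 2 * lpm %*% t(rp)
  D[D < 0] <- 0
  D <- sqrt(D) * grid$voxel_size_mm

  pairs <- list()
  used_l <- logical(nrow(D)); used_r <- logical(ncol(D))
  repeat {
    D2 <- D
    D2[used_l, ] <- Inf; D2[, used_r] <- Inf
    if (all(!is.finite(D2)) || min(D2) > max_peak_dist_mm) break
    w <- which(D2 == min(D2), arr.ind = TRUE)[1, ]
    pairs[[length(pairs) + 1L]] <- c(left[[w[1]]]$region_id,
                                     right[[w[2]]]$region_id, D2[w[1], w[2]])
    used_l[w[1]] <- TRUE; used_r[w[2]] <- TRUE
  }
  out <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    data.frame(pair_id = seq_len(nrow(m)), left_id = as.integer(m[, 1]),
               right_id = as.integer(m[, 2]), peak_dist_mm = m[, 3])
  } else {
    data.frame(pair_id = integer(0), left_id = integer(0),
               right_id = integer(0), peak_dist_mm = numeric(0))
  }
  paired_ids <- c(out$left_id, out$right_id)
  attr(out, "unpaired") <- setdiff(vapply(regions, `[[`, 0L, "region_id"),
                                   paired_ids)
  out
}

#' Symmetrize bilateral region pairs for hemispheric comparison
#'
#' Hemispheric score comparisons must read the two scores from anatomically
#' corresponding voxel sets: if the left and right members of a pair have
#' different shapes, the max-score of every subject inherits that shared
#' geometric difference and the left-right test rejects even for perfectly
#' symmetric cohorts. For each bilateral pair this returns two replacement
#' regions covering the union of the left member and the mirrored right
#' member (and its mirror image), so left and right scores are exchangeable
#' under a symmetric ground truth.
#'
#' @param regions output of [define_hub_regions()].
#' @param pairs a [pair_regions()] table.
#' @param grid the grid (mask must be mirror symmetric).
#' @return list of `hub_region` objects (one left + one right per pair,
#'   keeping the original region ids).
#' @export
symmetrize_regions <- function(regions, pairs, grid) {
  by_id <- stats::setNames(regions, vapply(regions, `[[`, 0L, "region_id"))
  row_of <- integer(prod(grid$shape))
  row_of[grid$gm_idx] <- seq_along(grid$gm_idx)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    rl <- by_id[[as.character(pairs$left_id[i])]]
    rr <- by_id[[as.character(pairs$right_id[i])]]
    mirror_rows <- function(rows) {
      mc <- mirror_coords(grid$coords[rows, , drop = FALSE], grid$shape)
      r <- row_of[vox_index(mc, grid$shape)]
      if (any(r == 0L))
        stop("mirrored region leaves the grey-matter mask; grid not symmetric")
      r
    }
    left_rows <- sort(unique(c(rl$voxel_rows, mirror_rows(rr$voxel_rows))))
    right_rows <- mirror_rows(left_rows)
    for (side in c("left", "right")) {
      src <- if (side == "left") rl else rr
      rows <- if (side == "left") left_rows else right_rows
      out[[length(out) + 1L]] <- structure(
        list(voxel_rows = rows,
             coords = grid$coords[rows, , drop = FALSE],
             hemisphere = side, peak_voxel = src$peak_voxel,
             peak_value = src$peak_value, n_voxels = length(rows),
             region_id = src$region_id),
        class = "hub_region")
    }
  }
  out
}

#' Per-subject hub scores
#'
#' A subject's hub score for a region is the maximum of the subject's
#' (smoothed) metric map over the region's voxels.
#'
#' @param subject_maps named list of subject `hub_map`s (names = subject
#'   ids), all sharing one metric and grid.
#' @param regions output of [define_hub_regions()].
#' @param manifest optional data frame with `subject_id` and `sex`.
#' @return data frame (`subject_id`, `sex`, `region_id`, `hemisphere`,
#'   `metric`, `score`).
#' @export
score_hubs <- function(subject_maps, regions, manifest = NULL) {
  assert_that(length(subject_maps) >= 1L, "need at least one subject map")
  metric <- subject_maps[[1]]$metric
  n_gm <- length(subject_maps[[1]]$values)
  for (r in regions)
    if (any(r$voxel_rows > n_gm)) stop("region lies outside the map's mask")
  sex_of <- if (!is.null(manifest))
    stats::setNames(manifest$sex, manifest$subject_id) else NULL
  rows <- list()
  for (sid in names(subject_maps)) {
    m <- subject_maps[[sid]]
    stopifnot(identical(m$metric, metric))
    for (r in regions) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid,
        sex = if (is.null(sex_of)) NA_character_ else unname(sex_of[sid]),
        region_id = r$region_id,
        hemisphere = r$hemisphere,
        metric = metric,
        score = max(m$values[r$voxel_rows]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Cluster-size bias diagnostic
#'
#' Pearson correlation between ROI volume fraction and ROI degree, pooled
#' over parcellations and subjects. A template-free parcellation is usable
#' only if node degree is not an artifact of cluster size, i.e. `r` is small.
#'
#' @param parcellations list of [parcellate_grid()] objects.
#' @param node_metrics list (same length/order) of [compute_node_metrics()]
#'   tables computed on those parcellations.
#' @return list with `r`, `r_squared` and the number of pooled ROIs.
#' @export
size_bias_diagnostic <- function(parcellations, node_metrics) {
  assert_that(length(parcellations) == length(node_metrics),
              "parcellations and node_metrics must align")
  frac <- unlist(lapply(parcellations, function(p)
    p$roi_volume_voxels / sum(p$roi_volume_voxels)))
  deg <- unlist(lapply(node_metrics, `[[`, "degree"))
  assert_that(length(frac) == length(deg) && length(frac) >= 2L,
              "need at least 2 pooled ROIs")
  if (stats::sd(frac) == 0 || stats::sd(deg) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(frac, deg)
  list(r = r, r_squared = r^2, n = length(frac))
}

#' Dice recovery of planted hub zones
#'
#' Diagnostic linking a set of recovered hub regions back to the generator's
#' ground truth: for every planted connector zone, the Dice coefficient
#' between the zone's spherical voxel footprint and the best-matching
#' recovered region.
#'
#' @param regions output of [define_hub_regions()].
#' @param truth the [make_ground_truth()] used to build the cohort.
#' @param grid the grid.
#' @return data frame (`zone_id`, `pair_id`, `hemisphere`, `best_region`,
#'   `dice`).
#' @export
zone_recovery <- function(regions, truth, grid) {
  zones <- truth$zones[truth$zones$kind == "connector_hub", , drop = FALSE]
  out <- lapply(seq_len(nrow(zones)), function(i) {
    ball <- zone_ball_rows(grid, unlist(zones[i, c("cx", "cy", "cz")]),
                           truth$zone_radius_mm)
    dices <- vapply(regions, function(r) dice_coefficient(r$voxel_rows, ball),
                    0)
    data.frame(zone_id = zones$zone_id[i], pair_id = zones$pair_id[i],
               hemisphere = zones$hemisphere[i],
               best_region = regions[[which.max(dices)]]$region_id,
               dice = max(dices))
  })
  do.call(rbind, out)
}
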