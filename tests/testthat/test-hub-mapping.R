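# Deterministic fixtures: hand-made ensembles and maps on a full-box grid.
tiny_map <- function(grid, values, metric = "betweenness", level = "group") {
  hubtopo:::new_hub_map(values, metric, level, 0, grid)
}

test_that("voxel averaging pools the metric of the containing ROI per member", {
  g <- full_box_grid(c(8, 8, 8))
  n <- length(g$gm_idx)
  hemi <- g$hemisphere[g$gm_idx]
  mk_parc <- function(split_y) {
    labels <- integer(n)
    y <- g$coords[, 2]
    labels[hemi == 1L] <- 1L + (y[hemi == 1L] >= split_y)
    labels[hemi == 2L] <- 3L + (y[hemi == 2L] >= split_y)
    structure(list(labels = labels, K_per_hemisphere = 2L, seed = split_y,
                   roi_hemisphere = c("left", "left", "right", "right"),
                   roi_volume_voxels = tabulate(labels, 4L)),
              class = "parcellation")
  }
  ens <- structure(list(parcellations = list(mk_parc(4L), mk_parc(2L)),
                        K = 2L, P = 2L, seeds = c(4L, 2L)),
                   class = "parcellation_ensemble")
  metrics <- list(
    data.frame(node = 1:4, hemisphere = ens$parcellations[[1]]$roi_hemisphere,
               degree = c(10, 20, 30, 40), betweenness = c(.1, .2, .3, .4)),
    data.frame(node = 1:4, hemisphere = ens$parcellations[[2]]$roi_hemisphere,
               degree = c(50, 60, 70, 80), betweenness = c(.5, .6, .7, .8))
  )
  m <- voxel_average_map(ens, metrics, "degree", g)
  # brute-force per-voxel loop
  expected <- vapply(seq_len(n), function(v) {
    mean(c(metrics[[1]]$degree[ens$parcellations[[1]]$labels[v]],
           metrics[[2]]$degree[ens$parcellations[[2]]$labels[v]]))
  }, 0)
  expect_equal(m$values, expected)
  # bounded by the contributing ROI metrics
  expect_true(all(m$values >= 10 & m$values <= 80))

  # P = 1: piecewise constant at the member's ROI metric
  ens1 <- structure(list(parcellations = ens$parcellations[1], K = 2L, P = 1L,
                         seeds = 4L), class = "parcellation_ensemble")
  m1 <- voxel_average_map(ens1, metrics[1], "betweenness", g)
  expect_equal(sort(unique(m1$values)), c(.1, .2, .3, .4))
})

test_that("smoothing is the identity at fwhm 0, preserves constants, matches the kernel", {
  g <- full_box_grid(c(16, 16, 16))
  n <- length(g$gm_idx)

  vals <- withr::with_seed(5, runif(n))
  m <- tiny_map(g, vals)
  expect_equal(smooth_map(m, 0, g)$values, vals)

  const <- tiny_map(g, rep(3.7, n))
  sm <- smooth_map(const, 10, g)
  expect_equal(sm$values, rep(3.7, n), tolerance = 1e-12)

  # impulse response equals the separable sampled Gaussian away from edges
  fwhm <- 6; voxel <- 2
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel
  imp <- numeric(n)
  center <- c(8, 8, 8)
  crow <- which(g$coords[, 1] == 8 & g$coords[, 2] == 8 & g$coords[, 3] == 8)
  imp[crow] <- 1
  sm <- smooth_map(tiny_map(g, imp), fwhm, g)
  r <- ceiling(3 * sigma)
  k1 <- dnorm(-r:r, sd = sigma); k1 <- k1 / sum(k1)
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0), c(-1, 2, 1))) {
    target <- center + off
    trow <- which(g$coords[, 1] == target[1] & g$coords[, 2] == target[2] &
                    g$coords[, 3] == target[3])
    expected <- prod(k1[off + r + 1])
    expect_equal(sm$values[trow], expected, tolerance = 1e-10)
  }
  # output range never exceeds the input range
  expect_true(all(sm$values >= 0 & sm$values <= 1))
  expect_error(smooth_map(m, -1, g), "non-negative")
})

test_that("group averaging is the voxelwise mean and rejects mismatches", {
  g <- full_box_grid(c(8, 8, 8))
  n <- length(g$gm_idx)
  maps <- withr::with_seed(6, lapply(1:5, function(i) tiny_map(g, runif(n))))
  ga <- group_average(maps)
  expected <- rowMeans(vapply(maps, `[[`, numeric(n), "values"))
  expect_equal(ga$values, expected)
  expect_equal(ga$level, "group")

  expect_equal(group_average(maps[1])$values, maps[[1]]$values)

  other <- tiny_map(g, runif(n), metric = "degree")
  expect_error(group_average(list(maps[[1]], other)), "mixed metrics")
})

test_that("hub regions split well-separated bumps and reject constant maps", {
  g <- full_box_grid(c(20, 12, 12))
  n <- length(g$gm_idx)
  bump <- function(center, width = 2.2) {
    d2 <- rowSums(sweep(g$coords, 2, center, "-")^2)
    exp(-d2 / (2 * width^2))
  }
  c1 <- c(4, 6, 6); c2 <- c(15, 6, 6)
  vals <- bump(c1) + 0.8 * bump(c2)
  regions <- define_hub_regions(tiny_map(g, vals), percentile = 80,
                                min_voxels = 5, grid = g)
  expect_length(regions, 2)
  peaks <- t(vapply(regions, `[[`, numeric(3), "peak_voxel"))
  expect_true(any(colSums(t(peaks) == c1) == 3))
  expect_true(any(colSums(t(peaks) == c2) == 3))
  expect_setequal(vapply(regions, `[[`, "", "hemisphere"), c("left", "right"))

  # region partition: disjoint, union = hub mask
  all_rows <- unlist(lapply(regions, `[[`, "voxel_rows"))
  expect_equal(length(all_rows), length(unique(all_rows)))
  thr <- attr(regions, "threshold")
  expect_setequal(all_rows, which(vals > thr))
  expect_equal(thr, unname(quantile(vals, 0.8)))

  expect_error(define_hub_regions(tiny_map(g, rep(1, n)), 80, 5, g),
               "threshold too high")
})

test_that("hub scores take the subject maximum over each region", {
  g <- full_box_grid(c(8, 8, 8))
  n <- length(g$gm_idx)
  reg <- list(
    structure(list(voxel_rows = 5L, coords = g$coords[5L, , drop = FALSE],
                   hemisphere = "left", peak_voxel = g$coords[5L, ],
                   peak_value = 1, n_voxels = 1L, region_id = 1L),
              class = "hub_region"),
    structure(list(voxel_rows = c(10L, 11L, 12L),
                   coords = g$coords[10:12, , drop = FALSE],
                   hemisphere = "left", peak_voxel = g$coords[10L, ],
                   peak_value = 1, n_voxels = 3L, region_id = 2L),
              class = "hub_region")
  )
  vals <- numeric(n)
  vals[5] <- 2.5
  vals[10:12] <- c(3, 7, 5)
  maps <- list(subjA = tiny_map(g, vals, level = "subject"))
  man <- data.frame(subject_id = "subjA", sex = "F")
  sc <- score_hubs(maps, reg, man)
  expect_equal(sc$score[sc$region_id == 1], 2.5)
  expect_equal(sc$score[sc$region_id == 2], 7)
  expect_equal(unique(sc$sex), "F")

  # brute-force max oracle on random maps and regions
  withr::with_seed(8, {
    maps <- list(s1 = tiny_map(g, runif(n), level = "subject"),
                 s2 = tiny_map(g, runif(n), level = "subject"))
    sc <- score_hubs(maps, reg)
    for (sid in names(maps)) for (r in reg) {
      expect_equal(sc$score[sc$subject_id == sid & sc$region_id == r$region_id],
                   max(maps[[sid]]$values[r$voxel_rows]))
    }
  })

  bad <- reg
  bad[[1]]$voxel_rows <- n + 50L
  expect_error(score_hubs(maps, bad), "outside")
})

test_that("region pairing mirrors peaks and symmetrization equalizes shapes", {
  g <- full_box_grid(c(20, 12, 12))
  bump <- function(center, width = 2.2) {
    d2 <- rowSums(sweep(g$coords, 2, center, "-")^2)
    exp(-d2 / (2 * width^2))
  }
  # left bump and its (slightly weaker) mirrored partner
  vals <- bump(c(4, 6, 6)) + 0.9 * bump(c(15, 6, 6))
  regions <- define_hub_regions(tiny_map(g, vals), 80, 5, g)
  pairs <- pair_regions(regions, g)
  expect_equal(nrow(pairs), 1)
  expect_length(attr(pairs, "unpaired"), 0)

  sym <- symmetrize_regions(regions, pairs, g)
  expect_length(sym, 2)
  sizes <- vapply(sym, `[[`, 0L, "n_voxels")
  expect_equal(sizes[1], sizes[2])
  # the right set is the mirror image of the left set
  l <- sym[[which(vapply(sym, `[[`, "", "hemisphere") == "left")]]
  r <- sym[[which(vapply(sym, `[[`, "", "hemisphere") == "right")]]
  mirrored <- hubtopo:::mirror_coords(l$coords, g$shape)
  expect_setequal(hubtopo:::vox_index(mirrored, g$shape),
                  hubtopo:::vox_index(r$coords, g$shape))
})

test_that("node degree is only weakly predictable from cluster size", {
  cfg <- demo_config("medium", seed = 9)
  g <- make_brain_grid(cfg$grid_shape, cfg$voxel_size_mm)
  tr <- make_ground_truth(g, n_zone_pairs = cfg$n_zone_pairs,
                          zone_radius_mm = cfg$zone_radius_mm,
                          prop_provincial = cfg$prop_provincial,
                          min_separation_mm = cfg$zone_min_sep_mm,
                          seed = cfg$seed)
  model <- build_streamline_model(g, tr)
  co <- make_cohort(g, tr, 3, 3, cfg$n_streamlines, seed = cfg$seed,
                    model = model)
  parcs <- list(); nms <- list()
  for (s in seq_along(co)) {
    ens <- ensemble_parcellate(g, cfg$K_per_hemisphere, 2,
                               master_seed = cfg$seed + 131L * s)
    for (p in 1:2) {
      cn <- make_connectome(co[[s]]$streamlines, ens$parcellations[[p]], g)
      parcs <- c(parcs, ens$parcellations[p])
      nms <- c(nms, list(compute_node_metrics(cn)))
    }
  }
  bias <- size_bias_diagnostic(parcs, nms)
  # cluster size must not explain more than a small fraction of the degree
  # variance (the parcellation heuristic would otherwise drive the metrics)
  expect_lt(bias$r_squared, 0.25)
  expect_gte(bias$n, 2000)
})

test_that("with effects off, hemispheres are exchangeable and asymmetry tests stay calibrated", {
  lr_sign <- logical(20)
  p_asym <- c()
  for (s in 1:20) {
    res <- run_cohort_analysis(demo_config("small", seed = 300 + s),
                               effects = FALSE)
    g <- res$grid
    hemi <- g$hemisphere[g$gm_idx]
    v <- res$group_bc$values
    # mirrored voxel pairing: left voxel vs its mirror image
    left_rows <- which(hemi == 1L)
    mir <- hubtopo:::mirror_coords(g$coords[left_rows, , drop = FALSE],
                                   g$shape)
    row_of <- integer(prod(g$shape))
    row_of[g$gm_idx] <- seq_along(g$gm_idx)
    right_rows <- row_of[hubtopo:::vox_index(mir, g$shape)]
    lr_sign[s] <- mean(v[left_rows] - v[right_rows]) > 0

    pairs <- pair_regions(res$regions, g)
    if (nrow(pairs)) {
      sym <- symmetrize_regions(res$regions, pairs, g)
      ssym <- rbind(score_hubs(res$maps$betweenness, sym, res$manifest),
                    score_hubs(res$maps$degree, sym, res$manifest))
      p_asym <- c(p_asym, asymmetry_suite(ssym, pairs)$p_adjusted)
    }
  }
  # sign test on the per-seed direction of the mirrored difference
  expect_gt(binom.test(sum(lr_sign), 20, 0.5)$p.value, 0.01)
  # corrected asymmetry rejections stay rare under the symmetric null
  expect_gte(length(p_asym), 20)
  expect_lte(mean(p_asym < 0.05), 0.1)
})

test_that("size-bias diagnostic reports pooled correlation and error paths", {
  p1 <- structure(list(roi_volume_voxels = c(10L, 20L, 30L, 40L)),
                  class = "parcellation")
  nm1 <- data.frame(degree = c(1, 2, 3, 4))
  r <- size_bias_diagnostic(list(p1), list(nm1))
  expect_equal(r$r, 1)
  expect_equal(r$r_squared, 1)

  nm_const <- data.frame(degree = rep(2, 4))
  expect_error(size_bias_diagnostic(list(p1), list(nm_const)), "zero variance")
})
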