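test_that("brain grids are symmetric, deterministic, and reject degenerate shapes", {
  g <- make_brain_grid(c(8, 8, 8))
  expect_equal(sum(g$hemisphere == 1L), sum(g$hemisphere == 2L))
  # mirror symmetry of the mask itself
  flipped <- g$mask[g$shape[1]:1, , ]
  expect_identical(flipped, g$mask)

  expect_identical(make_brain_grid(c(10, 12, 10))$mask,
                   make_brain_grid(c(10, 12, 10))$mask)
  expect_error(make_brain_grid(c(7, 8, 8)), "at least 8")

  # brute-force re-evaluation of the lobe inequalities over the whole grid
  g <- make_brain_grid(c(20, 24, 20), voxel_size_mm = 2)
  shape <- c(20, 24, 20)
  cx <- (shape[1] - 1) / 2; cy <- (shape[2] - 1) / 2; cz <- (shape[3] - 1) / 2
  dxc <- 0.24 * shape[1]
  ax <- 0.26 * shape[1]; ay <- 0.42 * shape[2]; az <- 0.42 * shape[3]
  count <- 0L
  for (x in 0:(shape[1] - 1)) for (y in 0:(shape[2] - 1)) for (z in 0:(shape[3] - 1)) {
    inl <- ((x - (cx - dxc)) / ax)^2 + ((y - cy) / ay)^2 + ((z - cz) / az)^2 <= 1
    inr <- ((x - (cx + dxc)) / ax)^2 + ((y - cy) / ay)^2 + ((z - cz) / az)^2 <= 1
    if ((inl || inr) && x != cx) count <- count + 1L
  }
  expect_equal(length(g$gm_idx), count)
})

test_that("ground truth mirrors zone pairs and stores the calibration target", {
  g <- make_brain_grid(c(16, 20, 16))
  tr <- make_ground_truth(g, n_zone_pairs = 1, jitter_vox = 0L,
                          zone_radius_mm = 5, seed = 4)
  zl <- tr$zones[tr$zones$hemisphere == "left", ]
  zr <- tr$zones[tr$zones$hemisphere == "right", ]
  expect_equal(unname(unlist(zr[, c("cx", "cy", "cz")])),
               unname(c(g$shape[1] - 1 - zl$cx, zl$cy, zl$cz)))
  expect_identical(tr$density_target, 0.0977)

  tr18 <- make_ground_truth(make_brain_grid(c(32, 38, 32)), n_zone_pairs = 18,
                            seed = 2)
  expect_equal(nrow(tr18$zones), 36)

  expect_error(make_ground_truth(g, n_zone_pairs = 200, seed = 1),
               "could not place")
  expect_error(make_ground_truth(g, density_target = 0.7), "0, 0.5")
})

test_that("streamline simulation honours counts, seeds and null sex effects", {
  g <- make_brain_grid(c(14, 16, 14))
  tr_null <- make_ground_truth(
    g, n_zone_pairs = 2, zone_radius_mm = 5, min_separation_mm = 10,
    sex_effects = c(female_bc_multiplier = 1, male_degree_multiplier = 1),
    seed = 3)
  model <- build_streamline_model(g, tr_null)

  sl <- simulate_streamlines(g, tr_null, "F", 1000, seed = 8, model = model)
  expect_equal(nrow(sl$endpoints), 1000)
  # every endpoint lies inside the grey-matter mask
  for (cols in list(1:3, 4:6)) {
    idx <- hubtopo:::vox_index(sl$endpoints[, cols], g$shape)
    expect_true(all(g$mask[idx]))
  }

  # identical seeds give identical draws; with unit multipliers the sexes
  # draw from the same distribution, so the draws coincide exactly
  sl_f <- simulate_streamlines(g, tr_null, "F", 500, seed = 9, model = model)
  sl_m <- simulate_streamlines(g, tr_null, "M", 500, seed = 9, model = model)
  expect_identical(sl_f$endpoints, sl_m$endpoints)

  # the male count multiplier scales the endpoint list length
  tr_eff <- make_ground_truth(
    g, n_zone_pairs = 2, zone_radius_mm = 5, min_separation_mm = 10,
    sex_effects = c(female_bc_multiplier = 1.5, male_degree_multiplier = 1.2),
    seed = 3)
  m2 <- build_streamline_model(g, tr_eff)
  sl_m2 <- simulate_streamlines(g, tr_eff, "M", 1000, seed = 9, model = m2)
  expect_equal(nrow(sl_m2$endpoints), 1200)
})

test_that("with no bridges, planted modules stay more wired within than across", {
  # two provincial zones, no connector bridges, background suppressed across
  # the midline: cross-module edges should almost always be fewer
  g <- make_brain_grid(c(12, 14, 12))
  tr <- make_ground_truth(
    g, n_zone_pairs = 1, zone_radius_mm = 6, prop_provincial = 1,
    n_lateralized = 0L, jitter_vox = 0L, seed = 5)
  expect_true(all(tr$zones$kind == "provincial_hub"))
  model <- build_streamline_model(g, tr, p_bridge = 0)
  hemi <- hubtopo:::grid_hemi_vec(g)

  hits <- vapply(1:100, function(s) {
    sl <- simulate_streamlines(g, tr, "F", 300, seed = 1000 + s, model = model)
    ha <- hemi[match(hubtopo:::vox_index(sl$endpoints[, 1:3], g$shape), g$gm_idx)]
    hb <- hemi[match(hubtopo:::vox_index(sl$endpoints[, 4:6], g$shape), g$gm_idx)]
    sum(ha != hb) < sum(ha == hb)
  }, TRUE)
  expect_gte(mean(hits), 0.99)
})

test_that("cohorts are reproducible with planted volume effects", {
  g <- make_brain_grid(c(14, 16, 14))
  tr <- make_ground_truth(g, n_zone_pairs = 2, zone_radius_mm = 5,
                          min_separation_mm = 10, seed = 3)
  model <- build_streamline_model(g, tr)

  co <- make_cohort(g, tr, n_female = 4, n_male = 3, n_streamlines = 200,
                    seed = 11, model = model)
  expect_length(co, 7)
  expect_equal(vapply(co, `[[`, "", "sex"), c(rep("F", 4), rep("M", 3)))

  co2 <- make_cohort(g, tr, n_female = 4, n_male = 3, n_streamlines = 200,
                     seed = 11, model = model)
  expect_identical(co, co2)

  expect_error(make_cohort(g, tr, 0, 1, 100, model = model), "at least 2")

  # volume effect off -> same distribution for both sexes (check determinism
  # of the generating quantiles by symmetry of construction)
  vols <- replicate(30, {
    s <- sample.int(1e6, 1)
    co <- make_cohort(g, tr, 10, 10, 10, seed = s, volume_effect = 0,
                      model = model)
    v <- vapply(co, `[[`, 0, "brain_volume")
    mean(v[1:10]) - mean(v[11:20])
  })
  expect_lt(abs(mean(vols)) / stats::sd(vols) * sqrt(30), 3)

  # with the effect on, female volumes are lower on average
  co <- make_cohort(g, tr, 15, 15, 10, seed = 2, volume_effect = 1,
                    model = model)
  v <- vapply(co, `[[`, 0, "brain_volume")
  expect_lt(mean(v[1:15]), mean(v[16:30]))
})

test_that("default-parameter connectomes land near the printed density and are right-skewed", {
  cfg <- demo_config("medium", seed = 3)
  g <- make_brain_grid(cfg$grid_shape, cfg$voxel_size_mm)
  tr <- make_ground_truth(g, n_zone_pairs = cfg$n_zone_pairs,
                          zone_radius_mm = cfg$zone_radius_mm,
                          prop_provincial = cfg$prop_provincial,
                          min_separation_mm = cfg$zone_min_sep_mm,
                          seed = cfg$seed)
  model <- build_streamline_model(g, tr)
  cohort <- make_cohort(g, tr, 5, 5, cfg$n_streamlines, seed = cfg$seed,
                        model = model)
  parc <- parcellate_grid(g, cfg$K_per_hemisphere, seed = 17)
  dens <- vapply(cohort, function(su) {
    connectome_density(make_connectome(su$streamlines, parc, g)$adjacency)
  }, 0)
  expect_true(abs(mean(dens) - 0.0977) < 0.02)

  cn <- make_connectome(cohort[[1]]$streamlines, parc, g)
  deg <- node_degree(cn$adjacency)
  skew <- mean((deg - mean(deg))^3) / stats::sd(deg)^3
  expect_gt(skew, 0)

  # whole-brain small-world regime for synthetic connectomes
  sigmas <- vapply(cohort[1:3], function(su) {
    cn <- make_connectome(su$streamlines, parc, g)
    small_world_sigma(cn$adjacency, n_null = 3, seed = 21)$sigma
  }, 0)
  expect_true(all(sigmas > 1))
})
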