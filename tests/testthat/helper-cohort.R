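# End-to-end cohort runners at the frozen validation scales, mirroring the
# pipeline stage chain in memory (per-subject parcellation ensembles).

# effects = FALSE builds the fully symmetric null cohort: sex, volume and
# lateralization effects off AND exact mirror placement (no zone jitter),
# so left and right are exchangeable by construction.
run_cohort_analysis <- function(cfg, effects = TRUE) {
  sex_eff <- if (effects)
    c(female_bc_multiplier = cfg$female_bc_multiplier,
      male_degree_multiplier = cfg$male_degree_multiplier)
  else c(female_bc_multiplier = 1, male_degree_multiplier = 1)

  g <- make_brain_grid(cfg$grid_shape, cfg$voxel_size_mm)
  tr <- make_ground_truth(
    g, n_zone_pairs = cfg$n_zone_pairs, zone_radius_mm = cfg$zone_radius_mm,
    sex_effects = sex_eff, prop_provincial = cfg$prop_provincial,
    n_lateralized = if (effects) cfg$n_lateralized else 0L,
    lateralization_strength = cfg$lateralization_strength,
    jitter_vox = if (effects) cfg$jitter_vox else 0L,
    min_separation_mm = cfg$zone_min_sep_mm,
    seed = cfg$seed)
  model <- build_streamline_model(
    g, tr, lambda_mm = cfg$lambda_mm, p_provincial = cfg$p_provincial,
    p_bridge = cfg$p_bridge,
    cross_hemisphere_penalty = cfg$cross_hemisphere_penalty,
      heterogeneity_sd = cfg$background_heterogeneity_sd)
  cohort <- make_cohort(g, tr, cfg$n_female, cfg$n_male, cfg$n_streamlines,
                        seed = cfg$seed,
                        volume_effect = if (effects) cfg$volume_effect else 0,
                        model = model)

  maps <- list(betweenness = list(), degree = list())
  dens <- c()
  for (s in seq_along(cohort)) {
    ens <- ensemble_parcellate(g, cfg$K_per_hemisphere, cfg$P_parcellations,
                               master_seed = cfg$seed + 131L * s)
    cns <- lapply(ens$parcellations, function(p)
      make_connectome(cohort[[s]]$streamlines, p, g))
    dens <- c(dens, vapply(cns, function(cn)
      connectome_density(cn$adjacency), 0))
    nms <- lapply(cns, compute_node_metrics)
    for (met in c("betweenness", "degree"))
      maps[[met]][[cohort[[s]]$subject_id]] <-
        smooth_map(voxel_average_map(ens, nms, met, g), cfg$fwhm_mm, g)
  }

  group_bc <- group_average(maps$betweenness)
  regions <- define_hub_regions(group_bc, percentile = cfg$hub_percentile,
                                min_voxels = cfg$min_region_voxels, grid = g)
  man <- cohort_manifest(cohort)
  scores <- rbind(score_hubs(maps$betweenness, regions, man),
                  score_hubs(maps$degree, regions, man))
  list(grid = g, truth = tr, maps = maps, group_bc = group_bc,
       regions = regions, manifest = man, scores = scores,
       density = mean(dens))
}
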