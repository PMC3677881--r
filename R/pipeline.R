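## End-to-end orchestration: simulate -> parcellate -> connect -> metrics ->
## hubmap -> stats, with stage-level resume and a machine-readable run
## manifest.

pipeline_stages <- c("simulate", "parcellate", "connect", "metrics",
                     "hubmap", "stats")

stage_files <- function(cfg, out_dir) {
  subj_ids <- sprintf("sub-%03d", seq_len(cfg$n_female + cfg$n_male))
  members <- sprintf("member-%02d", seq_len(cfg$P_parcellations))
  f <- function(...) file.path(out_dir, ...)
  list(
    simulate = c(f("grid.nii.gz"), f("truth.json"), f("config.yaml"),
                 f("manifest.csv"),
                 f("streamlines", paste0(subj_ids, ".tsv"))),
    parcellate = c(
      f("parcellations",
        paste0(rep(subj_ids, each = length(members)), "_",
               rep(members, length(subj_ids)), ".nii.gz")),
      f("parcellations",
        paste0(rep(subj_ids, each = length(members)), "_",
               rep(members, length(subj_ids)), ".json"))),
    connect = f("connectomes",
                paste0(rep(subj_ids, each = length(members)), "_",
                       rep(members, length(subj_ids)), ".tsv")),
    metrics = c(f("metrics",
                  paste0(rep(subj_ids, each = length(members)), "_",
                         rep(members, length(subj_ids)), ".csv")),
                f("metrics", "sigma_profiles.csv")),
    hubmap = c(f("hubmaps", paste0(subj_ids, "_degree.nii.gz")),
               f("hubmaps", paste0(subj_ids, "_betweenness.nii.gz")),
               f("hubmaps", "group_degree.nii.gz"),
               f("hubmaps", "group_betweenness.nii.gz"),
               f("hubmaps", "regions.nii.gz"),
               f("hubmaps", "scores.csv"),
               f("hubmaps", "scores_symmetrized.csv")),
    stats = c(f("stats", "gender_tests.csv"),
              f("stats", "gender_directions.json"),
              f("stats", "smallworld.json"),
              f("stats", "size_bias.json"))
  )
}

#' Run the full hub-mapping pipeline
#'
#' Executes every stage on a synthetic cohort defined by the configuration:
#' cohort simulation, the random parcellation ensemble, streamline-count
#' connectomes, node metrics and small-world profiles, topographic hub maps
#' with hub-region extraction and scoring, and the statistical suites. All
#' artifacts are written under `out_dir` in their standard formats, and a
#' run manifest (`run_manifest.json`) records the effective configuration
#' and an MD5 checksum per file. Every random draw derives from
#' `config$seed`, so a rerun with the same configuration reproduces every
#' table byte for byte.
#'
#' With `resume = TRUE`, stages whose output files are all present are
#' skipped and execution restarts at the first incomplete stage (everything
#' downstream of it is regenerated).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param resume skip completed stages.
#' @return invisibly, the run manifest list.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("streamlines", "parcellations", "connectomes", "metrics",
              "hubmaps", "stats"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)

  files <- stage_files(cfg, out_dir)
  done <- vapply(files, function(fs) all(file.exists(fs)), TRUE)
  first <- if (resume) {
    incomplete <- which(!done)
    if (!length(incomplete)) length(pipeline_stages) + 1L else min(incomplete)
  } else 1L
  run_stage <- function(i) i >= first

  subj_ids <- sprintf("sub-%03d", seq_len(cfg$n_female + cfg$n_male))
  members <- sprintf("member-%02d", seq_len(cfg$P_parcellations))

  ## ---- stage 1: simulate -------------------------------------------------
  if (run_stage(1L)) {
    message("[simulate] grid, ground truth and cohort")
    grid <- make_brain_grid(cfg$grid_shape, cfg$voxel_size_mm, seed = cfg$seed)
    truth <- make_ground_truth(
      grid, n_zone_pairs = cfg$n_zone_pairs,
      sex_effects = c(female_bc_multiplier = cfg$female_bc_multiplier,
                      male_degree_multiplier = cfg$male_degree_multiplier),
      density_target = cfg$density_target,
      zone_radius_mm = cfg$zone_radius_mm,
      prop_provincial = cfg$prop_provincial,
      n_lateralized = cfg$n_lateralized,
      lateralization_strength = cfg$lateralization_strength,
      jitter_vox = cfg$jitter_vox,
      min_separation_mm = cfg$zone_min_sep_mm, seed = cfg$seed
    )
    model <- build_streamline_model(
      grid, truth, lambda_mm = cfg$lambda_mm,
      p_provincial = cfg$p_provincial, p_bridge = cfg$p_bridge,
      cross_hemisphere_penalty = cfg$cross_hemisphere_penalty,
      heterogeneity_sd = cfg$background_heterogeneity_sd)
    cohort <- make_cohort(grid, truth, cfg$n_female, cfg$n_male,
                          cfg$n_streamlines, seed = cfg$seed,
                          volume_effect = cfg$volume_effect,
                          volume_cv = cfg$volume_cv, model = model)
    write_brain_grid(grid, file.path(out_dir, "grid.nii.gz"))
    write_ground_truth(truth, file.path(out_dir, "truth.json"))
    write_config(unclass(cfg), file.path(out_dir, "config.yaml"))
    sl_files <- file.path("streamlines", paste0(subj_ids, ".tsv"))
    for (s in seq_along(cohort))
      write_streamlines(cohort[[s]]$streamlines,
                        file.path(out_dir, sl_files[s]))
    manifest <- cohort_manifest(cohort, sl_files)
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  } else {
    grid <- read_brain_grid(file.path(out_dir, "grid.nii.gz"))
    truth <- read_ground_truth(file.path(out_dir, "truth.json"))
    manifest <- read_manifest(file.path(out_dir, "manifest.csv"))
  }

  read_cohort_streamlines <- function() {
    lapply(seq_len(nrow(manifest)), function(s)
      read_streamlines(file.path(out_dir, manifest$streamline_file[s]),
                       subject_id = manifest$subject_id[s]))
  }

  ## ---- stage 2: parcellate -----------------------------------------------
  ## every subject gets its own random parcellation ensemble (the template-
  ## free design: each brain is parcelled P times independently)
  parc_path <- function(s, p) file.path(out_dir, "parcellations",
                                        paste0(subj_ids[s], "_", members[p],
                                               ".nii.gz"))
  if (run_stage(2L)) {
    message("[parcellate] ", nrow(manifest), " subjects x ",
            cfg$P_parcellations, " random parcellations, K = ",
            cfg$K_per_hemisphere)
    ensembles <- lapply(seq_len(nrow(manifest)), function(s) {
      ens <- ensemble_parcellate(grid, cfg$K_per_hemisphere,
                                 cfg$P_parcellations,
                                 master_seed = cfg$seed + 131L * s)
      for (p in seq_len(cfg$P_parcellations))
        write_parcellation(ens$parcellations[[p]], grid, parc_path(s, p))
      ens
    })
  } else {
    ensembles <- lapply(seq_len(nrow(manifest)), function(s) {
      parcs <- lapply(seq_len(cfg$P_parcellations), function(p)
        read_parcellation(parc_path(s, p), grid))
      structure(list(parcellations = parcs, K = cfg$K_per_hemisphere,
                     P = cfg$P_parcellations,
                     seeds = vapply(parcs, `[[`, 0L, "seed")),
                class = "parcellation_ensemble")
    })
  }

  ## ---- stage 3: connect --------------------------------------------------
  conn_path <- function(s, p) file.path(out_dir, "connectomes",
                                        paste0(subj_ids[s], "_", members[p],
                                               ".tsv"))
  if (run_stage(3L)) {
    message("[connect] ", nrow(manifest) * cfg$P_parcellations,
            " connectomes")
    streams <- read_cohort_streamlines()
    connectomes <- lapply(seq_len(nrow(manifest)), function(s) {
      lapply(seq_len(cfg$P_parcellations), function(p) {
        cn <- make_connectome(streams[[s]],
                              ensembles[[s]]$parcellations[[p]],
                              grid, subject_id = manifest$subject_id[s],
                              threshold = cfg$connection_threshold)
        write_connectome(cn, conn_path(s, p))
        cn
      })
    })
  } else {
    connectomes <- lapply(seq_len(nrow(manifest)), function(s)
      lapply(seq_len(cfg$P_parcellations), function(p)
        read_connectome(conn_path(s, p))))
  }

  ## ---- stage 4: metrics --------------------------------------------------
  metr_path <- function(s, p) file.path(out_dir, "metrics",
                                        paste0(subj_ids[s], "_", members[p],
                                               ".csv"))
  if (run_stage(4L)) {
    message("[metrics] node metrics and small-world profiles")
    node_metrics <- lapply(seq_len(nrow(manifest)), function(s)
      lapply(seq_len(cfg$P_parcellations), function(p) {
        nm <- compute_node_metrics(connectomes[[s]][[p]])
        utils::write.csv(nm, metr_path(s, p), row.names = FALSE)
        nm
      }))
    profiles <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(s) {
      pr <- subject_sigma_profile(connectomes[[s]], n_null = cfg$n_null,
                                  seed = cfg$seed + 7L * s,
                                  swaps_per_edge = cfg$swaps_per_edge,
                                  null_model = cfg$null_model)
      data.frame(subject_id = manifest$subject_id[s],
                 sigma_whole = pr$sigma_whole, sigma_lh = pr$sigma_lh,
                 sigma_rh = pr$sigma_rh, delta = pr$delta,
                 stringsAsFactors = FALSE)
    }))
    write_sigma_profiles(profiles, file.path(out_dir, "metrics",
                                             "sigma_profiles.csv"))
  } else {
    node_metrics <- lapply(seq_len(nrow(manifest)), function(s)
      lapply(seq_len(cfg$P_parcellations), function(p)
        utils::read.csv(metr_path(s, p), stringsAsFactors = FALSE)))
    profiles <- read_sigma_profiles(file.path(out_dir, "metrics",
                                              "sigma_profiles.csv"))
  }

  ## ---- stage 5: hubmap ---------------------------------------------------
  if (run_stage(5L)) {
    message("[hubmap] topographic maps, regions and scores")
    subject_maps <- list(degree = list(), betweenness = list())
    for (s in seq_len(nrow(manifest))) {
      for (metric in c("degree", "betweenness")) {
        m <- voxel_average_map(ensembles[[s]], node_metrics[[s]], metric, grid)
        m <- smooth_map(m, cfg$fwhm_mm, grid)
        subject_maps[[metric]][[manifest$subject_id[s]]] <- m
        write_hub_map(m, file.path(out_dir, "hubmaps",
                                   paste0(manifest$subject_id[s], "_",
                                          metric, ".nii.gz")))
      }
    }
    group_maps <- lapply(subject_maps, group_average)
    for (metric in names(group_maps))
      write_hub_map(group_maps[[metric]],
                    file.path(out_dir, "hubmaps",
                              paste0("group_", metric, ".nii.gz")))
    ## regions from the betweenness map; both metrics scored on them
    regions <- define_hub_regions(group_maps$betweenness,
                                  percentile = cfg$hub_percentile,
                                  min_voxels = cfg$min_region_voxels,
                                  grid = grid)
    write_hub_regions(regions, grid,
                      file.path(out_dir, "hubmaps", "regions.nii.gz"))
    scores <- rbind(
      score_hubs(subject_maps$betweenness, regions, manifest),
      score_hubs(subject_maps$degree, regions, manifest)
    )
    write_scores(scores, file.path(out_dir, "hubmaps", "scores.csv"))
    ## hemispheric comparisons read scores from mirror-symmetrized pair
    ## regions so left and right scores come from corresponding voxel sets
    pairs <- pair_regions(regions, grid,
                          max_peak_dist_mm = cfg$pair_max_dist_mm)
    scores_sym <- if (nrow(pairs)) {
      sym <- symmetrize_regions(regions, pairs, grid)
      rbind(score_hubs(subject_maps$betweenness, sym, manifest),
            score_hubs(subject_maps$degree, sym, manifest))
    } else scores[0, ]
    write_scores(scores_sym,
                 file.path(out_dir, "hubmaps", "scores_symmetrized.csv"))
  } else {
    regions <- read_hub_regions(file.path(out_dir, "hubmaps",
                                          "regions.nii.gz"), grid)
    scores <- read_scores(file.path(out_dir, "hubmaps", "scores.csv"))
    scores_sym <- read_scores(file.path(out_dir, "hubmaps",
                                        "scores_symmetrized.csv"))
  }

  ## ---- stage 6: stats ----------------------------------------------------
  if (run_stage(6L)) {
    message("[stats] asymmetry, sex differences, small-world analysis")
    pairs <- pair_regions(regions, grid,
                          max_peak_dist_mm = cfg$pair_max_dist_mm)
    if (nrow(pairs) && nrow(scores_sym)) {
      asym <- asymmetry_suite(scores_sym, pairs)
      utils::write.csv(asym, file.path(out_dir, "stats", "asymmetry.csv"),
                       row.names = FALSE)
    }
    gen <- gender_suite(scores)
    utils::write.csv(gen$tests, file.path(out_dir, "stats",
                                          "gender_tests.csv"),
                     row.names = FALSE)
    jsonlite::write_json(gen$directions,
                         file.path(out_dir, "stats", "gender_directions.json"),
                         auto_unbox = TRUE, digits = NA)
    sw <- smallworld_suite(profiles, manifest)
    jsonlite::write_json(sw, file.path(out_dir, "stats", "smallworld.json"),
                         auto_unbox = TRUE, digits = NA)
    bias <- size_bias_diagnostic(
      do.call(c, lapply(ensembles, `[[`, "parcellations")),
      do.call(c, node_metrics)
    )
    jsonlite::write_json(bias, file.path(out_dir, "stats", "size_bias.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## ---- run manifest ------------------------------------------------------
  all_files <- sort(unname(unlist(stage_files(cfg, out_dir))))
  all_files <- all_files[file.exists(all_files)]
  manifest_json <- list(
    package = "hubtopo",
    config = unclass(cfg),
    stages = pipeline_stages,
    files = data.frame(
      path = sub(paste0("^", out_dir, "/?"), "", all_files),
      md5 = unname(tools::md5sum(all_files)),
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(manifest_json,
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest_json)
}
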