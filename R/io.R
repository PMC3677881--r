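## Round-trip readers and writers for every pipeline artifact.
## Volumes are NIfTI-1; tables are TSV/CSV; configs and sidecars are
## YAML/JSON. Voxel indices are 0-based everywhere; voxel size travels in
## the NIfTI header.

write_nifti_vol <- function(arr, path, voxel_size_mm, datatype = "auto") {
  attr(arr, "pixdim") <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = datatype), path)
  invisible(path)
}

#' Write / read a brain grid as a NIfTI label volume
#'
#' Labels: 0 = background, 1 = left grey matter, 2 = right grey matter.
#' @param grid a [make_brain_grid()] object.
#' @param path output `.nii.gz` path.
#' @export
write_brain_grid <- function(grid, path) {
  write_nifti_vol(grid$hemisphere, path, grid$voxel_size_mm,
                  datatype = "int16")
}

#' @rdname write_brain_grid
#' @export
read_brain_grid <- function(path) {
  img <- RNifti::readNifti(path)
  hemi <- array(as.integer(as.array(img)), dim = dim(img))
  mask <- hemi > 0L
  gm_idx <- which(mask)
  structure(
    list(shape = dim(hemi), voxel_size_mm = RNifti::pixdim(img)[1],
         mask = mask, hemisphere = hemi, gm_idx = gm_idx,
         coords = index_vox(gm_idx, dim(hemi)), seed = NA_integer_),
    class = "brain_grid"
  )
}

#' Write / read ground truth as JSON
#' @param truth a [make_ground_truth()] object.
#' @param path output `.json` path.
#' @export
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  x$sex_effects <- as.list(x$sex_effects)  # keep names through JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$zones <- as.data.frame(x$zones, stringsAsFactors = FALSE)
  x$sex_effects <- unlist(x$sex_effects)
  x$lateralized_pairs <- as.integer(x$lateralized_pairs)
  structure(x, class = "ground_truth")
}

#' Write / read streamline endpoints as TSV
#'
#' Columns `xa,ya,za,xb,yb,zb`: 0-based integer voxel indices, one row per
#' streamline (repeats encode fibre count).
#' @param streamlines a `streamline_set`.
#' @param path output `.tsv` path.
#' @export
write_streamlines <- function(streamlines, path) {
  utils::write.table(streamlines$endpoints, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_streamlines
#' @param subject_id id to attach on read.
#' @export
read_streamlines <- function(path, subject_id = NA_character_) {
  ep <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  storage.mode(ep) <- "integer"
  structure(list(endpoints = ep, subject_id = subject_id),
            class = "streamline_set")
}

#' Write / read the cohort manifest CSV
#' @param manifest a [cohort_manifest()] data frame.
#' @param path output `.csv` path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  # "F" alone would otherwise parse as logical FALSE
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sex = "character"))
}

#' Write / read a parcellation (NIfTI labels + JSON sidecar)
#' @param parcellation a [parcellate_grid()] object.
#' @param grid its grid.
#' @param path output `.nii.gz` path; the sidecar replaces the extension
#'   with `.json`.
#' @export
write_parcellation <- function(parcellation, grid, path) {
  write_nifti_vol(gm_to_array(grid, parcellation$labels, fill = 0L), path,
                  grid$voxel_size_mm, datatype = "int32")
  side <- sidecar_path(path)
  jsonlite::write_json(
    list(format_version = 1L,
         K_per_hemisphere = parcellation$K_per_hemisphere,
         seed = parcellation$seed, settings = parcellation$settings),
    side, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path, grid) {
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (is.null(side$format_version) || side$format_version != 1L)
    stop("version-mismatched parcellation sidecar: ", sidecar_path(path))
  vol <- as.array(RNifti::readNifti(path))
  labels <- as.integer(vol[grid$gm_idx])
  K <- as.integer(side$K_per_hemisphere)
  structure(
    list(labels = labels, K_per_hemisphere = K,
         seed = as.integer(side$seed),
         roi_hemisphere = rep(c("left", "right"), each = K),
         roi_centroid = centroids_of(grid_coords_mm(grid), labels, 2L * K),
         roi_volume_voxels = tabulate(labels, nbins = 2L * K),
         settings = side$settings),
    class = "parcellation"
  )
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write / read a connectome (TSV edge list + JSON sidecar)
#'
#' The TSV lists `roi_a, roi_b, count` for `roi_a < roi_b` with positive
#' counts; the sidecar carries node count, hemisphere labels and provenance
#' so the full matrices can be rebuilt on read.
#' @param connectome a [make_connectome()] object.
#' @param path output `.tsv` path.
#' @export
write_connectome <- function(connectome, path) {
  W <- connectome$weights
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- data.frame(roi_a = ut[, 1], roi_b = ut[, 2],
                      count = W[ut])
  edges <- edges[order(edges$roi_a, edges$roi_b), ]
  utils::write.table(edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(
    list(format_version = 1L, n_nodes = nrow(W),
         node_hemisphere = connectome$node_hemisphere,
         parcellation_seed = connectome$parcellation_seed,
         subject_id = connectome$subject_id,
         threshold = connectome$threshold,
         drop_log = connectome$drop_log),
    side, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  side <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                              simplifyVector = TRUE)
  if (is.null(side$format_version) || side$format_version != 1L)
    stop("version-mismatched connectome sidecar for ", path)
  edges <- utils::read.table(path, header = TRUE, sep = "\t")
  N <- as.integer(side$n_nodes)
  W <- matrix(0L, N, N)
  if (nrow(edges)) {
    W[cbind(edges$roi_a, edges$roi_b)] <- as.integer(edges$count)
    W[cbind(edges$roi_b, edges$roi_a)] <- as.integer(edges$count)
  }
  structure(
    list(weights = W, adjacency = binarize(W, side$threshold %||% 1L),
         node_hemisphere = side$node_hemisphere,
         parcellation_seed = side$parcellation_seed,
         subject_id = side$subject_id,
         threshold = as.integer(side$threshold %||% 1L),
         drop_log = side$drop_log),
    class = "connectome"
  )
}

#' Write / read a hub map (NIfTI float volume + JSON sidecar)
#' @param map a `hub_map`.
#' @param path output `.nii.gz` path.
#' @export
write_hub_map <- function(map, path) {
  write_nifti_vol(gm_to_array(map$grid, map$values), path,
                  map$grid$voxel_size_mm, datatype = "double")
  jsonlite::write_json(
    list(format_version = 1L, metric = map$metric, level = map$level,
         smoothing_fwhm_mm = map$smoothing_fwhm_mm),
    sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hub_map
#' @param grid the grid the map lives on.
#' @export
read_hub_map <- function(path, grid) {
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (is.null(side$format_version) || side$format_version != 1L)
    stop("version-mismatched hub-map sidecar for ", path)
  vol <- as.array(RNifti::readNifti(path))
  new_hub_map(vol[grid$gm_idx], side$metric, side$level,
              side$smoothing_fwhm_mm, grid)
}

#' Write / read hub regions (NIfTI label volume + JSON)
#' @param regions output of [define_hub_regions()].
#' @param grid the grid.
#' @param path output `.nii.gz` path.
#' @export
write_hub_regions <- function(regions, grid, path) {
  lab <- integer(length(grid$gm_idx))
  for (r in regions) lab[r$voxel_rows] <- r$region_id
  write_nifti_vol(gm_to_array(grid, lab, fill = 0L), path,
                  grid$voxel_size_mm, datatype = "int32")
  meta <- lapply(regions, function(r)
    list(region_id = r$region_id, hemisphere = r$hemisphere,
         peak_voxel = as.integer(r$peak_voxel), peak_value = r$peak_value,
         n_voxels = r$n_voxels))
  jsonlite::write_json(
    list(format_version = 1L, threshold = attr(regions, "threshold"),
         percentile = attr(regions, "percentile"), regions = meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hub_regions
#' @export
read_hub_regions <- function(path, grid) {
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = FALSE)
  if (is.null(side$format_version) || side$format_version != 1L)
    stop("version-mismatched hub-region sidecar for ", path)
  vol <- as.array(RNifti::readNifti(path))
  lab <- as.integer(vol[grid$gm_idx])
  regions <- lapply(side$regions, function(m) {
    rows <- which(lab == m$region_id)
    structure(
      list(voxel_rows = rows, coords = grid$coords[rows, , drop = FALSE],
           hemisphere = m$hemisphere,
           peak_voxel = as.integer(unlist(m$peak_voxel)),
           peak_value = m$peak_value, n_voxels = m$n_voxels,
           region_id = m$region_id),
      class = "hub_region")
  })
  attr(regions, "threshold") <- side$threshold
  attr(regions, "percentile") <- side$percentile
  regions
}

#' Write / read hub-score tables as CSV
#' @param scores a [score_hubs()] data frame.
#' @param path output `.csv`.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sex = "character"))
}

#' Write / read per-subject small-world profiles as CSV
#' @param profiles data frame of per-subject sigma indices.
#' @param path output `.csv`.
#' @export
write_sigma_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sigma_profiles
#' @export
read_sigma_profiles <- function(path) utils::read.csv(path,
                                                      stringsAsFactors = FALSE)

#' Write / read a pipeline configuration as YAML
#' @param config a validated configuration list.
#' @param path output `.yaml`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}
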