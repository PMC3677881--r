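#' Precompute the generative streamline model for a grid + ground truth
#'
#' The generator is an inhomogeneous random multigraph over grey-matter
#' voxels: each streamline is an i.i.d. draw of an unordered voxel pair from a
#' mixture of three components,
#' \itemize{
#'   \item background: rate `exp(-d/lambda)` decaying with inter-voxel
#'     distance `d` (short-range, lattice-like connectivity),
#'   \item provincial: dense within-zone wiring inside provincial hub zones,
#'   \item bridge: long-range streamlines linking every pair of connector hub
#'     zones (the shortcuts that give connector zones high betweenness).
#' }
#' Zone kernels are Gaussian in distance to the zone centre
#' (`sigma = zone_radius / 2`); a lateralized zone's kernel is scaled by its
#' rate multiplier. The expensive part (pair enumeration) depends only on grid
#' and truth, so the model is built once per cohort and reused by every
#' subject.
#'
#' @param grid a [make_brain_grid()] object.
#' @param truth a [make_ground_truth()] object.
#' @param lambda_mm background connectivity decay length (mm).
#' @param p_provincial,p_bridge mixture mass of the provincial and bridge
#'   components (background takes the remainder).
#' @param cross_hemisphere_penalty factor applied to the background rate of
#'   voxel pairs straddling the midline. Interhemispheric background wiring
#'   is kept sparse (callosal connections are far rarer than short
#'   association fibres), so long-range interhemispheric traffic routes
#'   through the planted connector bridges.
#' @param heterogeneity_sd log-scale standard deviation of an optional smooth
#'   multiplicative gain field on the background rate (0, the default,
#'   disables it). Regional heterogeneity weakens the coupling between ROI
#'   degree and ROI volume, but strong fields plant spurious betweenness
#'   peaks at reduced scales, so it is opt-in.
#' @param heterogeneity_smooth_vox Gaussian smoothing (voxels) of the gain
#'   field's white-noise seed, i.e. its correlation length.
#' @return An object of class `streamline_model`.
#' @export
build_streamline_model <- function(grid, truth,
                                   lambda_mm = 6,
                                   p_provincial = 0.10,
                                   p_bridge = 0.15,
                                   cross_hemisphere_penalty = 0.05,
                                   heterogeneity_sd = 0,
                                   heterogeneity_smooth_vox = 2) {
  stopifnot(inherits(grid, "brain_grid"), inherits(truth, "ground_truth"))
  n <- nrow(grid$coords)
  assert_that(n >= 2L, "empty or degenerate grey-matter mask")
  cmm <- grid_coords_mm(grid)

  ## background: all unordered voxel pairs. The weight vector is filled in
  ## blocks so that only O(block) temporaries exist at any time (the pair
  ## count is ~n^2/2 and a full-vector expression would transiently hold
  ## several copies).
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  hemi <- grid_hemi_vec(grid)
  gain <- if (heterogeneity_sd > 0)
    background_gain_field(grid, heterogeneity_sd, heterogeneity_smooth_vox,
                          seed = truth$seed + 7919L)
  else rep(1, n)
  ## a lateralized zone has stronger local connectivity overall, not just in
  ## its bridges: its rate multiplier also scales the background around it
  gain <- gain * lateral_gain_field(grid, truth)
  npair <- length(i)
  w <- numeric(npair)
  block <- 5e6L
  for (start in seq(1L, npair, by = block)) {
    idx <- start:min(start + block - 1L, npair)
    bi <- i[idx]; bj <- j[idx]
    d <- sqrt((cmm[bi, 1] - cmm[bj, 1])^2 + (cmm[bi, 2] - cmm[bj, 2])^2 +
                (cmm[bi, 3] - cmm[bj, 3])^2)
    wb <- exp(-d / lambda_mm) * gain[bi] * gain[bj]
    cross <- hemi[bi] != hemi[bj]
    wb[cross] <- wb[cross] * cross_hemisphere_penalty
    w[idx] <- wb
  }
  bg <- list(i = i, j = j, cw = cumsum(w))
  rm(i, j, w)

  zones <- truth$zones
  sigma <- truth$zone_radius_mm / 2
  ball <- lapply(seq_len(nrow(zones)), function(z)
    zone_ball_rows(grid, unlist(zones[z, c("cx", "cy", "cz")]),
                   truth$zone_radius_mm))
  ## kernels are normalized to unit mass before the rate multiplier, so every
  ## zone receives an equal fibre budget even when its ball is cropped by the
  ## mask boundary; the multiplier then plants the lateralization effect
  kern <- lapply(seq_len(nrow(zones)), function(z) {
    ctr <- unlist(zones[z, c("cx", "cy", "cz")]) * grid$voxel_size_mm
    d <- sqrt(rowSums((cmm[ball[[z]], , drop = FALSE] -
                         matrix(ctr, length(ball[[z]]), 3, byrow = TRUE))^2))
    k <- exp(-d^2 / (2 * sigma^2))
    zones$rate_multiplier[z] * k / sum(k)
  })

  ## provincial: pairs with both endpoints inside one provincial zone
  prov_idx <- which(zones$kind == "provincial_hub")
  pi <- pj <- integer(0); pw <- numeric(0)
  for (z in prov_idx) {
    b <- ball[[z]]; k <- kern[[z]]
    if (length(b) < 2L) next
    ut <- which(upper.tri(matrix(0, length(b), length(b))), arr.ind = TRUE)
    pi <- c(pi, b[ut[, 1]])
    pj <- c(pj, b[ut[, 2]])
    pw <- c(pw, k[ut[, 1]] * k[ut[, 2]])
  }
  provincial <- if (length(pw)) {
    o <- pmin(pi, pj); p <- pmax(pi, pj)
    list(i = o, j = p, cw = cumsum(pw))
  } else NULL

  ## bridge: one endpoint near each of two distinct connector zones
  conn_idx <- which(zones$kind == "connector_hub")
  bi <- bj <- integer(0); bw <- numeric(0)
  if (length(conn_idx) >= 2L) {
    for (a in seq_along(conn_idx)[-length(conn_idx)]) {
      for (b in seq.int(a + 1L, length(conn_idx))) {
        za <- conn_idx[a]; zb <- conn_idx[b]
        u <- rep(ball[[za]], times = length(ball[[zb]]))
        v <- rep(ball[[zb]], each = length(ball[[za]]))
        wk <- rep(kern[[za]], times = length(ball[[zb]])) *
          rep(kern[[zb]], each = length(ball[[za]]))
        keep <- u != v
        bi <- c(bi, pmin(u[keep], v[keep]))
        bj <- c(bj, pmax(u[keep], v[keep]))
        bw <- c(bw, wk[keep])
      }
    }
  }
  bridge <- if (length(bw)) list(i = bi, j = bj, cw = cumsum(bw)) else NULL

  base <- c(background = 1 - p_provincial - p_bridge,
            provincial = if (is.null(provincial)) 0 else p_provincial,
            bridge = if (is.null(bridge)) 0 else p_bridge)
  base <- base / sum(base)

  structure(
    list(
      components = list(background = bg, provincial = provincial,
                        bridge = bridge),
      base_probs = base,
      lambda_mm = lambda_mm,
      p_provincial = p_provincial,
      p_bridge = p_bridge,
      cross_hemisphere_penalty = cross_hemisphere_penalty,
      heterogeneity_sd = heterogeneity_sd,
      n_gm = n
    ),
    class = "streamline_model"
  )
}

## multiplicative background gain around zones whose rate multiplier differs
## from 1 (the planted lateralization): Gaussian bump peaking at the zone's
## multiplier, decaying with distance from the zone centre
lateral_gain_field <- function(grid, truth) {
  glat <- rep(1, nrow(grid$coords))
  zones <- truth$zones
  sigma <- truth$zone_radius_mm / 2
  for (z in which(zones$rate_multiplier != 1)) {
    rows <- zone_ball_rows(grid, unlist(zones[z, c("cx", "cy", "cz")]),
                           truth$zone_radius_mm)
    ctr <- unlist(zones[z, c("cx", "cy", "cz")]) * grid$voxel_size_mm
    d <- sqrt(rowSums((grid_coords_mm(grid)[rows, , drop = FALSE] -
                         matrix(ctr, length(rows), 3, byrow = TRUE))^2))
    glat[rows] <- glat[rows] *
      (1 + (zones$rate_multiplier[z] - 1) * exp(-d^2 / (2 * sigma^2)))
  }
  glat
}

## smooth lognormal gain over grey-matter voxels: white noise on the grid,
## Gaussian-smoothed (sigma 2 voxels) with mask renormalization, rescaled to
## the requested log-sd, exponentiated
background_gain_field <- function(grid, sd_log, smooth_vox = 2, seed = 1L) {
  noise <- with_seed(seed, stats::rnorm(length(grid$gm_idx)))
  V <- gm_to_array(grid, noise)
  M <- array(0, dim = grid$shape)
  M[grid$gm_idx] <- 1
  r <- ceiling(3 * smooth_vox)
  kern <- stats::dnorm(-r:r, sd = smooth_vox)
  kern <- kern / sum(kern)
  for (axis in 1:3) {
    V <- convolve_axis(V, kern, axis)
    M <- convolve_axis(M, kern, axis)
  }
  sm <- V[grid$gm_idx] / M[grid$gm_idx]
  sm <- (sm - mean(sm)) / stats::sd(sm)
  exp(sd_log * sm)
}

#' Simulate a subject's streamline endpoint set
#'
#' Draws `n_streamlines` i.i.d. endpoint pairs from the mixture model of
#' [build_streamline_model()]. Sex modulation follows the planted effects:
#' for female subjects the bridge-component rate is multiplied by
#' `female_bc_multiplier` (raising betweenness at connector zones); for male
#' subjects the total streamline count is multiplied by
#' `male_degree_multiplier` (raising node degree everywhere). With both
#' multipliers at 1 the two sexes draw from identical distributions.
#'
#' @param grid,truth as in [build_streamline_model()].
#' @param subject_sex `"F"` or `"M"`.
#' @param n_streamlines base number of endpoint pairs (before the male count
#'   multiplier).
#' @param seed integer seed; identical inputs give identical streamline sets.
#' @param model optional precomputed [build_streamline_model()] object.
#' @param subject_id identifier stored with the set.
#' @return An object of class `streamline_set`: an `endpoints` integer matrix
#'   with columns `xa,ya,za,xb,yb,zb` (0-based voxel indices) and the subject
#'   id. Repeated rows encode fibre-count multiplicity.
#' @export
simulate_streamlines <- function(grid, truth, subject_sex, n_streamlines,
                                 seed = 1L, model = NULL, subject_id = NA_character_) {
  stopifnot(inherits(grid, "brain_grid"), inherits(truth, "ground_truth"))
  subject_sex <- match.arg(subject_sex, c("F", "M"))
  assert_that(n_streamlines >= 1L, "n_streamlines must be at least 1")
  if (is.null(model)) model <- build_streamline_model(grid, truth)

  probs <- model$base_probs
  n <- n_streamlines
  if (subject_sex == "F") {
    probs["bridge"] <- probs["bridge"] *
      truth$sex_effects[["female_bc_multiplier"]]
    probs <- probs / sum(probs)
  } else {
    n <- round(n * truth$sex_effects[["male_degree_multiplier"]])
  }

  ep <- with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, n, probs))
    rows_a <- integer(n); rows_b <- integer(n)
    pos <- 0L
    for (ci in seq_along(probs)) {
      nc <- counts[ci]
      if (nc == 0L) next
      comp <- model$components[[ci]]
      pick <- sample_from_cw(nc, comp$cw)
      rows_a[(pos + 1L):(pos + nc)] <- comp$i[pick]
      rows_b[(pos + 1L):(pos + nc)] <- comp$j[pick]
      pos <- pos + nc
    }
    perm <- sample.int(n)
    cbind(grid$coords[rows_a[perm], , drop = FALSE],
          grid$coords[rows_b[perm], , drop = FALSE])
  })
  colnames(ep) <- c("xa", "ya", "za", "xb", "yb", "zb")

  structure(list(endpoints = ep, subject_id = subject_id),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %s: %d endpoint pairs\n",
              x$subject_id %||% "?", nrow(x$endpoints)))
  invisible(x)
}

#' Simulate a full cohort of subjects
#'
#' Generates `n_female + n_male` subject records on a shared grid. Per-subject
#' streamline seeds are `seed + subject index`, so subjects are independent
#' and the whole cohort is reproducible from the master seed. Brain volume is
#' the mask volume scaled by a subject factor drawn from a normal
#' distribution whose mean is lower for females (`1 - 0.10 * volume_effect`
#' vs 1 for males); `volume_effect = 0` makes the sexes identical.
#'
#' @param grid,truth shared grid and ground truth.
#' @param n_female,n_male group sizes (default 37 and 26).
#' @param n_streamlines per-subject base streamline count.
#' @param seed master seed.
#' @param volume_effect scales the female volume deficit.
#' @param volume_cv coefficient of variation of the subject volume factor.
#' @param model optional shared [build_streamline_model()].
#' @return list of `subject_record` objects (subject_id, sex, brain_volume in
#'   mm^3, streamlines).
#' @export
make_cohort <- function(grid, truth, n_female = 37L, n_male = 26L,
                        n_streamlines = 20000L, seed = 1L,
                        volume_effect = 1, volume_cv = 0.05, model = NULL) {
  stopifnot(inherits(grid, "brain_grid"), inherits(truth, "ground_truth"))
  n_female <- as.integer(n_female); n_male <- as.integer(n_male)
  if (n_female + n_male < 2L)
    stop("cohort must contain at least 2 subjects")
  if (is.null(model)) model <- build_streamline_model(grid, truth)

  n_sub <- n_female + n_male
  sexes <- c(rep("F", n_female), rep("M", n_male))
  ids <- sprintf("sub-%03d", seq_len(n_sub))

  base_vol <- length(grid$gm_idx) * grid$voxel_size_mm^3
  mean_ratio <- ifelse(sexes == "F", 1 - 0.10 * volume_effect, 1)
  vols <- with_seed(seed, base_vol *
                      stats::rnorm(n_sub, mean = mean_ratio, sd = volume_cv))
  vols <- pmax(vols, 0.5 * base_vol)

  lapply(seq_len(n_sub), function(s) {
    structure(
      list(
        subject_id = ids[s],
        sex = sexes[s],
        brain_volume = vols[s],
        streamlines = simulate_streamlines(grid, truth, sexes[s],
                                           n_streamlines, seed = seed + s,
                                           model = model,
                                           subject_id = ids[s])
      ),
      class = "subject_record"
    )
  })
}

#' Cohort manifest table
#'
#' @param cohort list of subject records from [make_cohort()].
#' @param streamline_files optional file names to record per subject.
#' @return data frame with subject_id, sex, brain_volume and streamline_file.
#' @export
cohort_manifest <- function(cohort, streamline_files = NA_character_) {
  data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    sex = vapply(cohort, `[[`, "", "sex"),
    brain_volume = vapply(cohort, `[[`, 0, "brain_volume"),
    streamline_file = streamline_files,
    stringsAsFactors = FALSE
  )
}
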