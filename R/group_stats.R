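## Statistical layer: hub-score asymmetry and sex-difference tests,
## direction-count binomial tests, multiple-comparison corrections, and the
## small-world group analysis. Pooled-variance (Student) t statistics are
## used throughout because the design's degrees of freedom conventions
## (df = n1 + n2 - 2) require them.

#' Pooled-variance two-sample t-test
#'
#' @param scores_a,scores_b numeric vectors (each at least 2 values).
#' @return list with `statistic` (positive when `mean(a) > mean(b)`), `df`,
#'   `p_two_tailed`, `mean_a`, `mean_b`, `method`.
#' @export
two_sample_t <- function(scores_a, scores_b) {
  assert_that(length(scores_a) >= 2L && length(scores_b) >= 2L,
              "each group needs at least 2 values")
  fit <- tryCatch(
    stats::t.test(scores_a, scores_b, var.equal = TRUE),
    error = function(e) stop("zero pooled variance: t undefined", call. = FALSE)
  )
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_two_tailed = fit$p.value,
       mean_a = mean(scores_a), mean_b = mean(scores_b),
       method = "two-sample t (pooled variance)")
}

#' Bonferroni correction with an explicit family size
#'
#' @param p_values numeric vector of raw p values.
#' @param n family size (defaults to the number of p values).
#' @return adjusted p values, `min(1, p * n)`.
#' @export
bonferroni <- function(p_values, n = length(p_values)) {
  assert_that(n >= 1, "n must be at least 1")
  stats::p.adjust(p_values, method = "bonferroni", n = max(n, length(p_values)))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' @param p_values raw p values in `[0, 1]`.
#' @param q target false discovery rate (default 0.05).
#' @return list with `p_adjusted` (BH step-up) and logical `rejected`
#'   (`p_adjusted < q`).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  assert_that(length(p_values) >= 1L, "empty p-value vector")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, rejected = adj < q)
}

#' Direction count over hub regions
#'
#' @param n_regions number of regions compared.
#' @param n_f_higher number of regions where the female mean exceeds the male
#'   mean.
#' @param metric metric label.
#' @return list of class `direction_count` with the favoured group and the
#'   count of regions going against it.
#' @export
direction_count <- function(n_regions, n_f_higher, metric = NA_character_) {
  assert_that(n_f_higher >= 0 && n_f_higher <= n_regions,
              "invalid direction count")
  favoured <- if (n_f_higher * 2L >= n_regions) "F" else "M"
  n_against <- if (favoured == "F") n_regions - n_f_higher else n_f_higher
  structure(list(n_regions = as.integer(n_regions),
                 n_against = as.integer(n_against),
                 favoured_group = favoured, metric = metric),
            class = "direction_count")
}

#' Exact binomial test on direction counts
#'
#' Under no group difference, the per-region direction indicators are
#' Binomial(n_regions, 1/2); the reported probability is the exact one-sided
#' lower tail `P(X <= n_against)`, Bonferroni-multiplied by `bonferroni_n`
#' (one family per metric) and capped at 1.
#'
#' @param count a [direction_count()] object.
#' @param bonferroni_n family size for the correction (default 2: one test
#'   per metric).
#' @return list with `p_raw`, `p_adjusted` and the count fields.
#' @export
direction_binomial <- function(count, bonferroni_n = 2L) {
  stopifnot(inherits(count, "direction_count"))
  p_raw <- stats::pbinom(count$n_against, count$n_regions, 0.5)
  list(n_regions = count$n_regions, n_against = count$n_against,
       favoured_group = count$favoured_group, metric = count$metric,
       p_raw = p_raw, p_adjusted = min(1, p_raw * bonferroni_n),
       method = sprintf("exact binomial lower tail, Bonferroni n = %d",
                        bonferroni_n))
}

#' Two-tailed Student-t critical value
#'
#' @param df degrees of freedom.
#' @param alpha_two_tailed two-tailed significance level in (0, 1).
#' @return the critical value `t` with `P(|T| > t) = alpha`.
#' @export
t_critical <- function(df, alpha_two_tailed = 0.05) {
  assert_that(df >= 1, "df must be at least 1")
  assert_that(alpha_two_tailed > 0 && alpha_two_tailed < 1,
              "alpha must lie in (0, 1)")
  stats::qt(1 - alpha_two_tailed / 2, df)
}

#' Hemispheric asymmetry tests on hub scores
#'
#' For every bilateral region pair and metric, a pooled two-sample t-test of
#' left vs right subject scores (df = 2 n_subjects - 2; subjects' left and
#' right scores are pooled as independent samples, matching the df
#' convention of the original design), Bonferroni-corrected over the number
#' of bilateral pairs within each metric.
#'
#' @param scores a [score_hubs()] table (possibly row-bound across metrics).
#' @param pairs a [pair_regions()] table.
#' @return data frame with one row per pair x metric: t statistic (positive
#'   when left > right), df, raw and corrected p, and the higher hemisphere.
#' @export
asymmetry_suite <- function(scores, pairs) {
  assert_that(nrow(pairs) >= 1L, "no bilateral pairs available")
  out <- list()
  for (metric in unique(scores$metric)) {
    sm <- scores[scores$metric == metric, ]
    res <- list()
    for (i in seq_len(nrow(pairs))) {
      sl <- sm$score[sm$region_id == pairs$left_id[i]]
      sr <- sm$score[sm$region_id == pairs$right_id[i]]
      if (length(sl) < 2L || length(sr) < 2L) {
        warning(sprintf("pair %d (%s): unpaired or missing scores; skipped",
                        pairs$pair_id[i], metric))
        next
      }
      t <- two_sample_t(sl, sr)
      res[[length(res) + 1L]] <- data.frame(
        metric = metric, pair_id = pairs$pair_id[i],
        left_id = pairs$left_id[i], right_id = pairs$right_id[i],
        statistic = t$statistic, df = t$df, p = t$p_two_tailed,
        higher = if (t$mean_a >= t$mean_b) "left" else "right",
        stringsAsFactors = FALSE
      )
    }
    if (!length(res)) next
    res <- do.call(rbind, res)
    res$p_adjusted <- bonferroni(res$p, n = nrow(pairs))
    res$n_comparisons <- nrow(pairs)
    out[[metric]] <- res
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Sex-difference tests on hub scores
#'
#' Per region and metric, a pooled two-sample t-test of female vs male
#' scores (df = n_F + n_M - 2) with BH false-discovery-rate adjustment
#' across regions within each metric, plus per-metric direction counts fed
#' into the exact binomial test (Bonferroni n = number of metrics).
#'
#' @param scores a [score_hubs()] table with the `sex` column filled.
#' @param q target false discovery rate.
#' @return list with `tests` (per region x metric data frame) and
#'   `directions` (per metric: direction count and binomial p values).
#' @export
gender_suite <- function(scores, q = 0.05) {
  assert_that(all(c("F", "M") %in% scores$sex), "both sexes must be present")
  metrics <- unique(scores$metric)
  tests <- list()
  directions <- list()
  for (metric in metrics) {
    sm <- scores[scores$metric == metric, ]
    res <- list()
    for (rid in sort(unique(sm$region_id))) {
      sf <- sm$score[sm$region_id == rid & sm$sex == "F"]
      sml <- sm$score[sm$region_id == rid & sm$sex == "M"]
      if (length(sf) < 2L || length(sml) < 2L)
        stop("a sex has fewer than 2 subjects with scores")
      t <- two_sample_t(sf, sml)
      res[[length(res) + 1L]] <- data.frame(
        metric = metric, region_id = rid,
        hemisphere = sm$hemisphere[sm$region_id == rid][1],
        statistic = t$statistic, df = t$df, p = t$p_two_tailed,
        f_higher = t$mean_a > t$mean_b, stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, res)
    fdr <- bh_fdr(res$p, q = q)
    res$p_adjusted <- fdr$p_adjusted
    res$rejected_fdr <- fdr$rejected
    tests[[metric]] <- res

    dc <- direction_count(nrow(res), sum(res$f_higher), metric = metric)
    directions[[metric]] <- direction_binomial(dc,
                                               bonferroni_n = length(metrics))
  }
  list(tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
       directions = directions)
}

#' Small-world group analysis
#'
#' Given per-subject small-world profiles and the cohort manifest, reports:
#' the left-vs-right comparison of sigma in both a paired and a pooled
#' two-sample design (the two-sample design is flagged primary, matching the
#' pooled df convention); pooled two-sample sex comparisons of sigma
#' (whole, left, right) and of the asymmetry index delta; the Pearson
#' correlation between hemispheric sigmas; an analysis of covariance (OLS,
#' sex as a two-level factor, no interaction) of each index on sex adjusted
#' for brain volume; and the correlation of each index with brain volume.
#'
#' @param profiles data frame with `subject_id`, `sigma_whole`, `sigma_lh`,
#'   `sigma_rh`, `delta` (one row per subject; see
#'   [subject_sigma_profile()]).
#' @param manifest data frame with `subject_id`, `sex`, `brain_volume`.
#' @return list of result tables (`hemisphere`, `gender`, `correlations`,
#'   `ancova`).
#' @export
smallworld_suite <- function(profiles, manifest) {
  assert_that(nrow(profiles) >= 4L, "need at least 4 subjects")
  d <- merge(profiles, manifest[, c("subject_id", "sex", "brain_volume")],
             by = "subject_id")
  assert_that(all(c("F", "M") %in% d$sex), "both sexes must be present")
  if (stats::sd(d$sigma_whole) == 0) stop("constant sigma vector")

  ## left vs right; the paired statistic is computed by hand so a constant
  ## difference degrades to t = 0 (identical) or +/-Inf instead of an error
  diffs <- d$sigma_lh - d$sigma_rh
  n <- length(diffs)
  pt <- if (stats::sd(diffs) == 0) {
    list(statistic = if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf,
         parameter = n - 1,
         p.value = if (mean(diffs) == 0) 1 else 0)
  } else {
    f <- stats::t.test(d$sigma_lh, d$sigma_rh, paired = TRUE)
    list(statistic = unname(f$statistic), parameter = unname(f$parameter),
         p.value = f$p.value)
  }
  tt <- two_sample_t(d$sigma_lh, d$sigma_rh)
  hemisphere <- data.frame(
    design = c("two-sample (primary)", "paired"),
    statistic = c(tt$statistic, pt$statistic),
    df = c(tt$df, pt$parameter),
    p = c(tt$p_two_tailed, pt$p.value),
    stringsAsFactors = FALSE
  )

  ## sex comparisons per index (degenerate indices yield NA rows)
  idx_names <- c("sigma_whole", "sigma_lh", "sigma_rh", "delta")
  gender <- do.call(rbind, lapply(idx_names, function(nm) {
    t <- tryCatch(two_sample_t(d[[nm]][d$sex == "F"], d[[nm]][d$sex == "M"]),
                  error = function(e) NULL)
    if (is.null(t))
      return(data.frame(index = nm, statistic = NA_real_, df = NA_real_,
                        p = NA_real_, f_higher = NA, stringsAsFactors = FALSE))
    data.frame(index = nm, statistic = t$statistic, df = t$df,
               p = t$p_two_tailed, f_higher = t$mean_a > t$mean_b,
               stringsAsFactors = FALSE)
  }))

  ## correlations (NA when one variable is constant)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  correlations <- rbind(
    data.frame(pair = "sigma_lh~sigma_rh",
               r = safe_cor(d$sigma_lh, d$sigma_rh)),
    do.call(rbind, lapply(idx_names, function(nm)
      data.frame(pair = paste0(nm, "~brain_volume"),
                 r = safe_cor(d[[nm]], d$brain_volume))))
  )

  ## ANCOVA: index ~ sex + brain_volume (OLS, two-level factor)
  ancova <- do.call(rbind, lapply(idx_names, function(nm) {
    fit <- stats::lm(d[[nm]] ~ factor(d$sex, levels = c("M", "F")) +
                       d$brain_volume)
    cf <- suppressWarnings(summary(fit))$coefficients
    data.frame(index = nm,
               sex_effect = cf[2, 1], sex_t = cf[2, 3], sex_p = cf[2, 4],
               volume_t = cf[3, 3], volume_p = cf[3, 4],
               stringsAsFactors = FALSE)
  }))

  list(hemisphere = hemisphere, gender = gender,
       correlations = correlations, ancova = ancova)
}
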