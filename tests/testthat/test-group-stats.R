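test_that("pooled t-test matches the hand formula and handles degenerate input", {
  a <- c(1.1, 2.3, 0.8, 1.9)
  b <- c(2.0, 2.7, 3.1, 2.4)
  r <- two_sample_t(a, b)
  sp2 <- ((3 * var(a)) + (3 * var(b))) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(r$statistic, t_hand)
  expect_equal(r$df, 6)
  expect_equal(r$p_two_tailed, 2 * pt(-abs(t_hand), 6))

  same <- c(1, 2, 3)
  r0 <- two_sample_t(same, same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_two_tailed, 1)

  r63 <- two_sample_t(rnorm(63), rnorm(63))
  expect_equal(r63$df, 124)

  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.003, n = 14), 0.042)
  expect_equal(bonferroni(0.2, n = 14), 1)
  p <- c(0.001, 0.02, 0.9)
  expect_equal(bonferroni(p, n = 5), pmin(1, p * 5))
})

test_that("BH step-up matches the hand computation", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(r$p_adjusted, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(r$rejected, c(TRUE, TRUE, TRUE, FALSE))

  expect_equal(bh_fdr(0.04)$p_adjusted, 0.04)
  expect_true(all(bh_fdr(rep(0.001, 4))$rejected))
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")

  # monotone non-decreasing after sorting raw p ascending
  withr::with_seed(1, {
    p <- runif(20)
    adj <- bh_fdr(p)$p_adjusted
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  })
})

test_that("exact binomial direction test matches brute-force tail sums", {
  # brute force over all outcomes for the printed direction counts
  tail_sum <- function(n, k) sum(choose(n, 0:k)) / 2^n

  dc <- direction_count(32, n_f_higher = 2, metric = "degree")
  expect_equal(dc$favoured_group, "M")
  expect_equal(dc$n_against, 2L)
  r <- direction_binomial(dc, bonferroni_n = 2)
  expect_equal(r$p_raw, tail_sum(32, 2), tolerance = 1e-12)
  expect_equal(r$p_adjusted, 2 * 529 / 2^32, tolerance = 1e-12)
  expect_lt(r$p_adjusted, 1e-6)

  dc <- direction_count(32, n_f_higher = 24, metric = "betweenness")
  expect_equal(dc$favoured_group, "F")
  expect_equal(dc$n_against, 8L)
  r <- direction_binomial(dc, bonferroni_n = 2)
  expect_equal(r$p_raw, tail_sum(32, 8), tolerance = 1e-12)
  expect_lt(r$p_adjusted, 0.01)
  expect_equal(r$p_adjusted, 2 * tail_sum(32, 8), tolerance = 1e-12)

  # even split: no effect, large p before correction
  r <- direction_binomial(direction_count(16, 8), bonferroni_n = 1)
  expect_gte(r$p_raw, 0.5)
})

test_that("t critical values reproduce the df = 61 thresholds", {
  expect_equal(round(t_critical(61, 0.05), 2), 2.00)
  expect_equal(round(t_critical(61, 0.001), 2), 3.46)
  expect_equal(t_critical(1e7, 0.05), qnorm(0.975), tolerance = 1e-3)

  # round trip with the two-tailed p of the t distribution
  tc <- t_critical(61, 0.05)
  expect_equal(2 * pt(-tc, 61), 0.05, tolerance = 1e-6)
})

## helper: synthetic hub-score tables with known group structure
make_score_table <- function(n_f, n_m, region_means_f, region_means_m,
                             hemisphere, sd = 1, seed = 1, metric = "betweenness") {
  n_reg <- length(region_means_f)
  withr::with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_f + n_m)) {
      sex <- if (s <= n_f) "F" else "M"
      mus <- if (sex == "F") region_means_f else region_means_m
      for (rg in seq_len(n_reg)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("s%02d", s), sex = sex, region_id = rg,
          hemisphere = hemisphere[rg], metric = metric,
          score = rnorm(1, mus[rg], sd), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

test_that("gender suite recovers planted directions and reports df", {
  # 8 regions, F higher on betweenness everywhere
  sc <- make_score_table(37, 26, rep(10, 8), rep(9, 8),
                         hemisphere = rep(c("left", "right"), 4), seed = 2)
  g <- gender_suite(sc)
  expect_equal(unique(g$tests$df), 61)
  expect_equal(g$directions$betweenness$favoured_group, "F")
  expect_true(all(g$tests$p_adjusted >= g$tests$p - 1e-15))

  sc$sex[1] <- "M"  # unbalanced but both present
  expect_silent(gender_suite(sc))
})

test_that("asymmetry suite tests left vs right with Bonferroni over pairs", {
  sc <- rbind(
    make_score_table(6, 6, c(12, 10), c(12, 10), hemisphere = c("left", "left"),
                     sd = 0.5, seed = 3),
    {
      s2 <- make_score_table(6, 6, c(9, 10), c(9, 10),
                             hemisphere = c("right", "right"), sd = 0.5, seed = 4)
      s2$region_id <- s2$region_id + 2L
      s2
    }
  )
  pairs <- data.frame(pair_id = 1:2, left_id = c(1L, 2L), right_id = c(3L, 4L),
                      peak_dist_mm = c(0, 0))
  a <- asymmetry_suite(sc, pairs)
  expect_equal(nrow(a), 2)
  expect_equal(unique(a$df), 22)  # 2 * 12 subjects - 2
  # pair 1: left mean 12 vs right 9 -> strongly significant, left higher
  r1 <- a[a$pair_id == 1, ]
  expect_lt(r1$p_adjusted, 0.01)
  expect_equal(r1$higher, "left")
  # pair 2: identical means -> not significant
  expect_gt(a[a$pair_id == 2, "p_adjusted"], 0.05)
  # single-pair family: adjustment is the identity
  a1 <- asymmetry_suite(sc, pairs[1, ])
  expect_equal(a1$p_adjusted, a1$p)
})

test_that("small-world suite reports both designs, correlations and ANCOVA", {
  n <- 40
  prof <- withr::with_seed(11, {
    lh <- rnorm(n, 1.8, 0.05)
    data.frame(subject_id = sprintf("s%02d", 1:n), sigma_whole = lh + 0.01,
               sigma_lh = lh, sigma_rh = lh - 0.02, delta = rep(0.02, n))
  })
  man <- data.frame(subject_id = prof$subject_id,
                    sex = rep(c("F", "M"), each = n / 2),
                    brain_volume = withr::with_seed(12, rnorm(n, 1.2e6, 5e4)))
  r <- smallworld_suite(prof, man)
  # rh = lh - constant: paired t is infinite/NA-free and r = 1
  expect_equal(r$correlations$r[r$correlations$pair == "sigma_lh~sigma_rh"], 1)
  expect_setequal(r$hemisphere$design, c("two-sample (primary)", "paired"))
  expect_equal(r$hemisphere$df, c(2 * n - 2, n - 1))
  expect_equal(nrow(r$ancova), 4)

  # identical hemispheres: paired t = 0
  prof2 <- prof
  prof2$sigma_rh <- prof2$sigma_lh
  prof2$delta <- 0
  expect_error(smallworld_suite(prof2, man), NA)
})

test_that("a planted lateralized hub zone shifts hemispheric degree scores rightward", {
  dirs <- logical(10)
  sigs <- logical(10)
  for (s in 1:10) {
    res <- run_cohort_analysis(demo_config("medium", seed = s))
    pairs <- pair_regions(res$regions, res$grid)
    rec <- zone_recovery(res$regions, res$truth, res$grid)
    lz <- rec[rec$pair_id %in% res$truth$lateralized_pairs &
                rec$hemisphere == "right", , drop = FALSE]
    pr <- pairs[pairs$right_id == lz$best_region[1], , drop = FALSE]
    if (!nrow(pr)) next
    sym <- symmetrize_regions(res$regions, pairs, res$grid)
    ssym <- score_hubs(res$maps$degree, sym, res$manifest)
    asym <- asymmetry_suite(ssym, pairs)
    row <- asym[asym$pair_id == pr$pair_id[1], , drop = FALSE]
    dirs[s] <- nrow(row) > 0 && row$higher[1] == "right"
    sigs[s] <- dirs[s] && is.finite(row$p_adjusted[1]) &&
      row$p_adjusted[1] < 0.05
  }
  # the planted direction dominates; about two thirds of cohorts also reach
  # corrected significance at this cohort size
  expect_gte(mean(dirs), 0.8)
  expect_gte(mean(sigs), 0.5)
})

test_that("volume can mediate a sex difference in the ANCOVA", {
  # sigma driven entirely by volume; volume differs by sex
  hits <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      n_f <- 20; n_m <- 20
      sex <- rep(c("F", "M"), c(n_f, n_m))
      vol <- rnorm(n_f + n_m, ifelse(sex == "F", 1.08e6, 1.22e6), 4e4)
      sig <- 1.5 + (1.3e6 - vol) * 4e-7 + rnorm(n_f + n_m, 0, 0.008)
      prof <- data.frame(subject_id = sprintf("s%02d", seq_along(sex)),
                         sigma_whole = sig, sigma_lh = sig, sigma_rh = sig,
                         delta = 0)
      man <- data.frame(subject_id = prof$subject_id, sex = sex,
                        brain_volume = vol)
      r <- smallworld_suite(prof, man)
      unadj <- r$gender$p[r$gender$index == "sigma_whole"]
      adj <- r$ancova$sex_p[r$ancova$index == "sigma_whole"]
      unadj < 0.05 && adj > 0.05
    })
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
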