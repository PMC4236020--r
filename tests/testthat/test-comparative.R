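test_that("one clean regime selects a single exact segment", {
  x <- seq(1, 10, length.out = 30)
  y <- 0.25 * x + 1
  f <- segmented_regression(x, y)
  expect_equal(f$n_segments, 1L)
  expect_equal(f$segments$slope, 0.25, tolerance = 1e-9)
  expect_equal(f$segments$intercept, 1, tolerance = 1e-9)
  expect_length(f$breakpoints, 0)
})

test_that("two-regime data select two segments and recover both slopes", {
  b <- gen_bimodal_gi(n_species = 200, noise_sd = 0.02, seed = 1)
  f <- segmented_regression(log(b$neurons), log(b$gi))
  expect_equal(f$n_segments, 2L)
  expect_equal(f$segments$slope[1], 0.072, tolerance = 0.01)
  expect_equal(f$segments$slope[2], 0.140, tolerance = 0.01)
  # breakpoint falls in the inter-regime gap around ln(1e9)
  expect_lt(abs(f$breakpoints - log(1e9)), 0.5)
})

test_that("optimal-breakpoint search matches exhaustive enumeration", {
  set.seed(3)
  x <- sort(runif(30))
  y <- ifelse(x < 0.5, x, 2 * x) + rnorm(30, 0, 0.05)
  f <- segmented_regression(x, y, max_segments = 2, breaks = "optimal")
  expect_equal(f$rss, exhaustive_segmented_rss(x, y, 2), tolerance = 1e-9)
  set.seed(4)
  y2 <- cumsum(rnorm(30))
  f3 <- segmented_regression(x, y2, max_segments = 3, breaks = "optimal")
  at <- f3$aic_table
  expect_equal(min(at$n_segments), 1L)
  three <- segmented_regression(x, y2, max_segments = 3,
                                breaks = "optimal")
  expect_lte(exhaustive_segmented_rss(x, y2, 3),
             exhaustive_segmented_rss(x, y2, 2) + 1e-12)
})

test_that("AIC prefers two segments on generated two-regime data", {
  sel <- vapply(1:100, function(s) {
    b <- gen_bimodal_gi(n_species = 100, noise_sd = 0.02, seed = s)
    suppressWarnings(
      segmented_regression(log(b$neurons), log(b$gi))$n_segments)
  }, integer(1))
  expect_gte(mean(sel == 2L), 0.90)
})

test_that("slope contrasts are calibrated and match a permutation oracle", {
  # identical groups give t = 0
  x <- seq(0, 1, length.out = 10); y <- 2 * x + 1
  sc0 <- slope_contrast(x, y, x, y)
  expect_equal(sc0$t, 0)
  expect_equal(sc0$df, 16L)
  # power: true slope gap 0.068, small noise
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    x1 <- runif(20, 15, 20); x2 <- runif(20, 21, 25)
    y1 <- 0.072 * x1 + rnorm(20, 0, 0.02)
    y2 <- 0.140 * x2 + rnorm(20, 0, 0.02)
    slope_contrast(x1, y1, x2, y2)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # permutation reference on n = 20
  set.seed(9)
  x1 <- runif(10); y1 <- 0.5 * x1 + rnorm(10, 0, 0.3)
  x2 <- runif(10); y2 <- 1.5 * x2 + rnorm(10, 0, 0.3)
  obs <- slope_contrast(x1, y1, x2, y2)
  perm <- replicate(4000, {
    lab <- sample(rep(1:2, each = 10))
    xx <- c(x1, x2); yy <- c(y1, y2)
    slope_contrast(xx[lab == 1], yy[lab == 1],
                   xx[lab == 2], yy[lab == 2])$t
  })
  p_perm <- mean(abs(perm) >= abs(obs$t))
  expect_lt(abs(obs$p - p_perm), 0.02)
  expect_error(slope_contrast(1:2, 1:2, x2, y2), ">= 3 points")
})

test_that("threshold estimate sits at the inter-group midpoint", {
  # disjoint clean groups: exact midpoint, no bootstrap
  x <- c(1, 2, 3, 10, 11, 12); y <- c(1, 1.1, 1.2, 2, 2.1, 2.2)
  g <- x > 5
  est <- threshold_estimate(x, y, g, n_boot = 0)
  expect_equal(est$x_star, 6.5)
  expect_equal(est$y_star, 1.6)
  expect_true(is.na(est$x_se))
  # planted boundary recovered within bootstrap uncertainty
  b <- gen_bimodal_gi(n_species = 150, seed = 5)
  est2 <- threshold_estimate(log(b$neurons), b$gi,
                             b$gi_group == "high", n_boot = 500, seed = 2)
  expect_lt(abs(est2$x_star - log(1e9)), max(4 * est2$x_se, 0.2))
  expect_lt(abs(est2$y_star - 1.5), 0.25)
  expect_error(threshold_estimate(c(1, 3), c(1, 1), c(TRUE, FALSE)),
               "overlap")
})

test_that("energy distance and clustering recover the planted bimodal split", {
  set.seed(21)
  a <- rnorm(10); b <- rnorm(10, 4)
  expect_equal(energy_distance(a, b), double_sum_energy(a, b),
               tolerance = 1e-12)
  expect_equal(energy_distance(1.3, 1.3), 0)
  gi_tab <- gen_bimodal_gi(n_species = 101, seed = 3)
  den <- energy_dendrogram(gi_tab$gi)
  planted <- ifelse(gi_tab$gi > 1.5, 2L, 1L)
  expect_equal(den$top_split, planted)
  # the final merge is the greatest clustering height
  expect_equal(max(den$merge_heights),
               den$merge_heights[length(den$merge_heights)])
  expect_error(energy_dendrogram(1), "at least 2")
})

test_that("Jenks natural breaks solve the exact partition problem", {
  jb <- jenks_breaks(c(1, 1, 1, 9, 9, 9), 2)
  expect_equal(jb$breaks, 5)
  expect_equal(jb$wss, 0)
  set.seed(6)
  v <- rnorm(12)
  expect_equal(jenks_breaks(v, 3)$wss, exhaustive_jenks_wss(v, 3),
               tolerance = 1e-9)
  # k = n: every value its own class
  v5 <- c(5, 1, 3, 2, 4)
  jb5 <- jenks_breaks(v5, 5)
  expect_equal(jb5$wss, 0)
  expect_equal(sort(jb5$classes), 1:5)
  expect_error(jenks_breaks(1:3, 4), "exceeds")
  expect_error(jenks_breaks(1:3, 1), ">= 2")
})

test_that("brain weight per gestation day contrasts the two GI groups", {
  b <- gen_bimodal_gi(n_species = 120, seed = 8)
  res <- brainweight_per_gestation(b)
  # planted ln-means -2.04 and 0.583; fold = exp(2.623) ~ 13.8
  expect_equal(res$means[["low"]], -2.04, tolerance = 0.15)
  expect_equal(res$means[["high"]], 0.583, tolerance = 0.15)
  expect_equal(res$fold, exp(0.583 + 2.04), tolerance = 0.15 * 14)
  expect_lt(res$p, 1e-6)
  # identical groups: ratio 1, t = 0
  same <- data.frame(brain_weight_g = rep(c(2, 4, 8), 2),
                     gestation_days = rep(20, 6),
                     gi_group = rep(c("low", "high"), each = 3))
  res0 <- brainweight_per_gestation(same)
  expect_equal(res0$fold, 1)
  expect_equal(res0$t, 0)
  # unit invariance: rescaling brain weight cancels in the fold
  kg <- b; kg$brain_weight_g <- kg$brain_weight_g * 1000
  expect_equal(brainweight_per_gestation(kg)$fold, res$fold)
  # rescaling gestation scales the fold accordingly (here: identically)
  gd <- b; gd$gestation_days <- gd$gestation_days * 2
  expect_equal(brainweight_per_gestation(gd)$fold, res$fold)
})
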