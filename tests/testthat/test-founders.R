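test_that("trapezoid-strip surfaces match closed forms and the shoelace oracle", {
  expect_equal(surface_from_sections(c(2, 2), 5), 10)        # rectangle
  expect_equal(surface_from_sections(c(0, 4, 0), 6), 12)     # triangle
  set.seed(19)
  contours <- pmax(0.1, 2.5 * sin(seq(0.2, pi - 0.2, length.out = 19)) +
                     rnorm(19, 0, 0.1))
  expect_equal(surface_from_sections(contours, 4.2),
               shoelace_surface(contours, 4.2), tolerance = 1e-9)
  expect_error(surface_from_sections(3, 5), "at least 2")
})

test_that("hexagonal end-foot area follows the across-flats formula", {
  expect_equal(endfoot_area(1), sqrt(3) / 2, tolerance = 1e-12)
  d <- 2 / sqrt(sqrt(3) / 2)
  expect_equal(endfoot_area(d), 4)
  expect_equal(endfoot_area(2), 4 * endfoot_area(1))  # quadratic in d
  expect_error(endfoot_area(0), "positive")
})

test_that("founder counts divide surface by end-foot area with unit handling", {
  # 2.5 um^2 end-feet give the reference density of 4e5 cells per mm^2
  expect_equal(founders_from_surface(1, 2.5), 4e5)
  expect_equal(founders_from_surface(1e-6 * 3, 3), 1)  # area equality
  expect_equal(founders_from_surface(7, 2.5), 7 * founders_from_surface(1, 2.5))
})

test_that("cylinder conversion has the documented closed form and inverse", {
  expect_equal(cylinder_surface_from_volume(4.5 * pi / 4), 4.5 * pi)
  # similarity: 8x volume doubles d, quadruples surface
  expect_equal(cylinder_surface_from_volume(8 * 2.2),
               4 * cylinder_surface_from_volume(2.2))
  for (v in c(0.013, 1, 77)) {
    expect_equal(cylinder_volume_from_surface(
      cylinder_surface_from_volume(v)), v)
  }
  expect_error(cylinder_surface_from_volume(0), "positive")
})

test_that("volume-derived founder counts are monotone and density-scaled", {
  expect_error(founders_from_volume(0), "positive")
  v <- c(0.5, 1, 5, 20)
  f <- founders_from_volume(v)
  expect_true(all(diff(f) > 0))
  expect_equal(founders_from_volume(3, density_per_mm2 = 8e5),
               2 * founders_from_volume(3))
  # the reference human founder pool implies ~77.5 mm^2 of surface
  implied_surface <- 3.10e7 / 4e5
  vol <- cylinder_volume_from_surface(implied_surface)
  expect_equal(founders_from_volume(vol), 3.10e7, tolerance = 1e-9)
})

test_that("surface and volume routes agree on matched geometry", {
  surface <- 12.3
  vol <- cylinder_volume_from_surface(surface)
  expect_equal(founders_from_volume(vol, density_per_mm2 = 4e5),
               founders_from_surface(surface, 2.5), tolerance = 1e-9)
})

test_that("allometric imputation recovers exact and noisy coefficients", {
  # zero-noise: exact recovery of the generating line
  set.seed(5)
  x <- exp(runif(12, log(15), log(300)))
  tab <- data.frame(g = x, np = exp(0.91 * log(x) - 0.42))
  tab$np[c(3, 8)] <- NA
  fit <- suppressWarnings(estimate_missing(tab, "np", "g"))
  expect_equal(fit$slope, 0.91, tolerance = 1e-9)
  expect_equal(fit$intercept, -0.42, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$table$np[3], exp(0.91 * log(x[3]) - 0.42))
  # coefficients-supplied mode: plug-in prediction
  plug <- estimate_missing(data.frame(g = 19, np = NA), "np", "g",
                           coefficients = c(0.91, -0.42))
  expect_equal(plug$table$np, exp(0.91 * log(19) - 0.42))  # ~9.5 days
  expect_equal(plug$n_imputed, 1L)
  # noisy recovery across replicates
  slopes <- vapply(1:50, function(s) {
    set.seed(s + 100)
    x <- exp(runif(50, log(15), log(300)))
    y <- exp(0.91 * log(x) - 0.42 + rnorm(50, 0, 0.05))
    estimate_missing(data.frame(g = x, np = y), "np", "g")$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.91), 0.05)
  expect_true(all(abs(slopes - 0.91) < 0.05))
  expect_error(estimate_missing(data.frame(g = c(1, 2), np = c(NA, NA)),
                                "np", "g"), ">= 3 complete rows")
})

test_that("leave-one-out calibration re-predicts held-out species closely", {
  # synthetic calibration set on the exact volume-to-founders pipeline
  set.seed(11)
  vols <- exp(runif(10, log(0.01), log(200)))
  founders <- founders_from_volume(vols) * exp(rnorm(10, 0, 0.03))
  for (i in c(1, 10)) {
    dens_others <- founders[-i] / cylinder_surface_from_volume(vols[-i])
    refit <- mean(dens_others)
    pred <- founders_from_volume(vols[i], density_per_mm2 = refit)
    expect_lt(abs(pred - founders[i]) / founders[i], 0.10)
  }
})
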