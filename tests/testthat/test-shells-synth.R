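test_that("shell populations have positive, correlated, reproducible measurements", {
  pop <- generate_shell_population(n = 3, seed = 5)
  expect_equal(nrow(pop), 3)
  expect_true(all(as.matrix(pop[, -1]) > 0))

  pop1 <- generate_shell_population(n = 50, seed = 9)
  pop2 <- generate_shell_population(n = 50, seed = 9)
  expect_identical(pop1, pop2)

  lg <- log(as.matrix(pop1[, c("length_mm", "width_mm", "aperture_mm")]))
  expect_true(all(cor(lg)[upper.tri(diag(3))] > 0))

  expect_error(generate_shell_population(n = 2), "n")
  expect_error(generate_shell_population(sd_length = 0), "sd_length")
})

test_that("zero isometry noise gives exact isometry and a rank-1 size axis", {
  pop <- generate_shell_population(n = 60, seed = 2, isometry_noise = 0)
  lg <- log(as.matrix(pop[, c("length_mm", "width_mm", "aperture_mm")]))
  expect_equal(unname(cor(lg)[upper.tri(diag(3))]), rep(1, 3),
               tolerance = 1e-12)
  iso <- test_isometry(pop)
  expect_equal(iso$slope, rep(1, 3), tolerance = 1e-10)
  expect_lt(max(iso$ci_high - iso$ci_low), 1e-8)
  expect_equal(pca_variance_explained(pop), 1, tolerance = 1e-10)
})

test_that("population summaries match order statistics and handle degenerate data", {
  const <- data.frame(length_mm = rep(40, 5), width_mm = rep(30, 5),
                      aperture_mm = rep(14, 5))
  s <- summarize_population(const)
  expect_equal(s$minimum, s$maximum)
  expect_equal(s$minimum, s$mean)
  expect_equal(s$sd, rep(0, 3))

  three <- data.frame(length_mm = c(1, 2, 3), width_mm = c(1, 2, 3),
                      aperture_mm = c(1, 2, 3))
  s3 <- summarize_population(three)
  expect_equal(s3$mean, rep(2, 3))
  expect_equal(s3$median, rep(2, 3))
  expect_equal(s3$sd, rep(1, 3))   # sample s.d.

  expect_error(summarize_population(data.frame()), "non-empty")

  # full 7-statistic x 3-attribute structure from generator output
  tab <- summarize_population(generate_shell_population(n = 113, seed = 4))
  expect_equal(dim(tab), c(3, 8))
  expect_true(all(tab$minimum <= tab$q1 & tab$q1 <= tab$median &
                    tab$median <= tab$q3 & tab$q3 <= tab$maximum))
})

test_that("isometry regression agrees with the closed-form OLS slope", {
  pop <- generate_shell_population(n = 25, seed = 11, isometry_noise = 0.05)
  x <- log(pop$length_mm); y <- log(pop$width_mm)
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  iso <- test_isometry(pop)
  expect_equal(iso$slope[iso$pair == "width ~ length"], slope_oracle,
               tolerance = 1e-10)

  degenerate <- data.frame(length_mm = rep(40, 12),
                           width_mm = exp(rnorm(12, log(30), 0.1)),
                           aperture_mm = exp(rnorm(12, log(14), 0.1)))
  expect_error(test_isometry(degenerate), "zero-variance")
})

test_that("PC1 fraction is 1/3 for independent attributes", {
  set.seed(31)
  indep <- data.frame(length_mm = exp(rnorm(4000, log(40), 0.1)),
                      width_mm = exp(rnorm(4000, log(30), 0.1)),
                      aperture_mm = exp(rnorm(4000, log(14), 0.1)))
  expect_lt(abs(pca_variance_explained(indep) - 1 / 3), 0.02)
  expect_error(pca_variance_explained(
    data.frame(length_mm = rep(1, 5), width_mm = 1:5, aperture_mm = 1:5)),
    "zero-variance")
})

test_that("replica levels span -3..+3 s.d. around the mean", {
  expect_equal(replica_levels(0, 1), -3:3)
  expect_equal(replica_levels(43.2, 5.8),
               c(25.8, 31.6, 37.4, 43.2, 49.0, 54.8, 60.6))
  lv <- replica_levels(15.0, 1.6)
  expect_equal(lv[1], 10.2)
  expect_equal(lv[7], 19.8)
  expect_error(replica_levels(10, 0), "sd")
  expect_error(replica_levels(10, -1), "sd")
})
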