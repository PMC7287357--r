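test_that("trait tables centre body size and put the reference group first", {
  d <- generate_choice_dataset(task = "size", seed = 41)
  co <- fit_cohort(d)
  nd <- simulate_random_traits(n_reps = 25, seed = 42)
  tt <- build_trait_table(co, null = nd)
  expect_s3_class(tt, "trait_table")
  expect_equal(levels(tt$task)[1], "RANDOM")
  real <- !is.na(tt$body_size_centred)
  expect_lt(abs(mean(tt$body_size_centred[real])), 1e-10)
  expect_equal(sum(!real), 25)
})

test_that("two-group heteroscedastic fits reproduce the Welch statistic", {
  set.seed(55)
  for (i in 1:5) {
    y <- c(rnorm(9, 0, 1), rnorm(14, 1, 2.5))
    g <- rep(c("a", "b"), c(9, 14))
    fit <- fit_group_model(group_table(y, g), "peak", variance = "per-group")
    tstat <- fit$coefficients$statistic[2]
    welch <- t.test(y[g == "b"], y[g == "a"], var.equal = FALSE)$statistic
    expect_equal(tstat^2, unname(welch)^2, tolerance = 1e-6)
  }
})

test_that("per-group and pooled fits coincide when sample variances are equal", {
  base <- rnorm(12)
  y <- c(base, base + 2)               # identical in-sample variances
  g <- rep(c("a", "b"), each = 12)
  p1 <- fit_group_model(group_table(y, g), "peak", variance = "pooled")
  p2 <- fit_group_model(group_table(y, g), "peak", variance = "per-group")
  expect_equal(p1$coefficients$estimate, p2$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(p1$coefficients$se, p2$coefficients$se, tolerance = 1e-6)
})

test_that("the per-group variance model never has lower ML likelihood", {
  set.seed(66)
  for (i in 1:5) {
    y <- c(rnorm(10, 0, 1), rnorm(10, 0.5, 1 + i / 2), rnorm(10, 1, 2))
    g <- rep(c("a", "b", "c"), each = 10)
    ml_pool <- fit_group_model(group_table(y, g), "peak", method = "ML")
    ml_het <- fit_group_model(group_table(y, g), "peak",
                              variance = "per-group", method = "ML")
    expect_gte(ml_het$loglik, ml_pool$loglik - 1e-6)
  }
})

test_that("ln transform requires positive values and changes the response scale", {
  y <- c(rexp(10) + 0.1, rexp(10) + 0.5)
  g <- rep(c("a", "b"), each = 10)
  fit <- fit_group_model(group_table(y, g), "peak", transform = "ln")
  expect_equal(fit$transform, "ln")
  y2 <- y; y2[1] <- 0
  expect_error(fit_group_model(group_table(y2, g), "peak", transform = "ln"),
               "positive")
})

test_that("non-significant interactions are dropped, real ones kept", {
  set.seed(77)
  g <- rep(c("a", "b"), each = 40)
  x <- rnorm(80, 0, 3)
  y_null <- 2 + (g == "b") + 0.5 * x + rnorm(80, 0, 0.5)
  f1 <- fit_group_model(group_table(y_null, g, body = x + 100), "peak",
                        predictors = c("task", "body_size", "interaction"))
  expect_false(f1$interaction_kept)
  y_int <- 2 + (g == "b") + 0.5 * x + 2 * (g == "b") * x + rnorm(80, 0, 0.5)
  f2 <- fit_group_model(group_table(y_int, g, body = x + 100), "peak",
                        predictors = c("task", "body_size", "interaction"))
  expect_true(f2$interaction_kept)
  expect_true(any(grepl(":", f2$coefficients$term)))
})

test_that("singular designs fail loudly naming the collinear terms", {
  y <- rnorm(20)
  g <- rep(c("a", "b"), each = 10)
  tab <- group_table(y, g, body = rep(1, 20))   # zero-variance covariate
  expect_error(fit_group_model(tab, "peak", predictors = c("task", "body_size")),
               "collinear")
})

test_that("group models require enough groups and observations", {
  expect_error(fit_group_model(group_table(rnorm(5), rep("a", 5)), "peak"),
               "2 groups")
  expect_error(fit_group_model(
    group_table(rnorm(3), c("a", "a", "b")), "peak"), "2 observations")
})

test_that("a single Dunnett contrast needs no adjustment", {
  set.seed(88)
  y <- c(rnorm(30), rnorm(30, 0.4))
  g <- rep(c("RANDOM", "size"), each = 30)
  fit <- fit_group_model(group_table(y, g, reference = "RANDOM"), "peak")
  ct <- dunnett_vs_reference(fit, n_mc = 2e5, seed = 1)
  expect_equal(nrow(ct), 1)
  expect_lt(abs(ct$p_adjusted - ct$p_raw), 0.02)
})

test_that("Monte-Carlo Dunnett agrees with the multcomp single-step oracle", {
  set.seed(99)
  y <- c(rnorm(40, 0), rnorm(20, 0.5), rnorm(20, 0.9), rnorm(20, -0.2),
         rnorm(20, 0.1))
  g <- rep(c("RANDOM", "size", "length", "aperture", "intactness"),
           c(40, 20, 20, 20, 20))
  tab <- group_table(y, g, reference = "RANDOM")
  fit <- fit_group_model(tab, "peak")
  mine <- dunnett_vs_reference(fit, n_mc = 2e5, seed = 2)

  dat <- data.frame(y = y, task = factor(g, levels = unique(g)))
  mod <- lm(y ~ task, data = dat)
  gl <- summary(multcomp::glht(mod, linfct = multcomp::mcp(task = "Dunnett")))
  ord <- match(sub(" - RANDOM", "", mine$label),
               sub(" - RANDOM.*", "", names(gl$test$coefficients)))
  expect_equal(mine$estimate, unname(gl$test$coefficients)[ord],
               tolerance = 1e-8)
  expect_equal(mine$se, unname(gl$test$sigma)[ord], tolerance = 1e-8)
  expect_equal(mine$p_adjusted, unname(gl$test$pvalues)[ord],
               tolerance = 0.01)
})

test_that("adjusted p-values never fall below raw ones", {
  set.seed(111)
  for (i in 1:5) {
    y <- rnorm(75)
    g <- rep(c("RANDOM", "a", "b", "c", "d"), each = 15)
    fit <- fit_group_model(group_table(y, g, reference = "RANDOM"), "peak")
    ct <- dunnett_vs_reference(fit, n_mc = 5000, seed = i)
    expect_true(all(ct$p_adjusted >= ct$p_raw))
    ap <- allpairs_contrasts(fit, n_mc = 5000, seed = i, exclude = "RANDOM")
    expect_true(all(ap$p_adjusted >= ap$p_raw))
  }
})

test_that("all-pairs contrasts enumerate C(g,2) pairs and are label-symmetric", {
  set.seed(123)
  y <- rnorm(60, rep(c(0, 1, 0.5, 2), each = 15))
  g <- rep(c("size", "length", "aperture", "intactness"), each = 15)
  fit <- fit_group_model(group_table(y, g), "peak")
  ap <- allpairs_contrasts(fit, n_mc = 5e4, seed = 4)
  expect_equal(nrow(ap), 6)

  # permuting group labels permutes labels but not the statistic multiset
  perm <- c(size = "length", length = "aperture", aperture = "intactness",
            intactness = "size")
  fit2 <- fit_group_model(group_table(y, unname(perm[g])), "peak")
  ap2 <- allpairs_contrasts(fit2, n_mc = 5e4, seed = 4)
  expect_equal(sort(abs(ap$statistic)), sort(abs(ap2$statistic)),
               tolerance = 1e-8)
})

test_that("likelihood-ratio tests detect nesting, nulls and real effects", {
  set.seed(131)
  y <- rnorm(40, rep(c(0, 1), each = 20))
  g <- rep(c("a", "b"), each = 20)
  tab <- group_table(y, g, body = rnorm(40, 30, 3))
  full <- fit_group_model(tab, "peak", predictors = c("task", "body_size"),
                          method = "ML")
  red <- fit_group_model(tab, "peak", method = "ML")
  same <- lrt(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  out <- lrt(full, red)
  expect_gte(out$chi2, 0)
  expect_equal(out$df, 1)

  reml <- fit_group_model(tab, "peak")
  expect_error(lrt(reml, red), "ML")

  # power: a 2-s.d. covariate effect is detected in >= 80% of replicates
  hits <- vapply(1:100, function(i) {
    set.seed(5000 + i)
    body <- rnorm(40, 30, 3)
    yy <- rnorm(40, rep(c(0, 1), each = 20) + 2 / 3 * (body - 30))
    t2 <- group_table(yy, g, body = body)
    f <- fit_group_model(t2, "peak", predictors = c("task", "body_size"),
                         method = "ML")
    r <- fit_group_model(t2, "peak", method = "ML")
    lrt(f, r)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("variance inflation factors match their definition", {
  x1 <- rep(c(-1, 1), 20)
  x2 <- rep(c(-1, 1), each = 20)
  orth <- data.frame(x1 = x1, x2 = x2)
  expect_equal(unname(vif(orth, c("x1", "x2"))), c(1, 1), tolerance = 1e-10)

  dup <- data.frame(a = rnorm(30))
  dup$b <- dup$a
  expect_true(is.infinite(vif(dup, c("a", "b"))["b"]))

  # sex and body size at the study's parameters are correlated; adding
  # their interaction product drives multicollinearity past the VIF > 5 flag
  set.seed(141)
  sex <- rep(c("male", "female"), each = 40)
  size <- rnorm(80, ifelse(sex == "male", 36.5, 30.1),
                ifelse(sex == "male", 4.5, 2.4))
  tab <- data.frame(sex = sex, body_size = size,
                    sex_by_size = (sex == "male") * size)
  v2 <- vif(tab, c("sex", "body_size"))
  expect_true(all(v2 > 1))
  # independent oracle: car::vif on the equivalent linear model
  mod <- lm(rnorm(80) ~ factor(sex) + size)
  expect_equal(unname(v2), unname(car::vif(mod)), tolerance = 1e-8)
  v3 <- vif(tab, c("sex", "body_size", "sex_by_size"))
  expect_gt(max(v3), 5)

  expect_error(vif(orth, "x1"), "2 predictors")
})

test_that("sex difference in body size is recovered at study parameters", {
  set.seed(151)
  sex <- rep(c("female", "male"), each = 40)
  size <- rnorm(80, ifelse(sex == "male", 36.5, 30.1),
                ifelse(sex == "male", 4.5, 2.4))
  fit <- fit_group_model(group_table(size, sex), "peak",
                         variance = "per-group")
  est <- fit$coefficients$estimate[2]
  mc_se <- sqrt(4.5^2 / 40 + 2.4^2 / 40)
  expect_lt(abs(est - 6.4), 3 * mc_se)
  expect_lt(fit$coefficients$p[2], 1e-4)
})
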