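test_that("choice counts validate their invariants", {
  expect_s3_class(cc7(1, 0, 0, 0, 0, 0, 1), "choice_counts")
  expect_error(choice_counts(c(1, 2), c(1, 1)), "levels")
  expect_error(choice_counts(c(1, 2, 2.5, 2), c(1, 1, 1, 1)), "levels")
  expect_error(cc7(0, 0, 0, 0, 0, 0, 0), "at least one")
  expect_error(cc7(1, -1, 0, 0, 0, 0, 2), "non-negative")
  expect_error(cc7(0.5, 0, 0, 0, 0, 0, 1), "non-negative")
})

test_that("constant counts give a flat unit curve with flat-curve trait conventions", {
  crv <- fit_preference_curve(cc7(1, 1, 1, 1, 1, 1, 1))
  expect_lt(max(abs(crv$height - 1)), 1e-6)
  expect_equal(extract_peak(crv), 0)         # midpoint tie-break
  expect_equal(extract_strength(crv), 0)
  expect_equal(extract_tolerance(crv), 6.0)  # full range
  expect_gte(crv$edf, 2)
  expect_lte(crv$edf, 6 + 1e-6)
})

test_that("symmetric concentrated counts peak at the centre", {
  crv <- fit_preference_curve(cc7(0, 0, 0, 4, 0, 0, 0))
  step <- diff(crv$grid[1:2])
  expect_lt(abs(extract_peak(crv)), step + 1e-12)
  expect_gt(extract_strength(crv), 0)
})

test_that("the infinite-penalty limit is the least-squares line", {
  y <- c(0, 1, 0, 2, 1, 3, 4)
  crv <- fit_preference_curve(choice_counts(-3:3, y), smoothing = 1e10)
  line <- lm(y ~ x, data = data.frame(x = -3:3, y = y))
  pred <- pmax(predict(line, newdata = data.frame(x = crv$grid)), 0)
  expect_lt(max(abs(crv$height - pred)), 1e-5)
})

test_that("boundary-concentrated counts give an open-ended peak", {
  crv <- fit_preference_curve(cc7(0, 0, 0, 0, 0, 0, 4))
  expect_gte(extract_peak(crv), 2.5)
})

test_that("strength is scale-invariant and orders spike above diffuse counts", {
  s1 <- extract_strength(fit_preference_curve(cc7(0, 1, 1, 0, 1, 1, 0)))
  s3 <- extract_strength(fit_preference_curve(cc7(0, 3, 3, 0, 3, 3, 0)))
  expect_lt(abs(s1 - s3), 1e-6)
  spike <- extract_strength(fit_preference_curve(cc7(0, 0, 0, 4, 0, 0, 0)))
  expect_gt(spike, s1)
})

test_that("tolerance definitions: strict never exceeds broad; bimodal is twice strict", {
  set.seed(42)
  for (i in 1:25) {
    crv <- fit_preference_curve(choice_counts(-3:3, random_counts()))
    expect_lte(extract_tolerance(crv, definition = "strict"),
               extract_tolerance(crv, definition = "broad") + 1e-12)
  }
  bi <- fit_preference_curve(cc7(4, 0, 0, 0, 0, 0, 4))
  broad <- extract_tolerance(bi, definition = "broad")
  strict <- extract_tolerance(bi, definition = "strict")
  expect_equal(broad, 2 * strict, tolerance = 0.02)
})

test_that("traits respect range invariants on random count vectors", {
  set.seed(7)
  for (i in 1:40) {
    crv <- fit_preference_curve(choice_counts(-3:3, random_counts()))
    tr <- extract_traits(crv)
    expect_true(all(crv$height >= 0))
    expect_gte(tr$peak, -3); expect_lte(tr$peak, 3)
    expect_gte(tr$strength, 0)
    expect_gt(tr$tolerance, 0); expect_lte(tr$tolerance, 6)
    expect_gte(crv$edf, 2 - 1e-6); expect_lte(crv$edf, 6 + 1e-6)
  }
})

test_that("mirroring counts mirrors the peak and preserves strength and tolerance", {
  set.seed(12)
  for (i in 1:20) {
    cnt <- random_counts(5)
    a <- fit_preference_curve(choice_counts(-3:3, cnt))
    b <- fit_preference_curve(choice_counts(-3:3, rev(cnt)))
    step <- diff(a$grid[1:2])
    expect_lt(abs(extract_peak(a) + extract_peak(b)), 2 * step + 1e-9)
    expect_lt(abs(extract_strength(a) - extract_strength(b)), 1e-6)
    expect_lt(abs(extract_tolerance(a) - extract_tolerance(b)), 1e-6)
  }
})

test_that("doubling the grid moves traits by less than a coarse grid step", {
  set.seed(19)
  for (i in 1:10) {
    cnt <- random_counts()
    a <- fit_preference_curve(choice_counts(-3:3, cnt), grid_size = 501)
    b <- fit_preference_curve(choice_counts(-3:3, cnt), grid_size = 1001)
    step <- diff(a$grid[1:2])
    expect_lt(abs(extract_peak(a) - extract_peak(b)), step)
    expect_lt(abs(extract_tolerance(a) - extract_tolerance(b)), step)
    expect_lt(abs(extract_strength(a) - extract_strength(b)), 0.05)
  }
})

test_that("individuals with fewer than three choices are excluded", {
  tr <- data.frame(fish_id = "f1", trial_index = 1:4,
                   choice = c(7L, 7L, NA, NA))
  out <- fit_individual(tr)
  expect_false(out$included)
  expect_true(is.na(out$peak))

  tr4 <- data.frame(fish_id = "f2", trial_index = 1:4,
                    choice = c(7L, 7L, 7L, 7L))
  out4 <- fit_individual(tr4)
  expect_true(out4$included)
  expect_gte(out4$peak, 2.5)
  expect_gt(out4$strength, 0)

  tr3 <- data.frame(fish_id = "f3", trial_index = 1:3,
                    choice = c(3L, 4L, 5L))
  out3 <- fit_individual(tr3)
  expect_gt(out3$tolerance, 1)   # plateau across -1..+1

  expect_error(fit_individual(data.frame()), "empty")
  expect_error(
    fit_individual(data.frame(fish_id = c("a", "b"), trial_index = 1:2,
                              choice = c(1L, 2L))), "single fish")
})

test_that("curve fits are deterministic and edf-capped for very few levels", {
  a <- fit_preference_curve(cc7(0, 2, 0, 1, 0, 1, 0))
  b <- fit_preference_curve(cc7(0, 2, 0, 1, 0, 1, 0))
  expect_identical(a$height, b$height)

  k3 <- fit_preference_curve(choice_counts(c(-1, 0, 1), c(3, 1, 2)),
                             smoothing = "gcv")
  expect_lte(k3$edf, 2 + 1e-4)
})
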