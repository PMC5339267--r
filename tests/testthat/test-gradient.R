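test_that("refractive index converts to density and round-trips", {
  # default CsCl calibration line evaluated at RI 1.4000
  expect_equal(density_from_ri(1.4000), 1.70674, tolerance = 1e-9)
  # linear invertibility
  ri <- ri_from_density(1.72)
  expect_equal(density_from_ri(ri), 1.72, tolerance = 1e-9)
  # degenerate calibration: constant output
  expect_equal(density_from_ri(1.40, slope = 0, intercept = 1.7), 1.7)
  expect_error(density_from_ri(1.50), "plausible CsCl range")
})

test_that("ratio of quantities normalizes to a maximum of exactly 1", {
  p <- make_profile(c(100, 400, 200))
  expect_equal(p$ratio_of_quantities[order(p$fraction)], c(0.25, 1, 0.5))
  expect_identical(max(p$ratio_of_quantities), 1)

  # ties at the maximum both get 1
  p2 <- make_profile(c(5, 5, 1))
  expect_equal(sum(p2$ratio_of_quantities == 1), 2L)

  # single fraction
  p3 <- gradient_profile(1, density = 1.72, copies = 7)
  expect_equal(p3$ratio_of_quantities, 1)

  # all-zero copies is rejected
  expect_error(make_profile(c(0, 0, 0)), "zero copies")
})

test_that("normalization is idempotent and scale-invariant", {
  set.seed(11)
  copies <- runif(12, 0, 1e6)
  p <- make_profile(copies)
  expect_equal(normalize_quantities(p)$ratio_of_quantities,
               p$ratio_of_quantities)
  p_scaled <- make_profile(copies * 37.5)
  expect_equal(p_scaled$ratio_of_quantities, p$ratio_of_quantities)
})

test_that("heavy-window selection is a closed interval, monotone in window", {
  p <- gradient_profile(1:4, density = c(1.750, 1.741, 1.730, 1.720),
                        copies = c(1, 2, 3, 4))
  w <- heavy_window(1.725, 1.742)
  sel <- select_heavy(p, w)
  expect_equal(nrow(sel), 2L)
  # boundary density exactly at density_min is included
  w2 <- heavy_window(1.720, 1.742)
  expect_true(1.720 %in% select_heavy(p, w2)$density)
  # whole-gradient window selects everything
  expect_equal(nrow(select_heavy(p, heavy_window(1.60, 1.85))), 4L)
  # monotone: enlarging the window never drops fractions
  expect_true(all(sel$fraction %in% select_heavy(p, w2)$fraction))
  # empty selection is legal but warned
  expect_warning(select_heavy(p, heavy_window(1.80, 1.84)), "no fractions")
})

test_that("density shift converts to percent incorporation linearly", {
  r <- incorporation_from_shift(0.01, 0.036)
  expect_identical(r$percent, 28)
  expect_equal(r$percent_raw, 27.7778, tolerance = 1e-4)
  expect_equal(incorporation_from_shift(0)$percent_raw, 0)
  expect_equal(incorporation_from_shift(0.036, 0.036)$percent_raw, 100)
  # linearity in the shift
  d <- seq(0, 0.03, 0.005)
  raw <- incorporation_from_shift(d, 0.036)$percent_raw
  expect_equal(diff(raw), rep(raw[2] - raw[1], length(d) - 1))
  expect_error(incorporation_from_shift(0.01, 0), "positive")
})

test_that("default heavy window tracks the labeled gradient's dense excess", {
  # unlabeled peaks mid-gradient; labeled adds a dense shoulder
  d <- seq(1.75, 1.69, length.out = 13)
  base <- dnorm(d, 1.715, 0.008)
  shoulder <- 0.6 * dnorm(d, 1.735, 0.006)
  p12 <- gradient_profile(1:13, density = d, copies = 1e5 * base,
                          treatment = "12C")
  p13 <- gradient_profile(1:13, density = d,
                          copies = 1e5 * (0.7 * base + shoulder),
                          treatment = "13C")
  w <- default_heavy_window(p12, p13)
  expect_s3_class(w, "heavy_window")
  # the window straddles the shoulder center, not the unlabeled peak
  expect_true(w$density_min > 1.715)
  expect_true(w$density_max >= 1.735)
  expect_lte(w$density_max - w$density_min, 0.015 + 1e-9)
})
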