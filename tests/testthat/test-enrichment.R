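test_that("window copy numbers match direct products on tiny cases", {
  # one fraction, copies 1000, proportions 0.2/0.8
  p <- gradient_profile(1, density = 1.73, copies = 1000)
  tt <- make_taxa(matrix(c(20, 80), ncol = 1), taxa = c("X", "Y"))
  w <- heavy_window(1.72, 1.74)
  expect_equal(taxon_copy_numbers(tt, p, w), c(X = 200, Y = 800))

  # two fractions, copies 100/300, equal proportions -> weighted sum
  p2 <- gradient_profile(1:2, density = c(1.735, 1.725),
                         copies = c(100, 300))
  tt2 <- make_taxa(matrix(c(5, 5, 15, 15), nrow = 2), taxa = c("X", "Y"))
  expect_equal(taxon_copy_numbers(tt2, p2, w)[["X"]], 200)
})

test_that("window copy numbers equal the brute-force oracle on random instances", {
  set.seed(202)
  for (i in 1:100) {
    n_tax <- sample(2:5, 1)
    n_frac <- sample(3:6, 1)
    counts <- matrix(rpois(n_tax * n_frac, 40), nrow = n_tax)
    tt <- make_taxa(counts)
    p <- make_profile(runif(n_frac, 1e3, 1e6))
    bounds <- sort(runif(2, 1.69, 1.75))
    if (diff(bounds) < 0.005) bounds[2] <- bounds[1] + 0.02
    w <- heavy_window(bounds[1], bounds[2])
    got <- suppressWarnings(taxon_copy_numbers(tt, p, w))
    want <- suppressWarnings(oracle_taxon_copies(tt, p, w))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("mismatched fraction identifiers are rejected, listing them", {
  p <- gradient_profile(1:3, density = c(1.74, 1.73, 1.72),
                        copies = c(1, 2, 3))
  counts <- matrix(1:4, nrow = 2)
  colnames(counts) <- c("1", "9")
  tt <- fraction_taxon_table(counts, taxa = c("X", "Y"), rank = "genus")
  expect_error(taxon_copy_numbers(tt, p, heavy_window(1.71, 1.75)),
               "missing from the taxon table: 2, 3")
})

test_that("relative copy numbers sum to one and ignore common rescaling", {
  x <- c(X = 200, Y = 800)
  expect_equal(relative_copy_numbers(x), c(X = 0.2, Y = 0.8))
  expect_equal(relative_copy_numbers(x * 10), relative_copy_numbers(x))
  expect_equal(relative_copy_numbers(c(Z = 5)), c(Z = 1))
  expect_error(relative_copy_numbers(c(A = 0, B = 0)), "positive")
})

test_that("percent enrichment follows its defining ratio", {
  expect_equal(percent_enrichment(c(t = 0.4), c(t = 0.2))[["t"]], 100)
  expect_equal(percent_enrichment(c(t = 0.3), c(t = 0.3))[["t"]], 0)
  expect_equal(percent_enrichment(c(t = 0), c(t = 0.3))[["t"]], -100)
  # rel12 = 0 with positive rel13 is undefined, marked NA
  out <- percent_enrichment(c(a = 0.5, b = 0.5), c(a = 0, b = 1))
  expect_true(is.na(out[["a"]]))
  expect_false(is.na(out[["b"]]))
})

test_that("two-taxon enrichments cannot both be positive", {
  set.seed(7)
  for (i in 1:50) {
    r12 <- relative_copy_numbers(c(X = runif(1, 1, 9), Y = runif(1, 1, 9)))
    r13 <- relative_copy_numbers(c(X = runif(1, 1, 9), Y = runif(1, 1, 9)))
    e <- percent_enrichment(r13, r12)
    expect_lte(min(e), 0)
  }
})

test_that("enrichment is invariant to common rescaling of raw copies", {
  set.seed(31)
  copies12 <- runif(5, 10, 100)
  copies13 <- runif(5, 10, 100)
  names(copies12) <- names(copies13) <- letters[1:5]
  base <- percent_enrichment(relative_copy_numbers(copies13),
                             relative_copy_numbers(copies12))
  scaled <- percent_enrichment(relative_copy_numbers(copies13 * 3.7),
                               relative_copy_numbers(copies12 * 0.01))
  expect_equal(base, scaled)
})

test_that("noise threshold uses only positive values, t-interval as stated", {
  # frozen closed-form t-interval for {100, 200, 300}:
  # mean 200, se 100/sqrt(3), t(0.975, df 2) = 4.302653
  thr <- noise_threshold(c(100, 200, 300), method = "ci_mean")
  expect_equal(thr$threshold, 448.41359, tolerance = 1e-5)
  expect_equal(thr$noise, 248.41359, tolerance = 1e-5)
  expect_identical(thr$n_positive, 3L)

  # negatives and NA are excluded by definition
  thr2 <- noise_threshold(c(100, 200, 300, -50, NA), method = "ci_mean")
  expect_equal(thr2$threshold, thr$threshold)

  # zero variance: threshold collapses to the common value
  expect_equal(noise_threshold(c(70, 70, 70))$threshold, 70)

  # percentile method
  thr3 <- noise_threshold(c(100, 200, 300), method = "percentile")
  expect_equal(thr3$threshold,
               unname(quantile(c(100, 200, 300), 0.975)))

  expect_error(noise_threshold(c(5, -2)), "at least 2")
})

test_that("threshold flagging is strict and abundance-filtered", {
  rep <- data.frame(taxon = c("a", "b", "c"),
                    percent_enrichment = c(90, 84, 200),
                    abundance = c(0.5, 0.3, 0.0005))
  out <- flag_enriched(rep, threshold = 84)
  expect_identical(out$above_threshold, c(TRUE, FALSE, TRUE))
  expect_identical(out$abundance_filter_passed, c(TRUE, TRUE, FALSE))
})

test_that("class aggregation sums genus counts before proportions", {
  counts <- matrix(c(10, 30, 60,
                     40, 20, 40), nrow = 3)
  tt <- make_taxa(counts, taxa = c("g1", "g2", "g3"))
  cls <- aggregate_to_class(tt, c(g1 = "A", g2 = "A", g3 = "B"))
  expect_identical(cls$rank, "class")
  expect_equal(unname(cls$counts["A", ]), c(40, 60))
  expect_equal(unname(cls$proportions["B", ]), c(0.6, 0.4))
  expect_error(aggregate_to_class(tt, c(g1 = "A")), "g2")
})

test_that("empty fractions are flagged, not zero-filled", {
  counts <- matrix(c(1, 2, 0, 0), nrow = 2)
  tt <- make_taxa(counts)
  expect_identical(tt$empty_fractions, "2")
  expect_true(all(is.na(tt$proportions[, "2"])))
})
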