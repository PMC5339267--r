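test_that("same seed gives bit-identical outputs", {
  comm <- synthetic_community(seed = 3)
  a <- simulate_gradient_pair(comm, sim_config(), seed = 3)
  b <- simulate_gradient_pair(comm, sim_config(), seed = 3)
  expect_identical(a, b)
  expect_identical(simulate_incubation(sim_config(), seed = 3),
                   simulate_incubation(sim_config(), seed = 3))
  # and different seeds differ
  c <- simulate_gradient_pair(comm, sim_config(), seed = 4)
  expect_false(identical(a$profile_13C$copies, c$profile_13C$copies))
})

test_that("community draws are valid and labeled taxa carry the label", {
  comm <- synthetic_community(n_taxa = 12, n_labeled = 4, seed = 9)
  expect_equal(sum(comm$abundance), 1, tolerance = 1e-9)
  expect_true(all(comm$GC_content >= 0.25 & comm$GC_content <= 0.75))
  expect_true(all(comm$atom_fraction_13C >= 0 &
                    comm$atom_fraction_13C <= 0.85))
  expect_identical(sum(comm$atom_fraction_13C > 0), 4L)
})

test_that("unlabeled band centers follow the GC-density relation", {
  cfg <- sim_config()
  expect_equal(density_from_gc(0.5, cfg), 1.660 + 0.098 * 0.5)
})

test_that("total DNA mass is conserved across fractions before noise", {
  comm <- synthetic_community(seed = 5)
  cfg <- sim_config(noise = FALSE)
  sim <- simulate_gradient_pair(comm, cfg, seed = 5)
  total_weight <- sum(comm$abundance * comm$growth_response)
  expect_equal(sum(sim$profile_12C$copies),
               cfg$total_copies * total_weight, tolerance = 1e-9)
  expect_equal(sum(sim$profile_13C$copies),
               cfg$total_copies * total_weight, tolerance = 1e-9)
})

test_that("labeling shifts a taxon's band by atom fraction times full shift", {
  comm <- data.frame(
    taxon = c("lab", "unlab"), class = c("c1", "c2"),
    genus = c("g1", "g2"), abundance = c(0.5, 0.5),
    GC_content = c(0.5, 0.5), atom_fraction_13C = c(0.85, 0),
    growth_response = c(1, 1)
  )
  cfg <- sim_config(noise = FALSE)
  sim <- simulate_gradient_pair(comm, cfg, seed = 1)
  # with identical GC, the unlabeled scenario is one coincident band
  peak_of <- function(tab, prof, taxon) {
    prof$density[which.max(tab$counts[taxon, as.character(prof$fraction)])]
  }
  p12_lab <- peak_of(sim$table_12C, sim$profile_12C, "lab")
  p12_unl <- peak_of(sim$table_12C, sim$profile_12C, "unlab")
  expect_equal(p12_lab, p12_unl)
  p13_lab <- peak_of(sim$table_13C, sim$profile_13C, "lab")
  p13_unl <- peak_of(sim$table_13C, sim$profile_13C, "unlab")
  # band peak moves by 0.85 x 0.036 = 0.0306 g/mL, up to grid resolution
  grid_step <- diff(range(sim$profile_13C$density)) / (cfg$n_fractions - 1)
  expect_lt(abs((p13_lab - p13_unl) - 0.85 * cfg$full_label_shift),
            grid_step)
})

test_that("null scenario with no label and no noise gives zero enrichment", {
  comm <- synthetic_community(n_taxa = 3, n_labeled = 0, seed = 2)
  sim <- simulate_gradient_pair(comm, sim_config(noise = FALSE), seed = 2)
  expect_identical(sim$profile_12C$copies, sim$profile_13C$copies)
  w <- heavy_window(1.70, 1.77)
  e <- percent_enrichment(
    relative_copy_numbers(taxon_copy_numbers(sim$table_13C,
                                             sim$profile_13C, w)),
    relative_copy_numbers(taxon_copy_numbers(sim$table_12C,
                                             sim$profile_12C, w))
  )
  expect_equal(unname(e), rep(0, 3))
})

test_that("enrichment is monotone in atom fraction with noise off", {
  comm <- synthetic_community(n_taxa = 5, n_labeled = 1, seed = 7)
  w <- heavy_window(1.72, 1.77)  # window reaching the gradient's dense end
  prev <- -Inf
  for (af in seq(0, 0.8, 0.1)) {
    comm$atom_fraction_13C[1] <- af
    sim <- simulate_gradient_pair(comm, sim_config(noise = FALSE), seed = 1)
    e <- percent_enrichment(
      relative_copy_numbers(taxon_copy_numbers(sim$table_13C,
                                               sim$profile_13C, w)),
      relative_copy_numbers(taxon_copy_numbers(sim$table_12C,
                                               sim$profile_12C, w))
    )[["t01"]]
    expect_gte(e, prev - 1e-9)
    prev <- e
  }
})

test_that("simulated incubation has the designed kinetic structure", {
  cfg <- sim_config(decay_k = 0.02, initial_peptide = 0.40,
                    times = seq(0, 48, 4), noise = FALSE)
  series <- simulate_incubation(cfg, seed = 1)
  pep <- series[series$analyte == "peptide" & series$treatment == "13C" &
                  series$depth == "surface" & series$replicate == "r1", ]
  pep <- pep[order(pep$time_h), ]
  # linear decline, depleted at 0.40 / 0.02 = 20 h
  expect_equal(pep$value[pep$time_h == 0], 0.40)
  expect_equal(min(pep$time_h[pep$value < 0.01]), 20)
  fit <- fit_zero_order(pep$time_h, pep$value)
  expect_equal(fit$k, 0.02, tolerance = 1e-9)
  expect_equal(fit$depletion_time, 20)

  # killed control is flat and fits to zero rate
  kc <- series[series$analyte == "peptide" & series$treatment == "killed" &
                 series$depth == "surface" & series$replicate == "r1", ]
  kc <- kc[order(kc$time_h), ]
  expect_true(killed_control_ok(kc$value))
  expect_equal(fit_zero_order(kc$time_h, kc$value)$k, 0, tolerance = 1e-12)

  # ammonium does not decrease; cells rise during decomposition
  nh4 <- series[series$analyte == "NH4" & series$treatment == "13C" &
                  series$depth == "surface" & series$replicate == "r1", ]
  expect_true(all(diff(nh4$value[order(nh4$time_h)]) >= -1e-12))
  cells <- series[series$analyte == "cells" & series$treatment == "13C" &
                    series$depth == "surface" & series$replicate == "r1", ]
  cells <- cells[order(cells$time_h), ]
  expect_gt(cells$value[cells$time_h == 16], cells$value[cells$time_h == 0])
})

test_that("rates simulated with noise are recovered by the kinetics fit", {
  # generator-to-estimator round trip at the fitted sampling times
  set.seed(77)
  cfg <- sim_config(decay_k = 0.018, initial_peptide = 0.47,
                    times = c(0, 8, 13, 24), conc_sigma = 0.01)
  khat <- replicate(100, {
    series <- simulate_incubation(cfg, seed = sample.int(1e6, 1),
                                  depths = "surface")
    pep <- series[series$analyte == "peptide" & series$treatment == "13C" &
                    series$replicate == "r1", ]
    pep <- pep[order(pep$time_h), ]
    fit_zero_order(pep$time_h, pep$value)$k
  })
  expect_lt(abs(mean(khat) - 0.018) / 0.018, 0.10)
})

test_that("empty communities are rejected", {
  comm <- synthetic_community(seed = 1)
  expect_error(simulate_gradient_pair(comm[0, ], sim_config()), "empty")
})
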