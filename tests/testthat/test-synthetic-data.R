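test_that("component bank profiles are peak-normalised with correct maxima", {
  bank <- trp_two_component_bank()
  expect_equal(bank$emission(330)[1], 1.0)
  expect_equal(bank$emission(362)[2], 1.0)
  wl <- seq(280, 480, by = 1)
  em <- bank$emission(wl)
  expect_equal(wl[apply(em, 2, which.max)], c(330, 362))
  ex <- bank$excitation(seq(240, 340, by = 1))
  expect_equal(seq(240, 340)[apply(ex, 2, which.max)], c(282, 284))
  # gaussian symmetry about the maximum
  cp <- fluorophore_component("x", 280, 8, 340, 15)
  b <- make_component_bank(list(cp))
  expect_equal(b$emission(340 - 7), b$emission(340 + 7))
})

test_that("invalid fluorophore components are rejected", {
  expect_error(fluorophore_component("bad", 340, 8, 330, 15), "Stokes")
  expect_error(fluorophore_component("bad", 280, -1, 330, 15), "width")
})

test_that("TSFS simulation is multilinear and has the documented shape", {
  bank <- trp_two_component_bank()
  cube <- simulate_tsfs(bank, matrix(c(100, 40), 1), seed = 1)
  expect_equal(dim(cube$values), c(1, 31, 71))

  # doubling a sample's scores doubles its slab
  two <- simulate_tsfs(bank, matrix(c(100, 40, 200, 80), 2, byrow = TRUE),
                       seed = 1)
  expect_equal(two$values[2, , ], 2 * two$values[1, , ], tolerance = 1e-12)

  # noise-free single-component single-sample cube is rank one in t-EEM:
  # on cells observed by any two excitation rows the value ratio between
  # the rows is constant (separability), and the fitted rank-1 model is
  # essentially exact
  one <- simulate_tsfs(make_component_bank(list(
    fluorophore_component("c", 282, 9, 330, 16))), matrix(50, 1), seed = 1)
  teem <- tsfs_to_teem(one)
  sl <- teem$values[1, , ]
  msk <- teem$missing_mask[1, , ]
  for (pair in list(c(1, 10), c(5, 20), c(12, 31))) {
    com <- which(!msk[pair[1], ] & !msk[pair[2], ] & sl[pair[2], ] > 1e-8)
    ratio <- sl[pair[1], com] / sl[pair[2], com]
    expect_lt(diff(range(ratio)), 1e-10 * max(abs(ratio)))
  }
  m1 <- parafac_fit(teem, K = 1, n_starts = 1, seed = 1)
  expect_lt(m1$fit_residual_fraction, 1e-10)
})

test_that("TSFS generators are reproducible and validate inputs", {
  bank <- trp_two_component_bank()
  a <- simulate_tsfs(bank, matrix(c(1, 2), 1), noise_sd = 2, seed = 9)
  b <- simulate_tsfs(bank, matrix(c(1, 2), 1), noise_sd = 2, seed = 9)
  expect_identical(a$values, b$values)
  expect_error(simulate_tsfs(bank, matrix(c(-1, 2), 1)), "nonnegative")
  expect_error(simulate_tsfs(bank, matrix(c(1, 2), 1), exc_grid = numeric(0)),
               "empty")
})

test_that("decay expectations match the analytic model integral", {
  # noise off: bin expectation sum equals the analytic integral within 0.1%
  truth <- decay_ground_truth(lifetimes = c(1.32, 5.5),
                              amplitudes = c(1, 0.0405),
                              irf_fwhm = 0, peak_counts = NA,
                              time_range = 60, n_bins = 2048)
  dc <- simulate_decays(truth)
  dt <- dc$time_bins[2] - dc$time_bins[1]
  # the decay clock starts at the first bin center, so the histogram
  # spans model times -dt/2 .. time_range - dt/2
  tau <- c(1.32, 5.5); al <- c(1, 0.0405)
  analytic <- sum(al * tau * (exp(dt / (2 * tau)) -
                                exp(-(60 - dt / 2) / tau)))
  expect_equal(sum(dc$counts) * dt, analytic, tolerance = 1e-3)
})

test_that("degenerate decay mixtures reduce to single exponentials", {
  base <- decay_ground_truth(lifetimes = c(2, 6), amplitudes = c(1, 0),
                             irf_fwhm = 0, peak_counts = NA)
  single <- decay_ground_truth(lifetimes = 2, amplitudes = 1,
                               irf_fwhm = 0, peak_counts = NA)
  expect_equal(simulate_decays(base)$counts, simulate_decays(single)$counts)

  # delta-IRF limit: expectation proportional to the bin-center decay
  dc <- simulate_decays(decay_ground_truth(lifetimes = 3, amplitudes = 5,
                                           irf_fwhm = 0, peak_counts = NA))
  expect_equal(dc$counts, 5 * exp(-(dc$time_bins - dc$time_bins[1]) / 3))
})

test_that("decay simulation is seed-deterministic and validates sizes", {
  truth <- decay_ground_truth()
  expect_identical(simulate_decays(truth, seed = 4)$counts,
                   simulate_decays(truth, seed = 4)$counts)
  bad <- decay_ground_truth(n_bins = 3)
  expect_error(simulate_decays(bad), "n_bins")
  expect_error(simulate_decays(decay_ground_truth(lifetimes = c(2, 2),
                                                  amplitudes = c(1, 1))),
               "distinct")
})

test_that("toy structures have ideal indole geometry and round-trip PQR", {
  s <- make_toy_structure(n_trp = 1, n_decoy_atoms = 0, seed = 5)
  fr <- locate_indole(s, "A:1")
  sep <- sqrt(sum((fr$pyrrole_centroid - fr$benzene_centroid)^2))
  expect_gt(sep, 2.15 - 0.2)
  expect_lt(sep, 2.15 + 0.2)
  expect_equal(compute_den2(s, fr), 0)

  path <- withr::local_tempfile(fileext = ".pqr")
  write_structure(s, path, "pqr")
  s2 <- read_structure(path)
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-3)
  expect_equal(s2$atoms$charge, s$atoms$charge, tolerance = 1e-4)

  # reproducibility
  expect_identical(make_toy_structure(2, 30, seed = 7)$atoms,
                   make_toy_structure(2, 30, seed = 7)$atoms)
})
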