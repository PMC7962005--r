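test_that("the decay model is linear, causal and exact in the delta limit", {
  tb <- (1:512 - 0.5) * 33.3 / 512
  ir0 <- delta_irf(tb)
  m1 <- model_decay(list(lifetimes = 4, amplitudes = 2), ir0, tb)
  expect_equal(m1, 2 * exp(-(tb - tb[1]) / 4))

  # degenerate two-component equals the one-component model
  m2 <- model_decay(list(lifetimes = c(4, 1), amplitudes = c(2, 0)), ir0, tb)
  expect_equal(m2, m1)

  # linearity in the amplitudes
  ir <- gaussian_irf(tb, 0.5)
  a <- model_decay(list(lifetimes = c(1.5, 5), amplitudes = c(1, 0.2)), ir, tb)
  b <- model_decay(list(lifetimes = c(1.5, 5), amplitudes = c(2, 0.4)), ir, tb)
  expect_equal(b, 2 * a, tolerance = 1e-12)
  expect_error(model_decay(list(lifetimes = -1, amplitudes = 1), ir, tb),
               "positive")
})

test_that("the reconvolution model matches an oversampled direct convolution", {
  tb <- (1:1024 - 0.5) * 33.3 / 1024
  ir <- gaussian_irf(tb, 0.5)
  tau <- c(1.32, 5.5); al <- c(1, 0.0405)
  m <- model_decay(list(lifetimes = tau, amplitudes = al), ir, tb)
  oracle <- reconvolution_oracle(tau, al, fwhm = 0.5, time_bins = tb,
                                 oversample = 10)
  expect_lt(max(abs(m - oracle)) / max(oracle), 1e-3)
})

test_that("a noiseless single exponential is recovered to 0.1 percent", {
  tb <- (1:1024 - 0.5) * 33.3 / 1024
  ir <- delta_irf(tb)
  expct <- model_decay(list(lifetimes = 4, amplitudes = 20000), ir, tb)
  dc <- structure(list(time_bins = tb, counts = expct, channel_id = 1,
                       em_range = c(NA, NA)), class = "decay_curve")
  f <- fit_decay(dc, ir, n_components = 1, seed = 1)
  expect_lt(abs(f$lifetimes - 4) / 4, 1e-3)
})

test_that("two-component decays at 20k peak counts are recovered", {
  truth <- decay_ground_truth()   # tau 1.32/5.5, fractions 86/14.5
  dc <- simulate_decays(truth, seed = 42)
  f <- fit_decay(dc, dc$irf, n_components = 2, seed = 1)
  expect_lt(abs(f$lifetimes[1] - 1.32) / 1.32, 0.05)
  expect_lt(abs(f$lifetimes[2] - 5.5) / 5.5, 0.05)
  expect_lt(abs(f$intensity_fractions[1] - 86), 3)
  expect_gt(f$chi2_red, 0.8)
  expect_lt(f$chi2_red, 1.6)
  expect_equal(sum(f$intensity_fractions), 100)
  expect_gte(f$tau_av, min(f$lifetimes))
  expect_lte(f$tau_av, max(f$lifetimes))
})

test_that("pure-background curves are flagged degenerate", {
  tb <- (1:512 - 0.5) * 33.3 / 512
  set.seed(11)
  dc <- structure(list(time_bins = tb, counts = rpois(512, 200),
                       channel_id = 1, em_range = c(NA, NA)),
                  class = "decay_curve")
  f <- fit_decay(dc, gaussian_irf(tb, 0.5), n_components = 1, seed = 2)
  expect_true(f$degenerate)
})

test_that("model selection stops when extra components stop paying", {
  one <- decay_ground_truth(lifetimes = 4, intensity_fractions = 100)
  dc1 <- simulate_decays(one, seed = 3)
  s1 <- select_model(dc1, dc1$irf, seed = 3, n_starts = 3)
  expect_equal(s1$n_components, 1)
  expect_equal(nrow(s1$candidates), 2)   # tried 2, rejected it

  two <- decay_ground_truth()            # tau ratio > 4
  dc2 <- simulate_decays(two, seed = 5)
  s2 <- select_model(dc2, dc2$irf, seed = 5, n_starts = 3)
  expect_equal(s2$n_components, 2)
})

test_that("close long lifetimes are only resolved at high counts", {
  # three components with two nearly equal long lifetimes: at moderate
  # counts the parsimonious two-component description wins
  truth <- decay_ground_truth(lifetimes = c(1.8, 6.0, 6.6),
                              intensity_fractions = c(31, 19, 50),
                              peak_counts = 20000)
  dc <- simulate_decays(truth, seed = 7)
  s <- select_model(dc, dc$irf, seed = 7, n_starts = 3)
  expect_lte(s$n_components, 3)
  expect_gte(s$n_components, 2)
  # the two-component fit still reproduces the mean lifetime well
  f2 <- fit_decay(dc, dc$irf, n_components = 2, seed = 7)
  true_tau_av <- weighted_lifetimes(c(1.8, 6.0, 6.6),
                                    fractions = c(31, 19, 50))$tau_av
  expect_lt(abs(f2$tau_av - true_tau_av) / true_tau_av, 0.1)
})

test_that("lifetime weighting reproduces printed-table arithmetic", {
  ref <- mts_reference_lifetimes()
  for (i in seq_len(nrow(ref))) {
    wl <- weighted_lifetimes(ref$lifetimes[[i]], fractions = ref$fractions[[i]])
    expect_equal(round(wl$tau_av, 2), round(ref$tau_av_printed[i], 2),
                 tolerance = 0.011)
  }
  # single component
  expect_equal(weighted_lifetimes(3.3, fractions = 100)$tau_av, 3.3)
  # intensity fractions from raw amplitudes
  wl <- weighted_lifetimes(c(1, 3), amplitudes = c(1, 1))
  expect_equal(wl$fractions, c(25, 75))
  # invariance under common amplitude rescaling
  wl2 <- weighted_lifetimes(c(1, 3), amplitudes = c(7, 7))
  expect_equal(wl2$tau_av, wl$tau_av)
  expect_error(weighted_lifetimes(c(1, 2), amplitudes = c(0, 0)), "positive")
})

test_that("channel tables carry all fits and round-trip through text", {
  chans <- emission_channels(n = 11)
  fits <- lapply(seq_len(11), function(i) {
    structure(list(n_components = if (i <= 6) 2L else 1L,
                   lifetimes = if (i <= 6) c(1.4, 5.6) else 6.7,
                   amplitudes = if (i <= 6) c(1, 0.04) else 1,
                   intensity_fractions = if (i <= 6) c(86, 14) else 100,
                   tau_av = 2, chi2_red = 1.1, background = 0,
                   degenerate = FALSE, channel_id = chans$channel[i],
                   em_range = c(chans$em_lo[i], chans$em_hi[i])),
              class = "decay_fit")
  })
  tab <- tabulate_channels(fits)
  expect_equal(nrow(tab), 11)
  expect_true(all(is.na(tab$tau_2[7:11])))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_channel_table(tab, path)
  expect_true(any(grepl("\t-\t", readLines(path))))
  back <- read_channel_table(path)
  expect_equal(back$tau_av, tab$tau_av)
  expect_equal(back$tau_1, tab$tau_1)
  expect_true(all(is.na(back$a_3)))
})

test_that("the default detector layout spans 300 nm upward in 12.5 nm steps", {
  ch <- emission_channels()
  expect_equal(nrow(ch), 16)
  expect_equal(ch$em_lo[1], 300)
  expect_equal(unique(diff(ch$em_lo)), 12.5)
})
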