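# shared fixtures, built in code at test time

# small gaussian helper for constructing spectra
gauss <- function(x, mu, sd) exp(-0.5 * ((x - mu) / sd)^2)

# a compact two-component TSFS cube (coarser grids than the defaults,
# for fast PARAFAC tests); returns cube plus ground truth
small_two_comp_cube <- function(n_samples = 8, noise_sd = 0, seed = 1) {
  bank <- trp_two_component_bank()
  set.seed(seed)
  scores <- matrix(stats::runif(n_samples * 2, 50, 150), ncol = 2)
  cube <- simulate_tsfs(bank, scores,
                        exc_grid = seq(260, 320, by = 4),
                        offset_grid = seq(20, 160, by = 2),
                        noise_sd = noise_sd, seed = seed)
  list(cube = cube, scores = scores, bank = bank,
       em_true = c(330, 362), exc_true = c(282, 284))
}

# independent trapezoid-rule reconvolution oracle at `oversample`x finer
# resolution, with exact integration endpoints (the causal jump at s = t)
reconvolution_oracle <- function(lifetimes, amplitudes, fwhm, time_bins,
                                 oversample = 10) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  center <- 2 * fwhm
  dt <- time_bins[2] - time_bins[1]
  dtf <- dt / oversample
  tf <- seq(dtf / 2, max(time_bins) + dt / 2, by = dtf)
  dens <- function(s) exp(-0.5 * ((s - center) / sigma)^2)
  norm <- sum(dens(tf)) * dtf
  dfun <- function(u) {
    acc <- 0
    for (n in seq_along(lifetimes)) acc <- acc + amplitudes[n] * exp(-u / lifetimes[n])
    acc
  }
  vapply(time_bins, function(t) {
    s <- c(0, tf[tf < t], t)
    y <- dens(s) / norm * dfun(t - s)
    sum((y[-1] + y[-length(y)]) / 2 * diff(s))
  }, numeric(1))
}

# brute-force Den2: plain double loop over (candidate atom, ring atom)
brute_force_den2 <- function(s, chain, resno, cutoff = 7.5) {
  a <- s$atoms
  own <- a$chain == chain & a$resno == resno & a$resid == "TRP"
  ring_names <- c("CG", "CD1", "NE1", "CE2", "CD2", "CE3", "CZ2", "CZ3", "CH2")
  ring <- a[own & a$name %in% ring_names, ]
  count <- 0L
  for (i in which(!own & a$element != "H" & !(a$resid %in% c("HOH", "WAT")))) {
    dmin <- Inf
    for (r in seq_len(nrow(ring))) {
      dmin <- min(dmin, sqrt((a$x[i] - ring$x[r])^2 +
                               (a$y[i] - ring$y[r])^2 +
                               (a$z[i] - ring$z[r])^2))
    }
    if (dmin < cutoff) count <- count + 1L
  }
  count
}
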