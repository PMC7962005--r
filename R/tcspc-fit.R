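#' Fit a TCSPC decay with n IRF-convolved exponentials
#'
#' Weighted nonlinear least squares with Neyman (Poisson) weights
#' `1 / max(counts, 1)`, multi-started from seed-controlled lifetime
#' initialisations.  The fit window starts where the rising edge first
#' reaches 1 percent of the peak and runs to the last bin.  Lifetimes are
#' optimised on a log scale (positivity), amplitudes likewise; a
#' nonnegative constant background is fitted alongside.
#'
#' If two fitted lifetimes collapse to within 1 percent of each other the
#' fit is reported as degenerate and refitted with one component fewer.
#' A fit whose decaying part contributes less than 1 percent of the
#' background level (a pure-background curve), or whose longest lifetime
#' exceeds three times the observation window (indistinguishable from a
#' constant), is also flagged degenerate.
#'
#' @param curve a `decay_curve` (peak counts must be at least 100).
#' @param irf an [irf()] object on the same grid.
#' @param n_components 1, 2 or 3 exponentials.
#' @param seed integer controlling the multi-start initialisations.
#' @param n_starts number of random starts.
#' @return a `decay_fit`: lifetimes (ns, ascending), amplitudes,
#'   `intensity_fractions` (percent), `tau_av` (ns), `chi2_red`,
#'   `background`, `residuals` (weighted, fit window), `degenerate` flag.
#' @export
fit_decay <- function(curve, irf, n_components = 2, seed = 1L, n_starts = 5L) {
  counts <- curve$counts
  tb <- curve$time_bins
  .assert(max(counts) >= 100, "insufficient counts: peak must be >= 100")
  .assert(n_components %in% 1:3, "n_components must be 1, 2 or 3")

  peak <- which.max(counts)
  rising <- which(counts[seq_len(peak)] >= 0.01 * counts[peak])
  i0 <- if (length(rising)) rising[1] else 1L
  win <- i0:length(counts)
  w <- 1 / pmax(counts[win], 1)

  resid_fn <- function(par) {
    n <- n_components
    p <- list(lifetimes = exp(par[seq_len(n)]),
              amplitudes = exp(par[n + seq_len(n)]),
              background = par[2 * n + 1]^2)
    m <- model_decay(p, irf, tb)
    (counts[win] - m[win]) * sqrt(w)
  }

  dt <- tb[2] - tb[1]
  t_max <- tb[length(tb)]
  set.seed(derive_seed(seed, "tcspc-fit"))
  best <- NULL
  for (s in seq_len(n_starts)) {
    # log-spaced lifetime guesses spanning the histogram, jittered
    tau0 <- exp(seq(log(3 * dt), log(t_max / 4), length.out = n_components + 2))
    tau0 <- tau0[1 + seq_len(n_components)] * exp(stats::rnorm(n_components, 0, 0.3))
    a0 <- rep(max(counts) / n_components, n_components)
    par0 <- c(log(tau0), log(a0), sqrt(max(min(counts), 1e-3)))
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  .assert(!is.null(best), "all fit starts failed")

  n <- n_components
  par <- best$fit$par
  tau <- exp(par[seq_len(n)])
  alpha <- exp(par[n + seq_len(n)])
  bg <- par[2 * n + 1]^2
  ord <- order(tau)
  tau <- tau[ord]; alpha <- alpha[ord]

  degenerate <- FALSE
  if (n > 1 && any(tau[-1] / tau[-n] < 1.01)) {
    sub <- fit_decay(curve, irf, n_components = n - 1, seed = seed,
                     n_starts = n_starts)
    sub$degenerate <- TRUE
    return(sub)
  }
  # pure-background or unresolvable curves: the decaying part is
  # negligible against the baseline, or a lifetime far exceeds the
  # observation window (indistinguishable from a constant)
  m_decay <- model_decay(list(lifetimes = tau, amplitudes = alpha), irf, tb)
  if (bg > 0 && max(m_decay) < 0.01 * bg) degenerate <- TRUE
  if (max(tau) > 3 * (tb[length(tb)] - tb[1])) degenerate <- TRUE

  chi2_red <- best$rss / (length(win) - (2 * n + 1))
  wl <- weighted_lifetimes(tau, amplitudes = alpha, mode = "intensity")
  structure(list(n_components = n, lifetimes = tau, amplitudes = alpha,
                 intensity_fractions = wl$fractions, tau_av = wl$tau_av,
                 chi2_red = chi2_red, background = bg,
                 residuals = best$fit$fvec, fit_window = win,
                 degenerate = degenerate, channel_id = curve$channel_id,
                 em_range = curve$em_range),
            class = "decay_fit")
}

#' Select the number of decay components by chi-square improvement
#'
#' Fits 1..`max_components` exponentials and stops adding components when
#' the relative drop in reduced chi-square falls below `threshold`
#' (default 10 percent); the accepted model is the smallest one before
#' that point.  All candidate chi-square values are reported.
#'
#' @inheritParams fit_decay
#' @param max_components largest model to try.
#' @param threshold minimum relative chi-square improvement required to
#'   accept an extra component.
#' @return the selected `decay_fit`, with a `candidates` data frame
#'   (`n`, `chi2_red`) attached.
#' @export
select_model <- function(curve, irf, max_components = 3, seed = 1L,
                         threshold = 0.10, n_starts = 5L) {
  fits <- list()
  chi2 <- numeric(0)
  chosen <- 1L
  for (n in seq_len(max_components)) {
    fits[[n]] <- fit_decay(curve, irf, n_components = n, seed = seed,
                           n_starts = n_starts)
    chi2[n] <- fits[[n]]$chi2_red
    if (n > 1) {
      if (is.finite(chi2[n - 1]) &&
          chi2[n] < (1 - threshold) * chi2[n - 1] &&
          fits[[n]]$n_components == n) {
        chosen <- n
      } else break
    }
  }
  out <- fits[[chosen]]
  out$candidates <- data.frame(n = seq_along(chi2), chi2_red = chi2)
  out
}

#' Component fractions and intensity-weighted mean lifetime
#'
#' In intensity mode the fractions are `a_n = 100 * alpha_n * tau_n /
#' sum(alpha_m * tau_m)` and the mean lifetime is
#' `tau_av = sum(a_n / 100 * tau_n)`; amplitude mode uses
#' `a_n = 100 * alpha_n / sum(alpha_m)`.  When printed-style `fractions`
#' are supplied directly they are taken as given — deliberately not
#' renormalised to exactly 100 — so that mean lifetimes recomputed from
#' published tables match their printed arithmetic.
#'
#' @param lifetimes component lifetimes (ns).
#' @param amplitudes raw pre-exponential amplitudes (used unless
#'   `fractions` is given).
#' @param fractions percent fractions taken as given.
#' @param mode `"intensity"` or `"amplitude"` weighting for the
#'   amplitude-based path.
#' @return list with `fractions` (percent) and `tau_av` (ns).
#' @examples
#' weighted_lifetimes(c(1.32, 5.5), fractions = c(86, 14.5))$tau_av  # 1.93
#' @export
weighted_lifetimes <- function(lifetimes, amplitudes = NULL, fractions = NULL,
                               mode = c("intensity", "amplitude")) {
  mode <- match.arg(mode)
  .assert(all(lifetimes > 0), "lifetimes must be positive")
  if (is.null(fractions)) {
    .assert(!is.null(amplitudes) && length(amplitudes) == length(lifetimes),
            "amplitudes required and must match lifetimes in length")
    .assert(all(amplitudes >= 0) && sum(amplitudes) > 0,
            "amplitudes must be nonnegative with a positive sum")
    fractions <- if (mode == "intensity") {
      100 * amplitudes * lifetimes / sum(amplitudes * lifetimes)
    } else {
      100 * amplitudes / sum(amplitudes)
    }
  } else {
    .assert(length(fractions) == length(lifetimes),
            "fractions must match lifetimes in length")
  }
  list(fractions = fractions, tau_av = sum(fractions / 100 * lifetimes))
}

#' Standard emission channel layout of a multi-anode TCSPC detector
#'
#' @param n number of channels.
#' @param start first channel's lower emission bound (nm).
#' @param width channel width (nm).
#' @return data frame with `channel`, `em_lo`, `em_hi`.
#' @export
emission_channels <- function(n = 16, start = 300, width = 12.5) {
  lo <- start + width * (seq_len(n) - 1)
  data.frame(channel = seq_len(n), em_lo = lo, em_hi = lo + width)
}

#' Tabulate per-channel decay fits
#'
#' Produces one row per channel with the mean lifetime, up to three
#' component lifetimes and intensity fractions, and the reduced
#' chi-square.  Components absent from a fit are NA in the data frame and
#' printed as `-` by [write_channel_table()].
#'
#' @param fits list of `decay_fit` objects, one per channel.
#' @return data frame with columns `channel`, `em_lo`, `em_hi`, `tau_av`,
#'   `tau_1..3`, `a_1..3`, `chi2_red`.
#' @export
tabulate_channels <- function(fits) {
  .assert(length(fits) >= 1, "no fits supplied")
  rows <- lapply(fits, function(f) {
    tau <- rep(NA_real_, 3); a <- rep(NA_real_, 3)
    tau[seq_len(f$n_components)] <- f$lifetimes
    a[seq_len(f$n_components)] <- f$intensity_fractions
    data.frame(channel = f$channel_id, em_lo = f$em_range[1],
               em_hi = f$em_range[2], tau_av = f$tau_av,
               tau_1 = tau[1], tau_2 = tau[2], tau_3 = tau[3],
               a_1 = a[1], a_2 = a[2], a_3 = a[3], chi2_red = f$chi2_red)
  })
  do.call(rbind, rows)
}

#' Write / read a channel table (absent components printed as `-`)
#'
#' @param table a [tabulate_channels()] data frame.
#' @param path output file.
#' @export
write_channel_table <- function(table, path) {
  out <- table
  for (cn in names(out)) out[[cn]] <- ifelse(is.na(out[[cn]]), "-", format(out[[cn]], digits = 10))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_channel_table
#' @export
read_channel_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "-")
  for (cn in names(df)) df[[cn]] <- as.numeric(df[[cn]])
  df
}
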