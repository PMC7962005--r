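#' Rate parameters for tryptophan excited-state decay
#'
#' Bundles the electron-transfer distance law parameters with the other
#' first-order decay channels: radiative emission (`kr`), intersystem
#' crossing (`kisc`), solvent quenching (`ksq`) and proton transfer
#' (`kpt`).  All rates are in 1/ns to match lifetime tables; `beta`
#' defaults to 1.4 1/A, a typical through-space electron-transfer range
#' parameter.
#'
#' @param k0 ET rate at van der Waals contact (1/ns).
#' @param beta range parameter (1/A).
#' @param R0 van der Waals contact distance (A).
#' @param kr,kisc,ksq,kpt other decay rates (1/ns).
#' @return a `rate_params` list.
#' @export
rate_params <- function(k0 = 1, beta = 1.4, R0 = 3.5,
                        kr = 0.05, kisc = 0, ksq = 0, kpt = 0) {
  vals <- c(k0 = k0, beta = beta, R0 = R0, kr = kr, kisc = kisc,
            ksq = ksq, kpt = kpt)
  .assert(all(vals >= 0), "all rate parameters must be >= 0")
  structure(as.list(vals), class = "rate_params")
}

#' Electron-transfer rate at donor-acceptor distance R
#'
#' `k_ET = k0 * exp(-beta * (R - R0))` — exponential fall-off of the
#' transfer rate from the indole ring to its acceptor (typically a
#' backbone amide) with separation; monotone non-increasing in R for
#' positive beta.
#'
#' @param R donor-acceptor distance (A, >= 0).
#' @param p a [rate_params()].
#' @return rate in 1/ns.
#' @export
k_et <- function(R, p) {
  .assert(all(R >= 0), "R must be >= 0")
  p$k0 * exp(-p$beta * (R - p$R0))
}

#' Fluorescence lifetime from the rate balance
#'
#' `1/tau = kr + knr` with `knr = kisc + ksq + kpt + k_ET(R)`: the
#' observed lifetime is the reciprocal of the summed first-order decay
#' rates, so a distance change that suppresses electron transfer
#' lengthens the lifetime directly.
#'
#' @param p a [rate_params()].
#' @param R donor-acceptor distance (A).
#' @return lifetime in ns.
#' @export
lifetime_from_rates <- function(p, R) {
  total <- p$kr + p$kisc + p$ksq + p$kpt + k_et(R, p)
  .assert(all(total > 0), "all rates are zero: lifetime undefined")
  1 / total
}

#' Lifetime sensitivity table versus donor-acceptor distance
#'
#' @param p a [rate_params()].
#' @param R numeric vector of distances (A).
#' @return data frame with `R`, `k_et`, `tau`.
#' @export
lifetime_vs_distance <- function(p, R) {
  data.frame(R = R, k_et = k_et(R, p),
             tau = vapply(R, function(r) lifetime_from_rates(p, r),
                          numeric(1)))
}
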