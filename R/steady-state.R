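#' Emission spectrum container
#'
#' @param wavelengths strictly increasing wavelength grid (nm).
#' @param intensities nonnegative intensities (counts or normalised).
#' @param exc_wavelength excitation wavelength (nm), metadata.
#' @param corrections character vector of flags already applied, any of
#'   `"blank"`, `"inner_filter"`, `"normalized"`.
#' @return an `emission_spectrum` object.
#' @export
emission_spectrum <- function(wavelengths, intensities, exc_wavelength = NA_real_,
                              corrections = character()) {
  .assert(length(wavelengths) == length(intensities), "grid/intensity length mismatch")
  .assert(.is_increasing(wavelengths), "wavelengths must be strictly increasing")
  .assert(all(is.finite(intensities)), "intensities must be finite")
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 exc_wavelength = exc_wavelength,
                 corrections = corrections),
            class = "emission_spectrum")
}

#' Inner-filter correction factor
#'
#' `G = 10^((dA_exc + dA_em) / 2)`, the standard primary/secondary
#' inner-filter factor from the absorbance changes at the excitation and
#' emission wavelengths.  `G >= 1` and is monotone increasing in both
#' arguments.
#'
#' @param delta_A_exc,delta_A_em nonnegative absorbance changes.
#' @return the scalar factor G.
#' @examples
#' inner_filter_factor(0.1, 0.1)  # 10^0.1 = 1.2589...
#' @export
inner_filter_factor <- function(delta_A_exc, delta_A_em) {
  .assert(all(delta_A_exc >= 0) && all(delta_A_em >= 0),
          "absorbances must be nonnegative")
  10^((delta_A_exc + delta_A_em) / 2)
}

#' Blank-subtract and inner-filter-correct a spectrum
#'
#' Corrected intensities are `(raw - blank) * G`, clipped at zero.
#'
#' @param raw,blank `emission_spectrum` objects on identical grids.
#' @param G inner-filter factor from [inner_filter_factor()].
#' @return corrected `emission_spectrum` with flags updated.
#' @export
correct_spectrum <- function(raw, blank, G = 1) {
  .assert(length(raw$wavelengths) == length(blank$wavelengths) &&
            all(raw$wavelengths == blank$wavelengths),
          "wavelength grids must match")
  out <- raw
  out$intensities <- pmax((raw$intensities - blank$intensities) * G, 0)
  out$corrections <- union(raw$corrections,
                           c("blank", if (G != 1) "inner_filter"))
  out
}

#' Normalise a spectrum to unit maximum
#'
#' Divides by the maximum intensity so the peak equals 1; intensity
#' ratios between wavelengths are preserved and the operation is
#' idempotent and scale-invariant.
#'
#' @param s an `emission_spectrum` with positive maximum.
#' @return normalised `emission_spectrum`.
#' @export
normalize_spectrum <- function(s) {
  m <- max(s$intensities)
  .assert(m > 0, "cannot normalise an all-zero spectrum")
  s$intensities <- s$intensities / m
  s$corrections <- union(s$corrections, "normalized")
  s
}

#' Difference of two normalised spectra
#'
#' Pointwise `a - b` of two unit-normalised spectra on the same grid,
#' reporting the wavelengths of the minimum and maximum of the
#' difference.  Normalisation first is part of the procedure: the
#' difference of raw spectra would be dominated by concentration, not
#' band shape.
#'
#' @param a,b normalised `emission_spectrum` objects on one grid.
#' @return list with `wavelengths`, `difference`, `argmin_nm`,
#'   `argmax_nm` (the extrema are NA for an identically zero difference).
#' @export
difference_spectrum <- function(a, b) {
  .assert("normalized" %in% a$corrections && "normalized" %in% b$corrections,
          "difference_spectrum requires normalised inputs")
  .assert(length(a$wavelengths) == length(b$wavelengths) &&
            all(a$wavelengths == b$wavelengths),
          "wavelength grids must match")
  d <- a$intensities - b$intensities
  if (all(d == 0)) {
    argmin <- argmax <- NA_real_
  } else {
    argmin <- a$wavelengths[which.min(d)]
    argmax <- a$wavelengths[which.max(d)]
  }
  list(wavelengths = a$wavelengths, difference = d,
       argmin_nm = argmin, argmax_nm = argmax)
}

#' Locate emission maxima and shoulders
#'
#' The spectrum is Savitzky-Golay smoothed and differentiated.  Maxima
#' are sign changes of the first derivative (+ to -).  A shoulder is an
#' interior local minimum of the absolute first derivative at which the
#' derivative itself stays bounded away from zero: such a point is a
#' zero-crossing of the second derivative on a monotone flank, which is
#' how a partially merged minor band manifests.  (The two plain
#' inflection points of a single clean band are local *maxima* of the
#' absolute derivative and are not reported.)
#'
#' @param s a normalised `emission_spectrum`.
#' @param shoulder_sensitivity fraction of the flank's peak slope below
#'   which a slope dip counts as a shoulder (default 0.8: the slope must
#'   dip below 80 percent of the surrounding flank slope).
#' @param sg_window,sg_order Savitzky-Golay smoothing parameters.
#' @return data frame with `wavelength` and `kind` (`"maximum"` or
#'   `"shoulder"`); empty for featureless spectra.
#' @export
locate_bands <- function(s, shoulder_sensitivity = 0.8,
                         sg_window = 7, sg_order = 2) {
  y <- s$intensities
  if (max(y) - min(y) < 1e-12) {
    return(data.frame(wavelength = numeric(0), kind = character(0)))
  }
  wl <- s$wavelengths
  n <- length(y)
  if (n >= sg_window) y <- signal::sgolayfilt(y, p = sg_order, n = sg_window)
  d1 <- c(NA, diff(y)) / c(NA, diff(wl))

  res <- data.frame(wavelength = numeric(0), kind = character(0))
  # maxima: derivative sign change + -> -
  for (i in 2:(n - 1)) {
    if (!is.na(d1[i]) && !is.na(d1[i + 1]) && d1[i] > 0 && d1[i + 1] <= 0) {
      res <- rbind(res, data.frame(wavelength = wl[i], kind = "maximum"))
    }
  }
  # shoulders: interior dips of |d1| with d1 bounded away from zero
  a <- abs(d1)
  slope_floor <- 0.02 * max(a, na.rm = TRUE)
  for (i in 3:(n - 2)) {
    if (any(is.na(a[(i - 1):(i + 1)]))) next
    if (a[i] < a[i - 1] && a[i] <= a[i + 1] && a[i] > slope_floor &&
        sign(d1[i - 1]) == sign(d1[i + 1])) {
      # the dip must be pronounced relative to the flank around it
      lo <- max(2, i - 5); hi <- min(n, i + 5)
      flank <- max(a[lo:hi], na.rm = TRUE)
      if (a[i] < shoulder_sensitivity * flank) {
        res <- rbind(res, data.frame(wavelength = wl[i], kind = "shoulder"))
      }
    }
  }
  res[order(res$wavelength), , drop = FALSE]
}

#' Write / read a spectrum as two-column delimited text
#'
#' @param s an `emission_spectrum`.
#' @param path output file (`wavelength_nm`, `intensity`).
#' @export
write_spectrum <- function(s, path) {
  utils::write.table(data.frame(wavelength_nm = s$wavelengths,
                                intensity = s$intensities),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, exc_wavelength = NA_real_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  emission_spectrum(df$wavelength_nm, df$intensity, exc_wavelength)
}
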