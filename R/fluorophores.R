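#' Define a fluorophore component
#'
#' A component is a separable excitation/emission band pair used by the
#' synthetic TSFS generator.  Bands are Gaussian (default) or log-normal
#' in the wavelength domain and are always peak-normalised to 1.
#'
#' @param name component label.
#' @param exc_max,em_max excitation/emission maxima in nm; `em_max` must
#'   exceed `exc_max` (positive Stokes shift).
#' @param exc_width,em_width band widths (Gaussian sigma, nm); must be
#'   positive.
#' @param band_shape `"gaussian"` or `"lognormal"`.
#' @return an object of class `fluorophore_component`.
#' @examples
#' fluorophore_component("blue", exc_max = 282, exc_width = 8,
#'                       em_max = 330, em_width = 18)
#' @export
fluorophore_component <- function(name, exc_max, exc_width, em_max, em_width,
                                  band_shape = c("gaussian", "lognormal")) {
  band_shape <- match.arg(band_shape)
  .assert(em_max > exc_max,
          "invalid component: em_max must exceed exc_max (Stokes shift)")
  .assert(exc_width > 0 && em_width > 0, "invalid component: widths must be > 0")
  structure(list(name = name, exc_max = exc_max, exc_width = exc_width,
                 em_max = em_max, em_width = em_width, band_shape = band_shape),
            class = "fluorophore_component")
}

# peak-normalised band profile on an arbitrary wavelength grid
.band_profile <- function(lambda, center, width, shape) {
  if (shape == "gaussian") {
    exp(-0.5 * ((lambda - center) / width)^2)
  } else {
    # log-normal in wavelength: asymmetric with a red tail, peak at `center`
    sdlog <- width / center
    v <- ifelse(lambda > 0,
                exp(-0.5 * ((log(lambda) - log(center)) / sdlog)^2), 0)
    v
  }
}

#' Build a bank of fluorophore components
#'
#' @param components list of [fluorophore_component()] objects.
#' @return a `component_bank` whose `$excitation(lambda)` and
#'   `$emission(lambda)` evaluate all component profiles on a grid,
#'   returning a `length(lambda) x K` matrix, each column peak-normalised
#'   to 1 at its band maximum.
#' @export
make_component_bank <- function(components) {
  .assert(length(components) >= 1, "component bank needs at least one component")
  ok <- vapply(components, inherits, logical(1), "fluorophore_component")
  .assert(all(ok), "all bank entries must be fluorophore_component objects")
  bank <- list(
    components = components,
    n = length(components),
    names = vapply(components, `[[`, character(1), "name"),
    excitation = function(lambda) {
      sapply(components, function(cp)
        .band_profile(lambda, cp$exc_max, cp$exc_width, cp$band_shape))
    },
    emission = function(lambda) {
      sapply(components, function(cp)
        .band_profile(lambda, cp$em_max, cp$em_width, cp$band_shape))
    }
  )
  structure(bank, class = "component_bank")
}

#' Two-component tryptophan emission bank
#'
#' Default bank emulating a protein whose emission resolves into a blue
#' component (buried tryptophans, emission maximum 330 nm) and a red
#' component (a solvent-relaxed tryptophan, 362 nm), with nearly
#' coincident excitation maxima at 282/284 nm.
#'
#' @param em_maxima numeric pair of emission maxima (nm).
#' @param exc_maxima numeric pair of excitation maxima (nm).
#' @return a `component_bank` with two components.
#' @export
trp_two_component_bank <- function(em_maxima = c(330, 362),
                                   exc_maxima = c(282, 284)) {
  make_component_bank(list(
    fluorophore_component("blue", exc_maxima[1], 9, em_maxima[1], 16),
    fluorophore_component("red",  exc_maxima[2], 9, em_maxima[2], 22)
  ))
}
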