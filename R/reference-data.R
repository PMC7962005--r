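#' Reference tryptophan microenvironment descriptors for mouse TS
#'
#' Published descriptor values for the five tryptophans in each subunit
#' of mouse thymidylate synthase (PDB 3IHI) and of its binary complexes
#' with dUMP (4E5O) and N4-OH-dCMP (4EIN): solvent accessibility (Acc,
#' GETAREA-derived and rescaled by 1.5), the packing density Den2
#' (neighbour atoms within 7.5 A of the indole ring), the electrostatic
#' potential over the benzene and pyrrole rings, the long-axis change
#' `delta = ep_pyrrole - ep_benzene`, and the spectral class labels
#' assigned to the Acc and Den2 values.  These rows calibrate
#' [burstein_class()] and serve as worked examples for the descriptor
#' arithmetic.
#'
#' @return data frame with one row per tryptophan per subunit per
#'   structure: `structure`, `trp`, `subunit`, `acc`, `acc_class`,
#'   `den2`, `den2_class`, `ep_benzene`, `ep_pyrrole`, `delta`.
#' @export
mts_reference_descriptors <- function() {
  rows <- rbind(
    # structure, trp, subunit, acc, acc_class, den2, den2_class, epb, epp, delta
    c("3IHI",  75, "A", 12.1, "II",   110, "II",    2.4,   7.2,  +4.8),
    c("3IHI",  84, "A", 0.9,  "S",    133, "I",     2.1,   1.5,  -0.6),
    c("3IHI", 103, "A", 7.1,  "I",    106, "II",   10,     5.3,  -4.7),
    c("3IHI", 133, "A", 1.14, "S",    143, "S",    16.85, 17.65, +0.8),
    c("3IHI", 176, "A", 0.8,  "S",    126, "I",     2,     3,    +1),
    c("3IHI",  75, "B", 12.1, "II",   111, "II",    2.7,   7.2,  +4.5),
    c("3IHI",  84, "B", 0.86, "S",    137, "I",     0.1,   1,    +0.9),
    c("3IHI", 103, "B", 5.9,  "I",    121, "I/II",  9,     4,    -5),
    c("3IHI", 133, "B", 1.2,  "S",    145, "S",    21,    22,    +1),
    c("3IHI", 176, "B", 0.65, "S",    125, "I",     2,     4.5,  +2.5),
    c("4E5O",  75, "A", 11.7, "II",   119, "II",    0.8,   6.4,  +5.6),
    c("4E5O",  84, "A", 1.3,  "S",    134, "I",    -3.6,   2,    +5.6),
    c("4E5O", 103, "A", 7.15, "I",    128, "I",     3.6,  -1.6,  -5.2),
    c("4E5O", 133, "A", 1.2,  "S",    142, "S",     6.9,   7.1,  +0.2),
    c("4E5O", 176, "A", 1.6,  "S",    132, "I",    -0.6,   1.6,  +2.2),
    c("4E5O",  75, "B", 7.9,  "I/II", 111, "II",    1.3,   6.4,  +5.1),
    c("4E5O",  84, "B", 0.9,  "S",    137, "I",     1.4,   2.65, +1.25),
    c("4E5O", 103, "B", 7,    "I",    127, "I",     2.45, -0.6,  -3.05),
    c("4E5O", 133, "B", 1.3,  "S",    140, "S",    19.45, 20,    +0.55),
    c("4E5O", 176, "B", 1.1,  "S",    131, "I",     0.75,  1.65, +0.9),
    c("4EIN",  75, "A", 12.1, "II",   109, "II",    1.4,   5.6,  +4.2),
    c("4EIN",  84, "A", 0.64, "S",    138, "I",    -1.7,  -0.2,  +1.5),
    c("4EIN", 103, "A", 7.6,  "I/II", 121, "I/II",  2.2,  -3,    -5.2),
    c("4EIN", 133, "A", 2.8,  "I",    142, "S",    19.5,  20.3,  +0.8),
    c("4EIN", 176, "A", 0.7,  "S",    127, "I",     2.4,   5.2,  +2.8),
    c("4EIN",  75, "B", 12,   "II",   113, "II",    1.4,   5.6,  +4.2),
    c("4EIN",  84, "B", 0.86, "S",    134, "I",    -0.6,   0,    +0.6),
    c("4EIN", 103, "B", 8.7,  "I/II", 118, "II",    2,    -1.4,  -3.4),
    c("4EIN", 133, "B", 2.7,  "I",    140, "S",    24.6,  25.4,  +0.8),
    c("4EIN", 176, "B", 0.8,  "S",    126, "I",    -1.7,   0.05, +1.75))
  df <- data.frame(structure = rows[, 1], trp = as.integer(rows[, 2]),
                   subunit = rows[, 3], acc = as.numeric(rows[, 4]),
                   acc_class = rows[, 5], den2 = as.integer(rows[, 6]),
                   den2_class = rows[, 7],
                   ep_benzene = as.numeric(rows[, 8]),
                   ep_pyrrole = as.numeric(rows[, 9]),
                   delta = as.numeric(rows[, 10]),
                   stringsAsFactors = FALSE)
  df
}

#' Reference multi-channel decay parameters for mouse TS and mutants
#'
#' Published multi-exponential TCSPC fit results (selected emission
#' channels) for wild-type mouse thymidylate synthase and its H190A and
#' W103G mutants: per-channel component lifetimes (ns), intensity
#' fractions (percent, as printed) and the printed intensity-weighted
#' mean lifetime.  Used as worked examples for the
#' [weighted_lifetimes()] arithmetic and as realistic ground truths for
#' decay simulations.
#'
#' @return data frame with `enzyme`, `channel`, `em_lo`, `em_hi`,
#'   `tau_av_printed` and list columns `lifetimes`, `fractions`.
#' @export
mts_reference_lifetimes <- function() {
  df <- data.frame(
    enzyme = c("mTS", "mTS", "H190A", "W103G", "W103G"),
    channel = c(2L, 5L, 3L, 2L, 4L),
    em_lo = c(303, 343, 316, 303, 329),
    em_hi = c(316, 356, 329, 316, 343),
    tau_av_printed = c(1.93, 5.0, 2.78, 2.55, 3.50),
    stringsAsFactors = FALSE)
  df$lifetimes <- list(c(1.32, 5.5), c(1.8, 6.0, 6.6), c(1.47, 5.95),
                       c(1.42, 3.97), c(2.46, 4.56))
  df$fractions <- list(c(86, 14.5), c(31, 19, 50), c(70.7, 29.3),
                       c(55.7, 44.3), c(50.3, 49.7))
  df
}
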