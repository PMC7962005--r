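#' Transform a TSFS cube to trilinear excitation-emission layout
#'
#' In TSFS coordinates each datum sits at (excitation, offset); its true
#' emission wavelength is `lambda_em = lambda_exc + delta_lambda`.  The
#' transform re-grids every (sample, excitation) row onto a common
#' emission axis by linear interpolation, which makes the cube trilinear
#' ("t-EEM") and suitable for PARAFAC.  Emission cells outside a row's
#' measured offset range carry no data and are flagged in the missing
#' mask.
#'
#' @param cube a `tsfs_cube` from [simulate_tsfs()] or [read_tsfs()].
#' @param em_grid emission grid (nm); default spans
#'   `min(exc) + min(offset)` to `max(exc) + max(offset)` at the offset
#'   grid's step.
#' @return an `eem_cube`: `sample_ids`, `exc_grid`, `em_grid`, `values`
#'   (sample x exc x em) and logical `missing_mask` of the same shape.
#' @export
tsfs_to_teem <- function(cube, em_grid = NULL) {
  exc <- cube$exc_grid; off <- cube$offset_grid
  if (is.null(em_grid)) {
    step <- min(diff(off))
    em_grid <- seq(min(exc) + min(off), max(exc) + max(off), by = step)
  }
  .assert(max(em_grid) >= min(exc) + min(off) &&
            min(em_grid) <= max(exc) + max(off),
          "em_grid does not overlap the measured emission range")
  S <- dim(cube$values)[1]; E <- length(exc); M <- length(em_grid)
  vals <- array(NA_real_, dim = c(S, E, M))
  for (s in seq_len(S)) {
    for (e in seq_len(E)) {
      vals[s, e, ] <- .interp_na(exc[e] + off, cube$values[s, e, ], em_grid)
    }
  }
  mask <- is.na(vals)
  .assert(!all(mask), "empty overlap between em_grid and measured data")
  vals[mask] <- 0
  structure(list(sample_ids = cube$sample_ids, exc_grid = exc,
                 em_grid = em_grid, values = vals, missing_mask = mask),
            class = "eem_cube")
}

#' Build an EEM cube directly (no TSFS intermediate)
#'
#' @param values sample x exc x em array.
#' @param exc_grid,em_grid wavelength grids (nm).
#' @param sample_ids optional sample labels.
#' @param missing_mask optional logical array; defaults to all observed.
#' @return an `eem_cube`.
#' @export
eem_cube <- function(values, exc_grid, em_grid, sample_ids = NULL,
                     missing_mask = NULL) {
  d <- dim(values)
  .assert(length(d) == 3, "values must be a 3-d array")
  .assert(d[2] == length(exc_grid) && d[3] == length(em_grid),
          "grid lengths must match array dimensions")
  if (is.null(missing_mask)) missing_mask <- array(FALSE, dim = d)
  structure(list(sample_ids = sample_ids %||% paste0("s", seq_len(d[1])),
                 exc_grid = exc_grid, em_grid = em_grid,
                 values = values, missing_mask = missing_mask),
            class = "eem_cube")
}

#' Pre-process a t-EEM cube
#'
#' Applies, in order: blank subtraction; replacement of the second-order
#' scatter band (cells within `scatter_window` nm of
#' `lambda_em = 2 * lambda_exc`) by linear interpolation along the
#' emission axis from the flanking cells; Savitzky-Golay smoothing along
#' emission per (sample, excitation) row.  The missing mask is
#' propagated untouched, and smoothing is skipped for rows whose
#' observed stretch is shorter than the filter window.
#'
#' @param c an `eem_cube`.
#' @param blank optional blank `eem_cube` on the same grids.
#' @param scatter_window half-width (nm) of the scatter band to excise;
#'   0 disables the correction.
#' @param sg_window odd Savitzky-Golay window length (> `sg_order`);
#'   0 disables smoothing.
#' @param sg_order Savitzky-Golay polynomial order.
#' @return the processed `eem_cube`.
#' @export
preprocess_teem <- function(c, blank = NULL, scatter_window = 10,
                            sg_window = 7, sg_order = 2) {
  if (sg_window > 0) {
    .assert(sg_window %% 2 == 1 && sg_window > sg_order,
            "sg_window must be odd and exceed sg_order")
  }
  vals <- c$values
  if (!is.null(blank)) {
    .assert(all(dim(blank$values) == dim(vals)) &&
              all(blank$exc_grid == c$exc_grid) &&
              all(blank$em_grid == c$em_grid),
            "blank grids must match")
    vals <- vals - blank$values
  }
  S <- dim(vals)[1]; E <- dim(vals)[2]
  for (s in seq_len(S)) {
    for (e in seq_len(E)) {
      row <- vals[s, e, ]
      obs <- !c$missing_mask[s, e, ]
      if (scatter_window > 0) {
        bad <- abs(c$em_grid - 2 * c$exc_grid[e]) <= scatter_window & obs
        good <- obs & !bad
        if (any(bad) && sum(good) >= 2) {
          row[bad] <- stats::approx(c$em_grid[good], row[good],
                                    xout = c$em_grid[bad], rule = 2)$y
        }
      }
      if (sg_window > 0 && sum(obs) >= sg_window) {
        idx <- which(obs)
        # observed support is contiguous by construction of the transform
        row[idx] <- signal::sgolayfilt(row[idx], p = sg_order, n = sg_window)
      }
      vals[s, e, ] <- row
    }
  }
  vals[c$missing_mask] <- 0
  c$values <- vals
  c
}
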