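#' Simulate a total synchronous fluorescence (TSFS) cube
#'
#' Generates a sample x excitation x offset intensity cube from a
#' component bank and per-sample scores.  In TSFS coordinates the
#' emission wavelength of a datum is `lambda_exc + delta_lambda`, so the
#' noiseless cube is exactly multilinear in the scores:
#' `value(s, x, d) = sum_k score[s, k] * exc_k(x) * em_k(x + d)`.
#'
#' An optional second-order scatter ridge is added along
#' `lambda_em = 2 * lambda_exc` (i.e. `delta_lambda = lambda_exc`) with a
#' Gaussian cross-section, emulating the instrument artefact that the
#' preprocessing step removes by interpolation.
#'
#' @param bank a [make_component_bank()] object.
#' @param scores nonnegative `S x K` matrix of per-sample component
#'   amplitudes.
#' @param exc_grid,offset_grid monotone increasing wavelength and offset
#'   grids in nm (defaults: 260-320 nm and 20-160 nm, both in 2 nm steps).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param scatter_on add the second-order scatter ridge?
#' @param scatter_amp,scatter_width ridge amplitude and Gaussian width (nm).
#' @param seed integer seed; the output is fully determined by the
#'   arguments and the seed.
#' @return a `tsfs_cube`: list with `sample_ids`, `exc_grid`,
#'   `offset_grid` and a 3-d `values` array.
#' @export
simulate_tsfs <- function(bank, scores,
                          exc_grid = seq(260, 320, by = 2),
                          offset_grid = seq(20, 160, by = 2),
                          noise_sd = 0, scatter_on = FALSE,
                          scatter_amp = 50, scatter_width = 6,
                          seed = 1L) {
  scores <- as.matrix(scores)
  .assert(all(is.finite(scores)) && all(scores >= 0),
          "scores must be nonnegative")
  .assert(length(exc_grid) > 0 && length(offset_grid) > 0, "empty grids")
  .assert(.is_increasing(exc_grid) && .is_increasing(offset_grid),
          "grids must be strictly increasing")
  .assert(ncol(scores) == bank$n, "scores must have one column per component")

  S <- nrow(scores); E <- length(exc_grid); D <- length(offset_grid)
  exc_prof <- matrix(bank$excitation(exc_grid), nrow = E)      # E x K
  # emission evaluated at lambda_exc + offset for every (exc, offset) pair
  em_lambda <- outer(exc_grid, offset_grid, "+")               # E x D
  slab <- matrix(0, E, D)
  base <- array(0, dim = c(S, E, D))
  for (k in seq_len(bank$n)) {
    em_k <- matrix(bank$emission(as.vector(em_lambda))[, k], E, D)
    ek <- exc_prof[, k] * em_k                                 # E x D
    for (s in seq_len(S)) base[s, , ] <- base[s, , ] + scores[s, k] * ek
  }
  if (scatter_on) {
    ridge <- scatter_amp * exp(-0.5 * (outer(exc_grid, offset_grid,
      function(x, d) (d - x) / scatter_width))^2)
    for (s in seq_len(S)) base[s, , ] <- base[s, , ] + ridge
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    base <- base + array(stats::rnorm(S * E * D, sd = noise_sd),
                         dim = c(S, E, D))
  }
  structure(list(sample_ids = rownames(scores) %||% paste0("s", seq_len(S)),
                 exc_grid = exc_grid, offset_grid = offset_grid,
                 values = base),
            class = "tsfs_cube")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a TSFS cube as long-format delimited text
#'
#' Columns: `sample`, `lambda_exc_nm`, `delta_lambda_nm`, `intensity`.
#'
#' @param cube a `tsfs_cube`.
#' @param path output file.
#' @return `read_tsfs()` returns a `tsfs_cube`.
#' @export
write_tsfs <- function(cube, path) {
  idx <- expand.grid(s = seq_along(cube$sample_ids),
                     e = seq_along(cube$exc_grid),
                     d = seq_along(cube$offset_grid))
  df <- data.frame(sample = cube$sample_ids[idx$s],
                   lambda_exc_nm = cube$exc_grid[idx$e],
                   delta_lambda_nm = cube$offset_grid[idx$d],
                   intensity = cube$values[cbind(idx$s, idx$e, idx$d)])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tsfs
#' @export
read_tsfs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ids <- unique(df$sample)
  exc <- sort(unique(df$lambda_exc_nm))
  off <- sort(unique(df$delta_lambda_nm))
  arr <- array(NA_real_, dim = c(length(ids), length(exc), length(off)))
  arr[cbind(match(df$sample, ids), match(df$lambda_exc_nm, exc),
            match(df$delta_lambda_nm, off))] <- df$intensity
  structure(list(sample_ids = ids, exc_grid = exc, offset_grid = off,
                 values = arr), class = "tsfs_cube")
}
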