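#' Derive a per-stage seed from a top-level seed
#'
#' Every stochastic stage of the pipeline receives its own deterministic
#' seed so that stages can be toggled without perturbing each other's
#' random streams.  The scheme is a fixed affine map per stage label,
#' folded into the 32-bit signed-integer range R requires.
#'
#' @param seed integer top-level seed.
#' @param stage character stage label (e.g. `"tsfs"`, `"tcspc"`).
#' @param index optional integer for repeated draws within a stage.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  ((as.integer(seed) %% 1000003L) * 1009L + h * 101L + as.integer(index)) %% 2147483587L
}

# internal: stop() with the caller's argument name in the message
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

.is_increasing <- function(x) all(diff(x) > 0)

# linear interpolation that returns NA outside the support
.interp_na <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", rule = 1)$y
}
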