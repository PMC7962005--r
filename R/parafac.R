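#' PARAFAC decomposition of an EEM cube
#'
#' Fits the trilinear model
#' `X[s, e, m] = sum_k A[s, k] * B[e, k] * C[m, k]`
#' by weighted alternating least squares.  Missing cells (the
#' unmeasured corners of a t-EEM layout) carry zero weight in every
#' factor update, so they never constrain the fit.  Updates are
#' hierarchical (columnwise, with nonnegative projection when
#' requested), the standard approach for nonnegative CP models.  The
#' best of `n_starts` random initialisations by observed residual is
#' returned.
#'
#' Scale and permutation indeterminacy are resolved deterministically:
#' excitation and emission loadings are peak-normalised to 1 with the
#' magnitude absorbed into the sample scores, and components are ordered
#' by ascending emission-loading maximum.
#'
#' Emission wavelengths observed in too small a fraction of the
#' (sample, excitation) rows — the extreme edges of a t-EEM wedge —
#' carry almost no information and would otherwise let a component fit
#' pure noise there; columns below `min_coverage` are dropped before
#' fitting and the model's `em_grid` reflects the trimmed axis.
#'
#' @param c an `eem_cube`.
#' @param K number of components (>= 1).
#' @param nonneg enforce nonnegative factors?
#' @param min_coverage minimum fraction of observed cells an emission
#'   column needs to enter the fit.
#' @param tol change in the observed relative residual fraction below
#'   which the fit stops.
#' @param max_iter maximum ALS sweeps per start.
#' @param n_starts random initialisations.
#' @param seed integer; fully determines the fit.
#' @return a `parafac_model`: `sample_scores` (S x K), `exc_loadings`
#'   (E x K, unit peak), `em_loadings` (M x K, unit peak),
#'   `fit_residual_fraction` (observed-cell residual sum of squares over
#'   observed sum of squares), `core_consistency` (percent), `converged`,
#'   plus the grids.
#' @export
parafac_fit <- function(c, K, nonneg = TRUE, tol = 1e-8, max_iter = 2000,
                        n_starts = 10, seed = 1L, min_coverage = 0.25) {
  .assert(K >= 1, "K must be >= 1")
  X <- c$values
  mask <- c$missing_mask
  em_grid <- c$em_grid
  keep <- apply(!mask, 3, mean) >= min_coverage
  if (!all(keep)) {
    .assert(any(keep), "min_coverage leaves no emission columns")
    X <- X[, , keep, drop = FALSE]
    mask <- mask[, , keep, drop = FALSE]
    em_grid <- em_grid[keep]
  }
  .assert(sum(!mask) > K * sum(dim(X)), "not enough unmasked data for the fit")
  d <- dim(X)
  S <- d[1]; E <- d[2]; M <- d[3]
  obs <- !mask
  ss_obs <- sum(X[obs]^2)
  .assert(ss_obs > 0, "cube is identically zero on observed cells")

  # masked cells are zeroed once; every update multiplies by the binary
  # weight array, so their stored values can never leak into the fit
  W <- array(as.numeric(obs), dim = d)
  Xw <- X * W
  X1 <- matrix(Xw, S, E * M)                       # e fastest, then m
  W1 <- matrix(W, S, E * M)
  X2 <- matrix(aperm(Xw, c(2, 1, 3)), E, S * M)    # s fastest, then m
  W2 <- matrix(aperm(W, c(2, 1, 3)), E, S * M)
  X3 <- matrix(aperm(Xw, c(3, 1, 2)), M, S * E)    # s fastest, then e
  W3 <- matrix(aperm(W, c(3, 1, 2)), M, S * E)

  best <- NULL
  for (st in seq_len(n_starts)) {
    set.seed(derive_seed(seed, "parafac", st))
    A <- matrix(abs(stats::rnorm(S * K)), S, K)
    B <- matrix(abs(stats::rnorm(E * K)), E, K)
    C <- matrix(abs(stats::rnorm(M * K)), M, K)
    prev <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      A <- .whals_update(A, X1, W1, .khatri_rao(C, B), nonneg)
      B <- .whals_update(B, X2, W2, .khatri_rao(C, A), nonneg)
      KR <- .khatri_rao(B, A)
      C <- .whals_update(C, X3, W3, KR, nonneg)
      res <- sum(((X3 - tcrossprod(C, KR)) * W3)^2) / ss_obs
      if (is.finite(prev) && abs(prev - res) < tol) {
        converged <- TRUE
        prev <- res
        break
      }
      prev <- res
    }
    if (is.null(best) || prev < best$res) {
      best <- list(A = A, B = B, C = C, res = prev, converged = converged)
    }
  }

  A <- best$A; B <- best$B; C <- best$C
  # absorb scale into scores; unit-peak loadings
  for (k in seq_len(K)) {
    pb <- max(abs(B[, k])); pc <- max(abs(C[, k]))
    if (pb > 0) { A[, k] <- A[, k] * pb; B[, k] <- B[, k] / pb }
    if (pc > 0) { A[, k] <- A[, k] * pc; C[, k] <- C[, k] / pc }
  }
  ord <- order(apply(C, 2, which.max))
  A <- A[, ord, drop = FALSE]; B <- B[, ord, drop = FALSE]
  C <- C[, ord, drop = FALSE]

  m <- structure(list(n_components = K, sample_scores = A,
                      exc_loadings = B, em_loadings = C,
                      exc_grid = c$exc_grid, em_grid = em_grid,
                      fit_residual_fraction = best$res,
                      converged = best$converged,
                      core_consistency = NA_real_),
                 class = "parafac_model")
  m$core_consistency <- core_consistency(
    m, eem_cube(X, c$exc_grid, em_grid, c$sample_ids, mask))
  m
}

# columnwise Khatri-Rao product: kr[, k] = kron(P[, k], Q[, k])
.khatri_rao <- function(P, Q) {
  K <- ncol(P)
  out <- matrix(0, nrow(P) * nrow(Q), K)
  for (k in seq_len(K)) out[, k] <- kronecker(P[, k], Q[, k])
  out
}

# weighted HALS update of factor F for unfolding Xu ~ F %*% t(KR), with
# binary observation weights Wu (same shape as Xu).  Each row has its own
# weighted Gram matrix of KR, assembled columnwise so the whole update is
# a handful of matrix-vector products.
.whals_update <- function(F, Xu, Wu, KR, nonneg) {
  K <- ncol(F)
  G <- matrix(0, nrow(F), K * K)       # G[i, (k-1)K+l] = sum_j w_ij KR_jk KR_jl
  for (k in seq_len(K)) {
    for (l in seq_len(k)) {
      v <- Wu %*% (KR[, k] * KR[, l])
      G[, (k - 1) * K + l] <- v
      G[, (l - 1) * K + k] <- v
    }
  }
  R <- Xu %*% KR                       # masked cells already zeroed in Xu
  for (k in seq_len(K)) {
    cross <- numeric(nrow(F))
    for (l in seq_len(K)) {
      if (l != k) cross <- cross + F[, l] * G[, (k - 1) * K + l]
    }
    val <- (R[, k] - cross) / pmax(G[, (k - 1) * K + k], 1e-12)
    F[, k] <- if (nonneg) pmax(0, val) else val
  }
  F
}

#' Core-consistency diagnostic (CONCORDIA)
#'
#' Computes the least-squares Tucker core G given the fitted PARAFAC
#' factors and compares it to the ideal superdiagonal target T (ones on
#' the superdiagonal): `100 * (1 - ||G - T||^2 / ||T||^2)`.  Values near
#' 100 indicate the trilinear model with K components is appropriate;
#' overfactored models score much lower.  Masked cells are filled from
#' the model reconstruction before the core is computed.
#'
#' @param m a `parafac_model`.
#' @param c the `eem_cube` it was fitted to.
#' @return the core consistency in percent (<= 100).
#' @export
core_consistency <- function(m, c) {
  A <- m$sample_scores; B <- m$exc_loadings; C <- m$em_loadings
  K <- m$n_components
  X <- c$values
  if (any(c$missing_mask)) {
    Xhat <- array(tcrossprod(A, .khatri_rao(C, B)), dim = dim(X))
    X[c$missing_mask] <- Xhat[c$missing_mask]
  }
  # LS core: G = X x1 pinv(A) x2 pinv(B) x3 pinv(C)
  G <- .ttm(.ttm(.ttm(X, .pinv(A), 1), .pinv(B), 2), .pinv(C), 3)
  Tgt <- array(0, dim = c(K, K, K))
  for (k in seq_len(K)) Tgt[k, k, k] <- 1
  100 * (1 - sum((G - Tgt)^2) / sum(Tgt^2))
}

.pinv <- function(A) {
  s <- svd(A)
  pos <- s$d > max(dim(A)) * .Machine$double.eps * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# mode-n tensor-times-matrix for 3-way arrays
.ttm <- function(X, Mmat, mode) {
  d <- dim(X)
  perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  Xp <- aperm(X, perm)
  Y <- Mmat %*% matrix(Xp, d[mode], prod(d[-mode]))
  Yd <- c(nrow(Mmat), d[-mode])
  Y <- array(Y, dim = Yd)
  aperm(Y, order(perm))
}

#' Choose the number of PARAFAC components
#'
#' Fits `K = 1..k_max` and returns the largest K whose core consistency
#' stays at or above `threshold_percent` and whose observed residual
#' fraction improves on the K-1 fit by at least `min_improvement`
#' (relative).  A structureless cube (K = 1 explaining less than half the
#' observed variance) is flagged.
#'
#' @param c an `eem_cube`.
#' @param k_max largest model to try.
#' @param threshold_percent core-consistency acceptance threshold.
#' @param min_improvement minimum relative residual improvement required
#'   of each extra component.
#' @param ... passed to [parafac_fit()].
#' @return list with `K`, `diagnostics` (data frame: K, core consistency,
#'   residual fraction), `no_structure` flag and the selected model.
#' @export
select_n_components <- function(c, k_max = 4, threshold_percent = 90,
                                min_improvement = 0.02, ...) {
  .assert(k_max >= 1, "k_max must be >= 1")
  fits <- vector("list", k_max)
  diag_df <- data.frame(K = integer(0), core_consistency = numeric(0),
                        residual_fraction = numeric(0))
  K_sel <- 1L
  for (K in seq_len(k_max)) {
    fits[[K]] <- parafac_fit(c, K, ...)
    diag_df <- rbind(diag_df, data.frame(
      K = K, core_consistency = fits[[K]]$core_consistency,
      residual_fraction = fits[[K]]$fit_residual_fraction))
    if (K > 1) {
      prev <- diag_df$residual_fraction[K - 1]
      improved <- (prev - diag_df$residual_fraction[K]) >=
        min_improvement * max(prev, .Machine$double.eps)
      if (diag_df$core_consistency[K] >= threshold_percent && improved) {
        K_sel <- K
      } else break
    }
  }
  no_structure <- diag_df$residual_fraction[1] > 0.5 && K_sel == 1L
  list(K = K_sel, diagnostics = diag_df, no_structure = no_structure,
       model = fits[[K_sel]])
}

#' Summarise PARAFAC components
#'
#' @param m a `parafac_model`.
#' @return data frame with per-component `exc_max_nm`, `em_max_nm` (grid
#'   argmax of each loading) and `score_share` (column sums of the
#'   scores, normalised to 1), ordered as in the model (ascending
#'   emission maximum).
#' @export
summarize_components <- function(m) {
  data.frame(
    component = seq_len(m$n_components),
    exc_max_nm = m$exc_grid[apply(m$exc_loadings, 2, which.max)],
    em_max_nm = m$em_grid[apply(m$em_loadings, 2, which.max)],
    score_share = colSums(m$sample_scores) / sum(colSums(m$sample_scores)))
}

#' Write a PARAFAC model as loading tables plus JSON metadata
#'
#' @param m a `parafac_model`.
#' @param dir output directory (created if needed).
#' @export
write_parafac_model <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(exc_nm = m$exc_grid, m$exc_loadings),
    file.path(dir, "exc_loadings.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(em_nm = m$em_grid, m$em_loadings),
    file.path(dir, "em_loadings.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    as.data.frame(m$sample_scores),
    file.path(dir, "sample_scores.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_components = m$n_components,
         fit_residual_fraction = m$fit_residual_fraction,
         core_consistency = m$core_consistency, converged = m$converged),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
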