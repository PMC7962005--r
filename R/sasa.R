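#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic rolling-probe SASA: each atom's extended sphere
#' (radius + probe) is sampled with a deterministic golden-spiral point
#' set and the fraction of points not buried inside any neighbour's
#' extended sphere gives the exposed area.
#'
#' @param s a `trp_structure` (hydrogens excluded from the calculation).
#' @param probe probe radius in A.
#' @param n_points sphere sample points per atom.
#' @return numeric vector of per-atom SASA (A^2), one entry per heavy
#'   atom row of `s$atoms` (hydrogens get NA).
#' @export
shrake_rupley <- function(s, probe = 1.4, n_points = 256) {
  a <- s$atoms
  heavy <- a$element != "H"
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  rad <- a$radius[heavy]
  .assert(all(is.finite(rad)), "missing radii: provide PQR radii or defaults")
  n <- nrow(xyz)
  # golden-spiral unit sphere points (deterministic)
  k <- seq_len(n_points)
  zf <- (2 * k - 1) / n_points - 1
  theta <- pi * (1 + sqrt(5)) * k
  sph <- cbind(sqrt(1 - zf^2) * cos(theta), sqrt(1 - zf^2) * sin(theta), zf)

  out <- numeric(n)
  ext <- rad + probe
  for (i in seq_len(n)) {
    pts <- sph * ext[i] +
      matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    # neighbours whose extended spheres can bury points of atom i
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (ext + ext[i])^2 & seq_len(n) != i)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      d2j <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2j > ext[j]^2
      if (!any(exposed)) break
    }
    out[i] <- 4 * pi * ext[i]^2 * mean(exposed)
  }
  res <- rep(NA_real_, nrow(a))
  res[heavy] <- out
  res
}

#' Tryptophan solvent accessibility (Acc)
#'
#' A GETAREA-style relative side-chain exposure: the summed SASA of the
#' residue's atoms in the full structure divided by the SASA of the same
#' atoms computed in isolation, times 100 — then divided by 1.5, the
#' empirical factor that maps such rolling-probe ratios onto the Acc
#' scale used for tryptophan spectral classification.
#'
#' @param s a `trp_structure` with radii.
#' @param trp_id `"chain:resno"` string or `c(chain, resno)` pair.
#' @param probe probe radius (A).
#' @param n_points sphere sample points per atom.
#' @return the Acc value (percent-like, >= 0).
#' @seealso [acc_from_raw()] for rescaling an externally computed ratio.
#' @export
compute_acc <- function(s, trp_id, probe = 1.4, n_points = 256) {
  id <- .parse_trp_id(trp_id)
  a <- s$atoms
  sel <- a$chain == id$chain & a$resno == id$resno
  .assert(any(sel), "trp_id not found in structure")
  .assert(all(is.finite(a$radius[sel & a$element != "H"])),
          "missing radii and no defaults available")
  sasa_all <- shrake_rupley(s, probe = probe, n_points = n_points)
  in_context <- sum(sasa_all[sel], na.rm = TRUE)
  iso <- trp_structure(a[sel, , drop = FALSE], source_format = s$source_format)
  sasa_iso <- sum(shrake_rupley(iso, probe = probe, n_points = n_points),
                  na.rm = TRUE)
  acc_from_raw(100 * in_context / sasa_iso)
}

#' Rescale a raw accessibility ratio onto the Acc scale
#'
#' `Acc = raw / 1.5` — e.g. a raw exposure of 18.15 gives Acc 12.1.
#'
#' @param raw raw rolling-probe exposure value.
#' @return Acc.
#' @export
acc_from_raw <- function(raw) {
  .assert(all(raw >= 0), "accessibility must be nonnegative")
  raw / 1.5
}

.parse_trp_id <- function(trp_id) {
  if (length(trp_id) == 1 && grepl(":", trp_id)) {
    parts <- strsplit(as.character(trp_id), ":")[[1]]
    list(chain = parts[1], resno = as.integer(parts[2]))
  } else if (length(trp_id) == 2) {
    list(chain = as.character(trp_id[[1]]), resno = as.integer(trp_id[[2]]))
  } else {
    stop("trp_id must be 'chain:resno' or c(chain, resno)", call. = FALSE)
  }
}
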