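#' Indole ring frame of a tryptophan
#'
#' The benzene centroid is the mean of CD2, CE2, CE3, CZ2, CZ3, CH2; the
#' pyrrole centroid the mean of CG, CD1, NE1, CE2, CD2 (the fused-bond
#' atoms CE2/CD2 belong to both rings).  The frame axis is the unit
#' vector from the benzene to the pyrrole centroid — the indole long
#' axis along which the electrostatic-potential change is read out.
#'
#' @param s a `trp_structure`.
#' @param trp_id `"chain:resno"` or `c(chain, resno)`.
#' @return an `indole_frame`: `trp_id`, `benzene_centroid`,
#'   `pyrrole_centroid`, `axis` (unit), `ring_atoms` (9-row data frame).
#' @export
locate_indole <- function(s, trp_id) {
  id <- .parse_trp_id(trp_id)
  a <- s$atoms
  sel <- a$resid == "TRP" & a$chain == id$chain & a$resno == id$resno
  ring <- a[sel & a$name %in% .INDOLE_ATOMS, , drop = FALSE]
  .assert(all(.INDOLE_ATOMS %in% ring$name),
          sprintf("incomplete indole ring for %s:%d", id$chain, id$resno))
  centroid <- function(names) {
    sub <- ring[match(names, ring$name), c("x", "y", "z")]
    unname(colMeans(as.matrix(sub)))
  }
  bz <- centroid(.BENZENE_ATOMS)
  py <- centroid(.PYRROLE_ATOMS)
  v <- py - bz
  structure(list(trp_id = paste0(id$chain, ":", id$resno),
                 benzene_centroid = bz, pyrrole_centroid = py,
                 axis = v / sqrt(sum(v^2)), ring_atoms = ring),
            class = "indole_frame")
}

#' Packing density around an indole ring (Den2)
#'
#' Counts the heavy atoms — excluding the tryptophan's own residue, and
#' by default excluding waters — whose minimum distance to any of the
#' nine indole heavy atoms is below the cutoff.  Ligand and decoy atoms
#' count; hydrogens never do.
#'
#' @param s a `trp_structure`.
#' @param frame an [locate_indole()] frame.
#' @param cutoff neighbour distance cutoff in A (default 7.5).
#' @param include_waters count HOH/WAT residues?
#' @return integer neighbour count.
#' @export
compute_den2 <- function(s, frame, cutoff = 7.5, include_waters = FALSE) {
  a <- s$atoms
  id <- .parse_trp_id(frame$trp_id)
  own <- a$chain == id$chain & a$resno == id$resno & a$resid == "TRP"
  cand <- !own & a$element != "H"
  if (!include_waters) cand <- cand & !(a$resid %in% c("HOH", "WAT"))
  if (!any(cand)) return(0L)
  ring <- as.matrix(frame$ring_atoms[, c("x", "y", "z")])
  pts <- as.matrix(a[cand, c("x", "y", "z")])
  # min distance from each candidate atom to the closest ring atom
  n <- nrow(pts)
  mind2 <- rep(Inf, n)
  for (r in seq_len(nrow(ring))) {
    d2 <- (pts[, 1] - ring[r, 1])^2 + (pts[, 2] - ring[r, 2])^2 +
      (pts[, 3] - ring[r, 3])^2
    mind2 <- pmin(mind2, d2)
  }
  sum(mind2 < cutoff^2)
}

#' Spectral (Burstein-style) tryptophan class from Acc or Den2
#'
#' Threshold classification onto the empirical classes ordered from
#' deeply buried, blue-emitting tryptophans to fully solvent-exposed,
#' red-emitting ones.  Acc thresholds:
#' `S < 2.0 <= I < 7.4 <= I/II < 10.0 <= II < 20.0 <= III`.
#' Den2 (higher density = more buried):
#' `S >= 140 > I >= 125 > I/II >= 121 > II`, with III below 30 and A
#' never assigned from these descriptors alone (the A and III
#' boundaries are extrapolations and are flagged).
#'
#' @param value Acc or Den2 value (nonnegative).
#' @param kind `"acc"` or `"den2"`.
#' @return the class label, one of `"A"`, `"S"`, `"I"`, `"I/II"`,
#'   `"II"`, `"III"`; extrapolated labels carry
#'   `attr(, "extrapolated") = TRUE`.
#' @examples
#' burstein_class(12.1, "acc")   # "II"
#' burstein_class(121, "den2")   # "I/II"
#' @export
burstein_class <- function(value, kind = c("acc", "den2")) {
  kind <- match.arg(kind)
  .assert(is.finite(value) && value >= 0, "value must be finite and >= 0")
  if (kind == "acc") {
    cls <- if (value < 2.0) "S"
    else if (value < 7.4) "I"
    else if (value < 10.0) "I/II"
    else if (value < 20.0) "II"
    else "III"
    if (cls == "III") attr(cls, "extrapolated") <- TRUE
  } else {
    cls <- if (value >= 140) "S"
    else if (value >= 125) "I"
    else if (value >= 121) "I/II"
    else if (value >= 30) "II"
    else "III"
    if (cls == "III") attr(cls, "extrapolated") <- TRUE
  }
  cls
}

#' Electrostatic-potential readout at the indole rings
#'
#' Samples the potential grid at the benzene and pyrrole centroids and
#' forms the long-axis descriptor `delta = ep_pyrrole - ep_benzene`: a
#' positive delta means the potential increases (electron density
#' decreases) going from the benzene to the pyrrole ring.
#'
#' @param grid a `potential_grid` (kT/e).
#' @param frame an [locate_indole()] frame; both centroids must lie
#'   inside the grid.
#' @return list with `ep_benzene`, `ep_pyrrole`, `delta` (kT/e).
#' @export
compute_ep_delta <- function(grid, frame) {
  epb <- sample_grid(grid, frame$benzene_centroid)
  epp <- sample_grid(grid, frame$pyrrole_centroid)
  list(ep_benzene = epb, ep_pyrrole = epp, delta = epp - epb)
}

#' Full descriptor table for every complete tryptophan
#'
#' One row per tryptophan per subunit with Acc, Den2, ring potentials,
#' delta and both class labels — the per-structure comparison table.
#'
#' @param s a `trp_structure` with radii (and charges if `grid` is to be
#'   generated from it).
#' @param grid optional `potential_grid`; when NULL a screened-Coulomb
#'   grid is generated from the structure's charges.
#' @param model a [solvent_model()] used when generating the grid.
#' @param probe SASA probe radius (A).
#' @return data frame with columns `trp_id`, `acc`, `den2`,
#'   `ep_benzene`, `ep_pyrrole`, `delta`, `acc_class`, `den2_class`.
#' @export
trp_descriptor_table <- function(s, grid = NULL, model = solvent_model(),
                                 probe = 1.4) {
  trps <- list_trp(s)
  trps <- trps[trps$complete, , drop = FALSE]
  .assert(nrow(trps) > 0, "no complete tryptophan residues in structure")
  if (is.null(grid)) {
    xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
    lo <- apply(xyz, 2, min) - 5
    hi <- apply(xyz, 2, max) + 5
    dims <- pmax(ceiling((hi - lo) / 1.0) + 1, 2)
    grid <- grid_from_structure(s, model, origin = lo,
                                spacing = (hi - lo) / (dims - 1), dims = dims)
  }
  rows <- lapply(seq_len(nrow(trps)), function(i) {
    tid <- paste0(trps$chain[i], ":", trps$resno[i])
    fr <- locate_indole(s, tid)
    ep <- compute_ep_delta(grid, fr)
    acc <- compute_acc(s, tid, probe = probe)
    den2 <- compute_den2(s, fr)
    data.frame(trp_id = tid, acc = acc, den2 = den2,
               ep_benzene = ep$ep_benzene, ep_pyrrole = ep$ep_pyrrole,
               delta = ep$delta,
               acc_class = as.character(burstein_class(acc, "acc")),
               den2_class = as.character(burstein_class(den2, "den2")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare two descriptor tables (e.g. apo vs complex)
#'
#' Per-tryptophan ratios `b/a` and differences `b - a` for Acc, Den2 and
#' delta, with cross-subunit means of the Acc ratio reported (tryptophans
#' are matched on `trp_id`).
#'
#' @param a,b descriptor tables from [trp_descriptor_table()] (or any
#'   data frame with `trp_id`, `acc`, `den2`, `delta`).
#' @return list with `per_trp` (data frame of ratios/differences) and
#'   `mean_acc_ratio`.
#' @export
descriptor_change <- function(a, b) {
  .assert(setequal(a$trp_id, b$trp_id), "tables cover different tryptophans")
  b <- b[match(a$trp_id, b$trp_id), , drop = FALSE]
  per <- data.frame(
    trp_id = a$trp_id,
    acc_ratio = b$acc / a$acc,
    acc_diff = b$acc - a$acc,
    den2_ratio = b$den2 / a$den2,
    den2_diff = b$den2 - a$den2,
    delta_diff = b$delta - a$delta,
    stringsAsFactors = FALSE)
  list(per_trp = per, mean_acc_ratio = mean(per$acc_ratio))
}
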