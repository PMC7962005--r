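#' Molecular structure container
#'
#' A light data-frame-backed structure: one row per atom with `name`
#' (atom name), `element`, `resid` (residue name), `resno`, `chain`,
#' coordinates in A, and per-atom `charge` (e) and `radius` (A) when the
#' source was PQR.  PDB sources leave `charge` as NA (flagged via
#' `has_charges`) and populate radii from a standard element table.
#'
#' @param atoms data frame with the columns listed above.
#' @param source_format `"PDB"`, `"PQR"` or `"synthetic"`.
#' @return a `trp_structure`.
#' @export
trp_structure <- function(atoms, source_format = "synthetic") {
  need <- c("name", "element", "resid", "resno", "chain",
            "x", "y", "z", "charge", "radius")
  .assert(all(need %in% names(atoms)), "atoms data frame misses columns")
  structure(list(atoms = atoms, source_format = source_format,
                 has_charges = any(!is.na(atoms$charge))),
            class = "trp_structure")
}

# the nine indole heavy atoms; CE2/CD2 are shared between the rings
.INDOLE_ATOMS <- c("CG", "CD1", "NE1", "CE2", "CD2", "CE3", "CZ2", "CZ3", "CH2")
.BENZENE_ATOMS <- c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
.PYRROLE_ATOMS <- c("CG", "CD1", "NE1", "CE2", "CD2")

# standard van der Waals radii by element, used when no PQR radii exist
.DEFAULT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                    P = 1.80, F = 1.47)

.element_radius <- function(element) {
  r <- .DEFAULT_RADII[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Read a structure from PDB or PQR
#'
#' PDB parsing is delegated to `bio3d::read.pdb`, PQR to
#' `bio3d::read.pqr` (whitespace-delimited dialect with per-atom charge
#' and radius).  Hydrogens are kept; downstream descriptor functions
#' filter them where their definitions require heavy atoms only.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"pqr"`.
#' @return a `trp_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "pqr")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pqr$", path, ignore.case = TRUE)) "pqr" else "pdb"
  }
  pdb <- if (format == "pqr") {
    bio3d::read.pqr(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, verbose = FALSE)
  }
  a <- pdb$atom
  element <- a$elesy
  if (is.null(element) || all(is.na(element)) || all(element == "")) {
    element <- substr(gsub("[0-9]", "", a$elety), 1, 1)
  }
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(
    name = a$elety, element = element, resid = a$resid, resno = a$resno,
    chain = chain, x = a$x, y = a$y, z = a$z,
    charge = if (format == "pqr") a$o else NA_real_,
    radius = if (format == "pqr") a$b else .element_radius(element),
    stringsAsFactors = FALSE)
  trp_structure(atoms, source_format = toupper(format))
}

#' Write a structure as PDB or PQR
#'
#' @param s a `trp_structure`.
#' @param path output file.
#' @param format `"pdb"` or `"pqr"`.
#' @export
write_structure <- function(s, path, format = c("pqr", "pdb")) {
  format <- match.arg(format)
  a <- s$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  if (format == "pqr") {
    q <- a$charge
    q[is.na(q)] <- 0
    bio3d::write.pqr(xyz = xyz, resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$name,
                     chain = a$chain, o = q, b = a$radius, file = path)
  } else {
    bio3d::write.pdb(xyz = xyz, resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$name,
                     chain = a$chain, file = path)
  }
  invisible(path)
}

#' List tryptophan residues and their completeness
#'
#' A tryptophan is usable for descriptors only when all nine indole
#' heavy atoms are present.
#'
#' @param s a `trp_structure`.
#' @return data frame with `chain`, `resno`, `complete`.
#' @export
list_trp <- function(s) {
  a <- s$atoms[s$atoms$resid == "TRP", ]
  if (nrow(a) == 0) {
    return(data.frame(chain = character(0), resno = integer(0),
                      complete = logical(0)))
  }
  key <- unique(a[, c("chain", "resno")])
  key$complete <- vapply(seq_len(nrow(key)), function(i) {
    sel <- a$chain == key$chain[i] & a$resno == key$resno[i]
    all(.INDOLE_ATOMS %in% a$name[sel])
  }, logical(1))
  key
}

# ---- ideal indole template --------------------------------------------------
# Fused regular hexagon (benzene) + regular pentagon (pyrrole) sharing the
# CD2-CE2 edge (bond length 1.40 A), in the z = 0 plane.  Benzene centroid at
# (-1.2124, 0, 0), pyrrole centroid at (+0.9635, 0, 0): separation 2.176 A.
.ideal_indole <- function() {
  ap_hex <- 1.40 * sqrt(3) / 2            # hexagon apothem
  ap_pen <- 1.40 / (2 * tan(pi / 5))      # pentagon apothem
  r_pen <- 1.40 / (2 * sin(pi / 5))       # pentagon circumradius
  cp <- ap_pen                            # pentagon centroid x
  coords <- rbind(
    CD2 = c(0, -0.70, 0),
    CE2 = c(0,  0.70, 0),
    CZ2 = c(-ap_hex, 1.40, 0),
    CH2 = c(-2 * ap_hex, 0.70, 0),
    CZ3 = c(-2 * ap_hex, -0.70, 0),
    CE3 = c(-ap_hex, -1.40, 0),
    NE1 = c(cp + r_pen * cos(2 * pi / 5),  r_pen * sin(2 * pi / 5), 0),
    CD1 = c(cp + r_pen, 0, 0),
    CG  = c(cp + r_pen * cos(2 * pi / 5), -r_pen * sin(2 * pi / 5), 0))
  coords
}

.random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a toy structure with geometrically correct indole rings
#'
#' Each tryptophan contributes the nine indole heavy atoms in ideal
#' planar fused-ring geometry (bond length 1.40 A), randomly rotated and
#' placed on a 15 A lattice so residues do not interpenetrate.  Decoy
#' atoms (carbon, residue name `DEC`) are scattered in a shell around
#' the structure with at least 2 A clearance from every existing atom.
#' Charges follow `charge_scheme`; radii come from the element table.
#'
#' @param n_trp number of tryptophan residues (>= 1).
#' @param n_decoy_atoms number of decoy atoms.
#' @param charge_scheme `"random"` (uniform in -0.5..0.5 e), `"unit"`
#'   (+1 e on every atom) or `"zero"`.
#' @param seed integer seed; output is fully reproducible.
#' @param decoy_shell radial extent (A) of the decoy cloud around the
#'   structure centroid.
#' @return a `trp_structure` (source `"synthetic"`).
#' @export
make_toy_structure <- function(n_trp = 1, n_decoy_atoms = 0,
                               charge_scheme = c("random", "unit", "zero"),
                               seed = 1L, decoy_shell = 12) {
  charge_scheme <- match.arg(charge_scheme)
  .assert(n_trp >= 1, "n_trp must be >= 1")
  set.seed(derive_seed(seed, "toy-structure"))
  tmpl <- .ideal_indole()
  rows <- list()
  for (i in seq_len(n_trp)) {
    R <- .random_rotation()
    shift <- c((i - 1) * 15, 0, 0) + stats::runif(3, -1, 1)
    xyz <- t(R %*% t(tmpl)) + matrix(shift, nrow(tmpl), 3, byrow = TRUE)
    rows[[i]] <- data.frame(
      name = rownames(tmpl),
      element = ifelse(substr(rownames(tmpl), 1, 1) == "N", "N", "C"),
      resid = "TRP", resno = i, chain = "A",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      charge = NA_real_, radius = NA_real_, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  if (n_decoy_atoms > 0) {
    center <- colMeans(atoms[, c("x", "y", "z")])
    placed <- 0
    dec <- matrix(NA_real_, n_decoy_atoms, 3)
    guard <- 0
    while (placed < n_decoy_atoms && guard < 50000) {
      guard <- guard + 1
      p <- center + stats::runif(3, -decoy_shell, decoy_shell)
      dmin <- min(sqrt((atoms$x - p[1])^2 + (atoms$y - p[2])^2 +
                         (atoms$z - p[3])^2))
      if (placed > 0) {
        dmin <- min(dmin, sqrt(min(colSums((t(dec[seq_len(placed), ,
                    drop = FALSE]) - p)^2))))
      }
      if (dmin >= 2.0) {
        placed <- placed + 1
        dec[placed, ] <- p
      }
    }
    .assert(placed == n_decoy_atoms, "could not place all decoy atoms")
    atoms <- rbind(atoms, data.frame(
      name = "C", element = "C", resid = "DEC",
      resno = n_trp + seq_len(n_decoy_atoms), chain = "A",
      x = dec[, 1], y = dec[, 2], z = dec[, 3],
      charge = NA_real_, radius = NA_real_, stringsAsFactors = FALSE))
  }
  atoms$radius <- .element_radius(atoms$element)
  atoms$charge <- switch(charge_scheme,
    random = round(stats::runif(nrow(atoms), -0.5, 0.5), 4),
    unit = rep(1, nrow(atoms)),
    zero = rep(0, nrow(atoms)))
  trp_structure(atoms, source_format = "synthetic")
}
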