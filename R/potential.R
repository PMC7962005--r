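#' Solvent model for screened-Coulomb electrostatics
#'
#' Defaults follow common continuum-electrostatics practice for proteins
#' in physiological saline: 0.15 M monovalent salt at 298.15 K, solute
#' and solvent dielectric constants 2.0 and 78.54, probe radius 1.4 A.
#'
#' @param ionic_strength mol/L of monovalent salt.
#' @param temperature K.
#' @param eps_solute,eps_solvent relative dielectric constants.
#' @param probe_radius A.
#' @return a `solvent_model` list.
#' @export
solvent_model <- function(ionic_strength = 0.15, temperature = 298.15,
                          eps_solute = 2.0, eps_solvent = 78.54,
                          probe_radius = 1.4) {
  .assert(ionic_strength >= 0, "ionic strength must be >= 0")
  .assert(temperature > 0 && eps_solute > 0 && eps_solvent > 0 &&
            probe_radius > 0, "solvent model parameters must be positive")
  structure(list(ionic_strength = ionic_strength, temperature = temperature,
                 eps_solute = eps_solute, eps_solvent = eps_solvent,
                 probe_radius = probe_radius), class = "solvent_model")
}

# Bjerrum length in Angstrom for a relative dielectric and temperature
.bjerrum_length <- function(eps, temperature) {
  e <- 1.602176634e-19          # C
  eps0 <- 8.8541878128e-12      # F/m
  kB <- 1.380649e-23            # J/K
  1e10 * e^2 / (4 * pi * eps0 * eps * kB * temperature)
}

#' Inverse Debye screening length
#'
#' `kappa = sqrt(8 * pi * l_B * n)` with `l_B` the Bjerrum length of the
#' solvent and `n` the number density of each ion of a 1:1 salt; `1/kappa`
#' is the Debye length (about 7.9 A at 0.15 M and 298.15 K, the familiar
#' ~3.04 A / sqrt(I) rule for water at room temperature).
#'
#' @param model a [solvent_model()].
#' @return kappa in 1/A (0 for zero ionic strength).
#' @export
debye_kappa <- function(model) {
  n_per_A3 <- model$ionic_strength * 6.02214076e23 * 1e-27
  lB <- .bjerrum_length(model$eps_solvent, model$temperature)
  sqrt(8 * pi * lB * n_per_A3)
}

#' Screened-Coulomb potential of point charges
#'
#' Linear superposition of Debye-Hueckel monopoles in a uniform solvent
#' dielectric: `phi = sum_i q_i * l_B * exp(-kappa * r_i) / r_i` in kT/e
#' with `l_B` the Bjerrum length (about 7.1 A in water at 298.15 K, so a
#' unit charge at one Bjerrum length contributes exactly 1 kT/e when
#' unscreened).  This is a single-dielectric model: it deliberately does
#' not reproduce the two-dielectric Poisson-Boltzmann solution of a
#' full solver, whose OpenDX output can be read instead via [read_dx()].
#'
#' @param charges list of `list(q = <e>, pos = <xyz A>)`, or a
#'   `trp_structure` (its atoms' charges are used).
#' @param point xyz coordinate (A).
#' @param model a [solvent_model()].
#' @return potential in kT/e.
#' @export
evaluate_potential <- function(charges, point, model = solvent_model()) {
  if (inherits(charges, "trp_structure")) charges <- .structure_charges(charges)
  if (length(charges) == 0) return(0)
  kappa <- debye_kappa(model)
  lB <- .bjerrum_length(model$eps_solvent, model$temperature)
  phi <- 0
  for (ch in charges) {
    r <- sqrt(sum((ch$pos - point)^2))
    .assert(r > 1e-6, "evaluation point coincides with a charge")
    phi <- phi + ch$q * lB * exp(-kappa * r) / r
  }
  phi
}

.structure_charges <- function(s) {
  a <- s$atoms
  q <- a$charge
  keep <- !is.na(q) & q != 0
  lapply(which(keep), function(i)
    list(q = q[i], pos = c(a$x[i], a$y[i], a$z[i])))
}

#' Regular 3-d potential grid
#'
#' @param values 3-d array (x, y, z order, z varying fastest on disk).
#' @param origin,spacing A triples.
#' @return a `potential_grid`.
#' @export
potential_grid <- function(values, origin, spacing) {
  d <- dim(values)
  .assert(length(d) == 3 && all(d >= 2), "grid needs >= 2 nodes per axis")
  .assert(all(spacing > 0), "spacing must be positive")
  .assert(all(is.finite(values)), "grid values must be finite")
  structure(list(origin = origin, spacing = spacing, dims = d,
                 values = values), class = "potential_grid")
}

#' Evaluate a screened-Coulomb grid from a structure's charges
#'
#' Every node gets the superposition potential of [evaluate_potential()].
#' A node coinciding with a charge (within 1e-6 A) is filled from its
#' nearest non-coincident neighbour node and flagged.
#'
#' @param structure a `trp_structure` with charges (PQR) or a charge list.
#' @param model a [solvent_model()].
#' @param origin,spacing A triples.
#' @param dims integer triple of node counts.
#' @return a `potential_grid`; flagged nodes are listed in
#'   `attr(, "filled_nodes")`.
#' @export
grid_from_structure <- function(structure, model = solvent_model(),
                                origin = c(-10, -10, -10),
                                spacing = c(1, 1, 1), dims = c(21, 21, 21)) {
  charges <- if (inherits(structure, "trp_structure")) {
    .structure_charges(structure)
  } else structure
  gx <- origin[1] + spacing[1] * (seq_len(dims[1]) - 1)
  gy <- origin[2] + spacing[2] * (seq_len(dims[2]) - 1)
  gz <- origin[3] + spacing[3] * (seq_len(dims[3]) - 1)
  vals <- array(0, dim = dims)
  filled <- matrix(numeric(0), ncol = 3)
  if (length(charges) > 0) {
    kappa <- debye_kappa(model)
    lB <- .bjerrum_length(model$eps_solvent, model$temperature)
    qs <- vapply(charges, `[[`, numeric(1), "q")
    ps <- t(vapply(charges, `[[`, numeric(3), "pos"))
    nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    phi <- numeric(nrow(nodes))
    coincident <- rep(FALSE, nrow(nodes))
    for (i in seq_along(qs)) {
      r <- sqrt((nodes[, 1] - ps[i, 1])^2 + (nodes[, 2] - ps[i, 2])^2 +
                  (nodes[, 3] - ps[i, 3])^2)
      hit <- r <= 1e-6
      coincident <- coincident | hit
      r[hit] <- Inf
      phi <- phi + qs[i] * lB * exp(-kappa * r) / r
    }
    if (any(coincident)) {
      for (j in which(coincident)) {
        dn <- rowSums((nodes - matrix(nodes[j, ], nrow(nodes), 3,
                                      byrow = TRUE))^2)
        dn[coincident] <- Inf
        phi[j] <- phi[which.min(dn)]
        filled <- rbind(filled, nodes[j, ])
      }
    }
    # expand.grid runs x fastest; reorder into an (x, y, z) array
    vals <- array(phi, dim = dims)
  }
  g <- potential_grid(vals, origin, spacing)
  attr(g, "filled_nodes") <- filled
  g
}

#' Trilinear interpolation of a potential grid
#'
#' Exact at the nodes and for any field linear in the coordinates.
#'
#' @param grid a `potential_grid`.
#' @param point xyz (A); must lie inside the grid bounding box.
#' @return interpolated value (kT/e).
#' @export
sample_grid <- function(grid, point) {
  u <- unname((point - grid$origin) / grid$spacing)
  .assert(all(u >= -1e-9) && all(u <= grid$dims - 1 + 1e-9),
          "point outside grid bounding box")
  u <- pmin(pmax(u, 0), grid$dims - 1)
  i0 <- pmin(floor(u) + 1, grid$dims - 1)   # lower node index (1-based)
  f <- u - (i0 - 1)
  v <- grid$values
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) *
         (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    acc <- acc + w * v[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  }
  acc
}
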