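test_that("the Debye screening parameter follows the closed form", {
  expect_equal(debye_kappa(solvent_model(ionic_strength = 0)), 0)
  # Debye length about 7.86 A at 0.15 M, 298.15 K in water
  expect_equal(1 / debye_kappa(solvent_model()), 7.86, tolerance = 0.01)
  # kappa scales as sqrt(I)
  k1 <- debye_kappa(solvent_model(ionic_strength = 0.15))
  k4 <- debye_kappa(solvent_model(ionic_strength = 0.60))
  expect_equal(k4 / k1, 2, tolerance = 1e-12)
})

test_that("screened-Coulomb potentials superpose and respect symmetry", {
  m0 <- solvent_model(ionic_strength = 0)
  # unit charge at one Bjerrum length gives 1 kT/e unscreened;
  # l_B computed here independently from physical constants
  lB <- 1e10 * 1.602176634e-19^2 /
    (4 * pi * 8.8541878128e-12 * 78.54 * 1.380649e-23 * 298.15)
  expect_equal(lB, 7.14, tolerance = 0.01)
  phi <- evaluate_potential(list(list(q = 1, pos = c(0, 0, 0))),
                            c(lB, 0, 0), m0)
  expect_equal(phi, 1.0, tolerance = 1e-9)

  q1 <- list(list(q = 0.7, pos = c(1, 0, 0)))
  q2 <- list(list(q = -0.3, pos = c(0, 2, 0)))
  p <- c(4, 4, 4)
  expect_equal(evaluate_potential(c(q1, q2), p),
               evaluate_potential(q1, p) + evaluate_potential(q2, p))
  neg <- list(list(q = -0.7, pos = c(1, 0, 0)), list(q = 0.3, pos = c(0, 2, 0)))
  expect_equal(evaluate_potential(neg, p), -evaluate_potential(c(q1, q2), p))
  expect_error(evaluate_potential(q1, c(1, 0, 0)), "coincides")
})

test_that("structure grids are symmetric, deterministic and spacing-consistent", {
  ch <- list(list(q = 1, pos = c(0, 0, 0)))
  g <- grid_from_structure(ch, origin = c(-4, -4, -4),
                           spacing = c(2, 2, 2), dims = c(5, 5, 5))
  # spherical symmetry: +x and -x nodes match
  expect_equal(g$values[1, 3, 3], g$values[5, 3, 3])
  expect_equal(g$values[3, 1, 3], g$values[3, 3, 1])

  empty <- grid_from_structure(list(), dims = c(3, 3, 3),
                               origin = c(0, 0, 0), spacing = c(1, 1, 1))
  expect_true(all(empty$values == 0))

  # doubling the spacing with the same extent matches at shared nodes
  # (the charge-coincident center node is excluded: it is filled from a
  # neighbour, which legitimately differs between the two grids)
  g2 <- grid_from_structure(ch, origin = c(-4, -4, -4),
                            spacing = c(4, 4, 4), dims = c(3, 3, 3))
  expect_equal(g2$values[1, 1, 1], g$values[1, 1, 1])
  expect_equal(g2$values[2, 2, 3], g$values[3, 3, 5])
  expect_equal(g2$values[3, 1, 2], g$values[5, 1, 3])

  # a charge on a node is filled from a neighbour, never infinite
  gc <- grid_from_structure(ch, origin = c(-2, -2, -2),
                            spacing = c(2, 2, 2), dims = c(3, 3, 3))
  expect_true(all(is.finite(gc$values)))
  expect_equal(nrow(attr(gc, "filled_nodes")), 1)
})

test_that("trilinear sampling is exact at nodes and on linear fields", {
  gx <- 0:4
  lin <- array(0, dim = c(5, 5, 5))
  for (i in 1:5) lin[i, , ] <- gx[i]          # field phi = x
  g <- potential_grid(lin, origin = c(0, 0, 0), spacing = c(1, 1, 1))
  expect_equal(sample_grid(g, c(2, 3, 1)), 2)
  expect_equal(sample_grid(g, c(1.37, 0.2, 3.9)), 1.37)
  expect_equal(sample_grid(g, c(0.5, 0, 0)), (0 + 1) / 2)
  expect_error(sample_grid(g, c(-1, 0, 0)), "outside")
})

test_that("trilinear interpolation converges at second order", {
  f <- function(x, y, z) exp(-0.5 * ((x - 2)^2 + (y - 2)^2 + (z - 2)^2) / 1.5)
  build <- function(h) {
    n <- as.integer(4 / h) + 1
    gx <- seq(0, 4, by = h)
    arr <- array(0, dim = c(n, n, n))
    for (i in seq_len(n)) for (j in seq_len(n))
      arr[i, j, ] <- f(gx[i], gx[j], gx)
    potential_grid(arr, c(0, 0, 0), rep(h, 3))
  }
  pts <- matrix(runif(60, 0.3, 3.7), ncol = 3)
  err <- function(g) max(abs(apply(pts, 1, function(p) sample_grid(g, p)) -
                               apply(pts, 1, function(p) f(p[1], p[2], p[3]))))
  e1 <- err(build(0.5))
  e2 <- err(build(0.25))
  expect_lt(e2 / e1, 0.35)   # ~x4 reduction expected for halved spacing
})

test_that("DX files round-trip origin, spacing, dims and values", {
  set.seed(2)
  g <- potential_grid(array(rnorm(4 * 3 * 5), dim = c(4, 3, 5)),
                      origin = c(-1.25, 0.5, 3), spacing = c(0.6, 0.8, 1.1))
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, path)
  g2 <- read_dx(path)
  expect_identical(g2$dims, g$dims)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$spacing, g$spacing)
  expect_equal(g2$values, g$values, tolerance = 1e-6)  # 6 significant digits
  # z runs fastest on disk (APBS convention)
  first_data <- readLines(path)[9]
  expect_equal(as.numeric(strsplit(first_data, " ")[[1]]),
               g$values[1, 1, 1:3], tolerance = 1e-6)
})
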