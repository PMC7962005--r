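test_that("indole frames are equivariant and antisymmetric", {
  s <- make_toy_structure(n_trp = 1, n_decoy_atoms = 0, seed = 2)
  fr <- locate_indole(s, "A:1")
  expect_equal(sqrt(sum(fr$axis^2)), 1)
  sep <- sqrt(sum((fr$pyrrole_centroid - fr$benzene_centroid)^2))
  expect_gt(sep, 1.8); expect_lt(sep, 2.5)

  # rigid rotation rotates the axis identically
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0), c(0, 0, 1))
  s2 <- s
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s2$atoms$x <- xyz[, 1]; s2$atoms$y <- xyz[, 2]; s2$atoms$z <- xyz[, 3]
  fr2 <- locate_indole(s2, "A:1")
  expect_equal(fr2$axis, as.numeric(R %*% fr$axis), tolerance = 1e-12)

  # swapping ring roles flips the axis: check via centroids
  swapped <- (fr$benzene_centroid - fr$pyrrole_centroid) /
    sqrt(sum((fr$benzene_centroid - fr$pyrrole_centroid)^2))
  expect_equal(swapped, -fr$axis)

  # incomplete ring errors out
  s3 <- s
  s3$atoms <- s3$atoms[s3$atoms$name != "CZ3", ]
  expect_error(locate_indole(s3, "A:1"), "incomplete")
  expect_false(list_trp(s3)$complete[1])
})

test_that("Den2 counts neighbours with a sharp 7.5 A boundary", {
  s <- make_toy_structure(n_trp = 1, n_decoy_atoms = 0, seed = 3)
  fr <- locate_indole(s, "A:1")
  ring <- as.matrix(fr$ring_atoms[, c("x", "y", "z")])
  # place one decoy at exactly 7.4 then 7.6 A from the nearest ring atom
  dirv <- fr$axis
  base <- fr$pyrrole_centroid
  place <- function(dist_from_ring) {
    # move along the axis until min distance to ring atoms hits the target
    f <- function(t) {
      p <- base + t * dirv
      min(sqrt(rowSums((ring - matrix(p, nrow(ring), 3, byrow = TRUE))^2))) -
        dist_from_ring
    }
    t_star <- uniroot(f, c(0.1, 30))$root
    base + t_star * dirv
  }
  for (spec in list(c(7.4, 1), c(7.6, 0))) {
    p <- place(spec[1])
    s_one <- s
    s_one$atoms <- rbind(s_one$atoms, data.frame(
      name = "C", element = "C", resid = "DEC", resno = 99, chain = "A",
      x = p[1], y = p[2], z = p[3], charge = 0, radius = 1.7))
    expect_equal(compute_den2(s_one, fr), spec[2])
  }
})

test_that("Den2 equals the brute-force pair loop on random toy structures", {
  for (seed in 1:8) {
    s <- make_toy_structure(n_trp = 2, n_decoy_atoms = 60, seed = seed)
    for (resno in 1:2) {
      fr <- locate_indole(s, paste0("A:", resno))
      expect_identical(compute_den2(s, fr),
                       brute_force_den2(s, "A", resno))
    }
  }
})

test_that("accessibility vanishes under burial and grows under exposure", {
  s <- make_toy_structure(n_trp = 1, n_decoy_atoms = 0, seed = 4)
  acc_free <- compute_acc(s, "A:1")
  expect_equal(acc_free, 100 / 1.5, tolerance = 1e-6)

  # enclose the ring in a dense shell of atoms
  fr <- locate_indole(s, "A:1")
  ctr <- (fr$benzene_centroid + fr$pyrrole_centroid) / 2
  pts <- list()
  k <- seq_len(200)
  zf <- (2 * k - 1) / 200 - 1
  th <- pi * (1 + sqrt(5)) * k
  shell <- cbind(sqrt(1 - zf^2) * cos(th), sqrt(1 - zf^2) * sin(th), zf) * 4.4
  buried <- s
  buried$atoms <- rbind(buried$atoms, data.frame(
    name = "C", element = "C", resid = "DEC", resno = 100 + k, chain = "A",
    x = ctr[1] + shell[, 1], y = ctr[2] + shell[, 2], z = ctr[3] + shell[, 3],
    charge = 0, radius = 1.7))
  acc_buried <- compute_acc(buried, "A:1")
  expect_lt(acc_buried, 2)
  expect_gt(acc_free, acc_buried)   # removing contacts raises Acc

  expect_equal(acc_from_raw(18.15), 12.1)
  expect_error(acc_from_raw(-3), "nonnegative")
})

test_that("the class thresholds reproduce every published label", {
  ref <- mts_reference_descriptors()
  acc_pred <- vapply(ref$acc, function(v)
    as.character(burstein_class(v, "acc")), character(1))
  den_pred <- vapply(ref$den2, function(v)
    as.character(burstein_class(v, "den2")), character(1))
  expect_identical(acc_pred, ref$acc_class)
  expect_identical(den_pred, ref$den2_class)
  expect_error(burstein_class(-1, "acc"), "0")
})

test_that("ring-potential readout matches linear fields and is antisymmetric", {
  s <- make_toy_structure(n_trp = 1, n_decoy_atoms = 0, seed = 5)
  fr <- locate_indole(s, "A:1")

  # uniform field: delta = 0
  unif <- potential_grid(array(3.3, dim = c(8, 8, 8)),
                         origin = c(-10, -10, -10), spacing = c(3, 3, 3))
  expect_equal(compute_ep_delta(unif, fr)$delta, 0)

  # gradient g along the frame axis: delta = g * centroid separation
  g <- 2.5
  gx <- seq(-10, 11, by = 3)
  arr <- array(0, dim = c(8, 8, 8))
  for (i in 1:8) for (j in 1:8)
    arr[i, j, ] <- g * (gx[i] * fr$axis[1] + gx[j] * fr$axis[2] +
                          gx * fr$axis[3])
  lin <- potential_grid(arr, origin = c(-10, -10, -10), spacing = c(3, 3, 3))
  ep <- compute_ep_delta(lin, fr)
  sep <- sqrt(sum((fr$pyrrole_centroid - fr$benzene_centroid)^2))
  expect_equal(ep$delta, g * sep, tolerance = 1e-9)
  expect_equal(ep$delta, ep$ep_pyrrole - ep$ep_benzene)

  # printed-pair arithmetic: 10 -> 5.3 gives -4.7
  ref <- mts_reference_descriptors()
  expect_equal(ref$ep_pyrrole - ref$ep_benzene, ref$delta, tolerance = 1e-9)
})

test_that("descriptor tables and comparisons behave end to end", {
  s <- make_toy_structure(n_trp = 2, n_decoy_atoms = 80,
                          charge_scheme = "random", seed = 6)
  tab <- trp_descriptor_table(s)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$delta, tab$ep_pyrrole - tab$ep_benzene, tolerance = 1e-9)
  expect_true(all(tab$den2 >= 0))

  same <- descriptor_change(tab, tab)
  expect_true(all(same$per_trp$acc_ratio == 1))
  expect_true(all(same$per_trp$delta_diff == 0))

  # published Trp133 accessibility doubling upon inhibitor binding
  ref <- mts_reference_descriptors()
  apo <- ref[ref$structure == "3IHI" & ref$trp == 133, ]
  holo <- ref[ref$structure == "4EIN" & ref$trp == 133, ]
  a <- data.frame(trp_id = apo$subunit, acc = apo$acc, den2 = apo$den2,
                  delta = apo$delta)
  b <- data.frame(trp_id = holo$subunit, acc = holo$acc, den2 = holo$den2,
                  delta = holo$delta)
  expect_equal(round(descriptor_change(a, b)$mean_acc_ratio, 2), 2.35)

  expect_error(descriptor_change(tab, tab[1, ]), "different")
})

test_that("descriptors are invariant under rigid motion of structure and grid", {
  s <- make_toy_structure(n_trp = 1, n_decoy_atoms = 40,
                          charge_scheme = "random", seed = 7)
  fr <- locate_indole(s, "A:1")
  den <- compute_den2(s, fr)
  acc <- compute_acc(s, "A:1")

  shift <- c(5, -3, 2)
  s2 <- s
  s2$atoms$x <- s2$atoms$x + shift[1]
  s2$atoms$y <- s2$atoms$y + shift[2]
  s2$atoms$z <- s2$atoms$z + shift[3]
  fr2 <- locate_indole(s2, "A:1")
  expect_identical(compute_den2(s2, fr2), den)
  expect_equal(compute_acc(s2, "A:1"), acc, tolerance = 1e-9)

  # potential grid translated with the structure gives identical delta
  g1 <- grid_from_structure(s, origin = c(-12, -12, -12),
                            spacing = c(2, 2, 2), dims = c(14, 14, 14))
  g2 <- grid_from_structure(s2, origin = c(-12, -12, -12) + shift,
                            spacing = c(2, 2, 2), dims = c(14, 14, 14))
  expect_equal(compute_ep_delta(g2, fr2)$delta,
               compute_ep_delta(g1, fr)$delta, tolerance = 1e-9)
})

test_that("PDB files read back without charges and flag them", {
  s <- make_toy_structure(n_trp = 1, n_decoy_atoms = 5, seed = 8)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path, "pdb")
  s2 <- read_structure(path)
  expect_false(s2$has_charges)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_true(all(is.finite(s2$atoms$radius)))  # element-table radii
})
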