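test_that("set_dihedral hits its target and preserves internal geometry", {
  topo <- glucose_template()
  xyz <- glucose_coordinates()
  idx <- atom_index(topo, c("O5", "C5", "C6", "O6"))
  cur <- 180 / pi * dihedral_angle(xyz, idx[1], idx[2], idx[3], idx[4])
  # no-op: driving to the current value leaves coordinates unchanged
  same <- set_dihedral(xyz, topo, c("O5", "C5", "C6", "O6"), cur)
  expect_lt(max(abs(same - xyz)), 1e-9)
  for (target in c(-170, -60, 0, 65, 179)) {
    out <- set_dihedral(xyz, topo, c("O5", "C5", "C6", "O6"), target)
    got <- 180 / pi * dihedral_angle(out, idx[1], idx[2], idx[3], idx[4])
    expect_lt(abs((got - target + 180) %% 360 - 180), 1e-6)
    # rigidity: all bond lengths unchanged
    r0 <- sqrt(rowSums((xyz[topo$bonds[, 1], ] - xyz[topo$bonds[, 2], ])^2))
    r1 <- sqrt(rowSums((out[topo$bonds[, 1], ] - out[topo$bonds[, 2], ])^2))
    expect_lt(max(abs(r1 - r0)), 1e-9)
  }
  expect_error(set_dihedral(xyz, topo, c("O5", "C1", "C2", "C3"), 30),
               "ring")
})

test_that("rotation scan covers the grid exactly", {
  topo <- glucose_template()
  xyz <- glucose_coordinates()
  scan <- make_rotation_scan(xyz, topo, c("O5", "C5", "C6", "O6"))
  expect_equal(n_conformers(scan), 36)
  idx <- atom_index(topo, c("O5", "C5", "C6", "O6"))
  got <- vapply(seq_len(36), function(s) {
    180 / pi * dihedral_angle(scan$xyz[, , s], idx[1], idx[2], idx[3],
                              idx[4])
  }, numeric(1))
  circ <- abs((got - seq(0, 350, 10) + 180) %% 360 - 180)
  expect_lt(max(circ), 1e-6)
  coarse <- make_rotation_scan(xyz, topo, c("O5", "C5", "C6", "O6"),
                               angles = seq(0, 270, by = 90))
  expect_equal(n_conformers(coarse), 4)
})

test_that("ring-flip scan has 10 structures and fixes the ring frame", {
  topo <- glucose_template()
  xyz <- glucose_coordinates()
  scan <- make_ring_flip_scan(xyz, topo, "C1")
  expect_equal(n_conformers(scan), 10)
  # zero-angle structure is the input
  expect_lt(max(abs(scan$xyz[, , 5] - xyz)), 1e-12)
  # the two ring neighbours (and all other non-moving atoms) stay put
  fixed <- atom_index(topo, c("O5", "C2", "C3", "C4", "C5", "C6"))
  for (s in c(1, 10)) {
    expect_lt(max(abs(scan$xyz[fixed, , s] - xyz[fixed, ])), 1e-12)
  }
  # the flip atom does move at nonzero angles
  c1 <- atom_index(topo, "C1")
  expect_gt(max(abs(scan$xyz[c1, , 1] - xyz[c1, ])), 1e-4)
  expect_error(make_ring_flip_scan(xyz, topo, "O6"), "ring")
})

test_that("rotamer classification uses the staggered bins", {
  expect_equal(as.character(classify_rotamer(c(-60, 60, 180))),
               c("gg", "gt", "tg"))
  expect_equal(as.character(classify_rotamer(c(-119, -1, 0, 119, 120, 240))),
               c("gg", "gg", "gt", "gt", "tg", "gg"))
  # driving the dihedral to a bin centre yields that bin
  topo <- glucose_template()
  xyz <- glucose_coordinates()
  for (case in list(c(-60, "gg"), c(60, "gt"), c(180, "tg"))) {
    out <- set_dihedral(xyz, topo, c("O5", "C5", "C6", "O6"),
                        as.numeric(case[1]))
    idx <- atom_index(topo, c("O5", "C5", "C6", "O6"))
    phi <- 180 / pi * dihedral_angle(out, idx[1], idx[2], idx[3], idx[4])
    expect_equal(as.character(classify_rotamer(phi)), case[2])
  }
})

test_that("rotamer populations sum to one and density integrates to one", {
  pops <- rotamer_populations(rep(-60, 5))
  expect_equal(unname(pops$fractions["gg"]), 1)
  grid <- seq(-179, 180, by = 1)
  pops2 <- rotamer_populations(grid)
  expect_equal(unname(pops2$fractions), rep(1 / 3, 3), tolerance = 0.01)
  expect_equal(sum(pops2$fractions), 1)
  expect_equal(sum(pops2$density$density) * 10, 1, tolerance = 1e-9)
  # on a conformer set: all structures driven to gg
  topo <- glucose_template()
  xyz <- set_dihedral(glucose_coordinates(), topo,
                      c("O5", "C5", "C6", "O6"), -60)
  cs <- conformer_set(topo, list(xyz, xyz))
  expect_equal(unname(rotamer_populations(cs)$fractions["gg"]), 1)
})

test_that("cremer-pople reproduces constructed geometries", {
  hexagon <- function(z) cbind(1.45 * cos(2 * pi * (0:5) / 6),
                               1.45 * sin(2 * pi * (0:5) / 6), z)
  expect_equal(cremer_pople(hexagon(rep(0, 6)))$Q, 0, tolerance = 1e-12)
  chair <- hexagon(0.25 * (-1)^(0:5))
  cp <- cremer_pople(chair)
  expect_equal(cp$Q, sqrt(6 * 0.25^2), tolerance = 1e-9)
  expect_true(cp$theta %in% c(0, 180) ||
                min(abs(cp$theta - c(0, 180))) < 1e-9)
  # rigid motion leaves Q invariant
  R <- rbind(c(0.36, -0.8, 0.48), c(0.8, 0.6, 0), c(-0.48, 0.384, 0.8))
  R <- qr.Q(qr(R))  # orthonormalize
  moved <- chair %*% R + matrix(c(3, -1, 2), 6, 3, byrow = TRUE)
  expect_equal(cremer_pople(moved)$Q, cp$Q, tolerance = 1e-10)
  expect_error(cremer_pople(cbind(0:5, 0, 0)), "degenerate|collinear")
})

test_that("scan generation is frame-independent", {
  topo <- glucose_template()
  xyz <- glucose_coordinates()
  R <- qr.Q(qr(matrix(c(1, 2, 0, -1, 1, 3, 2, 0, 1), 3)))
  moved <- xyz %*% R + matrix(c(4, 4, -4), 24, 3, byrow = TRUE)
  s1 <- make_rotation_scan(xyz, topo, c("C2", "C1", "O1", "HO1"),
                           angles = c(0, 120, 240))
  s2 <- make_rotation_scan(moved, topo, c("C2", "C1", "O1", "HO1"),
                           angles = c(0, 120, 240))
  # compare internal coordinates: all pairwise distances agree
  for (s in 1:3) {
    d1 <- dist(s1$xyz[, , s])
    d2 <- dist(s2$xyz[, , s])
    expect_lt(max(abs(d1 - d2)), 1e-9)
  }
})

test_that("pucker table flags chair versus flattened ring", {
  cs <- small_synth(n = 6)
  pk <- ring_pucker(cs)
  expect_equal(nrow(pk), 6)
  expect_true(all(pk$Q > 0.3 & pk$Q < 0.8))  # jittered 4C1 chairs
})
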