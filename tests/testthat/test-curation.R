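test_that("rmsd literal and superposed modes behave analytically", {
  X <- glucose_coordinates()
  expect_equal(rmsd(X, X), 0, tolerance = 1e-10)
  shifted <- X + matrix(c(1, 0, 0), 24, 3, byrow = TRUE)
  expect_equal(rmsd(X, shifted, superpose = FALSE), 1.0, tolerance = 1e-12)
  expect_equal(rmsd(X, shifted, superpose = TRUE), 0, tolerance = 1e-7)
  # 2-atom toy with displacements hand-computable from the formula
  A <- rbind(c(0, 0, 0), c(1, 0, 0))
  B <- rbind(c(0.3, 0.4, 0), c(1, 0, 0))
  expect_equal(rmsd(A, B, superpose = FALSE), sqrt(0.25 / 2),
               tolerance = 1e-12)
  expect_error(rmsd(A[0, , drop = FALSE], B[0, , drop = FALSE]), "empty")
})

test_that("deduplication drops exact copies and respects the threshold", {
  topo <- glucose_template()
  x <- glucose_coordinates()
  cs <- conformer_set(topo, list(x, x, x), ids = c("a", "b", "c"))
  dd <- deduplicate(cs)
  expect_equal(dd$n_retained, 1)
  expect_equal(dd$retained_ids, "a")
  expect_equal(dd$removed$matches_id, c("a", "a"))

  # a pair at exactly the threshold is removed (inclusive inequality);
  # shift one atom along x to get a literal RMSD of exactly d
  d <- 0.05
  y <- x; y[1, 1] <- y[1, 1] + d * sqrt(24)
  cs2 <- conformer_set(topo, list(x, y), ids = c("a", "b"))
  expect_equal(rmsd(x, y, superpose = FALSE), d, tolerance = 1e-12)
  dd2 <- deduplicate(cs2, threshold = d + 1e-9, superpose = FALSE)
  expect_equal(dd2$n_retained, 1)
  dd3 <- deduplicate(cs2, threshold = d / 2, superpose = FALSE)
  expect_equal(dd3$n_retained, 2)
})

test_that("deduplication is frame-independent and idempotent", {
  cs <- small_synth(n = 12)
  rot <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  xyz2 <- cs$xyz
  xyz2[, , 2] <- cs$xyz[, , 1] %*% rot + 3  # duplicate of frame 1, moved
  cs2 <- conformer_set(cs$topology, xyz2, ids = cs$ids)
  dd <- deduplicate(cs2)
  expect_equal(dd$n_removed, 1)
  expect_equal(dd$removed$id, cs$ids[2])
  # running again on the retained set removes nothing
  dd2 <- deduplicate(dd$retained)
  expect_equal(dd2$n_removed, 0)
})

test_that("LJ filter removes an injected steric clash and only it", {
  cs <- small_synth(n = 15)
  params <- glucose_parameters()
  clash <- cs$xyz[, , 1]
  j <- atom_index(cs$topology, "O4")  # push onto a non-bonded oxygen
  i <- atom_index(cs$topology, "O2")
  clash[j, ] <- clash[i, ] + c(0.5, 0, 0)
  cs2 <- conformer_set(cs$topology,
                       array(c(cs$xyz, clash), dim = c(24, 3, 16)),
                       ids = c(cs$ids, "clash"))
  lf <- filter_lj_outliers(cs2, params)
  expect_equal(lf$removed$id, "clash")
  expect_equal(lf$n_retained, 15)
  # disabled rule removes nothing
  lf2 <- filter_lj_outliers(cs2, params, rule = "none")
  expect_equal(lf2$n_removed, 0)
  # identical structures: none removed (IQR = 0 but nothing exceeds it)
  same <- conformer_set(cs$topology,
                        array(rep(cs$xyz[, , 1], 4), dim = c(24, 3, 4)))
  expect_equal(filter_lj_outliers(same, params)$n_removed, 0)
})

test_that("split is seeded, sized 7:3, and keeps the reference in train", {
  cs <- small_synth(n = 10)
  sp <- split_conformers(cs, seed = 9)
  expect_length(sp$train_ids, 7)
  expect_length(sp$test_ids, 3)
  sp2 <- split_conformers(cs, seed = 9)
  expect_identical(sp$train_ids, sp2$train_ids)
  expect_true(cs$ids[cs$ref] %in% sp$train_ids)
  # across many seeds the reference always lands in train
  for (s in 1:20) {
    expect_true(cs$ids[cs$ref] %in% split_conformers(cs, seed = s)$train_ids)
  }
  expect_error(split_conformers(cs), "seed")
})

test_that("charge statistics report ensemble mean and population SD", {
  topo <- glucose_template()
  x <- glucose_coordinates()
  q <- matrix(0, 2, 24, dimnames = list(NULL, topo$atoms$label))
  q[, "O5"] <- c(0.1, 0.3)
  q[, topo$atoms$charge_free] <- q[, topo$atoms$charge_free] + 0.01
  q[, "O5"] <- c(0.1, 0.3)
  cs <- conformer_set(topo, list(x, x), charges = q)
  st <- charge_statistics(cs)
  expect_equal(st$mean[st$label == "O5"], 0.2)
  expect_equal(st$sd[st$label == "O5"], 0.1)  # population SD of {0.1, 0.3}
  expect_equal(nrow(st), 17)
  # identical sets -> zero SD
  q2 <- q; q2[2, ] <- q2[1, ]
  st2 <- charge_statistics(conformer_set(topo, list(x, x), charges = q2))
  expect_true(all(st2$sd == 0))
  # nonzero aliphatic hydrogen charge is an error
  q3 <- q; q3[1, "H1"] <- 0.05
  expect_error(charge_statistics(conformer_set(topo, list(x, x),
                                               charges = q3)), "H1")
})

test_that("emulated charge ensembles recover their generating moments", {
  cs <- small_synth(n = 1000)
  st <- charge_statistics(cs)
  truth <- ground_truth_parameters()
  mu <- truth$charges[st$label]
  sigma <- 0.02
  n <- attr(st, "n_sets")
  se_mean <- sigma / sqrt(n)
  se_sd <- sigma / sqrt(2 * n)
  expect_true(all(abs(st$mean - mu) < 4 * se_mean))
  expect_true(all(abs(st$sd - sigma) < 4 * se_sd))
})

test_that("end-to-end curation report is consistent", {
  cs <- small_synth(n = 20)
  dup <- cs$xyz[, , 3]
  cs2 <- conformer_set(cs$topology,
                       array(c(cs$xyz, dup), dim = c(24, 3, 21)),
                       ids = c(cs$ids, "dup"),
                       qm_energy = c(cs$qm_energy, cs$qm_energy[3]))
  cur <- curate(cs2, glucose_parameters(), seed = 77)
  expect_equal(cur$n_duplicates, 1)
  expect_equal(cur$n_retained, cur$n_input - cur$n_duplicates -
                 cur$n_lj_outliers)
  expect_length(cur$train_ids, ceiling(0.7 * cur$n_retained))
  expect_equal(sort(c(cur$train_ids, cur$test_ids)),
               sort(cur$curated$ids))
})
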