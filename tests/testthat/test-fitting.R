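recovery_types <- c("Oh-Cg-Cg-Os", "Cg-Cg-Oh-Ho")

torsion_v_of <- function(params, type) {
  vapply(1:6, function(n) {
    r <- params$torsion[params$torsion$type == type & params$torsion$n == n, ]
    if (nrow(r)) r$v[1] else 0
  }, numeric(1))
}

test_that("cost is the penalty-free floor at the generating parameters", {
  cs <- small_synth(n = 30)
  truth <- ground_truth_parameters()
  fc <- fit_config(free_torsion_types = recovery_types, free_gamma = FALSE)
  ctx <- build_fit_context(cs, glucose_parameters(), fc)
  st <- charge_statistics(cs)
  # with charges at the ensemble means and lambda_chg active, only the
  # charge-restraint term can be nonzero; zero it and cost collapses
  fc0 <- fit_config(lambda_chg = 0, lambda_dih = 0, lambda_scee = 0,
                    free_torsion_types = recovery_types)
  out <- fit_cost(truth, ctx, fc0, charge_stats = st)
  expect_lt(out$cost, 1e-18)  # truth is neutral, REE identically zero
  expect_lt(abs(out$mse), 1e-20)
  expect_equal(unname(out$penalties["dih"] >= 0), TRUE)
})

test_that("single-structure cost with penalties off equals REE^2", {
  cs <- small_synth(n = 5)
  start <- glucose_parameters()
  fc0 <- fit_config(lambda_csum = 0, lambda_chg = 0, lambda_dih = 0,
                    lambda_scee = 0, free_torsion_types = recovery_types)
  ctx <- build_fit_context(cs, start, fc0)
  pick <- setdiff(seq_len(n_conformers(cs)), cs$ref)[1]
  out <- fit_cost(start, ctx, fc0, idx = pick)
  ree <- relative_energy_error(cs, start)$per_structure$ree[pick]
  expect_equal(out$cost, ree^2, tolerance = 1e-10)
})

test_that("cost with one free charge matches a symbolic expansion", {
  # 3-atom chain: only pair (1,3) interacts (1-3 pairs are excluded, so
  # use a 4-chain where 1-4 is the single scaled Coulomb pair)
  topo <- chain_topology(4)
  params <- parameter_set(
    bond = data.frame(type = "A-A", kb = 0, r0 = 1.5),
    angle = data.frame(type = "A-A-A", ktheta = 0, theta0 = 109.5),
    torsion = data.frame(type = "A-A-A-A", n = 1, v = 0, gamma = 0),
    lj = data.frame(type = "A", rmin2 = 0, eps = 0),
    charges = c(X1 = 0.2, X2 = 0, X3 = 0, X4 = -0.2), scee = 1.5)
  xyz1 <- cbind(c(0, 1.5, 2.25, 3.0), c(0, 0, 1.3, 2.6), 0)
  xyz2 <- cbind(c(0, 1.5, 2.25, 2.6), c(0, 0, 1.3, 0.2), 0)
  r1 <- sqrt(sum((xyz1[1, ] - xyz1[4, ])^2))
  r2 <- sqrt(sum((xyz2[1, ] - xyz2[4, ])^2))
  cs <- conformer_set(topo, list(xyz1, xyz2), qm_energy = c(0, 1))
  fc <- fit_config(lambda_csum = 0, lambda_chg = 0, lambda_dih = 0,
                   lambda_scee = 0)
  ctx <- build_fit_context(cs, params, fc)
  # vary q1: EMM_s = KCOUL * q1 * q4 / (scee * r_s); structure 1 is the
  # reference (qm 0 < 1), M = 2
  q1 <- 0.37
  p2 <- params; p2$charges["X1"] <- q1
  out <- fit_cost(p2, ctx, fc)
  emm <- KCOUL * q1 * (-0.2) / 1.5 / c(r1, r2)
  ree <- (c(0, 1) - 0) - (emm - emm[1])
  expect_equal(out$cost, mean(ree^2), tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  cs <- small_synth(n = 25)
  start <- glucose_parameters()
  fc <- fit_config(free_torsion_types = recovery_types)
  ctx <- build_fit_context(cs, start, fc)
  st <- charge_statistics(cs)
  h <- 1e-6
  set.seed(31)
  for (point in 1:3) {
    p <- start
    p$torsion$v <- p$torsion$v + rnorm(nrow(p$torsion), 0, 0.2)
    p$torsion$gamma <- (p$torsion$gamma + rnorm(nrow(p$torsion), 0, 20)) %% 360
    free <- names(p$charges)[cs$topology$atoms$charge_free]
    p$charges[free] <- p$charges[free] + rnorm(17, 0, 0.02)
    p$scee <- p$scee + runif(1, -0.1, 0.3)
    g <- fit_cost_gradient(p, ctx, fc, charge_stats = st)

    fd <- function(mutate) {
      pp <- mutate(p, h); pm <- mutate(p, -h)
      (fit_cost(pp, ctx, fc, st)$cost - fit_cost(pm, ctx, fc, st)$cost) / (2 * h)
    }
    # one V, one gamma, two charges, scee
    hit <- which(p$torsion$type == recovery_types[1] & p$torsion$n == 2)
    expect_equal(g$v[[paste0(recovery_types[1], ":2")]],
                 fd(function(q, d) { q$torsion$v[hit] <- q$torsion$v[hit] + d; q }),
                 tolerance = 1e-5)
    g_rad <- g$gamma[[paste0(recovery_types[2], ":1")]]
    hit2 <- which(p$torsion$type == recovery_types[2] & p$torsion$n == 1)
    fd_gamma <- fd(function(q, d) {
      q$torsion$gamma[hit2] <- q$torsion$gamma[hit2] + d * 180 / pi; q
    })
    expect_equal(g_rad, fd_gamma, tolerance = 1e-4)
    for (atom in c("O5", "HO1")) {
      expect_equal(g$q[[atom]],
                   fd(function(q, d) { q$charges[atom] <- q$charges[atom] + d; q }),
                   tolerance = 1e-5)
    }
    expect_equal(g$scee,
                 fd(function(q, d) { q$scee <- q$scee + d; q }),
                 tolerance = 1e-5)
  }
})

test_that("scee gradient opposes the sign of the 1-4 Coulomb term", {
  cs <- small_synth(n = 10)
  start <- glucose_parameters()
  fc <- fit_config(lambda_csum = 0, lambda_chg = 0, lambda_dih = 0,
                   lambda_scee = 0, free_torsion_types = recovery_types)
  ctx <- build_fit_context(cs, start, fc)
  # d EC14 / d scee = -EC14 / scee: raising scee lowers |EC14|
  theta <- glycofit:::theta_from_params(ctx, start)
  e14 <- as.numeric((ctx$P14 %*% (theta$q[ctx$i14] * theta$q[ctx$j14])) /
                      theta$scee)
  d_emm <- -e14 / theta$scee
  expect_true(all(sign(d_emm) == -sign(e14) | e14 == 0))
})

test_that("adadelta step follows the published update rule", {
  st <- adadelta_init(3)
  g <- c(0, 2, -1)
  out <- adadelta_step(g, st, rho = 0.95, eps = 1e-6)
  # zero gradient -> zero update; direction opposes the gradient
  expect_equal(out$delta[1], 0)
  expect_true(all(out$delta * g <= 0))
  # first step magnitude from substituting the empty state
  c_ <- 1e-6; rho <- 0.95
  expect_equal(abs(out$delta),
               sqrt(c_ / ((1 - rho) * g^2 + c_)) * abs(g),
               tolerance = 1e-12)
  # state accumulates
  expect_equal(out$state$eg2, (1 - rho) * g^2)
  expect_equal(out$state$edx2, (1 - rho) * out$delta^2)
})

test_that("one-free-parameter fit matches a golden-section oracle", {
  # data generated by the starting parameters themselves: the cost has
  # its global minimum at the start values, so the joint minimum of the
  # free Fourier terms coincides with the 1-D slice minimum the
  # golden-section oracle finds
  start <- glucose_parameters()
  cfg <- generator_config(n = 40, seed = 91, truth = start)
  cs <- synthetic_dataset(cfg)
  fc <- fit_config(lambda_csum = 0, lambda_chg = 0, lambda_dih = 0,
                   lambda_scee = 0, free_torsion_types = "Cg-Cg-Oh-Ho",
                   free_gamma = FALSE, fit_charges = FALSE,
                   fit_scee = FALSE, max_epochs = 400, seed = 3)
  ctx <- build_fit_context(cs, start, fc)
  cost_1d <- function(v1) {
    p <- start
    hit <- p$torsion$type == "Cg-Cg-Oh-Ho" & p$torsion$n == 1
    p$torsion$v[hit] <- v1
    fit_cost(p, ctx, fc)$cost
  }
  gold <- stats::optimize(cost_1d, c(-2, 3), tol = 1e-10)
  p0 <- start
  hit <- p0$torsion$type == "Cg-Cg-Oh-Ho" & p0$torsion$n == 1
  p0$torsion$v[hit] <- p0$torsion$v[hit] + 0.8
  fr <- fit_parameters(cs, p0, config = fc)
  fitted_v1 <- fr$params$torsion$v[fr$params$torsion$type == "Cg-Cg-Oh-Ho" &
                                     fr$params$torsion$n == 1]
  expect_equal(fitted_v1, gold$minimum, tolerance = 1e-4)
})

test_that("train cost decreases and charges stay pinned", {
  cs <- small_synth(n = 50)
  fc <- fit_config(free_torsion_types = recovery_types, max_epochs = 300,
                   seed = 5)
  fr <- suppressWarnings(
    fit_parameters(cs, glucose_parameters(),
                   charge_stats = charge_statistics(cs), config = fc))
  tc <- fr$trajectory$train_cost
  expect_lt(tail(tc, 1), tc[1])
  expect_equal(nrow(fr$trajectory), fr$epochs)
  ali <- cs$topology$atoms$label[cs$topology$atoms$aliphatic_h]
  expect_true(all(fr$params$charges[ali] == 0))
  expect_true(all(fr$params$torsion$gamma >= 0 &
                    fr$params$torsion$gamma < 360))
})

test_that("synthetic recovery returns the generating parameters", {
  cfg <- generator_config(n = 250, seed = 61)
  cs <- synthetic_dataset(cfg)
  truth <- cfg$truth
  fc <- fit_config(lambda_chg = 0, lambda_dih = 0, lambda_scee = 0,
                   free_torsion_types = recovery_types, free_gamma = FALSE,
                   max_epochs = 800, seed = 62)
  fr <- suppressWarnings(fit_parameters(cs, glucose_parameters(),
                                        config = fc))
  for (ty in recovery_types) {
    expect_lt(max(abs(torsion_v_of(fr$params, ty) - torsion_v_of(truth, ty))),
              0.1)
  }
  expect_lt(max(abs(fr$params$charges - truth$charges[names(fr$params$charges)])),
            0.01)
  expect_lt(abs(fr$params$scee - truth$scee), 0.01)
  expect_lt(abs(sum(fr$params$charges)), 1e-3)
})

test_that("fitted net charge scales down with the neutrality weight", {
  # with energy noise the unpenalized optimum is slightly charged; the
  # penalty shrinks the net charge roughly as 1/lambda
  cfg <- generator_config(n = 120, seed = 71, noise_sd = 1.0)
  cs <- synthetic_dataset(cfg)
  net <- vapply(c(1e3, 1e6), function(lam) {
    fc <- fit_config(lambda_csum = lam, lambda_chg = 0, lambda_dih = 0,
                     lambda_scee = 0, free_torsion_types = recovery_types,
                     free_gamma = FALSE, max_epochs = 200, seed = 72)
    fr <- suppressWarnings(fit_parameters(cs, glucose_parameters(),
                                          config = fc))
    abs(sum(fr$params$charges))
  }, numeric(1))
  expect_gt(net[1] / net[2], 50)  # ~1000x weight -> >=50x smaller net charge
})

test_that("overfitting can be inspected from the test-cost curve", {
  cfg <- generator_config(n = 80, seed = 81, noise_sd = 0.3)
  cs <- synthetic_dataset(cfg)
  sp <- split_conformers(cs, seed = 82)
  fc <- fit_config(free_torsion_types = recovery_types, max_epochs = 150,
                   seed = 83)
  fr <- suppressWarnings(
    fit_parameters(cs, glucose_parameters(),
                   charge_stats = charge_statistics(cs), config = fc,
                   train_ids = sp$train_ids, test_ids = sp$test_ids))
  expect_true(all(is.finite(fr$trajectory$test_cost)))
  expect_false(is.null(fr$test_ree))
})
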