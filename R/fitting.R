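# Penalized least-squares refit of torsion Fourier coefficients, atomic
# charges and the 1-4 electrostatic scaling factor, by full-batch
# Adadelta gradient descent on the mean squared relative energy error.

#' Fitting configuration
#'
#' Penalty weights default to the published study values: the neutrality
#' weight `lambda_csum` is large (1e7) so the fitted molecule stays
#' neutral; `lambda_chg` (0.1) restrains each charge to its ensemble
#' mean scaled by its ensemble spread; `lambda_dih` (3.0) restrains
#' torsion amplitudes to the reference set; `lambda_scee` (100.0)
#' restrains the 1-4 scaling factor to its reference value.
#'
#' @param lambda_csum,lambda_chg,lambda_dih,lambda_scee penalty weights
#' @param free_torsion_types character vector of dihedral type keys to
#'   fit, or NULL for every type present in the topology
#' @param free_gamma fit phase angles as well as amplitudes?
#' @param fit_charges fit the optimizable atomic charges?
#' @param fit_scee fit the 1-4 electrostatic scaling factor?
#' @param scee_ref reference scee for the penalty (1.0: unscaled 1-4
#'   electrostatics, the carbohydrate-force-field convention)
#' @param rho,adadelta_eps Adadelta decay and numerical-stability
#'   constants. The decay keeps its published default; the stability
#'   constant defaults to 1e-12 here because with the 1e7 neutrality
#'   weight the published 1e-6 makes the very first steps large enough
#'   to excite the stiff net-charge mode
#' @param lr_decay per-epoch multiplicative decay of the Adadelta step
#'   multiplier (annealing); 1 disables it
#' @param max_epochs,tol,patience stop after `max_epochs`, or when the
#'   relative train-cost change stays below `tol` for `patience`
#'   consecutive epochs
#' @param polish refine the free parameters from the Adadelta endpoint
#'   by Levenberg-Marquardt on the equivalent least-squares form of the
#'   cost (REE residuals plus square-root penalty residuals) with the
#'   analytic Jacobian; the descent locates the basin, the polish
#'   drives the gradient to zero in the very stiff valley the
#'   neutrality weight creates
#' @param polish_maxit iteration cap for the polish stage
#' @param sigma_floor lower bound (e) applied to the charge-ensemble
#'   standard deviations in the charge penalty denominator
#' @param seed integer seed recorded with the fit
#' @return list of class `fit_config`
#' @export
fit_config <- function(lambda_csum = 1e7, lambda_chg = 0.1,
                       lambda_dih = 3.0, lambda_scee = 100.0,
                       free_torsion_types = NULL, free_gamma = TRUE,
                       fit_charges = TRUE, fit_scee = TRUE, scee_ref = 1.0,
                       rho = 0.95, adadelta_eps = 1e-12, lr_decay = 0.9995,
                       max_epochs = 5000, tol = 1e-8, patience = 50,
                       polish = TRUE, polish_maxit = 200,
                       sigma_floor = 0.01, seed = 1L) {
  stopifnot(lambda_csum >= 0, lambda_chg >= 0, lambda_dih >= 0,
            lambda_scee >= 0, rho > 0, rho < 1, adadelta_eps > 0,
            lr_decay > 0, lr_decay <= 1, max_epochs >= 1, sigma_floor >= 0)
  structure(list(lambda_csum = lambda_csum, lambda_chg = lambda_chg,
                 lambda_dih = lambda_dih, lambda_scee = lambda_scee,
                 free_torsion_types = free_torsion_types,
                 free_gamma = free_gamma, fit_charges = fit_charges,
                 fit_scee = fit_scee, scee_ref = scee_ref, rho = rho,
                 adadelta_eps = adadelta_eps, lr_decay = lr_decay,
                 max_epochs = max_epochs, polish = polish,
                 polish_maxit = polish_maxit,
                 tol = tol, patience = patience, sigma_floor = sigma_floor,
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Precompute the fitting context for a conformer set
#'
#' Expands everything that does not depend on the free parameters:
#' per-structure frozen energies (bond, angle, Lennard-Jones, frozen
#' torsion types), cosine/sine torsion design matrices for the free
#' dihedral types, and Coulomb geometry matrices (the electrostatic
#' prefactor over pair distance) for the 1-4 and non-bonded pair sets.
#' Fitting and cost evaluation then reduce to dense linear algebra.
#'
#' @param cs a `conformer_set` with reference energies
#' @param start_params the reference [parameter_set()] (frozen terms are
#'   taken from it; it is also the penalty reference)
#' @param config a [fit_config()]
#' @return opaque list used by [fit_cost()], [fit_cost_gradient()] and
#'   [fit_parameters()]
#' @export
build_fit_context <- function(cs, start_params, config = fit_config()) {
  topo <- cs$topology
  if (is.null(cs$qm_energy) || is.na(cs$ref)) {
    stop("fitting requires reference energies and a reference structure")
  }
  S <- n_conformers(cs)
  dih_key <- term_types(topo, "dihedrals")
  all_types <- sort(unique(dih_key))
  free_types <- config$free_torsion_types
  if (is.null(free_types)) free_types <- all_types
  bad <- setdiff(free_types, all_types)
  if (length(bad)) stop("free torsion type(s) not present in topology: ",
                        paste(bad, collapse = ", "))

  tb <- energy_tables(topo, start_params)

  # per-structure dihedral angles
  phi <- matrix(0, S, nrow(topo$dihedrals))
  for (s in seq_len(S)) {
    phi[s, ] <- dihedral_angles_all(cs$xyz[, , s], topo$dihedrals)
  }

  # free-torsion design matrices: K = |free_types| x 6 columns
  K <- length(free_types) * 6L
  D1 <- matrix(0, S, K); D2 <- matrix(0, S, K)
  k_type <- character(K); k_n <- integer(K); n_inst <- integer(K)
  k <- 0L
  for (t in free_types) {
    inst <- which(dih_key == t)
    for (n in 1:6) {
      k <- k + 1L
      k_type[k] <- t; k_n[k] <- n; n_inst[k] <- length(inst)
      D1[, k] <- rowSums(cos(n * phi[, inst, drop = FALSE]))
      D2[, k] <- rowSums(sin(n * phi[, inst, drop = FALSE]))
    }
  }

  # Coulomb geometry matrices (include the conversion constant and the
  # dielectric so columns are energy per unit charge product)
  pref <- KCOUL / start_params$dielectric
  P14 <- matrix(0, S, nrow(topo$pairs_14))
  Pnb <- matrix(0, S, nrow(topo$pairs_nb))
  for (s in seq_len(S)) {
    P14[s, ] <- pref / pair_distances(cs$xyz[, , s], topo$pairs_14)
    Pnb[s, ] <- pref / pair_distances(cs$xyz[, , s], topo$pairs_nb)
  }

  # frozen part: everything except free-type torsions and all Coulomb
  e_frozen <- numeric(S)
  for (s in seq_len(S)) {
    b <- total_energy(topo, start_params, cs$xyz[, , s], tables = tb)
    e_frozen[s] <- b$total - b$coulomb_14 - b$coulomb_nb -
      sum(b$torsion_by_type[free_types])
  }

  # reference (penalty) values for the free torsion terms
  v_ref <- numeric(K); g_ref <- numeric(K)
  for (kk in seq_len(K)) {
    row <- start_params$torsion[start_params$torsion$type == k_type[kk] &
                                  start_params$torsion$n == k_n[kk], ]
    if (nrow(row)) { v_ref[kk] <- row$v[1]; g_ref[kk] <- deg2rad(row$gamma[1]) }
  }

  free_q <- topo$atoms$charge_free
  list(topology = topo, S = S, ref = cs$ref, ids = cs$ids,
       qm = cs$qm_energy, e_frozen = e_frozen,
       D1 = D1, D2 = D2, k_type = k_type, k_n = k_n, n_inst = n_inst,
       free_types = free_types, v_ref = v_ref, g_ref = g_ref,
       P14 = P14, Pnb = Pnb,
       i14 = topo$pairs_14[, 1], j14 = topo$pairs_14[, 2],
       inb = topo$pairs_nb[, 1], jnb = topo$pairs_nb[, 2],
       free_q = free_q, labels = topo$atoms$label,
       q_start = as.numeric(start_params$charges[topo$atoms$label]),
       scee_start = start_params$scee)
}

# Pack free-parameter values from a parameter_set into the theta list
# used internally: V and gamma (radians) over the context's (type, n)
# grid, full charge vector, scee.
theta_from_params <- function(ctx, params) {
  K <- length(ctx$k_type)
  v <- numeric(K); g <- numeric(K)
  for (k in seq_len(K)) {
    row <- params$torsion[params$torsion$type == ctx$k_type[k] &
                            params$torsion$n == ctx$k_n[k], ]
    if (nrow(row)) { v[k] <- row$v[1]; g[k] <- deg2rad(row$gamma[1]) }
  }
  q <- as.numeric(params$charges[ctx$labels])
  if (anyNA(q)) stop("parameter set lacks charges for some atoms")
  list(v = v, gamma = g, q = q, scee = params$scee)
}

# Write theta back into a parameter_set (free torsion types get a full
# 1..6 Fourier list; phases reported in degrees in [0, 360)).
params_from_theta <- function(ctx, params, theta) {
  keep <- !(params$torsion$type %in% ctx$free_types)
  new_rows <- data.frame(type = ctx$k_type, n = ctx$k_n, v = theta$v,
                         gamma = wrap_deg_360(rad2deg(theta$gamma)),
                         stringsAsFactors = FALSE)
  tors <- rbind(params$torsion[keep, , drop = FALSE], new_rows)
  tors <- tors[order(tors$type, tors$n), , drop = FALSE]
  rownames(tors) <- NULL
  params$torsion <- tors
  params$charges <- stats::setNames(theta$q, ctx$labels)
  params$scee <- theta$scee
  params
}

# MM energies of every context structure under theta.
ctx_energies <- function(ctx, theta) {
  a <- theta$v * cos(theta$gamma)
  b <- theta$v * sin(theta$gamma)
  w14 <- theta$q[ctx$i14] * theta$q[ctx$j14]
  wnb <- theta$q[ctx$inb] * theta$q[ctx$jnb]
  as.numeric(ctx$e_frozen + ctx$D1 %*% a + ctx$D2 %*% b +
               sum(theta$v * ctx$n_inst) +
               (ctx$P14 %*% w14) / theta$scee + ctx$Pnb %*% wnb)
}

ctx_ree <- function(ctx, theta, idx) {
  emm <- ctx_energies(ctx, theta)
  qm_rel <- ctx$qm[idx] - ctx$qm[ctx$ref]
  mm_rel <- emm[idx] - emm[ctx$ref]
  list(ree = qm_rel - mm_rel, emm = emm)
}

ctx_penalties <- function(ctx, theta, config) {
  sig <- pmax(attr(ctx, "sigma"), config$sigma_floor)
  c(csum = sum(theta$q)^2,
    chg = if (!is.null(attr(ctx, "qbar"))) {
      sum((theta$q[ctx$free_q] - attr(ctx, "qbar"))^2 / (2 * sig)^2)
    } else 0,
    dih = sum((theta$v - ctx$v_ref)^2),
    scee = (theta$scee - config$scee_ref)^2)
}

# Attach charge-ensemble statistics to a context (mean and floored SD
# over the free atoms, ordered as ctx$labels[free_q]).
attach_charge_statistics <- function(ctx, charge_stats, config) {
  if (is.null(charge_stats)) {
    if (config$lambda_chg > 0) {
      warning("no charge statistics supplied; charge-restraint penalty inactive")
    }
    attr(ctx, "qbar") <- NULL
    attr(ctx, "sigma") <- rep(config$sigma_floor, sum(ctx$free_q))
    return(ctx)
  }
  labs <- ctx$labels[ctx$free_q]
  m <- match(labs, charge_stats$label)
  if (anyNA(m)) stop("charge statistics missing for atom(s): ",
                     paste(labs[is.na(m)], collapse = ", "))
  sig <- charge_stats$sd[m]
  if (any(sig < config$sigma_floor) && config$lambda_chg > 0) {
    warning("charge-ensemble SD below floor for ",
            sum(sig < config$sigma_floor),
            " atom(s); floor ", config$sigma_floor, " e applied")
  }
  attr(ctx, "qbar") <- charge_stats$mean[m]
  attr(ctx, "sigma") <- sig
  ctx
}

#' Penalized fitting cost of a parameter set
#'
#' Mean squared relative energy error over the selected structures plus
#' the four weighted penalties: squared net charge (over all atoms,
#' including the fixed zeros), charge-restraint misfit relative to the
#' ensemble mean and spread, squared torsion-amplitude deviation from
#' the reference set (free terms only; phases are not penalized), and
#' squared scee deviation from its reference. The reference structure's
#' MM energy is recomputed from the supplied parameters inside the REE.
#'
#' @param params the [parameter_set()] to score
#' @param ctx a [build_fit_context()] result
#' @param config a [fit_config()]
#' @param charge_stats optional [charge_statistics()] table
#' @param idx structure indices to average over (default: all context
#'   structures)
#' @return list with `cost`, `mse`, `penalties` (named, unweighted),
#'   `ree`
#' @export
fit_cost <- function(params, ctx, config = fit_config(),
                     charge_stats = NULL, idx = NULL) {
  ctx <- attach_charge_statistics(ctx, charge_stats, config)
  theta <- theta_from_params(ctx, params)
  if (is.null(idx)) idx <- seq_len(ctx$S)
  rr <- ctx_ree(ctx, theta, idx)
  pen <- ctx_penalties(ctx, theta, config)
  mse <- mean(rr$ree^2)
  cost <- unname(mse + config$lambda_csum * pen["csum"] +
                   config$lambda_chg * pen["chg"] +
                   config$lambda_dih * pen["dih"] +
                   config$lambda_scee * pen["scee"])
  list(cost = cost, mse = mse, penalties = pen, ree = rr$ree)
}

# Jacobian of the per-structure MM energies with respect to the full
# theta vector (v, gamma, q, scee); analytic, S x npar.
ctx_emm_jacobian <- function(ctx, theta) {
  cg <- cos(theta$gamma); sg <- sin(theta$gamma)
  S <- ctx$S
  Jv <- sweep(ctx$D1, 2, cg, `*`) + sweep(ctx$D2, 2, sg, `*`) +
    matrix(ctx$n_inst, S, length(theta$v), byrow = TRUE)
  Jg <- sweep(sweep(ctx$D2, 2, cg, `*`) - sweep(ctx$D1, 2, sg, `*`),
              2, theta$v, `*`)
  n <- length(theta$q)
  mk_T <- function(ii, jj, m) {
    T_ <- matrix(0, m, n)
    T_[cbind(seq_len(m), ii)] <- T_[cbind(seq_len(m), ii)] + theta$q[jj]
    T_[cbind(seq_len(m), jj)] <- T_[cbind(seq_len(m), jj)] + theta$q[ii]
    T_
  }
  Jq <- (ctx$P14 %*% mk_T(ctx$i14, ctx$j14, length(ctx$i14))) / theta$scee +
    ctx$Pnb %*% mk_T(ctx$inb, ctx$jnb, length(ctx$inb))
  w14 <- theta$q[ctx$i14] * theta$q[ctx$j14]
  Jscee <- -(ctx$P14 %*% w14) / theta$scee^2
  cbind(Jv, Jg, Jq, Jscee)
}

# Gradient of the penalized cost with respect to theta; analytic.
ctx_gradient <- function(ctx, theta, config, idx) {
  M <- length(idx)
  rr <- ctx_ree(ctx, theta, idx)
  U <- numeric(ctx$S)
  U[idx] <- U[idx] - (2 / M) * rr$ree
  U[ctx$ref] <- U[ctx$ref] + (2 / M) * sum(rr$ree)

  cg <- cos(theta$gamma); sg <- sin(theta$gamma)
  d1u <- as.numeric(crossprod(ctx$D1, U))
  d2u <- as.numeric(crossprod(ctx$D2, U))
  # sum(U) == 0, so the constant V * n_inst term contributes nothing
  g_v <- cg * d1u + sg * d2u
  g_gamma <- theta$v * (cg * d2u - sg * d1u)

  n <- length(theta$q)
  u14 <- as.numeric(crossprod(ctx$P14, U)) / theta$scee
  unb <- as.numeric(crossprod(ctx$Pnb, U))
  g_q <- accumulate_by_index(
    c(u14 * theta$q[ctx$j14], u14 * theta$q[ctx$i14],
      unb * theta$q[ctx$jnb], unb * theta$q[ctx$inb]),
    c(ctx$i14, ctx$j14, ctx$inb, ctx$jnb), n)

  w14 <- theta$q[ctx$i14] * theta$q[ctx$j14]
  e14 <- as.numeric(ctx$P14 %*% w14) / theta$scee
  g_scee <- -sum(U * e14) / theta$scee

  # penalties
  g_v <- g_v + config$lambda_dih * 2 * (theta$v - ctx$v_ref)
  qsum <- sum(theta$q)
  g_q <- g_q + config$lambda_csum * 2 * qsum
  if (!is.null(attr(ctx, "qbar"))) {
    sig <- pmax(attr(ctx, "sigma"), config$sigma_floor)
    g_q[ctx$free_q] <- g_q[ctx$free_q] +
      config$lambda_chg * 2 * (theta$q[ctx$free_q] - attr(ctx, "qbar")) /
        (2 * sig)^2
  }
  g_scee <- g_scee + config$lambda_scee * 2 * (theta$scee - config$scee_ref)

  list(v = g_v, gamma = g_gamma, q = g_q, scee = g_scee)
}

#' Analytic gradient of the fitting cost
#'
#' Exact derivatives of [fit_cost()] with respect to every free torsion
#' amplitude and phase, every optimizable atomic charge and the 1-4
#' scaling factor, including the dependence through the reference
#' structure's MM energy. Entries for fixed parameters are zeroed.
#'
#' @inheritParams fit_cost
#' @return list with `v`, `gamma` (per free (type, n) term, phase
#'   derivatives per radian), `q` (per atom), `scee`
#' @export
fit_cost_gradient <- function(params, ctx, config = fit_config(),
                              charge_stats = NULL, idx = NULL) {
  ctx <- attach_charge_statistics(ctx, charge_stats, config)
  theta <- theta_from_params(ctx, params)
  if (is.null(idx)) idx <- seq_len(ctx$S)
  g <- ctx_gradient(ctx, theta, config, idx)
  if (!config$free_gamma) g$gamma[] <- 0
  if (!config$fit_charges) g$q[] <- 0
  g$q[!ctx$free_q] <- 0
  if (!config$fit_scee) g$scee <- 0
  names(g$v) <- names(g$gamma) <- paste0(ctx$k_type, ":", ctx$k_n)
  names(g$q) <- ctx$labels
  g
}

#' One Adadelta update
#'
#' The learning-rate-free update rule: accumulate a running average of
#' squared gradients with decay `rho`, scale the step by the ratio of
#' root-mean-square previous updates to root-mean-square gradients, and
#' accumulate the squared update.
#'
#' @param grad numeric gradient vector
#' @param state list with `eg2` and `edx2` running averages (use
#'   [adadelta_init()] for the empty state)
#' @param rho decay constant
#' @param eps numerical-stability constant
#' @param lr step multiplier; 1 gives the original learning-rate-free
#'   rule. Deep-learning frameworks expose the same multiplier, and the
#'   fitter anneals it: on very stiff penalty surfaces the original
#'   rule's step size never decays and the iterates enter a growing
#'   limit cycle
#' @return list with `delta` (the parameter update, already negated) and
#'   the new `state`
#' @export
adadelta_step <- function(grad, state, rho = 0.95, eps = 1e-6, lr = 1) {
  eg2 <- rho * state$eg2 + (1 - rho) * grad^2
  delta <- -lr * sqrt(state$edx2 + eps) / sqrt(eg2 + eps) * grad
  edx2 <- rho * state$edx2 + (1 - rho) * delta^2
  list(delta = delta, state = list(eg2 = eg2, edx2 = edx2))
}

#' Empty Adadelta state
#' @param n number of parameters
#' @export
adadelta_init <- function(n) list(eg2 = numeric(n), edx2 = numeric(n))

#' Fit torsion, charge and scee parameters by Adadelta descent
#'
#' Full-batch gradient descent on the penalized cost over the training
#' structures. Phases are wrapped into \[0, 360) after each step, fixed
#' charges (aliphatic hydrogens) are pinned at zero throughout, and the
#' test cost is tracked every epoch so over-fitting can be inspected.
#' Deterministic given identical inputs and configuration.
#'
#' @param cs a curated `conformer_set` with reference energies (must
#'   contain the reference structure)
#' @param start_params the starting and penalty-reference
#'   [parameter_set()]
#' @param charge_stats optional [charge_statistics()] restraint targets
#' @param config a [fit_config()]
#' @param train_ids,test_ids structure id subsets; default: all train
#' @return object of class `fit_result`: list with `params` (optimized
#'   [parameter_set()]), `trajectory` (data.frame epoch, train_cost,
#'   test_cost), `penalties` at the optimum (unweighted), `final_cost`
#'   (train cost after any polish), `train_ree` and `test_ree`
#'   summaries, `epochs`, `stop_reason`, `config`
#' @export
fit_parameters <- function(cs, start_params, charge_stats = NULL,
                           config = fit_config(), train_ids = NULL,
                           test_ids = NULL) {
  ctx <- build_fit_context(cs, start_params, config)
  ctx <- attach_charge_statistics(ctx, charge_stats, config)
  train_idx <- if (is.null(train_ids)) seq_len(ctx$S)
               else match(train_ids, ctx$ids)
  test_idx <- if (is.null(test_ids)) integer(0) else match(test_ids, ctx$ids)
  if (anyNA(train_idx) || anyNA(test_idx)) stop("unknown structure id in split")
  if (!(ctx$ref %in% train_idx)) {
    stop("the reference structure must be part of the training set")
  }

  theta <- theta_from_params(ctx, start_params)
  npar <- 2 * length(theta$v) + length(theta$q) + 1L
  state <- adadelta_init(npar)
  pack <- function(g) c(g$v, g$gamma, g$q, g$scee)
  Kv <- length(theta$v)
  nq <- length(theta$q)

  eval_cost <- function(idx) {
    rr <- ctx_ree(ctx, theta, idx)
    pen <- ctx_penalties(ctx, theta, config)
    unname(mean(rr$ree^2) + config$lambda_csum * pen["csum"] +
             config$lambda_chg * pen["chg"] +
             config$lambda_dih * pen["dih"] +
             config$lambda_scee * pen["scee"])
  }

  train_cost <- numeric(config$max_epochs)
  test_cost <- rep(NA_real_, config$max_epochs)
  prev_cost <- eval_cost(train_idx)
  stop_reason <- "max_epochs"
  quiet_epochs <- 0L
  last_good <- theta
  epochs <- 0L

  for (ep in seq_len(config$max_epochs)) {
    g <- ctx_gradient(ctx, theta, config, train_idx)
    if (!config$free_gamma) g$gamma[] <- 0
    if (!config$fit_charges) g$q[] <- 0
    g$q[!ctx$free_q] <- 0
    if (!config$fit_scee) g$scee <- 0

    st <- adadelta_step(pack(g), state, config$rho, config$adadelta_eps,
                        lr = config$lr_decay^(ep - 1))
    state <- st$state
    d <- st$delta
    theta$v <- theta$v + d[seq_len(Kv)]
    theta$gamma <- (theta$gamma + d[Kv + seq_len(Kv)]) %% (2 * pi)
    theta$q <- theta$q + d[2 * Kv + seq_len(nq)]
    theta$q[!ctx$free_q] <- 0
    theta$scee <- theta$scee + d[npar]

    ctr <- eval_cost(train_idx)
    if (!is.finite(ctr)) {
      theta <- last_good
      stop_reason <- "non-finite cost; reverted to last finite state"
      epochs <- ep
      train_cost[ep] <- NA_real_
      break
    }
    last_good <- theta
    train_cost[ep] <- ctr
    if (length(test_idx)) test_cost[ep] <- eval_cost(test_idx)

    rel <- abs(ctr - prev_cost) / max(abs(prev_cost), 1e-10)
    quiet_epochs <- if (rel < config$tol) quiet_epochs + 1L else 0L
    prev_cost <- ctr
    epochs <- ep
    if (quiet_epochs >= config$patience) {
      stop_reason <- "converged"
      break
    }
  }

  if (config$polish && !startsWith(stop_reason, "non-finite")) {
    free_mask <- c(rep(TRUE, Kv),
                   rep(config$free_gamma, Kv),
                   ctx$free_q & config$fit_charges,
                   config$fit_scee)
    full0 <- c(theta$v, theta$gamma, theta$q, theta$scee)
    unpack <- function(x) {
      full <- full0
      full[free_mask] <- x
      list(v = full[seq_len(Kv)], gamma = full[Kv + seq_len(Kv)],
           q = full[2 * Kv + seq_len(nq)], scee = full[npar])
    }
    M <- length(train_idx)
    qbar <- attr(ctx, "qbar")
    sig <- pmax(attr(ctx, "sigma"), config$sigma_floor)
    w_csum <- sqrt(config$lambda_csum)
    w_chg <- sqrt(config$lambda_chg)
    w_dih <- sqrt(config$lambda_dih)
    w_scee <- sqrt(config$lambda_scee)
    resid_fn <- function(x) {
      th <- unpack(x)
      rr <- ctx_ree(ctx, th, train_idx)
      c(rr$ree / sqrt(M),
        w_csum * sum(th$q),
        if (!is.null(qbar)) w_chg * (th$q[ctx$free_q] - qbar) / (2 * sig),
        w_dih * (th$v - ctx$v_ref),
        w_scee * (th$scee - config$scee_ref))
    }
    jac_fn <- function(x) {
      th <- unpack(x)
      J <- ctx_emm_jacobian(ctx, th)
      Jree <- -sweep(J[train_idx, , drop = FALSE], 2, J[ctx$ref, ]) / sqrt(M)
      rows <- list(Jree)
      r_csum <- numeric(npar)
      r_csum[2 * Kv + seq_len(nq)] <- w_csum
      rows$csum <- r_csum
      if (!is.null(qbar)) {
        Jchg <- matrix(0, sum(ctx$free_q), npar)
        Jchg[cbind(seq_len(sum(ctx$free_q)), 2 * Kv + which(ctx$free_q))] <-
          w_chg / (2 * sig)
        rows$chg <- Jchg
      }
      Jdih <- matrix(0, Kv, npar)
      Jdih[cbind(seq_len(Kv), seq_len(Kv))] <- w_dih
      rows$dih <- Jdih
      r_scee <- numeric(npar); r_scee[npar] <- w_scee
      rows$scee <- r_scee
      do.call(rbind, rows)[, free_mask, drop = FALSE]
    }
    lm <- minpack.lm::nls.lm(full0[free_mask], fn = resid_fn, jac = jac_fn,
                             control = minpack.lm::nls.lm.control(
                               maxiter = config$polish_maxit,
                               ftol = 1e-14, ptol = 1e-14))
    lm_cost <- sum(resid_fn(lm$par)^2)
    if (is.finite(lm_cost) && lm_cost <= prev_cost) {
      theta <- unpack(lm$par)
      theta$gamma <- theta$gamma %% (2 * pi)
      stop_reason <- paste0(stop_reason, " + polished")
    }
  }

  final_cost <- eval_cost(train_idx)
  out_params <- params_from_theta(ctx, start_params, theta)
  rr_train <- ctx_ree(ctx, theta, train_idx)$ree
  summary_of <- function(r) list(mean = mean(r), mean_abs = mean(abs(r)),
                                 sd = stats::sd(r))
  structure(list(
    params = out_params,
    trajectory = data.frame(epoch = seq_len(epochs),
                            train_cost = train_cost[seq_len(epochs)],
                            test_cost = test_cost[seq_len(epochs)]),
    penalties = ctx_penalties(ctx, theta, config),
    final_cost = final_cost,
    train_ree = summary_of(rr_train),
    test_ree = if (length(test_idx)) {
      summary_of(ctx_ree(ctx, theta, test_idx)$ree)
    } else NULL,
    epochs = epochs, stop_reason = stop_reason, config = config
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:", x$epochs, "epochs (", x$stop_reason, ")\n")
  cat(sprintf("  final train cost %.6g; train <REE> %.4f (|REE| %.4f, sd %.4f)\n",
              x$final_cost, x$train_ree$mean,
              x$train_ree$mean_abs, x$train_ree$sd))
  if (!is.null(x$test_ree)) {
    cat(sprintf("  test <REE> %.4f (|REE| %.4f, sd %.4f)\n",
                x$test_ree$mean, x$test_ree$mean_abs, x$test_ree$sd))
  }
  cat(sprintf("  fitted scee %.4f; net charge %.2e e\n",
              x$params$scee, sum(x$params$charges)))
  invisible(x)
}
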