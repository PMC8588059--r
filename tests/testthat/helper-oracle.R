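# Independent brute-force AMBER-form energy evaluator, written separately
# from the engine: Floyd-Warshall bond-path distances, plain double loops
# over every atom pair, scalar term-by-term sums. Used as the oracle the
# vectorized engine must match.

bf_canonical <- function(types) {
  fwd <- paste(types, collapse = "-")
  bwd <- paste(rev(types), collapse = "-")
  if (bwd < fwd) bwd else fwd
}

bf_path_distances <- function(n, bonds) {
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (b in seq_len(nrow(bonds))) {
    D[bonds[b, 1], bonds[b, 2]] <- 1
    D[bonds[b, 2], bonds[b, 1]] <- 1
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

bf_dihedral <- function(xyz, i, j, k, l) {
  u1 <- xyz[j, ] - xyz[i, ]; u2 <- xyz[k, ] - xyz[j, ]; u3 <- xyz[l, ] - xyz[k, ]
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(u1, u2); n2 <- cr(u2, u3)
  x <- sum(n1 * n2)
  y <- sum(cr(n1, n2) * u2 / sqrt(sum(u2^2)))
  atan2(y, x)
}

brute_force_energy <- function(topology, params, xyz) {
  n <- nrow(topology$atoms)
  ty <- topology$atoms$type
  q <- unname(params$charges[topology$atoms$label])
  bonds <- topology$bonds
  D <- bf_path_distances(n, bonds)
  adj <- lapply(seq_len(n), function(i) which(D[i, ] == 1))
  kc <- 332.0522173

  e_bond <- 0
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    key <- bf_canonical(c(ty[i], ty[j]))
    row <- params$bond[params$bond$type == key, ]
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    e_bond <- e_bond + row$kb * (r - row$r0)^2
  }

  e_angle <- 0
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    for (ii in seq_along(nb)) for (kk in seq_along(nb)) {
      if (nb[ii] >= nb[kk]) next
      key <- bf_canonical(c(ty[nb[ii]], ty[j], ty[nb[kk]]))
      row <- params$angle[params$angle$type == key, ]
      a <- xyz[nb[ii], ] - xyz[j, ]; b <- xyz[nb[kk], ] - xyz[j, ]
      th <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
      e_angle <- e_angle + row$ktheta * (th - row$theta0 * pi / 180)^2
    }
  }

  e_tor <- 0
  for (b in seq_len(nrow(bonds))) {
    j <- bonds[b, 1]; k <- bonds[b, 2]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
      if (i == l) next
      key <- bf_canonical(c(ty[i], ty[j], ty[k], ty[l]))
      rows <- params$torsion[params$torsion$type == key, ]
      phi <- bf_dihedral(xyz, i, j, k, l)
      for (r in seq_len(nrow(rows))) {
        e_tor <- e_tor + rows$v[r] *
          (1 + cos(rows$n[r] * phi - rows$gamma[r] * pi / 180))
      }
    }
  }

  e_lj14 <- 0; e_c14 <- 0; e_ljnb <- 0; e_cnb <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] <= 2) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    li <- params$lj[params$lj$type == ty[i], ]
    lj_ <- params$lj[params$lj$type == ty[j], ]
    rmin <- li$rmin2 + lj_$rmin2
    eps <- sqrt(li$eps * lj_$eps)
    A <- eps * rmin^12; B <- 2 * eps * rmin^6
    elj <- A / r^12 - B / r^6
    ec <- kc * q[i] * q[j] / (params$dielectric * r)
    if (D[i, j] == 3) {
      e_lj14 <- e_lj14 + elj / params$scnb
      e_c14 <- e_c14 + ec / params$scee
    } else {
      e_ljnb <- e_ljnb + elj
      e_cnb <- e_cnb + ec
    }
  }

  e_bond + e_angle + e_tor + e_lj14 + e_c14 + e_ljnb + e_cnb
}

# --- small constructed topologies -----------------------------------------

chain_topology <- function(n, type = "A") {
  atoms <- data.frame(label = paste0("X", seq_len(n)),
                      element = rep("C", n), type = rep(type, n),
                      stringsAsFactors = FALSE)
  bonds <- cbind(seq_len(n - 1), 2:n)
  build_connectivity(atoms, bonds)
}

# random small perturbation of the packaged chair, reproducible
jittered_glucose <- function(seed, sd = 0.05) {
  xyz <- glucose_coordinates()
  local_seed_jitter(seed, xyz, sd)
}

local_seed_jitter <- function(seed, xyz, sd) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  xyz + matrix(rnorm(length(xyz), 0, sd), nrow(xyz), 3)
}

# small synthetic dataset shared across tests (lazily built once)
small_synth <- local({
  cache <- NULL
  function(n = 60, seed = 2024, noise_sd = 0) {
    key <- paste(n, seed, noise_sd)
    if (is.null(cache[[key]])) {
      cfg <- generator_config(n = n, seed = seed, noise_sd = noise_sd)
      cache[[key]] <<- synthetic_dataset(cfg)
    }
    cache[[key]]
  }
})
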