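# AMBER-form vacuum energy: harmonic bonds and angles, torsion Fourier
# series, Lennard-Jones and Coulomb terms with 1-4 scaling, no cutoff.

#' Electrostatic conversion constant
#'
#' Coulomb prefactor in kcal A / (mol e^2), the AMBER convention, so that
#' q_i q_j / (eps r) with charges in elementary charge and distances in
#' Angstrom yields kcal/mol.
#' @export
KCOUL <- 332.0522173

#' Torsion Fourier-series energy
#'
#' Sum over terms of V (1 + cos(n phi - gamma)).
#'
#' @param phi dihedral angle in radians
#' @param fourier data.frame with columns `n` (1..6), `v` (kcal/mol),
#'   `gamma` (degrees); zero rows give zero energy
#' @return energy in kcal/mol
#' @export
torsion_energy <- function(phi, fourier) {
  if (is.null(fourier) || nrow(fourier) == 0) return(0)
  if (any(fourier$n < 1 | fourier$n > 6)) stop("periodicity must be in 1..6")
  sum(fourier$v * (1 + cos(fourier$n * phi - deg2rad(fourier$gamma))))
}

#' Coulomb pair energy
#' @param qi,qj charges in elementary charge
#' @param r distance in Angstrom (> 0)
#' @param dielectric relative permittivity
#' @return energy in kcal/mol
#' @export
coulomb <- function(qi, qj, r, dielectric = 1.0) {
  if (any(r <= 0)) stop("coulomb: r must be positive")
  KCOUL * qi * qj / (dielectric * r)
}

#' 1-4 Coulomb pair energy (divided by scee)
#' @inheritParams coulomb
#' @param scee 1-4 electrostatic scaling divisor
#' @export
coulomb_14 <- function(qi, qj, r, scee, dielectric = 1.0) {
  coulomb(qi, qj, r, dielectric) / scee
}

#' Lennard-Jones pair energy A/r^12 - B/r^6
#' @param A,B pair coefficients (kcal/mol A^12, kcal/mol A^6)
#' @param r distance in Angstrom (> 0)
#' @export
lj <- function(A, B, r) {
  if (any(r <= 0)) stop("lj: r must be positive")
  A / r^12 - B / r^6
}

#' 1-4 Lennard-Jones pair energy (divided by scnb)
#' @inheritParams lj
#' @param scnb 1-4 van der Waals scaling divisor
#' @export
lj_14 <- function(A, B, r, scnb) lj(A, B, r) / scnb

# Lorentz-Berthelot pair coefficients for atom-type pairs.
# Returns list(A, B) vectors for the given type pairs.
lj_pair_coefficients <- function(lj_table, types_i, types_j) {
  idx_i <- match(types_i, lj_table$type)
  idx_j <- match(types_j, lj_table$type)
  if (anyNA(idx_i) || anyNA(idx_j)) {
    missing <- unique(c(types_i[is.na(idx_i)], types_j[is.na(idx_j)]))
    stop("missing Lennard-Jones parameters for type(s): ",
         paste(missing, collapse = ", "))
  }
  rmin <- lj_table$rmin2[idx_i] + lj_table$rmin2[idx_j]
  eps <- sqrt(lj_table$eps[idx_i] * lj_table$eps[idx_j])
  list(A = eps * rmin^12, B = 2 * eps * rmin^6)
}

# Vectorized dihedral angles for a 4-column index matrix. Radians.
dihedral_angles_all <- function(xyz, quads) {
  if (nrow(quads) == 0) return(numeric(0))
  b1 <- xyz[quads[, 2], , drop = FALSE] - xyz[quads[, 1], , drop = FALSE]
  b2 <- xyz[quads[, 3], , drop = FALSE] - xyz[quads[, 2], , drop = FALSE]
  b3 <- xyz[quads[, 4], , drop = FALSE] - xyz[quads[, 3], , drop = FALSE]
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  m1 <- cross(n1, b2) / sqrt(rowSums(b2^2))
  phi <- atan2(rowSums(m1 * n2), rowSums(n1 * n2))
  phi[phi <= -pi] <- phi[phi <= -pi] + 2 * pi
  phi
}

# Coordinate-independent per-term parameter arrays for one
# topology/parameter-set combination.
energy_tables <- function(topology, params) {
  ty <- topology$atoms$type

  bond_key <- term_types(topology, "bonds")
  bi <- match(bond_key, params$bond$type)
  if (anyNA(bi)) stop("missing bond parameters for type(s): ",
                      paste(unique(bond_key[is.na(bi)]), collapse = ", "))

  ang_key <- term_types(topology, "angles")
  ai <- match(ang_key, params$angle$type)
  if (anyNA(ai)) stop("missing angle parameters for type(s): ",
                      paste(unique(ang_key[is.na(ai)]), collapse = ", "))

  dih_key <- term_types(topology, "dihedrals")
  have <- unique(params$torsion$type)
  missing <- setdiff(unique(dih_key), have)
  if (length(missing)) stop("missing torsion parameters for type(s): ",
                            paste(missing, collapse = ", "))
  # expand: one row per (dihedral instance, Fourier term)
  tor_rows <- lapply(seq_along(dih_key), function(d) {
    f <- params$torsion[params$torsion$type == dih_key[d], , drop = FALSE]
    if (nrow(f) == 0) return(NULL)
    data.frame(instance = d, type = dih_key[d], n = f$n, v = f$v,
               gamma_rad = deg2rad(f$gamma))
  })
  tor <- do.call(rbind, tor_rows)

  q <- params$charges[topology$atoms$label]
  if (is.null(params$charges) || anyNA(q)) {
    stop("missing charges for atom(s): ",
         paste(topology$atoms$label[is.na(q)], collapse = ", "))
  }

  p14 <- topology$pairs_14
  pnb <- topology$pairs_nb
  lj14 <- lj_pair_coefficients(params$lj, ty[p14[, 1]], ty[p14[, 2]])
  ljnb <- lj_pair_coefficients(params$lj, ty[pnb[, 1]], ty[pnb[, 2]])

  list(
    kb = params$bond$kb[bi], r0 = params$bond$r0[bi],
    ktheta = params$angle$ktheta[ai],
    theta0 = deg2rad(params$angle$theta0[ai]),
    tor = tor, dih_key = dih_key,
    q = as.numeric(q),
    q14 = q[p14[, 1]] * q[p14[, 2]],
    qnb = q[pnb[, 1]] * q[pnb[, 2]],
    lj14 = lj14, ljnb = ljnb
  )
}

pair_distances <- function(xyz, pairs) {
  if (nrow(pairs) == 0) return(numeric(0))
  d <- xyz[pairs[, 1], , drop = FALSE] - xyz[pairs[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Total AMBER-form energy with term decomposition
#'
#' Evaluates the full vacuum energy of one structure: harmonic bond and
#' angle terms, the torsion Fourier series over every dihedral instance,
#' 1-4 Lennard-Jones and Coulomb terms divided by `scnb` and `scee`, and
#' unscaled Lennard-Jones and Coulomb terms over all non-bonded pairs
#' (shortest-path class > 3 bonds). 1-2 and 1-3 pairs are fully
#' excluded; no distance cutoff is applied.
#'
#' @param topology a `topology`
#' @param params a complete [parameter_set()]
#' @param xyz N x 3 coordinate matrix (Angstrom)
#' @param tables precomputed result of the internal parameter expansion;
#'   supply when evaluating many structures under one parameter set
#' @return object of class `energy_breakdown`: list with components
#'   `bond`, `angle`, `torsion`, `lj_14`, `coulomb_14`, `lj_nb`,
#'   `coulomb_nb`, `total` (kcal/mol), `torsion_by_type` (named vector)
#'   and `coulomb_by_atom` (named vector of half-shares including the
#'   1-4 scaling)
#' @export
total_energy <- function(topology, params, xyz, tables = NULL) {
  tb <- if (is.null(tables)) energy_tables(topology, params) else tables

  r <- pair_distances(xyz, topology$bonds)
  e_bond <- sum(tb$kb * (r - tb$r0)^2)

  th <- vapply(seq_len(nrow(topology$angles)), function(a) {
    bend_angle(xyz, topology$angles[a, 1], topology$angles[a, 2],
               topology$angles[a, 3])
  }, numeric(1))
  e_angle <- sum(tb$ktheta * (th - tb$theta0)^2)

  phi <- dihedral_angles_all(xyz, topology$dihedrals)
  term_e <- tb$tor$v * (1 + cos(tb$tor$n * phi[tb$tor$instance] -
                                  tb$tor$gamma_rad))
  e_torsion <- sum(term_e)
  torsion_by_type <- vapply(split(term_e, tb$tor$type), sum, numeric(1))

  r14 <- pair_distances(xyz, topology$pairs_14)
  if (any(r14 <= 0)) stop("coincident atoms in 1-4 pair")
  e_lj14 <- sum(tb$lj14$A / r14^12 - tb$lj14$B / r14^6) / params$scnb
  ec14_pairs <- KCOUL * tb$q14 / (params$dielectric * r14) / params$scee
  e_c14 <- sum(ec14_pairs)

  rnb <- pair_distances(xyz, topology$pairs_nb)
  if (any(rnb <= 0)) stop("coincident atoms in non-bonded pair")
  e_ljnb <- sum(tb$ljnb$A / rnb^12 - tb$ljnb$B / rnb^6)
  ecnb_pairs <- KCOUL * tb$qnb / (params$dielectric * rnb)
  e_cnb <- sum(ecnb_pairs)

  n <- nrow(topology$atoms)
  coulomb_by_atom <- numeric(n)
  half <- ecnb_pairs / 2
  for (col in 1:2) {
    coulomb_by_atom <- coulomb_by_atom +
      unname(tapply(c(half, ec14_pairs / 2),
                    factor(c(topology$pairs_nb[, col],
                             topology$pairs_14[, col]), levels = seq_len(n)),
                    sum, default = 0))
  }
  names(coulomb_by_atom) <- topology$atoms$label

  structure(list(
    bond = e_bond, angle = e_angle, torsion = e_torsion,
    lj_14 = e_lj14, coulomb_14 = e_c14, lj_nb = e_ljnb, coulomb_nb = e_cnb,
    total = e_bond + e_angle + e_torsion + e_lj14 + e_c14 + e_ljnb + e_cnb,
    torsion_by_type = torsion_by_type, coulomb_by_atom = coulomb_by_atom
  ), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  comps <- c("bond", "angle", "torsion", "lj_14", "coulomb_14",
             "lj_nb", "coulomb_nb", "total")
  cat("energy breakdown (kcal/mol):\n")
  for (k in comps) cat(sprintf("  %-11s %12.4f\n", k, x[[k]]))
  invisible(x)
}

#' Total MM energies for every structure in a conformer set
#'
#' @param cs a `conformer_set`
#' @param params a [parameter_set()]
#' @return numeric vector of total energies (kcal/mol)
#' @export
conformer_energies <- function(cs, params) {
  tb <- energy_tables(cs$topology, params)
  vapply(seq_len(n_conformers(cs)), function(s) {
    total_energy(cs$topology, params, cs$xyz[, , s], tables = tb)$total
  }, numeric(1))
}

#' Relative energy error of a conformer set under a parameter set
#'
#' For each structure s, REE(s) = (Eqm_s - Eqm_ref) - (Emm_s - Emm_ref),
#' where ref is the designated reference structure (minimum reference
#' energy). The summary reports the signed mean, the mean absolute value
#' and the standard deviation, since published mean-REE summaries do not
#' always state which convention they use.
#'
#' @param cs a `conformer_set` with reference energies for all structures
#' @param params a [parameter_set()]
#' @param mm_energies optional precomputed total MM energies
#' @return list with `per_structure` (data.frame id, qm_rel, mm_rel,
#'   ree), `mean` (signed), `mean_abs`, `sd`, `ref_id`
#' @export
relative_energy_error <- function(cs, params, mm_energies = NULL) {
  if (is.null(cs$qm_energy) || is.na(cs$ref)) {
    stop("conformer set has no designated reference structure")
  }
  if (anyNA(cs$qm_energy)) stop("reference energies missing for some structures")
  emm <- if (is.null(mm_energies)) conformer_energies(cs, params) else mm_energies
  qm_rel <- cs$qm_energy - cs$qm_energy[cs$ref]
  mm_rel <- emm - emm[cs$ref]
  ree <- qm_rel - mm_rel
  list(per_structure = data.frame(id = cs$ids, qm_rel = qm_rel,
                                  mm_rel = mm_rel, ree = ree,
                                  stringsAsFactors = FALSE),
       mean = mean(ree), mean_abs = mean(abs(ree)), sd = stats::sd(ree),
       ref_id = cs$ids[cs$ref])
}
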