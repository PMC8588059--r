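# Synthetic glucose conformer datasets with a known ground-truth energy
# oracle, emulating the role of the quantum-chemistry reference so
# curation, fitting and evaluation are testable end to end.

#' Ground-truth parameter set for synthetic studies
#'
#' The shipped starting parameter set with fixed, documented
#' perturbations, so that recovering it by fitting is non-trivial:
#' the hydroxymethyl/vicinal O-C-C-O torsion type (`Oh-Cg-Cg-Os`) and
#' the hydroxyl torsion type (`Cg-Cg-Oh-Ho`) have shifted Fourier
#' amplitudes (within 1 kcal/mol of the start), the 17 optimizable
#' charges are displaced by a neutrality-preserving pattern (within
#' 0.05 e), and the 1-4 electrostatic scaling factor is 1.017 instead
#' of 1.
#'
#' @param start the starting [parameter_set()]
#' @return a [parameter_set()]
#' @export
ground_truth_parameters <- function(start = glucose_parameters()) {
  p <- start
  bump <- function(tors, type, n, dv) {
    hit <- tors$type == type & tors$n == n
    if (any(hit)) {
      tors$v[hit] <- tors$v[hit] + dv
    } else {
      tors <- rbind(tors, data.frame(type = type, n = n, v = dv, gamma = 0))
    }
    tors
  }
  p$torsion <- bump(p$torsion, "Oh-Cg-Cg-Os", 1L, 0.70)
  p$torsion <- bump(p$torsion, "Oh-Cg-Cg-Os", 2L, -0.45)
  p$torsion <- bump(p$torsion, "Oh-Cg-Cg-Os", 3L, 0.35)
  p$torsion <- bump(p$torsion, "Cg-Cg-Oh-Ho", 1L, -0.60)
  p$torsion <- bump(p$torsion, "Cg-Cg-Oh-Ho", 2L, 0.25)
  p$torsion <- bump(p$torsion, "Cg-Cg-Oh-Ho", 3L, 0.40)
  p$torsion <- p$torsion[order(p$torsion$type, p$torsion$n), ]
  rownames(p$torsion) <- NULL

  dq <- c(C1 = 0.030, O1 = -0.040, HO1 = 0.025, O5 = -0.030,
          C6 = 0.020, O6 = -0.035, HO6 = 0.030, C2 = -0.015,
          O2 = 0.020, HO2 = -0.020, C3 = 0.010, O3 = 0.015,
          HO3 = -0.025, C4 = -0.010, O4 = 0.030, HO4 = -0.020,
          C5 = 0.015)
  stopifnot(abs(sum(dq)) < 1e-12)
  p$charges[names(dq)] <- p$charges[names(dq)] + dq
  p$scee <- 1.017
  p
}

#' Generator configuration for synthetic glucose conformers
#'
#' Defaults emulate a diverse vacuum conformer ensemble of the 4C1
#' chair: every exocyclic rotatable bond (the five hydroxyl torsions
#' and the hydroxymethyl torsion) sampled uniformly over the full
#' circle, a small Cartesian jitter standing in for optimizer /
#' thermal scatter, and an optional ring-flip perturbation of the
#' anomeric carbon.
#'
#' @param n number of structures
#' @param dihedral_ranges named list: each element is
#'   `list(dihedral = c(4 labels), min, max)` sampled uniformly in
#'   degrees
#' @param jitter_sd Cartesian jitter standard deviation (Angstrom)
#' @param flip_range ring-flip angle range in degrees (length 2), or
#'   NULL for none
#' @param noise_sd energy noise standard deviation (kcal/mol)
#' @param truth ground-truth [parameter_set()] for the energy oracle
#' @param seed integer seed (mandatory)
#' @return list of class `generator_config`
#' @export
generator_config <- function(n = 1000,
                             dihedral_ranges = default_dihedral_ranges(),
                             jitter_sd = 0.01, flip_range = c(-4, 5),
                             noise_sd = 0,
                             truth = ground_truth_parameters(), seed) {
  if (missing(seed)) stop("generator_config: seed is required")
  stopifnot(n >= 1, jitter_sd >= 0, noise_sd >= 0)
  structure(list(n = as.integer(n), dihedral_ranges = dihedral_ranges,
                 jitter_sd = jitter_sd, flip_range = flip_range,
                 noise_sd = noise_sd, truth = truth,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Default sampled torsions of the glucose generator
#'
#' The five hydroxyl rotations and the hydroxymethyl rotation, each
#' over the full circle.
#' @return named list of sampling specifications
#' @export
default_dihedral_ranges <- function() {
  full <- c(-180, 180)
  list(
    omega = list(dihedral = c("O5", "C5", "C6", "O6"), min = full[1], max = full[2]),
    ho1 = list(dihedral = c("C2", "C1", "O1", "HO1"), min = full[1], max = full[2]),
    ho2 = list(dihedral = c("C1", "C2", "O2", "HO2"), min = full[1], max = full[2]),
    ho3 = list(dihedral = c("C2", "C3", "O3", "HO3"), min = full[1], max = full[2]),
    ho4 = list(dihedral = c("C3", "C4", "O4", "HO4"), min = full[1], max = full[2]),
    ho6 = list(dihedral = c("C5", "C6", "O6", "HO6"), min = full[1], max = full[2])
  )
}

#' Generate synthetic glucose conformers
#'
#' Starts from the packaged 4C1 chair, drives each configured dihedral
#' to a uniform random target, optionally applies a random ring-flip
#' perturbation of C1, and adds Gaussian Cartesian jitter. Fully
#' reproducible from the configuration seed.
#'
#' @param config a [generator_config()]
#' @return a `conformer_set` (no energies; attach them with
#'   [oracle_energies()])
#' @export
generate_conformers <- function(config) {
  topo <- glucose_template()
  base <- glucose_coordinates()
  local_rng(config$seed, {
    frames <- vector("list", config$n)
    for (s in seq_len(config$n)) {
      xyz <- base
      for (spec in config$dihedral_ranges) {
        target <- stats::runif(1, spec$min, spec$max)
        xyz <- set_dihedral(xyz, topo, spec$dihedral, target)
      }
      if (!is.null(config$flip_range)) {
        ang <- stats::runif(1, config$flip_range[1], config$flip_range[2])
        fs <- make_ring_flip_scan(xyz, topo, "C1", angles = ang)
        xyz <- fs$xyz[, , 1]
      }
      if (config$jitter_sd > 0) {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, config$jitter_sd),
                            nrow(xyz), 3)
      }
      frames[[s]] <- xyz
    }
    conformer_set(topo, frames)
  })
}

#' Attach ground-truth oracle energies to a conformer set
#'
#' The reference-energy role is played by the total MM energy under the
#' ground-truth parameters plus optional independent Gaussian noise.
#' The structure with the minimum oracle energy becomes the reference.
#'
#' @param cs a `conformer_set`
#' @param truth ground-truth [parameter_set()]
#' @param noise_sd Gaussian noise SD (kcal/mol)
#' @param seed integer seed for the noise draw
#' @return the conformer set with `qm_energy` (and reference) set
#' @export
oracle_energies <- function(cs, truth = ground_truth_parameters(),
                            noise_sd = 0, seed = 1L) {
  e <- conformer_energies(cs, truth)
  if (noise_sd > 0) {
    e <- e + local_rng(seed, stats::rnorm(length(e), 0, noise_sd))
  }
  conformer_set(cs$topology, cs$xyz, ids = cs$ids, qm_energy = e,
                charges = cs$charges)
}

#' Emulate per-structure restrained-charge ensembles
#'
#' Draws one charge set per structure: independent normal draws per
#' optimizable atom around the given means, with aliphatic hydrogens
#' fixed at exactly zero, emulating charge ensembles computed per
#' conformer under a zero-aliphatic-hydrogen constraint.
#'
#' @param cs a `conformer_set`
#' @param mu named means (e) for the optimizable atoms; defaults to the
#'   ground-truth charges
#' @param sigma named or scalar standard deviations (e)
#' @param seed integer seed
#' @return the conformer set with a `charges` matrix attached
#' @export
emulate_resp_sets <- function(cs, mu = NULL, sigma = 0.02, seed = 1L) {
  topo <- cs$topology
  free <- topo$atoms$charge_free
  labs <- topo$atoms$label[free]
  if (is.null(mu)) mu <- ground_truth_parameters()$charges[labs]
  mu <- mu[labs]
  if (anyNA(mu)) stop("charge means missing for: ",
                      paste(labs[is.na(mu)], collapse = ", "))
  if (length(sigma) == 1) sigma <- stats::setNames(rep(sigma, length(labs)), labs)
  sigma <- sigma[labs]
  S <- n_conformers(cs)
  q <- matrix(0, S, nrow(topo$atoms),
              dimnames = list(NULL, topo$atoms$label))
  draws <- local_rng(seed, matrix(stats::rnorm(S * length(labs)), S))
  q[, labs] <- sweep(sweep(draws, 2, sigma, `*`), 2, mu, `+`)
  conformer_set(topo, cs$xyz, ids = cs$ids, qm_energy = cs$qm_energy,
                charges = q)
}

#' One-call synthetic dataset
#'
#' [generate_conformers()] + [oracle_energies()] +
#' [emulate_resp_sets()] under a single seed.
#'
#' @inheritParams generate_conformers
#' @param resp_sigma SD of the emulated per-structure charge draws (e)
#' @return a `conformer_set` with energies and charge sets
#' @export
synthetic_dataset <- function(config, resp_sigma = 0.02) {
  cs <- generate_conformers(config)
  cs <- oracle_energies(cs, config$truth, config$noise_sd,
                        seed = config$seed + 1L)
  emulate_resp_sets(cs, mu = config$truth$charges, sigma = resp_sigma,
                    seed = config$seed + 2L)
}
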