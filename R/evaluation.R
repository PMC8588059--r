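# Improvement decomposition between two parameter sets, and the RMSE of
# relative energy errors over a deformation scan.

#' Decompose the mean-REE improvement between two parameter sets
#'
#' For parameter sets A (old) and B (new) sharing every frozen term,
#' computes the per-dihedral-type contribution `delta_d` (mean over
#' structures of the type's torsion-energy difference A - B) and the
#' per-atom electrostatic contribution `delta_i` (half-shares of the
#' Coulomb and scaled 1-4 Coulomb pair differences touching each atom),
#' together with their sums `delta_dih` and `delta_chg`.
#'
#' Two labelled variants are reported, both oriented A minus B. The
#' `literal` variant averages the raw per-structure term differences.
#' The `ref_corrected` variant measures every per-structure term
#' relative to the same term in the reference structure. With the
#' QM-minus-MM sign convention of the relative energy error, the
#' reference-corrected variant satisfies the additivity identity
#' exactly (signed means):
#' mean REE(B) - mean REE(A) = delta_dih + delta_chg,
#' and the literal variant misses it by exactly the
#' reference-structure term difference (reported as
#' `literal_residual`). Published summaries that print the identity as
#' old-minus-new on both sides are consistent with this once the REE is
#' read as MM relative energy minus QM relative energy.
#'
#' @param cs a `conformer_set` (reference energies required only for the
#'   mean-REE columns)
#' @param params_a,params_b two [parameter_set()]s valid for the
#'   topology
#' @return object of class `improvement_decomposition`: list with
#'   `per_type` (data.frame type, delta_literal, delta_ref_corrected),
#'   `per_atom` (same per atom), `delta_dih`, `delta_chg` (named
#'   vectors, one entry per variant), `ree_a`, `ree_b` (summaries or
#'   NULL), `additivity_residual` (ref-corrected variant),
#'   `literal_residual` (reference-structure term difference)
#' @export
improvement_decomposition <- function(cs, params_a, params_b) {
  topo <- cs$topology
  S <- n_conformers(cs)
  tba <- energy_tables(topo, params_a)
  tbb <- energy_tables(topo, params_b)
  types <- sort(unique(term_types(topo, "dihedrals")))
  n <- nrow(topo$atoms)

  dtor <- matrix(0, S, length(types), dimnames = list(NULL, types))
  datom <- matrix(0, S, n, dimnames = list(NULL, topo$atoms$label))
  ea <- numeric(S); eb <- numeric(S)
  for (s in seq_len(S)) {
    ba <- total_energy(topo, params_a, cs$xyz[, , s], tables = tba)
    bb <- total_energy(topo, params_b, cs$xyz[, , s], tables = tbb)
    dtor[s, ] <- ba$torsion_by_type[types] - bb$torsion_by_type[types]
    datom[s, ] <- ba$coulomb_by_atom - bb$coulomb_by_atom
    ea[s] <- ba$total; eb[s] <- bb$total
  }

  ref <- cs$ref
  has_ref <- !is.na(ref)
  lit_type <- colMeans(dtor)
  lit_atom <- colMeans(datom)
  if (has_ref) {
    rc_type <- colMeans(sweep(dtor, 2, dtor[ref, ]))
    rc_atom <- colMeans(sweep(datom, 2, datom[ref, ]))
  } else {
    rc_type <- rep(NA_real_, length(types))
    rc_atom <- rep(NA_real_, n)
  }

  delta_dih <- c(literal = sum(lit_type), ref_corrected = sum(rc_type))
  delta_chg <- c(literal = sum(lit_atom), ref_corrected = sum(rc_atom))

  ree_a <- ree_b <- NULL
  additivity_residual <- NA_real_
  if (!is.null(cs$qm_energy) && has_ref && !anyNA(cs$qm_energy)) {
    ree_a <- relative_energy_error(cs, params_a, mm_energies = ea)
    ree_b <- relative_energy_error(cs, params_b, mm_energies = eb)
    additivity_residual <- (ree_b$mean - ree_a$mean) -
      (delta_dih[["ref_corrected"]] + delta_chg[["ref_corrected"]])
  }
  literal_residual <- if (has_ref) {
    sum(dtor[ref, ]) + sum(datom[ref, ])
  } else NA_real_

  structure(list(
    per_type = data.frame(type = types, delta_literal = unname(lit_type),
                          delta_ref_corrected = unname(rc_type),
                          stringsAsFactors = FALSE),
    per_atom = data.frame(label = topo$atoms$label,
                          delta_literal = unname(lit_atom),
                          delta_ref_corrected = unname(rc_atom),
                          stringsAsFactors = FALSE),
    delta_dih = delta_dih, delta_chg = delta_chg,
    ree_a = ree_a, ree_b = ree_b,
    additivity_residual = unname(additivity_residual),
    literal_residual = unname(literal_residual)
  ), class = "improvement_decomposition")
}

#' @export
print.improvement_decomposition <- function(x, ...) {
  cat("improvement decomposition (kcal/mol, A - B):\n")
  cat(sprintf("  delta_dih  literal %8.4f   ref-corrected %8.4f\n",
              x$delta_dih[["literal"]], x$delta_dih[["ref_corrected"]]))
  cat(sprintf("  delta_chg  literal %8.4f   ref-corrected %8.4f\n",
              x$delta_chg[["literal"]], x$delta_chg[["ref_corrected"]]))
  if (!is.null(x$ree_a)) {
    cat(sprintf("  <REE> A %8.4f   <REE> B %8.4f   additivity residual %.2e\n",
                x$ree_a$mean, x$ree_b$mean, x$additivity_residual))
  }
  invisible(x)
}

#' Root-mean-square REE over a deformation scan
#'
#' The scan supplies its own reference: the structure with the minimum
#' reference energy within the scan. RMSE = sqrt(mean(REE^2)).
#'
#' @param scan a `conformer_set` holding the scan structures with
#'   reference energies
#' @param params a [parameter_set()]
#' @return RMSE in kcal/mol
#' @export
scan_rmse <- function(scan, params) {
  if (n_conformers(scan) == 0) stop("empty scan")
  ree <- relative_energy_error(scan, params)$per_structure$ree
  sqrt(mean(ree^2))
}
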