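#' Shipped starting parameter set for beta-d-glucose
#'
#' A GLYCAM06-role AMBER parameter set for the glucose topology, shipped
#' with the package as plain frcmod + prep text fixtures: bond, angle,
#' Lennard-Jones and torsion terms for the five atom types (Cg, Oh, Os,
#' H1, Ho), a neutral charge assignment with zero charge on the seven
#' aliphatic hydrogens, and unscaled 1-4 interactions (scee = scnb = 1).
#' It is a synthetic stand-in with GLYCAM-like magnitudes, not the
#' original published GLYCAM06 tables; within the package it plays the
#' role of the fixed reference set that fitting is penalized against.
#'
#' @return a complete [parameter_set()]
#' @export
glucose_parameters <- function() {
  frc <- system.file("extdata", "glucose_ff.frcmod", package = "glycofit",
                     mustWork = TRUE)
  prep <- system.file("extdata", "glucose_charges.prep", package = "glycofit",
                      mustWork = TRUE)
  p <- read_frcmod(frc)
  tab <- read_prep_charges(prep)
  p$charges <- stats::setNames(tab$charge, tab$label)
  p
}

#' Reference refit charges for beta-d-glucose
#'
#' The published re-optimized atomic partial charges of the 17
#' non-aliphatic-hydrogen atoms of beta-d-glucose (elementary charge
#' units), shipped as a comparison/reference set. The aliphatic
#' hydrogens carry charge zero by construction; the printed set is
#' neutral to within rounding (net charge about 2e-4 e).
#'
#' @return data.frame(label, charge)
#' @export
refit_charges <- function() {
  utils::read.csv(system.file("extdata", "refit_charges.csv",
                              package = "glycofit", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Reference mean-REE improvement summary for the glucose refit
#'
#' The reported mean relative-energy-error of the baseline parameter set
#' and of refits freeing charges only, dihedrals only, or both, together
#' with the corresponding improvement decomposition Delta (kcal/mol).
#' Shipped as a consistency-check fixture: the per-class Delta values
#' are additive, and each row's mean REE equals the baseline mean REE
#' minus its Delta, within table rounding.
#'
#' @return data.frame(parameter_class, mean_ree, delta)
#' @export
ree_improvement_reference <- function() {
  utils::read.csv(system.file("extdata", "ree_improvement_reference.csv",
                              package = "glycofit", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
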