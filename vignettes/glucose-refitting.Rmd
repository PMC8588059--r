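---
title: "Refitting torsion and charge parameters for beta-d-glucose"
author: "glycofit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refitting torsion and charge parameters for beta-d-glucose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Classical simulations of carbohydrates stand or fall with the quality of
the force field. For pyranoses the widely used GLYCAM-family parameters
describe bonds, angles and van der Waals terms well, but the torsion
Fourier coefficients and the fixed atomic charges — the terms that
control rotamer preferences of the exocyclic groups and the energetics
of ring deformation — were calibrated on small model compounds and can
misrank conformers of the full sugar. glycofit implements a
re-optimization workflow for one molecule, beta-d-glucopyranose: given a
set of conformers with reference ("QM-role") energies, it refits the
torsion amplitudes and phases, the atomic partial charges of the 17
non-aliphatic-hydrogen atoms, and the 1-4 electrostatic scaling factor
`scee`, so that the force field reproduces the *relative* energies of
the conformer ensemble.

## Energy model

The molecular-mechanics energy is the standard AMBER form,

$$E = \sum_{\text{bonds}} k_b (r - r_0)^2
    + \sum_{\text{angles}} k_\theta (\theta - \theta_0)^2
    + \sum_{\text{dihedrals}} \sum_{n=1}^{6} V_n\,[1 + \cos(n\phi - \gamma_n)]
    + \sum_{1\text{-}4} \Big[ \tfrac{1}{scnb}\Big(\tfrac{A_{ij}}{r^{12}} -
      \tfrac{B_{ij}}{r^{6}}\Big) + \tfrac{1}{scee}\,
      \tfrac{q_i q_j}{\epsilon r} \Big]
    + \sum_{\text{nonbonded}} \Big[ \tfrac{A_{ij}}{r^{12}} -
      \tfrac{B_{ij}}{r^{6}} + \tfrac{q_i q_j}{\epsilon r} \Big],$$

evaluated in vacuum with no cutoff, with the electrostatic constant
332.0522173 kcal A / (mol e^2) and relative permittivity 1. Pairs are
classed by their *shortest* bond path (1-2 and 1-3 excluded, 1-4
scaled, everything else plain); using the shortest path guarantees that
a ring pair is never simultaneously excluded and scaled. Dihedral
instances are enumerated per quadruple with no AMBER divider: each
instance contributes a full Fourier term (the divider column of frcmod
files is applied on read and emitted as 1 on write).

The fitting target is the relative energy error of each structure
against the most stable (reference) structure,

$$\mathrm{REE}(s) = (E^{QM}_s - E^{QM}_{ref}) - (E^{MM}_s - E^{MM}_{ref}),$$

and the cost is the mean of squared REE over the training structures
plus four penalties:

$$C = \tfrac{1}{M}\sum_s \mathrm{REE}(s)^2
 + \lambda_{csum} \Big(\sum_i q_i\Big)^2
 + \lambda_{chg} \sum_i \frac{(q_i - \bar q_i)^2}{(2\sigma_i)^2}
 + \lambda_{dih} \sum_{\phi,n} (V_{\phi,n} - V^{ref}_{\phi,n})^2
 + \lambda_{scee} (scee - scee^{ref})^2 .$$

The neutrality term runs over *all* atoms (the aliphatic hydrogens are
pinned at exactly zero throughout); the charge restraint uses the
ensemble mean and population standard deviation of per-conformer charge
sets; the torsion restraint penalizes amplitudes only — phases are
unpenalized; the scee reference is 1.0, the carbohydrate-force-field
convention of unscaled 1-4 electrostatics.

### Defaults that matter

| parameter | default | units | why |
|---|---|---|---|
| `lambda_csum` | 1e7 | — | the molecule must be neutral for periodic electrostatics; the weight is large enough that the fitted net charge is far below 1e-3 e |
| `lambda_chg` | 0.1 | — | keeps charges near their ensemble means without dominating the energy misfit |
| `lambda_dih` | 3.0 | — | discourages runaway torsion amplitudes |
| `lambda_scee` | 100.0 | — | scee is a single global factor; a strong restraint keeps it near 1 |
| dedup threshold | 0.05 | A (RMSD) | structures closer than this are the same conformer for fitting purposes |
| train fraction | 0.7 | — | 7:3 train/test split; the reference structure always trains |
| `sigma_floor` | 0.01 | e | lower bound on sigma_i in the charge-restraint denominator, so an atom with a tightly distributed charge ensemble cannot blow the penalty up |

## Optimization

The cost is minimized by full-batch gradient descent with Adadelta
(decay 0.95), using exact analytic gradients for every free amplitude,
phase, charge and scee, including the dependence through the reference
structure's MM energy. Two deliberate departures from the textbook
Adadelta configuration were necessary, and both are visible in
`fit_config()`:

* **Stability constant 1e-12 (not 1e-6).** Adadelta's first step has
  magnitude about `sqrt(eps)` per parameter. With the neutrality weight
  at 1e7, a collective first step of 1e-3 per charge moves the net
  charge by ~0.017 e and the penalty by ~3e3 — the descent immediately
  ricochets along the stiff net-charge direction. A smaller stability
  constant keeps the early steps below the width of that valley.
* **Annealed step multiplier.** The original update rule has no
  learning rate, and by construction its step size never decays to
  zero. On this cost surface (Hessian condition number ~2e8 between the
  neutrality direction and the softest torsion/charge trade-offs) the
  iterates enter a slowly *growing* limit cycle instead of converging.
  `adadelta_step()` therefore accepts a step multiplier — the same knob
  every deep-learning framework exposes — with default 1 (the published
  rule), and `fit_parameters()` decays it geometrically
  (`lr_decay = 0.9995` per epoch).
* **Levenberg-Marquardt polish.** The penalized cost is exactly a
  nonlinear least-squares problem (REE residuals plus square-root
  penalty residuals), so after the descent a Levenberg-Marquardt
  refinement with the analytic Jacobian (via minpack.lm) drives the
  gradient to zero. A quasi-Newton polish (L-BFGS-B) was tried first
  and crawls on the same surface; the trust-region scaling of LM
  handles the 1e7-stiff direction effortlessly. The polish is on by
  default and never accepted if it fails to improve the cost.

Phases are wrapped into [0, 360) after every step. Convergence is
declared when the relative train-cost change stays below 1e-8 for 50
consecutive epochs; the test-set cost is tracked every epoch so
over-fitting can be inspected from the trajectory.

## What the synthetic generator emulates — and what it does not

The package is testable without any quantum-chemistry software because
the reference-energy role is played by a *ground-truth* parameter set:
`generate_conformers()` builds glucose conformers from the packaged 4C1
chair by uniformly sampling the five hydroxyl torsions and the
hydroxymethyl torsion over the full circle, optionally perturbing the
ring by a small C1 flip (default -4..5 degrees), and adding Gaussian
Cartesian jitter (default 0.01 A); `oracle_energies()` then assigns
each structure its MM energy under `ground_truth_parameters()` plus
optional Gaussian noise. Per-conformer charge ensembles are emulated as
independent normal draws (default SD 0.02 e) around the ground-truth
charges, with aliphatic hydrogens exactly zero.

The ground truth is the shipped starting set with documented
perturbations: shifted Fourier amplitudes on the vicinal O-C-C-O type
(`Oh-Cg-Cg-Os`) and the hydroxyl type (`Cg-Cg-Oh-Ho`) within 1
kcal/mol, a neutrality-preserving charge displacement within 0.05 e,
and scee = 1.017. Recovering it from the shipped start is therefore a
non-trivial inverse problem whose answer is known exactly.

What this emulation deliberately lacks: Boltzmann-weighted sampling (the
dihedral distribution is uniform, not thermal), ring-pucker diversity
beyond small flips (no boat/skew populations), any systematic
QM-vs-MM model discrepancy (the oracle *is* the MM functional form, so
with zero noise the fit can reach zero error — real DFT references
cannot be matched exactly by this functional form), and solvent.
Passing the recovery tests therefore demonstrates the correctness of
the machinery — energies, gradients, curation, optimizer — not that a
refit against real QM data would reach any particular accuracy.

### Study conditions for the recovery checks

The headline recovery test uses n = 2000 conformers, zero energy noise,
a fixed seed, curation at defaults, and the 7:3 split. The free
parameters are the two perturbed torsion types (amplitudes only, phases
fixed — the generator does not perturb phases), the 17 charges and
scee. The restraint weights are relaxed to zero for this study —
`lambda_chg` and `lambda_dih` because restraining toward the start
would bias the recovered values away from the truth, and `lambda_scee`
because its default weight of 100 pulls the recovered scee about 0.016
toward the 1.0 reference when the truth is 1.017, more than the 0.01
tolerance the check uses. The neutrality weight stays at 1e7 (the truth
is neutral, so it introduces no bias and the fitted net charge can be
checked against it). Problem sizes elsewhere in the test suite (25-300
structures) were chosen so each property is exercised on the smallest
set that still identifies it.

## Curation

* **Deduplication** is a greedy keep-first pass in input order: a
  structure is dropped when its RMSD to any previously retained one is
  <= 0.05 A (inclusive). Superposition (centroid removal + optimal
  rotation) is applied before the deviation by default, since
  conformers arrive in arbitrary frames and the literal formula would
  be frame-dependent. Two rotation-invariant screens (mean interatomic
  distance, then the full sorted-pair distance fingerprint, both with
  proven lower bounds on the superposed RMSD) keep the pass close to
  O(N x retained) in practice.
* **Lennard-Jones outliers** — structures whose steric clashes produce
  an r^-12 spike that torsion/charge fitting could only absorb by
  corrupting other parameters — are removed by a robust rule: LJ term
  above median + 10 x IQR of the set (configurable absolute threshold,
  or off). The exact published criterion is unstated, so the rule and
  its parameters are explicit configuration.
* **Charge statistics** use the population (ensemble) standard
  deviation, matching the ensemble-statistic reading of the restraint
  denominator.

## Improvement decomposition

`improvement_decomposition()` attributes the change in mean REE between
two parameter sets A (old) and B (new) to individual dihedral types
(`delta_d`) and atoms (`delta_i`, half-shares of the Coulomb and scaled
1-4 pair sums touching the atom). Two labelled variants are computed,
both oriented A - B. The *literal* variant averages raw per-structure
term differences. The *reference-corrected* variant measures each term
relative to the reference structure; with the QM-minus-MM sign of the
REE it satisfies the additivity identity exactly,

$$\langle \mathrm{REE} \rangle_B - \langle \mathrm{REE} \rangle_A
  = \Delta_{DIH} + \Delta_{CHG},$$

to 1e-10 on any dataset, while the literal variant misses it by exactly
the reference-structure term difference (also reported). Published
summaries that print the identity as old-minus-new on both sides are
consistent with this algebra once their REE is read with the opposite
(MM-minus-QM) sign; rather than silently choosing, both variants are
reported and labelled. Mean REE summaries always report the signed
mean, the mean absolute value and the SD, because published tables do
not state which convention they use.

## Scans and ring analysis

Deformation scans drive a dihedral over 0..350 degrees in 10-degree
steps (36 structures) by rigid rotation of the distal subtree (ring
bonds refuse to rotate), or bend a ring atom: the C1 flip coordinate is
implemented as a rigid rotation of C1 plus its exocyclic substituents
about the axis through its ring neighbours O5 and C2, over -4..5
degrees in 1-degree steps (10 structures). The flip coordinate is a
documented convention — the source of the idea leaves it undefined.
Hydroxymethyl rotamers are classified from the O5-C5-C6-O6 dihedral
with 120-degree bins centred on the staggered values (gg at -60, gt at
+60, tg at 180) — again a documented convention. Ring puckering uses
the standard generalized puckering coordinates on the ring order O5,
C1..C5; the packaged chair has amplitude Q of about 0.58 A, and a
constructed ideal chair with alternating +-z displacements of 0.25 A
gives Q = sqrt(6 x 0.25^2) exactly.

## Numerical choices and degenerate inputs

* Angles are degrees in files and radians internally; coordinates are
  Angstrom; energies kcal/mol; charges elementary charge.
* Canonical ordering everywhere: bonds/angles/dihedrals sorted by atom
  indices, type keys reversed to the lexicographically smaller
  orientation, so outputs are reproducible byte for byte.
* Ties: the reference structure on equal minimum energies is the lowest
  row index; the split moves the reference into the training set by
  swapping with the last training slot.
* Degenerate inputs error loudly: coincident atoms in an interacting
  pair, rotating a ring bond, a collinear ring for puckering, missing
  parameters for a present type (named in the message), nonzero charge
  on an aliphatic hydrogen in a charge ensemble.
* A zero ensemble SD with an active charge restraint triggers the
  sigma floor with a warning rather than a division blow-up.

## Limitations

One molecule, one ring, no generalized bond perception: topologies are
built from explicit bond lists (the glucose template ships with the
package). The fit never touches bond, angle, Lennard-Jones or scnb
parameters. The synthetic oracle shares the MM functional form, so it
cannot probe model inadequacy — only parameter identifiability and the
correctness of the machinery. MD sampling, explicit solvent and any
quantum-chemistry computation are out of scope; real reference energies
and charge ensembles must be supplied through the manifest format.
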