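# Deformation scans: dihedral driving, ring flip, hydroxymethyl rotamer
# analysis and Cremer-Pople ring puckering.

# Atoms on the k-side of bond (j, k) after cutting it. Errors if the
# bond lies in a ring (the two sides would not separate).
distal_atoms <- function(topology, j, k) {
  n <- nrow(topology$atoms)
  seen <- rep(FALSE, n)
  seen[k] <- TRUE
  queue <- k
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in topology$adjacency[[cur]]) {
      if (cur == k && nb == j) next
      if (nb == j) {
        stop("bond ", topology$atoms$label[j], "-", topology$atoms$label[k],
             " lies in a ring; rotating it would tear the ring")
      }
      if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
    }
  }
  which(seen)
}

#' Drive a dihedral angle to a target value
#'
#' Rigidly rotates the distal side of the central bond about the bond
#' axis so the measured dihedral i-j-k-l equals `target` (degrees).
#' All bond lengths and bend angles are unchanged; rotating a ring bond
#' is an error.
#'
#' @param xyz N x 3 coordinate matrix
#' @param topology the `topology`
#' @param dihedral four atom labels (or indices) i, j, k, l
#' @param target target dihedral in degrees
#' @return new coordinate matrix; measured dihedral equals `target`
#'   within 1e-6 degrees
#' @export
set_dihedral <- function(xyz, topology, dihedral, target) {
  idx <- if (is.character(dihedral)) atom_index(topology, dihedral)
         else as.integer(dihedral)
  stopifnot(length(idx) == 4)
  i <- idx[1]; j <- idx[2]; k <- idx[3]; l <- idx[4]
  moving <- distal_atoms(topology, j, k)
  current <- rad2deg(dihedral_angle(xyz, i, j, k, l))
  delta <- deg2rad(wrap_deg_180(target - current))
  # the dihedral increases when the k-side rotates by +delta about j->k
  out <- rotate_about_axis(xyz, moving, xyz[k, ], xyz[k, ] - xyz[j, ], delta)
  achieved <- rad2deg(dihedral_angle(out, i, j, k, l))
  if (abs(wrap_deg_180(achieved - target)) > 1e-6) {
    out <- rotate_about_axis(xyz, moving, xyz[k, ], xyz[k, ] - xyz[j, ],
                             -delta)
    achieved <- rad2deg(dihedral_angle(out, i, j, k, l))
  }
  if (abs(wrap_deg_180(achieved - target)) > 1e-6) {
    stop("failed to drive dihedral to target (achieved ",
         format(achieved), " deg)")
  }
  out
}

#' Rotation scan about a bond
#'
#' One structure per grid angle of the driven dihedral; ids encode the
#' angle. The default grid 0..350 degrees in 10-degree steps yields 36
#' structures.
#'
#' @param xyz starting N x 3 coordinates
#' @param topology the `topology`
#' @param dihedral four atom labels defining the driven dihedral
#' @param angles grid of target angles in degrees
#' @return a `conformer_set` (no energies)
#' @export
make_rotation_scan <- function(xyz, topology, dihedral,
                               angles = seq(0, 350, by = 10)) {
  frames <- lapply(angles, function(a) set_dihedral(xyz, topology,
                                                    dihedral, a))
  lab <- if (is.character(dihedral)) paste(dihedral[2], dihedral[3],
                                           sep = "-") else "bond"
  conformer_set(topology, frames,
                ids = sprintf("rot_%s_%+04d", lab, as.integer(round(angles))))
}

#' Ring-flip scan of a ring atom
#'
#' The flip coordinate is implemented as a rigid rotation of the flip
#' atom together with its exocyclic substituents about the axis through
#' its two ring neighbours, signed toward ring inversion. The default
#' grid -4..5 degrees in 1-degree steps yields 10 structures; the
#' 0-degree structure is the input.
#'
#' @param xyz starting N x 3 coordinates
#' @param topology the `topology`
#' @param flip_atom label of the ring atom to displace (default "C1")
#' @param angles grid of bending angles in degrees
#' @return a `conformer_set` (no energies)
#' @export
make_ring_flip_scan <- function(xyz, topology, flip_atom = "C1",
                                angles = seq(-4, 5, by = 1)) {
  fi <- atom_index(topology, flip_atom)
  ring <- ring_atoms(topology)
  if (!(fi %in% ring)) stop(flip_atom, " is not a ring atom")
  ring_nb <- intersect(topology$adjacency[[fi]], ring)
  if (length(ring_nb) != 2) stop(flip_atom, " does not have two ring neighbours")
  # moving set: the flip atom plus its exocyclic branches
  moving <- fi
  for (nb in setdiff(topology$adjacency[[fi]], ring_nb)) {
    moving <- union(moving, distal_atoms(topology, fi, nb))
  }
  a1 <- ring_nb[1]; a2 <- ring_nb[2]
  frames <- lapply(angles, function(a) {
    rotate_about_axis(xyz, moving, xyz[a1, ], xyz[a2, ] - xyz[a1, ],
                      deg2rad(a))
  })
  conformer_set(topology, frames,
                ids = sprintf("flip_%s_%+03d", flip_atom,
                              as.integer(round(angles))))
}

# Indices of the atoms of the (single) ring of a topology.
ring_atoms <- function(topology) {
  g <- igraph::graph_from_edgelist(topology$bonds, directed = FALSE)
  if (igraph::vcount(g) < nrow(topology$atoms)) {
    g <- igraph::add_vertices(g, nrow(topology$atoms) - igraph::vcount(g))
  }
  coreness <- igraph::coreness(g)
  which(coreness >= 2)
}

#' Classify a hydroxymethyl rotamer
#'
#' Bins the O5-C5-C6-O6 dihedral into the three staggered classes with
#' 120-degree bins centred on the staggered values: gg at -60, gt at
#' +60, tg at 180 degrees.
#'
#' @param phi dihedral angle(s) in degrees
#' @return factor with levels gg, gt, tg
#' @export
classify_rotamer <- function(phi) {
  w <- wrap_deg_180(phi)
  cls <- ifelse(w >= -120 & w < 0, "gg", ifelse(w >= 0 & w < 120, "gt", "tg"))
  factor(cls, levels = c("gg", "gt", "tg"))
}

#' Rotamer populations and dihedral density of a conformer set
#'
#' Measures the chosen dihedral in every structure, classifies it with
#' [classify_rotamer()], and estimates the angular probability density
#' from a histogram normalized to integrate to 1 over 360 degrees.
#'
#' @param cs a `conformer_set`, or a numeric vector of dihedral angles
#'   in degrees
#' @param dihedral four atom labels (default the hydroxymethyl
#'   O5-C5-C6-O6)
#' @param bin_width histogram bin width in degrees
#' @return list with `fractions` (named, sums to 1), `angles` (degrees),
#'   `density` (data.frame mid, density; per-degree units)
#' @export
rotamer_populations <- function(cs, dihedral = c("O5", "C5", "C6", "O6"),
                                bin_width = 10) {
  angles <- if (is.numeric(cs)) {
    wrap_deg_180(cs)
  } else {
    idx <- atom_index(cs$topology, dihedral)
    vapply(seq_len(n_conformers(cs)), function(s) {
      rad2deg(dihedral_angle(cs$xyz[, , s], idx[1], idx[2], idx[3], idx[4]))
    }, numeric(1))
  }
  if (!length(angles)) stop("no structures to analyze")
  cls <- classify_rotamer(angles)
  fractions <- as.numeric(table(cls)) / length(cls)
  names(fractions) <- levels(cls)
  breaks <- seq(-180, 180, by = bin_width)
  h <- graphics::hist(wrap_deg_180(angles), breaks = breaks, plot = FALSE)
  list(fractions = fractions, angles = angles,
       density = data.frame(mid = h$mids, density = h$density))
}

#' Cremer-Pople puckering parameters of a six-membered ring
#'
#' Generalized ring-puckering coordinates from the standard definition:
#' displacements from the mean plane fixed by the ring's geometric
#' centre and the two lattice vectors, projected onto the m = 2 and
#' m = 3 puckering modes. For a six-membered ring the result is the
#' total amplitude Q (Angstrom), the polar angle theta (0 and 180
#' degrees are the two chairs) and the pseudorotation phase phi.
#'
#' @param ring_xyz 6 x 3 coordinate matrix in ring order; for pyranoses
#'   the convention O5, C1, C2, C3, C4, C5
#' @return list with `Q` (Angstrom), `theta` (degrees), `phi` (degrees),
#'   `z` (the six mean-plane displacements)
#' @export
cremer_pople <- function(ring_xyz) {
  stopifnot(nrow(ring_xyz) == 6, ncol(ring_xyz) == 3)
  centred <- sweep(ring_xyz, 2, colMeans(ring_xyz))
  jj <- 0:5
  rp <- colSums(centred * sin(2 * pi * jj / 6))
  rpp <- colSums(centred * cos(2 * pi * jj / 6))
  nrm <- c(rp[2] * rpp[3] - rp[3] * rpp[2],
           rp[3] * rpp[1] - rp[1] * rpp[3],
           rp[1] * rpp[2] - rp[2] * rpp[1])
  nn <- vec_norm(nrm)
  if (nn < 1e-10) stop("degenerate (collinear) ring geometry")
  nrm <- nrm / nn
  z <- as.numeric(centred %*% nrm)

  q2c <- sqrt(2 / 6) * sum(z * cos(4 * pi * jj / 6))
  q2s <- -sqrt(2 / 6) * sum(z * sin(4 * pi * jj / 6))
  q3 <- sqrt(1 / 6) * sum(z * (-1)^jj)
  q2 <- sqrt(q2c^2 + q2s^2)
  Q <- sqrt(q2^2 + q3^2)
  theta <- if (Q > 0) rad2deg(atan2(q2, q3)) else 0
  phi <- wrap_deg_360(rad2deg(atan2(q2s, q2c)))
  list(Q = Q, theta = theta, phi = phi, z = z)
}

#' Cremer-Pople amplitude of the pyranose ring in each conformer
#'
#' @param cs a `conformer_set` whose topology contains the glucose ring
#' @return data.frame(id, Q, theta, phi)
#' @export
ring_pucker <- function(cs) {
  idx <- glucose_ring_indices(cs$topology)
  out <- lapply(seq_len(n_conformers(cs)), function(s) {
    cp <- cremer_pople(cs$xyz[idx, , s])
    data.frame(id = cs$ids[s], Q = cp$Q, theta = cp$theta, phi = cp$phi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
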