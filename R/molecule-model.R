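#' Build a molecular topology from atoms and bonds
#'
#' Derives every bonded term and non-bonded pair class needed by the
#' AMBER-form energy function: angle triples, proper-dihedral quadruples,
#' and the classification of every atom pair as 1-2, 1-3, 1-4 or
#' non-bonded by its *shortest* bond-path length. Using the shortest path
#' guarantees the classes partition all pairs, so no ring pair is both
#' excluded and scaled.
#'
#' @param atoms data.frame with columns `label` (unique), `element`,
#'   `type` (force-field atom type) and optionally `charge_free`
#'   (logical; defaults to `TRUE` for non-hydrogen atoms and hydroxyl
#'   hydrogens, `FALSE` for aliphatic hydrogens).
#' @param bonds two-column integer matrix of bonded atom index pairs.
#' @return An object of class `topology`: list with `atoms` (data.frame,
#'   gains logical column `aliphatic_h`), `bonds` (sorted 2-col matrix),
#'   `angles` (3-col), `dihedrals` (4-col), `pair_class` (N x N integer
#'   matrix: 1 = bonded, 2 = 1-3, 3 = 1-4, 4 = non-bonded, 0 = self),
#'   `pairs_14`, `pairs_nb` (2-col matrices), `n_rings`, `connected`.
#' @export
build_connectivity <- function(atoms, bonds) {
  stopifnot(is.data.frame(atoms), all(c("label", "element", "type") %in% names(atoms)))
  n <- nrow(atoms)
  if (anyDuplicated(atoms$label)) {
    stop("duplicate atom labels: ",
         paste(unique(atoms$label[duplicated(atoms$label)]), collapse = ", "))
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (any(bonds < 1L) || any(bonds > n)) stop("bond index out of range")
  if (any(bonds[, 1] == bonds[, 2])) stop("self-bond not allowed")
  bonds <- t(apply(bonds, 1, sort))
  if (anyDuplicated(bonds)) stop("duplicate bonds")
  bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]

  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, sort)

  # angles: every pair of bonds sharing a middle atom
  angles <- matrix(integer(0), ncol = 3)
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      angles <- rbind(angles, cbind(cmb[1, ], j, cmb[2, ]))
    }
  }
  if (nrow(angles)) {
    flip <- angles[, 1] > angles[, 3]
    angles[flip, ] <- angles[flip, c(3, 2, 1), drop = FALSE]
    angles <- angles[order(angles[, 1], angles[, 2], angles[, 3]), , drop = FALSE]
  }

  # dihedrals: chains of three bonds, enumerated per central bond
  dihedrals <- matrix(integer(0), ncol = 4)
  for (b in seq_len(nrow(bonds))) {
    j <- bonds[b, 1]; k <- bonds[b, 2]
    for (i in setdiff(adj[[j]], k)) {
      for (l in setdiff(adj[[k]], j)) {
        if (i != l) dihedrals <- rbind(dihedrals, c(i, j, k, l))
      }
    }
  }
  if (nrow(dihedrals)) {
    dihedrals <- dihedrals[order(dihedrals[, 2], dihedrals[, 3],
                                 dihedrals[, 1], dihedrals[, 4]), , drop = FALSE]
  }

  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  d <- igraph::distances(g)
  comp <- igraph::components(g)
  connected <- comp$no == 1L
  if (!connected) warning("topology graph is disconnected")
  n_rings <- nrow(bonds) - n + comp$no

  pair_class <- matrix(4L, n, n)
  pair_class[d == 1] <- 1L
  pair_class[d == 2] <- 2L
  pair_class[d == 3] <- 3L
  diag(pair_class) <- 0L

  ut <- upper.tri(pair_class)
  idx <- which(ut & pair_class == 3L, arr.ind = TRUE)
  pairs_14 <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  idx <- which(ut & pair_class == 4L, arr.ind = TRUE)
  pairs_nb <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(pairs_14) <- colnames(pairs_nb) <- c("i", "j")

  atoms$aliphatic_h <- vapply(seq_len(n), function(i) {
    atoms$element[i] == "H" && length(adj[[i]]) == 1L &&
      atoms$element[adj[[i]][1]] == "C"
  }, logical(1))
  if (is.null(atoms$charge_free)) {
    atoms$charge_free <- !atoms$aliphatic_h
  }

  structure(list(
    atoms = atoms, bonds = bonds, angles = angles, dihedrals = dihedrals,
    pair_class = pair_class, pairs_14 = pairs_14, pairs_nb = pairs_nb,
    adjacency = adj, n_rings = n_rings, connected = connected
  ), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds,",
      nrow(x$angles), "angles,", nrow(x$dihedrals), "dihedrals,",
      x$n_rings, "ring(s)\n")
  invisible(x)
}

#' Atom index by label
#' @param topology a `topology`
#' @param labels character vector of atom labels
#' @return integer indices
#' @export
atom_index <- function(topology, labels) {
  idx <- match(labels, topology$atoms$label)
  if (anyNA(idx)) stop("unknown atom label: ",
                       paste(labels[is.na(idx)], collapse = ", "))
  idx
}

# Canonical type key for a bonded term: reverse if the reversed sequence
# sorts lower, so "Oh-Cg-Cg-Os" and "Os-Cg-Cg-Oh" name the same type.
canonical_type <- function(types) {
  fwd <- paste(types, collapse = "-")
  rev_ <- paste(rev(types), collapse = "-")
  if (rev_ < fwd) rev_ else fwd
}

#' Force-field type keys for the bonded terms of a topology
#'
#' @param topology a `topology`
#' @param what one of "bonds", "angles", "dihedrals"
#' @return character vector of canonical type keys, one per term row
#' @export
term_types <- function(topology, what = c("dihedrals", "angles", "bonds")) {
  what <- match.arg(what)
  terms <- topology[[what]]
  ty <- topology$atoms$type
  apply(terms, 1, function(r) canonical_type(ty[r]))
}

glucose_atom_table <- function() {
  labels <- c("C1", "C2", "C3", "C4", "C5", "C6",
              "O1", "O2", "O3", "O4", "O5", "O6",
              "H1", "H2", "H3", "H4", "H5", "H61", "H62",
              "HO1", "HO2", "HO3", "HO4", "HO6")
  element <- c(rep("C", 6), rep("O", 6), rep("H", 12))
  type <- c(rep("Cg", 6),
            rep("Oh", 4), "Os", "Oh",
            rep("H1", 7),
            rep("Ho", 5))
  data.frame(label = labels, element = element, type = type,
             stringsAsFactors = FALSE)
}

glucose_bond_list <- function() {
  rbind(
    c("C1", "C2"), c("C2", "C3"), c("C3", "C4"), c("C4", "C5"),
    c("C5", "O5"), c("O5", "C1"), c("C5", "C6"),
    c("C1", "O1"), c("C2", "O2"), c("C3", "O3"), c("C4", "O4"), c("C6", "O6"),
    c("C1", "H1"), c("C2", "H2"), c("C3", "H3"), c("C4", "H4"), c("C5", "H5"),
    c("C6", "H61"), c("C6", "H62"),
    c("O1", "HO1"), c("O2", "HO2"), c("O3", "HO3"), c("O4", "HO4"),
    c("O6", "HO6")
  )
}

#' Topology of beta-d-glucopyranose
#'
#' The 24-atom pyranose with the GLYCAM-style atom labels C1..C6, O1..O6
#' (O5 is the ring oxygen), aliphatic hydrogens H1..H5, H61, H62 and
#' hydroxyl hydrogens HO1..HO4, HO6. The 7 aliphatic hydrogens carry a
#' fixed zero charge; the remaining 17 atoms are flagged
#' charge-optimizable.
#'
#' @return a `topology` (24 atoms, 24 bonds, one ring)
#' @export
glucose_template <- function() {
  atoms <- glucose_atom_table()
  bl <- glucose_bond_list()
  bonds <- cbind(match(bl[, 1], atoms$label), match(bl[, 2], atoms$label))
  build_connectivity(atoms, bonds)
}

#' Reference 4C1 chair coordinates of beta-d-glucose
#'
#' Reads the packaged synthetic 4C1 chair geometry (MMFF94-relaxed) and
#' returns coordinates in the canonical atom order of
#' [glucose_template()].
#'
#' @return 24 x 3 coordinate matrix (Angstrom), rownames are atom labels
#' @export
glucose_coordinates <- function() {
  path <- system.file("extdata", "beta_glucose.pdb", package = "glycofit",
                      mustWork = TRUE)
  read_pdb_coordinates(path, glucose_template())
}

#' Ring atom indices in Cremer-Pople order (O5, C1..C5)
#' @param topology a glucose `topology`
#' @return integer indices of the six ring atoms
#' @export
glucose_ring_indices <- function(topology = glucose_template()) {
  atom_index(topology, c("O5", "C1", "C2", "C3", "C4", "C5"))
}
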