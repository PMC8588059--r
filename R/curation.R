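# Conformer-dataset curation: duplicate removal by RMSD, Lennard-Jones
# outlier filtering, train/test splitting, per-atom charge statistics.

#' Root-mean-square deviation between two structures
#'
#' With `superpose = TRUE` (the default) an optimal rigid-body
#' superposition (centroid removal plus least-squares rotation, via
#' `bio3d`) is applied before the deviation is computed, so the result is
#' frame-independent. With `superpose = FALSE` the literal coordinate
#' deviation is returned.
#'
#' @param X,Y N x 3 coordinate matrices (Angstrom)
#' @param superpose superpose Y onto X first?
#' @return RMSD in Angstrom
#' @export
rmsd <- function(X, Y, superpose = TRUE) {
  stopifnot(nrow(X) == nrow(Y))
  if (nrow(X) == 0) stop("rmsd: empty structures")
  if (superpose) {
    as.numeric(bio3d::rmsd(as.vector(t(X)), as.vector(t(Y)), fit = TRUE))
  } else {
    sqrt(sum((X - Y)^2) / nrow(X))
  }
}

# Rotation-invariant per-structure fingerprints used to screen candidate
# duplicate pairs before the exact superposed RMSD. For structures within
# RMSD t after superposition, every interatomic distance differs by at
# most 2 sqrt(N) t, and the mean interatomic distance by at most 2 t.
structure_fingerprints <- function(cs) {
  n <- nrow(cs$topology$atoms)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  S <- n_conformers(cs)
  fp <- matrix(0, S, nrow(pairs))
  for (s in seq_len(S)) {
    d <- cs$xyz[pairs[, 1], , s] - cs$xyz[pairs[, 2], , s]
    fp[s, ] <- sqrt(rowSums(d^2))
  }
  fp
}

#' Remove near-duplicate structures from a conformer set
#'
#' Greedy single pass in input order: a structure is dropped when its
#' RMSD to any previously retained structure is less than or equal to
#' `threshold` (the inequality is inclusive). Deterministic; with
#' superposition on, the outcome is independent of each structure's
#' coordinate frame.
#'
#' @param cs a `conformer_set`
#' @param threshold RMSD threshold in Angstrom
#' @param superpose superpose before the deviation (default TRUE)
#' @return list with `retained` (a `conformer_set`), `retained_ids`,
#'   `removed` (data.frame id, matches_id), and counts
#' @export
deduplicate <- function(cs, threshold = 0.05, superpose = TRUE) {
  S <- n_conformers(cs)
  n <- nrow(cs$topology$atoms)
  fp <- structure_fingerprints(cs)
  fp_mean <- rowMeans(fp)
  bound_pair <- 2 * sqrt(n) * threshold
  bound_mean <- 2 * threshold

  keep <- integer(0)
  removed_id <- character(0)
  removed_match <- character(0)
  for (s in seq_len(S)) {
    dup_of <- NA_character_
    cand <- keep[abs(fp_mean[keep] - fp_mean[s]) <= bound_mean]
    for (k in cand) {
      if (max(abs(fp[k, ] - fp[s, ])) > bound_pair) next
      if (rmsd(cs$xyz[, , k], cs$xyz[, , s], superpose = superpose) <=
          threshold) {
        dup_of <- cs$ids[k]
        break
      }
    }
    if (is.na(dup_of)) {
      keep <- c(keep, s)
    } else {
      removed_id <- c(removed_id, cs$ids[s])
      removed_match <- c(removed_match, dup_of)
    }
  }
  list(retained = cs[keep], retained_ids = cs$ids[keep],
       removed = data.frame(id = removed_id, matches_id = removed_match,
                            stringsAsFactors = FALSE),
       n_input = S, n_removed = S - length(keep), n_retained = length(keep))
}

#' Remove Lennard-Jones outlier structures
#'
#' Structures whose total Lennard-Jones energy (non-bonded plus scaled
#' 1-4) exceeds a robust threshold are removed: such structures carry
#' steric clashes whose r^-12 repulsion cannot be compensated by fitting
#' torsions or charges. The default rule removes structures with an LJ
#' term above median + k * IQR of the set; an absolute threshold
#' (kcal/mol) can be given instead, or the filter disabled.
#'
#' @param cs a `conformer_set`
#' @param params a [parameter_set()]
#' @param rule "iqr", "absolute" or "none"
#' @param k IQR multiplier for the robust rule
#' @param threshold absolute LJ threshold (kcal/mol) for rule "absolute"
#' @return list with `retained` (a `conformer_set`), `removed`
#'   (data.frame id, lj_energy), `lj_energy` for all inputs, `cutoff`,
#'   and counts
#' @export
filter_lj_outliers <- function(cs, params, rule = c("iqr", "absolute", "none"),
                               k = 10, threshold = NULL) {
  rule <- match.arg(rule)
  tb <- energy_tables(cs$topology, params)
  lj_e <- vapply(seq_len(n_conformers(cs)), function(s) {
    b <- total_energy(cs$topology, params, cs$xyz[, , s], tables = tb)
    b$lj_nb + b$lj_14
  }, numeric(1))
  cutoff <- switch(rule,
    iqr = stats::median(lj_e) + k * stats::IQR(lj_e),
    absolute = {
      if (is.null(threshold)) stop("rule 'absolute' needs a threshold")
      threshold
    },
    none = Inf)
  out <- lj_e > cutoff
  list(retained = cs[!out],
       removed = data.frame(id = cs$ids[out], lj_energy = lj_e[out],
                            stringsAsFactors = FALSE),
       lj_energy = stats::setNames(lj_e, cs$ids), cutoff = cutoff,
       n_input = n_conformers(cs), n_removed = sum(out),
       n_retained = sum(!out))
}

#' Split a conformer set into training and test subsets
#'
#' Uniform random shuffle driven by `seed`; the first ceiling(fraction N)
#' structures form the training set. The designated reference structure
#' is always placed in the training set (swapped in if necessary), since
#' every relative energy is anchored to it.
#'
#' @param cs a `conformer_set`
#' @param fraction training fraction (default 0.7)
#' @param seed integer seed (mandatory, for reproducibility)
#' @return list with `train_ids`, `test_ids`, `train`, `test`
#'   (conformer_sets), `seed`
#' @export
split_conformers <- function(cs, fraction = 0.7, seed) {
  if (missing(seed)) stop("split_conformers: seed is required")
  S <- n_conformers(cs)
  if (S < 2) stop("need at least 2 structures to split")
  perm <- local_rng(seed, sample.int(S))
  n_train <- ceiling(fraction * S)
  train <- perm[seq_len(n_train)]
  test <- perm[-seq_len(n_train)]
  if (!is.na(cs$ref) && !(cs$ref %in% train)) {
    swap <- train[n_train]       # deterministic: last training slot
    train[n_train] <- cs$ref
    test[test == cs$ref] <- swap
  }
  train <- sort(train); test <- sort(test)
  list(train_ids = cs$ids[train], test_ids = cs$ids[test],
       train = cs[train], test = cs[test], seed = seed)
}

#' Per-atom charge statistics over a conformer set
#'
#' Ensemble mean and population standard deviation of the per-structure
#' charge sets, reported for the charge-optimizable atoms. Structures
#' without a charge set are skipped (the count reports how many carried
#' one). Aliphatic hydrogens must carry exactly zero charge in every
#' set, mirroring the constraint under which such charge ensembles are
#' derived.
#'
#' @param cs a `conformer_set` with a `charges` matrix
#' @return object of class `charge_statistics`: data.frame(label, mean,
#'   sd) for the optimizable atoms, with attribute `n_sets`
#' @export
charge_statistics <- function(cs) {
  if (is.null(cs$charges)) stop("conformer set carries no charge sets")
  have <- stats::complete.cases(cs$charges)
  if (sum(have) < 2) stop("need at least 2 structures with charge sets")
  q <- cs$charges[have, , drop = FALSE]
  ali <- cs$topology$atoms$aliphatic_h
  if (any(q[, ali] != 0)) {
    stop("nonzero charge on aliphatic hydrogen(s): ",
         paste(unique(cs$topology$atoms$label[ali][colSums(q[, ali, drop = FALSE] != 0) > 0]),
               collapse = ", "))
  }
  free <- cs$topology$atoms$charge_free
  m <- colMeans(q[, free, drop = FALSE])
  # population (ensemble) standard deviation
  sdv <- sqrt(colMeans(sweep(q[, free, drop = FALSE], 2, m)^2))
  out <- data.frame(label = cs$topology$atoms$label[free],
                    mean = as.numeric(m), sd = as.numeric(sdv),
                    stringsAsFactors = FALSE)
  attr(out, "n_sets") <- sum(have)
  class(out) <- c("charge_statistics", class(out))
  out
}

#' Curate a conformer set: deduplicate, filter LJ outliers, split
#'
#' Convenience pipeline combining [deduplicate()], [filter_lj_outliers()]
#' and [split_conformers()], returning the curated set together with a
#' report of every removal and the split assignment.
#'
#' @inheritParams deduplicate
#' @inheritParams filter_lj_outliers
#' @inheritParams split_conformers
#' @param params parameter set used for the LJ filter
#' @return list with `curated` (a `conformer_set`), `train_ids`,
#'   `test_ids`, `report` (data.frame id, status, reason), counts, seed
#' @export
curate <- function(cs, params, threshold = 0.05, superpose = TRUE,
                   rule = "iqr", k = 10, lj_threshold = NULL,
                   fraction = 0.7, seed) {
  dd <- deduplicate(cs, threshold = threshold, superpose = superpose)
  lf <- filter_lj_outliers(dd$retained, params, rule = rule, k = k,
                           threshold = lj_threshold)
  sp <- split_conformers(lf$retained, fraction = fraction, seed = seed)
  status <- rep("retained", n_conformers(cs))
  reason <- rep("", n_conformers(cs))
  i <- match(dd$removed$id, cs$ids)
  status[i] <- "removed"; reason[i] <- paste0("duplicate of ",
                                              dd$removed$matches_id)
  i <- match(lf$removed$id, cs$ids)
  status[i] <- "removed"
  reason[i] <- sprintf("LJ outlier (%.3f kcal/mol > cutoff %.3f)",
                       lf$removed$lj_energy, lf$cutoff)
  i <- match(sp$train_ids, cs$ids); reason[i] <- "train"
  i <- match(sp$test_ids, cs$ids); reason[i] <- "test"
  list(curated = lf$retained, train_ids = sp$train_ids,
       test_ids = sp$test_ids,
       report = data.frame(id = cs$ids, status = status, reason = reason,
                           stringsAsFactors = FALSE),
       n_input = n_conformers(cs), n_duplicates = dd$n_removed,
       n_lj_outliers = lf$n_removed, n_retained = lf$n_retained,
       seed = seed)
}
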