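#' Construct a force-field parameter set
#'
#' Container for all constants of the AMBER-form energy function: bond
#' stretching, angle bending, torsion Fourier series, Lennard-Jones,
#' atomic charges and the global 1-4 scaling factors. Units follow the
#' AMBER ecosystem: kcal/mol/A^2 and A for bonds, kcal/mol/rad^2 and
#' degrees for angles, kcal/mol and degrees for torsions, A and kcal/mol
#' for Lennard-Jones Rmin/2 and epsilon, elementary charge for charges.
#'
#' @param bond data.frame(type, kb, r0)
#' @param angle data.frame(type, ktheta, theta0)
#' @param torsion data.frame(type, n, v, gamma): one row per Fourier
#'   term, periodicity `n` in 1..6, amplitude `v` kcal/mol, phase
#'   `gamma` degrees (wrapped into \[0, 360)).
#' @param lj data.frame(type, rmin2, eps) per atom type
#' @param charges named numeric vector, names are atom labels
#' @param scee,scnb dimensionless 1-4 electrostatic / van der Waals
#'   divisors
#' @param dielectric relative permittivity (> 0)
#' @param mass optional data.frame(type, mass)
#' @return object of class `parameter_set`
#' @export
parameter_set <- function(bond = NULL, angle = NULL, torsion = NULL,
                          lj = NULL, charges = NULL,
                          scee = 1.0, scnb = 1.0, dielectric = 1.0,
                          mass = NULL) {
  if (!is.null(torsion) && nrow(torsion)) {
    if (any(torsion$n < 1 | torsion$n > 6)) {
      stop("torsion periodicity must lie in 1..6")
    }
    torsion$gamma <- wrap_deg_360(torsion$gamma)
  }
  if (dielectric <= 0) stop("dielectric must be positive")
  structure(list(bond = bond, angle = angle, torsion = torsion, lj = lj,
                 charges = charges, scee = scee, scnb = scnb,
                 dielectric = dielectric, mass = mass),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  nt <- if (is.null(x$torsion)) 0 else length(unique(x$torsion$type))
  cat("parameter_set:",
      if (is.null(x$bond)) 0 else nrow(x$bond), "bond types,",
      if (is.null(x$angle)) 0 else nrow(x$angle), "angle types,",
      nt, "torsion types,",
      if (is.null(x$charges)) 0 else length(x$charges), "charges;",
      "scee =", format(x$scee), "scnb =", format(x$scnb), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# frcmod

#' Read an AMBER frcmod parameter file
#'
#' Parses the MASS, BOND, ANGLE, DIHE and NONBON sections of the frcmod
#' dialect. Negative-periodicity continuation lines in DIHE are merged
#' into a single Fourier list per dihedral type; the IDIVF divider column
#' is applied as written (amplitude = PK / IDIVF). Optional
#' `SCEE=` / `SCNB=` tokens on DIHE lines set the global scaling factors.
#' Duplicate definitions of a term: the last one wins, with a warning.
#'
#' @param file path to an frcmod file, or a character vector of lines
#' @return a partial [parameter_set()] (no charges)
#' @export
read_frcmod <- function(file) {
  lines <- if (length(file) == 1 && file.exists(file)) readLines(file) else file
  lines <- sub("\r$", "", lines)
  section <- NULL
  first <- TRUE
  mass <- list(); bond <- list(); angle <- list(); nonbon <- list()
  tors <- list()   # per type: data.frame(n, v, gamma)
  scee <- 1.0; scnb <- 1.0
  open_type <- NULL  # DIHE continuation in progress

  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    line <- trimws(raw)
    if (first) { first <- FALSE; next }   # title line
    if (line == "") { open_type <- NULL; next }
    up <- toupper(line)
    if (up %in% c("MASS", "BOND", "ANGLE", "DIHE", "DIHEDRAL", "NONBON",
                  "NONB", "IMPROPER", "IMPR")) {
      section <- sub("DIHEDRAL", "DIHE", up)
      section <- sub("NONB$", "NONBON", section)
      open_type <- NULL
      next
    }
    if (is.null(section)) {
      stop("frcmod line ", ln, ": content before any section header")
    }
    tok <- strsplit(line, "\\s+")[[1]]
    # the type field may embed spaces around hyphens (AMBER fixed-width
    # 2-character type columns, e.g. "A -B -B -A")
    split_typed <- function(line) {
      m <- regexpr("^\\S{1,2}(\\s?-\\s?\\S{1,2})+", line)
      if (m == -1) stop("frcmod line ", ln, ": cannot parse type field")
      type_raw <- regmatches(line, m)
      rest <- trimws(substring(line, attr(m, "match.length") + 1))
      list(types = strsplit(gsub("\\s", "", type_raw), "-", fixed = TRUE)[[1]],
           tok = strsplit(rest, "\\s+")[[1]])
    }
    if (section == "MASS") {
      mass[[tok[1]]] <- as.numeric(tok[2])
    } else if (section == "BOND") {
      f <- split_typed(line)
      key <- canonical_type(f$types)
      if (!is.null(bond[[key]])) warning("duplicate BOND entry for ", key,
                                         "; last wins")
      bond[[key]] <- as.numeric(f$tok[1:2])
    } else if (section == "ANGLE") {
      f <- split_typed(line)
      key <- canonical_type(f$types)
      if (!is.null(angle[[key]])) warning("duplicate ANGLE entry for ", key,
                                          "; last wins")
      angle[[key]] <- as.numeric(f$tok[1:2])
    } else if (section == "DIHE") {
      f <- split_typed(line)
      key <- canonical_type(f$types)
      idivf <- as.numeric(f$tok[1]); pk <- as.numeric(f$tok[2])
      phase <- as.numeric(f$tok[3]); pn <- as.numeric(f$tok[4])
      for (extra in f$tok[-(1:4)]) {
        if (grepl("^SCEE=", extra, ignore.case = TRUE)) {
          scee <- as.numeric(sub("^SCEE=", "", extra, ignore.case = TRUE))
        } else if (grepl("^SCNB=", extra, ignore.case = TRUE)) {
          scnb <- as.numeric(sub("^SCNB=", "", extra, ignore.case = TRUE))
        }
      }
      row <- data.frame(n = abs(as.integer(pn)), v = pk / idivf,
                        gamma = phase)
      continuing <- identical(open_type, key)
      if (!continuing && !is.null(tors[[key]]) ) {
        warning("duplicate DIHE entry for ", key, "; last wins")
        tors[[key]] <- NULL
      }
      tors[[key]] <- rbind(tors[[key]], row)
      open_type <- if (pn < 0) key else NULL
    } else if (section == "NONBON") {
      if (!is.null(nonbon[[tok[1]]])) warning("duplicate NONBON entry for ",
                                              tok[1], "; last wins")
      nonbon[[tok[1]]] <- as.numeric(tok[2:3])
    } else if (section %in% c("IMPROPER", "IMPR")) {
      next  # impropers not used by this molecule class
    } else {
      stop("frcmod line ", ln, ": unknown section ", section)
    }
  }

  to_df <- function(lst, cols) {
    if (!length(lst)) {
      return(stats::setNames(data.frame(character(), numeric(), numeric(),
                                        stringsAsFactors = FALSE),
                             c("type", cols)))
    }
    df <- do.call(rbind, lapply(names(lst), function(k) {
      stats::setNames(data.frame(k, lst[[k]][1], lst[[k]][2],
                                 stringsAsFactors = FALSE), c("type", cols))
    }))
    df[order(df$type), , drop = FALSE]
  }
  torsion <- if (length(tors)) {
    df <- do.call(rbind, lapply(sort(names(tors)), function(k) {
      d <- tors[[k]]; d <- d[order(d$n), , drop = FALSE]
      cbind(data.frame(type = k, stringsAsFactors = FALSE), d)
    }))
    rownames(df) <- NULL
    df
  } else {
    data.frame(type = character(), n = integer(), v = numeric(),
               gamma = numeric(), stringsAsFactors = FALSE)
  }
  mass_df <- if (length(mass)) {
    data.frame(type = names(mass), mass = unlist(mass),
               stringsAsFactors = FALSE, row.names = NULL)
  } else NULL

  parameter_set(bond = to_df(bond, c("kb", "r0")),
                angle = to_df(angle, c("ktheta", "theta0")),
                torsion = torsion,
                lj = to_df(nonbon, c("rmin2", "eps")),
                charges = NULL, scee = scee, scnb = scnb, mass = mass_df)
}

#' Write a parameter set in frcmod format
#'
#' Torsion Fourier lists are emitted with IDIVF = 1 and the frcmod
#' negative-periodicity continuation convention; `scee`/`scnb` are
#' written as `SCEE=`/`SCNB=` tokens on every DIHE line.
#'
#' @param params a [parameter_set()]
#' @param file optional output path; when missing, the lines are returned
#' @param title first line of the file
#' @return character vector of lines, invisibly when `file` is given
#' @export
write_frcmod <- function(params, file = NULL,
                         title = "parameter modifications written by glycofit") {
  fmt <- function(x) formatC(x, format = "f", digits = 4, width = 10)
  out <- c(title, "MASS")
  if (!is.null(params$mass)) {
    out <- c(out, sprintf("%-11s%s", params$mass$type, fmt(params$mass$mass)))
  }
  out <- c(out, "", "BOND")
  if (!is.null(params$bond) && nrow(params$bond)) {
    out <- c(out, sprintf("%-11s%s%s", params$bond$type,
                          fmt(params$bond$kb), fmt(params$bond$r0)))
  }
  out <- c(out, "", "ANGLE")
  if (!is.null(params$angle) && nrow(params$angle)) {
    out <- c(out, sprintf("%-11s%s%s", params$angle$type,
                          fmt(params$angle$ktheta), fmt(params$angle$theta0)))
  }
  out <- c(out, "", "DIHE")
  if (!is.null(params$torsion) && nrow(params$torsion)) {
    for (ty in unique(params$torsion$type)) {
      d <- params$torsion[params$torsion$type == ty, , drop = FALSE]
      d <- d[order(d$n), , drop = FALSE]
      for (r in seq_len(nrow(d))) {
        pn <- if (r < nrow(d)) -d$n[r] else d$n[r]
        out <- c(out, sprintf("%-11s%4d%s%s%6.1f   SCEE=%s SCNB=%s",
                              ty, 1L, fmt(d$v[r]), fmt(d$gamma[r]), pn,
                              format(params$scee), format(params$scnb)))
      }
    }
  }
  out <- c(out, "", "NONBON")
  if (!is.null(params$lj) && nrow(params$lj)) {
    out <- c(out, sprintf("%-11s%s%s", params$lj$type,
                          fmt(params$lj$rmin2), fmt(params$lj$eps)))
  }
  out <- c(out, "")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# ---------------------------------------------------------------------------
# prep (charge / atom-type table only)

#' Read atom names, types and charges from an AMBER prep file
#'
#' Only the atom table is consumed; the internal-coordinate (Z-matrix)
#' geometry columns are ignored, since geometry always comes from
#' coordinate files. Dummy (`DU`) atoms are skipped.
#'
#' @param file path or character vector of lines
#' @return data.frame(label, type, charge)
#' @export
read_prep_charges <- function(file) {
  lines <- if (length(file) == 1 && file.exists(file)) readLines(file) else file
  rows <- list()
  for (line in lines) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) != 11) next
    if (is.na(suppressWarnings(as.integer(tok[1])))) next
    if (toupper(tok[3]) == "DU") next
    rows[[length(rows) + 1]] <- data.frame(
      label = tok[2], type = tok[3], charge = as.numeric(tok[11]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no atom records found in prep input")
  do.call(rbind, rows)
}

#' Write a minimal AMBER prep file carrying charges and atom types
#'
#' The internal-coordinate columns are emitted as zeros: this file is a
#' charge/type carrier, not a geometry source.
#'
#' @param topology a `topology`
#' @param charges named numeric vector of charges (atom labels as names)
#' @param file optional output path
#' @param resname residue name
#' @return character vector of lines, invisibly when `file` is given
#' @export
write_prep_charges <- function(topology, charges, file = NULL,
                               resname = "BGC") {
  labs <- topology$atoms$label
  q <- charges[labs]
  if (anyNA(q)) stop("charges missing for: ",
                     paste(labs[is.na(q)], collapse = ", "))
  out <- c("    0    0    2", "",
           "atomic charges written by glycofit",
           paste0(resname, ".res"),
           sprintf("%s   INT  0", resname),
           "CORRECT  OMIT DU   BEG",
           "  0.0000",
           sprintf("%4d  %-5s %-5s M    %3d %3d %3d %9.3f %9.3f %9.3f %10.5f",
                   1L, "DUMM", "DU", 0L, -1L, -2L, 0, 0, 0, 0),
           sprintf("%4d  %-5s %-5s M    %3d %3d %3d %9.3f %9.3f %9.3f %10.5f",
                   2L, "DUMM", "DU", 1L, 0L, -1L, 1.449, 0, 0, 0),
           sprintf("%4d  %-5s %-5s M    %3d %3d %3d %9.3f %9.3f %9.3f %10.5f",
                   3L, "DUMM", "DU", 2L, 1L, 0L, 1.522, 111.1, 0, 0))
  for (i in seq_along(labs)) {
    out <- c(out, sprintf(
      "%4d  %-5s %-5s M    %3d %3d %3d %9.3f %9.3f %9.3f %10.5f",
      i + 3L, labs[i], topology$atoms$type[i], 0L, 0L, 0L, 0, 0, 0, q[i]))
  }
  out <- c(out, "", "DONE", "STOP")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# ---------------------------------------------------------------------------
# coordinates

#' Read XYZ coordinates (single or multi frame)
#'
#' @param file path to an XYZ file
#' @return list of N x 3 matrices, one per frame; each carries its
#'   comment line as attribute `comment` and element symbols as rownames
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list()
  pos <- 1
  while (pos <= length(lines) && trimws(lines[pos]) != "") {
    n <- as.integer(trimws(lines[pos]))
    if (is.na(n)) stop("malformed XYZ atom count in ", file, " line ", pos)
    comment <- if (pos + 1 <= length(lines)) lines[pos + 1] else ""
    block <- lines[(pos + 2):(pos + 1 + n)]
    tok <- strsplit(trimws(block), "\\s+")
    el <- vapply(tok, `[`, character(1), 1)
    m <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    rownames(m) <- el
    attr(m, "comment") <- comment
    frames[[length(frames) + 1]] <- m
    pos <- pos + 2 + n
  }
  frames
}

#' Write XYZ coordinates (single or multi frame)
#' @param frames an N x 3 matrix or a list of them
#' @param file output path
#' @param elements element symbols (defaults to frame rownames)
#' @param comments one comment line per frame
#' @export
write_xyz <- function(frames, file, elements = NULL, comments = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  out <- character(0)
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    el <- if (!is.null(elements)) elements else rownames(m)
    if (is.null(el)) stop("element symbols required to write XYZ")
    cm <- if (!is.null(comments)) comments[f] else ""
    out <- c(out, as.character(nrow(m)), cm,
             sprintf("%-3s %14.8f %14.8f %14.8f", el, m[, 1], m[, 2], m[, 3]))
  }
  writeLines(out, file)
  invisible(file)
}

#' Read one structure from a PDB file, ordered to match a topology
#'
#' Fixed-width ATOM/HETATM parsing is delegated to `bio3d`. When
#' alternate locations are present the first is kept with a warning; when
#' the file's atom-name order differs from the topology the coordinates
#' are reordered by label with a warning.
#'
#' @param file PDB path
#' @param topology the `topology` the coordinates must match
#' @return N x 3 coordinate matrix, rownames are topology labels
#' @export
read_pdb_coordinates <- function(file, topology) {
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$alt) & at$alt != "")) {
    keep_alt <- sort(unique(at$alt[!is.na(at$alt) & at$alt != ""]))[1]
    warning("alternate locations present in ", file,
            "; keeping altloc '", keep_alt, "'")
    at <- at[is.na(at$alt) | at$alt == "" | at$alt == keep_alt, , drop = FALSE]
  }
  labs <- topology$atoms$label
  if (nrow(at) != length(labs)) {
    stop("atom count mismatch in ", file, ": expected ", length(labs),
         ", found ", nrow(at))
  }
  m <- match(labs, at$elety)
  if (anyNA(m)) {
    stop("atoms missing from ", file, ": ",
         paste(labs[is.na(m)], collapse = ", "))
  }
  if (!identical(m, seq_along(labs))) {
    warning("atom order in ", file, " differs from topology; reordered by label")
  }
  xyz <- cbind(at$x, at$y, at$z)[m, , drop = FALSE]
  rownames(xyz) <- labs
  xyz
}

#' Read a coordinate file by extension (.pdb or .xyz)
#'
#' XYZ frames are assumed to follow the topology's canonical atom order.
#'
#' @inheritParams read_pdb_coordinates
#' @param frame frame number for multi-frame XYZ files
#' @return N x 3 coordinate matrix
#' @export
read_coordinates <- function(file, topology, frame = 1L) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "pdb") {
    read_pdb_coordinates(file, topology)
  } else if (ext == "xyz") {
    fr <- read_xyz(file)
    if (frame > length(fr)) stop("frame ", frame, " not present in ", file)
    m <- fr[[frame]]
    if (nrow(m) != nrow(topology$atoms)) {
      stop("atom count mismatch in ", file, ": expected ",
           nrow(topology$atoms), ", found ", nrow(m))
    }
    rownames(m) <- topology$atoms$label
    m
  } else {
    stop("unsupported coordinate format: ", file)
  }
}

# ---------------------------------------------------------------------------
# conformer sets

#' Construct a conformer set
#'
#' Per-structure Cartesian coordinates with optional reference ("QM"
#' energies, kcal/mol) and optional per-structure charge sets. The
#' designated reference structure is the one with the minimum reference
#' energy (ties broken by lowest index), matching the convention that the
#' most stable structure anchors all relative energies.
#'
#' @param topology the shared `topology`
#' @param xyz list of N x 3 matrices or an N x 3 x S array
#' @param ids character ids (default "s0001", ...)
#' @param qm_energy numeric reference energies or NULL
#' @param charges S x N matrix of per-structure charges or NULL; rows of
#'   NA mark structures without a charge set
#' @return object of class `conformer_set`
#' @export
conformer_set <- function(topology, xyz, ids = NULL, qm_energy = NULL,
                          charges = NULL) {
  if (is.list(xyz)) {
    n <- nrow(topology$atoms)
    bad <- vapply(xyz, function(m) !is.matrix(m) || !all(dim(m) == c(n, 3)),
                  logical(1))
    if (any(bad)) stop("all coordinate frames must be ", n, " x 3 matrices")
    xyz <- array(unlist(xyz), dim = c(n, 3, length(xyz)))
  }
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[1] == nrow(topology$atoms),
            dim(xyz)[2] == 3)
  S <- dim(xyz)[3]
  if (is.null(ids)) ids <- sprintf("s%04d", seq_len(S))
  stopifnot(length(ids) == S, !anyDuplicated(ids))
  if (!is.null(qm_energy)) stopifnot(length(qm_energy) == S)
  if (!is.null(charges)) {
    stopifnot(nrow(charges) == S, ncol(charges) == nrow(topology$atoms))
    colnames(charges) <- topology$atoms$label
  }
  ref <- if (!is.null(qm_energy) && any(is.finite(qm_energy))) {
    which.min(qm_energy)
  } else NA_integer_
  structure(list(topology = topology, xyz = xyz, ids = as.character(ids),
                 qm_energy = qm_energy, charges = charges, ref = ref),
            class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  cat("conformer_set:", n_conformers(x), "structures of",
      nrow(x$topology$atoms), "atoms;",
      if (is.null(x$qm_energy)) "no reference energies"
      else paste0("reference structure ", x$ids[x$ref]),
      "\n")
  invisible(x)
}

#' Number of structures in a conformer set
#' @param cs a `conformer_set`
#' @export
n_conformers <- function(cs) dim(cs$xyz)[3]

#' Subset a conformer set by index or id
#' @param x a `conformer_set`
#' @param i integer/logical indices or character ids
#' @param ... ignored
#' @export
`[.conformer_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  if (is.logical(i)) i <- which(i)
  conformer_set(x$topology, x$xyz[, , i, drop = FALSE], ids = x$ids[i],
                qm_energy = x$qm_energy[i],
                charges = if (!is.null(x$charges)) x$charges[i, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# manifest

#' Write a conformer set to disk as multi-frame XYZ plus a manifest
#'
#' The manifest is a tab-delimited table with columns `id`, `file`,
#' `frame`, `qm_energy` and (when charge sets are present) one
#' `q_<label>` column per atom. Coordinate paths are relative to the
#' manifest's directory.
#'
#' @param cs a `conformer_set`
#' @param dir output directory (created if missing)
#' @param name manifest file name
#' @param coords_file coordinate file name
#' @return path of the manifest, invisibly
#' @export
write_manifest <- function(cs, dir, name = "manifest.tsv",
                           coords_file = "conformers.xyz") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  el <- cs$topology$atoms$element
  frames <- lapply(seq_len(n_conformers(cs)), function(s) cs$xyz[, , s])
  write_xyz(frames, file.path(dir, coords_file), elements = el,
            comments = cs$ids)
  df <- data.frame(id = cs$ids, file = coords_file,
                   frame = seq_len(n_conformers(cs)),
                   qm_energy = if (is.null(cs$qm_energy)) NA_real_
                               else cs$qm_energy)
  if (!is.null(cs$charges)) {
    q <- as.data.frame(cs$charges)
    names(q) <- paste0("q_", cs$topology$atoms$label)
    df <- cbind(df, q)
  }
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a conformer set from a manifest
#'
#' @param file manifest path (tab-delimited; columns `id`, `file`,
#'   optional `frame`, optional `qm_energy`, optional `q_<label>` charge
#'   columns)
#' @param topology the `topology` the coordinates must match
#' @return a `conformer_set`; the reference structure is the row with the
#'   minimum `qm_energy` (lowest row index on ties)
#' @export
read_manifest <- function(file, topology) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  base <- dirname(file)
  if (!all(c("id", "file") %in% names(df))) {
    stop("manifest must have 'id' and 'file' columns")
  }
  frame <- if ("frame" %in% names(df)) df$frame else rep(1L, nrow(df))
  cache <- new.env(parent = emptyenv())
  frames <- lapply(seq_len(nrow(df)), function(r) {
    path <- file.path(base, df$file[r])
    if (!file.exists(path)) stop("coordinate file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext == "xyz") {
      key <- path
      if (is.null(cache[[key]])) cache[[key]] <- read_xyz(path)
      m <- cache[[key]][[frame[r]]]
      if (is.null(m)) stop("frame ", frame[r], " not present in ", path)
      if (nrow(m) != nrow(topology$atoms)) {
        stop("atom count mismatch in ", path)
      }
      rownames(m) <- topology$atoms$label
      m
    } else {
      read_coordinates(path, topology)
    }
  })
  qm <- if ("qm_energy" %in% names(df)) df$qm_energy else NULL
  if (!is.null(qm) && all(is.na(qm))) qm <- NULL
  qcols <- grep("^q_", names(df), value = TRUE)
  charges <- NULL
  if (length(qcols)) {
    labs <- sub("^q_", "", qcols)
    charges <- matrix(NA_real_, nrow(df), nrow(topology$atoms),
                      dimnames = list(NULL, topology$atoms$label))
    charges[, labs] <- as.matrix(df[, qcols])
  }
  conformer_set(topology, frames, ids = df$id, qm_energy = qm,
                charges = charges)
}
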