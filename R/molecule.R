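#' Shared molecular data model
#'
#' A `molecule` holds an atom table, a bond table, zero or more 3D
#' conformers and a free-form property list. Coordinates are Angstroms
#' throughout the package.
#'
#' @param id character molecule identifier.
#' @param atoms data.frame with columns `element` (chemical symbol),
#'   `formal_charge` (integer, e) and optionally `partial_charge` (e).
#' @param bonds data.frame with columns `a1`, `a2` (1-based atom indices),
#'   `order` (1, 2, 3) and `aromatic` (logical).
#' @param conformers list of numeric n_atoms x 3 matrices (Angstrom).
#' @param properties named list of record-level properties.
#' @return An object of class `molecule`.
#' @export
molecule <- function(id, atoms, bonds = empty_bonds(), conformers = list(),
                     properties = list()) {
  stopifnot(is.character(id), length(id) == 1L)
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  if (!all(atoms$element %in% names(.element_masses)))
    stop("unrecognized element symbol(s): ",
         paste(setdiff(atoms$element, names(.element_masses)), collapse = ", "))
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0L) {
    if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
    if (any(bonds$a1 > nrow(atoms)) || any(bonds$a2 > nrow(atoms)))
      stop("bond indices exceed atom count for molecule ", id)
  }
  for (cf in conformers) {
    if (!is.matrix(cf) || ncol(cf) != 3L || nrow(cf) != nrow(atoms))
      stop("conformer dimensions inconsistent with atom count for ", id)
    if (!all(is.finite(cf))) stop("non-finite coordinates in molecule ", id)
  }
  structure(list(id = id, atoms = atoms, bonds = bonds,
                 conformers = conformers, properties = properties),
            class = "molecule")
}

empty_bonds <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = integer(),
             aromatic = logical())
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", x$id, "-", nrow(x$atoms), "atoms,",
      nrow(x$bonds), "bonds,", length(x$conformers), "conformer(s)\n")
  if (length(x$properties))
    cat("  properties:", paste(names(x$properties), collapse = ", "), "\n")
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

#' Heavy-atom indices of a molecule
#' @param mol a `molecule`.
#' @return integer vector of non-hydrogen atom indices.
#' @export
heavy_atoms <- function(mol) which(mol$atoms$element != "H")

conformer <- function(mol, i = 1L) {
  if (length(mol$conformers) < i)
    stop("molecule ", mol$id, " has no conformer ", i)
  mol$conformers[[i]]
}

# Monoisotopic-ish average masses for common elements (g/mol).
.element_masses <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904,
  Fe = 55.845, Zn = 65.38, Se = 78.971)

molecular_weight <- function(mol) {
  sum(.element_masses[mol$atoms$element])
}

# Adjacency list over all atoms (list of integer vectors).
adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
  }
  adj
}

# All simple rings of size 3..max_size, canonicalized. Molecules here are
# small; plain DFS enumeration is adequate.
find_rings <- function(mol, max_size = 7L) {
  adj <- adjacency(mol)
  n <- n_atoms(mol)
  rings <- list()
  seen <- character()
  walk <- function(path) {
    tip <- path[length(path)]
    for (nb in adj[[tip]]) {
      if (nb == path[1] && length(path) >= 3L) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (!(nb %in% path) && length(path) < max_size && nb > path[1]) {
        walk(c(path, nb))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  # keep smallest rings: drop any ring that is a union of two smaller ones
  if (length(rings) > 1L) {
    keep <- rep(TRUE, length(rings))
    sizes <- lengths(rings)
    ord <- order(sizes)
    for (i in seq_along(rings)) {
      ri <- rings[[i]]
      smaller <- rings[sizes < length(ri)]
      if (length(smaller) >= 2L) {
        atoms_small <- unique(unlist(smaller))
        if (all(ri %in% atoms_small) && length(ri) > 6L) keep[i] <- FALSE
      }
    }
    rings <- rings[keep]
  }
  rings
}

# A ring counts as aromatic when it has 5 or 6 members, all C/N/O/S, and
# either its bonds are flagged aromatic or it carries the Kekule double-bond
# count (>= floor(size/2)) within the ring.
aromatic_rings <- function(mol) {
  rings <- find_rings(mol, max_size = 6L)
  b <- mol$bonds
  keep <- vapply(rings, function(r) {
    if (!length(r) %in% c(5L, 6L)) return(FALSE)
    if (!all(mol$atoms$element[r] %in% c("C", "N", "O", "S"))) return(FALSE)
    inring <- b$a1 %in% r & b$a2 %in% r
    if (sum(inring) != length(r)) return(FALSE)
    any(b$aromatic[inring]) || sum(b$order[inring] == 2L) >= length(r) %/% 2L
  }, logical(1))
  rings[keep]
}

# Indices of atoms belonging to any aromatic ring.
aromatic_atoms <- function(mol) unique(unlist(aromatic_rings(mol)))

#' A ligand-in-pocket structure
#'
#' Flat atom table in the PDB sense: chain, residue, atom name, element and
#' one set of coordinates. A logical `is_ligand` column flags HETATM-style
#' ligand residues.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `name`, `element`, `x`, `y`, `z`, `is_ligand`.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms) {
  atoms <- as.data.frame(atoms)
  need <- c("chain", "resno", "resname", "name", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("structure atoms need columns: ", paste(need, collapse = ", "))
  if (is.null(atoms$is_ligand)) atoms$is_ligand <- FALSE
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("atom names must be unique within a residue")
  structure(list(atoms = atoms), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("<structure3d>", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues,",
      sum(x$atoms$is_ligand), "ligand atoms\n")
  invisible(x)
}

coords3d <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' A frame-indexed trajectory
#'
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param atoms data.frame of atom metadata (as [structure3d()]).
#' @param dt time step between frames, ps.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(frames, atoms, dt = 1) {
  n <- nrow(atoms)
  for (f in frames)
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3L)
      stop("trajectory frames must all be ", n, " x 3 matrices")
  if (length(frames) < 1L) stop("trajectory needs at least one frame")
  frames <- lapply(frames, unname)
  structure(list(frames = frames, atoms = as.data.frame(atoms), dt = dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$frames), "frames x", nrow(x$atoms),
      "atoms, dt =", x$dt, "ps\n")
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

# Seed scoping: run expr under a given seed, restoring the caller's RNG
# state. No generator state leaks between calls.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
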