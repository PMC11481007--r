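#' Read a V2000 SDF file
#'
#' Each record is parsed independently (through ChemmineR); malformed
#' records are skipped with a warning and counted, never raised. V3000
#' records are rejected.
#'
#' @param path path to an SDF file.
#' @return list of [molecule()] objects, with attributes `n_skipped`
#'   (malformed record count) and `skipped` (record positions).
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("cannot read SDF file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("V3000", lines, fixed = TRUE)))
    stop("V3000 SDF records are not supported; supply V2000")
  # split into records on the $$$$ terminator
  ends <- grep("^\\${4}", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  mols <- list()
  skipped <- integer()
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    if (all(!nzchar(trimws(rec)))) next
    m <- tryCatch(parse_sdf_record(rec), error = function(e) NULL)
    if (is.null(m)) skipped <- c(skipped, r) else mols[[length(mols) + 1L]] <- m
  }
  if (length(skipped))
    warning(length(skipped), " malformed SDF record(s) skipped")
  if (length(mols) == 0L) stop("no parseable records in ", path)
  attr(mols, "n_skipped") <- length(skipped)
  attr(mols, "skipped") <- skipped
  mols
}

parse_sdf_record <- function(rec) {
  if (!any(grepl("^\\${4}", rec))) rec <- c(rec, "$$$$")
  sdfset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(rec))
  if (length(sdfset) != 1L || !ChemmineR::validSDF(sdfset))
    stop("invalid record")
  sdf_to_molecule(sdfset[[1]], charges = parse_chg_lines(rec))
}

# V2000 "M  CHG" property lines -> named integer vector (index -> charge)
parse_chg_lines <- function(rec) {
  chg <- integer()
  for (ln in grep("^M  CHG", rec, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[[:space:]]+")[[1]])
    n <- f[1]
    for (k in seq_len(n)) chg[as.character(f[2 * k])] <- f[2 * k + 1]
  }
  chg
}

# ChemmineR SDF object -> molecule
sdf_to_molecule <- function(sdf, id = NULL, charges = integer()) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_\\d+$", "", rownames(ab))
  n <- nrow(ab)
  fc <- integer(n)
  if (length(charges)) fc[as.integer(names(charges))] <- unname(charges)
  atoms <- data.frame(element = elements, formal_charge = fc)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = length(bb) %/% 7, ncol = 7,
                                     byrow = FALSE)
  if (nrow(bb) > 0L) {
    order <- as.integer(bb[, 3])
    aromatic <- order == 4L
    order[aromatic] <- 1L
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = order, aromatic = aromatic)
  } else bonds <- empty_bonds()
  hdr <- ChemmineR::header(sdf)
  nm <- if (!is.null(id)) id else unname(hdr["Molecule_Name"])
  if (is.na(nm) || !nzchar(nm)) nm <- "unnamed"
  props <- as.list(ChemmineR::datablock(sdf))
  coords <- unname(ab[, 1:3, drop = FALSE])
  is3d <- any(abs(coords[, 3]) > 1e-8) || grepl("3D", unname(hdr["Source"]))
  mol <- molecule(nm, atoms, bonds,
                  conformers = list(coords), properties = props)
  mol$properties$coord_dims <- if (is3d) "3d" else "2d"
  mol
}

# molecule -> ChemmineR SDF object (conformer `conf` as the coordinate block)
molecule_to_sdf <- function(mol, conf = 1L) {
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  xyz <- if (length(mol$conformers) >= conf) conformer(mol, conf)
         else matrix(0, n, 3)
  ab <- matrix(0, n, 15,
               dimnames = list(paste(mol$atoms$element, seq_len(n), sep = "_"),
                               c("C1", "C2", "C3", paste0("C", 5:16))))
  ab[, 1:3] <- xyz
  if (nb > 0L) {
    ord <- mol$bonds$order
    ord[mol$bonds$aromatic & ord == 1L] <- 1L
    bb <- cbind(mol$bonds$a1, mol$bonds$a2, ord, 0, 0, 0, 0)
  } else bb <- matrix(0, 0, 7)
  colnames(bb) <- paste0("C", 1:7)
  rownames(bb) <- if (nb > 0L) as.character(seq_len(nb)) else character()
  props <- mol$properties
  props <- props[!vapply(props, is.null, logical(1))]
  db <- vapply(props, function(v) paste(format(v), collapse = " "), character(1))
  if (!length(db)) db <- character(0)
  hdr <- c(Molecule_Name = mol$id, Source = " pharmfunnel",
           Comment = "",
           Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                 n, nb))
  methods::new("SDF", header = hdr, atomblock = ab, bondblock = bb,
               datablock = db)
}

#' Write molecules to a V2000 SDF file
#'
#' @param mols list of [molecule()] objects.
#' @param path output path.
#' @param conformer which conformer's coordinates to emit (default first).
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, conformer = 1L) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  sdfs <- lapply(mols, molecule_to_sdf, conf = conformer)
  ids <- vapply(mols, function(m) m$id, character(1))
  ChemmineR::write.SDF(methods::new("SDFset", SDF = sdfs, ID = ids), path)
  invisible(path)
}

#' Read molecules from a delimited SMILES table
#'
#' @param path CSV/TSV file with a header row.
#' @param smiles_column name of the column holding SMILES.
#' @param id_column optional name of an identifier column; defaults to
#'   `id` when present, else row numbers.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return list of [molecule()] objects with attribute `n_skipped` counting
#'   unparseable SMILES rows.
#' @export
read_smiles_table <- function(path, smiles_column = "smiles",
                              id_column = NULL, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "")
  if (!smiles_column %in% names(tab))
    stop("column '", smiles_column, "' not found in ", path)
  if (is.null(id_column)) id_column <- if ("id" %in% names(tab)) "id" else NA
  ids <- if (is.na(id_column)) paste0("row", seq_len(nrow(tab)))
         else as.character(tab[[id_column]])
  molecules_from_smiles(tab[[smiles_column]], ids)
}

#' Parse SMILES strings into molecules
#'
#' Unparseable SMILES are skipped and counted, mirroring the SDF reader's
#' skip contract.
#'
#' @param smiles character vector of SMILES.
#' @param ids molecule identifiers (defaults to names or positions).
#' @return list of [molecule()] with attribute `n_skipped`.
#' @export
molecules_from_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- names(smiles)
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  mols <- list()
  skipped <- 0L
  for (i in seq_along(smiles)) {
    m <- tryCatch({
      x <- smiles[i]; names(x) <- ids[i]
      sdfset <- suppressWarnings(ChemmineR::smiles2sdf(x))
      if (length(sdfset) != 1L) stop("unparseable")
      mol <- sdf_to_molecule(sdfset[[1]], id = ids[i],
                             charges = smiles_formal_charges(smiles[i]))
      mol$properties$smiles <- unname(smiles[i])
      mol
    }, error = function(e) NULL)
    if (is.null(m)) skipped <- skipped + 1L
    else mols[[length(mols) + 1L]] <- m
  }
  if (skipped > 0L) warning(skipped, " unparseable SMILES row(s) skipped")
  attr(mols, "n_skipped") <- skipped
  mols
}

# Formal charges straight from bracket-atom SMILES tokens, in atom order of
# the heavy atoms OB emits (OB preserves input atom order for SMILES input).
smiles_formal_charges <- function(smi) {
  toks <- regmatches(smi, gregexpr("\\[[^]]+\\]", smi))[[1]]
  if (!length(toks)) return(integer())
  # position of each bracket atom among all atoms in input order
  atom_pat <- "\\[[^]]+\\]|Cl|Br|[BCNOPSFI]|[bcnops]"
  all_toks <- regmatches(smi, gregexpr(atom_pat, smi))[[1]]
  chg <- integer()
  for (i in seq_along(all_toks)) {
    t <- all_toks[i]
    if (startsWith(t, "[")) {
      sign <- if (grepl("-", t)) -1L else if (grepl("\\+", t)) 1L else 0L
      mult <- regmatches(t, regexpr("[+-]\\d+", t))
      v <- if (length(mult)) as.integer(mult) else
        sign * max(1L, nchar(gsub("[^+-]", "", t)))
      if (v != 0L) chg[as.character(i)] <- v
    }
  }
  chg
}

#' Read a PDB file as a single structure
#'
#' @param path PDB file (first MODEL used when several are present).
#' @return a [structure3d()].
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  structure3d(data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain), resno = a$resno,
    resname = a$resid, name = a$elety,
    element = element_from_name(a$elesy, a$elety),
    x = a$x, y = a$y, z = a$z,
    is_ligand = a$type == "HETATM"))
}

element_from_name <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | !nzchar(el)
  el[miss] <- substr(gsub("[^A-Za-z].*", "", elety[miss]), 1, 1)
  el <- paste0(substr(el, 1, 1), tolower(substr(el, 2, 2)))
  el
}

#' Read a multi-frame trajectory (multi-model PDB or XYZ)
#'
#' @param path multi-model PDB (`MODEL`/`ENDMDL`) or multi-frame XYZ file.
#' @param dt time step between frames, ps.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, dt = 1) {
  if (grepl("\\.xyz$", path)) return(read_xyz_trajectory(path, dt))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain), resno = a$resno,
    resname = a$resid, name = a$elety,
    element = element_from_name(a$elesy, a$elety),
    is_ligand = a$type == "HETATM")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("inconsistent atom counts across trajectory frames")
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  trajectory(frames, atoms, dt = dt)
}

read_xyz_trajectory <- function(path, dt = 1) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  frames <- list()
  elements <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ frame header at line ", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    f <- do.call(rbind, strsplit(trimws(block), "[[:space:]]+"))
    el <- f[, 1]
    if (is.null(elements)) elements <- el
    else if (!identical(el, elements))
      stop("inconsistent atom ordering across trajectory frames")
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(f[, 2:4]), ncol = 3)
    i <- i + 2L + n
  }
  atoms <- data.frame(chain = "A", resno = 1L, resname = "MOL",
                      name = paste0(elements, seq_along(elements)),
                      element = elements, is_ligand = TRUE)
  trajectory(frames, atoms, dt = dt)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  xyz <- do.call(rbind, lapply(traj$frames, function(f) as.vector(t(f))))
  a <- traj$atoms
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$resno, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = a$chain, elesy = a$element,
                   type = ifelse(a$is_ligand, "HETATM", "ATOM"))
  invisible(path)
}

#' Write a structure as a single-model PDB
#' @param s a [structure3d()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path, xyz = as.vector(t(coords3d(s))),
                   resno = a$resno, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = a$chain, elesy = a$element,
                   type = ifelse(a$is_ligand, "HETATM", "ATOM"))
  invisible(path)
}
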