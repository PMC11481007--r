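# MM-PBSA-style energy bookkeeping. The binding free energy decomposes as
#   dG_gas  = dVDWAALS + dEEL
#   dG_solv = dEGB + dESURF
#   dTOTAL  = dG_gas + dG_solv
# All components in kcal/mol. The polar solvation term (dEGB) is ingested
# from external tools, not computed here; the gas-phase and surface terms
# have in-package toy implementations with closed-form oracles.

.coulomb_k <- 332.0637  # kcal A / (mol e^2)

#' Assemble an MM-PBSA energy ledger from its four components
#'
#' @param vdw van der Waals interaction energy (dVDWAALS), kcal/mol.
#' @param eel Coulomb interaction energy (dEEL), kcal/mol.
#' @param egb polar (generalized-Born) solvation term (dEGB), kcal/mol.
#' @param esurf nonpolar surface term (dESURF), kcal/mol.
#' @param id molecule identifier.
#' @return one-row data.frame of class `energy_ledger` with the derived
#'   `ggas`, `gsolv` and `total` sums.
#' @export
assemble_ledger <- function(vdw, eel, egb, esurf, id = "ligand") {
  vals <- c(vdw, eel, egb, esurf)
  if (!all(is.finite(vals))) stop("energy components must be finite")
  out <- data.frame(id = id, vdw = vdw, eel = eel, egb = egb,
                    esurf = esurf, ggas = vdw + eel, gsolv = egb + esurf,
                    total = vdw + eel + egb + esurf)
  class(out) <- c("energy_ledger", "data.frame")
  out
}

#' Verify the additive identities of an energy ledger
#'
#' Checks |ggas - (vdw+eel)|, |gsolv - (egb+esurf)| and
#' |total - (ggas+gsolv)| against `tol`; the default 0.015 absorbs
#' two-decimal rounding of independently printed components.
#'
#' @param ledger data.frame with columns vdw, eel, egb, esurf, ggas,
#'   gsolv, total (one or more rows).
#' @param tol tolerance, kcal/mol.
#' @return data.frame (id, r_ggas, r_gsolv, r_total, max_residual, pass).
#' @export
verify_ledger <- function(ledger, tol = 0.015) {
  r1 <- abs(ledger$ggas - (ledger$vdw + ledger$eel))
  r2 <- abs(ledger$gsolv - (ledger$egb + ledger$esurf))
  r3 <- abs(ledger$total - (ledger$ggas + ledger$gsolv))
  mx <- pmax(r1, r2, r3)
  data.frame(id = ledger$id, r_ggas = r1, r_gsolv = r2, r_total = r3,
             max_residual = mx, pass = mx <= tol)
}

#' Read an energy-ledger CSV
#'
#' Expected columns: id, vdw, eel, egb, esurf and optionally ggas, gsolv,
#' total (recomputed when absent). Compatible with exported MM-PBSA tool
#' component tables.
#'
#' @param path CSV path.
#' @return `energy_ledger` data.frame.
#' @export
read_ledger_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "vdw", "eel", "egb", "esurf")
  if (!all(need %in% names(tab)))
    stop("ledger CSV needs columns: ", paste(need, collapse = ", "))
  if (!all(c("ggas", "gsolv", "total") %in% names(tab))) {
    tab$ggas <- tab$vdw + tab$eel
    tab$gsolv <- tab$egb + tab$esurf
    tab$total <- tab$ggas + tab$gsolv
  }
  class(tab) <- c("energy_ledger", "data.frame")
  tab
}

# receptor x ligand pair table of a toy complex
cross_pairs <- function(complex) {
  rec <- which(!complex$atoms$is_ligand)
  lig <- which(complex$atoms$is_ligand)
  if (!length(rec) || !length(lig))
    stop("complex must contain both receptor and ligand atoms")
  expand.grid(i = rec, j = lig)
}

#' Lennard-Jones 6-12 interaction energy of a toy complex
#'
#' Sum over receptor x ligand pairs of
#' `4 eps_ij ((sigma_ij/r)^12 - (sigma_ij/r)^6)` with Lorentz-Berthelot
#' combination (arithmetic sigma, geometric epsilon); no cutoff.
#'
#' @param complex a [make_toy_complex()] structure (atom table with
#'   `sigma`, `eps` columns).
#' @return energy, kcal/mol.
#' @export
lj_energy <- function(complex) {
  a <- complex$atoms
  p <- cross_pairs(complex)
  X <- coords3d(complex)
  r <- sqrt(rowSums((X[p$i, , drop = FALSE] - X[p$j, , drop = FALSE])^2))
  if (any(r < 1e-9)) stop("overlapping atoms (r = 0) in complex")
  sij <- (a$sigma[p$i] + a$sigma[p$j]) / 2
  eij <- sqrt(a$eps[p$i] * a$eps[p$j])
  sr6 <- (sij / r)^6
  sum(4 * eij * (sr6^2 - sr6))
}

#' Coulomb interaction energy of a toy complex
#'
#' `sum 332.0637 q_i q_j / (eps_r r_ij)` over receptor x ligand pairs.
#'
#' @inheritParams lj_energy
#' @param eps_r relative dielectric; defaults to the complex's attached
#'   force field.
#' @return energy, kcal/mol.
#' @export
coulomb_energy <- function(complex, eps_r = NULL) {
  if (is.null(eps_r)) {
    ff <- attr(complex, "ff")
    eps_r <- if (is.null(ff)) 1 else ff$eps_r
  }
  a <- complex$atoms
  p <- cross_pairs(complex)
  X <- coords3d(complex)
  r <- sqrt(rowSums((X[p$i, , drop = FALSE] - X[p$j, , drop = FALSE])^2))
  if (any(r < 1e-9)) stop("overlapping atoms (r = 0) in complex")
  sum(.coulomb_k * a$charge[p$i] * a$charge[p$j] / (eps_r * r))
}

#' Born solvation energy of a single ion (test oracle)
#'
#' `-166 q^2 / R (1 - 1/eps_r)` - the closed-form generalized-Born limit
#' for one spherical ion, used to validate ingested polar terms.
#'
#' @param q charge, e.
#' @param radius Born radius, Angstrom.
#' @param eps_r solvent relative dielectric.
#' @return energy, kcal/mol.
#' @export
born_ion_energy <- function(q, radius, eps_r = 78.5) {
  -(.coulomb_k / 2) * q^2 / radius * (1 - 1 / eps_r)
}

# Bondi-type van der Waals radii, Angstrom
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98,
                Na = 2.27, K = 2.75, Mg = 1.73, Ca = 2.31, Zn = 1.39,
                Fe = 2.00, Se = 1.90, B = 1.92, Si = 2.10)

# deterministic quasi-uniform sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over element-based van der Waals radii using a
#' deterministic golden-spiral point lattice.
#'
#' @param x a [structure3d()], or an n x 3 coordinate matrix together
#'   with `elements`.
#' @param elements chemical symbols (when `x` is a bare matrix).
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param n_points surface sample points per atom (default 960).
#' @return list: `total` (A^2) and `per_atom` (A^2 per atom).
#' @export
sasa <- function(x, elements = NULL, probe = 1.4, n_points = 960L) {
  if (inherits(x, "structure3d")) {
    X <- coords3d(x)
    elements <- x$atoms$element
  } else X <- as.matrix(x)
  if (is.null(elements) || length(elements) != nrow(X))
    stop("need one element symbol per atom")
  bad <- setdiff(unique(elements), names(.vdw_radii))
  if (length(bad))
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "))
  R <- unname(.vdw_radii[elements]) + probe
  n <- nrow(X)
  pts <- sphere_points(n_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    nbr <- which(sqrt(rowSums((X - matrix(X[i, ], n, 3,
      byrow = TRUE))^2)) < R[i] + R)
    nbr <- setdiff(nbr, i)
    surf <- sweep(pts * R[i], 2, X[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nbr) {
      d2 <- rowSums(sweep(surf, 2, X[j, ])^2)
      acc <- acc & d2 >= R[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Nonpolar surface energy from SASA
#'
#' `esurf = gamma * SASA + beta` with the community-standard default
#' surface tension gamma = 0.0072 kcal/mol/A^2 and offset beta = 0.
#'
#' @param sasa_total total SASA, A^2.
#' @param gamma surface tension, kcal/mol/A^2.
#' @param beta offset, kcal/mol.
#' @return energy, kcal/mol.
#' @export
esurf_energy <- function(sasa_total, gamma = 0.0072, beta = 0) {
  gamma * sasa_total + beta
}

#' Rank energy ledgers against a control compound
#'
#' @param ledgers `energy_ledger` data.frame (one row per compound).
#' @param control one-row ledger of the control.
#' @return list: `ranked` (ledgers ascending by total, ties broken by
#'   id) and `better_than_control` (ids with total strictly below the
#'   control's).
#' @export
rank_against_control <- function(ledgers, control) {
  ord <- order(ledgers$total, ledgers$id)
  ranked <- ledgers[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  better <- ranked$id[ranked$total < control$total]
  list(ranked = ranked, control_total = control$total,
       better_than_control = better)
}
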