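# Seeded distance-geometry embedding.
#
# Bounds are built from ideal bond lengths (equality), ideal 1-3 angle
# distances (equality), regular-polygon geometry for aromatic rings
# (equality over all intra-ring pairs, which enforces planarity), and a
# van-der-Waals lower bound for all remaining pairs. Coordinates start from
# a seeded Gaussian cloud and are relaxed by L-BFGS on a quadratic bound
# violation penalty; the whole procedure is a pure function of the seed.

.bond_lengths <- c(
  "C-C" = 1.53, "C=C" = 1.34, "C#C" = 1.20, "C-N" = 1.47, "C=N" = 1.28,
  "C-O" = 1.43, "C=O" = 1.22, "C-S" = 1.81, "C-F" = 1.35, "C-Cl" = 1.77,
  "C-Br" = 1.94, "C-I" = 2.14, "N-N" = 1.45, "N-O" = 1.40, "N=O" = 1.21,
  "O-O" = 1.48, "S=O" = 1.44, "C-H" = 1.09, "N-H" = 1.01, "O-H" = 0.96,
  "S-H" = 1.34, "C-P" = 1.84, "P-O" = 1.63, "P=O" = 1.48)

ideal_bond_length <- function(e1, e2, order, aromatic) {
  if (aromatic) {
    if (all(c(e1, e2) == "C")) return(1.39)
    return(1.36)
  }
  sym <- c("-", "=", "#")[min(order, 3L)]
  k1 <- paste0(e1, sym, e2); k2 <- paste0(e2, sym, e1)
  if (!is.na(.bond_lengths[k1])) return(unname(.bond_lengths[k1]))
  if (!is.na(.bond_lengths[k2])) return(unname(.bond_lengths[k2]))
  1.5  # fallback for uncommon pairs
}

# Geometry bounds for one molecule: list of (i, j, target, type)
dg_bounds <- function(mol) {
  n <- n_atoms(mol)
  b <- mol$bonds
  # perceived aromatic rings override Kekule alternation: intra-ring bonds
  # take the uniform aromatic length so the polygon constraints agree
  rings <- aromatic_rings(mol)
  for (ring in rings) {
    inring <- b$a1 %in% ring & b$a2 %in% ring
    b$aromatic[inring] <- TRUE
    b$order[inring] <- 1L
  }
  adj <- adjacency(mol)
  eq_i <- integer(); eq_j <- integer(); eq_d <- numeric()
  add_eq <- function(i, j, d) {
    eq_i <<- c(eq_i, i); eq_j <<- c(eq_j, j); eq_d <<- c(eq_d, d)
  }
  blen <- matrix(NA_real_, n, n)
  for (k in seq_len(nrow(b))) {
    d <- ideal_bond_length(mol$atoms$element[b$a1[k]],
                           mol$atoms$element[b$a2[k]],
                           b$order[k], isTRUE(b$aromatic[k]))
    blen[b$a1[k], b$a2[k]] <- blen[b$a2[k], b$a1[k]] <- d
    add_eq(b$a1[k], b$a2[k], d)
  }
  arom <- unique(unlist(rings))
  has_double <- rep(FALSE, n)
  for (k in seq_len(nrow(b))) if (b$order[k] >= 2L)
    has_double[c(b$a1[k], b$a2[k])] <- TRUE
  # 1-3 distances from ideal angles at the central atom
  for (j in seq_len(n)) {
    nbs <- adj[[j]]
    if (length(nbs) < 2L) next
    theta <- if (j %in% arom || has_double[j]) 120 else 109.47
    if (length(nbs) == 2L && sum(b$order[b$a1 == j | b$a2 == j] >= 3L))
      theta <- 180
    th <- theta * pi / 180
    for (p in seq_along(nbs)) for (q in seq_len(p - 1L)) {
      i <- nbs[p]; k <- nbs[q]
      d <- sqrt(blen[i, j]^2 + blen[k, j]^2 -
                  2 * blen[i, j] * blen[k, j] * cos(th))
      add_eq(i, k, d)
    }
  }
  # aromatic rings: full regular-polygon distance sets (forces planarity)
  for (ring in rings) {
    m <- length(ring)
    side <- 1.39
    circ <- side / (2 * sin(pi / m))
    for (p in seq_along(ring)) for (q in seq_len(p - 1L)) {
      sep <- min(abs(p - q), m - abs(p - q))
      d <- 2 * circ * sin(pi * sep / m)
      add_eq(ring[p], ring[q], d)
    }
  }
  # de-duplicate equality pairs, keep first (bond/angle take precedence)
  key <- paste(pmin(eq_i, eq_j), pmax(eq_i, eq_j))
  keep <- !duplicated(key)
  eq <- cbind(i = eq_i[keep], j = eq_j[keep])
  list(eq = eq, eq_d = eq_d[keep],
       lb = setdiff_pairs(n, key[keep]))
}

# all unordered pairs not in `taken` (as "i j" keys with i<j)
setdiff_pairs <- function(n, taken) {
  if (n < 2L) return(cbind(i = integer(), j = integer()))
  all_p <- t(utils::combn(n, 2L))
  key <- paste(all_p[, 1], all_p[, 2])
  all_p[!key %in% taken, , drop = FALSE]
}

dg_energy_grad <- function(x, eq, eq_d, lb, lb_d = 2.7, w_eq = 10, w_lb = 1) {
  n <- length(x) / 3L
  X <- matrix(x, n, 3L)
  E <- 0
  G <- matrix(0, n, 3L)
  pair_terms <- function(P, target, w, one_sided) {
    if (nrow(P) == 0L) return()
    dvec <- X[P[, 1], , drop = FALSE] - X[P[, 2], , drop = FALSE]
    r <- sqrt(rowSums(dvec^2)) + 1e-12
    viol <- r - target
    if (one_sided) viol <- pmin(viol, 0)  # penalize only r < lower bound
    E <<- E + w * sum(viol^2)
    coef <- 2 * w * viol / r
    gvec <- dvec * coef
    for (d in 1:3) {
      G[, d] <<- G[, d] + tapply_add(gvec[, d], P[, 1], n)
      G[, d] <<- G[, d] - tapply_add(gvec[, d], P[, 2], n)
    }
  }
  pair_terms(eq, eq_d, w_eq, FALSE)
  pair_terms(lb, lb_d, w_lb, TRUE)
  list(E = E, G = as.vector(G))
}

tapply_add <- function(v, idx, n) {
  out <- numeric(n)
  agg <- rowsum(v, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

embed_once <- function(bounds, n, seed) {
  x0 <- with_seed(seed, stats::rnorm(3L * n, sd = max(2, sqrt(n))))
  fn <- function(x) dg_energy_grad(x, bounds$eq, bounds$eq_d, bounds$lb)$E
  gr <- function(x) dg_energy_grad(x, bounds$eq, bounds$eq_d, bounds$lb)$G
  opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 1e4))
  list(coords = matrix(opt$par, n, 3L), energy = opt$value)
}

#' Generate 3D conformers by seeded distance-geometry embedding
#'
#' Up to `max_conformers` conformers are produced from independent seeded
#' starts and deduplicated at a heavy-atom RMSD threshold of 0.5 Angstrom
#' (after optimal superposition, reflections included, so rigid molecules
#' collapse to a single conformer). Deterministic for a fixed seed.
#'
#' @param mol a [molecule()].
#' @param max_conformers maximum number of conformers to keep (default 3,
#'   mirroring per-ligand conformational sampling depth used in screening).
#' @param seed integer seed.
#' @param dedup_rmsd heavy-atom RMSD threshold below which two embeddings
#'   count as the same conformation (Angstrom).
#' @return the molecule with `conformers` replaced by the embedded set.
#' @export
generate_conformers <- function(mol, max_conformers = 3L, seed = 1L,
                                dedup_rmsd = 0.5) {
  n <- n_atoms(mol)
  if (n < 1L) stop("cannot embed empty molecule ", mol$id)
  bounds <- dg_bounds(mol)
  heavy <- heavy_atoms(mol)
  confs <- list()
  energies <- numeric()
  n_tries <- max_conformers + 3L
  for (t in seq_len(n_tries)) {
    res <- tryCatch(embed_once(bounds, n, seed = seed * 1000L + t),
                    error = function(e) NULL)
    if (is.null(res) || !all(is.finite(res$coords)))
      next
    dup <- FALSE
    for (cf in confs) {
      r <- conf_rmsd_refl(cf[heavy, , drop = FALSE],
                          res$coords[heavy, , drop = FALSE])
      if (r <= dedup_rmsd) { dup <- TRUE; break }
    }
    if (!dup) {
      confs[[length(confs) + 1L]] <- res$coords
      energies <- c(energies, res$energy)
    }
    if (length(confs) >= max_conformers) break
  }
  if (length(confs) == 0L)
    stop("conformer embedding failed for molecule ", mol$id)
  ord <- order(energies)
  mol$conformers <- confs[ord]
  mol$properties$coord_dims <- "3d"
  mol
}

# RMSD up to rotation AND reflection (mirror images of an achiral embedding
# count as the same conformation).
conf_rmsd_refl <- function(a, b) {
  if (nrow(a) < 3L) return(rmsd_plain(a, b))
  direct <- tryCatch(rmsd_fit(a, b), error = function(e) Inf)
  b_ref <- b; b_ref[, 3] <- -b_ref[, 3]
  mirrored <- tryCatch(rmsd_fit(a, b_ref), error = function(e) Inf)
  min(direct, mirrored)
}
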