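#' Atom selections on trajectories and structures
#'
#' @param x a [trajectory()] or [structure3d()].
#' @return integer atom indices.
#' @export
select_ligand <- function(x) which(x$atoms$is_ligand)

#' @rdname select_ligand
#' @export
select_receptor <- function(x) which(!x$atoms$is_ligand)

#' @rdname select_ligand
#' @export
select_heavy <- function(x) which(x$atoms$element != "H")

#' Per-frame RMSD series
#'
#' RMSD of `selection` against a reference frame, optionally after
#' least-squares fitting each frame on `fit_selection` (by default the
#' measured selection itself; pass the receptor selection to reproduce the
#' usual "ligand RMSD after receptor fit").
#'
#' @param traj a [trajectory()].
#' @param selection atom indices measured (default all atoms).
#' @param ref_frame reference frame index.
#' @param fit fit before measuring?
#' @param fit_selection atom indices used for the superposition.
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, selection = seq_len(nrow(traj$atoms)),
                        ref_frame = 1L, fit = TRUE,
                        fit_selection = selection) {
  if (length(selection) == 0L) stop("empty selection")
  ref <- traj$frames[[ref_frame]]
  vapply(traj$frames, function(f) {
    if (fit) f <- kabsch_superpose(ref, f, fit_selection)$coords
    rmsd_plain(ref[selection, , drop = FALSE],
               f[selection, , drop = FALSE])
  }, numeric(1))
}

#' Per-atom RMSF
#'
#' Root-mean-square fluctuation about the time-mean position, after
#' per-frame fitting.
#'
#' @inheritParams rmsd_series
#' @return numeric vector, one RMSF (Angstrom) per selected atom.
#' @export
rmsf <- function(traj, selection = seq_len(nrow(traj$atoms)), fit = TRUE,
                 fit_selection = selection) {
  if (length(selection) == 0L) stop("empty selection")
  ref <- traj$frames[[1L]]
  fitted <- lapply(traj$frames, function(f) {
    if (fit) f <- kabsch_superpose(ref, f, fit_selection)$coords
    f[selection, , drop = FALSE]
  })
  arr <- simplify2array(fitted)          # atoms x 3 x frames
  mean_pos <- apply(arr, c(1, 2), mean)
  sq <- vapply(seq_along(fitted), function(i)
    rowSums((arr[, , i] - mean_pos)^2), numeric(length(selection)))
  sqrt(rowMeans(matrix(sq, nrow = length(selection))))
}

#' Geometric hydrogen-bond detection
#'
#' A bond is counted when the donor-acceptor distance is at most `d_cut`
#' and the hydrogen-donor-acceptor angle is at most `angle_cut`. Hydrogens
#' are taken from `hydrogens` or located as H atoms within 1.2 Angstrom of
#' a donor; both the donor-acceptor and hydrogen-acceptor distances are
#' reported since reporting conventions differ between tools.
#'
#' @param x a [structure3d()] or [trajectory()].
#' @param donors indices of donor heavy atoms (with bound hydrogens).
#' @param acceptors indices of acceptor heavy atoms.
#' @param hydrogens optional indices of candidate hydrogens.
#' @param d_cut donor-acceptor distance cutoff, Angstrom.
#' @param angle_cut H-D-A angle cutoff, degrees.
#' @return data.frame (frame, donor, hydrogen, acceptor, dist_da, dist_ha,
#'   angle); use [hbond_count_series()] for per-frame counts.
#' @export
hydrogen_bonds <- function(x, donors, acceptors, hydrogens = NULL,
                           d_cut = 3.5, angle_cut = 30) {
  frames <- if (inherits(x, "trajectory")) x$frames else list(coords3d(x))
  el <- x$atoms$element
  if (is.null(hydrogens)) hydrogens <- which(el == "H")
  if (length(hydrogens) == 0L)
    stop("no hydrogens available; add explicit hydrogens ",
         "(normalization pass) before hydrogen-bond analysis")
  out <- list()
  for (fi in seq_along(frames)) {
    X <- frames[[fi]]
    for (d in donors) {
      hs <- hydrogens[sqrt(rowSums((X[hydrogens, , drop = FALSE] -
        matrix(X[d, ], length(hydrogens), 3, byrow = TRUE))^2)) <= 1.2]
      if (!length(hs)) next
      for (a in acceptors) {
        if (a == d) next
        rda <- sqrt(sum((X[d, ] - X[a, ])^2))
        if (rda > d_cut) next
        for (h in hs) {
          v1 <- X[h, ] - X[d, ]
          v2 <- X[a, ] - X[d, ]
          ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
            sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          if (ang <= angle_cut) {
            out[[length(out) + 1L]] <- data.frame(
              frame = fi, donor = d, hydrogen = h, acceptor = a,
              dist_da = rda,
              dist_ha = sqrt(sum((X[h, ] - X[a, ])^2)), angle = ang)
            break  # one bond per donor-acceptor pair
          }
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(), donor = integer(),
                      hydrogen = integer(), acceptor = integer(),
                      dist_da = numeric(), dist_ha = numeric(),
                      angle = numeric()))
  do.call(rbind, out)
}

#' Per-frame hydrogen-bond counts
#' @inheritParams hydrogen_bonds
#' @return integer vector, one count per frame.
#' @export
hbond_count_series <- function(x, donors, acceptors, hydrogens = NULL,
                               d_cut = 3.5, angle_cut = 30) {
  nf <- if (inherits(x, "trajectory")) n_frames(x) else 1L
  hb <- hydrogen_bonds(x, donors, acceptors, hydrogens, d_cut, angle_cut)
  counts <- integer(nf)
  if (nrow(hb)) {
    t <- table(hb$frame)
    counts[as.integer(names(t))] <- as.integer(t)
  }
  counts
}

#' Minimum cross-group distance per frame
#'
#' @param traj a [trajectory()].
#' @param groupA,groupB disjoint atom index sets.
#' @return numeric vector (Angstrom), one per frame.
#' @export
min_distance_series <- function(traj, groupA, groupB) {
  check_groups(groupA, groupB)
  vapply(traj$frames, function(X)
    min(cross_dist(X, groupA, groupB)), numeric(1))
}

#' Cross-group contact counts per frame
#'
#' Number of inter-group atom pairs within `cutoff` (the distance window
#' where non-covalent contacts live).
#'
#' @inheritParams min_distance_series
#' @param cutoff contact distance cutoff, Angstrom.
#' @return integer vector, one per frame.
#' @export
contact_count_series <- function(traj, groupA, groupB, cutoff = 4.0) {
  check_groups(groupA, groupB)
  vapply(traj$frames, function(X)
    sum(cross_dist(X, groupA, groupB) <= cutoff), integer(1))
}

check_groups <- function(groupA, groupB) {
  if (!length(groupA) || !length(groupB)) stop("empty atom group")
  if (length(intersect(groupA, groupB)))
    stop("atom groups overlap")
  invisible(TRUE)
}

cross_dist <- function(X, ga, gb) {
  A <- X[ga, , drop = FALSE]; B <- X[gb, , drop = FALSE]
  sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B))
}

#' Covariance principal component analysis of a trajectory
#'
#' Frames are superposed on the first frame (over `selection`), atomic
#' coordinates centered on their time means, and the 3n x 3n covariance
#' matrix diagonalized. Eigenpairs come back sorted descending together
#' with explained-variance fractions and the projections of every frame
#' onto the leading eigenvectors.
#'
#' @param traj a [trajectory()].
#' @param selection atom indices analyzed (default all).
#' @param fit superpose frames before analysis?
#' @param n_components how many leading projections to return.
#' @return list: `values`, `vectors`, `explained`, `scores`
#'   (frames x n_components).
#' @export
pca_covariance <- function(traj, selection = seq_len(nrow(traj$atoms)),
                           fit = TRUE, n_components = 2L) {
  if (n_frames(traj) < 3L)
    stop("covariance PCA needs at least 3 frames")
  ref <- traj$frames[[1L]]
  M <- do.call(rbind, lapply(traj$frames, function(f) {
    if (fit) f <- kabsch_superpose(ref, f, selection)$coords
    as.vector(t(f[selection, , drop = FALSE]))
  }))
  M <- sweep(M, 2, colMeans(M))
  C <- crossprod(M) / (nrow(M) - 1)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  k <- min(n_components, ncol(M))
  list(values = vals, vectors = eig$vectors,
       explained = vals / sum(vals),
       scores = M %*% eig$vectors[, seq_len(k), drop = FALSE])
}

#' Free-energy landscape by Boltzmann inversion of a 2D histogram
#'
#' `G_i = -kB T ln(P_i / P_max)` over a 2D histogram of the supplied
#' collective coordinates (typically the two leading PCA projections).
#' The most populated bin sits at exactly G = 0; empty bins carry the
#' capped value max(G over sampled bins) + 1 kB T so the surface stays
#' finite.
#'
#' @param points n x 2 matrix of collective coordinates.
#' @param bins number of bins per axis (default 32).
#' @param temperature temperature, K (default 300).
#' @return `fel_grid` object: `x`, `y` (bin midpoints), `G` (kcal/mol
#'   matrix), `counts`, `temperature`.
#' @export
free_energy_landscape <- function(points, bins = 32L, temperature = 300) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("need at least one point")
  if (bins < 1L) stop("need at least one bin per axis")
  kB <- 0.0019872  # kcal/mol/K
  rng <- function(v) {
    r <- range(v)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    r + c(-1, 1) * 1e-9 * max(1, abs(r))
  }
  xe <- seq(rng(points[, 1])[1], rng(points[, 1])[2], length.out = bins + 1L)
  ye <- seq(rng(points[, 2])[1], rng(points[, 2])[2], length.out = bins + 1L)
  xi <- pmin(pmax(findInterval(points[, 1], xe, all.inside = TRUE), 1L), bins)
  yi <- pmin(pmax(findInterval(points[, 2], ye, all.inside = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  for (i in seq_len(nrow(points)))
    counts[xi[i], yi[i]] <- counts[xi[i], yi[i]] + 1L
  P <- counts / sum(counts)
  G <- matrix(NA_real_, bins, bins)
  occ <- counts > 0L
  G[occ] <- -kB * temperature * log(P[occ] / max(P))
  cap <- max(G[occ]) + kB * temperature
  G[!occ] <- cap
  structure(list(x = (xe[-1] + xe[-length(xe)]) / 2,
                 y = (ye[-1] + ye[-length(ye)]) / 2,
                 G = G, counts = counts, temperature = temperature),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  cat("<fel_grid>", length(x$x), "x", length(x$y), "bins at",
      x$temperature, "K; G range [0,",
      sprintf("%.3f", max(x$G)), "] kcal/mol\n")
  invisible(x)
}

#' @export
plot.fel_grid <- function(x, ...) {
  graphics::filled.contour(
    x$x, x$y, x$G,
    color.palette = function(n) grDevices::hcl.colors(n, "viridis"),
    xlab = "PC1", ylab = "PC2",
    main = sprintf("Free-energy landscape (%g K), kcal/mol",
                   x$temperature), ...)
  invisible(x)
}
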