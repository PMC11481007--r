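#' Synthetic screening library with planted geometric ground truth
#'
#' Generates feature-cloud actives that satisfy every distance constraint
#' of a pharmacophore model (before noise) and decoys whose geometry
#' violates at least two constraints by more than twice the tolerance
#' under every possible feature assignment. Each entry also carries a
#' small real scaffold SMILES so the full file-format path can be smoke
#' tested. Everything is a pure function of the spec (seed included).
#'
#' @param n_actives,n_decoys entry counts.
#' @param model a [pharm_model()] with a full distance matrix.
#' @param geometric_noise_sd per-coordinate Gaussian displacement applied
#'   to active feature points, Angstrom.
#' @param seed integer seed.
#' @return list with `clouds` (list of [feature_cloud()]) and `labels`
#'   (data.frame: id, is_active, smiles).
#' @export
make_feature_library <- function(n_actives, n_decoys, model = default_pharm_model(),
                                 geometric_noise_sd = 0, seed = 1L) {
  if (nrow(model$features) < 2L)
    stop("library generation needs a model with at least 2 features")
  if (geometric_noise_sd < 0) stop("geometric_noise_sd must be >= 0")
  ref <- embed_model_points(model)
  kinds <- model$features$kind
  with_seed(seed, {
    clouds <- list()
    labels <- list()
    idx <- 0L
    for (a in seq_len(n_actives)) {
      idx <- idx + 1L
      id <- sprintf("ACT%04d", a)
      pts <- ref + matrix(stats::rnorm(length(ref), sd = geometric_noise_sd),
                          nrow(ref), 3)
      clouds[[idx]] <- feature_cloud(id, data.frame(
        kind = kinds, x = pts[, 1], y = pts[, 2], z = pts[, 3]))
      labels[[idx]] <- data.frame(id = id, is_active = TRUE,
                                  smiles = active_scaffold_smiles())
    }
    span <- max(stats::dist(ref))
    for (dcy in seq_len(n_decoys)) {
      idx <- idx + 1L
      id <- sprintf("DEC%04d", dcy)
      repeat {
        pts <- matrix(stats::runif(length(ref), -span / 2, span / 2),
                      nrow(ref), 3)
        if (is_hard_decoy(model, kinds, pts)) break
      }
      clouds[[idx]] <- feature_cloud(id, data.frame(
        kind = kinds, x = pts[, 1], y = pts[, 2], z = pts[, 3]))
      labels[[idx]] <- data.frame(id = id, is_active = FALSE,
                                  smiles = decoy_scaffold_smiles())
    }
    list(clouds = clouds, labels = do.call(rbind, labels))
  })
}

# 3D coordinates realizing the model's distance matrix. When the model was
# built from a reference pose the classical-MDS embedding reproduces it
# exactly (up to rigid motion).
embed_model_points <- function(model) {
  d <- model$distances
  if (any(is.na(d[upper.tri(d)])))
    stop("library generation needs a fully constrained model")
  diag(d) <- 0
  emb <- stats::cmdscale(stats::as.dist(d), k = 3)
  if (max(abs(as.matrix(stats::dist(emb)) - d)) > 0.05)
    stop("distance constraints are not realizable in 3D ",
         "(inconsistent geometry)")
  unname(emb)
}

# decoy admissibility: no k-of-n match even at twice the tolerance, and
# every full assignment violates >= 2 constraints by > 2 tau d
is_hard_decoy <- function(model, kinds, pts) {
  cloud <- data.frame(kind = kinds, x = pts[, 1], y = pts[, 2], z = pts[, 3])
  wide <- model
  wide$tolerance <- pmin(model$tolerance * 2, 0.49)
  if (!is.null(match_points(wide, cloud))) return(FALSE)
  viol <- full_assignment_min_violations(model, cloud, factor = 2)
  viol >= 2L
}

# minimum, over all injective same-kind full assignments, of the number of
# constrained pairs violated by more than `factor` * tau * d
full_assignment_min_violations <- function(model, points, factor = 2) {
  f <- model$features
  P <- as.matrix(points[, c("x", "y", "z")])
  cands <- lapply(f$kind, function(k) which(points$kind == k))
  best <- Inf
  assign <- integer(nrow(f))
  recurse <- function(pos) {
    if (pos > nrow(f)) {
      v <- 0L
      for (i in seq_len(nrow(f))) for (j in seq_len(i - 1L)) {
        d <- model$distances[i, j]
        if (is.na(d)) next
        r <- sqrt(sum((P[assign[i], ] - P[assign[j], ])^2))
        if (abs(r - d) > factor * model$tolerance[i, j] * d) v <- v + 1L
      }
      best <<- min(best, v)
      return()
    }
    for (p in setdiff(cands[[pos]], assign[seq_len(pos - 1L)])) {
      assign[pos] <<- p
      recurse(pos + 1L)
    }
  }
  recurse(1L)
  best
}

# small real scaffolds: aromatic + hydrophobic + acceptor groups for the
# active tier; plain chains/single rings for the decoy tier
active_scaffold_smiles <- function() {
  chain <- sample(1:4, 1)
  sub <- sample(c("", "C", "F", "Cl", "OC"), 1)
  tail <- if (nzchar(sub)) sprintf("c3ccc(%s)cc3", sub) else "c3ccccc3"
  sprintf("OC(=O)%sc1ccc(-c2ccc(-%s)cc2)cc1",
          paste(rep("C", chain), collapse = ""), tail)
}

decoy_scaffold_smiles <- function() {
  sample(c("CCCCCCO", "CCNCCO", "CCCC(C)CC", "CC(C)CCN", "CCOCCOC",
           "C1CCCCC1", "CCCCC(=O)C"), 1)
}

#' Synthetic EC50 activity table with a planted structure-activity rule
#'
#' The planted rule is: molecules carrying a carboxylic acid group and at
#' least two aromatic rings are potent. Rule-positive molecules draw
#' log10 EC50 (nM) around 2.0, rule-negatives around 4.0, with log-normal
#' (multiplicative) noise; the 1000 nM activity threshold then recovers
#' the rule exactly at zero noise.
#'
#' @param n number of rows.
#' @param active_fraction fraction of rule-positive molecules in \[0, 1\].
#' @param ec50_noise_sd standard deviation of the log10 EC50 noise.
#' @param seed integer seed.
#' @return data.frame (id, smiles, ec50_nM, rule_active).
#' @export
make_activity_table <- function(n, active_fraction = 0.5,
                                ec50_noise_sd = 0.4, seed = 1L) {
  if (active_fraction < 0 || active_fraction > 1)
    stop("active_fraction must lie in [0, 1]")
  with_seed(seed, {
    rule <- stats::runif(n) < active_fraction
    smiles <- vapply(rule, function(r)
      if (r) active_scaffold_smiles() else decoy_scaffold_smiles(),
      character(1))
    log_ec50 <- ifelse(rule, 2.0, 4.0) + stats::rnorm(n, sd = ec50_noise_sd)
    data.frame(id = sprintf("CPD%05d", seq_len(n)), smiles = smiles,
               ec50_nM = 10^log_ec50, rule_active = rule)
  })
}

#' Synthetic ligand-in-pocket trajectory with controlled wobble
#'
#' Frames are the pose plus i.i.d. Gaussian per-coordinate displacement
#' ("wobble"), an optional linear drift along +x, and optional planted
#' collective modes (low-rank motions for PCA tests). With wobble alone,
#' the expected squared RMSD between two frames is 6 sigma^2 (each of the
#' 3 coordinates of each atom contributes the variance of a difference of
#' two independent N(0, sigma) draws).
#'
#' @param pose a [structure3d()] (or bare n x 3 coordinate matrix).
#' @param n_frames number of frames (>= 2).
#' @param wobble_sd per-coordinate Gaussian displacement, Angstrom.
#' @param drift rigid displacement along +x per frame, Angstrom/frame.
#' @param modes optional list of n_atoms x 3 displacement matrices; each
#'   frame adds `a_k * modes[[k]]` with `a_k ~ N(0, mode_sd[k])`.
#' @param mode_sd amplitudes for `modes` (recycled).
#' @param dt frame spacing, ps.
#' @param seed integer seed.
#' @return a [trajectory()].
#' @export
make_trajectory <- function(pose, n_frames, wobble_sd = 0.3, drift = 0,
                            modes = NULL, mode_sd = 1, dt = 1, seed = 1L) {
  if (n_frames < 2L) stop("a trajectory needs at least 2 frames")
  if (inherits(pose, "structure3d")) {
    base <- coords3d(pose)
    atoms <- pose$atoms[, c("chain", "resno", "resname", "name",
                            "element", "is_ligand")]
  } else {
    base <- as.matrix(pose)
    atoms <- data.frame(chain = "A", resno = 1L, resname = "MOL",
                        name = paste0("C", seq_len(nrow(base))),
                        element = "C", is_ligand = TRUE)
  }
  n <- nrow(base)
  if (!is.null(modes)) mode_sd <- rep_len(mode_sd, length(modes))
  with_seed(seed, {
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      X <- base
      if (!is.null(modes))
        for (k in seq_along(modes))
          X <- X + stats::rnorm(1, sd = mode_sd[k]) * modes[[k]]
      X <- X + matrix(stats::rnorm(3 * n, sd = wobble_sd), n, 3)
      X[, 1] <- X[, 1] + drift * (f - 1)
      frames[[f]] <- X
    }
    trajectory(frames, atoms, dt = dt)
  })
}

#' Toy force field for closed-form interaction energies
#'
#' @param eps_r relative dielectric (>= 1).
#' @param gamma surface tension for the nonpolar term, kcal/mol/A^2.
#' @param beta surface-term offset, kcal/mol.
#' @return list of class `toy_forcefield`.
#' @export
toy_forcefield <- function(eps_r = 1, gamma = 0.0072, beta = 0) {
  if (eps_r < 1) stop("relative dielectric must be >= 1")
  structure(list(eps_r = eps_r, gamma = gamma, beta = beta),
            class = "toy_forcefield")
}

#' Toy receptor-ligand complex with per-atom nonbonded parameters
#'
#' Receptor atoms fill a sphere at the origin, ligand atoms a smaller
#' sphere offset along +x, so the two groups interact without overlapping.
#' Per-atom sigma (A), epsilon (kcal/mol) and charge (e) are drawn
#' uniformly, giving closed-form pairwise energy oracles.
#'
#' @param n_receptor_atoms,n_ligand_atoms atom counts.
#' @param ff a [toy_forcefield()].
#' @param seed integer seed.
#' @return a [structure3d()] whose atom table carries `sigma`, `eps`,
#'   `charge` columns; the force field is attached as attribute `ff`.
#' @export
make_toy_complex <- function(n_receptor_atoms, n_ligand_atoms,
                             ff = toy_forcefield(), seed = 1L) {
  with_seed(seed, {
    n <- n_receptor_atoms + n_ligand_atoms
    sphere <- function(m, radius, center) {
      pts <- matrix(stats::rnorm(3 * m), m, 3)
      pts <- pts / sqrt(rowSums(pts^2)) * radius * stats::runif(m)^(1 / 3)
      sweep(pts, 2, center, "+")
    }
    rec <- sphere(n_receptor_atoms, 5, c(0, 0, 0))
    lig <- sphere(n_ligand_atoms, 2.5, c(9, 0, 0))
    xyz <- rbind(rec, lig)
    atoms <- data.frame(
      chain = rep(c("A", "B"), c(n_receptor_atoms, n_ligand_atoms)),
      resno = rep(c(1L, 2L), c(n_receptor_atoms, n_ligand_atoms)),
      resname = rep(c("REC", "LIG"), c(n_receptor_atoms, n_ligand_atoms)),
      name = paste0("X", seq_len(n)),
      element = sample(c("C", "N", "O"), n, replace = TRUE),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      is_ligand = rep(c(FALSE, TRUE), c(n_receptor_atoms, n_ligand_atoms)),
      sigma = stats::runif(n, 3, 4),
      eps = stats::runif(n, 0.05, 0.2),
      charge = stats::runif(n, -0.3, 0.3))
    s <- structure3d(atoms)
    attr(s, "ff") <- ff
    s
  })
}

#' Materialize a complete synthetic demo dataset on disk
#'
#' Writes a screening library (SDF of scaffolds + feature-cloud CSV), an
#' activity table (CSV), a toy trajectory (multi-model PDB) and the
#' pharmacophore model (YAML) under `dir`, all derived from one seed.
#'
#' @param dir output directory (created if missing).
#' @param n_actives,n_decoys library composition.
#' @param n_compounds activity-table size.
#' @param seed integer seed.
#' @return invisibly, the paths written.
#' @export
write_demo_fixtures <- function(dir, n_actives = 20, n_decoys = 80,
                                n_compounds = 400, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- default_pharm_model()
  lib <- make_feature_library(n_actives, n_decoys, model, seed = seed)
  act <- make_activity_table(n_compounds, seed = seed + 1L)
  paths <- c(
    model = file.path(dir, "pharm_model.yaml"),
    clouds = file.path(dir, "library_clouds.csv"),
    labels = file.path(dir, "library_labels.csv"),
    activity = file.path(dir, "activity.csv"),
    traj = file.path(dir, "toy_trajectory.pdb"))
  write_model_yaml(model, paths["model"])
  cl <- do.call(rbind, lapply(lib$clouds, function(cd)
    cbind(id = cd$id, cd$points)))
  utils::write.csv(cl, paths["clouds"], row.names = FALSE)
  utils::write.csv(lib$labels, paths["labels"], row.names = FALSE)
  utils::write.csv(act, paths["activity"], row.names = FALSE)
  cx <- make_toy_complex(20, 8, seed = seed + 2L)
  traj <- make_trajectory(cx, n_frames = 50, wobble_sd = 0.3,
                          seed = seed + 3L)
  write_trajectory_pdb(traj, paths["traj"])
  invisible(paths)
}

#' Read feature clouds written by [write_demo_fixtures()]
#' @param path CSV with columns id, kind, x, y, z.
#' @return list of [feature_cloud()].
#' @export
read_cloud_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$id), function(g)
    feature_cloud(g$id[1], g[, c("kind", "x", "y", "z")]))
}
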