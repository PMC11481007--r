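#' Pharmacophore features and models
#'
#' A pharmacophore model is a set of typed feature points (aromatic,
#' hydrophobic, acceptor, donor, anionic, cationic) with pairwise distance
#' constraints, a fractional tolerance per constrained pair, and a k-of-n
#' requirement: a molecule matches when at least `min_required` features
#' (including every `required` one) can be mapped to perceived feature
#' points of the same kind so that every constrained pair among the mapped
#' features satisfies |r_ij - d_ij| <= tau_ij * d_ij.
#'
#' @param label short feature label (e.g. `R1`, `Hy1`, `A1`).
#' @param kind one of `aromatic`, `hydrophobic`, `acceptor`, `donor`,
#'   `anionic`, `cationic`.
#' @param weight nonnegative scoring weight (default 1).
#' @param required must this feature be matched in every hit?
#' @return `pharm_feature`: a one-row data.frame.
#' @export
pharm_feature <- function(label, kind, weight = 1, required = FALSE) {
  kinds <- c("aromatic", "hydrophobic", "acceptor", "donor",
             "anionic", "cationic")
  if (!kind %in% kinds)
    stop("unknown feature kind '", kind, "'")
  if (weight < 0) stop("feature weight must be nonnegative")
  data.frame(label = label, kind = kind, weight = weight,
             required = required)
}

#' @rdname pharm_feature
#' @param features data.frame of stacked [pharm_feature()] rows.
#' @param distances symmetric matrix of inter-feature distances, Angstrom;
#'   `NA` marks unconstrained pairs.
#' @param tolerance fractional tolerance tau, scalar or symmetric matrix;
#'   default 0.125 (midpoint of the 10--15 percent range used in
#'   structure-guided screening).
#' @param min_required minimum number of matched features (k of n).
#' @return `pharm_model` object.
#' @export
pharm_model <- function(features, distances, tolerance = 0.125,
                        min_required = 4L) {
  n <- nrow(features)
  if (!is.matrix(distances) || any(dim(distances) != n))
    stop("distances must be an n x n matrix over the features")
  if (!isSymmetric(unname(ifelse(is.na(distances), -1, distances))))
    stop("distance matrix must be symmetric")
  diag(distances) <- NA_real_   # self-distances are never constraints
  offd <- distances[upper.tri(distances)]
  if (any(offd[!is.na(offd)] <= 0))
    stop("constrained distances must be positive")
  if (is.matrix(tolerance)) tau <- tolerance
  else tau <- matrix(tolerance, n, n)
  if (any(tau <= 0 | tau >= 0.5))
    stop("tolerance must lie in (0, 0.5)")
  if (min_required > n)
    stop("min_required exceeds the feature count")
  check_triangle(distances, tau)
  structure(list(features = features, distances = distances,
                 tolerance = tau, min_required = as.integer(min_required)),
            class = "pharm_model")
}

check_triangle <- function(d, tau) {
  n <- nrow(d)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    if (any(is.na(c(d[i, j], d[j, k], d[i, k])))) next
    slack <- 1 + max(tau[i, j], tau[j, k], tau[i, k])
    if (d[i, k] > (d[i, j] + d[j, k]) * slack)
      stop("distance constraints violate the triangle inequality (",
           i, ",", j, ",", k, ")")
  }
  invisible(TRUE)
}

#' @export
print.pharm_model <- function(x, ...) {
  cat("<pharm_model>", nrow(x$features), "features, min_required =",
      x$min_required, "\n")
  print(x$features)
  invisible(x)
}

# Reference arrangement of the five-feature agonist model: three aromatic
# rings, one hydrophobic centroid near the first ring, and one acceptor
# (carboxylate-like) anchor. Coordinates in Angstrom; distances are derived
# from these points so the constraint set is geometrically consistent.
.reference_feature_points <- function() {
  data.frame(
    label = c("A1", "Hy1", "R1", "R2", "R3"),
    kind = c("acceptor", "hydrophobic", "aromatic", "aromatic", "aromatic"),
    x = c(0.0, 3.6, 5.4, 7.2, 9.0),
    y = c(0.0, 1.8, -0.6, 2.4, 0.3),
    z = c(0.0, 0.4, 0.0, -0.9, 1.1))
}

#' The packaged five-feature agonist pharmacophore model
#'
#' Three aromatic features (R1, R2, R3), one hydrophobic (Hy1) and one
#' acceptor (A1), with pairwise distance constraints taken from a reference
#' arrangement. The acceptor and hydrophobic features are required; one
#' aromatic feature may be dropped (4-of-5 matching).
#'
#' @param tolerance fractional distance tolerance (default 0.125).
#' @param min_required k in k-of-n matching (default 4).
#' @return a [pharm_model()].
#' @export
default_pharm_model <- function(tolerance = 0.125, min_required = 4L) {
  pts <- .reference_feature_points()
  feats <- do.call(rbind, Map(pharm_feature, pts$label, pts$kind,
                              weight = 1,
                              required = pts$kind %in% c("acceptor",
                                                         "hydrophobic")))
  d <- as.matrix(dist(pts[, c("x", "y", "z")]))
  dimnames(d) <- list(pts$label, pts$label)
  pharm_model(feats, d, tolerance, min_required)
}

#' A bare feature-point cloud
#'
#' Abstract representation of a molecule as labeled 3D feature points,
#' used by the synthetic library generator to test the matcher with exact
#' geometric control.
#'
#' @param id identifier.
#' @param points data.frame with columns `kind`, `x`, `y`, `z`.
#' @return object of class `feature_cloud`.
#' @export
feature_cloud <- function(id, points) {
  structure(list(id = id, points = as.data.frame(points)),
            class = "feature_cloud")
}

#' @export
print.feature_cloud <- function(x, ...) {
  cat("<feature_cloud>", x$id, "-", nrow(x$points), "points (",
      paste(x$points$kind, collapse = ", "), ")\n")
  invisible(x)
}

#' Perceive pharmacophore feature points in a conformer
#'
#' Rules (documented, deliberately simple):
#' * aromatic: centroid of each 5- or 6-membered aromatic ring;
#' * acceptor: each O, and each N with at most two heavy neighbours, with
#'   non-positive formal charge (both carboxylate oxygens emit points);
#' * hydrophobic: centroid of each maximal connected group of >= 3
#'   non-aromatic carbon atoms;
#' * donor: O with one heavy neighbour, or neutral/positive N with at most
#'   two heavy neighbours (implicit hydrogen assumed);
#' * anionic / cationic: atoms with negative / positive formal charge.
#'
#' @param mol a [molecule()] with at least one conformer.
#' @param conformer_index which conformer to use.
#' @return data.frame with columns `kind`, `x`, `y`, `z`, `atoms`
#'   (slash-separated source atom indices).
#' @export
perceive_features <- function(mol, conformer_index = 1L) {
  xyz <- conformer(mol, conformer_index)
  el <- mol$atoms$element
  fc <- mol$atoms$formal_charge
  adj <- adjacency(mol)
  heavy_deg <- vapply(adj, function(nb) sum(el[nb] != "H"), integer(1))
  arings <- aromatic_rings(mol)
  arom_atoms <- unique(unlist(arings))
  pts <- list()
  add <- function(kind, idx) {
    ctr <- colMeans(xyz[idx, , drop = FALSE])
    pts[[length(pts) + 1L]] <<- data.frame(
      kind = kind, x = ctr[1], y = ctr[2], z = ctr[3],
      atoms = paste(idx, collapse = "/"))
  }
  for (ring in arings) add("aromatic", ring)
  for (i in which((el == "O" & fc <= 0) |
                  (el == "N" & fc <= 0 & heavy_deg <= 2L)))
    add("acceptor", i)
  # maximal all-carbon non-aromatic connected groups
  cand <- which(el == "C" & !(seq_along(el) %in% arom_atoms))
  comp <- connected_components(adj, cand)
  for (grp in comp) if (length(grp) >= 3L) add("hydrophobic", grp)
  for (i in which((el == "O" & heavy_deg == 1L & fc == 0) |
                  (el == "N" & fc >= 0 & heavy_deg <= 2L)))
    add("donor", i)
  for (i in which(fc < 0)) add("anionic", i)
  for (i in which(fc > 0)) add("cationic", i)
  if (!length(pts))
    return(data.frame(kind = character(), x = numeric(), y = numeric(),
                      z = numeric(), atoms = character()))
  do.call(rbind, pts)
}

connected_components <- function(adj, subset) {
  comp <- list()
  left <- subset
  while (length(left)) {
    frontier <- left[1]
    grp <- integer()
    while (length(frontier)) {
      a <- frontier[1]; frontier <- frontier[-1]
      if (a %in% grp) next
      grp <- c(grp, a)
      frontier <- c(frontier, intersect(adj[[a]], setdiff(left, grp)))
    }
    comp[[length(comp) + 1L]] <- sort(grp)
    left <- setdiff(left, grp)
  }
  comp
}

#' Build a pharmacophore model from a reference ligand pose
#'
#' Distances are the Euclidean separations of the picked feature centroids
#' in the reference conformer; labels follow pick order.
#'
#' @param ligand a [molecule()] with a 3D conformer, or a
#'   [feature_cloud()].
#' @param picks list of lists with elements `kind` and `atoms` (atom
#'   indices of the reference conformer) or, for a cloud, `point` (row
#'   index); optional `label`, `weight`, `required`.
#' @param tolerance fractional tolerance (default 0.125).
#' @param min_required k of n (default: all picked features).
#' @return a [pharm_model()].
#' @export
build_model_from_reference <- function(ligand, picks, tolerance = 0.125,
                                       min_required = length(picks)) {
  ctrs <- matrix(NA_real_, length(picks), 3)
  feats <- list()
  for (i in seq_along(picks)) {
    p <- picks[[i]]
    if (inherits(ligand, "feature_cloud")) {
      ctrs[i, ] <- as.numeric(ligand$points[p$point, c("x", "y", "z")])
    } else {
      xyz <- conformer(ligand, 1L)
      if (any(p$atoms > n_atoms(ligand)))
        stop("pick ", i, " references atoms outside the ligand")
      ctrs[i, ] <- colMeans(xyz[p$atoms, , drop = FALSE])
    }
    feats[[i]] <- pharm_feature(
      label = if (!is.null(p$label)) p$label else paste0("F", i),
      kind = p$kind,
      weight = if (!is.null(p$weight)) p$weight else 1,
      required = isTRUE(p$required))
  }
  d <- as.matrix(dist(ctrs))
  if (any(d[upper.tri(d)] < 1e-6))
    stop("coincident feature centroids give a degenerate model")
  pharm_model(do.call(rbind, feats), d, tolerance, min_required)
}

# candidate feature points per conformer of a molecule or cloud
candidate_point_sets <- function(x) {
  if (inherits(x, "feature_cloud")) return(list(x$points))
  if (!inherits(x, "molecule")) stop("cannot match object of class ",
                                     class(x)[1])
  if (length(x$conformers) < 1L)
    stop("molecule ", x$id, " has no conformer; run generate_conformers()")
  lapply(seq_along(x$conformers), function(i) perceive_features(x, i))
}

#' Match a molecule (or feature cloud) against a pharmacophore model
#'
#' Over all conformers and all injective assignments of model features to
#' perceived points of the same kind, returns the assignment maximizing
#' (weighted matched count, then lowest deviation) subject to the k-of-n
#' requirement and all pairwise constraints among matched features. The
#' search is backtracking with distance-feasibility pruning; exactly one
#' conformer is reported.
#'
#' @param model a [pharm_model()].
#' @param x a [molecule()] with conformers, or a [feature_cloud()].
#' @return `NULL` when there is no admissible match, else a `pharm_match`
#'   list: `mapping` (feature label -> point row), `matched_count`,
#'   `conformer`, `deviation` (RMS fractional deviation over constrained
#'   matched pairs) and `score` (sum of matched weights minus deviation).
#' @export
match_pharmacophore <- function(model, x) {
  sets <- candidate_point_sets(x)
  best <- NULL
  for (ci in seq_along(sets)) {
    res <- match_points(model, sets[[ci]])
    if (is.null(res)) next
    res$conformer <- ci
    if (is.null(best) || better_match(res, best)) best <- res
  }
  if (!is.null(best)) {
    best$id <- if (inherits(x, "molecule")) x$id else x$id
    class(best) <- "pharm_match"
  }
  best
}

better_match <- function(a, b) {
  if (a$weight_sum != b$weight_sum) return(a$weight_sum > b$weight_sum)
  a$deviation < b$deviation - 1e-12
}

#' @export
print.pharm_match <- function(x, ...) {
  cat("<pharm_match>", x$id, "- matched", x$matched_count,
      "features on conformer", x$conformer,
      sprintf("(score %.3f, deviation %.4f)\n", x$score, x$deviation))
  invisible(x)
}

# Backtracking matcher on a single candidate point set.
match_points <- function(model, points) {
  f <- model$features
  nf <- nrow(f)
  d <- model$distances
  tau <- model$tolerance
  # candidate point rows per feature, same kind only
  cands <- lapply(f$kind, function(k) which(points$kind == k))
  P <- as.matrix(points[, c("x", "y", "z"), drop = FALSE])
  # visit features in an order that fails fast: required first, then
  # fewest candidates
  ord <- order(!f$required, lengths(cands))
  best <- NULL
  assign <- rep(NA_integer_, nf)
  recurse <- function(pos) {
    if (pos > nf) {
      matched <- which(!is.na(assign))
      if (length(matched) < model$min_required) return()
      devs <- numeric()
      for (ii in seq_along(matched)) for (jj in seq_len(ii - 1L)) {
        i <- matched[ii]; j <- matched[jj]
        if (is.na(d[i, j])) next
        r <- sqrt(sum((P[assign[i], ] - P[assign[j], ])^2))
        devs <- c(devs, abs(r - d[i, j]) / d[i, j])
      }
      dev <- if (length(devs)) sqrt(mean(devs^2)) else 0
      cand <- list(assign = assign, matched_count = length(matched),
                   weight_sum = sum(f$weight[matched]), deviation = dev)
      if (is.null(best) || better_match(cand, best)) best <<- cand
      return()
    }
    i <- ord[pos]
    # upper bound prune: even matching everything remaining cannot reach
    # min_required
    n_assigned <- sum(!is.na(assign))
    remaining <- nf - pos + 1L
    if (n_assigned + remaining >= model$min_required) {
      for (p in cands[[i]]) {
        if (p %in% assign) next
        ok <- TRUE
        for (j in which(!is.na(assign))) {
          if (is.na(d[i, j])) next
          r <- sqrt(sum((P[p, ] - P[assign[j], ])^2))
          if (abs(r - d[i, j]) > tau[i, j] * d[i, j]) { ok <- FALSE; break }
        }
        if (ok) {
          assign[i] <<- p
          recurse(pos + 1L)
          assign[i] <<- NA_integer_
        }
      }
    }
    # skip this feature (only if optional)
    if (!f$required[i] && n_assigned + remaining - 1L >= model$min_required)
      recurse(pos + 1L)
  }
  recurse(1L)
  if (is.null(best)) return(NULL)
  matched <- which(!is.na(best$assign))
  list(mapping = stats::setNames(best$assign, f$label),
       matched_count = best$matched_count,
       weight_sum = best$weight_sum,
       deviation = best$deviation,
       score = best$weight_sum - best$deviation)
}

#' Screen a library against a pharmacophore model
#'
#' @param model a [pharm_model()].
#' @param library list of [molecule()]s and/or [feature_cloud()]s.
#' @param verbose print the hit fraction summary line.
#' @return data.frame of hits (id, matched_count, score, conformer),
#'   sorted by score descending with ties broken lexicographically by id;
#'   attribute `hit_fraction` gives hits / library size.
#' @export
screen_library <- function(model, library, verbose = FALSE) {
  if (length(library) == 0L) stop("cannot screen an empty library")
  rows <- list()
  for (x in library) {
    m <- match_pharmacophore(model, x)
    if (is.null(m)) next
    rows[[length(rows) + 1L]] <- data.frame(
      id = m$id, matched_count = m$matched_count,
      score = m$score, conformer = m$conformer)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(id = character(), matched_count = integer(),
                         score = numeric(), conformer = integer())
  out <- out[order(-out$score, out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "hit_fraction") <- nrow(out) / length(library)
  if (verbose)
    message(sprintf("screen: %d / %d hits (%.2f%% of library)",
                    nrow(out), length(library),
                    100 * nrow(out) / length(library)))
  out
}

#' Write / read a pharmacophore model as a YAML config
#'
#' @param model a [pharm_model()].
#' @param path file path.
#' @return `path` (write) or a [pharm_model()] (read).
#' @export
write_model_yaml <- function(model, path) {
  f <- model$features
  cons <- list()
  d <- model$distances
  for (i in seq_len(nrow(f))) for (j in seq_len(i - 1L)) {
    if (is.na(d[i, j])) next
    cons[[length(cons) + 1L]] <- list(i = f$label[j], j = f$label[i],
                                      d = unname(d[i, j]),
                                      tau = unname(model$tolerance[i, j]))
  }
  yaml::write_yaml(precision = 12, list(
    features = lapply(seq_len(nrow(f)), function(i)
      list(label = f$label[i], kind = f$kind[i], weight = f$weight[i],
           required = f$required[i])),
    distances = cons,
    min_required = model$min_required), path)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  feats <- do.call(rbind, lapply(cfg$features, function(p)
    pharm_feature(p$label, p$kind, p$weight %||% 1,
                  isTRUE(p$required))))
  n <- nrow(feats)
  d <- matrix(NA_real_, n, n, dimnames = list(feats$label, feats$label))
  tau <- matrix(0.125, n, n)
  for (cn in cfg$distances) {
    i <- match(cn$i, feats$label); j <- match(cn$j, feats$label)
    d[i, j] <- d[j, i] <- cn$d
    tau[i, j] <- tau[j, i] <- cn$tau %||% 0.125
  }
  pharm_model(feats, d, tau, cfg$min_required %||% 4L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
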