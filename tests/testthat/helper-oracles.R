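# Independent oracles and shared fixtures for the test suite.

# Exhaustive pharmacophore matcher: enumerate every feature subset of size
# >= min_required containing all required features, and every injective
# same-kind assignment; keep the (weight sum, -deviation) maximum. Written
# independently of the package's backtracking search.
exhaustive_match <- function(model, points) {
  f <- model$features
  nf <- nrow(f)
  P <- as.matrix(points[, c("x", "y", "z")])
  d <- model$distances
  tau <- model$tolerance
  best <- NULL
  consider <- function(sub, assign) {
    ok <- TRUE
    devs <- numeric()
    for (ii in seq_along(sub)) for (jj in seq_len(ii - 1L)) {
      i <- sub[ii]; j <- sub[jj]
      if (is.na(d[i, j])) next
      r <- sqrt(sum((P[assign[ii], ] - P[assign[jj], ])^2))
      if (abs(r - d[i, j]) > tau[i, j] * d[i, j]) { ok <- FALSE; break }
      devs <- c(devs, abs(r - d[i, j]) / d[i, j])
    }
    if (!ok) return()
    dev <- if (length(devs)) sqrt(mean(devs^2)) else 0
    cand <- list(weight_sum = sum(f$weight[sub]), deviation = dev,
                 matched_count = length(sub))
    if (is.null(best) ||
        cand$weight_sum > best$weight_sum ||
        (cand$weight_sum == best$weight_sum &&
         cand$deviation < best$deviation - 1e-12))
      best <<- cand
  }
  subsets <- unlist(lapply(model$min_required:nf, function(k)
    utils::combn(nf, k, simplify = FALSE)), recursive = FALSE)
  for (sub in subsets) {
    if (!all(which(f$required) %in% sub)) next
    cand_sets <- lapply(sub, function(i) which(points$kind == f$kind[i]))
    if (any(lengths(cand_sets) == 0L)) next
    # enumerate injective assignments recursively
    rec <- function(pos, assign) {
      if (pos > length(sub)) { consider(sub, assign); return() }
      for (p in setdiff(cand_sets[[pos]], assign))
        rec(pos + 1L, c(assign, p))
    }
    rec(1L, integer())
  }
  best
}

# A mixed-difficulty matcher instance: half the draws are pure random
# clouds (mostly non-matching), half are noisy embeddings of the model's
# reference geometry plus distractor points (mostly matching), so the
# oracle-equivalence checks exercise both outcomes.
random_match_instance <- function(model, kinds) {
  if (runif(1) < 0.5) {
    random_cloud(sample(4:8, 1), kinds)
  } else {
    ref <- pharmfunnel:::embed_model_points(model)
    pts <- ref + matrix(rnorm(length(ref), sd = runif(1, 0.1, 0.8)),
                        nrow(ref), 3)
    cloud <- data.frame(kind = model$features$kind,
                        x = pts[, 1], y = pts[, 2], z = pts[, 3])
    extra <- sample(0:3, 1)
    if (extra > 0)
      cloud <- rbind(cloud, random_cloud(extra, kinds))
    cloud[sample(nrow(cloud)), , drop = FALSE]
  }
}

random_cloud <- function(n_points, kinds, span = 10) {
  data.frame(kind = sample(kinds, n_points, replace = TRUE),
             x = runif(n_points, -span / 2, span / 2),
             y = runif(n_points, -span / 2, span / 2),
             z = runif(n_points, -span / 2, span / 2))
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}
proper_rotation <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# brute-force double-loop nonbonded energies over receptor x ligand pairs
brute_lj <- function(complex) {
  a <- complex$atoms
  X <- as.matrix(a[, c("x", "y", "z")])
  rec <- which(!a$is_ligand); lig <- which(a$is_ligand)
  e <- 0
  for (i in rec) for (j in lig) {
    r <- sqrt(sum((X[i, ] - X[j, ])^2))
    s <- (a$sigma[i] + a$sigma[j]) / 2
    eps <- sqrt(a$eps[i] * a$eps[j])
    e <- e + 4 * eps * ((s / r)^12 - (s / r)^6)
  }
  e
}

brute_coulomb <- function(complex, eps_r = 1) {
  a <- complex$atoms
  X <- as.matrix(a[, c("x", "y", "z")])
  rec <- which(!a$is_ligand); lig <- which(a$is_ligand)
  e <- 0
  for (i in rec) for (j in lig) {
    r <- sqrt(sum((X[i, ] - X[j, ])^2))
    e <- e + 332.0637 * a$charge[i] * a$charge[j] / (eps_r * r)
  }
  e
}

# the published MM-PBSA component table used as a ledger fixture
# (10 candidate compounds plus the reference agonist as control)
mmpbsa_fixture <- function() {
  tab <- read.csv(text = "id,vdw,eel,egb,esurf,ggas,gsolv,total
1,-65.71,-46.92,59.63,-10.30,-112.63,49.34,-63.29
2,-44.26,-26.04,37.07,-7.04,-70.29,30.04,-40.26
3,-55.26,-21.45,34.37,-8.84,-57.67,29.07,-47.60
4,-53.93,-55.64,57.82,-8.12,-109.58,49.70,-59.87
5,-56.76,-19.40,40.30,-8.31,-76.16,31.99,-44.17
6,-54.69,-71.14,80.23,-9.18,-125.83,71.05,-54.77
7,-50.97,-17.73,38.13,-7.66,-68.70,30.47,-38.24
8,-41.37,-6.33,25.58,-5.41,-47.70,20.17,-27.53
9,-47.59,-6.12,31.13,-6.21,-53.70,24.92,-28.78
10,-62.65,-20.85,47.13,-8.79,-83.50,38.34,-45.16
Control,-53.54,-23.06,41.58,-7.43,-76.60,34.15,-42.45",
    stringsAsFactors = FALSE, colClasses = c(id = "character"))
  class(tab) <- c("energy_ledger", "data.frame")
  tab
}

# docking-score fixture for the top-10 + control cut (scores as published)
docking_fixture <- function() {
  data.frame(id = c(as.character(1:10), "Control"),
             score = c(-13.9, -13.9, -13.5, -13.4, -13.4, -12.9, -12.7,
                       -12.3, -12.1, -12.1, -12.1),
             stringsAsFactors = FALSE)
}

# shared featurized planted-rule activity dataset; built once per run
.ml_fixture_env <- new.env(parent = emptyenv())
ml_fixture <- function(n = 300L) {
  key <- paste0("n", n)
  if (is.null(.ml_fixture_env[[key]])) {
    act <- make_activity_table(n, active_fraction = 0.5, seed = 101L)
    lab <- label_activities(act)
    mols <- molecules_from_smiles(lab$smiles, ids = lab$id)
    X <- featurize_molecules(mols)
    y <- lab$label[match(rownames(X), lab$id)]
    .ml_fixture_env[[key]] <- list(table = lab, x = X, y = y)
  }
  .ml_fixture_env[[key]]
}
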