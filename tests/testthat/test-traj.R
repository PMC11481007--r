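test_that("Kabsch superposition nulls rigid motion and matches bio3d", {
  set.seed(2)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-12)
  R <- proper_rotation()
  B <- sweep(A %*% R, 2, c(4, -2, 7), "+")
  fit <- kabsch_superpose(A, B)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # independent route: bio3d's least-squares fit on random clouds
  for (rep in 1:10) {
    a <- matrix(rnorm(36), 12, 3)
    b <- matrix(rnorm(36), 12, 3)
    ours <- kabsch_superpose(a, b)$rmsd
    theirs <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
    expect_equal(ours, theirs, tolerance = 1e-3)  # bio3d rounds to 3 dp
  }
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
})

test_that("fitted RMSD never exceeds unfitted RMSD on any frame", {
  cx <- make_toy_complex(15, 6, seed = 8)
  tr <- make_trajectory(cx, 40, wobble_sd = 0.6, drift = 0.1, seed = 9)
  fitted <- rmsd_series(tr)
  plain <- rmsd_series(tr, fit = FALSE)
  expect_true(all(fitted <= plain + 1e-9))
  expect_length(fitted, 40L)
})

test_that("RMSD and RMSF vanish for rigid and zero-wobble trajectories", {
  pose <- matrix(rnorm(24), 8, 3)
  tr0 <- make_trajectory(pose, 10, wobble_sd = 0, seed = 1)
  expect_equal(rmsd_series(tr0, fit = FALSE), rep(0, 10))
  # rigidly translated copies: zero after fitting
  frames <- lapply(0:9, function(i) pose + i * 2)
  trt <- trajectory(frames, tr0$atoms)
  expect_equal(max(rmsd_series(trt)), 0, tolerance = 1e-10)
  expect_equal(max(rmsf(trt)), 0, tolerance = 1e-10)
  # wobbling ligand stays within the 3 A stability window
  trw <- make_trajectory(pose, 200, wobble_sd = 0.5, seed = 3)
  expect_lt(mean(rmsd_series(trw, fit = FALSE)), 3)
  expect_error(rmsd_series(tr0, selection = integer()), "empty")
})

test_that("hydrogen bonds follow the distance-plus-angle criterion", {
  # ideal linear O-H...O at 2.8 A donor-acceptor distance
  atoms <- data.frame(chain = "A", resno = 1:3, resname = "MOL",
                      name = c("O1", "H1", "O2"),
                      element = c("O", "H", "O"),
                      x = c(0, 0.96, 2.8), y = 0, z = 0,
                      is_ligand = FALSE)
  s <- structure3d(atoms)
  hb <- hydrogen_bonds(s, donors = 1, acceptors = 3)
  expect_identical(nrow(hb), 1L)
  expect_equal(hb$dist_da, 2.8)
  expect_equal(hb$dist_ha, 2.8 - 0.96)
  expect_equal(hb$angle, 0, tolerance = 1e-10)
  # same geometry stretched beyond the cutoff
  far <- atoms; far$x[3] <- 4.5
  expect_identical(nrow(hydrogen_bonds(structure3d(far), 1, 3)), 0L)
  # bent geometry beyond 30 degrees fails the angle test
  bent <- atoms
  bent$x[2] <- 0.96 * cos(50 * pi / 180)
  bent$y[2] <- 0.96 * sin(50 * pi / 180)
  expect_identical(nrow(hydrogen_bonds(structure3d(bent), 1, 3)), 0L)
  # no hydrogens at all -> instructive error
  noh <- structure3d(atoms[c(1, 3), ])
  expect_error(hydrogen_bonds(noh, 1, 2), "hydrogens")
})

test_that("a planted geometry set yields exactly its qualifying bond count", {
  # three donor/acceptor pairs: two qualify, one is too far
  atoms <- data.frame(
    chain = "A", resno = 1:9, resname = "MOL",
    name = paste0("X", 1:9),
    element = c("O", "H", "O", "N", "H", "O", "O", "H", "O"),
    x = c(0, 0.96, 2.9, 10, 10.96, 13.0, 20, 20.96, 25),
    y = 0, z = 0, is_ligand = FALSE)
  s <- structure3d(atoms)
  hb <- hydrogen_bonds(s, donors = c(1, 4, 7), acceptors = c(3, 6, 9))
  expect_identical(nrow(hb), 2L)
  counts <- hbond_count_series(s, c(1, 4, 7), c(3, 6, 9))
  expect_identical(counts, 2L)
})

test_that("minimum distances and contact counts match the double loop", {
  two <- trajectory(list(matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)),
                    data.frame(chain = "A", resno = 1:2, resname = "M",
                               name = c("C1", "C2"), element = "C",
                               is_ligand = c(FALSE, TRUE)))
  expect_equal(min_distance_series(two, 1, 2), 3)
  expect_identical(contact_count_series(two, 1, 2), 1L)
  expect_identical(contact_count_series(two, 1, 2, cutoff = 2.5), 0L)
  cx <- make_toy_complex(12, 7, seed = 4)
  tr <- make_trajectory(cx, 10, wobble_sd = 0.5, seed = 5)
  ga <- select_receptor(tr); gb <- select_ligand(tr)
  for (f in c(1L, 5L)) {
    X <- tr$frames[[f]]
    dd <- as.matrix(dist(X))[ga, gb]
    expect_equal(min_distance_series(tr, ga, gb)[f], min(dd))
    expect_identical(contact_count_series(tr, ga, gb)[f],
                     as.integer(sum(dd <= 4)))
  }
  expect_error(min_distance_series(tr, 1:3, 3:5), "overlap")
})

test_that("covariance PCA finds planted collective modes", {
  pose <- matrix(rnorm(60), 20, 3)
  mode1 <- matrix(rnorm(60), 20, 3); mode1 <- mode1 / sqrt(sum(mode1^2))
  mode2 <- matrix(rnorm(60), 20, 3); mode2 <- mode2 / sqrt(sum(mode2^2))
  tr1 <- make_trajectory(pose, 120, wobble_sd = 0.01,
                         modes = list(mode1), mode_sd = 3, seed = 6)
  p1 <- pca_covariance(tr1, fit = FALSE)
  expect_gte(p1$explained[1], 0.99)
  tr2 <- make_trajectory(pose, 150, wobble_sd = 0.02,
                         modes = list(mode1, mode2), mode_sd = c(3, 2),
                         seed = 7)
  p2 <- pca_covariance(tr2, fit = FALSE)
  expect_gte(sum(p2$explained[1:2]), 0.95)
  # eigenvectors orthonormal
  V <- p2$vectors[, 1:5]
  expect_equal(crossprod(V), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # isotropic wobble spreads variance: no eigenvalue dominates
  tri <- make_trajectory(pose, 400, wobble_sd = 0.5, seed = 8)
  pi_ <- pca_covariance(tri, fit = FALSE)
  expect_lt(max(pi_$explained), 3 * mean(pi_$explained))
  expect_error(pca_covariance(make_trajectory(pose, 2, seed = 1)),
               "3 frames")
})

test_that("free-energy landscapes invert histograms with G_min = 0", {
  # uniform occupancy -> flat landscape at exactly zero
  g <- expand.grid(x = 1:4, y = 1:4)
  fel <- free_energy_landscape(as.matrix(g), bins = 4)
  expect_true(all(abs(fel$G) < 1e-12))
  # two occupied bins at P = 0.8 / 0.2 and 300 K
  pts <- cbind(c(rep(0, 80), rep(1, 20)), 0.5)
  fel2 <- free_energy_landscape(pts, bins = 2, temperature = 300)
  occ <- sort(unique(as.vector(fel2$G[fel2$counts > 0])))
  expect_equal(occ[1], 0)
  expect_equal(occ[2], 0.0019872 * 300 * log(4), tolerance = 1e-9)
  expect_equal(occ[2], 0.8265, tolerance = 1e-3)
  # unimodal Gaussian sampling: single global minimum at the mode bin
  set.seed(10)
  pts3 <- cbind(rnorm(4000), rnorm(4000))
  fel3 <- free_energy_landscape(pts3, bins = 16)
  minidx <- which(fel3$G == 0, arr.ind = TRUE)
  expect_identical(nrow(minidx), 1L)
  expect_identical(unname(which.max(fel3$counts)),
                   unname(which.min(fel3$G)))
  expect_lt(abs(fel3$x[minidx[1]]), 0.5)
  expect_lt(abs(fel3$y[minidx[2]]), 0.5)
  # empty bins carry the finite cap
  expect_true(all(is.finite(fel3$G)))
  expect_error(free_energy_landscape(pts3, bins = 0), "bin")
})

test_that("trajectory analytics are invariant to a global rigid motion", {
  cx <- make_toy_complex(10, 5, seed = 12)
  tr <- make_trajectory(cx, 25, wobble_sd = 0.4, seed = 13)
  set.seed(14)
  R <- proper_rotation(); t <- rnorm(3, sd = 15)
  moved <- tr
  moved$frames <- lapply(tr$frames, function(f)
    sweep(f %*% R, 2, t, "+"))
  expect_equal(rmsd_series(moved), rmsd_series(tr), tolerance = 1e-8)
  expect_equal(rmsf(moved), rmsf(tr), tolerance = 1e-8)
  ga <- select_receptor(tr); gb <- select_ligand(tr)
  expect_equal(min_distance_series(moved, ga, gb),
               min_distance_series(tr, ga, gb), tolerance = 1e-9)
  expect_identical(contact_count_series(moved, ga, gb),
                   contact_count_series(tr, ga, gb))
})
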