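test_that("feature perception applies the documented rules", {
  benz <- generate_conformers(
    molecules_from_smiles(c(benzene = "c1ccccc1"))[[1]], seed = 1)
  fp <- perceive_features(benz)
  expect_identical(nrow(fp[fp$kind == "aromatic", ]), 1L)
  ring_centroid <- colMeans(conformer(benz)[1:6, ])
  expect_equal(unlist(fp[fp$kind == "aromatic", c("x", "y", "z")]),
               ring_centroid, ignore_attr = TRUE, tolerance = 1e-10)

  acetate <- generate_conformers(
    molecules_from_smiles(c(ace = "CC(=O)[O-]"))[[1]], seed = 1)
  fa <- perceive_features(acetate)
  expect_identical(nrow(fa[fa$kind == "acceptor", ]), 2L)  # both oxygens
  expect_identical(nrow(fa[fa$kind == "aromatic", ]), 0L)
  expect_identical(nrow(fa[fa$kind == "anionic", ]), 1L)

  # toluene: one ring, methyl too small for a hydrophobic group
  tol <- generate_conformers(
    molecules_from_smiles(c(tol = "Cc1ccccc1"))[[1]], seed = 1)
  ft <- perceive_features(tol)
  expect_identical(nrow(ft[ft$kind == "aromatic", ]), 1L)
  expect_identical(nrow(ft[ft$kind == "hydrophobic", ]), 0L)

  hex <- generate_conformers(
    molecules_from_smiles(c(hex = "CCCCCC"))[[1]], seed = 1)
  expect_identical(
    nrow(perceive_features(hex)[perceive_features(hex)$kind ==
                                  "hydrophobic", ]), 1L)
})

test_that("models built from a reference pose self-match with zero deviation", {
  pts <- pharmfunnel:::.reference_feature_points()
  cloud <- feature_cloud("ref", pts[, c("kind", "x", "y", "z")])
  model <- build_model_from_reference(
    cloud, picks = lapply(seq_len(5), function(i)
      list(kind = pts$kind[i], point = i, label = pts$label[i])),
    min_required = 4)
  expect_identical(sum(!is.na(model$distances)) / 2, 10)  # C(5,2) pairs
  m <- match_pharmacophore(model, cloud)
  expect_identical(m$matched_count, 5L)
  expect_lt(m$deviation, 1e-10)

  # two coincident picks are degenerate
  bad <- pts; bad[2, c("x", "y", "z")] <- bad[1, c("x", "y", "z")]
  badcloud <- feature_cloud("bad", bad[, c("kind", "x", "y", "z")])
  expect_error(build_model_from_reference(
    badcloud, picks = list(list(kind = bad$kind[1], point = 1),
                           list(kind = bad$kind[2], point = 2))),
    "degenerate")
})

test_that("backtracking matcher agrees with exhaustive enumeration", {
  model <- default_pharm_model()
  kinds <- unique(model$features$kind)
  set.seed(4711)
  n_checked <- 0L
  for (rep in seq_len(200)) {
    pts <- random_match_instance(model, kinds)
    got <- pharmfunnel:::match_points(model, pts)
    want <- exhaustive_match(model, pts)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_identical(got$matched_count, want$matched_count)
      expect_equal(got$weight_sum, want$weight_sum)
      expect_equal(got$deviation, want$deviation, tolerance = 1e-10)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 10L)  # the case mix must include real matches
})

test_that("matching is invariant under rigid motion of the conformer", {
  model <- default_pharm_model()
  lib <- make_feature_library(5, 5, model, geometric_noise_sd = 0.3,
                              seed = 77)
  set.seed(99)
  for (cd in lib$clouds) {
    base <- match_pharmacophore(model, cd)
    R <- proper_rotation()
    t <- rnorm(3, sd = 20)
    moved <- cd
    moved$points[, c("x", "y", "z")] <-
      sweep(as.matrix(cd$points[, c("x", "y", "z")]) %*% R, 2, t, "+")
    got <- match_pharmacophore(model, moved)
    if (is.null(base)) expect_null(got)
    else {
      expect_identical(got$matched_count, base$matched_count)
      expect_equal(got$deviation, base$deviation, tolerance = 1e-8)
    }
  }
})

test_that("enlarging the tolerance never loses matched features", {
  kinds <- unique(default_pharm_model()$features$kind)
  set.seed(31415)
  taus <- c(0.05, 0.1, 0.15, 0.2, 0.25)
  for (rep in seq_len(30)) {
    pts <- random_cloud(sample(5:8, 1), kinds)
    counts <- vapply(taus, function(tau) {
      m <- pharmfunnel:::match_points(
        default_pharm_model(tolerance = tau, min_required = 2), pts)
      if (is.null(m)) 0L else m$matched_count
    }, integer(1))
    expect_true(all(diff(counts) >= 0L))
  }
})

test_that("library screening separates planted actives from decoys", {
  model <- default_pharm_model()
  lib <- make_feature_library(10, 90, model, geometric_noise_sd = 0,
                              seed = 5)
  hits <- screen_library(model, lib$clouds)
  expect_identical(nrow(hits), 10L)
  expect_setequal(hits$id, lib$labels$id[lib$labels$is_active])
  expect_equal(attr(hits, "hit_fraction"), 0.10)
  # hits sorted by score descending, ties by id
  expect_true(all(diff(hits$score) <= 1e-12))
  expect_error(screen_library(model, list()), "empty")
})

test_that("model YAML config round trips", {
  model <- default_pharm_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(model, path)
  back <- read_model_yaml(path)
  expect_identical(back$features$kind, model$features$kind)
  expect_identical(back$min_required, model$min_required)
  expect_equal(back$distances, model$distances, tolerance = 1e-5,
               ignore_attr = TRUE)
})
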