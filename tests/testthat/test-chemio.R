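test_that("SDF round trip preserves atom counts, bond counts and property keys", {
  mols <- molecules_from_smiles(
    c(a = "c1ccccc1", b = "OC(=O)Cc1ccc(-c2ccccc2)cc1", c = "CCNCCO"))
  for (i in seq_along(mols))
    mols[[i]]$properties$batch <- sprintf("lot%d", i)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, path)
  back <- read_sdf(path)
  expect_length(back, 3L)
  expect_identical(attr(back, "n_skipped"), 0L)
  for (i in seq_along(mols)) {
    expect_equal(nrow(back[[i]]$atoms), nrow(mols[[i]]$atoms))
    expect_equal(nrow(back[[i]]$bonds), nrow(mols[[i]]$bonds))
    expect_true("batch" %in% names(back[[i]]$properties))
  }
})

test_that("malformed SDF records are skipped and counted, not raised", {
  mols <- molecules_from_smiles(c(a = "CCO", b = "CCC", c = "CCN"))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, path)
  lines <- readLines(path)
  ends <- grep("^\\${4}", lines)
  # truncate the middle record's atom block
  rec2 <- (ends[1] + 1L):(ends[2])
  lines <- c(lines[1:(ends[1])], lines[rec2[1:4]], "$$$$",
             lines[(ends[2] + 1L):length(lines)])
  writeLines(lines, path)
  expect_warning(back <- read_sdf(path), "skipped")
  expect_length(back, 2L)
  expect_identical(attr(back, "n_skipped"), 1L)
})

test_that("V3000 records and empty libraries are rejected with clear errors", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("m", "", "", "  0  0  0  0  0  0  0  0  0  0999 V3000",
               "$$$$"), path)
  expect_error(read_sdf(path), "V3000")
  writeLines(c("garbage", "$$$$"), path)
  expect_error(suppressWarnings(read_sdf(path)), "no parseable")
})

test_that("SMILES table reader parses valid rows and counts bad ones", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles", "benzene,c1ccccc1", "bad,xx((",
               "ethanol,CCO"), path)
  expect_warning(mols <- read_smiles_table(path), "skipped")
  expect_length(mols, 2L)
  expect_identical(attr(mols, "n_skipped"), 1L)
  benz <- mols[[1]]
  expect_identical(benz$id, "benzene")
  expect_length(pharmfunnel:::aromatic_atoms(benz), 6L)
  expect_error(read_smiles_table(path, smiles_column = "smi"), "not found")
})

test_that("conformer generation is seeded, deduplicated and 3D", {
  benz <- molecules_from_smiles(c(benzene = "c1ccccc1"))[[1]]
  benz <- generate_conformers(benz, seed = 7)
  expect_length(benz$conformers, 1L)  # rigid ring: one conformation
  flex <- molecules_from_smiles(c(f = "OC(=O)CCCCCCc1ccccc1"))[[1]]
  f1 <- generate_conformers(flex, max_conformers = 3, seed = 7)
  f2 <- generate_conformers(flex, max_conformers = 3, seed = 7)
  expect_identical(f1$conformers, f2$conformers)  # determinism contract
  expect_lte(length(f1$conformers), 3L)
  expect_gte(length(f1$conformers), 2L)
  hv <- heavy_atoms(f1)
  for (i in seq_along(f1$conformers)) for (j in seq_len(i - 1L))
    expect_gt(pharmfunnel:::conf_rmsd_refl(
      f1$conformers[[i]][hv, ], f1$conformers[[j]][hv, ]), 0.5)
})

test_that("multi-model PDB trajectories round trip at PDB precision", {
  cx <- make_toy_complex(12, 5, seed = 3)
  traj <- make_trajectory(cx, n_frames = 20, wobble_sd = 0.4, seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, path)
  back <- read_trajectory(path)
  expect_identical(length(back$frames), 20L)
  expect_identical(nrow(back$atoms), nrow(traj$atoms))
  for (f in c(1L, 10L, 20L))
    expect_equal(back$frames[[f]], traj$frames[[f]], tolerance = 1e-3)
})

test_that("single-model PDB reads as a structure, XYZ as a trajectory", {
  cx <- make_toy_complex(8, 4, seed = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(cx, path)
  s <- read_structure(path)
  expect_s3_class(s, "structure3d")
  expect_identical(nrow(s$atoms), 12L)
  expect_identical(sum(s$atoms$is_ligand), 4L)

  xyz <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "frame 1", "C 0.0 0.0 0.0", "O 1.2 0.0 0.0",
               "2", "frame 2", "C 0.1 0.0 0.0", "O 1.3 0.0 0.0"), xyz)
  tr <- read_trajectory(xyz)
  expect_identical(length(tr$frames), 2L)
  expect_equal(tr$frames[[2]][2, 1], 1.3)
  # inconsistent frames must fail loudly
  writeLines(c("2", "f", "C 0 0 0", "O 1 0 0",
               "2", "f", "O 0 0 0", "C 1 0 0"), xyz)
  expect_error(read_trajectory(xyz), "inconsistent")
})
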