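test_that("ledger assembly reproduces the published component sums", {
  m1 <- assemble_ledger(-65.71, -46.92, 59.63, -10.30, id = "1")
  expect_equal(m1$ggas, -112.63)
  ctrl <- assemble_ledger(-53.54, -23.06, 41.58, -7.43, id = "Control")
  expect_equal(ctrl$total, -42.45)
  z <- assemble_ledger(0, 0, 0, 0)
  expect_equal(unlist(z[, c("ggas", "gsolv", "total")]),
               c(ggas = 0, gsolv = 0, total = 0))
  expect_error(assemble_ledger(NA, 0, 0, 0), "finite")
})

test_that("published ledger rows pass verification except the misprinted one", {
  tab <- mmpbsa_fixture()
  v <- verify_ledger(tab)
  # compound 3's published row is internally inconsistent (its GGAS cell
  # does not equal vdw + eel by ~19 kcal/mol); the verifier must flag it
  # and pass every other row within two-decimal rounding
  expect_true(all(v$pass[v$id != "3"]))
  expect_false(v$pass[v$id == "3"])
  expect_gt(v$r_ggas[v$id == "3"], 15)
  # compound 1's printed GSOLV differs from its components by rounding
  expect_equal(v$r_gsolv[v$id == "1"], 0.01, tolerance = 1e-9)
  expect_equal(v$max_residual[v$id == "Control"], 0, tolerance = 1e-9)
  broken <- tab[1, ]; broken$total <- broken$total + 1
  expect_false(verify_ledger(broken)$pass)
})

test_that("ledgers assembled in-package satisfy the identities exactly", {
  set.seed(20)
  for (rep in 1:20) {
    l <- assemble_ledger(rnorm(1, -50, 10), rnorm(1, -20, 10),
                         rnorm(1, 40, 10), rnorm(1, -8, 2))
    expect_equal(verify_ledger(l, tol = 1e-12)$max_residual, 0,
                 tolerance = 1e-12)
  }
})

test_that("LJ and Coulomb terms hit their analytic anchors", {
  mk_pair <- function(r) {
    s <- structure3d(data.frame(
      chain = c("A", "B"), resno = 1:2, resname = c("REC", "LIG"),
      name = c("X1", "X2"), element = "C",
      x = c(0, r), y = 0, z = 0, is_ligand = c(FALSE, TRUE)))
    s$atoms$sigma <- 3.4; s$atoms$eps <- 0.1; s$atoms$charge <- 1
    attr(s, "ff") <- toy_forcefield(eps_r = 1)
    s
  }
  expect_equal(lj_energy(mk_pair(3.4)), 0, tolerance = 1e-12)
  expect_equal(lj_energy(mk_pair(2^(1 / 6) * 3.4)), -0.1,
               tolerance = 1e-12)
  # unit charges 1 A apart in vacuum: the Coulomb constant itself
  expect_equal(coulomb_energy(mk_pair(1)), 332.0637, tolerance = 1e-10)
  expect_equal(coulomb_energy(mk_pair(1), eps_r = 4), 332.0637 / 4)
  expect_error(lj_energy(mk_pair(0)), "overlap")
  cx <- make_toy_complex(20, 10, seed = 30)
  expect_equal(lj_energy(cx), brute_lj(cx), tolerance = 1e-10)
  expect_equal(coulomb_energy(cx), brute_coulomb(cx), tolerance = 1e-10)
})

test_that("Born single-ion closed form behaves as the ingestion oracle", {
  # neutral species costs nothing; vacuum solvent costs nothing
  expect_equal(born_ion_energy(0, 2), 0)
  expect_equal(born_ion_energy(1, 2, eps_r = 1), 0)
  e <- born_ion_energy(1, 2, eps_r = 78.5)
  expect_equal(e, -166.03185 / 2 * (1 - 1 / 78.5), tolerance = 1e-6)
  expect_lt(e, 0)
})

test_that("Shrake-Rupley SASA matches sphere geometry", {
  one <- sasa(matrix(0, 1, 3), "C")
  expect_equal(one$total, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.01)
  # two coincident atoms expose a single sphere (within sampling error)
  two <- sasa(matrix(0, 2, 3), c("C", "C"))
  expect_equal(two$total, one$total, tolerance = 0.02 * one$total)
  # a buried atom in a closed cage has (near) zero exposure
  cage <- rbind(c(0, 0, 0), 2.2 * pharmfunnel:::sphere_points(60))
  buried <- sasa(cage, rep("C", 61))
  expect_lt(buried$per_atom[1], 1)
  # convergence: doubling the point count barely moves the total
  lo <- sasa(cage, rep("C", 61), n_points = 480)
  hi <- sasa(cage, rep("C", 61), n_points = 960)
  expect_lt(abs(hi$total - lo$total) / hi$total, 0.005)
  expect_error(sasa(matrix(0, 1, 3), "Xx"), "radius")
  # esurf = gamma * SASA + beta with the community default gamma
  expect_equal(esurf_energy(1000), 7.2)
})

test_that("control-relative ranking recovers the published subset", {
  tab <- mmpbsa_fixture()
  ctrl <- tab[tab$id == "Control", ]
  cands <- tab[tab$id != "Control", ]
  rk <- rank_against_control(cands, ctrl)
  expect_setequal(rk$better_than_control, c("1", "3", "4", "5", "6", "10"))
  expect_identical(rk$ranked$id[1], "1")  # strongest binder first
  expect_equal(rk$control_total, -42.45)
  # control against itself: nothing strictly better
  expect_length(rank_against_control(ctrl, ctrl)$better_than_control, 0L)
  ties <- rbind(assemble_ledger(-10, 0, 0, 0, id = "b"),
                assemble_ledger(-10, 0, 0, 0, id = "a"))
  expect_identical(rank_against_control(ties, ctrl)$ranked$id,
                   c("a", "b"))
})

test_that("ledger CSV ingestion recomputes missing sums", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = "x", vdw = -10, eel = -5, egb = 8,
                       esurf = -2), path, row.names = FALSE)
  led <- read_ledger_csv(path)
  expect_equal(led$total, -9)
  expect_true(verify_ledger(led)$pass)
  write.csv(data.frame(id = "x", vdw = -10), path, row.names = FALSE)
  expect_error(read_ledger_csv(path), "columns")
})
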