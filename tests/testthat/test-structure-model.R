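test_that("center of mass follows the mass-weighted mean, in nm", {
  m <- make_structure(c("X1", "X2"), c("H", "H"), "GLY", "A", c(1, 1),
                      rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(center_of_mass(m, "A"), c(0.1, 0, 0))

  single <- make_structure("CA", "C", "GLY", "A", 1, rbind(c(3, -2, 7)))
  expect_equal(center_of_mass(single, "A"), c(0.3, -0.2, 0.7))

  # unequal masses: independent hand arithmetic oracle
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 2, 0))
  m3 <- make_structure(c("C1", "N1", "O1"), c("C", "N", "O"), "GLY", "A",
                       c(1, 1, 1), xyz)
  w <- c(12.011, 14.007, 15.999)
  manual <- c(w %*% xyz) / sum(w) / 10
  expect_equal(center_of_mass(m3, "A"), manual, tolerance = 1e-12)
  expect_error(center_of_mass(m3, "Z"), "not found")
})

test_that("COM distance is symmetric, translation-invariant, and exact on a translated copy", {
  xyz <- rbind(c(0, 0, 0), c(1, 2, 0), c(40.1, 0, 0), c(41.1, 2, 0))
  m <- make_structure(c("CA", "CB", "CA", "CB"), "C", "GLY",
                      c("A", "A", "B", "B"), c(1, 1, 2, 2), xyz)
  expect_equal(com_distance(m, "A", "B"), 4.01)
  expect_equal(com_distance(m, "B", "A"), com_distance(m, "A", "B"))
  shifted <- make_structure(c("CA", "CB", "CA", "CB"), "C", "GLY",
                            c("A", "A", "B", "B"), c(1, 1, 2, 2),
                            sweep(xyz, 2, c(5, -3, 11), "+"))
  expect_equal(com_distance(shifted, "A", "B"), 4.01)

  same <- make_structure(c("CA", "CA"), "C", "GLY", c("A", "B"), c(1, 2),
                         rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(com_distance(same, "A", "B"), 0)
})

test_that("RMSD matches its closed forms and is invariant under rigid motion", {
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(1, 1, 2), c(-2, 1, 0))
  displaced <- xyz
  displaced[3, ] <- displaced[3, ] + c(0, 0, 5)  # 0.5 nm
  expect_equal(rmsd_xyz(xyz, xyz, fit = FALSE), 0)
  expect_equal(rmsd_xyz(xyz, displaced, fit = FALSE), sqrt(25 / 5) / 10,
               tolerance = 1e-12)

  set.seed(11)
  for (rep in 1:5) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- stats::runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    moved <- xyz %*% t(R) + matrix(stats::rnorm(3, sd = 5), 5, 3, byrow = TRUE)
    expect_lt(rmsd_xyz(xyz, moved, fit = TRUE), 1e-10)
    expect_gt(rmsd_xyz(xyz, moved, fit = FALSE), 0.01)
  }
  expect_error(rmsd_xyz(xyz, xyz[1:3, ]), "shape mismatch")
})

test_that("degenerate selections fall back to no-fit RMSD with a warning", {
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_warning(r <- rmsd_xyz(two, two + 1, fit = TRUE), "degenerate")
  expect_equal(r, sqrt(3) / 10, tolerance = 1e-12)
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_warning(rmsd_xyz(collinear, collinear + 0.5, fit = TRUE),
                 "degenerate")
})

test_that("PDB reading parses fixtures, flags HETATM, and reports malformed lines", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(tiny_pdb_lines(), f)
  m <- read_pdb(f)
  expect_equal(nrow(m$atoms), 4L)
  expect_equal(chains(m), c("A", "B"))

  bad <- tiny_pdb_lines()
  bad[3] <- "ATOM      3  CA  GLY B   2      10.000   x.000   0.000  1.00  0.00           C"
  writeLines(bad, f)
  expect_error(read_pdb(f), "line 3")

  writeLines(c("REMARK none", "HETATM    1 ZN    ZN A 301       0.000   0.000   0.000  1.00  0.00          ZN"),
              f)
  expect_error(read_pdb(f), "no ATOM records")
})

test_that("write_pdb -> read_pdb round-trips atoms, chains, coordinates and frames", {
  m <- build_sod_like_dimer()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  m2 <- read_pdb(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(m2$atoms$name, m$atoms$name)
  expect_equal(m2$atoms$chain, m$atoms$chain)
  expect_equal(sum(m2$atoms$het), sum(m$atoms$het))
  expect_lt(max(abs(m2$xyz - m$xyz)), 1e-3 + 1e-9)

  traj <- dissociation_trajectory(m, n_frames = 4)
  write_pdb(traj, f)
  t2 <- read_pdb(f)
  expect_equal(n_frames(t2), 4L)
  expect_lt(max(abs(t2$xyz - traj$xyz)), 1e-3 + 1e-9)
})

test_that("alternate locations keep the highest-occupancy record", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  O   GLY A   1       1.500   0.000   0.000  1.00  0.00           O"),
    f)
  m <- read_pdb(f)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$xyz[1, m$atoms$name == "CA", 1], 2.0)
})

test_that("residue labels round-trip and unknown elements default to carbon", {
  lab <- residue_label("ILE", 149, "A")
  expect_equal(lab, "Ile149A")
  p <- parse_residue_label(c("Ile149A", "Gly49B"))
  expect_equal(p$resid, c("ILE", "GLY"))
  expect_equal(p$resno, c(149L, 49L))
  expect_equal(p$chain, c("A", "B"))
  expect_error(parse_residue_label("bogus"), "unparseable")
  expect_warning(mm <- atomic_mass("Xx"), "unknown element")
  expect_equal(mm, 12.011)
})

test_that("the synthetic dissociation trajectory spans 2.82 to 6.83 nm monotonically", {
  m <- build_sod_like_dimer()
  expect_equal(com_distance(m, "A", "B"), 2.82, tolerance = 1e-9)
  traj <- dissociation_trajectory(m, n_frames = 12)
  prof <- com_distance_profile(traj)
  expect_equal(prof[1], 2.82, tolerance = 1e-9)
  expect_equal(prof[12], 6.83, tolerance = 1e-9)
  expect_true(all(diff(prof) > 0))
  r <- rmsd_profile(traj, selection = "all", fit = FALSE)
  expect_equal(r[1], 0)
  expect_true(all(diff(r) > 0))
})
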