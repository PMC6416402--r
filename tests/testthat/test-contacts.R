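# Hand-built two-residue fixtures with controlled geometry.
hb_fixture <- function(no_dist) {
  make_structure(
    name = c("N", "CA", "C", "O", "N", "CA", "C", "O"),
    element = c("N", "C", "C", "O", "N", "C", "C", "O"),
    resid = "GLY", chain = rep(c("A", "B"), each = 4),
    resno = rep(c(10, 20), each = 4),
    xyz = rbind(c(-8, 0, 0), c(-6, 0, 0), c(-5, 1, 0), c(0, 0, 0),
                c(no_dist, 0, 0), c(no_dist + 2, 0, 0),
                c(no_dist + 3, 1, 0), c(no_dist + 5, 0, 0)))
}

test_that("hydrogen bonds respect the donor-acceptor distance criterion", {
  hit <- detect_hydrogen_bonds(hb_fixture(2.9))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$atom_a, "O"); expect_equal(hit$atom_b, "N")
  expect_equal(hit$distance, 2.9)
  expect_equal(hit$residue_a, "Gly10A"); expect_equal(hit$residue_b, "Gly20B")
  expect_equal(nrow(detect_hydrogen_bonds(hb_fixture(4.0))), 0L)
})

phobic_fixture <- function(d) {
  make_structure(
    name = c("CB", "CB"), element = "C", resid = "ALA",
    chain = c("A", "B"), resno = c(1, 2),
    xyz = rbind(c(0, 0, 0), c(d, 0, 0)))
}

test_that("hydrophobic contacts respect the apolar cutoff and collapse to residue pairs", {
  hit <- detect_hydrophobic_contacts(phobic_fixture(3.5))
  expect_equal(nrow(hit), 1L)
  expect_equal(nrow(detect_hydrophobic_contacts(phobic_fixture(4.5))), 0L)

  # 3 atom contacts within one residue pair
  m <- make_structure(
    name = c("CB", "CG1", "CB", "CG1"), element = "C", resid = "VAL",
    chain = c("A", "A", "B", "B"), resno = c(1, 1, 2, 2),
    xyz = rbind(c(0, 0, 0), c(0, 1, 0), c(3.5, 0, 0), c(3.5, 2.2, 0)))
  hit <- detect_hydrophobic_contacts(m)
  oracle <- brute_hydrophobic(m)
  expect_equal(nrow(hit), oracle$n_atom)
  expect_equal(nrow(hit), 3L)
  expect_equal(length(unique(paste(hit$residue_a, hit$residue_b))), 1L)
})

salt_fixture <- function(dz) {
  make_structure(
    name = c("CB", "CG", "OD1", "OD2", "CE", "NZ"),
    element = c("C", "C", "O", "O", "C", "N"),
    resid = c(rep("ASP", 4), rep("LYS", 2)),
    chain = c(rep("A", 4), rep("B", 2)), resno = c(rep(11, 4), rep(9, 2)),
    xyz = rbind(c(0, 0, -2), c(0, 0, -1), c(0.8, 0, 0), c(-0.8, 0, 0),
                c(0, 0, dz + 1.2), c(0, 0, dz)))
}

test_that("salt bridges use charged-group centroids against the 0.6 nm cutoff", {
  hit <- detect_salt_bridges(salt_fixture(3.5))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$distance, 3.5)  # OD centroid at z=0, NZ at z=3.5
  expect_equal(nrow(detect_salt_bridges(salt_fixture(6.5))), 0L)
  expect_equal(nrow(detect_salt_bridges(salt_fixture(6.5), cutoff_nm = 0.7)), 1L)
  # missing side-chain atoms are skipped with a warning
  broken <- make_structure(
    name = c("CB", "NZ"), element = c("C", "N"), resid = c("ASP", "LYS"),
    chain = c("A", "B"), resno = c(11, 9),
    xyz = rbind(c(0, 0, 0), c(0, 0, 3)))
  expect_warning(res <- detect_salt_bridges(broken), "skipped")
  expect_equal(nrow(res), 0L)
})

test_that("the census composes the detectors and counts consistently", {
  far <- make_structure(c("CA", "CA"), "C", "GLY", c("A", "B"), c(1, 2),
                        rbind(c(0, 0, 0), c(50, 0, 0)))
  cen <- interface_census(far)
  expect_equal(cen$n_hbond_pairs, 0L)
  expect_equal(cen$n_hydrophobic_atom_contacts, 0L)
  expect_equal(cen$n_salt_bridges, 0L)

  cen <- interface_census(build_sod_like_dimer())
  hb <- cen$contacts[cen$contacts$kind == "hydrogen_bond", ]
  expect_equal(cen$n_hbond_pairs,
               length(unique(pair_key(paste(hb$residue_a, hb$residue_b,
                                            sep = "-")))))
  ph <- cen$contacts[cen$contacts$kind == "hydrophobic", ]
  expect_equal(cen$n_hydrophobic_atom_contacts, nrow(ph))
  expect_equal(cen$n_hydrophobic_residue_pairs,
               length(unique(paste(ph$residue_a, ph$residue_b))))
})

test_that("census is invariant under rigid transforms and chain swap", {
  m <- build_sod_like_dimer()
  cen <- interface_census(m)
  th <- 0.7; R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- matrix(m$xyz[1, , ], ncol = 3) %*% R + matrix(c(3, -7, 2), nrow(m$atoms), 3, byrow = TRUE)
  m2 <- structure_model(m$atoms, xyz)
  cen2 <- interface_census(m2)
  expect_equal(cen2$n_hbond_pairs, cen$n_hbond_pairs)
  expect_equal(cen2$n_hydrophobic_atom_contacts, cen$n_hydrophobic_atom_contacts)
  expect_equal(cen2$n_hydrophobic_residue_pairs, cen$n_hydrophobic_residue_pairs)

  swapped <- interface_census(m, chain_a = "B", chain_b = "A")
  expect_equal(swapped$n_hbond_pairs, cen$n_hbond_pairs)
  expect_equal(swapped$n_hydrophobic_atom_contacts,
               cen$n_hydrophobic_atom_contacts)
  expect_setequal(pair_key(swapped$hydrophobic_pairs),
                  pair_key(cen$hydrophobic_pairs))
})

test_that("enlarging a cutoff never decreases the corresponding count", {
  m <- build_sod_like_dimer()
  counts <- vapply(c(3.4, 3.9, 4.4, 5.0), function(cut)
    interface_census(m, criteria = contact_criteria(hydrophobic_max = cut))$n_hydrophobic_atom_contacts,
    integer(1))
  expect_true(all(diff(counts) >= 0))
  hb <- vapply(c(3.0, 3.35, 3.8), function(cut)
    interface_census(m, criteria = contact_criteria(hbond_da_max = cut))$n_hbond_pairs,
    integer(1))
  expect_true(all(diff(hb) >= 0))
})

test_that("the vectorized census agrees with the brute-force all-pairs oracle", {
  m <- build_sod_like_dimer()
  cen <- interface_census(m)
  oracle <- brute_hydrophobic(m)
  expect_equal(cen$n_hydrophobic_atom_contacts, oracle$n_atom)
  expect_setequal(pair_key(cen$hydrophobic_pairs), oracle$pairs)
})

test_that("hydrogen-bond criteria use H geometry when hydrogens are present", {
  base <- function(hx, hy) make_structure(
    name = c("N", "H", "CA", "O", "CA"),
    element = c("N", "H", "C", "O", "C"),
    resid = "GLY", chain = c("A", "A", "A", "B", "B"),
    resno = c(1, 1, 1, 2, 2),
    xyz = rbind(c(0, 0, 0), c(hx, hy, 0), c(-1.4, 0.6, 0),
                c(3.0, 0, 0), c(4.4, 0.6, 0)))
  # H pointing at the acceptor: accepted
  expect_equal(nrow(detect_hydrogen_bonds(base(1.0, 0))), 1L)
  # H pointing away: D-H...A angle < 90, rejected
  expect_equal(nrow(detect_hydrogen_bonds(base(-1.0, 0))), 0L)
})
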