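test_that("XVG parsing skips directives, errors usefully, and round-trips", {
  f <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("# comment", '@    xaxis  label "Time (ps)"',
               "0 -1.0", "1 -2.0", "2 -3.0"), f)
  tr <- read_xvg(f)
  expect_equal(length(tr$times), 3L)
  expect_equal(tr$values, c(-1, -2, -3))

  writeLines(c("# only", "@ comments"), f)
  expect_error(read_xvg(f), "insufficient data")

  writeLines(c("0 -1.0", "1 oops", "2 -3.0"), f)
  expect_error(read_xvg(f), "line 2")

  ts <- generate_traceset(seed = 5)
  p <- names(ts$coul)[3]
  write_xvg(ts$coul[[p]], f)
  back <- read_xvg(f)
  expect_equal(back$pair, p)
  expect_equal(back$component, "coul_sr")
  expect_lt(max(abs(back$values - ts$coul[[p]]$values)), 1e-9)
  expect_lt(max(abs(back$times - ts$coul[[p]]$times)), 1e-9)
})

test_that("average_energy takes plain and windowed means", {
  tr <- energy_trace(0:99, rep(-14.42, 100))
  expect_equal(average_energy(tr), -14.42)
  expect_equal(average_energy(energy_trace(1:3, c(-1, -2, -3))), -2)
  expect_equal(average_energy(tr, window = c(10, 20)), -14.42)
  expect_error(average_energy(tr, window = c(500, 600)), "no samples")

  # mean recovery from an OU-noise trace that never ruptures
  b <- bond_spec("Arg113A-Ile149B", -5.85, 0.15, 1L, 0.3)
  ts <- generate_traceset(b, epochs = c(5000, 6000), seed = 3)
  est <- average_energy(ts$total[["Arg113A-Ile149B"]])
  se <- 0.2 * 5.85 * sqrt(2 * 1 / 600)
  expect_lt(abs(est - (-5.85)), 3 * se)
})

test_that("pair summaries reproduce the printed table rows", {
  t <- 0:59
  mk <- function(v, comp) energy_trace(t, rep(v, 60), "Ile149A-Gly49B", comp)
  s <- summarize_pair(mk(-14.42, "coul_sr"), mk(-1.66, "lj_sr"),
                      "hydrogen_bond")
  expect_equal(s$electrostatic_kJ_mol, -14.42)
  expect_equal(s$vdw_kJ_mol, -1.66)
  expect_equal(s$total_kJ_mol, -16.08)

  z <- summarize_pair(energy_trace(t, rep(0, 60), "p"),
                      energy_trace(t, rep(0, 60), "p"), "hydrophobic")
  expect_equal(unlist(z[, 3:5]), c(electrostatic_kJ_mol = 0,
                                   vdw_kJ_mol = 0, total_kJ_mol = 0))

  s2 <- summarize_pair(
    energy_trace(t, rep(-1.01, 60), "Arg113A-Ile149B", "coul_sr"),
    energy_trace(t, rep(-5.85, 60), "Arg113A-Ile149B", "lj_sr"),
    "hydrophobic")
  expect_equal(s2$total_kJ_mol, -6.86)

  expect_error(summarize_pair(mk(-1, "coul_sr"),
                              energy_trace(t, rep(-1, 60), "Other-Pair"),
                              "hydrophobic"),
               "pair mismatch")
})

test_that("mismatched grids join by nearest time within tolerance", {
  a <- energy_trace(seq(0, 10, by = 1), rep(-2, 11), "p", "coul_sr")
  b <- energy_trace(seq(0.2, 10.2, by = 1), rep(-4, 11), "p", "lj_sr")
  s <- summarize_pair(a, b, "hydrophobic")
  expect_equal(s$total_kJ_mol, -6)
  c2 <- energy_trace(c(0, 3, 7, 10), rep(-4, 4), "p", "lj_sr")
  expect_error(summarize_pair(a, c2, "hydrophobic"), "tolerance")
})

test_that("table aggregation reproduces the published totals", {
  t1 <- aggregate_table(sod_energy_table(1))
  expect_equal(unname(t1$totals), c(-49.57, -8.12, -57.69), tolerance = 1e-9)
  t2 <- aggregate_table(sod_energy_table(2))
  expect_equal(unname(t2$totals["total"]), -87.65, tolerance = 1e-9)
  expect_equal(unname(t2$totals["electrostatic"]), -13.55, tolerance = 1e-9)
  expect_equal(unname(aggregate_table(NULL)$totals), c(0, 0, 0))

  # row identity and column-consistency invariants across all 29 rows
  both <- sod_energy_table("both")
  expect_equal(nrow(both), 29L)
  expect_true(all(abs(both$electrostatic_kJ_mol + both$vdw_kJ_mol -
                        both$total_kJ_mol) <= 0.015))
})

test_that("aggregation is permutation-invariant and additive", {
  both <- sod_energy_table("both")
  set.seed(4)
  perm <- both[sample(nrow(both)), ]
  expect_equal(aggregate_table(perm)$totals, aggregate_table(both)$totals)
  idx <- sample(c(TRUE, FALSE), nrow(both), replace = TRUE)
  expect_equal(
    aggregate_table(both[idx, ])$totals + aggregate_table(both[!idx, ])$totals,
    aggregate_table(both)$totals)
})

test_that("dominant component follows magnitude with ties to vdW", {
  row <- function(el, vd) data.frame(electrostatic_kJ_mol = el,
                                     vdw_kJ_mol = vd)
  expect_equal(dominant_component(row(-1.01, -5.85))$component, "vdw")
  expect_equal(dominant_component(row(-14.42, -1.66))$component,
               "electrostatic")
  tie <- dominant_component(row(-2, -2))
  expect_equal(tie$component, "vdw")
  expect_true(tie$tie)

  # vdW dominates most hydrophobic pairs in the packaged table
  t2 <- sod_energy_table(2)
  dom <- vapply(seq_len(nrow(t2)), function(i)
    dominant_component(t2[i, ])$component, "")
  expect_gt(mean(dom == "vdw"), 0.8)
})
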