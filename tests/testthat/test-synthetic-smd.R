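test_that("the steering-spring force follows its closed form", {
  p <- pull_params(k = 250, v = 0.01)
  expect_equal(spring_force(p, x = p$x0, t = 0), 0)
  expect_equal(spring_force(p, x = p$x0 + 0.1, t = 20), 25)
  p2 <- pull_params(k = 500, v = 0.01)
  expect_equal(spring_force(p2, x = p2$x0 + 0.1, t = 20),
               2 * spring_force(p, x = p$x0 + 0.1, t = 20))
  expect_error(spring_force(p, 0, t = 1e6), "duration")
})

test_that("bond specs validate and derive stiffness from depth and break point", {
  b <- bond_spec("p", -10, 0.5, 1L, 0.2)
  expect_equal(b$stiffness, 2 * 10 / 0.04)
  expect_error(bond_spec("p", 3, 0.5, 1L, 0.2), "negative")
  expect_error(bond_spec("p", -3, 0.5, 1L, -0.1), "> 0")
  d <- default_bond_specs()
  expect_equal(nrow(d), 29L)
  expect_equal(sum(d$group == 1), 8L)
  expect_equal(sum(d$group == 2), 21L)
})

test_that("the parametric generator is deterministic and honors its contract", {
  a <- generate_traceset(seed = 21)
  b <- generate_traceset(seed = 21)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c3 <- generate_traceset(seed = 22)
  expect_false(identical(a$total[[1]]$values, c3$total[[1]]$values))

  # noiseless pre-epoch means equal the table depths exactly
  nl <- generate_traceset(noise_sd_frac = 0, epoch_jitter_sd = 0, seed = 1)
  for (p in names(nl$total)[c(1, 5, 12, 29)]) {
    depth <- nl$truth$depth[nl$truth$pair == p]
    expect_equal(average_energy(nl$total[[p]], window = c(0, 150)), depth,
                 tolerance = 1e-9)
    expect_equal(average_energy(nl$coul[[p]], window = c(0, 150)),
                 depth * nl$truth$coul_frac[nl$truth$pair == p],
                 tolerance = 1e-9)
    # fully decayed by the end of the pull
    expect_lt(abs(average_energy(nl$total[[p]], window = c(560, 600))), 1e-6)
  }
  # COM separation endpoints and monotonicity
  expect_equal(nl$com$separation_nm[1], 2.82)
  expect_equal(nl$com$separation_nm[nrow(nl$com)], 6.83)
  expect_true(all(diff(nl$com$separation_nm) >= 0))
  # truth describes exactly the emitted traces
  expect_setequal(nl$truth$pair, names(nl$total))
})

test_that("trace sets round-trip through an XVG directory", {
  ts <- generate_traceset(seed = 8)
  dir <- withr::local_tempdir()
  write_traceset(ts, dir)
  expect_true(file.exists(file.path(dir, "pullf.xvg")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_traceset_dir(dir)
  expect_setequal(names(back$total), names(ts$total))
  p <- names(ts$total)[7]
  expect_lt(max(abs(back$total[[p]]$values - ts$total[[p]]$values)), 1e-8)
})

test_that("a quasi-static zero-temperature pull ruptures at the analytic force", {
  b <- bond_spec("b1", depth = -5, coul_frac = 0.5, group = 1L,
                 break_extension = 0.2)
  sim <- simulate_pull(b, pull_params(k = 250, v = 5e-4, duration = 6000,
                                      dt = 0.01),
                       friction = 100, temperature = 0, record = FALSE)
  expect_equal(sim$rupture_force, b$stiffness * b$break_extension,
               tolerance = 0.02)
})

test_that("with no bonds the pulled coordinate tracks the tether", {
  empty <- bond_spec(character(0), numeric(0), numeric(0), integer(0),
                     numeric(0))
  sim <- simulate_pull(empty, pull_params(v = 0.01, duration = 100),
                       friction = 100, temperature = 300, seed = 3,
                       record = TRUE)
  lag <- 100 * 0.01 / 250  # friction * v / k
  late <- sim$times > 20
  expect_lt(abs(mean(sim$x[late] - (0.01 * sim$times[late]))), lag + 0.02)
  thermal_sd <- 250 * sqrt(0.0083145 * 300 / 250)
  expect_lt(max(abs(sim$force)), 6 * thermal_sd)
})

test_that("the simulator enforces its step-size stability bound", {
  b <- bond_spec("stiff", -30, 0.5, 1L, 0.05)
  expect_error(simulate_pull(b, pull_params(dt = 0.5), friction = 50),
               "stability")
})

test_that("pull simulations are seed-deterministic and break group 1 first", {
  s1 <- simulate_pull(seed = 42, n_rep = 4, record = FALSE)
  s2 <- simulate_pull(seed = 42, n_rep = 4, record = FALSE)
  expect_identical(s1$rupture_force, s2$rupture_force)
  expect_identical(s1$break_times, s2$break_times)

  sims <- simulate_pull(seed = 7, n_rep = 30, record = FALSE)
  expect_true(all(!is.na(sims$break_times)))
  expect_lt(mean(sims$break_times[, "lock1"]),
            mean(sims$break_times[, "lock2"]))
  # after every bond has broken, all pair energies are zero
  rec <- simulate_pull(seed = 7, n_rep = 1, record = TRUE)
  expect_true(all(rec$energies[nrow(rec$energies), ] == 0))
  expect_true(all(rec$energies[1, ] < 0))
})

test_that("kinetic-curve generation is seeded and carries its truth", {
  a <- generate_kinetic_curve(seed = 5, noise_sd = 0.01)
  b <- generate_kinetic_curve(seed = 5, noise_sd = 0.01)
  expect_identical(a$activity, b$activity)
  tr <- attr(a, "truth")
  expect_equal(tr$R, 2)
  one <- generate_kinetic_curve(step_fractions = 1, seed = 1)
  expect_equal(attr(one, "truth")$R, 1)
  expect_true(all(diff(one$activity) <= 1e-12))
})

test_that("pipeline closure: detection on generated tracesets recovers the lock structure", {
  bench <- evaluate_lock_recovery(n_runs = 10, base_seed = 3000)
  expect_true(all(bench$n_groups == 2))
  expect_true(all(bench$accuracy >= 0.95))
  expect_true(all(abs(bench$epoch1 - 240) <= 20))
  expect_true(all(abs(bench$epoch2 - 400) <= 20))
})
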