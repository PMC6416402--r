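test_that("rupture detection finds sigmoid decays and rejects flat traces", {
  b <- bond_spec("pairX", -10, 0.5, 1L, 0.2)
  ts <- generate_traceset(b, epochs = c(240, 400), epoch_jitter_sd = 0,
                          decay_width = 10, seed = 2)
  ev <- detect_rupture(ts$total[["pairX"]])
  expect_lt(abs(ev$rupture_time - 240), 15)
  expect_lt(abs(ev$baseline_energy - (-10)), 1)
  expect_gte(ev$zero_time, ev$rupture_time)

  t <- seq(0, 600, by = 0.5)
  flat <- energy_trace(t, rep(-10, length(t)), "flat")
  ev <- detect_rupture(flat)
  expect_true(is.na(ev$rupture_time))

  zero <- energy_trace(t, rep(0, length(t)), "zero")
  expect_error(detect_rupture(zero), "never bound")
  expect_error(detect_rupture(energy_trace(0:10, rep(-5, 11))), "too short")
})

test_that("largest-gap grouping matches the brute-force split oracle", {
  times <- c(235, 241, 244, 396, 401, 404, 399)
  events <- lapply(seq_along(times), function(i)
    mk_event(paste0("p", i), times[i]))
  summ <- mk_summaries(paste0("p", seq_along(times)), rep(-2, length(times)))
  rep <- group_locks(events, summ)
  expect_equal(length(rep$groups), 2L)
  expect_equal(lengths(lapply(rep$groups, `[[`, "members")), c(3L, 4L))
  expect_equal(sort(rep$groups[[1]]$members), c("p1", "p2", "p3"))

  # property: agreement with the independent oracle on random clustered times
  set.seed(9)
  for (case in 1:25) {
    k <- sample(2:4, 1)
    centers <- sort(stats::runif(k, 0, 1000))
    tt <- unlist(lapply(centers, function(cc) cc + stats::rnorm(sample(2:5, 1), 0, 8)))
    ev <- lapply(seq_along(tt), function(i) mk_event(paste0("q", i), tt[i]))
    sm <- mk_summaries(paste0("q", seq_along(tt)), rep(-1, length(tt)))
    got <- group_locks(ev, sm)
    lab <- integer(length(tt))
    for (g in got$groups)
      lab[match(g$members, paste0("q", seq_along(tt)))] <- g$group_id
    expect_equal(lab, brute_gap_groups(tt), info = paste("case", case))
  }
})

test_that("grouping is a partition, order-free, and shift-invariant", {
  times <- c(250, 238, 405, 399, 244, 412)
  pairs <- paste0("p", 1:6)
  summ <- mk_summaries(pairs, -(1:6))
  ev <- lapply(1:6, function(i) mk_event(pairs[i], times[i]))
  rep1 <- group_locks(ev, summ)
  members <- unlist(lapply(rep1$groups, `[[`, "members"))
  expect_setequal(c(members, rep1$unassigned), pairs)
  expect_equal(length(members) + length(rep1$unassigned), length(pairs))

  rep2 <- group_locks(rev(ev), summ)
  for (g in seq_along(rep1$groups))
    expect_setequal(rep2$groups[[g]]$members, rep1$groups[[g]]$members)

  ev3 <- lapply(1:6, function(i) mk_event(pairs[i], times[i] + 137))
  rep3 <- group_locks(ev3, summ)
  for (g in seq_along(rep1$groups)) {
    expect_setequal(rep3$groups[[g]]$members, rep1$groups[[g]]$members)
    expect_equal(rep3$groups[[g]]$mean_rupture_time,
                 rep1$groups[[g]]$mean_rupture_time + 137)
  }

  single <- group_locks(list(mk_event("only", 300)),
                        mk_summaries("only", -5))
  expect_equal(length(single$groups), 1L)
  expect_equal(single$groups[[1]]$members, "only")
})

test_that("lock energies reproduce the published group totals", {
  summ <- sod_energy_table("both")
  grp <- sod_lock_groups()
  g1 <- grp$pair[grp$group == 1]
  g2 <- grp$pair[grp$group == 2]
  expect_equal(length(g1), 8L)
  expect_equal(length(g2), 21L)
  expect_equal(lock_energy(g1, summ), -30.10, tolerance = 0.005 / 30.1)
  expect_equal(lock_energy(g2, summ), -115.23, tolerance = 0.02 / 115.23)
  expect_equal(lock_energy(character(0), summ), 0)
  expect_error(lock_energy(c("Ile149A-Gly49B", "Nope1X-Nope2Y"), summ),
               "Nope1X-Nope2Y")
  # the two groups partition all pairs, so their energies sum to the tables
  expect_equal(lock_energy(g1, summ) + lock_energy(g2, summ),
               unname(aggregate_table(summ)$totals["total"]),
               tolerance = 1e-9)
})

test_that("trace-set comparison reports baseline and rupture deltas", {
  ref <- generate_traceset(seed = 11)
  cmp0 <- compare_tracesets(ref$total, ref$total)
  expect_true(all(cmp0$delta_baseline == 0))
  expect_true(all(cmp0$delta_rupture[!is.na(cmp0$delta_rupture)] == 0))

  # variant with one pair's depth halved
  bonds <- default_bond_specs()
  target <- "Ile149A-Phe48B"
  bonds$depth[bonds$pair == target] <- bonds$depth[bonds$pair == target] / 2
  var1 <- generate_traceset(bonds, seed = 11)
  cmp1 <- compare_tracesets(ref$total, var1$total)
  d <- cmp1$delta_baseline[cmp1$pair == target]
  expect_lt(abs(d - 10.02 / 2), 0.8)

  # variant with the second epoch moved 100 ps earlier
  var2 <- generate_traceset(epochs = c(240, 300), seed = 11)
  cmp2 <- compare_tracesets(ref$total, var2$total)
  g2pairs <- ref$truth$pair[ref$truth$group == 2]
  dd <- cmp2$delta_rupture[cmp2$pair %in% g2pairs]
  expect_lt(abs(mean(dd, na.rm = TRUE) + 100), 15)
  expect_gt(attr(cmp2, "summary")["earlier"], 15)
})
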