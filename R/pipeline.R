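# Full-pipeline orchestration ----------------------------------------------

#' Pipeline configuration
#'
#' Exactly one of `traces_dir` (a directory of per-pair XVG traces) or
#' `synth` (arguments for [generate_traceset()]) must be supplied; the
#' structure is either a PDB path or `"synthetic"` for the packaged
#' synthetic dimer.
#'
#' @param structure PDB path or `"synthetic"`.
#' @param traces_dir directory of `<pair>_coul.xvg` / `<pair>_lj.xvg`.
#' @param synth list of [generate_traceset()] arguments (may be empty).
#' @param criteria a [contact_criteria()].
#' @param lock a [lock_config()].
#' @param output_dir where results are written.
#' @param seed integer seed, recorded in all outputs.
#' @export
pipeline_config <- function(structure = "synthetic", traces_dir = NULL,
                            synth = list(), criteria = contact_criteria(),
                            lock = lock_config(), output_dir = "conflock_out",
                            seed = 1L) {
  if (!is.null(traces_dir) && length(synth))
    stop("config error: supply either traces_dir or synth, not both")
  if (is.null(traces_dir) && is.null(synth))
    stop("config error: one of traces_dir / synth is required")
  structure(list(structure = structure, traces_dir = traces_dir,
                 synth = synth, criteria = criteria, lock = lock,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `structure`, `traces_dir`, `synth` (mapping of
#' generator arguments), `criteria`, `lock` (mappings of threshold
#' overrides), `output_dir`, `seed`.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  crit <- do.call(contact_criteria, as.list(y$criteria))
  lk <- do.call(lock_config, as.list(y$lock))
  pipeline_config(
    structure = if (is.null(y$structure)) "synthetic" else y$structure,
    traces_dir = y$traces_dir,
    synth = if (is.null(y$synth) && !is.null(y$traces_dir)) NULL
            else as.list(y$synth),
    criteria = crit, lock = lk,
    output_dir = if (is.null(y$output_dir)) "conflock_out" else y$output_dir,
    seed = if (is.null(y$seed)) 1L else y$seed)
}

.config_fingerprint <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(config), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

.pair_kind <- function(pairs) {
  hb <- sod_energy_table(1)$pair
  ifelse(pairs %in% hb, "hydrogen_bond", "hydrophobic")
}

#' Run the full conformational-lock pipeline
#'
#' Contact census on the structure, per-pair energy summaries from the
#' traces, rupture detection, lock grouping, and a written report. The run
#' is deterministic given the configuration and seed; every output embeds
#' the seed and a configuration fingerprint. Partial outputs are removed if
#' any stage fails.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list with `census`, `summaries`, `table` (aggregate totals),
#'   `events`, `report` (lock report), `paths` of the written files.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[conflock] ", ...)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  fp <- .config_fingerprint(config)

  # stage 1: structure + census
  census <- tryCatch({
    say("stage contacts: census")
    stru <- if (identical(config$structure, "synthetic"))
      build_sod_like_dimer() else read_pdb(config$structure)
    interface_census(stru, criteria = config$criteria)
  }, error = function(e) fail("contacts", e))

  # stage 2: traces, rupture detection, bound-window summaries. Each pair
  # is averaged over its bound phase (up to shortly before its detected
  # rupture) so the summaries estimate the bound-state interaction
  # energies; pairs that never rupture are averaged over the full trace.
  res <- tryCatch({
    say("stage energies: traces, ruptures and summaries")
    tr <- if (!is.null(config$traces_dir)) {
      read_traceset_dir(config$traces_dir)
    } else {
      do.call(generate_traceset,
              c(config$synth[setdiff(names(config$synth), "seed")],
                list(seed = config$seed)))
    }
    pairs <- names(tr$total)
    kinds <- .pair_kind(pairs)
    events <- list(); failed <- character()
    for (p in pairs) {
      ev <- tryCatch(detect_rupture(tr$total[[p]], config$lock),
                     error = function(e) NULL)
      if (is.null(ev)) failed <- c(failed, p) else events[[p]] <- ev
    }
    summaries <- do.call(rbind, lapply(seq_along(pairs), function(i) {
      p <- pairs[i]
      win <- NULL
      ev <- events[[p]]
      if (!is.null(ev) && !is.na(ev$rupture_time)) {
        hi <- ev$rupture_time - 2 * config$lock$smooth_window
        t0 <- tr$total[[p]]$times[1]
        if (hi > t0) win <- c(t0, hi)
      }
      summarize_pair(tr$coul[[p]], tr$lj[[p]], kinds[i], window = win)
    }))
    list(tr = tr, summaries = summaries, events = events, failed = failed)
  }, error = function(e) fail("energies", e))

  # stage 3: lock grouping
  rep_out <- tryCatch({
    say("stage locks: grouping")
    if (!length(res$events)) stop("no pair has a measurable rupture")
    report <- group_locks(unname(res$events), res$summaries, config$lock)
    report$unassigned <- union(report$unassigned, res$failed)
    list(events = res$events, report = report)
  }, error = function(e) fail("locks", e))

  # stage 4: outputs
  paths <- tryCatch({
    say("stage report: writing outputs")
    out <- config$output_dir
    p_census <- file.path(out, "census.csv")
    write_census_csv(census, p_census); written <- c(written, p_census)
    p_sum <- file.path(out, "summary.csv")
    write_pair_summaries(res$summaries, p_sum); written <- c(written, p_sum)
    p_rupt <- file.path(out, "ruptures.csv")
    rupt <- do.call(rbind, lapply(rep_out$events, function(e)
      data.frame(pair = e$pair, baseline_kJ_mol = e$baseline_energy,
                 rupture_time_ps = e$rupture_time,
                 zero_time_ps = e$zero_time, stringsAsFactors = FALSE)))
    utils::write.csv(rupt, p_rupt, row.names = FALSE, quote = FALSE)
    written <- c(written, p_rupt)
    p_json <- file.path(out, "lock_report.json")
    tab <- aggregate_table(res$summaries)
    jsonlite::write_json(list(
      seed = config$seed, config_fingerprint = fp,
      census = list(n_hbond_pairs = census$n_hbond_pairs,
                    n_hydrophobic_atom_contacts = census$n_hydrophobic_atom_contacts,
                    n_hydrophobic_residue_pairs = census$n_hydrophobic_residue_pairs,
                    n_salt_bridges = census$n_salt_bridges),
      totals = as.list(tab$totals),
      groups = lapply(rep_out$report$groups, function(g)
        list(group_id = g$group_id, members = g$members,
             n_hbond = g$n_hbond, n_hydrophobic = g$n_hydrophobic,
             total_energy = g$total_energy,
             rupture_window = g$rupture_window,
             mean_rupture_time = g$mean_rupture_time)),
      unassigned = rep_out$report$unassigned),
      p_json, auto_unbox = TRUE, digits = 10, pretty = TRUE)
    written <- c(written, p_json)
    p_md <- file.path(out, "report.md")
    g <- rep_out$report$groups
    writeLines(c(
      "# Conformational-lock pipeline report",
      sprintf("seed: %d  |  config: %s", config$seed, fp), "",
      sprintf("- hydrogen-bond residue pairs: %d", census$n_hbond_pairs),
      sprintf("- hydrophobic residue pairs: %d (atom contacts: %d)",
              census$n_hydrophobic_residue_pairs,
              census$n_hydrophobic_atom_contacts),
      sprintf("- salt bridges: %d", census$n_salt_bridges), "",
      sprintf("- interface energy totals (kJ/mol): electrostatic %.2f, vdW %.2f, total %.2f",
              tab$totals["electrostatic"], tab$totals["vdw"],
              tab$totals["total"]), "",
      sprintf("- lock groups: %d", length(g)),
      vapply(g, function(gg) sprintf(
        "  - group %d: %d pairs (%d H-bond, %d hydrophobic), %.2f kJ/mol, ruptures near %.0f ps",
        gg$group_id, length(gg$members), gg$n_hbond, gg$n_hydrophobic,
        gg$total_energy, gg$mean_rupture_time), ""),
      if (length(rep_out$report$unassigned))
        sprintf("- unassigned pairs: %s",
                paste(rep_out$report$unassigned, collapse = ", "))
      else "- unassigned pairs: none"), p_md)
    written <- c(written, p_md)
    c(census = p_census, summary = p_sum, ruptures = p_rupt,
      lock_report = p_json, report = p_md)
  }, error = function(e) fail("report", e))

  list(census = census, summaries = res$summaries,
       table = aggregate_table(res$summaries), events = rep_out$events,
       report = rep_out$report, paths = paths, seed = config$seed,
       fingerprint = fp)
}

#' Lock-recovery benchmark on seeded synthetic trace sets
#'
#' Generates `n_runs` parametric trace sets (seeds `base_seed + 1:n_runs`),
#' runs rupture detection and grouping on each, and scores group count,
#' membership accuracy against the generator truth, and the detected epoch
#' of each group.
#'
#' @param n_runs number of seeded runs (default 50).
#' @param base_seed seed offset.
#' @param lock a [lock_config()].
#' @param ... passed to [generate_traceset()].
#' @return data.frame with one row per run: `seed`, `n_groups`,
#'   `accuracy` (fraction of pairs assigned to their true group),
#'   `epoch1`, `epoch2` (mean rupture time of groups 1 and 2, `NA` when
#'   absent).
#' @export
evaluate_lock_recovery <- function(n_runs = 50L, base_seed = 0L,
                                   lock = lock_config(), ...) {
  summaries <- sod_energy_table("both")
  rows <- lapply(seq_len(n_runs), function(r) {
    ts <- generate_traceset(seed = base_seed + r, ...)
    events <- list()
    for (p in names(ts$total)) {
      ev <- tryCatch(detect_rupture(ts$total[[p]], lock),
                     error = function(e) NULL)
      if (!is.null(ev)) events[[p]] <- ev
    }
    rep <- group_locks(unname(events), summaries, lock)
    assigned <- stats::setNames(
      rep(NA_integer_, nrow(ts$truth)), ts$truth$pair)
    for (g in rep$groups) assigned[g$members] <- g$group_id
    acc <- sum(assigned == ts$truth$group, na.rm = TRUE) / nrow(ts$truth)
    ep <- function(i) if (length(rep$groups) >= i)
      rep$groups[[i]]$mean_rupture_time else NA_real_
    data.frame(seed = base_seed + r, n_groups = length(rep$groups),
               accuracy = acc, epoch1 = ep(1), epoch2 = ep(2))
  })
  do.call(rbind, rows)
}

#' Rupture force as a function of pull velocity
#'
#' Runs `n_rep` seeded replicates of the mechanistic pull at each velocity
#' and reports the mean and SD of the rupture force.
#'
#' @param velocities nm/ps values to test.
#' @param n_rep replicates per velocity (default 20).
#' @param seed base seed.
#' @param k spring constant, kJ mol^-1 nm^-2.
#' @param ... passed to [simulate_pull()].
#' @return data.frame `v`, `mean_rupture_force`, `sd_rupture_force`.
#' @export
sweep_velocity <- function(velocities = c(0.001, 0.01, 0.08), n_rep = 20L,
                           seed = 1L, k = 250, ...) {
  rows <- lapply(seq_along(velocities), function(i) {
    v <- velocities[i]
    dur <- max(200, 3 * max(default_pull_bonds()$break_extension) * 10 / v)
    sim <- simulate_pull(params = pull_params(k = k, v = v, duration = dur),
                         seed = seed + i, n_rep = n_rep, record = FALSE, ...)
    data.frame(v = v,
               mean_rupture_force = mean(sim$rupture_force, na.rm = TRUE),
               sd_rupture_force = stats::sd(sim$rupture_force, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Steering-force fluctuation as a function of spring constant
#'
#' @param ks spring constants to test, kJ mol^-1 nm^-2.
#' @param n_rep replicates per stiffness.
#' @param v pull velocity, nm/ps.
#' @param seed base seed.
#' @param ... passed to [simulate_pull()].
#' @return data.frame `k`, `mean_force_sd` (replicate-mean SD of the
#'   steering force over the bound phase), `sd_rupture_force`.
#' @export
sweep_spring_constant <- function(ks = c(100, 250, 400), n_rep = 20L,
                                  v = 0.01, seed = 1L, ...) {
  rows <- lapply(seq_along(ks), function(i) {
    k <- ks[i]
    dur <- max(200, 3 * max(default_pull_bonds()$break_extension) * 10 / v)
    sim <- simulate_pull(params = pull_params(k = k, v = v, duration = dur),
                         seed = seed + i, n_rep = n_rep, record = FALSE, ...)
    data.frame(k = k, mean_force_sd = mean(sim$force_sd, na.rm = TRUE),
               sd_rupture_force = stats::sd(sim$rupture_force, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
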