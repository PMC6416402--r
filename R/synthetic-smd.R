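# Synthetic steered-pull data ----------------------------------------------
#
# Two generator tiers replace the MD engine. The parametric tier emits
# per-pair energy traces with known lock structure (sigmoid decay at the
# group epoch + Ornstein-Uhlenbeck noise), a steering-force trace under the
# published pull parameters (k = 250 kJ mol^-1 nm^-2, v = 0.01 nm/ps), and
# a COM separation rising from 2.82 to 6.83 nm. The mechanistic tier is a
# 1-D overdamped Langevin pull with breakable bonds, kept for the
# force-phenomenology properties (rupture force grows with pull velocity;
# force fluctuations grow with spring stiffness).

#' Constant-velocity pull parameters
#'
#' @param k spring constant, kJ mol^-1 nm^-2 (default 250, the stiffness at
#'   which the rupture force is measurable and consistent).
#' @param v pull velocity, nm/ps (default 0.01, the slowest stable choice).
#' @param x0 initial pulled-coordinate position, nm.
#' @param duration pull duration, ps.
#' @param dt integration/sampling step, ps.
#' @export
pull_params <- function(k = 250, v = 0.01, x0 = 0, duration = 600, dt = 0.01) {
  stopifnot(k > 0, v >= 0, dt > 0, duration >= dt)
  list(k = k, v = v, x0 = x0, duration = duration, dt = dt)
}

#' Harmonic steering-spring force
#'
#' `F = -k * (x_pull(t) - x_pull(0) - v t)`: the spring tether moves at
#' constant velocity v and pulls the coordinate toward it; the force is zero
#' exactly when the coordinate sits on the moving tether.
#'
#' @param params a [pull_params()].
#' @param x pulled-coordinate position at time `t`, nm.
#' @param t time, ps (must lie in `[0, duration]`).
#' @return force in kJ mol^-1 nm^-1.
#' @export
spring_force <- function(params, x, t) {
  if (any(t < 0) || any(t > params$duration))
    stop("t outside [0, duration]")
  -params$k * (x - params$x0 - params$v * t)
}

#' Bond specification table for the generators
#'
#' One row per residue pair: `depth` (bound-state total energy, kJ/mol,
#' negative), `coul_frac` (fraction of the energy carried by the Coulombic
#' component; the remainder is Lennard-Jones), `group` (lock group 1
#' ruptures first), and for the mechanistic simulator `break_extension`
#' (nm) and the implied `stiffness` (kJ mol^-1 nm^-2).
#'
#' @param pair character vector of pair labels.
#' @param depth negative energies, kJ/mol.
#' @param coul_frac Coulombic fraction per pair (may exceed \[0,1\] when the
#'   components have opposite signs, as in the published tables).
#' @param group integer lock-group id.
#' @param break_extension extension at which the bond breaks, nm.
#' @return data.frame of class `bond_spec`.
#' @export
bond_spec <- function(pair, depth, coul_frac, group,
                      break_extension = ifelse(group == 1, 0.13, 0.30)) {
  if (any(depth >= 0)) stop("bond depth must be negative (attractive)")
  if (any(break_extension <= 0)) stop("break_extension must be > 0")
  out <- data.frame(pair = pair, depth = depth, coul_frac = coul_frac,
                    group = as.integer(group),
                    break_extension = break_extension,
                    stringsAsFactors = FALSE)
  out$stiffness <- -2 * out$depth / out$break_extension^2
  class(out) <- c("bond_spec", "data.frame")
  out
}

#' Default bond set: the 29 interface pairs with published energies
#'
#' Depths and component splits come from the packaged energy tables, group
#' membership from the packaged lock partition. One pair (Val5A-Gly49B,
#' total -0.43 kJ/mol) is shallower than typical trace noise; it is kept,
#' and rupture detection flags it as never-bound at default settings.
#'
#' @return a [bond_spec()] with 29 rows.
#' @export
default_bond_specs <- function() {
  tab <- sod_energy_table("both")
  grp <- sod_lock_groups()
  g <- grp$group[match(tab$pair, grp$pair)]
  bond_spec(tab$pair, tab$total_kJ_mol,
            tab$electrostatic_kJ_mol / tab$total_kJ_mol, g)
}

# OU process with stationary sd `sd` and correlation time `tau`, n steps of
# size dt, starting from its stationary distribution.
.ou_noise <- function(n, dt, sd, tau) {
  if (sd <= 0) return(numeric(n))
  a <- exp(-dt / tau)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - a^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  for (i in 2:n) x[i] <- a * x[i - 1] + innov[i]
  x
}

#' Generate a parametric steered-pull trace set
#'
#' Each pair's total-energy trace is `depth * S(t) + S(t) * OU(t)`, where
#' `S` is a sigmoid decay centered at the pair's group epoch (plus per-pair
#' jitter) so the trace sits at the table depth while bound and at zero
#' after rupture; it is split into Coulombic and Lennard-Jones components
#' by the pair's `coul_frac`. Also emitted: the steering-force trace under
#' the pull parameters and a monotone COM separation running 2.82 ->
#' 6.83 nm.
#'
#' @param bonds a [bond_spec()] (default [default_bond_specs()]).
#' @param epochs group rupture epochs, ps (default `c(240, 400)`).
#' @param params a [pull_params()] (its `duration` sets the time grid; the
#'   trace sampling step is `sample_dt`).
#' @param sample_dt trace sampling interval, ps (default 0.1).
#' @param noise_sd_frac OU noise SD as a fraction of each pair's |depth|
#'   (default 0.2).
#' @param noise_tau OU correlation time, ps (default 1).
#' @param decay_width sigmoid 10-90% decay width, ps (default 10).
#' @param epoch_jitter_sd per-pair jitter of the rupture center, ps
#'   (default 5).
#' @param com_range COM separation endpoints, nm (default `c(2.82, 6.83)`).
#' @param seed integer seed; identical seeds give identical output.
#' @return list of class `traceset`: `times`, `coul`/`lj`/`total` (lists of
#'   [energy_trace()] keyed by pair), `force` (data.frame time/force),
#'   `com` (data.frame time/separation_nm), `truth` (per-pair group,
#'   rupture center, depth, components), `params`.
#' @export
generate_traceset <- function(bonds = default_bond_specs(),
                              epochs = c(240, 400),
                              params = pull_params(),
                              sample_dt = 0.1,
                              noise_sd_frac = 0.2, noise_tau = 1,
                              decay_width = 10, epoch_jitter_sd = 5,
                              com_range = c(2.82, 6.83), seed = 1L) {
  stopifnot(all(diff(epochs) > 0), max(bonds$group) <= length(epochs))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  times <- seq(0, params$duration, by = sample_dt)
  n <- length(times)
  w <- decay_width / 4.394  # sigmoid scale giving a 10-90% span = decay_width
  coul <- list(); lj <- list(); total <- list()
  truth <- bonds[, c("pair", "depth", "coul_frac", "group")]
  truth$rupture_center <- epochs[bonds$group] +
    stats::rnorm(nrow(bonds), 0, epoch_jitter_sd)
  for (i in seq_len(nrow(bonds))) {
    S <- 1 / (1 + exp((times - truth$rupture_center[i]) / w))
    ou <- .ou_noise(n, sample_dt, noise_sd_frac * abs(bonds$depth[i]),
                    noise_tau)
    tot <- bonds$depth[i] * S + S * ou
    p <- bonds$pair[i]
    total[[p]] <- energy_trace(times, tot, p, "total")
    coul[[p]] <- energy_trace(times, bonds$coul_frac[i] * tot, p, "coul_sr")
    lj[[p]] <- energy_trace(times, (1 - bonds$coul_frac[i]) * tot, p, "lj_sr")
  }
  s <- times / params$duration
  sep <- com_range[1] + diff(com_range) * (3 * s^2 - 2 * s^3)  # smooth, monotone
  x_pull <- params$x0 + (sep - sep[1])
  force <- spring_force(params, x_pull, times)
  out <- list(times = times, coul = coul, lj = lj, total = total,
              force = data.frame(time = times, force = force),
              com = data.frame(time = times, separation_nm = sep),
              truth = truth,
              params = list(pull = params, epochs = epochs,
                            sample_dt = sample_dt,
                            noise_sd_frac = noise_sd_frac,
                            noise_tau = noise_tau, decay_width = decay_width,
                            epoch_jitter_sd = epoch_jitter_sd,
                            com_range = com_range, seed = seed))
  class(out) <- "traceset"
  out
}

#' @export
print.traceset <- function(x, ...) {
  cat("traceset:", length(x$total), "pairs,", length(x$times), "samples,",
      sprintf("t = 0..%g ps, epochs %s ps\n", max(x$times),
              paste(x$params$epochs, collapse = "/")))
  invisible(x)
}

#' Write a trace set to a directory of XVG files
#'
#' One `<pair>_coul.xvg` and `<pair>_lj.xvg` per pair, plus `pullf.xvg`
#' (steering force), `com.xvg` (COM separation) and `truth.json`.
#'
#' @param ts a `traceset`.
#' @param dir output directory (created if needed).
#' @export
write_traceset <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in names(ts$coul)) {
    write_xvg(ts$coul[[p]], file.path(dir, paste0(p, "_coul.xvg")))
    write_xvg(ts$lj[[p]], file.path(dir, paste0(p, "_lj.xvg")))
  }
  write_xvg(energy_trace(ts$force$time, ts$force$force, "pull", "total"),
            file.path(dir, "pullf.xvg"),
            ylabel = "Force (kJ/mol/nm)")
  write_xvg(energy_trace(ts$com$time, ts$com$separation_nm, "com", "total"),
            file.path(dir, "com.xvg"), ylabel = "COM separation (nm)")
  jsonlite::write_json(ts$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Read a trace-set directory back into paired traces
#'
#' @param dir directory written by [write_traceset()] (or any directory of
#'   `<pair>_coul.xvg` / `<pair>_lj.xvg` files).
#' @return list with `coul`, `lj`, `total` trace lists keyed by pair.
#' @export
read_traceset_dir <- function(dir) {
  cf <- list.files(dir, pattern = "_coul\\.xvg$", full.names = TRUE)
  if (!length(cf)) stop("no *_coul.xvg traces in ", dir)
  pairs <- sub("_coul\\.xvg$", "", basename(cf))
  coul <- list(); lj <- list(); total <- list()
  for (p in pairs) {
    coul[[p]] <- read_xvg(file.path(dir, paste0(p, "_coul.xvg")), p, "coul_sr")
    ljf <- file.path(dir, paste0(p, "_lj.xvg"))
    if (!file.exists(ljf)) stop("missing LJ trace for pair ", p)
    lj[[p]] <- read_xvg(ljf, p, "lj_sr")
    total[[p]] <- energy_trace(coul[[p]]$times,
                               coul[[p]]$values + lj[[p]]$values, p, "total")
  }
  list(coul = coul, lj = lj, total = total)
}

#' Default bond set for the mechanistic pull simulator
#'
#' Two effective bonds, one per lock group, with break extensions matching
#' the average stretching distances at which the two groups let go (0.13 nm
#' and 0.30 nm). Well depths are several kBT so that escape is
#' force-assisted rather than purely thermal, which is what gives the
#' rupture force its clear dependence on pull velocity.
#'
#' @export
default_pull_bonds <- function() {
  bond_spec(pair = c("lock1", "lock2"), depth = c(-12, -25),
            coul_frac = c(0.5, 0.2), group = c(1L, 2L),
            break_extension = c(0.13, 0.30))
}

#' Simulate a constant-velocity pull over breakable bonds
#'
#' Overdamped Langevin dynamics of a single pulled coordinate `x` (the
#' inter-chain separation increment, nm): `gamma dx = [F_spring + F_bonds]
#' dt + sqrt(2 gamma kB T) dW`. Each bond contributes a restoring force
#' `-stiffness * x` and energy `depth * (1 - (x/break_extension)^2)` while
#' `x < break_extension`, and breaks irreversibly beyond it. The rupture
#' force is the maximum steering force recorded before the last bond
#' breaks.
#'
#' @param bonds a [bond_spec()] (default [default_pull_bonds()]).
#' @param params a [pull_params()].
#' @param friction gamma, kJ mol^-1 nm^-2 ps (default 300).
#' @param temperature K (default 300; 0 disables noise).
#' @param seed integer seed.
#' @param n_rep replicates integrated simultaneously (default 1).
#' @param record keep full time series (default TRUE; set FALSE for
#'   replicate sweeps where only the rupture summary is needed).
#' @return list of class `pull_sim`: `rupture_force` (length `n_rep`),
#'   `break_times` (`n_rep x n_bonds`), `force_sd` (SD of the steering
#'   force over the bound phase, per replicate), and when `record`,
#'   `times`, `x`, `force`, `energies` (per-bond traces, replicate 1).
#' @export
simulate_pull <- function(bonds = default_pull_bonds(),
                          params = pull_params(duration = 2000),
                          friction = 300, temperature = 300, seed = 1L,
                          n_rep = 1L, record = TRUE) {
  stopifnot(friction > 0, temperature >= 0, n_rep >= 1L)
  k <- params$k; v <- params$v; dt <- params$dt
  s_tot <- sum(bonds$stiffness)
  if (dt * (k + s_tot) / friction > 0.2)
    stop("stability error: dt too large for these stiffnesses; ",
         "use dt <= ", signif(0.2 * friction / (k + s_tot), 3), " ps")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  kBT <- 0.0083145 * temperature
  nstep <- floor(params$duration / dt)
  nb <- nrow(bonds)
  x <- rep(params$x0, n_rep)
  intact <- matrix(TRUE, n_rep, nb)
  break_times <- matrix(NA_real_, n_rep, nb,
                        dimnames = list(NULL, bonds$pair))
  max_force <- rep(-Inf, n_rep)
  sum_f <- rep(0, n_rep); sum_f2 <- rep(0, n_rep); n_f <- rep(0L, n_rep)
  noise_scale <- sqrt(2 * kBT * dt / friction)
  rec_x <- if (record) numeric(nstep) else NULL
  rec_F <- if (record) numeric(nstep) else NULL
  rec_E <- if (record) matrix(0, nstep, nb, dimnames = list(NULL, bonds$pair))
           else NULL
  stiff <- bonds$stiffness; eb <- bonds$break_extension; dep <- bonds$depth
  for (i in seq_len(nstep)) {
    t <- i * dt
    F_spring <- -k * (x - params$x0 - v * t)
    F_bond <- if (nb) -drop(intact %*% stiff) * (x - params$x0) else 0
    drift <- (F_spring + F_bond) * dt / friction
    x <- x + drift + if (temperature > 0) noise_scale * stats::rnorm(n_rep) else 0
    ext <- x - params$x0
    newly <- intact & outer(ext, eb, ">=")
    if (any(newly)) {
      break_times[newly] <- t
      intact[newly] <- FALSE
    }
    F_now <- -k * (x - params$x0 - v * t)
    bound <- rowSums(intact) > 0
    max_force[bound] <- pmax(max_force[bound], F_now[bound])
    sum_f[bound] <- sum_f[bound] + F_now[bound]
    sum_f2[bound] <- sum_f2[bound] + F_now[bound]^2
    n_f[bound] <- n_f[bound] + 1L
    if (record) {
      rec_x[i] <- x[1]; rec_F[i] <- F_now[1]
      e <- dep * (1 - pmin(ext[1] / eb, 1)^2)
      e[!intact[1, ]] <- 0
      rec_E[i, ] <- e
    }
    if (!any(intact) && !record) break
  }
  force_sd <- sqrt(pmax(sum_f2 / pmax(n_f, 1) -
                          (sum_f / pmax(n_f, 1))^2, 0))
  out <- list(rupture_force = ifelse(is.finite(max_force), max_force, NA_real_),
              break_times = break_times, force_sd = force_sd,
              params = params, bonds = bonds, friction = friction,
              temperature = temperature, seed = seed)
  if (record) {
    out$times <- dt * seq_len(nstep)
    out$x <- rec_x; out$force <- rec_F
    out$energies <- rec_E
  }
  class(out) <- "pull_sim"
  out
}

#' Generate a residual-activity kinetic curve with known step structure
#'
#' Staircase decay: activity starts at 1 and loses fraction `f_i` of the
#' initial activity at each transition, each transition relaxing
#' exponentially at `rate`. The ground-truth kinetic ratio is
#' `R = sum(f) / f[1]`.
#'
#' @param step_fractions per-step activity losses (must sum to <= 1).
#' @param rate transition relaxation rate, 1/time (default 0.1).
#' @param transition_times transition onsets; default evenly spaced,
#'   `40 + 100 * (i - 1)`.
#' @param duration total duration (default covers all transitions + 100).
#' @param n_points samples (default 400).
#' @param noise_sd iid Gaussian noise SD on the activity (default 0).
#' @param seed integer seed.
#' @return a [kinetic_curve()] with attribute `"truth"` (list: `R`,
#'   `step_fractions`, `transition_times`).
#' @export
generate_kinetic_curve <- function(step_fractions = c(0.5, 0.5), rate = 0.1,
                                   transition_times = NULL, duration = NULL,
                                   n_points = 400L, noise_sd = 0,
                                   seed = 1L) {
  f <- step_fractions
  stopifnot(all(f > 0), sum(f) <= 1 + 1e-9)
  s <- length(f)
  if (is.null(transition_times)) transition_times <- 40 + 100 * (seq_len(s) - 1)
  stopifnot(length(transition_times) == s, all(diff(transition_times) > 0))
  if (is.null(duration)) duration <- max(transition_times) + 100
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  t <- seq(0, duration, length.out = n_points)
  a <- rep(1, n_points)
  for (i in seq_len(s))
    a <- a - f[i] * (1 - exp(-rate * pmax(0, t - transition_times[i])))
  if (noise_sd > 0) a <- a + stats::rnorm(n_points, 0, noise_sd)
  a <- pmin(pmax(a, 0), 1.05)
  out <- kinetic_curve(t, a)
  attr(out, "truth") <- list(R = sum(f) / f[1], step_fractions = f,
                             transition_times = transition_times)
  out
}
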