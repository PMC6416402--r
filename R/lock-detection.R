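# Rupture detection and conformational-lock grouping -----------------------
#
# A residue pair "ruptures" when its interaction-energy magnitude decays
# from its bound-state baseline to a small fraction of it and stays there.
# Pairs whose rupture times cluster form one conformational lock: the
# published pull shows two such epochs, near 240 ps and near 400 ps, with
# every trace at zero by ~520 ps.

#' Rupture/grouping configuration
#'
#' @param baseline_window initial window (ps) whose mean defines the
#'   bound-state baseline energy.
#' @param smooth_window centered moving-average width (ps) applied before
#'   thresholding.
#' @param alpha decay fraction: rupture is the first time the smoothed
#'   energy magnitude falls below `alpha * |baseline|`.
#' @param sustain_window the magnitude must stay below threshold for this
#'   long (ps) for the crossing to count.
#' @param noise_floor |baseline| below this (kJ/mol) means the pair was
#'   never bound and rupture is undefined.
#' @param min_gap smallest inter-event gap (ps) worth splitting groups at.
#' @param max_groups upper bound on the number of lock groups.
#' @export
lock_config <- function(baseline_window = 50, smooth_window = 10,
                        alpha = 0.1, sustain_window = 20, noise_floor = 0.5,
                        min_gap = 50, max_groups = 4L) {
  stopifnot(baseline_window > 0, smooth_window >= 0, alpha > 0, alpha < 1,
            sustain_window >= 0, noise_floor >= 0, min_gap > 0,
            max_groups >= 1L)
  structure(list(baseline_window = baseline_window,
                 smooth_window = smooth_window, alpha = alpha,
                 sustain_window = sustain_window, noise_floor = noise_floor,
                 min_gap = min_gap, max_groups = as.integer(max_groups)),
            class = "lock_config")
}

.moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  pad <- (k - 1L) %/% 2L
  xx <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  as.numeric(stats::filter(xx, rep(1 / k, k), sides = 2))[pad + seq_along(x)]
}

#' Detect the rupture of one residue pair
#'
#' @param trace an [energy_trace()] of the pair's total interaction energy.
#' @param config a [lock_config()].
#' @return list of class `rupture_event` with `pair`, `baseline_energy`
#'   (kJ/mol), `rupture_time` (ps, `NA` if the pair never lets go), and
#'   `zero_time` (ps after which the magnitude stays below the noise floor,
#'   `NA` if never).
#' @export
detect_rupture <- function(trace, config = lock_config()) {
  t <- trace$times; v <- trace$values
  dt <- stats::median(diff(t))
  need <- (config$baseline_window + config$sustain_window) / dt
  if (length(t) < need)
    stop("trace too short for baseline + sustain windows")
  base_idx <- t <= t[1] + config$baseline_window
  baseline <- mean(v[base_idx])
  if (abs(baseline) < config$noise_floor)
    stop("undefined rupture: baseline |", round(abs(baseline), 3),
         "| kJ/mol below the noise floor (pair never bound)")
  k <- max(1L, round(config$smooth_window / dt))
  sm <- .moving_average(v, k)
  thr <- config$alpha * abs(baseline)
  below <- abs(sm) < thr
  ns <- max(1L, round(config$sustain_window / dt))
  rupture_time <- NA_real_
  cand <- which(below)
  for (i in cand) {
    j <- min(length(t), i + ns - 1L)
    if (all(below[i:j])) { rupture_time <- t[i]; break }
  }
  zero_time <- NA_real_
  under <- abs(sm) < config$noise_floor
  if (any(under)) {
    run <- rev(cumprod(rev(under)))  # suffix of all-under samples
    if (run[length(run)] == 1 || any(run == 1)) {
      first <- which(run == 1)[1]
      if (first <= length(t)) zero_time <- t[first]
    }
  }
  if (!is.na(rupture_time) && !is.na(zero_time) && zero_time < rupture_time)
    zero_time <- rupture_time
  structure(list(pair = trace$pair, baseline_energy = baseline,
                 rupture_time = rupture_time, zero_time = zero_time),
            class = "rupture_event")
}

# Recursive largest-gap splitting of sorted 1-D rupture times. Returns a
# vector of group indices (1-based, in time order).
.gap_split <- function(times, min_gap, max_groups) {
  ord <- order(times)
  sorted <- times[ord]
  groups <- list(seq_along(sorted))
  repeat {
    if (length(groups) >= max_groups) break
    best <- NULL
    for (gi in seq_along(groups)) {
      idx <- groups[[gi]]
      if (length(idx) < 2L) next
      gaps <- diff(sorted[idx])
      g <- max(gaps)
      # ties between equal largest gaps: earlier split point wins
      at <- which(gaps == g)[1]
      if (g > min_gap && (is.null(best) || g > best$gap))
        best <- list(gi = gi, at = at, gap = g)
    }
    if (is.null(best)) break
    idx <- groups[[best$gi]]
    groups <- append(groups[-best$gi],
                     list(idx[seq_len(best$at)],
                          idx[(best$at + 1L):length(idx)]))
  }
  # order groups by mean time, label members
  means <- vapply(groups, function(idx) mean(sorted[idx]), numeric(1))
  groups <- groups[order(means)]
  lab <- integer(length(sorted))
  for (gi in seq_along(groups)) lab[groups[[gi]]] <- gi
  out <- integer(length(times))
  out[ord] <- lab
  out
}

#' Group ruptured pairs into conformational locks
#'
#' Sorts the detected rupture times and recursively splits at the largest
#' inter-event gap while it exceeds `min_gap`, up to `max_groups` groups --
#' a deterministic, order-free formalization of reading the epochs off the
#' energy curves. Groups are numbered by mean rupture time; each group's
#' total energy is the sum of its members' pair totals.
#'
#' @param events list of `rupture_event`s (one per pair).
#' @param summaries pair-summary data.frame covering every event's pair.
#' @param config a [lock_config()].
#' @return list of class `lock_report` with `groups` (each: `group_id`,
#'   `members`, `n_hbond`, `n_hydrophobic`, `total_energy`,
#'   `rupture_window`, `mean_rupture_time`), `unassigned` (pairs without a
#'   defined rupture), and `parameters`.
#' @export
group_locks <- function(events, summaries, config = lock_config()) {
  pairs <- vapply(events, function(e) e$pair, "")
  miss <- setdiff(pairs, summaries$pair)
  if (length(miss)) stop("no summary for pair(s): ", paste(miss, collapse = ", "))
  times <- vapply(events, function(e) e$rupture_time, numeric(1))
  defined <- !is.na(times)
  if (!any(defined)) {
    out <- structure(list(groups = list(), unassigned = pairs,
                          parameters = config), class = "lock_report")
    attr(out, "diagnostic") <- "no pair has a defined rupture time"
    return(out)
  }
  lab <- .gap_split(times[defined], config$min_gap, config$max_groups)
  groups <- lapply(sort(unique(lab)), function(gi) {
    sel <- which(defined)[lab == gi]
    mp <- pairs[sel]
    srows <- summaries[match(mp, summaries$pair), , drop = FALSE]
    list(group_id = gi, members = mp,
         kinds = srows$kind,
         n_hbond = sum(srows$kind == "hydrogen_bond"),
         n_hydrophobic = sum(srows$kind == "hydrophobic"),
         total_energy = sum(srows$total_kJ_mol),
         rupture_window = range(times[sel]),
         mean_rupture_time = mean(times[sel]))
  })
  structure(list(groups = groups, unassigned = pairs[!defined],
                 parameters = config),
            class = "lock_report")
}

#' @export
print.lock_report <- function(x, ...) {
  cat("lock_report:", length(x$groups), "group(s),",
      length(x$unassigned), "unassigned pair(s)\n")
  for (g in x$groups)
    cat(sprintf(
      "  group %d: %d pairs (%d H-bond, %d hydrophobic), total %.2f kJ/mol, ruptures %.0f-%.0f ps\n",
      g$group_id, length(g$members), g$n_hbond, g$n_hydrophobic,
      g$total_energy, g$rupture_window[1], g$rupture_window[2]))
  invisible(x)
}

#' Total average energy of a lock group
#'
#' @param members character vector of pair labels (or a group element of a
#'   `lock_report`).
#' @param summaries pair-summary data.frame.
#' @return sum of member total energies, kJ/mol (0 for an empty group).
#' @export
lock_energy <- function(members, summaries) {
  if (is.list(members) && !is.null(members$members)) members <- members$members
  if (!length(members)) return(0)
  hit <- match(members, summaries$pair)
  if (anyNA(hit))
    stop("pair(s) missing from summaries: ",
         paste(members[is.na(hit)], collapse = ", "))
  sum(summaries$total_kJ_mol[hit])
}

#' Compare two trace sets pair by pair
#'
#' Reports per-pair differences in baseline energy and rupture time between
#' a reference trace set and a variant (e.g. a mutant pulled under the same
#' conditions).
#'
#' @param reference,variant lists of total-energy [energy_trace()]s keyed
#'   by pair label (as produced by [generate_traceset()]`$total`).
#' @param config a [lock_config()].
#' @return data.frame with one row per shared pair: baselines, rupture
#'   times, `delta_baseline`, `delta_rupture`; plus attribute `"summary"`
#'   counting pairs rupturing earlier/later in the variant.
#' @export
compare_tracesets <- function(reference, variant, config = lock_config()) {
  shared <- intersect(names(reference), names(variant))
  if (!length(shared)) stop("no overlapping pairs between trace sets")
  rows <- lapply(shared, function(p) {
    er <- tryCatch(detect_rupture(reference[[p]], config),
                   error = function(e) NULL)
    ev <- tryCatch(detect_rupture(variant[[p]], config),
                   error = function(e) NULL)
    if (is.null(er) || is.null(ev)) return(NULL)  # never-bound pair
    data.frame(pair = p,
               baseline_ref = er$baseline_energy,
               baseline_var = ev$baseline_energy,
               delta_baseline = ev$baseline_energy - er$baseline_energy,
               rupture_ref = er$rupture_time, rupture_var = ev$rupture_time,
               delta_rupture = ev$rupture_time - er$rupture_time,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(
    earlier = sum(out$delta_rupture < 0, na.rm = TRUE),
    later = sum(out$delta_rupture > 0, na.rm = TRUE),
    unchanged = sum(out$delta_rupture == 0, na.rm = TRUE))
  out
}
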