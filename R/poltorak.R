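# Lock counting from residual-activity kinetics ----------------------------
#
# In the conformational-lock picture a dimer dissociates through a chain of
# still-active intermediates, E2 <-> E2^1 <-> ... <-> E2^m <-> 2E1 => 2Ed,
# and the shape of the residual-activity decay bounds the number of steps
# from below: n = (0.13 + delta) / (0.13 - 0.05 delta) with delta = R - 1.
# R is read off the kinetic plot as the ratio of the total activity loss to
# the loss of the first resolved decay step, so a clean single-step decay
# gives R = 1, delta = 0, n = 1.

#' Minimal number of dissociation steps from delta
#'
#' The empirical lock-counting relation `n = (0.13 + delta) / (0.13 -
#' 0.05 delta)`, strictly increasing on its domain `0 <= delta < 2.6` with
#' `n(0) = 1` and a pole at `delta = 2.6`.
#'
#' @param delta dimensionless kinetic shape parameter.
#' @return n (real, >= 1).
#' @export
n_from_delta <- function(delta) {
  if (any(delta < 0)) stop("domain error: delta must be >= 0")
  if (any(delta >= 2.6))
    stop("domain error: delta must be < 2.6 (denominator 0.13 - 0.05*delta <= 0)")
  (0.13 + delta) / (0.13 - 0.05 * delta)
}

#' Delta from the kinetic ratio R
#'
#' @param R kinetic ratio (total activity loss / first-step loss), >= 1.
#' @return delta = R - 1.
#' @export
delta_from_R <- function(R) {
  if (any(R < 1)) stop("domain error: R must be >= 1")
  R - 1
}

#' Construct a residual-activity kinetic curve
#'
#' @param times time points (arbitrary units), strictly increasing,
#'   length >= 3.
#' @param activity residual activity as a fraction of the initial value;
#'   values must lie in `[0, 1.05]` (small experimental overshoot is
#'   tolerated) and are expected to be non-increasing overall.
#' @return object of class `kinetic_curve`.
#' @export
kinetic_curve <- function(times, activity) {
  if (length(times) != length(activity)) stop("length mismatch")
  if (length(times) < 3L) stop("need at least 3 points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(activity < -1e-9) || any(activity > 1.05))
    stop("activity values must lie in [0, 1.05]")
  structure(list(times = as.numeric(times), activity = as.numeric(activity)),
            class = "kinetic_curve")
}

#' Read a kinetic curve from CSV (`time,activity`)
#' @param path CSV path.
#' @export
read_kinetic_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "activity") %in% names(df)))
    stop("kinetic CSV needs columns time,activity")
  kinetic_curve(df$time, df$activity)
}

#' Estimator configuration for the kinetic ratio R
#'
#' @param min_step smallest resolvable step height, as a fraction of the
#'   curve's dynamic range (default 0.05).
#' @param max_steps most steps considered (default 4).
#' @param n_boot residual-bootstrap replicates for the standard error
#'   (default 200; 0 disables).
#' @export
poltorak_config <- function(min_step = 0.05, max_steps = 4L, n_boot = 200L) {
  stopifnot(min_step > 0, min_step < 1, max_steps >= 1L, n_boot >= 0L)
  list(min_step = min_step, max_steps = as.integer(max_steps),
       n_boot = as.integer(n_boot))
}

# Core single-pass R estimate: change-point candidates from the smoothed
# derivative, number of steps selected by BIC on a plateau model, R = total
# decay / first-step decay. Returns list(R, tau, levels).
.estimate_R_once <- function(t, a, cfg, polish = TRUE, light = FALSE) {
  n <- length(t)
  rng <- max(a) - min(a)
  k <- max(3L, round(n / 60))
  sm <- .moving_average(a, k)
  dt <- diff(t)
  g <- .moving_average(diff(sm) / dt, k)  # smoothed derivative, length n-1
  tm <- (t[-1] + t[-n]) / 2
  # local minima of the derivative = candidate transitions
  loc <- which(diff(sign(diff(g))) > 0) + 1L
  loc <- loc[g[loc] < 0]
  if (!length(loc)) loc <- which.min(g)
  # step height of each candidate: drop of the smoothed curve across the
  # basin between the surrounding derivative local maxima
  basin_edges <- sort(unique(c(1L, which(diff(sign(diff(-g))) > 0) + 1L,
                               n - 1L)))
  height <- vapply(loc, function(i) {
    lo <- max(basin_edges[basin_edges <= i])
    hi <- min(basin_edges[basin_edges >= i])
    sm[lo] - sm[min(hi + 1L, n)]
  }, numeric(1))
  keep <- height >= cfg$min_step * rng
  if (!any(keep)) keep[which.max(height)] <- TRUE
  cand <- loc[keep]; ch <- height[keep]
  # merge candidates closer than a fraction of the span: one decay step can
  # throw several derivative minima once noise is added, and splitting a
  # single transition in two would halve the first-step height
  min_sep <- (t[n] - t[1]) / 15
  ord_t <- order(tm[cand])
  cand <- cand[ord_t]; ch <- ch[ord_t]
  merged_c <- integer(0); merged_h <- numeric(0)
  for (ii in seq_along(cand)) {
    if (length(merged_c) && tm[cand[ii]] - tm[merged_c[length(merged_c)]] < min_sep) {
      if (ch[ii] > merged_h[length(merged_h)] ||
          g[cand[ii]] < g[merged_c[length(merged_c)]]) {
        merged_c[length(merged_c)] <- cand[ii]
        merged_h[length(merged_h)] <- max(ch[ii], merged_h[length(merged_h)])
      }
    } else {
      merged_c <- c(merged_c, cand[ii]); merged_h <- c(merged_h, ch[ii])
    }
  }
  cand <- merged_c[order(-merged_h)]
  cand <- cand[seq_len(min(length(cand), cfg$max_steps))]

  plateau_model <- function(tau_idx) {
    ord <- order(tm[tau_idx])
    tix <- tau_idx[ord]
    tau <- tm[tix]
    bounds <- c(t[1] - 1, tau, t[n] + 1)
    seg <- findInterval(t, bounds, rightmost.closed = TRUE)
    # plateau level: mean over the settled tail of each segment
    levels <- vapply(seq_len(length(bounds) - 1L), function(s) {
      idx <- which(seg == s)
      if (!length(idx)) return(NA_real_)
      tail_idx <- idx[t[idx] >= bounds[s] + 0.6 * (bounds[s + 1] - bounds[s])]
      if (length(tail_idx) < 2L) tail_idx <- idx
      mean(a[tail_idx])
    }, numeric(1))
    # staircase with exponential transitions, relaxation rate of each step
    # taken from its derivative peak (|g| = h * r at the transition)
    fitted <- levels[seg]
    for (s in seq_len(length(tau))) {
      idx <- which(seg == s + 1L)
      if (!length(idx)) next
      h <- levels[s] - levels[s + 1L]
      r <- abs(g[tix[s]]) / max(abs(h), 1e-9)
      fitted[idx] <- levels[s + 1L] + h * exp(-r * (t[idx] - tau[s]))
    }
    list(tau = tau, levels = levels, rss = sum((a - fitted)^2),
         fitted = fitted)
  }

  best <- NULL
  for (kk in seq_len(length(cand))) {
    pm <- plateau_model(cand[seq_len(kk)])
    if (anyNA(pm$levels)) next
    bic <- n * log(max(pm$rss, 1e-12) / n) + (3 * kk + 1) * log(n)
    if (is.null(best) || bic < best$bic) best <- c(pm, list(bic = bic, k = kk))
  }
  if (is.null(best)) stop("fit error: no resolvable decay step")
  lv <- best$levels
  heights <- -diff(lv)
  total <- lv[1] - lv[length(lv)]
  if (total <= 0) stop("fit error: curve does not decay")
  if (heights[1] <= 0) stop("fit error: first step has non-positive height")
  if (!polish)
    return(list(R = max(1, total / heights[1]), tau = best$tau, levels = lv,
                fitted = best$fitted))

  # polish by least squares in the sum-of-exponentials family
  # A(t) = L0 - sum_i h_i * (1 - exp(-r_i * (t - tau_i)+))
  s <- length(best$tau)
  h0 <- pmax(heights, 1e-4)
  r0 <- vapply(seq_len(s), function(i)
    max(abs(g[which.min(abs(tm - best$tau[i]))]) / h0[i], 1e-4), numeric(1))
  par0 <- c(lv[1], log(h0), log(r0), best$tau)
  model <- function(par) {
    L0 <- par[1]; h <- exp(par[1 + seq_len(s)])
    r <- exp(par[1 + s + seq_len(s)]); tau <- par[1 + 2 * s + seq_len(s)]
    f <- rep(L0, n)
    for (i in seq_len(s))
      f <- f - h[i] * (1 - exp(-r[i] * pmax(t - tau[i], 0)))
    f
  }
  rss0 <- sum((a - best$fitted)^2)
  fn <- function(p) sum((a - model(p))^2)
  fit <- tryCatch({
    f1 <- stats::optim(par0, fn, method = "BFGS",
                       control = list(maxit = if (light) 200 else 1000,
                                      reltol = 1e-15))
    if (light) f1 else {
      # second pass with a fine finite-difference step tightens the last digits
      f2 <- stats::optim(f1$par, fn, method = "BFGS",
                         control = list(maxit = 1000, reltol = 1e-15,
                                        ndeps = rep(1e-7, length(par0))))
      if (f2$value < f1$value) f2 else f1
    }
  }, error = function(e) NULL)
  R_plateau <- max(1, total / heights[1])
  if (!is.null(fit) && fit$value <= rss0) {
    h <- exp(fit$par[1 + seq_len(s)])
    tau <- fit$par[1 + 2 * s + seq_len(s)]
    ord <- order(tau)
    h <- h[ord]; tau <- tau[ord]
    R_pol <- max(1, sum(h) / h[1])
    # the polish is a refinement: keep it only while it agrees with the
    # plateau estimate, otherwise it has wandered off fitting noise
    if (abs(R_pol - R_plateau) <= 0.2 * R_plateau) {
      lv2 <- fit$par[1] - cumsum(c(0, h))
      return(list(R = R_pol, tau = tau, levels = lv2,
                  fitted = model(fit$par)))
    }
  }
  list(R = R_plateau, tau = best$tau, levels = lv,
       fitted = best$fitted)
}

#' Estimate the kinetic ratio R from a residual-activity curve
#'
#' Transitions are located as local minima of the smoothed activity
#' derivative; the number of steps is chosen by BIC on a plateau model with
#' a minimum step height; R is the ratio of the total activity loss to the
#' first resolved step's loss. A residual bootstrap supplies a standard
#' error.
#'
#' @param curve a [kinetic_curve()].
#' @param config a [poltorak_config()].
#' @param seed optional integer seed for the bootstrap.
#' @return list with `R`, `se` (bootstrap SE, `NA` when disabled),
#'   `R_boot` (replicates), `transition_times`, `plateau_levels`.
#' @export
estimate_R <- function(curve, config = poltorak_config(), seed = NULL) {
  t <- curve$times; a <- curve$activity
  if (max(a) - min(a) < 0.2)
    stop("activity spans less than 0.2 of dynamic range; R is not estimable")
  if (stats::cor(t, a, method = "spearman") > 0.5)
    stop("fit error: activity increases with time")
  est <- .estimate_R_once(t, a, config)
  # plateau-level R with the transition times held fixed (bootstrap kernel)
  fixed_tau_R <- function(ab) {
    bounds <- c(t[1] - 1, est$tau, t[length(t)] + 1)
    seg <- findInterval(t, bounds, rightmost.closed = TRUE)
    lv <- vapply(seq_len(length(bounds) - 1L), function(s) {
      idx <- which(seg == s)
      tail_idx <- idx[t[idx] >= bounds[s] + 0.6 * (bounds[s + 1] - bounds[s])]
      if (length(tail_idx) < 2L) tail_idx <- idx
      mean(ab[tail_idx])
    }, numeric(1))
    total <- lv[1] - lv[length(lv)]
    first <- lv[1] - lv[2]
    if (!is.finite(total) || !is.finite(first) || first <= 0 || total <= 0)
      return(NA_real_)
    max(1, total / first)
  }
  R_boot <- NULL; se <- NA_real_
  if (config$n_boot > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    fitted <- est$fitted
    resid <- a - fitted
    blk <- max(5L, length(t) %/% 20L)
    R_boot <- vapply(seq_len(config$n_boot), function(b) {
      starts <- sample.int(length(t) - blk + 1L,
                           ceiling(length(t) / blk), replace = TRUE)
      idx <- as.vector(vapply(starts, function(s) s:(s + blk - 1L),
                              integer(blk)))[seq_along(t)]
      ab <- pmin(pmax(fitted + resid[idx], 0), 1.05)
      out <- tryCatch(.estimate_R_once(t, ab, config, polish = FALSE)$R,
                      error = function(e) NA_real_)
      if (is.na(out)) fixed_tau_R(ab) else out
    }, numeric(1))
    se <- stats::sd(R_boot, na.rm = TRUE)
  }
  list(R = est$R, se = se, R_boot = R_boot,
       transition_times = est$tau, plateau_levels = est$levels)
}

#' Estimate the number of conformational locks from a kinetic curve
#'
#' Chains [estimate_R()] -> [delta_from_R()] -> [n_from_delta()], reporting
#' n both as the real value of the lock-counting relation and as an integer
#' ceiling, with bootstrap uncertainty propagated through the chain.
#'
#' @inheritParams estimate_R
#' @return list of class `lock_count_estimate`: `R`, `delta`, `n`,
#'   `n_rounded`, `valid` (delta inside `[0, 2.6)`), `ci_n` (percentile 95%
#'   bootstrap CI, `NA` when unavailable), `diagnostic`.
#' @export
lock_count <- function(curve, config = poltorak_config(), seed = NULL) {
  est <- estimate_R(curve, config, seed)
  delta <- est$R - 1
  valid <- delta >= 0 && delta < 2.6
  n <- if (valid) n_from_delta(delta) else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (!is.null(est$R_boot) && valid) {
    db <- est$R_boot - 1
    nb <- ifelse(!is.na(db) & db >= 0 & db < 2.6,
                 (0.13 + db) / (0.13 - 0.05 * db), NA_real_)
    if (sum(!is.na(nb)) >= 20) {
      # the bootstrap runs the fast (unpolished) estimator; recenter its
      # distribution on the polished point estimate before taking quantiles
      nb <- nb - stats::median(nb, na.rm = TRUE) + n
      ci <- unname(stats::quantile(nb, c(0.025, 0.975), na.rm = TRUE))
    }
  }
  structure(list(R = est$R, delta = delta, n = n,
                 n_rounded = if (valid) as.integer(ceiling(n - 1e-9)) else NA_integer_,
                 valid = valid, ci_n = ci,
                 diagnostic = if (valid) "" else
                   sprintf("delta = %.3f outside [0, 2.6): lock count undefined", delta),
                 transition_times = est$transition_times),
            class = "lock_count_estimate")
}

#' @export
print.lock_count_estimate <- function(x, ...) {
  cat(sprintf("lock_count_estimate: R = %.3f, delta = %.3f", x$R, x$delta))
  if (x$valid) cat(sprintf(", n = %.3f (ceil %d)", x$n, x$n_rounded))
  else cat(" [", x$diagnostic, "]")
  cat("\n")
  invisible(x)
}
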