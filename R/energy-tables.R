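# Per-pair interaction-energy traces and their summary tables --------------
#
# The MD engine decomposes the A-B interaction into short-range Coulombic
# (coul_sr) and Lennard-Jones (lj_sr) components per residue pair; this
# module ingests such traces (GROMACS XVG dialect), averages them, and
# rebuilds the per-pair summary tables (electrostatic / vdW / total).

#' Construct an energy trace
#'
#' @param times time points in ps, strictly increasing, length >= 2.
#' @param values energies in kJ/mol, same length.
#' @param pair residue-pair label, e.g. `"Ile149A-Gly49B"`.
#' @param component `"coul_sr"`, `"lj_sr"`, or `"total"`.
#' @return object of class `energy_trace`.
#' @export
energy_trace <- function(times, values, pair = "", component = "total") {
  component <- match.arg(component, c("coul_sr", "lj_sr", "total"))
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) < 2L) stop("insufficient data: need >= 2 samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(times)) || !all(is.finite(values)))
    stop("non-finite trace data")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 pair = pair, component = component),
            class = "energy_trace")
}

#' @export
print.energy_trace <- function(x, ...) {
  cat("energy_trace", if (nzchar(x$pair)) paste0("[", x$pair, "]") else "",
      x$component, ":", length(x$times), "samples,",
      sprintf("t = %g..%g ps, mean %.3f kJ/mol", min(x$times), max(x$times),
              mean(x$values)), "\n")
  invisible(x)
}

#' Read a GROMACS-style XVG file
#'
#' Two-column time/energy payload; `#` comment and `@` plotting-directive
#' lines are skipped (axis labels are captured from `@ xaxis`/`@ yaxis`
#' directives when present).
#'
#' @param path XVG file path.
#' @param pair,component metadata attached to the trace; when missing, an
#'   `@ subtitle` directive of the form `pair component` is consulted.
#' @return an [energy_trace()].
#' @export
read_xvg <- function(path, pair = NULL, component = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- grepl("^\\s*[#@]", lines)
  sub <- grep('^@\\s*subtitle\\s+"', lines, value = TRUE)
  if (length(sub)) {
    tok <- strsplit(gsub('^@\\s*subtitle\\s+"|"\\s*$', "", sub[1]), "\\s+")[[1]]
    if (is.null(pair) && length(tok) >= 1) pair <- tok[1]
    if (is.null(component) && length(tok) >= 2) component <- tok[2]
  }
  body <- trimws(lines[!meta])
  body <- body[nzchar(body)]
  if (length(body) < 2L)
    stop("insufficient data: fewer than 2 numeric rows in ", path)
  fields <- strsplit(body, "\\s+")
  bad <- which(vapply(fields, function(f)
    length(f) < 2L || anyNA(suppressWarnings(as.numeric(f[1:2]))), logical(1)))
  if (length(bad)) {
    lineno <- which(!meta & nzchar(trimws(lines)))[bad[1]]
    stop("non-numeric payload at line ", lineno, " of ", path)
  }
  times <- vapply(fields, function(f) as.numeric(f[1]), numeric(1))
  values <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
  energy_trace(times, values, pair = if (is.null(pair)) "" else pair,
               component = if (is.null(component)) "total" else component)
}

#' Write an energy trace as XVG
#'
#' @param trace an [energy_trace()].
#' @param path output path.
#' @param xlabel,ylabel axis labels for the `@` directives.
#' @export
write_xvg <- function(trace, path, xlabel = "Time (ps)",
                      ylabel = "Energy (kJ/mol)") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# conflock energy trace",
               sprintf('@    subtitle "%s %s"', trace$pair, trace$component),
               sprintf('@    xaxis  label "%s"', xlabel),
               sprintf('@    yaxis  label "%s"', ylabel)), con)
  writeLines(sprintf("%.6f %.12g", trace$times, trace$values), con)
  invisible(path)
}

#' Time-average of an energy trace
#'
#' Arithmetic mean of the samples inside a time window (the whole trace by
#' default) -- the quantity tabulated as "average interaction energy".
#'
#' @param trace an [energy_trace()].
#' @param window optional `c(t_min, t_max)` in ps.
#' @return mean energy in kJ/mol.
#' @export
average_energy <- function(trace, window = NULL) {
  v <- trace$values
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] <= window[2])
    keep <- trace$times >= window[1] & trace$times <= window[2]
    if (!any(keep)) stop("window [", window[1], ", ", window[2],
                         "] contains no samples")
    v <- v[keep]
  }
  mean(v)
}

#' Summarize one residue pair from its component traces
#'
#' Electrostatic = mean of the short-range Coulombic trace, vdW = mean of
#' the short-range Lennard-Jones trace, total = their sum. Mismatched time
#' grids are joined by nearest time within half the smaller sampling
#' interval.
#'
#' @param coul_trace,lj_trace [energy_trace()] objects for the same pair.
#' @param kind `"hydrogen_bond"` or `"hydrophobic"`.
#' @param window optional averaging window `c(t_min, t_max)`, ps.
#' @return one-row data.frame with columns `pair`, `kind`,
#'   `electrostatic_kJ_mol`, `vdw_kJ_mol`, `total_kJ_mol`.
#' @export
summarize_pair <- function(coul_trace, lj_trace,
                           kind = c("hydrogen_bond", "hydrophobic"),
                           window = NULL) {
  kind <- match.arg(kind)
  if (nzchar(coul_trace$pair) && nzchar(lj_trace$pair) &&
      coul_trace$pair != lj_trace$pair)
    stop("pair mismatch: ", coul_trace$pair, " vs ", lj_trace$pair)
  if (!isTRUE(all.equal(coul_trace$times, lj_trace$times))) {
    tol <- min(min(diff(coul_trace$times)), min(diff(lj_trace$times))) / 2
    j <- vapply(coul_trace$times, function(t) {
      k <- which.min(abs(lj_trace$times - t))
      if (abs(lj_trace$times[k] - t) > tol) NA_integer_ else k
    }, integer(1))
    if (anyNA(j)) stop("time grids differ beyond the nearest-time tolerance")
    lj_trace <- energy_trace(coul_trace$times, lj_trace$values[j],
                             lj_trace$pair, lj_trace$component)
  }
  el <- average_energy(coul_trace, window)
  vd <- average_energy(lj_trace, window)
  data.frame(pair = if (nzchar(coul_trace$pair)) coul_trace$pair else lj_trace$pair,
             kind = kind, electrostatic_kJ_mol = el, vdw_kJ_mol = vd,
             total_kJ_mol = el + vd, stringsAsFactors = FALSE)
}

#' Aggregate per-pair summaries into table totals
#'
#' @param rows data.frame of pair summaries (as from [summarize_pair()] or
#'   [sod_energy_table()]).
#' @return list with `rows` and `totals` (named vector: electrostatic, vdw,
#'   total). Zero rows give zero totals.
#' @export
aggregate_table <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L) {
    totals <- c(electrostatic = 0, vdw = 0, total = 0)
  } else {
    totals <- c(electrostatic = sum(rows$electrostatic_kJ_mol),
                vdw = sum(rows$vdw_kJ_mol),
                total = sum(rows$total_kJ_mol))
  }
  list(rows = rows, totals = totals)
}

#' Dominant energy component of a pair summary
#'
#' The component with the larger magnitude; ties go to vdW with a flag
#' (hydrophobic pairs are expected to be vdW-dominated, hydrogen bonds
#' electrostatics-dominated).
#'
#' @param summary one-row pair summary.
#' @return list with `component` (`"electrostatic"` or `"vdw"`) and `tie`.
#' @export
dominant_component <- function(summary) {
  el <- abs(summary$electrostatic_kJ_mol)
  vd <- abs(summary$vdw_kJ_mol)
  list(component = if (el > vd) "electrostatic" else "vdw", tie = el == vd)
}

#' Packaged per-pair energy summary tables
#'
#' The published average interaction energies over the steered pull:
#' table 1 holds the four hydrogen-bond residue pairs, table 2 the 25
#' hydrophobic pairs (kJ/mol).
#'
#' @param which 1 (hydrogen bonds), 2 (hydrophobic), or `"both"`.
#' @return data.frame with columns `pair`, `kind`, `electrostatic_kJ_mol`,
#'   `vdw_kJ_mol`, `total_kJ_mol`.
#' @export
sod_energy_table <- function(which = "both") {
  read1 <- function(f) utils::read.csv(
    system.file("extdata", f, package = "conflock", mustWork = TRUE),
    stringsAsFactors = FALSE)
  if (identical(which, 1) || identical(which, 1L)) return(read1("table1.csv"))
  if (identical(which, 2) || identical(which, 2L)) return(read1("table2.csv"))
  rbind(read1("table1.csv"), read1("table2.csv"))
}

#' Packaged conformational-lock group membership
#'
#' The published two-group partition of the 29 interface residue pairs:
#' group 1 (one hydrogen bond + seven hydrophobic pairs) lets go first,
#' group 2 (three hydrogen bonds + eighteen hydrophobic pairs) second.
#'
#' @return data.frame with columns `pair`, `group`.
#' @export
sod_lock_groups <- function() {
  utils::read.csv(system.file("extdata", "lock_groups.csv",
                              package = "conflock", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Read / write pair-summary CSV
#'
#' Column scheme `pair,kind,electrostatic_kJ_mol,vdw_kJ_mol,total_kJ_mol`.
#'
#' @param path CSV path.
#' @export
read_pair_summaries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair", "kind", "electrostatic_kJ_mol", "vdw_kJ_mol",
            "total_kJ_mol")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("summary CSV lacks columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_pair_summaries
#' @param rows data.frame of pair summaries.
#' @export
write_pair_summaries <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
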