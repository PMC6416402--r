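# Small structure builders and independent oracles used across the suite.

# Build a structure_model from compact vectors; coordinates in Angstrom.
make_structure <- function(name, element, resid, chain, resno, xyz,
                           het = FALSE, occupancy = 1) {
  n <- length(name)
  atoms <- data.frame(serial = seq_len(n), name = name, element = element,
                      resid = resid, chain = chain, resno = resno,
                      occupancy = rep_len(occupancy, n), b_factor = 0,
                      het = rep_len(het, n), stringsAsFactors = FALSE)
  structure_model(atoms, as.matrix(xyz))
}

# Two-chain 4-atom PDB text fixture (one Gly CA + O per chain).
tiny_pdb_lines <- function() {
  c("ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  O   GLY A   1       1.500   0.000   0.000  1.00  0.00           O",
    "ATOM      3  CA  GLY B   2      10.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY B   2      11.500   0.000   0.000  1.00  0.00           O")
}

# Naive all-pairs inter-chain hydrophobic scan: the oracle for the census.
brute_hydrophobic <- function(m, cutoff = 3.9, frame = 1) {
  a <- m$atoms
  xyz <- matrix(m$xyz[frame, , ], ncol = 3)
  keep <- !a$het & a$element %in% c("C", "S")
  ia <- which(keep & a$chain == "A"); ib <- which(keep & a$chain == "B")
  n_at <- 0L; pairs <- character()
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= cutoff) {
      n_at <- n_at + 1L
      pairs <- c(pairs, paste(
        sort(c(residue_label(a$resid[i], a$resno[i], a$chain[i]),
               residue_label(a$resid[j], a$resno[j], a$chain[j]))),
        collapse = "-"))
    }
  }
  list(n_atom = n_at, pairs = sort(unique(pairs)))
}

# Independent largest-gap grouping oracle: cut the sorted times at the
# (max_groups - 1) biggest internal gaps exceeding min_gap (ties: earlier).
brute_gap_groups <- function(times, min_gap = 50, max_groups = 4L) {
  ord <- order(times)
  st <- times[ord]
  gaps <- diff(st)
  eligible <- which(gaps > min_gap)
  if (length(eligible)) {
    take <- eligible[order(-gaps[eligible], eligible)]
    take <- sort(take[seq_len(min(length(take), max_groups - 1L))])
  } else take <- integer(0)
  lab_sorted <- cumsum(c(1L, as.integer(seq_along(gaps) %in% take)))
  lab <- integer(length(times))
  lab[ord] <- lab_sorted
  lab
}

# Wrap a bare rupture time in a rupture_event for grouping tests.
mk_event <- function(pair, time, baseline = -10) {
  structure(list(pair = pair, baseline_energy = baseline,
                 rupture_time = time, zero_time = time + 50),
            class = "rupture_event")
}

mk_summaries <- function(pairs, totals,
                         kinds = rep("hydrophobic", length(pairs))) {
  data.frame(pair = pairs, kind = kinds,
             electrostatic_kJ_mol = totals / 2, vdw_kJ_mol = totals / 2,
             total_kJ_mol = totals, stringsAsFactors = FALSE)
}
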