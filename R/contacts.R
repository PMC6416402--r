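# Hydrogen-bond donor/acceptor typing for standard residues, used when the
# structure carries no hydrogens (crystal structures) and bonds must be
# assigned on heavy-atom distance alone.
.HB_DONORS <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1"
)
.HB_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"),
  MET = "SD"
)
.SB_ANIONIC  <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.SB_CATIONIC <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                     HIS = c("ND1", "NE2"))

#' Contact-detection criteria
#'
#' Distance/angle thresholds for the interface census. Defaults follow the
#' published HBPLUS/LigPlot conventions: donor-acceptor heavy-atom distance
#' <= 3.35 A (hydrogen-acceptor <= 2.70 A with a D-H...A angle >= 90 deg
#' when hydrogens are present), apolar C/S atom contacts <= 3.90 A, and
#' charged-group centroid separation <= 0.6 nm for salt bridges.
#'
#' @param hbond_da_max donor-acceptor distance cutoff, Angstrom.
#' @param hbond_ha_max hydrogen-acceptor cutoff, Angstrom (used only when
#'   hydrogens are present).
#' @param hbond_angle_min minimum donor-hydrogen-acceptor angle, degrees.
#' @param hydrophobic_max apolar atom-atom cutoff, Angstrom.
#' @param salt_bridge_max_nm charged-group centroid cutoff, nm.
#' @return list of class `contact_criteria`.
#' @export
contact_criteria <- function(hbond_da_max = 3.35, hbond_ha_max = 2.70,
                             hbond_angle_min = 90, hydrophobic_max = 3.90,
                             salt_bridge_max_nm = 0.6) {
  stopifnot(hbond_da_max > 0, hbond_ha_max > 0, hydrophobic_max > 0,
            salt_bridge_max_nm > 0)
  structure(list(hbond_da_max = hbond_da_max, hbond_ha_max = hbond_ha_max,
                 hbond_angle_min = hbond_angle_min,
                 hydrophobic_max = hydrophobic_max,
                 salt_bridge_max_nm = salt_bridge_max_nm),
            class = "contact_criteria")
}

#' Orientation-insensitive residue-pair key
#'
#' Pair labels such as `"Ile149B-Gly112A"` vs `"Gly112A-Ile149B"` name the
#' same unordered residue pair; this canonicalizes them by sorting the two
#' residue labels.
#'
#' @param pair character vector of `"<res>-<res>"` labels.
#' @export
pair_key <- function(pair) {
  vapply(strsplit(pair, "-"), function(s) paste(sort(s), collapse = "-"), "")
}

.empty_contacts <- function() {
  data.frame(residue_a = character(), residue_b = character(),
             kind = character(), atom_a = character(), atom_b = character(),
             distance = numeric(), stringsAsFactors = FALSE)
}

# Per-chain atom table with coordinates and residue labels for one frame.
.chain_table <- function(structure, chain, frame) {
  idx <- .chain_idx(structure, chain, include_het = FALSE)
  a <- structure$atoms[idx, , drop = FALSE]
  a$x <- .frame_xyz(structure, frame, idx)[, 1]
  a$y <- .frame_xyz(structure, frame, idx)[, 2]
  a$z <- .frame_xyz(structure, frame, idx)[, 3]
  a$label <- residue_label(a$resid, a$resno, a$chain)
  a
}

.cross_dist <- function(ta, tb, ia, ib) {
  pa <- cbind(ta$x, ta$y, ta$z)[ia, , drop = FALSE]
  pb <- cbind(tb$x, tb$y, tb$z)[ib, , drop = FALSE]
  dx <- outer(pa[, 1], pb[, 1], "-")
  dy <- outer(pa[, 2], pb[, 2], "-")
  dz <- outer(pa[, 3], pb[, 3], "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

.atom_is <- function(tab, typing) {
  hit <- tab$name %in% typing$backbone & !(tab$resid == "PRO" &
                                           identical(typing$backbone, "N"))
  for (res in setdiff(names(typing), "backbone"))
    hit <- hit | (tab$resid == res & tab$name %in% typing[[res]])
  hit
}

.has_hydrogens <- function(structure) any(structure$atoms$element == "H" &
                                          !structure$atoms$het)

#' Detect inter-chain hydrogen bonds
#'
#' Donor-acceptor N/O (and Met S acceptor) pairs across the two chains
#' within the distance criteria; when the structure carries hydrogens, the
#' hydrogen-acceptor distance and D-H...A angle are also enforced.
#'
#' @param structure a `structure_model`.
#' @param chain_a,chain_b chain identifiers (records report the `chain_a`
#'   residue first).
#' @param criteria a [contact_criteria()].
#' @param frame frame index.
#' @return data.frame of contact records (`residue_a`, `residue_b`, `kind`,
#'   `atom_a`, `atom_b`, `distance` in Angstrom), one row per atom pair.
#' @export
detect_hydrogen_bonds <- function(structure, chain_a = "A", chain_b = "B",
                                  criteria = contact_criteria(), frame = 1L) {
  ta <- .chain_table(structure, chain_a, frame)
  tb <- .chain_table(structure, chain_b, frame)
  use_h <- .has_hydrogens(structure)
  one_way <- function(td, tacc) {
    id <- which(.atom_is(td, .HB_DONORS) & td$element %in% c("N", "O"))
    ia <- which(.atom_is(tacc, .HB_ACCEPTORS))
    if (!length(id) || !length(ia)) return(NULL)
    d <- .cross_dist(td, tacc, id, ia)
    hit <- which(d <= criteria$hbond_da_max, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    out <- data.frame(
      donor_label = td$label[id[hit[, 1]]], donor_atom = td$name[id[hit[, 1]]],
      acc_label = tacc$label[ia[hit[, 2]]], acc_atom = tacc$name[ia[hit[, 2]]],
      distance = d[hit], di = id[hit[, 1]], ai = ia[hit[, 2]],
      stringsAsFactors = FALSE)
    if (use_h) {
      ok <- vapply(seq_len(nrow(out)), function(k) {
        don <- td[out$di[k], ]
        hs <- td[td$element == "H" & td$label == don$label, , drop = FALSE]
        if (!nrow(hs)) return(TRUE)  # donor without explicit H: distance rule
        dp <- c(don$x, don$y, don$z)
        hd <- sqrt((hs$x - dp[1])^2 + (hs$y - dp[2])^2 + (hs$z - dp[3])^2)
        hs <- hs[hd <= 1.25, , drop = FALSE]
        if (!nrow(hs)) return(TRUE)
        ap <- unlist(tacc[out$ai[k], c("x", "y", "z")])
        any(vapply(seq_len(nrow(hs)), function(j) {
          hp <- c(hs$x[j], hs$y[j], hs$z[j])
          ha <- sqrt(sum((hp - ap)^2))
          v1 <- dp - hp; v2 <- ap - hp
          ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          ha <= criteria$hbond_ha_max && ang >= criteria$hbond_angle_min
        }, logical(1)))
      }, logical(1))
      out <- out[ok, , drop = FALSE]
    }
    out
  }
  ab <- one_way(ta, tb)  # donor on A
  ba <- one_way(tb, ta)  # donor on B
  rows <- list()
  if (!is.null(ab) && nrow(ab))
    rows[[1]] <- data.frame(residue_a = ab$donor_label, residue_b = ab$acc_label,
                            kind = "hydrogen_bond", atom_a = ab$donor_atom,
                            atom_b = ab$acc_atom, distance = ab$distance,
                            stringsAsFactors = FALSE)
  if (!is.null(ba) && nrow(ba))
    rows[[2]] <- data.frame(residue_a = ba$acc_label, residue_b = ba$donor_label,
                            kind = "hydrogen_bond", atom_a = ba$acc_atom,
                            atom_b = ba$donor_atom, distance = ba$distance,
                            stringsAsFactors = FALSE)
  if (!length(rows)) return(.empty_contacts())
  out <- do.call(rbind, rows)
  out[order(out$residue_a, out$residue_b, out$distance), , drop = FALSE]
}

#' Detect inter-chain hydrophobic contacts
#'
#' Apolar (carbon or sulfur) atom pairs across the chains within the
#' hydrophobic cutoff; the residue-level collapse counts each unordered
#' residue pair once regardless of atom multiplicity.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return data.frame of atom-level contact records.
#' @export
detect_hydrophobic_contacts <- function(structure, chain_a = "A",
                                        chain_b = "B",
                                        criteria = contact_criteria(),
                                        frame = 1L) {
  ta <- .chain_table(structure, chain_a, frame)
  tb <- .chain_table(structure, chain_b, frame)
  ia <- which(ta$element %in% c("C", "S"))
  ib <- which(tb$element %in% c("C", "S"))
  if (!length(ia) || !length(ib)) return(.empty_contacts())
  d <- .cross_dist(ta, tb, ia, ib)
  hit <- which(d <= criteria$hydrophobic_max, arr.ind = TRUE)
  if (!nrow(hit)) return(.empty_contacts())
  out <- data.frame(
    residue_a = ta$label[ia[hit[, 1]]], residue_b = tb$label[ib[hit[, 2]]],
    kind = "hydrophobic",
    atom_a = ta$name[ia[hit[, 1]]], atom_b = tb$name[ib[hit[, 2]]],
    distance = d[hit], stringsAsFactors = FALSE)
  out[order(out$residue_a, out$residue_b, out$distance), , drop = FALSE]
}

#' Detect inter-chain salt bridges
#'
#' Distance between the anionic-group centroid (Asp/Glu carboxylate oxygens)
#' and the cationic-group centroid (Lys NZ, Arg guanidinium N, His ring N)
#' across the chains. Residues with missing side-chain atoms are skipped
#' with a warning. The default 0.6 nm cutoff is the one under which the
#' dimer's only inter-chain candidate (Asp11-Lys9) is excluded.
#'
#' @inheritParams detect_hydrogen_bonds
#' @param cutoff_nm centroid-centroid cutoff in nm.
#' @return data.frame of contact records (distance in Angstrom; `atom_a`,
#'   `atom_b` name the charged groups).
#' @export
detect_salt_bridges <- function(structure, chain_a = "A", chain_b = "B",
                                cutoff_nm = contact_criteria()$salt_bridge_max_nm,
                                frame = 1L) {
  stopifnot(cutoff_nm > 0)
  group_centroids <- function(tab, typing) {
    rows <- list()
    for (res in names(typing)) {
      sub <- tab[tab$resid == res, , drop = FALSE]
      for (lab in unique(sub$label)) {
        at <- sub[sub$label == lab & sub$name %in% typing[[res]], ,
                  drop = FALSE]
        if (!nrow(at)) {
          warning("salt-bridge group atoms missing for ", lab, "; skipped",
                  call. = FALSE)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          label = lab, group = paste(typing[[res]], collapse = "/"),
          x = mean(at$x), y = mean(at$y), z = mean(at$z),
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
  }
  ta <- .chain_table(structure, chain_a, frame)
  tb <- .chain_table(structure, chain_b, frame)
  pairs_for <- function(an, cat, flip) {
    if (is.null(an) || is.null(cat)) return(NULL)
    out <- NULL
    for (i in seq_len(nrow(an))) for (j in seq_len(nrow(cat))) {
      d <- sqrt((an$x[i] - cat$x[j])^2 + (an$y[i] - cat$y[j])^2 +
                (an$z[i] - cat$z[j])^2)
      if (d <= cutoff_nm * 10) {
        row <- data.frame(
          residue_a = if (flip) cat$label[j] else an$label[i],
          residue_b = if (flip) an$label[i] else cat$label[j],
          kind = "salt_bridge",
          atom_a = if (flip) cat$group[j] else an$group[i],
          atom_b = if (flip) an$group[i] else cat$group[j],
          distance = d, stringsAsFactors = FALSE)
        out <- rbind(out, row)
      }
    }
    out
  }
  res <- rbind(
    pairs_for(group_centroids(ta, .SB_ANIONIC),
              group_centroids(tb, .SB_CATIONIC), flip = FALSE),
    pairs_for(group_centroids(tb, .SB_ANIONIC),
              group_centroids(ta, .SB_CATIONIC), flip = TRUE))
  if (is.null(res) || !nrow(res)) return(.empty_contacts())
  res[order(res$residue_a, res$residue_b), , drop = FALSE]
}

#' Full interface contact census
#'
#' Composes the three detectors and tallies the counts the interface story
#' is told in: hydrogen-bond residue pairs, hydrophobic atom contacts and
#' their residue-pair collapse, and salt bridges.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return list of class `contact_census` with elements `contacts` (all
#'   records), `n_hbond_pairs`, `n_hydrophobic_atom_contacts`,
#'   `n_hydrophobic_residue_pairs`, `n_salt_bridges`, plus the deduplicated
#'   residue-pair tables `hbond_pairs` and `hydrophobic_pairs`.
#' @export
interface_census <- function(structure, chain_a = "A", chain_b = "B",
                             criteria = contact_criteria(), frame = 1L) {
  hb <- detect_hydrogen_bonds(structure, chain_a, chain_b, criteria, frame)
  ph <- detect_hydrophobic_contacts(structure, chain_a, chain_b, criteria, frame)
  sb <- detect_salt_bridges(structure, chain_a, chain_b,
                            criteria$salt_bridge_max_nm, frame)
  pair_key <- function(df) unique(paste(df$residue_a, df$residue_b, sep = "-"))
  census <- list(
    contacts = rbind(hb, ph, sb),
    hbond_pairs = pair_key(hb),
    hydrophobic_pairs = pair_key(ph),
    n_hbond_pairs = length(pair_key(hb)),
    n_hydrophobic_atom_contacts = nrow(ph),
    n_hydrophobic_residue_pairs = length(pair_key(ph)),
    n_salt_bridges = nrow(sb),
    chain_a = chain_a, chain_b = chain_b, criteria = criteria)
  class(census) <- "contact_census"
  census
}

#' @export
print.contact_census <- function(x, ...) {
  cat("Interface census (", x$chain_a, "-", x$chain_b, "):\n", sep = "")
  cat("  hydrogen-bond residue pairs: ", x$n_hbond_pairs, "\n")
  cat("  hydrophobic atom contacts:   ", x$n_hydrophobic_atom_contacts, "\n")
  cat("  hydrophobic residue pairs:   ", x$n_hydrophobic_residue_pairs, "\n")
  cat("  salt bridges:                ", x$n_salt_bridges, "\n")
  invisible(x)
}

#' Write a contact census to CSV
#' @param census a `contact_census`.
#' @param path output CSV path (columns
#'   `residue_a,residue_b,kind,atom_a,atom_b,distance_A`).
#' @export
write_census_csv <- function(census, path) {
  df <- census$contacts
  names(df)[names(df) == "distance"] <- "distance_A"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
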