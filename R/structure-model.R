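#' conflock: conformational-lock analysis of dimeric enzyme interfaces
#'
#' Classify inter-chain contacts from structure, aggregate per-residue-pair
#' interaction-energy traces from steered pulls, detect rupture epochs and
#' group residue pairs into conformational locks, and estimate lock counts
#' from residual-activity kinetics. A parametric trace generator and a 1-D
#' constant-velocity pull simulator stand in for the MD engine.
#'
#' @keywords internal
"_PACKAGE"

# Standard atomic weights (Da) for the elements that occur in protein PDB
# files plus the common metals/ions. Unknown elements fall back to carbon.
.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, CU = 63.546, ZN = 65.38, FE = 55.845, MG = 24.305,
  "NA" = 22.990, CL = 35.45, K = 39.098, CA = 40.078, MN = 54.938,
  I = 126.904
)

#' Atomic mass lookup
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in Da. Unknown symbols get the carbon
#'   mass with a warning.
#' @export
atomic_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .ATOMIC_MASS[key]
  bad <- is.na(m)
  if (any(bad)) {
    warning("unknown element(s) ", paste(unique(key[bad]), collapse = ", "),
            "; using carbon mass", call. = FALSE)
    m[bad] <- .ATOMIC_MASS[["C"]]
  }
  unname(m)
}

# Derive an element symbol from a PDB atom name when the element column is
# blank: strip digits/primes, take the leading alphabetic part; two-letter
# metals are only trusted when given in the element field, so "CA" -> C etc.
.element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  el <- toupper(substr(nm, 1, 1))
  el[el == ""] <- "C"
  el
}

#' Construct a structure model
#'
#' A `structure_model` holds an atom table and one or more coordinate frames
#' (a multi-model PDB read as a toy trajectory). Coordinates are stored in
#' Angstrom; geometric accessors report nm.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `resid`
#'   (3-letter code), `chain`, `resno`, `occupancy`, `b_factor`, `het`
#'   (logical HETATM flag).
#' @param xyz numeric array `n_frames x n_atoms x 3` (Angstrom), or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param header optional identifier string.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, xyz, header = "") {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "element", "resid", "chain", "resno")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(1L, nrow(xyz), 3L))
  if (length(dim(xyz)) != 3L || dim(xyz)[3] != 3L)
    stop("xyz must be an n_frames x n_atoms x 3 array")
  if (dim(xyz)[2] != nrow(atoms))
    stop("frame atom count (", dim(xyz)[2], ") != atom table rows (", nrow(atoms), ")")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (nrow(atoms) < 1L) stop("empty structure: no atoms")
  if (any(!nzchar(atoms$chain))) stop("empty chain identifier")
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$b_factor)) atoms$b_factor <- 0
  if (is.null(atoms$het)) atoms$het <- FALSE
  atoms$mass <- atomic_mass(atoms$element)
  structure(list(atoms = atoms, xyz = xyz, header = header),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(chains(x)), "chain(s),", n_frames(x), "frame(s)\n")
  if (nzchar(x$header)) cat("  header:", x$header, "\n")
  het <- sum(x$atoms$het)
  if (het) cat("  HETATM (flagged, excluded from interface analysis):", het, "\n")
  invisible(x)
}

#' Number of coordinate frames
#' @param structure a `structure_model`.
#' @export
n_frames <- function(structure) dim(structure$xyz)[1]

#' Chain identifiers, in deterministic (sorted) order
#' @param structure a `structure_model`.
#' @export
chains <- function(structure) sort(unique(structure$atoms$chain))

# Indices of the atoms of one chain; by default HETATM are excluded, matching
# the removal of the Cu/Zn ligands before interface analysis.
.chain_idx <- function(structure, chain, include_het = FALSE) {
  a <- structure$atoms
  keep <- a$chain == chain
  if (!include_het) keep <- keep & !a$het
  idx <- which(keep)
  if (!length(idx)) stop("chain '", chain, "' not found (or HETATM-only)")
  idx
}

.frame_xyz <- function(structure, frame = 1L, idx = NULL) {
  if (frame < 1L || frame > n_frames(structure))
    stop("frame ", frame, " out of range 1..", n_frames(structure))
  m <- structure$xyz[frame, , , drop = TRUE]
  m <- matrix(m, ncol = 3L)
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Mass-weighted center of mass of a chain
#'
#' @param structure a `structure_model`.
#' @param chain chain identifier.
#' @param frame frame index (default 1).
#' @param include_het include HETATM records (default FALSE).
#' @return length-3 numeric vector in nm.
#' @export
center_of_mass <- function(structure, chain, frame = 1L, include_het = FALSE) {
  idx <- .chain_idx(structure, chain, include_het)
  m <- structure$atoms$mass[idx]
  xyz <- .frame_xyz(structure, frame, idx)
  drop(crossprod(xyz, m)) / sum(m) / 10  # Angstrom -> nm
}

#' Distance between chain centers of mass
#'
#' The pulling reaction coordinate: in the published pull it rises from
#' 2.82 nm at the start to 6.83 nm at full separation.
#'
#' @inheritParams center_of_mass
#' @param chain_a,chain_b the two chains.
#' @return distance in nm (symmetric in its chain arguments).
#' @export
com_distance <- function(structure, chain_a, chain_b, frame = 1L,
                         include_het = FALSE) {
  d <- center_of_mass(structure, chain_a, frame, include_het) -
    center_of_mass(structure, chain_b, frame, include_het)
  sqrt(sum(d^2))
}

#' Time course of the chain-chain COM separation over all frames
#' @inheritParams com_distance
#' @return numeric vector, one nm distance per frame.
#' @export
com_distance_profile <- function(structure, chain_a = "A", chain_b = "B",
                                 include_het = FALSE) {
  vapply(seq_len(n_frames(structure)), function(f)
    com_distance(structure, chain_a, chain_b, f, include_het), numeric(1))
}

# Atom-selection predicate used by rmsd(): "calpha" (default, CA of standard
# residues), "backbone" (N/CA/C/O), "all" (non-HETATM), or a logical vector.
.selection_idx <- function(structure, selection) {
  a <- structure$atoms
  if (is.logical(selection)) {
    stopifnot(length(selection) == nrow(a))
    return(which(selection))
  }
  sel <- match.arg(selection, c("calpha", "backbone", "all"))
  keep <- !a$het & switch(sel,
    calpha   = a$name == "CA" & a$element == "C",
    backbone = a$name %in% c("N", "CA", "C", "O"),
    all      = TRUE)
  which(keep)
}

#' Root-mean-square deviation between two frames
#'
#' With `fit = TRUE` the mobile frame is first superposed on the reference by
#' optimal least squares (Kabsch, via bio3d); degenerate selections (< 3
#' atoms or collinear) fall back to the unfitted RMSD with a warning.
#'
#' @param structure a `structure_model`.
#' @param frame mobile frame index.
#' @param reference reference frame index (default 1).
#' @param selection `"calpha"` (default), `"backbone"`, `"all"`, or a logical
#'   atom mask.
#' @param fit superpose before measuring (default TRUE).
#' @return RMSD in nm; 0 for identical frames.
#' @export
rmsd <- function(structure, frame, reference = 1L, selection = "calpha",
                 fit = TRUE) {
  idx <- .selection_idx(structure, selection)
  if (!length(idx)) stop("empty atom selection")
  ref <- .frame_xyz(structure, reference, idx)
  mob <- .frame_xyz(structure, frame, idx)
  rmsd_xyz(ref, mob, fit = fit)
}

#' RMSD between two coordinate sets
#'
#' @param ref,mob `n x 3` matrices in Angstrom, equal `n`.
#' @param fit apply Kabsch superposition first.
#' @return RMSD in nm.
#' @export
rmsd_xyz <- function(ref, mob, fit = TRUE) {
  ref <- as.matrix(ref); mob <- as.matrix(mob)
  if (!identical(dim(ref), dim(mob)))
    stop("selection shape mismatch: ", nrow(ref), " vs ", nrow(mob), " atoms")
  if (fit) {
    degenerate <- nrow(ref) < 3L
    if (!degenerate) {
      sv <- svd(scale(ref, scale = FALSE), nu = 0, nv = 0)$d
      degenerate <- sv[2] < 1e-8 * max(sv[1], 1e-12)
    }
    if (degenerate) {
      warning("degenerate selection (<3 atoms or collinear); no-fit RMSD",
              call. = FALSE)
    } else {
      inds <- bio3d::atom2xyz(seq_len(nrow(ref)))
      mob <- matrix(bio3d::fit.xyz(fixed = as.vector(t(ref)),
                                   mobile = as.vector(t(mob)),
                                   fixed.inds = inds, mobile.inds = inds),
                    ncol = 3L, byrow = TRUE)
    }
  }
  sqrt(mean(rowSums((ref - mob)^2))) / 10  # Angstrom -> nm
}

#' RMSD of every frame to a reference frame
#' @inheritParams rmsd
#' @return numeric vector of nm RMSD values, one per frame.
#' @export
rmsd_profile <- function(structure, reference = 1L, selection = "calpha",
                         fit = TRUE) {
  vapply(seq_len(n_frames(structure)), function(f)
    rmsd(structure, f, reference, selection, fit), numeric(1))
}

## ---- residue labels ------------------------------------------------------

.title_case <- function(x) {
  x <- tolower(x)
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

#' Canonical residue label
#'
#' Residues are labelled residue-name + sequence number + chain, e.g.
#' `"Ile149A"`, the convention used throughout the pair tables.
#'
#' @param resid 3-letter residue code.
#' @param resno residue sequence number.
#' @param chain chain identifier.
#' @export
residue_label <- function(resid, resno, chain) {
  paste0(.title_case(resid), resno, chain)
}

#' Parse a residue label back into its parts
#' @param label label such as `"Gly49B"`.
#' @return data.frame with columns `resid` (upper-case 3-letter code),
#'   `resno`, `chain`.
#' @export
parse_residue_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z0-9])$", label))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("unparseable residue label(s): ",
                     paste(label[bad], collapse = ", "))
  data.frame(resid = toupper(vapply(m, `[`, "", 2L)),
             resno = as.integer(vapply(m, `[`, "", 3L)),
             chain = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

## ---- PDB I/O -------------------------------------------------------------

#' Read a PDB file into a structure model
#'
#' Parsing is delegated to [bio3d::read.pdb()] after a fixed-column sanity
#' scan that reports the first malformed ATOM/HETATM line. HETATM records
#' (metals, ligands, waters) are retained but flagged and excluded from
#' interface analysis by default. Alternate locations keep the highest
#' occupancy (ties: first encountered). Multi-model files become multi-frame
#' toy trajectories.
#'
#' @param path PDB file path.
#' @return a [structure_model()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(rec == "ATOM  ")) stop("empty structure: no ATOM records in ", path)
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record at line ", i, ": too short")
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (any(is.na(coords)))
      stop("malformed ATOM/HETATM record at line ", i,
           ": non-numeric coordinate field")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  xyz <- pdb$xyz  # frames x 3n
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)

  # alt-loc resolution: within (chain, resno, insert, name) keep the highest
  # occupancy record, first encountered on ties
  alt <- !is.na(a$alt) & nzchar(a$alt)
  if (any(alt)) {
    key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
    o <- ifelse(is.na(a$o), 1, a$o)
    ord <- order(key, -o, seq_len(nrow(a)))
    keep_first <- !duplicated(key[ord])
    keep <- sort(ord[keep_first])
    a <- a[keep, , drop = FALSE]
    xyz <- xyz[, as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep)),
               drop = FALSE]
  }

  el <- toupper(trimws(ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                              "", a$elesy)))
  blank <- !nzchar(el)
  el[blank] <- .element_from_name(a$elety[blank])
  # drop hydrogens? keep: crystal structures rarely have them, detectors
  # handle their absence.
  chain <- ifelse(is.na(a$chain) | !nzchar(a$chain), "A", a$chain)
  atoms <- data.frame(
    serial = a$eleno, name = trimws(a$elety), element = el,
    resid = trimws(a$resid), chain = chain, resno = a$resno,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b_factor = ifelse(is.na(a$b), 0, a$b),
    het = a$type == "HETATM", stringsAsFactors = FALSE)
  nfr <- nrow(xyz)
  arr <- array(NA_real_, dim = c(nfr, nrow(atoms), 3L))
  for (f in seq_len(nfr)) arr[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  structure_model(atoms, arr, header = basename(path))
}

#' Write a structure model to a PDB file
#'
#' Multi-frame models are written as MODEL/ENDMDL blocks so the file
#' round-trips through [read_pdb()] as a toy trajectory.
#'
#' @param structure a `structure_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  nfr <- n_frames(structure)
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(structure$header))
    writeLines(sprintf("REMARK   1 %s", structure$header), con)
  fmt_atom <- function(i, xyz) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (a$het[i]) "HETATM" else "ATOM",
            a$serial[i] %% 100000,
            if (nchar(a$name[i]) < 4) paste0(" ", a$name[i]) else a$name[i],
            " ", substr(a$resid[i], 1, 3), substr(a$chain[i], 1, 1),
            a$resno[i] %% 10000, " ",
            xyz[i, 1], xyz[i, 2], xyz[i, 3],
            a$occupancy[i], a$b_factor[i], a$element[i])
  }
  for (f in seq_len(nfr)) {
    if (nfr > 1L) writeLines(sprintf("MODEL %8d", f), con)
    xyz <- .frame_xyz(structure, f)
    writeLines(vapply(seq_len(nrow(a)), fmt_atom, "", xyz = xyz), con)
    if (nfr > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
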