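# Amber topology input pipeline: prmtop/inpcrd readers in the %VERSION /
# %FLAG / %FORMAT fixed-width layout, a minimal PDB reader/writer, and the
# builder that turns a parsed topology into an mm_system. Unit conventions:
# prmtop charges carry the Amber scale 18.2223 (kcal-A electrostatics),
# energies are kcal/mol (x 4.184 to kJ/mol), lengths Angstrom (x 0.1 to nm),
# angles already radians.

AMBER_CHARGE_SCALE <- 18.2223
KCAL_TO_KJ <- 4.184

parse_format <- function(fmt) {
  m <- regmatches(fmt, regexec(
    "\\(?([0-9]*)([aIEFGiefg])([0-9]+)(?:\\.([0-9]+))?\\)?", fmt))[[1]]
  if (length(m) == 0) stop(sprintf("unparseable FORMAT '%s'", fmt))
  list(count = if (nzchar(m[2])) as.integer(m[2]) else 1L,
       type = toupper(m[3]),
       width = as.integer(m[4]))
}

split_fixed <- function(lines, width) {
  unlist(lapply(lines, function(ln) {
    n <- nchar(ln)
    if (n == 0L) return(character(0))
    starts <- seq(1L, n, by = width)
    substring(ln, starts, pmin(starts + width - 1L, n))
  }))
}

#' Read an Amber prmtop topology file
#'
#' Parses every \code{\%FLAG} section according to its \code{\%FORMAT}
#' record. Returns the raw sections plus decoded convenience fields (atom
#' count, unscaled charges in e, masses, bond/angle/dihedral tables with
#' the Amber index/3 convention resolved to 1-based atom indices).
#'
#' @param path file path.
#' @return an object of class \code{mm_prmtop}.
#' @export
read_prmtop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  flag_rows <- grep("^%FLAG", lines)
  if (length(flag_rows) == 0) stop("not a prmtop file (no %FLAG sections)")
  sections <- list()
  bounds <- c(flag_rows, length(lines) + 1L)
  for (k in seq_along(flag_rows)) {
    name <- trimws(sub("^%FLAG\\s+", "", lines[flag_rows[k]]))
    body <- lines[(flag_rows[k] + 1L):(bounds[k + 1L] - 1L)]
    fmt_row <- grep("^%FORMAT", body)
    if (length(fmt_row) == 0)
      stop(sprintf("section %s lacks a %%FORMAT record", name))
    fmt <- parse_format(sub("^%FORMAT", "", body[fmt_row[1]]))
    data_lines <- body[-seq_len(fmt_row[1])]
    data_lines <- data_lines[!grepl("^%", data_lines)]
    raw <- split_fixed(data_lines, fmt$width)
    sections[[name]] <- if (fmt$type == "A") {
      trimws(raw)
    } else {
      vals <- suppressWarnings(as.numeric(raw))
      if (any(is.na(vals) & nzchar(trimws(raw))))
        stop(sprintf("malformed fixed-width field in section %s", name))
      vals[!is.na(vals)]
    }
  }
  need <- c("POINTERS", "CHARGE", "MASS")
  missing <- setdiff(need, names(sections))
  if (length(missing) > 0)
    stop(sprintf("missing mandatory flag(s): %s",
                 paste(missing, collapse = ", ")))
  ptr <- as.integer(sections$POINTERS)
  natom <- ptr[1]
  decode_bonded <- function(vals, stride) {
    if (is.null(vals) || length(vals) == 0)
      return(matrix(numeric(0), 0, stride))
    m <- matrix(vals, ncol = stride, byrow = TRUE)
    # Amber stores 3*(index-1); sign carries the improper/exclusion markers
    atoms <- m[, -stride, drop = FALSE]
    atoms <- sign(atoms) * (abs(atoms) / 3) + ifelse(atoms >= 0, 1, -1)
    cbind(atoms, m[, stride])
  }
  structure(list(
    sections = sections,
    pointers = ptr,
    natom = natom,
    atom_names = sections$ATOM_NAME,
    masses = sections$MASS,
    charges = sections$CHARGE / AMBER_CHARGE_SCALE,
    atom_type_index = as.integer(sections$ATOM_TYPE_INDEX),
    bonds_h = decode_bonded(sections$BONDS_INC_HYDROGEN, 3L),
    bonds_a = decode_bonded(sections$BONDS_WITHOUT_HYDROGEN, 3L),
    angles_h = decode_bonded(sections$ANGLES_INC_HYDROGEN, 4L),
    angles_a = decode_bonded(sections$ANGLES_WITHOUT_HYDROGEN, 4L),
    dihedrals_h = decode_bonded(sections$DIHEDRALS_INC_HYDROGEN, 5L),
    dihedrals_a = decode_bonded(sections$DIHEDRALS_WITHOUT_HYDROGEN, 5L),
    has_box = length(ptr) >= 28 && ptr[28] > 0),
    class = "mm_prmtop")
}

#' @export
print.mm_prmtop <- function(x, ...) {
  cat("<prmtop>", x$natom, "atoms,",
      nrow(x$bonds_h) + nrow(x$bonds_a), "bonds,",
      nrow(x$angles_h) + nrow(x$angles_a), "angles,",
      nrow(x$dihedrals_h) + nrow(x$dihedrals_a), "dihedral terms\n")
  invisible(x)
}

#' Read an Amber inpcrd/restart coordinate file
#'
#' @param path file path.
#' @return list with \code{positions} (N x 3, nm), optional
#'   \code{velocities}, and \code{box} (an \code{mm_box}) when present.
#' @export
read_inpcrd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  natom <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]][1])
  vals <- suppressWarnings(as.numeric(split_fixed(lines[-(1:2)], 12L)))
  vals <- vals[!is.na(vals)]
  npos <- 3L * natom
  if (length(vals) < npos)
    stop("coordinate count does not match the atom count in the header")
  positions <- matrix(vals[seq_len(npos)], ncol = 3, byrow = TRUE) * 0.1
  rest <- vals[-seq_len(npos)]
  velocities <- NULL
  box <- NULL
  if (length(rest) >= npos) {
    # restart velocities are in A/(1/20.455 ps); convert to nm/ps
    velocities <- matrix(rest[seq_len(npos)], ncol = 3, byrow = TRUE) *
      0.1 * 20.455
    rest <- rest[-seq_len(npos)]
  }
  if (length(rest) >= 6) {
    la <- rest[1] * 0.1; lb <- rest[2] * 0.1; lc <- rest[3] * 0.1
    al <- rest[4] * pi / 180; be <- rest[5] * pi / 180; ga <- rest[6] * pi / 180
    av <- c(la, 0, 0)
    bv <- c(lb * cos(ga), lb * sin(ga), 0)
    cx <- lc * cos(be)
    cy <- lc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
    cv <- c(cx, cy, sqrt(lc^2 - cx^2 - cy^2))
    box <- reduce_box(av, bv, cv)
  }
  list(positions = positions, velocities = velocities, box = box)
}

# Lennard-Jones sigma (nm) and epsilon (kJ/mol) per atom from the diagonal
# A/B coefficients of the prmtop type tables
prmtop_lj_per_atom <- function(prmtop) {
  s <- prmtop$sections
  ntypes <- prmtop$pointers[2]
  nbidx <- as.integer(s$NONBONDED_PARM_INDEX)
  A <- s$LENNARD_JONES_ACOEF
  B <- s$LENNARD_JONES_BCOEF
  ti <- prmtop$atom_type_index
  diag_idx <- nbidx[ntypes * (ti - 1L) + ti]
  Ai <- A[diag_idx]; Bi <- B[diag_idx]
  sigma <- ifelse(Bi > 0, (Ai / Bi)^(1 / 6) * 0.1, 0.1)
  epsilon <- ifelse(Bi > 0, Bi * Bi / (4 * Ai) * KCAL_TO_KJ, 0)
  list(sigma = sigma, epsilon = epsilon)
}

# excluded pairs from NUMBER_EXCLUDED_ATOMS / EXCLUDED_ATOMS_LIST
prmtop_exclusions <- function(prmtop) {
  s <- prmtop$sections
  counts <- as.integer(s$NUMBER_EXCLUDED_ATOMS)
  listed <- as.integer(s$EXCLUDED_ATOMS_LIST)
  out <- matrix(integer(0), 0, 2)
  pos <- 0L
  pairs <- list()
  for (i in seq_len(prmtop$natom)) {
    if (counts[i] > 0L) {
      js <- listed[pos + seq_len(counts[i])]
      pos <- pos + counts[i]
      js <- js[js > 0L]            # 0 is the "no exclusions" placeholder
      if (length(js) > 0L)
        pairs[[length(pairs) + 1L]] <- cbind(i, js)
    }
  }
  if (length(pairs) > 0L) out <- do.call(rbind, pairs)
  out
}

# 1-4 exception pairs from the dihedral records (positive third and fourth
# index); duplicates collapsed so each 1-4 pair is counted once
prmtop_exceptions <- function(prmtop, charges, sigma, epsilon) {
  s <- prmtop$sections
  dihedrals <- rbind(prmtop$dihedrals_h, prmtop$dihedrals_a)
  if (nrow(dihedrals) == 0L)
    return(data.frame(i = integer(0), j = integer(0),
                      chargeprod = numeric(0), sigma = numeric(0),
                      epsilon = numeric(0)))
  nptra <- prmtop$pointers[18]
  scee <- s$SCEE_SCALE_FACTOR
  scnb <- s$SCNB_SCALE_FACTOR
  if (is.null(scee)) scee <- rep(1.2, nptra)
  if (is.null(scnb)) scnb <- rep(2.0, nptra)
  keep <- dihedrals[, 3] > 0 & dihedrals[, 4] > 0
  d14 <- dihedrals[keep, , drop = FALSE]
  if (nrow(d14) == 0L)
    return(data.frame(i = integer(0), j = integer(0),
                      chargeprod = numeric(0), sigma = numeric(0),
                      epsilon = numeric(0)))
  i <- abs(d14[, 1]); l <- abs(d14[, 4]); idx <- d14[, 5]
  key <- paste(pmin(i, l), pmax(i, l))
  first <- !duplicated(key)
  i <- i[first]; l <- l[first]; idx <- idx[first]
  data.frame(i = i, j = l,
             chargeprod = charges[i] * charges[l] / scee[idx],
             sigma = 0.5 * (sigma[i] + sigma[l]),
             epsilon = sqrt(epsilon[i] * epsilon[l]) / scnb[idx])
}

#' Build a simulation system from a parsed Amber topology
#'
#' Creates the standard Amber-form bonded terms (with kcal/Angstrom native
#' units converted to kJ/nm), the Lennard-Jones + Coulomb nonbonded term
#' with the topology's exclusions and 1/SCEE, 1/SCNB scaled 1-4 exceptions
#' (defaults 1.2 and 2.0 when those sections are absent), and optionally
#' the OBC1 implicit-solvent term from the topology's GB radii and
#' screening factors. Bonds selected by the \code{constraints} option are
#' converted to rigid constraints and their harmonic terms removed.
#'
#' Explicit-solvent electrostatics (PME) is not supported; requesting it is
#' an error rather than an approximation.
#'
#' @param prmtop an \code{mm_prmtop} from \code{\link{read_prmtop}}.
#' @param solvent "vacuum" or "obc1" (or "pme", which errors).
#' @param constraints "none", "h_bonds", or "all_bonds".
#' @param sa_term logical, add the ACE surface-area term to OBC.
#' @param box optional \code{mm_box} (e.g. from the inpcrd).
#' @return an \code{mm_system}.
#' @export
system_from_prmtop <- function(prmtop, solvent = c("vacuum", "obc1", "pme"),
                               constraints = c("none", "h_bonds",
                                               "all_bonds"),
                               sa_term = FALSE, box = NULL) {
  solvent <- match.arg(solvent)
  constraints <- match.arg(constraints)
  if (solvent == "pme")
    stop("explicit-solvent PME is not supported by this engine; ",
         "use solvent = 'vacuum' or 'obc1'")
  s <- prmtop$sections
  charges <- prmtop$charges
  lj <- prmtop_lj_per_atom(prmtop)

  bond_table <- function(m) {
    if (nrow(m) == 0L)
      return(data.frame(i = integer(0), j = integer(0), k = numeric(0),
                        r0 = numeric(0)))
    idx <- m[, 3]
    data.frame(i = m[, 1], j = m[, 2],
               k = s$BOND_FORCE_CONSTANT[idx] * KCAL_TO_KJ * 100,
               r0 = s$BOND_EQUIL_VALUE[idx] * 0.1)
  }
  bonds_h <- bond_table(prmtop$bonds_h)
  bonds_a <- bond_table(prmtop$bonds_a)

  con_list <- list()
  if (constraints == "h_bonds") {
    con_list <- lapply(seq_len(nrow(bonds_h)), function(r)
      list(i = bonds_h$i[r], j = bonds_h$j[r], distance = bonds_h$r0[r]))
    bonds_h <- bonds_h[0, ]
  } else if (constraints == "all_bonds") {
    all_b <- rbind(bonds_h, bonds_a)
    con_list <- lapply(seq_len(nrow(all_b)), function(r)
      list(i = all_b$i[r], j = all_b$j[r], distance = all_b$r0[r]))
    bonds_h <- bonds_h[0, ]; bonds_a <- bonds_a[0, ]
  }
  bonds <- rbind(bonds_h, bonds_a)

  angles_m <- rbind(prmtop$angles_h, prmtop$angles_a)
  angles <- if (nrow(angles_m) == 0L) {
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               kf = numeric(0), theta0 = numeric(0))
  } else {
    idx <- angles_m[, 4]
    data.frame(i = angles_m[, 1], j = angles_m[, 2], k = angles_m[, 3],
               kf = s$ANGLE_FORCE_CONSTANT[idx] * KCAL_TO_KJ,
               theta0 = s$ANGLE_EQUIL_VALUE[idx])
  }

  dih_m <- rbind(prmtop$dihedrals_h, prmtop$dihedrals_a)
  torsions <- if (nrow(dih_m) == 0L) {
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               l = integer(0), kf = numeric(0), n = numeric(0),
               gamma = numeric(0))
  } else {
    idx <- dih_m[, 5]
    data.frame(i = abs(dih_m[, 1]), j = abs(dih_m[, 2]),
               k = abs(dih_m[, 3]), l = abs(dih_m[, 4]),
               kf = s$DIHEDRAL_FORCE_CONSTANT[idx] * KCAL_TO_KJ,
               n = s$DIHEDRAL_PERIODICITY[idx],
               gamma = s$DIHEDRAL_PHASE[idx])
  }
  torsions <- torsions[torsions$kf != 0, , drop = FALSE]

  exclusions <- prmtop_exclusions(prmtop)
  exceptions <- prmtop_exceptions(prmtop, charges, lj$sigma, lj$epsilon)

  terms <- list()
  if (nrow(bonds) > 0) terms <- c(terms, list(harmonic_bond_term(bonds)))
  if (nrow(angles) > 0) terms <- c(terms, list(harmonic_angle_term(angles)))
  if (nrow(torsions) > 0)
    terms <- c(terms, list(periodic_torsion_term(torsions)))
  terms <- c(terms, list(standard_nonbonded_term(
    charges, lj$sigma, lj$epsilon, exclusions = exclusions,
    exceptions = exceptions)))
  if (solvent == "obc1") {
    if (is.null(s$RADII) || is.null(s$SCREEN))
      stop("obc1 solvent requires RADII and SCREEN sections in the prmtop")
    terms <- c(terms, list(obc_term(charges, s$RADII * 0.1, s$SCREEN,
                                    sa_term = sa_term)))
  }
  mm_system(masses = prmtop$masses, constraints = con_list,
            force_terms = terms, box = box)
}

# ---- minimal PDB subset ----------------------------------------------------

#' Read ATOM/HETATM records from a PDB file
#'
#' @param path file path.
#' @return list with \code{names}, \code{elements} (inferred from the atom
#'   name when the element column is blank), \code{resnames}, and
#'   \code{positions} (N x 3, nm).
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) == 0) stop("no ATOM/HETATM records found")
  fx <- function(a, b) substr(rec, a, b)
  x <- suppressWarnings(as.numeric(fx(31, 38)))
  y <- suppressWarnings(as.numeric(fx(39, 46)))
  z <- suppressWarnings(as.numeric(fx(47, 54)))
  if (any(is.na(c(x, y, z)))) stop("malformed ATOM record coordinates")
  names <- trimws(fx(13, 16))
  elements <- trimws(fx(77, 78))
  infer <- !nzchar(elements)
  elements[infer] <- sub("^[0-9]*", "", names[infer])
  elements[infer] <- toupper(substr(elements[infer], 1, 1))
  list(names = names, elements = elements, resnames = trimws(fx(18, 20)),
       positions = cbind(x, y, z) * 0.1)
}

#' Write a minimal PDB file
#'
#' @param path output path.
#' @param positions N x 3 matrix (nm).
#' @param names atom names (recycled "X" if missing).
#' @param elements element symbols.
#' @param resname residue name for all atoms.
#' @export
write_pdb <- function(path, positions, names = NULL, elements = NULL,
                      resname = "MOL") {
  n <- nrow(positions)
  if (is.null(names)) names <- rep("X", n)
  if (is.null(elements)) elements <- toupper(substr(names, 1, 1))
  ang <- positions * 10
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n), substr(names, 1, 4), resname, 1L,
    ang[, 1], ang[, 2], ang[, 3], substr(elements, 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
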