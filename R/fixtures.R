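# Synthetic test systems and toy topology writers. Every generator is
# deterministic under a fixed seed. The matching independent reference
# energies live in reference.R (separate, naive code path).

#' Lennard-Jones fluid fixture
#'
#' Argon-like particles on a jittered cubic lattice in a periodic cubic
#' box, with Maxwell-Boltzmann velocities. The construction guarantees a
#' minimum interparticle distance of 0.8 sigma.
#'
#' @param n particle count.
#' @param box_length cubic box edge (nm).
#' @param temperature kelvin.
#' @param seed integer seed.
#' @param sigma,epsilon,mass LJ parameters (nm, kJ/mol, amu); defaults are
#'   argon-like.
#' @return list(system, state).
#' @export
make_lj_fluid <- function(n, box_length, temperature = 120, seed = 1,
                          sigma = 0.34, epsilon = 0.996, mass = 39.948) {
  per_side <- ceiling(n^(1 / 3))
  spacing <- box_length / per_side
  jitter_max <- max(0, (spacing - 0.8 * sigma) / 2) / sqrt(3)
  if (spacing < 0.8 * sigma)
    stop("density too high to place particles without overlaps")
  grid <- as.matrix(expand.grid(seq_len(per_side), seq_len(per_side),
                                seq_len(per_side)))[seq_len(n), , drop = FALSE]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  positions <- (grid - 0.5) * spacing +
    matrix(stats::runif(3 * n, -jitter_max, jitter_max), n, 3)
  box <- box_from_geometry("cube", box_length)
  term <- standard_nonbonded_term(numeric(n), rep(sigma, n),
                                  rep(epsilon, n), periodic = TRUE)
  system <- mm_system(masses = rep(mass, n), force_terms = list(term),
                      box = box)
  state <- mm_state(positions,
                    set_velocities_to_temperature(system, temperature,
                                                  seed + 1))
  list(system = system, state = state)
}

#' Harmonic diatomic fixture
#' @param k force constant (kJ/mol/nm^2, Amber convention E = k (r-r0)^2).
#' @param r0 equilibrium distance (nm).
#' @param mass amu per atom.
#' @param r starting separation (nm).
#' @return list(system, state).
#' @export
make_diatomic <- function(k = 1000, r0 = 0.1, mass = 12, r = 0.12) {
  term <- harmonic_bond_term(data.frame(i = 1, j = 2, k = k, r0 = r0))
  system <- mm_system(masses = rep(mass, 2), force_terms = list(term))
  state <- mm_state(rbind(c(0, 0, 0), c(r, 0, 0)))
  list(system = system, state = state)
}

#' Harmonic chain fixture
#' @param n atoms.
#' @param k,r0 bond parameters.
#' @param mass amu.
#' @param seed seed for a small position jitter.
#' @return list(system, state, bonds).
#' @export
make_harmonic_chain <- function(n = 5, k = 500, r0 = 0.15, mass = 12,
                                seed = 1) {
  bonds <- data.frame(i = seq_len(n - 1), j = 2:n, k = k, r0 = r0)
  system <- mm_system(masses = rep(mass, n),
                      force_terms = list(harmonic_bond_term(bonds)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pos <- cbind(seq_len(n) * r0, 0, 0) + matrix(stats::rnorm(3 * n), n) * 0.01
  list(system = system, state = mm_state(pos), bonds = bonds)
}

#' Flexible three-site water box fixture
#'
#' TIP3P-like waters with harmonic bonds and angle (flexible) or three
#' distance constraints per molecule (rigid), so both the bonded and the
#' constraint code paths are exercisable on the same fixture.
#'
#' @param n_molecules number of waters.
#' @param box_length cubic box edge (nm).
#' @param temperature kelvin.
#' @param seed integer seed.
#' @param rigid logical; replace the intramolecular terms by constraints.
#' @return list(system, state, molecule_groups).
#' @export
make_water_box <- function(n_molecules = 8, box_length = 1.6,
                           temperature = 300, seed = 1, rigid = FALSE) {
  rOH <- 0.09572; aHOH <- 104.52 * pi / 180
  rHH <- 2 * rOH * sin(aHOH / 2)
  qO <- -0.834; qH <- 0.417
  sigO <- 0.31507; epsO <- 0.635968
  n <- 3L * n_molecules
  per_side <- ceiling(n_molecules^(1 / 3))
  spacing <- box_length / per_side
  grid <- as.matrix(expand.grid(seq_len(per_side), seq_len(per_side),
                                seq_len(per_side)))[seq_len(n_molecules), ,
                                                    drop = FALSE]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  local_geom <- rbind(c(0, 0, 0),
                      c(rOH, 0, 0),
                      c(rOH * cos(aHOH), rOH * sin(aHOH), 0))
  positions <- matrix(0, n, 3)
  for (midx in seq_len(n_molecules)) {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
                  2 * (q[2] * q[4] + q[1] * q[3]),
                  2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
                  2 * (q[3] * q[4] - q[1] * q[2]),
                  2 * (q[2] * q[4] - q[1] * q[3]),
                  2 * (q[3] * q[4] + q[1] * q[2]),
                  1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
    center <- (grid[midx, ] - 0.5) * spacing
    positions[(midx - 1) * 3 + 1:3, ] <- local_geom %*% t(R) +
      matrix(center, 3, 3, byrow = TRUE)
  }
  oidx <- seq(1, n, by = 3)
  charges <- rep(c(qO, qH, qH), n_molecules)
  sigv <- rep(c(sigO, 0.04, 0.04), n_molecules)
  epsv <- rep(c(epsO, 0, 0), n_molecules)
  excl <- do.call(rbind, lapply(seq_len(n_molecules), function(mi) {
    a <- (mi - 1) * 3
    rbind(c(a + 1, a + 2), c(a + 1, a + 3), c(a + 2, a + 3))
  }))
  terms <- list(standard_nonbonded_term(charges, sigv, epsv,
                                        exclusions = excl, periodic = TRUE))
  cons <- list()
  if (rigid) {
    cons <- do.call(c, lapply(seq_len(n_molecules), function(mi) {
      a <- (mi - 1) * 3
      list(list(i = a + 1, j = a + 2, distance = rOH),
           list(i = a + 1, j = a + 3, distance = rOH),
           list(i = a + 2, j = a + 3, distance = rHH))
    }))
  } else {
    bonds <- do.call(rbind, lapply(seq_len(n_molecules), function(mi) {
      a <- (mi - 1) * 3
      data.frame(i = c(a + 1, a + 1), j = c(a + 2, a + 3),
                 k = 251208, r0 = rOH)
    }))
    angles <- do.call(rbind, lapply(seq_len(n_molecules), function(mi) {
      a <- (mi - 1) * 3
      data.frame(i = a + 2, j = a + 1, k = a + 3, kf = 314.01,
                 theta0 = aHOH)
    }))
    terms <- c(list(harmonic_bond_term(bonds),
                    harmonic_angle_term(angles)), terms)
  }
  system <- mm_system(masses = rep(c(15.9994, 1.008, 1.008), n_molecules),
                      constraints = cons, force_terms = terms,
                      box = box_from_geometry("cube", box_length))
  state <- mm_state(positions,
                    set_velocities_to_temperature(system, temperature,
                                                  seed + 1))
  list(system = system, state = state,
       molecule_groups = lapply(seq_len(n_molecules), function(mi)
         (mi - 1) * 3 + 1:3))
}

# ---- toy Amber file writers ------------------------------------------------

fmt_section <- function(name, fmt, values, per_line, formatter) {
  lines <- c(sprintf("%%FLAG %s", name), sprintf("%%FORMAT%s", fmt))
  if (length(values) == 0L) return(c(lines, ""))
  chunks <- split(values, ceiling(seq_along(values) / per_line))
  c(lines, vapply(chunks, function(ch) paste(formatter(ch), collapse = ""),
                  character(1)))
}

fmt_E_wide <- function(x) sprintf("%24.16E", x)
fmt_E_amber <- function(x) sprintf("%16.8E", x)
fmt_I <- function(x) sprintf("%8d", as.integer(x))
fmt_A <- function(x) sprintf("%-4s", substr(x, 1, 4))

# bond-graph exclusions: returns list(excl12, excl13, pairs14) of 2-col
# matrices (i < j)
bonded_exclusions <- function(n, bonds) {
  adj <- vector("list", n)
  if (nrow(bonds) > 0)
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  p12 <- list(); p13 <- list(); p14 <- list()
  for (i in seq_len(n)) {
    n1 <- unique(adj[[i]])
    n2 <- setdiff(unique(unlist(adj[n1])), c(i, n1))
    n3 <- setdiff(unique(unlist(adj[n2])), c(i, n1, n2))
    for (j in n1[n1 > i]) p12[[length(p12) + 1L]] <- c(i, j)
    for (j in n2[n2 > i]) p13[[length(p13) + 1L]] <- c(i, j)
    for (j in n3[n3 > i]) p14[[length(p14) + 1L]] <- c(i, j)
  }
  tomat <- function(p) if (length(p)) do.call(rbind, p)
                       else matrix(integer(0), 0, 2)
  list(excl12 = tomat(p12), excl13 = tomat(p13), pairs14 = tomat(p14))
}

#' Write a toy Amber prmtop from a system description
#'
#' Emits a syntactically valid prmtop (fixed-width \%FLAG sections) that
#' \code{\link{read_prmtop}} round-trips exactly. The description uses the
#' engine's internal units; the writer converts to Amber's native units
#' (kcal, Angstrom, scaled charges).
#'
#' @param desc list with \code{names}, \code{masses}, \code{charges} (e),
#'   \code{sigma} (nm), \code{epsilon} (kJ/mol), optional \code{bonds}
#'   (i, j, k kJ/mol/nm^2, r0 nm), \code{angles} (i, j, k atoms, kf, theta0),
#'   \code{dihedrals} (i, j, k, l, kf, n, gamma, optional improper flag),
#'   \code{radii} (nm), \code{screen}, \code{scee}, \code{scnb}.
#' @param path output file.
#' @param float_format "wide" (17 significant digits, exact round-trips;
#'   the \%FORMAT record is self-describing) or "amber" (the canonical
#'   5E16.8 layout some external parsers hard-code).
#' @return \code{path}, invisibly.
#' @export
write_toy_prmtop <- function(desc, path, float_format = c("wide", "amber")) {
  float_format <- match.arg(float_format)
  efmt <- if (float_format == "wide") "(3E24.16)" else "(5E16.8)"
  eper <- if (float_format == "wide") 3L else 5L
  fmt_E <- if (float_format == "wide") fmt_E_wide else fmt_E_amber
  n <- length(desc$masses)
  names <- if (is.null(desc$names)) sprintf("A%d", seq_len(n)) else desc$names
  bonds <- if (is.null(desc$bonds))
    data.frame(i = integer(0), j = integer(0), k = numeric(0),
               r0 = numeric(0)) else as.data.frame(desc$bonds)
  angles <- if (is.null(desc$angles))
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               kf = numeric(0), theta0 = numeric(0))
    else as.data.frame(desc$angles)
  dihedrals <- if (is.null(desc$dihedrals))
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               l = integer(0), kf = numeric(0), n = numeric(0),
               gamma = numeric(0)) else as.data.frame(desc$dihedrals)
  if (is.null(dihedrals$improper) && nrow(dihedrals) > 0)
    dihedrals$improper <- FALSE
  scee <- if (is.null(desc$scee)) 1.2 else desc$scee
  scnb <- if (is.null(desc$scnb)) 2.0 else desc$scnb
  hyd <- desc$masses < 3.5

  # LJ types from unique (sigma, epsilon)
  key <- paste(desc$sigma, desc$epsilon)
  types <- as.integer(factor(key, levels = unique(key)))
  ntypes <- max(types)
  usig <- desc$sigma[!duplicated(key)]
  ueps <- desc$epsilon[!duplicated(key)]
  ntri <- ntypes * (ntypes + 1) / 2
  A <- numeric(ntri); B <- numeric(ntri)
  ico <- integer(ntypes * ntypes)
  tt <- 0L
  tri_index <- matrix(0L, ntypes, ntypes)
  for (jt in seq_len(ntypes)) for (it in seq_len(jt)) {
    tt <- tt + 1L
    sij <- 0.5 * (usig[it] + usig[jt]) * 10          # A
    eij <- sqrt(ueps[it] * ueps[jt]) / KCAL_TO_KJ    # kcal/mol
    A[tt] <- 4 * eij * sij^12
    B[tt] <- 4 * eij * sij^6
    tri_index[it, jt] <- tt; tri_index[jt, it] <- tt
  }
  for (it in seq_len(ntypes)) for (jt in seq_len(ntypes))
    ico[ntypes * (it - 1L) + jt] <- tri_index[it, jt]

  # parameter tables (unique rows)
  uniq_params <- function(df, cols) {
    if (nrow(df) == 0L)
      return(list(idx = integer(0), table = df[0, cols, drop = FALSE]))
    key <- do.call(paste, df[cols])
    idx <- as.integer(factor(key, levels = unique(key)))
    list(idx = idx, table = df[!duplicated(key), cols, drop = FALSE])
  }
  bp <- uniq_params(bonds, c("k", "r0"))
  ap <- uniq_params(angles, c("kf", "theta0"))
  dp <- uniq_params(dihedrals, c("kf", "n", "gamma"))

  # bonded records with the Amber 3*(idx-1) convention, split by hydrogen
  enc <- function(i) 3L * (as.integer(i) - 1L)
  bond_rec <- function(rows) as.vector(t(cbind(enc(bonds$i[rows]),
                                               enc(bonds$j[rows]),
                                               bp$idx[rows])))
  bh <- which(hyd[bonds$i] | hyd[bonds$j])
  ba <- setdiff(seq_len(nrow(bonds)), bh)
  angle_rec <- function(rows) as.vector(t(cbind(enc(angles$i[rows]),
                                                enc(angles$j[rows]),
                                                enc(angles$k[rows]),
                                                ap$idx[rows])))
  ah <- which(hyd[angles$i] | hyd[angles$j] | hyd[angles$k])
  aa <- setdiff(seq_len(nrow(angles)), ah)
  # mark duplicate 1-4 pairs and impropers with negative third/fourth index
  # negative third/fourth entries carry the 1-4-exclusion and improper
  # markers; atom 1 encodes to 0 and cannot be negated, so such dihedrals
  # are reversed first (the Amber tools do the same)
  seen14 <- character(0)
  drec <- matrix(0L, nrow(dihedrals), 5)
  if (nrow(dihedrals) > 0) for (r in seq_len(nrow(dihedrals))) {
    i <- dihedrals$i[r]; j <- dihedrals$j[r]
    k <- dihedrals$k[r]; l <- dihedrals$l[r]
    imp <- isTRUE(dihedrals$improper[r])
    pkey <- paste(min(i, l), max(i, l))
    dup <- imp || pkey %in% seen14
    if (!dup) seen14 <- c(seen14, pkey)
    if ((dup && k == 1L) || (imp && l == 1L)) {
      tmp <- i; i <- l; l <- tmp
      tmp <- j; j <- k; k <- tmp
    }
    drec[r, ] <- c(enc(i), enc(j), if (dup) -enc(k) else enc(k),
                   if (imp) -enc(l) else enc(l), dp$idx[r])
  }
  dh <- which(hyd[dihedrals$i] | hyd[dihedrals$j] | hyd[dihedrals$k] |
                hyd[dihedrals$l])
  da <- setdiff(seq_len(nrow(dihedrals)), dh)

  ex <- bonded_exclusions(n, bonds)
  allex <- rbind(ex$excl12, ex$excl13, ex$pairs14)
  ex_counts <- integer(n); ex_list <- integer(0)
  for (i in seq_len(n)) {
    js <- sort(allex[allex[, 1] == i, 2])
    if (length(js) == 0L) { ex_counts[i] <- 1L; ex_list <- c(ex_list, 0L) }
    else { ex_counts[i] <- length(js); ex_list <- c(ex_list, js) }
  }

  ptr <- integer(31)
  ptr[1] <- n; ptr[2] <- ntypes
  ptr[3] <- length(bh); ptr[4] <- length(ba)
  ptr[5] <- length(ah); ptr[6] <- length(aa)
  ptr[7] <- length(dh); ptr[8] <- length(da)
  ptr[11] <- length(ex_list); ptr[12] <- 1L
  ptr[13] <- length(ba); ptr[14] <- length(aa); ptr[15] <- length(da)
  ptr[16] <- nrow(bp$table); ptr[17] <- nrow(ap$table)
  ptr[18] <- nrow(dp$table); ptr[19] <- ntypes

  radii <- if (is.null(desc$radii)) rep(0.15, n) else desc$radii
  screen <- if (is.null(desc$screen)) rep(0.8, n) else desc$screen

  out <- c("%VERSION  VERSION_STAMP = V0001.000  DATE = 01/01/26  00:00:00",
    fmt_section("TITLE", "(20a4)", "toy", 20, fmt_A),
    fmt_section("POINTERS", "(10I8)", ptr, 10, fmt_I),
    fmt_section("ATOM_NAME", "(20a4)", names, 20, fmt_A),
    fmt_section("CHARGE", efmt, desc$charges * AMBER_CHARGE_SCALE, eper,
                fmt_E),
    fmt_section("MASS", efmt, desc$masses, eper, fmt_E),
    fmt_section("ATOM_TYPE_INDEX", "(10I8)", types, 10, fmt_I),
    fmt_section("NUMBER_EXCLUDED_ATOMS", "(10I8)", ex_counts, 10, fmt_I),
    fmt_section("NONBONDED_PARM_INDEX", "(10I8)", ico, 10, fmt_I),
    fmt_section("RESIDUE_LABEL", "(20a4)", "MOL", 20, fmt_A),
    fmt_section("RESIDUE_POINTER", "(10I8)", 1L, 10, fmt_I),
    fmt_section("BOND_FORCE_CONSTANT", efmt,
                bp$table$k / (KCAL_TO_KJ * 100), eper, fmt_E),
    fmt_section("BOND_EQUIL_VALUE", efmt, bp$table$r0 * 10, eper, fmt_E),
    fmt_section("ANGLE_FORCE_CONSTANT", efmt,
                ap$table$kf / KCAL_TO_KJ, eper, fmt_E),
    fmt_section("ANGLE_EQUIL_VALUE", efmt, ap$table$theta0, eper, fmt_E),
    fmt_section("DIHEDRAL_FORCE_CONSTANT", efmt,
                dp$table$kf / KCAL_TO_KJ, eper, fmt_E),
    fmt_section("DIHEDRAL_PERIODICITY", efmt, dp$table$n, eper, fmt_E),
    fmt_section("DIHEDRAL_PHASE", efmt, dp$table$gamma, eper, fmt_E),
    fmt_section("SCEE_SCALE_FACTOR", efmt,
                rep(scee, nrow(dp$table)), eper, fmt_E),
    fmt_section("SCNB_SCALE_FACTOR", efmt,
                rep(scnb, nrow(dp$table)), eper, fmt_E),
    fmt_section("LENNARD_JONES_ACOEF", efmt, A, eper, fmt_E),
    fmt_section("LENNARD_JONES_BCOEF", efmt, B, eper, fmt_E),
    fmt_section("BONDS_INC_HYDROGEN", "(10I8)", bond_rec(bh), 10, fmt_I),
    fmt_section("BONDS_WITHOUT_HYDROGEN", "(10I8)", bond_rec(ba), 10, fmt_I),
    fmt_section("ANGLES_INC_HYDROGEN", "(10I8)", angle_rec(ah), 10, fmt_I),
    fmt_section("ANGLES_WITHOUT_HYDROGEN", "(10I8)", angle_rec(aa), 10,
                fmt_I),
    fmt_section("DIHEDRALS_INC_HYDROGEN", "(10I8)",
                as.vector(t(drec[dh, , drop = FALSE])), 10, fmt_I),
    fmt_section("DIHEDRALS_WITHOUT_HYDROGEN", "(10I8)",
                as.vector(t(drec[da, , drop = FALSE])), 10, fmt_I),
    fmt_section("EXCLUDED_ATOMS_LIST", "(10I8)", ex_list, 10, fmt_I),
    fmt_section("RADII", efmt, radii * 10, eper, fmt_E),
    fmt_section("SCREEN", efmt, screen, eper, fmt_E),
    fmt_section("AMBER_ATOM_TYPE", "(20a4)", sprintf("T%d", types), 20,
                fmt_A))
  writeLines(out[nzchar(out)], path)
  invisible(path)
}

#' Write an Amber inpcrd coordinate file
#'
#' @param path output path.
#' @param positions N x 3 matrix (nm); written in Angstroms.
#' @param box optional \code{mm_box} (written as lengths + angles).
#' @return \code{path}, invisibly.
#' @export
write_inpcrd <- function(path, positions, box = NULL) {
  n <- nrow(positions)
  vals <- as.vector(t(positions)) * 10
  lines <- c("toy", sprintf("%5d", n))
  chunks <- split(vals, ceiling(seq_along(vals) / 6))
  lines <- c(lines, vapply(chunks, function(ch)
    paste(sprintf("%12.7f", ch), collapse = ""), character(1)))
  if (!is.null(box)) {
    m <- unclass(box)
    la <- sqrt(sum(m[1, ]^2)); lb <- sqrt(sum(m[2, ]^2))
    lc <- sqrt(sum(m[3, ]^2))
    ga <- acos(sum(m[1, ] * m[2, ]) / (la * lb)) * 180 / pi
    be <- acos(sum(m[1, ] * m[3, ]) / (la * lc)) * 180 / pi
    al <- acos(sum(m[2, ] * m[3, ]) / (lb * lc)) * 180 / pi
    lines <- c(lines, paste(sprintf("%12.7f",
                                    c(la, lb, lc, al, be, ga) *
                                      c(10, 10, 10, 1, 1, 1)),
                            collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}
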