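# Independent brute-force reference energies for oracle comparisons.
# Deliberately naive: explicit scalar loops and formulas written out
# directly, sharing no code with the force-term machinery (no expression
# engine, no vectorized geometry helpers). Forces come from central finite
# differences of this file's own energy. Small systems only.

ref_dot <- function(a, b) a[1] * b[1] + a[2] * b[2] + a[3] * b[3]
ref_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                              a[3] * b[1] - a[1] * b[3],
                              a[1] * b[2] - a[2] * b[1])

ref_bond_energy <- function(desc, pos) {
  e <- 0
  b <- desc$bonds
  if (!is.null(b)) for (r in seq_len(nrow(b))) {
    d <- pos[b$i[r], ] - pos[b$j[r], ]
    rr <- sqrt(ref_dot(d, d))
    e <- e + b$k[r] * (rr - b$r0[r])^2
  }
  e
}

ref_angle_energy <- function(desc, pos) {
  e <- 0
  a <- desc$angles
  if (!is.null(a)) for (r in seq_len(nrow(a))) {
    u <- pos[a$i[r], ] - pos[a$j[r], ]
    v <- pos[a$k[r], ] - pos[a$j[r], ]
    ct <- ref_dot(u, v) / sqrt(ref_dot(u, u) * ref_dot(v, v))
    th <- acos(max(-1, min(1, ct)))
    e <- e + a$kf[r] * (th - a$theta0[r])^2
  }
  e
}

ref_dihedral_energy <- function(desc, pos) {
  e <- 0
  d <- desc$dihedrals
  if (!is.null(d)) for (r in seq_len(nrow(d))) {
    b1 <- pos[d$j[r], ] - pos[d$i[r], ]
    b2 <- pos[d$k[r], ] - pos[d$j[r], ]
    b3 <- pos[d$l[r], ] - pos[d$k[r], ]
    n1 <- ref_cross(b1, b2)
    n2 <- ref_cross(b2, b3)
    m1 <- ref_cross(n1, b2 / sqrt(ref_dot(b2, b2)))
    xcomp <- ref_dot(n1, n2)
    ycomp <- ref_dot(m1, n2)
    phi <- atan2(ycomp, xcomp)
    e <- e + d$kf[r] * (1 + cos(d$n[r] * phi - d$gamma[r]))
  }
  e
}

# topological distances up to 3 bonds, recomputed from the bond list with a
# breadth-first walk (independent of any exclusion bookkeeping elsewhere)
ref_bond_distance <- function(desc, n) {
  dist <- matrix(Inf, n, n); diag(dist) <- 0
  b <- desc$bonds
  if (!is.null(b)) for (r in seq_len(nrow(b))) {
    dist[b$i[r], b$j[r]] <- 1; dist[b$j[r], b$i[r]] <- 1
  }
  for (rep in 1:3)
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
      if (dist[i, k] + dist[k, j] < dist[i, j])
        dist[i, j] <- dist[i, k] + dist[k, j]
  dist
}

ref_nonbonded_energy <- function(desc, pos) {
  n <- nrow(pos)
  scee <- if (is.null(desc$scee)) 1.2 else desc$scee
  scnb <- if (is.null(desc$scnb)) 2.0 else desc$scnb
  topo <- ref_bond_distance(desc, n)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (topo[i, j] <= 2) next
    d <- pos[i, ] - pos[j, ]
    rr <- sqrt(ref_dot(d, d))
    sij <- (desc$sigma[i] + desc$sigma[j]) / 2
    eij <- sqrt(desc$epsilon[i] * desc$epsilon[j])
    elj <- 4 * eij * ((sij / rr)^12 - (sij / rr)^6)
    ecl <- 138.935456 * desc$charges[i] * desc$charges[j] / rr
    if (topo[i, j] == 3) { elj <- elj / scnb; ecl <- ecl / scee }
    e <- e + elj + ecl
  }
  e
}

ref_obc_energy <- function(desc, pos, sa = FALSE) {
  n <- nrow(pos)
  offset <- 0.009
  rad <- desc$radii; scr <- desc$screen; q <- desc$charges
  B <- numeric(n)
  for (i in seq_len(n)) {
    ori <- rad[i] - offset
    I <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      d <- pos[i, ] - pos[j, ]
      rr <- sqrt(ref_dot(d, d))
      srj <- scr[j] * (rad[j] - offset)
      if (ori >= rr + srj) next
      U <- rr + srj
      L <- max(ori, abs(rr - srj))
      term <- 1 / L - 1 / U + 0.25 * (rr - srj^2 / rr) * (1 / U^2 - 1 / L^2) +
        0.5 * log(L / U) / rr
      if (ori < srj - rr) term <- term + 2 * (1 / ori - 1 / L)
      I <- I + 0.5 * term
    }
    psi <- I * ori
    B[i] <- 1 / (1 / ori - tanh(0.8 * psi + 2.909125 * psi^3) / rad[i])
  }
  pre <- -138.935456 * (1 - 1 / 78.5)
  e <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- pos[i, ] - pos[j, ]
    r2 <- ref_dot(d, d)
    fgb <- if (i == j) B[i]
           else sqrt(r2 + B[i] * B[j] * exp(-r2 / (4 * B[i] * B[j])))
    e <- e + 0.5 * pre * q[i] * q[j] / fgb
  }
  if (sa)
    for (i in seq_len(n))
      e <- e + 28.3919551 * (rad[i] + 0.14)^2 * (rad[i] / B[i])^6
  e
}

#' Independent brute-force reference energies and forces
#'
#' A deliberately naive second implementation of every supported
#' functional form (scalar loops, explicit formulas, topology-derived
#' exclusions), used as an oracle against the engine. Forces are central
#' finite differences of this function's own energy (h = 1e-6 nm), so the
#' two code paths share nothing.
#'
#' @param desc fixture description (same fields as
#'   \code{\link{write_toy_prmtop}}).
#' @param positions N x 3 matrix (nm).
#' @param obc include the implicit-solvent energy.
#' @param sa include the surface-area term.
#' @param forces compute finite-difference forces (slow; small N only).
#' @return list(energies = named vector incl. Total, forces or NULL).
#' @export
reference_energy <- function(desc, positions, obc = FALSE, sa = FALSE,
                             forces = FALSE) {
  total_energy <- function(pos) {
    e <- c(Bond = ref_bond_energy(desc, pos),
           Angle = ref_angle_energy(desc, pos),
           Dihedral = ref_dihedral_energy(desc, pos),
           Nonbonded = ref_nonbonded_energy(desc, pos))
    if (obc) e <- c(e, OBC = ref_obc_energy(desc, pos, sa))
    e
  }
  e <- total_energy(positions)
  f <- NULL
  if (forces) {
    h <- 1e-6
    f <- positions * 0
    for (i in seq_len(nrow(positions))) for (d in 1:3) {
      pp <- positions; pp[i, d] <- pp[i, d] + h
      pm <- positions; pm[i, d] <- pm[i, d] - h
      f[i, d] <- -(sum(total_energy(pp)) - sum(total_energy(pm))) / (2 * h)
    }
  }
  list(energies = c(e, Total = sum(e)), forces = f)
}
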