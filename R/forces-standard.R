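# Standard force terms in the Amber functional forms:
#   E_bond    = sum k (r - r0)^2
#   E_angle   = sum k (theta - theta0)^2
#   E_torsion = sum k (1 + cos(n phi - gamma))
#   E_nonbond = sum 4 eps ((sig/r)^12 - (sig/r)^6) + 138.935456 qi qj / r
# with Lorentz-Berthelot combination unless an exception overrides a pair.
# Hand-vectorized rather than routed through the expression engine: these
# are the hot paths, and their expression-encoded equivalents are checked
# against them in the tests.

#' Standard harmonic bond term (Amber convention, no 1/2)
#'
#' @param bonds data.frame/matrix with columns \code{i, j, k, r0}
#'   (indices, force constant kJ/mol/nm^2, equilibrium length nm).
#' @param category decomposition label, default "Bond".
#' @return an \code{mm_force_term}.
#' @export
harmonic_bond_term <- function(bonds, category = "Bond") {
  bonds <- as.data.frame(bonds)
  ai <- as.integer(bonds$i); bi <- as.integer(bonds$j)
  k <- as.numeric(bonds$k); r0 <- as.numeric(bonds$r0)
  new_force_term(category, function(positions, box) {
    forces <- matrix(0, nrow(positions), 3)
    if (length(ai) == 0L) return(list(energy = 0, forces = forces))
    g <- geom_bond(positions, ai, bi)
    dr <- g$r - r0
    energy <- sum(k * dr * dr)
    contrib <- (-2 * k * dr) * g$u
    forces <- add_at(forces, ai, contrib)
    forces <- add_at(forces, bi, -contrib)
    list(energy = energy, forces = forces)
  })
}

#' Standard harmonic angle term (Amber convention)
#'
#' @param angles data.frame/matrix with columns \code{i, j, k, kf, theta0}
#'   (atom indices with j the vertex, force constant kJ/mol/rad^2,
#'   equilibrium angle radians).
#' @param category decomposition label, default "Angle".
#' @return an \code{mm_force_term}.
#' @export
harmonic_angle_term <- function(angles, category = "Angle") {
  angles <- as.data.frame(angles)
  ai <- as.integer(angles$i); bi <- as.integer(angles$j)
  ci <- as.integer(angles$k)
  kf <- as.numeric(angles$kf); theta0 <- as.numeric(angles$theta0)
  new_force_term(category, function(positions, box) {
    forces <- matrix(0, nrow(positions), 3)
    if (length(ai) == 0L) return(list(energy = 0, forces = forces))
    g <- geom_angle(positions, ai, bi, ci)
    dt <- g$theta - theta0
    energy <- sum(kf * dt * dt)
    dE <- 2 * kf * dt
    forces <- add_at(forces, ai, -dE * g$ga)
    forces <- add_at(forces, bi, -dE * g$gb)
    forces <- add_at(forces, ci, -dE * g$gc)
    list(energy = energy, forces = forces)
  })
}

#' Standard periodic torsion term (Amber convention)
#'
#' @param torsions data.frame/matrix with columns \code{i, j, k, l, kf, n,
#'   gamma} (atom indices, barrier kJ/mol, periodicity >= 1, phase radians).
#' @param category decomposition label, default "Dihedral".
#' @return an \code{mm_force_term}.
#' @export
periodic_torsion_term <- function(torsions, category = "Dihedral") {
  torsions <- as.data.frame(torsions)
  if (nrow(torsions) > 0 && any(torsions$n < 1))
    stop("torsion periodicity must be >= 1")
  ai <- as.integer(torsions$i); bi <- as.integer(torsions$j)
  ci <- as.integer(torsions$k); di <- as.integer(torsions$l)
  kf <- as.numeric(torsions$kf); nper <- as.numeric(torsions$n)
  gamma <- as.numeric(torsions$gamma)
  new_force_term(category, function(positions, box) {
    forces <- matrix(0, nrow(positions), 3)
    if (length(ai) == 0L) return(list(energy = 0, forces = forces))
    g <- geom_dihedral(positions, ai, bi, ci, di)
    energy <- sum(kf * (1 + cos(nper * g$phi - gamma)))
    dE <- -kf * nper * sin(nper * g$phi - gamma)
    forces <- add_at(forces, ai, -dE * g$ga)
    forces <- add_at(forces, bi, -dE * g$gb)
    forces <- add_at(forces, ci, -dE * g$gc)
    forces <- add_at(forces, di, -dE * g$gd)
    list(energy = energy, forces = forces)
  })
}

#' Standard Lennard-Jones + Coulomb nonbonded term
#'
#' Lennard-Jones 12-6 with Lorentz-Berthelot combination of per-particle
#' sigma/epsilon plus Coulomb \code{138.935456 qi qj / r}. Excluded pairs
#' contribute nothing; exception pairs replace the default interaction
#' entirely with their own \code{(chargeprod, sigma, epsilon)} (the
#' materialized 1-4 scaled pairs of a topology).
#'
#' @param charge numeric vector, per-particle charges (e).
#' @param sigma numeric vector, per-particle LJ sigma (nm, > 0).
#' @param epsilon numeric vector, per-particle LJ epsilon (kJ/mol, >= 0).
#' @param exclusions two-column integer matrix of excluded pairs.
#' @param exceptions data.frame with columns \code{i, j, chargeprod, sigma,
#'   epsilon} (chargeprod in e^2).
#' @param cutoff cutoff (nm) or NULL for no cutoff.
#' @param periodic logical, use minimum image.
#' @param category decomposition label, default "Nonbonded".
#' @return an \code{mm_force_term}.
#' @export
standard_nonbonded_term <- function(charge, sigma, epsilon,
                                    exclusions = NULL, exceptions = NULL,
                                    cutoff = NULL, periodic = FALSE,
                                    category = "Nonbonded") {
  stopifnot(all(epsilon >= 0), all(sigma > 0))
  charge <- as.numeric(charge)
  exclusions <- if (is.null(exclusions)) matrix(integer(0), 0, 2)
                else matrix(as.integer(as.matrix(exclusions)), ncol = 2)
  if (is.null(exceptions))
    exceptions <- data.frame(i = integer(0), j = integer(0),
                             chargeprod = numeric(0), sigma = numeric(0),
                             epsilon = numeric(0))
  exceptions <- as.data.frame(exceptions)
  if (nrow(exceptions) > 0) {
    key <- paste(pmin(exceptions$i, exceptions$j),
                 pmax(exceptions$i, exceptions$j))
    if (anyDuplicated(key)) stop("duplicate exception pair")
  }
  # the main loop skips both excluded and excepted pairs
  skip <- rbind(exclusions,
                cbind(as.integer(exceptions$i), as.integer(exceptions$j)))
  n <- length(charge)
  pr_cache <- pair_list(n, skip)

  pair_eval <- function(d, qq, sig, eps) {
    r2 <- rowSums(d * d)
    r <- sqrt(r2)
    sr6 <- (sig * sig / r2)^3
    elj <- 4 * eps * (sr6 * sr6 - sr6)
    ecoul <- COULOMB_CONSTANT * qq / r
    # dE/dr * (1/r): LJ: 4 eps (-12 sr12 + 6 sr6)/r^2 ; Coulomb: -ke qq/r^3
    fscale <- (4 * eps * (12 * sr6 * sr6 - 6 * sr6) +
                 COULOMB_CONSTANT * qq / r) / r2
    list(energy = sum(elj + ecoul), contrib = fscale * d)
  }

  new_force_term(category, function(positions, box) {
    forces <- matrix(0, nrow(positions), 3)
    energy <- 0
    pr <- pr_cache
    if (nrow(pr) > 0L) {
      d <- positions[pr[, 1], , drop = FALSE] -
           positions[pr[, 2], , drop = FALSE]
      if (periodic) {
        if (is.null(box)) stop("periodic nonbonded term requires a box")
        if (!is.null(cutoff)) check_cutoff(box, cutoff)
        d <- minimum_image(box, d)
      }
      if (!is.null(cutoff)) {
        keep <- which(rowSums(d * d) < cutoff^2)
        pr <- pr[keep, , drop = FALSE]; d <- d[keep, , drop = FALSE]
      }
      if (nrow(pr) > 0L) {
        pe <- pair_eval(d, charge[pr[, 1]] * charge[pr[, 2]],
                        0.5 * (sigma[pr[, 1]] + sigma[pr[, 2]]),
                        sqrt(epsilon[pr[, 1]] * epsilon[pr[, 2]]))
        energy <- energy + pe$energy
        forces <- add_at(forces, pr[, 1], pe$contrib)
        forces <- add_at(forces, pr[, 2], -pe$contrib)
      }
    }
    if (nrow(exceptions) > 0L) {
      ei <- as.integer(exceptions$i); ej <- as.integer(exceptions$j)
      d <- positions[ei, , drop = FALSE] - positions[ej, , drop = FALSE]
      if (periodic && !is.null(box)) d <- minimum_image(box, d)
      pe <- pair_eval(d, exceptions$chargeprod, exceptions$sigma,
                      exceptions$epsilon)
      energy <- energy + pe$energy
      forces <- add_at(forces, ei, pe$contrib)
      forces <- add_at(forces, ej, -pe$contrib)
    }
    list(energy = energy, forces = forces)
  })
}
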