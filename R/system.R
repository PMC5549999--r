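# The molecular system model. Units are fixed globally: nm, ps, amu, kJ/mol,
# elementary charge, kelvin. kB below follows from those choices.

#' Boltzmann constant in kJ/mol/K
#' @export
KB <- 0.00831446261815324

#' Coulomb constant in kJ mol^-1 nm e^-2
#' @export
COULOMB_CONSTANT <- 138.935456

#' Create a molecular system
#'
#' @param masses numeric vector of particle masses (amu); 0 marks a virtual
#'   site (which must also carry a site definition).
#' @param constraints list of \code{list(i, j, distance)} rigid distance
#'   constraints (1-based indices, nm).
#' @param force_terms list of force terms (see \code{\link{custom_bond_term}}
#'   and friends).
#' @param virtual_sites list of \code{mm_vsite} definitions (see
#'   \code{\link{three_particle_site}}).
#' @param box optional \code{mm_box} for periodic systems.
#' @return an object of class \code{mm_system}.
#' @export
mm_system <- function(masses, constraints = list(), force_terms = list(),
                      virtual_sites = list(), box = NULL) {
  masses <- as.numeric(masses)
  if (any(masses < 0)) stop("masses must be non-negative")
  vsite_idx <- vapply(virtual_sites, function(s) s$site, integer(1))
  if (anyDuplicated(vsite_idx)) stop("duplicate virtual-site definitions")
  zero_mass <- which(masses == 0)
  if (!setequal(zero_mass, vsite_idx))
    stop("a particle has mass 0 iff it is a virtual site")
  seen <- character(0)
  for (con in constraints) {
    if (con$i == con$j) stop("constraint endpoints must be distinct")
    if (con$i < 1 || con$j < 1 || con$i > length(masses) || con$j > length(masses))
      stop("constraint index out of range")
    if (con$i %in% vsite_idx || con$j %in% vsite_idx)
      stop("constraints may not touch virtual sites")
    if (con$distance <= 0) stop("constraint distance must be positive")
    key <- paste(sort(c(con$i, con$j)), collapse = "-")
    if (key %in% seen) stop("duplicate constraint")
    seen <- c(seen, key)
  }
  structure(list(masses = masses, constraints = constraints,
                 force_terms = force_terms, virtual_sites = virtual_sites,
                 box = box),
            class = "mm_system")
}

#' @export
print.mm_system <- function(x, ...) {
  cat("<mm_system>", length(x$masses), "particles,",
      length(x$constraints), "constraints,",
      length(x$force_terms), "force terms,",
      length(x$virtual_sites), "virtual sites,",
      if (is.null(x$box)) "non-periodic" else "periodic", "\n")
  invisible(x)
}

n_particles <- function(system) length(system$masses)

virtual_site_indices <- function(system) {
  vapply(system$virtual_sites, function(s) s$site, integer(1))
}

#' Create a simulation state
#'
#' @param positions N x 3 matrix (nm).
#' @param velocities N x 3 matrix (nm/ps); defaults to zeros.
#' @param time simulation time (ps).
#' @return an object of class \code{mm_state}.
#' @export
mm_state <- function(positions, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  velocities <- as.matrix(velocities)
  stopifnot(identical(dim(velocities), dim(positions)))
  structure(list(time = time, positions = positions, velocities = velocities,
                 forces = NULL, potential_energy = NA_real_,
                 kinetic_energy = NA_real_),
            class = "mm_state")
}

#' Kinetic energy of a state
#'
#' Sum of m v^2 / 2 over non-virtual particles, in kJ/mol.
#' @param system an \code{mm_system}.
#' @param state an \code{mm_state} with velocities set.
#' @export
kinetic_energy <- function(system, state) {
  m <- system$masses
  sum(0.5 * m * rowSums(state$velocities^2))
}

#' Number of degrees of freedom used for temperature reporting
#'
#' 3 x (non-virtual particles) minus the number of constraints minus 3 for
#' center-of-mass motion.
#' @param system an \code{mm_system}.
#' @export
degrees_of_freedom <- function(system) {
  3L * sum(system$masses > 0) - length(system$constraints) - 3L
}

#' Draw Maxwell-Boltzmann velocities at a temperature
#'
#' Each Cartesian component is Gaussian with variance kB T / m; virtual
#' sites get zero velocity. Deterministic for a fixed seed.
#'
#' @param system an \code{mm_system}.
#' @param temperature kelvin, >= 0.
#' @param seed integer RNG seed.
#' @return N x 3 velocity matrix (nm/ps).
#' @export
set_velocities_to_temperature <- function(system, temperature, seed) {
  stopifnot(temperature >= 0)
  m <- system$masses
  n <- length(m)
  v <- matrix(0, n, 3)
  if (temperature > 0) {
    mobile <- m > 0
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    sd <- sqrt(KB * temperature / m[mobile])
    v[mobile, ] <- matrix(stats::rnorm(3 * sum(mobile)), ncol = 3) * sd
  }
  v
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Repartition hydrogen masses
#'
#' Sets every flagged hydrogen's mass to \code{target_mass} and subtracts the
#' difference from the single heavy atom it is bonded to, leaving the total
#' system mass exactly unchanged. Used to push the fastest vibrational
#' frequencies down so a larger time step is stable.
#'
#' @param system an \code{mm_system}.
#' @param bonds two-column integer matrix of bonded pairs (1-based).
#' @param hydrogen_flags logical vector, TRUE for hydrogens.
#' @param target_mass amu, default 4.
#' @return the modified \code{mm_system}.
#' @export
repartition_hydrogen_mass <- function(system, bonds, hydrogen_flags,
                                      target_mass = 4) {
  m <- system$masses
  if (length(hydrogen_flags) != length(m))
    stop("hydrogen_flags length must match particle count")
  bonds <- matrix(as.integer(bonds), ncol = 2)
  for (h in which(hydrogen_flags)) {
    partners <- c(bonds[bonds[, 1] == h, 2], bonds[bonds[, 2] == h, 1])
    partners <- partners[!hydrogen_flags[partners]]
    if (length(partners) != 1L)
      stop(sprintf("hydrogen %d must be bonded to exactly one heavy atom", h))
    delta <- target_mass - m[h]
    if (m[partners] - delta <= 0)
      stop(sprintf("heavy atom %d mass would become non-positive", partners))
    m[h] <- target_mass
    m[partners] <- m[partners] - delta
  }
  system$masses <- m
  system
}
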