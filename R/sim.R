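# Simulation orchestration: force dispatch with precision modes and
# deterministic fixed-point accumulation, energy minimization, the
# simulation loop with reporters, the drift-rate estimator, per-category
# energy decomposition, and force-projection comparison.

# ---- 32-bit float emulation ------------------------------------------------

# round values through IEEE binary32; used to emulate single-precision
# arithmetic paths on double hardware
float32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                 what = "numeric", size = 4L, n = length(x))
  dim(out) <- d
  out
}

# ---- 64-bit fixed-point accumulator ----------------------------------------

# Two-limb (base 2^32) exact integer representation of a 64-bit signed
# fixed-point accumulator at 2^32 counts per kJ/mol/nm. Integer arithmetic
# on doubles below 2^53 is exact, so accumulation is associative and
# commutative: totals are bit-identical under any summation order.
FP_SCALE <- 2^32

#' Create a fixed-point force accumulator
#' @param n number of components.
#' @return an accumulator object (environment).
#' @export
fp_accumulator <- function(n) {
  acc <- new.env(parent = emptyenv())
  acc$hi <- numeric(n)
  acc$lo <- numeric(n)
  acc
}

#' Add values to a fixed-point accumulator
#'
#' Values are quantized to integer counts at 2^32 counts per kJ/mol/nm.
#' Magnitudes at or above 2^21 kJ/mol/nm per contribution, or accumulated
#' totals beyond the signed 64-bit range, raise an overflow error.
#'
#' @param acc accumulator from \code{\link{fp_accumulator}}.
#' @param values numeric vector of contributions.
#' @export
fp_add <- function(acc, values) {
  if (any(abs(values) >= 2^21))
    stop("fixed-point accumulator overflow: force contribution too large")
  counts <- round(as.numeric(values) * FP_SCALE)
  chi <- floor(counts / 2^32)
  clo <- counts - chi * 2^32
  lo <- acc$lo + clo
  carry <- floor(lo / 2^32)
  acc$hi <- acc$hi + chi + carry
  acc$lo <- lo - carry * 2^32
  if (any(abs(acc$hi) >= 2^31))
    stop("fixed-point accumulator overflow: accumulated force out of range")
  invisible(acc)
}

#' Read a fixed-point accumulator back as doubles
#' @param acc accumulator.
#' @return numeric vector of accumulated values (kJ/mol/nm).
#' @export
fp_value <- function(acc) {
  acc$hi + acc$lo / FP_SCALE
}

# ---- force dispatch --------------------------------------------------------

#' Compute total potential energy and forces
#'
#' Evaluates every force term of the system. Precision modes: "double" is
#' plain double arithmetic; in "mixed" and "single" the positions and each
#' term's energy and forces are rounded through 32-bit floats (forces in
#' single precision), with accumulation in double ("mixed") or 32-bit
#' ("single"). With \code{fixed_point = TRUE} per-term force contributions
#' are accumulated as 64-bit fixed-point integers (2^32 counts per
#' kJ/mol/nm), making the total independent of term order. Forces landing
#' on virtual sites are redistributed to their parents term by term.
#'
#' @param system an \code{mm_system}.
#' @param positions N x 3 matrix (nm); virtual sites should be current
#'   (see \code{\link{update_all_sites}}).
#' @param mode "double", "mixed", or "single".
#' @param fixed_point logical, use fixed-point force accumulation.
#' @return list(energy, forces).
#' @export
compute_forces <- function(system, positions,
                           mode = c("double", "mixed", "single"),
                           fixed_point = FALSE) {
  mode <- match.arg(mode)
  emulate32 <- mode %in% c("single", "mixed")
  if (emulate32) positions <- float32(positions)
  n <- nrow(positions)
  energy <- 0
  acc <- if (fixed_point) fp_accumulator(3L * n) else NULL
  forces <- matrix(0, n, 3)
  for (term in system$force_terms) {
    res <- term$eval(positions, system$box)
    fterm <- res$forces
    eterm <- res$energy
    if (length(system$virtual_sites) > 0)
      fterm <- redistribute_vsite_forces(system, positions, fterm)
    if (emulate32) {
      fterm <- float32(fterm)
      eterm <- float32(eterm)
    }
    if (fixed_point) {
      fp_add(acc, as.vector(fterm))
    } else {
      forces <- forces + fterm
      if (mode == "single") forces <- float32(forces)
    }
    energy <- energy + eterm
    if (mode == "single") energy <- float32(energy)
  }
  if (fixed_point)
    forces <- matrix(fp_value(acc), n, 3)
  list(energy = energy, forces = forces)
}

#' Per-category energy decomposition
#'
#' Sums term energies by their category label (Bond, Angle, Dihedral,
#' Nonbonded, OBC, ...) and appends their exact sum as "Total".
#'
#' @param system an \code{mm_system}.
#' @param state an \code{mm_state} (or an N x 3 position matrix).
#' @return named numeric vector of energies in kJ/mol.
#' @export
energy_decomposition <- function(system, state) {
  positions <- if (inherits(state, "mm_state")) state$positions else state
  positions <- update_all_sites(system, positions)
  cats <- c("Bond", "Angle", "Dihedral", "Nonbonded", "OBC")
  out <- stats::setNames(numeric(length(cats)), cats)
  for (term in system$force_terms) {
    e <- term$eval(positions, system$box)$energy
    cat <- if (term$category %in% cats) term$category else "Other"
    if (!cat %in% names(out)) out[cat] <- 0
    out[cat] <- out[cat] + e
  }
  out <- out[out != 0 | names(out) %in% c("Bond", "Angle", "Dihedral",
                                          "Nonbonded")]
  c(out, Total = sum(out))
}

# ---- minimization ----------------------------------------------------------

#' Local energy minimization
#'
#' Limited-memory quasi-Newton (L-BFGS-B) on the non-virtual coordinates,
#' with virtual sites repositioned inside every evaluation and constraints
#' re-projected (SHAKE) on exit. Stops when the largest force component is
#' at most \code{force_tolerance} or the iteration cap is reached.
#'
#' @param system an \code{mm_system}.
#' @param state an \code{mm_state}.
#' @param force_tolerance kJ/mol/nm, default 10.
#' @param max_iterations L-BFGS iteration cap, default 1000.
#' @return the minimized \code{mm_state} (forces and potential energy set).
#' @export
minimize <- function(system, state, force_tolerance = 10,
                     max_iterations = 1000L) {
  mobile <- which(system$masses > 0)
  pos0 <- update_all_sites(system, state$positions)
  e0 <- compute_forces(system, pos0)$energy
  if (!is.finite(e0)) stop("non-finite initial energy")
  unpack <- function(par) {
    pos <- pos0
    pos[mobile, ] <- matrix(par, ncol = 3)
    update_all_sites(system, pos)
  }
  fn <- function(par) {
    e <- compute_forces(system, unpack(par))$energy
    if (!is.finite(e)) stop("non-finite energy during minimization")
    e
  }
  gr <- function(par) {
    -as.vector(compute_forces(system, unpack(par))$forces[mobile, ])
  }
  par <- as.vector(pos0[mobile, ])
  res <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iterations,
                                     factr = 10, pgtol = force_tolerance / 10))
  pos <- unpack(res$par)
  if (length(system$constraints) > 0) {
    inv_m <- ifelse(system$masses > 0, 1 / system$masses, 0)
    pos <- shake_positions(system$constraints, state$positions, pos, inv_m)
    pos <- update_all_sites(system, pos)
  }
  state$positions <- pos
  ef <- compute_forces(system, pos)
  state$potential_energy <- ef$energy
  state$forces <- ef$forces
  state
}

# ---- reporters -------------------------------------------------------------

#' Reporter collecting state data at fixed intervals
#'
#' Collects a row every \code{interval} steps with the requested quantities
#' and optionally writes CSV to \code{file} when the run finishes. The
#' accumulated table is available as \code{reporter$data()}.
#'
#' @param interval steps between records, >= 1.
#' @param file optional CSV path.
#' @param quantities subset of c("time", "potential_energy",
#'   "kinetic_energy", "temperature", "total_energy").
#' @return a reporter object.
#' @export
state_data_reporter <- function(interval, file = NULL,
                                quantities = c("time", "potential_energy",
                                               "kinetic_energy",
                                               "temperature",
                                               "total_energy")) {
  stopifnot(interval >= 1)
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  obj <- list(
    interval = as.integer(interval),
    report = function(system, state) {
      ke <- kinetic_energy(system, state)
      pe <- state$potential_energy
      row <- list(time = state$time, potential_energy = pe,
                  kinetic_energy = ke,
                  temperature = 2 * ke / (degrees_of_freedom(system) * KB),
                  total_energy = pe + ke)
      env$rows[[length(env$rows) + 1L]] <- row[quantities]
    },
    finish = function() {
      df <- do.call(rbind, lapply(env$rows, function(r)
        as.data.frame(r, check.names = FALSE)))
      if (!is.null(file) && !is.null(df))
        utils::write.csv(df, file, row.names = FALSE)
      invisible(df)
    },
    data = function() {
      do.call(rbind, lapply(env$rows, function(r)
        as.data.frame(r, check.names = FALSE)))
    })
  class(obj) <- "mm_reporter"
  obj
}

#' Reporter writing a DCD trajectory
#'
#' CHARMM/X-PLOR binary layout with the unit-cell block when the system is
#' periodic; coordinates are written in Angstroms.
#'
#' @param file output path.
#' @param interval steps between frames.
#' @return a reporter object.
#' @export
dcd_reporter <- function(file, interval) {
  stopifnot(interval >= 1)
  env <- new.env(parent = emptyenv())
  env$frames <- list()
  env$box <- NULL
  obj <- list(
    interval = as.integer(interval),
    report = function(system, state) {
      env$frames[[length(env$frames) + 1L]] <- state$positions * 10  # nm -> A
      if (!is.null(system$box)) env$box <- unclass(system$box) * 10
    },
    finish = function() {
      write_dcd(file, env$frames, env$box, interval)
      invisible(file)
    },
    data = function() env$frames)
  class(obj) <- "mm_reporter"
  obj
}

# minimal DCD writer (little-endian, Fortran record markers)
write_dcd <- function(file, frames, box = NULL, interval = 1L) {
  con <- file(file, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L,
                               endian = "little")
  nframes <- length(frames)
  icntrl <- integer(20)
  icntrl[1] <- nframes
  icntrl[2] <- interval
  icntrl[3] <- interval
  icntrl[4] <- nframes * interval
  icntrl[11] <- if (is.null(box)) 0L else 1L
  icntrl[20] <- 24L
  wint(84L)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  wint(icntrl)
  wint(84L)
  title <- sprintf("%-80s", "Created by minimm")
  wint(4L + 80L); wint(1L); writeChar(title, con, nchars = 80, eos = NULL)
  wint(4L + 80L)
  natoms <- nrow(frames[[1]])
  wint(4L); wint(natoms); wint(4L)
  for (fr in frames) {
    if (!is.null(box)) {
      la <- sqrt(sum(box[1, ]^2)); lb <- sqrt(sum(box[2, ]^2))
      lc <- sqrt(sum(box[3, ]^2))
      cosg <- sum(box[1, ] * box[2, ]) / (la * lb)
      cosb <- sum(box[1, ] * box[3, ]) / (la * lc)
      cosa <- sum(box[2, ] * box[3, ]) / (lb * lc)
      wint(48L)
      writeBin(as.numeric(c(la, cosg, lb, cosb, cosa, lc)), con, size = 8L,
               endian = "little")
      wint(48L)
    }
    for (d in 1:3) {
      wint(4L * natoms)
      writeBin(as.numeric(fr[, d]), con, size = 4L, endian = "little")
      wint(4L * natoms)
    }
  }
  invisible(file)
}

# ---- simulation loop -------------------------------------------------------

#' Advance a simulation
#'
#' Runs \code{n_steps} of the integrator program, firing reporters at their
#' intervals. With identical (seed, mode) arguments reruns are bit-identical.
#'
#' @param system an \code{mm_system}.
#' @param program an \code{mm_integrator}.
#' @param state an \code{mm_state}.
#' @param n_steps number of time steps.
#' @param reporters list of reporter objects.
#' @param mode precision mode for force evaluation and integration.
#' @param seed integer seed for the integrator's random streams.
#' @param fixed_point logical, fixed-point force accumulation.
#' @return the final \code{mm_state}.
#' @export
run_simulation <- function(system, program, state, n_steps,
                           reporters = list(),
                           mode = c("double", "mixed", "single"),
                           seed = 0L, fixed_point = FALSE) {
  mode <- match.arg(mode)
  force_fn <- function(pos) compute_forces(system, pos, mode = mode,
                                           fixed_point = fixed_point)
  state$positions <- update_all_sites(system, state$positions)
  if (n_steps < 1) return(state)
  for (step in seq_len(n_steps)) {
    state <- execute_step(program, system, state, seed = seed,
                          step_index = step, force_fn = force_fn,
                          precision = mode)
    for (rep in reporters) {
      if (step %% rep$interval == 0L) {
        # refresh energies at the reported configuration
        res <- force_fn(state$positions)
        state$forces <- res$forces
        state$potential_energy <- res$energy
        state$kinetic_energy <- kinetic_energy(system, state)
        rep$report(system, state)
      }
    }
  }
  for (rep in reporters) rep$finish()
  state
}

# ---- analysis --------------------------------------------------------------

#' Energy drift rate by linear regression
#'
#' Ordinary least-squares slope of total energy versus time and its
#' standard error — the standard estimator for secular energy drift in a
#' nominally energy-conserving simulation.
#'
#' @param times numeric vector (ps), length >= 3.
#' @param total_energies numeric vector (kJ/mol), same length.
#' @return list(slope, stderr) in (kJ/mol)/ps.
#' @export
drift_rate <- function(times, total_energies) {
  if (length(times) < 3 || length(total_energies) != length(times))
    stop("need at least 3 aligned (time, energy) samples")
  fit <- stats::lm(total_energies ~ times)
  # summary.lm warns on exact fits; stderr 0 is a legitimate answer here
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(sm["times", "Estimate"]),
       stderr = unname(sm["times", "Std. Error"]))
}

#' Normalized projection of reference forces onto test forces
#'
#' Per atom, \code{(f_ref . f_test) / (f_test . f_test)}; the summary used
#' to cross-validate forces between engines (1.0 means perfect agreement).
#'
#' @param f_ref,f_test N x 3 force matrices.
#' @return list(mean, min, max) over atoms.
#' @export
force_projection <- function(f_ref, f_test) {
  f_ref <- as.matrix(f_ref); f_test <- as.matrix(f_test)
  if (!identical(dim(f_ref), dim(f_test)))
    stop("force arrays must have identical dimensions")
  denom <- rowSums(f_test * f_test)
  if (any(denom == 0)) stop("zero-norm test force on at least one atom")
  p <- rowSums(f_ref * f_test) / denom
  list(mean = mean(p), min = min(p), max = max(p))
}
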