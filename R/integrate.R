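# The custom-integrator DSL. A time-stepping algorithm is an ordered program
# of operations: per-degree-of-freedom computations (evaluated elementwise
# on the 3N Cartesian components), global computations, sums over degrees of
# freedom, constraint applications, and if/while blocks. The builtins
# x, v, f (3N component vectors), m (per-particle mass broadcast, Inf for
# virtual sites), dt, and the random streams gaussian/uniform are available
# in every expression.

.mm_builtins <- c("x", "v", "f", "m", "dt", "gaussian", "uniform")
.mm_comparators <- c("<", "<=", ">", ">=", "=", "!=")

#' DSL step: per-degree-of-freedom computation
#' @param target name of a per-DOF variable, or "x" or "v".
#' @param expression expression string evaluated elementwise on all 3N
#'   components.
#' @export
step_compute_per_dof <- function(target, expression) {
  structure(list(kind = "compute_per_dof", target = target,
                 expression = expression), class = "mm_step_op")
}

#' DSL step: global (scalar) computation
#' @param target name of a global variable.
#' @param expression expression string evaluated once.
#' @export
step_compute_global <- function(target, expression) {
  structure(list(kind = "compute_global", target = target,
                 expression = expression), class = "mm_step_op")
}

#' DSL step: sum an expression over all degrees of freedom
#'
#' Virtual-site components (mass Inf in the DSL) are excluded from the sum.
#' @param target name of a global variable receiving the sum.
#' @param expression per-DOF expression summed over the 3N components.
#' @export
step_compute_sum <- function(target, expression) {
  structure(list(kind = "compute_sum", target = target,
                 expression = expression), class = "mm_step_op")
}

#' DSL step: project positions onto the constraint manifold (SHAKE)
#' @export
step_constrain_positions <- function() {
  structure(list(kind = "constrain_positions"), class = "mm_step_op")
}

#' DSL step: remove velocity components along constrained bonds (RATTLE)
#' @export
step_constrain_velocities <- function() {
  structure(list(kind = "constrain_velocities"), class = "mm_step_op")
}

#' DSL step: conditional block
#' @param lhs,rhs global expression strings.
#' @param comparator one of \code{"<", "<=", ">", ">=", "=", "!="}.
#' @param body list of step ops.
#' @export
step_if <- function(lhs, comparator, rhs, body) {
  stopifnot(comparator %in% .mm_comparators)
  structure(list(kind = "if_block", lhs = lhs, comparator = comparator,
                 rhs = rhs, body = body), class = "mm_step_op")
}

#' DSL step: while loop (condition re-evaluated before each iteration)
#'
#' Iterations are capped (default 1000 per time step) to catch
#' non-terminating programs.
#' @inheritParams step_if
#' @export
step_while <- function(lhs, comparator, rhs, body) {
  stopifnot(comparator %in% .mm_comparators)
  structure(list(kind = "while_block", lhs = lhs, comparator = comparator,
                 rhs = rhs, body = body), class = "mm_step_op")
}

compile_step_ops <- function(steps, known) {
  lapply(steps, function(op) {
    if (op$kind %in% c("compute_per_dof", "compute_global", "compute_sum")) {
      pe <- parse_expression(op$expression)
      unknown <- setdiff(pe$free_variables, known)
      if (length(unknown) > 0L)
        stop(sprintf("unbound variable(s) in '%s': %s", op$expression,
                     paste(unknown, collapse = ", ")))
      op$fn <- compile_expression(pe)
      op$free <- pe$free_variables
    } else if (op$kind %in% c("if_block", "while_block")) {
      for (side in c("lhs", "rhs")) {
        pe <- parse_expression(op[[side]])
        unknown <- setdiff(pe$free_variables, known)
        if (length(unknown) > 0L)
          stop(sprintf("unbound variable(s) in condition '%s'", op[[side]]))
        op[[paste0(side, "_fn")]] <- compile_expression(pe)
        op[[paste0(side, "_free")]] <- pe$free_variables
      }
      op$body <- compile_step_ops(op$body, known)
    }
    op
  })
}

#' Create a custom integrator program
#'
#' @param dt step size (ps).
#' @param steps ordered list of step ops (see \code{step_compute_per_dof}
#'   and friends); executed in order once per time step.
#' @param per_dof_variables named list of per-DOF variables and their
#'   initial values (scalar, broadcast to 3N).
#' @param global_variables named list of global variables and initial values.
#' @return an object of class \code{mm_integrator}.
#' @export
mm_integrator <- function(dt, steps, per_dof_variables = list(),
                          global_variables = list()) {
  stopifnot(dt > 0)
  vnames <- c(names(per_dof_variables), names(global_variables))
  if (anyDuplicated(vnames))
    stop("variable names must be unique across per-DOF and global scopes")
  clash <- intersect(vnames, .mm_builtins)
  if (length(clash) > 0L)
    stop(sprintf("variable name(s) collide with builtins: %s",
                 paste(clash, collapse = ", ")))
  for (op in steps) {
    if (op$kind == "compute_sum" &&
        (op$target %in% names(per_dof_variables) ||
           op$target %in% c("x", "v")))
      stop("compute_sum target must be a global variable")
    if (op$kind == "compute_per_dof" &&
        !(op$target %in% c("x", "v", names(per_dof_variables))))
      stop(sprintf("compute_per_dof target '%s' is not per-DOF", op$target))
    if (op$kind == "compute_global" &&
        !(op$target %in% names(global_variables)))
      stop(sprintf("compute_global target '%s' is not a global", op$target))
  }
  known <- c(.mm_builtins, vnames)
  steps <- compile_step_ops(steps, known)
  structure(list(dt = dt, steps = steps,
                 per_dof_variables = per_dof_variables,
                 global_variables = global_variables),
            class = "mm_integrator")
}

# deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, a, b) {
  ((as.double(seed) %% 1e6) * 1009 + (a %% 1e6) * 9176 + b * 131) %% 2147483629
}

#' Execute one time step of an integrator program
#'
#' Steps run in order. Any write to \code{x} invalidates the forces, which
#' are recomputed lazily (with virtual sites repositioned) before the next
#' read of \code{f}. \code{gaussian}/\code{uniform} draw fresh
#' i.i.d. values per component on every evaluation, from a counter-based
#' stream keyed by (seed, step index, evaluation index), so execution is
#' deterministic.
#'
#' @param program an \code{mm_integrator}.
#' @param system an \code{mm_system}.
#' @param state an \code{mm_state} (forces may be NULL; they are computed
#'   on demand).
#' @param seed integer RNG seed.
#' @param step_index integer index of this step in the trajectory (keys the
#'   random streams).
#' @param force_fn function(positions) -> list(energy, forces); defaults to
#'   evaluating the system's force terms in double precision.
#' @param precision one of "double", "mixed", "single"; in single mode each
#'   computed per-DOF/global value is rounded through 32-bit floats.
#' @param while_cap iteration cap for while blocks.
#' @return the updated \code{mm_state} (with \code{potential_energy} from
#'   the last force evaluation).
#' @export
execute_step <- function(program, system, state, seed = 0L, step_index = 1L,
                         force_fn = NULL, precision = "double",
                         while_cap = 1000L) {
  n <- n_particles(system)
  vs_idx <- virtual_site_indices(system)
  dof_mask <- rep(TRUE, n)
  if (length(vs_idx) > 0) dof_mask[vs_idx] <- FALSE
  dof_mask3 <- rep(dof_mask, each = 3)
  m3 <- rep(ifelse(system$masses > 0, system$masses, Inf), each = 3)
  if (is.null(force_fn))
    force_fn <- function(pos) compute_forces(system, pos)

  ctx <- new.env(parent = emptyenv())
  ctx$x <- as.vector(t(state$positions))
  ctx$v <- as.vector(t(state$velocities))
  ctx$forces_valid <- !is.null(state$forces)
  ctx$f <- if (ctx$forces_valid) as.vector(t(state$forces)) else numeric(3 * n)
  ctx$pe <- state$potential_energy
  ctx$eval_counter <- 0L
  for (nm in names(program$per_dof_variables))
    ctx[[nm]] <- rep(program$per_dof_variables[[nm]], length.out = 3 * n) +
      numeric(3 * n)
  for (nm in names(program$global_variables))
    ctx[[nm]] <- program$global_variables[[nm]]
  # persisted variable values across steps live on the state
  if (!is.null(state$integrator_variables))
    for (nm in names(state$integrator_variables))
      ctx[[nm]] <- state$integrator_variables[[nm]]

  round32 <- if (precision == "single") float32 else identity

  refresh_forces <- function() {
    if (!ctx$forces_valid) {
      pos <- matrix(ctx$x, ncol = 3, byrow = TRUE)
      pos <- update_all_sites(system, pos)
      ctx$x <- as.vector(t(pos))
      res <- force_fn(pos)
      ctx$f <- as.vector(t(res$forces))
      ctx$pe <- res$energy
      ctx$forces_valid <- TRUE
    }
  }

  lookup <- function(name, per_dof) {
    if (name == "f") { refresh_forces(); return(ctx$f) }
    if (name == "dt") return(program$dt)
    if (name == "m") return(m3)
    if (name == "gaussian" || name == "uniform") {
      ctx$eval_counter <- ctx$eval_counter + 1L
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(derive_seed(seed, step_index, ctx$eval_counter))
      k <- if (per_dof) 3L * n else 1L
      return(if (name == "gaussian") stats::rnorm(k) else stats::runif(k))
    }
    val <- ctx[[name]]
    if (is.null(val)) stop(sprintf("unbound variable '%s'", name))
    val
  }

  eval_op_expr <- function(op, per_dof, fn = op$fn, free = op$free) {
    args <- lapply(free, lookup, per_dof = per_dof)
    do.call(fn, args)
  }

  assign_target <- function(target, value) {
    value <- round32(value)
    if (target == "x") {
      old <- ctx$x
      val <- old
      val[dof_mask3] <- (value + 0 * old)[dof_mask3]
      pos <- matrix(val, ncol = 3, byrow = TRUE)
      pos <- update_all_sites(system, pos)
      ctx$x <- as.vector(t(pos))
      ctx$forces_valid <- FALSE
    } else if (target == "v") {
      val <- ctx$v
      val[dof_mask3] <- (value + 0 * val)[dof_mask3]
      val[!dof_mask3] <- 0
      ctx$v <- val
    } else {
      ctx[[target]] <- value
    }
  }

  check_condition <- function(op) {
    lhs <- eval_op_expr(op, FALSE, op$lhs_fn, op$lhs_free)[1]
    rhs <- eval_op_expr(op, FALSE, op$rhs_fn, op$rhs_free)[1]
    switch(op$comparator,
           "<" = lhs < rhs, "<=" = lhs <= rhs, ">" = lhs > rhs,
           ">=" = lhs >= rhs, "=" = lhs == rhs, "!=" = lhs != rhs)
  }

  run_ops <- function(ops) {
    for (op in ops) {
      switch(op$kind,
        compute_per_dof = assign_target(op$target,
                                        eval_op_expr(op, TRUE)),
        compute_global = assign_target(op$target,
                                       eval_op_expr(op, FALSE)[1]),
        compute_sum = {
          vals <- eval_op_expr(op, TRUE) + numeric(3 * n)
          assign_target(op$target, sum(vals[dof_mask3]))
        },
        constrain_positions = {
          if (length(system$constraints) > 0) {
            x_new <- matrix(ctx$x, ncol = 3, byrow = TRUE)
            x_ref <- state$positions
            inv_m <- ifelse(system$masses > 0, 1 / system$masses, 0)
            x_new <- shake_positions(system$constraints, x_ref, x_new, inv_m)
            x_new <- update_all_sites(system, x_new)
            ctx$x <- as.vector(t(x_new))
            ctx$forces_valid <- FALSE
          }
        },
        constrain_velocities = {
          if (length(system$constraints) > 0) {
            vmat <- matrix(ctx$v, ncol = 3, byrow = TRUE)
            xmat <- matrix(ctx$x, ncol = 3, byrow = TRUE)
            inv_m <- ifelse(system$masses > 0, 1 / system$masses, 0)
            vmat <- rattle_velocities(system$constraints, xmat, vmat, inv_m)
            ctx$v <- as.vector(t(vmat))
          }
        },
        if_block = if (check_condition(op)) run_ops(op$body),
        while_block = {
          iter <- 0L
          while (check_condition(op)) {
            iter <- iter + 1L
            if (iter > while_cap)
              stop("while block exceeded the iteration cap (likely non-terminating)")
            run_ops(op$body)
          }
        })
    }
  }

  run_ops(program$steps)

  state$positions <- matrix(ctx$x, ncol = 3, byrow = TRUE)
  state$velocities <- matrix(ctx$v, ncol = 3, byrow = TRUE)
  state$forces <- if (ctx$forces_valid) matrix(ctx$f, ncol = 3, byrow = TRUE)
                  else NULL
  state$potential_energy <- ctx$pe
  state$time <- state$time + program$dt
  vars <- list()
  for (nm in c(names(program$per_dof_variables),
               names(program$global_variables)))
    vars[[nm]] <- ctx[[nm]]
  state$integrator_variables <- vars
  state
}

#' The leapfrog Verlet algorithm as a five-step DSL program
#'
#' Saves x0, kicks v by dt f/m, drifts x by dt v, projects constraints, and
#' recomputes v = (x - x0)/dt. Velocities are therefore stored at the half
#' step; kinetic-energy reports use them as-is.
#'
#' @param dt step size (ps).
#' @return an \code{mm_integrator}.
#' @export
leapfrog_program <- function(dt) {
  mm_integrator(dt,
    steps = list(
      step_compute_per_dof("x0", "x"),
      step_compute_per_dof("v", "v+dt*f/m"),
      step_compute_per_dof("x", "x+dt*v"),
      step_constrain_positions(),
      step_compute_per_dof("v", "(x-x0)/dt")),
    per_dof_variables = list(x0 = 0))
}

#' A Langevin integrator as a DSL program
#'
#' Per-DOF update \code{v <- a v + (1-a) f/(m gamma) + sqrt(kB T (1-a^2)/m)
#' gaussian} with \code{a = exp(-gamma dt)}, followed by a position drift
#' and constraint projection. \code{friction = 0} reduces exactly to the
#' deterministic leapfrog kick-drift. Randomness is keyed by the seed given
#' to \code{\link{execute_step}} or \code{\link{run_simulation}}.
#'
#' @param temperature kelvin, >= 0.
#' @param friction collision rate gamma (1/ps), >= 0.
#' @param dt step size (ps).
#' @return an \code{mm_integrator}.
#' @export
langevin_program <- function(temperature, friction, dt) {
  stopifnot(temperature >= 0, friction >= 0)
  if (friction == 0) return(leapfrog_program(dt))
  a <- exp(-friction * dt)
  kick <- sprintf("%.17g*v + %.17g*f/m + sqrt(%.17g/m)*gaussian",
                  a, (1 - a) / friction, KB * temperature * (1 - a * a))
  mm_integrator(dt,
    steps = list(
      step_compute_per_dof("x0", "x"),
      step_compute_per_dof("v", kick),
      step_compute_per_dof("x", "x+dt*v"),
      step_constrain_positions(),
      step_compute_per_dof("v", "(x-x0)/dt")),
    per_dof_variables = list(x0 = 0))
}

# ---- constraint solvers ----------------------------------------------------

#' Iterative SHAKE position projection
#'
#' Corrects \code{x_new} so every distance constraint is satisfied to
#' relative tolerance \code{tol}, applying corrections along the
#' reference-geometry bond directions weighted by inverse masses (immobile
#' particles have inverse mass 0).
#'
#' @param constraints list of \code{list(i, j, distance)}.
#' @param x_ref N x 3 reference positions (pre-step geometry).
#' @param x_new N x 3 positions to correct.
#' @param inv_masses per-particle inverse masses (1/amu).
#' @param tol relative tolerance on constraint distances.
#' @param max_iter iteration cap.
#' @return corrected N x 3 positions.
#' @export
shake_positions <- function(constraints, x_ref, x_new, inv_masses,
                            tol = 1e-8, max_iter = 150L) {
  if (length(constraints) == 0L) return(x_new)
  ci <- vapply(constraints, function(cc) cc$i, numeric(1))
  cj <- vapply(constraints, function(cc) cc$j, numeric(1))
  cd <- vapply(constraints, function(cc) cc$distance, numeric(1))
  for (iter in seq_len(max_iter)) {
    converged <- TRUE
    for (k in seq_along(ci)) {
      i <- ci[k]; j <- cj[k]; d0 <- cd[k]
      s <- x_new[i, ] - x_new[j, ]
      d2 <- sum(s * s)
      if (abs(sqrt(d2) - d0) / d0 > tol) {
        converged <- FALSE
        rp <- x_ref[i, ] - x_ref[j, ]
        denom <- 2 * sum(s * rp) * (inv_masses[i] + inv_masses[j])
        if (abs(denom) < 1e-12)
          stop("SHAKE failure: constraint direction orthogonal to displacement")
        g <- (d2 - d0 * d0) / denom
        x_new[i, ] <- x_new[i, ] - g * inv_masses[i] * rp
        x_new[j, ] <- x_new[j, ] + g * inv_masses[j] * rp
      }
    }
    if (converged) return(x_new)
  }
  stop(sprintf("SHAKE did not converge within %d iterations", max_iter))
}

#' Iterative RATTLE velocity projection
#'
#' Removes the component of the relative velocity along each constrained
#' bond, so that constrained distances are stationary. Positions must
#' already satisfy the constraints.
#'
#' @param constraints list of \code{list(i, j, distance)}.
#' @param x N x 3 positions satisfying the constraints.
#' @param v N x 3 velocities.
#' @param inv_masses per-particle inverse masses.
#' @param tol tolerance on relative bond-direction velocity (nm/ps).
#' @param max_iter iteration cap.
#' @return corrected N x 3 velocities.
#' @export
rattle_velocities <- function(constraints, x, v, inv_masses, tol = 1e-8,
                              max_iter = 150L) {
  if (length(constraints) == 0L) return(v)
  ci <- vapply(constraints, function(cc) cc$i, numeric(1))
  cj <- vapply(constraints, function(cc) cc$j, numeric(1))
  for (iter in seq_len(max_iter)) {
    converged <- TRUE
    for (k in seq_along(ci)) {
      i <- ci[k]; j <- cj[k]
      rij <- x[i, ] - x[j, ]
      rv <- v[i, ] - v[j, ]
      cv <- sum(rv * rij)
      if (abs(cv) / sqrt(sum(rij * rij)) > tol) {
        converged <- FALSE
        kfac <- cv / (sum(rij * rij) * (inv_masses[i] + inv_masses[j]))
        v[i, ] <- v[i, ] - kfac * inv_masses[i] * rij
        v[j, ] <- v[j, ] + kfac * inv_masses[j] * rij
      }
    }
    if (converged) return(v)
  }
  stop(sprintf("RATTLE did not converge within %d iterations", max_iter))
}
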