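constant_force_system <- function() {
  # E = -x gives a constant unit force along x
  mm_system(masses = 1,
            force_terms = list(custom_external_term("0-x", 1L)))
}

test_that("the five-step leapfrog program has exact kick-drift semantics", {
  sys <- constant_force_system()
  st <- mm_state(matrix(0, 1, 3))
  prog <- leapfrog_program(1)
  s1 <- run_simulation(sys, prog, st, 1)
  expect_identical(s1$velocities[1, 1], 1)
  expect_identical(s1$positions[1, 1], 1)
  s2 <- run_simulation(sys, prog, st, 2)
  expect_identical(s2$velocities[1, 1], 2)
  expect_identical(s2$positions[1, 1], 3)
  # final-velocity rule is exactly (x - x0) / dt
  expect_identical(s2$velocities[1, 1],
                   s2$positions[1, 1] - s1$positions[1, 1])
})

test_that("global computations and per-DOF sums work as specified", {
  sys <- mm_system(masses = c(2, 1))
  st <- mm_state(matrix(0, 2, 3), rbind(c(1, 0, 0), c(0, 2, 0)))
  counter <- mm_integrator(1, list(step_compute_global("t", "t + dt")),
                           global_variables = list(t = 0))
  s <- st
  for (k in 1:5) s <- execute_step(counter, sys, s)
  expect_equal(s$integrator_variables$t, 5)
  sum_prog <- mm_integrator(1, list(step_compute_sum("twoKE", "m*v*v")),
                            global_variables = list(twoKE = 0))
  expect_equal(execute_step(sum_prog, sys, st)$integrator_variables$twoKE, 6)
})

test_that("program validation rejects malformed variable usage", {
  expect_error(mm_integrator(1, list(), per_dof_variables = list(x = 1)),
               "builtins")
  expect_error(mm_integrator(1, list(step_compute_per_dof("q", "x")),
                             global_variables = list(q = 0)),
               "not per-DOF")
  expect_error(mm_integrator(1, list(step_compute_sum("s", "v*w")),
                             global_variables = list(s = 0)),
               "unbound")
  expect_error(mm_integrator(1, list(step_compute_sum("p", "v")),
                             per_dof_variables = list(p = 0)),
               "global")
})

test_that("if and while blocks control execution; runaway loops are caught", {
  sys <- mm_system(masses = 1)
  st <- mm_state(matrix(0, 1, 3))
  prog <- mm_integrator(1, list(
    step_compute_global("n", "0"),
    step_while("n", "<", "5", list(step_compute_global("n", "n+1"))),
    step_if("n", "=", "5", list(step_compute_global("hit", "1"))),
    step_if("n", ">", "10", list(step_compute_global("hit", "-1")))),
    global_variables = list(n = 0, hit = 0))
  s <- execute_step(prog, sys, st)
  expect_equal(s$integrator_variables$n, 5)
  expect_equal(s$integrator_variables$hit, 1)
  runaway <- mm_integrator(1, list(
    step_while("0", "<", "1", list(step_compute_global("n", "n+1")))),
    global_variables = list(n = 0))
  expect_error(execute_step(runaway, sys, st), "iteration cap")
})

test_that("leapfrog conserves the oscillator energy with no secular drift", {
  # unit-mass 3D harmonic well, k = 1, period 2 pi
  sys <- mm_system(masses = 1, force_terms = list(
    custom_external_term("0.5*(x^2+y^2+z^2)", 1L)))
  st <- mm_state(matrix(c(1, 0, 0), 1, 3))
  rep1 <- state_data_reporter(10)
  run_simulation(sys, leapfrog_program(0.05), st, 10000, list(rep1))
  d <- rep1$data()
  e0 <- d$total_energy[1]
  # bounded oscillation: with velocities at half steps the apparent total
  # energy ripples at amplitude ~ omega dt / 2 (plus O(dt^2)); bound with
  # a factor-2 margin, and check the band does not widen over time
  expect_lt(max(abs(d$total_energy - e0)) / e0, 2 * (0.05 / 2 + 10 * 0.05^2))
  half <- seq_len(nrow(d)) <= nrow(d) / 2
  expect_lt(max(abs(d$total_energy[!half] - e0)),
            1.1 * max(abs(d$total_energy[half] - e0)))
  # no secular drift: |slope| below 1e-6 per period (2 pi time units)
  dr <- drift_rate(d$time, d$total_energy)
  expect_lt(abs(dr$slope) * 2 * pi, 1e-6)
})

test_that("a re-expressed leapfrog agrees with the builtin to 1e-10", {
  # LJ dimer, unconstrained; same algorithm written with different ops
  n <- 2
  term <- standard_nonbonded_term(numeric(n), rep(0.34, n), rep(0.996, n))
  sys <- mm_system(masses = rep(39.948, n), force_terms = list(term))
  st <- mm_state(rbind(c(0, 0, 0), c(0.42, 0, 0)),
                 rbind(c(0.05, 0.02, 0), c(-0.05, 0, 0.01)))
  alt <- mm_integrator(0.002, list(
    step_compute_per_dof("x0", "x"),
    step_compute_per_dof("dv", "dt*f/m"),
    step_compute_per_dof("v", "v+0.5*dv"),
    step_compute_per_dof("v", "v+0.5*dv"),
    step_compute_per_dof("x", "x+dt*v"),
    step_constrain_positions(),
    step_compute_per_dof("v", "(x-x0)/dt")),
    per_dof_variables = list(x0 = 0, dv = 0))
  a <- run_simulation(sys, leapfrog_program(0.002), st, 100)
  b <- run_simulation(sys, alt, st, 100)
  expect_lt(max(abs(a$positions - b$positions)), 1e-10)
})

test_that("constrained leapfrog keeps bond lengths at the target", {
  fx <- make_diatomic(k = 0, r0 = 0.1, r = 0.1)
  sys <- mm_system(masses = fx$system$masses,
                   constraints = list(list(i = 1, j = 2, distance = 0.1)),
                   force_terms = list(custom_external_term("0.1*x^2", 1:2)))
  st <- mm_state(rbind(c(0, 0, 0), c(0.1, 0, 0)),
                 rbind(c(0.1, 0.2, 0), c(-0.1, 0.1, 0.3)))
  st$velocities <- rattle_velocities(sys$constraints, st$positions,
                                     st$velocities,
                                     1 / sys$masses)
  s <- st
  prog <- leapfrog_program(0.002)
  for (k in 1:50) {
    s <- execute_step(prog, sys, s, force_fn = function(p)
      compute_forces(sys, p))
    d <- sqrt(sum((s$positions[1, ] - s$positions[2, ])^2))
    expect_lt(abs(d - 0.1) / 0.1, 1e-7)
  }
})

test_that("Langevin reduces to leapfrog at zero friction and thermalizes", {
  expect_identical(class(langevin_program(300, 0, 0.002)), "mm_integrator")
  # gamma = 0 gives the deterministic kick-drift update
  sys <- constant_force_system()
  st <- mm_state(matrix(0, 1, 3))
  s <- run_simulation(sys, langevin_program(300, 0, 1), st, 2)
  expect_identical(s$positions[1, 1], 3)
  # free particles: long-run per-DOF velocity variance approaches kB T / m
  # (100 independent particles sampled every step for tight statistics)
  m <- 39.948; Temp <- 300
  np <- 100
  sysf <- mm_system(masses = rep(m, np), force_terms = list())
  stf <- mm_state(matrix(0, np, 3))
  prog <- langevin_program(Temp, 5, 0.01)
  s <- stf
  ssq <- 0; count <- 0
  for (k in 1:4000) {
    s <- execute_step(prog, sysf, s, seed = 99L, step_index = k,
                      force_fn = function(p) list(energy = 0,
                                                  forces = p * 0))
    if (k > 200) { ssq <- ssq + sum(s$velocities^2); count <- count + 3 * np }
  }
  expect_equal(ssq / count, KB * Temp / m, tolerance = 0.03)
  # same seed gives a bit-identical trajectory
  a <- run_simulation(sysf, prog, stf, 100, seed = 5)
  b <- run_simulation(sysf, prog, stf, 100, seed = 5)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)
  c2 <- run_simulation(sysf, prog, stf, 100, seed = 6)
  expect_false(identical(a$positions, c2$positions))
})

test_that("SHAKE projects positions onto the constraint manifold", {
  # symmetric correction for an equal-mass diatomic
  out <- shake_positions(list(list(i = 1, j = 2, distance = 1)),
                         rbind(c(0, 0, 0), c(0, 0, 1.2)),
                         rbind(c(0, 0, 0), c(0, 0, 1.2)), c(1, 1))
  expect_equal(out, rbind(c(0, 0, 0.1), c(0, 0, 1.1)), tolerance = 1e-8)
  # immobile partner (inverse mass 0): only the mobile particle moves
  out2 <- shake_positions(list(list(i = 1, j = 2, distance = 1)),
                          rbind(c(0, 0, 0), c(0, 0, 1.2)),
                          rbind(c(0, 0, 0), c(0, 0, 1.2)), c(0, 1))
  expect_equal(out2[1, ], c(0, 0, 0))
  expect_equal(out2[2, ], c(0, 0, 1), tolerance = 1e-8)
  # rigid water triangle converges for many random perturbations
  rOH <- 0.09572; aHOH <- 104.52 * pi / 180
  ref <- rbind(c(0, 0, 0), c(rOH, 0, 0),
               c(rOH * cos(aHOH), rOH * sin(aHOH), 0))
  cons <- list(list(i = 1, j = 2, distance = rOH),
               list(i = 1, j = 3, distance = rOH),
               list(i = 2, j = 3, distance = 2 * rOH * sin(aHOH / 2)))
  invm <- 1 / c(15.9994, 1.008, 1.008)
  set.seed(77)
  for (t in 1:1000) {
    pert <- ref + matrix(stats::runif(9, -0.02, 0.02), 3)
    out <- shake_positions(cons, ref, pert, invm)
    for (cc in cons) {
      d <- sqrt(sum((out[cc$i, ] - out[cc$j, ])^2))
      expect_lt(abs(d - cc$distance) / cc$distance, 1e-7)
    }
  }
})

test_that("RATTLE removes bond-direction velocity without adding energy", {
  x <- rbind(c(0, 0, 0), c(1, 0, 0))
  cons <- list(list(i = 1, j = 2, distance = 1))
  # equal and opposite radial velocities are zeroed
  v <- rbind(c(0.3, 0, 0), c(-0.3, 0, 0))
  out <- rattle_velocities(cons, x, v, c(1, 1))
  expect_equal(out, matrix(0, 2, 3), tolerance = 1e-9)
  # tangential velocities untouched
  vt <- rbind(c(0, 0.4, 0), c(0, 0.4, -0.2))
  expect_equal(rattle_velocities(cons, x, vt, c(1, 1)), vt)
  # random systems: postcondition holds, kinetic energy does not increase
  set.seed(78)
  for (t in 1:50) {
    n <- 4
    xs <- matrix(stats::rnorm(3 * n), n)
    cons2 <- list(list(i = 1, j = 2,
                       distance = sqrt(sum((xs[1, ] - xs[2, ])^2))),
                  list(i = 2, j = 3,
                       distance = sqrt(sum((xs[2, ] - xs[3, ])^2))))
    vs <- matrix(stats::rnorm(3 * n), n)
    m <- stats::runif(n, 1, 16)
    out <- rattle_velocities(cons2, xs, vs, 1 / m)
    for (cc in cons2) {
      rij <- xs[cc$i, ] - xs[cc$j, ]
      rv <- out[cc$i, ] - out[cc$j, ]
      expect_lt(abs(sum(rv * rij)) / sqrt(sum(rij * rij)), 1e-7)
    }
    expect_lte(sum(0.5 * m * rowSums(out^2)),
               sum(0.5 * m * rowSums(vs^2)) + 1e-12)
  }
})
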