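lj_expr <- paste0("4*eps*((sig/r)^12-(sig/r)^6); sig=0.5*(sig1+sig2); ",
                  "eps=sqrt(eps1*eps2)")

test_that("every force term passes the finite-difference gradient check", {
  set.seed(1)
  make_terms <- function() list(
    bond = list(custom_bond_term("0.5*kb*(r-r0)^2", matrix(c(1, 2), 1),
                                 c("kb", "r0"), matrix(c(250, 0.15), 1)),
                4, 0.3),
    angle = list(custom_angle_term("ka*(theta-t0)^2", matrix(1:3, 1),
                                   c("ka", "t0"), matrix(c(60, 1.8), 1)),
                 4, 0.6),
    torsion = list(custom_torsion_term("kt*(1+cos(2*theta-0.4))",
                                       matrix(1:4, 1), "kt", matrix(2, 1)),
                   5, 0.8),
    external = list(custom_external_term("x^2+sin(y)+exp(0.3*z)", 1:3),
                    4, 1),
    nonbonded = list(custom_nonbonded_term(lj_expr, c("sig", "eps"),
                                           cbind(rep(0.3, 6),
                                                 rep(0.5, 6))),
                     6, 1.2),
    compound = list(custom_compound_bond_term(
      "distance(p1,p2)*angle(p1,p2,p3)+0.2*dihedral(p1,p2,p3,p4)^2",
      matrix(1:4, 1)), 5, 0.9),
    centroid = list(custom_centroid_bond_term(
      "kc*(distance(p1,p2)-0.4)^2",
      list(list(indices = 1:2, weights = c(1, 2)),
           list(indices = 3:5, weights = c(1, 1, 1))),
      matrix(1:2, 1), "kc", matrix(30, 1)), 5, 0.7),
    standard_bond = list(harmonic_bond_term(
      data.frame(i = c(1, 2), j = c(2, 3), k = c(300, 200),
                 r0 = c(0.12, 0.2))), 4, 0.4),
    standard_angle = list(harmonic_angle_term(
      data.frame(i = 1, j = 2, k = 3, kf = 80, theta0 = 1.9)), 4, 0.6),
    standard_torsion = list(periodic_torsion_term(
      data.frame(i = 1, j = 2, k = 3, l = 4, kf = 3, n = 3, gamma = 0.5)),
      5, 0.8),
    standard_nb = list(standard_nonbonded_term(
      stats::runif(6, -0.5, 0.5), stats::runif(6, 0.25, 0.35),
      stats::runif(6, 0.2, 0.8),
      exceptions = data.frame(i = 1, j = 2, chargeprod = 0.05,
                              sigma = 0.3, epsilon = 0.2)), 6, 1.1),
    obc = list(obc_term(stats::runif(6, -0.8, 0.8),
                        stats::runif(6, 0.12, 0.2),
                        stats::runif(6, 0.7, 0.9)), 6, 0.6))

  for (nm in names(make_terms())) {
    spec <- make_terms()[[nm]]
    for (cfg in 1:20) {
      pos <- matrix(stats::rnorm(3 * spec[[2]]), spec[[2]]) * spec[[3]]
      err <- fd_force_error(spec[[1]], pos)
      expect_lt(err, 1e-4)
    }
  }
})

test_that("interparticle terms conserve net force and torque", {
  set.seed(2)
  terms <- list(
    custom_bond_term("r^3", matrix(c(1, 2), 1)),
    custom_angle_term("theta^2", matrix(1:3, 1)),
    custom_torsion_term("sin(theta)", matrix(1:4, 1)),
    custom_nonbonded_term(lj_expr, c("sig", "eps"),
                          cbind(rep(0.3, 5), rep(0.4, 5))),
    custom_centroid_bond_term("distance(p1,p2)^2",
                              list(list(indices = 1:2, weights = c(1, 1)),
                                   list(indices = 3:5,
                                        weights = c(1, 2, 1))),
                              matrix(1:2, 1)),
    obc_term(stats::runif(5, -0.5, 0.5), rep(0.15, 5), rep(0.8, 5)),
    harmonic_bond_term(data.frame(i = 1, j = 2, k = 100, r0 = 0.2)))
  for (term in terms) for (t in 1:5) {
    pos <- matrix(stats::rnorm(15), 5)
    f <- evaluate_force_term(term, pos)$forces
    expect_lt(max(abs(colSums(f))), 1e-9)
    torque <- colSums(cbind(pos[, 2] * f[, 3] - pos[, 3] * f[, 2],
                            pos[, 3] * f[, 1] - pos[, 1] * f[, 3],
                            pos[, 1] * f[, 2] - pos[, 2] * f[, 1]))
    expect_lt(max(abs(torque)), 1e-8)
  }
})

test_that("energies are translation invariant for non-periodic terms", {
  set.seed(3)
  term <- standard_nonbonded_term(stats::runif(5, -1, 1),
                                  stats::runif(5, 0.25, 0.35),
                                  stats::runif(5, 0.2, 1))
  pos <- matrix(stats::rnorm(15), 5)
  e0 <- evaluate_force_term(term, pos)$energy
  for (t in 1:5) {
    shift <- matrix(stats::rnorm(3), 5, 3, byrow = TRUE) * 10
    e1 <- evaluate_force_term(term, pos + shift)$energy
    expect_equal(e1, e0, tolerance = 1e-10)
  }
})

test_that("custom expression encodings match the standard terms exactly", {
  set.seed(4)
  # harmonic bond on 100 random diatomics
  std <- harmonic_bond_term(data.frame(i = 1, j = 2, k = 180, r0 = 0.14))
  cus <- custom_bond_term("kb*(r-r0)^2", matrix(c(1, 2), 1), c("kb", "r0"),
                          matrix(c(180, 0.14), 1))
  for (t in 1:100) {
    pos <- matrix(stats::rnorm(6), 2) * 0.3
    a <- evaluate_force_term(std, pos); b <- evaluate_force_term(cus, pos)
    expect_lt(abs(a$energy - b$energy) / max(1e-10, abs(a$energy)), 1e-10)
    expect_lt(max(abs(a$forces - b$forces)), 1e-8 * max(1, max(abs(a$forces))))
  }
  # harmonic angle
  stda <- harmonic_angle_term(data.frame(i = 1, j = 2, k = 3, kf = 70,
                                         theta0 = 2.0))
  cusa <- custom_angle_term("ka*(theta-t0)^2", matrix(1:3, 1), c("ka", "t0"),
                            matrix(c(70, 2.0), 1))
  # periodic torsion
  stdt <- periodic_torsion_term(data.frame(i = 1, j = 2, k = 3, l = 4,
                                           kf = 4, n = 2, gamma = 0.7))
  cust <- custom_torsion_term("kt*(1+cos(2*theta-0.7))", matrix(1:4, 1),
                              "kt", matrix(4, 1))
  for (t in 1:30) {
    pos3 <- matrix(stats::rnorm(9), 3)
    a <- evaluate_force_term(stda, pos3); b <- evaluate_force_term(cusa, pos3)
    expect_lt(abs(a$energy - b$energy) / max(1e-10, abs(a$energy)), 1e-10)
    expect_lt(max(abs(a$forces - b$forces)),
              1e-8 * max(1, max(abs(a$forces))))
    pos4 <- matrix(stats::rnorm(12), 4)
    a <- evaluate_force_term(stdt, pos4); b <- evaluate_force_term(cust, pos4)
    expect_lt(abs(a$energy - b$energy) / max(1e-10, abs(a$energy)), 1e-10)
    expect_lt(max(abs(a$forces - b$forces)),
              1e-8 * max(1, max(abs(a$forces))))
  }
  # LJ gas, 30 particles
  n <- 30
  sig <- stats::runif(n, 0.25, 0.35); eps <- stats::runif(n, 0.2, 1)
  stdlj <- standard_nonbonded_term(numeric(n), sig, eps)
  cuslj <- custom_nonbonded_term(lj_expr, c("sig", "eps"), cbind(sig, eps))
  pos <- matrix(stats::runif(3 * n, 0, 3), n)
  a <- evaluate_force_term(stdlj, pos); b <- evaluate_force_term(cuslj, pos)
  expect_lt(abs(a$energy - b$energy) / abs(a$energy), 1e-10)
  expect_lt(max(abs(a$forces - b$forces)) / max(abs(a$forces)), 1e-8)
})

test_that("frozen pointwise values: LJ minimum, Coulomb constant, examples", {
  # LJ dimer at the minimum
  t4 <- custom_nonbonded_term(lj_expr, c("sig", "eps"),
                              cbind(c(1, 1), c(1, 1)))
  expect_equal(evaluate_force_term(
    t4, rbind(c(0, 0, 0), c(2^(1 / 6), 0, 0)))$energy, -1.0)
  # LJ at r = sigma is zero
  expect_equal(evaluate_force_term(
    t4, rbind(c(0, 0, 0), c(1, 0, 0)))$energy, 0)
  # unit charges at 1 nm
  tc <- standard_nonbonded_term(c(1, 1), c(0.3, 0.3), c(0, 0))
  expect_equal(evaluate_force_term(
    tc, rbind(c(0, 0, 0), c(1, 0, 0)))$energy, 138.935456)
  # right-angle harmonic restraint
  ta <- custom_angle_term("k*(theta-theta0)^2", matrix(1:3, 1),
                          c("k", "theta0"), matrix(c(1, 0), 1))
  expect_equal(evaluate_force_term(
    ta, rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)))$energy, (pi / 2)^2)
  # external potential
  te <- custom_external_term("x^2", 1L)
  r <- evaluate_force_term(te, matrix(c(3, 1, 1), 1))
  expect_equal(r$energy, 9)
  expect_equal(r$forces[1, ], c(-6, 0, 0))
  # compound distance: unit pull along the axis
  t5 <- custom_compound_bond_term("distance(p1,p2)", matrix(1:2, 1))
  r5 <- evaluate_force_term(t5, rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(r5$energy, 1)
  expect_equal(r5$forces[, 1], c(1, -1))
  # standard bond arithmetic
  tb <- harmonic_bond_term(data.frame(i = 1, j = 2, k = 100, r0 = 0.1))
  expect_equal(evaluate_force_term(
    tb, rbind(c(0, 0, 0), c(0.11, 0, 0)))$energy, 0.01)
  # torsion k = 1, n = 2, gamma = pi at phi = 0
  tt <- periodic_torsion_term(data.frame(i = 1, j = 2, k = 3, l = 4, kf = 1,
                                         n = 2, gamma = pi))
  expect_equal(evaluate_force_term(
    tt, rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))$energy, 0,
    tolerance = 1e-12)
  expect_error(periodic_torsion_term(
    data.frame(i = 1, j = 2, k = 3, l = 4, kf = 1, n = 0, gamma = 0)),
    ">= 1")
})

test_that("nonbonded cutoff, exclusions and periodic images behave", {
  # pair beyond the cutoff contributes nothing
  t <- custom_nonbonded_term("1/r", cutoff = 1)
  pos <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  params0 <- custom_nonbonded_term("1/r", character(0),
                                   matrix(0, 2, 0), cutoff = 1)
  expect_equal(evaluate_force_term(params0, pos)$energy, 0)
  inside <- evaluate_force_term(params0, rbind(c(0, 0, 0), c(0.5, 0, 0)))
  expect_equal(inside$energy, 2)
  # excluded pair is skipped
  tex <- custom_nonbonded_term("1/r", character(0), matrix(0, 3, 0),
                               exclusions = rbind(c(1, 2)))
  pos3 <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(0, 2, 0))
  expect_equal(evaluate_force_term(tex, pos3)$energy,
               1 / 2 + 1 / sqrt(0.25 + 4))
  # periodic: image distance used, cutoff must fit in the box
  box <- box_from_geometry("cube", 2)
  tp <- custom_nonbonded_term("r", character(0), matrix(0, 2, 0),
                              periodic = TRUE)
  expect_equal(evaluate_force_term(tp, rbind(c(0.1, 0, 0), c(1.9, 0, 0)),
                                   box)$energy, 0.2)
  tbad <- custom_nonbonded_term("r", character(0), matrix(0, 2, 0),
                                cutoff = 1.5, periodic = TRUE)
  expect_error(evaluate_force_term(tbad, pos, box), "cutoff")
  # exceptions replace the default pair interaction entirely
  tstd <- standard_nonbonded_term(c(1, 1), c(0.3, 0.3), c(0.5, 0.5),
                                  exceptions = data.frame(
                                    i = 1, j = 2, chargeprod = 0,
                                    sigma = 0.3, epsilon = 0))
  expect_equal(evaluate_force_term(tstd,
                                   rbind(c(0, 0, 0), c(0.4, 0, 0)))$energy,
               0)
  expect_error(standard_nonbonded_term(
    c(0, 0), c(0.3, 0.3), c(0, 0),
    exceptions = data.frame(i = c(1, 2), j = c(2, 1),
                            chargeprod = 0, sigma = 0.3, epsilon = 0)),
    "duplicate")
})

test_that("compound and centroid bonds reduce to their simpler forms", {
  set.seed(5)
  # compound angle equals the dedicated angle term
  a <- custom_compound_bond_term("k*(angle(p1,p2,p3)-t0)^2", matrix(1:3, 1),
                                 c("k", "t0"), matrix(c(2, 1), 1))
  b <- custom_angle_term("k*(theta-t0)^2", matrix(1:3, 1), c("k", "t0"),
                         matrix(c(2, 1), 1))
  for (t in 1:20) {
    pos <- matrix(stats::rnorm(9), 3)
    ra <- evaluate_force_term(a, pos); rb <- evaluate_force_term(b, pos)
    expect_equal(ra$energy, rb$energy, tolerance = 1e-12)
    expect_equal(ra$forces, rb$forces, tolerance = 1e-10)
  }
  # singleton centroid groups reduce to the compound term
  cc <- custom_centroid_bond_term("distance(p1,p2)^2",
                                  list(list(indices = 1, weights = 1),
                                       list(indices = 2, weights = 1)),
                                  matrix(1:2, 1))
  cp <- custom_compound_bond_term("distance(p1,p2)^2", matrix(1:2, 1))
  pos2 <- matrix(stats::rnorm(6), 2)
  expect_equal(evaluate_force_term(cc, pos2)$energy,
               evaluate_force_term(cp, pos2)$energy, tolerance = 1e-14)
  expect_equal(evaluate_force_term(cc, pos2)$forces,
               evaluate_force_term(cp, pos2)$forces, tolerance = 1e-12)
  # equal-mass two-particle groups split the centroid force evenly
  c2 <- custom_centroid_bond_term("distance(p1,p2)",
                                  list(list(indices = 1:2, weights = c(1, 1)),
                                       list(indices = 3:4,
                                            weights = c(1, 1))),
                                  matrix(1:2, 1))
  r2 <- evaluate_force_term(c2, rbind(c(0, 0, 0), c(0.2, 0, 0),
                                      c(2, 0, 0), c(2.2, 0, 0)))
  expect_equal(r2$energy, 2)
  expect_equal(r2$forces[, 1], c(0.5, 0.5, -0.5, -0.5))
  expect_error(custom_centroid_bond_term(
    "distance(p1,p2)", list(list(indices = 1:2, weights = c(0, 0)),
                            list(indices = 3, weights = 1)),
    matrix(1:2, 1)), "zero total weight")
})

test_that("OBC term matches its closed-form and asymptotic limits", {
  # single-particle Born self energy (with and without dielectric offset)
  t0 <- obc_term(1, 0.15, 1)
  expect_equal(evaluate_force_term(t0, matrix(0, 1, 3))$energy,
               -138.935456 * (1 - 1 / 78.5) / (2 * 0.141))
  tz <- obc_term(1, 0.15, 1, dielectric_offset = 0)
  expect_equal(evaluate_force_term(tz, matrix(0, 1, 3))$energy,
               -138.935456 * (1 - 1 / 78.5) / (2 * 0.15))
  # two distant charges approach independent self energies plus the
  # screened Coulomb tail
  t2 <- obc_term(c(1, -1), c(0.15, 0.12), c(1, 1))
  e <- evaluate_force_term(t2, rbind(c(0, 0, 0), c(80, 0, 0)))$energy
  expected <- -138.935456 * (1 - 1 / 78.5) *
    (1 / (2 * 0.141) + 1 / (2 * 0.111) - 1 / 80)
  expect_equal(e, expected, tolerance = 1e-6)
  expect_error(obc_term(1, -0.1, 1), "gb_radii")
})
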