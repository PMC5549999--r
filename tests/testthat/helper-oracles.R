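# Shared oracles and generators for the test suite.

# relative error of analytic forces against a central finite difference of
# the term's own energy
fd_force_error <- function(term, positions, box = NULL, h = 1e-5) {
  res <- evaluate_force_term(term, positions, box)
  num <- positions * 0
  for (i in seq_len(nrow(positions))) for (d in 1:3) {
    pp <- positions; pp[i, d] <- pp[i, d] + h
    pm <- positions; pm[i, d] <- pm[i, d] - h
    num[i, d] <- -(evaluate_force_term(term, pp, box)$energy -
                     evaluate_force_term(term, pm, box)$energy) / (2 * h)
  }
  max(abs(num - res$forces)) / max(1, max(abs(res$forces)))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]),
           2 * (q[3] * q[4] + q[1] * q[2]),
           1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
}

# random expression ASTs over the differentiable function set, for
# property tests; depth-bounded, variables drawn from `vars`
random_expression <- function(vars, depth = 3) {
  build <- function(d) {
    if (d <= 0 || stats::runif(1) < 0.3) {
      if (stats::runif(1) < 0.5)
        return(sprintf("%.4f", stats::runif(1, 0.2, 2)))
      return(sample(vars, 1))
    }
    choice <- sample(c("bin", "fun", "pow"), 1,
                     prob = c(0.5, 0.35, 0.15))
    if (choice == "bin") {
      op <- sample(c("+", "-", "*", "/"), 1)
      return(sprintf("(%s%s%s)", build(d - 1), op, build(d - 1)))
    }
    if (choice == "pow")
      return(sprintf("(%s)^%d", build(d - 1), sample(1:3, 1)))
    f <- sample(c("sin", "cos", "exp", "sqrt", "log"), 1)
    arg <- build(d - 1)
    if (f %in% c("sqrt", "log"))
      arg <- sprintf("(0.5+(%s)^2)", arg)   # keep the domain safe
    sprintf("%s(%s)", f, arg)
  }
  build(depth)
}

toy_molecule_desc <- function() {
  list(
    names = c("C1", "C2", "C3", "C4", "H1"),
    masses = c(12.011, 12.011, 12.011, 12.011, 1.008),
    charges = c(-0.1, 0.05, 0.05, -0.1, 0.1),
    sigma = c(rep(0.34, 4), 0.26),
    epsilon = c(rep(0.45, 4), 0.065),
    bonds = data.frame(i = c(1, 2, 3, 1), j = c(2, 3, 4, 5),
                       k = c(26000, 26000, 26000, 28000),
                       r0 = c(0.153, 0.153, 0.153, 0.109)),
    angles = data.frame(i = c(1, 2, 5), j = c(2, 3, 1), k = c(3, 4, 2),
                        kf = c(400, 400, 300),
                        theta0 = c(1.9111, 1.9111, 1.89)),
    dihedrals = data.frame(i = c(1, 5), j = c(2, 1), k = c(3, 2),
                           l = c(4, 3), kf = c(5.9, 0.8), n = c(3, 3),
                           gamma = c(0, 0)),
    radii = c(rep(0.17, 4), 0.12),
    screen = c(rep(0.72, 4), 0.85))
}

toy_molecule_positions <- function(seed = 4) {
  set.seed(seed)
  rbind(c(0, 0, 0), c(0.153, 0, 0), c(0.22, 0.14, 0),
        c(0.37, 0.15, 0.05), c(-0.04, -0.06, 0.08)) +
    matrix(stats::rnorm(15), 5) * 0.005
}
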