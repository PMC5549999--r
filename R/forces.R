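# Force-term infrastructure and the expression-defined ("custom") terms.
# A force term maps (positions, box) to an energy (kJ/mol) and per-particle
# force contributions (kJ/mol/nm) equal to minus the energy gradient.

new_force_term <- function(category, fn) {
  structure(list(category = category, eval = fn), class = "mm_force_term")
}

#' Evaluate one force term
#' @param term an \code{mm_force_term}.
#' @param positions N x 3 matrix (nm).
#' @param box optional \code{mm_box}.
#' @return list with elements \code{energy} and \code{forces} (N x 3).
#' @export
evaluate_force_term <- function(term, positions, box = NULL) {
  term$eval(positions, box)
}

# scatter-add M x 3 contributions into rows idx of an N x 3 force matrix
add_at <- function(forces, idx, contrib) {
  s <- rowsum(contrib, idx)
  rows <- as.integer(rownames(s))
  forces[rows, ] <- forces[rows, , drop = FALSE] + s
  forces
}

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vnorm <- function(a) sqrt(rowSums(a * a))

# ---- geometric primitives (vectorized over items) --------------------------

# distance r = |ra - rb| and the gradient dr/dra = u (unit vector)
geom_bond <- function(positions, ai, bi) {
  d <- positions[ai, , drop = FALSE] - positions[bi, , drop = FALSE]
  r <- vnorm(d)
  list(r = r, u = d / r)
}

# angle at b formed by a-b-c, with gradients dtheta/dr{a,b,c}; sin(theta)
# clamped at 1e-8 to regularize collinear geometries
geom_angle <- function(positions, ai, bi, ci) {
  u <- positions[ai, , drop = FALSE] - positions[bi, , drop = FALSE]
  v <- positions[ci, , drop = FALSE] - positions[bi, , drop = FALSE]
  nu <- vnorm(u); nv <- vnorm(v)
  uh <- u / nu; vh <- v / nv
  cosq <- pmin(1, pmax(-1, rowSums(uh * vh)))
  theta <- acos(cosq)
  sinq <- pmax(sqrt(pmax(0, 1 - cosq^2)), 1e-8)
  ga <- (cosq * uh - vh) / (nu * sinq)
  gc <- (cosq * vh - uh) / (nv * sinq)
  list(theta = theta, ga = ga, gb = -(ga + gc), gc = gc)
}

# signed dihedral (IUPAC convention, range (-pi, pi]) for atoms a-b-c-d,
# with analytic gradients for all four atoms
geom_dihedral <- function(positions, ai, bi, ci, di) {
  b1 <- positions[bi, , drop = FALSE] - positions[ai, , drop = FALSE]
  b2 <- positions[ci, , drop = FALSE] - positions[bi, , drop = FALSE]
  b3 <- positions[di, , drop = FALSE] - positions[ci, , drop = FALSE]
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  nb2 <- vnorm(b2)
  phi <- atan2(rowSums(vcross(n1, n2) * b2) / nb2, rowSums(n1 * n2))
  n1sq <- pmax(rowSums(n1 * n1), 1e-16)
  n2sq <- pmax(rowSums(n2 * n2), 1e-16)
  ga <- -(nb2 / n1sq) * n1
  gd <- (nb2 / n2sq) * n2
  p <- rowSums(b1 * b2) / nb2^2
  q <- rowSums(b3 * b2) / nb2^2
  gb <- -(1 + p) * ga + q * gd
  gc <- p * ga - (1 + q) * gd
  list(phi = phi, ga = ga, gb = gb, gc = gc, gd = gd)
}

# ---- custom-term helpers ---------------------------------------------------

# compile a ParsedExpression together with its derivative wrt `geom_var`,
# with globals substituted as constants; returns evaluators over a values
# list keyed by variable name
compile_term_expression <- function(expression, geom_vars, param_names,
                                    globals) {
  pe <- if (inherits(expression, "mm_expr")) expression
        else parse_expression(expression)
  pe <- substitute_constants(pe, globals)
  unknown <- setdiff(pe$free_variables, c(geom_vars, param_names))
  if (length(unknown) > 0L)
    stop(sprintf("expression references unknown variable(s): %s",
                 paste(unknown, collapse = ", ")))
  inputs <- c(geom_vars, param_names)
  efun <- compile_expression(pe, inputs)
  dfuns <- lapply(geom_vars, function(v) {
    if (v %in% pe$free_variables)
      compile_expression(differentiate_expression(pe, v), inputs)
    else
      function(...) 0
  })
  names(dfuns) <- geom_vars
  list(energy = efun, deriv = dfuns, inputs = inputs)
}

check_param_table <- function(params, param_names, n_items) {
  if (length(param_names) == 0L) return(matrix(0, n_items, 0))
  params <- as.matrix(params)
  if (nrow(params) != n_items || ncol(params) != length(param_names))
    stop("parameter table dimensions do not match items / parameter names")
  colnames(params) <- param_names
  params
}

term_args <- function(geom_values, params) {
  c(geom_values, lapply(seq_len(ncol(params)), function(j) params[, j]))
}

#' Custom bonded force from an energy expression in r
#'
#' The expression gives the energy of one bonded pair as a function of the
#' distance \code{r} (nm) plus per-bond and global parameters; forces follow
#' by analytic differentiation and the chain rule through \code{r}.
#'
#' @param expression energy expression string (or \code{mm_expr}) in
#'   \code{r} and parameter names.
#' @param atoms two-column integer matrix of bonded pairs (1-based).
#' @param param_names character vector of per-bond parameter names.
#' @param params matrix/data.frame of per-bond parameter values, one row per
#'   bond, columns in \code{param_names} order.
#' @param globals named list of global parameter values.
#' @param category decomposition category label (default "Other").
#' @return an \code{mm_force_term}.
#' @export
custom_bond_term <- function(expression, atoms, param_names = character(0),
                             params = NULL, globals = list(),
                             category = "Other") {
  atoms <- matrix(as.integer(as.matrix(atoms)), ncol = 2)
  params <- check_param_table(params, param_names, nrow(atoms))
  ce <- compile_term_expression(expression, "r", param_names, globals)
  new_force_term(category, function(positions, box) {
    forces <- matrix(0, nrow(positions), 3)
    if (nrow(atoms) == 0L)
      return(list(energy = 0, forces = forces))
    g <- geom_bond(positions, atoms[, 1], atoms[, 2])
    args <- term_args(list(g$r), params)
    energy <- sum(do.call(ce$energy, args))
    dEdr <- do.call(ce$deriv$r, args)
    contrib <- -dEdr * g$u
    forces <- add_at(forces, atoms[, 1], contrib)
    forces <- add_at(forces, atoms[, 2], -contrib)
    list(energy = energy, forces = forces)
  })
}

#' Custom angle force from an energy expression in theta
#'
#' @param expression energy expression in \code{theta} (radians) and
#'   parameter names.
#' @param atoms three-column integer matrix (a, vertex, c).
#' @inheritParams custom_bond_term
#' @return an \code{mm_force_term}.
#' @export
custom_angle_term <- function(expression, atoms, param_names = character(0),
                              params = NULL, globals = list(),
                              category = "Other") {
  atoms <- matrix(as.integer(as.matrix(atoms)), ncol = 3)
  params <- check_param_table(params, param_names, nrow(atoms))
  ce <- compile_term_expression(expression, "theta", param_names, globals)
  new_force_term(category, function(positions, box) {
    forces <- matrix(0, nrow(positions), 3)
    if (nrow(atoms) == 0L)
      return(list(energy = 0, forces = forces))
    g <- geom_angle(positions, atoms[, 1], atoms[, 2], atoms[, 3])
    args <- term_args(list(g$theta), params)
    energy <- sum(do.call(ce$energy, args))
    dEdt <- do.call(ce$deriv$theta, args)
    forces <- add_at(forces, atoms[, 1], -dEdt * g$ga)
    forces <- add_at(forces, atoms[, 2], -dEdt * g$gb)
    forces <- add_at(forces, atoms[, 3], -dEdt * g$gc)
    list(energy = energy, forces = forces)
  })
}

#' Custom torsion force from an energy expression in theta
#'
#' \code{theta} is the signed dihedral angle (IUPAC convention, radians).
#'
#' @param atoms four-column integer matrix (a, b, c, d).
#' @inheritParams custom_bond_term
#' @return an \code{mm_force_term}.
#' @export
custom_torsion_term <- function(expression, atoms, param_names = character(0),
                                params = NULL, globals = list(),
                                category = "Other") {
  atoms <- matrix(as.integer(as.matrix(atoms)), ncol = 4)
  params <- check_param_table(params, param_names, nrow(atoms))
  ce <- compile_term_expression(expression, "theta", param_names, globals)
  new_force_term(category, function(positions, box) {
    forces <- matrix(0, nrow(positions), 3)
    if (nrow(atoms) == 0L)
      return(list(energy = 0, forces = forces))
    g <- geom_dihedral(positions, atoms[, 1], atoms[, 2], atoms[, 3], atoms[, 4])
    args <- term_args(list(g$phi), params)
    energy <- sum(do.call(ce$energy, args))
    dEdp <- do.call(ce$deriv$theta, args)
    forces <- add_at(forces, atoms[, 1], -dEdp * g$ga)
    forces <- add_at(forces, atoms[, 2], -dEdp * g$gb)
    forces <- add_at(forces, atoms[, 3], -dEdp * g$gc)
    forces <- add_at(forces, atoms[, 4], -dEdp * g$gd)
    list(energy = energy, forces = forces)
  })
}

#' Custom external force from an energy expression in x, y, z
#'
#' Applies an independent potential to individual particles as a function of
#' their Cartesian coordinates. The only term allowed to exert a nonzero net
#' force on the system.
#'
#' @param expression energy expression in \code{x}, \code{y}, \code{z} (nm)
#'   and parameter names.
#' @param atoms integer vector of particle indices.
#' @inheritParams custom_bond_term
#' @return an \code{mm_force_term}.
#' @export
custom_external_term <- function(expression, atoms,
                                 param_names = character(0), params = NULL,
                                 globals = list(), category = "Other") {
  atoms <- as.integer(atoms)
  params <- check_param_table(params, param_names, length(atoms))
  ce <- compile_term_expression(expression, c("x", "y", "z"), param_names,
                                globals)
  new_force_term(category, function(positions, box) {
    forces <- matrix(0, nrow(positions), 3)
    if (length(atoms) == 0L)
      return(list(energy = 0, forces = forces))
    p <- positions[atoms, , drop = FALSE]
    args <- term_args(list(p[, 1], p[, 2], p[, 3]), params)
    energy <- sum(do.call(ce$energy, args))
    contrib <- -cbind(do.call(ce$deriv$x, args) + numeric(length(atoms)),
                      do.call(ce$deriv$y, args) + numeric(length(atoms)),
                      do.call(ce$deriv$z, args) + numeric(length(atoms)))
    forces <- add_at(forces, atoms, contrib)
    list(energy = energy, forces = forces)
  })
}

#' Custom pairwise nonbonded force from an energy expression in r
#'
#' Sums the expression over all non-excluded particle pairs with distance
#' below the cutoff (all pairs if \code{cutoff} is NULL). Per-particle
#' parameters are referenced with suffixes 1 and 2 (e.g. \code{sig1},
#' \code{sig2}) and are typically combined by intermediate definitions such
#' as \code{"sig=0.5*(sig1+sig2)"}. With \code{periodic = TRUE} the minimum
#' image displacement is used; the cutoff must then not exceed half the
#' smallest box height.
#'
#' @param expression pair energy expression in \code{r} and suffixed
#'   parameter names.
#' @param param_names per-particle parameter base names (without suffix).
#' @param params N x length(param_names) matrix of per-particle values.
#' @param exclusions two-column integer matrix of excluded pairs.
#' @param globals named list of global parameters.
#' @param cutoff cutoff distance in nm, or NULL for no cutoff.
#' @param periodic logical; apply minimum image convention.
#' @param category decomposition category label.
#' @return an \code{mm_force_term}.
#' @export
custom_nonbonded_term <- function(expression, param_names = character(0),
                                  params = NULL, exclusions = NULL,
                                  globals = list(), cutoff = NULL,
                                  periodic = FALSE, category = "Other") {
  n <- if (is.null(params)) NULL else nrow(as.matrix(params))
  suffixed <- c(paste0(param_names, "1"), paste0(param_names, "2"))
  ce <- compile_term_expression(expression, "r", suffixed, globals)
  if (!is.null(params)) {
    params <- as.matrix(params)
    colnames(params) <- param_names
  }
  exclusions <- if (is.null(exclusions)) matrix(integer(0), 0, 2)
                else matrix(as.integer(as.matrix(exclusions)), ncol = 2)
  new_force_term(category, function(positions, box) {
    np <- nrow(positions)
    forces <- matrix(0, np, 3)
    pr <- pair_list(np, exclusions)
    if (nrow(pr) == 0L) return(list(energy = 0, forces = forces))
    d <- positions[pr[, 1], , drop = FALSE] - positions[pr[, 2], , drop = FALSE]
    if (periodic) {
      if (is.null(box)) stop("periodic nonbonded term requires a box")
      if (!is.null(cutoff)) check_cutoff(box, cutoff)
      d <- minimum_image(box, d)
    }
    r <- vnorm(d)
    keep <- if (is.null(cutoff)) seq_along(r) else which(r < cutoff)
    if (length(keep) == 0L) return(list(energy = 0, forces = forces))
    pr <- pr[keep, , drop = FALSE]; d <- d[keep, , drop = FALSE]; r <- r[keep]
    vals <- list(r)
    if (!is.null(params))
      vals <- c(vals,
                lapply(seq_len(ncol(params)), function(j) params[pr[, 1], j]),
                lapply(seq_len(ncol(params)), function(j) params[pr[, 2], j]))
    energy <- sum(do.call(ce$energy, vals))
    dEdr <- do.call(ce$deriv$r, vals)
    contrib <- -dEdr * d / r
    forces <- add_at(forces, pr[, 1], contrib)
    forces <- add_at(forces, pr[, 2], -contrib)
    list(energy = energy, forces = forces)
  })
}

# all i<j pairs minus exclusions, as a two-column matrix
pair_list <- function(n, exclusions) {
  if (n < 2) return(matrix(integer(0), 0, 2))
  pr <- cbind(rep(seq_len(n - 1), times = (n - 1):1),
              sequence((n - 1):1, from = 2:n))
  if (nrow(exclusions) > 0L) {
    ex <- paste(pmin(exclusions[, 1], exclusions[, 2]),
                pmax(exclusions[, 1], exclusions[, 2]))
    pr <- pr[!(paste(pr[, 1], pr[, 2]) %in% ex), , drop = FALSE]
  }
  pr
}

check_cutoff <- function(box, cutoff) {
  m <- unclass(box)
  vol <- abs(m[1, 1] * m[2, 2] * m[3, 3])
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  h <- c(vol / sqrt(sum(cr(m[2, ], m[3, ])^2)),
         vol / sqrt(sum(cr(m[3, ], m[1, ])^2)),
         vol / sqrt(sum(cr(m[1, ], m[2, ])^2)))
  if (cutoff > min(h) / 2)
    stop("cutoff exceeds half the smallest box height")
  invisible(TRUE)
}

# ---- compound and centroid bonds -------------------------------------------

# Rewrite geometric calls distance(p1,p2) / angle(p1,p2,p3) /
# dihedral(p1,p2,p3,p4) into synthetic variable names before parsing, and
# return the list of primitives referenced.
extract_geom_primitives <- function(text) {
  prims <- list()
  pat <- "(distance|angle|dihedral)\\s*\\(\\s*p(\\d+)\\s*(?:,\\s*p(\\d+)\\s*)?(?:,\\s*p(\\d+)\\s*)?(?:,\\s*p(\\d+)\\s*)?\\)"
  repeat {
    m <- regexpr(pat, text, perl = TRUE)
    if (m == -1) break
    frag <- regmatches(text, m)
    parts <- regmatches(frag, regexec(pat, frag, perl = TRUE))[[1]]
    kind <- parts[2]
    slots <- as.integer(parts[-(1:2)][nzchar(parts[-(1:2)])])
    need <- switch(kind, distance = 2L, angle = 3L, dihedral = 4L)
    if (length(slots) != need)
      stop(sprintf("%s() expects %d particle slots", kind, need))
    var <- paste0("geom_", kind, "_", paste(slots, collapse = "_"))
    if (is.null(prims[[var]]))
      prims[[var]] <- list(kind = kind, slots = slots, var = var)
    regmatches(text, m) <- var
  }
  list(text = text, prims = prims)
}

compound_eval_factory <- function(expression, slot_matrix, param_names,
                                  params, globals, category,
                                  centroid_groups = NULL) {
  n_slots <- ncol(slot_matrix)
  n_items <- nrow(slot_matrix)
  params <- check_param_table(params, param_names, n_items)
  ex <- extract_geom_primitives(
    if (inherits(expression, "mm_expr")) unparse_expression(expression)
    else expression)
  coord_vars <- as.vector(outer(c("x", "y", "z"), seq_len(n_slots),
                                function(a, b) paste0(a, b)))
  geom_vars <- c(names(ex$prims), coord_vars)
  ce <- compile_term_expression(ex$text, geom_vars, param_names, globals)
  for (p in ex$prims)
    if (max(p$slots) > n_slots)
      stop(sprintf("particle slot p%d out of range", max(p$slots)))

  # returns energy and forces acting on the SLOT positions (n_items rows per
  # slot); the caller maps slot forces onto actual particles
  function(slot_positions) {
    # slot_positions: list of n_slots matrices (n_items x 3)
    vals <- stats::setNames(vector("list", length(geom_vars)), geom_vars)
    geoms <- list()
    pos <- do.call(rbind, slot_positions)   # stacked; slot s rows offset
    off <- function(s) (s - 1) * n_items + seq_len(n_items)
    for (p in ex$prims) {
      g <- switch(p$kind,
        distance = geom_bond(pos, off(p$slots[1]), off(p$slots[2])),
        angle = geom_angle(pos, off(p$slots[1]), off(p$slots[2]),
                           off(p$slots[3])),
        dihedral = geom_dihedral(pos, off(p$slots[1]), off(p$slots[2]),
                                 off(p$slots[3]), off(p$slots[4])))
      geoms[[p$var]] <- g
      vals[[p$var]] <- if (p$kind == "distance") g$r
                       else if (p$kind == "angle") g$theta else g$phi
    }
    for (v in coord_vars) {
      s <- as.integer(substring(v, 2))
      col <- match(substr(v, 1, 1), c("x", "y", "z"))
      vals[[v]] <- slot_positions[[s]][, col]
    }
    args <- c(vals, lapply(seq_len(ncol(params)), function(j) params[, j]))
    energy <- sum(do.call(ce$energy, args))
    slot_forces <- lapply(seq_len(n_slots), function(s) matrix(0, n_items, 3))
    for (p in ex$prims) {
      dE <- do.call(ce$deriv[[p$var]], args)
      g <- geoms[[p$var]]
      grads <- switch(p$kind,
        distance = list(g$u, -g$u),
        angle = list(g$ga, g$gb, g$gc),
        dihedral = list(g$ga, g$gb, g$gc, g$gd))
      for (s in seq_along(p$slots)) {
        sl <- p$slots[s]
        slot_forces[[sl]] <- slot_forces[[sl]] - dE * grads[[s]]
      }
    }
    for (v in intersect(coord_vars, ce$inputs)) {
      s <- as.integer(substring(v, 2))
      col <- match(substr(v, 1, 1), c("x", "y", "z"))
      dE <- do.call(ce$deriv[[v]], args)
      slot_forces[[s]][, col] <- slot_forces[[s]][, col] - dE
    }
    list(energy = energy, slot_forces = slot_forces)
  }
}

#' Custom compound-bond force over sets of particles
#'
#' The expression may reference \code{distance(p_i,p_j)},
#' \code{angle(p_i,p_j,p_k)}, \code{dihedral(p_i,p_j,p_k,p_l)} and the
#' coordinates \code{x_i, y_i, z_i} of the participating particles; forces
#' follow by the chain rule through each geometric primitive.
#'
#' @param expression energy expression per item.
#' @param particles integer matrix, one row per item, columns = particle
#'   slots p1, p2, ...
#' @inheritParams custom_bond_term
#' @return an \code{mm_force_term}.
#' @export
custom_compound_bond_term <- function(expression, particles,
                                      param_names = character(0),
                                      params = NULL, globals = list(),
                                      category = "Other") {
  particles <- matrix(as.integer(as.matrix(particles)), nrow = NROW(particles))
  evalf <- compound_eval_factory(expression, particles, param_names, params,
                                 globals, category)
  n_slots <- ncol(particles)
  new_force_term(category, function(positions, box) {
    forces <- matrix(0, nrow(positions), 3)
    if (nrow(particles) == 0L) return(list(energy = 0, forces = forces))
    slot_pos <- lapply(seq_len(n_slots), function(s)
      positions[particles[, s], , drop = FALSE])
    res <- evalf(slot_pos)
    for (s in seq_len(n_slots))
      forces <- add_at(forces, particles[, s], res$slot_forces[[s]])
    list(energy = res$energy, forces = forces)
  })
}

#' Custom centroid-bond force over groups of particles
#'
#' Like \code{\link{custom_compound_bond_term}}, but the geometric
#' primitives are evaluated on weighted centroids of particle groups (slots
#' g1, g2, ... in the expression are written p1, p2, ...). The force on each
#' centroid is distributed to group members in proportion to their
#' normalized weights.
#'
#' @param expression energy expression per item.
#' @param groups list of groups, each \code{list(indices, weights)};
#'   \code{weights = NULL} means mass weights must be supplied via
#'   \code{default_weights}.
#' @param items integer matrix, one row per item, entries indexing
#'   \code{groups}.
#' @param default_weights numeric vector of per-particle weights (typically
#'   masses) used when a group omits its own.
#' @inheritParams custom_bond_term
#' @return an \code{mm_force_term}.
#' @export
custom_centroid_bond_term <- function(expression, groups, items,
                                      param_names = character(0),
                                      params = NULL, globals = list(),
                                      default_weights = NULL,
                                      category = "Other") {
  items <- matrix(as.integer(as.matrix(items)), nrow = NROW(items))
  groups <- lapply(groups, function(g) {
    idx <- as.integer(g$indices)
    if (length(idx) == 0L) stop("empty centroid group")
    w <- g$weights
    if (is.null(w)) {
      if (is.null(default_weights))
        stop("group without weights requires default_weights (masses)")
      w <- default_weights[idx]
    }
    w <- as.numeric(w)
    if (sum(w) == 0) stop("zero total weight in centroid group")
    list(indices = idx, weights = w / sum(w))
  })
  evalf <- compound_eval_factory(expression, items, param_names, params,
                                 globals, category)
  n_slots <- ncol(items)
  new_force_term(category, function(positions, box) {
    forces <- matrix(0, nrow(positions), 3)
    if (nrow(items) == 0L) return(list(energy = 0, forces = forces))
    centroids <- t(vapply(groups, function(g)
      colSums(positions[g$indices, , drop = FALSE] * g$weights),
      numeric(3)))
    slot_pos <- lapply(seq_len(n_slots), function(s)
      centroids[items[, s], , drop = FALSE])
    res <- evalf(slot_pos)
    for (s in seq_len(n_slots)) {
      fc <- res$slot_forces[[s]]
      for (row in seq_len(nrow(items))) {
        g <- groups[[items[row, s]]]
        forces[g$indices, ] <- forces[g$indices, , drop = FALSE] +
          outer(g$weights, fc[row, ])
      }
    }
    list(energy = res$energy, forces = forces)
  })
}
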