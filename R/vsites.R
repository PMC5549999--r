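# Generalized three-parent virtual sites. The site position is built from
# three weighted averages of the parent positions: an origin o and two axis
# vectors dx, dy, from which an orthonormal frame (xhat, yhat, zhat) is
# constructed; the site sits at a fixed local offset (p1, p2, p3) in that
# frame. Forces applied to the massless site are pushed back onto the
# parents through the exact transpose Jacobian of the construction.

#' Define a generalized three-particle virtual site
#'
#' @param site index of the virtual-site particle (1-based; must have mass 0
#'   in the system).
#' @param parents integer vector of the three parent particle indices.
#' @param origin_weights weights for the origin o; must sum to 1 (affine).
#' @param x_weights weights for the axis vector dx; must sum to 0
#'   (translation-invariant).
#' @param y_weights weights for the axis vector dy; must sum to 0.
#' @param local_position numeric 3-vector (p1, p2, p3) in nm.
#' @return an object of class \code{mm_vsite}.
#' @export
three_particle_site <- function(site, parents, origin_weights, x_weights,
                                y_weights, local_position) {
  stopifnot(length(parents) == 3, length(origin_weights) == 3,
            length(x_weights) == 3, length(y_weights) == 3,
            length(local_position) == 3)
  if (abs(sum(origin_weights) - 1) > 1e-10)
    stop("origin weights must sum to 1")
  if (abs(sum(x_weights)) > 1e-10 || abs(sum(y_weights)) > 1e-10)
    stop("axis weights must sum to 0")
  structure(list(site = as.integer(site), parents = as.integer(parents),
                 wo = as.numeric(origin_weights), wx = as.numeric(x_weights),
                 wy = as.numeric(y_weights), p = as.numeric(local_position)),
            class = "mm_vsite")
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

cross_matrix <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

site_frame <- function(vs, r1, r2, r3) {
  o  <- vs$wo[1] * r1 + vs$wo[2] * r2 + vs$wo[3] * r3
  dx <- vs$wx[1] * r1 + vs$wx[2] * r2 + vs$wx[3] * r3
  dy <- vs$wy[1] * r1 + vs$wy[2] * r2 + vs$wy[3] * r3
  dz <- cross3(dx, dy)
  ndx <- sqrt(sum(dx * dx)); ndz <- sqrt(sum(dz * dz))
  if (ndx < 1e-10 || ndz < 1e-10)
    stop("degenerate virtual-site geometry (axis vectors parallel or zero)")
  xhat <- dx / ndx
  zhat <- dz / ndz
  yhat <- cross3(zhat, xhat)
  list(o = o, dx = dx, dy = dy, dz = dz, ndx = ndx, ndz = ndz,
       xhat = xhat, yhat = yhat, zhat = zhat)
}

#' Compute a virtual-site position from its parents
#'
#' @param vs an \code{mm_vsite}.
#' @param r1,r2,r3 parent positions (numeric 3-vectors, nm).
#' @return numeric 3-vector, the site position.
#' @export
compute_site_position <- function(vs, r1, r2, r3) {
  fr <- site_frame(vs, r1, r2, r3)
  fr$o + vs$p[1] * fr$xhat + vs$p[2] * fr$yhat + vs$p[3] * fr$zhat
}

#' Redistribute a force acting on a virtual site onto its parents
#'
#' Returns the three parent force increments \code{t(J_k) \%*\% f_site}
#' where \code{J_k} is the analytic Jacobian of the site position with
#' respect to parent k (including the derivatives of the normalizations and
#' the cross product). The increments sum exactly to \code{f_site}.
#'
#' @param vs an \code{mm_vsite}.
#' @param r1,r2,r3 parent positions.
#' @param f_site numeric 3-vector, force on the site (kJ/mol/nm).
#' @return list of three numeric 3-vectors \code{(f1, f2, f3)}.
#' @export
distribute_site_force <- function(vs, r1, r2, r3, f_site) {
  fr <- site_frame(vs, r1, r2, r3)
  p <- vs$p
  I3 <- diag(3)
  A <- (I3 - tcrossprod(fr$xhat)) / fr$ndx          # d xhat / d dx
  Pz <- (I3 - tcrossprod(fr$zhat)) / fr$ndz         # d zhat / d dz
  Zdx <- -Pz %*% cross_matrix(fr$dy)                # d zhat / d dx
  Zdy <-  Pz %*% cross_matrix(fr$dx)                # d zhat / d dy
  Cz <- cross_matrix(fr$zhat); Cx <- cross_matrix(fr$xhat)
  Ydx <- Cz %*% A - Cx %*% Zdx                      # d yhat / d dx
  Ydy <- -Cx %*% Zdy                                # d yhat / d dy
  Jdx <- p[1] * A + p[2] * Ydx + p[3] * Zdx         # d r_site / d dx
  Jdy <- p[2] * Ydy + p[3] * Zdy                    # d r_site / d dy
  fx <- as.numeric(crossprod(Jdx, f_site))
  fy <- as.numeric(crossprod(Jdy, f_site))
  lapply(1:3, function(k) vs$wo[k] * f_site + vs$wx[k] * fx + vs$wy[k] * fy)
}

#' Recompute all virtual-site positions from their parents
#'
#' Called after every operation that modifies positions and before every
#' force evaluation. Idempotent.
#'
#' @param system an \code{mm_system}.
#' @param positions N x 3 matrix.
#' @return N x 3 matrix with virtual-site rows overwritten.
#' @export
update_all_sites <- function(system, positions) {
  for (vs in system$virtual_sites) {
    positions[vs$site, ] <- compute_site_position(
      vs, positions[vs$parents[1], ], positions[vs$parents[2], ],
      positions[vs$parents[3], ])
  }
  positions
}

# Push forces accumulated on virtual sites back onto parent atoms and zero
# the site rows. Used by the force dispatcher.
redistribute_vsite_forces <- function(system, positions, forces) {
  for (vs in system$virtual_sites) {
    f <- forces[vs$site, ]
    if (all(f == 0)) { next }
    inc <- distribute_site_force(vs, positions[vs$parents[1], ],
                                 positions[vs$parents[2], ],
                                 positions[vs$parents[3], ], f)
    for (k in 1:3)
      forces[vs$parents[k], ] <- forces[vs$parents[k], ] + inc[[k]]
    forces[vs$site, ] <- 0
  }
  forces
}
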