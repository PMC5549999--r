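# OBC generalized Born implicit solvent. Effective Born radii come from the
# pairwise descreening (HCT) integral with a tanh rescaling; the OBC1
# coefficient set is alpha = 0.8, beta = 0, gamma = 2.909125. The
# solute-solvent boundary uses the customary 0.009 nm dielectric offset on
# the intrinsic radii. Energies use the canonical smoothed generalized Born
# pair function f = sqrt(r^2 + Bi Bj exp(-r^2 / (4 Bi Bj))); forces are the
# exact analytic gradient, chained through the Born radii.

OBC_ALPHA <- 0.8
OBC_BETA <- 0
OBC_GAMMA <- 2.909125
DIELECTRIC_OFFSET <- 0.009      # nm
SA_FACTOR <- 28.3919551         # kJ/mol/nm^2, ACE surface-area prefactor
SA_PROBE <- 0.14                # nm, solvent probe radius

# descreening integral H(r; or_i, sr_j) and dH/dr, elementwise on matrices.
obc_integral <- function(r, ORi, SRj) {
  U <- r + SRj
  D <- abs(r - SRj)
  L <- pmax(ORi, D)
  active <- ORi < U
  invL <- ifelse(active, 1 / L, 0)
  invU <- ifelse(active, 1 / U, 0)
  # guard inactive entries so log() never sees garbage
  ratio <- ifelse(active, log(pmax(L, 1e-300) / pmax(U, 1e-300)), 0)
  inner <- ORi < (SRj - r)
  C <- ifelse(inner, 2 * (1 / ORi - invL), 0)
  H <- 0.5 * (invL - invU + 0.25 * (r - SRj^2 / r) * (invU^2 - invL^2) +
                0.5 * ratio / r + C)
  H[!active] <- 0
  # dL/dr is 0 where the lower bound is pinned at ORi, else sign(r - SRj)
  dL <- ifelse(L > D + 0, 0, sign(r - SRj))
  dL[ORi >= D] <- 0
  dH <- 0.5 * (-dL * invL^2 + invU^2 +
                 0.25 * (1 + SRj^2 / r^2) * (invU^2 - invL^2) +
                 0.25 * (r - SRj^2 / r) * (-2 * invU^3 + 2 * dL * invL^3) -
                 0.5 * ratio / r^2 + 0.5 * (dL * invL - invU) / r +
                 ifelse(inner, 2 * dL * invL^2, 0))
  dH[!active] <- 0
  list(H = H, dH = dH)
}

# Born radii and the chain factor dB/dI for a position set
obc_born_radii <- function(positions, radii, screen, offset) {
  n <- nrow(positions)
  or_ <- radii - offset
  sr <- screen * or_
  dx <- outer(positions[, 1], positions[, 1], "-")
  dy <- outer(positions[, 2], positions[, 2], "-")
  dz <- outer(positions[, 3], positions[, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  diag(r) <- 1                      # dummy; self entries masked below
  ORi <- matrix(or_, n, n)
  SRj <- matrix(sr, n, n, byrow = TRUE)
  gi <- obc_integral(r, ORi, SRj)
  diag(gi$H) <- 0
  diag(gi$dH) <- 0
  I <- rowSums(gi$H)
  psi <- I * or_
  phi <- OBC_ALPHA * psi - OBC_BETA * psi^2 + OBC_GAMMA * psi^3
  B <- 1 / (1 / or_ - tanh(phi) / radii)
  sech2 <- 1 / cosh(phi)^2
  dBdpsi <- B^2 * sech2 * (OBC_ALPHA - 2 * OBC_BETA * psi +
                             3 * OBC_GAMMA * psi^2) / radii
  list(B = B, dBdI = dBdpsi * or_, r = r, dH = gi$dH,
       dx = dx, dy = dy, dz = dz)
}

#' OBC1 generalized Born implicit-solvent term
#'
#' @param charge numeric vector of charges (e).
#' @param gb_radii intrinsic GB radii (nm, > 0), e.g. the mbondi set from a
#'   topology file.
#' @param screening dimensionless HCT screening factors, per particle.
#' @param solute_dielectric interior dielectric, default 1.
#' @param solvent_dielectric exterior dielectric, default 78.5.
#' @param sa_term logical; add the ACE nonpolar surface-area energy
#'   (default FALSE).
#' @param dielectric_offset offset subtracted from the intrinsic radii in
#'   the descreening integrals (nm, default 0.009).
#' @param category decomposition label, default "OBC".
#' @return an \code{mm_force_term}.
#' @export
obc_term <- function(charge, gb_radii, screening, solute_dielectric = 1,
                     solvent_dielectric = 78.5, sa_term = FALSE,
                     dielectric_offset = DIELECTRIC_OFFSET,
                     category = "OBC") {
  stopifnot(all(gb_radii > 0))
  charge <- as.numeric(charge)
  prefac <- -COULOMB_CONSTANT * (1 / solute_dielectric -
                                   1 / solvent_dielectric)
  n <- length(charge)
  new_force_term(category, function(positions, box) {
    br <- obc_born_radii(positions, gb_radii, screening, dielectric_offset)
    B <- br$B
    r <- br$r
    qq <- outer(charge, charge)
    BB <- outer(B, B)
    Dexp <- exp(-r^2 / (4 * BB))
    f2 <- r^2 + BB * Dexp
    diag(f2) <- B^2                       # f(i,i) = B_i
    f <- sqrt(f2)
    # energy: 0.5 * prefac * sum_{i,j} qi qj / f_ij (diagonal = self terms)
    energy <- 0.5 * prefac * sum(qq / f)
    # dEdf(i,j) = derivative of the UNORDERED pair energy prefac qi qj / f;
    # the i=j self term carries an extra 1/2, handled below
    dEdf <- -prefac * qq / f2
    # dE/dB_i: each off-diagonal f_ij involves B_i once via dfdBi(i,j) and
    # once via the symmetric element's dfdBj, which equals dfdBi(i,j) again
    dfdBi <- Dexp * (matrix(B, n, n, byrow = TRUE) + r^2 / (4 * B)) / (2 * f)
    diag(dfdBi) <- 1                      # f(i,i) = B_i
    dEdB <- rowSums(dEdf * dfdBi) - 0.5 * dEdf[cbind(1:n, 1:n)]
    if (sa_term) {
      sa_e <- SA_FACTOR * (gb_radii + SA_PROBE)^2 * (gb_radii / B)^6
      energy <- energy + sum(sa_e)
      dEdB <- dEdB - 6 * sa_e / B
    }
    # unordered-pair distance derivative: direct part at fixed B, plus the
    # chain through both Born radii (B_i via H_ij and B_j via H_ji)
    dfdr <- r * (1 - Dexp / 4) / f
    diag(dfdr) <- 0
    chain <- (dEdB * br$dBdI) * br$dH
    S <- dEdf * dfdr + chain + t(chain)
    W <- S / r
    diag(W) <- 0
    fx <- -(rowSums(W * br$dx))
    fy <- -(rowSums(W * br$dy))
    fz <- -(rowSums(W * br$dz))
    list(energy = energy, forces = cbind(fx, fy, fz))
  })
}
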