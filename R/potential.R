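#' Toy force-field parameters
#'
#' Bonds and angles in the CHARMM convention (\eqn{k(b-b_0)^2},
#' \eqn{k_\theta(\theta-\theta_0)^2}); nonbonded terms are Lennard-Jones
#' (CHARMM rmin form, Lorentz-Berthelot-like combination
#' \eqn{\epsilon_{ij}=\sqrt{\epsilon_i\epsilon_j}},
#' \eqn{r_{min,ij} = r_{min/2,i}+r_{min/2,j}}) plus Coulomb with a constant
#' dielectric.  Both nonbonded terms are brought smoothly to zero by the
#' CHARMM switching polynomial between `switch_on` and `switch_off`
#' (defaults 10 and 12 Angstrom).  Atom pairs connected by a bond (1-2) or
#' an angle (1-3) are excluded from the nonbonded sum.
#'
#' @param structure [md_structure()] supplying per-atom charge, eps,
#'   rmin_half and masses.
#' @param bonds data.frame with columns `i, j, k, r0`.
#' @param angles data.frame with columns `i, j, k, k_theta, theta0`
#'   (`j` is the apex atom); may be empty.
#' @param dielectric Relative dielectric constant (> 0), default 1.
#' @param switch_on,switch_off Switching window, Angstrom.
#' @param restraint Optional list `(k, ref, selection)`: harmonic positional
#'   restraint `k |x - ref|^2` on the selected atoms (default all).
#' @return Object of class `ff_params`.
#' @export
force_field_params <- function(structure, bonds,
                               angles = NULL,
                               dielectric = 1,
                               switch_on = 10, switch_off = 12,
                               restraint = NULL) {
  stopifnot(inherits(structure, "md_structure"))
  if (switch_on >= switch_off) stop("switch_on must be < switch_off")
  if (dielectric <= 0) stop("dielectric must be > 0")
  n <- n_atoms(structure)
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("i", "j", "k", "r0") %in% names(bonds)))
  if (is.null(angles))
    angles <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                         k_theta = numeric(0), theta0 = numeric(0))
  angles <- as.data.frame(angles)

  ## nonbonded pair list: all i<j minus 1-2 and 1-3 exclusions
  excl <- unique(rbind(
    t(apply(cbind(bonds$i, bonds$j), 1, sort)),
    if (nrow(angles)) t(apply(cbind(angles$i, angles$k), 1, sort))
  ))
  all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pi_ <- all_pairs[, 1]; pj_ <- all_pairs[, 2]
  if (!is.null(excl) && nrow(excl)) {
    key <- pi_ * (n + 1L) + pj_
    ekey <- excl[, 1] * (n + 1L) + excl[, 2]
    keep <- !(key %in% ekey)
    pi_ <- pi_[keep]; pj_ <- pj_[keep]
  }

  out <- list(
    bonds = bonds, angles = angles,
    charge = structure$atoms$charge, eps = structure$atoms$eps,
    rmin_half = structure$atoms$rmin_half, mass = structure$atoms$mass,
    dielectric = dielectric, switch_on = switch_on, switch_off = switch_off,
    coulomb_constant = COULOMB_CONSTANT,
    nb_i = pi_, nb_j = pj_, n_atoms = n,
    restraint = restraint
  )
  class(out) <- "ff_params"
  out
}

## CHARMM switching function and its radial derivative, vectorized.
switch_fn <- function(r, ron, roff) {
  r2 <- r^2; ron2 <- ron^2; roff2 <- roff^2
  denom <- (roff2 - ron2)^3
  A <- roff2 - r2
  B <- roff2 + 2 * r2 - 3 * ron2
  S <- ifelse(r <= ron, 1, ifelse(r >= roff, 0, A^2 * B / denom))
  dS <- ifelse(r <= ron | r >= roff, 0, 4 * r * A * (A - B) / denom)
  list(S = S, dS = dS)
}

#' Potential energy, per-term breakdown, and forces
#'
#' Forces are the exact negative gradient of the implemented energy,
#' including the switching-function derivative.
#'
#' @param params A [force_field_params()].
#' @param xyz N x 3 coordinate matrix, Angstrom.
#' @return List: `total` (kcal/mol), `terms` (named numeric: bond, angle,
#'   lj, elec, restraint), `forces` (N x 3, kcal/mol/A).
#' @export
potential_energy <- function(params, xyz) {
  stopifnot(inherits(params, "ff_params"))
  xyz <- as.matrix(xyz)
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  n <- params$n_atoms
  stopifnot(nrow(xyz) == n)
  F <- matrix(0, n, 3)
  terms <- c(bond = 0, angle = 0, lj = 0, elec = 0, restraint = 0)

  b <- params$bonds
  if (nrow(b)) {
    rv <- xyz[b$j, , drop = FALSE] - xyz[b$i, , drop = FALSE]
    r <- sqrt(rowSums(rv^2))
    terms["bond"] <- sum(b$k * (r - b$r0)^2)
    dEdr <- 2 * b$k * (r - b$r0)
    fj <- -rv * (dEdr / r)                 # force on j
    F <- accumulate_rows(F, b$j, fj)
    F <- accumulate_rows(F, b$i, -fj)
  }

  a <- params$angles
  if (nrow(a)) {
    u <- xyz[a$i, , drop = FALSE] - xyz[a$j, , drop = FALSE]
    v <- xyz[a$k, , drop = FALSE] - xyz[a$j, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    cth <- clamp(rowSums(u * v) / (nu * nv), -1 + 1e-12, 1 - 1e-12)
    th <- acos(cth)
    sth <- sqrt(1 - cth^2)
    terms["angle"] <- sum(a$k_theta * (th - a$theta0)^2)
    dEdth <- 2 * a$k_theta * (th - a$theta0)
    ## dth/du = (cth*u/nu^2 - v/(nu*nv)) / sth ; symmetric for v
    dth_du <- (u * (cth / nu^2) - v / (nu * nv)) / sth
    dth_dv <- (v * (cth / nv^2) - u / (nu * nv)) / sth
    Fi <- -dth_du * dEdth
    Fk <- -dth_dv * dEdth
    F <- accumulate_rows(F, a$i, Fi)
    F <- accumulate_rows(F, a$k, Fk)
    F <- accumulate_rows(F, a$j, -(Fi + Fk))
  }

  i <- params$nb_i; j <- params$nb_j
  if (length(i)) {
    rv <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
    r2 <- rowSums(rv^2)
    roff2 <- params$switch_off^2
    act <- which(r2 < roff2)
    if (length(act)) {
      ia <- i[act]; ja <- j[act]
      r <- sqrt(r2[act])
      if (any(r < 1e-6)) stop("singularity error: overlapping nonbonded atoms")
      epsij <- sqrt(params$eps[ia] * params$eps[ja])
      rmin <- params$rmin_half[ia] + params$rmin_half[ja]
      sr6 <- (rmin / r)^6
      e_lj <- epsij * (sr6^2 - 2 * sr6)
      de_lj <- (12 * epsij / r) * (sr6 - sr6^2)
      qq <- params$coulomb_constant * params$charge[ia] * params$charge[ja] /
        params$dielectric
      e_el <- qq / r
      de_el <- -qq / r^2
      sw <- switch_fn(r, params$switch_on, params$switch_off)
      terms["lj"] <- sum(e_lj * sw$S)
      terms["elec"] <- sum(e_el * sw$S)
      dEdr <- (de_lj + de_el) * sw$S + (e_lj + e_el) * sw$dS
      fj <- -rv[act, , drop = FALSE] * (dEdr / r)
      F <- accumulate_rows(F, ja, fj)
      F <- accumulate_rows(F, ia, -fj)
    }
  }

  rs <- params$restraint
  if (!is.null(rs)) {
    sel <- rs$selection %||% seq_len(n)
    d <- xyz[sel, , drop = FALSE] - rs$ref[sel, , drop = FALSE]
    terms["restraint"] <- rs$k * sum(d^2)
    F[sel, ] <- F[sel, ] - 2 * rs$k * d
  }

  list(total = sum(terms), terms = terms, forces = F)
}

#' Kinetic energy of a velocity set
#' @param velocities N x 3 matrix, Angstrom/ps.
#' @param masses Per-atom masses, amu.
#' @return Kinetic energy, kcal/mol.
#' @export
kinetic_energy <- function(velocities, masses) {
  0.5 * sum(masses * rowSums(as.matrix(velocities)^2)) / KCALMOL_TO_AKMA
}

#' Instantaneous kinetic temperature
#' @inheritParams kinetic_energy
#' @return Temperature, K (3N degrees of freedom).
#' @export
kinetic_temperature <- function(velocities, masses) {
  ndof <- 3 * length(masses)
  2 * kinetic_energy(velocities, masses) / (ndof * KB_KCALMOL)
}
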