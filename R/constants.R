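#' Physical constants and unit conventions
#'
#' All energies are in kcal/mol, lengths in Angstrom (\eqn{\AA}), masses in
#' amu, times in ps.  Velocities are therefore \eqn{\AA}/ps and kinetic
#' energy converts to kcal/mol through a single constant:
#' 1 kcal/mol = 418.4 amu \eqn{\AA^2}/ps\eqn{^2}.
#'
#' Harmonic terms follow the CHARMM convention without the 1/2 factor:
#' a bond contributes \eqn{k (b - b_0)^2}, an angle \eqn{k_\theta
#' (\theta - \theta_0)^2}, and a positional restraint \eqn{k |x - x_0|^2}.
#' The force-constant values quoted throughout (e.g. the 10, 1, 0.1
#' kcal/mol/\eqn{\AA^2} restraint ladder) are in this convention, so the
#' curvature (second derivative) of a bond at equilibrium is \eqn{2k}.
#'
#' @format Named numeric scalars.
#' @name amdenm-units
NULL

#' @describeIn amdenm-units Boltzmann constant, kcal/mol/K.
#' @export
KB_KCALMOL <- 0.0019872041

#' @describeIn amdenm-units 1 kcal/mol expressed in amu.A^2/ps^2.
#' @export
KCALMOL_TO_AKMA <- 418.4

#' @describeIn amdenm-units Coulomb prefactor, kcal.A/(mol.e^2).
#' @export
COULOMB_CONSTANT <- 332.0636
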