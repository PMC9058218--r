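#' Marcus activation energy
#'
#' Quadratic Marcus expression for the activation free energy of an
#' electron-transfer step: deltaG_act = (lambda/4) * (1 + deltaG/lambda)^2.
#' The barrier vanishes at deltaG = -lambda (the activationless point) and
#' grows again for more exergonic reactions — the inverted region.
#'
#' @param delta_G_ET Free energy of the electron-transfer step, kJ mol^-1.
#' @param lambda Reorganization energy, kJ mol^-1 (> 0).
#' @return Activation free energy in kJ mol^-1 (non-negative).
#' @examples
#' marcus_activation(-40, 40)  # 0: activationless
#' marcus_activation(0, 40)    # lambda/4 = 10
#' marcus_activation(-80, 40)  # 10 again: inverted-region symmetry
#' @export
marcus_activation <- function(delta_G_ET, lambda) {
  if (any(lambda <= 0)) stop("reorganization energy must be positive")
  (lambda / 4) * (1 + delta_G_ET / lambda)^2
}

#' Marcus reorganization energy from a vertical electron-transfer energy
#'
#' lambda = deltaE_vertical - deltaG_ET: the energy needed to distort the
#' reactant and solvent configuration to the product geometry without
#' transferring the electron.
#'
#' @param vertical_energy Vertical electron-transfer energy, kJ mol^-1.
#' @param delta_G_ET Adiabatic free energy of the step, kJ mol^-1.
#' @return Reorganization energy in kJ mol^-1.
#' @export
reorganization_energy <- function(vertical_energy, delta_G_ET) {
  lambda <- vertical_energy - delta_G_ET
  if (any(lambda <= 0)) stop("vertical energy below adiabatic")
  lambda
}

#' Stokes-Einstein diffusivity
#'
#' D = k_B T / (6 pi eta a) for a sphere of radius `a` in a solvent of
#' viscosity eta.
#'
#' @param radius Hydrodynamic radius in m (> 0).
#' @param solvent A [solvent()].
#' @param temperature Temperature in K (defaults to the solvent's).
#' @return Diffusivity in m^2 s^-1.
#' @examples
#' stokes_einstein_diffusivity(2e-10, solvent("water"))  # ~1.23e-9
#' @export
stokes_einstein_diffusivity <- function(radius, solvent,
                                        temperature = solvent$temperature) {
  stopifnot(radius > 0)
  .codata$k_B * temperature / (6 * pi * solvent$viscosity * radius)
}

#' Smoluchowski diffusion-limited rate constant
#'
#' Encounter rate of two spheres: k_D = 4 pi (a_A + a_B)(D_A + D_B) N_A,
#' converted to M^-1 s^-1, with Stokes-Einstein diffusivities.
#'
#' @param radius_A,radius_B Encounter radii in m (> 0).
#' @param solvent A [solvent()].
#' @param temperature Temperature in K (defaults to the solvent's).
#' @return Rate constant in M^-1 s^-1.
#' @examples
#' smoluchowski_rate(2e-10, 2e-10, solvent("water"))  # ~7.4e9
#' @export
smoluchowski_rate <- function(radius_A, radius_B, solvent,
                              temperature = solvent$temperature) {
  stopifnot(radius_A > 0, radius_B > 0)
  DA <- stokes_einstein_diffusivity(radius_A, solvent, temperature)
  DB <- stokes_einstein_diffusivity(radius_B, solvent, temperature)
  k_m3 <- 4 * pi * (radius_A + radius_B) * (DA + DB) * .codata$N_A
  k_m3 * 1000  # m^3 mol^-1 s^-1 -> L mol^-1 s^-1
}

#' Diffusion-limited rate constant of a solvent
#'
#' The rate constant assigned to barrierless (diffusion-controlled)
#' pathways: the solvent's fixed value when one is set (1.91e9 M^-1 s^-1
#' for the water preset), otherwise the Smoluchowski rate for two spheres
#' of radius `radius`.
#'
#' @param solvent A [solvent()].
#' @param radius Default encounter radius in m used in the Smoluchowski
#'   fallback.
#' @param temperature Temperature in K (defaults to the solvent's).
#' @return Rate constant in M^-1 s^-1.
#' @export
diffusion_rate <- function(solvent, radius = 2e-10,
                           temperature = solvent$temperature) {
  if (!is.null(solvent$diffusion_k)) return(solvent$diffusion_k)
  smoluchowski_rate(radius, radius, solvent, temperature)
}

.diffusion_clip <- function(k_act, k_D, clip) {
  switch(clip,
         "collins-kimball" = k_D * k_act / (k_D + k_act),
         "min" = pmin(k_act, k_D))
}

#' Marcus electron-transfer rate constant with diffusion correction
#'
#' Thermal activation rate k_act = (k_B T / h) exp(-deltaG_act / RT) with
#' the Marcus activation energy, combined with the diffusion-limited
#' encounter rate k_D. The default Collins-Kimball combination
#' k_app = k_D k_act / (k_D + k_act) guarantees k_app <= min(k_act, k_D);
#' the cruder `min(k_act, k_D)` clipping is available for sensitivity
#' checks.
#'
#' As deltaG_ET decreases at fixed lambda, k_app rises to the diffusion
#' plateau and then falls once deltaG_ET < -lambda: the Marcus inverted
#' region.
#'
#' @param delta_G_ET Free energy of the electron-transfer step, kJ mol^-1.
#' @param lambda Reorganization energy, kJ mol^-1 (> 0).
#' @param k_D Diffusion-limited rate constant, M^-1 s^-1 (> 0).
#' @param temperature Temperature in K.
#' @param clip `"collins-kimball"` (default) or `"min"`.
#' @return Apparent rate constant in M^-1 s^-1, with the Marcus activation
#'   energy (`delta_G_act`, kJ mol^-1) and activation-controlled rate
#'   (`k_act`) attached as attributes.
#' @examples
#' et_rate(-30, lambda = 80, k_D = 1.91e9)
#' @export
et_rate <- function(delta_G_ET, lambda, k_D, temperature = 298.15,
                    clip = c("collins-kimball", "min")) {
  clip <- match.arg(clip)
  stopifnot(lambda > 0, k_D > 0, temperature > 0)
  act <- marcus_activation(delta_G_ET, lambda)
  k_act <- .prefactor(temperature) *
    exp(-act * 1000 / (.codata$R * temperature))
  k_app <- .diffusion_clip(k_act, k_D, clip)
  structure(k_app, delta_G_act = act, k_act = k_act)
}
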