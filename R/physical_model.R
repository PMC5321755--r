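#' Physical constants of the host fluid
#'
#' Bundles the constant properties of the aqueous host fluid and the ambient
#' conditions. The dynamic viscosity `eta = rho0 * nu` is derived, never
#' supplied.
#'
#' @param rho0 Fluid density (kg m^-3). Default: water, 1000.
#' @param nu Kinematic viscosity (m^2 s^-1). Default: water, 1e-6.
#' @param g Gravitational acceleration (m s^-2).
#' @param T_amb Ambient absolute temperature (K) used for Brownian noise.
#' @param kB Boltzmann constant (J K^-1).
#'
#' @return An object of class `cc_constants`.
#' @export
#' @examples
#' consts <- physical_constants()
#' consts$eta  # 1e-3 Pa s
physical_constants <- function(rho0 = 1000, nu = 1e-6, g = 9.8,
                               T_amb = 298, kB = 1.380649e-23) {
  vals <- c(rho0 = rho0, nu = nu, g = g, T_amb = T_amb, kB = kB)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all physical constants must be finite and strictly positive")
  structure(list(rho0 = rho0, nu = nu, eta = rho0 * nu, g = g,
                 T_amb = T_amb, kB = kB),
            class = "cc_constants")
}

#' Reagent and reaction-kinetics parameters
#'
#' Describes the dissolved reagent (diffusivity, solutal expansion, supply)
#' and the Michaelis-Menten kinetics of its catalytic decomposition. When
#' `rmax` is not given it is derived as `M_sites * kcat * E_areal`.
#'
#' @param D Reagent diffusivity in water (m^2 s^-1).
#' @param beta_C Solutal expansion coefficient (M^-1): relative density excess
#'   per molar of dissolved reagent.
#' @param C0 Initial reagent concentration in the gel reservoir (M).
#' @param lam Inlet decay rate (s^-1); `1/lam` is the fuel-depletion time.
#' @param KM Michaelis constant (M): concentration at half-maximal rate.
#' @param M_sites Number of active sites per catalyst molecule.
#' @param kcat Turnover rate per active site (s^-1).
#' @param E_areal Areal catalyst concentration (mol m^-2).
#' @param rmax Maximal areal reaction rate (mol m^-2 s^-1); derived from the
#'   kinetic parameters when `NULL`.
#'
#' @return An object of class `cc_reagent`.
#' @export
reagent_model <- function(D = 1e-9, beta_C = 1e-2, C0 = 0.1, lam = 1 / 4200,
                          KM = 0.093, M_sites = 4, kcat = 2.12e5,
                          E_areal = 2e-8, rmax = NULL) {
  vals <- c(D = D, beta_C = beta_C, C0 = C0, lam = lam, M_sites = M_sites,
            kcat = kcat, E_areal = E_areal)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("reagent parameters must be finite and nonnegative")
  if (!is.finite(KM) || KM <= 0) stop("KM must be strictly positive")
  if (is.null(rmax)) rmax <- compute_rmax(M_sites, kcat, E_areal)
  if (!is.finite(rmax) || rmax < 0) stop("rmax must be finite and nonnegative")
  structure(list(D = D, beta_C = beta_C, C0 = C0, lam = lam, KM = KM,
                 M_sites = M_sites, kcat = kcat, E_areal = E_areal,
                 rmax = rmax),
            class = "cc_reagent")
}

#' Tracer-particle parameters
#'
#' Describes the suspended spherical tracers and derives their transport
#' coefficients: Stokes mobility `mu = 1/(6 pi eta R)`, Einstein diffusivity
#' `D_t = mu kB T`, and the Stokes sedimentation speed.
#'
#' @param R Tracer radius (m).
#' @param rho_t Tracer density (kg m^-3); must not be below the fluid density.
#' @param eps Wall Morse-potential strength (J).
#' @param omega Wall Morse-potential inverse width (m^-1).
#' @param consts A [physical_constants()] object used for the derived
#'   coefficients.
#'
#' @return An object of class `cc_tracer` with derived fields `mu`, `D_t`
#'   and `V_sed`.
#' @export
tracer_model <- function(R = 2e-6, rho_t = 1050, eps = 1.2e-14, omega = 6e4,
                         consts = physical_constants()) {
  vals <- c(R = R, rho_t = rho_t, eps = eps, omega = omega)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("tracer parameters must be finite and strictly positive")
  tr <- structure(list(R = R, rho_t = rho_t, eps = eps, omega = omega),
                  class = "cc_tracer")
  tr$mu <- 1 / (6 * pi * consts$eta * R)
  tr$D_t <- tracer_diffusivity(tr, consts)
  tr$V_sed <- sedimentation_speed(tr, consts)
  tr
}

#' Density of the reagent solution
#'
#' Linear single-solute density law `rho = rho0 (1 + beta_C C)`: the reagent
#' is the only solute whose weight matters; the reaction products and the
#' reaction heat contribute an order of magnitude less and are omitted by
#' construction.
#'
#' @param C Reagent concentration (M), scalar or array; must be nonnegative.
#' @param consts A [physical_constants()] object.
#' @param reagent A [reagent_model()] object.
#' @return Density (kg m^-3), same shape as `C`.
#' @export
solution_density <- function(C, consts, reagent) {
  if (any(C < 0)) stop("concentration must be nonnegative")
  consts$rho0 * (1 + reagent$beta_C * C)
}

#' Michaelis-Menten areal reaction rate
#'
#' `r(C) = rmax C / (KM + C)`: saturating decomposition rate per unit area of
#' catalytic surface, evaluated at the surface concentration.
#'
#' @param C_surface Reagent concentration at the surface (M), nonnegative.
#' @param reagent A [reagent_model()] object.
#' @return Areal rate (mol m^-2 s^-1), in `[0, rmax)`.
#' @export
reaction_rate <- function(C_surface, reagent) {
  if (any(C_surface < 0)) stop("concentration must be nonnegative")
  reagent$rmax * C_surface / (reagent$KM + C_surface)
}

#' Maximal areal reaction rate from catalyst kinetics
#'
#' `rmax = M_sites * kcat * E_areal`: active sites per molecule times turnover
#' per site times areal catalyst concentration.
#'
#' @param M_sites Active sites per catalyst molecule.
#' @param kcat Turnover per site (s^-1).
#' @param E_areal Areal catalyst concentration (mol m^-2).
#' @return Maximal rate (mol m^-2 s^-1).
#' @export
compute_rmax <- function(M_sites, kcat, E_areal) {
  if (any(c(M_sites, kcat, E_areal) < 0)) stop("inputs must be nonnegative")
  M_sites * kcat * E_areal
}

#' Stokes sedimentation speed of a tracer
#'
#' Terminal settling speed from the balance of buoyant weight and Stokes
#' drag: `V = 2 (rho_t - rho0) g R^2 / (9 eta)`.
#'
#' @param tracer A [tracer_model()] object (or any list with `R`, `rho_t`).
#' @param consts A [physical_constants()] object.
#' @return Speed (m s^-1), nonnegative.
#' @export
sedimentation_speed <- function(tracer, consts) {
  if (tracer$rho_t < consts$rho0)
    stop("tracer density below fluid density: buoyant tracers are not ",
         "supported (sedimentation speed would be negative)")
  2 * (tracer$rho_t - consts$rho0) * consts$g * tracer$R^2 / (9 * consts$eta)
}

#' Stokes-Einstein diffusivity of a tracer
#'
#' `D_t = kB T / (6 pi eta R) = mu kB T`.
#'
#' @inheritParams sedimentation_speed
#' @return Diffusivity (m^2 s^-1).
#' @export
tracer_diffusivity <- function(tracer, consts) {
  stopifnot(tracer$R > 0, consts$T_amb > 0)
  consts$kB * consts$T_amb / (6 * pi * consts$eta * tracer$R)
}
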