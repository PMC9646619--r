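#' Universal gas constant (J mol^-1 K^-1)
#' @keywords internal
#' @noRd
.R_GAS <- 8.314

# Kelvin offset used throughout; 25 degC maps to 298 K so that the
# Arrhenius exponent vanishes exactly at 25 degC.
.K0 <- 273

#' Rubisco kinetic constants
#'
#' Michaelis constants for CO2 and O2, the CO2 compensation point in the
#' absence of day respiration, their activation energies, and the oxygen
#' partial pressure. Defaults are the widely used tobacco in-vivo values of
#' Bernacchi et al. (2001), the de-facto standard of A-Ci fitting tools.
#' Gas mole fractions (umol mol^-1) and partial pressures (ubar) are treated
#' as numerically equal at a total pressure of 1 bar; `pressure` rescales
#' everything if measurements were taken elsewhere.
#'
#' @param Kc25 Michaelis constant for CO2 at 25 degC (ubar).
#' @param Ko25 Michaelis constant for O2 at 25 degC (mbar).
#' @param GammaStar25 CO2 compensation point without day respiration at
#'   25 degC (ubar).
#' @param O Oxygen partial pressure (mbar).
#' @param EaKc,EaKo,EaGammaStar Activation energies (kJ mol^-1).
#' @param pressure Total air pressure (bar).
#' @return A list of class `kinetic_constants`.
#' @examples
#' bernacchi_kinetics()
#' @export
bernacchi_kinetics <- function(Kc25 = 404.9, Ko25 = 278.4, GammaStar25 = 42.75,
                               O = 210, EaKc = 79.43, EaKo = 36.38,
                               EaGammaStar = 37.83, pressure = 1) {
  stopifnot(Kc25 > 0, Ko25 > 0, GammaStar25 > 0, O > 0, pressure > 0)
  if (GammaStar25 >= Kc25) {
    stop("GammaStar25 must be smaller than Kc25", call. = FALSE)
  }
  structure(
    list(Kc25 = Kc25, Ko25 = Ko25, GammaStar25 = GammaStar25, O = O,
         EaKc = EaKc, EaKo = EaKo, EaGammaStar = EaGammaStar,
         pressure = pressure),
    class = "kinetic_constants"
  )
}

#' Carbon isotope discrimination constants
#'
#' Fractionation factors (permil) used by the ternary-corrected mesophyll
#' conductance estimator: diffusion through air `a` = 4.4, boundary layer
#' `ab` = 2.9, combined boundary-layer + stomata `a_prime` (defaults to `a`,
#' the large-boundary-layer-conductance limit), dissolution plus liquid-phase
#' diffusion `ai` = 1.8, net carboxylation `b` = 27.3, photorespiration
#' `f` = 11.6 and day respiration `e` = 0 (null respiratory fractionation).
#'
#' @param a,ab,a_prime,ai,b,f,e Fractionations in permil.
#' @return A list of class `discrimination_constants`.
#' @examples
#' discrimination_constants()
#' @export
discrimination_constants <- function(a = 4.4, ab = 2.9, a_prime = a,
                                     ai = 1.8, b = 27.3, f = 11.6, e = 0) {
  stopifnot(b > a, a > 0, f > 0)
  structure(
    list(a = a, ab = ab, a_prime = a_prime, ai = ai, b = b, f = f, e = e),
    class = "discrimination_constants"
  )
}

#' FvCB model parameters for one leaf
#'
#' Bundles the two capacity parameters (`Vcmax25`, `Jmax25`), day respiration,
#' mesophyll conductance, light-response shape constants and the temperature
#' response of each component. At 25 degC every rate equals its `*25` value.
#'
#' @param Vcmax25 Maximal Rubisco carboxylation rate at 25 degC
#'   (umol m^-2 s^-1).
#' @param Jmax25 Maximal electron transport rate at 25 degC (umol m^-2 s^-1).
#' @param Rd25 Day (dark) respiration at 25 degC (umol m^-2 s^-1).
#' @param gm25 Mesophyll conductance at 25 degC (mol m^-2 s^-1 bar^-1);
#'   `Inf` collapses the chloroplast CO2 to the intercellular value.
#' @param theta Curvature of the non-rectangular hyperbola light response
#'   (0 < theta <= 1).
#' @param alpha Apparent quantum yield (mol e- mol photon^-1, 0 < alpha < 0.5).
#' @param EaV Activation energy of Vcmax (kJ mol^-1), standard Arrhenius.
#' @param EaJ,deltaSJ,HdJ Peaked-Arrhenius constants for Jmax: activation
#'   energy (kJ mol^-1), entropy term (J mol^-1 K^-1) and deactivation energy
#'   (kJ mol^-1, conventionally fixed at 200).
#' @param Q10 Temperature coefficient for respiration (rate multiplier per
#'   10 degC).
#' @param kinetics A [bernacchi_kinetics()] object.
#' @return A list of class `fvcb_params`.
#' @examples
#' fvcb_params() # Scout-like wheat defaults
#' @export
fvcb_params <- function(Vcmax25 = 192.7, Jmax25 = 187.9, Rd25 = 1.25,
                        gm25 = 0.31, theta = 0.85, alpha = 0.24,
                        EaV = 43.3, EaJ = 37.7, deltaSJ = 648.3, HdJ = 200,
                        Q10 = 1.51, kinetics = bernacchi_kinetics()) {
  stopifnot(Vcmax25 > 0, Jmax25 > 0, Rd25 > 0, gm25 > 0,
            theta > 0, theta <= 1, alpha > 0, alpha < 0.5, Q10 > 0)
  if (EaJ >= HdJ) stop("EaJ must be below HdJ for a peaked response",
                       call. = FALSE)
  structure(
    list(Vcmax25 = Vcmax25, Jmax25 = Jmax25, Rd25 = Rd25, gm25 = gm25,
         theta = theta, alpha = alpha, EaV = EaV, EaJ = EaJ,
         deltaSJ = deltaSJ, HdJ = HdJ, Q10 = Q10, kinetics = kinetics),
    class = "fvcb_params"
  )
}

#' @export
print.fvcb_params <- function(x, ...) {
  cat("<fvcb_params>\n")
  cat(sprintf("  Vcmax25 %.1f  Jmax25 %.1f  Rd25 %.2f  gm25 %s  (umol m-2 s-1; mol m-2 s-1 bar-1)\n",
              x$Vcmax25, x$Jmax25, x$Rd25, format(x$gm25)))
  cat(sprintf("  EaV %.1f  EaJ %.1f  dSJ %.1f  Hd %.0f  Q10 %.2f\n",
              x$EaV, x$EaJ, x$deltaSJ, x$HdJ, x$Q10))
  invisible(x)
}

#' Reference temperature-response parameter sets for two wheat cultivars
#'
#' Fitted leaf-level parameter sets for the early-maturing cultivar Scout and
#' the free-tillering cultivar Yitpi grown at ambient CO2: light-saturated
#' photosynthesis optimum (parabola), mesophyll conductance optimum
#' (quadratic vertex), Vcmax and Rd Arrhenius constants, Jmax peaked-Arrhenius
#' constants, and the respiration Q10.
#'
#' @return A tibble with one row per cultivar.
#' @examples
#' wheat_cultivars()
#' @export
wheat_cultivars <- function() {
  tibble::tibble(
    cultivar    = c("Scout", "Yitpi"),
    Asat_Topt   = c(23.4, 23.4),    # degC
    Aopt        = c(24.6, 22.0),    # umol m-2 s-1
    gm_Topt     = c(27.9, 32.5),    # degC
    gm25        = c(0.31, 0.25),    # mol m-2 s-1 bar-1
    Vcmax25     = c(192.7, 198.4),  # umol m-2 s-1
    EaV         = c(43.3, 46.4),    # kJ mol-1
    Jmax25      = c(187.9, 186.1),  # umol m-2 s-1
    EaJ         = c(37.7, 41.1),    # kJ mol-1
    deltaSJ     = c(648.3, 647.0),  # J mol-1 K-1
    HdJ         = c(200, 200),      # kJ mol-1
    Rd25        = c(1.25, 1.25),    # umol m-2 s-1
    EaR         = c(30.9, 33.2),    # kJ mol-1
    Q10         = c(1.51, 1.56)
  )
}

#' FvCB parameter object for a named wheat cultivar
#'
#' @param cultivar `"Scout"` or `"Yitpi"`.
#' @param ... Overrides passed on to [fvcb_params()].
#' @return A `fvcb_params` object with that cultivar's reference values.
#' @examples
#' cultivar_params("Yitpi")
#' @export
cultivar_params <- function(cultivar = c("Scout", "Yitpi"), ...) {
  cultivar <- match.arg(cultivar)
  row <- dplyr::filter(wheat_cultivars(), .data$cultivar == !!cultivar)
  args <- utils::modifyList(
    list(Vcmax25 = row$Vcmax25, Jmax25 = row$Jmax25, Rd25 = row$Rd25,
         gm25 = row$gm25, EaV = row$EaV, EaJ = row$EaJ,
         deltaSJ = row$deltaSJ, HdJ = row$HdJ, Q10 = row$Q10),
    list(...)
  )
  do.call(fvcb_params, args)
}
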