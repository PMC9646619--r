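#' Arrhenius temperature scaling of a biochemical rate
#'
#' Scales a rate known at 25 degC to another leaf temperature with the
#' standard Arrhenius function
#' \deqn{k(T_k) = k_{25}\exp\!\left[\frac{E_a (T_k - 298)}{R \cdot 298 \cdot T_k}\right]}
#' where \eqn{T_k = T_{leaf} + 273}. The function is continuous and, for
#' positive activation energy, strictly increasing in temperature; at
#' 25 degC it returns exactly `k25`.
#'
#' @param k25 Rate at 25 degC (any positive unit).
#' @param Ea Activation energy (kJ mol^-1).
#' @param Tleaf Leaf temperature (degC); vectorised.
#' @return The rate at `Tleaf`, same unit as `k25`.
#' @examples
#' arrhenius_scale(192.7, 43.3, c(15, 25, 35))
#' @export
arrhenius_scale <- function(k25, Ea, Tleaf) {
  if (any(k25 <= 0)) stop("k25 must be strictly positive", call. = FALSE)
  Tk <- Tleaf + .K0
  k25 * exp(Ea * 1000 * (Tk - 298) / (.R_GAS * 298 * Tk))
}

#' Peaked (modified) Arrhenius temperature scaling
#'
#' Arrhenius rise multiplied by a deactivation term so the rate peaks at an
#' interior optimum:
#' \deqn{k(T_k) = k_{25} \exp\!\left[\frac{E_a(T_k-298)}{R\,298\,T_k}\right]
#'  \frac{1+\exp\!\left(\frac{298\Delta S - H_d}{298 R}\right)}
#'       {1+\exp\!\left(\frac{T_k\Delta S - H_d}{T_k R}\right)}}
#' The deactivation bracket is exactly 1 at 298 K, so the function returns
#' `k25` at 25 degC and `k25` keeps its meaning as the 25 degC rate.
#'
#' @inheritParams arrhenius_scale
#' @param Hd Deactivation energy (kJ mol^-1); must exceed `Ea`.
#' @param deltaS Entropy term (J mol^-1 K^-1).
#' @return The rate at `Tleaf`.
#' @seealso [topt_peaked()] for the closed-form optimum.
#' @examples
#' peaked_arrhenius_scale(187.9, 37.7, 200, 648.3, c(25, 30, 35))
#' @export
peaked_arrhenius_scale <- function(k25, Ea, Hd, deltaS, Tleaf) {
  if (any(k25 <= 0)) stop("k25 must be strictly positive", call. = FALSE)
  if (Ea <= 0 || Ea >= Hd) {
    stop("need 0 < Ea < Hd for a peaked response (Topt undefined otherwise)",
         call. = FALSE)
  }
  if (deltaS <= 0) stop("deltaS must be positive", call. = FALSE)
  Tk <- Tleaf + .K0
  rise <- exp(Ea * 1000 * (Tk - 298) / (.R_GAS * 298 * Tk))
  peak <- (1 + exp((298 * deltaS - Hd * 1000) / (298 * .R_GAS))) /
          (1 + exp((Tk * deltaS - Hd * 1000) / (Tk * .R_GAS)))
  k25 * rise * peak
}

#' Closed-form temperature optimum of a peaked Arrhenius response
#'
#' \deqn{T_{opt} = \frac{H_d}{\Delta S - R\ln\!\left[E_a/(H_d-E_a)\right]}}
#' in Kelvin, returned in degC. Agrees with the numerical argmax of
#' [peaked_arrhenius_scale()].
#'
#' @param Ea Activation energy (kJ mol^-1).
#' @param Hd Deactivation energy (kJ mol^-1).
#' @param deltaS Entropy term (J mol^-1 K^-1).
#' @return Optimum leaf temperature (degC).
#' @examples
#' topt_peaked(Ea = 37.7, Hd = 200, deltaS = 648.3)
#' @export
topt_peaked <- function(Ea, Hd, deltaS) {
  if (any(Ea <= 0) || any(Ea >= Hd)) {
    stop("need 0 < Ea < Hd", call. = FALSE)
  }
  denom <- deltaS - .R_GAS * log(Ea / (Hd - Ea))
  if (any(denom <= 0)) stop("deltaS - R log(Ea/(Hd-Ea)) must be positive",
                            call. = FALSE)
  Hd * 1000 / denom - .K0
}

#' Q10 temperature scaling of respiration
#'
#' \deqn{R_d(T) = R_{d25} \, Q_{10}^{(T-25)/10}}
#'
#' @param Rd25 Respiration at 25 degC (umol m^-2 s^-1).
#' @param Q10 Rate multiplier per 10 degC.
#' @param Tleaf Leaf temperature (degC); vectorised.
#' @return Respiration at `Tleaf`.
#' @examples
#' q10_respiration(1.25, 1.51, c(15, 25, 35))
#' @export
q10_respiration <- function(Rd25, Q10, Tleaf) {
  stopifnot(Rd25 > 0, Q10 > 0)
  Rd25 * Q10^((Tleaf - 25) / 10)
}

#' Electron transport rate from the non-rectangular hyperbola light response
#'
#' J is the smaller root of
#' \eqn{\theta J^2 - (\alpha Q + J_{max})J + \alpha Q J_{max} = 0},
#' so that J <= Jmax and J approaches Jmax under saturating light.
#'
#' @param PPFD Photosynthetic photon flux density (umol m^-2 s^-1);
#'   vectorised.
#' @param Jmax Maximal electron transport rate at the leaf temperature
#'   (umol m^-2 s^-1).
#' @param theta Curvature (0 < theta <= 1).
#' @param alpha Apparent quantum yield (mol e- mol photon^-1).
#' @return Electron transport rate J (umol e- m^-2 s^-1).
#' @examples
#' electron_transport(1500, 187.9)
#' @export
electron_transport <- function(PPFD, Jmax, theta = 0.85, alpha = 0.24) {
  stopifnot(all(PPFD >= 0), Jmax > 0, theta > 0, theta <= 1,
            alpha > 0, alpha < 0.5)
  aQ <- alpha * PPFD
  disc <- (aQ + Jmax)^2 - 4 * theta * aQ * Jmax
  if (any(disc < 0)) stop("negative discriminant in light response",
                          call. = FALSE)
  (aQ + Jmax - sqrt(disc)) / (2 * theta)
}

#' Parabolic temperature response of light-saturated photosynthesis
#'
#' \deqn{A_{sat}(T) = A_{opt} - b (T - T_{opt})^2}
#'
#' @param Aopt Assimilation at the optimum (umol m^-2 s^-1).
#' @param Topt Optimum leaf temperature (degC).
#' @param b_curv Curvature (umol m^-2 s^-1 degC^-2), positive.
#' @param Tleaf Leaf temperature (degC); vectorised.
#' @return Predicted Asat.
#' @examples
#' parabola_asat(24.6, 23.4, 0.05, c(15, 25, 35))
#' @export
parabola_asat <- function(Aopt, Topt, b_curv, Tleaf) {
  stopifnot(b_curv > 0)
  Aopt - b_curv * (Tleaf - Topt)^2
}

# Kinetic constants scaled from 25 degC to Tleaf (internal).
.kinetics_at <- function(kin, Tleaf) {
  list(
    Kc        = arrhenius_scale(kin$Kc25, kin$EaKc, Tleaf),
    Ko        = arrhenius_scale(kin$Ko25, kin$EaKo, Tleaf),
    GammaStar = arrhenius_scale(kin$GammaStar25, kin$EaGammaStar, Tleaf),
    O         = kin$O
  )
}

# Single-limitation assimilation with finite mesophyll conductance.
# Solves A = V (Cc - GammaStar)/(Cc + K) - Rd with Cc = Ci - A/gm,
# i.e. the lower root of
#   A^2 + A (Rd - V - gm (Ci + K)) + gm (V (Ci - GammaStar) - Rd (Ci + K)) = 0.
# V and K are Vcmax and Kc(1 + O/Ko) for Rubisco limitation, or J/4 and
# 2 GammaStar for RuBP-regeneration limitation. All vectorised over Ci.
.assim_limited <- function(Ci, V, K, GammaStar, Rd, gm) {
  if (is.infinite(gm)) {
    return(V * (Ci - GammaStar) / (Ci + K) - Rd)
  }
  B <- Rd - V - gm * (Ci + K)
  C <- gm * (V * (Ci - GammaStar) - Rd * (Ci + K))
  disc <- B^2 - 4 * C
  if (any(disc < 0)) {
    stop("no physical root for assimilation (check Ci, gm, Rd)",
         call. = FALSE)
  }
  (-B - sqrt(disc)) / 2
}

#' Net assimilation from the FvCB model with finite mesophyll conductance
#'
#' Forward Farquhar-von Caemmerer-Berry prediction of net CO2 assimilation.
#' Each capacity is first scaled to the leaf temperature (Vcmax and the
#' Rubisco kinetics by Arrhenius, Jmax by the peaked Arrhenius, Rd by Q10),
#' then the Rubisco-limited and RuBP-regeneration-limited rates are each
#' solved jointly with the mesophyll diffusion equation
#' \eqn{C_c = C_i - A/g_m} (quadratic, physical root), and the minimum is
#' taken. Ties are reported as Rubisco-limited; no TPU limitation and no
#' smoothing between limitations.
#'
#' @param env A data frame with columns `Ci` (umol mol^-1), `Tleaf` (degC)
#'   and `PPFD` (umol m^-2 s^-1). Missing `Tleaf`/`PPFD` columns default to
#'   25 degC and 1500.
#' @param params A [fvcb_params()] object.
#' @return The input tibble with columns `A` (net assimilation,
#'   umol m^-2 s^-1), `Ac`, `Aj` (net rates under each limitation), `Cc`
#'   (chloroplastic CO2, umol mol^-1), `Rd` and `limitation`
#'   (`"Rubisco"`/`"RuBP"`).
#' @examples
#' net_assimilation(data.frame(Ci = c(100, 300, 900)), fvcb_params())
#' @export
net_assimilation <- function(env, params) {
  stopifnot(inherits(params, "fvcb_params"))
  env <- tibble::as_tibble(env)
  if (!"Ci" %in% names(env)) stop("env must contain a Ci column",
                                  call. = FALSE)
  if (!"Tleaf" %in% names(env)) env$Tleaf <- 25
  if (!"PPFD" %in% names(env)) env$PPFD <- 1500
  if (any(env$Ci < 0) || any(env$PPFD < 0)) {
    stop("Ci and PPFD must be non-negative", call. = FALSE)
  }
  if (any(env$Tleaf < -10 | env$Tleaf > 55)) {
    stop("Tleaf outside the supported -10..55 degC range", call. = FALSE)
  }

  kinT  <- .kinetics_at(params$kinetics, env$Tleaf)
  Vcmax <- arrhenius_scale(params$Vcmax25, params$EaV, env$Tleaf)
  Jmax  <- peaked_arrhenius_scale(params$Jmax25, params$EaJ,
                                  params$HdJ, params$deltaSJ, env$Tleaf)
  Rd    <- q10_respiration(params$Rd25, params$Q10, env$Tleaf)
  J     <- electron_transport(env$PPFD, Jmax, params$theta, params$alpha)
  Km    <- kinT$Kc * (1 + kinT$O / kinT$Ko)
  Ac <- .assim_limited(env$Ci, Vcmax, Km, kinT$GammaStar, Rd, params$gm25)
  Aj <- .assim_limited(env$Ci, J / 4, 2 * kinT$GammaStar, kinT$GammaStar,
                       Rd, params$gm25)
  A  <- pmin(Ac, Aj)
  dplyr::mutate(
    env,
    A = A, Ac = Ac, Aj = Aj,
    Cc = if (is.infinite(params$gm25)) .data$Ci else .data$Ci - A / params$gm25,
    Rd = Rd,
    limitation = ifelse(Ac <= Aj, "Rubisco", "RuBP")
  )
}
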