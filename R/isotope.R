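#' Observed carbon isotope discrimination from chamber gas measurements
#'
#' Computes the observed photosynthetic 13C discrimination from the CO2
#' concentration and delta-13C of dry air entering (reference) and exiting
#' (sample) the leaf chamber:
#' \deqn{\epsilon = \frac{C_{ref}}{C_{ref} - C_{sam}},\qquad
#' \Delta_o = \frac{1000\,\epsilon\,(\delta_{sam} - \delta_{ref})}
#'   {1000 + \delta_{sam} - \epsilon(\delta_{sam} - \delta_{ref})}}
#'
#' @param obs A data frame with columns `Cref`, `Csam` (umol mol^-1) and
#'   `delta_ref`, `delta_sam` (permil).
#' @param min_drawdown Relative CO2 drawdown `(Cref-Csam)/Cref` below which
#'   a low-drawdown warning is raised (`epsilon` blows up as the drawdown
#'   vanishes).
#' @return The input tibble with columns `epsilon` and `Delta_o` (permil).
#' @examples
#' observed_discrimination(
#'   data.frame(Cref = 400, Csam = 380, delta_ref = -8, delta_sam = -7))
#' @export
observed_discrimination <- function(obs, min_drawdown = 1e-3) {
  obs <- tibble::as_tibble(obs)
  req <- c("Cref", "Csam", "delta_ref", "delta_sam")
  miss <- setdiff(req, names(obs))
  if (length(miss)) stop("missing isotope columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(obs$Cref <= 0 | obs$Csam <= 0)) {
    stop("CO2 concentrations must be positive", call. = FALSE)
  }
  if (any(obs$Cref == obs$Csam)) {
    stop("Cref equals Csam: no CO2 drawdown, epsilon undefined",
         call. = FALSE)
  }
  drawdown <- (obs$Cref - obs$Csam) / obs$Cref
  if (any(abs(drawdown) < min_drawdown)) {
    warning("very low CO2 drawdown in some observations; ",
            "discrimination is numerically unstable", call. = FALSE)
  }
  eps <- obs$Cref / (obs$Cref - obs$Csam)
  dd  <- obs$delta_sam - obs$delta_ref
  dplyr::mutate(obs,
    epsilon = eps,
    Delta_o = 1000 * eps * dd / (1000 + obs$delta_sam - eps * dd)
  )
}

# delta_sam that yields a target Delta_o for given Cref/Csam/delta_ref.
# Exact algebraic inverse of observed_discrimination; used by the
# synthetic-experiment generator.
.delta_sam_for <- function(Delta_o, Cref, Csam, delta_ref) {
  eps <- Cref / (Cref - Csam)
  d <- (Delta_o * (1000 + delta_ref)) / (1000 * eps + Delta_o * eps - Delta_o)
  delta_ref + d
}

#' Ternary correction factor
#'
#' \deqn{t = \frac{(1 + a')E}{2 g^t_{ac}}} with the combined boundary-layer
#' plus stomata fractionation `a_prime` converted from permil to fractional
#' form. `t` is dimensionless and must lie in `[0, 1)` for a physical leaf.
#'
#' @param E Transpiration rate (mol m^-2 s^-1).
#' @param gt_ac Total conductance to CO2 through boundary layer and stomata
#'   (mol m^-2 s^-1).
#' @param a_prime Combined fractionation (permil), default 4.4 (large
#'   boundary-layer conductance limit).
#' @return The ternary factor `t`.
#' @examples
#' ternary_t(E = 0.003, gt_ac = 0.4)
#' @export
ternary_t <- function(E, gt_ac, a_prime = 4.4) {
  if (any(gt_ac <= 0)) stop("gt_ac must be positive", call. = FALSE)
  t <- (1 + a_prime / 1000) * E / (2 * gt_ac)
  if (any(t >= 1)) stop("ternary factor t >= 1: unphysical leaf state",
                        call. = FALSE)
  t
}

#' Combined boundary-layer + stomata fractionation
#'
#' Conductance-weighted combination of the boundary-layer (`ab` = 2.9 permil)
#' and stomatal (`a` = 4.4 permil) diffusion fractionations using the
#' leaf-surface CO2 `Cs`:
#' \deqn{a' = \frac{a_b (C_a - C_s) + a (C_s - C_i)}{C_a - C_i}}
#' With `Cs = Ca` (boundary-layer conductance not measured / very large)
#' this reduces to `a`.
#'
#' @param Ca,Cs,Ci Ambient, leaf-surface and intercellular CO2
#'   (umol mol^-1).
#' @param consts A [discrimination_constants()] object.
#' @return `a_prime` in permil.
#' @export
combined_a_prime <- function(Ca, Cs, Ci, consts = discrimination_constants()) {
  if (any(Ca <= Ci)) stop("need Ca > Ci", call. = FALSE)
  (consts$ab * (Ca - Cs) + consts$a * (Cs - Ci)) / (Ca - Ci)
}

# Shared component algebra for Eq. components (internal).
# state: list/tibble-row with A, Rd, Ca, Ci, GammaStar.
.components <- function(state, consts, t) {
  w <- (1 + t) / (1 - t)
  Delta_i <- (1 / (1 - t)) *
    (consts$a_prime + ((1 + t) * consts$b - consts$a_prime) * state$Ci / state$Ca)
  Delta_e <- w * (consts$e * state$Rd / ((state$A + state$Rd) * state$Ca)) *
    (state$Ci - state$GammaStar)
  Delta_f <- w * consts$f * state$GammaStar / state$Ca
  list(Delta_i = Delta_i, Delta_e = Delta_e, Delta_f = Delta_f)
}

#' Predicted discrimination components
#'
#' Computes the ternary-corrected discrimination components: `Delta_i`, the
#' discrimination that would occur at infinite mesophyll conductance,
#' `Delta_e` (day respiration) and `Delta_f` (photorespiration), all in
#' permil:
#' \deqn{\Delta_i = \frac{1}{1-t}\left[a' + \big((1+t)b - a'\big)\frac{C_i}{C_a}\right]}
#' \deqn{\Delta_e = \frac{1+t}{1-t}\,\frac{e R_d}{(A+R_d) C_a}(C_i - \Gamma^*),\qquad
#'  \Delta_f = \frac{1+t}{1-t}\, f\,\frac{\Gamma^*}{C_a}}
#'
#' @param state A data frame with columns `A`, `Rd` (umol m^-2 s^-1),
#'   `Ca`, `Ci`, `GammaStar` (umol mol^-1).
#' @param consts A [discrimination_constants()] object.
#' @param t Ternary correction factor(s) from [ternary_t()].
#' @return The input tibble with columns `t`, `Delta_i`, `Delta_e`,
#'   `Delta_f`.
#' @export
predicted_components <- function(state, consts = discrimination_constants(),
                                 t) {
  state <- tibble::as_tibble(state)
  if (any(t < 0 | t >= 1)) stop("t must lie in [0, 1)", call. = FALSE)
  if (any(state$GammaStar <= 0)) stop("GammaStar must be positive",
                                      call. = FALSE)
  cmp <- .components(state, consts, t)
  dplyr::mutate(state, t = t, Delta_i = cmp$Delta_i,
                Delta_e = cmp$Delta_e, Delta_f = cmp$Delta_f)
}

#' Mesophyll conductance from observed discrimination
#'
#' Ternary-corrected estimator of mesophyll conductance from the gap between
#' the infinite-gm prediction and the observed discrimination:
#' \deqn{g_m = \frac{\frac{1+t}{1-t}\left(b - a_i - \frac{e R_d}{A+R_d}\right)
#'   \frac{A}{C_a}}{\Delta_i - \Delta_o - \Delta_e - \Delta_f}}
#'
#' @param state A data frame with columns `A`, `Rd`, `E`, `Ca`, `Ci`,
#'   `GammaStar`, `gt_ac` (see [ternary_t()] for units).
#' @param consts A [discrimination_constants()] object.
#' @param Delta_o Observed discrimination (permil), one per row of `state`.
#' @return The input tibble with the component columns and `gm`
#'   (mol m^-2 s^-1 bar^-1).
#' @examples
#' st <- data.frame(A = 20, Rd = 1.25, E = 0.003, Ca = 400, Ci = 280,
#'                  GammaStar = 42.75, gt_ac = 0.4)
#' d  <- predict_delta_obs(st, gm = 0.31)
#' gm_from_discrimination(st, Delta_o = d$Delta_o)$gm
#' @export
gm_from_discrimination <- function(state, consts = discrimination_constants(),
                                   Delta_o) {
  state <- tibble::as_tibble(state)
  t <- ternary_t(state$E, state$gt_ac, consts$a_prime)
  cmp <- .components(state, consts, t)
  gap <- cmp$Delta_i - Delta_o - cmp$Delta_e - cmp$Delta_f
  if (any(gap <= 0)) {
    bad <- which(gap <= 0)[1]
    stop(sprintf(paste0(
      "observed discrimination is not below the infinite-gm prediction ",
      "(row %d: Delta_i=%.3f, Delta_o=%.3f, Delta_e=%.3f, Delta_f=%.3f); ",
      "gm estimation impossible"),
      bad, cmp$Delta_i[bad], Delta_o[bad], cmp$Delta_e[bad], cmp$Delta_f[bad]),
      call. = FALSE)
  }
  w <- (1 + t) / (1 - t)
  num <- w * (consts$b - consts$ai -
                consts$e * state$Rd / (state$A + state$Rd)) *
    state$A / state$Ca
  dplyr::mutate(state, t = t, Delta_o = Delta_o,
                Delta_i = cmp$Delta_i, Delta_e = cmp$Delta_e,
                Delta_f = cmp$Delta_f, gm = num / gap)
}

#' Forward prediction of observed discrimination at known gm
#'
#' Exact algebraic rearrangement of the gm estimator: predicts the
#' discrimination an instrument would observe for a leaf with mesophyll
#' conductance `gm`. Composing with [gm_from_discrimination()] is the
#' identity.
#'
#' @inheritParams gm_from_discrimination
#' @param gm Mesophyll conductance (mol m^-2 s^-1 bar^-1), positive.
#' @return The input tibble with component columns and `Delta_o` (permil).
#' @export
predict_delta_obs <- function(state, consts = discrimination_constants(), gm) {
  if (any(gm <= 0)) stop("gm must be positive", call. = FALSE)
  state <- tibble::as_tibble(state)
  t <- ternary_t(state$E, state$gt_ac, consts$a_prime)
  cmp <- .components(state, consts, t)
  w <- (1 + t) / (1 - t)
  drawdown <- w * (consts$b - consts$ai -
                     consts$e * state$Rd / (state$A + state$Rd)) *
    state$A / (gm * state$Ca)
  dplyr::mutate(state, t = t, Delta_i = cmp$Delta_i,
                Delta_e = cmp$Delta_e, Delta_f = cmp$Delta_f,
                Delta_o = cmp$Delta_i - cmp$Delta_e - cmp$Delta_f - drawdown)
}

#' Estimate mesophyll conductance from a concurrent isotope log
#'
#' Data-frame pipeline wrapper: takes one row per observation with the raw
#' isotope measurements and the concurrent gas exchange, computes the
#' observed discrimination, the ternary factor and all components, and
#' returns the per-observation gm estimate.
#'
#' @param data A data frame with columns `Cref`, `Csam`, `delta_ref`,
#'   `delta_sam`, `A`, `Rd`, `E`, `Ca`, `Ci`, `GammaStar`, `gt_ac`.
#' @param consts A [discrimination_constants()] object.
#' @return A tibble with the inputs plus `epsilon`, `Delta_o`, `t`,
#'   `Delta_i`, `Delta_e`, `Delta_f` and `gm`.
#' @export
estimate_gm <- function(data, consts = discrimination_constants()) {
  data <- observed_discrimination(data)
  gm_from_discrimination(data, consts, Delta_o = data$Delta_o)
}
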