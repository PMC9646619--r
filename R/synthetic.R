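# Stable per-stage RNG sub-seed: master seed plus an integer hash of the
# stage label, kept below 2^31 so it is always a valid R seed. Adding a new
# stage never shifts the draws of an existing one.
.stage_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# Multiplicative lognormal noise with unit mean: exp(sigma Z - sigma^2/2)
# where sigma^2 = log(1 + cv^2), so the configured multipliers are the
# exact population means of the generated values.
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sigma) - sigma^2 / 2)
}

#' Calibration multipliers and baselines for the synthetic experiment
#'
#' One object holds every treatment effect the generator encodes, each as a
#' multiplicative factor, plus the absolute trait baselines. Effects whose
#' magnitude is known from glasshouse measurements of these cultivars carry
#' that magnitude; effects reported only as (non-)significance are left at
#' multiplier 1 and tagged `unquantified`. Absolute baselines (grams per
#' plant, tiller counts, ...) are plausible wheat-pot-experiment values, not
#' measured ones, and downstream checks treat them as generator properties
#' only.
#'
#' @return A list of class `wheat_calibration` with elements
#'   `gas_exchange`, `aci`, `traits`, `baselines`, `yitpi_ratio` and
#'   `notes`.
#' @export
default_calibration <- function() {
  structure(list(
    gas_exchange = list(
      # eCO2-grown vs aCO2-grown, measured at each plant's growth CO2
      a_growth_stimulation = 1.21,
      # eCO2-grown vs aCO2-grown, both measured at the common 400 umol mol-1
      a_common_downregulation = 0.88,
      gs_common_downregulation = 0.90,
      # parabola curvature used to move A between 25 and 35 degC
      asat_curvature = 0.05
    ),
    aci = list(
      # downregulation of carboxylation capacity under eCO2 growth
      vcmax_eco2 = c(Scout = 0.86, Yitpi = 0.85),
      jmax_eco2  = c(Scout = 1.00, Yitpi = 1.00)   # unquantified: no effect
    ),
    isotope = list(
      gm_curvature = 5e-4   # mol m-2 s-1 bar-1 degC-2, free choice
    ),
    traits = list(
      # eCO2/aCO2 multipliers in control (non-heat-stressed) cells
      eco2 = list(
        total_dry_mass = list(T3 = c(Scout = 1.09, Yitpi = 1.29),
                              T4 = c(Scout = 1.00, Yitpi = 1.00)), # unquantified
        grain_number   = list(T4 = c(Scout = 1.64, Yitpi = 1.50)),
        grain_n_pct    = list(T4 = c(Scout = 1.00, Yitpi = 0.82))
      ),
      # heat-stressed cells gain nothing from eCO2: the interaction divides
      # the eCO2 multiplier back out of biomass and yield traits
      hs_removes_eco2_gain = c("total_dry_mass", "grain_number")
    ),
    yitpi_ratio = list(
      # Yitpi relative to Scout; T3/T4 entries are measured contrasts,
      # other time points are smooth plausible interpolations
      total_dry_mass = c(T0 = 1, T1 = 1.10, T2 = 1.25, T3 = 1.42, T4 = 1.84),
      tillers        = c(T0 = 1, T1 = 1.50, T2 = 1.80, T3 = 2.30, T4 = 1.88),
      leaf_area      = c(T0 = 1, T1 = 1.50, T2 = 2.00, T3 = 3.54, T4 = 2.00),
      leaf_number    = c(T0 = 1, T1 = 1.50, T2 = 1.80, T3 = 2.28, T4 = 2.00),
      height         = c(T0 = 1, T1 = 0.90, T2 = 0.575, T3 = 1.00, T4 = 1.00),
      grain_number   = c(T4 = 1.54),
      grain_size     = c(T4 = 1 / 1.31),
      grain_n_pct    = c(T4 = 1.26),
      fvfm           = c(T0 = 1, T1 = 1, T2 = 1, T3 = 1, T4 = 1)
    ),
    baselines = list(
      # Scout absolute values per time point (synthetic, not measured)
      total_dry_mass = c(T0 = 0.05, T1 = 1.2, T2 = 8, T3 = 20, T4 = 26), # g
      tillers        = c(T0 = 1, T1 = 2, T2 = 5, T3 = 6, T4 = 7),
      leaf_area      = c(T0 = 10, T1 = 60, T2 = 250, T3 = 350, T4 = 150), # cm2
      leaf_number    = c(T0 = 3, T1 = 10, T2 = 30, T3 = 40, T4 = 35),
      height         = c(T0 = 10, T1 = 30, T2 = 60, T3 = 75, T4 = 75),   # cm
      grain_number   = c(T4 = 260),
      grain_size     = c(T4 = 42),     # mg per grain
      grain_n_pct    = c(T4 = 2.0),    # % dry mass
      fvfm           = c(T0 = 0.82, T1 = 0.82, T2 = 0.82, T3 = 0.82,
                         T4 = 0.80)
    ),
    notes = c(
      "a_growth_stimulation: eCO2 stimulation of A at growth CO2, control cells",
      "a_common_downregulation: A of eCO2-grown plants at common 400, T2-style contrast",
      "vcmax_eco2: carboxylation downregulation under eCO2 growth, per cultivar",
      "jmax_eco2 = 1: electron transport unaffected by growth CO2 (unquantified)",
      "eco2 total_dry_mass T4 = 1: enhancement reported without magnitude (unquantified)",
      "hs multipliers on trait baselines = 1: moderate well-watered HS left growth unchanged",
      "baselines: plausible magnitudes only; never compared against measured plants"
    )
  ), class = "wheat_calibration")
}

#' Configuration of the synthetic factorial glasshouse experiment
#'
#' Defines the full design (2 cultivars x 2 growth CO2 x 4 heat-stress
#' regimes x 5 time points x `n_per_cell` plants), the measurement noise,
#' and the calibration multipliers. The seed is mandatory: every generator
#' stage draws from a sub-stream derived from it.
#'
#' @param seed Master RNG seed (integer).
#' @param n_per_cell Plants per treatment cell per time point.
#' @param co2_levels Growth CO2 levels (umol mol^-1).
#' @param hs_regimes Heat-stress regimes; `HS1` is the vegetative-stage and
#'   `HS2` the flowering-stage 3-day cycle.
#' @param timepoints Harvest/measurement time points.
#' @param noise_cv_gas Coefficient of variation of gas-exchange noise.
#' @param noise_cv_traits Coefficient of variation of trait noise.
#' @param calibration A [default_calibration()] object.
#' @return A list of class `experiment_config`.
#' @examples
#' experiment_config(seed = 1)
#' @export
experiment_config <- function(seed, n_per_cell = 10,
                              co2_levels = c(450, 650),
                              hs_regimes = c("Control", "HS1", "HS2", "HS1+2"),
                              timepoints = paste0("T", 0:4),
                              noise_cv_gas = 0.05,
                              noise_cv_traits = 0.10,
                              calibration = default_calibration()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_per_cell >= 2, noise_cv_gas >= 0, noise_cv_traits >= 0)
  structure(
    list(seed = as.integer(seed), n_per_cell = n_per_cell,
         co2_levels = co2_levels, hs_regimes = hs_regimes,
         timepoints = timepoints, noise_cv_gas = noise_cv_gas,
         noise_cv_traits = noise_cv_traits, calibration = calibration),
    class = "experiment_config"
  )
}

#' Generate the experimental design table
#'
#' Full factorial crossing of cultivar, growth CO2, heat-stress regime and
#' time point with `n_per_cell` plants per cell, minus the cells that were
#' never harvested: plants exposed only to the vegetative heat stress (HS1)
#' are absent at final harvest (T4).
#'
#' @param config An [experiment_config()] object.
#' @return A tibble with columns `plant_id`, `cultivar`, `co2`,
#'   `hs_regime`, `timepoint`.
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  design <- tidyr::expand_grid(
    cultivar = c("Scout", "Yitpi"),
    co2 = config$co2_levels,
    hs_regime = config$hs_regimes,
    timepoint = config$timepoints,
    replicate = seq_len(config$n_per_cell)
  ) |>
    dplyr::filter(!(.data$timepoint == "T4" & .data$hs_regime == "HS1"))
  dplyr::mutate(design,
    plant_id = sprintf("%s_%d_%s_%s_p%02d", .data$cultivar, .data$co2,
                       gsub("[^A-Za-z0-9]", "", .data$hs_regime),
                       .data$timepoint, .data$replicate),
    .before = 1) |>
    dplyr::select(-"replicate")
}

# Reference A of a cultivar: FvCB prediction at Ca 400 umol mol-1 (operating
# Ci/Ca = 0.7), 25 degC, saturating light. Treatment contrasts are applied
# as multipliers around this baseline.
.a_reference <- function(cultivar) {
  p <- cultivar_params(cultivar)
  net_assimilation(data.frame(Ci = 280, Tleaf = 25, PPFD = 1500), p)$A
}

#' Generate steady-state gas-exchange observations
#'
#' One record per plant, measurement CO2 (the common 400 umol mol^-1
#' reference and the plant's growth CO2) and leaf temperature (25 and
#' 35 degC) at the three vegetative-to-anthesis time points (T1-T3). Net
#' assimilation is the cultivar's FvCB baseline times the calibrated
#' treatment multipliers (growth-CO2 stimulation for elevated-CO2 cells at
#' growth CO2; downregulation at common CO2) times unit-mean lognormal
#' noise, so with zero noise the configured percent effects are exact.
#' Stomatal conductance, transpiration and Ci are derived consistently from
#' A and the measurement CO2.
#'
#' @param design A design table from [generate_design()].
#' @param config The [experiment_config()].
#' @return A tibble with columns `plant_id`, `cultivar`, `co2`,
#'   `hs_regime`, `timepoint`, `meas_co2_type`, `Ca`, `Tleaf`, `PPFD`,
#'   `A`, `gs`, `Ci`, `E`, `Rd`.
#' @export
generate_gas_exchange <- function(design, config) {
  cal <- config$calibration$gas_exchange
  seed <- .stage_seed(config$seed, "gas_exchange")
  aco2 <- min(config$co2_levels)
  base <- purrr::map_dbl(c(Scout = "Scout", Yitpi = "Yitpi"), .a_reference)
  cul <- wheat_cultivars()

  obs <- design |>
    dplyr::filter(.data$timepoint %in% c("T1", "T2", "T3")) |>
    tidyr::expand_grid(meas_co2_type = c("common", "growth"),
                       Tleaf = c(25, 35)) |>
    dplyr::mutate(
      Ca = dplyr::if_else(.data$meas_co2_type == "growth" & .data$co2 != aco2,
                          .data$co2, 400),
      PPFD = 1500
    )

  ratio35 <- function(cultivar, Tleaf) {
    r <- cul[match(cultivar, cul$cultivar), ]
    ifelse(Tleaf == 25, 1,
           parabola_asat(r$Aopt, r$Asat_Topt, cal$asat_curvature, Tleaf) /
             parabola_asat(r$Aopt, r$Asat_Topt, cal$asat_curvature, 25))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(obs)
  mult <- dplyr::case_when(
    obs$co2 == aco2 ~ 1,
    obs$meas_co2_type == "growth" ~ cal$a_growth_stimulation,
    TRUE ~ cal$a_common_downregulation
  )
  gs_mult <- dplyr::case_when(
    obs$co2 != aco2 & obs$meas_co2_type == "common" ~
      cal$gs_common_downregulation / cal$a_common_downregulation,
    TRUE ~ 1
  )
  A <- unname(base[obs$cultivar]) * mult * ratio35(obs$cultivar, obs$Tleaf) *
    .ln_noise(n, config$noise_cv_gas)
  Ci <- obs$Ca * pmin(0.7 * (1 + stats::rnorm(n, 0, config$noise_cv_gas / 5)),
                      0.95)
  gsc <- A / (obs$Ca - Ci)                       # mol CO2 m-2 s-1
  gs <- 1.6 * gsc                                # mol H2O m-2 s-1
  Rd <- cul$Rd25[match(obs$cultivar, cul$cultivar)] *
    .ln_noise(n, config$noise_cv_gas)
  dplyr::mutate(obs, A = A, Ci = Ci, gs = gs * gs_mult,
                E = gs * gs_mult * 0.015, Rd = Rd)
}

# Save/restore the global RNG state so generator stages do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate A-Ci response curves at anthesis (T3)
#'
#' One 8-step curve per T3 plant at 25 degC and saturating light, computed
#' by the forward FvCB model at the plant's effective capacities: the
#' cultivar baseline with the calibrated carboxylation downregulation
#' applied in elevated-CO2 cells (electron transport capacity unaffected),
#' plus multiplicative noise on A.
#'
#' @inheritParams generate_gas_exchange
#' @param ci_steps Measurement Ci ladder (umol mol^-1).
#' @return A tibble with one row per plant and Ci step: `plant_id`,
#'   treatment columns, `Ci`, `A`, `Tleaf`, `PPFD`, plus the generating
#'   `Vcmax25`, `Jmax25`, `Rd25`, `gm25`.
#' @export
generate_aci_curves <- function(design, config,
                                ci_steps = c(50, 100, 230, 330, 420,
                                             650, 1200, 1800)) {
  cal <- config$calibration$aci
  aco2 <- min(config$co2_levels)
  seed <- .stage_seed(config$seed, "aci_curves")
  plants <- dplyr::filter(design, .data$timepoint == "T3")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  purrr::pmap_dfr(plants, function(plant_id, cultivar, co2, hs_regime,
                                   timepoint, ...) {
    eco2 <- co2 != aco2
    p <- cultivar_params(
      cultivar,
      Vcmax25 = wheat_cultivars()$Vcmax25[wheat_cultivars()$cultivar == cultivar] *
        (if (eco2) cal$vcmax_eco2[[cultivar]] else 1),
      Jmax25 = wheat_cultivars()$Jmax25[wheat_cultivars()$cultivar == cultivar] *
        (if (eco2) cal$jmax_eco2[[cultivar]] else 1))
    fwd <- net_assimilation(
      data.frame(Ci = ci_steps, Tleaf = 25, PPFD = 1500), p)
    tibble::tibble(
      plant_id = plant_id, cultivar = cultivar, co2 = co2,
      hs_regime = hs_regime, timepoint = timepoint,
      Ci = ci_steps,
      A = fwd$A * .ln_noise(length(ci_steps), config$noise_cv_gas),
      Tleaf = 25, PPFD = 1500,
      Vcmax25 = p$Vcmax25, Jmax25 = p$Jmax25, Rd25 = p$Rd25, gm25 = p$gm25)
  })
}

#' Generate concurrent isotope-discrimination observations
#'
#' Emulates the tunable-diode-laser protocol: ambient-CO2-grown plants of
#' both cultivars measured at the five leaf temperatures (15-35 degC). Each
#' plant's true mesophyll conductance follows the cultivar's quadratic
#' temperature profile (vertex at the cultivar's gm optimum, anchored at
#' the 25 degC value), times lognormal noise. The observed discrimination
#' is computed by the forward ternary-corrected predictor and converted to
#' chamber quantities (`Cref`, `Csam`, `delta_ref`, `delta_sam`) that
#' invert exactly through [observed_discrimination()], so the whole record
#' round-trips through [estimate_gm()].
#'
#' @inheritParams generate_gas_exchange
#' @param temperatures Measurement leaf temperatures (degC).
#' @return A tibble with the chamber isotope columns, the concurrent gas
#'   exchange (`A`, `Rd`, `E`, `Ca`, `Ci`, `GammaStar`, `gt_ac`, `Tleaf`)
#'   and the generating `gm_true`.
#' @export
generate_isotope_obs <- function(design, config,
                                 temperatures = c(15, 20, 25, 30, 35)) {
  aco2 <- min(config$co2_levels)
  curv <- config$calibration$isotope$gm_curvature
  seed <- .stage_seed(config$seed, "isotope")
  cul <- wheat_cultivars()
  plants <- design |>
    dplyr::filter(.data$co2 == aco2, .data$hs_regime == "Control",
                  .data$timepoint == "T1")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  obs <- tidyr::expand_grid(plants, Tleaf = temperatures)
  r <- cul[match(obs$cultivar, cul$cultivar), ]
  gm_opt <- r$gm25 + curv * (25 - r$gm_Topt)^2
  gm_true <- (gm_opt - curv * (obs$Tleaf - r$gm_Topt)^2) *
    .ln_noise(nrow(obs), config$noise_cv_gas)

  state <- purrr::map_dfr(unique(obs$Tleaf), function(Tl) {
    sc <- net_assimilation(data.frame(Ci = 280, Tleaf = Tl, PPFD = 1500),
                           cultivar_params("Scout"))
    yi <- net_assimilation(data.frame(Ci = 280, Tleaf = Tl, PPFD = 1500),
                           cultivar_params("Yitpi"))
    tibble::tibble(Tleaf = Tl, cultivar = c("Scout", "Yitpi"),
                   A = c(sc$A, yi$A), Rd = c(sc$Rd, yi$Rd))
  })
  obs <- dplyr::left_join(obs, state, by = c("cultivar", "Tleaf")) |>
    dplyr::mutate(
      Ca = 400, Ci = 280,
      GammaStar = arrhenius_scale(42.75, 37.83, .data$Tleaf),
      gt_ac = .data$A / (.data$Ca - .data$Ci),
      E = 1.6 * .data$gt_ac * 0.015,
      gm_true = gm_true)

  pred <- predict_delta_obs(obs, gm = obs$gm_true)
  dplyr::mutate(obs,
    Cref = .data$Ca,
    Csam = .data$Ca - 20,
    delta_ref = -8,
    delta_sam = .delta_sam_for(pred$Delta_o, .data$Ca, .data$Ca - 20, -8))
}

#' Generate the per-plant trait table
#'
#' Lognormal multiplicative model:
#' trait = Scout baseline(time point) x cultivar ratio x eCO2 multiplier x
#' heat-stress interaction x unit-mean noise. Grain traits exist only at
#' final harvest; grain mass is derived as grain number x grain size so the
#' elevated-CO2 yield gain enters through grain number, and heat-stressed
#' cells have the elevated-CO2 gain on biomass and grain number divided
#' back out (no yield response to eCO2 under heat). Fv/Fm is clamped to its
#' physiological ceiling of 0.87.
#'
#' @inheritParams generate_gas_exchange
#' @return A tibble with one row per plant: treatment columns plus
#'   `total_dry_mass` (g), `tillers`, `leaf_area` (cm^2), `leaf_number`,
#'   `height` (cm), `grain_number`, `grain_size` (mg), `grain_mass` (g),
#'   `grain_n_pct` (%), `fvfm`.
#' @export
generate_traits <- function(design, config) {
  cal <- config$calibration
  aco2 <- min(config$co2_levels)
  seed <- .stage_seed(config$seed, "traits")
  cv <- config$noise_cv_traits

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n <- nrow(design)
  tp <- design$timepoint
  yit <- design$cultivar == "Yitpi"
  eco2 <- design$co2 != aco2
  hs <- design$hs_regime != "Control"

  one_trait <- function(trait) {
    base <- cal$baselines[[trait]][tp]
    ratio <- cal$yitpi_ratio[[trait]][tp]
    ratio[is.na(ratio)] <- 1
    val <- base * ifelse(yit, ratio, 1)
    emap <- cal$traits$eco2[[trait]]
    if (!is.null(emap)) {
      for (t_at in names(emap)) {
        m <- emap[[t_at]][design$cultivar]
        apply_to <- eco2 & tp == t_at &
          !(hs & trait %in% cal$traits$hs_removes_eco2_gain)
        val <- val * ifelse(apply_to, m, 1)
      }
    }
    val * .ln_noise(n, cv)
  }

  traits <- purrr::map(stats::setNames(nm = c(
    "total_dry_mass", "tillers", "leaf_area", "leaf_number", "height",
    "grain_number", "grain_size", "grain_n_pct", "fvfm")), one_trait)
  out <- dplyr::bind_cols(design, tibble::as_tibble(traits)) |>
    dplyr::mutate(
      fvfm = pmin(.data$fvfm, 0.87),
      grain_mass = .data$grain_number * .data$grain_size / 1000)
  # grain traits are undefined before final harvest
  grain_cols <- c("grain_number", "grain_size", "grain_mass", "grain_n_pct")
  out[out$timepoint != "T4", grain_cols] <- NA_real_
  out
}

#' Derived leaf- and plant-level indices
#'
#' Adds whichever of the standard derived indices the input columns
#' support: intrinsic water-use efficiency `iWUE = A/gs`
#' (umol CO2 mol H2O^-1), leaf nitrogen per area
#' `Narea = N_mmol_g x LMA` (mmol m^-2), photosynthetic nitrogen-use
#' efficiency `PNUE = A/Narea`, grain protein `= grain N x 5.7` (%), and
#' nitrogen utilisation efficiency `NUtE = grain mass / total plant N`.
#' Division by a zero denominator yields `NA` (flagged missing), never an
#' error.
#'
#' @param records A data frame; recognised columns are `A`, `gs`,
#'   `N_mmol_g`, `LMA`, `grain_n_pct`, `grain_mass`, `total_plant_n`.
#' @return The input tibble with the supported index columns appended.
#' @examples
#' derived_leaf_indices(data.frame(A = 20, gs = 0.4))
#' @export
derived_leaf_indices <- function(records) {
  records <- tibble::as_tibble(records)
  has <- function(...) all(c(...) %in% names(records))
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  if (has("A", "gs")) {
    records$iWUE <- safe_div(records$A, records$gs)
  }
  if (has("N_mmol_g", "LMA")) {
    records$Narea <- records$N_mmol_g * records$LMA
    if (has("A")) records$PNUE <- safe_div(records$A, records$Narea)
  }
  if (has("grain_n_pct")) {
    records$protein <- records$grain_n_pct * 5.7
  }
  if (has("grain_mass", "total_plant_n")) {
    records$NUtE <- safe_div(records$grain_mass, records$total_plant_n)
  }
  records
}

#' Run every generator stage of the synthetic experiment
#'
#' @param config An [experiment_config()] object.
#' @return A list with `design`, `gas_exchange`, `aci_curves`, `isotope`
#'   and `traits` tibbles.
#' @examples
#' sim <- simulate_experiment(experiment_config(seed = 42, n_per_cell = 2))
#' names(sim)
#' @export
simulate_experiment <- function(config) {
  design <- generate_design(config)
  list(
    design = design,
    gas_exchange = generate_gas_exchange(design, config),
    aci_curves = generate_aci_curves(design, config),
    isotope = generate_isotope_obs(design, config),
    traits = generate_traits(design, config)
  )
}
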