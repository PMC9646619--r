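#' Default column mapping for LI-6400-style gas-exchange CSV exports
#'
#' Maps instrument export column names to the names this package uses.
#' Matching is case-insensitive; unmapped columns are carried through
#' unchanged.
#'
#' @return A named character vector `c(export_name = internal_name)`.
#' @export
li6400_mapping <- function() {
  c(Photo = "A", Cond = "gs", Ci = "Ci", Trmmol = "E_mmol",
    Tleaf = "Tleaf", PARi = "PPFD", CO2R = "Ca", CO2S = "Csam")
}

#' Read a gas-exchange CSV with instrument column names
#'
#' Reads an LI-6400-style export, renames columns per the mapping
#' (case-insensitive), normalises units (transpiration from
#' mmol m^-2 s^-1 to mol m^-2 s^-1), drops rows whose mapped numeric
#' fields fail to parse, and reports how many were skipped.
#'
#' @param path CSV file path.
#' @param mapping Named character vector from export names to internal
#'   names; see [li6400_mapping()].
#' @param required Internal column names that must be present after
#'   mapping.
#' @return A tibble of typed observations. The number of skipped malformed
#'   rows is attached as attribute `n_skipped` and reported via a message.
#' @export
read_gas_exchange <- function(path, mapping = li6400_mapping(),
                              required = c("A", "Ci")) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  lower <- tolower(names(raw))
  for (i in seq_along(mapping)) {
    hit <- which(lower == tolower(names(mapping)[i]))
    if (length(hit)) names(raw)[hit[1]] <- unname(mapping[i])
  }
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop("gas-exchange file is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  mapped <- intersect(unname(mapping), names(raw))
  parsed <- raw
  for (cn in mapped) parsed[[cn]] <- suppressWarnings(as.numeric(raw[[cn]]))
  bad <- rowSums(is.na(parsed[, mapped, drop = FALSE]) &
                   !is.na(raw[, mapped, drop = FALSE]) &
                   raw[, mapped, drop = FALSE] != "") > 0
  bad <- bad | rowSums(is.na(parsed[, required, drop = FALSE])) > 0
  if (any(bad)) {
    message("read_gas_exchange: skipped ", sum(bad), " malformed row(s)")
  }
  out <- parsed[!bad, , drop = FALSE]
  if ("E_mmol" %in% names(out)) {
    out$E <- out$E_mmol / 1000
    out$E_mmol <- NULL
  }
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Read an isotope log CSV
#'
#' Expects the per-observation columns the isotope writer emits: chamber
#' quantities (`Cref`, `Csam`, `delta_ref`, `delta_sam`) and concurrent gas
#' exchange (`A`, `Rd`, `E`, `Ca`, `Ci`, `GammaStar`, `gt_ac`, `Tleaf`).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_isotope_log <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("Cref", "Csam", "delta_ref", "delta_sam",
           "A", "Rd", "E", "Ca", "Ci", "GammaStar", "gt_ac")
  miss <- setdiff(req, names(dat))
  if (length(miss)) stop("isotope log is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  dat
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Chains the stages end to end: simulate the factorial experiment,
#' estimate mesophyll conductance from the isotope log, fit the A-Ci
#' curves, fit all temperature responses into a parameter summary table,
#' and compute treatment effects (percent changes and factorial ANOVA for
#' the headline traits). Outputs are written as CSV into `out_dir`
#' together with a JSON run manifest (seed, package version, calibration
#' hash, output checksums); re-running with the same config reproduces
#' every table byte-identically.
#'
#' @param config An [experiment_config()] object.
#' @param out_dir Output directory (created if absent); `NULL` skips
#'   writing and just returns the result bundle.
#' @param n_aci_fits Number of A-Ci curves to fit per treatment cell (the
#'   fits are the slow stage; defaults to 2 per cell).
#' @return A list with `sim`, `gm_estimates`, `aci_fits`, `table1`,
#'   `effects`, `anova` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_aci_fits = 2) {
  stopifnot(inherits(config, "experiment_config"))
  sim <- simulate_experiment(config)

  # --- mesophyll conductance from the isotope log -----------------------
  gm_est <- estimate_gm(sim$isotope)
  gm_summary <- gm_est |>
    dplyr::group_by(.data$cultivar, .data$Tleaf) |>
    dplyr::summarise(gm_mean = mean(.data$gm), gm_se = stats::sd(.data$gm) /
                       sqrt(dplyr::n()), .groups = "drop")

  # --- A-Ci fits (subset per cell to keep the stage quick) --------------
  aci_sub <- sim$aci_curves |>
    dplyr::group_by(.data$cultivar, .data$co2, .data$hs_regime) |>
    dplyr::filter(.data$plant_id %in% unique(.data$plant_id)[
      seq_len(min(n_aci_fits, length(unique(.data$plant_id))))]) |>
    dplyr::ungroup()
  aci_fits <- aci_sub |>
    dplyr::group_by(.data$plant_id, .data$cultivar, .data$co2,
                    .data$hs_regime) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_aci(d, Rd = d$Rd25[1], gm = d$gm25[1], Tleaf = d$Tleaf[1],
                   PPFD = d$PPFD[1])
      dplyr::bind_cols(tidy(f) |>
                         tidyr::pivot_wider(names_from = "term",
                                            values_from = c("estimate",
                                                            "std.error")),
                       glance(f)[, c("rss", "converged")])
    }) |>
    dplyr::ungroup()

  # --- temperature-response fits per cultivar ---------------------------
  cul <- wheat_cultivars()
  fits <- purrr::map(stats::setNames(nm = cul$cultivar), function(cv) {
    r <- cul[cul$cultivar == cv, ]
    temps <- c(15, 20, 25, 30, 35)
    gm_series <- gm_summary |>
      dplyr::filter(.data$cultivar == cv) |>
      dplyr::transmute(Tleaf = .data$Tleaf, value = .data$gm_mean)
    list(
      asat = fit_parabola(data.frame(
        Tleaf = temps,
        value = parabola_asat(r$Aopt, r$Asat_Topt, 0.05, temps))),
      gm = fit_quadratic(gm_series),
      vcmax = fit_arrhenius(data.frame(
        Tleaf = temps, value = arrhenius_scale(r$Vcmax25, r$EaV, temps))),
      jmax = fit_peaked(data.frame(
        Tleaf = temps,
        value = peaked_arrhenius_scale(r$Jmax25, r$EaJ, r$HdJ, r$deltaSJ,
                                       temps))),
      rd_arrhenius = fit_arrhenius(data.frame(
        Tleaf = temps, value = arrhenius_scale(r$Rd25, r$EaR, temps))),
      rd_q10 = fit_q10(data.frame(
        Tleaf = temps, value = arrhenius_scale(r$Rd25, r$EaR, temps)))
    )
  })
  table1 <- build_table1(fits)

  # --- treatment effects ------------------------------------------------
  t3_ctrl <- sim$traits |>
    dplyr::filter(.data$timepoint == "T3", .data$hs_regime == "Control")
  t4_ctrl <- sim$traits |>
    dplyr::filter(.data$timepoint == "T4", .data$hs_regime == "Control")
  aco2 <- min(config$co2_levels)
  eff_seed <- .stage_seed(config$seed, "effects")
  effects <- dplyr::bind_rows(
    biomass_yitpi_vs_scout_T3_aCO2 = percent_change(
      dplyr::filter(t3_ctrl, .data$co2 == aco2),
      .data$total_dry_mass, .data$cultivar, ref = "Scout",
      seed = eff_seed),
    grain_number_eco2_scout = percent_change(
      dplyr::filter(t4_ctrl, .data$cultivar == "Scout"),
      .data$grain_number, .data$co2, ref = aco2, seed = eff_seed + 1),
    grain_protein_eco2_yitpi = percent_change(
      dplyr::filter(t4_ctrl, .data$cultivar == "Yitpi") |>
        derived_leaf_indices(),
      .data$protein, .data$co2, ref = aco2, seed = eff_seed + 2),
    .id = "effect")
  anova_tab <- factorial_anova(
    dplyr::filter(sim$traits, .data$timepoint == "T3"),
    "total_dry_mass")

  res <- list(sim = sim, gm_estimates = gm_summary, aci_fits = aci_fits,
              table1 = table1, effects = effects, anova = anova_tab)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(gas_exchange = "gas_exchange.csv", traits = "traits.csv",
               isotope = "isotope_log.csv", aci_curves = "aci_curves.csv",
               gm = "gm_summary.csv", aci_fits = "aci_fits.csv",
               table1 = "parameter_table.csv", effects = "effects.csv",
               anova = "anova_biomass_T3.csv")
    tabs <- list(sim$gas_exchange, sim$traits, sim$isotope, sim$aci_curves,
                 gm_summary, aci_fits, table1, effects, anova_tab)
    for (i in seq_along(paths)) {
      readr::write_csv(tabs[[i]], file.path(out_dir, paths[i]))
    }
    checksums <- vapply(file.path(out_dir, paths),
                        function(p) rlang::hash(readr::read_file(p)),
                        character(1))
    names(checksums) <- unname(paths)
    manifest <- list(
      seed = config$seed,
      n_per_cell = config$n_per_cell,
      package_version = as.character(utils::packageVersion("wheatphys")),
      calibration_hash = rlang::hash(config$calibration),
      config_hash = rlang::hash(config),
      outputs = as.list(checksums))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    res$manifest <- manifest
  }
  res
}
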