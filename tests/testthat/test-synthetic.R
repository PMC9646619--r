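test_that("design crossing matches the protocol including the missing T4 cells", {
  cfg <- experiment_config(seed = 1)
  d <- generate_design(cfg)
  # 160 plants per fully crossed time point
  expect_equal(sum(d$timepoint == "T3"), 2 * 2 * 4 * 10)
  # plants exposed only to the vegetative heat stress are not harvested at T4
  expect_setequal(unique(d$hs_regime[d$timepoint == "T4"]),
                  c("Control", "HS2", "HS1+2"))
  expect_equal(sum(d$timepoint == "T4"), 2 * 2 * 3 * 10)
  # a different seed changes nothing about the design table itself
  expect_identical(dplyr::select(d, -"plant_id"),
                   dplyr::select(generate_design(experiment_config(seed = 99)),
                                 -"plant_id"))
  expect_error(experiment_config(), "seed")
})

test_that("identical seed and config reproduce every table exactly", {
  cfg <- experiment_config(seed = 12, n_per_cell = 3)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_experiment(experiment_config(seed = 13, n_per_cell = 3))
  expect_false(identical(s1$traits, s3$traits))
})

test_that("zero-noise gas exchange reproduces the configured multipliers exactly", {
  cfg <- experiment_config(seed = 3, n_per_cell = 2,
                           noise_cv_gas = 0, noise_cv_traits = 0)
  d <- generate_design(cfg)
  gx <- generate_gas_exchange(d, cfg) |>
    dplyr::filter(.data$Tleaf == 25, .data$timepoint == "T2",
                  .data$hs_regime == "Control")
  a_ref <- gx$A[gx$co2 == 450 & gx$meas_co2_type == "growth"][1]
  a_growth <- gx$A[gx$co2 == 650 & gx$meas_co2_type == "growth"][1]
  a_common <- gx$A[gx$co2 == 650 & gx$meas_co2_type == "common"][1]
  expect_equal(a_growth / a_ref, 1.21, tolerance = 1e-12)
  expect_equal(a_common / a_ref, 0.88, tolerance = 1e-12)
})

test_that("generated gas exchange is physically consistent", {
  cfg <- experiment_config(seed = 21, n_per_cell = 4)
  gx <- generate_gas_exchange(generate_design(cfg), cfg)
  expect_true(all(gx$Ci < gx$Ca))
  expect_true(all(gx$A > 0))
  expect_true(all(gx$gs > 0 & gx$E > 0))
  # 35 degC runs below the 25 degC optimum-side value for the same plant
  wide <- gx |>
    dplyr::filter(.data$meas_co2_type == "growth") |>
    dplyr::group_by(.data$plant_id, .data$timepoint) |>
    dplyr::summarise(r = .data$A[.data$Tleaf == 35] / .data$A[.data$Tleaf == 25],
                     .groups = "drop")
  expect_lt(mean(wide$r), 1)
})

test_that("noiseless A-Ci curves refit to the cell's effective capacities", {
  cfg <- experiment_config(seed = 8, n_per_cell = 2, noise_cv_gas = 0)
  curves <- generate_aci_curves(generate_design(cfg), cfg)
  one <- function(co2_level, cultivar) {
    d <- dplyr::filter(curves, .data$co2 == co2_level,
                       .data$cultivar == cultivar,
                       .data$hs_regime == "Control")
    d <- d[d$plant_id == d$plant_id[1], ]
    fit_aci(d, Rd = d$Rd25[1], gm = d$gm25[1])
  }
  f_amb <- one(450, "Scout")
  expect_equal(unname(f_amb$coef[["Vcmax"]]), 192.7, tolerance = 0.005)
  expect_equal(unname(f_amb$coef[["Jmax"]]), 187.9, tolerance = 0.005)
  # elevated-CO2 Scout carries the 14% carboxylation downregulation
  f_elev <- one(650, "Scout")
  expect_equal(unname(f_elev$coef[["Vcmax"]]), 192.7 * 0.86,
               tolerance = 0.005)
  expect_equal(unname(f_elev$coef[["Jmax"]]), 187.9, tolerance = 0.005)
})

test_that("isotope observations round-trip to the cultivar gm profiles", {
  cfg <- experiment_config(seed = 31, n_per_cell = 5, noise_cv_gas = 0)
  iso <- generate_isotope_obs(generate_design(cfg), cfg)
  est <- estimate_gm(iso)
  # exact round trip of the generating gm, observation by observation
  expect_equal(est$gm, iso$gm_true, tolerance = 1e-8)
  at25 <- est |>
    dplyr::filter(.data$Tleaf == 25) |>
    dplyr::group_by(.data$cultivar) |>
    dplyr::summarise(gm = mean(.data$gm))
  expect_equal(at25$gm[at25$cultivar == "Scout"], 0.31, tolerance = 1e-6)
  expect_equal(at25$gm[at25$cultivar == "Yitpi"], 0.25, tolerance = 1e-6)
})

test_that("zero-noise traits carry the configured contrasts exactly", {
  cfg <- experiment_config(seed = 2, n_per_cell = 2, noise_cv_traits = 0)
  tr <- generate_traits(generate_design(cfg), cfg)
  t3 <- dplyr::filter(tr, .data$timepoint == "T3",
                      .data$hs_regime == "Control", .data$co2 == 450)
  expect_equal(mean(t3$total_dry_mass[t3$cultivar == "Yitpi"]) /
                 mean(t3$total_dry_mass[t3$cultivar == "Scout"]),
               1.42, tolerance = 1e-12)
  t4 <- dplyr::filter(tr, .data$timepoint == "T4",
                      .data$hs_regime == "Control", .data$cultivar == "Scout")
  expect_equal(mean(t4$grain_number[t4$co2 == 650]) /
                 mean(t4$grain_number[t4$co2 == 450]),
               1.64, tolerance = 1e-12)
  # heat-stressed cells gain no yield from elevated CO2
  hs <- dplyr::filter(tr, .data$timepoint == "T4",
                      .data$hs_regime == "HS1+2", .data$cultivar == "Scout")
  expect_equal(mean(hs$grain_mass[hs$co2 == 650]) /
                 mean(hs$grain_mass[hs$co2 == 450]),
               1, tolerance = 1e-12)
  # grain traits are undefined before final harvest; Fv/Fm stays bounded
  expect_true(all(is.na(tr$grain_mass[tr$timepoint != "T4"])))
  expect_true(all(tr$fvfm <= 0.87 & tr$fvfm > 0))
})

test_that("derived indices compute where defined and flag where not", {
  out <- derived_leaf_indices(data.frame(A = 20, gs = 0.4))
  expect_equal(out$iWUE, 50)
  out0 <- derived_leaf_indices(data.frame(A = 20, gs = 0))
  expect_true(is.na(out0$iWUE))
  prot <- derived_leaf_indices(data.frame(grain_n_pct = 2))
  expect_equal(prot$protein, 11.4)
  full <- derived_leaf_indices(data.frame(
    A = 20, gs = 0.4, N_mmol_g = 1.5, LMA = 50,
    grain_mass = 10, total_plant_n = 0.5))
  expect_equal(full$Narea, 75)
  expect_equal(full$PNUE, 20 / 75)
  expect_equal(full$NUtE, 20)
})

test_that("generator RNG streams are independent and restore global state", {
  cfg <- experiment_config(seed = 4, n_per_cell = 2)
  d <- generate_design(cfg)
  tr1 <- generate_traits(d, cfg)
  # running another stage in between does not shift the trait draws
  invisible(generate_gas_exchange(d, cfg))
  tr2 <- generate_traits(d, cfg)
  expect_identical(tr1, tr2)
  # global RNG state is untouched by the generators
  set.seed(500); x1 <- rnorm(1)
  set.seed(500); invisible(generate_traits(d, cfg)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})
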