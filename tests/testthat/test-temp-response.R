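test_that("Arrhenius fitter recovers its own noiseless forward model", {
  for (truth in list(c(1.25, 30.9), c(192.7, 43.3), c(198.4, 46.4))) {
    d <- data.frame(Tleaf = five_temps,
                    value = arrhenius_scale(truth[1], truth[2], five_temps))
    fit <- fit_arrhenius(d)
    expect_equal(unname(fit$coef[["k25"]]), truth[1], tolerance = 1e-6)
    expect_equal(unname(fit$coef[["Ea"]]), truth[2], tolerance = 1e-6)
  }
  # a constant series is a zero-activation-energy process
  flat <- fit_arrhenius(data.frame(Tleaf = five_temps, value = rep(3.2, 5)))
  expect_equal(unname(flat$coef[["Ea"]]), 0, tolerance = 1e-6)
  expect_equal(unname(flat$coef[["k25"]]), 3.2, tolerance = 1e-8)
})

test_that("Q10 fitter is exact on Q10 data and matches the printed value on Arrhenius data", {
  d <- data.frame(Tleaf = five_temps,
                  value = q10_respiration(1.25, 1.51, five_temps))
  fit <- fit_q10(d)
  expect_equal(unname(fit$coef[["Rd25"]]), 1.25, tolerance = 1e-9)
  expect_equal(unname(fit$coef[["Q10"]]), 1.51, tolerance = 1e-9)
  # consistency of the two respiration models: Arrhenius-generated series
  da <- data.frame(Tleaf = five_temps,
                   value = arrhenius_scale(1.25, 30.9, five_temps))
  fa <- fit_q10(da)
  expect_equal(unname(fa$coef[["Q10"]]), 1.51, tolerance = 0.03 / 1.51)
  # two points a decade apart give the ratio exactly
  d2 <- data.frame(Tleaf = c(25, 35), value = c(1.1, 1.76))
  expect_equal(unname(fit_q10(d2)$coef[["Q10"]]), 1.76 / 1.1,
               tolerance = 1e-10)
  expect_error(fit_q10(data.frame(Tleaf = five_temps, value = c(1, 2, -1, 2, 3))),
               "positive")
})

test_that("peaked fitter recovers both cultivar parameter sets and their optima", {
  for (truth in list(c(187.9, 37.7, 648.3, 29.6), c(186.1, 41.1, 647, 30.5))) {
    d <- data.frame(
      Tleaf = five_temps,
      value = peaked_arrhenius_scale(truth[1], truth[2], 200, truth[3],
                                     five_temps))
    fit <- fit_peaked(d, Hd = 200)
    expect_equal(unname(fit$coef[["k25"]]), truth[1], tolerance = 1e-4)
    expect_equal(unname(fit$coef[["Ea"]]), truth[2], tolerance = 1e-4)
    expect_equal(unname(fit$coef[["deltaS"]]), truth[3], tolerance = 1e-4)
    # the derived optimum agrees with the printed one to input-rounding slack
    expect_equal(fit$Topt, truth[4], tolerance = 0.5 / truth[4])
    # fitted optimum dominates every observation on noiseless data
    expect_true(all(fit$value_at_Topt >= d$value - 1e-8))
  }
  # monotone series: optimum pushed to the boundary, flagged
  mono <- data.frame(Tleaf = five_temps,
                     value = arrhenius_scale(100, 60, five_temps))
  expect_warning(fit_peaked(mono), "monotone|beyond")
})

test_that("parabola fitter equals the closed-form quadratic-vertex solution", {
  for (truth in list(c(24.6, 23.4, 0.05), c(22, 23.4, 0.05))) {
    d <- data.frame(Tleaf = five_temps,
                    value = parabola_asat(truth[1], truth[2], truth[3],
                                          five_temps))
    fit <- fit_parabola(d)
    expect_equal(unname(fit$coef[["Aopt"]]), truth[1], tolerance = 1e-9)
    expect_equal(unname(fit$coef[["Topt"]]), truth[2], tolerance = 1e-9)
    expect_equal(unname(fit$coef[["b_curv"]]), truth[3], tolerance = 1e-9)
    # oracle equivalence: plain quadratic regression vertex
    quad <- stats::lm(value ~ Tleaf + I(Tleaf^2), data = d)
    cf <- stats::coef(quad)
    expect_equal(unname(fit$coef[["Topt"]]), -cf[[2]] / (2 * cf[[3]]),
                 tolerance = 1e-9)
    expect_equal(unname(fit$coef[["Aopt"]]),
                 cf[[1]] - cf[[2]]^2 / (4 * cf[[3]]), tolerance = 1e-9)
  }
  noisy <- data.frame(Tleaf = five_temps,
                      value = parabola_asat(24.6, 23.4, 0.05, five_temps) +
                        c(0.3, -0.2, 0.1, -0.3, 0.2))
  fit <- fit_parabola(noisy)
  quad <- stats::lm(value ~ Tleaf + I(Tleaf^2), data = noisy)
  cf <- stats::coef(quad)
  expect_equal(unname(fit$coef[["Topt"]]), -cf[[2]] / (2 * cf[[3]]),
               tolerance = 1e-9)
})

test_that("quadratic fitter reports the vertex and flags linear data", {
  # build a gm series with a vertex at the printed optimum
  curv <- 5e-4
  gm <- 0.315 - curv * (five_temps - 27.9)^2
  fit <- fit_quadratic(data.frame(Tleaf = five_temps, value = gm))
  expect_equal(fit$vertex, 27.9, tolerance = 1e-8)
  lin_fit <- suppressWarnings(
    fit_quadratic(data.frame(Tleaf = five_temps,
                             value = 2 + 0.1 * five_temps)))
  expect_true(is.na(lin_fit$vertex))
  # three exact points are interpolated with zero residual
  d3 <- data.frame(Tleaf = c(15, 25, 35), value = c(1, 4, 2))
  expect_lt(fit_quadratic(d3)$rss, 1e-20)
})

test_that("Ea estimates are nearly unbiased with calibrated interval coverage", {
  set.seed(404)
  truth <- c(k25 = 192.7, Ea = 43.3)
  n_rep <- 500
  est <- se <- numeric(n_rep)
  base <- arrhenius_scale(truth[["k25"]], truth[["Ea"]], five_temps)
  for (i in seq_len(n_rep)) {
    d <- data.frame(Tleaf = five_temps,
                    value = base * (1 + rnorm(5, 0, 0.03)))
    fit <- fit_arrhenius(d)
    est[i] <- fit$coef[["Ea"]]
    se[i] <- fit$se[["Ea"]]
  }
  expect_lt(abs(mean(est) - truth[["Ea"]]) / truth[["Ea"]], 0.02)
  cover <- mean(abs(est - truth[["Ea"]]) <= stats::qt(0.975, 3) * se)
  expect_gte(cover, 0.90)
  expect_lte(cover, 0.99)
})

test_that("the summary table assembles all rows and tolerates missing fits", {
  temps <- five_temps
  fits <- list(Scout = list(
    asat = fit_parabola(data.frame(
      Tleaf = temps, value = parabola_asat(24.6, 23.4, 0.05, temps))),
    gm = fit_quadratic(data.frame(
      Tleaf = temps, value = 0.315 - 5e-4 * (temps - 27.9)^2)),
    vcmax = fit_arrhenius(data.frame(
      Tleaf = temps, value = arrhenius_scale(192.7, 43.3, temps))),
    jmax = fit_peaked(data.frame(
      Tleaf = temps,
      value = peaked_arrhenius_scale(187.9, 37.7, 200, 648.3, temps))),
    rd_arrhenius = fit_arrhenius(data.frame(
      Tleaf = temps, value = arrhenius_scale(1.25, 30.9, temps))),
    rd_q10 = fit_q10(data.frame(
      Tleaf = temps, value = arrhenius_scale(1.25, 30.9, temps)))
  ))
  tab <- build_table1(fits)
  expect_equal(nrow(tab), 15)
  expect_true(all(tab$available))
  expect_equal(tab$estimate[tab$constant == "Hd (kJ mol-1)"], 200)
  # dropping the gm fit marks only the gm rows unavailable
  fits$Scout$gm <- NULL
  tab2 <- build_table1(fits)
  expect_equal(sum(!tab2$available), 2)
  expect_true(all(tab2$parameter[!tab2$available] == "gm"))
})
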