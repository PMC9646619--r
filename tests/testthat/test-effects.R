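test_that("percent change point estimate and interval behave on exact inputs", {
  d <- data.frame(g = rep(c("ref", "trt"), each = 5),
                  y = c(rep(10, 5), rep(12, 5)))
  out <- percent_change(d, y, g, ref = "ref", seed = 1)
  expect_equal(out$percent_change, 20)
  ident <- data.frame(g = rep(c("a", "b"), each = 6), y = rep(5, 12))
  out0 <- percent_change(ident, y, g, ref = "a", seed = 1)
  expect_equal(out0$percent_change, 0)
  expect_true(out0$conf.low <= 0 && out0$conf.high >= 0)
  # CI always contains the point estimate on noisy data
  set.seed(9)
  noisy <- data.frame(g = rep(c("a", "b"), each = 10),
                      y = rlnorm(20, 2, 0.2))
  o <- percent_change(noisy, y, g, ref = "a", seed = 2)
  expect_true(o$conf.low <= o$percent_change &&
                o$percent_change <= o$conf.high)
  expect_error(percent_change(d[c(1, 6), ], y, g, ref = "ref", seed = 1),
               "at least 2")
  neg <- data.frame(g = rep(c("a", "b"), each = 3), y = c(-1, -2, -3, 1, 2, 3))
  expect_error(percent_change(neg, y, g, ref = "a", seed = 1),
               "not positive")
})

test_that("percent change recovers the calibrated cultivar biomass contrast", {
  cfg <- experiment_config(seed = 77, n_per_cell = 1000,
                           timepoints = "T3", hs_regimes = "Control")
  tr <- generate_traits(generate_design(cfg), cfg) |>
    dplyr::filter(.data$co2 == 450)
  out <- percent_change(tr, total_dry_mass, cultivar, ref = "Scout",
                        seed = 5)
  expect_equal(out$percent_change, 42, tolerance = 2 / 42)
  expect_true(out$conf.low < 42 && out$conf.high > 42)
})

test_that("bootstrap interval coverage is calibrated at nominal 95%", {
  set.seed(606)
  n_rep <- 1000
  hits <- logical(n_rep)
  sigma <- sqrt(log(1 + 0.1^2))
  for (i in seq_len(n_rep)) {
    d <- data.frame(
      g = rep(c("a", "b"), each = 10),
      y = c(rlnorm(10, log(10) - sigma^2 / 2, sigma),
            rlnorm(10, log(12) - sigma^2 / 2, sigma)))
    o <- percent_change(d, y, g, ref = "a", B = 999, seed = i)
    hits[i] <- o$conf.low <= 20 && 20 <= o$conf.high
  }
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)
})

test_that("factorial ANOVA is order invariant on balanced data and guards cells", {
  cfg <- experiment_config(seed = 15, n_per_cell = 4, timepoints = "T3")
  tr <- generate_traits(generate_design(cfg), cfg)
  a1 <- factorial_anova(tr, "total_dry_mass",
                        c("cultivar", "co2", "hs_regime"))
  a2 <- factorial_anova(tr, "total_dry_mass",
                        c("hs_regime", "co2", "cultivar"))
  expect_equal(sort(a1$sumsq), sort(a2$sumsq), tolerance = 1e-9)
  # degrees of freedom decompose the sample size
  expect_equal(sum(a1$df), nrow(tr) - 1)
  expect_true(all(a1$sumsq >= 0))
  # an empty cell is named, not silently dropped
  broken <- dplyr::filter(tr, !(.data$cultivar == "Scout" &
                                  .data$co2 == 650 &
                                  .data$hs_regime == "HS1"))
  expect_error(factorial_anova(broken, "total_dry_mass"),
               "empty design cell")
  expect_error(factorial_anova(tr, "no_such_column"), "missing columns")
})

test_that("a pure CO2 effect is detected and permuted labels are null", {
  cfg <- experiment_config(seed = 18, n_per_cell = 10, timepoints = "T4",
                           hs_regimes = c("Control", "HS1+2"))
  tr <- generate_traits(generate_design(cfg), cfg)
  a <- factorial_anova(tr, "grain_number")
  expect_lt(a$p.value[a$term == "co2"], 0.001)
  # permuting treatment labels destroys the signal on average
  set.seed(42)
  p_perm <- replicate(50, {
    perm <- tr
    perm$co2 <- sample(perm$co2)
    factorial_anova(perm, "grain_number")$p.value[2]
  })
  expect_gt(mean(p_perm > 0.05), 0.8)
})

test_that("three-way interaction on yield is detected with good power", {
  # the heat-stress x CO2 x cultivar structure built into the generator:
  # under heat stress the eCO2 grain-number gain is absent
  set.seed(77)
  detected <- replicate(20, {
    cfg <- experiment_config(seed = sample.int(1e6, 1), n_per_cell = 10,
                             timepoints = "T4",
                             hs_regimes = c("Control", "HS1+2"))
    tr <- generate_traits(generate_design(cfg), cfg)
    a <- factorial_anova(tr, "grain_number")
    a$p.value[a$term == "co2:hs_regime"] < 0.05
  })
  expect_gt(mean(detected), 0.8)
})

test_that("ANOVA type-I error is nominal under the null generator", {
  # null: all multiplicative effects off, pure lognormal noise
  set.seed(1001)
  n_sim <- 2000
  terms <- c("cultivar", "co2", "hs", "cultivar:co2", "cultivar:hs",
             "co2:hs", "cultivar:co2:hs")
  rejections <- matrix(FALSE, n_sim, length(terms),
                       dimnames = list(NULL, terms))
  grid <- tidyr::expand_grid(cultivar = c("a", "b"), co2 = c("x", "y"),
                             hs = c("c", "h"), rep = 1:5)
  for (i in seq_len(n_sim)) {
    grid$y <- rlnorm(nrow(grid), 0, 0.1)
    a <- factorial_anova(grid, "y", c("cultivar", "co2", "hs"))
    rejections[i, ] <- a$p.value[match(terms, a$term)] < 0.05
  }
  rates <- colMeans(rejections)
  expect_true(all(rates >= 0.03 & rates <= 0.07))
})

test_that("Tukey letters separate exactly the significantly different cells", {
  # all equal means share a single letter
  eq <- tukey_letters(c(a = 10, b = 10, c = 10), s2 = 1, n = 5, df = 12)
  expect_true(all(eq$letters == "a"))
  # two far-separated means get distinct letters
  sep <- tukey_letters(c(lo = 1, hi = 100), s2 = 0.01, n = 5, df = 8)
  expect_setequal(sep$letters, c("a", "b"))
  expect_error(tukey_letters(c(a = 1, b = 2), s2 = 1, n = 5, df = 0), "degrees")

  # 4-cell pattern checked against the all-pairs studentized-range oracle
  means <- c(m1 = 10, m2 = 10.2, m3 = 14, m4 = 19)
  s2 <- 1.2; n <- 6; df <- 20
  out <- tukey_letters(means, s2, n, df)
  share_letter <- function(i, j) {
    li <- out$letters[out$group == names(means)[i]]
    lj <- out$letters[out$group == names(means)[j]]
    any(strsplit(li, "")[[1]] %in% strsplit(lj, "")[[1]])
  }
  for (i in 1:3) {
    for (j in (i + 1):4) {
      q <- abs(means[i] - means[j]) / sqrt(s2 / n)
      sig <- unname(stats::ptukey(q, 4, df, lower.tail = FALSE) < 0.05)
      expect_identical(share_letter(i, j), !sig)
    }
  }
})
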