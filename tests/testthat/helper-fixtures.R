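# Shared fixtures: printed Ci ladder and the two cultivar parameter sets.

ci_ladder <- c(50, 100, 230, 330, 420, 650, 1200, 1800)
five_temps <- c(15, 20, 25, 30, 35)

scout <- cultivar_params("Scout")
yitpi <- cultivar_params("Yitpi")

# Noiseless forward A-Ci curve for a parameter set at 25 degC.
make_curve <- function(params, ci = ci_ladder, Tleaf = 25, PPFD = 1500) {
  net_assimilation(data.frame(Ci = ci, Tleaf = Tleaf, PPFD = PPFD), params)
}

# A representative leaf state for isotope round-trip tests.
make_leaf_state <- function(A = 20, Rd = 1.25, E = 0.003, Ca = 400,
                            Ci = 280, GammaStar = 42.75, gt_ac = 0.4) {
  data.frame(A = A, Rd = Rd, E = E, Ca = Ca, Ci = Ci,
             GammaStar = GammaStar, gt_ac = gt_ac)
}

# Random physically plausible leaf states (seeded by the caller).
random_leaf_states <- function(n) {
  Ca <- runif(n, 300, 800)
  data.frame(
    A = runif(n, 5, 40),
    Rd = runif(n, 0.5, 2.5),
    E = runif(n, 0.001, 0.008),
    Ca = Ca,
    Ci = Ca * runif(n, 0.4, 0.85),
    GammaStar = runif(n, 35, 55),
    gt_ac = runif(n, 0.1, 0.8)
  )
}
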