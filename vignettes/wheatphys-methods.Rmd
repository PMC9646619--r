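---
title: "Models and methods behind wheatphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wheatphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatphys)
library(dplyr)
```

`wheatphys` analyses leaf gas exchange of wheat grown under elevated CO₂
(eCO₂) and short heat-stress cycles, and ships a calibrated synthetic
generator of the full factorial glasshouse experiment so that every
estimator can be exercised, end to end, against known truth. This vignette
explains the models, the numerical choices, what the generator does and
does not emulate, and the limits of what the passing checks demonstrate.

## The forward photosynthesis model

The FvCB model treats net assimilation as the minimum of two enzyme-limited
rates evaluated at the chloroplastic CO₂ mole fraction $C_c$:

$$A_c = \frac{V_{cmax}(C_c - \Gamma^*)}{C_c + K_c(1 + O/K_o)} - R_d,
\qquad
A_j = \frac{J}{4}\,\frac{C_c - \Gamma^*}{C_c + 2\Gamma^*} - R_d .$$

Electron transport $J$ follows the non-rectangular hyperbola light
response, the smaller root of
$\theta J^2 - (\alpha Q + J_{max})J + \alpha Q J_{max} = 0$, with curvature
$\theta = 0.85$ and apparent quantum yield $\alpha = 0.24$ — the customary
defaults of A-Cᵢ fitting tools, exposed as arguments.

Finite mesophyll conductance couples $C_c$ to the measured intercellular
CO₂ through $C_c = C_i - A/g_m$. Substituting this into either limited rate
gives a quadratic in $A$,

$$A^2 + A\,[R_d - V - g_m(C_i + K)] +
  g_m\,[V(C_i - \Gamma^*) - R_d(C_i + K)] = 0,$$

whose lower root is the physical solution (the upper root implies
$C_c > C_i$ for a photosynthesising leaf). With $g_m = \infty$ the code
switches to the exact $C_c = C_i$ closed form rather than a large-number
approximation. Ties between limitations are reported as Rubisco-limited,
and no smoothing hyperbola is applied between the two — the min rule keeps
the limitation switch identifiable. Triose-phosphate-utilisation
limitation is deliberately not modelled: the fits estimate only
$V_{cmax}$ and $J_{max}$.

### Temperature scaling

Each component carries its own temperature response, all anchored so the
rate at 25 °C equals the `*25` parameter exactly:

* $V_{cmax}$, $K_c$, $K_o$, $\Gamma^*$ — standard Arrhenius,
  $k(T_k) = k_{25}\exp[E_a(T_k-298)/(R\,298\,T_k)]$;
* $J_{max}$ — peaked Arrhenius with deactivation energy $H_d$ and entropy
  term $\Delta S$; $H_d$ is fixed at 200 kJ mol⁻¹ in fitting to avoid the
  well-known over-parametrisation of the three-constant deactivation term;
* $R_d$ — $Q_{10}$ scaling (an Arrhenius fit of respiration is also
  provided; on the same data the two agree to within the reported
  uncertainty of $Q_{10}$).

Kelvin conversion uses the offset 273, so 25 °C maps to exactly 298 K and
the Arrhenius exponent vanishes at the reference temperature; the same
offset is used everywhere, including the closed-form optimum

$$T_{opt} = \frac{H_d}{\Delta S - R\ln[E_a/(H_d - E_a)]} .$$

This convention matters at the 0.1 °C level: with 273.15 the Scout Jmax
optimum would shift by about −0.15 °C. The closed form is verified against
a 0.001 °C grid search of the peaked function in the test suite.

Rubisco kinetic constants are not something a gas-exchange experiment
measures; the package defaults to the Bernacchi tobacco in-vivo set
($K_{c25} = 404.9$ µbar, $K_{o25} = 278.4$ mbar, $\Gamma^*_{25} = 42.75$
µbar, with activation energies 79.43, 36.38 and 37.83 kJ mol⁻¹;
$O = 210$ mbar), the de-facto standard of A-Cᵢ fitting tools. Because
recovery tests generate and refit with the same constants, they validate
the estimator, not the constants. Gas mole fractions (µmol mol⁻¹) and
partial pressures (µbar) are treated as numerically equal at 1 bar total
pressure; `bernacchi_kinetics(pressure = )` rescales if needed.

## Mesophyll conductance from isotope discrimination

Observed discrimination is computed from the CO₂ concentration and δ¹³C of
air entering and leaving the chamber,
$\Delta_o = 1000\,\xi(\delta_{sam}-\delta_{ref}) /
[1000 + \delta_{sam} - \xi(\delta_{sam}-\delta_{ref})]$ with
$\xi = C_{ref}/(C_{ref}-C_{sam})$. The estimator compares $\Delta_o$
against the ternary-corrected infinite-$g_m$ prediction

$$\Delta_i = \frac{1}{1-t}\left[a' + \big((1+t)b - a'\big)
  \frac{C_i}{C_a}\right],$$

minus respiratory ($\Delta_e$) and photorespiratory ($\Delta_f$)
components, where $t = (1+a')E/(2g^t_{ac})$. Constants: diffusion through
air $a = 4.4$‰, boundary layer $a_b = 2.9$‰, carboxylation $b = 27.3$‰,
photorespiration $f = 11.6$‰, respiration $e = 0$ (null respiratory
fractionation) — all permil quantities stay in permil and are divided by
1000 only inside $(1 + a')$-type factors. Two design points were genuinely
open:

* **Liquid-phase fractionation $a_i$** enters the numerator but no single
  agreed value exists; the default is 1.8‰ (1.1 dissolution + 0.7 aqueous
  diffusion), exposed in `discrimination_constants()`.
* **The combined boundary-layer + stomata fractionation $a'$** requires
  leaf-surface CO₂, hence boundary-layer conductance. Both variants are
  implemented: `combined_a_prime()` computes the conductance-weighted
  value when $C_s$ is available, and the default $a' = a = 4.4$‰ is the
  large-boundary-layer-conductance limit appropriate for a well-stirred
  cuvette.

`predict_delta_obs()` is the exact algebraic inverse of
`gm_from_discrimination()`; their composition is tested to 1 part in
10¹⁰ over 1000 random leaf states, and with $t = 0$, $e = 0$ the estimator
collapses to the classical simple-form expression to 1 part in 10¹².
Estimation fails loudly (with the component breakdown) when the observed
discrimination is not below the infinite-$g_m$ prediction, rather than
returning a signed infinity.

## A-Cᵢ fitting

`fit_aci()` performs joint two-parameter least squares of
$(V_{cmax}, J_{max})$ on the $\min(A_c, A_j)$ surface over all points
simultaneously — not segmented per-limitation fitting — with measured
$R_d$ and $g_m$ held fixed. Reported estimates are valid at the curve's
leaf temperature (no normalisation to 25 °C); the kinetic constants are
still evaluated at that temperature. Numerical choices:

* Levenberg–Marquardt (`minpack.lm::nls.lm`) from
  $V_{cmax,0} = 100$, $J_{max,0} = 170$, with bounded restarts from half
  and double those values if the first attempt fails; box constraints
  $[1, 2000]$;
* convergence at $10^{-8}$ relative change in the residual sum of squares,
  at most 500 iterations;
* standard errors from the Gauss–Newton Jacobian at the optimum
  (asymptotic, and honest only when both limitations are represented —
  a one-limitation curve triggers a weak-identification warning);
* curves must span below 300 and above 600 µmol mol⁻¹ for both capacities
  to be identifiable, and need at least 5 points.

`fit_from_cc()` implements the alternative route: transform each point to
$C_c = C_i - A/g_m$, then fit with mesophyll resistance removed. On
synthetic curves generated with finite $g_m$ the two routes agree within
0.5%; they are exactly equal in the $g_m \to \infty$ limit. The default
(non-bilinear) fit method is recorded in the result object.

## Temperature-response fitting

Five fitters cover the measured responses at 15, 20, 25, 30 and 35 °C,
each exactly recovering its own noiseless forward model: Arrhenius
($V_{cmax}$, $R_d$), $Q_{10}$ in log space (an exact linear regression),
peaked Arrhenius for $J_{max}$ ($H_d$ fixed at 200 kJ mol⁻¹, $\Delta S$
bounded to [500, 800] J mol⁻¹ K⁻¹ to prevent parameter exchange with
$E_a$, starts at $k_{25,0}$ = the observed 25 °C value, $E_{a,0} = 40$,
$\Delta S_0 = 640$), the Asat parabola
$A_{opt} - b(T - T_{opt})^2$ (solved in closed form as re-parametrised
quadratic regression, with delta-method standard errors), and a plain
quadratic whose vertex is the reported optimum for conductances. Replicate
measurements at a temperature enter as individual points — no
pre-averaging — matching mean-with-standard-error reporting. A monotone
series pushes the peaked optimum to the boundary of the measured range and
is flagged rather than silently extrapolated. `build_table1()` assembles
the per-cultivar fits into one summary table, marking missing components
unavailable instead of failing.

The $Q_{10}$ fit uses all five temperatures. Fitted to
Arrhenius-generated respiration (the two models differ in shape), the
five-temperature $Q_{10}$ for the Scout constants comes out near 1.52 —
the small systematic offset from the Arrhenius truth is a property of the
model mismatch, not a fitting error.

## The synthetic experiment

`simulate_experiment()` emulates the design: 2 cultivars (Scout, Yitpi) ×
2 growth CO₂ (450, 650 µmol mol⁻¹) × 4 heat-stress regimes (control, a
vegetative-stage cycle HS1, a flowering-stage cycle HS2, both) × 5 time
points × 10 plants, minus the HS1-only cells at final harvest, which were
never harvested. All treatment effects are multiplicative and live in one
calibration object (`default_calibration()`):

* gas exchange: eCO₂ stimulates assimilation at growth CO₂ by ×1.21 and
  depresses it at the common 400 µmol mol⁻¹ reference by ×0.88 (stomatal
  conductance ×0.90), applied to an FvCB-computed cultivar baseline
  (Ca = 400, Cᵢ/Ca = 0.7, 25 °C, saturating light);
* capacities: eCO₂ growth reduces $V_{cmax}$ ×0.86 (Scout) / ×0.85
  (Yitpi) and leaves $J_{max}$ unchanged;
* traits: Yitpi/Scout ratios (e.g. ×1.42 biomass, ×2.30 tillers, ×3.54
  leaf area at anthesis), eCO₂ grain-number gains ×1.64 / ×1.50, a
  grain-nitrogen reduction ×0.82 in Yitpi only, and an interaction that
  divides the eCO₂ biomass/yield gain back out of heat-stressed cells —
  heat-stressed plants gain no yield from eCO₂;
* effects reported in the underlying experiment only as significance
  statements, without magnitude, default to multiplier 1 and are tagged
  `unquantified` in the calibration notes.

The treatment contrasts are encoded as multipliers around the FvCB
baseline rather than emerging from the mechanistic model, because the
generator's contract is exactness: with noise switched off, every
configured percent effect must be recovered exactly by the downstream
estimators, which a purely mechanistic generator cannot guarantee. The
FvCB model supplies the absolute scale and the A-Cᵢ and isotope stages,
which *are* mechanistic and round-trip through the real estimators.

Noise is multiplicative lognormal with unit mean
($\exp(\sigma Z - \sigma^2/2)$, $\sigma^2 = \log(1 + CV^2)$), defaulting
to CV 10% for traits and 5% for gas exchange — positive-valued
measurements with roughly constant coefficient of variation. The unit-mean
correction keeps configured multipliers equal to population means, so
percent-change estimates converge to the calibrated values.

Absolute baselines (grams per plant, tiller counts, leaf areas) are
plausible magnitudes for pot-grown wheat, chosen once and documented in
the calibration object as synthetic, non-measured values; checks against
them are generator self-consistency checks only. Each generator stage
draws from its own RNG sub-stream derived from the master seed by a
stable label hash, so adding a stage never shifts another stage's draws,
and the generators save and restore the caller's RNG state.

What the generator does **not** emulate: chamber effects and blocking
(pots were re-randomised continually, so the analysis treats the design
as fully randomised), phenology-driven time-point spacing, leaf energy
balance, instrument drift in the isotope line, and any covariance between
traits beyond the shared design factors. Passing recovery tests therefore
demonstrate estimator correctness under the calibrated data-generating
process, not field realism.

## Treatment-effect statistics

`percent_change()` reports $100(\bar{x}_{trt} - \bar{x}_{ref})/
\bar{x}_{ref}$ with a seeded bootstrap interval, resampling groups
independently. The default interval is **studentized** (percentile-t):
each resample's estimate is pivoted by its own delta-method standard
error of the ratio of means. The plain percentile interval is available
as an option but undercovers at glasshouse cell sizes (about 91–92%
empirical coverage at $n = 10$, CV 10%, against the studentized
interval's ≈95%); that comparison drove the default.

`factorial_anova()` is a thin, guarded wrapper around `stats::aov` with
all interactions: empty cells are named in the error, sequential sums of
squares are reported, and on the balanced designs the generator produces
all SS types coincide, so term order is immaterial (asserted in the
tests). Type-I error of every term is calibrated against the null
generator in the suite. No multiplicity correction is applied across
traits, matching common reporting practice in this literature; figure
stars map p < 0.05 / 0.01 / 0.001. Where two-group comparisons are needed
outside the ANOVA, Welch (unpooled) variances are the package's
recommendation.

`tukey_letters()` implements the studentized-range all-pairs test from
cell means, a pooled variance and its degrees of freedom, followed by the
insert–absorb compact-letter-display algorithm; unbalanced designs should
pass the harmonic mean cell size. The letters are verified against a
brute-force all-pairs `ptukey` oracle.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → estimate-gm → fit-aci → fit-temp →
effects → report, writes every table as CSV, and emits a JSON manifest
containing the seed, package version, calibration hash and per-file
checksums. Re-running with the same configuration reproduces every output
byte-identically; the suite asserts this, and asserts that no stage reads
entropy outside the configured seed. By default the A-Cᵢ fitting stage
fits two curves per treatment cell (the fits are the only slow stage);
`n_aci_fits` raises that. The problem sizes used by the shipped checks —
1000 plants per cell for effect recovery, 2000 simulations for the ANOVA
null calibration, 1000 replicates for bootstrap coverage, 200 noisy curves
for A-Cᵢ recovery — were chosen to pin Monte Carlo error well below the
tolerances being asserted.

## Known limitations

* C₄ photosynthesis, TPU limitation, stomatal-optimisation models and
  leaf energy balance are out of scope.
* $g_m$ and $R_d$ are inputs to the A-Cᵢ fit, never co-fitted; curves
  lacking high-CO₂ points leave $J_{max}$ unidentifiable (flagged).
* The temperature-acclimation question — whether optima shift with growth
  temperature — is not modelled; fitted optima describe the measured
  range only.
* Asymptotic (Jacobian-based) standard errors are reported for nonlinear
  fits; they are approximate at five-point sample sizes, which is why the
  suite checks interval calibration by simulation where it matters.
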