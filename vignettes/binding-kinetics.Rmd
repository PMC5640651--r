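---
title: "Biosensor binding kinetics with bindkin: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biosensor binding kinetics with bindkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindkin)
```

## The measurement and the model

A resonant-mirror or SPR biosensor reports an angular response
(arcsec here) proportional to the mass bound at a functionalised
surface. An experiment alternates association phases — soluble analyte
at concentration $C$ binding immobilised receptor — and dissociation
phases after the analyte is washed out. For a reversible 1:1
interaction with the analyte in large excess over surface sites
(pseudo-first-order conditions), the occupancy relaxes
mono-exponentially and the response follows

$$R_t = (R_{eq} - R_0)\,\bigl(1 - e^{-k_{on} t}\bigr) + R_0,
  \qquad k_{on} = k_{ass}\,C + k_{diss},$$

so the *observed* rate $k_{on}$ is affine in $C$: regressing fitted
$k_{on}$ values against concentration over a titration gives
$k_{ass}$ (slope) and $k_{diss}$ (intercept). The equilibrium constant
is obtained by two independent routes that should agree when the 1:1
model holds:

- **kinetic ratio**: $K_D = k_{diss}/k_{ass}$;
- **extent of binding**: the plateau responses follow the rectangular
  hyperbola $R_{eq} = R_{max}\,(C/K_D)/(1 + C/K_D)$, fitted by
  nonlinear least squares.

Dissociation phases decay as $R_t = A\,e^{-k_{diss} t}$, optionally
with a constant offset for incomplete wash-out.

Key assumptions: instantaneous, well-mixed injection; no
mass-transport limitation (experimentally suppressed by fast
stirring); a homogeneous receptor population binding one analyte
molecule per site; signal strictly proportional to bound mass.
Deviations from any of these typically surface as biphasic kinetics,
which is why every curve is also fitted bi-exponentially and the extra
component is admitted only if a nested F-test at 95% confidence says
it significantly improves the fit:

$$F = \frac{(SSR_{mono} - SSR_{bi})/(p_{bi} - p_{mono})}
          {SSR_{bi}/(n - p_{bi})}.$$

A tie at the threshold keeps the mono model (parsimony); a negative
improvement clamps $F$ at 0.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `noise_sd` | 0.5 | arcsec | instrument class has short-term noise below 1 arcsec; 0.5 is a representative mid-band value |
| `sampling_interval` | 0.4 | s | typical acquisition rate of cuvette instruments |
| `association_window` | 360 | s | the standard 6-minute accumulation interval |
| `dissociation_window` | 600 | s | long enough to resolve $k_{diss}$ down to ~1e-3 s⁻¹ |
| concentration grid | 6 points, 16–600 nM, log-spaced | M | the standard titration for the reference system; spans ~0.26–9.8 × $K_D$, bracketing the isotherm |
| `confidence` | 0.95 | — | conventional F-test level for admitting a second exponential |
| rate bounds | [1e-6, 10] | s⁻¹ | physically plausible band for this instrument's time resolution and window lengths |
| `response_per_density` | 600 | arcsec/(ng/mm²) | chosen so a 750 arcsec immobilisation shift maps to 1.25 ng/mm², the midpoint of the quoted density band |
| `layer_thickness` | 132 | nm | chosen so 1.25 ng/mm² corresponds to ~9.5 mg/mL in the sensing layer, inside the quoted 9–10 mg/mL |
| `receptor_mass` | 161 | kDa | see "Surface bookkeeping" below |
| `temperature` | 37 | °C | metadata only; no temperature dependence is modelled |

Seeds are always explicit arguments; simulating with noise and no seed
is an error, and no function leaves the global RNG state altered.

## What the simulator emulates — and what it does not

`simulate_association()` / `simulate_dissociation()` produce the exact
closed-form kinetics above plus i.i.d. Gaussian noise per sample and an
optional linear baseline drift (default 0). That reproduces the
statistical structure the fitting stage assumes: homoscedastic,
uncorrelated noise around a mono-exponential mean. Real sensorgrams
additionally contain bulk refractive-index jumps at injection,
regeneration artefacts, slow receptor decay, correlated (1/f) noise
and, at high capture density, mass-transport limitation — none of which
are simulated. A green recovery test therefore establishes that the
inference chain is correct *under the stated model*, not that the
model is adequate for any particular instrument record; on real data
the residual diagnostics (`tail_mean_residual`, the F-test verdict,
the `poorly_constrained` and `negative_intercept` flags) are the
guards.

## Numerical choices

- **Optimiser.** All curve fits use bounded Gauss–Newton
  (`nls`, port algorithm) with relative tolerance 1e-10 and
  deterministic jittered restarts (×1, ×0.4, ×2.5, ×0.1 on the start
  vector). "False convergence" at that tolerance — the optimiser
  stalled at the optimum's numerical resolution — is accepted as a
  fallback when no strictly converged solution exists.
- **Starts.** $R_0$ ← first sample; $R_{eq}$ ← mean of the last decile;
  $k_{on}$ ← reciprocal of the first 63%-amplitude crossing time (the
  log-free analogue of the exponential time constant). The bi fit is
  seeded from the mono solution with the rate split ×0.3 / ×3.
- **Nested dominance by construction.** If no bi-exponential start
  beats the mono solution, the mono fit is embedded (one amplitude
  zero) and flagged `degenerate`, guaranteeing
  $SSR_{bi} \le SSR_{mono}$ and a well-defined F statistic.
- **Identifiability guards.** Flat association or dissociation traces
  (amplitude within 3 estimated noise SDs of zero) raise an
  unidentifiable-rate error rather than returning a boundary rate; an
  increasing "dissociation" trace is rejected as wrong-phase.
- **Error propagation** on ratios is first-order relative-error
  quadrature, $sd_{K_D} = K_D\sqrt{(sd_a/k_{ass})^2 +
  (sd_d/k_{diss})^2}$. The test suite cross-checks it against a
  10,000-draw Monte-Carlo oracle on every reference-table row (it
  agrees within 10% whenever relative errors are ≲20%, the regime of
  all published rows).
- **Negative regression intercepts** ($k_{diss} < 0$ is unphysical)
  are reported with a `negative_intercept` flag, never clamped:
  clamping at zero would bias the kinetic-route $K_D$ downward.
- **Competition dynamics.** The two-ligand one-site system
  $$\dot\theta_A = k_{ass,A} C_A (1 - \theta_A - \theta_C)
    - k_{diss,A}\theta_A$$
  (and symmetrically for the competitor) is *linear* with constant
  coefficients within each phase, so it is solved exactly by
  eigendecomposition of the 2×2 rate matrix rather than by a numerical
  integrator — an exactness upgrade over an adaptive-tolerance ODE
  solver; a fixed-step RK4 backs up the measure-zero defective case,
  and the suite cross-checks the two routes. The instrument signal is
  mass-weighted, $R = \mathrm{capacity}\cdot(\theta_A + (m_C/m_A)\,
  \theta_C)$, so a light competitor (an 11-mer peptide, ~1.1 kDa,
  versus a ~16 kDa protein analyte) contributes little signal even at
  high occupancy.

## Design decisions where the ground truth is open

- **Unweighted least squares** throughout (curve fits, $k_{on}$
  regression, isotherm) because the simulated noise is homoscedastic;
  `weighted = TRUE` switches to $1/se^2$ weights where measurement
  errors differ per point.
- **Extent of binding** is taken as the *fitted* $R_{eq}$ of each
  association curve, not the last-sample plateau: at the lowest
  concentrations ($k_{on}\,T \approx 3$) the curve has not fully
  plateaued, and the fitted asymptote is the estimator consistent with
  the model.
- **Surface bookkeeping.** The quoted pairing of the immobilisation
  band (700–800 arcsec ↔ 1.20–1.30 ng/mm² ↔ 9–10 mg/mL ↔ 59 µM
  receptor) is internally consistent only for a receptor mass of
  ~161 kDa, not the nominal ~100 kDa monomer (9.5 mg/mL ÷ 59 µM ≈
  161 kg/mol — plausibly a glycosylated/tagged dimer-equivalent
  effective mass). `surface_calibration()` therefore defaults to
  161 kDa but exposes `receptor_mass` explicitly; no conversion
  hard-codes either figure. Note also that no single linear response
  calibration maps *both* band endpoints exactly (the arcsec band is
  wider in relative terms than the density band); the default maps the
  midpoint exactly and the bands overlap.
- **Competition protocol timings** (pre-saturation 600 s, observation
  360 s, analyte 600 nM) are a calibration choice — the published
  assay does not state them. Under these defaults a 100 µM
  pre-saturation with the interface peptide ($K_D \approx 1.4\,\mu$M,
  i.e. ~70 × $K_D$) blocks ~90% of the analyte's equilibrium-phase
  rise, more than the ~50% reported for the wet assay; shorter
  pre-incubation, analyte-phase wash-out of the competitor, or
  partial-overlap epitopes would all lower the simulated blockade.
  The package treats the printed 50% as a qualitative reference
  ("largely prevented"), and the tests assert the properties that are
  timing-independent: zero reduction for a null competitor, complete
  blockade for an irreversible saturating one, monotonicity in
  competitor concentration, and a substantial reduction at 100 µM.
- **"Nearly N-fold" claims** are checked as round-to-nearest-integer
  of the computed ratio (4.8e-7/6.1e-8 → 7.87 → 8; 2.6e-6/6.1e-8 →
  42.6 → 43), the convention that reproduces both published phrasings.
- **Per-curve fitting only.** Global (multi-curve simultaneous)
  fitting is not implemented: the analysis route specified is
  per-curve fits followed by the $k_{on}$ regression, and a global
  scheme would need design choices (shared parameters, weighting) the
  source procedure does not pin down.

## Known limitations

- The 1:1 pseudo-first-order model ignores analyte depletion in the
  cuvette; at very high capacity and low concentration the effective
  $C$ falls during association.
- Rate constants outside [1e-6, 10] s⁻¹ are not estimable by design;
  interactions faster than the sampling rate alias into the bounds and
  are flagged `rate_at_bound`.
- The quadrature error propagation is first-order; for relative errors
  above ~30% (not reached by any reference row) the ratio distribution
  skews and a Monte-Carlo interval should be preferred.
- The scrambled-peptide control carries only an equilibrium constant
  in the reference tables (no kinetic constants), so it participates
  in no ratio consistency check.
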