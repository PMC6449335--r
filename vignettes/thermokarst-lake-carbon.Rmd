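---
title: "Estimating lake carbon emission from chamber records: models, QC and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lake carbon emission from chamber records: models, QC and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thawflux)
```

## The problem

Shallow thermokarst lakes — formed where ice-rich permafrost thaws and the
ground collapses — are hotspots of carbon evasion: thawed peat is mineralized
in their sediments and water column and leaves as CO2 and CH4. Quantifying
that evasion for a whole permafrost region requires chaining several
estimation steps, each with its own conventions and failure modes:

1. convert floating-chamber CO2 records into areal fluxes, with explicit
   quality control;
2. convert dissolved CH4 concentrations into diffusive fluxes via a gas
   transfer velocity;
3. average chambers per lake, seasons per year, and annualize by the
   ice-free season length;
4. upscale the mean areal emission to a region with propagated uncertainty;
5. compare chamber-based fluxes against wind-model fluxes.

`thawflux` implements this chain as small, composable functions plus a
synthetic campaign generator with known ground truth, so every stage — and
the pipeline end to end — is testable without any field data.

## Physical-chemistry kernel

**Solubility.** Dissolved concentrations follow Henry's law,
`C = K_H(T) * p`, with the partial pressure taken as mixing ratio times the
*measured* barometric pressure (never assumed 1 atm). For CO2 we evaluate
the classic zero-salinity Weiss-type fit; for CH4 the Wiesenburg-Guinasso
Bunsen-coefficient fit divided by the STP molar volume. The survey never
names its solubility functions, so these community defaults live in a single
constants table (`flux_constants()`) and can be overridden, including from a
YAML file.

**Schmidt scaling.** Transfer velocities are exchanged between gases and
temperatures through the Schmidt-number convention
`k = k600 (Sc/600)^n`, with freshwater fourth-order `Sc(T)` polynomials
(CO2 at 20 °C evaluates to ≈600, anchoring the convention). The exponent
defaults to n = −1/2 (wavy, wind-mixed surfaces, the usual lake choice) and
can be set to −2/3 for smooth surfaces.

**Wind models.** Two published k600 parameterizations are provided
(in cm h⁻¹, converted to the canonical m d⁻¹ on rescaling):

- Cole & Caraco: `k600 = 2.07 + 0.215 · U10^1.7`
- Vachon & Prairie: `k600 = 2.51 + 1.48 · U10 + 0.39 · U10 · log10(LA)`,
  LA in km².

**Flux.** `F = k (C_water − C_eq) · 12.01` g C m⁻² d⁻¹; positive is outward.
Both gases carry one carbon atom per molecule, so fluxes add directly in
carbon units.

Unit canon: velocities in m d⁻¹, fluxes in g C m⁻² d⁻¹, concentrations in
mol m⁻³, annual emissions in kg C m⁻² yr⁻¹, regional totals in Tg C yr⁻¹.
Wind-model outputs are converted from cm h⁻¹ immediately on rescaling, so no
mixed-unit quantity crosses a module boundary.

## Chamber fluxes and quality control

Chamber CO2 records (300 s cadence) are fit by ordinary least squares over
the first 1–2.5 h; the default window is the longest available stretch up to
2.5 h, configurable per call. The slope converts to a flux through the ideal
gas law, `F = slope · 10⁻⁶ · P/(R·T) · (V/A) · 12.01 · 86400`; the
volume-to-footprint ratio `V/A` scales the flux linearly and is therefore a
required input (the fixture geometry uses V/A = 0.15 m on a 31 cm chamber).

QC follows the chamber protocol's retention rules:

- positive slopes with r² > 0.75 are retained as linear accumulation (the
  nominal rule is stated as r² ≥ 0.76 retained / r² ≤ 0.75 referred to the
  replicate rule; values inside the open gap (0.75, 0.76) are routed to the
  stricter linear branch);
- weaker positive slopes are retained only if the mean r² across the
  lake-season's replicate chambers is ≥ 0.55 ("average r² between the
  replicates", read as the mean over all chamber fits of that visit),
  otherwise discarded as nonlinear;
- persistent decreases are interpreted as CO2 uptake and retained only when
  the lake's water pCO2 is close to or below the atmospheric equilibrium of
  404.2 ppmv. "Close to" is unquantified in the protocol; we make it an
  explicit tolerance parameter, default 5% (≤ 424.4 ppmv), surfaced in the
  constants table.

A zero-variance chamber record gets r² = 0 (not NaN) so degenerate series
fail QC cleanly. Every verdict, with its fit diagnostics, is kept in the
per-chamber output table — QC is auditable, never silent.

**CH4 transfer velocity.** The protocol does not state where the CH4
velocity comes from. Default: invert the flux equation on the lake-season's
mean retained CO2 flux to get a chamber-derived k_CO2 (guarded by a minimum
disequilibrium of 5×10⁻⁴ mol m⁻³ — near equilibrium the inversion is
ill-posed and flagged instead), then rescale by `(Sc_CH4/Sc_CO2)^(−1/2)`.
When no usable chamber velocity exists, the Cole & Caraco wind model is the
fallback; the source actually used is recorded per lake-season.

## Aggregation, annualization, upscaling

Chambers are averaged per lake-season with an unweighted arithmetic mean
(that is how the protocol words it; no inverse-variance weighting), CH4 is
added, and the annual emission is the unweighted mean of the available
seasonal campaigns times the lake's ice-free days. Equal season weights are
the simplest reading of "mean daily flux"; a season-length weighting would
be a different estimand and is deliberately not the default. Net-uptake
lakes keep their negative annual emission — uptake measurements were
retained, so truncation at zero would bias the regional mean upward.

Dispersion is reported as mean ± IQR throughout (skewed data), with
quantiles by linear interpolation (`stats::quantile` type 7) — documented
because the IQR is itself a reported output, and different quantile
definitions change it.

Regional totals multiply the region area by the lake coverage fraction
(default 6%, with 3%/9% sensitivity scenarios) and the pooled mean annual
emission over all lakes (not zone-weighted; a zone-weighted pooling can be
had by summarizing zones first). Uncertainty follows the product rule for
relative errors, `δR = |R|·sqrt((δx/x)² + (δy/y)²)`, default 15% on each
factor. CO2-equivalents use GWP₁₀₀ = 28 for CH4.

## What the synthetic generator emulates

The generator reproduces the design of a pan-regional survey: 76 lakes in
four permafrost zones (isolated 20, sporadic 22, discontinuous 18,
continuous 16), three seasonal campaigns, lake areas log-uniform on
115–1,237,000 m², shallow depths (mean 0.8 m, IQR 0.7 m), supersaturated
gases (pCO2 mean 1044, IQR 554 ppmv; pCH4 mean 20.4, IQR 21.8 ppmv), DOC
15.7 ± 7.7 mg L⁻¹, chambers logging every 300 s for 2.5 h, 2–6 chambers per
lake, logger noise σ = 5 ppm.

Distributional choices:

- Skewed positive variables are lognormal with (meanlog, sdlog) solved
  numerically from the configured mean and IQR. A lognormal can only reach
  IQR/mean ≈ 0.887; requests beyond that are a configuration error rather
  than a silent approximation.
- pCH4's configured moments (IQR/mean ≈ 1.07) exceed that bound, so pCH4 is
  drawn as the 1.8 ppmv atmospheric equilibrium plus a gamma-distributed
  excess, moment-matched on the mean/IQR of the excess. This both fits the
  heavier tail and guarantees every lake is CH4-supersaturated, as observed.
- Zone emission multipliers (0.75 south / 1.30 north by default) scale the
  gas draws; combined with shorter northern ice-free seasons
  (170/165/155/150 days south→north, a configurable stand-in for field
  observations) they put the north:south annual-emission contrast in the
  2–3× range.

**Ground truth.** Each lake-season's true transfer velocity is the
Cole & Caraco k600 at its zone-season wind times a configurable
`chamber_k_inflation` (default 3): chamber-measured fluxes are commonly
several-fold above wind-model fluxes for small sheltered lakes, and making
the factor a simulator knob lets the comparison stage demonstrate it can
*recover* such a discrepancy — it is not a physical claim. True fluxes
follow from the package's own forward physics; chamber slopes are the exact
algebraic inverse of the flux conversion, so zero-noise recovery is exact by
construction and any pipeline regression is attributable.

**Within-lake heterogeneity.** Chambers along a shore-to-center transect do
not see identical fluxes. Each chamber's true flux is the lake-season truth
times a lognormal factor with mean 1 and CV 20% — a documented guess, not a
surveyed value. Recovery tests therefore compare fitted fluxes against the
*chamber-level* truth (what each chamber actually sampled); the difference
between a finite chamber mean and the lake-wide truth is sampling design,
not estimation error.

**Contamination.** 13% of lake-seasons get saturating chamber curves
(exponential approach with τ = 600 s, the physically expected shape of a
headspace nearing equilibrium), tuned so a linear fit yields r² ≈ 0.3–0.5.
Contamination is drawn per lake-season, not per chamber: disturbed
deployments (wind chop, a leaking seal re-seated across replicates) affect
the whole visit, and the replicate-average QC rule can only reject
measurements when low-r² curves cluster within a lake. With independent
per-chamber contamination a single bad chamber among clean replicates would
always be rescued by the replicate mean and the discard rate would collapse
to zero.

What the generator does **not** emulate: spatial autocorrelation between
lakes, storage-and-release seasonality mechanisms, ebullition, drifting
chamber turbulence artifacts, or real wind fields (one station per
zone-season, gamma-distributed around 3 m s⁻¹). Passing recovery tests show
the estimation chain is consistent and unit-correct under the emulated
design; they do not validate the physics against real lakes.

## Numerical choices and degenerate inputs

- OLS via `stats::lm`; the test suite cross-checks slope, intercept and r²
  against an independent closed-form sums-of-squares oracle at 10⁻¹⁰.
- Moment matching solves 1-D root problems with `uniroot` at tolerance
  10⁻¹²; the gamma match uses the large-shape branch of the bimodal
  IQR/mean curve (better-behaved densities).
- All generation flows from one config seed through sub-seeds per stage
  (lakes, winds, chambers); the caller's RNG state is saved and restored.
- Near-equilibrium lakes: chamber-derived k is undefined below the
  disequilibrium floor, flagged, and the CH4 stage falls back to the wind
  model rather than dividing by ≈0.
- Lake-seasons with zero retained chambers are *missing*, not zero, and are
  dropped (with a message) from annualization.
- The CH4 share of annual emission is undefined (`NA`) for net-uptake lakes
  rather than a number outside [0, 100].

## Problem sizes used by the test suite

The default validation campaign is one seed of the full design: 76 lakes,
228 lake-seasons, ~900 chambers (~28,000 logger readings); it simulates and
analyzes in a few seconds. Unit and property tests use an 8-lake campaign.
The shipped fixture campaign (4 lakes × 3 seasons × 1 chamber) exists so
file-format tests do not depend on the generator.

## Known limitations

- Diffusive CH4 only; ebullition can exceed diffusion severalfold in
  thermokarst lakes and is out of scope here.
- No salinity corrections (fresh waters) and no chemically enhanced CO2
  exchange at high pH.
- The chamber-vs-wind-model comparison inherits whatever wind record it is
  given; distant stations (20–70 km) are a real caveat the package records
  (`station_distance_km`) but does not correct for.
- Linear chamber fits only; a nonlinear (saturating) chamber model is a
  deliberate non-goal — saturating records are *rejected*, not refit.
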