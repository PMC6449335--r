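# thawflux

Carbon emission estimation for shallow thermokarst lakes: from floating-chamber
CO2 records and dissolved CH4 concentrations to quality-controlled daily
fluxes, annual per-lake emissions, and regional totals with propagated
uncertainty.

## Who this is for

Limnologists and biogeochemists running (or re-analyzing) chamber-based lake
flux campaigns across permafrost gradients, who need the whole estimation
chain — slope fitting, QC, gas-exchange physics, annualization, upscaling —
reproducible, auditable and testable, rather than scattered across ad-hoc
scripts.

## What it computes

**Chamber fluxes.** The CO2 accumulation rate in each floating chamber is fit
by OLS over the first 1–2.5 h and converted to an areal flux with the ideal
gas law:

    F = slope · 1e-6 · P/(R·T) · (V/A) · 12.01 · 86400   [g C m⁻² d⁻¹]

QC retains linear accumulations (r² > 0.75), rescues weaker fits when the
replicate-mean r² ≥ 0.55, and keeps apparent CO2 uptake only when the lake's
water pCO2 is close to or below the 404.2 ppmv atmospheric equilibrium.

**Diffusive CH4 flux.** `F = k·(C_water − C_eq)·12.01`, with C from Henry's
law at the measured pressure and k obtained by Schmidt-rescaling
(`k = k600·(Sc/600)^(−1/2)`) of either the lake's chamber-derived CO2
transfer velocity (default) or a wind-model k600.

**Wind models.** Cole & Caraco `k600 = 2.07 + 0.215·U10^1.7` and
Vachon & Prairie `k600 = 2.51 + 1.48·U10 + 0.39·U10·log10(LA)` (cm h⁻¹),
plus a comparison stage quantifying how far chamber fluxes sit above
wind-model fluxes.

**Aggregation.** Chamber means per lake-season → seasonal means × ice-free
days → annual emission (kg C m⁻² yr⁻¹); mean ± IQR summaries per permafrost
zone; CO2-equivalents (GWP₁₀₀ = 28); regional upscaling
`R = area × lake fraction × mean emission` with
`δR = |R|·sqrt((δx/x)² + (δy/y)²)`.

**Synthetic campaigns.** `simulate_campaign()` generates a full survey — 76
lakes in four permafrost zones, three seasons, 2–6 chambers per lake at 300 s
cadence — with known ground truth at every level, so the pipeline validates
end to end without field data.

## Worked example

```r
library(thawflux)

camp <- simulate_campaign(campaign_config(seed = 1))
res  <- run_pipeline(camp)

print(res$zone_summary, digits = 3)
#>            zone mean_annual_c iqr_annual_c  n
#> 1      isolated        0.0791       0.0534 20
#> 2      sporadic        0.0598       0.0508 22
#> 3 discontinuous        0.1512       0.0536 18
#> 4    continuous        0.1400       0.0616 16
#> 5       overall        0.1034       0.0876 76
```

The northern, permafrost-rich zones emit roughly twice what the southern
zones do (annual emission in kg C m⁻² yr⁻¹, mean ± IQR over lakes) — the
contrast the generator is configured to produce. Continuing:

```r
res$pooled
#> pooled annual emission: 0.103 +/- 0.088 kg C m-2 yr-1 (n = 76)

res$regional[res$regional$name == "coverage_6pct", c("total_tg_yr", "uncertainty_tg_yr")]
#> regional total at 6% coverage: 8.1 +/- 1.7 Tg C yr-1

res$wind_comparison$cole_caraco$comparison$co2$mean_ratio
#> 2.99   # chamber fluxes ~3x the wind-model fluxes, the configured inflation

sum(startsWith(res$chamber_fits$qc_verdict, "discarded")) / nrow(res$chamber_fits)
#> 0.163  # QC discard rate, tracking the 13% configured contamination
```

A single chamber record goes through the same functions directly:

```r
t <- seq(0, 9000, by = 300)                       # 2.5 h at 300 s cadence
f <- fit_accumulation(t, 404 + 0.012 * t)         # slope 0.0120 ppm/s, r2 1.00
slope_to_flux(f$slope_ppm_s, volume_m3 = 0.0113,
              area_m2 = 0.0755, air_temp_c = 15, pressure_kpa = 101.3)
#> 0.0788  # g C m-2 d-1
```

Campaigns round-trip through plain TSV (`write_campaign()` /
`read_campaign()`), and `inst/scripts/thawflux-cli.R` exposes the stages as
shell subcommands (`simulate`, `chamber-fit`, `fluxes`, `annualize`,
`upscale`, `compare-k`, `report`).

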