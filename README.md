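# VegRestore

Quantifying the effectiveness of large-scale vegetation restoration —
and attributing it to its drivers — from annual raster time series.

`VegRestore` is an R package for landscape-ecology studies that ask two
questions about a restoration program: *did vegetation recover, where,
and by how much relative to a baseline period?* and *which climatic,
soil, topographic, socioeconomic and engineering factors explain the
spatial pattern of that recovery?* It targets workflows built on
annual NDVI and NPP grids over a region tessellated into evaluation
units ("counties").

## The method in brief

1. **Composite index.** FVC from NDVI by the dimidiate pixel model,
   `FVC = (NDVI − NDVI_soil)/(NDVI_veg − NDVI_soil)`; FVC and NPP
   min–max normalized (globally over all years and pixels) and
   averaged with equal weights on a percentage scale,
   `VQQI = (N_FVC + N_NPP)/2 × 100%`.
2. **Trend grading.** Per-pixel OLS slope of VQQI on year with an
   F test; five grades with weights ω = (2, 1, 0, −1, −2) from
   extremely significant improvement (slope > 0, p < 0.01) to
   extremely significant degradation (slope < 0, p < 0.01).
3. **Effectiveness.** Per county, grade area fractions A_k, net change
   `N_t = Σ ω_k A_k ∈ [−2, 2]`; baseline N₀ = cross-county mean of the
   first-period net change; effectiveness `E_t = N_t / N₀`, classed
   degraded (E_t ≤ 0), recovered-below-baseline (0 < E_t ≤ 1) or
   significantly recovered (E_t > 1).
4. **Attribution.** Geodetector factor detector
   `q = 1 − Σ N_h σ_h² / (N σ²)` over natural-breaks strata (exact
   Fisher dynamic program), with noncentral-F significance; main
   factors = top-50% q that pass p < 0.05; interaction detector on the
   cross-classification; risk detector for the most favorable factor
   range.
5. **Series diagnostics.** Regional annual mean VQQI with OLS trend
   and a Pettitt change-point year.

A seeded synthetic-scenario generator produces every input (annual
NDVI/NPP stacks with injected trends and a step change, county maps,
land-use epochs with exact transition bookkeeping, afforestation
records, and factor stratifications with *designed* q values), so the
entire pipeline is testable against known ground truth.

## Worked example

```r
library(VegRestore)
cfg <- scenarioConfig(seed = 1)       # 81 counties, 2000-2020
res <- runPipeline(cfg, outDir = "run1")

res$series
#> AnnualSeries 2000-2020: mean 48.073, slope 0.5365/yr (p = 6.05e-14)
#>   change point: 2010 (p = 0.00113)
```

The regional VQQI series rises by about 0.54 percentage points per
year (highly significant) with a regime shift detected at the
2010/2011 boundary — the scenario injects an abrupt gain in 2011 on
top of the trend.

```r
subset(res$summary, scope == "all" & period == "2000-2020")
#>   scope    period           class areaFraction nUnits
#>     all 2000-2020        degraded   0.20987654     17
#>     all 2000-2020 not-significant   0.02469136      2
#>     all 2000-2020     significant   0.76543210     62
```

62 of 81 counties (76.5% of the area) end the study period
significantly above the 2000–2010 baseline; 17 counties degraded.

```r
head(res$mainFactors, 3)
#>                  factor         q            p
#>    annual_precipitation 0.7500094 6.008845e-10
#>                     gdp 0.6132590 5.564957e-10
#>   farmland_to_grassland 0.5634314 2.433409e-09
res$risk
#> RiskDetection 'annual_precipitation': max mean response in stratum 7
#>   (values 6.7399..7.18917)
res$interactions[["annual_precipitation x gdp"]]
#> Interaction annual_precipitation ∩ gdp: q = 0.9551
#>   (single: 0.7500, 0.6133) -> enhance-bivariate
```

The detector recovers the designed factor ranking (precipitation
dominant with q = 0.75), selects exactly the seven factors in the
designed top half, finds the wettest stratum most favorable to
restoration, and classifies the precipitation × GDP interaction as a
bivariate enhancement.

`runPipeline(..., outDir = )` also writes every product to disk:
per-year VQQI rasters (plain-text ESRI ASCII grids), the effectiveness
and area-summary CSVs, factor detections, interactions, a JSON report
and a manifest with content hashes — reruns of the same configuration
are bit-identical.

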