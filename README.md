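# agbird

Landscape-scale analysis of the spatial relationship between forest
above-ground biomass (AGB) and bird species richness, for spatial ecologists
and conservation remote-sensing practitioners asking whether carbon-dense
forest and biodiversity-rich forest are the *same* forest.

The package implements the full chain as tested, reusable R functions:

* **SAR preprocessing** — digital numbers to sigma-nought via
  σ⁰ = 10·log₁₀(DN²) + CF (CF = −83 dB), Lee speckle filtering, and the
  radar forest degradation index RFDI = (HH − HV)/(HH + HV) on linear power;
* **GLCM texture** — the eight Haralick features (mean, variance,
  homogeneity, contrast, dissimilarity, entropy, second moment, correlation)
  plus first-order window statistics over moving windows, in compiled code
  with an exact R-level reference implementation;
* **AGB modelling** — DBH-only allometric plot AGB, deterministic
  r ≥ 0.75 correlation screening, log-log (power-law) regression
  ln(AGB) = a + b·ln(X), random-forest regression with ten-fold
  cross-validation (r, RMSE, MAE, %bias), wall-to-wall prediction and
  kernel-correlation fusion of the local map with a global 1-km product;
* **Richness mapping** — species range polygons rasterised into a
  presence–absence matrix on a 1-km grid, with IUCN-listed and endemic
  richness strata;
* **Richness drivers** — smoother-R² variable importance (loess vs the
  intercept-only null, rescaled to 0–100), radial-kernel support vector
  regression with seeded cross-validated tuning, partial-dependence curves,
  correlation-based effect directions;
* **Spatial congruence** — Getis-Ord Gi* hot/coldspot z-scores, class maps
  with a high-AGB mask (>180 Mg ha⁻¹), percent area overlap under four
  denominator conventions, and Dutilleul-style correlation tests with an
  effective sample size estimated from the fields' spatial autocovariance;
* **A synthetic-landscape generator** (`sceneConfig()`, `generateScene()`)
  producing a fully self-consistent study area — terrain, land cover, roads,
  AGB truth, speckled dual-pol SAR whose texture encodes AGB past the
  ~100 Mg ha⁻¹ saturation level, field plots whose DBH lists invert the
  allometry exactly, a degraded global AGB map, and species ranges with
  *known* habitat-effect weights — so every stage is verifiable by parameter
  recovery without downloading anything.

Rasters are exchanged as plain-text ESRI ASCII grids (`.asc`, with a small
JSON sidecar carrying the CRS id), vectors as GeoJSON, tables as CSV.

## A worked example

Run the whole synthetic study end to end (about two minutes):

```r
library(agbird)
cfg <- runConfig(seed = 1, outDir = "run1")   # 30 x 30 km scene, 36 plots
runAll(cfg)

fit <- jsonlite::read_json("run1/agb_fit.json", simplifyVector = TRUE)
fit$cvMetrics
#> $r        0.8324895
#> $rmse     32.21801
#> $mae      25.31574
#> $pctBias  1.534692
```

The ten-fold cross-validated AGB model recovers the synthetic truth with
r ≈ 0.83 and RMSE ≈ 32 Mg ha⁻¹ from 36 plots — SAR texture carries the
biomass signal well past backscatter saturation, at the accuracy level
texture-based AGB studies typically report. The driver table confirms the
planted effects:

```r
head(read.csv("run1/importance_iucn.csv"), 3)
#>   predictor     score     rawR2
#> 1       agb 100.00000 0.7333692
#> 2      rfdi  95.78869 0.7024847
#> 3 roadDistance 82.24755 0.6031782
```

AGB ranks first (RFDI is itself an AGB-linked radar index) and road
distance third — exactly the structure the generator planted. The
congruence report gives the headline overlap and correlation numbers:

```r
rep <- jsonlite::read_json("run1/congruence_report.json", simplifyVector = TRUE)
subset(rep$overlaps, denominator == "union" & class == "HOT")
rep$correlations
#>          pair         r effectiveDf        t            p   n
#> 1    agb-iucn 0.8056239    30.90798 7.560189 1.633001e-08 900
#> 2 agb-endemic 0.7978477    31.53855 7.432333 2.034044e-08 900
```

Note the effective degrees of freedom: 900 one-km cells shrink to ~31
independent observations once spatial autocorrelation is accounted for —
the reason naive correlation p-values overstate congruence significance.

Individual stages are available as plain functions (`calibrateSigma0()`,
`textureStack()`, `rfFit()`, `buildPam()`, `giStar()`, ...), and
`inst/scripts/run-pipeline.R` wraps `runAll()` for shell use with a YAML
configuration.

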