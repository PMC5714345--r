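---
title: "Mapping biomass-biodiversity congruence on a synthetic landscape"
author: "agbird"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping biomass-biodiversity congruence on a synthetic landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agbird)
```

## The scientific question

Payments-for-ecosystem-services schemes such as REDD+ protect forest carbon.
Whether they also protect biodiversity depends on how well areas of high
above-ground biomass (AGB) coincide with areas of high species richness — a
congruence that varies strongly between tropical landscapes and scales.
`agbird` implements a complete landscape-scale analysis of this question:

1. map AGB wall-to-wall from L-band SAR backscatter *texture* calibrated
   against a handful of field plots;
2. map bird species richness at 1 km by rasterising range polygons into a
   presence–absence matrix (PAM);
3. rank the environmental and anthropogenic drivers of richness;
4. quantify spatial congruence between AGB and richness with Getis-Ord Gi*
   hot/coldspot maps, percent area overlap, and correlations corrected for
   spatial autocorrelation.

Real inputs for such a study (satellite scenes, range databases, field
censuses) are large and partly proprietary. The package therefore ships a
first-class synthetic-landscape generator with *known ground truth*: every
stage of the pipeline can be scored by parameter recovery, on any machine,
with no downloads. The synthetic scene is the package's reference study
condition, not a unit-test convenience.

## The synthetic study landscape

`sceneConfig()` defaults describe one fixed set of study conditions:

* a 30 × 30 km scene of 25-m cells (1200 × 1200; 900 one-km analysis cells),
  the size of a typical sub-national REDD+ pilot area (~950 km²);
* terrain up to 1700 m built from smoothed random bumps; two roads and two
  rivers crossing the scene; three land-cover classes (non-forest, secondary
  forest, primary forest) driven by road proximity and a patch field;
* a latent AGB surface: class levels of roughly 115 (secondary) and
  205 Mg ha⁻¹ (primary) plus a ±45 Mg ha⁻¹ smooth field and a mild positive
  road-distance effect, clipped to 0–400 Mg ha⁻¹ — the working range over
  which L-band texture models of AGB are credible;
* 36 field plots of 0.25 ha (the four-transects-of-nine design), half in
  each forest stratum, with tree DBH lists (all ≥ 30 cm) drawn so that the
  DBH-only allometry sums *exactly* to the local truth times a lognormal
  noise factor (sd 0.05 by default; 0 gives exact inversion);
* dual-polarisation SAR digital numbers. Mean HV backscatter follows the
  saturating curve σ⁰ = s_max − (s_max − s_min)·exp(−AGB/L) with
  L = 100 Mg ha⁻¹ (the canonical L-band saturation level) over −25…−9 dB;
  HH uses a narrower range (−14…−7.5 dB) and saturates *faster* (0.5 L), as
  HH does in practice. On top of the mean power the generator multiplies
  gamma speckle (equivalent number of looks 4) and a lognormal fine-scale
  heterogeneity field whose amplitude grows with AGB
  (τ = 0.55·(0.15 + 0.85·AGB/400)), so that moving-window texture continues
  to encode AGB where mean backscatter has saturated. Digital numbers are
  the exact calibration inverse DN = √p · 10^{83/20};
* a degraded global 1-km AGB product (aggregated truth, 3 × 3 smoothing,
  ×1.2 bias, 30 Mg ha⁻¹ additive noise) emulating a pan-tropical map built
  without local calibration;
* 25 species ranges (15 IUCN-stratum, 10 endemic) placed by per-species
  habitat rules on the 1-km lattice: suitability is a weighted sum of
  standardised AGB, road distance, elevation and aspect-northness plus a
  species-specific smooth noise field; cells above the species' prevalence
  quantile form the range. The realised weights are returned as ground
  truth, which is what makes driver-importance recovery testable.

These values were chosen once, as a deliberate calibration: they place the
default scene in the regime tropical AGB-texture studies report (plot AGB
spanning ~60–300 Mg ha⁻¹, cross-validated model r around 0.85–0.9, RMSE
around 30 Mg ha⁻¹), so that recovery tests exercise the pipeline under
realistic difficulty rather than under a toy signal. What the generator
deliberately omits: topographic SAR distortion (layover/shadow),
radiative-transfer realism, cloud/atmosphere effects, taxonomic error in
ranges, and plot geolocation error. Passing recovery tests on this scene
therefore demonstrates correctness of the *analysis machinery* under the
stated noise model, not performance guarantees on any particular real
sensor/landscape combination.

## SAR preprocessing

Digital numbers are calibrated with the standard sensor equation
σ⁰ = 10·log₁₀(DN²) + CF with CF = −83 dB; DN = 0 cells become nodata.
Speckle is reduced with a Lee local-statistics filter (3 × 3 by default,
assumed 4 looks): out = m + k(x − m), k = max(0, 1 − c_u²/c_I²). The radar
forest degradation index RFDI = (HH − HV)/(HH + HV) is computed on *linear
power* by default — a ratio of dB values has no physical meaning — with a
flag to compute it on dB for sensitivity checks. Higher RFDI means weaker
volume scattering, i.e. more degraded forest.

## Texture features

Grey-level co-occurrence matrices (GLCM) are built per moving window after
linear min–max quantisation of the band. Defaults: 32 grey levels, 5 × 5
window, distance-1 offsets in the four standard directions, symmetric
counting — common practice for AGB texture work; all are configurable.
Eight Haralick features (mean, variance, homogeneity, contrast,
dissimilarity, entropy, second moment, correlation) are computed per cell
by compiled code, plus first-order windowed mean/variance of the raw
values. Border cells with incomplete windows are nodata. The R-level
`glcmMatrix()`/`haralickFeatures()` pair is a deliberately independent
per-window reference implementation; the test suite requires the compiled
moving-window engine to agree with it exactly, cell by cell.

## AGB modelling

Plot AGB comes from a DBH-only ln-polynomial allometry
(AGB_kg = exp(c₀ + c₁ lnD + c₂ (lnD)² + c₃ (lnD)³); defaults are a
moist-forest Chave-type form at wood density 0.6, all four coefficients
configurable). Predictors are extracted at plots as 3 × 3 footprint means —
a 0.25-ha plot spans several 25-m pixels.

Two model families are provided. `loglogFit()` implements the power-law
regression ln(AGB) = a + b·ln(X), with the lognormal half-variance
back-transform correction exp(s²/2) applied by default (switchable).
`rfFit()` is the workhorse: a 500-tree random-forest regression with the
trees-per-split parameter tuned by ten-fold cross-validation, pooled
out-of-fold r/RMSE/MAE/%bias as the honest skill estimate, and out-of-bag
permutation importance rescaled to 0–100.

`screenPredictors()` implements the r ≥ 0.75 screening rule as a
deterministic greedy procedure: repeatedly find the worst pair, drop the
member with the larger mean absolute correlation to the others,
lexicographic tie-break. One consequence is worth knowing: when several
*individually excellent* predictors are mutually correlated above the
threshold (as mean-backscatter features inevitably are), at most one
survives, and the survivor — the member least correlated with everything
else — can be the noisier proxy. Random forests are robust to correlated
predictors, which is precisely why the parameter-recovery analyses fit
`rfFit()` on the full texture table; the pipeline stage still screens, as
the emulated workflow does, and reports which predictors survived.

`fuseMaps()` blends the local prediction (aggregated to 1 km) with the
global product by kernel-correlation weighting: moving-window Pearson
correlations at kernel sizes 4, 8 and 16 cells, each gated at its
one-sided 5 % critical value (a 4 × 4 window produces |r| ≈ 0.2 by pure
chance; ungated weights would hand spurious trust to an uninformative local
map), clamped at zero, averaged into a weight w, and fused as
w·local + (1 − w)·global. Identical maps give w = 1; independent noise
gives w ≈ 0 and the fused map reverts to the global product; every fused
cell lies in the envelope of its inputs.

## Richness and its drivers

`buildPam()` rasterises range polygons by exact polygon–rectangle clipping
(Sutherland–Hodgman + shoelace area): a cell is present when the
intersection area exceeds `minCover` times the cell area, with the default
`minCover = 0` meaning any overlap of positive area (boundary contact does
not count). Richness grids are filtered column sums — strata for IUCN-listed
(CR ∪ EN ∪ VU ∪ NT), endemic, and their complements — so
richness(all) = richness(endemic) + richness(non-endemic) holds exactly.

Driver analysis works on a 1-km predictor stack (AGB, road and river
distance, elevation, slope, aspect via circular mean, RFDI, landscape
diversity and fragmentation, and three synthetic bioclim gradients).
`rankImportance()` follows the smoother-R² recipe: per predictor, a loess
smoother (span 0.75, degree 2) of richness on that predictor is compared
with the intercept-only null; importance_raw = max(0, 1 − SSE/SSE₀), then
rescaled so the top predictor scores 100. `svrFit()` provides the
radial-kernel ε-SVR with internal standardisation and seeded ten-fold
tuning of cost and kernel width. Partial-dependence curves are computed on
a random-forest surrogate refit to the same sample (the standard
partial-plot practice); a model handle can be supplied to compute them on
the SVR instead. `directionOfEffect()` reports the plain correlation with
its classical p-value — deliberately uncorrected, since the spatially
corrected test lives in the congruence module.

## Congruence

`giStar()` computes the Getis-Ord Gi* statistic with binary weights
(fixed distance band, default 3000 m on the 1-km grid, self included):

z_i = (Σ_j w_ij x_j − X̄ W_i) / (S·√((n·C_i − W_i²)/(n − 1))).

Hotspots are z ≥ z_crit(α), coldspots z ≤ −z_crit, with α = 0.05 and no
multiplicity correction by default (a Benjamini–Hochberg step could be
layered on the z grid, but raw thresholds are the convention this analysis
follows). AGB hotspots additionally require AGB > 180 Mg ha⁻¹, the
high-biomass convention for Asian tropical forests. Percent overlap of two
class maps is reported under four denominator conventions — union (default),
either single map, and the study area — because published overlap figures
rarely state their denominator; all four are written side by side.

`dutilleulCorrelation()` reports the plain Pearson r but replaces n in the
t-test with an effective sample size estimated from the two fields' spatial
autocovariance over distance classes (equal-width classes, Sturges count
capped at 30): var(r) ≈ (1/n²)(n + Σ_k S_k m_x(k) m_y(k)) over ordered
off-diagonal pairs, M̂ = 1 + 1/var(r) capped at n, t = r√((M̂−2)/(1−r²)) on
M̂−2 df. For independent fields M̂ ≈ n; for strongly co-smoothed fields M̂
collapses well below n/2, widening the test appropriately.

## Orchestration and determinism

`runAll()` executes generate → calibrate → texturize → fit-agb → richness →
drivers → congruence, writing plain-text artifacts (ESRI ASCII grids with a
JSON CRS sidecar, GeoJSON vectors, CSV tables, JSON reports), a run log and
a manifest with per-stage output checksums. One global seed is fanned out
into fixed per-stage sub-seeds, so a (config, seed) pair determines every
numeric artifact bit-for-bit; re-running skips stages whose outputs match
their recorded checksums, and deleting an artifact re-executes only its
stage. Configurations serialise to YAML with unknown-key rejection.

Numerical conventions worth stating: nodata is `NA` internally and a
sentinel (−9999) only on disk; moving-window operations return nodata where
the window leaves the grid (the Lee filter passes border cells through
unfiltered); aggregation ignores nodata within a block and keeps trailing
partial blocks; constant fields degrade explicitly (Gi* warns and returns
nodata, quantisation warns and returns zeros, screening drops constant
columns with a warning); grey-level quantisation is global min–max, so
texture features are invariant to adding a constant to the band.

## Problem sizes used by the checks

The shipped checks run the full default pipeline (1200² base cells, 900
one-km cells, ~2 minutes end to end) twice for determinism; AGB recovery
uses the default 36-plot scene; driver-effect recovery uses twenty coarse
40 × 40 km scenes of 500-m cells (1600 one-km cells, 1500 sampled); the
Gi* null calibration uses 200 iid 30 × 30 grids. These sizes are the
package's reference experiment design: large enough that the statistics are
in their asymptotic regime, small enough to re-run routinely.

## Known limitations

* The raster format is single-band ESRI ASCII; there is no reprojection —
  all layers must share one projected metric CRS.
* Polygon holes are not supported in ranges (outer rings only).
* The screening rule's winner-take-one behaviour on correlated feature
  clusters is faithful to its definition but can discard the strongest
  single predictor; see the AGB modelling section.
* Partial windows at grid borders are nodata rather than shrunken windows,
  so wall-to-wall maps lose a border of (window−1)/2 cells per windowed
  operation.
* The Dutilleul effective-df estimator is a moment estimator; for very
  small grids (n < ~100) its sampling noise is visible, which is why the
  checks run it at n = 1600.
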