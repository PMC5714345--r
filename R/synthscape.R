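#' Scene configuration for the synthetic-landscape generator
#'
#' The generator produces a fully self-consistent study landscape with known
#' ground truth: terrain, land cover, roads and rivers; a latent AGB surface;
#' dual-polarisation SAR digital numbers whose backscatter and local texture
#' encode AGB (with the L-band loss of sensitivity beyond the saturation
#' level); field plots whose tree DBH lists invert exactly to the local AGB
#' truth via the package allometry; a degraded 1-km global AGB product; and
#' species range polygons whose placement follows configurable AGB, road,
#' elevation and aspect effects recorded as recoverable ground truth.
#' Identical configuration + seed always yields an identical scene.
#'
#' @param nRows,nCols grid size at base resolution (>= 50 each).
#' @param cellSize base cell edge in metres (25 emulates L-band SAR pixels).
#' @param seed integer RNG seed; sub-seeds are derived per stage.
#' @param agbRange latent AGB range in Mg/ha, \code{c(min, max)}.
#' @param saturationLevel AGB (Mg/ha) at which backscatter sensitivity decays
#'   (e-folding constant of the saturating curve).
#' @param nSpeciesIucn,nSpeciesEndemic species counts for the two strata.
#' @param nPlots number of 0.25-ha field plots (default 36, i.e. four
#'   transects of nine plots).
#' @param enl equivalent number of looks of the gamma speckle model.
#' @param textureStrength amplitude of the AGB-dependent fine-scale variance
#'   added to backscatter so that window texture tracks AGB beyond
#'   saturation.
#' @param plotNoise lognormal sd of plot AGB around the local truth
#'   (0 = plots invert truth exactly).
#' @param rangeNoise weight of the species-specific spatial noise field in
#'   the habitat rule.
#' @param rangeEffects named weights of the habitat rule,
#'   \code{c(agb=, road=, elevation=, aspect=)}; per species they are
#'   jittered by U(0.7, 1.3) and recorded as ground truth.
#' @param globalBias,globalNoiseSd,globalSmooth multiplicative bias, additive
#'   noise sd (Mg/ha) and 3x3 smoothing passes of the synthetic global 1-km
#'   AGB product.
#' @return a validated \code{sceneConfig} list.
#' @export
sceneConfig <- function(nRows = 1200, nCols = 1200, cellSize = 25, seed = 1,
                        agbRange = c(0, 400), saturationLevel = 100,
                        nSpeciesIucn = 15, nSpeciesEndemic = 10, nPlots = 36,
                        enl = 4, textureStrength = 0.55, plotNoise = 0.05,
                        rangeNoise = 0.5,
                        rangeEffects = c(agb = 1.2, road = 0.8,
                                         elevation = 0.25, aspect = 0.25),
                        globalBias = 1.2, globalNoiseSd = 30,
                        globalSmooth = 1) {
  if (agbRange[1] >= agbRange[2]) stop("agbRange must have min < max")
  if (cellSize <= 0) stop("cellSize must be positive")
  need <- c("agb", "road", "elevation", "aspect")
  if (!all(need %in% names(rangeEffects)))
    stop("rangeEffects must name agb, road, elevation, aspect")
  structure(list(nRows = as.integer(nRows), nCols = as.integer(nCols),
                 cellSize = cellSize, seed = as.integer(seed),
                 agbRange = agbRange, saturationLevel = saturationLevel,
                 nSpeciesIucn = as.integer(nSpeciesIucn),
                 nSpeciesEndemic = as.integer(nSpeciesEndemic),
                 nPlots = as.integer(nPlots), enl = enl,
                 textureStrength = textureStrength, plotNoise = plotNoise,
                 rangeNoise = rangeNoise, rangeEffects = rangeEffects[need],
                 globalBias = globalBias, globalNoiseSd = globalNoiseSd,
                 globalSmooth = globalSmooth),
            class = "sceneConfig")
}

# smooth standard random field: coarse white noise, bilinear upsampling,
# standardised to zero mean / unit sd
.smoothField <- function(nr, nc, scaleCells) {
  cr <- max(2, ceiling(nr / scaleCells) + 1)
  cc <- max(2, ceiling(nc / scaleCells) + 1)
  coarse <- matrix(rnorm(cr * cc), cr, cc)
  rowPos <- seq(1, cr, length.out = nr)
  colPos <- seq(1, cc, length.out = nc)
  tmp <- apply(coarse, 2, function(col) approx(seq_len(cr), col, rowPos)$y)
  fine <- t(apply(tmp, 1, function(row) approx(seq_len(cc), row, colPos)$y))
  (fine - mean(fine)) / sd(fine)
}

# wiggly polyline across the scene; axis = "ns" or "ew"
.wigglyLine <- function(frac, axis, extentX, extentY, nVerts = 24) {
  t <- seq(0, 1, length.out = nVerts)
  wig <- cumsum(rnorm(nVerts))
  wig <- (wig - mean(wig)) / max(1e-9, sd(wig)) * 0.06
  if (axis == "ns") cbind(x = (frac + wig) * extentX, y = t * extentY)
  else cbind(x = t * extentX, y = (frac + wig) * extentY)
}

#' Generate terrain, land cover and line features
#'
#' DEM = smoothed random bumps plus a broad random field, scaled to
#' [0, 1700] m (the elevation span of the emulated mountain-range setting).
#' Land cover has three classes - 0 non-forest, 1 secondary forest, 2 primary
#' forest - driven by road proximity and a patch field: cells near roads tend
#' to be cleared or logged, remote cells hold primary forest. Two roads and
#' two rivers cross the scene as wiggly polylines.
#'
#' @param config a [sceneConfig()].
#' @return \code{list(dem, landcover, roads, rivers, roadDistance)} where the
#'   grids are [Grid-class] and the line layers [VectorLayer-class].
#' @export
makeTerrain <- function(config) {
  nr <- config$nRows; nc <- config$nCols
  if (nr < 50 || nc < 50) stop("degenerate grid: scene must be at least 50 x 50")
  set.seed(config$seed)
  cs <- config$cellSize
  extX <- nc * cs; extY <- nr * cs
  cc <- list(x = (seq_len(nc) - 0.5) * cs, y = extY - (seq_len(nr) - 0.5) * cs)
  # ridge-and-bump elevation
  bumps <- matrix(0, nr, nc)
  X <- matrix(cc$x, nr, nc, byrow = TRUE); Y <- matrix(cc$y, nr, nc)
  for (b in seq_len(6)) {
    cx <- runif(1, 0.15, 0.85) * extX; cy <- runif(1, 0.15, 0.85) * extY
    sx <- runif(1, 0.12, 0.35) * extX; sy <- runif(1, 0.12, 0.35) * extY
    amp <- runif(1, 0.4, 1)
    bumps <- bumps + amp * exp(-((X - cx)^2 / (2 * sx^2) +
                                 (Y - cy)^2 / (2 * sy^2)))
  }
  broad <- .smoothField(nr, nc, max(8, nr / 8))
  demRaw <- 0.65 * (bumps - min(bumps)) / diff(range(bumps)) +
    0.35 * (broad - min(broad)) / diff(range(broad))
  dem <- grid((demRaw - min(demRaw)) / diff(range(demRaw)) * 1700,
              cellSize = cs)
  roads <- vectorLayer(list(
    list(type = "polyline", coords = .wigglyLine(0.28, "ns", extX, extY)),
    list(type = "polyline", coords = .wigglyLine(0.62, "ew", extX, extY))),
    data.frame(name = c("road-1", "road-2")), dem@crsId)
  rivers <- vectorLayer(list(
    list(type = "polyline", coords = .wigglyLine(0.75, "ns", extX, extY)),
    list(type = "polyline", coords = .wigglyLine(0.2, "ew", extX, extY))),
    data.frame(name = c("river-1", "river-2")), dem@crsId)
  roadDist <- euclideanDistance(roads, dem)
  patch <- .smoothField(nr, nc, max(6, nr / 10))
  zz <- function(m) (m - mean(m)) / sd(m)
  score <- 0.55 * zz(roadDist@values) + 0.45 * zz(patch)
  qs <- quantile(score, c(0.25, 0.6))
  lc <- ifelse(score < qs[1], 0, ifelse(score < qs[2], 1, 2))
  landcover <- grid(lc, cellSize = cs)
  list(dem = dem, landcover = landcover, roads = roads, rivers = rivers,
       roadDistance = roadDist)
}

#' Generate the latent AGB truth surface
#'
#' AGB is a monotone function of forest class (non-forest near 0, secondary
#' intermediate, primary high), plus a smoothed spatial random field and a
#' mild positive effect of distance from roads, clipped to the configured
#' range. This is the ground truth every downstream stage is scored against.
#'
#' @param dem,landcover aligned [Grid-class]s from [makeTerrain()].
#' @param roads road [VectorLayer-class].
#' @param config a [sceneConfig()].
#' @return [Grid-class] of AGB (Mg/ha).
#' @export
makeAgbTruth <- function(dem, landcover, roads, config) {
  stopIfMisaligned(dem, landcover, "dem and landcover")
  set.seed(config$seed + 1L)
  nr <- nrow(dem@values); nc <- ncol(dem@values)
  lc <- landcover@values
  base <- ifelse(lc == 2, 205, ifelse(lc == 1, 115, 4))
  field <- .smoothField(nr, nc, max(5, nr / 6)) * 45
  rd <- euclideanDistance(roads, dem)@values
  rdn <- pmin(rd / max(1e-9, quantile(rd, 0.95)), 1)
  forest <- lc > 0
  agb <- base + forest * (field + 30 * rdn)
  agb <- pmin(pmax(agb, config$agbRange[1]), config$agbRange[2])
  agb[!forest] <- pmin(agb[!forest], 15)
  grid(agb, dem@originX, dem@originY, dem@cellSize, dem@crsId, dem@nodata)
}

.sigmaMean <- function(agb, sMin, sMax, L) sMax - (sMax - sMin) * exp(-agb / L)

#' Generate HH/HV SAR digital numbers from the AGB truth
#'
#' Mean HV backscatter follows the saturating curve
#' \eqn{\sigma^0 = s_{max} - (s_{max}-s_{min}) e^{-AGB/L}} with L the
#' configured saturation level (the simplest curve with the ~100 Mg/ha
#' L-band saturation behaviour); HH uses a narrower dynamic range and a
#' slower response (weaker AGB sensitivity). On top of the mean power the
#' generator multiplies (i) gamma speckle with shape = \code{enl} and (ii) a
#' lognormal fine-scale heterogeneity field whose amplitude grows with AGB,
#' so that moving-window texture keeps encoding AGB where mean backscatter
#' has saturated. DN are the exact calibration inverse
#' \eqn{DN = \sqrt{p} \cdot 10^{83/20}}, hence strictly positive.
#'
#' @param agbTruth [Grid-class] of non-negative AGB.
#' @param config a [sceneConfig()].
#' @return \code{list(hh = Grid, hv = Grid)} of digital numbers.
#' @export
makeSar <- function(agbTruth, config) {
  a <- agbTruth@values
  if (any(a < 0, na.rm = TRUE)) stop("AGB grid must be non-negative")
  set.seed(config$seed + 2L)
  nr <- nrow(a); nc <- ncol(a)
  L <- config$saturationLevel
  aMax <- max(config$agbRange[2], 1)
  mk <- function(sMin, sMax, Leff) {
    sig <- .sigmaMean(a, sMin, sMax, Leff)
    p <- 10^(sig / 10)
    tau <- config$textureStrength * (0.15 + 0.85 * a / aMax)
    tex <- .smoothField(nr, nc, 1.2)
    p <- p * exp(tau * tex - tau^2 / 2)
    speckle <- matrix(rgamma(nr * nc, shape = config$enl,
                             rate = config$enl), nr, nc)
    dn <- sqrt(p * speckle) * 10^(83 / 20)
    grid(dn, agbTruth@originX, agbTruth@originY, agbTruth@cellSize,
         agbTruth@crsId, agbTruth@nodata)
  }
  hv <- mk(-25, -9, L)
  hh <- mk(-14, -7.5, 0.5 * L)
  list(hh = hh, hv = hv)
}

#' Generate field plots whose DBH lists invert to the AGB truth
#'
#' Plots (0.25 ha) are stratified over the forest classes (half primary,
#' half secondary). Each plot's target AGB is the truth at its cell times a
#' lognormal noise factor (sd \code{plotNoise}; 0 gives exact inversion), and
#' a tree DBH list (all >= 30 cm, the census threshold) is drawn so the
#' summed allometric tree mass hits the target exactly: trees are sampled
#' from a shifted-exponential DBH distribution and the last diameter is
#' solved from the allometry.
#'
#' @param agbTruth,landcover aligned [Grid-class]s.
#' @param config a [sceneConfig()].
#' @param coeffs [allometryCoefficients()] shared with [plotAgb()].
#' @return \code{list(plots = data.frame(plotId, x, y, areaHa, stratum),
#'   trees = data.frame(plotId, dbhCm))}.
#' @export
makePlots <- function(agbTruth, landcover, config,
                      coeffs = allometryCoefficients()) {
  stopIfMisaligned(agbTruth, landcover, "agbTruth and landcover")
  set.seed(config$seed + 3L)
  lc <- landcover@values
  nrL <- nrow(lc); ncL <- ncol(lc)
  margin <- 4L  # keep plots clear of the border so window features exist
  rowsAll <- ((seq_along(lc) - 1) %% nrL) + 1
  colsAll <- ((seq_along(lc) - 1) %/% nrL) + 1
  interior <- rowsAll > margin & rowsAll <= nrL - margin &
    colsAll > margin & colsAll <= ncL - margin
  prim <- which(lc == 2 & interior); sec <- which(lc == 1 & interior)
  if (length(prim) == 0 && length(sec) == 0)
    stop("no forest cells to place plots")
  nP <- config$nPlots
  nPrim <- min(length(prim), ceiling(nP / 2))
  nSec <- min(length(sec), nP - nPrim)
  cells <- c(sample(prim, nPrim), sample(sec, nSec))
  strata <- c(rep("primary", nPrim), rep("secondary", nSec))
  cc <- cellCenters(agbTruth)
  nr <- nrow(lc)
  rows <- ((cells - 1) %% nr) + 1
  cols <- ((cells - 1) %/% nr) + 1
  areaHa <- 0.25
  massAt <- function(D) treeAgbKg(D, coeffs)
  m30 <- massAt(30)
  solveD <- function(targetKg) {
    f <- function(D) massAt(D) - targetKg
    if (f(30) >= 0) return(30)
    hi <- 30
    while (f(hi) < 0 && hi < 1000) hi <- hi * 2
    stats::uniroot(f, c(30, hi), tol = 1e-10)$root
  }
  plots <- data.frame(plotId = sprintf("P%02d", seq_along(cells)),
                      x = cc$x[cols], y = cc$y[rows], areaHa = areaHa,
                      stratum = strata, stringsAsFactors = FALSE)
  treeRows <- list()
  for (i in seq_along(cells)) {
    truth <- agbTruth@values[rows[i], cols[i]]
    target <- truth * exp(rnorm(1, 0, config$plotNoise))
    targetKg <- target * 1000 * areaHa
    dbh <- numeric(0); cum <- 0
    repeat {
      remaining <- targetKg - cum
      if (remaining < m30) break
      D <- 30 + min(rexp(1, 1 / 15), 150)
      m <- massAt(D)
      if (m > remaining) { D <- solveD(remaining); m <- massAt(D) }
      dbh <- c(dbh, D); cum <- cum + m
      if (abs(targetKg - cum) < 1e-6) break
    }
    remaining <- targetKg - cum
    if (remaining > 1e-9 && length(dbh) > 0) {
      # fold the sub-threshold remainder into the last tree: exact inversion
      dbh[length(dbh)] <- solveD(massAt(dbh[length(dbh)]) + remaining)
    }
    if (length(dbh) == 0 && targetKg > 0) dbh <- 30  # tiny plots: one minimum tree
    if (length(dbh))
      treeRows[[i]] <- data.frame(plotId = plots$plotId[i], dbhCm = dbh)
  }
  trees <- do.call(rbind, treeRows)
  rownames(trees) <- NULL
  list(plots = plots, trees = trees)
}

#' Generate a degraded global 1-km AGB product
#'
#' The AGB truth aggregated to 1 km, optionally smoothed (3x3 neighbourhood
#' mean passes), multiplied by a bias factor and perturbed with additive
#' Gaussian noise - a deliberately degraded oracle emulating a pan-tropical
#' map built without local calibration data, for testing map fusion. With
#' \code{globalBias = 1}, \code{globalNoiseSd = 0}, \code{globalSmooth = 0}
#' it equals \code{aggregateGrid(truth, 1000/cellSize, "mean")} exactly.
#'
#' @inheritParams makeSar
#' @return 1-km [Grid-class] of AGB (Mg/ha).
#' @export
makeGlobalAgb <- function(agbTruth, config) {
  set.seed(config$seed + 4L)
  f <- round(1000 / agbTruth@cellSize)
  g <- aggregateGrid(agbTruth, f, "mean")
  v <- g@values
  if (config$globalSmooth > 0) {
    off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
    for (pass in seq_len(config$globalSmooth)) {
      ok <- is.finite(v)
      num <- .shiftAccum(ifelse(ok, v, 0), off)
      den <- .shiftAccum(ok * 1, off)
      v <- ifelse(den > 0, num / den, NA_real_)
    }
  }
  v <- v * config$globalBias +
    matrix(rnorm(length(v), 0, config$globalNoiseSd), nrow(v))
  v <- pmax(v, 0)
  grid(v, g@originX, g@originY, g@cellSize, g@crsId, g@nodata)
}

#' Generate species ranges from habitat rules with known effect weights
#'
#' Works on the 1-km lattice. Every species gets a habitat suitability
#' surface \code{w_agb z(AGB) + w_road z(roadDist) + w_elev z(elev) +
#' w_asp z(northness) + rangeNoise * eta_s} with species-jittered weights and
#' its own smooth noise field \code{eta_s}; its range is the union of cells
#' whose suitability exceeds the species' prevalence quantile, exported as
#' row-run rectangles of a multipolygon. The realised per-species weights are
#' attached as \code{attr(, "effects")} - the ground truth for
#' driver-importance recovery. IUCN categories are sampled over
#' CR/EN/VU/NT/LC; the last \code{nSpeciesEndemic} species are endemic.
#'
#' @param agbTruth base-resolution AGB [Grid-class].
#' @param dem base-resolution elevation [Grid-class].
#' @param roads road [VectorLayer-class].
#' @param config a [sceneConfig()].
#' @return list of [SpeciesRange-class] with attribute \code{effects}
#'   (data.frame of realised weights).
#' @export
makeRanges <- function(agbTruth, dem, roads, config) {
  stopIfMisaligned(agbTruth, dem, "agbTruth and dem")
  set.seed(config$seed + 5L)
  f <- round(1000 / agbTruth@cellSize)
  agb1k <- aggregateGrid(agbTruth, f, "mean")
  elev1k <- aggregateGrid(dem, f, "mean")
  asp <- slopeAspect(dem)$aspect
  asp1k <- aggregateGrid(asp, f, "circular_mean")
  north <- cos(asp1k@values * pi / 180)
  north[!is.finite(north)] <- 0
  rd1k <- euclideanDistance(roads, agb1k)
  nr <- nrow(agb1k@values); nc <- ncol(agb1k@values)
  zz <- function(m) {
    m[!is.finite(m)] <- mean(m[is.finite(m)])
    s <- sd(m); if (!is.finite(s) || s == 0) s <- 1
    (m - mean(m)) / s
  }
  zAgb <- zz(agb1k@values); zRoad <- zz(rd1k@values)
  zElev <- zz(elev1k@values); zNorth <- zz(north)
  cc <- cellCenters(agb1k); cs <- agb1k@cellSize
  nTot <- config$nSpeciesIucn + config$nSpeciesEndemic
  statuses <- sample(c("CR", "EN", "VU", "NT", "LC"), nTot, replace = TRUE,
                     prob = c(0.1, 0.2, 0.3, 0.25, 0.15))
  ranges <- vector("list", nTot)
  eff <- vector("list", nTot)
  for (s in seq_len(nTot)) {
    w <- config$rangeEffects * runif(4, 0.7, 1.3)
    prev <- runif(1, 0.15, 0.45)
    cellsIn <- NULL
    for (try in seq_len(10)) {
      eta <- .smoothField(nr, nc, 2)
      suit <- w["agb"] * zAgb + w["road"] * zRoad + w["elevation"] * zElev +
        w["aspect"] * zNorth + config$rangeNoise * eta
      thr <- quantile(suit, 1 - prev)
      cellsIn <- which(suit >= thr)
      if (length(cellsIn) > 0) break
    }
    if (length(cellsIn) == 0) {
      warning("species ", s, ": empty range after 10 tries; using best cell")
      cellsIn <- which.max(suit)
    }
    rows <- ((cellsIn - 1) %% nr) + 1
    cols <- ((cellsIn - 1) %/% nr) + 1
    # merge horizontal runs of cells into rectangles (open rings, ccw)
    polys <- list()
    for (r in sort(unique(rows))) {
      cr <- sort(cols[rows == r])
      runStart <- cr[c(TRUE, diff(cr) != 1)]
      runEnd <- cr[c(diff(cr) != 1, TRUE)]
      for (k in seq_along(runStart)) {
        x0 <- cc$x[runStart[k]] - cs / 2; x1 <- cc$x[runEnd[k]] + cs / 2
        y1 <- cc$y[r] + cs / 2; y0 <- cc$y[r] - cs / 2
        polys[[length(polys) + 1]] <-
          cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
      }
    }
    ranges[[s]] <- new("SpeciesRange",
                       speciesId = sprintf("SP%03d", s), polygons = polys,
                       iucnStatus = statuses[s],
                       endemic = s > config$nSpeciesIucn)
    eff[[s]] <- data.frame(speciesId = sprintf("SP%03d", s),
                           wAgb = w[["agb"]], wRoad = w[["road"]],
                           wElev = w[["elevation"]], wAspect = w[["aspect"]],
                           prevalence = prev)
  }
  attr(ranges, "effects") <- do.call(rbind, eff)
  ranges
}

#' Generate synthetic bioclimatic gradients
#'
#' Smooth annual-rainfall (1600-3000 mm), mean-temperature (26-28 C, with an
#' elevation lapse) and precipitation-seasonality surfaces tied to the DEM
#' plus broad random fields. These stand in for gridded climatology layers
#' as richness predictors; they are deliberately smooth, low-information
#' gradients.
#'
#' @param dem elevation [Grid-class].
#' @param config a [sceneConfig()] (seed source).
#' @return \code{list(rainfall, temperature, seasonality)} of [Grid-class]s.
#' @export
makeBioclim <- function(dem, config) {
  set.seed(config$seed + 6L)
  v <- dem@values
  nr <- nrow(v); nc <- ncol(v)
  elevN <- (v - min(v)) / max(1e-9, diff(range(v)))
  n01 <- function(m) (m - min(m)) / max(1e-9, diff(range(m)))
  f1 <- n01(.smoothField(nr, nc, max(10, nr / 5)))
  f2 <- n01(.smoothField(nr, nc, max(10, nr / 5)))
  f3 <- n01(.smoothField(nr, nc, max(10, nr / 5)))
  mk <- function(m) grid(m, dem@originX, dem@originY, dem@cellSize,
                         dem@crsId, dem@nodata)
  list(rainfall = mk(1600 + 1400 * (0.55 * elevN + 0.45 * f1)),
       temperature = mk(28 - 2 * (0.7 * elevN + 0.3 * f2)),
       seasonality = mk(40 + 40 * f3))
}

#' Generate and write a full synthetic scene
#'
#' Runs every generator stage and writes the artifact set: \code{dem.asc},
#' \code{landcover.asc}, \code{hh_dn.asc}, \code{hv_dn.asc},
#' \code{agb_truth.asc}, \code{global_agb.asc}, \code{roads.geojson},
#' \code{rivers.geojson}, \code{plots.csv}, \code{trees.csv},
#' \code{ranges.geojson} and \code{truth.json} (per-species effect weights).
#'
#' @param config a [sceneConfig()].
#' @param outDir output directory (created if needed).
#' @return (invisibly) the list of generated in-memory objects.
#' @export
generateScene <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  terr <- makeTerrain(config)
  agb <- makeAgbTruth(terr$dem, terr$landcover, terr$roads, config)
  sar <- makeSar(agb, config)
  fp <- makePlots(agb, terr$landcover, config)
  glob <- makeGlobalAgb(agb, config)
  ranges <- makeRanges(agb, terr$dem, terr$roads, config)
  p <- function(f) file.path(outDir, f)
  writeGrid(terr$dem, p("dem.asc"))
  writeGrid(terr$landcover, p("landcover.asc"))
  writeGrid(sar$hh, p("hh_dn.asc"))
  writeGrid(sar$hv, p("hv_dn.asc"))
  writeGrid(agb, p("agb_truth.asc"))
  writeGrid(glob, p("global_agb.asc"))
  writeVector(terr$roads, p("roads.geojson"))
  writeVector(terr$rivers, p("rivers.geojson"))
  write.csv(fp$plots, p("plots.csv"), row.names = FALSE)
  write.csv(fp$trees, p("trees.csv"), row.names = FALSE)
  writeVector(rangesToLayer(ranges), p("ranges.geojson"))
  jsonlite::write_json(attr(ranges, "effects"), p("truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(list(dem = terr$dem, landcover = terr$landcover,
                 roads = terr$roads, rivers = terr$rivers, agbTruth = agb,
                 sar = sar, plots = fp$plots, trees = fp$trees,
                 globalAgb = glob, ranges = ranges))
}
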