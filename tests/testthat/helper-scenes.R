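# Shared fixture builders. Heavy scenes are memoised so acceptance and unit
# tests reuse the same objects within a test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# small complete scene (base resolution 25 m) for structural tests
smallScene <- function(seed = 1, nRows = 240, nCols = 240) {
  memo(sprintf("small-%d-%d-%d", seed, nRows, nCols), {
    cfg <- sceneConfig(nRows = nRows, nCols = nCols, seed = seed)
    terr <- makeTerrain(cfg)
    agb <- makeAgbTruth(terr$dem, terr$landcover, terr$roads, cfg)
    list(cfg = cfg, terr = terr, agb = agb)
  })
}

# default-condition scene with SAR textures and the plot predictor table
defaultSceneTable <- function(seed = 1) {
  memo(sprintf("table-%d", seed), {
    cfg <- sceneConfig(seed = seed)
    terr <- makeTerrain(cfg)
    agb <- makeAgbTruth(terr$dem, terr$landcover, terr$roads, cfg)
    sar <- makeSar(agb, cfg)
    hv <- calibrateSigma0(leeFilter(sar$hv, 3, cfg$enl))
    hh <- calibrateSigma0(leeFilter(sar$hh, 3, cfg$enl))
    layers <- c(textureStack(hv, textureConfig(), "hv")@layers,
                textureStack(hh, textureConfig(), "hh")@layers)
    fp <- makePlots(agb, terr$landcover, cfg)
    obs <- plotAgbTable(fp$plots, fp$trees)
    X <- extractAtPlots(layers, fp$plots)
    list(cfg = cfg, agb = agb, layers = layers, plots = fp$plots,
         trees = fp$trees, obs = obs, X = X)
  })
}

# coarse 40 x 40 km scene (500-m cells) with >= 1500 complete 1-km cells,
# richness response built from generated ranges
coarseDriverSample <- function(seed, effects = c(agb = 1.2, road = 0.8,
                                                 elevation = 0.25,
                                                 aspect = 0.25),
                               rangeNoise = 0.5, n = 1500) {
  cfg <- sceneConfig(nRows = 80, nCols = 80, cellSize = 500, seed = seed,
                     rangeEffects = effects, rangeNoise = rangeNoise)
  terr <- makeTerrain(cfg)
  agb <- makeAgbTruth(terr$dem, terr$landcover, terr$roads, cfg)
  ranges <- makeRanges(agb, terr$dem, terr$roads, cfg)
  agb1k <- aggregateGrid(agb, 2, "mean")
  rich <- richnessGrid(buildPam(ranges, agb1k), "all")
  sa <- slopeAspect(terr$dem)
  layers <- list(agb = agb,
                 roadDistance = euclideanDistance(terr$roads, agb1k),
                 riverDistance = euclideanDistance(terr$rivers, agb1k),
                 elevation = terr$dem, slope = sa$slope, aspect = sa$aspect)
  stack <- buildStack(layers, agb1k)
  suppressWarnings(sampleCells(stack, rich, n, seed))
}

# brute-force Gi* oracle: double loop over all cell pairs
giStarBrute <- function(g, band) {
  v <- gridValues(g)
  nr <- nrow(v); nc <- ncol(v)
  cs <- cellSize(g)
  ok <- is.finite(v)
  n <- sum(ok)
  xbar <- mean(v[ok])
  S <- sqrt(sum((v[ok] - xbar)^2) / n)
  z <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!ok[r, c]) next
    s <- 0; W <- 0
    for (r2 in seq_len(nr)) for (c2 in seq_len(nc)) {
      if (!ok[r2, c2]) next
      if (((r - r2)^2 + (c - c2)^2) * cs^2 <= band^2 + 1e-9) {
        s <- s + v[r2, c2]; W <- W + 1
      }
    }
    den <- S * sqrt((n * W - W^2) / (n - 1))
    if (den > 0) z[r, c] <- (s - xbar * W) / den
  }
  z
}

# brute-force richness oracle: point-in-polygon counting per cell over a
# dense sub-grid of sample points (independent of the clipping code path)
richnessBrute <- function(ranges, template, pts = 21) {
  v <- gridValues(template)
  nr <- nrow(v); nc <- ncol(v)
  cs <- cellSize(template)
  o <- gridOrigin(template)
  pip <- function(px, py, ring) {
    n <- nrow(ring); inside <- rep(FALSE, length(px)); j <- n
    for (i in seq_len(n)) {
      xi <- ring[i, 1]; yi <- ring[i, 2]
      xj <- ring[j, 1]; yj <- ring[j, 2]
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
      j <- i
    }
    inside
  }
  out <- matrix(0, nr, nc)
  eps <- cs / (2 * pts)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    xs <- seq(o["x"] + (cl - 1) * cs + eps, o["x"] + cl * cs - eps,
              length.out = pts)
    ys <- seq(o["y"] - r * cs + eps, o["y"] - (r - 1) * cs - eps,
              length.out = pts)
    px <- rep(xs, times = pts); py <- rep(ys, each = pts)
    for (rg in ranges) {
      hit <- FALSE
      for (ring in rg@polygons) if (any(pip(px, py, ring))) { hit <- TRUE; break }
      out[r, cl] <- out[r, cl] + hit
    }
  }
  out
}
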