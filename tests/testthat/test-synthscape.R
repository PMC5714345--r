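test_that("terrain generation is deterministic and satisfies its contract", {
  sc <- smallScene(1)
  terr <- sc$terr
  expect_lte(max(gridValues(terr$dem)), 1700)
  expect_gte(min(gridValues(terr$dem)), 0)
  expect_gte(length(unique(as.vector(gridValues(terr$landcover)))), 3)

  terr2 <- makeTerrain(sc$cfg)
  expect_identical(gridValues(terr$dem), gridValues(terr2$dem))

  cfgB <- sceneConfig(nRows = 240, nCols = 240, seed = 2)
  expect_false(identical(gridValues(makeTerrain(cfgB)$dem),
                         gridValues(terr$dem)))

  expect_error(makeTerrain(sceneConfig(nRows = 40, nCols = 40)), "degenerate")
})

test_that("AGB truth is forest-driven and deterministic", {
  sc <- smallScene(1)
  lc <- gridValues(sc$terr$landcover)
  a <- gridValues(sc$agb)
  expect_gt(mean(a[lc == 2]), mean(a[lc == 1]))  # primary > secondary
  expect_lt(mean(a[lc == 0]), 20)                # non-forest near zero
  expect_identical(
    gridValues(makeAgbTruth(sc$terr$dem, sc$terr$landcover, sc$terr$roads,
                            sc$cfg)), a)

  # an all-non-forest scene carries essentially no biomass
  bare <- grid(matrix(0, 240, 240), cellSize = 25)
  aBare <- makeAgbTruth(sc$terr$dem, bare, sc$terr$roads, sc$cfg)
  expect_lt(max(gridValues(aBare)), 20)

  expect_error(makeAgbTruth(sc$terr$dem, grid(matrix(0, 5, 5)), sc$terr$roads,
                            sc$cfg), "not aligned")
})

test_that("SAR backscatter saturates in AGB and stays positive", {
  cfg <- sceneConfig(nRows = 60, nCols = 240, seed = 3)
  blocks <- cbind(matrix(0, 60, 80), matrix(150, 60, 80), matrix(300, 60, 80))
  agb <- grid(blocks, cellSize = 25)
  sar <- makeSar(agb, cfg)
  expect_true(all(gridValues(sar$hh) > 0))
  expect_true(all(gridValues(sar$hv) > 0))
  s <- gridValues(calibrateSigma0(sar$hv))
  m0 <- mean(s[, 1:80]); m150 <- mean(s[, 81:160]); m300 <- mean(s[, 161:240])
  expect_gt(m150, m0)
  expect_gt(m300, m150)                        # monotone increase
  expect_lt(m300 - m150, m150 - m0)            # saturation flattens the curve

  expect_error(makeSar(grid(matrix(-1, 60, 60), cellSize = 25), cfg),
               "non-negative")
})

test_that("field plots invert the allometry against local truth", {
  sc <- smallScene(1)
  cfg0 <- sceneConfig(nRows = 240, nCols = 240, seed = 1, plotNoise = 0)
  fp <- makePlots(sc$agb, sc$terr$landcover, cfg0)
  expect_equal(nrow(fp$plots), 36)
  expect_true(all(fp$trees$dbhCm >= 30))
  expect_setequal(unique(fp$plots$stratum), c("primary", "secondary"))

  obs <- plotAgbTable(fp$plots, fp$trees)
  rc <- agbird:::.cellIndex(sc$agb, fp$plots$x, fp$plots$y)
  truth <- gridValues(sc$agb)[rc]
  expect_lt(max(abs(obs - truth) / truth), 0.01)   # noise 0: within 1 %

  expect_error(makePlots(sc$agb, grid(matrix(0, 240, 240), cellSize = 25),
                         cfg0), "no forest cells")
})

test_that("the global 1-km product degrades the aggregated truth", {
  sc <- smallScene(1)
  glob <- makeGlobalAgb(sc$agb, sc$cfg)
  expect_equal(cellSize(glob), 1000)

  # identity limit: no bias, no noise, no smoothing
  cfgId <- sceneConfig(nRows = 240, nCols = 240, seed = 1, globalBias = 1,
                       globalNoiseSd = 0, globalSmooth = 0)
  expect_equal(gridValues(makeGlobalAgb(sc$agb, cfgId)),
               gridValues(aggregateGrid(sc$agb, 40, "mean")))

  # default noise still correlates with the aggregated truth
  agg <- aggregateGrid(sc$agb, 40, "mean")
  expect_gt(cor(as.vector(gridValues(glob)), as.vector(gridValues(agg))), 0)
})

test_that("species ranges follow their habitat rules and record the truth", {
  sc <- smallScene(1)
  ranges <- makeRanges(sc$agb, sc$terr$dem, sc$terr$roads, sc$cfg)
  expect_length(ranges, sc$cfg$nSpeciesIucn + sc$cfg$nSpeciesEndemic)
  eff <- attr(ranges, "effects")
  expect_equal(nrow(eff), length(ranges))
  expect_equal(sum(vapply(ranges, function(r) r@endemic, TRUE)),
               sc$cfg$nSpeciesEndemic)

  ranges2 <- makeRanges(sc$agb, sc$terr$dem, sc$terr$roads, sc$cfg)
  expect_identical(ranges[[1]]@polygons, ranges2[[1]]@polygons)

  # a pure high-AGB specialist centres its range on high-AGB cells
  cfgA <- sceneConfig(nRows = 240, nCols = 240, seed = 5,
                      rangeEffects = c(agb = 3, road = 0, elevation = 0,
                                       aspect = 0),
                      rangeNoise = 0.1, nSpeciesIucn = 3, nSpeciesEndemic = 0)
  rngA <- makeRanges(sc$agb, sc$terr$dem, sc$terr$roads, cfgA)
  agb1k <- aggregateGrid(sc$agb, 40, "mean")
  pamA <- buildPam(rngA, agb1k)
  aVec <- as.vector(t(gridValues(agb1k)))   # row-major, matches PAM rows
  for (s in seq_along(rngA)) {
    inRange <- pamMatrix(pamA)[, s] == 1
    expect_gte(mean(aVec[inRange]), quantile(aVec, 0.6))
  }
})

test_that("bioclim gradients stay inside their climatological ranges", {
  sc <- smallScene(1)
  bio <- makeBioclim(sc$terr$dem, sc$cfg)
  expect_gte(min(gridValues(bio$rainfall)), 1600)
  expect_lte(max(gridValues(bio$rainfall)), 3000)
  expect_gte(min(gridValues(bio$temperature)), 26)
  expect_lte(max(gridValues(bio$temperature)), 28)
})

test_that("generateScene writes the complete artifact set", {
  d <- withr::local_tempdir()
  cfg <- sceneConfig(nRows = 60, nCols = 60, seed = 9)
  generateScene(cfg, d)
  files <- c("dem.asc", "landcover.asc", "hh_dn.asc", "hv_dn.asc",
             "agb_truth.asc", "global_agb.asc", "roads.geojson",
             "rivers.geojson", "plots.csv", "trees.csv", "ranges.geojson",
             "truth.json")
  expect_true(all(file.exists(file.path(d, files))))
  # the written truth grid reads back identically (to print precision)
  back <- readGrid(file.path(d, "agb_truth.asc"))
  expect_equal(dim(gridValues(back)), c(60, 60))
})
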