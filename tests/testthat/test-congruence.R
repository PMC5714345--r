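test_that("Gi* matches the brute-force double loop cellwise", {
  set.seed(42)
  g <- grid(matrix(rnorm(100), 10, 10), cellSize = 1000)
  hs <- giStar(g, spatialWeights(bandDistance = 3000))
  zb <- giStarBrute(g, band = 3000)
  expect_lt(max(abs(gridValues(hs@z) - zb)), 1e-10)
})

test_that("Gi* flags local clusters and respects its invariances", {
  v <- matrix(0, 12, 12); v[5:7, 5:7] <- 10
  v <- v + matrix(rnorm(144, 0, 0.01), 12, 12)
  g <- grid(v, cellSize = 1000)
  hs <- giStar(g)
  z <- gridValues(hs@z)
  mx <- which(z == max(z), arr.ind = TRUE)[1, ]
  expect_true(all(mx >= 5) && all(mx <= 7))   # peak inside the high block
  expect_lt(abs(z[1, 12]), z[6, 6])

  # affine invariance of z-scores
  g2 <- grid(v * 13 - 100, cellSize = 1000)
  expect_equal(gridValues(giStar(g2)@z), z, tolerance = 1e-9)

  # full-neighbourhood weights: Gi* numerators sum to zero over the grid
  off <- agbird:::.weightOffsets(spatialWeights(bandDistance = 1e6), 1000)
  num <- agbird:::.shiftAccum(v, off)
  W <- agbird:::.shiftAccum(matrix(1, 12, 12), off)
  expect_lt(abs(sum(num - mean(v) * W)) / sum(abs(v)), 1e-9)

  expect_warning(giStar(grid(matrix(5, 10, 10), cellSize = 1000)), "constant")
  expect_error(giStar(grid(matrix(1:4, 2, 2), cellSize = 1000)), "at least 9")
})

test_that("hotspot classification applies alpha and the AGB mask", {
  z <- grid(matrix(c(2.5, -2.5, 0.3, 1.9), 2, 2, byrow = TRUE),
            cellSize = 1000)
  cls <- gridValues(classifyHotspots(z, alpha = 0.05))
  expect_equal(cls[1, 1], 1)    # HOT
  expect_equal(cls[1, 2], -1)   # COLD
  expect_equal(cls[2, 1], 0)    # NS
  expect_equal(cls[2, 2], 0)

  # value mask: significant but low AGB -> NS
  agb <- grid(matrix(c(150, 200, 300, 300), 2, 2, byrow = TRUE),
              cellSize = 1000)
  clsM <- gridValues(classifyHotspots(z, agb, highMaskThreshold = 180))
  expect_equal(clsM[1, 1], 0)
  expect_equal(clsM[1, 2], -1)  # mask only affects HOT

  # nested significance: stricter alpha shrinks the HOT set
  set.seed(3)
  zr <- grid(matrix(rnorm(400, 0, 2), 20, 20), cellSize = 1000)
  h5 <- gridValues(classifyHotspots(zr, alpha = 0.05)) == 1
  h1 <- gridValues(classifyHotspots(zr, alpha = 0.01)) == 1
  expect_true(all(which(h1) %in% which(h5)))

  # BH correction is conservative: corrected classes nest inside raw classes
  hBH <- gridValues(classifyHotspots(zr, alpha = 0.05, fdrCorrect = TRUE))
  hRaw <- gridValues(classifyHotspots(zr, alpha = 0.05))
  expect_true(all(which(hBH == 1) %in% which(hRaw == 1)))
  expect_true(all(which(hBH == -1) %in% which(hRaw == -1)))

  expect_error(classifyHotspots(z, highMaskThreshold = 180), "value grid")
})

test_that("overlap percentages follow the denominator conventions", {
  mkCls <- function(hotCells, n = 100) {
    m <- matrix(0, 10, 10); m[hotCells] <- 1
    grid(m, cellSize = 1000)
  }
  a <- mkCls(1:10); b <- mkCls(6:15)
  expect_equal(overlapPercent(a, b, "HOT", "union"), 100 * 5 / 15)
  expect_equal(overlapPercent(a, b, "HOT", "first"), 50)
  expect_equal(overlapPercent(a, b, "HOT", "second"), 50)
  expect_equal(overlapPercent(a, b, "HOT", "study_area"), 5)

  # symmetric under union
  expect_equal(overlapPercent(a, b, "HOT"), overlapPercent(b, a, "HOT"))

  expect_equal(overlapPercent(a, a, "HOT"), 100)
  expect_equal(overlapPercent(mkCls(1:5), mkCls(50:55), "HOT"), 0)
  expect_warning(ov <- overlapPercent(a, b, "COLD", "union"), "empty")
  expect_true(is.na(ov))
})

test_that("the corrected correlation keeps r and adjusts only the df", {
  set.seed(21)
  x <- grid(matrix(rnorm(900), 30, 30), cellSize = 1000)
  y <- grid(matrix(rnorm(900), 30, 30), cellSize = 1000)
  d <- dutilleulCorrelation(x, y)
  rPlain <- cor(as.vector(gridValues(x)), as.vector(gridValues(y)))
  expect_equal(d$r, rPlain, tolerance = 1e-12)
  expect_lte(d$effectiveDf, d$n - 2)

  expect_error(dutilleulCorrelation(grid(matrix(rnorm(9), 3, 3),
                                         cellSize = 1000),
                                    grid(matrix(rnorm(9), 3, 3),
                                         cellSize = 1000)),
               "at least 20")
  expect_error(dutilleulCorrelation(x, y, nDistClasses = 2), "3 distance")
})

test_that("the congruence report assembles overlaps and correlations", {
  set.seed(31)
  base <- agbird:::.smoothField(25, 25, 5)
  agb <- grid(150 + 60 * base, cellSize = 1000)
  iucn <- grid(round(8 + 4 * base + rnorm(625, 0, 0.3)), cellSize = 1000)
  endm <- grid(round(5 + 2 * agbird:::.smoothField(25, 25, 5)),
               cellSize = 1000)
  rep <- congruenceReport(agb, iucn, endm, alpha = 0.05,
                          agbHighThreshold = 180)
  ov <- overlapTable(rep)
  expect_equal(nrow(ov), 16)   # 2 pairs x 2 classes x 4 denominators
  expect_true(all(ov$overlapPct >= 0 & ov$overlapPct <= 100, na.rm = TRUE))
  ct <- correlationTable(rep)
  expect_equal(nrow(ct), 2)
  expect_gt(ct$r[ct$pair == "agb-iucn"], 0.5)  # congruent construction
})
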