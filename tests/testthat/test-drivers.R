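mk1k <- function(m) grid(m, cellSize = 1000)

test_that("the predictor stack aggregates by the right statistic per layer", {
  tm <- mk1k(matrix(0, 3, 3))
  base <- grid(matrix(0, 6, 6), cellSize = 500)

  # passthrough for layers already on the template
  already <- mk1k(matrix(1:9, 3, 3))
  st <- buildStack(list(agb = already), tm)
  expect_identical(gridValues(st$agb), gridValues(already))

  # circular mean: {350, 10} averages to 0, never 180
  av <- matrix(90, 6, 6); av[1:2, 1:2] <- c(350, 10, 350, 10)
  st2 <- buildStack(list(aspect = grid(av, cellSize = 500)), tm)
  expect_lt(min(abs(c(gridValues(st2$aspect)[1, 1],
                      gridValues(st2$aspect)[1, 1] - 360))), 1e-6)

  # constant continuous layer stays constant; categorical by majority
  st3 <- buildStack(list(elevation = grid(matrix(7, 6, 6), cellSize = 500),
                         landcover = grid(matrix(c(1, 1, 2, 1), 6, 6),
                                          cellSize = 500)), tm)
  expect_true(all(gridValues(st3$elevation) == 7))
  expect_true(all(gridValues(st3$landcover) %in% c(1, 2)))

  expect_error(buildStack(list(x = grid(matrix(0, 2, 2), cellSize = 500)), tm),
               "cover the template")
})

test_that("cell sampling is reproducible and reads the right cells", {
  set.seed(1)
  stack <- list(a = mk1k(matrix(rnorm(100), 10, 10)),
                b = mk1k(matrix(rnorm(100), 10, 10)))
  rich <- mk1k(matrix(rpois(100, 5), 10, 10))

  s1 <- sampleCells(stack, rich, 40, seed = 7)
  s2 <- sampleCells(stack, rich, 40, seed = 7)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$X, s2$X)

  # lookup oracle: sampled values equal the grids at the sampled cells
  av <- as.vector(t(gridValues(stack$a)))
  rv <- as.vector(t(gridValues(rich)))
  expect_equal(s1$X$a, av[s1$cells])
  expect_equal(s1$y, rv[s1$cells])

  expect_warning(sAll <- sampleCells(stack, rich, 1500, seed = 1),
                 "using all")
  expect_equal(length(sAll$cells), 100)

  allNA <- list(a = mk1k(matrix(NA_real_, 10, 10)))
  expect_error(sampleCells(allNA, rich, 10), "no complete cells")
})

test_that("SVR skill is high on clean signal and null on permuted response", {
  set.seed(5)
  n <- 300
  X <- data.frame(u = runif(n, 0, 10), v = runif(n, 0, 10),
                  w = runif(n, 0, 10))
  smpLin <- structure(list(cells = seq_len(n), X = X, y = 3 * X$u + 2),
                      class = "driverSample")
  fitLin <- svrFit(smpLin, folds = 5, seed = 2)
  expect_gte(fitLin$cvR2, 0.9)

  smpNull <- structure(list(cells = seq_len(n), X = X,
                            y = sample(3 * X$u + 2)), class = "driverSample")
  fitNull <- svrFit(smpNull, folds = 5, seed = 2)
  expect_lte(fitNull$cvR2, 0.1)

  # identical seed/config give identical tuned parameters
  expect_identical(svrFit(smpLin, folds = 5, seed = 2)$best, fitLin$best)

  smpConst <- structure(list(cells = 1:10, X = X[1:10, ], y = rep(2, 10)),
                        class = "driverSample")
  expect_error(svrFit(smpConst), "constant")
})

test_that("smoother-R2 importance finds real drivers and ignores noise", {
  set.seed(9)
  n <- 1500
  X <- data.frame(signal = runif(n, 0, 10), noise1 = rnorm(n),
                  noise2 = rnorm(n))
  y <- sin(X$signal / 3) * 5 + rnorm(n, 0, 0.4)
  smp <- structure(list(cells = seq_len(n), X = X, y = y),
                   class = "driverSample")
  imp <- rankImportance(smp)
  expect_equal(names(imp)[1], "signal")
  expect_equal(unname(imp[1]), 100)
  raw <- attr(imp, "raw")
  expect_lt(raw[["noise1"]], 0.05)
  expect_lt(raw[["noise2"]], 0.05)

  # affine rescaling of a predictor leaves the ranking unchanged
  X2 <- X; X2$signal <- X$signal * 37 - 500
  smp2 <- structure(list(cells = seq_len(n), X = X2, y = y),
                    class = "driverSample")
  expect_equal(unname(rankImportance(smp2)), unname(imp), tolerance = 1e-6)

  # constant predictor scores 0
  X3 <- X; X3$noise1 <- 1
  smp3 <- structure(list(cells = seq_len(n), X = X3, y = y),
                    class = "driverSample")
  expect_equal(unname(rankImportance(smp3)[["noise1"]]), 0)

  expect_error(rankImportance(structure(list(cells = 1:10, X = X[1:10, ],
                                             y = y[1:10]),
                                        class = "driverSample")),
               "at least 30")
})

test_that("partial dependence marginalises correctly", {
  set.seed(13)
  n <- 400
  X <- data.frame(a = runif(n, 0, 10), b = runif(n, 0, 10))
  y <- 2 * X$a + rnorm(n, 0, 0.2)
  smp <- structure(list(cells = seq_len(n), X = X, y = y),
                   class = "driverSample")

  pdA <- partialDependence(smp, "a", nPoints = 20, seed = 1)
  # additive monotone dependence -> monotone curve
  expect_true(all(diff(pdA$yhat) > -0.1))
  expect_gt(pdA$yhat[20] - pdA$yhat[1], 10)
  # endpoints stay inside the observed range
  expect_gte(min(pdA$x), min(X$a)); expect_lte(max(pdA$x), max(X$a))

  # a predictor the model ignores gives a flat curve
  pdB <- partialDependence(smp, "b", nPoints = 20, seed = 1)
  expect_lt(diff(range(pdB$yhat)), 0.15 * diff(range(pdA$yhat)))

  expect_error(partialDependence(smp, "zz"), "not in the sample")
})

test_that("effect directions come from plain correlation", {
  n <- 50
  X <- data.frame(p = seq_len(n), q = -seq_len(n))
  smp <- structure(list(cells = seq_len(n), X = X, y = as.numeric(seq_len(n))),
                   class = "driverSample")
  expect_equal(directionOfEffect(smp, "p")$r, 1)
  expect_equal(directionOfEffect(smp, "q")$r, -1)

  # hand formula on a 5-row table
  x5 <- c(1, 2, 4, 7, 11); y5 <- c(2, 1, 5, 4, 9)
  rHand <- sum((x5 - mean(x5)) * (y5 - mean(y5))) /
    sqrt(sum((x5 - mean(x5))^2) * sum((y5 - mean(y5))^2))
  smp5 <- structure(list(cells = 1:5, X = data.frame(p = x5), y = y5),
                    class = "driverSample")
  expect_equal(directionOfEffect(smp5, "p")$r, rHand, tolerance = 1e-12)
})
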