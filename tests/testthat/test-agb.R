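test_that("plot AGB follows the allometry, additively and per area", {
  co <- allometryCoefficients(log(1000), 0, 0, 0)   # every tree 1000 kg
  expect_equal(plotAgb(50, areaHa = 0.25, coeffs = co), 4)  # 1 t / 0.25 ha

  expect_warning(z <- plotAgb(numeric(0)), "empty tree list")
  expect_equal(z, 0)
  expect_error(plotAgb(c(30, -5)), "positive")

  # doubling the tree list doubles the plot AGB; halving area doubles it too
  d <- c(31, 45, 60, 80)
  expect_equal(plotAgb(c(d, d)), 2 * plotAgb(d))
  expect_equal(plotAgb(d, areaHa = 0.125), 2 * plotAgb(d, areaHa = 0.25))

  # table interface matches per-plot calls
  plots <- data.frame(plotId = c("a", "b"), areaHa = 0.25)
  trees <- data.frame(plotId = c("a", "a", "b"), dbhCm = c(35, 40, 90))
  pa <- plotAgbTable(plots, trees)
  expect_equal(unname(pa["a"]), plotAgb(c(35, 40)))
  expect_equal(unname(pa["b"]), plotAgb(90))

  expect_error(allometryCoefficients(0, 0, 0, 50), "positive, finite")
})

test_that("correlation screening is deterministic with the stated tie rule", {
  set.seed(21)
  n <- 30
  a <- rnorm(n)
  tbl <- data.frame(a = a, b = a, c = rnorm(n))   # identical pair + free col
  keep <- screenPredictors(tbl, 0.75)
  expect_setequal(keep, c("a", "c"))              # exact tie drops later name

  # orthogonal-ish columns all retained
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  expect_setequal(screenPredictors(X, 0.75), names(X))

  # near-duplicate pair: one survivor plus the independent column
  y <- a + rnorm(n, 0, 0.05)
  tbl2 <- data.frame(p = a, q = y, r = rnorm(n))
  keep2 <- screenPredictors(tbl2, 0.75)
  expect_length(keep2, 2)
  expect_true("r" %in% keep2)
  expect_identical(keep2, screenPredictors(tbl2, 0.75))  # deterministic

  expect_warning(k3 <- screenPredictors(data.frame(u = rnorm(n), v = 1,
                                                   w = rnorm(n)), 0.75),
                 "constant")
  expect_false("v" %in% k3)
  expect_error(screenPredictors(data.frame(x = 1:5), 0.75), "at least 2")
})

test_that("screening agrees with an independent implementation", {
  skip_if_not_installed("caret")
  set.seed(33)
  n <- 40
  base <- rnorm(n)
  X <- data.frame(a = base + rnorm(n, 0, 0.2), b = base + rnorm(n, 0, 0.2),
                  c = rnorm(n), d = rnorm(n))
  keep <- screenPredictors(X, 0.75)
  dropRef <- names(X)[caret::findCorrelation(cor(X), cutoff = 0.75,
                                             exact = TRUE)]
  expect_setequal(keep, setdiff(names(X), dropRef))
})

test_that("log-log regression recovers power laws and reports honest fit", {
  x <- seq(1, 20, length.out = 30)
  f <- loglogFit(2 * x^3, x)
  expect_equal(unname(f$coefficients[1]), log(2), tolerance = 1e-12)
  expect_equal(unname(f$coefficients[2]), 3, tolerance = 1e-12)
  expect_equal(f$adjR2, 1, tolerance = 1e-12)
  expect_equal(unname(predict(f, data.frame(x = 2))), 16, tolerance = 1e-9)

  # flat response: adjusted R2 <= 0
  set.seed(2)
  expect_lte(loglogFit(exp(rnorm(30, 2, 0.1)), x)$adjR2, 0.1)

  # Monte-Carlo recovery at n = 36, 0.2 ln-noise: estimates within 2 SE
  set.seed(7)
  hits <- replicate(40, {
    xs <- exp(runif(36, 0, 2))
    ys <- 2 * xs^1.5 * exp(rnorm(36, 0, 0.2))
    ft <- loglogFit(ys, xs)
    se <- summary(ft$lm)$coefficients[, 2]
    abs(ft$coefficients[1] - log(2)) < 2 * se[1] &
      abs(ft$coefficients[2] - 1.5) < 2 * se[2]
  })
  expect_gte(mean(hits), 0.8)   # ~95 % nominal coverage

  expect_error(loglogFit(c(-1, 2, 3), 1:3), "positive")
  # bias correction widens back-transformed predictions
  set.seed(8)
  yn <- 2 * x^3 * exp(rnorm(30, 0, 0.4))
  fn <- loglogFit(yn, x)
  expect_gt(mean(predict(fn, data.frame(x = x), biasCorrect = TRUE)),
            mean(predict(fn, data.frame(x = x), biasCorrect = FALSE)))
})

test_that("accuracy metrics match hand arithmetic and degenerate safely", {
  m0 <- accuracyMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(m0), c(1, 0, 0, 0))

  m1 <- accuracyMetrics(c(100, 100), c(101, 103))
  expect_equal(unname(m1["rmse"]), sqrt(5), tolerance = 1e-12)
  expect_equal(unname(m1["mae"]), 2)
  expect_equal(unname(m1["pctBias"]), 2)
  expect_true(is.na(m1["r"]))          # constant observed -> r undefined

  m2 <- accuracyMetrics(c(1, 2, 3), c(2, 2, 2))
  expect_true(is.na(m2["r"]))
  expect_true(all(is.finite(m2[c("rmse", "mae", "pctBias")])))
})

test_that("random-forest fitting is honest on noise and dominant signals", {
  set.seed(12)
  n <- 36
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))

  # pure-noise response: cross-validated r stays near zero (median over seeds)
  rs <- sapply(1:5, function(s) {
    set.seed(100 + s)
    y <- rnorm(n)
    abs(cvMetrics(rfFit(X, y, folds = 10, seed = s))["r"])
  })
  expect_lt(median(rs), 0.35)

  # response equal to one predictor: that predictor dominates importance
  fit <- rfFit(X, X$x2, folds = 10, seed = 3)
  expect_equal(unname(importanceScores(fit)["x2"]), 100)
  expect_true(all(importanceScores(fit)[c("x1", "x3")] < 50))

  # fewer plots than folds: folds reduced with a warning
  w <- capture_warnings(rfFit(X[1:6, ], rnorm(6) * 50, folds = 10, seed = 1))
  expect_true(any(grepl("reducing folds", w)))

  # determinism: identical seed, identical pooled metrics
  y <- X$x1 + 0.2 * X$x2
  expect_identical(cvMetrics(rfFit(X, y, folds = 5, seed = 4)),
                   cvMetrics(rfFit(X, y, folds = 5, seed = 4)))
})

test_that("map prediction respects training bounds and nodata", {
  set.seed(14)
  n <- 30
  X <- data.frame(u = runif(n, 0, 10), v = runif(n, 0, 10))
  y <- 10 + 3 * X$u + rnorm(n, 0, 0.5)
  fit <- rfFit(X, y, folds = 5, seed = 2)

  mkStack <- function(u, v) list(
    u = grid(matrix(u, 4, 4), cellSize = 25),
    v = grid(matrix(v, 4, 4), cellSize = 25))

  # constant stack equal to a training row -> constant map
  st <- mkStack(X$u[5], X$v[5])
  pm <- predictMap(fit, st)
  expect_equal(max(gridValues(pm)) - min(gridValues(pm)), 0)

  # forest predictions bounded by the training response range
  st2 <- mkStack(runif(16, -5, 15), runif(16, -5, 15))
  pm2 <- predictMap(fit, st2)
  expect_gte(min(gridValues(pm2)), min(y))
  expect_lte(max(gridValues(pm2)), max(y))

  # nodata predictor -> nodata cell
  uu <- matrix(5, 4, 4); uu[2, 2] <- NA
  pm3 <- predictMap(fit, mkStack(uu, 5))
  expect_true(is.na(gridValues(pm3)[2, 2]))
  expect_false(anyNA(gridValues(pm3)[-6]))

  expect_error(predictMap(fit, list(u = st$u)), "lacks predictors")
})

test_that("kernel-correlation fusion is a trust-weighted convex combination", {
  set.seed(16)
  loc <- grid(matrix(runif(900, 50, 250), 30, 30), cellSize = 1000)

  # identical inputs: weight 1, fused identical
  f1 <- fuseMaps(loc, loc)
  expect_equal(gridValues(f1$fused), gridValues(loc))
  expect_true(all(gridValues(f1$weight) == 1))

  # uncorrelated local noise: fused hugs the global product
  glob <- grid(matrix(100 + 50 * sin(outer(1:30, 1:30) / 5), 30, 30),
               cellSize = 1000)
  noise <- grid(matrix(rnorm(900, 150, 30), 30, 30), cellSize = 1000)
  f2 <- fuseMaps(noise, glob)
  expect_lt(mean(abs(gridValues(f2$fused) - gridValues(glob))),
            0.1 * sd(gridValues(glob)))

  # every fused cell inside the per-cell input envelope
  lo <- pmin(gridValues(noise), gridValues(glob))
  hi <- pmax(gridValues(noise), gridValues(glob))
  expect_true(all(gridValues(f2$fused) >= lo - 1e-9 &
                  gridValues(f2$fused) <= hi + 1e-9))

  expect_error(fuseMaps(loc, grid(matrix(0, 5, 5), cellSize = 1000)),
               "not aligned")
})
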