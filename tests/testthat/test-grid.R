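test_that("ASCII grid round trip preserves values, geotransform and nodata", {
  d <- withr::local_tempdir()
  v <- matrix(c(1:8, NA), 3, 3, byrow = TRUE)
  g <- grid(v, originX = 1000, originY = 5000, cellSize = 25,
            crsId = "utm-50n", nodata = -9999)
  p <- file.path(d, "g.asc")
  writeGrid(g, p)
  g2 <- readGrid(p)
  expect_identical(gridValues(g2), gridValues(g))
  expect_equal(gridOrigin(g2), gridOrigin(g))
  expect_equal(cellSize(g2), 25)
  expect_identical(g2@crsId, "utm-50n")
  expect_identical(g2@nodata, -9999)

  # nodata cells stay out of statistics
  expect_equal(max(gridValues(g2), na.rm = TRUE), 8)

  # write -> read -> write is byte-identical
  p2 <- file.path(d, "g2.asc")
  writeGrid(g2, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("grid reading rejects broken input", {
  d <- withr::local_tempdir()
  expect_error(readGrid(file.path(d, "missing.asc")), "no such raster")
  bad <- file.path(d, "bad.asc")
  writeLines(c("NCOLS 2", "NROWS 2", "XLLCORNER 0", "YLLCORNER 0",
               "CELLSIZE 10", "1 2 3 4 5 6"), bad)
  expect_error(readGrid(bad), "multi-band or truncated")
  rect <- file.path(d, "rect.asc")
  writeLines(c("NCOLS 2", "NROWS 2", "XLLCORNER 0", "YLLCORNER 0",
               "CELLSIZE 10", "DX 10", "DY 5", "1 2", "3 4"), rect)
  expect_error(readGrid(rect), "non-square")
})

test_that("aggregation follows the block rules", {
  g1 <- grid(matrix(1, 4, 4), cellSize = 10)
  expect_true(all(gridValues(aggregateGrid(g1, 2, "mean")) == 1))
  expect_equal(dim(gridValues(aggregateGrid(g1, 2, "mean"))), c(2, 2))

  g2 <- grid(matrix(c(1, 3, 5, 7), 2, 2, byrow = TRUE), cellSize = 10)
  expect_equal(gridValues(aggregateGrid(g2, 2, "mean"))[1, 1], 4)
  expect_equal(cellSize(aggregateGrid(g2, 2, "mean")), 20)

  # nodata: mean of the remaining cells; all-nodata block stays nodata
  g3 <- grid(matrix(c(1, 2, NA, NA, 3, NA, NA, NA), 2, 4, byrow = TRUE),
             cellSize = 10)
  a3 <- aggregateGrid(g3, 2, "mean")
  expect_equal(gridValues(a3)[1, 1], 2)
  expect_true(is.na(gridValues(a3)[1, 2]))

  # factor 1 mean is the identity
  g4 <- grid(matrix(rnorm(30), 5, 6), cellSize = 25)
  expect_identical(gridValues(aggregateGrid(g4, 1, "mean")), gridValues(g4))

  # trailing partial blocks use the available cells
  g5 <- grid(matrix(1:15, 3, 5, byrow = TRUE), cellSize = 10)
  a5 <- aggregateGrid(g5, 2, "sum")
  expect_equal(dim(gridValues(a5)), c(2, 3))
  expect_equal(gridValues(a5)[1, 3], 5 + 10)  # lone trailing column pair
  expect_equal(gridValues(a5)[2, 3], 15)

  # majority picks the most frequent class
  g6 <- grid(matrix(c(1, 1, 2, 1), 2, 2, byrow = TRUE), cellSize = 10)
  expect_equal(gridValues(aggregateGrid(g6, 2, "majority"))[1, 1], 1)

  expect_error(aggregateGrid(g1, 0), "positive integer")
  expect_error(aggregateGrid(g1, -2), "positive integer")
})

test_that("slope and aspect match the analytic gradient of tilted planes", {
  nr <- 11
  # z = x (rising eastward), 1 m cells -> 45 degree slope, west-facing (270)
  v <- matrix(rep((seq_len(nr) - 0.5), each = 1), nr, nr, byrow = TRUE)
  sa <- slopeAspect(grid(v, cellSize = 1))
  expect_lt(max(abs(gridValues(sa$slope)[2:(nr - 1), 2:(nr - 1)] - 45)), 1e-6)
  expect_lt(max(abs(gridValues(sa$aspect)[2:(nr - 1), 2:(nr - 1)] - 270)), 1e-6)

  # rising northward -> south-facing (aspect 180)
  v2 <- matrix(rep(rev(seq_len(nr)), times = nr), nr, nr)
  sa2 <- slopeAspect(grid(v2, cellSize = 1))
  expect_lt(max(abs(gridValues(sa2$aspect)[2:(nr - 1), 2:(nr - 1)] - 180)), 1e-6)

  # gentler tilted plane, arbitrary direction, still analytic
  gx <- 0.3; gy <- -0.2; cs <- 5
  xs <- (seq_len(nr) - 0.5) * cs
  v3 <- outer(rev(xs) * gy / 1, xs * gx / 1, "+")  # z = gx*x + gy*y
  sa3 <- slopeAspect(grid(v3, cellSize = cs))
  expect_lt(max(abs(gridValues(sa3$slope)[2:(nr - 1), 2:(nr - 1)] -
                    atan(sqrt(gx^2 + gy^2)) * 180 / pi)), 1e-6)

  # constant DEM: zero slope, nodata aspect
  sa4 <- slopeAspect(grid(matrix(7, 5, 5), cellSize = 1))
  expect_true(all(gridValues(sa4$slope)[2:4, 2:4] == 0))
  expect_true(all(is.na(gridValues(sa4$aspect)[2:4, 2:4])))

  expect_error(slopeAspect(grid(matrix(0, 2, 5))), "3 x 3")
})

test_that("distance surfaces follow hand geometry and the triangle inequality", {
  tmpl <- grid(matrix(0, 7, 7), cellSize = 10)
  # vertical line through the grid centre (x = 35)
  line <- vectorLayer(list(list(type = "polyline",
                                coords = cbind(c(35, 35), c(0, 70)))))
  d <- gridValues(euclideanDistance(line, tmpl))
  for (cl in 1:7) expect_equal(d[4, cl], abs((cl - 0.5) * 10 - 35))

  # point target at a cell centre: 4-neighbour centres at one cell size
  pt <- vectorLayer(list(list(type = "polyline",
                              coords = cbind(35, 35))))
  dp <- gridValues(euclideanDistance(pt, tmpl))
  expect_equal(dp[4, 4], 0)
  expect_equal(dp[3, 4], 10); expect_equal(dp[5, 4], 10)
  expect_equal(dp[4, 3], 10); expect_equal(dp[4, 5], 10)

  # polygon covering the whole grid -> all zeros
  poly <- vectorLayer(list(list(type = "polygon",
    coords = cbind(c(-5, 75, 75, -5), c(-5, -5, 75, 75)))))
  expect_true(all(gridValues(euclideanDistance(poly, tmpl)) == 0))

  # triangle inequality: |d(a) - d(b)| <= dist(a, b)
  set.seed(4)
  irregular <- vectorLayer(list(list(type = "polyline",
    coords = cbind(runif(4, 0, 70), runif(4, 0, 70)))))
  dd <- gridValues(euclideanDistance(irregular, tmpl))
  cc <- cellCenters(tmpl)
  for (k in 1:50) {
    a <- c(sample(7, 1), sample(7, 1)); b <- c(sample(7, 1), sample(7, 1))
    ab <- sqrt((cc$x[a[2]] - cc$x[b[2]])^2 + (cc$y[a[1]] - cc$y[b[1]])^2)
    expect_lte(abs(dd[a[1], a[2]] - dd[b[1], b[2]]), ab + 1e-9)
  }

  expect_error(euclideanDistance(vectorLayer(list()), tmpl), "empty")
})

test_that("landscape diversity and fragmentation behave like Shannon and edge density", {
  # single class -> H = 0; equal halves -> ln 2 at the midline
  lc1 <- grid(matrix(1, 7, 7), cellSize = 10)
  expect_true(all(gridValues(landscapeDiversity(lc1, 3))[2:6, 2:6] == 0))

  half <- grid(cbind(matrix(1, 6, 3), matrix(2, 6, 3)), cellSize = 10)
  H <- gridValues(landscapeDiversity(half, 3))
  expect_equal(H[3, 3], log(2) * 0 + (-(2 / 3) * log(2 / 3) - (1 / 3) * log(1 / 3)),
               tolerance = 1e-12)

  # k equiprobable classes in the window -> ln k, monotone in k
  for (k in c(3, 9)) {
    m <- matrix(rep(seq_len(k), each = 9 / k), 3, 3)
    Hk <- gridValues(landscapeDiversity(grid(m, cellSize = 10), 3))[2, 2]
    expect_equal(Hk, log(k), tolerance = 1e-12)
  }

  # fragmentation: 0 homogeneous, 1 checkerboard, in between for two halves
  expect_true(all(gridValues(landscapeFragmentation(lc1, 3))[2:6, 2:6] == 0))
  cb <- grid(outer(1:6, 1:6, function(r, c) (r + c) %% 2), cellSize = 10)
  expect_true(all(gridValues(landscapeFragmentation(cb, 3))[2:5, 2:5] == 1))
  fr <- gridValues(landscapeFragmentation(half, 5))[3, 3]
  expect_gt(fr, 0); expect_lt(fr, 1)

  # both metrics invariant to class relabelling
  set.seed(2)
  lc <- grid(matrix(sample(0:3, 100, TRUE), 10, 10), cellSize = 10)
  relab <- grid(matrix(c(7, 2, 9, 4)[gridValues(lc) + 1], 10, 10), cellSize = 10)
  expect_equal(gridValues(landscapeDiversity(lc, 5)),
               gridValues(landscapeDiversity(relab, 5)))
  expect_equal(gridValues(landscapeFragmentation(lc, 5)),
               gridValues(landscapeFragmentation(relab, 5)))

  expect_error(landscapeDiversity(lc1, 4), "odd")
  expect_error(landscapeFragmentation(lc1, 2), "odd")
})
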