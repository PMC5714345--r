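#' DBH-only allometry for tree above-ground biomass
#'
#' Tree AGB (kg) is a ln-polynomial in diameter at breast height:
#' \eqn{AGB = \exp(c_0 + c_1 \ln D + c_2 (\ln D)^2 + c_3 (\ln D)^3)} with D in
#' cm. The defaults are a moist-forest DBH-only form (a Chave-type moist
#' model folded with wood density 0.6 g/cm3); all four coefficients are
#' configurable so local equations can be substituted. The synthetic-scene
#' generator uses the same coefficients, which makes plot-AGB inversion exact
#' by construction.
#'
#' @param c0,c1,c2,c3 coefficients of the ln-polynomial.
#' @return an \code{allometryCoefficients} object.
#' @export
allometryCoefficients <- function(c0 = -2.010, c1 = 2.148, c2 = 0.207,
                                  c3 = -0.0281) {
  co <- structure(list(c0 = c0, c1 = c1, c2 = c2, c3 = c3),
                  class = "allometryCoefficients")
  d <- c(30, 60, 120, 200)
  m <- treeAgbKg(d, co)
  if (any(!is.finite(m) | m <= 0))
    stop("allometry must predict positive, finite tree AGB for DBH in [30, 200] cm")
  co
}

#' @rdname allometryCoefficients
#' @param dbhCm tree diameters at breast height (cm).
#' @param coeffs an [allometryCoefficients()].
#' @return \code{treeAgbKg}: predicted per-tree AGB in kg.
#' @export
treeAgbKg <- function(dbhCm, coeffs = allometryCoefficients()) {
  if (any(dbhCm <= 0)) stop("DBH must be positive")
  ld <- log(dbhCm)
  exp(coeffs$c0 + coeffs$c1 * ld + coeffs$c2 * ld^2 + coeffs$c3 * ld^3)
}

#' Plot-level AGB from a tree DBH list
#'
#' Sums the allometric per-tree masses and scales to Mg per hectare:
#' \code{sum(kg) / 1000 / areaHa}. Additive over disjoint tree sets and
#' inversely proportional to plot area. An empty tree list yields 0 with a
#' warning.
#'
#' @param dbhCm tree DBH values (cm) for one plot; all must be positive.
#' @param areaHa plot area in hectares (census plots are 0.25 ha).
#' @param coeffs an [allometryCoefficients()].
#' @return plot AGB in Mg/ha.
#' @export
plotAgb <- function(dbhCm, areaHa = 0.25, coeffs = allometryCoefficients()) {
  if (areaHa <= 0) stop("areaHa must be positive")
  if (length(dbhCm) == 0) {
    warning("empty tree list: plot AGB = 0")
    return(0)
  }
  sum(treeAgbKg(dbhCm, coeffs)) / 1000 / areaHa
}

#' @rdname plotAgb
#' @param plots data.frame with plotId and areaHa columns.
#' @param trees data.frame with plotId and dbhCm columns.
#' @return \code{plotAgbTable}: named vector of plot AGB (Mg/ha), one entry
#'   per row of \code{plots}.
#' @export
plotAgbTable <- function(plots, trees, coeffs = allometryCoefficients()) {
  out <- vapply(seq_len(nrow(plots)), function(i) {
    d <- trees$dbhCm[trees$plotId == plots$plotId[i]]
    if (length(d) == 0) 0 else plotAgb(d, plots$areaHa[i], coeffs)
  }, numeric(1))
  names(out) <- plots$plotId
  out
}

# (row, col) of the cells containing map points; NA outside the grid
.cellIndex <- function(g, x, y) {
  col <- floor((x - g@originX) / g@cellSize) + 1
  row <- floor((g@originY - y) / g@cellSize) + 1
  bad <- col < 1 | col > ncol(g@values) | row < 1 | row > nrow(g@values)
  row[bad] <- NA; col[bad] <- NA
  cbind(row = row, col = col)
}

#' Extract predictor values at plot locations
#'
#' Values are averaged over a small square neighbourhood around the cell
#' containing each plot centre (default \code{footprint = 1}, i.e. 3 x 3
#' cells): a 0.25-ha plot spans several 25-m pixels, so the footprint mean
#' is the natural support for matching plot AGB against raster predictors.
#' \code{footprint = 0} extracts the single containing cell.
#'
#' @param stack a [TextureStack-class] or named list of aligned [Grid-class]s.
#' @param plots data.frame with x, y (and plotId) columns.
#' @param footprint neighbourhood half-width in cells.
#' @return data.frame of predictor values, one row per plot.
#' @export
extractAtPlots <- function(stack, plots, footprint = 1) {
  layers <- if (is(stack, "TextureStack")) stack@layers else stack
  ref <- layers[[1]]
  rc <- .cellIndex(ref, plots$x, plots$y)
  nr <- nrow(ref@values); nc <- ncol(ref@values)
  out <- lapply(layers, function(g) {
    v <- g@values
    vapply(seq_len(nrow(rc)), function(i) {
      if (is.na(rc[i, 1])) return(NA_real_)
      rs <- max(1, rc[i, 1] - footprint):min(nr, rc[i, 1] + footprint)
      cs <- max(1, rc[i, 2] - footprint):min(nc, rc[i, 2] + footprint)
      mean(v[rs, cs], na.rm = TRUE)
    }, numeric(1))
  })
  df <- as.data.frame(out)
  if (!is.null(plots$plotId)) rownames(df) <- plots$plotId
  df
}

#' Remove highly correlated predictors
#'
#' Greedy correlation screening: while any pair of predictors has
#' \code{|r| >= threshold} (default 0.75), the member of the worst pair with
#' the larger mean absolute correlation to all remaining predictors is
#' dropped; exact ties drop the lexicographically later name, making the
#' procedure fully deterministic. Constant columns are uninformative
#' (undefined r) and are dropped first with a warning.
#'
#' @param table data.frame or matrix, plots x predictors (>= 2 predictors,
#'   >= 3 rows).
#' @param threshold absolute-correlation cut-off.
#' @return character vector of retained predictor names.
#' @export
screenPredictors <- function(table, threshold = 0.75) {
  X <- as.data.frame(table)
  if (ncol(X) < 2 || nrow(X) < 3)
    stop("need at least 2 predictors and 3 rows")
  sds <- vapply(X, function(col) sd(col, na.rm = TRUE), numeric(1))
  if (any(!is.finite(sds) | sds == 0)) {
    warning("dropping constant predictor(s): ",
            paste(names(X)[!is.finite(sds) | sds == 0], collapse = ", "))
    X <- X[, is.finite(sds) & sds > 0, drop = FALSE]
  }
  keep <- sort(names(X))
  repeat {
    if (length(keep) < 2) break
    C <- abs(cor(X[, keep, drop = FALSE], use = "pairwise.complete.obs"))
    diag(C) <- 0
    mx <- max(C)
    if (mx < threshold) break
    hit <- which(C == mx, arr.ind = TRUE)[1, ]
    pair <- keep[sort(hit)]
    meanAbs <- rowMeans(C)[pair]
    drop <- if (abs(diff(meanAbs)) > 1e-12) pair[which.max(meanAbs)]
            else max(pair)  # tie: lexicographically later name goes
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Log-log (power-law) regression for AGB
#'
#' Ordinary least squares of \eqn{\ln(AGB) = a + b \ln(X) + e} (multiple
#' predictors allowed). Back-transformed predictions use the half-variance
#' lognormal correction \eqn{\exp(\hat{y}) \exp(s^2/2)} by default; the
#' uncorrected back-transform is available via \code{biasCorrect = FALSE} in
#' \code{predict}.
#'
#' @param agb positive response values (Mg/ha).
#' @param predictors positive predictor vector, matrix or data.frame.
#' @return a \code{loglogFit} object with elements \code{coefficients}
#'   (intercept a, slopes b), \code{adjR2}, \code{sigma2} and the underlying
#'   \code{lm}.
#' @export
loglogFit <- function(agb, predictors) {
  X <- as.data.frame(predictors)
  if (ncol(X) == 1 && is.null(colnames(predictors))) names(X) <- "x"
  if (any(agb <= 0)) stop("AGB values must be positive on the log scale")
  if (any(as.matrix(X) <= 0)) stop("predictors must be positive on the log scale")
  lX <- log(X); names(lX) <- names(X)
  dat <- cbind(.lnAgb = log(agb), lX)
  fit <- lm(.lnAgb ~ ., data = dat)
  s2 <- sum(fit$residuals^2) / max(1, fit$df.residual)
  structure(list(coefficients = coef(fit),
                 adjR2 = summary(fit)$adj.r.squared,
                 sigma2 = s2, lm = fit),
            class = "loglogFit")
}

#' @rdname loglogFit
#' @param object a \code{loglogFit}.
#' @param newdata positive predictor values to predict for.
#' @param biasCorrect apply the exp(s^2/2) back-transform correction.
#' @param ... unused.
#' @export
predict.loglogFit <- function(object, newdata, biasCorrect = TRUE, ...) {
  X <- as.data.frame(newdata)
  vars <- names(object$lm$model)[-1]
  if (ncol(X) == 1 && !all(vars %in% names(X))) names(X) <- vars
  lp <- predict(object$lm, newdata = log(X))
  exp(lp) * if (biasCorrect) exp(object$sigma2 / 2) else 1
}

#' @export
print.loglogFit <- function(x, ...) {
  cat("log-log AGB model: ln(AGB) = a + b ln(X)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("adjusted R2 = %.4f, residual variance = %.4g\n",
              x$adjR2, x$sigma2))
  invisible(x)
}

#' Prediction accuracy metrics
#'
#' Pearson r, RMSE, MAE and percent bias
#' \eqn{100 \sum(p - o) / \sum o}. r is nodata (NA) when either side is
#' constant; the other metrics remain finite.
#'
#' @param observed,predicted paired numeric vectors.
#' @return named vector \code{c(r, rmse, mae, pctBias)}.
#' @export
accuracyMetrics <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  r <- if (length(o) > 1 && sd(o) > 0 && sd(p) > 0) cor(o, p) else NA_real_
  c(r = r,
    rmse = sqrt(mean((p - o)^2)),
    mae = mean(abs(p - o)),
    pctBias = 100 * sum(p - o) / sum(o))
}

#' Random-forest AGB model with ten-fold cross-validation
#'
#' Screens nothing by itself (combine with [screenPredictors()]); fits a
#' random-forest regression (500 trees), tuning the trees-per-split
#' parameter \code{mtry} over a small grid by cross-validated RMSE. Pooled
#' out-of-fold predictions give the honest r / RMSE / MAE / %bias; variable
#' importance is the out-of-bag permutation importance (%IncMSE) of the
#' final full-data forest, clamped at 0 and rescaled so the best predictor
#' scores 100. Fully deterministic given \code{seed}.
#'
#' @param table plots x predictors data.frame (numeric).
#' @param agb response vector (Mg/ha).
#' @param folds cross-validation folds (reduced with a warning when there
#'   are fewer plots than folds).
#' @param seed integer seed controlling fold assignment and forests.
#' @param ntree trees per forest.
#' @return an [AgbModelFit-class].
#' @export
rfFit <- function(table, agb, folds = 10, seed = 1, ntree = 500) {
  X <- as.data.frame(table)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 plots")
  if (n < folds) {
    warning("fewer plots than folds: reducing folds to ", n)
    folds <- n
  }
  p <- ncol(X)
  mtryGrid <- sort(unique(pmax(1, pmin(p, c(floor(p / 3), floor(p / 2), p)))))
  set.seed(seed)
  foldId <- sample(rep(seq_len(folds), length.out = n))
  cvPred <- matrix(NA_real_, n, length(mtryGrid))
  for (m in seq_along(mtryGrid)) {
    for (f in seq_len(folds)) {
      tr <- foldId != f
      set.seed(seed + 1000L * m + f)
      rf <- randomForest::randomForest(X[tr, , drop = FALSE], agb[tr],
                                       ntree = ntree, mtry = mtryGrid[m])
      cvPred[!tr, m] <- predict(rf, X[!tr, , drop = FALSE])
    }
  }
  cvRmse <- apply(cvPred, 2, function(pr) sqrt(mean((pr - agb)^2)))
  best <- which.min(cvRmse)
  pooled <- accuracyMetrics(agb, cvPred[, best])
  perFold <- do.call(rbind, lapply(seq_len(folds), function(f) {
    sel <- foldId == f
    as.data.frame(t(accuracyMetrics(agb[sel], cvPred[sel, best])))
  }))
  perFold$fold <- seq_len(folds)
  set.seed(seed)
  finalRf <- randomForest::randomForest(X, agb, ntree = ntree,
                                        mtry = mtryGrid[best],
                                        importance = TRUE)
  imp <- randomForest::importance(finalRf, type = 1)[, 1]
  imp[!is.finite(imp)] <- 0
  imp <- pmax(imp, 0)
  if (max(imp) > 0) imp <- imp / max(imp) * 100
  new("AgbModelFit",
      retainedPredictors = names(X),
      cvMetrics = list(pooled = pooled, perFold = perFold,
                       cvPredictions = cvPred[, best], folds = folds),
      importance = imp, model = finalRf,
      tuning = list(mtry = mtryGrid[best], mtryGrid = mtryGrid,
                    cvRmse = cvRmse, ntree = ntree, seed = seed))
}

#' @export
setMethod("show", "AgbModelFit", function(object) {
  m <- object@cvMetrics$pooled
  cat(sprintf("AgbModelFit: %d predictors, mtry = %d, %d-fold CV\n",
              length(object@retainedPredictors), object@tuning$mtry,
              object@cvMetrics$folds))
  cat(sprintf("  CV r = %.3f, RMSE = %.2f Mg/ha, MAE = %.2f Mg/ha, %%bias = %.2f\n",
              m["r"], m["rmse"], m["mae"], m["pctBias"]))
})

#' @describeIn rfFit pooled cross-validation metrics of a fit.
#' @param fit an [AgbModelFit-class].
#' @export
cvMetrics <- function(fit) fit@cvMetrics$pooled

#' @describeIn rfFit variable-importance scores (0-100) of a fit.
#' @export
importanceScores <- function(fit) fit@importance

#' Wall-to-wall AGB prediction from a texture stack
#'
#' Applies a fitted model to every cell of the stack. Cells where any
#' retained predictor is nodata are nodata. Random-forest predictions are
#' averages of training responses, so the map range is bounded by the range
#' of the training AGB values.
#'
#' @param fit an [AgbModelFit-class].
#' @param stack a [TextureStack-class] or named list of aligned grids
#'   containing every retained predictor.
#' @return [Grid-class] of predicted AGB.
#' @export
predictMap <- function(fit, stack) {
  layers <- if (is(stack, "TextureStack")) stack@layers else stack
  miss <- setdiff(fit@retainedPredictors, names(layers))
  if (length(miss)) stop("stack lacks predictors: ", paste(miss, collapse = ", "))
  ref <- layers[[fit@retainedPredictors[1]]]
  df <- as.data.frame(lapply(layers[fit@retainedPredictors],
                             function(g) as.vector(g@values)))
  names(df) <- fit@retainedPredictors
  out <- rep(NA_real_, nrow(df))
  okRows <- complete.cases(df)
  if (any(okRows))
    out[okRows] <- predict(fit@model, df[okRows, , drop = FALSE])
  grid(matrix(out, nrow(ref@values), ncol(ref@values)),
       ref@originX, ref@originY, ref@cellSize, ref@crsId, ref@nodata)
}

# moving-window Pearson correlation via summed-area tables; window of edge k
# is centred with the extra cell trailing (rows r-floor((k-1)/2) ..
# r+ceil((k-1)/2)); partial windows at the border use the available cells
.movingCor <- function(x, y, k) {
  nr <- nrow(x); nc <- ncol(x)
  ok <- is.finite(x) & is.finite(y)
  x0 <- ifelse(ok, x, 0); y0 <- ifelse(ok, y, 0)
  sat <- function(m) {
    s <- apply(m, 2, cumsum)
    t(apply(s, 1, cumsum))
  }
  lo <- floor((k - 1) / 2); hi <- k - 1 - lo
  r0 <- pmax(seq_len(nr) - lo, 1); r1 <- pmin(seq_len(nr) + hi, nr)
  c0 <- pmax(seq_len(nc) - lo, 1); c1 <- pmin(seq_len(nc) + hi, nc)
  rr0 <- rep(r0, times = nc); rr1 <- rep(r1, times = nc)
  cc0 <- rep(c0, each = nr); cc1 <- rep(c1, each = nr)
  win <- function(S) {
    Sp <- rbind(0, cbind(0, S))
    v <- Sp[cbind(rr1 + 1, cc1 + 1)] - Sp[cbind(rr0, cc1 + 1)] -
      Sp[cbind(rr1 + 1, cc0)] + Sp[cbind(rr0, cc0)]
    matrix(v, nr, nc)
  }
  n <- win(sat(ok * 1))
  sx <- win(sat(x0)); sy <- win(sat(y0))
  sxx <- win(sat(x0^2)); syy <- win(sat(y0^2)); sxy <- win(sat(x0 * y0))
  num <- n * sxy - sx * sy
  den <- sqrt(pmax(n * sxx - sx^2, 0) * pmax(n * syy - sy^2, 0))
  r <- num / den
  r[!is.finite(r) | n < 3] <- NA_real_
  list(r = r, n = n)
}

#' Fuse a local AGB map with a global product
#'
#' Kernel-correlation map fusion: for every cell of the (shared, 1-km) grid,
#' the Pearson correlation between the two maps is computed over moving
#' kernel windows of each configured size. A kernel contributes its
#' correlation only where that correlation is positive and exceeds the
#' one-sided 5 % critical value for the window's sample size (small windows
#' produce large spurious correlations by chance, so ungated weights would
#' lend unwarranted trust to an uninformative local map); zero-variance
#' windows contribute 0. The gated correlations are averaged across kernel
#' sizes into a weight \code{w} and the fused value is the convex
#' combination \code{w * local + (1 - w) * global}: the locally trusted map
#' dominates where the maps agree, and each fused cell lies within the
#' envelope of its two inputs.
#'
#' @param local local-scale AGB [Grid-class], already aggregated to the
#'   global grid.
#' @param globalMap global AGB [Grid-class] on the same geometry.
#' @param kernelSizes kernel window edges in cells.
#' @param alpha one-sided significance level of the correlation gate.
#' @return \code{list(fused = Grid, weight = Grid)}.
#' @export
fuseMaps <- function(local, globalMap, kernelSizes = c(4, 8, 16),
                     alpha = 0.05) {
  stopIfMisaligned(local, globalMap, "local and global maps")
  lv <- local@values; gv <- globalMap@values
  wAcc <- matrix(0, nrow(lv), ncol(lv))
  for (k in kernelSizes) {
    mc <- .movingCor(lv, gv, k)
    r <- mc$r
    r[!is.finite(r)] <- 0
    df <- pmax(mc$n - 2, 1)
    tc <- stats::qt(1 - alpha, df)
    rc <- tc / sqrt(df + tc^2)          # critical r per window
    r[r < rc] <- 0
    wAcc <- wAcc + r
  }
  w <- wAcc / length(kernelSizes)
  fused <- w * lv + (1 - w) * gv
  fused[is.na(lv)] <- gv[is.na(lv)]
  fused[is.na(gv)] <- lv[is.na(gv)]
  mk <- function(m) grid(m, local@originX, local@originY, local@cellSize,
                         local@crsId, local@nodata)
  list(fused = mk(fused), weight = mk(w))
}
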