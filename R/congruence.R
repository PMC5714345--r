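#' Define spatial weights for local statistics
#'
#' @param scheme \code{"fixed_distance_band"} (default; every cell whose
#'   centre lies within \code{bandDistance} metres is a neighbour with
#'   weight 1) or \code{"queen"} (the 8 surrounding cells).
#' @param bandDistance band radius in metres; the default 3000 m gives each
#'   interior cell of a 1-km grid about 28 neighbours plus itself.
#' @param includeSelf include the focal cell with weight 1 (the Gi* "star"
#'   form); \code{FALSE} gives plain Gi.
#' @return a [SpatialWeights-class].
#' @export
spatialWeights <- function(scheme = c("fixed_distance_band", "queen"),
                           bandDistance = 3000, includeSelf = TRUE) {
  scheme <- match.arg(scheme)
  new("SpatialWeights", scheme = scheme, bandDistance = bandDistance,
      includeSelf = isTRUE(includeSelf))
}

# neighbour offsets (dr, dc) implied by the weights on a given cell size
.weightOffsets <- function(weights, cellSize) {
  if (weights@scheme == "queen") {
    off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  } else {
    m <- floor(weights@bandDistance / cellSize)
    off <- as.matrix(expand.grid(dr = -m:m, dc = -m:m))
    keep <- (off[, 1]^2 + off[, 2]^2) * cellSize^2 <=
      weights@bandDistance^2 + 1e-9
    off <- off[keep, , drop = FALSE]
  }
  self <- off[, 1] == 0 & off[, 2] == 0
  if (!weights@includeSelf) off <- off[!self, , drop = FALSE]
  off
}

#' Getis-Ord Gi* hot/coldspot statistic
#'
#' For each cell i over the n non-nodata cells, with binary weights
#' \eqn{w_{ij}} (including \eqn{w_{ii} = 1} in the star form),
#' \eqn{W_i = \sum_j w_{ij}}, \eqn{C_i = \sum_j w_{ij}^2} and global mean
#' \eqn{\bar{X}} / population SD \eqn{S} including \eqn{x_i}:
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar{X} W_i}
#'   {S \sqrt{(n C_i - W_i^2) / (n - 1)}}}
#' Large positive z flags clustering of high values (hotspot), large
#' negative z clustering of low values (coldspot). Cells with a zero
#' denominator (e.g. a neighbourhood spanning all n cells) are nodata; a
#' constant field has S = 0 and returns all nodata with a warning. z-scores
#' are invariant under affine transforms of x.
#'
#' @param x a [Grid-class].
#' @param weights a [spatialWeights()]; each evaluated cell needs at least
#'   one neighbour.
#' @param alpha significance level stored for the default classification.
#' @return a [HotspotGrid-class] with z-scores and classes.
#' @export
giStar <- function(x, weights = spatialWeights(), alpha = 0.05) {
  v <- x@values
  ok <- is.finite(v)
  n <- sum(ok)
  if (n < 9) stop("need at least 9 non-nodata cells")
  xbar <- mean(v[ok])
  S <- sqrt(sum((v[ok] - xbar)^2) / n)  # population SD
  nr <- nrow(v); nc <- ncol(v)
  if (S == 0) {
    warning("constant field: Gi* undefined everywhere")
    z <- matrix(NA_real_, nr, nc)
  } else {
    off <- .weightOffsets(weights, x@cellSize)
    sumx <- .shiftAccum(ifelse(ok, v, 0), off)
    W <- .shiftAccum(ok * 1, off)
    den <- S * sqrt(pmax(n * W - W^2, 0) / (n - 1))
    z <- (sumx - xbar * W) / den
    z[!ok | den == 0 | W == 0] <- NA_real_
  }
  zg <- grid(z, x@originX, x@originY, x@cellSize, x@crsId, x@nodata)
  new("HotspotGrid", z = zg, classes = classifyHotspots(zg, alpha = alpha),
      alpha = alpha)
}

#' Classify z-scores into hotspot classes
#'
#' HOT (+1) where \eqn{z \ge z_{crit}(\alpha)}, COLD (-1) where
#' \eqn{z \le -z_{crit}}, otherwise not significant (0); nodata z stays
#' nodata. For AGB layers a value mask can be required on top of
#' significance: with \code{highMaskThreshold = 180} (the high-AGB
#' convention for the Asian tropics, Mg/ha) a significant cell only counts
#' as HOT when its value exceeds the threshold. \code{fdrCorrect = TRUE}
#' applies a Benjamini-Hochberg correction to the two-sided normal p-values
#' before thresholding at alpha; the default follows the raw-z convention
#' of hotspot mapping practice and never corrects.
#'
#' @param z a z-score [Grid-class] or a [HotspotGrid-class].
#' @param value value [Grid-class] used by the mask (required when
#'   \code{highMaskThreshold} is given).
#' @param highMaskThreshold optional value threshold for HOT cells.
#' @param alpha two-sided significance level.
#' @param fdrCorrect apply Benjamini-Hochberg control over the grid's cells.
#' @return classes [Grid-class] coded +1 / 0 / -1 (HOT / NS / COLD).
#' @export
classifyHotspots <- function(z, value = NULL, highMaskThreshold = NULL,
                             alpha = 0.05, fdrCorrect = FALSE) {
  if (is(z, "HotspotGrid")) z <- z@z
  zv <- z@values
  if (fdrCorrect) {
    ok <- is.finite(zv)
    p <- stats::p.adjust(2 * pnorm(-abs(zv[ok])), method = "BH")
    sig <- matrix(FALSE, nrow(zv), ncol(zv))
    sig[ok] <- p < alpha
    cls <- ifelse(sig & zv > 0, 1, ifelse(sig & zv < 0, -1, 0))
  } else {
    zcrit <- qnorm(1 - alpha / 2)
    cls <- ifelse(zv >= zcrit, 1, ifelse(zv <= -zcrit, -1, 0))
  }
  if (!is.null(highMaskThreshold)) {
    if (is.null(value)) stop("highMaskThreshold needs the value grid")
    stopIfMisaligned(z, value, "z and value grids")
    cls[cls == 1 & !(value@values > highMaskThreshold)] <- 0
  }
  cls[!is.finite(zv)] <- NA_real_
  grid(cls, z@originX, z@originY, z@cellSize, z@crsId, z@nodata)
}

#' @export
setMethod("show", "HotspotGrid", function(object) {
  cl <- object@classes@values
  cat(sprintf("HotspotGrid (alpha = %g): %d hot, %d cold, %d ns, %d nodata\n",
              object@alpha, sum(cl == 1, na.rm = TRUE),
              sum(cl == -1, na.rm = TRUE), sum(cl == 0, na.rm = TRUE),
              sum(!is.finite(cl))))
})

#' Percent area overlap of two hotspot class maps
#'
#' \code{100 * |cells in the class in both maps| / |denominator cells|}.
#' The default denominator is the union of the two class sets (symmetric in
#' the arguments); \code{"first"} / \code{"second"} divide by one map's
#' class set, \code{"study_area"} by all cells classified in both maps.
#'
#' @param a,b aligned class [Grid-class]s (or [HotspotGrid-class]s).
#' @param which \code{"HOT"} or \code{"COLD"}.
#' @param denominator denominator convention.
#' @return percent overlap in [0, 100], or NA (with a warning) when the
#'   denominator is empty.
#' @export
overlapPercent <- function(a, b, which = c("HOT", "COLD"),
                           denominator = c("union", "first", "second",
                                           "study_area")) {
  which <- match.arg(which)
  denominator <- match.arg(denominator)
  if (is(a, "HotspotGrid")) a <- a@classes
  if (is(b, "HotspotGrid")) b <- b@classes
  stopIfMisaligned(a, b, "class grids")
  code <- if (which == "HOT") 1 else -1
  av <- a@values; bv <- b@values
  inA <- av == code & is.finite(av)
  inB <- bv == code & is.finite(bv)
  den <- switch(denominator,
                union = sum(inA | inB),
                first = sum(inA),
                second = sum(inB),
                study_area = sum(is.finite(av) & is.finite(bv)))
  if (den == 0) {
    warning("empty denominator for ", which, " overlap")
    return(NA_real_)
  }
  100 * sum(inA & inB) / den
}

#' Spatially corrected correlation (Dutilleul's modified t-test)
#'
#' Pearson correlation between two aligned fields with the test adjusted
#' for spatial autocorrelation: the reported r always equals the plain
#' Pearson r (the correction touches only the degrees of freedom). The
#' variance of r is estimated from the two fields' spatial autocovariance
#' over distance classes,
#' \deqn{\widehat{var}(r) = \frac{1}{n^2}\Big(n + \sum_k S_k\,
#'   m_x(k)\, m_y(k)\Big)}
#' where \eqn{S_k} counts the (ordered) cell pairs in distance class k and
#' \eqn{m_x(k)} is the Moran autocorrelation of x at that class; the
#' effective sample size is \eqn{\hat{M} = 1 + 1/\widehat{var}(r)}, capped
#' at n. The statistic \eqn{t = r\sqrt{(\hat{M} - 2)/(1 - r^2)}} is
#' referred to Student's t with \eqn{\hat{M} - 2} degrees of freedom. For
#' independent fields \eqn{\hat{M} \approx n}; strong shared smoothness
#' deflates \eqn{\hat{M}} well below n.
#'
#' @param x,y aligned [Grid-class]s with at least 20 paired non-nodata
#'   cells.
#' @param nDistClasses number of equal-width distance classes; default is
#'   the Sturges rule on the pair count, capped at 30.
#' @return list with \code{r}, \code{effectiveDf} (\eqn{\hat{M} - 2}),
#'   \code{t}, \code{p}, \code{Mhat} and \code{n}.
#' @export
dutilleulCorrelation <- function(x, y, nDistClasses = NULL) {
  stopIfMisaligned(x, y, "x and y")
  xv <- as.vector(t(x@values)); yv <- as.vector(t(y@values))
  ok <- is.finite(xv) & is.finite(yv)
  n <- sum(ok)
  if (n < 20) stop("need at least 20 paired non-nodata cells")
  cc <- cellCenters(x)
  px <- rep(cc$x, times = nrow(x@values))[ok]
  py <- rep(cc$y, each = ncol(x@values))[ok]
  xs <- xv[ok] - mean(xv[ok]); ys <- yv[ok] - mean(yv[ok])
  r <- sum(xs * ys) / sqrt(sum(xs^2) * sum(ys^2))
  D <- as.matrix(stats::dist(cbind(px, py)))
  nPairs <- n * (n - 1) / 2
  K <- if (is.null(nDistClasses)) min(30, ceiling(log2(nPairs) + 1))
       else nDistClasses
  if (K < 3) stop("fewer than 3 distance classes supportable")
  offDiag <- upper.tri(D)
  breaks <- seq(0, max(D[offDiag]), length.out = K + 1)
  cls <- matrix(0L, n, n)
  cls[offDiag] <- pmin(K, findInterval(D[offDiag], breaks,
                                       left.open = TRUE, rightmost.closed = TRUE))
  XX <- outer(xs, xs); YY <- outer(ys, ys)
  vx <- sum(xs^2) / n; vy <- sum(ys^2) / n
  idx <- cls[offDiag]
  sk <- tabulate(idx, nbins = K) * 2                    # ordered pairs
  sxx <- numeric(K); syy <- numeric(K)
  xxOff <- XX[offDiag]; yyOff <- YY[offDiag]
  for (k in seq_len(K)) {
    sel <- idx == k
    sxx[k] <- 2 * sum(xxOff[sel]); syy[k] <- 2 * sum(yyOff[sel])
  }
  mX <- ifelse(sk > 0, sxx / sk, 0) / vx                # Moran per class
  mY <- ifelse(sk > 0, syy / sk, 0) / vy
  varR <- (n + sum(sk * mX * mY)) / n^2
  Mhat <- min(n, 1 + 1 / varR)
  effDf <- Mhat - 2
  t <- r * sqrt(effDf / (1 - r^2))
  p <- 2 * pt(-abs(t), df = effDf)
  list(r = r, effectiveDf = effDf, t = t, p = p, Mhat = Mhat, n = n)
}

#' Full AGB-richness congruence report
#'
#' Runs Gi* + classification on the 1-km AGB map (with the high-AGB value
#' mask) and on both richness strata, then computes HOT-HOT and COLD-COLD
#' percent overlaps for (AGB, IUCN) and (AGB, endemic) under all four
#' denominator conventions, plus Dutilleul-corrected correlations for both
#' pairs.
#'
#' @param agb1km fused/aggregated 1-km AGB [Grid-class].
#' @param richnessIucn,richnessEndemic 1-km richness [Grid-class]s.
#' @param weights a [spatialWeights()].
#' @param alpha significance level for hot/coldspots.
#' @param agbHighThreshold AGB mask (Mg/ha) required of AGB hotspots.
#' @return a [CongruenceReport-class].
#' @export
congruenceReport <- function(agb1km, richnessIucn, richnessEndemic,
                             weights = spatialWeights(), alpha = 0.05,
                             agbHighThreshold = 180) {
  hsAgb <- giStar(agb1km, weights, alpha)
  hsAgb@classes <- classifyHotspots(hsAgb@z, agb1km, agbHighThreshold, alpha)
  hsIucn <- giStar(richnessIucn, weights, alpha)
  hsEnd <- giStar(richnessEndemic, weights, alpha)
  pairs <- list(iucn = hsIucn, endemic = hsEnd)
  rows <- list()
  for (nm in names(pairs)) for (wh in c("HOT", "COLD"))
    for (dn in c("union", "first", "second", "study_area")) {
      ov <- suppressWarnings(
        overlapPercent(hsAgb, pairs[[nm]], wh, dn))
      rows[[length(rows) + 1]] <- data.frame(
        pair = paste0("agb-", nm), class = wh, denominator = dn,
        overlapPct = ov)
    }
  overlaps <- do.call(rbind, rows)
  corrs <- do.call(rbind, lapply(names(pairs), function(nm) {
    d <- dutilleulCorrelation(agb1km,
                              if (nm == "iucn") richnessIucn else richnessEndemic)
    data.frame(pair = paste0("agb-", nm), r = d$r, effectiveDf = d$effectiveDf,
               t = d$t, p = d$p, n = d$n)
  }))
  new("CongruenceReport",
      hotspots = list(agb = hsAgb, iucn = hsIucn, endemic = hsEnd),
      overlaps = overlaps, correlations = corrs,
      agbHighThreshold = agbHighThreshold)
}

#' @export
setMethod("show", "CongruenceReport", function(object) {
  cat("CongruenceReport (AGB high threshold =",
      object@agbHighThreshold, "Mg/ha)\n")
  un <- object@overlaps[object@overlaps$denominator == "union", ]
  for (i in seq_len(nrow(un)))
    cat(sprintf("  %s %s overlap (union): %.1f%%\n", un$pair[i], un$class[i],
                un$overlapPct[i]))
  for (i in seq_len(nrow(object@correlations)))
    cat(sprintf("  %s: r = %.3f (eff. df %.1f, p = %.3f)\n",
                object@correlations$pair[i], object@correlations$r[i],
                object@correlations$effectiveDf[i],
                object@correlations$p[i]))
})

#' @describeIn congruenceReport overlap table of a report.
#' @param report a [CongruenceReport-class].
#' @export
overlapTable <- function(report) report@overlaps

#' @describeIn congruenceReport corrected-correlation table of a report.
#' @export
correlationTable <- function(report) report@correlations
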