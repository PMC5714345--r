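#' Texture extraction settings
#'
#' Grey-level co-occurrence (GLCM) texture is extracted over a centred moving
#' window after linear min-max quantisation of the band. Defaults - 32 grey
#' levels, a 5 x 5 window, distance-1 offsets in the four standard directions
#' (0, 45, 90, 135 degrees) accumulated symmetrically - follow common
#' AGB-texture practice; every choice is exposed here.
#'
#' @param levels number of grey levels (>= 2).
#' @param window odd window edge length (>= 3).
#' @param offsets integer matrix of (dr, dc) displacements, one per row.
#' @param symmetric count each pair in both orders.
#' @param features which features to compute; subset of
#'   \code{c("mean", "variance", "homogeneity", "contrast", "dissimilarity",
#'   "entropy", "second_moment", "correlation")}.
#' @param firstOrder also include windowed mean/variance of the raw
#'   (unquantised) values as first-order statistics.
#' @return a \code{textureConfig} list.
#' @export
textureConfig <- function(levels = 32, window = 5,
                          offsets = rbind(c(0L, 1L), c(-1L, 1L),
                                          c(-1L, 0L), c(-1L, -1L)),
                          symmetric = TRUE,
                          features = c("mean", "variance", "homogeneity",
                                       "contrast", "dissimilarity", "entropy",
                                       "second_moment", "correlation"),
                          firstOrder = TRUE) {
  if (levels < 2) stop("levels must be >= 2")
  .checkWindow(window)
  offsets <- matrix(as.integer(offsets), ncol = 2)
  if (any(rowSums(abs(offsets)) == 0)) stop("offsets must be non-zero")
  features <- match.arg(features, several.ok = TRUE)
  structure(list(levels = as.integer(levels), window = as.integer(window),
                 offsets = offsets, symmetric = isTRUE(symmetric),
                 features = features, firstOrder = isTRUE(firstOrder)),
            class = "textureConfig")
}

#' Quantise a grid to integer grey levels
#'
#' Linear min-max binning into \code{0 .. levels - 1}: the grid minimum maps
#' to level 0 and the maximum to \code{levels - 1}. Monotone (x <= y implies
#' q(x) <= q(y)) and invariant to adding a constant to the input. Nodata is
#' preserved. A constant grid quantises to all zeros with a warning.
#'
#' @param g a [Grid-class].
#' @param levels number of grey levels.
#' @return [Grid-class] of integer levels.
#' @export
quantizeGrid <- function(g, levels = 32) {
  v <- g@values
  fin <- v[is.finite(v)]
  if (length(fin) == 0) stop("grid has no finite values")
  lo <- min(fin); hi <- max(fin)
  if (hi == lo) {
    warning("constant grid: quantised to all zeros")
    out <- ifelse(is.finite(v), 0, NA_real_)
  } else {
    out <- floor((v - lo) / (hi - lo) * levels)
    out <- pmin(out, levels - 1)
  }
  grid(out, g@originX, g@originY, g@cellSize, g@crsId, g@nodata)
}

#' Co-occurrence matrix of a quantised window
#'
#' Counts pairs of grey levels at each configured offset over the given
#' window, accumulates across offsets, symmetrises if configured, and
#' normalises to probabilities summing to 1. This is the plain per-window
#' reference implementation; [textureStack()] runs the equivalent compiled
#' moving-window version.
#'
#' @param windowValues integer matrix with values in \code{0 .. levels - 1}
#'   (NA allowed).
#' @param config a [textureConfig()].
#' @return \code{levels x levels} probability matrix.
#' @export
glcmMatrix <- function(windowValues, config = textureConfig()) {
  L <- config$levels
  m <- as.matrix(windowValues)
  if (any(m < 0 | m >= L, na.rm = TRUE))
    stop("window values must lie in 0 .. levels-1")
  nr <- nrow(m); nc <- ncol(m)
  span <- apply(abs(config$offsets), 2, max)
  if (nr <= span[1] || nc <= span[2])
    stop("window smaller than the offset span: empty co-occurrence matrix")
  P <- matrix(0, L, L)
  for (k in seq_len(nrow(config$offsets))) {
    dr <- config$offsets[k, 1]; dc <- config$offsets[k, 2]
    rs <- seq_len(nr)[(seq_len(nr) + dr) >= 1 & (seq_len(nr) + dr) <= nr]
    cs <- seq_len(nc)[(seq_len(nc) + dc) >= 1 & (seq_len(nc) + dc) <= nc]
    for (i in rs) for (j in cs) {
      a <- m[i, j]; b <- m[i + dr, j + dc]
      if (is.na(a) || is.na(b)) next
      P[a + 1, b + 1] <- P[a + 1, b + 1] + 1
      if (config$symmetric) P[b + 1, a + 1] <- P[b + 1, a + 1] + 1
    }
  }
  tot <- sum(P)
  if (tot == 0) stop("no valid pairs in window")
  P / tot
}

#' Haralick features of a co-occurrence matrix
#'
#' Standard definitions over a normalised GLCM \code{P} with marginals
#' \code{p_i}, \code{p_j}: mean \eqn{\mu = \sum_i i \, p_i}; variance
#' \eqn{\sum_i (i-\mu)^2 p_i}; homogeneity \eqn{\sum P/(1+(i-j)^2)}; contrast
#' \eqn{\sum (i-j)^2 P}; dissimilarity \eqn{\sum |i-j| P}; entropy
#' \eqn{-\sum P \ln P}; second moment (ASM) \eqn{\sum P^2}; correlation
#' \eqn{\sum (i-\mu_i)(j-\mu_j) P / (\sigma_i \sigma_j)} (nodata when
#' \eqn{\sigma_i \sigma_j = 0}). Grey-level indices start at 0.
#'
#' @param P normalised co-occurrence matrix (entries sum to 1).
#' @return named numeric vector of the eight features.
#' @export
haralickFeatures <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) stop("P must be normalised (sum to 1)")
  L <- nrow(P)
  lev <- 0:(L - 1)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  I <- matrix(lev, L, L); J <- matrix(lev, L, L, byrow = TRUE)
  mi <- sum(lev * pi_); mj <- sum(lev * pj_)
  vi <- sum((lev - mi)^2 * pi_); vj <- sum((lev - mj)^2 * pj_)
  pos <- P > 0
  cor <- if (sqrt(vi) * sqrt(vj) > 0)
    sum((I - mi) * (J - mj) * P) / (sqrt(vi) * sqrt(vj)) else NA_real_
  c(mean = mi,
    variance = vi,
    homogeneity = sum(P / (1 + (I - J)^2)),
    contrast = sum((I - J)^2 * P),
    dissimilarity = sum(abs(I - J) * P),
    entropy = -sum(P[pos] * log(P[pos])),
    second_moment = sum(P^2),
    correlation = cor)
}

#' Moving-window texture feature stack
#'
#' Quantises the band once over its global range, then computes the
#' configured Haralick features from the GLCM of the window centred on each
#' cell (compiled implementation; identical to applying [glcmMatrix()] +
#' [haralickFeatures()] to every window). Border cells with incomplete
#' windows are nodata. With \code{firstOrder = TRUE} the stack additionally
#' carries the windowed mean and variance of the raw values
#' (\code{<band>_fo_mean}, \code{<band>_fo_variance}).
#'
#' @param g source [Grid-class] (e.g. HV sigma-nought).
#' @param config a [textureConfig()].
#' @param bandName prefix for layer names (e.g. \code{"hv"}).
#' @return a [TextureStack-class].
#' @export
textureStack <- function(g, config = textureConfig(), bandName = "band") {
  if (config$window > min(dim(g@values)))
    stop("window larger than the grid")
  q <- quantizeGrid(g, config$levels)
  qi <- q@values
  storage.mode(qi) <- "integer"
  res <- .glcmStackCpp(qi, config$levels, config$window, config$offsets,
                       config$symmetric)
  mk <- function(m) grid(m, g@originX, g@originY, g@cellSize, g@crsId, g@nodata)
  layers <- list()
  for (f in config$features) layers[[paste0(bandName, "_", f)]] <- mk(res[[f]])
  if (config$firstOrder) {
    v <- g@values; ok <- is.finite(v)
    v0 <- ifelse(ok, v, 0)
    n <- .boxSum(ok * 1, config$window)
    m1 <- .boxSum(v0, config$window) / n
    m2 <- .boxSum(v0^2, config$window) / n
    vr <- pmax(m2 - m1^2, 0)
    m1[n == 0 | !is.finite(n)] <- NA_real_
    vr[n == 0 | !is.finite(n)] <- NA_real_
    layers[[paste0(bandName, "_fo_mean")]] <- mk(m1)
    layers[[paste0(bandName, "_fo_variance")]] <- mk(vr)
  }
  new("TextureStack", layers = layers, band = bandName)
}

#' @export
setMethod("show", "TextureStack", function(object) {
  cat(sprintf("TextureStack '%s': %d layers (%s)\n", object@band,
              length(object@layers),
              paste(names(object@layers), collapse = ", ")))
})

#' @describeIn textureStack extract one feature grid by name.
#' @param stack a [TextureStack-class].
#' @param name full layer name (e.g. \code{"hv_homogeneity"}).
#' @export
stackLayer <- function(stack, name) {
  if (!name %in% names(stack@layers)) stop("no such layer: ", name)
  stack@layers[[name]]
}
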