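#' Calibrate SAR digital numbers to sigma-nought
#'
#' Converts raw digital numbers (DN) of an L-band scene to the normalised
#' radar cross-section \eqn{\sigma^0 = 10 \log_{10}(DN^2) + CF} in dB, with
#' the sensor calibration factor \code{cf} defaulting to -83 dB. DN = 0 cells
#' become nodata (the log is undefined there); negative DN are rejected.
#' Calibration is strictly monotone in DN.
#'
#' @param dn [Grid-class] of non-negative digital numbers.
#' @param cf calibration factor in dB.
#' @return [Grid-class] of sigma-nought (dB).
#' @examples
#' g <- grid(matrix(c(1, 10, 0, 100), 2, 2))
#' gridValues(calibrateSigma0(g))  # -83, -63, NA, -43
#' @export
calibrateSigma0 <- function(dn, cf = -83) {
  if (!is.finite(cf)) stop("cf must be finite")
  v <- dn@values
  if (any(v < 0, na.rm = TRUE)) stop("negative DN values are not allowed")
  out <- 10 * log10(v^2) + cf
  out[!is.finite(out)] <- NA_real_
  grid(out, dn@originX, dn@originY, dn@cellSize, dn@crsId, dn@nodata)
}

#' Lee local-statistics speckle filter
#'
#' Reduces multiplicative speckle while preserving texture. For each cell,
#' \code{out = m + k (x - m)} with \code{m} the window mean and
#' \code{k = max(0, 1 - cu^2 / ci^2)}, where \code{ci} is the local
#' coefficient of variation and \code{cu = 1 / sqrt(enl)} the speckle
#' coefficient of variation for the assumed equivalent number of looks.
#' Homogeneous windows (\code{ci <= cu}) collapse to the window mean; strong
#' structure (\code{ci >> cu}) passes through. Nodata-aware; border cells
#' whose window leaves the grid are returned unfiltered.
#'
#' @param g [Grid-class] (amplitude or power domain).
#' @param window odd window edge (default 3).
#' @param enl assumed equivalent number of looks (default 4).
#' @return filtered [Grid-class].
#' @export
leeFilter <- function(g, window = 3, enl = 4) {
  window <- .checkWindow(window)
  v <- g@values
  ok <- is.finite(v)
  v0 <- ifelse(ok, v, 0)
  n <- .boxSum(ok * 1, window)
  s1 <- .boxSum(v0, window)
  s2 <- .boxSum(v0^2, window)
  m <- s1 / n
  varw <- pmax(s2 / n - m^2, 0)
  cu2 <- 1 / enl
  ci2 <- varw / m^2
  k <- pmax(1 - cu2 / ci2, 0)
  k[!is.finite(k) | varw == 0] <- 0
  out <- m + k * (v - m)
  out[!is.finite(m) | n == 0] <- v[!is.finite(m) | n == 0]  # borders untouched
  out[!ok] <- NA_real_
  grid(out, g@originX, g@originY, g@cellSize, g@crsId, g@nodata)
}

#' Construct a calibrated SAR scene
#'
#' @param hh,hv aligned sigma-nought [Grid-class]s (dB).
#' @param calibrationFactor calibration constant (dB) used upstream.
#' @return a [SarScene-class].
#' @export
sarScene <- function(hh, hv, calibrationFactor = -83) {
  new("SarScene", hh = hh, hv = hv, calibrationFactor = calibrationFactor)
}

#' @export
setMethod("show", "SarScene", function(object) {
  cat(sprintf("SarScene (CF = %g dB)\n", object@calibrationFactor))
  cat("  HH: "); show(object@hh)
  cat("  HV: "); show(object@hv)
})

#' Radar forest degradation index
#'
#' RFDI = (HH - HV) / (HH + HV). By default the ratio is formed on linear
#' power, \eqn{p = 10^{\sigma^0 / 10}} (a ratio of dB values is not
#' physically meaningful); \code{linearDomain = FALSE} computes it on the dB
#' values directly for sensitivity checks. On positive powers the index lies
#' in [-1, 1], is invariant to a common scaling of HH and HV, and decreases
#' as HV grows at fixed HH: degraded forests lose volume scattering, so
#' higher RFDI signals more degradation.
#'
#' @param scene a [SarScene-class].
#' @param linearDomain compute on linear power (default) or on dB.
#' @param eps denominators smaller than this in absolute value give nodata.
#' @return [Grid-class] of RFDI values.
#' @export
rfdi <- function(scene, linearDomain = TRUE, eps = 1e-12) {
  hh <- scene@hh@values; hv <- scene@hv@values
  if (linearDomain) {
    hh <- 10^(hh / 10); hv <- 10^(hv / 10)
  }
  den <- hh + hv
  out <- (hh - hv) / den
  out[!is.finite(out) | abs(den) < eps] <- NA_real_
  g <- scene@hh
  grid(out, g@originX, g@originY, g@cellSize, g@crsId, g@nodata)
}
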