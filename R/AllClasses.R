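#' @useDynLib agbird, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats approx coef complete.cases cor cor.test filter lm loess
#'   median na.omit pnorm predict pt qnorm quantile rbinom rexp rgamma rlnorm
#'   rnorm runif sd var aggregate
#' @importFrom utils head read.csv write.csv
NULL

#' Grid: a georeferenced raster lattice
#'
#' The universal raster currency of the package: digital numbers, backscatter,
#' texture features, above-ground biomass, richness counts and z-scores are all
#' carried as \code{Grid} objects. Values are stored as a numeric matrix in
#' row-major, north-up orientation (row 1 is the northernmost row); missing
#' cells are \code{NA} internally and only materialised as the \code{nodata}
#' sentinel on disk. Coordinates are in a projected, metric CRS: the centre of
#' cell \code{(r, c)} is \code{(originX + (c - 0.5) * cellSize,
#' originY - (r - 0.5) * cellSize)} where \code{(originX, originY)} is the
#' north-west corner of the raster.
#'
#' @slot values numeric matrix of cell values (\code{NA} = nodata).
#' @slot originX,originY map coordinates (m) of the north-west corner.
#' @slot cellSize cell edge length in metres (cells are square).
#' @slot crsId free-text identifier of the projected CRS.
#' @slot nodata sentinel written for \code{NA} cells on export.
#'
#' @seealso [grid()], [readGrid()], [writeGrid()], [aggregateGrid()]
#' @export
setClass("Grid",
  representation(values = "matrix", originX = "numeric", originY = "numeric",
                 cellSize = "numeric", crsId = "character", nodata = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
    if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
        object@cellSize <= 0) msg <- c(msg, "cellSize must be a single positive number")
    if (length(object@originX) != 1 || length(object@originY) != 1)
      msg <- c(msg, "origin must be a single coordinate pair")
    if (length(msg)) msg else TRUE
  })

#' VectorLayer: polylines or polygons with attributes
#'
#' Roads, rivers and species ranges are carried as \code{VectorLayer}s.
#' Each geometry is a list with fields \code{type} (\code{"polyline"} or
#' \code{"polygon"}) and \code{coords}: either a two-column coordinate matrix
#' (a single part; polygon rings need not repeat the first vertex) or a list
#' of such matrices (a multi-part geometry). Coordinates are in the same
#' projected CRS as the grids they are used with.
#'
#' @slot geometries list of geometry records (see Description).
#' @slot attributes data.frame with one row per geometry.
#' @slot crsId CRS identifier, matched against grids on use.
#' @export
setClass("VectorLayer",
  representation(geometries = "list", attributes = "data.frame",
                 crsId = "character"),
  validity = function(object) {
    if (nrow(object@attributes) > 0 &&
        nrow(object@attributes) != length(object@geometries))
      return("attributes must have one row per geometry")
    for (g in object@geometries) {
      if (!is.list(g) || is.null(g$type) || is.null(g$coords))
        return("each geometry needs $type and $coords")
      if (!g$type %in% c("polyline", "polygon"))
        return("geometry type must be 'polyline' or 'polygon'")
    }
    TRUE
  })

#' SarScene: a calibrated dual-polarisation SAR scene
#'
#' Holds aligned HH and HV backscatter grids (sigma-nought, dB) together with
#' the calibration factor that produced them.
#'
#' @slot hh,hv [Grid] of sigma-nought (dB) per polarisation.
#' @slot calibrationFactor calibration constant (dB) used in
#'   \code{sigma0 = 10 log10(DN^2) + CF}; the sensor standard is -83.
#' @export
setClass("SarScene",
  representation(hh = "Grid", hv = "Grid", calibrationFactor = "numeric"),
  validity = function(object) {
    if (!sameGeometry(object@hh, object@hv))
      return("hh and hv grids must share shape, origin and cell size")
    TRUE
  })

#' TextureStack: named, aligned texture-feature grids
#'
#' A named collection of [Grid]s, one per texture feature, all aligned to the
#' source band. Names are prefixed with the band (e.g. \code{hv_homogeneity}).
#'
#' @slot layers named list of aligned [Grid]s.
#' @slot band source band name used as the prefix.
#' @export
setClass("TextureStack",
  representation(layers = "list", band = "character"),
  validity = function(object) {
    if (length(object@layers) == 0) return("empty stack")
    if (is.null(names(object@layers)) || anyDuplicated(names(object@layers)))
      return("layers must be uniquely named")
    ref <- object@layers[[1]]
    for (g in object@layers)
      if (!sameGeometry(ref, g)) return("all layers must be aligned")
    TRUE
  })

#' SpeciesRange: one species' range polygons plus conservation metadata
#'
#' @slot speciesId species identifier.
#' @slot polygons list of polygon rings (two-column coordinate matrices),
#'   interpreted as a multipolygon (union of parts).
#' @slot iucnStatus one of CR, EN, VU, NT, LC.
#' @slot endemic logical flag for range-restricted (endemic) species.
#' @export
setClass("SpeciesRange",
  representation(speciesId = "character", polygons = "list",
                 iucnStatus = "character", endemic = "logical"),
  validity = function(object) {
    if (!object@iucnStatus %in% c("CR", "EN", "VU", "NT", "LC"))
      return("iucnStatus must be one of CR, EN, VU, NT, LC")
    if (length(object@polygons) < 1) return("range must have at least one polygon")
    TRUE
  })

#' PresenceAbsenceMatrix: binary cells-by-species table on a 1-km grid
#'
#' Rows index the cells of the template grid in row-major order
#' (\code{cellId = (row - 1) * ncol + col}); columns index species.
#'
#' @slot grid the 1-km template [Grid].
#' @slot pam binary matrix, cells x species.
#' @slot species data.frame with speciesId, iucnStatus, endemic per column.
#' @export
setClass("PresenceAbsenceMatrix",
  representation(grid = "Grid", pam = "matrix", species = "data.frame"),
  validity = function(object) {
    d <- dim(object@grid@values)
    if (nrow(object@pam) != d[1] * d[2])
      return("pam must have one row per template cell")
    if (ncol(object@pam) != nrow(object@species))
      return("pam must have one column per species")
    if (!all(object@pam %in% c(0, 1)))
      return("pam entries must be 0/1")
    TRUE
  })

#' SpatialWeights: binary neighbourhood definition for local statistics
#'
#' @slot scheme \code{"fixed_distance_band"} (all cells whose centre lies
#'   within \code{bandDistance} metres) or \code{"queen"} (the 8 surrounding
#'   cells).
#' @slot bandDistance band radius in metres (fixed-band scheme only).
#' @slot includeSelf if \code{TRUE} the focal cell has weight 1 (the
#'   "star" form of the Getis-Ord statistic).
#' @export
setClass("SpatialWeights",
  representation(scheme = "character", bandDistance = "numeric",
                 includeSelf = "logical"),
  validity = function(object) {
    if (!object@scheme %in% c("fixed_distance_band", "queen"))
      return("scheme must be 'fixed_distance_band' or 'queen'")
    if (object@scheme == "fixed_distance_band" &&
        (!is.finite(object@bandDistance) || object@bandDistance <= 0))
      return("bandDistance must be positive")
    TRUE
  })

#' HotspotGrid: Getis-Ord Gi* z-scores and hot/coldspot classes
#'
#' Classes are coded in the class grid as +1 (HOT), -1 (COLD), 0 (not
#' significant) and \code{NA} (nodata); see [classifyHotspots()].
#'
#' @slot z [Grid] of Gi* z-scores.
#' @slot classes [Grid] of class codes.
#' @slot alpha two-sided significance level behind the classes.
#' @export
setClass("HotspotGrid",
  representation(z = "Grid", classes = "Grid", alpha = "numeric"),
  validity = function(object) {
    if (!sameGeometry(object@z, object@classes))
      return("z and classes must be aligned")
    if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
    TRUE
  })

#' AgbModelFit: a cross-validated AGB model
#'
#' @slot retainedPredictors predictor names surviving correlation screening.
#' @slot cvMetrics list with pooled out-of-fold r, RMSE, MAE and %bias plus
#'   the per-fold table.
#' @slot importance named out-of-bag importance scores rescaled to [0, 100].
#' @slot model the fitted model object (opaque handle).
#' @slot tuning list of tuned hyper-parameters.
#' @export
setClass("AgbModelFit",
  representation(retainedPredictors = "character", cvMetrics = "list",
                 importance = "numeric", model = "ANY", tuning = "list"))

#' CongruenceReport: hotspot overlap and corrected correlation summary
#'
#' @slot hotspots named list of [HotspotGrid]s (agb, iucn, endemic).
#' @slot overlaps data.frame of percent overlaps (pair, class, denominator).
#' @slot correlations data.frame of Dutilleul-corrected correlations.
#' @slot agbHighThreshold AGB mask (Mg/ha) required of AGB hotspots.
#' @export
setClass("CongruenceReport",
  representation(hotspots = "list", overlaps = "data.frame",
                 correlations = "data.frame", agbHighThreshold = "numeric"))
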