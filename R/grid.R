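#' Create a Grid
#'
#' @param values numeric matrix, row 1 = northernmost row; \code{NA} = nodata.
#' @param originX,originY map coordinates (m) of the north-west corner.
#'   \code{originY} defaults to \code{nrow(values) * cellSize} so that the
#'   raster occupies positive y.
#' @param cellSize cell edge in metres; must be positive.
#' @param crsId projected-CRS identifier. Geographic (degree) rasters are not
#'   supported: all distances and areas in the package are metric.
#' @param nodata sentinel used for \code{NA} cells when writing to disk.
#' @return a [Grid-class] object.
#' @examples
#' g <- grid(matrix(1:9, 3, 3, byrow = TRUE), cellSize = 25)
#' gridValues(g)
#' @export
grid <- function(values, originX = 0, originY = NULL, cellSize = 25,
                 crsId = "local-metric", nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(originY)) originY <- nrow(values) * cellSize
  new("Grid", values = values, originX = originX, originY = originY,
      cellSize = cellSize, crsId = crsId, nodata = nodata)
}

#' @describeIn grid accessor for the value matrix.
#' @param x,g a [Grid-class].
#' @export
gridValues <- function(x) x@values

#' @describeIn grid replace the value matrix (geometry unchanged).
#' @param value replacement matrix of identical dimensions.
#' @export
`gridValues<-` <- function(x, value) {
  value <- as.matrix(value)
  if (!all(dim(value) == dim(x@values)))
    stop("replacement values must match grid dimensions")
  storage.mode(value) <- "double"
  x@values <- value
  x
}

#' @describeIn grid cell edge length in metres.
#' @export
cellSize <- function(x) x@cellSize

#' @describeIn grid map coordinates of the north-west corner.
#' @export
gridOrigin <- function(x) c(x = x@originX, y = x@originY)

#' @describeIn grid grid dimensions \code{c(nrow, ncol)}.
#' @export
gridDim <- function(x) dim(x@values)

#' @describeIn grid x coordinates of cell-column centres and y coordinates of
#'   cell-row centres, as \code{list(x =, y =)}.
#' @export
cellCenters <- function(g) {
  list(x = g@originX + (seq_len(ncol(g@values)) - 0.5) * g@cellSize,
       y = g@originY - (seq_len(nrow(g@values)) - 0.5) * g@cellSize)
}

#' @describeIn grid TRUE when two grids share shape, origin, cell size and CRS.
#' @param a,b grids to compare.
#' @export
sameGeometry <- function(a, b) {
  isTRUE(all(dim(a@values) == dim(b@values)) &&
    abs(a@originX - b@originX) < 1e-6 && abs(a@originY - b@originY) < 1e-6 &&
    abs(a@cellSize - b@cellSize) < 1e-9 && a@crsId == b@crsId)
}

stopIfMisaligned <- function(a, b, what = "grids") {
  if (!sameGeometry(a, b)) stop(what, " are not aligned (shape/origin/cellSize/crs)")
  invisible(TRUE)
}

#' @export
setMethod("show", "Grid", function(object) {
  v <- object@values
  fin <- v[is.finite(v)]
  cat(sprintf("Grid %d x %d @ %g m, origin (%g, %g), crs '%s'\n",
              nrow(v), ncol(v), object@cellSize, object@originX,
              object@originY, object@crsId))
  if (length(fin))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g (%d nodata)\n",
                min(fin), mean(fin), max(fin), sum(!is.finite(v))))
  else cat("  all nodata\n")
})

#' @export
setMethod("show", "VectorLayer", function(object) {
  cat(sprintf("VectorLayer: %d geometries (%s), crs '%s'\n",
              length(object@geometries),
              paste(unique(vapply(object@geometries, `[[`, "", "type")),
                    collapse = ", "),
              object@crsId))
})

# ---- file IO: ESRI ASCII grid + JSON sidecar for the CRS id ----------------

#' Read / write rasters as ESRI ASCII grids
#'
#' Rasters are exchanged as plain-text ESRI ASCII grids (.asc): a six-line
#' header (NCOLS, NROWS, XLLCORNER, YLLCORNER, CELLSIZE, NODATA_VALUE)
#' followed by the value block, north row first. The format is single-band
#' and square-pixel by construction; files carrying the DX/DY extension with
#' unequal pixel edges are rejected. The CRS identifier travels in a small
#' JSON sidecar (\code{<path>.aux.json}) and defaults to \code{local-metric}
#' when absent. A write-read round trip preserves the value block exactly
#' (values are printed with 9 significant digits) as well as the
#' geotransform and nodata sentinel.
#'
#' @param path file path of the .asc raster.
#' @return \code{readGrid} returns a [Grid-class]; \code{writeGrid} invisibly
#'   returns \code{path}.
#' @export
readGrid <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  lines <- readLines(path, n = 8)
  hdr <- list()
  nHeader <- 0
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[toupper(tok[1])]] <- as.numeric(tok[2])
      nHeader <- nHeader + 1
    } else break
  }
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE")
  if (!all(need %in% names(hdr)))
    stop("not a single-band ESRI ASCII grid (bad header): ", path)
  if (!is.null(hdr$DX) && !is.null(hdr$DY) && hdr$DX != hdr$DY)
    stop("non-square pixels (DX != DY) are not supported: ", path)
  nc <- hdr$NCOLS; nr <- hdr$NROWS
  nodata <- if (!is.null(hdr$NODATA_VALUE)) hdr$NODATA_VALUE else -9999
  vals <- scan(path, what = double(), skip = nHeader, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("value block has ", length(vals), " cells, expected ", nr * nc,
         " (multi-band or truncated file?): ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  crsId <- "local-metric"
  aux <- paste0(path, ".aux.json")
  if (file.exists(aux)) {
    meta <- jsonlite::read_json(aux)
    if (!is.null(meta$crs_id)) crsId <- meta$crs_id
  }
  grid(m, originX = hdr$XLLCORNER, originY = hdr$YLLCORNER + nr * hdr$CELLSIZE,
       cellSize = hdr$CELLSIZE, crsId = crsId, nodata = nodata)
}

#' @rdname readGrid
#' @param g a [Grid-class] to write.
#' @export
writeGrid <- function(g, path) {
  v <- g@values
  nr <- nrow(v); nc <- ncol(v)
  out <- v
  out[!is.finite(out)] <- g@nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("NCOLS", nc), paste("NROWS", nr),
    paste("XLLCORNER", formatC(g@originX, format = "g", digits = 12)),
    paste("YLLCORNER", formatC(g@originY - nr * g@cellSize,
                               format = "g", digits = 12)),
    paste("CELLSIZE", formatC(g@cellSize, format = "g", digits = 12)),
    paste("NODATA_VALUE", formatC(g@nodata, format = "g", digits = 12))), con)
  for (r in seq_len(nr))
    writeLines(paste(formatC(out[r, ], format = "g", digits = 9),
                     collapse = " "), con)
  jsonlite::write_json(list(crs_id = g@crsId), paste0(path, ".aux.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

# ---- grid algebra ----------------------------------------------------------

#' Block-aggregate a grid to a coarser resolution
#'
#' Aggregates \code{factor x factor} blocks of cells into one output cell, the
#' standard step for bringing 25-m layers to the 1-km analysis resolution.
#' Dimensions need not divide evenly: trailing partial blocks use the cells
#' available. \code{mean} and \code{sum} ignore nodata cells; \code{majority}
#' returns the most frequent class (ties broken by smallest class value). A
#' block that is entirely nodata stays nodata.
#'
#' @param g a [Grid-class].
#' @param factor positive integer aggregation factor.
#' @param stat one of \code{"mean"}, \code{"sum"}, \code{"majority"},
#'   \code{"circular_mean"} (for aspect-like layers in degrees).
#' @return a [Grid-class] with \code{cellSize * factor}.
#' @export
aggregateGrid <- function(g, factor, stat = c("mean", "sum", "majority",
                                              "circular_mean")) {
  stat <- match.arg(stat)
  if (length(factor) != 1 || !is.finite(factor) || factor < 1 ||
      factor != round(factor))
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  v <- g@values
  nr <- nrow(v); nc <- ncol(v)
  if (factor == 1L && stat %in% c("mean", "sum", "majority")) {
    return(g)
  }
  nbr <- ceiling(nr / factor); nbc <- ceiling(nc / factor)
  br <- (seq_len(nr) - 1L) %/% factor          # 0-based block row per row
  bc <- (seq_len(nc) - 1L) %/% factor
  idx <- outer(br * nbc, bc, "+") + 1L         # block id per cell, row-major
  vv <- as.vector(v); ii <- as.vector(idx)
  ok <- is.finite(vv)
  out <- rep(NA_real_, nbr * nbc)
  if (any(ok)) {
    if (stat == "mean" || stat == "sum") {
      s <- rowsum(vv[ok], ii[ok])
      n <- rowsum(rep(1, sum(ok)), ii[ok])
      ids <- as.integer(rownames(s))
      out[ids] <- if (stat == "mean") s / n else s
    } else if (stat == "majority") {
      sp <- split(vv[ok], ii[ok])
      out[as.integer(names(sp))] <- vapply(sp, function(z) {
        tb <- table(z)
        as.numeric(names(tb)[which.max(tb)])
      }, numeric(1))
    } else { # circular mean of degrees, clockwise from north
      rad <- vv[ok] * pi / 180
      s1 <- rowsum(sin(rad), ii[ok]); c1 <- rowsum(cos(rad), ii[ok])
      ids <- as.integer(rownames(s1))
      ang <- atan2(s1, c1) * 180 / pi
      out[ids] <- (ang + 360) %% 360
    }
  }
  grid(matrix(out, nbr, nbc, byrow = TRUE), originX = g@originX,
       originY = g@originY, cellSize = g@cellSize * factor,
       crsId = g@crsId, nodata = g@nodata)
}

#' Terrain slope and aspect (Horn's method)
#'
#' Slope and aspect from a metric DEM using Horn's 3x3 finite differences.
#' Slope is in degrees in [0, 90]; aspect is the downslope (facing) direction
#' in degrees clockwise from north in [0, 360). Flat cells and border cells
#' get nodata aspect; border cells get nodata slope.
#'
#' @param dem elevation [Grid-class] in metres (metric cell size).
#' @return \code{list(slope = Grid, aspect = Grid)}.
#' @export
slopeAspect <- function(dem) {
  v <- dem@values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3 || nc < 3) stop("DEM must be at least 3 x 3")
  cs <- dem@cellSize
  z <- function(dr, dc) v[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)]
  # compass neighbours of the interior cells
  a <- z(-1, -1); bN <- z(-1, 0); cNE <- z(-1, 1)
  d <- z(0, -1);               f <- z(0, 1)
  gSW <- z(1, -1); h <- z(1, 0); i <- z(1, 1)
  gx <- ((cNE + 2 * f + i) - (a + 2 * d + gSW)) / (8 * cs)   # d z / d east
  gy <- ((a + 2 * bN + cNE) - (gSW + 2 * h + i)) / (8 * cs)  # d z / d north
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  asp <- (atan2(-gx, -gy) * 180 / pi) %% 360                 # downslope azimuth
  asp[gx == 0 & gy == 0] <- NA_real_
  sl <- matrix(NA_real_, nr, nc); am <- matrix(NA_real_, nr, nc)
  sl[2:(nr - 1), 2:(nc - 1)] <- slope
  am[2:(nr - 1), 2:(nc - 1)] <- asp
  list(slope = grid(sl, dem@originX, dem@originY, cs, dem@crsId, dem@nodata),
       aspect = grid(am, dem@originX, dem@originY, cs, dem@crsId, dem@nodata))
}

# squared distance from points (px, py) to segment a-b, vectorised over points
.segDist2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return((px - ax)^2 + (py - ay)^2)
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
}

# even-odd point-in-polygon test for a single ring, vectorised over points
.pointInRing <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & is.finite(cross))
    j <- i
  }
  inside
}

.geometryParts <- function(geom) {
  if (is.matrix(geom$coords)) list(geom$coords) else geom$coords
}

#' Euclidean distance surface to the nearest vector feature
#'
#' For every cell of the template, the distance in metres from the cell centre
#' to the nearest geometry of the layer (e.g. distance to the nearest road).
#' Cells whose centre lies inside a polygon, or exactly on a feature, get 0.
#'
#' @param target a non-empty [VectorLayer-class].
#' @param template [Grid-class] defining the output lattice.
#' @return a [Grid-class] of distances (m).
#' @export
euclideanDistance <- function(target, template) {
  if (length(target@geometries) == 0) stop("empty vector layer")
  cc <- cellCenters(template)
  nr <- length(cc$y); nc <- length(cc$x)
  px <- rep(cc$x, each = nr)   # column-major over (row, col)
  py <- rep(cc$y, times = nc)
  best <- rep(Inf, length(px))
  for (geom in target@geometries) {
    for (part in .geometryParts(geom)) {
      m <- as.matrix(part)
      if (nrow(m) == 1) {
        best <- pmin(best, (px - m[1, 1])^2 + (py - m[1, 2])^2)
        next
      }
      segs <- if (geom$type == "polygon") rbind(m, m[1, , drop = FALSE]) else m
      for (k in seq_len(nrow(segs) - 1))
        best <- pmin(best, .segDist2(px, py, segs[k, 1], segs[k, 2],
                                     segs[k + 1, 1], segs[k + 1, 2]))
      if (geom$type == "polygon")
        best[.pointInRing(px, py, m)] <- 0
    }
  }
  grid(matrix(sqrt(best), nr, nc), template@originX, template@originY,
       template@cellSize, template@crsId, template@nodata)
}

# moving-window sum with stats::filter; borders (incomplete windows) come
# back NA, interiors are exact sums of the zero-filled input
.boxSum <- function(m, w) {
  k <- rep(1, w)
  f1 <- stats::filter(m, k, sides = 2)                 # down columns
  f2 <- t(apply(f1, 1, function(row) stats::filter(row, k, sides = 2)))
  matrix(as.numeric(f2), nrow(m), ncol(m))
}

.checkWindow <- function(window) {
  if (length(window) != 1 || window < 3 || window %% 2 != 1)
    stop("window must be an odd integer >= 3")
  as.integer(window)
}

#' Landscape diversity index (windowed Shannon diversity)
#'
#' Shannon diversity \eqn{H = -\sum_k p_k \ln p_k} of land-cover class
#' proportions within a centred moving window, a landscape-scale habitat
#' descriptor used as a richness predictor. Invariant to class relabelling;
#' 0 for a single-class window, \eqn{\ln k} for k equiprobable classes.
#' Border cells whose window leaves the grid are nodata.
#'
#' @param landcover categorical [Grid-class] (integer class codes).
#' @param window odd window edge length in cells (>= 3).
#' @return a [Grid-class] of H values.
#' @export
landscapeDiversity <- function(landcover, window = 5) {
  window <- .checkWindow(window)
  v <- landcover@values
  classes <- sort(unique(v[is.finite(v)]))
  valid <- is.finite(v) * 1
  tot <- .boxSum(valid, window)
  H <- matrix(0, nrow(v), ncol(v))
  for (k in classes) {
    cnt <- .boxSum((v == k & is.finite(v)) * 1, window)
    p <- cnt / tot
    term <- p * log(p)
    term[!is.finite(term)] <- 0
    H <- H - term
  }
  H[!is.finite(tot) | tot == 0] <- NA_real_
  grid(H, landcover@originX, landcover@originY, landcover@cellSize,
       landcover@crsId, landcover@nodata)
}

# sum of shifted copies of m over offsets (dr, dc), zero padding
.shiftAccum <- function(m, offsets) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    r0 <- max(1, 1 - dr); r1 <- min(nr, nr - dr)
    c0 <- max(1, 1 - dc); c1 <- min(nc, nc - dc)
    if (r0 > r1 || c0 > c1) next
    rs <- r0:r1; cs <- c0:c1
    acc[rs, cs] <- acc[rs, cs] + m[rs + dr, cs + dc]
  }
  acc
}

#' Landscape fragmentation index (windowed rook edge density)
#'
#' Fraction of rook-adjacent cell pairs inside the moving window whose
#' land-cover classes differ, in [0, 1]: 0 for a homogeneous window, 1 for a
#' perfect checkerboard. Higher values indicate greater habitat
#' heterogeneity. Border cells whose window leaves the grid are nodata.
#'
#' @inheritParams landscapeDiversity
#' @return a [Grid-class] of edge densities.
#' @export
landscapeFragmentation <- function(landcover, window = 5) {
  window <- .checkWindow(window)
  v <- landcover@values
  nr <- nrow(v); nc <- ncol(v)
  h <- (window - 1L) %/% 2L
  # pair grids: horizontal pairs indexed by their left cell, vertical by top
  diffH <- (v[, -nc, drop = FALSE] != v[, -1, drop = FALSE]) * 1
  okH <- (is.finite(v[, -nc, drop = FALSE]) & is.finite(v[, -1, drop = FALSE])) * 1
  diffH[okH == 0] <- 0
  diffV <- (v[-nr, , drop = FALSE] != v[-1, , drop = FALSE]) * 1
  okV <- (is.finite(v[-nr, , drop = FALSE]) & is.finite(v[-1, , drop = FALSE])) * 1
  diffV[okV == 0] <- 0
  offH <- as.matrix(expand.grid(dr = -h:h, dc = -h:(h - 1)))
  offV <- as.matrix(expand.grid(dr = -h:(h - 1), dc = -h:h))
  num <- den <- matrix(0, nr, nc)
  pad <- function(m) { out <- matrix(0, nr, nc); out[seq_len(nrow(m)), seq_len(ncol(m))] <- m; out }
  # left cell of a horizontal pair at (r, c) participates in windows centred
  # at rows r-h..r+h, cols c-h..c+h-1 is handled by accumulating shifted pads
  num <- .shiftAccum(pad(diffH), offH) + .shiftAccum(pad(diffV), offV)
  den <- .shiftAccum(pad(okH), offH) + .shiftAccum(pad(okV), offV)
  out <- num / den
  out[den == 0] <- NA_real_
  if (h > 0) { # nodata where the window leaves the grid
    out[c(seq_len(h), (nr - h + 1):nr), ] <- NA_real_
    out[, c(seq_len(h), (nc - h + 1):nc)] <- NA_real_
  }
  grid(out, landcover@originX, landcover@originY, landcover@cellSize,
       landcover@crsId, landcover@nodata)
}
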