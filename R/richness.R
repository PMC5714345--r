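#' Create a SpeciesRange
#'
#' @param speciesId species identifier.
#' @param polygons one polygon ring (two-column matrix, open) or a list of
#'   rings forming a multipolygon.
#' @param iucnStatus IUCN Red List category: CR, EN, VU, NT or LC.
#' @param endemic endemic (range-restricted) flag.
#' @return a [SpeciesRange-class].
#' @export
speciesRange <- function(speciesId, polygons, iucnStatus = "LC",
                         endemic = FALSE) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  new("SpeciesRange", speciesId = as.character(speciesId),
      polygons = polygons, iucnStatus = iucnStatus, endemic = isTRUE(endemic))
}

#' @export
setMethod("show", "SpeciesRange", function(object) {
  cat(sprintf("SpeciesRange %s [%s%s]: %d polygon part(s)\n",
              object@speciesId, object@iucnStatus,
              if (object@endemic) ", endemic" else "",
              length(object@polygons)))
})

# signed (shoelace) area of an open ring
.ringArea <- function(ring) {
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2)
}

# Sutherland-Hodgman clip of a simple ring against an axis-aligned rectangle
.clipRingToRect <- function(ring, xmin, xmax, ymin, ymax) {
  clipEdge <- function(poly, inside, intersect) {
    if (nrow(poly) == 0) return(poly)
    out <- matrix(numeric(0), 0, 2)
    n <- nrow(poly)
    for (i in seq_len(n)) {
      cur <- poly[i, ]; prev <- poly[if (i == 1) n else i - 1, ]
      curIn <- inside(cur); prevIn <- inside(prev)
      if (curIn) {
        if (!prevIn) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prevIn) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, xv) { t <- (xv - p[1]) / (q[1] - p[1]); c(xv, p[2] + t * (q[2] - p[2])) }
  iy <- function(p, q, yv) { t <- (yv - p[2]) / (q[2] - p[2]); c(p[1] + t * (q[1] - p[1]), yv) }
  poly <- ring
  poly <- clipEdge(poly, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin))
  poly <- clipEdge(poly, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax))
  poly <- clipEdge(poly, function(p) p[2] >= ymin, function(p, q) iy(p, q, ymin))
  poly <- clipEdge(poly, function(p) p[2] <= ymax, function(p, q) iy(p, q, ymax))
  poly
}

# area of ring intersected with a rectangle (cells are closed rectangles;
# zero-area boundary touching contributes 0 by construction)
.ringRectArea <- function(ring, xmin, xmax, ymin, ymax) {
  clipped <- .clipRingToRect(ring, xmin, xmax, ymin, ymax)
  if (nrow(clipped) < 3) return(0)
  .ringArea(clipped)
}

#' Build a presence-absence matrix from species ranges
#'
#' Rasterises every species' range polygons onto the 1-km template: a cell
#' is scored present (1) when the intersection area of the range with the
#' closed cell rectangle exceeds \code{minCover} times the cell area.
#' The default \code{minCover = 0} counts any overlap of positive area,
#' mirroring the presence-absence tooling the richness literature uses;
#' boundary contact of zero area never counts.
#'
#' @param ranges list of [SpeciesRange-class].
#' @param template 1-km [Grid-class] (cell size 1000 m) in the ranges' CRS.
#' @param minCover minimum covered fraction of a cell in [0, 1).
#' @param crsId CRS the ranges are expressed in, checked against the
#'   template.
#' @return a [PresenceAbsenceMatrix-class].
#' @export
buildPam <- function(ranges, template, minCover = 0,
                     crsId = template@crsId) {
  if (!identical(crsId, template@crsId))
    stop("CRS mismatch between ranges (", crsId, ") and template (",
         template@crsId, ")")
  if (abs(template@cellSize - 1000) > 1e-6)
    stop("template must be a 1-km grid (cellSize 1000 m)")
  nr <- nrow(template@values); nc <- ncol(template@values)
  cs <- template@cellSize
  cellArea <- cs * cs
  pam <- matrix(0, nr * nc, length(ranges))
  xl <- template@originX + (seq_len(nc) - 1) * cs
  yt <- template@originY - (seq_len(nr) - 1) * cs
  for (s in seq_along(ranges)) {
    rg <- ranges[[s]]
    for (ring in rg@polygons) {
      ring <- as.matrix(ring)
      if (nrow(ring) < 3) stop("invalid polygon (fewer than 3 vertices)")
      bb <- c(range(ring[, 1]), range(ring[, 2]))
      cMin <- max(1, floor((bb[1] - template@originX) / cs) + 1)
      cMax <- min(nc, ceiling((bb[2] - template@originX) / cs))
      rMin <- max(1, floor((template@originY - bb[4]) / cs) + 1)
      rMax <- min(nr, ceiling((template@originY - bb[3]) / cs))
      if (cMin > cMax || rMin > rMax) next
      for (r in rMin:rMax) for (cl in cMin:cMax) {
        a <- .ringRectArea(ring, xl[cl], xl[cl] + cs, yt[r] - cs, yt[r])
        if (a > max(minCover * cellArea, cellArea * 1e-12)) {
          pam[(r - 1) * nc + cl, s] <- 1
        }
      }
    }
  }
  species <- data.frame(
    speciesId = vapply(ranges, function(r) r@speciesId, ""),
    iucnStatus = vapply(ranges, function(r) r@iucnStatus, ""),
    endemic = vapply(ranges, function(r) r@endemic, TRUE),
    stringsAsFactors = FALSE)
  new("PresenceAbsenceMatrix", grid = template, pam = pam, species = species)
}

#' @export
setMethod("show", "PresenceAbsenceMatrix", function(object) {
  cat(sprintf("PresenceAbsenceMatrix: %d cells x %d species (%d presences)\n",
              nrow(object@pam), ncol(object@pam), sum(object@pam)))
})

#' @describeIn buildPam the binary cells-by-species matrix.
#' @param pam a [PresenceAbsenceMatrix-class].
#' @export
pamMatrix <- function(pam) pam@pam

#' @describeIn buildPam the species metadata table.
#' @export
pamSpecies <- function(pam) pam@species

#' @describeIn buildPam export the PAM as a CSV table (cellId, x, y, one
#'   column per species).
#' @param path CSV path to write.
#' @export
writePamCsv <- function(pam, path) {
  nr <- nrow(pam@grid@values); nc <- ncol(pam@grid@values)
  cc <- cellCenters(pam@grid)
  # row-major cell order: row 1 (northernmost) cells first
  df <- data.frame(cellId = seq_len(nr * nc),
                   x = rep(cc$x, times = nr),
                   y = rep(cc$y, each = nc))
  m <- as.data.frame(pam@pam)
  names(m) <- pam@species$speciesId
  write.csv(cbind(df, m), path, row.names = FALSE)
  invisible(path)
}

#' Species richness grid from a presence-absence matrix
#'
#' Sums presences per cell over the species passing a filter. Built-in
#' filters match the study strata: \code{"all"}; \code{"iucn"} = IUCN-listed
#' conservation-dependent species (CR, EN, VU, NT); \code{"endemic"};
#' \code{"nonendemic"}. A function of the species data.frame returning a
#' logical vector selects any other stratum. Richness is monotone under
#' adding species and bounded by the species count; cellwise,
#' richness(all) = richness(endemic) + richness(nonendemic).
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param filter stratum name or predicate function.
#' @return [Grid-class] of species counts on the template geometry.
#' @export
richnessGrid <- function(pam, filter = "all") {
  sp <- pam@species
  sel <- if (is.function(filter)) filter(sp)
  else switch(filter,
              all = rep(TRUE, nrow(sp)),
              iucn = sp$iucnStatus %in% c("CR", "EN", "VU", "NT"),
              endemic = sp$endemic,
              nonendemic = !sp$endemic,
              stop("unknown filter: ", filter))
  counts <- if (any(sel)) rowSums(pam@pam[, sel, drop = FALSE]) else
    rep(0, nrow(pam@pam))
  g <- pam@grid
  grid(matrix(counts, nrow(g@values), ncol(g@values), byrow = TRUE),
       g@originX, g@originY, g@cellSize, g@crsId, g@nodata)
}
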