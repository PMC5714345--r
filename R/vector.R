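#' Create a VectorLayer
#'
#' @param geometries list of geometry records: each a list with \code{type}
#'   ("polyline" or "polygon") and \code{coords} (a two-column coordinate
#'   matrix, or a list of such matrices for multi-part geometries; polygon
#'   rings are open, i.e. the first vertex is not repeated).
#' @param attributes data.frame with one row per geometry (may be empty).
#' @param crsId projected-CRS identifier; matched against grids on use.
#' @return a [VectorLayer-class].
#' @export
vectorLayer <- function(geometries, attributes = data.frame(), crsId = "local-metric") {
  new("VectorLayer", geometries = geometries, attributes = attributes,
      crsId = crsId)
}

.closeRing <- function(m) rbind(m, m[1, , drop = FALSE])
.openRing <- function(m) {
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m[-nrow(m), , drop = FALSE] else m
}

.coordsToJson <- function(m) lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))

#' Read / write vector layers as GeoJSON
#'
#' Polylines map to LineString/MultiLineString, polygons to
#' Polygon/MultiPolygon (outer rings only; holes are not supported). Feature
#' properties become the layer's attribute table. The CRS identifier is
#' stored under the FeatureCollection's \code{crs_id} member.
#'
#' @param path GeoJSON file path.
#' @return \code{readVector} returns a [VectorLayer-class]; \code{writeVector}
#'   invisibly returns \code{path}.
#' @export
readVector <- function(path) {
  if (!file.exists(path)) stop("no such vector file: ", path)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(js$features)) stop("not a GeoJSON FeatureCollection: ", path)
  geoms <- list(); rows <- list()
  toMat <- function(coords)
    do.call(rbind, lapply(coords, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  for (ft in js$features) {
    gj <- ft$geometry
    geom <- switch(gj$type,
      LineString = list(type = "polyline", coords = toMat(gj$coordinates)),
      MultiLineString = list(type = "polyline",
                             coords = lapply(gj$coordinates, toMat)),
      Polygon = list(type = "polygon",
                     coords = .openRing(toMat(gj$coordinates[[1]]))),
      MultiPolygon = list(type = "polygon",
                          coords = lapply(gj$coordinates,
                                          function(p) .openRing(toMat(p[[1]])))),
      stop("unsupported GeoJSON geometry type: ", gj$type))
    geoms[[length(geoms) + 1]] <- geom
    props <- ft$properties
    rows[[length(rows) + 1]] <-
      if (length(props)) as.data.frame(lapply(props, function(z) if (is.null(z)) NA else z))
      else data.frame(row.names = 1)[0, , drop = FALSE]
  }
  attrs <- if (length(rows) && ncol(rows[[1]]) > 0) do.call(rbind, rows) else data.frame()
  crsId <- if (!is.null(js$crs_id)) js$crs_id else "local-metric"
  vectorLayer(geoms, attrs, crsId)
}

#' @rdname readVector
#' @param layer a [VectorLayer-class] to write.
#' @export
writeVector <- function(layer, path) {
  features <- lapply(seq_along(layer@geometries), function(i) {
    geom <- layer@geometries[[i]]
    parts <- .geometryParts(geom)
    gj <- if (geom$type == "polyline") {
      if (length(parts) == 1)
        list(type = "LineString", coordinates = .coordsToJson(parts[[1]]))
      else list(type = "MultiLineString",
                coordinates = lapply(parts, .coordsToJson))
    } else {
      if (length(parts) == 1)
        list(type = "Polygon",
             coordinates = list(.coordsToJson(.closeRing(parts[[1]]))))
      else list(type = "MultiPolygon",
                coordinates = lapply(parts, function(p)
                  list(.coordsToJson(.closeRing(p)))))
    }
    props <- if (nrow(layer@attributes) >= i)
      as.list(layer@attributes[i, , drop = FALSE]) else structure(list(), names = character(0))
    list(type = "Feature", geometry = gj, properties = props)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", crs_id = layer@crsId, features = features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert species ranges to a VectorLayer (and back)
#'
#' @param ranges list of [SpeciesRange-class] objects.
#' @param crsId CRS identifier for the layer.
#' @return a [VectorLayer-class] with speciesId, iucnStatus and endemic
#'   attributes.
#' @export
rangesToLayer <- function(ranges, crsId = "local-metric") {
  geoms <- lapply(ranges, function(rg) list(type = "polygon", coords = rg@polygons))
  attrs <- data.frame(
    speciesId = vapply(ranges, function(r) r@speciesId, ""),
    iucnStatus = vapply(ranges, function(r) r@iucnStatus, ""),
    endemic = vapply(ranges, function(r) r@endemic, TRUE),
    stringsAsFactors = FALSE)
  vectorLayer(geoms, attrs, crsId)
}

#' @rdname rangesToLayer
#' @param layer a [VectorLayer-class] carrying range polygons.
#' @export
layerToRanges <- function(layer) {
  lapply(seq_along(layer@geometries), function(i) {
    geom <- layer@geometries[[i]]
    new("SpeciesRange",
        speciesId = as.character(layer@attributes$speciesId[i]),
        polygons = .geometryParts(geom),
        iucnStatus = as.character(layer@attributes$iucnStatus[i]),
        endemic = as.logical(layer@attributes$endemic[i]))
  })
}
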