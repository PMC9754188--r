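# Geometry serialization: WKT for the tile CSV, GeoJSON for vector layers.
# Coordinates are written with 17 significant digits so every read/write
# round-trip is lossless at double precision.

fmt_num <- function(x) {
  s <- formatC(x, format = "g", digits = 17)
  gsub(" ", "", s)
}

#' Format a polygon as WKT
#' @param poly two-column vertex matrix (unclosed ring).
#' @return `POLYGON ((...))` string; closing vertex added on output.
#' @export
wkt_polygon <- function(poly) {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  coords <- paste(fmt_num(ring[, 1]), fmt_num(ring[, 2]), collapse = ", ")
  paste0("POLYGON ((", coords, "))")
}

#' Parse a WKT POLYGON (outer ring only)
#' @param wkt string like `POLYGON ((x y, x y, ...))`.
#' @return two-column vertex matrix with the duplicated closing vertex removed.
#' @export
parse_wkt_polygon <- function(wkt) {
  body <- sub("^\\s*POLYGON\\s*\\(\\(", "", wkt)
  body <- sub("\\)\\).*$", "", body)
  parts <- strsplit(strsplit(body, ",")[[1]], "\\s+")
  m <- t(vapply(parts, function(p) as.numeric(p[nzchar(p)]), numeric(2)))
  colnames(m) <- c("x", "y")
  n <- nrow(m)
  if (n > 1 && all(abs(m[1, ] - m[n, ]) < 1e-12)) m <- m[-n, , drop = FALSE]
  m
}

geojson_coords_polygon <- function(poly) {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  list(lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2])))
}

geojson_coords_linestring <- function(line) {
  lapply(seq_len(nrow(line)), function(i) c(line[i, 1], line[i, 2]))
}

feature <- function(geom_type, coords, props) {
  list(type = "Feature",
       geometry = list(type = geom_type, coordinates = coords),
       properties = props)
}

#' Write a GeoJSON FeatureCollection
#'
#' @param features list of features built internally (polygon or linestring).
#' @param path output path.
#' @export
write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection
#'
#' @param path GeoJSON file path.
#' @return list with one element per feature: `geometry` (vertex matrix),
#'   `type` ("Polygon" or "LineString"), and `properties` (named list).
#' @export
read_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(fc$features, function(f) {
    ty <- f$geometry$type
    if (ty == "Polygon") {
      ring <- f$geometry$coordinates[[1]]
      m <- t(vapply(ring, function(p) c(p[[1]], p[[2]]), numeric(2)))
      n <- nrow(m)
      if (n > 1 && all(abs(m[1, ] - m[n, ]) < 1e-12)) m <- m[-n, , drop = FALSE]
    } else if (ty == "LineString") {
      m <- t(vapply(f$geometry$coordinates, function(p) c(p[[1]], p[[2]]), numeric(2)))
    } else {
      stop("unsupported geometry type: ", ty)
    }
    colnames(m) <- c("x", "y")
    list(type = ty, geometry = m, properties = lapply(f$properties, identity))
  })
}

#' Write activity tiles to CSV
#'
#' Columns: cell_id, wkt_geometry, month, day_stratum, window_start_hour,
#' activity_index. Sub-threshold records are absent, never zero.
#'
#' @param tiles data.frame of activity records (see [render_activity_tiles()]).
#' @param path output CSV path.
#' @export
write_tiles_csv <- function(tiles, path) {
  out <- tiles[, c("cell_id", "wkt_geometry", "month", "day_stratum",
                   "window_start_hour", "activity_index")]
  out$activity_index <- fmt_num(out$activity_index)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read activity tiles from CSV
#' @param path CSV written by [write_tiles_csv()].
#' @return data.frame with parsed numeric activity_index.
#' @export
read_tiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$activity_index <- as.numeric(df$activity_index)
  df
}
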