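# Activity-cell handling: parsing tile records into cell objects, clipping
# them to green-space polygons, and trail intersection tests.

#' Construct a green-space object
#'
#' @param id identifier.
#' @param geometry convex polygon (two-column vertex matrix).
#' @param name display name.
#' @param land_type one of Conservation Area, Natural Area, Reserve Area,
#'   Other.
#' @param managed logical.
#' @param reservations_required logical.
#' @param repair how to treat an invalid (non-convex or self-intersecting)
#'   polygon: "reject" (default, error) or "hull" (replace by its convex
#'   hull).
#' @return object of class `green_space`; `area` is computed from geometry.
#' @export
green_space <- function(id, geometry, name = id, land_type = "Conservation Area",
                        managed = TRUE, reservations_required = FALSE,
                        repair = c("reject", "hull")) {
  repair <- match.arg(repair)
  if (!poly_is_convex(geometry)) {
    if (repair == "hull") {
      geometry <- geometry[grDevices::chull(geometry[, 1], geometry[, 2]), ,
                           drop = FALSE]
    } else {
      stop("green space ", id, " polygon is not convex/simple; ",
           "pass repair = \"hull\" to replace it by its convex hull")
    }
  }
  geometry <- poly_ccw(geometry)
  a <- poly_area(geometry)
  if (a <= 0) stop("green space ", id, " has zero area")
  structure(list(id = id, name = name, geometry = geometry, area = a,
                 land_type = land_type, managed = managed,
                 reservations_required = reservations_required),
            class = "green_space")
}

#' Parse tile records into activity cells
#'
#' @param tiles data.frame as produced by [render_activity_tiles()] or
#'   [read_tiles_csv()].
#' @return list of `activity_cell` objects: one per record, geometry parsed
#'   from WKT, `clipped_geometry` unset until [clip_cells()].
#' @export
tiles_to_cells <- function(tiles) {
  stopifnot(all(c("cell_id", "wkt_geometry", "month", "day_stratum",
                  "window_start_hour", "activity_index") %in% names(tiles)))
  if (any(tiles$activity_index <= 0))
    stop("activity_index must be strictly positive: suppressed records are absent, never zero")
  geos <- lapply(unique(tiles$wkt_geometry), parse_wkt_polygon)
  names(geos) <- unique(tiles$wkt_geometry)
  lapply(seq_len(nrow(tiles)), function(i) {
    structure(list(cell_id = tiles$cell_id[i],
                   geometry = geos[[tiles$wkt_geometry[i]]],
                   clipped_geometry = NULL,
                   activity_index = tiles$activity_index[i],
                   month = tiles$month[i],
                   day_stratum = tiles$day_stratum[i],
                   window_start_hour = tiles$window_start_hour[i]),
              class = "activity_cell")
  })
}

#' Clip activity cells to a green space
#'
#' Keeps only cells whose geometry has a positive-area intersection with the
#' property polygon; `clipped_geometry` is set to the intersection and the
#' activity index is left untouched (it always describes the full cell; the
#' area weighting happens in the metrics). Boundary-touching cells (zero-area
#' intersection) are dropped, since area-weighted metrics give them no weight.
#'
#' @param cells list of `activity_cell`.
#' @param space a `green_space` (convex polygon).
#' @return filtered list with `clipped_geometry` set.
#' @export
clip_cells <- function(cells, space) {
  stopifnot(inherits(space, "green_space"))
  if (length(cells) == 0) return(list())
  # records share cell geometries across months/windows: clip each distinct
  # cell id once, with a bbox prefilter against the property
  ids <- vapply(cells, function(c) as.character(c$cell_id), character(1))
  first <- match(unique(ids), ids)
  sb <- poly_bbox(space$geometry)
  cache <- new.env(parent = emptyenv())
  for (i in first) {
    g <- cells[[i]]$geometry
    gb <- poly_bbox(g)
    inter <- if (gb["xmin"] >= sb["xmax"] || gb["xmax"] <= sb["xmin"] ||
                 gb["ymin"] >= sb["ymax"] || gb["ymax"] <= sb["ymin"]) NULL
             else clip_poly_convex(g, space$geometry)
    assign(ids[i], inter, envir = cache)
  }
  out <- lapply(seq_along(cells), function(i) {
    inter <- get(ids[i], envir = cache)
    if (is.null(inter)) return(NULL)
    cl <- cells[[i]]
    cl$clipped_geometry <- inter
    cl
  })
  Filter(Negate(is.null), out)
}

#' Does an activity cell intersect a trail network?
#'
#' TRUE iff the cell's clipped geometry (or full geometry when not yet
#' clipped) comes within `buffer_m` of any trail segment. With the default
#' buffer of 0 this is plain geometric intersection, as used in the trail
#' attribution; the buffer is exposed for sensitivity analysis and is
#' monotone (a larger buffer can only add intersections).
#'
#' @param cell an `activity_cell`.
#' @param trails list of trail objects (`geometry` = polyline matrix) or a
#'   single polyline matrix.
#' @param buffer_m nonnegative buffer in meters.
#' @export
intersects_trail <- function(cell, trails, buffer_m = 0) {
  stopifnot(buffer_m >= 0)
  geo <- cell$clipped_geometry %||% cell$geometry
  if (is.matrix(trails)) trails <- list(list(geometry = trails))
  if (length(trails) == 0) return(FALSE)
  for (t in trails) {
    line <- if (is.list(t)) t$geometry else t
    for (s in seq_len(nrow(line) - 1)) {
      if (dist_seg_poly(line[s, ], line[s + 1, ], geo) <= buffer_m) return(TRUE)
    }
  }
  FALSE
}
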