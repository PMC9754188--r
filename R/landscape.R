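# Synthetic landscape generator.
#
# Emulates the study system: a set of managed green-space properties (convex
# polygons, misaligned with the tile grid so boundary cells get clipped to
# partial areas), each partitioned into ecological land-classification
# community-class (ELC-CC) polygons, with official trail networks inside some
# properties and roads running along property boundaries. The tile grid is
# axis-aligned 100 m squares, as delivered by commercial mobility products.

ELC_CLASSES <- c("forest", "cultural", "talus", "cliff", "marsh", "open water")
LAND_TYPES <- c("Conservation Area", "Natural Area", "Reserve Area", "Other")

#' Landscape generation configuration
#'
#' Defaults describe a desk-scale analog of a conservation-authority
#' jurisdiction: a handful of properties of 0.2--1.4 km^2, most with trail
#' networks, boundary roads on most properties, and 1--4 land-cover classes
#' per property.
#'
#' @param n_properties number of green-space properties.
#' @param cell_size tile grid resolution in meters (100 m as delivered by
#'   mobility-data vendors).
#' @param property_size_range min/max side length of a property in meters.
#' @param corner_cut_prob probability a property polygon gets one corner cut
#'   (convex pentagon), exercising non-rectangular clipping.
#' @param n_cover_range min/max number of ELC-CC units per property.
#' @param elc_classes palette of community-class labels.
#' @param trail_count_range min/max trails per property with trails.
#' @param trail_points_range vertices per trail polyline.
#' @param trail_prob probability a property has an official trail network.
#' @param road_prob probability a property has a road along one boundary edge.
#' @param reservation_prob probability a Conservation Area property is
#'   reservation-managed.
#' @param land_type_probs sampling probabilities for the four land types
#'   (Conservation Area, Natural Area, Reserve Area, Other).
#' @param gap_cells spacing between neighboring properties, in cells.
#' @return list of class `landscape_config`.
#' @export
landscape_config <- function(n_properties = 8,
                             cell_size = 100,
                             property_size_range = c(450, 1200),
                             corner_cut_prob = 0.5,
                             n_cover_range = c(1, 4),
                             elc_classes = ELC_CLASSES,
                             trail_count_range = c(1, 3),
                             trail_points_range = c(3, 6),
                             trail_prob = 0.7,
                             road_prob = 0.7,
                             reservation_prob = 1,
                             land_type_probs = c(0.45, 0.25, 0.15, 0.15),
                             gap_cells = 3) {
  cfg <- list(n_properties = n_properties, cell_size = cell_size,
              property_size_range = property_size_range,
              corner_cut_prob = corner_cut_prob,
              n_cover_range = n_cover_range, elc_classes = elc_classes,
              trail_count_range = trail_count_range,
              trail_points_range = trail_points_range,
              trail_prob = trail_prob, road_prob = road_prob,
              reservation_prob = reservation_prob,
              land_type_probs = land_type_probs, gap_cells = gap_cells)
  class(cfg) <- "landscape_config"
  cfg
}

validate_landscape_config <- function(cfg) {
  if (cfg$n_properties < 1) stop("need at least one property")
  if (cfg$cell_size <= 0) stop("cell_size must be positive")
  if (cfg$property_size_range[1] < cfg$cell_size)
    stop("infeasible config: property smaller than one grid cell (",
         cfg$property_size_range[1], " m < cell_size ", cfg$cell_size, " m)")
  if (length(cfg$elc_classes) < 1) stop("need at least one ELC-CC class")
  if (cfg$n_cover_range[1] < 1) stop("need at least one land-cover unit")
  invisible(cfg)
}

# Uniform point inside a convex polygon (rejection from the bbox).
runif_in_convex <- function(poly) {
  bb <- poly_bbox(poly)
  repeat {
    p <- c(stats::runif(1, bb["xmin"], bb["xmax"]),
           stats::runif(1, bb["ymin"], bb["ymax"]))
    if (point_in_poly(p, poly)) return(unname(p))
  }
}

# Split a convex polygon by a vertical or horizontal line; both halves convex.
split_convex <- function(poly, vertical, at) {
  if (vertical) {
    a <- c(at, 0); n1 <- c(1, 0); n2 <- c(-1, 0)
  } else {
    a <- c(0, at); n1 <- c(0, 1); n2 <- c(0, -1)
  }
  list(clip_halfplane(poly, a, n1), clip_halfplane(poly, a, n2))
}

#' Generate a synthetic landscape
#'
#' Deterministic for a fixed seed. Properties are convex polygons laid out in
#' a row with gaps, deliberately offset from the grid so boundary cells clip
#' to partial areas. Each property is partitioned into convex ELC-CC units by
#' recursive axis-parallel splits (exact partition: unit areas sum to the
#' property area). Trails are polylines through random interior points (inside
#' the property by convexity). Roads run along one randomly chosen boundary
#' edge of road-bearing properties.
#'
#' @param config a [landscape_config()].
#' @param seed integer seed; same config + seed gives identical geometry.
#' @return object of class `synthetic_landscape` with elements
#'   `green_spaces`, `land_cover`, `trails`, `roads`, `grid`, `config`, `seed`.
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1) {
  validate_landscape_config(config)
  with_seed(seed, {
    cs <- config$cell_size
    gap <- config$gap_cells * cs
    green_spaces <- list()
    land_cover <- list()
    trails <- list()
    roads <- list()
    x_cursor <- cs / 2
    for (k in seq_len(config$n_properties)) {
      w <- stats::runif(1, config$property_size_range[1], config$property_size_range[2])
      h <- stats::runif(1, config$property_size_range[1], config$property_size_range[2])
      # offset from grid lines so clipping is non-trivial
      x0 <- x_cursor + stats::runif(1, 0, cs)
      y0 <- cs / 2 + stats::runif(1, 0, cs)
      poly <- poly_rect(x0, y0, x0 + w, y0 + h)
      if (stats::runif(1) < config$corner_cut_prob) {
        # cut one corner with a diagonal chord; polygon stays convex
        cut <- stats::runif(2, 0.2, 0.6) * c(w, h)
        corner <- sample(4, 1)
        a <- switch(corner,
          c(x0 + cut[1], y0), c(x0 + w, y0 + cut[2]),
          c(x0 + w - cut[1], y0 + h), c(x0, y0 + h - cut[2]))
        b <- switch(corner,
          c(x0, y0 + cut[2]), c(x0 + w - cut[1], y0),
          c(x0 + w, y0 + h - cut[2]), c(x0 + cut[1], y0 + h))
        e <- b - a
        poly <- clip_halfplane(poly, a, c(-e[2], e[1]))
        # orientation of the normal depends on corner; keep the bigger half
        alt <- clip_halfplane(poly_rect(x0, y0, x0 + w, y0 + h), a, c(e[2], -e[1]))
        if (!is.null(alt) && poly_area(alt) > poly_area(poly)) poly <- alt
      }
      poly <- poly_ccw(poly)
      land_type <- sample(LAND_TYPES, 1, prob = config$land_type_probs)
      has_trails <- stats::runif(1) < config$trail_prob &&
        land_type != "Reserve Area"
      reservations <- land_type == "Conservation Area" &&
        stats::runif(1) < config$reservation_prob
      pid <- sprintf("gs%02d", k)
      green_spaces[[k]] <- structure(list(
        id = pid, name = paste("Property", k), geometry = poly,
        area = poly_area(poly), land_type = land_type,
        managed = land_type != "Natural Area",
        reservations_required = reservations), class = "green_space")

      # ELC-CC partition by recursive splits of the largest unit
      n_units <- sample(seq(config$n_cover_range[1], config$n_cover_range[2]), 1)
      units <- list(poly)
      while (length(units) < n_units) {
        areas <- vapply(units, poly_area, numeric(1))
        i <- which.max(areas)
        bb <- poly_bbox(units[[i]])
        vertical <- (bb["xmax"] - bb["xmin"]) >= (bb["ymax"] - bb["ymin"])
        at <- if (vertical) stats::runif(1, bb["xmin"] + 0.3 * (bb["xmax"] - bb["xmin"]),
                                         bb["xmin"] + 0.7 * (bb["xmax"] - bb["xmin"]))
              else stats::runif(1, bb["ymin"] + 0.3 * (bb["ymax"] - bb["ymin"]),
                                bb["ymin"] + 0.7 * (bb["ymax"] - bb["ymin"]))
        halves <- split_convex(units[[i]], vertical, at)
        halves <- Filter(Negate(is.null), halves)
        if (length(halves) < 2) break
        units <- c(units[-i], halves)
      }
      cls <- sample(config$elc_classes, length(units), replace =
                      length(units) > length(config$elc_classes))
      for (u in seq_along(units)) {
        land_cover[[length(land_cover) + 1L]] <- list(
          property_id = pid, elc_cc = cls[u], geometry = poly_ccw(units[[u]]))
      }

      if (has_trails) {
        n_tr <- sample(seq(config$trail_count_range[1], config$trail_count_range[2]), 1)
        for (t in seq_len(n_tr)) {
          npts <- sample(seq(config$trail_points_range[1], config$trail_points_range[2]), 1)
          pts <- t(vapply(seq_len(npts), function(i) runif_in_convex(poly), numeric(2)))
          colnames(pts) <- c("x", "y")
          trails[[length(trails) + 1L]] <- list(
            property_id = pid, trail_id = sprintf("%s_t%d", pid, t), geometry = pts)
        }
      }

      if (stats::runif(1) < config$road_prob) {
        # road along one boundary edge of the property polygon
        i <- sample(nrow(poly), 1)
        j <- if (i == nrow(poly)) 1L else i + 1L
        roads[[length(roads) + 1L]] <- list(
          property_id = pid, geometry = rbind(poly[i, ], poly[j, ]))
      }
      x_cursor <- x0 + w + gap
    }

    # grid covering all properties, anchored at multiples of cell_size
    all_bb <- Reduce(function(a, b) c(xmin = min(a["xmin"], b["xmin"]),
                                      ymin = min(a["ymin"], b["ymin"]),
                                      xmax = max(a["xmax"], b["xmax"]),
                                      ymax = max(a["ymax"], b["ymax"])),
                     lapply(green_spaces, function(g) poly_bbox(g$geometry)))
    gx0 <- floor(all_bb["xmin"] / cs) * cs
    gy0 <- floor(all_bb["ymin"] / cs) * cs
    grid <- list(x0 = unname(gx0), y0 = unname(gy0),
                 nx = as.integer(ceiling((all_bb["xmax"] - gx0) / cs)),
                 ny = as.integer(ceiling((all_bb["ymax"] - gy0) / cs)),
                 cell_size = cs)

    structure(list(green_spaces = green_spaces, land_cover = land_cover,
                   trails = trails, roads = roads, grid = grid,
                   config = config, seed = seed),
              class = "synthetic_landscape")
  })
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat("synthetic_landscape:", length(x$green_spaces), "properties,",
      length(x$land_cover), "land-cover units,", length(x$trails), "trails,",
      length(x$roads), "roads; grid", x$grid$nx, "x", x$grid$ny,
      "cells of", x$grid$cell_size, "m\n")
  invisible(x)
}

# ---- grid helpers ---------------------------------------------------------

cell_id_at <- function(col, row) sprintf("c%04d_%04d", col, row)

#' Polygon of one grid cell
#' @param grid grid spec from a `synthetic_landscape`.
#' @param col,row 1-based cell indices.
#' @export
cell_polygon <- function(grid, col, row) {
  cs <- grid$cell_size
  poly_rect(grid$x0 + (col - 1) * cs, grid$y0 + (row - 1) * cs,
            grid$x0 + col * cs, grid$y0 + row * cs)
}

# Enumerate grid cells whose bbox overlaps a polygon's bbox; returns
# data.frame(col, row).
cells_over_bbox <- function(grid, bb) {
  cs <- grid$cell_size
  c0 <- max(1L, floor((bb["xmin"] - grid$x0) / cs) + 1L)
  c1 <- min(grid$nx, ceiling((bb["xmax"] - grid$x0) / cs))
  r0 <- max(1L, floor((bb["ymin"] - grid$y0) / cs) + 1L)
  r1 <- min(grid$ny, ceiling((bb["ymax"] - grid$y0) / cs))
  if (c1 < c0 || r1 < r0) return(data.frame(col = integer(0), row = integer(0)))
  expand.grid(col = seq(c0, c1), row = seq(r0, r1))
}

#' Per-cell intersection table for a landscape
#'
#' One row per (cell, property) pair with positive intersection area, plus
#' derived flags used by the visitation simulator: whether the cell touches a
#' road, intersects a trail, and its majority ELC-CC class (the class holding
#' the largest share of the cell's clipped area).
#'
#' @param landscape a `synthetic_landscape`.
#' @return data.frame with columns cell_id, col, row, property_id,
#'   clipped_area, cell_area, road_flag, on_trail, elc_cc.
#' @export
landscape_cells <- function(landscape) {
  grid <- landscape$grid
  out <- list()
  for (gs in landscape$green_spaces) {
    bb <- poly_bbox(gs$geometry)
    cand <- cells_over_bbox(grid, bb)
    p_trails <- Filter(function(t) t$property_id == gs$id, landscape$trails)
    p_roads <- Filter(function(r) r$property_id == gs$id, landscape$roads)
    for (i in seq_len(nrow(cand))) {
      cp <- cell_polygon(grid, cand$col[i], cand$row[i])
      inter <- clip_poly_convex(cp, gs$geometry)
      if (is.null(inter)) next
      a <- poly_area(inter)
      road <- any(vapply(p_roads, function(r)
        dist_seg_poly(r$geometry[1, ], r$geometry[2, ], cp) == 0, logical(1)))
      on_trail <- any(vapply(p_trails, function(t) {
        segs <- nrow(t$geometry) - 1
        any(vapply(seq_len(segs), function(s)
          dist_seg_poly(t$geometry[s, ], t$geometry[s + 1, ], cp) == 0, logical(1)))
      }, logical(1)))
      # majority class by clipped-area share
      best_cls <- NA_character_; best_a <- -1
      for (lc in landscape$land_cover) {
        if (lc$property_id != gs$id) next
        ci <- clip_poly_convex(cp, lc$geometry)
        ai <- if (is.null(ci)) 0 else poly_area(ci)
        if (ai > best_a) { best_a <- ai; best_cls <- lc$elc_cc }
      }
      out[[length(out) + 1L]] <- data.frame(
        cell_id = cell_id_at(cand$col[i], cand$row[i]),
        col = cand$col[i], row = cand$row[i], property_id = gs$id,
        clipped_area = a, cell_area = poly_area(cp),
        road_flag = road, on_trail = on_trail, elc_cc = best_cls,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    stop("landscape produced no cells intersecting properties")
  do.call(rbind, out)
}

#' Write landscape layers as GeoJSON
#'
#' Writes `properties.geojson`, `trails.geojson`, `landcover.geojson` and
#' `roads.geojson` into `dir`.
#'
#' @param landscape a `synthetic_landscape`.
#' @param dir output directory (created if absent).
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  props <- lapply(landscape$green_spaces, function(g)
    feature("Polygon", geojson_coords_polygon(g$geometry),
            list(id = g$id, name = g$name, land_type = g$land_type,
                 managed = g$managed,
                 reservations_required = g$reservations_required)))
  write_geojson(props, file.path(dir, "properties.geojson"))
  write_geojson(lapply(landscape$trails, function(t)
    feature("LineString", geojson_coords_linestring(t$geometry),
            list(property_id = t$property_id, trail_id = t$trail_id))),
    file.path(dir, "trails.geojson"))
  write_geojson(lapply(landscape$land_cover, function(lc)
    feature("Polygon", geojson_coords_polygon(lc$geometry),
            list(property_id = lc$property_id, elc_cc = lc$elc_cc))),
    file.path(dir, "landcover.geojson"))
  write_geojson(lapply(landscape$roads, function(r)
    feature("LineString", geojson_coords_linestring(r$geometry),
            list(property_id = r$property_id))),
    file.path(dir, "roads.geojson"))
  invisible(dir)
}

#' Read landscape layers back from GeoJSON
#'
#' Inverse of [write_landscape()] for the pipeline's file-based mode. The grid
#' is reconstructed from the property bounding boxes and `cell_size`.
#'
#' @param dir directory holding the GeoJSON layers.
#' @param cell_size grid resolution in meters.
#' @return a `synthetic_landscape`-shaped list (no config/seed).
#' @export
read_landscape <- function(dir, cell_size = 100) {
  pf <- read_geojson(file.path(dir, "properties.geojson"))
  green_spaces <- lapply(pf, function(f) {
    structure(list(id = f$properties$id, name = f$properties$name,
                   geometry = poly_ccw(f$geometry),
                   area = poly_area(f$geometry),
                   land_type = f$properties$land_type,
                   managed = isTRUE(f$properties$managed),
                   reservations_required = isTRUE(f$properties$reservations_required)),
              class = "green_space")
  })
  trails_path <- file.path(dir, "trails.geojson")
  trails <- if (file.exists(trails_path)) {
    lapply(read_geojson(trails_path), function(f)
      list(property_id = f$properties$property_id,
           trail_id = f$properties$trail_id, geometry = f$geometry))
  } else list()
  lc_path <- file.path(dir, "landcover.geojson")
  land_cover <- if (file.exists(lc_path)) {
    lapply(read_geojson(lc_path), function(f)
      list(property_id = f$properties$property_id,
           elc_cc = f$properties$elc_cc, geometry = poly_ccw(f$geometry)))
  } else list()
  roads_path <- file.path(dir, "roads.geojson")
  roads <- if (file.exists(roads_path)) {
    lapply(read_geojson(roads_path), function(f)
      list(property_id = f$properties$property_id, geometry = f$geometry))
  } else list()
  all_bb <- Reduce(function(a, b) c(xmin = min(a["xmin"], b["xmin"]),
                                    ymin = min(a["ymin"], b["ymin"]),
                                    xmax = max(a["xmax"], b["xmax"]),
                                    ymax = max(a["ymax"], b["ymax"])),
                   lapply(green_spaces, function(g) poly_bbox(g$geometry)))
  gx0 <- floor(all_bb["xmin"] / cell_size) * cell_size
  gy0 <- floor(all_bb["ymin"] / cell_size) * cell_size
  grid <- list(x0 = unname(gx0), y0 = unname(gy0),
               nx = as.integer(ceiling((all_bb["xmax"] - gx0) / cell_size)),
               ny = as.integer(ceiling((all_bb["ymax"] - gy0) / cell_size)),
               cell_size = cell_size)
  structure(list(green_spaces = green_spaces, land_cover = land_cover,
                 trails = trails, roads = roads, grid = grid,
                 config = NULL, seed = NULL),
            class = "synthetic_landscape")
}
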