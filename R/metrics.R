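# Per-property activity metrics.
#
# Two core quantities summarize device activity over a green space:
#
#   activity density  = sum over retained records of
#                       (activity index x clipped cell area) / property area
#   activity coverage = 100 x union area of retained activity-bearing cells
#                       (each distinct cell counted once) / property area
#
# The density deliberately uses a SUM rather than a mean or median: because
# sub-threshold records are absent (never zero), the number of records per
# cell varies with activity level, and a mean over surviving records would be
# biased upward for quiet properties. The sum runs over all retained records
# (every month, window and requested stratum).
#
# Before either metric, cells showing any overnight (00:00-06:00) activity
# are excluded globally: parks are closed or near-empty overnight, so
# overnight activity marks road/commercial contamination, typically along
# property boundaries. A flagged cell is dropped for ALL hours and months.

#' Flag cells with overnight activity
#'
#' A cell id is flagged iff ANY of its records (any month, any stratum) falls
#' in a night window. Flagged cells should be excluded from all downstream
#' metrics at all hours.
#'
#' @param cells list of `activity_cell` (or a tiles data.frame).
#' @param night_windows window start hours treated as overnight; default
#'   `c(0, 2, 4)`, the half-open 2-hour windows covering 00:00-06:00.
#' @return character vector of flagged cell ids.
#' @export
flag_overnight_cells <- function(cells, night_windows = c(0L, 2L, 4L)) {
  if (is.data.frame(cells)) {
    ids <- cells$cell_id
    hrs <- cells$window_start_hour
  } else {
    ids <- vapply(cells, function(c) as.character(c$cell_id), character(1))
    hrs <- vapply(cells, function(c) as.numeric(c$window_start_hour), numeric(1))
  }
  sort(unique(ids[hrs %in% night_windows]))
}

#' Drop flagged cells from a cell list
#' @param cells list of `activity_cell`.
#' @param flagged cell ids from [flag_overnight_cells()].
#' @return list without any record of a flagged cell.
#' @export
exclude_cells <- function(cells, flagged) {
  Filter(function(c) !(c$cell_id %in% flagged), cells)
}

#' Activity density of a green space
#'
#' Area-weighted sum of activity indices over retained clipped records,
#' divided by the property area. Zero when no records remain (absence means
#' sub-threshold activity, not missing data).
#'
#' @param cells list of clipped, overnight-filtered `activity_cell`.
#' @param space a `green_space`.
#' @param stratum "all" (default), "weekday" or "weekend"; under the sum
#'   aggregation, density("all") = density(weekday) + density(weekend).
#' @return nonnegative unitless density.
#' @export
activity_density <- function(cells, space, stratum = "all") {
  cells <- filter_stratum(cells, stratum)
  if (length(cells) == 0) return(0)
  contrib <- vapply(cells, function(c) {
    geo <- c$clipped_geometry
    if (is.null(geo)) stop("cells must be clipped before activity_density")
    c$activity_index * poly_area(geo)
  }, numeric(1))
  sum(contrib) / space$area
}

filter_stratum <- function(cells, stratum) {
  if (identical(stratum, "all")) return(cells)
  stopifnot(stratum %in% c("weekday", "weekend"))
  Filter(function(c) c$day_stratum == stratum, cells)
}

# Distinct clipped geometries of activity-bearing cells (one per cell id).
distinct_cell_geoms <- function(cells) {
  ids <- vapply(cells, function(c) as.character(c$cell_id), character(1))
  lapply(cells[!duplicated(ids)], function(c) c$clipped_geometry)
}

#' Activity coverage of a green space (percent)
#'
#' Percent of the property area covered by cells with at least one retained
#' record in any window; each distinct cell counts once regardless of how
#' many records it has.
#'
#' @inheritParams activity_density
#' @return percentage in [0, 100].
#' @export
activity_coverage <- function(cells, space, stratum = "all") {
  cells <- filter_stratum(cells, stratum)
  if (length(cells) == 0) return(0)
  100 * union_area(distinct_cell_geoms(cells)) / space$area
}

#' Trail density of a green space (km per square km)
#'
#' Total official trail length inside the property divided by property area.
#'
#' @param trails list of trail objects (`geometry` polyline) or matrices.
#' @param space a `green_space`.
#' @return km/km^2 (numerically equal to m/m^2 x 1000).
#' @export
trail_density <- function(trails, space) {
  if (is.matrix(trails)) trails <- list(list(geometry = trails))
  if (length(trails) == 0) return(0)
  len_m <- sum(vapply(trails, function(t) {
    line <- if (is.list(t)) t$geometry else t
    polyline_length_in_convex(line, space$geometry)
  }, numeric(1)))
  (len_m / 1000) / (space$area / 1e6)
}

#' Percent of activity area on trails
#'
#' Area of retained activity-bearing cells intersecting the trail network, as
#' a percentage of all retained activity-bearing area. `NA` when the property
#' has no activity area at all (the ratio is undefined, and an explicit
#' missing value is reported rather than 0).
#'
#' @param cells list of clipped, filtered `activity_cell`.
#' @param trails trail list (possibly empty -> 0 when activity exists).
#' @param buffer_m trail buffer in meters (default 0, raw intersection).
#' @return percentage in [0, 100], or `NA_real_`.
#' @export
on_trail_activity_pct <- function(cells, trails, buffer_m = 0) {
  geoms <- distinct_cell_geoms(cells)
  total <- union_area(geoms)
  if (total <= 0) return(NA_real_)
  ids <- vapply(cells, function(c) as.character(c$cell_id), character(1))
  uniq <- cells[!duplicated(ids)]
  on <- vapply(uniq, intersects_trail, logical(1), trails = trails,
               buffer_m = buffer_m)
  100 * union_area(lapply(uniq[on], function(c) c$clipped_geometry)) / total
}

#' Land-cover usage fractions
#'
#' Apportions the retained activity area among ELC-CC units by geometric
#' intersection and reports, per class: the share of all activity area lying
#' in that class (shares sum to 1 when the cover partitions the property),
#' and the fraction of the class's own area that carries activity (`NA` for
#' zero-area classes).
#'
#' @param cells list of clipped, filtered `activity_cell`.
#' @param cover list of land-cover units (`property_id`, `elc_cc`, `geometry`).
#' @param space a `green_space`.
#' @return data.frame: property_id, elc_cc, class_area, activity_area,
#'   prop_activity_by_class, prop_class_used.
#' @export
landcover_usage <- function(cells, cover, space) {
  cover <- Filter(function(u) u$property_id == space$id, cover)
  if (length(cover) == 0) stop("no land-cover units for property ", space$id)
  geoms <- distinct_cell_geoms(cells)
  total_activity <- union_area(geoms)
  classes <- unique(vapply(cover, function(u) u$elc_cc, character(1)))
  rows <- lapply(classes, function(cl) {
    units <- Filter(function(u) u$elc_cc == cl, cover)
    class_area <- sum(vapply(units, function(u) poly_area(u$geometry), numeric(1)))
    # activity cells are disjoint and each unit is convex: intersect pairwise
    act_area <- 0
    for (u in units) {
      for (g in geoms) {
        inter <- clip_poly_convex(g, u$geometry)
        if (!is.null(inter)) act_area <- act_area + poly_area(inter)
      }
    }
    data.frame(property_id = space$id, elc_cc = cl, class_area = class_area,
               activity_area = act_area,
               prop_activity_by_class =
                 if (total_activity > 0) act_area / total_activity else NA_real_,
               prop_class_used =
                 if (class_area > 0) act_area / class_area else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full activity summary for one green space
#'
#' Runs the canonical order -- clip, overnight-exclude, then metrics -- and
#' returns one row per requested stratum plus "all". Coverage is computed on
#' the post-filter cell set, keeping density and coverage on the same
#' retained records.
#'
#' @param tiles tiles data.frame (all properties; clipping selects), or a
#'   prebuilt list of `activity_cell` objects.
#' @param space a `green_space`.
#' @param trails trail list for this property (may be empty).
#' @param night_windows see [flag_overnight_cells()].
#' @param buffer_m trail buffer for the on-trail percentage.
#' @param strata which strata to report alongside "all".
#' @return data.frame with one row per stratum: property_id, day_stratum,
#'   activity_density, activity_coverage_pct, trail_density, on_trail_pct,
#'   n_cells_retained, n_cells_excluded.
#' @export
summarize_activity <- function(tiles, space, trails = list(),
                               night_windows = c(0L, 2L, 4L), buffer_m = 0,
                               strata = c("all", "weekday", "weekend")) {
  cells <- if (is.data.frame(tiles)) tiles_to_cells(tiles) else tiles
  clipped <- clip_cells(cells, space)
  flagged <- flag_overnight_cells(clipped, night_windows)
  retained <- exclude_cells(clipped, flagged)
  n_ids <- length(unique(vapply(clipped, function(c) as.character(c$cell_id),
                                character(1))))
  td <- trail_density(trails, space)
  rows <- lapply(strata, function(st) {
    sub <- filter_stratum(retained, st)
    data.frame(property_id = space$id, day_stratum = st,
               activity_density = activity_density(retained, space, st),
               activity_coverage_pct = activity_coverage(retained, space, st),
               trail_density = td,
               on_trail_pct = on_trail_activity_pct(sub, trails, buffer_m),
               n_cells_retained = length(unique(vapply(sub, function(c)
                 as.character(c$cell_id), character(1)))),
               n_cells_excluded = length(flagged),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
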