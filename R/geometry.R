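# Planar geometry primitives.
#
# All geometry in this package lives in an abstract projected Cartesian plane
# with coordinates in meters; no geodesy is performed because every downstream
# quantity (activity density, coverage, trail density) needs areas and lengths
# only. Polygons are plain two-column numeric matrices of vertices, implicitly
# closed (the last vertex is NOT repeated), stored counter-clockwise. All
# polygons handled by the clipping and union routines are assumed CONVEX: grid
# cells are axis-aligned squares, property and land-cover polygons produced by
# the landscape generator are convex, and the intersection of convex polygons
# is convex, so convexity is closed under every operation the pipeline uses.

#' Construct an axis-aligned rectangle polygon
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds in meters.
#' @return A two-column vertex matrix (counter-clockwise, not closed).
#' @export
poly_rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Polygon area by the shoelace formula
#'
#' @param poly two-column vertex matrix; `NULL` or fewer than 3 vertices
#'   give area 0.
#' @return Area in square meters (nonnegative).
#' @export
poly_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Signed area: positive for counter-clockwise rings.
poly_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Ensure counter-clockwise orientation.
poly_ccw <- function(poly) {
  if (poly_signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

# TRUE iff the ring is convex (all cross products of consecutive edges share
# a sign); convex rings are automatically simple.
poly_is_convex <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    k <- if (j == n) 1L else j + 1L
    cr <- (poly[j, 1] - poly[i, 1]) * (poly[k, 2] - poly[j, 2]) -
          (poly[j, 2] - poly[i, 2]) * (poly[k, 1] - poly[j, 1])
    if (abs(cr) < 1e-12) next
    if (s == 0) s <- sign(cr)
    else if (sign(cr) != s) return(FALSE)
  }
  s != 0
}

poly_bbox <- function(poly) {
  c(xmin = min(poly[, 1]), ymin = min(poly[, 2]),
    xmax = max(poly[, 1]), ymax = max(poly[, 2]))
}

poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

#' Test whether a point lies inside (or on) a polygon
#'
#' Ray-casting with an on-boundary check; boundary points count as inside.
#'
#' @param pt numeric length-2 vector.
#' @param poly two-column vertex matrix.
#' @export
point_in_poly <- function(pt, poly) {
  n <- nrow(poly)
  x <- pt[1]; y <- pt[2]
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-segment check
    if (dist_point_seg(pt, c(xi, yi), c(xj, yj)) < 1e-12) return(TRUE)
    if ((yi > y) != (yj > y)) {
      xint <- (xj - xi) * (y - yi) / (yj - yi) + xi
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Clip a polygon against the half-plane {p : dot(p - a, nrm) <= 0}, where the
# boundary line passes through a with inward normal -nrm. Sutherland-Hodgman
# single-edge step; subject may be any polygon, result is its intersection
# with the half-plane.
clip_halfplane <- function(poly, a, nrm) {
  if (is.null(poly) || nrow(poly) < 3) return(NULL)
  n <- nrow(poly)
  d <- (poly[, 1] - a[1]) * nrm[1] + (poly[, 2] - a[2]) * nrm[2]
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) out <- rbind(out, poly[i, ])
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  if (nrow(out) < 3) return(NULL)
  dedupe_ring(out)
}

# Drop consecutive duplicate vertices (within 1e-12 m).
dedupe_ring <- function(poly) {
  n <- nrow(poly)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep[j] && abs(poly[i, 1] - poly[j, 1]) < 1e-12 &&
        abs(poly[i, 2] - poly[j, 2]) < 1e-12 && sum(keep) > 3) keep[j] <- FALSE
  }
  out <- poly[keep, , drop = FALSE]
  if (nrow(out) < 3) NULL else out
}

#' Intersection of a polygon with a convex polygon
#'
#' Sutherland-Hodgman clipping of `subject` against each edge of the convex
#' polygon `clip`. Returns `NULL` when the intersection is empty or has zero
#' area (boundary-touching counts as empty, since area-weighted metrics give
#' zero-area pieces no weight).
#'
#' @param subject polygon to clip (two-column vertex matrix).
#' @param clip convex clipping polygon.
#' @return Clipped polygon matrix, or `NULL`.
#' @export
clip_poly_convex <- function(subject, clip) {
  clip <- poly_ccw(clip)
  out <- poly_ccw(subject)
  n <- nrow(clip)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- clip[j, ] - clip[i, ]
    nrm <- c(e[2], -e[1])  # outward normal of a CCW edge
    out <- clip_halfplane(out, clip[i, ], nrm)
    if (is.null(out)) return(NULL)
  }
  if (poly_area(out) < 1e-12) NULL else out
}

# ---- segments -------------------------------------------------------------

dist_point_seg <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-300) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - (a + t * ab))^2))
}

segments_intersect <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(v) < 1e-12) 0 else sign(v)
  }
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  # collinear / endpoint touching
  on <- function(a, b, c) dist_point_seg(c, a, b) < 1e-12
  (o1 == 0 && on(p1, p2, q1)) || (o2 == 0 && on(p1, p2, q2)) ||
    (o3 == 0 && on(q1, q2, p1)) || (o4 == 0 && on(q1, q2, p2))
}

# x-coordinate(s) of the proper intersection of two segments, if any.
seg_intersection_x <- function(p1, p2, q1, q2) {
  r <- p2 - p1; s <- q2 - q1
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < 1e-300) return(numeric(0))
  qp <- q1 - p1
  t <- (qp[1] * s[2] - qp[2] * s[1]) / denom
  u <- (qp[1] * r[2] - qp[2] * r[1]) / denom
  if (t < -1e-12 || t > 1 + 1e-12 || u < -1e-12 || u > 1 + 1e-12) return(numeric(0))
  p1[1] + t * r[1]
}

dist_seg_seg <- function(p1, p2, q1, q2) {
  if (segments_intersect(p1, p2, q1, q2)) return(0)
  min(dist_point_seg(q1, p1, p2), dist_point_seg(q2, p1, p2),
      dist_point_seg(p1, q1, q2), dist_point_seg(p2, q1, q2))
}

# Minimum distance between a segment and a polygon (0 if the segment touches
# or enters the polygon).
dist_seg_poly <- function(a, b, poly) {
  if (point_in_poly(a, poly) || point_in_poly(b, poly)) return(0)
  n <- nrow(poly)
  d <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- min(d, dist_seg_seg(a, b, poly[i, ], poly[j, ]))
    if (d == 0) return(0)
  }
  d
}

#' Length of a polyline
#'
#' @param line two-column matrix of polyline vertices.
#' @return Length in meters.
#' @export
polyline_length <- function(line) {
  if (is.null(line) || nrow(line) < 2) return(0)
  sum(sqrt(rowSums((line[-1, , drop = FALSE] - line[-nrow(line), , drop = FALSE])^2)))
}

# Length of the part of a polyline inside a convex polygon (Cyrus-Beck
# parametric clipping per segment).
polyline_length_in_convex <- function(line, poly) {
  if (is.null(line) || nrow(line) < 2) return(0)
  poly <- poly_ccw(poly)
  n <- nrow(poly)
  total <- 0
  for (k in seq_len(nrow(line) - 1)) {
    a <- line[k, ]; b <- line[k + 1, ]
    d <- b - a
    t0 <- 0; t1 <- 1
    ok <- TRUE
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      e <- poly[j, ] - poly[i, ]
      nrm <- c(e[2], -e[1])                 # outward normal
      num <- sum((a - poly[i, ]) * nrm)     # >0 means outside this edge
      den <- sum(d * nrm)
      if (abs(den) < 1e-300) {
        if (num > 1e-12) { ok <- FALSE; break }
      } else {
        t <- -num / den
        if (den > 0) t1 <- min(t1, t) else t0 <- max(t0, t)
        if (t0 > t1) { ok <- FALSE; break }
      }
    }
    if (ok && t1 > t0) total <- total + (t1 - t0) * sqrt(sum(d^2))
  }
  total
}

# ---- union area -----------------------------------------------------------

# y-interval cut by the vertical line x = x0 through a convex polygon;
# returns c(ymin, ymax) or NULL.
convex_vertical_cut <- function(poly, x0) {
  n <- nrow(poly)
  ys <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- poly[i, 1]; x2 <- poly[j, 1]
    if ((x1 <= x0 && x2 >= x0) || (x1 >= x0 && x2 <= x0)) {
      if (abs(x2 - x1) < 1e-300) {
        ys <- c(ys, poly[i, 2], poly[j, 2])
      } else {
        t <- (x0 - x1) / (x2 - x1)
        ys <- c(ys, poly[i, 2] + t * (poly[j, 2] - poly[i, 2]))
      }
    }
  }
  if (length(ys) == 0) return(NULL)
  c(min(ys), max(ys))
}

interval_union_length <- function(ints) {
  if (length(ints) == 0) return(0)
  m <- do.call(rbind, ints)
  m <- m[order(m[, 1]), , drop = FALSE]
  total <- 0; lo <- m[1, 1]; hi <- m[1, 2]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] > hi) { total <- total + (hi - lo); lo <- m[i, 1]; hi <- m[i, 2] }
    else hi <- max(hi, m[i, 2])
  }
  total + (hi - lo)
}

# Exact union area of a set of convex polygons via vertical slab
# decomposition: slab boundaries at every vertex x and every pairwise edge
# crossing x, so within a slab each polygon cuts one y-interval whose
# endpoints are linear in x and never cross; the union length is then linear
# in x and the slab area equals width times the union length at midpoint.
union_area_component <- function(polys) {
  if (length(polys) == 1) return(poly_area(polys[[1]]))
  xs <- unlist(lapply(polys, function(p) p[, 1]))
  # pairwise edge crossings
  edges <- list()
  for (p in polys) {
    n <- nrow(p)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      edges[[length(edges) + 1L]] <- rbind(p[i, ], p[j, ])
    }
  }
  ne <- length(edges)
  for (i in seq_len(ne - 1)) {
    for (j in seq(i + 1, ne)) {
      xs <- c(xs, seg_intersection_x(edges[[i]][1, ], edges[[i]][2, ],
                                     edges[[j]][1, ], edges[[j]][2, ]))
    }
  }
  xs <- sort(unique(xs))
  area <- 0
  for (k in seq_len(length(xs) - 1)) {
    x0 <- xs[k]; x1 <- xs[k + 1]
    if (x1 - x0 < 1e-300) next
    xm <- (x0 + x1) / 2
    cuts <- lapply(polys, convex_vertical_cut, x0 = xm)
    cuts <- Filter(Negate(is.null), cuts)
    area <- area + (x1 - x0) * interval_union_length(cuts)
  }
  area
}

#' Area of the union of convex polygons
#'
#' Exact (to floating point) union area. Polygons whose bounding boxes do not
#' strictly overlap are summed directly; overlapping groups are resolved by a
#' vertical slab decomposition. All polygons must be convex -- which holds for
#' everything this package produces (grid cells, clipped cells, convex
#' property and land-cover polygons).
#'
#' @param polys list of two-column vertex matrices (`NULL` entries ignored).
#' @return Union area in square meters; never exceeds the sum of areas.
#' @export
union_area <- function(polys) {
  polys <- Filter(function(p) !is.null(p) && nrow(p) >= 3, polys)
  np <- length(polys)
  if (np == 0) return(0)
  if (np == 1) return(poly_area(polys[[1]]))
  bb <- t(vapply(polys, poly_bbox, numeric(4)))
  # strict bbox overlap (touching boundaries contribute zero shared area),
  # vectorized: overlap matrix, then union-find over overlapping pairs
  xmin <- bb[, "xmin"]; xmax <- bb[, "xmax"]
  ymin <- bb[, "ymin"]; ymax <- bb[, "ymax"]
  ov <- outer(xmin, xmax, function(a, b) a < b - 1e-12) &
        outer(xmax, xmin, function(a, b) b < a - 1e-12) &
        outer(ymin, ymax, function(a, b) a < b - 1e-12) &
        outer(ymax, ymin, function(a, b) b < a - 1e-12)
  pairs <- which(ov & upper.tri(ov), arr.ind = TRUE)
  parent <- seq_len(np)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(np), find, integer(1))
  total <- 0
  for (r in unique(roots)) {
    total <- total + union_area_component(polys[roots == r])
  }
  total
}
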