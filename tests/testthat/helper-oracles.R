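# Independent oracles, written on purpose with different algorithms than the
# package (interval arithmetic instead of polygon clipping, dense projection
# matrices instead of QR/SVD), so agreement is evidence rather than tautology.

# ---- geometry oracles -----------------------------------------------------

# y-interval cut by a vertical line through a convex polygon, by direct edge
# scan (duplicated here so the oracle does not share package internals).
oracle_vcut <- function(poly, x0) {
  n <- nrow(poly)
  ys <- c()
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    x1 <- poly[i, 1]; x2 <- poly[j, 1]
    if ((x1 - x0) * (x2 - x0) <= 0 && !(x1 == x0 && x2 == x0)) {
      t <- if (x2 == x1) 0 else (x0 - x1) / (x2 - x1)
      ys <- c(ys, poly[i, 2] + t * (poly[j, 2] - poly[i, 2]))
    } else if (x1 == x0 && x2 == x0) {
      ys <- c(ys, poly[i, 2], poly[j, 2])
    }
  }
  if (!length(ys)) return(NULL)
  range(ys)
}

# Intersection area of two convex polygons by slab integration of the
# overlap of their y-intervals (no Sutherland-Hodgman, no shoelace).
oracle_intersection_area <- function(A, B) {
  xs <- c(A[, 1], B[, 1])
  segs <- function(P) {
    n <- nrow(P)
    lapply(seq_len(n), function(i) rbind(P[i, ], P[if (i == n) 1 else i + 1, ]))
  }
  for (ea in segs(A)) for (eb in segs(B)) {
    r <- ea[2, ] - ea[1, ]; s <- eb[2, ] - eb[1, ]
    den <- r[1] * s[2] - r[2] * s[1]
    if (abs(den) > 1e-300) {
      qp <- eb[1, ] - ea[1, ]
      t <- (qp[1] * s[2] - qp[2] * s[1]) / den
      u <- (qp[1] * r[2] - qp[2] * r[1]) / den
      if (t >= 0 && t <= 1 && u >= 0 && u <= 1) xs <- c(xs, ea[1, 1] + t * r[1])
    }
  }
  xs <- sort(unique(xs))
  area <- 0
  for (k in seq_len(length(xs) - 1)) {
    xm <- (xs[k] + xs[k + 1]) / 2
    ia <- oracle_vcut(A, xm); ib <- oracle_vcut(B, xm)
    if (is.null(ia) || is.null(ib)) next
    ov <- min(ia[2], ib[2]) - max(ia[1], ib[1])
    if (ov > 0) area <- area + ov * (xs[k + 1] - xs[k])
  }
  area
}

# Monte-Carlo union-area estimate with standard error.
oracle_mc_union <- function(polys, n = 20000, seed = 99) {
  bb <- sapply(polys, function(p) c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2])))
  lo <- c(min(bb[1, ]), min(bb[2, ])); hi <- c(max(bb[3, ]), max(bb[4, ]))
  set.seed(seed)
  px <- runif(n, lo[1], hi[1]); py <- runif(n, lo[2], hi[2])
  inside <- rep(FALSE, n)
  for (p in polys) {
    # even-odd rule point-in-polygon, vectorized over points
    np <- nrow(p)
    inp <- rep(FALSE, n)
    j <- np
    for (i in seq_len(np)) {
      cross <- ((p[i, 2] > py) != (p[j, 2] > py)) &
        (px < (p[j, 1] - p[i, 1]) * (py - p[i, 2]) / (p[j, 2] - p[i, 2]) + p[i, 1])
      inp <- xor(inp, cross)
      j <- i
    }
    inside <- inside | inp
  }
  box_area <- prod(hi - lo)
  phat <- mean(inside)
  list(area = phat * box_area,
       se = sqrt(phat * (1 - phat) / n) * box_area)
}

# ---- CCA oracle -----------------------------------------------------------

# Dense-matrix (partial) CCA: explicit weighted projection matrices and a
# generalized eigen decomposition, no QR, no SVD of fitted values.
oracle_pcca <- function(Y, X, Z = NULL) {
  Y <- as.matrix(Y)
  yt <- sum(Y); P <- Y / yt
  r <- rowSums(P); cc <- colSums(P)
  Q <- (P - r %o% cc) / sqrt(r %o% cc)
  W <- diag(sqrt(r))
  wcenter <- function(M) {
    M <- as.matrix(M)
    sweep(M, 2, colSums(M * r) / sum(r))
  }
  proj <- function(Mw) {
    # projector onto column space, via pseudo-inverse of the cross-product
    G <- crossprod(Mw)
    Gi <- MASS_ginv(G)
    Mw %*% Gi %*% t(Mw)
  }
  if (!is.null(Z)) {
    Zw <- W %*% wcenter(Z)
    Hz <- proj(Zw)
    Qr <- Q - Hz %*% Q
    Xw <- W %*% wcenter(X)
    Xr <- Xw - Hz %*% Xw
    cond <- sum((Hz %*% Q)^2)
  } else {
    Qr <- Q
    Xr <- W %*% wcenter(X)
    cond <- 0
  }
  Hx <- proj(Xr)
  F1 <- Hx %*% Qr
  S <- F1 %*% t(F1)
  ev <- eigen(S, symmetric = TRUE)$values
  list(constrained_eig = ev[ev > 1e-10],
       constrained = sum((F1)^2),
       conditioned = cond,
       residual = sum(Qr^2) - sum(F1^2),
       total = sum(Q^2))
}

# Tiny Moore-Penrose pseudo-inverse so the oracle does not depend on MASS.
MASS_ginv <- function(G, tol = 1e-10) {
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) return(matrix(0, nrow(G), ncol(G)))
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / e$values[keep], sum(keep)) %*% t(e$vectors[, keep, drop = FALSE])
}

# ---- fixture builders -----------------------------------------------------

# Minimal tiles data.frame from explicit records.
make_tiles <- function(cell_id, poly_list, activity_index,
                       month = 6L, day_stratum = "weekday",
                       window_start_hour = 12L) {
  data.frame(cell_id = cell_id,
             wkt_geometry = vapply(poly_list, wkt_polygon, character(1)),
             month = month, day_stratum = day_stratum,
             window_start_hour = window_start_hour,
             activity_index = activity_index,
             stringsAsFactors = FALSE)
}

small_landscape_config <- function(...) {
  landscape_config(n_properties = 2, property_size_range = c(450, 700),
                   ...)
}
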