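# (Partial) canonical correspondence analysis, written out explicitly.
#
# The community table Y (sites x species, nonnegative) is chi-square
# standardized: with P = Y / grand total, row masses r and column masses c,
#
#   Qbar_ij = (P_ij - r_i c_j) / sqrt(r_i c_j),
#
# whose total sum of squares is the total inertia of the correspondence
# analysis. Constraints X (and optional conditioning covariates Z) enter as
# row-weighted regressors: columns are weighted-centered and scaled by
# sqrt(r). Conditioning projects both Qbar and X onto the orthogonal
# complement of Z's column space; the constrained solution is the SVD of the
# projection of the (conditioned) Qbar onto the residualized X space.
# Inertia decomposes exactly: conditioned + constrained + residual = total.

# Core decomposition used by both the full fit and the permutation loop.
# Returns inertias and the pieces needed for scores.
pcca_core <- function(Qbar, sr, Xw, Zw = NULL, want_svd = TRUE) {
  if (!is.null(Zw)) {
    qz <- qr(Zw)
    pz <- qz$rank
    Qcond <- qr.fitted(qz, Qbar)
    Qr <- Qbar - Qcond
    Xr <- Xw - qr.fitted(qz, Xw)
    cond_inertia <- sum(Qcond^2)
  } else {
    pz <- 0L
    Qr <- Qbar
    Xr <- Xw
    cond_inertia <- 0
  }
  # a qr rank of 0 means the (residualized) constraints carry no information:
  # constant X, or X entirely within the span of Z. The fit degrades
  # gracefully to zero constrained inertia (callers warn).
  qx <- qr(Xr)
  q <- qx$rank
  if (q == 0) {
    Yfit <- Qr * 0
    constrained <- 0
    residual <- sum(Qr^2)
  } else {
    Yfit <- qr.fitted(qx, Qr)
    constrained <- sum(Yfit^2)
    residual <- sum(Qr^2) - constrained
  }
  out <- list(pz = pz, q = q, cond_inertia = cond_inertia,
              constrained = constrained, residual = max(residual, 0),
              Xr = Xr)
  if (want_svd) {
    out$svd <- svd(Yfit)
    out$Qr <- Qr
    out$Yfit <- Yfit
  }
  out
}

prep_community <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("community table must be nonnegative")
  rz <- rowSums(Y) <= 0
  cz <- colSums(Y) <= 0
  if (any(rz)) warning("dropping ", sum(rz), " all-zero row(s)")
  if (any(cz)) warning("dropping ", sum(cz), " all-zero column(s)")
  Y[!rz, !cz, drop = FALSE]
}

# Weighted-center columns and scale rows by sqrt(row masses).
weight_env <- function(M, r) {
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  ctr <- colSums(M * r) / sum(r)
  sweep(M, 2, ctr) * sqrt(r)
}

#' Partial canonical correspondence analysis
#'
#' Constrained ordination of a nonnegative community table on predictor
#' matrix `X`, optionally after partialling out conditioning covariates `Z`
#' (e.g. survey year). Significance of the constrained fraction is assessed
#' separately with [pcca_permutation()].
#'
#' Because the three variance fractions in use in the literature are easily
#' conflated, the result reports all of them explicitly:
#' `frac_constrained_of_total` (constrained / total inertia),
#' `frac_constrained_conditional` (constrained / (total - conditioned)), and
#' `r_squared_adj` (Ezekiel adjustment of the first fraction).
#'
#' @param Y sites x species nonnegative matrix or data.frame (all-zero rows
#'   and columns are dropped with a warning).
#' @param X constraint matrix/data.frame, rows aligned with Y.
#' @param Z optional conditioning matrix, rows aligned with Y.
#' @return object of class `pcca`: eigenvalues (`constrained_eig`,
#'   `residual_eig`), inertias (`total_inertia`, `conditioned_inertia`,
#'   `constrained_inertia`, `residual_inertia`), `pseudo_f`, scores
#'   (`site_scores_lc`, `site_scores_wa`, `species_scores`,
#'   `biplot_scores`), ranks (`q`, `pz`), `n`, and the variance fractions.
#' @export
pcca <- function(Y, X, Z = NULL) {
  Y <- prep_community(Y)
  n <- nrow(Y)
  m <- ncol(Y)
  if (n < 2 || m < 2) stop("need at least 2 sites and 2 species")
  X <- as.matrix(X)
  if (nrow(X) != n) stop("rows of X must align with Y")
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != n) stop("rows of Z must align with Y")
  }
  yt <- sum(Y)
  P <- Y / yt
  r <- rowSums(P)
  cc <- colSums(P)
  Qbar <- (P - r %o% cc) / sqrt(r %o% cc)
  total <- sum(Qbar^2)
  sr <- sqrt(r)
  Xw <- weight_env(X, r)
  Zw <- if (is.null(Z)) NULL else weight_env(Z, r)
  core <- pcca_core(Qbar, sr, Xw, Zw, want_svd = TRUE)
  q <- core$q
  if (q == 0) warning("constraints aliased with condition (or constant); ",
                      "constrained inertia is zero")

  sv <- core$svd
  pos <- which(sv$d^2 > 1e-12 * max(sv$d^2, 1e-300))
  nax <- min(q, length(pos))
  ax <- seq_len(nax)
  d <- sv$d[ax]
  U <- sv$u[, ax, drop = FALSE]
  V <- sv$v[, ax, drop = FALSE]
  # axis orientation: sign so that the lc site scores correlate nonnegatively
  # with the first (residualized) constraint variable
  ref <- core$Xr[, 1]
  for (k in ax) {
    s <- sum(ref * U[, k])
    if (s < 0) { U[, k] <- -U[, k]; V[, k] <- -V[, k] }
  }
  site_lc <- U / sr
  site_wa <- (core$Qr %*% V) / sr
  site_wa <- sweep(site_wa, 2, d, "/")
  species <- V / sqrt(cc)
  biplot <- suppressWarnings(stats::cor(core$Xr, U))
  # residual (unconstrained) axes
  Qres <- core$Qr - core$Yfit
  dres <- svd(Qres, nu = 0, nv = 0)$d
  residual_eig <- dres[dres^2 > 1e-12 * max(dres^2, 1e-300)]^2

  df_resid <- n - 1 - q - core$pz
  pseudo_f <- if (q > 0 && df_resid > 0)
    (core$constrained / q) / (core$residual / df_resid) else NA_real_
  frac_total <- core$constrained / total
  frac_cond <- core$constrained / (total - core$cond_inertia)
  r2adj <- if (n - 1 - q - core$pz > 0)
    1 - (1 - frac_total) * (n - 1) / (n - 1 - q - core$pz) else NA_real_

  rn <- rownames(Y) %||% as.character(seq_len(n))
  cn <- colnames(Y) %||% as.character(seq_len(m))
  if (nax > 0) {
    dimnames(site_lc) <- list(rn, paste0("CCA", ax))
    dimnames(site_wa) <- list(rn, paste0("CCA", ax))
    dimnames(species) <- list(cn, paste0("CCA", ax))
    colnames(biplot) <- paste0("CCA", seq_len(ncol(biplot)))
  }

  structure(list(
    constrained_eig = d^2, residual_eig = residual_eig,
    total_inertia = total, conditioned_inertia = core$cond_inertia,
    constrained_inertia = core$constrained, residual_inertia = core$residual,
    pseudo_f = pseudo_f, q = q, pz = core$pz, n = n,
    df_residual = df_resid,
    site_scores_lc = site_lc, site_scores_wa = site_wa,
    species_scores = species, biplot_scores = biplot,
    frac_constrained_of_total = frac_total,
    frac_constrained_conditional = frac_cond,
    r_squared_adj = r2adj), class = "pcca")
}

#' @export
print.pcca <- function(x, ...) {
  cat("Partial canonical correspondence analysis\n")
  cat(sprintf("total inertia %.4f = conditioned %.4f + constrained %.4f + residual %.4f\n",
              x$total_inertia, x$conditioned_inertia, x$constrained_inertia,
              x$residual_inertia))
  cat(sprintf("constrained axes: %d; pseudo-F = %.3f (df %d, %d)\n",
              x$q, x$pseudo_f, x$q, x$df_residual))
  cat(sprintf("constrained/total = %.3f; constrained/(total-conditioned) = %.3f; adj R^2 = %.3f\n",
              x$frac_constrained_of_total, x$frac_constrained_conditional,
              x$r_squared_adj))
  invisible(x)
}

#' Permutation test for (partial) CCA
#'
#' Permutes the rows of `X` freely while holding `Y` and `Z` fixed,
#' recomputing the residualization of the permuted constraints on `Z` at
#' every draw, and compares pseudo-F statistics:
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm).
#'
#' @param Y,X,Z as in [pcca()].
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed (results are reproducible).
#' @return list: `p_value`, `f_obs`, `f_perm` (vector), `n_perm`.
#' @export
pcca_permutation <- function(Y, X, Z = NULL, n_perm = 999, seed = 1) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  Y <- prep_community(Y)
  n <- nrow(Y)
  if (n < 3) stop("too few rows for exchangeable permutations")
  X <- as.matrix(X)
  yt <- sum(Y)
  P <- Y / yt
  r <- rowSums(P)
  cc <- colSums(P)
  Qbar <- (P - r %o% cc) / sqrt(r %o% cc)
  sr <- sqrt(r)
  Zw <- if (is.null(Z)) NULL else weight_env(as.matrix(Z), r)
  fstat <- function(Xperm) {
    Xw <- weight_env(Xperm, r)
    core <- pcca_core(Qbar, sr, Xw, Zw, want_svd = FALSE)
    df_resid <- n - 1 - core$q - core$pz
    (core$constrained / core$q) / (core$residual / df_resid)
  }
  f_obs <- fstat(X)
  f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    fstat(X[sample.int(n), , drop = FALSE]), numeric(1)))
  list(p_value = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
       f_obs = f_obs, f_perm = f_perm, n_perm = n_perm)
}

#' Interannual stability check: CCA with year as sole predictor
#'
#' Convenience wrapper used before conditioning composition on year: fits a
#' plain (non-partial) CCA of the survey table on numeric survey year and
#' permutation-tests it. A non-significant result supports treating
#' composition as stable across survey years.
#'
#' @param surveys data.frame from [generate_tree_surveys()] (or any table
#'   with site_id, year, then species columns).
#' @param n_perm permutations for the test.
#' @param seed integer seed.
#' @return list: `fit` (a `pcca`), `test` (from [pcca_permutation()]).
#' @export
cca_year_check <- function(surveys, n_perm = 999, seed = 1) {
  parts <- split_survey_table(surveys)
  if (length(unique(parts$meta$year)) < 2)
    stop("need at least 2 distinct survey years")
  X <- cbind(year = as.numeric(parts$meta$year))
  list(fit = pcca(parts$Y, X),
       test = pcca_permutation(parts$Y, X, n_perm = n_perm, seed = seed))
}

# Split a survey data.frame into metadata (site_id, year) and Y matrix.
split_survey_table <- function(surveys) {
  stopifnot(all(c("site_id", "year") %in% names(surveys)))
  spcols <- setdiff(names(surveys), c("site_id", "year"))
  Y <- as.matrix(surveys[, spcols, drop = FALSE])
  rownames(Y) <- paste(surveys$site_id, surveys$year, sep = "_")
  list(meta = surveys[, c("site_id", "year")], Y = Y)
}

#' Build standardized activity constraints for the composition analysis
#'
#' Assembles, per survey row, the three activity predictors: activity
#' density averaged over the weekday and weekend strata, activity coverage,
#' and the weekend proportion (weekend activity density divided by weekday
#' activity density). Each column is standardized to zero mean and unit
#' variance across rows, since the predictors live on heterogeneous scales.
#'
#' @param surveys survey table (site_id, year, species...).
#' @param summaries ActivitySummary data.frame from [summarize_activity()]
#'   covering every survey site (strata "weekday" and "weekend" present).
#' @return list: `X` (n x 3 standardized constraints), `Z` (n x 1 numeric
#'   year), aligned with the survey rows.
#' @export
build_activity_constraints <- function(surveys, summaries) {
  need <- unique(surveys$site_id)
  get1 <- function(pid, stratum, col) {
    v <- summaries[summaries$property_id == pid &
                     summaries$day_stratum == stratum, col]
    if (length(v) != 1) stop("missing activity summary for site ", pid,
                             " stratum ", stratum)
    v
  }
  per_site <- do.call(rbind, lapply(need, function(pid) {
    dwd <- get1(pid, "weekday", "activity_density")
    dwe <- get1(pid, "weekend", "activity_density")
    data.frame(site_id = pid,
               density_mean = (dwd + dwe) / 2,
               coverage = get1(pid, "all", "activity_coverage_pct"),
               weekend_prop = if (dwd > 0) dwe / dwd else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (anyNA(per_site$weekend_prop))
    stop("weekend proportion undefined (zero weekday density) for site(s): ",
         paste(per_site$site_id[is.na(per_site$weekend_prop)], collapse = ", "))
  i <- match(surveys$site_id, per_site$site_id)
  X <- as.matrix(per_site[i, c("density_mean", "coverage", "weekend_prop")])
  # a predictor constant across sites (e.g. the weekend proportion in a
  # noise-free world, where it equals the weekend multiplier everywhere)
  # carries no constraint information: drop it rather than fail
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) stop("all activity constraints are constant across sites")
  if (any(sds == 0)) {
    warning("dropping constant constraint column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  X <- scale(X)
  rownames(X) <- paste(surveys$site_id, surveys$year, sep = "_")
  list(X = X, Z = cbind(year = as.numeric(surveys$year)))
}
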