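# Ground-truth visitation simulator and forward anonymization model.
#
# Truth is an intensity surface (expected device-presence density) per
# (cell, month, day stratum, 2-hour window), not individual trajectories:
# the vendor's five-minute aggregation and trip-end discarding are not
# reproduced, only their output structure. The anonymization renderer then
# applies the three documented distortions -- additive noise, sub-threshold
# suppression (records are absent, never zero), and normalization to a
# country-level baseline -- as parametric stand-ins, since the vendor's
# threshold and noise magnitude are unpublished.

WINDOWS <- seq(0L, 22L, by = 2L)
NIGHT_WINDOWS <- c(0L, 2L, 4L)
DAY_WINDOWS <- setdiff(WINDOWS, NIGHT_WINDOWS)

# Fixed synthetic calendar: every month has 30 days, days 1-22 are weekdays
# and 23-30 weekend days (22/8 split). Deterministic stratum means follow.
WEEKDAYS_PER_MONTH <- 22L
WEEKEND_PER_MONTH <- 8L

#' Visitation simulation parameters
#'
#' Defaults encode the qualitative structure reported for summer green-space
#' use: activity concentrated on trails (trail cells several-fold busier than
#' off-trail cells), land-cover classes differing in attractiveness (open
#' recreational and rock-formation classes drawing disproportionate use,
#' wetlands little), somewhat higher weekend use, and roads active around the
#' clock at intensities well above park interiors.
#'
#' @param baseline expected device-presence intensity of an ordinary daytime
#'   park cell (unitless; the normalization baseline is expressed in the same
#'   unit).
#' @param trail_multiplier intensity multiplier for cells intersecting a trail.
#' @param class_multipliers named vector of ELC-CC multipliers; classes not
#'   named get 1.
#' @param weekend_multiplier weekend/weekday intensity ratio.
#' @param road_intensity additive intensity on road cells, all windows
#'   including 00:00-06:00.
#' @param visitor_rate expected daily visitors per unit of property-total
#'   daytime intensity.
#' @param months month labels simulated (June-August analog).
#' @return list of class `visitation_params`.
#' @export
visitation_params <- function(baseline = 1,
                              trail_multiplier = 3,
                              class_multipliers = c(forest = 1, cultural = 1.6,
                                                    talus = 1.4, cliff = 1.8,
                                                    marsh = 0.3, `open water` = 0.5),
                              weekend_multiplier = 1.3,
                              road_intensity = 6,
                              visitor_rate = 0.5,
                              months = c(6L, 7L, 8L)) {
  if (baseline < 0) stop("baseline must be nonnegative")
  if (trail_multiplier < 0 || weekend_multiplier < 0 || road_intensity < 0 ||
      any(class_multipliers < 0))
    stop("negative multipliers rejected")
  structure(list(baseline = baseline, trail_multiplier = trail_multiplier,
                 class_multipliers = class_multipliers,
                 weekend_multiplier = weekend_multiplier,
                 road_intensity = road_intensity, visitor_rate = visitor_rate,
                 months = months),
            class = "visitation_params")
}

#' Simulate ground-truth visitation intensity
#'
#' Cell intensity is multiplicative: baseline x trail multiplier (if the cell
#' intersects a trail) x ELC-CC class multiplier x stratum multiplier, zero in
#' the 00:00-06:00 windows; road cells additionally receive a constant road
#' term in every window. Daily visitor counts per reservation-managed property
#' are Poisson with mean proportional to the property's total daytime
#' intensity for that day's stratum.
#'
#' @param landscape a `synthetic_landscape`.
#' @param params a [visitation_params()].
#' @param seed integer seed (drives the Poisson visitor draws only; the
#'   intensity surface is deterministic).
#' @return object of class `visitation_truth`: `cells` (per-cell metadata from
#'   [landscape_cells()]), `intensity` (cell x month x stratum x window rows),
#'   `daily_visitors`, `params`.
#' @export
simulate_visitation <- function(landscape, params = visitation_params(), seed = 1) {
  cells <- landscape_cells(landscape)
  cm <- params$class_multipliers
  cls_mult <- ifelse(cells$elc_cc %in% names(cm), cm[cells$elc_cc], 1)
  day_base <- params$baseline *
    ifelse(cells$on_trail, params$trail_multiplier, 1) * cls_mult

  frame <- expand.grid(idx = seq_len(nrow(cells)), month = params$months,
                       day_stratum = c("weekday", "weekend"),
                       window_start_hour = WINDOWS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  strat_mult <- ifelse(frame$day_stratum == "weekend", params$weekend_multiplier, 1)
  base <- ifelse(frame$window_start_hour %in% NIGHT_WINDOWS, 0,
                 day_base[frame$idx] * strat_mult)
  road <- ifelse(cells$road_flag[frame$idx], params$road_intensity, 0)
  intensity <- data.frame(
    cell_id = cells$cell_id[frame$idx],
    property_id = cells$property_id[frame$idx],
    month = frame$month, day_stratum = frame$day_stratum,
    window_start_hour = frame$window_start_hour,
    true_intensity = base + road, stringsAsFactors = FALSE)

  # property-level expected daytime intensity by stratum (sum over cells and
  # daytime windows of the road-free visitation term)
  prop_ids <- vapply(landscape$green_spaces, function(g) g$id, character(1))
  lambda <- function(pid, stratum) {
    i <- cells$property_id == pid
    mult <- if (stratum == "weekend") params$weekend_multiplier else 1
    sum(day_base[i]) * mult * length(DAY_WINDOWS)
  }
  resv_props <- prop_ids[vapply(landscape$green_spaces,
                                function(g) isTRUE(g$reservations_required),
                                logical(1))]
  daily <- with_seed(seed, {
    rows <- list()
    for (pid in resv_props) {
      for (m in params$months) {
        for (d in seq_len(WEEKDAYS_PER_MONTH + WEEKEND_PER_MONTH)) {
          stratum <- if (d <= WEEKDAYS_PER_MONTH) "weekday" else "weekend"
          mu <- params$visitor_rate * lambda(pid, stratum)
          rows[[length(rows) + 1L]] <- data.frame(
            property_id = pid, month = m, day = d, day_stratum = stratum,
            visitors = stats::rpois(1, mu), stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(property_id = character(0), month = integer(0),
                    day = integer(0), day_stratum = character(0),
                    visitors = integer(0))
  })

  structure(list(cells = cells, intensity = intensity, daily_visitors = daily,
                 params = params, grid = landscape$grid),
            class = "visitation_truth")
}

#' Anonymization parameters
#'
#' Parametric stand-ins for the vendor's unpublished privacy pipeline.
#'
#' @param threshold suppression threshold tau (pre-normalization scale);
#'   records with noisy intensity below tau are omitted entirely.
#' @param noise_sd standard deviation of zero-mean Gaussian noise added before
#'   thresholding; the noisy value is truncated at zero.
#' @param baseline positive normalization constant (January-mean analog);
#'   emitted indices are noisy intensity / baseline.
#' @param seed integer seed for the noise draws.
#' @return list of class `anonymization_params`.
#' @export
anonymization_params <- function(threshold = 0.5, noise_sd = 0, baseline = 1,
                                 seed = 1) {
  if (threshold < 0) stop("threshold must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (baseline <= 0) stop("baseline must be positive")
  structure(list(threshold = threshold, noise_sd = noise_sd,
                 baseline = baseline, seed = seed),
            class = "anonymization_params")
}

#' Render anonymized activity tiles from ground truth
#'
#' Applies noise, sub-threshold suppression and baseline normalization to the
#' truth intensity surface and emits vendor-style tile records. Suppressed
#' records are ABSENT from the output (a zero activity index never occurs).
#'
#' @param truth a `visitation_truth`.
#' @param anon an [anonymization_params()].
#' @return data.frame with columns cell_id, wkt_geometry, month, day_stratum,
#'   window_start_hour, activity_index (only surviving records).
#' @export
render_activity_tiles <- function(truth, anon = anonymization_params()) {
  stopifnot(inherits(anon, "anonymization_params"))
  int <- truth$intensity
  noisy <- with_seed(anon$seed, {
    if (anon$noise_sd > 0)
      pmax(0, int$true_intensity + stats::rnorm(nrow(int), 0, anon$noise_sd))
    else int$true_intensity
  })
  keep <- noisy >= anon$threshold & noisy > 0
  out <- int[keep, c("cell_id", "month", "day_stratum", "window_start_hour"),
             drop = FALSE]
  out$activity_index <- noisy[keep] / anon$baseline
  # attach full-cell geometry (the index always describes the whole cell)
  cellgeo <- unique(truth$cells[, c("cell_id", "col", "row")])
  wkt <- vapply(seq_len(nrow(cellgeo)), function(i)
    wkt_polygon(cell_polygon(truth$grid, cellgeo$col[i], cellgeo$row[i])),
    character(1))
  names(wkt) <- cellgeo$cell_id
  out$wkt_geometry <- unname(wkt[out$cell_id])
  rownames(out) <- NULL
  out[, c("cell_id", "wkt_geometry", "month", "day_stratum",
          "window_start_hour", "activity_index")]
}

#' Generate a reservation table consistent with truth
#'
#' Splits each property-day's true visitor count into parties (sizes 1-8,
#' shifted-Poisson) whose sizes sum exactly to the truth, with check-in hours
#' uniform on 9:00-18:00 (the reservation window).
#'
#' @param truth a `visitation_truth`.
#' @param seed integer seed.
#' @return data.frame: property_id, month, day, day_stratum, party_size,
#'   checkin_hour. Empty when no visitors anywhere.
#' @export
generate_reservations <- function(truth, seed = 1) {
  dv <- truth$daily_visitors
  with_seed(seed, {
    rows <- vector("list", nrow(dv))
    for (i in seq_len(nrow(dv))) {
      n <- dv$visitors[i]
      if (n <= 0) next
      sizes <- integer(0)
      remaining <- n
      while (remaining > 0) {
        s <- min(remaining, 1L + stats::rpois(1, 1.4), 8L)
        sizes <- c(sizes, s)
        remaining <- remaining - s
      }
      rows[[i]] <- data.frame(
        property_id = dv$property_id[i], month = dv$month[i], day = dv$day[i],
        day_stratum = dv$day_stratum[i], party_size = sizes,
        checkin_hour = round(stats::runif(length(sizes), 9, 18), 2),
        stringsAsFactors = FALSE)
    }
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) do.call(rbind, rows)
    else data.frame(property_id = character(0), month = integer(0),
                    day = integer(0), day_stratum = character(0),
                    party_size = integer(0), checkin_hour = numeric(0))
  })
}

#' Species response specification for tree-survey generation
#'
#' @param n_species number of species (>= 2).
#' @param loadings per-species response of log mean basal area to standardized
#'   property activity; default alternates sign with varying magnitude.
#' @param intercepts per-species log baseline basal area (m^2/ha scale).
#' @param year_loading magnitude of a species-specific year trend in log
#'   basal area (applied with alternating sign across species, since a
#'   species-uniform year effect scales whole rows and cancels in
#'   composition-based ordination). 0 = composition constant across years,
#'   the usual case for long-lived trees.
#' @param noise_sd lognormal noise sd on basal areas.
#' @param years survey years (>= 2 required).
#' @return list of class `species_response`.
#' @export
species_response <- function(n_species = 8,
                             loadings = NULL,
                             intercepts = NULL,
                             year_loading = 0,
                             noise_sd = 0.1,
                             years = c(2014L, 2017L, 2020L)) {
  if (n_species < 2) stop("ordination needs at least 2 species")
  if (length(years) < 2) stop("need at least 2 survey years")
  if (is.null(loadings))
    loadings <- rep_len(c(0.8, -0.8, 0.5, -0.5, 0.3, -0.3, 0.1, -0.1), n_species)
  # intercepts are paired with the +/- loading pairs so the abundance-weighted
  # mean loading is ~0: correspondence analysis sees composition, so a species
  # score reflects its loading RELATIVE to that mean, and only a centered
  # loading set makes score signs match loading signs
  if (is.null(intercepts))
    intercepts <- rep_len(c(1.5, 1.5, 1.2, 1.2, 1.0, 1.0, 0.8, 0.8), n_species)
  stopifnot(length(loadings) == n_species, length(intercepts) == n_species)
  structure(list(n_species = n_species, loadings = loadings,
                 intercepts = intercepts, year_loading = year_loading,
                 noise_sd = noise_sd, years = years),
            class = "species_response")
}

#' Generate tree-survey tables tied to property activity
#'
#' Every property is a survey site. Mean basal area of species s at site i in
#' year t is exp(intercept_s + loading_s * z_i + year_loading * z_t + noise),
#' where z_i is the standardized property-total daytime intensity -- so
#' species with positive loadings increase along the true human-activity
#' gradient, emulating composition differences across use levels.
#'
#' @param landscape a `synthetic_landscape` (>= 2 properties).
#' @param truth the matching `visitation_truth`.
#' @param effect a [species_response()].
#' @param seed integer seed.
#' @return data.frame: site_id, year, then one column per species (sp01...);
#'   attribute `"loadings"` carries the generating loadings.
#' @export
generate_tree_surveys <- function(landscape, truth, effect = species_response(),
                                  seed = 1) {
  sites <- vapply(landscape$green_spaces, function(g) g$id, character(1))
  if (length(sites) < 2) stop("ordination needs at least 2 sites")
  act <- vapply(sites, function(pid) {
    i <- truth$cells$property_id == pid & !truth$cells$road_flag
    day <- truth$intensity$property_id == pid &
      !(truth$intensity$window_start_hour %in% NIGHT_WINDOWS) &
      truth$intensity$cell_id %in% truth$cells$cell_id[i]
    sum(truth$intensity$true_intensity[day])
  }, numeric(1))
  z <- if (stats::sd(act) > 0) (act - mean(act)) / stats::sd(act) else act * 0
  zy <- if (stats::sd(effect$years) > 0)
    (effect$years - mean(effect$years)) / stats::sd(effect$years)
  else effect$years * 0
  sp_names <- sprintf("sp%02d", seq_len(effect$n_species))
  with_seed(seed, {
    rows <- list()
    for (i in seq_along(sites)) {
      for (t in seq_along(effect$years)) {
        yl <- effect$year_loading * rep_len(c(1, -1), effect$n_species)
        mu <- effect$intercepts + effect$loadings * z[i] + yl * zy[t]
        ba <- exp(mu + stats::rnorm(effect$n_species, 0, effect$noise_sd))
        row <- as.data.frame(as.list(ba))
        names(row) <- sp_names
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(site_id = sites[i], year = effect$years[t],
                     stringsAsFactors = FALSE), row)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "loadings") <- stats::setNames(effect$loadings, sp_names)
    attr(out, "activity_z") <- stats::setNames(z, sites)
    out
  })
}
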