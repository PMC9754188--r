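ls_small <- generate_landscape(small_landscape_config(trail_prob = 1,
                                                      road_prob = 1), seed = 3)

test_that("identity parameters give intensity = baseline on non-road daytime cells", {
  p <- visitation_params(baseline = 2, trail_multiplier = 1,
                         class_multipliers = c(forest = 1), weekend_multiplier = 1,
                         road_intensity = 0)
  tr <- simulate_visitation(ls_small, p, seed = 1)
  day <- !(tr$intensity$window_start_hour %in% c(0, 2, 4))
  expect_true(all(tr$intensity$true_intensity[day] == 2))
  night <- tr$intensity$window_start_hour %in% c(0, 2, 4)
  expect_true(all(tr$intensity$true_intensity[night] == 0))
})

test_that("weekend multiplier forces an exact intensity ratio on non-road cells", {
  p <- visitation_params(weekend_multiplier = 2, road_intensity = 0)
  tr <- simulate_visitation(ls_small, p, seed = 1)
  int <- tr$intensity[!(tr$intensity$window_start_hour %in% c(0, 2, 4)), ]
  wd <- int[int$day_stratum == "weekday", ]
  we <- int[int$day_stratum == "weekend", ]
  key <- function(d) paste(d$cell_id, d$month, d$window_start_hour)
  m <- match(key(wd), key(we))
  expect_true(all(is.finite(m)))
  expect_equal(we$true_intensity[m], 2 * wd$true_intensity, tolerance = 1e-12)
})

test_that("trail multiplier is recovered cell-by-cell (enumeration oracle)", {
  p <- visitation_params(trail_multiplier = 3, weekend_multiplier = 1,
                         class_multipliers = c(forest = 1), road_intensity = 0)
  # single-class landscape so only the trail flag differentiates cells
  ls1 <- generate_landscape(small_landscape_config(trail_prob = 1, road_prob = 0,
                                                   n_cover_range = c(1, 1)),
                            seed = 9)
  tr <- simulate_visitation(ls1, p, seed = 1)
  day <- tr$intensity[tr$intensity$window_start_hour == 12 &
                        tr$intensity$day_stratum == "weekday" &
                        tr$intensity$month == 6, ]
  flag <- tr$cells$on_trail[match(day$cell_id, tr$cells$cell_id)]
  expect_true(all(day$true_intensity[flag] == 3 * day$true_intensity[!flag][1]))
  expect_equal(mean(day$true_intensity[flag]) / mean(day$true_intensity[!flag]), 3)
})

test_that("negative multipliers are rejected", {
  expect_error(visitation_params(trail_multiplier = -1), "negative")
  expect_error(visitation_params(road_intensity = -2), "negative")
  expect_error(anonymization_params(threshold = -0.1), "nonnegative")
  expect_error(anonymization_params(baseline = 0), "positive")
})

truth <- simulate_visitation(ls_small, visitation_params(), seed = 4)

test_that("identity anonymization emits exactly the positive intensities", {
  tiles <- render_activity_tiles(truth, anonymization_params(threshold = 0,
                                                             noise_sd = 0,
                                                             baseline = 1))
  expect_equal(nrow(tiles), sum(truth$intensity$true_intensity > 0))
  key <- function(d) paste(d$cell_id, d$month, d$day_stratum, d$window_start_hour)
  m <- match(key(tiles), key(truth$intensity))
  expect_equal(tiles$activity_index, truth$intensity$true_intensity[m])
})

test_that("a threshold above the global max suppresses everything", {
  tau <- max(truth$intensity$true_intensity) + 1
  tiles <- render_activity_tiles(truth, anonymization_params(threshold = tau))
  expect_equal(nrow(tiles), 0)
})

test_that("threshold at the median matches a brute-force count", {
  tau <- stats::median(truth$intensity$true_intensity[truth$intensity$true_intensity > 0])
  tiles <- render_activity_tiles(truth, anonymization_params(threshold = tau))
  expect_equal(nrow(tiles), sum(truth$intensity$true_intensity >= tau &
                                  truth$intensity$true_intensity > 0))
})

test_that("suppression is monotone in the threshold", {
  taus <- c(0, 0.1, 0.5, 1, 2, 5, 10)
  counts <- vapply(taus, function(tau)
    nrow(render_activity_tiles(truth, anonymization_params(threshold = tau))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("normalization only rescales: property totals proportional to truth", {
  tiles <- render_activity_tiles(truth, anonymization_params(threshold = 0,
                                                             baseline = 7))
  cells <- truth$cells
  for (pid in unique(cells$property_id)) {
    ids <- cells$cell_id[cells$property_id == pid]
    got <- sum(tiles$activity_index[tiles$cell_id %in% ids])
    want <- sum(truth$intensity$true_intensity[truth$intensity$cell_id %in% ids]) / 7
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("tiles and noise draws are bit-identical for a fixed seed", {
  a1 <- anonymization_params(threshold = 0.3, noise_sd = 0.2, seed = 6)
  t1 <- render_activity_tiles(truth, a1)
  t2 <- render_activity_tiles(truth, a1)
  expect_identical(t1, t2)
  t3 <- render_activity_tiles(truth, anonymization_params(threshold = 0.3,
                                                          noise_sd = 0.2, seed = 7))
  expect_false(identical(t1, t3))
})

test_that("reservations aggregate exactly to the true daily visitors", {
  resv <- generate_reservations(truth, seed = 2)
  expect_identical(resv, generate_reservations(truth, seed = 2))
  agg <- stats::aggregate(party_size ~ property_id + month + day, data = resv, sum)
  dv <- truth$daily_visitors[truth$daily_visitors$visitors > 0, ]
  m <- merge(dv, agg, by = c("property_id", "month", "day"), all.x = TRUE)
  expect_true(all(m$party_size == m$visitors))
  expect_true(all(resv$checkin_hour >= 9 & resv$checkin_hour <= 18))
  # zero visitors everywhere -> empty table
  tr0 <- truth
  tr0$daily_visitors$visitors <- 0L
  expect_equal(nrow(generate_reservations(tr0, seed = 2)), 0)
})

test_that("tree surveys respond to activity as specified", {
  ls5 <- generate_landscape(landscape_config(n_properties = 5), seed = 13)
  tr5 <- simulate_visitation(ls5, visitation_params(), seed = 13)
  # all loadings 0, noise 0 -> identical composition at every site and year
  eff0 <- species_response(n_species = 4, loadings = rep(0, 4),
                           year_loading = 0, noise_sd = 0)
  s0 <- generate_tree_surveys(ls5, tr5, eff0, seed = 1)
  Y0 <- as.matrix(s0[, -(1:2)])
  expect_true(all(apply(Y0, 2, function(col) diff(range(col)) < 1e-12)))

  # one positive loading -> basal area strictly increasing in activity rank
  eff1 <- species_response(n_species = 3, loadings = c(1, 0, 0), noise_sd = 0)
  s1 <- generate_tree_surveys(ls5, tr5, eff1, seed = 1)
  z <- attr(s1, "activity_z")
  one_year <- s1[s1$year == s1$year[1], ]
  ord <- order(z[one_year$site_id])
  expect_true(all(diff(one_year$sp01[ord]) > 0))
  # exhaustive pairwise comparison
  for (i in seq_len(nrow(one_year) - 1)) for (j in seq(i + 1, nrow(one_year))) {
    zi <- z[one_year$site_id[i]]; zj <- z[one_year$site_id[j]]
    if (zi < zj) expect_lt(one_year$sp01[i], one_year$sp01[j])
    if (zi > zj) expect_gt(one_year$sp01[i], one_year$sp01[j])
  }

  # errors: too few species or sites
  expect_error(species_response(n_species = 1), "at least 2 species")
  ls1 <- generate_landscape(landscape_config(n_properties = 1), seed = 2)
  tr1 <- simulate_visitation(ls1, visitation_params(), seed = 2)
  expect_error(generate_tree_surveys(ls1, tr1, species_response(), seed = 1),
               "at least 2 sites")
})
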