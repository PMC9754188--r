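gs <- green_space("p1", poly_rect(0, 0, 1000, 500))

clip_and_filter <- function(tiles, space, night = c(0L, 2L, 4L)) {
  cells <- clip_cells(tiles_to_cells(tiles), space)
  exclude_cells(cells, flag_overnight_cells(cells, night))
}

test_that("overnight flagging is cell-global", {
  tiles <- rbind(
    make_tiles("n1", list(poly_rect(0, 0, 100, 100)), 1, window_start_hour = 2L),
    make_tiles("n1", list(poly_rect(0, 0, 100, 100)), 2, window_start_hour = 12L),
    make_tiles("d1", list(poly_rect(100, 0, 200, 100)), 1, window_start_hour = 8L),
    make_tiles("d2", list(poly_rect(200, 0, 300, 100)), 1, window_start_hour = 20L))
  flagged <- flag_overnight_cells(tiles_to_cells(tiles))
  expect_equal(flagged, "n1")
  kept <- clip_and_filter(tiles, gs)
  expect_setequal(vapply(kept, function(c) c$cell_id, character(1)), c("d1", "d2"))
})

test_that("activity density matches hand summation and the area-ratio identity", {
  # one record whose cell clips to exactly the whole property
  one <- make_tiles("w", list(poly_rect(-100, -100, 1100, 600)), 4.2)
  cells <- clip_and_filter(one, gs)
  expect_equal(activity_density(cells, gs), 4.2)
  # empty record set -> 0, not an error
  expect_equal(activity_density(list(), gs), 0)
  # three records with known clipped areas vs brute-force summation
  tiles <- make_tiles(c("a", "b", "c"),
                      list(poly_rect(0, 0, 100, 100),        # full 1e4
                           poly_rect(950, 0, 1050, 100),     # half  5e3
                           poly_rect(950, 450, 1050, 550)),  # quarter 2.5e3
                      activity_index = c(1.1, 2.2, 3.3))
  cells <- clip_and_filter(tiles, gs)
  want <- (1.1 * 1e4 + 2.2 * 5e3 + 3.3 * 2.5e3) / (1000 * 500)
  expect_equal(activity_density(cells, gs), want, tolerance = 1e-12)
})

test_that("density decomposes exactly over strata under sum aggregation", {
  set.seed(3)
  polys <- lapply(0:9, function(i) poly_rect(i * 100, 0, i * 100 + 100, 100))
  tiles <- rbind(
    make_tiles(paste0("c", 0:9), polys, runif(10, 0.5, 3), day_stratum = "weekday"),
    make_tiles(paste0("c", 0:9), polys, runif(10, 0.5, 3), day_stratum = "weekend"))
  cells <- clip_and_filter(tiles, gs)
  expect_equal(activity_density(cells, gs, "all"),
               activity_density(cells, gs, "weekday") +
                 activity_density(cells, gs, "weekend"), tolerance = 1e-12)
})

test_that("activity coverage counts each cell once and matches the union oracle", {
  polys <- lapply(0:4, function(i) poly_rect(i * 100, 0, i * 100 + 100, 100))
  # each cell has several records across windows; still counted once
  tiles <- rbind(
    make_tiles(paste0("c", 0:4), polys, 1, window_start_hour = 8L),
    make_tiles(paste0("c", 0:4), polys, 2, window_start_hour = 14L))
  cells <- clip_and_filter(tiles, gs)
  expect_equal(activity_coverage(cells, gs), 100 * 5 * 1e4 / (1000 * 500))
  expect_equal(activity_coverage(list(), gs), 0)

  # random suppression pattern against brute-force union-of-squares
  set.seed(11)
  grid <- expand.grid(i = 0:9, j = 0:4)
  keep <- grid[runif(nrow(grid)) < 0.6, ]
  polys <- lapply(seq_len(nrow(keep)), function(k)
    poly_rect(keep$i[k] * 100, keep$j[k] * 100,
              keep$i[k] * 100 + 100, keep$j[k] * 100 + 100))
  tiles <- make_tiles(sprintf("g%d", seq_len(nrow(keep))), polys,
                      runif(nrow(keep), 0.5, 2))
  cells <- clip_and_filter(tiles, gs)
  expect_equal(activity_coverage(cells, gs),
               100 * nrow(keep) * 1e4 / (1000 * 500), tolerance = 1e-9)
})

test_that("coverage after overnight exclusion never exceeds coverage before", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 12
    polys <- lapply(seq_len(n), function(i)
      poly_rect((i - 1) * 80, 0, (i - 1) * 80 + 100, 100))
    tiles <- make_tiles(sprintf("c%d", seq_len(n)), polys, runif(n, 0.5, 2),
                        window_start_hour = sample(seq(0L, 22L, 2L), n, TRUE))
    cells <- clip_cells(tiles_to_cells(tiles), gs)
    pre <- activity_coverage(cells, gs)
    post <- activity_coverage(exclude_cells(cells, flag_overnight_cells(cells)), gs)
    expect_lte(post, pre + 1e-12)
  }
})

test_that("trail density is length over area in km per km^2", {
  expect_equal(trail_density(cbind(c(0, 1000), c(250, 250)),
                             green_space("sq", poly_rect(0, 0, 1000, 1000))), 1)
  expect_equal(trail_density(list(), gs), 0)
  # multi-segment network with a part outside the property
  net <- list(list(geometry = cbind(c(0, 300, 300), c(100, 100, 400))),
              list(geometry = cbind(c(-200, 200), c(200, 200))))
  want_m <- 300 + 300 + 200
  expect_equal(trail_density(net, gs), (want_m / 1000) / (gs$area / 1e6))
})

test_that("on-trail percentage classifies cells like brute force and flags NA", {
  polys <- lapply(0:4, function(i) poly_rect(i * 100, 0, i * 100 + 100, 100))
  tiles <- make_tiles(paste0("c", 0:4), polys, 1)
  cells <- clip_and_filter(tiles, gs)
  trail_all <- cbind(c(0, 500), c(50, 50))      # crosses every cell
  expect_equal(on_trail_activity_pct(cells, trail_all), 100)
  expect_equal(on_trail_activity_pct(cells, list()), 0)
  trail_two <- cbind(c(0, 150), c(50, 50))      # crosses cells 0 and 1
  expect_equal(on_trail_activity_pct(cells, trail_two), 100 * 2 / 5)
  expect_true(is.na(on_trail_activity_pct(list(), trail_all)))
})

test_that("land-cover usage fractions match intersection areas and sum to 1", {
  cover <- list(list(property_id = "p1", elc_cc = "forest",
                     geometry = poly_rect(0, 0, 600, 500)),
                list(property_id = "p1", elc_cc = "marsh",
                     geometry = poly_rect(600, 0, 1000, 500)))
  # single class covering property
  cover1 <- list(list(property_id = "p1", elc_cc = "forest",
                      geometry = poly_rect(0, 0, 1000, 500)))
  polys <- lapply(0:4, function(i) poly_rect(i * 100, 0, i * 100 + 100, 100))
  tiles <- make_tiles(paste0("c", 0:4), polys, 1)
  cells <- clip_and_filter(tiles, gs)
  u1 <- landcover_usage(cells, cover1, gs)
  expect_equal(u1$prop_activity_by_class, 1)

  # activity confined to one of two classes
  u <- landcover_usage(cells, cover, gs)
  expect_equal(u$prop_activity_by_class[u$elc_cc == "forest"], 1)
  expect_equal(u$prop_activity_by_class[u$elc_cc == "marsh"], 0)
  expect_equal(u$prop_class_used[u$elc_cc == "forest"],
               5 * 1e4 / (600 * 500), tolerance = 1e-12)

  # straddling cell split between classes; fractions sum to 1
  tiles2 <- make_tiles(c("l", "x", "r"),
                       list(poly_rect(400, 0, 500, 100),
                            poly_rect(550, 0, 650, 100),
                            poly_rect(800, 0, 900, 100)), 1)
  cells2 <- clip_and_filter(tiles2, gs)
  u2 <- landcover_usage(cells2, cover, gs)
  expect_equal(sum(u2$prop_activity_by_class), 1, tolerance = 1e-9)
  expect_equal(u2$activity_area[u2$elc_cc == "forest"], 1e4 + 5e3,
               tolerance = 1e-9)
})

test_that("summarize_activity runs the canonical order and reports counts", {
  polys <- lapply(0:3, function(i) poly_rect(i * 100, 0, i * 100 + 100, 100))
  tiles <- rbind(
    make_tiles(paste0("c", 0:3), polys, c(1, 1, 1, 5)),
    make_tiles("c3", list(polys[[4]]), 4, window_start_hour = 2L))  # road-like
  s <- summarize_activity(tiles, gs, trails = list(list(geometry = cbind(c(0, 400), c(50, 50)))))
  all_row <- s[s$day_stratum == "all", ]
  expect_equal(all_row$n_cells_excluded, 1)
  expect_equal(all_row$n_cells_retained, 3)
  expect_equal(all_row$activity_density, 3 * 1e4 / gs$area)
  expect_equal(all_row$activity_coverage_pct, 100 * 3e4 / gs$area)
  expect_equal(all_row$on_trail_pct, 100)
  # weekend row has no records -> zero density, NA on-trail
  we <- s[s$day_stratum == "weekend", ]
  expect_equal(we$activity_density, 0)
  expect_true(is.na(we$on_trail_pct))
})
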