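test_that("hex grid has uniform centroid spacing and covers the bbox", {
  bbox <- c(-74.05, 40.55, -73.70, 40.95)
  grid <- build_hex_grid(bbox)
  cells <- grid$cells
  # sample cells; all six axial neighbors at exactly 2640 ft
  withr::local_seed(2)
  idx <- sample(nrow(cells), 30)
  nbrs <- rbind(c(1, 0), c(1, -1), c(0, -1), c(-1, 0), c(-1, 1), c(0, 1))
  key <- paste(cells$q, cells$r)
  for (i in idx) {
    for (k in 1:6) {
      j <- match(paste(cells$q[i] + nbrs[k, 1], cells$r[i] + nbrs[k, 2]),
                 key)
      if (is.na(j)) next
      d <- sqrt((cells$cx[i] - cells$cx[j])^2 +
                (cells$cy[i] - cells$cy[j])^2)
      expect_equal(d, 2640, tolerance = 1e-6)
    }
  }
  # every random point in the bbox maps to the nearest centroid
  lon <- runif(200, bbox[1], bbox[3])
  lat <- runif(200, bbox[2], bbox[4])
  assigned <- assign_cells(grid, lon, lat)
  p <- foodenv:::project_xy(grid$projection, lon, lat)
  for (i in seq_len(200)) {
    d2 <- (cells$cx - p$x[i])^2 + (cells$cy - p$y[i])^2
    nearest <- which.min(d2)
    expect_equal(c(assigned$q[i], assigned$r[i]),
                 c(cells$q[nearest], cells$r[nearest]))
  }
})

test_that("degenerate and invalid grids are handled", {
  tiny <- build_hex_grid(c(-73.951, 40.749, -73.949, 40.751))
  expect_gte(nrow(tiny$cells), 1)
  a <- assign_cells(tiny, -73.95, 40.75)
  expect_true(paste(a$q, a$r) %in% paste(tiny$cells$q, tiny$cells$r))
  expect_error(build_hex_grid(c(-74, 41, -73, 40)), "bbox")
  expect_error(build_hex_grid(c(-74, 40, -73, 41), spacing_ft = -1),
               "spacing")
  expect_error(build_hex_grid(c(-74, 40, -73, 41), crs_id = "EPSG:4326"),
               "geographic")
})

test_that("operating intervals follow inspection dates and closures", {
  iv <- operating_interval(
    list(as.Date(c("2015-03-01", "2018-06-01")), as.Date("2019-05-01")),
    as.Date(c(NA, "2020-02-01")))
  expect_equal(iv$start, as.Date(c("2015-03-01", "2019-05-01")))
  expect_equal(iv$end, as.Date(c("2018-06-01", "2020-02-01")))
  op <- function(i, y) foodenv:::operating_in_year(iv[i, ], y)
  expect_true(all(vapply(2015:2018, function(y) op(1, y), logical(1))))
  expect_false(op(1, 2019))
  expect_true(op(2, 2019) && op(2, 2020))
  expect_false(op(2, 2021))
  expect_warning(operating_interval(list(as.Date(character())),
                                    as.Date(NA)), "excluded")
})

test_that("year membership equals brute-force interval intersection", {
  withr::local_seed(14)
  for (rep in 1:25) {
    dates <- as.Date("2015-01-01") + sample(0:2500, sample(1:5, 1))
    oob <- if (runif(1) < 0.5) max(dates) + sample(1:400, 1) else
      as.Date(NA)
    iv <- operating_interval(list(dates), oob)
    for (y in 2015:2022) {
      days <- seq(as.Date(sprintf("%d-01-01", y)),
                  as.Date(sprintf("%d-12-31", y)), by = "day")
      brute <- any(days >= iv$start[1] & days <= iv$end[1])
      expect_identical(foodenv:::operating_in_year(iv, y), brute)
    }
  }
})

churn_fixture <- function(seed = 23, closure = 0, planted = list()) {
  cfg <- synth_config(n_stores = 250, closure_rate = closure,
                      planted_churn = planted,
                      year_range = c(2019, 2021), seed = seed)
  list(cfg = cfg, g = generate_longitudinal(cfg),
       grid = build_hex_grid(cfg$bbox))
}

test_that("static directories have zero churn everywhere", {
  fx <- churn_fixture()
  cm <- mean_annual_change(fx$g$records, fx$g$labels, fx$grid,
                           food_classes(), 2019, 2021)
  expect_true(all(cm$cells$mean_annual_change == 0))
  expect_true(all(cm$cells$count_y0 == cm$cells$count_y1))
})

test_that("constructed and planted cell deltas are recovered exactly", {
  # direct arithmetic: 4 grocery stores in 2019, 2 remain in 2021
  recs <- do.call(rbind, lapply(1:4, function(i) {
    r <- make_record(sprintf("G%d", i), "grocery", lon = -73.9, lat = 40.7)
    last <- if (i <= 2) 2019 else 2021
    r$inspection_dates <- list(as.Date(sprintf(c("2019-02-01"))))
    r$out_of_business_date <- if (i <= 2) as.Date("2019-11-01") else
      as.Date(NA)
    if (last == 2021)
      r$inspection_dates <- list(as.Date(c("2019-02-01", "2021-03-01")))
    r
  }))
  grid <- build_hex_grid(c(-74, 40.5, -73.8, 40.9))
  cm <- mean_annual_change(recs, as_label_matrix(rep(list("Grocery"), 4)),
                           grid, "Grocery", 2019, 2021)
  cell <- assign_cells(grid, -73.9, 40.7)
  got <- cm$cells[cm$cells$q == cell$q & cm$cells$r == cell$r, ]
  expect_equal(got$count_y0, 4)
  expect_equal(got$count_y1, 2)
  expect_equal(got$mean_annual_change, -1.0)

  # generator plant: -2 per year at an anchor point
  pl <- list(list(lon = -73.87, lat = 40.81, classes = "Grocery",
                  delta = -2))
  fx <- churn_fixture(seed = 29, planted = pl)
  cm2 <- mean_annual_change(fx$g$records, fx$g$labels, fx$grid, "Grocery",
                            2019, 2021)
  pc <- assign_cells(fx$grid, pl[[1]]$lon, pl[[1]]$lat)
  got2 <- cm2$cells[cm2$cells$q == pc$q & cm2$cells$r == pc$r, ]
  expect_equal(got2$mean_annual_change, -2.0)
})

test_that("churn is additive over label-disjoint class groups", {
  fx <- churn_fixture(seed = 37, closure = 0.25)
  lab_g <- fx$g$labels
  # make the two groups label-disjoint: drop stores holding both
  both <- lab_g[, "Grocery"] & lab_g[, "Convenience"]
  recs <- fx$g$records[!both, ]
  labs <- lab_g[!both, ]
  mA <- mean_annual_change(recs, labs, fx$grid, "Grocery", 2019, 2021)
  mB <- mean_annual_change(recs, labs, fx$grid, "Convenience", 2019, 2021)
  mAB <- mean_annual_change(recs, labs, fx$grid,
                            c("Grocery", "Convenience"), 2019, 2021)
  expect_equal(mAB$cells$count_y0, mA$cells$count_y0 + mB$cells$count_y0)
  expect_equal(mAB$cells$mean_annual_change,
               mA$cells$mean_annual_change + mB$cells$mean_annual_change)
})

test_that("cell deltas sum to the directory-wide net change", {
  fx <- churn_fixture(seed = 41, closure = 0.3)
  cm <- mean_annual_change(fx$g$records, fx$g$labels, fx$grid, "Restaurant",
                           2019, 2021)
  iv <- operating_interval(fx$g$records$inspection_dates,
                           fx$g$records$out_of_business_date)
  in_g <- fx$g$labels[, "Restaurant"]
  net <- sum(in_g & foodenv:::operating_in_year(iv, 2021)) -
    sum(in_g & foodenv:::operating_in_year(iv, 2019))
  expect_equal(sum(cm$cells$count_y1) - sum(cm$cells$count_y0), net)
  expect_error(mean_annual_change(fx$g$records, fx$g$labels, fx$grid,
                                  character(), 2019, 2021), "class_group")
  expect_error(mean_annual_change(fx$g$records, fx$g$labels, fx$grid,
                                  "Grocery", 2021, 2019), "greater")
})

test_that("GeoJSON export writes valid polygons with churn properties", {
  fx <- churn_fixture(seed = 43, closure = 0.2)
  cm <- mean_annual_change(fx$g$records, fx$g$labels, fx$grid,
                           "Convenience", 2019, 2021)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_churn_geojson(cm, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_gt(length(gj$features), 0)
  f <- gj$features[[1]]
  expect_equal(f$geometry$type, "Polygon")
  ring <- f$geometry$coordinates[[1]]
  expect_length(ring, 7)  # closed hexagon
  expect_identical(ring[[1]], ring[[7]])
  expect_true(all(c("count_y0", "count_y1", "mean_annual_change") %in%
                  names(f$properties)))
})
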