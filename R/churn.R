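#' @title Temporospatial churn on a hexagonal grid
#' @description Assigns point-located stores to flat-top hexagonal cells
#'   whose adjacent centroids are a fixed walking distance apart (default
#'   2,640 ft, a half mile — roughly a 10-minute walk), determines each
#'   store's evident operating interval from inspection dates and the
#'   recorded out-of-business date, and computes per-cell mean annual
#'   change in operating counts for a class group over a year window.
#'   The custom grid avoids tying the analysis to administrative
#'   boundaries (the modifiable areal unit problem).
#' @name churn
NULL

FT_PER_M <- 3.28084
EARTH_R_M <- 6371008.8

# Local equirectangular projection centred on the bbox: planar feet
# coordinates adequate for city-scale binning. Geographic (unprojected)
# CRS identifiers are rejected: hex binning needs linear units.
make_projection <- function(bbox, crs_id = "local-equirect-ft") {
  if (grepl("4326|wgs\\s*84|geographic", tolower(crs_id)))
    stop("crs '", crs_id, "' is geographic (unprojected); hex binning ",
         "requires a projected CRS with linear units — use the default ",
         "local equirectangular projection or supply a projected CRS id",
         call. = FALSE)
  lon0 <- (bbox[1L] + bbox[3L]) / 2
  lat0 <- (bbox[2L] + bbox[4L]) / 2
  k <- EARTH_R_M * pi / 180 * FT_PER_M
  list(crs_id = crs_id, lon0 = lon0, lat0 = lat0,
       kx = k * cos(lat0 * pi / 180), ky = k)
}

project_xy <- function(proj, lon, lat) {
  list(x = (lon - proj$lon0) * proj$kx, y = (lat - proj$lat0) * proj$ky)
}

unproject_xy <- function(proj, x, y) {
  list(lon = x / proj$kx + proj$lon0, lat = y / proj$ky + proj$lat0)
}

#' Build a flat-top hexagonal grid covering a bounding box
#'
#' Centroid spacing (distance between any two adjacent cell centroids) is
#' `spacing_ft`; with flat-top axial indexing this makes the hexagon size
#' (centre-to-corner) `spacing_ft / sqrt(3)`. Cell centroids are laid out
#' at `x = 1.5 a q`, `y = sqrt(3) a (r + q/2)` for axial indices `(q, r)`.
#'
#' @param bbox `c(lon_min, lat_min, lon_max, lat_max)` in WGS84 degrees.
#' @param spacing_ft Centroid-to-centroid distance in feet (default
#'   2640, one half mile).
#' @param crs_id Identifier recorded for the projected CRS; geographic
#'   identifiers are rejected.
#' @return A `hex_grid`: cells data.frame (`q`, `r`, `cx`, `cy` in feet,
#'   `lon`, `lat`), the projection, and the spacing.
#' @export
build_hex_grid <- function(bbox, spacing_ft = 2640, crs_id = "local-equirect-ft") {
  if (length(bbox) != 4L || bbox[1L] >= bbox[3L] || bbox[2L] >= bbox[4L])
    stop("bbox must be c(lon_min, lat_min, lon_max, lat_max) with ",
         "positive extent", call. = FALSE)
  if (spacing_ft <= 0) stop("spacing_ft must be positive", call. = FALSE)
  proj <- make_projection(bbox, crs_id)
  a <- spacing_ft / sqrt(3)
  c1 <- project_xy(proj, bbox[1L], bbox[2L])
  c2 <- project_xy(proj, bbox[3L], bbox[4L])
  q_rng <- floor(c1$x / (1.5 * a)) : ceiling(c2$x / (1.5 * a))
  cells <- do.call(rbind, lapply(q_rng, function(q) {
    cx <- 1.5 * a * q
    r_lo <- floor(c1$y / (sqrt(3) * a) - q / 2) - 1L
    r_hi <- ceiling(c2$y / (sqrt(3) * a) - q / 2) + 1L
    r <- r_lo:r_hi
    data.frame(q = q, r = r, cx = cx, cy = sqrt(3) * a * (r + q / 2))
  }))
  ll <- unproject_xy(proj, cells$cx, cells$cy)
  cells$lon <- ll$lon; cells$lat <- ll$lat
  structure(list(cells = cells, size = a, spacing_ft = spacing_ft,
                 projection = proj, bbox = bbox),
            class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat("<hex_grid> ", nrow(x$cells), " cells, centroid spacing ",
      x$spacing_ft, " ft (", x$projection$crs_id, ")\n", sep = "")
  invisible(x)
}

# cube-rounding of fractional axial coordinates: yields the cell whose
# centroid is nearest the point
axial_round <- function(qf, rf) {
  sf <- -qf - rf
  q <- round(qf); r <- round(rf); s <- round(sf)
  dq <- abs(q - qf); dr <- abs(r - rf); ds <- abs(s - sf)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  q[fix_q] <- -r[fix_q] - s[fix_q]
  r[fix_r] <- -q[fix_r] - s[fix_r]
  list(q = q, r = r)
}

#' Assign points to hex cells
#'
#' @param grid A `hex_grid`.
#' @param lon,lat Numeric vectors of WGS84 coordinates.
#' @return Data.frame with columns `q`, `r` (axial cell index per point).
#' @export
assign_cells <- function(grid, lon, lat) {
  p <- project_xy(grid$projection, lon, lat)
  a <- grid$size
  qf <- (2 / 3) * p$x / a
  rf <- (-p$x / 3 + sqrt(3) / 3 * p$y) / a
  ax <- axial_round(qf, rf)
  data.frame(q = ax$q, r = ax$r)
}

#' Evident operating interval of a store
#'
#' The interval runs from the earliest inspection date to the recorded
#' out-of-business date, or to the latest inspection date when no closure
#' is recorded. A store counts as operating in a calendar year iff the
#' interval intersects it. Records with no inspection dates are excluded
#' with a warning.
#'
#' @param inspection_dates List of Date vectors (one element per record).
#' @param out_of_business Date vector (NA when still operating).
#' @return Data.frame with `start`, `end` Dates; NA rows for excluded
#'   records.
#' @export
operating_interval <- function(inspection_dates, out_of_business) {
  n <- length(inspection_dates)
  start <- end <- as.Date(rep(NA, n))
  empty <- !vapply(inspection_dates, length, 0L)
  if (any(empty))
    warning(sum(empty), " record(s) without inspection dates excluded ",
            "from operating intervals", call. = FALSE)
  for (i in which(!empty)) {
    d <- sort(as.Date(inspection_dates[[i]]))
    start[i] <- d[1L]
    end[i] <- if (!is.na(out_of_business[i]))
      as.Date(out_of_business[i]) else d[length(d)]
  }
  data.frame(start = start, end = end)
}

operating_in_year <- function(interval, year) {
  y_start <- as.Date(sprintf("%d-01-01", year))
  y_end <- as.Date(sprintf("%d-12-31", year))
  !is.na(interval$start) & interval$start <= y_end & interval$end >= y_start
}

#' Per-cell mean annual change in operating stores of a class group
#'
#' A record contributes to a cell-year count iff its label set intersects
#' `class_group` (non-exclusive classes: a Grocery+Convenience store
#' counts in both a Grocery-group and a Convenience-group map) and its
#' operating interval intersects that year. Per cell, the mean annual
#' change is `(count_y1 - count_y0) / (y1 - y0)` — identical, by
#' telescoping, to the mean of consecutive annual differences. Every grid
#' cell is reported, zero-count cells included with change 0.
#'
#' @param records Storefront data.frame with `longitude`, `latitude`,
#'   `inspection_dates` (list of Dates), `out_of_business_date`.
#' @param labels Label matrix aligned with `records`.
#' @param grid A `hex_grid`.
#' @param class_group Character vector of food classes (non-empty).
#' @param y0,y1 Window years, `y1 > y0`.
#' @return A `churn_map`: cells data.frame (`q`, `r`, `lon`, `lat`,
#'   `count_y0`, `count_y1`, `mean_annual_change`) plus window metadata.
#' @export
mean_annual_change <- function(records, labels, grid, class_group, y0, y1) {
  if (!length(class_group))
    stop("class_group must be non-empty", call. = FALSE)
  bad <- setdiff(class_group, food_classes())
  if (length(bad))
    stop("unknown food class name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (y1 <= y0) stop("y1 must be greater than y0", call. = FALSE)
  labels <- as_label_matrix(labels)
  in_group <- rowSums(labels[, class_group, drop = FALSE]) > 0
  interval <- operating_interval(records$inspection_dates,
                                 records$out_of_business_date)
  cell <- assign_cells(grid, records$longitude, records$latitude)
  key <- paste(cell$q, cell$r)
  cells <- grid$cells
  cell_key <- paste(cells$q, cells$r)
  tally <- function(year) {
    ok <- in_group & operating_in_year(interval, year)
    tab <- table(key[ok])
    cnt <- integer(nrow(cells))
    m <- match(names(tab), cell_key)
    keep <- !is.na(m)
    cnt[m[keep]] <- as.integer(tab)[keep]
    cnt
  }
  c0 <- tally(y0); c1 <- tally(y1)
  out <- data.frame(q = cells$q, r = cells$r, lon = cells$lon,
                    lat = cells$lat, count_y0 = c0, count_y1 = c1,
                    mean_annual_change = (c1 - c0) / (y1 - y0))
  structure(list(cells = out, class_group = class_group, y0 = y0, y1 = y1,
                 grid = grid), class = "churn_map")
}

#' @export
print.churn_map <- function(x, ...) {
  nz <- x$cells[x$cells$count_y0 > 0 | x$cells$count_y1 > 0, ]
  cat("<churn_map> {", paste(x$class_group, collapse = ", "), "} ",
      x$y0, "-", x$y1, ": ", nrow(nz), " occupied cells, net change ",
      sum(x$cells$count_y1) - sum(x$cells$count_y0), "\n", sep = "")
  invisible(x)
}

hex_vertices <- function(grid, cx, cy) {
  ang <- (0:5) * pi / 3  # flat-top: first vertex due east
  x <- cx + grid$size * cos(ang)
  y <- cy + grid$size * sin(ang)
  ll <- unproject_xy(grid$projection, x, y)
  cbind(c(ll$lon, ll$lon[1L]), c(ll$lat, ll$lat[1L]))
}

#' Write a churn map to GeoJSON
#'
#' One polygon feature per cell with properties `q`, `r`, `count_y0`,
#' `count_y1`, `mean_annual_change`. By default only cells occupied in at
#' least one window year are written.
#'
#' @param churn A `churn_map`.
#' @param path Output path.
#' @param occupied_only Drop never-occupied cells (default TRUE).
#' @return `path`, invisibly.
#' @export
write_churn_geojson <- function(churn, path, occupied_only = TRUE) {
  stopifnot(inherits(churn, "churn_map"))
  cells <- churn$cells
  if (occupied_only)
    cells <- cells[cells$count_y0 > 0 | cells$count_y1 > 0, , drop = FALSE]
  grid <- churn$grid
  p <- project_xy(grid$projection, cells$lon, cells$lat)
  features <- lapply(seq_len(nrow(cells)), function(i) {
    ring <- hex_vertices(grid, p$x[i], p$y[i])
    list(type = "Feature",
         properties = list(q = cells$q[i], r = cells$r[i],
                           count_y0 = cells$count_y0[i],
                           count_y1 = cells$count_y1[i],
                           mean_annual_change = cells$mean_annual_change[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                 function(j) c(ring[j, 1L], ring[j, 2L])))))
  })
  gj <- list(type = "FeatureCollection",
             properties = list(crs_id = grid$projection$crs_id,
                               spacing_ft = grid$spacing_ft,
                               class_group = churn$class_group,
                               y0 = churn$y0, y1 = churn$y1),
             features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
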