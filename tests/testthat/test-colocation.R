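square_farm <- function(id, x0, x1, y0, y1, status = "production")
  list(id = id, name = id, type = "polygon",
       geometry = cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)),
       attributes = list(status = status))

test_that("zonal mean averages covered cell centers", {
  g <- make_grid(c(0, 2, 50, 52), 0.25)
  uni <- raster_layer(g, matrix(0.7, 8, 8))
  farms <- vector_set(list(square_farm("f1", 0.3, 1.2, 50.3, 51.4)))
  expect_equal(zonal_mean(uni, farms)$value, 0.7)
  # a polygon covering exactly two cell centers averages them
  v <- matrix(0, 8, 8)
  v[1, 1] <- 0.6; v[1, 2] <- 0.8 # centers (0.125, 50.125), (0.375, 50.125)
  two <- vector_set(list(square_farm("f2", 0.01, 0.49, 50.01, 50.24)))
  expect_equal(zonal_mean(raster_layer(g, v), two)$value, 0.7)
  # a tiny polygon with no center inside takes the nearest-center value
  tiny <- vector_set(list(square_farm("f3", 0.30, 0.34, 50.30, 50.34)))
  expect_equal(zonal_mean(raster_layer(g, v), tiny)$value,
               v[2, 2])
})

test_that("zonal mean equals a ray-casting point-in-polygon oracle", {
  g <- make_grid(c(0, 2, 50, 52), 0.25)
  set.seed(81)
  for (i in 1:10) {
    v <- matrix(stats::runif(64), 8, 8)
    x0 <- stats::runif(1, 0, 1.2); y0 <- stats::runif(1, 50, 51.2)
    farm <- square_farm("f", x0, x0 + stats::runif(1, 0.3, 0.7),
                        y0, y0 + stats::runif(1, 0.3, 0.7))
    got <- zonal_mean(raster_layer(g, v), vector_set(list(farm)))$value
    ring <- farm$geometry
    acc <- c()
    for (r in 1:8) for (c in 1:8) {
      if (oracle_point_in_polygon(grid_lons(g)[c], grid_lats(g)[r], ring))
        acc <- c(acc, v[r, c])
    }
    if (length(acc)) expect_equal(got, mean(acc), tolerance = 1e-12)
    # zonal mean lies within the covered min/max
    if (length(acc)) {
      expect_gte(got, min(acc)); expect_lte(got, max(acc))
    }
  }
})

test_that("missing cells are excluded; fully missing farms get NA", {
  g <- make_grid(c(0, 2, 50, 52), 0.25)
  v <- matrix(0.5, 8, 8)
  v[3:4, 3:4] <- NA
  v[3, 5] <- 0.9
  farms <- vector_set(list(
    square_farm("partial", 0.51, 1.24, 50.51, 50.99), # covers NA + 0.9 area
    square_farm("allmiss", 0.51, 0.99, 50.51, 50.99)))
  zm <- zonal_mean(raster_layer(g, v), farms)
  expect_false(is.na(zm$value[1]))
  expect_true(is.na(zm$value[2]))
})

test_that("farm ranking is SI desc, accessibility desc, id — and total", {
  rec <- data.frame(id = c("d", "c", "b", "a", "e"),
                    si = c(0.7, 0.8, 0.8, 0.8, NA),
                    accessibility = c(99, 50, 90, 90, 100),
                    stringsAsFactors = FALSE)
  r <- rank_farms(rec)
  expect_identical(r$id, c("a", "b", "c", "d", "e"))
  expect_identical(r$rank, 1:5)
  expect_true(r$si_missing[5])
  expect_identical(sort(r$id), sort(rec$id)) # total order, no loss
  # deterministic under resampling of input order
  r2 <- rank_farms(rec[sample(5), ])
  expect_identical(r2$id, r$id)
})

test_that("farm report carries the full column set and spherical areas", {
  b <- generate_scenario(small_scenario(seed = 82, n_farms = 5))
  g <- b$coarse_grid
  si <- raster_layer(g, matrix(0.6, g$nlat, g$nlon))
  dsi <- raster_layer(g, matrix(2.5, g$nlat, g$nlon))
  acc <- raster_layer(g, matrix(80, g$nlat, g$nlon))
  dist <- raster_layer(g, matrix(12, g$nlat, g$nlon))
  rep1 <- farm_report(b$farms, si, dsi, acc, dist)
  expect_equal(nrow(rep1), 5)
  expect_true(all(c("id", "name", "status", "area_km2", "si",
                    "dsi_2050_pct", "distance_to_port_nm",
                    "accessibility_pct", "rank") %in% names(rep1)))
  expect_true(all(rep1$status %in% c("production", "accepted", "planned")))
  expect_true(all(rep1$area_km2 > 0))
  # a 0.1 x 0.1 degree square at the equator matches the closed form
  sq <- vector_set(list(square_farm("eq", 0, 0.1, -0.05, 0.05)))
  geq <- make_grid(c(-1, 1, -1, 1), 0.25)
  si_eq <- raster_layer(geq, matrix(0.5, 8, 8))
  rep2 <- farm_report(sq, si_eq, NULL, si_eq, si_eq)
  R <- 6371
  closed <- R^2 * (0.1 * pi / 180) *
    (sin(0.05 * pi / 180) - sin(-0.05 * pi / 180))
  expect_equal(rep2$area_km2, closed, tolerance = 1e-3)
  # identical inputs give a byte-identical CSV
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ranking_csv(rep1, f1)
  write_ranking_csv(farm_report(b$farms, si, dsi, acc, dist), f2)
  expect_identical(readLines(f1), readLines(f2))
})
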