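test_that("a fixed seed gives identical bundles; fields obey the layout", {
  cfg <- small_scenario(seed = 5)
  b1 <- generate_scenario(cfg)
  b2 <- generate_scenario(cfg)
  expect_identical(b1$sst$values, b2$sst$values)
  expect_identical(b1$waves$values, b2$waves$values)
  expect_identical(b1$sss$values, b2$sss$values)
  expect_identical(lapply(b1$farms$features, `[[`, "geometry"),
                   lapply(b2$farms$features, `[[`, "geometry"))
  # cadences mirror the emulated products
  expect_identical(b1$sst$cadence, "daily")
  expect_identical(b1$chl$cadence, "daily")
  expect_identical(b1$current$cadence, "daily")
  expect_identical(b1$sss$cadence, "monthly")
  expect_identical(b1$spm$cadence, "monthly")
  expect_identical(b1$waves$cadence, "3-hourly")
})

test_that("zero-noise SST is exactly the gradient plus seasonal cycle", {
  cfg <- small_scenario(seed = 6,
                        sst = list(south_mean = 14, gradient = 0.8,
                                   seasonal_amp = 5, noise_sd = 0,
                                   noise_rho = 0.8),
                        heat_spikes = list())
  b <- generate_scenario(cfg)
  lat <- grid_lats(b$fine_grid)
  doy <- as.POSIXlt(b$sst$times)$yday
  sea_col <- b$fine_grid$nlon # easternmost column is open sea
  for (t in c(1, 100, 300)) {
    expected <- 14 - 0.8 * (lat - 50) +
      5 * cos(2 * pi * (doy[t] - 210) / 365.25)
    expect_equal(b$sst$values[t, , sea_col], expected, tolerance = 1e-12)
  }
  # zonal-mean SST strictly decreases poleward
  zonal <- rowMeans(apply(b$sst$values, c(2, 3), mean), na.rm = TRUE)
  expect_true(all(diff(zonal) < 0))
  expect_gt(zonal[1], zonal[length(zonal)])
})

test_that("chlorophyll and sediment are enriched toward the coast", {
  b <- generate_scenario(small_scenario(seed = 7))
  chl_mean <- apply(b$chl$values, c(2, 3), mean)
  spm_mean <- apply(b$spm$values, c(2, 3), mean)
  sea_cols <- which(!is.na(chl_mean[1, ]))
  nearshore <- sea_cols[1:3]
  offshore <- utils::tail(sea_cols, 3)
  expect_gt(mean(chl_mean[, nearshore], na.rm = TRUE),
            mean(chl_mean[, offshore], na.rm = TRUE))
  expect_gt(mean(spm_mean[, nearshore], na.rm = TRUE),
            mean(spm_mean[, offshore], na.rm = TRUE))
})

test_that("the low-salinity basin stays well below the marine baseline", {
  cfg <- small_scenario(seed = 8)
  b <- generate_scenario(cfg)
  g <- b$coarse_grid
  lon <- matrix(grid_lons(g), g$nlat, g$nlon, byrow = TRUE)
  lat <- matrix(grid_lats(g), g$nlat, g$nlon)
  box <- cfg$sss$basin
  basin <- lon >= box[1] & lon <= box[2] & lat >= box[3] & lat <= box[4]
  contrast <- cfg$sss$baseline - cfg$sss$basin_value
  limit <- cfg$sss$baseline - contrast / 2
  for (t in seq_along(b$sss$times)) {
    slice <- b$sss$values[t, , ]
    expect_true(all(slice[basin] < limit, na.rm = TRUE))
  }
})

test_that("injected heat spikes are exact and leave the outside untouched", {
  cfg <- small_scenario(seed = 9, heat_spikes = list())
  b <- generate_scenario(cfg)
  region <- c(0.5, 0.9, 50.2, 50.6)
  spiked <- inject_heat_spikes(b$sst, region, episodes = 1, duration = 3)
  counts <- count_heat_spike_episodes(spiked)
  g <- b$fine_grid
  lon <- matrix(grid_lons(g), g$nlat, g$nlon, byrow = TRUE)
  lat <- matrix(grid_lats(g), g$nlat, g$nlon)
  inside <- lon >= region[1] & lon <= region[2] &
    lat >= region[3] & lat <= region[4]
  expect_true(all(counts$values[inside] == 1))
  expect_true(all(counts$values[!inside] == 0, na.rm = TRUE))
  # outside the region the series is bitwise unchanged
  out_cell <- which(!inside & !is.na(counts$values))[1]
  flat0 <- matrix(b$sst$values, nrow = length(b$sst$times))
  flat1 <- matrix(spiked$values, nrow = length(spiked$times))
  expect_identical(flat1[, out_cell], flat0[, out_cell])
  # zero episodes requested leaves the stack unchanged by default
  expect_identical(inject_heat_spikes(b$sst, region, 0, 3)$values,
                   b$sst$values)
  # too many episodes for the record length is a configuration error
  expect_error(inject_heat_spikes(b$sst, region, 80, 5), "too short")
})

test_that("farm generation is seeded, disjoint and inside the region", {
  expect_equal(length(generate_farms(0, c(0, 1, 50, 51), 1)), 0L)
  region <- c(0.2, 1.4, 50.2, 51.4)
  f1 <- generate_farms(5, region, seed = 10)
  f2 <- generate_farms(5, region, seed = 10)
  expect_identical(lapply(f1$features, `[[`, "geometry"),
                   lapply(f2$features, `[[`, "geometry"))
  boxes <- lapply(f1$features, function(f) apply(f$geometry, 2, range))
  for (b in boxes) {
    expect_true(b[1, 1] >= region[1] && b[2, 1] <= region[2])
    expect_true(b[1, 2] >= region[3] && b[2, 2] <= region[4])
  }
  for (i in 1:4) for (j in (i + 1):5) {
    a <- boxes[[i]]; b <- boxes[[j]]
    disjoint <- a[2, 1] <= b[1, 1] || b[2, 1] <= a[1, 1] ||
      a[2, 2] <= b[1, 2] || b[2, 2] <= a[1, 2]
    expect_true(disjoint)
  }
  expect_error(generate_farms(500, c(0, 0.2, 50, 50.2), 1), "too small")
})

test_that("a storm-free wave record is fully accessible below the limit", {
  cfg <- small_scenario(seed = 11,
                        waves = list(mean = 1.0, offshore_amp = 0.3,
                                     storm_freq = 0, storm_amp = 0,
                                     cadence = "3-hourly"))
  b <- generate_scenario(cfg)
  acc <- accessibility(b$waves, 1.5)
  wave_mean <- apply(b$waves$values, c(2, 3), mean)
  calm <- !is.na(wave_mean) & wave_mean < 1.5
  expect_true(all(acc$values[calm] == 100))
})
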