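# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (rle, rowsum, mgcv, geosphere).

# loop-based maximal-run counter: runs of consecutive values strictly above
# `thr` with length >= min_run; NA breaks a run
oracle_count_episodes <- function(x, thr, min_run) {
  count <- 0L
  run <- 0L
  for (v in x) {
    if (!is.na(v) && v > thr) {
      run <- run + 1L
      if (run == min_run) count <- count + 1L
    } else {
      run <- 0L
    }
  }
  count
}

# even-odd ray casting point-in-polygon (horizontal ray to +x)
oracle_point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

# haversine distance in km written from the formula, R = 6371 km
oracle_haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

# loop-based area-weighted block average of a fine matrix onto a coarse
# grid whose cells each contain an integer block of fine cells
oracle_block_mean <- function(values, fine, coarse) {
  k <- round(coarse$resolution / fine$resolution)
  a <- cell_areas(fine)$values
  out <- matrix(NA_real_, coarse$nlat, coarse$nlon)
  for (R in seq_len(coarse$nlat)) {
    for (C in seq_len(coarse$nlon)) {
      rows <- ((R - 1) * k + 1):(R * k)
      cols <- ((C - 1) * k + 1):(C * k)
      v <- values[rows, cols]
      w <- a[rows, cols]
      ok <- !is.na(v)
      if (any(ok)) out[R, C] <- sum(v[ok] * w[ok]) / sum(w[ok])
    }
  }
  out
}

# a small daily SST-like stack for unit tests
make_test_stack <- function(values_fun, nlat = 4, nlon = 4, ndays = 30,
                            variable = "sst", units = "degC",
                            res = 0.5, lat0 = 50) {
  g <- make_grid(c(0, nlon * res, lat0, lat0 + nlat * res), res)
  times <- as.Date("2020-01-01") + 0:(ndays - 1)
  vals <- array(values_fun(ndays * nlat * nlon), c(ndays, nlat, nlon))
  ts_stack(g, times, vals, cadence = "daily", variable = variable,
           units = units)
}

# a fast one-year mini scenario used where the full default is overkill
small_scenario <- function(seed = 1, ...) {
  args <- list(years = 1, n_farms = 4, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scenario_config, args)
}
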