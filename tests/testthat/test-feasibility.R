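daily_stack_from_series <- function(series_list, variable = "sst") {
  # one cell per series, 1 x n grid
  n <- length(series_list)
  nt <- length(series_list[[1]])
  g <- make_grid(c(0, n * 0.5, 50, 50.5), 0.5)
  vals <- array(NA_real_, c(nt, 1, n))
  for (i in seq_len(n)) vals[, 1, i] <- series_list[[i]]
  ts_stack(g, as.Date("2020-01-01") + 0:(nt - 1), vals, "daily",
           variable = variable)
}

test_that("heat-spike episodes are maximal runs strictly above threshold", {
  s1 <- c(26, 26, 26, rep(20, 7))             # one 3-day episode
  s2 <- c(26, 24, 26, 24, 26, rep(20, 5))     # never 3 in a row
  s3 <- c(rep(26, 7), rep(20, 3))             # one long episode, not five
  s4 <- c(25, 25, 25, rep(20, 7))             # exactly 25 is not "above"
  s5 <- c(26, 26, NA, 26, 26, 26, rep(20, 4)) # missing day breaks the run
  st <- daily_stack_from_series(list(s1, s2, s3, s4, s5))
  counts <- count_heat_spike_episodes(st, threshold = 25, min_run = 3)
  expect_equal(as.numeric(counts$values), c(1, 0, 1, 0, 1))
})

test_that("episode counting equals a loop-based run-length oracle", {
  set.seed(41)
  for (i in 1:1000) {
    x <- 24 + stats::rnorm(60, 0, 2)
    x[sample(60, 3)] <- NA
    st <- daily_stack_from_series(list(x))
    got <- as.numeric(count_heat_spike_episodes(st, 25, 3)$values)
    expect_identical(got, as.numeric(oracle_count_episodes(x, 25, 3)))
  }
})

test_that("episode counts ignore leading/trailing sub-threshold padding", {
  set.seed(42)
  x <- 24 + stats::rnorm(60, 0, 2)
  base <- oracle_count_episodes(x, 25, 3)
  padded <- c(rep(20, 5), x, rep(20, 8))
  st <- daily_stack_from_series(list(padded))
  expect_equal(as.numeric(count_heat_spike_episodes(st, 25, 3)$values),
               base)
})

test_that("the heat mask excludes any cell with more episodes than allowed", {
  g <- make_grid(c(0, 1, 50, 51), 0.5)
  counts <- raster_layer(g, matrix(c(0, 1, 2, NA), 2, 2))
  m <- heat_mask(counts, max_allowed = 0)
  expect_identical(as.vector(m$values), c(TRUE, FALSE, FALSE, FALSE))
  m1 <- heat_mask(counts, max_allowed = 1)
  expect_identical(as.vector(m1$values), c(TRUE, TRUE, FALSE, FALSE))
  zeros <- heat_mask(raster_layer(g, matrix(0, 2, 2)))
  expect_true(all(zeros$values))
})

test_that("the depth band is inclusive and respects the sign convention", {
  g <- make_grid(c(0, 2, 50, 50.5), 0.5)
  depth <- raster_layer(g, matrix(c(3, 5, 50, 100), 1, 4), "depth", "m")
  attr(depth, "sign") <- "depth"
  expect_identical(as.vector(depth_mask(depth)$values),
                   c(FALSE, TRUE, TRUE, TRUE))
  elev <- raster_layer(g, matrix(c(-3, -5, -200, NA), 1, 4))
  attr(elev, "sign") <- "elevation"
  expect_identical(as.vector(depth_mask(elev)$values),
                   c(FALSE, TRUE, FALSE, FALSE))
  nosign <- raster_layer(g, matrix(1, 1, 4))
  expect_error(depth_mask(nosign), "sign convention")
})

test_that("the current criterion uses the record max of daily means", {
  calm <- rep(0.5, 30)
  spike <- c(rep(0.3, 15), 1.2, rep(0.3, 14))
  st <- daily_stack_from_series(list(calm, spike), variable = "current")
  m <- current_mask(st, limit = 1)
  expect_identical(as.vector(m$values), c(TRUE, FALSE))
  # the period-mean alternative admits the spiky cell
  m2 <- current_mask(st, limit = 1, rule = "mean")
  expect_identical(as.vector(m2$values), c(TRUE, TRUE))
  set.seed(43)
  for (i in 1:20) {
    x <- abs(stats::rnorm(40, 0.6, 0.3))
    sto <- daily_stack_from_series(list(x), variable = "current")
    expect_identical(as.vector(current_mask(sto, 1)$values), max(x) < 1)
  }
  neg <- daily_stack_from_series(list(c(-0.1, rep(0.2, 29))),
                                 variable = "current")
  expect_error(current_mask(neg), "non-negative")
})

test_that("combined feasibility is the cellwise AND with its area", {
  g <- make_grid(c(0, 1, 50, 51), 0.25)
  set.seed(44)
  mk <- function() raster_layer(g, matrix(stats::runif(16) < 0.6, 4, 4))
  for (i in 1:10) {
    h <- mk(); d <- mk(); cu <- mk()
    res <- combine_feasibility(h, d, cu)
    expect_identical(res$combined$values,
                     h$values & d$values & cu$values)
    expect_equal(res$area_km2, masked_total_area(res$combined))
  }
  allf <- raster_layer(g, matrix(FALSE, 4, 4))
  expect_equal(combine_feasibility(mk(), allf, mk())$area_km2, 0)
  g2 <- make_grid(c(0, 1, 40, 41), 0.25)
  expect_error(combine_feasibility(mk(), mk(),
                                   raster_layer(g2, matrix(TRUE, 4, 4))),
               "grids do not match")
})

test_that("relaxing any threshold never shrinks the feasible set", {
  b <- generate_scenario(small_scenario(seed = 45))
  ep <- count_heat_spike_episodes(b$sst)
  base <- combine_feasibility(heat_mask(ep, 0),
                              depth_mask(b$bathymetry, 5, 100),
                              current_mask(b$current, 1))
  relaxed <- combine_feasibility(heat_mask(ep, 2),
                                 depth_mask(b$bathymetry, 4, 150),
                                 current_mask(b$current, 1.5))
  expect_true(all(relaxed$combined$values | !base$combined$values))
  expect_gte(relaxed$area_km2, base$area_km2)
})

test_that("farms overlapping the mask are counted, even partially", {
  g <- make_grid(c(0, 2, 50, 52), 0.25)
  m <- matrix(FALSE, 8, 8)
  m[, 1:4] <- TRUE # feasible west half (lon < 1)
  mask <- raster_layer(g, m)
  farm <- function(id, x0, x1, y0, y1)
    list(id = id, name = id, type = "polygon",
         geometry = cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)),
         attributes = list())
  farms <- vector_set(list(
    farm("inside", 0.3, 0.6, 50.3, 50.6),
    farm("outside", 1.5, 1.8, 51.5, 51.8),
    farm("straddle", 0.9, 1.2, 51.0, 51.3)))
  res <- count_overlapping_farms(farms, mask)
  expect_equal(res$count, 2L)
  expect_identical(unname(res$overlaps),
                   c(TRUE, FALSE, TRUE))
  expect_equal(count_overlapping_farms(vector_set(list()), mask)$count, 0L)
})
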