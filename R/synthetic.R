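#' Synthetic ocean-scenario configuration
#'
#' Describes a seed-deterministic "mini-Europe" domain with the statistical
#' structure the site-selection analysis assumes: a latitudinal SST gradient
#' with a seasonal cycle and AR(1) noise, optional injectable heat-spike
#' episodes, coastally enriched chlorophyll and suspended sediment, a
#' low-salinity sub-basin (a Baltic-like brackish pocket), a high-current
#' channel, storm-modulated waves, and a shelf-to-deep bathymetry profile
#' with land along the western grid edge.
#'
#' Defaults give a 2 deg x 2 deg domain at 0.05 deg (fine) and 0.25 deg
#' (coarse) resolution and a 5-year record (2019-2023), mirroring the
#' cadences of the source products emulated: daily SST/chlorophyll/current,
#' monthly salinity/sediment, sub-daily waves, decadal-mean SST rasters.
#'
#' @param bounds Outer domain edges `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param fine_res,coarse_res Grid resolutions in degrees.
#' @param years Number of full calendar years, starting at `start_year`.
#' @param start_year First calendar year of the record.
#' @param land_fraction Fraction of the longitude extent that is land along
#'   the western edge (missing cells); the coast is its eastern limit.
#' @param sst List: `south_mean` (deg C at the southern edge), `gradient`
#'   (deg C per degree latitude, poleward decrease), `seasonal_amp` (deg C),
#'   `noise_sd`, `noise_rho` (AR(1) marginal sd and autocorrelation).
#' @param heat_spikes List of injections, each
#'   `list(region = c(lon0, lon1, lat0, lat1), episodes =, duration =,
#'   exceed =)`; `list()` for none.
#' @param chl List: `offshore` baseline (mg m-3), `coastal_amp`,
#'   `decay_km`, `seasonal_amp`, `noise_sd`.
#' @param sss List: `baseline` (marine salinity), `basin` box, `basin_value`,
#'   `noise_sd`.
#' @param spm List: `offshore` (g m-3), `coastal_amp`, `decay_km`,
#'   `hotspots` (list of `list(box =, amp =)`), `noise_sd`.
#' @param current List: `background` (m s-1), `channel` box, `peak`,
#'   `noise_sd`.
#' @param waves List: `mean` (m), `offshore_amp` (m added across the
#'   domain offshore), `storm_freq` (expected storms per 30 days),
#'   `storm_amp` (m), `cadence` (`"3-hourly"` or `"hourly"`).
#' @param bathymetry List: `nearshore_km` (extent of the <5 m fringe),
#'   `shelf_depth` (m), `shelf_km`, `deep_depth` (m), `slope_km`.
#' @param climate List: `warming_south`, `warming_north` (deg C added to
#'   the decadal-mean SST at the southern/northern edge by mid-century).
#' @param n_farms,farm_region,n_ports Wind-farm polygon count and placement
#'   box; number of coastal ports.
#' @param status_probs Probabilities for farm status
#'   (production/accepted/planned).
#' @param seed Integer master seed; fixed seed gives byte-identical bundles.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(bounds = c(0, 2, 50, 52),
                            fine_res = 0.05, coarse_res = 0.25,
                            years = 5, start_year = 2019,
                            land_fraction = 0.1,
                            sst = list(south_mean = 14, gradient = 0.8,
                                       seasonal_amp = 5, noise_sd = 0.4,
                                       noise_rho = 0.8),
                            heat_spikes = list(
                              list(region = c(1.0, 1.5, 50.2, 50.7),
                                   episodes = 2, duration = 4, exceed = 2)),
                            chl = list(offshore = 0.4, coastal_amp = 3,
                                       decay_km = 30, seasonal_amp = 0.3,
                                       noise_sd = 0.1),
                            sss = list(baseline = 35,
                                       basin = c(1.25, 2, 51.5, 52),
                                       basin_value = 4, noise_sd = 0.2),
                            spm = list(offshore = 1, coastal_amp = 40,
                                       decay_km = 20,
                                       hotspots = list(
                                         list(box = c(0.2, 0.5, 50.8, 51.1),
                                              amp = 30)),
                                       noise_sd = 0.5),
                            current = list(background = 0.25,
                                           channel = c(0.5, 0.8, 51.0, 51.6),
                                           peak = 1.3, noise_sd = 0.05),
                            waves = list(mean = 1.0, offshore_amp = 0.3,
                                         storm_freq = 1.5, storm_amp = 3,
                                         cadence = "3-hourly"),
                            bathymetry = list(nearshore_km = 5,
                                              shelf_depth = 60,
                                              shelf_km = 80,
                                              deep_depth = 500,
                                              slope_km = 40),
                            climate = list(warming_south = 0.5,
                                           warming_north = 1.5),
                            n_farms = 6,
                            farm_region = c(0.4, 1.0, 50.3, 50.9),
                            n_ports = 2,
                            status_probs = c(production = 0.5,
                                             accepted = 0.25,
                                             planned = 0.25),
                            seed = 42) {
  cfg <- structure(as.list(environment()), class = "scenario_config")
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  b <- cfg$bounds
  chk_box <- function(box, what) {
    if (box[1] < b[1] || box[2] > b[2] || box[3] < b[3] || box[4] > b[4] ||
        box[1] >= box[2] || box[3] >= box[4])
      stop(sprintf("%s box must lie inside the grid bounds", what),
           call. = FALSE)
  }
  for (hs in cfg$heat_spikes) chk_box(hs$region, "heat-spike region")
  chk_box(cfg$sss$basin, "low-salinity basin")
  chk_box(cfg$current$channel, "current channel")
  for (h in cfg$spm$hotspots) chk_box(h$box, "SPM hotspot")
  chk_box(cfg$farm_region, "farm region")
  if (cfg$years < 1) stop("years must be >= 1", call. = FALSE)
  if (cfg$land_fraction < 0 || cfg$land_fraction >= 1)
    stop("land_fraction must be in [0, 1)", call. = FALSE)
  invisible(cfg)
}

# evaluate expr under a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# AR(1) noise, [ntime x ncell], marginal sd `sd`, lag-1 autocorrelation `rho`
ar1_noise <- function(nt, ncell, sd, rho) {
  if (sd == 0) return(matrix(0, nt, ncell))
  innov_sd <- sd * sqrt(1 - rho^2)
  out <- matrix(0, nt, ncell)
  out[1, ] <- stats::rnorm(ncell, 0, sd)
  if (nt > 1)
    for (t in 2:nt)
      out[t, ] <- rho * out[t - 1, ] + stats::rnorm(ncell, 0, innov_sd)
  out
}

in_box <- function(lon, lat, box)
  lon >= box[1] & lon <= box[2] & lat >= box[3] & lat <= box[4]

# lon/lat matrices of cell centers plus land mask and coastal distance (km)
grid_geometry <- function(grid, coast_lon) {
  lon <- matrix(grid_lons(grid), nrow = grid$nlat, ncol = grid$nlon,
                byrow = TRUE)
  lat <- matrix(grid_lats(grid), nrow = grid$nlat, ncol = grid$nlon)
  land <- lon < coast_lon
  dist <- (lon - coast_lon) * 111.320 * cos(lat * pi / 180)
  dist[land] <- NA
  list(lon = lon, lat = lat, land = land, dist_km = dist)
}

#' Generate a synthetic scenario bundle
#'
#' Produces every input layer the pipeline consumes: daily SST,
#' chlorophyll a and current-speed stacks on the fine grid, monthly
#' salinity (coarse) and suspended sediment (fine), sub-daily significant
#' wave height (coarse), a bathymetry raster, reference and projected
#' decadal-mean SST rasters (coarse), wind-farm polygons and port points.
#' Identical configurations (including the seed) give identical bundles.
#'
#' @param config A [scenario_config()].
#' @return A `scenario_bundle` list with elements `sst`, `chl`, `sss`,
#'   `spm`, `current`, `waves`, `bathymetry`, `sst_decadal_ref`,
#'   `sst_decadal_proj`, `farms`, `ports`, `fine_grid`, `coarse_grid`,
#'   `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  validate_scenario_config(config)
  b <- config$bounds
  fine <- make_grid(b, config$fine_res)
  coarse <- make_grid(b, config$coarse_res)
  coast_lon <- b[1] + config$land_fraction * (b[2] - b[1])
  gf <- grid_geometry(fine, coast_lon)
  gc_ <- grid_geometry(coarse, coast_lon)
  seed <- config$seed

  start <- as.Date(sprintf("%d-01-01", config$start_year))
  end <- as.Date(sprintf("%d-12-31", config$start_year + config$years - 1))
  days <- seq(start, end, by = "day")
  months <- seq(start, end, by = "month")

  sst <- gen_sst(config, fine, gf, days, seed + 1L)
  for (hs in config$heat_spikes)
    sst <- inject_heat_spikes(sst, hs$region, hs$episodes, hs$duration,
                              exceed = hs$exceed)
  chl <- gen_chl(config, fine, gf, days, seed + 2L)
  sss <- gen_sss(config, coarse, gc_, months, seed + 3L)
  spm <- gen_spm(config, fine, gf, months, seed + 4L)
  cur <- gen_current(config, fine, gf, days, seed + 5L)
  wav <- gen_waves(config, coarse, gc_, start, end, seed + 6L)
  bat <- gen_bathymetry(config, fine, gf)
  dec <- gen_decadal_sst(config, coarse, gc_)
  farms <- generate_farms(config$n_farms, config$farm_region, seed + 8L,
                          status_probs = config$status_probs)
  ports <- gen_ports(config$n_ports, coast_lon, b, seed + 9L)

  structure(list(sst = sst, chl = chl, sss = sss, spm = spm, current = cur,
                 waves = wav, bathymetry = bat,
                 sst_decadal_ref = dec$ref, sst_decadal_proj = dec$proj,
                 farms = farms, ports = ports,
                 fine_grid = fine, coarse_grid = coarse, config = config),
            class = "scenario_bundle")
}

seasonal_cycle <- function(times, amp, peak_doy = 210) {
  doy <- as.POSIXlt(times)$yday
  amp * cos(2 * pi * (doy - peak_doy) / 365.25)
}

# base field [nlat x nlon] + time signal [nt] + AR(1) noise, land masked
assemble_stack <- function(grid, geom, times, cadence, base, signal, noise,
                           variable, units, floor = NULL) {
  nt <- length(times)
  arr <- array(rep(as.numeric(base), each = nt), c(nt, grid$nlat, grid$nlon))
  arr <- arr + signal # signal recycles along the time (first) dimension
  arr <- arr + array(noise, c(nt, grid$nlat, grid$nlon))
  if (!is.null(floor)) arr[arr < floor] <- floor
  land3 <- array(rep(geom$land, each = nt), c(nt, grid$nlat, grid$nlon))
  arr[land3] <- NA_real_
  ts_stack(grid, times, arr, cadence = cadence, variable = variable,
           units = units)
}

gen_sst <- function(cfg, grid, geom, days, seed) {
  p <- cfg$sst
  base <- p$south_mean - p$gradient * (geom$lat - cfg$bounds[3])
  sig <- seasonal_cycle(days, p$seasonal_amp)
  noise <- with_seed(seed, ar1_noise(length(days), grid$nlat * grid$nlon,
                                     p$noise_sd, p$noise_rho))
  assemble_stack(grid, geom, days, "daily", base, sig, noise, "sst", "degC")
}

gen_chl <- function(cfg, grid, geom, days, seed) {
  p <- cfg$chl
  base <- p$offshore + p$coastal_amp * exp(-geom$dist_km / p$decay_km)
  base[geom$land] <- 0
  sig <- seasonal_cycle(days, p$seasonal_amp, peak_doy = 120) # spring bloom
  noise <- with_seed(seed, ar1_noise(length(days), grid$nlat * grid$nlon,
                                     p$noise_sd, 0.6))
  assemble_stack(grid, geom, days, "daily", base, sig, noise, "chl",
                 "mg m-3", floor = 0.01)
}

gen_sss <- function(cfg, grid, geom, months, seed) {
  p <- cfg$sss
  base <- matrix(p$baseline, grid$nlat, grid$nlon)
  base[in_box(geom$lon, geom$lat, p$basin)] <- p$basin_value
  noise <- with_seed(seed, matrix(stats::rnorm(length(months) *
                                                 grid$nlat * grid$nlon,
                                               0, p$noise_sd),
                                  nrow = length(months)))
  assemble_stack(grid, geom, months, "monthly", base, 0, noise, "sss", "1",
                 floor = 0)
}

gen_spm <- function(cfg, grid, geom, months, seed) {
  p <- cfg$spm
  base <- p$offshore + p$coastal_amp * exp(-geom$dist_km / p$decay_km)
  base[geom$land] <- 0
  for (h in p$hotspots)
    base <- base + h$amp * in_box(geom$lon, geom$lat, h$box) *
      exp(-geom$dist_km / p$decay_km)
  noise <- with_seed(seed, matrix(stats::rnorm(length(months) *
                                                 grid$nlat * grid$nlon,
                                               0, p$noise_sd),
                                  nrow = length(months)))
  assemble_stack(grid, geom, months, "monthly", base, 0, noise, "spm",
                 "g m-3", floor = 0)
}

gen_current <- function(cfg, grid, geom, days, seed) {
  p <- cfg$current
  base <- matrix(p$background, grid$nlat, grid$nlon)
  base[in_box(geom$lon, geom$lat, p$channel)] <- p$peak
  noise <- with_seed(seed, ar1_noise(length(days), grid$nlat * grid$nlon,
                                     p$noise_sd, 0.5))
  assemble_stack(grid, geom, days, "daily", base, 0, noise, "current_speed",
                 "m s-1", floor = 0)
}

gen_waves <- function(cfg, grid, geom, start, end, seed) {
  p <- cfg$waves
  cadence <- match.arg(p$cadence, c("3-hourly", "hourly"))
  step <- if (cadence == "hourly") 3600 else 3 * 3600
  times <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
               as.POSIXct(paste(end, "21:00:00"), tz = "UTC"), by = step)
  nt <- length(times)
  # waves grow offshore with distance from the coast
  dmax <- max(geom$dist_km, na.rm = TRUE)
  base <- p$mean + p$offshore_amp * geom$dist_km / dmax
  base[geom$land] <- 0
  # domain-wide storm pulses (triangular), deterministic under the seed;
  # storm_amp = 0 switches storms and their noise off entirely
  sig <- rep(0, nt)
  noise <- 0
  if (p$storm_amp > 0) {
    n_storms <- max(0L, round(p$storm_freq * nt * step / (30 * 86400)))
    sig <- with_seed(seed, {
      s <- rep(0, nt)
      if (n_storms > 0) {
        starts <- sort(sample.int(nt, n_storms))
        for (k in seq_len(n_storms)) {
          dur <- sample(8:24, 1) * 3600 * 3 / step # 24-72 h in steps
          inten <- stats::runif(1, 0.5, 1.5)
          idx <- starts[k]:min(nt, starts[k] + dur - 1)
          pulse <- inten * (1 - abs(seq_along(idx) - length(idx) / 2) /
                              (length(idx) / 2))
          s[idx] <- pmax(s[idx], pulse)
        }
      }
      s
    })
    noise <- with_seed(seed + 1000L,
                       matrix(stats::rnorm(nt * grid$nlat * grid$nlon, 0,
                                           0.05 * p$storm_amp), nrow = nt))
  }
  assemble_stack(grid, geom, times, cadence, base, p$storm_amp * sig, noise,
                 "swh", "m", floor = 0)
}

gen_bathymetry <- function(cfg, grid, geom) {
  p <- cfg$bathymetry
  d <- geom$dist_km
  depth <- ifelse(d <= p$nearshore_km,
                  3,
                  pmin(5 + (p$shelf_depth - 5) * (d - p$nearshore_km) /
                         (p$shelf_km - p$nearshore_km),
                       p$shelf_depth))
  beyond <- !is.na(d) & d > p$shelf_km
  depth[beyond] <- pmin(p$shelf_depth +
                          (p$deep_depth - p$shelf_depth) *
                            (d[beyond] - p$shelf_km) / p$slope_km,
                        p$deep_depth)
  depth[geom$land] <- NA
  out <- raster_layer(grid, depth, variable = "depth", units = "m")
  attr(out, "sign") <- "depth" # positive numbers are below sea level
  out
}

gen_decadal_sst <- function(cfg, grid, geom) {
  p <- cfg$sst
  ref_vals <- p$south_mean - p$gradient * (geom$lat - cfg$bounds[3])
  warming <- cfg$climate$warming_south +
    (cfg$climate$warming_north - cfg$climate$warming_south) *
      (geom$lat - cfg$bounds[3]) / (cfg$bounds[4] - cfg$bounds[3])
  ref_vals[geom$land] <- NA
  proj_vals <- ref_vals + warming
  list(ref = raster_layer(grid, ref_vals, "sst_decadal_ref", "degC"),
       proj = raster_layer(grid, proj_vals, "sst_decadal_proj", "degC"))
}

#' Inject heat-spike episodes into a daily SST stack
#'
#' Within a region box, forces exactly `episodes` disjoint maximal runs of
#' `duration` consecutive days with SST above 25 deg C (value
#' `25 + exceed`), evenly spaced through the record and separated by at
#' least two sub-threshold days; all other in-region days are capped just
#' below the threshold so no accidental extra run can appear. Cells outside
#' the region are untouched.
#'
#' @param sst A daily `ts_stack` of SST.
#' @param region Box `c(lon0, lon1, lat0, lat1)`.
#' @param episodes Number of episodes (0 returns the stack unchanged).
#' @param duration Run length in days (>= 1).
#' @param exceed Deg C above the 25 deg C threshold during an episode.
#' @param threshold Heat-spike threshold (deg C).
#' @return The modified `ts_stack`.
#' @export
inject_heat_spikes <- function(sst, region, episodes, duration, exceed = 2,
                               threshold = 25) {
  stopifnot(inherits(sst, "ts_stack"))
  if (sst$cadence != "daily")
    stop("heat-spike injection needs a daily stack", call. = FALSE)
  if (episodes == 0) return(sst)
  if (episodes < 0 || duration < 1)
    stop("episodes and duration must be positive", call. = FALSE)
  g <- sst$grid
  if (region[1] < g$lon_min || region[2] > g$lon_max ||
      region[3] < g$lat_min || region[4] > g$lat_max)
    stop("injection region must lie inside the grid", call. = FALSE)
  nt <- length(sst$times)
  gap <- floor((nt - episodes * duration) / (episodes + 1))
  if (gap < 2)
    stop(sprintf(
      "record of %d days is too short for %d episodes of %d days",
      nt, episodes, duration), call. = FALSE)
  lon <- matrix(grid_lons(g), g$nlat, g$nlon, byrow = TRUE)
  lat <- matrix(grid_lats(g), g$nlat, g$nlon)
  cells <- which(in_box(lon, lat, region))
  if (!length(cells)) return(sst)
  vals <- matrix(sst$values, nrow = nt) # time x cell view
  sub <- vals[, cells, drop = FALSE]
  sub <- pmin(sub, threshold - 0.5)
  for (k in seq_len(episodes)) {
    s <- k * gap + (k - 1) * duration + 1
    sub[s:(s + duration - 1), ] <- threshold + exceed
  }
  vals[, cells] <- sub
  sst$values <- array(vals, dim(sst$values))
  sst
}

#' Generate disjoint rectangular wind-farm polygons
#'
#' Places `n` mutually disjoint axis-aligned rectangles inside a region box
#' by jittering each inside its own slot of a regular layout; statuses are
#' drawn from the configured probabilities. Deterministic under the seed.
#'
#' @param n Number of farms (>= 0).
#' @param region Box `c(lon0, lon1, lat0, lat1)`.
#' @param seed Integer seed.
#' @param status_probs Named probabilities for
#'   production/accepted/planned.
#' @return A `vector_set` of polygons with a `status` attribute.
#' @export
generate_farms <- function(n, region, seed,
                           status_probs = c(production = 0.5,
                                            accepted = 0.25,
                                            planned = 0.25)) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (n == 0) return(vector_set(list()))
  k <- ceiling(sqrt(n))
  w <- (region[2] - region[1]) / k
  h <- (region[4] - region[3]) / k
  if (w < 0.02 || h < 0.02)
    stop("region too small to place that many disjoint farms", call. = FALSE)
  with_seed(seed, {
    feats <- vector("list", n)
    statuses <- sample(names(status_probs), n, replace = TRUE,
                       prob = status_probs)
    for (i in seq_len(n)) {
      row <- (i - 1) %/% k
      col <- (i - 1) %% k
      fw <- stats::runif(1, 0.35, 0.6) * w
      fh <- stats::runif(1, 0.35, 0.6) * h
      x0 <- region[1] + col * w + stats::runif(1, 0.05, 0.95 - fw / w) * w
      y0 <- region[3] + row * h + stats::runif(1, 0.05, 0.95 - fh / h) * h
      ring <- cbind(c(x0, x0 + fw, x0 + fw, x0),
                    c(y0, y0, y0 + fh, y0 + fh))
      feats[[i]] <- list(id = sprintf("farm_%02d", i),
                         name = sprintf("Farm %02d", i),
                         type = "polygon", geometry = ring,
                         attributes = list(status = statuses[i]))
    }
    vector_set(feats)
  })
}

gen_ports <- function(n, coast_lon, bounds, seed) {
  if (n < 1) stop("at least one port is required", call. = FALSE)
  lats <- bounds[3] + (seq_len(n) - 0.5) * (bounds[4] - bounds[3]) / n
  feats <- lapply(seq_len(n), function(i)
    list(id = sprintf("port_%02d", i), name = sprintf("Port %02d", i),
         type = "point",
         geometry = matrix(c(coast_lon + 0.01, lats[i]), ncol = 2),
         attributes = list()))
  vector_set(feats)
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf(
    "scenario_bundle: %d x %d fine / %d x %d coarse grid, %d farms, %d ports\n",
    x$fine_grid$nlat, x$fine_grid$nlon, x$coarse_grid$nlat,
    x$coarse_grid$nlon, length(x$farms), length(x$ports)))
  invisible(x)
}
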