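#' Feasibility criteria for offshore mussel longlines
#'
#' Hard Boolean exclusion thresholds: heat spikes (more episodes than
#' allowed rule a cell out), a bathymetry band workable for longline
#' anchoring, and a daily-average current-speed limit the gear tolerates.
#'
#' @param heat_threshold Heat-spike SST threshold, deg C (strictly above).
#' @param heat_min_run Minimum consecutive days above threshold per episode.
#' @param max_episodes_allowed Maximum episode count still feasible
#'   (default 0: a single episode over the record excludes the cell).
#' @param depth_min,depth_max Workable depth band in m, both inclusive.
#' @param current_limit Daily-average current-speed limit, m s-1.
#' @return A `feasibility_criteria` list.
#' @export
feasibility_criteria <- function(heat_threshold = 25, heat_min_run = 3,
                                 max_episodes_allowed = 0,
                                 depth_min = 5, depth_max = 100,
                                 current_limit = 1) {
  if (depth_min >= depth_max)
    stop("depth_min must be below depth_max", call. = FALSE)
  if (heat_threshold <= 0 || heat_min_run < 1 || current_limit <= 0 ||
      depth_min <= 0)
    stop("all thresholds must be positive", call. = FALSE)
  structure(list(heat_threshold = heat_threshold,
                 heat_min_run = heat_min_run,
                 max_episodes_allowed = max_episodes_allowed,
                 depth_min = depth_min, depth_max = depth_max,
                 current_limit = current_limit),
            class = "feasibility_criteria")
}

# runs of TRUE in x > threshold, NA breaks runs; count maximal runs >= min_run
count_runs_above <- function(x, threshold, min_run) {
  v <- x > threshold
  v[is.na(v)] <- FALSE
  r <- rle(v)
  sum(r$values & r$lengths >= min_run)
}

#' Count heat-spike episodes per cell
#'
#' A heat spike is a maximal run of at least `min_run` consecutive days with
#' SST strictly above `threshold` (default: 3 days above 25 deg C). Missing
#' days break runs. A 7-day run counts as one episode, not several
#' overlapping ones.
#'
#' @param sst A daily `ts_stack` of SST in deg C.
#' @param threshold Deg C, exceedance is strict (`>`).
#' @param min_run Minimum run length in days.
#' @return A `raster_layer` of episode counts (NA where every day is
#'   missing).
#' @export
count_heat_spike_episodes <- function(sst, threshold = 25, min_run = 3) {
  stopifnot(inherits(sst, "ts_stack"))
  if (sst$cadence != "daily")
    stop("heat-spike counting needs a daily stack", call. = FALSE)
  if (min_run < 1) stop("min_run must be >= 1", call. = FALSE)
  nt <- length(sst$times)
  flat <- matrix(sst$values, nrow = nt)
  counts <- vapply(seq_len(ncol(flat)), function(i) {
    x <- flat[, i]
    if (all(is.na(x))) return(NA_real_)
    count_runs_above(x, threshold, min_run)
  }, numeric(1))
  raster_layer(sst$grid, matrix(counts, sst$grid$nlat, sst$grid$nlon),
               variable = "heat_spike_episodes", units = "count")
}

#' Heat-spike feasibility mask
#'
#' @param episode_counts A count `raster_layer` from
#'   [count_heat_spike_episodes()].
#' @param max_allowed Maximum number of episodes still feasible (default 0,
#'   i.e. occurrence < 1).
#' @return Boolean `raster_layer`: `TRUE` where feasible; missing cells are
#'   `FALSE`.
#' @export
heat_mask <- function(episode_counts, max_allowed = 0) {
  stopifnot(inherits(episode_counts, "raster_layer"))
  v <- episode_counts$values
  if (any(v < 0, na.rm = TRUE)) stop("episode counts must be >= 0",
                                     call. = FALSE)
  m <- !is.na(v) & v <= max_allowed
  raster_layer(episode_counts$grid, m, variable = "heat_feasible", units = "")
}

#' Depth-band feasibility mask
#'
#' @param bathymetry A `raster_layer` with a declared sign convention
#'   (`attr(x, "sign")`): `"depth"` (positive below sea level) or
#'   `"elevation"` (negative below sea level).
#' @param depth_min,depth_max Inclusive depth band in m.
#' @return Boolean `raster_layer`; land/missing cells are `FALSE`.
#' @export
depth_mask <- function(bathymetry, depth_min = 5, depth_max = 100) {
  stopifnot(inherits(bathymetry, "raster_layer"))
  sgn <- attr(bathymetry, "sign")
  if (is.null(sgn) || !sgn %in% c("depth", "elevation"))
    stop(paste("bathymetry sign convention undeclared:",
               "set attr(x, 'sign') to 'depth' or 'elevation'"),
         call. = FALSE)
  d <- bathymetry$values
  if (sgn == "elevation") d <- -d
  m <- !is.na(d) & d >= depth_min & d <= depth_max
  raster_layer(bathymetry$grid, m, variable = "depth_feasible", units = "")
}

#' Current-speed feasibility mask
#'
#' Default rule (`"max"`): a cell is feasible only if *no* daily-average
#' speed over the record reaches the limit (a single extreme day endangers
#' longline gear). The alternative `"mean"` rule compares the record mean of
#' daily averages instead.
#'
#' @param current A daily `ts_stack` of daily-average current speed, m s-1.
#' @param limit Limit in m s-1 (strict `<`).
#' @param rule `"max"` (record maximum of daily means, default) or
#'   `"mean"` (record mean).
#' @return Boolean `raster_layer`; all-missing cells are `FALSE`.
#' @export
current_mask <- function(current, limit = 1, rule = c("max", "mean")) {
  stopifnot(inherits(current, "ts_stack"))
  rule <- match.arg(rule)
  if (current$cadence != "daily")
    stop("current feasibility needs daily averages", call. = FALSE)
  if (any(current$values < 0, na.rm = TRUE))
    stop("current speeds must be non-negative", call. = FALSE)
  nt <- length(current$times)
  flat <- matrix(current$values, nrow = nt)
  stat <- if (rule == "max") {
    suppressWarnings(apply(flat, 2, max, na.rm = TRUE))
  } else {
    colMeans(flat, na.rm = TRUE)
  }
  stat[!is.finite(stat)] <- NA
  m <- !is.na(stat) & stat < limit
  raster_layer(current$grid, matrix(m, current$grid$nlat, current$grid$nlon),
               variable = "current_feasible", units = "")
}

#' Combine the three Boolean criteria into the feasibility product
#'
#' @param heat,depth,current Boolean `raster_layer`s on one grid.
#' @return A `feasibility_result`: the per-criterion grids, the combined
#'   AND mask, and the feasible area in km^2.
#' @export
combine_feasibility <- function(heat, depth, current) {
  for (m in list(heat, depth, current)) {
    stopifnot(inherits(m, "raster_layer"))
    if (!is.logical(m$values)) stop("criteria must be Boolean grids",
                                    call. = FALSE)
  }
  if (!same_grid(heat$grid, depth$grid) ||
      !same_grid(heat$grid, current$grid))
    stop("criterion grids do not match", call. = FALSE)
  comb <- raster_layer(heat$grid,
                       heat$values & depth$values & current$values,
                       variable = "feasible", units = "")
  structure(list(heat = heat, depth = depth, current = current,
                 combined = comb, area_km2 = masked_total_area(comb)),
            class = "feasibility_result")
}

#' @export
print.feasibility_result <- function(x, ...) {
  cat(sprintf(
    "feasibility_result: %d of %d cells feasible, %.0f km2\n",
    sum(x$combined$values), length(x$combined$values), x$area_km2))
  invisible(x)
}

#' Count wind farms overlapping the feasible area
#'
#' A farm counts if its polygon overlaps the union of `TRUE` cell boxes
#' completely or partially. The test checks feasible-cell centers inside the
#' polygon and a densified polygon boundary against feasible cell boxes, so
#' partial overlaps at either scale are caught.
#'
#' @param farms A `vector_set` of polygons.
#' @param mask A Boolean `raster_layer`.
#' @return List with `count` and named logical `overlaps` per farm.
#' @export
count_overlapping_farms <- function(farms, mask) {
  stopifnot(inherits(farms, "vector_set"), inherits(mask, "raster_layer"))
  if (!is.logical(mask$values)) stop("mask must be Boolean", call. = FALSE)
  g <- mask$grid
  polys <- Filter(function(f) f$type == "polygon", farms$features)
  if (!length(polys)) return(list(count = 0L, overlaps = logical(0)))
  tru <- which(mask$values, arr.ind = TRUE)
  res <- g$resolution
  lons <- grid_lons(g); lats <- grid_lats(g)
  centers <- cbind(lons[tru[, 2]], lats[tru[, 1]])
  ov <- vapply(polys, function(f) {
    if (!nrow(tru)) return(FALSE)
    # feasible-cell centers inside the polygon
    bb <- apply(unique_ring(f$geometry), 2, range)
    near <- centers[, 1] >= bb[1, 1] - res & centers[, 1] <= bb[2, 1] + res &
            centers[, 2] >= bb[1, 2] - res & centers[, 2] <= bb[2, 2] + res
    if (any(near) &&
        any(points_in_polygon(centers[near, , drop = FALSE], f)))
      return(TRUE)
    # densified polygon boundary falling inside a feasible cell box
    pts <- densify_ring(unique_ring(f$geometry), res / 4)
    ci <- findInterval(pts[, 1], g$lon_min + (0:g$nlon) * res,
                       rightmost.closed = TRUE)
    ri <- findInterval(pts[, 2], g$lat_min + (0:g$nlat) * res,
                       rightmost.closed = TRUE)
    ok <- ci >= 1 & ci <= g$nlon & ri >= 1 & ri <= g$nlat
    any(mask$values[cbind(ri[ok], ci[ok])])
  }, logical(1))
  names(ov) <- vapply(polys, function(f) as.character(f$id), character(1))
  list(count = sum(ov), overlaps = ov)
}

densify_ring <- function(ring, step) {
  n <- nrow(ring)
  out <- list()
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[if (i == n) 1 else i + 1, ]
    len <- max(abs(b - a))
    k <- max(2L, ceiling(len / step) + 1L)
    out[[i]] <- cbind(seq(a[1], b[1], length.out = k),
                      seq(a[2], b[2], length.out = k))
  }
  do.call(rbind, out)
}
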