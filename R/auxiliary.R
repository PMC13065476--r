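#' Auxiliary decision-support parameters
#'
#' Non-masking criteria kept alongside the feasibility product: operational
#' wave limit for site access, a structural maximum-wave limit for the
#' longlines, and distance-to-port screening thresholds.
#'
#' @param wave_limit Significant wave height under which a site is workable
#'   by service vessels, m (strict `<`).
#' @param max_wave_limit Structural maximum wave height, m.
#' @param port_distances_nm Screening distances to the nearest port,
#'   nautical miles.
#' @return An `accessibility_params` list.
#' @export
accessibility_params <- function(wave_limit = 1.5, max_wave_limit = 6,
                                 port_distances_nm = c(25, 55)) {
  if (wave_limit <= 0 || max_wave_limit <= 0 || any(port_distances_nm <= 0))
    stop("limits must be positive", call. = FALSE)
  structure(list(wave_limit = wave_limit, max_wave_limit = max_wave_limit,
                 port_distances_nm = port_distances_nm),
            class = "accessibility_params")
}

#' Site accessibility from the wave record
#'
#' Percentage of time steps with significant wave height strictly under the
#' working limit, per cell: 100 means the site is workable all the time.
#' Ties at exactly the limit count as inaccessible ("under" is strict).
#'
#' @param waves A `ts_stack` of significant wave height, m (>= 0).
#' @param limit Working wave limit, m.
#' @return A `raster_layer` of percentages in \[0, 100\] (missing where the
#'   whole record is missing).
#' @export
accessibility <- function(waves, limit = 1.5) {
  stopifnot(inherits(waves, "ts_stack"))
  if (any(waves$values < 0, na.rm = TRUE))
    stop("wave heights must be non-negative", call. = FALSE)
  nt <- length(waves$times)
  flat <- matrix(waves$values, nrow = nt)
  nvalid <- colSums(!is.na(flat))
  nok <- colSums(flat < limit, na.rm = TRUE)
  pct <- 100 * nok / nvalid
  pct[nvalid == 0] <- NA_real_
  raster_layer(waves$grid, matrix(pct, waves$grid$nlat, waves$grid$nlon),
               variable = "accessibility", units = "%")
}

#' Record-maximum wave height and structural flag
#'
#' @param waves A `ts_stack` of significant wave height, m.
#' @param limit Structural maximum-wave limit, m.
#' @return List with `max` (m `raster_layer`) and `ok` (Boolean
#'   `raster_layer`, `TRUE` where the record maximum stays under the
#'   limit).
#' @export
max_wave <- function(waves, limit = 6) {
  stopifnot(inherits(waves, "ts_stack"))
  nt <- length(waves$times)
  flat <- matrix(waves$values, nrow = nt)
  mx <- suppressWarnings(apply(flat, 2, max, na.rm = TRUE))
  mx[!is.finite(mx)] <- NA
  mx_m <- matrix(mx, waves$grid$nlat, waves$grid$nlon)
  list(max = raster_layer(waves$grid, mx_m, "max_wave", "m"),
       ok = raster_layer(waves$grid, !is.na(mx_m) & mx_m < limit,
                         "max_wave_ok", ""))
}

#' Great-circle distance to the nearest port
#'
#' Haversine distance from each cell center to the nearest port point
#' (R = 6371 km), in nautical miles (1 nm = 1.852 km), with a companion
#' Boolean layer per screening threshold (within-distance = `TRUE`).
#' No land-avoiding routing is attempted.
#'
#' @param grid A `grid_spec`.
#' @param ports A `vector_set` containing at least one point feature.
#' @param thresholds_nm Screening distances in nautical miles.
#' @return List with `distance_nm` (`raster_layer`) and `within` (named
#'   list of Boolean `raster_layer`s, one per threshold).
#' @export
distance_to_port <- function(grid, ports, thresholds_nm = c(25, 55)) {
  stopifnot(inherits(grid, "grid_spec"), inherits(ports, "vector_set"))
  pts <- Filter(function(f) f$type == "point", ports$features)
  if (!length(pts)) stop("at least one port point is required",
                         call. = FALSE)
  port_xy <- do.call(rbind, lapply(pts, function(f) f$geometry[1, ]))
  centers <- cbind(rep(grid_lons(grid), each = grid$nlat),
                   rep(grid_lats(grid), grid$nlon))
  dm <- geosphere::distm(centers, port_xy,
                         fun = function(p1, p2)
                           geosphere::distHaversine(p1, p2, r = 6371000))
  d_nm <- apply(dm, 1, min) / 1000 / 1.852
  d_m <- matrix(d_nm, grid$nlat, grid$nlon)
  within <- lapply(thresholds_nm, function(thr)
    raster_layer(grid, d_m <= thr,
                 variable = sprintf("within_%g_nm", thr), units = ""))
  names(within) <- sprintf("%g_nm", thresholds_nm)
  list(distance_nm = raster_layer(grid, d_m, "distance_to_port", "nm"),
       within = within)
}
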