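#' Georeferenced regular grid
#'
#' A `grid_spec` describes a regular geographic grid with square cells,
#' cell-center registration, latitude rows ascending south to north and
#' longitudes in \[-180, 180). `lon_min`/`lat_min` etc. are the *outer edges*
#' of the grid; cell centers sit half a cell inside.
#'
#' @param lon_min,lon_max,lat_min,lat_max Outer grid edges in decimal degrees.
#' @param resolution Cell size in degrees (one scalar; cells are square).
#' @return A `grid_spec` object.
#' @examples
#' g <- make_grid(c(0, 1, 0, 1), 0.05)
#' grid_dims(g)
#' @export
make_grid <- function(bounds, resolution) {
  stopifnot(is.numeric(bounds), length(bounds) == 4L,
            is.numeric(resolution), length(resolution) == 1L)
  lon_min <- bounds[1]; lon_max <- bounds[2]
  lat_min <- bounds[3]; lat_max <- bounds[4]
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  if (lon_max <= lon_min || lat_max <= lat_min)
    stop("bounds must span positive extents", call. = FALSE)
  if (lat_min < -90 || lat_max > 90)
    stop("latitude bounds must lie within [-90, 90]", call. = FALSE)
  if (lon_min < -180 || lon_max > 180)
    stop("longitude bounds must lie within [-180, 180]", call. = FALSE)
  nx <- (lon_max - lon_min) / resolution
  ny <- (lat_max - lat_min) / resolution
  if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8)
    stop("grid extents are not integer multiples of the resolution",
         call. = FALSE)
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max,
                 resolution = resolution,
                 nlon = as.integer(round(nx)), nlat = as.integer(round(ny)),
                 registration = "cell-center"),
            class = "grid_spec")
}

#' @rdname make_grid
#' @param grid A `grid_spec`.
#' @export
grid_dims <- function(grid) c(nlat = grid$nlat, nlon = grid$nlon)

#' Cell-center coordinates
#'
#' @param grid A `grid_spec`.
#' @return Numeric vector of cell-center latitudes (ascending) or longitudes.
#' @export
grid_lats <- function(grid)
  grid$lat_min + (seq_len(grid$nlat) - 0.5) * grid$resolution

#' @rdname grid_lats
#' @export
grid_lons <- function(grid)
  grid$lon_min + (seq_len(grid$nlon) - 0.5) * grid$resolution

same_grid <- function(a, b, tol = 1e-9) {
  all(abs(c(a$lon_min - b$lon_min, a$lon_max - b$lon_max,
            a$lat_min - b$lat_min, a$lat_max - b$lat_max,
            a$resolution - b$resolution)) < tol)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells @ %g deg, lon [%g, %g], lat [%g, %g]\n",
              x$nlat, x$nlon, x$resolution, x$lon_min, x$lon_max,
              x$lat_min, x$lat_max))
  invisible(x)
}

#' Gridded 2-D field
#'
#' A `raster_layer` binds a `grid_spec` to a numeric matrix of dimension
#' nlat x nlon (row 1 = southernmost row). `NA` marks missing cells (land,
#' no data).
#'
#' @param grid A `grid_spec`.
#' @param values Numeric or logical matrix, nlat x nlon.
#' @param variable Variable name (e.g. `"sst"`).
#' @param units Unit string (e.g. `"degC"`).
#' @return A `raster_layer`.
#' @export
raster_layer <- function(grid, values, variable = "value", units = "") {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(values))
    values <- matrix(values, nrow = grid$nlat, ncol = grid$nlon)
  if (nrow(values) != grid$nlat || ncol(values) != grid$nlon)
    stop(sprintf("values are %d x %d but the grid is %d x %d",
                 nrow(values), ncol(values), grid$nlat, grid$nlon),
         call. = FALSE)
  structure(list(grid = grid, values = values,
                 variable = variable, units = units),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  cat(sprintf("raster_layer '%s' [%s]: %d x %d, range [%g, %g], %d missing\n",
              x$variable, x$units, nrow(x$values), ncol(x$values),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(is.na(x$values))))
  invisible(x)
}

#' Gridded time series stack
#'
#' A `ts_stack` is a (time x lat x lon) array on a `grid_spec` with an
#' explicit cadence. Daily and monthly stacks carry `Date` times; sub-daily
#' stacks carry POSIXct (UTC).
#'
#' @param grid A `grid_spec`.
#' @param times Strictly increasing `Date` or `POSIXct` vector.
#' @param values Numeric array, time x nlat x nlon.
#' @param cadence One of `"hourly"`, `"3-hourly"`, `"daily"`, `"monthly"`,
#'   `"decadal"`.
#' @param variable,units Variable name and units.
#' @return A `ts_stack`.
#' @export
ts_stack <- function(grid, times, values, cadence, variable = "value",
                     units = "") {
  stopifnot(inherits(grid, "grid_spec"))
  cadence <- match.arg(cadence,
                       c("hourly", "3-hourly", "daily", "monthly", "decadal"))
  if (length(dim(values)) != 3L)
    stop("values must be a 3-D array (time x lat x lon)", call. = FALSE)
  d <- dim(values)
  if (d[1] != length(times) || d[2] != grid$nlat || d[3] != grid$nlon)
    stop(sprintf(
      "values are %d x %d x %d but expected %d x %d x %d (time x lat x lon)",
      d[1], d[2], d[3], length(times), grid$nlat, grid$nlon), call. = FALSE)
  tn <- as.numeric(times)
  if (length(tn) > 1 && any(diff(tn) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  check_cadence(times, cadence)
  structure(list(grid = grid, times = times, cadence = cadence,
                 values = values, variable = variable, units = units),
            class = "ts_stack")
}

check_cadence <- function(times, cadence) {
  if (length(times) < 2) return(invisible(TRUE))
  step <- diff(as.numeric(times))
  ok <- switch(cadence,
    hourly    = all(abs(step - 3600) < 1e-6),
    "3-hourly" = all(abs(step - 3 * 3600) < 1e-6),
    daily     = all(abs(step - day_step(times)) < 1e-6),
    monthly   = all(step >= 28 * day_step(times) &
                    step <= 31 * day_step(times)),
    decadal   = TRUE)
  if (!ok)
    stop(sprintf("timestamps are not consistent with the '%s' cadence",
                 cadence), call. = FALSE)
  invisible(TRUE)
}

# Dates count in days, POSIXct in seconds
day_step <- function(times) if (inherits(times, "Date")) 1 else 86400

#' @export
print.ts_stack <- function(x, ...) {
  cat(sprintf("ts_stack '%s' [%s]: %d %s steps on %d x %d grid\n",
              x$variable, x$units, length(x$times), x$cadence,
              x$grid$nlat, x$grid$nlon))
  invisible(x)
}

#' Spherical cell areas
#'
#' Per-cell area on the sphere,
#' \deqn{A = R^2 \, \Delta\lambda \, (\sin\phi_{top} - \sin\phi_{bottom})}
#' with \eqn{R = 6371} km and \eqn{\Delta\lambda} the cell width in radians.
#' Area decreases with |latitude|.
#'
#' @param grid A `grid_spec`.
#' @return A `raster_layer` of areas in km^2.
#' @export
cell_areas <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  R <- 6371 # km
  res <- grid$resolution
  dlon <- res * pi / 180
  lat_bot <- (grid$lat_min + (seq_len(grid$nlat) - 1) * res) * pi / 180
  lat_top <- lat_bot + res * pi / 180
  band <- R^2 * dlon * (sin(lat_top) - sin(lat_bot)) # one value per lat row
  raster_layer(grid, matrix(band, nrow = grid$nlat, ncol = grid$nlon),
               variable = "cell_area", units = "km2")
}

#' Total area of a Boolean mask
#'
#' Sum of spherical cell areas over the `TRUE` cells of a mask. `NA` cells
#' count as `FALSE`.
#'
#' @param mask A logical `raster_layer`.
#' @return Area in km^2 (0 for an all-false mask).
#' @export
masked_total_area <- function(mask) {
  stopifnot(inherits(mask, "raster_layer"))
  m <- mask$values
  if (!is.logical(m)) stop("mask must hold logical values", call. = FALSE)
  a <- cell_areas(mask$grid)$values
  sum(a[which(m)])
}
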