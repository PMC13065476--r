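#' Read and write rasters as ESRI ASCII grids
#'
#' Static rasters are exchanged as ESRI ASCII grid (`.asc`) files — the
#' plain-text raster interchange format — in geographic coordinates
#' (EPSG:4326). Values are written with 17 significant digits so a
#' write-then-read round trip reproduces doubles exactly.
#'
#' @param layer A `raster_layer`.
#' @param path Output file path.
#' @param variable,units Metadata to attach on read (the `.asc` format does
#'   not carry them).
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a `raster_layer`.
#' @export
write_ascii_grid <- function(layer, path) {
  stopifnot(inherits(layer, "raster_layer"))
  g <- layer$grid
  v <- layer$values
  if (is.logical(v)) v <- v * 1
  v[is.na(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$nlon),
               sprintf("nrows %d", g$nlat),
               sprintf("xllcorner %.17g", g$lon_min),
               sprintf("yllcorner %.17g", g$lat_min),
               sprintf("cellsize %.17g", g$resolution),
               "NODATA_value -9999"), con)
  # .asc rows run north to south
  for (r in rev(seq_len(g$nlat)))
    writeLines(paste(formatC(v[r, ], format = "g", digits = 17),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, variable = "value", units = "") {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2)
      stop(sprintf("malformed ASCII grid header line %d: '%s'", i, lines[i]),
           call. = FALSE)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop(sprintf("ASCII grid header is missing field '%s'", miss[1]),
         call. = FALSE)
  nr <- hdr$nrows; nc <- hdr$ncols
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop(sprintf("ASCII grid body has %d rows but header field nrows says %d",
                 length(body), nr), call. = FALSE)
  rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(vapply(rows, length, integer(1)) != nc))
    stop("ASCII grid row length does not match header field ncols",
         call. = FALSE)
  v <- do.call(rbind, rows)
  v <- v[rev(seq_len(nr)), , drop = FALSE] # back to south-first rows
  v[v == hdr$nodata_value] <- NA
  g <- make_grid(c(hdr$xllcorner, hdr$xllcorner + nc * hdr$cellsize,
                   hdr$yllcorner, hdr$yllcorner + nr * hdr$cellsize),
                 hdr$cellsize)
  raster_layer(g, v, variable = variable, units = units)
}

#' Read and write gridded time-series stacks
#'
#' A stack is stored as a plain-text pair: `<prefix>.json` holds the grid,
#' cadence, timestamps, variable and units; `<prefix>.csv` holds the data as
#' an ntime x ncell matrix (cells in column-major lat-major order). The
#' layout mirrors a CF-style NetCDF variable (dimensions time/lat/lon with
#' units attributes) in text form.
#'
#' @param stack A `ts_stack`.
#' @param prefix Path prefix (without extension).
#' @return `write_stack` returns `prefix` invisibly; `read_stack` a
#'   `ts_stack`.
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "ts_stack"))
  g <- stack$grid
  hdr <- list(
    variable = stack$variable, units = stack$units, cadence = stack$cadence,
    time_class = if (inherits(stack$times, "Date")) "Date" else "POSIXct",
    times = if (inherits(stack$times, "Date")) format(stack$times, "%Y-%m-%d")
            else format(stack$times, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    grid = list(lon_min = g$lon_min, lon_max = g$lon_max,
                lat_min = g$lat_min, lat_max = g$lat_max,
                resolution = g$resolution))
  jsonlite::write_json(hdr, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  nt <- length(stack$times)
  flat <- matrix(stack$values, nrow = nt) # time x cell
  data.table::fwrite(data.table::as.data.table(flat),
                     paste0(prefix, ".csv"), col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_stack
#' @export
read_stack <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  for (f in c("variable", "units", "cadence", "time_class", "times", "grid"))
    if (is.null(hdr[[f]]))
      stop(sprintf("stack header is missing field '%s'", f), call. = FALSE)
  g <- make_grid(c(hdr$grid$lon_min, hdr$grid$lon_max,
                   hdr$grid$lat_min, hdr$grid$lat_max), hdr$grid$resolution)
  times <- if (hdr$time_class == "Date") as.Date(hdr$times)
           else as.POSIXct(hdr$times, format = "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC")
  dt <- data.table::fread(paste0(prefix, ".csv"), header = FALSE)
  m <- as.matrix(dt)
  dimnames(m) <- NULL
  if (nrow(m) != length(times))
    stop(sprintf("stack data has %d rows but header field times lists %d",
                 nrow(m), length(times)), call. = FALSE)
  if (ncol(m) != g$nlat * g$nlon)
    stop(sprintf("stack data has %d cells but header field grid implies %d",
                 ncol(m), g$nlat * g$nlon), call. = FALSE)
  ts_stack(g, times, array(m, c(length(times), g$nlat, g$nlon)),
           cadence = hdr$cadence, variable = hdr$variable, units = hdr$units)
}

#' Read and write vector features as GeoJSON
#'
#' Wind-farm polygons and port points are exchanged as GeoJSON
#' FeatureCollections (RFC 7946, lon/lat order). Feature `id` and `name` and
#' any extra attributes live in `properties`.
#'
#' @param vs A `vector_set`.
#' @param path File path.
#' @return `write_geojson` returns `path` invisibly; `read_geojson` a
#'   `vector_set`.
#' @export
write_geojson <- function(vs, path) {
  stopifnot(inherits(vs, "vector_set"))
  feats <- lapply(vs$features, function(f) {
    geom <- if (f$type == "polygon") {
      ring <- unique_ring(f$geometry)
      ring <- rbind(ring, ring[1, ])
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(i) as.numeric(ring[i, ]))))
    } else {
      list(type = "Point", coordinates = as.numeric(f$geometry[1, ]))
    }
    props <- c(list(id = f$id, name = f$name), f$attributes)
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_geojson
#' @export
read_geojson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$type) || j$type != "FeatureCollection")
    stop("GeoJSON field 'type' is not 'FeatureCollection'", call. = FALSE)
  feats <- lapply(j$features, function(f) {
    if (is.null(f$geometry) || is.null(f$geometry$type))
      stop("GeoJSON feature is missing field 'geometry.type'", call. = FALSE)
    if (is.null(f$properties$id))
      stop("GeoJSON feature is missing field 'properties.id'", call. = FALSE)
    gt <- f$geometry$type
    if (gt == "Polygon") {
      ring <- f$geometry$coordinates[[1]]
      coords <- do.call(rbind, lapply(ring, function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
      coords <- unique_ring(coords)
      type <- "polygon"
    } else if (gt == "Point") {
      coords <- matrix(c(as.numeric(f$geometry$coordinates[[1]]),
                         as.numeric(f$geometry$coordinates[[2]])), ncol = 2)
      type <- "point"
    } else {
      stop(sprintf("unsupported GeoJSON geometry type '%s'", gt),
           call. = FALSE)
    }
    attrs <- f$properties
    attrs$id <- NULL; attrs$name <- NULL
    list(id = f$properties$id,
         name = if (is.null(f$properties$name)) f$properties$id
                else f$properties$name,
         type = type, geometry = coords, attributes = attrs)
  })
  ids <- vapply(feats, function(f) as.character(f$id), character(1))
  if (anyDuplicated(ids))
    stop(sprintf("GeoJSON field 'properties.id' duplicated: '%s'",
                 ids[duplicated(ids)][1]), call. = FALSE)
  vector_set(feats)
}

#' Read and write farm-ranking tables as CSV
#'
#' UTF-8 CSV with a header row; re-reading reproduces the table.
#'
#' @param ranking A data frame (one row per farm).
#' @param path File path.
#' @return `write_ranking_csv` returns `path` invisibly; `read_ranking_csv`
#'   a data frame.
#' @export
write_ranking_csv <- function(ranking, path) {
  utils::write.csv(ranking, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ranking_csv
#' @export
read_ranking_csv <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
}

#' Write or read a whole scenario bundle
#'
#' Serializes every layer of a `scenario_bundle` into a directory: stacks as
#' JSON+CSV pairs, rasters as ASCII grids, farms/ports as GeoJSON. The
#' bathymetry sign convention travels in its own JSON sidecar.
#'
#' @param bundle A `scenario_bundle`.
#' @param dir Directory (created if needed).
#' @return `write_bundle` returns `dir` invisibly; `read_bundle` a
#'   `scenario_bundle` (without the generating config).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("sst", "chl", "sss", "spm", "current", "waves"))
    write_stack(bundle[[nm]], file.path(dir, nm))
  write_ascii_grid(bundle$bathymetry, file.path(dir, "bathymetry.asc"))
  jsonlite::write_json(list(sign = attr(bundle$bathymetry, "sign")),
                       file.path(dir, "bathymetry.json"),
                       auto_unbox = TRUE)
  write_ascii_grid(bundle$sst_decadal_ref,
                   file.path(dir, "sst_decadal_ref.asc"))
  write_ascii_grid(bundle$sst_decadal_proj,
                   file.path(dir, "sst_decadal_proj.asc"))
  write_geojson(bundle$farms, file.path(dir, "farms.geojson"))
  write_geojson(bundle$ports, file.path(dir, "ports.geojson"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  stacks <- lapply(c(sst = "sst", chl = "chl", sss = "sss", spm = "spm",
                     current = "current", waves = "waves"),
                   function(nm) read_stack(file.path(dir, nm)))
  bat <- read_ascii_grid(file.path(dir, "bathymetry.asc"),
                         variable = "depth", units = "m")
  meta <- jsonlite::read_json(file.path(dir, "bathymetry.json"),
                              simplifyVector = TRUE)
  attr(bat, "sign") <- meta$sign
  structure(c(stacks, list(
    bathymetry = bat,
    sst_decadal_ref = read_ascii_grid(file.path(dir, "sst_decadal_ref.asc"),
                                      "sst_decadal_ref", "degC"),
    sst_decadal_proj = read_ascii_grid(
      file.path(dir, "sst_decadal_proj.asc"), "sst_decadal_proj", "degC"),
    farms = read_geojson(file.path(dir, "farms.geojson")),
    ports = read_geojson(file.path(dir, "ports.geojson")),
    fine_grid = stacks$sst$grid, coarse_grid = stacks$sss$grid,
    config = NULL)), class = "scenario_bundle")
}
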