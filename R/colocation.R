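#' Zonal mean of a raster over farm polygons
#'
#' Mean of the raster values at cells whose centers fall inside each
#' polygon (cell-center rasterization; missing cells excluded). If no cell
#' center falls inside a polygon, the value at the cell center nearest the
#' polygon centroid is used instead.
#'
#' @param raster A `raster_layer`.
#' @param farms A `vector_set` of polygons.
#' @return Data frame with columns `id` and `value` (NA where every covered
#'   cell is missing).
#' @export
zonal_mean <- function(raster, farms) {
  stopifnot(inherits(raster, "raster_layer"), inherits(farms, "vector_set"))
  if (is.null(raster$values) || length(raster$values) == 0)
    stop("raster is empty", call. = FALSE)
  g <- raster$grid
  centers <- cbind(rep(grid_lons(g), each = g$nlat),
                   rep(grid_lats(g), g$nlon))
  polys <- Filter(function(f) f$type == "polygon", farms$features)
  vals <- vapply(polys, function(f) {
    inside <- points_in_polygon(centers, f)
    if (any(inside)) {
      v <- raster$values[inside]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    } else {
      ctr <- polygon_centroid(f)
      i <- which.min((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2)
      raster$values[i]
    }
  }, numeric(1))
  data.frame(id = vapply(polys, function(f) as.character(f$id),
                         character(1)),
             value = vals, stringsAsFactors = FALSE)
}

#' Rank wind farms for co-location
#'
#' Orders farm records by descending mean suitability index, ties broken by
#' descending accessibility, remaining ties by id — a deterministic total
#' order. Records with a missing SI sort last and are flagged.
#'
#' @param records Data frame with at least `id`, `si` and `accessibility`
#'   columns.
#' @return The data frame reordered, with `rank` and `si_missing` columns
#'   added.
#' @export
rank_farms <- function(records) {
  stopifnot(all(c("id", "si", "accessibility") %in% names(records)))
  miss <- is.na(records$si)
  ord <- order(miss, -ifelse(miss, 0, records$si),
               -records$accessibility, as.character(records$id))
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$si_missing <- miss[ord]
  rownames(out) <- NULL
  out
}

#' Per-farm co-location report
#'
#' Assembles the ranking table: per farm the status, spherical polygon area
#' (km^2), mean SI, projected mid-century SI change (%), distance from the
#' farm centroid to the nearest port (nm) and accessibility (%), ranked by
#' SI then accessibility.
#'
#' @param farms A `vector_set` of polygons with a `status` attribute.
#' @param si SI `raster_layer`.
#' @param dsi Percent-change `raster_layer` (may be `NULL`).
#' @param accessibility Accessibility `raster_layer`.
#' @param distance_nm Distance-to-port `raster_layer` in nm.
#' @return Ranked data frame (one row per farm).
#' @export
farm_report <- function(farms, si, dsi, accessibility, distance_nm) {
  polys <- Filter(function(f) f$type == "polygon", farms$features)
  if (!length(polys))
    return(data.frame(id = character(0), name = character(0),
                      status = character(0), area_km2 = numeric(0),
                      si = numeric(0), dsi_2050_pct = numeric(0),
                      distance_to_port_nm = numeric(0),
                      accessibility_pct = numeric(0),
                      rank = integer(0), si_missing = logical(0)))
  tab <- data.frame(
    id = vapply(polys, function(f) as.character(f$id), character(1)),
    name = vapply(polys, function(f) as.character(f$name), character(1)),
    status = vapply(polys, function(f) {
      s <- f$attributes$status
      if (is.null(s)) NA_character_ else as.character(s)
    }, character(1)),
    area_km2 = vapply(polys, polygon_area_km2, numeric(1)),
    stringsAsFactors = FALSE)
  tab$si <- zonal_mean(si, farms)$value
  tab$dsi_2050_pct <- if (is.null(dsi)) NA_real_ else zonal_mean(dsi, farms)$value
  tab$distance_to_port_nm <- zonal_mean(distance_nm, farms)$value
  tab$accessibility <- zonal_mean(accessibility, farms)$value
  ranked <- rank_farms(tab)
  names(ranked)[names(ranked) == "accessibility"] <- "accessibility_pct"
  ranked
}
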