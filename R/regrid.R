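#' Regrid a raster layer or time-series stack
#'
#' Moves a field onto a target grid. `bilinear` (via [pracma::interp2()])
#' refines continuous fields; `block_mean` coarsens them by averaging all
#' source cells whose centers fall in each target cell (a coarse cell is
#' missing only if *all* contributing cells are missing); `nearest` picks the
#' closest source cell center; `majority` coarsens Boolean fields
#' (strict majority of valid contributing cells, >50% true).
#'
#' @param x A `raster_layer` or `ts_stack`.
#' @param target Target `grid_spec`; must overlap the source domain.
#' @param method One of `"bilinear"`, `"block_mean"`, `"nearest"`,
#'   `"majority"`.
#' @return Object of the same class as `x`, on `target`.
#' @export
regrid <- function(x, target, method = c("bilinear", "block_mean", "nearest",
                                         "majority")) {
  method <- match.arg(method)
  stopifnot(inherits(target, "grid_spec"))
  UseMethod("regrid")
}

#' @export
regrid.raster_layer <- function(x, target, method = c("bilinear", "block_mean",
                                                      "nearest", "majority")) {
  method <- match.arg(method)
  check_overlap(x$grid, target)
  vals <- regrid_matrix(x$values, x$grid, target, method)
  raster_layer(target, vals, variable = x$variable, units = x$units)
}

#' @export
regrid.ts_stack <- function(x, target, method = c("bilinear", "block_mean",
                                                  "nearest", "majority")) {
  method <- match.arg(method)
  check_overlap(x$grid, target)
  nt <- length(x$times)
  out <- array(NA_real_, c(nt, target$nlat, target$nlon))
  if (method == "block_mean") {
    # one grouped area-weighted mean over all time steps at once
    idx <- block_index(x$grid, target)
    w <- as.numeric(cell_areas(x$grid)$values)
    flat <- matrix(aperm(x$values, c(2, 3, 1)),
                   nrow = x$grid$nlat * x$grid$nlon) # cell x time
    keep <- !is.na(idx)
    fk <- flat[keep, , drop = FALSE]
    valid <- !is.na(fk)
    sums <- rowsum(ifelse(valid, fk * w[keep], 0), idx[keep])
    wsum <- rowsum(valid * w[keep], idx[keep])
    means <- sums / wsum
    means[wsum == 0] <- NA_real_
    full <- matrix(NA_real_, target$nlat * target$nlon, nt)
    full[as.integer(rownames(means)), ] <- means
    out <- aperm(array(full, c(target$nlat, target$nlon, nt)), c(3, 1, 2))
  } else {
    for (t in seq_len(nt))
      out[t, , ] <- regrid_matrix(x$values[t, , ], x$grid, target, method)
  }
  ts_stack(target, x$times, out, cadence = x$cadence,
           variable = x$variable, units = x$units)
}

check_overlap <- function(src, dst) {
  if (dst$lon_min >= src$lon_max || dst$lon_max <= src$lon_min ||
      dst$lat_min >= src$lat_max || dst$lat_max <= src$lat_min)
    stop("source and target grids do not overlap", call. = FALSE)
  invisible(TRUE)
}

# index of the target cell each source cell center falls into (NA if outside)
block_index <- function(src, dst) {
  lons <- grid_lons(src); lats <- grid_lats(src)
  ci <- findInterval(lons, dst$lon_min + (0:dst$nlon) * dst$resolution,
                     rightmost.closed = TRUE)
  ri <- findInterval(lats, dst$lat_min + (0:dst$nlat) * dst$resolution,
                     rightmost.closed = TRUE)
  ci[ci < 1 | ci > dst$nlon] <- NA
  ri[ri < 1 | ri > dst$nlat] <- NA
  # values matrices are lat-major (row = lat), flattened column-wise
  outer(ri, ci, function(r, c) (c - 1L) * dst$nlat + r)
}

regrid_matrix <- function(values, src, dst, method) {
  was_logical <- is.logical(values)
  switch(method,
    bilinear = {
      if (was_logical)
        stop("bilinear regridding needs a continuous field", call. = FALSE)
      xs <- grid_lons(src); ys <- grid_lats(src)
      # clamp target centers onto the source center range (edge extension)
      xq <- pmin(pmax(grid_lons(dst), xs[1]), xs[length(xs)])
      yq <- pmin(pmax(grid_lats(dst), ys[1]), ys[length(ys)])
      pts <- expand.grid(y = yq, x = xq) # column-wise = lat-major layout
      v <- pracma::interp2(xs, ys, values, pts$x, pts$y, method = "linear")
      matrix(v, nrow = dst$nlat, ncol = dst$nlon)
    },
    block_mean = {
      if (was_logical)
        stop("use method = 'majority' for Boolean fields", call. = FALSE)
      # area-weighted so the coarse field conserves the area-weighted mean
      grouped_weighted_mean(values, src, dst)
    },
    majority = {
      if (!was_logical)
        stop("majority regridding is for Boolean fields", call. = FALSE)
      out <- grouped_stat(values * 1, src, dst, function(v) mean(v))
      res <- out > 0.5
      res
    },
    nearest = {
      xs <- grid_lons(src); ys <- grid_lats(src)
      ci <- pmin(pmax(round((grid_lons(dst) - xs[1]) / src$resolution) + 1L,
                      1L), src$nlon)
      ri <- pmin(pmax(round((grid_lats(dst) - ys[1]) / src$resolution) + 1L,
                      1L), src$nlat)
      values[ri, ci, drop = FALSE]
    })
}

grouped_stat <- function(values, src, dst, fun) {
  idx <- block_index(src, dst)
  keep <- !is.na(idx) & !is.na(values)
  out <- rep(NA_real_, dst$nlat * dst$nlon)
  if (any(keep)) {
    agg <- tapply(values[keep], idx[keep], fun)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  matrix(out, nrow = dst$nlat, ncol = dst$nlon)
}

grouped_weighted_mean <- function(values, src, dst) {
  idx <- block_index(src, dst)
  w <- cell_areas(src)$values
  keep <- !is.na(idx) & !is.na(values)
  out <- rep(NA_real_, dst$nlat * dst$nlon)
  if (any(keep)) {
    sums <- tapply(values[keep] * w[keep], idx[keep], sum)
    wsum <- tapply(w[keep], idx[keep], sum)
    out[as.integer(names(sums))] <- as.numeric(sums) / as.numeric(wsum)
  }
  matrix(out, nrow = dst$nlat, ncol = dst$nlon)
}
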