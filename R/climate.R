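#' Suitability index under a decadal-mean SST scenario
#'
#' Recomputes the suitability index with the temperature factor scored from
#' a single decadal-mean SST raster (no temporal averaging) while the
#' chlorophyll, salinity and sediment mean scores stay fixed. Both the
#' reference and projected SI for a climate delta should come through this
#' same pathway so the two decades are processed identically.
#'
#' @param factors Named list of non-SST mean-score `raster_layer`s
#'   (`chl`, `sss`, `spm`).
#' @param decadal_sst Decadal-mean SST `raster_layer`, deg C.
#' @param weights A [weight_vector()] including an `sst` weight.
#' @param sst_params [sst_response_params()].
#' @return SI `raster_layer`.
#' @export
si_under_scenario <- function(factors, decadal_sst,
                              weights = weight_vector(),
                              sst_params = sst_response_params()) {
  stopifnot(inherits(decadal_sst, "raster_layer"))
  for (f in factors)
    if (!same_grid(f$grid, decadal_sst$grid))
      stop("factor and decadal SST grids do not match", call. = FALSE)
  f_sst <- raster_layer(decadal_sst$grid,
                        sst_score(decadal_sst$values, sst_params),
                        variable = "sst_score", units = "")
  weighted_overlay(c(list(sst = f_sst), factors), weights)
}

#' Percent change of the suitability index between scenarios
#'
#' \deqn{100 \times (Proj - Ref) / Ref} cellwise. Cells with a zero (or
#' missing) reference are returned missing rather than infinite.
#'
#' @param ref_si,proj_si Reference and projected SI `raster_layer`s on one
#'   grid.
#' @return Percent-change `raster_layer`.
#' @export
si_percent_change <- function(ref_si, proj_si) {
  stopifnot(inherits(ref_si, "raster_layer"),
            inherits(proj_si, "raster_layer"))
  if (!same_grid(ref_si$grid, proj_si$grid))
    stop("reference and projected grids do not match", call. = FALSE)
  r <- ref_si$values; p <- proj_si$values
  out <- 100 * (p - r) / r
  out[!is.na(r) & r == 0] <- NA_real_
  raster_layer(ref_si$grid, out, variable = "si_change", units = "%")
}
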