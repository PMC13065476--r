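#' Pipeline configuration
#'
#' Bundles every stage's parameters. All defaults equal the published
#' method's values (thresholds, depth band, current limit, membership
#' parameters, factor weights, wave and port criteria), so a run with no
#' overrides is the reference method applied to the synthetic scenario.
#'
#' @param scenario A [scenario_config()] (the synthetic input generator),
#'   or `NULL` to supply a pre-built bundle to [run_pipeline()].
#' @param criteria [feasibility_criteria()].
#' @param sst_params [sst_response_params()].
#' @param chl_params [chl_response_params()].
#' @param sss_params,spm_params Polynomial responses
#'   ([sss_response_params()], [spm_response_params()]).
#' @param weights A [weight_vector()], or `NULL` to derive weights from
#'   `pairwise`.
#' @param pairwise Optional reciprocal judgment matrix for [ahp_weights()];
#'   when `NULL` the consistent matrix rebuilt from `weights` is used, so
#'   the consistency machinery always runs.
#' @param aux [accessibility_params()].
#' @param current_rule `"max"` or `"mean"` (see [current_mask()]).
#' @param outdir Output directory for rasters, tables, summary and log.
#' @param seed Master seed (overrides the scenario seed for a synthetic
#'   run).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            criteria = feasibility_criteria(),
                            sst_params = sst_response_params(),
                            chl_params = chl_response_params(),
                            sss_params = sss_response_params(),
                            spm_params = spm_response_params(),
                            weights = weight_vector(),
                            pairwise = NULL,
                            aux = accessibility_params(),
                            current_rule = "max",
                            outdir = tempfile("smce_run_"),
                            seed = NULL) {
  if (!is.null(seed) && !is.null(scenario)) scenario$seed <- seed
  structure(list(scenario = scenario, criteria = criteria,
                 sst_params = sst_params, chl_params = chl_params,
                 sss_params = sss_params, spm_params = spm_params,
                 weights = weights, pairwise = pairwise, aux = aux,
                 current_rule = current_rule, outdir = outdir,
                 seed = if (!is.null(seed)) seed
                        else if (!is.null(scenario)) scenario$seed
                        else NA_integer_),
            class = "pipeline_config")
}

#' Run the full site-selection pipeline
#'
#' Executes generate (optional) -> feasibility (fine grid) -> suitability
#' (coarse grid, masked by the majority-regridded feasibility product) ->
#' auxiliary criteria -> climate delta -> co-location ranking, writing all
#' rasters (ASCII grid), the ranking CSV, a JSON summary and a log into
#' `config$outdir`. Identical config + seed give a byte-identical summary.
#'
#' @param config A [pipeline_config()].
#' @param bundle Optional pre-generated `scenario_bundle`; when `NULL` the
#'   scenario in `config` is generated.
#' @return Invisibly, a list with the bundle, stage results and the summary
#'   (also written to `summary.json`).
#' @export
run_pipeline <- function(config, bundle = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$outdir, "run.log")
  log_line <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    log_line("[%s] start", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  crit <- config$criteria
  log_line("seed = %s", config$seed)
  log_line(paste("criteria: heat > %g degC x %d d (max %d episodes),",
                 "depth %g-%g m, current < %g m/s (%s rule)"),
           crit$heat_threshold, crit$heat_min_run,
           crit$max_episodes_allowed, crit$depth_min, crit$depth_max,
           crit$current_limit, config$current_rule)

  if (is.null(bundle))
    bundle <- stage("generate", generate_scenario(config$scenario))

  # --- feasibility on the fine grid ---------------------------------------
  feas <- stage("feasibility", {
    episodes <- count_heat_spike_episodes(bundle$sst, crit$heat_threshold,
                                          crit$heat_min_run)
    combine_feasibility(
      heat_mask(episodes, crit$max_episodes_allowed),
      depth_mask(bundle$bathymetry, crit$depth_min, crit$depth_max),
      current_mask(bundle$current, crit$current_limit,
                   rule = config$current_rule))
  })
  farm_overlap <- stage("feasibility",
                        count_overlapping_farms(bundle$farms,
                                                feas$combined))
  log_line("feasible area %.1f km2; %d/%d farms overlap",
           feas$area_km2, farm_overlap$count, length(bundle$farms))

  # --- suitability on the coarse grid -------------------------------------
  suit <- stage("suitability", {
    ahp <- if (is.null(config$pairwise)) {
      ahp_weights(consistent_matrix(config$weights))
    } else {
      ahp_weights(config$pairwise, factor_names = names(config$weights))
    }
    w <- ahp$weights
    log_line("weights: %s; CR = %.4f",
             paste(sprintf("%s=%.3f", names(w), as.numeric(w)),
                   collapse = " "), ahp$cr)
    coarse <- bundle$coarse_grid
    fbar <- list(
      sst = regrid(mean_factor_score(bundle$sst, function(v)
        sst_score(v, config$sst_params)), coarse, "block_mean"),
      chl = regrid(mean_factor_score(bundle$chl, function(v)
        chl_score(v, config$chl_params)), coarse, "block_mean"),
      sss = if (same_grid(bundle$sss$grid, coarse))
        mean_factor_score(bundle$sss, function(v)
          sss_score(v, config$sss_params))
      else regrid(mean_factor_score(bundle$sss, function(v)
        sss_score(v, config$sss_params)), coarse, "block_mean"),
      spm = regrid(mean_factor_score(bundle$spm, function(v)
        spm_score(v, config$spm_params)), coarse, "block_mean"))
    mask_coarse <- regrid(feas$combined, coarse, "majority")
    si_all <- weighted_overlay(fbar, w)
    si <- si_all
    si$values[!mask_coarse$values] <- NA_real_
    list(ahp = ahp, fbar = fbar, mask_coarse = mask_coarse,
         si_unmasked = si_all, si = si, classes = classify_si(si))
  })

  # --- auxiliary criteria --------------------------------------------------
  aux <- stage("aux", {
    waves_c <- if (same_grid(bundle$waves$grid, bundle$coarse_grid))
      bundle$waves else regrid(bundle$waves, bundle$coarse_grid,
                               "block_mean")
    acc <- accessibility(waves_c, config$aux$wave_limit)
    mw <- max_wave(waves_c, config$aux$max_wave_limit)
    dp <- distance_to_port(bundle$coarse_grid, bundle$ports,
                           config$aux$port_distances_nm)
    list(accessibility = acc, max_wave = mw, port = dp)
  })

  # --- climate delta -------------------------------------------------------
  clim <- stage("climate", {
    non_sst <- suit$fbar[c("chl", "sss", "spm")]
    w <- suit$ahp$weights
    ref <- si_under_scenario(non_sst, bundle$sst_decadal_ref, w,
                             config$sst_params)
    proj <- si_under_scenario(non_sst, bundle$sst_decadal_proj, w,
                              config$sst_params)
    delta <- si_percent_change(ref, proj)
    # feasibility mask deliberately NOT updated under the projection
    delta$values[!suit$mask_coarse$values] <- NA_real_
    list(ref = ref, proj = proj, delta = delta)
  })

  # --- co-location ranking -------------------------------------------------
  report <- stage("colocate",
                  farm_report(bundle$farms, suit$si, clim$delta,
                              aux$accessibility, aux$port$distance_nm))

  # --- outputs -------------------------------------------------------------
  stage("write", {
    w <- function(layer, name)
      write_ascii_grid(layer, file.path(config$outdir,
                                        paste0(name, ".asc")))
    w(feas$heat, "mask_heat"); w(feas$depth, "mask_depth")
    w(feas$current, "mask_current"); w(feas$combined, "mask_feasible")
    for (nm in names(suit$fbar)) w(suit$fbar[[nm]], paste0("fbar_", nm))
    w(suit$si, "si"); w(suit$classes, "si_class")
    w(aux$accessibility, "accessibility"); w(aux$max_wave$max, "max_wave")
    w(aux$port$distance_nm, "distance_to_port")
    w(clim$ref, "si_ref_decadal"); w(clim$proj, "si_proj_decadal")
    w(clim$delta, "si_change_pct")
    write_ranking_csv(report, file.path(config$outdir, "ranking.csv"))
    write_geojson(bundle$farms, file.path(config$outdir, "farms.geojson"))
    write_geojson(bundle$ports, file.path(config$outdir, "ports.geojson"))
  })

  summary <- pipeline_summary(config, bundle, feas, farm_overlap, suit,
                              clim, report)
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_line("done")
  invisible(list(bundle = bundle, feasibility = feas,
                 farm_overlap = farm_overlap, suitability = suit,
                 aux = aux, climate = clim, report = report,
                 summary = summary, outdir = config$outdir))
}

pipeline_summary <- function(config, bundle, feas, farm_overlap, suit, clim,
                             report) {
  areas_c <- cell_areas(bundle$coarse_grid)$values
  cls <- suit$classes$values
  band_area <- vapply(1:5, function(k)
    sum(areas_c[which(cls == k)]), numeric(1))
  names(band_area) <- si_class_levels()
  si_vals <- suit$si$values
  delta_vals <- clim$delta$values
  top <- utils::head(report, 5)
  list(
    seed = config$seed,
    feasible_area_km2 = feas$area_km2,
    feasible_area_coarse_km2 = sum(areas_c[which(suit$mask_coarse$values)]),
    class_band_areas_km2 = as.list(band_area),
    farms_total = length(bundle$farms),
    farms_overlapping_feasible = farm_overlap$count,
    ahp = list(weights = as.list(as.numeric(suit$ahp$weights) |>
                                   stats::setNames(names(suit$ahp$weights))),
               lambda_max = suit$ahp$lambda_max, cr = suit$ahp$cr),
    si = list(mean = mean(si_vals, na.rm = TRUE),
              min = suppressWarnings(min(si_vals, na.rm = TRUE)),
              max = suppressWarnings(max(si_vals, na.rm = TRUE))),
    si_change_pct = list(
      min = suppressWarnings(min(delta_vals, na.rm = TRUE)),
      max = suppressWarnings(max(delta_vals, na.rm = TRUE))),
    top_farms = lapply(seq_len(nrow(top)), function(i)
      list(id = top$id[i], name = top$name[i], status = top$status[i],
           si = top$si[i], dsi_2050_pct = top$dsi_2050_pct[i],
           area_km2 = top$area_km2[i],
           distance_to_port_nm = top$distance_to_port_nm[i],
           accessibility_pct = top$accessibility_pct[i])))
}
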