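#' Temperature response parameters for M. edulis growth
#'
#' Parameters of the cardinal-temperature-style growth response: zero at and
#' above `t_max`, maximum 1 at `t_opt`.
#'
#' @param t_max Upper lethal/critical temperature, deg C.
#' @param t_opt Optimal growth temperature, deg C.
#' @param c Shape rate, per deg C.
#' @return An `sst_response_params` list.
#' @export
sst_response_params <- function(t_max = 30, t_opt = 15.8, c = 0.393) {
  if (t_opt >= t_max) stop("t_opt must be below t_max", call. = FALSE)
  if (c <= 0) stop("c must be positive", call. = FALSE)
  structure(list(t_max = t_max, t_opt = t_opt, c = c),
            class = "sst_response_params")
}

#' Temperature suitability score
#'
#' \deqn{f(T) = \left(\frac{T_{max}-T}{T_{max}-T_{opt}}\right)^{c\,(T_{max}-T_{opt})}
#'   e^{c\,(T-T_{opt})}} for \eqn{T < T_{max}}, else 0. Unimodal with
#' maximum 1 at `t_opt`; clamped to \[0, 1\] against floating-point
#' overshoot.
#'
#' @param sst Temperature(s), deg C (vector/matrix/array).
#' @param params [sst_response_params()].
#' @return Scores in \[0, 1\], same shape as `sst`.
#' @export
sst_score <- function(sst, params = sst_response_params()) {
  p <- params
  k <- p$c * (p$t_max - p$t_opt)
  out <- ((p$t_max - sst) / (p$t_max - p$t_opt))^k *
    exp(p$c * (sst - p$t_opt))
  out[!is.na(sst) & sst >= p$t_max] <- 0
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(dim(sst))) dim(out) <- dim(sst)
  out
}

#' Chlorophyll-a response parameters (ingestion saturation)
#'
#' @param x_k Half-saturation chlorophyll concentration, mg m-3.
#' @return A `chl_response_params` list.
#' @export
chl_response_params <- function(x_k = 1.06) {
  if (x_k <= 0) stop("x_k must be positive", call. = FALSE)
  structure(list(x_k = x_k), class = "chl_response_params")
}

#' Chlorophyll suitability score
#'
#' Michaelis-Menten ingestion response `CHL / (CHL + x_k)`: 0 at zero food,
#' 0.5 at the half-saturation concentration, limit 1.
#'
#' @param chl Chlorophyll a, mg m-3 (>= 0).
#' @param params [chl_response_params()].
#' @return Scores in \[0, 1), same shape as `chl`.
#' @export
chl_score <- function(chl, params = chl_response_params()) {
  if (any(chl < 0, na.rm = TRUE))
    stop("chlorophyll concentrations must be >= 0", call. = FALSE)
  out <- chl / (chl + params$x_k)
  if (!is.null(dim(chl))) dim(out) <- dim(chl)
  out
}

#' Polynomial response with min-max standardization
#'
#' A fitted polynomial response (salinity quartic, sediment quadratic)
#' together with its evaluation domain. Raw values below zero are clamped
#' (a negative physiological proportion is meaningless), then the response
#' is min-max standardized to \[0, 1\] over the domain. The extrema are
#' located by a dense grid search refined with the polynomial's critical
#' points (roots of the derivative).
#'
#' @param coefficients Numeric coefficients in descending degree.
#' @param domain `c(lo, hi)` evaluation domain in the factor's units.
#' @param clamp_negative Clamp raw values below 0 before standardizing.
#' @return A `polynomial_response` with precomputed `f_min`/`f_max`.
#' @export
polynomial_response <- function(coefficients, domain,
                                clamp_negative = TRUE) {
  if (!any(coefficients != 0))
    stop("at least one coefficient must be nonzero", call. = FALSE)
  if (domain[1] >= domain[2])
    stop("domain lo must be below hi", call. = FALSE)
  obj <- structure(list(coefficients = coefficients, domain = domain,
                        clamp_negative = clamp_negative),
                   class = "polynomial_response")
  cand <- seq(domain[1], domain[2], length.out = 4001)
  n <- length(coefficients)
  if (n > 1) {
    deriv <- coefficients[-n] * ((n - 1):1)
    cr <- polyroot(rev(deriv))
    cr <- Re(cr[abs(Im(cr)) < 1e-9])
    cand <- c(cand, cr[cr >= domain[1] & cr <= domain[2]])
  }
  v <- raw_poly(obj, cand)
  if (clamp_negative) v <- pmax(v, 0)
  obj$f_min <- min(v)
  obj$f_max <- max(v)
  if (obj$f_max - obj$f_min < 1e-12)
    stop("polynomial is constant over the domain; cannot standardize",
         call. = FALSE)
  obj
}

# raw polynomial value, no clamping or standardization
raw_poly <- function(params, x) {
  out <- pracma::polyval(params$coefficients, as.numeric(x))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

standardize_poly <- function(params, x) {
  v <- raw_poly(params, x)
  if (params$clamp_negative) v <- pmax(v, 0)
  out <- (v - params$f_min) / (params$f_max - params$f_min)
  pmin(pmax(out, 0), 1)
}

#' Salinity response parameters
#'
#' Quartic fit of the dry-weight/wet-weight condition response to
#' sea-surface salinity, evaluated on \[0, 40\] by default.
#'
#' @param coefficients Descending-degree coefficients of the quartic.
#' @param domain Evaluation/standardization domain.
#' @return A `polynomial_response`.
#' @export
sss_response_params <- function(coefficients = c(-9e-6, 6.91e-4, -2.087e-2,
                                                 0.296816, -0.875038),
                                domain = c(0, 40)) {
  polynomial_response(coefficients, domain)
}

#' Suspended-sediment response parameters
#'
#' Quadratic fit of the carbon absorption efficiency against suspended
#' particulate inorganic matter, evaluated on \[0, 100\] g m-3 by default
#' (the quadratic goes negative around 54.7 g m-3 and is clamped there).
#'
#' @inheritParams sss_response_params
#' @return A `polynomial_response`.
#' @export
spm_response_params <- function(coefficients = c(-2e-4, -4.2e-3, 0.8273),
                                domain = c(0, 100)) {
  polynomial_response(coefficients, domain)
}

#' Salinity suitability score
#'
#' Evaluates the salinity quartic, clamps negatives, and min-max
#' standardizes over the domain. Salinities outside the domain are clipped
#' to it with a warning.
#'
#' @param sss Sea-surface salinity (practical salinity, dimensionless).
#' @param params [sss_response_params()].
#' @param raw Return the raw polynomial value (no clamp/standardization)?
#' @return Scores in \[0, 1\] (or raw values), same shape as `sss`.
#' @export
sss_score <- function(sss, params = sss_response_params(), raw = FALSE) {
  if (raw) return(raw_poly(params, sss))
  d <- params$domain
  if (any(sss < d[1] | sss > d[2], na.rm = TRUE)) {
    warning("salinities outside the response domain were clipped to it")
    sss <- pmin(pmax(sss, d[1]), d[2])
  }
  standardize_poly(params, sss)
}

#' Suspended-sediment suitability score
#'
#' Evaluates the sediment quadratic, clamps negatives (beyond the positive
#' root the raw efficiency is negative and scores 0), and min-max
#' standardizes over the domain. Monotone non-increasing in SPM.
#'
#' @param spm Suspended particulate inorganic matter, g m-3 (>= 0).
#' @param params [spm_response_params()].
#' @param raw Return the raw polynomial value?
#' @return Scores in \[0, 1\] (or raw values), same shape as `spm`.
#' @export
spm_score <- function(spm, params = spm_response_params(), raw = FALSE) {
  if (any(spm < 0, na.rm = TRUE))
    stop("SPM concentrations must be >= 0", call. = FALSE)
  if (raw) return(raw_poly(params, spm))
  d <- params$domain
  spm <- pmin(spm, d[2]) # beyond the domain the clamped response is flat 0
  standardize_poly(params, spm)
}

#' Temporal mean of a factor score
#'
#' Scores every time slice at the factor's native cadence, then averages the
#' scores over the record per cell (score-then-average, not
#' average-then-score). Missing slices are excluded from the mean; all-miss
#' cells come back missing.
#'
#' @param stack A `ts_stack` of the factor.
#' @param scorer Function mapping values to scores in \[0, 1\] (e.g.
#'   [sst_score()], or an anonymous wrapper fixing parameters).
#' @return A `raster_layer` of mean scores.
#' @export
mean_factor_score <- function(stack, scorer) {
  stopifnot(inherits(stack, "ts_stack"))
  nt <- length(stack$times)
  flat <- matrix(stack$values, nrow = nt)
  keep <- !is.na(flat)
  sc <- flat
  sc[keep] <- scorer(flat[keep])
  mean_sc <- colMeans(sc, na.rm = TRUE)
  mean_sc[colSums(keep) == 0] <- NA_real_
  raster_layer(stack$grid,
               matrix(mean_sc, stack$grid$nlat, stack$grid$nlon),
               variable = paste0(stack$variable, "_score"), units = "")
}

#' Factor weight vector
#'
#' @param weights Named non-negative weights summing to 1 (within 1e-9).
#' @return A `weight_vector`.
#' @export
weight_vector <- function(weights = c(sst = 0.45, chl = 0.30, sss = 0.16,
                                      spm = 0.09)) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be named by factor", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1", call. = FALSE)
  structure(weights, class = "weight_vector")
}

#' Saaty random consistency indices
#'
#' Average random index RI(n) for reciprocal matrices of order n.
#'
#' @param n Matrix order.
#' @return RI value.
#' @export
saaty_ri <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)
  if (n < 1 || n > length(ri))
    stop("RI is tabulated for n in 1..10", call. = FALSE)
  ri[n]
}

#' Analytic hierarchy process weights and consistency
#'
#' Derives factor weights as the principal right eigenvector of a positive
#' reciprocal pairwise-comparison matrix (power iteration to 1e-12),
#' normalized to sum 1, and reports Saaty's consistency diagnostics:
#' CI = (lambda_max - n)/(n - 1), CR = CI / RI(n). CR >= 0.1 flags
#' inconsistent judgments; a perfectly consistent matrix gives CR = 0.
#'
#' @param pairwise n x n positive reciprocal matrix (Saaty 1-9 scale and
#'   reciprocals; diagonal 1).
#' @param factor_names Optional names for the weights (defaults to the
#'   matrix dimnames or `f1..fn`).
#' @return An `ahp_result`: `weights` (a [weight_vector()]), `lambda_max`,
#'   `ci`, `cr`, `ri`, `consistent`, and the input matrix.
#' @export
ahp_weights <- function(pairwise, factor_names = NULL) {
  A <- as.matrix(pairwise)
  n <- nrow(A)
  if (n < 2 || ncol(A) != n)
    stop("pairwise matrix must be square with n >= 2", call. = FALSE)
  if (any(A <= 0)) stop("pairwise matrix must be positive", call. = FALSE)
  if (max(abs(A * t(A) - 1)) > 1e-8)
    stop("pairwise matrix is not reciprocal (a_ij * a_ji must be 1)",
         call. = FALSE)
  if (max(abs(diag(A) - 1)) > 1e-12)
    stop("pairwise matrix diagonal must be 1", call. = FALSE)
  w <- rep(1 / n, n)
  for (i in 1:10000) {
    w_new <- as.numeric(A %*% w)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < 1e-12) { w <- w_new; break }
    w <- w_new
  }
  lambda_max <- mean(as.numeric(A %*% w) / w)
  ci <- (lambda_max - n) / (n - 1)
  ri <- saaty_ri(n)
  cr <- if (ri > 0) ci / ri else 0
  cr <- max(cr, 0) # guard the consistent case against -1e-16 round-off
  if (is.null(factor_names))
    factor_names <- if (!is.null(rownames(A))) rownames(A)
                    else paste0("f", seq_len(n))
  names(w) <- factor_names
  structure(list(pairwise = A, weights = weight_vector(w),
                 lambda_max = lambda_max, ci = ci, cr = cr, ri = ri,
                 consistent = cr < 0.1),
            class = "ahp_result")
}

#' @export
print.ahp_result <- function(x, ...) {
  cat("AHP weights:", paste(sprintf("%s = %.4f", names(x$weights),
                                    as.numeric(x$weights)),
                            collapse = ", "), "\n")
  cat(sprintf("lambda_max = %.6f, CI = %.4f, CR = %.4f (%s)\n",
              x$lambda_max, x$ci, x$cr,
              if (x$consistent) "consistent" else "INCONSISTENT"))
  invisible(x)
}

#' Consistent pairwise matrix from target weights
#'
#' Builds the perfectly consistent reciprocal matrix `a_ij = w_i / w_j`
#' whose principal eigenvector reproduces the weights exactly (CR = 0).
#' Used as the default judgment matrix when only published weights, not the
#' expert pairwise scores, are available.
#'
#' @param weights A [weight_vector()] or named positive numeric vector.
#' @return A reciprocal matrix with dimnames from the weight names.
#' @export
consistent_matrix <- function(weights = weight_vector()) {
  w <- as.numeric(weights)
  A <- outer(w, w, "/")
  dimnames(A) <- list(names(weights), names(weights))
  A
}

#' Weighted suitability overlay
#'
#' Cellwise convex combination of mean factor scores,
#' \deqn{SI = \sum_i w_i \bar{F}_i .} Missing in any factor makes the cell
#' missing.
#'
#' @param factors Named list of score `raster_layer`s on one grid; names
#'   must match the weight names.
#' @param weights A [weight_vector()].
#' @return SI `raster_layer` in \[0, 1\].
#' @export
weighted_overlay <- function(factors, weights = weight_vector()) {
  wn <- names(weights)
  if (!setequal(names(factors), wn))
    stop("factor names do not match weight names", call. = FALSE)
  g <- factors[[1]]$grid
  for (f in factors) {
    stopifnot(inherits(f, "raster_layer"))
    if (!same_grid(f$grid, g))
      stop("factor grids do not match", call. = FALSE)
  }
  si <- matrix(0, g$nlat, g$nlon)
  for (nm in wn) si <- si + weights[[nm]] * factors[[nm]]$values
  si <- pmin(pmax(si, 0), 1)
  raster_layer(g, si, variable = "si", units = "")
}

#' Classify the suitability index into five bands
#'
#' Bands are left-closed, right-open — very low \[0, 0.2), low \[0.2, 0.4),
#' medium \[0.4, 0.6), high \[0.6, 0.8) — except the last, very high
#' \[0.8, 1.0\], which is closed. Every finite SI in \[0, 1\] maps to
#' exactly one class.
#'
#' @param si SI `raster_layer` with values in \[0, 1\].
#' @return A `raster_layer` whose values are an integer matrix 1..5 with a
#'   `levels` attribute (`"Very low"` .. `"Very high"`).
#' @export
classify_si <- function(si) {
  stopifnot(inherits(si, "raster_layer"))
  v <- si$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("SI values must lie in [0, 1]", call. = FALSE)
  cls <- findInterval(v, c(0, 0.2, 0.4, 0.6, 0.8), rightmost.closed = FALSE)
  cls[!is.na(v) & v == 1] <- 5L # closed last bin
  cls <- matrix(as.integer(cls), nrow(v), ncol(v))
  cls[is.na(v)] <- NA_integer_
  out <- raster_layer(si$grid, cls, variable = "si_class", units = "")
  attr(out, "levels") <- si_class_levels()
  out
}

#' @rdname classify_si
#' @export
si_class_levels <- function()
  c("Very low", "Low", "Medium", "High", "Very high")
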