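#' Empirical semivariogram of point samples
#'
#' Pairwise semivariances `0.5 * (v_i - v_j)^2` averaged in equal-width lag
#' bins up to half the maximum pairwise distance.
#'
#' @param samples Data frame with columns `x`, `y`, `value` (>= 4 rows).
#' @param n_bins Number of lag bins.
#' @return Data frame with columns `lag` (bin centre), `gamma` (mean
#'   semivariance) and `n` (pair count); empty bins are dropped.
#' @export
empirical_semivariogram <- function(samples, n_bins = 10) {
  n <- nrow(samples)
  if (n < 4L) stop("need at least 4 samples")
  d <- sqrt(outer(samples$x, samples$x, "-")^2 +
              outer(samples$y, samples$y, "-")^2)
  g <- 0.5 * outer(samples$value, samples$value, "-")^2
  iu <- upper.tri(d)
  dv <- d[iu]; gv <- g[iu]
  if (all(dv == 0)) stop("all sample locations coincide")
  max_lag <- max(dv) / 2
  keep <- dv > 0 & dv <= max_lag
  if (!any(keep)) {  # very few, widely spread points: keep all pairs
    max_lag <- max(dv)
    keep <- dv > 0
  }
  dv <- dv[keep]; gv <- gv[keep]
  edges <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(dv, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  out <- data.frame(
    lag = vapply(seq_len(n_bins), function(b)
      if (any(bin == b)) mean(dv[bin == b]) else NA_real_, numeric(1)),
    gamma = vapply(seq_len(n_bins), function(b)
      if (any(bin == b)) mean(gv[bin == b]) else NA_real_, numeric(1)),
    n = vapply(seq_len(n_bins), function(b) sum(bin == b), numeric(1)))
  out[out$n > 0, , drop = FALSE]
}

#' Construct a spherical semivariogram model
#'
#' @param nugget Non-negative nugget variance.
#' @param partial_sill Non-negative partial sill.
#' @param range_m Positive range in metres.
#' @return An object of class `spherical_variogram`.
#' @export
spherical_variogram <- function(nugget, partial_sill, range_m) {
  stopifnot(nugget >= 0, partial_sill >= 0, range_m > 0)
  structure(list(nugget = nugget, partial_sill = partial_sill,
                 range_m = range_m),
            class = "spherical_variogram")
}

#' @export
print.spherical_variogram <- function(x, ...) {
  cat(sprintf("spherical_variogram: nugget %.4g, partial sill %.4g, range %.4g m\n",
              x$nugget, x$partial_sill, x$range_m))
  invisible(x)
}

#' Evaluate a spherical semivariogram
#'
#' `gamma(h) = nugget + psill * (1.5 h/a - 0.5 (h/a)^3)` for `0 < h < a`,
#' the full sill for `h >= a`, and exactly 0 at `h = 0`.
#'
#' @param model A [spherical_variogram()].
#' @param h Non-negative lag distance(s) in metres.
#' @return Semivariance value(s).
#' @export
variogram_value <- function(model, h) {
  if (any(h < 0)) stop("lag distances must be non-negative")
  u <- pmin(h / model$range_m, 1)
  out <- model$nugget + model$partial_sill * (1.5 * u - 0.5 * u^3)
  out[h == 0] <- 0
  out
}

#' Fit a spherical semivariogram to an empirical one
#'
#' Pair-count-weighted least squares over (nugget, partial sill, range)
#' with non-negativity bounds; the weight normalization makes the fit
#' invariant to rescaling all pair counts. If the optimizer fails a
#' pure-structure fallback (zero nugget, empirical variance, half the
#' maximum lag) is returned with a warning.
#'
#' @param empirical Data frame from [empirical_semivariogram()].
#' @return A [spherical_variogram()].
#' @export
fit_spherical <- function(empirical) {
  emp <- empirical[is.finite(empirical$gamma) & empirical$n > 0, ]
  if (nrow(emp) < 3L) stop("need at least 3 non-empty lag bins")
  w <- emp$n / sum(emp$n)
  obj <- function(par) {
    m <- spherical_variogram(par[1], par[2], par[3])
    sum(w * (variogram_value(m, emp$lag) - emp$gamma)^2)
  }
  sill0 <- max(emp$gamma)
  init <- c(nugget = max(0, min(emp$gamma) * 0.5),
            psill = max(sill0 - min(emp$gamma) * 0.5, 1e-8),
            range = max(emp$lag) * 2 / 3)
  fit <- tryCatch(
    stats::optim(init, obj, method = "L-BFGS-B",
                 lower = c(0, 0, min(emp$lag) * 1e-3),
                 upper = c(Inf, Inf, max(emp$lag) * 4)),
    error = function(e) NULL)
  # restart from a no-nugget initialization and keep the better optimum
  fit2 <- tryCatch(
    stats::optim(c(0, sill0, max(emp$lag)), obj, method = "L-BFGS-B",
                 lower = c(0, 0, min(emp$lag) * 1e-3),
                 upper = c(Inf, Inf, max(emp$lag) * 4)),
    error = function(e) NULL)
  cands <- Filter(Negate(is.null), list(fit, fit2))
  cands <- Filter(function(f) is.finite(f$value), cands)
  if (!length(cands)) {
    warning("variogram optimization failed; using pure-structure fallback")
    return(spherical_variogram(0, stats::var(emp$gamma) + mean(emp$gamma),
                               max(emp$lag) / 2))
  }
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "value"))]]
  spherical_variogram(best$par[1], best$par[2], best$par[3])
}

# ordinary-kriging system: factor once, predict at many points.
# Returns weights so callers can verify the unbiasedness constraint.
ok_system <- function(samples, vario) {
  n <- nrow(samples)
  d <- sqrt(outer(samples$x, samples$x, "-")^2 +
              outer(samples$y, samples$y, "-")^2)
  G <- matrix(variogram_value(vario, as.vector(d)), n, n)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  A
}

ok_solve <- function(A, rhs) {
  tryCatch(solve(A, rhs), error = function(e) {
    # near-singular sample configuration: tiny diagonal jitter on the
    # semivariance block
    n <- nrow(A) - 1L
    scale <- mean(abs(A[seq_len(n), seq_len(n)])) + 1e-12
    warning("singular kriging system; adding diagonal jitter")
    A[cbind(seq_len(n), seq_len(n))] <- A[cbind(seq_len(n), seq_len(n))] +
      1e-10 * scale
    solve(A, rhs)
  })
}

#' Ordinary-kriging prediction at points
#'
#' Solves the ordinary-kriging system (semivariance matrix bordered by the
#' unbiasedness constraint) for each prediction location. Weights sum to 1;
#' with a zero nugget the prediction at a sample location reproduces the
#' sample value.
#'
#' @param samples Data frame with columns `x`, `y`, `value` (>= 3
#'   non-collinear rows).
#' @param vario A [spherical_variogram()].
#' @param x,y Prediction coordinates.
#' @param return_weights If `TRUE`, also return the kriging weight matrix.
#' @return Numeric predictions, or (with `return_weights`) a list with
#'   `pred` and `weights` (n_samples x n_points).
#' @export
ok_predict <- function(samples, vario, x, y, return_weights = FALSE) {
  n <- nrow(samples)
  if (n < 3L) stop("ordinary kriging needs at least 3 samples")
  A <- ok_system(samples, vario)
  d0 <- sqrt(outer(samples$x, x, "-")^2 + outer(samples$y, y, "-")^2)
  rhs <- rbind(matrix(variogram_value(vario, as.vector(d0)), n),
               rep(1, length(x)))
  sol <- ok_solve(A, rhs)
  lambda <- sol[seq_len(n), , drop = FALSE]
  pred <- drop(crossprod(lambda, samples$value))
  if (return_weights) list(pred = pred, weights = lambda) else pred
}

#' Ordinary-kriging interpolation surface
#'
#' @param samples Data frame with columns `x`, `y`, `value`.
#' @param vario A [spherical_variogram()].
#' @param spec Target [grid_spec()].
#' @param name Output layer name.
#' @return A [raster_layer()] of kriged predictions.
#' @export
ordinary_krige <- function(samples, vario, spec, name = "ok") {
  ctr <- cell_centers(spec)
  pred <- ok_predict(samples, vario, as.vector(ctr$x), as.vector(ctr$y))
  raster_layer(spec, matrix(pred, spec$n_rows, spec$n_cols), name = name)
}

# x, y, elevation design matrix for the three-variable MARS baseline
mars3_design <- function(dem, x, y) {
  cbind(x = x, y = y, elevation = sample_at(dem, x, y))
}

#' Fit the three-variable MARS baseline
#'
#' A MARS model on longitude, latitude (as projected x/y coordinates) and
#' elevation only — the classic three-predictor spline interpolator the
#' richer covariate pipeline is compared against. Shares the same MARS
#' engine as the full pipeline.
#'
#' @param stations Data frame with columns `x`, `y`, `value`.
#' @param dem A [raster_layer()] covering the stations.
#' @param max_terms,max_degree,penalty Passed to [fit_mars()].
#' @return A list of class `mars3_fit` with elements `model` (the
#'   [fit_mars()] result) and `dem`.
#' @export
fit_mars3 <- function(stations, dem, max_terms = NULL, max_degree = 2,
                      penalty = 3, minspan = "auto") {
  X <- mars3_design(dem, stations$x, stations$y)
  if (any(!is.finite(X[, "elevation"])))
    stop("DEM does not cover all stations")
  model <- fit_mars(X, stations$value, max_terms = max_terms,
                    max_degree = max_degree, penalty = penalty,
                    minspan = minspan)
  structure(list(model = model, dem = dem,
                 value_range = range(stations$value)),
            class = "mars3_fit")
}

#' @param clamp Truncate predictions to the training concentration range
#'   (the exposure-mapping convention; hinge models are not credible
#'   outside the observed range).
#' @rdname fit_mars3
#' @param object A `mars3_fit`.
#' @param x,y Prediction coordinates.
#' @param ... Unused.
#' @export
predict.mars3_fit <- function(object, x, y, clamp = TRUE, ...) {
  p <- predict(object$model, mars3_design(object$dem, x, y))
  if (clamp) p <- pmin(pmax(p, object$value_range[1]), object$value_range[2])
  p
}

#' @export
print.mars3_fit <- function(x, ...) {
  cat("mars3_fit (x, y, elevation predictors)\n")
  print(x$model)
  invisible(x)
}
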