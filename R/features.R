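#' Inverse-distance-weighted interpolation surface
#'
#' Deterministic interpolation of point samples onto a grid with weights
#' `d^-power` over all samples. IDW is an exact interpolator: a cell whose
#' centre (numerically) coincides with a sample returns that sample's value.
#'
#' @param samples Data frame with columns `x`, `y`, `value`.
#' @param spec Target [grid_spec()].
#' @param power Positive distance-decay exponent.
#' @param name Output layer name.
#' @return A [raster_layer()].
#' @export
idw_surface <- function(samples, spec, power = 2, name = "idw") {
  if (nrow(samples) == 0L) stop("idw_surface needs at least one sample")
  stopifnot(power > 0)
  ctr <- cell_centers(spec)
  pred <- idw_predict(samples, as.vector(ctr$x), as.vector(ctr$y), power,
                      snap_dist = spec$cell_size / 1000)
  raster_layer(spec, matrix(pred, spec$n_rows, spec$n_cols), name = name)
}

#' Inverse-distance-weighted prediction at points
#'
#' @param samples Data frame with columns `x`, `y`, `value`.
#' @param x,y Prediction locations.
#' @param power Positive distance-decay exponent.
#' @param snap_dist Distance below which a prediction point is considered
#'   coincident with a sample and returns its value exactly.
#' @return Numeric vector of predictions.
#' @export
idw_predict <- function(samples, x, y, power = 2, snap_dist = 1e-9) {
  n <- nrow(samples)
  d2 <- outer(x, samples$x, "-")^2 + outer(y, samples$y, "-")^2
  d <- sqrt(d2)
  near <- d < snap_dist
  w <- d^(-power)
  w[near] <- 0  # handled by exact snap below
  num <- w %*% samples$value
  den <- rowSums(w)
  pred <- as.vector(num) / den
  hit <- which(rowSums(near) > 0)
  for (i in hit) {
    j <- which.min(d[i, ])
    pred[i] <- samples$value[j]
  }
  pred
}

#' Select the IDW power by leave-one-out cross-validation
#'
#' Evaluates each candidate exponent by point-to-point leave-one-out IDW
#' prediction over the samples and returns the candidate with the smallest
#' RMSE; ties are broken toward the smallest power.
#'
#' @param samples Data frame with columns `x`, `y`, `value` (at least 3 rows).
#' @param candidate_powers Numeric vector of candidate exponents.
#' @return The selected power (a single number).
#' @export
select_idw_power <- function(samples, candidate_powers = c(1, 2, 3)) {
  if (nrow(samples) < 3L) stop("need at least 3 samples to select a power")
  if (length(candidate_powers) == 0L) stop("no candidate powers supplied")
  candidate_powers <- sort(candidate_powers)
  score <- vapply(candidate_powers, function(p) {
    pred <- vapply(seq_len(nrow(samples)), function(i) {
      idw_predict(samples[-i, , drop = FALSE], samples$x[i], samples$y[i], p)
    }, numeric(1))
    sqrt(mean((samples$value - pred)^2))
  }, numeric(1))
  # tolerance on ties: identical-quality candidates (e.g. all-zero RMSE up
  # to float noise) resolve to the smallest power
  best <- min(score)
  candidate_powers[which(score <= best + 1e-9 * max(best, 1))[1]]
}

#' Focal (neighbourhood) mean of a raster
#'
#' Each output cell is the mean of the non-nodata input cells whose centres
#' lie within `radius` of its centre (circular neighbourhood, centre
#' included). Nodata cells stay nodata in the output.
#'
#' @param layer A [raster_layer()].
#' @param radius Neighbourhood radius in metres; must be at least one cell.
#' @return A [raster_layer()].
#' @export
focal_mean <- function(layer, radius) {
  cs <- layer$spec$cell_size
  if (radius < cs) stop("focal radius must be at least one cell size")
  nr <- layer$spec$n_rows; nc <- layer$spec$n_cols
  k <- ceiling(radius / cs)
  offs <- expand.grid(dr = -k:k, dc = -k:k)
  # strict containment: a neighbour centre exactly at distance `radius` is
  # excluded, so radius = cell_size gives the singleton neighbourhood
  offs <- offs[offs$dr^2 + offs$dc^2 < (radius / cs)^2, ]
  V <- layer$values
  fin <- is.finite(V)
  Vz <- ifelse(fin, V, 0)
  S <- matrix(0, nr, nc); C <- matrix(0, nr, nc)
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]; dc <- offs$dc[i]
    tr <- max(1, 1 - dr):min(nr, nr - dr)
    tc <- max(1, 1 - dc):min(nc, nc - dc)
    S[tr, tc] <- S[tr, tc] + Vz[tr + dr, tc + dc]
    C[tr, tc] <- C[tr, tc] + fin[tr + dr, tc + dc]
  }
  out <- S / C
  out[C == 0] <- NA_real_
  out[!fin] <- NA_real_
  raster_layer(layer$spec, out, name = paste0(layer$name, "_focal"))
}

#' Kernel density surface of weighted events
#'
#' Planar kernel density estimation with the quartic (biweight) kernel
#' `K(u) = (3/pi) (1 - u^2)^2` for `u < 1`: each cell receives
#' `sum_i w_i K(d_i / radius) / radius^2` over contributing events, so the
#' surface integrates to the total event weight (for events away from the
#' grid edge). Polylines are densified to points every half cell weighted
#' by represented length; polygons contribute their centroid with the full
#' weight.
#'
#' @param layer A [vector_layer()] of events; an empty layer yields an
#'   all-zero surface.
#' @param spec Target [grid_spec()].
#' @param radius Kernel search radius in metres; at least one cell.
#' @param name Output layer name.
#' @return A [raster_layer()] of densities (per square metre, >= 0; exactly
#'   0 beyond `radius` of every event).
#' @export
kde_surface <- function(layer, spec, radius, name = "kde") {
  cs <- spec$cell_size
  if (radius < cs) stop("KDE radius must be at least one cell size")
  out <- matrix(0, spec$n_rows, spec$n_cols)
  ev <- as_event_points(layer, step = cs / 2)
  if (nrow(ev$xy) == 0L)
    return(raster_layer(spec, out, name = name))
  cx <- spec$origin_x + (seq_len(spec$n_cols) - 0.5) * cs
  cy <- spec$origin_y - (seq_len(spec$n_rows) - 0.5) * cs
  r2 <- radius^2
  for (i in seq_len(nrow(ev$xy))) {
    px <- ev$xy[i, 1]; py <- ev$xy[i, 2]
    cols <- which(abs(cx - px) < radius)
    rows <- which(abs(cy - py) < radius)
    if (!length(cols) || !length(rows)) next
    d2 <- outer((cy[rows] - py)^2, (cx[cols] - px)^2, "+")
    inside <- d2 < r2
    if (!any(inside)) next
    u2 <- d2[inside] / r2
    contrib <- matrix(0, length(rows), length(cols))
    contrib[inside] <- ev$w[i] * (3 / pi) * (1 - u2)^2 / r2
    out[rows, cols] <- out[rows, cols] + contrib
  }
  raster_layer(spec, out, name = name)
}

#' Bivariate Moran's I
#'
#' Cross-variable spatial autocorrelation between a dependent variable and
#' the spatial lag of a covariate under a spatial weight matrix:
#' `I = (n / S0) * sum_ij w_ij z_i c_j / sqrt(sum z^2 * sum c^2)` with `z`,
#' `c` the mean-centred variables and `S0` the sum of all weights. With
#' `cov = dep` this reduces to the univariate Moran's I.
#'
#' @param dep,cov Equal-length numeric vectors (n >= 3).
#' @param weights n x n non-negative spatial weight matrix with a zero
#'   diagonal (need not be row-standardized).
#' @return The Moran's I statistic (a single number).
#' @export
bivariate_morans_i <- function(dep, cov, weights) {
  n <- length(dep)
  if (length(cov) != n) stop("dep and cov must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  weights <- as.matrix(weights)
  if (!all(dim(weights) == n)) stop("weights must be an n x n matrix")
  if (any(diag(weights) != 0)) stop("weight matrix must have a zero diagonal")
  if (any(weights < 0)) stop("weights must be non-negative")
  z <- dep - mean(dep)
  cc <- cov - mean(cov)
  sz <- sum(z^2); sc <- sum(cc^2)
  if (sz == 0 || sc == 0)
    stop("Moran's I is undefined for a zero-variance variable")
  s0 <- sum(weights)
  if (s0 == 0) stop("weight matrix sums to zero")
  (n / s0) * as.numeric(t(z) %*% weights %*% cc) / sqrt(sz * sc)
}

#' Inverse-distance spatial weights between stations
#'
#' `w_ij = 1 / d_ij^power` with a zero diagonal; the conventional weight
#' matrix used here for the Moran's I radius search.
#'
#' @param x,y Station coordinates.
#' @param power Distance-decay exponent (default 1).
#' @return An n x n weight matrix.
#' @export
inverse_distance_weights <- function(x, y, power = 1) {
  d <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
  if (any(d[upper.tri(d)] == 0))
    stop("coincident stations give infinite inverse-distance weights")
  w <- d^(-power)
  diag(w) <- 0
  w
}

#' Select a neighbourhood radius by maximizing bivariate Moran's I
#'
#' For each candidate radius the covariate surface is built, sampled at the
#' station locations, and scored by the absolute bivariate Moran's I
#' against the dependent values; the radius attaining the maximum |I| is
#' selected (smallest radius on ties). The magnitude is used so that
#' covariates with strong negative association (e.g. green areas vs NO2)
#' are handled symmetrically.
#'
#' @param dep_samples Data frame with columns `x`, `y`, `value` (>= 4 rows).
#' @param surface_builder Function `radius -> raster_layer`.
#' @param radii Candidate radii in metres (>= 2 unless a single candidate
#'   is deliberately passed).
#' @param weights Optional station weight matrix; defaults to
#'   inverse-distance power-2 weights, held fixed across candidates
#'   (stronger decay keeps the cross-lag statistic focused on the nearest
#'   station pairs, whose neighbourhoods actually overlap at the candidate
#'   radii).
#' @return An object of class `radius_search`: list with `radii`,
#'   `moran_values` and `selected_radius`.
#' @export
select_radius <- function(dep_samples, surface_builder, radii,
                          weights = NULL) {
  if (nrow(dep_samples) < 4L) stop("need at least 4 stations")
  if (length(radii) < 1L) stop("no candidate radii supplied")
  radii <- sort(radii)
  if (is.null(weights))
    weights <- inverse_distance_weights(dep_samples$x, dep_samples$y,
                                        power = 2)
  moran <- vapply(radii, function(r) {
    layer <- surface_builder(r)
    cv <- sample_at(layer, dep_samples$x, dep_samples$y)
    ok <- is.finite(cv) & is.finite(dep_samples$value)
    if (sum(ok) < 3L) return(NA_real_)
    tryCatch(
      bivariate_morans_i(dep_samples$value[ok], cv[ok],
                         weights[ok, ok, drop = FALSE]),
      error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(moran)))
    stop("covariate surface is degenerate at every candidate radius")
  sel <- radii[which.max(abs(moran))]
  structure(list(radii = radii, moran_values = moran, selected_radius = sel),
            class = "radius_search")
}

#' @export
print.radius_search <- function(x, ...) {
  cat(sprintf("radius_search: %d candidates, selected %g m (|I| = %.4f)\n",
              length(x$radii), x$selected_radius,
              abs(x$moran_values[match(x$selected_radius, x$radii)])))
  invisible(x)
}

#' Min-max normalization of a raster layer
#'
#' Rescales non-nodata values to `[0, 1]` and returns the bounds so the
#' transform can be reused (or inverted) later.
#'
#' @param layer A [raster_layer()] with at least two distinct finite values.
#' @return A list with `layer` (the normalized [raster_layer()]) and
#'   `bounds = c(min, max)`.
#' @export
min_max_normalize <- function(layer) {
  v <- layer$values
  fin <- v[is.finite(v)]
  if (length(fin) < 2L || max(fin) == min(fin))
    stop("cannot min-max normalize a degenerate (constant) layer: ",
         layer$name)
  lo <- min(fin); hi <- max(fin)
  raster <- raster_layer(layer$spec, (v - lo) / (hi - lo), name = layer$name)
  list(layer = raster, bounds = c(min = lo, max = hi))
}

# default radius-search ladder: one cell up to a quarter of the shorter
# grid extent, in one-cell steps
default_radii <- function(spec) {
  k <- max(2L, floor(0.25 * min(spec$n_rows, spec$n_cols)))
  spec$cell_size * seq_len(k)
}

# canonical covariate order of the 14-layer stack
stack_layer_names <- function() {
  c("wind_speed", "temperature", "pressure", "relative_humidity",
    "gas_density", "petrol_density", "green_density", "sport_density",
    "dem", "avg_elevation", "population_density", "road_density",
    "x_coord", "y_coord")
}

# Precompute everything in the covariate stack that does not depend on the
# dependent-variable values: IDW met surfaces (power chosen by LOOCV on the
# met samples themselves), the resampled DEM, coordinate rasters, and the
# full ladder of candidate surfaces (with their station samples) for every
# Moran-radius-driven layer. Radius selection can then be re-run per
# cross-validation fold at negligible cost.
feature_candidates <- function(inputs, spec, config = list()) {
  need <- c("stations", "met", "dem", "pois", "roads", "population")
  miss <- setdiff(need, names(inputs))
  if (length(miss))
    stop("missing input class(es): ", paste(miss, collapse = ", "))
  met_names <- c("wind_speed", "temperature", "pressure", "relative_humidity")
  miss_met <- setdiff(met_names, names(inputs$met))
  if (length(miss_met))
    stop("missing meteorological input(s): ", paste(miss_met, collapse = ", "))
  poi_names <- c("gas", "petrol", "green", "sport")
  miss_poi <- setdiff(poi_names, names(inputs$pois))
  if (length(miss_poi))
    stop("missing POI class(es): ", paste(miss_poi, collapse = ", "))

  radii <- if (!is.null(config$radii)) config$radii else default_radii(spec)
  powers <- if (!is.null(config$idw_powers)) config$idw_powers else c(1, 2, 3)
  st <- inputs$stations

  met_layers <- list(); met_powers <- numeric(0)
  for (nm in met_names) {
    p <- select_idw_power(inputs$met[[nm]], powers)
    met_layers[[nm]] <- idw_surface(inputs$met[[nm]], spec, p, name = nm)
    met_powers[nm] <- p
  }

  dem <- resample_to(inputs$dem, spec)
  dem$name <- "dem"
  ctr <- cell_centers(spec)
  xc <- raster_layer(spec, ctr$x, name = "x_coord")
  yc <- raster_layer(spec, ctr$y, name = "y_coord")

  kde_sources <- list(
    gas_density = inputs$pois$gas, petrol_density = inputs$pois$petrol,
    green_density = inputs$pois$green, sport_density = inputs$pois$sport,
    population_density = inputs$population, road_density = inputs$roads)

  moran <- list()
  for (nm in names(kde_sources)) {
    surfaces <- lapply(radii, function(r)
      kde_surface(kde_sources[[nm]], spec, r, name = nm))
    station_vals <- vapply(surfaces, function(s) sample_at(s, st$x, st$y),
                           numeric(nrow(st)))
    moran[[nm]] <- list(radii = radii, surfaces = surfaces,
                        station_vals = station_vals)
  }
  focal_surfaces <- lapply(radii, function(r) {
    s <- focal_mean(dem, r); s$name <- "avg_elevation"; s
  })
  moran[["avg_elevation"]] <- list(
    radii = radii, surfaces = focal_surfaces,
    station_vals = vapply(focal_surfaces,
                          function(s) sample_at(s, st$x, st$y),
                          numeric(nrow(st))))

  list(spec = spec, stations = st, met_layers = met_layers,
       met_powers = met_powers, dem = dem, x_coord = xc, y_coord = yc,
       moran = moran,
       station_weights = inverse_distance_weights(st$x, st$y, power = 2))
}

# Assemble the normalized 14-layer stack from precomputed candidates,
# selecting each Moran-driven radius against dep values at a subset of
# stations (all stations by default).
assemble_stack <- function(cand, dep_values = NULL, station_idx = NULL) {
  if (is.null(station_idx)) station_idx <- seq_len(nrow(cand$stations))
  if (is.null(dep_values)) dep_values <- cand$stations$value[station_idx]
  W <- cand$station_weights[station_idx, station_idx, drop = FALSE]
  sel_radii <- numeric(0)
  sel_moran <- numeric(0)
  chosen <- list()
  for (nm in names(cand$moran)) {
    m <- cand$moran[[nm]]
    moran_vals <- vapply(seq_along(m$radii), function(j) {
      cv <- m$station_vals[station_idx, j]
      ok <- is.finite(cv) & is.finite(dep_values)
      if (sum(ok) < 3L) return(NA_real_)
      tryCatch(bivariate_morans_i(dep_values[ok], cv[ok],
                                  W[ok, ok, drop = FALSE]),
               error = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(moran_vals)))
      stop("layer '", nm, "' is degenerate at every candidate radius")
    j <- which.max(abs(moran_vals))
    sel_radii[nm] <- m$radii[j]
    sel_moran[nm] <- moran_vals[j]
    chosen[[nm]] <- m$surfaces[[j]]
  }
  raw <- c(cand$met_layers,
           chosen[c("gas_density", "petrol_density", "green_density",
                    "sport_density")],
           list(dem = cand$dem, avg_elevation = chosen$avg_elevation,
                population_density = chosen$population_density,
                road_density = chosen$road_density,
                x_coord = cand$x_coord, y_coord = cand$y_coord))
  raw <- raw[stack_layer_names()]
  layers <- list(); bounds <- matrix(NA_real_, 14, 2,
                                     dimnames = list(stack_layer_names(),
                                                     c("min", "max")))
  for (nm in names(raw)) {
    nz <- min_max_normalize(raw[[nm]])
    layers[[nm]] <- nz$layer
    bounds[nm, ] <- nz$bounds
  }
  structure(
    list(spec = cand$spec, layers = layers, bounds = bounds,
         provenance = list(idw_powers = as.list(cand$met_powers),
                           radii = as.list(sel_radii),
                           moran = as.list(sel_moran))),
    class = "feature_stack")
}

#' Build the normalized 14-covariate feature stack
#'
#' The GIS feature-engineering step of the pipeline: meteorological point
#' samples are interpolated by IDW (power chosen by leave-one-out RMSE over
#' the candidates), POI/population/road layers become kernel density
#' surfaces and the DEM a resampled elevation plus a focal-mean elevation,
#' each density/focal radius selected by maximizing the absolute bivariate
#' Moran's I against the station values of the dependent variable, and cell
#' centre x/y coordinate rasters complete the stack. All 14 layers are
#' min-max normalized to `[0, 1]`.
#'
#' @param inputs A list with elements `stations` (data frame `x,y,value` of
#'   the dependent variable), `met` (list of data frames `wind_speed`,
#'   `temperature`, `pressure`, `relative_humidity`), `dem` (a
#'   [raster_layer()]), `pois` (list of [vector_layer()]s `gas`, `petrol`,
#'   `green`, `sport`), `roads` and `population` ([vector_layer()]s).
#' @param spec Target [grid_spec()].
#' @param config Optional list: `radii` (candidate radii in metres; default
#'   one cell up to a quarter of the shorter grid extent in one-cell steps)
#'   and `idw_powers` (default `c(1, 2, 3)`).
#' @return An object of class `feature_stack`: the 14 normalized
#'   [raster_layer()]s in canonical order, the per-layer normalization
#'   bounds, and provenance (selected radii, Moran's I values, IDW powers).
#' @export
build_feature_stack <- function(inputs, spec, config = list()) {
  cand <- feature_candidates(inputs, spec, config)
  assemble_stack(cand)
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("feature_stack: %d layers on %d x %d grid\n",
              length(x$layers), x$spec$n_rows, x$spec$n_cols))
  cat("  selected radii (m):",
      paste(names(x$provenance$radii),
            unlist(x$provenance$radii), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Per-pixel feature matrix of a stack
#'
#' @param stack A [build_feature_stack()] result.
#' @return A numeric matrix with one row per grid cell at which all 14
#'   layers are valid and one named column per layer; the attribute
#'   `"cell_index"` holds the linear (column-major) cell indices of the
#'   retained rows.
#' @export
stack_pixel_matrix <- function(stack) {
  X <- vapply(stack$layers, function(l) as.vector(l$values),
              numeric(stack$spec$n_rows * stack$spec$n_cols))
  keep <- rowSums(!is.finite(X)) == 0L
  out <- X[keep, , drop = FALSE]
  attr(out, "cell_index") <- which(keep)
  out
}

#' Extract normalized feature vectors at point locations
#'
#' @param stack A [build_feature_stack()] result.
#' @param x,y Point coordinates (inside the grid).
#' @return A matrix with one row per point and one column per stack layer.
#' @export
stack_feature_vectors <- function(stack, x, y) {
  out <- vapply(stack$layers, function(l) sample_at(l, x, y),
                numeric(length(x)))
  if (length(x) == 1L)
    out <- matrix(out, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  out
}

#' Write feature-stack provenance to a JSON sidecar
#'
#' Records the selected radii, Moran's I values, IDW powers and
#' normalization bounds needed to reproduce or audit a run.
#'
#' @param stack A [build_feature_stack()] result.
#' @param path Output JSON path.
#' @export
write_stack_provenance <- function(stack, path) {
  jsonlite::write_json(
    list(idw_powers = stack$provenance$idw_powers,
         radii = stack$provenance$radii,
         moran = stack$provenance$moran,
         normalization_bounds = apply(stack$bounds, 1, as.list)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
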