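#' Configuration of a synthetic urban scene
#'
#' Describes a complete synthetic city for end-to-end testing: a 500-m grid
#' roughly the footprint of a large city, 21 pollution monitoring stations,
#' a handful of meteorological stations, clustered POI point processes,
#' random road polylines, population blocks, a DEM with a north-south
#' elevation gradient, and a ground-truth NO2 surface built as a
#' linear-plus-hinge combination of smoothed covariates plus a spatially
#' correlated residual.
#'
#' Default effect sizes (in micrograms per cubic metre per unit of the
#' min-max-scaled covariate) give stations a spread of several tens of
#' micrograms per cubic metre, with green areas and sport fields acting
#' negatively; measurement noise defaults to 5.
#'
#' @param seed Integer RNG seed; the scene is fully reproducible from it.
#' @param n_rows,n_cols,cell_size Grid shape (default 60 x 80 cells of
#'   500 m).
#' @param n_stations Number of monitoring stations (default 21).
#' @param n_met_stations Number of meteorological stations (default 8).
#' @param noise_sd Station measurement noise, micrograms per cubic metre.
#' @param spatial_sd Standard deviation of the spatially correlated
#'   residual field.
#' @param spatial_range Correlation length of the residual field, metres.
#' @param effects Named effect sizes; unnamed entries fall back to the
#'   defaults listed under `scene_default_effects()`.
#' @param gen_radii Named smoothing radii (metres) used when building the
#'   truth covariate surfaces.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(seed = 1, n_rows = 60, n_cols = 80, cell_size = 500,
                         n_stations = 21, n_met_stations = 8,
                         noise_sd = 5, spatial_sd = 2, spatial_range = 3000,
                         effects = list(), gen_radii = list()) {
  stopifnot(n_stations >= 4, noise_sd >= 0, spatial_sd >= 0)
  def_eff <- scene_default_effects()
  for (nm in names(effects)) def_eff[[nm]] <- effects[[nm]]
  def_rad <- list(gas = 5000, petrol = 5000, green = 5000, sport = 5000,
                  population = 5000, road = 5000, focal = 2000)
  for (nm in names(gen_radii)) def_rad[[nm]] <- gen_radii[[nm]]
  structure(
    list(seed = as.integer(seed), n_rows = n_rows, n_cols = n_cols,
         cell_size = cell_size, n_stations = as.integer(n_stations),
         n_met_stations = as.integer(n_met_stations),
         noise_sd = noise_sd, spatial_sd = spatial_sd,
         spatial_range = spatial_range,
         effects = def_eff, gen_radii = def_rad),
    class = "scene_config")
}

#' Default covariate effect sizes of the scene generator
#'
#' @return Named list of coefficients (micrograms per cubic metre per unit
#'   scaled covariate); `base` is the city-wide background level. The road
#'   and population effects act through a hinge (only densities above a
#'   threshold contribute), matching the piecewise-linear functional class
#'   of the downstream spline model.
#' @export
scene_default_effects <- function() {
  list(base = 60,
       road = 70, road_hinge = 0.15,
       gas = 35, petrol = 22,
       green = -30, sport = -15,
       population = 32, population_hinge = 0.10,
       elevation = -60,
       temperature = -20, wind_speed = -20,
       pressure = 12, relative_humidity = 12)
}

# separable Gaussian blur with edge renormalization
gauss_smooth <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  K <- max(1L, ceiling(3 * sigma_cells))
  k <- stats::dnorm(-K:K, sd = sigma_cells)
  smooth_rows <- function(mm) {
    nr <- nrow(mm)
    out <- matrix(0, nr, ncol(mm)); wt <- matrix(0, nr, ncol(mm))
    for (o in -K:K) {
      lo <- max(1, 1 - o); hi <- min(nr, nr - o)
      if (lo > hi) next
      tr <- lo:hi
      out[tr, ] <- out[tr, ] + k[o + K + 1] * mm[tr + o, , drop = FALSE]
      wt[tr, ] <- wt[tr, ] + k[o + K + 1]
    }
    out / wt
  }
  t(smooth_rows(t(smooth_rows(m))))
}

scale01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi == lo) return(m * 0)
  (m - lo) / (hi - lo)
}

# sample cell-centre locations with probability proportional to a weight
# field, with uniform jitter inside each cell
weighted_cell_points <- function(n, spec, wfield) {
  w <- pmax(as.vector(wfield), 0)
  idx <- sample.int(length(w), n, replace = TRUE, prob = w / sum(w))
  row <- (idx - 1L) %% spec$n_rows + 1L
  col <- (idx - 1L) %/% spec$n_rows + 1L
  cs <- spec$cell_size
  cbind(spec$origin_x + (col - 1 + stats::runif(n)) * cs,
        spec$origin_y - (row - 1 + stats::runif(n)) * cs)
}

# clustered (Neyman-Scott style) point process clipped to the grid
# interior; cluster centres drawn with probability proportional to
# `intensity` (e.g. an urban-core field) when supplied. A fraction of the
# points is scattered city-wide so facilities exist everywhere, with
# density peaking where the intensity does — the way urban POI layers look.
cluster_points <- function(n_pts, n_clusters, spec, scatter_m,
                           intensity = NULL, background_frac = 0.3) {
  w <- spec$n_cols * spec$cell_size; h <- spec$n_rows * spec$cell_size
  if (is.null(intensity)) {
    cx <- spec$origin_x + stats::runif(n_clusters, 0.05, 0.95) * w
    cy <- spec$origin_y - stats::runif(n_clusters, 0.05, 0.95) * h
    n_bg <- 0L
  } else {
    ctrs <- weighted_cell_points(n_clusters, spec, intensity)
    cx <- ctrs[, 1]; cy <- ctrs[, 2]
    n_bg <- round(background_frac * n_pts)
  }
  n_cl <- n_pts - n_bg
  idx <- sample.int(n_clusters, n_cl, replace = TRUE)
  px <- stats::rnorm(n_cl, cx[idx], scatter_m)
  py <- stats::rnorm(n_cl, cy[idx], scatter_m)
  if (n_bg > 0) {
    px <- c(px, spec$origin_x + stats::runif(n_bg) * w)
    py <- c(py, spec$origin_y - stats::runif(n_bg) * h)
  }
  eps <- spec$cell_size / 100
  px <- pmin(pmax(px, spec$origin_x + eps), spec$origin_x + w - eps)
  py <- pmin(pmax(py, spec$origin_y - h + eps), spec$origin_y - eps)
  cbind(px, py)
}

# jittered regular station layout covering the grid interior
quasi_uniform_points <- function(n, spec, jitter_frac = 0.3) {
  w <- spec$n_cols * spec$cell_size; h <- spec$n_rows * spec$cell_size
  nx <- ceiling(sqrt(n * w / h)); ny <- ceiling(n / nx)
  gx <- (seq_len(nx) - 0.5) / nx; gy <- (seq_len(ny) - 0.5) / ny
  pts <- expand.grid(gx = gx, gy = gy)[seq_len(n), ]
  sx <- w / nx; sy <- h / ny
  px <- spec$origin_x + pts$gx * w + stats::rnorm(n, 0, jitter_frac * sx)
  py <- spec$origin_y - pts$gy * h - stats::rnorm(n, 0, jitter_frac * sy)
  eps <- spec$cell_size / 100
  px <- pmin(pmax(px, spec$origin_x + eps), spec$origin_x + w - eps)
  py <- pmin(pmax(py, spec$origin_y - h + eps), spec$origin_y - eps)
  # edge clamping can collapse two points onto one spot; nudge duplicates
  for (tries in 1:20) {
    dup <- duplicated(cbind(px, py))
    if (!any(dup)) break
    px[dup] <- pmin(pmax(px[dup] + stats::rnorm(sum(dup), 0, sx / 4),
                         spec$origin_x + eps), spec$origin_x + w - eps)
    py[dup] <- pmin(pmax(py[dup] + stats::rnorm(sum(dup), 0, sy / 4),
                         spec$origin_y - h + eps), spec$origin_y - eps)
  }
  cbind(px, py)
}

# random-walk road polylines; with an intensity field supplied, road
# starts are drawn from it and each step prefers the direction with the
# higher intensity, so the network concentrates where the city is dense
random_roads <- function(n_roads, spec, n_seg = 25, step_m = 1500,
                         intensity = NULL) {
  w <- spec$n_cols * spec$cell_size; h <- spec$n_rows * spec$cell_size
  eps <- spec$cell_size / 100
  starts <- if (is.null(intensity)) NULL
            else weighted_cell_points(n_roads, spec, intensity)
  ifield <- if (is.null(intensity)) NULL
            else raster_layer(spec, as.matrix(intensity))
  clamp <- function(x, y) {
    c(pmin(pmax(x, spec$origin_x + eps), spec$origin_x + w - eps),
      pmin(pmax(y, spec$origin_y - h + eps), spec$origin_y - eps))
  }
  lapply(seq_len(n_roads), function(i) {
    if (is.null(starts)) {
      x <- spec$origin_x + stats::runif(1, 0.05, 0.95) * w
      y <- spec$origin_y - stats::runif(1, 0.05, 0.95) * h
    } else {
      x <- starts[i, 1]; y <- starts[i, 2]
    }
    ang <- stats::runif(1, 0, 2 * pi)
    pts <- matrix(NA_real_, n_seg + 1, 2)
    pts[1, ] <- c(x, y)
    for (s in seq_len(n_seg)) {
      cand_ang <- ang + stats::rnorm(3, 0, 0.5)
      if (!is.null(ifield)) {
        gain <- vapply(cand_ang, function(a) {
          p <- clamp(x + step_m * cos(a), y + step_m * sin(a))
          sample_at(ifield, p[1], p[2])
        }, numeric(1))
        ang <- cand_ang[which.max(gain)]
      } else {
        ang <- cand_ang[1]
      }
      p <- clamp(x + step_m * cos(ang), y + step_m * sin(ang))
      x <- p[1]; y <- p[2]
      pts[s + 1, ] <- c(x, y)
    }
    pts
  })
}

#' Generate a complete synthetic scene
#'
#' Builds every raw input of the interpolation pipeline plus the known
#' ground-truth pollutant surface, fully reproducibly from the config
#' seed. The DEM falls from about 1700 m in the north to 1100 m in the
#' south with smooth hills; POIs are clustered point processes; roads are
#' random polylines; population blocks are square polygons weighted by a
#' smooth density; the truth surface combines the smoothed covariates
#' (hinged for roads and population, negative for green areas and sport
#' fields) with a correlated Gaussian residual; stations sample the truth
#' with additive measurement noise.
#'
#' @param config A [scene_config()].
#' @return A list of class `scene`: `spec`, `dem`, `met` (4 data frames),
#'   `pois` (4 [vector_layer()]s), `roads`, `population`, `truth`
#'   ([raster_layer()]), `stations` (data frame) and `truth_covariates`
#'   (the generator's scaled covariate surfaces, for diagnostics).
#' @export
generate_scene <- function(config = scene_config()) {
  if (!inherits(config, "scene_config")) stop("config must be a scene_config")
  set.seed(config$seed)
  spec <- grid_spec(config$n_rows, config$n_cols, config$cell_size,
                    crs_tag = "LOCAL_METRIC")
  nr <- spec$n_rows; nc <- spec$n_cols; cs <- spec$cell_size
  eff <- config$effects; rad <- config$gen_radii

  # terrain: north-south ramp 1700 -> 1100 plus smooth bumps
  ramp <- matrix(seq(1700, 1100, length.out = nr), nr, nc)
  bumps <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), 3)
  bumps <- bumps / stats::sd(bumps) * 150
  dem <- raster_layer(spec, ramp + bumps - mean(bumps), name = "dem")

  # latent urban-intensity field: the shared driver that makes land-use,
  # traffic, population and (inversely) green-space covariates mutually
  # correlated, the way they are in a real city
  urban <- scale01(gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), 9))

  # vector inputs: activity POIs and roads concentrate where the city is
  # dense; green areas and sport fields where it is not
  pois <- list(
    gas = vector_layer("points", apply_rows(
      cluster_points(90, 18, spec, 2000, intensity = urban^2))),
    petrol = vector_layer("points", apply_rows(
      cluster_points(70, 14, spec, 2000, intensity = urban^2))),
    green = vector_layer("points", apply_rows(
      cluster_points(55, 11, spec, 2500, intensity = (1 - urban)^2))),
    sport = vector_layer("points", apply_rows(
      cluster_points(45, 9, spec, 2500, intensity = (1 - urban)^2))))
  roads <- vector_layer("polylines",
                        random_roads(40, spec, n_seg = 30,
                                     intensity = urban + 0.05))
  pop_density <- urban * scale01(gauss_smooth(
    matrix(stats::rexp(nr * nc), nr, nc), 5))
  blocks <- list(); bw <- numeric(0)
  step <- 4L
  for (r in seq(2L, nr - 2L, by = step)) for (c in seq(2L, nc - 2L, by = step)) {
    x0 <- spec$origin_x + (c - 1) * cs; y0 <- spec$origin_y - (r - 1) * cs
    blocks <- c(blocks, list(rbind(c(x0, y0), c(x0 + 2 * cs, y0),
                                   c(x0 + 2 * cs, y0 - 2 * cs),
                                   c(x0, y0 - 2 * cs))))
    bw <- c(bw, 4000 * (0.05 + pop_density[r, c]) * stats::rlnorm(1, 0, 0.3))
  }
  population <- vector_layer("polygons", blocks, bw)

  # meteorological truth fields (smooth), tied to terrain and the urban
  # heat island, sampled at met stations
  dem01 <- scale01(dem$values)
  met_fields <- list(
    wind_speed = pmax(3 + 3 * dem01 - 2.5 * urban + scale01(gauss_smooth(
      matrix(stats::rnorm(nr * nc), nr, nc), 8)), 0.2),
    temperature = 18 - 6 * dem01 + 3 * urban + scale01(gauss_smooth(
      matrix(stats::rnorm(nr * nc), nr, nc), 8)) * 0.8,
    pressure = 1015 - 8 * dem01 + scale01(gauss_smooth(
      matrix(stats::rnorm(nr * nc), nr, nc), 10)) * 0.5,
    relative_humidity = 35 + 10 * dem01 - 8 * urban + scale01(gauss_smooth(
      matrix(stats::rnorm(nr * nc), nr, nc), 8)) * 4)
  met_xy <- quasi_uniform_points(config$n_met_stations, spec)
  met <- lapply(names(met_fields), function(nm) {
    f <- raster_layer(spec, met_fields[[nm]])
    v <- sample_at(f, met_xy[, 1], met_xy[, 2])
    data.frame(id = paste0("met", seq_len(nrow(met_xy))),
               x = met_xy[, 1], y = met_xy[, 2],
               value = v + stats::rnorm(nrow(met_xy),
                                        0, 0.02 * diff(range(v)) + 1e-9),
               stringsAsFactors = FALSE)
  })
  names(met) <- names(met_fields)

  # truth covariate surfaces at the generator's smoothing radii
  cov_surf <- list(
    gas = scale01(kde_surface(pois$gas, spec, rad$gas)$values),
    petrol = scale01(kde_surface(pois$petrol, spec, rad$petrol)$values),
    green = scale01(kde_surface(pois$green, spec, rad$green)$values),
    sport = scale01(kde_surface(pois$sport, spec, rad$sport)$values),
    population = scale01(kde_surface(population, spec, rad$population)$values),
    road = scale01(kde_surface(roads, spec, rad$road)$values),
    elevation = scale01(focal_mean(dem, rad$focal)$values),
    temperature = scale01(met_fields$temperature),
    wind_speed = scale01(met_fields$wind_speed),
    pressure = scale01(met_fields$pressure),
    relative_humidity = scale01(met_fields$relative_humidity))

  resid <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                        config$spatial_range / cs)
  if (stats::sd(resid) > 0)
    resid <- resid / stats::sd(resid) * config$spatial_sd

  truth_vals <- eff$base +
    eff$road * pmax(0, cov_surf$road - eff$road_hinge) +
    eff$gas * cov_surf$gas +
    eff$petrol * cov_surf$petrol +
    eff$green * cov_surf$green +
    eff$sport * cov_surf$sport +
    eff$population * pmax(0, cov_surf$population - eff$population_hinge) +
    eff$elevation * cov_surf$elevation +
    eff$temperature * cov_surf$temperature +
    eff$wind_speed * cov_surf$wind_speed +
    eff$pressure * cov_surf$pressure +
    eff$relative_humidity * cov_surf$relative_humidity +
    resid
  truth <- raster_layer(spec, truth_vals, name = "no2_truth")

  st_xy <- quasi_uniform_points(config$n_stations, spec)
  stations <- data.frame(
    id = sprintf("st%02d", seq_len(config$n_stations)),
    x = st_xy[, 1], y = st_xy[, 2],
    value = sample_at(truth, st_xy[, 1], st_xy[, 2]) +
      stats::rnorm(config$n_stations, 0, config$noise_sd),
    stringsAsFactors = FALSE)

  structure(
    list(config = config, spec = spec, dem = dem, met = met, pois = pois,
         roads = roads, population = population, truth = truth,
         stations = stations,
         truth_covariates = lapply(cov_surf, function(v)
           raster_layer(spec, v))),
    class = "scene")
}

# split an n x 2 coordinate matrix into a list of 1 x 2 point matrices
apply_rows <- function(m) {
  lapply(seq_len(nrow(m)), function(i) m[i, , drop = FALSE])
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("scene (seed %d): %d x %d grid @ %g m, %d stations\n",
              x$config$seed, x$spec$n_rows, x$spec$n_cols,
              x$spec$cell_size, nrow(x$stations)))
  cat(sprintf("  truth range [%.1f, %.1f], station range [%.1f, %.1f]\n",
              min(x$truth$values), max(x$truth$values),
              min(x$stations$value), max(x$stations$value)))
  invisible(x)
}

#' Pipeline inputs of a scene
#'
#' @param scene A [generate_scene()] scene.
#' @return The input list expected by [build_feature_stack()] and
#'   [pcamars_fit()].
#' @export
scene_inputs <- function(scene) {
  list(stations = scene$stations, met = scene$met, dem = scene$dem,
       pois = scene$pois, roads = scene$roads,
       population = scene$population)
}

#' Write a scene to files
#'
#' Serializes every input layer in the formats the I/O layer reads (ESRI
#' ASCII rasters, CSV points, GeoJSON vectors) and a `manifest.json`
#' listing every file, so a pipeline run from disk reproduces the
#' in-memory run.
#'
#' @param scene A [generate_scene()] scene.
#' @param directory Output directory (created if needed).
#' @return The manifest (a named list of relative file paths), invisibly
#'   written to `manifest.json`.
#' @export
scene_to_files <- function(scene, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(directory, f)
  manifest <- list(
    grid = list(n_rows = scene$spec$n_rows, n_cols = scene$spec$n_cols,
                cell_size = scene$spec$cell_size,
                origin_x = scene$spec$origin_x,
                origin_y = scene$spec$origin_y),
    stations = "stations.csv", dem = "dem.asc", truth = "truth.asc",
    met = list(wind_speed = "met_wind_speed.csv",
               temperature = "met_temperature.csv",
               pressure = "met_pressure.csv",
               relative_humidity = "met_relative_humidity.csv"),
    pois = list(gas = "poi_gas.geojson", petrol = "poi_petrol.geojson",
                green = "poi_green.geojson", sport = "poi_sport.geojson"),
    roads = "roads.geojson", population = "population.geojson")
  write_points(scene$stations, p(manifest$stations))
  write_raster(scene$dem, p(manifest$dem))
  write_raster(scene$truth, p(manifest$truth))
  for (nm in names(manifest$met))
    write_points(scene$met[[nm]], p(manifest$met[[nm]]))
  for (nm in names(manifest$pois))
    write_vector(scene$pois[[nm]], p(manifest$pois[[nm]]))
  write_vector(scene$roads, p(manifest$roads))
  write_vector(scene$population, p(manifest$population))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Read pipeline inputs from a scene directory
#'
#' @param directory Directory written by [scene_to_files()] (must contain
#'   `manifest.json`).
#' @return A list with `inputs` (for [pcamars_fit()]), `spec` and, when
#'   present, `truth`.
#' @export
read_scene_files <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", directory)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  p <- function(f) {
    path <- file.path(directory, f)
    if (!file.exists(path)) stop("missing input file listed in manifest: ", f)
    path
  }
  g <- manifest$grid
  spec <- grid_spec(g$n_rows, g$n_cols, g$cell_size, g$origin_x, g$origin_y)
  inputs <- list(
    stations = read_points(p(manifest$stations)),
    met = lapply(manifest$met, function(f) read_points(p(f))),
    dem = read_raster(p(manifest$dem)),
    pois = lapply(manifest$pois, function(f) read_vector(p(f))),
    roads = read_vector(p(manifest$roads)),
    population = read_vector(p(manifest$population)))
  truth <- if (!is.null(manifest$truth) &&
               file.exists(file.path(directory, manifest$truth)))
    read_raster(file.path(directory, manifest$truth)) else NULL
  list(inputs = inputs, spec = spec, truth = truth)
}
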