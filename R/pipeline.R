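#' Fit the full covariate-PCA-spline interpolation pipeline
#'
#' End-to-end fit: builds the normalized 14-covariate stack (with
#' Moran's-I-selected radii and LOOCV-selected IDW powers), fits PCA on all
#' valid grid pixels, keeps the leading components (default 3), projects
#' the station feature vectors into component space and fits the MARS model
#' on the station values there.
#'
#' @param inputs Input list as for [build_feature_stack()] (see
#'   [scene_inputs()] for the synthetic case).
#' @param spec Target [grid_spec()].
#' @param config Optional list: `pca_k` (components kept, default 3),
#'   `radii`, `idw_powers` (feature-engineering candidates), `mars` (list
#'   with `max_terms`, `max_degree`, `penalty` for [fit_mars()]).
#' @return An object of class `pcamars_fit` with elements `stack`, `pca`,
#'   `model`, `spec`, `stations` and `config`.
#' @export
pcamars_fit <- function(inputs, spec, config = list()) {
  if (nrow(inputs$stations) < 4L) stop("need at least 4 stations")
  cand <- feature_candidates(inputs, spec, config)
  refit_pcamars(cand, config)
}

# fit from precomputed feature candidates (shared by LOOCV folds)
refit_pcamars <- function(cand, config = list(), dep_values = NULL,
                          station_idx = NULL, stack = NULL, pca = NULL) {
  if (is.null(station_idx)) station_idx <- seq_len(nrow(cand$stations))
  st <- cand$stations[station_idx, , drop = FALSE]
  if (!is.null(dep_values)) st$value <- dep_values
  if (is.null(stack))
    stack <- assemble_stack(cand, st$value, station_idx)
  if (is.null(pca)) {
    pca <- fit_pca(stack_pixel_matrix(stack))
    pca <- select_components(pca, k = config$pca_k %||% 3)
  }
  feats <- stack_feature_vectors(stack, st$x, st$y)
  if (any(!is.finite(feats)))
    stop("stations fall on nodata pixels of the covariate stack")
  scores <- pca_scores(pca, feats)
  mc <- config$mars %||% list()
  model <- fit_mars(scores, st$value,
                    max_terms = mc$max_terms %||% NULL,
                    max_degree = mc$max_degree %||% 2,
                    penalty = mc$penalty %||% 3,
                    endspan = mc$endspan %||% NULL,
                    minspan = mc$minspan %||% "auto")
  structure(list(stack = stack, pca = pca, model = model,
                 spec = cand$spec, stations = st, config = config),
            class = "pcamars_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pcamars_fit <- function(x, ...) {
  cat("pcamars_fit\n")
  cat(sprintf("  PCA: keeping %d of %d components (%.1f%% of variance)\n",
              x$pca$n_keep, length(x$pca$eigenvalues),
              100 * sum(x$pca$explained_ratio[seq_len(x$pca$n_keep)])))
  print(x$model)
  invisible(x)
}

#' Predict pollutant values at point locations
#'
#' @param object A [pcamars_fit()].
#' @param x,y Projected coordinates inside the grid.
#' @param clamp Truncate predictions to the range of the training
#'   concentrations (default `TRUE`). Hinge models extrapolate linearly
#'   (or, for interactions, quadratically) outside the training hull, and
#'   concentrations outside the observed station range are not physically
#'   credible; truncation to the observed range is the usual convention in
#'   exposure mapping.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.pcamars_fit <- function(object, x, y, clamp = TRUE, ...) {
  feats <- stack_feature_vectors(object$stack, x, y)
  p <- predict(object$model, pca_scores(object$pca, feats))
  if (clamp) p <- pmin(pmax(p, min(object$stations$value)),
                       max(object$stations$value))
  p
}

#' Evaluate the fitted pipeline at every grid pixel
#'
#' @param fit A [pcamars_fit()].
#' @param name Output layer name.
#' @param clamp Truncate the map to the training concentration range (see
#'   [predict.pcamars_fit()]).
#' @return A [raster_layer()] of predictions; pixels where any covariate is
#'   nodata stay nodata.
#' @export
predict_map <- function(fit, name = "no2_pred", clamp = TRUE) {
  X <- stack_pixel_matrix(fit$stack)
  pred <- predict(fit$model, pca_scores(fit$pca, X))
  if (clamp) pred <- pmin(pmax(pred, min(fit$stations$value)),
                          max(fit$stations$value))
  vals <- rep(NA_real_, fit$spec$n_rows * fit$spec$n_cols)
  vals[attr(X, "cell_index")] <- pred
  raster_layer(fit$spec, matrix(vals, fit$spec$n_rows, fit$spec$n_cols),
               name = name)
}

# LOOCV fit/predict closures for the reference methods and the pipeline
make_method <- function(method, scene, config = list()) {
  switch(
    method,
    idw = function(train, test) {
      p <- select_idw_power(train, config$idw_powers %||% c(1, 2, 3))
      idw_predict(train, test$x, test$y, p)
    },
    ok = function(train, test) {
      vario <- fit_spherical(empirical_semivariogram(train))
      ok_predict(train, vario, test$x, test$y)
    },
    mars3 = {
      dem <- resample_to(scene$dem, scene$spec)
      mc <- config$mars %||% list()
      function(train, test) {
        f <- fit_mars3(train, dem, max_terms = mc$max_terms %||% NULL,
                       max_degree = mc$max_degree %||% 2,
                       penalty = mc$penalty %||% 3)
        predict(f, test$x, test$y)
      }
    },
    pcamars = {
      cand <- feature_candidates(scene_inputs(scene), scene$spec, config)
      frozen <- isTRUE(config$freeze_radii)
      fr_stack <- if (frozen) assemble_stack(cand) else NULL
      fr_pca <- if (frozen) {
        select_components(fit_pca(stack_pixel_matrix(fr_stack)),
                          k = config$pca_k %||% 3)
      } else NULL
      all_idx <- seq_len(nrow(scene$stations))
      function(train, test) {
        idx <- match(train$id, scene$stations$id)
        fit <- refit_pcamars(cand, config, dep_values = train$value,
                             station_idx = idx,
                             stack = fr_stack, pca = fr_pca)
        predict(fit, test$x, test$y)
      }
    },
    stop("unknown method: ", method))
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

resolve_inputs <- function(config) {
  if (!is.null(config$scene_dir)) {
    sc <- read_scene_files(config$scene_dir)
    return(list(inputs = sc$inputs, spec = sc$spec))
  }
  if (is.null(config$inputs)) stop("config must name inputs or a scene_dir")
  ip <- config$inputs
  inputs <- list(
    stations = read_points(ip$stations),
    met = lapply(ip$met, read_points),
    dem = read_raster(ip$dem),
    pois = lapply(ip$pois, read_vector),
    roads = read_vector(ip$roads),
    population = read_vector(ip$population))
  g <- config$grid
  spec <- if (!is.null(g))
    grid_spec(g$n_rows, g$n_cols, g$cell_size %||% 500,
              g$origin_x %||% 0, g$origin_y %||% (g$n_rows * (g$cell_size %||% 500)))
  else inputs$dem$spec
  list(inputs = inputs, spec = spec)
}

#' Run the full interpolation pipeline from a configuration
#'
#' Orchestrates featurize, PCA, spline fit and full-grid prediction. The
#' configuration (a list or a YAML file) names the input files (or a
#' `scene_dir` written by [scene_to_files()]), the grid, and the model
#' parameters; when `output_dir` is set the prediction map, serialized
#' models and provenance are written there (`map.asc`, `mars_model.json`,
#' `pca.json`, `provenance.json`). Identical configuration yields
#' byte-identical outputs.
#'
#' @param config List or YAML path; see [pcamars_fit()] for the model keys.
#' @param quiet Suppress progress messages.
#' @return A list with `map` ([raster_layer()]), `fit` ([pcamars_fit()])
#'   and `output_dir` (or `NULL`).
#' @export
run_pcamars <- function(config, quiet = FALSE) {
  config <- read_pipeline_config(config)
  say <- function(...) if (!quiet) message(...)
  rs <- resolve_inputs(config)
  say("featurize: building 14-layer covariate stack")
  fit <- pcamars_fit(rs$inputs, rs$spec, config)
  say("  radii (m): ",
      paste(names(fit$stack$provenance$radii),
            unlist(fit$stack$provenance$radii), sep = "=", collapse = ", "))
  say(sprintf("pca: %d components keep %.1f%% of variance",
              fit$pca$n_keep,
              100 * sum(fit$pca$explained_ratio[seq_len(fit$pca$n_keep)])))
  say(sprintf("mars: %d basis function(s), GCV %.4g",
              length(fit$model$basis), fit$model$gcv))
  map <- predict_map(fit)
  out <- config$output_dir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_raster(map, file.path(out, "map.asc"))
    write_mars(fit$model, file.path(out, "mars_model.json"))
    write_pca(fit$pca, file.path(out, "pca.json"))
    write_stack_provenance(fit$stack, file.path(out, "provenance.json"))
    say("outputs written to ", out)
  }
  list(map = map, fit = fit, output_dir = out)
}

#' Cross-validate interpolation methods from a configuration
#'
#' Builds (or loads) the scene and runs [compare_methods()]; with
#' `output_dir` set the comparison table is written as
#' `crossval.csv` and per-fold predictions as `crossval_folds.csv`.
#'
#' @param config List or YAML path. For synthetic runs, `scene` holds
#'   [scene_config()] fields (e.g. `seed`); otherwise inputs are resolved
#'   as in [run_pcamars()].
#' @param methods Methods passed to [compare_methods()].
#' @return The comparison table (see [compare_methods()]).
#' @export
run_crossval <- function(config,
                         methods = c("idw", "ok", "mars3", "pcamars")) {
  config <- read_pipeline_config(config)
  scene <- if (!is.null(config$scene)) {
    generate_scene(do.call(scene_config, config$scene))
  } else {
    rs <- resolve_inputs(config)
    # wrap file inputs in a scene-shaped list for compare_methods
    structure(list(config = NULL, spec = rs$spec, dem = rs$inputs$dem,
                   met = rs$inputs$met, pois = rs$inputs$pois,
                   roads = rs$inputs$roads,
                   population = rs$inputs$population,
                   stations = rs$inputs$stations, truth = NULL),
              class = "scene")
  }
  tab <- compare_methods(scene, methods, config)
  out <- config$output_dir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out, "crossval.csv"), row.names = FALSE)
    folds <- do.call(rbind, lapply(attr(tab, "cv"), as.data.frame))
    utils::write.csv(folds, file.path(out, "crossval_folds.csv"),
                     row.names = FALSE)
  }
  tab
}
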