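#' Root-mean-square error
#'
#' `sqrt(mean((obs - pred)^2))`.
#'
#' @param obs,pred Equal-length numeric vectors.
#' @return A single non-negative number.
#' @export
rmse <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred lengths differ")
  if (length(obs) == 0L) stop("need at least one pair")
  sqrt(mean((obs - pred)^2))
}

#' Leave-one-out cross-validation of a spatial predictor
#'
#' For each station, removes it from the data, calls `fit_predict` on the
#' remaining stations to predict at the held-out location, and scores the
#' collected predictions by RMSE.
#'
#' @param fit_predict Function `(train, test) -> numeric(1)` where `train`
#'   is the data frame of remaining stations and `test` the held-out row.
#' @param stations Data frame with columns `x`, `y`, `value` (>= 3 rows;
#'   an `id` column is carried through if present).
#' @param method Label stored on the result.
#' @return An object of class `cv_result`: per-station `obs`/`pred` and the
#'   overall `rmse`.
#' @export
loocv <- function(fit_predict, stations, method = "method") {
  n <- nrow(stations)
  if (n < 3L) stop("LOOCV needs at least 3 stations")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    p <- tryCatch(
      fit_predict(stations[-i, , drop = FALSE],
                  stations[i, , drop = FALSE]),
      error = function(e) stop("LOOCV fold ", i, " failed: ",
                               conditionMessage(e), call. = FALSE))
    if (length(p) != 1L || !is.finite(p))
      stop("LOOCV fold ", i, " returned a non-finite or non-scalar prediction")
    pred[i] <- p
  }
  structure(
    list(method = method,
         id = if ("id" %in% names(stations)) stations$id else
           as.character(seq_len(n)),
         obs = stations$value, pred = pred,
         rmse = rmse(stations$value, pred)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s]: %d folds, RMSE = %.4f\n",
              x$method, length(x$obs), x$rmse))
  invisible(x)
}

#' @export
as.data.frame.cv_result <- function(x, ...) {
  data.frame(method = x$method, id = x$id, obs = x$obs, pred = x$pred,
             stringsAsFactors = FALSE)
}

#' Compare interpolation methods by LOOCV on one scene
#'
#' Runs leave-one-out cross-validation for each requested method on a
#' synthetic scene and tabulates the RMSEs (ascending). Methods that fail
#' are reported as `NA` with a warning rather than aborting the table.
#'
#' @param scene A [generate_scene()] scene.
#' @param methods Character subset of `"idw"`, `"ok"`, `"mars3"`,
#'   `"pcamars"`, or a named list of custom `(train, test) -> numeric(1)`
#'   functions (e.g. externally computed predictors).
#' @param config Pipeline configuration passed to the PCAMARS method (see
#'   [pcamars_fit()]); `config$freeze_radii = TRUE` selects the Moran radii
#'   once on the full data instead of per fold.
#' @return A data frame with columns `method` and `rmse`, sorted ascending;
#'   the per-fold `cv_result`s are attached as the `"cv"` attribute.
#' @export
compare_methods <- function(scene,
                            methods = c("idw", "ok", "mars3", "pcamars"),
                            config = list()) {
  if (is.character(methods)) {
    fns <- lapply(methods, function(m) make_method(m, scene, config))
    names(fns) <- methods
  } else {
    fns <- methods
    if (is.null(names(fns)) || any(!nzchar(names(fns))))
      stop("custom methods must be a named list")
  }
  cvs <- list()
  out <- data.frame(method = names(fns), rmse = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(fns)) {
    cv <- tryCatch(loocv(fns[[i]], scene$stations, method = names(fns)[i]),
                   error = function(e) {
                     warning("method '", names(fns)[i], "' failed: ",
                             conditionMessage(e))
                     NULL
                   })
    if (!is.null(cv)) {
      out$rmse[i] <- cv$rmse
      cvs[[names(fns)[i]]] <- cv
    }
  }
  out <- out[order(out$rmse), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cv") <- cvs
  out
}
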