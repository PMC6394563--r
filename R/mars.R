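#' Hinge term of a MARS basis function
#'
#' `sign = +1` encodes `max(0, x[var] - knot)`; `sign = -1` encodes
#' `max(0, knot - x[var])`.
#'
#' @param var 1-based predictor index.
#' @param sign `+1` or `-1`.
#' @param knot Breakpoint on the predictor's scale.
#' @return A list describing the hinge.
#' @export
hinge_term <- function(var, sign, knot) {
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  if (var < 1) stop("var must be a positive index")
  list(var = as.integer(var), sign = as.numeric(sign), knot = as.numeric(knot))
}

#' Evaluate a MARS basis function
#'
#' A basis function is a product of hinge terms over distinct predictors;
#' the empty product is the constant 1.
#'
#' @param terms List of [hinge_term()]s (possibly empty).
#' @param X Numeric matrix (rows = observations) or a single numeric vector
#'   of predictor values.
#' @return Numeric vector of non-negative basis values.
#' @export
eval_basis <- function(terms, X) {
  X <- rbind(X)
  out <- rep(1, nrow(X))
  for (tm in terms) {
    if (tm$var > ncol(X))
      stop("basis refers to predictor ", tm$var, " but X has only ",
           ncol(X), " columns")
    out <- out * pmax(0, tm$sign * (X[, tm$var] - tm$knot))
  }
  out
}

# design matrix: intercept column followed by one column per basis function
basis_matrix <- function(basis, X) {
  X <- rbind(X)
  cols <- c(list(rep(1, nrow(X))),
            lapply(basis, function(b) eval_basis(b$terms, X)))
  do.call(cbind, cols)
}

# least squares with pivoted QR; aliased columns get coefficient 0 so the
# fitted values equal the projection onto the retained columns
ls_fit <- function(B, y) {
  qrB <- qr(B)
  coef <- qr.coef(qrB, y)
  coef[is.na(coef)] <- 0
  fitted <- drop(B %*% coef)
  list(coef = coef, fitted = fitted, sse = sum((y - fitted)^2))
}

#' Generalized cross-validation score
#'
#' `GCV = (SSE / n) / (1 - (m + d (m - 1) / 2) / n)^2`, where `m` counts
#' the model terms including the intercept and `d` is the per-knot
#' complexity penalty. When the effective number of parameters reaches `n`
#' the score is `Inf` (infinite-complexity signal). With `m = 1` the
#' penalty term vanishes and the score is independent of `d`.
#'
#' @param sse Training sum of squared errors.
#' @param n Number of training observations.
#' @param m Number of model terms including the intercept (`m >= 1`).
#' @param d Penalty per basis function (default 3, the usual choice for
#'   models with interactions).
#' @return The GCV score (non-negative, possibly `Inf`).
#' @export
gcv_score <- function(sse, n, m, d = 3) {
  stopifnot(n > 0, m >= 1, sse >= 0)
  denom <- 1 - (m + d * (m - 1) / 2) / n
  if (denom <= 0) return(Inf)
  (sse / n) / denom^2
}

#' MARS forward pass: greedy hinge-pair addition
#'
#' Starting from the intercept-only model, repeatedly considers every
#' existing basis function (of degree below `max_degree`) as a parent,
#' every predictor not already in it, and every distinct observed value of
#' that predictor as a candidate knot; tentatively adds the reflected hinge
#' pair (parent times `max(0, x - t)` and parent times `max(0, t - x)`),
#' refits all coefficients by least squares, and commits the addition with
#' the smallest resulting SSE. Ties are broken toward the earlier parent,
#' earlier predictor index and smaller knot. The search stops at
#' `max_terms` model terms or when the relative SSE improvement falls below
#' `1e-6`. The returned model is typically over-fit and meant to be pruned
#' by [backward_pass()].
#'
#' @param X Numeric predictor matrix (n x p).
#' @param y Numeric response vector.
#' @param max_terms Maximum number of model terms including the intercept
#'   (default `min(21, n - 1)`, which keeps the design overdetermined at
#'   the 21-station scale of the NO2 pipeline).
#' @param max_degree Maximum number of interacting hinges per basis
#'   function (default 2).
#' @param penalty GCV penalty `d` recorded on the model (default 3).
#' @param endspan Minimum number of observations required strictly on each
#'   side of a candidate knot, counted within the region where the parent
#'   basis function is active (Friedman's endspan protection against
#'   near-boundary hinges supported by one or two points, whose
#'   coefficients explode and extrapolate wildly). Default is Friedman's
#'   `floor(3 - log2(alpha / p))` with `alpha = 0.05`, capped at
#'   `(n - 1) / 3` so tiny samples keep some candidates.
#' @param minspan Minimum number of observations strictly between a
#'   candidate knot and any knot already placed on the same variable
#'   (Friedman's minspan protection against near-duplicate hinges whose
#'   almost-collinear columns take huge cancelling coefficients). `0`
#'   (the default) disables it, retaining the engine's ability to
#'   interpolate exactly; `"auto"` uses Friedman's
#'   `floor(-log2(-log(1 - alpha) / (p n)) / 2.5)`, the setting the
#'   interpolation pipeline adopts for its small-sample fits.
#' @return An object of class `mars_model`.
#' @export
forward_pass <- function(X, y, max_terms = NULL, max_degree = 2,
                         penalty = 3, endspan = NULL, minspan = 0) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (is.null(max_terms)) max_terms <- min(21L, n - 1L)
  if (max_terms < 2) stop("max_terms must be at least 2")
  if (max_degree < 1) stop("max_degree must be at least 1")
  if (is.null(endspan))
    endspan <- max(1L, min(floor(3 - log2(0.05 / p)),
                           floor((n - 1) / 3)))
  if (identical(minspan, "auto"))
    minspan <- max(1L, floor(-log2(-log(0.95) / (p * n)) / 2.5))

  basis <- list()
  fit <- ls_fit(matrix(1, n, 1), y)
  sse_cur <- fit$sse
  r <- y - fit$fitted
  # candidate knots for splitting on `xv` within the region where the
  # parent basis function is active: endspan active observations are
  # required strictly on each side, so no hinge (or hinge product) ends up
  # supported by just one or two points
  # The active-region minimum is always a candidate: its upward hinge is
  # linear over the whole region (supported by every active point, mirror
  # identically zero), so plain linear structure costs a single term.
  candidate_knots <- function(xv, active) {
    xa <- xv[active]
    ks <- sort(unique(xa))
    if (length(ks) < 2L) return(numeric(0))
    n_lt <- vapply(ks, function(t) sum(xa < t), numeric(1))
    n_gt <- vapply(ks, function(t) sum(xa > t), numeric(1))
    union(ks[1], ks[n_lt >= endspan & n_gt >= endspan])
  }

  while (length(basis) + 1L < max_terms && sse_cur > 0) {
    B <- basis_matrix(basis, X)
    qrB <- qr(B)
    Q <- qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE]
    best <- NULL
    best_dec <- 1e-12 * max(sse_cur, 1)

    parent_vals <- cbind(rep(1, n),
                         if (length(basis))
                           B[, -1, drop = FALSE] else NULL)
    for (parent in 0:length(basis)) {
      pterms <- if (parent == 0) list() else basis[[parent]]$terms
      if (length(pterms) >= max_degree) next
      pvals <- parent_vals[, parent + 1L]
      if (all(pvals == 0)) next
      pvars <- vapply(pterms, `[[`, integer(1), "var")
      active <- pvals != 0
      used_knots <- lapply(seq_len(p), function(v)
        unlist(lapply(basis, function(b) {
          ks <- vapply(b$terms, function(tm)
            if (tm$var == v) tm$knot else NA_real_, numeric(1))
          ks[!is.na(ks)]
        })))
      for (v in setdiff(seq_len(p), pvars)) {
        xv <- X[, v]
        knots <- candidate_knots(xv, active)
        if (minspan > 0 && length(used_knots[[v]]) && length(knots)) {
          ok <- vapply(knots, function(t) {
            all(vapply(used_knots[[v]], function(t2)
              sum(xv > min(t, t2) & xv < max(t, t2)) >= minspan,
              logical(1)))
          }, logical(1))
          knots <- knots[ok]
        }
        if (!length(knots)) next  # constant or too-thin column: skipped
        A1 <- pvals * pmax(outer(xv, knots, "-"), 0)
        A2 <- pvals * pmax(-outer(xv, knots, "-"), 0)
        W1 <- A1 - Q %*% crossprod(Q, A1)
        W2 <- A2 - Q %*% crossprod(Q, A2)
        n1 <- colSums(W1^2); n2 <- colSums(W2^2)
        b1 <- drop(crossprod(W1, r)); b2 <- drop(crossprod(W2, r))
        ok1 <- n1 > 1e-10 * (colSums(A1^2) + 1e-300)
        ok2 <- n2 > 1e-10 * (colSums(A2^2) + 1e-300)
        g12 <- colSums(W1 * W2)
        det2 <- n1 * n2 - g12^2
        both <- ok1 & ok2 & det2 > 1e-10 * n1 * n2
        dec <- numeric(length(knots))
        dec[both] <- (n2[both] * b1[both]^2 - 2 * g12[both] * b1[both] *
                        b2[both] + n1[both] * b2[both]^2) / det2[both]
        single <- !both
        d1 <- ifelse(ok1, b1^2 / pmax(n1, 1e-300), 0)
        d2 <- ifelse(ok2, b2^2 / pmax(n2, 1e-300), 0)
        dec[single] <- pmax(d1[single], d2[single])
        j <- which.max(dec)
        if (length(j) && dec[j] > best_dec) {
          best_dec <- dec[j]
          best <- list(parent = parent, var = v, knot = knots[j],
                       add1 = ok1[j], add2 = ok2[j])
        }
      }
    }
    if (is.null(best)) break

    pterms <- if (best$parent == 0) list() else basis[[best$parent]]$terms
    new_bfs <- list()
    if (best$add1)
      new_bfs <- c(new_bfs, list(list(
        terms = c(pterms, list(hinge_term(best$var, 1, best$knot))))))
    if (best$add2)
      new_bfs <- c(new_bfs, list(list(
        terms = c(pterms, list(hinge_term(best$var, -1, best$knot))))))
    if (length(basis) + 1L + length(new_bfs) > max_terms)
      new_bfs <- new_bfs[seq_len(max_terms - length(basis) - 1L)]
    if (!length(new_bfs)) break
    cand_basis <- c(basis, new_bfs)
    fit <- ls_fit(basis_matrix(cand_basis, X), y)
    if ((sse_cur - fit$sse) / max(sse_cur, 1e-300) < 1e-6) break
    basis <- cand_basis
    sse_cur <- fit$sse
    r <- y - fit$fitted
  }

  fit <- ls_fit(basis_matrix(basis, X), y)
  new_mars_model(basis, fit, y, penalty = penalty,
                 max_terms = max_terms, max_degree = max_degree)
}

new_mars_model <- function(basis, fit, y, penalty, max_terms, max_degree) {
  n <- length(y)
  m <- length(basis) + 1L
  structure(
    list(intercept = unname(fit$coef[1]),
         coefficients = unname(fit$coef[-1]),
         basis = basis,
         sse = fit$sse,
         gcv = gcv_score(fit$sse, n, m, penalty),
         penalty = penalty,
         n_train = n,
         max_terms = max_terms,
         max_degree = max_degree),
    class = "mars_model")
}

#' MARS backward pass: GCV pruning
#'
#' Starting from a forward-pass model, iteratively deletes the basis
#' function whose removal yields the minimum increase in training SSE
#' (refitting all coefficients after each deletion), producing the nested
#' model sequence down to the intercept-only model, and returns the member
#' of the sequence (including the unpruned input) with the lowest GCV.
#' Reflected pairs added together by the forward pass are pruned
#' independently here.
#'
#' @param model A `mars_model` from [forward_pass()].
#' @param X,y The training data the model was fitted on.
#' @return The GCV-optimal `mars_model`.
#' @export
backward_pass <- function(model, X, y) {
  X <- as.matrix(X)
  n <- length(y)
  basis <- model$basis
  best <- model
  while (length(basis) > 0) {
    sses <- vapply(seq_along(basis), function(j) {
      ls_fit(basis_matrix(basis[-j], X), y)$sse
    }, numeric(1))
    j <- which.min(sses)
    basis <- basis[-j]
    fit <- ls_fit(basis_matrix(basis, X), y)
    cand <- new_mars_model(basis, fit, y, penalty = model$penalty,
                           max_terms = model$max_terms,
                           max_degree = model$max_degree)
    if (cand$gcv < best$gcv) best <- cand
  }
  best
}

#' Fit a MARS model
#'
#' Forward hinge-pair search minimizing SSE followed by backward GCV
#' pruning. The fit is fully deterministic: identical data and settings
#' always produce identical models.
#'
#' @inheritParams forward_pass
#' @return The pruned `mars_model`.
#' @export
fit_mars <- function(X, y, max_terms = NULL, max_degree = 2, penalty = 3,
                     endspan = NULL, minspan = 0) {
  fwd <- forward_pass(X, y, max_terms = max_terms, max_degree = max_degree,
                      penalty = penalty, endspan = endspan,
                      minspan = minspan)
  backward_pass(fwd, X, y)
}

#' Construct a MARS model from explicit terms
#'
#' Instantiates a model directly from an intercept, coefficients and basis
#' functions — e.g. to evaluate a model published elsewhere or reloaded
#' from JSON.
#'
#' @param intercept Model intercept.
#' @param coefficients Coefficient per basis function.
#' @param basis List of basis functions, each a list with a `terms` element
#'   holding [hinge_term()]s.
#' @param penalty GCV penalty recorded on the model.
#' @return A `mars_model` (with `sse`/`gcv` unset).
#' @export
mars_model <- function(intercept, coefficients, basis, penalty = 3) {
  if (length(coefficients) != length(basis))
    stop("need one coefficient per basis function")
  structure(
    list(intercept = as.numeric(intercept),
         coefficients = as.numeric(coefficients),
         basis = basis, sse = NA_real_, gcv = NA_real_,
         penalty = penalty, n_train = NA_integer_,
         max_terms = NA_integer_, max_degree = NA_integer_),
    class = "mars_model")
}

#' Predict from a MARS model
#'
#' @param object A `mars_model`.
#' @param newdata Numeric predictor matrix (or a single observation
#'   vector).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mars_model <- function(object, newdata, ...) {
  X <- rbind(newdata)
  out <- rep(object$intercept, nrow(X))
  for (i in seq_along(object$basis))
    out <- out + object$coefficients[i] * eval_basis(object$basis[[i]]$terms, X)
  out
}

#' @export
print.mars_model <- function(x, digits = 5, ...) {
  cat(sprintf("mars_model: %d basis function(s) + intercept", length(x$basis)))
  if (is.finite(x$gcv)) cat(sprintf(", GCV = %.4g", x$gcv))
  cat("\n")
  cat(sprintf("  f(x) = %.*g", digits, x$intercept))
  for (i in seq_along(x$basis)) {
    cat(sprintf(" %s %.*g * BF%d", if (x$coefficients[i] < 0) "-" else "+",
                digits, abs(x$coefficients[i]), i))
  }
  cat("\n")
  for (i in seq_along(x$basis)) {
    parts <- vapply(x$basis[[i]]$terms, function(tm) {
      if (tm$sign > 0) sprintf("max(0, x%d - %.*g)", tm$var, digits, tm$knot)
      else sprintf("max(0, %.*g - x%d)", digits, tm$knot, tm$var)
    }, character(1))
    cat(sprintf("  BF%d = %s\n", i, paste(parts, collapse = " * ")))
  }
  invisible(x)
}

#' Serialize a MARS model to JSON
#'
#' @param model A `mars_model`.
#' @param path Output JSON path.
#' @export
write_mars <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = model$coefficients,
         basis = lapply(model$basis, function(b) {
           list(terms = lapply(b$terms, function(tm)
             list(var = tm$var, sign = tm$sign, knot = tm$knot)))
         }),
         penalty = model$penalty, sse = model$sse, gcv = model$gcv,
         n_train = model$n_train),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Load a MARS model from JSON
#'
#' Re-instantiates a model written by [write_mars()] (or authored by hand
#' in the same structure).
#'
#' @param path JSON path.
#' @return A `mars_model`.
#' @export
read_mars <- function(path) {
  j <- jsonlite::read_json(path)
  basis <- lapply(j$basis, function(b) {
    list(terms = lapply(b$terms, function(tm)
      hinge_term(tm$var, tm$sign, tm$knot)))
  })
  m <- mars_model(j$intercept, as.numeric(unlist(j$coefficients)), basis,
                  penalty = if (is.null(j$penalty)) 3 else j$penalty)
  if (!is.null(j$sse)) m$sse <- as.numeric(j$sse)
  if (!is.null(j$gcv)) m$gcv <- as.numeric(j$gcv)
  if (!is.null(j$n_train)) m$n_train <- as.integer(j$n_train)
  m
}
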