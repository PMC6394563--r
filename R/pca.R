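#' Fit a principal component transform
#'
#' Eigen-decomposition of the sample covariance matrix of the mean-centred
#' columns of `X`. Eigenvalues are sorted descending (negative rounding
#' noise clamped to zero; zero eigenvalues of rank-deficient input are
#' retained, not dropped) and each eigenvector's sign is fixed so that its
#' largest-magnitude element is positive, making the decomposition fully
#' deterministic.
#'
#' @param X Numeric matrix (rows = observations such as grid pixels,
#'   columns = variables; `n > p`, no missing values).
#' @return An object of class `pca_transform`: `means` (column means), `P`
#'   (p x p orthogonal matrix, rows = eigenvectors), `eigenvalues`,
#'   `explained_ratio` (summing to 1) and `n_keep` (initially `p`).
#' @export
fit_pca <- function(X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be finite")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than variables (n > p)")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (n - 1)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(p)) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  tot <- sum(vals)
  structure(
    list(means = mu, P = t(vecs), eigenvalues = vals,
         explained_ratio = if (tot > 0) vals / tot else rep(0, p),
         n_keep = p,
         var_names = colnames(X)),
    class = "pca_transform")
}

#' @export
print.pca_transform <- function(x, ...) {
  p <- length(x$eigenvalues)
  cat(sprintf("pca_transform: %d variables, keeping %d component(s)\n",
              p, x$n_keep))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_ratio[seq_len(min(p, 5))]),
            collapse = ", "),
      if (p > 5) "...\n" else "\n")
  invisible(x)
}

#' Project data into principal component space
#'
#' Scores are `(X - means) %*% t(P)` truncated to the first `n_keep`
#' components; over the training data the score columns are uncorrelated
#' with variances equal to the eigenvalues.
#'
#' @param t A [fit_pca()] transform.
#' @param X Matrix (or single row) with the training columns in training
#'   order.
#' @param n_keep Optional override of the number of components.
#' @return An `nrow(X)` x `n_keep` score matrix (columns `PC1`, `PC2`, ...).
#' @export
pca_scores <- function(t, X, n_keep = t$n_keep) {
  X <- rbind(X)  # promotes a bare vector to a single-row matrix
  p <- length(t$means)
  if (ncol(X) != p)
    stop("X has ", ncol(X), " columns; transform expects ", p)
  stopifnot(n_keep >= 1, n_keep <= p)
  S <- sweep(X, 2, t$means) %*% t(t$P[seq_len(n_keep), , drop = FALSE])
  colnames(S) <- paste0("PC", seq_len(n_keep))
  S
}

#' Reconstruct data from principal component scores
#'
#' Inverse of [pca_scores()]; exact when all `p` components are kept.
#'
#' @param t A [fit_pca()] transform.
#' @param S Score matrix with `n_keep` columns.
#' @return Matrix in the original variable space.
#' @export
pca_inverse <- function(t, S) {
  S <- rbind(S)
  k <- ncol(S)
  sweep(S %*% t$P[seq_len(k), , drop = FALSE], 2, t$means, "+")
}

#' Choose how many principal components to keep
#'
#' Either a fixed count `k` (the pipeline default is 3 leading components,
#' which typically carry more than 80% of the total variance of the
#' normalized covariate stack) or the smallest count whose cumulative
#' explained-variance ratio reaches `variance_threshold`.
#'
#' @param t A [fit_pca()] transform.
#' @param k Number of components to keep (ignored if `variance_threshold`
#'   is given).
#' @param variance_threshold Fraction of total variance in `(0, 1]`.
#' @return The transform with `n_keep` set.
#' @export
select_components <- function(t, k = 3, variance_threshold = NULL) {
  p <- length(t$eigenvalues)
  if (!is.null(variance_threshold)) {
    if (variance_threshold <= 0 || variance_threshold > 1)
      stop("variance_threshold must be in (0, 1]")
    k <- which(cumsum(t$explained_ratio) >= variance_threshold - 1e-12)[1]
    if (is.na(k)) k <- p
  }
  if (k < 1 || k > p) stop("k must be between 1 and ", p)
  t$n_keep <- as.integer(k)
  t
}

#' Serialize a PCA transform to JSON
#'
#' @param t A [fit_pca()] transform.
#' @param path Output JSON path.
#' @export
write_pca <- function(t, path) {
  jsonlite::write_json(
    list(means = t$means, P = t$P, eigenvalues = t$eigenvalues,
         n_keep = t$n_keep, var_names = t$var_names),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a PCA transform from JSON
#'
#' @param path Path written by [write_pca()].
#' @return A `pca_transform`.
#' @export
read_pca <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- as.numeric(j$eigenvalues)
  tot <- sum(vals)
  structure(
    list(means = as.numeric(j$means), P = as.matrix(j$P),
         eigenvalues = vals,
         explained_ratio = if (tot > 0) vals / tot else rep(0, length(vals)),
         n_keep = as.integer(j$n_keep),
         var_names = j$var_names),
    class = "pca_transform")
}
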