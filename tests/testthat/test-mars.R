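test_that("basis functions evaluate hinge products as printed models do", {
  m <- worked_no2_model()
  # a hinge vanishes exactly at its knot
  expect_identical(eval_basis(m$basis[[1]]$terms, c(-2.3324, 0)), 0)
  # two-hinge interaction at the origin: 0.55517 * 2.8871
  expect_equal(eval_basis(m$basis[[3]]$terms, c(0, 0)), 0.55517 * 2.8871,
               tolerance = 1e-12)
  # the empty product is the constant 1
  expect_equal(eval_basis(list(), c(5, -3)), 1)
  expect_error(eval_basis(list(hinge_term(3, 1, 0)), c(1, 2)), "predictor")
  expect_error(hinge_term(1, 0.5, 0), "sign")
})

test_that("the worked NO2 model reproduces its printed predictions", {
  m <- worked_no2_model()
  # at the point where every hinge argument is non-positive the prediction
  # is the intercept, exactly
  expect_identical(predict(m, c(-2.3324, 0.55517)), 76.358)
  # hand arithmetic over the printed coefficients at the origin
  expect_equal(predict(m, c(0, 0)),
               76.358 - 16.112 * 2.3324 + 32.65 * 0.55517 -
                 8.6937 * (0.55517 * 2.8871), tolerance = 1e-12)
  # intercept-only model predicts its intercept everywhere
  m0 <- mars_model(5, numeric(0), list())
  expect_equal(predict(m0, matrix(rnorm(10), 5, 2)), rep(5, 5))
})

test_that("GCV matches hand arithmetic and degenerates sensibly", {
  expect_equal(gcv_score(2100, 21, 5, 3), 441)
  expect_equal(gcv_score(0, 21, 5, 3), 0)
  expect_equal(gcv_score(0, 10, 2, 1), 0)
  # m = 1: penalty vanishes, d-independent
  for (d in c(0, 1, 3, 10))
    expect_equal(gcv_score(50, 25, 1, d), (50 / 25) / (1 - 1 / 25)^2)
  # effective parameters >= n: infinite-complexity signal
  expect_equal(gcv_score(10, 10, 9, 3), Inf)
  expect_error(gcv_score(-1, 10, 2, 3))
})

test_that("forward pass recovers a single planted hinge exactly", {
  set.seed(1)
  x <- matrix(runif(50), 50, 1)
  y <- pmax(0, x[, 1] - 0.5)
  fwd <- forward_pass(x, y)
  expect_lt(fwd$sse, 1e-10)
  knots <- vapply(fwd$basis, function(b) b$terms[[1]]$knot, numeric(1))
  expect_lt(min(abs(knots - 0.5)), 0.05)
  # backward pruning keeps the exact fit
  m <- backward_pass(fwd, x, y)
  expect_lt(m$sse, 1e-10)
  expect_lt(min(abs(vapply(m$basis, function(b) b$terms[[1]]$knot,
                           numeric(1)) - 0.5)), 0.05)
})

test_that("degenerate responses and designs stay harmless", {
  set.seed(2)
  x <- matrix(runif(60), 30, 2)
  m <- fit_mars(x, rep(4, 30))
  expect_length(m$basis, 0L)            # constant y: intercept-only
  expect_equal(m$intercept, 4)
  # an all-constant column is skipped, not fatal
  x2 <- cbind(x[, 1], 7)
  y2 <- 2 * x2[, 1] + 1
  m2 <- fit_mars(x2, y2)
  expect_gt(1 - m2$sse / sum((y2 - mean(y2))^2), 0.999)
  vars <- unlist(lapply(m2$basis, function(b)
    vapply(b$terms, `[[`, integer(1), "var")))
  expect_true(all(vars == 1L))
})

test_that("a hinge pair reproduces a pure linear trend", {
  set.seed(3)
  x <- matrix(runif(50), 50, 1)
  y <- 3 * x[, 1] + 1
  m <- fit_mars(x, y, max_terms = 5)
  expect_gt(1 - m$sse / sum((y - mean(y))^2), 0.999)
})

test_that("forward SSE descends monotonically and coefficients match the normal equations", {
  set.seed(4)
  n <- 60
  X <- matrix(runif(3 * n), n, 3)
  y <- 10 * pmax(0, X[, 1] - 0.5) + 5 * X[, 2] + rnorm(n, 0, 0.3)
  fwd <- forward_pass(X, y)
  # replay the nested forward sequence: SSE never increases and every
  # refit equals an independent normal-equations oracle
  prev <- sum((y - mean(y))^2)
  for (k in 0:length(fwd$basis)) {
    B <- pcamars:::basis_matrix(fwd$basis[seq_len(k)], X)
    fit <- pcamars:::ls_fit(B, y)
    expect_lte(fit$sse, prev + 1e-8)
    prev <- fit$sse
    if (qr(B)$rank == ncol(B))
      expect_equal(unname(fit$coef), lstsq_oracle(B, y), tolerance = 1e-6)
  }
  # final model coefficients also match the oracle
  m <- backward_pass(fwd, X, y)
  B <- pcamars:::basis_matrix(m$basis, X)
  if (qr(B)$rank == ncol(B))
    expect_equal(unname(c(m$intercept, m$coefficients)),
                 lstsq_oracle(B, y), tolerance = 1e-6)
})

test_that("backward pass prunes noise fits and is a fixed point on optimal models", {
  # pure-noise forward fits collapse to at most 2 basis functions (median)
  sizes <- vapply(1:20, function(s) {
    set.seed(300 + s)
    X <- matrix(runif(100), 50, 2)
    y <- rnorm(50)
    length(fit_mars(X, y)$basis)
  }, numeric(1))
  expect_lte(median(sizes), 2)
  # an already GCV-optimal model is returned unchanged
  set.seed(5)
  x <- matrix(runif(40), 40, 1)
  y <- 4 * pmax(0, x[, 1] - 0.4) + rnorm(40, 0, 0.05)
  m <- fit_mars(x, y)
  again <- backward_pass(m, x, y)
  expect_equal(again$gcv, m$gcv)
  expect_equal(length(again$basis), length(m$basis))
})

test_that("backward deletion sequence is nested and GCV-ordered", {
  set.seed(6)
  X <- matrix(runif(90), 45, 2)
  y <- 6 * pmax(0, X[, 1] - 0.5) - 4 * pmax(0, 0.6 - X[, 2]) + rnorm(45, 0.2)
  fwd <- forward_pass(X, y)
  pruned <- backward_pass(fwd, X, y)
  key <- function(b) paste(vapply(b$terms, function(tm)
    sprintf("%d|%+d|%.12g", tm$var, tm$sign, tm$knot), character(1)),
    collapse = "&")
  expect_true(all(vapply(pruned$basis, key, character(1)) %in%
                    vapply(fwd$basis, key, character(1))))
  expect_lte(pruned$gcv, fwd$gcv)
})

test_that("noisy single-hinge truth survives pruning with its knot intact", {
  knots <- vapply(1:20, function(s) {
    set.seed(500 + s)
    x <- matrix(runif(50), 50, 1)
    y <- pmax(0, x[, 1] - 0.5) + rnorm(50, 0, 0.1)
    m <- fit_mars(x, y)
    ks <- unlist(lapply(m$basis, function(b)
      vapply(b$terms, `[[`, numeric(1), "knot")))
    if (length(ks)) min(abs(ks - 0.5)) else Inf
  }, numeric(1))
  expect_lte(median(knots), 0.1)
})

test_that("fit_mars generalizes on a hinge-plus-linear benchmark", {
  r2 <- vapply(1:10, function(s) {
    set.seed(700 + s)
    X <- matrix(runif(600), 200, 3)
    y <- 10 * pmax(0, X[, 1] - 0.5) + 5 * X[, 2] + rnorm(200, 0, 0.5)
    Xt <- matrix(runif(600), 200, 3)
    yt <- 10 * pmax(0, Xt[, 1] - 0.5) + 5 * Xt[, 2] + rnorm(200, 0, 0.5)
    m <- fit_mars(X, y)
    1 - mean((yt - predict(m, Xt))^2) / var(yt)
  }, numeric(1))
  expect_gt(median(r2), 0.8)
})

test_that("fitting is deterministic and sane at the 21-station scale", {
  set.seed(9)
  X <- matrix(rnorm(63), 21, 3)
  y <- 40 + 8 * X[, 1] - 5 * pmax(0, X[, 2]) + rnorm(21, 0, 2)
  m1 <- fit_mars(X, y)
  m2 <- fit_mars(X, y)
  expect_identical(m1, m2)
  expect_lt(length(m1$basis), 21)
  expect_true(is.finite(m1$gcv))
})

test_that("MARS models serialize to JSON and back verbatim", {
  set.seed(10)
  x <- matrix(runif(60), 30, 2)
  y <- 2 * pmax(0, x[, 1] - 0.4) + rnorm(30, 0, 0.1)
  m <- fit_mars(x, y)
  p <- withr::local_tempfile(fileext = ".json")
  write_mars(m, p)
  m2 <- read_mars(p)
  Xnew <- matrix(runif(20), 10, 2)
  expect_equal(predict(m2, Xnew), predict(m, Xnew), tolerance = 1e-12)
  expect_equal(m2$intercept, m$intercept, tolerance = 1e-15)
})
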