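test_that("empirical semivariogram matches hand arithmetic and counts pairs", {
  cst <- data.frame(x = runif(6, 0, 1000), y = runif(6, 0, 1000),
                    value = rep(3, 6))
  emp <- empirical_semivariogram(cst, 5)
  expect_true(all(emp$gamma == 0))
  # an isolated close pair valued 0 and 2 occupies its own lag bin with
  # semivariance 0.5 * 2^2 / ... = 2
  iso <- data.frame(x = c(0, 600, 10000, 20000), y = 0,
                    value = c(0, 2, 1, 1))
  emp2 <- empirical_semivariogram(iso, 10)
  expect_equal(emp2$gamma[1], 2)
  expect_equal(emp2$n[1], 1)
  # retained pair counts never exceed n(n-1)/2 and match the lag cutoff
  set.seed(2)
  s <- data.frame(x = runif(10, 0, 5000), y = runif(10, 0, 5000),
                  value = rnorm(10))
  emp3 <- empirical_semivariogram(s, 8)
  expect_lte(sum(emp3$n), 45)
  expect_gt(sum(emp3$n), 0)
  expect_error(empirical_semivariogram(s[1:3, ], 5), "at least 4")
  coincident <- data.frame(x = rep(1, 4), y = rep(1, 4), value = 1:4)
  expect_error(empirical_semivariogram(coincident), "coincide")
})

test_that("the spherical model follows its closed form", {
  v <- spherical_variogram(0, 1, 1)
  expect_equal(variogram_value(v, 0.5), 0.6875)  # 1.5*0.5 - 0.5*0.125
  expect_equal(variogram_value(v, 1), 1)
  expect_equal(variogram_value(v, 7), 1)          # sill attained beyond range
  expect_identical(variogram_value(v, 0), 0)      # exactly zero at h = 0
  vn <- spherical_variogram(0.3, 2, 1000)
  expect_equal(variogram_value(vn, 1000), 2.3)
  expect_equal(variogram_value(vn, 1e-9), 0.3, tolerance = 1e-6)
  expect_error(variogram_value(v, -1), "non-negative")
  expect_error(spherical_variogram(-1, 1, 1))
})

test_that("fit_spherical recovers known parameters and respects weights", {
  truth <- spherical_variogram(0.5, 4, 3000)
  lags <- seq(200, 6000, length.out = 12)
  emp <- data.frame(lag = lags, gamma = variogram_value(truth, lags),
                    n = rep(30, 12))
  fit <- fit_spherical(emp)
  expect_equal(fit$nugget, truth$nugget, tolerance = 0.05 * 4.5)
  expect_equal(fit$partial_sill, truth$partial_sill, tolerance = 0.05 * 4)
  expect_equal(fit$range_m, truth$range_m, tolerance = 0.05 * 3000)
  # duplicating every bin (doubling all weights) changes nothing
  fit2 <- fit_spherical(rbind(emp, emp))
  expect_equal(fit2$range_m, fit$range_m, tolerance = 1e-6)
  # flat curve: essentially pure nugget
  flat <- data.frame(lag = lags, gamma = rep(2, 12), n = rep(10, 12))
  expect_lt(fit_spherical(flat)$partial_sill, 0.05)
  expect_error(fit_spherical(emp[1:2, ]), "at least 3")
})

test_that("ordinary kriging satisfies unbiasedness, exactness and a dense-solve oracle", {
  s <- data.frame(x = c(0, 4000, 0, 4000), y = c(0, 0, 4000, 4000),
                  value = c(10, 20, 30, 24))
  v <- spherical_variogram(0, 5, 6000)
  px <- c(1000, 2500, 3300); py <- c(1200, 2500, 700)
  res <- ok_predict(s, v, px, py, return_weights = TRUE)
  expect_equal(colSums(res$weights), rep(1, 3), tolerance = 1e-8)
  # independent dense assembly and solve, point by point
  n <- 4
  d <- as.matrix(dist(s[, c("x", "y")]))
  A <- rbind(cbind(matrix(variogram_value(v, d), n), 1), c(rep(1, n), 0))
  oracle <- vapply(seq_along(px), function(k) {
    d0 <- sqrt((s$x - px[k])^2 + (s$y - py[k])^2)
    sol <- solve(A, c(variogram_value(v, d0), 1))
    sum(sol[1:n] * s$value)
  }, numeric(1))
  expect_equal(res$pred, oracle, tolerance = 1e-8)
  # zero-nugget kriging is exact at sample locations
  expect_equal(ok_predict(s, v, s$x, s$y), s$value, tolerance = 1e-6)
  expect_error(ok_predict(s[1:2, ], v, 0, 0), "at least 3")
})

test_that("kriging is translation-equivariant and range-bounded on convex toys", {
  set.seed(12)
  s <- data.frame(x = runif(8, 0, 8000), y = runif(8, 0, 8000),
                  value = rnorm(8, 40, 6))
  v <- spherical_variogram(0, 4, 5000)
  spec <- grid_spec(8, 8, 1000)
  base <- ordinary_krige(s, v, spec)
  s2 <- s; s2$value <- s$value + 13
  shifted <- ordinary_krige(s2, v, spec)
  expect_equal(shifted$values, base$values + 13, tolerance = 1e-8)
})

test_that("the three-variable spline baseline shares the MARS engine", {
  set.seed(14)
  spec <- grid_spec(20, 20, 500)
  dem <- raster_layer(spec, matrix(seq(1700, 1100, length.out = 20), 20, 20))
  st <- toy_stations(25, seed = 15, spec = spec)
  # truth linear in elevation only, noiseless
  st$value <- 100 - 0.04 * sample_at(dem, st$x, st$y)
  f <- fit_mars3(st, dem)
  pred <- predict(f, st$x, st$y)
  expect_gt(1 - mean((st$value - pred)^2) / var(st$value), 0.99)
  # identical inputs give identical models (determinism)
  f2 <- fit_mars3(st, dem)
  expect_identical(f$model, f2$model)
  # constant dependent: intercept-only
  st$value <- rep(30, 25)
  expect_length(fit_mars3(st, dem)$model$basis, 0L)
  # engine identity: same design matrix, bitwise-identical fit
  X <- pcamars:::mars3_design(dem, st$x, st$y)
  set.seed(16)
  st$value <- rnorm(25, 50, 10)
  direct <- fit_mars(X, st$value, minspan = "auto")
  via_baseline <- fit_mars3(st, dem)$model
  expect_identical(direct, via_baseline)
})
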