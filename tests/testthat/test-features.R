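test_that("IDW surfaces honour symmetry, exactness and hand arithmetic", {
  spec <- grid_spec(1, 1, 100, origin_x = -50, origin_y = 50)  # centre (0,0)
  two <- data.frame(x = c(-10, 10), y = c(0, 0), value = c(10, 20))
  for (p in c(1, 2, 3))
    expect_equal(idw_surface(two, spec, p)$values[1, 1], 15)
  # exact interpolator at a sample location
  at <- data.frame(x = 0, y = 0, value = 42)
  expect_identical(idw_surface(at, spec, 2)$values[1, 1], 42)
  # power 1, distances 1 and 3: (10*1 + 20/3) / (1 + 1/3) = 12.5
  s <- data.frame(x = c(-1, 3), y = c(0, 0), value = c(10, 20))
  expect_equal(idw_predict(s, 0, 0, 1), 12.5)
  expect_error(idw_surface(s[0, ], spec, 2), "at least one")
})

test_that("IDW predictions are bounded by the sample range", {
  set.seed(3)
  s <- data.frame(x = runif(10, 0, 5000), y = runif(10, 0, 5000),
                  value = rnorm(10, 30, 8))
  spec <- grid_spec(10, 10, 500)
  for (p in c(1, 2, 3.5)) {
    v <- idw_surface(s, spec, p)$values
    expect_true(all(v >= min(s$value) - 1e-9 & v <= max(s$value) + 1e-9))
  }
})

test_that("select_idw_power agrees with an independent LOOCV enumeration", {
  set.seed(5)
  s <- data.frame(x = runif(25, 0, 10000), y = runif(25, 0, 10000))
  s$value <- s$x / 1000 + rnorm(25, 0, 0.5)
  cands <- c(1, 2, 3)
  # independent enumeration oracle over candidates
  oracle <- vapply(cands, function(p) {
    sqrt(mean(vapply(seq_len(25), function(i) {
      tr <- s[-i, ]
      d <- sqrt((tr$x - s$x[i])^2 + (tr$y - s$y[i])^2)
      w <- d^(-p)
      (s$value[i] - sum(w * tr$value) / sum(w))^2
    }, numeric(1))))
  }, numeric(1))
  expect_equal(select_idw_power(s, cands), cands[which.min(oracle)])
  s$value <- rep(5, 25)
  expect_equal(select_idw_power(s, c(3, 1, 2)), 1)  # all tie at 0 -> smallest
  expect_equal(select_idw_power(s, 2), 2)
  expect_error(select_idw_power(s[1:2, ], c(1, 2)), "at least 3")
})

test_that("focal_mean averages circular neighbourhoods and keeps constants", {
  cst <- raster_layer(toy_spec(5, 5), 5)
  expect_true(all(focal_mean(cst, 1200)$values == 5))
  # 3x3 with centre 9: radius covering all 9 cells -> centre mean 1
  m <- matrix(0, 3, 3); m[2, 2] <- 9
  r <- raster_layer(grid_spec(3, 3, 500), m)
  expect_equal(focal_mean(r, 800)$values[2, 2], 1)
  # radius equal to the cell size: strict containment leaves the centre
  # cell as the whole neighbourhood
  rnd <- toy_raster(4, 4)
  expect_equal(focal_mean(rnd, 500)$values, rnd$values)
  expect_error(focal_mean(rnd, 100), "at least one cell")
})

test_that("focal_mean commutes with adding a constant", {
  r <- toy_raster(8, 8, seed = 9)
  shifted <- raster_layer(r$spec, r$values + 3)
  expect_equal(focal_mean(shifted, 1500)$values,
               focal_mean(r, 1500)$values + 3, tolerance = 1e-12)
})

test_that("KDE conserves mass, has compact support and handles empties", {
  spec <- grid_spec(40, 40, 500)
  # interior unit-weight point, radius 8 cells: sum * cell area within 2% of 1
  pt <- vector_layer("points", list(cbind(10000, -10000) + c(10000, 0)))
  pt$geometries[[1]] <- cbind(10250, spec$origin_y - 10250)
  kde <- kde_surface(pt, spec, 4000)
  expect_equal(sum(kde$values) * 500^2, 1, tolerance = 0.02)
  expect_true(all(kde$values >= 0))
  # cells farther than the radius are exactly zero
  ctr <- cell_centers(spec)
  d <- sqrt((ctr$x - 10250)^2 + (ctr$y - (spec$origin_y - 10250))^2)
  expect_true(all(kde$values[d > 4000] == 0))
  # empty layer -> all-zero raster, not an error
  expect_true(all(kde_surface(vector_layer("points"), spec, 2000)$values == 0))
  expect_error(kde_surface(pt, spec, 100), "at least one cell")
})

test_that("KDE mass scales with weights for all geometry kinds", {
  spec <- grid_spec(40, 40, 500)
  mid <- c(10000, spec$origin_y - 10000)
  pts <- vector_layer("points", list(cbind(mid[1], mid[2]),
                                     cbind(mid[1] + 2000, mid[2])),
                      weights = c(2, 3))
  expect_equal(sum(kde_surface(pts, spec, 3000)$values) * 500^2, 5,
               tolerance = 0.02)
  # a polygon contributes its centroid with the full weight
  sq <- rbind(c(9000, 11000), c(11000, 11000), c(11000, 9000), c(9000, 9000))
  poly <- vector_layer("polygons", list(sq), weights = 7)
  kp <- kde_surface(poly, spec, 3000)
  expect_equal(sum(kp$values) * 500^2, 7, tolerance = 0.02)
  peak <- which(kp$values == max(kp$values), arr.ind = TRUE)[1, ]
  ctr <- cell_centers(spec)
  expect_lt(abs(ctr$x[peak[1], peak[2]] - 10000), 600)
})

test_that("bivariate Moran's I matches hand and brute-force oracles", {
  W <- path_graph_weights()
  expect_equal(bivariate_morans_i(1:4, 1:4, W), 1 / 3)
  expect_error(bivariate_morans_i(rep(2, 4), 1:4, W), "zero-variance")
  # relabeling invariance
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:10, 1)
    dep <- rnorm(n); cov <- rnorm(n)
    Wr <- matrix(runif(n * n), n, n); diag(Wr) <- 0
    expect_equal(bivariate_morans_i(dep, cov, Wr),
                 moran_brute(dep, cov, Wr), tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(bivariate_morans_i(dep[perm], cov[perm], Wr[perm, perm]),
                 bivariate_morans_i(dep, cov, Wr), tolerance = 1e-12)
    # bivariate form with cov = dep reduces to univariate Moran's I
    expect_equal(bivariate_morans_i(dep, dep, Wr),
                 moran_brute(dep, dep, Wr), tolerance = 1e-12)
  }
})

test_that("radius selection recovers a planted smoothing radius", {
  # dep field smoothed at 3 cells; candidate builders smooth the raw field
  # at each radius; a dense network can see the neighbourhood scale
  picks <- vapply(1:20, function(s) {
    set.seed(100 + s)
    sp <- grid_spec(30, 30, 500)
    base <- matrix(rnorm(900), 30, 30)
    depl <- focal_mean(raster_layer(sp, base), 1500)
    stxy <- pcamars:::quasi_uniform_points(100, sp)
    v <- sample_at(depl, stxy[, 1], stxy[, 2])
    dep <- data.frame(x = stxy[, 1], y = stxy[, 2],
                      value = v + rnorm(100, 0, 0.05 * sd(v)))
    builder <- function(r) focal_mean(raster_layer(sp, base), r)
    select_radius(dep, builder, 500 * (1:6))$selected_radius
  }, numeric(1))
  expect_lte(abs(median(picks) - 1500), 500)
})

test_that("radius selection by |I| is invariant to covariate sign flips", {
  set.seed(33)
  sp <- grid_spec(20, 20, 500)
  base <- matrix(rnorm(400), 20, 20)
  depl <- focal_mean(raster_layer(sp, base), 1000)
  stxy <- pcamars:::quasi_uniform_points(40, sp)
  dep <- data.frame(x = stxy[, 1], y = stxy[, 2],
                    value = sample_at(depl, stxy[, 1], stxy[, 2]))
  pos <- select_radius(dep, function(r) focal_mean(raster_layer(sp, base), r),
                       500 * (1:5))
  neg <- select_radius(dep, function(r) focal_mean(raster_layer(sp, -base), r),
                       500 * (1:5))
  expect_equal(neg$selected_radius, pos$selected_radius)
  expect_equal(neg$moran_values, -pos$moran_values, tolerance = 1e-12)
  # single candidate is returned as selected
  one <- select_radius(dep, function(r) focal_mean(raster_layer(sp, base), r),
                       1500)
  expect_equal(one$selected_radius, 1500)
})

test_that("min-max normalization maps to [0,1] and inverts with its bounds", {
  r <- raster_layer(grid_spec(1, 3, 500), matrix(c(2, 4, 6), 1))
  nz <- min_max_normalize(r)
  expect_equal(as.vector(nz$layer$values), c(0, 0.5, 1))
  expect_equal(unname(nz$bounds), c(2, 6))
  # already [0,1] with attained bounds: unchanged
  u <- raster_layer(grid_spec(1, 3, 500), matrix(c(0, 0.3, 1), 1))
  expect_equal(min_max_normalize(u)$layer$values, u$values)
  expect_error(min_max_normalize(raster_layer(grid_spec(1, 3, 500), 5)),
               "degenerate")
  # denormalization with the stored bounds recovers the input
  rr <- toy_raster(6, 6, seed = 2)
  nz2 <- min_max_normalize(rr)
  back <- nz2$layer$values * diff(nz2$bounds) + nz2$bounds[1]
  expect_equal(back, rr$values, tolerance = 1e-12)
})

test_that("the feature stack has 14 normalized layers and is deterministic", {
  sc <- generate_scene(fast_scene_config(seed = 4))
  stk <- build_feature_stack(scene_inputs(sc), sc$spec)
  expect_length(stk$layers, 14L)
  expect_identical(names(stk$layers), pcamars:::stack_layer_names())
  for (l in stk$layers) {
    v <- l$values[is.finite(l$values)]
    expect_true(all(v >= 0 & v <= 1))
  }
  stk2 <- build_feature_stack(scene_inputs(sc), sc$spec)
  expect_identical(lapply(stk$layers, `[[`, "values"),
                   lapply(stk2$layers, `[[`, "values"))
  expect_identical(stk$provenance, stk2$provenance)
  # provenance records a radius per Moran-driven layer and met powers
  expect_length(stk$provenance$radii, 7L)
  expect_length(stk$provenance$idw_powers, 4L)
  # missing input class fails loudly
  bad <- scene_inputs(sc); bad$roads <- NULL
  expect_error(build_feature_stack(bad, sc$spec), "missing input")
})
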