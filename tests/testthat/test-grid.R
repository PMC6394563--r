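test_that("raster write/read round-trips values, nodata and georeferencing", {
  r <- toy_raster(3, 3)
  r$values[2, 3] <- NA
  p <- withr::local_tempfile(fileext = ".asc")
  write_raster(r, p)
  r2 <- read_raster(p)
  expect_equal(r2$values, r$values, tolerance = 1e-12)
  expect_equal(sum(is.na(r2$values)), 1L)
  expect_true(same_spec <- isTRUE(all.equal(r$spec, r2$spec)))

  # constant layer round-trips its mean
  cst <- raster_layer(toy_spec(3, 3), 7, "c")
  p2 <- withr::local_tempfile(fileext = ".asc")
  write_raster(cst, p2)
  expect_equal(mean(read_raster(p2)$values), 7)

  # two writes are byte-identical (deterministic serialization)
  pa <- withr::local_tempfile(fileext = ".asc")
  pb <- withr::local_tempfile(fileext = ".asc")
  write_raster(r, pa); write_raster(r, pb)
  expect_identical(readBin(pa, "raw", file.size(pa)),
                   readBin(pb, "raw", file.size(pb)))
})

test_that("read_raster rejects malformed files", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("not a header", "1 2 3"), p)
  expect_error(read_raster(p), "ESRI ASCII")
  expect_error(read_raster(file.path(tempdir(), "nope.asc")), "not found")
})

test_that("sample_at matches a brute-force containment oracle", {
  r <- toy_raster(6, 7)
  spec <- r$spec
  set.seed(11)
  n <- 100
  x <- spec$origin_x + runif(n) * spec$n_cols * spec$cell_size
  y <- spec$origin_y - runif(n) * spec$n_rows * spec$cell_size
  got <- sample_at(r, x, y)
  oracle <- vapply(seq_len(n), function(i) {
    for (rr in seq_len(spec$n_rows)) for (cc in seq_len(spec$n_cols)) {
      x0 <- spec$origin_x + (cc - 1) * spec$cell_size
      y0 <- spec$origin_y - (rr - 1) * spec$cell_size
      if (x[i] >= x0 && x[i] < x0 + spec$cell_size &&
          y[i] <= y0 && y[i] > y0 - spec$cell_size)
        return(r$values[rr, cc])
    }
    NA_real_
  }, numeric(1))
  expect_equal(got, oracle)
})

test_that("sample_at honours the half-open containment convention", {
  r <- toy_raster(2, 2, cs = 100)
  ctr <- cell_centers(r$spec)
  expect_equal(sample_at(r, ctr$x[1, 1], ctr$y[1, 1]), r$values[1, 1])
  # 1 mm inside the right edge of the last column
  expect_equal(sample_at(r, r$spec$origin_x + 200 - 0.001,
                         ctr$y[2, 1]), r$values[2, 2])
  # a point on an interior shared edge belongs to the cell to its right
  expect_equal(sample_at(r, r$spec$origin_x + 100, ctr$y[1, 1]),
               r$values[1, 2])
  expect_error(sample_at(r, r$spec$origin_x - 1, ctr$y[1, 1]), "outside")
})

test_that("resample_to is identity on matching specs and nearest-neighbour otherwise", {
  r <- toy_raster(4, 4)
  expect_equal(resample_to(r, r$spec)$values, r$values)
  cst <- raster_layer(toy_spec(4, 4), 3.5)
  half <- grid_spec(2, 2, 1000)
  expect_true(all(resample_to(cst, half)$values == 3.5))
  # brute-force centre-sampling oracle on the 4x4 -> 2x2 case
  rs <- resample_to(r, half)
  ctr <- cell_centers(half)
  oracle <- matrix(sample_at(r, as.vector(ctr$x), as.vector(ctr$y)), 2, 2)
  expect_equal(rs$values, oracle)
  # 400-m pixels resampled onto the 500-m toy spec
  fine <- raster_layer(grid_spec(5, 5, 400), matrix(runif(25), 5, 5))
  out <- resample_to(fine, toy_spec(4, 4))
  expect_equal(dim(out$values), c(4L, 4L))
  far <- grid_spec(2, 2, 500, origin_x = 1e7, origin_y = 1e7)
  expect_error(resample_to(r, far), "disjoint")
})

test_that("point CSV and GeoJSON vector I/O preserve records and weights", {
  st <- toy_stations(21)
  p <- withr::local_tempfile(fileext = ".csv")
  write_points(st, p)
  st2 <- read_points(p)
  expect_equal(nrow(st2), 21L)
  expect_equal(st2$value, st$value, tolerance = 1e-12)
  expect_equal(st2$id, st$id)
  writeLines("a,b\n1,2", p)
  expect_error(read_points(p), "required column")

  vl <- vector_layer("points", list(cbind(100, 200), cbind(300, 50)),
                     weights = c(2.5, 1))
  g <- withr::local_tempfile(fileext = ".geojson")
  write_vector(vl, g)
  vl2 <- read_vector(g)
  expect_equal(vl2$kind, "points")
  expect_equal(vl2$weights, c(2.5, 1))
  expect_equal(vl2$geometries[[1]][1, ], c(100, 200))

  empty <- vector_layer("points")
  write_vector(empty, g)
  expect_length(read_vector(g)$geometries, 0L)

  line <- vector_layer("polylines", list(rbind(c(0, 0), c(100, 100))))
  write_vector(line, g)
  expect_equal(read_vector(g)$kind, "polylines")
})

test_that("polyline densification conserves represented length as weight", {
  coords <- rbind(c(0, 0), c(1000, 0))
  d <- pcamars:::densify_polyline(coords, 100, weight = 2)
  expect_equal(sum(d$w), 2 * 1000)
  expect_true(all(d$xy[, 2] == 0))
  expect_true(max(diff(sort(d$xy[, 1]))) <= 100 + 1e-9)
})
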