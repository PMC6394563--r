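# shared fixtures built in code

toy_spec <- function(nr = 4, nc = 5, cs = 500) grid_spec(nr, nc, cs)

toy_raster <- function(nr = 4, nc = 5, cs = 500, seed = 42) {
  set.seed(seed)
  raster_layer(toy_spec(nr, nc, cs), matrix(runif(nr * nc), nr, nc), "toy")
}

# the published Tehran NO2 worked model shipped as a fixture: intercept
# 76.358 with four hinge basis functions over two predictors
worked_no2_model <- function() {
  read_mars(system.file("extdata", "no2_mars_model.json",
                        package = "pcamars", mustWork = TRUE))
}

# 4-node path graph, binary weights
path_graph_weights <- function() {
  W <- matrix(0, 4, 4)
  W[cbind(c(1, 2, 2, 3, 3, 4), c(2, 1, 3, 2, 4, 3))] <- 1
  W
}

# independent brute-force Moran double sum (oracle; no matrix algebra)
moran_brute <- function(dep, cov, W) {
  n <- length(dep)
  z <- dep - mean(dep); cc <- cov - mean(cov)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) acc <- acc + W[i, j] * z[i] * cc[j]
  (n / sum(W)) * acc / sqrt(sum(z^2) * sum(cc^2))
}

# normal-equations least-squares oracle
lstsq_oracle <- function(B, y) {
  as.vector(solve(crossprod(B), crossprod(B, y)))
}

# small station set on a toy grid
toy_stations <- function(n = 8, seed = 7, spec = toy_spec(10, 10)) {
  set.seed(seed)
  w <- spec$n_cols * spec$cell_size
  h <- spec$n_rows * spec$cell_size
  data.frame(id = paste0("s", seq_len(n)),
             x = spec$origin_x + runif(n, 0.05, 0.95) * w,
             y = spec$origin_y - runif(n, 0.05, 0.95) * h,
             value = rnorm(n, 50, 10), stringsAsFactors = FALSE)
}

fast_scene_config <- function(seed = 1, ...) {
  scene_config(seed = seed, n_rows = 30, n_cols = 40, ...)
}
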