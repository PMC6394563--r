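#' Grid geometry for a regular raster
#'
#' A `grid_spec` describes a regular grid of square cells in projected
#' (metric) coordinates. Row 1 is the northernmost row and
#' (`origin_x`, `origin_y`) is the outer top-left corner, so the centre of
#' the cell in row `r`, column `c` (1-based) is
#' `(origin_x + (c - 0.5) * cell_size, origin_y - (r - 0.5) * cell_size)`.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in metres (default 500, the working
#'   resolution of the NO2 pipeline).
#' @param origin_x,origin_y Projected coordinates of the top-left outer
#'   corner, in metres.
#' @param crs_tag Free-form coordinate reference system tag (opaque string).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 500,
                      origin_x = 0, origin_y = n_rows * cell_size,
                      crs_tag = "") {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         crs_tag = as.character(crs_tag)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells @ %g m, origin (%g, %g)%s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
              if (nzchar(x$crs_tag)) paste0(" [", x$crs_tag, "]") else ""))
  invisible(x)
}

#' @exportS3Method base::all.equal
all.equal.grid_spec <- function(target, current, ...) {
  all.equal(unclass(target)[1:5], unclass(current)[1:5], ...)
}

same_spec <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol
}

#' Cell-centre coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @return A list with matrices `x` and `y` (`n_rows` x `n_cols`) giving the
#'   projected coordinates of each cell centre.
#' @export
cell_centers <- function(spec) {
  cx <- spec$origin_x + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
  cy <- spec$origin_y - (seq_len(spec$n_rows) - 0.5) * spec$cell_size
  list(x = matrix(cx, spec$n_rows, spec$n_cols, byrow = TRUE),
       y = matrix(cy, spec$n_rows, spec$n_cols))
}

#' Construct a raster layer
#'
#' The universal covariate carrier: a named matrix of values on a
#' [grid_spec()], with `NA` as the nodata sentinel.
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix (`n_rows` x `n_cols`), or a single number to
#'   be recycled. `NA` marks nodata.
#' @param name Layer name.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(spec, values, name = "layer") {
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), spec$n_rows, spec$n_cols)
  values <- as.matrix(values)
  if (!identical(dim(values), c(spec$n_rows, spec$n_cols)))
    stop("values dimensions (", paste(dim(values), collapse = "x"),
         ") do not match spec (", spec$n_rows, "x", spec$n_cols, ")")
  if (any(is.infinite(values)))
    stop("raster values must be finite or NA")
  storage.mode(values) <- "double"
  structure(list(spec = spec, name = as.character(name), values = values),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("raster_layer '%s': %d x %d @ %g m; range [%g, %g], %d nodata\n",
              x$name, x$spec$n_rows, x$spec$n_cols, x$spec$cell_size,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(is.na(x$values))))
  invisible(x)
}

# row/col (1-based) of the cells containing points; half-open convention:
# a point on a shared edge belongs to the cell to its right/below.
cell_index <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$cell_size) + 1L
  row <- floor((spec$origin_y - y) / spec$cell_size) + 1L
  list(row = as.integer(row), col = as.integer(col))
}

in_bounds <- function(spec, x, y) {
  idx <- cell_index(spec, x, y)
  idx$row >= 1L & idx$row <= spec$n_rows & idx$col >= 1L & idx$col <= spec$n_cols
}

#' Sample a raster at point locations
#'
#' Returns the value of the cell containing each point (no interpolation).
#' Cell containment is half-open: a point on a shared cell edge belongs to
#' the cell to its right/below, which makes sampling deterministic.
#'
#' @param layer A [raster_layer()].
#' @param x,y Projected coordinates (vectors of equal length).
#' @return Numeric vector of cell values; nodata cells yield `NA`.
#' @export
sample_at <- function(layer, x, y) {
  spec <- layer$spec
  if (length(x) != length(y)) stop("x and y must have equal length")
  idx <- cell_index(spec, x, y)
  bad <- idx$row < 1L | idx$row > spec$n_rows | idx$col < 1L | idx$col > spec$n_cols
  if (any(bad))
    stop(sprintf("point (%g, %g) is outside the grid bounds",
                 x[which(bad)[1]], y[which(bad)[1]]))
  layer$values[cbind(idx$row, idx$col)]
}

#' Resample a raster onto a new grid
#'
#' Nearest-neighbour resampling: each target cell takes the source value at
#' the target cell centre. Identical source and target specs return the
#' layer unchanged.
#'
#' @param layer Source [raster_layer()].
#' @param spec Target [grid_spec()].
#' @return A [raster_layer()] on `spec`.
#' @export
resample_to <- function(layer, spec) {
  if (same_spec(layer$spec, spec)) {
    out <- layer
    out$spec <- spec
    return(out)
  }
  ctr <- cell_centers(spec)
  if (!any(in_bounds(layer$spec, ctr$x, ctr$y)))
    stop("source and target extents are disjoint")
  idx <- cell_index(layer$spec, ctr$x, ctr$y)
  row <- pmin(pmax(idx$row, 1L), layer$spec$n_rows)
  col <- pmin(pmax(idx$col, 1L), layer$spec$n_cols)
  vals <- matrix(layer$values[cbind(as.vector(row), as.vector(col))],
                 spec$n_rows, spec$n_cols)
  raster_layer(spec, vals, name = layer$name)
}

#' Read a raster from an ESRI ASCII grid file
#'
#' Single-band georeferenced plain-text rasters (`.asc`) with square cells
#' and a `NODATA_value` tag. If a sidecar `.prj` file is present its first
#' line is stored as the layer's CRS tag.
#'
#' @param path Path to an `.asc` file.
#' @param name Layer name; defaults to the file stem.
#' @return A [raster_layer()]; nodata cells are mapped to `NA`.
#' @export
read_raster <- function(path, name = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list(); n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2]))) ||
        !is.na(suppressWarnings(as.numeric(parts[1]))))
      break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    n_hdr <- n_hdr + 1L
  }
  if (n_hdr == 0L) stop("not an ESRI ASCII grid: ", path)
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("ESRI ASCII header must define ncols, nrows and cellsize")
  if (!any(c("xllcorner", "xllcenter") %in% names(hdr)))
    stop("ESRI ASCII header lacks an x origin")
  cs <- hdr$cellsize
  if (is.na(cs) || cs <= 0) stop("non-positive cell size")
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " cells, found ", length(vals))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA_real_
  if (!is.na(nodata)) vals[vals == nodata] <- NA_real_
  crs <- ""
  prj <- sub("\\.asc$", ".prj", path)
  if (!identical(prj, path) && file.exists(prj))
    crs <- readLines(prj, n = 1L)
  spec <- grid_spec(nr, nc, cs, origin_x = xll, origin_y = yll + nr * cs,
                    crs_tag = crs)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  raster_layer(spec, matrix(vals, nr, nc, byrow = TRUE), name = name)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' `NA` cells are written as the nodata value. A non-empty CRS tag is
#' written to a sidecar `.prj` file. Output is deterministic: the same
#' layer always produces byte-identical files.
#'
#' @param layer A [raster_layer()].
#' @param path Output path (conventionally `.asc`).
#' @param nodata Numeric sentinel written for `NA` cells.
#' @export
write_raster <- function(layer, path, nodata = -9999) {
  spec <- layer$spec
  vals <- layer$values
  vals[is.na(vals)] <- nodata
  hdr <- c(sprintf("ncols %d", spec$n_cols),
           sprintf("nrows %d", spec$n_rows),
           sprintf("xllcorner %.17g", spec$origin_x),
           sprintf("yllcorner %.17g", spec$origin_y - spec$n_rows * spec$cell_size),
           sprintf("cellsize %.17g", spec$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(vals, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  con <- file(path, "wb")  # binary mode: fixed newlines on any platform
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  if (nzchar(spec$crs_tag)) {
    prj <- sub("\\.asc$", ".prj", path)
    if (!identical(prj, path)) writeLines(spec$crs_tag, prj)
  }
  invisible(path)
}

#' Read point samples from CSV
#'
#' Station observations: one row per sample with columns `id,x,y,value`
#' (header required; order preserved).
#'
#' @param path Path to a CSV file.
#' @return A data frame with columns `id` (character), `x`, `y`, `value`.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("points file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("points CSV lacks required column(s): ", paste(miss, collapse = ", "))
  data.frame(id = as.character(df$id), x = as.numeric(df$x),
             y = as.numeric(df$y), value = as.numeric(df$value),
             stringsAsFactors = FALSE)
}

#' Write point samples to CSV
#'
#' @param samples Data frame with columns `id,x,y,value`.
#' @param path Output path.
#' @export
write_points <- function(samples, path) {
  utils::write.csv(samples[, c("id", "x", "y", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a vector layer
#'
#' Weighted geometries of a single kind: points (e.g. POIs), polylines
#' (roads) or polygons (population blocks, weight = population).
#'
#' @param kind One of `"points"`, `"polylines"`, `"polygons"`.
#' @param geometries List of 2-column coordinate matrices (one per
#'   geometry). Points are 1 x 2; polylines need at least 2 vertices;
#'   polygon rings need at least 3 (closing vertex optional).
#' @param weights Non-negative weight per geometry (default 1).
#' @return An object of class `vector_layer`.
#' @export
vector_layer <- function(kind = c("points", "polylines", "polygons"),
                         geometries = list(), weights = NULL) {
  kind <- match.arg(kind)
  geometries <- lapply(geometries, function(g) {
    g <- matrix(as.numeric(g), ncol = 2)
    if (kind == "polylines" && nrow(g) < 2)
      stop("polylines need at least 2 vertices")
    if (kind == "polygons" && nrow(g) < 3)
      stop("polygon rings need at least 3 vertices")
    g
  })
  if (is.null(weights)) weights <- rep(1, length(geometries))
  if (length(weights) != length(geometries))
    stop("one weight per geometry required")
  if (any(weights < 0)) stop("weights must be non-negative")
  structure(list(kind = kind, geometries = geometries,
                 weights = as.numeric(weights)),
            class = "vector_layer")
}

#' @export
print.vector_layer <- function(x, ...) {
  cat(sprintf("vector_layer: %d %s, total weight %g\n",
              length(x$geometries), x$kind, sum(x$weights)))
  invisible(x)
}

geojson_kind <- function(type) {
  switch(type,
         Point = , MultiPoint = "points",
         LineString = , MultiLineString = "polylines",
         Polygon = , MultiPolygon = "polygons",
         stop("unsupported GeoJSON geometry type: ", type))
}

#' Read a vector layer from GeoJSON
#'
#' Supports FeatureCollections of Point, LineString and Polygon features
#' (the outer ring only for polygons). A numeric `weight` property is
#' carried through; other features default to weight 1.
#'
#' @param path Path to a GeoJSON file.
#' @return A [vector_layer()]; an empty collection yields an empty layer of
#'   kind `"points"`.
#' @export
read_vector <- function(path) {
  if (!file.exists(path)) stop("vector file not found: ", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  feats <- gj$features
  if (length(feats) == 0L) return(vector_layer("points"))
  kinds <- character(0); geoms <- list(); wts <- numeric(0)
  for (f in feats) {
    g <- f$geometry
    if (is.null(g$type) || is.null(g$coordinates))
      stop("unparseable GeoJSON geometry")
    kinds <- c(kinds, geojson_kind(g$type))
    co <- g$coordinates
    m <- switch(g$type,
      Point = matrix(unlist(co), ncol = 2),
      LineString = do.call(rbind, lapply(co, unlist)),
      Polygon = do.call(rbind, lapply(co[[1]], unlist)),
      stop("unsupported GeoJSON geometry type: ", g$type))
    geoms <- c(geoms, list(m))
    w <- f$properties$weight
    wts <- c(wts, if (is.null(w)) 1 else as.numeric(w))
  }
  if (length(unique(kinds)) > 1L)
    stop("mixed geometry kinds in one layer are not supported")
  vector_layer(kinds[1], geoms, wts)
}

#' Write a vector layer to GeoJSON
#'
#' @param layer A [vector_layer()].
#' @param path Output path.
#' @export
write_vector <- function(layer, path) {
  type <- switch(layer$kind, points = "Point", polylines = "LineString",
                 polygons = "Polygon")
  feats <- lapply(seq_along(layer$geometries), function(i) {
    g <- layer$geometries[[i]]
    coords <- switch(layer$kind,
      points = as.numeric(g[1, ]),
      polylines = lapply(seq_len(nrow(g)), function(r) as.numeric(g[r, ])),
      polygons = list(lapply(seq_len(nrow(g)), function(r) as.numeric(g[r, ]))))
    list(type = "Feature",
         geometry = list(type = type, coordinates = coords),
         properties = list(weight = layer$weights[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# polygon ring centroid (shoelace); falls back to vertex mean for
# degenerate (zero-area) rings
polygon_centroid <- function(ring) {
  if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ])))
    ring <- rbind(ring, ring[1, ])
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  cross <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(colMeans(ring[-n, , drop = FALSE]))
  c(sum((x[-n] + x[-1]) * cross) / (6 * a),
    sum((y[-n] + y[-1]) * cross) / (6 * a))
}

# densify a polyline to points spaced at most `step` apart, each weighted
# by the length of line it represents (times the line weight)
densify_polyline <- function(coords, step, weight = 1) {
  seg <- diff(coords)
  len <- sqrt(rowSums(seg^2))
  total <- sum(len)
  if (total == 0) return(list(xy = coords[1, , drop = FALSE], w = weight))
  n_pts <- max(2L, ceiling(total / step) + 1L)
  s <- seq(0, total, length.out = n_pts)
  cum <- c(0, cumsum(len))
  idx <- findInterval(pmin(s, total - 1e-12), cum, rightmost.closed = TRUE)
  frac <- (s - cum[idx]) / pmax(len[idx], 1e-12)
  xy <- coords[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  list(xy = xy, w = rep(weight * total / n_pts, n_pts))
}

# collapse any vector layer to weighted event points for density analysis:
# points keep their weights, polylines are densified (weight spread along
# length), polygons contribute their centroid with the full weight
as_event_points <- function(layer, step) {
  if (length(layer$geometries) == 0L)
    return(list(xy = matrix(numeric(0), 0, 2), w = numeric(0)))
  parts <- lapply(seq_along(layer$geometries), function(i) {
    g <- layer$geometries[[i]]; w <- layer$weights[i]
    switch(layer$kind,
           points = list(xy = g[1, , drop = FALSE], w = w),
           polylines = densify_polyline(g, step, w),
           polygons = list(xy = matrix(polygon_centroid(g), 1, 2), w = w))
  })
  list(xy = do.call(rbind, lapply(parts, `[[`, "xy")),
       w = unlist(lapply(parts, `[[`, "w")))
}
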