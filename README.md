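# pcamars

Spatial interpolation of urban NO2 concentrations from a sparse monitoring
network, for exposure assessment and air-quality mapping. Plain
interpolators (inverse distance weighting, kriging) only see station
coordinates; in a city, NO2 varies with traffic, land use, terrain and
weather at scales finer than the station spacing. `pcamars` builds a
continuous 500-m concentration surface by fusing the station values with
14 gridded covariates, compressing them by principal component analysis,
and fitting a multivariate adaptive regression splines (MARS) model in
component space.

The fitted model has the form

    f(x) = c0 + sum_i c_i B_i(x),      B_i(x) = prod_j max(0, ±(x_j - t_j))

with hinge basis functions B_i grown by a greedy forward knot search
(minimizing the residual sum of squares) and pruned backward by
generalized cross-validation,

    GCV = (SSE / n) / (1 - (m + d (m - 1) / 2) / n)^2 ,

where m counts model terms and d is the complexity penalty. The model's
inputs are the three leading principal components of a normalized
covariate stack: four IDW-interpolated meteorological surfaces, six
kernel-density surfaces (roads, population, four point-of-interest
classes) whose search radii are selected by maximizing the absolute
bivariate Moran's I against the station NO2 values, elevation and focal
elevation, and the cell coordinates.

The package also provides the reference interpolators the method is
judged against (IDW with LOOCV-selected power, ordinary kriging with a
fitted spherical semivariogram, and a three-variable MARS on x, y and
elevation), leave-one-out cross-validation tooling, plain-text raster
(ESRI ASCII grid), CSV and GeoJSON I/O, and a synthetic-city generator
that plants known covariate effects so the whole pipeline is testable
without proprietary monitoring data.

## Worked example

```r
library(pcamars)

scene <- generate_scene(scene_config(seed = 10))    # synthetic city
fit   <- pcamars_fit(scene_inputs(scene), scene$spec)
print(fit)
#> pcamars_fit
#>   PCA: keeping 3 of 14 components (78.7% of variance)
#> mars_model: 4 basis function(s) + intercept, GCV = 112.2
#>   f(x) = 45.517 + 487.45 * BF1 - 514.68 * BF2 - 267.96 * BF3 + 43.351 * BF4
#>   BF1 = max(0, -0.093695 - x3)
#>   BF2 = max(0, -0.093695 - x3) * max(0, x2 - -0.57896)
#>   BF3 = max(0, 0.012676 - x3)
#>   BF4 = max(0, x1 - 0.31092)

map <- predict_map(fit)                             # 60 x 80 NO2 surface
print(map)
#> raster_layer 'no2_pred': 60 x 80 @ 500 m; range [15.747, 56.6048], 0 nodata

compare_methods(scene, c("idw", "ok", "mars3", "pcamars"))
#>    method      rmse
#> 1 pcamars  9.714141
#> 2      ok 13.534982
#> 3     idw 13.843999
#> 4   mars3 14.339850
```

The three predictors x1-x3 are the leading principal components of the
covariate stack (axes dominated by terrain with its correlated
meteorology and by urban density); the hinges carve the city into regimes
where those factors raise or lower NO2, and BF2 is a two-factor
interaction. On this scene the leave-one-out comparison ranks the
covariate-assisted model well ahead of the coordinate-only interpolators
(RMSE 9.7 vs 13.8 for IDW). Concentrations are micrograms per cubic
metre; individual scenes vary, and the shipped tests assert the ordering
statistically over 20 scenes.

A YAML-driven command-line front end with `simulate`, `featurize`, `fit`,
`predict` and `crossval` subcommands ships in `inst/cli/pcamars.R`.

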