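Package: pcamars
Title: Urban Air-Pollution Interpolation with PCA-Reduced Multivariate
    Adaptive Regression Splines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatial interpolation of urban NO2 concentrations from sparse
    monitoring-station measurements, fusing station values with gridded
    covariates (inverse-distance-weighted meteorological surfaces, kernel
    density surfaces of roads, population and points of interest, and
    terrain variables) whose neighbourhood radii are selected by maximizing
    the bivariate Moran's I against the pollutant. The covariate stack is
    reduced by principal component analysis and the pollutant surface is
    fitted with multivariate adaptive regression splines (piecewise-linear
    hinge bases grown by a forward sum-of-squares knot search and pruned by
    generalized cross-validation). Includes reference interpolators
    (inverse distance weighting, ordinary kriging with a spherical
    semivariogram, and a three-variable MARS), leave-one-out
    cross-validation tooling, a synthetic-city scene generator for
    end-to-end testing, and plain-text raster/vector I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
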