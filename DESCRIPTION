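Package: SOCmap
Title: Geostatistical Mapping and Stock Accounting of Soil Organic Carbon
    in Mountain Ecosystems
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping soil organic carbon (SOC) across mountain
    landscapes from point surveys: empirical semivariogram estimation and
    weighted-least-squares model fitting; six spatial interpolators
    (inverse distance weighting, local polynomial interpolation, radial
    basis functions with five kernels, ordinary kriging, ordinary
    cokriging with up to four secondary variables, and a
    spectrum-of-semivariograms empirical Bayes kriging); stratified
    spatially separated hold-out cross-validation with ME/RMSE/MRE/R2
    error indices; per-point and per-landscape SOC stock accounting with
    land-use-change scenario projection; NDVI computation from
    reflectance rasters; and a seeded synthetic mountain-survey generator
    that emulates a high-altitude volcanic park so the whole workflow
    runs at desk scale. Raster I/O uses the ESRI ASCII grid format and
    land-use polygons are read from GeoJSON.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
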