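test_that("sample table round-trips and resolves land-use classes", {
  path <- withr::local_tempfile(fileext = ".csv")
  sv <- soilSurvey(tinySites(3))
  writeSampleTable(sv, path)
  sv2 <- readSampleTable(path)
  expect_s4_class(sv2, "SoilSurvey")
  expect_equal(nrow(sites(sv2)), 3)
  expect_equal(sites(sv2), sites(sv))
  expect_true(all(sites(sv2)$land_use %in% landUseLevels))
})

test_that("sample table schema and parse errors are specific", {
  path <- withr::local_tempfile(fileext = ".csv")
  bad <- tinySites(3)
  bad$bulk_density <- NULL
  write.csv(bad, path, row.names = FALSE)
  expect_error(readSampleTable(path), "bulk_density")

  bad <- tinySites(3)
  bad$soc_a <- as.character(bad$soc_a)
  bad$soc_a[2] <- "ten"
  write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(readSampleTable(path), "row 2")
})

test_that("invariant-violating rows are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  bad <- tinySites(3)
  bad$coarse_pct[3] <- 120
  write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(readSampleTable(path), "coarse_pct")
  # O-horizon SOC present iff thickness positive
  bad <- tinySites(2)
  bad$soc_o <- c(NA, 310)
  bad$o_thickness <- c(4, 0)
  write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(readSampleTable(path), "soc_o")
})

test_that("ESRI ASCII grids round-trip losslessly with nodata mapping", {
  path <- withr::local_tempfile(fileext = ".asc")
  m <- matrix(c(1.5, -9999, 3.25, 4), 2, 2)
  r <- gridRaster(m, 100, 200, 50)
  r@values[2, 1] <- NA
  writeAsciiGrid(r, path)
  r2 <- readAsciiGrid(path)
  expect_equal(values(r2), r@values, tolerance = 1e-9)
  expect_equal(origin(r2), c(x = 100, y = 200))
  expect_equal(cellSize(r2), 50)
  # the sentinel in the file reads back as NA
  expect_true(is.na(values(r2)[2, 1]))
})

test_that("malformed ASCII grids raise format errors", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 3", "xllcorner 0", "yllcorner 0",
               "cellsize 10", "NODATA_value -9999",
               "1 2", "3 4"), path)
  expect_error(readAsciiGrid(path), "format error")
  writeLines(c("ncols 2", "xllcorner 0", "yllcorner 0", "cellsize 10",
               "1 2"), path)
  expect_error(readAsciiGrid(path), "nrows")
})

test_that("rasterized polygons label cells by containment with a
           first-polygon tie-break", {
  # two half-plane rectangles sharing the edge x = 500 over a 10x10 grid
  tpl <- gridRaster(matrix(NA_real_, 10, 10), 0, 0, 100)
  rect <- function(x0, x1, lu) list(
    land_use = lu,
    rings = list(cbind(c(x0, x1, x1, x0, x0), c(0, 0, 1000, 1000, 0))),
    area_ha = (x1 - x0) * 1000 / 1e4)
  m <- structure(list(rect(0, 500, "forest"),
                      rect(500, 1000, "agriculture")),
                 class = "landuseMap")
  lr <- rasterizeLanduse(m, tpl)
  # brute-force oracle: classify each cell centre by x < 500 / > 500
  cc <- cellCenters(tpl)
  oracle <- ifelse(cc[, 1] <= 500, 1, 3)  # centre on edge -> first polygon
  expect_equal(as.vector(values(lr)), as.numeric(oracle))

  # a single polygon covering everything labels every cell
  m1 <- structure(list(rect(0, 1000, "grassland")), class = "landuseMap")
  expect_true(all(values(rasterizeLanduse(m1, tpl)) == 2))
})

test_that("rasterized class areas converge to polygon areas with
           resolution", {
  rect <- function(x0, x1, lu) list(
    land_use = lu,
    rings = list(cbind(c(x0, x1, x1, x0, x0), c(0, 0, 1000, 1000, 0))),
    area_ha = (x1 - x0) * 1000 / 1e4)
  m <- structure(list(rect(0, 330, "forest"), rect(330, 1000, "agriculture")),
                 class = "landuseMap")
  err <- sapply(c(100, 25), function(cs) {
    tpl <- gridRaster(matrix(NA_real_, 1000 / cs, 1000 / cs), 0, 0, cs)
    lr <- rasterizeLanduse(m, tpl)
    got <- sum(values(lr) == 1, na.rm = TRUE) * cs^2 / 1e4
    abs(got - 33)
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2] / 33, 0.05)
})

test_that("GeoJSON land-use polygons read with areas", {
  path <- withr::local_tempfile(fileext = ".geojson")
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(land_use = "forest"),
         geometry = list(type = "Polygon", coordinates = list(
           list(list(0, 0), list(2000, 0), list(2000, 1000), list(0, 1000),
                list(0, 0)))))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  m <- readLanduseGeoJSON(path)
  expect_equal(unname(landuseAreas(m)["forest"]), 200)
})

test_that("Horn slope matches analytic planes and a stencil oracle", {
  flat <- gridRaster(matrix(5, 6, 6), 0, 0, 1)
  s <- computeSlope(flat)
  expect_equal(max(values(s)[2:5, 2:5]), 0)
  expect_true(all(is.na(values(s)[1, ])))

  # plane z = x rises 1 m per metre: slope 45 degrees everywhere inside
  d <- 8
  plane <- gridRaster(matrix(rep(seq_len(d) - 0.5, each = d), d, d), 0, 0, 1)
  s <- computeSlope(plane)
  expect_equal(values(s)[3, 3], 45, tolerance = 1e-6)

  # random DEM vs direct per-cell Horn stencil
  set.seed(11)
  z <- matrix(rnorm(100, 3000, 50), 10, 10)
  dem <- gridRaster(z, 0, 0, 30)
  s <- values(computeSlope(dem))
  horn <- function(i, j) {
    dzdx <- ((z[i + 1, j + 1] + 2 * z[i, j + 1] + z[i - 1, j + 1]) -
             (z[i + 1, j - 1] + 2 * z[i, j - 1] + z[i - 1, j - 1])) / (8 * 30)
    dzdy <- ((z[i + 1, j + 1] + 2 * z[i + 1, j] + z[i + 1, j - 1]) -
             (z[i - 1, j + 1] + 2 * z[i - 1, j] + z[i - 1, j - 1])) / (8 * 30)
    atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  }
  for (i in c(2, 5, 9)) for (j in c(2, 6, 9))
    expect_equal(s[i, j], horn(i, j), tolerance = 1e-10)

  expect_error(computeSlope(gridRaster(matrix(0, 2, 5), 0, 0, 1)), "3 x 3")
})

test_that("extractAt samples the nearest cell and NA outside", {
  r <- gridRaster(matrix(1:6, 2, 3), 0, 0, 10)
  expect_equal(extractAt(r, c(5, 25), c(5, 15)), c(1, 6))
  expect_true(is.na(extractAt(r, 100, 5)))
})
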