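## Readers and writers for the plain-text geodata formats the workflow
## touches: the sample CSV, ESRI ASCII grids and GeoJSON land-use polygons.
## Coordinates are planar metric throughout; the package never computes on
## lon/lat.

.mandatorySampleCols <- c("site_id", "x", "y", "altitude", "land_use",
                          "soc_a", "soc_o", "o_thickness", "bulk_density",
                          "coarse_pct")

#' Read a soil sample table
#'
#' Parses a CSV of survey points into a \linkS4class{SoilSurvey}. Mandatory
#' columns: \code{site_id, x, y, altitude, land_use, soc_a, soc_o,
#' o_thickness, bulk_density, coarse_pct}; optional: \code{slope, ndvi}.
#' Empty \code{soc_o} / \code{o_thickness} fields are read as "no O
#' horizon". Rows violating the survey invariants are rejected with a
#' row-numbered error.
#'
#' @param path CSV file path.
#' @param crs coordinate-system tag recorded on the survey.
#' @return A \linkS4class{SoilSurvey}.
#' @seealso \code{\link{writeSampleTable}}
#' @export
readSampleTable <- function(path, crs = "local-metric") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(.mandatorySampleCols, names(raw))
  if (length(missing_cols))
    stop("sample table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  num_cols <- setdiff(.surveyColumns, c("site_id", "land_use"))
  for (cl in intersect(num_cols, names(raw))) {
    v <- raw[[cl]]
    v[v == ""] <- NA
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad))
      stop(sprintf("parse error in column '%s', row %d: '%s' is not numeric",
                   cl, bad[1], v[bad[1]]))
    raw[[cl]] <- parsed
  }
  raw$o_thickness[is.na(raw$o_thickness)] <- 0
  soilSurvey(raw, crs = crs)
}

#' Write a soil sample table
#'
#' Inverse of \code{\link{readSampleTable}}; absent O horizons are written
#' as empty fields so the round-trip is exact.
#'
#' @param survey a \linkS4class{SoilSurvey}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSampleTable <- function(survey, path) {
  stopifnot(is(survey, "SoilSurvey"))
  utils::write.csv(survey@sites, path, row.names = FALSE, na = "")
  invisible(path)
}

## ---------------------------------------------------------------------------
## ESRI ASCII grid
## ---------------------------------------------------------------------------

#' Read an ESRI ASCII grid
#'
#' Expects the standard six-line header (\code{ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value}; the nodata line may be absent)
#' followed by \code{nrows} rows of \code{ncols} values, first file row =
#' northernmost. Values equal to the nodata sentinel become \code{NA}.
#'
#' @param path .asc file path.
#' @param crs coordinate-system tag to record.
#' @return A \linkS4class{GridRaster}.
#' @export
readAsciiGrid <- function(path, crs = "local-metric") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ESRI ASCII grid format error: header must define ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows)
    stop(sprintf("ESRI ASCII grid format error: %d data rows, header says %d",
                 length(body), hdr$nrows))
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(lengths(vals) != hdr$ncols))
    stop("ESRI ASCII grid format error: row width does not match ncols")
  ## file rows run north to south; matrix row 1 is the southernmost
  m <- do.call(rbind, rev(vals))
  m[m == nodata] <- NA
  gridRaster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
             nodata = nodata, crs = crs)
}

#' Write an ESRI ASCII grid
#'
#' @param r a \linkS4class{GridRaster}.
#' @param path output .asc path.
#' @param digits significant digits written per value.
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(r, path, digits = 10) {
  stopifnot(is(r, "GridRaster"))
  d <- dim(r@values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", r@xllcorner),
    sprintf("yllcorner %.10g", r@yllcorner),
    sprintf("cellsize %.10g", r@cellsize),
    sprintf("NODATA_value %.10g", r@nodata)), con)
  v <- r@values
  v[is.na(v)] <- r@nodata
  for (i in rev(seq_len(d[1])))      # northernmost row first
    writeLines(paste(formatC(v[i, ], format = "g", digits = digits),
                     collapse = " "), con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Land-use polygons (GeoJSON)
## ---------------------------------------------------------------------------

#' Read land-use polygons from GeoJSON
#'
#' Reads a FeatureCollection of Polygon/MultiPolygon features carrying a
#' \code{land_use} property. Coordinates must already be planar metric.
#' Returns a list with one element per feature: \code{land_use} and
#' \code{rings} (list of x/y matrices; the first ring is the outer
#' boundary, later rings are holes), plus the shoelace \code{area_ha}.
#'
#' @param path GeoJSON file path.
#' @return A list of polygon records, class \code{"landuseMap"}.
#' @export
readLanduseGeoJSON <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (!is.null(g$features)) g$features else list(g)
  polys <- list()
  for (f in feats) {
    lu <- f$properties$land_use
    if (is.null(lu)) stop("GeoJSON feature lacks a 'land_use' property")
    geom <- f$geometry
    ringsets <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type))
    for (rs in ringsets) {
      rings <- lapply(rs, function(ring)
        do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]]))))
      polys[[length(polys) + 1L]] <- list(
        land_use = lu, rings = rings,
        area_ha = .polyNetArea(rings) / 1e4)
    }
  }
  if (!length(polys)) stop("GeoJSON contains no polygons")
  structure(polys, class = "landuseMap")
}

#' Class areas of a land-use map
#'
#' @param m a \code{landuseMap} from \code{\link{readLanduseGeoJSON}}.
#' @return named numeric vector of hectares per land-use class.
#' @export
landuseAreas <- function(m) {
  lus <- vapply(m, `[[`, "", "land_use")
  areas <- vapply(m, `[[`, 0, "area_ha")
  tapply(areas, lus, sum)
}

## shoelace area of one ring (absolute, m2)
.ringArea <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

## outer ring minus holes
.polyNetArea <- function(rings) {
  a <- .ringArea(rings[[1]])
  if (length(rings) > 1)
    a <- a - sum(vapply(rings[-1], .ringArea, 0))
  a
}

## even-odd ray casting; points exactly on an edge count as inside, which
## (with first-polygon-wins iteration) makes the shared-edge tie-break
## deterministic.
.pointInRing <- function(px, py, xy) {
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    ## on-segment test
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- pmin(xi, xj) - 1e-9 <= px & px <= pmax(xi, xj) + 1e-9 &
              pmin(yi, yj) - 1e-9 <= py & py <= pmax(yi, yj) + 1e-9
    on_edge <- on_edge | (abs(cross) < 1e-6 & within)
    crosses <- ((yi > py) != (yj > py)) &
               (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

.pointInPolygon <- function(px, py, rings) {
  inside <- .pointInRing(px, py, rings[[1]])
  if (length(rings) > 1)
    for (hole in rings[-1])
      inside <- inside & !.pointInRing(px, py, hole)
  inside
}

#' Rasterize a land-use polygon map
#'
#' Labels each cell of the template grid with the integer code (index into
#' \code{\link{landUseLevels}}) of the first listed polygon containing the
#' cell centre; uncovered cells are nodata. Cell centres exactly on a
#' shared edge go to the first polygon in file order (documented
#' tie-break).
#'
#' @param m a \code{landuseMap}.
#' @param template a \linkS4class{GridRaster} providing the grid geometry.
#' @return A \linkS4class{GridRaster} of integer class codes.
#' @export
rasterizeLanduse <- function(m, template) {
  stopifnot(is(template, "GridRaster"))
  cc <- cellCenters(template)
  out <- rep(NA_real_, nrow(cc))
  for (p in m) {
    code <- match(p$land_use, landUseLevels)
    if (is.na(code)) stop("unknown land_use class: ", p$land_use)
    todo <- is.na(out)
    if (!any(todo)) break
    hit <- .pointInPolygon(cc[todo, 1], cc[todo, 2], p$rings)
    out[which(todo)[hit]] <- code
  }
  if (all(is.na(out)))
    stop("rasterize error: polygons and template extents are disjoint")
  d <- gridDim(template)
  gridRaster(matrix(out, d[1], d[2]), template@xllcorner,
             template@yllcorner, template@cellsize,
             nodata = template@nodata, crs = template@crs)
}

## ---------------------------------------------------------------------------
## Terrain
## ---------------------------------------------------------------------------

#' Slope of a DEM (Horn's method)
#'
#' Computes slope in degrees per interior cell with Horn's 3x3
#' finite-difference stencil (the de facto GIS standard); border cells are
#' nodata.
#'
#' @param dem a \linkS4class{GridRaster} of altitudes (m).
#' @return A \linkS4class{GridRaster} of slope in degrees.
#' @export
computeSlope <- function(dem) {
  stopifnot(is(dem, "GridRaster"))
  z <- dem@values
  d <- dim(z)
  if (any(d < 3)) stop("size error: slope needs a grid of at least 3 x 3")
  cs <- dem@cellsize
  out <- matrix(NA_real_, d[1], d[2])
  ri <- 2:(d[1] - 1); ci <- 2:(d[2] - 1)
  ## neighbours: rows run south->north so row+1 is the northern neighbour
  zNW <- z[ri + 1, ci - 1]; zN <- z[ri + 1, ci]; zNE <- z[ri + 1, ci + 1]
  zW  <- z[ri,     ci - 1];                      zE  <- z[ri,     ci + 1]
  zSW <- z[ri - 1, ci - 1]; zS <- z[ri - 1, ci]; zSE <- z[ri - 1, ci + 1]
  dzdx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * cs)
  dzdy <- ((zNE + 2 * zN + zNW) - (zSE + 2 * zS + zSW)) / (8 * cs)
  out[ri, ci] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  gridRaster(out, dem@xllcorner, dem@yllcorner, cs,
             nodata = dem@nodata, crs = dem@crs)
}

## ---------------------------------------------------------------------------
## Point sampling of rasters
## ---------------------------------------------------------------------------

#' Sample a raster at point locations (nearest cell)
#'
#' @param r a \linkS4class{GridRaster}.
#' @param x,y point coordinates (m).
#' @return numeric vector of cell values; \code{NA} outside the grid or on
#'   nodata cells.
#' @export
extractAt <- function(r, x, y) {
  d <- dim(r@values)
  col <- floor((x - r@xllcorner) / r@cellsize) + 1
  row <- floor((y - r@yllcorner) / r@cellsize) + 1
  ok <- row >= 1 & row <= d[1] & col >= 1 & col <= d[2]
  out <- rep(NA_real_, length(x))
  out[ok] <- r@values[cbind(row[ok], col[ok])]
  out
}
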