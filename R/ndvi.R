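## NDVI from reflectance rasters and its association with the soil survey.

#' Compute NDVI from NIR and RED reflectance rasters
#'
#' Per cell, NDVI = (NIR - RED) / (NIR + RED); cells where both bands are
#' zero (or either is nodata) propagate as nodata. Values lie in [-1, 1]
#' for nonnegative reflectances.
#'
#' @param nir,red \linkS4class{GridRaster} reflectance bands on one grid.
#' @return list with \code{ndvi} (\linkS4class{GridRaster}) and
#'   \code{stats} (min/max/mean over data cells).
#' @examples
#' nir <- gridRaster(matrix(0.5, 2, 2), 0, 0, 30)
#' red <- gridRaster(matrix(0.25, 2, 2), 0, 0, 30)
#' computeNdvi(nir, red)$stats$mean  # 1/3
#' @export
computeNdvi <- function(nir, red) {
  if (!identical(gridDim(nir), gridDim(red)) ||
      nir@cellsize != red@cellsize ||
      nir@xllcorner != red@xllcorner || nir@yllcorner != red@yllcorner)
    stop("grid error: NIR and RED rasters must share grid geometry")
  a <- nir@values; b <- red@values
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    stop("reflectances must be nonnegative")
  denom <- a + b
  v <- (a - b) / denom
  v[denom == 0] <- NA
  r <- gridRaster(v, nir@xllcorner, nir@yllcorner, nir@cellsize,
                  nodata = nir@nodata, crs = nir@crs)
  ok <- !is.na(v)
  list(ndvi = r,
       stats = list(min = min(v[ok]), max = max(v[ok]), mean = mean(v[ok])))
}

#' Composite monthly NDVI rasters into an annual surface
#'
#' Per-cell aggregate over the valid (non-nodata) months; the default is
#' the arithmetic mean, \code{method = "max"} gives maximum-value
#' compositing.
#'
#' @param rasters list of \linkS4class{GridRaster} on one grid.
#' @param method "mean" or "max".
#' @return A \linkS4class{GridRaster}.
#' @export
compositeNdvi <- function(rasters, method = c("mean", "max")) {
  method <- match.arg(method)
  stopifnot(length(rasters) >= 1)
  d <- gridDim(rasters[[1]])
  for (r in rasters)
    if (!identical(gridDim(r), d))
      stop("grid error: all rasters must share grid geometry")
  arr <- vapply(rasters, function(r) r@values, rasters[[1]]@values)
  agg <- apply(arr, c(1, 2), function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_
    else if (method == "mean") mean(x) else max(x)
  })
  gridRaster(agg, rasters[[1]]@xllcorner, rasters[[1]]@yllcorner,
             rasters[[1]]@cellsize, nodata = rasters[[1]]@nodata,
             crs = rasters[[1]]@crs)
}

#' Correlate NDVI with surveyed SOC
#'
#' Samples the NDVI raster at each site (nearest cell) and returns the
#' Pearson correlation with A-horizon SOC, the pair count, and the paired
#' table for plotting.
#'
#' @param ndvi an NDVI \linkS4class{GridRaster}.
#' @param survey a \linkS4class{SoilSurvey}.
#' @return list with \code{r}, \code{n} and \code{pairs} (data.frame
#'   site_id, ndvi, soc_a).
#' @export
correlateNdviSoc <- function(ndvi, survey) {
  s <- survey@sites
  v <- extractAt(ndvi, s$x, s$y)
  ok <- !is.na(v) & !is.na(s$soc_a)
  if (sum(ok) < 3)
    stop("insufficient data: fewer than 3 sites with valid NDVI")
  list(r = stats::cor(v[ok], s$soc_a[ok]), n = sum(ok),
       pairs = data.frame(site_id = s$site_id[ok], ndvi = v[ok],
                          soc_a = s$soc_a[ok]))
}
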