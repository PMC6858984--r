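#' @import methods
NULL

#' Land-use strata recognised by the package
#'
#' Canonical class labels for the three land-use strata of a high-mountain
#' park: closed forest, natural grassland / high moor, and seasonal
#' agriculture. The order is also the tie-break order used when rasterizing
#' polygons.
#'
#' @export
landUseLevels <- c("forest", "grassland", "agriculture")

## ---------------------------------------------------------------------------
## GridRaster
## ---------------------------------------------------------------------------

#' GridRaster: a georeferenced regular grid
#'
#' A minimal single-band raster on a square-cell regular grid with planar
#' (projected, metric) coordinates. Row 1 of the value matrix is the
#' southernmost row; column 1 the westernmost column; a cell's value refers
#' to its centre. Missing cells are stored as \code{NA} and mapped to the
#' \code{nodata} sentinel on write.
#'
#' @slot values numeric matrix (n_rows x n_cols), \code{NA} = nodata.
#' @slot xllcorner,yllcorner coordinates (m) of the lower-left corner of the
#'   lower-left cell.
#' @slot cellsize cell edge length in metres (square cells).
#' @slot nodata sentinel written to file for \code{NA} cells.
#' @slot crs free-text tag of the projected coordinate reference system.
#' @export
setClass("GridRaster",
  representation(
    values    = "matrix",
    xllcorner = "numeric",
    yllcorner = "numeric",
    cellsize  = "numeric",
    nodata    = "numeric",
    crs       = "character"
  ),
  prototype(nodata = -9999, crs = "local-metric")
)

setValidity("GridRaster", function(object) {
  msgs <- character()
  if (length(object@cellsize) != 1L || !is.finite(object@cellsize) ||
      object@cellsize <= 0)
    msgs <- c(msgs, "cellsize must be a single positive number")
  if (!is.numeric(object@values))
    msgs <- c(msgs, "values must be numeric")
  if (length(object@xllcorner) != 1L || length(object@yllcorner) != 1L)
    msgs <- c(msgs, "xllcorner/yllcorner must be single numbers")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GridRaster
#'
#' @param values numeric matrix; row 1 is the southernmost row.
#' @param xllcorner,yllcorner lower-left corner of the grid (m).
#' @param cellsize cell size (m).
#' @param nodata sentinel value used in files for missing cells.
#' @param crs coordinate-system tag.
#' @return A \linkS4class{GridRaster}.
#' @examples
#' r <- gridRaster(matrix(1:6, 2, 3), 0, 0, 100)
#' dim(values(r))
#' @export
gridRaster <- function(values, xllcorner = 0, yllcorner = 0, cellsize = 1,
                       nodata = -9999, crs = "local-metric") {
  new("GridRaster", values = values, xllcorner = as.numeric(xllcorner),
      yllcorner = as.numeric(yllcorner), cellsize = as.numeric(cellsize),
      nodata = as.numeric(nodata), crs = crs)
}

## ---------------------------------------------------------------------------
## SoilSurvey
## ---------------------------------------------------------------------------

#' SoilSurvey: a table of soil sampling sites
#'
#' Wraps a data frame with one row per survey point: projected coordinates,
#' altitude, land-use stratum, A-horizon SOC concentration, optional
#' O-horizon SOC and thickness, bulk density, coarse-fragment percentage,
#' and optional slope and NDVI covariates. Validity enforces the physical
#' invariants (positive SOC and bulk density, coarse fraction in [0, 100],
#' O-horizon SOC present exactly when the O horizon has thickness).
#'
#' @slot sites data.frame with columns \code{site_id, x, y, altitude,
#'   land_use, soc_a, soc_o, o_thickness, bulk_density, coarse_pct, slope,
#'   ndvi}.
#' @slot crs coordinate-system tag shared by all sites.
#' @export
setClass("SoilSurvey",
  representation(sites = "data.frame", crs = "character"),
  prototype(crs = "local-metric")
)

.surveyColumns <- c("site_id", "x", "y", "altitude", "land_use", "soc_a",
                    "soc_o", "o_thickness", "bulk_density", "coarse_pct",
                    "slope", "ndvi")

setValidity("SoilSurvey", function(object) {
  s <- object@sites
  missing_cols <- setdiff(.surveyColumns, names(s))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  msgs <- character()
  if (nrow(s)) {
    if (anyDuplicated(s$site_id))
      msgs <- c(msgs, "site_id values must be unique")
    if (!all(s$land_use %in% landUseLevels))
      msgs <- c(msgs, paste("land_use must be one of:",
                            paste(landUseLevels, collapse = ", ")))
    bad <- which(!(s$soc_a > 0))
    if (length(bad))
      msgs <- c(msgs, paste0("soc_a must be > 0 (rows ",
                             paste(utils::head(bad, 5), collapse = ","), ")"))
    bad <- which(s$o_thickness < 0)
    if (length(bad))
      msgs <- c(msgs, paste0("o_thickness must be >= 0 (rows ",
                             paste(utils::head(bad, 5), collapse = ","), ")"))
    bad <- which(s$coarse_pct < 0 | s$coarse_pct > 100)
    if (length(bad))
      msgs <- c(msgs, paste0("coarse_pct must lie in [0,100] (rows ",
                             paste(utils::head(bad, 5), collapse = ","), ")"))
    bad <- which(!(s$bulk_density > 0))
    if (length(bad))
      msgs <- c(msgs, paste0("bulk_density must be > 0 (rows ",
                             paste(utils::head(bad, 5), collapse = ","), ")"))
    ## O-horizon SOC is recorded exactly when an O horizon exists
    bad <- which(xor(!is.na(s$soc_o), s$o_thickness > 0))
    if (length(bad))
      msgs <- c(msgs, paste0("soc_o must be present iff o_thickness > 0 ",
                             "(rows ", paste(utils::head(bad, 5),
                                             collapse = ","), ")"))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SoilSurvey from a site table
#'
#' Optional columns (\code{soc_o}, \code{o_thickness}, \code{slope},
#' \code{ndvi}) are filled with \code{NA} / 0 when absent.
#'
#' @param sites data.frame of sampling sites (see \linkS4class{SoilSurvey}).
#' @param crs coordinate-system tag.
#' @return A \linkS4class{SoilSurvey}.
#' @export
soilSurvey <- function(sites, crs = "local-metric") {
  sites <- as.data.frame(sites)
  if (!"soc_o" %in% names(sites)) sites$soc_o <- NA_real_
  if (!"o_thickness" %in% names(sites)) sites$o_thickness <- 0
  if (!"slope" %in% names(sites)) sites$slope <- NA_real_
  if (!"ndvi" %in% names(sites)) sites$ndvi <- NA_real_
  sites$site_id <- as.character(sites$site_id)
  sites$land_use <- as.character(sites$land_use)
  sites$o_thickness[is.na(sites$o_thickness)] <- 0
  new("SoilSurvey", sites = sites[, .surveyColumns], crs = crs)
}

## ---------------------------------------------------------------------------
## Variography
## ---------------------------------------------------------------------------

#' EmpiricalVariogram: binned sample semivariances
#'
#' The classical Matheron estimator evaluated on half-open distance bins:
#' for each bin, half the mean squared difference over all unordered point
#' pairs whose separation falls in the bin. Empty bins carry
#' \code{pair_count = 0} and \code{gamma = NA}.
#'
#' @slot lag_centers bin mid-points (m), strictly increasing.
#' @slot gamma semivariance per bin (data units squared); NA for empty bins.
#' @slot pair_counts number of point pairs per bin.
#' @slot max_lag largest separation considered (m).
#' @slot n_lags number of bins.
#' @export
setClass("EmpiricalVariogram",
  representation(lag_centers = "numeric", gamma = "numeric",
                 pair_counts = "numeric", max_lag = "numeric",
                 n_lags = "integer"))

setValidity("EmpiricalVariogram", function(object) {
  msgs <- character()
  if (any(diff(object@lag_centers) <= 0))
    msgs <- c(msgs, "lag_centers must be strictly increasing")
  if (any(object@gamma < 0, na.rm = TRUE))
    msgs <- c(msgs, "gamma must be nonnegative")
  if (any(object@pair_counts < 0))
    msgs <- c(msgs, "pair_counts must be nonnegative")
  if (length(object@lag_centers) != length(object@gamma) ||
      length(object@gamma) != length(object@pair_counts))
    msgs <- c(msgs, "lag_centers, gamma, pair_counts must share length")
  if (length(msgs)) msgs else TRUE
})

#' VariogramModel: a bounded parametric semivariogram
#'
#' Supported families (h > 0; gamma(0) = 0 by convention):
#' \describe{
#'   \item{exponential}{\eqn{\gamma(h) = c_0 + c (1 - e^{-h/a})}; effective
#'     range \eqn{3a}.}
#'   \item{spherical}{\eqn{\gamma(h) = c_0 + c (1.5 h/a - 0.5 (h/a)^3)} for
#'     \eqn{h \le a}, sill beyond.}
#'   \item{gaussian}{\eqn{\gamma(h) = c_0 + c (1 - e^{-(h/a)^2})}; effective
#'     range \eqn{\sqrt{3} a}.}
#' }
#' with nugget \eqn{c_0}, partial sill \eqn{c}, range parameter \eqn{a};
#' the sill is \eqn{c_0 + c}.
#'
#' @slot family one of "exponential", "spherical", "gaussian".
#' @slot nugget nugget variance (>= 0).
#' @slot psill partial sill (>= 0).
#' @slot range_param distance parameter a (m, > 0).
#' @export
setClass("VariogramModel",
  representation(family = "character", nugget = "numeric",
                 psill = "numeric", range_param = "numeric"))

setValidity("VariogramModel", function(object) {
  msgs <- character()
  if (!object@family %in% c("exponential", "spherical", "gaussian"))
    msgs <- c(msgs, "family must be exponential, spherical or gaussian")
  if (object@nugget < 0) msgs <- c(msgs, "nugget must be >= 0")
  if (object@psill < 0) msgs <- c(msgs, "partial sill must be >= 0")
  if (!(object@range_param > 0)) msgs <- c(msgs, "range must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a VariogramModel
#'
#' @param family model family ("exponential", "spherical", "gaussian").
#' @param nugget nugget variance.
#' @param psill partial sill (sill minus nugget).
#' @param range_param range parameter a in metres.
#' @return A \linkS4class{VariogramModel}.
#' @examples
#' vm <- variogramModel("exponential", nugget = 0.529,
#'                      psill = 2.226 - 0.529, range_param = 3000)
#' sill(vm)
#' @export
variogramModel <- function(family = "exponential", nugget = 0, psill = 1,
                           range_param = 1) {
  new("VariogramModel", family = family, nugget = as.numeric(nugget),
      psill = as.numeric(psill), range_param = as.numeric(range_param))
}

## ---------------------------------------------------------------------------
## Interpolation
## ---------------------------------------------------------------------------

#' NeighborhoodSpec: local search neighbourhood
#'
#' All local interpolators take their data from the nearest
#' \code{max_neighbors} training sites within \code{search_radius} of the
#' prediction location; fewer than \code{min_neighbors} usable sites is a
#' coverage error.
#'
#' @slot max_neighbors maximum neighbours used (default 15).
#' @slot min_neighbors minimum neighbours required (default 4).
#' @slot search_radius search radius in metres (\code{Inf} = unlimited).
#' @export
setClass("NeighborhoodSpec",
  representation(max_neighbors = "integer", min_neighbors = "integer",
                 search_radius = "numeric"),
  prototype(max_neighbors = 15L, min_neighbors = 4L, search_radius = Inf))

setValidity("NeighborhoodSpec", function(object) {
  msgs <- character()
  if (object@min_neighbors > object@max_neighbors)
    msgs <- c(msgs, "min_neighbors must be <= max_neighbors")
  if (object@min_neighbors < 1L)
    msgs <- c(msgs, "min_neighbors must be >= 1")
  if (!(object@search_radius > 0))
    msgs <- c(msgs, "search_radius must be > 0 (use Inf for unlimited)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a NeighborhoodSpec
#'
#' @param max_neighbors,min_neighbors neighbour count bounds.
#' @param search_radius search radius (m), \code{Inf} for unlimited.
#' @return A \linkS4class{NeighborhoodSpec}.
#' @export
neighborhoodSpec <- function(max_neighbors = 15, min_neighbors = 4,
                             search_radius = Inf) {
  new("NeighborhoodSpec", max_neighbors = as.integer(max_neighbors),
      min_neighbors = as.integer(min_neighbors),
      search_radius = as.numeric(search_radius))
}

#' PredictionSurface: interpolated values at target locations
#'
#' @slot coords n x 2 matrix of target coordinates (m).
#' @slot estimates predicted values, one per target.
#' @slot variance prediction variance per target (kriging-type methods) or
#'   length-0 when the method defines none.
#' @slot method_tag short method label ("IDW", "OK", ...).
#' @slot params full parameter echo of the call.
#' @export
setClass("PredictionSurface",
  representation(coords = "matrix", estimates = "numeric",
                 variance = "numeric", method_tag = "character",
                 params = "list"))

setValidity("PredictionSurface", function(object) {
  msgs <- character()
  if (nrow(object@coords) != length(object@estimates))
    msgs <- c(msgs, "one estimate per target required")
  if (length(object@variance) &&
      length(object@variance) != length(object@estimates))
    msgs <- c(msgs, "variance must be absent or one value per target")
  if (any(object@variance < 0, na.rm = TRUE))
    msgs <- c(msgs, "variance must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Validation
## ---------------------------------------------------------------------------

#' HoldoutSplit: stratified train/validation partition
#'
#' @slot train,validation \linkS4class{SoilSurvey} objects partitioning the
#'   input survey.
#' @slot quota named per-stratum validation counts.
#' @slot min_separation requested minimum pairwise distance (m) among
#'   validation sites.
#' @slot achieved_separation smallest realised pairwise validation distance.
#' @slot separation_met whether the requested separation was achieved (if
#'   not, the best-separated draw is returned and this flag is FALSE).
#' @export
setClass("HoldoutSplit",
  representation(train = "SoilSurvey", validation = "SoilSurvey",
                 quota = "numeric", min_separation = "numeric",
                 achieved_separation = "numeric", separation_met = "logical"))

#' CVReport: cross-validation comparison table
#'
#' One row per interpolation method with the four error indices; the
#' ranking orders methods by R-squared (descending), ties broken by RMSE
#' (ascending).
#'
#' @slot table data.frame with columns \code{method, r2, rmse, me, mre}.
#' @slot ranking method tags sorted best first.
#' @export
setClass("CVReport",
  representation(table = "data.frame", ranking = "character"))

setValidity("CVReport", function(object) {
  tb <- object@table
  msgs <- character()
  need <- c("method", "r2", "rmse", "me", "mre")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (any(tb$rmse < 0, na.rm = TRUE)) msgs <- c(msgs, "rmse must be >= 0")
  if (any(tb$mre < 0, na.rm = TRUE)) msgs <- c(msgs, "mre must be >= 0")
  if (any(tb$r2 > 1 + 1e-12, na.rm = TRUE)) msgs <- c(msgs, "r2 must be <= 1")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Stocks
## ---------------------------------------------------------------------------

#' StockLedger: landscape-level SOC stock accounts
#'
#' @slot per_landscape data.frame with columns \code{land_use, horizon,
#'   mean_stock_t_ha, area_ha, total_Tg}.
#' @slot park_total_Tg sum of all landscape x horizon totals (Tg C).
#' @slot shares named fractions of the park total per landscape (sum to 1).
#' @export
setClass("StockLedger",
  representation(per_landscape = "data.frame", park_total_Tg = "numeric",
                 shares = "numeric"))

setValidity("StockLedger", function(object) {
  msgs <- character()
  tot <- sum(object@per_landscape$total_Tg)
  if (abs(tot - object@park_total_Tg) > 1e-9)
    msgs <- c(msgs, "park total must equal the sum of landscape totals")
  if (length(object@shares) &&
      abs(sum(object@shares) - 1) > 1e-9)
    msgs <- c(msgs, "shares must sum to 1")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic survey
## ---------------------------------------------------------------------------

#' SurveyConfig: parameters of the synthetic mountain park
#'
#' Defaults emulate a 482 km2 volcanic national park surveyed at 440
#' sites: three altitude-banded land-use strata with lognormal SOC, a
#' log-scale exponential variogram (nugget 0.529, sill 2.226), land-use
#' specific organic-horizon thickness, and an NDVI surface positively
#' linked to SOC. See \code{\link{surveyConfig}} for field-by-field
#' documentation.
#'
#' @slot seed integer RNG seed.
#' @slot n_sites number of survey points.
#' @slot extent_km park width (km); the park is square.
#' @slot cell_size raster cell size (m).
#' @slot altitude_range c(min, max) altitude (m a.s.l.).
#' @slot strata data.frame: land_use, mean_soc, sd_soc, alt_min, alt_max.
#' @slot mix_prob probability that a cell in the forest/agriculture overlap
#'   altitude band is forest.
#' @slot variogram \linkS4class{VariogramModel} of the log-SOC field.
#' @slot o_thickness_mean named mean O-horizon thickness (cm) per stratum.
#' @slot o_soc_range c(min, max) O-horizon SOC (g/kg).
#' @slot o_bulk_density O-horizon bulk density (g/cm3).
#' @slot bd_range c(min, max) A-horizon bulk density (g/cm3).
#' @slot coarse_range c(min, max) coarse-fragment volume percentage.
#' @slot ndvi_link c(intercept, slope, noise_sd) of the NDVI ~ SOC link.
#' @export
setClass("SurveyConfig",
  representation(seed = "integer", n_sites = "integer", extent_km = "numeric",
                 cell_size = "numeric", altitude_range = "numeric",
                 strata = "data.frame", mix_prob = "numeric",
                 variogram = "VariogramModel",
                 o_thickness_mean = "numeric", o_soc_range = "numeric",
                 o_bulk_density = "numeric", bd_range = "numeric",
                 coarse_range = "numeric", ndvi_link = "numeric"))

setValidity("SurveyConfig", function(object) {
  msgs <- character()
  if (object@n_sites < 10L) msgs <- c(msgs, "n_sites must be >= 10")
  if (!(object@extent_km > 0)) msgs <- c(msgs, "extent_km must be > 0")
  if (any(object@strata$sd_soc <= 0))
    msgs <- c(msgs, "stratum sd_soc must be > 0")
  if (any(object@strata$mean_soc <= 0))
    msgs <- c(msgs, "stratum mean_soc must be > 0")
  if (diff(object@altitude_range) <= 0)
    msgs <- c(msgs, "altitude_range must be increasing")
  if (object@mix_prob < 0 || object@mix_prob > 1)
    msgs <- c(msgs, "mix_prob must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticPark: a generated mountain park
#'
#' All rasters share one grid geometry; the SOC field is strictly positive
#' on data cells. The generating \linkS4class{SurveyConfig} is carried as
#' the ground truth for parameter-recovery experiments.
#'
#' @slot dem altitude raster (m a.s.l.).
#' @slot landuse stratum raster (integer codes into
#'   \code{\link{landUseLevels}}).
#' @slot soc A-horizon SOC raster (g/kg).
#' @slot ndvi NDVI raster in [-1, 1].
#' @slot config the generating \linkS4class{SurveyConfig}.
#' @export
setClass("SyntheticPark",
  representation(dem = "GridRaster", landuse = "GridRaster",
                 soc = "GridRaster", ndvi = "GridRaster",
                 config = "SurveyConfig"))

setValidity("SyntheticPark", function(object) {
  d <- dim(object@dem@values)
  msgs <- character()
  for (nm in c("landuse", "soc", "ndvi")) {
    if (!identical(dim(slot(object, nm)@values), d))
      msgs <- c(msgs, paste0(nm, " raster must share the DEM grid"))
  }
  if (any(object@soc@values <= 0, na.rm = TRUE))
    msgs <- c(msgs, "SOC field must be strictly positive on data cells")
  if (length(msgs)) msgs else TRUE
})
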