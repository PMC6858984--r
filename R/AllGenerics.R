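## Generics and accessors for the core classes. `values` and `sill` are the
## only domain-specific generics; the rest are plain accessors so user code
## never touches slots.

#' Extract the value grid of a raster
#' @param x a \linkS4class{GridRaster}.
#' @return numeric matrix (row 1 = southernmost row).
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
#' @export
setMethod("values", "GridRaster", function(x) x@values)

#' Raster grid geometry helpers
#'
#' \code{cellSize}, \code{origin} and \code{gridDim} expose the grid
#' geometry; \code{cellCenters} returns the x/y coordinates of all cell
#' centres as an (n_cells x 2) matrix in row-major order over the value
#' matrix (south to north within west to east columns follow R's
#' column-major matrix order: index = row + (col-1)*n_rows).
#'
#' @param x a \linkS4class{GridRaster}.
#' @return \code{cellSize}: single number (m); \code{origin}: c(x, y);
#'   \code{gridDim}: c(n_rows, n_cols); \code{cellCenters}: matrix.
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname cellSize
#' @export
setMethod("cellSize", "GridRaster", function(x) x@cellsize)

#' @rdname cellSize
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname cellSize
#' @export
setMethod("origin", "GridRaster",
          function(x) c(x = x@xllcorner, y = x@yllcorner))

#' @rdname cellSize
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname cellSize
#' @export
setMethod("gridDim", "GridRaster", function(x) dim(x@values))

#' @rdname cellSize
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @rdname cellSize
#' @export
setMethod("cellCenters", "GridRaster", function(x) {
  d <- dim(x@values)
  rows <- seq_len(d[1]); cols <- seq_len(d[2])
  xs <- x@xllcorner + (cols - 0.5) * x@cellsize
  ys <- x@yllcorner + (rows - 0.5) * x@cellsize
  cbind(x = rep(xs, each = d[1]), y = rep(ys, times = d[2]))
})

setMethod("show", "GridRaster", function(object) {
  d <- dim(object@values)
  cat(sprintf("GridRaster %d x %d, cell %g m, origin (%g, %g), crs '%s'\n",
              d[1], d[2], object@cellsize, object@xllcorner,
              object@yllcorner, object@crs))
  v <- object@values[!is.na(object@values)]
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g], mean %.4g, %d nodata cells\n",
                min(v), max(v), mean(v), sum(is.na(object@values))))
})

#' Site table of a survey
#' @param x a \linkS4class{SoilSurvey} or \linkS4class{SyntheticPark}.
#' @return data.frame of sampling sites.
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname sites
#' @export
setMethod("sites", "SoilSurvey", function(x) x@sites)

#' Number of sites in a survey
#' @param x a \linkS4class{SoilSurvey}.
#' @export
setMethod("length", "SoilSurvey", function(x) nrow(x@sites))

setMethod("show", "SoilSurvey", function(object) {
  s <- object@sites
  cat(sprintf("SoilSurvey with %d sites (crs '%s')\n", nrow(s), object@crs))
  if (nrow(s)) {
    tb <- table(factor(s$land_use, levels = landUseLevels))
    cat("  strata:", paste(sprintf("%s %d", names(tb), tb), collapse = ", "),
        "\n")
    cat(sprintf("  soc_a: [%.3g, %.3g] g/kg, mean %.3g\n",
                min(s$soc_a), max(s$soc_a), mean(s$soc_a)))
  }
})

#' Total sill of a variogram model
#' @param x a \linkS4class{VariogramModel}.
#' @return nugget + partial sill.
#' @export
setGeneric("sill", function(x) standardGeneric("sill"))

#' @rdname sill
#' @export
setMethod("sill", "VariogramModel", function(x) x@nugget + x@psill)

#' Nugget variance of a variogram model
#' @param x a \linkS4class{VariogramModel}.
#' @export
setGeneric("nugget", function(x) standardGeneric("nugget"))

#' @rdname nugget
#' @export
setMethod("nugget", "VariogramModel", function(x) x@nugget)

#' Effective range of a variogram model
#'
#' Distance at which the model reaches ~95% of the sill: 3a for the
#' exponential family, sqrt(3) a for the gaussian, a for the spherical.
#'
#' @param x a \linkS4class{VariogramModel}.
#' @export
setGeneric("effectiveRange", function(x) standardGeneric("effectiveRange"))

#' @rdname effectiveRange
#' @export
setMethod("effectiveRange", "VariogramModel", function(x) {
  switch(x@family,
         exponential = 3 * x@range_param,
         gaussian = sqrt(3) * x@range_param,
         spherical = x@range_param)
})

setMethod("show", "VariogramModel", function(object) {
  cat(sprintf(paste0("VariogramModel: %s, nugget %.4g, partial sill %.4g, ",
                     "sill %.4g\n  range parameter %.4g m ",
                     "(effective range %.4g m)\n"),
              object@family, object@nugget, object@psill, sill(object),
              object@range_param, effectiveRange(object)))
})

setMethod("show", "EmpiricalVariogram", function(object) {
  cat(sprintf("EmpiricalVariogram: %d lags to %.4g m (%d empty bins)\n",
              object@n_lags, object@max_lag, sum(object@pair_counts == 0)))
})

#' Estimates and prediction variance of a surface
#' @param x a \linkS4class{PredictionSurface}.
#' @return numeric vector, one value per target.
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' @rdname estimates
#' @export
setMethod("estimates", "PredictionSurface", function(x) x@estimates)

#' @rdname estimates
#' @export
setGeneric("predVariance", function(x) standardGeneric("predVariance"))

#' @rdname estimates
#' @export
setMethod("predVariance", "PredictionSurface", function(x) x@variance)

setMethod("show", "PredictionSurface", function(object) {
  cat(sprintf("PredictionSurface [%s]: %d targets", object@method_tag,
              length(object@estimates)))
  if (length(object@variance)) cat(", with prediction variance")
  cat("\n")
})

#' Cross-validation table and ranking
#' @param x a \linkS4class{CVReport}.
#' @return \code{cvTable}: data.frame; \code{cvRanking}: character vector.
#' @export
setGeneric("cvTable", function(x) standardGeneric("cvTable"))

#' @rdname cvTable
#' @export
setMethod("cvTable", "CVReport", function(x) x@table)

#' @rdname cvTable
#' @export
setGeneric("cvRanking", function(x) standardGeneric("cvRanking"))

#' @rdname cvTable
#' @export
setMethod("cvRanking", "CVReport", function(x) x@ranking)

setMethod("show", "CVReport", function(object) {
  cat("CVReport (ranked by R2):\n")
  tb <- object@table[match(object@ranking, object@table$method), ]
  print(format(tb, digits = 4), row.names = FALSE)
})

setMethod("show", "HoldoutSplit", function(object) {
  cat(sprintf(paste0("HoldoutSplit: %d train / %d validation sites\n",
                     "  min separation requested %.0f m, achieved %.0f m",
                     " (%s)\n"),
              length(object@train), length(object@validation),
              object@min_separation, object@achieved_separation,
              if (object@separation_met) "met" else "best effort"))
})

#' Landscape table, park total and shares of a stock ledger
#' @param x a \linkS4class{StockLedger}.
#' @export
setGeneric("stockTable", function(x) standardGeneric("stockTable"))

#' @rdname stockTable
#' @export
setMethod("stockTable", "StockLedger", function(x) x@per_landscape)

#' @rdname stockTable
#' @export
setGeneric("parkTotal", function(x) standardGeneric("parkTotal"))

#' @rdname stockTable
#' @export
setMethod("parkTotal", "StockLedger", function(x) x@park_total_Tg)

#' @rdname stockTable
#' @export
setGeneric("stockShares", function(x) standardGeneric("stockShares"))

#' @rdname stockTable
#' @export
setMethod("stockShares", "StockLedger", function(x) x@shares)

setMethod("show", "StockLedger", function(object) {
  cat(sprintf("StockLedger: park total %.4g Tg C\n", object@park_total_Tg))
  print(format(object@per_landscape, digits = 4), row.names = FALSE)
  cat("  shares:", paste(sprintf("%s %.1f%%", names(object@shares),
                                 100 * object@shares), collapse = ", "), "\n")
})

setMethod("show", "SyntheticPark", function(object) {
  d <- dim(object@dem@values)
  cat(sprintf("SyntheticPark: %d x %d cells of %g m (seed %d)\n",
              d[1], d[2], object@dem@cellsize, object@config@seed))
})
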