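## SOC stock accounting: per-point stocks, per-landscape summary
## statistics, park totals and land-use-change scenarios.

#' Per-point SOC stock
#'
#' stock (t C / ha) = T * SOC * B * (1 - C/100) / 10, with T the layer
#' thickness in cm (15 cm for the A horizon by convention, the measured
#' thickness for the O horizon), SOC the carbon concentration in g/kg,
#' B the bulk density in g/cm3 and C the coarse-fragment volume
#' percentage.
#'
#' @param thickness_cm layer thickness (cm).
#' @param soc_g_kg SOC concentration (g/kg).
#' @param bulk_density_g_cm3 bulk density (g/cm3).
#' @param coarse_pct volume percentage of the >2 mm fraction, in [0, 100].
#' @return stock in t C per hectare.
#' @examples
#' pointStock(15, 40.31, 1.14, 0)  # 68.93 t C/ha, a typical forest topsoil
#' @export
pointStock <- function(thickness_cm, soc_g_kg, bulk_density_g_cm3,
                       coarse_pct = 0) {
  if (any(thickness_cm < 0) || any(soc_g_kg < 0) ||
      any(bulk_density_g_cm3 < 0) || any(coarse_pct < 0))
    stop("domain error: stock inputs must be nonnegative")
  if (any(coarse_pct > 100))
    stop("domain error: coarse_pct cannot exceed 100")
  thickness_cm * soc_g_kg * bulk_density_g_cm3 * (1 - coarse_pct / 100) / 10
}

#' Per-site stock records for a survey
#'
#' One A-horizon record per site (fixed 15 cm) and one O-horizon record
#' where an O horizon exists (measured thickness, the given O bulk
#' density, zero coarse fragments).
#'
#' @param survey a \linkS4class{SoilSurvey}.
#' @param a_thickness_cm A-horizon thickness convention (default 15).
#' @param o_bulk_density O-horizon bulk density (g/cm3, default 0.15).
#' @return data.frame with columns \code{site_id, land_use, horizon,
#'   thickness_cm, stock_t_ha}.
#' @export
surveyStocks <- function(survey, a_thickness_cm = 15, o_bulk_density = 0.15) {
  s <- survey@sites
  a <- data.frame(site_id = s$site_id, land_use = s$land_use, horizon = "A",
                  thickness_cm = a_thickness_cm,
                  stock_t_ha = pointStock(a_thickness_cm, s$soc_a,
                                          s$bulk_density, s$coarse_pct))
  has_o <- s$o_thickness > 0
  if (any(has_o)) {
    o <- data.frame(site_id = s$site_id[has_o], land_use = s$land_use[has_o],
                    horizon = "O", thickness_cm = s$o_thickness[has_o],
                    stock_t_ha = pointStock(s$o_thickness[has_o],
                                            s$soc_o[has_o], o_bulk_density,
                                            0))
    a <- rbind(a, o)
  }
  a
}

## summary statistics of one vector, Table-style: type-7 quartiles,
## n-1 SD, CV as a percentage
.summaryStats <- function(x) {
  n <- length(x)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  sdv <- if (n > 1) stats::sd(x) else NA_real_
  m <- mean(x)
  data.frame(n = n, min = min(x), max = max(x), range = max(x) - min(x),
             mean = m, median = q[2], sd = sdv,
             cv = if (is.na(sdv)) NA_real_ else 100 * sdv / m,
             q1 = q[1], q3 = q[3], iqr = q[3] - q[1])
}

#' Landscape summary statistics of stock records
#'
#' Per landscape and horizon: n, min, max, range, mean, median, SD (n-1),
#' CV (%), type-7 quartiles and IQR. Landscapes without records are
#' omitted with a warning.
#'
#' @param records stock records from \code{\link{surveyStocks}} (or any
#'   data.frame with \code{land_use, horizon, stock_t_ha}).
#' @return data.frame, one row per landscape x horizon plus an
#'   \code{"ecosystem"} row per horizon pooling all landscapes.
#' @export
landscapeSummary <- function(records) {
  out <- list()
  for (hz in unique(records$horizon)) {
    rh <- records[records$horizon == hz, ]
    pooled <- cbind(land_use = "ecosystem", horizon = hz,
                    .summaryStats(rh$stock_t_ha))
    out[[length(out) + 1L]] <- pooled
    for (lu in landUseLevels) {
      x <- rh$stock_t_ha[rh$land_use == lu]
      if (!length(x)) {
        warning(sprintf("landscape '%s' has no %s-horizon records; omitted",
                        lu, hz))
        next
      }
      out[[length(out) + 1L]] <- cbind(land_use = lu, horizon = hz,
                                       .summaryStats(x))
    }
  }
  do.call(rbind, out)
}

#' Total SOC stock ledger
#'
#' total (Tg) = mean stock (t C/ha) x area (ha) x 1e-6 per landscape and
#' horizon; the park total is their sum and each landscape's share is its
#' (all-horizon) total over the park total.
#'
#' @param mean_stocks data.frame with columns \code{land_use, horizon,
#'   mean_stock_t_ha}, or a named vector (then a single "A" horizon is
#'   assumed).
#' @param areas_ha named vector of hectares per landscape.
#' @return A \linkS4class{StockLedger}.
#' @examples
#' ms <- data.frame(land_use = c("forest", "grassland", "agriculture"),
#'                  horizon = "A", mean_stock_t_ha = c(68.94, 21.81, 8.82))
#' areas <- c(forest = 0.390, grassland = 0.070,
#'            agriculture = 0.533) * 48200
#' parkTotal(totalStock(ms, areas))
#' @export
totalStock <- function(mean_stocks, areas_ha) {
  if (!is.data.frame(mean_stocks))
    mean_stocks <- data.frame(land_use = names(mean_stocks), horizon = "A",
                              mean_stock_t_ha = as.numeric(mean_stocks))
  missing_area <- setdiff(unique(mean_stocks$land_use), names(areas_ha))
  if (length(missing_area))
    stop("config error: no area given for landscape(s) ",
         paste(missing_area, collapse = ", "))
  tb <- mean_stocks
  tb$area_ha <- as.numeric(areas_ha[tb$land_use])
  tb$total_Tg <- tb$mean_stock_t_ha * tb$area_ha * 1e-6
  park <- sum(tb$total_Tg)
  by_lu <- tapply(tb$total_Tg, tb$land_use, sum)
  shares <- if (park > 0) as.numeric(by_lu) / park else
    rep(NA_real_, length(by_lu))
  names(shares) <- names(by_lu)
  new("StockLedger", per_landscape = tb, park_total_Tg = park,
      shares = shares)
}

#' Project a land-use change scenario
#'
#' Reassigns each converted landscape's area the per-hectare all-horizon
#' stock density of its target landscape (computed from the ledger) and
#' returns the new park total in Tg. \code{conversion} maps source to
#' target landscape, e.g. \code{c(forest = "agriculture", grassland =
#' "agriculture")} for the all-arable scenario.
#'
#' @param ledger a \linkS4class{StockLedger} describing the present state.
#' @param conversion named character vector, source -> target landscape.
#' @return new park total (Tg C).
#' @export
scenarioStock <- function(ledger, conversion) {
  tb <- ledger@per_landscape
  lus <- unique(tb$land_use)
  unknown <- setdiff(c(names(conversion), unname(conversion)), lus)
  if (length(unknown))
    stop("config error: unknown landscape key(s) ",
         paste(unknown, collapse = ", "))
  area_by_lu <- tapply(tb$area_ha, tb$land_use, max)
  density <- tapply(tb$total_Tg, tb$land_use, sum) / area_by_lu  # Tg/ha
  total <- 0
  for (lu in lus) {
    target <- if (lu %in% names(conversion)) conversion[[lu]] else lu
    total <- total + area_by_lu[[lu]] * density[[target]]
  }
  unname(total)
}

#' Write a stock ledger (and optional scenarios) to CSV + YAML
#'
#' @param ledger a \linkS4class{StockLedger}.
#' @param csv_path,yaml_path output paths (either may be NULL).
#' @param scenarios optional named numeric vector of scenario park totals.
#' @return invisibly, the paths written.
#' @export
writeStockLedger <- function(ledger, csv_path = NULL, yaml_path = NULL,
                             scenarios = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(ledger@per_landscape, csv_path, row.names = FALSE)
  if (!is.null(yaml_path))
    yaml::write_yaml(list(
      park_total_Tg = ledger@park_total_Tg,
      shares = as.list(ledger@shares),
      scenarios_Tg = if (is.null(scenarios)) NULL else as.list(scenarios)),
      yaml_path)
  invisible(c(csv_path, yaml_path))
}
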