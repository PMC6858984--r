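## End-to-end orchestration: simulate (or load) -> variogram -> interpolate
## -> cross-validate -> stocks -> scenarios -> NDVI, from one config list
## or YAML file, with seeded reproducibility and a written manifest.

#' Write the synthetic fixture bundle
#'
#' Generates a synthetic park and survey and writes the file bundle the
#' pipeline consumes: \code{samples.csv}, \code{dem.asc},
#' \code{landuse.asc}, \code{soc.asc}, \code{ndvi.asc} and
#' \code{truth.yaml} (an echo of the generating configuration, including
#' the log-scale variogram truth).
#'
#' @param cfg a \linkS4class{SurveyConfig}.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
makeFixtures <- function(cfg = surveyConfig(), out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create output directory ", out_dir)
  park <- generatePark(cfg)
  survey <- sampleSurvey(park, cfg)
  paths <- c(samples = file.path(out_dir, "samples.csv"),
             dem = file.path(out_dir, "dem.asc"),
             landuse = file.path(out_dir, "landuse.asc"),
             soc = file.path(out_dir, "soc.asc"),
             ndvi = file.path(out_dir, "ndvi.asc"),
             truth = file.path(out_dir, "truth.yaml"))
  writeSampleTable(survey, paths["samples"])
  writeAsciiGrid(park@dem, paths["dem"])
  writeAsciiGrid(park@landuse, paths["landuse"])
  writeAsciiGrid(park@soc, paths["soc"])
  writeAsciiGrid(park@ndvi, paths["ndvi"])
  vm <- cfg@variogram
  yaml::write_yaml(list(
    seed = cfg@seed, n_sites = cfg@n_sites, extent_km = cfg@extent_km,
    cell_size = cfg@cell_size,
    altitude_range = cfg@altitude_range,
    variogram = list(family = vm@family, nugget = vm@nugget,
                     partial_sill = vm@psill, sill = sill(vm),
                     range_param = vm@range_param),
    strata = lapply(seq_len(nrow(cfg@strata)), function(i)
      as.list(cfg@strata[i, ])),
    o_thickness_mean = as.list(cfg@o_thickness_mean),
    o_soc_range = cfg@o_soc_range,
    o_bulk_density = cfg@o_bulk_density,
    bd_range = cfg@bd_range, coarse_range = cfg@coarse_range,
    ndvi_link = as.list(cfg@ndvi_link)), paths["truth"])
  paths
}

#' Default pipeline configuration
#'
#' @param seed master seed for all stages.
#' @param out_dir output directory.
#' @return a config list understood by \code{\link{runPipeline}}.
#' @export
defaultPipelineConfig <- function(seed = 1, out_dir = tempfile("socmap")) {
  list(
    synthetic = list(seed = seed),
    crs_id = "local-metric",
    variogram = list(log_transform = TRUE, detrend_strata = TRUE,
                     family = "exponential", n_lags = 15, max_lag = 5000),
    methods = c("IDW", "LPI", "RBF", "OK", "CK", "EBK"),
    holdout = list(quota = c(grassland = 7, forest = 17, agriculture = 21),
                   min_separation = 1000, seed = seed),
    stocks = list(a_thickness = 15, o_bulk_density = 0.15),
    scenarios = list(all_arable = c(forest = "agriculture",
                                    grassland = "agriculture")),
    surfaces = list(cell_size = 2200),   # coarse map grid for the demo run
    out_dir = out_dir)
}

## replicate the outermost interior ring into the nodata border that the
## 3x3 slope stencil leaves, so slope can serve as a full-coverage covariate
.fillBorder <- function(r) {
  v <- r@values
  d <- dim(v)
  v[1, ] <- v[2, ]; v[d[1], ] <- v[d[1] - 1, ]
  v[, 1] <- v[, 2]; v[, d[2]] <- v[, d[2] - 1]
  gridRaster(v, r@xllcorner, r@yllcorner, r@cellsize, nodata = r@nodata,
             crs = r@crs)
}

.logLine <- function(con, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  writeLines(line, con)
  message(line)
}

#' Run the full SOC mapping pipeline
#'
#' Stages, mirroring a complete survey-to-stocks workflow: load or
#' simulate the survey; fit the log-scale variogram; cross-validate the
#' configured interpolation methods on a stratified spatially separated
#' hold-out split; interpolate prediction surfaces with the best method
#' plus OK; compute per-site stocks, landscape summaries, the park stock
#' ledger and the configured land-use-change scenarios; quantify the
#' NDVI-SOC association. All outputs land in \code{cfg$out_dir}; the
#' manifest lists every file written. Identical config + seed give
#' identical outputs.
#'
#' @param cfg config list (see \code{\link{defaultPipelineConfig}}) or
#'   path to a YAML file with the same structure.
#' @return invisibly, a list with \code{status} (0 = ok), \code{manifest}
#'   (named file paths) and the key in-memory results (variogram model,
#'   CV report, stock ledger, scenario totals, NDVI correlation).
#' @export
runPipeline <- function(cfg = defaultPipelineConfig()) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  has_synth <- !is.null(cfg$synthetic)
  has_input <- !is.null(cfg$input)
  if (has_synth == has_input)
    stop("config error: exactly one of 'synthetic' or 'input' must be given")
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("config error: out_dir required")
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))

  ## ---- stage: data -------------------------------------------------------
  stage <- "data"
  result <- tryCatch({
    if (has_synth) {
      sc_args <- cfg$synthetic
      scfg <- do.call(surveyConfig, sc_args)
      .logLine(log_con, stage, sprintf("simulating park (seed %d, %d sites)",
                                       scfg@seed, scfg@n_sites))
      park <- generatePark(scfg)
      survey <- sampleSurvey(park, scfg)
      dem <- park@dem; landuse_r <- park@landuse; ndvi_r <- park@ndvi
    } else {
      .logLine(log_con, stage, paste("reading", cfg$input$samples))
      survey <- readSampleTable(cfg$input$samples,
                                crs = if (is.null(cfg$crs_id)) "local-metric"
                                      else cfg$crs_id)
      dem <- if (!is.null(cfg$input$dem)) readAsciiGrid(cfg$input$dem)
             else NULL
      landuse_r <- if (!is.null(cfg$input$landuse))
        readAsciiGrid(cfg$input$landuse) else NULL
      ndvi_r <- if (!is.null(cfg$input$ndvi))
        readAsciiGrid(cfg$input$ndvi) else NULL
      park <- NULL
    }
    samples_echo <- file.path(out_dir, "samples.csv")
    writeSampleTable(survey, samples_echo)
    manifest["samples"] <- samples_echo

    ## ---- stage: variogram ------------------------------------------------
    stage <- "variogram"
    vopt <- cfg$variogram
    log_tf <- isTRUE(vopt$log_transform)
    z <- survey@sites$soc_a
    vz <- if (log_tf) log(z) else z
    if (isTRUE(vopt$detrend_strata)) {
      ## stationary residuals: remove per-stratum means before variography
      mu <- tapply(vz, survey@sites$land_use, mean)
      vz_fit <- vz - mu[survey@sites$land_use]
    } else vz_fit <- vz
    ev <- empiricalVariogram(as.matrix(survey@sites[, c("x", "y")]),
                             values = vz_fit,
                             max_lag = vopt$max_lag,
                             n_lags = if (is.null(vopt$n_lags)) 15
                                      else vopt$n_lags)
    vm <- fitVariogram(ev, if (is.null(vopt$family)) "exponential"
                           else vopt$family)
    nsr <- nuggetSillRatio(vm)
    .logLine(log_con, stage,
             sprintf("fitted %s: nugget %.3f sill %.3f range %.0f m; %s",
                     vm@family, vm@nugget, sill(vm), vm@range_param,
                     sprintf("nugget-sill ratio %.3f (%s dependence)",
                             nsr$ratio, nsr$dependence)))
    manifest["variogram_csv"] <- writeVariogramCSV(
      ev, file.path(out_dir, "variogram.csv"))
    manifest["variogram_yaml"] <- writeVariogramYAML(
      vm, file.path(out_dir, "variogram.yaml"))

    ## ---- stage: crossval ---------------------------------------------------
    stage <- "crossval"
    hopt <- cfg$holdout
    split <- splitHoldout(survey, quota = unlist(hopt$quota),
                          min_separation = hopt$min_separation,
                          seed = hopt$seed)
    .logLine(log_con, stage,
             sprintf("split %d/%d, min validation separation %.0f m",
                     length(split@train), length(split@validation),
                     split@achieved_separation))
    secondary <- NULL
    if (!is.null(ndvi_r)) secondary <- c(secondary, list(ndvi_r))
    if (!is.null(dem))
      secondary <- c(secondary, list(dem, .fillBorder(computeSlope(dem))))
    mc <- defaultMethodConfigs(seed = hopt$seed)[cfg$methods]
    report <- compareMethods(split, mc, vm, secondary = secondary,
                             log_transform = log_tf)
    .logLine(log_con, stage, paste("ranking:",
                                   paste(report@ranking, collapse = " > ")))
    manifest["cv_report"] <- writeCVReport(
      report, file.path(out_dir, "cv_report.csv"))

    ## ---- stage: surfaces ---------------------------------------------------
    stage <- "surfaces"
    if (!is.null(dem) && !is.null(cfg$surfaces)) {
      cs <- cfg$surfaces$cell_size
      ext <- gridDim(dem) * cellSize(dem)
      tpl <- gridRaster(matrix(NA_real_, max(2, floor(ext[1] / cs)),
                               max(2, floor(ext[2] / cs))),
                        dem@xllcorner, dem@yllcorner, cs)
      tr_coords <- as.matrix(survey@sites[, c("x", "y")])
      tr_values <- if (log_tf) log(survey@sites$soc_a) else
        survey@sites$soc_a
      for (tag in intersect(c("OK", report@ranking[1]), cfg$methods)) {
        ps <- .runMethod(mc[[tag]], tr_coords, tr_values,
                         cellCenters(tpl), vm, secondary)
        est <- estimates(ps)
        if (log_tf) est <- exp(est)
        d <- gridDim(tpl)
        est_r <- gridRaster(matrix(est, d[1], d[2]), tpl@xllcorner,
                            tpl@yllcorner, cs)
        p_est <- file.path(out_dir, sprintf("surface_%s.asc", tag))
        writeAsciiGrid(est_r, p_est)
        manifest[paste0("surface_", tag)] <- p_est
        if (length(predVariance(ps))) {
          var_r <- gridRaster(matrix(predVariance(ps), d[1], d[2]),
                              tpl@xllcorner, tpl@yllcorner, cs)
          p_var <- file.path(out_dir, sprintf("surface_%s_variance.asc", tag))
          writeAsciiGrid(var_r, p_var)
          manifest[paste0("surface_", tag, "_variance")] <- p_var
        }
        .logLine(log_con, stage, sprintf("wrote %s surface", tag))
      }
    }

    ## ---- stage: stocks -----------------------------------------------------
    stage <- "stocks"
    sopt <- cfg$stocks
    records <- surveyStocks(survey,
                            a_thickness_cm = if (is.null(sopt$a_thickness))
                              15 else sopt$a_thickness,
                            o_bulk_density = if (is.null(sopt$o_bulk_density))
                              0.15 else sopt$o_bulk_density)
    summary_tb <- landscapeSummary(records)
    manifest["landscape_summary"] <- file.path(out_dir,
                                               "landscape_summary.csv")
    utils::write.csv(summary_tb, manifest["landscape_summary"],
                     row.names = FALSE)
    areas <- unlist(sopt$areas)
    if (is.null(areas)) {
      if (is.null(landuse_r))
        stop("config error: stock areas missing and no land-use raster")
      codes <- as.vector(landuse_r@values)
      cell_ha <- cellSize(landuse_r)^2 / 1e4
      tab <- table(factor(landUseLevels[codes], levels = landUseLevels))
      areas <- as.numeric(tab) * cell_ha
      names(areas) <- names(tab)
    }
    mean_tb <- summary_tb[summary_tb$land_use != "ecosystem",
                          c("land_use", "horizon", "mean")]
    names(mean_tb)[3] <- "mean_stock_t_ha"
    ledger <- totalStock(mean_tb, areas)
    .logLine(log_con, stage,
             sprintf("park total %.3f Tg C", ledger@park_total_Tg))
    scen <- vapply(cfg$scenarios, function(cv)
      scenarioStock(ledger, unlist(cv)), 0)
    for (nm in names(scen))
      .logLine(log_con, stage, sprintf("scenario %s: %.3f Tg C", nm,
                                       scen[nm]))
    manifest["stock_ledger"] <- file.path(out_dir, "stock_ledger.csv")
    manifest["stock_yaml"] <- file.path(out_dir, "stocks.yaml")
    writeStockLedger(ledger, manifest["stock_ledger"],
                     manifest["stock_yaml"], scenarios = scen)

    ## ---- stage: ndvi -------------------------------------------------------
    stage <- "ndvi"
    ndvi_cor <- NULL
    if (!is.null(ndvi_r)) {
      ndvi_cor <- correlateNdviSoc(ndvi_r, survey)
      .logLine(log_con, stage,
               sprintf("NDVI-SOC Pearson r %.3f (n = %d)", ndvi_cor$r,
                       ndvi_cor$n))
      manifest["ndvi_pairs"] <- file.path(out_dir, "ndvi_soc_pairs.csv")
      utils::write.csv(ndvi_cor$pairs, manifest["ndvi_pairs"],
                       row.names = FALSE)
    }

    manifest["log"] <- log_path
    list(status = 0L, manifest = manifest, variogram = vm,
         nugget_sill = nsr, cv_report = report, ledger = ledger,
         scenarios = scen, ndvi_correlation = ndvi_cor, split = split,
         survey = survey)
  }, error = function(e) {
    .logLine(log_con, stage, paste("FAILED:", conditionMessage(e)))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
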