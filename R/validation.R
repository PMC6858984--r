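## Hold-out cross-validation harness: stratified spatially separated
## split, error indices, and the six-method comparison table.

#' Stratified spatially separated hold-out split
#'
#' Draws \code{sum(quota)} validation sites, \code{quota[s]} from each
#' stratum, by seeded rejection sampling: up to \code{max_attempts}
#' stratified draws are made and the first whose validation sites are
#' pairwise at least \code{min_separation} apart is returned; if none
#' achieves it, the best-separated draw is returned with
#' \code{separation_met = FALSE}.
#'
#' @param survey a \linkS4class{SoilSurvey}.
#' @param quota named vector of validation counts per stratum
#'   (e.g. \code{c(grassland = 7, forest = 17, agriculture = 21)}).
#' @param min_separation minimum pairwise distance (m) among validation
#'   sites (default 1000).
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling budget (default 1000).
#' @return A \linkS4class{HoldoutSplit}.
#' @export
splitHoldout <- function(survey, quota = c(grassland = 7, forest = 17,
                                           agriculture = 21),
                         min_separation = 1000, seed = 1,
                         max_attempts = 1000) {
  stopifnot(is(survey, "SoilSurvey"))
  s <- survey@sites
  for (st in names(quota)) {
    avail <- sum(s$land_use == st)
    if (avail < quota[[st]])
      stop(sprintf("config error: stratum '%s' has %d sites, quota is %d",
                   st, avail, quota[[st]]))
  }
  set.seed(as.integer(seed))
  best_idx <- NULL
  best_sep <- -Inf
  for (attempt in seq_len(max_attempts)) {
    idx <- unlist(lapply(names(quota), function(st)
      sample(which(s$land_use == st), quota[[st]])))
    sep <- min(stats::dist(s[idx, c("x", "y")]))
    if (sep > best_sep) { best_sep <- sep; best_idx <- idx }
    if (sep >= min_separation) break
  }
  validation <- soilSurvey(s[best_idx, ], crs = survey@crs)
  train <- soilSurvey(s[-best_idx, ], crs = survey@crs)
  new("HoldoutSplit", train = train, validation = validation,
      quota = as.numeric(quota), min_separation = min_separation,
      achieved_separation = best_sep,
      separation_met = best_sep >= min_separation)
}

#' Cross-validation error indices
#'
#' ME = mean(observed - predicted); RMSE = root mean squared difference;
#' MRE = RMSE / Delta with Delta the observed range of the validation
#' data (or of \code{full_range} when supplied); R2 = squared Pearson
#' correlation of observed vs predicted.
#'
#' @param observed,predicted equal-length numeric vectors (n >= 2).
#' @param full_range optional vector whose range supplies Delta instead of
#'   the validation observations.
#' @return list with \code{me}, \code{rmse}, \code{mre}, \code{r2}.
#' @examples
#' errorIndices(c(1, 2, 3), c(2, 2, 2))  # me 0, rmse 0.816, mre 0.408
#' @export
errorIndices <- function(observed, predicted, full_range = NULL) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  resid <- observed - predicted
  me <- mean(resid)
  rmse <- sqrt(mean(resid^2))
  delta <- diff(range(if (is.null(full_range)) observed else full_range))
  if (!(delta > 0)) stop("mre undefined: observed range is zero")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    if (rmse == 0)
      return(list(me = me, rmse = rmse, mre = rmse / delta, r2 = 1))
    warning("r2 undefined: zero variance in observed or predicted values")
    return(list(me = me, rmse = rmse, mre = rmse / delta, r2 = NA_real_))
  }
  list(me = me, rmse = rmse, mre = rmse / delta,
       r2 = stats::cor(observed, predicted)^2)
}

#' Default configurations of the six interpolation methods
#'
#' @param seed seed forwarded to the EBK spectrum.
#' @param nb shared \linkS4class{NeighborhoodSpec}.
#' @return named list of method-config lists understood by
#'   \code{\link{compareMethods}}.
#' @export
defaultMethodConfigs <- function(seed = 1, nb = neighborhoodSpec()) {
  list(
    IDW = list(fun = "idw", beta = 2, nb = nb),
    LPI = list(fun = "lpi", order = 1, nb = nb),
    RBF = list(fun = "rbf", basis = "spline_with_tension", nb = nb),
    OK  = list(fun = "ok", nb = nb),
    CK  = list(fun = "ck", nb = nb),
    EBK = list(fun = "ebk", subset_size = 100, overlap = 0.5,
               n_simulations = 30, seed = seed, nb = nb))
}

## run one configured method; values are the (possibly log) training values
.runMethod <- function(cfg, train_coords, train_values, targets, vm,
                       secondary) {
  nb <- if (!is.null(cfg$nb)) cfg$nb else neighborhoodSpec()
  switch(cfg$fun,
    idw = idwPredict(train_coords, targets, values = train_values,
                     beta = if (is.null(cfg$beta)) 2 else cfg$beta, nb = nb),
    lpi = lpiPredict(train_coords, targets, values = train_values,
                     order = if (is.null(cfg$order)) 1 else cfg$order,
                     bandwidth = cfg$bandwidth, nb = nb),
    rbf = rbfPredict(train_coords, targets, values = train_values,
                     basis = if (is.null(cfg$basis)) "thin_plate_spline"
                             else cfg$basis,
                     shape_param = if (is.null(cfg$shape_param)) 1
                                   else cfg$shape_param, nb = nb),
    ok  = okPredict(train_coords, targets, vm, values = train_values,
                    nb = nb),
    ck  = ckPredict(train_coords, secondary, targets, vm,
                    values = train_values, nb = nb),
    ebk = ebkPredict(train_coords, targets, values = train_values,
                     subset_size = if (is.null(cfg$subset_size)) 100
                                   else cfg$subset_size,
                     overlap = if (is.null(cfg$overlap)) 0.5 else cfg$overlap,
                     n_simulations = if (is.null(cfg$n_simulations)) 100
                                     else cfg$n_simulations,
                     seed = if (is.null(cfg$seed)) 1 else cfg$seed, nb = nb),
    stop("unknown method fun: ", cfg$fun))
}

#' Compare interpolation methods on a hold-out split
#'
#' Trains every configured method on the training sites, predicts the
#' validation sites, and tabulates the error indices. With
#' \code{log_transform = TRUE} (the convention for skewed SOC data) the
#' methods are trained on natural-log values and, by default, the error
#' indices are computed on that same log scale — the scale on which the
#' interpolation models operate and on which errors are near-Gaussian.
#' \code{back_transform = TRUE} instead exponentiates the predictions and
#' scores on the original concentration scale (heavier-tailed, so the
#' indices are dominated by the largest values). The ranking orders
#' methods by R2 descending, ties broken by RMSE ascending.
#'
#' @param split a \linkS4class{HoldoutSplit}.
#' @param method_configs named list of method configs (see
#'   \code{\link{defaultMethodConfigs}}).
#' @param vm \linkS4class{VariogramModel} on the (possibly log) scale used
#'   by the kriging-type methods.
#' @param secondary list of secondary rasters for cokriging (NULL drops
#'   CK's secondaries).
#' @param value site-table column holding the predictand.
#' @param log_transform train on natural-log values.
#' @param back_transform score exp(predictions) against raw observations
#'   instead of scoring on the log scale.
#' @return A \linkS4class{CVReport}.
#' @export
compareMethods <- function(split, method_configs, vm, secondary = NULL,
                           value = "soc_a", log_transform = TRUE,
                           back_transform = FALSE) {
  stopifnot(is(split, "HoldoutSplit"), length(method_configs) >= 1)
  tr <- split@train@sites
  va <- split@validation@sites
  train_coords <- as.matrix(tr[, c("x", "y")])
  targets <- as.matrix(va[, c("x", "y")])
  z <- tr[[value]]
  train_values <- if (log_transform) log(z) else z
  observed <- if (log_transform && !back_transform) log(va[[value]])
              else va[[value]]
  rows <- vector("list", length(method_configs))
  for (k in seq_along(method_configs)) {
    tag <- names(method_configs)[k]
    ps <- tryCatch(
      .runMethod(method_configs[[k]], train_coords, train_values, targets,
                 vm, secondary),
      error = function(e) stop(sprintf("[%s] %s", tag, conditionMessage(e))))
    pred <- estimates(ps)
    if (log_transform && back_transform) pred <- exp(pred)
    ei <- errorIndices(observed, pred)
    rows[[k]] <- data.frame(method = tag, r2 = ei$r2, rmse = ei$rmse,
                            me = ei$me, mre = ei$mre)
  }
  tb <- do.call(rbind, rows)
  ranking <- tb$method[order(-tb$r2, tb$rmse)]
  new("CVReport", table = tb, ranking = as.character(ranking))
}

#' Write a cross-validation report as CSV
#'
#' @param report a \linkS4class{CVReport}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCVReport <- function(report, path) {
  utils::write.csv(report@table, path, row.names = FALSE)
  invisible(path)
}
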