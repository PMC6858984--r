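## Semivariogram estimation, model fitting and spatial-dependence
## classification. The empirical estimator is the classical Matheron
## moment estimator on half-open distance bins; fitting is Cressie-weighted
## least squares with deterministic multi-start.

#' Evaluate a variogram model
#'
#' \code{gammaModel(vm, h)} returns the model semivariance at lag h (>= 0),
#' with \code{gammaModel(vm, 0) == 0} (the nugget is the h -> 0+ limit).
#'
#' @param vm a \linkS4class{VariogramModel}.
#' @param h numeric lags (m).
#' @return semivariances, same length as \code{h}.
#' @export
gammaModel <- function(vm, h) {
  a <- vm@range_param
  struct <- switch(vm@family,
    exponential = 1 - exp(-h / a),
    gaussian = 1 - exp(-(h / a)^2),
    spherical = ifelse(h >= a, 1, 1.5 * h / a - 0.5 * (h / a)^3))
  out <- vm@nugget + vm@psill * struct
  out[h == 0] <- 0
  out
}

#' Empirical semivariogram
#'
#' Bins all unordered site pairs by separation distance into \code{n_lags}
#' half-open bins \code{[low, high)} of equal width up to \code{max_lag}
#' and computes, per bin, half the mean squared value difference. Empty
#' bins are reported with \code{pair_count} 0 and \code{gamma = NA}.
#'
#' @param object a \linkS4class{SoilSurvey}, or an n x 2 coordinate matrix.
#' @param values values at the sites; defaults to the survey's
#'   \code{soc_a} column (after \code{log} if requested).
#' @param value column of the site table to use when \code{values} is
#'   missing.
#' @param log if TRUE, natural-log transform the values first (the
#'   convention used for skewed SOC data before variography).
#' @param max_lag largest separation considered; default half the maximum
#'   pairwise distance.
#' @param n_lags number of bins (default 15).
#' @return An \linkS4class{EmpiricalVariogram}.
#' @export
empiricalVariogram <- function(object, values = NULL, value = "soc_a",
                               log = FALSE, max_lag = NULL, n_lags = 15) {
  if (is(object, "SoilSurvey")) {
    coords <- as.matrix(object@sites[, c("x", "y")])
    if (is.null(values)) values <- object@sites[[value]]
  } else {
    coords <- as.matrix(object)
    if (is.null(values)) stop("values required with a coordinate matrix")
  }
  if (nrow(coords) < 2) stop("at least two sites required")
  if (log) values <- base::log(values)
  dm <- as.vector(stats::dist(coords))
  if (is.null(max_lag)) max_lag <- max(dm) / 2
  if (!(max_lag > 0)) stop("max_lag must be > 0")
  n_lags <- as.integer(n_lags)
  ## half the squared difference per unordered pair, in dist order
  n <- nrow(coords)
  dz2 <- as.vector(stats::dist(matrix(values, ncol = 1)))^2 / 2
  keep <- dm < max_lag
  if (!any(keep)) stop("empty variogram: all pairs lie beyond max_lag")
  width <- max_lag / n_lags
  bin <- pmin(floor(dm[keep] / width), n_lags - 1) + 1L
  counts <- tabulate(bin, nbins = n_lags)
  sums <- rep(0, n_lags)
  agg <- tapply(dz2[keep], bin, sum)
  sums[as.integer(names(agg))] <- agg
  gamma <- ifelse(counts > 0, sums / counts, NA_real_)
  ## abscissa = mean pair distance per bin (less biased than the midpoint
  ## when pair distances are unevenly spread within a bin); empty bins
  ## keep the midpoint so the centres stay strictly increasing
  centers <- (seq_len(n_lags) - 0.5) * width
  dsum <- rep(0, n_lags)
  dagg <- tapply(dm[keep], bin, sum)
  dsum[as.integer(names(dagg))] <- dagg
  centers[counts > 0] <- (dsum / counts)[counts > 0]
  new("EmpiricalVariogram",
      lag_centers = centers,
      gamma = gamma, pair_counts = as.numeric(counts),
      max_lag = max_lag, n_lags = n_lags)
}

## Cressie WLS objective: sum N(h) * (gamma_emp/gamma_mod - 1)^2
.wlsObjective <- function(par, family, lags, gamma, counts) {
  vm <- new("VariogramModel", family = family, nugget = par[1],
            psill = par[2], range_param = par[3])
  gm <- gammaModel(vm, lags)
  gm <- pmax(gm, 1e-12)
  sum(counts * (gamma / gm - 1)^2)
}

#' Fit a variogram model by weighted least squares
#'
#' Minimises the Cressie objective \eqn{\sum_h N(h) (\hat\gamma(h) /
#' \gamma_{model}(h) - 1)^2} over (nugget, partial sill, range) under
#' nonnegativity bounds, restarting L-BFGS-B from five deterministic
#' initialisations (combinations of 0 / half the empirical variance for
#' the nugget and fractions of the maximum lag for the range) and keeping
#' the best objective.
#'
#' @param ev an \linkS4class{EmpiricalVariogram} with >= 4 non-empty bins.
#' @param family model family to fit.
#' @param inits optional list of c(nugget, psill, range) start vectors
#'   replacing the five deterministic defaults (used e.g. for warm-started
#'   bootstrap refits).
#' @return A \linkS4class{VariogramModel} with attribute
#'   \code{"objective"} (achieved WLS objective) and \code{"initials"}
#'   (objective at each start).
#' @export
fitVariogram <- function(ev, family = "exponential", inits = NULL) {
  stopifnot(is(ev, "EmpiricalVariogram"))
  ok <- ev@pair_counts > 0 & !is.na(ev@gamma)
  if (sum(ok) < 4) stop("fit error: need >= 4 non-empty variogram bins")
  lags <- ev@lag_centers[ok]
  gamma <- ev@gamma[ok]
  counts <- ev@pair_counts[ok]
  if (all(gamma == 0)) stop("fit error: degenerate variogram (all gamma 0)")
  s2 <- max(gamma)
  hmax <- max(lags)
  if (is.null(inits)) inits <- list(
    c(0,          s2,      hmax / 3),
    c(s2 / 2,     s2 / 2,  hmax / 3),
    c(gamma[1],   s2,      hmax / 6),
    c(0,          s2,      hmax),
    c(s2 / 4, 3 * s2 / 4,  hmax / 10))
  lower <- c(0, 0, hmax * 1e-4)
  upper <- c(2 * s2, 5 * s2, 10 * hmax)
  inits <- lapply(inits, function(p) pmin(pmax(p, lower), upper))
  best <- NULL
  init_obj <- numeric(length(inits))
  for (k in seq_along(inits)) {
    fit <- try(stats::optim(inits[[k]], .wlsObjective, method = "L-BFGS-B",
                            lower = lower, upper = upper, family = family,
                            lags = lags, gamma = gamma, counts = counts,
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) { init_obj[k] <- NA; next }
    init_obj[k] <- fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("fit error: all optimisation starts failed")
  vm <- new("VariogramModel", family = family, nugget = best$par[1],
            psill = best$par[2], range_param = best$par[3])
  attr(vm, "objective") <- best$value
  attr(vm, "initials") <- init_obj
  vm
}

#' Nugget-sill ratio and spatial-dependence class
#'
#' The ratio nugget/sill classifies spatial dependence: below 0.25 strong,
#' 0.25 to 0.75 moderate, above 0.75 weak.
#'
#' @param vm a \linkS4class{VariogramModel} with positive sill.
#' @return list with \code{ratio} and \code{dependence} ("strong",
#'   "moderate" or "weak").
#' @examples
#' vm <- variogramModel("exponential", 0.529, 2.226 - 0.529, 3000)
#' nuggetSillRatio(vm)   # ratio 0.238, strong dependence
#' @export
nuggetSillRatio <- function(vm) {
  s <- sill(vm)
  if (!(s > 0)) stop("undefined ratio: sill is zero")
  ratio <- vm@nugget / s
  dependence <- if (ratio < 0.25) "strong"
                else if (ratio <= 0.75) "moderate"
                else "weak"
  list(ratio = ratio, dependence = dependence)
}

#' Export / import variogram artifacts
#'
#' \code{writeVariogramCSV} writes the empirical variogram as a
#' (lag, gamma, n_pairs) table; \code{writeVariogramYAML} /
#' \code{readVariogramYAML} round-trip a fitted model.
#'
#' @param ev an \linkS4class{EmpiricalVariogram}.
#' @param vm a \linkS4class{VariogramModel}.
#' @param path output file path.
#' @return \code{path} (writers, invisibly) or the re-read model.
#' @export
writeVariogramCSV <- function(ev, path) {
  utils::write.csv(data.frame(lag = ev@lag_centers, gamma = ev@gamma,
                              n_pairs = ev@pair_counts),
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeVariogramCSV
#' @export
writeVariogramYAML <- function(vm, path) {
  yaml::write_yaml(list(family = vm@family, nugget = vm@nugget,
                        partial_sill = vm@psill, sill = sill(vm),
                        range_param = vm@range_param,
                        effective_range = effectiveRange(vm)), path)
  invisible(path)
}

#' @rdname writeVariogramCSV
#' @export
readVariogramYAML <- function(path) {
  y <- yaml::read_yaml(path)
  variogramModel(y$family, y$nugget, y$partial_sill, y$range_param)
}
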