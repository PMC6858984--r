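## The six prediction engines: inverse distance weighting (IDW), local
## polynomial interpolation (LPI), radial basis functions (RBF, five
## kernels), ordinary kriging (OK), ordinary cokriging (CK) and a
## spectrum-of-semivariograms empirical Bayes kriging (EBK). All share one
## interface: (training sites, target locations) -> PredictionSurface.

## ---- shared plumbing ------------------------------------------------------

.asCoordsValues <- function(train, values, value) {
  if (is(train, "SoilSurvey")) {
    coords <- as.matrix(train@sites[, c("x", "y")])
    if (is.null(values)) values <- train@sites[[value]]
  } else {
    coords <- as.matrix(train)
    if (is.null(values)) stop("values required with a coordinate matrix")
  }
  storage.mode(coords) <- "double"
  list(coords = coords, z = as.numeric(values))
}

.asTargets <- function(targets) {
  if (is(targets, "GridRaster")) cellCenters(targets)
  else {
    m <- as.matrix(targets)
    storage.mode(m) <- "double"
    m
  }
}

## average duplicate coordinates (exact ties) into one site; used by the
## kriging-type methods to keep their systems nonsingular
.dedupeSites <- function(coords, z, quiet = FALSE) {
  key <- paste(coords[, 1], coords[, 2])
  if (!anyDuplicated(key)) return(list(coords = coords, z = z))
  if (!quiet)
    warning("duplicate site coordinates averaged before kriging")
  agg_z <- tapply(z, key, mean)
  first <- !duplicated(key)
  ord <- match(key[first], names(agg_z))
  list(coords = coords[first, , drop = FALSE], z = as.numeric(agg_z[ord]))
}

.neighborIdx <- function(tx, ty, coords, nb) {
  d <- sqrt((coords[, 1] - tx)^2 + (coords[, 2] - ty)^2)
  idx <- which(d <= nb@search_radius)
  idx[order(d[idx])][seq_len(min(length(idx), nb@max_neighbors))]
}

.coverageError <- function(which_targets, method) {
  stop(sprintf("coverage error [%s]: fewer than min_neighbors at target(s) %s",
               method, paste(utils::head(which_targets, 10), collapse = ", ")))
}

.newSurface <- function(targets, est, var, tag, params) {
  new("PredictionSurface", coords = targets, estimates = est,
      variance = if (is.null(var)) numeric(0) else var,
      method_tag = tag, params = params)
}

#' Write a prediction surface onto a raster grid
#'
#' Reshapes a \linkS4class{PredictionSurface} whose targets are the cell
#' centres of \code{template} back into rasters.
#'
#' @param ps a \linkS4class{PredictionSurface} predicted at
#'   \code{cellCenters(template)}.
#' @param template the \linkS4class{GridRaster} that supplied the targets.
#' @return list with \code{estimate} and (when defined) \code{variance}
#'   rasters.
#' @export
surfaceToRaster <- function(ps, template) {
  d <- gridDim(template)
  if (nrow(ps@coords) != prod(d))
    stop("surface was not predicted on this template's cell centres")
  out <- list(estimate = gridRaster(matrix(ps@estimates, d[1], d[2]),
                                    template@xllcorner, template@yllcorner,
                                    template@cellsize, crs = template@crs))
  if (length(ps@variance))
    out$variance <- gridRaster(matrix(ps@variance, d[1], d[2]),
                               template@xllcorner, template@yllcorner,
                               template@cellsize, crs = template@crs)
  out
}

## ---- IDW ------------------------------------------------------------------

#' Inverse distance weighting
#'
#' \eqn{Z(x_0) = \sum_i z_i h_i^{-\beta} / \sum_i h_i^{-\beta}} over the
#' neighbourhood. A target within 1e-9 m of a training site receives that
#' site's value exactly (snap rule).
#'
#' @param train a \linkS4class{SoilSurvey} or n x 2 coordinate matrix.
#' @param targets m x 2 coordinate matrix, data.frame or
#'   \linkS4class{GridRaster} (predicts at all cell centres).
#' @param values training values (default: the survey's \code{value}
#'   column).
#' @param value site-table column used when \code{values} is missing.
#' @param beta weighting power (>= 0, default 2).
#' @param nb a \linkS4class{NeighborhoodSpec}.
#' @return A \linkS4class{PredictionSurface} (no variance).
#' @examples
#' tr <- cbind(x = c(0, 0), y = c(1, 2))
#' estimates(idwPredict(tr, cbind(0, 0), values = c(10, 20), beta = 2,
#'                      nb = neighborhoodSpec(min_neighbors = 1)))  # 12
#' @export
idwPredict <- function(train, targets, values = NULL, value = "soc_a",
                       beta = 2, nb = neighborhoodSpec()) {
  stopifnot(beta >= 0)
  tv <- .asCoordsValues(train, values, value)
  tg <- .asTargets(targets)
  est <- numeric(nrow(tg))
  short <- integer(0)
  for (i in seq_len(nrow(tg))) {
    idx <- .neighborIdx(tg[i, 1], tg[i, 2], tv$coords, nb)
    if (length(idx) < max(1L, nb@min_neighbors)) { short <- c(short, i); next }
    h <- sqrt((tv$coords[idx, 1] - tg[i, 1])^2 +
              (tv$coords[idx, 2] - tg[i, 2])^2)
    if (any(h < 1e-9)) { est[i] <- tv$z[idx][which.min(h)]; next }
    w <- h^(-beta)
    est[i] <- sum(w * tv$z[idx]) / sum(w)
  }
  if (length(short)) .coverageError(short, "IDW")
  .newSurface(tg, est, NULL, "IDW", list(beta = beta, nb = nb))
}

## ---- LPI ------------------------------------------------------------------

.polyTerms <- function(dx, dy, order) {
  one <- rep(1, length(dx))
  switch(order + 1L,
         cbind(one),
         cbind(one, dx, dy),
         cbind(one, dx, dy, dx^2, dx * dy, dy^2))
}

#' Local polynomial interpolation
#'
#' At each target, fits a polynomial of the given order in (x, y) to the
#' neighbourhood by weighted least squares with kernel weights
#' \eqn{(1 - h/b)^2} for \eqn{h < b}; the prediction is the fitted value
#' at the target. The surface is a smoother, not an exact interpolator.
#' Rank-deficient local systems fall back to order 0 (the kernel-weighted
#' mean) with a warning.
#'
#' @inheritParams idwPredict
#' @param order polynomial order, 0, 1 or 2.
#' @param bandwidth kernel bandwidth b in metres; \code{NULL} (default)
#'   uses an adaptive bandwidth of 1.1 times the farthest neighbour
#'   distance at each target.
#' @return A \linkS4class{PredictionSurface} (no variance).
#' @export
lpiPredict <- function(train, targets, values = NULL, value = "soc_a",
                       order = 1, bandwidth = NULL,
                       nb = neighborhoodSpec()) {
  stopifnot(order %in% 0:2)
  tv <- .asCoordsValues(train, values, value)
  tg <- .asTargets(targets)
  est <- numeric(nrow(tg))
  short <- integer(0)
  fell_back <- FALSE
  nterms <- ncol(.polyTerms(0, 0, order))
  for (i in seq_len(nrow(tg))) {
    idx <- .neighborIdx(tg[i, 1], tg[i, 2], tv$coords, nb)
    h <- sqrt((tv$coords[idx, 1] - tg[i, 1])^2 +
              (tv$coords[idx, 2] - tg[i, 2])^2)
    bw <- if (is.null(bandwidth)) 1.1 * max(h, 1e-9) else bandwidth
    keep <- h < bw
    idx <- idx[keep]; h <- h[keep]
    if (length(idx) < nb@min_neighbors) { short <- c(short, i); next }
    w <- (1 - h / bw)^2
    dx <- (tv$coords[idx, 1] - tg[i, 1]) / bw     # scaled for conditioning
    dy <- (tv$coords[idx, 2] - tg[i, 2]) / bw
    X <- .polyTerms(dx, dy, order)
    fit_order <- order
    if (length(idx) < nterms || qr(sqrt(w) * X)$rank < ncol(X)) {
      fit_order <- 0
      fell_back <- TRUE
      X <- .polyTerms(dx, dy, 0L)
    }
    beta_hat <- stats::lm.wfit(X, tv$z[idx], w)$coefficients
    est[i] <- beta_hat[1]                          # value at dx = dy = 0
  }
  if (length(short)) .coverageError(short, "LPI")
  if (fell_back)
    warning("LPI: rank-deficient local system(s); fell back to order 0")
  .newSurface(tg, est, NULL, "LPI",
              list(order = order, bandwidth = bandwidth, nb = nb))
}

## ---- RBF ------------------------------------------------------------------

.rbfBases <- c("thin_plate_spline", "spline_with_tension",
               "completely_regularized_spline", "multiquadric",
               "inverse_multiquadric")

.rbfPhi <- function(r, basis, c0) {
  eg <- 0.57721566490153286                       # Euler-Mascheroni
  switch(basis,
    thin_plate_spline = ifelse(r == 0, 0, r^2 * log(r)),
    multiquadric = sqrt(r^2 + c0^2),
    inverse_multiquadric = 1 / sqrt(r^2 + c0^2),
    spline_with_tension = {
      u <- c0 * r
      ifelse(u == 0, 0, -(log(u / 2) + besselK(u, 0) + eg))
    },
    completely_regularized_spline = {
      u <- (c0 * r / 2)^2
      ifelse(u == 0, 0, -(log(u) + pracma::expint_E1(u) + eg))
    },
    stop("unknown RBF basis: ", basis))
}

## polynomial trend block: linear for the thin-plate spline (conditional
## positive definiteness of order 2), constant otherwise
.rbfPoly <- function(xy, basis) {
  if (basis == "thin_plate_spline") cbind(1, xy[, 1], xy[, 2])
  else cbind(rep(1, nrow(xy)))
}

#' Radial basis function interpolation
#'
#' Exact interpolation on the local neighbourhood: solves the augmented
#' system \eqn{[\Phi, P; P^T, 0]} so the surface passes through every
#' training value, then evaluates at the target. Five kernels are
#' available: thin-plate spline, spline with tension, completely
#' regularized spline, multiquadric and inverse multiquadric.
#'
#' @inheritParams idwPredict
#' @param basis one of \code{"thin_plate_spline"},
#'   \code{"spline_with_tension"}, \code{"completely_regularized_spline"},
#'   \code{"multiquadric"}, \code{"inverse_multiquadric"}.
#' @param shape_param kernel shape/tension parameter, expressed in units
#'   of the local mean neighbour spacing (distances inside each local
#'   system are normalised by that spacing for numerical conditioning);
#'   default 1.
#' @return A \linkS4class{PredictionSurface} (no variance).
#' @export
rbfPredict <- function(train, targets, values = NULL, value = "soc_a",
                       basis = "thin_plate_spline", shape_param = 1,
                       nb = neighborhoodSpec()) {
  basis <- match.arg(basis, .rbfBases)
  tv <- .asCoordsValues(train, values, value)
  key <- paste(tv$coords[, 1], tv$coords[, 2])
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    pair <- which(key == key[dup])
    stop(sprintf("conditioning error: duplicate sites at rows %d and %d",
                 pair[1], pair[2]))
  }
  tg <- .asTargets(targets)
  est <- numeric(nrow(tg))
  short <- integer(0)
  for (i in seq_len(nrow(tg))) {
    idx <- .neighborIdx(tg[i, 1], tg[i, 2], tv$coords, nb)
    if (length(idx) < nb@min_neighbors) { short <- c(short, i); next }
    X <- tv$coords[idx, , drop = FALSE]
    D <- as.matrix(stats::dist(X))
    ## normalise the local system by the mean neighbour spacing: keeps the
    ## augmented matrix well conditioned regardless of the map units
    s <- mean(D[upper.tri(D)])
    Xs <- cbind((X[, 1] - tg[i, 1]) / s, (X[, 2] - tg[i, 2]) / s)
    Phi <- .rbfPhi(D / s, basis, shape_param)
    P <- .rbfPoly(Xs, basis)
    k <- length(idx); p <- ncol(P)
    A <- rbind(cbind(Phi, P), cbind(t(P), matrix(0, p, p)))
    rhs <- c(tv$z[idx], rep(0, p))
    sol <- tryCatch(solve(A, rhs), error = function(e)
      stop("conditioning error: singular RBF system at target ", i))
    r0 <- sqrt(Xs[, 1]^2 + Xs[, 2]^2)
    est[i] <- sum(sol[1:k] * .rbfPhi(r0, basis, shape_param)) +
      sum(sol[(k + 1):(k + p)] *
            .rbfPoly(matrix(0, 1, 2), basis))
  }
  if (length(short)) .coverageError(short, "RBF")
  .newSurface(tg, est, NULL, paste0("RBF-", basis),
              list(basis = basis, shape_param = shape_param, nb = nb))
}

## ---- ordinary kriging -----------------------------------------------------

## Solve one OK system: semivariance matrix among neighbours plus the
## Lagrange row enforcing sum(lambda) = 1. Returns estimate, variance
## (floored at 0) and the weights.
.okSolve <- function(X, z, vm, tx, ty) {
  k <- nrow(X)
  G <- gammaModel(vm, as.matrix(stats::dist(X)))
  A <- rbind(cbind(G, 1), c(rep(1, k), 0))
  g0 <- gammaModel(vm, sqrt((X[, 1] - tx)^2 + (X[, 2] - ty)^2))
  sol <- tryCatch(solve(A, c(g0, 1)), error = function(e)
    stop("conditioning error: singular kriging matrix"))
  lambda <- sol[1:k]; mu <- sol[k + 1]
  list(estimate = sum(lambda * z),
       variance = max(0, sum(lambda * g0) + mu),
       weights = lambda, mu = mu)
}

#' Ordinary kriging
#'
#' Per target, solves the ordinary kriging system over the neighbourhood
#' (semivariance matrix with a Lagrange multiplier enforcing that the
#' weights sum to one) and returns the BLUP estimate and the kriging
#' variance (floored at zero against numerical noise).
#'
#' @inheritParams idwPredict
#' @param vm a \linkS4class{VariogramModel}.
#' @return A \linkS4class{PredictionSurface} with variance.
#' @export
okPredict <- function(train, targets, vm, values = NULL, value = "soc_a",
                      nb = neighborhoodSpec()) {
  stopifnot(is(vm, "VariogramModel"))
  tv <- .asCoordsValues(train, values, value)
  dd <- .dedupeSites(tv$coords, tv$z)
  tg <- .asTargets(targets)
  est <- numeric(nrow(tg)); v <- numeric(nrow(tg))
  short <- integer(0)
  for (i in seq_len(nrow(tg))) {
    idx <- .neighborIdx(tg[i, 1], tg[i, 2], dd$coords, nb)
    if (length(idx) < nb@min_neighbors) { short <- c(short, i); next }
    sol <- .okSolve(dd$coords[idx, , drop = FALSE], dd$z[idx], vm,
                    tg[i, 1], tg[i, 2])
    est[i] <- sol$estimate; v[i] <- sol$variance
  }
  if (length(short)) .coverageError(short, "OK")
  .newSurface(tg, est, v, "OK", list(vm = vm, nb = nb))
}

## ---- cokriging ------------------------------------------------------------

## Empirical direct and cross variograms of a multivariate sample on
## common bins. Z: n x p matrix. Returns lags, counts and a p x p x nbin
## array of (cross-)semivariances.
.empCrossVariogram <- function(coords, Z, max_lag, n_lags) {
  dm <- as.vector(stats::dist(coords))
  keep <- dm < max_lag
  width <- max_lag / n_lags
  bin <- pmin(floor(dm[keep] / width), n_lags - 1) + 1L
  counts <- tabulate(bin, nbins = n_lags)
  p <- ncol(Z)
  G <- array(NA_real_, c(p, p, n_lags))
  ## signed pairwise differences in dist() (lower-triangle) order
  n <- nrow(coords)
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  diffs <- lapply(seq_len(p), function(a) Z[ij[, 1], a] - Z[ij[, 2], a])
  for (a in seq_len(p)) for (b in a:p) {
    prod_ab <- (diffs[[a]] * diffs[[b]])[keep] / 2
    sums <- rep(0, n_lags)
    agg <- tapply(prod_ab, bin, sum)
    sums[as.integer(names(agg))] <- agg
    G[a, b, ] <- G[b, a, ] <- ifelse(counts > 0, sums / counts, NA)
  }
  list(lags = (seq_len(n_lags) - 0.5) * width, counts = counts, gamma = G)
}

## project a symmetric matrix to the nearest PSD matrix (eigenvalue clip)
.projectPSD <- function(B) {
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tcrossprod(e$vectors %*% diag(pmax(e$values, 0), nrow(B)), e$vectors)
}

#' Fit a linear model of coregionalization
#'
#' Two-structure LMC (nugget + one bounded structure with a common range):
#' \eqn{\gamma_{ab}(h) = B0_{ab} + B1_{ab} g(h)} where g is the unit
#' variogram of the given family. Entries are fitted by weighted least
#' squares (pair counts as weights) on the empirical direct and cross
#' variograms; the coefficient matrices are then projected to positive
#' semidefiniteness (eigenvalue clipping), which keeps the model valid.
#'
#' @param coords n x 2 site coordinates.
#' @param Z n x p matrix of collocated variables (column 1 = primary).
#' @param family structure family.
#' @param range_param common range parameter (m); typically taken from the
#'   primary variable's own fit.
#' @param max_lag,n_lags empirical variogram binning.
#' @return list with matrices \code{B0}, \code{B1}, the \code{family} and
#'   \code{range_param}.
#' @export
fitLMC <- function(coords, Z, family = "exponential", range_param,
                   max_lag = NULL, n_lags = 15) {
  if (is.null(max_lag)) max_lag <- max(stats::dist(coords)) / 2
  ev <- .empCrossVariogram(coords, Z, max_lag, n_lags)
  g_unit <- gammaModel(new("VariogramModel", family = family, nugget = 0,
                           psill = 1, range_param = range_param), ev$lags)
  p <- ncol(Z)
  B0 <- matrix(0, p, p); B1 <- matrix(0, p, p)
  ok <- ev$counts > 0
  W <- ev$counts[ok]
  X <- cbind(1, g_unit[ok])
  XtW <- t(X * W)
  for (a in seq_len(p)) for (b in a:p) {
    y <- ev$gamma[a, b, ok]
    cf <- solve(XtW %*% X, XtW %*% y)
    B0[a, b] <- B0[b, a] <- cf[1]
    B1[a, b] <- B1[b, a] <- cf[2]
  }
  B0 <- .projectPSD(B0); B1 <- .projectPSD(B1)
  list(B0 = B0, B1 = B1, family = family, range_param = range_param)
}

.lmcGamma <- function(lmc, a, b, h) {
  g <- gammaModel(new("VariogramModel", family = lmc$family, nugget = 0,
                      psill = 1, range_param = lmc$range_param), h)
  out <- lmc$B0[a, b] + lmc$B1[a, b] * g
  out[h == 0] <- 0
  out
}

#' Ordinary cokriging with raster secondary variables
#'
#' Samples 1-4 secondary rasters (e.g. NDVI, altitude, slope) at the site
#' and target locations, fits a linear model of coregionalization with
#' \code{\link{fitLMC}} (common range from \code{vm}, or the supplied
#' \code{lmc}), and solves the ordinary cokriging system per target:
#' primary weights sum to one, each secondary's weights sum to zero.
#' Secondaries whose fitted direct sill is numerically zero are dropped
#' (with a warning), in which case the method reduces to ordinary kriging.
#'
#' @inheritParams okPredict
#' @param secondary list of 1-4 \linkS4class{GridRaster} covariates
#'   covering all sites and targets.
#' @param lmc optional precomputed LMC (from \code{\link{fitLMC}}).
#' @return A \linkS4class{PredictionSurface} with cokriging variance.
#' @export
ckPredict <- function(train, secondary, targets, vm, values = NULL,
                      value = "soc_a", nb = neighborhoodSpec(),
                      lmc = NULL) {
  stopifnot(is(vm, "VariogramModel"))
  if (!is.list(secondary)) secondary <- list(secondary)
  if (length(secondary) > 4)
    stop("config error: cokriging supports at most 4 secondary variables")
  tv <- .asCoordsValues(train, values, value)
  dd <- .dedupeSites(tv$coords, tv$z)
  tg <- .asTargets(targets)
  sec_site <- lapply(secondary, function(r)
    extractAt(r, dd$coords[, 1], dd$coords[, 2]))
  if (any(vapply(sec_site, anyNA, TRUE)))
    stop("secondary raster does not cover all training sites")
  Z <- cbind(dd$z, do.call(cbind, sec_site))
  if (is.null(lmc))
    lmc <- fitLMC(dd$coords, Z, family = vm@family,
                  range_param = vm@range_param)
  ## drop degenerate secondaries (zero direct sill): they carry no signal
  ## and would make the cokriging system singular
  sec_sill <- diag(lmc$B0)[-1] + diag(lmc$B1)[-1]
  prim_sill <- lmc$B0[1, 1] + lmc$B1[1, 1]
  keep <- which(sec_sill > 1e-10 * max(prim_sill, 1e-300))
  if (length(keep) < length(secondary)) {
    warning("cokriging: dropped ", length(secondary) - length(keep),
            " degenerate secondary variable(s)")
    if (!length(keep)) {
      ps <- okPredict(dd$coords, tg, vm, values = dd$z, nb = nb)
      ps@method_tag <- "CK"
      return(ps)
    }
    sel <- c(1L, keep + 1L)
    Z <- Z[, sel, drop = FALSE]
    lmc$B0 <- lmc$B0[sel, sel]; lmc$B1 <- lmc$B1[sel, sel]
  }
  p <- ncol(Z)
  sec_tg <- lapply(seq_len(p - 1), function(a)
    extractAt(secondary[[keep[a]]], tg[, 1], tg[, 2]))
  if (any(vapply(sec_tg, anyNA, TRUE)))
    stop("secondary raster does not cover all targets")
  est <- numeric(nrow(tg)); v <- numeric(nrow(tg))
  short <- integer(0)
  for (i in seq_len(nrow(tg))) {
    idx <- .neighborIdx(tg[i, 1], tg[i, 2], dd$coords, nb)
    if (length(idx) < nb@min_neighbors) { short <- c(short, i); next }
    X <- dd$coords[idx, , drop = FALSE]
    k <- length(idx)
    ## secondaries are also observed at the target itself (their rasters
    ## cover it), so each secondary contributes k + 1 data: the neighbour
    ## values plus the collocated value
    Xa <- rbind(X, tg[i, , drop = FALSE])
    Da <- as.matrix(stats::dist(Xa))
    D <- Da[seq_len(k), seq_len(k), drop = FALSE]
    h0 <- Da[seq_len(k), k + 1]
    ka <- k + 1
    np <- k + (p - 1) * ka
    G <- matrix(0, np, np)
    g0 <- numeric(np)
    blk <- function(a) if (a == 1) seq_len(k) else
      (k + (a - 2) * ka) + seq_len(ka)
    for (a in seq_len(p)) for (b in seq_len(p)) {
      Dab <- if (a == 1 && b == 1) D else if (a == 1) Da[seq_len(k), ,
                                                        drop = FALSE]
             else if (b == 1) Da[, seq_len(k), drop = FALSE] else Da
      G[blk(a), blk(b)] <- .lmcGamma(lmc, a, b, Dab)
    }
    g0[blk(1)] <- .lmcGamma(lmc, 1, 1, h0)
    for (a in seq_len(p)[-1])
      g0[blk(a)] <- .lmcGamma(lmc, a, 1, c(h0, 0))
    ## unbiasedness: primary weights sum to 1, secondary weights to 0
    A_c <- matrix(0, np, p)
    for (a in seq_len(p)) A_c[blk(a), a] <- 1
    A <- rbind(cbind(G, A_c), cbind(t(A_c), matrix(0, p, p)))
    rhs <- c(g0, 1, rep(0, p - 1))
    ## perfectly redundant secondaries (e.g. an exact copy of the primary)
    ## make the system rank deficient; a tiny ridge restores solvability
    ## without visibly moving the solution
    sol <- tryCatch(solve(A, rhs), error = function(e) {
      ridge <- diag(c(rep(1e-8 * max(abs(G)), np), rep(0, p)))
      tryCatch(solve(A + ridge, rhs), error = function(e2)
        stop("conditioning error: singular cokriging system at target ", i))
    })
    lambda <- sol[seq_len(np)]
    zdat <- c(dd$z[idx],
              unlist(lapply(seq_len(p)[-1], function(a)
                c(Z[idx, a], sec_tg[[a - 1]][i]))))
    est[i] <- sum(lambda * zdat)
    v[i] <- max(0, sum(lambda * g0) + sol[np + 1])
  }
  if (length(short)) .coverageError(short, "CK")
  .newSurface(tg, est, v, "CK",
              list(vm = vm, lmc = lmc, n_secondary = p - 1, nb = nb))
}

## ---- empirical Bayes kriging ----------------------------------------------

#' Empirical Bayes kriging (spectrum of semivariograms)
#'
#' A simplified re-creation of EBK's subset-and-simulate scheme (the
#' proprietary algorithm is not published at implementable detail): sites
#' are partitioned into overlapping spatial subsets; each subset gets a
#' base exponential variogram fit plus \code{n_simulations - 1} parametric
#' bootstrap refits (bin semivariances perturbed by their approximate
#' sampling noise \eqn{\gamma\sqrt{2/N(h)}}), yielding a spectrum of
#' semivariogram models. Each target is predicted by every simulated model
#' of its nearest subsets and the results are mixed with inverse squared
#' distance weights to the subset centroids; the reported standard error
#' is the total (within + between) standard deviation of the mixture.
#' Fully deterministic per seed.
#'
#' @inheritParams idwPredict
#' @param subset_size sites per spatial subset (default 100).
#' @param overlap fraction of subset overlap (default 0.5) controlling how
#'   many subsets are formed.
#' @param n_simulations variogram spectrum size per subset (>= 1; the base
#'   fit is always the first member).
#' @param seed RNG seed for subsetting and bootstrap.
#' @param n_mix number of nearest subsets mixed per target.
#' @return A \linkS4class{PredictionSurface} whose \code{variance} slot
#'   holds the squared mixture standard error.
#' @export
ebkPredict <- function(train, targets, values = NULL, value = "soc_a",
                       subset_size = 100, overlap = 0.5,
                       n_simulations = 100, seed = 1, nb = neighborhoodSpec(),
                       n_mix = 3) {
  tv <- .asCoordsValues(train, values, value)
  dd <- .dedupeSites(tv$coords, tv$z)
  n <- nrow(dd$coords)
  subset_size <- min(subset_size, n)
  if (subset_size < 10)
    stop("config error: EBK subsets need at least 10 sites")
  tg <- .asTargets(targets)
  set.seed(as.integer(seed))
  ns <- max(1L, round(n / max(1, subset_size * (1 - overlap))))
  centers <- if (ns == 1) {
    matrix(colMeans(dd$coords), 1)
  } else {
    stats::kmeans(dd$coords, centers = ns, nstart = 3, iter.max = 50)$centers
  }
  ns <- nrow(centers)
  ## per subset: member sites and the variogram spectrum
  subsets <- vector("list", ns)
  for (k in seq_len(ns)) {
    d <- sqrt((dd$coords[, 1] - centers[k, 1])^2 +
              (dd$coords[, 2] - centers[k, 2])^2)
    mem <- order(d)[seq_len(subset_size)]
    ev <- empiricalVariogram(dd$coords[mem, , drop = FALSE],
                             values = dd$z[mem])
    base <- fitVariogram(ev, "exponential")
    spectrum <- list(base)
    okb <- ev@pair_counts > 0 & !is.na(ev@gamma)
    gfit <- gammaModel(base, ev@lag_centers[okb])
    for (s in seq_len(max(0, n_simulations - 1))) {
      noise <- stats::rnorm(sum(okb), 0,
                            gfit * sqrt(2 / ev@pair_counts[okb]))
      ev_s <- new("EmpiricalVariogram",
                  lag_centers = ev@lag_centers[okb],
                  gamma = pmax(gfit + noise, 0),
                  pair_counts = ev@pair_counts[okb],
                  max_lag = ev@max_lag, n_lags = sum(okb))
      fit_s <- try(fitVariogram(ev_s, "exponential",
                                inits = list(c(base@nugget, base@psill,
                                               base@range_param))),
                   silent = TRUE)
      spectrum[[s + 1]] <- if (inherits(fit_s, "try-error")) base else fit_s
    }
    subsets[[k]] <- list(members = mem, center = centers[k, ],
                         spectrum = spectrum)
  }
  est <- numeric(nrow(tg)); v <- numeric(nrow(tg))
  short <- integer(0)
  for (i in seq_len(nrow(tg))) {
    dc <- vapply(subsets, function(s)
      sqrt((s$center[1] - tg[i, 1])^2 + (s$center[2] - tg[i, 2])^2), 0)
    use <- order(dc)[seq_len(min(n_mix, ns))]
    w <- 1 / pmax(dc[use], 1e-6)^2
    w <- w / sum(w)
    means <- kvars <- mvars <- numeric(length(use))
    bad <- FALSE
    for (j in seq_along(use)) {
      sb <- subsets[[use[j]]]
      Xs <- dd$coords[sb$members, , drop = FALSE]
      idx <- .neighborIdx(tg[i, 1], tg[i, 2], Xs, nb)
      if (length(idx) < nb@min_neighbors) { bad <- TRUE; break }
      e_s <- v_s <- numeric(length(sb$spectrum))
      for (s in seq_along(sb$spectrum)) {
        sol <- .okSolve(Xs[idx, , drop = FALSE], dd$z[sb$members][idx],
                        sb$spectrum[[s]], tg[i, 1], tg[i, 2])
        e_s[s] <- sol$estimate; v_s[s] <- sol$variance
      }
      means[j] <- mean(e_s)
      kvars[j] <- mean(v_s)
      mvars[j] <- if (length(e_s) > 1) stats::var(e_s) * # population var
                    (length(e_s) - 1) / length(e_s) else 0
    }
    if (bad) { short <- c(short, i); next }
    est[i] <- sum(w * means)
    v[i] <- sum(w * (kvars + mvars + (means - est[i])^2))
  }
  if (length(short)) .coverageError(short, "EBK")
  .newSurface(tg, est, v, "EBK",
              list(subset_size = subset_size, overlap = overlap,
                   n_simulations = n_simulations, seed = seed,
                   n_subsets = ns, nb = nb))
}
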