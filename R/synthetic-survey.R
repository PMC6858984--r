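## Seeded generator of a synthetic high-mountain park and its soil survey.
## The park emulates a square volcanic national park: a central peak with
## altitude-banded land-use strata (seasonal agriculture on the lower
## slopes, forest on the mid slopes, grassland/high moor near the summit),
## a log-scale spatially autocorrelated SOC field, land-use specific
## organic horizons and an NDVI surface positively linked to SOC.

#' Build a synthetic-survey configuration
#'
#' Defaults describe the emulated park: 440 sites over a 22 km (484 km2)
#' square park rising from 2200 to 4461 m a.s.l.; strata with A-horizon
#' SOC means/SDs of agriculture 5.19/1.98 (2200-3000 m), forest
#' 40.31/18.55 (2500-4000 m) and grassland 12.82/5.17 (above 4000 m)
#' g/kg; a log-scale exponential variogram with nugget 0.529 and sill
#' 2.226 (range parameter 2000 m, i.e. an effective range of 6 km — a
#' configuration knob chosen so the survey extent comfortably contains
#' the effective range); O-horizon mean
#' thickness 5.31 cm under forest, 1 cm under grassland, none under
#' agriculture, with O-horizon SOC drawn between 284.76 and 484.20 g/kg
#' and O bulk density 0.15 g/cm3; A-horizon bulk density uniform on
#' 0.9-1.4 g/cm3 and coarse fragments uniform on 0-20 vol%.
#'
#' Note the strata SD values are descriptive metadata of the emulated
#' survey: the realised stratum SD is governed by the log-scale variogram
#' sill (a lognormal with log-variance equal to the sill), which is the
#' quantity the variography stages must recover.
#'
#' @param seed integer RNG seed.
#' @param n_sites number of survey points (>= 10).
#' @param extent_km park width in km.
#' @param cell_size raster cell size in m.
#' @param altitude_range c(min, max) altitude in m.
#' @param strata data.frame with columns land_use, mean_soc, sd_soc,
#'   alt_min, alt_max.
#' @param mix_prob P(forest) in the forest/agriculture overlap band.
#' @param variogram \linkS4class{VariogramModel} of the log-SOC field.
#' @param o_thickness_mean named vector, mean O thickness (cm) per stratum.
#' @param o_soc_range,o_bulk_density O-horizon SOC range (g/kg) and bulk
#'   density (g/cm3).
#' @param bd_range,coarse_range A-horizon bulk density (g/cm3) and
#'   coarse-fragment (vol%) sampling ranges.
#' @param ndvi_link c(intercept, slope, noise_sd) of the NDVI ~
#'   standardised-SOC link.
#' @return A \linkS4class{SurveyConfig}.
#' @export
surveyConfig <- function(seed = 1L, n_sites = 440L, extent_km = 22,
                         cell_size = 200,
                         altitude_range = c(2200, 4461),
                         strata = data.frame(
                           land_use = c("forest", "grassland", "agriculture"),
                           mean_soc = c(40.31, 12.82, 5.19),
                           sd_soc   = c(18.55, 5.17, 1.98),
                           alt_min  = c(2500, 4000, 2200),
                           alt_max  = c(4000, Inf, 3000)),
                         mix_prob = 0.5,
                         variogram = variogramModel("exponential",
                           nugget = 0.529, psill = 2.226 - 0.529,
                           range_param = 2000),
                         o_thickness_mean = c(forest = 5.31, grassland = 1,
                                              agriculture = 0),
                         o_soc_range = c(284.76, 484.20),
                         o_bulk_density = 0.15,
                         bd_range = c(0.9, 1.4),
                         coarse_range = c(0, 20),
                         ndvi_link = c(intercept = 0.32, slope = 0.08,
                                       noise_sd = 0.05)) {
  new("SurveyConfig", seed = as.integer(seed), n_sites = as.integer(n_sites),
      extent_km = extent_km, cell_size = cell_size,
      altitude_range = altitude_range, strata = strata, mix_prob = mix_prob,
      variogram = variogram, o_thickness_mean = o_thickness_mean,
      o_soc_range = o_soc_range, o_bulk_density = o_bulk_density,
      bd_range = bd_range, coarse_range = coarse_range,
      ndvi_link = ndvi_link)
}

## grid template shared by all park rasters
.parkTemplate <- function(cfg) {
  n <- max(3L, round(cfg@extent_km * 1000 / cfg@cell_size))
  gridRaster(matrix(NA_real_, n, n), 0, 0, cfg@cell_size)
}

#' Generate the park DEM
#'
#' A radial volcano profile: altitude declines from the configured maximum
#' at the park centre to the minimum at a radius of half the park width
#' (slightly concave profile so the low-altitude skirt is broad, as on a
#' real shield of agricultural footslopes), plus smooth seeded harmonic
#' noise of ~60 m amplitude, clamped to the configured altitude range.
#'
#' @param cfg a \linkS4class{SurveyConfig}.
#' @return A \linkS4class{GridRaster} of altitudes.
#' @export
generateDem <- function(cfg) {
  tpl <- .parkTemplate(cfg)
  set.seed(cfg@seed + 1L)
  cc <- cellCenters(tpl)
  half <- cfg@extent_km * 1000 / 2
  r <- sqrt((cc[, 1] - half)^2 + (cc[, 2] - half)^2)
  lo <- cfg@altitude_range[1]; hi <- cfg@altitude_range[2]
  prof <- pmax(0, 1 - r / half)^0.8
  alt <- lo + (hi - lo) * prof
  ## smooth harmonic noise, seeded phases
  k <- 3
  amp <- 60
  ph <- stats::runif(2 * k, 0, 2 * pi)
  fr <- stats::runif(2 * k, 1, 3)
  L <- cfg@extent_km * 1000
  noise <- rep(0, nrow(cc))
  for (j in seq_len(k)) {
    noise <- noise +
      sin(2 * pi * fr[j] * cc[, 1] / L + ph[j]) *
      cos(2 * pi * fr[k + j] * cc[, 2] / L + ph[k + j])
  }
  alt <- alt + amp * noise / k
  alt <- pmin(pmax(alt, lo), hi)
  d <- gridDim(tpl)
  gridRaster(matrix(alt, d[1], d[2]), 0, 0, cfg@cell_size, crs = tpl@crs)
}

#' Assign land-use classes from altitude
#'
#' Each cell gets the stratum whose altitude band contains its altitude.
#' Bands are half-open at the bottom, `(alt_min, alt_max]`, except the
#' lowest band which includes its lower edge, so a cell exactly at a
#' shared boundary belongs to the lower band. Where the forest and
#' agriculture bands overlap the class is drawn seeded-Bernoulli with
#' P(forest) = \code{mix_prob}.
#'
#' @param dem altitude raster.
#' @param cfg a \linkS4class{SurveyConfig}.
#' @return A \linkS4class{GridRaster} of integer codes into
#'   \code{\link{landUseLevels}}.
#' @export
assignLanduse <- function(dem, cfg) {
  force(dem)                       # evaluate before seeding the RNG
  set.seed(cfg@seed + 2L)
  alt <- as.vector(dem@values)
  st <- cfg@strata
  global_min <- min(st$alt_min)
  cand <- sapply(seq_len(nrow(st)), function(i) {
    lo <- st$alt_min[i]
    incl_lo <- if (lo == global_min) alt >= lo else alt > lo
    incl_lo & alt <= st$alt_max[i]
  })
  ncand <- rowSums(cand, na.rm = TRUE)
  if (any(ncand == 0 & !is.na(alt)))
    stop("config error: altitude ", alt[which(ncand == 0)[1]],
         " lies outside all configured bands")
  code <- rep(NA_real_, length(alt))
  single <- which(ncand == 1)
  code[single] <- apply(cand[single, , drop = FALSE], 1, which.max)
  multi <- which(ncand > 1)
  if (length(multi)) {
    ## overlap band: choose between forest and agriculture
    i_forest <- which(st$land_use == "forest")
    i_ag <- which(st$land_use == "agriculture")
    pick <- stats::rbinom(length(multi), 1, cfg@mix_prob)
    code[multi] <- ifelse(pick == 1, i_forest, i_ag)
  }
  ## stratum row index -> canonical land-use code
  code <- match(st$land_use[code], landUseLevels)
  d <- gridDim(dem)
  gridRaster(matrix(code, d[1], d[2]), dem@xllcorner, dem@yllcorner,
             dem@cellsize, crs = dem@crs)
}

## Stationary Gaussian random field on the grid by circulant embedding:
## the covariance of the base torus is diagonalised by the 2D DFT, so a
## field with covariance psill * exp(-h/range) (or the gaussian/spherical
## analogue) is synthesised in O(N log N). Small negative embedding
## eigenvalues are clipped at zero (standard approximate embedding).
.simGRF <- function(nr, nc, cellsize, vm) {
  if (vm@psill <= 0) return(matrix(0, nr, nc))
  m <- 2L * nr; n <- 2L * nc
  dy <- cellsize * pmin(0:(m - 1), m - (0:(m - 1)))
  dx <- cellsize * pmin(0:(n - 1), n - (0:(n - 1)))
  D <- sqrt(outer(dy^2, dx^2, "+"))
  C <- vm@psill * (1 - gammaModel(
    new("VariogramModel", family = vm@family, nugget = 0, psill = 1,
        range_param = vm@range_param), D))
  lambda <- Re(stats::fft(C))
  neg <- lambda < 0
  if (any(neg)) {
    if (sum(-lambda[neg]) > 0.01 * sum(lambda[!neg]))
      warning("circulant embedding clipped a non-trivial negative mass")
    lambda[neg] <- 0
  }
  xi <- matrix(stats::rnorm(m * n), m, n) +
        1i * matrix(stats::rnorm(m * n), m, n)
  f <- stats::fft(sqrt(lambda / (m * n)) * xi)
  Re(f)[seq_len(nr), seq_len(nc)]
}

#' Simulate the log-lognormal SOC field
#'
#' Draws a Gaussian random field on the log scale with the configured
#' variogram structure: a smooth component with covariance
#' \eqn{c\,e^{-h/a}} (circulant-embedding spectral synthesis) plus
#' independent nugget noise, then shifts each stratum by the additive
#' log-scale constant \eqn{\log(\mu_c) - \sigma^2/2} (with \eqn{\sigma^2}
#' the total sill) so the back-transformed field has expectation equal to
#' each stratum's configured mean SOC. The output is strictly positive.
#'
#' @param landuse stratum code raster from \code{\link{assignLanduse}}.
#' @param cfg a \linkS4class{SurveyConfig}.
#' @return A \linkS4class{GridRaster} of SOC (g/kg).
#' @export
simulateSocField <- function(landuse, cfg) {
  vm <- cfg@variogram
  if (vm@nugget < 0 || vm@psill < 0)
    stop("simulation error: variogram must have nonnegative variances")
  force(landuse)                   # evaluate before seeding the RNG
  set.seed(cfg@seed + 3L)
  d <- gridDim(landuse)
  smooth <- .simGRF(d[1], d[2], landuse@cellsize, vm)
  eps <- matrix(stats::rnorm(d[1] * d[2], sd = sqrt(vm@nugget)), d[1], d[2])
  sill_tot <- sill(vm)
  mu <- log(cfg@strata$mean_soc) - sill_tot / 2
  names(mu) <- cfg@strata$land_use
  shift <- matrix(mu[landUseLevels[as.vector(landuse@values)]], d[1], d[2])
  soc <- exp(shift + smooth + eps)
  gridRaster(soc, landuse@xllcorner, landuse@yllcorner, landuse@cellsize,
             crs = landuse@crs)
}

#' Generate an NDVI surface linked to SOC
#'
#' NDVI = clip(intercept + slope * standardised(SOC) + noise, -1, 1),
#' giving a positive Pearson correlation with SOC over data cells
#' (defaults yield r around 0.85 before clipping).
#'
#' @param soc_field SOC raster.
#' @param cfg a \linkS4class{SurveyConfig} (uses \code{ndvi_link} and
#'   seed).
#' @return A \linkS4class{GridRaster} with values in [-1, 1].
#' @export
generateNdvi <- function(soc_field, cfg) {
  if (!(cfg@ndvi_link["slope"] > 0))
    stop("ndvi_link slope must be > 0")
  force(soc_field)                 # evaluate before seeding the RNG
  set.seed(cfg@seed + 5L)
  v <- as.vector(soc_field@values)
  z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  ndvi <- cfg@ndvi_link["intercept"] + cfg@ndvi_link["slope"] * z +
    stats::rnorm(length(z), sd = cfg@ndvi_link["noise_sd"])
  ndvi <- pmin(pmax(ndvi, -1), 1)
  d <- gridDim(soc_field)
  gridRaster(matrix(ndvi, d[1], d[2]), soc_field@xllcorner,
             soc_field@yllcorner, soc_field@cellsize, crs = soc_field@crs)
}

#' Generate a complete synthetic park
#'
#' Chains DEM, land-use, SOC-field and NDVI generation under one seed.
#'
#' @param cfg a \linkS4class{SurveyConfig}.
#' @return A \linkS4class{SyntheticPark}.
#' @examples
#' park <- generatePark(surveyConfig(seed = 7, extent_km = 6, n_sites = 30))
#' park
#' @export
generatePark <- function(cfg = surveyConfig()) {
  dem <- generateDem(cfg)
  lu <- assignLanduse(dem, cfg)
  soc <- simulateSocField(lu, cfg)
  ndvi <- generateNdvi(soc, cfg)
  new("SyntheticPark", dem = dem, landuse = lu, soc = soc, ndvi = ndvi,
      config = cfg)
}

#' Draw a soil survey from a synthetic park
#'
#' Sites are placed one per 1 km2 block (quasi-uniform coverage, the
#' classical square-grid sampling template) with stratum counts
#' apportioned to the class areas (largest-remainder method). Each site
#' records the SOC-field value of its cell, altitude and slope from the
#' DEM, NDVI from the NDVI raster, bulk density and coarse fragments drawn
#' uniform from their configured ranges, an exponential O-horizon
#' thickness around the stratum mean (none under agriculture) and an
#' O-horizon SOC uniform over the configured range where an O horizon
#' exists.
#'
#' @param park a \linkS4class{SyntheticPark}.
#' @param cfg configuration (defaults to the park's own).
#' @return A \linkS4class{SoilSurvey} with \code{cfg@n_sites} sites.
#' @export
sampleSurvey <- function(park, cfg = park@config) {
  force(park)                      # evaluate before seeding the RNG
  set.seed(cfg@seed + 4L)
  lu <- park@landuse
  d <- gridDim(lu)
  codes <- as.vector(lu@values)
  data_cells <- which(!is.na(codes))
  if (cfg@n_sites > length(data_cells))
    stop("n_sites exceeds the number of data cells")
  ## largest-remainder apportionment of sites to strata by cell counts
  counts <- tabulate(codes[data_cells], nbins = length(landUseLevels))
  exact <- cfg@n_sites * counts / sum(counts)
  quota <- floor(exact)
  rem <- cfg@n_sites - sum(quota)
  if (rem > 0) {
    extra <- order(exact - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  ## block id (1 km2) per cell, for quasi-uniform placement
  cs <- lu@cellsize
  cell_row <- (data_cells - 1) %% d[1] + 1
  cell_col <- (data_cells - 1) %/% d[1] + 1
  bs <- max(1L, round(1000 / cs))                 # cells per block edge
  block <- (cell_row - 1) %/% bs + ((cell_col - 1) %/% bs) * 10000L
  chosen <- integer(0)
  for (k in seq_along(landUseLevels)) {
    if (quota[k] == 0) next
    in_class <- data_cells[codes[data_cells] == k]
    cls_block <- block[codes[data_cells] == k]
    blocks <- unique(cls_block)
    if (length(blocks) >= quota[k]) {
      pick_blocks <- sample(blocks, quota[k])
      picks <- vapply(pick_blocks, function(b) {
        cand <- in_class[cls_block == b]
        if (length(cand) == 1) cand else sample(cand, 1)
      }, integer(1))
    } else {
      ## more sites than blocks: one per block, remainder at random
      picks <- vapply(blocks, function(b) {
        cand <- in_class[cls_block == b]
        if (length(cand) == 1) cand else sample(cand, 1)
      }, integer(1))
      pool <- setdiff(in_class, picks)
      picks <- c(picks, sample(pool, quota[k] - length(picks)))
    }
    chosen <- c(chosen, picks)
  }
  n <- length(chosen)
  row <- (chosen - 1) %% d[1] + 1
  col <- (chosen - 1) %/% d[1] + 1
  ## sites sit at cell centres so coordinates are exactly consistent with
  ## the gridded field values (no artificial short-lag decorrelation)
  x <- lu@xllcorner + (col - 0.5) * cs
  y <- lu@yllcorner + (row - 0.5) * cs
  stratum <- landUseLevels[codes[chosen]]
  o_mean <- cfg@o_thickness_mean[stratum]
  o_thick <- ifelse(o_mean > 0, stats::rexp(n, rate = 1 / pmax(o_mean, 1e-9)),
                    0)
  soc_o <- ifelse(o_thick > 0,
                  stats::runif(n, cfg@o_soc_range[1], cfg@o_soc_range[2]),
                  NA_real_)
  slope_r <- computeSlope(park@dem)
  sites <- data.frame(
    site_id = sprintf("S%03d", seq_len(n)),
    x = x, y = y,
    altitude = park@dem@values[cbind(row, col)],
    land_use = stratum,
    soc_a = park@soc@values[cbind(row, col)],
    soc_o = soc_o,
    o_thickness = o_thick,
    bulk_density = stats::runif(n, cfg@bd_range[1], cfg@bd_range[2]),
    coarse_pct = stats::runif(n, cfg@coarse_range[1], cfg@coarse_range[2]),
    slope = slope_r@values[cbind(row, col)],
    ndvi = park@ndvi@values[cbind(row, col)])
  soilSurvey(sites, crs = lu@crs)
}
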