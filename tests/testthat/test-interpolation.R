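nb1 <- neighborhoodSpec(min_neighbors = 1)

test_that("IDW reproduces the hand-evaluated two-point case and the snap
           rule", {
  tr <- cbind(c(0, 0), c(1, 2))
  ps <- idwPredict(tr, cbind(0, 0), values = c(10, 20), beta = 2, nb = nb1)
  expect_equal(estimates(ps), 12)           # (10 + 20/4) / (1 + 1/4)
  # coincident target snaps to the site value
  ps <- idwPredict(tr, cbind(0, 2), values = c(10, 20), beta = 2, nb = nb1)
  expect_equal(estimates(ps), 20)
  # constant data are reproduced for any power
  for (b in c(0.5, 2, 5)) {
    ps <- idwPredict(tr, cbind(0.3, 1.1), values = c(7, 7), beta = b,
                     nb = nb1)
    expect_equal(estimates(ps), 7)
  }
})

test_that("IDW coverage failures identify the targets", {
  tr <- cbind(c(0, 10), c(0, 0))
  expect_error(
    idwPredict(tr, cbind(1e6, 0), values = c(1, 2),
               nb = neighborhoodSpec(search_radius = 100)),
    "coverage error")
})

test_that("LPI reproduces exact planes and falls back on degenerate
           systems", {
  set.seed(3)
  tr <- cbind(runif(30, 0, 100), runif(30, 0, 100))
  z <- 2 * tr[, 1] + 3 * tr[, 2] + 1
  tg <- cbind(runif(5, 20, 80), runif(5, 20, 80))
  ps <- lpiPredict(tr, tg, values = z, order = 1)
  expect_equal(estimates(ps), 2 * tg[, 1] + 3 * tg[, 2] + 1,
               tolerance = 1e-8)

  # order 0 equals the kernel-weighted neighbour mean
  z2 <- rnorm(30)
  tg1 <- cbind(50, 50)
  bw <- 200
  ps0 <- lpiPredict(tr, tg1, values = z2, order = 0, bandwidth = bw)
  h <- sqrt((tr[, 1] - 50)^2 + (tr[, 2] - 50)^2)
  idx <- order(h)[1:15]
  w <- (1 - h[idx] / bw)^2
  expect_equal(estimates(ps0), sum(w * z2[idx]) / sum(w), tolerance = 1e-10)

  # collinear neighbours cannot support order 2: order-0 fallback + warning
  trc <- cbind(seq(0, 100, length.out = 12), seq(0, 50, length.out = 12))
  expect_warning(
    psf <- lpiPredict(trc, cbind(50, 25), values = rnorm(12), order = 2),
    "order 0")
  expect_true(is.finite(estimates(psf)))
})

test_that("all five RBF bases interpolate the training data exactly", {
  set.seed(8)
  tr <- cbind(runif(25, 0, 1000), runif(25, 0, 1000))
  z <- rnorm(25, 50, 10)
  for (b in c("thin_plate_spline", "spline_with_tension",
              "completely_regularized_spline", "multiquadric",
              "inverse_multiquadric")) {
    ps <- rbfPredict(tr, tr, values = z, basis = b,
                     nb = neighborhoodSpec(max_neighbors = 25))
    expect_equal(estimates(ps), z, tolerance = 1e-6)
  }
  # constant data give a constant surface
  ps <- rbfPredict(tr, cbind(c(333, 707), c(250, 600)), values = rep(3, 25),
                   basis = "multiquadric")
  expect_equal(estimates(ps), c(3, 3), tolerance = 1e-8)
})

test_that("a 1-D multiquadric section matches a dense textbook solve", {
  # small full system solved directly from the definition
  x <- c(0, 250, 520, 760, 1000)
  z <- c(3, 5, 2, 6, 4)
  tr <- cbind(x, 0)
  tg <- cbind(c(100, 400, 900), 0)
  ps <- rbfPredict(tr, tg, values = z, basis = "multiquadric",
                   shape_param = 1, nb = neighborhoodSpec(5, 1))
  # oracle: same definition, built independently (scaled by mean spacing,
  # kernel sqrt(r^2 + c^2), constant trend)
  oracle <- sapply(tg[, 1], function(t0) {
    D <- as.matrix(dist(tr))
    s <- mean(D[upper.tri(D)])
    Phi <- sqrt((D / s)^2 + 1)
    A <- rbind(cbind(Phi, 1), c(rep(1, 5), 0))
    sol <- solve(A, c(z, 0))
    r0 <- abs(x - t0) / s
    sum(sol[1:5] * sqrt(r0^2 + 1)) + sol[6]
  })
  expect_equal(estimates(ps), unname(oracle), tolerance = 1e-8)
})

test_that("RBF rejects duplicate sites with a conditioning error", {
  tr <- cbind(c(0, 0, 100), c(0, 0, 100))
  expect_error(rbfPredict(tr, cbind(50, 50), values = 1:3),
               "rows 1 and 2")
})

test_that("ordinary kriging weights sum to one and honour exactness", {
  set.seed(12)
  tr <- cbind(runif(10, 0, 5000), runif(10, 0, 5000))
  z <- rnorm(10, 20, 5)
  vm <- variogramModel("exponential", 0.3, 1.5, 1500)
  for (k in 1:4) {
    tgt <- c(runif(1, 0, 5000), runif(1, 0, 5000))
    sol <- SOCmap:::.okSolve(tr, z, vm, tgt[1], tgt[2])
    expect_lt(abs(sum(sol$weights) - 1), 1e-10)
    expect_gte(sol$variance, 0)
  }
  # zero nugget: prediction at a site reproduces it with zero variance
  vm0 <- variogramModel("exponential", 0, 1.5, 1500)
  ps <- okPredict(tr, tr[3, , drop = FALSE], vm0, values = z)
  expect_equal(estimates(ps), z[3], tolerance = 1e-8)
  expect_equal(predVariance(ps), 0, tolerance = 1e-8)
})

test_that("neighbourhood kriging equals an independent dense solve on
           small instances", {
  set.seed(31)
  for (n in c(5, 8, 10)) {
    tr <- cbind(runif(n, 0, 4000), runif(n, 0, 4000))
    z <- rnorm(n, 10, 2)
    vm <- variogramModel("exponential", 0.4, 1.2, 1200)
    tg <- cbind(runif(3, 500, 3500), runif(3, 500, 3500))
    ps <- okPredict(tr, tg, vm, values = z,
                    nb = neighborhoodSpec(max_neighbors = n,
                                          min_neighbors = 1))
    for (i in 1:3) {
      # dense oracle built from the model definition
      G <- gammaModel(vm, as.matrix(dist(tr)))
      A <- rbind(cbind(G, 1), c(rep(1, n), 0))
      g0 <- gammaModel(vm, sqrt((tr[, 1] - tg[i, 1])^2 +
                                (tr[, 2] - tg[i, 2])^2))
      lam <- solve(A, c(g0, 1))[1:n]
      expect_equal(estimates(ps)[i], sum(lam * z), tolerance = 1e-8)
    }
  }
})

test_that("kriging averages duplicate sites instead of failing", {
  tr <- cbind(c(0, 0, 1000, 2000), c(0, 0, 0, 500))
  z <- c(4, 8, 5, 7)
  vm <- variogramModel("exponential", 0.1, 1, 800)
  expect_warning(ps <- okPredict(tr, cbind(500, 100), vm, values = z,
                                 nb = neighborhoodSpec(min_neighbors = 1)),
                 "duplicate")
  expect_true(is.finite(estimates(ps)))
})

test_that("cokriging degenerates to kriging when the secondary is
           uninformative and beats it when the secondary is the signal", {
  cfg <- smallParkConfig()
  park <- generatePark(cfg)
  sv <- sampleSurvey(park, cfg)
  s <- sites(sv)
  trc <- as.matrix(s[, c("x", "y")])
  z <- log(s$soc_a)
  ev <- empiricalVariogram(trc, values = z - mean(z), max_lag = 3000)
  vm <- fitVariogram(ev)
  tg <- cbind(c(2000, 4000, 6000), c(3000, 4000, 5000))
  zero <- gridRaster(matrix(0, 32, 32), 0, 0, 250)
  expect_warning(ck0 <- ckPredict(trc, list(zero), tg, vm, values = z),
                 "degenerate")
  ok0 <- okPredict(trc, tg, vm, values = z)
  expect_equal(estimates(ck0), estimates(ok0), tolerance = 1e-6)

  # secondary = the SOC field itself: cokriging variance cannot exceed
  # the kriging variance (it has strictly more information)
  sec <- gridRaster(log(values(park@soc)), 0, 0, cellSize(park@soc))
  ck1 <- ckPredict(trc, list(sec), tg, vm, values = z)
  expect_true(all(predVariance(ck1) <= predVariance(ok0) + 1e-6))
})

test_that("cokriging enforces its configuration limits", {
  tr <- smallSurvey(20)
  r <- gridRaster(matrix(1, 5, 5), 0, 0, 2500)
  vm <- variogramModel("exponential", 0.2, 1, 1000)
  expect_error(
    ckPredict(tr, rep(list(r), 5), cbind(5000, 5000), vm),
    "at most 4")
})

test_that("EBK collapses to ordinary kriging for a single subset and
           simulation, and is seed-deterministic", {
  sv <- smallSurvey(60)
  s <- sites(sv)
  trc <- as.matrix(s[, c("x", "y")])
  z <- s$soc_a
  tg <- cbind(c(2500, 7000), c(2500, 7000))
  ebk1 <- ebkPredict(trc, tg, values = z, subset_size = 60, overlap = 0,
                     n_simulations = 1, seed = 4)
  # the one-member spectrum is the base fit on the full data
  ev <- empiricalVariogram(trc, values = z)
  vm <- fitVariogram(ev)
  ok <- okPredict(trc, tg, vm, values = z)
  expect_equal(estimates(ebk1), estimates(ok), tolerance = 1e-8)

  a <- ebkPredict(trc, tg, values = z, subset_size = 30, n_simulations = 15,
                  seed = 99)
  b <- ebkPredict(trc, tg, values = z, subset_size = 30, n_simulations = 15,
                  seed = 99)
  expect_identical(estimates(a), estimates(b))
  expect_identical(predVariance(a), predVariance(b))
  expect_error(ebkPredict(trc, tg, values = z, subset_size = 5), "at least")
})

test_that("EBK's mixture standard error dominates the single-model kriging
           error on most targets", {
  # default-scale survey: the spectrum's parameter spread adds variance
  # the single fitted model does not carry
  cfg <- surveyConfig(seed = 1)
  sv <- sampleSurvey(generatePark(cfg), cfg)
  s <- sites(sv)
  trc <- as.matrix(s[, c("x", "y")])
  z <- log(s$soc_a)
  mu <- tapply(z, s$land_use, mean)
  vm <- fitVariogram(empiricalVariogram(trc, values = z - mu[s$land_use],
                                        max_lag = 5000))
  set.seed(5)
  tg <- cbind(runif(20, 2000, 20000), runif(20, 2000, 20000))
  ok <- okPredict(trc, tg, vm, values = z)
  ebk <- ebkPredict(trc, tg, values = z, subset_size = 100,
                    n_simulations = 12, seed = 1)
  frac <- mean(sqrt(predVariance(ebk)) >= sqrt(predVariance(ok)) - 1e-9)
  expect_gte(frac, 0.9)
})

test_that("every interpolator is translation-equivariant and the convex
           ones stay within the neighbourhood hull", {
  sv <- smallSurvey(45)
  s <- sites(sv)
  trc <- as.matrix(s[, c("x", "y")])
  z <- s$soc_a
  tg <- cbind(c(3000, 6000, 8000), c(2000, 5000, 8000))
  vm <- variogramModel("exponential", 0.2, 1.4, 2000)
  zero <- gridRaster(matrix(0, 6, 6), 0, 0, 2000)
  run <- function(zz) list(
    idw = estimates(idwPredict(trc, tg, values = zz)),
    lpi = estimates(lpiPredict(trc, tg, values = zz)),
    rbf = estimates(rbfPredict(trc, tg, values = zz,
                               basis = "spline_with_tension")),
    ok  = estimates(okPredict(trc, tg, vm, values = zz)),
    ck  = estimates(suppressWarnings(
      ckPredict(trc, list(zero), tg, vm, values = zz))),
    ebk = estimates(ebkPredict(trc, tg, values = zz, subset_size = 45,
                               overlap = 0, n_simulations = 3, seed = 2)))
  base <- run(z)
  shifted <- run(z + 13.5)
  for (m in names(base))
    expect_equal(shifted[[m]], base[[m]] + 13.5, tolerance = 1e-6,
                 label = paste("translation equivariance of", m))

  # convex-weight methods respect neighbourhood bounds
  for (i in seq_len(nrow(tg))) {
    h <- sqrt((trc[, 1] - tg[i, 1])^2 + (trc[, 2] - tg[i, 2])^2)
    nbv <- z[order(h)[1:15]]
    expect_gte(base$idw[i], min(nbv)); expect_lte(base$idw[i], max(nbv))
  }
  lpi0 <- estimates(suppressWarnings(lpiPredict(trc, tg, values = z,
                                                order = 0)))
  for (i in seq_len(nrow(tg))) {
    h <- sqrt((trc[, 1] - tg[i, 1])^2 + (trc[, 2] - tg[i, 2])^2)
    nbv <- z[order(h)[1:15]]
    expect_gte(lpi0[i], min(nbv)); expect_lte(lpi0[i], max(nbv))
  }
})

test_that("zero-nugget kriging with an unlimited neighbourhood reproduces
           the training data", {
  sv <- smallSurvey(25)
  s <- sites(sv)
  trc <- as.matrix(s[, c("x", "y")])
  z <- s$soc_a
  vm <- variogramModel("exponential", 0, 1.5, 2500)
  nb <- neighborhoodSpec(max_neighbors = 25, min_neighbors = 1)
  ok <- okPredict(trc, trc, vm, values = z, nb = nb)
  expect_equal(estimates(ok), z, tolerance = 1e-6)
})

test_that("kriging outpredicts IDW on a strongly autocorrelated field", {
  # range far beyond the site spacing: the BLUP advantage is systematic
  set.seed(77)
  n <- 120
  co <- cbind(runif(n, 0, 10000), runif(n, 0, 10000))
  vm <- variogramModel("exponential", 0.05, 1, 8000)
  G <- exp(-as.matrix(dist(co)) / 8000)
  z <- 10 + t(chol(G + diag(1e-8, n))) %*% rnorm(n) +
    rnorm(n, 0, sqrt(0.05))
  z <- as.numeric(z)
  tr_idx <- 1:90; va_idx <- 91:120
  ok <- estimates(okPredict(co[tr_idx, ], co[va_idx, ], vm,
                            values = z[tr_idx]))
  idw <- estimates(idwPredict(co[tr_idx, ], co[va_idx, ],
                              values = z[tr_idx]))
  rmse <- function(p) sqrt(mean((z[va_idx] - p)^2))
  expect_lte(rmse(ok), rmse(idw))
})

test_that("prediction surfaces reshape onto raster grids", {
  sv <- smallSurvey(30)
  s <- sites(sv)
  tpl <- gridRaster(matrix(NA_real_, 4, 5), 0, 0, 2000)
  ps <- idwPredict(as.matrix(s[, c("x", "y")]), tpl, values = s$soc_a,
                   nb = neighborhoodSpec(min_neighbors = 1))
  out <- surfaceToRaster(ps, tpl)
  expect_equal(dim(values(out$estimate)), c(4, 5))
  expect_no_na(values(out$estimate))
})
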