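test_that("semivariances match hand calculations on degenerate cases", {
  co <- cbind(c(0, 100), c(0, 0))
  ev <- empiricalVariogram(co, values = c(1, 3), max_lag = 200, n_lags = 1)
  expect_equal(ev@gamma, 2)               # (3 - 1)^2 / 2
  expect_equal(ev@pair_counts, 1)
  expect_equal(ev@lag_centers, 100)       # mean pair distance abscissa

  set.seed(1)
  co <- cbind(runif(12, 0, 100), runif(12, 0, 100))
  ev <- empiricalVariogram(co, values = rep(4, 12), max_lag = 150, n_lags = 5)
  expect_true(all(ev@gamma[ev@pair_counts > 0] == 0))
})

test_that("binned semivariances equal an O(n^2) pair-enumeration oracle", {
  set.seed(123)
  n <- 20
  co <- cbind(runif(n, 0, 5000), runif(n, 0, 5000))
  z <- rnorm(n, 10, 3)
  max_lag <- 3000; n_lags <- 6
  ev <- empiricalVariogram(co, values = z, max_lag = max_lag, n_lags = n_lags)
  # oracle: explicit double loop over unordered pairs
  width <- max_lag / n_lags
  g_sum <- d_sum <- cnt <- numeric(n_lags)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    h <- sqrt(sum((co[i, ] - co[j, ])^2))
    if (h >= max_lag) next
    b <- min(floor(h / width), n_lags - 1) + 1
    g_sum[b] <- g_sum[b] + (z[i] - z[j])^2 / 2
    d_sum[b] <- d_sum[b] + h
    cnt[b] <- cnt[b] + 1
  }
  expect_equal(ev@pair_counts, cnt)
  expect_equal(ev@gamma[cnt > 0], (g_sum / cnt)[cnt > 0], tolerance = 1e-12)
  expect_equal(ev@lag_centers[cnt > 0], (d_sum / cnt)[cnt > 0],
               tolerance = 1e-12)
})

test_that("the estimator is invariant to value shifts and coordinate
           rotations, and scales as data squared", {
  set.seed(5)
  co <- cbind(runif(15, 0, 1000), runif(15, 0, 1000))
  z <- rnorm(15)
  ev0 <- empiricalVariogram(co, values = z, max_lag = 800, n_lags = 4)
  ev_shift <- empiricalVariogram(co, values = z + 100, max_lag = 800,
                                 n_lags = 4)
  expect_equal(ev_shift@gamma, ev0@gamma)
  th <- 0.7
  rot <- co %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ev_rot <- empiricalVariogram(rot, values = z, max_lag = 800, n_lags = 4)
  expect_equal(ev_rot@gamma, ev0@gamma, tolerance = 1e-9)
  ev2 <- empiricalVariogram(co, values = 2 * z, max_lag = 800, n_lags = 4)
  expect_equal(ev2@gamma, 4 * ev0@gamma)
})

test_that("variogram estimation guards its preconditions", {
  co <- cbind(c(0, 5000), c(0, 0))
  expect_error(empiricalVariogram(co, values = c(1, 2), max_lag = 100),
               "beyond max_lag")
  expect_error(empiricalVariogram(co[1, , drop = FALSE], values = 1),
               "two sites")
})

test_that("noiseless exponential bins invert to their parameters", {
  truth <- variogramModel("exponential", 0.5, 1.7, 3000)
  lags <- seq(200, 9000, length.out = 12)
  ev <- new("EmpiricalVariogram", lag_centers = lags,
            gamma = gammaModel(truth, lags),
            pair_counts = rep(100, 12), max_lag = 9200, n_lags = 12L)
  fit <- fitVariogram(ev, "exponential")
  expect_equal(fit@nugget, 0.5, tolerance = 1e-4)
  expect_equal(fit@psill, 1.7, tolerance = 1e-4)
  expect_equal(fit@range_param, 3000, tolerance = 1e-3)
})

test_that("pure-nugget data fit with a negligible partial sill", {
  set.seed(9)
  lags <- seq(100, 4000, length.out = 10)
  g <- 0.8 + rnorm(10, 0, 0.005)
  ev <- new("EmpiricalVariogram", lag_centers = lags, gamma = pmax(g, 0),
            pair_counts = rep(200, 10), max_lag = 4200, n_lags = 10L)
  fit <- fitVariogram(ev)
  expect_lt(fit@psill, 0.05 * fit@nugget)
})

test_that("the returned fit is at least as good as every initialisation", {
  set.seed(21)
  truth <- variogramModel("exponential", 0.3, 1.2, 1500)
  lags <- seq(150, 6000, length.out = 15)
  ev <- new("EmpiricalVariogram", lag_centers = lags,
            gamma = pmax(gammaModel(truth, lags) * (1 + rnorm(15, 0, 0.1)), 0),
            pair_counts = rep(150, 15), max_lag = 6200, n_lags = 15L)
  fit <- fitVariogram(ev)
  expect_true(all(attr(fit, "objective") <=
                    attr(fit, "initials") + 1e-8, na.rm = TRUE))
})

test_that("fit errors on degenerate input", {
  ev <- new("EmpiricalVariogram", lag_centers = c(1, 2, 3, 4),
            gamma = rep(0, 4), pair_counts = rep(5, 4), max_lag = 5,
            n_lags = 4L)
  expect_error(fitVariogram(ev), "degenerate")
  ev2 <- new("EmpiricalVariogram", lag_centers = c(1, 2, 3),
             gamma = c(1, 1, 1), pair_counts = c(1, 1, 1), max_lag = 4,
             n_lags = 3L)
  expect_error(fitVariogram(ev2), "4 non-empty")
})

test_that("nugget-sill ratio classifies spatial dependence", {
  vm <- variogramModel("exponential", 0.529, 2.226 - 0.529, 2000)
  r <- nuggetSillRatio(vm)
  expect_equal(r$ratio, 0.529 / 2.226, tolerance = 1e-12)
  expect_equal(round(r$ratio, 4), 0.2376)
  expect_equal(r$dependence, "strong")
  expect_equal(nuggetSillRatio(variogramModel(nugget = 0, psill = 1,
                                              range_param = 1))$ratio, 0)
  weak <- nuggetSillRatio(variogramModel(nugget = 1, psill = 0,
                                         range_param = 1))
  expect_equal(weak$ratio, 1)
  expect_equal(weak$dependence, "weak")
  expect_error(nuggetSillRatio(variogramModel(nugget = 0, psill = 0,
                                              range_param = 1)), "sill")
})

test_that("variogram artifacts round-trip through CSV and YAML", {
  csv <- withr::local_tempfile(fileext = ".csv")
  yml <- withr::local_tempfile(fileext = ".yaml")
  ev <- empiricalVariogram(cbind(c(0, 100, 300), c(0, 0, 0)),
                           values = c(1, 2, 4), max_lag = 400, n_lags = 2)
  writeVariogramCSV(ev, csv)
  tb <- read.csv(csv)
  expect_equal(tb$n_pairs, ev@pair_counts)
  vm <- variogramModel("spherical", 0.2, 1.1, 2500)
  writeVariogramYAML(vm, yml)
  vm2 <- readVariogramYAML(yml)
  expect_equal(vm2@family, "spherical")
  expect_equal(sill(vm2), sill(vm))
  expect_equal(vm2@range_param, 2500)
})

test_that("variogram model families are monotone with correct limits", {
  for (fam in c("exponential", "spherical", "gaussian")) {
    vm <- variogramModel(fam, 0.4, 1.6, 1000)
    h <- seq(1, 10000, length.out = 400)
    g <- gammaModel(vm, h)
    expect_true(all(diff(g) > -1e-12))
    expect_equal(gammaModel(vm, 0), 0)
    expect_equal(g[1], 0.4, tolerance = 0.02)     # h -> 0+ limit = nugget
    expect_equal(g[length(g)], 2.0, tolerance = 1e-3)
  }
})
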