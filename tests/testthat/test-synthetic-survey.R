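test_that("park generation is deterministic per seed and differs across
           seeds", {
  cfg <- smallParkConfig(seed = 3)
  p1 <- generatePark(cfg)
  p2 <- generatePark(cfg)
  expect_identical(values(p1@soc), values(p2@soc))
  expect_identical(values(p1@dem), values(p2@dem))
  p3 <- generatePark(smallParkConfig(seed = 4))
  expect_false(identical(values(p1@soc), values(p3@soc)))

  s1 <- sites(sampleSurvey(p1, cfg))
  s2 <- sites(sampleSurvey(p1, cfg))
  expect_identical(s1, s2)
})

test_that("the DEM is a noisy cone: summit near the configured maximum,
           ring means declining outward", {
  cfg <- smallParkConfig(seed = 11)
  dem <- generateDem(cfg)
  d <- gridDim(dem)
  centre <- values(dem)[round(d[1] / 2), round(d[2] / 2)]
  expect_gt(centre, cfg@altitude_range[2] - 100)   # noise amplitude ~60 m
  expect_lte(centre, cfg@altitude_range[2])
  # ring-averaging oracle
  cc <- cellCenters(dem)
  half <- cfg@extent_km * 1000 / 2
  r <- sqrt((cc[, 1] - half)^2 + (cc[, 2] - half)^2)
  ring <- cut(r, seq(0, half, length.out = 8))
  ring_mean <- tapply(as.vector(values(dem)), ring, mean)
  expect_true(all(diff(ring_mean) < 0))
})

test_that("land use follows the altitude bands with the documented edge
           convention", {
  cfg <- surveyConfig()
  dem <- gridRaster(matrix(c(4100, 2300, 3000.0, 3500, 2500, 4600), 2, 3),
                    0, 0, 200)
  lu <- assignLanduse(dem, cfg)
  lab <- matrix(landUseLevels[values(lu)], 2, 3)
  expect_equal(lab[1, 1], "grassland")         # over 4000
  expect_equal(lab[2, 1], "agriculture")       # 2300
  # 3000.0 sits in the lower (overlap) band, never pure forest
  expect_true(lab[1, 2] %in% c("agriculture", "forest"))
  expect_equal(lab[2, 2], "forest")            # 3500
  expect_equal(lab[1, 3], "agriculture")       # 2500 belongs to the lowest
  expect_equal(lab[2, 3], "grassland")
  cfg_bad <- surveyConfig(altitude_range = c(2200, 4461))
  dem_bad <- gridRaster(matrix(1000, 2, 2), 0, 0, 200)
  expect_error(assignLanduse(dem_bad, cfg_bad), "outside all")
})

test_that("a nugget-only configuration yields spatially uncorrelated
           values", {
  # full-size grid (~1.2e4 cells) so the correlation bound is sharp
  cfg <- surveyConfig(seed = 5,
    variogram = variogramModel("exponential", 0.6, 0, 1000))
  park <- generatePark(cfg)
  v <- log(values(park@soc))
  # strip stratum means, then lag-1 (row-neighbour) correlation
  mu <- tapply(as.vector(v), as.vector(values(park@landuse)), mean)
  res <- v - matrix(mu[as.character(values(park@landuse))], nrow(v))
  r <- cor(as.vector(res[-1, ]), as.vector(res[-nrow(res), ]))
  expect_lt(abs(r), 0.05)
})

test_that("one realization's empirical semivariogram tracks the generating
           model within 15% inside the range", {
  cfg <- surveyConfig(seed = 8)
  park <- generatePark(cfg)
  set.seed(1)
  d <- gridDim(park@soc)
  cells <- sample(prod(d), 1200)
  row <- (cells - 1) %% d[1] + 1; col <- (cells - 1) %/% d[1] + 1
  cs <- cellSize(park@soc)
  co <- cbind((col - 0.5) * cs, (row - 0.5) * cs)
  z <- log(values(park@soc)[cbind(row, col)])
  lu <- landUseLevels[values(park@landuse)[cbind(row, col)]]
  mu <- tapply(z, lu, mean)
  ev <- empiricalVariogram(co, values = z - mu[lu], max_lag = 2200,
                           n_lags = 8)
  model <- gammaModel(cfg@variogram, ev@lag_centers)
  ok <- ev@pair_counts > 30
  expect_true(all(abs(ev@gamma[ok] / model[ok] - 1) < 0.15))
})

test_that("back-transformed stratum means land within sampling error of the
           configured means", {
  cfg <- surveyConfig(seed = 6)
  park <- generatePark(cfg)
  soc <- as.vector(values(park@soc))
  lu <- landUseLevels[as.vector(values(park@landuse))]
  sill_tot <- sill(cfg@variogram)
  for (i in seq_len(nrow(cfg@strata))) {
    cls <- cfg@strata$land_use[i]
    x <- soc[lu == cls]
    m <- mean(x)
    # lognormal mean has SE ~ mean * sqrt((exp(sill)-1)/n_eff); spatial
    # correlation shrinks n_eff, so allow 2 SE with n_eff = n / 50
    se <- cfg@strata$mean_soc[i] *
      sqrt((exp(sill_tot) - 1) / (length(x) / 50))
    expect_lt(abs(m - cfg@strata$mean_soc[i]), 2 * se)
  }
})

test_that("stratum log-scale spreads match the generating sill", {
  cfg <- surveyConfig(seed = 2)
  sv <- sites(sampleSurvey(generatePark(cfg), cfg))
  truth_sd <- sqrt(sill(cfg@variogram))
  for (cls in c("forest", "agriculture")) {
    x <- log(sv$soc_a[sv$land_use == cls])
    if (length(x) < 100) next
    expect_lt(abs(sd(x) - truth_sd) / truth_sd, 0.3)
  }
})

test_that("the default survey has 440 valid sites with stratum counts
           proportional to class areas", {
  cfg <- surveyConfig(seed = 1)
  park <- generatePark(cfg)
  sv <- sampleSurvey(park, cfg)
  expect_equal(length(sv), 440)
  expect_true(validObject(sv))
  s <- sites(sv)
  # agriculture carries no O horizon
  ag <- s[s$land_use == "agriculture", ]
  expect_true(all(ag$o_thickness == 0))
  expect_true(all(is.na(ag$soc_o)))
  # forest sites carry O horizons with SOC in the configured range
  fo <- s[s$land_use == "forest", ]
  expect_true(all(fo$o_thickness > 0))
  expect_true(all(fo$soc_o >= cfg@o_soc_range[1] &
                  fo$soc_o <= cfg@o_soc_range[2]))
  # counts proportional to areas (largest-remainder apportionment)
  codes <- as.vector(values(park@landuse))
  cnt <- tabulate(codes, 3)
  expected <- 440 * cnt / sum(cnt)
  got <- table(factor(s$land_use, levels = landUseLevels))
  expect_true(all(abs(as.numeric(got) - expected) <= 1))
  # enough grassland for the hold-out quota
  expect_gte(sum(s$land_use == "grassland"), 7)
})

test_that("NDVI is clipped, positively linked to SOC and monotone without
           noise", {
  cfg <- smallParkConfig(seed = 9)
  park <- generatePark(cfg)
  expect_true(all(values(park@ndvi) >= -1 & values(park@ndvi) <= 1))
  r <- cor(as.vector(values(park@ndvi)), as.vector(values(park@soc)))
  expect_gt(r, 0)

  cfg0 <- smallParkConfig(seed = 9,
    ndvi_link = c(intercept = 0.32, slope = 0.08, noise_sd = 0))
  park0 <- generatePark(cfg0)
  rs <- cor(as.vector(values(park0@ndvi)), as.vector(values(park0@soc)),
            method = "spearman")
  expect_equal(rs, 1, tolerance = 1e-12)

  # default link strength: r in [0.4, 0.9] at full scale
  cfg1 <- surveyConfig(seed = 10)
  park1 <- generatePark(cfg1)
  r1 <- cor(as.vector(values(park1@ndvi)), as.vector(values(park1@soc)))
  expect_gt(r1, 0.4); expect_lt(r1, 0.9)
})
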