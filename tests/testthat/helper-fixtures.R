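# Shared fixture builders. Everything is generated in code; nothing is
# stored on disk.

# a tiny valid site table
tinySites <- function(n = 3) {
  data.frame(
    site_id = sprintf("S%02d", seq_len(n)),
    x = seq(0, by = 1500, length.out = n),
    y = seq(0, by = 900, length.out = n),
    altitude = seq(2400, by = 300, length.out = n),
    land_use = rep(c("forest", "grassland", "agriculture"), length.out = n),
    soc_a = seq(10, by = 5, length.out = n),
    soc_o = c(300, rep(NA, n - 1)),
    o_thickness = c(5, rep(0, n - 1)),
    bulk_density = rep(1.1, n),
    coarse_pct = rep(10, n))
}

# a small survey with spatially structured values, deterministic
smallSurvey <- function(n = 40, seed = 42) {
  set.seed(seed)
  x <- runif(n, 0, 10000); y <- runif(n, 0, 10000)
  z <- 20 + 10 * sin(x / 3000) + 8 * cos(y / 2500) + rnorm(n, 0, 1)
  soilSurvey(data.frame(
    site_id = sprintf("P%03d", seq_len(n)), x = x, y = y,
    altitude = 2500 + z * 10,
    land_use = rep(landUseLevels, length.out = n),
    soc_a = pmax(z, 1), bulk_density = 1.1, coarse_pct = 5))
}

# small park configuration that keeps grids tiny and tests fast
smallParkConfig <- function(seed = 7, extent_km = 8, n_sites = 80, ...) {
  surveyConfig(seed = seed, extent_km = extent_km, n_sites = n_sites,
               cell_size = 250, ...)
}

expect_no_na <- function(x) expect_false(anyNA(x))
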