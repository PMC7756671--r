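# Synthetic campaign generator: determinism, driver structure, flux truth,
# series synthesis round trips.

test_that("identical config and seed give identical campaigns", {
  cfg <- small_config()
  d1 <- generate_drivers(cfg)
  d2 <- generate_drivers(cfg)
  expect_identical(d1, d2)
  s1 <- simulate_campaign(cfg, seed = 3)
  s2 <- simulate_campaign(cfg, seed = 3)
  expect_identical(s1$conc, s2$conc)
  expect_identical(s1$truth, s2$truth)
})

test_that("zero amplitude and zero noise give season-free drivers", {
  cfg <- campaign_config(sites = default_site_design(), n_replicates = 2,
                         n_months = 5, seasonal_amplitude = 0,
                         driver_noise_sd = 0, seed = 1)
  d <- generate_drivers(cfg)
  for (col in c("wt", "wfps", "air_t", "soil_t", "co2", "no3", "net_nit",
                "precip")) {
    per_chamber <- tapply(d[[col]], d$chamber_id,
                          function(x) diff(range(x)))
    expect_true(all(per_chamber == 0), info = col)
  }
})

test_that("the hollow-hummock water-table offset matches the configuration", {
  cfg <- campaign_config(n_replicates = 9, n_months = 12,
                         wt_hummock_offset_cm = 12, seed = 1)
  d <- generate_drivers(cfg)
  hollow <- d$wt[d$microtopography == "hollow"]
  hummock <- d$wt[d$microtopography == "hummock"]
  # same seasonal term in expectation; AR(1) noise has SD 6 cm
  mc_se <- 6 * sqrt(1 / length(hollow) + 1 / length(hummock))
  expect_lt(abs(mean(hollow) - mean(hummock) - 12), 4 * mc_se + 0.5)
  expect_gt(mean(hollow), mean(hummock))
  expect_true(all(d$wfps >= 0))
  expect_true(all(d$precip > 0))
  expect_true(all(is.finite(as.matrix(
    d[c("wt", "wfps", "air_t", "soil_t", "co2", "no3", "net_nit")]))))
})

test_that("true fluxes evaluate the generative forms", {
  drv <- data.frame(wt = c(0, -20), wfps = c(0, 60), co2 = c(0, 40))
  # water-table form at WT = 0 gives the published intercept
  tf <- generate_true_fluxes(drv, catalog_truth_spec(30), noise_sd = 0)
  expect_equal(tf$true_flux[1], 616.09)
  expect_equal(tf$true_flux[2], 14.95 * -20 + 616.09)
  # log-offset form at zero covariates: exp(intercept) - 4
  tf2 <- generate_true_fluxes(drv, catalog_truth_spec(15), noise_sd = 0)
  expect_equal(tf2$true_flux[1], exp(0.63) - 4)
  expect_error(flux_model_spec("cubic", c(wt = 1), 0), "supported forms")
  expect_error(generate_true_fluxes(drv, flux_model_spec(
    "linear", c(net_nit = 1), 0)), "lacks columns")
})

test_that("noisy linear truths converge to the noiseless value", {
  drv <- data.frame(wt = rep(-10, 1e5))
  spec <- catalog_truth_spec(30)
  tf <- generate_true_fluxes(drv, spec, noise_sd = 50, seed = 6)
  noiseless <- 14.95 * -10 + 616.09
  expect_lt(abs(mean(tf$true_flux) - noiseless), 3 * 50 / sqrt(1e5))
})

test_that("series synthesis is the exact inverse of flux fitting", {
  # zero flux, no noise: flat at ambient
  s0 <- synthesize_chamber_series(0, "N2O", 330, gc_cv = 0)
  expect_equal(s0$conc_ppb, rep(330, 4))
  # noiseless round trip across random conditions
  set.seed(31)
  for (i in 1:25) {
    flux <- runif(1, -50, 400)
    h <- runif(1, 0.15, 0.4)
    temp <- runif(1, 20, 35)
    p <- runif(1, 98, 103)
    s <- synthesize_chamber_series(flux, "CH4", 1522, gc_cv = 0,
                                   geometry = chamber_geometry(h),
                                   air_temp_c = temp, pressure_kpa = p)
    e <- fit_flux(s)
    # fit_flux converts with the series' own conditions
    e_flux <- convert_slope(e$slope, chamber_geometry(h), temp, p, "CH4")
    expect_lt(abs(e_flux - flux) / max(abs(flux), 1e-9), 1e-3)
  }
})

test_that("anomalies deform the series as designed", {
  s_leak <- synthesize_chamber_series(300, "CH4", 1522, gc_cv = 0,
                                      anomaly = "leak_point", seed = 5)
  # the t = 0 sample already sits at ambient; the leaked later point
  # returns there, so two values equal ambient and the rest stay on the line
  expect_equal(sum(s_leak$conc_ppb == 1522), 2L)
  ideal <- 1522 + 300 / convert_slope(1, gas = "CH4") * c(0, 10, 20, 30)
  expect_true(all(s_leak$conc_ppb %in% c(1522, ideal)))
  s_nl <- synthesize_chamber_series(300, "CH4", 1522, gc_cv = 0,
                                    anomaly = "nonlinear")
  # saturating curvature: increments shrink over time
  expect_true(all(diff(diff(s_nl$conc_ppb)) < 0))
  expect_lt(ols_r2 <- fit_flux(s_nl, qc_policy(r2_min = 0))$r2, 1)
})

test_that("truth and observation tables agree on keys, and CSV round-trips", {
  sim <- simulate_campaign(small_config(), seed = 9)
  series <- as_series_df(sim)
  truth_keys <- unique(paste(sim$truth$chamber_id, sim$truth$date))
  series_keys <- unique(paste(series$chamber_id, series$date))
  expect_setequal(series_keys, truth_keys)

  dir <- tempfile("campaign")
  paths <- write_campaign_csv(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_chamber_csv(paths[1])
  expect_equal(nrow(back), nrow(series))
  expect_equal(back$conc_ppb, series$conc_ppb, tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
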