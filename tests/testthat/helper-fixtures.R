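# Shared fixtures for the test suite.

# A clean four-point series with a known slope (ppb min^-1).
make_series <- function(slope = 1, ambient = 330, gas = "N2O",
                        times = c(0, 10, 20, 30), ...) {
  chamber_series(times, ambient + slope * times, gas = gas, ...)
}

# Small campaign config (one degraded site, few replicates/months) for fast
# pipeline tests.
small_config <- function(...) {
  design <- default_site_design()
  campaign_config(sites = design[design$site == "hDeg", ],
                  n_replicates = 3, n_months = 6, seed = 42L, ...)
}

# Budget-year starts used throughout (April to March).
year_starts <- as.Date(c("2015-04-01", "2016-04-01", "2017-04-01"))
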