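# Whole-campaign simulation, vectorised estimation and budget pipeline.

#' Simulate a complete synthetic campaign
#'
#' Chains [generate_drivers()], [generate_true_fluxes()] and (vectorised)
#' chamber-series synthesis into a campaign with known ground truth:
#' drivers, true fluxes, anomaly assignments and noisy four-point
#' concentration series for every chamber-month. Identical `(config, seed)`
#' give identical campaigns. Sub-stage seeds are derived as `seed`,
#' `seed + 1`, `seed + 2`, `seed + 3` (drivers, flux noise, anomalies, GC
#' noise).
#'
#' @param config A [campaign_config()].
#' @param gas `"N2O"` or `"CH4"`.
#' @param truth_spec A [flux_model_spec()]; default the catalogued
#'   water-table model for CH4 (slope 14.95, intercept 616.09).
#' @param flux_noise_sd Chamber-to-chamber flux noise SD on the truth
#'   model's response scale. Default 200 g C ha^-1 day^-1 for the default
#'   CH4 truth.
#' @param hotspot_chamber Optional chamber_id to plant as a hotspot.
#' @param hotspot_months Month indices receiving injected extreme fluxes.
#' @param hotspot_flux Injected true flux for those months.
#' @param seed Base seed (default `config$seed`).
#' @return Object of class `campaign_sim`: `truth` (drivers + true_flux +
#'   anomaly), `conc` (matrix, one series per row), `times_min`, `gas`,
#'   `config`.
#' @export
simulate_campaign <- function(config, gas = c("CH4", "N2O"),
                              truth_spec = catalog_truth_spec(30),
                              flux_noise_sd = 200, hotspot_chamber = NULL,
                              hotspot_months = integer(0),
                              hotspot_flux = NULL, seed = config$seed) {
  gas <- match.arg(gas)
  stopifnot(inherits(config, "campaign_config"))
  truth <- generate_true_fluxes(generate_drivers(config, seed), truth_spec,
                                noise_sd = flux_noise_sd, seed = seed + 1L)
  if (!is.null(hotspot_chamber)) {
    sel <- truth$chamber_id == hotspot_chamber &
      truth$month %in% hotspot_months
    if (!any(sel)) stop("hotspot chamber/months not found in the design")
    truth$true_flux[sel] <- hotspot_flux
  }
  n <- nrow(truth)

  truth$anomaly <- with_seed(seed + 2L, {
    a <- rep("none", n)
    hit <- stats::runif(n) < config$anomaly_prob
    a[hit] <- sample(c("leak_point", "nonlinear"), sum(hit), replace = TRUE)
    a
  })

  times <- config$times_min
  k <- length(times)
  ambient <- config$ambient_ppb[[gas]]
  cv <- config$gc_cv[[gas]]
  slope <- truth$true_flux /
    convert_slope(1, config$geometry, truth$air_t, gas = gas)

  conc <- with_seed(seed + 3L, {
    ideal <- outer(slope, times)
    nl <- truth$anomaly == "nonlinear"
    if (any(nl)) {
      tau <- 20
      ideal[nl, ] <- outer(slope[nl], tau * (1 - exp(-times / tau)))
    }
    cm <- (ambient + ideal) *
      (1 + cv * matrix(stats::rnorm(n * k), n, k))
    leak <- which(truth$anomaly == "leak_point")
    if (length(leak))
      cm[cbind(leak, sample.int(k, length(leak), replace = TRUE))] <- ambient
    pmax(cm, 0.001)
  })

  structure(list(truth = truth, conc = conc, times_min = times, gas = gas,
                 config = config),
            class = "campaign_sim")
}

#' @export
print.campaign_sim <- function(x, ...) {
  cat(sprintf("Simulated campaign: %d chamber series (%s), %d anomalies\n",
              nrow(x$truth), x$gas, sum(x$truth$anomaly != "none")))
  invisible(x)
}

#' Estimate fluxes for a simulated campaign
#'
#' Vectorised per-series OLS with the leave-one-out QC fallback, then unit
#' conversion — the fast equivalent of calling [fit_flux()] on every series.
#'
#' @param sim A [simulate_campaign()] result.
#' @param policy A [qc_policy()].
#' @return The truth table with `slope`, `r2`, `n_used`, `qc_flag` and
#'   estimated `flux` columns appended.
#' @export
estimate_campaign <- function(sim, policy = qc_policy()) {
  stopifnot(inherits(sim, "campaign_sim"))
  fits <- fit_flux_matrix(sim$conc, sim$times_min, policy)
  out <- sim$truth
  out$slope <- fits$slope
  out$r2 <- fits$r2
  out$n_used <- fits$n_used
  out$qc_flag <- fits$qc_flag
  out$flux <- convert_slope(fits$slope, sim$config$geometry, out$air_t,
                            gas = sim$gas)
  out
}

#' Site-scale annual budgets from a per-chamber flux table
#'
#' The full aggregation chain: replicate chambers to monthly stratum means,
#' trapezoid integration to per-stratum annual budgets for each requested
#' year window, then area-weighted site-scale combination with Gaussian
#' error propagation.
#'
#' @param df Data frame with columns `site`, `status`, `microtopography`,
#'   `date` and the value column.
#' @param weights Named list per site of stratum weight vectors, as from
#'   [area_weights()].
#' @param window_starts `Date` vector of budget-year starts (April 1 by
#'   convention).
#' @param value Value column name (default `"flux"`).
#' @return Data frame: site, window_start, cumulative (kg ha^-1 yr^-1), se.
#' @export
site_annual_budget <- function(df, weights = area_weights(),
                               window_starts, value = "flux") {
  monthly <- monthly_means(df, value = value)
  out <- list()
  for (site in unique(monthly$site)) {
    msite <- monthly[monthly$site == site, ]
    w <- weights[[site]]
    if (is.null(w)) stop("no weights for site ", site)
    for (ws in as.list(window_starts)) {
      key <- paste(msite$status, msite$microtopography, sep = "_")
      ann <- lapply(split(msite, key), function(d) {
        d <- d[order(d$date), ]
        annual_cumulative(d$date, d$mean, d$se, window_start = ws)
      })
      vals <- vapply(ann, `[[`, numeric(1), "cumulative")
      ses <- vapply(ann, `[[`, numeric(1), "se")
      sc <- site_scale(vals, w, ses)
      out[[length(out) + 1L]] <- data.frame(
        site = site, window_start = ws, cumulative = sc$mean, se = sc$se,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Long-format chamber series table of a simulated campaign
#'
#' Materialises the campaign's concentration matrix as the long CSV schema
#' (one row per sampling point) consumed by [fit_flux_table()].
#'
#' @param sim A [simulate_campaign()] result.
#' @return Data frame: chamber_id, site, status, microtopography, replicate,
#'   date, t_min, conc_ppb, gas, air_temp_C, soil_temp_C, pressure_kPa,
#'   headspace_m.
#' @export
as_series_df <- function(sim) {
  stopifnot(inherits(sim, "campaign_sim"))
  n <- nrow(sim$truth)
  k <- length(sim$times_min)
  idx <- rep(seq_len(n), each = k)
  data.frame(
    chamber_id = sim$truth$chamber_id[idx],
    site = sim$truth$site[idx],
    status = sim$truth$status[idx],
    microtopography = sim$truth$microtopography[idx],
    replicate = sim$truth$replicate[idx],
    date = sim$truth$date[idx],
    t_min = rep(sim$times_min, times = n),
    conc_ppb = as.vector(t(sim$conc)),
    gas = sim$gas,
    air_temp_C = sim$truth$air_t[idx],
    soil_temp_C = sim$truth$soil_t[idx],
    pressure_kPa = 101.325,
    headspace_m = sim$config$geometry$height_m,
    stringsAsFactors = FALSE)
}

#' Write a simulated campaign to CSV files
#'
#' Writes the chamber-series, driver and truth tables of a campaign as
#' plain CSV (`series.csv`, `drivers.csv`, `truth.csv`). Column definitions
#' and units are documented in the bundled schema file
#' `system.file("extdata", "campaign_schema.csv", package = "peatflux")`.
#'
#' @param sim A [simulate_campaign()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_campaign_csv <- function(sim, dir) {
  stopifnot(inherits(sim, "campaign_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("series.csv", "drivers.csv", "truth.csv"))
  utils::write.csv(as_series_df(sim), paths[1], row.names = FALSE)
  drv <- sim$truth[setdiff(names(sim$truth),
                           c("true_flux", "anomaly"))]
  utils::write.csv(drv, paths[2], row.names = FALSE)
  utils::write.csv(sim$truth, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a chamber-series CSV
#'
#' Reads the long-format schema written by [write_campaign_csv()] (dates
#' restored as `Date`).
#'
#' @param path CSV path.
#' @return Data frame suitable for [fit_flux_table()].
#' @export
read_chamber_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  df
}
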