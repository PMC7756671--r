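# Synthetic field campaigns: design, seasonal drivers, true fluxes and noisy
# chamber series with known ground truth.

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Default stratified site design
#'
#' Three sites along a degradation gradient (Intact, mDeg, hDeg), stratified
#' by palm status (live, cut) and microtopography (hummock, hollow), with
#' the mapped area fractions of each stratum. The intact site has no cut
#' palms.
#'
#' @return Data frame with columns `site`, `status`, `microtopography`,
#'   `weight`.
#' @export
default_site_design <- function() {
  data.frame(
    site = c("Intact", "Intact",
             "mDeg", "mDeg", "mDeg", "mDeg",
             "hDeg", "hDeg", "hDeg", "hDeg"),
    status = c("live", "live",
               "live", "live", "cut", "cut",
               "live", "live", "cut", "cut"),
    microtopography = c("hummock", "hollow",
                        "hummock", "hollow", "hummock", "hollow",
                        "hummock", "hollow", "hummock", "hollow"),
    # hDeg fractions are published as 0.02/0.59/0.02/0.38 (sum 1.01 from
    # printed rounding); normalized here so strata tile the site exactly.
    weight = c(0.15, 0.85,
               0.08, 0.79, 0.01, 0.12,
               c(0.02, 0.59, 0.02, 0.38) / 1.01),
    stringsAsFactors = FALSE)
}

#' Area weights per site from a site design
#'
#' @param design A site design as from [default_site_design()].
#' @return Named list (per site) of named weight vectors
#'   (`status_microtopography`).
#' @export
area_weights <- function(design = default_site_design()) {
  lapply(split(design, design$site), function(d)
    stats::setNames(d$weight, paste(d$status, d$microtopography, sep = "_")))
}

#' Campaign configuration
#'
#' Describes a synthetic monitoring campaign: the stratified design, number
#' of replicate chambers, monthly campaigns, chamber sampling scheme, GC
#' precision, and the seasonal/noise structure of the environmental drivers.
#' Defaults mirror the monitored design: 3 sites x up to 4
#' status-microtopography strata x 9 replicate chambers x 40 monthly
#' campaigns starting April 2015, samples at 0/10/20/30 min in a 25 cm x
#' 30 cm chamber, GC CV 9% at 330 ppb (N2O) and 1% at 1522 ppb (CH4), and a
#' 7% anomaly rate (leaked or nonlinear series).
#'
#' @param sites Site design data frame (see [default_site_design()]).
#' @param n_replicates Replicate chambers per stratum (>= 1). Default 9.
#' @param n_months Monthly campaigns. Default 40.
#' @param start_date Date of the first campaign. Default 2015-04-15
#'   (mid-month sampling).
#' @param times_min Chamber sampling times, minutes, strictly increasing.
#' @param geometry A [chamber_geometry()].
#' @param gc_cv Named GC analytical CVs per gas (fractions).
#' @param ambient_ppb Named ambient concentrations per gas.
#' @param anomaly_prob Probability that a chamber series carries one anomaly
#'   (leaked point or saturating nonlinearity). Default 0.07.
#' @param seasonal_amplitude Multiplier on all seasonal amplitudes (0 =
#'   season-free drivers). Default 1.
#' @param driver_noise_sd Multiplier on all stochastic driver components
#'   (0 = deterministic drivers). Default 1.
#' @param wt_hummock_offset_cm How much lower the hummock water table sits
#'   relative to the adjacent hollow, cm. Default 12 (observed gaps range
#'   from about 7 cm at degraded sites to 16 cm at the intact site).
#' @param seed Integer RNG seed.
#' @return Object of class `campaign_config`.
#' @export
campaign_config <- function(sites = default_site_design(), n_replicates = 9,
                            n_months = 40,
                            start_date = as.Date("2015-04-15"),
                            times_min = c(0, 10, 20, 30),
                            geometry = chamber_geometry(),
                            gc_cv = c(N2O = 0.09, CH4 = 0.01),
                            ambient_ppb = c(N2O = 330, CH4 = 1522),
                            anomaly_prob = 0.07, seasonal_amplitude = 1,
                            driver_noise_sd = 1, wt_hummock_offset_cm = 12,
                            seed = 1L) {
  stopifnot(is.data.frame(sites),
            all(c("site", "status", "microtopography", "weight") %in%
                  names(sites)))
  wsum <- tapply(sites$weight, sites$site, sum)
  if (any(abs(wsum - 1) > 1e-9))
    stop("area weights must sum to 1 per site: ",
         paste(names(wsum)[abs(wsum - 1) > 1e-9], collapse = ", "))
  if (!is.numeric(n_replicates) || n_replicates < 1)
    stop("n_replicates must be >= 1")
  if (!is.numeric(n_months) || n_months < 1)
    stop("n_months must be >= 1")
  if (length(times_min) < 3L || any(diff(times_min) <= 0))
    stop("sampling times must be >= 3 strictly increasing values")
  if (anomaly_prob < 0 || anomaly_prob > 1)
    stop("anomaly_prob must be in [0, 1]")
  if (seasonal_amplitude < 0 || driver_noise_sd < 0)
    stop("amplitude/noise multipliers must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  structure(list(sites = sites, n_replicates = as.integer(n_replicates),
                 n_months = as.integer(n_months), start_date = start_date,
                 times_min = times_min, geometry = geometry, gc_cv = gc_cv,
                 ambient_ppb = ambient_ppb, anomaly_prob = anomaly_prob,
                 seasonal_amplitude = seasonal_amplitude,
                 driver_noise_sd = driver_noise_sd,
                 wt_hummock_offset_cm = wt_hummock_offset_cm,
                 seed = as.integer(seed)),
            class = "campaign_config")
}

#' @export
print.campaign_config <- function(x, ...) {
  cat(sprintf("Campaign: %d sites, %d strata, %d replicates, %d months from %s\n",
              length(unique(x$sites$site)), nrow(x$sites), x$n_replicates,
              x$n_months, format(x$start_date)))
  invisible(x)
}

# Stationary AR(1) noise matrix (rows = chambers, cols = months).
.ar1_noise <- function(n, m, sd, rho = 0.5) {
  e <- matrix(0, n, m)
  if (sd <= 0 || n == 0L) return(e)
  e[, 1] <- stats::rnorm(n, 0, sd)
  if (m > 1) {
    innov_sd <- sd * sqrt(1 - rho^2)
    for (t in 2:m) e[, t] <- rho * e[, t - 1] + stats::rnorm(n, 0, innov_sd)
  }
  e
}

#' Generate seasonal environmental drivers
#'
#' Simulates the driver fields of a campaign: monthly precipitation and
#' chamber-level water table (WT), WFPS, air and soil temperature, soil
#' respiration, NO3- content and net nitrification rate. Seasonality is
#' sinusoidal on the calendar month — wet season peaking January-April
#' (> 400 mm at full amplitude), dry June-September (< 200 mm) — with
#' stratum structure (hummock WT `wt_hummock_offset_cm` below the hollow,
#' higher respiration on hummocks) and AR(1) chamber-level noise. Identical
#' `(config, seed)` give identical tables.
#'
#' @param config A [campaign_config()].
#' @param seed Seed (default `config$seed`).
#' @return Data frame keyed on (chamber_id, month): site, status,
#'   microtopography, replicate, month, date, wt (cm, positive above the
#'   surface), wfps (%), air_t, soil_t (degC), co2 (soil respiration,
#'   kg C ha^-1 day^-1), no3 (mg N kg^-1), net_nit
#'   (mg N kg^-1 day^-1), precip (mm month^-1).
#' @export
generate_drivers <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "campaign_config"))
  with_seed(seed, {
    A <- config$seasonal_amplitude
    D <- config$driver_noise_sd
    m <- config$n_months

    chambers <- merge(config$sites,
                      data.frame(replicate = seq_len(config$n_replicates)))
    chambers <- chambers[order(chambers$site, chambers$status,
                               chambers$microtopography,
                               chambers$replicate), ]
    chambers$chamber_id <- sprintf("%s_%s_%s_r%02d", chambers$site,
                                   chambers$status,
                                   chambers$microtopography,
                                   chambers$replicate)
    nc <- nrow(chambers)
    dates <- seq(config$start_date, by = "month", length.out = m)
    cal <- as.integer(format(dates, "%m"))

    # Shared (site-independent) monthly climate.
    precip_season <- 275 + A * 150 * cospi((cal - 2.5) / 6)
    p_sd <- 0.15 * D
    precip <- precip_season *
      exp(stats::rnorm(m, 0, p_sd) - p_sd^2 / 2)

    wt_season <- -8 + A * 20 * cospi((cal - 3) / 6)
    air_season <- 30 + A * 1.5 * cospi((cal - 10) / 6)
    soil_season <- 25.5 + A * 1.5 * cospi((cal - 10) / 6)

    hummock <- chambers$microtopography == "hummock"
    wt <- matrix(wt_season, nc, m, byrow = TRUE) -
      ifelse(hummock, config$wt_hummock_offset_cm, 0) +
      .ar1_noise(nc, m, 6 * D)
    wfps <- pmin(pmax(72 + 0.30 * wt +
                        matrix(stats::rnorm(nc * m, 0, 3 * D), nc, m), 0), 120)
    air_t <- matrix(air_season, nc, m, byrow = TRUE) +
      matrix(stats::rnorm(nc * m, 0, 0.8 * D), nc, m)
    soil_t <- matrix(soil_season, nc, m, byrow = TRUE) +
      matrix(stats::rnorm(nc * m, 0, 0.8 * D), nc, m)
    co2 <- pmax(ifelse(hummock, 45, 30) - 0.25 * wt +
                  matrix(stats::rnorm(nc * m, 0, 5 * D), nc, m), 0)
    no3 <- exp(log(2.5) + matrix(stats::rnorm(nc * m, 0, 0.4 * D), nc, m))
    net_nit <- 0.3 + matrix(stats::rnorm(nc * m, 0, 0.25 * D), nc, m)

    out <- data.frame(
      chamber_id = rep(chambers$chamber_id, times = m),
      site = rep(chambers$site, times = m),
      status = rep(chambers$status, times = m),
      microtopography = rep(chambers$microtopography, times = m),
      replicate = rep(chambers$replicate, times = m),
      month = rep(seq_len(m), each = nc),
      date = rep(dates, each = nc),
      wt = as.vector(wt), wfps = as.vector(wfps),
      air_t = as.vector(air_t), soil_t = as.vector(soil_t),
      co2 = as.vector(co2), no3 = as.vector(no3),
      net_nit = as.vector(net_nit),
      precip = rep(precip, each = nc),
      stringsAsFactors = FALSE)
    out[order(out$chamber_id, out$month), ]
  })
}

SUPPORTED_FLUX_FORMS <- c("linear", "log_offset_linear", "exponential_wt",
                          "quadratic_wfps")

#' Generative flux model specification
#'
#' Names a supported functional form plus its coefficients for use as the
#' ground truth of [generate_true_fluxes()].
#'
#' @param form One of `"linear"`, `"log_offset_linear"` (linear predictor on
#'   `log(flux + offset)`, back-transformed so uptake is possible),
#'   `"exponential_wt"` (`flux = exp(a + b wt)`), `"quadratic_wfps"`
#'   (`flux = a + b wfps + c wfps^2`; name the square coefficient
#'   `"wfps^2"`).
#' @param coefficients Named slopes (names are driver columns).
#' @param intercept Intercept.
#' @param offset Back-transform offset of the log-offset form (default 4).
#' @return A `flux_model_spec` list.
#' @export
flux_model_spec <- function(form, coefficients, intercept,
                            offset = LN_FLUX_OFFSET) {
  if (!form %in% SUPPORTED_FLUX_FORMS)
    stop("unknown form '", form, "'; supported forms: ",
         paste(SUPPORTED_FLUX_FORMS, collapse = ", "))
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            is.numeric(intercept))
  structure(list(form = form, coefficients = coefficients,
                 intercept = intercept, offset = offset),
            class = "flux_model_spec")
}

#' Generative spec from a catalogued driver model
#'
#' Maps a [driver_catalog()] entry to a [flux_model_spec()]: `identity`
#' responses become the `linear` form, `ln_offset` responses the
#' `log_offset_linear` form.
#'
#' @param eq Catalog equation number.
#' @return A `flux_model_spec`.
#' @export
catalog_truth_spec <- function(eq) {
  m <- catalog_model(eq)
  form <- if (m$transform == "ln_offset") "log_offset_linear" else "linear"
  flux_model_spec(form, m$coefficients, m$intercept, offset = m$offset)
}

#' Generate true fluxes from drivers
#'
#' Evaluates the generative model on the driver table and adds Gaussian
#' noise on the model's response scale (the linear predictor for log-link
#' forms, which are then back-transformed; `exp(eta) - offset` for the
#' log-offset form, so simulated fluxes can be negative).
#'
#' @param drivers Driver table from [generate_drivers()].
#' @param model_spec A [flux_model_spec()].
#' @param noise_sd Gaussian noise SD on the response scale of the form.
#' @param seed RNG seed.
#' @return The driver table with a `true_flux` column appended.
#' @export
generate_true_fluxes <- function(drivers, model_spec, noise_sd = 0,
                                 seed = 1L) {
  if (!inherits(model_spec, "flux_model_spec"))
    stop("model_spec must be a flux_model_spec; supported forms: ",
         paste(SUPPORTED_FLUX_FORMS, collapse = ", "))
  stopifnot(noise_sd >= 0)
  n <- nrow(drivers)
  b <- model_spec$coefficients
  terms <- unique(sub("\\^2$", "", names(b)))
  miss <- setdiff(terms, names(drivers))
  if (length(miss))
    stop("drivers table lacks columns: ", paste(miss, collapse = ", "))

  eta <- model_spec$intercept + switch(model_spec$form,
    linear = ,
    log_offset_linear = as.vector(
      as.matrix(drivers[names(b)]) %*% b),
    exponential_wt = b[["wt"]] * drivers$wt,
    quadratic_wfps = b[["wfps"]] * drivers$wfps +
      b[["wfps^2"]] * drivers$wfps^2)

  noise <- if (noise_sd > 0)
    with_seed(seed, stats::rnorm(n, 0, noise_sd)) else numeric(n)
  eta <- eta + noise
  drivers$true_flux <- switch(model_spec$form,
    linear = , quadratic_wfps = eta,
    log_offset_linear = exp(eta) - model_spec$offset,
    exponential_wt = exp(eta))
  drivers
}

#' Synthesize one chamber series from a true flux
#'
#' Inverts [convert_slope()] to turn an areal flux into a concentration
#' slope, builds the ideal headspace series and perturbs it with
#' multiplicative GC noise of coefficient of variation `gc_cv`. Anomalies:
#' `"leak_point"` replaces one randomly chosen point with the ambient
#' concentration (a leaked vial); `"nonlinear"` bends the accumulation onto
#' a saturating curve `ambient + slope * tau * (1 - exp(-t/tau))` with the
#' same initial slope. Concentrations are floored at 0.001 ppb (a chamber
#' cannot be depleted below zero; extreme uptake saturates).
#'
#' @param true_flux Areal flux (g N or g C ha^-1 day^-1).
#' @param gas `"N2O"` or `"CH4"`.
#' @param ambient_ppb Ambient concentration.
#' @param gc_cv GC noise CV (fraction; 0 = noiseless).
#' @param times_min Sampling times (>= 3 points).
#' @param geometry A [chamber_geometry()].
#' @param air_temp_c,pressure_kpa Conditions (also used for inversion).
#' @param anomaly `"none"`, `"leak_point"` or `"nonlinear"`.
#' @param nonlinear_tau_min Saturation timescale of the nonlinear anomaly.
#' @param seed Optional seed for the noise draws.
#' @param ... Passed to [chamber_series()] (chamber_id, date).
#' @return A [chamber_series()].
#' @export
synthesize_chamber_series <- function(true_flux, gas = c("N2O", "CH4"),
                                      ambient_ppb, gc_cv = 0,
                                      times_min = c(0, 10, 20, 30),
                                      geometry = chamber_geometry(),
                                      air_temp_c = 27, pressure_kpa = 101.325,
                                      anomaly = c("none", "leak_point",
                                                  "nonlinear"),
                                      nonlinear_tau_min = 20, seed = NULL,
                                      ...) {
  gas <- match.arg(gas)
  anomaly <- match.arg(anomaly)
  if (length(times_min) < 3L)
    stop("need at least 3 sampling times")
  slope <- true_flux / convert_slope(1, geometry, air_temp_c, pressure_kpa,
                                     gas)
  run <- function() {
    ideal <- if (anomaly == "nonlinear")
      ambient_ppb + slope * nonlinear_tau_min *
        (1 - exp(-times_min / nonlinear_tau_min))
    else ambient_ppb + slope * times_min
    conc <- ideal * (1 + gc_cv * stats::rnorm(length(times_min)))
    if (anomaly == "leak_point")
      conc[sample.int(length(conc), 1L)] <- ambient_ppb
    pmax(conc, 0.001)
  }
  conc <- if (is.null(seed)) run() else with_seed(seed, run())
  chamber_series(times_min, conc, gas = gas, geometry = geometry,
                 air_temp_c = air_temp_c, pressure_kpa = pressure_kpa, ...)
}
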