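# Per-chamber flux estimation from timed headspace concentrations.

#' Chamber headspace series
#'
#' One static-chamber deployment: timed headspace concentrations of a single
#' gas plus the ambient conditions needed for unit conversion.
#'
#' @param times_min Sampling times since closure, minutes, strictly
#'   increasing, at least 3 points (typically 0, 10, 20, 30).
#' @param conc_ppb Headspace concentrations, ppb, positive; `NA` marks a lost
#'   sample.
#' @param gas `"N2O"` or `"CH4"`.
#' @param geometry A [chamber_geometry()].
#' @param air_temp_c,pressure_kpa Conditions at deployment (defaults 27 degC,
#'   101.325 kPa when unrecorded).
#' @param chamber_id,date Optional identifiers carried through to estimates.
#' @return An object of class `chamber_series`.
#' @export
chamber_series <- function(times_min, conc_ppb, gas = c("N2O", "CH4"),
                           geometry = chamber_geometry(),
                           air_temp_c = 27, pressure_kpa = 101.325,
                           chamber_id = NA_character_, date = NA) {
  gas <- match.arg(gas)
  stopifnot(is.numeric(times_min), is.numeric(conc_ppb))
  if (length(times_min) != length(conc_ppb))
    stop("times and concentrations must have equal length")
  if (length(times_min) < 3L)
    stop("a chamber series needs at least 3 sampling points")
  if (any(diff(times_min) <= 0))
    stop("sampling times must be strictly increasing")
  if (any(conc_ppb <= 0, na.rm = TRUE))
    stop("concentrations must be positive")
  structure(list(times_min = as.numeric(times_min),
                 conc_ppb = as.numeric(conc_ppb), gas = gas,
                 geometry = geometry, air_temp_c = air_temp_c,
                 pressure_kpa = pressure_kpa, chamber_id = chamber_id,
                 date = date),
            class = "chamber_series")
}

#' @export
print.chamber_series <- function(x, ...) {
  cat(sprintf("Chamber series (%s), %d points\n", x$gas, length(x$times_min)))
  print(data.frame(t_min = x$times_min, conc_ppb = x$conc_ppb))
  invisible(x)
}

# Closed-form simple OLS of y on x. R^2 of a zero-variance response is 0 by
# convention (flat series: slope 0, not 0/0).
ols_line <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  sxy <- sum((x - xb) * (y - yb))
  syy <- sum((y - yb)^2)
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  r2 <- if (syy > 0) (sxy * sxy) / (sxx * syy) else 0
  sse <- max(syy - slope * sxy, 0)
  slope_se <- if (n > 2) sqrt(sse / (n - 2) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, r2 = r2, slope_se = slope_se,
       sxx = sxx)
}

#' Quality-control policy for chamber fits
#'
#' The three-point fallback is triggered when the full four-point regression
#' is poor (`r2_min`) but dropping a single point rescues it (`loo_r2_min`),
#' which is the signature of one leaked sample or late-closure nonlinearity.
#'
#' @param r2_min Four-point R^2 below which the fallback is considered
#'   (default 0.90).
#' @param loo_r2_min Minimum best leave-one-out R^2 required to accept the
#'   three-point fit (default 0.95).
#' @return A list with the two thresholds.
#' @export
qc_policy <- function(r2_min = 0.90, loo_r2_min = 0.95) {
  stopifnot(r2_min >= 0, r2_min <= 1, loo_r2_min >= 0, loo_r2_min <= 1)
  list(r2_min = r2_min, loo_r2_min = loo_r2_min)
}

#' Estimate a chamber flux by linear regression
#'
#' Fits the change in headspace concentration against time by ordinary least
#' squares on all available points, applying the leave-one-out three-point
#' fallback of [qc_policy()] when the four-point fit is poor, and converts
#' the slope to an areal flux via [convert_slope()].
#'
#' @param series A [chamber_series()].
#' @param policy A [qc_policy()].
#' @return An object of class `flux_estimate`: slope (ppb min^-1) and its SE,
#'   R^2, number of points used, index of a dropped point (if any), areal
#'   flux (g N or g C ha^-1 day^-1), and a QC flag among `"ok"`,
#'   `"three_point"`, `"rejected"`.
#' @export
fit_flux <- function(series, policy = qc_policy()) {
  stopifnot(inherits(series, "chamber_series"))
  usable <- which(!is.na(series$conc_ppb))
  t <- series$times_min[usable]
  y <- series$conc_ppb[usable]
  n <- length(usable)

  est <- list(slope = NA_real_, slope_se = NA_real_, r2 = NA_real_,
              n_used = n, dropped = NA_integer_, flux = NA_real_,
              qc_flag = "rejected", gas = series$gas,
              chamber_id = series$chamber_id, date = series$date,
              below_detection = NA)
  if (n < 3L) {
    warning("fewer than 3 usable points: estimate rejected")
    class(est) <- "flux_estimate"
    return(est)
  }

  fit <- ols_line(t, y)
  qc <- if (n == 3L) "three_point" else "ok"
  dropped <- NA_integer_

  if (n == 4L && fit$r2 < policy$r2_min) {
    loo <- lapply(seq_len(4L), function(i) ols_line(t[-i], y[-i]))
    r2s <- vapply(loo, `[[`, numeric(1), "r2")
    best <- which.max(r2s)
    if (r2s[best] >= policy$loo_r2_min) {
      fit <- loo[[best]]
      qc <- "three_point"
      dropped <- usable[best]
      n <- 3L
    }
  }

  est$slope <- fit$slope
  est$slope_se <- fit$slope_se
  est$r2 <- fit$r2
  est$n_used <- n
  est$dropped <- dropped
  est$qc_flag <- qc
  est$flux <- convert_slope(fit$slope, series$geometry, series$air_temp_c,
                            series$pressure_kpa, series$gas)
  class(est) <- "flux_estimate"
  est
}

#' @export
print.flux_estimate <- function(x, ...) {
  unit <- if (identical(x$gas, "N2O")) "g N ha-1 day-1" else "g C ha-1 day-1"
  cat(sprintf("%s flux estimate: %.3f %s\n", x$gas, x$flux, unit))
  cat(sprintf("  slope %.4f +/- %.4f ppb min-1, R2 %.3f, n = %d, QC: %s\n",
              x$slope, ifelse(is.na(x$slope_se), NaN, x$slope_se), x$r2,
              x$n_used, x$qc_flag))
  if (!is.na(x$dropped)) cat(sprintf("  dropped point index %d\n", x$dropped))
  if (isTRUE(x$below_detection)) cat("  below detection limit (retained)\n")
  invisible(x)
}

#' @export
coef.flux_estimate <- function(object, ...) {
  c(slope = object$slope)
}

#' Estimate fluxes for a long-format table of chamber series
#'
#' Vectorised counterpart of [fit_flux()] for the CSV schema written by
#' [write_campaign_csv()] (one row per sampling point). The four-point OLS
#' is computed in closed form for every series at once; only series failing
#' the QC policy go through the leave-one-out search.
#'
#' @param series_df Data frame with columns `chamber_id`, `date`, `gas`,
#'   `t_min`, `conc_ppb`, and optionally `air_temp_C`, `pressure_kPa`,
#'   `headspace_m` (defaults 27, 101.325, 0.25).
#' @param policy A [qc_policy()].
#' @return Data frame with one row per (chamber_id, date, gas): slope,
#'   slope_se, r2, n_used, flux, qc_flag.
#' @export
fit_flux_table <- function(series_df, policy = qc_policy()) {
  need <- c("chamber_id", "date", "gas", "t_min", "conc_ppb")
  miss <- setdiff(need, names(series_df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(series_df$air_temp_C)) series_df$air_temp_C <- 27
  if (is.null(series_df$pressure_kPa)) series_df$pressure_kPa <- 101.325
  if (is.null(series_df$headspace_m)) series_df$headspace_m <- 0.25

  key <- interaction(series_df$chamber_id, series_df$date, series_df$gas,
                     drop = TRUE, lex.order = TRUE)
  out <- lapply(split(series_df, key), function(d) {
    d <- d[order(d$t_min), , drop = FALSE]
    s <- chamber_series(d$t_min, d$conc_ppb, gas = d$gas[1],
                        geometry = chamber_geometry(d$headspace_m[1]),
                        air_temp_c = d$air_temp_C[1],
                        pressure_kpa = d$pressure_kPa[1],
                        chamber_id = as.character(d$chamber_id[1]),
                        date = d$date[1])
    e <- suppressWarnings(fit_flux(s, policy))
    data.frame(chamber_id = e$chamber_id, date = d$date[1], gas = e$gas,
               slope = e$slope, slope_se = e$slope_se, r2 = e$r2,
               n_used = e$n_used, flux = e$flux, qc_flag = e$qc_flag,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
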