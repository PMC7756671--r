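# Aggregation: monthly stratum means, annual trapezoid budgets, area-weighted
# site-scale values, multi-year summaries, interval-overlap comparison.

#' Monthly stratum mean
#'
#' Arithmetic mean and standard error of replicate chamber fluxes within one
#' stratum-month. Missing replicates are dropped; `n` records the replicates
#' actually used.
#'
#' @param x Replicate fluxes (or covariate values); `NA` allowed.
#' @return List with `mean`, `se` (sample SD / sqrt(n); 0 when n = 1 is not
#'   assumed — `se` is `NA` for a single replicate), and `n`.
#' @export
monthly_mean <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) {
    warning("all replicates missing: no monthly record")
    return(list(mean = NA_real_, se = NA_real_, n = 0L))
  }
  list(mean = mean(x), se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
       n = n)
}

#' Monthly means for a flux table
#'
#' Applies [monthly_mean()] per group of a long flux table.
#'
#' @param df Data frame of per-chamber fluxes.
#' @param value Name of the value column (default `"flux"`).
#' @param by Grouping columns (default site, status, microtopography, date).
#' @return Data frame with the grouping columns plus `mean`, `se`, `n`.
#' @export
monthly_means <- function(df, value = "flux",
                          by = c("site", "status", "microtopography", "date")) {
  stopifnot(all(c(value, by) %in% names(df)))
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE, sep = "\r")
  v <- df[[value]]
  miss <- is.na(v)
  v0 <- ifelse(miss, 0, v)
  agg <- rowsum(cbind(n = as.numeric(!miss), s1 = v0, s2 = v0^2), key)
  n <- agg[, "n"]
  if (any(n == 0)) warning("all replicates missing in some stratum-months")
  m <- ifelse(n > 0, agg[, "s1"] / n, NA_real_)
  var_ <- ifelse(n > 1, pmax(agg[, "s2"] - n * m^2, 0) / (n - 1), NA_real_)
  out <- df[match(rownames(agg), as.character(key)), by, drop = FALSE]
  out$mean <- unname(m)
  out$se <- unname(ifelse(n > 1, sqrt(var_ / n), NA_real_))
  out$n <- unname(as.integer(n))
  rownames(out) <- NULL
  out
}

# Weights w such that sum(w * values) is the trapezoid integral of the
# piecewise-linear interpolant of (dates, values) over [start, end], with
# constant extrapolation beyond the first/last measurement. The integral is
# linear in the values, so the weights capture it exactly and also carry the
# Gaussian error propagation. Dates and window bounds in days (numeric).
.trapz_weights <- function(dates, start, end) {
  m <- length(dates)
  inner <- dates[dates > start & dates < end]
  knots <- sort(unique(c(start, inner, end)))
  dk <- diff(knots)
  # quadrature weight of each knot = half the span of its adjacent segments
  a <- (c(dk, 0) + c(0, dk)) / 2
  # each knot value is a convex combination of the two bracketing
  # measurements (fractional index from linear interpolation; rule 2 clamps
  # to the nearest measurement beyond the range)
  idx <- stats::approx(dates, seq_len(m), xout = knots, rule = 2)$y
  lo <- pmax(floor(idx), 1L)
  hi <- pmin(lo + 1L, m)
  frac <- idx - lo
  w <- numeric(m)
  for (j in seq_along(knots)) {
    w[lo[j]] <- w[lo[j]] + a[j] * (1 - frac[j])
    w[hi[j]] <- w[hi[j]] + a[j] * frac[j]
  }
  w
}

#' Annual cumulative flux by linear interpolation
#'
#' Integrates a monthly series of daily flux rates over a 12-month window by
#' linear interpolation between measurement dates (trapezoid rule), with
#' constant extrapolation from the first/last measurement to the window
#' edges. The result is in kg ha^-1 yr^-1 (g integrated over days, / 1000).
#' The SE propagates the per-date SEs through the (linear) trapezoid weights
#' assuming independence between dates.
#'
#' @param dates Measurement dates (`Date` or numeric days), strictly
#'   increasing.
#' @param flux Daily flux at each date, g ha^-1 day^-1.
#' @param se Optional SE of each flux (same units).
#' @param window_start Start of the budget year (`Date`), e.g. April 1.
#' @param window_end End (exclusive), default one calendar year after
#'   `window_start`; the window must span 365 or 366 days.
#' @return Object of class `annual_budget`: `cumulative` and `se` in
#'   kg ha^-1 yr^-1, window bounds, number of dates used, and the trapezoid
#'   `weights` (days) attached to each measurement date.
#' @export
annual_cumulative <- function(dates, flux, se = NULL, window_start,
                              window_end = NULL) {
  if (inherits(window_start, "Date") && is.null(window_end))
    window_end <- seq(window_start, by = "1 year", length.out = 2L)[2L]
  if (is.null(window_end)) stop("window_end required for numeric dates")
  d <- as.numeric(dates)
  s <- as.numeric(window_start)
  e <- as.numeric(window_end)
  if (!(e - s) %in% c(365, 366))
    stop("budget window must span 365 or 366 days, got ", e - s)
  if (is.unsorted(d, strictly = TRUE)) stop("dates must be strictly increasing")
  keep <- !is.na(flux)
  d <- d[keep]; f <- flux[keep]
  if (!is.null(se)) se <- se[keep]
  if (sum(d >= s & d <= e) < 2L)
    stop("need at least 2 measurement dates intersecting the window")

  w <- .trapz_weights(d, s, e)
  total_g <- sum(w * f)
  se_kg <- if (!is.null(se)) sqrt(sum(w^2 * se^2, na.rm = TRUE)) / 1000
           else NA_real_
  structure(list(cumulative = total_g / 1000, se = se_kg,
                 window_start = window_start, window_end = window_end,
                 n_dates = length(d), weights = w),
            class = "annual_budget")
}

#' @export
print.annual_budget <- function(x, ...) {
  cat(sprintf("Annual cumulative flux: %.2f%s kg ha-1 yr-1 (%d dates, window %s to %s)\n",
              x$cumulative,
              if (!is.na(x$se)) sprintf(" +/- %.2f", x$se) else "",
              x$n_dates, format(x$window_start), format(x$window_end)))
  invisible(x)
}

#' Area-weighted site-scale value
#'
#' Combines per-stratum values (e.g. annual budgets of live/cut palms on
#' hummocks/hollows) into a site-scale value using mapped area fractions:
#' weighted mean with Gaussian error propagation
#' \eqn{SE = \sqrt{\sum w_i^2 SE_i^2}} (independent strata).
#'
#' @param values Named numeric vector of stratum values.
#' @param weights Named numeric vector of area fractions (>= 0, summing to 1
#'   up to a printed-rounding tolerance of 0.015 — published inventory tables
#'   can sum to e.g. 1.01 as printed; the weights are used as given, not
#'   renormalized) covering every supplied stratum; names must match
#'   `values`.
#' @param ses Optional named SEs of the stratum values.
#' @return List with `mean` and `se` (`NA` when `ses` is absent).
#' @export
site_scale <- function(values, weights, ses = NULL) {
  if (!is.null(names(values)) && !is.null(names(weights))) {
    if (!all(names(values) %in% names(weights)))
      stop("weights missing for strata: ",
           paste(setdiff(names(values), names(weights)), collapse = ", "))
    weights <- weights[names(values)]
    if (!is.null(ses)) ses <- ses[names(values)]
  }
  if (length(values) != length(weights))
    stop("values and weights must align")
  if (any(weights < 0)) stop("area weights must be >= 0")
  if (abs(sum(weights) - 1) > 0.015)
    stop("area weights must sum to 1 (got ", sum(weights), ")")
  m <- sum(weights * values)
  s <- if (!is.null(ses)) sqrt(sum(weights^2 * ses^2)) else NA_real_
  list(mean = m, se = s)
}

#' Multi-year mean and standard error
#'
#' Mean of yearly cumulative values with SE = sample SD / sqrt(N) over the
#' years (N = number of monitored years, typically 3).
#'
#' @param yearly Numeric vector of annual values (>= 1; SE is `NA` for a
#'   single year).
#' @return List with `mean`, `se`, `n`.
#' @export
multi_year_summary <- function(yearly) {
  yearly <- yearly[!is.na(yearly)]
  n <- length(yearly)
  if (n == 0L) stop("no yearly values")
  list(mean = mean(yearly),
       se = if (n >= 2) stats::sd(yearly) / sqrt(n) else NA_real_,
       n = n)
}

#' Compare two mean +/- SE intervals
#'
#' Two values are declared different when their `mean +/- SE` intervals do
#' not overlap (closed intervals: touching endpoints overlap, hence
#' `not_different`).
#'
#' @param a_mean,a_se,b_mean,b_se Means and standard errors (SEs >= 0).
#' @return `"different"` or `"not_different"`.
#' @export
compare_intervals <- function(a_mean, a_se, b_mean, b_se) {
  stopifnot(a_se >= 0, b_se >= 0)
  disjoint <- (a_mean + a_se < b_mean - b_se) ||
              (b_mean + b_se < a_mean - a_se)
  if (disjoint) "different" else "not_different"
}

#' Round a report table the way the printed budget tables are
#'
#' Applies half-up rounding at 1 decimal place to every numeric column,
#' matching the convention of the published cumulative-flux tables.
#'
#' @param df Data frame.
#' @param digits Decimal places (default 1).
#' @return The data frame with numeric columns rounded.
#' @export
round_report <- function(df, digits = 1) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round_half_up, digits = digits)
  df
}
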