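# Hotspot detection from per-chamber flux histories (boxplot-outlier rule).

#' Detect hotspot chambers
#'
#' A chamber is a hotspot when its flux history contains at least
#' `min_extremes` values strictly above `Q3 + k_iqr * (Q3 - Q1)`, the
#' extreme-outlier fence of its own boxplot ("three times the interquartile
#' range above the upper edge of the central 50% box"). Quartiles use linear
#' interpolation between order statistics by default (`stats::quantile`
#' type 7).
#'
#' @param x Numeric flux history of one chamber (>= 4 values; with fewer the
#'   quartiles are not meaningful and the record is skipped with a warning).
#' @param k_iqr IQR multiplier for the fence. Default 3 (extreme outliers).
#' @param min_extremes Minimum number of exceedances. Default 3.
#' @param qtype Quantile type passed to [stats::quantile()]. Default 7.
#' @return List with `q1`, `q3`, `threshold`, `n_extreme`, `hotspot`.
#' @export
detect_hotspots <- function(x, k_iqr = 3, min_extremes = 3, qtype = 7) {
  x <- x[!is.na(x)]
  if (length(x) < 4L) {
    warning("fewer than 4 values: hotspot status undefined, record skipped")
    return(list(q1 = NA_real_, q3 = NA_real_, threshold = NA_real_,
                n_extreme = NA_integer_, hotspot = NA))
  }
  q <- stats::quantile(x, c(0.25, 0.75), type = qtype, names = FALSE)
  threshold <- q[2] + k_iqr * (q[2] - q[1])
  n_extreme <- sum(x > threshold)
  list(q1 = q[1], q3 = q[2], threshold = threshold,
       n_extreme = as.integer(n_extreme),
       hotspot = n_extreme >= min_extremes)
}

#' Hotspot report for a flux table
#'
#' Applies [detect_hotspots()] to each chamber's history in a long flux
#' table (per gas: the rule is evaluated per chamber and gas).
#'
#' @param df Data frame with columns `chamber_id`, `flux` and optionally
#'   `gas`.
#' @param ... Passed to [detect_hotspots()].
#' @return Data frame: chamber_id (gas), q1, q3, threshold, n_extreme,
#'   hotspot.
#' @export
hotspot_report <- function(df, ...) {
  stopifnot(all(c("chamber_id", "flux") %in% names(df)))
  by <- if ("gas" %in% names(df)) c("chamber_id", "gas") else "chamber_id"
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(d) {
    h <- suppressWarnings(detect_hotspots(d$flux, ...))
    cbind(d[1, by, drop = FALSE], as.data.frame(h))
  }))
  rownames(out) <- NULL
  out
}
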