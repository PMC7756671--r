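# Soil physical and nitrogen-cycling covariates.

#' Water-filled pore space
#'
#' Computes WFPS (% of pore volume occupied by water) from gravimetric
#' moisture and bulk density, following Linn and Doran:
#' \deqn{WFPS = 100 \times \frac{(m_G/100) \times BD}{1 - BD/PD}}
#' with a particle density of 1.4 g cm^-3 by default (tropical peat).
#' Gravimetric moisture is percent of dry mass and routinely exceeds 100%
#' in peat. Values above 100% WFPS indicate supersaturation (water table
#' above the surface) and are flagged, not truncated.
#'
#' @param m_g Gravimetric soil moisture, % of dry mass (>= 0; vectorised).
#' @param bd Bulk density, g cm^-3 (0 < bd < pd).
#' @param pd Particle density, g cm^-3. Default 1.4.
#' @return Numeric vector of WFPS in %, with attribute `supersaturated`
#'   (logical vector, TRUE where WFPS > 100).
#' @export
wfps <- function(m_g, bd, pd = 1.4) {
  stopifnot(is.numeric(m_g), is.numeric(bd), is.numeric(pd))
  if (any(m_g < 0)) stop("gravimetric moisture must be >= 0")
  if (any(bd <= 0)) stop("bulk density must be > 0")
  if (any(bd >= pd)) stop("bulk density must be below particle density (porosity <= 0)")
  porosity <- 1 - bd / pd
  out <- 100 * (m_g / 100 * bd) / porosity
  attr(out, "supersaturated") <- out > 100
  out
}

#' Net N mineralization and nitrification rates
#'
#' Rates from a fixed-duration aerobic incubation: net mineralization is the
#' change in total inorganic N (NH4+ + NO3-) and net nitrification the
#' change in NO3-, each divided by the incubation duration. Negative net
#' mineralization indicates immobilization.
#'
#' @param nh4_initial,no3_initial,nh4_final,no3_final Pools in
#'   mg N kg^-1 dry mass (>= 0; vectorised).
#' @param duration_days Incubation length, days (> 0). Default 10.
#' @return Data frame with columns `net_min` and `net_nit`, both in
#'   mg N kg^-1 d.m. day^-1.
#' @export
net_rates <- function(nh4_initial, no3_initial, nh4_final, no3_final,
                      duration_days = 10) {
  pools <- c(nh4_initial, no3_initial, nh4_final, no3_final)
  if (any(pools < 0, na.rm = TRUE)) stop("N pools must be >= 0")
  if (any(duration_days <= 0)) stop("incubation duration must be > 0")
  net_min <- ((nh4_final + no3_final) - (nh4_initial + no3_initial)) /
    duration_days
  net_nit <- (no3_final - no3_initial) / duration_days
  data.frame(net_min = net_min, net_nit = net_nit)
}
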