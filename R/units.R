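# Physical constants and unit helpers.

# Universal gas constant, J mol^-1 K^-1 (CODATA 2018 exact value).
GAS_CONSTANT <- 8.314462618

# Grams of reported element per mole of gas: N2O carries two N atoms and is
# reported on the N basis; CH4 carries one C and is reported on the C basis.
ELEMENT_MASS_PER_MOL <- c(N2O = 2 * 14.007, CH4 = 12.011)

# Molecular masses, used only when reporting on the molecule basis.
MOLECULE_MASS_PER_MOL <- c(N2O = 44.013, CH4 = 16.043)

#' Chamber geometry
#'
#' Static-chamber headspace geometry. The headspace height is the effective
#' volume-to-area ratio of the closed chamber and is recorded at each
#' deployment (insertion depth varies); the diameter is fixed by the chamber
#' design. Defaults describe a 25 cm tall, 30 cm diameter PVC chamber.
#'
#' @param height_m Headspace height in metres (> 0). Default 0.25.
#' @param diameter_m Chamber diameter in metres (> 0). Default 0.30.
#' @return An object of class `chamber_geometry`.
#' @export
chamber_geometry <- function(height_m = 0.25, diameter_m = 0.30) {
  stopifnot(is.numeric(height_m), length(height_m) == 1L, is.finite(height_m),
            is.numeric(diameter_m), length(diameter_m) == 1L,
            is.finite(diameter_m))
  if (height_m <= 0) stop("chamber headspace height must be > 0 m")
  if (diameter_m <= 0) stop("chamber diameter must be > 0 m")
  structure(list(height_m = height_m, diameter_m = diameter_m),
            class = "chamber_geometry")
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat(sprintf("Chamber geometry: headspace height %.3f m, diameter %.3f m\n",
              x$height_m, x$diameter_m))
  invisible(x)
}

#' Convert a concentration slope to an areal flux
#'
#' Converts the rate of change of headspace mixing ratio (ppb per minute)
#' into an areal mass flux using the ideal gas law:
#' \deqn{F = s \times 10^{-9} \times \frac{P}{RT} \times h \times M
#'       \times 1440 \times 10^{4}}
#' where \eqn{s} is the slope, \eqn{P} pressure (Pa), \eqn{T} temperature
#' (K), \eqn{h} the headspace height (m, the chamber volume-to-area ratio),
#' and \eqn{M} the mass of reported element per mole of gas (28.014 g N
#' mol^-1 for N2O, 12.011 g C mol^-1 for CH4). The factors 1440 and 1e4
#' rescale minutes to days and m^2 to hectares. The result is in
#' g N ha^-1 day^-1 for N2O and g C ha^-1 day^-1 for CH4.
#'
#' @param slope_ppb_per_min Concentration slope, ppb min^-1 (vectorised).
#' @param geometry A [chamber_geometry()].
#' @param air_temp_c Chamber air temperature, degrees C. Default 27 (regional
#'   mean; logged as imputed when unrecorded).
#' @param pressure_kpa Atmospheric pressure, kPa. Default 101.325.
#' @param gas `"N2O"` or `"CH4"`.
#' @param basis `"element"` (default; g N or g C) or `"molecule"`
#'   (g N2O or g CH4).
#' @return Areal flux in g element ha^-1 day^-1 (same length as the slope).
#' @export
convert_slope <- function(slope_ppb_per_min, geometry = chamber_geometry(),
                          air_temp_c = 27, pressure_kpa = 101.325,
                          gas = c("N2O", "CH4"), basis = c("element", "molecule")) {
  gas <- match.arg(gas)
  basis <- match.arg(basis)
  stopifnot(inherits(geometry, "chamber_geometry"))
  temp_k <- air_temp_c + 273.15
  if (any(temp_k <= 0)) stop("temperature must exceed 0 K")
  if (any(pressure_kpa <= 0)) stop("pressure must be > 0 kPa")
  mass <- switch(basis, element = ELEMENT_MASS_PER_MOL[[gas]],
                 molecule = MOLECULE_MASS_PER_MOL[[gas]])
  molar_density <- pressure_kpa * 1000 / (GAS_CONSTANT * temp_k)  # mol m^-3
  slope_ppb_per_min * 1e-9 * molar_density * geometry$height_m * mass *
    1440 * 1e4
}

#' Round half away from zero
#'
#' Rounds at `digits` decimals with halves away from zero, the convention of
#' the printed budget tables (base [round()] is round-half-even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
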