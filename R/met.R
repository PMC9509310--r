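# Thermodynamic and solar-geometry helpers shared by the radiation,
# resistance and solver modules. Units: temperature K, pressure and vapor
# pressure kPa, fluxes W m-2.

#' Physical constants used throughout the package
#'
#' @format A named list: `sigma` Stefan-Boltzmann constant (W m-2 K-4),
#'   `karman` von Karman constant, `gravity` (m s-2), `cp` specific heat of
#'   air at constant pressure (J kg-1 K-1), `Rd` gas constant of dry air
#'   (J kg-1 K-1), `solar_constant` (W m-2).
#' @export
seb_constants <- list(
  sigma          = 5.670374419e-8,
  karman         = 0.41,
  gravity        = 9.80665,
  cp             = 1013,
  Rd             = 287.04,
  solar_constant = 1367
)

#' Saturation vapor pressure and related psychrometric quantities
#'
#' Magnus-type saturation vapor pressure over water, its slope with
#' temperature, the psychrometric constant and the latent heat of
#' vaporization.
#'
#' @param T_A air temperature (K).
#' @param p air pressure (kPa).
#' @return `esat()`: saturation vapor pressure (kPa). `esat_slope()`: slope
#'   Delta (kPa K-1). `latent_heat()`: latent heat of vaporization
#'   (J kg-1). `psychrometric_gamma()`: psychrometric constant (kPa K-1).
#' @export
esat <- function(T_A) {
  tc <- T_A - 273.15
  0.61078 * exp(17.269 * tc / (tc + 237.3))
}

#' @rdname esat
#' @export
esat_slope <- function(T_A) {
  tc <- T_A - 273.15
  esat(T_A) * 17.269 * 237.3 / (tc + 237.3)^2
}

#' @rdname esat
#' @export
latent_heat <- function(T_A) {
  (2.501 - 0.002361 * (T_A - 273.15)) * 1e6
}

#' @rdname esat
#' @export
psychrometric_gamma <- function(T_A, p) {
  seb_constants$cp * p / (0.622 * latent_heat(T_A))
}

#' Volumetric heat capacity of moist air
#'
#' @param T_A air temperature (K).
#' @param p air pressure (kPa).
#' @param e_a actual vapor pressure (kPa).
#' @return rho * Cp (J m-3 K-1).
#' @export
rho_cp <- function(T_A, p, e_a) {
  # virtual temperature accounts for the density effect of water vapor
  T_v <- T_A / (1 - 0.378 * e_a / p)
  rho <- 1000 * p / (seb_constants$Rd * T_v)
  rho * seb_constants$cp
}

#' Solar position for a time series
#'
#' Solar declination, hour angle and zenith angle from day of year, local
#' solar hour and latitude. Clock time is treated as local solar time
#' (adequate for synthetic forcing; pass a longitude-corrected hour for
#' real towers if sub-degree precision matters).
#'
#' @param doy day of year (1-366).
#' @param hour local solar hour (0-24, decimal).
#' @param lat latitude (degrees, positive north).
#' @return list with `zenith` (rad), `cos_zenith`, `declination` (rad).
#' @export
solar_position <- function(doy, hour, lat) {
  decl <- 0.409 * sin(2 * pi * (doy - 81) / 365)
  phi <- lat * pi / 180
  ha <- (hour - 12) * pi / 12
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
  cosz <- pmin(pmax(cosz, -1), 1)
  list(zenith = acos(cosz), cos_zenith = cosz, declination = decl)
}
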