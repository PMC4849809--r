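#' Water conditions for oxygen solubility and unit conversion
#'
#' Bundles the temperature, salinity and barometric pressure needed to
#' evaluate oxygen solubility and to move between pressure-type and
#' concentration-type dissolved-oxygen units.
#'
#' @param temperature Water temperature in degrees Celsius (-2 to 40).
#' @param salinity Practical salinity (PSU, 0 to 100).
#' @param barometric_pressure Barometric pressure in mmHg (400 to 800);
#'   defaults to standard sea-level pressure, 760 mmHg.
#'
#' @return An object of class `water_conditions`.
#' @examples
#' water_conditions(15, 35)
#' @export
water_conditions <- function(temperature, salinity, barometric_pressure = 760) {
  stopifnot(is.numeric(temperature), is.numeric(salinity),
            is.numeric(barometric_pressure))
  if (any(temperature < -2 | temperature > 40))
    stop("temperature out of range [-2, 40] degC", call. = FALSE)
  if (any(salinity < 0 | salinity > 100))
    stop("salinity out of range [0, 100] PSU", call. = FALSE)
  if (any(barometric_pressure < 400 | barometric_pressure > 800))
    stop("barometric_pressure out of range [400, 800] mmHg", call. = FALSE)
  structure(list(temperature = temperature, salinity = salinity,
                 barometric_pressure = barometric_pressure),
            class = "water_conditions")
}

#' @export
print.water_conditions <- function(x, ...) {
  cat(sprintf("Water conditions: %.2f degC, %.2f PSU, %.1f mmHg\n",
              x$temperature, x$salinity, x$barometric_pressure))
  invisible(x)
}

as_water_conditions <- function(x) {
  if (inherits(x, "water_conditions")) return(x)
  if (is.list(x) && all(c("temperature", "salinity") %in% names(x)))
    return(water_conditions(x$temperature, x$salinity,
                            x$barometric_pressure %||% 760))
  stop("conditions must be a water_conditions object", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Saturation water vapour pressure
#'
#' Benson-Krause empirical fit for the vapour pressure of water as a
#' function of temperature; the small salinity effect (<0.1%) is ignored,
#' as is standard respirometry practice.
#'
#' @param temperature Degrees Celsius.
#' @return Vapour pressure in kPa.
#' @export
water_vapour_pressure <- function(temperature) {
  tk <- temperature + 273.15
  # ln p(atm) = 11.8571 - 3840.70/T - 216961/T^2
  exp(11.8571 - 3840.70 / tk - 216961 / tk^2) * 101.325
}

# Millero & Poisson (1980) one-atmosphere seawater density, kg/m^3
seawater_density <- function(temperature, salinity) {
  t <- temperature
  s <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 0.824493 - 4.0899e-3 * t + 7.6438e-5 * t^2 - 8.2467e-7 * t^3 +
    5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  rho_w + a * s + b * s^1.5 + 4.8314e-4 * s^2
}

# dry-air O2 mole fraction
.x_o2 <- 0.20946
# molar mass of O2, g/mol
.m_o2 <- 31.998

#' Partial pressure of oxygen in air-saturated water
#'
#' @param conditions A [water_conditions()] object.
#' @return PO2 of water-vapour-saturated air in kPa:
#'   `0.20946 * (barometric - vapour pressure)`.
#' @export
po2_air_saturation <- function(conditions) {
  conditions <- as_water_conditions(conditions)
  p_kpa <- conditions$barometric_pressure * 101.325 / 760
  .x_o2 * (p_kpa - water_vapour_pressure(conditions$temperature))
}

#' Oxygen solubility in water
#'
#' Air-saturated dissolved-oxygen concentration and the per-kPa solubility
#' coefficient, from the Garcia & Gordon (1992) fit to the Benson & Krause
#' data, evaluated in umol/kg and converted to per-litre units with the
#' Millero-Poisson surface seawater density.
#'
#' @param conditions A [water_conditions()] object.
#'
#' @return A list with components
#'   \describe{
#'     \item{c_sat}{air-saturated concentration, mg/L}
#'     \item{beta}{solubility coefficient, mg L^-1 kPa^-1 (`c_sat` divided
#'       by the air-saturation PO2)}
#'     \item{c_sat_umol_kg, beta_umol_kg}{the same quantities per kilogram
#'       of water, in umol/kg and umol kg^-1 kPa^-1}
#'     \item{po2_air_sat}{air-saturation PO2, kPa}
#'   }
#' @examples
#' o2_solubility(water_conditions(15, 0))$c_sat   # ~10.08 mg/L
#' @export
o2_solubility <- function(conditions) {
  conditions <- as_water_conditions(conditions)
  t <- conditions$temperature
  s <- conditions$salinity
  ts <- log((298.15 - t) / (273.15 + t))
  a <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  b <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  c0 <- -2.75915e-7
  ln_c <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 + s * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * s^2
  c_umol_kg_std <- exp(ln_c)   # at 1 atm moist-air total pressure
  # scale saturation to the actual barometric pressure via the dry-air part
  pw <- water_vapour_pressure(t)
  p_kpa <- conditions$barometric_pressure * 101.325 / 760
  c_umol_kg <- c_umol_kg_std * (p_kpa - pw) / (101.325 - pw)
  po2_sat <- .x_o2 * (p_kpa - pw)
  rho <- seawater_density(t, s) / 1000   # kg/L
  c_mg_l <- c_umol_kg * rho * .m_o2 / 1000
  list(c_sat = c_mg_l,
       beta = c_mg_l / po2_sat,
       c_sat_umol_kg = c_umol_kg,
       beta_umol_kg = c_umol_kg / po2_sat,
       po2_air_sat = po2_sat)
}

.o2_units <- c("kPa", "mmHg", "torr", "percent_air_saturation",
               "mg_per_L", "umol_per_L")

normalize_o2_unit <- function(unit) {
  u <- tolower(gsub("[ /%]+", "_", trimws(unit)))
  u <- sub("^_+", "", u)
  u <- c(kpa = "kPa", mmhg = "mmHg", torr = "torr",
         percent_air_saturation = "percent_air_saturation",
         air_sat = "percent_air_saturation",
         mg_per_l = "mg_per_L", mg_l = "mg_per_L",
         umol_per_l = "umol_per_L", umol_l = "umol_per_L", um = "umol_per_L")[u]
  if (is.na(u)) stop("unknown oxygen unit; use one of: ",
                     paste(.o2_units, collapse = ", "), call. = FALSE)
  unname(u)
}

#' Convert dissolved-oxygen values between units
#'
#' Converts among the oxygen units found in the hypoxia literature:
#' partial pressures (kPa, mmHg, torr), percent air saturation, and
#' concentrations (mg/L, umol/L). Pressure-family conversions use exact
#' factors (760 mmHg = 101.325 kPa; torr = mmHg); percent air saturation
#' and concentration conversions require the water conditions, via the
#' air-saturation PO2 and the solubility coefficient from
#' [o2_solubility()]. umol/L and mg/L interconvert through the O2 molar
#' mass, 31.998 g/mol.
#'
#' @param value Numeric vector of oxygen values (>= 0).
#' @param from,to Unit names from
#'   `c("kPa","mmHg","torr","percent_air_saturation","mg_per_L","umol_per_L")`.
#' @param conditions A [water_conditions()] object; required whenever the
#'   conversion crosses between the pressure family and percent saturation
#'   or concentration.
#'
#' @return Numeric vector in the target unit.
#' @examples
#' convert_o2(760, "mmHg", "kPa")                        # 101.325
#' convert_o2(6, "kPa", "umol_per_L", water_conditions(15, 35))
#' @export
convert_o2 <- function(value, from, to, conditions = NULL) {
  stopifnot(is.numeric(value))
  if (any(value < 0)) stop("oxygen values must be >= 0", call. = FALSE)
  from <- normalize_o2_unit(from)
  to <- normalize_o2_unit(to)
  if (from == to) return(value)

  pressure_family <- c("kPa", "mmHg", "torr")
  needs_conditions <- !(from %in% pressure_family && to %in% pressure_family) &&
    !(from %in% c("mg_per_L", "umol_per_L") && to %in% c("mg_per_L", "umol_per_L"))
  if (needs_conditions && is.null(conditions))
    stop("conversion between ", from, " and ", to,
         " requires water_conditions (temperature, salinity)", call. = FALSE)

  sol <- if (!is.null(conditions)) o2_solubility(conditions)

  to_kpa <- function(v, u) {
    switch(u,
      kPa = v,
      mmHg = v * 101.325 / 760,
      torr = v * 101.325 / 760,
      percent_air_saturation = v / 100 * sol$po2_air_sat,
      mg_per_L = v / sol$beta,
      umol_per_L = v * .m_o2 / 1000 / sol$beta)
  }
  from_kpa <- function(v, u) {
    switch(u,
      kPa = v,
      mmHg = v * 760 / 101.325,
      torr = v * 760 / 101.325,
      percent_air_saturation = v / sol$po2_air_sat * 100,
      mg_per_L = v * sol$beta,
      umol_per_L = v * sol$beta * 1000 / .m_o2)
  }
  # direct within-family shortcuts keep round trips exact
  if (from %in% c("mg_per_L", "umol_per_L") && to %in% c("mg_per_L", "umol_per_L")) {
    return(if (from == "mg_per_L") value * 1000 / .m_o2 else value * .m_o2 / 1000)
  }
  from_kpa(to_kpa(value, from), to)
}

.pressure_to_kpa <- c(uatm = 101.325e-6, atm = 101.325, mmHg = 101.325 / 760,
                      kPa = 1)

#' Convert between pressure units
#'
#' Exact chained conversion over uatm, atm, mmHg and kPa
#' (1 atm = 1e6 uatm = 760 mmHg = 101.325 kPa).
#'
#' @param value Numeric vector.
#' @param from,to One of `"uatm"`, `"atm"`, `"mmHg"`, `"kPa"`.
#' @return Numeric vector in the target unit.
#' @examples
#' pressure_unit(1500, "uatm", "mmHg")   # 1.14
#' @export
pressure_unit <- function(value, from, to) {
  norm <- function(u) {
    u <- c(uatm = "uatm", "µatm" = "uatm", atm = "atm", mmhg = "mmHg",
           torr = "mmHg", kpa = "kPa")[tolower(trimws(u))]
    if (is.na(u)) stop("unknown pressure unit", call. = FALSE)
    unname(u)
  }
  value * .pressure_to_kpa[[norm(from)]] / .pressure_to_kpa[[norm(to)]]
}
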