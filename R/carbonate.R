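#' Seawater carbonate-system equilibrium constants (NBS pH scale)
#'
#' Evaluates the constant set that the classic CO2SYS program pairs with
#' the NBS pH scale: K0 (CO2 solubility) from Weiss (1974); K1 and K2
#' from the original Mehrbach et al. (1973) fits, which are reported
#' directly on the NBS scale; KB from Dickson (1990, total scale) and KW
#' from Millero (1995, seawater scale), both converted to NBS through the
#' activity factor fH (Takahashi et al. 1982) and the sulfate/fluoride
#' association constants (Dickson 1990; Dickson & Riley 1979). Total
#' borate is 415.7 * S/35 umol/kg (Uppstrom 1974).
#'
#' All K are expressed so that they can be used with hydrogen-ion
#' "concentration" equal to `10^-pH(NBS)`: K units mol/kg (K0 in
#' mol kg^-1 atm^-1).
#'
#' @param temperature Degrees Celsius, 0-40.
#' @param salinity PSU, 19-43 (the validity range of the Mehrbach fits).
#' @return An object of class `carb_constants`: list with `K0`, `K1`,
#'   `K2`, `KB`, `KW`, `fH`, `TB` (total borate, mol/kg), `temperature`,
#'   `salinity`.
#' @examples
#' -log10(carb_constants(25, 35)$K1)   # pK1 ~ 6.00 (NBS)
#' @export
carb_constants <- function(temperature, salinity) {
  if (temperature < 0 || temperature > 40)
    stop("temperature outside 0-40 degC validity of the Mehrbach/Weiss ",
         "constant set", call. = FALSE)
  if (salinity < 19 || salinity > 43)
    stop("salinity outside 19-43 PSU validity of the Mehrbach constant set",
         call. = FALSE)
  tk <- temperature + 273.15
  s <- salinity

  # Weiss (1974) CO2 solubility, mol kg^-1 atm^-1
  k0 <- exp(-60.2409 + 93.4517 * (100 / tk) + 23.3585 * log(tk / 100) +
              s * (0.023517 - 0.023656 * (tk / 100) +
                     0.0047036 * (tk / 100)^2))

  # Mehrbach et al. (1973), NBS scale, mol/kg
  pk1 <- -13.7201 + 0.031334 * tk + 3235.76 / tk + 1.3e-5 * s * tk -
    0.1032 * sqrt(s)
  k1 <- 10^(-pk1)
  pk2 <- 5371.9645 + 1.671221 * tk + 0.22913 * s + 18.3802 * log10(s) -
    128375.28 / tk - 2194.3055 * log10(tk) - 8.0944e-4 * s * tk -
    5617.11 * log10(s) / tk + 2.136 * s / tk
  k2 <- 10^(-pk2)

  # NBS activity factor, Takahashi et al. (1982)
  fh <- 1.2948 - 0.002036 * tk + (0.0004607 - 0.000001475 * tk) * s^2

  # sulfate / fluoride chemistry for the total->seawater scale conversion
  ts <- (0.14 / 96.062) * (s / 1.80655)
  tf <- (0.000067 / 18.998) * (s / 1.80655)
  is <- 19.924 * s / (1000 - 1.005 * s)
  ks <- exp(-4276.1 / tk + 141.328 - 23.093 * log(tk) +
              (-13856 / tk + 324.57 - 47.986 * log(tk)) * sqrt(is) +
              (35474 / tk - 771.54 + 114.723 * log(tk)) * is -
              2698 / tk * is^1.5 + 1776 / tk * is^2 +
              log(1 - 0.001005 * s))
  kf <- exp(1590.2 / tk - 12.641 + 1.525 * sqrt(is) + log(1 - 0.001005 * s))
  sws_to_tot <- (1 + ts / ks) / (1 + ts / ks + tf / kf)

  # Dickson (1990) boric acid, total scale -> SWS -> NBS
  sq <- sqrt(s)
  kb_tot <- exp((-8966.9 - 2890.53 * sq - 77.942 * s + 1.728 * s^1.5 -
                   0.0996 * s^2) / tk +
                  148.0248 + 137.1942 * sq + 1.62142 * s +
                  (-24.4344 - 25.085 * sq - 0.2474 * s) * log(tk) +
                  0.053105 * sq * tk)
  kb <- kb_tot / sws_to_tot * fh

  # Millero (1995) water dissociation, SWS scale -> NBS
  kw <- exp(148.9802 - 13847.26 / tk - 23.6521 * log(tk) +
              (118.67 / tk - 5.977 + 1.0495 * log(tk)) * sqrt(s) -
              0.01615 * s) * fh

  if (k1 <= k2) stop("constant evaluation inconsistent: K1 <= K2",
                     call. = FALSE)
  structure(list(K0 = k0, K1 = k1, K2 = k2, KB = kb, KW = kw, fH = fh,
                 TB = 0.0004157 * s / 35,
                 temperature = temperature, salinity = salinity),
            class = "carb_constants")
}

carbonate_state <- function(k, h, dic_mol) {
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  co2 <- dic_mol * h^2 / denom
  hco3 <- dic_mol * k$K1 * h / denom
  co3 <- dic_mol * k$K1 * k$K2 / denom
  boh4 <- k$TB * k$KB / (k$KB + h)
  oh <- k$KW / h
  hfree <- h / k$fH
  ta <- hco3 + 2 * co3 + boh4 + oh - hfree
  structure(list(temperature = k$temperature, salinity = k$salinity,
                 pH = -log10(h),
                 pCO2 = co2 / k$K0 * 1e6,
                 DIC = dic_mol * 1e6, TA = ta * 1e6,
                 speciation = c(CO2 = co2, HCO3 = hco3, CO3 = co3,
                                BOH4 = boh4, OH = oh, H = hfree) * 1e6,
                 constants = k),
            class = "carbonate_state")
}

#' @export
print.carbonate_state <- function(x, ...) {
  cat(sprintf(paste0("Carbonate state (NBS): %.2f degC, %.1f PSU | pH %.4f, ",
                     "pCO2 %.1f uatm\n  DIC %.1f, TA %.1f umol/kg\n"),
              x$temperature, x$salinity, x$pH, x$pCO2, x$DIC, x$TA))
  invisible(x)
}

#' Carbonate state from pH and pCO2
#'
#' Full carbonate speciation of seawater in equilibrium with a given CO2
#' partial pressure at a given NBS pH: `CO2* = K0 * pCO2`,
#' `HCO3 = K1 CO2*/[H]`, `CO3 = K2 HCO3/[H]`, with borate, hydroxide and
#' (free) hydrogen terms from the constants; DIC and total alkalinity
#' (`TA = HCO3 + 2 CO3 + B(OH)4 + OH - H`) are assembled from the
#' species.
#'
#' @param ph NBS-scale pH, in (2, 12).
#' @param pco2 CO2 partial pressure, uatm (> 0).
#' @param temperature,salinity Passed to [carb_constants()].
#' @return A `carbonate_state` (concentrations in umol/kg).
#' @export
carb_state_from_ph_pco2 <- function(ph, pco2, temperature, salinity) {
  if (ph <= 2 || ph >= 12) stop("pH must be in (2, 12)", call. = FALSE)
  if (pco2 <= 0) stop("pCO2 must be > 0", call. = FALSE)
  k <- carb_constants(temperature, salinity)
  h <- 10^(-ph)
  co2 <- k$K0 * pco2 * 1e-6
  dic <- co2 * (1 + k$K1 / h + k$K1 * k$K2 / h^2)
  carbonate_state(k, h, dic)
}

#' Carbonate state (and pCO2) from total alkalinity and DIC
#'
#' Solves the total-alkalinity balance for pH by Brent root-finding over
#' pH in [2, 12] (residual tolerance |dTA| < 1e-4 umol/kg), then emits the
#' full speciation and `pCO2 = CO2*/K0`. This is the operation used to
#' propagate respiratory CO2 addition at constant TA.
#'
#' @param ta Total alkalinity, umol/kg (> 0).
#' @param dic Dissolved inorganic carbon, umol/kg (> 0).
#' @param temperature,salinity Passed to [carb_constants()].
#' @return A `carbonate_state`.
#' @export
carb_state_from_ta_dic <- function(ta, dic, temperature, salinity) {
  if (ta <= 0 || dic <= 0) stop("TA and DIC must be > 0", call. = FALSE)
  k <- carb_constants(temperature, salinity)
  dic_mol <- dic * 1e-6
  resid <- function(ph) {
    h <- 10^(-ph)
    denom <- h^2 + k$K1 * h + k$K1 * k$K2
    hco3 <- dic_mol * k$K1 * h / denom
    co3 <- dic_mol * k$K1 * k$K2 / denom
    (hco3 + 2 * co3 + k$TB * k$KB / (k$KB + h) + k$KW / h - h / k$fH) -
      ta * 1e-6
  }
  lo <- resid(2)
  hi <- resid(12)
  if (sign(lo) == sign(hi))
    stop(sprintf("no pH root in [2, 12]: TA residual %.3g at pH 2, %.3g at pH 12",
                 lo, hi), call. = FALSE)
  ph <- stats::uniroot(resid, c(2, 12), tol = 1e-12)$root
  st <- carbonate_state(k, 10^(-ph), dic_mol)
  if (abs(st$TA - ta) > 1e-4)
    stop("alkalinity solver did not meet tolerance", call. = FALSE)
  st
}

#' Closed-respirometer CO2 accumulation model
#'
#' Models the CO2 partial pressure reached inside a closed respirometer
#' after a fish has added respiratory CO2 to the water. For each
#' combination of starting pH and salinity, the initial state is taken in
#' equilibrium with the atmosphere (`atm_pco2`), the stated amount of CO2
#' is added to DIC while total alkalinity stays constant (CO2 is a neutral
#' gas), and the final pCO2 is recovered with
#' [carb_state_from_ta_dic()].
#'
#' @param start_ph Starting NBS pH grid (default 7.5-8.5 in 0.25 steps).
#' @param salinity Salinity grid, PSU (default 20-40 in steps of 5).
#' @param temperature Degrees Celsius (default 15).
#' @param atm_pco2 Atmospheric pCO2, uatm (default 395).
#' @param delta_dic Respiratory DIC addition, umol/kg (default 140,
#'   roughly the DIC excreted while O2 falls from air saturation to a
#'   typical Pcrit of ~6 kPa at a respiratory quotient of 0.85; see
#'   [delta_dic_from_o2()]).
#'
#' @return A data frame with one row per (start_ph, salinity) cell:
#'   `start_ph, salinity, ta, dic_initial, dic_final, final_pco2_uatm,
#'   final_pco2_mmHg, final_ph`, with the matrix of final pCO2 (rows =
#'   start_ph, cols = salinity) in attribute `"pco2_matrix"` and the full
#'   initial/final states in attribute `"states"`.
#' @examples
#' m <- respirometer_co2_model()
#' attr(m, "pco2_matrix")
#' @export
respirometer_co2_model <- function(start_ph = c(7.5, 7.75, 8.0, 8.25, 8.5),
                                   salinity = c(20, 25, 30, 35, 40),
                                   temperature = 15, atm_pco2 = 395,
                                   delta_dic = 140) {
  if (!length(start_ph) || !length(salinity))
    stop("start_ph and salinity grids must be non-empty", call. = FALSE)
  if (delta_dic < 0) stop("delta_dic must be >= 0", call. = FALSE)
  grid <- expand.grid(start_ph = start_ph, salinity = salinity,
                      KEEP.OUT.ATTRS = FALSE)
  states <- vector("list", nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ph <- grid$start_ph[i]
    s <- grid$salinity[i]
    init <- carb_state_from_ph_pco2(ph, atm_pco2, temperature, s)
    fin <- carb_state_from_ta_dic(init$TA, init$DIC + delta_dic,
                                  temperature, s)
    stopifnot(abs(fin$TA - init$TA) < 1e-4)   # TA conserved by construction
    states[[i]] <<- list(initial = init, final = fin)
    data.frame(start_ph = ph, salinity = s, ta = init$TA,
               dic_initial = init$DIC, dic_final = fin$DIC,
               final_pco2_uatm = fin$pCO2,
               final_pco2_mmHg = pressure_unit(fin$pCO2, "uatm", "mmHg"),
               final_ph = fin$pH)
  })
  out <- do.call(rbind, rows)
  m <- matrix(out$final_pco2_uatm, nrow = length(start_ph),
              dimnames = list(start_ph = start_ph, salinity = salinity))
  structure(out, pco2_matrix = m, states = states,
            scenario = list(temperature = temperature, atm_pco2 = atm_pco2,
                            delta_dic = delta_dic,
                            note = "delta_dic in umol/kg; uM treated as umol/kg"))
}

#' Respiratory DIC addition implied by an oxygen drawdown
#'
#' The increase in dissolved inorganic carbon produced while ambient O2
#' falls between two partial pressures, at a given respiratory quotient:
#' `delta_DIC = RQ * (C(po2_start) - C(po2_end))` with the dissolved O2
#' concentrations in umol/kg from [o2_solubility()].
#'
#' @param po2_start,po2_end Starting and ending PO2, kPa
#'   (`po2_start > po2_end >= 0`).
#' @param rq Respiratory quotient (mol CO2 per mol O2), default 0.85.
#' @param conditions A [water_conditions()] object.
#' @return DIC increase in umol/kg.
#' @examples
#' delta_dic_from_o2(20, 6, 0.85, water_conditions(15, 35))  # ~140 umol/kg
#' @export
delta_dic_from_o2 <- function(po2_start, po2_end, rq = 0.85, conditions) {
  if (po2_start < po2_end || po2_end < 0)
    stop("need po2_start >= po2_end >= 0", call. = FALSE)
  sol <- o2_solubility(conditions)
  rq * (po2_start - po2_end) * sol$beta_umol_kg
}
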