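#' Seawater conditions
#'
#' Validated container for the temperature/salinity/pressure triple at which
#' equilibrium constants are evaluated. Tide pools are sampled at the surface,
#' so pressure defaults to 0 dbar and no pressure corrections are applied.
#'
#' @param temperature Water temperature, degrees Celsius. Must lie in
#'   \[-2, 40\], the validity range of the constant formulations used here.
#' @param salinity Practical salinity (dimensionless). Must lie in \[0, 45\].
#' @param pressure Pressure, dbar (default 0; must be >= 0).
#' @return An object of class `sw_conditions`: a list with elements
#'   `temperature`, `salinity`, `pressure`. `temperature` and `salinity` may
#'   be vectors of equal length (or either scalar); they are recycled.
#' @examples
#' sw_conditions(15, 34)
#' @export
sw_conditions <- function(temperature, salinity, pressure = 0) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature < -2) || any(temperature > 40)) {
    stop("`temperature` must be finite and within [-2, 40] degC", call. = FALSE)
  }
  if (!is.numeric(salinity) || any(!is.finite(salinity)) ||
      any(salinity < 0) || any(salinity > 45)) {
    stop("`salinity` must be finite and within [0, 45]", call. = FALSE)
  }
  if (!is.numeric(pressure) || any(pressure < 0)) {
    stop("`pressure` must be >= 0 dbar", call. = FALSE)
  }
  n <- max(length(temperature), length(salinity))
  structure(list(temperature = rep_len(temperature, n),
                 salinity = rep_len(salinity, n),
                 pressure = rep_len(pressure, n)),
            class = "sw_conditions")
}

#' Dissolved inorganic nutrient concentrations
#'
#' @param NH4,NO3,PO4,Si Ammonium, nitrate, phosphate and silicate
#'   concentrations in umol/kg (all >= 0; silicate defaults to 0, it was not
#'   measured in typical tide-pool campaigns).
#' @return A `nutrient_conc` list with the four concentrations.
#' @export
nutrients <- function(NH4 = 0, NO3 = 0, PO4 = 0, Si = 0) {
  vals <- list(NH4 = NH4, NO3 = NO3, PO4 = PO4, Si = Si)
  for (nm in names(vals)) {
    if (any(!is.finite(vals[[nm]])) || any(vals[[nm]] < 0)) {
      stop(sprintf("nutrient `%s` must be finite and >= 0", nm), call. = FALSE)
    }
  }
  structure(vals, class = "nutrient_conc")
}

#' CO2 solubility in seawater (Weiss 1974)
#'
#' Solubility of CO2 (the Henry's-law coefficient K0) used both in the
#' speciation equations (pCO2 = \[CO2*\]/K0) and in the air-sea flux term.
#' Decreases monotonically with temperature at fixed salinity.
#'
#' @param cond A [sw_conditions()] object.
#' @return K0 in mol kg-1 atm-1 (vectorised over `cond`).
#' @export
co2_solubility <- function(cond) {
  stopifnot(inherits(cond, "sw_conditions"))
  TK <- cond$temperature + 273.15
  S <- cond$salinity
  exp(93.4517 * (100 / TK) - 60.2409 + 23.3585 * log(TK / 100) +
        S * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2))
}

#' Equilibrium constants of the seawater CO2 system (total pH scale)
#'
#' Evaluates the full acid-base constant set at the given temperature and
#' salinity, on the total hydrogen-ion scale. Formulations follow the
#' de-facto community defaults: K1/K2 from Lueker et al. (2000), KB from
#' Dickson (1990), KW and the phosphoric/silicic constants from Millero
#' (1995), ammonium from Yao & Millero (1995), bisulfate from Dickson
#' (1990), fluoride from Perez & Fraga (1987), and the aragonite solubility
#' product from Mucci (1983). Constants published on the seawater scale are
#' converted to the total scale internally. Total borate follows Uppstrom
#' (1974) and total calcium Riley & Tongudai (1967); both scale linearly
#' with salinity.
#'
#' @param cond A [sw_conditions()] object.
#' @return A `carb_constants` list with vector elements `K0`, `K1`, `K2`,
#'   `KB`, `KW`, `KP1`, `KP2`, `KP3`, `KSi`, `KNH4`, `KS`, `KF`,
#'   `Ksp_arag`, `BT`, `CaT`, `ST`, `FT` (mol/kg units; `KW` and `Ksp_arag`
#'   mol^2/kg^2), plus the conditions they were evaluated at.
#' @examples
#' k <- equilibrium_constants(sw_conditions(25, 35))
#' -log10(k$K1) # pK1, approx 5.847
#' @export
equilibrium_constants <- function(cond) {
  stopifnot(inherits(cond, "sw_conditions"))
  TK <- cond$temperature + 273.15
  S <- cond$salinity
  lnT <- log(TK)
  sqS <- sqrt(S)

  pK1 <- 3633.86 / TK - 61.2172 + 9.67770 * lnT - 0.011555 * S + 0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.9290 - 3.16967 * lnT - 0.01781 * S + 0.0001122 * S^2

  lnKB <- (-8966.90 - 2890.53 * sqS - 77.942 * S + 1.728 * S^1.5 - 0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqS + 1.62142 * S -
    (24.4344 + 25.085 * sqS + 0.2474 * S) * lnT + 0.053105 * sqS * TK

  Ion <- 19.924 * S / (1000 - 1.005 * S)
  lnKS <- -4276.1 / TK + 141.328 - 23.093 * lnT +
    (-13856 / TK + 324.57 - 47.986 * lnT) * sqrt(Ion) +
    (35474 / TK - 771.54 + 114.723 * lnT) * Ion -
    2698 / TK * Ion^1.5 + 1776 / TK * Ion^2 + log(1 - 0.001005 * S)
  KS <- exp(lnKS)

  ST <- 0.14 / 96.062 * S / 1.80655
  FT <- 0.000067 / 18.998 * S / 1.80655
  KF_total <- exp(874 / TK - 9.68 + 0.111 * sqS)
  KF <- KF_total / (1 + ST / KS)            # free scale
  # seawater-scale -> total-scale conversion factor for [H+]-proportional K's
  sws2tot <- (1 + ST / KS) / (1 + ST / KS + FT / KF)

  lnKW <- 148.9802 - 13847.26 / TK - 23.6521 * lnT +
    (118.67 / TK - 5.977 + 1.0495 * lnT) * sqS - 0.01615 * S

  lnKP1 <- -4576.752 / TK + 115.525 - 18.453 * lnT +
    (-106.736 / TK + 0.69171) * sqS + (-0.65643 / TK - 0.01844) * S
  lnKP2 <- -8814.715 / TK + 172.0883 - 27.927 * lnT +
    (-160.340 / TK + 1.3566) * sqS + (0.37335 / TK - 0.05778) * S
  lnKP3 <- -3070.75 / TK - 18.141 +
    (17.27039 / TK + 2.81197) * sqS + (-44.99486 / TK - 0.09984) * S

  lnKSi <- -8904.2 / TK + 117.385 - 19.334 * lnT +
    (-458.79 / TK + 3.5913) * sqrt(Ion) +
    (188.74 / TK - 1.5998) * Ion + (-12.1652 / TK + 0.07871) * Ion^2 +
    log(1 - 0.001005 * S)

  lnKNH4 <- -6285.33 / TK + 0.0001635 * TK - 0.25444 +
    (0.46532 - 123.7184 / TK) * sqS + (-0.01992 + 3.17556 / TK) * S

  logKsp <- -171.945 - 0.077993 * TK + 2903.293 / TK + 71.595 * log10(TK) +
    (-0.068393 + 0.0017276 * TK + 88.135 / TK) * sqS -
    0.10018 * S + 0.0059415 * S^1.5

  structure(list(
    K0 = co2_solubility(cond),
    K1 = 10^(-pK1), K2 = 10^(-pK2),
    KB = exp(lnKB),
    KW = exp(lnKW) * sws2tot,
    KP1 = exp(lnKP1) * sws2tot, KP2 = exp(lnKP2) * sws2tot,
    KP3 = exp(lnKP3) * sws2tot,
    KSi = exp(lnKSi) * sws2tot,
    KNH4 = exp(lnKNH4) * sws2tot,
    KS = KS, KF = KF,
    Ksp_arag = 10^logKsp,
    BT = 0.0004157 * S / 35,
    CaT = 0.02128 / 40.087 * S / 1.80655,
    ST = ST, FT = FT,
    conditions = cond
  ), class = "carb_constants")
}
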