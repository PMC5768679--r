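# Interval metabolism from discrete bottle samples: the alkalinity-anomaly
# NEC, the DIC-budget NCP, and the wind-driven air-sea CO2 flux.

#' Physical constants and conventions for the rate calculations
#'
#' @param rho Seawater density, kg/m3 (default 1023).
#' @param pco2_air Atmospheric pCO2, uatm (default 400).
#' @param salinity_ref Reference salinity for evaporation normalisation
#'   (default 36).
#' @param nutrient_signs Named vector giving the sign with which each
#'   nutrient enters the alkalinity correction (default NO3 +1, PO4 +1,
#'   NH4 -1): the correction removes the nutrient uptake/release alkalinity
#'   signal so the remaining delta-TA is attributable to CaCO3.
#' @return A `phys_config` list.
#' @export
phys_config <- function(rho = 1023, pco2_air = 400, salinity_ref = 36,
                        nutrient_signs = c(NO3 = 1, PO4 = 1, NH4 = -1)) {
  stopifnot(rho > 0, pco2_air > 0, salinity_ref > 0)
  structure(list(rho = rho, pco2_air = pco2_air, salinity_ref = salinity_ref,
                 nutrient_signs = nutrient_signs),
            class = "phys_config")
}

#' Normalise a concentration to a reference salinity
#'
#' Multiplies by `S_ref / S`, removing the concentration signal caused by
#' evaporation (or dilution). Applied to both TA and DIC series before
#' differencing.
#'
#' @param x Concentration (umol/kg or mmol/kg, any consistent unit).
#' @param S Observed practical salinity (> 0).
#' @param S_ref Reference salinity (default 36).
#' @return Normalised concentration, same unit as `x`.
#' @examples
#' normalize_to_reference_salinity(2300, 33, 36) # 2509.09...
#' @export
normalize_to_reference_salinity <- function(x, S, S_ref = 36) {
  if (any(S <= 0)) stop("`S` must be > 0", call. = FALSE)
  x * S_ref / S
}

#' Nutrient correction of total alkalinity
#'
#' Adds the small acid-base contributions of the measured dissolved
#' inorganic nitrogen and phosphorus back onto TA so that interval TA
#' changes reflect CaCO3 precipitation/dissolution only:
#' `TA* = TA + NO3 + PO4 - NH4` under the default sign convention
#' (configurable via [phys_config()]).
#'
#' @param TA Total alkalinity, umol/kg.
#' @param nutr A [nutrients()] object (umol/kg) or a list with NH4/NO3/PO4.
#' @param signs Named sign vector, see [phys_config()].
#' @return Corrected TA, umol/kg.
#' @examples
#' nutrient_corrected_ta(2300, nutrients(NH4 = 1, NO3 = 2, PO4 = 0.5)) # 2301.5
#' @export
nutrient_corrected_ta <- function(TA, nutr,
                                  signs = c(NO3 = 1, PO4 = 1, NH4 = -1)) {
  TA + signs[["NO3"]] * nutr$NO3 + signs[["PO4"]] * nutr$PO4 +
    signs[["NH4"]] * nutr$NH4
}

#' Schmidt number for CO2 in seawater
#'
#' Fourth-order polynomial in temperature (Wanninkhof 2014, salinity 35
#' seawater fit); decreases with temperature, about 668 at 20 degC.
#'
#' @param temperature Temperature, degC, within \[-2, 40\].
#' @return Dimensionless Schmidt number.
#' @export
schmidt_number <- function(temperature) {
  if (any(temperature < -2) || any(temperature > 40)) {
    stop("`temperature` outside the polynomial validity range [-2, 40] degC",
         call. = FALSE)
  }
  t <- temperature
  2116.8 - 136.25 * t + 4.7353 * t^2 - 0.092307 * t^3 + 0.0007555 * t^4
}

#' Gas transfer (piston) velocity for CO2
#'
#' Quadratic wind-speed parameterisation of Ho et al. (2006),
#' k600 = 0.266 u10^2 (cm/h), rescaled to the in-situ Schmidt number with
#' the customary square-root exponent: k = k600 (Sc/600)^(-1/2), returned
#' in m/h.
#'
#' @param u10 Wind speed at 10 m, m/s (>= 0).
#' @param temperature Water temperature, degC (sets the Schmidt number).
#' @return Transfer velocity, m/h.
#' @examples
#' gas_transfer_velocity(5, 20) # about 0.0665 * (668/600)^-0.5
#' @export
gas_transfer_velocity <- function(u10, temperature) {
  if (any(u10 < 0)) stop("`u10` must be >= 0", call. = FALSE)
  k600_cm_h <- 0.266 * u10^2
  sc <- schmidt_number(temperature)
  k600_cm_h * (sc / 600)^(-0.5) / 100
}

#' Air-sea CO2 flux
#'
#' `FCO2 = k * K0 * rho * (pCO2_water - pCO2_air) * 1e-3` in mmol/m2/h;
#' positive values are an efflux from the water to the atmosphere.
#'
#' @param k Gas transfer velocity, m/h (>= 0).
#' @param K0 CO2 solubility, mol/kg/atm (see [co2_solubility()]).
#' @param pco2_water Seawater pCO2, uatm.
#' @param pco2_air Atmospheric pCO2, uatm (default 400).
#' @param rho Seawater density, kg/m3.
#' @return Flux in mmol/m2/h.
#' @export
co2_flux <- function(k, K0, pco2_water, pco2_air = 400, rho = 1023) {
  if (any(k < 0)) stop("`k` must be >= 0", call. = FALSE)
  k * K0 * rho * (pco2_water - pco2_air) * 1e-3
}

#' Net ecosystem calcification from the alkalinity anomaly
#'
#' `NEC = dTA * rho * V / (2 SA t)` with one mole of CaCO3 per two moles of
#' TA. `dTA` is the salinity-normalised, nutrient-corrected TA change
#' taken as start minus end, so TA drawdown (calcification) gives positive
#' NEC and TA gain (dissolution) negative NEC.
#'
#' @param dTA TA difference start minus end, mmol/kg.
#' @param rho Seawater density, kg/m3.
#' @param V Pool water volume, m3 (> 0).
#' @param SA Pool bottom surface area, m2 (> 0).
#' @param t Interval length, h (> 0).
#' @return NEC in mmol CaCO3 / m2 / h.
#' @examples
#' net_ecosystem_calcification(0.010, 1023, 0.1, 0.5, 1) # 1.023
#' @export
net_ecosystem_calcification <- function(dTA, rho, V, SA, t) {
  if (any(V <= 0) || any(SA <= 0) || any(t <= 0)) {
    stop("`V`, `SA` and `t` must all be > 0", call. = FALSE)
  }
  dTA * rho * V / (2 * SA * t)
}

#' Net community production from the DIC budget
#'
#' `NCP = dDIC * rho * V / (SA t) - NEC - FCO2`, with `dDIC` the
#' salinity-normalised DIC change start minus end (mmol/kg): DIC drawdown
#' not explained by calcification or outgassing is net photosynthesis
#' (positive), DIC gain is net respiration (negative).
#'
#' @param dDIC DIC difference start minus end, mmol/kg.
#' @param NEC Net ecosystem calcification, mmol/m2/h.
#' @param FCO2 Air-sea CO2 flux, mmol/m2/h (positive = efflux).
#' @inheritParams net_ecosystem_calcification
#' @return NCP in mmol C / m2 / h.
#' @export
net_community_production <- function(dDIC, NEC, FCO2, rho, V, SA, t) {
  if (any(V <= 0) || any(SA <= 0) || any(t <= 0)) {
    stop("`V`, `SA` and `t` must all be > 0", call. = FALSE)
  }
  dDIC * rho * V / (SA * t) - NEC - FCO2
}

#' Interval metabolic rates from a pool's water-sample series
#'
#' For each consecutive pair of samples: solves the carbonate state at
#' in-situ conditions from (pH, TA), normalises TA and DIC to the reference
#' salinity, applies the nutrient correction to TA, computes the air-sea
#' flux from the interval-mean pCO2 / solubility / transfer velocity, and
#' evaluates NEC then NCP.
#'
#' @param samples Data frame for one pool and sampling event, with columns
#'   `time_h`, `pH_total`, `TA_umol_kg`, `temp_C`, `sal_psu`, `NH4`, `NO3`,
#'   `PO4`, `wind_m_s` (nutrients umol/kg). Times must be strictly
#'   increasing; at least 2 rows.
#' @param geometry List or one-row data frame with `volume_m3` and
#'   `surface_area_m2`.
#' @param config A [phys_config()] object.
#' @param gas_exchange If `FALSE`, FCO2 is forced to zero (useful for
#'   closed-budget checks).
#' @return A `metabolic_intervals` data frame with one row per interval:
#'   `t_start`, `t_end`, `delta_t`, `NEC`, `NCP`, `FCO2` (mmol/m2/h),
#'   `mean_pH`, `mean_omega`, plus the normalised endpoint `TA_norm`,
#'   `DIC_norm` used (umol/kg, start values).
#' @export
rate_series <- function(samples, geometry, config = phys_config(),
                        gas_exchange = TRUE) {
  req <- c("time_h", "pH_total", "TA_umol_kg", "temp_C", "sal_psu",
           "NH4", "NO3", "PO4", "wind_m_s")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("`samples` missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(samples) < 2) {
    stop("need at least 2 samples to form an interval", call. = FALSE)
  }
  if (any(diff(samples$time_h) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  V <- if (is.list(geometry)) geometry$volume_m3 else geometry["volume_m3"]
  SA <- if (is.list(geometry)) geometry$surface_area_m2 else geometry["surface_area_m2"]

  cond <- sw_conditions(samples$temp_C, samples$sal_psu)
  nutr <- nutrients(NH4 = samples$NH4, NO3 = samples$NO3, PO4 = samples$PO4)
  st <- tryCatch(
    carb_from_ph_ta(samples$pH_total, samples$TA_umol_kg, cond, nutr),
    error = function(e) stop("carbonate solver failed on sample series: ",
                             conditionMessage(e), call. = FALSE))

  TA_corr <- nutrient_corrected_ta(samples$TA_umol_kg, nutr,
                                   config$nutrient_signs)
  TA_n <- normalize_to_reference_salinity(TA_corr, samples$sal_psu,
                                          config$salinity_ref)
  DIC_n <- normalize_to_reference_salinity(st$DIC, samples$sal_psu,
                                           config$salinity_ref)

  i <- seq_len(nrow(samples) - 1)
  dt <- samples$time_h[i + 1] - samples$time_h[i]
  dTA <- (TA_n[i] - TA_n[i + 1]) / 1000   # umol/kg -> mmol/kg
  dDIC <- (DIC_n[i] - DIC_n[i + 1]) / 1000

  NEC <- net_ecosystem_calcification(dTA, config$rho, V, SA, dt)

  if (gas_exchange) {
    u_mid <- (samples$wind_m_s[i] + samples$wind_m_s[i + 1]) / 2
    t_mid <- (samples$temp_C[i] + samples$temp_C[i + 1]) / 2
    k <- gas_transfer_velocity(u_mid, t_mid)
    K0 <- co2_solubility(cond)
    K0_mid <- (K0[i] + K0[i + 1]) / 2
    pco2_mid <- (st$pCO2[i] + st$pCO2[i + 1]) / 2
    FCO2 <- co2_flux(k, K0_mid, pco2_mid, config$pco2_air, config$rho)
  } else {
    FCO2 <- rep(0, length(i))
  }
  NCP <- net_community_production(dDIC, NEC, FCO2, config$rho, V, SA, dt)

  structure(data.frame(
    t_start = samples$time_h[i], t_end = samples$time_h[i + 1], delta_t = dt,
    NEC = NEC, NCP = NCP, FCO2 = FCO2,
    mean_pH = (st$pH[i] + st$pH[i + 1]) / 2,
    mean_omega = (st$omega_arag[i] + st$omega_arag[i + 1]) / 2,
    TA_norm = TA_n[i], DIC_norm = DIC_n[i]
  ), class = c("metabolic_intervals", "data.frame"))
}
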