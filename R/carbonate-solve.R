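# Speciation solvers for the seawater CO2 system, total pH scale.
# Concentrations are umol/kg at the user interface and mol/kg internally.

# Non-carbonate contributions to total alkalinity (mol/kg) at [H+] = H
# (total scale): borate, water, free-H, fluoride, phosphate, silicate,
# ammonium. NH4/NO3/PO4/Si are in mol/kg here.
noncarb_alkalinity <- function(H, k, NH4, NO3, PO4, Si) {
  BOH4 <- k$BT * k$KB / (k$KB + H)
  OH <- k$KW / H
  Hfree <- H / (1 + k$ST / k$KS)
  HF <- k$FT / (1 + k$KF / Hfree)
  dp <- H^3 + k$KP1 * H^2 + k$KP1 * k$KP2 * H + k$KP1 * k$KP2 * k$KP3
  phos <- PO4 * (k$KP1 * k$KP2 * H + 2 * k$KP1 * k$KP2 * k$KP3 - H^3) / dp
  SiOOH3 <- Si * k$KSi / (k$KSi + H)
  NH3 <- NH4 * k$KNH4 / (k$KNH4 + H)
  BOH4 + OH - H - HF + phos + SiOOH3 + NH3
}

# Fast scalar pH solve for (TA, DIC) with scalar constants `kk` and
# nutrient concentrations in mol/kg: damped Newton (numerical derivative)
# from a warm start, falling back to bracketed uniroot on [3, 12]. Used in
# the simulator's inner loop where thousands of sequential solves occur.
solve_ph_core <- function(TA_mol, DIC_mol, kk, NH4, NO3, PO4, Si, guess = 8) {
  f <- function(p) {
    H <- 10^(-p)
    CA <- DIC_mol * (kk$K1 * H + 2 * kk$K1 * kk$K2) /
      (H^2 + kk$K1 * H + kk$K1 * kk$K2)
    CA + noncarb_alkalinity(H, kk, NH4, NO3, PO4, Si) - TA_mol
  }
  p <- guess
  for (it in 1:30) {
    fp <- f(p)
    if (abs(fp) < 1e-12) return(p)
    h <- 1e-6
    d <- (f(p + h) - fp) / h
    step <- fp / d
    if (!is.finite(step) || abs(step) > 1) break
    p <- p - step
    if (p < 3 || p > 12) break
  }
  flo <- f(3); fhi <- f(12)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop(sprintf("no pH in [3, 12] satisfies the alkalinity balance (TA=%.1f, DIC=%.1f)",
                 TA_mol * 1e6, DIC_mol * 1e6), call. = FALSE)
  }
  stats::uniroot(f, lower = 3, upper = 12, f.lower = flo, f.upper = fhi,
                 tol = 1e-12)$root
}

carb_state <- function(pH, TA, DIC, CO2star, HCO3, CO3, pCO2, omega_arag, cond) {
  structure(data.frame(pH = pH, TA = TA, DIC = DIC, CO2star = CO2star,
                       HCO3 = HCO3, CO3 = CO3, pCO2 = pCO2,
                       omega_arag = omega_arag,
                       temperature = cond$temperature,
                       salinity = cond$salinity),
            class = c("carb_state", "data.frame"))
}

resolve_constants <- function(cond, constants) {
  if (is.null(constants)) equilibrium_constants(cond) else constants
}

#' Carbonate speciation from pH and total alkalinity
#'
#' Closed-form solution of the CO2 system given a (pH, TA) pair: the
#' non-carbonate alkalinity (borate, water, fluoride, phosphate, silicate,
#' ammonium terms) is subtracted from TA at the known \[H+\], and the linear
#' relation between carbonate alkalinity and DIC is inverted. No iteration
#' is involved, so this is the fast path used sample-by-sample on bottle
#' data measured as pH plus titrated TA.
#'
#' @param pH pH on the total scale, in \[6, 10\].
#' @param TA Total alkalinity, umol/kg, in (0, 5000\].
#' @param cond A [sw_conditions()] object (recycled against `pH`/`TA`).
#' @param nutr A [nutrients()] object (umol/kg), default all zero.
#' @param constants Optional precomputed [equilibrium_constants()] for
#'   `cond`; computed on the fly when `NULL`.
#' @return A `carb_state` data frame with columns `pH`, `TA`, `DIC`,
#'   `CO2star`, `HCO3`, `CO3` (umol/kg), `pCO2` (uatm), `omega_arag`,
#'   `temperature`, `salinity`.
#' @examples
#' carb_from_ph_ta(8.1, 2300, sw_conditions(25, 35))
#' @export
carb_from_ph_ta <- function(pH, TA, cond, nutr = nutrients(), constants = NULL) {
  stopifnot(inherits(cond, "sw_conditions"))
  if (any(pH < 6) || any(pH > 10)) {
    stop("`pH` outside [6, 10]", call. = FALSE)
  }
  if (any(TA <= 0) || any(TA > 5000)) {
    stop("`TA` outside (0, 5000] umol/kg", call. = FALSE)
  }
  n <- max(length(pH), length(TA), length(cond$temperature))
  pH <- rep_len(pH, n); TA <- rep_len(TA, n)
  cond <- sw_conditions(rep_len(cond$temperature, n), rep_len(cond$salinity, n))
  k <- resolve_constants(cond, constants)

  H <- 10^(-pH)
  NC <- noncarb_alkalinity(H, k, rep_len(nutr$NH4, n) * 1e-6,
                           rep_len(nutr$NO3, n) * 1e-6,
                           rep_len(nutr$PO4, n) * 1e-6,
                           rep_len(nutr$Si, n) * 1e-6)
  CA <- TA * 1e-6 - NC
  if (any(CA <= 0)) {
    stop("computed carbonate alkalinity <= 0: inconsistent pH/TA pair",
         call. = FALSE)
  }
  den <- H^2 + k$K1 * H + k$K1 * k$K2
  DIC <- CA * den / (k$K1 * H + 2 * k$K1 * k$K2)
  CO2star <- DIC * H^2 / den
  HCO3 <- DIC * k$K1 * H / den
  CO3 <- DIC * k$K1 * k$K2 / den
  carb_state(pH, TA, DIC * 1e6, CO2star * 1e6, HCO3 * 1e6, CO3 * 1e6,
             pCO2 = CO2star / k$K0 * 1e6,
             omega_arag = k$CaT * CO3 / k$Ksp_arag, cond)
}

#' Carbonate speciation from total alkalinity and DIC
#'
#' Solves for the pH (total scale) at which the full total-alkalinity
#' expression evaluated at the given DIC equals TA, by a bracketed
#' root search on pH in \[3, 12\] (Brent's bisection/secant hybrid, as in
#' [stats::uniroot()]), then populates the speciation. TA and DIC are
#' conservative under temperature change, so this is the path used to move
#' a measured state to in-situ conditions and the forward model of the
#' simulator.
#'
#' @inheritParams carb_from_ph_ta
#' @param TA Total alkalinity, umol/kg (> 0).
#' @param DIC Dissolved inorganic carbon, umol/kg (> 0).
#' @param ph_guess Optional previous pH used to warm-start the bracket.
#' @return A `carb_state` data frame (see [carb_from_ph_ta()]). The root is
#'   polished until the TA residual is below 1e-4 umol/kg.
#' @examples
#' carb_from_ta_dic(2300, 2000, sw_conditions(25, 35))
#' @export
carb_from_ta_dic <- function(TA, DIC, cond, nutr = nutrients(),
                             constants = NULL, ph_guess = NULL) {
  stopifnot(inherits(cond, "sw_conditions"))
  if (any(TA <= 0) || any(DIC <= 0)) {
    stop("`TA` and `DIC` must be > 0", call. = FALSE)
  }
  n <- max(length(TA), length(DIC), length(cond$temperature))
  TA <- rep_len(TA, n); DIC <- rep_len(DIC, n)
  cond <- sw_conditions(rep_len(cond$temperature, n), rep_len(cond$salinity, n))
  k <- resolve_constants(cond, constants)
  NH4 <- rep_len(nutr$NH4, n) * 1e-6; NO3 <- rep_len(nutr$NO3, n) * 1e-6
  PO4 <- rep_len(nutr$PO4, n) * 1e-6; Si <- rep_len(nutr$Si, n) * 1e-6

  ki <- function(i) lapply(k[c("K1", "K2", "KB", "KW", "KP1", "KP2", "KP3",
                               "KSi", "KNH4", "KS", "KF", "BT", "ST", "FT")],
                           function(v) v[min(i, length(v))])
  pH <- numeric(n)
  for (i in seq_len(n)) {
    kk <- ki(i)
    f <- function(p) {
      H <- 10^(-p)
      CA <- DIC[i] * 1e-6 * (kk$K1 * H + 2 * kk$K1 * kk$K2) /
        (H^2 + kk$K1 * H + kk$K1 * kk$K2)
      CA + noncarb_alkalinity(H, kk, NH4[i], NO3[i], PO4[i], Si[i]) - TA[i] * 1e-6
    }
    lo <- 3; hi <- 12
    if (!is.null(ph_guess)) {
      g <- rep_len(ph_guess, n)[i]
      glo <- max(3, g - 0.5); ghi <- min(12, g + 0.5)
      if (f(glo) * f(ghi) < 0) { lo <- glo; hi <- ghi }
    }
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
      stop(sprintf("no pH in [3, 12] satisfies the alkalinity balance (TA=%.1f, DIC=%.1f)",
                   TA[i], DIC[i]), call. = FALSE)
    }
    r <- stats::uniroot(f, lower = lo, upper = hi, f.lower = flo,
                        f.upper = fhi, tol = 1e-12)
    pH[i] <- r$root
  }
  st <- carb_from_ph_ta(pH, TA, cond, nutr, constants = k)
  # report the target TA/DIC pair (closure checked by the root residual)
  st$DIC <- DIC
  st
}

#' Aragonite saturation state
#'
#' Omega = \[Ca2+\]\[CO3^2-\] / Ksp(aragonite), with total calcium scaled
#' linearly with salinity and the stoichiometric solubility product of
#' Mucci (1983).
#'
#' @param CO3 Carbonate-ion concentration, umol/kg.
#' @param cond A [sw_conditions()] object.
#' @param constants Optional precomputed constants.
#' @return Dimensionless saturation state (>= 0); values below 1 favour
#'   dissolution.
#' @export
omega_aragonite <- function(CO3, cond, constants = NULL) {
  stopifnot(inherits(cond, "sw_conditions"))
  if (any(CO3 < 0)) stop("`CO3` must be >= 0", call. = FALSE)
  k <- resolve_constants(cond, constants)
  k$CaT * (CO3 * 1e-6) / k$Ksp_arag
}

#' Convert a laboratory pH/TA measurement to in-situ conditions
#'
#' pH is measured on a bottle sample at laboratory temperature; TA and DIC
#' are conservative with respect to temperature, so the in-situ state is
#' obtained by solving DIC at laboratory conditions from (pH_lab, TA) and
#' re-solving pH and the full speciation at in-situ temperature (and
#' salinity) from (TA, DIC).
#'
#' @param pH_lab pH (total scale) measured at `T_lab`.
#' @param T_lab Laboratory temperature, degC.
#' @param TA Total alkalinity, umol/kg.
#' @param cond_insitu In-situ [sw_conditions()].
#' @param nutr A [nutrients()] object, umol/kg.
#' @return A `carb_state` data frame at in-situ conditions.
#' @examples
#' adjust_to_insitu(8.0, 20, 2250, sw_conditions(14, 34))
#' @export
adjust_to_insitu <- function(pH_lab, T_lab, TA, cond_insitu, nutr = nutrients()) {
  stopifnot(inherits(cond_insitu, "sw_conditions"))
  cond_lab <- sw_conditions(T_lab, cond_insitu$salinity)
  lab <- carb_from_ph_ta(pH_lab, TA, cond_lab, nutr)
  carb_from_ta_dic(TA, lab$DIC, cond_insitu, nutr, ph_guess = pH_lab)
}
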