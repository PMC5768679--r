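# Independent brute-force oracle for the CO2 system: the total-alkalinity
# expression is written out as an explicit species sum and inverted by
# plain bisection (on DIC given pH, or on a dense pH bracket given DIC).
# This deliberately avoids the package's closed-form/Newton solution paths;
# only the equilibrium-constant values themselves are shared (they are
# checked separately against frozen external references).

oracle_ta <- function(pH, DIC_mol, k, NH4 = 0, NO3 = 0, PO4 = 0, Si = 0) {
  H <- 10^(-pH)
  den <- H^2 + k$K1 * H + k$K1 * k$K2
  HCO3 <- DIC_mol * k$K1 * H / den
  CO3 <- DIC_mol * k$K1 * k$K2 / den
  BOH4 <- k$BT * k$KB / (k$KB + H)
  OH <- k$KW / H
  Hfree <- H / (1 + k$ST / k$KS)
  HF <- k$FT / (1 + k$KF / Hfree)
  dp <- H^3 + k$KP1 * H^2 + k$KP1 * k$KP2 * H + k$KP1 * k$KP2 * k$KP3
  H3PO4 <- PO4 * H^3 / dp
  HPO4 <- PO4 * k$KP1 * k$KP2 * H / dp
  PO4i <- PO4 * k$KP1 * k$KP2 * k$KP3 / dp
  SiOOH3 <- Si * k$KSi / (k$KSi + H)
  NH3 <- NH4 * k$KNH4 / (k$KNH4 + H)
  HCO3 + 2 * CO3 + BOH4 + OH - H - HF + HPO4 + 2 * PO4i - H3PO4 + SiOOH3 + NH3
}

# DIC (umol/kg) from (pH, TA) by bisection on DIC
oracle_dic <- function(pH, TA_umol, cond, NH4 = 0, NO3 = 0, PO4 = 0, Si = 0) {
  k <- equilibrium_constants(cond)
  TA <- TA_umol * 1e-6
  lo <- 1e-9; hi <- 0.02
  for (i in 1:64) {
    mid <- (lo + hi) / 2
    if (oracle_ta(pH, mid, k, NH4 * 1e-6, NO3 * 1e-6, PO4 * 1e-6, Si * 1e-6) < TA) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2 * 1e6
}

# pH from (TA, DIC), both umol/kg, by bisection on pH in [3, 12]
oracle_ph <- function(TA_umol, DIC_umol, cond, NH4 = 0, NO3 = 0, PO4 = 0,
                      Si = 0) {
  k <- equilibrium_constants(cond)
  TA <- TA_umol * 1e-6
  lo <- 3; hi <- 12
  for (i in 1:64) {
    mid <- (lo + hi) / 2
    if (oracle_ta(mid, DIC_umol * 1e-6, k, NH4 * 1e-6, NO3 * 1e-6,
                  PO4 * 1e-6, Si * 1e-6) < TA) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# random feasible coastal states used by several property tests
random_states <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(pH = runif(n, 7.0, 8.9),
             TA = runif(n, 1800, 2600),
             temp = runif(n, 8, 25),
             sal = runif(n, 30, 36),
             NH4 = runif(n, 0, 3),
             NO3 = runif(n, 0, 8),
             PO4 = runif(n, 0, 2))
}
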