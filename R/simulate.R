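# Forward simulator of closed tide-pool diel biogeochemistry. Generates
# bottle-sample tables in the same schema the analysis consumes, together
# with the generating truth, so that every estimator in the package can be
# validated by parameter recovery.

#' Simulation configuration
#'
#' Defaults emulate the study design the package is built around: 4 sites
#' spanning a latitudinal ocean-pH gradient, 13-15 pools per site, day and
#' night low-tide events with 6 hourly bottle samples each. Producer
#' dominance scales the light-saturated production amplitude, and net
#' calcification responds to the aragonite saturation state when the
#' biophysical feedback is enabled.
#'
#' @param n_sites Number of sites.
#' @param site_names,pools_per_site,ocean_ph Site presets. The default
#'   ocean pH runs from 8.12 (southernmost) to 7.87 (northernmost); the
#'   two middle values are interpolated.
#' @param ocean_ta Ocean total alkalinity, umol/kg.
#' @param ocean_ph_sd Slow ocean pH variability (0 gives a constant series).
#' @param samples_per_event Bottle samples per low-tide event (hourly).
#' @param dt Sampling interval, h.
#' @param P_max Light-saturated gross production amplitude at producer
#'   dominance +100, mmol C m-2 h-1.
#' @param R Community respiration, mmol C m-2 h-1.
#' @param k_calc Calcification gain per unit (Omega - 1),
#'   mmol CaCO3 m-2 h-1.
#' @param dissolution_rate Dissolution gain per unit (1 - Omega),
#'   mmol CaCO3 m-2 h-1.
#' @param omega_feedback Couple NEC to the aragonite saturation state?
#' @param forcing `"mechanistic"` (light- and Omega-driven rates) or
#'   `"constant"` (fixed `ncp_const`/`nec_const`, for rate-recovery tests).
#' @param ncp_const,nec_const Constant rates used when
#'   `forcing = "constant"` (and `nec_const` also when the Omega feedback
#'   is off), mmol m-2 h-1.
#' @param peak_par Midday peak PAR, umol photons m-2 s-1.
#' @param I_k Light-saturation parameter of the tanh P-I curve, same unit.
#' @param wind Wind speed, m/s.
#' @param evaporation_rate Fractional evaporative concentration per hour
#'   (scales salinity, TA and DIC conservatively; default 0).
#' @param temperature,salinity Water temperature (degC) and salinity of the
#'   pools and ocean. The default salinity equals the reference salinity of
#'   the rate calculations, so salinity normalisation is the identity
#'   unless evaporation is switched on.
#' @param noise Named list of observation noise SDs: `pH` (total scale),
#'   `TA` (umol/kg), `nutrients` (umol/kg).
#' @param nutrient_base Baseline NH4/NO3/PO4 concentrations, umol/kg.
#' @param pq Photosynthetic quotient linking DO to cumulative NCP.
#' @param do_init Initial dissolved oxygen, mg/L.
#' @param hypoxia_taper Taper respiration as DO approaches zero (emulates
#'   nighttime hypoxia; off by default for clean recovery tests).
#' @param dt_inner Euler step of the forward integration, h (default 1
#'   min), small enough that discretisation error is below measurement
#'   noise.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 4,
                       site_names = c("CoronaDelMar", "MontereyBay",
                                      "BodegaBay", "BobCreek"),
                       pools_per_site = c(14, 13, 15, 15),
                       ocean_ph = c(8.12, 8.04, 7.95, 7.87),
                       ocean_ta = 2250,
                       ocean_ph_sd = 0.02,
                       samples_per_event = 6,
                       dt = 1,
                       P_max = 15, R = 4,
                       k_calc = 0.6, dissolution_rate = 0.3,
                       omega_feedback = TRUE,
                       forcing = c("mechanistic", "constant"),
                       ncp_const = 0, nec_const = 0,
                       peak_par = 1500, I_k = 300,
                       wind = 1,
                       evaporation_rate = 0,
                       temperature = 15, salinity = 36,
                       noise = list(pH = 0.005, TA = 3, nutrients = 0.1),
                       nutrient_base = c(NH4 = 1, NO3 = 2, PO4 = 0.5),
                       pq = 1.1, do_init = 8,
                       hypoxia_taper = FALSE,
                       dt_inner = 1 / 60) {
  forcing <- match.arg(forcing)
  n_sites <- as.integer(n_sites)
  stopifnot(n_sites >= 1, samples_per_event >= 2, dt > 0, dt_inner > 0,
            dt_inner <= dt, evaporation_rate >= 0)
  cfg <- list(n_sites = n_sites,
              site_names = rep_len(site_names, n_sites),
              pools_per_site = rep_len(pools_per_site, n_sites),
              ocean_ph = rep_len(ocean_ph, n_sites),
              ocean_ta = ocean_ta, ocean_ph_sd = ocean_ph_sd,
              samples_per_event = samples_per_event, dt = dt,
              P_max = P_max, R = R, k_calc = k_calc,
              dissolution_rate = dissolution_rate,
              omega_feedback = omega_feedback, forcing = forcing,
              ncp_const = ncp_const, nec_const = nec_const,
              peak_par = peak_par, I_k = I_k, wind = wind,
              evaporation_rate = evaporation_rate,
              temperature = temperature, salinity = salinity,
              noise = noise, nutrient_base = nutrient_base,
              pq = pq, do_init = do_init, hypoxia_taper = hypoxia_taper,
              dt_inner = dt_inner)
  structure(cfg, class = "sim_config")
}

#' Random pool geometries
#'
#' Draws physical attributes typical of mid-to-high intertidal pools:
#' log-normal volumes around 0.08 m3, bottom surface areas scaling as
#' V^(2/3), and uniform normalised tide heights.
#'
#' @param n Number of pools.
#' @param seed Optional RNG seed.
#' @return Data frame with `pool_id`, `tide_height_norm`, `max_depth_m`,
#'   `volume_m3`, `perimeter_m`, `surface_area_m2`, `sa_to_vol`.
#' @export
sim_pool_geometry <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  V <- pmin(pmax(stats::rlnorm(n, log(0.1), 0.4), 0.04), 0.6)
  SA <- 3.5 * V^(2 / 3) * exp(stats::rnorm(n, 0, 0.15))
  data.frame(pool_id = sprintf("P%02d", seq_len(n)),
             tide_height_norm = stats::runif(n, 0.2, 0.9),
             max_depth_m = stats::runif(n, 0.06, 0.35),
             volume_m3 = V,
             perimeter_m = 4 * sqrt(SA) * exp(stats::rnorm(n, 0, 0.1)),
             surface_area_m2 = SA,
             sa_to_vol = SA / V)
}

#' Ocean boundary pH series
#'
#' Slowly varying adjacent-ocean pH: a low-frequency sinusoid of amplitude
#' `sd` plus white noise of half that amplitude around the configured site
#' mean. `sd = 0` yields a constant series.
#'
#' @param times_h Sample times, hours.
#' @param mean_ph Site mean ocean pH.
#' @param ta Ocean TA, umol/kg.
#' @param sd Variability scale (pH units).
#' @param seed Optional RNG seed.
#' @return Data frame with `time_h`, `pH_total`, `TA_umol_kg`.
#' @export
ocean_boundary_series <- function(times_h, mean_ph, ta = 2250, sd = 0.02,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phase <- if (sd > 0) stats::runif(1, 0, 2 * pi) else 0
  noise <- if (sd > 0) stats::rnorm(length(times_h), 0, sd / 2) else 0
  data.frame(time_h = times_h,
             pH_total = mean_ph + sd * sin(2 * pi * times_h / 12 + phase) + noise,
             TA_umol_kg = ta)
}

# instantaneous PAR over a low-tide window: half-sine for day, dark at night
par_curve <- function(t, duration, event, peak_par) {
  if (event == "night") return(0 * t)
  peak_par * sin(pi * pmin(pmax(t / duration, 0), 1))
}

#' Simulate one pool's low-tide sampling event
#'
#' Forward Euler integration of the closed-pool TA/DIC budget at
#' `dt_inner` resolution. Production follows a tanh photosynthesis-
#' irradiance curve scaled by producer dominance minus a constant
#' respiration; calcification either responds linearly to (Omega - 1)
#' (feedback on) or is constant; air-sea exchange uses the same flux
#' formulation as the analysis; pH is re-solved from (TA, DIC) at every
#' step; DO tracks cumulative NCP through a photosynthetic quotient.
#' Hourly bottle samples are emitted with configurable observation noise,
#' alongside interval-averaged true rates.
#'
#' @param geometry One row of [sim_pool_geometry()] (or any list with
#'   `volume_m3`, `surface_area_m2`).
#' @param config A [sim_config()].
#' @param ocean_state List with `pH` and `TA` giving the flushing state at
#'   the start of the event.
#' @param event `"day"` or `"night"`.
#' @param producer_dominance Pool producer dominance in \[-100, 100\];
#'   scales the production amplitude.
#' @param seed Optional RNG seed (noise only).
#' @param site,pool_id Labels copied into the output tables.
#' @return List with `samples` (bottle-sample data frame in the standard
#'   schema) and `truth` (per-interval time-averaged `NCP`, `NEC`, `FCO2`
#'   plus labels).
#' @export
simulate_pool_series <- function(geometry, config, ocean_state,
                                 event = "day", producer_dominance = 0,
                                 seed = NULL, site = "S1", pool_id = "P01") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  V <- geometry$volume_m3
  SA <- geometry$surface_area_m2
  duration <- (config$samples_per_event - 1) * config$dt
  n_steps <- round(duration / config$dt_inner)
  steps_per_interval <- round(config$dt / config$dt_inner)

  S <- config$salinity
  cond <- sw_conditions(config$temperature, S)
  k <- equilibrium_constants(cond)
  kgas <- gas_transfer_velocity(config$wind, config$temperature)
  nb <- config$nutrient_base
  nut <- nutrients(NH4 = nb[["NH4"]], NO3 = nb[["NO3"]], PO4 = nb[["PO4"]])
  # scalar speciation used in the inner loop (pH warm-started step to step)
  speciate <- function(TA, DIC, kk, guess) {
    pH <- solve_ph_core(TA * 1e-6, DIC * 1e-6, kk,
                        nut$NH4 * 1e-6, nut$NO3 * 1e-6, nut$PO4 * 1e-6, 0,
                        guess)
    H <- 10^(-pH)
    den <- H^2 + kk$K1 * H + kk$K1 * kk$K2
    list(pH = pH,
         pCO2 = DIC * H^2 / den / kk$K0,
         omega_arag = kk$CaT * (DIC * kk$K1 * kk$K2 / den) * 1e-6 / kk$Ksp_arag)
  }

  st0 <- carb_from_ph_ta(ocean_state$pH, ocean_state$TA, cond, nut,
                         constants = k)
  TA <- ocean_state$TA
  DIC <- st0$DIC
  DO <- config$do_init
  pH <- ocean_state$pH
  P_pool <- config$P_max * (producer_dominance + 100) / 200

  n_samp <- config$samples_per_event
  times <- seq(0, duration, by = config$dt)
  samp <- data.frame(time_h = times, pH = NA_real_, TA = NA_real_,
                     DO = NA_real_, S = NA_real_)
  rate_ncp <- rate_nec <- rate_fco2 <- numeric(n_steps)

  record <- function(i_samp, pH, TA, DO, S) {
    samp$pH[i_samp] <<- pH
    samp$TA[i_samp] <<- TA
    samp$DO[i_samp] <<- DO
    samp$S[i_samp] <<- S
  }

  state <- speciate(TA, DIC, k, pH)
  record(1, state$pH, TA, DO, S)

  for (s in seq_len(n_steps)) {
    t <- (s - 1) * config$dt_inner
    par <- par_curve(t, duration, event, config$peak_par)
    R_eff <- config$R
    if (config$hypoxia_taper) R_eff <- R_eff * DO / (DO + 0.5)
    if (config$forcing == "constant") {
      ncp <- config$ncp_const
      nec <- config$nec_const
    } else {
      # gross production saturates with light and shuts down when CO2 is
      # depleted (tanh factor is exactly 1 at any normal pCO2 and only
      # bites below ~60 uatm, i.e. pH beyond ~9.2)
      ncp <- P_pool * tanh(par / config$I_k) * tanh(state$pCO2 / 20) - R_eff
      nec <- if (config$omega_feedback) {
        config$k_calc * max(state$omega_arag - 1, 0) -
          config$dissolution_rate * max(1 - state$omega_arag, 0)
      } else {
        config$nec_const
      }
    }
    fco2 <- co2_flux(kgas, k$K0, state$pCO2, 400, 1023)
    rate_ncp[s] <- ncp; rate_nec[s] <- nec; rate_fco2[s] <- fco2

    # budget updates, umol/kg per inner step
    fac <- SA * config$dt_inner / (1023 * V) * 1000
    DIC <- DIC - (ncp + nec + fco2) * fac
    TA <- TA - 2 * nec * fac
    DO <- max(DO + config$pq * ncp * SA * config$dt_inner / V * 32 / 1000,
              0.05)
    if (config$evaporation_rate > 0) {
      ef <- 1 + config$evaporation_rate * config$dt_inner
      S <- S * ef; TA <- TA * ef; DIC <- DIC * ef
      cond <- sw_conditions(config$temperature, S)
      k <- equilibrium_constants(cond)
    }
    state <- tryCatch(
      speciate(TA, DIC, k, state$pH),
      error = function(e) {
        stop(sprintf("simulation infeasible at t=%.2f h (TA=%.1f, DIC=%.1f): %s",
                     t, TA, DIC, conditionMessage(e)), call. = FALSE)
      })
    if (s %% steps_per_interval == 0) {
      record(s / steps_per_interval + 1, state$pH, TA, DO, S)
    }
  }

  nz <- config$noise
  obs_ph <- samp$pH + stats::rnorm(n_samp, 0, nz$pH)
  obs_ta <- samp$TA + stats::rnorm(n_samp, 0, nz$TA)
  nb <- config$nutrient_base
  obs_nut <- vapply(c("NH4", "NO3", "PO4"), function(nm) {
    pmax(nb[[nm]] + stats::rnorm(n_samp, 0, nz$nutrients), 0)
  }, numeric(n_samp))

  samples <- data.frame(
    site = site, pool_id = pool_id, event = event,
    time_h = samp$time_h, pH_total = obs_ph, TA_umol_kg = obs_ta,
    temp_C = config$temperature, sal_psu = samp$S, DO_mg_L = samp$DO,
    NH4 = obs_nut[, "NH4"], NO3 = obs_nut[, "NO3"], PO4 = obs_nut[, "PO4"],
    wind_m_s = config$wind, is_ocean = FALSE)

  idx <- rep(seq_len(n_samp - 1), each = steps_per_interval)
  truth <- data.frame(
    site = site, pool_id = pool_id, event = event,
    t_start = times[-n_samp], t_end = times[-1],
    NCP = as.numeric(tapply(rate_ncp, idx, mean)),
    NEC = as.numeric(tapply(rate_nec, idx, mean)),
    FCO2 = as.numeric(tapply(rate_fco2, idx, mean)),
    producer_dominance = producer_dominance)

  list(samples = samples, truth = truth)
}

#' Simulate one site (all pools, day and night events, paired ocean)
#'
#' Pools receive an even gradient of producer dominance over \[-90, 90\],
#' random geometries, and day plus night sampling events initialised from
#' the site's ocean series.
#'
#' @param config A [sim_config()].
#' @param site_index Which site preset to use (1-based).
#' @param seed RNG seed (all randomness for this site flows from it).
#' @return List with `samples` (pool and ocean rows), `truth`, `pools`
#'   (per-pool geometry and producer dominance).
#' @export
simulate_site <- function(config, site_index = 1, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  site <- config$site_names[site_index]
  n_pools <- config$pools_per_site[site_index]
  geom <- sim_pool_geometry(n_pools)
  pd <- seq(-90, 90, length.out = n_pools) + stats::rnorm(n_pools, 0, 3)
  pd <- pmin(pmax(pd, -100), 100)
  times <- seq(0, (config$samples_per_event - 1) * config$dt, by = config$dt)

  all_samples <- list(); all_truth <- list()
  for (ev in c("day", "night")) {
    oc <- ocean_boundary_series(times, config$ocean_ph[site_index],
                                config$ocean_ta, config$ocean_ph_sd)
    oc_rows <- data.frame(
      site = site, pool_id = "OCEAN", event = ev, time_h = oc$time_h,
      pH_total = oc$pH_total, TA_umol_kg = oc$TA_umol_kg,
      temp_C = config$temperature, sal_psu = config$salinity,
      DO_mg_L = config$do_init,
      NH4 = config$nutrient_base[["NH4"]],
      NO3 = config$nutrient_base[["NO3"]],
      PO4 = config$nutrient_base[["PO4"]],
      wind_m_s = config$wind, is_ocean = TRUE)
    all_samples[[paste0("ocean_", ev)]] <- oc_rows
    # shallow pools heat above (day) or cool below (night) the ocean
    dT <- if (ev == "day") stats::runif(n_pools, 0, 4) else
      stats::runif(n_pools, -2, 0.5)
    for (p in seq_len(n_pools)) {
      cfg_p <- config
      cfg_p$temperature <- config$temperature + dT[p]
      run <- simulate_pool_series(
        geom[p, ], cfg_p,
        ocean_state = list(pH = oc$pH_total[1], TA = oc$TA_umol_kg[1]),
        event = ev, producer_dominance = pd[p],
        site = site, pool_id = geom$pool_id[p])
      all_samples[[paste(ev, p)]] <- run$samples
      all_truth[[paste(ev, p)]] <- run$truth
    }
  }
  pools <- cbind(site = site, geom, producer_dominance = pd)
  list(samples = do.call(rbind, all_samples),
       truth = do.call(rbind, all_truth),
       pools = pools)
}

#' Simulate the full multi-site campaign
#'
#' @param config A [sim_config()].
#' @param seed Master seed; per-site seeds are derived from it.
#' @return List with `samples`, `truth` and `pools` tables covering all
#'   sites.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  runs <- lapply(seq_len(config$n_sites), function(i) {
    simulate_site(config, site_index = i, seed = seed + 1000 * i)
  })
  out <- list(samples = do.call(rbind, lapply(runs, `[[`, "samples")),
              truth = do.call(rbind, lapply(runs, `[[`, "truth")),
              pools = do.call(rbind, lapply(runs, `[[`, "pools")))
  rownames(out$samples) <- rownames(out$truth) <- rownames(out$pools) <- NULL
  out
}

#' Simulate pool-summary tables for driver-model calibration
#'
#' Statistical-level generator used to calibrate the mixed-effects driver
#' models: standardised predictors are drawn independently per pool, and a
#' standardised pH response is built from user-specified effect sizes plus
#' site and pool random intercepts and day/night-specific residual noise.
#' No biogeochemistry is involved; this isolates the inference machinery.
#'
#' @param effects Named vector of standardized effect sizes (names must be
#'   predictor columns; defaults to all six study predictors at zero).
#' @param n_sites,pools_per_site Design dimensions.
#' @param day_night Emit two rows per pool (day/night) with a pool random
#'   intercept and unequal residual SDs, as in the pH-mean model; otherwise
#'   one row per pool, as in the pH-range model.
#' @param sd_site,sd_pool Random-intercept SDs.
#' @param sd_day,sd_night Residual SDs for day and night rows (`sd_day` is
#'   used for all rows when `day_night = FALSE`).
#' @param seed RNG seed.
#' @return Data frame with `site`, `pool_id`, predictors, optionally
#'   `event`, and the `response` column.
#' @export
simulate_pool_summaries <- function(effects = c(producer_dominance = 0,
                                                ta_dic_slope = 0,
                                                pc1_size = 0,
                                                pc2_location = 0,
                                                log_int_par = 0,
                                                temp_mean = 0),
                                    n_sites = 4,
                                    pools_per_site = c(14, 13, 15, 15),
                                    day_night = TRUE,
                                    sd_site = 0.3, sd_pool = 0.4,
                                    sd_day = 0.6, sd_night = 0.3,
                                    seed = 1) {
  set.seed(seed)
  pools_per_site <- rep_len(pools_per_site, n_sites)
  n <- sum(pools_per_site)
  site <- rep(sprintf("S%d", seq_len(n_sites)), pools_per_site)
  X <- matrix(stats::rnorm(n * length(effects)), n,
              dimnames = list(NULL, names(effects)))
  b_site <- stats::rnorm(n_sites, 0, sd_site)[match(site, unique(site))]
  lin <- drop(X %*% effects) + b_site
  df <- data.frame(site = site,
                   pool_id = sprintf("%s_P%02d", site,
                                     unlist(lapply(pools_per_site, seq_len))),
                   X)
  if (day_night) {
    df2 <- rbind(cbind(df, event = "day"), cbind(df, event = "night"))
    b_pool <- stats::rnorm(n, 0, sd_pool)
    eps <- c(stats::rnorm(n, 0, sd_day), stats::rnorm(n, 0, sd_night))
    df2$response <- c(lin, lin) + rep(b_pool, 2) + eps
    df2
  } else {
    df$response <- lin + stats::rnorm(n, 0, sd_day)
    df
  }
}
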