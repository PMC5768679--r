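# Readers/writers, configuration and the orchestration of the full
# analysis: speciation -> interval rates -> pool summaries -> driver and
# feedback models. All tables travel as plain CSV; configuration is YAML.

water_sample_columns <- c("site", "pool_id", "event", "time_h", "pH_total",
                          "TA_umol_kg", "temp_C", "sal_psu", "DO_mg_L",
                          "NH4", "NO3", "PO4", "wind_m_s", "is_ocean")

#' Read and validate a water-sample CSV
#'
#' Checks the schema, basic physical ranges, and sorts rows by time within
#' each (site, pool, event) series.
#'
#' @param path CSV file with the columns `site, pool_id, event, time_h,
#'   pH_total, TA_umol_kg, temp_C, sal_psu, DO_mg_L, NH4, NO3, PO4,
#'   wind_m_s, is_ocean`.
#' @return Validated, time-sorted data frame.
#' @export
read_water_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(water_sample_columns, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(df$sal_psu <= 0)
  if (length(bad)) {
    stop("non-positive salinity at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$site, df$pool_id, df$event, df$time_h), ]
  key <- interaction(df$site, df$pool_id, df$event, drop = TRUE)
  dup <- unlist(tapply(df$time_h, key, function(t) any(duplicated(t))))
  if (any(dup)) {
    stop("duplicated sample times within series: ",
         paste(names(dup)[dup], collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a pipeline run configuration (YAML)
#'
#' @param path YAML file; recognised top-level keys: `seed`, `out_dir`,
#'   `constants` (overrides for rho / pco2_air / salinity_ref),
#'   `simulation` (overrides for [sim_config()] fields), and `inputs`
#'   (paths to `samples` / `pools` CSVs when analysing existing tables
#'   instead of simulating).
#' @return A `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

as_run_config <- function(cfg = list()) {
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$out_dir <- if (is.null(cfg$out_dir)) "poolchem_out" else cfg$out_dir
  pc <- do.call(phys_config, cfg$constants %||% list())
  sc <- do.call(sim_config, cfg$simulation %||% list())
  cfg$phys <- pc
  cfg$sim <- sc
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interval rates for every pool series in a sample table
#'
#' Applies [rate_series()] to each (site, pool, event) group of non-ocean
#' rows, using each pool's geometry.
#'
#' @param samples Water-sample table (schema of [read_water_samples()]).
#' @param pools Pool table with `site`, `pool_id`, `volume_m3`,
#'   `surface_area_m2`.
#' @param config A [phys_config()].
#' @param gas_exchange Passed through to [rate_series()].
#' @return Interval table keyed by `site`, `pool_id`, `event`, `t_start`.
#' @export
pool_rates <- function(samples, pools, config = phys_config(),
                       gas_exchange = TRUE) {
  pool_rows <- samples[!samples$is_ocean, ]
  keys <- unique(pool_rows[c("site", "pool_id", "event")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- pool_rows$site == keys$site[i] &
      pool_rows$pool_id == keys$pool_id[i] &
      pool_rows$event == keys$event[i]
    g <- pools[pools$site == keys$site[i] &
                 pools$pool_id == keys$pool_id[i], ]
    if (nrow(g) != 1) {
      stop(sprintf("geometry missing for pool %s/%s", keys$site[i],
                   keys$pool_id[i]), call. = FALSE)
    }
    r <- rate_series(pool_rows[sel, ], g, config, gas_exchange)
    out[[i]] <- cbind(keys[i, ], r, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Pool-level summary table
#'
#' Per pool: day/night mean pH, pH range and signed pH divergence from the
#' paired ocean series ([ph_summaries()]), the TA/DIC slope over all time
#' points, producer dominance, the first two physical-attribute principal
#' components, and mean temperature.
#'
#' @param samples Water-sample table including ocean rows
#'   (`pool_id == "OCEAN"` or `is_ocean`).
#' @param pools Pool table (geometry + `producer_dominance`).
#' @param rates Interval table from [pool_rates()] (supplies normalised
#'   TA/DIC for the slope).
#' @return One row per pool with summary metrics.
#' @export
summarize_pools <- function(samples, pools, rates) {
  pca <- physical_pca(pools[c("tide_height_norm", "max_depth_m", "volume_m3",
                              "perimeter_m", "surface_area_m2", "sa_to_vol")])
  pools$pc1_size <- pca$scores[, 1]
  pools$pc2_location <- pca$scores[, 2]

  out <- vector("list", nrow(pools))
  for (i in seq_len(nrow(pools))) {
    si <- pools$site[i]; pid <- pools$pool_id[i]
    ps <- samples[!samples$is_ocean & samples$site == si &
                    samples$pool_id == pid, ]
    os <- samples[samples$is_ocean & samples$site == si, ]
    sm <- ph_summaries(ps, os)
    rr <- rates[rates$site == si & rates$pool_id == pid, ]
    # slope across the series: per-sample normalised TA/DIC carried on the
    # interval table (interval start values)
    sl <- ta_dic_slope(rr$TA_norm, rr$DIC_norm)
    out[[i]] <- data.frame(
      site = si, pool_id = pid,
      ph_mean_day = sm$ph_mean_day, ph_mean_night = sm$ph_mean_night,
      ph_range = sm$ph_range, ph_divergence = sm$ph_divergence,
      ta_dic_slope = sl$slope,
      producer_dominance = pools$producer_dominance[i],
      pc1_size = pools$pc1_size[i], pc2_location = pools$pc2_location[i],
      temp_mean = mean(ps$temp_C), temp_range = diff(range(ps$temp_C)))
  }
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Simulates a campaign (or reads existing tables), computes interval
#' rates, pool summaries, driver-model effects and feedback-model slopes,
#' writes every table as CSV into `out_dir` together with a JSON manifest
#' (configuration, seed, file checksums), and returns the bundle
#' invisibly. Rerunning with the same configuration and seed reproduces
#' the outputs exactly.
#'
#' @param config A `run_config` (see [read_run_config()]) or a plain list
#'   with the same keys.
#' @return Invisibly, a list with `samples`, `rates`, `summaries`,
#'   `mean_effects`, `range_effects`, `feedback`, `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$inputs)) {
    samples <- read_water_samples(config$inputs$samples)
    pools <- utils::read.csv(config$inputs$pools, stringsAsFactors = FALSE)
    truth <- NULL
  } else {
    ds <- simulate_dataset(config$sim, seed = config$seed)
    samples <- ds$samples; pools <- ds$pools; truth <- ds$truth
  }
  if (nrow(samples[!samples$is_ocean, ]) == 0) {
    stop("insufficient data: no pool samples in input", call. = FALSE)
  }

  rates <- pool_rates(samples, pools, config$phys)
  summaries <- summarize_pools(samples, pools, rates)

  mean_tab <- rbind(
    data.frame(summaries[c("site", "pool_id", "producer_dominance",
                           "ta_dic_slope", "pc1_size", "pc2_location",
                           "temp_mean")],
               event = "day", ph_mean = summaries$ph_mean_day),
    data.frame(summaries[c("site", "pool_id", "producer_dominance",
                           "ta_dic_slope", "pc1_size", "pc2_location",
                           "temp_mean")],
               event = "night", ph_mean = summaries$ph_mean_night))
  mean_fit <- fit_driver_model(
    mean_tab, "ph_mean",
    c("producer_dominance", "ta_dic_slope", "pc1_size", "pc2_location",
      "temp_mean"),
    day_night = TRUE)
  range_fit <- fit_driver_model(
    summaries, "ph_range",
    c("producer_dominance", "ta_dic_slope", "pc1_size", "pc2_location",
      "temp_range"),
    day_night = FALSE)

  feedback <- fit_feedback_models(rates)

  paths <- list(
    samples = file.path(config$out_dir, "water_samples.csv"),
    rates = file.path(config$out_dir, "interval_rates.csv"),
    summaries = file.path(config$out_dir, "pool_summaries.csv"),
    effects = file.path(config$out_dir, "effects.csv"))
  utils::write.csv(samples, paths$samples, row.names = FALSE)
  utils::write.csv(rates, paths$rates, row.names = FALSE)
  utils::write.csv(summaries, paths$summaries, row.names = FALSE)
  effects <- rbind(mean_fit$effects, range_fit$effects)
  utils::write.csv(effects, paths$effects, row.names = FALSE)
  if (!is.null(truth)) {
    utils::write.csv(truth, file.path(config$out_dir, "truth.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("poolchem")),
    seed = config$seed,
    outputs = lapply(paths, function(p) unname(tools::md5sum(p))),
    n_samples = nrow(samples), n_pools = nrow(pools))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(samples = samples, rates = rates, summaries = summaries,
                 mean_effects = mean_fit$effects,
                 range_effects = range_fit$effects,
                 feedback = feedback, manifest = manifest))
}
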