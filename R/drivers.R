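# Pool-level pH summaries, TA/DIC ecosystem-metabolism slopes, standardised
# mixed-effects driver models, and the NCP -> pH -> NEC feedback regressions.
# Mixed models delegate to nlme (random intercepts, optional varIdent
# day/night residual variances); the significance convention is a 95% CI
# that excludes zero.

#' TA/DIC slope as an integrative metabolism metric
#'
#' Ordinary least-squares slope of salinity-normalised TA on DIC across all
#' of a pool's time points. The slope summarises the stoichiometric mix of
#' processes: 2 for pure calcification/dissolution (2 mol TA per mol CaCO3
#' against 1 mol DIC), 0 for pure production/respiration (TA conservative).
#'
#' @param TA,DIC Salinity-normalised series, umol/kg (>= 3 points).
#' @return List with `slope`, `se`, `r_squared`, `n`.
#' @export
ta_dic_slope <- function(TA, DIC) {
  stopifnot(length(TA) == length(DIC))
  if (length(TA) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(DIC) == 0) {
    stop("degenerate fit: DIC has zero variance", call. = FALSE)
  }
  fit <- stats::lm(TA ~ DIC)
  # exact stoichiometric series legitimately fit perfectly; keep quiet
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       se = sm$coefficients[2, 2],
       r_squared = sm$r.squared,
       n = length(TA))
}

#' Pool-level pH summaries against the adjacent ocean
#'
#' Computes, per pool: mean pH per day/night event, the pH range over all
#' samples (day and night pooled), and the signed pH divergence - the
#' pool-minus-ocean difference of largest absolute magnitude over the
#' sampling period, with its sign retained (producer-dominated pools
#' diverge upwards, consumer-dominated pools downwards).
#'
#' @param pool_samples Data frame with columns `event` ("day"/"night"),
#'   `time_h`, `pH_total` for one pool.
#' @param ocean_samples Matching data frame for the adjacent ocean; paired
#'   to the pool samples by `event` and `time_h`.
#' @return List with `ph_mean_day`, `ph_mean_night`, `ph_range`,
#'   `ph_divergence`.
#' @export
ph_summaries <- function(pool_samples, ocean_samples) {
  stopifnot(all(c("event", "time_h", "pH_total") %in% names(pool_samples)),
            all(c("event", "time_h", "pH_total") %in% names(ocean_samples)))
  key_p <- paste(pool_samples$event, pool_samples$time_h)
  key_o <- paste(ocean_samples$event, ocean_samples$time_h)
  m <- match(key_p, key_o)
  if (anyNA(m)) {
    stop("pairing error: ", sum(is.na(m)),
         " pool sample(s) have no matching ocean sample", call. = FALSE)
  }
  mean_ev <- function(ev) {
    x <- pool_samples$pH_total[pool_samples$event == ev]
    if (length(x) < 2) NA_real_ else mean(x)
  }
  diff_all <- pool_samples$pH_total - ocean_samples$pH_total[m]
  list(ph_mean_day = mean_ev("day"),
       ph_mean_night = mean_ev("night"),
       ph_range = max(pool_samples$pH_total) - min(pool_samples$pH_total),
       ph_divergence = diff_all[which.max(abs(diff_all))])
}

#' Standardise columns to z-scores
#'
#' @param data Data frame (>= 2 rows).
#' @param cols Columns to standardise (default: all numeric columns).
#' @return `data` with the selected columns centred to mean 0, sd 1.
#' @export
standardize_variables <- function(data, cols = NULL) {
  if (nrow(data) < 2) stop("need at least 2 rows", call. = FALSE)
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  for (cl in cols) {
    s <- stats::sd(data[[cl]])
    if (!is.finite(s) || s == 0) {
      stop(sprintf("column `%s` has zero variance and cannot be standardized", cl),
           call. = FALSE)
    }
    data[[cl]] <- (data[[cl]] - mean(data[[cl]])) / s
  }
  data
}

# fit lme trying both optimisers before giving up
try_lme <- function(args) {
  for (opt in c("optim", "nlminb")) {
    args$control <- nlme::lmeControl(opt = opt, maxIter = 500,
                                     msMaxIter = 500, niterEM = 50)
    fit <- tryCatch(do.call(nlme::lme, args), error = identity)
    if (!inherits(fit, "condition")) return(fit)
  }
  stop("mixed-model fit failed (possibly singular): ",
       conditionMessage(fit), call. = FALSE)
}

# extract standardized effects +- 95% CI from an nlme fit
effects_table <- function(fit, model = "") {
  tt <- summary(fit)$tTable
  crit <- stats::qt(0.975, tt[, "DF"])
  data.frame(predictor = rownames(tt),
             estimate = tt[, "Value"],
             ci_lo = tt[, "Value"] - crit * tt[, "Std.Error"],
             ci_hi = tt[, "Value"] + crit * tt[, "Std.Error"],
             significant = abs(tt[, "Value"]) > crit * tt[, "Std.Error"],
             model = model, row.names = NULL)
}

#' Mixed-effects driver model for pH mean or range
#'
#' Fits a random-intercept linear mixed model (REML, via `nlme::lme`) of a
#' standardised pool-level pH response on standardised predictors, with
#' site as a random intercept. For the pH-mean model (two rows per pool,
#' day and night) a pool-within-site random intercept accounts for the
#' repeated measure, selected predictors interact with time of day, and
#' day/night residual variances may differ (`varIdent`). Significance is a
#' 95% CI excluding zero.
#'
#' @param data Pool-summary data frame containing `response`, the
#'   predictors, a `site` column, and - when `day_night = TRUE` - `event`
#'   ("day"/"night") and `pool_id` columns.
#' @param response Response column name (e.g. `"ph_mean"` or `"ph_range"`).
#' @param predictors Character vector of predictor column names.
#' @param day_night Model day/night structure (interactions, pool random
#'   intercept, unequal variances)? Use `TRUE` for the mean model, `FALSE`
#'   for the range model.
#' @param interact_with_daynight Predictors crossed with time of day when
#'   `day_night = TRUE`.
#' @param unequal_variances Allow different residual variances for day and
#'   night events (`varIdent`).
#' @param standardize Standardise response and predictors internally
#'   (default `TRUE`; set `FALSE` if the table is already z-scored).
#' @return List with `effects` (data frame: predictor, estimate, ci_lo,
#'   ci_hi, significant) and the underlying `fit`.
#' @export
fit_driver_model <- function(data, response, predictors,
                             day_night = FALSE,
                             interact_with_daynight = intersect(
                               c("producer_dominance", "ta_dic_slope"),
                               predictors),
                             unequal_variances = day_night,
                             standardize = TRUE) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)),
            "site" %in% names(data))
  if (standardize) {
    data <- standardize_variables(data, cols = c(response, predictors))
  }
  main <- setdiff(predictors, interact_with_daynight)
  if (day_night) {
    stopifnot(all(c("event", "pool_id") %in% names(data)))
    data$event <- factor(data$event)
    terms <- c(main, sprintf("%s * event", interact_with_daynight))
    random <- ~ 1 | site / pool_id
  } else {
    terms <- predictors
    random <- ~ 1 | site
  }
  fml <- stats::reformulate(terms, response = response)
  args <- list(fixed = fml, random = random, data = data, method = "REML")
  if (day_night && unequal_variances) {
    args$weights <- nlme::varIdent(form = ~ 1 | event)
  }
  fit <- try_lme(args)
  list(effects = effects_table(fit, model = response), fit = fit)
}

# per-site slopes of `x` from an lme fit of y ~ x * site
site_slopes <- function(fit, x, sites) {
  fe <- nlme::fixef(fit)
  vc <- stats::vcov(fit)
  ref <- sites[1]
  out <- lapply(sites, function(s) {
    v <- rep(0, length(fe)); names(v) <- names(fe)
    v[x] <- 1
    inter <- paste0(x, ":site", s)
    if (s != ref && inter %in% names(fe)) v[inter] <- 1
    est <- sum(v * fe)
    se <- sqrt(drop(t(v) %*% vc %*% v))
    data.frame(site = s, slope = est, se = se,
               ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se)
  })
  do.call(rbind, out)
}

# average slope across sites with its SE (linear combination of fixed effects)
mean_slope <- function(fit, x, sites) {
  fe <- nlme::fixef(fit)
  vc <- stats::vcov(fit)
  v <- rep(0, length(fe)); names(v) <- names(fe)
  v[x] <- 1
  inters <- paste0(x, ":site", sites[-1])
  inters <- inters[inters %in% names(fe)]
  v[inters] <- 1 / length(sites)
  est <- sum(v * fe)
  se <- sqrt(drop(t(v) %*% vc %*% v))
  c(slope = est, se = se, ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se)
}

#' Biophysical feedback regressions between pH, NCP and NEC
#'
#' Fits the three interval-level feedback models - pH ~ NCP, NEC ~ pH and
#' NEC ~ NCP - each as a random-intercept (pool) mixed model with a site
#' interaction on the slope, mirroring the causal loop in which production
#' raises pH and higher pH promotes calcification.
#'
#' @param intervals Data frame of interval rates with columns `NCP`, `NEC`,
#'   `mean_pH`, `site`, `pool_id` (>= 2 sites, >= 2 pools per site).
#' @return Named list (`ph_ncp`, `nec_ph`, `nec_ncp`); each element holds
#'   the `fit`, the per-site `slopes` (with 95% CIs), the across-site
#'   `mean_slope`, and `interaction_p` - the p-value of the slope-by-site
#'   interaction (marginal ANOVA).
#' @export
fit_feedback_models <- function(intervals) {
  need <- c("NCP", "NEC", "mean_pH", "site", "pool_id")
  stopifnot(all(need %in% names(intervals)))
  intervals$site <- factor(intervals$site)
  # pools are nested in sites; build a globally unique pool identifier
  intervals$pool_uid <- interaction(intervals$site, intervals$pool_id,
                                    drop = TRUE)
  sites <- levels(intervals$site)
  if (length(sites) < 2) stop("need >= 2 sites", call. = FALSE)

  one <- function(fml, x) {
    fit <- try_lme(list(fixed = fml, random = ~ 1 | pool_uid,
                        data = intervals, method = "REML"))
    an <- stats::anova(fit, type = "marginal")
    ip <- an[grepl(":", rownames(an)), "p-value"]
    list(fit = fit, slopes = site_slopes(fit, x, sites),
         mean_slope = mean_slope(fit, x, sites),
         interaction_p = if (length(ip)) ip[1] else NA_real_)
  }
  list(ph_ncp = one(mean_pH ~ NCP * site, "NCP"),
       nec_ph = one(NEC ~ mean_pH * site, "mean_pH"),
       nec_ncp = one(NEC ~ NCP * site, "NCP"))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor `j` on the others.
#' Perfect collinearity is reported as `Inf` rather than an error.
#'
#' @param data Data frame of >= 2 numeric predictors.
#' @return Named numeric vector of VIFs.
#' @export
variance_inflation <- function(data) {
  num <- data[vapply(data, is.numeric, logical(1))]
  if (ncol(num) < 2) stop("need at least 2 predictors", call. = FALSE)
  vapply(names(num), function(j) {
    r2 <- summary(stats::lm(stats::reformulate(setdiff(names(num), j), j),
                            data = num))$r.squared
    if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Dissolved oxygen vs pH correlation
#'
#' OLS of pH on DO across samples; a high R2 indicates that pH variation is
#' tightly coupled to production/respiration.
#'
#' @param DO Dissolved oxygen, mg/L.
#' @param pH pH, total scale (same length, >= 3 finite pairs).
#' @return List with `r_squared`, `slope`, `n`.
#' @export
do_ph_correlation <- function(DO, pH) {
  ok <- is.finite(DO) & is.finite(pH)
  if (sum(ok) < 3) stop("need at least 3 finite DO/pH pairs", call. = FALSE)
  fit <- stats::lm(pH[ok] ~ DO[ok])
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]), n = sum(ok))
}
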