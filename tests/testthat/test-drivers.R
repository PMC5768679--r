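# Pool summaries, TA/DIC slopes, standardisation, VIF, and the
# mixed-effects driver / feedback machinery.

test_that("TA/DIC slope reflects the generating process stoichiometry", {
  # pure calcification: TA falls 2 per 1 of DIC
  dic <- seq(2100, 2000, length.out = 8)
  ta <- 2400 + 2 * (dic - 2100)
  s <- ta_dic_slope(ta, dic)
  expect_equal(s$slope, 2, tolerance = 1e-12)
  expect_equal(s$r_squared, 1)
  # pure production: TA conservative
  expect_equal(ta_dic_slope(rep(2300, 5) + 0, seq(2100, 1900, length.out = 5))$slope,
               0, tolerance = 1e-12)
  # mixed process with NEC:NCP molar ratio r -> slope 2r/(1+r)
  for (r in c(0.25, 0.5, 2)) {
    nec <- r; ncp <- 1
    t <- 0:6
    ta_m <- 2400 - 2 * nec * t
    dic_m <- 2150 - (nec + ncp) * t
    expect_equal(ta_dic_slope(ta_m, dic_m)$slope, 2 * r / (1 + r),
                 tolerance = 1e-10)
  }
  expect_error(ta_dic_slope(c(1, 2), c(1, 2)), "3 points")
  expect_error(ta_dic_slope(c(1, 2, 3), c(2, 2, 2)), "degenerate")
})

test_that("pH summaries: means, range, signed divergence of maximal magnitude", {
  pool <- data.frame(event = "day", time_h = 0:2,
                     pH_total = c(7.5, 8.2, 8.9))
  ocean <- data.frame(event = "day", time_h = 0:2, pH_total = rep(7.9, 3))
  sm <- ph_summaries(pool, ocean)
  expect_equal(sm$ph_range, 1.4)
  expect_equal(sm$ph_divergence, 1.0)       # +1.0 beats -0.4 in magnitude
  expect_equal(sm$ph_mean_day, mean(pool$pH_total))
  # pool always below ocean: sign retained
  low <- transform(pool, pH_total = ocean$pH_total - 0.4)
  expect_equal(ph_summaries(low, ocean)$ph_divergence, -0.4)
  # range invariant to sample order
  shuf <- pool[c(3, 1, 2), ]
  expect_equal(ph_summaries(shuf, ocean)$ph_range, 1.4)
  expect_error(ph_summaries(pool, ocean[1:2, ]), "pairing")
})

test_that("standardisation produces z-scores and is affine-invariant", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize_variables(d)
  expect_equal(unname(colMeans(z)), c(0, 0))
  expect_equal(unname(vapply(z, sd, numeric(1))), c(1, 1))
  expect_equal(z$a, c(-1, 0, 1))
  z2 <- standardize_variables(transform(d, a = 100 + 7 * a))
  expect_equal(z2$a, z$a)
  expect_error(standardize_variables(data.frame(a = c(1, 1, 1))), "a")
})

test_that("variance inflation factors match the closed form", {
  # balanced orthogonal design -> VIF exactly 1
  d <- data.frame(x1 = c(1, -1, 1, -1), x2 = c(1, 1, -1, -1))
  expect_equal(unname(variance_inflation(d)), c(1, 1))
  # exact correlation 0.6 -> VIF = 1/(1-0.36)
  u1 <- c(1, -1, 0, 0, 1, -1) / sqrt(4)
  u2 <- c(0, 0, 1, -1, 0, 0) / sqrt(2)
  d2 <- data.frame(x1 = u1, x2 = 0.6 * u1 + sqrt(1 - 0.36) * u2)
  expect_equal(unname(variance_inflation(d2)), rep(1 / (1 - 0.36), 2),
               tolerance = 1e-10)
  # duplicated predictor flags Inf instead of crashing (the perfect-fit
  # warning from summary.lm is expected on this degenerate fixture)
  expect_equal(suppressWarnings(
    unname(variance_inflation(data.frame(a = 1:5, b = 1:5)))),
    c(Inf, Inf))
})

test_that("DO/pH correlation behaves at the extremes", {
  DO <- seq(2, 10, length.out = 10)
  expect_equal(suppressWarnings(do_ph_correlation(DO, 7 + 0.1 * DO)$r_squared),
               1)
  set.seed(9)
  r2 <- mean(replicate(20, do_ph_correlation(rnorm(30), rnorm(30))$r_squared))
  expect_lt(r2, 0.2)
  expect_error(do_ph_correlation(c(1, 2), c(1, 2)), "3 finite")
})

test_that("driver model recovers a known standardized effect", {
  preds <- c("producer_dominance", "ta_dic_slope", "pc1_size",
             "pc2_location", "log_int_par", "temp_mean")
  d <- simulate_pool_summaries(effects = c(producer_dominance = 0.8,
                                           ta_dic_slope = 0, pc1_size = 0,
                                           pc2_location = 0, log_int_par = 0,
                                           temp_mean = 0),
                               seed = 21)
  f <- fit_driver_model(d, "response", preds, day_night = TRUE)
  e <- f$effects[f$effects$predictor == "producer_dominance", ]
  expect_gt(e$estimate, 0)
  expect_true(e$significant)
  # adding an irrelevant predictor barely moves the other effects
  set.seed(22)
  d$noise_pred <- rnorm(nrow(d))
  f2 <- fit_driver_model(d, "response", c(preds, "noise_pred"),
                         day_night = TRUE)
  for (p in preds) {
    expect_lt(abs(f2$effects$estimate[f2$effects$predictor == p] -
                    f$effects$estimate[f$effects$predictor == p]), 0.05)
  }
})

test_that("range-style driver model runs without day/night structure", {
  d <- simulate_pool_summaries(day_night = FALSE, seed = 31)
  f <- fit_driver_model(d, "response", c("producer_dominance", "pc1_size"))
  expect_equal(nrow(f$effects), 3)  # intercept + 2 predictors
  expect_true(all(f$effects$ci_lo <= f$effects$estimate))
  expect_true(all(f$effects$estimate <= f$effects$ci_hi))
})

test_that("feedback models recover injected slopes and site structure", {
  set.seed(41)
  sites <- c("A", "B")
  d <- expand.grid(site = sites, pool = sprintf("P%d", 1:6),
                   interval = 1:8)
  d$pool_id <- paste(d$site, d$pool)
  b_pool <- rnorm(length(unique(d$pool_id)), 0, 0.2)
  names(b_pool) <- unique(d$pool_id)
  d$mean_pH <- 8 + rnorm(nrow(d), 0, 0.3)
  slope_by_site <- c(A = 2.0, B = 0.8)  # site interaction present
  d$NEC <- slope_by_site[as.character(d$site)] * (d$mean_pH - 8) +
    b_pool[d$pool_id] + rnorm(nrow(d), 0, 0.2)
  d$NCP <- 3 * (d$mean_pH - 8) + rnorm(nrow(d), 0, 0.3)
  fb <- fit_feedback_models(d)
  expect_true(all(fb$nec_ph$slopes$slope > 0))
  expect_equal(fb$nec_ph$slopes$slope[fb$nec_ph$slopes$site == "A"], 2,
               tolerance = 0.25)
  expect_lt(fb$nec_ph$interaction_p, 0.05)
  expect_true(all(fb$ph_ncp$slopes$slope > 0))
})
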