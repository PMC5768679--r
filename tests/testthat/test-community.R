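# Community metrics, light processing and the physical-attribute PCA.

survey <- function(...) {
  x <- list(...)
  data.frame(group = names(x), percent_cover = unlist(x))
}

test_that("relative cover is a composition over the groups present", {
  expect_equal(unname(relative_cover(survey(fleshy_algae = 73))), 1)
  rc <- relative_cover(survey(fleshy_algae = 60, invertebrate = 60))
  expect_equal(unname(rc), c(0.5, 0.5))
  rc2 <- relative_cover(survey(fleshy_algae = 80, coralline_algae = 20,
                               invertebrate = 100))
  expect_equal(rc2[["fleshy_algae"]], 0.4)
  expect_equal(rc2[["coralline_algae"]], 0.1)
  expect_equal(rc2[["invertebrate"]], 0.5)
  expect_equal(sum(relative_cover(survey(fleshy_algae = 120, surfgrass = 30,
                                         bare_rock = 10))), 1)
  expect_error(relative_cover(survey(fleshy_algae = 0)), "degenerate")
  expect_error(relative_cover(survey(kelp_forest = 10)), "unknown")
})

test_that("producer dominance spans [-100, 100] and excludes crusts from both terms", {
  expect_equal(producer_dominance(survey(fleshy_algae = 85)), 100)
  expect_equal(producer_dominance(survey(invertebrate = 40)), -100)
  # relative producers 60%, consumers 40% -> +20
  expect_equal(producer_dominance(survey(fleshy_algae = 60,
                                         invertebrate = 40)), 20)
  # crusts and bare rock dilute the denominator but join neither term:
  # covers 40 fleshy + 40 crust + 20 inverts -> (40 - 20)/100*100 = 20
  expect_equal(producer_dominance(survey(fleshy_algae = 40,
                                         non_coralline_crust = 40,
                                         invertebrate = 20)), 20)
  # mussels count as consumers, surfgrass as producer
  expect_equal(producer_dominance(survey(surfgrass = 30, mussel = 70)), -40)
})

test_that("producer dominance is antisymmetric under swapping the two guilds", {
  set.seed(3)
  for (i in 1:20) {
    p <- runif(1, 5, 120); c <- runif(1, 5, 120); crust <- runif(1, 0, 60)
    a <- producer_dominance(survey(fleshy_algae = p, invertebrate = c,
                                   coralline_algae = crust))
    b <- producer_dominance(survey(fleshy_algae = c, invertebrate = p,
                                   coralline_algae = crust))
    expect_equal(a, -b)
  }
})

test_that("mobile counts convert to cover by footprint area", {
  mc <- data.frame(taxon = c("snail", "crab"), count = c(10, 0),
                   area_cm2 = c(10, 25))
  out <- mobile_counts_to_cover(mc, 1)
  expect_equal(out$percent_cover, c(1, 0))
  expect_equal(out$group, c("invertebrate", "invertebrate"))
  # linear in count
  mc2 <- transform(mc, count = count * 3)
  expect_equal(mobile_counts_to_cover(mc2, 1)$percent_cover,
               3 * out$percent_cover)
  # taxa without explicit areas fall back to the default footprint table
  lk <- mobile_counts_to_cover(data.frame(taxon = "limpet", count = 5), 2)
  expect_equal(lk$percent_cover, 5 * 6 / (2 * 1e4) * 100)
  expect_error(mobile_counts_to_cover(data.frame(taxon = "x", count = 1,
                                                 area_cm2 = NA), 1),
               "area_cm2")
})

test_that("tide-height normalisation and PAR conversion are linear maps", {
  expect_equal(normalize_tide_height(2.4, 2.4), 1)
  expect_equal(normalize_tide_height(0.6, 2.4), 0.25)
  expect_equal(normalize_tide_height(0, 2.4), 0)
  expect_error(normalize_tide_height(1, 0), "extent")
  expect_equal(lumens_to_par(0), 0)
  expect_equal(lumens_to_par(2000), 2 * lumens_to_par(1000))
  expect_error(lumens_to_par(-5), "intensity")
})

test_that("PAR integration matches closed forms", {
  tm <- seq(0, 360, by = 1)
  # constant PAR p over tau seconds -> p * tau
  p <- 800
  expect_equal(integrate_par(tm, rep(p, length(tm)), 0, 360),
               p * 360 * 60 * 1e-6)
  expect_equal(integrate_par(tm, rep(0, length(tm)), 0, 360), 0)
  # triangular ramp peaking mid-window -> 1/2 * peak * tau
  tri <- 1000 * (1 - abs(tm - 180) / 180)
  expect_equal(integrate_par(tm, tri, 0, 360), 0.5 * 1000 * 360 * 60 * 1e-6,
               tolerance = 1e-6)
  expect_error(integrate_par(tm, tri, 400, 500), "window")
})

test_that("physical PCA matches an independent eigendecomposition", {
  geom <- sim_pool_geometry(20, seed = 5)
  X <- geom[c("tide_height_norm", "max_depth_m", "volume_m3",
              "perimeter_m", "surface_area_m2", "sa_to_vol")]
  p <- physical_pca(X)
  expect_equal(sum(p$explained), 1)
  expect_gt(p$loadings["volume_m3", 1], 0)
  # eigen-oracle on the correlation matrix
  ev <- eigen(cor(X), symmetric = TRUE)
  expect_equal(p$explained, ev$values / sum(ev$values), tolerance = 1e-10)
  expect_equal(abs(p$loadings[, 1]), abs(ev$vectors[, 1]),
               ignore_attr = TRUE, tolerance = 1e-8)
  # scores are orthogonal across components
  g <- crossprod(p$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("PCA handles degenerate geometry tables", {
  X <- data.frame(a = rnorm(10), b = rnorm(10), c = rep(1, 10))
  expect_warning(p <- physical_pca(X), "constant")
  expect_equal(ncol(p$scores), 2)
  # collinear data: one axis carries all the variance
  z <- rnorm(12)
  line <- data.frame(a = z, b = 2 * z + 1, c = -z)
  expect_equal(physical_pca(line)$explained[1], 1, tolerance = 1e-10)
  expect_error(physical_pca(data.frame(a = 1:2, b = 2:3)), "3 pools")
})
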