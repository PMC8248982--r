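test_that("predictability scores obey the sign and symmetry contracts", {
  flat <- data.frame(q = c(0.01, 0.1, 1), n = c(100, 1000, 10000),
                     n_concordant = c(50, 500, 5000))
  s <- predictability_score(flat)
  expect_equal(s$score, 0, tolerance = 1e-12)
  expect_equal(s$slope, 0, tolerance = 1e-9)
  high <- flat; high$n_concordant <- round(0.7 * high$n)
  expect_gt(predictability_score(high)$score, 0)
  mirror <- high; mirror$n_concordant <- high$n - high$n_concordant
  expect_equal(predictability_score(mirror)$score,
               -predictability_score(high)$score, tolerance = 1e-9)
  expect_equal(abs(predictability_score(mirror)$slope),
               abs(predictability_score(high)$slope), tolerance = 1e-6)
  expect_error(predictability_score(flat[, ][flat$n > 1e9, ]), ">= 3")
})

test_that("score sign tracks the SNP-weighted mean concordance on random curves", {
  set.seed(71)
  for (i in 1:50) {
    q <- sort(runif(6, 0.001, 1))
    n <- rpois(6, 500) + 10
    k <- rbinom(6, n, runif(1, 0.3, 0.7))
    s <- predictability_score(data.frame(q = q, n = n, n_concordant = k))
    wm <- sum(k) / sum(n)
    if (abs(wm - 0.5) > 1e-9)
      expect_equal(s$score > 0, wm > 0.5)
  }
})

test_that("leave-one-out recovers reversed and concordant held-out pairs", {
  set.seed(72)
  cfg <- sim_config(n_snps = 4000, n_pairs = 8, frac_seasonal = 0.2,
                    seasonal_shift = 0.08, reversed_pops = 3L,
                    n_clinal_pops = 0, seed = 72)
  ds <- simulate_snp_table(cfg)
  loo <- leave_one_out(ds$table, ds$sheet, quantiles = c(0.01, 0.05, 0.2, 1))
  expect_equal(nrow(loo), 8)
  # the reversed pair disagrees with the remaining 7 -> negative score
  expect_lt(loo$score[3], 0)
  expect_gt(median(loo$score[-3]), loo$score[3])
  curves <- attr(loo, "curves")
  tight <- curves[[3]][curves[[3]]$q == 0.01, ]
  expect_lt(tight$concordance, 0.5)
  non_rev <- curves[[1]][curves[[1]]$q == 0.01, ]
  expect_gt(non_rev$concordance, 0.5)
})

test_that("null data give flat ~50% leave-one-out concordance", {
  set.seed(73)
  cfg <- sim_config(n_snps = 3000, n_pairs = 6, frac_seasonal = 0,
                    n_clinal_pops = 0, seed = 73)
  ds <- simulate_snp_table(cfg)
  loo <- leave_one_out(ds$table, ds$sheet, quantiles = c(0.2, 0.5, 1))
  curves <- attr(loo, "curves")
  bulk <- vapply(curves, function(cu) cu$concordance[cu$q == 1], numeric(1))
  expect_true(all(abs(bulk - 0.5) < 0.06))
})

test_that("thermal day counts and degree days follow their definitions", {
  wx <- data.frame(station_id = "S",
                   date = seq(as.Date("2012-06-01"), as.Date("2012-06-14"),
                              by = "day"),
                   tmin_c = 20, tmax_c = 40)
  n <- thermal_days(wx, "S", "2012-06-15", season = "spring", upper = 32)
  expect_equal(as.integer(n), 14L)
  expect_equal(as.integer(thermal_days(wx, "S", "2012-06-15",
                                       season = "spring", upper = 45)), 0L)
  expect_true(is.na(thermal_days(wx, "S", "2013-06-15", season = "spring")))
  dd <- degree_days(data.frame(station_id = "S", date = as.Date("2012-06-01"),
                               tmin_c = 10, tmax_c = 20), "S",
                    "2012-06-01", "2012-06-01")
  expect_equal(as.numeric(dd), 5)
  cold <- wx; cold$tmin_c <- 0; cold$tmax_c <- 8
  expect_equal(as.numeric(degree_days(cold, "S", "2012-06-01", "2012-06-14")), 0)
  # upper cutoff equal to base clamps everything to zero
  expect_equal(as.numeric(degree_days(wx, "S", "2012-06-01", "2012-06-14",
                                      base_temp = 10, upper_cutoff = 10)), 0)
})

test_that("nearest station selection uses great-circle distance", {
  stations <- data.frame(station_id = c("here", "near", "far"),
                         latitude = c(40, 41, -40),
                         longitude = c(-75, -75, 105))
  hit <- nearest_station(data.frame(latitude = 40, longitude = -75), stations)
  expect_equal(hit$station_id, "here")
  expect_equal(hit$distance_km, 0)
  hit2 <- nearest_station(data.frame(latitude = 40.4, longitude = -75), stations)
  expect_equal(hit2$station_id, "here")
  anti <- nearest_station(data.frame(latitude = 40, longitude = -75),
                          stations[3, ])
  expect_equal(anti$distance_km, pi * 6371, tolerance = 0.001)
})

test_that("the thermal grid has the documented size and recovers planted limits", {
  set.seed(74)
  np <- 15
  spec <- sim_weather_spec(localities = sprintf("p%02d", 1:np),
                           latitudes = seq(25, 45, length.out = np),
                           longitudes = -75,
                           spring_dates = "2012-06-15", fall_dates = "2012-10-15",
                           n_hot_spring_days = c(rep(c(0, 1, 2, 3), length.out = 11),
                                                 10, 12, 13, 14),
                           n_cold_fall_days = c(rep(c(1, 0, 2, 1), length.out = 11),
                                                 11, 9, 13, 12))
  wx <- simulate_weather(spec, seed = 74)
  y <- -0.3 * spec$pops$n_hot_spring_days - 0.3 * spec$pops$n_cold_fall_days +
    rnorm(np, 0, 0.1)
  scores <- data.frame(locality = spec$pops$locality, score = y,
                       station_id = spec$pops$station_id,
                       spring_date = "2012-06-15", fall_date = "2012-10-15")
  expect_equal(length(seq(-5, 40, by = 0.1)), 451)
  scan <- thermal_scan(scores, wx$weather)
  expect_equal(dim(scan$grid), c(451L, 451L))
  expect_lt(abs(scan$best$upper - 32), 1)
  expect_lt(abs(scan$best$lower - 5), 1)
  expect_gt(scan$best$r2, 0.8)
  expect_lt(scan$best$coef_x1, 0)
})

test_that("permutation p-values behave at the extremes and under the null", {
  set.seed(75)
  x <- rnorm(12)
  y <- 2 * x                       # perfect fit
  pr <- permutation_r2(y, data.frame(x = x), n_perms = 200, seed = 1)
  expect_equal(pr$r2, 1, tolerance = 1e-12)
  expect_equal(pr$p, 1 / 201)
  # null scores: p should not concentrate near 0
  ps <- replicate(40, {
    yy <- rnorm(12)
    suppressWarnings(permutation_r2(yy, data.frame(x = x), n_perms = 60,
                                    seed = sample.int(1e6, 1))$p)
  })
  expect_gt(mean(ps > 0.2), 0.5)
  expect_gt(min(ps), 0.01)
})

test_that("environmental model comparison ranks the true covariate first", {
  set.seed(76)
  n <- 15
  cov <- data.frame(latitude = seq(25, 45, length.out = n),
                    longitude = rnorm(n), method = rep("net", n))
  y <- 0.2 * cov$latitude + rnorm(n, 0, 0.3)
  res <- env_models(y, cov,
                    models = list(latitude = "latitude", longitude = "longitude",
                                  method = "method",
                                  lat_lon = c("latitude", "longitude")),
                    n_perms = 300, seed = 2)
  expect_false("method" %in% res$model)   # single-level factor skipped
  expect_gt(res$r2[res$model == "latitude"], res$r2[res$model == "longitude"])
  # nested models: bivariate R2 >= univariate R2
  expect_gte(res$r2[res$model == "lat_lon"] + 1e-12,
             res$r2[res$model == "latitude"])
  expect_lt(res$p_perm[res$model == "latitude"], 0.05)
  expect_true(all(res$fdr >= res$p_perm - 1e-12))
})

test_that("scores regressed on exact covariates give R2 = 1", {
  y <- c(1, 2, 3, 4.5, 6, 7)
  pr <- permutation_r2(y, data.frame(z = y), n_perms = 100, seed = 3)
  expect_equal(pr$r2, 1, tolerance = 1e-12)
})
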