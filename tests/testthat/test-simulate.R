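test_that("null configurations plant no spring/fall difference", {
  cfg <- sim_config(n_snps = 500, frac_seasonal = 0, seed = 5)
  sim <- simulate_true_frequencies(cfg)
  expect_equal(sim$f_spring, sim$f_fall)
  expect_false(any(sim$truth$is_seasonal))
})

test_that("seasonal shifts are additive on the frequency scale and flip in reversed pairs", {
  cfg <- sim_config(n_snps = 400, n_pairs = 4, frac_seasonal = 1,
                    seasonal_shift = 0.06, reversed_pops = 2L, seed = 9,
                    frac_clinal = 0)
  sim <- simulate_true_frequencies(cfg)
  d <- sim$f_fall - sim$f_spring
  interior <- sim$f_spring > 0.07 & sim$f_spring < 0.93  # away from clipping
  expect_equal(abs(d[interior]), rep(0.06, sum(interior)))
  # reversed pair moves opposite to the others at every unclipped SNP
  row_ok <- rowSums(interior) == 4
  expect_true(all(sign(d[row_ok, 2]) == -sign(d[row_ok, 1])))
  expect_equal(sim$reversed, c(FALSE, TRUE, FALSE, FALSE))
  # shared direction across non-reversed pairs
  expect_true(all(sign(d[row_ok, 3]) == sign(d[row_ok, 1])))
})

test_that("clipping keeps planted sites inside the polymorphic range", {
  cfg <- sim_config(n_snps = 300, n_pairs = 2, frac_seasonal = 1,
                    seasonal_shift = 0.08,
                    base_freq_law = list(dist = "uniform", min = 0.001, max = 0.05),
                    seed = 2)
  sim <- simulate_true_frequencies(cfg)
  eps <- 1 / (2 * 75 * 10)
  expect_true(all(sim$f_fall >= eps & sim$f_fall <= 1 - eps))
  expect_gt(sim$n_clipped, 0)
})

test_that("two-stage binomial sampling matches the effective-coverage variance", {
  nrep <- 1e5
  cnt <- sample_pool_counts(matrix(0.5, nrep, 1), n_flies = 75, depth = 94,
                            seed = 123)
  f <- cnt$alt / (cnt$alt + cnt$ref)
  v_expect <- 0.25 / effective_coverage(150, 94)
  expect_equal(var(as.vector(f)), v_expect, tolerance = 0.02)
  # degenerate inputs
  z <- sample_pool_counts(matrix(0, 10, 1), 75, 94, seed = 1)
  expect_true(all(z$alt == 0))
  o <- sample_pool_counts(matrix(1, 10, 1), 75, 94, seed = 1)
  expect_true(all(o$ref == 0))
  # reproducible from seed
  a <- sample_pool_counts(matrix(0.3, 50, 2), 75, 94, seed = 7)
  b <- sample_pool_counts(matrix(0.3, 50, 2), 75, 94, seed = 7)
  expect_identical(a, b)
})

test_that("simulated weather plants exact exceedance counts in the windows", {
  spec <- sim_weather_spec(localities = c("a", "b", "c"),
                           latitudes = c(30, 35, 40), longitudes = -75,
                           spring_dates = "2012-06-15", fall_dates = "2012-10-15",
                           n_hot_spring_days = c(0, 5, 14),
                           n_cold_fall_days = c(14, 3, 0))
  wx <- simulate_weather(spec, seed = 4)
  expect_true(all(wx$weather$tmin_c <= wx$weather$tmax_c))
  for (i in 1:3) {
    hot <- thermal_days(wx$weather, spec$pops$station_id[i], "2012-06-15",
                        season = "spring", upper = 32)
    cold <- thermal_days(wx$weather, spec$pops$station_id[i], "2012-10-15",
                         season = "fall", lower = 5)
    expect_equal(as.integer(hot), spec$pops$n_hot_spring_days[i])
    expect_equal(as.integer(cold), spec$pops$n_cold_fall_days[i])
  }
  # round-trip through the weather writer/reader preserves the counts
  path <- withr::local_tempfile(fileext = ".csv")
  write_weather(wx$weather, path)
  back <- read_weather(path)
  hot <- thermal_days(back, "ST_c", "2012-06-15", season = "spring", upper = 32)
  expect_equal(as.integer(hot), 14L)
  expect_error(sim_weather_spec("a", 30, -75, "2012-06-15", "2012-10-15",
                                15, 0), "window")
})

test_that("generated datasets have the configured shape and are seed-reproducible", {
  cfg <- sim_config(n_snps = 200, n_pairs = 3, n_clinal_pops = 4,
                    frac_seasonal = 0.2, seed = 31)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- generate_dataset(cfg, d1, overwrite = TRUE)
  generate_dataset(cfg, d2, overwrite = TRUE)
  tbl <- read_allele_counts(p1$counts)
  expect_equal(n_snps(tbl), 200)
  expect_equal(length(sample_ids(tbl)), 2 * 3 + 4)
  sheet <- read_sample_sheet(p1$samples)
  expect_equal(nrow(season_pairs(sheet)), 3)
  # same seed, same bytes
  for (f in c("allele_counts.tsv", "samples.csv", "weather.csv", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # manifest records the configuration
  man <- jsonlite::read_json(p1$manifest)
  expect_equal(man$config$n_snps, 200)
  expect_equal(man$seed, 31)
  # refuses to clobber without overwrite
  expect_error(generate_dataset(cfg, d1), "not empty")
})

test_that("truth labels are consistent with configured fractions", {
  cfg <- sim_config(n_snps = 4000, frac_seasonal = 0.1, frac_clinal = 0.3,
                    seed = 8)
  sim <- simulate_true_frequencies(cfg)
  expect_equal(mean(sim$truth$is_seasonal), 0.1, tolerance = 0.25)
  expect_equal(mean(sim$truth$is_clinal), 0.3, tolerance = 0.15)
  expect_true(all(sim$truth$effect[sim$truth$is_seasonal] >= 0.04 - 1e-12))
  expect_true(all(sim$truth$effect[sim$truth$is_seasonal] <= 0.08 + 1e-12))
  expect_true(all(sim$truth$effect[!sim$truth$is_seasonal] == 0))
})
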