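## Synthetic pooled-sequencing datasets with planted seasonal and clinal
## structure plus daily weather series, so every downstream stage of the
## pipeline has a truth-known test surface.

#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: 20 paired
#' spring/fall pooled samples of ~75 flies sequenced to ~94x, common SNPs
#' biased toward intermediate frequencies, a subset of SNPs with parallel
#' spring-to-fall shifts of ~4-8%, and latitudinal clinality that can run
#' parallel to the seasonal axis.
#'
#' @param n_snps number of SNPs.
#' @param n_pairs number of spring/fall pairs (default 20).
#' @param n_clinal_pops number of additional spring-only populations along
#'   a latitudinal transect (default 4).
#' @param frac_seasonal fraction of SNPs with a true seasonal shift.
#' @param seasonal_shift per-season allele-frequency change; a length-2
#'   range is drawn per SNP uniformly (default `c(0.04, 0.08)`).
#' @param frac_clinal fraction of SNPs with a true latitudinal cline.
#' @param clinal_parallel_prob probability that a SNP that is both seasonal
#'   and clinal has its fall-favored allele favored at low latitude.
#' @param cline_slope cline steepness, logit units per degree latitude.
#' @param base_freq_law list `list(dist = "uniform", min, max)` or a
#'   `function(n)`; default uniform on `[0.05, 0.95]` (common polymorphisms
#'   skew toward intermediate frequencies).
#' @param n_flies pool size per sample (default 75, male, autosomes).
#' @param depth_law list `list(dist = "poisson", mean = 94)` or
#'   `list(dist = "fixed", depth = ...)` or a `function(n)`.
#' @param reversed_pops integer indices of pairs whose spring/fall shift is
#'   sign-flipped (populations where the seasonal signal runs backwards).
#' @param pair_latitudes,clinal_latitudes population latitudes; defaults
#'   spread the pairs over 25-45 deg N and place the clinal transect at the
#'   four east-coast collection latitudes.
#' @param seed master seed; every stage derives a named sub-stream from it.
#' @export
sim_config <- function(n_snps, n_pairs = 20L, n_clinal_pops = 4L,
                       frac_seasonal = 0, seasonal_shift = c(0.04, 0.08),
                       frac_clinal = 0, clinal_parallel_prob = 0.5,
                       cline_slope = 0.05,
                       base_freq_law = list(dist = "uniform", min = 0.05, max = 0.95),
                       n_flies = 75L,
                       depth_law = list(dist = "poisson", mean = 94),
                       reversed_pops = integer(0),
                       pair_latitudes = NULL, clinal_latitudes = NULL,
                       seed = 1L) {
  stopifnot(n_snps >= 1, n_pairs >= 1, n_clinal_pops >= 0)
  for (fr in c(frac_seasonal, frac_clinal, clinal_parallel_prob))
    if (fr < 0 || fr > 1) stop_invalid("sim_config: fractions must lie in [0,1]")
  if (any(reversed_pops < 1 | reversed_pops > n_pairs))
    stop_invalid("sim_config: reversed_pops out of range")
  if (is.null(pair_latitudes))
    pair_latitudes <- round(seq(25, 45, length.out = n_pairs), 2)
  if (is.null(clinal_latitudes))
    clinal_latitudes <- if (n_clinal_pops > 0)
      round(seq(25.5, 39.9, length.out = n_clinal_pops), 2) else numeric(0)
  stopifnot(length(pair_latitudes) == n_pairs,
            length(clinal_latitudes) == n_clinal_pops)
  structure(list(n_snps = as.integer(n_snps), n_pairs = as.integer(n_pairs),
                 n_clinal_pops = as.integer(n_clinal_pops),
                 frac_seasonal = frac_seasonal, seasonal_shift = seasonal_shift,
                 frac_clinal = frac_clinal,
                 clinal_parallel_prob = clinal_parallel_prob,
                 cline_slope = cline_slope, base_freq_law = base_freq_law,
                 n_flies = as.integer(n_flies), depth_law = depth_law,
                 reversed_pops = as.integer(reversed_pops),
                 pair_latitudes = pair_latitudes,
                 clinal_latitudes = clinal_latitudes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

draw_law <- function(law, n) {
  if (is.function(law)) return(law(n))
  switch(law$dist,
         uniform = runif(n, law$min, law$max),
         poisson = rpois(n, law$mean),
         fixed = rep(law$depth %||% law$mean, n),
         stop_invalid("unknown distribution '%s'", law$dist))
}

#' Simulate true allele frequencies and the ground-truth table
#'
#' Per SNP a base frequency is drawn; clinal SNPs tilt it on the logit
#' scale by `cline_slope * (latitude - mean latitude)`; seasonal SNPs shift
#' additively on the frequency scale from spring to fall, with a direction
#' shared across pairs and sign-flipped in `reversed_pops`. Frequencies are
#' clipped to stay inside `(1/(20 n_flies), 1 - 1/(20 n_flies))` so planted
#' sites remain polymorphic.
#'
#' @param cfg a [sim_config()].
#' @return list with matrices `f_spring`, `f_fall` (SNPs x pairs),
#'   `f_clinal` (SNPs x clinal pops), the `truth` data.frame (per-SNP
#'   `is_seasonal`, `is_clinal`, `effect`, `seasonal_sign`, `clinal_sign`),
#'   `reversed` flags per pair, and `n_clipped`.
#' @export
simulate_true_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_snps
  with_seed(substream_seed(cfg$seed, "true_frequencies"), {
    base <- draw_law(cfg$base_freq_law, n)
    is_seasonal <- runif(n) < cfg$frac_seasonal
    is_clinal <- runif(n) < cfg$frac_clinal
    seasonal_sign <- ifelse(is_seasonal, sign(runif(n) - 0.5), 0)
    seasonal_sign[seasonal_sign == 0 & is_seasonal] <- 1
    effect <- numeric(n)
    if (length(cfg$seasonal_shift) == 2)
      effect[is_seasonal] <- runif(sum(is_seasonal), cfg$seasonal_shift[1],
                                   cfg$seasonal_shift[2])
    else effect[is_seasonal] <- cfg$seasonal_shift
    # clinal direction: parallel means the fall-favored allele is the
    # low-latitude-favored allele, i.e. the latitude slope opposes the
    # seasonal sign
    clinal_sign <- numeric(n)
    both <- is_seasonal & is_clinal
    par <- runif(n) < cfg$clinal_parallel_prob
    clinal_sign[both] <- ifelse(par[both], -seasonal_sign[both], seasonal_sign[both])
    only_c <- is_clinal & !is_seasonal
    clinal_sign[only_c] <- sign(runif(sum(only_c)) - 0.5)
    clinal_sign[only_c & clinal_sign == 0] <- 1

    all_lat <- c(cfg$pair_latitudes, cfg$clinal_latitudes)
    lat0 <- mean(all_lat)
    eps <- 1 / (2 * cfg$n_flies * 10)
    clip <- function(x) pmin(pmax(x, eps), 1 - eps)
    n_clipped <- 0L
    pop_freq <- function(lat) {
      lo <- qlogis(base) + clinal_sign * cfg$cline_slope * (lat - lat0)
      plogis(lo)
    }
    f_spring <- vapply(cfg$pair_latitudes, pop_freq, numeric(n))
    sgn <- matrix(seasonal_sign, n, cfg$n_pairs)
    if (length(cfg$reversed_pops))
      sgn[, cfg$reversed_pops] <- -sgn[, cfg$reversed_pops]
    f_fall <- f_spring + sgn * effect
    n_clipped <- sum(f_fall <= eps | f_fall >= 1 - eps | f_spring <= eps |
                       f_spring >= 1 - eps)
    f_spring <- clip(f_spring); f_fall <- clip(f_fall)
    f_clinal <- if (cfg$n_clinal_pops > 0)
      clip(vapply(cfg$clinal_latitudes, pop_freq, numeric(n)))
    else matrix(numeric(0), n, 0)
    reversed <- seq_len(cfg$n_pairs) %in% cfg$reversed_pops
    list(f_spring = f_spring, f_fall = f_fall, f_clinal = f_clinal,
         truth = data.frame(is_seasonal = is_seasonal, is_clinal = is_clinal,
                            effect = effect, seasonal_sign = seasonal_sign,
                            clinal_sign = clinal_sign),
         reversed = reversed, n_clipped = n_clipped)
  })
}

#' Two-stage binomial pool-seq sampling
#'
#' Stage 1 draws the alternate-allele count among the `2 * n_flies`
#' chromosomes of the pool; stage 2 draws alternate reads among `depth`
#' reads at the realized pool frequency. This is exactly the error model
#' the effective-coverage correction assumes, with read-frequency variance
#' `p(1-p) (1/N + 1/R)`.
#'
#' @param true_freq matrix or vector of true frequencies in `[0, 1]`.
#' @param n_flies pool size.
#' @param depth read depth(s), recycled to the shape of `true_freq`.
#' @param seed optional seed (draws from the current RNG stream if `NULL`).
#' @return list of `ref` and `alt` integer count arrays shaped like
#'   `true_freq`.
#' @export
sample_pool_counts <- function(true_freq, n_flies, depth, seed = NULL) {
  if (any(true_freq < 0 | true_freq > 1, na.rm = TRUE))
    stop_invalid("sample_pool_counts: frequencies outside [0,1]")
  draw <- function() {
    nchr <- pool_chromosomes(n_flies)
    k <- rbinom(length(true_freq), nchr, as.vector(true_freq))
    alt <- rbinom(length(true_freq), as.vector(depth + 0 * true_freq), k / nchr)
    ref <- as.vector(depth + 0 * true_freq) - alt
    dim(alt) <- dim(ref) <- dim(true_freq)
    list(ref = ref, alt = alt)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Weather-simulation specification
#'
#' One row per population: collection dates and the exact number of
#' threshold-exceeding days to plant in the 14-day windows strictly before
#' each collection (hot days with Tmax above `gen_upper` before spring,
#' cold days with Tmin below `gen_lower` before fall).
#'
#' @param localities character vector of locality names.
#' @param latitudes,longitudes station coordinates.
#' @param spring_dates,fall_dates collection dates.
#' @param n_hot_spring_days,n_cold_fall_days planted exceedance counts,
#'   each at most `window_days`.
#' @param gen_upper,gen_lower generating thermal limits in deg C (defaults
#'   32 and 5).
#' @param window_days pre-collection window length (default 14).
#' @export
sim_weather_spec <- function(localities, latitudes, longitudes,
                             spring_dates, fall_dates,
                             n_hot_spring_days, n_cold_fall_days,
                             gen_upper = 32, gen_lower = 5, window_days = 14L) {
  np <- length(localities)
  if (any(n_hot_spring_days > window_days) || any(n_cold_fall_days > window_days))
    stop_invalid("sim_weather_spec: requested exceedance count exceeds the %d-day window",
                 window_days)
  if (any(n_hot_spring_days < 0) || any(n_cold_fall_days < 0))
    stop_invalid("sim_weather_spec: negative exceedance count")
  structure(list(pops = data.frame(locality = localities,
                                   station_id = paste0("ST_", localities),
                                   latitude = latitudes, longitude = longitudes,
                                   spring_date = as.Date(spring_dates),
                                   fall_date = as.Date(fall_dates),
                                   n_hot_spring_days = as.integer(n_hot_spring_days),
                                   n_cold_fall_days = as.integer(n_cold_fall_days),
                                   stringsAsFactors = FALSE),
                 gen_upper = gen_upper, gen_lower = gen_lower,
                 window_days = as.integer(window_days)),
            class = "sim_weather_spec")
}

#' Simulate daily weather series with planted threshold exceedances
#'
#' Daily Tmin/Tmax follow a seasonal sinusoid plus noise; inside the 14-day
#' pre-collection windows, exactly the requested number of days exceed the
#' generating limits (with a margin of at least 0.3 deg C on either side of
#' the limit so that exceedance counts are stable in a small neighbourhood
#' of the generating limit). Tmin <= Tmax always holds.
#'
#' @param spec a [sim_weather_spec()].
#' @param seed integer seed.
#' @return list with `weather` (daily data.frame: `station_id`, `date`,
#'   `tmin_c`, `tmax_c`) and `stations` (`station_id`, `latitude`,
#'   `longitude`).
#' @export
simulate_weather <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sim_weather_spec"))
  wd <- spec$window_days
  with_seed(substream_seed(seed, "weather"), {
    rows <- lapply(seq_len(nrow(spec$pops)), function(i) {
      p <- spec$pops[i, ]
      dates <- seq(p$spring_date - 30, p$fall_date + 5, by = "day")
      doy <- as.integer(format(dates, "%j"))
      tmean <- 12 + 12 * sin(2 * pi * (doy - 105) / 365) + rnorm(length(dates), 0, 2)
      tmax <- tmean + runif(length(dates), 4, 8)
      tmin <- tmean - runif(length(dates), 4, 8)

      spring_win <- dates >= p$spring_date - wd & dates <= p$spring_date - 1
      fall_win <- dates >= p$fall_date - wd & dates <= p$fall_date - 1
      iw <- which(spring_win)
      hot <- sample(iw, p$n_hot_spring_days)
      tmax[hot] <- spec$gen_upper + runif(length(hot), 0.3, 6)
      cooler <- setdiff(iw, hot)
      tmax[cooler] <- spec$gen_upper - runif(length(cooler), 0.3, 8)
      tmin[iw] <- tmax[iw] - runif(length(iw), 5, 15)

      iw <- which(fall_win)
      cold <- sample(iw, p$n_cold_fall_days)
      tmin[cold] <- spec$gen_lower - runif(length(cold), 0.3, 6)
      milder <- setdiff(iw, cold)
      tmin[milder] <- spec$gen_lower + runif(length(milder), 0.3, 8)
      tmax[iw] <- tmin[iw] + runif(length(iw), 5, 15)

      data.frame(station_id = p$station_id, date = dates,
                 tmin_c = round(pmin(tmin, tmax), 1),
                 tmax_c = round(pmax(tmin, tmax), 1))
    })
    list(weather = do.call(rbind, rows),
         stations = data.frame(station_id = spec$pops$station_id,
                               latitude = spec$pops$latitude,
                               longitude = spec$pops$longitude))
  })
}

default_weather_spec <- function(cfg) {
  np <- cfg$n_pairs
  # reversed populations experience hot pre-spring and cold pre-fall windows
  hot <- ifelse(seq_len(np) %in% cfg$reversed_pops,
                10L + (seq_len(np) %% 4L), seq_len(np) %% 4L)
  cold <- ifelse(seq_len(np) %in% cfg$reversed_pops,
                 9L + (seq_len(np) %% 5L), (seq_len(np) + 2L) %% 4L)
  sim_weather_spec(localities = sprintf("loc%02d", seq_len(np)),
                   latitudes = cfg$pair_latitudes,
                   longitudes = round(-70 - seq_len(np) * 0.7, 2),
                   spring_dates = as.Date("2012-06-15") + (seq_len(np) %% 5) * 3,
                   fall_dates = as.Date("2012-10-15") + (seq_len(np) %% 5) * 3,
                   n_hot_spring_days = hot, n_cold_fall_days = cold)
}

sim_chrom_lengths <- c("2L" = 23011544, "2R" = 21146708,
                       "3L" = 24543557, "3R" = 27905053)

sim_positions <- function(n_snps) {
  lens <- sim_chrom_lengths
  n_per <- floor(n_snps * lens / sum(lens))
  n_per[1] <- n_per[1] + n_snps - sum(n_per)
  out <- lapply(names(lens), function(ch) {
    pos <- sort(sample.int(lens[[ch]] - 2L, n_per[[ch]])) + 1L
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

sim_recomb_map <- function(win = 1e6L) {
  out <- lapply(names(sim_chrom_lengths), function(ch) {
    len <- sim_chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = win)
    ends <- pmin(starts + win, len)
    # centromere-proximal windows get ~0 rates, arm middles 2-4 cM/Mb
    x <- seq_along(starts) / length(starts)
    rate <- round(pmax(0, 4 * sin(pi * x)^2 - 0.3), 2)
    data.frame(chrom = ch, start = starts, end = ends, rate = rate)
  })
  recomb_map(do.call(rbind, out))
}

#' Simulate a complete dataset in memory
#'
#' Draws true frequencies, applies two-stage pool-seq sampling with the
#' configured depth law, and assembles the [snp_table()], [sample_sheet()]
#' and ground-truth table. The sheet holds `2 * n_pairs` seasonal samples
#' plus `n_clinal_pops` spring-only clinal samples (season blank, `role =
#' "clinal"`) at distinct localities.
#'
#' @param cfg a [sim_config()].
#' @param weather_spec optional [sim_weather_spec()] used for collection
#'   dates; defaults to [generate_dataset()]'s convention (reversed pairs
#'   get hot pre-spring / cold pre-fall windows).
#' @return list `table`, `sheet`, `truth` (with coordinates), `reversed`,
#'   `weather_spec`.
#' @export
simulate_snp_table <- function(cfg, weather_spec = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(weather_spec)) weather_spec <- default_weather_spec(cfg)
  sim <- simulate_true_frequencies(cfg)
  tf <- cbind(sim$f_spring, sim$f_fall, sim$f_clinal)
  depth <- with_seed(substream_seed(cfg$seed, "depth"), {
    matrix(pmax(draw_law(cfg$depth_law, length(tf)), 1), nrow(tf), ncol(tf))
  })
  cnt <- sample_pool_counts(tf, cfg$n_flies, depth,
                            seed = substream_seed(cfg$seed, "pool_counts"))
  np <- cfg$n_pairs
  ids <- c(sprintf("loc%02d_spring", seq_len(np)), sprintf("loc%02d_fall", seq_len(np)),
           if (cfg$n_clinal_pops > 0) sprintf("clin%02d_spring", seq_len(cfg$n_clinal_pops)))
  colnames(cnt$ref) <- colnames(cnt$alt) <- ids
  coords <- with_seed(substream_seed(cfg$seed, "positions"), sim_positions(cfg$n_snps))
  alleles <- with_seed(substream_seed(cfg$seed, "alleles"), {
    nuc <- c("A", "T", "C", "G")
    ref <- sample(nuc, cfg$n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nuc, r), 1), character(1))
    data.frame(ref_allele = ref, alt_allele = unname(alt))
  })
  tbl <- snp_table(cbind(coords, alleles), cnt$ref, cnt$alt)
  wsp <- weather_spec$pops
  sheet <- sample_sheet(data.frame(
    sample_id = ids,
    locality = c(rep(wsp$locality[seq_len(np)], 2),
                 if (cfg$n_clinal_pops > 0) sprintf("clinloc%02d", seq_len(cfg$n_clinal_pops))),
    latitude = c(rep(cfg$pair_latitudes, 2), cfg$clinal_latitudes),
    longitude = c(rep(wsp$longitude[seq_len(np)], 2),
                  if (cfg$n_clinal_pops > 0) round(-75 - seq_len(cfg$n_clinal_pops) * 0.5, 2)),
    season = c(rep("spring", np), rep("fall", np),
               rep(NA_character_, cfg$n_clinal_pops)),
    year = 2012L,
    collection_date = as.character(c(wsp$spring_date[seq_len(np)],
                                     wsp$fall_date[seq_len(np)],
                                     rep(as.Date("2012-06-15"), cfg$n_clinal_pops))),
    n_flies = cfg$n_flies,
    stringsAsFactors = FALSE))
  sheet$role <- c(rep("seasonal", 2 * np), rep("clinal", cfg$n_clinal_pops))
  list(table = tbl, sheet = sheet,
       truth = cbind(coords, sim$truth),
       reversed = data.frame(pair = seq_len(np),
                             locality = wsp$locality[seq_len(np)],
                             reversed = sim$reversed),
       n_clipped = sim$n_clipped,
       weather_spec = weather_spec)
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes allele counts, sample sheet, weather and station tables, a
#' recombination map, a repeats BED, the ground-truth table and a JSON
#' manifest recording the full configuration and seed, so that every
#' downstream module can run on the directory with no other inputs. The
#' sample sheet contains `2 * n_pairs` seasonal samples plus
#' `n_clinal_pops` spring-only samples (season left blank, `role =
#' "clinal"`) at distinct localities.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @param weather_spec optional [sim_weather_spec()]; by default reversed
#'   populations get hot pre-spring and cold pre-fall windows.
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, the list of file paths.
#' @export
generate_dataset <- function(cfg, out_dir, weather_spec = NULL,
                             overwrite = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop_invalid("generate_dataset: '%s' is not empty (use overwrite = TRUE)", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_snp_table(cfg, weather_spec)
  weather_spec <- ds$weather_spec
  wx <- simulate_weather(weather_spec, seed = substream_seed(cfg$seed, "weather_master"))

  paths <- list(counts = file.path(out_dir, "allele_counts.tsv"),
                samples = file.path(out_dir, "samples.csv"),
                weather = file.path(out_dir, "weather.csv"),
                stations = file.path(out_dir, "stations.csv"),
                recomb = file.path(out_dir, "recomb_map.csv"),
                repeats = file.path(out_dir, "repeats.bed"),
                truth = file.path(out_dir, "truth.tsv"),
                reversed = file.path(out_dir, "reversed_pairs.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_allele_counts(ds$table, paths$counts)
  write_sample_sheet(ds$sheet, paths$samples)
  write_weather(wx$weather, paths$weather)
  write_vc(wx$stations, paths$stations, "stations")
  write_recomb_map(sim_recomb_map(), paths$recomb)
  rep_iv <- data.frame(chrom = "2L", start = c(0L, 5000000L), end = c(20000L, 5050000L))
  write_regions(region_set(rep_iv, "repeats"), paths$repeats)
  write_vc(ds$truth, paths$truth, "truth-table", sep = "\t")
  write_vc(ds$reversed, paths$reversed, "reversed-pairs", sep = "\t")
  manifest <- list(package = "seasonscan",
                   version = as.character(utils::packageVersion("seasonscan")),
                   seed = cfg$seed,
                   config = unclass(cfg),
                   n_clipped = ds$n_clipped,
                   files = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}
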