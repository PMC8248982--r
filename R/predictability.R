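## Leave-one-out predictability analysis, predictability scores, and
## environmental models including the thermal-limit grid scan.

#' Leave-one-out seasonal predictability
#'
#' For each spring/fall pair in turn: the seasonal GLM is refitted on the
#' remaining pairs, the held-out pair gets a single-pair exact test
#' (two-sided, at effective coverage), and for each joint quantile the
#' fraction of SNPs in the top of both tests whose direction of change
#' agrees is recorded. The per-pair concordance curve is summarized by
#' [predictability_score()].
#'
#' @inheritParams glm_seasonal
#' @param quantiles joint quantile grid.
#' @return data.frame with one row per held-out pair: `pair_id`, `score`,
#'   `slope` (raw slope of the stated concordance-on-quantile binomial
#'   regression), plus a `curves` attribute (list of per-pair concordance
#'   data.frames).
#' @export
leave_one_out <- function(table, sheet, pairs = NULL,
                          quantiles = default_quantile_grid()) {
  sheet <- as_sample_sheet(sheet)
  if (is.null(pairs)) pairs <- season_pairs(sheet)
  if (nrow(pairs) < 3) stop_invalid("leave_one_out: need >= 3 pairs")
  m <- season_matrices(table, sheet, pairs)
  nchr <- pool_chromosomes(sheet$n_flies[match(pairs$spring_id, sheet$sample_id)])
  curves <- vector("list", nrow(pairs))
  scores <- data.frame(pair_id = pairs$pair_id, score = NA_real_,
                       slope = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(pairs))) {
    rest <- fit_season_glm(m$ys[, -j, drop = FALSE], m$yf[, -j, drop = FALSE],
                           m$ws[, -j, drop = FALSE], m$wf[, -j, drop = FALSE])
    single <- fisher_pair(table$ref_count[, pairs$spring_id[j]],
                          table$alt_count[, pairs$spring_id[j]],
                          table$ref_count[, pairs$fall_id[j]],
                          table$alt_count[, pairs$fall_id[j]], nchr[j])
    keep <- !is.na(rest$p) & !is.na(single$p_two)
    cur <- do.call(rbind, lapply(quantiles, function(q) {
      thr_g <- quantile(rest$p[keep], q, na.rm = TRUE, names = FALSE)
      thr_f <- quantile(single$p_two[keep], q, na.rm = TRUE, names = FALSE)
      idx <- which(keep & rest$p <= thr_g & single$p_two <= thr_f)
      agree <- sign(rest$coef[idx]) == single$sign[idx]
      agree[sign(rest$coef[idx]) == 0 | single$sign[idx] == 0] <- NA
      k <- sum(agree, na.rm = TRUE); n <- sum(!is.na(agree))
      data.frame(q = q, n = n, n_concordant = k,
                 concordance = if (n > 0) k / n else NA_real_)
    }))
    curves[[j]] <- cur
    sc <- predictability_score(cur)
    scores$score[j] <- sc$score
    scores$slope[j] <- sc$slope
  }
  attr(scores, "curves") <- setNames(curves, pairs$pair_id)
  scores
}

#' Predictability score of a concordance curve
#'
#' Fits the binomial-error regression of concordant counts on the
#' quantile threshold, weighted by the number of SNPs below each
#' threshold, and returns its raw slope together with the reported score:
#' the log-odds of the SNP-weighted mean concordance. The score is
#' positive exactly when the concordance rate exceeds 50% over the bulk
#' of the genome (the weights concentrate on the loosest thresholds,
#' where most SNPs reside), zero for a flat 50% curve, and antisymmetric
#' under mirroring the curve about 50%.
#'
#' @param curve data.frame with columns `q`, `n`, `n_concordant` (or
#'   `concordance`).
#' @return list `score`, `slope`, `intercept`, `mean_concordance`.
#' @export
predictability_score <- function(curve) {
  if (nrow(curve) < 3) stop_invalid("predictability_score: need >= 3 quantile points")
  if (is.null(curve$n_concordant))
    curve$n_concordant <- round(curve$concordance * curve$n)
  cur <- curve[curve$n > 0 & !is.na(curve$n_concordant), , drop = FALSE]
  if (nrow(cur) == 0 || sum(cur$n) == 0)
    stop_invalid("predictability_score: degenerate curve (no SNPs at any threshold)")
  fit <- suppressWarnings(
    glm(cbind(n_concordant, n - n_concordant) ~ q, family = binomial(),
        data = cur))
  cf <- coef(fit)
  mean_conc <- sum(cur$n_concordant) / sum(cur$n)
  ntot <- sum(cur$n)
  mean_conc <- min(max(mean_conc, 1 / (ntot + 1)), ntot / (ntot + 1))
  list(score = qlogis(mean_conc), slope = unname(cf["q"]),
       intercept = unname(cf["(Intercept)"]), mean_concordance = mean_conc)
}

#' Threshold-exceedance day counts before a collection
#'
#' Counts days in the 14 calendar days strictly before the collection
#' date with maximum temperature above the upper limit (spring mode) or
#' minimum temperature below the lower limit (fall mode).
#'
#' @param weather daily weather data.frame ([read_weather()] layout).
#' @param station_id station to use.
#' @param collection_date collection date.
#' @param season `"spring"` or `"fall"`.
#' @param upper,lower thermal limits in deg C.
#' @param window_days window length (default 14).
#' @return integer count with attribute `n_missing` (days of the window
#'   absent from the series); `NA` if the whole window is missing.
#' @export
thermal_days <- function(weather, station_id, collection_date,
                         season = c("spring", "fall"), upper = 32, lower = 5,
                         window_days = 14L) {
  season <- match.arg(season)
  collection_date <- as.Date(collection_date)
  win <- weather[weather$station_id == station_id &
                   weather$date >= collection_date - window_days &
                   weather$date <= collection_date - 1, , drop = FALSE]
  n_missing <- window_days - nrow(win)
  if (nrow(win) == 0) {
    out <- NA_integer_
  } else if (season == "spring") {
    out <- sum(win$tmax_c > upper, na.rm = TRUE)
  } else {
    out <- sum(win$tmin_c < lower, na.rm = TRUE)
  }
  attr(out, "n_missing") <- n_missing
  out
}

#' Cumulative growing degree-days
#'
#' Simple-average method with lower and upper clamps: each day contributes
#' `max(0, min((Tmin + Tmax)/2, upper_cutoff) - base_temp)`. Defaults
#' follow a drosophilid development model (base 10 deg C, cutoff 31 deg C).
#' Missing days are skipped and counted.
#'
#' @param weather daily weather data.frame.
#' @param station_id station to use.
#' @param start_date,end_date inclusive date range.
#' @param base_temp,upper_cutoff clamps in deg C.
#' @return degree-days (deg C day) with attribute `n_missing`.
#' @export
degree_days <- function(weather, station_id, start_date, end_date,
                        base_temp = 10, upper_cutoff = 31) {
  d <- weather[weather$station_id == station_id &
                 weather$date >= as.Date(start_date) &
                 weather$date <= as.Date(end_date), , drop = FALSE]
  ok <- !is.na(d$tmin_c) & !is.na(d$tmax_c)
  contrib <- pmax(0, pmin((d$tmin_c[ok] + d$tmax_c[ok]) / 2, upper_cutoff) - base_temp)
  n_days <- as.integer(as.Date(end_date) - as.Date(start_date)) + 1L
  out <- sum(contrib)
  attr(out, "n_missing") <- n_days - sum(ok)
  out
}

#' Nearest weather station by great-circle distance
#'
#' @param sample_coords data.frame `latitude`, `longitude` (one row per
#'   locality).
#' @param stations data.frame `station_id`, `latitude`, `longitude`.
#' @return data.frame `station_id`, `distance_km`.
#' @export
nearest_station <- function(sample_coords, stations) {
  if (nrow(stations) == 0) stop_invalid("nearest_station: no stations")
  out <- lapply(seq_len(nrow(sample_coords)), function(i) {
    d <- geosphere::distHaversine(
      c(sample_coords$longitude[i], sample_coords$latitude[i]),
      cbind(stations$longitude, stations$latitude), r = 6371000)
    j <- which.min(d)
    data.frame(station_id = stations$station_id[j], distance_km = d[j] / 1000)
  })
  do.call(rbind, out)
}

## Closed-form R^2 of y ~ x1 + x2 over all (upper, lower) grid cells:
## with row-centered count matrices X1 (limits x pops) and X2, every
## cross-product the 2-covariate OLS needs is a matrix product, so the
## whole grid costs one X1 %*% t(X2).
r2_grid <- function(X1c, X2c, yc) {
  S11 <- rowSums(X1c^2); S22 <- rowSums(X2c^2)
  S12 <- X1c %*% t(X2c)
  A <- drop(X1c %*% yc); B <- drop(X2c %*% yc)
  Syy <- sum(yc^2)
  det_ <- outer(S11, S22) - S12^2
  num <- outer(A^2, S22) - 2 * S12 * outer(A, B) + outer(S11, B^2)
  r2 <- num / (det_ * Syy)
  r2[det_ <= 1e-12 * outer(S11, S22) | outer(S11, S22) == 0] <- NA_real_
  if (Syy == 0) r2[] <- NA_real_
  r2
}

count_exceed <- function(temps_by_pop, limits, above = TRUE) {
  # limits x pops matrix of exceedance counts
  vapply(temps_by_pop, function(t)
    if (above) vapply(limits, function(u) sum(t > u), numeric(1))
    else vapply(limits, function(l) sum(t < l), numeric(1)),
    numeric(length(limits)))
}

thermal_design <- function(weather, pops, window_days = 14L) {
  spring_t <- lapply(seq_len(nrow(pops)), function(i) {
    d <- pops$spring_date[i]
    w <- weather[weather$station_id == pops$station_id[i] &
                   weather$date >= d - window_days & weather$date <= d - 1, ]
    w$tmax_c
  })
  fall_t <- lapply(seq_len(nrow(pops)), function(i) {
    d <- pops$fall_date[i]
    w <- weather[weather$station_id == pops$station_id[i] &
                   weather$date >= d - window_days & weather$date <= d - 1, ]
    w$tmin_c
  })
  list(spring_tmax = spring_t, fall_tmin = fall_t)
}

#' Thermal-limit grid scan
#'
#' Regresses per-population predictability scores on the number of
#' pre-spring days with Tmax above an upper limit (`x1`) and pre-fall days
#' with Tmin below a lower limit (`x2`), for every pair of limits on a
#' grid (default -5 to 40 deg C in 0.1 deg C steps, 451 x 451 models), and
#' reports the fit maximizing R^2. Grid cells where either count is
#' constant across populations are skipped. Ties on R^2 are broken toward
#' the smallest `upper - lower` gap.
#'
#' @param scores data.frame with `locality`, `score`, `station_id`,
#'   `spring_date`, `fall_date` (one row per population).
#' @param weather daily weather data.frame covering the windows.
#' @param limits_range `c(min, max)` limits in deg C.
#' @param step grid step in deg C.
#' @param window_days pre-collection window (default 14).
#' @return list with `best` (data.frame: `upper`, `lower`, `r2`,
#'   `coef_x1`, `coef_x2`, `intercept`), `grid` (R^2 matrix, uppers x
#'   lowers), `uppers`, `lowers`, and the design at the best limits.
#' @export
thermal_scan <- function(scores, weather, limits_range = c(-5, 40), step = 0.1,
                         window_days = 14L) {
  if (nrow(scores) < 5)
    stop_invalid("thermal_scan: need >= 5 populations with scores and weather")
  scores$spring_date <- as.Date(scores$spring_date)
  scores$fall_date <- as.Date(scores$fall_date)
  des <- thermal_design(weather, scores, window_days)
  limits <- seq(limits_range[1], limits_range[2], by = step)
  X1 <- count_exceed(des$spring_tmax, limits, above = TRUE)
  X2 <- count_exceed(des$fall_tmin, limits, above = FALSE)
  y <- scores$score
  yc <- y - mean(y)
  r2 <- r2_grid(X1 - rowMeans(X1), X2 - rowMeans(X2), yc)
  if (all(is.na(r2))) stop_invalid("thermal_scan: no grid cell is estimable")
  best_r2 <- max(r2, na.rm = TRUE)
  cand <- which(r2 >= best_r2 - 1e-12, arr.ind = TRUE)
  gap <- limits[cand[, 1]] - limits[cand[, 2]]
  pick <- cand[which.min(gap), ]
  upper <- limits[pick[1]]; lower <- limits[pick[2]]
  x1 <- X1[pick[1], ]; x2 <- X2[pick[2], ]
  fit <- lm(y ~ x1 + x2)
  list(best = data.frame(upper = upper, lower = lower, r2 = best_r2,
                         intercept = coef(fit)[[1]], coef_x1 = coef(fit)[[2]],
                         coef_x2 = coef(fit)[[3]], n_ties = nrow(cand)),
       grid = r2, uppers = limits, lowers = limits,
       x1 = x1, x2 = x2)
}

#' Permutation p-value for the thermal-scan maximum R^2
#'
#' Permutes the score vector across populations and recomputes the
#' max-over-grid R^2 for each permutation. The null scan runs on a
#' coarsened grid (default 1 deg C) -- the maximum is insensitive to the
#' 0.1 deg C refinement and the coarse grid keeps 25,000 scans cheap; set
#' `coarse_step = step` for the full-grid null.
#'
#' @inheritParams thermal_scan
#' @param n_perms number of permutations (default 25000).
#' @param coarse_step grid step for the permutation scans.
#' @param seed integer seed.
#' @return list `p` (add-one permutation p for the observed max R^2),
#'   `observed_r2`, `null_max_r2` (vector, one per permutation), `scan`
#'   (the observed full-grid scan).
#' @export
thermal_scan_perm <- function(scores, weather, limits_range = c(-5, 40),
                              step = 0.1, coarse_step = 1, n_perms = 25000L,
                              seed = 1L, window_days = 14L) {
  if (n_perms < 100) warning("thermal_scan_perm: fewer than 100 permutations")
  scan <- thermal_scan(scores, weather, limits_range, step, window_days)
  des <- thermal_design(weather,
                        transform(scores, spring_date = as.Date(spring_date),
                                  fall_date = as.Date(fall_date)),
                        window_days)
  limits <- seq(limits_range[1], limits_range[2], by = coarse_step)
  X1 <- count_exceed(des$spring_tmax, limits, above = TRUE)
  X2 <- count_exceed(des$fall_tmin, limits, above = FALSE)
  X1c <- X1 - rowMeans(X1); X2c <- X2 - rowMeans(X2)
  y <- scores$score
  P <- length(y)
  Yp <- with_seed(substream_seed(seed, "thermal_perm"), {
    vapply(seq_len(n_perms), function(i) y[sample.int(P)], numeric(P))
  })
  Yc <- Yp - matrix(colMeans(Yp), P, n_perms, byrow = TRUE)
  Syy <- colSums(Yc^2)
  S11 <- rowSums(X1c^2); S22 <- rowSums(X2c^2)
  S12 <- X1c %*% t(X2c)
  A <- X1c %*% Yc               # uppers x perms
  B <- X2c %*% Yc               # lowers x perms
  max_r2 <- rep(-Inf, n_perms)
  for (u in seq_along(S11)) {
    if (S11[u] == 0) next
    det_ <- S11[u] * S22 - S12[u, ]^2          # by lower
    ok <- det_ > 1e-12 * S11[u] * pmax(S22, 1e-300) & S22 > 0
    if (!any(ok)) next
    Au <- matrix(A[u, ], sum(ok), n_perms, byrow = TRUE)
    num <- S22[ok] * Au^2 - 2 * S12[u, ok] * Au * B[ok, , drop = FALSE] +
      S11[u] * B[ok, , drop = FALSE]^2
    r2u <- num / (det_[ok] * matrix(Syy, sum(ok), n_perms, byrow = TRUE))
    mx <- apply(r2u, 2, max)
    max_r2 <- pmax(max_r2, mx)
  }
  obs <- scan$best$r2
  list(p = (1 + sum(max_r2 >= obs)) / (1 + n_perms),
       observed_r2 = obs, null_max_r2 = max_r2, scan = scan)
}

#' Permutation p-value for the R^2 of a fixed regression design
#'
#' Shuffles the response across populations and recomputes R^2 against the
#' same design matrix; p-values use the add-one estimator.
#'
#' @param y response vector (predictability scores).
#' @param X design matrix or data.frame of covariates (no intercept
#'   column; factors are expanded).
#' @param n_perms number of permutations.
#' @param seed integer seed.
#' @return list `r2`, `p`, `null_r2`.
#' @export
permutation_r2 <- function(y, X, n_perms = 25000L, seed = 1L) {
  if (n_perms < 100) warning("permutation_r2: fewer than 100 permutations")
  X <- as.data.frame(X)
  mm <- model.matrix(~ ., data = X)
  keep <- complete.cases(mm) & !is.na(y)
  mm <- mm[keep, , drop = FALSE]; yk <- y[keep]
  n <- length(yk)
  qr_ <- qr(mm)
  fit_r2 <- function(v) {
    vc <- v - mean(v)
    res <- qr.resid(qr_, v)
    1 - sum(res^2) / sum(vc^2)
  }
  obs <- fit_r2(yk)
  null_r2 <- with_seed(substream_seed(seed, "permutation_r2"), {
    vapply(seq_len(n_perms), function(i) fit_r2(yk[sample.int(n)]), numeric(1))
  })
  list(r2 = obs, p = (1 + sum(null_r2 >= obs)) / (1 + n_perms), null_r2 = null_r2)
}

#' Environmental models of predictability scores
#'
#' Regresses per-population predictability scores on each candidate
#' covariate set (univariate or small multivariate models), records R^2
#' and a permutation p-value, and adjusts across models by
#' Benjamini-Hochberg. Categorical covariates with a single level are
#' skipped.
#'
#' @param scores numeric vector, one per population.
#' @param covariates data.frame of per-population covariates.
#' @param models named list of character vectors of covariate names;
#'   default: one univariate model per covariate.
#' @param n_perms permutations per model.
#' @param seed integer seed.
#' @return data.frame `model`, `r2`, `p_perm`, `fdr`.
#' @export
env_models <- function(scores, covariates, models = NULL, n_perms = 1000L,
                       seed = 1L) {
  covariates <- as.data.frame(covariates)
  if (is.null(models))
    models <- setNames(as.list(names(covariates)), names(covariates))
  rows <- lapply(names(models), function(nm) {
    vars <- models[[nm]]
    X <- covariates[, vars, drop = FALSE]
    drop_ <- vapply(X, function(v) !is.numeric(v) &&
                      length(unique(v[!is.na(v)])) < 2, logical(1))
    if (any(drop_)) return(NULL)
    pr <- permutation_r2(scores, X, n_perms = n_perms,
                         seed = substream_seed(seed, nm))
    data.frame(model = nm, r2 = pr$r2, p_perm = pr$p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_invalid("env_models: no estimable model")
  out$fdr <- p.adjust(out$p_perm, method = "BH")
  rownames(out) <- NULL
  out
}
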