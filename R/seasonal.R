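## Per-SNP seasonal statistics: the weighted binomial GLM, the per-pair
## exact tests feeding the rank-normalized Fisher's-method (RFM) statistic,
## within-pair label permutations, and quantile-enrichment summaries.

season_matrices <- function(table, sheet, pairs = NULL) {
  sheet <- as_sample_sheet(sheet)
  if (is.null(pairs)) pairs <- season_pairs(sheet)
  ids <- sample_ids(table)
  missing <- setdiff(c(pairs$spring_id, pairs$fall_id), ids)
  if (length(missing))
    stop_invalid("season samples absent from the SNP table: %s",
                 paste(missing, collapse = ", "))
  f <- snp_freq(table)
  nc <- snp_nc(table, sheet)
  list(pairs = pairs,
       ys = f[, pairs$spring_id, drop = FALSE],
       yf = f[, pairs$fall_id, drop = FALSE],
       ws = nc[, pairs$spring_id, drop = FALSE],
       wf = nc[, pairs$fall_id, drop = FALSE])
}

#' Seasonal GLM scan
#'
#' Regresses per-SNP alternate-allele frequency on season (spring = 0,
#' fall = 1) plus an unordered population factor, with binomial error and
#' effective-coverage weights, across every SNP of the table. The p-value
#' is the two-sided Wald test of the season term.
#'
#' @param table a [snp_table()].
#' @param sheet a [sample_sheet()].
#' @param pairs optional pair table from [season_pairs()]; defaults to all
#'   resolvable pairs in the sheet.
#' @param flips optional logical vector of within-pair label swaps (used by
#'   the permutation machinery).
#' @param nc_scale multiplier on the effective-coverage weights — a
#'   sensitivity hook for misestimated allele-frequency precision.
#' @return data.frame with `chrom`, `pos`, `glm_coef`, `glm_se`, `glm_p`,
#'   `glm_sign`, plus a `pair_sign` attribute (SNPs x pairs matrix of
#'   -1/0/+1 per-pair frequency-change signs) and a `pairs` attribute.
#' @export
glm_seasonal <- function(table, sheet, pairs = NULL, flips = NULL,
                         nc_scale = 1) {
  m <- season_matrices(table, sheet, pairs)
  if (nrow(m$pairs) < 2)
    stop_invalid("glm_seasonal: need at least 2 spring/fall pairs")
  fit <- fit_season_glm(m$ys, m$yf, nc_scale * m$ws, nc_scale * m$wf,
                        flips = flips)
  out <- data.frame(chrom = table$snps$chrom, pos = table$snps$pos,
                    glm_coef = fit$coef, glm_se = fit$se, glm_p = fit$p,
                    glm_sign = sign(fit$coef), stringsAsFactors = FALSE)
  ps <- sign(m$yf - m$ys)
  colnames(ps) <- m$pairs$pair_id
  attr(out, "pair_sign") <- ps
  attr(out, "pairs") <- m$pairs
  out
}

#' Within-pair label permutation plan
#'
#' Each permutation independently flips the spring/fall labels of each pair
#' with probability 1/2 (the identity assignment is allowed), never moving
#' labels across pairs.
#'
#' @param pairs pair table from [season_pairs()] (or an integer number of
#'   pairs).
#' @param n_perms number of permutations.
#' @param seed integer seed; the plan is reproducible from it.
#' @return logical matrix `n_perms x n_pairs`.
#' @export
permute_plan <- function(pairs, n_perms, seed) {
  np <- if (is.data.frame(pairs)) nrow(pairs) else as.integer(pairs)
  if (n_perms < 1) stop_invalid("permute_plan: n_perms must be >= 1")
  with_seed(substream_seed(seed, "permute_plan"), {
    matrix(runif(n_perms * np) < 0.5, n_perms, np)
  })
}

#' Per-pair exact test of spring/fall differentiation at effective coverage
#'
#' Read counts are rescaled to the effective coverage (`alt' =
#' round(freq * Nc)`, `ref' = round(Nc) - alt'`) so that the exact test sees
#' the binomial sample size implied by both sampling stages, then one-sided
#' Fisher exact p-values (hypergeometric tails of the 2x2 table) are
#' computed for an alternate-allele increase (`p_up`) and decrease
#' (`p_down`) from spring to fall. Vectorized over SNPs.
#'
#' @param spring_ref,spring_alt,fall_ref,fall_alt read-count vectors.
#' @param n_chromosomes chromosomes in the pool (scalar or vector).
#' @param nc_scale multiplier applied to the effective coverage before
#'   rescaling — a sensitivity hook for asking how results react when
#'   allele-frequency precision is misestimated (1 = the Nc model).
#' @return data.frame `p_up`, `p_down`, `p_two` (two-sided as twice the
#'   smaller tail, capped at 1), `sign` of the frequency change; `NA` where
#'   a season has zero reads.
#' @export
fisher_pair <- function(spring_ref, spring_alt, fall_ref, fall_alt,
                        n_chromosomes, nc_scale = 1) {
  rs <- spring_ref + spring_alt
  rf <- fall_ref + fall_alt
  ok <- rs > 0 & rf > 0
  fs <- ifelse(ok, spring_alt / rs, NA_real_)
  ff <- ifelse(ok, fall_alt / rf, NA_real_)
  ncs <- ifelse(ok, nc_scale * effective_coverage(n_chromosomes, pmax(rs, 1)),
                NA_real_)
  ncf <- ifelse(ok, nc_scale * effective_coverage(n_chromosomes, pmax(rf, 1)),
                NA_real_)
  as_ <- round(fs * ncs); rs_ <- round(ncs) - as_
  af_ <- round(ff * ncf); rf_ <- round(ncf) - af_
  m <- as_ + af_          # total alt
  n <- rs_ + rf_          # total ref
  k <- af_ + rf_          # fall draws
  p_up <- phyper(af_ - 1, m, n, k, lower.tail = FALSE)
  p_down <- phyper(af_, m, n, k, lower.tail = TRUE)
  data.frame(p_up = p_up, p_down = p_down,
             p_two = pmin(1, 2 * pmin(p_up, p_down)),
             sign = sign(ff - fs))
}

#' Rank-normalize p-values within read-count classes
#'
#' Exact-test p-values from pooled data are granular and depend on the
#' read-count configuration. Grouping SNPs into classes of similar total
#' and alternate read counts (summed spring + fall) and replacing each
#' p-value by its class-based rank yields uniform p-values with equal power
#' in every sample pair. Classes are the cross of `n_bins` quantile buckets
#' of each keying variable, greedily merged (nearest class centroid) until
#' every class holds at least `min_bin` SNPs. Within a class of size k the
#' ascending mid-rank r (ties averaged) maps to `(r - 0.5)/k`, which keeps
#' Fisher combination calibrated and avoids p in {0, 1}; `mapping =
#' "plain"` uses `r/k` instead.
#'
#' @param p p-values to normalize.
#' @param total_reads,alt_reads per-SNP class keys (spring + fall sums).
#' @param n_bins quantile buckets per keying variable (default 10).
#' @param min_bin minimum class size after merging (default 50).
#' @param mapping `"midrank"` or `"plain"`.
#' @return numeric vector of uniformized p-values in (0, 1).
#' @export
rank_normalize <- function(p, total_reads, alt_reads, n_bins = 10L,
                           min_bin = 50L, mapping = c("midrank", "plain")) {
  mapping <- match.arg(mapping)
  stopifnot(length(p) == length(total_reads), length(p) == length(alt_reads))
  bin <- count_bins(total_reads, alt_reads, n_bins, min_bin)
  rank_in_bins(p, bin, mapping)
}

rank_in_bins <- function(p, bin, mapping = "midrank") {
  # stabilize ties: mathematically equal exact-test tails can differ by an
  # ulp depending on which hypergeometric tail was summed, which would
  # break the exact up/down exchange symmetry under label flips
  p <- signif(p, 12)
  out <- rep(NA_real_, length(p))
  for (ids in split(seq_along(p), bin)) {
    k <- length(ids)
    r <- rank(p[ids], ties.method = "average", na.last = "keep")
    out[ids] <- if (mapping == "midrank") (r - 0.5) / k else r / k
  }
  out
}

count_bins <- function(total_reads, alt_reads, n_bins, min_bin) {
  bucket <- function(x) {
    qs <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                          na.rm = TRUE, type = 1))
    findInterval(x, qs, rightmost.closed = TRUE, all.inside = TRUE)
  }
  bin <- interaction(bucket(total_reads), bucket(alt_reads), drop = TRUE)
  bin <- as.integer(bin)
  # greedy merge of undersized classes into the nearest class centroid
  repeat {
    sizes <- table(bin)
    small <- names(sizes)[sizes < min_bin]
    if (length(small) == 0 || length(sizes) == 1) break
    ct <- vapply(split(seq_along(bin), bin), function(i)
      c(mean(total_reads[i]), mean(alt_reads[i])), numeric(2))
    sdt <- max(stats::sd(total_reads), 1e-9)
    sda <- max(stats::sd(alt_reads), 1e-9)
    sm <- small[which.min(sizes[small])]
    d <- (ct[1, ] - ct[1, sm])^2 / sdt^2 + (ct[2, ] - ct[2, sm])^2 / sda^2
    d[sm] <- Inf
    bin[bin == as.integer(sm)] <- as.integer(names(which.min(d)))
  }
  bin
}

#' Combine rank-normalized p-values with Fisher's method
#'
#' The per-SNP statistic is `X^2 = -2 * sum_j log p_j` over the spring/fall
#' pairs (one tail at a time); under the null it is chi-squared with
#' `2 * n_pairs` degrees of freedom.
#'
#' @param rank_p matrix (SNPs x pairs) of rank-normalized p-values.
#' @return data.frame `x2`, `p` (upper-tail chi-squared).
#' @export
rfm_combine <- function(rank_p) {
  rank_p <- as.matrix(rank_p)
  if (any(rank_p <= 0, na.rm = TRUE))
    stop_invalid("rfm_combine: p-values must be strictly positive")
  x2 <- -2 * rowSums(log(rank_p))
  data.frame(x2 = x2, p = pchisq(x2, df = 2 * ncol(rank_p), lower.tail = FALSE))
}

#' Rank-Fisher's-method (RFM) seasonal scan
#'
#' For each spring/fall pair, a one-sided exact test of allele-frequency
#' differentiation at effective coverage ([fisher_pair()]); p-values are
#' rank-normalized within read-count classes per pair ([rank_normalize()])
#' and combined across pairs by Fisher's method ([rfm_combine()]), each
#' tail separately. Robust to misestimated allele-frequency precision,
#' since only ranks within count classes enter the statistic.
#'
#' @inheritParams glm_seasonal
#' @inheritParams fisher_pair
#' @param n_bins,min_bin,mapping passed to [rank_normalize()].
#' @param keep_pair_p keep the per-pair log rank-p matrices as attributes
#'   (`log_rank_up`, `log_rank_down`), which makes label permutations of
#'   the combined statistic essentially free: flipping a pair's labels
#'   exchanges its up and down tails and leaves count classes unchanged.
#' @return data.frame `chrom`, `pos`, `rfm_x2_up`, `rfm_x2_down`,
#'   `rfm_p_up`, `rfm_p_down`.
#' @export
rfm_seasonal <- function(table, sheet, pairs = NULL, n_bins = 10L,
                         min_bin = 50L, mapping = "midrank",
                         keep_pair_p = TRUE, nc_scale = 1) {
  sheet <- as_sample_sheet(sheet)
  if (is.null(pairs)) pairs <- season_pairs(sheet)
  np <- nrow(pairs)
  n <- n_snps(table)
  nchr <- pool_chromosomes(sheet$n_flies[match(pairs$spring_id, sheet$sample_id)])
  lup <- ldown <- matrix(NA_real_, n, np, dimnames = list(NULL, pairs$pair_id))
  for (j in seq_len(np)) {
    sr <- table$ref_count[, pairs$spring_id[j]]
    sa <- table$alt_count[, pairs$spring_id[j]]
    fr <- table$ref_count[, pairs$fall_id[j]]
    fa <- table$alt_count[, pairs$fall_id[j]]
    ft <- fisher_pair(sr, sa, fr, fa, nchr[j], nc_scale = nc_scale)
    bin <- count_bins(sr + sa + fr + fa, sa + fa, n_bins, min_bin)
    lup[, j] <- log(rank_in_bins(ft$p_up, bin, mapping))
    ldown[, j] <- log(rank_in_bins(ft$p_down, bin, mapping))
  }
  up <- rfm_combine(exp(lup))
  down <- rfm_combine(exp(ldown))
  out <- data.frame(chrom = table$snps$chrom, pos = table$snps$pos,
                    rfm_x2_up = up$x2, rfm_x2_down = down$x2,
                    rfm_p_up = up$p, rfm_p_down = down$p,
                    stringsAsFactors = FALSE)
  if (keep_pair_p) {
    attr(out, "log_rank_up") <- lup
    attr(out, "log_rank_down") <- ldown
    attr(out, "pairs") <- pairs
  }
  out
}

#' Permuted RFM statistics from a fitted scan
#'
#' Applies a within-pair flip plan to an [rfm_seasonal()] result (fitted
#' with `keep_pair_p = TRUE`): for a flipped pair the up-tail p becomes the
#' pair's down-tail p and vice versa, and the read-count classes are
#' unchanged, so each permutation is a column re-selection plus a row sum.
#'
#' @param rfm result of [rfm_seasonal()].
#' @param plan logical flip matrix from [permute_plan()].
#' @param tail `"up"` or `"down"`.
#' @return matrix (SNPs x permutations) of permuted X^2 statistics.
#' @export
rfm_permute <- function(rfm, plan, tail = c("up", "down")) {
  tail <- match.arg(tail)
  lup <- attr(rfm, "log_rank_up"); ldown <- attr(rfm, "log_rank_down")
  if (is.null(lup))
    stop_invalid("rfm_permute: rfm must come from rfm_seasonal(keep_pair_p = TRUE)")
  if (ncol(plan) != ncol(lup))
    stop_invalid("rfm_permute: plan has %d pairs, scan has %d", ncol(plan), ncol(lup))
  a <- if (tail == "up") lup else ldown
  b <- if (tail == "up") ldown else lup
  out <- matrix(NA_real_, nrow(a), nrow(plan))
  for (i in seq_len(nrow(plan))) {
    fl <- plan[i, ]
    s <- rowSums(a[, !fl, drop = FALSE])
    if (any(fl)) s <- s + rowSums(b[, fl, drop = FALSE])
    out[, i] <- -2 * s
  }
  out
}

#' Permuted seasonal-GLM significance counts
#'
#' Refits the seasonal GLM under each within-pair label permutation and
#' counts SNPs at or below each p-value threshold; the full permuted
#' p-value matrix is only retained on request (it is large at genome
#' scale).
#'
#' @inheritParams glm_seasonal
#' @param plan flip matrix from [permute_plan()].
#' @param thresholds p-value thresholds at which to count.
#' @param keep_p keep the full permuted p matrix (`SNPs x n_perms`).
#' @param tol IRLS tolerance; the looser default is ample for counting
#'   p-values against thresholds and halves the cost of a permutation
#'   pass.
#' @return list with `counts` (n_perms x length(thresholds)) and optionally
#'   `p`.
#' @export
glm_permute <- function(table, sheet, plan, pairs = NULL, thresholds,
                        keep_p = FALSE, tol = 1e-6) {
  m <- season_matrices(table, sheet, pairs)
  if (ncol(plan) != nrow(m$pairs))
    stop_invalid("glm_permute: plan has %d pairs, design has %d",
                 ncol(plan), nrow(m$pairs))
  counts <- matrix(NA_real_, nrow(plan), length(thresholds))
  pm <- if (keep_p) matrix(NA_real_, n_snps(table), nrow(plan)) else NULL
  for (i in seq_len(nrow(plan))) {
    fit <- fit_season_glm(m$ys, m$yf, m$ws, m$wf, flips = plan[i, ], tol = tol)
    counts[i, ] <- vapply(thresholds, function(th) sum(fit$p <= th, na.rm = TRUE),
                          numeric(1))
    if (keep_p) pm[, i] <- fit$p
  }
  colnames(counts) <- as.character(thresholds)
  list(counts = counts, p = pm)
}

#' Enrichment of extreme statistics relative to permutations
#'
#' The threshold is the `q`-quantile of the observed statistic (smaller =
#' more extreme, i.e. p-values); enrichment is the observed count at or
#' below the threshold over the median permutation count, and the
#' permutation p-value uses the add-one estimator
#' `(1 + #{perm count >= observed}) / (1 + n_perms)`.
#'
#' @param observed numeric vector of observed per-SNP statistics.
#' @param permuted list of permuted statistic vectors, or a precomputed
#'   integer vector of per-permutation counts (`perm_counts`).
#' @param q quantile in (0, 1) defining the threshold.
#' @param threshold optional fixed cutoff overriding the quantile rule.
#' @return data.frame with `q`, `threshold`, `observed_count`,
#'   `perm_median`, `enrichment`, `p_perm`, plus a `perm_counts` attribute.
#' @export
quantile_enrichment <- function(observed, permuted = NULL, q = 0.01,
                                threshold = NULL, perm_counts = NULL) {
  if (is.null(threshold)) {
    if (q <= 0 || q >= 1) stop_invalid("quantile_enrichment: q must be in (0,1)")
    threshold <- quantile(observed, q, na.rm = TRUE, names = FALSE)
  }
  obs_count <- sum(observed <= threshold, na.rm = TRUE)
  if (is.null(perm_counts)) {
    if (is.null(permuted)) stop_invalid("quantile_enrichment: no permutations given")
    perm_counts <- vapply(permuted, function(v) sum(v <= threshold, na.rm = TRUE),
                          numeric(1))
  }
  med <- median(perm_counts)
  enr <- if (med > 0) obs_count / med else NA_real_
  if (med == 0) warning("quantile_enrichment: zero median permutation count")
  out <- data.frame(q = q, threshold = threshold, observed_count = obs_count,
                    perm_median = med, enrichment = enr,
                    p_perm = (1 + sum(perm_counts >= obs_count)) /
                      (1 + length(perm_counts)))
  attr(out, "perm_counts") <- perm_counts
  out
}

#' Seasonal frequency-shift profile by folded spring frequency
#'
#' For each SNP, the mean across pairs of the spring-to-fall frequency
#' change polarized toward the fall-favored allele (sign of the seasonal
#' GLM coefficient), plotted against the folded mean spring frequency
#' `min(f, 1 - f)` as a moving average. Run on a top set and its matched
#' controls it shows the magnitude of seasonal shifts against the sampling
#' noise floor.
#'
#' @inheritParams glm_seasonal
#' @param snp_sets named list of integer SNP index vectors (e.g.
#'   `list(seasonal = ..., control = ...)`).
#' @param polarity per-SNP sign used to polarize the change (typically
#'   `sign(glm_coef)`); zero-sign SNPs keep their raw change.
#' @param window moving-average width in SNPs.
#' @return data.frame `set`, `folded_freq`, `mean_change` (one row per SNP,
#'   moving-average smoothed) sorted by folded frequency.
#' @export
shift_profile <- function(table, sheet, snp_sets, polarity, pairs = NULL,
                          window = 50L) {
  if (!length(snp_sets) || any(!lengths(snp_sets)))
    stop_invalid("shift_profile: empty SNP set")
  m <- season_matrices(table, sheet, pairs)
  dchange <- rowMeans(m$yf - m$ys, na.rm = TRUE)
  pol <- ifelse(polarity == 0, 1, polarity)
  dchange <- dchange * pol
  fbar <- rowMeans(m$ys, na.rm = TRUE)
  folded <- pmin(fbar, 1 - fbar)
  out <- lapply(names(snp_sets), function(nm) {
    idx <- snp_sets[[nm]]
    o <- idx[order(folded[idx])]
    k <- min(window, length(o))
    sm <- data.table::frollmean(dchange[o], k, align = "center")
    data.frame(set = nm, folded_freq = folded[o],
               mean_change = ifelse(is.na(sm), dchange[o], sm))
  })
  do.call(rbind, out)
}

#' Overlap of top sets of two per-SNP statistics
#'
#' Fraction of the top `q` SNPs of statistic `a` (smallest values, i.e.
#' p-values or any smaller-is-more-extreme score) that also fall in the top
#' `q` of statistic `b`. Under independence the expectation is `q`.
#'
#' @param stat_a,stat_b per-SNP statistics over the same SNP set.
#' @param q top fraction; `q * length(stat_a)` must be at least 1.
#' @export
overlap_top_sets <- function(stat_a, stat_b, q = 0.01) {
  stopifnot(length(stat_a) == length(stat_b))
  k <- floor(q * length(stat_a))
  if (k < 1) stop_invalid("overlap_top_sets: q * n < 1")
  top_a <- order(stat_a)[seq_len(k)]
  top_b <- order(stat_b)[seq_len(k)]
  length(intersect(top_a, top_b)) / k
}

#' Write a seasonal scan result as TSV
#'
#' @param glm_res result of [glm_seasonal()].
#' @param rfm_res result of [rfm_seasonal()] (optional).
#' @param path output file.
#' @export
write_seasonal <- function(glm_res, rfm_res = NULL, path) {
  df <- glm_res
  if (!is.null(rfm_res))
    df <- cbind(df, rfm_res[, c("rfm_x2_up", "rfm_x2_down", "rfm_p_up", "rfm_p_down")])
  write_vc(df, path, "seasonal-result", sep = "\t")
  invisible(path)
}
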