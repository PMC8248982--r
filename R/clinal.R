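## Clinal GLM along latitude and seasonal-clinal concordance.

#' Clinal GLM scan along latitude
#'
#' Regresses per-SNP alternate-allele frequency on population latitude
#' with binomial error and effective-coverage weights, across the supplied
#' (typically spring-only) samples. The coefficient sign is the direction
#' of change with increasing latitude.
#'
#' @param table a [snp_table()].
#' @param sheet a [sample_sheet()].
#' @param sample_ids samples to use; default: all samples of the table
#'   present in the sheet. At least 3 distinct latitudes are required.
#' @return data.frame `chrom`, `pos`, `clinal_coef`, `clinal_se`,
#'   `clinal_p`, `clinal_sign`, with the sample ids used as an attribute.
#' @export
glm_clinal <- function(table, sheet, sample_ids = NULL) {
  sheet <- as_sample_sheet(sheet)
  ids <- sample_ids %||% intersect(colnames(table$ref_count), sheet$sample_id)
  m <- match(ids, sheet$sample_id)
  if (anyNA(m)) stop_invalid("glm_clinal: samples missing from sheet")
  lat <- sheet$latitude[m]
  if (length(unique(lat)) < 3)
    stop_invalid("glm_clinal: need >= 3 populations with distinct latitudes")
  sub <- subset_snps(table, samples = ids)
  fit <- fit_latitude_glm(snp_freq(sub), snp_nc(sub, sheet), lat)
  out <- data.frame(chrom = table$snps$chrom, pos = table$snps$pos,
                    clinal_coef = fit$coef, clinal_se = fit$se,
                    clinal_p = fit$p, clinal_sign = sign(fit$coef),
                    stringsAsFactors = FALSE)
  attr(out, "sample_ids") <- ids
  out
}

#' Seasonal-clinal concordance of a single SNP
#'
#' Concordant means the fall-favored allele is the allele favored at low
#' latitude (the winter-favored allele is assumed to be the
#' high-latitude-favored allele): the sign of the spring-to-fall change
#' equals minus the sign of the latitude coefficient.
#'
#' @param seasonal_sign sign of the fall-vs-spring change (-1/0/+1).
#' @param clinal_sign sign of the latitude coefficient (-1/0/+1).
#' @return logical; `NA` where either sign is zero (such SNPs are excluded
#'   from both numerator and denominator of concordance rates).
#' @export
concordant <- function(seasonal_sign, clinal_sign) {
  out <- seasonal_sign == -clinal_sign
  out[seasonal_sign == 0 | clinal_sign == 0] <- NA
  out
}

#' Verify that seasonal and clinal sample sets share no locality
#'
#' The concordance analysis requires the seasonal scan to be fitted
#' without any sample from a locality used in the clinal scan, so the two
#' signals are estimated from disjoint collections.
#'
#' @param sheet a `sample_sheet`.
#' @param seasonal_ids,clinal_ids sample id vectors.
#' @return invisibly `TRUE`; errors on overlap.
#' @export
assert_disjoint_localities <- function(sheet, seasonal_ids, clinal_ids) {
  sheet <- as_sample_sheet(sheet)
  loc <- function(ids) unique(sheet$locality[match(ids, sheet$sample_id)])
  shared <- intersect(loc(seasonal_ids), loc(clinal_ids))
  if (length(shared))
    stop_invalid("seasonal and clinal analyses share localit%s: %s",
                 if (length(shared) > 1) "ies" else "y",
                 paste(shared, collapse = ", "))
  invisible(TRUE)
}

default_quantile_grid <- function()
  c(0.0005, 0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5, 1.0)

concordance_at <- function(p_a, p_b, sign_a, sign_b, q) {
  thr_a <- quantile(p_a, q, na.rm = TRUE, names = FALSE)
  thr_b <- quantile(p_b, q, na.rm = TRUE, names = FALSE)
  joint <- which(p_a <= thr_a & p_b <= thr_b)
  conc <- concordant(sign_a[joint], sign_b[joint])
  k <- sum(conc, na.rm = TRUE)
  n <- sum(!is.na(conc))
  ci <- if (n > 0) binom.test(k, n)$conf.int else c(NA_real_, NA_real_)
  data.frame(q = q, n_joint = length(joint), n_used = n, n_concordant = k,
             concordance = if (n > 0) k / n else NA_real_,
             ci_low = ci[1], ci_high = ci[2], empty = n == 0)
}

#' Concordance of seasonal and clinal signals across joint quantiles
#'
#' For each quantile `q`, takes the SNPs in the top `q` of both the
#' seasonal and the clinal scan (thresholds from each observed p-value
#' distribution) and reports the fraction whose spring-to-fall direction
#' matches the south-favored direction, with an exact binomial CI. Under
#' independent signals the expectation is 50%.
#'
#' @param seasonal result of [glm_seasonal()] (columns `glm_p`, `glm_sign`).
#' @param clinal result of [glm_clinal()].
#' @param quantiles quantile grid (default spans 5e-4 ... 1).
#' @return data.frame, one row per quantile; empty joint sets are flagged.
#' @export
concordance_curve <- function(seasonal, clinal,
                              quantiles = default_quantile_grid()) {
  stopifnot(nrow(seasonal) == nrow(clinal))
  out <- do.call(rbind, lapply(quantiles, function(q)
    concordance_at(seasonal$glm_p, clinal$clinal_p,
                   seasonal$glm_sign, clinal$clinal_sign, q)))
  rownames(out) <- NULL
  out
}

#' Concordance by genomic region class
#'
#' As [concordance_curve()] at a single quantile, split by region class,
#' with a one-sided exact binomial test against 50% concordance.
#'
#' @inheritParams concordance_curve
#' @param region per-SNP region class (from [classify_region()]).
#' @param q joint quantile (default 0.05).
#' @return data.frame, one row per region, with `p_binom` and
#'   `significant` (p < 0.05).
#' @export
concordance_by_region <- function(seasonal, clinal, region, q = 0.05) {
  stopifnot(length(region) == nrow(seasonal))
  thr_s <- quantile(seasonal$glm_p, q, na.rm = TRUE, names = FALSE)
  thr_c <- quantile(clinal$clinal_p, q, na.rm = TRUE, names = FALSE)
  lv <- if (is.factor(region)) levels(region) else sort(unique(region))
  out <- lapply(lv, function(rg) {
    idx <- which(region == rg & seasonal$glm_p <= thr_s & clinal$clinal_p <= thr_c)
    conc <- concordant(seasonal$glm_sign[idx], clinal$clinal_sign[idx])
    k <- sum(conc, na.rm = TRUE); n <- sum(!is.na(conc))
    if (n == 0)
      return(data.frame(region = rg, q = q, n_used = 0L, n_concordant = 0L,
                        concordance = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_binom = NA_real_,
                        significant = NA, empty = TRUE))
    bt <- binom.test(k, n, p = 0.5, alternative = "greater")
    ci <- binom.test(k, n)$conf.int
    data.frame(region = rg, q = q, n_used = n, n_concordant = k,
               concordance = k / n, ci_low = ci[1], ci_high = ci[2],
               p_binom = bt$p.value, significant = bt$p.value < 0.05,
               empty = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Matched-control concordance band
#'
#' Recomputes the concordance rate with each matched-control set standing
#' in for the focal seasonal SNPs and returns the empirical band from
#' [control_interval()].
#'
#' @param controls result of [matched_controls()] for the joint focal set.
#' @param seasonal,clinal scan results (whole genome).
#' @return list with `per_set` concordance rates and `interval`.
#' @export
control_concordance <- function(controls, seasonal, clinal) {
  rates <- apply(controls$sets, 2, function(idx) {
    conc <- concordant(seasonal$glm_sign[idx], clinal$clinal_sign[idx])
    n <- sum(!is.na(conc))
    if (n == 0) NA_real_ else sum(conc, na.rm = TRUE) / n
  })
  list(per_set = rates, interval = control_interval(rates[!is.na(rates)]))
}
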