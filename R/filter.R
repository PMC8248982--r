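#' SNP filtering configuration
#'
#' Thresholds for the standard pool-seq filtering cascade: proximity to
#' indels, repeat regions, rare median frequency, low recombination,
#' multi-allelic sites, X-chromosome exclusion, minimum depth, and the
#' "common polymorphism" rule requiring segregation in every sample.
#'
#' @param indel_buffer_bp drop SNPs within this many bp of an indel (default 10).
#' @param min_median_freq drop SNPs whose median minor-allele frequency
#'   across samples is below this (default 0.01).
#' @param min_recomb_cM_per_Mb drop SNPs in map windows below this rate;
#'   the default 0.5 reads "~0 cM/Mb" as the map's lowest bins rather than a
#'   brittle hard zero.
#' @param min_depth drop SNPs with read depth below this in any sample
#'   (default 10).
#' @param require_polymorphic_all keep only SNPs with 0 < freq < 1 in every
#'   sample (the "common polymorphisms" core set).
#' @param autosomes_only drop X-linked SNPs (male-only pools halve X
#'   coverage).
#' @param x_chroms chromosome names treated as X.
#' @export
filter_config <- function(indel_buffer_bp = 10L, min_median_freq = 0.01,
                          min_recomb_cM_per_Mb = 0.5, min_depth = 10L,
                          require_polymorphic_all = TRUE, autosomes_only = TRUE,
                          x_chroms = c("X", "chrX")) {
  if (indel_buffer_bp < 0 || min_median_freq < 0 || min_recomb_cM_per_Mb < 0 ||
      min_depth < 0)
    stop_invalid("filter_config: thresholds must be non-negative")
  structure(list(indel_buffer_bp = as.integer(indel_buffer_bp),
                 min_median_freq = min_median_freq,
                 min_recomb_cM_per_Mb = min_recomb_cM_per_Mb,
                 min_depth = as.integer(min_depth),
                 require_polymorphic_all = isTRUE(require_polymorphic_all),
                 autosomes_only = isTRUE(autosomes_only),
                 x_chroms = x_chroms),
            class = "filter_config")
}

#' Apply the SNP filtering cascade
#'
#' Rules are applied sequentially in the order: indel proximity, repeat
#' regions, median minor-allele frequency, low recombination, multi-allelic
#' sites, X-chromosome removal, minimum depth, polymorphic-in-all-samples.
#' Counts removed by each rule (in that order, on the table surviving the
#' previous rules) are returned so a run can be audited. Filtering is
#' idempotent: re-filtering a filtered table removes nothing.
#'
#' @param table a [snp_table()].
#' @param cfg a [filter_config()].
#' @param repeats optional `region_set` of repeat-masked intervals.
#' @param indel_positions optional data.frame `chrom`, `pos` (1-based) of
#'   indels; indel calling itself is outside the package.
#' @param rmap optional [recomb_map()].
#' @return list with `table` (filtered `snp_table`) and `removed` (named
#'   integer vector of per-rule removal counts).
#' @export
filter_snps <- function(table, cfg = filter_config(), repeats = NULL,
                        indel_positions = NULL, rmap = NULL) {
  stopifnot(inherits(table, "snp_table"), inherits(cfg, "filter_config"))
  removed <- c(indel_proximity = 0L, repeats = 0L, median_freq = 0L,
               low_recomb = 0L, multiallelic = 0L, x_chromosome = 0L,
               min_depth = 0L, not_polymorphic_all = 0L)
  drop_rule <- function(tbl, bad, rule) {
    removed[rule] <<- sum(bad, na.rm = TRUE)
    if (any(bad, na.rm = TRUE)) subset_snps(tbl, !bad %in% TRUE) else tbl
  }
  tbl <- table

  if (!is.null(indel_positions) && nrow(as.data.frame(indel_positions)) > 0 &&
      n_snps(tbl) > 0) {
    ip <- as.data.frame(indel_positions)
    buf <- cfg$indel_buffer_bp
    iv <- data.frame(chrom = ip$chrom, start = pmax(ip$pos - 1L - buf, 0L),
                     end = ip$pos + buf)          # 1-based pos +/- buf, half-open
    bad <- in_regions(tbl$snps$chrom, tbl$snps$pos, region_set(iv, "indel-buffer"))
    tbl <- drop_rule(tbl, bad, "indel_proximity")
  }
  if (!is.null(repeats) && n_snps(tbl) > 0) {
    bad <- in_regions(tbl$snps$chrom, tbl$snps$pos, repeats)
    tbl <- drop_rule(tbl, bad, "repeats")
  }
  if (n_snps(tbl) > 0) {
    f <- snp_freq(tbl)
    maf <- pmin(f, 1 - f)
    med <- apply(maf, 1, median, na.rm = TRUE)
    tbl <- drop_rule(tbl, med < cfg$min_median_freq, "median_freq")
  }
  if (!is.null(rmap) && n_snps(tbl) > 0) {
    maxend <- tapply(rmap$windows$end, rmap$windows$chrom, max)
    over <- tbl$snps$pos - 1L >= maxend[tbl$snps$chrom] &
      !is.na(maxend[tbl$snps$chrom])
    if (any(over, na.rm = TRUE))
      stop_invalid("filter_snps: SNP %s:%d beyond recombination map extent (coordinate-system mismatch?)",
                   tbl$snps$chrom[over][1], tbl$snps$pos[over][1])
    rate <- recomb_rate_at(tbl$snps$chrom, tbl$snps$pos, rmap)
    tbl <- drop_rule(tbl, !is.na(rate) & rate < cfg$min_recomb_cM_per_Mb, "low_recomb")
  }
  if (n_snps(tbl) > 0)
    tbl <- drop_rule(tbl, tbl$snps$multiallelic %in% TRUE, "multiallelic")
  if (cfg$autosomes_only && n_snps(tbl) > 0)
    tbl <- drop_rule(tbl, tbl$snps$chrom %in% cfg$x_chroms, "x_chromosome")
  if (cfg$min_depth > 0 && n_snps(tbl) > 0) {
    d <- snp_depth(tbl)
    tbl <- drop_rule(tbl, apply(d, 1, min) < cfg$min_depth, "min_depth")
  }
  if (cfg$require_polymorphic_all && n_snps(tbl) > 0) {
    f <- snp_freq(tbl)
    poly <- rowSums(is.na(f) | f <= 0 | f >= 1) == 0
    tbl <- drop_rule(tbl, !poly, "not_polymorphic_all")
  }
  list(table = tbl, removed = removed)
}
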