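#' SNP-by-sample allele count table
#'
#' The central container of the package: biallelic SNPs (rows) by pooled
#' samples (columns), holding reference and alternate read counts together
#' with genomic coordinates. Positions are 1-based (VCF/SYNC convention).
#'
#' @param snps data.frame with columns `chrom`, `pos`, `ref_allele`,
#'   `alt_allele` and optionally `multiallelic` (logical flag set by the SYNC
#'   reader when more than two nucleotides segregate at the site).
#' @param ref_count,alt_count integer matrices (SNPs x samples) of reference
#'   and alternate read counts; column names are sample ids.
#' @return an object of class `snp_table`.
#' @export
snp_table <- function(snps, ref_count, alt_count) {
  snps <- as.data.frame(snps)
  ref_count <- as.matrix(ref_count)
  alt_count <- as.matrix(alt_count)
  need <- c("chrom", "pos", "ref_allele", "alt_allele")
  miss <- setdiff(need, names(snps))
  if (length(miss))
    stop_invalid("snp_table: missing SNP columns: %s", paste(miss, collapse = ", "))
  if (nrow(snps) != nrow(ref_count) || nrow(snps) != nrow(alt_count))
    stop_invalid("snp_table: count matrices must have one row per SNP")
  if (!identical(dim(ref_count), dim(alt_count)))
    stop_invalid("snp_table: ref and alt count matrices differ in shape")
  if (ncol(ref_count) > 0 && is.null(colnames(ref_count)))
    stop_invalid("snp_table: count matrices need sample ids as column names")
  if (!identical(colnames(ref_count), colnames(alt_count)))
    stop_invalid("snp_table: ref/alt sample columns disagree")
  if (nrow(snps) > 0) {
    if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE))
      stop_invalid("snp_table: negative read counts")
    ord <- order(snps$chrom, snps$pos)
    if (is.unsorted(ord) && !identical(ord, seq_len(nrow(snps)))) {
      snps <- snps[ord, , drop = FALSE]
      ref_count <- ref_count[ord, , drop = FALSE]
      alt_count <- alt_count[ord, , drop = FALSE]
    }
    dup <- duplicated(snps[, c("chrom", "pos")])
    if (any(dup))
      stop_invalid("snp_table: duplicated positions (first at %s:%d)",
                   snps$chrom[dup][1], snps$pos[dup][1])
  }
  if (is.null(snps$multiallelic)) snps$multiallelic <- logical(nrow(snps))
  rownames(snps) <- NULL
  structure(list(snps = snps, ref_count = ref_count, alt_count = alt_count),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d SNPs x %d samples\n", n_snps(x), length(sample_ids(x))))
  if (n_snps(x) > 0)
    cat(" chromosomes:", paste(unique(x$snps$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.snp_table <- function(x) c(nrow(x$snps), ncol(x$ref_count))

#' Number of SNPs in a table
#' @param x a `snp_table`.
#' @export
n_snps <- function(x) nrow(x$snps)

#' Sample ids of a table
#' @param x a `snp_table`.
#' @export
sample_ids <- function(x) colnames(x$ref_count)

#' Subset a SNP table by SNP row and/or sample id
#'
#' @param x a `snp_table`.
#' @param snps integer or logical index over SNP rows.
#' @param samples character sample ids or index over columns.
#' @export
subset_snps <- function(x, snps = NULL, samples = NULL) {
  stopifnot(inherits(x, "snp_table"))
  s <- x$snps; rc <- x$ref_count; ac <- x$alt_count
  if (!is.null(snps)) {
    s <- s[snps, , drop = FALSE]
    rc <- rc[snps, , drop = FALSE]
    ac <- ac[snps, , drop = FALSE]
  }
  if (!is.null(samples)) {
    rc <- rc[, samples, drop = FALSE]
    ac <- ac[, samples, drop = FALSE]
  }
  snp_table(s, rc, ac)
}

#' Effective coverage of a pooled sample
#'
#' Pool-seq read counts carry two layers of binomial noise: sampling of
#' chromosomes into the pool and sampling of reads from the pool. The
#' effective coverage `Nc = (1/N + 1/R)^-1`, where `N` is the number of
#' chromosomes in the pool and `R` the read depth at the site, is the
#' binomial sample size that matches the combined sampling variance and is
#' used as the regression weight throughout the package.
#'
#' @param n_chromosomes number of chromosomes in the pool (`N`), positive.
#' @param read_depth read depth at the site (`R`), positive.
#' @return effective sample size, always `<= min(N, R)`. Vectorized.
#' @examples
#' effective_coverage(150, 75)  # 50
#' @export
effective_coverage <- function(n_chromosomes, read_depth) {
  if (any(n_chromosomes <= 0, na.rm = TRUE) || any(read_depth <= 0, na.rm = TRUE))
    stop_invalid("effective_coverage: N and R must be positive")
  1 / (1 / n_chromosomes + 1 / read_depth)
}

#' Chromosomes sampled per pool
#'
#' Pools of male flies carry two copies of each autosome, so an autosomal
#' pool of `n` flies samples `2n` chromosomes.
#'
#' @param n_flies pool size in individuals, `>= 1`.
#' @param ploidy_mode only `"male-autosome"` is supported.
#' @export
pool_chromosomes <- function(n_flies, ploidy_mode = "male-autosome") {
  if (!identical(ploidy_mode, "male-autosome"))
    stop_invalid("pool_chromosomes: unsupported ploidy_mode '%s'", ploidy_mode)
  if (any(n_flies < 1, na.rm = TRUE))
    stop_invalid("pool_chromosomes: n_flies must be >= 1")
  2L * as.integer(n_flies)
}

#' Alternate-allele frequency from read counts
#'
#' @param ref_count,alt_count non-negative read counts (vectors or matrices).
#' @return `alt / (ref + alt)`; `NA` where the total is zero (a site with no
#'   reads has no defined frequency, never frequency zero).
#' @export
allele_frequency <- function(ref_count, alt_count) {
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE))
    stop_invalid("allele_frequency: negative counts")
  tot <- ref_count + alt_count
  out <- alt_count / tot
  out[tot == 0] <- NA_real_
  out
}

#' Per-cell allele frequencies, depths and effective coverages of a table
#'
#' @param x a `snp_table`.
#' @param sheet a `sample_sheet`; needed for `snp_nc()` to supply pool sizes.
#' @return matrices (SNPs x samples).
#' @export
snp_freq <- function(x) allele_frequency(x$ref_count, x$alt_count)

#' @rdname snp_freq
#' @export
snp_depth <- function(x) x$ref_count + x$alt_count

#' @rdname snp_freq
#' @export
snp_nc <- function(x, sheet) {
  sheet <- as_sample_sheet(sheet)
  ids <- sample_ids(x)
  m <- match(ids, sheet$sample_id)
  if (anyNA(m))
    stop_invalid("snp_nc: samples missing from sheet: %s",
                 paste(ids[is.na(m)], collapse = ", "))
  nchr <- pool_chromosomes(sheet$n_flies[m])
  depth <- snp_depth(x)
  nc <- matrix(NA_real_, nrow(depth), ncol(depth), dimnames = dimnames(depth))
  ok <- depth > 0
  nchr_mat <- matrix(nchr, nrow(depth), ncol(depth), byrow = TRUE)
  nc[ok] <- effective_coverage(nchr_mat[ok], depth[ok])
  nc
}
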