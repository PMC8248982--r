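## Inversion-region classification, per-region enrichment and
## matched-control resampling.

#' The six cosmopolitan D. melanogaster inversions
#'
#' Breakpoint coordinates (1-based, inclusive) of In(2L)t, In(2R)NS,
#' In(3L)P, In(3R)K, In(3R)Mo and In(3R)P. The three overlapping 3R
#' inversions are combined into one span by [classify_region()].
#'
#' @return data.frame `name`, `chrom`, `start`, `stop`.
#' @export
cosmopolitan_inversions <- function() {
  data.frame(
    name = c("In(2L)t", "In(2R)NS", "In(3L)P", "In(3R)K", "In(3R)Mo", "In(3R)P"),
    chrom = c("2L", "2R", "3L", "3R", "3R", "3R"),
    start = c(2225744L, 11278659L, 3173046L, 7576289L, 17232639L, 12257931L),
    stop = c(13154180L, 16163839L, 16301941L, 21966092L, 24857019L, 20569732L),
    stringsAsFactors = FALSE)
}

merged_inversion_spans <- function(inversions = cosmopolitan_inversions()) {
  iv <- region_set(data.frame(chrom = inversions$chrom,
                              start = inversions$start - 1L,
                              end = inversions$stop),
                   label = "inversions")
  m <- merge_regions(iv)$intervals
  data.frame(chrom = m$chrom, start = m$start + 1L, stop = m$end)  # back to 1-based
}

#' Classify autosomal positions relative to the cosmopolitan inversions
#'
#' Overlapping inversions are merged first; a position is `breakpoint` if
#' it lies within `buffer_bp` of a merged-span boundary, else `inside` if
#' within a span, else `outside`. Every position receives exactly one
#' label.
#'
#' @param chrom,pos 1-based positions.
#' @param inversions inversion table as from [cosmopolitan_inversions()].
#' @param buffer_bp breakpoint buffer (default 500 kb).
#' @param known_chroms chromosomes accepted without error.
#' @return factor with levels `breakpoint`, `inside`, `outside`.
#' @export
classify_region <- function(chrom, pos, inversions = cosmopolitan_inversions(),
                            buffer_bp = 500000L,
                            known_chroms = c("2L", "2R", "3L", "3R")) {
  bad <- !(chrom %in% known_chroms)
  if (any(bad))
    stop_invalid("classify_region: unknown chromosome '%s'", unique(chrom[bad])[1])
  spans <- merged_inversion_spans(inversions)
  out <- rep("outside", length(pos))
  for (i in seq_len(nrow(spans))) {
    sel <- chrom == spans$chrom[i]
    if (!any(sel)) next
    p <- pos[sel]
    near_bp <- abs(p - spans$start[i]) <= buffer_bp |
      abs(p - spans$stop[i]) <= buffer_bp
    inside <- p >= spans$start[i] & p <= spans$stop[i]
    lab <- out[sel]
    lab[inside & lab == "outside"] <- "inside"
    lab[near_bp] <- "breakpoint"
    out[sel] <- lab
  }
  factor(out, levels = c("breakpoint", "inside", "outside"))
}

#' Enrichment of seasonal SNPs by genomic region
#'
#' Applies [quantile_enrichment()] within each chromosome x region-class
#' cell, using one genome-wide threshold (the `q`-quantile of the observed
#' statistic, e.g. the top-1% p-value cutoff). Cells with no SNPs are
#' skipped with a warning.
#'
#' @param observed per-SNP observed statistic (smaller = more extreme).
#' @param permuted SNPs x permutations matrix of permuted statistics.
#' @param region per-SNP region class (from [classify_region()]).
#' @param chrom per-SNP chromosome; set to a constant to pool chromosomes.
#' @param q genome-wide quantile defining the threshold.
#' @return data.frame, one row per cell: `chrom`, `region`, `n_snps`,
#'   enrichment columns from [quantile_enrichment()], and `significant`
#'   (observed count exceeds >95% of permutations).
#' @export
region_enrichment <- function(observed, permuted, region, chrom, q = 0.01) {
  stopifnot(length(observed) == length(region), length(observed) == length(chrom),
            nrow(permuted) == length(observed))
  threshold <- quantile(observed, q, na.rm = TRUE, names = FALSE)
  cells <- split(seq_along(observed), list(chrom = chrom, region = region),
                 drop = FALSE)
  out <- lapply(names(cells), function(nm) {
    idx <- cells[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(idx) == 0) {
      warning("region_enrichment: no SNPs in cell ", nm, "; skipped")
      return(NULL)
    }
    pc <- colSums(permuted[idx, , drop = FALSE] <= threshold, na.rm = TRUE)
    qe <- quantile_enrichment(observed[idx], threshold = threshold,
                              perm_counts = pc)
    cbind(data.frame(chrom = parts[1], region = parts[2], n_snps = length(idx)),
          qe, significant = mean(pc < qe$observed_count) > 0.95)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Matching specification for control resampling
#'
#' @param n_sets number of control sets (default 100).
#' @param min_candidates focal SNPs with fewer candidate matches are
#'   discarded (default 10).
#' @param nc_bin,freq_bin,recomb_bin bin widths for effective coverage,
#'   median spring frequency and recombination rate; chromosome and
#'   inversion status are matched exactly.
#' @param seed integer seed for control sampling.
#' @export
match_spec <- function(n_sets = 100L, min_candidates = 10L, nc_bin = 10,
                       freq_bin = 0.02, recomb_bin = 0.5, seed = 1L) {
  structure(list(n_sets = as.integer(n_sets),
                 min_candidates = as.integer(min_candidates),
                 nc_bin = nc_bin, freq_bin = freq_bin, recomb_bin = recomb_bin,
                 seed = as.integer(seed)),
            class = "match_spec")
}

#' Per-SNP matching covariates
#'
#' Builds the covariates used by [matched_controls()]: chromosome, mean
#' effective coverage across samples, median spring allele frequency,
#' inversion status (inside/outside the merged cosmopolitan spans,
#' breakpoint buffers counted as inside) and local recombination rate.
#'
#' @param table a [snp_table()].
#' @param sheet a [sample_sheet()].
#' @param rmap optional [recomb_map()].
#' @param inversions inversion table.
#' @param pairs optional pair table.
#' @return data.frame with one row per SNP.
#' @export
control_covariates <- function(table, sheet, rmap = NULL,
                               inversions = cosmopolitan_inversions(),
                               pairs = NULL) {
  sheet <- as_sample_sheet(sheet)
  if (is.null(pairs)) pairs <- season_pairs(sheet)
  nc <- snp_nc(table, sheet)
  f <- snp_freq(table)
  spans <- merged_inversion_spans(inversions)
  inv <- in_regions(table$snps$chrom, table$snps$pos,
                    region_set(data.frame(chrom = spans$chrom,
                                          start = spans$start - 1L,
                                          end = spans$stop), "inv"))
  data.frame(chrom = table$snps$chrom,
             nc = rowMeans(nc, na.rm = TRUE),
             med_spring_freq = apply(f[, pairs$spring_id, drop = FALSE], 1,
                                     median, na.rm = TRUE),
             inversion = ifelse(inv, "in", "out"),
             recomb = if (is.null(rmap)) 0 else
               recomb_rate_at(table$snps$chrom, table$snps$pos, rmap),
             stringsAsFactors = FALSE)
}

#' Matched-control SNP sets
#'
#' For each focal SNP, candidate controls share its chromosome and
#' inversion status exactly and its effective-coverage, median
#' spring-frequency and recombination-rate bins; the focal SNP itself is
#' never a candidate. Focal SNPs with fewer than `min_candidates`
#' candidates are discarded and reported. Each of the `n_sets` control
#' sets samples one match per retained focal SNP, independently across
#' sets (a control may recur across sets).
#'
#' @param focal integer indices of focal SNPs.
#' @param covars covariate data.frame from [control_covariates()].
#' @param spec a [match_spec()].
#' @return list: `sets` (matrix, retained focals x n_sets, of control SNP
#'   indices), `retained`, `discarded` (focal indices), `n_candidates`.
#' @export
matched_controls <- function(focal, covars, spec = match_spec()) {
  stopifnot(inherits(spec, "match_spec"))
  key <- paste(covars$chrom,
               covars$inversion,
               round(covars$nc / spec$nc_bin),
               floor(covars$med_spring_freq / spec$freq_bin),
               floor((covars$recomb %||% 0) / spec$recomb_bin),
               sep = "|")
  groups <- split(seq_len(nrow(covars)), key)
  n_cand <- integer(length(focal))
  with_seed(substream_seed(spec$seed, "matched_controls"), {
    picks <- vector("list", length(focal))
    for (i in seq_along(focal)) {
      cand <- setdiff(groups[[key[focal[i]]]], focal[i])
      n_cand[i] <- length(cand)
      if (length(cand) >= spec$min_candidates)
        picks[[i]] <- cand[sample.int(length(cand), spec$n_sets, replace = TRUE)]
    }
    keep <- !vapply(picks, is.null, logical(1))
    if (!any(keep))
      stop_invalid("matched_controls: no focal SNP has enough candidates")
    sets <- do.call(rbind, picks[keep])
    list(sets = sets, retained = focal[keep], discarded = focal[!keep],
         n_candidates = n_cand)
  })
}

#' Empirical 95% band from matched-control sets
#'
#' With the canonical 100 control sets the band is the 3rd and 98th ranked
#' values of the per-set statistic; for other set counts the same
#' fractional ranks (0.03 and 0.98 of n, rounded to the nearest rank) are
#' used.
#'
#' @param stat_per_set one summary statistic per control set.
#' @return numeric `c(low, high)`.
#' @export
control_interval <- function(stat_per_set) {
  n <- length(stat_per_set)
  if (n < 5) stop_invalid("control_interval: need at least 5 control sets")
  s <- sort(stat_per_set)
  lo <- min(max(1L, round(0.03 * n)), n)
  hi <- min(max(1L, round(0.98 * n)), n)
  c(low = s[lo], high = s[hi])
}
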