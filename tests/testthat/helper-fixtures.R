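# Shared fixture builders. Everything is generated in code; no binary
# fixtures are stored.

# A tiny hand-specified paired design: counts are alt/ref per sample.
toy_two_pair_table <- function() {
  snps <- data.frame(chrom = "2L", pos = c(100L, 200L, 300L),
                     ref_allele = "A", alt_allele = "C")
  # columns: p1 spring, p2 spring, p1 fall, p2 fall
  alt <- rbind(c(40, 45, 60, 55),
               c(50, 50, 50, 50),
               c(20, 80, 35, 70))
  ref <- 100 - alt
  colnames(alt) <- colnames(ref) <- c("p1_spring", "p2_spring", "p1_fall", "p2_fall")
  snp_table(snps, ref, alt)
}

toy_two_pair_sheet <- function() {
  sample_sheet(data.frame(
    sample_id = c("p1_spring", "p2_spring", "p1_fall", "p2_fall"),
    locality = c("p1", "p2", "p1", "p2"),
    latitude = c(40, 30, 40, 30), longitude = -75,
    season = c("spring", "spring", "fall", "fall"),
    year = 2012L, collection_date = c("2012-06", "2012-06", "2012-10", "2012-10"),
    n_flies = 75L))
}

# Paired pool-seq design simulated straight at the matrix level (quicker
# than a full dataset when coordinates/weather are not needed).
sim_pair_matrices <- function(n_snps, n_pairs = 20, n_flies = 75, depth = 94,
                              shift = 0, shift_frac = 0, seed = 1) {
  set.seed(seed)
  base <- runif(n_snps, 0.05, 0.95)
  seas <- seq_len(n_snps) <= shift_frac * n_snps
  sgn <- sample(c(-1, 1), n_snps, replace = TRUE)
  fs <- matrix(base, n_snps, n_pairs)
  ff <- fs + (seas * sgn * shift)
  ff <- pmin(pmax(ff, 0.001), 0.999)
  draw <- function(f) {
    k <- rbinom(length(f), 2 * n_flies, f) / (2 * n_flies)
    d <- rpois(length(f), depth) + 1L
    alt <- rbinom(length(f), d, k)
    list(alt = matrix(alt, n_snps), depth = matrix(d, n_snps))
  }
  s <- draw(fs); f <- draw(ff)
  list(ys = s$alt / s$depth, yf = f$alt / f$depth,
       ws = effective_coverage(2 * n_flies, s$depth),
       wf = effective_coverage(2 * n_flies, f$depth),
       alt_s = s$alt, depth_s = s$depth, alt_f = f$alt, depth_f = f$depth,
       seasonal = seas, sign = sgn)
}

# Wrap matrix-level simulation into snp_table + sheet for pipeline-level
# functions.
matrices_to_dataset <- function(m, n_flies = 75) {
  n_pairs <- ncol(m$ys)
  ids <- c(sprintf("l%02d_spring", seq_len(n_pairs)),
           sprintf("l%02d_fall", seq_len(n_pairs)))
  alt <- cbind(m$alt_s, m$alt_f)
  ref <- cbind(m$depth_s - m$alt_s, m$depth_f - m$alt_f)
  colnames(alt) <- colnames(ref) <- ids
  n <- nrow(alt)
  tbl <- snp_table(data.frame(chrom = "2L", pos = seq_len(n) * 10L,
                              ref_allele = "A", alt_allele = "C"),
                   ref, alt)
  sheet <- sample_sheet(data.frame(
    sample_id = ids,
    locality = rep(sprintf("l%02d", seq_len(n_pairs)), 2),
    latitude = rep(seq(25, 45, length.out = n_pairs), 2), longitude = -75,
    season = rep(c("spring", "fall"), each = n_pairs),
    year = 2012L, collection_date = "2012-07-01", n_flies = n_flies))
  list(table = tbl, sheet = sheet)
}
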