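---
title: "Detecting parallel seasonal adaptation from pooled sequencing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parallel seasonal adaptation from pooled sequencing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Populations of short-lived organisms such as *Drosophila melanogaster* go
through many generations between spring and fall. If selection pressures
reverse with the seasons, allele frequencies can oscillate measurably
within a single year, and — if the pressures are shared across localities —
in parallel across populations sampled hundreds of kilometres apart.
`seasonscan` implements the statistical machinery for detecting such
parallel seasonal adaptation from paired spring/fall pooled-sequencing
("pool-seq") samples: per-SNP seasonal tests with permutation nulls,
region-level enrichment relative to chromosomal inversions,
matched-control resampling, concordance between seasonal and latitudinal
(clinal) change, and a leave-one-out predictability analysis that asks
whether one population's seasonal change is predictable from the others,
and whether deviations track the weather each population actually
experienced before sampling.

Because the interesting quantities are second-order (enrichments,
concordances, calibrations), every stage of the pipeline is paired with a
synthetic-data generator with known ground truth. The package's tests are
largely statements about recovery and calibration on that generator.

# Data model and effective coverage

Pool-seq estimates a population allele frequency by sequencing DNA pooled
from `n` individuals. Two binomial sampling layers separate the true
frequency from the read counts: the draw of `N = 2n` chromosomes into the
pool (males, autosomes), and the draw of `R` reads from the pool. A read
frequency therefore has variance `p(1-p)(1/N + 1/R)`, and the *effective
coverage*

```
Nc = (1/N + 1/R)^-1
```

is the binomial sample size that reproduces this variance. `Nc` is used as
the prior weight in every regression and as the rescaling target for the
exact tests. It is always at most `min(N, R)`: with 75-fly pools
(`N = 150`) at 94x depth, `Nc` is roughly 58 — substantially less
information than the raw depth suggests.

# The seasonal generalized linear model

For each SNP the package fits a weighted binomial GLM of the
alternate-allele frequency on season plus an unordered population factor:

```
logit E[y] = population + season,   weights = Nc
```

with spring coded 0 and fall 1, and reports the two-sided Wald p-value of
the season term. The null is calibrated by permutation: spring/fall labels
are flipped *within* each population pair (each pair independently with
probability 1/2, 500 permutations by default), which preserves every
between-population difference and tests only the seasonal axis.

Because the permutation null refits the model hundreds of times across up
to ~10^5 SNPs, the fitter is a hand-vectorized IRLS. The population factor
contributes a diagonal block to the weighted least-squares system, so each
IRLS step reduces to a closed-form Schur complement; all quantities are
SNPs-by-populations matrices and one iteration is a handful of elementwise
matrix operations. The fitter converges on the coefficient updates
(root-sum-of-squares below `1e-9` by default; `1e-6` inside permutation
passes, where p-values are only counted against thresholds) and switches
to a compacted active set once most SNPs have converged, so the rare
boundary-frequency sites that need many steps do not drag the genome
through extra sweeps. Unit tests verify agreement with `stats::glm` to
better than 10^-6 in the p-value on hand-built fixtures. SNPs fixed at 0
or 1 in every weighted observation have no seasonal information and are
flagged missing rather than fitted.

The `Nc` weighting is known to be anti-conservative for pool-seq (true
sampling variance exceeds the two-binomial model when library preparation
adds overdispersion), which is why the GLM is used as an outlier/ranking
test against its own permutation null rather than as a calibrated
significance test.

# The rank-Fisher's-method (RFM) statistic

The second seasonal test avoids the precision assumption altogether. For
each spring/fall pair, a one-sided Fisher exact test of allele-frequency
differentiation is computed on counts rescaled to effective coverage
(`alt' = round(freq * Nc)`, `ref' = round(Nc) - alt'`; the rounding rule
preserves the observed frequency — the integerization is otherwise
arbitrary and is exposed in code). Exact-test p-values from pooled counts
are granular and depend on the count configuration, so within each pair
the p-values are *rank-normalized*: SNPs are grouped into classes by total
reads and alternate reads (summed over spring and fall), and each p-value
is replaced by its class-based rank. Classes are the cross of deciles of
the two keying variables, greedily merged until every class holds at least
50 SNPs; the granularity is a package choice — the keying variables are
the method's definition, their bucketing is not.

Within a class of size `k`, the ascending mid-rank `r` (ties averaged)
maps to `(r - 0.5)/k`. The mid-rank form keeps `E[-2 log p]` at 2 to
`O(1/k^2)` and cannot produce 0 or 1, which matters because the per-pair
values are then combined with Fisher's method:

```
X^2 = -2 * sum_j log p_j    ~  chi-squared(df = 2 * n_pairs)
```

each tail separately (an allele consistently *rising* in fall scores in
the up-tail statistic). With 20 pairs the null is chi-squared with 40
degrees of freedom; the package's calibration tests check the null mean to
within 1% and the full distribution by a Kolmogorov–Smirnov test on
20,000 simulated null SNPs. A plain `r/k` mapping is available by
configuration.

Two implementation details are worth recording. First, flipping a pair's
labels exactly exchanges its up- and down-tail p-values (the 2x2 margins
are unchanged), and the count classes are flip-invariant — so the entire
permutation null of the combined statistic is a column re-selection of two
precomputed matrices, essentially free at genome scale. Second, p-values
are rounded to 12 significant digits before ranking: mathematically equal
hypergeometric tails can differ in the last ulp depending on which tail
was summed, and without stabilization those phantom differences would
break the exact exchange symmetry through tie handling.

# Enrichment, inversions and matched controls

Seasonal enrichment is summarized at a quantile `q` (default 0.01): the
threshold is the `q`-quantile of the observed statistic, enrichment is the
observed count at or below it divided by the median permutation count, and
the permutation p-value uses the add-one estimator `(1 + b)/(1 + m)`. The
threshold comes from the observed distribution (not observed + permuted
pooled); the value used is recorded in the output.

Because large cosmopolitan inversions — In(2L)t, In(2R)NS, In(3L)P and the
three overlapping 3R inversions, which are merged — segregate seasonally
and suppress recombination, enrichment is also reported by genomic
region: within 500 kb of a merged-inversion boundary (`breakpoint`),
inside a span (`inside`), or outside (`outside`), crossed with
chromosome arm. The 500 kb buffer follows the methods convention; a 1 Mb
variant appears in some figure legends, so the buffer is an explicit
argument.

For questions of the form "are seasonal SNPs unusual in property X", the
package builds matched-control sets: for each focal SNP, 100 sets each
draw one non-focal SNP matching it exactly on chromosome and inversion
status and approximately on effective coverage (bins of 10), median spring
frequency (bins of 0.02) and recombination rate (bins of 0.5 cM/Mb).
Focal SNPs with fewer than 10 candidates are discarded and reported;
draws are independent across sets, so a control may recur. The empirical
95% band of a per-set statistic is the 3rd and 98th ranked values of the
100 sets (fractional ranks 0.03/0.98 for other set counts). Bin widths
are package choices, set so that typical SNPs retain enough candidates at
10^5-SNP scale.

# Clinal concordance

Latitudinal clines are fitted per SNP as `logit E[y] = latitude` with
binomial error and `Nc` weights over spring samples from a latitudinal
transect. A SNP is *concordant* when its fall-favored allele is its
low-latitude-favored allele — the convention that winter conditions
resemble high-latitude conditions, stated in code as
`sign(fall - spring) == -sign(latitude coefficient)`. Concordance curves
report, at each joint quantile of the two scans, the concordant fraction
with an exact binomial confidence interval; under independent signals the
expectation is 50%. The seasonal scan used here must not share a locality
with the clinal samples (estimating both signals from the same collections
would couple their errors); `assert_disjoint_localities()` enforces this
and the generator lays clinal samples at their own localities.

# Leave-one-out predictability and the thermal-limit model

For each pair in turn, the remaining pairs are refitted with the seasonal
GLM and the held-out pair gets a single-pair exact test (two-sided for
ranking; its direction of change is kept separately). The concordance
curve across joint quantiles summarizes how predictable the held-out
population's seasonal change is from the rest of the genome-wide signal.

The per-population *predictability score* is reported as the log-odds of
the SNP-weighted mean concordance across the quantile grid. The
binomial-error regression of concordance on quantile (weights = SNPs below
threshold) is also fitted and its raw slope returned, but the slope's sign
does not match the quantity of interest — a population whose concordance
sits above 50% over the bulk of the genome can have a flat or negative
slope — so the reported score is anchored directly to the
">50% over the bulk" criterion: it is positive exactly when the weighted
mean concordance exceeds 1/2, zero for a flat 50% curve, and antisymmetric
under mirroring the curve about 50%. Both numbers are always emitted.

Scores are then regressed on environmental covariates. The thermal-limit
model counts, for each population, the days in the 14 calendar days
strictly before the spring collection with Tmax above an upper limit
(`x1`) and before the fall collection with Tmin below a lower limit
(`x2`), and fits `score ~ x1 + x2` by least squares for every limit pair
on a grid from -5 to 40 °C in 0.1 °C steps (451 x 451 models; the grid
R^2 surface is computed in closed form from centred cross-products, so
the scan is one matrix product). The best-fit limits maximize R^2, with
ties broken toward the smallest upper-lower gap. Significance of the
scan maximum is assessed by permuting scores across populations and
re-running the scan per permutation on a 1 °C-coarsened grid (25,000
permutations by default): the maximum is insensitive to 0.1 °C refinement
and the coarse grid keeps the null affordable; a full-grid null is a
parameter away. Other covariates (mean temperatures, growing degree-days,
latitude, longitude, collection method, ...) run through the same
permutation-R^2 machinery with Benjamini–Hochberg adjustment across
models. Growing degree-days use the simple-average formula
`max(0, min((Tmin+Tmax)/2, upper) - base)` with defaults base 10 °C and
cutoff 31 °C (a drosophilid development model; the cited original is not
reproduced in the methods we follow, so the parameters are exposed).
Populations without usable collection dates or station weather are
dropped from the environmental analysis with a logged reason.

# The synthetic-data generator

The generator emulates the study design the pipeline targets: 20 paired
spring/fall populations (default), pools of 75 male flies, read depth
Poisson with mean 94, plus 4 spring-only populations on a latitudinal
transect for the clinal scan. Its knobs are the study conditions:

* **Base frequencies** uniform on [0.05, 0.95] — "common polymorphism"
  ascertainment skews pool-seq SNP sets toward intermediate frequencies.
* **Seasonal SNPs**: a configurable fraction shift additively on the
  frequency scale by 4–8% (drawn per SNP) from spring to fall, direction
  shared across pairs; designated *reversed* pairs flip the sign.
  Frequencies are clipped into `(1/(20 n_flies), 1 - 1/(20 n_flies))`.
* **Clinal SNPs** tilt the base frequency on the logit scale by
  `cline_slope` (default 0.05 per degree) times latitude;
  `clinal_parallel_prob` controls whether a SNP that is both seasonal and
  clinal has its fall-favored allele favored at low latitude.
* **Noise** is exactly two-stage binomial — the error model the `Nc`
  correction assumes — so calibration tests are sharp. Real pool-seq has
  extra library overdispersion; the RFM's robustness to that is tested by
  scaling `Nc` away from truth, not by simulating it.
* **Weather**: daily Tmin/Tmax follow a seasonal sinusoid plus noise,
  except that the 14-day pre-collection windows contain *exactly* the
  requested number of threshold-exceeding days at the generating limits
  (default 32 °C / 5 °C), each at least 0.3 °C clear of the limit so
  nearby scan limits see stable counts. Reversed populations are given
  hot pre-spring and cold pre-fall windows by default, wiring the
  planted reversal to the planted weather.

All randomness derives from one master seed through named sub-streams, so
any stage can be regenerated independently and whole datasets are
byte-reproducible. What the generator does **not** emulate: linkage
disequilibrium and inversion haplotype structure (SNPs are independent),
migration and drift between seasons, shared ancestry among populations,
sequencing error, and beta-binomial overdispersion. Passing recovery
tests on this generator therefore demonstrates the statistics do what
they claim under their own assumptions — not that real data satisfy those
assumptions.

# Numerical choices and degenerate inputs

* IRLS: fitted means clamped to `[1e-10, 1 - 1e-10]`; convergence on
  coefficient updates; 50-iteration cap with a convergence flag.
  Monomorphic SNPs are flagged, not fitted; sites with zero reads in a
  sample get weight 0, frequency `NA` (never a silent 0).
* Exact tests return `NA` when a season has zero reads.
* Rank classes of size 1 map to p = 0.5 under the mid-rank rule; the
  merge floor makes this a corner case rather than a regime.
* `quantile_enrichment` flags a zero median permutation count instead of
  dividing by it.
* Thermal-scan grid cells with constant counts are skipped; R^2 ties are
  resolved by the smallest limit gap and the tie count is reported.
* Region files are BED (0-based half-open); SNP coordinates are 1-based
  (VCF/SYNC). Conversion happens once at the reader boundary and is
  tested at the off-by-one positions.
* Low recombination ("~0 cM/Mb") is implemented as rate < 0.5 cM/Mb by
  default and configurable — a hard zero would be brittle against map
  precision.
* The median-frequency filter uses the median *minor*-allele frequency
  across samples, so alt-fixed sites are removed symmetrically with
  ref-fixed ones. The filter order is: indel proximity, repeats, median
  frequency, recombination, multi-allelic, X removal, depth,
  polymorphic-in-all; counts are reported per rule and filtering is
  idempotent.

# Problem sizes in the shipped tests

The test suite exercises calibration at 20,000 null SNPs (RFM mean and
distribution), null concordance and power/recovery at 10^5 SNPs with 100
within-pair permutations, thermal-scan recovery on 15 populations across
10 replicate seeds with 2,000-permutation nulls, and matched-control
contracts at 8,000 SNPs — sizes chosen so the full suite runs on a
single CPU in well under half an hour while keeping Monte-Carlo error
far from the asserted tolerances. The acceptance script recomputes the
RFM null-mean calibration on a fresh 20,000-SNP simulation at the full
20-pair design.

# Known limitations

* The GLM's `Nc` weights understate true pool-seq variance; its absolute
  p-values should not be taken at face value (use the permutation null,
  as the pipeline does).
* The RFM statistic conditions on read-count classes per pair; with very
  few SNPs (< a few thousand) the classes are coarse and the chi-squared
  null degrades.
* Matched-control quality depends on SNP density within matching cells;
  at small SNP counts most focals are discarded by the 10-candidate rule.
* The thermal scan's grid search with 15 populations can plateau: counts
  are step functions of the limits, so best-fit limits are identified up
  to the margin structure of the data (the generator plants a 0.3 °C
  guard band for exactly this reason).
* Weather handling assumes one relevant station per locality
  (nearest-station matching by great-circle distance) and complete daily
  series in the windows; missing days are counted and reported, not
  imputed.
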