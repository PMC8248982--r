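test_that("effective coverage follows the two-stage sampling formula", {
  expect_equal(effective_coverage(150, 75), 50)
  expect_equal(effective_coverage(100, 100), 50)
  expect_equal(effective_coverage(2, 1e9), 2, tolerance = 1e-6)
  expect_error(effective_coverage(0, 10), "positive")
  expect_error(effective_coverage(10, -1), "positive")
})

test_that("effective coverage is symmetric and bounded by min(N, R)", {
  set.seed(11)
  N <- runif(200, 1, 500); R <- runif(200, 1, 500)
  expect_equal(effective_coverage(N, R), effective_coverage(R, N))
  expect_true(all(effective_coverage(N, R) <= pmin(N, R)))
})

test_that("pool chromosome counting doubles male autosomal pools", {
  expect_identical(pool_chromosomes(75), 150L)
  expect_identical(pool_chromosomes(1), 2L)
  expect_identical(pool_chromosomes(27), 54L)
  expect_error(pool_chromosomes(75, "haploid"), "unsupported")
  expect_error(pool_chromosomes(0), ">= 1")
})

test_that("allele frequency handles zero totals as missing, never zero", {
  expect_equal(allele_frequency(50, 50), 0.5)
  expect_equal(allele_frequency(100, 0), 0)
  expect_true(is.na(allele_frequency(0, 0)))
  expect_error(allele_frequency(-1, 5), "negative")
})

test_that("snp_table validates shape, ordering and duplicates", {
  tbl <- toy_two_pair_table()
  expect_equal(n_snps(tbl), 3)
  expect_equal(dim(tbl), c(3L, 4L))
  snps <- tbl$snps[c(2, 1, 3), ]
  re <- snp_table(snps, tbl$ref_count[c(2, 1, 3), ], tbl$alt_count[c(2, 1, 3), ])
  expect_equal(re$snps$pos, c(100L, 200L, 300L))  # re-sorted
  snps2 <- tbl$snps; snps2$pos[2] <- 100L
  expect_error(snp_table(snps2, tbl$ref_count, tbl$alt_count), "duplicated")
  expect_error(snp_table(tbl$snps, -tbl$ref_count, tbl$alt_count), "negative")
})

test_that("TSV allele counts round-trip exactly", {
  tbl <- toy_two_pair_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_allele_counts(tbl, path)
  back <- read_allele_counts(path)
  expect_identical(back$snps$pos, tbl$snps$pos)
  expect_equal(unname(back$ref_count), unname(tbl$ref_count))
  expect_equal(unname(back$alt_count), unname(tbl$alt_count))
  expect_identical(sample_ids(back), sample_ids(tbl))
})

test_that("SYNC reading maps nucleotide fields and flags multi-allelics", {
  path <- withr::local_tempfile(fileext = ".sync")
  writeLines(c("## seasonscan sync v1",
               "#chrom\tpos\tref\ts1\ts2",
               "2L\t100\tA\t10:0:5:0:0:0\t8:0:7:0:0:0",
               "2L\t200\tA\t5:3:4:0:0:0\t6:2:5:0:0:0",
               "2R\t50\tG\t0:0:10:0:0:0\t0:0:4:6:0:0"), path)
  tbl <- read_allele_counts(path, format = "sync")
  expect_equal(n_snps(tbl), 3)
  expect_identical(sample_ids(tbl), c("s1", "s2"))
  # A ref, C alt at 2L:100
  expect_equal(tbl$ref_count[tbl$snps$pos == 100, ], c(s1 = 10, s2 = 8))
  expect_equal(tbl$alt_count[tbl$snps$pos == 100, ], c(s1 = 5, s2 = 7))
  # 2L:200 has A, T and C segregating; the others have exactly two alleles
  expect_equal(tbl$snps$multiallelic, c(FALSE, TRUE, FALSE))
  # round-trip through the SYNC writer preserves biallelic counts
  out <- withr::local_tempfile(fileext = ".sync")
  write_allele_counts(tbl, out, format = "sync")
  back <- read_allele_counts(out, format = "sync")
  expect_equal(unname(back$alt_count), unname(tbl$alt_count))
})

test_that("malformed inputs produce parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".sync")
  writeLines(c("2L\t100\tA\t10:0:5:0:0:0", "2L\t200\tA\t10:0:5"), path)
  expect_error(read_allele_counts(path, format = "sync", sample_ids = "s1"),
               "line 2")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref_allele\talt_allele\ts1_ref\ts1_alt",
               "2L\t100\tA\tC\t-3\t5"), tsv)
  expect_error(read_allele_counts(tsv), "negative")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tpos\tref_allele\talt_allele\ts1_ref\ts1_alt", empty)
  expect_warning(tb <- read_allele_counts(empty), "empty")
  expect_equal(n_snps(tb), 0)
})

test_that("sample sheet completes month-only dates and validates fields", {
  expect_equal(complete_month_date("2012-07"), as.Date("2012-07-15"))
  expect_equal(complete_month_date("2012-07-03"), as.Date("2012-07-03"))
  sheet <- toy_two_pair_sheet()
  expect_equal(sheet$collection_date[1], as.Date("2012-06-15"))
  bad <- data.frame(sample_id = "x", locality = "l", latitude = 95,
                    longitude = 0, season = "spring", year = 2012,
                    collection_date = "2012-06-01", n_flies = 10)
  expect_error(sample_sheet(bad), "latitude")
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_sheet(sheet, path)
  back <- read_sample_sheet(path)
  expect_equal(back$collection_date, sheet$collection_date)
  expect_equal(back$latitude, sheet$latitude)
  nohdr <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,locality\nx,l", nohdr)
  expect_error(read_sample_sheet(nohdr), "latitude")
})

test_that("season pairing requires exactly one spring and one fall per locality-year", {
  sheet <- toy_two_pair_sheet()
  pr <- season_pairs(sheet)
  expect_equal(nrow(pr), 2)
  expect_equal(pr$spring_id[pr$locality == "p1"], "p1_spring")
  unpaired <- sheet[-4, ]
  expect_error(season_pairs(unpaired), "exactly one spring and one fall")
})

test_that("BED regions are read 0-based half-open and queried with 1-based SNPs", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("2L\t0\t100", "2L\t500\t600"), path)
  rs <- read_regions(path)
  expect_equal(rs$intervals$start, c(0L, 500L))
  # 1-based position 100 is the last base of [0,100); 101 is outside
  expect_equal(in_regions(rep("2L", 4), c(1L, 100L, 101L, 501L), rs),
               c(TRUE, TRUE, FALSE, TRUE))
  expect_error(region_set(data.frame(chrom = "2L", start = 10, end = 10)),
               "start must be <")
})

test_that("recombination map lookups respect window boundaries", {
  rm <- recomb_map(data.frame(chrom = "2L", start = c(0, 1000),
                              end = c(1000, 2000), rate = c(0.1, 3)))
  expect_equal(recomb_rate_at(c("2L", "2L", "2L"), c(500L, 1500L, 2500L), rm),
               c(0.1, 3, NA))
  expect_error(recomb_map(data.frame(chrom = "2L", start = c(0, 500),
                                     end = c(1000, 1500), rate = 1)),
               "overlapping")
})

test_that("the filtering cascade applies each rule and reports counts", {
  # 5 SNPs: #1 near an indel, #2 in a repeat, #3 rare everywhere,
  # #4 multiallelic, #5 clean
  snps <- data.frame(chrom = "2L", pos = c(100L, 210L, 300L, 400L, 500L),
                     ref_allele = "A", alt_allele = "C",
                     multiallelic = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  alt <- rbind(c(50, 50), c(50, 50), c(0, 1), c(50, 50), c(40, 60))
  ref <- 100 - alt
  colnames(alt) <- colnames(ref) <- c("s1", "s2")
  tbl <- snp_table(snps, ref, alt)
  repeats <- region_set(data.frame(chrom = "2L", start = 200L, end = 250L))
  indels <- data.frame(chrom = "2L", pos = 105L)
  res <- filter_snps(tbl, filter_config(), repeats = repeats,
                     indel_positions = indels)
  expect_equal(n_snps(res$table), 1)
  expect_equal(res$table$snps$pos, 500L)
  expect_equal(unname(res$removed[c("indel_proximity", "repeats", "median_freq",
                                    "multiallelic")]),
               c(1L, 1L, 1L, 1L))
  # indel buffer boundary: pos 100 with indel at 105 is within 10 bp
  expect_equal(unname(res$removed["indel_proximity"]), 1L)
})

test_that("filtering removes X SNPs, low-recombination windows and non-polymorphic sites", {
  snps <- data.frame(chrom = c("2L", "2L", "X"), pos = c(100L, 5000L, 100L),
                     ref_allele = "A", alt_allele = "C")
  alt <- rbind(c(50, 50), c(50, 100), c(50, 50))
  ref <- 100 - alt   # SNP2 sample2 has freq 1 -> not polymorphic everywhere
  colnames(alt) <- colnames(ref) <- c("s1", "s2")
  tbl <- snp_table(snps, ref, alt)
  rm <- recomb_map(data.frame(chrom = "2L", start = c(0, 1000),
                              end = c(1000, 10000), rate = c(0.1, 2)))
  res <- filter_snps(tbl, filter_config(min_median_freq = 0), rmap = rm)
  expect_equal(unname(res$removed[c("low_recomb", "x_chromosome",
                                    "not_polymorphic_all")]),
               c(1L, 1L, 1L))
  expect_equal(n_snps(res$table), 0)
})

test_that("filtering is idempotent", {
  m <- sim_pair_matrices(300, n_pairs = 4, seed = 3)
  ds <- matrices_to_dataset(m)
  res1 <- filter_snps(ds$table, filter_config())
  res2 <- filter_snps(res1$table, filter_config())
  expect_equal(sum(res2$removed), 0L)
  expect_equal(n_snps(res2$table), n_snps(res1$table))
})

test_that("coordinate-system mismatch against the recombination map errors", {
  tbl <- toy_two_pair_table()
  rm <- recomb_map(data.frame(chrom = "2L", start = 0, end = 150, rate = 2))
  expect_error(filter_snps(tbl, filter_config(), rmap = rm), "mismatch")
})
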