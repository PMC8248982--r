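test_that("region classification places the canonical coordinates", {
  expect_equal(as.character(classify_region("2L", 2225744L)), "breakpoint")
  expect_equal(as.character(classify_region("2L", 8000000L)), "inside")
  expect_equal(as.character(classify_region("2R", 1000000L)), "outside")
  # 3R inversions are merged: In(3R)K start .. In(3R)Mo stop is one span
  expect_equal(as.character(classify_region("3R", 15000000L)), "inside")
  expect_error(classify_region("4", 100L), "unknown chromosome")
})

test_that("region classification is a partition over every autosomal SNP", {
  set.seed(51)
  chrom <- sample(c("2L", "2R", "3L", "3R"), 5000, replace = TRUE)
  pos <- sample.int(2e7, 5000)
  lab <- classify_region(chrom, pos)
  expect_false(anyNA(lab))
  expect_equal(sum(table(lab)), 5000)
  # buffer flag respected
  lab2 <- classify_region("2L", 2225744L + 600000L, buffer_bp = 500000L)
  expect_equal(as.character(lab2), "inside")
  lab3 <- classify_region("2L", 2225744L + 600000L, buffer_bp = 1000000L)
  expect_equal(as.character(lab3), "breakpoint")
})

test_that("control_interval returns the 3rd and 98th ranked values at n = 100", {
  expect_equal(unname(control_interval(1:100)), c(3, 98))
  expect_equal(unname(control_interval(100:1)), c(3, 98))
  expect_equal(unname(control_interval(rep(7, 100))), c(7, 7))
  expect_equal(unname(control_interval(1:50)), c(round(0.03 * 50), round(0.98 * 50)))
  expect_error(control_interval(1:4), "at least 5")
})

test_that("matched controls honor hard constraints and the candidate floor", {
  set.seed(52)
  n <- 8000
  covars <- data.frame(
    chrom = sample(c("2L", "2R"), n, replace = TRUE),
    nc = runif(n, 40, 70),
    med_spring_freq = runif(n, 0.3, 0.4),
    inversion = sample(c("in", "out"), n, replace = TRUE),
    recomb = sample(c(0.2, 1.2), n, replace = TRUE))
  # an isolated focal SNP: unique chromosome, nothing can match it
  covars <- rbind(covars,
                  data.frame(chrom = "3L", nc = 50, med_spring_freq = 0.5,
                             inversion = "in", recomb = 1))
  focal <- c(sample.int(n, 40), n + 1L)
  mc <- matched_controls(focal, covars, match_spec(n_sets = 100, seed = 9))
  expect_true((n + 1L) %in% mc$discarded)
  expect_equal(ncol(mc$sets), 100)
  expect_equal(nrow(mc$sets), length(mc$retained))
  # hard constraints hold in all 100 sets, and the focal never matches itself
  for (k in seq_along(mc$retained)) {
    ctrl <- mc$sets[k, ]
    expect_false(any(ctrl == mc$retained[k]))
    expect_true(all(covars$chrom[ctrl] == covars$chrom[mc$retained[k]]))
    expect_true(all(covars$inversion[ctrl] == covars$inversion[mc$retained[k]]))
  }
  # determinism from the match_spec seed
  mc2 <- matched_controls(focal, covars, match_spec(n_sets = 100, seed = 9))
  expect_identical(mc$sets, mc2$sets)
  mc3 <- matched_controls(focal, covars, match_spec(n_sets = 100, seed = 10))
  expect_false(identical(mc$sets, mc3$sets))
})

test_that("matched controls preserve the soft covariate distributions", {
  set.seed(53)
  n <- 5000
  covars <- data.frame(chrom = "2L",
                       nc = runif(n, 40, 70),
                       med_spring_freq = runif(n, 0.1, 0.9),
                       inversion = "out", recomb = 1)
  spec <- match_spec(n_sets = 50, seed = 3)
  focal <- sample.int(n, 200)
  mc <- matched_controls(focal, covars, spec)
  foc_nc <- mean(covars$nc[mc$retained])
  foc_f <- mean(covars$med_spring_freq[mc$retained])
  set_nc <- apply(mc$sets, 2, function(i) mean(covars$nc[i]))
  set_f <- apply(mc$sets, 2, function(i) mean(covars$med_spring_freq[i]))
  expect_true(all(abs(set_nc - foc_nc) < spec$nc_bin))
  expect_true(all(abs(set_f - foc_f) < spec$freq_bin))
})

test_that("region enrichment is calibrated on null data and finds planted regions", {
  set.seed(54)
  n <- 6000
  chrom <- sample(c("2L", "2R"), n, replace = TRUE)
  region <- factor(sample(c("breakpoint", "inside", "outside"), n, replace = TRUE),
                   levels = c("breakpoint", "inside", "outside"))
  obs <- runif(n)
  perm <- matrix(runif(n * 50), n)
  re <- region_enrichment(obs, perm, region, chrom, q = 0.05)
  expect_true(all(abs(re$enrichment - 1) < 0.8))
  expect_lt(mean(re$significant), 0.3)
  # plant signal only in 2L breakpoints
  hot <- chrom == "2L" & region == "breakpoint"
  obs2 <- obs; obs2[hot] <- obs2[hot] / 50
  re2 <- region_enrichment(obs2, perm, region, chrom, q = 0.05)
  top <- re2[which.max(re2$enrichment), ]
  expect_equal(paste(top$chrom, top$region), "2L breakpoint")
  expect_true(top$significant)
})
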