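# The package's own vectorized IRLS is checked against stats::glm, an
# independent implementation of the same weighted binomial regression.

glm_oracle_season <- function(ys, yf, ws, wf, i) {
  P <- ncol(ys)
  y <- c(ys[i, ], yf[i, ]); w <- c(ws[i, ], wf[i, ])
  season <- rep(c(0, 1), each = P); pop <- factor(rep(seq_len(P), 2))
  fit <- suppressWarnings(glm(y ~ pop + season, family = binomial(), weights = w))
  unname(summary(fit)$coefficients["season", c(1, 4)])
}

test_that("seasonal GLM matches the independent reference to >= 6 decimals", {
  # fixture 1: the 2-pair toy with N=150, R=100 (Nc = 60 per cell)
  ys <- rbind(c(40, 45) / 100); yf <- rbind(c(60, 55) / 100)
  w <- matrix(effective_coverage(150, 100), 1, 2)
  fit <- fit_season_glm(ys, yf, w, w)
  o <- glm_oracle_season(ys, yf, w, w, 1)
  expect_equal(fit$coef[1], o[1], tolerance = 1e-9)
  expect_lt(abs(fit$p[1] - o[2]), 1e-6)

  # fixtures 2-3: unequal depths and pair counts
  set.seed(21)
  for (P in c(5, 12)) {
    ys <- matrix(runif(P, 0.1, 0.9), 1)
    yf <- pmin(pmax(ys + rnorm(P, 0, 0.08), 0.02), 0.98)
    ws <- matrix(effective_coverage(150, rpois(P, 90) + 5), 1)
    wf <- matrix(effective_coverage(150, rpois(P, 90) + 5), 1)
    fit <- fit_season_glm(ys, yf, ws, wf)
    o <- glm_oracle_season(ys, yf, ws, wf, 1)
    expect_equal(fit$coef[1], o[1], tolerance = 1e-8)
    expect_lt(abs(fit$p[1] - o[2]), 1e-6)
  }
})

test_that("clinal GLM matches the independent reference to >= 6 decimals", {
  lat <- c(25.5, 30.1, 33.4, 39.9)
  set.seed(22)
  y <- matrix(runif(3 * 4, 0.15, 0.85), 3)
  w <- matrix(effective_coverage(150, rpois(12, 90) + 5), 3)
  fit <- fit_latitude_glm(y, w, lat)
  for (i in 1:3) {
    g <- suppressWarnings(glm(y[i, ] ~ lat, family = binomial(), weights = w[i, ]))
    s <- summary(g)$coefficients["lat", ]
    expect_equal(fit$coef[i], unname(s[1]), tolerance = 1e-8)
    expect_lt(abs(fit$p[i] - unname(s[4])), 1e-6)
  }
})

test_that("a null fit returns coefficient 0 and p = 1", {
  ys <- rbind(c(0.4, 0.6, 0.5)); w <- matrix(50, 1, 3)
  fit <- fit_season_glm(ys, ys, w, w)
  expect_equal(fit$coef[1], 0, tolerance = 1e-10)
  expect_equal(fit$p[1], 1, tolerance = 1e-10)
})

test_that("swapping all season labels negates the coefficient, keeps p", {
  set.seed(23)
  m <- sim_pair_matrices(50, n_pairs = 6)
  a <- fit_season_glm(m$ys, m$yf, m$ws, m$wf)
  b <- fit_season_glm(m$yf, m$ys, m$wf, m$ws)
  expect_equal(a$coef, -b$coef, tolerance = 1e-8)
  expect_equal(a$p, b$p, tolerance = 1e-8)
  # flips argument realizes the same swap
  d <- fit_season_glm(m$ys, m$yf, m$ws, m$wf, flips = rep(TRUE, 6))
  expect_equal(d$coef, b$coef, tolerance = 1e-12)
})

test_that("negating latitudes negates the clinal coefficient, keeps p", {
  set.seed(24)
  lat <- c(25, 32, 38, 44)
  y <- matrix(runif(20 * 4, 0.2, 0.8), 20)
  w <- matrix(60, 20, 4)
  a <- fit_latitude_glm(y, w, lat)
  b <- fit_latitude_glm(y, w, -lat)
  expect_equal(a$coef, -b$coef, tolerance = 1e-8)
  expect_equal(a$p, b$p, tolerance = 1e-8)
  expect_error(fit_latitude_glm(y, w, rep(30, 4)), "constant")
})

test_that("degenerate SNPs (fixed everywhere) are flagged missing", {
  ys <- rbind(c(0, 0, 0), c(1, 1, 1), c(0.5, 0.4, 0.6))
  w <- matrix(50, 3, 3)
  fit <- fit_season_glm(ys, ys, w, w)
  expect_true(all(fit$degenerate[1:2]))
  expect_false(fit$degenerate[3])
  expect_true(all(is.na(fit$coef[1:2])))
})

test_that("glm_seasonal wires tables, sheets and per-pair signs together", {
  tbl <- toy_two_pair_table()
  sheet <- toy_two_pair_sheet()
  res <- glm_seasonal(tbl, sheet)
  expect_equal(nrow(res), 3)
  ps <- attr(res, "pair_sign")
  expect_equal(dim(ps), c(3L, 2L))
  expect_equal(unname(ps[1, ]), c(1, 1))   # alt rises in both pairs
  expect_equal(unname(ps[2, ]), c(0, 0))
  expect_gt(res$glm_coef[1], 0)
  expect_equal(res$glm_p[2], 1, tolerance = 1e-9)
  expect_error(glm_seasonal(tbl, sheet, season_pairs(sheet)[1, ]), "2 spring/fall")
})
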