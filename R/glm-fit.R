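## Vectorized weighted binomial IRLS fitters.
##
## The seasonal model (per SNP): logit E[y] = population intercept + b*fall,
## fitted by IRLS. Because the population factor gives the weighted
## least-squares system an arrow structure (diagonal block for the
## population intercepts, one extra row/column for the season effect), each
## IRLS step reduces to a Schur complement with closed form: with working
## weights Ws/Wf and working responses zs/zf per (SNP, population),
##   b  = sum_k h_k (zf_k - zs_k) / sum_k h_k,   h_k = Ws_k Wf_k/(Ws_k+Wf_k)
##   a_k = (Ws_k zs_k + Wf_k (zf_k - b)) / (Ws_k + Wf_k)
## and Var(b) = 1/sum_k h_k (the (b,b) entry of (X'WX)^-1). Every quantity
## is a SNPs x populations matrix, so the whole genome is fitted with a
## handful of elementwise matrix operations per iteration -- the same
## estimates and Wald tests as stats::glm, at genome scale. The inner loop
## avoids ifelse()/deviance bookkeeping deliberately: the permutation null
## refits this model hundreds of times.

MU_EPS <- 1e-10

clamp_mu <- function(eta) {
  mu <- 1 / (1 + exp(-eta))
  pmin(pmax(mu, MU_EPS), 1 - MU_EPS)
}

#' Fit the paired seasonal binomial GLM across all SNPs at once
#'
#' Low-level fitter: allele frequencies and effective-coverage weights come
#' as SNPs x populations matrices, one column per spring/fall pair. The
#' model is `logit(freq) ~ population + season` with binomial error and
#' prior weights equal to the effective coverage; the returned p-value is
#' the two-sided Wald test of the season term (fall vs spring, on the
#' log-odds scale of the alternate allele).
#'
#' @param ys,yf spring and fall alternate-allele frequencies (SNPs x pairs).
#' @param ws,wf effective coverages (same shape); `NA` or 0 drops the cell.
#' @param flips optional logical vector (length = pairs): pairs whose
#'   spring/fall labels are exchanged (the within-pair permutation move).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the coefficient updates (root sum
#'   of squared changes across all parameters of a SNP).
#' @return list of per-SNP vectors: `coef`, `se`, `p`, `converged`,
#'   `degenerate` (all frequencies 0 or all 1 -> estimates are `NA`).
#' @export
fit_season_glm <- function(ys, yf, ws, wf, flips = NULL,
                           max_iter = 50L, tol = 1e-9) {
  stopifnot(is.matrix(ys), identical(dim(ys), dim(yf)),
            identical(dim(ys), dim(ws)), identical(dim(ys), dim(wf)))
  if (!is.null(flips)) {
    stopifnot(length(flips) == ncol(ys))
    if (any(flips)) {
      tmp <- ys[, flips, drop = FALSE]
      ys[, flips] <- yf[, flips, drop = FALSE]; yf[, flips] <- tmp
      tmp <- ws[, flips, drop = FALSE]
      ws[, flips] <- wf[, flips, drop = FALSE]; wf[, flips] <- tmp
    }
  }
  if (anyNA(ws) || anyNA(ys)) { ws[is.na(ws) | is.na(ys)] <- 0; ys[ws == 0] <- 0.5 }
  if (anyNA(wf) || anyNA(yf)) { wf[is.na(wf) | is.na(yf)] <- 0; yf[wf == 0] <- 0.5 }
  n <- nrow(ys)

  # degenerate: every weighted observation at 0 (or every one at 1)
  all0 <- rowSums(ws * (ys > 0)) + rowSums(wf * (yf > 0)) == 0
  all1 <- rowSums(ws * (ys < 1)) + rowSums(wf * (yf < 1)) == 0
  degen <- all0 | all1 | rowSums(ws) + rowSums(wf) == 0

  mus0 <- pmin(pmax((ys * ws + 0.5) / (ws + 1), MU_EPS), 1 - MU_EPS)
  muf0 <- pmin(pmax((yf * wf + 0.5) / (wf + 1), MU_EPS), 1 - MU_EPS)
  state <- list(
    mus = mus0, muf = muf0,
    etas = log(mus0 / (1 - mus0)), etaf = log(muf0 / (1 - muf0)),
    b = numeric(n), a = matrix(0, n, ncol(ys)), H = numeric(n),
    done = rep(FALSE, n))
  one_iter <- function(s, ys, yf, ws, wf) {
    vs <- s$mus * (1 - s$mus); vf <- s$muf * (1 - s$muf)
    Ws <- ws * vs; Wf <- wf * vf
    zs <- s$etas + (ys - s$mus) / vs
    zf <- s$etaf + (yf - s$muf) / vf
    sw <- Ws + Wf
    h <- Ws * Wf / sw
    if (anyNA(h)) h[is.na(h)] <- 0            # cells where both weights are 0
    H <- rowSums(h)
    b_new <- rowSums(h * (zf - zs)) / H
    if (anyNA(b_new)) b_new[is.na(b_new)] <- 0
    a_new <- (Ws * zs + Wf * (zf - b_new)) / sw
    if (anyNA(a_new)) a_new[is.na(a_new)] <- 0
    delta <- (b_new - s$b)^2 + rowSums((a_new - s$a)^2)
    etaf_new <- a_new + b_new        # length-n vector recycles along rows
    list(mus = clamp_mu(a_new), muf = clamp_mu(etaf_new),
         etas = a_new, etaf = etaf_new,
         b = b_new, a = a_new, H = H, done = s$done | delta < tol^2)
  }
  # phase 1: full-matrix sweeps while most SNPs are still moving; phase 2:
  # compact to the stragglers (boundary-frequency sites needing many steps)
  # so they do not drag the whole genome through extra sweeps
  it <- 0L
  while (it < max_iter && mean(state$done | degen) < 0.5) {
    state <- one_iter(state, ys, yf, ws, wf)
    it <- it + 1L
  }
  act <- which(!state$done & !degen)
  if (length(act) && it < max_iter) {
    sub <- list(mus = state$mus[act, , drop = FALSE],
                muf = state$muf[act, , drop = FALSE],
                etas = state$etas[act, , drop = FALSE],
                etaf = state$etaf[act, , drop = FALSE],
                b = state$b[act], a = state$a[act, , drop = FALSE],
                H = state$H[act], done = state$done[act])
    ys_a <- ys[act, , drop = FALSE]; yf_a <- yf[act, , drop = FALSE]
    ws_a <- ws[act, , drop = FALSE]; wf_a <- wf[act, , drop = FALSE]
    while (it < max_iter && length(act)) {
      sub <- one_iter(sub, ys_a, yf_a, ws_a, wf_a)
      it <- it + 1L
      state$b[act] <- sub$b; state$a[act, ] <- sub$a
      state$H[act] <- sub$H; state$done[act] <- sub$done
      if (any(sub$done)) {
        keep <- !sub$done
        act <- act[keep]
        sub <- list(mus = sub$mus[keep, , drop = FALSE],
                    muf = sub$muf[keep, , drop = FALSE],
                    etas = sub$etas[keep, , drop = FALSE],
                    etaf = sub$etaf[keep, , drop = FALSE],
                    b = sub$b[keep], a = sub$a[keep, , drop = FALSE],
                    H = sub$H[keep], done = sub$done[keep])
        ys_a <- ys_a[keep, , drop = FALSE]; yf_a <- yf_a[keep, , drop = FALSE]
        ws_a <- ws_a[keep, , drop = FALSE]; wf_a <- wf_a[keep, , drop = FALSE]
      }
    }
  }
  b <- state$b; conv <- state$done
  se <- 1 / sqrt(state$H)
  se[!(state$H > 0)] <- NA_real_
  b[degen] <- NA_real_; se[degen] <- NA_real_
  p <- 2 * pnorm(-abs(b / se))
  list(coef = b, se = se, p = p, converged = conv & !degen, degenerate = degen)
}

#' Fit the latitudinal binomial GLM across all SNPs at once
#'
#' `logit(freq) ~ latitude` with binomial error and effective-coverage
#' weights, fitted by vectorized IRLS (one 2x2 weighted least-squares solve
#' per SNP per iteration, done in closed form). The coefficient is the
#' change in log-odds of the alternate allele per degree of latitude.
#'
#' @param y alternate-allele frequencies (SNPs x samples).
#' @param w effective coverages (same shape).
#' @param latitude numeric vector, one latitude per sample.
#' @inheritParams fit_season_glm
#' @return list of per-SNP vectors as in [fit_season_glm()].
#' @export
fit_latitude_glm <- function(y, w, latitude, max_iter = 50L, tol = 1e-9) {
  stopifnot(is.matrix(y), identical(dim(y), dim(w)),
            length(latitude) == ncol(y))
  if (length(unique(latitude)) < 2)
    stop_invalid("fit_latitude_glm: latitude is constant across samples")
  if (anyNA(w) || anyNA(y)) { w[is.na(w) | is.na(y)] <- 0; y[w == 0] <- 0.5 }
  n <- nrow(y)
  lat <- matrix(latitude, n, ncol(y), byrow = TRUE)
  all0 <- rowSums(w * (y > 0)) == 0
  all1 <- rowSums(w * (y < 1)) == 0
  degen <- all0 | all1 | rowSums(w) == 0

  mu <- pmin(pmax((y * w + 0.5) / (w + 1), MU_EPS), 1 - MU_EPS)
  eta <- log(mu / (1 - mu))
  b <- numeric(n); a0 <- numeric(n)
  conv <- rep(FALSE, n)
  det_ <- NULL; S0 <- NULL
  for (it in seq_len(max_iter)) {
    v <- mu * (1 - mu)
    W <- w * v
    z <- eta + (y - mu) / v
    S0 <- rowSums(W); S1 <- rowSums(W * lat); S2 <- rowSums(W * lat^2)
    t0 <- rowSums(W * z); t1 <- rowSums(W * lat * z)
    det_ <- S0 * S2 - S1^2
    b_new <- (S0 * t1 - S1 * t0) / det_
    bad <- !(det_ > 0)
    if (any(bad)) b_new[bad] <- 0
    a_new <- (t0 - S1 * b_new) / S0
    if (anyNA(a_new)) a_new[is.na(a_new)] <- 0
    delta <- (b_new - b)^2 + (a_new - a0)^2
    b <- b_new; a0 <- a_new
    eta <- a0 + b * lat
    mu <- clamp_mu(eta)
    done <- delta < tol^2
    conv <- conv | done
    if (all(done | degen)) break
  }
  se <- sqrt(S0 / det_)
  se[!(det_ > 0)] <- NA_real_
  b[degen] <- NA_real_; se[degen] <- NA_real_
  p <- 2 * pnorm(-abs(b / se))
  list(coef = b, se = se, p = p, converged = conv & !degen, degenerate = degen)
}
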