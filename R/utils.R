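#' @import data.table
#' @importFrom stats glm binomial coef pchisq pnorm phyper plogis qlogis
#'   quantile median rbinom runif rnorm rpois setNames complete.cases
#'   binom.test pbinom qbinom lm as.formula model.matrix p.adjust var
#' @importFrom utils head write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed and a stage name
#'
#' All randomness in the package flows from one master seed; each stage
#' (frequency simulation, pool sampling, weather, permutations, control
#' resampling) draws from its own named sub-stream so stages can be
#' regenerated independently without disturbing one another.
#'
#' @param seed master integer seed.
#' @param name character stage name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 2654435 %% 2147483647) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

msg <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))
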