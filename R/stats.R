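#' Exact (Clopper-Pearson) binomial confidence intervals
#'
#' Computes the exact binomial confidence interval for a proportion from the
#' variant read count `v` and the total read depth `n`, the estimator used for
#' mtDNA heteroplasmy (the variant-read fraction v/n). Bounds come from the
#' beta-quantile inversion of the binomial tails, so the interval has
#' guaranteed coverage at the nominal level: the lower bound solves
#' P(X >= v | n, p) = (1 - level)/2 (0 when v = 0) and the upper bound solves
#' P(X <= v | n, p) = (1 - level)/2 (1 when v = n).
#'
#' @param v Integer vector of success (variant read) counts, `0 <= v <= n`.
#' @param n Integer vector of trials (total read depth), `n >= 1`. Recycled
#'   against `v`.
#' @param level Confidence level, default 0.95.
#' @return A tibble with one row per input: `v`, `n`, `estimate` (v/n),
#'   `conf.low`, `conf.high`, `level`.
#' @examples
#' clopper_pearson(3, 17)          # the 18% (4-43%) heteroplasmy interval
#' clopper_pearson(1:9, 10)
#' @export
clopper_pearson <- function(v, n, level = 0.95) {
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1) {
    rlang::abort("`level` must be a single value in (0, 1).")
  }
  m <- vctrs_recycle2(v, n)
  v <- m[[1]]; n <- m[[2]]
  if (any(!is.finite(v)) || any(!is.finite(n))) {
    rlang::abort("`v` and `n` must be finite.")
  }
  if (any(n < 1)) rlang::abort("`n` must be >= 1.")
  if (any(v < 0) || any(v > n)) rlang::abort("`v` must satisfy 0 <= v <= n.")
  alpha <- (1 - level) / 2
  low <- ifelse(v == 0, 0, stats::qbeta(alpha, v, n - v + 1))
  high <- ifelse(v == n, 1, stats::qbeta(1 - alpha, v + 1, n - v))
  tibble::tibble(
    v = as.integer(v), n = as.integer(n),
    estimate = v / n,
    conf.low = low, conf.high = high,
    level = level
  )
}

#' Exact Poisson rate-ratio test
#'
#' Tests whether two Poisson processes have the same event rate, given event
#' counts and base-pair exposures for each. Conditional on the total count
#' `count_a + count_b`, `count_a` is Binomial with success probability
#' `exposure_a / (exposure_a + exposure_b)` under a rate ratio of 1; the
#' two-sided p-value sums every binomial point probability not exceeding that
#' of the observed count (the minimum-likelihood method). This is the test
#' used to compare per-base discordance rates between sequencing platforms.
#'
#' @param count_a,count_b Non-negative event counts (e.g. unconfirmed
#'   discordant base calls per platform).
#' @param exposure_a,exposure_b Positive exposures (e.g. total bases
#'   sequenced on each platform).
#' @return An object of class `rate_ratio_test` with components `estimate`
#'   (the rate ratio (count_a/exposure_a)/(count_b/exposure_b)), `p.value`,
#'   the inputs, and the conditional null probability `p0`. `tidy()` and
#'   `glance()` methods return one-row tibbles.
#' @examples
#' poisson_ratio_test(24, 10, 762174, 762174)  # P = 0.02431
#' poisson_ratio_test(2, 10, 761714, 761714)   # P = 0.03857 (= 158/4096)
#' @export
poisson_ratio_test <- function(count_a, count_b, exposure_a, exposure_b) {
  for (x in list(count_a, count_b, exposure_a, exposure_b)) {
    if (length(x) != 1L || !is.finite(x)) {
      rlang::abort("counts and exposures must be finite scalars.")
    }
  }
  if (count_a < 0 || count_b < 0) rlang::abort("counts must be >= 0.")
  if (exposure_a <= 0 || exposure_b <= 0) rlang::abort("exposures must be > 0.")
  total <- count_a + count_b
  if (total < 1) {
    rlang::abort("undefined test: count_a + count_b must be >= 1.")
  }
  p0 <- exposure_a / (exposure_a + exposure_b)
  # minimum-likelihood two-sided tail: include every outcome whose point
  # probability does not exceed the observed one (relative 1e-7 slack guards
  # against floating-point ties, as base binom.test does)
  d <- stats::dbinom(0:total, total, p0)
  p <- sum(d[d <= d[count_a + 1] * (1 + 1e-7)])
  p <- min(1, p)
  rate_a <- count_a / exposure_a
  rate_b <- count_b / exposure_b
  structure(
    list(
      estimate = rate_a / rate_b,
      p.value = p,
      count_a = count_a, count_b = count_b,
      exposure_a = exposure_a, exposure_b = exposure_b,
      rate_a = rate_a, rate_b = rate_b,
      p0 = p0,
      method = "Exact Poisson rate-ratio test (conditional binomial, minimum likelihood)"
    ),
    class = "rate_ratio_test"
  )
}

#' @export
print.rate_ratio_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("counts: %g vs %g   exposures: %g vs %g\n",
              x$count_a, x$count_b, x$exposure_a, x$exposure_b))
  cat(sprintf("rate ratio = %.4g, p-value = %.4g\n", x$estimate, x$p.value))
  invisible(x)
}

#' @rdname poisson_ratio_test
#' @param x A `rate_ratio_test` object.
#' @param ... Unused.
#' @method tidy rate_ratio_test
#' @export
tidy.rate_ratio_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate,
    p.value = x$p.value,
    count_a = x$count_a, count_b = x$count_b,
    exposure_a = x$exposure_a, exposure_b = x$exposure_b,
    method = x$method
  )
}

#' @rdname poisson_ratio_test
#' @method glance rate_ratio_test
#' @export
glance.rate_ratio_test <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, p.value = x$p.value,
                 n.events = x$count_a + x$count_b)
}

#' Pearson correlation with squared coefficient
#'
#' Product-moment correlation between two numeric vectors, reported as R^2
#' with the two-sided p-value from the t transform on n - 2 degrees of
#' freedom. Used to relate mean off-target read depth to relative mtDNA copy
#' number.
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be constant.
#' @return One-row tibble: `r`, `r_squared`, `p_value`, `n`.
#' @examples
#' pearson_r2(1:10, 2 * (1:10) + 1)
#' @export
pearson_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3) {
    rlang::abort("`x` and `y` must be equal-length vectors with >= 3 finite pairs.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("correlation undefined: constant vector.")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate),
    r_squared = unname(ct$estimate)^2,
    p_value = ct$p.value,
    n = length(x)
  )
}

# recycle two vectors to a common length, erroring on incompatibility
vctrs_recycle2 <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == lb) return(list(a, b))
  if (la == 1L) return(list(rep(a, lb), b))
  if (lb == 1L) return(list(a, rep(b, la)))
  rlang::abort("lengths of `v` and `n` are incompatible.")
}
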