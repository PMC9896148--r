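#' Biased lag-1 autocorrelation
#'
#' The classical early-warning AR1 estimator with the biased (divisor `n`)
#' normalization:
#' `sum_{t=1}^{n-1} (x_t - xbar)(x_{t+1} - xbar) / sum_{t=1}^{n} (x_t - xbar)^2`.
#' Rises under critical slowing down.
#'
#' @param x Numeric window.
#' @return Lag-1 autocorrelation.
#' @export
ar1 <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  d <- x - mean(x)
  denom <- sum(d^2)
  if (denom == 0) stop("undefined: window has zero variance", call. = FALSE)
  sum(d[-n] * d[-1]) / denom
}

#' Biased standard deviation
#'
#' Square root of the divisor-`n` variance, `sqrt(mean((x - xbar)^2))`.
#'
#' @param x Numeric window.
#' @return Biased standard deviation.
#' @export
std_biased <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' Biased (not-adjusted Fisher-Pearson) skewness
#'
#' `g1 = m3 / m2^(3/2)` with biased central moments `m_k = mean((x - xbar)^k)`.
#'
#' @param x Numeric window.
#' @return Skewness `g1`.
#' @export
skewness_biased <- function(x) {
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) stop("undefined: window has zero variance", call. = FALSE)
  mean(d^3) / m2^1.5
}

#' Pearson kurtosis
#'
#' `omega = m4 / m2^2` with biased central moments; equals 3 for a Gaussian
#' sample in the large-`n` limit (no excess subtraction).
#'
#' @param x Numeric window.
#' @return Kurtosis `omega`.
#' @export
kurtosis_pearson <- function(x) {
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) stop("undefined: window has zero variance", call. = FALSE)
  mean(d^4) / m2^2
}

.indicator_funs <- list(ar1 = ar1, std = std_biased,
                        skewness = skewness_biased,
                        kurtosis = kurtosis_pearson)

#' Rolling early-warning indicators
#'
#' Applies the selected indicator estimators to every rolling window.
#' Windows on which an estimator is undefined (e.g. zero variance for the
#' AR1) are recorded as `NA` rather than dropped, so the indicator series
#' stay aligned across statistics.
#'
#' @param x Numeric series.
#' @param spec A [window_spec()].
#' @param which Character vector among `"ar1"`, `"std"`, `"skewness"`,
#'   `"kurtosis"`.
#' @param times Optional timestamps of `x`.
#' @return A `data.frame` with `window_end_time` and one column per
#'   requested indicator.
#' @export
rolling_indicator <- function(x, spec, which = c("ar1", "std", "skewness",
                                                 "kurtosis"),
                              times = NULL) {
  which <- match.arg(which, names(.indicator_funs), several.ok = TRUE)
  w <- rolling_windows(x, spec, times = times)
  out <- data.frame(window_end_time = w$end_time)
  for (nm in which) {
    fun <- .indicator_funs[[nm]]
    out[[nm]] <- vapply(seq_len(nrow(w)), function(k) {
      tryCatch(fun(x[w$start[k]:w$end[k]]), error = function(e) NA_real_)
    }, numeric(1))
  }
  out
}
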