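#' Build the trend-model prior from an indicator series
#'
#' Prior recipe for the Bayes-factor comparison of a linear trend model
#' `y = a t + b` against a constant model `y = b`: the intercept/constant
#' `b` is Gaussian with mean equal to the first indicator value and unit
#' standard deviation; the slope `a` is uniform on
#' `[0, 1.5 (max - min) / (t_end - t_start)]` (mirrored to negative slopes
#' for indicators expected to decrease); the noise scale is log-uniform on
#' `[log 0.5, log 5]`.
#'
#' @param y Indicator series (at least 2 points).
#' @param times Timestamps of `y` (years).
#' @param direction `"positive"` or `"negative"` slope prior.
#' @param n_draws Monte-Carlo draws used for the evidence estimate.
#' @return An object of class `trend_prior`.
#' @export
build_trend_prior <- function(y, times, direction = c("positive", "negative"),
                              n_draws = 1e5) {
  direction <- match.arg(direction)
  y <- y[is.finite(y)]
  if (length(y) < 2)
    stop("need at least 2 indicator values", call. = FALSE)
  if (n_draws < 1e3) stop("n_draws must be at least 1000", call. = FALSE)
  amax <- 1.5 * (max(y) - min(y)) / (max(times) - min(times))
  slope <- if (direction == "positive") c(0, amax) else c(-amax, 0)
  structure(list(intercept_mean = y[1], intercept_sd = 1,
                 slope_min = slope[1], slope_max = slope[2],
                 log_noise_min = log(0.5), log_noise_max = log(5),
                 n_draws = as.integer(n_draws), direction = direction),
            class = "trend_prior")
}

#' @export
print.trend_prior <- function(x, ...) {
  cat(sprintf("trend_prior: b ~ N(%.4g, 1); a ~ U(%.4g, %.4g); log-noise ~ U(log 0.5, log 5); %d draws\n",
              x$intercept_mean, x$slope_min, x$slope_max, x$n_draws))
  invisible(x)
}

## log of the smallest positive normal double: the "numerical zero" floor
.log_tiny <- log(.Machine$double.xmin)

#' Monte-Carlo evidence of the trend or constant model
#'
#' Estimates the marginal likelihood by averaging the data likelihood over
#' prior draws.  The likelihood is i.i.d. Gaussian about the drawn model
#' curve with the drawn noise scale; averaging is done in log space
#' (log-sum-exp).  The constant model consumes the same intercept and noise
#' draw stream as the linear model (given the same seed), so the two models
#' are compared on matched intercepts.  When every draw's log-likelihood
#' falls below the smallest normal float the evidence is reported as exactly
#' zero.
#'
#' @param y Indicator series.
#' @param times Timestamps of `y`.
#' @param model `"linear"` or `"constant"`.
#' @param prior A [build_trend_prior()] result.
#' @param seed Optional integer seed (share it between the two models).
#' @return An object of class `evidence`: list with `log_evidence`,
#'   `evidence`, `zero`, `model`, `n_draws`.
#' @export
model_evidence <- function(y, times, model = c("linear", "constant"), prior,
                           seed = NULL) {
  model <- match.arg(model)
  keep <- is.finite(y)
  y <- y[keep]; times <- times[keep]
  if (length(y) == 0) stop("empty indicator series", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- prior$n_draws
  k <- length(y)
  ## shared draw stream: b then s, then (linear only) a
  b <- stats::rnorm(n, prior$intercept_mean, prior$intercept_sd)
  s <- exp(stats::runif(n, prior$log_noise_min, prior$log_noise_max))
  if (model == "linear") {
    a <- stats::runif(n, prior$slope_min, prior$slope_max)
    resid2 <- rowSums((tcrossprod(a, times) + b -
                         matrix(y, n, k, byrow = TRUE))^2)
  } else {
    resid2 <- rowSums((b - matrix(y, n, k, byrow = TRUE))^2)
  }
  ll <- -k * (log(s) + 0.5 * log(2 * pi)) - resid2 / (2 * s^2)
  zero <- all(ll < .log_tiny)
  log_ev <- if (zero) -Inf else logsumexp(ll) - log(n)
  structure(list(log_evidence = log_ev,
                 evidence = if (zero) 0 else exp(log_ev), zero = zero,
                 model = model, n_draws = n, seed = seed),
            class = "evidence")
}

#' @export
print.evidence <- function(x, ...) {
  cat(sprintf("evidence (%s model): log evidence %.4g (%s), %d draws\n",
              x$model, x$log_evidence,
              if (x$zero) "numerically zero" else sprintf("%.4g", x$evidence),
              x$n_draws))
  invisible(x)
}

#' Bayes factors with degenerate-evidence conventions
#'
#' `BF12 = p(I | M1) / p(I | M2)`.  When one evidence is numerically zero
#' the other model is preferred with an infinite Bayes factor; when both are
#' zero neither model explains the data and the pair is flagged inadequate.
#'
#' @param e1,e2 [model_evidence()] results (or bare evidence numbers) for
#'   the linear and the constant model.
#' @return A list with `BF12`, `BF21` and logical `inadequate`.
#' @export
bayes_factor <- function(e1, e2) {
  as_ev <- function(e) {
    if (inherits(e, "evidence")) return(e)
    list(log_evidence = if (e == 0) -Inf else log(e), zero = e == 0)
  }
  e1 <- as_ev(e1); e2 <- as_ev(e2)
  if (e1$zero && e2$zero)
    return(list(BF12 = NaN, BF21 = NaN, inadequate = TRUE))
  if (e2$zero) return(list(BF12 = Inf, BF21 = 0, inadequate = FALSE))
  if (e1$zero) return(list(BF12 = 0, BF21 = Inf, inadequate = FALSE))
  l <- e1$log_evidence - e2$log_evidence
  list(BF12 = exp(l), BF21 = exp(-l), inadequate = FALSE)
}

#' Classify a Bayes-factor pair
#'
#' A model is declared significant when its Bayes factor over the competitor
#' exceeds the threshold (100 by convention, i.e. decisive evidence); when
#' both evidences are numerically zero the comparison is inadequate;
#' otherwise the result is undecided.
#'
#' @param bf A [bayes_factor()] result (or a list with `BF12`, `BF21`,
#'   `inadequate`).
#' @param threshold Significance threshold on the Bayes factor.
#' @return One of `"significant_linear"`, `"significant_constant"`,
#'   `"undecided"`, `"inadequate"`.
#' @export
classify_trend <- function(bf, threshold = 100) {
  if (isTRUE(bf$inadequate)) return("inadequate")
  if (bf$BF12 > threshold) return("significant_linear")
  if (bf$BF21 > threshold) return("significant_constant")
  "undecided"
}

#' Truncate an indicator series at a landmark time
#'
#' Keeps the samples with `times <= landmark_time`; the early-warning
#' comparison is made on data available before the destabilization is
#' irreversible.
#'
#' @param y Indicator series.
#' @param times Timestamps of `y`.
#' @param landmark_time Truncation time (years).
#' @return A list with the truncated `values` and `times`.
#' @export
truncate_at_landmark <- function(y, times, landmark_time) {
  keep <- times <= landmark_time
  list(values = y[keep], times = times[keep])
}
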