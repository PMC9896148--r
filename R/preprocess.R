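#' Rolling-window specification
#'
#' @param size Window length in samples (default 750, i.e. 15 years at 50
#'   samples per year).
#' @param shift Shift between consecutive windows in samples.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(size = 750, shift = 30) {
  if (shift <= 0 || shift > size)
    stop("need 0 < shift <= size", call. = FALSE)
  structure(list(size = as.integer(size), shift = as.integer(shift)),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("window_spec: size %d, shift %d samples\n", x$size, x$shift))
  invisible(x)
}

#' Enumerate rolling windows over a series
#'
#' Windows `[k * shift + 1, k * shift + size]` for `k = 0, ..., K - 1` with
#' `K = floor((n - size) / shift) + 1`.  Each window is stamped with the time
#' of its last sample (right-aligned), so that indicator trends are causal.
#'
#' @param x Numeric series (only its length is used).
#' @param spec A [window_spec()].
#' @param times Optional timestamps (defaults to the sample index).
#' @return A `data.frame` with columns `start`, `end` (sample indices) and
#'   `end_time`.
#' @export
rolling_windows <- function(x, spec, times = NULL) {
  n <- length(x)
  if (spec$size > n)
    stop(sprintf("window size %d exceeds series length %d", spec$size, n),
         call. = FALSE)
  if (is.null(times)) times <- seq_len(n)
  K <- (n - spec$size) %/% spec$shift + 1L
  start <- (seq_len(K) - 1L) * spec$shift + 1L
  end <- start + spec$size - 1L
  data.frame(start = start, end = end, end_time = times[end])
}

#' Deseasonalize by year-over-year differencing
#'
#' Subtracts from every sample the value at the same within-year position of
#' the previous year: `out[t] = x[t] - x[t - samples_per_year]`.  Removes any
#' exactly annual-periodic component; the output is one year shorter and
#' keeps the later year's timestamps.
#'
#' @param x Numeric series.
#' @param samples_per_year Samples per year (default 50).
#' @param times Optional timestamps of `x`.
#' @return The differenced series; when `times` is given, the shifted
#'   timestamps are attached as attribute `"times"`.
#' @export
deseasonalize_yoy <- function(x, samples_per_year = 50, times = NULL) {
  n <- length(x)
  if (n <= samples_per_year)
    stop("series must be longer than one year", call. = FALSE)
  out <- x[(samples_per_year + 1):n] - x[1:(n - samples_per_year)]
  if (!is.null(times)) attr(out, "times") <- times[(samples_per_year + 1):n]
  out
}

## gaussian kernel, radius 4 sd (matching the common truncation of image
## filters), normalized to unit sum
.gauss_kernel <- function(sd) {
  r <- ceiling(4 * sd)
  k <- exp(-0.5 * ((-r):r / sd)^2)
  k / sum(k)
}

#' Deseasonalize by Gaussian-kernel smoothing
#'
#' Estimates the joint seasonal-plus-trend component as a Gaussian-kernel
#' smooth (standard deviation `kernel_sd` samples, reflect-padded
#' boundaries) and returns the residual `x - smooth(x)`.  With a kernel
#' narrower than the annual period this removes the seasonal oscillation and
#' any slow trend at the same time, which suits correlated-noise series whose
#' annual amplitudes the noise modulates rather than hides.
#'
#' @param x Numeric series.
#' @param kernel_sd Kernel standard deviation in samples (default 2.5).
#' @param times Optional timestamps, passed through as attribute `"times"`.
#' @return Residual series of the same length as `x`.
#' @export
deseasonalize_smooth <- function(x, kernel_sd = 2.5, times = NULL) {
  k <- .gauss_kernel(kernel_sd)
  r <- (length(k) - 1L) / 2L
  n <- length(x)
  if (n < r + 1)
    stop("series too short for the smoothing kernel", call. = FALSE)
  ## reflect padding: (d c b a | a b c d | d c b a)
  padded <- c(x[r:1], x, x[n:(n - r + 1)])
  sm <- stats::filter(padded, k, sides = 2)[(r + 1):(r + n)]
  out <- x - as.numeric(sm)
  if (!is.null(times)) attr(out, "times") <- times
  out
}
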