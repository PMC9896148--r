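#' Stochastic forcing series
#'
#' Container for a calibrated forcing sequence.  `values` is the noise signal
#' `Z` sampled at spacing `dt`; `increments` is what one Euler-Maruyama step
#' adds to the forced equation before scaling by the noise level: the Wiener
#' increment `dW` itself for white noise, and `Z * dt` for the correlated
#' (state-like) signals.
#'
#' @param values Sampled noise signal.
#' @param increments Per-step forcing increments (same length).
#' @param dt Sampling step in years.
#' @param kind One of `"white"`, `"pink"`, `"red"`.
#' @param beta Nominal spectral exponent of the power spectrum.
#' @param phi Relaxation rate (red noise only).
#' @param seed Seed used to generate the series.
#' @return An object of class `noise_series`.
#' @export
noise_series <- function(values, increments, dt, kind, beta, phi = NA_real_,
                         seed = NULL) {
  kind <- match.arg(kind, c("white", "pink", "red"))
  if (length(values) == 0 || length(values) != length(increments))
    stop("values and increments must be non-empty and of equal length",
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("noise values must be finite", call. = FALSE)
  structure(list(values = values, increments = increments, dt = dt,
                 kind = kind, beta = beta, phi = phi,
                 power = total_power(values), seed = seed),
            class = "noise_series")
}

#' @export
print.noise_series <- function(x, ...) {
  cat(sprintf("noise_series: %s, n = %d, dt = %g, beta = %g, power = %.4g\n",
              x$kind, length(x$values), x$dt, x$beta, x$power))
  invisible(x)
}

#' Forcing increments of a noise series
#' @param noise A [noise_series()].
#' @return Numeric vector of per-step forcing increments.
#' @export
noise_increments <- function(noise) noise$increments

#' White-noise forcing (Wiener increments)
#'
#' Independent Gaussian increments with mean 0 and variance `dt`.
#'
#' @param n Number of increments.
#' @param dt Step in years.
#' @param seed Optional integer seed.
#' @return A [noise_series()] of kind `"white"`.
#' @export
white_noise <- function(n, dt, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dW <- stats::rnorm(n, 0, sqrt(dt))
  noise_series(values = dW, increments = dW, dt = dt, kind = "white",
               beta = 0, seed = seed)
}

#' Pink-noise forcing by spectral shaping
#'
#' Fourier transform of a white sequence, amplitude at frequency `f` scaled
#' by `f^(-beta/2)` (so the power spectrum falls as `f^(-beta)`), the
#' zero-frequency component removed, inverse transform, and rescaling to the
#' target total power.  The frequency axis is folded (`min(k, n - k)`), which
#' keeps the spectrum conjugate-symmetric; the vanishing imaginary residue is
#' discarded.
#'
#' @param n Number of samples (at least 4).
#' @param dt Step in years.
#' @param beta Spectral exponent of the power spectrum (default 0.8).
#' @param target_power Total power (time-domain mean square) of the returned
#'   signal; `NULL` leaves the raw amplitude.
#' @param seed Optional integer seed.
#' @return A [noise_series()] of kind `"pink"`; increments are `values * dt`.
#' @export
pink_noise <- function(n, dt, beta = 0.8, target_power = 1, seed = NULL) {
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (n < 4) stop("n must be at least 4", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  xi <- stats::rnorm(n)
  X <- stats::fft(xi)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) / (n * dt)
  scale <- c(0, f[-1]^(-beta / 2))       # zero-frequency bin removed
  z <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  if (!is.null(target_power)) z <- normalize_power(z, target_power)
  noise_series(values = z, increments = z * dt, dt = dt, kind = "pink",
               beta = beta, seed = seed)
}

#' Red-noise forcing (Ornstein-Uhlenbeck process)
#'
#' Euler-Maruyama integration of `dZ = -phi * Z dt + sqrt(2 * phi) dW`,
#' started from the stationary distribution (unit variance), optionally
#' rescaled to a target total power.  With `phi = 0.53` sampled at
#' `dt = 1/50` the periodogram falls with spectral exponent close to 1.6
#' over the sampled band.
#'
#' @param n Number of samples.
#' @param dt Step in years.
#' @param phi Relaxation rate (1/yr).
#' @param target_power Total power of the returned signal; `NULL` leaves the
#'   raw (approximately unit-variance) process.
#' @param seed Optional integer seed.
#' @return A [noise_series()] of kind `"red"`; increments are `values * dt`.
#' @export
red_noise <- function(n, dt, phi = 0.53, target_power = 1, seed = NULL) {
  if (phi <= 0) stop("phi must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  z0 <- stats::rnorm(1)                  # stationary variance 2*phi/(2*phi) = 1
  w <- stats::rnorm(n, 0, sqrt(2 * phi * dt))
  ## Z_k = (1 - phi dt) Z_{k-1} + w_k, seeded by the stationary draw
  z <- stats::filter(c(z0 * (1 - phi * dt) + w[1], w[-1]),
                     1 - phi * dt, method = "recursive")
  z <- as.numeric(z)
  if (!is.null(target_power)) z <- normalize_power(z, target_power)
  noise_series(values = z, increments = z * dt, dt = dt, kind = "red",
               beta = 1.6, phi = phi, seed = seed)
}

#' Total power of a signal
#'
#' Sum of the periodogram, normalized so that it equals the time-domain mean
#' square (Parseval's identity): `sum(|fft(x)|^2) / n^2`.
#'
#' @param x Numeric signal or [noise_series()].
#' @param dt Sampling step (kept for interface symmetry; the convention is
#'   `dt`-free).
#' @return Total power (mean square).
#' @export
total_power <- function(x, dt = NULL) {
  if (inherits(x, "noise_series")) x <- x$values
  n <- length(x)
  sum(Mod(stats::fft(x))^2) / n^2
}

#' Rescale a signal to a target total power
#'
#' Multiplies by `sqrt(target / current)`; idempotent at the target and
#' spectral-shape preserving.
#'
#' @param x Numeric signal or [noise_series()].
#' @param target Target total power (mean square).
#' @return Same type as the input, rescaled.
#' @export
normalize_power <- function(x, target) {
  if (inherits(x, "noise_series")) {
    fac <- sqrt(target / total_power(x$values))
    x$values <- x$values * fac
    x$increments <- x$increments * fac
    x$power <- total_power(x$values)
    return(x)
  }
  cur <- total_power(x)
  if (cur == 0) {
    if (target == 0) return(x)
    stop("cannot rescale an all-zero signal to positive power", call. = FALSE)
  }
  x * sqrt(target / cur)
}

#' Write a noise series to CSV with a JSON metadata sidecar
#'
#' The CSV holds `time` and `value`; the sidecar `<path>.json` records kind,
#' spectral exponent, relaxation rate, calibrated power and seed.
#'
#' @param noise A [noise_series()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_noise_series <- function(noise, path) {
  utils::write.csv(data.frame(time = seq_along(noise$values) * noise$dt,
                              value = noise$values),
                   path, row.names = FALSE)
  jsonlite::write_json(list(kind = noise$kind, beta = noise$beta,
                            phi = noise$phi, dt = noise$dt,
                            power = noise$power, seed = noise$seed),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Estimate the spectral exponent of a signal
#'
#' Least-squares slope of log power versus log frequency on an (optionally
#' ensemble-averaged) one-sided periodogram; returns the negated slope, i.e.
#' the `beta` of a `f^(-beta)` power spectrum.  The lowest frequency bins are
#' excluded (they carry the largest estimator variance and any residual
#' mean).
#'
#' @param x A numeric vector, a matrix whose columns are realizations, or a
#'   list of equal-length numeric vectors; periodograms are averaged across
#'   realizations.
#' @param dt Sampling step in years.
#' @param n_exclude Number of lowest positive-frequency bins excluded from
#'   the fit.
#' @return Estimated spectral exponent (positive for decaying spectra).
#' @export
estimate_spectral_exponent <- function(x, dt, n_exclude = 3) {
  if (inherits(x, "noise_series")) x <- x$values
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (is.list(x)) x <- do.call(cbind, x)
  n <- nrow(x)
  kmax <- floor(n / 2)
  pg <- rowMeans(apply(x, 2, function(col) Mod(stats::fft(col))^2 / n))
  keep <- seq.int(n_exclude + 1, kmax)       # one-sided, skip lowest bins
  f <- keep / (n * dt)
  fit <- stats::lm(log(pg[keep + 1]) ~ log(f))
  -unname(stats::coef(fit)[2])
}
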