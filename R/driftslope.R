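#' Prior specification for the drift-diffusion model
#'
#' The window model is a Langevin equation with third-order polynomial drift
#' `h(x) = theta0 + theta1 x + theta2 x^2 + theta3 x^3` and constant
#' diffusion `sigma_diff`.  Priors: a flat Jeffreys straight-line prior
#' `1 / (2 pi (1 + theta1^2)^(3/2))` on `(theta0, theta1)` inside a box, the
#' scale prior `1/sigma` on `sigma_diff` inside its range, and zero-mean
#' Gaussians on the curvature parameters `theta2`, `theta3`.
#'
#' @param theta01_bound Half-width of the `(theta0, theta1)` box (50 by
#'   default; 70 for the deseasonalized correlated-noise cases, see `wide`).
#' @param sigma_bound Upper end of the `sigma_diff` range (lower end is 0).
#' @param theta2_sd,theta3_sd Standard deviations of the Gaussian priors on
#'   `theta2` and `theta3`.
#' @param wide Convenience switch: `TRUE` widens the box and sigma range to
#'   70, as used for deseasonalized correlated-noise series.
#' @return An object of class `drift_prior_spec`.
#' @export
drift_prior_spec <- function(theta01_bound = 50, sigma_bound = 50,
                             theta2_sd = 4, theta3_sd = 8, wide = FALSE) {
  if (wide) {
    theta01_bound <- 70
    sigma_bound <- 70
  }
  if (theta01_bound <= 0 || sigma_bound <= 0)
    stop("prior ranges must be non-empty", call. = FALSE)
  if (theta2_sd <= 0 || theta3_sd <= 0)
    stop("prior scales must be > 0", call. = FALSE)
  structure(list(theta01_bound = theta01_bound, sigma_bound = sigma_bound,
                 theta2_sd = theta2_sd, theta3_sd = theta3_sd),
            class = "drift_prior_spec")
}

#' @export
print.drift_prior_spec <- function(x, ...) {
  cat(sprintf("drift_prior_spec: theta0,1 in (-%g, %g); sigma in (0, %g); theta2 ~ N(0, %g), theta3 ~ N(0, %g)\n",
              x$theta01_bound, x$theta01_bound, x$sigma_bound, x$theta2_sd,
              x$theta3_sd))
  invisible(x)
}

#' Polynomial drift function
#'
#' @param x State value (vectorized).
#' @param theta Numeric vector `c(theta0, theta1, theta2, theta3)`.
#' @return `theta0 + theta1 x + theta2 x^2 + theta3 x^3`.
#' @export
polynomial_drift <- function(x, theta) {
  theta[1] + theta[2] * x + theta[3] * x^2 + theta[4] * x^3
}

#' Drift slope at the fixed point
#'
#' The derivative of the drift polynomial at `x_star`:
#' `zeta = theta1 + 2 theta2 x_star + 3 theta3 x_star^2`.  Negative for
#' stable dynamics; a sign change marks the loss of linear stability.
#'
#' @param theta Numeric vector `c(theta0, ..., theta3)` or a draws matrix
#'   whose first four columns are the drift coefficients.
#' @param x_star Fixed-point estimate (the window mean by convention).
#' @return Drift slope(s) `zeta`.
#' @export
slope_from_params <- function(theta, x_star) {
  if (is.matrix(theta))
    return(theta[, 2] + 2 * theta[, 3] * x_star + 3 * theta[, 4] * x_star^2)
  theta[2] + 2 * theta[3] * x_star + 3 * theta[4] * x_star^2
}

#' Log-likelihood of a window under the drift-diffusion model
#'
#' Product of short-time Euler-Maruyama Gaussian transition densities:
#' each consecutive pair contributes
#' `N(x_{i+1}; x_i + h(x_i) dt, sigma_diff^2 dt)`.
#'
#' @param window Numeric window (length at least 2).
#' @param theta Drift coefficients `c(theta0, ..., theta3)`.
#' @param sigma_diff Constant diffusion amplitude; non-positive values give
#'   `-Inf` by contract.
#' @param dt Sampling step of the window.
#' @return Log-likelihood.
#' @export
drift_loglik <- function(window, theta, sigma_diff, dt) {
  if (length(window) < 2) stop("window must hold at least 2 samples",
                               call. = FALSE)
  if (!is.finite(sigma_diff) || sigma_diff <= 0) return(-Inf)
  x0 <- window[-length(window)]
  x1 <- window[-1]
  mu <- x0 + polynomial_drift(x0, theta) * dt
  sum(stats::dnorm(x1, mu, sigma_diff * sqrt(dt), log = TRUE))
}

#' Log-prior of the drift-diffusion parameters
#'
#' @param theta Drift coefficients `c(theta0, ..., theta3)`.
#' @param sigma_diff Diffusion amplitude.
#' @param spec A [drift_prior_spec()].
#' @return Unnormalized log-prior density; `-Inf` outside the support.
#' @export
drift_logprior <- function(theta, sigma_diff, spec) {
  b <- spec$theta01_bound
  if (abs(theta[1]) >= b || abs(theta[2]) >= b) return(-Inf)
  if (!is.finite(sigma_diff) || sigma_diff <= 0 ||
      sigma_diff >= spec$sigma_bound) return(-Inf)
  -log(2 * pi) - 1.5 * log1p(theta[2]^2) - log(sigma_diff) +
    stats::dnorm(theta[3], 0, spec$theta2_sd, log = TRUE) +
    stats::dnorm(theta[4], 0, spec$theta3_sd, log = TRUE)
}

## ---- vectorized posterior over a matrix of walkers ------------------------

## builds a closure evaluating the log-posterior for a m x 5 matrix of
## parameter rows (theta0..theta3, sigma)
.make_logpost <- function(window, dt, spec) {
  x0 <- window[-length(window)]
  x1 <- window[-1]
  X <- cbind(1, x0, x0^2, x0^3)
  m1 <- length(x0)
  sqdt <- sqrt(dt)
  b <- spec$theta01_bound
  function(P) {
    th <- P[, 1:4, drop = FALSE]
    sg <- P[, 5]
    ok <- abs(P[, 1]) < b & abs(P[, 2]) < b & sg > 0 & sg < spec$sigma_bound
    out <- rep(-Inf, nrow(P))
    if (any(ok)) {
      mu <- x0 + (X %*% t(th[ok, , drop = FALSE])) * dt
      sd <- sg[ok] * sqdt
      ss <- colSums((x1 - mu)^2)
      ll <- -m1 * (log(sd) + 0.5 * log(2 * pi)) - ss / (2 * sd^2)
      lp <- -log(2 * pi) - 1.5 * log1p(P[ok, 2]^2) - log(sg[ok]) +
        stats::dnorm(P[ok, 3], 0, spec$theta2_sd, log = TRUE) +
        stats::dnorm(P[ok, 4], 0, spec$theta3_sd, log = TRUE)
      out[ok] <- ll + lp
    }
    out
  }
}

#' MCMC configuration for the drift-slope fit
#'
#' Defaults follow the ensemble-sampler conventions of the method: 50
#' walkers, 1500 steps, the first 500 discarded as burn-in, thinning by 5
#' (10000 retained draws), stretch-move scale `a = 2`.
#'
#' @param n_walkers Number of walkers (at least 12, even).
#' @param n_steps Total steps per walker.
#' @param n_burnin Burn-in steps discarded.
#' @param thin Thinning interval.
#' @param a Stretch-move scale parameter.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_walkers = 50, n_steps = 1500, n_burnin = 500,
                        thin = 5, a = 2) {
  if (n_walkers < 12 || n_walkers %% 2 != 0)
    stop("n_walkers must be an even number >= 12", call. = FALSE)
  if (n_burnin >= n_steps) stop("n_burnin must be < n_steps", call. = FALSE)
  if (a <= 1) stop("stretch scale a must be > 1", call. = FALSE)
  structure(list(n_walkers = as.integer(n_walkers),
                 n_steps = as.integer(n_steps),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 a = a),
            class = "mcmc_config")
}

## affine-invariant ensemble sampler (Goodman-Weare stretch moves, updating
## the two half-ensembles alternately); logpost takes an m x d matrix
.ensemble_sampler <- function(logpost, init, n_steps, n_burnin, thin, a = 2) {
  W <- nrow(init)
  d <- ncol(init)
  pos <- init
  lp <- logpost(pos)
  half <- list(seq_len(W %/% 2), (W %/% 2 + 1):W)
  keep <- seq.int(n_burnin + thin, n_steps, by = thin)
  draws <- matrix(NA_real_, length(keep) * W, d)
  n_acc <- 0
  row <- 0
  for (s in seq_len(n_steps)) {
    for (hh in 1:2) {
      S <- half[[hh]]
      C <- half[[3 - hh]]
      m <- length(S)
      j <- C[sample.int(length(C), m, replace = TRUE)]
      z <- ((a - 1) * stats::runif(m) + 1)^2 / a
      prop <- pos[j, , drop = FALSE] +
        z * (pos[S, , drop = FALSE] - pos[j, , drop = FALSE])
      lp_prop <- logpost(prop)
      logr <- (d - 1) * log(z) + lp_prop - lp[S]
      acc <- log(stats::runif(m)) < logr
      if (any(acc)) {
        pos[S[acc], ] <- prop[acc, , drop = FALSE]
        lp[S[acc]] <- lp_prop[acc]
        n_acc <- n_acc + sum(acc)
      }
    }
    if (length(keep) && s == keep[1]) {
      draws[row + seq_len(W), ] <- pos
      row <- row + W
      keep <- keep[-1]
    }
  }
  list(draws = draws, acceptance_rate = n_acc / (n_steps * W),
       final = pos, final_lp = lp)
}

#' Fit the drift-diffusion model to one window by ensemble MCMC
#'
#' Samples the posterior of `(theta0, ..., theta3, sigma_diff)` under the
#' short-time Gaussian transition likelihood and the priors of
#' [drift_prior_spec()], using an affine-invariant ensemble sampler with
#' stretch moves.  Walkers start jittered around a least-squares polynomial
#' fit of the increment field, clamped into the prior support.
#'
#' @param window Numeric window (at least 8 samples, non-constant).
#' @param dt Sampling step.
#' @param prior A [drift_prior_spec()].
#' @param config An [mcmc_config()].
#' @param seed Optional integer seed (makes the fit reproducible).
#' @return An object of class `drift_posterior`: list with `draws` (matrix
#'   with columns `theta0..theta3`, `sigma`), `acceptance_rate`, `n_retained`,
#'   `seed`.
#' @export
fit_drift_window <- function(window, dt, prior = drift_prior_spec(),
                             config = mcmc_config(), seed = NULL) {
  if (length(window) < 8)
    stop("window too short to constrain a 5-parameter model", call. = FALSE)
  if (stats::sd(window) == 0)
    stop("estimation failure: constant window", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x0 <- window[-length(window)]
  dx <- diff(window) / dt
  fit <- stats::lm(dx ~ x0 + I(x0^2) + I(x0^3))
  th0 <- unname(stats::coef(fit))
  th0[!is.finite(th0)] <- 0
  sg0 <- stats::sd(stats::resid(fit)) * sqrt(dt)   # residuals of dx scale as sigma/sqrt(dt)
  if (!is.finite(sg0) || sg0 <= 0) sg0 <- stats::sd(diff(window)) / sqrt(dt)
  b <- prior$theta01_bound
  th0[1:2] <- pmin(pmax(th0[1:2], -0.95 * b), 0.95 * b)
  sg0 <- min(max(sg0, 1e-6), 0.95 * prior$sigma_bound)
  W <- config$n_walkers
  init <- cbind(
    th0[1] + stats::rnorm(W, 0, pmax(abs(th0[1]) * 0.01, 1e-3)),
    th0[2] + stats::rnorm(W, 0, pmax(abs(th0[2]) * 0.01, 1e-3)),
    th0[3] + stats::rnorm(W, 0, pmax(abs(th0[3]) * 0.01, 1e-3)),
    th0[4] + stats::rnorm(W, 0, pmax(abs(th0[4]) * 0.01, 1e-3)),
    sg0 * exp(stats::rnorm(W, 0, 0.01)))
  init[, 1] <- pmin(pmax(init[, 1], -0.99 * b), 0.99 * b)
  init[, 2] <- pmin(pmax(init[, 2], -0.99 * b), 0.99 * b)
  init[, 5] <- pmin(pmax(init[, 5], 1e-8), 0.99 * prior$sigma_bound)
  logpost <- .make_logpost(window, dt, prior)
  if (all(!is.finite(logpost(init))))
    stop("estimation failure: posterior not finite at initialization",
         call. = FALSE)
  res <- .ensemble_sampler(logpost, init, config$n_steps, config$n_burnin,
                           config$thin, config$a)
  draws <- res$draws
  colnames(draws) <- c("theta0", "theta1", "theta2", "theta3", "sigma")
  structure(list(draws = draws, acceptance_rate = res$acceptance_rate,
                 n_retained = nrow(draws), seed = seed, prior = prior,
                 config = config, dt = dt),
            class = "drift_posterior")
}

#' @export
print.drift_posterior <- function(x, ...) {
  cat(sprintf("drift_posterior: %d retained draws, acceptance rate %.2f\n",
              x$n_retained, x$acceptance_rate))
  print(round(apply(x$draws, 2, stats::quantile,
                    probs = c(0.16, 0.5, 0.84)), 4))
  invisible(x)
}

#' Summarize the drift-slope posterior of one window
#'
#' Maps every retained draw through [slope_from_params()] at the fixed-point
#' estimate `x_star`, then reports the mode of a Gaussian kernel density
#' estimate (normal-reference bandwidth, 512-point grid) as the point
#' estimate, with the empirical 16-84\% and 1-99\% percentile bands.
#'
#' @param post A `drift_posterior` from [fit_drift_window()].
#' @param x_star Fixed-point estimate (the window mean by convention).
#' @param time Optional window-end timestamp carried into the result.
#' @return An object of class `slope_estimate`: list with `time`, `zeta_map`,
#'   `band_68`, `band_98`, `x_star`.
#' @export
slope_summary <- function(post, x_star, time = NA_real_) {
  zeta <- slope_from_params(post$draws, x_star)
  if (stats::sd(zeta) == 0) {
    zmap <- zeta[1]
    q <- rep(zeta[1], 4)
  } else {
    bw <- stats::sd(zeta) * length(zeta)^(-1 / 5)
    dens <- stats::density(zeta, bw = bw, n = 512)
    zmap <- dens$x[which.max(dens$y)]
    q <- stats::quantile(zeta, probs = c(0.16, 0.84, 0.01, 0.99),
                         names = FALSE)
  }
  structure(list(time = time, zeta_map = zmap,
                 band_68 = c(q16 = q[1], q84 = q[2]),
                 band_98 = c(q01 = q[3], q99 = q[4]), x_star = x_star),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("slope_estimate: zeta = %.4g [68%%: %.4g, %.4g] [98%%: %.4g, %.4g] (x* = %.4g)\n",
              x$zeta_map, x$band_68[1], x$band_68[2], x$band_98[1],
              x$band_98[2], x$x_star))
  invisible(x)
}

#' Rolling drift-slope scan
#'
#' Fits the drift-diffusion model to every rolling window and summarizes the
#' drift-slope posterior, with the fixed point `x_star` set to each window's
#' mean.  Windows on which the fit fails are recorded as `NA` rows rather
#' than aborting the scan.
#'
#' @param x Numeric series.
#' @param dt Sampling step.
#' @param spec A [window_spec()].
#' @param prior A [drift_prior_spec()].
#' @param config An [mcmc_config()].
#' @param seed Integer seed; window `k` is fitted with seed `seed + k`.
#' @param times Optional timestamps of `x`.
#' @return A `data.frame` of class `slope_series` with columns
#'   `window_end_time`, `zeta_map`, `q16`, `q84`, `q01`, `q99`, `x_star`.
#' @export
rolling_drift_slope <- function(x, dt, spec = window_spec(),
                                prior = drift_prior_spec(),
                                config = mcmc_config(), seed = 1,
                                times = NULL) {
  w <- rolling_windows(x, spec, times = times)
  K <- nrow(w)
  out <- data.frame(window_end_time = w$end_time, zeta_map = NA_real_,
                    q16 = NA_real_, q84 = NA_real_, q01 = NA_real_,
                    q99 = NA_real_, x_star = NA_real_)
  for (k in seq_len(K)) {
    win <- x[w$start[k]:w$end[k]]
    est <- tryCatch({
      post <- fit_drift_window(win, dt, prior = prior, config = config,
                               seed = seed + k)
      slope_summary(post, x_star = mean(win), time = w$end_time[k])
    }, error = function(e) NULL)
    if (!is.null(est)) {
      out$zeta_map[k] <- est$zeta_map
      out$q16[k] <- est$band_68[1]; out$q84[k] <- est$band_68[2]
      out$q01[k] <- est$band_98[1]; out$q99[k] <- est$band_98[2]
      out$x_star[k] <- est$x_star
    }
  }
  class(out) <- c("slope_series", "data.frame")
  out
}
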