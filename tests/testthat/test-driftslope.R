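test_that("drift polynomial and slope evaluate exactly", {
  expect_equal(polynomial_drift(2, c(0, -1, 0, 0)), -2)
  expect_equal(polynomial_drift(5, c(0, 0, 0, 0)), 0)
  expect_equal(polynomial_drift(2, c(1, 1, 1, 1)), 15)

  expect_equal(slope_from_params(c(0, -3, 1, 2), 0), -3)
  expect_equal(slope_from_params(c(9, -3, 0, 0), 7), -3)
  expect_equal(slope_from_params(c(0, 1, 1, 1), 2), 17)
  ## matrix form maps every draw
  draws <- rbind(c(0, 1, 1, 1, 1), c(0, -1, 0, 0, 1))
  expect_equal(slope_from_params(draws, 2), c(17, -1))
})

test_that("window log-likelihood is the product of Euler transition densities", {
  dt <- 0.02
  theta <- c(0.3, -1.2, 0.1, 0)
  win <- c(0.5, 0.7)
  mu <- 0.5 + polynomial_drift(0.5, theta) * dt
  manual <- -0.5 * log(2 * pi * 0.8^2 * dt) - (0.7 - mu)^2 / (2 * 0.8^2 * dt)
  expect_equal(drift_loglik(win, theta, 0.8, dt), manual)

  ## translation covariance with theta0 re-centring (linear drift)
  set.seed(5)
  w <- cumsum(rnorm(100, 0, 0.1))
  th <- c(0.2, -0.8, 0, 0)
  shift <- 3.7
  th_shifted <- c(0.2 - (-0.8) * shift, -0.8, 0, 0)
  expect_equal(drift_loglik(w, th, 1, dt),
               drift_loglik(w + shift, th_shifted, 1, dt),
               tolerance = 1e-9)

  expect_identical(drift_loglik(w, th, -1, dt), -Inf)
  expect_identical(drift_loglik(w, th, 0, dt), -Inf)
  expect_error(drift_loglik(1, th, 1, dt), "at least 2")

  ## the true parameters beat perturbed ones on long windows
  x <- sim_ou(5000, -1, 1, dt, seed = 6)
  ll_true <- drift_loglik(x, c(0, -1, 0, 0), 1, dt)
  expect_gt(ll_true, drift_loglik(x, c(0, 0, 0, 0), 1, dt))
  expect_gt(ll_true, drift_loglik(x, c(0, -2, 0, 0), 1, dt))
})

test_that("log-prior implements the Jeffreys line prior, scale prior and Gaussians", {
  spec <- drift_prior_spec()
  lp0 <- drift_logprior(c(0, 0, 0, 0), 1, spec)
  manual <- log(1 / (2 * pi)) + log(1) +
    dnorm(0, 0, 4, log = TRUE) + dnorm(0, 0, 8, log = TRUE)
  expect_equal(lp0, manual)

  ## prior odds between slope 0 and slope 1: (1 + 1)^{3/2}
  lp1 <- drift_logprior(c(0, 1, 0, 0), 1, spec)
  expect_equal(exp(lp0 - lp1), 2^1.5)

  expect_identical(drift_logprior(c(51, 0, 0, 0), 1, spec), -Inf)
  expect_identical(drift_logprior(c(0, -51, 0, 0), 1, spec), -Inf)
  expect_identical(drift_logprior(c(0, 0, 0, 0), 51, spec), -Inf)
  expect_identical(drift_logprior(c(0, 0, 0, 0), -1, spec), -Inf)

  wide <- drift_prior_spec(wide = TRUE)
  expect_equal(wide$theta01_bound, 70)
  expect_true(is.finite(drift_logprior(c(60, 0, 0, 0), 60, wide)))
})

test_that("ensemble fit recovers a known linear drift and honours its contracts", {
  x <- sim_ou(2000, -1, 1, 0.02, seed = 20)
  post <- fit_drift_window(x, 0.02, config = tiny_mcmc(), seed = 77)
  est <- slope_summary(post, mean(x))
  expect_lte(est$band_98[[1]], -1)
  expect_gte(est$band_98[[2]], -1)
  expect_gte(post$n_retained, 1000)

  ## draws never leave the prior support
  d <- post$draws
  expect_true(all(abs(d[, "theta0"]) < 50 & abs(d[, "theta1"]) < 50))
  expect_true(all(d[, "sigma"] > 0 & d[, "sigma"] < 50))

  ## reproducibility under a fixed seed
  post2 <- fit_drift_window(x, 0.02, config = tiny_mcmc(), seed = 77)
  expect_identical(post$draws, post2$draws)

  expect_error(fit_drift_window(rep(1, 100), 0.02), "constant")
  expect_error(fit_drift_window(c(1, 2, 3), 0.02), "too short")
})

test_that("slope posterior summaries are ordered and match a histogram-mode oracle", {
  x <- sim_ou(1500, -0.8, 0.7, 0.02, seed = 30)
  post <- fit_drift_window(x, 0.02, config = tiny_mcmc(), seed = 31)
  est <- slope_summary(post, mean(x), time = 12)
  expect_equal(est$time, 12)
  expect_lte(est$band_98[[1]], est$band_68[[1]])
  expect_lte(est$band_68[[1]], est$band_68[[2]])
  expect_lte(est$band_68[[2]], est$band_98[[2]])

  zeta <- slope_from_params(post$draws, mean(x))
  h <- hist(zeta, breaks = 40, plot = FALSE)
  mode_oracle <- h$mids[which.max(h$counts)]
  expect_lt(abs(est$zeta_map - mode_oracle), diff(h$mids[1:2]))

  ## degenerate draws give degenerate bands
  post_deg <- post
  post_deg$draws <- matrix(rep(c(0, -2, 0, 0, 1), each = 10), 10, 5,
                           dimnames = list(NULL, colnames(post$draws)))
  est_deg <- slope_summary(post_deg, 0)
  expect_equal(est_deg$zeta_map, -2)
  expect_equal(unname(est_deg$band_98), c(-2, -2))
})

test_that("rolling drift-slope scan matches the window contract and recovers stationary drift", {
  x <- sim_ou(3000, -1, 1, 0.02, seed = 40)
  spec <- window_spec(1000, 1000)
  out <- rolling_drift_slope(x, 0.02, spec = spec, config = tiny_mcmc(),
                             seed = 41)
  expect_s3_class(out, "slope_series")
  expect_equal(nrow(out), nrow(rolling_windows(x, spec)))
  expect_true(all(is.finite(out$zeta_map)))
  ## stationary series: every window's 98% band covers the true drift slope
  ## and the point estimates scatter around it
  expect_true(all(out$q01 <= -1 & -1 <= out$q99))
  expect_lt(abs(mean(out$zeta_map) - (-1)), 0.5)
  expect_equal(out$x_star[1], mean(x[1:1000]))

  ## a failing window is recorded as missing, not fatal
  x2 <- c(rep(0, 1000), x)
  out2 <- rolling_drift_slope(x2, 0.02, spec = spec, config = tiny_mcmc(),
                              seed = 42)
  expect_true(is.na(out2$zeta_map[1]))
  expect_false(any(is.na(out2$zeta_map[-1])))
})
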