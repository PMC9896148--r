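test_that("trend prior follows the series-adapted recipe", {
  y <- c(0.3, 0.5, 0.9, 1.1)
  t <- c(0, 1, 2, 3)
  pr <- build_trend_prior(y, t)
  expect_equal(pr$intercept_mean, 0.3)
  expect_equal(pr$intercept_sd, 1)
  expect_equal(pr$slope_min, 0)
  expect_equal(pr$slope_max, 1.5 * (1.1 - 0.3) / 3)
  expect_equal(c(pr$log_noise_min, pr$log_noise_max), log(c(0.5, 5)))

  neg <- build_trend_prior(y, t, direction = "negative")
  expect_equal(c(neg$slope_min, neg$slope_max), c(-pr$slope_max, 0))

  const <- build_trend_prior(c(2, 2, 2), 0:2)
  expect_equal(c(const$slope_min, const$slope_max), c(0, 0))

  expect_error(build_trend_prior(1, 0), "at least 2")
  expect_error(build_trend_prior(y, t, n_draws = 10), "1000")
})

test_that("Monte-Carlo evidence matches a quadrature oracle on a single point", {
  ## one observation; priors fixed by a reference series
  pr <- build_trend_prior(c(0.3, 1.3), c(0, 10), n_draws = 2e5)
  y <- 0.3; tt <- 5

  ## independent oracle: direct numerical integration over (b, s[, a])
  lik <- function(b, s, a = 0) dnorm(y, a * tt + b, s)
  s_dens <- function(s) 1 / (s * (log(5) - log(0.5)))
  ev_const_oracle <- integrate(function(s) {
    sapply(s, function(si) {
      integrate(function(b) lik(b, si) * dnorm(b, 0.3, 1), -8, 8)$value *
        s_dens(si)
    })
  }, 0.5, 5)$value
  ev_lin_oracle <- integrate(function(a) {
    sapply(a, function(ai) {
      integrate(function(s) {
        sapply(s, function(si) {
          integrate(function(b) lik(b, si, ai) * dnorm(b, 0.3, 1),
                    -8, 8)$value * s_dens(si)
        })
      }, 0.5, 5)$value / pr$slope_max
    })
  }, 0, pr$slope_max)$value

  e_const <- model_evidence(y, tt, "constant", pr, seed = 1)
  e_lin <- model_evidence(y, tt, "linear", pr, seed = 1)
  expect_equal(e_const$evidence, ev_const_oracle, tolerance = 0.03)
  expect_equal(e_lin$evidence, ev_lin_oracle, tolerance = 0.03)
  ## a positive-slope prior wastes mass away from a flat datum
  expect_gt(e_const$evidence, e_lin$evidence)

  expect_error(model_evidence(numeric(0), numeric(0), "linear", pr),
               "empty")
})

test_that("evidence estimates converge with the number of draws", {
  set.seed(12)
  y <- 0.5 + 0.04 * (0:20) + rnorm(21, 0, 0.3)
  t <- 0:20
  ev_at <- function(n, seeds) {
    pr <- build_trend_prior(y, t, n_draws = n)
    sapply(seeds, function(s)
      model_evidence(y, t, "linear", pr, seed = s)$evidence)
  }
  e_small <- ev_at(2e3, 1:12)
  e_big <- ev_at(3.2e4, 1:12)
  ## 16x draws: Monte-Carlo scatter should shrink about 4x
  ratio <- sd(e_small) / sd(e_big)
  expect_gt(ratio, 1.8)
  ## and the two means agree
  expect_equal(mean(e_small), mean(e_big),
               tolerance = 4 * sd(e_small) / sqrt(12) / mean(e_big))
})

test_that("trending series earn decisive Bayes factors, flat series do not", {
  t <- 0:29
  decisive <- 0; flat_ok <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    y_trend <- 1 + 0.1 * t + rnorm(30, 0, 0.2)
    pr <- build_trend_prior(y_trend, t, n_draws = 2e4)
    bf <- bayes_factor(model_evidence(y_trend, t, "linear", pr, seed = s),
                       model_evidence(y_trend, t, "constant", pr, seed = s))
    decisive <- decisive + (bf$BF12 > 100)

    y_flat <- 2 + rnorm(30, 0, 0.2)
    pr2 <- build_trend_prior(y_flat, t, n_draws = 2e4)
    bf2 <- bayes_factor(model_evidence(y_flat, t, "linear", pr2, seed = s),
                        model_evidence(y_flat, t, "constant", pr2, seed = s))
    flat_ok <- flat_ok + (bf2$BF12 < 100 && bf2$BF21 < 100)
  }
  expect_equal(decisive, 20)
  expect_gte(flat_ok, 19)                   # no false strong preference
})

test_that("Bayes-factor degeneracies follow the zero-evidence conventions", {
  e_pos <- function(le) structure(list(log_evidence = le, evidence = exp(le),
                                       zero = FALSE), class = "evidence")
  e_zero <- structure(list(log_evidence = -Inf, evidence = 0, zero = TRUE),
                      class = "evidence")
  bf <- bayes_factor(e_pos(-5), e_pos(-5))
  expect_equal(c(bf$BF12, bf$BF21), c(1, 1))
  expect_false(bf$inadequate)
  expect_equal(bf$BF12 * bf$BF21, 1)

  bf <- bayes_factor(e_pos(-3), e_zero)
  expect_identical(c(bf$BF12, bf$BF21), c(Inf, 0))

  bf <- bayes_factor(e_zero, e_pos(-3))
  expect_identical(c(bf$BF12, bf$BF21), c(0, Inf))

  bf <- bayes_factor(e_zero, e_zero)
  expect_true(bf$inadequate)

  ## bare numbers work too
  expect_equal(bayes_factor(2e-5, 1e-5)$BF12, 2)
  expect_true(bayes_factor(0, 0)$inadequate)
})

test_that("classification is a pure threshold rule over all degenerate combinations", {
  lab <- function(b12, b21, inad = FALSE)
    classify_trend(list(BF12 = b12, BF21 = b21, inadequate = inad))
  expect_equal(lab(101, 1 / 101), "significant_linear")
  expect_equal(lab(Inf, 0), "significant_linear")
  expect_equal(lab(1 / 101, 101), "significant_constant")
  expect_equal(lab(0, Inf), "significant_constant")
  expect_equal(lab(50, 0.02), "undecided")
  expect_equal(lab(100, 0.01), "undecided")   # strict threshold
  expect_equal(lab(1, 1), "undecided")
  expect_equal(lab(NaN, NaN, inad = TRUE), "inadequate")
  expect_equal(lab(200, 1 / 200, inad = TRUE), "inadequate")
})

test_that("landmark truncation keeps alignment and handles edge cases", {
  y <- 1:10; t <- seq(2, 20, by = 2)
  tr <- truncate_at_landmark(y, t, 11)
  expect_equal(tr$values, 1:5)
  expect_equal(tr$times, seq(2, 10, by = 2))
  expect_length(truncate_at_landmark(y, t, 1)$values, 0)
  expect_equal(truncate_at_landmark(y, t, 100)$values, y)
})
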