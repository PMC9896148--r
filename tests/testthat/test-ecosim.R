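test_that("drift field reproduces the model equations", {
  p <- eco_params()
  d <- drift_field(eco_state(A = 10, J = 0, F = 0, qE = 1), p)
  expect_equal(d[["dA_dt"]], -10)

  d <- drift_field(eco_state(A = 0, J = 0, F = 100, qE = 1), p)
  expect_equal(d[["dF_dt"]], 0)  # refuge equilibrium

  d <- drift_field(eco_state(A = 1, J = 1, F = 8, qE = 1), p)
  expect_equal(d[["dJ_dt"]], -0.001 - 4 / 13)

  bad <- list(A = NaN, J = 1, F = 1, qE = 1)
  expect_error(drift_field(bad, p), "invalid state")
})

test_that("Euler-Maruyama step advances drift, adds forcing to F only, clips at zero", {
  p <- eco_params(sigma = 1)
  s1 <- step_euler_maruyama(eco_state(A = 10, J = 0, F = 0, qE = 1), p, z = 0)
  expect_equal(s1$A, 10 * (1 - 1 / 50))

  ## fixed point of the continuous flow: A = J = 0, F = F_R
  s2 <- step_euler_maruyama(eco_state(A = 0, J = 0, F = 100, qE = 1),
                            eco_params(), z = 0)
  expect_equal(c(s2$A, s2$J, s2$F), c(0, 0, 100))

  ## large negative forcing cannot push F below zero
  s3 <- step_euler_maruyama(eco_state(A = 0, J = 0, F = 0.5, qE = 1), p,
                            z = -100)
  expect_equal(s3$F, 0)

  expect_error(step_euler_maruyama(eco_state(1, 1, 1, qE = 1),
                                   within(unclass(p), dt <- -1)),
               "dt")
})

test_that("maturation map updates cohorts, year and harvest ramp", {
  p <- eco_params()
  s <- maturation(eco_state(A = 10, J = 6, F = 3, year = 4, tau = 1), p)
  expect_equal(s$A, 0.5 * 16)
  expect_equal(s$J, 2 * s$A)
  expect_equal(s$F, 3)                      # planktivores carry over
  expect_equal(s$year, 5L)
  expect_equal(s$qE, 1 + 0.013 * 5)

  s0 <- maturation(eco_state(A = 10, J = 6, F = 3, tau = 1),
                   eco_params(s_surv = 0))
  expect_equal(c(s0$A, s0$J), c(0, 0))      # extinction when nothing survives

  expect_error(maturation(eco_state(1, 1, 1, tau = 0.5), p), "tau = 1")
})

test_that("deterministic simulation stays in the piscivore regime and is reproducible", {
  p <- eco_params()
  tr <- simulate_foodweb(p, years = 30)
  expect_true(all(tr$F >= 0 & tr$F < 1))    # tiny planktivore abundance
  ## later stable-regime years: planktivores strictly present but scarce
  ## (earlier years clip F to 0 at year starts, an explicit-Euler overshoot)
  mid <- tr$qE > 1.5 & tr$qE < 1.7
  expect_true(all(tr$F[mid] > 0 & tr$F[mid] < 1))
  expect_true(all(diff(tr$time_years) > 0))
  expect_equal(nrow(tr), 30 * 50)
  expect_equal(tr$qE[1], 1)
  expect_equal(tr$qE[nrow(tr)], 1 + 0.013 * 29)

  nz <- white_noise(20 * 50, 1 / 50, seed = 11)
  p2 <- eco_params(sigma = 2.2)
  tr1 <- simulate_foodweb(p2, 20, noise = nz, seed = 11)
  tr2 <- simulate_foodweb(p2, 20, noise = nz, seed = 11)
  expect_identical(tr1, tr2)                # bit-identical rerun
  expect_true(all(tr1$F >= 0))

  expect_error(simulate_foodweb(p2, 30, noise = nz), "too short")
  expect_error(simulate_foodweb(p2, 10), "noise series is required")
})

test_that("with piscivores extinct the planktivores relax monotonically to the refuge level", {
  p <- eco_params()
  tr <- simulate_foodweb(p, years = 200, burn_in = 0,
                         init = c(A = 0, J = 0, F = 1))
  expect_true(all(diff(tr$F) >= 0))
  expect_lt(abs(tr$F[nrow(tr)] - 100), 1e-4)
})

test_that("deterministic year-end abundances converge under step halving", {
  end_A <- function(dt) {
    tr <- simulate_foodweb(eco_params(dt = dt), years = 30)
    tr$A[nrow(tr)]
  }
  a1 <- end_A(1 / 50); a2 <- end_A(1 / 100); a4 <- end_A(1 / 200)
  ## first-order scheme: the dt -> dt/2 change shrinks roughly twofold
  expect_lt(abs(a1 - a2) / a2, 0.05)
  expect_lt(abs(a2 - a4), abs(a1 - a2))
})

test_that("transition detection flags the first planktivore exceedance", {
  expect_null(detect_transition(data.frame(time_years = 1:10, F = 5)))

  t <- seq(0.02, 40, by = 0.02)
  traj <- data.frame(time_years = t, F = t)
  res <- detect_transition(traj)
  expect_equal(res$time, t[t > 21][1])

  ## stochastic run: the transition follows the attractor switch
  nz <- white_noise(125 * 50, 1 / 50, seed = 7)
  tr <- simulate_foodweb(eco_params(sigma = 2.2), 125, noise = nz, seed = 7)
  res <- detect_transition(tr)
  expect_false(is.null(res))
  expect_gt(res$time, cached_switch()$year)
})

test_that("landmark scans honour their preconditions and degenerate contracts", {
  expect_error(find_attractor_switch(eco_params(sigma = 1)), "sigma = 0")
  expect_error(find_point_of_no_return(eco_params(sigma = 1)), "sigma = 0")

  ## reproduction strong enough to compensate any scanned harvest: no switch
  p_safe <- eco_params(f_fec = 60)
  sw <- find_attractor_switch(p_safe, years = 40, horizon = 60)
  expect_false(sw$found)
  expect_true(is.na(sw$qE))

  expect_error(find_point_of_no_return(p_safe, years = 40),
               "never occurs")
})

test_that("the attractor switch is stable under integration-step halving", {
  sw1 <- cached_switch()
  sw2 <- find_attractor_switch(eco_params(dt = 1 / 100), years = 80,
                               horizon = 300)
  expect_lte(abs(sw1$qE - sw2$qE), 2 * 0.013 + 1e-9)  # within two ramp steps
})

test_that("rescue failure is monotone along the ramp", {
  pnr <- cached_pnr()
  p <- eco_params()
  ramp <- ecoresilience:::.run_ramp(p, pnr$year + 10)
  fails <- vapply((pnr$year - 3):(pnr$year + 3), function(y) {
    ecoresilience:::.rescue_fails(ramp$starts[y, ], p)
  }, logical(1))
  expect_equal(fails, c(rep(FALSE, 3), rep(TRUE, 4)))
})

test_that("analytic drift slope follows the realized adult abundance", {
  p <- eco_params()
  tr <- simulate_foodweb(p, years = 4)
  ## constant A: smoothing is the identity
  fake <- data.frame(time_years = tr$time_years, A = 10)
  out <- analytic_drift_slope(fake, p, window_spec(50, 50))
  expect_true(all(abs(out$slope - (-3.1)) < 1e-12))
  fake$A <- 0
  out0 <- analytic_drift_slope(fake, p, window_spec(50, 50))
  expect_true(all(out0$slope == -0.1))
  ## per-window mean oracle
  out2 <- analytic_drift_slope(tr, p, window_spec(100, 37))
  w <- rolling_windows(tr$A, window_spec(100, 37))
  manual <- sapply(seq_len(nrow(w)),
                   function(k) mean(-(0.1 + 0.3 * tr$A[w$start[k]:w$end[k]])))
  expect_equal(out2$slope, manual)
})

test_that("trajectories round-trip through CSV with their JSON sidecar", {
  tr <- simulate_foodweb(eco_params(), years = 2, seed = 3)
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
  expect_equal(attr(back, "params")$c_FA, 0.3)
  expect_equal(attr(back, "seed"), 3)
  unlink(c(path, paste0(path, ".json")))
})
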