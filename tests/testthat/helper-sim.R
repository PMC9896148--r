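## Euler-Maruyama simulation of a linear-drift Langevin (OU) process,
## independent of the package's simulators; used as a known-truth source for
## estimator-recovery tests
sim_ou <- function(n, theta1, sigma, dt, seed, x_star = 0) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- x_star + stats::rnorm(1, 0, sigma / sqrt(-2 * theta1))
  w <- stats::rnorm(n - 1, 0, sigma * sqrt(dt))
  for (i in 2:n) x[i] <- x[i - 1] + theta1 * (x[i - 1] - x_star) * dt + w[i - 1]
  x
}

## small MCMC settings for unit tests (posterior checks that do not need the
## full production chain)
tiny_mcmc <- function() mcmc_config(n_walkers = 20, n_steps = 600,
                                    n_burnin = 200, thin = 4)
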