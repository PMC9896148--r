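#' Deterministic right-hand sides of the continuous monitoring interval
#'
#' Within a year the model evolves continuously: adults decay under harvest,
#' planktivores exchange with their refuge and are consumed by adults, and
#' juveniles are lost to adult control and planktivore predation through a
#' foraging-arena saturation term.
#'
#' @param state An [eco_state()] (or any list with `A`, `J`, `F`, `qE`).
#' @param p An [eco_params()].
#' @return Named numeric vector `c(dA_dt, dF_dt, dJ_dt)`.
#' @examples
#' p <- eco_params()
#' drift_field(eco_state(A = 10, J = 0, F = 0, qE = 1), p)
#' @export
drift_field <- function(state, p) {
  A <- state$A; J <- state$J; F <- state$F; qE <- state$qE
  if (any(!is.finite(c(A, J, F, qE))))
    stop("invalid state: non-finite abundances or harvest rate", call. = FALSE)
  if (any(c(A, J, F) < 0))
    stop("invalid state: negative abundances", call. = FALSE)
  dA <- -qE * A
  dF <- p$D_F * (p$F_R - F) - p$c_FA * F * A
  dJ <- -p$c_JA * J * A - p$c_JF * p$nu * F * J / (p$h_ref + p$nu + p$c_JF * F)
  c(dA_dt = dA, dF_dt = dF, dJ_dt = dJ)
}

#' One Euler-Maruyama step of the monitoring interval
#'
#' Advances the state by `dt` with explicit Euler drift; the stochastic
#' forcing increment `z` (already on the per-step scale) enters the
#' planktivore equation only, scaled by `sigma`.  Abundances are clipped at
#' zero so the state stays physical for arbitrarily large negative forcing.
#'
#' @param state An [eco_state()].
#' @param p An [eco_params()].
#' @param z One forcing increment for this step (defaults to 0).
#' @return The advanced `eco_state`.
#' @examples
#' p <- eco_params()
#' s <- step_euler_maruyama(eco_state(A = 10, J = 0, F = 0, qE = 1), p)
#' s$A  # 10 * (1 - 1/50)
#' @export
step_euler_maruyama <- function(state, p, z = 0) {
  if (p$dt <= 0) stop("dt must be > 0", call. = FALSE)
  d <- drift_field(state, p)
  dt <- p$dt
  A <- max(state$A + d[["dA_dt"]] * dt, 0)
  F <- max(state$F + d[["dF_dt"]] * dt + p$sigma * z, 0)
  J <- max(state$J + d[["dJ_dt"]] * dt, 0)
  eco_state(A = A, J = J, F = F, year = state$year,
            tau = min(state$tau + dt, 1), qE = state$qE)
}

#' Annual maturation map
#'
#' At the end of each monitoring interval (`tau = 1`) surviving adults and
#' juveniles merge into the new adult cohort with overwinter survival
#' `s_surv`, the new juvenile cohort is spawned with fecundity `f_fec`,
#' planktivores carry over unchanged, and the harvest ramp advances by one
#' year.
#'
#' @param state An [eco_state()] with `tau = 1`.
#' @param p An [eco_params()].
#' @return The post-maturation `eco_state` at `tau = 0` of the next year.
#' @examples
#' p <- eco_params()
#' maturation(eco_state(A = 10, J = 6, F = 1, tau = 1), p)
#' @export
maturation <- function(state, p) {
  if (abs(state$tau - 1) > 1e-8)
    stop("maturation must be applied at tau = 1 (end of the year)",
         call. = FALSE)
  A_new <- p$s_surv * (state$A + state$J)
  year <- state$year + 1L
  eco_state(A = A_new, J = p$f_fec * A_new, F = state$F, year = year,
            tau = 0, qE = p$qE_init + p$dqE * year)
}

## ---- fast internal kernels (plain vectors, no S3 dispatch) ----------------

## one monitoring interval; st = c(A, J, F); z = per-step forcing increments
## (length 1/dt) or NULL; returns either the year-end state or, if record,
## the full (1/dt) x 3 matrix of states after every Euler step.
.year_monitor <- function(st, qE, p, z = NULL, record = FALSE) {
  dt <- p$dt
  n <- round(1 / dt)
  A <- st[1]; J <- st[2]; F <- st[3]
  sig <- p$sigma
  if (record) out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    dA <- -qE * A
    dF <- p$D_F * (p$F_R - F) - p$c_FA * F * A
    dJ <- -p$c_JA * J * A - p$c_JF * p$nu * F * J /
      (p$h_ref + p$nu + p$c_JF * F)
    A <- max(A + dA * dt, 0)
    F <- max(F + dF * dt + (if (is.null(z)) 0 else sig * z[i]), 0)
    J <- max(J + dJ * dt, 0)
    if (record) { out[i, 1] <- A; out[i, 2] <- J; out[i, 3] <- F }
  }
  if (record) out else c(A, J, F)
}

.maturate_vec <- function(st, p) {
  A <- p$s_surv * (st[1] + st[2])
  c(A, p$f_fec * A, st[3])
}

## deterministic burn-in at qE_init; returns the year-start state on the
## (approximate) attractor
.burn_in <- function(p, init = c(A = 200, J = 400, F = 1), years = 20) {
  st <- unname(init)
  for (y in seq_len(years))
    st <- .maturate_vec(.year_monitor(st, p$qE_init, p, z = NULL), p)
  st
}

#' Simulate the seasonal model under the harvest ramp
#'
#' Alternates `1/dt` Euler-Maruyama steps of the continuous dynamics with one
#' maturation map per year while the harvest rate follows its linear ramp.
#' The run starts on the deterministic attractor at `qE_init`, found by a
#' discarded deterministic burn-in; the state is recorded after every Euler
#' step (so the first record of each year already reflects the maturation
#' map applied at the year boundary).
#'
#' @param p An [eco_params()]; `p$sigma` scales the forcing.
#' @param years Number of ramp years to simulate.
#' @param noise A [noise_series()] whose increments drive the planktivore
#'   equation; required when `p$sigma > 0` and must hold at least
#'   `years / dt` increments.
#' @param seed Optional integer; only recorded for provenance (all
#'   randomness lives in `noise`).
#' @param burn_in Deterministic burn-in years discarded before the ramp.
#' @param init Abundances `c(A, J, F)` from which the burn-in starts.
#' @return An `eco_trajectory`: a `data.frame` with columns `time_years`,
#'   `A`, `J`, `F`, `qE` and attributes `params`, `seed`, `noise_kind`.
#' @examples
#' tr <- simulate_foodweb(eco_params(), years = 5)
#' head(tr)
#' @export
simulate_foodweb <- function(p, years, noise = NULL, seed = NULL,
                             burn_in = 20, init = c(A = 200, J = 400, F = 1)) {
  spy <- round(1 / p$dt)
  n <- years * spy
  z <- NULL
  if (p$sigma > 0) {
    if (is.null(noise))
      stop("a noise series is required when sigma > 0", call. = FALSE)
    z <- noise_increments(noise)
    if (length(z) < n)
      stop(sprintf("noise series too short: %d increments needed, %d given",
                   n, length(z)), call. = FALSE)
  }
  st <- .burn_in(p, init = init, years = burn_in)
  A <- J <- F <- qE <- numeric(n)
  for (y in seq_len(years) - 1L) {
    qE_y <- p$qE_init + p$dqE * y
    zy <- if (is.null(z)) NULL else z[(y * spy + 1):((y + 1) * spy)]
    rec <- .year_monitor(st, qE_y, p, z = zy, record = TRUE)
    idx <- (y * spy + 1):((y + 1) * spy)
    A[idx] <- rec[, 1]; J[idx] <- rec[, 2]; F[idx] <- rec[, 3]
    qE[idx] <- qE_y
    st <- .maturate_vec(rec[spy, ], p)
  }
  tr <- data.frame(time_years = seq_len(n) * p$dt, A = A, J = J, F = F,
                   qE = qE)
  attr(tr, "params") <- p
  attr(tr, "seed") <- seed
  attr(tr, "noise_kind") <- if (is.null(noise)) "none" else noise$kind
  class(tr) <- c("eco_trajectory", "data.frame")
  tr
}

#' @export
print.eco_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("eco_trajectory: %d samples (%g years at %d/yr), noise = %s, sigma = %g\n",
              nrow(x), max(x$time_years), round(1 / p$dt),
              attr(x, "noise_kind"), p$sigma))
  cat(sprintf("  qE ramp %.3f -> %.3f; final A = %.3g, F = %.3g\n",
              x$qE[1], x$qE[nrow(x)], x$A[nrow(x)], x$F[nrow(x)]))
  invisible(x)
}
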