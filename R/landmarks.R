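#' Detect the planktivore transition
#'
#' The regime shift is flagged at the first sample at which the planktivore
#' abundance exceeds a threshold (21 by convention: the level beyond which
#' the planktivore population grows without bound toward its refuge
#' equilibrium).
#'
#' @param traj An `eco_trajectory` (or any data.frame with `time_years`, `F`).
#' @param threshold Planktivore abundance threshold.
#' @return A list with `time` (years), `index` and `qE` of the first
#'   exceedance, or `NULL` when the threshold is never crossed.
#' @export
detect_transition <- function(traj, threshold = 21) {
  i <- which(traj$F > threshold)[1]
  if (is.na(i)) return(NULL)
  list(time = traj$time_years[i], index = i,
       qE = if ("qE" %in% names(traj)) traj$qE[i] else NA_real_)
}

## deterministic ramp bookkeeping: year-start states, year-end states and the
## per-year harvest rate, after burn-in
.run_ramp <- function(p, years, burn_in = 20,
                      init = c(A = 200, J = 400, F = 1)) {
  st <- .burn_in(p, init = init, years = burn_in)
  starts <- ends <- matrix(NA_real_, years, 3)
  qE <- p$qE_init + p$dqE * (seq_len(years) - 1)
  for (y in seq_len(years)) {
    starts[y, ] <- st
    e <- .year_monitor(st, qE[y], p)
    ends[y, ] <- e
    st <- .maturate_vec(e, p)
  }
  list(starts = starts, ends = ends, qE = qE)
}

## does the frozen-qE system, started from st, keep a positive piscivore
## attractor?  FALSE once the planktivore transition (F > 21) occurs.
.frozen_stable <- function(st, qE, p, horizon = 300, threshold = 21) {
  prevA <- NA_real_
  for (y in seq_len(horizon)) {
    e <- .year_monitor(st, qE, p)
    if (e[3] > threshold) return(FALSE)
    st <- .maturate_vec(e, p)
    if (!is.na(prevA) && abs(e[1] - prevA) < 1e-9 * max(e[1], 1e-12) &&
        e[1] > 1e-3)
      return(TRUE)
    prevA <- e[1]
  }
  TRUE
}

#' Locate the attractor switch point of the deterministic model
#'
#' Scans the deterministic (`sigma = 0`) harvest ramp for the harvest rate at
#' which the piscivore-dominated annual cycle ceases to exist.  For each ramp
#' year the harvest rate is frozen at that year's value and the annual
#' map-flow dynamics are iterated from the ramp state: while a stable
#' piscivore attractor exists the iteration settles onto it; past the switch
#' the frozen system relaxes to the planktivore-dominated state instead.  The
#' switch is the first ramp year whose frozen dynamics collapse, reported at
#' the ramp resolution `dqE`.
#'
#' @param p An [eco_params()] with `sigma = 0`.
#' @param years Ramp years to scan.
#' @param horizon Years each frozen-qE probe may run before it is declared
#'   stable.
#' @param burn_in Deterministic burn-in years before the ramp.
#' @return A list with `qE`, `year` (1-based ramp year) and `found`; when no
#'   switch occurs within the scan, `found` is `FALSE` and `qE` is `NA`.
#' @export
find_attractor_switch <- function(p, years = 120, horizon = 300,
                                  burn_in = 20) {
  if (p$sigma != 0)
    stop("the attractor switch is defined on the deterministic model (sigma = 0)",
         call. = FALSE)
  ramp <- .run_ramp(p, years, burn_in = burn_in)
  for (y in seq_len(years)) {
    if (!.frozen_stable(ramp$starts[y, ], ramp$qE[y], p, horizon = horizon))
      return(list(qE = ramp$qE[y], year = y, found = TRUE))
  }
  list(qE = NA_real_, year = NA_integer_, found = FALSE)
}

## outcome of one rescue experiment: TRUE when the transition still occurs
.rescue_fails <- function(st, p, rescue_qE = 0.1, horizon = 200,
                          threshold = 21) {
  for (y in seq_len(horizon)) {
    e <- .year_monitor(st, rescue_qE, p)
    if (e[3] > threshold) return(TRUE)
    ## planktivores pushed back into the piscivore-regime range: recovered
    if (y > 1 && e[3] < 0.5) return(FALSE)
    st <- .maturate_vec(e, p)
  }
  FALSE
}

#' Locate the point of no return of the deterministic model
#'
#' For each ramp year the state is cloned, the harvest rate is abruptly
#' reduced to `rescue_qE`, and the deterministic dynamics are integrated for
#' `horizon` further years.  The rescue fails when the planktivore transition
#' (`F > threshold`) still occurs; the point of no return is the smallest
#' ramp harvest rate at which it fails.  Rescue outcomes are monotone along
#' the ramp, so the scan stops at the first failure.
#'
#' @param p An [eco_params()] with `sigma = 0`.
#' @param rescue_qE Harvest rate applied from the rescue year on.
#' @param horizon Years the rescue experiment is integrated.
#' @param years Ramp years to scan.
#' @param threshold Planktivore transition threshold.
#' @param burn_in Deterministic burn-in years before the ramp.
#' @return A list with `qE` and `year` of the first failing rescue.
#' @export
find_point_of_no_return <- function(p, rescue_qE = 0.1, horizon = 200,
                                    years = 140, threshold = 21,
                                    burn_in = 20) {
  if (p$sigma != 0)
    stop("the point of no return is defined on the deterministic model (sigma = 0)",
         call. = FALSE)
  ramp <- .run_ramp(p, years, burn_in = burn_in)
  for (y in seq_len(years)) {
    if (.rescue_fails(ramp$starts[y, ], p, rescue_qE = rescue_qE,
                      horizon = horizon, threshold = threshold))
      return(list(qE = ramp$qE[y], year = y))
  }
  stop("the transition never occurs within the scanned ramp; no point of no return",
       call. = FALSE)
}

#' Analytic drift slope of the planktivore equation along a trajectory
#'
#' The partial derivative of the planktivore drift with respect to `F` is
#' `-(D_F + c_FA * A(t))`: the planktivore relaxation rate along the realized
#' adult abundance.  Smoothed over the same rolling windows as the estimator,
#' it is the analytic reference curve for the estimated drift slope.
#'
#' @param traj An `eco_trajectory`.
#' @param p An [eco_params()].
#' @param spec A [window_spec()].
#' @return A `data.frame` with `window_end_time` and `slope` (per-window mean
#'   of the pointwise derivative).
#' @export
analytic_drift_slope <- function(traj, p, spec) {
  s_t <- -(p$D_F + p$c_FA * traj$A)
  w <- rolling_windows(s_t, spec, times = traj$time_years)
  slope <- vapply(seq_len(nrow(w)),
                  function(k) mean(s_t[w$start[k]:w$end[k]]), numeric(1))
  data.frame(window_end_time = w$end_time, slope = slope)
}
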