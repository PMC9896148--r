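#' Parameters of the seasonal harvested food-web model
#'
#' Constructs the full parameter set of the three-species model: adult
#' piscivores `A` are removed by harvest, planktivores `F` exchange with a
#' refuge reservoir and are eaten by adults, and juvenile piscivores `J` are
#' controlled by adults and consumed by planktivores through a foraging-arena
#' functional response.  Once a year a discrete maturation map promotes
#' surviving adults and juveniles and spawns the next juvenile cohort.
#'
#' Defaults are the standard parameterization of this model family; the
#' harvest rate ramps linearly as `qE(year) = qE_init + dqE * year`.
#'
#' @param qE_init Initial harvest rate (catchability times effort),
#'   dimensionless.
#' @param dqE Harvest-rate increase per year.
#' @param F_R Planktivore refuge reservoir abundance.
#' @param D_F Foraging-arena exchange rate between refuge and arena (1/yr).
#' @param c_FA Consumption rate of planktivores by adult piscivores.
#' @param c_JA Control rate of juveniles by adult piscivores.
#' @param c_JF Consumption rate of juvenile piscivores by planktivores.
#' @param nu Rate at which juveniles become vulnerable to planktivores.
#' @param h_ref Rate at which juveniles enter their refuge.
#' @param f_fec Fecundity of adult piscivores (juveniles per adult and year).
#' @param s_surv Overwinter survival of adults and juveniles, in `[0, 1]`.
#' @param dt Integration step in years; `1/dt` must be a whole number of
#'   samples per year.
#' @param sigma Noise level applied to the planktivore equation (0 for the
#'   deterministic model; the study levels are 0.1, 2.2 and 4.5).
#'
#' @return An object of class `eco_params`: a validated named list.
#' @examples
#' p <- eco_params()
#' p$c_FA
#' @export
eco_params <- function(qE_init = 1, dqE = 0.013, F_R = 100, D_F = 0.1,
                       c_FA = 0.3, c_JA = 0.001, c_JF = 0.5, nu = 1,
                       h_ref = 8, f_fec = 2, s_surv = 0.5, dt = 1 / 50,
                       sigma = 0) {
  p <- list(qE_init = qE_init, dqE = dqE, F_R = F_R, D_F = D_F, c_FA = c_FA,
            c_JA = c_JA, c_JF = c_JF, nu = nu, h_ref = h_ref, f_fec = f_fec,
            s_surv = s_surv, dt = dt, sigma = sigma)
  validate_eco_params(p)
  structure(p, class = "eco_params")
}

validate_eco_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("all parameters must be single finite numbers", call. = FALSE)
  rates <- c("qE_init", "dqE", "F_R", "D_F", "c_FA", "c_JA", "c_JF", "nu",
             "h_ref", "f_fec", "sigma")
  if (any(unlist(p[rates]) < 0))
    stop("all rates must be >= 0", call. = FALSE)
  if (p$s_surv < 0 || p$s_surv > 1)
    stop("s_surv must lie in [0, 1]", call. = FALSE)
  if (p$dt <= 0 || p$dt > 1)
    stop("dt must lie in (0, 1]", call. = FALSE)
  spy <- 1 / p$dt
  if (abs(spy - round(spy)) > 1e-8)
    stop("1/dt must be an integer number of samples per year", call. = FALSE)
  invisible(p)
}

#' @export
print.eco_params <- function(x, ...) {
  cat("Seasonal food-web model parameters\n")
  cat(sprintf("  harvest ramp : qE = %g + %g * year\n", x$qE_init, x$dqE))
  cat(sprintf("  planktivores : F_R = %g, D_F = %g, c_FA = %g\n",
              x$F_R, x$D_F, x$c_FA))
  cat(sprintf("  juveniles    : c_JA = %g, c_JF = %g, nu = %g, h_ref = %g\n",
              x$c_JA, x$c_JF, x$nu, x$h_ref))
  cat(sprintf("  maturation   : f = %g, s = %g\n", x$f_fec, x$s_surv))
  cat(sprintf("  integration  : dt = 1/%d yr, sigma = %g\n",
              round(1 / x$dt), x$sigma))
  invisible(x)
}

#' Model state at one instant
#'
#' @param A,J,F Adult piscivore, juvenile piscivore and planktivore abundance.
#' @param year Integer year index (0-based, counts maturation events).
#' @param tau Within-year time in `[0, 1]`.
#' @param qE Current harvest rate.
#' @return An object of class `eco_state`.
#' @export
eco_state <- function(A, J, F, year = 0L, tau = 0, qE = 1) {
  if (any(!is.finite(c(A, J, F))))
    stop("abundances must be finite", call. = FALSE)
  if (A < 0 || J < 0 || F < 0)
    stop("abundances must be >= 0", call. = FALSE)
  if (tau < 0 || tau > 1)
    stop("tau must lie in [0, 1]", call. = FALSE)
  structure(list(A = A, J = J, F = F, year = as.integer(year), tau = tau,
                 qE = qE),
            class = "eco_state")
}

#' @export
print.eco_state <- function(x, ...) {
  cat(sprintf("eco_state: A = %.4g, J = %.4g, F = %.4g (year %d, tau %.3f, qE %.3f)\n",
              x$A, x$J, x$F, x$year, x$tau, x$qE))
  invisible(x)
}
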