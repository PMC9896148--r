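#' Configuration of one analysis case
#'
#' Bundles everything one study case needs: the noise scenario, the
#' deseasonalization mode, the windowing, the MCMC and evidence settings and
#' the seed.  Two profiles are provided: `"desk"` (window shift 150 samples,
#' 1e5 evidence draws) keeps a full case tractable on a single core;
#' `"full"` (shift 30, 1e7 draws) restores the fine-grained settings.
#'
#' @param noise Noise kind: `"white"`, `"pink"` or `"red"`.
#' @param sigma Noise level (0 for the deterministic model).
#' @param years Simulated ramp years.
#' @param deseason `"auto"` (year-over-year differencing for white noise,
#'   kernel smoothing for correlated noise, none for the deterministic
#'   model), `"none"`, `"yoy"` or `"smooth"`.
#' @param window Window size in samples.
#' @param shift Window shift in samples; `NULL` takes the profile default.
#' @param profile `"desk"` or `"full"`.
#' @param seed Integer master seed for the case.
#' @param n_draws Evidence draws; `NULL` takes the profile default.
#' @param mcmc An [mcmc_config()].
#' @param landmarks Compute the deterministic landmarks and truncate the
#'   indicator series at the point of no return (`TRUE` for study-scale
#'   runs; disable for short test runs where no landmark exists).
#' @return An object of class `case_config`.
#' @export
case_config <- function(noise = c("white", "pink", "red"), sigma = 2.2,
                        years = 120, deseason = "auto", window = 750,
                        shift = NULL, profile = c("desk", "full"), seed = 1,
                        n_draws = NULL, mcmc = mcmc_config(),
                        landmarks = TRUE) {
  noise <- match.arg(noise)
  profile <- match.arg(profile)
  deseason <- match.arg(deseason, c("auto", "none", "yoy", "smooth"))
  if (is.null(shift)) shift <- if (profile == "desk") 150 else 30
  if (is.null(n_draws)) n_draws <- if (profile == "desk") 1e5 else 1e7
  if (deseason == "auto")
    deseason <- if (sigma == 0) "none"
                else if (noise == "white") "yoy" else "smooth"
  structure(list(noise = noise, sigma = sigma, years = years,
                 deseason = deseason, window = as.integer(window),
                 shift = as.integer(shift), profile = profile,
                 seed = as.integer(seed), n_draws = n_draws, mcmc = mcmc,
                 landmarks = isTRUE(landmarks)),
            class = "case_config")
}

## noise generation for a case; seeds derived from the master seed
.case_noise <- function(config, n, dt) {
  switch(config$noise,
         white = white_noise(n, dt, seed = config$seed),
         pink = pink_noise(n, dt, seed = config$seed),
         red = red_noise(n, dt, seed = config$seed))
}

## deseasonalized working series (values + times) for a case
.case_series <- function(config, traj) {
  y <- traj$F
  times <- traj$time_years
  switch(config$deseason,
         none = list(values = y, times = times),
         yoy = {
           d <- deseasonalize_yoy(y, samples_per_year = round(1 / attr(traj, "params")$dt),
                                  times = times)
           list(values = as.numeric(d), times = attr(d, "times"))
         },
         smooth = list(values = as.numeric(deseasonalize_smooth(y)),
                       times = times))
}

#' Run one end-to-end analysis case
#'
#' Simulates the model under the configured noise scenario, deseasonalizes,
#' computes the rolling classical indicators and the rolling drift slope,
#' truncates every indicator series at the point of no return, and ranks all
#' five indicator series (drift slope, AR1, standard deviation, skewness,
#' kurtosis) by the Bayes-factor trend test.
#'
#' @param config A [case_config()].
#' @param out_dir Optional directory; when given, the trajectory, indicator
#'   and drift-slope tables (CSV) and the case report (JSON) are written
#'   there, each stamped with the configuration hash and seed.
#' @return An object of class `case_report`.
#' @export
run_case <- function(config, out_dir = NULL) {
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  p <- eco_params(sigma = config$sigma)
  dt <- p$dt
  spy <- round(1 / dt)
  n <- config$years * spy
  noise <- if (config$sigma > 0) .case_noise(config, n, dt) else NULL
  traj <- stage("simulate",
                simulate_foodweb(p, config$years, noise = noise,
                                 seed = config$seed))
  ser <- stage("deseasonalize", .case_series(config, traj))
  spec <- window_spec(size = config$window, shift = config$shift)

  p_det <- eco_params(sigma = 0)
  landmarks <- list(switch_qE = NA_real_, switch_time = NA_real_,
                    pnr_qE = NA_real_, pnr_time = NA_real_,
                    transition_time = NA_real_)
  if (config$landmarks) {
    t0 <- proc.time()[["elapsed"]]
    sw <- find_attractor_switch(p_det, years = config$years)
    if (sw$found) {
      landmarks$switch_qE <- sw$qE
      landmarks$switch_time <- sw$year - 1
    }
    pnr <- tryCatch(find_point_of_no_return(p_det,
                                            years = config$years + 30),
                    error = function(e) NULL)
    if (!is.null(pnr)) {
      landmarks$pnr_qE <- pnr$qE
      landmarks$pnr_time <- pnr$year - 1
    }
    tra <- detect_transition(traj)
    if (!is.null(tra)) landmarks$transition_time <- tra$time
    timings[["landmarks"]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  indicators <- stage("indicators",
                      rolling_indicator(ser$values, spec, times = ser$times))
  wide <- config$deseason == "smooth" && config$noise %in% c("pink", "red")
  slopes <- stage("drift_slope",
                  rolling_drift_slope(ser$values, dt, spec = spec,
                                      prior = drift_prior_spec(wide = wide),
                                      config = config$mcmc,
                                      seed = config$seed * 1000,
                                      times = ser$times))
  analytic <- analytic_drift_slope(traj, p, spec)

  cutoff <- if (is.finite(landmarks$pnr_time)) landmarks$pnr_time else Inf
  series_list <- list(zeta = list(values = slopes$zeta_map,
                                  times = slopes$window_end_time),
                      ar1 = list(values = indicators$ar1,
                                 times = indicators$window_end_time),
                      std = list(values = indicators$std,
                                 times = indicators$window_end_time),
                      skewness = list(values = indicators$skewness,
                                      times = indicators$window_end_time),
                      kurtosis = list(values = indicators$kurtosis,
                                      times = indicators$window_end_time))
  bf_table <- stage("bayes_factors", do.call(rbind, lapply(names(series_list), function(nm) {
    sl <- series_list[[nm]]
    tr <- truncate_at_landmark(sl$values, sl$times, cutoff)
    keep <- is.finite(tr$values)
    if (sum(keep) < 2)
      return(data.frame(indicator = nm, evidence_linear = NA_real_,
                        evidence_constant = NA_real_, BF12 = NA_real_,
                        BF21 = NA_real_, label = "inadequate"))
    prior <- build_trend_prior(tr$values[keep], tr$times[keep],
                               n_draws = config$n_draws)
    ev_seed <- config$seed * 100 + match(nm, names(series_list))
    e1 <- model_evidence(tr$values[keep], tr$times[keep], "linear", prior,
                         seed = ev_seed)
    e2 <- model_evidence(tr$values[keep], tr$times[keep], "constant", prior,
                         seed = ev_seed)
    bf <- bayes_factor(e1, e2)
    data.frame(indicator = nm, evidence_linear = e1$evidence,
               evidence_constant = e2$evidence, BF12 = bf$BF12,
               BF21 = bf$BF21, label = classify_trend(bf))
  })))

  report <- structure(list(config = config, hash = config_hash(config),
                           landmarks = landmarks, indicators = indicators,
                           slopes = slopes, analytic = analytic,
                           bf_table = bf_table, traj = traj,
                           timings = timings),
                      class = "case_report")
  if (!is.null(out_dir)) write_case_report(report, out_dir)
  report
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("case_report: %s noise, sigma = %g, deseason = %s (hash %s)\n",
              x$config$noise, x$config$sigma, x$config$deseason, x$hash))
  cat(sprintf("  landmarks: switch qE %.3f, point of no return qE %.3f, transition t %.1f\n",
              x$landmarks$switch_qE, x$landmarks$pnr_qE,
              x$landmarks$transition_time))
  print(x$bf_table, row.names = FALSE)
  invisible(x)
}

## CSV with a provenance comment header
.write_stamped_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Write the artifacts of a case report
#'
#' @param report A `case_report`.
#' @param out_dir Output directory (created when missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_case_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- report$hash
  s <- report$config$seed
  paths <- c(trajectory = file.path(out_dir, "trajectory.csv"),
             indicators = file.path(out_dir, "indicators.csv"),
             slopes = file.path(out_dir, "drift_slope.csv"),
             report = file.path(out_dir, "report.json"))
  write_trajectory(report$traj, paths[["trajectory"]])
  .write_stamped_csv(report$indicators, paths[["indicators"]], h, s)
  .write_stamped_csv(report$slopes, paths[["slopes"]], h, s)
  jsonlite::write_json(list(config = unclass(report$config)[
                              setdiff(names(report$config), "mcmc")],
                            mcmc = unclass(report$config$mcmc),
                            config_hash = h, landmarks = report$landmarks,
                            bf_table = report$bf_table,
                            stage_timings_s = as.list(report$timings)),
                       paths[["report"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Window-size study for the drift-slope trend
#'
#' Repeats the drift-slope scan of a case for decreasing window sizes and
#' reports, per size, whether the truncated drift-slope series still carries
#' a significant positive linear trend — locating the minimal amount of data
#' per window that the estimator needs.  The trajectory is simulated once
#' and shared across sizes.
#'
#' @param config A [case_config()]; its `window` entry is overridden.
#' @param sizes Window sizes in samples, evaluated in the given order.
#' @return An object of class `window_size_study`: list with `table`
#'   (size, BF12, label) and `smallest_significant`.
#' @export
window_size_study <- function(config, sizes = c(150, 100, 50, 25)) {
  p <- eco_params(sigma = config$sigma)
  dt <- p$dt
  n <- config$years * round(1 / dt)
  noise <- if (config$sigma > 0) .case_noise(config, n, dt) else NULL
  traj <- simulate_foodweb(p, config$years, noise = noise, seed = config$seed)
  ser <- .case_series(config, traj)
  cutoff <- Inf
  if (config$landmarks) {
    pnr <- tryCatch(find_point_of_no_return(eco_params(sigma = 0),
                                            years = config$years + 30),
                    error = function(e) NULL)
    if (!is.null(pnr)) cutoff <- pnr$year - 1
  }
  wide <- config$deseason == "smooth" && config$noise %in% c("pink", "red")
  rows <- lapply(sizes, function(sz) {
    spec <- window_spec(size = sz, shift = min(config$shift, sz))
    slopes <- rolling_drift_slope(ser$values, dt, spec = spec,
                                  prior = drift_prior_spec(wide = wide),
                                  config = config$mcmc,
                                  seed = config$seed * 1000 + sz,
                                  times = ser$times)
    tr <- truncate_at_landmark(slopes$zeta_map, slopes$window_end_time,
                               cutoff)
    keep <- is.finite(tr$values)
    if (sum(keep) < 2)
      return(data.frame(size = sz, BF12 = NA_real_, label = "inadequate"))
    prior <- build_trend_prior(tr$values[keep], tr$times[keep],
                               n_draws = config$n_draws)
    e1 <- model_evidence(tr$values[keep], tr$times[keep], "linear", prior,
                         seed = config$seed * 10 + sz)
    e2 <- model_evidence(tr$values[keep], tr$times[keep], "constant", prior,
                         seed = config$seed * 10 + sz)
    bf <- bayes_factor(e1, e2)
    data.frame(size = sz, BF12 = bf$BF12, label = classify_trend(bf))
  })
  tab <- do.call(rbind, rows)
  sig <- tab$size[tab$label == "significant_linear"]
  structure(list(table = tab,
                 smallest_significant = if (length(sig)) min(sig) else NA,
                 config = config, hash = config_hash(config)),
            class = "window_size_study")
}

#' @export
print.window_size_study <- function(x, ...) {
  cat(sprintf("window_size_study (%s noise, sigma = %g):\n", x$config$noise,
              x$config$sigma))
  print(x$table, row.names = FALSE)
  cat(sprintf("  smallest significant window: %s samples\n",
              x$smallest_significant))
  invisible(x)
}
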