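#' Define a monitoring power-analysis scenario
#'
#' The reference scenario mirrors the monitoring target of the species
#' action plan: 50 transects surveyed 3 times a year for 10 years under a
#' yearly log-linear trend of -0.02 (an 18% decline over the decade; pass
#' `r_true = log(0.8) / 10` for an exact 20% decline).  Each simulated
#' trajectory is generated by [simulate_monitoring()] from the estimated
#' effect sizes and calibrated intercepts of [default_study_parameters()],
#' and both estimators are applied to the *same* simulated datasets
#' (paired comparison).
#'
#' Two success criteria for the detection-corrected estimator are offered:
#' `"cri_contains_truth"` counts a simulation as a success when the 95%
#' credible interval of the trend includes the generating value (the
#' criterion the monitoring assessment is defined with), and
#' `"cri_excludes_zero"` is the conventional significance-style criterion.
#' Non-converged fits count as failures either way.
#'
#' @param n_transects,n_years,n_visits survey design.
#' @param r_true generating yearly log-linear trend.
#' @param params generating parameters ([default_study_parameters()]).
#' @param n_sims number of simulated trajectories (>= 1).
#' @param seed scenario seed; per-simulation sub-seeds are derived from it.
#' @param estimator `"both"`, `"mixture"` or `"rawcount"`.
#' @param criterion success criterion for the mixture estimator (above).
#' @param mcmc a [trend_control()] for the per-simulation Bayesian fits
#'   (default: the `"power"` profile).
#' @param habitat_probs,weather passed to [generator_config()].
#' @return A list of class `power_scenario`.
#' @export
power_scenario <- function(n_transects = 50, n_years = 10, n_visits = 3,
                           r_true = -0.02,
                           params = default_study_parameters(),
                           n_sims = 1000, seed = 1,
                           estimator = c("both", "mixture", "rawcount"),
                           criterion = c("cri_contains_truth",
                                         "cri_excludes_zero"),
                           mcmc = trend_control("power"),
                           habitat_probs = NULL, weather = NULL) {
  estimator <- match.arg(estimator)
  criterion <- match.arg(criterion)
  if (n_sims < 1) stop("n_sims must be at least 1", call. = FALSE)
  if (n_years < 2) stop("n_years must be at least 2", call. = FALSE)
  if (!is.finite(r_true)) stop("r_true must be finite", call. = FALSE)
  set.seed(seed)
  sim_seeds <- sample.int(2147483646L, n_sims)
  structure(list(n_transects = n_transects, n_years = n_years,
                 n_visits = n_visits, r_true = r_true, params = params,
                 n_sims = as.integer(n_sims), seed = as.integer(seed),
                 sim_seeds = sim_seeds, estimator = estimator,
                 criterion = criterion, mcmc = mcmc,
                 habitat_probs = habitat_probs, weather = weather),
            class = "power_scenario")
}

#' Simulate one monitoring trajectory of a power scenario
#'
#' Deterministic given `(scenario$seed, sim_index)`: the scenario pre-draws
#' one sub-seed per simulation, so the generated data do not depend on
#' which estimators are subsequently run (paired simulation streams).
#'
#' @param scenario a [power_scenario()].
#' @param sim_index simulation number in `1..n_sims`.
#' @return A `survey_simulation` (see [simulate_survey()]).
#' @export
simulate_monitoring <- function(scenario, sim_index) {
  stopifnot(inherits(scenario, "power_scenario"),
            sim_index >= 1, sim_index <= scenario$n_sims)
  args <- list(n_transects = scenario$n_transects,
               n_years = scenario$n_years, n_visits = scenario$n_visits,
               params = scenario$params, trend = scenario$r_true,
               seed = scenario$sim_seeds[sim_index])
  if (!is.null(scenario$habitat_probs))
    args$habitat_probs <- scenario$habitat_probs
  if (!is.null(scenario$weather)) args$weather <- scenario$weather
  simulate_survey(do.call(generator_config, args))
}

#' Trend detection by the detection-corrected (mixture) estimator
#'
#' Fits the Bayesian trend model of [nmix_trend()] to one simulated dataset
#' and applies the scenario's success criterion to the 95% credible
#' interval of the trend.  A fit that fails the R-hat convergence check is
#' recorded as a failure, never dropped.
#'
#' @param dataset a [survey_dataset()] (normally from
#'   [simulate_monitoring()]).
#' @param scenario the [power_scenario()] supplying `r_true`, the criterion
#'   and the MCMC settings.
#' @return A list: `success`, `lcl`, `ucl`, `mean`, `converged`.
#' @export
mixture_detects <- function(dataset, scenario) {
  fit <- tryCatch(
    suppressWarnings(nmix_trend(dataset, config = scenario$mcmc,
                                sample_latent = FALSE)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(success = FALSE, lcl = NA_real_, ucl = NA_real_,
                mean = NA_real_, converged = FALSE))
  r <- trend_draws(fit)
  ci <- unname(quantile(r, c(0.025, 0.975)))
  hit <- cri_hit(ci, scenario$r_true, scenario$criterion)
  list(success = hit && fit$converged, lcl = ci[1], ucl = ci[2],
       mean = mean(r), converged = fit$converged)
}

cri_hit <- function(ci, r_true, criterion) {
  switch(criterion,
         cri_contains_truth = ci[1] <= r_true && r_true <= ci[2],
         cri_excludes_zero = ci[1] > 0 || ci[2] < 0,
         stop("unknown criterion: ", criterion, call. = FALSE))
}

#' Trend detection by raw-count linear regression
#'
#' The traditional analysis: counts are summed across all transects and
#' regressed on the year index by ordinary least squares; success is a
#' two-sided slope test with p < 0.05.  By default one total per year (all
#' rounds summed) is used: the three rounds of a year share the same
#' yearly detection conditions, so treating round totals as independent
#' replicates (`aggregate = "round"`, available for comparison)
#' pseudo-replicates the dominant year-level noise and overstates
#' significance.
#'
#' @param dataset a [survey_dataset()] with at least 2 years.
#' @param aggregate `"year"` (default: one summed total per year) or
#'   `"round"` (each year x round total is an observation).
#' @return A list: `success`, `p_value`, `slope`, `note` (set when the
#'   regression is degenerate, e.g. zero count variance).
#' @export
rawcount_detects <- function(dataset, aggregate = c("year", "round")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  aggregate <- match.arg(aggregate)
  if (length(dataset$years) < 2)
    stop("rawcount_detects() needs at least 2 years", call. = FALSE)
  rt <- round_totals(dataset)
  yr <- as.numeric(rownames(rt))
  d <- if (aggregate == "round")
    data.frame(total = as.vector(rt),
               year = rep(match(yr, sort(yr)) - 1, ncol(rt)))
  else
    data.frame(total = rowSums(rt, na.rm = TRUE),
               year = match(yr, sort(yr)) - 1)
  d <- d[is.finite(d$total), , drop = FALSE]
  if (nrow(d) < 3 || var(d$total) == 0)
    return(list(success = FALSE, p_value = NA_real_, slope = NA_real_,
                note = "degenerate regression (zero count variance)"))
  sm <- suppressWarnings(summary(lm(total ~ year, data = d)))$coefficients
  pv <- sm["year", "Pr(>|t|)"]
  list(success = is.finite(pv) && pv < 0.05, p_value = unname(pv),
       slope = unname(sm["year", "Estimate"]), note = NULL)
}

#' Run a simulation-based power analysis
#'
#' Loops simulate -> detect over the scenario's trajectories, applying the
#' requested estimator(s) to identical datasets, and aggregates successes
#' into power estimates with exact binomial confidence intervals.
#'
#' @param scenario a [power_scenario()].
#' @param progress print a line every 10 simulations.
#' @return An object of class `power_result`: `power` (data frame with one
#'   row per estimator: successes, n_sims, power, binomial 95% CI) and
#'   `records` (per-simulation trend estimates, intervals / p-values and
#'   convergence flags).
#' @export
run_power_analysis <- function(scenario, progress = FALSE) {
  stopifnot(inherits(scenario, "power_scenario"))
  do_mix <- scenario$estimator %in% c("both", "mixture")
  do_raw <- scenario$estimator %in% c("both", "rawcount")
  rec <- vector("list", scenario$n_sims)
  for (s in seq_len(scenario$n_sims)) {
    ds <- simulate_monitoring(scenario, s)$dataset
    row <- list(sim = s)
    if (do_mix) {
      m <- mixture_detects(ds, scenario)
      row <- c(row, list(mix_success = m$success, mix_lcl = m$lcl,
                         mix_ucl = m$ucl, mix_mean = m$mean,
                         mix_converged = m$converged))
    }
    if (do_raw) {
      r <- rawcount_detects(ds)
      row <- c(row, list(raw_success = r$success, raw_p = r$p_value,
                         raw_slope = r$slope))
    }
    rec[[s]] <- as.data.frame(row)
    if (progress && s %% 10 == 0)
      message("simulation ", s, "/", scenario$n_sims)
  }
  records <- do.call(rbind, rec)

  agg <- function(success) {
    k <- sum(success); n <- length(success)
    ci <- binom.test(k, n)$conf.int
    data.frame(successes = k, n_sims = n, power = k / n,
               lcl = ci[1], ucl = ci[2])
  }
  pw <- NULL
  if (do_mix) pw <- rbind(pw, cbind(estimator = "mixture",
                                    agg(records$mix_success)))
  if (do_raw) pw <- rbind(pw, cbind(estimator = "rawcount",
                                    agg(records$raw_success)))
  structure(list(power = pw, records = records, scenario = scenario),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("Power analysis: %d transects x %d years x %d visits, trend %.3f/yr, %d simulations\n",
              sc$n_transects, sc$n_years, sc$n_visits, sc$r_true, sc$n_sims))
  cat("  criterion:", sc$criterion, "\n")
  pw <- x$power
  for (i in seq_len(nrow(pw)))
    cat(sprintf("  %-9s power %.1f%% (%d/%d, 95%% CI %.1f-%.1f%%)\n",
                pw$estimator[i], 100 * pw$power[i], pw$successes[i],
                pw$n_sims[i], 100 * pw$lcl[i], 100 * pw$ucl[i]))
  invisible(x)
}
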