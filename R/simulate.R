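#' Generating parameters emulating the Biebrza transect study
#'
#' Effect sizes are the posterior means of the final trend model fitted to
#' the 2011-2013 transect surveys: water-depth effects on log abundance
#' (wet ground 0.51, standing water < 15 cm 0.36, > 15 cm 0.26 relative to
#' dry ground), and detection effects on the logit scale (rain 0.01 per SD,
#' vegetation 41-80 cm 0.65, 81-120 cm 0.70, > 120 cm 0.15 relative to
#' < 40 cm).  The remaining generating quantities are not published and are
#' calibrated here so that simulated surveys match the printed count
#' summaries (about 12 singing males per transect visit, range 0-51, per-visit
#' detection probability roughly 0.55-0.75):
#'
#' * `beta0 = 2.42`: first-year log abundance of an average dry transect;
#' * `sigma_b = 0.5`: SD of the transect random effect on log abundance;
#' * `alpha_year_mean = 0.25`, `alpha_year_sd = 0.25`: yearly detection
#'   intercepts are drawn from this normal distribution, reproducing the
#'   between-year variation in detectability that motivates the design;
#' * `trend = 0.08`: yearly log-linear population trend (the estimate for
#'   2011-2013); power scenarios override it.
#'
#' @return A named list of generating parameters, including `beta_water`,
#'   `alpha_veg`, `alpha_rain`, the calibrated intercepts and `sigma_b`.
#' @export
default_study_parameters <- function() {
  list(beta0 = 2.42,
       trend = 0.08,
       beta_water = c(water.wet = 0.51, water.lt15 = 0.36, water.gt15 = 0.26),
       sigma_b = 0.5,
       alpha_year_mean = 0.25,
       alpha_year_sd = 0.25,
       alpha_rain = 0.01,
       alpha_veg = c(veg.41_80 = 0.65, veg.81_120 = 0.70, veg.gt120 = 0.15))
}

#' Configuration of the synthetic survey generator
#'
#' @param n_transects,n_years,n_visits survey design (defaults 50 x 3 x 3,
#'   the study layout).
#' @param params generating parameters, see [default_study_parameters()].
#' @param trend yearly log-linear trend; overrides `params$trend` if given.
#' @param habitat_probs list with elements `veg`, `water`, `litter`: category
#'   probabilities used when assigning each of the 5 field points per
#'   transect to a category (proportions therefore come in multiples of
#'   0.2).  Default: uniform over the four categories.
#' @param weather list with `p_dry` (probability of a rain-free survey day),
#'   `rain_mean` (mean precipitation in mm on wet days, exponential),
#'   `temp_mean`, `temp_sd` (daily mean temperature, normal, deg C),
#'   `wind_shape`, `wind_scale` (daily mean wind speed, gamma).
#' @param seed mandatory integer seed.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_transects = 50, n_years = 3, n_visits = 3,
                             params = default_study_parameters(),
                             trend = NULL,
                             habitat_probs = list(veg = rep(0.25, 4),
                                                  water = rep(0.25, 4),
                                                  litter = rep(0.25, 4)),
                             weather = list(p_dry = 0.6, rain_mean = 4,
                                            temp_mean = 15, temp_sd = 3,
                                            wind_shape = 2, wind_scale = 1.5),
                             seed) {
  if (missing(seed) || is.null(seed))
    stop("generator_config() requires an explicit seed", call. = FALSE)
  stopifnot(n_transects >= 1, n_years >= 1, n_visits >= 1)
  if (!is.null(trend)) params$trend <- trend
  for (h in c("veg", "water", "litter")) {
    pr <- habitat_probs[[h]]
    if (length(pr) != 4 || abs(sum(pr) - 1) > 1e-9 || any(pr < 0))
      stop("habitat_probs$", h, " must be 4 non-negative values summing to 1",
           call. = FALSE)
  }
  structure(list(n_transects = n_transects, n_years = n_years,
                 n_visits = n_visits, params = params,
                 habitat_probs = habitat_probs, weather = weather,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# 5-point habitat profile: proportions in multiples of 0.2
draw_profile <- function(probs) as.vector(rmultinom(1, 5, probs)) / 5

#' Simulate a repeated transect survey
#'
#' Generates a multi-year survey with the hierarchical structure of the
#' monitoring design: a transect random effect `b_i ~ N(0, sigma_b^2)` drawn
#' once per transect; habitat profiles re-measured every year at 5 field
#' points per transect; latent abundances
#' `N_it ~ Poisson(exp(beta0 + b_i + trend * (t-1) + water effects))`;
#' yearly detection intercepts drawn from
#' `N(alpha_year_mean, alpha_year_sd^2)`; and per-visit counts
#' `y_itj ~ Binomial(N_it, p_itj)` with
#' `logit p_itj = alpha_year[t] + alpha_rain * rain_z + vegetation effects`
#' (`rain_z` is rain standardised over all visits of the dataset, matching
#' how the model is fitted).  Weather and the day of season are drawn from
#' the simple visit-level model of [generator_config()].
#'
#' Everything latent is returned in a truth record so that estimators can be
#' tested against the generating values.
#'
#' @param config a [generator_config()].
#' @return A list of class `survey_simulation`: `dataset` (a validated
#'   [survey_dataset()]) and `truth` (list with `b`, `alpha_year`, `lambda`,
#'   `N`, `p`, the generating `params` and the `seed`).
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  pars <- config$params
  nT <- config$n_transects; nY <- config$n_years; J <- config$n_visits

  b <- rnorm(nT, 0, pars$sigma_b)
  alpha_year <- rnorm(nY, pars$alpha_year_mean, pars$alpha_year_sd)

  site <- expand.grid(year = seq_len(nY), transect = seq_len(nT))
  site <- site[order(site$transect, site$year), c("transect", "year")]
  n <- nrow(site)

  hp <- config$habitat_probs
  veg <- t(vapply(seq_len(n), function(i) draw_profile(hp$veg), numeric(4)))
  water <- t(vapply(seq_len(n), function(i) draw_profile(hp$water), numeric(4)))
  litter <- t(vapply(seq_len(n), function(i) draw_profile(hp$litter), numeric(4)))

  eta_lam <- pars$beta0 + b[site$transect] + pars$trend * (site$year - 1) +
    drop(water[, 2:4, drop = FALSE] %*% pars$beta_water)
  lambda <- exp(eta_lam)
  N <- rpois(n, lambda)

  wx <- config$weather
  obs <- data.frame(transect = rep(site$transect, each = J),
                    year = rep(site$year, each = J),
                    visit = rep(seq_len(J), n))
  start_day <- sample.int(30, n, replace = TRUE)
  obs$day_of_season <- rep(start_day, each = J) + 2L * (obs$visit - 1L)
  wet <- rbinom(n * J, 1, 1 - wx$p_dry)
  obs$rain_mm <- wet * rexp(n * J, 1 / wx$rain_mean)
  obs$temp_c <- rnorm(n * J, wx$temp_mean, wx$temp_sd)
  obs$wind <- rgamma(n * J, shape = wx$wind_shape, scale = wx$wind_scale)

  rain_z <- (obs$rain_mm - mean(obs$rain_mm)) / max(sd(obs$rain_mm), 1e-12)
  eta_p <- alpha_year[obs$year] + pars$alpha_rain * rain_z +
    rep(drop(veg[, 2:4, drop = FALSE] %*% pars$alpha_veg), each = J)
  p <- plogis(eta_p)
  y <- rbinom(n * J, rep(N, each = J), p)

  counts <- data.frame(transect = obs$transect, year = obs$year,
                       visit = obs$visit, count = y)
  site_cov <- data.frame(site, veg, water, litter)
  names(site_cov) <- c("transect", "year", site_cov_columns())

  dataset <- survey_dataset(counts, site_cov, obs)
  truth <- list(b = b, alpha_year = alpha_year,
                site_index = site, lambda = lambda, N = N,
                p = matrix(p, n, J, byrow = TRUE),
                params = pars, seed = config$seed)
  structure(list(dataset = dataset, truth = truth),
            class = "survey_simulation")
}

#' @export
print.survey_simulation <- function(x, ...) {
  cat("Simulated survey (seed ", x$truth$seed, ")\n", sep = "")
  print(x$dataset)
  invisible(x)
}

#' Write a small golden fixture dataset
#'
#' Generates a 5-transect, 2-year survey from a fixed seed (42) and writes
#' the three CSV tables plus the latent truth record (`truth.json`) to
#' `out_dir`.  Regenerating from the recorded seed reproduces the files
#' bit-for-bit, which unit tests rely on.
#'
#' @param out_dir output directory.
#' @return Invisibly, the paths written.
#' @export
make_goldens <- function(out_dir) {
  sim <- simulate_survey(generator_config(n_transects = 5, n_years = 2,
                                          n_visits = 3, seed = 42))
  paths <- write_survey_dataset(sim$dataset, out_dir)
  tr <- sim$truth
  truth <- list(seed = tr$seed, b = tr$b, alpha_year = tr$alpha_year,
                lambda = tr$lambda, N = tr$N, p = as.vector(t(tr$p)),
                params = tr$params)
  tp <- file.path(out_dir, "truth.json")
  writeLines(simple_json(truth), tp)
  invisible(c(paths, tp))
}

# minimal JSON serialiser for numeric/list structures (full precision)
simple_json <- function(x) {
  fmt <- function(v) {
    if (is.list(v))
      return(paste0("{", paste0('"', names(v), '":',
                                vapply(v, fmt, ""), collapse = ","), "}"))
    s <- sprintf("%.17g", as.numeric(v))
    if (length(s) == 1 && is.null(names(v))) s
    else if (!is.null(names(v)))
      paste0("{", paste0('"', names(v), '":', s, collapse = ","), "}")
    else paste0("[", paste0(s, collapse = ","), "]")
  }
  fmt(x)
}
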