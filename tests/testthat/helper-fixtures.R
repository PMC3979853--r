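# Hand-built one-transect dataset (1 transect, 1 year, 3 visits).
tiny_tables <- function(counts = c(2, 3, 1)) {
  list(counts = data.frame(transect = 1, year = 2011, visit = 1:3,
                           count = counts),
       site = data.frame(transect = 1, year = 2011,
                         veg1 = 0.2, veg2 = 0.4, veg3 = 0.4, veg4 = 0,
                         water1 = 0, water2 = 0.6, water3 = 0.4, water4 = 0,
                         litter1 = 0.2, litter2 = 0.2, litter3 = 0.2,
                         litter4 = 0.4),
       obs = data.frame(transect = 1, year = 2011, visit = 1:3,
                        rain_mm = c(0, 2.5, 0), temp_c = c(14, 16, 15),
                        wind = c(2, 3, 1), day_of_season = c(3, 5, 7)))
}

tiny_dataset <- function(counts = c(2, 3, 1)) {
  tt <- tiny_tables(counts)
  survey_dataset(tt$counts, tt$site, tt$obs)
}

# small simulated survey for quick model fits
small_sim <- function(seed, n_transects = 15, n_years = 2, ...) {
  simulate_survey(generator_config(n_transects = n_transects,
                                   n_years = n_years, seed = seed, ...))
}

# short MCMC settings for unit tests (convergence not asserted there)
quick_mcmc <- function(seed = 1, ...) {
  trend_control(n_chains = 2, n_iter = 1500, n_burnin = 400, thin = 3,
                seed = seed, ...)
}

# plain-R term-by-term oracle for the marginal site likelihood
brute_site_loglik <- function(lambda, p, y, K) {
  keep <- !is.na(y)
  y <- y[keep]; p <- p[keep]
  lo <- if (length(y)) max(y) else 0
  terms <- vapply(lo:K, function(N)
    dpois(N, lambda) * prod(dbinom(y, N, p)), 0)
  log(sum(terms))
}

golden_dir <- function() system.file("extdata", "golden", package = "nmixtrend")
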