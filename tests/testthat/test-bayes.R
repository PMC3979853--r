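# one shared small fit reused across assertions in this file
shared_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- suppressWarnings(
        nmix_trend(small_sim(61, n_transects = 12)$dataset,
                   config = quick_mcmc(seed = 2)))
    memo
  }
})

test_that("MCMC configuration enforces its invariants", {
  expect_error(trend_control(n_iter = 100, n_burnin = 200), "smaller")
  expect_error(trend_control(n_chains = 1), "2 chains")
  expect_error(trend_control(chain_seeds = 1:3, n_chains = 2), "one seed per")
  cfg <- trend_control("paper")
  expect_equal(cfg$n_iter, 350000L)
  expect_equal(cfg$n_burnin, 50000L)
  expect_equal(cfg$n_chains, 3L)
})

test_that("seeded runs are reproducible draw-for-draw", {
  ds <- small_sim(62, n_transects = 8)$dataset
  f1 <- suppressWarnings(nmix_trend(ds, config = quick_mcmc(seed = 7)))
  f2 <- suppressWarnings(nmix_trend(ds, config = quick_mcmc(seed = 7)))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$N_draws, f2$N_draws)
})

test_that("identically seeded chains are flagged as degenerate with R-hat 1", {
  ds <- small_sim(63, n_transects = 8)$dataset
  cfg <- quick_mcmc(chain_seeds = c(5L, 5L))
  expect_warning(fit <- nmix_trend(ds, config = cfg), "degenerate")
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_equal(unname(fit$rhat), rep(1, length(fit$rhat)))
})

test_that("posterior draws respect hard support constraints", {
  fit <- shared_fit()
  expect_true(all(fit$draws[, "sigma_b"] > 0))
  expect_true(all(fit$N_draws >= rep(fit$design$maxy,
                                     each = nrow(fit$N_draws))))
  s <- fit$summary
  expect_true(all(s$lcl <= s$mean & s$mean <= s$ucl))
})

test_that("annual totals never fall below the best raw round", {
  fit <- shared_fit()
  tot <- annual_totals(fit)
  mx <- apply(round_totals(fit$dataset), 1, max)
  expect_true(all(attr(tot, "draws") >= rep(mx, each = nrow(fit$N_draws))))
  # totals are the by-year sums of the latent draws
  expect_equal(tot$mean,
               unname(drop(colMeans(fit$N_draws) %*%
                             outer(fit$design$year_of_site, 1:2, `==`))),
               tolerance = 1e-9)
})

test_that("with perfect detection the totals concentrate on the counts", {
  pars <- default_study_parameters()
  pars$alpha_year_mean <- 12; pars$alpha_year_sd <- 0
  pars$alpha_veg <- c(0, 0, 0); pars$alpha_rain <- 0
  sim <- simulate_survey(generator_config(n_transects = 6, n_years = 1,
                                          params = pars, seed = 64))
  fit <- suppressWarnings(nmix_trend(sim$dataset, config = quick_mcmc(seed = 3)))
  tot <- annual_totals(fit)
  expect_equal(tot$mean, sum(sim$truth$N), tolerance = 0.02)
  expect_lt(tot$sd, 2)
})

test_that("correction factors and extrapolation do the published arithmetic", {
  expect_equal(round(correction_factor(780, round_counts = c(542, 574, 608)), 2),
               1.28)
  expect_equal(correction_factor(600, round_counts = c(600, 550)), 1)
  expect_error(correction_factor(100, round_counts = c(0, 0)), "zero")

  ex <- extrapolate_population(2594, 1)
  expect_equal(ex$estimate, 2594)
  set.seed(1); dr <- runif(500, 1.1, 1.5)
  e1 <- extrapolate_population(1000, dr)
  e2 <- extrapolate_population(2000, dr)
  expect_equal(e2$mean, 2 * e1$mean)

  fit <- shared_fit()
  cf <- correction_factor(fit)
  tot <- annual_totals(fit)
  mx <- apply(round_totals(fit$dataset), 1, max)
  expect_equal(cf$mean, unname(tot$mean / mx), tolerance = 1e-9)
  expect_true(all(cf$mean >= 1))
})

test_that("trend summaries transform monotonically to percent change", {
  fit <- shared_fit()
  ts <- trend_summary(fit)
  r <- fit$draws[, "lam.trend"]
  expect_equal(ts$trend[["mean"]], mean(r))
  expect_equal(ts$percent_change[["lcl"]],
               100 * (exp(unname(quantile(r, 0.025))) - 1))
  expect_equal(ts$percent_change[["ucl"]],
               100 * (exp(unname(quantile(r, 0.975))) - 1))
})

test_that("the posterior predictive check is deterministic given its seed", {
  fit <- shared_fit()
  p1 <- posterior_predictive_check(fit, seed = 5)
  p2 <- posterior_predictive_check(fit, seed = 5)
  expect_identical(p1$p_value, p2$p_value)
  expect_identical(p1$T_rep, p2$T_rep)
  expect_gte(p1$p_value, 0); expect_lte(p1$p_value, 1)
  sub <- posterior_predictive_check(fit, seed = 5, ndraws = 100)
  expect_length(sub$T_rep, 100)
})

test_that("grossly overdispersed counts fail the predictive check", {
  sim <- small_sim(65, n_transects = 25)
  ds <- sim$dataset
  # inflate the count noise far beyond the binomial mixture's variance
  set.seed(66)
  infl <- pmax(0, round(ds$counts$count *
                          exp(rnorm(nrow(ds$counts), 0, 0.8))))
  ds_bad <- survey_dataset(transform(ds$counts, count = infl),
                           ds$site_covariates, ds$obs_covariates)
  fit <- suppressWarnings(nmix_trend(ds_bad, config = quick_mcmc(seed = 4)))
  expect_lt(posterior_predictive_check(fit)$p_value, 0.05)
})

test_that("with the random effect switched off the posterior matches the MLE", {
  ds <- small_sim(67, n_transects = 25)$dataset
  ml <- nmix(ds, abundance = "water", detection = c("Year", "rain",
                                                    "vegetation"),
             nstarts = 2, hessian = TRUE)
  cfg <- trend_control(n_chains = 2, n_iter = 4000, n_burnin = 1000,
                       thin = 4, seed = 5, sigma_b_max = 1e-3)
  bay <- suppressWarnings(nmix_trend(ds, config = cfg, sample_latent = FALSE))
  # map the Bayesian year-mean coding back to the ML contrast coding
  pm <- fit_means <- colMeans(bay$draws)
  ml_se <- sqrt(pmax(diag(ml$vcov), 1e-8))
  comp <- rbind(
    trend = c(pm[["lam.trend"]], coef(ml)[["lam.trend"]],
              ml_se[["lam.trend"]]),
    wet = c(pm[["lam.water.wet"]], coef(ml)[["lam.water.wet"]],
            ml_se[["lam.water.wet"]]),
    rain = c(pm[["det.rain"]], coef(ml)[["det.rain"]], ml_se[["det.rain"]]),
    y2 = c(pm[["det.year2"]] - pm[["det.year1"]],
           coef(ml)[["det.year2"]], ml_se[["det.year2"]]))
  # posterior means within half a standard error of the MLEs
  expect_true(all(abs(comp[, 1] - comp[, 2]) < pmax(0.5 * comp[, 3], 0.03)),
              info = paste(capture.output(print(comp)), collapse = "\n"))
})

test_that("the sampler agrees with an independent JAGS implementation", {
  library(rjags)
  sim <- small_sim(68, n_transects = 15)
  ds <- sim$dataset
  fit <- suppressWarnings(nmix_trend(ds, config = trend_control(
    n_chains = 2, n_iter = 6000, n_burnin = 1500, thin = 5, seed = 6)))
  d <- fit$design
  model_str <- "
  model {
    for (s in 1:n) {
      log(lambda[s]) <- inprod(X[s,], beta[]) + b[trans[s]]
      N[s] ~ dpois(lambda[s])
      for (j in 1:J) {
        logit(p[s,j]) <- inprod(W[(s-1)*J+j,], alpha[])
        y[s,j] ~ dbin(p[s,j], N[s])
      }
    }
    for (k in 1:P) { beta[k] ~ dnorm(0, 0.01) }
    for (k in 1:Q) { alpha[k] ~ dnorm(0, 0.01) }
    for (i in 1:nT) { b[i] ~ dnorm(0, tau_b) }
    tau_b <- pow(sigma_b, -2)
    sigma_b ~ dunif(0, 10)
  }"
  data <- list(y = d$y, X = d$X, W = d$W, n = nrow(d$y), J = d$J,
               P = ncol(d$X), Q = ncol(d$W),
               trans = as.integer(d$transect), nT = nlevels(d$transect))
  inits <- function() list(N = d$maxy + 1L,
                           .RNG.name = "base::Mersenne-Twister",
                           .RNG.seed = 99)
  jm <- jags.model(textConnection(model_str), data = data, inits = inits,
                   n.chains = 2, quiet = TRUE)
  update(jm, 2000, progress.bar = "none")
  js <- coda.samples(jm, c("beta", "alpha", "sigma_b"), n.iter = 6000,
                     thin = 5, progress.bar = "none")
  jdraws <- do.call(rbind, lapply(js, as.matrix))
  jmean <- colMeans(jdraws)
  mymean <- colMeans(fit$draws)
  pairs <- rbind(c("lam.trend", "beta[2]"),
                 c("lam.water.wet", "beta[3]"),
                 c("det.rain", sprintf("alpha[%d]", which(colnames(d$W) ==
                                                            "rain"))),
                 c("sigma_b", "sigma_b"))
  for (i in seq_len(nrow(pairs))) {
    mc_sd <- sd(fit$draws[, pairs[i, 1]])
    expect_lt(abs(mymean[[pairs[i, 1]]] - jmean[[pairs[i, 2]]]),
              pmax(0.35 * mc_sd, 0.03))
  }
})
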