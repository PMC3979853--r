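test_that("link functions behave as documented", {
  expect_equal(expected_abundance(c(0, 0), c(1, 3)), 1)
  expect_equal(expected_abundance(c(log(22), 0, 0), c(1, 0, 0)), 22)
  expect_error(expected_abundance(c(1000, 0), c(1, 5)), "overflow")
  expect_error(expected_abundance(c(1, 2, 3), c(1, 5)), "dimension mismatch")

  expect_equal(detection_prob(0, 1), 0.5)
  expect_equal(detection_prob(0.65, 1), plogis(0.65))  # ~0.657
  p_seq <- detection_prob(1, cbind(seq(-8, 8, by = 0.5)))
  expect_true(all(diff(p_seq) > 0))
  expect_true(all(p_seq > 0 & p_seq < 1))
  expect_lte(detection_prob(1e6, 1), 1 - 1e-13)

  # vectorised evaluation agrees with a naive elementwise loop
  set.seed(3)
  beta <- rnorm(4); X <- matrix(rnorm(40), 10)
  loop <- vapply(seq_len(10), function(i) exp(sum(X[i, ] * beta)), 0)
  expect_equal(expected_abundance(beta, X), loop, tolerance = 1e-12)
})

test_that("marginal site likelihood matches degenerate closed forms", {
  # p = 1 collapses the mixture to the Poisson pmf
  expect_equal(site_marginal_loglik(2, 1, 3, K = 50),
               dpois(3, 2, log = TRUE), tolerance = 1e-9)
  # p = 1 on all visits with equal counts: exactly Poisson(c; lambda)
  expect_equal(site_marginal_loglik(7, c(1, 1, 1), c(5, 5, 5), K = 80),
               dpois(5, 7, log = TRUE), tolerance = 1e-9)
  expect_error(site_marginal_loglik(2, c(0.5, 0.5), c(3, 60), K = 50),
               "increase K")
  # missing visits drop out of the product
  expect_equal(site_marginal_loglik(5, c(0.4, 0.6, 0.5), c(2, NA, 1), K = 60),
               site_marginal_loglik(5, c(0.4, 0.5), c(2, 1), K = 60))
})

test_that("marginal site likelihood agrees with the brute-force oracle", {
  set.seed(11)
  for (rep in 1:20) {
    lam <- runif(1, 0.5, 30)
    J <- sample(1:4, 1)
    p <- runif(J, 0.05, 0.95)
    y <- rbinom(J, rpois(1, lam), p)
    K <- max(y) + 80
    expect_equal(site_marginal_loglik(lam, p, y, K),
                 brute_site_loglik(lam, p, y, K), tolerance = 1e-10)
  }
})

test_that("the marginal likelihood decays in a count far beyond lambda * p", {
  lam <- 8; p <- c(0.6, 0.5, 0.7); K <- 200
  for (j in 1:3) {
    grid <- ceiling(lam * p[j]) + 1:30
    ll <- vapply(grid, function(yj) {
      y <- c(4, 3, 5); y[j] <- yj
      site_marginal_loglik(lam, p, y, K)
    }, 0)
    expect_true(all(diff(ll) <= 1e-12))
  }
})

test_that("the truncated mixture is a proper distribution at small K", {
  lam <- 1; p <- c(0.4, 0.4); K <- 40
  tot <- 0
  for (y1 in 0:K) for (y2 in 0:K)
    tot <- tot + exp(site_marginal_loglik(lam, p, c(y1, y2), K))
  expect_equal(tot, 1, tolerance = 1e-8)
})

test_that("the default truncation bound has converged", {
  sim <- small_sim(21)
  ds <- sim$dataset
  spec <- nmix_spec("water", c("rain", "vegetation"))
  k <- build_design(ds, spec)$k
  set.seed(2); theta <- rnorm(k, c(2.5, rep(0, k - 1)), 0.3)
  K <- default_K(ds)
  expect_lt(abs(dataset_loglik(theta, ds, spec, K) -
                  dataset_loglik(theta, ds, spec, K + 50)), 1e-6)
})

test_that("dataset log-likelihood is additive and exchangeable over transects", {
  tt <- tiny_tables()
  ds1 <- survey_dataset(tt$counts, tt$site, tt$obs)
  dup <- function(d) { d2 <- d; d2$transect <- 2; rbind(d, d2) }
  ds2 <- survey_dataset(dup(tt$counts), dup(tt$site), dup(tt$obs))
  # vegetation on detection: a site covariate, so no data-dependent
  # standardisation enters (rain's z-scores would differ after duplication)
  spec <- nmix_spec("water", "vegetation")
  k <- build_design(ds1, spec)$k
  set.seed(4); theta <- rnorm(k, 0, 0.4); theta[1] <- 1
  expect_equal(dataset_loglik(theta, ds2, spec, 100),
               2 * dataset_loglik(theta, ds1, spec, 100), tolerance = 1e-12)

  # permuting transect labels (hence row order) leaves the value unchanged
  ds <- small_sim(22)$dataset
  perm <- sample(unique(ds$counts$transect))
  relab <- function(d) { d$transect <- match(d$transect, perm); d }
  dsp <- survey_dataset(relab(ds$counts), relab(ds$site_covariates),
                        relab(ds$obs_covariates))
  spec2 <- nmix_spec("water", c("Year", "vegetation"))
  k2 <- build_design(ds, spec2)$k
  set.seed(5); th2 <- rnorm(k2, 0, 0.3); th2[1] <- 2
  expect_equal(dataset_loglik(th2, dsp, spec2, 120),
               dataset_loglik(th2, ds, spec2, 120), tolerance = 1e-12)
})

test_that("dataset log-likelihood matches an oracle built from raw tables", {
  # independent path: no DesignMatrices, covariate math done by hand
  sim <- small_sim(23, n_transects = 6)
  ds <- sim$dataset
  spec <- nmix_spec("water", c("Year", "rain", "vegetation"))
  k <- build_design(ds, spec)$k
  expect_equal(k, 11)  # 5 abundance + (intercept, year2, rain, 3 vegetation)
  set.seed(6); theta <- rnorm(k, 0, 0.3); theta[1] <- 2
  beta <- theta[1:5]; alpha <- theta[6:11]
  obs <- ds$obs_covariates
  rain_z <- (obs$rain_mm - mean(obs$rain_mm)) / sd(obs$rain_mm)
  oracle <- 0
  site <- ds$site_covariates
  for (i in seq_len(nrow(site))) {
    lam <- exp(beta[1] + beta[2] * (site$year[i] - min(ds$years)) +
                 sum(beta[3:5] * unlist(site[i, paste0("water", 2:4)])))
    rows <- which(obs$transect == site$transect[i] & obs$year == site$year[i])
    p <- plogis(alpha[1] + alpha[2] * (site$year[i] == max(ds$years)) +
                  alpha[3] * rain_z[rows] +
                  sum(alpha[4:6] * unlist(site[i, paste0("veg", 2:4)])))
    y <- ds$counts$count[ds$counts$transect == site$transect[i] &
                           ds$counts$year == site$year[i]]
    oracle <- oracle + brute_site_loglik(lam, p, y, 200)
  }
  expect_equal(dataset_loglik(theta, ds, spec, 200), oracle,
               tolerance = 1e-8)
})
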