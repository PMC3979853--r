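test_that("generation is deterministic given the seed", {
  a <- simulate_survey(generator_config(n_transects = 8, n_years = 2, seed = 51))
  b <- simulate_survey(generator_config(n_transects = 8, n_years = 2, seed = 51))
  expect_identical(a$dataset$counts, b$dataset$counts)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_survey(generator_config(n_transects = 8, n_years = 2, seed = 52))
  expect_false(identical(a$dataset$counts, c_$dataset$counts))
})

test_that("generator configuration is validated", {
  expect_error(generator_config(n_transects = 5), "seed")
  expect_error(generator_config(seed = 1,
                                habitat_probs = list(veg = c(0.5, 0.5, 0, 0.2),
                                                     water = rep(0.25, 4),
                                                     litter = rep(0.25, 4))),
               "summing to 1")
})

test_that("habitat profiles follow the 5-point field protocol", {
  ds <- small_sim(53)$dataset
  pm <- as.matrix(ds$site_covariates[-(1:2)])
  expect_true(all(abs(pm * 5 - round(pm * 5)) < 1e-12))  # multiples of 0.2
  for (block in list(1:4, 5:8, 9:12))
    expect_equal(unname(rowSums(pm[, block])), rep(1, nrow(pm)))
})

test_that("default generating parameters carry the published effect sizes", {
  pars <- default_study_parameters()
  expect_equal(unname(pars$beta_water), c(0.51, 0.36, 0.26))
  expect_equal(unname(pars$alpha_veg), c(0.65, 0.70, 0.15))
  expect_equal(pars$alpha_rain, 0.01)
  effects <- unlist(pars)
  expect_true(all(is.finite(effects) & abs(effects) < 5))
})

test_that("the truth record stores every latent quantity consistently", {
  sim <- small_sim(54)
  tr <- sim$truth
  n <- nrow(sim$dataset$site_covariates)
  expect_length(tr$N, n)
  expect_length(tr$lambda, n)
  expect_equal(dim(tr$p), c(n, sim$dataset$J))
  expect_true(all(tr$p > 0 & tr$p < 1))
  expect_true(all(tr$lambda > 0))
  expect_true(all(tr$N >= 0))
  # counts can never exceed the latent abundance of their site-year
  y <- matrix(sim$dataset$counts$count, n, sim$dataset$J, byrow = TRUE)
  expect_true(all(y <= tr$N))
})

test_that("study-scale simulations match the survey's count summaries", {
  ds <- simulate_survey(generator_config(seed = 55))$dataset  # 50 x 3 x 3
  y <- ds$counts$count
  expect_gt(mean(y), 9); expect_lt(mean(y), 15)   # ~12 per transect visit
  expect_gte(min(y), 0)
  expect_gt(max(y), 25); expect_lt(max(y), 80)    # range comparable to 0-51
  expect_gt(sd(y), 6); expect_lt(sd(y), 12)       # ~8.8
})

test_that("with no heterogeneity the latent abundances are Poisson-dispersed", {
  pars <- default_study_parameters()
  pars$sigma_b <- 0; pars$trend <- 0; pars$beta_water <- c(0, 0, 0)
  sim <- simulate_survey(generator_config(n_transects = 1000, n_years = 2,
                                          params = pars, seed = 56))
  N <- sim$truth$N  # 2000 site-years, constant lambda
  expect_equal(var(N) / mean(N), 1, tolerance = 0.1)
})

test_that("realised detection frequency converges to the generated p", {
  sim <- simulate_survey(generator_config(n_transects = 600, n_years = 3,
                                          seed = 57))
  tr <- sim$truth
  y <- matrix(sim$dataset$counts$count, length(tr$N), 3, byrow = TRUE)
  freq <- sum(y) / (3 * sum(tr$N))
  expected <- sum(tr$N * rowSums(tr$p)) / (3 * sum(tr$N))  # exposure-weighted p
  expect_lt(abs(freq - expected) / expected, 0.01)
})

test_that("golden fixtures regenerate bit-for-bit from their seed", {
  dir <- withr::local_tempdir()
  make_goldens(dir)
  for (f in c("counts.csv", "site_covariates.csv", "obs_covariates.csv",
              "truth.json"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(golden_dir(), f)),
                     label = f)
})

test_that("golden data reproduce the frozen marginal likelihood", {
  ds <- read_survey_dataset(file.path(golden_dir(), "counts.csv"),
                            file.path(golden_dir(), "site_covariates.csv"),
                            file.path(golden_dir(), "obs_covariates.csv"))
  tr <- simulate_survey(generator_config(n_transects = 5, n_years = 2,
                                         seed = 42))$truth
  n <- length(tr$N)
  y <- matrix(ds$counts$count, n, 3, byrow = TRUE)
  ll <- sum(vapply(seq_len(n), function(s)
    site_marginal_loglik(tr$lambda[s], tr$p[s, ], y[s, ], K = 300), 0))
  # reference value computed once with the plain-R term-by-term oracle
  expect_equal(ll, -74.4449637603, tolerance = 1e-10)
})
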