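#' MCMC configuration for the Bayesian trend model
#'
#' Three profiles are provided: `"paper"` (3 chains x 350,000 iterations,
#' 50,000 burn-in, thin 100 — the full analysis setting), `"desk"` (3 x
#' 10,000, 2,000 burn-in, thin 5 — the package default, sized so that the
#' adaptive sampler passes the R-hat < 1.1 check reliably on study-scale
#' data) and `"power"` (2 x 12,000, 2,000 burn-in, thin 10 — the
#' per-simulation setting used inside the power analysis, where only the
#' trend's credible interval is needed).
#'
#' @param profile one of `"desk"`, `"paper"`, `"power"`.
#' @param n_chains,n_iter,n_burnin,thin override the profile's settings.
#' @param seed integer seed; chains use derived sub-seeds.
#' @param chain_seeds optional integer vector of explicit per-chain seeds
#'   (overrides the derivation from `seed`; passing identical seeds
#'   produces identical chains, which the fit flags as degenerate).
#' @param K truncation bound (default: max observed count + 100).
#' @param prior_sd SD of the normal prior on every regression coefficient
#'   and yearly detection intercept (default 10, effectively flat on the
#'   link scales).
#' @param sigma_b_max upper bound of the uniform prior on the transect
#'   random-effect SD (default 10).
#' @return A list of class `trend_control`.
#' @export
trend_control <- function(profile = c("desk", "paper", "power"),
                          n_chains = NULL, n_iter = NULL, n_burnin = NULL,
                          thin = NULL, seed = 1, K = NULL,
                          prior_sd = 10, sigma_b_max = 10,
                          chain_seeds = NULL) {
  profile <- match.arg(profile)
  def <- switch(profile,
                desk = list(3L, 10000L, 2000L, 5L),
                paper = list(3L, 350000L, 50000L, 100L),
                power = list(2L, 12000L, 2000L, 10L))
  cfg <- list(profile = profile,
              n_chains = as.integer(n_chains %||% def[[1]]),
              n_iter = as.integer(n_iter %||% def[[2]]),
              n_burnin = as.integer(n_burnin %||% def[[3]]),
              thin = as.integer(thin %||% def[[4]]),
              seed = as.integer(seed), K = K,
              prior_sd = prior_sd, sigma_b_max = sigma_b_max,
              chain_seeds = if (!is.null(chain_seeds)) as.integer(chain_seeds))
  if (cfg$n_burnin >= cfg$n_iter)
    stop("n_burnin must be smaller than n_iter", call. = FALSE)
  if (cfg$n_chains < 2)
    stop("at least 2 chains are required for convergence diagnostics",
         call. = FALSE)
  if (!is.null(cfg$chain_seeds) && length(cfg$chain_seeds) != cfg$n_chains)
    stop("chain_seeds must have one seed per chain", call. = FALSE)
  structure(cfg, class = "trend_control")
}

# split-half R-hat for a draws matrix (iterations x chains)
split_rhat <- function(x) {
  n <- nrow(x) %/% 2
  if (n < 2) return(NA_real_)
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  mns <- colMeans(halves)
  vrs <- apply(halves, 2, var)
  W <- mean(vrs)
  B <- n * var(mns)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the Bayesian hierarchical trend model
#'
#' The final model of the analysis pipeline: latent transect-year abundance
#' `N_it ~ Poisson(lambda_it)` with
#' `log lambda_it = beta0 + b_i + r * (t-1) + ` water-depth effects and a
#' random transect effect `b_i ~ N(0, sigma_b^2)` (annual surveys of the
#' same transect are not independent), and counts
#' `y_itj ~ Binomial(N_it, p_itj)` with
#' `logit p_itj = alpha_year[t] + alpha_rain * rain_z + ` vegetation-height
#' effects (yearly detection intercepts are independent fixed effects).
#'
#' Inference runs on the marginal likelihood — the latent `N_it` are summed
#' out up to `K` with log-sum-exp — using blocked random-walk Metropolis
#' updates: one joint adaptive block for all fixed effects (running-history
#' proposal covariance with diminishing adaptation), vectorised
#' per-transect updates of the random effects, and a log-scale random walk
#' for `sigma_b`.  For retained draws the latent abundances are re-drawn from
#' their discrete full conditional, giving exact posterior samples of every
#' `N_it` for the derived population quantities.  Priors: `N(0, prior_sd^2)`
#' on all coefficients, `Uniform(0, sigma_b_max)` on `sigma_b`.
#'
#' @param dataset a [survey_dataset()].
#' @param abundance site covariate on abundance (default `"water"`).
#' @param detection detection terms (default `Year + rain + vegetation`, the
#'   selected structure).
#' @param config a [trend_control()].
#' @param sample_latent draw latent abundances for retained iterations
#'   (needed for [annual_totals()], [correction_factor()],
#'   [posterior_predictive_check()]; switch off inside power simulations
#'   where only the trend is needed).
#' @return An object of class `nmix_trend`: posterior draws (`draws`,
#'   iterations x parameters with chain ids; `b_draws`; `N_draws` if
#'   requested), a summary table (`summary`: mean, sd, 2.5%, 97.5%, Rhat),
#'   `converged` (all split-Rhat < 1.1), `degenerate` (identical chains,
#'   diagnostics meaningless), the designs and the dataset.
#' @seealso [trend_summary()], [annual_totals()], [correction_factor()],
#'   [posterior_predictive_check()]
#' @export
nmix_trend <- function(dataset, abundance = "water",
                       detection = c("Year", "rain", "vegetation"),
                       config = trend_control(), sample_latent = TRUE) {
  stopifnot(inherits(dataset, "survey_dataset"),
            inherits(config, "trend_control"))
  spec <- nmix_spec(abundance, detection)
  coding <- if ("Year" %in% spec$detection) "means" else "contrast"
  design <- build_design(dataset, spec, year_coding = coding)
  K <- as.integer(config$K %||% default_K(dataset))
  if (any(design$maxy > K))
    stop("truncation bound K below maximum observed count", call. = FALSE)

  y <- design$y; storage.mode(y) <- "integer"
  A <- nm_lchoose_table(y, K)
  n <- nrow(y); J <- ncol(y)
  X <- design$X; W <- design$W
  P <- ncol(X); Q <- ncol(W)
  trans_idx <- as.integer(design$transect)
  nT <- nlevels(design$transect)
  site_of_trans <- split(seq_len(n), trans_idx)
  maxy <- design$maxy
  prior_sd <- config$prior_sd; sb_max <- config$sigma_b_max

  sll <- function(eta_lam, eta_p)
    nm_siteyear_loglik(eta_lam, eta_p, y, A, maxy, K)

  # cheap ML fit of the fixed effects (no random effect): supplies
  # overdispersed-but-central chain starts and a proposal covariance that
  # already encodes the trend / yearly-detection ridge
  D <- P + Q
  ml_mode <- NULL; ml_cov <- NULL
  negll <- function(th) {
    v <- -sum(sll(drop(X %*% th[seq_len(P)]),
                  matrix(drop(W %*% th[-seq_len(P)]), n, J, byrow = TRUE)))
    if (!is.finite(v)) 1e10 else v
  }
  st <- c(log(mean(maxy) + 0.5), rep(0, D - 1))
  op <- tryCatch(optim(st, negll, method = "BFGS", hessian = TRUE,
                       control = list(maxit = 300, reltol = 1e-8)),
                 error = function(e) NULL)
  if (!is.null(op) && all(is.finite(op$par))) {
    ml_mode <- op$par
    ml_cov <- tryCatch(solve(op$hessian), error = function(e) NULL)
    if (!is.null(ml_cov) &&
        (any(!is.finite(ml_cov)) || any(diag(ml_cov) <= 0) ||
         inherits(tryCatch(chol(ml_cov), error = function(e) e), "error")))
      ml_cov <- NULL
  }

  n_keep <- (config$n_iter - config$n_burnin) %/% config$thin
  par_names <- c(paste0("lam.", colnames(X)), paste0("det.", colnames(W)),
                 "sigma_b")
  chains <- vector("list", config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    set.seed(if (!is.null(config$chain_seeds)) config$chain_seeds[ch]
             else (config$seed + 104729L * ch) %% 2147483647L)
    if (!is.null(ml_mode)) {
      sds <- if (!is.null(ml_cov)) sqrt(diag(ml_cov)) else rep(0.1, D)
      th0 <- ml_mode + rnorm(D, 0, pmin(2 * sds, 0.5))
    } else {
      th0 <- c(log(mean(maxy) + 0.5), rep(0, D - 1)) + rnorm(D, 0, 0.2)
    }
    beta <- th0[seq_len(P)]; alpha <- th0[-seq_len(P)]
    b <- rnorm(nT, 0, min(0.1, sb_max / 3))
    sigma <- runif(1, 0.2, 1) * min(1, sb_max)  # inside the prior support

    eta_lam <- drop(X %*% beta) + b[trans_idx]
    eta_p <- matrix(drop(W %*% alpha), n, J, byrow = TRUE)
    ll <- sll(eta_lam, eta_p)

    # adaptive RW-Metropolis state: all fixed effects move as one joint
    # block (the trend and the yearly detection intercepts are strongly
    # correlated in the posterior, so a joint proposal with an adapted
    # covariance mixes far better than separate blocks).  The proposal
    # covariance is the running full-history covariance (Haario-style
    # adaptive Metropolis with diminishing adaptation), rescaled towards a
    # 0.234 acceptance rate.
    Lf <- if (!is.null(ml_cov)) t(chol(2.38^2 / D * ml_cov)) else diag(0.05, D)
    ls_f <- 0; s_re <- 0.3; s_sig <- 0.3
    acc <- c(fix = 0, re = 0, sig = 0)
    n_rw <- 0
    tot <- c(n_rw = 0, a_rw = 0)
    if (!is.null(ml_cov)) {
      # seed the running moments with the ML covariance (200 pseudo-draws)
      run_mu <- ml_mode; run_S <- ml_cov * 200; run_n <- 200
    } else {
      run_mu <- c(beta, alpha); run_S <- matrix(0, D, D); run_n <- 1
    }

    keep_par <- matrix(NA_real_, n_keep, P + Q + 1)
    keep_b <- matrix(NA_real_, n_keep, nT)
    keep_N <- if (sample_latent) matrix(NA_integer_, n_keep, n) else NULL
    ki <- 0L
    # unthinned post-burn-in draws, used only for convergence diagnostics
    diag_par <- matrix(NA_real_, config$n_iter - config$n_burnin, P + Q + 1)

    for (it in seq_len(config$n_iter)) {
      # joint fixed-effects block (abundance + detection coefficients)
      cur <- c(beta, alpha)
      prop <- cur + exp(ls_f) * drop(Lf %*% rnorm(D))
      bp_ <- prop[seq_len(P)]; ap_ <- prop[-seq_len(P)]
      eta_new <- drop(X %*% bp_) + b[trans_idx]
      ep_new <- matrix(drop(W %*% ap_), n, J, byrow = TRUE)
      ll_new <- sll(eta_new, ep_new)
      lr <- sum(ll_new) - sum(ll) +
        sum(dnorm(prop, 0, prior_sd, log = TRUE) -
              dnorm(cur, 0, prior_sd, log = TRUE))
      n_rw <- n_rw + 1
      tot["n_rw"] <- tot["n_rw"] + 1
      if (is.finite(lr) && log(runif(1)) < lr) {
        beta <- bp_; alpha <- ap_
        eta_lam <- eta_new; eta_p <- ep_new; ll <- ll_new
        acc["fix"] <- acc["fix"] + 1
        tot["a_rw"] <- tot["a_rw"] + 1
      }

      # random transect effects: vectorised proposal, per-transect accept
      # (valid because the likelihood factorises over transects given the
      # fixed effects)
      bp <- b + s_re * rnorm(nT)
      eta_new <- eta_lam + (bp - b)[trans_idx]
      ll_new <- sll(eta_new, eta_p)
      dll <- rowsum(ll_new - ll, trans_idx)[, 1] +
        dnorm(bp, 0, sigma, log = TRUE) - dnorm(b, 0, sigma, log = TRUE)
      take <- is.finite(dll) & log(runif(nT)) < dll
      if (any(take)) {
        b[take] <- bp[take]
        idx <- unlist(site_of_trans[take], use.names = FALSE)
        eta_lam[idx] <- eta_new[idx]
        ll[idx] <- ll_new[idx]
        acc["re"] <- acc["re"] + mean(take)
      }

      # recentering sweep along the intercept / mean-random-effect ridge:
      # shifting every b_i by delta and beta0 by -delta leaves the
      # likelihood unchanged, and delta has a closed-form Gaussian full
      # conditional given the priors, so this is an exact (always-accepted)
      # Gibbs move that removes the slow beta0 <-> mean(b) random walk
      tau_d <- nT / sigma^2 + 1 / prior_sd^2
      mu_d <- (-nT * mean(b) / sigma^2 + beta[1] / prior_sd^2) / tau_d
      dlt0 <- rnorm(1, mu_d, 1 / sqrt(tau_d))
      b <- b + dlt0
      beta[1] <- beta[1] - dlt0

      # sigma_b: random walk on log scale, Uniform(0, sb_max) prior
      sp <- sigma * exp(s_sig * rnorm(1))
      if (sp < sb_max) {
        lr <- sum(dnorm(b, 0, sp, log = TRUE) -
                    dnorm(b, 0, sigma, log = TRUE)) + log(sp) - log(sigma)
        if (is.finite(lr) && log(runif(1)) < lr) {
          sigma <- sp
          acc["sig"] <- acc["sig"] + 1
        }
      }

      # diminishing adaptation (running moments over the whole history)
      xx <- c(beta, alpha)
      run_n <- run_n + 1
      dlt <- xx - run_mu
      run_mu <- run_mu + dlt / run_n
      run_S <- run_S + tcrossprod(dlt, xx - run_mu)
      if (it %% 50 == 0) {
        step <- 2 / sqrt(it / 50)
        if (n_rw > 0) ls_f <- ls_f + step * (acc["fix"] / n_rw - 0.234)
        if (it <= config$n_burnin) {
          s_re <- s_re * exp(0.6 * (acc["re"] / 25 - 0.4))
          s_sig <- s_sig * exp(0.6 * (acc["sig"] / 50 - 0.4))
        }
        acc[] <- 0; n_rw <- 0
      }
      if (it %% 200 == 0 && it >= 400)
        Lf <- t(chol(2.38^2 / D * (run_S / (run_n - 1) + diag(1e-8, D))))

      if (it > config$n_burnin) {
        diag_par[it - config$n_burnin, ] <- c(beta, alpha, sigma)
        if ((it - config$n_burnin) %% config$thin == 0) {
          ki <- ki + 1L
          keep_par[ki, ] <- c(beta, alpha, sigma)
          keep_b[ki, ] <- b
          if (sample_latent)
            keep_N[ki, ] <- nm_draw_latent(eta_lam, eta_p, y, A, maxy, K)
        }
      }
    }
    chains[[ch]] <- list(par = keep_par, b = keep_b, N = keep_N,
                         diag = diag_par,
                         mix = c(rw_accept = unname(tot["a_rw"] /
                                                      max(tot["n_rw"], 1))))
  }

  par_arr <- lapply(chains, `[[`, "par")
  draws <- do.call(rbind, par_arr)
  colnames(draws) <- par_names
  chain_id <- rep(seq_len(config$n_chains), each = n_keep)

  diag_arr <- lapply(chains, `[[`, "diag")
  rhat <- vapply(seq_along(par_names), function(j)
    split_rhat(sapply(diag_arr, function(m) m[, j])), 0)
  names(rhat) <- par_names
  degenerate <- config$n_chains >= 2 &&
    all(vapply(seq_along(par_arr)[-1],
               function(i) identical(par_arr[[i]], par_arr[[1]]), TRUE))
  if (degenerate) rhat[] <- 1  # no between-chain information whatsoever
  converged <- !degenerate && all(rhat < 1.1, na.rm = TRUE)
  if (degenerate)
    warning("chains are identical draw-for-draw; R-hat diagnostics are ",
            "meaningless (degenerate initialisation)", call. = FALSE)
  else if (!converged)
    warning("MCMC did not converge: max split R-hat = ",
            round(max(rhat, na.rm = TRUE), 3), call. = FALSE)

  qs <- t(apply(draws, 2, quantile, c(0.025, 0.975)))
  summ <- data.frame(mean = colMeans(draws), sd = apply(draws, 2, sd),
                     lcl = qs[, 1], ucl = qs[, 2], Rhat = rhat)

  structure(list(draws = draws, chain_id = chain_id,
                 mixing = t(sapply(chains, `[[`, "mix")),
                 b_draws = do.call(rbind, lapply(chains, `[[`, "b")),
                 N_draws = if (sample_latent)
                   do.call(rbind, lapply(chains, `[[`, "N")) else NULL,
                 summary = summ, rhat = rhat, converged = converged,
                 degenerate = degenerate, config = config, spec = spec,
                 design = design, K = K, dataset = dataset,
                 par_names = par_names, P = P, Q = Q),
            class = "nmix_trend")
}

#' @export
print.nmix_trend <- function(x, digits = 3, ...) {
  cat("Bayesian binomial mixture trend model:", x$spec$label,
      "+ random transect effect\n")
  cat(sprintf("  %d chains x %d iterations (%d burn-in, thin %d); %s\n",
              x$config$n_chains, x$config$n_iter, x$config$n_burnin,
              x$config$thin,
              if (x$degenerate) "DEGENERATE chains"
              else if (x$converged) "converged (all R-hat < 1.1)"
              else sprintf("NOT converged (max R-hat %.3f)", max(x$rhat))))
  print(round(x$summary, digits))
  invisible(x)
}

#' @export
summary.nmix_trend <- function(object, ...) object$summary

#' @export
coef.nmix_trend <- function(object, ...) {
  setNames(object$summary$mean, rownames(object$summary))
}

#' @export
plot.nmix_trend <- function(x, pars = "lam.trend", ...) {
  n_keep <- nrow(x$draws) / x$config$n_chains
  op <- par(mfrow = c(length(pars), 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (pp in pars) {
    m <- matrix(x$draws[, pp], n_keep, x$config$n_chains)
    matplot(m, type = "l", lty = 1, xlab = "retained iteration", ylab = pp,
            main = pp, ...)
  }
  invisible(x)
}

trend_draws <- function(fit) fit$draws[, "lam.trend"]

#' Posterior summary of the population trend
#'
#' Reports the posterior of the yearly log-linear trend `r` and its
#' interpretation as a percent change per year, `100 * (exp(r) - 1)`.
#'
#' @param fit an [nmix_trend()] fit.
#' @return A list with `trend` (mean, sd, lcl, ucl on the log scale) and
#'   `percent_change` (the same posterior mapped through the exponential).
#' @export
trend_summary <- function(fit) {
  stopifnot(inherits(fit, "nmix_trend"))
  r <- trend_draws(fit)
  pc <- 100 * (exp(r) - 1)
  ci <- unname(quantile(r, c(0.025, 0.975)))
  list(trend = c(mean = mean(r), sd = sd(r), lcl = ci[1], ucl = ci[2]),
       # the percent-change interval is the monotone transform of the
       # trend interval (quantiles commute with monotone maps)
       percent_change = c(mean = mean(pc), sd = sd(pc),
                          lcl = 100 * (exp(ci[1]) - 1),
                          ucl = 100 * (exp(ci[2]) - 1)))
}

#' Posterior of the annual population totals
#'
#' Sums the latent super-population abundances over all transects for each
#' year, per retained draw.  By construction every total is at least the
#' year's maximum round total.
#'
#' @param fit an [nmix_trend()] fit with latent draws
#'   (`sample_latent = TRUE`).
#' @return A data frame (year, mean, sd, lcl, ucl) with the per-draw totals
#'   attached as attribute `"draws"` (draws x years).
#' @export
annual_totals <- function(fit) {
  stopifnot(inherits(fit, "nmix_trend"))
  if (is.null(fit$N_draws))
    stop("fit has no latent abundance draws; rerun with sample_latent = TRUE",
         call. = FALSE)
  years <- fit$dataset$years
  ind <- outer(fit$design$year_of_site, seq_along(years), `==`) + 0
  tot <- fit$N_draws %*% ind
  colnames(tot) <- years
  out <- data.frame(year = years, mean = colMeans(tot),
                    sd = apply(tot, 2, sd),
                    lcl = apply(tot, 2, quantile, 0.025),
                    ucl = apply(tot, 2, quantile, 0.975))
  rownames(out) <- NULL
  attr(out, "draws") <- tot
  out
}

#' Detection-correction factor relative to the best raw count
#'
#' The ratio of the model-estimated super-population total to the maximum
#' round total (the best single uncorrected survey round of the year) — the
#' factor by which a traditional census underestimates the population.
#'
#' @param x an [nmix_trend()] fit, or a numeric vector of estimated totals
#'   (posterior draws or a single point estimate).
#' @param ... method arguments: for the default method, `round_counts`, the
#'   raw per-round totals of the matching year.
#' @return For the fit method, a data frame (year, max_round_count, mean,
#'   lcl, ucl) with per-draw factors as attribute `"draws"`.  For the
#'   default method, `x / max(round_counts)`.
#' @examples
#' correction_factor(780, round_counts = c(542, 574, 608))  # 1.28
#' @export
correction_factor <- function(x, ...) UseMethod("correction_factor")

#' @rdname correction_factor
#' @export
correction_factor.default <- function(x, round_counts, ...) {
  stopifnot(is.numeric(x), is.numeric(round_counts))
  mx <- max(round_counts, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stop("correction factor undefined: maximum round count is zero",
         call. = FALSE)
  x / mx
}

#' @rdname correction_factor
#' @export
correction_factor.nmix_trend <- function(x, ...) {
  tot <- annual_totals(x)
  draws <- attr(tot, "draws")
  rt <- round_totals(x$dataset)
  mx <- apply(rt, 1, max, na.rm = TRUE)
  if (any(mx <= 0))
    stop("correction factor undefined: a year has zero maximum round count",
         call. = FALSE)
  fd <- sweep(draws, 2, mx, "/")
  out <- data.frame(year = tot$year, max_round_count = mx,
                    mean = colMeans(fd),
                    lcl = apply(fd, 2, quantile, 0.025),
                    ucl = apply(fd, 2, quantile, 0.975))
  rownames(out) <- NULL
  attr(out, "draws") <- fd
  out
}

#' Correct an uncorrected full-count census
#'
#' Multiplies a traditional full-count total by the posterior of the
#' detection-correction factor, giving a detection-corrected population
#' estimate with a credible interval.
#'
#' @param full_count positive integer: the uncorrected census total.
#' @param factor numeric vector of correction-factor draws (or a single
#'   factor).
#' @return A list with `estimate`, `lcl`, `ucl` (rounded to whole birds)
#'   and the unrounded `mean`.
#' @examples
#' extrapolate_population(2594, 780 / 608)
#' @export
extrapolate_population <- function(full_count, factor) {
  stopifnot(length(full_count) == 1, full_count > 0, is.numeric(factor))
  draws <- full_count * factor
  list(estimate = round(mean(draws)),
       lcl = round(unname(quantile(draws, 0.025))),
       ucl = round(unname(quantile(draws, 0.975))),
       mean = mean(draws))
}

#' Posterior predictive check of model fit
#'
#' For every retained draw, replicate counts are simulated from the fitted
#' model (`y_rep ~ Binomial(N_it, p_itj)` at that draw's latent abundances
#' and detection probabilities) and a Pearson chi-square discrepancy
#' `T = sum (y - E)^2 / (E + 0.5)` with `E = N_it * p_itj` is computed for
#' the replicated and the observed data.  The Bayesian p-value is the
#' fraction of draws with `T_rep >= T_obs`; values near 0.5 indicate
#' adequate fit, values near 0 or 1 systematic misfit.  A secondary
#' calibration summary is the least-squares slope of observed counts on
#' posterior-mean predicted counts (near 1 when the model reproduces the
#' count magnitudes).
#'
#' @param fit an [nmix_trend()] fit with latent draws.
#' @param seed seed for the replicate simulations (the check is
#'   deterministic given the fit and the seed).
#' @param ndraws optionally use only an evenly spaced subset of this many
#'   retained draws (the p-value needs far fewer draws than the posterior
#'   summaries).
#' @return A list of class `nmix_ppc`: `p_value`, `slope`, and the per-draw
#'   discrepancies `T_obs`, `T_rep`.
#' @export
posterior_predictive_check <- function(fit, seed = 1, ndraws = NULL) {
  stopifnot(inherits(fit, "nmix_trend"))
  if (is.null(fit$N_draws))
    stop("fit has no latent abundance draws; rerun with sample_latent = TRUE",
         call. = FALSE)
  set.seed(seed)
  y <- fit$design$y
  obs_vec <- as.vector(y)
  miss <- is.na(obs_vec)
  W <- fit$design$W
  n <- nrow(y); J <- ncol(y)
  use <- seq_len(nrow(fit$draws))
  if (!is.null(ndraws) && ndraws < length(use))
    use <- unique(round(seq(1, length(use), length.out = ndraws)))
  nd <- length(use)
  alpha_cols <- fit$P + seq_len(fit$Q)
  T_obs <- T_rep <- numeric(nd)
  pred_sum <- numeric(n * J)
  for (d in seq_len(nd)) {
    alpha <- fit$draws[use[d], alpha_cols]
    p <- matrix(plogis(drop(W %*% alpha)), n, J, byrow = TRUE)
    N <- fit$N_draws[use[d], ]
    E <- as.vector(N * p)
    yrep <- rbinom(n * J, rep(N, J), as.vector(p))
    T_obs[d] <- sum(((obs_vec - E)^2 / (E + 0.5))[!miss])
    T_rep[d] <- sum(((yrep - E)^2 / (E + 0.5))[!miss])
    pred_sum <- pred_sum + E
  }
  pred <- pred_sum / nd
  slope <- unname(coef(lm(obs_vec[!miss] ~ pred[!miss]))[2])
  structure(list(p_value = mean(T_rep >= T_obs), slope = slope,
                 T_obs = T_obs, T_rep = T_rep),
            class = "nmix_ppc")
}

#' @export
print.nmix_ppc <- function(x, ...) {
  cat(sprintf("Posterior predictive check: Bayesian p-value = %.2f, slope = %.3f\n",
              x$p_value, x$slope))
  invisible(x)
}
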